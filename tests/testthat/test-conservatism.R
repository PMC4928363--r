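test_that("count matrices separate proteins (architectures) and domains (families)", {
  d <- rbind(dom_row("G1|P1", "GH5", 100L, 200L),
             dom_row("G1|P2", "GH5", 100L, 200L),
             dom_row("G1|P2", "CBM2", 300L, 380L))
  arch <- build_architectures(d)
  cm <- count_matrices(arch)
  expect_equal(sort(colnames(cm$architecture)), c("GH5", "GH5-CBM2"))
  expect_true(all(cm$architecture == 1L))
  expect_equal(unname(cm$family[, "GH5"]), 2L)
  expect_identical(rownames(cm$architecture), rownames(cm$family))
})

test_that("genomes without target proteins get all-zero rows", {
  pr <- make_proteome(proteome_spec(3, c("GH5" = 1), seed = 3))
  arch <- build_architectures(
    resolve_overlaps(filter_hits(pr$hits)),
    pr$proteins[, c("protein_id", "genome_id", "length")])
  cm <- count_matrices(arch, genome_ids = c("G0001", "GZERO"))
  expect_true(all(cm$architecture["GZERO", ] == 0L))
  expect_true(all(cm$family["GZERO", ] == 0L))
})

test_that("bray_curtis equals the direct formula", {
  set.seed(42)
  m <- matrix(rpois(20, 3), nrow = 5, ncol = 4,
              dimnames = list(paste0("g", 1:5), NULL))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d, oracle_bray(m), tolerance = 1e-12, ignore_attr = TRUE)
  # identical rows -> 0; disjoint rows -> 1
  m2 <- rbind(a = c(1, 2, 0, 0), b = c(1, 2, 0, 0), c = c(0, 0, 3, 1))
  d2 <- as.matrix(bray_curtis(m2))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # all-zero pair convention
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  d3 <- as.matrix(bray_curtis(m3))
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 1)
})

test_that("bray_curtis is invariant to column permutation", {
  set.seed(5)
  m <- matrix(rpois(24, 2), nrow = 4)
  expect_equal(bray_curtis(m), bray_curtis(m[, sample(ncol(m))]))
})

test_that("average-linkage merge heights match the quadratic UPGMA oracle", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(runif(6 * 3), nrow = 6,
                dimnames = list(paste0("g", 1:6), NULL))
    d <- dist(x)
    h <- hclust_tree(d, linkage = "average")
    expect_equal(sort(h$height), oracle_upgma_heights(d), tolerance = 1e-12)
    expect_setequal(h$labels, paste0("g", 1:6))
    # monotone merge heights
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("two and three item clusterings behave as expected", {
  d2 <- as.dist(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  h2 <- hclust_tree(d2)
  expect_equal(h2$height, 0.3)
  m <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h3 <- hclust_tree(as.dist(m))
  expect_equal(h3$height[1], 0.1)  # A,B join first
  nwk <- dendrogram_newick(h3)
  expect_match(nwk, "^\\(")
  expect_setequal(ape::read.tree(text = nwk)$tip.label, c("A", "B", "C"))
})

test_that("mantel r is exactly 1 on self-comparison", {
  set.seed(17)
  d <- dist(matrix(runif(12), 6))
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)  # observed beats every permutation
})

test_that("mantel p matches exhaustive 4! enumeration", {
  set.seed(23)
  for (i in 1:5) {
    m1 <- as.matrix(dist(matrix(runif(8), 4)))
    m2 <- as.matrix(dist(matrix(runif(8), 4)))
    perms <- all_perms(4L)
    mt <- mantel_test(m1, m2, perms = perms)
    want <- oracle_mantel_exact(m1, m2, perms)
    expect_equal(mt$r, want$r, tolerance = 1e-12)
    expect_equal(mt$p, want$p, tolerance = 1e-12)
    expect_gte(mt$p, 1 / (nrow(perms) + 1))
    expect_lte(mt$p, 1)
  }
})

test_that("mantel agrees with an independent implementation on r", {
  set.seed(29)
  d1 <- dist(matrix(runif(16), 8))
  d2 <- dist(matrix(runif(16), 8))
  mt <- mantel_test(d1, d2, n_perm = 99, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(mt$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel rejects mismatched or degenerate input", {
  d1 <- as.matrix(dist(matrix(runif(8), 4)))
  rownames(d1) <- colnames(d1) <- letters[1:4]
  d2 <- d1; rownames(d2) <- colnames(d2) <- letters[2:5]
  expect_error(mantel_test(d1, d2), "mismatched")
  flat <- matrix(0.5, 4, 4); diag(flat) <- 0
  expect_error(mantel_test(as.dist(flat), as.dist(flat)), "zero variance")
})

test_that("mantel is reproducible under a fixed seed", {
  set.seed(3)
  d1 <- dist(matrix(runif(16), 8)); d2 <- dist(matrix(runif(16), 8))
  a <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  expect_identical(a$p, b$p)
})

test_that("compare_clusterings tests large genera, skips small, flags degenerate", {
  cc <- make_genome_collection(
    collection_spec(n_genera = 1, genomes_per_genus = 8,
                    conservation = 0.3, coupling = "coupled", seed = 12))
  # an extra 2-genome genus and a fully-conserved (degenerate) genus
  cc2 <- make_genome_collection(
    collection_spec(n_genera = 1, genomes_per_genus = 5,
                    conservation = 1, coupling = "coupled", seed = 13))
  cc2$taxonomy$genus <- "Conserved"
  cc2$taxonomy$genome_id <- paste0("K", cc2$taxonomy$genome_id)
  cc2$hits$genome_id <- paste0("K", cc2$hits$genome_id)
  cc2$hits$protein_id <- paste0("K", cc2$hits$protein_id)
  cc2$proteins$genome_id <- paste0("K", cc2$proteins$genome_id)
  cc2$proteins$protein_id <- paste0("K", cc2$proteins$protein_id)
  hits <- rbind(cc$hits, cc2$hits)
  prots <- rbind(cc$proteins, cc2$proteins)
  tax <- rbind(cc$taxonomy, cc2$taxonomy,
               data.frame(genome_id = c("T1", "T2"), genus = "Tiny",
                          species = "t", strain = "",
                          stringsAsFactors = FALSE))
  arch <- build_architectures(
    resolve_overlaps(filter_hits(hits)),
    prots[, c("protein_id", "genome_id", "length")])
  res <- compare_clusterings(arch, tax, n_perm = 199, seed = 50)
  expect_equal(res$status[res$genus == "Tiny"], "skipped_small")
  expect_equal(res$status[res$genus == "Conserved"], "degenerate")
  g1 <- res[res$genus == "Genus01", ]
  expect_equal(g1$status, "tested")
  # coupled construction: architecture distances mirror family distances
  expect_gte(g1$r, 0.9)
  expect_lte(g1$p, 0.05)
})
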