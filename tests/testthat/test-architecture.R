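test_that("protein classes follow the single/MDGH/MAGH rules", {
  expect_equal(arch_of("GH5")$protein_class, "SINGLE")
  expect_equal(arch_of(c("GH5", "CBM2"))$protein_class, "MDGH")
  a <- arch_of(c("GH10", "CBM3", "GH5"))
  expect_equal(a$protein_class, "MAGH")
  expect_equal(a$canonical, "GH10-CBM3-GH5")
  expect_equal(arch_of("CBM2")$protein_class, "NON_TARGET")
  # a target GH plus a non-target GH is MDGH, not MAGH
  expect_equal(arch_of(c("GH5", "GH3"))$protein_class, "MDGH")
})

test_that("domain coordinates beyond the protein length are an error", {
  d <- dom_row("G1|P1", "GH5", 100L, 300L)
  prot <- data.frame(protein_id = "G1|P1", genome_id = "G1", length = 200L,
                     stringsAsFactors = FALSE)
  expect_error(build_architectures(d, prot), "exceed")
})

test_that("canonical strings collapse accessory runs but never GH runs", {
  expect_equal(canonical_string(c("GH9", "CBM3", "CBM3", "CBM3", "GH48"),
                                c(TRUE, FALSE, FALSE, FALSE, TRUE)),
               "GH9-3(CBM3)-GH48")
  expect_equal(canonical_string("GH5", TRUE), "GH5")
  expect_equal(canonical_string(c("GH5", "Ricin_B_lectin", "GH12"),
                                c(TRUE, FALSE, TRUE)),
               "GH5-Ricin_B_lectin-GH12")
  expect_equal(canonical_string(c("GH5", "GH5"), c(TRUE, TRUE)), "GH5-GH5")
  expect_equal(canonical_string(c("CBM2", "CBM2"), c(FALSE, FALSE)),
               "2(CBM2)")
})

test_that("canonical strings round-trip through parse_canonical", {
  fam <- gh_family_map()$gh_family
  acc_labels <- accessory_catalogue()$label
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    labels <- sample(c(fam, acc_labels), n, replace = TRUE)
    is_t <- labels %in% fam
    # collapse-run-free sequences: target runs allowed, accessory runs
    # re-expand to the same labels either way
    s <- canonical_string(labels, is_t)
    expect_equal(parse_canonical(s), labels, label = s)
  }
  expect_equal(parse_canonical("GH9-3(CBM3)-GH48"),
               c("GH9", "CBM3", "CBM3", "CBM3", "GH48"))
})

test_that("class partition is exhaustive and exclusive", {
  sp <- proteome_spec(60, c("GH5" = 2, "GH5-CBM2" = 2, "GH5-GH5" = 1,
                            "CBM3" = 1, "GH18-GH18-GH18" = 1), seed = 13)
  pr <- make_proteome(sp)
  arch <- build_architectures(
    resolve_overlaps(filter_hits(pr$hits)),
    pr$proteins[, c("protein_id", "genome_id", "length")])
  with_target <- arch[arch$n_target_gh > 0L, ]
  expect_equal(sum(with_target$protein_class %in%
                     c("SINGLE", "MDGH", "MAGH")), nrow(with_target))
  expect_equal(sum(arch$protein_class == "NON_TARGET"),
               sum(arch$n_target_gh == 0L))
})

test_that("MAGH classification separates homo and hetero with sorted labels", {
  m <- classify_magh(arch_of(c("GH5", "GH5")))
  expect_true(m$homo)
  expect_equal(m$pair_label, "cellulase:cellulase")

  m2 <- classify_magh(arch_of(c("GH10", "CBM3", "GH5")))
  expect_false(m2$homo)
  expect_equal(m2$pair_label, "cellulase:xylanase")

  m3 <- classify_magh(arch_of(c("GH18", "GH18", "GH18")))
  expect_true(m3$homo)
  expect_equal(m3$n_gh, 3L)
  expect_equal(m3$pair_label, "chitinase:chitinase:chitinase")

  # substrate-noun rendering
  m4 <- classify_magh(arch_of(c("GH10", "CBM3", "GH5")), style = "substrate")
  expect_equal(m4$pair_label, "cellulose:xylan")

  expect_error(classify_magh(arch_of("GH5")), "non-MAGH")
})

test_that("pair labels are invariant under domain-order reversal", {
  set.seed(21)
  fam <- gh_family_map()$gh_family
  for (i in 1:20) {
    labels <- sample(fam, sample(2:4, 1), replace = TRUE)
    a <- classify_magh(arch_of(labels))
    b <- classify_magh(arch_of(rev(labels)))
    expect_equal(a$pair_label, b$pair_label)
    expect_equal(a$homo, b$homo)
  }
})

test_that("homo/hetero partition MAGHs", {
  fix <- make_table1_fixture()
  arch <- build_architectures(
    resolve_overlaps(filter_hits(fix$hits)),
    fix$proteins[, c("protein_id", "genome_id", "length")])
  m <- magh_classification(arch)
  expect_equal(sum(m$homo) + sum(!m$homo), nrow(m))
})

test_that("terminal bias counts first/last GH occurrences", {
  m <- classify_magh(arch_of(c("GH9", "GH48")))
  tb <- terminal_bias(m)
  expect_equal(tb$n_first[tb$gh_family == "GH9"], 1L)
  expect_equal(tb$bias[tb$gh_family == "GH9"], "N_TERMINAL")
  expect_equal(tb$n_last[tb$gh_family == "GH48"], 1L)
  expect_equal(tb$bias[tb$gh_family == "GH48"], "C_TERMINAL")
})

test_that("terminal bias recovers planted first/last rates", {
  # 1000 simulated MAGHs: GH9 always first, GH48 always last, GH5 on
  # either end with known counts
  set.seed(99)
  n <- 1000L
  first <- sample(c("GH9", "GH5"), n, replace = TRUE, prob = c(0.7, 0.3))
  last <- sample(c("GH48", "GH5"), n, replace = TRUE, prob = c(0.8, 0.2))
  m <- data.frame(protein_id = paste0("G1|P", 1:n), genome_id = "G1",
                  n_gh = 2L, gh_families = paste(first, last, sep = ","),
                  homo = first == last, pair_label = "cellulase:cellulase",
                  first_family = first, last_family = last,
                  stringsAsFactors = FALSE)
  tb <- terminal_bias(m)
  expect_equal(tb$n_first[tb$gh_family == "GH9"], sum(first == "GH9"))
  expect_equal(tb$n_last[tb$gh_family == "GH48"], sum(last == "GH48"))
  expect_equal(tb$n_first[tb$gh_family == "GH5"], sum(first == "GH5"))
  expect_equal(tb$bias[tb$gh_family == "GH9"], "N_TERMINAL")
  expect_equal(tb$bias[tb$gh_family == "GH48"], "C_TERMINAL")
})
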