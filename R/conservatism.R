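# Conservatism of protein architecture versus GH family content:
# genome-by-feature count matrices, Bray-Curtis dissimilarity,
# hierarchical clustering, and the permutation Mantel test.

#' Genome-by-feature count matrices
#'
#' Builds the two matrices compared throughout the conservatism
#' analysis: the architecture matrix counts proteins per canonical
#' architecture string per genome (only proteins carrying at least one
#' target GH domain), and the family matrix counts target GH domains
#' per family per genome. Both have the same row set.
#'
#' @param arch A `gh_architectures` data.frame.
#' @param genome_ids Row set; defaults to the genomes present in
#'   `arch`. Genomes without target proteins get all-zero rows.
#' @return List with integer matrices `architecture` and `family`.
#' @export
count_matrices <- function(arch, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- unique(arch$genome_id)
  tgt <- arch[arch$n_target_gh > 0L, , drop = FALSE]
  g <- factor(tgt$genome_id, levels = genome_ids)

  arch_mat <- if (nrow(tgt)) {
    as.matrix(table(g, factor(tgt$canonical)))
  } else {
    matrix(0L, length(genome_ids), 0L, dimnames = list(genome_ids, NULL))
  }

  fams <- strsplit(tgt$gh_families, ",", fixed = TRUE)
  fam_long_g <- rep(tgt$genome_id, lengths(fams))
  fam_long_f <- unlist(fams, use.names = FALSE)
  fam_mat <- if (length(fam_long_f)) {
    as.matrix(table(factor(fam_long_g, levels = genome_ids),
                    factor(fam_long_f)))
  } else {
    matrix(0L, length(genome_ids), 0L, dimnames = list(genome_ids, NULL))
  }
  storage.mode(arch_mat) <- "integer"
  storage.mode(fam_mat) <- "integer"
  attr(arch_mat, "class") <- NULL
  attr(fam_mat, "class") <- NULL
  names(dimnames(arch_mat)) <- NULL
  names(dimnames(fam_mat)) <- NULL
  list(architecture = arch_mat, family = fam_mat)
}

#' Bray-Curtis dissimilarity between genome count profiles
#'
#' `d(i, j) = sum(|x_i - x_j|) / sum(x_i + x_j)` over features. Pairs
#' of all-zero rows (undefined ratio) are assigned distance 0.
#' Computed through [vegan::vegdist()].
#'
#' @param m Count matrix, genomes as rows.
#' @return A `dist` object over the rows of `m`.
#' @export
bray_curtis <- function(m) {
  stopifnot(nrow(m) >= 2L)
  if (ncol(m) == 0L) {
    d <- stats::as.dist(matrix(0, nrow(m), nrow(m),
                               dimnames = list(rownames(m), rownames(m))))
    return(d)
  }
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  d[is.nan(d)] <- 0  # both profiles empty
  d
}

#' Hierarchical clustering of genomes
#'
#' Agglomerative clustering of a genome distance matrix. Ids are
#' ordered lexicographically before clustering so tied merges resolve
#' deterministically.
#'
#' @param d A `dist` object or symmetric matrix with ids.
#' @param linkage `"average"` (UPGMA, default), `"complete"` or
#'   `"single"`.
#' @return An `hclust` object.
#' @export
hclust_tree <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(d)
  stopifnot(nrow(m) >= 2L)
  ord <- order(rownames(m))
  stats::hclust(stats::as.dist(m[ord, ord]), method = linkage)
}

#' Serialize a dendrogram as Newick
#'
#' @param tree An `hclust` object (see [hclust_tree()]).
#' @param file Optional path; when given the Newick string is written
#'   there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.lower_tri <- function(m) m[lower.tri(m)]

#' Permutation Mantel test
#'
#' Tests the association between two distance matrices over the same
#' objects. The statistic is the correlation (Pearson by default,
#' Spearman optional) of the strictly-lower-triangle entries; the null
#' distribution is obtained by jointly permuting rows and columns of
#' `d2`. The one-sided (positive association) p-value uses the add-one
#' convention: `p = (1 + #{r* >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects or symmetric matrices with identical ids
#'   in identical order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param perms Optional integer matrix, one permutation of
#'   `1:n` per row; overrides random sampling (used e.g. to enumerate
#'   all relabelings exhaustively on small matrices).
#' @return An object of class `"mantel_result"`: list with `r`, `p`,
#'   `n_perm`, `seed`, `method`, `n` (number of objects).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        method = c("pearson", "spearman"), perms = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stop("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("distance matrices have mismatched ids")
  }
  n <- nrow(m1)
  stopifnot(n >= 3L)
  v1 <- .lower_tri(m1)
  if (stats::sd(v1) == 0 || stats::sd(.lower_tri(m2)) == 0) {
    stop("zero variance in a distance matrix; Mantel r undefined")
  }
  r_obs <- stats::cor(v1, .lower_tri(m2), method = method)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(perms)) {
    stopifnot(ncol(perms) == n)
    n_perm <- nrow(perms)
  }
  r_perm <- numeric(n_perm)
  lt <- lower.tri(m2)
  for (i in seq_len(n_perm)) {
    p <- if (is.null(perms)) sample.int(n) else perms[i, ]
    r_perm[i] <- stats::cor(v1, m2[p, p][lt], method = method)
  }
  p_val <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p_val, n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 method = method, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d objects): r = %.4f, p = %.4g (%d permutations%s)\n",
              x$method, x$n, x$r, x$p, x$n_perm,
              if (is.na(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}

#' Architecture-versus-content conservatism per genus
#'
#' The genus-level comparison of the two clusterings: for every genus
#' with at least `min_genomes` genomes, builds the architecture and
#' family count matrices, computes Bray-Curtis distances for both, and
#' runs a permutation Mantel test between them. Genera below the size
#' threshold, or with degenerate (zero-variance) distances, are
#' reported with a reason instead of a test.
#'
#' @param arch A `gh_architectures` data.frame.
#' @param taxonomy Taxonomy table covering all genomes in `arch`.
#' @param n_perm Mantel permutations (default 999).
#' @param seed Integer seed; each genus uses `seed + its index` so
#'   results are reproducible yet independent across genera.
#' @param min_genomes Minimum genomes per genus (default 4).
#' @param method Correlation method passed to [mantel_test()].
#' @return Data.frame: `genus`, `n_genomes`, `r`, `p`, `n_perm`,
#'   `seed`, `status` (`"tested"`, `"skipped_small"`, `"degenerate"`).
#' @export
compare_clusterings <- function(arch, taxonomy, n_perm = 999, seed = NULL,
                                min_genomes = 4,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  missing <- setdiff(unique(arch$genome_id), taxonomy$genome_id)
  if (length(missing)) {
    stop("genomes absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  genera <- sort(unique(taxonomy$genus))
  rows <- lapply(seq_along(genera), function(i) {
    gen <- genera[i]
    ids <- taxonomy$genome_id[taxonomy$genus == gen]
    base <- data.frame(genus = gen, n_genomes = length(ids),
                       r = NA_real_, p = NA_real_, n_perm = n_perm,
                       seed = if (is.null(seed)) NA_integer_ else seed + i,
                       status = "tested", stringsAsFactors = FALSE)
    if (length(ids) < min_genomes) {
      base$status <- "skipped_small"
      return(base)
    }
    sub <- arch[arch$genome_id %in% ids, , drop = FALSE]
    cm <- count_matrices(sub, genome_ids = ids)
    d_arch <- bray_curtis(cm$architecture)
    d_fam <- bray_curtis(cm$family)
    if (stats::sd(as.vector(d_arch)) == 0 ||
        stats::sd(as.vector(d_fam)) == 0) {
      base$status <- "degenerate"
      return(base)
    }
    mt <- mantel_test(d_arch, d_fam, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + i,
                      method = method)
    base$r <- mt$r; base$p <- mt$p
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
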