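#' Target GH family catalogue
#'
#' Returns the mapping from Pfam accession to glycoside hydrolase (GH)
#' family and substrate for the fourteen target families used throughout
#' the package: cellulases (GH5, 6, 8, 9, 12, 44, 45, 48), xylanases
#' (GH10, 11, 30) and chitinases (GH18, 19, 85). GH7 (PF00840) is a
#' fungal-type cellulase profile and is excluded by default; set
#' `include_gh7 = TRUE` to add it.
#'
#' @param file Path to a tab-delimited catalogue with columns
#'   `pfam_accession`, `gh_family`, `substrate`. Defaults to the
#'   catalogue shipped with the package.
#' @param include_gh7 Logical; include the GH7 row (PF00840)?
#' @return A data.frame with columns `pfam_accession`, `gh_family`,
#'   `substrate` (one of `"cellulose"`, `"xylan"`, `"chitin"`).
#' @examples
#' fam <- gh_family_map()
#' nrow(fam)  # 14
#' @export
gh_family_map <- function(file = NULL, include_gh7 = FALSE) {
  if (is.null(file)) {
    file <- system.file("extdata", "gh_family_map.tsv", package = "ghArch",
                        mustWork = TRUE)
  }
  fam <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("pfam_accession", "gh_family", "substrate")
  if (!all(need %in% names(fam))) {
    stop("family map must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(fam$pfam_accession)) {
    stop("family map: duplicated pfam_accession")
  }
  bad <- setdiff(unique(fam$substrate), c("cellulose", "xylan", "chitin"))
  if (length(bad)) stop("family map: unknown substrate(s): ",
                        paste(bad, collapse = ", "))
  if (!include_gh7) fam <- fam[fam$pfam_accession != "PF00840", , drop = FALSE]
  rownames(fam) <- NULL
  fam
}

#' Accessory-domain catalogue
#'
#' Maps Pfam accessions of non-target domains (CBMs, dockerin, cohesin,
#' SLH, fibronectin, cadherin, other-GH families, ...) to human-readable
#' labels used in architecture strings. Accessions absent from the
#' catalogue fall back to the raw accession as their label, so the
#' catalogue never needs to be exhaustive.
#'
#' @param file Path to a tab-delimited catalogue with columns
#'   `pfam_accession`, `label`; defaults to the shipped catalogue.
#' @return A data.frame with columns `pfam_accession`, `label`.
#' @export
accessory_catalogue <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "accessory_map.tsv", package = "ghArch",
                        mustWork = TRUE)
  }
  acc <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("pfam_accession", "label") %in% names(acc))) {
    stop("accessory catalogue must have columns: pfam_accession, label")
  }
  if (any(!nzchar(acc$label))) stop("accessory catalogue: empty label")
  if (anyDuplicated(acc$pfam_accession)) {
    stop("accessory catalogue: duplicated pfam_accession")
  }
  rownames(acc) <- NULL
  acc
}

#' Hit-filtering policy
#'
#' Bundles the thresholds applied to raw Pfam hits: E-value below
#' `evalue_max` (strict) and profile coverage above `coverage_min`
#' (strict), plus the overlap tolerance used when resolving competing
#' hits on one protein. Defaults are E-value < 1e-5 on the per-domain
#' independent E-value and coverage > 60% of the Pfam profile length.
#'
#' @param evalue_max Maximum E-value (exclusive). Default `1e-5`.
#' @param coverage_min Minimum profile coverage (exclusive), in (0, 1].
#' @param evalue_field Which parsed E-value the threshold applies to:
#'   `"dom_ievalue"` (per-domain independent E-value, default) or
#'   `"seq_evalue"` (full-sequence E-value).
#' @param overlap_max_fraction Maximum tolerated overlap between two
#'   kept domains, as a fraction of the shorter domain, in [0, 1).
#' @return An object of class `"filter_policy"`.
#' @export
filter_policy <- function(evalue_max = 1e-5, coverage_min = 0.60,
                          evalue_field = c("dom_ievalue", "seq_evalue"),
                          overlap_max_fraction = 0.5) {
  evalue_field <- match.arg(evalue_field)
  stopifnot(is.numeric(evalue_max), length(evalue_max) == 1L, evalue_max > 0,
            is.numeric(coverage_min), length(coverage_min) == 1L,
            coverage_min > 0, coverage_min <= 1,
            is.numeric(overlap_max_fraction), length(overlap_max_fraction) == 1L,
            overlap_max_fraction >= 0, overlap_max_fraction < 1)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 evalue_field = evalue_field,
                 overlap_max_fraction = overlap_max_fraction),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("Filter policy: ", x$evalue_field, " < ", format(x$evalue_max),
      ", coverage > ", format(x$coverage_min),
      ", overlap tolerance ", format(x$overlap_max_fraction), "\n", sep = "")
  invisible(x)
}
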