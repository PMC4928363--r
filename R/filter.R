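# The significance/coverage filter and overlap resolution that turn raw
# Pfam hits into the accepted domains architectures are built from.

#' Profile coverage of a hit
#'
#' Fraction of the Pfam profile spanned by the hit's profile (HMM)
#' coordinates: `(hmm_to - hmm_from + 1) / profile_length`.
#'
#' @param hits A `raw_hits` data.frame.
#' @return Numeric vector in (0, 1], one value per hit.
#' @export
profile_coverage <- function(hits) {
  (hits$hmm_to - hits$hmm_from + 1) / hits$profile_length
}

#' Filter raw hits on E-value and profile coverage
#'
#' A hit survives iff its E-value (the field named by
#' `policy$evalue_field`) is strictly below `policy$evalue_max` and its
#' profile coverage is strictly above `policy$coverage_min`. Survivors
#' are annotated from the catalogues: accessions in the target family
#' map become `TARGET_GH` domains labelled with their GH family and
#' substrate; all others become `ACCESSORY` domains labelled from the
#' accessory catalogue (unknown accessions keep the raw accession as
#' label). Input order is preserved.
#'
#' @param hits A `raw_hits` data.frame (see [parse_domtblout()]).
#' @param policy A [filter_policy()].
#' @param family_map Target family catalogue, see [gh_family_map()].
#' @param accessories Accessory catalogue, see [accessory_catalogue()].
#' @return A data.frame of class `"accepted_domains"` with columns
#'   `protein_id`, `genome_id`, `pfam_accession`, `label`, `role`,
#'   `substrate`, `start`, `end` (envelope coordinates, 1-based
#'   inclusive), `evalue`, `bitscore`, `coverage`.
#' @export
filter_hits <- function(hits, policy = filter_policy(),
                        family_map = gh_family_map(),
                        accessories = accessory_catalogue()) {
  cov <- profile_coverage(hits)
  ev <- hits[[policy$evalue_field]]
  keep <- ev < policy$evalue_max & cov > policy$coverage_min
  h <- hits[keep, , drop = FALSE]
  cov <- cov[keep]
  ev <- ev[keep]

  fi <- match(h$pfam_accession, family_map$pfam_accession)
  ai <- match(h$pfam_accession, accessories$pfam_accession)
  target <- !is.na(fi)
  label <- ifelse(target, family_map$gh_family[fi],
                  ifelse(is.na(ai), h$pfam_accession, accessories$label[ai]))
  out <- data.frame(
    protein_id = h$protein_id,
    genome_id = h$genome_id,
    pfam_accession = h$pfam_accession,
    label = label,
    role = ifelse(target, "TARGET_GH", "ACCESSORY"),
    substrate = ifelse(target, family_map$substrate[fi], "none"),
    start = h$env_from,
    end = h$env_to,
    evalue = ev,
    bitscore = h$bitscore,
    coverage = cov,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("accepted_domains", "data.frame")
  out
}

# length of the overlap between [s1,e1] and [s2,e2] (0 if disjoint)
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

.resolve_one <- function(d, tol) {
  if (nrow(d) <= 1L) return(d)
  ord <- order(d$evalue, -d$bitscore, d$start)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    len_i <- d$end[i] - d$start[i] + 1L
    len_k <- d$end[kept] - d$start[kept] + 1L
    ov <- .overlap_len(d$start[i], d$end[i], d$start[kept], d$end[kept])
    if (all(ov <= tol * pmin(len_i, len_k))) kept <- c(kept, i)
  }
  d[kept[order(d$start[kept], d$end[kept], d$label[kept])], , drop = FALSE]
}

#' Resolve overlapping accepted domains
#'
#' Greedy selection per protein in ascending E-value order (ties broken
#' by higher bit score, then lower start): a candidate is discarded if
#' its overlap with any already-kept domain exceeds
#' `policy$overlap_max_fraction` of the shorter of the two. The result
#' is sorted by start (then end, then label).
#'
#' @param domains An `accepted_domains` data.frame; may span several
#'   proteins, resolution is applied within each protein.
#' @param policy A [filter_policy()]; only `overlap_max_fraction` is
#'   used.
#' @return An `accepted_domains` data.frame.
#' @export
resolve_overlaps <- function(domains, policy = filter_policy()) {
  if (!nrow(domains)) return(domains)
  tol <- policy$overlap_max_fraction
  parts <- split(seq_len(nrow(domains)), domains$protein_id)
  kept <- lapply(parts, function(idx) {
    .resolve_one(domains[idx, , drop = FALSE], tol)
  })
  out <- do.call(rbind, kept)
  out <- out[order(match(out$protein_id, unique(domains$protein_id))), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accepted_domains", "data.frame")
  out
}
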