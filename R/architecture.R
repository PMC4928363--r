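# Per-protein domain architectures: canonical strings, protein classes
# (single / multi-domain / multi-activity GH), MAGH subclassification
# and terminal-position bias of GH families.

#' Canonical architecture string
#'
#' Joins ordered domain labels with `"-"`. Maximal runs of two or more
#' identical consecutive *accessory* labels are collapsed to
#' `"k(label)"` (e.g. `GH9-3(CBM3)-GH48`); target-GH labels are never
#' collapsed, so a tandem catalytic repeat stays explicit (`GH5-GH5`).
#'
#' @param labels Character vector of domain labels, ordered by start.
#' @param is_target Logical vector: is each label a target GH family?
#' @return A single string ("" for no domains).
#' @export
canonical_string <- function(labels, is_target) {
  n <- length(labels)
  if (!n) return("")
  stopifnot(length(is_target) == n)
  run_id <- cumsum(c(TRUE, labels[-1L] != labels[-n] |
                       is_target[-1L] | is_target[-n]))
  parts <- vapply(split(seq_len(n), run_id), function(idx) {
    k <- length(idx)
    lab <- labels[idx[1L]]
    if (k >= 2L && !is_target[idx[1L]]) sprintf("%d(%s)", k, lab) else {
      paste(rep(lab, k), collapse = "-")
    }
  }, character(1L))
  paste(parts, collapse = "-")
}

#' Expand a canonical architecture string back to labels
#'
#' Inverse of [canonical_string()]: splits on `"-"` and re-expands
#' `"k(label)"` tokens to `k` copies of `label`.
#'
#' @param x A canonical string.
#' @return Character vector of labels ("" input gives length 0).
#' @export
parse_canonical <- function(x) {
  stopifnot(length(x) == 1L)
  if (!nzchar(x)) return(character(0))
  toks <- strsplit(x, "-", fixed = TRUE)[[1L]]
  out <- lapply(toks, function(t) {
    m <- regmatches(t, regexec("^(\\d+)\\((.+)\\)$", t))[[1L]]
    if (length(m) == 3L) rep(m[3L], as.integer(m[2L])) else t
  })
  unlist(out, use.names = FALSE)
}

.arch_one <- function(protein_id, genome_id, length, d) {
  if (nrow(d)) {
    if (any(d$end > length)) {
      stop("domain coordinates exceed protein length for ", protein_id)
    }
    d <- d[order(d$start, d$end, d$label), , drop = FALSE]
  }
  tgt <- d$role == "TARGET_GH"
  n_tgt <- sum(tgt)
  klass <- if (n_tgt == 0L) "NON_TARGET" else if (n_tgt >= 2L) "MAGH" else {
    if (nrow(d) > 1L) "MDGH" else "SINGLE"
  }
  fams <- d$label[tgt]
  data.frame(
    protein_id = protein_id, genome_id = genome_id, length = length,
    n_domains = nrow(d), n_target_gh = n_tgt, protein_class = klass,
    canonical = canonical_string(d$label, tgt),
    gh_families = paste(fams, collapse = ","),
    gh_substrates = paste(d$substrate[tgt], collapse = ","),
    first_family = if (n_tgt) fams[1L] else "",
    last_family = if (n_tgt) fams[n_tgt] else "",
    stringsAsFactors = FALSE
  )
}

#' Build the architecture of one protein
#'
#' @param protein A one-row data.frame with `protein_id`, `genome_id`,
#'   `length`.
#' @param domains Overlap-resolved `accepted_domains` for this protein.
#' @return A one-row architecture data.frame (see
#'   [build_architectures()]).
#' @export
build_architecture <- function(protein, domains) {
  stopifnot(nrow(protein) == 1L)
  if (nrow(domains) && !all(domains$protein_id == protein$protein_id)) {
    stop("domains do not belong to protein ", protein$protein_id)
  }
  out <- .arch_one(protein$protein_id, protein$genome_id, protein$length,
                   domains)
  class(out) <- c("gh_architectures", "data.frame")
  out
}

#' Build per-protein architectures for a collection
#'
#' Orders each protein's accepted domains by start position (ties:
#' smaller end, then label) and assigns the protein class:
#' `NON_TARGET` (no target GH domain), `SINGLE` (one target GH, no
#' other domain), `MDGH` (one target GH plus at least one other
#' domain), `MAGH` (two or more target GH domains). Proteins present in
#' `proteins` but without accepted domains appear as `NON_TARGET` rows,
#' so per-genome accounting stays complete.
#'
#' @param domains Overlap-resolved `accepted_domains` (see
#'   [resolve_overlaps()]).
#' @param proteins Data.frame with `protein_id`, `genome_id`, `length`
#'   (see [read_protein_lengths()]). If `NULL`, proteins are taken from
#'   `domains` with length set to the maximal domain end.
#' @return A data.frame of class `"gh_architectures"`, one row per
#'   protein: `protein_id`, `genome_id`, `length`, `n_domains`,
#'   `n_target_gh`, `protein_class`, `canonical`, `gh_families`
#'   (comma-joined, in order), `gh_substrates`, `first_family`,
#'   `last_family`.
#' @export
build_architectures <- function(domains, proteins = NULL) {
  if (is.null(proteins)) {
    if (nrow(domains)) {
      agg <- stats::aggregate(end ~ protein_id + genome_id, data = domains,
                              FUN = max)
      proteins <- data.frame(protein_id = agg$protein_id,
                             genome_id = agg$genome_id,
                             length = agg$end, stringsAsFactors = FALSE)
    } else {
      proteins <- data.frame(protein_id = character(),
                             genome_id = character(),
                             length = integer(), stringsAsFactors = FALSE)
    }
  }
  if (!nrow(proteins)) {
    out <- .arch_one("x", "x", 1L, domains[0L, , drop = FALSE])[0L, ]
    class(out) <- c("gh_architectures", "data.frame")
    return(out)
  }
  idx <- split(seq_len(nrow(domains)), domains$protein_id)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    ii <- idx[[proteins$protein_id[i]]]
    d <- if (is.null(ii)) domains[0L, , drop = FALSE] else {
      domains[ii, , drop = FALSE]
    }
    .arch_one(proteins$protein_id[i], proteins$genome_id[i],
              proteins$length[i], d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gh_architectures", "data.frame")
  out
}

#' @export
print.gh_architectures <- function(x, ...) {
  cat("Architectures for", nrow(x), "proteins in",
      length(unique(x$genome_id)), "genome(s)\n")
  cat("Classes:", paste(sprintf("%s=%d",
                                names(table(x$protein_class)),
                                as.integer(table(x$protein_class))),
                        collapse = ", "), "\n")
  invisible(as.data.frame(x))
}

.SUBSTRATE_ACTIVITY <- c(cellulose = "cellulase", xylan = "xylanase",
                         chitin = "chitinase")

#' Classify multi-activity GHs
#'
#' For proteins with two or more target GH domains (MAGHs), reports
#' whether all catalytic domains come from one family (`homo = TRUE`)
#' or several (hetero), and the substrate-pair label: the sorted
#' multiset of activities implied by the GH families, joined with
#' `":"` (e.g. `"cellulase:xylanase"`; for three or more GH domains all
#' are listed, e.g. `"chitinase:chitinase:chitinase"`).
#'
#' @param arch A `gh_architectures` data.frame whose rows are all
#'   `MAGH`; any other class is an error.
#' @param style `"activity"` (default: cellulase/xylanase/chitinase) or
#'   `"substrate"` (cellulose/xylan/chitin) rendering of the pair
#'   label.
#' @return A data.frame of class `"magh_classification"`: `protein_id`,
#'   `genome_id`, `n_gh`, `gh_families`, `homo`, `pair_label`,
#'   `first_family`, `last_family`.
#' @export
classify_magh <- function(arch, style = c("activity", "substrate")) {
  style <- match.arg(style)
  if (any(arch$protein_class != "MAGH")) {
    stop("classify_magh: input contains non-MAGH proteins (",
         paste(utils::head(arch$protein_id[arch$protein_class != "MAGH"], 3L),
               collapse = ", "), ")")
  }
  fams <- strsplit(arch$gh_families, ",", fixed = TRUE)
  subs <- strsplit(arch$gh_substrates, ",", fixed = TRUE)
  pair <- vapply(subs, function(s) {
    if (style == "activity") s <- unname(.SUBSTRATE_ACTIVITY[s])
    paste(sort(s), collapse = ":")
  }, character(1L))
  out <- data.frame(
    protein_id = arch$protein_id,
    genome_id = arch$genome_id,
    n_gh = arch$n_target_gh,
    gh_families = arch$gh_families,
    homo = vapply(fams, function(f) length(unique(f)) == 1L, logical(1L)),
    pair_label = pair,
    first_family = arch$first_family,
    last_family = arch$last_family,
    stringsAsFactors = FALSE
  )
  class(out) <- c("magh_classification", "data.frame")
  out
}

#' All MAGH classifications in an architecture table
#'
#' Convenience wrapper: subsets `arch` to its MAGH rows and applies
#' [classify_magh()].
#'
#' @inheritParams classify_magh
#' @return See [classify_magh()]; zero rows if no MAGHs.
#' @export
magh_classification <- function(arch, style = c("activity", "substrate")) {
  classify_magh(arch[arch$protein_class == "MAGH", , drop = FALSE], style)
}

#' Summarize multi-activity GHs by substrate category
#'
#' Collapses MAGH classifications into the survey-style breakdown: one
#' category per combination of activities (`"cellulase:cellulase"` for
#' any all-cellulase MAGH regardless of domain count,
#' `"cellulase:xylanase"` for mixed cellulose/xylan, ...), with homo
#' and hetero counts per category, the overall homo/hetero split, and
#' the number of proteins with three or more GH domains.
#'
#' @param maghs A `magh_classification` data.frame.
#' @return List: `n_total`, `n_homo`, `n_hetero`, `pct_hetero` (percent
#'   of MAGHs that are hetero-GH), `n_three_domain` (proteins with
#'   `n_gh >= 3`), and `categories` (data.frame `category`, `n_homo`,
#'   `n_hetero`, `n`).
#' @export
magh_summary <- function(maghs) {
  acts <- strsplit(maghs$pair_label, ":", fixed = TRUE)
  category <- vapply(acts, function(a) {
    u <- sort(unique(a))
    if (length(u) == 1L) paste(u, u, sep = ":") else paste(u, collapse = ":")
  }, character(1L))
  tab <- table(category, factor(maghs$homo, levels = c(TRUE, FALSE)))
  cats <- data.frame(category = rownames(tab),
                     n_homo = as.integer(tab[, 1L]),
                     n_hetero = as.integer(tab[, 2L]),
                     n = as.integer(rowSums(tab)),
                     stringsAsFactors = FALSE)
  rownames(cats) <- NULL
  list(n_total = nrow(maghs),
       n_homo = sum(maghs$homo),
       n_hetero = sum(!maghs$homo),
       pct_hetero = 100 * sum(!maghs$homo) / nrow(maghs),
       n_three_domain = sum(maghs$n_gh >= 3L),
       categories = cats)
}

#' Terminal-position bias of GH families in MAGHs
#'
#' For each GH family observed in multi-activity proteins, counts how
#' often it is the N-most (`n_first`) and C-most (`n_last`) target GH
#' domain of a MAGH (in a homo-pair it is both). The family is called
#' `N_TERMINAL` when `n_first / (n_first + n_last)` exceeds
#' `thresholds[2]`, `C_TERMINAL` when below `thresholds[1]`, otherwise
#' `MIXED` (also when it is never terminal).
#'
#' @param maghs A `magh_classification` data.frame.
#' @param thresholds Length-2 numeric, the C/N cut points (default
#'   `c(0.4, 0.6)`).
#' @return Data.frame: `gh_family`, `n_first`, `n_last`,
#'   `n_total_in_magh`, `bias`.
#' @export
terminal_bias <- function(maghs, thresholds = c(0.4, 0.6)) {
  stopifnot(nrow(maghs) > 0, length(thresholds) == 2L,
            thresholds[1] <= thresholds[2])
  fams <- strsplit(maghs$gh_families, ",", fixed = TRUE)
  all_f <- sort(unique(unlist(fams)))
  n_first <- table(factor(maghs$first_family, levels = all_f))
  n_last <- table(factor(maghs$last_family, levels = all_f))
  n_tot <- table(factor(unlist(fams), levels = all_f))
  frac <- as.integer(n_first) / pmax(1L, as.integer(n_first) +
                                       as.integer(n_last))
  bias <- ifelse(as.integer(n_first) + as.integer(n_last) == 0L, "MIXED",
                 ifelse(frac > thresholds[2], "N_TERMINAL",
                        ifelse(frac < thresholds[1], "C_TERMINAL", "MIXED")))
  data.frame(gh_family = all_f,
             n_first = as.integer(n_first),
             n_last = as.integer(n_last),
             n_total_in_magh = as.integer(n_tot),
             bias = bias, stringsAsFactors = FALSE)
}
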