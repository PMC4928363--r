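# Readers and writers for the standard inputs: HMMER3 domtblout tables,
# protein lengths (FASTA or TSV), and the genome taxonomy table.

# domtblout has 22 fixed whitespace-delimited columns followed by a
# free-text description; column meaning depends on scan vs search
# orientation (which of target/query is the Pfam profile).
.DOMTBL_NCOL <- 22L

.strip_version <- function(acc) sub("\\.\\d+$", "", acc)

.num_or_stop <- function(x, what, line_no) {
  suppressWarnings(v <- as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stop("domtblout parse error at line ", line_no[bad][1L],
         ": non-numeric ", what, " ('", x[bad][1L], "')")
  }
  v
}

#' Extract genome ids from protein ids
#'
#' @param protein_id Character vector of protein identifiers.
#' @param genome_pattern Regular expression whose first capture group is
#'   the genome id (default: everything before the first `"|"`).
#' @param genome_map Optional data.frame with columns `protein_id`,
#'   `genome_id`; when given it overrides the pattern.
#' @return Character vector of genome ids.
#' @export
genome_from_protein <- function(protein_id,
                                genome_pattern = "^([^|]+)\\|",
                                genome_map = NULL) {
  if (!is.null(genome_map)) {
    stopifnot(all(c("protein_id", "genome_id") %in% names(genome_map)))
    idx <- match(protein_id, genome_map$protein_id)
    if (anyNA(idx)) {
      stop("protein ids missing from genome map: ",
           paste(utils::head(unique(protein_id[is.na(idx)]), 5L),
                 collapse = ", "))
    }
    return(genome_map$genome_id[idx])
  }
  m <- regexec(genome_pattern, protein_id)
  parts <- regmatches(protein_id, m)
  ok <- lengths(parts) >= 2L
  if (!all(ok)) {
    stop("genome pattern '", genome_pattern, "' did not match protein ids: ",
         paste(utils::head(unique(protein_id[!ok]), 5L), collapse = ", "))
  }
  vapply(parts, `[[`, character(1L), 2L)
}

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Reads the standard whitespace-delimited per-domain output of
#' `hmmscan`/`hmmsearch` into one row per domain hit. The `orientation`
#' argument states which of the two name/accession column pairs holds
#' the Pfam profile: for `"scan"` (hmmscan) the *target* is the profile
#' and the *query* the protein; for `"search"` (hmmsearch) the reverse.
#' Version suffixes are stripped from Pfam accessions (`PF00150.19` ->
#' `PF00150`).
#'
#' @param file Path to a domtblout file, or a character vector of its
#'   lines.
#' @param orientation `"scan"` (default) or `"search"`.
#' @inheritParams genome_from_protein
#' @return A data.frame of class `"raw_hits"` with columns
#'   `protein_id`, `genome_id`, `pfam_accession`, `pfam_name`,
#'   `profile_length`, `seq_evalue`, `dom_ievalue`, `bitscore`,
#'   `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `env_from`, `env_to`.
#'   All coordinates are 1-based inclusive.
#' @export
parse_domtblout <- function(file, orientation = c("scan", "search"),
                            genome_pattern = "^([^|]+)\\|",
                            genome_map = NULL) {
  orientation <- match.arg(orientation)
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  line_no <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]

  empty <- data.frame(protein_id = character(), genome_id = character(),
                      pfam_accession = character(), pfam_name = character(),
                      profile_length = integer(), seq_evalue = numeric(),
                      dom_ievalue = numeric(), bitscore = numeric(),
                      hmm_from = integer(), hmm_to = integer(),
                      ali_from = integer(), ali_to = integer(),
                      env_from = integer(), env_to = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("raw_hits", "data.frame")
  if (!length(lines)) return(empty)

  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf < .DOMTBL_NCOL)) {
    i <- which(nf < .DOMTBL_NCOL)[1L]
    stop("domtblout parse error at line ", line_no[i], ": expected at least ",
         .DOMTBL_NCOL, " columns before the description, found ", nf[i])
  }
  col <- function(k) vapply(toks, `[[`, character(1L), k)

  if (orientation == "scan") {
    pfam_name <- col(1L); pfam_acc <- col(2L)
    profile_length <- col(3L); protein_id <- col(4L)
  } else {
    protein_id <- col(1L)
    pfam_name <- col(4L); pfam_acc <- col(5L)
    profile_length <- col(6L)
  }
  # hmmsearch tables may carry "-" as the profile accession; fall back
  # to the profile name so downstream joins still have a key.
  pfam_acc <- ifelse(pfam_acc == "-", pfam_name, pfam_acc)

  hits <- data.frame(
    protein_id = protein_id,
    genome_id = genome_from_protein(protein_id, genome_pattern, genome_map),
    pfam_accession = .strip_version(pfam_acc),
    pfam_name = pfam_name,
    profile_length = as.integer(.num_or_stop(profile_length,
                                             "profile length", line_no)),
    seq_evalue = .num_or_stop(col(7L), "E-value", line_no),
    dom_ievalue = .num_or_stop(col(13L), "E-value", line_no),
    bitscore = .num_or_stop(col(14L), "bit score", line_no),
    hmm_from = as.integer(.num_or_stop(col(16L), "coordinate", line_no)),
    hmm_to = as.integer(.num_or_stop(col(17L), "coordinate", line_no)),
    ali_from = as.integer(.num_or_stop(col(18L), "coordinate", line_no)),
    ali_to = as.integer(.num_or_stop(col(19L), "coordinate", line_no)),
    env_from = as.integer(.num_or_stop(col(20L), "coordinate", line_no)),
    env_to = as.integer(.num_or_stop(col(21L), "coordinate", line_no)),
    stringsAsFactors = FALSE
  )

  bad <- with(hits, hmm_from > hmm_to | ali_from > ali_to |
                env_from > env_to | profile_length < hmm_to |
                hmm_from < 1L | ali_from < 1L | env_from < 1L |
                seq_evalue < 0 | dom_ievalue < 0)
  if (any(bad)) {
    stop("domtblout parse error at line ", line_no[bad][1L],
         ": inconsistent coordinates or negative E-value")
  }
  class(hits) <- c("raw_hits", "data.frame")
  hits
}

#' Write hits as a HMMER3 domtblout table
#'
#' Emits hits in `hmmscan` orientation (profile as target). Used by the
#' synthetic-data generator; numeric fields round-trip through
#' [parse_domtblout()] at the printed precision.
#'
#' @param hits A `raw_hits` data.frame (see [parse_domtblout()]).
#' @param file Output path.
#' @param protein_lengths Optional named integer vector giving protein
#'   lengths for the `qlen` column; defaults to each hit's `env_to`.
#' @return Invisibly, `file`.
#' @export
write_domtblout <- function(hits, file, protein_lengths = NULL) {
  qlen <- if (is.null(protein_lengths)) hits$env_to else {
    unname(protein_lengths[hits$protein_id])
  }
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  body <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9.3g %6.1f %5.1f %3d %3d %9.3g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
    hits$pfam_name, hits$pfam_accession, hits$profile_length,
    hits$protein_id, "-", qlen,
    hits$seq_evalue, hits$bitscore, 0, 1L, 1L,
    hits$dom_ievalue, hits$dom_ievalue, hits$bitscore, 0,
    hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
    hits$env_from, hits$env_to, 0.95)
  writeLines(c(header, body, "#"), file)
  invisible(file)
}

#' Read protein lengths from FASTA or TSV
#'
#' Accepts either a protein FASTA file (lengths are residue counts) or
#' a two-column tab-delimited table `protein_id<TAB>length` (an optional
#' header row is detected and skipped).
#'
#' @param file Path to the FASTA or TSV file.
#' @inheritParams genome_from_protein
#' @return A data.frame with columns `protein_id`, `genome_id`, `length`.
#' @export
read_protein_lengths <- function(file, genome_pattern = "^([^|]+)\\|",
                                 genome_map = NULL) {
  first <- readLines(file, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    aa <- Biostrings::readAAStringSet(file)
    ids <- sub("\\s.*$", "", names(aa))
    len <- Biostrings::width(aa)
  } else {
    tab <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("protein_id", "length"))
    if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab$length[1L])))) {
      tab <- tab[-1L, , drop = FALSE]  # header row
    }
    ids <- as.character(tab$protein_id)
    len <- suppressWarnings(as.integer(tab$length))
    if (anyNA(len)) stop("protein length table: non-numeric length for ",
                         ids[is.na(len)][1L])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  if (any(len < 1L)) stop("zero-length protein: ", ids[len < 1L][1L])
  data.frame(protein_id = ids,
             genome_id = genome_from_protein(ids, genome_pattern, genome_map),
             length = as.integer(len), stringsAsFactors = FALSE)
}

#' Read the genome taxonomy table
#'
#' @param file Tab-delimited file with header columns `genome_id`,
#'   `genus`, `species`, `strain` (strain may be empty).
#' @return A data.frame with those four character columns.
#' @export
read_taxonomy <- function(file) {
  tax <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("genome_id", "genus", "species")
  if (!all(need %in% names(tax))) {
    stop("taxonomy table must have header columns: ",
         paste(need, collapse = ", "))
  }
  if (!"strain" %in% names(tax)) tax$strain <- ""
  tax$strain[is.na(tax$strain)] <- ""
  if (anyDuplicated(tax$genome_id)) {
    stop("duplicate genome_id in taxonomy: ",
         paste(unique(tax$genome_id[duplicated(tax$genome_id)]),
               collapse = ", "))
  }
  if (any(is.na(tax$genus) | !nzchar(tax$genus))) {
    stop("taxonomy: missing genus for genome ",
         tax$genome_id[is.na(tax$genus) | !nzchar(tax$genus)][1L])
  }
  if (any(is.na(tax$species) | !nzchar(tax$species))) {
    stop("taxonomy: missing species for genome ",
         tax$genome_id[is.na(tax$species) | !nzchar(tax$species)][1L])
  }
  tax[, c("genome_id", "genus", "species", "strain")]
}

# Tab-delimited writer used for all package outputs (UTF-8, header row).
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
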