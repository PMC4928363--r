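# Per-genome GH content profiles, per-taxon summaries, and flagging of
# genomes/taxa with high polysaccharide-degradation potential.

#' Per-genome GH content profiles
#'
#' Aggregates architectures into one profile per genome: counts of
#' target GH domains and of proteins per class, a genome-by-family
#' count matrix and a genome-by-architecture count matrix. Every genome
#' in `taxonomy` appears, including genomes with zero target proteins
#' (all-zero profile).
#'
#' @param arch A `gh_architectures` data.frame.
#' @param taxonomy Taxonomy table (see [read_taxonomy()]). Every
#'   `genome_id` in `arch` must be present; offenders are reported.
#' @return An object of class `"genome_profiles"`: a list with
#'   `genomes` (data.frame: `genome_id`, `genus`, `species`, `strain`,
#'   `n_target_domains`, `n_target_proteins`, `n_single`, `n_mdgh`,
#'   `n_magh`), `family_matrix` and `architecture_matrix` (integer
#'   matrices, genomes as rows).
#' @export
genome_profiles <- function(arch, taxonomy) {
  missing <- setdiff(unique(arch$genome_id), taxonomy$genome_id)
  if (length(missing)) {
    stop("genomes absent from taxonomy: ", paste(missing, collapse = ", "))
  }
  cm <- count_matrices(arch, genome_ids = taxonomy$genome_id)
  g <- factor(arch$genome_id, levels = taxonomy$genome_id)
  cls <- function(k) {
    as.integer(table(g[arch$protein_class == k]))
  }
  n_single <- cls("SINGLE"); n_mdgh <- cls("MDGH"); n_magh <- cls("MAGH")
  genomes <- data.frame(
    taxonomy,
    n_target_domains = as.integer(rowSums(cm$family)),
    n_target_proteins = n_single + n_mdgh + n_magh,
    n_single = n_single, n_mdgh = n_mdgh, n_magh = n_magh,
    stringsAsFactors = FALSE
  )
  structure(list(genomes = genomes, family_matrix = cm$family,
                 architecture_matrix = cm$architecture),
            class = "genome_profiles")
}

#' @export
print.genome_profiles <- function(x, ...) {
  cat("GH content profiles for", nrow(x$genomes), "genomes\n")
  cat("Target GH domains:", sum(x$genomes$n_target_domains),
      "in", sum(x$genomes$n_target_proteins), "proteins (",
      sum(x$genomes$n_single), "single /", sum(x$genomes$n_mdgh),
      "MDGH /", sum(x$genomes$n_magh), "MAGH )\n")
  cat(ncol(x$architecture_matrix), "distinct architectures,",
      ncol(x$family_matrix), "GH families\n")
  invisible(x)
}

#' Per-taxon GH content summaries
#'
#' Mean and standard deviation of target GH domains per genome, grouped
#' by genus or by species (genus + species). Single-genome groups get
#' `sd = 0` by convention.
#'
#' @param profiles A `"genome_profiles"` object.
#' @param rank `"genus"` or `"species"`.
#' @param count `"domains"` (default) or `"proteins"`: whether the
#'   per-genome quantity is target GH domains or target proteins.
#' @return Data.frame: `taxon`, `rank`, `n_genomes`,
#'   `mean_gh_per_genome`, `sd`.
#' @export
taxon_summary <- function(profiles, rank = c("genus", "species"),
                          count = c("domains", "proteins")) {
  rank <- match.arg(rank)
  count <- match.arg(count)
  g <- profiles$genomes
  stopifnot(nrow(g) > 0)
  key <- if (rank == "genus") g$genus else paste(g$genus, g$species)
  val <- if (count == "domains") g$n_target_domains else g$n_target_proteins
  grp <- split(val, key)
  out <- data.frame(
    taxon = names(grp),
    rank = rank,
    n_genomes = lengths(grp),
    mean_gh_per_genome = vapply(grp, mean, numeric(1L)),
    sd = vapply(grp, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Flag high-potential degrader taxa and genomes
#'
#' Taxa whose mean target-GH count per genome strictly exceeds
#' `threshold_taxon` are flagged `HIGH_POTENTIAL`; individual genomes
#' whose target-GH domain count strictly exceeds `threshold_isolate`
#' are flagged `HIGH_POTENTIAL_ISOLATE`.
#'
#' @param profiles A `"genome_profiles"` object.
#' @param threshold_taxon Mean GHs per genome above which a taxon is
#'   flagged (default 8).
#' @param threshold_isolate GHs per genome above which a single genome
#'   is flagged (default 20).
#' @param rank Rank for the taxon-level summary (default `"genus"`).
#' @return Data.frame: `unit` (`"taxon"` or `"genome"`), `id`, `value`,
#'   `flag`.
#' @export
flag_degraders <- function(profiles, threshold_taxon = 8,
                           threshold_isolate = 20,
                           rank = c("genus", "species")) {
  rank <- match.arg(rank)
  ts <- taxon_summary(profiles, rank = rank)
  tax_hit <- ts[ts$mean_gh_per_genome > threshold_taxon, , drop = FALSE]
  g <- profiles$genomes
  gen_hit <- g[g$n_target_domains > threshold_isolate, , drop = FALSE]
  out <- rbind(
    if (nrow(tax_hit)) data.frame(unit = "taxon", id = tax_hit$taxon,
                                  value = tax_hit$mean_gh_per_genome,
                                  flag = "HIGH_POTENTIAL",
                                  stringsAsFactors = FALSE),
    if (nrow(gen_hit)) data.frame(unit = "genome", id = gen_hit$genome_id,
                                  value = as.numeric(gen_hit$n_target_domains),
                                  flag = "HIGH_POTENTIAL_ISOLATE",
                                  stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(unit = character(), id = character(),
                      value = numeric(), flag = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
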