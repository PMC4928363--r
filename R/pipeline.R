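# End-to-end orchestration: parse -> filter -> resolve -> architectures
# -> profiling -> conservatism, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one object. Defaults
#' reproduce the survey's published settings (E-value < 1e-5, coverage
#' > 60% of the profile, degrader thresholds 8 and 20, 999 Mantel
#' permutations).
#'
#' @param policy A [filter_policy()].
#' @param orientation domtblout orientation, `"scan"` or `"search"`.
#' @param genome_pattern Regex extracting genome ids from protein ids.
#' @param family_map_file,accessory_map_file Optional catalogue
#'   overrides (paths to TSVs of the packaged schema).
#' @param include_gh7 Include the GH7 profile in the target set?
#' @param terminal_thresholds Length-2 numeric, see [terminal_bias()].
#' @param threshold_taxon,threshold_isolate Degrader flags, see
#'   [flag_degraders()].
#' @param linkage Clustering linkage, see [hclust_tree()].
#' @param mantel_method `"pearson"` or `"spearman"`.
#' @param n_perm Mantel permutations.
#' @param min_genomes Minimum genomes per genus for the conservatism
#'   test.
#' @param seed Integer seed (required when `n_perm > 0`).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(policy = filter_policy(),
                            orientation = c("scan", "search"),
                            genome_pattern = "^([^|]+)\\|",
                            family_map_file = NULL,
                            accessory_map_file = NULL,
                            include_gh7 = FALSE,
                            terminal_thresholds = c(0.4, 0.6),
                            threshold_taxon = 8, threshold_isolate = 20,
                            linkage = c("average", "complete", "single"),
                            mantel_method = c("pearson", "spearman"),
                            n_perm = 999, min_genomes = 4, seed = 1) {
  orientation <- match.arg(orientation)
  linkage <- match.arg(linkage)
  mantel_method <- match.arg(mantel_method)
  if (n_perm > 0 && (is.null(seed) || is.na(seed))) {
    stop("config error: a seed is required when n_perm > 0")
  }
  structure(list(policy = policy, orientation = orientation,
                 genome_pattern = genome_pattern,
                 family_map_file = family_map_file,
                 accessory_map_file = accessory_map_file,
                 include_gh7 = include_gh7,
                 terminal_thresholds = terminal_thresholds,
                 threshold_taxon = threshold_taxon,
                 threshold_isolate = threshold_isolate,
                 linkage = linkage, mantel_method = mantel_method,
                 n_perm = as.integer(n_perm),
                 min_genomes = as.integer(min_genomes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_manifest <- function(config) {
  list(evalue_max = config$policy$evalue_max,
       coverage_min = config$policy$coverage_min,
       evalue_field = config$policy$evalue_field,
       overlap_max_fraction = config$policy$overlap_max_fraction,
       orientation = config$orientation,
       genome_pattern = config$genome_pattern,
       include_gh7 = config$include_gh7,
       terminal_thresholds = config$terminal_thresholds,
       threshold_taxon = config$threshold_taxon,
       threshold_isolate = config$threshold_isolate,
       linkage = config$linkage, mantel_method = config$mantel_method,
       n_perm = config$n_perm, min_genomes = config$min_genomes,
       seed = config$seed)
}

#' Run the full survey pipeline
#'
#' Executes every stage in order — parse the domtblout, filter hits,
#' resolve overlaps, build architectures, classify MAGHs, profile
#' genomes, flag degraders, and run the per-genus conservatism
#' analysis — and writes all result tables, per-genus Newick
#' dendrograms, and a JSON run manifest into `out_dir`. A failure in
#' any stage aborts with a stage-named error and removes partial
#' outputs.
#'
#' @param domtblout Path(s) to domtblout files, or an in-memory
#'   `raw_hits` data.frame.
#' @param taxonomy Path to a taxonomy TSV, or a taxonomy data.frame.
#' @param proteins Optional path to a FASTA/length TSV, or a protein
#'   data.frame; when `NULL` protein extents are inferred from hits.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   all file output.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `"gh_pipeline_result"`:
#'   `architectures`, `maghs`, `terminal_bias`, `profiles`,
#'   `taxon_summary`, `degrader_flags`, `mantel_by_genus`, `manifest`.
#' @export
run_pipeline <- function(domtblout, taxonomy, proteins = NULL,
                         out_dir = NULL, config = pipeline_config()) {
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "read_catalogues"
    fam <- gh_family_map(config$family_map_file,
                         include_gh7 = config$include_gh7)
    acc <- accessory_catalogue(config$accessory_map_file)

    stage <- "parse"
    input_files <- character(0)
    if (is.data.frame(domtblout)) {
      hits <- domtblout
    } else {
      input_files <- c(input_files, domtblout)
      hits <- do.call(rbind, lapply(domtblout, parse_domtblout,
                                    orientation = config$orientation,
                                    genome_pattern = config$genome_pattern))
    }
    if (is.character(taxonomy)) {
      input_files <- c(input_files, taxonomy)
      taxonomy <- read_taxonomy(taxonomy)
    }
    if (is.character(proteins)) {
      input_files <- c(input_files, proteins)
      proteins <- read_protein_lengths(proteins,
                                       genome_pattern = config$genome_pattern)
    }

    stage <- "filter"
    accepted <- filter_hits(hits, config$policy, fam, acc)
    stage <- "resolve_overlaps"
    resolved <- resolve_overlaps(accepted, config$policy)
    stage <- "architectures"
    prot_tab <- if (is.null(proteins)) NULL else {
      proteins[, c("protein_id", "genome_id", "length")]
    }
    arch <- build_architectures(resolved, prot_tab)
    maghs <- magh_classification(arch)
    tb <- if (nrow(maghs)) {
      terminal_bias(maghs, config$terminal_thresholds)
    } else {
      data.frame(gh_family = character(), n_first = integer(),
                 n_last = integer(), n_total_in_magh = integer(),
                 bias = character(), stringsAsFactors = FALSE)
    }

    stage <- "profiling"
    profiles <- genome_profiles(arch, taxonomy)
    ts <- taxon_summary(profiles, rank = "genus")
    flags <- flag_degraders(profiles, config$threshold_taxon,
                            config$threshold_isolate)

    stage <- "conservatism"
    mantel_tab <- compare_clusterings(arch, taxonomy,
                                      n_perm = config$n_perm,
                                      seed = config$seed,
                                      min_genomes = config$min_genomes,
                                      method = config$mantel_method)

    stage <- "write_outputs"
    manifest <- list(
      config = .config_manifest(config),
      inputs = if (length(input_files)) {
        lapply(stats::setNames(as.list(input_files), basename(input_files)),
               function(f) unname(tools::md5sum(f)))
      } else list(),
      counts = list(
        hits_read = nrow(hits),
        hits_accepted = nrow(accepted),
        domains_after_overlap = nrow(resolved),
        proteins_classified = sum(arch$n_target_gh > 0L),
        n_single = sum(arch$protein_class == "SINGLE"),
        n_mdgh = sum(arch$protein_class == "MDGH"),
        n_magh = sum(arch$protein_class == "MAGH"),
        n_genomes = nrow(taxonomy)))

    result <- structure(
      list(architectures = arch, maghs = maghs, terminal_bias = tb,
           profiles = profiles, taxon_summary = ts, degrader_flags = flags,
           mantel_by_genus = mantel_tab, manifest = manifest),
      class = "gh_pipeline_result")

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      wf <- function(df, name) {
        p <- file.path(out_dir, name)
        written <<- c(written, p)
        write_tsv(df, p)
      }
      wf(as.data.frame(arch), "architectures.tsv")
      wf(as.data.frame(maghs), "magh_classification.tsv")
      wf(tb, "terminal_bias.tsv")
      wf(profiles$genomes, "genome_profiles.tsv")
      wf(data.frame(genome_id = rownames(profiles$family_matrix),
                    profiles$family_matrix, check.names = FALSE),
         "family_matrix.tsv")
      wf(data.frame(genome_id = rownames(profiles$architecture_matrix),
                    profiles$architecture_matrix, check.names = FALSE),
         "architecture_matrix.tsv")
      wf(ts, "taxon_summary.tsv")
      wf(flags, "degrader_flags.tsv")
      wf(mantel_tab, "mantel_by_genus.tsv")

      nwk_dir <- file.path(out_dir, "newick")
      dir.create(nwk_dir, showWarnings = FALSE)
      for (gen in mantel_tab$genus[mantel_tab$status == "tested"]) {
        ids <- taxonomy$genome_id[taxonomy$genus == gen]
        cm <- count_matrices(arch[arch$genome_id %in% ids, , drop = FALSE],
                             genome_ids = ids)
        for (what in c("architecture", "family")) {
          p <- file.path(nwk_dir, paste0(gen, "_", what, ".nwk"))
          written <- c(written, p)
          dendrogram_newick(hclust_tree(bray_curtis(cm[[what]]),
                                        config$linkage), p)
        }
      }
      mp <- file.path(out_dir, "manifest.json")
      written <- c(written, mp)
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    invisible(result)
  }, error = on_fail)
}

#' @export
print.gh_pipeline_result <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("GH architecture pipeline result\n")
  cat(sprintf("  hits: %d read, %d passed filters, %d after overlap resolution\n",
              cnt$hits_read, cnt$hits_accepted, cnt$domains_after_overlap))
  cat(sprintf("  proteins with target GH: %d (SINGLE %d / MDGH %d / MAGH %d) in %d genomes\n",
              cnt$proteins_classified, cnt$n_single, cnt$n_mdgh,
              cnt$n_magh, cnt$n_genomes))
  tested <- x$mantel_by_genus[x$mantel_by_genus$status == "tested", ,
                              drop = FALSE]
  if (nrow(tested)) {
    cat("  conservatism (Mantel, per genus):\n")
    for (i in seq_len(nrow(tested))) {
      cat(sprintf("    %s (n=%d): r = %.3f, p = %.4g\n", tested$genus[i],
                  tested$n_genomes[i], tested$r[i], tested$p[i]))
    }
  }
  invisible(x)
}
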