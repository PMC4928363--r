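# Ground-truthed synthetic inputs: proteomes with planted architectures
# and decoy hits, genus-structured genome collections with tunable
# architecture conservatism, and the catalogued MAGH fixture. Every
# generator emits the same domtblout/FASTA/TSV formats the readers
# consume, alongside the truth tables tests compare against.

# Deterministic pseudo profile length per accession (>= 100 residues);
# only coordinates derived from it matter downstream.
.plen_for <- function(acc) {
  100L + (vapply(acc, function(a) sum(utf8ToInt(a)), integer(1L)) %% 15L) * 20L
}

# label -> accession lookup across both catalogues; labels not in either
# catalogue are used verbatim as accession (the filter's fallback then
# reproduces the label).
.label_accessions <- function(family_map, accessories) {
  c(stats::setNames(family_map$pfam_accession, family_map$gh_family),
    stats::setNames(accessories$pfam_accession, accessories$label))
}

.ACCESSIONS_DECOY <- c("PF07690", "PF00005", "PF01370", "PF13561",
                       "PF00106", "PF08240")

# One planted hit row for a domain of `acc` occupying [from, to] on the
# protein; E-value log-uniform in [1e-30, 1e-6], coverage in (0.61, 1].
.plant_hit <- function(protein_id, genome_id, acc, from, to) {
  plen <- .plen_for(acc)
  span <- as.integer(max(floor(0.62 * plen) + 1L,
                         ceiling(stats::runif(1, 0.62, 1) * plen)))
  span <- min(span, plen)
  hfrom <- sample.int(plen - span + 1L, 1L)
  ev <- as.numeric(sprintf("%.3g", 10^stats::runif(1, -30, -6)))
  data.frame(protein_id = protein_id, genome_id = genome_id,
             pfam_accession = acc, pfam_name = acc,
             profile_length = plen,
             seq_evalue = ev, dom_ievalue = ev,
             bitscore = as.numeric(sprintf("%.1f",
                                           -2 * log10(ev) +
                                             stats::runif(1, 0, 5))),
             hmm_from = hfrom, hmm_to = hfrom + span - 1L,
             ali_from = from, ali_to = to,
             env_from = from, env_to = to,
             stringsAsFactors = FALSE)
}

# Plant one protein realizing `labels` (ordered). Returns hits rows and
# the protein length.
.plant_protein <- function(protein_id, genome_id, labels, lab2acc, slack) {
  pos <- 1L + sample.int(slack + 1L, 1L) - 1L
  rows <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    acc <- lab2acc[labels[j]]
    if (is.na(acc)) acc <- labels[j]
    dom_len <- 60L + sample.int(120L, 1L)
    from <- pos + 1L
    to <- from + dom_len - 1L
    rows[[j]] <- .plant_hit(protein_id, genome_id, unname(acc), from, to)
    pos <- to + sample.int(slack + 1L, 1L)
  }
  list(hits = do.call(rbind, rows), length = pos + slack)
}

# Decoy violating exactly one filter criterion, placed inside the
# protein away from thresholds (E-value >= 1e-4 or coverage <= 0.5).
.decoy_subthreshold <- function(protein_id, genome_id, prot_len) {
  acc <- sample(.ACCESSIONS_DECOY, 1L)
  plen <- .plen_for(acc)
  bad_evalue <- stats::runif(1) < 0.5
  if (bad_evalue) {
    cov <- stats::runif(1, 0.7, 0.95)
    ev <- as.numeric(sprintf("%.3g", 10^stats::runif(1, -4, -1)))
  } else {
    cov <- stats::runif(1, 0.2, 0.5)
    ev <- as.numeric(sprintf("%.3g", 10^stats::runif(1, -20, -8)))
  }
  span <- as.integer(max(1L, round(cov * plen)))
  hfrom <- sample.int(plen - span + 1L, 1L)
  from <- sample.int(max(1L, prot_len - span), 1L)
  to <- as.integer(min(prot_len, from + span - 1L))
  h <- data.frame(protein_id = protein_id, genome_id = genome_id,
                  pfam_accession = acc, pfam_name = acc,
                  profile_length = plen,
                  seq_evalue = ev, dom_ievalue = ev,
                  bitscore = as.numeric(sprintf("%.1f",
                                                stats::runif(1, 5, 25))),
                  hmm_from = hfrom, hmm_to = hfrom + span - 1L,
                  ali_from = from, ali_to = to,
                  env_from = from, env_to = to,
                  stringsAsFactors = FALSE)
  h$decoy_type <- if (bad_evalue) "subthreshold_evalue" else {
    "subthreshold_coverage"
  }
  h
}

# Decoy passing the thresholds but overlapping a planted hit by ~75% of
# its span with a strictly worse E-value: removed by overlap resolution.
.decoy_overlap <- function(planted_row, accessories) {
  acc <- sample(accessories$pfam_accession, 1L)
  plen <- .plen_for(acc)
  span_p <- planted_row$env_to - planted_row$env_from + 1L
  span <- as.integer(max(1L, floor(0.75 * span_p)))
  from <- planted_row$env_from + (span_p - span)  # right-aligned inside
  cov <- stats::runif(1, 0.65, 0.95)
  hspan <- as.integer(min(plen, max(floor(0.62 * plen) + 1L,
                                    round(cov * plen))))
  hfrom <- sample.int(plen - hspan + 1L, 1L)
  ev <- as.numeric(sprintf("%.3g",
                           min(planted_row$dom_ievalue *
                                 10^stats::runif(1, 1, 3), 1e-6)))
  h <- data.frame(protein_id = planted_row$protein_id,
                  genome_id = planted_row$genome_id,
                  pfam_accession = acc, pfam_name = acc,
                  profile_length = plen,
                  seq_evalue = ev, dom_ievalue = ev,
                  bitscore = as.numeric(sprintf("%.1f",
                                                max(1, planted_row$bitscore - 10))),
                  hmm_from = hfrom, hmm_to = hfrom + hspan - 1L,
                  ali_from = from, ali_to = from + span - 1L,
                  env_from = from, env_to = from + span - 1L,
                  stringsAsFactors = FALSE)
  h$decoy_type <- "overlap"
  h
}

.class_for_labels <- function(labels, target_set) {
  n_tgt <- sum(labels %in% target_set)
  if (n_tgt == 0L) "NON_TARGET" else if (n_tgt >= 2L) "MAGH" else {
    if (length(labels) > 1L) "MDGH" else "SINGLE"
  }
}

# Realize a vector of canonical strings as planted proteins for one
# genome. Returns hits (with planted/decoy annotation), protein table,
# and the per-protein truth table.
.plant_genome <- function(canonicals, genome_id, family_map, accessories,
                          decoy_subthreshold_rate = 0,
                          overlap_decoy_rate = 0, length_slack = 25L,
                          id_offset = 0L) {
  lab2acc <- .label_accessions(family_map, accessories)
  target_set <- family_map$gh_family
  hit_rows <- list()
  prot_rows <- vector("list", length(canonicals))
  for (i in seq_along(canonicals)) {
    pid <- sprintf("%s|P%05d", genome_id, i + id_offset)
    labels <- parse_canonical(canonicals[i])
    pp <- .plant_protein(pid, genome_id, labels, lab2acc, length_slack)
    pp$hits$planted <- TRUE
    pp$hits$decoy_type <- ""
    rows <- list(pp$hits)
    for (j in seq_len(nrow(pp$hits))) {
      if (stats::runif(1) < decoy_subthreshold_rate) {
        d <- .decoy_subthreshold(pid, genome_id, pp$length)
        d$planted <- FALSE
        rows <- c(rows, list(d))
      }
      if (stats::runif(1) < overlap_decoy_rate) {
        d <- .decoy_overlap(pp$hits[j, , drop = FALSE], accessories)
        d$planted <- FALSE
        rows <- c(rows, list(d))
      }
    }
    hit_rows[[i]] <- do.call(rbind, rows)
    prot_rows[[i]] <- data.frame(
      protein_id = pid, genome_id = genome_id, length = pp$length,
      canonical = canonicals[i],
      protein_class = .class_for_labels(labels, target_set),
      n_target_gh = sum(labels %in% target_set),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) {
    hits <- .plant_hit("x", "x", "PF00150", 1L, 1L)[0L, ]
    hits$planted <- logical(0)
    hits$decoy_type <- character(0)
  }
  rownames(hits) <- NULL
  proteins <- do.call(rbind, prot_rows)
  list(hits = hits, proteins = proteins)
}

.random_fasta <- function(proteins, file) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  seqs <- vapply(proteins$length, function(n) {
    paste(sample(aa, n, replace = TRUE), collapse = "")
  }, character(1L))
  set <- Biostrings::AAStringSet(stats::setNames(seqs, proteins$protein_id))
  Biostrings::writeXStringSet(set, file, width = 70L)
  invisible(file)
}

#' Specification for a synthetic proteome
#'
#' @param n_proteins Number of proteins to generate.
#' @param architecture_pool Named numeric vector: canonical
#'   architecture strings with sampling weights (weights >= 0, sum > 0).
#' @param decoy_subthreshold_rate Per planted hit, probability of an
#'   extra hit violating exactly one filter criterion (E-value or
#'   coverage), in [0, 1).
#' @param overlap_decoy_rate Per planted hit, probability of an extra
#'   threshold-passing hit that overlaps it beyond the overlap
#'   tolerance with a worse E-value, in [0, 1).
#' @param length_slack Maximum inter-domain spacing in residues.
#' @param seed Integer seed; output is fully deterministic given the
#'   spec.
#' @return An object of class `"proteome_spec"`.
#' @export
proteome_spec <- function(n_proteins, architecture_pool,
                          decoy_subthreshold_rate = 0,
                          overlap_decoy_rate = 0,
                          length_slack = 25, seed = 1) {
  stopifnot(n_proteins >= 1, length(architecture_pool) >= 1,
            !is.null(names(architecture_pool)),
            all(architecture_pool >= 0), sum(architecture_pool) > 0,
            decoy_subthreshold_rate >= 0, decoy_subthreshold_rate < 1,
            overlap_decoy_rate >= 0, overlap_decoy_rate < 1,
            length_slack >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 architecture_pool = architecture_pool,
                 decoy_subthreshold_rate = decoy_subthreshold_rate,
                 overlap_decoy_rate = overlap_decoy_rate,
                 length_slack = as.integer(length_slack),
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic proteome with planted architectures
#'
#' Draws architectures from `spec$architecture_pool`, plants one Pfam hit per
#' domain (E-value log-uniform in \[1e-30, 1e-6\], profile coverage in
#' (0.61, 1\], i.e. clear of the default filter thresholds), and adds
#' the requested decoys. With `dir` given, writes
#' `<genome_id>.domtblout`, `<genome_id>.faa` and two truth TSVs;
#' identical spec and seed give byte-identical files.
#'
#' @param spec A [proteome_spec()].
#' @param dir Output directory, or `NULL` for in-memory output only.
#' @param genome_id Genome identifier embedded in protein ids
#'   (`"<genome_id>|P<num>"`).
#' @param family_map,accessories Catalogues used to translate
#'   architecture labels to accessions.
#' @return List: `hits` (a `raw_hits` data.frame including decoys, with
#'   truth columns `planted`, `decoy_type`), `proteins` (truth table:
#'   `protein_id`, `genome_id`, `length`, `canonical`, `protein_class`,
#'   `n_target_gh`), and, when written, `paths`.
#' @export
make_proteome <- function(spec, dir = NULL, genome_id = "G0001",
                          family_map = gh_family_map(),
                          accessories = accessory_catalogue()) {
  stopifnot(inherits(spec, "proteome_spec"))
  set.seed(spec$seed)
  pool <- spec$architecture_pool
  canonicals <- sample(names(pool), spec$n_proteins, replace = TRUE,
                       prob = pool / sum(pool))
  pg <- .plant_genome(canonicals, genome_id, family_map, accessories,
                      spec$decoy_subthreshold_rate,
                      spec$overlap_decoy_rate, spec$length_slack)
  out <- list(hits = pg$hits, proteins = pg$proteins)
  class(out$hits) <- c("raw_hits", "data.frame")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      domtblout = file.path(dir, paste0(genome_id, ".domtblout")),
      fasta = file.path(dir, paste0(genome_id, ".faa")),
      truth_proteins = file.path(dir, paste0(genome_id, ".truth_proteins.tsv")),
      truth_hits = file.path(dir, paste0(genome_id, ".truth_hits.tsv")))
    plens <- stats::setNames(pg$proteins$length, pg$proteins$protein_id)
    write_domtblout(pg$hits, paths$domtblout, protein_lengths = plens)
    .random_fasta(pg$proteins, paths$fasta)
    write_tsv(pg$proteins, paths$truth_proteins)
    write_tsv(pg$hits, paths$truth_hits)
    out$paths <- paths
  }
  out
}

#' Specification for a genus-structured genome collection
#'
#' Describes a collection of genera, each with a family-content
#' signature, whose genomes either reuse the genus repertoire (with
#' probability `conservation`) or carry a private one. Under
#' `coupling = "coupled"` every genome's architecture repertoire is a
#' fixed deterministic function of its family counts (each family
#' yields singles plus, for every third domain, a CBM2-decorated
#' variant), so architecture distances reproduce family distances.
#' Under `"decoupled"` each domain is decorated independently at random
#' from a large pool, so architecture composition is uninformative
#' about family composition.
#'
#' @param n_genera,genomes_per_genus Collection dimensions.
#' @param conservation Probability a genome reuses its genus
#'   repertoire, in [0, 1].
#' @param coupling `"coupled"` or `"decoupled"`.
#' @param n_domains Target GH domains per genome.
#' @param families GH families drawn from (must be in the family map).
#' @param seed Integer seed.
#' @return An object of class `"collection_spec"`.
#' @export
collection_spec <- function(n_genera = 3, genomes_per_genus = 6,
                            conservation = 0.8,
                            coupling = c("coupled", "decoupled"),
                            n_domains = 30,
                            families = c("GH5", "GH9", "GH10", "GH11",
                                         "GH18", "GH48"),
                            seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(n_genera >= 1, genomes_per_genus >= 1,
            conservation >= 0, conservation <= 1, n_domains >= 1,
            length(families) >= 2)
  structure(list(n_genera = as.integer(n_genera),
                 genomes_per_genus = as.integer(genomes_per_genus),
                 conservation = conservation, coupling = coupling,
                 n_domains = as.integer(n_domains), families = families,
                 seed = as.integer(seed)),
            class = "collection_spec")
}

# architecture strings for one genome given its per-family counts
.genome_architectures <- function(counts, families, coupling, deco_pool) {
  strs <- character(0)
  for (k in seq_along(families)) {
    c_f <- counts[k]
    if (c_f == 0L) next
    f <- families[k]
    if (coupling == "coupled") {
      n_dec <- c_f %/% 3L
      strs <- c(strs, rep(f, c_f - n_dec),
                if (n_dec) rep(paste0(f, "-CBM2"), n_dec))
    } else {
      # decoupled: decorations come from the genome's private subset of
      # a large pool, so architecture overlap between genomes reflects
      # decoration-set overlap, not family content
      deco <- sample(deco_pool, c_f, replace = TRUE)
      strs <- c(strs, paste0(f, "-", deco))
    }
  }
  strs
}

#' Generate a genus-structured genome collection
#'
#' @param spec A [collection_spec()].
#' @param dir Output directory (per-genome domtblout + FASTA, a
#'   taxonomy TSV and truth TSVs), or `NULL` for in-memory output.
#' @param family_map,accessories Catalogues, as in [make_proteome()].
#' @param emit_hits When `FALSE`, skip planting per-protein hits and
#'   return only `taxonomy` and `truth` (fast path for studies that
#'   need many replicate collections).
#' @return List: `hits` (all genomes, a `raw_hits` data.frame),
#'   `proteins`, `taxonomy`, and `truth` with `family_matrix` and
#'   `architecture_matrix` (genome-by-feature integer count matrices)
#'   — plus `paths` when written.
#' @export
make_genome_collection <- function(spec, dir = NULL,
                                   family_map = gh_family_map(),
                                   accessories = accessory_catalogue(),
                                   emit_hits = TRUE) {
  stopifnot(inherits(spec, "collection_spec"))
  set.seed(spec$seed)
  k <- length(spec$families)
  # decoupled mode decorates from a large pool of accessory-label pairs;
  # each genome uses a small private subset of it
  deco_global <- as.vector(outer(accessories$label[1:2], accessories$label,
                                 paste, sep = "-"))
  all_hits <- list(); all_prots <- list(); tax_rows <- list()
  arch_lists <- list()
  for (g in seq_len(spec$n_genera)) {
    base_probs <- if (spec$coupling == "decoupled") rep(1 / k, k) else {
      p <- stats::rgamma(k, 1); p / sum(p)
    }
    base_counts <- as.integer(stats::rmultinom(1L, spec$n_domains,
                                               base_probs))
    for (j in seq_len(spec$genomes_per_genus)) {
      gid <- sprintf("G%02d%02d", g, j)
      counts <- if (stats::runif(1) < spec$conservation) base_counts else {
        if (spec$coupling == "decoupled") {
          as.integer(stats::rmultinom(1L, spec$n_domains, rep(1 / k, k)))
        } else {
          p <- stats::rgamma(k, 1)
          as.integer(stats::rmultinom(1L, spec$n_domains, p / sum(p)))
        }
      }
      deco_pool <- if (spec$coupling == "decoupled") {
        sample(deco_global, 6L)
      } else character(0)
      strs <- .genome_architectures(counts, spec$families, spec$coupling,
                                    deco_pool)
      arch_lists[[gid]] <- strs
      if (emit_hits) {
        pg <- .plant_genome(strs, gid, family_map, accessories,
                            length_slack = 20L)
        all_hits[[gid]] <- pg$hits
        all_prots[[gid]] <- pg$proteins
      }
      tax_rows[[gid]] <- data.frame(
        genome_id = gid, genus = sprintf("Genus%02d", g),
        species = sprintf("species%02d", g), strain = sprintf("st%02d", j),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, all_hits); rownames(hits) <- NULL
  proteins <- do.call(rbind, all_prots); rownames(proteins) <- NULL
  taxonomy <- do.call(rbind, tax_rows); rownames(taxonomy) <- NULL
  if (!is.null(hits)) class(hits) <- c("raw_hits", "data.frame")

  gids <- taxonomy$genome_id
  fam_long <- lapply(gids, function(gid) {
    unlist(lapply(arch_lists[[gid]], function(s) {
      lab <- parse_canonical(s); lab[lab %in% family_map$gh_family]
    }))
  })
  fam_levels <- sort(unique(unlist(fam_long)))
  fam_mat <- t(vapply(fam_long, function(f) {
    as.integer(table(factor(f, levels = fam_levels)))
  }, integer(length(fam_levels))))
  dimnames(fam_mat) <- list(gids, fam_levels)
  all_strs <- sort(unique(unlist(arch_lists)))
  arch_mat <- t(vapply(gids, function(gid) {
    as.integer(table(factor(arch_lists[[gid]], levels = all_strs)))
  }, integer(length(all_strs))))
  dimnames(arch_mat) <- list(gids, all_strs)

  out <- list(hits = hits, proteins = proteins, taxonomy = taxonomy,
              truth = list(family_matrix = fam_mat,
                           architecture_matrix = arch_mat))
  if (!is.null(dir)) {
    if (!emit_hits) stop("emit_hits = FALSE cannot write per-genome files")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    plens <- stats::setNames(proteins$length, proteins$protein_id)
    dom_paths <- character(0)
    for (gid in gids) {
      p <- file.path(dir, paste0(gid, ".domtblout"))
      write_domtblout(hits[hits$genome_id == gid, , drop = FALSE], p,
                      protein_lengths = plens)
      .random_fasta(proteins[proteins$genome_id == gid, , drop = FALSE],
                    file.path(dir, paste0(gid, ".faa")))
      dom_paths <- c(dom_paths, p)
    }
    tax_path <- file.path(dir, "taxonomy.tsv")
    write_tsv(taxonomy, tax_path)
    write_tsv(data.frame(genome_id = rownames(fam_mat), fam_mat,
                         check.names = FALSE),
              file.path(dir, "truth_family_matrix.tsv"))
    write_tsv(data.frame(genome_id = rownames(arch_mat), arch_mat,
                         check.names = FALSE),
              file.path(dir, "truth_architecture_matrix.tsv"))
    out$paths <- list(domtblout = dom_paths, taxonomy = tax_path)
  }
  out
}

#' The catalogued multi-activity GH fixture
#'
#' Emits one synthetic MAGH protein per catalogued multi-activity GH of
#' the bacterial survey's category breakdown: 217 proteins in total —
#' 99 all-cellulase (26 homo GH5-GH5 + 73 hetero), 53 all-chitinase
#' (51 homo + 2 hetero), 48 all-xylanase (28 homo + 20 hetero), 11
#' cellulase:xylanase, 6 cellulase:chitinase, including 16 proteins
#' with three GH domains (10 homo, 5 hetero xylanase, 1 hetero
#' chitinase). Family pairs are drawn from families attested in
#' multi-activity proteins (GH5, 6, 9, 10, 11, 12, 18, 19, 30, 44,
#' 48), and terminal placements honor the observed biases (GH6/10/44/48
#' C-terminal, GH9/11/12/18 N-terminal) wherever the category leaves a
#' choice. Output is deterministic.
#'
#' @param dir Output directory (domtblout, FASTA, expected-category
#'   TSV), or `NULL` for in-memory output.
#' @param family_map,accessories Catalogues, as in [make_proteome()].
#' @return List: `hits`, `proteins` (truth table), `expected` (list
#'   with `n_total`, `n_homo`, `n_hetero`, `n_three_domain`, and
#'   `categories` data.frame), plus `paths` when written.
#' @export
make_table1_fixture <- function(dir = NULL,
                                family_map = gh_family_map(),
                                accessories = accessory_catalogue()) {
  canonicals <- c(
    rep("GH5-GH5", 26),                 # homo cellulase
    rep("GH9-3(CBM3)-GH48", 20),        # hetero cellulase ...
    rep("GH9-GH44", 10),
    rep("GH12-GH48", 10),
    rep("GH12-GH44", 8),
    rep("GH9-GH5", 10),
    rep("GH5-CBM2-GH48", 10),
    rep("GH5-GH6", 5),
    rep("GH18-GH18", 46),               # homo chitinase
    rep("GH18-GH18-GH18", 5),           # homo chitinase, 3 domains
    rep("GH18-GH19", 1),                # hetero chitinase
    rep("GH18-GH18-GH19", 1),           # hetero chitinase, 3 domains
    rep("GH11-GH11", 23),               # homo xylanase
    rep("GH11-GH11-GH11", 5),           # homo xylanase, 3 domains
    rep("GH11-GH10", 15),               # hetero xylanase
    rep("GH11-GH30-GH10", 5),           # hetero xylanase, 3 domains
    rep("GH10-CBM3-GH5", 6),            # cellulase:xylanase
    rep("GH5-CBM2-GH10", 5),
    rep("GH18-GH5", 6)                  # cellulase:chitinase
  )
  stopifnot(length(canonicals) == 217L)
  set.seed(217L)
  gid <- "MAGHFIX01"
  pg <- .plant_genome(canonicals, gid, family_map, accessories,
                      length_slack = 20L)
  class(pg$hits) <- c("raw_hits", "data.frame")
  expected <- list(
    n_total = 217L, n_homo = 105L, n_hetero = 112L, n_three_domain = 16L,
    categories = data.frame(
      category = c("cellulase:cellulase", "cellulase:chitinase",
                   "cellulase:xylanase", "chitinase:chitinase",
                   "xylanase:xylanase"),
      n_homo = c(26L, 0L, 0L, 51L, 28L),
      n_hetero = c(73L, 6L, 11L, 2L, 20L),
      n = c(99L, 6L, 11L, 53L, 48L),
      stringsAsFactors = FALSE))
  out <- list(hits = pg$hits, proteins = pg$proteins, expected = expected,
              taxonomy = data.frame(genome_id = gid, genus = "Fixturella",
                                    species = "synthetica", strain = "T1",
                                    stringsAsFactors = FALSE))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(domtblout = file.path(dir, paste0(gid, ".domtblout")),
                  fasta = file.path(dir, paste0(gid, ".faa")),
                  expected = file.path(dir, "expected_categories.tsv"),
                  taxonomy = file.path(dir, "taxonomy.tsv"))
    plens <- stats::setNames(pg$proteins$length, pg$proteins$protein_id)
    write_domtblout(pg$hits, paths$domtblout, protein_lengths = plens)
    .random_fasta(pg$proteins, paths$fasta)
    write_tsv(expected$categories, paths$expected)
    write_tsv(out$taxonomy, paths$taxonomy)
    out$paths <- paths
  }
  out
}
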