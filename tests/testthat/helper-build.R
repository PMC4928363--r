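# Shared constructors for hand-built accepted domains / architectures.

dom_row <- function(protein_id, label, start, end,
                    role = if (label %in% gh_family_map()$gh_family)
                      "TARGET_GH" else "ACCESSORY") {
  fam <- gh_family_map()
  data.frame(protein_id = protein_id, genome_id = sub("\\|.*", "", protein_id),
             pfam_accession = "PFX", label = label, role = role,
             substrate = if (role == "TARGET_GH")
               fam$substrate[match(label, fam$gh_family)] else "none",
             start = start, end = end, evalue = 1e-10, bitscore = 50,
             coverage = 0.9, stringsAsFactors = FALSE)
}

# architecture of a single protein with the given ordered labels
arch_of <- function(labels, protein_id = "G1|P1", len = 2000L) {
  d <- do.call(rbind, lapply(seq_along(labels), function(i) {
    dom_row(protein_id, labels[i], start = i * 100L, end = i * 100L + 80L)
  }))
  prot <- data.frame(protein_id = protein_id,
                     genome_id = sub("\\|.*", "", protein_id),
                     length = len, stringsAsFactors = FALSE)
  build_architectures(d, prot)
}

# plant a proteome from a pool and run the annotation stages
build_from_pool <- function(pool, n, seed, genome_id = "G0001") {
  pr <- make_proteome(proteome_spec(n, pool, seed = seed),
                      genome_id = genome_id)
  list(arch = build_architectures(
    resolve_overlaps(filter_hits(pr$hits)),
    pr$proteins[, c("protein_id", "genome_id", "length")]),
    truth = pr$proteins)
}

# run the full annotation on any in-memory generator output
annotate <- function(gen) {
  build_architectures(
    resolve_overlaps(filter_hits(gen$hits)),
    gen$proteins[, c("protein_id", "genome_id", "length")])
}
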