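domtbl_line <- function(prot = "G1|P1", acc = "PF00150.19", name = "Cellulase",
                        tlen = 300, ev = "1.2e-20", iev = "3.4e-19",
                        score = "55.1", hmm = c(5, 290), ali = c(10, 300),
                        env = c(8, 305)) {
  paste(name, acc, tlen, prot, "-", 400, ev, score, "0.1", 1, 1,
        iev, iev, score, "0.1", hmm[1], hmm[2], ali[1], ali[2],
        env[1], env[2], "0.95", "some description here")
}

test_that("parse_domtblout reads hit lines, skips comments, strips versions", {
  lines <- c("# comment", "# another comment", domtbl_line())
  hits <- parse_domtblout(lines)
  expect_s3_class(hits, "raw_hits")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pfam_accession, "PF00150")
  expect_equal(hits$protein_id, "G1|P1")
  expect_equal(hits$genome_id, "G1")
  expect_equal(hits$profile_length, 300L)
  expect_equal(hits$seq_evalue, 1.2e-20)
  expect_equal(hits$dom_ievalue, 3.4e-19)
  expect_equal(hits$env_from, 8L)
  expect_equal(hits$env_to, 305L)
})

test_that("parsing is insensitive to runs of blanks between columns", {
  one <- domtbl_line()
  padded <- gsub(" ", "   ", one)
  expect_equal(parse_domtblout(one)[, -1L], parse_domtblout(padded)[, -1L])
})

test_that("search orientation swaps the protein and profile columns", {
  # hmmsearch: target = protein, query = profile
  line <- paste("G1|P1", "-", 400, "Cellulase", "PF00150.19", 300,
                "1e-20", "55.1", "0.1", 1, 1, "1e-19", "1e-19", "55.1",
                "0.1", 5, 290, 10, 300, 8, 305, "0.95", "desc")
  hits <- parse_domtblout(line, orientation = "search")
  expect_equal(hits$protein_id, "G1|P1")
  expect_equal(hits$pfam_accession, "PF00150")
  expect_equal(hits$profile_length, 300L)
})

test_that("malformed lines are rejected with their line number", {
  bad <- c("# header", domtbl_line(), "too few columns here")
  expect_error(parse_domtblout(bad), "line 3")
  nonnum <- domtbl_line(ev = "not_a_number")
  expect_error(parse_domtblout(nonnum), "non-numeric")
  inverted <- domtbl_line(hmm = c(290, 5))
  expect_error(parse_domtblout(inverted), "inconsistent")
})

test_that("genome ids come from the pattern or an explicit map", {
  hits <- parse_domtblout(domtbl_line(prot = "ABC123|p77"))
  expect_equal(hits$genome_id, "ABC123")
  expect_error(parse_domtblout(domtbl_line(prot = "no_separator")),
               "did not match")
  map <- data.frame(protein_id = "no_separator", genome_id = "GZ",
                    stringsAsFactors = FALSE)
  hits2 <- parse_domtblout(domtbl_line(prot = "no_separator"),
                           genome_map = map)
  expect_equal(hits2$genome_id, "GZ")
})

test_that("generator-written domtblout round-trips field by field", {
  sp <- proteome_spec(25, c("GH5" = 1, "GH5-CBM2" = 1, "GH18-GH18" = 1),
                      decoy_subthreshold_rate = 0.3,
                      overlap_decoy_rate = 0.3, seed = 42)
  td <- withr::local_tempdir()
  pr <- make_proteome(sp, dir = td, genome_id = "G0042")
  expect_gte(nrow(pr$hits), 25L)
  hits <- parse_domtblout(pr$paths$domtblout)
  expect_equal(nrow(hits), nrow(pr$hits))
  for (cn in names(hits)) {
    expect_identical(hits[[cn]], pr$hits[[cn]], label = cn)
  }
})

test_that("protein lengths read identically from FASTA and TSV", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "p.faa")
  writeLines(c(">G1|P1 some desc", strrep("M", 70), strrep("A", 30),
               ">G1|P2", "MKV"), fa)
  rec <- read_protein_lengths(fa)
  expect_equal(rec$length, c(100L, 3L))
  expect_equal(rec$genome_id, c("G1", "G1"))

  tsv <- file.path(td, "p.tsv")
  writeLines(c("protein_id\tlength", "G1|P1\t250"), tsv)
  rec2 <- read_protein_lengths(tsv)
  expect_equal(rec2$protein_id, "G1|P1")
  expect_equal(rec2$length, 250L)

  dup <- file.path(td, "dup.faa")
  writeLines(c(">G1|P1", "MK", ">G1|P1", "MA"), dup)
  expect_error(read_protein_lengths(dup), "duplicate")
})

test_that("FASTA lengths from the generator match its truth table", {
  sp <- proteome_spec(10, c("GH9-3(CBM3)-GH48" = 1), seed = 5)
  td <- withr::local_tempdir()
  pr <- make_proteome(sp, dir = td)
  rec <- read_protein_lengths(pr$paths$fasta)
  expect_identical(rec$length, pr$proteins$length)
  expect_identical(rec$protein_id, pr$proteins$protein_id)
})

test_that("taxonomy reader enforces uniqueness and required fields", {
  td <- withr::local_tempdir()
  ok <- file.path(td, "tax.tsv")
  writeLines(c("genome_id\tgenus\tspecies\tstrain",
               "G1\tCaldicellulosiruptor\tbescii\tDSM6725"), ok)
  tax <- read_taxonomy(ok)
  expect_equal(nrow(tax), 1L)
  expect_equal(tax$genus, "Caldicellulosiruptor")

  dup <- file.path(td, "dup.tsv")
  writeLines(c("genome_id\tgenus\tspecies\tstrain",
               "G1\tA\tb\t", "G1\tA\tc\t"), dup)
  expect_error(read_taxonomy(dup), "duplicate")

  nog <- file.path(td, "nog.tsv")
  writeLines(c("genome_id\tgenus\tspecies\tstrain", "G1\t\tb\t"), nog)
  expect_error(read_taxonomy(nog), "genus")
})

test_that("collection taxonomy round-trips through the reader", {
  td <- withr::local_tempdir()
  cc <- make_genome_collection(
    collection_spec(n_genera = 2, genomes_per_genus = 2, seed = 9),
    dir = td)
  tax <- read_taxonomy(cc$paths$taxonomy)
  expect_identical(tax, cc$taxonomy)
})
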