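---
title: "Reconstructing and comparing glycoside hydrolase domain architectures"
author: "ghArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and comparing glycoside hydrolase domain architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghArch)
```

## The model

ghArch treats a bacterial proteome as a collection of proteins, each
carrying zero or more Pfam domain hits, and asks three things: which
hits are trustworthy, how the accepted domains are organized along
each protein, and whether that organization is taxonomically
conserved.

**Target families.** Fourteen GH families define the catalytic target
set: cellulases GH5, 6, 8, 9, 12, 44, 45, 48; xylanases GH10, 11, 30;
chitinases GH18, 19, 85 — each identified by one Pfam profile
(`gh_family_map()`). GH7 is a predominantly fungal cellulase family
whose profile is part of the same catalogue but disabled by default
(`include_gh7 = TRUE` restores it); it is absent from the bacterial
census the defaults reproduce. Every other accepted domain — CBMs,
dockerin/cohesin, SLH, fibronectin, cadherin, other GH families such
as GH3, and anything unrecognized — is *accessory*: it decorates
architectures and feeds the architecture-level clustering but never
counts as a catalytic target. Consequently a protein with GH5 + GH3 is
a multi-domain GH, not a multi-activity one.

**Hit acceptance.** A hit survives iff its E-value is strictly below
`evalue_max` (default 1e-5) *and* its profile coverage — the spanned
fraction `(hmm_to − hmm_from + 1) / profile_length` of the Pfam model,
not of the protein — is strictly above `coverage_min` (default 0.60).
Both thresholds are taken verbatim from the survey the package
re-implements and both are strict, which the tests pin down at the
boundary (an E-value of exactly 1e-5 or coverage of exactly 0.60
fails). HMMER reports two E-values per domain line; the filter applies
to the per-domain independent E-value by default (`evalue_field =
"dom_ievalue"`), because architecture work needs per-domain
significance — a multi-domain protein can have an excellent
full-sequence E-value carried by one strong domain. The full-sequence
E-value remains available as a policy switch since the original survey
does not say which it used.

**Overlap resolution.** Pfam scans regularly produce overlapping hits.
Absent a published rule, ghArch uses the standard greedy scheme:
candidates are ranked by ascending E-value (ties: higher bit score,
then lower start) and accepted unless they overlap an already-kept
domain by more than `overlap_max_fraction` (default 0.5) of the
shorter of the two. This is deterministic and small enough to check
exhaustively — the tests compare it against a brute-force search over
all conflict-free subsets for up to 10 candidates.

**Architectures and classes.** Accepted domains are ordered by
envelope start (envelopes are HMMER's best estimate of domain extent;
ties break by smaller end, then label, so output is deterministic).
The canonical string joins the ordered labels with `-`, collapsing
runs of k ≥ 2 identical *accessory* labels to `k(label)` — e.g.
`GH9-3(CBM3)-GH48` — while tandem catalytic repeats stay explicit
(`GH5-GH5`), since the number of catalytic domains is the classifying
quantity. Classes partition all proteins with at least one target GH:
SINGLE (one target GH and nothing else), MDGH (one target GH plus
other domains), MAGH (≥ 2 target GHs). MAGHs are homo-GH when all
catalytic domains come from one family, hetero-GH otherwise, and carry
a substrate-pair label — the sorted multiset of implied activities
(`cellulase:xylanase`), rendered with activity nouns to match the
survey's text; a substrate-noun rendering (`cellulose:xylan`) is a
formatting option.

**Terminal bias.** Statements like "GH48 is mostly C-terminal" are
operationalized on domain order within MAGHs, not absolute residue
position: per family, count how often it is the N-most and C-most
catalytic domain across MAGHs, and call it N_TERMINAL when the
first-position fraction exceeds 0.6, C_TERMINAL below 0.4, MIXED
otherwise (a family observed only in protein interiors is also
MIXED). The 0.4/0.6 cut points are package choices surfaced in
`terminal_bias(thresholds = )`; order-based rather than residue-based
placement was chosen because the survey's claims concern the relative
arrangement of catalytic domains, and a residue-based reading would
make the answer depend on linker lengths the census never tabulated.

## The conservatism analysis

Per genus with at least 4 genomes (the census analyzed genera with
more than 3 sequenced genomes), two genome-by-feature count matrices
are built: proteins per canonical architecture string, and target GH
domains per family. Both are turned into Bray-Curtis dissimilarities
(`d = Σ|x−y| / Σ(x+y)`, with pairs of all-zero genomes assigned
d = 0), clustered by UPGMA, and compared with a one-sided permutation
Mantel test: r is the Pearson correlation of the lower-triangle
entries and `p = (1 + #{r* ≥ r}) / (1 + n_perm)` with rows and columns
of the second matrix permuted jointly (default 999 permutations,
matching the published analysis; Spearman is a flag). Bray-Curtis and
average linkage are package defaults — the survey names its analysis
environment but not its dissimilarity or linkage — and both are
configurable. Genera whose distance matrices have zero variance
(e.g. all genomes identical) are reported as `degenerate` rather than
tested, since r is undefined there.

Seeds are explicit everywhere a permutation or simulation happens:
`mantel_test(seed = )`, and per genus `compare_clusterings()` uses
`seed + genus index` so genera are reproducible yet independent.

## What the synthetic data emulate

No genome accessions are distributed with the census, so the package
ships generators instead of fixtures:

- `make_proteome()` plants architectures drawn from a weighted pool.
  Planted hits sample E-values log-uniformly in [1e-30, 1e-6] and
  coverages in (0.61, 1] — deliberately clear of the 1e-5 / 0.60
  thresholds so boundary behavior is tested on purpose-built cases,
  never by accident. Decoys violate exactly one criterion (E-value in
  [1e-4, 1e-1] or coverage ≤ 0.5), or pass both criteria but overlap a
  planted domain by ~75% of its span with a strictly worse E-value, so
  each filtering stage has hits only it can remove. Profile lengths
  are a deterministic function of the accession; sequences are random
  residues — only lengths and coordinates matter downstream.
- `make_genome_collection()` builds genus-structured collections. Each
  genus has a family-content signature (Dirichlet-weighted multinomial
  over six families, 30 domains per genome); each genome reuses it
  with probability `conservation` or draws a private one. Under
  `coupling = "coupled"` the architecture repertoire is a fixed
  monotone function of the family counts (singles plus a
  CBM2-decorated variant for every third domain), which provably
  preserves Bray-Curtis distances — so the architecture and family
  clusterings agree (Mantel r = 1) and the pipeline must recover that.
  Under `"decoupled"` each domain is instead decorated from a small
  genome-private subset (6) of a 56-element pool of accessory-label
  pairs: architecture overlap between genomes is then driven by
  decoration-set overlap, which is independent of family content, and
  the Mantel correlation is near zero by construction. A small
  positive residual remains because architecture strings necessarily
  embed their family label; the subset/pool sizes were chosen so that
  this residual is well inside the ±0.1 band the decoupling contract
  asserts, with no degenerate (zero-variance) replicates.
- `make_table1_fixture()` realizes the published multi-activity census
  as 217 synthetic proteins: 26 homo + 73 hetero all-cellulase, 51 + 2
  all-chitinase, 28 + 20 all-xylanase, 11 cellulase:xylanase, 6
  cellulase:chitinase, including 16 three-domain proteins (10 homo, 5
  hetero xylanase, 1 hetero chitinase). The census prints only
  category totals, so family compositions within categories are
  package choices restricted to families the text attests
  (GH5-GH5, GH9…GH48 with a 3×CBM3 linker, GH18 tandems, GH11 homo
  pairs, GH10-CBM3-GH5, GH18+GH5), with terminal placements honoring
  the published N/C biases wherever the category leaves a choice —
  homo pairs are symmetric and constrain nothing. The three-domain
  homo proteins are split 5 xylanase / 5 chitinase; the census says
  only that they target xylan and chitin.

What passing these tests shows — and does not. The generators emulate
coordinates, scores and taxonomic structure, not HMMER scoring of real
sequences: E-values are planted, domains never truncate at protein
ends, and within-genus structure is exchangeable rather than
phylogenetic. Exact recovery of planted truth therefore validates the
bookkeeping (parsing, filtering, resolution, classification,
counting), and the coupled/decoupled contrasts validate the
statistics; neither certifies annotation quality on real proteomes,
which inherits whatever error the upstream Pfam scan carries.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive throughout, as in HMMER output.
- An empty domtblout is valid input: every pipeline output is written
  with zero rows and the run succeeds.
- Proteins whose accepted domains are all accessory are NON_TARGET:
  they appear in the architecture table but are excluded from GH
  counts and both count matrices, matching the census's restriction to
  proteins targeting the three substrates.
- Genomes present in the taxonomy but absent from the hits keep
  all-zero profiles, so per-genus matrices always have the full row
  set; a genome in the hits but missing from the taxonomy is an error
  naming the offenders.
- "GHs per genome" counts domains, not proteins (a GH5-GH5 protein
  contributes 2); the census tallies domains and proteins separately
  and the degrader thresholds (mean > 8 per taxon, > 20 per isolate,
  both strict) are read against the domain counts. A protein-based
  mode is a flag in `taxon_summary()`.
- Mantel r requires variance in both triangles; zero variance is an
  error (`mantel_test`) or a `degenerate` status
  (`compare_clusterings`), never a silent 0 or 1.

## Problem sizes used by the tests

The suite runs the overlap oracle on ≤ 10 candidates (exhaustive
enumeration is exact there), 50 random proteome specifications of
5–15 proteins for closed-loop recovery, a 12-genome coupled genus at
999 permutations, 100 decoupled replicate collections of 8 genomes for
the null-coupling contrast, and 500 null simulations at 199
permutations for the type-I-error calibration of the Mantel test —
sizes at which the exact oracles remain computable and the binomial
bounds on a 5% rejection rate are tight (99% interval ±2.5 points).

## Known limitations

- No clan-aware overlap logic or Pfam gathering thresholds; the
  E-value/coverage filter is the whole acceptance story.
- Substrate assignment is family-level; polyspecific families are
  collapsed onto their canonical substrate.
- The conservatism analysis is genus-bound and distance-based; it does
  not infer trees across genera or attach bootstrap support.
- Terminal bias uses domain order, not residue position; an
  absolute-position mode would require linker-length conventions the
  package deliberately avoids.
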