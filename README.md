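# ghArch

Domain architectures of bacterial glycoside hydrolases (GHs) targeting
cellulose, xylan and chitin, reconstructed from Pfam/HMMER3 scans of
predicted proteomes.

## The problem

Bacterial polysaccharide degraders carry glycoside hydrolase domains
from a well-characterized set of families — cellulases (GH5, 6, 8, 9,
12, 44, 45, 48), xylanases (GH10, 11, 30) and chitinases (GH18, 19,
85), each mapped to a Pfam profile. A protein may carry one catalytic
domain alone (*single-domain*), one catalytic domain plus accessory
domains such as carbohydrate-binding modules, dockerins or S-layer
homology domains (*multi-domain GH*, MDGH), or two or more catalytic
domains (*multi-activity GH*, MAGH) whose physical linkage makes them
act synergistically — proteins of direct interest to biofuel
technology. Two questions drive the analysis:

1. **What architectures exist?** Per protein, the ordered set of
   accepted domains, written as a canonical string such as
   `GH9-3(CBM3)-GH48`, and the classification into
   SINGLE / MDGH / MAGH (with MAGHs subclassified as homo- vs
   hetero-GH and by substrate pair, e.g. `cellulase:xylanase`).
2. **Is architecture taxonomically conserved?** Per genus, genomes are
   clustered twice — once on their architecture repertoire, once on
   their GH family content — and the two distance structures are
   compared with a permutation Mantel test (Bray-Curtis
   dissimilarity, UPGMA clustering, one-sided
   p = (1 + #{r\* ≥ r}) / (1 + n_perm)).

Hits are accepted when the per-domain independent E-value is below
1e-5 and the hit covers more than 60% of the Pfam profile (both
strict); competing hits on one protein are resolved greedily by
E-value with a 50%-of-the-shorter-domain overlap tolerance.

## Worked example

Everything is testable without downloads through the ground-truthed
synthetic-data generators. The built-in fixture reproduces the
catalogued MAGH census of the bacterial survey:

```r
library(ghArch)

fix  <- make_table1_fixture(dir = "fixture")      # domtblout + FASTA + truth
res  <- run_pipeline(fix$paths$domtblout,
                     taxonomy = fix$paths$taxonomy,
                     proteins = fix$paths$fasta,
                     out_dir  = "fixture_out",
                     config   = pipeline_config(seed = 1))
print(res)
#> GH architecture pipeline result
#>   hits: 531 read, 531 passed filters, 531 after overlap resolution
#>   proteins with target GH: 217 (SINGLE 0 / MDGH 0 / MAGH 217) in 1 genomes

s <- magh_summary(res$maghs)
s$categories
#>              category n_homo n_hetero  n
#> 1 cellulase:cellulase     26       73 99
#> 2 cellulase:chitinase      0        6  6
#> 3  cellulase:xylanase      0       11 11
#> 4 chitinase:chitinase     51        2 53
#> 5   xylanase:xylanase     28       20 48
round(s$pct_hetero)   # 52  (% of multi-activity proteins that are hetero-GH)
s$n_three_domain      # 16  (proteins with three catalytic domains)
```

All 217 fixture proteins are multi-activity by construction; the
category table is the published census arithmetic: 105 homo vs 112
hetero (52%), 99 cellulase:cellulase, 53 chitinase:chitinase, 48
xylanase:xylanase, 11 cellulase:xylanase, 6 cellulase:chitinase.

For the conservatism question, a coupled synthetic genus (architecture
repertoires a deterministic function of family content) gives a strong
association:

```r
cc  <- make_genome_collection(collection_spec(n_genera = 1,
         genomes_per_genus = 12, conservation = 0.4,
         coupling = "coupled", seed = 1), dir = "sim")
res <- run_pipeline(cc$paths$domtblout, cc$paths$taxonomy,
                    out_dir = "sim_out",
                    config = pipeline_config(n_perm = 999, seed = 1))
res$mantel_by_genus
#>     genus n_genomes r     p n_perm seed status
#> 1 Genus01        12 1 0.001    999    2 tested
```

`run_pipeline()` writes `architectures.tsv`, `magh_classification.tsv`,
`terminal_bias.tsv`, `genome_profiles.tsv`, `taxon_summary.tsv`,
`degrader_flags.tsv`, the two count matrices, `mantel_by_genus.tsv`,
per-genus Newick dendrograms and a JSON run manifest with stage counts
and input checksums. A thin command-line wrapper lives at
`inst/cli/gharch.R` (`run`, `simulate`, `fixture` subcommands).

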