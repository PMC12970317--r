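# barcodelim

Integrative single-locus species delimitation from DNA barcodes, in R.

Reference libraries of animal barcodes (typically ~600 bp of
mitochondrial COI) routinely hide cryptic diversity behind widespread
"species" names, and mix well-vouchered records with misidentified ones.
Algorithmic delimiters disagree with each other, and none of them knows
about geography, morphology or type specimens. `barcodelim` implements
the full working chain a barcoding taxonomist uses, as tested,
reproducible code:

1. **K2P distances** under pairwise deletion:
   `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with transition/transversion
   proportions `P`, `Q`, plus saturation handling;
2. a **guide tree** — neighbor joining + midpoint rooting, or an
   externally built ML tree;
3. two independent **OTU delimiters**: a barcode-gap threshold sweep
   (single-linkage partitions ranked by gap width) and a **Poisson tree
   processes** (PTP) model with exact/greedy maximum-likelihood search
   and a Bayesian MCMC mode (`bptp_mcmc`, default 500,000 generations);
4. an **integrative reconciliation** layer: congruent OTUs pass through;
   conflicts are resolved sister-pair by sister-pair on the guide tree —
   sympatric pairs are retained, shallow allopatric pairs are merged,
   allopatric pairs at or above a strong-divergence override (default
   5.5% K2P) are retained — with a 3% divergence guide reported
   throughout, morphological overrides honored, misidentification
   (name-incongruence) flags, and species names anchored on
   type-locality membership;
5. a **coalescent K80 simulator** with known species truth, so every
   stage and the end-to-end recovery rate are verifiable offline.

The intended users are molecular taxonomists and barcoding labs curating
single-locus reference libraries — the package was built around a
lizardfish-scale problem (tens of nominal species, hundreds of
sequences, 8 biogeographic region codes: GC, BP, TEA, ECS, SCS, SAS,
CWP, IO), but nothing in it is taxon-specific.

## Worked example

Simulate a 5-species fauna with 10% label noise, run the pipeline, and
compare against the truth:

```r
library(barcodelim)

sim <- simulate_barcodes(sim_config(n_species = 5, n_per_species = 6,
                                    mislabel_rate = 0.1, seed = 2024))
run <- delim_run(sim$alignment, sim$meta, seed = 1)
run$report
#> Delimitation run: 30 specimens x 615 bp (guide tree: nj_midpoint)
#>   OTUs - gap best: 5; gap@0.030: 5; PTP ML: 5
#>   Final species hypotheses: 5
#>   Flags: congruent=5, name_incongruent=2

run$table$hypotheses[, c("otu_id", "n_members", "assigned_name", "name_basis")]
#>   otu_id n_members assigned_name    name_basis
#> 1   H001         6  Simulus sp04 type_locality
#> 2   H002         6  Simulus sp02 type_locality
#> 3   H003         6  Simulus sp03 type_locality
#> 4   H004         6  Simulus sp04 type_locality
#> 5   H005         6  Simulus sp05 type_locality

score_recovery(run$partitions$final, sim$truth$partition)[c("exact_count_match", "adjusted_rand")]
#> $exact_count_match [1] TRUE
#> $adjusted_rand     [1] 1
```

Both delimiters agree on 5 OTUs (all flagged `congruent`), the final
partition matches the simulated truth exactly, and the label noise shows
up exactly where it should: two hypotheses are flagged
`name_incongruent` — a mislabeled type specimen has dragged the name
"Simulus sp04" onto two different OTUs, which is the package telling you
those names need curation, not silently picking one.

Divergence summaries (percent K2P, min/mean/max per hypothesis pair):

```r
head(summarize_divergences(run$table, run$distances)$by_otu, 3)
#>   group1 group2  min_pct mean_pct  max_pct
#> 1   H001   H002 14.86823 15.06739 15.27164
#> 2   H001   H003 12.65937 13.02064 13.26422
#> 3   H001   H004 11.54680 11.76618 11.93211
```

Real data enter through `read_fasta()` (aligned FASTA),
`read_metadata()` (TSV: id, species, locality, region, type_locality)
and optionally `read_guide_tree()` (newick); `write_delim_run()` writes
all artifacts (distance matrices, partitions, gap ranking, species
table, run report JSON) under stable filenames. A thin CLI wrapper
lives at `inst/scripts/delim.R` (`run` and `simulate` subcommands).

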