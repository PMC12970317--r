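---
title: "Methods: integrative single-locus species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative single-locus species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelim)
```

## The problem

DNA barcoding compares short standardized fragments (for animals,
~600–650 bp of mitochondrial COI) across many specimens to sort them into
operational taxonomic units (OTUs) — putative species — without a prior
species hypothesis. Reference libraries assembled from public databases
mix carefully identified voucher specimens with misidentified records,
and morphologically conservative groups (the motivating case is marine
fishes with widespread "species" spanning ocean basins) often hide
substantial cryptic diversity. A single locus cannot settle species
limits by itself: different algorithmic delimiters disagree, and a
genetic cluster is only a species *hypothesis* until geography,
morphology and nomenclature are brought to bear.

`barcodelim` implements that whole chain as reproducible code: K2P
distances, a guide tree, two independent delimiters, and an integrative
reconciliation step that applies congruence, divergence thresholds, a
sympatry/allopatry criterion over discrete biogeographic regions,
misidentification flags, and type-locality-anchored naming. A
ground-truth simulator makes every stage testable at desk scale.

## Distances

Pairwise distances use the Kimura two-parameter correction,

$$ d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q), $$

where $P$ and $Q$ are the observed transition and transversion
proportions. Only columns where **both** sequences carry an unambiguous
A/C/G/T are compared (pairwise deletion); this is the standard choice for
mixed-provenance barcode data, where complete deletion would discard most
of the alignment whenever a few records are ragged. The convention is a
documented default, not a switch hidden in the code: `count_site_pairs()`
exposes the per-pair site counts so any analysis can be audited.

Saturated pairs — those with $1-2P-Q \le 0$ or $1-2Q \le 0$, where the
correction diverges — are assigned a configurable cap (default 1.0
substitutions/site) so the matrix stays finite for clustering, but they
are excluded from barcode-gap statistics and threshold sweeps: a capped
value is a placeholder, not a distance. Distances are proportions
internally; percentages appear only in reports, which is the scale
barcoding studies print.

## Guide tree

When no externally built tree is supplied, `nj_tree()` runs
neighbor joining on the K2P matrix and `midpoint_root()` places the root
at the midpoint of the longest leaf-to-leaf path. Negative NJ branch
estimates are clamped to zero and counted. An external maximum-likelihood
tree (newick) is accepted and preferred when available — tree quality is
the main limit on the tree-based delimiter, and NJ is offered as the
dependency-free default, not as a substitute for a proper phylogenetic
analysis. Polytomies are resolved arbitrarily with zero-length edges
before tree-based steps, with a logged note.

## Barcode-gap partitioner

The gap delimiter sweeps candidate thresholds (midpoints between
consecutive distinct pairwise distances), forms the single-linkage
partition at each — OTUs are connected components of the graph joining
pairs with $d \le t$ — and scores every distinct partition by its
**barcode gap**: the smallest between-OTU distance minus the largest
within-OTU distance. Partitions are ranked by gap width; the relative gap
(width over the gap-center threshold) is reported alongside.

Two design points deserve comment.

* **Why absolute width, not the relative gap?** The relative gap
  $(d_{\min}^{between} - d_{\max}^{within})/t$ diverges as $t \to 0$
  whenever near-identical haplotypes exist — and they always do in
  population samples — so a ratio-based ranking systematically puts
  trivial oversplits first. Absolute width has no such pathology; the
  relative gap is still computed for inspection.
* **`gap_floor`** (default 0.005 substitutions/site): a "gap" narrower
  than typical intraspecific COI variation (commonly 0.3–1%) is no
  evidence of species structure. When no candidate reaches the floor the
  ranking is flagged `no_barcode_gap` and the one-OTU partition leads,
  with the all-singleton partition also listed.

Single-linkage is used (rather than average or complete linkage) because
it matches the "connected below threshold" reading of threshold
clustering and makes the partitions provably nested in $t$ — a property
the test suite checks. OTUs whose internal distance distribution shows a
wider gap than the parent partition's are recursively re-split and the
refined partition added as an extra candidate.

Distance-only delimiters lump hierarchically structured faunas: when
between-species divergences span an order of magnitude, the widest gap
sits at a deep split. This is expected and harmless here because the gap
partition serves as the *coarse* delimiter; the reconciliation step works
through its conflicts with the finer tree-based partition.

## Poisson tree processes (PTP)

The tree-based delimiter models branch lengths (in expected
substitutions) as draws from two exponential processes: *speciation*
(between-species branching) and *coalescent* (within-species branching).
A delimitation is encoded by the set $S$ of "speciation nodes",
constrained to be ancestrally closed — a node can be speciation-class
only if its parent is — with the root in $S$ for any non-trivial state;
$S = \emptyset$ is the one-species state. Edges whose parent node is in
$S$ are speciation-class; species are the maximal subtrees whose internal
edges are all coalescent-class, so for a binary tree the species count is
$|S| + 1$.

Class rates are profiled analytically, $\hat\lambda = n/\sum b$, giving
the log-likelihood $\sum_{\text{class}} [\,n \ln(n/\textstyle\sum b) - n\,]$;
this keeps the state space discrete and the maximum-likelihood partition
well defined. Three numerical safeguards matter in practice:

* **Branch-length floor** (`min_branch`, default $10^{-3}$
  substitutions/site). Estimated trees contain near-zero branches —
  identical haplotypes, clamped NJ negatives — and with an unbounded
  rate the ML solution degenerates into "isolate the shortest edges in
  one class". $10^{-3}$ is below one substitution on a ~600 bp locus,
  i.e. the resolution of the data; flooring there removes the
  degeneracy without touching informative branches.
* **Null guard.** The two-rate model always gains some likelihood over
  the single-rate null on noisy lengths, so a literal ML search never
  returns "one species". `ptp_ml_search()` therefore applies a
  likelihood-ratio test against the single-rate null ($\chi^2$, 1 df,
  `null_alpha` = 0.05) and returns the one-species partition when the
  best split is not supported. On simulated single coalescent clusters
  this restores the correct answer essentially always, while true
  species structure passes the test by tens of log-units.
* **Search.** Up to 12 leaves the valid states are enumerated
  exhaustively; above that a greedy hill-climb (best single add/remove
  move to convergence) runs from the one-species and all-singleton
  states plus seeded random restarts. On hundreds of random trees of
  ≤ 12 leaves the heuristic matches exhaustive enumeration exactly,
  which the acceptance suite re-verifies.

`bptp_mcmc()` adds a Bayesian treatment: a Metropolis sampler over the
same state space (uniform prior, single-node flip proposals with a
Hastings correction for the differing numbers of legal moves). Defaults
are 500,000 generations with 10% burn-in; the run report carries the
acceptance rate and a non-mixing warning outside [1%, 99%]. It reports
the ML partition encountered, the posterior distribution of the species
count, and per-OTU posterior support (the fraction of post-burn-in
samples in which exactly that member set is a species). On a tree with
all edges equal — where all states have equal likelihood — the sampler's
visit frequencies are uniform within Monte-Carlo error, which the test
suite checks against the enumerated stationary distribution. The MCMC
reproduces bit-for-bit from its seed. A known property of this model
family, preserved here, is oversplitting when within-species structure
is deep — which is exactly why the pipeline treats the PTP partition as
the *fine* hypothesis to be reconciled rather than as the answer.

## Reconciliation

The integrative step mirrors how a taxonomist actually closes the gap
between two disagreeing delimiters:

1. **Congruence.** OTUs with identical member sets in both partitions
   pass through unchanged (`congruent`) — agreement of two methods with
   different error modes is treated as provisional support.
2. **Conflict blocks.** The remaining specimens fall into connected
   components of the union of the non-identical OTUs. Within each block
   the finer partition (typically PTP's) supplies candidate sub-OTUs and
   the guide tree supplies sister relationships.
3. **Sister-pair rule**, applied cherry-first and repeated until no
   merge applies:
   * strong morphological evidence, when supplied as per-pair overrides,
     wins outright (`distinct` keeps the split, `conspecific` merges);
   * *sympatric* pairs (region sets intersect) are kept split
     (`retained_sympatric`) — co-occurrence without interbreeding is the
     one observable test of reproductive isolation a single locus allows;
   * *allopatric* pairs below `t_strong` are merged
     (`merged_allopatric`, flagged `tentative`) — allopatric genetic
     clusters cannot be distinguished from geographic population
     structure at shallow divergence;
   * *allopatric* pairs at or above `t_strong` are kept
     (`strong_divergence_retained`);
   * pairs with unknown region status are kept but flagged `tentative` —
     absence of locality data never manufactures a merge.
4. **Flags and names.** OTUs containing several morphospecies labels, or
   sharing a label with another OTU, are flagged `name_incongruent`
   (both directions are also reported per label — mixed OTUs and
   polyphyletic labels are different curation problems). Names are
   assigned from a type-locality member's label when exactly one
   candidate label has one, else by majority label, else left
   `unassigned`.

Defaults: `t_low` = 0.03 — the 3% COI divergence guide widely applied to
species boundaries in sibling marine fishes; it is reported (the
partition at 3% is always computed) but does not by itself merge or
split. `t_strong` = 0.055 — in the lizardfish work that motivated this
package, allopatric sister OTUs were merged at divergences up to ~5.5%
while a transatlantic pair at 5.7% was retained, so 5.5% is the boundary
consistent with both practices; it is exposed in the configuration and
every merge it licenses is flagged tentative. Raising `t_strong` can only
merge more (the final count is monotonically non-increasing), a property
under test.

Every reconciled table is checked to partition the input specimen set;
violation is a hard error, not a warning. Specimen-level divergence
summaries report min/mean/max for every hypothesis pair, since published
divergence figures are variously minima, means or ranges and a single
statistic invites misreading.

Sister sub-OTUs are read off the guide tree (nodes whose descendants
span exactly two current groups, smallest first), not from all-vs-all
distances: the sympatry criterion is about sister lineages, and
evaluating arbitrary pairs would let distant groups merge through
chained comparisons. Non-monophyletic sub-OTUs are handled by this same
nearest-ancestor logic with a logged warning.

## The simulator

`simulate_barcodes()` generates data where the species truth is known:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 5 | species in the fauna |
| `n_per_species` | 6 | specimens sampled per species |
| `seq_length` | 615 | alignment columns (typical trimmed COI barcode) |
| `mu` | 0.075 | root-to-tip depth, substitutions/site |
| `pop_scale` | 0.02 | within-species coalescent depth as a fraction of `mu` |
| `kappa` | 4 | K80 transition/transversion rate ratio |
| `max_depth_ratio` | 0.1 | enforced ceiling on within/between depth ratio |
| `regions_per_species` | 1 | region codes drawn per species |
| `p_sympatric_sisters` | 1 | probability sister species share a region |
| `mislabel_rate` | 0 | fraction of specimens given a wrong label |

A Yule species tree is drawn and rescaled so the root-to-tip depth is
`mu`; with `mu` = 0.075 the between-species K2P divergences span roughly
1–15%, the range over which single-locus delimitation is actually
contested. Each tip is replaced by a coalescent subtree of depth
`pop_scale * mu` (0.15% by default — intraspecific COI variation of a few
tenths of a percent), capped at 90% of the species' stem so coalescence
always completes before the split: there is no incomplete lineage sorting
by construction, and the true partition is unambiguous. The species tree
is redrawn until every split depth is at least `pop_scale/max_depth_ratio`
of the root depth, so the within/between depth contrast holds for *every*
species pair, not just on average. Sequences evolve under K80 via its
closed-form transition probabilities — exactly the model the K2P
estimator inverts, so estimator consistency is a clean test rather than
an approximation — and the transition/transversion proportions are
verified in the tests against an independent matrix-exponential oracle.

`kappa` = 4 reflects typical fish COI transition bias. Mislabeling swaps
a specimen's label with that of a uniformly chosen other species,
emulating database misidentifications. One specimen per species carries
a type-locality flag.

`p_sympatric_sisters` defaults to 1: sister species are simulated
sympatric. This is a deliberate choice about what "recovery" can mean.
The reconciliation rule merges shallow allopatric sisters *by design* —
that is its scientific content — so in a fauna of allopatric sisters the
pipeline's output is not supposed to equal the simulated species truth.
Recovery statistics are therefore computed in the regime where the
sympatry criterion is informative, and the allopatric behavior is pinned
by dedicated scenario tests (merge at 1.52%, retain at 5.73%, retain any
sympatric pair) instead.

What the simulator does **not** emulate: indels and alignment error,
among-site rate variation, base-composition bias, selection,
introgression, incomplete lineage sorting, and uneven sampling. Passing
the recovery suite therefore shows the pipeline's logic is sound under
its own model assumptions — it does not certify performance on real
barcode compilations, where tree error and ILS are material.

## Validation problem sizes

The acceptance suite runs, entirely from code: 200 random sequence pairs
against an independent K2P closed form (equality to 1e-12); 50 random
additive matrices through NJ (path-length recovery to 1e-9); 100 random
trees of ≤ 12 leaves comparing greedy and exhaustive PTP searches; 180
nestedness checks of single-linkage partitions; 100 simulated 5-species
faunas (30 specimens × 615 bp each) through the complete pipeline,
requiring at least 90 exact species-count recoveries and mean adjusted
Rand ≥ 0.95; and the three anchored reconciliation scenarios. These sizes
were chosen to exercise every code path at desk scale while keeping the
whole suite under a minute.

## Known limitations

* Everything is single-locus: gene trees are not species trees, and no
  amount of reconciliation logic repairs that.
* The gap partitioner is a deterministic simplification of
  composite-score gap delimiters; it shares their principle (rank
  partitions by the barcode gap) but not their exact scores, and may
  rank differently in edge cases.
* PTP inherits the oversplitting bias of its model family on deep
  within-species structure; the LRT null guard handles the one-species
  case but not partial oversplits, which surface as `retained_sympatric`
  singletons for manual review.
* The sympatry predicate is only as good as the region coding; `UNKNOWN`
  regions block merging and flag the outcome tentative rather than
  guessing.
* Name assignment trusts the labels it is given; it flags incongruence
  but cannot identify specimens.
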