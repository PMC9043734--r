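---
title: "Methods: origin authentication and cophylogeography of caterpillar-fungus host moths"
author: "yartsa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin authentication and cophylogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yartsa)
```

## The problem

Caterpillar fungus — the mummified complex of a *Thitarodes* ghost-moth
larva and its parasite *Ophiocordyceps sinensis* — is traded at prices that
depend strongly on claimed geographic origin, yet traded material carries
no provenance. The host moth's genome does: host moths show roughly 5%
mean pairwise sequence divergence across the Qinghai–Tibet Plateau,
Hengduan Mountains, Himalaya and their transition zone, while the fungus
shows only ~1%, so the *host* is the carrier of the geographic signal.
`yartsa` implements the computational side of a two-step authentication
framework — build a multi-locus reference phylogeny of host moths, then
place unknown market samples onto it and read origin off the placement —
together with the population-level analyses that justify it: isolation by
distance (IBD), host–parasite cophylogeny, and discrete-range
biogeography.

Because the real data (94 market samples, 14 target-capture loci, 58
fungal ITS sequences) cannot be bundled here, the package includes a
first-class synthetic-data generator whose defaults encode the study
conditions; every analysis stage is exercised end to end on generated
data.

## The synthetic-data generator

`sim_config()` fixes the study conditions:

* **Host tree** — a birth–death tree conditioned on 90 surviving tips
  (`ape::rphylo`), pure-birth by default (λ = 1, μ = 0). Ninety tips
  matches the samples with complete locus recovery in the study.
* **Geography** — latitude and longitude evolve by Brownian motion from a
  root location in the central mountain arc (30°N, 96°E). The dispersal
  rate σ² = 10 deg²/time was chosen so that the realized sample cloud
  spans ~3000 km, matching the breadth of the real sampling arc, and so
  that all four regions receive samples in every run. Each tip's region is
  the nearest of four configured centroids by great-circle distance
  (a Voronoi assignment); the climate covariate is a linear function of
  latitude (intercept 25, slope −1 °C/degree, Gaussian noise σ = 1 °C),
  a deliberate confound with geography as in real mountain systems.
* **Sequences** — 14 loci of 600 bp evolve i.i.d. per site under JC69 (or
  HKY85) via `phangorn::simSeq`. The global rate scaler is calibrated by
  root-finding on the closed-form expected pairwise distance so the
  realized mean pairwise uncorrected distance is 0.05 ± 10%; a
  multiplicative correction is applied in the rare case the realized value
  falls outside the band.
* **Parasite** — the parasite tree starts as a copy of the host tree with
  branch lengths scaled by 0.2 (yielding ~1% divergence at the host's
  calibrated rate). Each host cladogenesis event triggers, with
  probability `p_switch` (default 0.1), a host switch implemented as a
  subtree-prune-regraft at fixed height: one daughter lineage is pruned at
  its origin time and regrafted onto a uniformly chosen contemporary
  lineage. The association remains the identity tip map, so it is total
  and one-to-one for every `p_switch`, and cophylogenetic signal degrades
  monotonically as `p_switch` grows.
* **Dropout** — each sample–locus pair is masked independently with
  probability 0.057, giving a mean of ~13.2 recovered loci out of 14; a
  floor of one locus per sample mirrors the study's retention of partial
  samples.

Everything is a pure function of `(config, seed)`; `simulate_dataset()`
derives per-stage seeds from the global seed via `stage_seed()` (a fixed
hash of the stage name), so any stage can be replayed in isolation.

**What the generator does not emulate.** Real market samples carry indels,
within-locus rate variation, contamination and species-level saturation of
genetic distances; the generator has none of these (i.i.d. sites, no Γ
heterogeneity, a single clock). Two consequences matter for
interpretation. First, placement is *easier* on generated data than on
degraded market DNA, so sensitivity curves here are upper bounds. Second,
under homogeneous Brownian dispersal the genetic–geographic relationship
is globally linear, so Mantel correlations *grow* with the geographic
radius of the cluster tested; the real study's pattern — IBD strongest
within 500 km and weak globally — requires deep clades whose genetic
distances are saturated while their ranges overlap spatially, a mechanism
deliberately outside this generator's scope. The radius sweep is still
implemented and tested; it simply should not be expected to reproduce that
localization on BM data, and the package's acceptance checks record this
honestly rather than tuning around it.

## Distances

All matrices share one container with labels and a `kind` tag.

* Genetic distances are uncorrected p-distances (optionally
  Jukes–Cantor-corrected) over the concatenation of selected loci, with
  *pairwise* deletion of sites containing `-`/`N` — column deletion would
  discard most sites in degraded samples. A pair with no comparable sites
  is an error, as is JC correction at p ≥ 0.75 (the caller should fall
  back to uncorrected distances rather than receive infinities).
* Geographic distances are great-circle (haversine, Earth radius
  6371.0088 km). At a 2000-km extent planar Euclidean distance on raw
  lat/lon is ill-defined; an equirectangular planar option exists behind a
  flag for comparison.
* Climatic distance is the absolute difference of the climate covariate.
* Landscape resistance is a least-cost-path distance on the 8-connected
  raster lattice (edge weight = mean endpoint cell cost × great-circle
  center distance, Dijkstra via `igraph`). This is a stand-in for
  circuit-theory resistance: no published raster or cost model exists for
  the study system, so any substrate is synthetic, and least-cost paths
  are exactly checkable against brute-force shortest-path oracles.

## Mantel tests and the two signal-localization sweeps

`mantel_test()` correlates the upper triangles of two labelled matrices
and builds its null by simultaneously permuting the rows and columns of
the second. The p estimator is (1 + k)/(1 + N) so p is never zero; the
default tail is one-sided ("greater") because IBD and codivergence are
directional predictions. For n ≤ 7 with enough requested permutations the
full n! set is enumerated and the exact p returned. Zero off-diagonal
variance is an error, not an `NA` — silent degenerate correlations are a
classic source of spurious sweep output.

The **radius sweep** asks where in space the signal lives: samples are
clustered by complete-linkage on geographic distance (complete linkage so
that a cut at height h bounds cluster *diameter* by h — the natural
reading of "samples within h km of each other"), the dendrogram is cut at
each radius from 100 to 2000 km in 100-km steps, and a Mantel test runs
inside every cluster with at least `min_cluster = 5` samples (≥ 10
distance pairs; below that the permutation distribution is too coarse).
Per radius the sweep reports mean/min/max r and mean p across clusters.
The same machinery serves the cophylogeny-by-radius question by
correlating host against parasite genetic distances within geographic
clusters (`cluster_on` argument).

The **time-slice sweep** asks how deep in the phylogeny the signal lives:
at age t the lineages crossing the slice partition the tips into clades;
each clade is represented by its *medoid* tip under the comparison matrix
(ties broken lexicographically), and the Mantel pair is the sliced
patristic matrix (path lengths truncated at t) against the comparison
submatrix on the medoids. Ages with fewer than four surviving lineages
are skipped and flagged. The medoid construction is one defensible
reading of summarizing a collapsed clade; a within-clade-mean aggregation
would be a reasonable alternative and the choice is recorded in results.

## Host–parasite congruence

`parafit_test()` embeds both distance matrices by principal coordinates
(double-centred Gower matrix; axes with eigenvalues above 1e-8 of the
maximum kept) and computes the global statistic trace(DᵀD) with
D = Cᵀ A B. Its null permutes, independently for each parasite, which
hosts it links to — the original row-wise null. Per-link statistics are
leave-one-link-out trace drops computed in closed form. For tiny
instances the full product-of-row-permutations null can be enumerated
(`exact = TRUE`), which the test suite compares against an independent
nested-loop oracle.

`paco_test()` uses Cailliez-corrected principal coordinates (the additive
constant from the 2n × 2n companion-matrix eigenproblem), replicates rows
per association link, and superimposes the parasite configuration on the
host configuration by least-squares Procrustes (translation, scaling,
rotation via SVD). Small m² means congruence, so the null counts
permuted-association m² values *below* the observed one. The two tests
keep their original papers' differing conventions for negative eigenvalues
(ParaFit drops axes, PACo corrects) deliberately — hybridizing them would
match neither reference implementation.

Either sequence distances or patristic distances may be supplied; the
result records which, since the study ran both sample-level and
species-level comparisons.

## Phylogenetic placement and origin assignment

`tree_loglik()` is Felsenstein pruning over compressed site patterns with
per-pattern log scalers, in C++, under JC69 or HKY85 (analytic transition
probabilities). `place_query()` attaches a query at the midpoint of every
edge of the reference tree in turn, with only the pendant branch length
optimized (golden-section search on [1e-8, 2] substitutions/site,
tolerance 1e-6). Per-edge likelihoods are computed from cached "down" and
"up" partial vectors, so the per-edge cost is independent of tree size;
the test suite verifies every edge against an oracle that rebuilds the
grafted tree from scratch. Midpoint-only attachment is a deliberate
simplification of EPA-style placement: it is lower-fidelity (it cannot
re-balance the split edge), but it is exactly testable, and its failure
mode — confusing adjacent edges inside sub-1% cherries — is visible and
quantified in the sensitivity experiment rather than hidden behind a
heuristic. Likelihood weight ratios (LWRs) are the per-edge likelihoods
normalized over edges; ties break toward the root, then by smallest
descendant tip label, so results are deterministic.

The reference tree for placement must carry branch lengths in expected
substitutions per site (an ML tree, or `tree_subs` from the generator).
Passing a time-calibrated tree is a unit mismatch that destroys placement.

`loci_sensitivity()` runs the leave-one-out protocol: prune a tip, re-place
it from a uniformly drawn subset of k loci, and score (a) the LWR mass on
the edges corresponding to the original attachment and (b) whether the
best edge falls there. When a tip is pruned its attachment edge
disappears and its two halves merge; the package defines the
correct-placement set as that merged parent–sibling edge plus the
sibling's two child edges when the sibling is internal — the immediate
neighbourhood that inherits correctness. This definition is the package's
own (the underlying notion of "confidence of correct placement" admits
several readings) and is stated here so results are interpretable.

`assign_origin()` implements the monophyly/sister rule: a query is
assigned a labelled origin if its best edge is nested strictly inside a
labelled clade, or is that clade's root edge (grafting there makes the
query the clade's sister); a best-edge LWR below `lwr_floor = 0.5` leaves
it unassigned. With a known truth label the outcome is classed as
true/false positive/negative, false positive meaning assignment to a
label that is not the truth — the error mode that matters for
authentication, where a non-Himalayan sample passed off as Himalayan is
the costly mistake.

## Discrete-range biogeography

`dec_loglik()` implements the dispersal–extinction–cladogenesis model on
the state space of non-empty region subsets of size ≤ K (default K = 2;
the study's four regions give 10 states). Along branches, a range gains
an unoccupied area at rate d × (current range size) — all region pairs
equal, since the four regions are pairwise adjacent along the mountain
arc — and loses a non-last area at rate e. At cladogenesis a single-area
range copies itself; a widespread range undergoes subset sympatry or
single-area vicariance, each ordered elementary event with weight 1; the
+J variant adds founder events (one daughter jumps to a single unoccupied
area) with weight j ∈ [0, 3]. Event probabilities are normalized per
ancestor state; the root prior is uniform over states (recorded in the
fit's metadata). Branch transition matrices come from one
eigendecomposition of the generator, with a scaling-and-squaring series
fallback for near-defective cases.

`fit_range_model()` maximizes by Nelder–Mead from five jittered starts,
with d and e log-transformed inside box bounds ([1e-6, 5] events per unit
branch length) and j logit-transformed. Two details matter in practice
and are worth stating. First, without upper bounds the DEC likelihood on
jump-dominated data drifts to degenerate huge-rate optima in which the
chain mixes to quasi-stationarity — biologically meaningless and
numerically delicate. Second, DEC+J is additionally started from the
fitted DEC optimum with j ≈ 0, so the nested model is never reported with
a likelihood below its special case because of a local optimum. AIC is
2k − 2lnL with k = 2 (DEC) or 3 (DEC+J).

One comparability caveat: because the root prior is uniform over states,
likelihoods at different K are penalized differently (−log of the state
count), so raw lnL values should not be compared across K — only within a
K, across models. This mirrors the behaviour of standard DEC software.

`mk_stochastic_maps()` is the sample-level analogue of the study's
regional-transition map: a single-rate (equal-rates) Mk model over the
four regions is fitted by ML, node states are sampled from the pruning
partials (root from the uniform prior times its partials), and branch
histories are sampled by uniformization conditioned on endpoint states.
With the uniformization rate chosen as kq the auxiliary jump chain is
uniform over states, so conditioned jump counts and intermediate states
have closed sampling forms. The default 3000 maps matches the study's
map count; the summary is the mean directional transition-count matrix.
A quadrature oracle for the conditional expected number of changes on a
single branch (`mk_expected_changes`) validates the sampler.

## Numerical choices and degenerate inputs

* Partial likelihoods carry per-pattern log scalers (rescaled below
  1e-100) so 90-taxon trees do not underflow.
* Golden-section pendant optimization: interval [1e-8, 2], tolerance 1e-6.
* PCoA axes kept above 1e-8 × max eigenvalue; Cailliez constant from the
  companion-matrix eigenproblem.
* The Mantel estimator (1 + k)/(1 + N) never returns 0; exact enumeration
  returns k/n! including the identity, so exact p ≥ 1/n!.
* All-missing queries yield exactly uniform LWRs (every edge equally
  uninformative), and the root-nearest tie-break makes the reported best
  edge deterministic.
* Readers are total over their error domain: ragged alignments, invalid
  characters (read through `Biostrings` so nothing is silently coerced),
  out-of-range coordinates, unknown regions, non-ultrametric trees where
  ultrametry is required — each raises a typed error naming the offender.

## Problem sizes used in the checks

The shipped test suite runs the full pipeline at the study's structural
scale — 90 samples, 14 × 600 bp loci — for the isolation-by-distance
recovery (50 seeds) and the loci-count sensitivity experiment (k = 1..14,
100 replicates per k), and uses reduced but statistically adequate sizes
elsewhere (e.g. 12-tip trees with 199-permutation tests for cophylogeny
power curves, 30-tip trees for 20 range-model selection replicates,
3000-draw checks of the stochastic-mapping sampler). These sizes are the
package's choices for routine verification; all of them can be raised
through the exported functions.

## Known limitations

* Placement fixes reference branch lengths and model parameters; no
  re-estimation, no Γ rate heterogeneity, no heuristic edge preselection.
* The DEC implementation supports equal pairwise dispersal only (an
  optional multiplier matrix is accepted in the generator but not
  time-stratified models); BAYAREALIKE/DIVALIKE variants are out of scope.
* Stochastic mapping is the single-region Mk chain, not DEC-history
  counting.
* The generator's Brownian geography cannot reproduce locally-confined
  IBD (see above); conclusions about the *width* sweep on real data
  should rest on the real data.
* Partial Mantel tests, correlograms and circuit-theory resistance are
  intentionally absent.
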