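---
title: "Inferring a core stress microbiome from compositional OTU data"
author: "coreshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a core stress microbiome from compositional OTU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreshift)
```

## The scientific question

When a plant is stressed — by heavy-metal toxicity, water limitation, or
light limitation — its root-associated bacterial community shifts. The
interesting question is not whether each stress perturbs the microbiome
(each does, in its own way) but whether a *common* signature exists: a set
of OTUs whose abundance moves in the same direction under every stress,
presumably responding to the stressed state of the host rather than to the
specific environmental insult. `coreshift` implements the statistical
machinery for detecting such a "core stress microbiome" from 16S OTU count
tables in a design with one control and several stress treatments, a handful
of replicate plants per treatment, and optional paired metabolite or
gene-expression measurements.

Every stage is driven by a synthetic-data generator with a ground-truth
record, so the whole pipeline is testable end to end without sequencing
data.

## The data model

The generator (`sim_config()`, `simulate_dataset()`) produces data with the
statistical structure the analysis assumes:

* **Latent basis abundances.** Each OTU has a mean log abundance drawn from
  `N(0, basis_log_mean_sd^2)` (default sd 1.5 on the natural-log scale,
  giving the uneven, long-tailed communities real surveys show), with
  per-sample log-normal fluctuation `basis_log_sd` (default 0.5).
* **Planted effects.** Core OTUs are shifted by `2^(+/- effect_log2)` on
  the basis scale in *all* stress treatments with a consistent sign
  (defaults: 5 up, 5 down, `effect_log2 = 1.5`); treatment-specific OTUs
  (3 per stress) shift in exactly one. Effects are applied to the latent
  means *before* closure, so the planted fold changes live on latent
  abundances; the compositional distortion this induces in all other OTUs
  is deliberate — it is exactly the artifact real relative-abundance data
  carry, and the tests quantify its cost (see the FDR discussion below).
* **Planted correlations.** Chosen OTU pairs receive a basis correlation
  (`corr_strength`, default 0.7) through a block-structured covariance;
  this is what the network estimator must recover through the closure.
* **Sampling.** Per-sample library sizes are drawn uniformly between
  19,000 and 60,000 reads and counts are multinomial given the closed
  composition — so column totals are exact, depth is heterogeneous, and
  rarefaction is always exercised. The default design is 8 plants per
  treatment x 4 treatments (control, copper, drought, shade) x 50 OTUs.

One root seed drives named substreams (per sample, per OTU, per iteration),
so any piece of a simulation can be reproduced in isolation and everything
is bit-reproducible.

What the generator does **not** emulate: read-level errors, chimeras and
contaminants, phylogenetic autocorrelation of effects, overdispersion beyond
the log-normal-multinomial hierarchy, and compartment differences (all
samples are labelled `root` by default). A passing test suite therefore
says the *statistics* behave as claimed under the assumed model, not that
the model captures every feature of a real survey.

## Diversity and community structure

* `rarefy()` subsamples each column without replacement to a common depth
  (default 19,000 reads, the floor of the simulated depth range), dropping
  shallower samples. Rarefaction before everything else mirrors standard
  amplicon practice and makes relative abundances comparable.
* `shannon_index()` computes `H = -sum(p_i ln p_i)` after discarding OTUs
  at or below a relative-abundance floor (`min_frac = 1e-4`, i.e. > 0.01%
  kept, then renormalized) — the floor suppresses noise from taxa observed
  a handful of times.
* `weighted_unifrac()` accumulates, per tree branch, each sample's read
  fraction descending through the branch; the raw distance is
  `sum_b len_b |p_A(b) - p_B(b)|`. The *raw* (unnormalized) variant is the
  default — the historical default of amplicon pipelines; `normalized =
  TRUE` divides by `sum_b len_b (p_A + p_B)`. The implementation is a
  single postorder accumulation; tests compare it to an exhaustive
  per-branch oracle (tolerance 1e-10) and to an independent implementation.
* `pcoa()` is classical scaling (via `stats::cmdscale`); axes with negative
  eigenvalues are counted and excluded.
* `permanova()` partitions the total squared distance into between/within
  components and permutes labels; `within_between_test()` compares
  within-group distances against between-group distances with a Student t
  statistic under sample-assignment permutation, giving the two asymmetric
  values per treatment pair that a pairwise comparison table reports.

Permutation p-values use the add-one convention `(1 + #extreme)/(1 + n)`,
so they are never exactly zero. Two consequences worth knowing: the
smallest achievable p is `1/(n_perm + 1)`, and permutations that recreate
the observed grouping (or its mirror image, for two-group designs) tie with
the observed statistic. With groups of four, ties alone put the floor near
0.03 — which is why power checks in the tests use larger groups. Note that
weighted UniFrac is abundance-weighted: when one unshifted OTU dominates
the community, treatment effects carried by low-abundance OTUs move the
distance matrix very little, and PERMANOVA power drops accordingly. That is
a property of the metric, not of the test.

## Calling core stress OTUs

Per stress treatment, `differential_otus()` runs an equal-variance Student
t-test on relative abundances against the control group, applies
Benjamini-Hochberg across OTUs *within the treatment*, and calls an OTU
significant when raw `p < 0.05` **and** BH `q <= 0.10`. The dual rule is
the conjunction of the two printed thresholds; it is deliberately the
stricter reading. `core_consistency()` then tallies, per OTU, in how many
stress treatments it was called and whether all calls share a sign;
`responsive_summary()` aggregates abundance by sharedness class (3/3, 2/3,
1/3) per treatment; `cluster_response_profiles()` groups log2 response
profiles by average-linkage clustering, cutting the dendrogram at the
widest gap between merge heights subject to a minimum cluster size — a
deliberately simple, deterministic stand-in for dynamic tree cutting, which
is under-specified for reimplementation.

Two measurement subtleties, both visible in the acceptance checks:

* *Sensitivity* is defined as recovery of planted core OTUs into the
  stress-responsive set (significant in >= 1 treatment); with three
  treatments each core OTU has three chances, so this exceeds per-treatment
  power (0.93 vs roughly 0.8 at the default effect size).
* *Realized false discovery* is measured per treatment, where BH is
  applied. It runs near 0.13–0.15 — above the nominal 0.10 because planted
  basis effects shift every null OTU's *relative* abundance through the
  closure (mass conservation), a bias intrinsic to compositional
  differential abundance at this design size. The union of calls across
  three treatments accumulates errors further (~0.17); that union is not a
  quantity BH controls, and the package reports it only through the
  consistency tallies.

## The treatment classifier

`prevalence_filter()` keeps OTUs present (nonzero) in at least 80% of
samples — boundary inclusive — and emits relative-abundance features.
`gnb_fit()`/`predict()` implement Gaussian naive Bayes with empirical class
priors and a variance floor of `1e-9 x` the largest feature variance;
posteriors are computed in log space and ties break deterministically by
class-name order. `loo_evaluate()` refits the model n times, leaving each
sample out, and reports the full confusion matrix plus a collapsed
stress-vs-control view (all stress labels mapped to one class) — the
operationally interesting question being whether a stressed plant is
recognizable as stressed at all. Features are relative abundances
post-rarefaction, matching the rest of the pipeline. Under label shuffling,
leave-one-out accuracy sits slightly *below* 1/k (the left-out sample's own
class is underrepresented in training), a well-known pessimism of LOO that
the calibration test accommodates by judging chance-level against the
binomial spread of one evaluation.

## Compositionality-aware correlation networks

Pearson correlations between relative abundances are confounded by the
closure, so inter-OTU association is estimated on the *basis* scale
(`sparcc_correlations()`): log-ratio variances `t_ij = Var(log f_i/f_j)`
are closure-invariant, and under a sparsity assumption the basis variances
`omega` solve the linear system with `D - 1` on the diagonal and 1
elsewhere, giving `rho_ij = (omega_i + omega_j - t_ij) /
(2 sqrt(omega_i omega_j))`. Strong pairs violate sparsity, so the single
strongest pair above `|rho| = 0.1` is iteratively excluded — its `t_ij`
leaves both row sums and its two off-diagonal coefficients leave the system
(dropping only the diagonals leaves phantom variance mass and measurably
inflates null correlations) — and the system is re-solved, up to 10 times.
Fraction uncertainty is integrated by averaging the estimate over 20
Dirichlet (add-one) posterior draws of the per-sample compositions;
`deterministic = TRUE` uses the posterior mean in a single pass, which is
convenient for exact-reproducibility tests.

Numerical choices: estimates are clipped to `[-1, 1]` with clip events
counted (silent clipping hides degenerate solves); OTUs whose solved basis
variance is nonpositive get undefined correlations with a warning rather
than a fabricated value; computation happens in canonical OTU-id order with
substreams keyed by OTU id, so the estimate is exactly invariant to input
row order.

`sparcc_pvalues()` builds the null by permuting each OTU's counts across
samples independently (marginals preserved, association destroyed), reruns
the full estimator on each of 100 resampled datasets, and reports add-one
two-sided pseudo-p-values with floor `1/(n_boot + 1)`. `select_edges()`
keeps pairs with `p < 0.1`, ranks by the signed coefficient by default
(absolute ranking behind a flag) and truncates to the top 10,000.
`degree_rank_stability()` reports edge counts and pairwise Spearman
agreement of node-degree rankings across a ladder of cutoffs — the
diagnostic justifying an edge-count cutoff choice.

## Hub subnetworks and the merged core

Per treatment, `hub_subnetwork()` takes the 20 most-connected nodes (ties
at the boundary are all kept — deterministic, logged) plus their immediate
neighbors, as a vertex-induced subgraph. `merge_subnetworks()` forms the
node union and partitions OTUs by the set of treatments whose subnetwork
contains them: treatment-specific classes, k-shared classes, and the
all-treatment core — the "central subnetwork" of OTUs correlated with
others under every condition. Membership is node-level presence (the
set-overlap reading of a merged-network figure); per-treatment edge weights
are kept separate because the treatments are separate estimations.
`taxonomy_composition()` summarizes a node set at phylum level, optionally
splitting Proteobacteria into classes.

## Linking OTUs to metabolites and transcripts

`pearson_link_table()` tests all feature pairs across two matrices on their
shared samples (product-moment r, two-sided p from the t transform with
n - 2 df) and keeps `p < 0.05` — deliberately without multiple-testing
correction, matching the exploratory convention for such screens; a BH
option exists but is off by default. `rank_by_link_count()` orders features
by number of distinct partners. `signed_log2_fc()` expresses a ratio of
positive means as a magnitude-plus-sign log2 fold change.
`simulate_linked_omics()` plants features as linear functions of an OTU's
clr abundance plus Gaussian noise so link recovery and the null retention
rate are both testable.

## Problem sizes in the tests

The suite and the acceptance script regenerate everything from code at
fixed problem sizes chosen to estimate each property stably: 50 random
trees of <= 8 tips for the UniFrac oracle; 1,000 random vectors for the BH
oracle; D = 40, n = 200 for SparCC recovery and D = 20, n = 150 for its
bootstrap calibration (100 resamples; 20 seeds for the floor-rate check);
50 simulated studies for the caller's operating characteristics; 200 null
replicates at 199 permutations for test calibration; and three full
pipeline replicates at the default 50 x 32 design. The complete run takes
a few minutes on one core.

## Known limitations

* The differential caller tests relative abundances directly; it does not
  attempt compositional bias correction (no ALDEx2/ANCOM-style modelling),
  so its realized FDR is honest only under modest effect mass (documented
  above).
* The SparCC sparsity approximation degrades for very small panels
  (< about 10 OTUs) and for communities with many strong correlations;
  nonpositive solved variances are surfaced, not hidden.
* With n = 8 samples per treatment, per-treatment networks are
  structurally noisy; the merged-core machinery is exercised and tested on
  toys and synthetic data, but biological interpretation at that n rests
  on the cross-treatment overlap, not on any single network.
* The cluster-cut rule is a simplification of dynamic tree cutting; it is
  deterministic and tested for block recovery, identical-row collapse and
  row-order invariance, but it is not the hybrid algorithm.
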