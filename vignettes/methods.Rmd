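---
title: "Methods: group analysis of control-related functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group analysis of control-related functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlnet)
```

## Scope and model

`ctrlnet` implements a complete group-level graph analysis of resting-state
functional connectivity among 34 regions spanning four control-related
systems — the frontoparietal (FPN), cingulo-opercular (CON), cerebellar (CN)
and default-mode (DMN) networks. The pipeline takes per-subject regional
BOLD time series (T × 34) plus a phenotype table and produces:

1. rectified Pearson correlation matrices (negative correlations set to 0);
2. binary graphs under two complementary thresholding strategies
   (fixed correlation threshold; fixed sparsity), with automatic selection
   of the operating thresholds;
3. global topology (global efficiency $E_{glob}$, local efficiency
   $E_{loc}$, modularity $Q_{max}$, module count) normalized against
   degree-preserving rewired null graphs, and nodal degree, efficiency and
   betweenness;
4. an edge-level network-based statistic (NBS): covariate-controlled
   two-sample comparison with family-wise error control over connected
   components by group-label permutation;
5. an anatomical-distance characterization of any significant component —
   long-range (> 75 mm) and inter-network proportions, a component-vs-rest
   two-sample t-test on edge distances, and a resampling null over random
   connected edge sets matched on edge and node counts;
6. covariate-controlled permutation tests for all topological measures
   (BH-FDR across nodes for nodal measures), rank partial correlations of
   component connectivity strength with clinical scores, and an in-sample
   ROC analysis of that strength as a diagnostic feature.

Because no raw imaging data ship with the package, a first-class synthetic
cohort generator stands in for the study sample; every downstream stage is
developed and tested against it.

## Definitions and conventions

With $a_{ij} \in \{0,1\}$ the adjacency and $d_{ij}$ the BFS hop distance,

$$E_{glob}(G) = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}}, \qquad
  E_{loc}(G) = \frac{1}{N}\sum_i E_{glob}(G_i),$$

where $G_i$ is the subgraph induced by the neighbours of $i$; disconnected
pairs contribute $1/\infty = 0$ and nodes with fewer than two neighbours
contribute 0 to $E_{loc}$. Modularity of a partition $p$ is
$Q(p) = \sum_s [\, l_s/L - (d_s/2L)^2 \,]$ with $l_s$ the intra-module edge
count, $d_s$ the module degree sum and $L$ the total edge count. Nodal
measures are degree $k_i = \sum_j a_{ij}$, nodal efficiency
$e_i = \frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$, and betweenness
$b_i = \sum_{m<n,\; m,n\ne i} \sigma_{mn}(i)/\sigma_{mn}$ over unordered
pairs (the Freeman convention).

Module detection is Newman's leading-eigenvector bisection on the
(generalized) modularity matrix with Kernighan–Lin fine-tuning after each
candidate split, recursing while the split increases $Q$. The algorithm is
deterministic: eigenvector sign ties (zero loadings) go to the first
module, and the `seed` argument exists only for interface symmetry.
Disconnected graphs are handled on the full modularity matrix rather than
per component, so the degree-null term always refers to the whole graph.

Thresholding conventions: correlation thresholding keeps edges with weight
strictly greater than $r_0$; sparsity thresholding keeps exactly
`round(s * N(N-1)/2)` strongest edges, breaking ties at the cutoff weight
in favour of the lexicographically smaller node pair so the edge sets are
nested across $s$ and reproducible. Automatic selection walks a 0.01 grid
(matching the resolution at which such thresholds are conventionally
reported) and requires, for *every* subject, mean degree above
$2\ln N$ (the natural-log small-world convention; $\approx 7.05$ at
$N = 34$) and no isolated nodes; it returns the largest admissible
correlation threshold and the smallest admissible sparsity.

## The NBS implementation

Edge weights (rectified correlations) enter the analysis when positive in
at least 50% of all subjects, both groups pooled. All masked edge weights
are residualized by pooled OLS on the nuisance covariates (age, gender, IQ
and three head-motion summaries, plus an intercept) before any group
comparison — a Freedman–Lane-style approximation, since the mechanism of
covariate control is a free design choice. Pooled-variance two-sample t
statistics are computed per edge, signed controls-minus-patients so that
positive values mean hypoconnectivity in patients.

The primary threshold is interpreted as a *two-tailed* edge p value below
`primary_p` **in the tested direction** (default: controls > patients),
i.e. $t > t_{1-\alpha/2}$. Two considerations drove this default over the
one-tailed alternative (which remains available via
`nbs_config(edge_p = "one_sided")`). First, the edge statistic is a
standard two-sample t-test, whose p values are conventionally two-tailed,
and component-based inference in this literature tests one contrast at a
time at a fixed t threshold. Second, and substantively: at $N = 34$ a
one-sided 5% edge rate yields about 28 supra-threshold edges — mean degree
1.65, *above* the percolation threshold of a random graph — so null
maximal components become giant and component inference loses all
resolution; the $t_{0.975}$ rule keeps the null supra-threshold graph
subcritical.

For each of `n_perm` permutations (default 10,000) subjects are reassigned
to two groups of the original sizes, the same masked, residualized weights
are re-tested, and the maximal supra-threshold component size in *edges*
is recorded. A component of size $M$ receives the corrected p value
$\#\{\text{null maxima} > M\}/n_{perm}$ — strictly larger, ties not
counted, exactly as the decision rule is usually stated. This means a
corrected p of exactly 0 is possible; the scalar permutation tests below
use the add-one convention instead, and the package documents both. When
the group sizes admit fewer distinct label arrangements than `n_perm`,
the permutations are enumerated exhaustively.

## Anatomical distance analysis

Distances are straight-line Euclidean distances between the atlas's sphere
centres, in millimetres; a connection is long-range when its distance
strictly exceeds 75 mm. The resampling null draws random *connected* edge
sets from the complete 561-pair universe with the same edge count and node
count as the observed component: a uniformly chosen starting edge is grown
by uniformly random incident edges, and the draw is rejected unless the
final node count matches. The growth sampler is not exactly uniform over
all connected (m, n)-subgraphs — no simple sampler is — so an exhaustive
enumeration mode exists for tiny universes to audit the bias; the
empirical p (proportion of null mean distances strictly larger than the
observed mean) is insensitive to this at the effect sizes involved. The
full universe (561 pairs) rather than the NBS prevalence mask defines the
null, consistent with a 30-versus-531 component/complement split;
with synthetic cohorts the mask retains essentially all pairs, so the
distinction is immaterial there.

## The synthetic cohort generator

The generator emulates *post-preprocessed* regional time series: band-pass
smoothness is approximated by an AR(1) temporal kernel
(`temporal_ar = 0.3`) applied per latent series before spatial mixing, and
nuisance regression (including global-signal removal) is emulated by the
*structure* of the covariance model rather than by explicit filtering.
Concretely, each group has a block target: correlation 0.45 within a
network, 0.15 between networks, unit diagonal. The patient group's target
is additionally reduced by `effect_delta = 0.25` on a planted component —
by default a deterministic connected set of 30 long-range inter-network
pairs spanning 26 nodes, chosen greedily by decreasing distance. Planted
correlations are floored at zero: hypoconnectivity is modelled as loss of
positive coupling, not induced anticorrelation, which keeps the analysis
regime (rectified positive weights, prevalence masking) coherent;
inter-network planted edges therefore drop from 0.15 to 0 (an effective
reduction of 0.15), and a within-network planted edge would drop by the
full 0.25.

Between-subject variability is essential — with identical true covariance
for every subject, per-edge group effects at T = 230 would reach t ≈ 10–15,
a regime no real cohort occupies. Each subject's target is produced by
adding independent N(0, `subject_sd`²) noise (default 0.10) to the group
target's canonical partial-correlation (C-vine) parametrization and mapping
back. This construction is positive definite by construction, induces
edge-level deviations that are approximately independent across edges
(cross-edge deviation correlations around 0.05) — the signature of
nuisance-regressed connectivity, where shared global fluctuations have been
removed — and places planted edge-level effects at t ≈ 4–5, the upper range
of published component edge statistics. Wishart-style alternatives
(subject targets as finite-sample correlations of the group target)
were rejected because their deviations concentrate on the target's common
mode, re-creating exactly the shared fluctuations that global-signal
regression removes and inflating the null component-size distribution.

Time series are then drawn as $Z U$ where $Z$ has i.i.d. AR(1) columns of
unit marginal variance and $U$ is the Cholesky factor of the subject
target, so the cross-sectional correlation of the process equals the
target exactly in expectation.

Covariates (age, gender, IQ, three motion summaries) are drawn from
*common* distributions for both groups — the generator plants no covariate
confound, so covariate control is exercised against null covariates and
any residual group difference in them is sampling noise. Clinical scores
(hyperactivity index and impulsivity, 0–3 scale) are higher in patients by
construction and, within patients, correlate positively
(`clinical_rho = 0.4`) with the subject's realized mean planted-edge
correlation, reproducing the counterintuitive positive brain–symptom
association that motivates the rank-partial-correlation stage.

What the generator does *not* emulate: head-motion spikes and their
correlation with connectivity, scanner/site effects, non-Gaussian BOLD
features, spatial autocorrelation of noise within networks beyond the
block structure, and any geometry-dependent connectivity decay with
distance. Passing tests therefore demonstrate that the *statistical
machinery* behaves correctly under the stated model, not that real ADHD
cohorts would yield these effect sizes.

## Numerical choices and degenerate inputs

* Positive-definiteness repairs use eigenvalue clipping at $10^{-6}$ with
  re-symmetrization and rescaling to unit diagonal; the vine construction
  makes this a safety net rather than a routine step.
* Constant time series, empty masks, edgeless graphs, rank-deficient
  covariate designs and infeasible (m, n) sampler requests all raise
  errors naming the offending object rather than propagating NaNs.
* Zero pooled variance in an edge test yields t = 0 with a warning.
* Degenerate ROC inputs (one class absent) error; Youden ties take the
  smallest cutoff; patients are classified positive *below* the cutoff,
  following the hypoconnectivity direction of the planted effect.
* The permutation critical value reported alongside each metric test is
  the 95th percentile of the signed null, matching a one-tailed 5% rule.

## Problem sizes used by the test suite

The packaged test suite runs the full design at sizes chosen to make each
check statistically informative while completing comfortably on one CPU:
oracle equivalence uses 200 random graphs with up to 12 nodes (exhaustive
modularity enumeration up to 10); family-wise error calibration uses 500
null cohorts of 20 + 20 subjects with 1,000 permutations each; power and
distance-signature recovery use 20 replicate cohorts at the full design
(46 + 31 subjects, 230 volumes) with 1,000 permutations and 1,000
resampling draws; the acceptance script uses 2,000 permutations and 2,000
draws, and 50 rewired nulls per subject for metric normalization. The
10,000-permutation defaults remain the package's production settings.

## Known limitations

* The in-sample ROC is optimistic by construction (the component is
  selected on the same data it classifies); cross-validated classification
  is deliberately out of scope.
* The growth sampler's non-uniformity over connected subgraphs is
  documented but not corrected.
* Printed atlas-derived distances in published component tables may differ
  from sphere-centre geometry by ~1 mm (voxel-grid centroids); fixture
  tables are treated as authoritative for their own columns.
* Modularity of very sparse thresholded graphs can be dominated by
  disconnected fragments; the package reports module counts as found and
  leaves interpretation to the analyst.
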