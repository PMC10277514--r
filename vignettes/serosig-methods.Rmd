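---
title: "serosig: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serosig: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serosig)
```

# The problem

Serum multiplex protein panels (proximity extension assays, reporting NPX —
a relative, log2-like abundance unit) are used to ask whether inflammatory
liver disease leaves a signature in the circulating proteome that (i)
distinguishes steatohepatitis (NASH) from simple steatosis (NAFL)
independently of comorbidities, (ii) supports a practical multi-marker
diagnostic rule, and (iii) reveals disease-specific rewiring of protein
co-expression and patient subgroups. `serosig` packages that full analysis
path, with every stochastic or numerically delicate step validated against
independent oracles and a ground-truth simulator.

# Statistical machinery

## Rank tests and ties

All group comparisons of protein levels use the two-sided Mann–Whitney U
test. Ties — which are guaranteed at the LOD floor (see below) — are
handled with mid-ranks everywhere (Mann–Whitney and Spearman alike); this
convention is stated explicitly because published methods sections rarely
do. The exact mode enumerates the permutation distribution of U over all
$\binom{n+m}{n}$ assignments of the observed mid-ranks; since complementary
assignments map $U \mapsto nm-U$, that distribution is symmetric about
$nm/2$ even under ties and the two-sided p-value is
$P(|U - nm/2| \ge |u_{obs} - nm/2|)$. The asymptotic mode uses the
tie-corrected normal approximation with a 0.5 continuity correction, which
has the desirable exact property that $U = nm/2$ gives $p = 1$ (so
duplicated groups are never "significant"). `auto` uses the exact mode for
$n+m \le 20$ without ties.

## Two-stage FDR

Multiplicity control is the two-stage Benjamini–Krieger–Yekutieli sharpened
linear step-up at $Q = 5\%$: stage 1 is the linear step-up at
$q' = q/(1+q)$; its rejection count $r_1$ estimates the number of true
nulls as $m_0 = m - r_1$; stage 2 reruns the step-up at $q' \cdot m/m_0$
(rejecting nothing if $r_1 = 0$, everything if $r_1 = m$). Plain BH and the
dependency-robust BY variant are available behind `method=` because
figure-level legends and methods text in this literature often name the
procedures inconsistently; the two-stage procedure is the package-wide
default. One subtlety the test suite documents: the two-stage procedure
dominates plain BH only in the $0 < r_1 < m$ regime — when $r_1 = 0$ it can
reject strictly less (stage 1 runs at the deflated level $q'$).

The family is always one volcano: all proteins of one comparison are
corrected jointly, and each stratified re-test is its own family.

## McNemar comparisons

Paired diagnostic rules are compared through their discordant counts $b$
and $c$. The exact test (package default) is the two-sided binomial test of
$b$ against $\mathrm{Bin}(b+c, 1/2)$. The asymptotic mode uses the
continuity-corrected $(|b-c|-1)^2/(b+c)$ statistic: without the correction
the chi-square p deviates from the exact binomial p by up to ~0.1 at
$b+c \approx 25$, which would defeat the purpose of offering an asymptotic
fallback.

## Ward clustering

All hierarchical clustering is Ward's minimum-variance method on Euclidean
distances, implemented via the Lance–Williams recurrence on
$D(A,B) = 2\,\frac{|A||B|}{|A|+|B|}\,\lVert \mu_A - \mu_B \rVert^2$.
Reported merge heights are $D/2$, i.e. exactly the increase in
within-cluster sum of squares, so the tree can be (and in the tests, is)
checked against direct evaluation of the Ward objective. Merge-cost ties
break deterministically to the pair of clusters with the lexicographically
smallest (smallest-original-member) ids, making the tree a pure function of
its input — important because residual matrices and marker panels routinely
produce exact ties. Flat clusters come from `cut_tree()` by count or
height; where no cut is specified (residual clustering), k defaults to the
largest relative gap between consecutive merge heights, scanned over
$k \le 10$ — a stated heuristic, overridable, chosen because published
cluster counts in this setting come with no cut rule.

# The data model

`npx_matrix` couples the samples × proteins value matrix with a same-shaped
below-LOD mask. Two conventions are deliberate:

* **Censoring is a floor, not missingness.** Below-LOD values are stored at
  the per-protein LOD. Rank tests then see a block of ties at the bottom of
  the ranking, which is the honest information content of "below
  detection". The alternative (dropping censored values) biases group
  comparisons whenever censoring rates differ between groups.
* **The detection filter is strict.** A protein is excluded when its
  below-LOD fraction strictly exceeds 10% ("more than 10%"); exactly 10% is
  retained. The filter is idempotent and never drops samples.

Sample metadata carries the closed group set (HC/NAFL/NASH), Kleiner
fibrosis stage F0–F4, the NAFLD activity score (NAS 0–8) with its three
subscores (validated to sum to NAS), comorbidities and demographics. NASH
is operationally NAS ≥ 5.

# The synthetic cohort generator

`simulate_cohort()` states a world with the structure the analysis assumes.
Cohort design mirrors the reference study: 15 healthy controls, 35 NAFL, 35
NASH; a 92-protein panel of which 25 are never detected and 4 are censored
in 20% of samples, so the detection filter retains exactly 63; 13 proteins
shifted in NASH only (11 down, 2 up); one five-protein correlation block
(ρ = 0.6) present only in NASH; hypertension prevalence 29/70 and T2D 25/70
among patients, controls screened healthy (BMI < 25, no T2D, NAS 0);
fibrosis skewed so a F0–1 vs F2–4 split lands near 35/35 over patients.

Choices the references do not state, fixed here once and documented:

* **Marginal family and noise.** Group-wise multivariate normal on the NPX
  scale with per-protein SD 1 and block-exchangeable correlation. Every
  downstream test is rank-based, so the marginal family is a convenience;
  what matters is the copula, and for a Gaussian copula the population
  Spearman of a block with Pearson ρ is $\frac{6}{\pi}\arcsin(\rho/2)$
  (0.582 for ρ = 0.6) — the value the recovery tests check against.
* **Planted effect size.** 1.5 NPX (≈ 2.8-fold), a strong but realistic
  cytokine effect; at 35 + 35 samples it gives essentially complete power
  for all 13 effects jointly after BKY correction. This number is a package
  choice, not a reported value.
* **Censoring mechanics.** For a configured fraction f, the
  `round(f·n)` smallest values of that protein are floored at the realized
  LOD (the largest censored value) and flagged, so realized censoring is
  within one sample of f by construction.
* **Covariates** are drawn independently of protein values by default —
  planting *no* confounding — so stratified re-tests are calibrated null
  experiments. A confounded mode (`confounders=`) adds a stated shift to
  named proteins in covariate-positive samples to verify that the
  stratified analysis, and only it, finds them.
* **PSD guard.** Each correlation block and each assembled group matrix is
  eigenvalue-checked; a non-PSD block is rejected by index and group (e.g.
  exchangeable ρ < −1/(b−1)).

`simulate_subgrouped_transcriptome()` is the test bed for subgroup
discovery: subgroup centers in marker space are distinct binary codes
scaled by `marker_sep` (default 6 SD). The generator's contract is that
subgroups *separate* in marker space; 6 SD is the smallest round value at
which that holds operationally (per-sample assignment ambiguity
~Φ(−3) ≈ 0.1%) — at 3–4 SD roughly 7% of samples are ambiguous and
hierarchical clustering demonstrably cannot deliver agreement ≥ 0.9, which
would contradict the stated contract rather than test it. Each subgroup
additionally carries `deg_per_pair/2` dedicated non-marker genes shifted by
2 SD, so every subgroup pair differs in exactly `deg_per_pair` non-marker
genes (the geometry of pairwise differences makes "exactly d genes per
pair with disjoint per-pair sets" impossible for ≥ 3 subgroups; dedicating
d/2 genes per subgroup is the construction that achieves exact per-pair
counts, and requires `deg_per_pair` to be even).

## What a green test does and does not establish

The generator emulates group structure, effect geometry, censoring and
prevalences — not assay chemistry. It has no plate effects, no inter-plate
bridging, no batch structure, no heavy-tailed or skewed marginals, no
missing metadata, and covariates are independent of proteins unless
explicitly confounded. Recovery tests therefore establish that the
*machinery* is correct and calibrated on data with the stated structure;
they say nothing about how a particular real cohort behaves.

# Panel classification choices

* Operating points are **resubstitution** (derivation-set) estimates, as is
  standard when no held-out cohort exists; this overstates real-world
  performance and is flagged as such.
* "Positive" for a marker *lower* in cases means *below* threshold; the
  direction comes from the differential table's effect sign (or the median
  difference if no table is supplied).
* `threshold_at_specificity()` picks the smallest achieved specificity
  ≥ target, breaking ties toward higher sensitivity — so the achieved
  specificity always meets the target, at the cost of a sensitivity that
  can be conservative on small control groups.
* Subset selection scores a maximum-likelihood logistic fit by **AIC**
  (BIC selectable), exhaustively over all subsets of ≤ `max_size` when the
  candidate pool has ≤ 20 proteins, greedy-forward otherwise. Ties break
  lexicographically. Perfect separation is detected (fitted probabilities
  saturating at the labels) and the reported scores then come from a
  lightly ridge-penalized refit; the AIC of a separated fit (≈ 2·df) still
  orders subsets sensibly for selection.
* A finding worth stating: at pilot scale (35 + 35) with several strong
  redundant markers, AIC-parsimonious selection correctly returns *fewer*
  than the planted number of informative proteins — additional markers add
  less conditional information than the penalty once the model nearly
  separates the classes. The selection-recovery experiment in the
  acceptance suite therefore states a 150-per-group derivation cohort with
  moderate (0.8 NPX) effects, the regime in which six non-redundant markers
  are individually recoverable. The pilot-scale redundancy behavior is a
  documented limitation of subset selection, not a bug.

# Co-expression and subgroup choices

* Residual matrices are clustered on their **raw row profiles** (no
  transformation); missing entries (constant proteins) are imputed to 0
  with a warning — conservative toward the null, since 0 means "no change
  in co-expression".
* Euclidean row distances are invariant under a global sign flip of the
  residual matrix, so clustering `residual(a,b)` and `residual(b,a)` yields
  identical partitions; the tests assert this rather than assume it.
* No significance procedure for residual clusters is defined in this
  literature; the package's calibration against simulated nulls (cluster
  mean |residual| against the ~$O(1/\sqrt{n})$ sampling noise of Spearman
  differences) is an extension and labeled as such.
* Pairwise DEG counting uses Welch's t per gene with BKY FDR — a
  desk-scale stand-in for external web-tool pipelines — and is therefore
  validated *only* against its own random-cluster permutation null, which
  re-assigns samples to clusters of matched sizes and records the pairwise
  DEG count distribution. Clusters below `min_cluster = 3` samples are
  skipped with a note. The single-marker stratification control (high vs
  low expression of one marker, k = 2) needs no extra machinery:
  `cluster_samples_on_markers()` with one marker.

# Numerical and reproducibility choices

* All simulation functions restore the caller's RNG state; outputs are pure
  functions of (config, seed). The pipeline derives per-stage seeds from
  one root seed.
* Exact p-value enumeration is used automatically only where its cost is
  trivial; every exact/asymptotic pair is cross-checked in the tests.
* File outputs format numbers deterministically, so a rerun with identical
  config and seed is byte-identical (asserted in the acceptance suite).
* Degenerate inputs have stated behaviors rather than errors where a
  convention exists: all-tied Mann–Whitney gives p = 1; McNemar with no
  discordant pairs gives p = 1, flagged; constant proteins give NA
  correlations, flagged and imputed to 0 only for clustering distances;
  an all-zero residual matrix collapses to one flagged cluster.

# Known limitations

* NPX values are taken as already normalized; no plate/bridging machinery.
* No covariate-adjusted regression models — the design stratifies, it does
  not adjust; confounding subtler than a two-stratum split can hide.
* Resubstitution operating points by default, to keep fidelity with the
  reference design; `evaluate_k_of_n_cv()` is the opt-in honesty check.
* The subgroup DEG test is a t-based stand-in validated against its own
  permutation null, not against any external differential-expression tool.
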