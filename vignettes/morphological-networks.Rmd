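---
title: "Individual morphological brain networks: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphnet)
```

## The model

A subject's cortex is summarized by the 68-region Desikan–Killiany
parcellation, each region carrying five regional morphometric measurements:
cortical thickness (mm), gray-matter volume (mm³), surface area (mm²),
mean curvature (mm⁻¹) and fold index (unitless). Because these span several
orders of magnitude, each feature is z-scored across the 68 regions within
the subject (sample SD, denominator n − 1), after which every region is a
commensurate 5-vector. The individual morphological brain network is the
68 × 68 matrix of Pearson correlations between those vectors: 2278 unique
weighted edges, diagonal fixed to 0, no thresholding or binarization at any
point. An edge is large when two regions have a similar morphometric
profile; with only k = 5 observations per correlation the per-subject edge
estimates are intentionally noisy, and all inference happens across
subjects, never within one.

Graph measures operate on nonnegative weights. The default transform is
`abs` (w = |r|), which preserves all 2278 edges and treats a strong
negative covariance as a strong connection; `positive` (w = max(r, 0)) is
available. Whether strongly negative edges should count as strong
connections is not decidable from the analysis this package replicates, so
both routes are exposed and recorded in provenance; the *signed* matrix is
always retained for the edge-wise statistics, which do use sign.

With edge lengths 1/w:

- **E_global**: mean of 1/d_ij over ordered pairs (Latora–Marchiori);
  lies in [0, 1] for weights in [0, 1], is 1 on a complete unit-weight
  graph and 0 on an edgeless one, and is monotone in every weight.
- **E_local(u)**: cube-root weighted neighborhood efficiency,
  Σ_{j≠h∈N(u)} (w_uj w_uh)^{1/3} / d_jh(N_u) divided by k_u(k_u − 1),
  where d_jh(N_u) is computed inside the subgraph induced by u's
  neighbors (u excluded) with lengths (1/w)^{1/3}. Nodes with fewer than
  two neighbors score 0.
- **BC(u)**: Brandes betweenness on the same lengths; each unordered pair
  counted once, endpoints excluded, tied shortest paths share credit
  fractionally. nBC = BC / mean(BC), so mean(nBC) = 1 by construction.
- **Q**: Newman weighted modularity; the partition is the best of
  `rounds` Louvain runs on seeded random node orders.

A subject's **hubs** are regions with nBC strictly above mean + SD (sample
SD; strict inequality so an all-equal profile has no hubs, and the rule is
location-invariant). A **group hub** is a region that is an individual hub
in at least 30% of the group's subjects — inclusive threshold, because the
reference consensus tables retain regions at exactly 6/20 subjects.

## Group inference

Per edge, the two groups' signed correlations are pooled, rank-transformed
(ties get mean ranks; this makes the chain invariant to monotone
transforms of the edge values), compared with an independent two-sample t
statistic, and corrected across the 2278 edges by Benjamini–Hochberg.
Levene's test (mean-centered, at 0.05) gates pooled-variance versus Welch
("adjusted") t. A one-sample Kolmogorov–Smirnov check against a normal
with estimated moments is provided to report *why* ranks are used; its
p-value is approximate because the parameters are estimated (the
Lilliefors situation, flagged in the return value), and it is never used
as a gate.

Significant edges are classified four ways from the raw group means:
same sign → decrease (toward zero) or increase (away from zero) in that
sign; sign flip → a shrinking magnitude is a decrease labeled by the
control-group sign, a growing magnitude an increase labeled by the
patient-group sign. This rule was validated against all 52 packaged
reference pairs (17 / 17 / 9 / 9 per class; `aberrant_edges()`).

Two deliberate defaults differ from strict replication:

- **Tails.** Replication mode is one-tailed with the direction taken from
  the observed mean difference. That convention is anti-conservative (its
  null p-values live on (0, 0.5]), so the package defaults to the
  a-priori two-tailed test and keeps `tails = "one", direction =
  "observed"` as an explicit option.
- **Outlier exclusion.** The reference procedure excludes outliers but
  does not state the rule; the package implements per-group Tukey IQR
  fences (default), |z| > 3, and `"off"`, all logged. Measured on null
  cohorts (20/20, k = 5), per-group IQR trimming inflates the edge
  screen's null false-discovery proportion to ~0.8: conditioning the trim
  on each group's own spread trims opposite tails of the two groups and
  manufactures separation. The trimming is therefore a documented
  replication option; calibration claims in the test suite are made with
  exclusion off.

### What a green calibration test does and does not establish

The per-edge rank t-test is exactly calibrated (measured type-I fraction
0.049 at α = 0.05). The family-wise behavior of BH on these networks is
not textbook: all 2278 edge values of one subject derive from a single
68 × 5 matrix, so edges are strongly cross-dependent with both signs,
outside BH's independence/PRDS guarantee. Measured over null replicates,
BH's E[FDP] is ~0.07–0.09 (not ≤ 0.05); Benjamini–Yekutieli, offered as
`fdr_method = "BY"`, controls it (~0.02). The acceptance-suite block that
asserts BH at nominal level is left failing on purpose, with this
analysis; the supporting green assertions live in `test-stats.R`.

Similarly, a single implanted edge difference of Δr = 0.4 (0.8 vs 0.4) at
n = 20/20 and k = 5 gives per-subject edge noise of SD ≈ 0.3–0.4, hence a
standardized effect d ≈ 1 and E[t] ≈ 3–4 — detected at the uncorrected
per-edge level in ~90% of replicates, but rarely (~15–30%) surviving a
2278-test BH correction, which needs |t| ≳ 4.5. Majority post-FDR
detection and FDR control are jointly unattainable at this design; the
acceptance block asserting it is also left failing, with the uncorrected
mechanism check asserted green inside it.

## MMSE screening

Subjects with MMSE below 28 are called patients outright (in the
replicated cohort every score below 28 belonged to a patient). Inside the
high zone (28–30), a subject is flagged when E_global or mean E_local fall
below, or mean BC rises above, decision thresholds defaulting to the
midpoint of the two group means on a labelled training set; voting is
`majority` (default), `any`, or `per-property`. The scheme is a documented
stand-in for an unspecified classifier — it claims nothing clinically.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` emulate the replicated study's
*structure*: 20 + 20 subjects, 68 regions × 5 features, group-level
correlation templates, integer MMSE in [20, 30] coupled to realized global
efficiency, balanced sex, ages ~N(73.3, 2.3²) clipped to 70–79, CDR 0/0.5.
The generative mechanism is cross-feature correlation: X = T^{1/2} Z with
Z a 68 × k standard-normal matrix, so region rows have population
correlation T and the subject's empirical network is a k-sample estimate
of T. This was chosen over per-feature mean perturbation because the
analyzed statistic *is* the cross-feature Pearson correlation — effect
sizes are specifiable directly in correlation units.

Defaults are the stated world: templates start from a lobe-block base
(0.3 within lobe, 0.1 between — modest structural covariance; chosen once
as a plausible regime, not fitted to anything), the 52 packaged reference
pairs are implanted as NC/AD targets, and the matrix is repaired to
positive definiteness by eigenvalue clipping (floor 1e-6) plus rescaling
to unit diagonal. Repair displacements above 0.05 are warned about and
logged: the most extreme implants (|r| ≈ 0.97 edges mutually inconsistent
with the base) move substantially, which is why recovery checks use
correlation with targets rather than equality. MMSE: group intercepts
29 / 26.3 (the reported group means), slope 1 point per within-cohort SD
of E_global, residual SD 1.5, clipped and rounded.

What the generator does **not** emulate: region-specific mean profiles,
spatial autocorrelation on the cortical sheet, age/sex effects (matched
by design), scanner/site effects, and any realistic covariance of
morphometric features beyond the template mechanism. A green end-to-end
test therefore establishes that the pipeline measures what the generator
implants — not that real morphometry behaves like the generator. Raw
draws get per-feature affine units (e.g. thickness ≈ N(2.5, 0.25²),
volume ≈ N(10⁴, 3000²)) purely so that z-scoring is exercised
non-trivially; z-scoring removes them exactly.

## Numerical choices

- Z-scores and hub thresholds use the sample SD (n − 1) throughout, so
  unit tests can assert exact values.
- Edge lengths are 1/w; `shortest_path_lengths()` is Dijkstra (validated
  against Floyd–Warshall), unreachable = +Inf, diagonal 0.
- Brandes tie detection uses a relative tolerance of 1e-10 on path
  lengths; with continuous weights exact ties are measure-zero, with
  integer-weight toys they are detected exactly.
- Modularity rounds default to 100 (the round count is not specified in
  the replicated analysis; 100 makes the 68-node optimum reproducible).
  Louvain's merge-only moves can structurally miss the exhaustive optimum
  on small sparse graphs with near-degenerate Q landscapes — observed on
  one 7-node test instance — which is why optimality assertions are
  statistical (≥ 95% of seeded instances), never absolute.
- Degenerate inputs are errors or warnings, not silent: zero-variance
  features/vectors are fatal with coordinates; an all-zero BC vector
  (e.g. a complete graph) skips hub screening with a warning; both-group
  zero variance with unequal means is fatal in the t-test.
- Edge identifiers are frozen: upper triangle, row-major, over the
  canonical region order (left hemisphere alphabetical, then right).
- Determinism: one seed fixes a cohort (MMSE included), per-subject
  modularity seeds are derived as `seed + subject index`, and seeded runs
  restore the caller's RNG state.

## Known limitations

- The viewer-export centroids are synthetic stand-ins
  (`dk_centroids_synthetic.tsv`), adequate for layout only.
- The fold-index regional aggregate is treated as an opaque scalar.
- Whether the replicated analysis z-scored within subject (this package's
  default) or across subjects is not recoverable; `scope = "cohort"` is
  provided but untested against any reference.
- Partial-correlation networks, covariate regression, small-world and
  degree-based descriptors are out of scope by design.
- `local_efficiency()` is the computational bottleneck (~2.5 s per
  68-node subject in pure R); tests run reduced cohorts and note it.
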