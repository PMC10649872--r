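---
title: "Methods and design choices in mgskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mgskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mgskit implements the computational arms of a MYCN-driven neuroblastoma
study — bulk genotype-by-time divergence, targeted single-cell qPCR
classification, tumor-cohort stratification with survival analysis, and
Bliss-based drug-combination scoring — together with a synthetic-data module
that generates every input with planted ground truth. This vignette explains
the models, the tunable parameters and their defaults, the numerical
conventions, and what the simulations do and do not establish about real
data.

## Divergence model

For each gene the package fits, by ordinary least squares,

```
expression ~ genotype + time + genotype:time
```

with genotype coded 0 (wild-type) / 1 (transgenic) and time numeric in
weeks. The interaction coefficient is the divergence slope in log2 units per
week; its two-sided t p-value is adjusted across genes by Benjamini–Hochberg
and genes with q below `alpha` (default 0.05) are selected. Time is treated
as a numeric trend rather than a factor because divergence *over time* is
the target contrast; a factor coding would also absorb non-monotone
profiles that are not divergence in this sense. The per-gene fits share one
QR decomposition of the design, so a 1000-gene, 12-sample fit is effectively
instant and the null calibration below can afford 200 replicate datasets.

Degenerate noiseless fits (residual variance at rounding-error level) are
resolved deterministically: a zero interaction estimate gives p = 1, a
non-zero one p = 0. Without this guard, floating-point residuals of order
1e-15 would turn exact fits into arbitrary t statistics.

Selected genes are clustered with agglomerative Ward clustering in the
`ward.D2` convention: Euclidean distances are passed unsquared and squared
inside the merge criterion. Genes are standardized (per-gene Z across all
samples) first, so clustering groups trajectory *shapes*, not expression
levels. The default of k = 3 gene groups reflects the archetypes a
two-genotype timecourse supports: up-diverging, down-diverging, and shared
trends. The test suite verifies the merge sequence against a brute-force
minimal-variance-increase oracle on 8-gene instances, where exhaustive
search is feasible.

Over-representation of flat gene sets uses the hypergeometric upper tail
(`phyper`) with BH adjustment across sets. No GO DAG structure is modelled:
sets are plain gene lists read from GMT, and the toy sets shipped by the
simulation scripts are labelled synthetic.

## Single-cell qPCR model

Raw Ct values are normalized as `expression = LOD − Ct`, floored at 0, with
not-detected wells set to 0 and a default LOD of 24 cycles. One cycle is one
doubling, so the result is log2-scaled with the detection limit as zero.

Signature scores are the mean per-gene Z across **all** cells. This
reference population is locked deliberately: classification removes cells,
and recomputing Z on the filtered population would shift every threshold.
The test suite asserts that pre- and post-exclusion scores differ, i.e.
that the lock is load-bearing.

Cell typing applies strict-inequality threshold rules in a fixed order of
precedence: Schwannian score > 0.75 first, then neuroblast score > 0 and
greater than the ganglion score, then the symmetric ganglion rule;
everything else — including exact neuroblast/ganglion ties — is excluded.
The Schwannian rule is evaluated first because its threshold is the only
absolute one; a cell passing both the Schwannian and neuroblast rules is
Schwannian. The precedence is configurable only through the cutoff argument;
the order itself is part of the classification contract. Cells with no
detected signature gene at all have scores that reflect only the
not-detected convention, so `classify_cells` accepts an optional
detected-gene count and excludes such cells outright with a warning.

Group comparisons use the Wilcoxon rank-sum test, exact for combined n ≤ 20
(the tie-corrected normal approximation otherwise), and marker
relationships use Pearson correlation — in both cases the field-standard
tests, delegated to `stats`.

## Cohort stratification and survival

Tumors are clustered on the divergence panel exactly as genes are (per-gene
Z, Ward/`ward.D2`, cut at k = 3). The three clusters are *named* by
descending mean MGS score — `MGS.High`, `MGS.Int`, `MGS.Low` — because
cluster ids from a tree cut are arbitrary; the naming rule makes the labels
reproducible under any permutation of raw ids.

The Kaplan–Meier estimator and the k-group log-rank test are delegated to
the `survival` package, which the analysis convention of this field treats
as canonical; mgskit wraps them behind its own surface and the tests verify
them against hand-computed product limits and a brute-force aggregated-
risk-set oracle, so the wrappers cannot drift from the definitions. Ties in
event times follow the standard aggregated-risk-set formulation. Clinical
splits compare the MGS score by rank-sum across MYCN amplification (tumors
with unknown status dropped from this split only), stage 4 versus other
stages, and age above versus below 18 months.

## Dose–response, AUC, and Bliss synergy

Viability is the fraction of untreated control, computed per replicate by
dividing each well by its replicate's mean control signal. Values above 1
are **retained**: clipping would bias the AUC of weak agents downward.

The curve summary is the trapezoidal integral of mean viability over log10
dose, across the observed ladder, with no interpolation or Hill re-fitting
in between — the integrated object is the curve as plotted, which avoids
fit failures on non-sigmoidal combination curves. Mean viability is
integrated (rather than integrating each replicate and averaging) for the
headline AUC; replicate-level AUCs exist separately for inference. AUCs are
normalized within a comparison set to the maximum raw area, anchoring the
least potent condition at 1; by default the set holds the two singles and
the combination of one experiment (optionally across both MYCN states, the
convention used by the analysis drivers).

The Bliss additivity curve converts each single agent's mean viability to a
fraction affected (`1 − viability`, clamped to [0, 1] because Bliss is a
probability statement), combines the pair as `fa + fb − fa·fb`, and
converts back. Synergy is the additive curve's normalized AUC minus the
combination's; potency is 1 minus the combination's normalized AUC. Both
additive and measured curves are normalized within the same comparison set
— comparing unlike-normalized areas would make the synergy sign depend on
the normalization anchor. Statistical comparison of two AUCs uses a Welch
t-test on replicate-level AUCs; two zero-variance groups yield p = 1 when
identical and the machine-floor p when separated, so degenerate noiseless
inputs remain well-defined.

MYCN selectivity ranks combinations lexicographically by Δsynergy then
Δpotency between induction states, with ties broken by label. Both metrics
matter but no weighting between them is defensible a priori, so the
ordering is lexicographic rather than a weighted sum.

## The synthetic-data module

The generators define the study conditions under which the pipeline is
verified:

* **Dose–response**: Hill curves
  `floor + (1 − floor) / (1 + (d/ic50)^slope)` with i.i.d. Gaussian
  replicate noise truncated at 0. Truncation is implemented as a floor at 0
  (censoring) rather than rejection sampling so that a seed always consumes
  the same number of draws; there is no upper truncation because plate
  readers report values above control. Default noise SD 0.05 viability
  units and 3 replicates, typical of resazurin-style viability assays.
* **Combinations**: the combined fraction affected is
  `clamp01(fa + fb − fa·fb + interaction)` at each constant-ratio dose
  pair, so `interaction = 0` is exactly Bliss-additive and the sign of
  `interaction` is the planted truth the scorer must recover.
* **Single cells**: each cell draws a type from the mixing proportions and
  a Ct vector around its archetype (noise SD 1 cycle); Ct at or above the
  LOD becomes not-detected. The default archetypes separate on- from
  off-type marker genes by 3 noise SDs — the separation at which the
  recovery guarantee (≥ 95 % correct among non-excluded cells at n = 1000)
  is asserted — with a mix of 45 % neuroblasts, 35 % ganglion cells and
  20 % Schwannian stroma, a plausible composition for dissociated
  sympathetic ganglia.
* **Timecourse**: diverging genes rise at `+effect/2` log2/week in the
  transgenic genotype and fall at `−effect/2` in the wild type, so the
  planted interaction equals `effect` exactly; null genes share one random
  mild slope. The flagged gene count is `round(n_genes × fraction)`,
  deterministic by construction. Defaults: 1000 genes, 10 % divergent,
  weeks 1/2/6, 2 replicates per genotype-timepoint, noise SD 0.5 log2
  units — microarray-like. The recall check plants `effect = 3 × noise SD`.
* **Cohort**: three latent classes of deterministic sizes
  (`round(cumsum(props) × n)`), MGS genes shifted +2/0/−2 log2 by class
  (panel filler genes at half that), exponential event times with class
  hazard ratios (default 3/1.5/1 over a baseline of 0.01 events per time
  unit), administrative censoring at a 120-unit horizon plus uniform
  dropout on (0, 2 × horizon). MYCN amplification, stage 4 and age > 18
  months are drawn with class-dependent probabilities (0.6/0.25/0.05,
  0.6/0.35/0.2, 0.6/0.45/0.3) so the clinical splits carry signal. The
  default n = 475 matches a published neuroblastoma microarray cohort's
  size.

The assay variance levels are not taken from any measured source; they are
chosen once as values a practitioner would call realistic for the
respective platforms, and they stay fixed. Every generator is
seed-deterministic (identical config ⇒ byte-identical output, without
touching the caller's RNG state) and returns its ground truth, so
downstream recovery is scored without re-derivation.

**What passing tests show — and what they do not.** The generators emulate
the statistical *shape* of the study's data: Hill-shaped viability,
archetype-plus-noise Ct structure with an LOD, linear-in-time log2
trajectories, class-shifted cohort expression with exponential survival.
They do not emulate microarray probe-level artifacts, amplification
chemistry, Fluidigm chip layouts, batch structure, or non-proportional
hazards. Green tests therefore certify the *computations* — the estimators
recover what was planted under the stated noise — not the biological
conclusions of any particular dataset.

## Numerical conventions and problem sizes

* Exact examples (trapezoid AUC, LOD boundaries, Bliss values, rank-sum
  2/252, hypergeometric 1/15504) are asserted to 1e-12 or exactly.
* The noiseless synergy-versus-oracle check uses a 200 001-point fine-grid
  integral and a 1e-9 relative tolerance; the grid, not the method, limits
  the agreement.
* Calibration checks use 500 simulated null AUC comparisons, 200 × 1000
  genes for divergence false selection, 1000 log-rank null simulations, 500
  seeded sign-recovery panels, and 100 Ward-oracle instances of 8 genes —
  sizes chosen so each property is measured with small Monte-Carlo error
  while the whole suite stays quick on one core.
* Ward merge ties are theoretically possible but have probability zero
  under continuous noise; the brute-force oracle breaks ties by lowest pair
  index, matching `hclust`'s behavior on the instances tested.

## Known limitations

* The divergence model is a per-gene OLS interaction stand-in with a
  configurable design; it does not model probe-level microarray error or
  moderated variance (no empirical-Bayes shrinkage), which limma-style
  pipelines would add for small n.
* Synergy inherits the comparison-set convention: a combination's score
  changes if the set it is normalized within changes. The default set is
  documented and kept fixed within each experiment.
* The additive curve is built from mean single-agent viabilities;
  replicate-resampled additive curves (and hence confidence intervals on
  synergy) are not implemented.
* No Cox modelling or multivariable adjustment is provided for the cohort
  arm; the stratified analysis is deliberately univariate.
* Gene identifiers are exact case-sensitive strings; mouse/human symbol
  mapping is the caller's responsibility.
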