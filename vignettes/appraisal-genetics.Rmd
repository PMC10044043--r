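---
title: "Genetic parameters for dairy-goat appraisal traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic parameters for dairy-goat appraisal traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprigen)
```

## The problem

Dairy-goat breeding programmes such as CAPRIGRAN's for the
Murciano-Granadina evaluate conformation by a Linear Appraisal System
(LAS): seventeen traits in does (ten in bucks, which carry no mammary
system), each rated 1–9 between its biological extremes, grouped into
four weighted major areas. Many traits are also measurable directly
(zoometry, in cm or degrees), and the two representations should carry
the same genetic information if the scales are well constructed. Whether
selection on major areas is sensible depends on the genetic parameters:
per-trait heritabilities and the genetic/phenotypic correlation structure
across the panel. This package implements the whole estimation pipeline
and, because appraisal datasets of this kind are not public, validates it
by parameter recovery on synthetic herds whose true parameters are set to
the published Murciano-Granadina estimates (`reference_components()`,
`reference_correlations()`).

## Scale translation

Measured traits map onto scores by piecewise-linear interpolation through
the anchors (minimum → 1, midpoint → 5, maximum → 9), with two
refinements:

* **Decreasing scales** (rump angle 55°→31°, rear insertion height
  11→3 cm, nipple placement 90°→0°) run the interpolation in reverse, so
  the biologically better low measurement earns the high score.
* **Anterior insertion** is the one non-uniform scale: the published
  anchors (45°, 1), (90°, 5), (120°, 9) imply a steeper step below the
  midpoint than above it, so it is stored as explicit knots.

Rounding is half-away-from-zero (the published system states no rounding
rule; half-to-even would bias scores toward even points). Scores are
clipped to the point range. The revised "proposal" scale set keeps the
same anchors and rescales them linearly onto the narrower ranges
(e.g. mobility 1–5), which reproduces the published statements that
optima formerly at 9 sit at 5 on the new scales.

Two aggregation conventions are the package's own, since the published
system does not print them: each trait contributes
`min(score / optimum, 1)` against the mature-animal optimum, and a major
area scores the mean contribution × 100. The doe weights 25/15/40/20 and
buck weights 50/20/30 and the qualification bands (IN ≤ 69 … E ≥ 90) are
as published; a fractional final score is rounded half-away-from-zero
before classification. The catalogue is exportable/overridable as YAML
(`write_scales()`/`read_scales()`), so a programme using different
anchors loses nothing.

One published irregularity: the nipple-diameter range is printed in
degrees but its midpoint and optimum in cm; the package stores cm.

## Screening

The pre-model screens mirror standard appraisal-data practice:

* **Distribution diagnostics**: moment skewness and excess kurtosis with
  the platykurtic/leptokurtic label.
* **Hoeffding's D** from joint midranks. The p-value comes from a seeded
  label-permutation null (`(1 + #{D* ≥ D}) / (B + 1)`), not from the
  classical table interpolation — reproducible, exact under
  exchangeability, and tested for uniformity under independence.
* **VIF filter**: `VIF_j = 1/(1 − R²_j)` with categorical predictors
  one-hot encoded (reference level dropped; a factor is judged by its
  worst dummy), dropping the largest VIF iteratively until all ≤ 5.
  Perfect collinearity reports `Inf` and is dropped first.
* **Spearman redundancy**: pairs with |ρ| ≥ 0.5 are redundant; the member
  with the larger mean |ρ| against the other remaining variables is
  dropped (tie: the later column). The published procedure left this
  tie-break implicit; here it is explicit and reported per decision.
* Normality/homoscedasticity gatekeepers delegate to `stats::ks.test`
  and `car::leveneTest` — they gate, they are not re-derived.

## The fixed-effects (ANCOVA) layer

Per trait, ordinary least squares on
`y = μ + farm + lactation stage + kidding month + farm:kidding year +
b₁·DIM + b₂·age + b₃·age²` (covariates centred; age enters linearly and
quadratically). Factors are effects-coded (sum-to-zero), the classical
convention under which "Type III" marginal tests are meaningful in
unbalanced data; each term's SS is the RSS increase from deleting exactly
that term's columns while all others stay — which is also the brute-force
definition, so the implementation and the classical computation coincide
(and are cross-checked against `car::Anova(type = 3)` in the tests).
Goodness of fit reports R², adjusted R², predicted R² from PRESS using
the hat diagonal (observations with `h = 1` are excluded with a warning),
MSE = RSS/df, RMSE and Durbin–Watson. The DW ordering is whatever
ordering the records carry; the pipeline sorts by farm, date, animal. The
residual rule flags internally studentized residuals
(`e / (s√(1−h))`) outside ±1.96 and passes at ≤ 5%. Note that for
heavy-tailed errors studentization rescales by the inflated sample SD, so
a t₃ error distribution actually flags *fewer* than 5% — the property
tests therefore use double-exponential errors, whose exceedance after
rescaling is ≈ 6.3%.

## Pedigree algebra

The numerator relationship matrix is built by the tabular method
(`a_ii = 1 + a_sd/2`, `a_ij = (a_js + a_jd)/2`), dense only up to 5,000
animals — beyond that only the sparse inverse is ever needed. Inbreeding
uses recursive kinship with memoization (no full A), and A⁻¹ follows
Henderson's rules with the inbreeding-adjusted Mendelian-sampling
variance `d_i = ½ − ¼(F_s + F_d)` (¾ − ¼F with one known parent). The
by-product `log|A| = Σ log d_i` is stored on the matrix and reused by the
REML likelihood. Unknown parents are unique unrelated non-inbred
founders; no genetic groups are fitted. All of this is validated against
a gene-dropping Monte-Carlo oracle and dense inversion.

## REML

The animal model is `y = Xb + Za + e`, `var(a) = Aσ²ₐ`,
`var(e) = Iσ²ₑ`, with one record per animal (the appraisal is done once
per lifetime, so no permanent-environment effect is identifiable and
repeatability is out of scope). With `W = [X Z]`, `C0 = W′W` and
`D0 = blkdiag(0, A⁻¹)`, the mixed-model coefficient matrix at variance
ratio λ = σ²ₑ/σ²ₐ is `C0 + λD0`, and

`−2 logL_R = (n−p−q)·log σ²ₑ + q·log σ²ₐ + log|A| + log|M(λ)| + SSR/σ²ₑ`

up to a constant, where SSR is the MME residual quadratic form. One
supernodal symbolic Cholesky is analysed per pattern and numerically
updated at every evaluation.

**Univariate.** For fixed λ the criterion profiles analytically
(σ̂²ₑ = SSR/(n−p)), leaving a one-dimensional search in h². The default
algorithm runs EM-REML sweeps first — monotone in the restricted
likelihood, which the tests assert per iteration, but each sweep needs a
dense MME inverse block for the trace term, so EM is gated to systems of
at most `em_limit = 600` equations — and then a Brent search plus
quadratic refinement on the profiled likelihood down to a relative
change of 10⁻¹² in −2 logL (the convergence criterion the appraisal
evaluations used). A solution at the h² → 0 boundary is flagged and
reported as h² = 0.

**Bivariate.** Two traits measured on the same records share X and Z;
the coefficient matrix is `kron(E⁻¹, C0) + kron(G⁻¹, D0)` in
trait-major ordering. The six parameters are maximized directly under the
parameterization (log variances, Fisher-z correlations), which keeps
every iterate strictly inside the admissible cone — no mid-iteration
bending is ever needed (bending, `bend_psd()`, is still used to repair
*published* pairwise tables when they seed the simulator). Optimization
is Nelder-Mead to a relative 10⁻⁹, then coordinate-wise quadratic
refinement to the 10⁻¹² criterion; starting values come from univariate
fits of each trait with the sample phenotypic correlation assigned to
both G and E (the classical 0.2/0.8 phenotypic split,
`starting_values()`, remains the documented default start for single
fits). Full multi-trait REML over all 17 traits is deliberately not
attempted: heritabilities come from univariate runs and correlations
from the 136 pairwise runs, mirroring the published workflow, with
`bend_psd()` available to pool a jointly PSD G afterwards.

**Standard errors** are computed from the finite-difference observed
information of −2 logL_R at the optimum (central differences, relative
step 10⁻⁴), with delta-method propagation to h² and to the correlations.
This replaces the original software's internal machinery, which is not
reproducible from its description; observed and average information agree
asymptotically, and the tests check the SEs against the empirical
replicate spread.

**BLUE/BLUP.** `solve_mme()` solves the sparse symmetric system at the
converged components for all pedigree animals (unscored animals get
predictions through relatives; animals with no scored relatives shrink
exactly to 0). Reliabilities `1 − PEV/(σ²ₐ(1+F))` need the inverse
diagonal and are only offered for systems small enough to invert densely
(3,000 equations by default). The fixed-effect solutions are BLUEs under
the full-rank treatment coding that `build_design()` produces; aliased
columns are dropped and reported, never silently absorbed.

## The synthetic-herd generator

`simulate_herd()` emulates the appraisal data's structure: discrete
generations (founders unrelated; random or half-sib-heavy mating),
farms, primipara/multipara stages, kidding months and years, a
farm×year interaction, DIM and age covariates, and multivariate
breeding values (founders ~ N(0, G); descendants get the parent average
plus Mendelian sampling with covariance `½G(1 − (F_s+F_d)/2)`).
Records are `y = fixed structure + a + e`, e ~ N(0, E), one record per
scored animal, with every true contribution stored alongside so recovery
can be checked exactly.

Defaults follow the published cohort description where one exists: 76
farms in the `caprigran` preset (desk preset: 15), kidding years
2005–2019, DIM uniform on 30–210 d, primipara age ~ N(1.61, 0.35) and
multipara age ~ N(3.96, 1.74) truncated at 1 year, and G/E built from the
published component and correlation tables, bent to PSD (the bending
shift is logged in attributes). Where nothing is published the values
are ordinary for Spanish dairy-goat herds and fixed once: farm SD 0.3–0.5
phenotypic SDs, month SD 0.2, farm×year SD 0.25–0.3, DIM slope 0.002/d,
age coefficients 0.15 and −0.015.

What the generator does *not* emulate — rater bias and drift, ordinal
discreteness (by default; `round_to_las` exists and the tests document
that rounding attenuates recovered h², never inflates it), selection and
culling over time, heterogeneous farm variances — bounds what passing
recovery tests prove: the estimator is correct under its own model at
realistic scale, not that any field dataset satisfies that model.

## Problem sizes and numerical choices

The recovery studies run at "desk" scale, chosen so the full validation
suite completes on one CPU while leaving the estimates' sampling error
well inside the acceptance bands: univariate recovery on 1,500-animal
pedigrees (300 founders, 3 × 400 offspring, 1,200 records), bivariate
recovery on 2,600-animal pedigrees (500 founders, 3 × 700 offspring,
2,100 records; the pair studies need the extra information because
correlation estimates at moderate heritability are the noisiest
quantities in the pipeline), ten seeded replicates per quantity.
Degenerate inputs are handled explicitly: empty factor levels are
dropped with a warning, aliased design columns reported, hat values of 1
excluded from PRESS, constant screening columns excluded with a reason,
and REML boundary solutions flagged rather than hidden.

## Known limitations

* Ordinal 1–9 scores are treated as Gaussian, as in the source
  evaluations; the rounding experiment quantifies the attenuation this
  causes but no threshold model is offered.
* No genetic groups for unknown parents, no maternal or
  permanent-environment effects, no genomic relationships.
* The bivariate optimizer is derivative-free; it is robust but not the
  fastest route for very large pedigrees (the 279k-animal national
  pedigree is out of desk scope by design — the sparse structures scale,
  the dense reliability and EM paths do not).
* Published h² values differ in the third decimal from the ratio
  σ²ₐ/σ²ₚ of the same published rows (stature: 0.4986/1.15511 = 0.4316
  vs 0.4300 printed); the package always reports the ratio and keeps
  both in the reference table.
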