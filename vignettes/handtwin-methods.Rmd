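---
title: "Models and methods in handtwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in handtwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handtwin)
```

`handtwin` takes raw hand-preference questionnaire responses and pegboard
trial times through laterality scoring, prevalence statistics, and classical
twin-design variance decomposition. This vignette documents the models, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## Laterality scoring

Each of the 10 inventory items is answered with a hand (left / right / no
preference) and, when a hand is preferred, a degree (always / usually).
Points go into Left/Right columns: always = 2 in the preferred column,
usually = 1, no preference = 1 in both. The laterality quotient is
EHI = (RH − LH)/(RH + LH) over the summed columns, so all-always-right gives
+1 and all-always-left gives −1. Two deliberate readings of the instrument:

* **"Usually" contributes (1, 0)** — one point in the preferred column and
  none in the other. The instrument text is silent about the non-preferred
  column; assigning it 0 is the only reading under which the stated ±1
  range is attainable.
* **Missing items** are simply omitted from the sums (no imputation or
  proration); a record with no usable item has no EHI rather than a silent
  zero. The number of items actually used is carried through as
  `n_items_used`.

The binary direction measures put the zero boundary in the non-right
class: EHI2 = 1 iff EHI > 0, and likewise PegQ2. Writing- and drawing-hand
binaries code "no preference" as 0 (non-right), matching the convention
that NRH pools left-preferring and no-preference children.

PegQ averages the **three fastest** of the five recorded trials per hand
("best" = smallest duration; ties keep the earliest trials, which cannot
change the mean) and applies 2(L − R)/(L + R). The practice trial is never
part of the input. The switch-inference flag is true when the child writes
with the right hand but the left column outscores the right over the eight
items other than writing and drawing.

## Prevalence statistics

Contingency tests are uncorrected Pearson chi-squares — the form under
which published 2×2 statistics of this design reproduce exactly; Yates
continuity correction is never applied. Per-item tables are built from each
item's own valid responses, so item denominators may differ. The
Bonferroni level for the family of 10 item comparisons is α/10.

Two documented defaults where software conventions vary:

* **Item-total correlations** default to the uncorrected item-vs-total
  form; the corrected (item-vs-rest) variant is available via
  `corrected = TRUE`. Published tables rarely state which was used.
* **The sample-by-sex ANOVA** defaults to Type III sums of squares with
  sum-to-zero contrasts (via `car::Anova`); Types I and II are selectable
  because the originating software's convention is typically unstated. In
  a balanced design all three coincide (this is tested); in unbalanced data
  published F values can only be matched qualitatively without knowing the
  convention.

Cronbach's alpha uses the classical variance-ratio form on complete cases.
Cross-measure correlations are pairwise-complete Pearson with binary
measures entered as 0/1 codes and sex coded 0 = male, 1 = female.

## Twin models

Variance is decomposed into additive-genetic (A), shared-environment (C)
and non-shared (E) parts. All models use the **path (Cholesky)
parameterisation**: implied component covariances are XX′ with X lower
triangular, hence positive semi-definite by construction — negative
"variance estimates" are impossible and only squared/standardized
quantities are reported (path signs are not identified; diagonals are
reported non-negative). The DZ additive-genetic correlation is fixed at
0.5 and no dominance component is modelled.

**Continuous traits** use the full-information Gaussian pair likelihood:
each pair contributes the density of its observed sub-vector (pairs with a
missing co-twin contribute the univariate marginal), so missing data need
no deletion. Internally pairs are grouped by zygosity and missingness
pattern and the likelihood is evaluated from sufficient statistics, which
makes the 200-replicate recovery studies cheap; the grouped value equals
the per-pair density summation to machine precision (tested against a
brute-force oracle).

**Binary traits** use the liability-threshold model with total liability
variance constrained to 1: the trait is 1 when a standard-normal liability
exceeds a threshold τ, and pair concordance cells are bivariate-normal
orthant probabilities with correlation a² + c² (MZ) or a²/2 + c² (DZ).
Orthant probabilities come from `mvtnorm::pmvnorm`, whose bivariate case is
a deterministic high-accuracy routine; the tests verify it against direct
2-D quadrature of the density to 1e−6.

**Optimisation.** Quasi-Newton (BFGS) for continuous and bivariate models,
Nelder–Mead (plus Brent in one dimension) for the threshold models, each
with moment-based starting values and seeded jittered restarts. Infeasible
points (non-PD implied covariance, a² + c² ≥ 1) are penalised, never
errors mid-search. Ladders are fitted with warm starts (each constrained
model starts from its parent's solution) and a repair pass refits any
parent that a nested model beats — so nesting of −2LL holds on every
dataset, and a genuinely negative LRT statistic raises an error naming the
optimizer rather than reporting nonsense.

**Conventions.** Degrees of freedom are observed statistics minus free
parameters: a univariate ACE fit counts μ, a, c, e (binary: τ, a, c — the
unit-variance constraint removes e). The bivariate ladder has 11 (ACE),
8 (AE), 7 (AE1, AE2), 8 (CE) and 5 (E) free parameters. AIC is
−2LL − 2·df, the OpenMx-style convention, which differs from −2LL + 2k by
a per-dataset constant and therefore ranks models identically. LRT
p-values use the naive χ² reference even for variance components on the
boundary, matching common practice in this literature; the conservative
50:50 mixture correction is easy to apply externally to the reported
Δ(−2LL) but is deliberately not the default.

The **homogeneity ladder** fits a saturated Gaussian model (means and
variances free per group and twin order, twin correlations per group) and
successively equates across twin order, across pair sex composition
(male–male, female–female, opposite-sex), and across zygosity, testing each
step by likelihood ratio. Twin correlations stay zygosity-specific
throughout — they carry the genetic signal. Opposite-sex DZ pairs are
pooled with same-sex DZ pairs in the model fits (the ladder is the place to
check that pooling); age and sex are not regressed out of the means by
default.

The **correlated-factors view** of a bivariate fit reports per-trait
standardized components plus factor correlations
rX = (XX′)₁₂ / √((XX′)₁₁(XX′)₂₂); it is an exact reparameterisation (the
component covariances are unchanged), and a correlation is reported as
undefined when a trait has zero variance in that component.

## The synthetic-data generator

The generator inverts the models above, with defaults fixed to the study
conditions the package is designed around:

* **Cohort shape**: 91 MZ pairs (41 male, 50 female), 114 DZ pairs
  (25 male, 21 female, 68 opposite-sex; opposite-sex pairs are ordered
  male-first), 426 singletons (221 boys, 205 girls); twin ages ~N(8.7, 1.2²)
  years shared within pair, singleton ages ~N(8.3, 1.2²).
* **Latent structure**: standardized a² = .205 for the preference liability
  and .217 for pegboard laterality, no shared environment, independent
  genetic factors and correlated non-shared factors (rE = .53, chosen so
  the implied phenotypic cross-trait correlation is ≈ .42).
* **Items**: a graded-response model — item latent = loading × liability +
  noise, cut into always-left … always-right at ±`np` and ±`always`.
  Loadings are highest for writing/drawing (.92) and lowest for broom and
  box lid (.45), with wide no-preference bands on the weakly lateralised
  items. The population liability mean (1.5) was calibrated once at large
  n so that ~8% of children have EHI ≤ 0, and then frozen; the resulting
  composite is J-shaped and the 10-item alpha on simulated cohorts is
  around .85.
* **Sex effect**: a male:female non-right-handedness odds ratio (default
  1.27, the canonical meta-analytic magnitude) implemented as a symmetric
  liability mean shift solved from the target odds ratio — not as extra
  variance components.
* **Pegboard**: subject-true index q ~ N(.095, .095²); hand mean times
  base·(1 ± q/2) (so the noise-free scored index equals q exactly) plus
  i.i.d. trial noise of 0.25 s on a 10 s base. Configurations that could
  produce a non-positive time are rejected, never floored.
* **RNG contract**: one root seed split deterministically per
  sub-generator, with draws in subject order, so appending subjects does
  not perturb earlier subjects' data; fixed seed gives byte-identical
  files.

What the generator does **not** emulate: age trends in handedness strength,
chorionicity, mirror twinning, item-specific cultural pressure beyond the
loading/threshold pattern, and non-Gaussian trial-time tails. A further
honest caveat: the configured a² applies to the latent liability; observed
EHI computed from the simulated items is attenuated by item measurement
error and by the bounded J-shaped scale (to roughly .14–.15 at the default
settings), exactly as real questionnaire composites are attenuated relative
to the liability. Passing recovery tests on `simulate_pairs()` output
therefore shows the estimator is correct for the trait it sees; it does not
show that a questionnaire instrument measures the liability without error.

## Problem sizes and tolerances in the test-suite

The suite verifies published contingency statistics from their printed
counts to 2 decimal places; likelihood values against brute-force oracles
at 1e−8 relative (continuous) and 1e−6 (orthant probabilities); parameter
recovery as the mean of 200 replicates at 1,000 + 1,000 pairs (continuous,
tolerance ±.02) and 2,000 + 2,000 pairs (binary at 8% prevalence,
tolerance ±.03); and AIC model selection under the independent-genetic-
factor truth at the study's own size (40 replicates) and at ten times it
(20 replicates). These sizes keep the full suite in the low minutes while
leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

* No dominance (ADE), sex-limitation, or extended-family designs; the
  homogeneity ladder is the only heterogeneity instrument.
* Boundary-aware LRT reference distributions are not the default (see
  above).
* The binary-trait parameter count (τ, a, c) is one convention among
  several; published tables sometimes imply different bookkeeping, and the
  package documents its own rather than forcing agreement.
* `pmvnorm`'s bivariate routine is accurate to ~1e−15, far below the 1e−8
  tolerance the likelihood code targets, but extremely small cell
  probabilities (prevalence ≪ 1%) will still lose relative precision.
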