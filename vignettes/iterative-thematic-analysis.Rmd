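---
title: "Iterative thematic analysis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative thematic analysis: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical procedure and its assumptions, the parameters that matter, what
the synthetic generator does and does not emulate, and the numerical and
design choices made where the protocol left them open.

## The procedure

The pipeline addresses a screening problem: a binary outcome observed on
n respondents of a weighted survey, p encoded covariate columns with
p on the order of thousands, outcome prevalence far below one half. The aim
is not a single predictive model but a *layered* description: groups of
topically related correlates ("themes"), ordered by how strongly they carry
the outcome signal.

One round consists of five steps.

**1. Lasso screen.** Survey-weighted L1-penalized logistic regression over
all current columns. The fitted objective is

$$\ell(\theta_0,\theta) \;=\; \sum_i w_i\left[y_i\eta_i - \log(1+e^{\eta_i})\right] \;-\; \lambda\,\lVert\theta\rVert_1, \qquad \eta_i = \theta_0 + X_i\theta,$$

with weights normalized to mean 1 (so $\sum_i w_i = n$ and the objective is
on the effective-sample-size scale), columns standardized to weighted mean
0 / variance 1, and the intercept unpenalized. λ is chosen by k-fold
cross-validation (k = 5), maximizing the mean held-out *weighted
log-likelihood* — not classification accuracy, which is uninformative at
14% prevalence and meaningless at 1%. Variables whose standardized
coefficient is zero (|θ̂ⱼ| ≤ `zero_tol`) are dropped.

**2. Ridge refit.** The same objective with penalty $\lambda\lVert\theta\rVert_2^2$
on the lasso survivors, λ again by 5-fold CV. The ridge penalty is written
*without* the conventional ½ factor; this is deliberate and documented so λ
values are comparable across implementations. Ridge shrinks but never
zeroes, giving every survivor a usable rank.

**3. Knee selection.** Standardized coefficient magnitudes are sorted
descending and the Kneedle algorithm locates the knee: x and y are min–max
normalized to [0, 1], the difference curve $d_i = (1-y_i) - x_i$ is formed,
and the first local maximum of d that is followed by a drop of more than
S · mean(Δx) (before any higher maximum) is the knee. Variables strictly
above the knee are the round's selection. Normalization makes the result
invariant to affine rescaling of the coefficients; an exactly linear or
flat curve has no knee.

**4. Theme coding.** Selection is handed to a *coder* — in real analyses a
human working through two-column assignment files (`file_coder()`), in
automated runs the generator's ground-truth map (`truth_coder()`). A
reserved label `uncategorized` marks variables that fit no theme.
Agreement between two coders is the percentage of identically coded
variables after case/whitespace normalization.

**5. Theme removal.** The theme containing the maximum-coefficient
variable is identified and its *coded* variables are removed from train
and test data before the next round.

Stopping: three consecutive rounds with no new theme, or any round with no
new variable, or the `max_rounds` safety cap, or a degenerate round (no
lasso survivor, or no knee). Every round's ridge model is scored on the
same held-out stratified 20% test split, fixed before round 1 and reduced
column-wise in lock-step with the training data so no refit ever sees test
rows.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `ratio` | 0.8 | conventional 80:20 train/test protocol |
| `stratified` | `TRUE` | at 1% prevalence an unstratified 20% split can end up with a handful of positives; plain random splitting remains available |
| `k` | 5 | standard fold count for CV-based λ selection |
| λ grid | 50 log-spaced points, λ_max → 10⁻⁴λ_max | λ_max is the smallest λ with an all-zero L1 solution, computed from the weighted score at the null model; re-derived each round because the column set shrinks |
| `sensitivity` (Kneedle S) | 1.0 | the customary default; larger values demand a sharper knee |
| `mode` | `"absolute"` | rank by magnitude: protective (negative) correlates are substantively as relevant as risk factors; `"signed"` mode is retained for sensitivity analyses |
| `zero_tol` | 1e-8 | "coefficient equals zero" on the standardized scale; coordinate-descent solvers return exact zeros but the contract must not rely on it |
| `max_rounds` | 10 | safety net only; the substantive stopping rules fire first on realistic data |
| `threshold` | 0.5 | conventional BER cut-off, reported alongside the prevalence-matched threshold, which is the informative one for rare outcomes (at 1% prevalence a 0.5 cut-off labels everything negative and BER degenerates to 0.5) |

λ is re-selected by CV in **every** round: the design shrinks each round,
so a fixed λ would change meaning. Both this and the single fixed test
split are configuration-level choices; the alternative (re-splitting per
round) would entangle round-to-round metric changes with split noise.

## The synthetic generator

`synthetic_spec()` describes a cohort emulating the structure of a
DHS-like IPV help-seeking extract at its published scale: n = 19,468
respondents; six themed blocks of five binary variables; 970 independent
Bernoulli noise columns (~1,000 columns total); positive log-normal
sampling weights; a rare outcome. Mechanics:

* **Correlated binaries** by latent-Gaussian thresholding: a block shares
  a factor $g$, each member's latent value is
  $z = \sqrt{\rho}\,g + \sqrt{1-\rho}\,\varepsilon$, binarized at the
  quantile giving the marginal positive rate. This yields exact marginals
  and a closed-form (by bivariate-normal quadrature) implied phi
  correlation, which the tests verify empirically. Across-block latent
  correlation is 0 by default to isolate the theme-removal logic.
* **Outcome** from the logistic model over signal columns, with log-odds
  effects drawn once per spec from U[0.5, 1.2] and an intercept calibrated
  by bisection so that the Monte-Carlo mean of the event probability over
  200,000 fresh covariate draws hits the target prevalence within 1e-3.
  Targets: 14.4% (any-source help-seeking) and, via
  `formal_outcome_spec()`, 1.0% (formal institutions).
* **Weights** log-normal (sdlog 0.5, normalized to mean 1), independent of
  covariates by default — survey weights of this dispersion are typical of
  national household surveys, and independence keeps weighted and
  unweighted estimands equal so calibration is checkable.
* Free parameters not pinned by the emulated study were fixed once at
  field-realistic values: signal-item marginal rates 0.3 (common for
  attitudinal/experience indicators), noise-column rates uniform on
  [0.05, 0.5].

What the generator does **not** emulate: real DHS questionnaire content,
skip patterns and "don't know" codes, informative (covariate-dependent)
weights, cross-theme correlation, and any mismatch between the logistic
data-generating model and the fitted model family. Passing tests therefore
demonstrate that the pipeline recovers planted structure under its own
assumptions at realistic scale and prevalence — not that it would uncover
the same themes in the restricted survey data.

## Numerical notes

* The convex subproblems are solved by glmnet's coordinate descent. The
  mapping between the summed, weight-normalized objective above and
  glmnet's per-observation parameterization (glmnet λ = λ/n for L1 and
  2λ/n for L2, with weights summing to n) was verified against direct
  optimization; correctness of a fit is defined by the KKT conditions of
  the stated objective, which the test suite checks at 1e-6 with
  independently computed gradients, and by agreement with a
  Newton–Raphson MLE at λ = 0.
* CV path fits run at the solver's default tolerance on a sparse copy of
  the design (they only *rank* λ values); the final fit at the chosen λ is
  converged tightly (thresh 1e-14). glmnet's internal weighted
  standardization is numerically identical to the package's (weighted
  mean 0, variance 1 with denominator n), which the equivalence is keyed
  on.
* The log-partition term log(1 + e^η) is evaluated through a sign branch
  and never overflows.
* Zero-variance columns pass through fitting with coefficient 0 rather
  than producing NaNs from a zero scale.
* Printed log-likelihood displays in some descriptions of this family of
  models split the sum over the two outcome classes; the package
  implements the standard Bernoulli form, to which that split is
  algebraically equal.
* Sorting ties (equal coefficient magnitudes) are broken by original
  column order (stable radix sort); among tied *leaders* of a selection,
  an `uncategorized` variable never defines the dropped theme while a
  categorized one is available.
* `uncategorized` is excluded from new-theme accounting (it denotes the
  *absence* of a theme); its variables still count as new variables, so a
  round selecting only uncategorizable novelty does not stop the loop
  by rule (a).
* Degenerate inputs are explicit, never silent: no lasso survivors, a
  knee at position 1, or an unknee-able curve all mark the round
  degenerate and stop the run with `degenerate_selection`.

## Missing data and encoding

The encoder resolves missingness by an explicit indicator level per
variable (`var=<missing>`), preserving n — survey skip patterns make
listwise deletion destructive. One-hot coding drops each variable's first
level as reference (k − 1 columns) to avoid perfect collinearity; full
k-column coding is available for sensitivity checks. "Don't know" codes
are not special-cased: if the source data distinguishes them they arrive
as ordinary levels, otherwise as missing — flagged here rather than
guessed. Within a construct measured by several variables, the canonical
member is metadata-driven (a human decision), not automatic.

## Problem sizes used in the shipped checks

The benchmark calibration, the three-round AUC-floor check and the
acceptance script run at the full emulated scale (n = 19,468, ~1,000
columns). The ten-seed theme-recovery sweep runs a one-third-scale
replicate (n = 6,000, 250 noise columns, themes/effects/correlation/
prevalence unchanged) — chosen once as the smallest scale at which the
selection behaviour is representative, and stated here as the package's
own test design. Unit and property tests use purpose-built fixtures of
tens-to-hundreds of rows with independently computed expected values
(direct summation, exhaustive pair enumeration, Newton–Raphson,
max-distance-to-chord, bivariate-normal quadrature).

## Known limitations

* The pipeline is exploratory and correlational; nothing here supports
  causal or even adjusted-association interpretation of a selected theme.
* No inference (standard errors, selective-inference corrections) on
  penalized coefficients; the knee point is a heuristic cut, not a test.
* Theme quality is bounded by the coder: with file-driven assignments the
  package checks coverage and agreement, not sense.
* Weighted metrics treat the test split as a weighted subsample; no
  finite-population or design-effect corrections are applied.
* The `max_coefficient_theme` drop removes only variables coded in the
  current selection, so a theme can recur in later rounds as deeper block
  members surface — by design, mirroring the iterative protocol, but it
  means "rounds" do not partition variables by theme.
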