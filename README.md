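# itascreen

Iterative thematic analysis (ITA) for rare binary outcomes in
high-dimensional survey data.

## The problem

Large household surveys such as the Demographic and Health Surveys (DHS)
record thousands of variables per respondent, and outcomes of public-health
interest — here, whether a woman who has experienced intimate partner
violence (IPV) ever sought help, and whether she sought it from a formal
institution (police, lawyer, doctor, social services) — are rare (~14% and
~1% of respondents respectively). Hypothesis-generating analyses in this
setting need a principled way to sift a few interpretable groups of
correlates out of several thousand encoded indicator columns without
pretending that a single sparse model tells the whole story: once the
dominant correlates are removed, the next tier of correlates becomes
visible, and so on.

ITA combines penalized regression with qualitative coding to do exactly
that. Each round:

1. **Lasso screen.** A survey-weighted L1-penalized logistic regression,
   with λ chosen by 5-fold cross-validated held-out log-likelihood,
   shrinks the coefficients of noise variables to exactly zero; those
   variables are dropped.
2. **Ridge refit.** A survey-weighted L2-penalized logistic regression on
   the survivors (λ again by 5-fold CV) produces a stable coefficient
   ranking.
3. **Knee selection.** The coefficient magnitudes are sorted from high to
   low and the Kneedle algorithm locates the knee of the curve — the point
   where it "becomes flat". Variables above the knee are the round's
   selection.
4. **Theme coding.** The selected variables are coded into topical themes
   (by humans in a real analysis, via assignment files; by the generator's
   ground-truth map in automated runs). Inter-coder agreement is the
   percentage of variables coded identically.
5. **Theme removal.** The theme containing the maximum-coefficient
   variable is dropped from the data and the next round begins.

The loop stops when no new themes appear for three consecutive rounds, or a
round contributes no new variables. Each round's ridge model is scored on a
fixed held-out 20% test set with AUC and the balanced error rate
BER = 1 − (sensitivity + specificity)/2, the metrics of choice for
imbalanced outcomes.

The objective maximized by both penalized fits is the weighted Bernoulli
log-likelihood (weights w\_i normalized to mean 1, so the scale is the
effective sample size),

    l(θ) = Σᵢ wᵢ [ yᵢ ηᵢ − log(1 + exp(ηᵢ)) ] − λ P(θ),
    ηᵢ = θ₀ + Xᵢ θ,   P(θ) = ‖θ‖₁ (lasso)  or  ‖θ‖₂² (ridge),

with columns standardized to weighted mean 0 / variance 1 and the
intercept unpenalized.

Because the original DHS individual recode is access-restricted, the
package ships a calibrated synthetic generator that reproduces the
*structure* of the input — 19,468 respondents, ~1,000 encoded columns of
which 30 form six correlated "themes" of 5 binary variables (latent
equicorrelated Gaussian blocks, within-block correlation 0.3, log-odds
effects in [0.5, 1.2]), log-normal sampling weights, and an outcome
prevalence calibrated by bisection to 14.4% (any-source) or 1.0%
(formal) — together with the ground-truth theme map, so every pipeline
stage is testable end to end.

## Worked example

```r
library(itascreen)

spec <- synthetic_spec(n = 6000, p_noise = 250, seed = 1)
sim  <- synth_generate(spec)
sim$data
#> <encoded_dataset> 6000 respondents x 280 columns, prevalence 0.147, weight range [0.0992, 4.66]

res <- run_ita(sim$data, ita_config(seed = 1),
               truth_coder(sim$truth$theme_map))
res
#> <ita_result> 4 rounds, 6 themes, 33 variables selected, stopped: no_new_variables
#> <ita_round 1> 280 vars -> 126 survivors -> 18 selected; 6 new themes; drop 'theme_E'; AUC 0.934
#> <ita_round 2> 277 vars -> 105 survivors -> 12 selected; 0 new themes; drop 'theme_A'; AUC 0.915
#> <ita_round 3> 274 vars -> 107 survivors -> 27 selected; 0 new themes; drop 'theme_A'; AUC 0.882
#> <ita_round 4> 272 vars -> 89 survivors -> 7 selected; 0 new themes; drop 'theme_F'; AUC 0.844

mean(sim$truth$signal_vars %in% res$all_selected)
#> [1] 0.9666667
```

Reading the output: round 1 lasso-screens 280 columns down to 126, the
knee of the ridge coefficient curve selects 18 variables, and the
ground-truth coder recognizes all six planted themes among them; the theme
holding the largest coefficient (`theme_E`) is removed before round 2.
Round 4 selects only variables already seen, so the loop stops
(`no_new_variables`). Held-out AUC decays from 0.934 to 0.844 as
successively weaker theme tiers carry the prediction, and the union of
selections recovers 97% of the planted signal variables.
`round_table(res)`, `theme_table(res)` and `write_report(res, dir)` expose
the full audit trail (JSON/CSV/markdown).

For a file-based analysis with human coders, see `read_table()` /
`one_hot_encode()` for the typed survey-table pathway and `file_coder()`
for per-round theme-assignment files; the scripts under `analysis/`
(`01_simulate.R` … `04_agreement.R`) walk the whole workflow and write
their tables under `results/`.

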