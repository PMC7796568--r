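---
title: "Delta-adjusted chained-equations imputation for form-missing questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-adjusted chained-equations imputation for form-missing questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltami)
```

## The model

Let `Y` be an `n x J` table of mixed-type patient variables with missing
entries. `deltami` partitions the missingness indicator into two disjoint
matrices: `R^I` flags *item-missing* cells (an unanswered question inside an
otherwise returned questionnaire) and `R^F` flags *form-missing* cells (the
patient's entire follow-up questionnaire is absent — possible only at
follow-up, never at baseline). The working assumptions are

- item missingness is MAR: `f(Y_mis | Y_obs, R^I, R^F) = f(Y_mis | Y_obs)`
  for cells in `R^I`;
- form missingness may be MNAR: for the flagged endpoints the posterior
  predictive distribution of a form-missing value differs from that of an
  observed-pattern value by a location shift `k` in the direction of worse
  health.

This is a pattern-mixture formulation: rather than modelling *why* forms go
missing (a selection model), we assert *how different* the missing values
are, and vary that difference over a grid of scenarios. The shift parameter
is not estimable from the data — that is the point; it encodes an external
assumption whose influence the sensitivity analysis measures.

### The chained-equations algorithm

For each incomplete `Y_j` a univariate conditional regression
`f(Y_j | Y_-j, θ_j)` is specified by type: linear for continuous scores,
logistic for binary factors, multinomial logistic for unordered factors with
more than two levels, proportional odds for ordered factors. One chain
performs:

0. initialise every missing cell by a draw from the variable's empirical
   marginal distribution;
1. for each incomplete variable (ascending missing count): draw `θ̂_j` from
   the posterior given the target's observed values and the current
   completed predictors;
2. draw imputations for all the variable's missing cells from the posterior
   predictive;
3. if the variable is a flagged endpoint and a shift scenario is active, add
   `shift_sign × k` to the draws that land on form-missing cells (only
   those), clipping to the declared range.

Steps 1–3 sweep all incomplete variables and are iterated `n_iter` times
(default 100, matching common chained-equations practice of a fixed budget
rather than a convergence test); the whole chain is repeated `M` times.
Because step 3 happens inside the sweep, shifted values feed the *other*
variables' conditional models at the next iteration, so the assumed MNAR
departure propagates coherently instead of being a post-hoc correction of
the final draws. This in-sweep placement is the package's core design
commitment; with zero form-missing cells it reduces *bit-for-bit* to the
plain MAR algorithm at equal seed, which the test suite asserts literally.

### Parameter draws

The linear family uses the exact conjugate posterior under the
noninformative prior: `σ² | y ~ RSS / χ²(n-p)` and
`β | σ² ~ N(β̂, σ²(X'X)⁻¹)`. The categorical families use the standard
chained-equations approximation — maximum likelihood plus one multivariate
normal perturbation with the asymptotic covariance; after perturbing a
proportional-odds fit the cutpoints are re-sorted to keep them ordered.
Designs that separate or go singular are refitted with a small ridge penalty
and a logged warning; targets with fewer observed cases than `p + 2` fall
back to an empirical-marginal draw. The multinomial fitter is implemented in
the package (Newton–Raphson with the analytic block Hessian) because no
multinomial backend is guaranteed in the dependency footprint; it is tested
against a direct `optim` oracle on the same likelihood.

### Predictor preselection

With ~120 candidate predictors and 30–40% missingness, full conditionals are
ill-posed, so each incomplete variable gets a one-predictor AIC screen: all
variables are completed once from their marginals, each candidate is
regressed against the target's observed values alone, and the 15 smallest
AIC values win. The reading "each candidate fitted alone" (rather than a
subset search) is the literal interpretation of screening *each variable on
each of the other variables*; ties break by schema column order for
reproducibility. The selected set is unioned with the four forced
covariates (gender, age, cancer type, WHO performance status), so at most
`15 + 4` predictors enter a model. Candidates with more than 50%
missingness remain eligible — their marginal completion is used — because
the procedure imposes no cap.

## Shift scenarios and their parameters

Two shift families define the scenario grid, always in the direction of
*worse* health (subtracted for quality of life, physical and emotional
functioning; added for pain, dyspnoea and fatigue):

- **constant** (`k1`–`k4`): the equispaced values in `(0, IQR/2]` of the
  endpoint's observed follow-up distribution. The labelling is descending —
  `k1 = IQR/2`, `k2 = 3·IQR/8`, `k3 = IQR/4`, `k4 = IQR/8` — so `k1` is the
  most severe scenario. The source description ("equispaced values between 0
  and half the interquartile range") does not fix the labels or whether the
  endpoints of the interval are included; this convention reproduces the
  reported qualitative ordering in which `k1` departs farthest from MAR and
  excludes the trivial `k = 0`, which is just MAR. Quantiles use R's default
  type-7 definition (documented so the brute-force test oracle can match it
  exactly).
- **WHO-dependent** (`kwho`): `k_i = WHO_i × sd(Y_j,obs) / 4`, where
  `WHO_i ∈ {0,1,2,3}` is the patient's performance status (chained-imputed
  value if missing) and `sd(Y_j,obs)` is the sample standard deviation of
  the endpoint's observed follow-up values, computed once before imputation.
  The formula's "sd" is read as a standard deviation, not a standard error
  of the mean: only the former produces shifts on the scale of the reported
  scenario means (an SEM-based shift would be ~20× smaller and
  indistinguishable from MAR).

Shifted draws are clipped to the declared `[0, 100]` range and clips are
counted in the run metadata; the boundary behaviour of the original
procedure is unstated, and clipping is the only choice that keeps the
imputations inside the instrument's scale.

`M` defaults to `ceiling(max per-variable % missing)` — the rule of thumb
that sets `M ≈ 40` at ~39% missingness — and 90% intervals are the default
(`alpha = 0.10`), chosen upstream to discourage reading them as 5% tests.

## Pooling

Per-imputation statistics are computed on each completed dataset and then
combined (never the reverse): `Q̄ = Σ Q̂_m / M`, `U = Σ Û_m / M`,
`B = Σ(Q̂_m − Q̄)²/(M−1)`, `T = U + (1 + 1/M)B`, with the classic Rubin
degrees of freedom `ν = (M−1)(1 + U/((1+1/M)B))²` (the small-sample
Barnard–Rubin correction is deliberately not used, matching the source's
citation of the classic rule; with `B = 0` the normal quantile applies). A
mean's within-imputation variance is `s²/n` (subgroup `n` for
gender-stratified means). Correlations are pooled on the Fisher-z scale with
variance `1/(n−3)` and back-transformed — the standard variance-stabilised
choice; the source does not state its transform.

## The synthetic cohort

No public dataset accompanies the motivating study (its records are
available only on request), so every stage is exercised against a generator
with known ground truth. Each patient carries a standard-normal latent
health factor `h` (higher = healthier); follow-up health is an AR(1) update
(`ρ = 0.8`). A score is
`mean + sd × (λ·(±h) + ω·ψ + τ·ε)` with loading `λ = 0.6` on health
(positive for functioning scores, negative for symptoms), a score-specific
stable component `ω = 0.55` (so baseline–follow-up correlations land near
0.6, typical of quality-of-life test–retest values), and transient noise;
values are truncated to `[0, 100]`. Default moments follow the descriptive
table of the motivating cohort (e.g. follow-up quality of life 64.2 (21.8),
pain 20.7 (25.2)); gender differences arise from a latent-health advantage
of 0.5 SD for males, WHO status is an ordinal cut of a latent correlated
0.6 with poor health, and the default cohort size is 487 with 35% missing
forms and 1–5% missing items — the reported structure.

Missing *forms* are drawn per patient by one of three mechanisms: MCAR
(constant probability), MAR (logistic in the observed baseline score), or
MNAR (logistic in the unobserved follow-up health, slope `δ`); the logistic
intercept is calibrated by root-finding so the realized marginal rate hits
the configured probability. Independently, `form_shift` applies a generative
*pattern* effect: form-missers' true endpoint values are moved `δ` points in
the worsening direction before truncation. The pattern knob is the exact
generative counterpart of the constant-delta imputation model, which is what
makes calibrated recovery tests possible (impute with `k = δ` and the truth
must come back); the selection knob produces MNAR bias whose size is *not*
`δ` but follows from the logistic selection — both are provided because they
answer different testing questions.

What a green test does not establish: the generator's scores are truncated
normals on a common latent factor — real questionnaire scores are discrete,
skewed, and multidimensional; form-missingness in the field mixes health
deterioration with administrative loss; and treatment arms, clustering and
death are deliberately absent (out of scope). Green recovery tests certify
the imputation machinery against its own stated world, not the realism of
that world.

### Numerical choices in the tests

The recovery and shift-algebra acceptance checks (unbiasedness under MCAR,
CI coverage, `mean departure = shift_sign·k·f`, `k = δ` recovery) use scores
placed mid-scale (means 50–55, sd 15–18) instead of the cohort-scaled
moments. This was decided analytically before the tests were first run: with
follow-up quality of life at 64 (21.8), about 4% of the mass truncates at
100, which perturbs means by a few tenths of a point — the same order as
the Monte-Carlo tolerances — so boundary artifacts would confound the
mechanism under test. Mid-scale scores push truncation below 0.5% and make
the algebraic identities hold to the stated tolerances. Structural checks
(bit-level reduction to MAR, scenario monotonicity) keep cohort-scaled
moments, where truncation is harmless because clipping is monotone.

## Degenerate inputs and edge policies

- A variable with zero observed values cannot be imputed (no marginal
  exists): hard error naming the variable.
- Zero observed IQR collapses all constant shifts to 0 with a warning.
- An explicit form indicator takes precedence over the all-follow-up-missing
  inference rule, with a warning on conflict; partially filled follow-up
  forms are item-missing under the inference rule (the literal
  all-or-nothing reading of a "completely missing" form).
- WHO codes for the `kwho` shift use the numeric face value of the level
  labels (0–3), falling back to 0-based positions for non-numeric labels.
- Scenario failures inside `run_scenarios` are caught and reported; the
  remaining scenarios still run.

## Known limitations

- The NARFCS-style variant (missingness indicators as covariates in every
  conditional model) is out of scope, as are tree-based imputation models,
  cluster/treatment-arm structure, and truncation by death.
- The AIC screen scores candidates one at a time, so jointly informative but
  marginally weak predictors can be missed; this mirrors the source
  procedure rather than improving on it.
- Classic Rubin df can be optimistic at small `M` with large missing-data
  fractions; switch to 90% normal-approximation intervals is not provided —
  the df formula is the documented, deliberate choice.
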