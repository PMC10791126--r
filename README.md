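# bayesvas

Bayesian analysis tools for prospective two-group pre/post studies whose
outcomes are bounded 0–100 visual-analog-scale (VAS) ratings and
region-of-interest (ROI) fMRI signal time courses — the design used to ask
whether an intervention (for example, two weeks of violent-video-game play)
changes empathy-related behavior and brain responses.

Ratings on a bounded scale pile up at the endpoints, so the package models
them with a **hierarchical censored (Tobit) regression**: for subject *s*
and trial *i*,

    y*_si = x_si' β + z_si' b_s + ε_si,   ε_si ~ N(0, σ_s²)
    y_si  = min(max(y*_si, 0), 100)

with ±1-coded design factors (Group, Session, Intensity, … and all
interactions) in `x`, per-subject random effects `b_s ~ MVN(0, Σ)` for the
within-subject terms, and a *per-subject* residual SD σ_s. Observations at
a bound contribute the Normal tail probability beyond it rather than a
point density. Around this core the package provides:

- **Bayes-factor hypothesis tests** — Savage–Dickey density ratios for
  point nulls on coefficients, sign-restricted (one-sided) variants via
  posterior/prior mass ratios, and the default JZS two-sample *t*-test
  Bayes factor (Cauchy prior on the standardized effect, scale √2/2) by
  numerical integration; evidence categories use the conventional BF > 3
  / BF < 1/3 thresholds, boundaries inclusive.
- **Test–retest reliability** from random-effect variance components:
  ρ = (σ²_bI − σ²_bI:S) / √[(σ²_bI + σ²_bI:S − 2rσσ)(σ²_bI + σ²_bI:S + 2rσσ)],
  applied per posterior draw; neural reliability as the cross-session
  correlation of subject-level contrast effects.
- **Design analysis** — exact noncentral-F power for the within–between
  ANOVA interaction (f = d/2, λ = f²·N·m/(1−ρ)), a required-N search, and
  Monte-Carlo Bayes-factor design analysis (BFDA) over effect-size ×
  reliability grids.
- A **simplified hierarchical ROI model**: canonical double-gamma HRF,
  event-to-design-matrix construction, per-run GLM amplitudes, and a
  second level with group structure and session-specific subject effects.
- **Synthetic-data generators** for every input, so the full pipeline runs
  and is testable without any external data.

## Worked example

Simulate a small two-session empathy rating study, fit the censored model,
and test the focal Group×Session×Intensity interaction:

```r
library(bayesvas)

cfg <- study_config(n_control = 12, n_experimental = 12,
                    ratings_per_cell = 4, seed = 1)
ratings <- generate_empathy_ratings(cfg)

fit <- fit_posterior(ratings, model_spec(),
                     sampler_config(chains = 2, adapt = 500,
                                    warmup = 500, draws = 2000, seed = 1))
fit
#> Censored rating model fit: 4000 draws (2 chains), 24 subjects
#>   max split-R-hat (fixed effects): 1.0005
#>                      term       beta    ci_low   ci_high
#> 1               intercept 49.1160384 44.575095 53.532751
#> 2                   group  2.7827103 -1.591318  7.252927
#> 3                 session  0.9081846 -1.822556  3.574195
#> 4               intensity 25.8901063 21.973154 29.669714
#> 5           group:session -0.8328311 -3.620338  1.988355
#> 6         group:intensity  1.5400001 -2.257675  5.307048
#> 7       session:intensity -0.5638992 -3.382082  2.310094
#> 8 group:session:intensity -0.8584291 -3.722537  1.918911

coef_bf(fit, "group:session:intensity", "negative")
#> Bayes factor (BF10): 0.2479
#>   method: sign_restricted, direction: negative, evidence: H0

reliability_from_fit(fit)
#> Test-retest reliability (behavioral): rho = 0.320, 95% CrI [-0.052, 0.630]
```

The generative intensity effect here is 27.86 rating points; because the
factors are ±1-coded, that is a `condition_difference(27.86) = 55.72`-point
gap between painful and non-painful trials, and the fit recovers it
(posterior mean 25.9, CrI [22.0, 29.7]). The simulated data are null for
the three-way interaction, and the one-sided Bayes factor of 0.25 correctly
favors the null.

Summary-statistic group comparisons and design analysis:

```r
t <- summary_t(1.93, 0.43, 83, 2.01, 0.51, 132)   # t = -1.188
jzs_ttest_bf(t, 83, 132, direction = "positive")
#> Bayes factor (BF10): 0.07416
#>   method: jzs_t, direction: positive, evidence: H0

interaction_power(d = 0.3, n_total = 90, rho = 0.5)  # 0.804
required_n(0.3, 0.8, 0.5)                            # 90

bfda(d = 0.3, rho = 0.9, n_reps = 2000, seed = 42)
#> BFDA (d = 0.30, rho = 0.90, n = 44/45, 2000 reps)
#>   P(inconclusive) = 0.134, P(H0) = 0.005, P(H1) = 0.861
```

`run_pipeline(run_config(out_dir = "out"))` chains the stages
(simulate → fit → Bayes factors → reliability → power → BFDA → report) and
writes TSV tables plus a JSON manifest with content hashes.

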