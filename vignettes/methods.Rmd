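---
title: "Models and methods behind bayesvas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bayesvas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bayesvas` implements the statistical machinery of a prospective two-group
pre/post study of empathy: hierarchical censored regression of bounded
rating scales, Bayes-factor hypothesis tests, variance-component
test–retest reliability, ANOVA interaction power, Monte-Carlo Bayes-factor
design analysis, and a simplified hierarchical model for ROI fMRI time
courses. This vignette documents the models, their assumptions, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The censored rating model

Ratings are given on a 0–100 visual analog scale. Participants cannot
respond below 0 or above 100, so observed endpoint ratings are bounded
versions of a latent continuous response. The model is a hierarchical
Tobit regression:

$$y^*_{si} = \mathbf{x}_{si}'\boldsymbol\beta + \mathbf{z}_{si}'\mathbf{b}_s + \varepsilon_{si},
\qquad \varepsilon_{si} \sim N(0, \sigma_s^2),$$

with $y = \min(\max(y^*, 0), 100)$. All design factors are coded −1/1
(Group, Session, Intensity for the empathy task; Group, Content, Context
for the reactivity task), and the fixed effects comprise the intercept,
all main effects and all interactions. Random effects $\mathbf{b}_s \sim
\mathrm{MVN}(0, \Sigma)$ cover the within-subject terms (intercept,
Session, Intensity, Session:Intensity), with a full correlation matrix —
the correlation between the Intensity and Session:Intensity effects is
what the reliability estimator consumes. Each subject has their own
residual SD $\sigma_s$, reflecting how differently participants use the
rating scale.

In the likelihood (`censored_loglik()`), interior observations contribute
a Normal density; observations at a bound contribute the tail probability
beyond that bound. Ratings *exactly* at 0 or 100 are always treated as
censored — there is no "observed boundary" dialect, since a response at
the endpoint carries exactly the information that the latent value lies at
or beyond it.

### Estimation

`fit_posterior()` samples the joint posterior with JAGS (via `rjags`),
with the `glm` module loaded so the Gaussian linear substructure is
block-sampled; this raises the effective sample size of the fixed effects
from a few dozen to essentially the nominal draw count on typical data.
Censored observations are handled by interval data augmentation: the
latent response beyond the bound is sampled alongside the parameters,
which targets exactly the posterior implied by the tail-probability
likelihood. The direct tail-probability likelihood is implemented and
tested independently (against numerical quadrature) and serves as the
package's analytic definition of the model; the augmented sampler is the
estimation route because it keeps the model conjugate for block updates.

Convergence is checked with split-$\widehat{R}$ on every fixed effect
(each chain split in half, between/within variance ratio); the fit fails
loudly above 1.01 by default (`sampler_config(rhat_action=)` can demote
this to a warning for quick exploratory fits). Effective sample sizes are
reported per fixed effect.

### Priors

The published study formulated informed priors, but their exact values are
not part of the running text, so the package states its own defaults and
exposes every scale (`prior_spec()`), because Savage–Dickey Bayes factors
depend on them directly:

- effect coefficients: Normal(0, 10) rating points — sized so that
  plausible condition differences (up to ±40 points across two levels)
  are well covered without being diffuse;
- intercept: Normal(50, 50) — centered mid-scale, weakly informative;
- per-subject residual SDs: half-Normal(0, 20);
- random-effect covariance: Wishart prior on the precision matrix. JAGS
  has no LKJ prior, so the correlation-concentration parameter $c$ maps to
  Wishart degrees of freedom $K - 1 + 2c$ ($c = 1$ gives near-uniform
  marginal correlations; the default $c = 2$ mildly favors moderate
  correlations), and the scale matrix is calibrated so the prior mean of
  each random-effect variance is `re_sd_scale`² (default 20²).

`fit_posterior(prior_only = TRUE)` returns draws from exactly this prior,
used in the tests to confirm prior recovery.

## Bayes factors

Three test families are implemented:

- **Savage–Dickey** (`savage_dickey_bf()`): for a point null nested in the
  unrestricted model, $\mathrm{BF}_{10} = p(\beta = 0 \mid \text{prior}) /
  p(\beta = 0 \mid \text{posterior})$. The posterior density at zero is
  estimated from the draws by a Normal moment fit (coefficient posteriors
  in these models are near-Gaussian); a kernel estimate is always computed
  alongside and reported in the result so disagreement is visible. When
  the posterior has moved so far from zero that the density underflows,
  the result is flagged as a lower bound rather than reported as a clean
  number.
- **Sign-restricted** (`sign_restricted_bf()`): the alternative restricts
  the coefficient to one sign. By the chain rule through the unrestricted
  model, the BF against the point null is the posterior/prior mass ratio
  on that side times the Savage–Dickey BF. The original analyses computed
  these by bridge sampling; the mass-ratio route needs only a single fit
  and is exact in the same limit.
- **JZS t-test** (`jzs_ttest_bf()`): the default Bayesian two-sample
  t-test — Cauchy prior with scale √2/2 on the standardized effect,
  marginal likelihood of the observed $t$ integrated numerically over the
  noncentral-$t$ likelihood. One-sided versions truncate and renormalize
  the prior. The integrand is evaluated in log space and anchored at its
  approximate mode before quadrature, so extreme $t$ values (|t| > 30)
  remain stable. The test suite checks this route against an independent
  quadrature of the equivalent $g$-mixture representation to 10⁻⁴.

Evidence categories follow the BF > 3 / BF < 1/3 convention with the
closed interval [1/3, 3] inclusive counting as inconclusive; the
thresholds are arguments, not constants.

## Test–retest reliability

With Session coded −1/1, a subject's condition effect is
$b_I - b_{I:S}$ in session 1 and $b_I + b_{I:S}$ in session 2, so the
test–retest correlation of the condition effect is

$$\rho = \frac{\sigma_{b_I}^2 - \sigma_{b_{I:S}}^2}
{\sqrt{(\sigma_{b_I}^2 + \sigma_{b_{I:S}}^2 - 2r\sigma_{b_I}\sigma_{b_{I:S}})
       (\sigma_{b_I}^2 + \sigma_{b_{I:S}}^2 + 2r\sigma_{b_I}\sigma_{b_{I:S}})}}.$$

This is the correlation form of $\mathrm{Cov}(b_I - b_{I:S},\, b_I +
b_{I:S})$ expanded by bilinearity (the covariance-over-variances display
is read with the minus sign in its first argument, which the parameter
form makes unambiguous). `reliability_from_fit()` evaluates the formula
*per posterior draw* and summarizes, so the reported interval carries the
full posterior uncertainty of the variance components rather than a
point-estimate plug-in. Neural reliability is the cross-session
correlation of subject-level contrast effects — either computed per draw
from two effect matrices (`neural_reliability()`) or read off directly as
the bivariate random-effect correlation parameter of the ROI model.

## Design analysis

**Power** (`interaction_power()`): exact noncentral-F power for the
group-by-time interaction in a 2×2 within–between ANOVA, with the
repeated-measures convention of the standard power software: Cohen's
$f = d/2$, noncentrality $\lambda = f^2 N m/(1-\rho)$, $df_1 =
(g-1)(m-1)$, $df_2 = (N-g)(m-1)$. With $d = 0.3$, $\rho = 0.5$,
$\alpha = 0.05$ the required-N search returns 90. One reproduction detail:
the published achieved-power values match at three decimals when Cohen's
$f$ is rounded to three decimals before entering the routine (as one types
it into the power software), computed from the unrounded $d$ implied by
the meta-analytic correlations $r = 0.170/0.194/0.217$; the function
itself is exact and also accepts `f` directly.

**BFDA** (`bfda()`): for each replicate, a dataset of the study's size
(n = 44/45) is simulated, the one-sided JZS BF computed, and the outcome
classified as H1 (BF > 3), H0 (BF < 1/3) or inconclusive. The generative
model is deliberately simple and documented rather than guessed from the
original code: each subject contributes a pre/post pair, bivariate Normal
with unit marginal SD and correlation ρ, and the true effect $d$ is a mean
shift on the *raw post score* of the experimental group. The analysis then
runs on change scores, so the standardized change-score effect is
$d/\sqrt{2(1-\rho)}$ — this is what makes high reliability amplify
(ρ = 0.9) and zero reliability dampen (ρ = 0) the same raw effect, the
pattern the published design-analysis table shows. Single-session
scenarios draw one measurement per subject with a raw shift of $d$ and
test the raw scores. The simulation is subject-level: trial-level noise is
already absorbed into the per-subject summaries, which matches how the
BF t-test consumes the data. Whether the original analysis used exactly
this construction is not stated in the text; agreement with the published
table (checked in the acceptance suite at ±0.03 with 2,000 replicates, and
by `scripts/acceptance.R` at 10,000) is the empirical validation.

## The ROI model

The fMRI side operates on extracted ROI time courses, never on images.
`build_design_matrix()` builds one regressor per trial type: event boxcars
on a microtime grid (default 16 bins per TR), convolved with the canonical
double-gamma HRF (peak at ~5 s, undershoot ratio 1/6, unit peak), sampled
at volume onsets, plus a discrete-cosine high-pass drift basis (cutoff
128 s) and an intercept. Convolution is FFT-based and tested against a
direct-summation oracle to 10⁻¹⁰.

`fit_roi_hierarchical()` is a two-level summary-statistics model, a
documented simplification of a joint time-course model:

1. per run (subject × session), OLS yields amplitude estimates and
   standard errors for the condition regressors;
2. the two amplitudes of interest (e.g. Other Pain, Other No Pain) enter a
   Bayesian measurement-error model: fixed effects for Group, Session,
   Intensity and all interactions; a subject random intercept; a
   *session-specific* subject random effect on the intensity contrast,
   bivariate Normal across sessions — its correlation is exactly the
   neural test–retest reliability; and a residual term. Stage-1 standard
   errors enter as known observation noise.

Observation noise within a run is white Gaussian; the residual term at
level two absorbs run-level variation not captured by the design. Default
prior scales are 5 (fixed effects) and 1 (variance components) in units of
the ROI signal, sized for amplitudes of order one.

## Synthetic data: what it emulates, what it does not

The generators reproduce the statistical structure the models assume:
censored VAS ratings with correlated subject random effects and
log-normally distributed per-subject residual SDs (strictly positive,
heavy-ish tail), two-session designs with the experimental factors fully
crossed, correlated pre/post subject summaries, and HRF-shaped ROI
signals with jittered event timing (2 s cues, 3–7 s jitter, 0.5/1 s
stimulation, rating epochs after half of the trials). Default effect
sizes are the published posterior means (e.g. intensity 27.86, content
37.08), sample sizes 44/45, 8 ratings per cell for the empathy task
(16 trials per condition, rated after half) and 4 blocks per condition for
the reactivity task; the mid-scale intercept of 50 and the random-effect
SDs (10/3/10/3) and residual scale (log-normal around 8) are the package's
own choices of realistic magnitudes, stated once here and not tuned. A
random intercept is included even though only the within-subject slopes
enter the reliability formula, because between-subject spread in overall
scale use is a robust feature of rating data.

Not emulated: sequential trial effects, drift in scale use across a
session, physiological confounds and motion in the ROI signals, dropout,
and any systematic relation between a subject's residual SD and their
random effects. Passing tests therefore show that the estimators are
correct and calibrated *under the model's own assumptions*, not that real
data meet those assumptions.

Seeding: every generator takes one master seed; subject-level child seeds
are derived from it, so per-subject streams are stable. `bfda()` and
`bfda_grid()` derive independent child seeds per cell.

## Numerical choices and degenerate inputs

- JZS integration: log-space integrand anchored at its mode, 500
  subdivisions, relative tolerance 10⁻⁸; integration failure raises an
  error rather than returning a number.
- Savage–Dickey density at zero: Normal moment fit by default, kernel
  estimate always reported alongside; underflow yields a flagged
  lower-bound result. Fewer than 4,000 draws triggers a warning.
- Sign restriction with zero posterior mass on the restricted side
  reports the mass as 1/(draws+1) and flags the result.
- `behavioral_reliability()` errors on a zero denominator (no random
  variation in a session effect) instead of returning 0/0.
- Evidence thresholds are inclusive: BF = 3 and BF = 1/3 are
  "inconclusive".
- The rank-deficiency check in `roi_glm()` names the collinear columns.
- `required_n()` scans even totals (equal groups) from the smallest
  admissible size; saturation returns that minimum.

## Interpreting coded effects

Under −1/1 coding a coefficient β corresponds to a difference of 2β
points between the two levels of a factor, and that is what
`condition_difference()` returns — matching the printed interpretation of
both the intensity effect (2·27.86 = 55.72) and the three-way interaction
(reported as a 2β double difference). Note that strict contrast algebra
for a double difference across three ±1-coded factors would give 8β; the
package keeps the 2β reading for comparability and exposes
`contrast_estimate()` for explicit weighted contrasts when the algebraic
quantity is wanted.

## Problem sizes used in the test suite

The simulation tests run at sizes chosen to make the checks sharp but the
suite quick to re-run: moment checks at ~2,000 trials with 3·SE bands;
posterior calibration (coverage and rank uniformity) over 100 refits of a
12-subject, 2-ratings-per-cell design with parameters drawn from the
model prior; BFDA reproduction at 2,000 replicates per cell (±0.03); the
ROI null-calibration and detection checks at 10–12 subjects over 12 and 6
replicates. The acceptance script uses 10,000 BFDA replicates per cell,
the replicate count of the original design analysis.

## Known limitations

- The rating model's priors are the package's defaults, not the original
  informed priors; Bayes factors on real data will differ under other
  prior scales (which is why all scales are exposed).
- The Wishart correlation prior is an approximation to an LKJ shape; with
  four random-effect terms and weak data the implied marginal correlation
  prior is not flat.
- The ROI model is a two-stage summary-statistics approximation to a
  joint hierarchical time-course model and ignores temporal
  autocorrelation (an AR(1) option would sharpen stage-1 standard errors
  on real data).
- Savage–Dickey with the Normal density fit assumes near-Gaussian
  coefficient posteriors; for strongly skewed posteriors the kernel
  estimate, reported alongside, is the better guide.
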