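# Bayes-factor hypothesis tests: Savage-Dickey density ratios on posterior
# draws, sign-restricted (one-sided) variants, and the default JZS t-test
# Bayes factor computed by numerical integration.

#' Evidence categories for a Bayes factor
#'
#' Classifies a Bayes factor BF10 using the conventional thresholds:
#' BF10 > 3 is evidence for the alternative (`"H1"`), BF10 < 1/3 evidence for
#' the null (`"H0"`), and anything in the closed interval `[1/3, 3]` is
#' `"inconclusive"` (boundaries inclusive).
#'
#' @param bf10 Positive numeric vector of Bayes factors (alternative over
#'   null).
#' @param lower,upper Evidence thresholds; defaults 1/3 and 3.
#' @return Character vector in `{"H1", "H0", "inconclusive"}`.
#' @examples
#' categorize_bf(c(0.13, 3, 10))
#' @export
categorize_bf <- function(bf10, lower = 1 / 3, upper = 3) {
  if (any(is.na(bf10)) || any(bf10 <= 0))
    stop("`bf10` must be positive")
  ifelse(bf10 > upper, "H1", ifelse(bf10 < lower, "H0", "inconclusive"))
}

new_bf_result <- function(bf10, direction, method, lower_bound = FALSE,
                          details = list()) {
  structure(
    c(list(bf10 = bf10, direction = direction, method = method,
           category = categorize_bf(bf10), lower_bound = lower_bound),
      details),
    class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("Bayes factor (BF10): %.4g%s\n", x$bf10,
              if (isTRUE(x$lower_bound)) " (lower bound)" else ""))
  cat(sprintf("  method: %s, direction: %s, evidence: %s\n",
              x$method, x$direction, x$category))
  invisible(x)
}

#' Pooled-variance two-sample t statistic from summary statistics
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return The t statistic `(mean1 - mean2) / (s_p * sqrt(1/n1 + 1/n2))`
#'   with the pooled standard deviation `s_p`.
#' @examples
#' summary_t(1.93, 0.43, 83, 2.01, 0.51, 132)
#' @export
summary_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
}

# Log marginal likelihood of t under a Cauchy(0, scale) prior on the
# standardized effect delta, optionally truncated to one sign. The integrand
# is the noncentral-t density at the observed t with ncp = delta * n_eff,
# weighted by the (renormalized) prior. Integration is carried out relative
# to the integrand value at the approximate mode for numerical stability.
jzs_log_marginal <- function(t, df, n_eff, scale, direction) {
  logf <- function(delta) {
    suppressWarnings(dt(t, df = df, ncp = delta * n_eff, log = TRUE)) +
      dcauchy(delta, 0, scale, log = TRUE)
  }
  delta_hat <- t / n_eff
  anchor <- switch(direction,
    two_sided = delta_hat,
    positive  = max(delta_hat, 0),
    negative  = min(delta_hat, 0))
  log_f0 <- logf(anchor)
  g <- function(delta) exp(logf(delta) - log_f0)
  quad <- function(lo, hi) integrate(g, lo, hi, rel.tol = 1e-8,
                                     abs.tol = 0, subdivisions = 500L,
                                     stop.on.error = FALSE)
  res <- switch(direction,
    two_sided = quad(-Inf, Inf),
    positive  = quad(0, Inf),
    negative  = quad(-Inf, 0))
  if (!res$message %in% c("OK", "roundoff error was detected"))
    stop("JZS integration failed: ", res$message)
  log_mass <- if (direction == "two_sided") 0 else log(2) # prior renormalization
  log_f0 + log(res$value) + log_mass
}

#' Default JZS two-sample t-test Bayes factor
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor for a two-sample design
#' by numerical integration: a Cauchy prior with the given `scale` is placed
#' on the standardized effect size, and the marginal likelihood of the
#' observed t statistic under the alternative is divided by its likelihood
#' under the point null. One-sided tests truncate (and renormalize) the
#' Cauchy prior to the requested sign. The default scale `sqrt(2)/2` is the
#' conventional "medium" prior width.
#'
#' @param t Observed two-sample t statistic (group 1 minus group 2 in the
#'   numerator; see [summary_t()]).
#' @param n1,n2 Group sample sizes.
#' @param scale Cauchy prior scale on the standardized effect.
#' @param direction `"two_sided"`, `"positive"` or `"negative"`; the sign
#'   refers to the standardized effect in the orientation of `t`.
#' @return A `bf_result` with elements `bf10`, `direction`, `method`,
#'   `category`.
#' @examples
#' jzs_ttest_bf(-1.189, n1 = 83, n2 = 132, direction = "positive")
#' @export
jzs_ttest_bf <- function(t, n1, n2, scale = sqrt(2) / 2,
                         direction = c("two_sided", "positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(t), n1 >= 2, n2 >= 2, scale > 0)
  df <- n1 + n2 - 2
  n_eff <- sqrt(n1 * n2 / (n1 + n2))
  log_m1 <- jzs_log_marginal(t, df, n_eff, scale, direction)
  log_m0 <- dt(t, df = df, log = TRUE)
  new_bf_result(exp(log_m1 - log_m0), direction, "jzs_t",
                details = list(t = t, n1 = n1, n2 = n2, scale = scale))
}

#' Prior specifications for coefficient-level Bayes factors
#'
#' Helpers describing the prior of a single coefficient by its density at
#' zero and its mass on each sign, the two quantities needed by
#' [savage_dickey_bf()] and [sign_restricted_bf()].
#'
#' @param mean,sd Mean and standard deviation of a Normal prior.
#' @return A list with `density0`, `mass_negative`, `mass_positive`.
#' @export
normal_prior <- function(mean = 0, sd) {
  stopifnot(sd > 0)
  list(density0 = dnorm(0, mean, sd),
       mass_negative = pnorm(0, mean, sd),
       mass_positive = pnorm(0, mean, sd, lower.tail = FALSE))
}

#' @rdname normal_prior
#' @param location,scale Location and scale of a Cauchy prior.
#' @export
cauchy_prior <- function(location = 0, scale) {
  stopifnot(scale > 0)
  list(density0 = dcauchy(0, location, scale),
       mass_negative = pcauchy(0, location, scale),
       mass_positive = pcauchy(0, location, scale, lower.tail = FALSE))
}

posterior_density0 <- function(draws, method) {
  if (method == "normal") {
    dnorm(0, mean(draws), sd(draws))
  } else {
    d <- density(draws, n = 2048,
                 from = min(0, min(draws)) - sd(draws),
                 to = max(0, max(draws)) + sd(draws))
    stats::approx(d$x, d$y, xout = 0, rule = 2)$y
  }
}

#' Savage-Dickey Bayes factor for a point null on one coefficient
#'
#' For a point null nested in the unrestricted model, the Bayes factor in
#' favor of the unrestricted model equals the ratio of the prior to the
#' posterior density of the coefficient at zero (Savage-Dickey identity).
#' The posterior density at zero is estimated from the draws, by default
#' with a Normal moment fit (coefficient posteriors are near-Gaussian), and
#' a kernel estimate is always computed alongside for comparison.
#'
#' @param draws Numeric vector of posterior draws of one coefficient.
#' @param prior Prior description as returned by [normal_prior()] or
#'   [cauchy_prior()] (only `density0` is used here).
#' @param density_method `"normal"` (default) or `"kernel"` estimator for
#'   the posterior density at zero.
#' @return A `bf_result`; `details` carry both density estimates. When the
#'   posterior density at zero underflows, `bf10` is a lower bound and
#'   `lower_bound` is `TRUE`.
#' @export
savage_dickey_bf <- function(draws, prior,
                             density_method = c("normal", "kernel")) {
  density_method <- match.arg(density_method)
  draws <- draws[is.finite(draws)]
  if (length(draws) < 4000)
    warning("fewer than 4000 draws; Savage-Dickey density estimate at 0 ",
            "may be unstable")
  d_norm <- posterior_density0(draws, "normal")
  d_kern <- posterior_density0(draws, "kernel")
  post0 <- if (density_method == "normal") d_norm else d_kern
  lower_bound <- FALSE
  if (post0 < .Machine$double.xmin) {
    # posterior mass has moved too far from 0 for density estimation:
    # report a bounded estimate based on the smallest representable density
    post0 <- .Machine$double.xmin
    lower_bound <- TRUE
    warning("posterior density at 0 is numerically zero; ",
            "reporting a lower bound for bf10")
  }
  new_bf_result(prior$density0 / post0, "two_sided", "savage_dickey",
                lower_bound = lower_bound,
                details = list(density0_normal = d_norm,
                               density0_kernel = d_kern,
                               density_method = density_method))
}

#' Sign-restricted (one-sided) Bayes factor on one coefficient
#'
#' Compares a model in which the coefficient is restricted to one sign
#' against the point-null model. By the chain rule through the unrestricted
#' model, this equals the ratio of posterior to prior mass on the restricted
#' side times the Savage-Dickey point-null Bayes factor.
#'
#' @inheritParams savage_dickey_bf
#' @param direction `"negative"` or `"positive"`: the sign the alternative
#'   restricts the coefficient to.
#' @return A `bf_result` with `method = "sign_restricted"`.
#' @export
sign_restricted_bf <- function(draws, prior,
                               direction = c("negative", "positive"),
                               density_method = c("normal", "kernel")) {
  direction <- match.arg(direction)
  density_method <- match.arg(density_method)
  draws <- draws[is.finite(draws)]
  sd_bf <- savage_dickey_bf(draws, prior, density_method)
  post_mass <- if (direction == "negative") mean(draws < 0) else mean(draws > 0)
  prior_mass <- if (direction == "negative") prior$mass_negative else
    prior$mass_positive
  if (prior_mass <= 0)
    stop("prior places no mass on the restricted side")
  lower_bound <- sd_bf$lower_bound
  if (post_mass == 0) {
    # no draws on the restricted side: bound the mass from below
    post_mass <- 1 / (length(draws) + 1)
    lower_bound <- TRUE
    warning("no posterior draws on the restricted side; ",
            "reporting a lower-bound estimate")
  }
  new_bf_result(post_mass / prior_mass * sd_bf$bf10, direction,
                "sign_restricted", lower_bound = lower_bound,
                details = list(posterior_mass = post_mass,
                               prior_mass = prior_mass,
                               savage_dickey_bf10 = sd_bf$bf10))
}
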