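# Independent oracles used across tests. These deliberately take different
# computational routes than the package implementation.

# JZS two-sample Bayes factor via the g-prior mixture representation:
# Cauchy(0, r) on the standardized effect is an inverse-gamma(1/2, r^2/2)
# scale mixture of normals; the marginal likelihood ratio then reduces to
# a one-dimensional integral over g. Two-sided only.
jzs_bf_g_oracle <- function(t, n1, n2, r = sqrt(2) / 2) {
  v <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  dinvgamma <- function(g, a, b) b^a / gamma(a) * g^(-a - 1) * exp(-b / g)
  num <- integrate(function(g) {
    (1 + n_eff * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n_eff * g) * v))^(-(v + 1) / 2) *
      dinvgamma(g, 1 / 2, r^2 / 2)
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / v)^(-(v + 1) / 2)
  num / den
}

# Direct O(n m) summation convolution of a neural vector with a kernel.
naive_convolve <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq_len(min(i, length(kernel)))
    out[i] <- sum(x[i - js + 1] * kernel[js])
  }
  out
}

# Marginal likelihood of one observation y ~ N(theta, sigma) under a
# Normal(mu0, sd0) prior restricted to theta < 0 (renormalized), by
# quadrature. Used as the brute-force oracle for sign-restricted BFs.
truncated_marginal_oracle <- function(y, sigma, mu0, sd0,
                                      side = c("negative", "positive")) {
  side <- match.arg(side)
  mass <- if (side == "negative") pnorm(0, mu0, sd0) else
    pnorm(0, mu0, sd0, lower.tail = FALSE)
  f <- function(th) dnorm(y, th, sigma) * dnorm(th, mu0, sd0) / mass
  if (side == "negative") integrate(f, -Inf, 0, rel.tol = 1e-10)$value
  else integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# Tail probability of a Normal by quadrature (censored-likelihood oracle).
normal_tail_quadrature <- function(bound, mu, sigma, upper = TRUE) {
  if (upper) {
    integrate(function(x) dnorm(x, mu, sigma), bound, Inf,
              rel.tol = 1e-12, abs.tol = 1e-300)$value
  } else {
    integrate(function(x) dnorm(x, mu, sigma), -Inf, bound,
              rel.tol = 1e-12, abs.tol = 1e-300)$value
  }
}

# A small, well-behaved rating config used by several tests: modest random
# effects and residual noise so that censoring is rare unless forced.
quiet_config <- function(n_per_group = 6, ratings_per_cell = 2, seed = 1,
                         effects = NULL) {
  fe <- c(intercept = 50, group = 0, session = 0, intensity = 20,
          "group:session" = 0, "group:intensity" = 0,
          "session:intensity" = 0, "group:session:intensity" = 0)
  if (!is.null(effects)) fe[names(effects)] <- effects
  study_config(n_control = n_per_group, n_experimental = n_per_group,
               ratings_per_cell = ratings_per_cell,
               fixed_effects = fe,
               re_sd = c(intercept = 4, session = 1.5, intensity = 4,
                         "session:intensity" = 1.5),
               sigma_meanlog = log(4), sigma_sdlog = 0.2, seed = seed)
}

fast_sampler <- function(chains = 2, draws = 600, seed = 1,
                         rhat_action = "warn", ...) {
  sampler_config(chains = chains, adapt = 300, warmup = 300, draws = draws,
                 seed = seed, rhat_action = rhat_action, ...)
}
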