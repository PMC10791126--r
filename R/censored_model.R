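# Hierarchical Bayesian censored (Tobit) regression for bounded VAS
# ratings: direct tail-probability log-likelihood, MCMC fitting through
# JAGS (censoring via interval data augmentation), and posterior summaries.

#' Prior specification of the censored rating model
#'
#' All scales are in rating units. Effect coefficients get Normal(0,
#' `beta_scale`) priors; the intercept gets Normal(`intercept_location`,
#' `intercept_scale`). Random-effect SDs are governed by the scale matrix
#' of a Wishart prior on the random-effect precision matrix, calibrated so
#' that the prior mean of each random-effect variance is `re_sd_scale^2`;
#' `re_corr_concentration` c maps to Wishart degrees of freedom
#' `K - 1 + 2c` (c = 1 gives near-uniform marginal correlations). Residual
#' SDs are half-Normal(0, `sigma_scale`) per subject.
#'
#' These priors matter: the Savage-Dickey Bayes factors of
#' [savage_dickey_bf()] are ratios of prior to posterior density, so the
#' prior scale of a coefficient is part of the hypothesis test.
#'
#' @param beta_scale SD of the Normal prior on non-intercept effects.
#' @param intercept_location,intercept_scale Normal prior of the intercept.
#' @param re_sd_scale Prior scale of random-effect SDs.
#' @param re_corr_concentration Concentration of the random-effect
#'   correlation prior (>= 1).
#' @param sigma_scale Half-Normal scale of per-subject residual SDs.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(beta_scale = 10, intercept_location = 50,
                       intercept_scale = 50, re_sd_scale = 20,
                       re_corr_concentration = 2, sigma_scale = 20) {
  stopifnot(beta_scale > 0, intercept_scale > 0, re_sd_scale > 0,
            re_corr_concentration >= 1, sigma_scale > 0)
  structure(list(beta_scale = beta_scale,
                 intercept_location = intercept_location,
                 intercept_scale = intercept_scale,
                 re_sd_scale = re_sd_scale,
                 re_corr_concentration = re_corr_concentration,
                 sigma_scale = sigma_scale),
            class = "prior_spec")
}

all_interaction_terms <- function(factors) {
  terms <- "intercept"
  for (k in seq_along(factors))
    terms <- c(terms, apply(utils::combn(factors, k), 2, paste,
                            collapse = ":"))
  terms
}

#' Model specification of the censored rating regression
#'
#' Fixed effects are the intercept plus all main effects and interactions
#' of the -1/1-coded `factors` (in the conventional table ordering: main
#' effects, two-way, three-way). Random (per-subject) terms must be
#' within-subject, i.e. not involve the between-subject factor.
#'
#' @param factors Character vector of coded factors, the first being the
#'   between-subject group factor. Default: the empathy design
#'   `c("group", "session", "intensity")`.
#' @param random_terms Per-subject random-effect terms (include
#'   `"intercept"`).
#' @param bounds Censoring bounds of the rating scale.
#' @param priors A [prior_spec()].
#' @return A `model_spec` list with the expanded `fixed_terms`.
#' @export
model_spec <- function(factors = c("group", "session", "intensity"),
                       random_terms = c("intercept", "session", "intensity",
                                        "session:intensity"),
                       bounds = c(0, 100), priors = prior_spec()) {
  stopifnot(length(factors) >= 1, bounds[1] < bounds[2])
  fixed_terms <- all_interaction_terms(factors)
  between <- factors[1]
  bad <- random_terms[vapply(strsplit(random_terms, ":", fixed = TRUE),
                             function(p) between %in% p, logical(1))]
  if (length(bad))
    stop("between-subject terms cannot be random: ",
         paste(bad, collapse = ", "))
  if (!all(random_terms %in% c("intercept", fixed_terms)))
    stop("unknown random term(s)")
  structure(list(factors = factors, fixed_terms = fixed_terms,
                 random_terms = random_terms, bounds = bounds,
                 priors = priors),
            class = "model_spec")
}

# Fixed- and random-effect design matrices from a trial table.
spec_design <- function(data, spec) {
  need <- c("subject_id", spec$factors, "rating")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cell <- data[spec$factors]
  list(x = design_row(cell, cell$group, spec$fixed_terms, spec$factors),
       z = design_row(cell, cell$group, spec$random_terms, spec$factors))
}

#' Censored Gaussian log-likelihood of a trial table
#'
#' Direct tail-probability likelihood of the hierarchical censored
#' regression at fixed parameter values: interior ratings contribute a
#' Normal log-density with the subject's residual SD; ratings at a bound
#' contribute the log tail probability beyond that bound. Ratings exactly
#' at a bound are always treated as censored.
#'
#' @param params List with `beta` (named by fixed term), `b` (subjects x
#'   random terms matrix, rows named by subject id) and `sigma` (per
#'   subject, named).
#' @param data Trial table (see [generate_empathy_ratings()]).
#' @param spec A [model_spec()].
#' @return The total log-likelihood (scalar).
#' @export
censored_loglik <- function(params, data, spec) {
  d <- spec_design(data, spec)
  if (!identical(names(params$beta), spec$fixed_terms))
    stop("`params$beta` must be named by the spec's fixed terms")
  low <- spec$bounds[1]; high <- spec$bounds[2]
  if (any(data$rating < low | data$rating > high))
    stop("ratings outside the censoring bounds")
  sid <- as.character(data$subject_id)
  b <- params$b[sid, , drop = FALSE]
  mu <- drop(d$x %*% params$beta) + rowSums(d$z * b)
  sigma <- params$sigma[sid]
  ll <- ifelse(
    data$rating <= low,
    pnorm(low, mu, sigma, log.p = TRUE),
    ifelse(data$rating >= high,
           pnorm(high, mu, sigma, lower.tail = FALSE, log.p = TRUE),
           dnorm(data$rating, mu, sigma, log = TRUE)))
  sum(ll)
}

#' Sampler configuration for [fit_posterior()]
#'
#' @param chains,adapt,warmup,draws MCMC chain settings.
#' @param thin Thinning interval.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param rhat_tol Split-R-hat threshold checked on every fixed effect.
#' @param rhat_action `"error"` (default, fail loudly), `"warn"`, or
#'   `"none"`.
#' @param monitor_ranef Monitor per-subject random effects (needed for
#'   reliability and cross-task correlations).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(chains = 4, adapt = 500, warmup = 1000,
                           draws = 1000, thin = 1, seed = 1L,
                           rhat_tol = 1.01,
                           rhat_action = c("error", "warn", "none"),
                           monitor_ranef = TRUE) {
  structure(list(chains = chains, adapt = adapt, warmup = warmup,
                 draws = draws, thin = thin, seed = as.integer(seed),
                 rhat_tol = rhat_tol,
                 rhat_action = match.arg(rhat_action),
                 monitor_ranef = monitor_ranef),
            class = "sampler_config")
}

jags_model_string <- function() {
  "model {
  for (n in 1:N) {
    cens[n] ~ dinterval(y[n], lim[1:2])
    y[n] ~ dnorm(mu[n], prec_s[subj[n]])
    mu[n] <- inprod(X[n, ], beta[]) + inprod(Z[n, ], b[subj[n], ])
  }
  for (p in 1:P) {
    beta[p] ~ dnorm(beta_mean[p], beta_prec[p])
  }
  for (s in 1:S) {
    b[s, 1:K] ~ dmnorm(zero[1:K], Omega[1:K, 1:K])
    sigma_s[s] ~ dnorm(0, sigma_prec) T(0, )
    prec_s[s] <- pow(sigma_s[s], -2)
  }
  Omega[1:K, 1:K] ~ dwish(Rmat[1:K, 1:K], wish_df)
  Sigma_b[1:K, 1:K] <- inverse(Omega[, ])
  for (k in 1:K) {
    sd_b[k] <- sqrt(Sigma_b[k, k])
  }
  for (k1 in 1:K) {
    for (k2 in 1:K) {
      corr_b[k1, k2] <- Sigma_b[k1, k2] / (sd_b[k1] * sd_b[k2])
    }
  }
}"
}

# Split-R-hat of one parameter: each chain is split in half and the usual
# between/within variance ratio is computed over the resulting sequences.
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the hierarchical censored regression by MCMC
#'
#' Samples the joint posterior of the censored rating model: fixed effects
#' for all coded terms, correlated per-subject random effects, per-subject
#' residual SDs. Censored observations are handled by interval data
#' augmentation (the latent rating beyond the bound is sampled alongside
#' the parameters), which targets the same posterior as the direct
#' tail-probability likelihood of [censored_loglik()]. Convergence is
#' checked with split-R-hat on every fixed effect and the fit fails loudly
#' (configurable) when any exceeds `sampler$rhat_tol`.
#'
#' @param data Trial table with columns `subject_id`, the coded factors of
#'   `spec`, `rating` (and optionally `censored`; censoring is re-derived
#'   from the bounds, ratings exactly at a bound are always censored).
#' @param spec A [model_spec()].
#' @param sampler A [sampler_config()].
#' @param prior_only If `TRUE`, return draws from the prior instead (no
#'   data enter; useful for prior-recovery checks and as the reference
#'   distribution of Savage-Dickey tests).
#' @return A `vas_fit` object: `draws` (list of per-chain matrices with
#'   labelled columns), `spec`, `diagnostics` (split-R-hat and effective
#'   sample size per fixed effect), `subjects`.
#' @export
fit_posterior <- function(data, spec, sampler = sampler_config(),
                          prior_only = FALSE) {
  if (prior_only)
    return(prior_fit(spec, sampler))
  need2 <- tapply(data$rating, data$subject_id, length)
  if (any(need2 < 2)) stop("every subject needs observations in >= 2 cells")
  if (any(!is.finite(data$rating))) stop("non-finite ratings")
  gr <- tapply(data$group, data$subject_id, function(g) length(unique(g)))
  if (any(gr != 1)) stop("`group` must be constant within subject")
  if (length(unique(data$group)) < 2 &&
      "group" %in% unlist(strsplit(spec$fixed_terms, ":")))
    warning("only one group present; group terms are unidentified")

  d <- spec_design(data, spec)
  subj <- factor(data$subject_id)
  s_levels <- levels(subj)
  low <- spec$bounds[1]; high <- spec$bounds[2]
  y <- data$rating
  cens <- ifelse(y <= low, 0L, ifelse(y >= high, 2L, 1L))
  y_obs <- ifelse(cens == 1L, y, NA_real_)
  p <- spec$priors
  k <- length(spec$random_terms)
  np <- length(spec$fixed_terms)
  wish_df <- k - 1 + 2 * p$re_corr_concentration
  beta_mean <- ifelse(spec$fixed_terms == "intercept",
                      p$intercept_location, 0)
  beta_sd <- ifelse(spec$fixed_terms == "intercept",
                    p$intercept_scale, p$beta_scale)
  jdata <- list(
    N = nrow(data), P = np, S = length(s_levels), K = k,
    y = y_obs, cens = cens, lim = c(low, high),
    X = unname(d$x), Z = unname(d$z), subj = as.integer(subj),
    zero = rep(0, k),
    beta_mean = beta_mean, beta_prec = 1 / beta_sd^2,
    sigma_prec = 1 / p$sigma_scale^2,
    Rmat = diag(p$re_sd_scale^2 * max(wish_df - k - 1, 1), k),
    wish_df = wish_df)
  y_init <- ifelse(cens == 0L, low - 1, ifelse(cens == 2L, high + 1,
                                               NA_real_))
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    list(y = y_init,
         beta = beta_mean + rnorm(np, 0, 0.1),
         sigma_s = rep(max(sd(y), 1), length(s_levels)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed + ch)
  })
  set.seed(sampler$seed)
  monitors <- c("beta", "sd_b", "corr_b", "sigma_s",
                if (sampler$monitor_ranef) "b")
  rjags::load.module("glm", quiet = TRUE) # block-samples the linear part
  jm <- rjags::jags.model(textConnection(jags_model_string()), data = jdata,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = sampler$adapt, quiet = TRUE)
  update(jm, sampler$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = sampler$draws,
                              thin = sampler$thin, progress.bar = "none")
  fit <- new_vas_fit(samp, spec, s_levels)
  fit$diagnostics <- fit_diagnostics(fit, sampler)
  fit
}

new_vas_fit <- function(coda_samples, spec, subjects) {
  draws <- lapply(coda_samples, function(ch) {
    m <- as.matrix(ch)
    colnames(m) <- relabel_params(colnames(m), spec, subjects)
    m
  })
  structure(list(draws = draws, spec = spec, subjects = subjects),
            class = "vas_fit")
}

relabel_params <- function(nm, spec, subjects) {
  ft <- spec$fixed_terms; rt <- spec$random_terms
  out <- nm
  for (i in seq_along(nm)) {
    n <- nm[i]
    if (grepl("^beta\\[", n)) {
      out[i] <- paste0("beta:", ft[as.integer(gsub("\\D", "", n))])
    } else if (grepl("^sd_b\\[", n)) {
      out[i] <- paste0("sd_b:", rt[as.integer(gsub("\\D", "", n))])
    } else if (grepl("^sigma_s\\[", n)) {
      out[i] <- paste0("sigma:", subjects[as.integer(gsub("\\D", "", n))])
    } else if (grepl("^corr_b\\[", n)) {
      ij <- as.integer(strsplit(gsub("corr_b\\[|\\]", "", n),
                                ",")[[1]])
      out[i] <- paste0("corr_b:", rt[ij[1]], "|", rt[ij[2]])
    } else if (grepl("^b\\[", n)) {
      ij <- as.integer(strsplit(gsub("b\\[|\\]", "", n), ",")[[1]])
      out[i] <- paste0("b:", rt[ij[2]], ":", subjects[ij[1]])
    }
  }
  out
}

fit_diagnostics <- function(fit, sampler) {
  ft <- fit$spec$fixed_terms
  rhat <- vapply(ft, function(tm) {
    split_rhat(lapply(fit$draws, function(m) m[, paste0("beta:", tm)]))
  }, numeric(1))
  ess <- vapply(ft, function(tm) {
    sum(vapply(fit$draws, function(m)
      unname(coda::effectiveSize(m[, paste0("beta:", tm)])), numeric(1)))
  }, numeric(1))
  bad <- rhat > sampler$rhat_tol
  if (any(bad)) {
    msg <- paste0("split-R-hat above ", sampler$rhat_tol, " for: ",
                  paste(ft[bad], collapse = ", "),
                  " (max ", round(max(rhat), 4), ")")
    if (sampler$rhat_action == "error") stop(msg)
    if (sampler$rhat_action == "warn") warning(msg)
  }
  list(rhat = rhat, ess = ess)
}

# Draws from the prior, shaped like a one-chain fit. Used for
# prior-recovery checks and prior-predictive reasoning.
prior_fit <- function(spec, sampler = sampler_config()) {
  p <- spec$priors
  k <- length(spec$random_terms)
  n <- sampler$draws * sampler$chains
  set.seed(sampler$seed)
  wish_df <- k - 1 + 2 * p$re_corr_concentration
  rmat <- diag(p$re_sd_scale^2 * max(wish_df - k - 1, 1), k)
  cols <- list()
  for (tm in spec$fixed_terms) {
    mu <- if (tm == "intercept") p$intercept_location else 0
    sc <- if (tm == "intercept") p$intercept_scale else p$beta_scale
    cols[[paste0("beta:", tm)]] <- rnorm(n, mu, sc)
  }
  sds <- matrix(NA_real_, n, k)
  cors <- array(NA_real_, c(n, k, k))
  om <- stats::rWishart(n, wish_df, solve(rmat))
  for (i in seq_len(n)) {
    sig <- solve(om[, , i])
    s <- sqrt(diag(sig))
    sds[i, ] <- s
    cors[i, , ] <- sig / tcrossprod(s)
  }
  for (j in seq_len(k))
    cols[[paste0("sd_b:", spec$random_terms[j])]] <- sds[, j]
  for (j1 in seq_len(k)) for (j2 in seq_len(k))
    cols[[paste0("corr_b:", spec$random_terms[j1], "|",
                 spec$random_terms[j2])]] <- cors[, j1, j2]
  m <- do.call(cbind, cols)
  structure(list(draws = list(m), spec = spec, subjects = character(0),
                 diagnostics = NULL, prior_only = TRUE),
            class = "vas_fit")
}

#' @export
print.vas_fit <- function(x, ...) {
  n <- sum(vapply(x$draws, nrow, integer(1)))
  cat(sprintf("Censored rating model fit: %d draws (%d chain%s), %d subjects\n",
              n, length(x$draws), if (length(x$draws) > 1) "s" else "",
              length(x$subjects)))
  if (!is.null(x$diagnostics))
    cat(sprintf("  max split-R-hat (fixed effects): %.4f\n",
                max(x$diagnostics$rhat)))
  print(summarize_fixed(x))
  invisible(x)
}

# Stacked draws (all chains) of one labelled parameter, or a matrix for a
# label prefix.
#' Extract posterior draws from a fit
#'
#' `fixed_draws()` returns the stacked draws of one fixed effect;
#' `re_sd_draws()` of a random-effect SD; `re_corr_draws()` of the
#' correlation between two random effects; `ranef_draws()` a draws-by-
#' subjects matrix of one random-effect term; `sigma_draws()` a draws-by-
#' subjects matrix of residual SDs.
#'
#' @param fit A `vas_fit` from [fit_posterior()].
#' @param term Term name (as in the model spec).
#' @return Numeric vector, or matrix with one column per subject.
#' @export
fixed_draws <- function(fit, term) stacked_column(fit, paste0("beta:", term))

#' @rdname fixed_draws
#' @export
re_sd_draws <- function(fit, term) stacked_column(fit, paste0("sd_b:", term))

#' @rdname fixed_draws
#' @param term2 Second term of the correlation.
#' @export
re_corr_draws <- function(fit, term, term2)
  stacked_column(fit, paste0("corr_b:", term, "|", term2))

#' @rdname fixed_draws
#' @export
ranef_draws <- function(fit, term) {
  cols <- paste0("b:", term, ":", fit$subjects)
  m <- do.call(rbind, lapply(fit$draws, function(d) d[, cols, drop = FALSE]))
  colnames(m) <- fit$subjects
  m
}

#' @rdname fixed_draws
#' @export
sigma_draws <- function(fit) {
  cols <- paste0("sigma:", fit$subjects)
  m <- do.call(rbind, lapply(fit$draws, function(d) d[, cols, drop = FALSE]))
  colnames(m) <- fit$subjects
  m
}

stacked_column <- function(fit, label) {
  if (!label %in% colnames(fit$draws[[1]]))
    stop("no such parameter: ", label)
  unlist(lapply(fit$draws, function(d) d[, label]), use.names = FALSE)
}

#' Posterior summaries of the fixed effects
#'
#' Posterior mean and central 95% credible interval per fixed term, in the
#' model-spec (table) ordering.
#'
#' @param x A `vas_fit`, or a draws matrix with one named column per term.
#' @param level Credible level (default 0.95).
#' @return A data.frame with columns `term`, `beta`, `ci_low`, `ci_high`.
#' @export
summarize_fixed <- function(x, level = 0.95) UseMethod("summarize_fixed")

#' @export
summarize_fixed.vas_fit <- function(x, level = 0.95) {
  m <- sapply(x$spec$fixed_terms, function(tm) fixed_draws(x, tm))
  summarize_fixed(m, level)
}

#' @export
summarize_fixed.matrix <- function(x, level = 0.95) {
  stopifnot(nrow(x) >= 1)
  a <- (1 - level) / 2
  data.frame(
    term = colnames(x),
    beta = colMeans(x),
    ci_low = apply(x, 2, quantile, probs = a, names = FALSE),
    ci_high = apply(x, 2, quantile, probs = 1 - a, names = FALSE),
    row.names = NULL)
}

#' Two-level condition difference implied by a coded effect
#'
#' Under -1/1 coding, a coefficient beta corresponds to a difference of
#' `2 * beta` rating points between the two levels of the factor.
#'
#' @param beta Coefficient(s) in rating units.
#' @return `2 * beta`.
#' @examples
#' condition_difference(27.86)
#' @export
condition_difference <- function(beta) {
  stopifnot(all(is.finite(beta)))
  2 * beta
}

#' Posterior summary of an arbitrary fixed-effect contrast
#'
#' Evaluates `sum(weights * beta)` per posterior draw and summarizes. Use
#' this for condition differences that involve several coded terms (for
#' example, a double difference across three factors).
#'
#' @param fit A `vas_fit`.
#' @param weights Named numeric vector; names are fixed terms.
#' @param level Credible level.
#' @return A one-row data.frame like [summarize_fixed()].
#' @export
contrast_estimate <- function(fit, weights, level = 0.95) {
  if (!all(names(weights) %in% fit$spec$fixed_terms))
    stop("unknown term(s) in `weights`")
  v <- rowSums(as.matrix(sapply(names(weights), function(tm)
    weights[[tm]] * fixed_draws(fit, tm))))
  a <- (1 - level) / 2
  data.frame(term = paste(names(weights), collapse = "+"),
             beta = mean(v),
             ci_low = quantile(v, a, names = FALSE),
             ci_high = quantile(v, 1 - a, names = FALSE))
}

#' Coefficient-level Bayes factor from a fit
#'
#' Convenience wrapper: runs [savage_dickey_bf()] or [sign_restricted_bf()]
#' on the draws of one fixed effect, using the model's own prior for that
#' term.
#'
#' @param fit A `vas_fit`.
#' @param term Fixed-effect term.
#' @param direction `"two_sided"`, `"negative"` or `"positive"`.
#' @return A `bf_result`.
#' @export
coef_bf <- function(fit, term,
                    direction = c("two_sided", "negative", "positive")) {
  direction <- match.arg(direction)
  p <- fit$spec$priors
  sc <- if (term == "intercept") p$intercept_scale else p$beta_scale
  mu <- if (term == "intercept") p$intercept_location else 0
  prior <- normal_prior(mu, sc)
  draws <- fixed_draws(fit, term)
  if (direction == "two_sided") savage_dickey_bf(draws, prior)
  else sign_restricted_bf(draws, prior, direction)
}
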