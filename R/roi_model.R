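# Simplified hierarchical model for ROI-averaged fMRI time courses:
# canonical double-gamma HRF, event-to-design-matrix construction with
# discrete-cosine drift, per-run GLM amplitude estimation, and a two-level
# Bayesian model on the condition amplitudes with session-specific subject
# effects (whose cross-session correlation is the neural reliability).

#' Canonical double-gamma HRF configuration
#'
#' @param peak_delay,undershoot_delay Delays of the response peak and the
#'   undershoot (seconds; gamma shape * scale).
#' @param peak_disp,undershoot_disp Dispersions (gamma scale, seconds).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param length Kernel length in seconds.
#' @return An `hrf_config` list.
#' @export
hrf_config <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       undershoot_ratio = 1 / 6, length = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, undershoot_ratio >= 0,
            length >= undershoot_delay)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 undershoot_ratio = undershoot_ratio, length = length),
            class = "hrf_config")
}

#' Sampled canonical HRF kernel
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' sampled at interval `dt` and scaled to unit peak.
#'
#' @param cfg An [hrf_config()].
#' @param dt Sampling interval in seconds (e.g. the TR, or a microtime
#'   resolution).
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
canonical_hrf <- function(cfg = hrf_config(), dt) {
  t <- seq(0, cfg$length, by = dt)
  h <- stats::dgamma(t, shape = cfg$peak_delay / cfg$peak_disp,
                     scale = cfg$peak_disp) -
    cfg$undershoot_ratio *
    stats::dgamma(t, shape = cfg$undershoot_delay / cfg$undershoot_disp,
                  scale = cfg$undershoot_disp)
  h / max(h)
}

dct_drift_basis <- function(n_scans, tr, cutoff) {
  if (!is.finite(cutoff)) return(NULL)
  order <- floor(2 * n_scans * tr / cutoff)
  if (order < 1) return(NULL)
  t <- seq_len(n_scans) - 0.5
  m <- sapply(seq_len(order), function(k)
    sqrt(2 / n_scans) * cos(pi * k * t / n_scans))
  m <- as.matrix(m)
  colnames(m) <- paste0("drift_", seq_len(order))
  m
}

#' Design matrix from an event table
#'
#' One column per `trial_type`: the event boxcar (impulse when duration is
#' zero) is built on a microtime grid, convolved with the HRF kernel, and
#' sampled at the scan times. Optional discrete-cosine drift columns
#' (high-pass cutoff in seconds) and an intercept column are appended.
#'
#' @param events Data.frame with `onset`, `duration` (seconds) and
#'   `trial_type`.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes.
#' @param hrf An [hrf_config()], or a numeric vector taken as the kernel
#'   already sampled on the microtime grid.
#' @param trial_types Condition set; events with a `trial_type` outside it
#'   are an error. Default: the types present, sorted.
#' @param oversample Microtime bins per TR.
#' @param drift_cutoff High-pass cutoff in seconds (`Inf` for none).
#' @param intercept Append a constant column.
#' @return Matrix `n_scans` x regressors with stable column names:
#'   condition columns in `trial_types` order, then `drift_k`, then
#'   `intercept`.
#' @export
build_design_matrix <- function(events, tr, n_scans, hrf = hrf_config(),
                                trial_types = NULL, oversample = 16,
                                drift_cutoff = 128, intercept = TRUE) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)),
            all(events$duration >= 0), n_scans >= 1, tr > 0)
  t_end <- n_scans * tr
  if (nrow(events) && any(events$onset + events$duration > t_end))
    stop("events extend past the end of the scan")
  if (is.null(trial_types)) {
    trial_types <- sort(unique(as.character(events$trial_type)))
  } else {
    unknown <- setdiff(unique(as.character(events$trial_type)), trial_types)
    if (length(unknown))
      stop("unknown trial_type(s): ", paste(unknown, collapse = ", "))
  }
  dt <- tr / oversample
  n_fine <- n_scans * oversample
  kernel <- if (inherits(hrf, "hrf_config")) canonical_hrf(hrf, dt) else
    as.numeric(hrf)
  scan_idx <- 1 + (seq_len(n_scans) - 1) * oversample # sample at volume onset
  cols <- lapply(trial_types, function(tt) {
    ev <- events[as.character(events$trial_type) == tt, , drop = FALSE]
    neural <- numeric(n_fine)
    for (i in seq_len(nrow(ev))) {
      from <- floor(ev$onset[i] / dt) + 1
      to <- if (ev$duration[i] > 0)
        min(ceiling((ev$onset[i] + ev$duration[i]) / dt), n_fine) else from
      neural[from:to] <- 1
    }
    conv <- stats::convolve(neural, rev(kernel), type = "open")
    conv[scan_idx]
  })
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n_scans, ncol = 0)
  colnames(x) <- trial_types
  drift <- dct_drift_basis(n_scans, tr, drift_cutoff)
  if (!is.null(drift)) x <- cbind(x, drift)
  if (intercept) x <- cbind(x, intercept = 1)
  x
}

#' Per-run GLM amplitudes of ROI condition regressors
#'
#' Ordinary least squares of one ROI time course on the event design
#' matrix; returns the amplitude estimate and standard error of every
#' condition regressor. This is the first (within-run) level of the
#' hierarchical ROI model.
#'
#' @param values Numeric vector: the ROI signal, one value per volume.
#' @param events Event table for the run.
#' @param tr,hrf,drift_cutoff,oversample Passed to
#'   [build_design_matrix()].
#' @param conditions Condition regressors to report (default: all
#'   non-drift, non-intercept columns).
#' @return A data.frame with `condition`, `estimate`, `se`.
#' @export
roi_glm <- function(values, events, tr, hrf = hrf_config(),
                    drift_cutoff = 128, oversample = 16,
                    conditions = NULL) {
  x <- build_design_matrix(events, tr, length(values), hrf = hrf,
                           oversample = oversample,
                           drift_cutoff = drift_cutoff, intercept = TRUE)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(x, values)
  sigma2 <- sum(fit$residuals^2) / (length(values) - ncol(x))
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  if (is.null(conditions))
    conditions <- setdiff(colnames(x), c("intercept",
                                         grep("^drift_", colnames(x),
                                              value = TRUE)))
  data.frame(condition = conditions,
             estimate = unname(fit$coefficients[conditions]),
             se = unname(se[match(conditions, colnames(x))]),
             row.names = NULL)
}

roi_jags_model <- function() {
  "model {
  for (n in 1:N) {
    est[n] ~ dnorm(theta[n], prec_obs[n])
    prec_obs[n] <- pow(obs_se[n], -2) # stage-1 measurement variance
    theta[n] <- inprod(X[n, ], beta[]) + u0[subj[n]] +
      uI[subj[n], sess[n]] * intensity[n] + eps[n]
    eps[n] ~ dnorm(0, prec_eps)
  }
  for (p in 1:P) {
    beta[p] ~ dnorm(0, beta_prec)
  }
  for (s in 1:S) {
    u0[s] ~ dnorm(0, prec_u0)
    uI[s, 1:2] ~ dmnorm(zero2[1:2], OmegaI[1:2, 1:2])
  }
  OmegaI[1:2, 1:2] ~ dwish(RI[1:2, 1:2], 4)
  SigmaI[1:2, 1:2] <- inverse(OmegaI[, ])
  tau_i <- sqrt((SigmaI[1, 1] + SigmaI[2, 2]) / 2)
  rho_sessions <- SigmaI[1, 2] / sqrt(SigmaI[1, 1] * SigmaI[2, 2])
  tau_0 ~ dnorm(0, re_prec) T(0, )
  prec_u0 <- pow(tau_0, -2)
  sigma_eps ~ dnorm(0, re_prec) T(0, )
  prec_eps <- pow(sigma_eps, -2)
}"
}

#' Fit the two-level hierarchical ROI model
#'
#' Stage 1 estimates per-run condition amplitudes by GLM ([roi_glm()]).
#' Stage 2 models the amplitude estimates of the two condition levels
#' (e.g. Other Pain / Other No Pain) per subject and session with their
#' stage-1 standard errors as known measurement error:
#' fixed effects for Group, Session, Intensity and all interactions
#' (-1/1 coded), a subject random intercept, a session-specific subject
#' random effect on the intensity contrast (bivariate normal across
#' sessions -- its correlation `rho_sessions` is the neural test-retest
#' reliability), and a residual term.
#'
#' @param runs A list of run records, each a list with elements
#'   `subject_id`, `group` (-1/1), `session` (-1/1), `values` (ROI signal)
#'   and `events` (event table).
#' @param tr Repetition time in seconds.
#' @param conditions Character vector of length 2: the trial types of the
#'   negative (-1) and positive (+1) level of the intensity factor, in that
#'   order.
#' @param hrf,drift_cutoff,oversample Stage-1 settings; see [roi_glm()].
#' @param priors List with `beta_scale` and `re_scale` (half-Normal scale
#'   of variance components), in signal units.
#' @param sampler A [sampler_config()].
#' @return A `roi_fit` object: `draws` (per-chain labelled matrices),
#'   `subjects`, `stage1` (amplitude table), `conditions`, `diagnostics`.
#' @export
fit_roi_hierarchical <- function(runs, tr,
                                 conditions = c("stim_other_nopain",
                                                "stim_other_pain"),
                                 hrf = hrf_config(), drift_cutoff = 128,
                                 oversample = 16,
                                 priors = list(beta_scale = 5, re_scale = 1),
                                 sampler = sampler_config()) {
  stopifnot(length(conditions) == 2)
  stage1 <- do.call(rbind, lapply(runs, function(r) {
    g <- roi_glm(r$values, r$events, tr, hrf = hrf,
                 drift_cutoff = drift_cutoff, oversample = oversample)
    g <- g[g$condition %in% conditions, , drop = FALSE]
    if (nrow(g) != 2)
      stop("run lacks a condition regressor: subject ", r$subject_id)
    data.frame(subject_id = r$subject_id, group = r$group,
               session = r$session,
               intensity = ifelse(g$condition == conditions[2], 1, -1),
               estimate = g$estimate, se = g$se, row.names = NULL)
  }))
  subj <- factor(stage1$subject_id)
  sessions <- sort(unique(stage1$session))
  if (!identical(sessions, c(-1, 1)))
    stop("every subject needs runs in both sessions (coded -1/1)")
  per_subj <- tapply(stage1$session, stage1$subject_id,
                     function(s) length(unique(s)))
  if (any(per_subj != 2)) stop("every subject needs both sessions")
  fixed_terms <- all_interaction_terms(c("group", "session", "intensity"))
  x <- design_row(stage1[c("group", "session", "intensity")], stage1$group,
                  fixed_terms, c("group", "session", "intensity"))
  jdata <- list(
    N = nrow(stage1), P = length(fixed_terms),
    S = nlevels(subj),
    est = stage1$estimate, obs_se = stage1$se,
    X = unname(x), subj = as.integer(subj),
    sess = ifelse(stage1$session > 0, 2L, 1L),
    intensity = stage1$intensity,
    zero2 = c(0, 0),
    beta_prec = 1 / priors$beta_scale^2,
    re_prec = 1 / priors$re_scale^2,
    RI = diag(priors$re_scale^2, 2))
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    list(beta = rnorm(length(fixed_terms), 0, 0.1),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed + ch)
  })
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(roi_jags_model()), data = jdata,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = sampler$adapt, quiet = TRUE)
  update(jm, sampler$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, c("beta", "uI", "u0", "tau_0", "tau_i", "rho_sessions",
          "sigma_eps"),
    n.iter = sampler$draws, thin = sampler$thin, progress.bar = "none")
  s_levels <- levels(subj)
  draws <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    nm <- colnames(m)
    for (i in seq_along(nm)) {
      n <- nm[i]
      if (grepl("^beta\\[", n))
        nm[i] <- paste0("beta:", fixed_terms[as.integer(gsub("\\D", "", n))])
      else if (grepl("^u0\\[", n))
        nm[i] <- paste0("u0:", s_levels[as.integer(gsub("\\D", "", n))])
      else if (grepl("^uI\\[", n)) {
        ij <- as.integer(strsplit(gsub("uI\\[|\\]", "", n), ",")[[1]])
        nm[i] <- paste0("uI:session", ij[2], ":", s_levels[ij[1]])
      }
    }
    colnames(m) <- nm
    m
  })
  fit <- structure(list(draws = draws, subjects = s_levels,
                        fixed_terms = fixed_terms, stage1 = stage1,
                        conditions = conditions),
                   class = "roi_fit")
  rhat <- vapply(fixed_terms, function(tm)
    split_rhat(lapply(draws, function(m) m[, paste0("beta:", tm)])),
    numeric(1))
  bad <- rhat > sampler$rhat_tol
  if (any(bad)) {
    msg <- paste0("ROI model split-R-hat above ", sampler$rhat_tol,
                  " for: ", paste(fixed_terms[bad], collapse = ", "))
    if (sampler$rhat_action == "error") stop(msg)
    if (sampler$rhat_action == "warn") warning(msg)
  }
  fit$diagnostics <- list(rhat = rhat)
  fit
}

#' @export
print.roi_fit <- function(x, ...) {
  cat(sprintf("Hierarchical ROI fit: %d subjects, conditions %s vs %s\n",
              length(x$subjects), x$conditions[2], x$conditions[1]))
  print(roi_fixed_summary(x))
  invisible(x)
}

roi_stacked <- function(fit, label)
  unlist(lapply(fit$draws, function(d) d[, label]), use.names = FALSE)

#' @rdname fit_roi_hierarchical
#' @param fit A `roi_fit`.
#' @export
roi_fixed_summary <- function(fit) {
  m <- sapply(fit$fixed_terms, function(tm)
    roi_stacked(fit, paste0("beta:", tm)))
  summarize_fixed(m)
}

#' Session-specific subject intensity effects of an ROI fit
#'
#' Draws-by-subjects matrix of the subject-level intensity-contrast random
#' effect in one session; feed both sessions to [neural_reliability()]
#' (or read the model's `rho_sessions` parameter directly via
#' [roi_session_correlation()]).
#'
#' @param fit A `roi_fit`.
#' @param session 1 or 2.
#' @return Draws-by-subjects matrix.
#' @export
roi_session_effects <- function(fit, session) {
  stopifnot(session %in% c(1, 2))
  cols <- paste0("uI:session", session, ":", fit$subjects)
  m <- do.call(rbind, lapply(fit$draws,
                             function(d) d[, cols, drop = FALSE]))
  colnames(m) <- fit$subjects
  m
}

#' @rdname roi_session_effects
#' @export
roi_session_correlation <- function(fit)
  new_reliability_estimate(roi_stacked(fit, "rho_sessions"), "neural")

#' Posterior summary of the intensity condition contrast
#'
#' The mean amplitude difference between the positive and negative
#' condition level (e.g. Other Pain minus Other No Pain), which under the
#' -1/1 coding is `2 * beta_intensity` per draw.
#'
#' @param fit A `roi_fit`, or a draws matrix whose columns include the two
#'   amplitude terms named in `terms`.
#' @param terms For the matrix method: `c(positive, negative)` column
#'   names; the contrast is their per-draw difference.
#' @return A one-row data.frame `term`, `beta`, `ci_low`, `ci_high`.
#' @export
roi_contrast <- function(fit, terms = NULL) {
  v <- if (inherits(fit, "roi_fit")) {
    condition_difference(roi_stacked(fit, "beta:intensity"))
  } else {
    m <- as.matrix(fit)
    if (is.null(terms) || !all(terms %in% colnames(m)))
      stop("missing amplitude term(s)")
    m[, terms[1]] - m[, terms[2]]
  }
  data.frame(term = "pain - no pain", beta = mean(v),
             ci_low = quantile(v, 0.025, names = FALSE),
             ci_high = quantile(v, 0.975, names = FALSE))
}

#' One-sided Bayes factor on an ROI group-by-session-by-intensity effect
#'
#' Sign-restricted test of the `group:session:intensity` coefficient of a
#' fitted ROI model, against the point null, using the model's own Normal
#' prior for that coefficient.
#'
#' @param fit A `roi_fit`.
#' @param direction Restricted sign of the alternative.
#' @param beta_scale Prior scale used in the fit.
#' @return A `bf_result`.
#' @export
roi_interaction_bf <- function(fit, direction = "negative",
                               beta_scale = 5) {
  draws <- roi_stacked(fit, "beta:group:session:intensity")
  sign_restricted_bf(draws, normal_prior(0, beta_scale),
                     direction = direction)
}
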