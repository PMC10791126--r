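# HRF kernel, design-matrix construction, per-run GLM, and the two-level
# hierarchical ROI model.

simulate_roi_runs <- function(n_subj, three_way = 0, noise_sd = 0.6,
                              subj_sd = 0.2, n_trials = 16, n_scans = 220,
                              tr = 1.2, seed = 1) {
  set.seed(seed)
  runs <- list()
  for (s in seq_len(n_subj)) {
    g <- ifelse(s <= n_subj / 2, -1, 1)
    u <- rnorm(1, 0, subj_sd)
    for (sess in c(-1, 1)) {
      ev <- empathy_event_table(n_trials = n_trials,
                                seed = seed * 1000 + s * 10 + sess)
      # pain - nopain contrast of 0.6, modulated by the three-way effect
      half_gap <- 0.3 + three_way * g * sess / 2
      amps <- c(stim_other_pain = 0.7 + u + half_gap,
                stim_other_nopain = 0.7 + u - half_gap,
                stim_self_pain = 0.5, stim_self_nopain = 0.2,
                cue_other_pain = 0.3, cue_other_nopain = 0.3,
                cue_self_pain = 0.3, cue_self_nopain = 0.3, rating = 0.2)
      y <- generate_roi_timecourse(ev, amps, noise_sd = noise_sd, tr = tr,
                                   n_scans = n_scans,
                                   seed = seed * 2000 + s * 10 + sess)
      runs[[length(runs) + 1]] <- list(subject_id = sprintf("S%02d", s),
                                       group = g, session = sess,
                                       values = y, events = ev)
    }
  }
  runs
}

test_that("the canonical HRF peaks near 5 s with unit height", {
  h <- canonical_hrf(hrf_config(), dt = 0.01) # dense-grid evaluation
  expect_equal(max(h), 1)
  t_peak <- (which.max(h) - 1) * 0.01
  expect_lt(abs(t_peak - 5), 0.2)
  h_tr <- canonical_hrf(hrf_config(), dt = 1.2)
  expect_lt(abs((which.max(h_tr) - 1) * 1.2 - t_peak), 1.2)
  # no undershoot: a single gamma is nonnegative everywhere
  h_pos <- canonical_hrf(hrf_config(undershoot_ratio = 0), dt = 0.1)
  expect_true(all(h_pos >= 0))
  expect_true(any(h < 0)) # the default kernel does undershoot
})

test_that("design-matrix columns are HRF convolutions of the boxcars", {
  ev <- data.frame(onset = c(6, 30, 61), duration = c(2, 2, 1),
                   trial_type = c("a", "b", "a"))
  x <- build_design_matrix(ev, tr = 1, n_scans = 100, drift_cutoff = Inf,
                           intercept = FALSE)
  expect_identical(colnames(x), c("a", "b"))
  # identity kernel and an impulse event: the column is a shifted impulse
  ev_imp <- data.frame(onset = 12, duration = 0, trial_type = "a")
  xi <- build_design_matrix(ev_imp, tr = 1, n_scans = 30, hrf = 1,
                            oversample = 1, drift_cutoff = Inf,
                            intercept = FALSE)
  expect_equal(drop(xi), c(rep(0, 12), 1, rep(0, 17)))
  # empty events: only drift and intercept remain
  x0 <- build_design_matrix(ev[0, ], tr = 1, n_scans = 128,
                            drift_cutoff = 128)
  expect_true(all(grepl("^drift_|^intercept$", colnames(x0))))
  expect_error(build_design_matrix(ev, tr = 1, n_scans = 100,
                                   trial_types = "a"), "unknown trial_type")
  expect_error(build_design_matrix(data.frame(onset = 99, duration = 5,
                                              trial_type = "a"),
                                   tr = 1, n_scans = 100), "past the end")
})

test_that("FFT convolution matches the direct-summation oracle", {
  set.seed(81)
  ev <- empathy_event_table(n_trials = 8, seed = 3)
  tr <- 1.2; n_scans <- 120; oversample <- 8
  x <- build_design_matrix(ev, tr, n_scans, oversample = oversample,
                           drift_cutoff = Inf, intercept = FALSE)
  dt <- tr / oversample
  kernel <- canonical_hrf(hrf_config(), dt)
  for (tt in colnames(x)) {
    evt <- ev[ev$trial_type == tt, ]
    neural <- numeric(n_scans * oversample)
    for (i in seq_len(nrow(evt))) {
      from <- floor(evt$onset[i] / dt) + 1
      to <- if (evt$duration[i] > 0)
        min(ceiling((evt$onset[i] + evt$duration[i]) / dt),
            length(neural)) else from
      neural[from:to] <- 1
    }
    direct <- naive_convolve(neural, kernel)
    idx <- 1 + (seq_len(n_scans) - 1) * oversample
    expect_lt(max(abs(x[, tt] - direct[idx])), 1e-10)
  }
})

test_that("convolution is linear and nonnegative for nonnegative kernels", {
  ev1 <- data.frame(onset = 10, duration = 2, trial_type = "a")
  ev2 <- data.frame(onset = 40, duration = 2, trial_type = "a")
  both <- rbind(ev1, ev2)
  args <- list(tr = 1, n_scans = 80, drift_cutoff = Inf, intercept = FALSE)
  xa <- do.call(build_design_matrix, c(list(ev1), args))
  xb <- do.call(build_design_matrix, c(list(ev2), args))
  xab <- do.call(build_design_matrix, c(list(both), args))
  expect_equal(drop(xab), drop(xa) + drop(xb), tolerance = 1e-12)
  pos_args <- c(list(both), args)
  pos_args$hrf <- hrf_config(undershoot_ratio = 0)
  xpos <- do.call(build_design_matrix, pos_args)
  expect_true(all(xpos >= -1e-12))
})

test_that("per-run GLM recovers amplitudes exactly without noise", {
  ev <- empathy_event_table(n_trials = 8, seed = 4)
  amps <- c(stim_other_pain = 1.2, stim_other_nopain = 0.5,
            stim_self_pain = 0.8, stim_self_nopain = 0.1,
            cue_other_pain = 0.4, cue_other_nopain = 0.4,
            cue_self_pain = 0.4, cue_self_nopain = 0.4, rating = 0.3)
  y <- generate_roi_timecourse(ev, amps, noise_sd = 0, tr = 1.2,
                               n_scans = 120)
  g <- roi_glm(y, ev, tr = 1.2, drift_cutoff = Inf)
  got <- setNames(g$estimate, g$condition)[names(amps)]
  expect_equal(got, amps, tolerance = 1e-6)
})

test_that("the hierarchical ROI model recovers the condition contrast", {
  runs <- simulate_roi_runs(n_subj = 10, three_way = 0, seed = 7)
  fit <- fit_roi_hierarchical(runs, tr = 1.2,
                              sampler = fast_sampler(draws = 800, seed = 2,
                                                     rhat_action = "none"))
  ct <- roi_contrast(fit)
  expect_true(ct$ci_low < 0.6 && 0.6 < ct$ci_high)
  expect_gt(ct$beta, 0.2)
  # matrix route: contrast of identical columns is exactly zero
  m <- cbind(p = rnorm(100), q = 0)
  m[, "q"] <- m[, "p"]
  z <- roi_contrast(m, terms = c("p", "q"))
  expect_equal(z$beta, 0)
  expect_equal(z$ci_high - z$ci_low, 0)
  expect_error(roi_contrast(m, terms = c("p", "missing")), "missing")
  # session-effect machinery is draw-consistent
  e1 <- roi_session_effects(fit, 1)
  e2 <- roi_session_effects(fit, 2)
  expect_identical(dim(e1), dim(e2))
  rel <- neural_reliability(e1, e2)
  expect_true(rel$ci_low <= rel$rho_mean & rel$rho_mean <= rel$ci_high)
  # the model's correlation parameter agrees in sign coverage
  rel2 <- roi_session_correlation(fit)
  expect_true(abs(rel2$rho_mean) <= 1)
})

test_that("a null three-way effect mostly yields evidence for the null", {
  n_h0 <- 0
  reps <- 12
  for (i in seq_len(reps)) {
    runs <- simulate_roi_runs(n_subj = 10, three_way = 0, seed = 100 + i)
    fit <- fit_roi_hierarchical(runs, tr = 1.2,
                                sampler = fast_sampler(chains = 1,
                                                       draws = 1000,
                                                       seed = i,
                                                       rhat_action = "none"))
    bf <- suppressWarnings(roi_interaction_bf(fit))
    n_h0 <- n_h0 + (bf$bf10 < 1 / 3)
  }
  expect_gt(n_h0 / reps, 0.5)
})

test_that("a real negative three-way effect is detected", {
  n_h1 <- 0
  reps <- 6
  for (i in seq_len(reps)) {
    runs <- simulate_roi_runs(n_subj = 12, three_way = -0.4,
                              noise_sd = 0.4, seed = 200 + i)
    fit <- fit_roi_hierarchical(runs, tr = 1.2,
                                sampler = fast_sampler(chains = 1,
                                                       draws = 1000,
                                                       seed = i,
                                                       rhat_action = "none"))
    bf <- suppressWarnings(roi_interaction_bf(fit))
    sgn <- mean(unlist(lapply(fit$draws, function(d)
      d[, "beta:group:session:intensity"]))) < 0
    n_h1 <- n_h1 + (bf$bf10 > 3 && sgn)
  }
  expect_gt(n_h1 / reps, 0.5)
})

test_that("degenerate ROI inputs are rejected", {
  runs <- simulate_roi_runs(n_subj = 4, seed = 5)
  # collinear design: duplicate a condition at identical onsets
  ev <- runs[[1]]$events
  dup <- ev[ev$trial_type == "stim_other_pain", ]
  dup$trial_type <- "stim_other_pain2"
  expect_error(roi_glm(runs[[1]]$values, rbind(ev, dup), tr = 1.2),
               "rank deficient")
  # missing session
  half <- runs[c(1, 3, 5, 7)] # only session -1 runs
  expect_error(fit_roi_hierarchical(half, tr = 1.2), "session")
})
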