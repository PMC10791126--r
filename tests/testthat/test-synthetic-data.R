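# Synthetic-data generators: determinism, censoring bookkeeping, and
# Monte-Carlo agreement of empirical moments with the generative settings.

test_that("rating generators are deterministic given the seed", {
  cfg <- quiet_config(seed = 99)
  expect_identical(generate_empathy_ratings(cfg),
                   generate_empathy_ratings(cfg))
  rcfg <- reactivity_config(n_control = 4, n_experimental = 4, seed = 5)
  expect_identical(generate_reactivity_ratings(rcfg),
                   generate_reactivity_ratings(rcfg))
  expect_false(identical(
    generate_empathy_ratings(cfg),
    generate_empathy_ratings(quiet_config(seed = 100))))
})

test_that("noise-free configurations reproduce the linear predictor", {
  fe <- c(intercept = 40, group = 2, session = 1, intensity = 10,
          "group:session" = 0.5, "group:intensity" = -1,
          "session:intensity" = 0.25, "group:session:intensity" = 0)
  cfg <- study_config(n_control = 3, n_experimental = 3,
                      ratings_per_cell = 2, fixed_effects = fe,
                      re_sd = c(intercept = 0, session = 0, intensity = 0,
                                "session:intensity" = 0),
                      sigma_meanlog = -Inf, sigma_sdlog = 0, seed = 3)
  d <- generate_empathy_ratings(cfg)
  pred <- fe["intercept"] + fe["group"] * d$group +
    fe["session"] * d$session + fe["intensity"] * d$intensity +
    fe["group:session"] * d$group * d$session +
    fe["group:intensity"] * d$group * d$intensity +
    fe["session:intensity"] * d$session * d$intensity
  expect_equal(d$rating, unname(pred))
  expect_true(all(d$censored == "none"))
})

test_that("out-of-range intercepts force boundary censoring", {
  fe <- c(intercept = 200, group = 0, session = 0, intensity = 0,
          "group:session" = 0, "group:intensity" = 0,
          "session:intensity" = 0, "group:session:intensity" = 0)
  cfg <- study_config(n_control = 2, n_experimental = 2,
                      ratings_per_cell = 2, fixed_effects = fe,
                      re_sd = c(intercept = 0, session = 0, intensity = 0,
                                "session:intensity" = 0),
                      sigma_meanlog = 0, sigma_sdlog = 0, seed = 2)
  d <- generate_empathy_ratings(cfg)
  expect_true(all(d$rating == 100))
  expect_true(all(d$censored == "high"))
})

test_that("censoring states partition the rows", {
  cfg <- study_config(n_control = 10, n_experimental = 10, seed = 8)
  d <- generate_empathy_ratings(cfg)
  tab <- table(factor(d$censored, levels = c("none", "low", "high")))
  expect_equal(sum(tab), nrow(d))
  expect_true(all(d$rating >= 0 & d$rating <= 100))
  expect_true(all(d$rating[d$censored == "high"] == 100))
  expect_true(all(d$rating[d$censored == "low"] == 0))
  # both sessions per subject, constant group
  by_subj <- split(d, d$subject_id)
  expect_true(all(vapply(by_subj, function(s)
    length(unique(s$session)) == 2, logical(1))))
  expect_true(all(vapply(by_subj, function(s)
    length(unique(s$group)) == 1, logical(1))))
})

test_that("a coded intensity effect of 27.86 yields a ~55.72 contrast", {
  fe <- c(intercept = 50, group = 0, session = 0, intensity = 27.86,
          "group:session" = 0, "group:intensity" = 0,
          "session:intensity" = 0, "group:session:intensity" = 0)
  cfg <- study_config(n_control = 70, n_experimental = 70,
                      ratings_per_cell = 4, fixed_effects = fe,
                      re_sd = c(intercept = 2, session = 1, intensity = 2,
                                "session:intensity" = 1),
                      sigma_meanlog = log(3), sigma_sdlog = 0.1, seed = 21)
  d <- generate_empathy_ratings(cfg)
  expect_lt(mean(d$censored != "none"), 0.01)
  # subject-level contrasts (ratings within subject are correlated)
  per_subj <- tapply(seq_len(nrow(d)), d$subject_id, function(i)
    mean(d$rating[i][d$intensity[i] == 1]) -
      mean(d$rating[i][d$intensity[i] == -1]))
  se <- sd(per_subj) / sqrt(length(per_subj))
  expect_lt(abs(mean(per_subj) - 2 * 27.86), 3 * se)
})

test_that("reactivity content effect of 37.08 yields a ~74.16 contrast", {
  fe <- c(intercept = 50, group = 0, content = 37.08, context = 0,
          "group:content" = 0, "group:context" = 0,
          "content:context" = 0, "group:content:context" = 0)
  cfg <- reactivity_config(n_control = 100, n_experimental = 100,
                           ratings_per_cell = 4, fixed_effects = fe,
                           re_sd = c(intercept = 2, content = 2,
                                     context = 1, "content:context" = 1),
                           sigma_meanlog = log(3), sigma_sdlog = 0.1,
                           seed = 22)
  d <- generate_reactivity_ratings(cfg)
  expect_lt(mean(d$censored != "none"), 0.02)
  per_subj <- tapply(seq_len(nrow(d)), d$subject_id, function(i)
    mean(d$rating[i][d$content[i] == 1]) -
      mean(d$rating[i][d$content[i] == -1]))
  se <- sd(per_subj) / sqrt(length(per_subj))
  expect_lt(abs(mean(per_subj) - 2 * 37.08), 3 * se)
})

test_that("empirical cell moments converge to the generative values", {
  cfg <- quiet_config(n_per_group = 32, ratings_per_cell = 8, seed = 31)
  d <- generate_empathy_ratings(cfg)
  expect_gt(nrow(d), 2000)
  cell <- d[d$session == 1 & d$intensity == 1, ]
  mu_true <- 50 + 20 # intercept + intensity effect of quiet_config
  se <- sd(cell$rating) / sqrt(nrow(cell))
  expect_lt(abs(mean(cell$rating) - mu_true), 3 * se)
  # between-subject spread: dominated by intercept SD + intensity SD
  subj_means <- tapply(cell$rating, cell$subject_id, mean)
  expect_gt(sd(subj_means), 2)
})

test_that("invalid configurations are rejected", {
  bad_corr <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3)
  expect_error(study_config(re_sd = c(a = 1, b = 1, c = 1),
                            re_corr = bad_corr,
                            fixed_effects = default_empathy_effects),
               "positive definite")
  expect_error(study_config(n_control = 1), ">= 2")
  expect_error(study_config(censor_low = 100, censor_high = 0))
})

test_that("pre/post samples have the requested correlation structure", {
  set.seed(41)
  s <- generate_prepost_groups(0, 0.75, 4000, 4000)
  expect_equal(cor(s$pre, s$post), 0.75, tolerance = 0.02)
  expect_equal(table(s$group)[["1"]], 4000)
  ch <- s$post - s$pre
  expect_lt(abs(mean(ch[s$group == 2]) - mean(ch[s$group == 1])),
            3 * sd(ch) * sqrt(2 / 4000))
  expect_error(generate_prepost_groups(0.3, 1, 10, 10), "rho")
})

test_that("the post-only shift gives the derived change-score effect", {
  # d = 0.3 on the post score with rho = 0.9: standardized change-score
  # effect d / sqrt(2 * 0.1) = 0.6708
  set.seed(42)
  s <- generate_prepost_groups(0.3, 0.9, 20000, 20000)
  ch <- s$post - s$pre
  d_emp <- (mean(ch[s$group == 2]) - mean(ch[s$group == 1])) /
    sqrt((var(ch[s$group == 1]) + var(ch[s$group == 2])) / 2)
  expect_equal(d_emp, 0.3 / sqrt(2 * (1 - 0.9)), tolerance = 0.03)
})

test_that("ROI time courses follow the HRF-convolved event model", {
  ev <- data.frame(onset = c(10, 40), duration = c(1, 1),
                   trial_type = c("a", "b"))
  # zero amplitudes, zero noise: flat series
  y0 <- generate_roi_timecourse(ev, c(a = 0, b = 0), 0, tr = 1.2,
                                n_scans = 60)
  expect_equal(y0, rep(0, 60))
  # a single impulse with no noise equals the shifted, scaled kernel
  ev1 <- data.frame(onset = 12, duration = 0, trial_type = "a")
  y1 <- generate_roi_timecourse(ev1, c(a = 2.5), 0, tr = 1, n_scans = 50,
                                hrf = hrf_config())
  x <- build_design_matrix(ev1, tr = 1, n_scans = 50, drift_cutoff = Inf,
                           intercept = FALSE)
  expect_equal(y1, 2.5 * drop(x))
  expect_equal(max(abs(y1)), 2.5, tolerance = 1e-6) # unit-peak kernel
  # determinism under a seed
  expect_identical(
    generate_roi_timecourse(ev, c(a = 1, b = 2), 0.5, 1.2, 60, seed = 7),
    generate_roi_timecourse(ev, c(a = 1, b = 2), 0.5, 1.2, 60, seed = 7))
  expect_error(generate_roi_timecourse(ev, c(a = 1, b = 1), -1, 1.2, 60),
               "non-negative")
})

test_that("event schedules are well-formed", {
  ev <- empathy_event_table(n_trials = 16, seed = 9)
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$duration >= 0))
  expect_equal(sum(ev$trial_type == "rating"), 8)
  expect_setequal(
    unique(sub("^(cue|stim)_", "", ev$trial_type[ev$trial_type != "rating"])),
    c("self_nopain", "self_pain", "other_nopain", "other_pain"))
})
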