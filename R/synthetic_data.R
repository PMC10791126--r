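# Synthetic-data generators. These emulate the statistical structure the
# downstream models assume: censored 0-100 VAS ratings with subject-level
# random effects and heterogeneous residual SDs, correlated pre/post group
# designs, and HRF-shaped ROI signal time courses.

empathy_fixed_terms <- c("intercept", "group", "session", "intensity",
                         "group:session", "group:intensity",
                         "session:intensity", "group:session:intensity")
empathy_random_terms <- c("intercept", "session", "intensity",
                          "session:intensity")
reactivity_fixed_terms <- c("intercept", "group", "content", "context",
                            "group:content", "group:context",
                            "content:context", "group:content:context")
reactivity_random_terms <- c("intercept", "content", "context",
                             "content:context")

default_empathy_effects <- c(
  intercept = 50, group = 0.66, session = 0.42, intensity = 27.86,
  "group:session" = -0.48, "group:intensity" = -1.12,
  "session:intensity" = -0.26, "group:session:intensity" = -0.78)

default_reactivity_effects <- c(
  intercept = 50, group = 1.26, content = 37.08, context = -7.24,
  "group:content" = 2.28, "group:context" = -1.23,
  "content:context" = -5.36, "group:content:context" = 0.33)

#' Configuration of a synthetic rating study
#'
#' Collects the generative settings of a two-group rating study: sample
#' sizes, trial structure, censoring bounds, fixed effects (the beta of the
#' generative model, in rating units), random-effect SDs and their
#' correlation matrix, and the distribution of per-subject residual SDs
#' (log-normal: strictly positive with a heavy-ish tail).
#'
#' The defaults describe the empathy-for-pain rating design: 44 control and
#' 45 experimental subjects, 8 ratings per condition cell per session
#' (ratings are collected after half of the 16 trials per condition), and
#' fixed effects at the published posterior means with a mid-scale
#' intercept of 50.
#'
#' @param n_control,n_experimental Subjects per group (each >= 2).
#' @param ratings_per_cell Ratings per condition cell (per session where
#'   applicable).
#' @param censor_low,censor_high Censoring bounds of the rating scale.
#' @param fixed_effects Named vector of generative fixed effects; names
#'   must match the design's term set, in order.
#' @param re_sd Named vector of random-effect SDs (rating units).
#' @param re_corr Correlation matrix over the random-effect terms
#'   (symmetric positive-definite, unit diagonal).
#' @param sigma_meanlog,sigma_sdlog Location and scale of the log-normal
#'   distribution of per-subject residual SDs.
#' @param seed Integer master seed; per-subject child streams are derived
#'   from it.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_control = 44, n_experimental = 45,
                         ratings_per_cell = 8,
                         censor_low = 0, censor_high = 100,
                         fixed_effects = default_empathy_effects,
                         re_sd = c(intercept = 10, session = 3,
                                   intensity = 10, "session:intensity" = 3),
                         re_corr = diag(length(re_sd)),
                         sigma_meanlog = log(8), sigma_sdlog = 0.4,
                         seed = 1L) {
  cfg <- list(n_control = n_control, n_experimental = n_experimental,
              ratings_per_cell = ratings_per_cell, censor_low = censor_low,
              censor_high = censor_high, fixed_effects = fixed_effects,
              re_sd = re_sd, re_corr = re_corr,
              sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
              seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  stopifnot(cfg$n_control >= 2, cfg$n_experimental >= 2,
            cfg$ratings_per_cell >= 1,
            cfg$censor_low < cfg$censor_high,
            all(cfg$re_sd >= 0), cfg$sigma_sdlog >= 0)
  k <- length(cfg$re_sd)
  rc <- cfg$re_corr
  if (!is.matrix(rc) || any(dim(rc) != k) ||
      max(abs(rc - t(rc))) > 1e-12 || max(abs(diag(rc) - 1)) > 1e-12)
    stop("`re_corr` must be a symmetric correlation matrix matching `re_sd`")
  ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("`re_corr` is not positive definite")
  invisible(cfg)
}

# Child seeds per subject from the master seed, so per-subject streams are
# stable under changes in group sizes elsewhere.
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

clamp_ratings <- function(latent, low, high) {
  censored <- ifelse(latent <= low, "low", ifelse(latent >= high, "high",
                                                  "none"))
  data.frame(rating = pmin(pmax(latent, low), high), censored = censored,
             stringsAsFactors = FALSE)
}

draw_subject_effects <- function(cfg) {
  k <- length(cfg$re_sd)
  # factor the correlation matrix so zero-SD terms are exactly zero
  cfg$re_sd * drop(rnorm(k) %*% chol(cfg$re_corr))
}

generate_ratings <- function(cfg, factor_names, fixed_terms, random_terms,
                             sessions) {
  stopifnot(identical(names(cfg$fixed_effects), fixed_terms),
            identical(names(cfg$re_sd), random_terms))
  n <- cfg$n_control + cfg$n_experimental
  group <- c(rep(-1, cfg$n_control), rep(1, cfg$n_experimental))
  seeds <- child_seeds(cfg$seed, n)
  rows <- vector("list", n)
  within <- expand.grid(lapply(factor_names[-1], function(f) c(-1, 1)))
  names(within) <- factor_names[-1]
  if (length(sessions) == 1 && !"session" %in% names(within))
    within$session <- sessions
  for (s in seq_len(n)) {
    set.seed(seeds[s])
    b <- draw_subject_effects(cfg)
    names(b) <- random_terms
    sigma_s <- rlnorm(1, cfg$sigma_meanlog, cfg$sigma_sdlog)
    cell <- within[rep(seq_len(nrow(within)), each = cfg$ratings_per_cell),
                   , drop = FALSE]
    x <- design_row(cell, group[s], fixed_terms, factor_names)
    z <- design_row(cell, group[s], random_terms, factor_names)
    latent <- drop(x %*% cfg$fixed_effects) + drop(z %*% b) +
      rnorm(nrow(cell), 0, sigma_s)
    cl <- clamp_ratings(latent, cfg$censor_low, cfg$censor_high)
    rows[[s]] <- cbind(
      data.frame(subject_id = sprintf("S%03d", s), group = group[s]),
      cell, cl, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Expand coded factor columns (plus the subject's group code) into the
# requested model terms; term "a:b" is the product of the codes.
design_row <- function(cell, group_code, terms, factor_names) {
  vals <- as.list(cell)
  vals$group <- group_code
  cols <- lapply(terms, function(tm) {
    if (tm == "intercept") return(rep(1, nrow(cell)))
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) {
      v <- vals[[p]]
      if (is.null(v)) stop("unknown factor in term: ", tm)
      rep(v, length.out = nrow(cell))
    }))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

#' Generate censored empathy-for-pain ratings
#'
#' Simulates the two-session empathy rating design: each subject rates
#' `ratings_per_cell` trials in every session-by-intensity cell, both
#' sessions, all factors coded -1/1. The latent rating is the linear
#' predictor over all eight fixed terms (Group, Session, Intensity and
#' their interactions) plus the subject's random effects (intercept,
#' Session, Intensity, Session:Intensity) plus Normal noise with the
#' subject's own residual SD, then clamped to the censoring bounds with the
#' censoring flag set. Deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @return A trial table data.frame with columns `subject_id`, `group`,
#'   `session`, `target`, `intensity`, `rating`, `censored`.
#' @export
generate_empathy_ratings <- function(config) {
  validate_study_config(config)
  out <- generate_ratings(config, c("group", "session", "intensity"),
                          empathy_fixed_terms, empathy_random_terms,
                          sessions = c(-1, 1))
  out$target <- "other" # rated trials concern the other-directed condition
  out[, c("subject_id", "group", "session", "target", "intensity",
          "rating", "censored")]
}

#' Generate censored emotional-reactivity ratings
#'
#' Single-session block design with factors Group, Content (neutral vs.
#' violent) and Context (real vs. game), all coded -1/1; one rating per
#' block, 4 blocks per condition by default. Random effects: intercept,
#' Content, Context, Content:Context.
#'
#' @param config A [study_config()] whose `fixed_effects`/`re_sd` names
#'   follow the reactivity term set; see [reactivity_config()].
#' @return A trial table data.frame with columns `subject_id`, `group`,
#'   `content`, `context`, `rating`, `censored`.
#' @export
generate_reactivity_ratings <- function(config) {
  validate_study_config(config)
  generate_ratings(config, c("group", "content", "context"),
                   reactivity_fixed_terms, reactivity_random_terms,
                   sessions = 1)[, c("subject_id", "group", "content",
                                     "context", "rating", "censored")]
}

#' @rdname study_config
#' @param ... Overrides passed to [study_config()].
#' @export
reactivity_config <- function(ratings_per_cell = 4,
                              fixed_effects = default_reactivity_effects,
                              re_sd = c(intercept = 12, content = 10,
                                        context = 4,
                                        "content:context" = 3), ...) {
  study_config(ratings_per_cell = ratings_per_cell,
               fixed_effects = fixed_effects, re_sd = re_sd, ...)
}

#' Generate a correlated pre/post two-group sample
#'
#' Per subject, (pre, post) are bivariate Normal with unit marginal SD and
#' correlation `rho`; subjects of group 2 receive a mean shift of `d` on
#' the post measurement only. The implied standardized effect on change
#' scores is `d / sqrt(2 (1 - rho))`.
#'
#' @param d Standardized mean shift applied to group 2's post scores.
#' @param rho Pre/post correlation, strictly inside (-1, 1).
#' @param n1,n2 Sizes of groups 1 and 2.
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used (so callers running many replicates stay reproducible from their
#'   own seed).
#' @return A data.frame with columns `subject_id`, `group` (1 or 2), `pre`,
#'   `post`.
#' @export
generate_prepost_groups <- function(d, rho, n1, n2, seed = NULL) {
  if (abs(rho) >= 1) stop("`rho` must lie strictly inside (-1, 1)")
  stopifnot(n1 >= 2, n2 >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  pre <- rnorm(n)
  post <- rho * pre + sqrt(1 - rho^2) * rnorm(n)
  group <- rep(c(1, 2), c(n1, n2))
  post[group == 2] <- post[group == 2] + d
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group,
             pre = pre, post = post)
}

#' Generate an ROI signal time course from event timings
#'
#' Builds HRF-convolved condition regressors from the event table and sums
#' them with the given amplitudes, adding white Gaussian noise.
#' Deterministic given `seed`.
#'
#' @param events Event table (`onset`, `duration`, `trial_type`, seconds).
#' @param amplitudes Named vector of condition amplitudes; names must match
#'   the event table's `trial_type` values.
#' @param noise_sd Standard deviation of the additive white noise (>= 0).
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes.
#' @param seed Optional integer seed.
#' @param hrf An [hrf_config()].
#' @return Numeric vector of length `n_scans`.
#' @export
generate_roi_timecourse <- function(events, amplitudes, noise_sd, tr,
                                    n_scans, seed = NULL,
                                    hrf = hrf_config()) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  x <- build_design_matrix(events, tr, n_scans, hrf = hrf,
                           trial_types = names(amplitudes),
                           drift_cutoff = Inf, intercept = FALSE)
  drop(x %*% amplitudes[colnames(x)]) + rnorm(n_scans, 0, noise_sd)
}

#' Generate an empathy-task event schedule
#'
#' Produces a BIDS-style events table for one run of the empathy-for-pain
#' paradigm: per trial a 2 s cue, a jittered 3-7 s interval, the
#' stimulation (0.5 s self / 1 s other), and after half of the trials a 4 s
#' rating epoch. Trial types are `cue_<target>_<intensity>`,
#' `stim_<target>_<intensity>` and `rating`.
#'
#' @param n_trials Total trials (divisible by 4; 16 per condition by
#'   default).
#' @param iti Inter-trial interval in seconds.
#' @param seed Optional integer seed (jitter and condition order).
#' @return A data.frame with columns `onset`, `duration`, `trial_type`.
#' @export
empathy_event_table <- function(n_trials = 64, iti = 2, seed = NULL) {
  stopifnot(n_trials %% 4 == 0)
  if (!is.null(seed)) set.seed(seed)
  conds <- expand.grid(target = c("self", "other"),
                       intensity = c("nopain", "pain"),
                       stringsAsFactors = FALSE)
  order <- sample(rep(seq_len(4), n_trials / 4))
  rated <- sample(rep(c(TRUE, FALSE), n_trials / 2))
  t <- 0
  rows <- list()
  for (i in seq_len(n_trials)) {
    cd <- conds[order[i], ]
    stim_dur <- if (cd$target == "self") 0.5 else 1
    rows[[length(rows) + 1]] <- data.frame(
      onset = t, duration = 2,
      trial_type = paste("cue", cd$target, cd$intensity, sep = "_"))
    t <- t + 2 + runif(1, 3, 7)
    rows[[length(rows) + 1]] <- data.frame(
      onset = t, duration = stim_dur,
      trial_type = paste("stim", cd$target, cd$intensity, sep = "_"))
    t <- t + stim_dur
    if (rated[i]) {
      t <- t + runif(1, 1, 2)
      rows[[length(rows) + 1]] <- data.frame(onset = t, duration = 4,
                                             trial_type = "rating")
      t <- t + 4
    }
    t <- t + iti
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
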