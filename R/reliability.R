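# Test-retest reliability from random-effect variance components, neural
# reliability from session-specific subject effects, and cross-task
# correlation summaries.

#' Test-retest reliability from variance components
#'
#' In the two-session rating design, a subject's condition effect in
#' session 1 is `b_I - b_I:S` and in session 2 `b_I + b_I:S` (the session
#' factor is coded -1/1), where `b_I` is the subject's random effect of the
#' condition factor and `b_I:S` the random effect of its interaction with
#' session. The test-retest correlation of the condition effect is then
#'
#' `rho = (sd_i^2 - sd_is^2) / sqrt((sd_i^2 + sd_is^2 - 2 r sd_i sd_is)
#'  (sd_i^2 + sd_is^2 + 2 r sd_i sd_is))`
#'
#' i.e. the correlation of `b_I - b_I:S` with `b_I + b_I:S` under the
#' random-effect distribution.
#'
#' @param sd_i SD of the condition random effect (>= 0); vectorized.
#' @param sd_is SD of the condition-by-session random effect (>= 0).
#' @param r Correlation between the two random effects, in [-1, 1].
#' @return The reliability, in [-1, 1].
#' @examples
#' behavioral_reliability(1, 0.5, 0) # (1 - 0.25) / 1.25
#' @export
behavioral_reliability <- function(sd_i, sd_is, r) {
  if (any(sd_i < 0) || any(sd_is < 0)) stop("SDs must be non-negative")
  if (any(abs(r) > 1)) stop("`r` must lie in [-1, 1]")
  s2 <- sd_i^2 + sd_is^2
  cross <- 2 * r * sd_i * sd_is
  denom2 <- (s2 - cross) * (s2 + cross)
  if (any(denom2 <= 0))
    stop("degenerate random effects: zero variance in a session effect")
  (sd_i^2 - sd_is^2) / sqrt(denom2)
}

new_reliability_estimate <- function(draws, source) {
  structure(list(rho_mean = mean(draws),
                 ci_low = quantile(draws, 0.025, names = FALSE),
                 ci_high = quantile(draws, 0.975, names = FALSE),
                 source = source, draws = draws),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("Test-retest reliability (%s): rho = %.3f, 95%% CrI [%.3f, %.3f]\n",
              x$source, x$rho_mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' Behavioral test-retest reliability of a fitted rating model
#'
#' Applies [behavioral_reliability()] to every posterior draw of the
#' random-effect SDs and their correlation (full uncertainty propagation)
#' and summarizes with the posterior mean and central 95% interval.
#'
#' @param fit A `vas_fit` from [fit_posterior()].
#' @param condition Condition random-effect term (default `"intensity"`).
#' @param interaction Its session interaction (default
#'   `"session:intensity"`).
#' @return A `reliability_estimate` (source `"behavioral"`).
#' @export
reliability_from_fit <- function(fit, condition = "intensity",
                                 interaction = paste0("session:", condition)) {
  sd_i <- re_sd_draws(fit, condition)
  sd_is <- re_sd_draws(fit, interaction)
  r <- re_corr_draws(fit, condition, interaction)
  new_reliability_estimate(behavioral_reliability(sd_i, sd_is, r),
                           "behavioral")
}

#' Neural test-retest reliability from session-specific subject effects
#'
#' Per posterior draw, the Pearson correlation across subjects between the
#' session-1 and session-2 subject-level effect vectors; summarized as the
#' posterior mean and central 95% interval. Inputs are draws-by-subjects
#' matrices (matching subject order), e.g. from [fit_roi_hierarchical()].
#'
#' @param effects1,effects2 Draws-by-subjects matrices of the same shape
#'   (>= 3 subjects).
#' @return A `reliability_estimate` (source `"neural"`).
#' @export
neural_reliability <- function(effects1, effects2) {
  effects1 <- as.matrix(effects1); effects2 <- as.matrix(effects2)
  if (!all(dim(effects1) == dim(effects2)))
    stop("effect matrices must have the same shape")
  if (ncol(effects1) < 3) stop("need at least 3 subjects")
  if (!is.null(colnames(effects1)) && !is.null(colnames(effects2)) &&
      !identical(colnames(effects1), colnames(effects2)))
    stop("subject ids of the two sessions do not match")
  rho <- vapply(seq_len(nrow(effects1)), function(i)
    cor(effects1[i, ], effects2[i, ]), numeric(1))
  new_reliability_estimate(rho, "neural")
}

#' Cross-task correlations of subject-level effects
#'
#' Per posterior draw, the Pearson correlation matrix across subjects of
#' several subject-level effect vectors (one per task or ROI); summarized
#' as posterior means and central 95% intervals.
#'
#' @param effects Named list of draws-by-subjects matrices over a common
#'   subject set (matching column names; all matrices must have the same
#'   number of draws).
#' @return A `cross_task_correlations` object: `mean` (correlation matrix),
#'   `ci_low`, `ci_high`.
#' @export
cross_task_correlations <- function(effects) {
  stopifnot(is.list(effects), length(effects) >= 2)
  effects <- lapply(effects, as.matrix)
  ids <- colnames(effects[[1]])
  for (e in effects) {
    if (!all(dim(e) == dim(effects[[1]])))
      stop("all effect matrices must have the same shape")
    if (!is.null(ids) && !is.null(colnames(e)) &&
        !identical(colnames(e), ids))
      stop("subject ids do not match across measures")
  }
  m <- length(effects)
  nd <- nrow(effects[[1]])
  acc <- array(NA_real_, c(nd, m, m))
  for (i in seq_len(nd)) {
    x <- sapply(effects, function(e) e[i, ])
    acc[i, , ] <- cor(x)
  }
  nm <- names(effects)
  mk <- function(f) {
    out <- apply(acc, c(2, 3), f)
    dimnames(out) <- list(nm, nm)
    out
  }
  structure(list(mean = mk(mean),
                 ci_low = mk(function(v) quantile(v, 0.025, names = FALSE)),
                 ci_high = mk(function(v) quantile(v, 0.975, names = FALSE))),
            class = "cross_task_correlations")
}

#' Above/below-diagonal layout of a cross-task correlation summary
#'
#' Posterior means above the diagonal, `(ci_low, ci_high)` strings below --
#' the conventional compact layout for correlation tables.
#'
#' @param x A `cross_task_correlations` object.
#' @return A character matrix.
#' @export
format_corr_table <- function(x) {
  nm <- rownames(x$mean)
  m <- length(nm)
  out <- matrix("", m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j) out[i, j] <- sprintf("%.3f", x$mean[i, j])
    if (i > j) out[i, j] <- sprintf("(%.3f,%.3f)", x$ci_low[i, j],
                                    x$ci_high[i, j])
  }
  out
}

#' @export
print.cross_task_correlations <- function(x, ...) {
  print(format_corr_table(x), quote = FALSE)
  invisible(x)
}

#' TSV summary of reliability estimates
#'
#' @param estimates Named list of `reliability_estimate` objects.
#' @param path Output file.
#' @return The summary data.frame, invisibly.
#' @export
write_reliability_table <- function(estimates, path) {
  df <- data.frame(
    measure = names(estimates),
    rho_mean = vapply(estimates, `[[`, numeric(1), "rho_mean"),
    ci_low = vapply(estimates, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(estimates, `[[`, numeric(1), "ci_high"),
    row.names = NULL)
  write_tsv(df, path)
  invisible(df)
}
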