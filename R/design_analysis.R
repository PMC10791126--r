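# Design analysis: effect-size conversion, noncentral-F power for the
# within-between ANOVA interaction, required-N search, and Monte-Carlo
# Bayes-factor design analysis (BFDA).

#' Convert a correlation effect size to Cohen's d
#'
#' `d = 2 r / sqrt(1 - r^2)`, the standard conversion for two-group designs.
#'
#' @param r Correlation effect size, `|r| < 1`.
#' @return Cohen's d.
#' @examples
#' r_to_d(0.194)
#' @export
r_to_d <- function(r) {
  if (any(abs(r) >= 1)) stop("`r` must lie strictly inside (-1, 1)")
  2 * r / sqrt(1 - r^2)
}

#' Power of the within-between interaction in a mixed ANOVA
#'
#' Exact noncentral-F power for the group-by-time interaction in a design
#' with `n_groups` between-subject groups and `n_measurements` repeated
#' measurements, following the repeated-measures convention of the common
#' power software: Cohen's `f = d/2`, noncentrality
#' `lambda = f^2 * N * m / (1 - rho)`, `df1 = (g-1)(m-1)`,
#' `df2 = (N-g)(m-1)`.
#'
#' @param d Standardized between-group effect size (Cohen's d).
#' @param n_total Total sample size N across groups.
#' @param rho Correlation between repeated measurements (test-retest
#'   reliability), `0 <= rho < 1`.
#' @param alpha Type-I error level.
#' @param n_groups,n_measurements Number of groups and repeated
#'   measurements (both default 2).
#' @param f Cohen's f; overrides `d/2` when supplied directly (useful when
#'   reproducing results computed from a rounded f).
#' @return The power, `P(F' > F_crit)`.
#' @examples
#' interaction_power(d = 0.396, n_total = 90, rho = 0.5)
#' @export
interaction_power <- function(d, n_total, rho, alpha = 0.05,
                              n_groups = 2, n_measurements = 2, f = d / 2) {
  stopifnot(n_total > n_groups, rho >= 0, rho < 1, alpha > 0, alpha < 1)
  df1 <- (n_groups - 1) * (n_measurements - 1)
  df2 <- (n_total - n_groups) * (n_measurements - 1)
  lambda <- f^2 * n_total * n_measurements / (1 - rho)
  f_crit <- qf(1 - alpha, df1, df2)
  pf(f_crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest total sample size reaching a target interaction power
#'
#' Scans even total sample sizes (equal groups) upward until
#' [interaction_power()] reaches `target_power`.
#'
#' @inheritParams interaction_power
#' @param target_power Desired power in (0, 1).
#' @return The smallest admissible even total N.
#' @examples
#' required_n(d = 0.3, target_power = 0.8, rho = 0.5)
#' @export
required_n <- function(d, target_power = 0.8, rho = 0.5, alpha = 0.05,
                       n_groups = 2, n_measurements = 2) {
  stopifnot(target_power > 0, target_power < 1)
  n <- n_groups + 2 # smallest even N with positive error df per group
  while (n <= 1e6) {
    if (interaction_power(d, n, rho, alpha, n_groups,
                          n_measurements) >= target_power)
      return(n)
    n <- n + 2
  }
  stop("target power unreachable with N <= 1e6")
}

#' Monte-Carlo Bayes-factor design analysis
#'
#' Estimates the long-run probabilities that a default one-sided JZS
#' two-sample t-test yields evidence for the alternative (BF10 > `upper`),
#' evidence for the null (BF10 < `lower`), or an inconclusive result, when
#' the true standardized effect is `d`. Pre/post designs are simulated with
#' [generate_prepost_groups()] (the effect lands on the raw post score, so
#' the test on change scores sees a standardized effect of
#' `d / sqrt(2 (1 - rho))`); single-session designs draw one measurement
#' per subject with a raw standardized shift of `d`.
#'
#' @param d True standardized effect size on the raw (post) measurement.
#' @param rho Test-retest correlation of the pre/post measurements; ignored
#'   when `single_session = TRUE`.
#' @param single_session If `TRUE`, simulate a two-group single-measurement
#'   design and test the raw scores.
#' @param n1,n2 Group sizes (control, experimental).
#' @param n_reps Number of simulated datasets (>= 100).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param scale Cauchy prior scale of the JZS test.
#' @param lower,upper Evidence thresholds (defaults 1/3 and 3).
#' @return A `bfda_result` list: `p_inconclusive`, `p_H0`, `p_H1`, their
#'   Monte-Carlo standard errors `se`, `n_reps`, and the scenario settings.
#' @examples
#' bfda(d = 0, rho = 0.75, n_reps = 200, seed = 1)
#' @export
bfda <- function(d, rho = NULL, single_session = FALSE, n1 = 44, n2 = 45,
                 n_reps = 10000, seed = NULL, scale = sqrt(2) / 2,
                 lower = 1 / 3, upper = 3) {
  stopifnot(n_reps >= 100)
  if (!single_session && is.null(rho))
    stop("`rho` is required for pre/post designs")
  if (!is.null(seed)) set.seed(seed)
  cat_counts <- c(H1 = 0, H0 = 0, inconclusive = 0)
  for (i in seq_len(n_reps)) {
    if (single_session) {
      x1 <- rnorm(n1)
      x2 <- rnorm(n2, mean = d)
    } else {
      s <- generate_prepost_groups(d, rho, n1, n2)
      ch <- s$post - s$pre
      x1 <- ch[s$group == 1]
      x2 <- ch[s$group == 2]
    }
    t <- summary_t(mean(x2), sd(x2), n2, mean(x1), sd(x1), n1)
    bf <- jzs_ttest_bf(t, n2, n1, scale = scale, direction = "positive")
    cat <- categorize_bf(bf$bf10, lower, upper)
    cat_counts[cat] <- cat_counts[cat] + 1
  }
  p <- cat_counts / n_reps
  structure(list(
    p_inconclusive = unname(p["inconclusive"]),
    p_H0 = unname(p["H0"]),
    p_H1 = unname(p["H1"]),
    se = sqrt(p * (1 - p) / n_reps),
    n_reps = n_reps, d = d, rho = rho,
    single_session = single_session, n1 = n1, n2 = n2, scale = scale),
    class = "bfda_result")
}

#' @export
print.bfda_result <- function(x, ...) {
  cat(sprintf(
    "BFDA (d = %.2f, %s, n = %d/%d, %d reps)\n", x$d,
    if (x$single_session) "single session" else sprintf("rho = %.2f", x$rho),
    x$n1, x$n2, x$n_reps))
  cat(sprintf("  P(inconclusive) = %.3f, P(H0) = %.3f, P(H1) = %.3f\n",
              x$p_inconclusive, x$p_H0, x$p_H1))
  invisible(x)
}

#' BFDA over a grid of effect sizes and scenarios
#'
#' Runs [bfda()] for every combination of effect size and scenario and
#' returns a long-format table mirroring the usual design-analysis layout
#' (one row per effect size and scenario, columns for the three outcome
#' probabilities).
#'
#' @param d_values Numeric vector of true effect sizes.
#' @param scenarios A data.frame with columns `name`, `rho`,
#'   `single_session`; defaults to the four standard scenarios (pre/post
#'   with rho 0.75, 0.90, 0, and a single-session design).
#' @param n_reps,seed,n1,n2,scale Passed to [bfda()]; each cell uses an
#'   independent child seed derived from `seed`.
#' @return A data.frame with columns `scenario`, `rho`, `single_session`,
#'   `d`, `p_inconclusive`, `p_H0`, `p_H1`.
#' @export
bfda_grid <- function(d_values = c(0, 0.2, 0.3, 0.4),
                      scenarios = default_bfda_scenarios(),
                      n_reps = 2000, seed = NULL, n1 = 44, n2 = 45,
                      scale = sqrt(2) / 2) {
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(row = seq_len(nrow(scenarios)), d = d_values)
  cell_seeds <- sample.int(.Machine$integer.max - 1, nrow(cells))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- scenarios[cells$row[i], ]
    res <- bfda(cells$d[i], rho = if (sc$single_session) NULL else sc$rho,
                single_session = sc$single_session, n1 = n1, n2 = n2,
                n_reps = n_reps, seed = cell_seeds[i], scale = scale)
    data.frame(scenario = sc$name, rho = sc$rho,
               single_session = sc$single_session, d = cells$d[i],
               p_inconclusive = res$p_inconclusive, p_H0 = res$p_H0,
               p_H1 = res$p_H1)
  })
  do.call(rbind, out)
}

#' @rdname bfda_grid
#' @export
default_bfda_scenarios <- function() {
  data.frame(
    name = c("painfulness", "unpleasantness", "neural", "reactivity"),
    rho = c(0.75, 0.90, 0, NA),
    single_session = c(FALSE, FALSE, FALSE, TRUE))
}
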