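#' Power specification
#'
#' @param test `"two_sample"` (two independent means) or `"paired"`
#'   (matched pairs).
#' @param alpha Significance level (default 0.05).
#' @param tails `"two"` (default) or `"one"`.
#' @param pair_correlation Assumed correlation between the paired readings
#'   (default 0.5; paired test only).
#' @return A list of class `ncountr_power_spec`.
#' @export
power_spec <- function(test = c("two_sample", "paired"), alpha = 0.05,
                       tails = c("two", "one"), pair_correlation = 0.5) {
  stopifnot(alpha > 0, alpha < 1,
            pair_correlation > -1, pair_correlation < 1)
  structure(list(test = match.arg(test), alpha = alpha,
                 tails = match.arg(tails),
                 pair_correlation = pair_correlation),
            class = "ncountr_power_spec")
}

# exact power of a t test from its noncentrality and df
t_power <- function(ncp, df, alpha, tails) {
  if (tails == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Exact power of the two-independent-means t test
#'
#' Noncentrality delta = d * sqrt(n1 n2 / (n1 + n2)), df = n1 + n2 - 2,
#' power from the noncentral t distribution (the calculation G*Power
#' performs for post-hoc two-sample power).
#'
#' @param d Standardized mean difference (Cohen's d).
#' @param n1,n2 Group sizes (each >= 2).
#' @param spec A [power_spec()].
#' @return One-row tibble: `power`, `effect_size_d`, `n1`, `n2`,
#'   `noncentrality`, `df`.
#' @export
#' @examples
#' power_two_sample(1.0, 8, 8)
power_two_sample <- function(d, n1, n2, spec = power_spec()) {
  if (n1 < 2 || n2 < 2) {
    stop_ncountr("group sizes must be >= 2", "ncountr_value_error")
  }
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tibble::tibble(power = t_power(ncp, df, spec$alpha, spec$tails),
                 effect_size_d = d, n1 = n1, n2 = n2,
                 noncentrality = ncp, df = df)
}

#' Exact power of the matched-pairs t test
#'
#' The difference SD is sqrt(sd1^2 + sd2^2 - 2 r sd1 sd2); dz =
#' mean_diff / sd_diff; delta = dz * sqrt(n_pairs); df = n_pairs - 1.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd1,sd2 SDs at the two time points.
#' @param r Correlation between the paired readings (default
#'   `spec$pair_correlation`).
#' @param n_pairs Number of pairs (>= 2).
#' @param spec A [power_spec()].
#' @return One-row tibble: `power`, `effect_size_dz`, `n_pairs`,
#'   `noncentrality`, `df`.
#' @export
power_paired <- function(mean_diff, sd1, sd2, r = NULL, n_pairs,
                         spec = power_spec("paired")) {
  r <- r %||% spec$pair_correlation
  if (n_pairs < 2) stop_ncountr("n_pairs must be >= 2", "ncountr_value_error")
  if (sd1 <= 0 || sd2 <= 0) {
    stop_ncountr("sd1 and sd2 must be positive", "ncountr_value_error")
  }
  sd_diff <- sqrt(sd1^2 + sd2^2 - 2 * r * sd1 * sd2)
  if (sd_diff == 0) {
    stop_ncountr("difference SD is zero", "ncountr_value_error")
  }
  dz <- mean_diff / sd_diff
  ncp <- dz * sqrt(n_pairs)
  df <- n_pairs - 1
  tibble::tibble(power = t_power(ncp, df, spec$alpha, spec$tails),
                 effect_size_dz = dz, n_pairs = n_pairs,
                 noncentrality = ncp, df = df)
}

#' Calibrate the effect size achieving a target two-sample power
#'
#' Bisection on d >= 0 so that [power_two_sample()] at (n1, n2) equals the
#' target; used to back out the standardized effect implied by a reported
#' realised power.
#'
#' @param target_power Power in (alpha, 1).
#' @param n1,n2 Group sizes.
#' @param spec A [power_spec()].
#' @param tol Convergence tolerance on d.
#' @return The effect size d as a single number.
#' @export
#' @examples
#' d <- solve_effect_size(0.706, 8, 8)  # realised power reported at n = 8
#' power_two_sample(d, 10, 10)$power    # extrapolated power at n = 10
solve_effect_size <- function(target_power, n1, n2, spec = power_spec(),
                              tol = 1e-8) {
  alpha_floor <- if (spec$tails == "two") spec$alpha else spec$alpha
  if (target_power <= alpha_floor || target_power >= 1) {
    stop_ncountr("target power must lie in (alpha, 1)",
                 "ncountr_value_error")
  }
  f <- function(d) power_two_sample(d, n1, n2, spec)$power - target_power
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) {
    stop_ncountr("target power unattainable", "ncountr_convergence_error")
  }
  stats::uniroot(f, c(0, hi), tol = tol)$root
}

#' Smallest per-group sample size achieving a target power
#'
#' Integer search upward from n = 2 for the smallest n with
#' `power_two_sample(d, n, n) >= target_power`.
#'
#' @inheritParams solve_effect_size
#' @param d Effect size (> 0).
#' @param n_max Search cap.
#' @return The sample size per group as an integer.
#' @export
solve_n <- function(target_power, d, spec = power_spec(), n_max = 1e6) {
  if (d <= 0) stop_ncountr("d must be > 0", "ncountr_value_error")
  if (target_power <= spec$alpha || target_power >= 1) {
    stop_ncountr("target power must lie in (alpha, 1)",
                 "ncountr_value_error")
  }
  n <- 2
  while (n <= n_max) {
    if (power_two_sample(d, n, n, spec)$power >= target_power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop_ncountr(paste0("no n <= ", n_max, " reaches the target power"),
               "ncountr_convergence_error")
}

#' Power curve over a range of sample sizes
#'
#' @param d Effect size.
#' @param n_range Integer vector of per-group sizes.
#' @param spec A [power_spec()].
#' @return Tibble `n`, `power`.
#' @export
power_curve <- function(d, n_range = 2:30, spec = power_spec()) {
  purrr::map_dfr(n_range, function(n) {
    tibble::tibble(n = n, power = power_two_sample(d, n, n, spec)$power)
  })
}

#' Plot a power curve
#' @inheritParams power_curve
#' @return A ggplot object.
#' @export
plot_power_curve <- function(d, n_range = 2:30, spec = power_spec()) {
  ggplot2::ggplot(power_curve(d, n_range, spec),
                  ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "animals per group", y = "power")
}
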