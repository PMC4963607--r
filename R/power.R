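#' Power of a two-tailed dependent-means t test
#'
#' Exact noncentral-t computation: with `n` pairs, effect size `d`
#' (standardized mean difference of the paired scores), the test statistic
#' follows a noncentral t with `df = n - 1` and noncentrality
#' `d * sqrt(n)`; power is the probability of exceeding the two-tailed
#' critical value.
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardized effect size (Cohen's d for dependent means).
#' @param alpha Two-tailed significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' power_dependent_t(54, 0.5)  # just above 0.95
#' @export
power_dependent_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Required sample size for a dependent-means t test
#'
#' Smallest `n` whose noncentral-t power reaches the target — the
#' computation behind a priori sample-size planning for paired designs
#' (e.g. d = 0.5, two-tailed alpha .05, power .95 requires 54
#' participants).
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search bound; exceeding it signals unattainable power.
#' @return The smallest integer `n` with power >= `power`.
#' @examples
#' required_n_dependent_t(0.5, 0.05, 0.95)  # 54
#' @export
required_n_dependent_t <- function(d, alpha = 0.05, power = 0.95,
                                   n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2
  while (power_dependent_t(n, d, alpha) < power) {
    n <- n + 1
    if (n > n_max) stop("target power unattainable within n_max pairs")
  }
  as.integer(n)
}

#' Monte-Carlo power check for the dependent-means t test
#'
#' Simulates paired-difference samples from `N(d, 1)` and reports the
#' rejection rate of the two-tailed one-sample t test — an independent
#' cross-check of [power_dependent_t()].
#'
#' @param n Number of pairs.
#' @param d True standardized effect.
#' @param alpha Two-tailed significance level.
#' @param n_rep Number of replicates.
#' @param seed Optional integer seed.
#' @return Estimated power (proportion of rejections).
#' @export
mc_power_dependent_t <- function(n, d, alpha = 0.05, n_rep = 1e5,
                                 seed = NULL) {
  with_seed(seed, {
    x <- matrix(rnorm(n * n_rep, mean = d), n, n_rep)
    m <- colMeans(x)
    v <- (colSums(x^2) - n * m^2) / (n - 1)
    tstat <- sqrt(n) * m / sqrt(v)
    mean(abs(tstat) > qt(1 - alpha / 2, n - 1))
  })
}
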