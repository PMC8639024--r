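#' Analysis configuration
#'
#' Bundles the constants of the analytic protocol: significance level,
#' normal quantile for 95% intervals, the relative-standard-error
#' suppression threshold, and the permutation-test settings.  All internal
#' arithmetic is unrounded; rounding half-away-from-zero to one decimal is
#' applied only at the reporting boundary.
#'
#' @param alpha significance level (default 0.05).
#' @param z normal quantile for the intervals (default 1.959964, the 97.5th
#'   percentile).
#' @param rse_threshold estimates with relative standard error above this
#'   are suppressed (default 0.30).
#' @param n_permutations Monte-Carlo permutations (default 10,000) when
#'   exhaustive enumeration is not feasible.
#' @param permutation_seed mandatory seed for the Monte-Carlo permutation
#'   path.
#' @return an `asdsurv_analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, z = 1.959964, rse_threshold = 0.30,
                            n_permutations = 10000L, permutation_seed = 1L) {
  check_prob(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  check_prob(z, "z", lo = 0, hi = Inf)
  check_prob(rse_threshold, "rse_threshold", lo = 0, hi = Inf)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1)
  permutation_seed <- check_count(permutation_seed, "permutation_seed")
  structure(list(alpha = alpha, z = z, rse_threshold = rse_threshold,
                 n_permutations = n_permutations,
                 permutation_seed = permutation_seed),
            class = "asdsurv_analysis_config")
}

default_cfg <- function(cfg) {
  if (is.null(cfg)) analysis_config() else cfg
}

#' Relative standard error of a binomial prevalence estimate
#'
#' `sqrt(p(1-p)/n) / p` with `p = numerator/denominator`; infinite (hence
#' always suppressed) when the numerator is zero.
#'
#' @param numerator case count.
#' @param denominator population denominator (> 0, may be fractional).
#' @return numeric vector of relative standard errors.
#' @export
relative_standard_error <- function(numerator, denominator) {
  p <- numerator / denominator
  ifelse(numerator == 0, Inf, sqrt(p * (1 - p) / denominator) / p)
}

#' Wilson score interval for a binomial proportion, per 1,000
#'
#' Standard Wilson score bounds: center `(p + z^2/2n) / (1 + z^2/n)`,
#' half-width `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, scaled by
#' 1,000.  The lower bound is exactly zero at a zero numerator.
#'
#' @param numerator,denominator counts (vectorized).
#' @param cfg an [analysis_config()] (supplies `z`).
#' @return list with numeric vectors `low` and `high`, per 1,000.
#' @export
#' @examples
#' wilson_interval(5058, 220281)
wilson_interval <- function(numerator, denominator, cfg = NULL) {
  cfg <- default_cfg(cfg)
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive", class = "asdsurv_validation_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator]",
          class = "asdsurv_validation_error")
  }
  z <- cfg$z
  p <- numerator / denominator
  n <- denominator
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half) * 1000,
       high = pmin(1, center + half) * 1000)
}

#' Prevalence per 1,000 with Wilson interval and suppression
#'
#' @param numerator case count(s).
#' @param denominator population denominator(s), positive (fractional
#'   tract-sum denominators allowed).
#' @param cfg an [analysis_config()].
#' @return an `asdsurv_prevalence_estimate` tibble with `numerator`,
#'   `denominator`, `per_1000`, `ci_low_per_1000`, `ci_high_per_1000`,
#'   `rse`, `suppressed`.  Values are unrounded; see [render_estimate()].
#' @export
#' @examples
#' prevalence(5058, 220281)
prevalence <- function(numerator, denominator, cfg = NULL) {
  cfg <- default_cfg(cfg)
  ci <- wilson_interval(numerator, denominator, cfg)
  rse <- relative_standard_error(numerator, denominator)
  out <- tibble::tibble(
    numerator = numerator,
    denominator = denominator,
    per_1000 = 1000 * numerator / denominator,
    ci_low_per_1000 = ci$low,
    ci_high_per_1000 = ci$high,
    rse = rse,
    suppressed = rse > cfg$rse_threshold)
  class(out) <- c("asdsurv_prevalence_estimate", class(out))
  out
}

#' Prevalence ratio with a log-normal (Katz) interval
#'
#' The ratio of two prevalence estimates, computed from the unrounded
#' per-1,000 values, with the Katz interval
#' `exp(ln R +/- z * sqrt(1/a_num - 1/a_den + 1/b_num - 1/b_den))`.
#' Suppression propagates: a ratio of a suppressed estimate is suppressed.
#'
#' @param a,b [prevalence()] estimates (aligned row-wise); `b` is the
#'   reference (denominator) group and must have a positive numerator.
#' @param cfg an [analysis_config()].
#' @return an `asdsurv_ratio_estimate` tibble with `ratio`, `ci_low`,
#'   `ci_high`, `suppressed` (unrounded).
#' @export
prevalence_ratio <- function(a, b, cfg = NULL) {
  cfg <- default_cfg(cfg)
  if (any(b$numerator == 0)) {
    abort("reference numerator is zero: ratio undefined",
          class = "asdsurv_validation_error")
  }
  ratio <- (a$per_1000) / (b$per_1000)
  se <- sqrt(1 / a$numerator - 1 / a$denominator +
               1 / b$numerator - 1 / b$denominator)
  out <- tibble::tibble(
    ratio = ratio,
    ci_low = exp(log(ratio) - cfg$z * se),
    ci_high = exp(log(ratio) + cfg$z * se),
    suppressed = a$suppressed | b$suppressed)
  out$ci_low[!is.finite(out$ratio)] <- NaN
  out$ci_high[!is.finite(out$ratio)] <- NaN
  class(out) <- c("asdsurv_ratio_estimate", class(out))
  out
}

#' Mark an estimate suppressed when its precision is too low
#'
#' Re-applies the relative-standard-error rule (RSE above the configured
#' threshold) to a prevalence estimate, or propagates component suppression
#' into a ratio estimate.  The reporting layer renders suppressed cells as
#' an em dash.
#'
#' @param estimate a [prevalence()] or [prevalence_ratio()] tibble.
#' @param cfg an [analysis_config()].
#' @return the estimate with its `suppressed` flag set.
#' @export
suppress <- function(estimate, cfg = NULL) {
  cfg <- default_cfg(cfg)
  if ("rse" %in% names(estimate)) {
    estimate$suppressed <- estimate$rse > cfg$rse_threshold
  }
  estimate
}

#' Pearson chi-square test for equality of proportions
#'
#' Pearson's chi-square without continuity correction on a 2 x k count
#' table, as used to compare proportions between groups.
#'
#' @param table 2 x k matrix of nonnegative counts with positive margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_proportions <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) != 2L) {
    abort("`table` must be a 2 x k matrix of nonnegative counts",
          class = "asdsurv_validation_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all row and column margins must be positive",
          class = "asdsurv_validation_error")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Woolf test of homogeneity of prevalence ratios across strata
#'
#' Inverse-variance weighted homogeneity of log prevalence ratios:
#' `w_i = 1 / (1/a_i - 1/n_ai + 1/b_i - 1/n_bi)`, pooled log ratio
#' `sum(w_i log R_i) / sum(w_i)`, statistic
#' `sum(w_i (log R_i - pooled)^2)` on `k - 1` degrees of freedom.  Strata
#' with a zero numerator in either group are excluded with a warning.
#'
#' @param strata data frame (or matrix) with columns `a_num`, `a_den`,
#'   `b_num`, `b_den`: numerator and denominator of the two groups per
#'   stratum.
#' @return list with `statistic`, `df`, `p`, `n_strata` (used).
#' @export
woolf_homogeneity <- function(strata) {
  strata <- as.data.frame(strata)
  needed <- c("a_num", "a_den", "b_num", "b_den")
  stopifnot(all(needed %in% names(strata)))
  usable <- strata$a_num > 0 & strata$b_num > 0
  if (any(!usable)) {
    warn(sprintf("%d stratum/strata with zero numerators excluded from homogeneity test",
                 sum(!usable)))
    strata <- strata[usable, , drop = FALSE]
  }
  k <- nrow(strata)
  if (k < 2) {
    abort("need at least 2 usable strata",
          class = "asdsurv_validation_error")
  }
  lnR <- log((strata$a_num / strata$a_den) / (strata$b_num / strata$b_den))
  w <- 1 / (1 / strata$a_num - 1 / strata$a_den +
              1 / strata$b_num - 1 / strata$b_den)
  pooled <- sum(w * lnR) / sum(w)
  stat <- sum(w * (lnR - pooled)^2)
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, df = k - 1, lower.tail = FALSE), n_strata = k)
}

#' Cochran-Armitage test for trend in prevalence across ordered groups
#'
#' The standard Cochran-Armitage z statistic for binomial proportions with
#' equally spaced scores (0, 1, 2 for the three SES tertiles), with a
#' two-sided p value.  Degenerate inputs (no cases, or all cases) return
#' `z = 0`, `p = 1`.
#'
#' @param cases case counts per ordered group.
#' @param denominators population denominators per group (positive; may be
#'   fractional tract sums).
#' @param scores group scores (default equally spaced `0:(k-1)`).
#' @return list with `z`, `p` (two-sided).
#' @export
cochran_armitage_trend <- function(cases, denominators,
                                   scores = seq_along(cases) - 1) {
  k <- length(cases)
  stopifnot(length(denominators) == k, length(scores) == k)
  if (any(denominators <= 0)) {
    abort("denominators must be positive", class = "asdsurv_validation_error")
  }
  if (any(cases < 0) || any(cases > denominators)) {
    abort("cases must lie in [0, denominator] per group",
          class = "asdsurv_validation_error")
  }
  N <- sum(denominators)
  pbar <- sum(cases) / N
  if (pbar <= 0 || pbar >= 1) return(list(z = 0, p = 1))
  num <- sum(scores * (cases - denominators * pbar))
  v <- pbar * (1 - pbar) *
    (sum(denominators * scores^2) - sum(denominators * scores)^2 / N)
  if (v <= 0) return(list(z = 0, p = 1))
  z <- num / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Permutation test for a difference in medians
#'
#' Tests `|median(x) - median(y)|` by permuting group labels.  Sample
#' medians average the two central order statistics for even sizes.  When
#' the number of distinct label arrangements `choose(nx+ny, nx)` is at most
#' 20,000 the test enumerates all of them exactly; otherwise it draws
#' `n_permutations` Monte-Carlo permutations under the configured seed and
#' uses the add-one estimator `(count + 1) / (B + 1)` so the p value is
#' never zero.
#'
#' @param x,y non-empty numeric samples (ages in months).
#' @param cfg an [analysis_config()] (supplies `n_permutations` and
#'   `permutation_seed`).
#' @param force_monte_carlo use the Monte-Carlo path even when exhaustive
#'   enumeration would be feasible (used to validate the sampler against
#'   the exact distribution).
#' @return list with `statistic` (observed absolute median difference),
#'   `p`, `method` (`"exhaustive"` or `"monte-carlo"`), `n_arrangements`.
#' @export
#' @examples
#' permutation_median_test(c(1, 2), c(10, 11))
permutation_median_test <- function(x, y, cfg = NULL,
                                    force_monte_carlo = FALSE) {
  cfg <- default_cfg(cfg)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty",
          class = "asdsurv_validation_error")
  }
  nx <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  obs <- abs(median(x) - median(y))
  n_arr <- choose(n, nx)
  tol <- 1e-12
  if (n_arr <= 20000 && !force_monte_carlo) {
    idx <- combn(n, nx)
    stats <- apply(idx, 2, function(i) abs(median(pool[i]) -
                                             median(pool[-i])))
    p <- sum(stats >= obs - tol) / n_arr
    return(list(statistic = obs, p = p, method = "exhaustive",
                n_arrangements = n_arr))
  }
  B <- cfg$n_permutations
  count <- with_seed(cfg$permutation_seed, {
    hits <- 0L
    for (b in seq_len(B)) {
      i <- sample.int(n, nx)
      if (abs(median(pool[i]) - median(pool[-i])) >= obs - tol) {
        hits <- hits + 1L
      }
    }
    hits
  })
  list(statistic = obs, p = (count + 1) / (B + 1), method = "monte-carlo",
       n_arrangements = n_arr)
}

#' Render an estimate for reporting
#'
#' Formats a prevalence or ratio estimate as `"rate (low-high)"` with
#' one-decimal half-away-from-zero rounding; suppressed cells render as an
#' em dash.
#'
#' @param estimate a [prevalence()] or [prevalence_ratio()] tibble.
#' @return character vector of formatted cells.
#' @export
render_estimate <- function(estimate) {
  if ("per_1000" %in% names(estimate)) {
    txt <- sprintf("%.1f (%.1f-%.1f)",
                   round_half_away(estimate$per_1000),
                   round_half_away(estimate$ci_low_per_1000),
                   round_half_away(estimate$ci_high_per_1000))
  } else {
    txt <- sprintf("%.1f (%.1f-%.1f)",
                   round_half_away(estimate$ratio),
                   round_half_away(estimate$ci_low),
                   round_half_away(estimate$ci_high))
  }
  ifelse(estimate$suppressed, "—", txt)
}
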