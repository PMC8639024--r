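test_that("prevalence reproduces published site rates from printed counts", {
  cases <- list(list(5058, 220281, 23.0, 22.3, 23.6),
                list(586, 15076, 38.9, 35.9, 42.1),
                list(405, 24481, 16.5, 15.0, 18.2))
  for (cs in cases) {
    est <- prevalence(cs[[1]], cs[[2]])
    expect_equal(round_half_away(est$per_1000), cs[[3]])
    expect_equal(round_half_away(est$ci_low_per_1000), cs[[4]])
    expect_equal(round_half_away(est$ci_high_per_1000), cs[[5]])
    expect_false(est$suppressed)
  }
  z <- prevalence(0, 1000)
  expect_equal(z$per_1000, 0)
  expect_true(z$suppressed)
  expect_equal(z$ci_low_per_1000, 0)
  expect_error(prevalence(1, 0), class = "asdsurv_validation_error")
})

test_that("Wilson bounds agree with score-test inversion to 1e-9", {
  grid <- expand.grid(n = c(10, 47, 133, 500),
                      frac = c(0.01, 0.1, 0.3, 0.5, 0.9, 1))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    x <- round(grid$frac[i] * n)
    got <- wilson_interval(x, n)
    want <- wilson_oracle(x, n)
    expect_equal(got$low, want[1], tolerance = 1e-9)
    expect_equal(got$high, want[2], tolerance = 1e-9)
  }
  expect_equal(wilson_interval(0, 250)$low, 0)
})

test_that("prevalence ratio uses the Katz interval and propagates suppression", {
  m <- prevalence(4111, 220281 * 0.511)
  f <- prevalence(945, 220281 * 0.489)
  r <- prevalence_ratio(m, f)
  expect_equal(round_half_away(r$ratio), 4.2)
  expect_equal(round_half_away(r$ci_low), 3.9)
  expect_equal(round_half_away(r$ci_high), 4.5)

  same <- prevalence_ratio(m, m)
  expect_equal(same$ratio, 1)
  expect_true(same$ci_low < 1 && same$ci_high > 1)

  # reciprocal consistency before rounding
  fwd <- prevalence_ratio(m, f)$ratio
  bwd <- prevalence_ratio(f, m)$ratio
  expect_equal(fwd * bwd, 1, tolerance = 1e-9)

  small <- prevalence(5, 10000)
  expect_true(small$suppressed)
  expect_true(prevalence_ratio(small, f)$suppressed)
  expect_true(prevalence_ratio(f, small)$suppressed)
  expect_error(prevalence_ratio(m, prevalence(0, 100)),
               class = "asdsurv_validation_error")
})

test_that("RSE suppression thresholds behave as the 30% rule implies", {
  expect_true(prevalence(10, 10000)$suppressed)   # rse ~ 31.6%
  expect_false(prevalence(12, 10000)$suppressed)  # rse ~ 28.8%
  expect_equal(relative_standard_error(10, 10000),
               sqrt(0.001 * 0.999 / 10000) / 0.001)
  # monotone: rse strictly decreases in the numerator below n/2
  n <- 5000
  rses <- relative_standard_error(1:100, n)
  expect_true(all(diff(rses) < 0))
  loose <- analysis_config(rse_threshold = 0.5)
  expect_false(suppress(prevalence(10, 10000), loose)$suppressed)
})

test_that("Pearson chi-square matches the direct formula and the z^2 identity", {
  tab <- rbind(c(10, 90), c(20, 80))
  got <- chi_square_proportions(tab)
  # direct sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 1)
  # square of the two-proportion z statistic
  p1 <- 10 / 100; p2 <- 20 / 100; pp <- 30 / 200
  zstat <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(got$statistic, zstat^2, tolerance = 1e-12)

  flat <- rbind(c(30, 70), c(60, 140))
  expect_equal(chi_square_proportions(flat)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square_proportions(flat)$p, 1)
  expect_error(chi_square_proportions(rbind(c(0, 0), c(1, 1))),
               class = "asdsurv_validation_error")
})

test_that("Woolf homogeneity matches a hand computation and is zero for equal ratios", {
  equal <- data.frame(a_num = c(20, 40), a_den = c(1000, 2000),
                      b_num = c(10, 20), b_den = c(1000, 2000))
  expect_equal(woolf_homogeneity(equal)$statistic, 0, tolerance = 1e-12)

  st <- data.frame(a_num = c(12, 30), a_den = c(500, 800),
                   b_num = c(5, 40), b_den = c(600, 700))
  lnR <- log((st$a_num / st$a_den) / (st$b_num / st$b_den))
  w <- 1 / (1 / st$a_num - 1 / st$a_den + 1 / st$b_num - 1 / st$b_den)
  pooled <- sum(w * lnR) / sum(w)
  want <- sum(w * (lnR - pooled)^2)
  got <- woolf_homogeneity(st)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE))

  with_zero <- rbind(st, data.frame(a_num = 0, a_den = 100, b_num = 5,
                                    b_den = 100))
  expect_warning(res <- woolf_homogeneity(with_zero), "excluded")
  expect_equal(res$n_strata, 2)
  expect_error(suppressWarnings(
    woolf_homogeneity(data.frame(a_num = c(1, 0), a_den = c(10, 10),
                                 b_num = c(1, 1), b_den = c(10, 10)))),
    class = "asdsurv_validation_error")
})

test_that("Cochran-Armitage trend agrees with prop.trend.test and the 2x2 identity", {
  cases <- c(30, 45, 70); dens <- c(1000, 1000, 1000)
  got <- cochran_armitage_trend(cases, dens)
  ref <- suppressWarnings(stats::prop.trend.test(cases, dens, score = 0:2))
  expect_equal(got$z^2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)

  # two groups: squared z equals Pearson chi-square on the 2x2
  two <- cochran_armitage_trend(c(10, 25), c(200, 210))
  tab <- rbind(c(10, 190), c(25, 185))
  expect_equal(two$z^2, chi_square_proportions(t(tab))$statistic,
               tolerance = 1e-9)

  flat <- cochran_armitage_trend(c(20, 20, 20), c(500, 500, 500))
  expect_equal(flat$z, 0)
  expect_equal(flat$p, 1)
  expect_equal(cochran_armitage_trend(c(0, 0, 0), c(10, 10, 10))$p, 1)
})

test_that("permutation median test enumerates exactly and handles ties", {
  res <- permutation_median_test(c(1, 2), c(10, 11))
  expect_equal(res$method, "exhaustive")
  expect_equal(res$statistic, 9)
  expect_equal(res$p, 1 / 3)

  ident <- permutation_median_test(c(3, 5, 7), c(5, 3, 7))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)

  expect_equal(median(c(40, 41)), 40.5)  # central averaging, half-months
  expect_error(permutation_median_test(numeric(0), 1:3),
               class = "asdsurv_validation_error")
})

test_that("Monte-Carlo permutation p converges to the exhaustive value", {
  x <- c(31, 35, 40, 44, 52)
  y <- c(45, 50, 58, 61, 66, 70)
  exact <- permutation_median_test(x, y)
  expect_equal(exact$method, "exhaustive")
  cfg <- analysis_config(n_permutations = 200000L, permutation_seed = 42L)
  mc <- permutation_median_test(x, y, cfg, force_monte_carlo = TRUE)
  expect_equal(mc$method, "monte-carlo")
  se <- sqrt(exact$p * (1 - exact$p) / cfg$n_permutations)
  expect_lt(abs(mc$p - exact$p), 3 * se + 2 / cfg$n_permutations)
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(round_half_away(c(0.25, 0.35, -0.25, 2.45)),
               c(0.3, 0.4, -0.3, 2.5))
  expect_equal(round_half_away(22.344), 22.3)
})
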