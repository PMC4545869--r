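expand_2x2 <- function(e1, e0, u1, u0) {
  # exposed: e1 events / e0 non-events; unexposed: u1 / u0
  data.frame(
    y = c(rep(1, e1), rep(0, e0), rep(1, u1), rep(0, u0)),
    x = c(rep(1, e1 + e0), rep(0, u1 + u0)))
}

test_that("the logistic fit matches the closed-form 2x2 log-odds-ratio", {
  d <- expand_2x2(30, 10, 20, 40)
  fit <- fit_logistic(d$y, d$x)
  expect_equal(fit$beta, log(6), tolerance = 1e-6)  # (30*40)/(20*10)
  expect_equal(fit$or, 6, tolerance = 1e-5)
  expect_identical(fit$n_used, 100L)
  # equivariance: rescaling the exposure rescales the coefficient,
  # leaving the Wald p unchanged
  fit10 <- fit_logistic(d$y, d$x * 10)
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-8)
  expect_equal(fit10$p, fit$p, tolerance = 1e-8)
})

test_that("null exposures give near-zero coefficients and degenerate inputs error", {
  set.seed(31)
  y <- rep(c(0, 1), each = 5000)
  x <- rnorm(10000)
  expect_lt(abs(fit_logistic(y, x)$beta), 0.1)
  expect_error(fit_logistic(rep(1, 50), rnorm(50)), "constant")
  expect_error(fit_logistic(c(0, 1), c(1, 2)), "too few")
  # separation is flagged, not silently returned
  ys <- rep(c(0, 1), each = 30)
  xs <- c(rnorm(30, -5), rnorm(30, 5))
  expect_error(fit_logistic(ys, xs), "separation")
  # collinear covariates are named
  set.seed(32)
  xc <- rnorm(100); y2 <- rbinom(100, 1, 0.5)
  expect_error(fit_logistic(y2, xc, covariates = data.frame(c1 = xc)),
               "collinear")
})

test_that("crude-vs-adjusted reports the (adjusted - crude)/crude percent change", {
  # orientation check against printed coefficients: 2.43 -> 2.61 is +7.4%,
  # within half a point of the value derived from unrounded fits (7.49)
  expect_equal(100 * (2.61 - 2.43) / 2.43, 7.49, tolerance = 0.5 / 7.49)
  # a strengthening negative coefficient reports a positive change
  expect_gt(100 * (-1.43 - (-1.18)) / (-1.18), 21)
  set.seed(33)
  n <- 4000
  x <- rnorm(n); z <- rnorm(n)  # covariate independent of exposure
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x))
  res <- crude_vs_adjusted(y, x, data.frame(z = z))
  expect_lt(abs(res$pct_diff_beta), 5)
  expect_gt(res$adjusted_or, 0)
  expect_identical(res$significant, res$adjusted_p < 0.05)
})

test_that("Bonferroni alpha divides the family rate", {
  expect_identical(signif(bonferroni_alpha(62), 3), 8.06e-4)
  expect_identical(bonferroni_alpha(1), 0.05)
  expect_identical(bonferroni_alpha(10), 0.005)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("significance filtering is strict, order-preserving and monotone", {
  p <- c(0.04, 0.05, 0.001, 0.9)
  kept <- significance_filter(p, 0.05)
  expect_identical(as.numeric(kept), c(0.04, 0.001))
  expect_identical(attr(significance_filter(p, 0), "n_retained"), 0L)
  # elementwise oracle on a random vector
  set.seed(34)
  pv <- runif(200)
  for (alpha in c(0.01, 0.2, 0.5)) {
    kept <- significance_filter(pv, alpha)
    oracle <- pv[vapply(pv, function(z) z < alpha, logical(1))]
    expect_identical(as.numeric(kept), oracle)
  }
  # monotone in alpha
  counts <- vapply(seq(0, 1, by = 0.1), function(a)
    attr(significance_filter(pv, a), "n_retained"), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(significance_filter(c(0.5, 1.2), 0.05), "invalid")
})

test_that("the prevalence chi-square matches its oracle and printed value", {
  tab <- matrix(c(24, 77, 18, 25), 2)  # high-IgE: females 24/77, males 18/25
  res <- prevalence_chi2(tab)
  expect_equal(round(res$p_value, 3), 0.047)
  # independent oracle: stats::chisq.test
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  # perfectly balanced table: corrected statistic clamps to zero
  flat <- prevalence_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_identical(flat$statistic, 0)
  expect_identical(flat$p_value, 1)
  # uncorrected statistic against the hand formula n(ad-bc)^2/(r1 r2 c1 c2)
  tab2 <- matrix(c(76, 166, 49, 71), 2, byrow = TRUE)
  res2 <- prevalence_chi2(tab2, continuity_correction = FALSE)
  hand <- 362 * (76 * 71 - 166 * 49)^2 / (242 * 120 * 125 * 237)
  expect_equal(res2$statistic, hand, tolerance = 1e-12)
  ct2 <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE))
  expect_equal(res2$statistic, unname(ct2$statistic), tolerance = 1e-10)
  expect_error(prevalence_chi2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(prevalence_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("the association scan tests every probe and logs failures", {
  set.seed(35)
  n <- 120; p <- 8L
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%03d", 1:p), sprintf("S%03d", 1:n)))
  y <- rbinom(n, 1, plogis(1.5 * m[1, ]))   # probe 1 carries signal
  covs <- data.frame(z = rnorm(n))
  scan <- test_associations(m, y, covs, outcome_name = "atopy")
  expect_identical(nrow(scan), p)
  expect_equal(attr(scan, "alpha"), 0.05 / p)
  expect_true(all(scan$wald_p > 0 & scan$wald_p <= 1))
  expect_identical(scan$significant, scan$wald_p < 0.05 / p)
  expect_lt(scan$wald_p[scan$probe_id == "cg001"], 0.05 / p)
  # a probe with a separating exposure is skipped and logged
  m2 <- m
  m2[2, ] <- ifelse(y == 1, 100, -100)
  scan2 <- test_associations(m2, y, covs)
  expect_identical(nrow(scan2), p - 1L)
  expect_identical(attr(scan2, "skipped")$probe_id, "cg002")
})

test_that("Bonferroni control holds over null probes across replicates", {
  set.seed(36)
  m_tests <- 20; n <- 120; reps <- 200
  any_fp <- logical(reps)
  for (r in seq_len(reps)) {
    y <- rbinom(n, 1, 0.4)
    covs <- data.frame(z = rnorm(n))
    alpha <- bonferroni_alpha(m_tests)
    pvals <- vapply(seq_len(m_tests), function(j)
      fit_logistic(y, rnorm(n), covs)$p, numeric(1))
    any_fp[r] <- any(pvals < alpha)
  }
  # FWER <= 0.05 within binomial tolerance (3 sigma at 200 replicates)
  expect_lte(mean(any_fp), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
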