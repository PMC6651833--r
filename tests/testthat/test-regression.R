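test_that("OLS reproduces the hand-computed worked example", {
  fit <- fit_ols(worked_points())
  expect_equal(fit$B, 0.9)
  expect_equal(fit$A, 1.3)
  expect_equal(fit$r, 0.9)
  expect_equal(fit$r2, 0.81)
  expect_equal(fit$n, 5L)
  # cross-check against the base linear-model fitter
  lm_fit <- stats::lm(y ~ x, data.frame(x = c(1, 2, 3, 4, 5),
                                        y = c(2, 3, 5, 4, 6)))
  expect_equal(fit$B, unname(coef(lm_fit)[2]))
  expect_equal(fit$A, unname(coef(lm_fit)[1]))
  expect_equal(fit$se_B, unname(sqrt(diag(vcov(lm_fit)))[2]))
  expect_equal(fit$se_A, unname(sqrt(diag(vcov(lm_fit)))[1]))
})

test_that("SMA, MA and RMA reproduce the worked example", {
  d <- worked_points()
  sma <- fit_sma(d)
  expect_equal(sma$B, 1.0)
  expect_equal(sma$A, 1.0)
  ma <- fit_ma(d)
  expect_equal(ma$B, 1.0)  # Syy = Sxx puts the major axis at 45 degrees
  expect_equal(ma$A, 1.0)
  # RMA = MA on range-normalized data, back-transformed by range_y/range_x
  rma <- fit_rma(d)
  rx <- diff(range(d$x)); ry <- diff(range(d$y))
  dn <- bivariate_data(d$x / rx, d$y / ry)
  expect_equal(rma$B, fit_ma(dn)$B * ry / rx)
})

test_that("an exact line is recovered identically by all four methods", {
  d <- bivariate_data(c(-1, 0, 2, 5), 2 * c(-1, 0, 2, 5) + 1)
  for (f in list(fit_ols, fit_sma, fit_ma, fit_rma)) {
    fit <- f(d)
    expect_equal(fit$B, 2, tolerance = 1e-12)
    expect_equal(fit$A, 1, tolerance = 1e-12)
    expect_equal(fit$r, 1)
  }
})

test_that("degenerate inputs are refused with informative errors", {
  expect_error(fit_ols(bivariate_data(c(2, 2, 2), c(1, 2, 3))),
               "zero variance")
  expect_error(fit_ols(bivariate_data(c(1, 2), c(1, 2))), "insufficient")
  expect_error(fit_sma(bivariate_data(1:5, rep(3, 5))), "zero variance")
  # zero covariance: SMA sign and MA orientation undefined
  d0 <- bivariate_data(c(-1, 0, 1, 0), c(0, 1, 0, -1))
  expect_error(fit_ma(d0), "undefined")
  expect_error(fit_sma(d0, require_significance = FALSE), "undefined|zero")
})

test_that("non-finite rows are dropped and counted on ingestion", {
  d <- bivariate_data(c(1, 2, NA, 4, 5, 6), c(2, NaN, 3, 8, 10, Inf))
  expect_equal(d$n, 3L)
  expect_equal(d$n_dropped, 3L)
})

test_that("the SMA significance gate refuses uncorrelated data", {
  set.seed(42)
  x <- rnorm(30)
  y <- sample(x)  # shuffled: r near 0
  d <- bivariate_data(x, y)
  expect_true(abs(d |> fit_ols() |> getElement("r")) < 0.3)
  expect_error(fit_sma(d), "not significant")
  expect_s3_class(fit_sma(d, require_significance = FALSE), "linear_fit")
})

test_that("correlation significance matches the closed-form t test", {
  g <- correlation_significance(worked_points(), alpha = 0.05)
  expect_equal(g$t, 0.9 * sqrt(3) / sqrt(1 - 0.81), tolerance = 1e-12)
  expect_equal(g$t, 3.576237, tolerance = 1e-6)
  expect_equal(g$p, 0.0373861, tolerance = 1e-5)
  expect_true(g$significant)
  expect_equal(g$df, 3L)
  # agreement with the base correlation test
  ct <- stats::cor.test(c(1, 2, 3, 4, 5), c(2, 3, 5, 4, 6))
  expect_equal(g$p, unname(ct$p.value))

  perfect <- correlation_significance(bivariate_data(1:4, 2 * (1:4) + 1))
  expect_true(perfect$significant)
  expect_true(perfect$degenerate)
  expect_equal(perfect$t, Inf)
})

test_that("OLS and MA match their numeric-minimizer oracles", {
  for (seed in 1:8) {
    d <- random_dataset(seed)
    ols <- fit_ols(d)
    ov <- oracle_vertical(d$x, d$y)
    expect_equal(ols$B, ov$B, tolerance = 1e-6)
    expect_equal(ols$A, ov$A, tolerance = 1e-6)
    ma <- fit_ma(d)
    op <- oracle_perpendicular(d$x, d$y)
    expect_equal(ma$B, op$B, tolerance = 1e-6)
    expect_equal(ma$A, op$A, tolerance = 1e-6)
  }
})

test_that("closed-form identities hold on random datasets", {
  for (seed in 1:20) {
    d <- random_dataset(seed)
    ols <- fit_ols(d)
    sma <- fit_sma(d, require_significance = FALSE)
    ma <- fit_ma(d)
    rma <- fit_rma(d)
    # B_SMA = B_OLS / |r| (reduces to B_OLS / r for positive correlation)
    expect_equal(sma$B, ols$B / abs(ols$r), tolerance = 1e-12)
    # attenuation: |B_OLS| <= |B_SMA|
    expect_lte(abs(ols$B), abs(sma$B) + 1e-12)
    # every line passes through the centroid
    for (fit in list(ols, sma, ma, rma)) {
      expect_equal(fit$B * mean(d$x) + fit$A, mean(d$y), tolerance = 1e-10)
    }
    # r and r2 do not depend on the method
    expect_identical(ols$r, sma$r)
    expect_identical(ols$r2, ma$r2)
    expect_identical(ols$r2, rma$r2)
  }
})

test_that("SMA is symmetric under axis swap; OLS is not", {
  d <- worked_points()
  dsw <- bivariate_data(d$y, d$x)
  expect_equal(fit_sma(d)$B, 1 / fit_sma(dsw)$B, tolerance = 1e-12)
  # counterexample: OLS slopes are not reciprocal unless |r| = 1
  expect_false(isTRUE(all.equal(fit_ols(d)$B, 1 / fit_ols(dsw)$B)))
  # MA geometric invariance: swapped slope is the reciprocal
  expect_equal(fit_ma(d)$B, 1 / fit_ma(dsw)$B, tolerance = 1e-12)
})

test_that("SMA converges to OLS monotonically as noise vanishes", {
  set.seed(7)
  x <- rnorm(200)
  eps <- rnorm(200)
  gaps <- vapply(c(1, 0.5, 0.25, 0.1, 0.05, 0.01), function(s) {
    d <- bivariate_data(x, 2 * x + 1 + s * eps)
    abs(fit_sma(d)$B - fit_ols(d)$B)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 1e-3)
})

test_that("RMA is sensitive to a single extreme outlier", {
  d <- worked_points()
  d_out <- bivariate_data(c(d$x, 6), c(d$y, 60))
  base <- fit_rma(d)$B
  shifted <- fit_rma(d_out)$B
  expect_gt(abs(shifted - base) / abs(base), 0.2)
})

test_that("fit_methods tabulates fits and records refusals", {
  tab <- fit_methods(worked_points(), c("OLS", "SMA", "MA", "RMA"))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$B, c(0.9, 1, 1, 1))
  expect_true(all(tab$note == ""))
  set.seed(4)
  x <- rnorm(20)
  bad <- bivariate_data(x, sample(x))
  tab2 <- fit_methods(bad, c("OLS", "SMA"))
  expect_true(is.na(tab2$B[tab2$method == "SMA"]))
  expect_match(tab2$note[tab2$method == "SMA"], "not significant")
})
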