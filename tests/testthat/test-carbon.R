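test_that("bbp_k is the intercept of the TChla->bbp fit, per method", {
  # noise-free line: both methods recover the true background exactly
  tchla <- c(0.05, 0.2, 0.5, 1, 2, 3)
  bbp <- 2.0e-3 * tchla + 5.0e-4
  d <- bivariate_data(tchla, bbp, labels = c("TChla", "bbp700"))
  for (m in c("OLS", "SMA")) {
    p <- derive_bbpk(d, m)
    expect_equal(p$bbp_k, 5.0e-4, tolerance = 1e-12)
    expect_equal(p$method, m)
  }
})

test_that("errors-in-x attenuation raises the OLS intercept above SMA's", {
  scn <- bivariate_scenario(b_true = 2.0e-3, a_true = 5.0e-4, n = 5000,
                            seed = 11, x_family = "lognormal",
                            x_location = log(0.4), x_scale = 0.8,
                            sd_x = 0.15, sd_y = 3e-4,
                            labels = c("TChla", "bbp700"))
  mu <- gen_matchups(scn)
  d <- matchups_bivariate(mu)
  p_ols <- derive_bbpk(d, "OLS")
  p_sma <- derive_bbpk(d, "SMA")
  # the attenuated OLS slope tilts the intercept upward; SMA overshoots
  # the slope and lands below
  expect_gt(p_ols$bbp_k, p_sma$bbp_k)
  # OLS intercept within ~3 standard errors of its closed-form expectation
  vx <- var(mu$x_true)
  b_att <- 2.0e-3 * vx / (vx + scn$sd_x^2)
  a_exp <- (2.0e-3 * mean(mu$x_true) + 5.0e-4) - b_att * mean(mu$x_true)
  expect_lt(abs(p_ols$bbp_k - a_exp), 3 * p_ols$se_bbp_k)
})

test_that("derive_bbpk refuses interchanged variables and gates SMA", {
  d_rev <- bivariate_data(c(1e-3, 2e-3, 3e-3), c(0.1, 0.2, 0.3),
                          labels = c("bbp700", "TChla"))
  expect_error(derive_bbpk(d_rev, "OLS"), "interchanged|orientation")
  set.seed(5)
  x <- rlnorm(40)
  noise <- bivariate_data(x, sample(2e-3 * x) + 5e-4,
                          labels = c("TChla", "bbp700"))
  expect_error(derive_bbpk(noise, "SMA"), "not significant")
})

test_that("a negative fitted background is flagged with a warning", {
  tchla <- c(0.5, 1, 1.5, 2, 3)
  bbp <- 2e-3 * tchla - 1e-4
  d <- bivariate_data(tchla, bbp, labels = c("TChla", "bbp700"))
  expect_warning(p <- derive_bbpk(d, "OLS"), "negative")
  expect_true(p$negative_intercept)
})

test_that("SF calibration follows the mean chlorophyll-to-carbon target", {
  # single-sample arithmetic
  expect_equal(calibrate_sf(0.2, 1.5e-3, bbp_k = 5e-4)$sf, 20000)
  # inverse construction: every sample at ratio 164.55 -> SF = 16455
  tchla <- c(0.1, 0.3, 0.8, 1.5, 2.5)
  bbp <- 5.5e-4 + tchla / 164.55
  cal <- calibrate_sf(tchla, bbp, bbp_k = 5.5e-4)
  expect_equal(cal$sf, 16455, tolerance = 1e-10)
  # samples at or below the background are excluded and counted
  cal2 <- calibrate_sf(c(tchla, 0.2), c(bbp, 5.5e-4), bbp_k = 5.5e-4)
  expect_equal(cal2$n_used, 5L)
  expect_equal(cal2$n_excluded, 1L)
  expect_equal(cal2$sf, cal$sf)
  expect_error(calibrate_sf(0.2, 4e-4, bbp_k = 5e-4), "no valid samples")
})

test_that("calibrated SF reproduces the target Chl:C on synthetic truth", {
  scn <- tchla_bbp_scenario(seed = 3, n = 2000)
  mu <- gen_matchups(scn)
  cal <- calibrate_sf(mu$TChla, mu$bbp700, bbp_k = scn$a_true)
  p <- carbon_model_params(700, scn$a_true, cal$sf)
  cp <- cphyto_from_bbp(mu$bbp700, p)
  ok <- as.numeric(cp) > 0
  chl_to_c <- mean(mu$TChla[ok] / as.numeric(cp)[ok])
  expect_equal(chl_to_c, 0.010, tolerance = 0.02)
})

test_that("C_phyto arithmetic, clamping and flags behave as specified", {
  p <- carbon_model_params(700, bbp_k = 5.8e-4, sf = 16455)
  expect_equal(as.numeric(cphyto_from_bbp(2.0e-3, p)), 23.3661,
               tolerance = 1e-6)
  expect_equal(as.numeric(cphyto_from_bbp(5.8e-4, p)), 0)
  low <- cphyto_from_bbp(4e-4, p)
  expect_lt(as.numeric(low), 0)
  expect_true(attr(low, "negative"))
  clamped <- cphyto_from_bbp(4e-4, p, clamp_negative = TRUE)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "negative"))
  expect_warning(cphyto_from_bbp(2e-3, p, wavelength = 443), "mismatch")
})

test_that("POC model fits reproduce the rescaled worked example", {
  d <- bivariate_data(c(1, 2, 3, 4, 5) * 1e-3, c(20, 30, 50, 40, 60),
                      labels = c("bbp700", "POC"))
  ols <- fit_poc_model(d, "OLS")
  expect_equal(ols$B, 9000)
  expect_equal(ols$A, 13)
  sma <- fit_poc_model(d, "SMA")
  expect_equal(sma$B, 10000)
  expect_equal(sma$A, 10)
  # |B_OLS| = |r| * |B_SMA| makes the OLS slope lower whenever r < 1
  expect_lt(ols$B, sma$B)
  # noise-free identity: fitting then predicting is the identity on (A, B)
  d0 <- bivariate_data(c(1, 2, 4, 8) * 1e-3, 4e4 * c(1, 2, 4, 8) * 1e-3 + 10)
  for (m in c("SMA", "OLS")) {
    p <- fit_poc_model(d0, m)
    expect_equal(p$B, 4e4, tolerance = 1e-9)
    expect_equal(p$A, 10, tolerance = 1e-9)
    expect_equal(poc_from_bbp(d0$x, p), d0$y, tolerance = 1e-9)
  }
})

test_that("POC predictions are linear in the parameters", {
  expect_equal(poc_from_bbp(0, poc_model_params(700, 10000, 10)), 10)
  expect_equal(poc_from_bbp(2e-3, poc_model_params(700, 10000, 10)), 30)
  d <- bivariate_data(c(1, 2, 3, 4, 5) * 1e-3, c(20, 30, 50, 40, 60),
                      labels = c("bbp700", "POC"))
  p_ols <- fit_poc_model(d, "OLS")
  p_sma <- fit_poc_model(d, "SMA")
  bbp <- seq(5e-4, 5e-3, length.out = 20)
  diff_direct <- poc_from_bbp(bbp, p_ols) - poc_from_bbp(bbp, p_sma)
  diff_closed <- (p_ols$B - p_sma$B) * bbp + (p_ols$A - p_sma$A)
  expect_equal(diff_direct, diff_closed, tolerance = 1e-12)
})

test_that("a non-positive POC slope is warned about", {
  expect_warning(poc_model_params(700, B = -5, A = 50), "not physically")
})

test_that("model parameters serialize to JSON with provenance", {
  p <- carbon_model_params(700, 5.8e-4, 16455, method = "OLS")
  js <- jsonlite::fromJSON(params_json(p))
  expect_equal(js$bbp_k, 5.8e-4)
  expect_equal(js$method, "OLS")
  expect_equal(js$sf, 16455)
})
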