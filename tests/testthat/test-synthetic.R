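test_that("generators are bit-identical under a fixed seed", {
  scn <- tchla_bbp_scenario(seed = 99, n = 50)
  expect_identical(gen_matchups(scn), gen_matchups(scn))
  ps <- profile_scenario(n_casts = 4, seed = 99)
  a <- gen_profile_series(ps); b <- gen_profile_series(ps)
  expect_identical(lapply(a$profiles, `[`, c("depth", "value")),
                   lapply(b$profiles, `[`, c("depth", "value")))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  g <- bivariate_scenario(2e-3, 5e-4, n = 24, seed = 99, sd_y = 1e-4)
  expect_identical(gen_gridded_series(g, 24), gen_gridded_series(g, 24))
})

test_that("zero error gives an exact line that every fit recovers", {
  scn <- bivariate_scenario(b_true = 2, a_true = 1, n = 20, seed = 5,
                            x_family = "gaussian", x_location = 3)
  mu <- gen_matchups(scn)
  expect_equal(mu$x, mu$x_true)
  d <- matchups_bivariate(mu)
  for (f in list(fit_ols, fit_sma, fit_ma)) {
    expect_equal(f(d)$B, 2, tolerance = 1e-12)
    expect_equal(f(d)$A, 1, tolerance = 1e-10)
  }
})

test_that("generated moments match their closed forms", {
  # x* ~ N(0,1), B=2, A=0, sd_x=0.25, sd_y=0.5:
  # Var(x_obs) = 1.0625, Var(y_obs) = 4*1 + 0.25 = 4.25
  scn <- bivariate_scenario(b_true = 2, a_true = 0, n = 10000, seed = 8,
                            x_family = "gaussian", sd_x = 0.25, sd_y = 0.5)
  mu <- gen_matchups(scn)
  expect_equal(var(mu$x), 1.0625, tolerance = 0.05)
  expect_equal(var(mu$y), 4.25, tolerance = 0.05)
  # within 3 standard errors in most seeded replicates
  hits <- vapply(1:40, function(s) {
    m <- gen_matchups(bivariate_scenario(2, 0, n = 400, seed = s,
                                         x_family = "gaussian",
                                         sd_x = 0.25, sd_y = 0.5))
    se_var <- 1.0625 * sqrt(2 / (400 - 1))  # SE of a normal sample variance
    abs(var(m$x) - 1.0625) < 3 * se_var
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("attenuation scenario: OLS is diluted, SMA recovers the slope", {
  ols <- numeric(10); sma <- numeric(10)
  for (s in 1:10) {
    mu <- gen_matchups(bivariate_scenario(2, 0, n = 10000, seed = 300 + s,
                                          x_family = "gaussian",
                                          sd_x = 0.25, sd_y = 0.5))
    d <- matchups_bivariate(mu)
    ols[s] <- fit_ols(d)$B
    sma[s] <- fit_sma(d)$B
  }
  expect_equal(mean(ols), 2 / 1.0625, tolerance = 0.02)
  expect_equal(mean(sma), 2, tolerance = 0.02)
})

test_that("positivity redraws keep physical variables non-negative", {
  scn <- bivariate_scenario(b_true = 2e-3, a_true = 1e-4, n = 500, seed = 3,
                            x_family = "lognormal", x_location = log(0.05),
                            x_scale = 0.5, sd_x = 0.02, sd_y = 3e-4,
                            require_positive = TRUE,
                            labels = c("TChla", "bbp700"))
  mu <- gen_matchups(scn)
  expect_true(all(mu$TChla >= 0))
  expect_true(all(mu$bbp700 >= 0))
  expect_gt(attr(mu, "n_redrawn"), 0)
})

test_that("outlier rows are marked and inflate the scatter", {
  scn <- bivariate_scenario(1, 0, n = 400, seed = 12,
                            x_family = "gaussian", sd_x = 0.1, sd_y = 0.1,
                            outlier_fraction = 0.05, outlier_inflation = 20)
  mu <- gen_matchups(scn)
  expect_equal(sum(mu$outlier), 20)
  res <- abs(mu$y - mu$y_true)
  expect_gt(mean(res[mu$outlier]), 3 * mean(res[!mu$outlier]))
})

test_that("the float grid follows the three-segment resolution spec", {
  g <- argo_grid()
  expect_true(all(diff(g) > 0))
  expect_equal(diff(g)[g[-length(g)] < 10][1], 0.2, tolerance = 1e-12)
  expect_true(all(abs(diff(g[g >= 11 & g <= 250]) - 1) < 1e-12))
  expect_true(all(abs(diff(g[g >= 260]) - 10) < 1e-12))
  expect_equal(max(g), 1000)
})

test_that("the default float series matches the sampling envelope", {
  scn <- profile_scenario(seed = 17)
  expect_equal(scn$n_casts, 87L)
  # ~87 casts at ~5.4-day cadence spans about 15 months
  span_days <- (scn$n_casts - 1) * scn$cadence_days
  expect_gt(span_days, 14 * 30)
  expect_lt(span_days, 16 * 30)
  ser <- gen_profile_series(profile_scenario(n_casts = 5, seed = 17))
  expect_s3_class(ser, "profile_series")
  truth <- attr(ser, "truth")
  expect_length(truth, 5)
  # spike truth is recorded and spikes are strictly positive additions
  for (k in seq_along(truth)) {
    idx <- truth[[k]]$spike_index
    if (length(idx) > 0) {
      expect_true(all(ser$profiles[[k]]$value[idx] >
                        truth[[k]]$baseline[idx]))
    }
  }
})

test_that("noise- and spike-free profiles are smooth and left untouched", {
  ser <- gen_profile_series(profile_scenario(n_casts = 2, seed = 1,
                                             noise_sd = 0, spike_rate = 0))
  p <- ser$profiles[[1]]
  expect_equal(p$value, attr(ser, "truth")[[1]]$baseline)
  expect_equal(despike(p)$n, p$n)
})

test_that("gridded series hits the requested r2 and its edge cases", {
  scn <- bivariate_scenario(2.3e-3, 8.5e-4, n = 216, seed = 31,
                            x_location = log(0.25), x_scale = 0.35,
                            sd_y = 2e-4, labels = c("TChla", "bbp443"))
  g <- gen_gridded_series(scn, n_months = 216, target_r2 = 0.56)
  expect_equal(nrow(g), 216)
  r2 <- attr(g, "realized_r2")
  expect_equal(r2, 0.56, tolerance = 0.05)
  expect_equal(cor(g$tchla, g$bbp)^2, r2, tolerance = 1e-12)
  # zero noise -> perfect correlation
  scn0 <- bivariate_scenario(2.3e-3, 8.5e-4, n = 24, seed = 31, sd_y = 0,
                             x_location = log(0.25), x_scale = 0.35)
  expect_equal(attr(gen_gridded_series(scn0, 24), "realized_r2"), 1)
  # no signal: tuning is infeasible; untuned fit fails the SMA gate
  flat <- bivariate_scenario(0, 8.5e-4, n = 120, seed = 31, sd_y = 2e-4,
                             x_location = log(0.25), x_scale = 0.35)
  expect_error(gen_gridded_series(flat, 120, target_r2 = 0.5), "infeasible")
  g0 <- gen_gridded_series(flat, 120)
  expect_lt(attr(g0, "realized_r2"), 0.1)
  expect_error(fit_sma(bivariate_data(g0$tchla, g0$bbp)), "not significant")
})

test_that("match-up tables round-trip through CSV with truth sidecar", {
  mu <- gen_matchups(tchla_bbp_scenario(seed = 2, n = 30))
  path <- tempfile(fileext = ".csv")
  write_matchups(mu, path)
  back <- read_bivariate(path, "TChla", "bbp700")
  expect_equal(back$x, mu$TChla)
  expect_equal(back$y, mu$bbp700)
  truth <- jsonlite::fromJSON(paste0(path, ".truth.json"))
  expect_equal(truth$b_true, 6.1e-3)
  expect_equal(truth$seed, 2)
  unlink(c(path, paste0(path, ".truth.json")))
})
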