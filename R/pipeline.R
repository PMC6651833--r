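#' @title End-to-end reference analysis
#' @description
#' Orchestration of the full chain on synthetic stand-ins for the three
#' observing systems: cruise bottle match-ups (to derive the carbon model
#' parameters under both OLS and SMA), a float profile series (to measure
#' the budget impact of the method choice on C_phyto and POC), and a
#' gridded monthly ocean-colour-like series (to measure the impact on a
#' satellite C_phyto time series). Everything is a deterministic function
#' of one integer seed.
#' @name pipeline
NULL

#' Despike every cast of a profile series
#'
#' @param series A [profile_series].
#' @param ... Passed to [despike()].
#' @return The despiked series; attribute `n_spikes_removed` totals the
#'   removed points.
#' @export
despike_series <- function(series, ...) {
  stopifnot(inherits(series, "profile_series"))
  cleaned <- lapply(series$profiles, despike, ...)
  n_rm <- sum(vapply(cleaned, function(p) length(attr(p, "spike_index")),
                     numeric(1)))
  out <- profile_series(cleaned, platform = series$platform)
  attr(out, "truth") <- attr(series, "truth")
  attr(out, "n_spikes_removed") <- n_rm
  out
}

#' Percent increase of a recalibrated constant over its original value
#'
#' Reported truncated to whole percent, the convention used for quoting a
#' scaling-factor recalibration (e.g., 16455 over 13000 is "26% more").
#'
#' @param new,original The two values (original non-zero).
#' @param truncate Truncate toward zero to a whole percent (default TRUE).
#' @return The percent increase.
#' @examples
#' percent_increase(16455, 13000)  # 26
#' @export
percent_increase <- function(new, original, truncate = TRUE) {
  if (original == 0) stop("original value must be non-zero")
  p <- 100 * (new - original) / original
  if (truncate) trunc(p) else p
}

#' Run the full synthetic reference analysis
#'
#' Generates cruise-style TChla-b_bp and b_bp-POC match-ups, derives the
#' background backscattering `bbp_k` under OLS and SMA, calibrates the
#' carbon scaling factor SF on the OLS parameterization (shared by both
#' branches), fits the POC model under both methods, generates and
#' despikes a float-like profile series, compares depth/time-integrated
#' C_phyto and POC budgets under the two parameterizations, repeats the
#' C_phyto comparison on a cruise-like 0-400 m cast series, and runs the
#' satellite-style analysis on a gridded monthly series tuned to the
#' target correlation. Sub-seeds are derived from `seed` so the whole
#' report is reproducible from one integer.
#'
#' @param seed Integer master seed.
#' @param n_matchups Cruise match-ups per relationship.
#' @param n_casts Float casts.
#' @param n_cruise_casts Cruise casts (0-400 m).
#' @param n_months Months in the gridded series.
#' @param target_chl_to_c Chl:C target for the SF calibration.
#' @param target_r2 Sample r2 the gridded series is tuned to.
#' @param sf_satellite SF applied to the satellite-style series, mg C m-2
#'   (the original 443 nm constant by default).
#' @param sf_original Reference SF for the percent-increase diagnostic.
#' @param z_range_float,z_range_cruise Depth integration ranges, m.
#' @return A list of class `carbon_method_report` (see the README for a
#'   walk-through of its fields).
#' @export
run_reference_analysis <- function(seed = 1,
                                   n_matchups = 300,
                                   n_casts = 87,
                                   n_cruise_casts = 27,
                                   n_months = 216,
                                   target_chl_to_c = 0.010,
                                   target_r2 = 0.56,
                                   sf_satellite = 13000,
                                   sf_original = 13000,
                                   z_range_float = c(0, 250),
                                   z_range_cruise = c(0, 400)) {
  seed <- as.integer(seed)

  ## --- cruise match-ups and model parameters -------------------------
  chl_mu <- gen_matchups(tchla_bbp_scenario(seed + 1L, n = n_matchups))
  chl_d <- matchups_bivariate(chl_mu)
  bbpk_ols <- derive_bbpk(chl_d, "OLS")
  bbpk_sma <- derive_bbpk(chl_d, "SMA")
  sf_cal <- calibrate_sf(chl_mu[[1]], chl_mu[[2]], bbpk_ols,
                         target_chl_to_c = target_chl_to_c)
  cp_ols <- carbon_model_params(700, bbpk_ols$bbp_k, sf_cal$sf,
                                method = "OLS",
                                se_bbp_k = bbpk_ols$se_bbp_k)
  cp_sma <- carbon_model_params(700, bbpk_sma$bbp_k, sf_cal$sf,
                                method = "SMA",
                                se_bbp_k = bbpk_sma$se_bbp_k)

  poc_mu <- gen_matchups(bbp_poc_scenario(seed + 2L, n = n_matchups))
  poc_d <- matchups_bivariate(poc_mu)
  poc_sma <- fit_poc_model(poc_d, "SMA")
  poc_ols <- fit_poc_model(poc_d, "OLS")

  # diagnostic: mean phytoplankton contribution to POC over the chl
  # match-ups (the +-30% consistency check, reported, not constrained)
  cp_mu <- cphyto_from_bbp(chl_mu[[2]], cp_ols)
  poc_mu_est <- poc_from_bbp(chl_mu[[2]], poc_sma)
  cphyto_to_poc <- mean(as.numeric(cp_mu) / poc_mu_est)

  ## --- float series budgets ------------------------------------------
  float_raw <- gen_profile_series(profile_scenario(n_casts = n_casts,
                                                   seed = seed + 3L))
  float <- despike_series(float_raw)
  cphyto_float <- compare_budgets(float, cp_ols, cp_sma, "cphyto",
                                  z_range = z_range_float)
  poc_float <- compare_budgets(float, poc_sma, poc_ols, "poc",
                               z_range = z_range_float)
  ratio_suitable <- cphyto_float$integral_suitable /
    poc_float$integral_suitable
  ratio_unsuitable <- cphyto_float$integral_unsuitable /
    poc_float$integral_unsuitable
  ratio_rpd <- rpd(ratio_unsuitable, ratio_suitable)

  ## --- cruise-like 0-400 m casts -------------------------------------
  cruise <- gen_profile_series(profile_scenario(
    n_casts = n_cruise_casts, cadence_days = 30.4,
    grid = seq(0, 400, by = 1), spike_rate = 0, seed = seed + 4L))
  cphyto_cruise <- compare_budgets(cruise, cp_ols, cp_sma, "cphyto",
                                   z_range = z_range_cruise)

  ## --- satellite-style gridded series --------------------------------
  sat_scn <- bivariate_scenario(
    b_true = 2.3e-3, a_true = 8.5e-4, n = n_months, seed = seed + 5L,
    x_family = "lognormal", x_location = log(0.25), x_scale = 0.35,
    sd_y = 2e-4, labels = c("TChla", "bbp443"))
  grid_mu <- gen_gridded_series(sat_scn, n_months = n_months,
                                target_r2 = target_r2)
  grid_d <- bivariate_data(grid_mu$tchla, grid_mu$bbp,
                           labels = c("TChla", "bbp443"))
  sat_ols <- derive_bbpk(grid_d, "OLS", wavelength = 443)
  sat_sma <- derive_bbpk(grid_d, "SMA", wavelength = 443)
  sat_p_ols <- carbon_model_params(443, sat_ols$bbp_k, sf_satellite, "OLS")
  sat_p_sma <- carbon_model_params(443, sat_sma$bbp_k, sf_satellite, "SMA")
  sat_cmp <- compare_series_means(grid_mu$bbp, sat_p_ols, sat_p_sma,
                                  "cphyto")

  structure(
    list(
      seed = seed,
      config = list(n_matchups = n_matchups, n_casts = n_casts,
                    n_cruise_casts = n_cruise_casts, n_months = n_months,
                    target_chl_to_c = target_chl_to_c,
                    target_r2 = target_r2, sf_satellite = sf_satellite,
                    z_range_float = z_range_float,
                    z_range_cruise = z_range_cruise),
      fits = list(
        tchla_bbp = fit_methods(chl_d, c("OLS", "SMA")),
        bbp_poc = fit_methods(poc_d, c("OLS", "SMA"))),
      bbpk = c(OLS = bbpk_ols$bbp_k, SMA = bbpk_sma$bbp_k),
      sf = sf_cal$sf,
      sf_percent_increase = percent_increase(sf_cal$sf, sf_original,
                                             truncate = FALSE),
      cphyto_to_poc_mean_ratio = cphyto_to_poc,
      poc_model = list(SMA = poc_sma[c("B", "A")],
                       OLS = poc_ols[c("B", "A")]),
      n_spikes_removed = attr(float, "n_spikes_removed"),
      cphyto_float = cphyto_float,
      poc_float = poc_float,
      ratio_rpd = ratio_rpd,
      cphyto_cruise = cphyto_cruise,
      satellite = list(
        realized_r2 = attr(grid_mu, "realized_r2"),
        bbpk = c(OLS = sat_ols$bbp_k, SMA = sat_sma$bbp_k),
        mean_difference = sat_cmp$mean_difference,
        percent_of_mean = sat_cmp$percent_of_mean)
    ),
    class = "carbon_method_report"
  )
}

#' @export
print.carbon_method_report <- function(x, ...) {
  cat("<carbon_method_report> seed", x$seed, "\n")
  cat(sprintf("  cruise bbp_k: OLS %.4g, SMA %.4g m-1; SF %.0f mg C m-2\n",
              x$bbpk["OLS"], x$bbpk["SMA"], x$sf))
  cat(sprintf("  float C_phyto RPD %+.1f%%; POC RPD %+.1f%%; ratio RPD %+.1f%%\n",
              x$cphyto_float$rpd, x$poc_float$rpd, x$ratio_rpd))
  cat(sprintf("  cruise C_phyto RPD %+.1f%%\n", x$cphyto_cruise$rpd))
  cat(sprintf("  satellite: r2 %.3f, mean diff %.3g mg C m-3 (%.1f%% of mean)\n",
              x$satellite$realized_r2, x$satellite$mean_difference,
              x$satellite$percent_of_mean))
  invisible(x)
}

#' Serialize a reference-analysis report to JSON
#'
#' Writes the scalar summary of a [run_reference_analysis()] report; the
#' output is a pure function of the seed and configuration, so reruns are
#' byte-identical.
#'
#' @param report A `carbon_method_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "carbon_method_report"))
  obj <- list(
    seed = report$seed,
    config = report$config,
    fits = report$fits,
    bbpk = as.list(report$bbpk),
    sf = report$sf,
    sf_percent_increase = report$sf_percent_increase,
    cphyto_to_poc_mean_ratio = report$cphyto_to_poc_mean_ratio,
    poc_model = report$poc_model,
    n_spikes_removed = report$n_spikes_removed,
    cphyto_float_rpd = report$cphyto_float$rpd,
    poc_float_rpd = report$poc_float$rpd,
    ratio_rpd = report$ratio_rpd,
    cphyto_cruise_rpd = report$cphyto_cruise$rpd,
    satellite = report$satellite,
    note = paste("depth ranges: float", report$config$z_range_float[1],
                 "-", report$config$z_range_float[2], "m; cruise",
                 report$config$z_range_cruise[1], "-",
                 report$config$z_range_cruise[2], "m")
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
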