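#!/usr/bin/env Rscript
# Stage 4 — the cost of the wrong regression method, in carbon units.
#
# Applies the stage-3 parameter pairs to the despiked float series, the
# cruise cast series and the satellite-like monthly series, and quantifies
# the method impact as anomalies (unsuitable minus suitable estimate) and
# relative percent differences (RPD) of the depth/time-integrated budgets.
# For C_phyto the anomaly is a constant, (bbp_k,OLS - bbp_k,SMA) * SF,
# so the RPD is large wherever the mean C_phyto is small; for POC the
# anomaly varies linearly with b_bp and largely cancels.

suppressPackageStartupMessages(library(bbpcarbon))

data_dir <- "results/data"
par_dir <- "results/params"
out <- "results/tables"
fig <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create(fig, recursive = TRUE, showWarnings = FALSE)

load_cp <- function(f) {
  j <- jsonlite::fromJSON(file.path(par_dir, f))
  carbon_model_params(j$wavelength, j$bbp_k, j$sf, j$method, j$se_bbp_k)
}
load_poc <- function(f) {
  j <- jsonlite::fromJSON(file.path(par_dir, f))
  poc_model_params(j$wavelength, j$B, j$A, j$method, j$se_B, j$se_A)
}
cp_ols <- load_cp("cphyto_ols.json"); cp_sma <- load_cp("cphyto_sma.json")
poc_sma <- load_poc("poc_sma.json"); poc_ols <- load_poc("poc_ols.json")

float <- read_profile_series(file.path(data_dir,
                                       "float_bbp700_despiked.csv"))
cruise <- read_profile_series(file.path(data_dir, "cruise_bbp700.csv"))
sat <- read.csv(file.path(data_dir, "satellite_tchla_bbp443.csv"))

## float budgets (0-250 m) ---------------------------------------------------
cphyto_float <- compare_budgets(float, cp_ols, cp_sma, "cphyto",
                                z_range = c(0, 250))
poc_float <- compare_budgets(float, poc_sma, poc_ols, "poc",
                             z_range = c(0, 250))
print(cphyto_float)
print(poc_float)
budget_json(cphyto_float, file.path(out, "budget_cphyto_float.json"))
budget_json(poc_float, file.path(out, "budget_poc_float.json"))
write.csv(poc_float$anomaly, file.path(out, "poc_anomaly_float.csv"),
          row.names = FALSE)

ratio_s <- cphyto_float$integral_suitable / poc_float$integral_suitable
ratio_u <- cphyto_float$integral_unsuitable / poc_float$integral_unsuitable
message(sprintf("total C_phyto:POC ratio RPD (both unsuitable vs both suitable): %+.1f%%",
                rpd(ratio_u, ratio_s)))

## cruise budget (0-400 m) ---------------------------------------------------
cphyto_cruise <- compare_budgets(cruise, cp_ols, cp_sma, "cphyto",
                                 z_range = c(0, 400))
print(cphyto_cruise)
budget_json(cphyto_cruise, file.path(out, "budget_cphyto_cruise.json"))

## satellite series (443 nm, original SF = 13,000) ---------------------------
sat_d <- bivariate_data(sat$tchla, sat$bbp, labels = c("TChla", "bbp443"))
sat_ols <- derive_bbpk(sat_d, "OLS", wavelength = 443)
sat_sma <- derive_bbpk(sat_d, "SMA", wavelength = 443)
sp_ols <- carbon_model_params(443, sat_ols$bbp_k, 13000, "OLS")
sp_sma <- carbon_model_params(443, sat_sma$bbp_k, 13000, "SMA")
cmp <- compare_series_means(sat$bbp, sp_ols, sp_sma, "cphyto")
message(sprintf("satellite bbp_k(443): OLS %.4g, SMA %.4g m-1 (r2 = %.3f)",
                sat_ols$bbp_k, sat_sma$bbp_k,
                cor(sat$tchla, sat$bbp)^2))
message(sprintf("satellite C_phyto: mean difference (SMA-based minus OLS-based) %.2f mg C m-3 = %.0f%% of the OLS-based mean",
                cmp$mean_difference, cmp$percent_of_mean))
writeLines(jsonlite::toJSON(cmp[c("mean_suitable", "mean_unsuitable",
                                  "mean_difference", "percent_of_mean")],
                            auto_unbox = TRUE, digits = NA),
           file.path(out, "satellite_cphyto_comparison.json"))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  an <- poc_float$anomaly
  g <- ggplot(an, aes(time, depth, fill = anomaly)) +
    geom_tile() +
    scale_y_reverse(limits = c(250, 0)) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "day", y = "depth (m)",
         fill = "POC anomaly\n(OLS - SMA,\nmg m-3)") +
    theme_minimal()
  ggsave(file.path(fig, "poc_anomaly_float.png"), g,
         width = 7, height = 4, dpi = 150)
  sat_cp <- data.frame(
    month = sat$month,
    OLS = as.numeric(cphyto_from_bbp(sat$bbp, sp_ols)),
    SMA = as.numeric(cphyto_from_bbp(sat$bbp, sp_sma)))
  g2 <- ggplot(reshape(sat_cp, direction = "long", varying = c("OLS", "SMA"),
                       v.names = "cphyto", timevar = "method",
                       times = c("OLS", "SMA")),
               aes(month, cphyto, colour = method)) +
    geom_line() +
    labs(x = "month", y = "C_phyto (mg C m-3)", colour = "bbp_k from") +
    theme_minimal()
  ggsave(file.path(fig, "satellite_cphyto_series.png"), g2,
         width = 7, height = 4, dpi = 150)
  message("Figures written to ", fig)
}
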