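#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic observing systems.
#
# Emulates the three data sources the analysis chain consumes: monthly
# cruise bottle match-ups (TChla-b_bp and b_bp-POC pairs with error on
# both axes), a ~15-month float b_bp(700) profile series on the
# three-segment float grid (with injected positive spikes), a monthly
# cruise-like 0-400 m cast series, and an 18-year satellite-like monthly
# TChla/b_bp(443) series tuned to a moderate correlation (r2 = 0.56).
# Everything is written under results/data/ with truth sidecars.

suppressPackageStartupMessages(library(bbpcarbon))

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Cruise match-ups (n = 300 each) ...")
chl_mu <- gen_matchups(tchla_bbp_scenario(seed + 1L))
poc_mu <- gen_matchups(bbp_poc_scenario(seed + 2L))
write_matchups(chl_mu, file.path(out, "matchups_tchla_bbp.csv"))
write_matchups(poc_mu, file.path(out, "matchups_bbp_poc.csv"))

message("Float series (87 casts, 5.4-day cadence) ...")
float <- gen_profile_series(profile_scenario(seed = seed + 3L))
write_profile_series(float, file.path(out, "float_bbp700.csv"))
truth <- lapply(attr(float, "truth"), function(t)
  list(time = t$time, spike_index = t$spike_index))
writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE),
           file.path(out, "float_bbp700.spikes.json"))

message("Cruise cast series (27 casts, 0-400 m at 1 m) ...")
cruise <- gen_profile_series(profile_scenario(
  n_casts = 27, cadence_days = 30.4, grid = seq(0, 400, by = 1),
  spike_rate = 0, seed = seed + 4L))
write_profile_series(cruise, file.path(out, "cruise_bbp700.csv"))

message("Satellite-like monthly series (216 months, r2 tuned to 0.56) ...")
sat <- gen_gridded_series(
  bivariate_scenario(b_true = 2.3e-3, a_true = 8.5e-4, n = 216,
                     seed = seed + 5L, x_family = "lognormal",
                     x_location = log(0.25), x_scale = 0.35, sd_y = 2e-4,
                     labels = c("TChla", "bbp443")),
  n_months = 216, target_r2 = 0.56)
write_matchups(sat, file.path(out, "satellite_tchla_bbp443.csv"))

n_spk <- sum(lengths(lapply(attr(float, "truth"), `[[`, "spike_index")))
message(sprintf(
  "Done. %d chl match-ups, %d POC match-ups, %d float casts (%d spikes injected), %d cruise casts, %d months (realized r2 = %.3f).",
  nrow(chl_mu), nrow(poc_mu), float$n_casts, n_spk, cruise$n_casts,
  nrow(sat), attr(sat, "realized_r2")))
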