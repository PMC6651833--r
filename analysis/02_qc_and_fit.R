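#!/usr/bin/env Rscript
# Stage 2 — quality control and regression fits.
#
# Despikes the float series (removing positive spikes above twice the 90th
# residual quantile of a 5-sample running-median filter), then fits the two
# bio-optical relationships with all four regression methods, side by side.
# The point of the side-by-side table: OLS and SMA disagree on slope and
# intercept exactly as much as the correlation falls short of 1
# (B_SMA = B_OLS/|r|), and those disagreements carry straight into the
# carbon models of stage 3.

suppressPackageStartupMessages(library(bbpcarbon))

data_dir <- "results/data"
out <- "results/tables"
fig <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create(fig, recursive = TRUE, showWarnings = FALSE)

message("Despiking the float series ...")
float <- read_profile_series(file.path(data_dir, "float_bbp700.csv"))
clean <- despike_series(float)
qc_report(clean, file.path(out, "float_qc_report.json"))
write_profile_series(clean, file.path(data_dir, "float_bbp700_despiked.csv"))
message(sprintf("  removed %d spike points across %d casts",
                attr(clean, "n_spikes_removed"), clean$n_casts))

message("Fitting TChla -> b_bp(700) and b_bp(700) -> POC ...")
chl <- read_bivariate(file.path(data_dir, "matchups_tchla_bbp.csv"),
                      "TChla", "bbp700")
poc <- read_bivariate(file.path(data_dir, "matchups_bbp_poc.csv"),
                      "bbp700", "POC")
sat <- read_bivariate(file.path(data_dir, "satellite_tchla_bbp443.csv"),
                      "tchla", "bbp")

tabs <- list(
  tchla_bbp700 = fit_methods(chl, c("OLS", "SMA", "MA", "RMA")),
  bbp700_poc = fit_methods(poc, c("OLS", "SMA", "MA", "RMA")),
  satellite_tchla_bbp443 = fit_methods(sat, c("OLS", "SMA")))
for (nm in names(tabs)) {
  write.csv(tabs[[nm]], file.path(out, paste0("fits_", nm, ".csv")),
            row.names = FALSE)
  print(cbind(relation = nm, tabs[[nm]][, c("method", "B", "A", "r2")]))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  scatter_with_fits <- function(d, tab, xlab, ylab) {
    df <- data.frame(x = d$x, y = d$y)
    tab <- tab[!is.na(tab$B) & tab$method %in% c("OLS", "SMA"), ]
    ggplot(df, aes(x, y)) +
      geom_point(alpha = 0.4, size = 0.8) +
      geom_abline(data = tab,
                  aes(slope = B, intercept = A, colour = method)) +
      labs(x = xlab, y = ylab, colour = NULL) +
      theme_minimal()
  }
  ggsave(file.path(fig, "fit_tchla_bbp.png"),
         scatter_with_fits(chl, tabs$tchla_bbp700,
                           "TChla (mg m-3)", "bbp(700) (m-1)"),
         width = 5, height = 4, dpi = 150)
  ggsave(file.path(fig, "fit_bbp_poc.png"),
         scatter_with_fits(poc, tabs$bbp700_poc,
                           "bbp(700) (m-1)", "POC (mg m-3)"),
         width = 5, height = 4, dpi = 150)
  message("Figures written to ", fig)
}
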