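#' @title Synthetic bio-optical data generators
#' @description
#' Seeded generators for the three kinds of observation the analysis chain
#' consumes: cruise-style bottle match-up tables (paired variables with
#' measurement error on both axes), float-style b_bp profile series on the
#' three-segment vertical grid typical of profiling floats, and
#' satellite-style monthly gridded chlorophyll/backscattering pairs with a
#' controlled correlation. Every generator records the generating truth
#' alongside the observations so that parameter recovery and QC performance
#' can be scored exactly, and every output stream is a deterministic
#' function of the scenario seed.
#' @name synthetic_data
NULL

#' Scenario for paired observations with errors on both axes
#'
#' Observations are generated as `x = x* + e_x`, `y = B*x* + A + e_y` with
#' latent `x*` drawn from a lognormal (the natural choice for chlorophyll-
#' like, strictly positive and right-skewed variables) or Gaussian family,
#' and independent zero-mean Gaussian errors. Because the predictor is
#' observed with error, OLS on such data is attenuated by the factor
#' `Var(x*)/(Var(x*) + sd_x^2)` while SMA recovers the true slope whenever
#' `sd_y/sd_x` equals `|B|` — the core errors-in-variables phenomenon the
#' package quantifies.
#'
#' @param b_true,a_true True slope and intercept.
#' @param n Number of pairs (>= 3).
#' @param x_family `"lognormal"` or `"gaussian"`.
#' @param x_location,x_scale Location/scale of the latent x distribution:
#'   meanlog/sdlog for lognormal, mean/sd for Gaussian.
#' @param sd_x,sd_y Error standard deviations (>= 0) for the observed x
#'   and y.
#' @param outlier_fraction Fraction of rows replaced by inflated-error
#'   draws (default 0).
#' @param outlier_inflation Error-sd multiplier for outlier rows.
#' @param require_positive Reject-and-redraw observed values that come out
#'   negative (physical positivity for b_bp/POC-like variables).
#' @param labels Variable names attached to the generated table.
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `bivariate_scenario`.
#' @export
bivariate_scenario <- function(b_true, a_true, n, seed,
                               x_family = c("lognormal", "gaussian"),
                               x_location = 0, x_scale = 1,
                               sd_x = 0, sd_y = 0,
                               outlier_fraction = 0, outlier_inflation = 10,
                               require_positive = FALSE,
                               labels = c("x", "y")) {
  x_family <- match.arg(x_family)
  stopifnot(n >= 3, sd_x >= 0, sd_y >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  structure(
    list(b_true = b_true, a_true = a_true, n = as.integer(n),
         x_family = x_family, x_location = x_location, x_scale = x_scale,
         sd_x = sd_x, sd_y = sd_y,
         outlier_fraction = outlier_fraction,
         outlier_inflation = outlier_inflation,
         require_positive = require_positive,
         labels = labels, seed = as.integer(seed)),
    class = "bivariate_scenario"
  )
}

# Redraw negative entries (up to 50 rounds), counting redraws.
.redraw_positive <- function(v, draw) {
  n_redrawn <- 0L
  for (i in 1:50) {
    bad <- which(v < 0)
    if (length(bad) == 0) break
    n_redrawn <- n_redrawn + length(bad)
    v[bad] <- draw(length(bad), bad)
  }
  attr(v, "n_redrawn") <- n_redrawn
  v
}

#' Generate a match-up table from a bivariate scenario
#'
#' @param scenario A [bivariate_scenario].
#' @return A data frame with observed `x`, `y` and the generating truth
#'   `x_true`, `y_true`, plus a logical `outlier` column. Attributes:
#'   `scenario`, `n_redrawn` (positivity redraws).
#' @export
gen_matchups <- function(scenario) {
  stopifnot(inherits(scenario, "bivariate_scenario"))
  s <- scenario
  set.seed(s$seed)
  x_true <- switch(s$x_family,
    lognormal = stats::rlnorm(s$n, meanlog = s$x_location, sdlog = s$x_scale),
    gaussian  = stats::rnorm(s$n, mean = s$x_location, sd = s$x_scale))
  y_true <- s$b_true * x_true + s$a_true
  sd_x <- rep(s$sd_x, s$n)
  sd_y <- rep(s$sd_y, s$n)
  outlier <- rep(FALSE, s$n)
  if (s$outlier_fraction > 0) {
    k <- max(1L, round(s$outlier_fraction * s$n))
    idx <- sample.int(s$n, k)
    outlier[idx] <- TRUE
    sd_x[idx] <- sd_x[idx] * s$outlier_inflation
    sd_y[idx] <- sd_y[idx] * s$outlier_inflation
  }
  x <- x_true + stats::rnorm(s$n, 0, sd_x)
  y <- y_true + stats::rnorm(s$n, 0, sd_y)
  n_redrawn <- 0L
  if (s$require_positive) {
    x <- .redraw_positive(x, function(k, bad) {
      x_true[bad] + stats::rnorm(k, 0, sd_x[bad])
    })
    y <- .redraw_positive(y, function(k, bad) {
      y_true[bad] + stats::rnorm(k, 0, sd_y[bad])
    })
    n_redrawn <- attr(x, "n_redrawn") + attr(y, "n_redrawn")
    attributes(x) <- NULL; attributes(y) <- NULL
  }
  out <- data.frame(x = x, y = y, x_true = x_true, y_true = y_true,
                    outlier = outlier)
  names(out)[1:2] <- s$labels
  attr(out, "scenario") <- s
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' As a [bivariate_data] object
#'
#' @param matchups Output of [gen_matchups()].
#' @return The observed columns wrapped for fitting.
#' @export
matchups_bivariate <- function(matchups) {
  s <- attr(matchups, "scenario")
  bivariate_data(matchups[[1]], matchups[[2]],
                 labels = if (!is.null(s)) s$labels else names(matchups)[1:2])
}

#' The reference cruise match-up scenarios
#'
#' Default study conditions emulating ~27 monthly cruise visits with 12
#' bottle depths each (minus losses): n = 300 match-ups. The TChla -> b_bp
#' truth uses slope 6.1e-3 m-1 per mg m-3 and background intercept 5.5e-4
#' m-1, with chlorophyll lognormal around 0.3 mg m-3 (range ~0.03-3) and
#' noise on both axes; the b_bp -> POC truth uses slope 4e4 mg C m-3 per
#' m-1 and intercept 10 mg C m-3.
#'
#' @param seed Integer seed.
#' @param n Number of match-ups.
#' @return A [bivariate_scenario].
#' @export
tchla_bbp_scenario <- function(seed, n = 300) {
  bivariate_scenario(
    b_true = 6.1e-3, a_true = 5.5e-4, n = n, seed = seed,
    x_family = "lognormal", x_location = log(0.3), x_scale = 0.9,
    sd_x = 0.05, sd_y = 8e-4, require_positive = TRUE,
    labels = c("TChla", "bbp700"))
}

#' @rdname tchla_bbp_scenario
#' @export
bbp_poc_scenario <- function(seed, n = 300) {
  bivariate_scenario(
    b_true = 4e4, a_true = 10, n = n, seed = seed,
    x_family = "lognormal", x_location = log(1e-3), x_scale = 0.7,
    sd_x = 1e-4, sd_y = 10, require_positive = TRUE,
    labels = c("bbp700", "POC"))
}

#' Profiling-float vertical grid
#'
#' The three-segment acquisition grid of the emulated floats: 10 m
#' resolution between 1000 and 250 m, 1 m between 250 and 10 m, 0.2 m
#' between 10 m and the surface.
#'
#' @param z_max Deepest depth, m (default 1000).
#' @return Strictly increasing vector of depths, m.
#' @export
argo_grid <- function(z_max = 1000) {
  d <- c(seq(0, 10, by = 0.2), seq(11, 250, by = 1), seq(260, z_max, by = 10))
  d[d <= z_max]
}

#' Scenario for a float-like b_bp profile series
#'
#' Each cast is a smooth deterministic baseline — a deep background plus a
#' surface-intensified exponential layer and a Gaussian subsurface maximum,
#' both seasonally modulated — with additive white noise and Poisson-placed
#' positive spikes whose amplitudes follow a shifted exponential between
#' about 5 and 50 times the noise sd. Injected spike positions are kept at
#' a minimum separation of 3 samples so each spike's running-median
#' reference stays uncontaminated and the injected truth is unambiguous.
#'
#' @param n_casts Number of casts (default 87, ~15 months at the default
#'   cadence).
#' @param cadence_days Days between casts (default 5.4).
#' @param grid Vertical grid, m (default [argo_grid()]).
#' @param bbp_deep Deep background b_bp, m-1.
#' @param surf_amp Surface-layer amplitude, m-1.
#' @param surf_scale E-folding depth of the surface layer, m.
#' @param dcm_amp,dcm_depth,dcm_width Subsurface-maximum Gaussian amplitude
#'   (m-1), center depth (m) and width (m).
#' @param seasonal_amp Relative seasonal modulation of the surface layer
#'   (0-1).
#' @param seasonal_phase Day of year of the seasonal maximum.
#' @param noise_sd White-noise sd, m-1.
#' @param spike_rate Per-sample probability of a positive spike.
#' @param spike_min,spike_mean_excess Spike amplitude = noise_sd *
#'   (spike_min + Exp(mean = spike_mean_excess)).
#' @param wavelength Wavelength, nm.
#' @param seed Integer seed.
#' @return A list of class `profile_scenario`.
#' @export
profile_scenario <- function(n_casts = 87, cadence_days = 5.4,
                             grid = argo_grid(),
                             bbp_deep = 6.0e-4, surf_amp = 1.0e-3,
                             surf_scale = 40, dcm_amp = 6e-4,
                             dcm_depth = 45, dcm_width = 15,
                             seasonal_amp = 0.5, seasonal_phase = 30,
                             noise_sd = 5e-5, spike_rate = 0.015,
                             spike_min = 5, spike_mean_excess = 15,
                             wavelength = 700, seed = 1) {
  stopifnot(n_casts >= 1, all(diff(grid) > 0), noise_sd >= 0,
            spike_rate >= 0, spike_rate < 1, spike_min > 0)
  structure(
    list(n_casts = as.integer(n_casts), cadence_days = cadence_days,
         grid = grid, bbp_deep = bbp_deep, surf_amp = surf_amp,
         surf_scale = surf_scale, dcm_amp = dcm_amp, dcm_depth = dcm_depth,
         dcm_width = dcm_width, seasonal_amp = seasonal_amp,
         seasonal_phase = seasonal_phase, noise_sd = noise_sd,
         spike_rate = spike_rate, spike_min = spike_min,
         spike_mean_excess = spike_mean_excess,
         wavelength = wavelength, seed = as.integer(seed)),
    class = "profile_scenario"
  )
}

# Smooth baseline b_bp(z, t) for a scenario; exact, noise-free.
profile_baseline <- function(scenario, z, t_days) {
  s <- scenario
  season <- 1 + s$seasonal_amp *
    cos(2 * pi * (t_days - s$seasonal_phase) / 365.25)
  s$bbp_deep +
    s$surf_amp * season * exp(-z / s$surf_scale) +
    s$dcm_amp * season * exp(-(z - s$dcm_depth)^2 / (2 * s$dcm_width^2))
}

# Poisson-like spike placement thinned to a minimum index separation.
# Endpoints are excluded: at a profile's first/last sample a shrinking
# median filter has no neighbours, so a spike there is undetectable by any
# residual method and would make the recorded truth unusable for scoring.
.place_spikes <- function(n, rate, min_sep = 3L) {
  if (rate <= 0) return(integer(0))
  u <- stats::runif(n)
  idx <- which(u < rate)
  idx <- idx[idx > 1L & idx < n]
  if (length(idx) < 2) return(idx)
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
  keep
}

#' Generate a float-like profile series with recorded truth
#'
#' @param scenario A [profile_scenario].
#' @return A [profile_series]; its attribute `truth` is a list per cast
#'   with `baseline` (noise- and spike-free values) and `spike_index`
#'   (indices of injected spikes in the cast's grid).
#' @export
gen_profile_series <- function(scenario) {
  stopifnot(inherits(scenario, "profile_scenario"))
  s <- scenario
  set.seed(s$seed)
  truth <- vector("list", s$n_casts)
  profiles <- vector("list", s$n_casts)
  for (k in seq_len(s$n_casts)) {
    t_k <- (k - 1) * s$cadence_days
    base <- profile_baseline(s, s$grid, t_k)
    val <- base + stats::rnorm(length(base), 0, s$noise_sd)
    spikes <- .place_spikes(length(base), s$spike_rate)
    if (length(spikes) > 0) {
      amp <- s$noise_sd *
        (s$spike_min + stats::rexp(length(spikes), 1 / s$spike_mean_excess))
      val[spikes] <- val[spikes] + amp
    }
    profiles[[k]] <- bbp_profile(s$grid, val, time = t_k,
                                 wavelength = s$wavelength)
    truth[[k]] <- list(baseline = base, spike_index = spikes,
                       time = t_k)
  }
  out <- profile_series(profiles, platform = "synthetic-float")
  attr(out, "truth") <- truth
  attr(out, "scenario") <- s
  out
}

#' Generate a satellite-like monthly TChla / b_bp series
#'
#' Monthly paired chlorophyll and backscattering with seasonality and
#' lognormal interannual variability in TChla, and
#' `b_bp = B*TChla + A + noise`. When `target_r2` is given, the y-noise is
#' residualized against the realized TChla and rescaled so the sample
#' coefficient of determination equals the target (a noise-tuning step;
#' infeasible when the deterministic signal has no variance, e.g.
#' `b_true = 0`).
#'
#' @param scenario A [bivariate_scenario]; `x_location`/`x_scale` set the
#'   lognormal level and interannual spread of monthly TChla, `sd_y` the
#'   untuned noise sd.
#' @param n_months Number of months (default 216 = 18 years).
#' @param target_r2 Requested sample r2 in (0, 1), or `NULL` to use the
#'   scenario noise as-is.
#' @param seasonal_amp Amplitude of the seasonal cycle of log-TChla.
#' @param seasonal_phase Month (1-12) of the seasonal maximum.
#' @return Data frame with `month`, `time` (decimal year offset), `tchla`,
#'   `bbp`, and truth columns; attribute `realized_r2`.
#' @export
gen_gridded_series <- function(scenario, n_months = 216, target_r2 = NULL,
                               seasonal_amp = 0.7, seasonal_phase = 3) {
  stopifnot(inherits(scenario, "bivariate_scenario"))
  s <- scenario
  if (!is.null(target_r2)) {
    if (target_r2 <= 0 || target_r2 >= 1) {
      stop("requested r2 band is infeasible: target must lie in (0, 1)",
           call. = FALSE)
    }
    if (s$b_true == 0) {
      stop("requested r2 band is infeasible: the true slope is zero, so ",
           "the signal has no variance to tune against", call. = FALSE)
    }
  }
  set.seed(s$seed)
  m <- seq_len(n_months)
  logx <- s$x_location +
    seasonal_amp * cos(2 * pi * (m - seasonal_phase) / 12) +
    stats::rnorm(n_months, 0, s$x_scale)
  tchla <- exp(logx)
  signal <- s$b_true * tchla + s$a_true
  eps <- stats::rnorm(n_months, 0, if (s$sd_y > 0) s$sd_y else 1)
  if (!is.null(target_r2)) {
    # orthogonalize the noise against x, then scale it so the in-sample
    # r2 of (x, y) is exactly the target
    xc <- tchla - mean(tchla)
    eps <- eps - mean(eps) - sum(eps * xc) / sum(xc^2) * xc
    var_sig <- stats::var(signal)
    var_target <- var_sig * (1 / target_r2 - 1)
    eps <- eps * sqrt(var_target / stats::var(eps))
  } else if (s$sd_y == 0) {
    eps <- rep(0, n_months)
  }
  bbp <- signal + eps
  out <- data.frame(month = m, time = (m - 1) / 12, tchla = tchla,
                    bbp = bbp, bbp_true = signal)
  r2 <- if (stats::sd(bbp) > 0 && stats::sd(tchla) > 0) {
    stats::cor(tchla, bbp)^2
  } else {
    NA_real_
  }
  attr(out, "realized_r2") <- r2
  attr(out, "scenario") <- s
  out
}

#' Write a match-up table and its truth sidecar
#'
#' @param matchups Output of [gen_matchups()] or [gen_gridded_series()].
#' @param path CSV output path; the truth sidecar (scenario parameters)
#'   goes to `paste0(path, ".truth.json")`.
#' @return `path`, invisibly.
#' @export
write_matchups <- function(matchups, path) {
  utils::write.csv(matchups, path, row.names = FALSE)
  s <- attr(matchups, "scenario")
  if (!is.null(s)) {
    sj <- s[setdiff(names(s), "grid")]
    writeLines(jsonlite::toJSON(sj, auto_unbox = TRUE, digits = NA),
               paste0(path, ".truth.json"))
  }
  invisible(path)
}
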