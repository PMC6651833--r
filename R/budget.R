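#' @title Carbon budgets and method-impact statistics
#' @description
#' Depth/time integration of carbon fields estimated from backscattering
#' profiles, and the two statistics used to quantify the impact of the
#' regression-method choice: per-point anomalies (difference between the
#' estimates under the two parameterizations) and the relative percent
#' difference (RPD) between the budget computed with the unsuitable method
#' and the budget computed with the suitable one.
#' @name budget_analysis
NULL

#' Trapezoidal depth integral of a profile
#'
#' Integrates `value` over depth on the profile's native (irregular) grid,
#' restricted to `[z_top, z_bottom]`. No extrapolation is performed beyond
#' the shallowest/deepest sample inside the range; the attribute
#' `coverage` records the depth span actually integrated.
#'
#' @param profile A [bbp_profile] (or any value profile in mg m-3).
#' @param z_top,z_bottom Integration bounds, m, with `z_top < z_bottom`.
#' @param values Optional replacement values aligned with `profile$depth`
#'   (e.g., C_phyto computed from the profile's b_bp); defaults to
#'   `profile$value`.
#' @return The areal value (input units times m), e.g. mg m-2; `NA` with a
#'   warning when fewer than 2 samples fall in range.
#' @examples
#' p <- bbp_profile(c(0, 100), c(2, 2), time = 1)
#' depth_integrate(p, 0, 100)  # 200
#' @export
depth_integrate <- function(profile, z_top, z_bottom, values = NULL) {
  stopifnot(inherits(profile, "bbp_profile"))
  if (z_top >= z_bottom) stop("z_top must be less than z_bottom")
  v <- if (is.null(values)) profile$value else values
  if (length(v) != profile$n) stop("values must align with profile depths")
  sel <- profile$depth >= z_top & profile$depth <= z_bottom
  if (sum(sel) < 2) {
    warning("fewer than 2 samples in [", z_top, ", ", z_bottom,
            "] m; integral undefined", call. = FALSE)
    return(structure(NA_real_, coverage = c(NA_real_, NA_real_)))
  }
  z <- profile$depth[sel]
  vv <- v[sel]
  integral <- sum(diff(z) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  structure(integral, coverage = range(z))
}

#' Per-point anomalies between two aligned series of estimates
#'
#' Elementwise `a - b` on matching grids. The orientation (which
#' parameterization is `a`) is recorded in the result's attributes.
#'
#' @param series_a,series_b Numeric vectors/matrices on identical grids.
#' @param labels Length-2 character vector naming a and b (e.g.,
#'   `c("OLS", "SMA")`).
#' @return `a - b` with attribute `orientation = "a - b"` spelled with the
#'   labels.
#' @export
anomaly_field <- function(series_a, series_b, labels = c("a", "b")) {
  if (length(series_a) != length(series_b) ||
      !identical(dim(series_a), dim(series_b))) {
    stop("grid mismatch: the two series have different shapes", call. = FALSE)
  }
  out <- series_a - series_b
  attr(out, "orientation") <- paste(labels[1], "-", labels[2])
  out
}

#' Relative percent difference between unsuitable- and suitable-method values
#'
#' `RPD = 100 * (value_unsuitable - value_suitable) / value_suitable`.
#' The sign is retained (positive = the unsuitable method overestimates);
#' note the statistic is asymmetric in its arguments:
#' `rpd(a, b) = -rpd(b, a) * b / a`.
#'
#' @param value_unsuitable Estimate under the method not adapted to the
#'   problem.
#' @param value_suitable Reference estimate under the appropriate method
#'   (non-zero).
#' @return Signed percent difference.
#' @examples
#' rpd(110, 100)  # +10
#' @export
rpd <- function(value_unsuitable, value_suitable) {
  if (any(value_suitable == 0)) {
    stop("RPD undefined: reference (suitable-method) value is zero",
         call. = FALSE)
  }
  100 * (value_unsuitable - value_suitable) / value_suitable
}

# Trapezoidal accumulation of per-cast areal values over cast times.
.time_accumulate <- function(times, values) {
  if (length(times) < 2) return(NA_real_)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Compare carbon budgets under two parameterizations
#'
#' Applies the C_phyto or POC model to every cast of a profile series under
#' both a suitable-method and an unsuitable-method parameter set, computes
#' per-cast trapezoidal depth integrals over `z_range`, accumulates them
#' trapezoidally over cast time, and summarizes the impact as per-point
#' anomalies (unsuitable minus suitable) and the RPD of the two integrals.
#'
#' @param series A [profile_series] of b_bp casts.
#' @param params_suitable,params_unsuitable Both `carbon_model_params`
#'   (model `"cphyto"`, sharing `sf` and wavelength) or both
#'   `poc_model_params` (model `"poc"`).
#' @param model `"cphyto"` or `"poc"`.
#' @param z_range Depth integration range, m. Defaults to `c(0, 250)`, the
#'   float-budget convention; cruise casts typically use `c(0, 400)`.
#' @return An object of class `budget_comparison`: list with
#'   `integral_suitable`, `integral_unsuitable` (mg C m-2 accumulated over
#'   cast days -> mg C m-2 day), `rpd`, `anomaly` (long data frame
#'   `time, depth, anomaly` of unsuitable - suitable), per-cast integrals,
#'   and labels recording which method played which role.
#' @export
compare_budgets <- function(series, params_suitable, params_unsuitable,
                            model = c("cphyto", "poc"),
                            z_range = c(0, 250)) {
  model <- match.arg(model)
  stopifnot(inherits(series, "profile_series"), length(z_range) == 2)
  cls <- switch(model, cphyto = "carbon_model_params",
                poc = "poc_model_params")
  if (!inherits(params_suitable, cls) || !inherits(params_unsuitable, cls)) {
    stop("parameter objects do not match model '", model, "'", call. = FALSE)
  }
  if (params_suitable$wavelength != params_unsuitable$wavelength) {
    stop("parameter sets are for different wavelengths", call. = FALSE)
  }
  if (model == "cphyto" &&
      !isTRUE(all.equal(params_suitable$sf, params_unsuitable$sf))) {
    stop("C_phyto comparison requires a shared scaling factor SF",
         call. = FALSE)
  }
  apply_model <- function(bbp, p) {
    if (model == "cphyto") as.numeric(cphyto_from_bbp(bbp, p))
    else poc_from_bbp(bbp, p)
  }
  per_cast <- lapply(series$profiles, function(pr) {
    est_s <- apply_model(pr$value, params_suitable)
    est_u <- apply_model(pr$value, params_unsuitable)
    list(
      time = as.numeric(pr$time),
      int_s = as.numeric(depth_integrate(pr, z_range[1], z_range[2],
                                         values = est_s)),
      int_u = as.numeric(depth_integrate(pr, z_range[1], z_range[2],
                                         values = est_u)),
      anomaly = data.frame(time = as.numeric(pr$time), depth = pr$depth,
                           anomaly = est_u - est_s)
    )
  })
  times <- vapply(per_cast, `[[`, numeric(1), "time")
  int_s <- vapply(per_cast, `[[`, numeric(1), "int_s")
  int_u <- vapply(per_cast, `[[`, numeric(1), "int_u")
  ok <- is.finite(int_s) & is.finite(int_u)
  total_s <- .time_accumulate(times[ok], int_s[ok])
  total_u <- .time_accumulate(times[ok], int_u[ok])
  structure(
    list(
      model = model,
      integral_suitable = total_s,
      integral_unsuitable = total_u,
      rpd = rpd(total_u, total_s),
      anomaly = do.call(rbind, lapply(per_cast, `[[`, "anomaly")),
      cast_times = times,
      cast_integral_suitable = int_s,
      cast_integral_unsuitable = int_u,
      z_range = z_range,
      labels = c(suitable = params_suitable$method,
                 unsuitable = params_unsuitable$method)
    ),
    class = "budget_comparison"
  )
}

#' @export
print.budget_comparison <- function(x, ...) {
  cat(sprintf("<budget_comparison %s> %s (suitable) vs %s (unsuitable)\n",
              x$model, x$labels["suitable"], x$labels["unsuitable"]))
  cat(sprintf("  integral over %g-%g m and time: suitable %.6g, unsuitable %.6g\n",
              x$z_range[1], x$z_range[2],
              x$integral_suitable, x$integral_unsuitable))
  cat(sprintf("  RPD = %+.2f%% (|RPD| = %.2f%%)\n", x$rpd, abs(x$rpd)))
  invisible(x)
}

#' Compare depth-less (satellite-style) series under two parameterizations
#'
#' For gridded monthly series there is no depth axis; the impact of the
#' method choice is summarized as the time-mean difference between the two
#' estimate series and that difference expressed as a percentage of the
#' suitable-method mean.
#'
#' @param bbp Numeric vector of the b_bp series.
#' @param params_suitable,params_unsuitable As in [compare_budgets()].
#' @param model `"cphyto"` or `"poc"`.
#' @return List with `mean_suitable`, `mean_unsuitable`,
#'   `mean_difference` (unsuitable - suitable), `percent_of_mean`
#'   (100 * mean_difference / mean_suitable) and the anomaly series.
#' @export
compare_series_means <- function(bbp, params_suitable, params_unsuitable,
                                 model = c("cphyto", "poc")) {
  model <- match.arg(model)
  apply_model <- function(p) {
    if (model == "cphyto") as.numeric(cphyto_from_bbp(bbp, p))
    else poc_from_bbp(bbp, p)
  }
  est_s <- apply_model(params_suitable)
  est_u <- apply_model(params_unsuitable)
  ms <- mean(est_s); mu <- mean(est_u)
  list(mean_suitable = ms, mean_unsuitable = mu,
       mean_difference = mu - ms,
       percent_of_mean = 100 * (mu - ms) / ms,
       anomaly = anomaly_field(est_u, est_s,
                               labels = c(params_unsuitable$method,
                                          params_suitable$method)))
}

#' Serialize a budget comparison to JSON
#'
#' @param comparison A `budget_comparison` object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
budget_json <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "budget_comparison"))
  obj <- comparison[c("model", "integral_suitable", "integral_unsuitable",
                      "rpd", "z_range", "labels")]
  obj$n_casts <- length(comparison$cast_times)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
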