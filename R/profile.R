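#' @title Backscattering profiles and their quality control
#' @description
#' Containers and QC operations for vertical profiles of the particulate
#' backscattering coefficient, as acquired by profiling floats (irregular
#' vertical grids, occasional positive spikes from large aggregates or
#' zooplankton crossing the sensor volume) or by ship casts (dark-offset
#' subtraction, depth binning around nominal bottle depths).
#' @name profile_qc
NULL

#' A depth-ordered backscattering profile
#'
#' @param depth Depths in m, strictly increasing.
#' @param value b_bp values, m-1 (same length as depth).
#' @param time A timestamp for the cast (numeric day or POSIXct).
#' @param wavelength Wavelength, nm.
#' @param flags Optional character vector of per-point QC flags; defaults
#'   to `"ok"`.
#' @return An object of class `bbp_profile`: list with `depth`, `value`,
#'   `time`, `wavelength`, `flags`, `n`, and a `removed` data frame
#'   recording points dropped by QC (empty initially).
#' @export
bbp_profile <- function(depth, value, time = NA, wavelength = 700,
                        flags = NULL) {
  if (length(depth) != length(value)) {
    stop("depth and value must have equal length")
  }
  ord <- order(depth)
  depth <- depth[ord]; value <- value[ord]
  if (any(diff(depth) <= 0)) {
    stop("depths must be strictly increasing (duplicates found)")
  }
  if (is.null(flags)) flags <- rep("ok", length(depth)) else flags <- flags[ord]
  structure(
    list(depth = depth, value = value, time = time,
         wavelength = wavelength, flags = flags, n = length(depth),
         removed = data.frame(depth = numeric(0), value = numeric(0),
                              flag = character(0),
                              stringsAsFactors = FALSE)),
    class = "bbp_profile"
  )
}

#' @export
print.bbp_profile <- function(x, ...) {
  cat(sprintf("<bbp_profile> %d points, %.1f-%.1f m, lambda = %g nm",
              x$n, min(x$depth), max(x$depth), x$wavelength))
  if (nrow(x$removed) > 0) cat(",", nrow(x$removed), "removed")
  cat("\n")
  invisible(x)
}

#' An ordered collection of profiles
#'
#' @param profiles List of [bbp_profile] objects with strictly increasing
#'   times and a shared wavelength.
#' @param platform Platform identifier (free text).
#' @return An object of class `profile_series`.
#' @export
profile_series <- function(profiles, platform = "synthetic") {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "bbp_profile")))
  times <- vapply(profiles, function(p) as.numeric(p$time), numeric(1))
  if (any(!is.finite(times))) stop("every profile needs a finite time")
  if (any(diff(times) <= 0)) stop("profile times must be strictly increasing")
  wl <- unique(vapply(profiles, function(p) p$wavelength, numeric(1)))
  if (length(wl) != 1L) {
    stop("profiles mix wavelengths: ", paste(wl, collapse = ", "))
  }
  structure(
    list(profiles = profiles, times = times, wavelength = wl,
         platform = platform, n_casts = length(profiles)),
    class = "profile_series"
  )
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("<profile_series> %d casts, lambda = %g nm, platform %s\n",
              x$n_casts, x$wavelength, x$platform))
  invisible(x)
}

# Running median with symmetrically shrinking windows at the profile ends
# (window stays odd, so a locally linear profile has exactly zero residual
# everywhere); near-surface points, where float resolution is finest, are
# never discarded for lack of filter support.
.running_median <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    stats::median(v[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Remove positive spikes from a profile
#'
#' The residual signal is the difference between the profile and a running
#' median filter (window of `window` samples, default 5; windows shrink
#' symmetrically at the profile ends). Points whose
#' residual exceeds `factor` times the `quantile`-th quantile of the
#' residual signal (default: twice the 90th quantile) are flagged as
#' positive spikes and removed. Negative excursions are never removed.
#'
#' @param profile A [bbp_profile].
#' @param window Odd filter width in samples (default 5).
#' @param quantile Quantile of the residual signal defining the spike
#'   threshold (default 0.90). Quantiles use linear interpolation between
#'   order statistics (type 7).
#' @param factor Threshold multiplier (default 2).
#' @param positive_only Compute the threshold quantile over the positive
#'   residuals only, instead of the full signed residual signal (default
#'   FALSE).
#' @return The despiked profile; removed points are appended to the
#'   `removed` record with flag `"spike"`, and the attribute
#'   `spike_index` on the result gives their indices in the input profile.
#' @export
despike <- function(profile, window = 5L, quantile = 0.90, factor = 2.0,
                    positive_only = FALSE) {
  stopifnot(inherits(profile, "bbp_profile"))
  if (window %% 2L != 1L) stop("window must be odd")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (factor <= 0) stop("factor must be positive")
  if (profile$n < window) {
    warning("profile shorter than the filter window (", profile$n, " < ",
            window, "); returned unchanged", call. = FALSE)
    attr(profile, "spike_index") <- integer(0)
    return(profile)
  }
  med <- .running_median(profile$value, window)
  resid <- profile$value - med
  basis <- if (positive_only) resid[resid > 0] else resid
  if (length(basis) == 0) {
    attr(profile, "spike_index") <- integer(0)
    return(profile)
  }
  threshold <- factor * stats::quantile(basis, probs = quantile,
                                        names = FALSE, type = 7)
  # a non-positive threshold means the residual distribution is degenerate
  # (noise-free or all-equal profile), not spiky: remove nothing rather
  # than flag every point with the slightest positive curvature residual
  spike <- if (threshold > 0) resid > threshold else rep(FALSE, profile$n)
  out <- profile
  if (any(spike)) {
    out$removed <- rbind(
      profile$removed,
      data.frame(depth = profile$depth[spike], value = profile$value[spike],
                 flag = "spike", stringsAsFactors = FALSE))
    out$depth <- profile$depth[!spike]
    out$value <- profile$value[!spike]
    out$flags <- profile$flags[!spike]
    out$n <- sum(!spike)
  }
  attr(out, "spike_index") <- which(spike)
  attr(out, "threshold") <- threshold
  out
}

#' Bin a profile around nominal depths
#'
#' Each output point is the mean of input values within `halfwidth` of the
#' bin center (closed interval, so points exactly at center +- halfwidth
#' are included). Empty bins are omitted and counted.
#'
#' @param profile A [bbp_profile].
#' @param centers Nominal bin-center depths, m.
#' @param halfwidth Half-width of each bin, m (default 0.5).
#' @return A binned [bbp_profile] whose points carry flag `"binned"`, with
#'   attribute `n_empty` counting requested bins that contained no data.
#' @export
bin_profile <- function(profile, centers, halfwidth = 0.5) {
  stopifnot(inherits(profile, "bbp_profile"), halfwidth > 0)
  centers <- sort(centers)
  vals <- vapply(centers, function(ct) {
    sel <- abs(profile$depth - ct) <= halfwidth
    if (any(sel)) mean(profile$value[sel]) else NA_real_
  }, numeric(1))
  keep <- is.finite(vals)
  out <- bbp_profile(centers[keep], vals[keep], time = profile$time,
                     wavelength = profile$wavelength,
                     flags = rep("binned", sum(keep)))
  out$removed <- profile$removed
  attr(out, "n_empty") <- sum(!keep)
  out
}

#' Subtract a dark offset from a profile
#'
#' The instrument dark signal (measured as a capped-sensor profile,
#' averaged) is removed from every point. Points driven negative are
#' flagged but retained.
#'
#' @param profile A [bbp_profile].
#' @param dark_value Dark offset in the profile's units (finite scalar).
#' @return The corrected profile with flags `"dark-corrected"` (and
#'   attribute `n_negative` counting points pushed below zero).
#' @export
dark_offset <- function(profile, dark_value) {
  stopifnot(inherits(profile, "bbp_profile"),
            is.numeric(dark_value), length(dark_value) == 1L,
            is.finite(dark_value))
  out <- profile
  out$value <- profile$value - dark_value
  out$flags <- rep("dark-corrected", profile$n)
  neg <- out$value < 0
  if (any(neg)) out$flags[neg] <- "dark-corrected-negative"
  attr(out, "n_negative") <- sum(neg)
  out
}

#' Pair a binned profile with bottle sampling depths
#'
#' For each bottle depth, the profile value at the nearest depth within
#' `tolerance` is selected; when two candidates are equidistant the
#' shallower one is chosen. Bottles with no candidate are reported with a
#' missing value.
#'
#' @param profile A (typically binned) [bbp_profile].
#' @param bottle_depths Nominal bottle depths, m.
#' @param tolerance Maximum |depth difference| for a match, m (default 0.5,
#'   matching the binning half-width).
#' @return A data frame with columns `bottle_depth`, `depth` (matched
#'   profile depth or NA) and `value`.
#' @export
match_bottles <- function(profile, bottle_depths, tolerance = 0.5) {
  stopifnot(inherits(profile, "bbp_profile"), tolerance > 0)
  rows <- lapply(sort(bottle_depths), function(bd) {
    dist <- abs(profile$depth - bd)
    ok <- which(dist <= tolerance)
    if (length(ok) == 0) {
      return(data.frame(bottle_depth = bd, depth = NA_real_,
                        value = NA_real_))
    }
    # ties broken toward the shallower depth: order by distance then depth
    best <- ok[order(dist[ok], profile$depth[ok])][1]
    data.frame(bottle_depth = bd, depth = profile$depth[best],
               value = profile$value[best])
  })
  do.call(rbind, rows)
}

#' Read / write profiles as delimited text
#'
#' The on-disk convention is long format with columns
#' `time, depth, value, flag`; one file may hold many casts.
#'
#' @param path File path.
#' @param wavelength Wavelength to attach, nm.
#' @param sep Field separator.
#' @return `read_profile_series()` returns a [profile_series];
#'   `write_profile_series()` returns the path invisibly.
#' @export
read_profile_series <- function(path, wavelength = 700, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time", "depth", "value")
  if (!all(need %in% names(df))) {
    stop("profile file must have columns time, depth, value")
  }
  profs <- lapply(split(df, df$time), function(g) {
    bbp_profile(g$depth, g$value, time = g$time[1], wavelength = wavelength,
                flags = if ("flag" %in% names(g)) g$flag else NULL)
  })
  profs <- profs[order(vapply(profs, function(p) as.numeric(p$time),
                              numeric(1)))]
  profile_series(profs)
}

#' @rdname read_profile_series
#' @param series A [profile_series] to write.
#' @export
write_profile_series <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "profile_series"))
  df <- do.call(rbind, lapply(series$profiles, function(p) {
    data.frame(time = as.numeric(p$time), depth = p$depth, value = p$value,
               flag = p$flags, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' QC report for a profile or series
#'
#' Counts of points removed or flagged per QC step, serializable to JSON.
#'
#' @param x A [bbp_profile] or [profile_series].
#' @param path Optional JSON output path.
#' @return A list of per-flag counts (invisibly when written to a file).
#' @export
qc_report <- function(x, path = NULL) {
  profiles <- if (inherits(x, "profile_series")) x$profiles else list(x)
  removed <- do.call(rbind, lapply(profiles, function(p) p$removed))
  counts <- if (is.null(removed) || nrow(removed) == 0) {
    list()
  } else {
    as.list(table(removed$flag))
  }
  rep <- list(n_profiles = length(profiles),
              n_points = sum(vapply(profiles, function(p) p$n, numeric(1))),
              removed = counts)
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA), path)
    return(invisible(rep))
  }
  rep
}
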