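#' @title Type-I and type-II linear regression
#' @description
#' Fits of the line `y = B * x + A` by four methods: ordinary least squares
#' (OLS, type I), and the type-II family — standard major axis (SMA), major
#' axis (MA) and ranged major axis (RMA). Type-I regression minimizes
#' vertical deviations and is appropriate when the aim is predicting y from
#' an x that carries negligible error; type-II methods treat the errors on
#' both variables symmetrically and are appropriate when the aim is the
#' slope/intercept of the underlying relationship between two measured
#' quantities. When the predictor is noisy, the OLS slope is attenuated
#' toward zero (regression dilution) by the factor
#' `Var(x_true) / (Var(x_true) + Var(x_error))`, which is why the two
#' families disagree unless the correlation is perfect.
#'
#' All four estimators share the properties that the fitted line passes
#' through the centroid `(mean(x), mean(y))` and that `r` and `r^2` are
#' those of the data, independent of the method.
#' @name regression
NULL

# Internal: centered sums of squares/products and centroid.
.biv_moments <- function(d) {
  x <- d$x; y <- d$y; n <- d$n
  xbar <- mean(x); ybar <- mean(y)
  dx <- x - xbar; dy <- y - ybar
  list(n = n, xbar = xbar, ybar = ybar,
       Sxx = sum(dx * dx), Syy = sum(dy * dy), Sxy = sum(dx * dy))
}

.check_fittable <- function(m, need_y_var = FALSE) {
  if (m$n < 3) {
    stop("insufficient data: at least 3 paired observations are required (n = ",
         m$n, ")", call. = FALSE)
  }
  if (m$Sxx <= 0) {
    stop("unfittable dataset: x has zero variance", call. = FALSE)
  }
  if (need_y_var && m$Syy <= 0) {
    stop("unfittable dataset: y has zero variance", call. = FALSE)
  }
  invisible(TRUE)
}

.corr <- function(m) {
  if (m$Sxx <= 0 || m$Syy <= 0) return(NA_real_)
  m$Sxy / sqrt(m$Sxx * m$Syy)
}

# Internal: residual variance about an arbitrary line (vertical deviations),
# and OLS-convention standard errors. se_B for the type-II methods is set to
# the OLS slope standard error; se_A is propagated through the centroid
# constraint A = ybar - B*xbar as se_A^2 = se_B^2*xbar^2 + s_res^2/n.
.fit_se <- function(d, m, B, A, method) {
  res <- d$y - (B * d$x + A)
  s2 <- if (m$n > 2) sum(res^2) / (m$n - 2) else NA_real_
  if (method == "OLS") {
    res_ols <- d$y - (m$ybar + (m$Sxy / m$Sxx) * (d$x - m$xbar))
    s2_ols <- if (m$n > 2) sum(res_ols^2) / (m$n - 2) else NA_real_
    se_B <- sqrt(s2_ols / m$Sxx)
    se_A <- sqrt(s2_ols * (1 / m$n + m$xbar^2 / m$Sxx))
  } else {
    res_ols <- d$y - (m$ybar + (m$Sxy / m$Sxx) * (d$x - m$xbar))
    s2_ols <- if (m$n > 2) sum(res_ols^2) / (m$n - 2) else NA_real_
    se_B <- sqrt(s2_ols / m$Sxx)
    se_A <- sqrt(se_B^2 * m$xbar^2 + s2 / m$n)
  }
  list(se_B = se_B, se_A = se_A, s2 = s2)
}

.new_linear_fit <- function(method, d, m, B, A) {
  r <- .corr(m)
  se <- .fit_se(d, m, B, A, method)
  structure(
    list(method = method, B = B, A = A,
         se_B = se$se_B, se_A = se$se_A,
         r = r, r2 = r * r, n = m$n,
         xbar = m$xbar, ybar = m$ybar,
         labels = d$labels, units = d$units),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit %s> %s = B * %s + A\n", x$method,
              x$labels[2], x$labels[1]))
  cat(sprintf("  B = %.6g (se %.3g)   A = %.6g (se %.3g)\n",
              x$B, x$se_B, x$A, x$se_A))
  cat(sprintf("  r = %.4f  r2 = %.4f  n = %d\n", x$r, x$r2, x$n))
  invisible(x)
}

#' Ordinary least squares fit (type-I regression)
#'
#' Minimizes the sum of squared vertical deviations of y from the line.
#' Appropriate when predicting y from x, or when x is error-free.
#'
#' @param data A [bivariate_data] object (or data frame with columns
#'   `x`, `y`).
#' @return A `linear_fit` object with elements `method`, `B` (slope), `A`
#'   (intercept), `se_B`, `se_A`, `r`, `r2`, `n`.
#' @examples
#' fit_ols(bivariate_data(1:5, c(2, 3, 5, 4, 6)))
#' @seealso [fit_sma()], [fit_ma()], [fit_rma()]
#' @export
fit_ols <- function(data) {
  d <- as_bivariate(data)
  m <- .biv_moments(d)
  .check_fittable(m)
  B <- m$Sxy / m$Sxx
  A <- m$ybar - B * m$xbar
  .new_linear_fit("OLS", d, m, B, A)
}

#' Significance test for the correlation coefficient
#'
#' Two-tailed t-test of the null hypothesis r = 0, with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Type-II slopes themselves cannot be tested for significance, so this
#' correlation test is the gate controlling whether an SMA fit is
#' meaningful at all.
#'
#' @inheritParams fit_ols
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A list with `significant` (logical), `t`, `p`, `r`, `df`,
#'   `alpha`, and `degenerate` (TRUE when |r| = 1, where t is infinite and
#'   significance holds by convention).
#' @examples
#' correlation_significance(bivariate_data(1:5, c(2, 3, 5, 4, 6)))
#' @export
correlation_significance <- function(data, alpha = 0.05) {
  d <- as_bivariate(data)
  m <- .biv_moments(d)
  if (m$n < 3) stop("insufficient data: n >= 3 required", call. = FALSE)
  r <- .corr(m)
  df <- m$n - 2L
  degenerate <- is.finite(r) && abs(abs(r) - 1) < .Machine$double.eps^0.5
  if (degenerate) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df = df)
  }
  list(significant = is.finite(p) && p < alpha,
       t = t, p = p, r = r, df = df, alpha = alpha,
       degenerate = degenerate)
}

#' Standard major axis fit (type-II regression)
#'
#' Slope is the ratio of the standard deviations, signed by the
#' correlation: `B = sign(r) * sd(y)/sd(x)`, equivalently `B = B_OLS / r`.
#' This is the symmetric method of choice when both variables carry
#' comparable measurement uncertainty and the aim is the relationship, not
#' prediction. Because its own slope cannot be tested for significance, the
#' fit is gated on the correlation test: by default it refuses datasets
#' whose correlation is not significant at `alpha`.
#'
#' @inheritParams fit_ols
#' @param require_significance Gate the fit on [correlation_significance()]
#'   (default TRUE).
#' @param alpha Significance level for the gate.
#' @return A `linear_fit` object.
#' @examples
#' fit_sma(bivariate_data(1:5, c(2, 3, 5, 4, 6)))
#' @export
fit_sma <- function(data, require_significance = TRUE, alpha = 0.05) {
  d <- as_bivariate(data)
  m <- .biv_moments(d)
  .check_fittable(m, need_y_var = TRUE)
  r <- .corr(m)
  if (r == 0) {
    stop("SMA slope sign is undefined: correlation is exactly zero",
         call. = FALSE)
  }
  if (require_significance) {
    gate <- correlation_significance(d, alpha = alpha)
    if (!gate$significant) {
      stop(sprintf(paste0(
        "SMA fit refused: correlation not significant at alpha = %g ",
        "(r = %.4f, t = %.3f, p = %.4f, df = %d). ",
        "A standard major axis should be computed only when the ",
        "correlation is significant; pass require_significance = FALSE ",
        "to override."), alpha, gate$r, gate$t, gate$p, gate$df),
        call. = FALSE)
    }
  }
  B <- sign(r) * sqrt(m$Syy / m$Sxx)
  A <- m$ybar - B * m$xbar
  .new_linear_fit("SMA", d, m, B, A)
}

#' Major axis fit (type-II regression)
#'
#' Minimizes the sum of squared perpendicular distances to the line (the
#' first principal axis of the covariance matrix). Appropriate when the two
#' variables share units and comparable error variance.
#'
#' @inheritParams fit_ols
#' @return A `linear_fit` object.
#' @examples
#' fit_ma(bivariate_data(1:5, c(2, 3, 5, 4, 6)))
#' @export
fit_ma <- function(data) {
  d <- as_bivariate(data)
  m <- .biv_moments(d)
  .check_fittable(m, need_y_var = TRUE)
  if (m$Sxy == 0) {
    stop("MA orientation is undefined: covariance of x and y is exactly zero",
         call. = FALSE)
  }
  B <- ((m$Syy - m$Sxx) + sqrt((m$Syy - m$Sxx)^2 + 4 * m$Sxy^2)) /
    (2 * m$Sxy)
  A <- m$ybar - B * m$xbar
  .new_linear_fit("MA", d, m, B, A)
}

#' Ranged major axis fit (type-II regression)
#'
#' A major axis computed on range-normalized data, with the slope
#' back-transformed by `range(y)/range(x)`. The normalization makes the
#' method usable for variables with heterogeneous units, at the price of a
#' strong sensitivity to outliers (which stretch the ranges); outliers
#' should be screened before use.
#'
#' @inheritParams fit_ols
#' @return A `linear_fit` object.
#' @export
fit_rma <- function(data) {
  d <- as_bivariate(data)
  m <- .biv_moments(d)
  .check_fittable(m, need_y_var = TRUE)
  rx <- diff(range(d$x))
  ry <- diff(range(d$y))
  if (rx <= 0 || ry <= 0) {
    stop("RMA requires strictly positive ranges in both variables",
         call. = FALSE)
  }
  dn <- bivariate_data(d$x / rx, d$y / ry, labels = d$labels)
  mn <- .biv_moments(dn)
  if (mn$Sxy == 0) {
    stop("RMA orientation is undefined: covariance is exactly zero",
         call. = FALSE)
  }
  Bn <- ((mn$Syy - mn$Sxx) + sqrt((mn$Syy - mn$Sxx)^2 + 4 * mn$Sxy^2)) /
    (2 * mn$Sxy)
  B <- Bn * ry / rx
  A <- m$ybar - B * m$xbar
  .new_linear_fit("RMA", d, m, B, A)
}

#' Fit one or more regression methods at once
#'
#' Convenience wrapper running any subset of the four methods on the same
#' dataset and returning a side-by-side coefficient table.
#'
#' @inheritParams fit_ols
#' @param methods Character vector among `"OLS"`, `"SMA"`, `"MA"`, `"RMA"`.
#' @param require_significance,alpha Passed to [fit_sma()].
#' @return A data frame with one row per requested method and columns
#'   `method`, `B`, `A`, `se_B`, `se_A`, `r`, `r2`, `n`, `note` (empty, or
#'   the refusal/error message for methods that could not be fitted).
#' @export
fit_methods <- function(data, methods = c("OLS", "SMA"),
                        require_significance = TRUE, alpha = 0.05) {
  methods <- match.arg(methods, c("OLS", "SMA", "MA", "RMA"),
                       several.ok = TRUE)
  rows <- lapply(methods, function(mth) {
    fit <- tryCatch(
      switch(mth,
             OLS = fit_ols(data),
             SMA = fit_sma(data, require_significance, alpha),
             MA  = fit_ma(data),
             RMA = fit_rma(data)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      data.frame(method = mth, B = NA_real_, A = NA_real_,
                 se_B = NA_real_, se_A = NA_real_, r = NA_real_,
                 r2 = NA_real_, n = NA_integer_,
                 note = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = mth, B = fit$B, A = fit$A, se_B = fit$se_B,
                 se_A = fit$se_A, r = fit$r, r2 = fit$r2, n = fit$n,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Serialize a fit (or fit table) to JSON
#'
#' @param fit A `linear_fit` object or the data frame from [fit_methods()].
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_report_json <- function(fit, path = NULL) {
  obj <- if (inherits(fit, "linear_fit")) {
    fit[c("method", "B", "A", "se_B", "se_A", "r", "r2", "n")]
  } else {
    fit
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
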