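#' @title Bio-optical carbon models
#' @description
#' Two empirical carbon models built on the particulate backscattering
#' coefficient b_bp(lambda):
#'
#' * Phytoplankton carbon: `C_phyto = (b_bp - bbp_k) * SF`, where `bbp_k`
#'   is the background backscattering of non-algal particles (the b_bp when
#'   chlorophyll is zero, i.e., the intercept of the TChla -> b_bp fit) and
#'   `SF` is a scaling factor calibrated so the mean chlorophyll-to-carbon
#'   ratio equals a laboratory-consistent target (0.010 by default).
#' * Particulate organic carbon: `POC = B * b_bp + A`, a direct linear
#'   model whose coefficients come from b_bp-POC match-ups.
#'
#' The TChla -> b_bp relation is asymmetric (chlorophyll is the cause,
#' backscattering the effect), so its intercept is derived with TChla on
#' the x axis, never interchanged. The b_bp-POC relation is symmetric with
#' comparable errors on both axes, so SMA is its default method.
#' @name carbon_models
NULL

# Patterns used to sanity-check variable orientation from labels.
.chl_pattern <- "chl"
.bbp_pattern <- "bbp|backscat|b_bp"

#' Carbon model parameters for the phytoplankton carbon model
#'
#' @param wavelength Wavelength of b_bp in nm (443, 555 and 700 are the
#'   usual choices).
#' @param bbp_k Background particulate backscattering, m-1 (>= 0 for a
#'   physically meaningful background; a negative value is kept but
#'   flagged).
#' @param sf Scaling factor, mg C m-2 (> 0).
#' @param method Regression method that produced `bbp_k`.
#' @param se_bbp_k Optional standard error of `bbp_k`.
#' @return An object of class `carbon_model_params`.
#' @export
carbon_model_params <- function(wavelength, bbp_k, sf, method = "OLS",
                                se_bbp_k = NA_real_) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L,
            is.numeric(bbp_k), length(bbp_k) == 1L,
            is.numeric(sf), length(sf) == 1L)
  if (sf <= 0) stop("SF must be strictly positive", call. = FALSE)
  flagged <- FALSE
  if (bbp_k < 0) {
    warning("negative background backscattering bbp_k = ", signif(bbp_k, 4),
            " m-1 is not physically meaningful; flagged", call. = FALSE)
    flagged <- TRUE
  }
  structure(
    list(wavelength = wavelength, bbp_k = bbp_k, sf = sf, method = method,
         se_bbp_k = se_bbp_k, negative_intercept = flagged),
    class = "carbon_model_params"
  )
}

#' @export
print.carbon_model_params <- function(x, ...) {
  cat(sprintf(
    "<carbon_model_params> lambda = %g nm, bbp_k = %.4g m-1 (%s), SF = %g mg C m-2\n",
    x$wavelength, x$bbp_k, x$method, x$sf))
  invisible(x)
}

#' POC model parameters
#'
#' @param wavelength Wavelength of b_bp in nm.
#' @param B Slope, mg C m-3 per m-1 (> 0 for physically meaningful fits;
#'   warned otherwise).
#' @param A Intercept, mg C m-3.
#' @param method Regression method that produced the coefficients.
#' @param se_B,se_A Optional standard errors.
#' @return An object of class `poc_model_params`.
#' @export
poc_model_params <- function(wavelength, B, A, method = "SMA",
                             se_B = NA_real_, se_A = NA_real_) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L,
            is.numeric(B), length(B) == 1L, is.numeric(A), length(A) == 1L)
  if (B <= 0) {
    warning("non-positive POC slope B = ", signif(B, 4),
            " is not physically meaningful", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, B = B, A = A, method = method,
         se_B = se_B, se_A = se_A),
    class = "poc_model_params"
  )
}

#' @export
print.poc_model_params <- function(x, ...) {
  cat(sprintf(
    "<poc_model_params> lambda = %g nm, POC = %.6g * bbp + %.4g (%s)\n",
    x$wavelength, x$B, x$A, x$method))
  invisible(x)
}

#' Derive the background backscattering bbp_k from TChla-b_bp match-ups
#'
#' The background backscattering of non-algal particles is the intercept of
#' the linear fit of b_bp on TChla: the b_bp remaining when chlorophyll is
#' zero. The orientation is fixed — TChla is the independent variable and
#' b_bp the dependent one — and a dataset whose labels indicate the reverse
#' is refused: for parameter estimation in an asymmetric relation the
#' variables cannot be interchanged.
#'
#' @param matchups A [bivariate_data] object with TChla as x and b_bp as y.
#' @param method `"OLS"` (the appropriate method for this asymmetric
#'   parameter-estimation problem) or `"SMA"` (used for comparison).
#' @param wavelength Wavelength of b_bp, nm.
#' @param ... Passed to [fit_sma()] (gate control).
#' @return A `carbon_model_params` object with `bbp_k`, its standard error
#'   and the method tag; `sf` is `NA` until [calibrate_sf()] supplies it.
#' @export
derive_bbpk <- function(matchups, method = c("OLS", "SMA"),
                        wavelength = 700, ...) {
  method <- match.arg(method)
  d <- as_bivariate(matchups)
  xl <- tolower(d$labels[1]); yl <- tolower(d$labels[2])
  if (grepl(.bbp_pattern, xl) && grepl(.chl_pattern, yl)) {
    stop("orientation error: bbp_k is the intercept of the fit of b_bp ",
         "(dependent, y) on TChla (independent, x); the supplied dataset ",
         "has '", d$labels[1], "' as x and '", d$labels[2], "' as y. ",
         "These variables cannot be interchanged for this purpose.",
         call. = FALSE)
  }
  fit <- switch(method, OLS = fit_ols(d), SMA = fit_sma(d, ...))
  p <- structure(
    list(wavelength = wavelength, bbp_k = fit$A, sf = NA_real_,
         method = method, se_bbp_k = fit$se_A,
         negative_intercept = fit$A < 0, fit = fit),
    class = "carbon_model_params"
  )
  if (fit$A < 0) {
    warning("fitted background intercept is negative (",
            signif(fit$A, 4), " m-1); flagged", call. = FALSE)
  }
  p
}

#' Calibrate the carbon scaling factor SF
#'
#' `SF` converts the chlorophyll-covarying part of b_bp into phytoplankton
#' carbon. It is chosen so that the mean chlorophyll-to-carbon ratio over
#' the match-ups equals `target_chl_to_c` (0.010 by default): with
#' `C_phyto = (b_bp - bbp_k) * SF`, requiring `mean(TChla / C_phyto)` to hit
#' the target gives `SF = mean(TChla / (b_bp - bbp_k)) / target_chl_to_c`.
#' Samples with `b_bp <= bbp_k` (no chlorophyll-covarying signal) are
#' excluded and counted.
#'
#' @param tchla,bbp Numeric vectors of matched TChla (mg m-3) and b_bp
#'   (m-1) observations.
#' @param bbp_k Background backscattering, m-1 (scalar or a
#'   `carbon_model_params` object).
#' @param target_chl_to_c Target mean Chl:C ratio (default 0.010).
#' @param stat `"mean_of_ratios"` (default) averages per-sample
#'   `TChla/(b_bp - bbp_k)`; `"ratio_of_means"` uses
#'   `mean(TChla)/mean(b_bp - bbp_k)`.
#' @return A list with `sf` (mg C m-2), `n_used`, `n_excluded`,
#'   `target_chl_to_c` and `stat`.
#' @examples
#' calibrate_sf(0.2, 1.5e-3, bbp_k = 5e-4)$sf  # 20000
#' @export
calibrate_sf <- function(tchla, bbp, bbp_k, target_chl_to_c = 0.010,
                         stat = c("mean_of_ratios", "ratio_of_means")) {
  stat <- match.arg(stat)
  if (inherits(bbp_k, "carbon_model_params")) bbp_k <- bbp_k$bbp_k
  if (target_chl_to_c <= 0) {
    stop("target chlorophyll-to-carbon ratio must be positive", call. = FALSE)
  }
  if (length(tchla) != length(bbp)) stop("tchla and bbp lengths differ")
  excess <- bbp - bbp_k
  valid <- is.finite(tchla) & is.finite(excess) & excess > 0
  if (!any(valid)) {
    stop("no valid samples: every b_bp is at or below the background bbp_k",
         call. = FALSE)
  }
  ratio <- switch(stat,
    mean_of_ratios = mean(tchla[valid] / excess[valid]),
    ratio_of_means = mean(tchla[valid]) / mean(excess[valid]))
  list(sf = ratio / target_chl_to_c,
       n_used = sum(valid), n_excluded = sum(!valid),
       target_chl_to_c = target_chl_to_c, stat = stat)
}

#' Phytoplankton carbon from particulate backscattering
#'
#' Elementwise `C_phyto = (b_bp - bbp_k) * SF`. Values where b_bp falls
#' below the background are negative; they are retained and flagged by
#' default (clamping silently changes depth-integrated budgets), or set to
#' zero with `clamp_negative = TRUE`.
#'
#' @param bbp Numeric vector/matrix of b_bp (m-1) at the model wavelength.
#' @param params A `carbon_model_params` object with `bbp_k` and `sf` set.
#' @param clamp_negative Set negative estimates to zero (default FALSE).
#' @param wavelength Optional wavelength metadata of `bbp`; a mismatch with
#'   `params$wavelength` raises a warning.
#' @return C_phyto in mg C m-3, same shape as `bbp`, with attribute
#'   `negative`: a logical vector marking estimates that were negative
#'   before any clamping.
#' @examples
#' p <- carbon_model_params(700, bbp_k = 5.8e-4, sf = 16455)
#' cphyto_from_bbp(2.0e-3, p)  # ~23.4 mg C m-3
#' @export
cphyto_from_bbp <- function(bbp, params, clamp_negative = FALSE,
                            wavelength = NULL) {
  stopifnot(inherits(params, "carbon_model_params"))
  if (!is.finite(params$sf)) {
    stop("params$sf is not set; calibrate SF first (see calibrate_sf())",
         call. = FALSE)
  }
  if (!is.null(wavelength) && wavelength != params$wavelength) {
    warning("wavelength mismatch: data at ", wavelength,
            " nm, parameters for ", params$wavelength, " nm", call. = FALSE)
  }
  cp <- (bbp - params$bbp_k) * params$sf
  neg <- cp < 0
  if (clamp_negative) cp[neg] <- 0
  attr(cp, "negative") <- neg
  cp
}

#' Fit the POC model from b_bp-POC match-ups
#'
#' Both POC and b_bp are measured with comparable methodological
#' uncertainty and the relation is symmetric, so SMA is the recommended
#' default; OLS is available for comparison. By convention b_bp is x and
#' POC is y.
#'
#' @param matchups A [bivariate_data] object with b_bp as x and POC as y.
#' @param method `"SMA"` (default) or `"OLS"`.
#' @param wavelength Wavelength of b_bp, nm.
#' @param ... Passed to [fit_sma()].
#' @return A `poc_model_params` object carrying the fit's coefficients,
#'   standard errors and method tag.
#' @export
fit_poc_model <- function(matchups, method = c("SMA", "OLS"),
                          wavelength = 700, ...) {
  method <- match.arg(method)
  d <- as_bivariate(matchups)
  fit <- switch(method, OLS = fit_ols(d), SMA = fit_sma(d, ...))
  p <- poc_model_params(wavelength, B = fit$B, A = fit$A, method = method,
                        se_B = fit$se_B, se_A = fit$se_A)
  p$fit <- fit
  p
}

#' Particulate organic carbon from backscattering
#'
#' Elementwise `POC = B * b_bp + A`.
#'
#' @param bbp Numeric vector/matrix of b_bp (m-1).
#' @param params A `poc_model_params` object.
#' @return POC in mg C m-3, same shape as `bbp`.
#' @export
poc_from_bbp <- function(bbp, params) {
  stopifnot(inherits(params, "poc_model_params"))
  params$B * bbp + params$A
}

#' Serialize model parameters to JSON with method provenance
#'
#' @param params A `carbon_model_params` or `poc_model_params` object.
#' @param path Optional file path.
#' @return JSON string (invisibly when written to a file).
#' @export
params_json <- function(params, path = NULL) {
  keep <- setdiff(names(params), "fit")
  js <- jsonlite::toJSON(params[keep], auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
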