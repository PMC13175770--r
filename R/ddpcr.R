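#' Poisson droplet-occupancy correction
#'
#' Mean template copies per droplet from the positive-droplet fraction:
#' `lambda = -ln((total - positives)/total)`.
#' @param positives Positive droplet count(s).
#' @param total Total droplet count(s).
#' @return `lambda`; `Inf` (saturated sentinel) when every droplet is
#'   positive.
#' @export
poisson_concentration <- function(positives, total) {
  if (any(positives < 0) || any(positives > total) || any(total <= 0))
    stop("need 0 <= positives <= total with total > 0", call. = FALSE)
  ifelse(positives == total, Inf, -log((total - positives) / total))
}

#' Raw knockout percentage of a well
#'
#' `100 * (1 - lambda_WT / lambda_ref)` from the Poisson-corrected channel
#' concentrations: the wild-type probe spans the cut site and detects only
#' unedited alleles, the reference probe detects all alleles.
#' @param well One-row data frame (or list) with `wt_positive`,
#'   `ref_positive`, `total_droplets`.
#' @return List: `raw_ko` (clipped to `[0, 100]`), `clipped` flag,
#'   `lambda_wt`, `lambda_ref`.
#' @export
raw_ko <- function(well) {
  lam_wt <- poisson_concentration(well$wt_positive, well$total_droplets)
  lam_ref <- poisson_concentration(well$ref_positive, well$total_droplets)
  if (any(lam_ref == 0))
    stop("reference channel concentration is zero", call. = FALSE)
  raw <- 100 * (1 - lam_wt / lam_ref)
  clipped <- raw < 0 | raw > 100
  list(raw_ko = pmin(pmax(raw, 0), 100), clipped = clipped,
       lambda_wt = lam_wt, lambda_ref = lam_ref)
}

#' Fit the knockout standard curve
#'
#' Least-squares line of measured raw KO against the nominal control
#' levels (default 50/75/100%). The calibration is accepted iff every
#' control's deviation (measured minus nominal, in percentage points) is
#' within the tolerance.
#'
#' @param wells Control-well data frame with `nominal_ko`, `wt_positive`,
#'   `ref_positive`, `total_droplets`.
#' @param tolerance Allowed absolute deviation, percentage points.
#' @return Object of class `ko_calibration`: `slope`, `intercept`,
#'   `controls` (nominal, measured, deviation), `accepted`, `tolerance`.
#' @export
fit_ko_curve <- function(wells, tolerance = 10) {
  if (length(unique(wells$nominal_ko)) < 2)
    stop("need controls at >= 2 distinct nominal KO levels", call. = FALSE)
  measured <- raw_ko(wells)$raw_ko
  fit <- stats::lm.fit(cbind(1, wells$nominal_ko), measured)
  dev <- measured - wells$nominal_ko
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    controls = data.frame(nominal = wells$nominal_ko, measured = measured,
                          deviation = dev),
    accepted = all(abs(dev) <= tolerance),
    tolerance = tolerance), class = "ko_calibration")
}

#' @export
print.ko_calibration <- function(x, ...) {
  cat(sprintf("ko_calibration: slope %.4f, intercept %.3f, %s (tol ±%g pp)\n",
              x$slope, x$intercept,
              if (x$accepted) "ACCEPTED" else "REJECTED", x$tolerance))
  print(x$controls)
  invisible(x)
}

#' Calibrated knockout estimate for a sample well
#'
#' Inverts the accepted standard curve: `(raw - intercept) / slope`,
#' clipped to `[0, 100]`.
#' @param well Sample well (see [raw_ko()]).
#' @param calibration An accepted [fit_ko_curve()] result.
#' @return List: `ko` (calibrated %), `raw_ko`, `clipped`.
#' @export
estimate_ko <- function(well, calibration) {
  stopifnot(inherits(calibration, "ko_calibration"))
  if (!calibration$accepted)
    stop("calibration rejected: control deviation exceeds ±",
         calibration$tolerance, " percentage points", call. = FALSE)
  r <- raw_ko(well)
  ko <- (r$raw_ko - calibration$intercept) / calibration$slope
  clipped <- ko < 0 | ko > 100
  list(ko = pmin(pmax(ko, 0), 100), raw_ko = r$raw_ko,
       clipped = clipped | r$clipped)
}
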