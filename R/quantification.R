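#' Fit a linear calibration curve
#'
#' Ordinary least-squares regression of integrated peak area (mAU) on
#' concentration (mg/mL), the standard external-calibration model.
#'
#' @param conc concentrations in mg/mL (>= 2 distinct values).
#' @param area peak areas in mAU.
#' @param analyte optional analyte label.
#' @return An object of class `"calibration_curve"`: list with `analyte`,
#'   `slope`, `intercept`, `r2`, `fit_range` (mg/mL).
#' @export
fit_calibration <- function(conc, area, analyte = NA_character_) {
  stopifnot(length(conc) == length(area), length(conc) >= 2)
  if (length(unique(conc)) < 2) stop("all concentrations equal")
  fit <- stats::lm(area ~ conc)
  sst <- sum((area - mean(area))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  res <- list(analyte = analyte,
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r2 = r2,
              fit_range = range(conc))
  class(res) <- "calibration_curve"
  res
}

#' Calibration curve from published slope/intercept
#'
#' Wraps known regression coefficients (e.g. the published curves from
#' [gsb_calibration_curves()]) as a `"calibration_curve"` object usable with
#' [concentration_from_area()].
#'
#' @param slope mAU per (mg/mL), > 0.
#' @param intercept mAU.
#' @param analyte optional label.
#' @param fit_range concentration range of the original fit, mg/mL.
#' @return a `"calibration_curve"`.
#' @export
calibration_curve <- function(slope, intercept, analyte = NA_character_,
                              fit_range = c(0, Inf)) {
  stopifnot(slope > 0)
  res <- list(analyte = analyte, slope = slope, intercept = intercept,
              r2 = NA_real_, fit_range = fit_range)
  class(res) <- "calibration_curve"
  res
}

#' Invert a calibration curve
#'
#' Concentration `(area - intercept) / slope` in mg/mL. Areas below the
#' intercept would give negative concentrations; these are reported as 0
#' with a warning and flagged `below_lod`. Concentrations outside the fitted
#' range are flagged `extrapolated`.
#'
#' @param curve a `"calibration_curve"`.
#' @param area peak area(s) in mAU.
#' @return numeric concentration(s) in mg/mL with logical attributes
#'   `below_lod` and `extrapolated`.
#' @export
concentration_from_area <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope != 0)
  conc <- (area - curve$intercept) / curve$slope
  below <- conc < 0
  if (any(below)) {
    warning("area(s) below the calibration intercept: reported as 0 ",
            "(below limit of detection)")
    conc[below] <- 0
  }
  extra <- conc < curve$fit_range[1] | conc > curve$fit_range[2]
  attr(conc, "below_lod") <- below
  attr(conc, "extrapolated") <- extra & !below
  conc
}

#' Content in mg per g of powder
#'
#' Converts an extract concentration to content under the extraction scheme:
#' `content = conc * volume * dilution / mass`. Defaults are the standard
#' prep of 0.5 g powder extracted into 20 mL of methanol, undiluted.
#'
#' @param conc extract concentration, mg/mL.
#' @param mass powder mass, g.
#' @param volume extraction solvent volume, mL.
#' @param dilution dilution factor (>= 1).
#' @return content in mg/g.
#' @export
content_mg_g <- function(conc, mass = 0.5, volume = 20, dilution = 1) {
  stopifnot(mass > 0, volume > 0, dilution >= 1)
  conc * volume * dilution / mass
}

#' Spike recovery rate
#'
#' `(measured - original) / added * 100`, the accuracy statistic of the
#' standard-addition recovery test.
#'
#' @param original analyte amount in the unspiked portion, mg.
#' @param added spiked amount, mg (> 0).
#' @param measured total amount found after spiking, mg.
#' @return recovery in percent.
#' @export
spike_recovery <- function(original, added, measured) {
  if (any(added <= 0)) stop("added amount must be positive")
  (measured - original) / added * 100
}
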