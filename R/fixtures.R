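#' Published 44-batch Q-marker content table
#'
#' Loads the packaged content table for the 44 Gentiana scabra Bunge. (GSB)
#' batches S1--S44: swertiamarin, gentiopicroside and sweroside in mg/g dry
#' powder, plus the published per-batch total. This table is the canonical
#' input of the quality-evaluation stage (composite PCA score, entropy-weighted
#' TOPSIS, hierarchical grading).
#'
#' An integrity check verifies that every row's three components sum to the
#' published total within `1e-3` mg/g, that batch S42 sums exactly to
#' 32.1386 mg/g, and that the table has 44 rows; a corrupted fixture aborts.
#'
#' @param check logical; run the integrity check (default `TRUE`).
#' @return A data.frame with 44 rows (batch ids as rownames) and columns
#'   `swertiamarin`, `gentiopicroside`, `sweroside`, `total` (mg/g).
#' @export
#' @examples
#' contents <- gsb_contents()
#' contents["S10", ]
gsb_contents <- function(check = TRUE) {
  path <- system.file("extdata", "gsb_qmarker_contents.csv",
                      package = "qmarkereval", mustWork = TRUE)
  tab <- utils::read.csv(path, row.names = 1)
  if (check) {
    if (nrow(tab) != 44L || !identical(names(tab),
        c("swertiamarin", "gentiopicroside", "sweroside", "total")))
      stop("content fixture corrupted: unexpected shape")
    if (any(tab[, 1:3] <= 0))
      stop("content fixture corrupted: non-positive content")
    sums <- rowSums(tab[, 1:3])
    if (any(abs(sums - tab$total) > 1e-3))
      stop("content fixture corrupted: row totals disagree with components")
    if (abs(sums["S42"] - 32.1386) > 1e-9)
      stop("content fixture corrupted: S42 checksum failed")
  }
  tab
}

#' Published calibration curves for the three Q-markers
#'
#' Linear calibration curves (peak area in mAU versus concentration in mg/mL)
#' for swertiamarin, gentiopicroside and sweroside, as fitted on the
#' quantification gradient.
#'
#' @return A data.frame with one row per analyte and columns `analyte`,
#'   `slope` (mAU per mg/mL) and `intercept` (mAU).
#' @export
#' @examples
#' gsb_calibration_curves()
gsb_calibration_curves <- function() {
  data.frame(
    analyte   = c("swertiamarin", "gentiopicroside", "sweroside"),
    slope     = c(4650.7, 5908.2, 8083.9),
    intercept = c(1.0924, 61.304, -1.5587),
    stringsAsFactors = FALSE
  )
}

#' Published reference tables for the quality-evaluation stage
#'
#' Expected intermediate results of the quality evaluation of the 44 GSB
#' batches, as published: the min-max normalized content matrix, the
#' proportion ("specific gravity") matrix, and the first-principal-component
#' scores, overall scores and ranks. Values are printed at 3 (matrices) or 2
#' (scores) decimals; they serve as regression anchors for the pipeline.
#'
#' @param which one of `"normalized"`, `"proportions"`, `"scores"`.
#' @return A data.frame with 44 rows, batch ids as rownames.
#' @export
gsb_expected <- function(which = c("normalized", "proportions", "scores")) {
  which <- match.arg(which)
  file <- paste0("gsb_expected_", which, ".csv")
  path <- system.file("extdata", file, package = "qmarkereval", mustWork = TRUE)
  utils::read.csv(path, row.names = 1)
}
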