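#' Fluorescence-quenching activity percentage
#'
#' The binding statistic of the four-control plate design (A: lysate, B:
#' lysate + ligand, C: protein, D: protein + ligand):
#'
#' \deqn{AP = \frac{F_B + F_C - F_A - F_D}{F_B + F_C - 2F_A} \times 100}
#'
#' i.e. the shortfall of the observed mixture fluorescence D below its
#' additive expectation (B + C - A), as a percentage of the
#' background-corrected interaction signal. AP is 0 under perfect
#' additivity (no interaction), 100 when the mixture fluoresces no more than
#' the lysate alone (complete quench), negative for enhancement; values are
#' reported unclipped. Invariant to rescaling all four intensities by a
#' common positive factor, and strictly decreasing in `fd`.
#'
#' @param fa,fb,fc,fd mean fluorescence intensities of control groups A-D
#'   (arbitrary units); vectorized.
#' @return activity percentage(s).
#' @export
activity_percentage <- function(fa, fb, fc, fd) {
  denom <- fb + fc - 2 * fa
  if (any(denom <= 0))
    stop("invalid assay: FB + FC - 2*FA must be positive")
  (fb + fc - fa - fd) / denom * 100
}

#' Activity percentages from a plate-reading table
#'
#' Computes the per-component activity percentage on replicate means, plus
#' replicate-wise activity percentages (replicates paired by index across
#' the four groups) and their standard deviation.
#'
#' @param plate data.frame with columns `component`, `group` (values A-D),
#'   `replicate`, `intensity`, e.g. from [generate_fluorescence_assay()].
#' @return data.frame with columns `component`, `activity_pct` (from group
#'   means), `sd` (across replicate-wise APs), `n_replicates`.
#' @export
activity_from_plate <- function(plate) {
  stopifnot(all(c("component", "group", "replicate", "intensity")
                %in% names(plate)),
            all(plate$group %in% c("A", "B", "C", "D")))
  out <- lapply(split(plate, plate$component), function(d) {
    mu <- tapply(d$intensity, d$group, mean)
    wide <- stats::reshape(d[, c("group", "replicate", "intensity")],
                           direction = "wide", idvar = "replicate",
                           timevar = "group")
    ap_rep <- activity_percentage(wide$intensity.A, wide$intensity.B,
                                  wide$intensity.C, wide$intensity.D)
    data.frame(component = d$component[1],
               activity_pct = activity_percentage(mu[["A"]], mu[["B"]],
                                                  mu[["C"]], mu[["D"]]),
               sd = stats::sd(ap_rep),
               n_replicates = nrow(wide))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Z-score normalization
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation; removes the
#' scale differences between the components' raw activity percentages so
#' their relative activities are comparable.
#'
#' @param x numeric vector, length >= 2.
#' @return z-scores (mean 0, sd 1).
#' @export
z_normalize <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (x - mean(x)) / s
}

#' Rank components by binding activity and select the top candidates
#'
#' Z-normalizes the activity percentages, ranks the components by descending
#' z-score (ties broken alphabetically by component id) and marks the top
#' `k` as selected active Q-marker candidates.
#'
#' @param activity data.frame with columns `component` and `activity_pct`
#'   (e.g. from [activity_from_plate()]).
#' @param k number of components to select.
#' @return data.frame with columns `component`, `activity_pct`, `z`, `rank`,
#'   `selected`, ordered by rank.
#' @export
screen_binding <- function(activity, k = 3) {
  stopifnot(all(c("component", "activity_pct") %in% names(activity)))
  n <- nrow(activity)
  if (k > n) stop("k exceeds the number of components")
  z <- z_normalize(activity$activity_pct)
  ord <- order(-z, as.character(activity$component))
  res <- data.frame(component = activity$component,
                    activity_pct = activity$activity_pct,
                    z = z)[ord, ]
  res$rank <- seq_len(n)
  res$selected <- res$rank <= k
  rownames(res) <- NULL
  res
}

#' Selected active component ids
#'
#' @param results data.frame from [screen_binding()], or any data.frame with
#'   `component` and `z` columns.
#' @param k number of components to select (default 3).
#' @return character vector of the top-`k` component ids by z-score,
#'   descending, ties broken alphabetically.
#' @export
select_active <- function(results, k = 3) {
  if (k > nrow(results)) stop("k exceeds the number of components")
  ord <- order(-results$z, as.character(results$component))
  as.character(results$component[ord][seq_len(k)])
}
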