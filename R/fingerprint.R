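#' Detect chromatographic peaks
#'
#' Finds local maxima above a height and prominence threshold and integrates
#' each peak by the trapezoid rule between its flanking local minima, with a
#' valley-to-valley chord subtracted as local baseline.
#'
#' @param chrom data.frame with columns `time_min` and `intensity_mau`
#'   (strictly increasing time grid).
#' @param min_height minimum apex intensity (mAU).
#' @param min_prominence minimum prominence (mAU): apex height above the
#'   higher of the two flanking valleys bounded by taller peaks or the
#'   signal edges.
#' @return data.frame with columns `rt` (min), `area` (mAU·min), `height`
#'   (mAU); zero rows for a flat or empty signal.
#' @export
detect_peaks <- function(chrom, min_height = 5, min_prominence = 5) {
  stopifnot(min_height >= 0, min_prominence >= 0)
  t <- chrom[[1]]
  y <- chrom[[2]]
  n <- length(y)
  if (n < 3 || any(diff(t) <= 0)) {
    if (n >= 3) stop("time grid must be strictly increasing")
    return(data.frame(rt = numeric(0), area = numeric(0), height = numeric(0)))
  }
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= min_height]
  if (!length(apex))
    return(data.frame(rt = numeric(0), area = numeric(0), height = numeric(0)))

  prom <- vapply(apex, function(a) {
    left <- a
    while (left > 1 && y[left] <= y[a]) left <- left - 1
    lo_l <- if (y[left] > y[a]) min(y[left:a]) else min(y[1:a])
    right <- a
    while (right < n && y[right] <= y[a]) right <- right + 1
    lo_r <- if (y[right] > y[a]) min(y[a:right]) else min(y[a:n])
    y[a] - max(lo_l, lo_r)
  }, numeric(1))
  apex <- apex[prom >= min_prominence]
  if (!length(apex))
    return(data.frame(rt = numeric(0), area = numeric(0), height = numeric(0)))

  # integration bounds: minimum of the signal between consecutive kept apexes
  bounds <- c(1L, vapply(seq_len(length(apex) - 1), function(j) {
    seg <- apex[j]:apex[j + 1]
    seg[which.min(y[seg])]
  }, integer(1)), n)
  out <- lapply(seq_along(apex), function(j) {
    l <- bounds[j]; r <- bounds[j + 1]
    idx <- l:r
    raw <- sum(diff(t[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2)
    base <- (y[l] + y[r]) / 2 * (t[r] - t[l])
    a <- apex[j]
    data.frame(rt = t[a], area = raw - base,
               height = y[a] - (y[l] + (y[r] - y[l]) * (t[a] - t[l]) / (t[r] - t[l])))
  })
  do.call(rbind, out)
}

# lower median: deterministic, order-free convention for even counts
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

# greedy centroid-seeded clustering of pooled peaks, seeds in descending
# area (ties: smaller rt); at most one member per batch, nearest rt wins
cluster_peaks <- function(pool, window) {
  pool <- pool[order(-pool$area, pool$rt), ]
  assigned <- rep(FALSE, nrow(pool))
  clusters <- list()
  repeat {
    free <- which(!assigned)
    if (!length(free)) break
    seed <- free[1]
    centroid <- pool$rt[seed]
    members <- integer(0)
    for (b in unique(pool$batch)) {
      cand <- free[pool$batch[free] == b &
                     abs(pool$rt[free] - centroid) <= window]
      if (!length(cand)) next
      d <- abs(pool$rt[cand] - centroid)
      pick <- cand[order(d, pool$rt[cand])][1]
      members <- c(members, pick)
    }
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      cbind(pool[members, , drop = FALSE],
            centroid = lower_median(pool$rt[members]))
  }
  clusters
}

#' Multi-point retention-time calibration
#'
#' Warps each batch's retention times onto a shared reference peak set, the
#' software-style "multi-point calibration" that precedes narrow-window peak
#' matching. A first proportional pass scales each batch by the retention
#' time of its largest peak; anchor peaks (large peaks recovered in every
#' batch) are then clustered, and each batch is warped piecewise-linearly
#' through its (own RT, anchor median RT) pairs, end segments extrapolated.
#' With two or fewer anchors the warp is the identity.
#'
#' @param tables named list of peak tables (data.frames with `rt`, `area`).
#' @param max_anchors maximum number of anchor peaks; by default every peak
#'   recovered in all batches anchors the warp, so anchor retention times map
#'   exactly onto their cluster medians and extrapolation is minimal.
#' @param anchor_window matching window (min) used on the pre-scaled RTs when
#'   forming anchor clusters; wider than the final matching window because
#'   the pre-scaled residual jitter grows with retention time.
#' @return the list of peak tables with calibrated `rt` (original retention
#'   times kept in `rt_raw`).
#' @export
calibrate_rt <- function(tables, max_anchors = Inf, anchor_window = 0.30) {
  stopifnot(length(tables) >= 2)
  nb <- length(tables)
  if (is.null(names(tables))) names(tables) <- sprintf("B%02d", seq_len(nb))
  # proportional pre-scaling on the dominant peak
  s <- vapply(tables, function(pt) pt$rt[which.max(pt$area)], numeric(1))
  m <- stats::median(s)
  pool <- do.call(rbind, lapply(names(tables), function(b) {
    data.frame(batch = b, rt = tables[[b]]$rt * (m / s[[b]]),
               rt_orig = tables[[b]]$rt, area = tables[[b]]$area)
  }))
  cl <- cluster_peaks(pool, anchor_window)
  full <- Filter(function(x) nrow(x) == nb, cl)
  if (length(full) > max_anchors) {
    med_area <- vapply(full, function(x) stats::median(x$area), numeric(1))
    full <- full[order(-med_area)[seq_len(max_anchors)]]
  }
  lapply(stats::setNames(names(tables), names(tables)), function(b) {
    pt <- tables[[b]]
    pt$rt_raw <- pt$rt
    if (length(full) > 2) {
      xa <- vapply(full, function(cc) cc$rt_orig[cc$batch == b], numeric(1))
      ya <- vapply(full, function(cc) cc$centroid[1], numeric(1))
      o <- order(xa)
      xa <- xa[o]; ya <- ya[o]
      pt$rt <- stats::approx(xa, ya, xout = pt$rt_raw, rule = 2)$y
      # linear extrapolation beyond the end anchors
      k <- length(xa)
      lo <- pt$rt_raw < xa[1]
      hi <- pt$rt_raw > xa[k]
      pt$rt[lo] <- ya[1] + (pt$rt_raw[lo] - xa[1]) * (ya[2] - ya[1]) / (xa[2] - xa[1])
      pt$rt[hi] <- ya[k] + (pt$rt_raw[hi] - xa[k]) * (ya[k] - ya[k - 1]) / (xa[k] - xa[k - 1])
    }
    pt
  })
}

#' Match common peaks across batches
#'
#' Pools the (calibrated) peak tables of all batches and clusters them by
#' greedy centroid-seeded nearest-RT assignment, seeds taken in descending
#' area. A peak is matched to a cluster when its retention time lies within
#' `window` minutes of the cluster centroid; each batch contributes at most
#' one peak per cluster. Only clusters containing exactly one peak from
#' every batch — the common peaks — are retained.
#'
#' @param tables named list of per-batch peak tables (`rt`, `area`).
#' @param window matching tolerance in minutes (maximum |RT - centroid|).
#' @param calibrate apply [calibrate_rt()] first (default `TRUE`).
#' @return An object of class `"common_peak_matrix"`: a list with `areas` and
#'   `rts` (batches x common peaks matrices, columns ordered by retention
#'   time), `centroids`, `window`, and `n_total_clusters`. Zero common peaks
#'   yields empty matrices with a warning.
#' @export
match_common_peaks <- function(tables, window = 0.10, calibrate = TRUE) {
  stopifnot(length(tables) >= 2, window > 0)
  nb <- length(tables)
  if (is.null(names(tables))) names(tables) <- sprintf("B%02d", seq_len(nb))
  if (calibrate) tables <- calibrate_rt(tables, anchor_window = 3 * window)
  pool <- do.call(rbind, lapply(names(tables), function(b) {
    pt <- tables[[b]]
    data.frame(batch = b, rt = pt$rt,
               rt_raw = if ("rt_raw" %in% names(pt)) pt$rt_raw else pt$rt,
               area = pt$area)
  }))
  cl <- cluster_peaks(pool, window)
  full <- Filter(function(x) nrow(x) == nb, cl)
  if (!length(full)) {
    warning("no common peaks found")
    res <- list(areas = matrix(numeric(0), nb, 0,
                               dimnames = list(names(tables), NULL)),
                rts = matrix(numeric(0), nb, 0,
                             dimnames = list(names(tables), NULL)),
                centroids = numeric(0), window = window,
                n_total_clusters = length(cl))
    class(res) <- "common_peak_matrix"
    return(res)
  }
  full <- full[order(vapply(full, function(x) x$centroid[1], numeric(1)))]
  ids <- sprintf("P%02d", seq_along(full))
  areas <- sapply(full, function(cc) cc$area[match(names(tables), cc$batch)])
  rts <- sapply(full, function(cc) cc$rt_raw[match(names(tables), cc$batch)])
  dimnames(areas) <- dimnames(rts) <- list(names(tables), ids)
  res <- list(areas = areas, rts = rts,
              centroids = vapply(full, function(x) x$centroid[1], numeric(1)),
              window = window, n_total_clusters = length(cl))
  class(res) <- "common_peak_matrix"
  res
}

#' Median reference fingerprint
#'
#' Element-wise median of the common-peak matrix over batches — the "median
#' method" reference chromatogram R against which batch similarities are
#' computed. The lower median is used for even batch counts so the reference
#' is always an observed value and the operation is deterministic.
#'
#' @param matrix a `"common_peak_matrix"`.
#' @return data.frame with one row per common peak: `peak`, `rt`, `area`.
#' @export
build_reference <- function(matrix) {
  stopifnot(inherits(matrix, "common_peak_matrix"), ncol(matrix$areas) > 0)
  data.frame(peak = colnames(matrix$areas),
             rt = apply(matrix$rts, 2, lower_median),
             area = apply(matrix$areas, 2, lower_median),
             row.names = NULL)
}

#' Fingerprint similarity
#'
#' Congruence (cosine) between two common-peak area vectors: the convention
#' of chromatographic fingerprint similarity software. Scale-invariant,
#' symmetric, 1 iff the vectors are proportional. A Pearson correlation
#' variant is available.
#'
#' @param sample_areas,reference_areas equal-length non-negative area vectors.
#' @param method `"cosine"` (default) or `"correlation"`.
#' @return similarity in \[-1, 1\] (non-negative vectors give \[0, 1\]).
#' @export
fingerprint_similarity <- function(sample_areas, reference_areas,
                                   method = c("cosine", "correlation")) {
  method <- match.arg(method)
  stopifnot(length(sample_areas) == length(reference_areas))
  if (all(sample_areas == 0) || all(reference_areas == 0))
    stop("similarity undefined for a zero vector")
  if (method == "cosine") {
    sum(sample_areas * reference_areas) /
      sqrt(sum(sample_areas^2) * sum(reference_areas^2))
  } else {
    stats::cor(sample_areas, reference_areas)
  }
}

#' Relative retention times and areas against the reference peak S
#'
#' Divides every cell of the common-peak matrix by that batch's value for the
#' reference peak S. When `reference_peak = "auto"`, S is the common peak
#' with the largest median area — the well-separated, large, stable peak the
#' fingerprint convention designates.
#'
#' @param matrix a `"common_peak_matrix"`.
#' @param reference_peak `"auto"`, a column name, or a column index.
#' @return list with `relative_rt`, `relative_area` (same shape as the input
#'   matrices; the S column is identically 1) and `reference_peak` (column
#'   index).
#' @export
relative_metrics <- function(matrix, reference_peak = "auto") {
  stopifnot(inherits(matrix, "common_peak_matrix"), ncol(matrix$areas) > 0)
  s <- if (identical(reference_peak, "auto")) {
    unname(which.max(apply(matrix$areas, 2, stats::median)))
  } else if (is.character(reference_peak)) {
    match(reference_peak, colnames(matrix$areas))
  } else as.integer(reference_peak)
  if (is.na(s) || s < 1 || s > ncol(matrix$areas))
    stop("reference peak is not a common peak")
  if (any(matrix$areas[, s] == 0)) stop("reference peak area of zero")
  list(relative_rt = matrix$rts / matrix$rts[, s],
       relative_area = matrix$areas / matrix$areas[, s],
       reference_peak = s)
}

#' Relative standard deviation
#'
#' Sample (n-1) standard deviation divided by the mean, in percent: the
#' method-validation statistic for precision, repeatability and stability.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Build a complete fingerprint from multi-batch chromatograms or peak tables
#'
#' Convenience wrapper over the fingerprint stage: peak detection (if
#' chromatograms are supplied), retention-time calibration, common-peak
#' matching, the median reference, per-batch similarities and the RSD
#' validation statistics of the relative metrics.
#'
#' @param x named list of chromatograms (data.frames `time_min`,
#'   `intensity_mau`) or of peak tables (`rt`, `area`).
#' @param window matching window in minutes.
#' @param min_height,min_prominence peak-detection thresholds (chromatogram
#'   input only).
#' @param method similarity metric, see [fingerprint_similarity()].
#' @param reference_peak see [relative_metrics()].
#' @return list with `matrix` (common-peak matrix), `reference`,
#'   `similarity` (named, rounded to 3 decimals for reporting), `relative`
#'   (relative metrics), and `rsd` (per-peak RSD % of relative RT and
#'   relative area).
#' @export
build_fingerprint <- function(x, window = 0.10, min_height = 2,
                              min_prominence = 2,
                              method = "cosine", reference_peak = "auto") {
  is_chrom <- all(vapply(x, function(d) "time_min" %in% names(d), logical(1)))
  tables <- if (is_chrom) {
    lapply(x, detect_peaks, min_height = min_height,
           min_prominence = min_prominence)
  } else x
  m <- match_common_peaks(tables, window = window)
  ref <- build_reference(m)
  sim <- round(apply(m$areas, 1, fingerprint_similarity, ref$area,
                     method = method), 3)
  rel <- relative_metrics(m, reference_peak)
  list(matrix = m, reference = ref, similarity = sim, relative = rel,
       rsd = data.frame(peak = colnames(m$areas),
                        relative_rt_rsd = apply(rel$relative_rt, 2, rsd),
                        relative_area_rsd = apply(rel$relative_area, 2, rsd),
                        row.names = NULL))
}
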