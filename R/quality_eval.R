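#' Min-max normalization of a decision matrix
#'
#' `(x - column min) / (column max - column min)`, mapping every criterion to
#' \[0, 1\]. All criteria are treated as benefit-type (higher content =
#' better quality); invariant to affine rescaling of any raw column.
#'
#' @param x batches x criteria matrix or data.frame of raw contents (mg/g).
#' @return matrix of normalized values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, all(is.finite(x)))
  rng <- apply(x, 2, range)
  flat <- rng[2, ] - rng[1, ] == 0
  if (any(flat))
    stop("constant column(s): ", paste(colnames(x)[flat], collapse = ", "))
  sweep(sweep(x, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' Proportion ("specific gravity") matrix
#'
#' Each normalized value divided by its column sum: `p_ij = xn_ij / sum_i
#' xn_ij`. Columns sum to 1; the input to the entropy weights.
#'
#' @param nm min-max normalized matrix from [minmax_normalize()].
#' @return matrix of proportions.
#' @export
proportion_matrix <- function(nm) {
  nm <- as.matrix(nm)
  cs <- colSums(nm)
  if (any(cs <= 0)) stop("all-zero column in normalized matrix")
  sweep(nm, 2, cs, "/")
}

#' Entropy weights
#'
#' Information-entropy weighting of the criteria: per-criterion entropy
#' `e_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), divergence
#' `d_j = 1 - e_j`, and weights `w_j = d_j / sum_k d_k`. Criteria whose
#' proportions are more dispersed (lower entropy) carry more weight —
#' objective weighting from the data's own variability.
#'
#' @param p proportion matrix from [proportion_matrix()].
#' @return An object of class `"entropy_weights"`: list with `e` (entropies),
#'   `d` (divergences), `w` (weights summing to 1).
#' @export
entropy_weights <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  stopifnot(n >= 2, all(p >= 0),
            all(abs(colSums(p) - 1) < 1e-8))
  e <- apply(p, 2, function(col) {
    terms <- ifelse(col > 0, col * log(col), 0)
    -sum(terms) / log(n)
  })
  d <- 1 - e
  if (all(d < 1e-12)) stop("all criteria uniform: entropy weights undefined")
  res <- list(e = e, d = d, w = d / sum(d))
  class(res) <- "entropy_weights"
  res
}

#' TOPSIS closeness to the ideal solution
#'
#' Weighted normalized matrix `v_ij = w_j * xn_ij`; per-criterion ideal
#' (column maximum) and anti-ideal (column minimum) solutions; row-wise
#' Euclidean distances `d+` and `d-` to each; closeness
#' `C_i = d- / (d+ + d-)` in \[0, 1\], ranked descending. The default
#' variant weights the min-max normalized matrix; `variant = "proportion"`
#' weights the proportion matrix instead.
#'
#' @param nm min-max normalized matrix from [minmax_normalize()].
#' @param w weight vector summing to 1, or an `"entropy_weights"` object.
#' @param variant `"normalized"` (default) or `"proportion"`: which matrix
#'   the weights multiply.
#' @return An object of class `"topsis_result"`: list with `v`, `ideal`,
#'   `anti_ideal`, `d_plus`, `d_minus`, `closeness` (named), `rank`
#'   (average-tie ranks, 1 = best).
#' @export
topsis <- function(nm, w, variant = c("normalized", "proportion")) {
  variant <- match.arg(variant)
  if (inherits(w, "entropy_weights")) w <- w$w
  nm <- as.matrix(nm)
  stopifnot(length(w) == ncol(nm), abs(sum(w) - 1) < 1e-8, all(w >= 0))
  base <- if (variant == "proportion") proportion_matrix(nm) else nm
  v <- sweep(base, 2, w, "*")
  ideal <- apply(v, 2, max)
  anti <- apply(v, 2, min)
  d_plus <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, anti)^2))
  if (any(d_plus + d_minus == 0))
    stop("degenerate alternative set: d+ + d- = 0")
  cl <- d_minus / (d_plus + d_minus)
  res <- list(v = v, ideal = ideal, anti_ideal = anti,
              d_plus = d_plus, d_minus = d_minus,
              closeness = stats::setNames(cl, rownames(nm)),
              rank = rank(-cl, ties.method = "average"),
              variant = variant)
  class(res) <- "topsis_result"
  res
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("Entropy-weighted TOPSIS (", x$variant, " variant), ",
      length(x$closeness), " alternatives\n", sep = "")
  cat(sprintf("closeness range: %.3f (%s) to %.3f (%s)\n",
              min(x$closeness), names(which.min(x$closeness)),
              max(x$closeness), names(which.max(x$closeness))))
  invisible(x)
}

#' First-principal-component composite quality score
#'
#' Standardizes the content table, runs correlation-matrix PCA, and scores
#' each batch on the first component: `Y = sum_j a_j X_j` with `a` the first
#' eigenvector and `X_j` the z-scored contents. The overall score weights Y
#' by the first component's variance proportion: `F = (lambda_1 / p) * Y`.
#' Batches are ranked by descending F. Coefficients are recomputed from the
#' eigendecomposition of the input, never fixed.
#'
#' @param contents batches x analytes content table (mg/g).
#' @return data.frame with columns `pc_score` (Y), `overall_score` (F),
#'   `rank` (1 = best; ties by first occurrence), batch rownames; the
#'   `"pca_cor"` fit attached as attribute `"pca"`.
#' @export
composite_score <- function(contents) {
  fit <- pca_cor(contents)
  y <- drop(fit$scores[, 1])
  f <- fit$variance_pct[1] / 100 * y
  out <- data.frame(pc_score = y, overall_score = f,
                    rank = rank(-f, ties.method = "first"),
                    row.names = rownames(fit$scores))
  attr(out, "pca") <- fit
  out
}

#' Hierarchical cluster grading
#'
#' Agglomerative clustering of the z-scored columns (typically the three
#' component contents plus their total) with Euclidean distance, cut into
#' `k` quality grades. Grade labels are reordered so grade 1 has the highest
#' mean quality score (TOPSIS closeness when supplied, otherwise the mean of
#' the standardized row sums).
#'
#' @param x batches x columns table (contents plus total).
#' @param k number of grades (default 3).
#' @param linkage `"average"` (between-groups, the default) or `"ward.D2"`.
#' @param score optional per-batch quality score used to order grades.
#' @return An object of class `"grade_result"`: list with `tree` (hclust),
#'   `labels` (named grade per batch, 1 = best), `sizes`, `k`, `linkage`.
#' @export
hca_grade <- function(x, k = 3, linkage = c("average", "ward.D2"),
                      score = NULL) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  stopifnot(k < nrow(x), k >= 1)
  z <- standardize(x)
  tree <- stats::hclust(stats::dist(unclass(z)), method = linkage)
  raw <- stats::cutree(tree, k = k)
  if (is.null(score)) score <- rowMeans(unclass(z))
  grade_score <- tapply(score, raw, mean)
  remap <- integer(k)
  remap[order(-grade_score)] <- seq_len(k)
  labels <- stats::setNames(remap[raw], rownames(x))
  res <- list(tree = tree, labels = labels,
              sizes = table(factor(labels, levels = seq_len(k))),
              k = k, linkage = linkage)
  class(res) <- "grade_result"
  res
}

#' Merge the quality-evaluation results into a per-batch report
#'
#' Joins TOPSIS closeness, the composite score and the cluster grade on the
#' batch ids and reports the Spearman rank concordance between the two
#' ranking devices.
#'
#' @param topsis a `"topsis_result"`.
#' @param composite data.frame from [composite_score()].
#' @param grades a `"grade_result"`.
#' @return list with `table` (per-batch: closeness, closeness_rank,
#'   pc_score, overall_score, score_rank, grade) and `spearman` (rank
#'   correlation between the two rankings).
#' @export
quality_report <- function(topsis, composite, grades) {
  ids <- names(topsis$closeness)
  if (!setequal(ids, rownames(composite)) ||
      !setequal(ids, names(grades$labels)))
    stop("batch ids differ between stages")
  tab <- data.frame(
    closeness = topsis$closeness[ids],
    closeness_rank = rank(-topsis$closeness[ids], ties.method = "first"),
    pc_score = composite[ids, "pc_score"],
    overall_score = composite[ids, "overall_score"],
    score_rank = composite[ids, "rank"],
    grade = grades$labels[ids],
    row.names = ids)
  rho <- stats::cor(tab$closeness, tab$overall_score, method = "spearman")
  list(table = tab, spearman = rho)
}

#' Full quality evaluation of a content table
#'
#' The complete quality-ranking stage: min-max normalization, proportion
#' matrix, entropy weights, TOPSIS closeness and ranking, PCA composite
#' score, hierarchical grading of contents plus total (grades ordered by
#' mean closeness), and the merged report.
#'
#' @param contents batches x analytes content table (mg/g), e.g.
#'   [gsb_contents()] component columns.
#' @param variant TOPSIS variant, see [topsis()].
#' @param linkage HCA linkage, see [hca_grade()].
#' @param k number of grades.
#' @return list with `normalized`, `proportions`, `weights`, `topsis`,
#'   `composite`, `grades`, `report`.
#' @export
evaluate_quality <- function(contents, variant = "normalized",
                             linkage = "average", k = 3) {
  x <- as.matrix(contents)
  nm <- minmax_normalize(x)
  p <- proportion_matrix(nm)
  w <- entropy_weights(p)
  tp <- topsis(nm, w, variant = variant)
  cs <- composite_score(x)
  gr <- hca_grade(cbind(x, total = rowSums(x)), k = k, linkage = linkage,
                  score = tp$closeness)
  list(normalized = nm, proportions = p, weights = w, topsis = tp,
       composite = cs, grades = gr,
       report = quality_report(tp, cs, gr))
}
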