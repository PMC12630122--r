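#' Column-wise z-score standardization
#'
#' Centers and scales each variable to zero mean and unit sample (n-1)
#' standard deviation, retaining the centers and scales for the inverse
#' transform.
#'
#' @param x samples x variables matrix or data.frame.
#' @return matrix with attributes `"center"` and `"scale"`.
#' @seealso [destandardize()]
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, is.numeric(x))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  out
}

#' Invert [standardize()]
#' @param z matrix produced by [standardize()].
#' @return the original-scale matrix.
#' @export
destandardize <- function(z) {
  ctr <- attr(z, "center"); scl <- attr(z, "scale")
  stopifnot(!is.null(ctr), !is.null(scl))
  out <- sweep(sweep(unclass(z), 2, scl, "*"), 2, ctr, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

# flip eigenvector signs so the largest-magnitude loading per component is
# positive (gives the conventional all-positive first component on
# positively correlated content data)
fix_signs <- function(vectors) {
  flip <- apply(vectors, 2, function(v) sign(v[which.max(abs(v))]))
  sweep(vectors, 2, ifelse(flip == 0, 1, flip), "*")
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the input (i.e. PCA of
#' z-scored variables, the SPSS-style analysis whose eigenvalues sum to the
#' number of variables). Loadings are eigenvectors scaled by the square root
#' of their eigenvalues; scores are projections of the z-scores onto the
#' eigenvectors.
#'
#' @param x samples x variables matrix or data.frame (raw scale; the
#'   function standardizes internally).
#' @return An object of class `"pca_cor"`: list with `eigenvalues`
#'   (descending), `variance_pct`, `cumulative_pct`, `eigenvectors`,
#'   `loadings`, `scores`, `center`, `scale`.
#' @export
pca_cor <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in input")
  if (nrow(x) <= ncol(x))
    warning("fewer samples than variables + 1; PCA may be unstable")
  z <- standardize(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  vec <- fix_signs(e$vectors)
  p <- ncol(x)
  lam <- pmax(e$values, 0)
  loadings <- sweep(vec, 2, sqrt(lam), "*")
  dimnames(vec) <- dimnames(loadings) <-
    list(colnames(x), paste0("PC", seq_len(p)))
  scores <- unclass(z) %*% vec
  res <- list(eigenvalues = lam,
              variance_pct = lam / p * 100,
              cumulative_pct = cumsum(lam / p * 100),
              eigenvectors = vec,
              loadings = loadings,
              scores = scores,
              center = attr(z, "center"),
              scale = attr(z, "scale"))
  class(res) <- "pca_cor"
  res
}

#' @export
print.pca_cor <- function(x, ...) {
  cat("Correlation-matrix PCA:", ncol(x$eigenvectors), "variables,",
      nrow(x$scores), "samples\n")
  print(round(data.frame(eigenvalue = x$eigenvalues,
                         variance_pct = x$variance_pct,
                         cumulative_pct = x$cumulative_pct), 3))
  invisible(x)
}

# one NIPALS predictive PLS1 pass on (X, y); y centered numeric
pls1_component <- function(X, y) {
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  q <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, q = q)
}

# core O-PLS fit used by both the public fit and cross-validation
opls_core <- function(X, y, n_orthogonal) {
  t_o <- matrix(0, nrow(X), 0)
  p_o <- matrix(0, ncol(X), 0)
  w_o <- matrix(0, ncol(X), 0)
  for (a in seq_len(n_orthogonal)) {
    c1 <- pls1_component(X, y)
    wo <- c1$p - sum(c1$w * c1$p) * c1$w       # X-loading part orthogonal to w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break                      # no orthogonal variation left
    wo <- wo / nrm
    to <- drop(X %*% wo)
    po <- drop(crossprod(X, to)) / sum(to^2)
    X <- X - tcrossprod(to, po)
    t_o <- cbind(t_o, to); p_o <- cbind(p_o, po); w_o <- cbind(w_o, wo)
  }
  pred <- pls1_component(X, y)
  list(pred = pred, t_orth = t_o, p_orth = p_o, w_orth = w_o, X_deflated = X)
}

#' Orthogonal partial least squares discriminant analysis (OPLS-DA)
#'
#' Two-class OPLS-DA by the NIPALS O-PLS algorithm: variation in X
#' uncorrelated with the class vector is removed by `n_orthogonal`
#' components, then a single predictive PLS component is fitted on the
#' deflated matrix. X is standardized internally (unit-variance scaling);
#' the class vector is coded numerically and centered. The fit is
#' deterministic. Predictive-component VIP scores, R2Y, and a 7-fold
#' (interleaved, sample-order) cross-validated Q2 are reported.
#'
#' @param x samples x variables matrix (raw scale).
#' @param labels two-class factor/character/logical vector, >= 3 samples per
#'   class.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param n_folds folds for the Q2 cross-validation.
#' @return An object of class `"oplsda"`: list with `scores` (predictive t),
#'   `weights`, `loadings`, `q`, `t_orth`, `p_orth`, `w_orth`, `vip`,
#'   `r2y`, `q2`, `labels`, `n_orthogonal`.
#' @export
opls_da <- function(x, labels, n_orthogonal = 1, n_folds = 7) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (any(table(labels) < 3)) stop("each class needs >= 3 samples")
  stopifnot(nrow(x) == length(labels))
  z <- standardize(x)
  y0 <- ifelse(labels == levels(labels)[1], 1, -1)
  y <- y0 - mean(y0)
  fit <- opls_core(unclass(z), y, n_orthogonal)

  w <- fit$pred$w
  t <- fit$pred$t
  q <- fit$pred$q
  yhat <- t * q
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  p_var <- ncol(x)
  vip <- sqrt(p_var * w^2)      # single predictive component: SSY ratio = 1
  names(vip) <- colnames(x)

  # interleaved sample-order folds, deterministic
  folds <- rep(seq_len(n_folds), length.out = nrow(x))
  press <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2) next
    ztr <- standardize(x[tr, , drop = FALSE])
    zte <- sweep(sweep(x[!tr, , drop = FALSE], 2, attr(ztr, "center")),
                 2, attr(ztr, "scale"), "/")
    ytr <- y0[tr] - mean(y0[tr])
    cf <- opls_core(unclass(ztr), ytr, n_orthogonal)
    Xte <- zte
    if (ncol(cf$w_orth) > 0) {
      for (a in seq_len(ncol(cf$w_orth))) {
        to <- drop(Xte %*% cf$w_orth[, a])
        Xte <- Xte - tcrossprod(to, cf$p_orth[, a])
      }
    }
    yhat_te <- drop(Xte %*% cf$pred$w) * cf$pred$q
    press <- press + sum((y0[!tr] - mean(y0[tr]) - yhat_te)^2)
  }
  q2 <- 1 - press / sum(y^2)

  res <- list(scores = t, weights = w, loadings = fit$pred$p, q = q,
              t_orth = fit$t_orth, p_orth = fit$p_orth, w_orth = fit$w_orth,
              x_deflated = fit$X_deflated,
              vip = vip, r2y = r2y, q2 = q2, labels = labels,
              n_orthogonal = n_orthogonal)
  class(res) <- "oplsda"
  res
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA: 1 predictive +", ncol(x$t_orth), "orthogonal component(s)\n")
  cat(sprintf("R2Y = %.3f, Q2 (7-fold) = %.3f\n", x$r2y, x$q2))
  cat("Variables with VIP > 1:",
      paste(names(sort(x$vip[x$vip > 1], decreasing = TRUE)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP scores of a fitted OPLS-DA model, computed on the predictive
#' component: `VIP_j = sqrt(p * w_j^2)` for normalized predictive weights
#' `w`, so the mean squared VIP is exactly 1.
#'
#' @param fit an `"oplsda"` object.
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "oplsda"))
  fit$vip
}

#' Select discriminating markers by VIP threshold
#'
#' Variables with VIP strictly greater than the threshold, ordered by
#' decreasing VIP (the usual "VIP > 1" significance convention).
#'
#' @param vip_scores named numeric vector (e.g. from [vip()]).
#' @param threshold selection threshold (default 1).
#' @return integer vector of variable indices, names carried over.
#' @export
select_markers <- function(vip_scores, threshold = 1.0) {
  sel <- which(vip_scores > threshold)
  sel[order(-vip_scores[sel])]
}

#' Permutation null distribution of Q2
#'
#' Refits the OPLS-DA model under random label permutations; the resulting
#' Q2 values form the null distribution against which the real-label Q2 is
#' judged.
#'
#' @param x,labels,n_orthogonal as in [opls_da()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return numeric vector of permuted-label Q2 values.
#' @export
opls_permutation_q2 <- function(x, labels, n_perm = 100, n_orthogonal = 1,
                                seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    opls_da(x, sample(labels), n_orthogonal = n_orthogonal)$q2
  }, numeric(1))
}
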