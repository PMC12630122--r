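contents <- function() as.matrix(gsb_contents()[, 1:3])

test_that("min-max normalization reproduces the published matrix", {
  nm <- minmax_normalize(contents())
  expect_equal(round(nm["S1", "swertiamarin"], 3), 0.804)
  expect_equal(nm["S23", "swertiamarin"], 1.000)
  expect_equal(nm["S42", "swertiamarin"], 0.000)
  expect_true(all(apply(nm, 2, min) == 0))
  expect_true(all(apply(nm, 2, max) == 1))
  # full-matrix regression: at most 2 one-ulp (0.001) rounding differences
  diffs <- abs(round(nm, 3) - as.matrix(gsb_expected("normalized")))
  expect_lte(sum(diffs > 5e-4), 2L)
  expect_lt(max(diffs), 1.5e-3)
})

test_that("min-max normalization is affine-invariant and guarded", {
  x <- contents()
  x2 <- x
  x2[, 1] <- 3 * x2[, 1] + 7
  expect_equal(minmax_normalize(x2), minmax_normalize(x),
               ignore_attr = TRUE)
  xc <- cbind(x, flat = 1)
  expect_error(minmax_normalize(xc), "flat")
})

test_that("proportion matrix reproduces the published specific gravities", {
  p <- proportion_matrix(minmax_normalize(contents()))
  expect_equal(round(p["S1", "swertiamarin"], 3), 0.037)
  expect_equal(unname(colSums(p)), rep(1, 3))
  diffs <- abs(round(p, 3) - as.matrix(gsb_expected("proportions")))
  expect_lte(sum(diffs > 5e-4), 2L)
  # degenerate column behaviour
  expect_equal(drop(proportion_matrix(matrix(c(0, 1)))), c(0, 1))
})

test_that("entropy weights follow the dispersion logic", {
  # uniform column has entropy 1 and weight 0
  p <- cbind(u = rep(0.25, 4), v = c(0.7, 0.1, 0.1, 0.1))
  w <- entropy_weights(p)
  expect_equal(unname(w$e["u"]), 1)
  expect_equal(unname(w$w), c(0, 1))
  # fully concentrated two-row column has entropy 0
  p2 <- cbind(a = c(1, 0), b = c(0.5, 0.5))
  expect_equal(unname(entropy_weights(p2)$e["a"]), 0)
  # weight conservation on the published proportions, re-summed independently
  pp <- proportion_matrix(minmax_normalize(contents()))
  ww <- entropy_weights(pp)$w
  expect_equal(unname(ww[1] + ww[2] + ww[3]), 1, tolerance = 1e-12)
  expect_true(all(ww >= 0))
  expect_error(entropy_weights(cbind(rep(0.5, 2), rep(0.5, 2))), "uniform")
})

test_that("entropy weights are invariant to row permutation and duplication", {
  nm <- minmax_normalize(contents())
  p <- proportion_matrix(nm)
  w0 <- entropy_weights(p)$w
  set.seed(1)
  expect_equal(entropy_weights(p[sample(nrow(p)), ])$w, w0)
  nm2 <- rbind(nm, nm)
  expect_equal(entropy_weights(proportion_matrix(nm2))$w, w0,
               tolerance = 1e-6)
})

test_that("TOPSIS closeness behaves on canonical cases", {
  # single criterion: closeness equals the normalized value itself
  nm1 <- matrix(c(0, 0.5, 1), dimnames = list(c("a", "b", "c"), "x"))
  tp1 <- topsis(nm1, w = 1)
  expect_equal(unname(tp1$closeness), c(0, 0.5, 1))
  # an alternative at the column maxima has closeness exactly 1
  nm <- minmax_normalize(contents())
  aug <- rbind(nm, ideal = apply(nm, 2, max))
  w <- entropy_weights(proportion_matrix(nm))
  tp <- topsis(aug, w)
  expect_equal(unname(tp$closeness["ideal"]), 1)
})

test_that("TOPSIS endpoints match the published range", {
  nm <- minmax_normalize(contents())
  w <- entropy_weights(proportion_matrix(nm))
  tp <- topsis(nm, w)
  expect_equal(names(which.max(tp$closeness)), "S10")
  expect_equal(names(which.min(tp$closeness)), "S33")
  expect_equal(round(unname(max(tp$closeness)), 3), 0.953)
  expect_equal(round(unname(min(tp$closeness)), 3), 0.043)
})

test_that("TOPSIS agrees with a hand-computed 5x2 oracle to 6 decimals", {
  nm <- matrix(c(0.0, 0.25, 0.5, 0.75, 1.0,
                 1.0, 0.0, 0.5, 1.0, 0.25), ncol = 2,
               dimnames = list(paste0("r", 1:5), c("c1", "c2")))
  w <- c(0.6, 0.4)
  # spreadsheet-style scalar recomputation, independent of the package path
  v1 <- nm[, 1] * 0.6; v2 <- nm[, 2] * 0.4
  dp <- sqrt((max(v1) - v1)^2 + (max(v2) - v2)^2)
  dm <- sqrt((v1 - min(v1))^2 + (v2 - min(v2))^2)
  oracle <- dm / (dp + dm)
  tp <- topsis(nm, w)
  expect_equal(unname(tp$closeness), unname(oracle), tolerance = 1e-6)
})

test_that("raising a non-extreme alternative never lowers its closeness", {
  nm <- minmax_normalize(contents())
  w <- entropy_weights(proportion_matrix(nm))$w
  base <- topsis(nm, w)$closeness
  set.seed(6)
  for (i in 1:10) {
    r <- sample(rownames(nm), 1)
    j <- sample(3, 1)
    up <- nm
    # stay inside the column extremes so ideals are unchanged
    up[r, j] <- min(1, up[r, j] + runif(1) * (1 - up[r, j]))
    expect_gte(topsis(up, w)$closeness[r] + 1e-12, base[r])
  }
})

test_that("composite scores reproduce the published ranking table", {
  cs <- composite_score(contents())
  exp_tab <- gsb_expected("scores")
  expect_equal(cs["S10", "pc_score"], 2.66, tolerance = 5e-3)
  expect_equal(cs["S10", "overall_score"], 2.25, tolerance = 5e-3)
  expect_equal(cs["S10", "rank"], 1L)
  expect_equal(cs["S33", "rank"], 44L)
  expect_equal(mean(cs$pc_score), 0, tolerance = 1e-10)
  # published scores are printed at 2 decimals
  expect_lt(max(abs(cs$pc_score - exp_tab$pc_score)), 0.015)
  expect_lt(max(abs(cs$overall_score - exp_tab$overall_score)), 0.015)
  expect_gt(cor(cs$rank, exp_tab$rank, method = "spearman"), 0.999)
  # F is a constant multiple of Y (the first variance proportion)
  expect_equal(sd(cs$overall_score / cs$pc_score), 0, tolerance = 1e-12)
})

test_that("composite score is invariant to affine rescaling of a column", {
  x <- contents()
  x2 <- x
  x2[, 2] <- 0.1 * x2[, 2] + 100
  expect_equal(composite_score(x2)$overall_score,
               composite_score(x)$overall_score, tolerance = 1e-9)
})

test_that("hierarchical grading recovers planted structure", {
  set.seed(2)
  blob <- function(mu, n) sweep(matrix(rnorm(n * 4, sd = 0.1), n, 4), 2, mu, "+")
  x <- rbind(blob(c(0, 0, 0, 0), 8), blob(c(5, 5, 5, 5), 7),
             blob(c(-5, 5, -5, 5), 6))
  rownames(x) <- paste0("b", 1:21)
  truth <- rep(1:3, c(8, 7, 6))
  gr <- hca_grade(x, k = 3)
  expect_equal(length(unique(paste(gr$labels, truth))), 3L)

  # duplicated batches always share a grade
  xd <- rbind(x, x[3, , drop = FALSE])
  rownames(xd)[22] <- "dup"
  grd <- hca_grade(xd, k = 3)
  expect_equal(unname(grd$labels["dup"]), unname(grd$labels["b3"]))
})

test_that("published contents grade into a 15-batch top cluster", {
  x <- contents()
  cs <- composite_score(x)
  gr <- hca_grade(cbind(x, total = rowSums(x)), k = 3)
  top_grade <- gr$labels[rownames(cs)[cs$rank == 1]]
  expect_equal(unname(gr$sizes[top_grade]), 15L)
  expect_equal(unname(sort(as.integer(gr$sizes))), c(12L, 15L, 17L))
})

test_that("quality report merges stages and measures rank concordance", {
  ev <- evaluate_quality(contents())
  expect_equal(rownames(ev$report$table)[ev$report$table$closeness_rank == 1],
               "S10")
  expect_equal(rownames(ev$report$table)[ev$report$table$score_rank == 1],
               "S10")
  expect_gt(ev$report$spearman, 0.9)
  # identical and reversed rankings give rho = 1 and -1
  mk <- function(cl, f) {
    tp <- list(closeness = cl)
    class(tp) <- "topsis_result"
    comp <- data.frame(pc_score = f, overall_score = f,
                       rank = rank(-f, ties.method = "first"),
                       row.names = names(cl))
    gr <- list(labels = stats::setNames(rep(1L, length(cl)), names(cl)),
               sizes = table(rep(1L, length(cl))), k = 1)
    class(gr) <- "grade_result"
    quality_report(tp, comp, gr)
  }
  cl <- c(a = 0.9, b = 0.5, c = 0.1)
  expect_equal(mk(cl, c(3, 2, 1))$spearman, 1)
  expect_equal(mk(cl, c(1, 2, 3))$spearman, -1)
})
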