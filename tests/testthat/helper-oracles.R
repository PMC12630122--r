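# shared fixtures and independent oracles, built in code

# noiseless Gaussian chromatogram on a fine grid
gauss_chrom <- function(rts, areas, sigma = 0.1, tmax = max(rts) + 3,
                        dt = 0.005) {
  t <- seq(0, tmax, by = dt)
  y <- rep(0, length(t))
  for (k in seq_along(rts))
    y <- y + areas[k] / (sigma * sqrt(2 * pi)) *
      exp(-((t - rts[k])^2) / (2 * sigma^2))
  data.frame(time_min = t, intensity_mau = y)
}

# brute-force common-peak matching on a tiny batch set: enumerate every
# assignment of one peak per batch to a candidate cluster and count the
# clusters whose members all lie within `window` of their median
brute_force_common <- function(tables, window = 0.10) {
  nb <- length(tables)
  grids <- lapply(tables, function(pt) seq_len(nrow(pt)))
  best <- 0
  # candidate clusters: all combinations of one peak index per batch
  combos <- expand.grid(grids)
  ok <- apply(combos, 1, function(idx) {
    rts <- mapply(function(pt, i) pt$rt[i], tables, idx)
    all(abs(rts - median(rts)) <= window)
  })
  feas <- combos[ok, , drop = FALSE]
  # greedy packing of disjoint feasible clusters, largest count wins
  if (!nrow(feas)) return(0)
  count_disjoint <- function(rows, used) {
    if (!length(rows)) return(0)
    r <- rows[1]
    skip <- count_disjoint(rows[-1], used)
    idx <- as.integer(feas[r, ])
    keys <- paste(seq_len(nb), idx)
    if (any(keys %in% used)) return(skip)
    max(skip, 1 + count_disjoint(rows[-1], c(used, keys)))
  }
  count_disjoint(seq_len(nrow(feas)), character(0))
}

# correlation-PCA eigenvalues via the characteristic polynomial (polyroot),
# independent of eigen()
eigen_polyroot <- function(R) {
  p <- nrow(R)
  stopifnot(p == 3)
  # det(R - lambda I) expanded for 3x3 symmetric R
  a <- R[1, 2]; b <- R[1, 3]; c <- R[2, 3]
  # lambda^3 - tr lambda^2 + M lambda - det
  tr <- sum(diag(R))
  M <- (R[1, 1] * R[2, 2] - a^2) + (R[1, 1] * R[3, 3] - b^2) +
    (R[2, 2] * R[3, 3] - c^2)
  dt <- det(R)
  roots <- polyroot(c(-dt, M, -tr, 1))
  sort(Re(roots), decreasing = TRUE)
}

paper_content_fixture <- function() gsb_contents()
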