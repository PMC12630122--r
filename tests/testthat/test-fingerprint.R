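test_that("peak detection handles flat and simple signals", {
  flat <- data.frame(time_min = seq(0, 10, 0.01), intensity_mau = 0)
  expect_equal(nrow(detect_peaks(flat)), 0L)

  one <- gauss_chrom(10, 100)
  pk <- detect_peaks(one, min_height = 1, min_prominence = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$area, 100, tolerance = 0.01)
})

test_that("resolved neighbouring peaks are located at their template RTs", {
  ch <- gauss_chrom(c(10, 11), c(100, 80), sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, min_prominence = 1)
  expect_equal(nrow(pk), 2L)
  # grid-argmax oracle: apex of each half of the signal
  half <- ch$time_min < 10.5
  oracle <- c(ch$time_min[half][which.max(ch$intensity_mau[half])],
              ch$time_min[!half][which.max(ch$intensity_mau[!half])])
  expect_equal(pk$rt, oracle, tolerance = 1e-9)
  expect_equal(pk$rt, c(10, 11), tolerance = 0.01)
})

toy_tables <- function(shift = 0, drop_last = FALSE) {
  base <- data.frame(rt = c(5, 8, 12), area = c(50, 200, 80))
  b2 <- base; b2$rt[1] <- b2$rt[1] + shift
  b3 <- if (drop_last) base[-3, ] else base
  list(A = base, B = b2, C = b3)
}

test_that("matching keeps within-window peaks and drops absent ones", {
  m0 <- match_common_peaks(toy_tables(), calibrate = FALSE)
  expect_equal(ncol(m0$areas), 3L)

  m_shift <- match_common_peaks(toy_tables(shift = 0.05), calibrate = FALSE)
  expect_equal(ncol(m_shift$areas), 3L)
  expect_equal(ncol(m_shift$areas), brute_force_common(toy_tables(0.05)))

  m_far <- match_common_peaks(toy_tables(shift = 0.5), calibrate = FALSE)
  expect_equal(ncol(m_far$areas), 2L)
  expect_equal(ncol(m_far$areas), brute_force_common(toy_tables(0.5)))

  m_drop <- match_common_peaks(toy_tables(drop_last = TRUE), calibrate = FALSE)
  expect_equal(ncol(m_drop$areas), 2L)

  expect_warning(
    match_common_peaks(list(A = data.frame(rt = 1, area = 1),
                            B = data.frame(rt = 5, area = 1)),
                       calibrate = FALSE), "no common peaks")
})

test_that("matching is idempotent", {
  m <- match_common_peaks(toy_tables(shift = 0.05), calibrate = FALSE)
  again <- lapply(rownames(m$areas), function(b)
    data.frame(rt = m$rts[b, ], area = m$areas[b, ]))
  names(again) <- rownames(m$areas)
  m2 <- match_common_peaks(again, calibrate = FALSE)
  expect_equal(unname(m2$areas), unname(m$areas))
  expect_equal(unname(m2$rts), unname(m$rts))
})

test_that("median reference uses the lower median and resists outliers", {
  tabs <- toy_tables()
  m <- match_common_peaks(tabs, calibrate = FALSE)
  ref <- build_reference(m)
  expect_equal(ref$area, tabs$A$area)  # identical batches -> any batch

  m$areas[1, 2] <- 1e6                 # gross outlier in one batch
  expect_equal(build_reference(m)$area, ref$area)

  # explicit lower-median convention on {1, 2, 10}
  m3 <- m
  m3$areas[, 1] <- c(10, 1, 2)
  expect_equal(build_reference(m3)$area[1], 2)
  # even count: lower of the two middle values
  expect_equal(qmarkereval:::lower_median(c(4, 1, 3, 2)), 2)
})

test_that("similarity satisfies the congruence axioms", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(fingerprint_similarity(x, x), 1)
  expect_equal(fingerprint_similarity(x, 2 * x), 1)
  expect_equal(fingerprint_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(fingerprint_similarity(c(0, 0), x[1:2]), "zero")
  set.seed(1)
  for (i in 1:25) {
    a <- runif(8); b <- runif(8)
    s <- fingerprint_similarity(a, b)
    expect_equal(s, fingerprint_similarity(b, a))
    expect_lte(s, 1 + 1e-12)
    prop <- fingerprint_similarity(a, a * runif(1, 0.1, 10))
    expect_equal(prop, 1)
  }
})

test_that("relative metrics divide by the reference peak S", {
  m <- match_common_peaks(toy_tables(), calibrate = FALSE)
  rel <- relative_metrics(m)                 # auto: largest median area
  expect_equal(rel$reference_peak, 2L)       # area 200 column
  expect_true(all(rel$relative_area[, 2] == 1))
  expect_true(all(rel$relative_rt[, 2] == 1))
  expect_equal(rel$relative_area[1, 1], 50 / 200)
  # argmax oracle for auto-selection
  expect_equal(rel$reference_peak,
               unname(which.max(apply(m$areas, 2, median))))
  expect_error(relative_metrics(m, "nope"), "not a common peak")
})

test_that("rsd matches hand calculations and guards degenerate input", {
  expect_equal(rsd(rep(7, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)          # sd 1, mean 2
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_error(rsd(3), "length")
})

test_that("repeated-injection precision stays under the 3% acceptance", {
  tpl <- default_peak_templates(10)
  cfg <- sim_config(n_batches = 6, peak_templates = tpl,
                    rt_jitter_rsd_pct = 0.02,
                    area_rsd_pct_range = c(0.5, 1.5),
                    noise_sd = 0.1, seed = 42)
  sim <- generate_chromatograms(cfg)
  fp <- build_fingerprint(sim$chromatograms)
  expect_true(all(fp$rsd$relative_area_rsd < 3))
  expect_true(all(fp$rsd$relative_rt_rsd < 3))
})

test_that("paper-scale synthetic fingerprint is fully recovered", {
  sim <- generate_chromatograms(sim_config())
  fp <- build_fingerprint(sim$chromatograms)
  expect_equal(ncol(fp$matrix$areas), 25L)
  expect_true(all(fp$similarity >= 0.95))
  # detected areas recover the generated truth
  truth_mean <- as.numeric(tapply(sim$truth$area, sim$truth$peak, mean))
  detected_mean <- unname(colMeans(fp$matrix$areas))
  # integration over noisy baselines biases areas up by ~the noise floor
  expect_equal(detected_mean, truth_mean, tolerance = 0.05)
})
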