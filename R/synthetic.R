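#' Default Gaussian peak templates for the synthetic fingerprint
#'
#' A deterministic 25-peak template set emulating an 80-min gradient run:
#' retention times evenly spaced over 5--75 min, constant peak width, and a
#' fixed quasi-random area pattern with one dominant peak (index 13) standing
#' in for the reference constituent, an order of magnitude larger than the
#' rest — mirroring the role of the major secoiridoid peak in the real
#' fingerprint.
#'
#' @param n_peaks number of template peaks.
#' @param sigma common Gaussian width (min).
#' @return data.frame with columns `rt` (min), `sigma` (min), `area`
#'   (mAU·min).
#' @export
default_peak_templates <- function(n_peaks = 25, sigma = 0.08) {
  rt <- seq(5, 75, length.out = n_peaks)
  # fixed pattern, no RNG: minor peaks spread ~20-200 mAU.min around a
  # dominant reference peak carrying most of the signal, as in the real
  # fingerprint where one major secoiridoid dwarfs the other constituents;
  # the floor keeps the most variable trace peaks above detection
  area <- 40 + 180 * (((seq_len(n_peaks) * 7L) %% n_peaks) / n_peaks)
  ref <- min(13L, n_peaks)
  area[ref] <- 3000
  data.frame(rt = rt, sigma = sigma, area = area)
}

#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators. Defaults are the
#' study conditions: 44 batches, 25 template peaks, retention-time
#' reproducibility in the observed 0.635--3.917% RSD band (default 2%),
#' per-peak area RSDs spanning the observed 19.439--144.854% band (small
#' peaks varying most), five candidate binding components with quench
#' fractions (0.8, 0.7, 0.6, 0.2, 0.1), and a two-fold content shift for the
#' high-quality group.
#'
#' @param n_batches number of batches (>= 2).
#' @param peak_templates data.frame as from [default_peak_templates()].
#' @param rt_jitter_rsd_pct target retention-time RSD across batches, percent.
#'   Realised as a per-batch linear time stretch plus a small (0.01 min)
#'   peak-level jitter; the stretch is removable by multi-point RT
#'   calibration, keeping 0.10-min matching feasible.
#' @param area_rsd_pct_range (low, high) percent band for per-peak area RSDs;
#'   peaks are assigned RSDs evenly across the band, largest areas getting
#'   the smallest RSDs.
#' @param baseline_drift linear baseline slope, mAU per min.
#' @param noise_sd additive detector noise, mAU.
#' @param quench_fractions named vector in \[0,1\]: true quench fraction per
#'   candidate component for the fluorescence assay.
#' @param group_effect multiplicative content shift applied to the
#'   high-quality group in [generate_content_table()].
#' @param seed integer seed; every generator is bit-reproducible given the
#'   config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_batches = 44,
                       peak_templates = default_peak_templates(),
                       rt_jitter_rsd_pct = 2,
                       area_rsd_pct_range = c(19.439, 144.854),
                       baseline_drift = 0,
                       noise_sd = 0.2,
                       quench_fractions = c(swertiamarin = 0.8,
                                            gentiopicroside = 0.7,
                                            sweroside = 0.6,
                                            loganic_acid = 0.2,
                                            glucosylgentiopicroside = 0.1),
                       group_effect = 2,
                       seed = 20251106) {
  stopifnot(n_batches >= 2, all(peak_templates$sigma > 0),
            all(peak_templates$area > 0),
            rt_jitter_rsd_pct >= 0, rt_jitter_rsd_pct <= 10,
            length(area_rsd_pct_range) == 2,
            area_rsd_pct_range[1] > 0,
            diff(area_rsd_pct_range) >= 0,
            all(quench_fractions >= 0), all(quench_fractions <= 1),
            group_effect > 0, noise_sd >= 0)
  cfg <- list(n_batches = n_batches,
              peak_templates = peak_templates[order(peak_templates$rt), ],
              rt_jitter_rsd_pct = rt_jitter_rsd_pct,
              area_rsd_pct_range = area_rsd_pct_range,
              baseline_drift = baseline_drift,
              noise_sd = noise_sd,
              quench_fractions = quench_fractions,
              group_effect = group_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# per-peak target area RSDs: geometrically spaced over the band, largest
# areas getting the smallest RSDs — in real material the dominant
# constituents are the most stable and only trace peaks vary wildly, which
# is what keeps fingerprint similarities high despite >100% RSDs
peak_area_rsds <- function(cfg) {
  n <- nrow(cfg$peak_templates)
  lo <- cfg$area_rsd_pct_range[1]
  hi <- cfg$area_rsd_pct_range[2]
  u <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  band <- lo * (hi / lo)^(u^2)
  rsd <- numeric(n)
  rsd[order(cfg$peak_templates$area, decreasing = TRUE)] <- band
  rsd
}

#' Generate multi-batch synthetic chromatograms
#'
#' Draws `n_batches` chromatograms on a common time grid. Each batch carries
#' every template peak as a Gaussian with lognormal area variation (per-peak
#' coefficient of variation from the configured band) and retention times
#' transformed by a per-batch linear stretch (sd = `rt_jitter_rsd_pct`%) plus
#' a small independent jitter, then additive baseline drift and detector
#' noise. Deterministic for a fixed `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @param dt time-grid step in minutes.
#' @return A list with `chromatograms` (named list of data.frames with
#'   columns `time_min`, `intensity_mau`), and `truth` (data.frame of the
#'   realised per-batch peak retention times and areas).
#' @export
generate_chromatograms <- function(config, seed = config$seed, dt = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  tpl <- config$peak_templates
  gaps <- diff(tpl$rt)
  if (any(gaps < 3 * pmax(utils::head(tpl$sigma, -1), utils::tail(tpl$sigma, -1))))
    warning("peak templates closer than 3 sigma: peaks may merge")
  set.seed(seed)
  n <- config$n_batches
  npk <- nrow(tpl)
  rsd <- peak_area_rsds(config)
  sdlog <- sqrt(log(1 + (rsd / 100)^2))
  meanlog <- log(tpl$area) - sdlog^2 / 2

  stretch <- stats::rnorm(n, mean = 1, sd = config$rt_jitter_rsd_pct / 100)
  tmax <- max(tpl$rt) + 5
  grid <- seq(0, tmax, by = dt)
  batches <- sprintf("B%02d", seq_len(n))

  chroms <- vector("list", n)
  names(chroms) <- batches
  truth <- vector("list", n)
  for (b in seq_len(n)) {
    rt_b <- stretch[b] * tpl$rt + stats::rnorm(npk, 0, 0.01)
    area_b <- stats::rlnorm(npk, meanlog, sdlog)
    sig <- rep(0, length(grid))
    for (k in seq_len(npk)) {
      s <- tpl$sigma[k]
      idx <- which(abs(grid - rt_b[k]) < 6 * s)
      sig[idx] <- sig[idx] +
        area_b[k] / (s * sqrt(2 * pi)) * exp(-((grid[idx] - rt_b[k])^2) / (2 * s^2))
    }
    sig <- sig + config$baseline_drift * grid
    if (config$noise_sd > 0)
      sig <- sig + stats::rnorm(length(grid), 0, config$noise_sd)
    chroms[[b]] <- data.frame(time_min = grid, intensity_mau = sig)
    truth[[b]] <- data.frame(batch = batches[b], peak = seq_len(npk),
                             rt = rt_b, area = area_b)
  }
  list(chromatograms = chroms, truth = do.call(rbind, truth))
}

#' Generate a synthetic fluorescence binding assay
#'
#' Builds four-control plate readings (A: lysate, B: lysate + ligand, C:
#' protein, D: protein + ligand) for each candidate component so that the
#' noiseless activity percentage equals the configured quench fraction times
#' 100: the mixture reading D is placed at the additive expectation
#' `FB + FC - FA` minus the quenched share of the interaction denominator.
#' Intensities then receive multiplicative Gaussian noise.
#'
#' @param quench_fractions named vector in \[0,1\], one entry per component.
#' @param noise_frac relative noise (sd as a fraction of the true intensity).
#' @param n_replicates replicates per condition (default 3, i.e. triplicate).
#' @param seed integer seed.
#' @param base true intensities `c(FA =, FB =, FC =)` of the three pure
#'   controls, arbitrary units.
#' @return data.frame with columns `component`, `group` (A--D), `replicate`,
#'   `intensity`.
#' @export
generate_fluorescence_assay <- function(quench_fractions,
                                        noise_frac = 0,
                                        n_replicates = 3,
                                        seed = 20251106,
                                        base = c(FA = 100, FB = 160, FC = 150)) {
  stopifnot(all(quench_fractions >= 0), all(quench_fractions <= 1),
            noise_frac >= 0, n_replicates >= 1)
  if (is.null(names(quench_fractions)))
    names(quench_fractions) <- paste0("C", seq_along(quench_fractions))
  set.seed(seed)
  denom <- base[["FB"]] + base[["FC"]] - 2 * base[["FA"]]
  stopifnot(denom > 0)
  out <- list()
  for (comp in names(quench_fractions)) {
    q <- quench_fractions[[comp]]
    mu <- c(A = base[["FA"]], B = base[["FB"]], C = base[["FC"]],
            D = base[["FB"]] + base[["FC"]] - base[["FA"]] - q * denom)
    for (g in names(mu)) {
      val <- mu[[g]] * (1 + stats::rnorm(n_replicates, 0, noise_frac))
      out[[length(out) + 1L]] <- data.frame(
        component = comp, group = g, replicate = seq_len(n_replicates),
        intensity = val)
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic content table with known quality groups
#'
#' Draws lognormal per-analyte contents around realistic means (roughly the
#' scale of the real material: ~4, ~45 and ~0.5 mg/g for the three
#' Q-markers), multiplies the "high-quality" half of the batches by
#' `group_effect`, and records the ground-truth group labels.
#'
#' @param config a [sim_config()]; uses `n_batches`, `group_effect`, `seed`.
#' @param cv lognormal coefficient of variation of each content.
#' @param base_means named analyte means (mg/g) for the low-quality group.
#' @param seed optional override of `config$seed`.
#' @return data.frame of contents with batch rownames and attributes `group`
#'   (factor `"high"`/`"low"`) and `group_effect`.
#' @export
generate_content_table <- function(config,
                                   cv = 0.2,
                                   base_means = c(swertiamarin = 4,
                                                  gentiopicroside = 45,
                                                  sweroside = 0.5),
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), config$group_effect > 0, cv >= 0)
  set.seed(seed)
  n <- config$n_batches
  n_high <- ceiling(n / 2)
  group <- factor(rep(c("high", "low"), c(n_high, n - n_high)),
                  levels = c("high", "low"))
  sdlog <- sqrt(log(1 + cv^2))
  x <- sapply(base_means, function(m) {
    mu <- ifelse(group == "high", m * config$group_effect, m)
    stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
  })
  out <- as.data.frame(x)
  rownames(out) <- sprintf("S%02d", seq_len(n))
  attr(out, "group") <- group
  attr(out, "group_effect") <- config$group_effect
  out
}
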