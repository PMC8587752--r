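#' Default band catalogue for synthetic striated-muscle spectra
#'
#' One Gaussian component per assigned mid-IR band, with per-tissue linear
#' age slopes encoding the qualitative aging directions the analysis is
#' designed to detect: the intermolecular beta-sheet band (1628 cm^-1) grows
#' with age in cardiac muscle and shrinks in skeletal muscle, the
#' antiparallel beta-sheet band (1693 cm^-1) shrinks in both, the ester
#' carbonyl (1741 cm^-1) and glucose (1045 cm^-1) bands grow in both, and
#' the glycogen (1155 cm^-1) and phosphate (1081 cm^-1) bands shrink in
#' skeletal muscle. The noiseless amplitude of a band is
#' \code{base_amplitude + slope(tissue) * age_months}, plus
#' \code{tissue_offset} for cardiac samples.
#'
#' @return data.frame with columns \code{label}, \code{center} (cm^-1),
#'   \code{sigma} (cm^-1), \code{base_amplitude}, \code{slope_skeletal},
#'   \code{slope_cardiac} (absorbance per month) and \code{tissue_offset}
#'   (absorbance added for cardiac).
#' @export
default_band_catalogue <- function() {
  b <- function(label, center, sigma, base, ssk, sca, off)
    data.frame(label = label, center = center, sigma = sigma,
               base_amplitude = base, slope_skeletal = ssk,
               slope_cardiac = sca, tissue_offset = off,
               stringsAsFactors = FALSE)
  rbind(
    b("amide A (N-H stretch)",        3290, 55, 0.70,  0,       0,       0),
    b("olefinic =CH stretch",         3013,  7, 0.10,  0,       0.002,   0),
    b("CH3 asymmetric stretch",       2959,  7, 0.30,  0,       0,       0.02),
    b("CH2 asymmetric stretch",       2922,  7, 0.45,  0.004,  -0.002,   0),
    b("CH3 symmetric stretch",        2871,  7, 0.18, -0.0015,  0.0015,  0),
    b("CH2 symmetric stretch",        2851,  7, 0.28,  0,      -0.002,   0),
    b("ester carbonyl C=O",           1741,  8, 0.15,  0.001,   0.001,   0),
    b("antiparallel beta-sheet",      1693,  5, 0.25, -0.003,  -0.003,   0),
    b("beta-sheet",                   1682,  5, 0.30,  0,       0,       0),
    b("beta-turn",                    1662,  5, 0.35,  0,      -0.001,   0),
    b("alpha-helix (Amide I)",        1651, 14, 1.00,  0.002,   0.002,   0.05),
    b("intermolecular beta-sheet",    1628,  5, 0.55, -0.004,   0.007,  -0.20),
    b("Amide II 1554",                1554,  5, 0.35, -0.002,  -0.002,   0),
    b("Amide II 1540",                1540,  5, 0.45,  0.002,   0.002,   0.10),
    b("Amide II 1512",                1512,  6, 0.12,  0.001,   0.001,   0),
    b("COO- symmetric stretch",       1398, 12, 0.30,  0,       0,       0),
    b("cholesterol ester",            1169,  5, 0.15,  0,       0,       0.03),
    b("glycogen",                     1155,  5, 0.30, -0.004,   0,      -0.10),
    b("DNA phosphate PO4",            1081,  8, 0.25, -0.002,   0,       0),
    b("glucose",                      1045,  8, 0.20,  0.003,   0.003,   0)
  )
}

#' Configuration of a synthetic ATR-FTIR cohort
#'
#' Defaults reproduce the study design the pipeline targets: 2 tissues x
#' 4 ages (6, 12, 17, 24 months) x 10 biological x 3 technical replicates
#' (240 spectra) on a 3998-902 cm^-1 grid at 2 cm^-1 spacing, with a random
#' quadratic baseline per spectrum, multiplicative lognormal sample-amount
#' scatter (what area normalization must remove), a per-animal lognormal
#' amplitude effect shared across that animal's technical replicates, and
#' additive Gaussian noise at 5\% of the largest band amplitude.
#'
#' @param bands Band catalogue data.frame (see
#'   \code{\link{default_band_catalogue}}).
#' @param grid_min,grid_max,grid_step Wavenumber grid, cm^-1.
#' @param ages Age groups in months.
#' @param n_bio,n_tech Biological / technical replicates per group.
#' @param tissues Character vector of tissue types.
#' @param baseline_coeffs_sd SDs of the three coefficients of the random
#'   quadratic baseline b0 + b1*u + b2*u^2, u scaled to [-1, 1] over the grid.
#' @param scale_jitter_sd SD of the lognormal multiplicative scale per
#'   spectrum (sample-amount scatter).
#' @param noise_sd SD of additive Gaussian noise, absorbance units.
#' @param bio_amplitude_sd SD of the lognormal per-animal, per-band amplitude
#'   effect.
#' @param center_jitter_sd Optional SD (cm^-1) of a per-animal band-center
#'   shift, emulating tissue-dependent peak drift; 0 disables it.
#' @param seed Integer RNG seed.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(bands = default_band_catalogue(),
                          grid_min = 902, grid_max = 3998, grid_step = 2,
                          ages = c(6L, 12L, 17L, 24L),
                          n_bio = 10L, n_tech = 3L,
                          tissues = c("cardiac", "skeletal"),
                          baseline_coeffs_sd = c(0.05, 0.05, 0.02),
                          scale_jitter_sd = 0.15,
                          noise_sd = 0.05 * max(bands$base_amplitude +
                                                  pmax(bands$tissue_offset, 0)),
                          bio_amplitude_sd = 0.05,
                          center_jitter_sd = 0,
                          seed = 1L) {
  cfg <- list(bands = bands, grid_min = grid_min, grid_max = grid_max,
              grid_step = grid_step, ages = as.integer(ages),
              n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
              tissues = tissues,
              baseline_coeffs_sd = rep_len(baseline_coeffs_sd, 3L),
              scale_jitter_sd = scale_jitter_sd, noise_sd = noise_sd,
              bio_amplitude_sd = bio_amplitude_sd,
              center_jitter_sd = center_jitter_sd, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_bio >= 1L, n_tech >= 1L, noise_sd >= 0, grid_step > 0,
              grid_min < grid_max, all(bands$sigma > 0),
              scale_jitter_sd >= 0, bio_amplitude_sd >= 0,
              center_jitter_sd >= 0)
    if (!all(tissues %in% c("cardiac", "skeletal")))
      stop("tissues must be a subset of {cardiac, skeletal}", call. = FALSE)
  })
  gt <- ground_truth(cfg)
  if (any(gt$amplitude < 0))
    stop("configured slopes drive a band amplitude negative over the age ",
         "range (first offender: band ",
         gt$label[which(gt$amplitude < 0)[1L]], ")", call. = FALSE)
  invisible(cfg)
}

band_amplitude <- function(bands, tissue, age) {
  slope <- if (tissue == "cardiac") bands$slope_cardiac else bands$slope_skeletal
  off <- if (tissue == "cardiac") bands$tissue_offset else 0
  bands$base_amplitude + slope * age + off
}

#' Expected noiseless band amplitudes per (tissue, age)
#'
#' The ground truth behind \code{\link{generate_cohort}}: for each band,
#' \code{amplitude = base_amplitude + slope(tissue) * age + tissue_offset},
#' enabling parameter-recovery tests of the downstream pipeline.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return data.frame with columns \code{tissue}, \code{age_months},
#'   \code{label}, \code{center}, \code{sigma}, \code{amplitude}.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- list()
  for (ti in config$tissues) for (a in config$ages) {
    out[[length(out) + 1L]] <- data.frame(
      tissue = ti, age_months = a, label = config$bands$label,
      center = config$bands$center, sigma = config$bands$sigma,
      amplitude = band_amplitude(config$bands, ti, a),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Noiseless group spectrum for one (tissue, age) cell
#'
#' @param config A \code{\link{cohort_config}}.
#' @param tissue,age_months Group identifiers.
#' @return List with \code{wavenumbers} and \code{absorbance} (no baseline,
#'   no noise, unit scale).
#' @export
noiseless_spectrum <- function(config, tissue, age_months) {
  grid <- seq(config$grid_min, config$grid_max, by = config$grid_step)
  amp <- band_amplitude(config$bands, tissue, age_months)
  y <- numeric(length(grid))
  for (i in seq_len(nrow(config$bands)))
    y <- y + amp[i] *
      exp(-(grid - config$bands$center[i])^2 / (2 * config$bands$sigma[i]^2))
  list(wavenumbers = grid, absorbance = y)
}

#' Generate a seeded synthetic cohort of ATR-FTIR spectra
#'
#' Each spectrum is
#' \code{scale * (sum of Gaussian bands + quadratic baseline) + noise}, where
#' the band amplitudes carry the configured tissue offsets and linear age
#' slopes times a per-animal lognormal effect (shared across that animal's
#' technical replicates), \code{scale} is lognormal sample-amount scatter,
#' the baseline is a random quadratic per spectrum, and the noise is iid
#' Gaussian. Fully reproducible from \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A \code{\link{spectra_set}} with
#'   \code{length(tissues) * length(ages) * n_bio * n_tech} spectra.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  grid <- seq(config$grid_min, config$grid_max, by = config$grid_step)
  u <- 2 * (grid - mean(range(grid))) / diff(range(grid))
  nb <- nrow(config$bands)
  specs <- list()
  for (ti in config$tissues) for (a in config$ages) {
    amp0 <- band_amplitude(config$bands, ti, a)
    for (bio in seq_len(config$n_bio)) {
      bio_mult <- if (config$bio_amplitude_sd > 0)
        exp(stats::rnorm(nb, 0, config$bio_amplitude_sd)) else rep(1, nb)
      centers <- config$bands$center
      if (config$center_jitter_sd > 0)
        centers <- centers + stats::rnorm(nb, 0, config$center_jitter_sd)
      pure <- numeric(length(grid))
      for (i in seq_len(nb))
        pure <- pure + amp0[i] * bio_mult[i] *
          exp(-(grid - centers[i])^2 / (2 * config$bands$sigma[i]^2))
      for (te in seq_len(config$n_tech)) {
        bl <- stats::rnorm(3L, 0, config$baseline_coeffs_sd)
        baseline <- bl[1L] + bl[2L] * u + bl[3L] * u^2
        scl <- if (config$scale_jitter_sd > 0)
          stats::rlnorm(1L, 0, config$scale_jitter_sd) else 1
        noise <- if (config$noise_sd > 0)
          stats::rnorm(length(grid), 0, config$noise_sd) else 0
        y <- scl * (pure + baseline) + noise
        id <- sprintf("%s_%02dM_b%02d_t%d", substr(ti, 1, 4), a, bio, te)
        specs[[length(specs) + 1L]] <- ftir_spectrum(
          grid, y, list(sample_id = id, tissue = ti, age_months = a,
                        bio_rep = bio, tech_rep = te))
      }
    }
  }
  spectra_set(specs)
}
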