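test_that("peak intensity inverts derivatives and matches the Gaussian form", {
  g <- gaussian_spectrum(a = 0.6, center = 1650, sigma = 10, step = 2)
  d2 <- second_derivative_sg(g, sg_params())
  pk <- peak_intensity(d2, 1650, 6, "second_derivative_inverted")
  expect_lt(abs(as.numeric(pk) - 0.6 / 100), 0.02 * 0.6 / 100)
  expect_equal(attr(pk, "at"), 1650)
  # direct max on a raw trace
  x <- seq(1600, 1700, 2)
  s <- ftir_spectrum(x, ifelse(x == 1628, 0.42, 0.1), meta_n(1))
  expect_equal(as.numeric(peak_intensity(s, 1628, 6, "normalized_raw")),
               0.42)
  expect_error(peak_intensity(s, 1628, 0.5), "halfwidth")
  expect_error(peak_intensity(s, 3000, 6), "intersect")
})

make_regions <- function(set, sg = sg_params(7)) {
  list(lipid = preprocess_region(set, "lipid", sg = sg),
       amide = preprocess_region(set, "amide", sg = sg),
       fingerprint = preprocess_region(set, "fingerprint", sg = sg))
}

test_that("panel indices follow their definitions on a noiseless cohort", {
  cfg <- noise_free(small_config(n_bio = 1L, n_tech = 1L))
  set <- generate_cohort(cfg)
  regions <- make_regions(set)
  panel <- compute_panel(regions)
  expect_equal(nrow(panel), length(set))
  # beta fractions live in [0, 1] and leave room for the 1682 share
  expect_true(all(panel$antiparallel_beta_fraction >= 0 &
                    panel$antiparallel_beta_fraction <= 1))
  expect_true(all(panel$antiparallel_beta_fraction +
                    panel$intermolecular_beta_fraction <= 1))
  # fraction arithmetic against directly extracted intensities
  s1 <- panel$sample_id[1]
  d <- regions$amide$derivative$spectra[[s1]]
  I <- function(t) as.numeric(peak_intensity(d, t, 6))
  expect_equal(panel$antiparallel_beta_fraction[1],
               I(1693) / (I(1693) + I(1682) + I(1628)))
  expect_equal(panel$intermolecular_beta_fraction[1],
               I(1628) / (I(1693) + I(1682) + I(1628)))
  expect_equal(panel$triglycerides[1], I(1741))
})

test_that("panel is invariant to positive scaling of the raw spectra", {
  cfg <- noise_free(small_config(n_bio = 1L, n_tech = 1L))
  set <- generate_cohort(cfg)
  scaled <- map_set(set, function(s)
    ftir_spectrum(s$wavenumbers, 7 * s$absorbance, s$meta))
  p1 <- compute_panel(make_regions(set))
  p2 <- compute_panel(make_regions(scaled))
  for (v in c("acyl_chain_length", "lipid_unsaturation", "triglycerides",
              "total_protein", "antiparallel_beta_fraction",
              "intermolecular_beta_fraction", "fibril_formation",
              "cholesterol_esters", "glucose"))
    expect_equal(p2[[v]], p1[[v]], tolerance = 1e-9)
})

test_that("single-band age slopes propagate monotonically to their index", {
  cat <- default_band_catalogue()
  cat$slope_skeletal <- 0
  cat$slope_cardiac <- 0
  cat$tissue_offset <- 0
  i1045 <- which(cat$center == 1045)
  cat$slope_cardiac[i1045] <- cat$slope_skeletal[i1045] <- 0.005
  cfg <- noise_free(cohort_config(bands = cat, n_bio = 1L, n_tech = 1L,
                                  grid_step = 4))
  set <- generate_cohort(cfg)
  panel <- compute_panel(make_regions(set))
  glu <- panel$glucose[panel$tissue == "cardiac"][
    order(panel$age_months[panel$tissue == "cardiac"])]
  expect_true(all(diff(glu) > 0))
})

test_that("summary reports group mean and sample SD", {
  cfg <- noise_free(small_config(n_bio = 3L, n_tech = 1L))
  set <- generate_cohort(cfg)
  panel <- compute_panel(make_regions(set))
  sm <- summarize_panel(panel)
  expect_equal(nrow(sm), 8)
  expect_true(all(sm$n == 3))
  # noiseless cohort: zero SD within each group
  expect_lt(max(sm$glucose_sd), 1e-12)
  # hand arithmetic on a constructed group
  panel3 <- panel[panel$tissue == "cardiac" & panel$age_months == 6, ]
  panel3$glucose <- c(1, 2, 3)
  class(panel3) <- c("band_index_panel", "data.frame")
  sm3 <- summarize_panel(panel3)
  expect_equal(sm3$glucose_mean, 2)
  expect_equal(sm3$glucose_sd, 1)
})

test_that("technical-replicate spectrum averaging collapses to animals", {
  cfg <- noise_free(small_config())
  set <- generate_cohort(cfg)
  av <- average_tech_spectra(set)
  expect_equal(length(av), 2 * 4 * cfg$n_bio)
  # identical technical replicates: averaging reproduces the replicate
  m <- set_meta(set)
  i <- which(m$tissue == "cardiac" & m$age_months == 6 & m$bio_rep == 1)
  target <- av$spectra[[grep("card_06M_b01", names(av$spectra))]]
  expect_equal(target$absorbance, set$spectra[[i[1]]]$absorbance)
})
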