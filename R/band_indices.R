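#' Peak intensity in a wavenumber window
#'
#' Extracts the intensity of an assigned band as the maximum of the trace
#' over \code{[target - halfwidth, target + halfwidth]}. For
#' \code{source = "second_derivative_inverted"} the input must be a
#' second-derivative trace; it is multiplied by -1 inside this operation so
#' the sharp derivative minima become maxima (second-derivative
#' spectroscopy). The window absorbs the few-cm^-1 drift of band positions
#' between tissues.
#'
#' @param spectrum An \code{ftir_spectrum} (raw-normalized or
#'   second-derivative, per \code{source}).
#' @param target Band center, cm^-1.
#' @param halfwidth Search half-window, cm^-1 (default 6; must be >= the
#'   grid step).
#' @param source "second_derivative_inverted" or "normalized_raw".
#' @return Numeric intensity with attribute \code{"at"} giving the argmax
#'   wavenumber.
#' @export
peak_intensity <- function(spectrum, target, halfwidth = 6,
                           source = c("second_derivative_inverted",
                                      "normalized_raw")) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  source <- match.arg(source)
  x <- spectrum$wavenumbers
  step <- min(diff(x))
  if (halfwidth < step)
    stop("halfwidth (", halfwidth, ") below grid step (", step, ")",
         call. = FALSE)
  w <- x >= target - halfwidth & x <= target + halfwidth
  if (!any(w))
    stop("window ", target, " +/- ", halfwidth,
         " cm-1 does not intersect the grid", call. = FALSE)
  y <- spectrum$absorbance[w]
  if (source == "second_derivative_inverted") y <- -y
  i <- which.max(y)
  structure(y[i], at = x[w][i])
}

band_targets <- list(
  olefinic = 3013, ch3_asym = 2959, ch2_asym = 2922, ch3_sym = 2871,
  ch2_sym = 2851, carbonyl = 1741, beta_antiparallel = 1693,
  beta_sheet = 1682, beta_intermolecular = 1628,
  cholesterol = 1169, glucose = 1045)

#' Compute the nine band-intensity biomarker indices
#'
#' Per-sample panel of the nine aging indices, from inverted
#' second-derivative peak intensities (lipid, carbonyl, beta-sheet,
#' fingerprint bands) and from baseline-corrected, area-normalized,
#' non-derived spectra (Amide I / Amide II peaks):
#' \itemize{
#'   \item acyl_chain_length = (I2851 + I2922) / (I2959 + I2871)
#'   \item lipid_unsaturation = I3013 / (I2851 + I2922)
#'   \item triglycerides = I1741
#'   \item total_protein = I_AmideI + I_AmideII (non-derived spectra)
#'   \item antiparallel_beta_fraction = I1693 / (I1693 + I1682 + I1628)
#'   \item intermolecular_beta_fraction = I1628 / (I1693 + I1682 + I1628)
#'   \item fibril_formation = I_AmideII / I_AmideI (non-derived spectra)
#'   \item cholesterol_esters = I1169
#'   \item glucose = I1045
#' }
#' Amide I and Amide II are located as raw-spectrum maxima in 1700-1600 and
#' 1560-1480 cm^-1.
#'
#' @param regions List as returned by \code{\link{preprocess_region}} for
#'   the three canonical regions, named \code{lipid}, \code{amide},
#'   \code{fingerprint} (each with \code{$normalized} and
#'   \code{$derivative}).
#' @param halfwidth Peak search half-window, cm^-1 (default 6).
#' @return data.frame of class \code{band_index_panel}: metadata columns
#'   plus the nine indices, one row per sample.
#' @export
compute_panel <- function(regions, halfwidth = 6) {
  need <- c("lipid", "amide", "fingerprint")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("missing preprocessed region(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- set_meta(regions$lipid$derivative)
  ids <- meta$sample_id
  for (r in need) {
    for (part in c("normalized", "derivative")) {
      if (!identical(set_meta(regions[[r]][[part]])$sample_id, ids))
        stop("regions hold different samples or sample order", call. = FALSE)
    }
  }
  inv <- function(region, sample, target)
    peak_intensity(regions[[region]]$derivative$spectra[[sample]], target,
                   halfwidth, "second_derivative_inverted")
  raw <- function(sample, lo, hi) {
    s <- regions$amide$normalized$spectra[[sample]]
    ctr <- (lo + hi) / 2
    peak_intensity(s, ctr, (hi - lo) / 2, "normalized_raw")
  }
  one <- function(i) {
    sm <- ids[i]
    I <- function(name) inv(switch(name,
                                   olefinic = , ch3_asym = , ch2_asym = ,
                                   ch3_sym = , ch2_sym = "lipid",
                                   carbonyl = , beta_antiparallel = ,
                                   beta_sheet = ,
                                   beta_intermolecular = "amide",
                                   cholesterol = , glucose = "fingerprint"),
                            sm, band_targets[[name]])
    amide1 <- raw(sm, 1600, 1700)
    amide2 <- raw(sm, 1480, 1560)
    ratio <- function(num, den, index) {
      if (den <= 0)
        stop("nonpositive denominator for index '", index,
             "' in sample '", sm, "'", call. = FALSE)
      num / den
    }
    beta_sum <- I("beta_antiparallel") + I("beta_sheet") +
      I("beta_intermolecular")
    data.frame(
      acyl_chain_length = ratio(I("ch2_sym") + I("ch2_asym"),
                                I("ch3_asym") + I("ch3_sym"),
                                "acyl_chain_length"),
      lipid_unsaturation = ratio(I("olefinic"),
                                 I("ch2_sym") + I("ch2_asym"),
                                 "lipid_unsaturation"),
      triglycerides = I("carbonyl"),
      total_protein = amide1 + amide2,
      antiparallel_beta_fraction = ratio(I("beta_antiparallel"), beta_sum,
                                         "antiparallel_beta_fraction"),
      intermolecular_beta_fraction = ratio(I("beta_intermolecular"),
                                           beta_sum,
                                           "intermolecular_beta_fraction"),
      fibril_formation = ratio(amide2, amide1, "fibril_formation"),
      cholesterol_esters = I("cholesterol"),
      glucose = I("glucose"))
  }
  panel <- cbind(meta, do.call(rbind, lapply(seq_along(ids), one)))
  rownames(panel) <- NULL
  class(panel) <- c("band_index_panel", "data.frame")
  panel
}

#' Average technical-replicate spectra per animal
#'
#' Collapses a set to one spectrum per (tissue, age, bio_rep) by averaging
#' the absorbance traces of that animal's technical replicates. Peak
#' extraction is a nonlinear operation (a windowed maximum), so averaging
#' the spectra before extraction both reduces the noise variance and
#' removes the upward bias a maximum takes on a noisy trace; the animal is
#' also the statistical unit downstream.
#'
#' @param set A \code{spectra_set}.
#' @return A \code{spectra_set} with one spectrum per animal
#'   (\code{tech_rep} set to 1, sample id stripped of its replicate
#'   suffix).
#' @export
average_tech_spectra <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  meta <- set_meta(set)
  groups <- split(seq_along(set$spectra),
                  list(meta$tissue, meta$age_months, meta$bio_rep),
                  drop = TRUE)
  specs <- lapply(groups, function(ix) {
    Y <- vapply(set$spectra[ix], function(s) s$absorbance,
                numeric(length(set$grid)))
    m <- set$spectra[[ix[1L]]]$meta
    m$tech_rep <- 1L
    m$sample_id <- sub("_t[0-9]+$", "", m$sample_id)
    ftir_spectrum(set$grid, rowMeans(as.matrix(Y)), m)
  })
  spectra_set(specs)
}

#' Index columns of a band index panel
#' @keywords internal
panel_index_names <- function() {
  c("acyl_chain_length", "lipid_unsaturation", "triglycerides",
    "total_protein", "antiparallel_beta_fraction",
    "intermolecular_beta_fraction", "fibril_formation",
    "cholesterol_esters", "glucose")
}

#' Group means and SDs of the band index panel
#'
#' @param panel A \code{band_index_panel}.
#' @param average_technical Average technical replicates per animal before
#'   summarizing (default FALSE here; the statistics layer averages them
#'   itself).
#' @return data.frame with one row per (tissue, age_months) and, per index,
#'   \code{<index>_mean} and \code{<index>_sd} (sample SD, n - 1; NA with a
#'   warning for groups of size 1) plus \code{n}.
#' @export
summarize_panel <- function(panel, average_technical = FALSE) {
  stopifnot(inherits(panel, "band_index_panel"))
  if (average_technical) panel <- average_tech_reps(panel)
  idx <- panel_index_names()
  groups <- split(panel, list(panel$tissue, panel$age_months), drop = TRUE)
  out <- lapply(groups, function(g) {
    row <- data.frame(tissue = g$tissue[1L], age_months = g$age_months[1L],
                      n = nrow(g))
    if (nrow(g) < 2L)
      warning("group ", g$tissue[1L], "/", g$age_months[1L],
              " has a single sample; SD undefined", call. = FALSE)
    for (v in idx) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(g) >= 2L) stats::sd(g[[v]]) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$tissue, out$age_months), ]
  rownames(out) <- NULL
  out
}

#' Average technical replicates per animal
#'
#' Collapses a panel to one row per (tissue, age, bio_rep), the unit used
#' for inference (prevents pseudoreplication).
#'
#' @param panel A \code{band_index_panel}.
#' @return A \code{band_index_panel} with one row per animal.
#' @export
average_tech_reps <- function(panel) {
  stopifnot(inherits(panel, "band_index_panel"))
  idx <- intersect(panel_index_names(), names(panel))
  groups <- split(panel,
                  list(panel$tissue, panel$age_months, panel$bio_rep),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1L, c("sample_id", "tissue", "age_months", "bio_rep")]
    row$tech_rep <- 1L
    row$sample_id <- sub("_t[0-9]+$", "", row$sample_id)
    for (v in idx) row[[v]] <- mean(g[[v]])
    row
  }))
  out <- out[order(out$tissue, out$age_months, out$bio_rep), ]
  rownames(out) <- NULL
  class(out) <- c("band_index_panel", "data.frame")
  out
}
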