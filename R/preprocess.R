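#' Canonical analysis regions
#'
#' The three mid-IR windows the analysis is carried out in: the lipid C-H
#' stretch region (3050-2800 cm^-1), the Amide/carbonyl region
#' (1800-1500 cm^-1) and the fingerprint region (1200-900 cm^-1).
#'
#' @return data.frame with columns \code{name}, \code{lo}, \code{hi} (cm^-1).
#' @export
canonical_regions <- function() {
  data.frame(name = c("lipid", "amide", "fingerprint"),
             lo = c(2800, 1500, 900), hi = c(3050, 1800, 1200),
             stringsAsFactors = FALSE)
}

region_spec <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    r <- canonical_regions()
    hit <- r[r$name == region, ]
    if (!nrow(hit)) stop("unknown region name '", region, "'", call. = FALSE)
    return(hit)
  }
  region <- as.list(region)
  stopifnot(!is.null(region$lo), !is.null(region$hi))
  if (region$lo >= region$hi) stop("region needs lo < hi", call. = FALSE)
  if (is.null(region$name)) region$name <- sprintf("%g-%g", region$hi, region$lo)
  data.frame(name = region$name, lo = region$lo, hi = region$hi,
             stringsAsFactors = FALSE)
}

#' Cut a spectra set to one wavenumber region
#'
#' @param set A \code{spectra_set}.
#' @param region A region name from \code{\link{canonical_regions}}
#'   ("lipid", "amide", "fingerprint") or a list with \code{lo} and \code{hi}
#'   (closed interval, cm^-1).
#' @return A \code{spectra_set} restricted to grid points in [lo, hi];
#'   metadata untouched. Idempotent.
#' @export
cut_region <- function(set, region) {
  stopifnot(inherits(set, "spectra_set"))
  r <- region_spec(region)
  keep <- set$grid >= r$lo & set$grid <= r$hi
  if (!any(keep))
    stop("region ", r$name, " (", r$lo, "-", r$hi,
         " cm-1) does not intersect the grid", call. = FALSE)
  spectra_set(lapply(set$spectra, function(s)
    ftir_spectrum(s$wavenumbers[keep], s$absorbance[keep], s$meta)))
}

# lower convex hull of (x, y) by Andrew's monotone chain; x strictly increasing
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # pop b if it lies on or above segment a-i (non-convex turn)
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Baseline-correct one spectrum
#'
#' \code{rubberband} (default): subtract the piecewise-linear lower convex
#' hull of the points (wavenumber, absorbance) — the standard elastic-band
#' correction for ATR tissue spectra; the result is nonnegative and exactly
#' zero at the hull contact points. \code{linear_endpoints}: subtract the
#' chord through the first and last points.
#'
#' @param spectrum An \code{ftir_spectrum} with at least 3 points.
#' @param method "rubberband" or "linear_endpoints".
#' @return The corrected \code{ftir_spectrum}.
#' @export
baseline_correct <- function(spectrum,
                             method = c("rubberband", "linear_endpoints")) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  method <- match.arg(method)
  x <- spectrum$wavenumbers; y <- spectrum$absorbance
  if (length(x) < 3L) stop("baseline correction needs >= 3 points",
                           call. = FALSE)
  if (method == "rubberband") {
    idx <- lower_hull_idx(x, y)
    base <- stats::approx(x[idx], y[idx], xout = x, method = "linear",
                          ties = "ordered")$y
    out <- pmax(y - base, 0)  # clamp -0/rounding dust at contact points
  } else {
    n <- length(x)
    base <- y[1L] + (y[n] - y[1L]) * (x - x[1L]) / (x[n] - x[1L])
    out <- y - base
  }
  ftir_spectrum(x, out, spectrum$meta)
}

#' Area-normalize one spectrum
#'
#' Divides by the trapezoidal integral over the grid so the integral of the
#' output is 1, removing differences in the amount of sample on the ATR
#' crystal. Idempotent up to floating point; invariant under positive
#' scaling of the input.
#'
#' @param spectrum An \code{ftir_spectrum} with positive integral.
#' @return The normalized \code{ftir_spectrum}.
#' @export
area_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  a <- pracma::trapz(spectrum$wavenumbers, spectrum$absorbance)
  if (!is.finite(a) || a <= 0)
    stop("nonpositive integral (", signif(a, 4), ") for sample '",
         spectrum$meta$sample_id, "'; cannot area-normalize", call. = FALSE)
  ftir_spectrum(spectrum$wavenumbers, spectrum$absorbance / a, spectrum$meta)
}

#' Savitzky-Golay parameters
#'
#' @param window_points Odd window length >= 3. The default 3-point window
#'   with a quadratic is the classic central second difference; wider windows
#'   trade resolution for noise suppression.
#' @param poly_order Polynomial order >= 2, < \code{window_points}.
#' @param derivative_order Fixed at 2 (second-derivative spectroscopy).
#' @return List of class \code{sg_params}.
#' @export
sg_params <- function(window_points = 3L, poly_order = 2L,
                      derivative_order = 2L) {
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  derivative_order <- as.integer(derivative_order)
  if (window_points < 3L || window_points %% 2L == 0L)
    stop("window_points must be an odd integer >= 3", call. = FALSE)
  if (poly_order < 2L || poly_order >= window_points)
    stop("need 2 <= poly_order < window_points", call. = FALSE)
  if (derivative_order != 2L)
    stop("only derivative_order = 2 is supported", call. = FALSE)
  structure(list(window_points = window_points, poly_order = poly_order,
                 derivative_order = derivative_order), class = "sg_params")
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Local least-squares polynomial differentiation on a uniform grid,
#' returning true d2A/dnu2 (the filter output is scaled by 1/step^2).
#' Boundary points are handled by refitting the polynomial at the edge
#' windows, so the trace keeps its full length. Linear in the input.
#'
#' @param spectrum An \code{ftir_spectrum} on a uniform grid.
#' @param params An \code{\link{sg_params}} object.
#' @return An \code{ftir_spectrum} holding the second-derivative trace
#'   (absorbance x cm^2, i.e. absorbance per unit wavenumber squared).
#' @export
second_derivative_sg <- function(spectrum, params = sg_params()) {
  stopifnot(inherits(spectrum, "ftir_spectrum"), inherits(params, "sg_params"))
  x <- spectrum$wavenumbers
  n <- length(x)
  if (params$window_points > n)
    stop("SG window (", params$window_points, ") exceeds spectrum length (",
         n, ")", call. = FALSE)
  h <- diff(x)
  if (max(abs(h - h[1L])) > 1e-6 * abs(h[1L]))
    stop("SG differentiation needs a uniform wavenumber grid", call. = FALSE)
  d2 <- signal::sgolayfilt(spectrum$absorbance, p = params$poly_order,
                           n = params$window_points, m = 2L, ts = h[1L])
  ftir_spectrum(x, d2, spectrum$meta)
}

#' Apply a per-spectrum operation to every member of a set
#'
#' @param set A \code{spectra_set}.
#' @param f Function \code{ftir_spectrum -> ftir_spectrum}.
#' @param ... Passed on to \code{f}.
#' @return A \code{spectra_set}.
#' @export
map_set <- function(set, f, ...) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(lapply(set$spectra, f, ...))
}

#' Preprocess one region: cut, baseline-correct, area-normalize, derive
#'
#' The standard per-region chain. Returns both the normalized
#' (non-derived) spectra, used for Amide-peak indices, and the
#' second-derivative spectra used for chemometrics and peak extraction.
#'
#' @param set A \code{spectra_set} (full-range spectra).
#' @param region Region name or list (see \code{\link{cut_region}}).
#' @param baseline_method Passed to \code{\link{baseline_correct}}.
#' @param sg An \code{\link{sg_params}} object.
#' @return List with elements \code{normalized} and \code{derivative}
#'   (both \code{spectra_set}), and \code{region} (the region spec used).
#' @export
preprocess_region <- function(set, region, baseline_method = "rubberband",
                              sg = sg_params()) {
  cutd <- cut_region(set, region)
  norm <- map_set(map_set(cutd, baseline_correct, method = baseline_method),
                  area_normalize)
  der <- map_set(norm, second_derivative_sg, params = sg)
  list(normalized = norm, derivative = der, region = region_spec(region))
}
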