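#' Construct a single FTIR spectrum
#'
#' A spectrum is one absorbance trace on a strictly increasing wavenumber
#' grid, plus sample metadata. Wavenumbers are stored ascending internally
#' (FTIR software conventionally plots them descending; \code{\link{plot.ftir_spectrum}}
#' reverses the axis).
#'
#' @param wavenumbers Numeric vector, cm^-1, strictly increasing (a descending
#'   vector is reordered together with \code{absorbance}).
#' @param absorbance Numeric vector, same length as \code{wavenumbers}.
#' @param meta A list or one-row data.frame with fields \code{sample_id},
#'   \code{tissue} ("cardiac" or "skeletal"), \code{age_months} (6, 12, 17 or
#'   24), \code{bio_rep} (1..10), \code{tech_rep} (1..3). See
#'   \code{\link{sample_meta}}.
#' @return An object of class \code{ftir_spectrum}.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  if (length(wavenumbers) < 8L)
    stop("a spectrum needs at least 8 points", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(absorbance) ||
      any(!is.finite(wavenumbers)) || any(!is.finite(absorbance)))
    stop("NaN/Inf not allowed in a spectrum", call. = FALSE)
  o <- order(wavenumbers)
  wavenumbers <- wavenumbers[o]
  absorbance <- absorbance[o]
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly monotone (duplicated points?)",
         call. = FALSE)
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = sample_meta(meta)),
            class = "ftir_spectrum")
}

#' Validate sample metadata
#'
#' @param meta list or one-row data.frame with \code{sample_id},
#'   \code{tissue}, \code{age_months}, \code{bio_rep}, \code{tech_rep}.
#' @return A validated list of the five fields.
#' @export
sample_meta <- function(meta) {
  meta <- as.list(meta)
  need <- c("sample_id", "tissue", "age_months", "bio_rep", "tech_rep")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- meta[need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$tissue <- as.character(meta$tissue)
  if (!meta$tissue %in% c("cardiac", "skeletal"))
    stop("unknown tissue '", meta$tissue,
         "' (expected 'cardiac' or 'skeletal')", call. = FALSE)
  meta$age_months <- as.integer(meta$age_months)
  if (!meta$age_months %in% c(6L, 12L, 17L, 24L))
    stop("age_months must be one of 6, 12, 17, 24 (got ",
         meta$age_months, ")", call. = FALSE)
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  if (is.na(meta$bio_rep) || meta$bio_rep < 1L || meta$bio_rep > 10L)
    stop("bio_rep must be in 1..10", call. = FALSE)
  if (is.na(meta$tech_rep) || meta$tech_rep < 1L || meta$tech_rep > 3L)
    stop("tech_rep must be in 1..3", call. = FALSE)
  meta
}

#' Construct a set of spectra sharing one wavenumber grid
#'
#' @param spectra List of \code{\link{ftir_spectrum}} objects, all on the same
#'   grid (use \code{\link{to_common_grid}} first if they are not).
#' @return An object of class \code{spectra_set} with elements \code{spectra}
#'   and \code{grid}.
#' @export
spectra_set <- function(spectra) {
  if (!length(spectra)) stop("empty spectra set", call. = FALSE)
  if (!all(vapply(spectra, inherits, logical(1), "ftir_spectrum")))
    stop("all elements must be ftir_spectrum objects", call. = FALSE)
  grid <- spectra[[1L]]$wavenumbers
  for (s in spectra)
    if (!identical(length(s$wavenumbers), length(grid)) ||
        !isTRUE(all(s$wavenumbers == grid)))
      stop("spectra are not on a common grid; run to_common_grid() first",
           call. = FALSE)
  key <- vapply(spectra, function(s)
    paste(s$meta$tissue, s$meta$age_months, s$meta$bio_rep, s$meta$tech_rep),
    character(1))
  if (anyDuplicated(key))
    stop("duplicate (tissue, age, bio_rep, tech_rep) combination in set",
         call. = FALSE)
  names(spectra) <- vapply(spectra, function(s) s$meta$sample_id, character(1))
  structure(list(spectra = spectra, grid = grid), class = "spectra_set")
}

#' @export
length.spectra_set <- function(x) length(x$spectra)

#' @export
print.spectra_set <- function(x, ...) {
  g <- x$grid
  cat(sprintf("spectra_set: %d spectra, %d points, %.1f-%.1f cm-1\n",
              length(x$spectra), length(g), min(g), max(g)))
  m <- set_meta(x)
  cat("tissues:", paste(sort(unique(m$tissue)), collapse = ", "),
      "| ages:", paste(sort(unique(m$age_months)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("ftir_spectrum '%s' (%s, %d M, bio %d, tech %d): %d points\n",
              x$meta$sample_id, x$meta$tissue, x$meta$age_months,
              x$meta$bio_rep, x$meta$tech_rep, length(x$wavenumbers)))
  invisible(x)
}

#' Metadata table of a spectra set
#'
#' @param set A \code{spectra_set}.
#' @return data.frame with one row per spectrum, in set order.
#' @export
set_meta <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  do.call(rbind, lapply(set$spectra, function(s)
    data.frame(s$meta, stringsAsFactors = FALSE)))
}

#' Subset a spectra set by a predicate on metadata
#'
#' @param set A \code{spectra_set}.
#' @param keep Logical vector (one per spectrum) or a function taking the
#'   metadata data.frame and returning one.
#' @return A \code{spectra_set} with the selected spectra.
#' @export
subset_set <- function(set, keep) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.function(keep)) keep <- keep(set_meta(set))
  keep <- as.logical(keep)
  stopifnot(length(keep) == length(set$spectra))
  spectra_set(set$spectra[keep])
}

csv_columns <- c("sample_id", "tissue", "age_months", "bio_rep", "tech_rep",
                 "wavenumber_cm1", "absorbance")

#' Read spectra from long-format CSV
#'
#' Canonical interchange format: one row per spectral point with columns
#' \code{sample_id, tissue, age_months, bio_rep, tech_rep, wavenumber_cm1,
#' absorbance}. Rows may appear in any wavenumber order (instrument exports
#' are often descending); spectra are stored ascending.
#'
#' @param path Path to a CSV file.
#' @return A \code{\link{spectra_set}}.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(csv_columns, names(d))
  if (length(miss))
    stop("CSV missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d[c("sample_id", "wavenumber_cm1")]))
    stop("duplicate (sample_id, wavenumber) rows in ", path, call. = FALSE)
  specs <- lapply(split(d, factor(d$sample_id, levels = unique(d$sample_id))),
                  function(g) {
    ftir_spectrum(g$wavenumber_cm1, g$absorbance,
                  meta = g[1L, c("sample_id", "tissue", "age_months",
                                 "bio_rep", "tech_rep")])
  })
  spectra_set(specs)
}

#' Write spectra to long-format CSV
#'
#' Inverse of \code{\link{read_spectra_csv}}: values survive a round-trip to
#' at least 12 significant digits.
#'
#' @param set A nonempty \code{spectra_set}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  if (!length(set$spectra)) stop("empty spectra set", call. = FALSE)
  rows <- lapply(set$spectra, function(s)
    data.frame(sample_id = s$meta$sample_id, tissue = s$meta$tissue,
               age_months = s$meta$age_months, bio_rep = s$meta$bio_rep,
               tech_rep = s$meta$tech_rep,
               wavenumber_cm1 = s$wavenumbers, absorbance = s$absorbance,
               stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  d$wavenumber_cm1 <- formatC(d$wavenumber_cm1, format = "g", digits = 15)
  d$absorbance <- formatC(d$absorbance, format = "g", digits = 15)
  ok <- tryCatch({
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Interpolate all spectra onto one wavenumber grid
#'
#' Linear interpolation; the grid must lie inside every member's wavenumber
#' range (no extrapolation). Idempotent when the set is already on the grid.
#'
#' @param set A \code{spectra_set}.
#' @param grid Strictly increasing wavenumber vector, cm^-1.
#' @return A \code{spectra_set} on \code{grid}.
#' @export
to_common_grid <- function(set, grid) {
  stopifnot(inherits(set, "spectra_set"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  specs <- lapply(set$spectra, function(s) {
    if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers))
      stop("grid extends beyond the range of sample '", s$meta$sample_id,
           "' (", min(s$wavenumbers), "-", max(s$wavenumbers),
           " cm-1); refusing to extrapolate", call. = FALSE)
    if (length(s$wavenumbers) == length(grid) &&
        isTRUE(all(s$wavenumbers == grid))) return(s)
    y <- stats::approx(s$wavenumbers, s$absorbance, xout = grid,
                       method = "linear", ties = "ordered")$y
    ftir_spectrum(grid, y, s$meta)
  })
  spectra_set(specs)
}
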