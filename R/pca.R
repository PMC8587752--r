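#' Build a sample-by-wavenumber data matrix from a spectra set
#'
#' @param set A \code{spectra_set}.
#' @return Numeric matrix (rows = spectra in set order, columns = grid
#'   points, dimnames = sample ids / wavenumbers) with the metadata
#'   data.frame attached as attribute \code{"meta"}.
#' @export
spectra_matrix <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  X <- t(vapply(set$spectra, function(s) s$absorbance,
                numeric(length(set$grid))))
  dimnames(X) <- list(names(set$spectra), format(set$grid, trim = TRUE))
  attr(X, "meta") <- set_meta(set)
  X
}

check_matrix <- function(X) {
  if (anyNA(X)) stop("data matrix contains NA", call. = FALSE)
  if (nrow(X) < 3L || ncol(X) < 2L)
    stop("data matrix needs >= 3 rows and >= 2 columns", call. = FALSE)
  invisible(X)
}

#' Principal component analysis of a spectral data matrix
#'
#' Mean-centered singular value decomposition: \code{scores = Xc \%*\%
#' loadings}, \code{explained_variance = sigma^2 / (n - 1)}. Used both for
#' Q-residual outlier screening on raw spectra and for tissue comparison on
#' second-derivative spectra (conventionally with up to seven components).
#'
#' @param X Numeric matrix, rows = samples.
#' @param n_components Number of components to retain
#'   (default \code{min(7, n - 1, p)}).
#' @return List of class \code{pca_model}: \code{column_means},
#'   \code{loadings} (p x k, orthonormal), \code{scores} (n x k),
#'   \code{explained_variance}, \code{explained_fraction}, \code{n_components}.
#' @export
pca_fit <- function(X, n_components = NULL) {
  check_matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- min(7L, kmax)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be in 1..", kmax, call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = 0L)
  rank <- sum(sv$d > max(sv$d) * max(n, p) * .Machine$double.eps)
  if (n_components > rank)
    stop("requested ", n_components, " components but matrix rank is ",
         rank, call. = FALSE)
  sv <- svd(Xc, nu = 0L, nv = n_components)
  ev_all <- sv$d^2 / (n - 1)
  structure(list(column_means = mu,
                 loadings = sv$v,
                 scores = Xc %*% sv$v,
                 explained_variance = ev_all[seq_len(n_components)],
                 explained_fraction = ev_all[seq_len(n_components)] /
                   sum(ev_all),
                 n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", x$n_components, "components;",
      "explained fraction:",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' Q residuals (squared prediction error) of samples against a PCA model
#'
#' \code{Q_i = || x_ci - P P' x_ci ||^2} with \code{x_ci} the centered row
#' and \code{P} the retained loadings: the squared distance of a sample
#' from the model subspace. Rows inside the span give 0; large values mark
#' spectra the model cannot explain (outliers).
#'
#' @param model A \code{pca_model}.
#' @param X Matrix with the same columns the model was fitted on.
#' @return Nonnegative numeric vector, one value per row.
#' @export
q_residuals <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$column_means))
    stop("X has ", ncol(X), " columns; model expects ",
         length(model$column_means), call. = FALSE)
  Xc <- sweep(X, 2L, model$column_means)
  E <- Xc - (Xc %*% model$loadings) %*% t(model$loadings)
  rowSums(E^2)
}

#' Flag outliers from Q residuals
#'
#' \code{mad} rule (default): flag \code{q > median(q) + k * 1.4826 * mad},
#' k = 3.5 — robust to the outliers themselves; if the MAD is zero, nothing
#' exceeding the median is flagged unless strictly above it by the (zero)
#' band, i.e. identical values are never flagged. \code{quantile} rule: flag
#' values above the k-quantile (type 7).
#'
#' @param q Nonnegative numeric vector of Q residuals.
#' @param rule "mad" or "quantile".
#' @param k Multiplier (mad rule, default 3.5) or probability
#'   (quantile rule).
#' @return Logical mask, TRUE = outlier.
#' @export
flag_outliers <- function(q, rule = c("mad", "quantile"), k = 3.5) {
  rule <- match.arg(rule)
  if (any(q < 0)) stop("Q residuals must be nonnegative", call. = FALSE)
  if (rule == "mad") {
    med <- stats::median(q)
    madv <- stats::median(abs(q - med))
    q > med + k * 1.4826 * madv
  } else {
    if (k <= 0 || k >= 1) stop("quantile rule needs 0 < k < 1", call. = FALSE)
    q > stats::quantile(q, k, names = FALSE)
  }
}

#' Remove Q-residual outliers from a spectra set, per tissue
#'
#' Fits a PCA per tissue on the raw full-range spectra (the screening is
#' done before region cutting) and drops spectra whose Q residuals the
#' chosen rule flags.
#'
#' @param set A \code{spectra_set}.
#' @param n_components PCA components for the screening model.
#' @param rule,k Passed to \code{\link{flag_outliers}}.
#' @return List: \code{kept} (a \code{spectra_set}), \code{removed}
#'   (character vector of sample ids), \code{q} (named Q-residual vector).
#' @export
screen_outliers <- function(set, n_components = 7L, rule = "mad", k = 3.5) {
  meta <- set_meta(set)
  flagged <- character(0)
  qall <- stats::setNames(numeric(0), character(0))
  for (ti in unique(meta$tissue)) {
    sub <- subset_set(set, meta$tissue == ti)
    X <- spectra_matrix(sub)
    m <- pca_fit(X, min(n_components, nrow(X) - 1L, ncol(X)))
    q <- q_residuals(m, X)
    names(q) <- rownames(X)
    qall <- c(qall, q)
    flagged <- c(flagged, names(q)[flag_outliers(q, rule, k)])
  }
  keep <- !(names(set$spectra) %in% flagged)
  list(kept = spectra_set(set$spectra[keep]), removed = flagged, q = qall)
}
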