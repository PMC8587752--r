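#' Plot an FTIR spectrum
#'
#' Wavenumber axis drawn descending, the spectroscopy convention.
#'
#' @param x An \code{ftir_spectrum}.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.ftir_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$absorbance, type = "l",
                 xlim = rev(range(x$wavenumbers)),
                 xlab = expression(Wavenumber ~ (cm^-1)),
                 ylab = "Absorbance", main = x$meta$sample_id, ...)
  invisible(x)
}

#' Plot group-mean spectra of a set
#'
#' One mean trace per (tissue, age) group, wavenumber axis descending.
#'
#' @param x A \code{spectra_set}.
#' @param ... Passed to \code{\link[graphics]{matplot}}.
#' @export
plot.spectra_set <- function(x, ...) {
  meta <- set_meta(x)
  grp <- interaction(meta$tissue, meta$age_months, drop = TRUE)
  X <- spectra_matrix(x)
  M <- t(vapply(levels(grp), function(g)
    colMeans(X[grp == g, , drop = FALSE]), numeric(ncol(X))))
  graphics::matplot(x$grid, t(M), type = "l", lty = 1,
                    col = grDevices::hcl.colors(nrow(M), "viridis"),
                    xlim = rev(range(x$grid)),
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance", ...)
  graphics::legend("topleft", legend = levels(grp), lty = 1, cex = 0.7,
                   col = grDevices::hcl.colors(nrow(M), "viridis"))
  invisible(x)
}

#' Score plot of a fitted PLS model
#'
#' @param x A \code{pls_model}.
#' @param factors Two factor indices to plot (default 1:2, or factor 1
#'   against the response when only one factor was extracted).
#' @param labels Optional point labels/colors (e.g. age groups).
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.pls_model <- function(x, factors = c(1L, 2L), labels = NULL, ...) {
  s <- x$scores
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  if (ncol(s) >= max(factors)) {
    graphics::plot(s[, factors[1L]], s[, factors[2L]], col = col, pch = 19,
                   xlab = paste("Factor", factors[1L]),
                   ylab = paste("Factor", factors[2L]), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  } else {
    graphics::plot(s[, 1L], x$y_predicted, col = col, pch = 19,
                   xlab = "Factor 1", ylab = "Predicted age (months)", ...)
  }
  if (!is.null(labels))
    graphics::legend("topleft", legend = levels(factor(labels)), pch = 19,
                     col = seq_along(levels(factor(labels))), cex = 0.7)
  invisible(x)
}
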