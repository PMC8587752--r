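#' Read a JCAMP-DX infrared spectrum (XYDATA dialect)
#'
#' Minimal reader for the fixed-format \code{##XYDATA=(X++(Y..Y))} dialect
#' with \code{XUNITS=1/CM} and \code{YUNITS=ABSORBANCE}: each data line holds
#' an X start value followed by equally spaced Y values, scaled by
#' \code{XFACTOR}/\code{YFACTOR}. Compressed (SQZ/DIF/DUP) encodings are not
#' supported.
#'
#' @param path Path to a JCAMP-DX file.
#' @param meta Sample metadata for the resulting spectrum
#'   (see \code{\link{sample_meta}}).
#' @return An \code{\link{ftir_spectrum}}.
#' @export
read_jcampdx <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^##", name, "="), "", hit[1L]))
  }
  xu <- toupper(ldr("XUNITS")); yu <- toupper(ldr("YUNITS"))
  if (!is.na(xu) && xu != "1/CM")
    stop("unsupported XUNITS '", xu, "' (expected 1/CM)", call. = FALSE)
  if (!is.na(yu) && yu != "ABSORBANCE")
    stop("unsupported YUNITS '", yu, "' (expected ABSORBANCE)", call. = FALSE)
  xf <- ldr("XFACTOR"); yf <- ldr("YFACTOR")
  xf <- if (is.na(xf)) 1 else as.numeric(xf)
  yf <- if (is.na(yf)) 1 else as.numeric(yf)
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start))
    stop("no ##XYDATA=(X++(Y..Y)) block in ", path, call. = FALSE)
  body <- lines[(start[1L] + 1L):length(lines)]
  endl <- grep("^##", body)
  if (length(endl)) body <- body[seq_len(endl[1L] - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty XYDATA block in ", path, call. = FALSE)
  # need the x step to expand X++(Y..Y); take it from successive line starts
  # or, for a single line, from FIRSTX/LASTX/NPOINTS
  toks <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[ \t,;]+")[[1L]]))
  if (any(vapply(toks, anyNA, logical(1))))
    stop("non-numeric token in XYDATA (compressed JCAMP not supported)",
         call. = FALSE)
  nys <- vapply(toks, length, integer(1)) - 1L
  if (any(nys < 1L)) stop("malformed XYDATA line", call. = FALSE)
  x0 <- vapply(toks, `[`, numeric(1), 1L) * xf
  if (length(body) > 1L) {
    dx <- (x0[2L] - x0[1L]) / nys[1L]
  } else {
    fx <- as.numeric(ldr("FIRSTX")); lx <- as.numeric(ldr("LASTX"))
    np <- as.numeric(ldr("NPOINTS"))
    if (anyNA(c(fx, lx, np)))
      stop("single-line XYDATA needs FIRSTX/LASTX/NPOINTS", call. = FALSE)
    dx <- (lx - fx) / (np - 1)
  }
  xs <- unlist(mapply(function(x, n) x + dx * (seq_len(n) - 1L), x0, nys,
                      SIMPLIFY = FALSE))
  ys <- unlist(lapply(toks, `[`, -1L)) * yf
  ftir_spectrum(xs, ys, meta)
}
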