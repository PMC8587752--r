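#' Cross-validation specification for PLS
#'
#' @param folds Number of random folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return List of class \code{cv_spec}.
#' @export
cv_spec <- function(folds = 10L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("need >= 2 CV folds", call. = FALSE)
  structure(list(folds = folds, seed = as.integer(seed)), class = "cv_spec")
}

# Kernel PLS1 (improved kernel algorithm, XtX / Xty form) on centered data.
# Returns R (p x a), W, P, q, tt such that T = Xc %*% R and the k-factor
# coefficient vector is R[, 1:k] %*% q[1:k].
kernel_pls1_core <- function(Xc, yc, max_factors) {
  p <- ncol(Xc)
  A <- crossprod(Xc)            # XtX, p x p
  b <- drop(crossprod(Xc, yc))  # Xty
  W <- R <- P <- matrix(0, p, max_factors)
  q <- tt <- numeric(max_factors)
  a <- 0L
  for (i in seq_len(max_factors)) {
    nb <- sqrt(sum(b^2))
    if (nb < 1e-12) break
    w <- b / nb
    r <- w
    if (a > 0L) for (j in seq_len(a)) r <- r - sum(P[, j] * w) * R[, j]
    Ar <- drop(A %*% r)
    tti <- sum(r * Ar)
    if (tti < 1e-12) break
    a <- a + 1L
    W[, a] <- w; R[, a] <- r
    P[, a] <- Ar / tti
    q[a] <- sum(r * b) / tti
    tt[a] <- tti
    b <- b - P[, a] * (tti * q[a])
  }
  if (a == 0L)
    stop("degenerate predictors: X carries no variance correlated with ",
         "itself (all columns constant?)", call. = FALSE)
  list(W = W[, seq_len(a), drop = FALSE], R = R[, seq_len(a), drop = FALSE],
       P = P[, seq_len(a), drop = FALSE], q = q[seq_len(a)],
       tt = tt[seq_len(a)], n = a)
}

#' Fit a kernel PLS1 regression of age on spectra
#'
#' Single-response partial least squares fitted with the kernel algorithm
#' (all factor extraction done on the cross-product matrices X'X and X'y of
#' the mean-centered data; numerically equivalent to NIPALS for one
#' response). Per-factor prediction error is estimated by seeded random
#' K-fold cross-validation, and the working factor count is chosen by the
#' parsimony rule of \code{\link{select_n_factors}}.
#'
#' @param X Numeric matrix, rows = samples (typically second-derivative
#'   spectra of one region).
#' @param y Numeric response (age in months), length \code{nrow(X)}, >= 6.
#' @param max_factors Largest factor count to extract (default 7, capped at
#'   \code{min(n - 1, p)} and at the available rank).
#' @param cv A \code{\link{cv_spec}}; \code{NULL} skips cross-validation
#'   (then \code{n_factors = max_factors}).
#' @return List of class \code{pls_model}: \code{x_means}, \code{y_mean},
#'   \code{weights} (W), \code{x_loadings} (P), \code{y_loadings} (q),
#'   \code{rotations} (R, with \code{scores = Xc \%*\% R}), \code{scores},
#'   \code{coefficients} (per factor count, p x a), \code{cv_rmse},
#'   \code{y_cv} (cross-validated predictions, one column per factor
#'   count; unbiased, unlike training scores), \code{n_factors},
#'   \code{y_predicted} (training fit at \code{n_factors}),
#'   \code{pearson_r}.
#' @export
pls_fit <- function(X, y, max_factors = 7L, cv = cv_spec()) {
  check_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 6L) stop("PLS needs at least 6 samples", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("constant response: cannot regress on a single age", call. = FALSE)
  max_factors <- min(as.integer(max_factors), n - 1L, ncol(X))
  if (max_factors < 1L) stop("max_factors must be >= 1", call. = FALSE)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2L, mx); yc <- y - my
  core <- kernel_pls1_core(Xc, yc, max_factors)
  a <- core$n
  # cumulative coefficient vectors: column k = R[,1:k] %*% q[1:k]
  B <- sapply(seq_len(a), function(k)
    core$R[, seq_len(k), drop = FALSE] %*% core$q[seq_len(k)])
  B <- matrix(B, ncol = a)
  cv_rmse <- NULL
  if (!is.null(cv)) {
    stopifnot(inherits(cv, "cv_spec"))
    if (n < cv$folds) stop("fewer samples (", n, ") than CV folds (",
                           cv$folds, ")", call. = FALSE)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(cv$seed)
    fold <- sample(rep_len(seq_len(cv$folds), n))
    press <- matrix(0, cv$folds, a)
    cnt <- integer(cv$folds)
    y_cv <- matrix(NA_real_, n, a)
    for (f in seq_len(cv$folds)) {
      tr <- fold != f
      mtx <- colMeans(X[tr, , drop = FALSE]); mty <- mean(y[tr])
      corf <- kernel_pls1_core(sweep(X[tr, , drop = FALSE], 2L, mtx),
                               y[tr] - mty, a)
      af <- corf$n
      Bf <- sapply(seq_len(af), function(k)
        corf$R[, seq_len(k), drop = FALSE] %*% corf$q[seq_len(k)])
      Bf <- matrix(Bf, ncol = af)
      pred <- sweep(X[!tr, , drop = FALSE], 2L, mtx) %*% Bf + mty
      if (af < a) pred <- cbind(pred, matrix(pred[, af], nrow(pred),
                                             a - af))
      y_cv[!tr, ] <- pred
      press[f, ] <- colSums((pred - y[!tr])^2)
      cnt[f] <- sum(!tr)
    }
    cv_rmse <- sqrt(colSums(press) / sum(cnt))
  } else y_cv <- NULL
  model <- structure(list(
    x_means = mx, y_mean = my,
    weights = core$W, x_loadings = core$P, y_loadings = core$q,
    rotations = core$R, scores = Xc %*% core$R,
    coefficients = B, cv_rmse = cv_rmse, y_cv = y_cv, max_factors = a),
    class = "pls_model")
  model$n_factors <- if (is.null(cv_rmse)) a else select_n_factors(model)
  model$y_predicted <- drop(Xc %*% B[, model$n_factors] + my)
  model$pearson_r <- pearson_r(y, model$y_predicted)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d factors extracted, %d selected, training R = %.3f\n",
              x$max_factors, x$n_factors, x$pearson_r))
  if (!is.null(x$cv_rmse))
    cat("cv_rmse:", paste(sprintf("%.3f", x$cv_rmse), collapse = " "), "\n")
  invisible(x)
}

#' Predict ages from a fitted PLS model
#'
#' @param object A \code{pls_model}.
#' @param newdata Matrix with the columns the model was fitted on.
#' @param n_factors Factor count (default the model's selected count).
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_factors = object$n_factors,
                              ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  stopifnot(n_factors >= 1L, n_factors <= object$max_factors)
  drop(sweep(newdata, 2L, object$x_means) %*%
         object$coefficients[, n_factors] + object$y_mean)
}

#' Choose the PLS factor count from the CV error curve
#'
#' Parsimony rule: the smallest factor count whose cross-validated RMSE is
#' within 2\% of the curve minimum (\code{cv_rmse <= 1.02 * min}), avoiding
#' overfitting factor counts whose gain is marginal.
#'
#' @param model A \code{pls_model} with \code{cv_rmse} populated.
#' @return Integer factor count.
#' @export
select_n_factors <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$cv_rmse))
    stop("model has no cv_rmse; fit with a cv_spec", call. = FALSE)
  which(model$cv_rmse <= 1.02 * min(model$cv_rmse))[1L]
}

#' Pearson product-moment correlation with domain checks
#'
#' @param a,b Numeric vectors, length >= 3, neither constant.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(a, b)
}

#' Score-plot discrimination statistics for two groups
#'
#' Classifies samples by the sign of a latent-variable score, the way a
#' score plot is read: the axis is oriented so the positive group (the older
#' age) has the higher mean score, then samples with score > 0 are called
#' positive. Reports the confusion counts and sensitivity / specificity in
#' percent.
#'
#' @param scores Numeric score vector (one latent factor), one value per
#'   sample.
#' @param labels Group label per sample; exactly two groups, both nonempty.
#' @param positive_group The label treated as positive (e.g. the older age).
#' @return List of class \code{discrimination_result}: \code{positive_group},
#'   \code{threshold} (0), \code{flipped} (whether the axis was mirrored),
#'   \code{tp}, \code{fn}, \code{tn}, \code{fp}, \code{sensitivity},
#'   \code{specificity} (percent).
#' @export
score_discrimination <- function(scores, labels, positive_group) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == as.character(positive_group)
  if (!any(pos) || all(pos))
    stop("both groups must be nonempty (positive_group = '",
         positive_group, "')", call. = FALSE)
  flipped <- mean(scores[pos]) < mean(scores[!pos])
  if (flipped) scores <- -scores
  called_pos <- scores > 0
  tp <- sum(pos & called_pos); fn <- sum(pos & !called_pos)
  tn <- sum(!pos & !called_pos); fp <- sum(!pos & called_pos)
  structure(list(positive_group = positive_group, threshold = 0,
                 flipped = flipped, tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp)),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "discrimination vs '%s': sensitivity %.1f%%, specificity %.1f%% (tp %d, fn %d, tn %d, fp %d)\n",
    x$positive_group, x$sensitivity, x$specificity, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}
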