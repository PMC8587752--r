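#' Ordinary two-way ANOVA (tissue x age)
#'
#' Fixed-effects, not-repeated-measures two-way ANOVA of one index on
#' tissue, age and their interaction. Balanced designs use the classical
#' orthogonal partition (sequential sums of squares coincide with it);
#' unbalanced designs (e.g. after outlier removal) use Type II sums of
#' squares via nested model comparisons. One observation per animal is the
#' intended unit (average technical replicates first; see
#' \code{\link{average_tech_reps}}).
#'
#' @param values Numeric response vector.
#' @param tissue,age Factors (coerced), each with >= 2 levels.
#' @return data.frame of class \code{anova_table}, rows tissue / age /
#'   tissue:age / residual, columns \code{sum_sq}, \code{df},
#'   \code{mean_sq}, \code{F}, \code{p}.
#' @export
two_way_anova <- function(values, tissue, age) {
  values <- as.numeric(values)
  tissue <- factor(tissue); age <- factor(age)
  stopifnot(length(values) == length(tissue),
            length(values) == length(age))
  if (nlevels(tissue) < 2L || nlevels(age) < 2L)
    stop("both factors need >= 2 levels", call. = FALSE)
  counts <- table(tissue, age)
  if (any(counts == 0L)) {
    i <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: tissue=", levels(tissue)[i[1L]],
         ", age=", levels(age)[i[2L]], call. = FALSE)
  }
  if (stats::sd(values) == 0)
    stop("response has no variance; F undefined", call. = FALSE)
  n <- length(values)
  df_resid <- n - nlevels(tissue) * nlevels(age)
  if (df_resid < 1L)
    stop("zero residual degrees of freedom (one observation per cell)",
         call. = FALSE)
  d <- data.frame(values = values, tissue = tissue, age = age)
  # effect coding so Type II SS are the standard ones on unbalanced data
  fit <- stats::lm(values ~ tissue * age, data = d,
                   contrasts = list(tissue = "contr.sum", age = "contr.sum"))
  balanced <- length(unique(as.vector(counts))) == 1L
  if (balanced) {
    a <- stats::anova(fit)
    tab <- data.frame(effect = c("tissue", "age", "tissue:age", "residual"),
                      sum_sq = a$`Sum Sq`, df = a$Df,
                      mean_sq = a$`Mean Sq`, F = a$`F value`,
                      p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = 2)
    rs <- a["Residuals", ]
    tab <- data.frame(effect = c("tissue", "age", "tissue:age", "residual"),
                      sum_sq = c(a[c("tissue", "age", "tissue:age"),
                                   "Sum Sq"], rs$`Sum Sq`),
                      df = c(a[c("tissue", "age", "tissue:age"), "Df"],
                             rs$Df),
                      F = c(a[c("tissue", "age", "tissue:age"), "F value"],
                            NA),
                      p = c(a[c("tissue", "age", "tissue:age"), "Pr(>F)"],
                            NA))
    tab$mean_sq <- tab$sum_sq / tab$df
    tab <- tab[c("effect", "sum_sq", "df", "mean_sq", "F", "p")]
  }
  rownames(tab) <- NULL
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Sidak multiplicity adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m}, clipped to [0, 1]: the exact familywise
#' correction for m independent comparisons.
#'
#' @param raw_p Numeric vector of p-values in [0, 1].
#' @param m Number of comparisons in the family (default
#'   \code{length(raw_p)}).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(raw_p, m = length(raw_p)) {
  raw_p <- as.numeric(raw_p)
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE) || anyNA(raw_p))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  pmin(pmax(1 - (1 - raw_p)^m, 0), 1)
}

p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Age-wise tissue contrasts with Sidak adjustment
#'
#' The comparison family used for the index panels: at each age, cardiac vs
#' skeletal cell means, tested with
#' \code{t = dmean / sqrt(MS_residual * (1/n_a + 1/n_b))} on the two-way
#' ANOVA's residual degrees of freedom, two-sided, Sidak-adjusted over the
#' family (one family per index).
#'
#' @param values,tissue,age As in \code{\link{two_way_anova}}.
#' @param alpha Familywise significance level (default 0.05).
#' @return data.frame of class \code{comparison_set}: \code{age},
#'   \code{group_a}, \code{group_b}, \code{mean_difference} (a - b),
#'   \code{raw_p}, \code{sidak_p}, \code{significant}, \code{stars}.
#' @export
pairwise_cells <- function(values, tissue, age, alpha = 0.05) {
  values <- as.numeric(values)
  tissue <- factor(tissue); age <- factor(age)
  tab <- two_way_anova(values, tissue, age)
  ms_res <- tab$mean_sq[tab$effect == "residual"]
  df_res <- tab$df[tab$effect == "residual"]
  tl <- levels(tissue)
  if (nlevels(tissue) != 2L)
    stop("pairwise_cells compares exactly two tissues", call. = FALSE)
  rows <- lapply(levels(age), function(a) {
    ia <- age == a & tissue == tl[1L]
    ib <- age == a & tissue == tl[2L]
    if (!any(ia) || !any(ib))
      stop("empty cell at age ", a, call. = FALSE)
    dm <- mean(values[ia]) - mean(values[ib])
    se <- sqrt(ms_res * (1 / sum(ia) + 1 / sum(ib)))
    tstat <- dm / se
    data.frame(age = a, group_a = tl[1L], group_b = tl[2L],
               mean_difference = dm,
               raw_p = 2 * stats::pt(-abs(tstat), df_res))
  })
  out <- do.call(rbind, rows)
  out$sidak_p <- sidak_adjust(out$raw_p, nrow(out))
  out$significant <- out$sidak_p < alpha
  out$stars <- p_stars(out$sidak_p)
  rownames(out) <- NULL
  class(out) <- c("comparison_set", "data.frame")
  out
}

#' ANOVA and tissue contrasts for every panel index
#'
#' Averages technical replicates per animal, then runs
#' \code{\link{two_way_anova}} and \code{\link{pairwise_cells}} per index.
#'
#' @param panel A \code{band_index_panel}.
#' @param alpha Familywise level for the contrasts.
#' @return List with \code{anova} (named list of \code{anova_table}) and
#'   \code{comparisons} (named list of \code{comparison_set}).
#' @export
panel_stats <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "band_index_panel"))
  avg <- average_tech_reps(panel)
  idx <- panel_index_names()
  anovas <- comps <- list()
  for (v in idx) {
    anovas[[v]] <- two_way_anova(avg[[v]], avg$tissue, avg$age_months)
    comps[[v]] <- pairwise_cells(avg[[v]], avg$tissue, avg$age_months,
                                 alpha)
  }
  list(anova = anovas, comparisons = comps)
}
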