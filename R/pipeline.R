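#' Pipeline configuration
#'
#' Everything the end-to-end workflow needs. Spectra come either from a
#' long-format CSV (\code{input}) or from the synthetic cohort generator
#' (\code{cohort}); exactly one must be given.
#'
#' @param input Path to a spectra CSV (see \code{\link{read_spectra_csv}}),
#'   or \code{NULL}.
#' @param cohort A \code{\link{cohort_config}}, or \code{NULL}. If both are
#'   \code{NULL} a default cohort seeded from \code{seed} is used.
#' @param regions Region table (default \code{\link{canonical_regions}}).
#' @param baseline_method Passed to \code{\link{baseline_correct}}.
#' @param sg \code{\link{sg_params}} for the derivative stage. The pipeline
#'   default is a 9-point quadratic window: the widest window whose
#'   windowed-maximum peak positions still resolve the closest assigned
#'   band pairs (11 cm^-1 apart at sub-band widths of ~5 cm^-1), cutting
#'   the second-derivative noise gain to ~0.03 per unit noise SD (a
#'   3-point second difference has gain ~0.61). The window used is always
#'   recorded in the report.
#' @param outlier_rule,outlier_k Passed to \code{\link{flag_outliers}}.
#' @param cv_folds Folds for PLS cross-validation.
#' @param max_factors Largest PLS factor count / PCA component count.
#' @param factors Optional manual override of the PLS factor count (single
#'   integer, applied to every tissue x region model); \code{NULL} selects
#'   automatically.
#' @param halfwidth Peak search half-window for the index panel, cm^-1.
#' @param panel_replicates "average_spectra" (default): average each
#'   animal's technical-replicate spectra after preprocessing, before peak
#'   extraction (see \code{\link{average_tech_spectra}}); "rows": extract
#'   per technical replicate and average the index values per animal only
#'   at the statistics stage. PCA/PLS always keep technical replicates as
#'   rows.
#' @param young,old The two age groups (months) whose score-plot
#'   discrimination is reported.
#' @param alpha Familywise level for the tissue contrasts.
#' @param seed Master seed; the simulation (when \code{cohort} is NULL) and
#'   the CV fold assignment both derive from it.
#' @param out_dir Directory for CSV/JSON artifacts, or \code{NULL} to skip
#'   writing.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, cohort = NULL,
                            regions = canonical_regions(),
                            baseline_method = "rubberband",
                            sg = sg_params(window_points = 9L),
                            outlier_rule = "mad", outlier_k = 3.5,
                            cv_folds = 10L, max_factors = 7L,
                            factors = NULL, halfwidth = 6,
                            panel_replicates = c("average_spectra", "rows"),
                            young = 6L, old = 24L, alpha = 0.05,
                            seed = 1L, out_dir = NULL) {
  if (!is.null(input) && !is.null(cohort))
    stop("give either an input CSV or a cohort config, not both",
         call. = FALSE)
  if (is.null(input) && is.null(cohort))
    cohort <- cohort_config(seed = as.integer(seed))
  stopifnot(inherits(sg, "sg_params"))
  structure(list(input = input, cohort = cohort, regions = regions,
                 baseline_method = baseline_method, sg = sg,
                 outlier_rule = outlier_rule, outlier_k = outlier_k,
                 cv_folds = as.integer(cv_folds),
                 max_factors = as.integer(max_factors),
                 factors = factors, halfwidth = halfwidth,
                 panel_replicates = match.arg(panel_replicates),
                 young = as.integer(young), old = as.integer(old),
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Cross-tissue PCA discrimination per region
#'
#' Pools the second-derivative spectra of both tissues in one region, fits a
#' PCA and reads tissue separation off the first principal component
#' (score-plot classification, cardiac as the positive group).
#'
#' @param X Second-derivative data matrix with both tissues (rows carry a
#'   \code{"meta"} attribute, as from \code{\link{spectra_matrix}}).
#' @param n_components PCA components to fit (PC1 is used for the
#'   discrimination).
#' @return List: \code{pca} (the \code{pca_model}) and \code{discrimination}
#'   (a \code{discrimination_result} on PC1).
#' @export
compare_tissues_pca <- function(X, n_components = 7L) {
  meta <- attr(X, "meta")
  if (is.null(meta)) stop("X must carry a 'meta' attribute", call. = FALSE)
  if (length(unique(meta$tissue)) < 2L)
    stop("both tissues must be present", call. = FALSE)
  m <- pca_fit(X, min(n_components, nrow(X) - 1L, ncol(X)))
  disc <- score_discrimination(m$scores[, 1L], meta$tissue, "cardiac")
  list(pca = m, discrimination = disc)
}

pls_region_tissue <- function(X, meta, config) {
  y <- meta$age_months
  model <- pls_fit(X, y, max_factors = config$max_factors,
                   cv = cv_spec(config$cv_folds, config$seed + 1L))
  if (!is.null(config$factors)) {
    model$n_factors <- min(as.integer(config$factors), model$max_factors)
    model$y_predicted <- predict(model, X, model$n_factors)
    model$pearson_r <- pearson_r(y, model$y_predicted)
  }
  sel <- meta$age_months %in% c(config$young, config$old)
  # read discrimination off the single factor (<= the selected count) that
  # separates the two named age groups best, the way a score plot is chosen
  best <- NULL
  for (k in seq_len(model$n_factors)) {
    d <- score_discrimination(model$scores[sel, k],
                              meta$age_months[sel], config$old)
    d$factor_index <- k
    if (is.null(best) ||
        d$sensitivity + d$specificity > best$sensitivity + best$specificity)
      best <- d
  }
  list(model = model, discrimination = best)
}

#' Run the full aging-fingerprint workflow
#'
#' Stages, in order: load or simulate the cohort; PCA Q-residual outlier
#' screening per tissue on the raw full-range spectra; per region cut,
#' rubberband baseline correction, area normalization and Savitzky-Golay
#' second derivative; per tissue x region kernel-PLS regression against age
#' with cross-validated factor selection and 6 M vs 24 M score
#' discrimination; per region cross-tissue PCA (PC1 separation); the
#' nine-index band panel with group summaries; two-way ANOVA with
#' Sidak-adjusted age-wise tissue contrasts per index. Deterministic given
#' the config (all randomness flows from \code{config$seed}).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{study_report}; see the elements written by
#'   this function (\code{outliers}, \code{pls}, \code{tissue_pca},
#'   \code{panel}, \code{panel_summary}, \code{stats}, \code{provenance}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set <- stage("load", {
    if (!is.null(config$input)) read_spectra_csv(config$input)
    else generate_cohort(config$cohort)
  })
  qc <- stage("outlier_screen",
              screen_outliers(set, n_components = config$max_factors,
                              rule = config$outlier_rule,
                              k = config$outlier_k))
  kept <- qc$kept
  regions <- stage("preprocess", {
    out <- list()
    for (i in seq_len(nrow(config$regions))) {
      r <- config$regions[i, ]
      out[[r$name]] <- preprocess_region(kept, as.list(r),
                                         config$baseline_method, config$sg)
    }
    out
  })
  meta <- set_meta(kept)
  pls <- stage("pls", {
    out <- list()
    for (rn in names(regions)) {
      X <- spectra_matrix(regions[[rn]]$derivative)
      for (ti in unique(meta$tissue)) {
        rows <- meta$tissue == ti
        out[[paste(ti, rn, sep = ".")]] <-
          pls_region_tissue(X[rows, , drop = FALSE], meta[rows, ], config)
      }
    }
    out
  })
  tissue_pca <- stage("tissue_pca", {
    out <- list()
    if (length(unique(meta$tissue)) >= 2L)
      for (rn in names(regions))
        out[[rn]] <- compare_tissues_pca(
          spectra_matrix(regions[[rn]]$derivative), config$max_factors)
    out
  })
  panel <- stage("panel", {
    pr <- regions
    if (config$panel_replicates == "average_spectra")
      pr <- lapply(regions, function(r)
        list(normalized = average_tech_spectra(r$normalized),
             derivative = average_tech_spectra(r$derivative),
             region = r$region))
    compute_panel(pr, config$halfwidth)
  })
  panel_summary <- stage("panel_summary",
                         summarize_panel(panel, average_technical = TRUE))
  pstats <- stage("stats", panel_stats(panel, config$alpha))
  report <- structure(list(
    outliers = list(removed = qc$removed, q = qc$q,
                    rule = config$outlier_rule, k = config$outlier_k),
    pls = pls, tissue_pca = tissue_pca,
    panel = panel, panel_summary = panel_summary, stats = pstats,
    provenance = list(
      seed = config$seed, n_spectra = length(set),
      n_removed = length(qc$removed),
      sg_window = config$sg$window_points,
      sg_poly_order = config$sg$poly_order,
      baseline_method = config$baseline_method,
      cv_folds = config$cv_folds, max_factors = config$max_factors,
      halfwidth = config$halfwidth,
      panel_replicates = config$panel_replicates,
      simulated = is.null(config$input))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  spectra: %d (removed %d outliers)\n",
              x$provenance$n_spectra, x$provenance$n_removed))
  for (nm in names(x$pls)) {
    p <- x$pls[[nm]]
    cat(sprintf(
      "  PLS %-22s factors %d (disc. factor %d), R = %.3f, sens %.1f%%, spec %.1f%%\n",
      nm, p$model$n_factors, p$discrimination$factor_index,
      p$model$pearson_r, p$discrimination$sensitivity,
      p$discrimination$specificity))
  }
  for (nm in names(x$tissue_pca)) {
    d <- x$tissue_pca[[nm]]$discrimination
    cat(sprintf("  PCA tissue separation %-12s PC1 sens %.1f%%, spec %.1f%%\n",
                nm, d$sensitivity, d$specificity))
  }
  invisible(x)
}

#' Write the report artifacts of a pipeline run
#'
#' @param report A \code{study_report}.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wp <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wp(report$panel, "panel.csv")
  wp(report$panel_summary, "panel_summary.csv")
  an <- do.call(rbind, lapply(names(report$stats$anova), function(v)
    cbind(index = v, report$stats$anova[[v]])))
  wp(an, "anova.csv")
  cm <- do.call(rbind, lapply(names(report$stats$comparisons), function(v)
    cbind(index = v, report$stats$comparisons[[v]])))
  wp(cm, "comparisons.csv")
  js <- list(provenance = report$provenance,
             outliers_removed = report$outliers$removed,
             pls = lapply(report$pls, function(p) list(
               n_factors = p$model$n_factors,
               discriminating_factor = p$discrimination$factor_index,
               cv_rmse = p$model$cv_rmse,
               pearson_r = p$model$pearson_r,
               sensitivity = p$discrimination$sensitivity,
               specificity = p$discrimination$specificity)),
             tissue_pca = lapply(report$tissue_pca, function(d) list(
               explained_fraction = d$pca$explained_fraction,
               sensitivity = d$discrimination$sensitivity,
               specificity = d$discrimination$specificity)))
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
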