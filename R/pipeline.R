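#' Run the full equation-development workflow
#'
#' Reproduces the analysis pipeline end to end on one cohort:
#' (1) obtain the cohort (from a CSV path or the synthetic generator);
#' (2) random development / cross-validation split; (3) per-frequency
#' bivariate scan on the development part; (4) stepwise multiple linear
#' regression on the development part; (5) validation battery of the
#' developed equation on the holdout; (6) refit of the selected terms on
#' the whole cohort (the "final" equation); (7) sarcopenia diagnostic
#' agreement of the final equation against DXA on the whole cohort.
#' One global seed fans out to fixed per-stage child seeds, so the report
#' is bit-reproducible.
#'
#' @param cohort a `bia_cohort`, a CSV path, or `NULL` to generate a
#'   synthetic cohort from `config`.
#' @param config a [cohort_config()] used when `cohort` is `NULL`; its
#'   `seed` is the pipeline's global seed.
#' @param candidates candidate predictor names for the stepwise stage.
#' @param dev_fraction development-group fraction for the split.
#' @param alpha_enter,alpha_remove stepwise thresholds; see
#'   [stepwise_select()].
#' @param scan run the bivariate frequency scan stage.
#' @param direction Bland-Altman difference direction.
#' @param rule AWGS cutoff rule for the diagnostic stage.
#' @return An `alm_pipeline_report` list with elements `scan`,
#'   `development` (`alm_fit`), `developed_equation`, `validation`
#'   (`validation_report`), `final_fit`, `final_equation`, `diagnosis`
#'   (`confusion_summary`), and `provenance`.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         candidates = c(paste0("ZI@",
                                               names(bia_frequencies())),
                                        "Xc@5kHz", "Xc@50kHz", "sex",
                                        "weight"),
                         dev_fraction = 2 / 3,
                         alpha_enter = 0.05, alpha_remove = 0.10,
                         scan = TRUE,
                         direction = "measured-minus-predicted",
                         rule = awgs_cutoff()) {
  stage <- "input"
  report <- list()
  tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config)
    else if (is.character(cohort)) cohort <- read_cohort(cohort)
    stopifnot(inherits(cohort, "bia_cohort"))

    stage <- "split"
    parts <- split_cohort(cohort, dev_fraction,
                          seed = derive_seed(config$seed, 2L))
    dev <- parts$development; holdout <- parts$cross_validation

    stage <- "frequency scan"
    report$scan <- if (scan) frequency_scan(dev) else NULL

    stage <- "development"
    fit <- stepwise_select(dev$alm_dxa_kg,
                           predictor_matrix(dev, candidates),
                           alpha_enter, alpha_remove)
    report$development <- fit
    if (isTRUE(fit$empty_model))
      stop("no candidate entered the stepwise model", call. = FALSE)
    report$developed_equation <- alm_equation(
      "developed", fit$terms, fit$intercept,
      population = sprintf("synthetic development split, n = %d", fit$n))

    stage <- "internal cross-validation"
    report$validation <- validate_equation(holdout,
                                           report$developed_equation,
                                           direction = direction)

    stage <- "final refit"
    final_fit <- fit_ols(cohort$alm_dxa_kg,
                         predictor_matrix(cohort, names(fit$terms)))
    report$final_fit <- final_fit
    report$final_equation <- alm_equation(
      "final-refit", final_fit$terms, final_fit$intercept,
      population = sprintf("whole cohort, n = %d", final_fit$n))

    stage <- "diagnosis"
    report$diagnosis <- diagnostic_report(cohort, report$final_equation,
                                          rule)$summary

    report$provenance <- list(
      seed = config$seed,
      n = nrow(cohort), n_development = nrow(dev),
      n_cross_validation = nrow(holdout),
      candidates = candidates,
      alpha_enter = alpha_enter, alpha_remove = alpha_remove,
      direction = direction,
      package_version = as.character(utils::packageVersion("leanmass")))
    class(report) <- "alm_pipeline_report"
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.alm_pipeline_report <- function(x, ...) {
  cat("== leanmass pipeline report (seed ", x$provenance$seed, ") ==\n",
      "cohort: n = ", x$provenance$n, " (",
      x$provenance$n_development, " development / ",
      x$provenance$n_cross_validation, " cross-validation)\n\n", sep = "")
  if (!is.null(x$scan)) { print(x$scan); cat("\n") }
  cat("-- stepwise development fit --\n"); print(x$development); cat("\n")
  cat("-- holdout validation --\n"); print(x$validation); cat("\n")
  cat("-- final refit on all subjects --\n"); print(x$final_fit); cat("\n")
  cat("-- sarcopenia diagnostic agreement (final refit vs DXA) --\n")
  print(x$diagnosis)
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Every number shown by the printed summary is also present in the JSON
#' payload; timestamps are deliberately excluded so identical runs produce
#' identical files.
#'
#' @param report an `alm_pipeline_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "alm_pipeline_report"))
  strip <- function(x) {
    if (inherits(x, "alm_fit"))
      x <- x[c("terms", "intercept", "r", "r2", "adj_r2", "see",
               "p_values", "std_errors", "vif", "n", "p", "degenerate")]
    if (inherits(x, "alm_equation")) x <- unclass(x)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  payload <- strip(unclass(report))
  payload$scan_best_r2 <- attr(report$scan, "best_r2")
  payload$scan_best_see <- attr(report$scan, "best_see")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}
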