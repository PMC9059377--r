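## Accuracy / agreement battery for comparing BIA-predicted ALM against the
## DXA reference: SEE, TE, CV, PIA, subjective rating bands, paired t,
## line-of-best-fit, Bland-Altman.

#' Standard error of estimate
#'
#' Root residual sum of squares with denominator n - p - 1, where p is the
#' number of predictor variables of the equation that produced the
#' predictions. The group-level accuracy statistic of equation development.
#'
#' @param measured,predicted ALM vectors in kg, equal length.
#' @param p number of predictor variables.
#' @return SEE in kg.
#' @export
#' @examples
#' compute_see(c(10, 12, 14, 16), c(11, 11, 15, 15), p = 1)
compute_see <- function(measured, predicted, p) {
  check_paired(measured, predicted)
  n <- length(measured)
  if (n <= p + 1)
    stop("SEE needs n > p + 1 (n = ", n, ", p = ", p, ")", call. = FALSE)
  sqrt(sum((measured - predicted)^2) / (n - p - 1))
}

#' Total error
#'
#' Root mean squared difference between measured and predicted ALM,
#' denominator n — the holdout / cross-validation error statistic. Always
#' <= the SEE of the same residuals.
#'
#' @inheritParams compute_see
#' @return TE in kg.
#' @export
compute_te <- function(measured, predicted) {
  check_paired(measured, predicted)
  if (!length(measured)) stop("need at least one pair", call. = FALSE)
  sqrt(mean((measured - predicted)^2))
}

#' Coefficient of variation of a prediction error
#'
#' The error statistic (SEE in a development context, TE in a
#' cross-validation context) as a percentage of mean measured ALM.
#'
#' @param error_stat SEE or TE in kg.
#' @param mean_measured mean measured ALM in kg; positive.
#' @return CV in percent.
#' @export
#' @examples
#' compute_cv(0.97, 17.28)  # -> 5.6 % to 1 dp
compute_cv <- function(error_stat, mean_measured) {
  if (!is.numeric(mean_measured) || mean_measured <= 0)
    stop("'mean_measured' must be positive", call. = FALSE)
  if (error_stat < 0) stop("'error_stat' must be >= 0", call. = FALSE)
  100 * error_stat / mean_measured
}

#' Percentage of individual agreement (PIA)
#'
#' Share of subjects whose absolute prediction error falls within a
#' sex-specific threshold (boundary counts as within). The default
#' thresholds are the upper bounds of the "good" subjective-rating band:
#' 1.45 kg for men, 1.16 kg for women.
#'
#' @param sex vector of sex codes (1/0 or M/F).
#' @param measured,predicted ALM vectors in kg.
#' @param threshold_m,threshold_f absolute-error thresholds in kg.
#' @return PIA in percent (0-100).
#' @export
compute_pia <- function(sex, measured, predicted,
                        threshold_m = 1.45, threshold_f = 1.16) {
  check_paired(measured, predicted)
  if (length(sex) != length(measured))
    stop("'sex' length differs from the ALM vectors", call. = FALSE)
  if (threshold_m <= 0 || threshold_f <= 0)
    stop("thresholds must be positive", call. = FALSE)
  sex <- normalise_sex(sex)
  thr <- ifelse(sex == 1, threshold_m, threshold_f)
  100 * mean(abs(measured - predicted) <= thr)
}

#' Subjective rating bands for SEE/TE
#'
#' Sex-specific ordinal quality bands applied to a group error statistic
#' (kg). Defaults: men ideal [0.72, 0.90), excellent [0.90, 1.09),
#' very good [1.09, 1.27), good [1.27, 1.45); women ideal [0.54, 0.65),
#' excellent [0.65, 0.83), very good [0.83, 1.01), good [1.01, 1.16).
#' Intervals are half-open with the lower band winning at shared
#' endpoints; errors below the ideal band are rated ideal and errors at or
#' above the good band's upper bound are rated `"below-good"` (the finer
#' fairly good / fair / poor bounds are not specified by the source
#' criteria).
#'
#' @return List with elements `M` and `F`, each a numeric vector of five
#'   ascending breakpoints delimiting ideal/excellent/very good/good.
#' @export
rating_bands <- function() {
  list(M = c(0.72, 0.90, 1.09, 1.27, 1.45),
       F = c(0.54, 0.65, 0.83, 1.01, 1.16))
}

rating_labels <- c("ideal", "excellent", "very good", "good", "below-good")

#' Subjective rating of an error statistic
#'
#' @param error_stat SEE or TE in kg; >= 0.
#' @param sex `"M"` or `"F"`.
#' @param bands breakpoints as returned by [rating_bands()].
#' @return Band label: one of ideal, excellent, very good, good,
#'   below-good.
#' @export
#' @examples
#' subjective_rating(0.97, "M")  # excellent
#' subjective_rating(0.97, "F")  # very good
subjective_rating <- function(error_stat, sex = c("M", "F"),
                              bands = rating_bands()) {
  sex <- match.arg(sex)
  if (error_stat < 0) stop("'error_stat' must be >= 0", call. = FALSE)
  br <- bands[[sex]]
  ## half-open [lo, hi); below the first break maps to ideal
  idx <- findInterval(error_stat, br[-1]) + 1L
  rating_labels[min(idx, length(rating_labels))]
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference), 95% limits of agreement (bias +/- 1.96 SD of
#' the differences, sample SD), and the correlation between the
#' per-subject differences and means (a proportional-bias screen).
#' The difference direction is explicit in every result because both
#' conventions are in common use.
#'
#' @param measured,predicted ALM vectors in kg; n >= 3.
#' @param direction `"measured-minus-predicted"` (default) or
#'   `"predicted-minus-measured"`.
#' @return List: `bias`, `sd_diff`, `loa_low`, `loa_high` (kg),
#'   `r_diff_mean` (NA with `degenerate = TRUE` when the differences have
#'   zero variance), `direction`, `n`.
#' @export
bland_altman <- function(measured, predicted,
                         direction = c("measured-minus-predicted",
                                       "predicted-minus-measured")) {
  direction <- match.arg(direction)
  check_paired(measured, predicted)
  n <- length(measured)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- if (direction == "measured-minus-predicted") measured - predicted
       else predicted - measured
  m <- (measured + predicted) / 2
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0 || stats::sd(m) == 0
  list(bias = mean(d), sd_diff = sd_d,
       loa_low = mean(d) - 1.96 * sd_d,
       loa_high = mean(d) + 1.96 * sd_d,
       r_diff_mean = if (degenerate) NA_real_ else stats::cor(d, m),
       degenerate = degenerate,
       direction = direction, n = n)
}

#' Paired t-test between measured and predicted ALM
#'
#' Two-sided paired t-test on the differences. Zero-variance differences
#' (including identical vectors) are returned flagged degenerate rather
#' than as an error so batch reports never abort.
#'
#' @param measured,predicted ALM vectors in kg; n >= 2.
#' @return List: `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(measured, predicted) {
  check_paired(measured, predicted)
  n <- length(measured)
  if (n < 2) stop("paired t needs n >= 2", call. = FALSE)
  d <- measured - predicted
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  ht <- stats::t.test(measured, predicted, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Line of best fit between measured and predicted ALM
#'
#' Bivariate calibration regression. The default regresses measured on
#' predicted ALM, for which an unbiased prediction gives slope 1 and an
#' intercept not significantly different from zero (the reverse
#' regression, predicted on measured, has expected slope equal to the
#' shared R-squared by attenuation, so it is not the calibration check;
#' it remains available via `response = "predicted"`).
#'
#' @param measured,predicted ALM vectors in kg; n >= 3 with variance in
#'   the regressor.
#' @param response which variable is regressed on the other.
#' @return List: `slope`, `intercept`, `intercept_p` (two-sided t-test of
#'   intercept = 0), `slope_p`, `r2`, `response`.
#' @export
line_of_best_fit <- function(measured, predicted,
                             response = c("measured", "predicted")) {
  response <- match.arg(response)
  check_paired(measured, predicted)
  if (length(measured) < 3) stop("need n >= 3", call. = FALSE)
  y <- if (response == "measured") measured else predicted
  x <- if (response == "measured") predicted else measured
  if (stats::sd(x) == 0)
    stop("regressor values have zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ## noiseless case handled explicitly below; silence summary.lm's
  ## "essentially perfect fit" chatter
  sm <- suppressWarnings(summary(fit))
  noiseless <- sm$sigma < 1e-10  # exact line: t-tests meaningless
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       intercept_p = if (noiseless) NA_real_
                     else sm$coefficients[1, "Pr(>|t|)"],
       slope_p = if (noiseless) NA_real_ else sm$coefficients[2, "Pr(>|t|)"],
       r2 = sm$r.squared, response = response)
}

#' Full validation report for a prediction equation on a cohort
#'
#' Runs the whole agreement battery of the method-comparison workflow:
#' summary moments, squared Pearson correlation between measured and
#' predicted ALM, SEE, TE, CV, PIA, per-sex subjective ratings,
#' Bland-Altman bias and limits of agreement, the difference-vs-mean
#' correlation, a paired t-test, and the line of best fit.
#'
#' @param cohort a `bia_cohort` with `alm_dxa_kg` for every subject.
#' @param equation an `alm_equation` (or registry name via `registry`).
#' @param direction Bland-Altman difference direction; see
#'   [bland_altman()].
#' @param context `"cross-validation"` (CV uses TE) or `"development"`
#'   (CV uses SEE).
#' @return A `validation_report` list; see the field list in
#'   [bland_altman()], [compute_see()] etc.
#' @export
validate_equation <- function(cohort, equation,
                              direction = c("measured-minus-predicted",
                                            "predicted-minus-measured"),
                              context = c("cross-validation",
                                          "development")) {
  direction <- match.arg(direction)
  context <- match.arg(context)
  stopifnot(inherits(equation, "alm_equation"), is.data.frame(cohort))
  if (is.null(cohort$alm_dxa_kg) || anyNA(cohort$alm_dxa_kg))
    stop("validation needs DXA ALM for every subject", call. = FALSE)

  measured <- cohort$alm_dxa_kg
  pred <- predict_cohort(equation, cohort)$predicted
  p <- length(equation$terms)
  see <- compute_see(measured, pred, p)
  te <- compute_te(measured, pred)
  err <- if (context == "development") see else te
  ba <- bland_altman(measured, pred, direction)
  tt <- paired_t(measured, pred)
  lbf <- line_of_best_fit(measured, pred)

  structure(list(
    equation = equation$name, n = length(measured), context = context,
    mean_measured = mean(measured), sd_measured = stats::sd(measured),
    mean_predicted = mean(pred), sd_predicted = stats::sd(pred),
    r2 = stats::cor(measured, pred)^2,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    r_diff_mean = ba$r_diff_mean, direction = direction,
    see = see, te = te,
    cv = compute_cv(err, mean(measured)),
    pia = compute_pia(cohort$sex, measured, pred),
    rating_m = subjective_rating(err, "M"),
    rating_f = subjective_rating(err, "F"),
    paired_t = tt$t, paired_t_p = tt$p,
    slope = lbf$slope, intercept = lbf$intercept,
    intercept_p = lbf$intercept_p),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  f <- function(v, d = 2) formatC(v, digits = d, format = "f")
  cat("<validation_report> equation '", x$equation, "', n = ", x$n,
      " (", x$context, ")\n",
      "  measured  ALM: ", f(x$mean_measured), " +/- ", f(x$sd_measured),
      " kg\n",
      "  predicted ALM: ", f(x$mean_predicted), " +/- ", f(x$sd_predicted),
      " kg (paired t p = ", f(x$paired_t_p, 3), ")\n",
      "  R^2 = ", f(x$r2, 3), ", SEE = ", f(x$see), " kg, TE = ", f(x$te),
      " kg, CV = ", f(x$cv, 1), "%\n",
      "  bias (", x$direction, ") = ", f(x$bias), " kg, LoA [",
      f(x$loa_low), ", ", f(x$loa_high), "], r(diff, mean) = ",
      f(x$r_diff_mean, 3), "\n",
      "  PIA = ", f(x$pia, 1), "%, rating: ", x$rating_m, " (M) / ",
      x$rating_f, " (F)\n",
      "  best fit: measured = ", f(x$slope, 3), " * predicted + ",
      f(x$intercept, 3), " (intercept p = ", f(x$intercept_p, 3), ")\n",
      sep = "")
  invisible(x)
}

check_paired <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("'measured' and 'predicted' differ in length", call. = FALSE)
  if (anyNA(measured) || anyNA(predicted))
    stop("missing values in measured/predicted ALM", call. = FALSE)
  invisible()
}
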