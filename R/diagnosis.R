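#' AWGS sarcopenia cutoff rule
#'
#' Asian Working Group for Sarcopenia thresholds on the appendicular
#' skeletal muscle mass index: sarcopenic when ASMI is strictly below
#' 7.0 kg/m^2 for men or 5.4 kg/m^2 for women.
#'
#' @param male_cutoff,female_cutoff ASMI cutoffs in kg/m^2.
#' @return A `cutoff_rule` list.
#' @export
awgs_cutoff <- function(male_cutoff = 7.0, female_cutoff = 5.4) {
  if (male_cutoff <= 0 || female_cutoff <= 0)
    stop("cutoffs must be positive", call. = FALSE)
  structure(list(male_cutoff = male_cutoff, female_cutoff = female_cutoff,
                 comparison = "strictly-less-than"),
            class = "cutoff_rule")
}

#' Classify sarcopenia from ASMI
#'
#' @param asmi ASMI in kg/m^2; positive. Vectorised.
#' @param sex sex codes (1/0 or M/F), recycled against `asmi`.
#' @param rule a [awgs_cutoff()] rule.
#' @return Logical vector: `TRUE` = sarcopenic (ASMI strictly below the
#'   sex-specific cutoff).
#' @export
#' @examples
#' classify_sarcopenia(7.0, "M")          # FALSE: boundary is non-sarcopenic
#' classify_sarcopenia(compute_asmi(12, 153), "F")
classify_sarcopenia <- function(asmi, sex, rule = awgs_cutoff()) {
  if (any(!is.finite(asmi)) || any(asmi <= 0))
    stop("'asmi' must be positive and finite", call. = FALSE)
  sex <- normalise_sex(sex)
  cut <- ifelse(sex == 1, rule$male_cutoff, rule$female_cutoff)
  asmi < cut
}

#' Confusion summary for a binary diagnostic comparison
#'
#' Counts the 2x2 table with the DXA-derived classification as reference
#' and the BIA-derived classification as test, positive = sarcopenic, and
#' derives overall agreement, Cohen's kappa with its ordinal band, and
#' sensitivity / specificity / PPV / NPV as percents. Rates whose
#' denominator is zero are `NA`.
#'
#' @param reference logical vector (DXA: `TRUE` = sarcopenic).
#' @param test logical vector (BIA), same length.
#' @return A `confusion_summary` list: `tp`, `fp`, `fn`, `tn`,
#'   `agreement`, `kappa`, `kappa_band`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `n`.
#' @export
confusion_from_labels <- function(reference, test) {
  if (length(reference) != length(test))
    stop("'reference' and 'test' differ in length", call. = FALSE)
  reference <- as.logical(reference); test <- as.logical(test)
  if (anyNA(reference) || anyNA(test))
    stop("labels must be non-missing", call. = FALSE)
  tp <- sum(reference & test);  fp <- sum(!reference & test)
  fn <- sum(reference & !test); tn <- sum(!reference & !test)
  confusion_summary(tp, fp, fn, tn)
}

#' @rdname confusion_from_labels
#' @param tp,fp,fn,tn cell counts (reference in columns of the usual
#'   layout: tp = both sarcopenic, tn = both non-sarcopenic).
#' @export
confusion_summary <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty table", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  k <- cohens_kappa(tp, fp, fn, tn)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    agreement = 100 * (tp + tn) / n,
    kappa = k$kappa, kappa_band = k$band,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn)), class = "confusion_summary")
}

#' Cohen's kappa for a 2x2 diagnostic table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with
#' expected agreement p_e from the row/column marginals. Banded on the
#' conventional ordinal scale (poor < 0, slight, fair, moderate,
#' substantial, almost perfect > 0.80); the boundary values 0.00, 0.20,
#' 0.40, 0.60, 0.80 are assigned to the lower band. Degenerate marginals
#' (p_e = 1) yield `NA` with band `"undefined"`.
#'
#' @inheritParams confusion_summary
#' @return List: `kappa`, `band`.
#' @export
#' @examples
#' cohens_kappa(20, 2, 8, 165)
cohens_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty table", call. = FALSE)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  if (abs(1 - pe) < 1e-12)
    return(list(kappa = NA_real_, band = "undefined"))
  k <- (po - pe) / (1 - pe)
  eps <- 1e-9  # boundary values belong to the lower band despite fp noise
  band <- if (k < 0) "poor"
          else if (k <= 0.20 + eps) "slight"
          else if (k <= 0.40 + eps) "fair"
          else if (k <= 0.60 + eps) "moderate"
          else if (k <= 0.80 + eps) "substantial"
          else "almost perfect"
  list(kappa = k, band = band)
}

#' @export
print.confusion_summary <- function(x, ...) {
  f <- function(v) if (is.na(v)) "undefined" else
    paste0(formatC(v, digits = 1, format = "f"), "%")
  cat("<confusion_summary> n = ", x$n,
      " (reference = DXA, positive = sarcopenic)\n",
      "  tp = ", x$tp, ", fp = ", x$fp, ", fn = ", x$fn, ", tn = ", x$tn,
      "\n  agreement = ", f(x$agreement), ", kappa = ",
      formatC(x$kappa, digits = 3, format = "f"), " (", x$kappa_band, ")\n",
      "  sensitivity = ", f(x$sensitivity), ", specificity = ",
      f(x$specificity), ", PPV = ", f(x$ppv), ", NPV = ", f(x$npv), "\n",
      sep = "")
  invisible(x)
}

#' Diagnostic agreement between a BIA equation and the DXA reference
#'
#' Classifies every subject twice — once from DXA-measured ALM and once
#' from equation-predicted ALM, both via ASMI and the AWGS cutoffs — and
#' summarises the agreement.
#'
#' @param cohort a `bia_cohort` with `alm_dxa_kg` throughout.
#' @param equation an `alm_equation`.
#' @param rule a [awgs_cutoff()] rule.
#' @return List: `summary` (a `confusion_summary`) and `subjects`
#'   (data.frame of per-subject ASMI and classifications).
#' @export
diagnostic_report <- function(cohort, equation, rule = awgs_cutoff()) {
  stopifnot(is.data.frame(cohort), inherits(equation, "alm_equation"))
  if (is.null(cohort$alm_dxa_kg) || anyNA(cohort$alm_dxa_kg))
    stop("diagnosis needs DXA ALM for every subject", call. = FALSE)
  pred <- predict_cohort(equation, cohort)$predicted
  if (any(pred <= 0))
    stop("non-positive predicted ALM for subject(s) ",
         paste(utils::head(cohort$id[pred <= 0], 5), collapse = ", "),
         call. = FALSE)
  asmi_dxa <- compute_asmi(cohort$alm_dxa_kg, cohort$height_cm)
  asmi_bia <- compute_asmi(pred, cohort$height_cm)
  ref <- classify_sarcopenia(asmi_dxa, cohort$sex, rule)
  test <- classify_sarcopenia(asmi_bia, cohort$sex, rule)
  list(summary = confusion_from_labels(ref, test),
       subjects = data.frame(id = cohort$id, sex = cohort$sex,
                             asmi_dxa = asmi_dxa, asmi_bia = asmi_bia,
                             sarcopenic_dxa = ref, sarcopenic_bia = test,
                             stringsAsFactors = FALSE))
}
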