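#' ALM prediction equations
#'
#' A prediction equation is an affine map from named predictors to ALM in
#' kg: `intercept + sum(coefficient * predictor)`. Predictor names use the
#' vocabulary of [predictor_values()] (`ZI@2MHz`, `Xc@5kHz`, `sex`, ...).
#' Provenance fields (`population`, `posture`, `citation`) are metadata
#' only and never enter the computation.
#'
#' @param name unique label for the equation.
#' @param terms named numeric vector or list: predictor name -> coefficient.
#' @param intercept intercept in kg.
#' @param population free-text provenance of the development sample.
#' @param posture measurement posture: `"supine"`, `"standing"` or
#'   `"unspecified"`.
#' @param citation free-text citation.
#' @return An `alm_equation` object.
#' @export
#' @examples
#' eq <- alm_equation("demo", c("ZI@50kHz" = 0.3, sex = 1.1), 2.0)
#' eq
alm_equation <- function(name, terms, intercept,
                         population = "unspecified",
                         posture = c("unspecified", "supine", "standing"),
                         citation = "") {
  posture <- match.arg(posture)
  terms <- unlist(terms)
  if (!length(terms)) stop("an equation needs at least one term", call. = FALSE)
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("every term needs a predictor name", call. = FALSE)
  if (anyDuplicated(names(terms)))
    stop("duplicate predictor names in equation '", name, "'", call. = FALSE)
  if (!is.numeric(terms) || anyNA(terms))
    stop("coefficients must be numeric and non-missing", call. = FALSE)
  structure(list(name = as.character(name), terms = terms,
                 intercept = as.numeric(intercept),
                 population = population, posture = posture,
                 citation = citation),
            class = "alm_equation")
}

#' @export
print.alm_equation <- function(x, ...) {
  rhs <- paste(sprintf("%g*%s", x$terms, names(x$terms)), collapse = " + ")
  cat("<alm_equation> ", x$name, "\n  ALM = ", rhs, " + ", x$intercept,
      "  [kg]\n", sep = "")
  if (nzchar(x$population) && x$population != "unspecified")
    cat("  population: ", x$population, "\n", sep = "")
  invisible(x)
}

#' Built-in prediction equations
#'
#' `equation_final()` is the 2 MHz muscle-specific equation fitted on the
#' full cohort of 195 Korean older adults:
#' ALM = 0.247 ZI@2MHz + 1.254 sex + 0.067 Xc@5kHz + 1.739.
#' `equation_development()` is the companion equation fitted on the 2/3
#' development split (n = 131):
#' ALM = 0.254 ZI@2MHz + 1.0324 sex + 0.066 Xc@5kHz + 1.396.
#' Sex is coded 1 for men, 0 for women in both.
#'
#' @return An `alm_equation`.
#' @export
equation_final <- function() {
  alm_equation("final",
               c("ZI@2MHz" = 0.247, "sex" = 1.254, "Xc@5kHz" = 0.067),
               intercept = 1.739,
               population = "Korean community-dwelling adults aged 70-92, n = 195",
               posture = "supine")
}

#' @rdname equation_final
#' @export
equation_development <- function() {
  alm_equation("development",
               c("ZI@2MHz" = 0.254, "sex" = 1.0324, "Xc@5kHz" = 0.066),
               intercept = 1.396,
               population = "Korean community-dwelling adults aged 70-92, development split n = 131",
               posture = "supine")
}

#' Predict ALM for one covariate vector
#'
#' Evaluates the affine equation at explicitly supplied predictor values.
#' For whole cohorts use [predict_cohort()], which resolves predictors from
#' the cohort's channels.
#'
#' @param equation an `alm_equation`.
#' @param values named numeric vector supplying every predictor the
#'   equation uses.
#' @return Predicted ALM in kg.
#' @export
#' @examples
#' predict_alm(equation_final(), c("ZI@2MHz" = 67.3, sex = 1, "Xc@5kHz" = 13.6))
predict_alm <- function(equation, values) {
  stopifnot(inherits(equation, "alm_equation"))
  values <- unlist(values)
  need <- setdiff(names(equation$terms), names(values))
  if (length(need))
    stop("missing predictor value(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  as.numeric(equation$intercept +
               sum(equation$terms * values[names(equation$terms)]))
}

#' Predict ALM over a cohort
#'
#' Applies a prediction equation to every subject, resolving each predictor
#' from the cohort's anthropometry and impedance channels. A missing
#' channel fails loudly with the predictor and column name. Because the
#' equation is affine, the mean of the per-subject predictions equals the
#' prediction at the cohort's covariate means, exactly.
#'
#' @param equation an `alm_equation`.
#' @param cohort a `bia_cohort`.
#' @return List with `predicted` (kg, one per subject), `mean`, and `sd`
#'   (sample SD, n-1 denominator; `NA` with a flag for a single subject).
#' @export
predict_cohort <- function(equation, cohort) {
  stopifnot(inherits(equation, "alm_equation"), is.data.frame(cohort))
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  X <- predictor_matrix(cohort, names(equation$terms))
  pred <- as.numeric(equation$intercept + X %*% equation$terms)
  if (any(pred <= 0))
    warning(sum(pred <= 0), " non-positive ALM prediction(s); reported raw,",
            " not clipped", call. = FALSE)
  list(predicted = pred,
       mean = mean(pred),
       sd = if (length(pred) > 1) stats::sd(pred) else NA_real_,
       single_subject = length(pred) == 1L)
}

#' Load an equation registry
#'
#' Reads user-supplied prediction equations from a YAML or JSON document
#' and merges them with the built-ins (`final`, `development`). Each entry
#' needs `name`, `intercept` and a `terms` map; `population`, `posture`
#' and `citation` are optional provenance. Redefining an existing name is
#' an error.
#'
#' @param path path to a YAML/JSON file, or `NULL` for built-ins only.
#' @param text document text, as an alternative to `path`.
#' @return Named list of `alm_equation` objects.
#' @export
load_equation_registry <- function(path = NULL, text = NULL) {
  registry <- list(final = equation_final(),
                   development = equation_development())
  doc <- NULL
  if (!is.null(text)) {
    doc <- yaml::yaml.load(text)
  } else if (!is.null(path)) {
    doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
  }
  if (is.null(doc)) return(registry)
  if (!is.list(doc)) stop("registry document must be a list of entries",
                          call. = FALSE)
  for (entry in doc) {
    nm <- entry$name
    if (is.null(nm) || is.null(entry$intercept) || is.null(entry$terms) ||
        !length(entry$terms))
      stop("malformed registry entry",
           if (!is.null(nm)) paste0(" '", nm, "'"),
           ": need name, intercept and a non-empty terms map", call. = FALSE)
    if (nm %in% names(registry))
      stop("registry entry '", nm, "' collides with an existing equation",
           call. = FALSE)
    registry[[nm]] <- alm_equation(
      nm, unlist(entry$terms), entry$intercept,
      population = entry$population %||% "unspecified",
      posture = entry$posture %||% "unspecified",
      citation = entry$citation %||% "")
  }
  registry
}

`%||%` <- function(a, b) if (is.null(a)) b else a
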