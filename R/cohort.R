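## Cohort container: one data.frame row per subject.
## Required columns: id, sex (1 = man, 0 = woman), age, height_cm, weight_kg.
## Optional: alm_dxa_kg (DXA reference), and per-frequency channels
## z_<f>, r_<f>, xc_<f> with f in {1khz,...,3mhz}; NA = channel not measured.

cohort_channel_columns <- function() {
  sfx <- freq_suffix(names(bia_frequencies()))
  c(paste0("z_", sfx), paste0("r_", sfx), paste0("xc_", sfx))
}

cohort_required_columns <- function() {
  c("id", "sex", "age", "height_cm", "weight_kg")
}

#' Construct a BIA cohort
#'
#' Validates and classes a subject-level data frame. Subjects carry sex
#' (1 = man, 0 = woman), anthropometry, optionally a DXA-measured ALM
#' reference, and any subset of per-frequency impedance channels; missing
#' channels stay `NA` and downstream operations that need them fail with
#' the channel name rather than imputing.
#'
#' @param data data.frame with at least `id`, `sex`, `age`, `height_cm`,
#'   `weight_kg`; `sex` may be coded `M`/`F` or `1`/`0`. Channel columns
#'   `z_*`, `r_*`, `xc_*` use the frequency suffixes `1khz`, `5khz`,
#'   `50khz`, `250khz`, `500khz`, `1mhz`, `2mhz`, `3mhz`.
#' @param check_spectrum warn when Z, R and Xc are all present at a
#'   frequency but violate Z^2 = R^2 + Xc^2 beyond 1% relative error.
#' @return The validated data.frame with class `bia_cohort`.
#' @export
bia_cohort <- function(data, check_spectrum = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_columns(), names(data))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  data$sex <- normalise_sex(data$sex)
  for (col in c("age", "height_cm", "weight_kg", "alm_dxa_kg",
                cohort_channel_columns())) {
    if (!is.null(data[[col]])) data[[col]] <- as.numeric(data[[col]])
  }

  check_positive <- function(col, allow_na = FALSE) {
    v <- data[[col]]
    if (is.null(v)) return(invisible())
    bad <- which(if (allow_na) !is.na(v) & v <= 0 else (is.na(v) | v <= 0))
    if (length(bad))
      stop("non-positive ", col, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(data)) {
    check_positive("height_cm")
    check_positive("weight_kg")
    check_positive("alm_dxa_kg", allow_na = TRUE)
    for (col in intersect(cohort_channel_columns(), names(data)))
      check_positive(col, allow_na = TRUE)
  }

  if (check_spectrum && nrow(data)) {
    bad <- spectrum_inconsistencies(data)
    if (nrow(bad))
      warning(nrow(bad), " spectrum entr",
              if (nrow(bad) == 1) "y" else "ies",
              " violate Z^2 = R^2 + Xc^2 beyond 1% (first at row ",
              bad$row[1], ", ", bad$frequency[1], ")", call. = FALSE)
  }

  class(data) <- c("bia_cohort", "data.frame")
  data
}

normalise_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1)))
      stop("numeric sex codes must be 1 (man) or 0 (woman)", call. = FALSE)
    return(as.numeric(sex))
  }
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("M", "MALE", "1"), 1,
                ifelse(s %in% c("F", "FEMALE", "0"), 0, NA_real_))
  if (any(is.na(out) & !is.na(s)))
    stop("unrecognised sex code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' @export
print.bia_cohort <- function(x, ...) {
  n <- nrow(x)
  cat("<bia_cohort> ", n, " subject", if (n != 1) "s", " (",
      sum(x$sex == 1), " men, ", sum(x$sex == 0), " women)\n", sep = "")
  have <- intersect(cohort_channel_columns(), names(x))
  measured <- have[vapply(have, function(c) any(!is.na(x[[c]])), logical(1))]
  cat("  channels: ", if (length(measured)) paste(measured, collapse = " ")
      else "none", "\n", sep = "")
  cat("  DXA ALM: ",
      if (!is.null(x$alm_dxa_kg)) paste0(sum(!is.na(x$alm_dxa_kg)), "/", n)
      else "absent", "\n", sep = "")
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' `read_cohort()` loads the documented subject-level schema and validates
#' it; `write_cohort()` writes it back so that a read/write round trip
#' reproduces all values to full precision. Unknown columns are preserved
#' untouched.
#'
#' @param path CSV file path.
#' @param check_spectrum passed to [bia_cohort()].
#' @return `read_cohort()`: a `bia_cohort`; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, check_spectrum = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bia_cohort(raw, check_spectrum = check_spectrum)
}

#' @rdname read_cohort
#' @param cohort a `bia_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "bia_cohort"))
  df <- as.data.frame(cohort)
  ## full-precision text so round trips are exact
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 17,
                                                   trim = TRUE,
                                                   scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a named predictor on a cohort
#'
#' Resolves the predictor vocabulary used by prediction equations and the
#' development engine: `ZI@<f>` / `RI@<f>` (impedance / resistance index at
#' a grid frequency), `Xc@<f>` (reactance), `sex`, `weight`, `height`,
#' `age`, `BMI`.
#'
#' @param cohort a `bia_cohort`.
#' @param name predictor name, e.g. `"ZI@2MHz"`, `"Xc@5kHz"`, `"sex"`.
#' @return Numeric vector, one value per subject.
#' @export
predictor_values <- function(cohort, name) {
  stopifnot(is.data.frame(cohort), length(name) == 1L)
  if (grepl("@", name, fixed = TRUE)) {
    parts <- strsplit(name, "@", fixed = TRUE)[[1]]
    kind <- toupper(parts[1]); lab <- match_frequency(parts[2])
    sfx <- freq_suffix(lab)
    col <- switch(kind,
                  ZI = paste0("z_", sfx),
                  RI = paste0("r_", sfx),
                  XC = paste0("xc_", sfx),
                  stop("unknown predictor kind '", parts[1], "' in '", name,
                       "'", call. = FALSE))
    v <- cohort[[col]]
    if (is.null(v) || all(is.na(v)))
      stop("predictor '", name, "' needs channel column '", col,
           "', which is not measured in this cohort", call. = FALSE)
    if (anyNA(v))
      stop("predictor '", name, "' is missing for subject(s) ",
           paste(utils::head(cohort$id[is.na(v)], 5), collapse = ", "),
           call. = FALSE)
    if (kind %in% c("ZI", "RI"))
      return(as.numeric(compute_index(cohort$height_cm, v, kind)))
    return(v)
  }
  switch(name,
         sex = cohort$sex,
         weight = cohort$weight_kg,
         height = cohort$height_cm,
         age = cohort$age,
         BMI = cohort$weight_kg / (cohort$height_cm / 100)^2,
         stop("unknown predictor '", name, "'", call. = FALSE))
}

#' @rdname predictor_values
#' @param names character vector of predictor names; the returned matrix
#'   keeps them in declaration order (the stepwise tie-break order).
#' @export
predictor_matrix <- function(cohort, names) {
  cols <- lapply(names, function(nm) predictor_values(cohort, nm))
  m <- do.call(cbind, cols)
  colnames(m) <- names
  m
}
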