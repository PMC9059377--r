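#' @keywords internal
"_PACKAGE"

## Fixed measurement grid of the multifrequency device: 1 kHz - 3 MHz.
## Frequencies outside this grid are rejected at parse time so the
## frequency-scan axis is always well defined.

#' Supported measurement frequencies
#'
#' The fixed eight-point frequency grid at which multifrequency
#' bioimpedance devices of the class supported here report impedance
#' magnitude (Z), resistance (R) and reactance (Xc).
#'
#' @return Named numeric vector of frequencies in Hz; names are the
#'   human-readable labels used throughout the package
#'   (`"1kHz"` ... `"3MHz"`).
#' @export
#' @examples
#' bia_frequencies()
bia_frequencies <- function() {
  c("1kHz" = 1e3, "5kHz" = 5e3, "50kHz" = 5e4, "250kHz" = 2.5e5,
    "500kHz" = 5e5, "1MHz" = 1e6, "2MHz" = 2e6, "3MHz" = 3e6)
}

## lower-case CSV column suffix for a frequency label, e.g. "2MHz" -> "2mhz"
freq_suffix <- function(label) tolower(label)

#' Normalise a frequency specification to a grid label
#'
#' Accepts a grid label (`"2MHz"`, case-insensitive) or a numeric frequency
#' in Hz and returns the canonical label. Frequencies off the grid are an
#' error: the device grid is fixed.
#'
#' @param frequency label or numeric Hz.
#' @return Canonical label, e.g. `"50kHz"`.
#' @export
match_frequency <- function(frequency) {
  grid <- bia_frequencies()
  if (is.numeric(frequency)) {
    hit <- which(abs(grid - frequency) <= 1e-6 * frequency)
    if (length(hit) != 1L)
      stop("frequency ", frequency, " Hz is not on the supported grid (",
           paste(names(grid), collapse = ", "), ")", call. = FALSE)
    return(names(grid)[hit])
  }
  hit <- match(tolower(as.character(frequency)), tolower(names(grid)))
  if (is.na(hit))
    stop("unknown frequency label '", frequency, "'; supported: ",
         paste(names(grid), collapse = ", "), call. = FALSE)
  names(grid)[hit]
}

#' Impedance and resistance indices
#'
#' The conductive-volume predictor of lean mass: squared height divided by
#' an impedance-type measurement at one frequency. With height in cm and
#' the measurement in ohm the index has units cm^2/ohm. `kind` records
#' whether the denominator was an impedance magnitude (`"ZI"`) or a pure
#' resistance (`"RI"`); it labels the result and does not change the
#' arithmetic.
#'
#' @param height_cm standing height in cm; must be positive.
#' @param measurement_ohm impedance magnitude Z or resistance R in ohm;
#'   must be positive. Vectorised.
#' @param kind `"ZI"` (impedance index) or `"RI"` (resistance index).
#' @return Numeric vector of index values (cm^2/ohm) with attributes
#'   `kind` and, when supplied, `frequency`.
#' @param frequency optional frequency label attached to the result.
#' @export
#' @examples
#' compute_index(166, 500)          # ~ men's 50 kHz impedance index
#' compute_index(153, 595, "RI")    # ~ women's 50 kHz resistance index
compute_index <- function(height_cm, measurement_ohm, kind = c("ZI", "RI"),
                          frequency = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(height_cm) || any(!is.finite(height_cm)) ||
      any(height_cm <= 0))
    stop("'height_cm' must be positive and finite", call. = FALSE)
  if (!is.numeric(measurement_ohm) || any(!is.finite(measurement_ohm)) ||
      any(measurement_ohm <= 0))
    stop("'measurement_ohm' must be positive and finite", call. = FALSE)
  out <- height_cm^2 / measurement_ohm
  attr(out, "kind") <- kind
  if (!is.null(frequency)) attr(out, "frequency") <- match_frequency(frequency)
  out
}

#' Appendicular skeletal muscle mass index (ASMI)
#'
#' ALM normalised by squared height in metres, the quantity to which the
#' AWGS sarcopenia cutoffs apply.
#'
#' @param alm_kg appendicular lean mass in kg; positive.
#' @param height_cm height in cm; positive. Vectorised.
#' @return ASMI in kg/m^2.
#' @export
#' @examples
#' compute_asmi(21.3, 168)
compute_asmi <- function(alm_kg, height_cm) {
  if (!is.numeric(alm_kg) || any(!is.finite(alm_kg)) || any(alm_kg <= 0))
    stop("'alm_kg' must be positive and finite", call. = FALSE)
  if (!is.numeric(height_cm) || any(!is.finite(height_cm)) ||
      any(height_cm <= 0))
    stop("'height_cm' must be positive and finite", call. = FALSE)
  alm_kg / (height_cm / 100)^2
}

## Check Z^2 = R^2 + Xc^2 wherever all three channels are present.
## Returns a data.frame of violations (possibly 0 rows).
spectrum_inconsistencies <- function(cohort, rel_tol = 1e-2) {
  out <- list()
  for (lab in names(bia_frequencies())) {
    sfx <- freq_suffix(lab)
    z <- cohort[[paste0("z_", sfx)]]
    r <- cohort[[paste0("r_", sfx)]]
    xc <- cohort[[paste0("xc_", sfx)]]
    if (is.null(z) || is.null(r) || is.null(xc)) next
    ok <- is.finite(z) & is.finite(r) & is.finite(xc)
    if (!any(ok)) next
    rel <- abs(z[ok]^2 - (r[ok]^2 + xc[ok]^2)) / z[ok]^2
    bad <- which(rel > rel_tol)
    if (length(bad))
      out[[lab]] <- data.frame(row = which(ok)[bad], frequency = lab,
                               rel_error = rel[bad])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(), frequency = character(),
               rel_error = numeric())
}
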