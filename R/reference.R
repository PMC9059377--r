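#' Published sex-stratified group covariate means
#'
#' The per-group means of the covariates used by the shipped prediction
#' equations (2 MHz impedance index and 5 kHz reactance), for the
#' development and cross-validation groups of the source cohort, together
#' with group sizes and measured-ALM moments. These are the inputs for
#' group-level consistency checks: because the equations are affine, the
#' equation evaluated at size-weighted pooled covariate means equals the
#' mean of per-subject predictions.
#'
#' @return data.frame with one row per sex-by-group cell: `group`,
#'   `sex` (1 = men), `n`, `zi_2mhz`, `xc_5khz`, `alm_mean`, `alm_sd`.
#' @export
#' @examples
#' pooled_mean_prediction(equation_final())
reference_group_means <- function() {
  data.frame(
    group = c("development", "development",
              "cross-validation", "cross-validation"),
    sex = c(1, 0, 1, 0),
    n = c(63, 68, 31, 33),
    zi_2mhz = c(67.3, 47.6, 70.1, 47.7),
    xc_5khz = c(13.6, 12.5, 13.8, 14.0),
    alm_mean = c(20.4, 14.3, 21.3, 14.4),
    alm_sd = c(2.2, 1.6, 2.1, 1.4),
    stringsAsFactors = FALSE)
}

#' Group-mean ALM prediction via pooled covariate means
#'
#' Pools the group covariate means of [reference_group_means()] with
#' size weights and evaluates an equation there — the group-level mean
#' prediction implied by linearity.
#'
#' @param equation an `alm_equation` over `ZI@2MHz`, `sex`, `Xc@5kHz`.
#' @param groups subset of `c("development", "cross-validation")`.
#' @return Predicted mean ALM in kg.
#' @export
pooled_mean_prediction <- function(equation,
                                   groups = c("development",
                                              "cross-validation")) {
  tab <- reference_group_means()
  tab <- tab[tab$group %in% groups, , drop = FALSE]
  w <- tab$n / sum(tab$n)
  predict_alm(equation,
              c("ZI@2MHz" = sum(w * tab$zi_2mhz),
                sex = sum(w * tab$sex),
                "Xc@5kHz" = sum(w * tab$xc_5khz)))
}
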