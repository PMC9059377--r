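#' Ordinary least-squares fit with equation-development statistics
#'
#' Wraps [stats::lm()] and returns the statistics the equation-development
#' workflow reports: coefficients, multiple correlation R, R^2, adjusted
#' R^2, standard error of estimate (residual SD, denominator n - p - 1),
#' two-sided t-based coefficient p-values, and variance-inflation factors
#' when the model has two or more predictors.
#'
#' @param response numeric response vector (ALM in kg).
#' @param predictors data.frame or matrix of named predictor columns.
#' @param degenerate `"error"` to fail on a rank-deficient design,
#'   `"flag"` to return a zero-slope intercept-only fit flagged
#'   `degenerate = TRUE` (used by the frequency scan so one bad channel
#'   never aborts a whole scan).
#' @return An `alm_fit`: list with `terms`, `intercept`, `r`, `r2`,
#'   `adj_r2`, `see`, `p_values`, `std_errors`, `vif`, `n`, `p`, `fitted`,
#'   `residuals`, `degenerate`.
#' @export
#' @examples
#' fit_ols(c(10, 12, 14, 16), data.frame(x = 1:4))
fit_ols <- function(response, predictors, degenerate = c("error", "flag")) {
  degenerate <- match.arg(degenerate)
  X <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(X)) || any(!nzchar(colnames(X))))
    stop("all predictor columns must be named", call. = FALSE)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("response and predictors differ in length",
                         call. = FALSE)
  if (n <= p + 1)
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")",
         call. = FALSE)

  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design) || stats::var(y) == 0) {
    dropped <- colnames(design)[qrd$pivot[seq_len(ncol(design)) > qrd$rank]]
    if (degenerate == "error")
      stop("singular design: linearly dependent column(s) ",
           paste(setdiff(dropped, "(Intercept)"), collapse = ", "),
           call. = FALSE)
    res <- y - mean(y)
    return(structure(list(
      terms = stats::setNames(rep(0, p), colnames(X)),
      intercept = mean(y), r = 0, r2 = 0, adj_r2 = 0,
      see = sqrt(sum(res^2) / (n - p - 1)),
      p_values = stats::setNames(rep(NA_real_, p), colnames(X)),
      std_errors = stats::setNames(rep(NA_real_, p), colnames(X)),
      vif = NULL, n = n, p = p,
      fitted = rep(mean(y), n), residuals = res,
      degenerate = TRUE), class = "alm_fit"))
  }

  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste0(
    ".y ~ ", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  ## exact linear relations (r2 = 1) are legitimate inputs here; silence
  ## summary.lm's "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  coefs <- stats::coef(fit)
  structure(list(
    terms = stats::setNames(coefs[-1], colnames(X)),
    intercept = unname(coefs[1]),
    r = sqrt(sm$r.squared), r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    see = sm$sigma,
    p_values = stats::setNames(sm$coefficients[-1, "Pr(>|t|)"], colnames(X)),
    std_errors = stats::setNames(sm$coefficients[-1, "Std. Error"],
                                 colnames(X)),
    vif = if (p >= 2) compute_vif(X) else NULL,
    n = n, p = p,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    degenerate = FALSE), class = "alm_fit")
}

#' @export
print.alm_fit <- function(x, digits = 4, ...) {
  rhs <- paste(sprintf("%.*g*%s", digits, x$terms, names(x$terms)),
               collapse = " + ")
  cat("<alm_fit> n = ", x$n, ", p = ", x$p,
      if (isTRUE(x$degenerate)) "  [degenerate: zero-slope fit]", "\n",
      "  fit: ", rhs, " + ", signif(x$intercept, digits), "\n",
      "  R = ", signif(x$r, digits), ", adj R^2 = ", signif(x$adj_r2, digits),
      ", SEE = ", signif(x$see, digits), " kg\n", sep = "")
  if (!is.null(x$vif))
    cat("  VIF: ", paste(sprintf("%s = %.3g", names(x$vif), x$vif),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Variance-inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing predictor j
#' on all the others (with intercept). Perfect collinearity yields `Inf`.
#'
#' @param predictors matrix or data.frame with at least two named columns.
#' @return Named numeric vector of VIFs (each >= 1, or `Inf`).
#' @export
#' @examples
#' compute_vif(cbind(a = c(1, 2, 3, 4), b = c(1, -1, 1, -1)))
compute_vif <- function(predictors) {
  X <- as.matrix(as.data.frame(predictors))
  storage.mode(X) <- "double"
  if (ncol(X) < 2) stop("VIF needs at least two predictors", call. = FALSE)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2j <- 1 - rss / tss
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1), USE.NAMES = FALSE) -> v
  stats::setNames(v, colnames(X))
}

#' Per-frequency bivariate regression scan
#'
#' Regresses DXA-measured ALM on the impedance (or resistance) index at
#' each grid frequency separately and reports R^2 and SEE per fit —
#' the screen used to locate the muscle-specific frequency. The best
#' frequency is reported twice, by highest R^2 and by lowest SEE, because
#' the two can disagree.
#'
#' @param cohort a `bia_cohort` with `alm_dxa_kg`.
#' @param kinds character subset of `c("ZI", "RI")`.
#' @param frequencies frequency labels to scan (default: full grid).
#' @param strict error (rather than skip with a warning) when a requested
#'   channel is absent.
#' @return A `frequency_scan` object: data.frame with columns `frequency`,
#'   `kind`, `r2`, `see`, `n`, plus attributes `best_r2` and `best_see`
#'   (named list: frequency, kind, value).
#' @export
frequency_scan <- function(cohort, kinds = "ZI",
                           frequencies = names(bia_frequencies()),
                           strict = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$alm_dxa_kg) || anyNA(cohort$alm_dxa_kg))
    stop("frequency scan needs DXA ALM for every subject", call. = FALSE)
  kinds <- match.arg(kinds, c("ZI", "RI"), several.ok = TRUE)
  frequencies <- vapply(frequencies, match_frequency, character(1),
                        USE.NAMES = FALSE)
  rows <- list()
  for (kind in kinds) {
    for (lab in frequencies) {
      pname <- paste0(kind, "@", lab)
      x <- tryCatch(predictor_values(cohort, pname), error = identity)
      if (inherits(x, "error")) {
        if (strict) stop(conditionMessage(x), call. = FALSE)
        warning("skipping ", pname, ": ", conditionMessage(x), call. = FALSE)
        next
      }
      fit <- fit_ols(cohort$alm_dxa_kg,
                     stats::setNames(data.frame(x), pname),
                     degenerate = "flag")
      rows[[pname]] <- data.frame(frequency = lab, kind = kind,
                                  r2 = fit$r2, see = fit$see, n = fit$n,
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no scannable frequency/kind combinations",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  i_r2 <- which.max(out$r2); i_see <- which.min(out$see)
  attr(out, "best_r2") <- list(frequency = out$frequency[i_r2],
                               kind = out$kind[i_r2], value = out$r2[i_r2])
  attr(out, "best_see") <- list(frequency = out$frequency[i_see],
                                kind = out$kind[i_see], value = out$see[i_see])
  class(out) <- c("frequency_scan", "data.frame")
  out
}

#' @export
print.frequency_scan <- function(x, ...) {
  cat("<frequency_scan> ", nrow(x), " bivariate fits, n = ", x$n[1], "\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  b1 <- attr(x, "best_r2"); b2 <- attr(x, "best_see")
  cat("best by R^2:  ", b1$kind, "@", b1$frequency,
      " (R^2 = ", signif(b1$value, 4), ")\n",
      "best by SEE: ", b2$kind, "@", b2$frequency,
      " (SEE = ", signif(b2$value, 4), " kg)\n", sep = "")
  invisible(x)
}

#' Stepwise multiple linear regression by entry/removal p-values
#'
#' Classic p-value stepwise selection: at each round the excluded candidate
#' with the smallest partial-F p-value enters if that p-value is below
#' `alpha_enter`; then included terms with the largest p-value above
#' `alpha_remove` are removed; iterate to a fixpoint. For a single added
#' variable the partial-F test is equivalent to the coefficient's
#' two-sided t-test, which is what is used. Entry ties are broken by the
#' larger partial F, then by candidate declaration order, so selection is
#' deterministic.
#'
#' @param response numeric response vector.
#' @param candidates data.frame or matrix of named candidate predictors,
#'   in declaration (tie-break) order.
#' @param alpha_enter p-value below which a candidate may enter
#'   (default 0.05).
#' @param alpha_remove p-value above which an included term is removed
#'   (default 0.10); must be >= `alpha_enter`.
#' @return An `alm_fit` of the final model with an extra element
#'   `selected` (character vector, selection order). If nothing enters,
#'   an intercept-only fit flagged `empty_model = TRUE`.
#' @export
stepwise_select <- function(response, candidates,
                            alpha_enter = 0.05, alpha_remove = 0.10) {
  if (alpha_enter > alpha_remove)
    stop("alpha_enter must be <= alpha_remove", call. = FALSE)
  X <- as.matrix(as.data.frame(candidates))
  storage.mode(X) <- "double"
  if (!ncol(X)) stop("need at least one candidate", call. = FALSE)
  y <- as.numeric(response)
  cand <- colnames(X)
  included <- character(0)

  entry_stats <- function(nm) {
    ## t-test p-value (== partial F p-value) of nm added to current model
    cols <- c(included, nm)
    fit <- tryCatch(fit_ols(y, X[, cols, drop = FALSE]), error = identity)
    if (inherits(fit, "error") || isTRUE(fit$degenerate))
      return(c(p = NA_real_, f = NA_real_))
    pv <- fit$p_values[[nm]]
    ## |t| recovered from the two-sided p; F = t^2 for a one-term addition
    tstat <- stats::qt(pv / 2, fit$n - fit$p - 1, lower.tail = FALSE)
    c(p = pv, f = tstat^2)
  }

  for (round in seq_len(2L * ncol(X) + 10L)) {
    changed <- FALSE
    ## forward entry
    pool <- setdiff(cand, included)
    if (length(pool)) {
      st <- vapply(pool, entry_stats, numeric(2))
      ps <- st["p", ]; fs <- st["f", ]
      ok <- which(!is.na(ps) & ps < alpha_enter)
      if (length(ok)) {
        best <- ok[order(ps[ok], -fs[ok], match(pool[ok], cand))][1]
        included <- c(included, pool[best])
        changed <- TRUE
      }
    }
    ## backward removal
    repeat {
      if (length(included) == 0) break
      fit <- fit_ols(y, X[, included, drop = FALSE])
      worst <- which.max(fit$p_values)
      if (fit$p_values[worst] > alpha_remove) {
        included <- setdiff(included, names(fit$p_values)[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (!length(included)) {
    n <- length(y)
    res <- y - mean(y)
    out <- structure(list(
      terms = stats::setNames(numeric(0), character(0)),
      intercept = mean(y), r = 0, r2 = 0, adj_r2 = 0,
      see = sqrt(sum(res^2) / (n - 1)),
      p_values = numeric(0), vif = NULL, n = n, p = 0,
      fitted = rep(mean(y), n), residuals = res,
      degenerate = FALSE), class = "alm_fit")
    out$empty_model <- TRUE
    out$selected <- character(0)
    return(out)
  }
  out <- fit_ols(y, X[, included, drop = FALSE])
  out$selected <- included
  out$empty_model <- FALSE
  out
}
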