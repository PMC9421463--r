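#' Tidy a proportional-odds QC fit
#'
#' Broom-style one-row-per-term summary on the raw predictor scale.
#'
#' @param x An `ordinal_qc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `odds.ratio`, `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.ordinal_qc_fit <- function(x, ...) {
  tibble::tibble(
    term = x$coefficients$feature,
    estimate = x$coefficients$estimate,
    std.error = x$coefficients$se,
    odds.ratio = x$coefficients$odds_ratio,
    conf.low = x$coefficients$ci_low,
    conf.high = x$coefficients$ci_high,
    p.value = x$coefficients$p_value
  )
}

#' Glance at a proportional-odds QC fit
#'
#' @param x An `ordinal_qc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `nobs`, `n.features`, `df`.
#' @export
glance.ordinal_qc_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, nobs = x$n,
    n.features = length(x$features),
    df = length(x$features) + x$K - 1L
  )
}

#' Turn a fitted object into a tidy tibble
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Export an ordinal fit as a results table
#'
#' One row per retained feature with its domain, odds ratio, 95% CI and
#' p-value — the conventional layout for reporting QC-feature
#' informativeness.
#'
#' @param fit An `ordinal_qc_fit`.
#' @param domains Optional named character vector mapping feature to domain.
#' @return A tibble: `parameter`, `domain`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
informativeness_table <- function(fit, domains = NULL) {
  co <- fit$coefficients
  dom <- if (is.null(domains)) NA_character_ else unname(domains[co$feature])
  tibble::tibble(parameter = co$feature, domain = dom,
                 odds_ratio = co$odds_ratio, ci_low = co$ci_low,
                 ci_high = co$ci_high, p_value = co$p_value)
}
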