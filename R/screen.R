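#' Covariate screen of QC feature distributions
#'
#' For each QC feature, fits one linear model of the feature on the scanning
#' site (categorical) and the subject covariates, and reports per-covariate
#' marginal F-tests (`drop1`), with Bonferroni correction across all feature
#' x covariate tests. Constant features are skipped with a notice;
#' rank-deficient designs raise an error naming the collinear columns.
#'
#' @param cohort A data frame with feature columns and the covariate columns.
#' @param features Character vector of feature columns; default: all numeric
#'   non-identifier columns.
#' @param covariates Covariate columns to test; `site`, `sex`, `amyloid` and
#'   `apoe` are treated as categorical.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble of class `qc_screen`: one row per feature x covariate
#'   with `statistic` (F), `df`, `p_value`, `p_adjusted` (Bonferroni) and
#'   `significant`; the number of tests is attribute `n_tests`.
#' @export
covariate_screen <- function(cohort,
                             features = NULL,
                             covariates = c("site", "age", "sex", "mmse",
                                            "amyloid", "apoe"),
                             alpha = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  covariates <- intersect(covariates, names(cohort))
  if (length(covariates) == 0L) stop("no covariate columns present", call. = FALSE)
  features <- feature_columns(cohort, features)
  features <- setdiff(features, covariates)
  if (length(features) == 0L) stop("no feature columns present", call. = FALSE)

  cat_cov <- intersect(covariates, c("site", "sex", "amyloid", "apoe"))
  dat <- cohort
  for (cc in cat_cov) dat[[cc]] <- factor(dat[[cc]])

  rows <- list()
  for (f in features) {
    sub <- dat[stats::complete.cases(dat[, c(f, covariates)]), c(f, covariates)]
    if (nrow(sub) < 10L) {
      stop("fewer than 10 complete rows for feature '", f, "'", call. = FALSE)
    }
    if (sd(sub[[f]]) == 0) {
      message("feature '", f, "' is constant: skipped")
      next
    }
    fml <- stats::reformulate(covariates, response = f)
    fit <- stats::lm(fml, data = sub)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design for feature '", f, "': collinear term(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    d1 <- stats::drop1(fit, test = "F")
    terms <- rownames(d1)[-1]
    rows[[f]] <- tibble::tibble(
      feature = f, covariate = terms,
      statistic = d1$`F value`[-1], df = d1$Df[-1],
      p_value = d1$`Pr(>F)`[-1]
    )
  }
  if (length(rows) == 0L) stop("all features constant: nothing to screen", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(out)
  out$p_adjusted <- pmin(1, out$p_value * n_tests)
  out$significant <- out$p_adjusted < alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  class(out) <- c("qc_screen", class(out))
  out
}
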