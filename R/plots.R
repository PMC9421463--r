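#' @importFrom ggplot2 ggplot aes geom_violin geom_jitter geom_point geom_hline
#'   geom_errorbarh facet_wrap labs theme_minimal scale_colour_manual autoplot
NULL

#' Plot QC feature distributions by site
#'
#' Violin plots of one or more features across sites, the visual companion
#' of the site-wise flagging step.
#'
#' @param cohort Wide cohort tibble with `site` and feature columns.
#' @param features Feature columns to show (default: all numeric
#'   non-identifier columns, capped at 12).
#' @return A ggplot object.
#' @export
plot_features_by_site <- function(cohort, features = NULL) {
  features <- utils::head(feature_columns(cohort, features), 12)
  long <- cohort |>
    dplyr::select("site", dplyr::all_of(features)) |>
    tidyr::pivot_longer(dplyr::all_of(features),
                        names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$site, y = .data$value)) +
    geom_violin(fill = "grey85") +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.6) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = "site", y = "feature value") +
    theme_minimal()
}

#' Plot flagging results
#'
#' Summed-deviation scores per site with flagged and matched-inlier scans
#' highlighted.
#'
#' @param object A `qc_flags` tibble from [flag_outliers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_flags <- function(object, ...) {
  ggplot(object, aes(x = .data$site, y = .data$score, colour = .data$status)) +
    geom_jitter(width = 0.2, alpha = 0.8) +
    scale_colour_manual(values = c(flagged = "#D55E00",
                                   matched_inlier = "#0072B2",
                                   unreviewed = "grey60")) +
    labs(y = "summed |within-site Z|", x = "site", colour = NULL) +
    theme_minimal()
}

#' Plot an ordinal QC fit
#'
#' Odds ratios with Wald 95% confidence intervals per feature.
#'
#' @param object An `ordinal_qc_fit` from [fit_ordinal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ordinal_qc_fit <- function(object, ...) {
  co <- object$coefficients
  ggplot(co, aes(x = .data$odds_ratio, y = stats::reorder(.data$feature, .data$odds_ratio))) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    labs(x = "odds ratio (95% CI)", y = NULL) +
    theme_minimal()
}

#' Plot framewise displacement with the cohort exclusion threshold
#'
#' @param cohort Output of [fd_exclusion()].
#' @return A ggplot object.
#' @export
plot_fd_exclusion <- function(cohort) {
  thr <- attr(cohort, "threshold")
  cohort$rank <- rank(cohort$mean_fd, ties.method = "first")
  ggplot(cohort, aes(x = .data$rank, y = .data$mean_fd, colour = .data$excluded)) +
    geom_point() +
    geom_hline(yintercept = thr, linetype = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#D55E00")) +
    labs(x = "scan (ranked)", y = "mean FD (mm)",
         colour = "excluded") +
    theme_minimal()
}
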