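#' Pivot tidy QC records into a wide cohort table
#'
#' Stacks per-scan QC records (long tibbles from the feature extractors) into
#' one row per scan with one column per feature, optionally joining site and
#' covariate columns.
#'
#' @param records A tibble of stacked QC records (columns `scan_id`,
#'   `feature`, `value`, ...).
#' @param scan_info Optional tibble keyed by `scan_id` with site and
#'   covariates to join.
#' @return A wide tibble, one row per scan.
#' @export
qc_records_to_cohort <- function(records, scan_info = NULL) {
  wide <- records |>
    dplyr::select("scan_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  if (!is.null(scan_info)) {
    wide <- dplyr::left_join(tibble::as_tibble(scan_info), wide, by = "scan_id")
  }
  wide
}

feature_columns <- function(cohort, features) {
  if (!is.null(features)) return(features)
  reserved <- c("scan_id", "site", "session_id", "study_id", "modality",
                "age", "sex", "mmse", "amyloid", "apoe", "visual_label",
                "is_corrupted", "status", "score")
  cand <- setdiff(names(cohort), reserved)
  cand[vapply(cohort[cand], is.numeric, logical(1))]
}

#' Site-wise Z-scores of QC features
#'
#' Standardises each feature within each site: `Z = (x - mean_site) /
#' sd_site`, with the sample SD of that site. Features constant within a site
#' get Z = 0 for that site's scans (with a message); missing values stay
#' missing.
#'
#' @param cohort A data frame with `scan_id`, `site` and feature columns.
#' @param features Character vector of feature column names; by default all
#'   numeric columns that are not identifiers or covariates.
#' @return A tibble with `scan_id`, `site` and the Z-scored feature columns;
#'   the feature names are kept in attribute `features`.
#' @export
#' @examples
#' co <- tibble::tibble(scan_id = c("a", "b", "c"), site = "s1", snr = c(1, 2, 3))
#' site_zscores(co)$snr   # -1 0 1
site_zscores <- function(cohort, features = NULL) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("scan_id", "site") %in% names(cohort)))
  features <- feature_columns(cohort, features)
  if (length(features) == 0L) stop("no feature columns found", call. = FALSE)
  n_site <- table(cohort$site)
  if (any(n_site < 2L)) {
    stop("site(s) with a single scan cannot be Z-scored: ",
         paste(names(n_site)[n_site < 2L], collapse = ", "), call. = FALSE)
  }
  constant_any <- FALSE
  z <- cohort |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(features), function(v) {
      s <- sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        constant_any <<- TRUE
        out <- rep(0, length(v))
        out[is.na(v)] <- NA_real_
        out
      } else (v - mean(v, na.rm = TRUE)) / s
    })) |>
    dplyr::ungroup() |>
    dplyr::select("scan_id", "site", dplyr::all_of(features))
  if (constant_any) message("feature(s) constant within a site: Z set to 0 there")
  attr(z, "features") <- features
  z
}

#' Flag the highest-deviation scans for visual QC
#'
#' Ranks scans by the sum of absolute within-site Z-scores over all features
#' (rescaled by `n_features / n_non_missing` when some features are missing)
#' and flags the top `fraction` per site (`ceiling(fraction * n_site)` scans;
#' ties at the boundary broken by scan id). A pooled global cut is available
#' via `scope = "global"`.
#'
#' @param z A Z-score table from [site_zscores()].
#' @param fraction Fraction of scans to flag, in (0, 1); default 0.15.
#' @param scope `"site"` (default) selects the top fraction within each site;
#'   `"global"` applies one cut to the pooled ranking.
#' @return A `qc_flags` tibble: `scan_id`, `site`, `score`, `status`
#'   (`"flagged"` or `"unreviewed"`), with attributes `fraction`, `scope`,
#'   `features`.
#' @export
flag_outliers <- function(z, fraction = 0.15, scope = c("site", "global")) {
  scope <- match.arg(scope)
  stopifnot(fraction > 0, fraction < 1)
  features <- attr(z, "features")
  if (is.null(features)) features <- feature_columns(z, NULL)
  zm <- as.matrix(z[, features, drop = FALSE])
  n_feat <- length(features)
  n_ok <- rowSums(!is.na(zm))
  score <- rowSums(abs(zm), na.rm = TRUE) * n_feat / n_ok
  score[n_ok == 0L] <- NA_real_
  if (all(is.na(score))) stop("all scores are missing", call. = FALSE)
  out <- tibble::tibble(scan_id = z$scan_id, site = z$site, score = score,
                        status = "unreviewed")
  if (all(score[!is.na(score)] == score[which(!is.na(score))[1]])) {
    warning("uniform deviation scores: flagging falls back to the scan-id tie-break",
            call. = FALSE)
  }
  grp <- if (scope == "site") out$site else rep("all", nrow(out))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    k <- ceiling(fraction * length(idx))
    ord <- idx[order(-replace(score[idx], is.na(score[idx]), -Inf), out$scan_id[idx])]
    out$status[head(ord, k)] <- "flagged"
  }
  attr(out, "fraction") <- fraction
  attr(out, "scope") <- scope
  attr(out, "features") <- features
  class(out) <- c("qc_flags", class(out))
  out
}

#' Select matched random inliers for blinded review
#'
#' Samples, without replacement, a set of non-flagged scans of the same size
#' as the flagged set (when enough inliers exist), stratified by site to
#' match the flagged per-site counts where possible; any per-site shortfall
#' is made up by a random top-up from the remaining inliers so the total
#' matches `min(n_flagged, n_inliers)`.
#'
#' @param flags A `qc_flags` tibble from [flag_outliers()].
#' @param seed Integer seed; the selection is reproducible from it.
#' @return The flags tibble with sampled scans set to status
#'   `"matched_inlier"`; the seed is recorded in attribute `seed`.
#' @export
sample_matched_inliers <- function(flags, seed) {
  stopifnot(inherits(flags, "qc_flags"))
  pool <- which(flags$status == "unreviewed")
  if (length(pool) == 0L) stop("no non-flagged scans to sample from", call. = FALSE)
  n_target <- min(sum(flags$status == "flagged"), length(pool))
  chosen <- integer()
  with_seed_(seed, {
    for (s in unique(flags$site)) {
      fl_s <- sum(flags$status == "flagged" & flags$site == s)
      pool_s <- pool[flags$site[pool] == s]
      k <- min(fl_s, length(pool_s))
      if (k < fl_s) {
        message("site ", s, ": only ", k, " inliers available for ",
                fl_s, " flagged scans")
      }
      if (k > 0L) chosen <- c(chosen, sample(pool_s, k))
    }
    left <- setdiff(pool, chosen)
    if (length(chosen) < n_target && length(left) > 0L) {
      chosen <- c(chosen, sample(left, min(n_target - length(chosen), length(left))))
    }
  })
  flags$status[chosen] <- "matched_inlier"
  attr(flags, "seed") <- as.integer(seed)
  flags
}

#' Assemble a blinded review batch
#'
#' Pools flagged and matched-inlier scans in a seeded random order with the
#' status withheld, plus a sealed key for post-hoc unblinding.
#'
#' @param flags A `qc_flags` tibble, after [sample_matched_inliers()].
#' @param seed Integer seed for the presentation order.
#' @return A list of class `review_batch`: `batch` (tibble `position`,
#'   `scan_id`) and `key` (tibble `position`, `scan_id`, `status`).
#' @export
build_review_batch <- function(flags, seed) {
  stopifnot(inherits(flags, "qc_flags"))
  sel <- flags[flags$status %in% c("flagged", "matched_inlier"), ]
  if (nrow(sel) == 0L) stop("no flagged or matched-inlier scans to review", call. = FALSE)
  ord <- with_seed_(seed, sample.int(nrow(sel)))
  sel <- sel[ord, ]
  structure(list(
    batch = tibble::tibble(position = seq_len(nrow(sel)), scan_id = sel$scan_id),
    key = tibble::tibble(position = seq_len(nrow(sel)), scan_id = sel$scan_id,
                         status = sel$status)
  ), class = "review_batch")
}

#' Write flagging results to disk
#'
#' Writes the flag table as TSV plus a JSON run manifest (fraction, scope,
#' seed, feature list, package version).
#'
#' @param flags A `qc_flags` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_flags <- function(flags, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "flags.tsv")
  readr::write_tsv(as.data.frame(flags), tsv)
  manifest <- list(
    fraction = attr(flags, "fraction"), scope = attr(flags, "scope"),
    seed = attr(flags, "seed"), features = attr(flags, "features"),
    software = paste0("scanqc ", as.character(utils::packageVersion("scanqc")))
  )
  js <- file.path(dir, "flags_manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, js))
}
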