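#' Construct a 4D series image
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxel_size Length-3 numeric, mm.
#' @param tr Repetition time in seconds.
#' @return An object of class `series_image`.
#' @export
series_image <- function(data, voxel_size = c(1, 1, 1), tr = 1) {
  stopifnot(is.array(data), length(dim(data)) == 4L, tr > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size), tr = tr),
            class = "series_image")
}

#' Read a rigid-body motion trace
#'
#' Whitespace-delimited text, six columns per volume: translations
#' `tx ty tz` (mm) then rotations `rx ry rz` (radians). Lines starting with
#' `#` are comments.
#'
#' @param path Path to the motion parameter file.
#' @return A tibble with columns `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion_trace <- function(path) {
  m <- utils::read.table(path, comment.char = "#",
                         col.names = c("tx", "ty", "tz", "rx", "ry", "rz"))
  tibble::as_tibble(m)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at frame t is the sum of absolute parameter differences from the
#' previous frame, with rotations converted to arc length on a sphere of
#' `head_radius` mm:
#' `FD_t = |dtx| + |dty| + |dtz| + r * (|drx| + |dry| + |drz|)`, and
#' `FD_1 = 0`.
#'
#' @param trace A data frame with columns `tx, ty, tz` (mm) and
#'   `rx, ry, rz` (radians), one row per volume.
#' @param head_radius Assumed head radius in mm (default 50).
#' @return A tibble with columns `frame` and `fd` (mm), carrying the series
#'   mean as attribute `mean_fd`.
#' @export
#' @examples
#' tr <- tibble::tibble(tx = c(0, 1), ty = c(0, 1), tz = c(0, 1),
#'                      rx = 0, ry = 0, rz = 0)
#' framewise_displacement(tr)$fd   # 0, 3
framewise_displacement <- function(trace, head_radius = 50) {
  trace <- tibble::as_tibble(trace)
  need <- c("tx", "ty", "tz", "rx", "ry", "rz")
  stopifnot(all(need %in% names(trace)))
  n <- nrow(trace)
  if (n < 2L) stop("motion trace must have at least 2 volumes", call. = FALSE)
  p <- as.matrix(trace[, need])
  if (!all(is.finite(p))) stop("motion parameters must be finite", call. = FALSE)
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               head_radius * rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble::tibble(frame = seq_len(n), fd = fd)
  attr(out, "mean_fd") <- mean(fd)
  out
}

#' Cohort-level motion exclusion on mean framewise displacement
#'
#' Flags scans whose mean FD exceeds the group mean by more than
#' `n_sd` sample standard deviations.
#'
#' @param cohort A data frame with a `mean_fd` column (one row per scan), or a
#'   bare numeric vector of mean FDs.
#' @param n_sd Exclusion threshold in group SD units (default 2).
#' @return The input as a tibble with a logical `excluded` column appended;
#'   the numeric cut-off is attached as attribute `threshold`.
#' @export
fd_exclusion <- function(cohort, n_sd = 2) {
  if (is.numeric(cohort) && is.null(dim(cohort))) {
    cohort <- tibble::tibble(mean_fd = cohort)
  }
  cohort <- tibble::as_tibble(cohort)
  stopifnot("mean_fd" %in% names(cohort))
  v <- cohort$mean_fd
  if (length(v) < 3L) {
    stop("fewer than 3 scans: group SD not estimable, review motion manually",
         call. = FALSE)
  }
  thr <- mean(v) + n_sd * sd(v)
  cohort$excluded <- v > thr
  attr(cohort, "threshold") <- thr
  cohort
}

bold_domains <- c(
  fd_mean = "motion", fd_max = "motion", fd_frac_high = "motion",
  dvars_mean = "motion", dvars_sd = "motion",
  tsnr_mean = "noise", tsnr_median = "noise", tsnr_p05 = "noise",
  tsd_p95 = "noise", gs_sd = "noise",
  tmean_cv = "inhomogeneity", tmean_fber = "inhomogeneity",
  tmean_efc = "inhomogeneity",
  tmean_ai_perc = "asymmetry",
  n_volumes = "descriptives", mask_frac = "descriptives",
  gs_drift = "descriptives"
)

#' Temporal-stability and motion QC features for 4D series
#'
#' Computes the 17-feature functional QC panel: framewise-displacement
#' summaries from the motion trace; DVARS (RMS volume-to-volume signal change
#' in the mask, normalised by the median in-mask intensity); temporal SNR
#' (voxelwise mean over temporal SD) summaries; the 95th percentile of the
#' voxelwise temporal-SD map; global-signal SD and drift; and spatial
#' features of the temporal-mean volume (coefficient of variation,
#' foreground-background energy ratio, entropy-focus criterion, left-right
#' asymmetry). A series with zero temporal variance yields DVARS 0 and
#' missing temporal SNR.
#'
#' @param series A [series_image()] with at least 2 volumes.
#' @param mask Logical 3D array, the analysis mask (non-empty).
#' @param trace Motion-parameter data frame as for
#'   [framewise_displacement()], one row per volume.
#' @param scan_id Identifier recorded in the output.
#' @param fd_threshold FD above which a frame counts as high-motion (mm).
#' @param head_radius Head radius for the rotation term (mm).
#' @param orientation Axis labels of the spatial grid, for the asymmetry
#'   feature.
#' @return A tidy QC record tibble (17 rows), as for
#'   [compute_structural_features()].
#' @export
temporal_features <- function(series, mask, trace, scan_id = "scan",
                              fd_threshold = 0.5, head_radius = 50,
                              orientation = "RAS") {
  stopifnot(inherits(series, "series_image"))
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 2L) stop("series must have at least 2 volumes", call. = FALSE)
  stopifnot(identical(dim(mask), d[1:3]))
  mask <- array(as.logical(mask), d[1:3])
  if (!any(mask)) stop("empty mask", call. = FALSE)

  vmat <- matrix(series$data, prod(d[1:3]), nt)[as.vector(mask), , drop = FALSE]
  mu <- rowMeans(vmat)
  sdt <- apply(vmat, 1, sd)
  med_int <- median(vmat)

  tsnr <- mu / sdt
  tsnr[sdt <= 0] <- NA_real_   # zero temporal variance: tSNR undefined
  summ <- function(f, v) if (all(is.na(v))) NA_real_ else f(v[!is.na(v)])

  dif <- vmat[, -1, drop = FALSE] - vmat[, -nt, drop = FALSE]
  dvars <- sqrt(colMeans(dif^2)) / med_int

  fd <- framewise_displacement(trace, head_radius = head_radius)$fd

  gs <- colMeans(vmat)

  tmean <- array(rowMeans(matrix(series$data, prod(d[1:3]), nt)), d[1:3])
  tm_in <- tmean[mask]
  # crude air background for the mean volume: outside the mask, off the border
  bgm <- !mask
  brd <- 2L
  if (all(d[1:3] > 2L * brd)) {
    inner <- array(FALSE, d[1:3])
    inner[(brd + 1L):(d[1] - brd), (brd + 1L):(d[2] - brd), (brd + 1L):(d[3] - brd)] <- TRUE
    bgm <- bgm & inner
  }
  tm_bg <- tmean[bgm]
  fber <- if (length(tm_bg) && median(tm_bg^2) > 0) median(tm_in^2) / median(tm_bg^2) else NA_real_

  xa <- abs(as.numeric(tmean))
  n <- length(xa)
  b_max <- sqrt(sum(xa^2))
  efc <- sum((xa / b_max) * log((xa + 1e-16) / b_max)) / (n / sqrt(n) * log(1 / sqrt(n)))

  ax <- lr_axis(orientation)
  tmf <- flip_axis(tmean, ax)
  eps <- 1e-6 * quantile(tm_in, 0.99, names = FALSE)
  ai <- 100 * mean(abs(tmean[mask] - tmf[mask]) / ((tmean[mask] + tmf[mask]) / 2 + eps))

  tt <- seq_len(nt)
  gs_drift <- if (sd(gs) > 0) abs(stats::cor(gs, tt)) else 0

  feats <- c(
    fd_mean = mean(fd), fd_max = max(fd),
    fd_frac_high = mean(fd > fd_threshold),
    dvars_mean = mean(dvars), dvars_sd = sd(dvars),
    tsnr_mean = summ(mean, tsnr),
    tsnr_median = summ(median, tsnr),
    tsnr_p05 = summ(function(v) quantile(v, 0.05, names = FALSE), tsnr),
    tsd_p95 = quantile(sdt, 0.95, names = FALSE),
    gs_sd = sd(gs),
    tmean_cv = sd(tm_in) / mean(tm_in),
    tmean_fber = fber, tmean_efc = efc, tmean_ai_perc = ai,
    n_volumes = nt, mask_frac = mean(mask),
    gs_drift = gs_drift
  )
  qc_record(scan_id, "bold", feats, bold_domains)
}
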