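#' Construct a 3D volume image
#'
#' Lightweight container for a 3D voxel array with its voxel dimensions and an
#' axis-orientation label (used to locate the left-right axis for asymmetry
#' features).
#'
#' @param data 3D numeric array of intensities (finite).
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @param orientation Three-letter axis label triple, e.g. `"RAS"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), orientation = "RAS") {
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) >= 1L))
  if (!all(is.finite(data))) stop("image intensities must be finite", call. = FALSE)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  lr_axis(orientation)  # validates the label
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 orientation = orientation),
            class = "volume_image")
}

#' Construct tissue probability maps
#'
#' Bundles grey-matter, white-matter and CSF probability volumes on the same
#' grid as the image, together with binary brain and background masks. Masks
#' default to a binarisation of the probability sum: brain where
#' `gm + wm + csf >= 0.5`, background where the sum is below
#' `background_threshold` excluding a `border` voxel frame at the image edge.
#'
#' @param gm,wm,csf 3D arrays of tissue probabilities in \[0, 1\].
#' @param brain_mask,background_mask Optional logical arrays; derived from the
#'   probabilities when `NULL`.
#' @param prob_threshold Probability cut used to binarise tissue masks.
#' @param background_threshold Brain-probability sum below which a voxel
#'   counts as air background.
#' @param border Number of edge voxels excluded from the background mask.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(gm, wm, csf, brain_mask = NULL, background_mask = NULL,
                        prob_threshold = 0.5, background_threshold = 0.05,
                        border = 2L) {
  stopifnot(identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)))
  for (p in list(gm, wm, csf)) {
    if (min(p) < -1e-9 || max(p) > 1 + 1e-9) {
      stop("tissue probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(prob_threshold > 0, prob_threshold < 1)
  psum <- gm + wm + csf
  if (is.null(brain_mask)) brain_mask <- psum >= 0.5
  if (is.null(background_mask)) {
    background_mask <- psum < background_threshold
    d <- dim(gm)
    if (border > 0L) {
      inner <- array(FALSE, d)
      ix <- lapply(d, function(n) if (n > 2L * border) (border + 1L):(n - border) else integer())
      if (all(lengths(ix) > 0L)) inner[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
      background_mask <- background_mask & inner
    }
  }
  if (any(brain_mask & background_mask)) {
    stop("brain and background masks must be disjoint", call. = FALSE)
  }
  structure(list(gm = gm, wm = wm, csf = csf,
                 brain_mask = brain_mask, background_mask = background_mask,
                 prob_threshold = prob_threshold),
            class = "tissue_maps")
}

t1w_domains <- c(
  SNR = "noise", CNR = "noise", CJV = "inhomogeneity", FBER = "inhomogeneity",
  AI_perc = "asymmetry", IQR = "inhomogeneity", CSF_k = "descriptives",
  WM2MAX = "inhomogeneity", GMfrac = "descriptives", WMfrac = "descriptives",
  CSFfrac = "descriptives", EFC = "descriptives"
)

#' Structural (T1w) image-quality features
#'
#' Computes the 12-feature structural QC panel from an image and its tissue
#' maps. Tissue moments use probability weighting by default (hard-mask mode
#' via `weighting = "mask"`). The panel:
#'
#' * `SNR` = mu_WM / sigma_WM
#' * `CNR` = |mu_GM - mu_WM| / sqrt(sigma_GM^2 + sigma_WM^2 + sigma_bg^2)
#' * `CJV` = (sigma_WM + sigma_GM) / |mu_WM - mu_GM|
#' * `FBER` = median(foreground^2) / median(background^2)
#' * `AI_perc` = 100 x mean over brain voxels of
#'   |I - I_flip| / ((I + I_flip)/2 + eps), flipping along the L/R axis
#' * `IQR` = image-quality rating surrogate: RMS of two logistic-mapped
#'   sub-scores, a noise-to-contrast ratio sigma_WM/|mu_WM - mu_GM| and a bias
#'   estimate (coefficient of variation of a heavily smoothed image over WM)
#' * `CSF_k` = excess kurtosis of intensities in the CSF mask
#' * `WM2MAX` = mu_WM / P99.95 of the whole image
#' * `GMfrac`, `WMfrac`, `CSFfrac` = tissue volume fractions of brain volume
#' * `EFC` = entropy-focus criterion of the whole image
#'
#' Degenerate GM/WM contrast (|mu_WM - mu_GM| below tolerance) yields `NA` for
#' `CJV` with a warning rather than an unbounded value.
#'
#' @param img A [volume_image()].
#' @param tissues A [tissue_maps()] on the same grid.
#' @param scan_id Identifier recorded in the output.
#' @param weighting `"probability"` (default) weights voxels by tissue
#'   probability; `"mask"` uses hard masks at `prob_threshold`.
#' @param bias_smooth_sigma Gaussian sigma (voxels) of the smoothing used for
#'   the IQR bias sub-score.
#' @return A tidy QC record: tibble with columns `scan_id`, `modality`,
#'   `feature`, `value`, `domain` (12 rows).
#' @export
compute_structural_features <- function(img, tissues, scan_id = "scan",
                                        weighting = c("probability", "mask"),
                                        bias_smooth_sigma = 6) {
  stopifnot(inherits(img, "volume_image"), inherits(tissues, "tissue_maps"))
  if (!identical(dim(img$data), dim(tissues$gm))) {
    stop("tissue maps and image are on different grids", call. = FALSE)
  }
  weighting <- match.arg(weighting)
  x <- img$data
  thr <- tissues$prob_threshold

  wts <- function(p, name) {
    w <- if (weighting == "probability") p else as.numeric(p >= thr)
    if (sum(w >= thr) == 0) stop("empty ", name, " mask after binarization", call. = FALSE)
    w
  }
  w_gm <- wts(tissues$gm, "gm"); w_wm <- wts(tissues$wm, "wm"); w_csf <- wts(tissues$csf, "csf")
  if (!any(tissues$background_mask)) stop("empty background mask", call. = FALSE)
  if (!any(tissues$brain_mask)) stop("empty brain mask", call. = FALSE)

  gm <- weighted_moments(x, w_gm)
  wm <- weighted_moments(x, w_wm)
  bg_vox <- x[tissues$background_mask]
  sigma_bg <- sd(bg_vox)

  contrast <- abs(wm$mean - gm$mean)
  contrast_tol <- 1e-6 * (abs(wm$mean) + abs(gm$mean) + .Machine$double.eps)

  snr <- wm$mean / wm$sd
  cnr <- contrast / sqrt(gm$sd^2 + wm$sd^2 + sigma_bg^2)
  cjv <- if (contrast <= contrast_tol) {
    warning("degenerate GM/WM contrast: CJV reported as missing", call. = FALSE)
    NA_real_
  } else (wm$sd + gm$sd) / contrast

  fg <- x[tissues$brain_mask]
  fber <- median(fg^2) / median(bg_vox^2)

  ax <- lr_axis(img$orientation)
  xf <- flip_axis(x, ax)
  eps <- 1e-6 * quantile(fg, 0.99, names = FALSE)
  bm <- tissues$brain_mask
  ai <- 100 * mean(abs(x[bm] - xf[bm]) / ((x[bm] + xf[bm]) / 2 + eps))

  # IQR surrogate sub-scores, each logistic-mapped to (0, 1)
  ncr <- if (contrast <= contrast_tol) NA_real_ else wm$sd / contrast
  sm <- gaussian_smooth3d(x, bias_smooth_sigma)
  smw <- weighted_moments(sm, w_wm)
  bias_cv <- smw$sd / smw$mean
  sub <- function(u) plogis((u - 0.1) / 0.05)
  iqr <- sqrt(0.5 * sub(ncr)^2 + 0.5 * sub(bias_cv)^2)

  csf_hard <- tissues$csf >= thr
  csf_k <- excess_kurtosis(x[csf_hard])

  wm2max <- wm$mean / quantile(x, 0.9995, names = FALSE)

  vox_sums <- c(gm = sum(tissues$gm), wm = sum(tissues$wm), csf = sum(tissues$csf))
  fracs <- vox_sums / sum(vox_sums)

  xa <- abs(as.numeric(x))
  n <- length(xa)
  b_max <- sqrt(sum(xa^2))
  efc_max <- n / sqrt(n) * log(1 / sqrt(n))
  efc <- sum((xa / b_max) * log((xa + 1e-16) / b_max)) / efc_max

  feats <- c(SNR = snr, CNR = cnr, CJV = cjv, FBER = fber, AI_perc = ai,
             IQR = iqr, CSF_k = csf_k, WM2MAX = wm2max,
             GMfrac = unname(fracs["gm"]), WMfrac = unname(fracs["wm"]),
             CSFfrac = unname(fracs["csf"]), EFC = efc)
  qc_record(scan_id, "T1w", feats, t1w_domains)
}
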