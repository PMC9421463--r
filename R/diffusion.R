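#' Construct a diffusion gradient scheme
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n or n x 3 numeric matrix of gradient directions; rows
#'   with nonzero b must be unit-norm within 1e-3 (b = 0 directions are
#'   arbitrary).
#' @return An object of class `diffusion_scheme` with `bvals` and a 3 x n
#'   `bvecs` matrix.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be 3 x n or n x 3", call. = FALSE)
  if (ncol(bvecs) != length(bvals)) stop("bvals and bvecs lengths differ", call. = FALSE)
  nz <- bvals > 0
  nrm <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    stop("nonzero-b gradient directions must be unit norm (within 1e-3)", call. = FALSE)
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

#' Read an FSL-dialect bval/bvec pair
#'
#' `bval`: one whitespace-separated row of b-values. `bvec`: three rows of
#' x, y, z direction components.
#'
#' @param bval_path,bvec_path File paths.
#' @return A [diffusion_scheme()].
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  diffusion_scheme(bvals, bv)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_k - mean)^2) / sum(lambda_k^2))`.
#'
#' @param l1,l2,l3 Eigenvalues (vectors of equal length).
#' @return FA values (not clipped to \[0, 1\]).
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(1.5) * sqrt(num / den)
  out[den <= 0] <- NA_real_
  out
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, solves `log S_i = log S_0 - b_i g_i' D g_i` by ordinary least
#' squares on the six unique tensor elements plus `log S_0`, then
#' eigen-decomposes the tensor into scalar maps. Nonpositive signals inside
#' the mask are clamped to the smallest positive signal in that voxel's
#' series before the log (the clamp count is reported). Negative eigenvalues
#' are retained: they drive the pre-clip FA used for QC, while the released
#' `fa` map is clipped to \[0, 1\].
#'
#' @param dwi A [series_image()] or bare 4D array of diffusion-weighted
#'   signals.
#' @param scheme A [diffusion_scheme()] matching the 4th dimension.
#' @param mask Logical 3D array of voxels to fit.
#' @return An object of class `tensor_fit`: 3D maps `fa`, `fa_preclip`, `md`,
#'   `ad`, `rd`, `sse`, `s0`; `evals` (voxels x 3, descending); `mask`;
#'   `b0_mean`/`b0_sd` maps over the b = 0 volumes; `n_b0`; `clamp_count`;
#'   `condition_number` of the design.
#' @export
fit_tensor <- function(dwi, scheme, mask) {
  data <- if (inherits(dwi, "series_image")) dwi$data else dwi
  stopifnot(length(dim(data)) == 4L, inherits(scheme, "diffusion_scheme"))
  d <- dim(data)
  if (d[4] != length(scheme$bvals)) {
    stop("scheme length does not match number of volumes", call. = FALSE)
  }
  mask <- array(as.logical(mask), d[1:3])
  if (!any(mask)) stop("empty fit mask", call. = FALSE)
  b <- scheme$bvals
  g <- scheme$bvecs
  nz <- b > 0
  if (sum(!nz) < 1L) stop("at least one b = 0 volume is required", call. = FALSE)
  if (sum(nz) < 6L) stop("at least 6 nonzero-b directions are required", call. = FALSE)
  if (d[4] < 7L) stop("fewer than 7 usable volumes", call. = FALSE)

  X <- cbind(1,
             -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  sv <- svd(X, nu = 0, nv = 0)$d
  cnd <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cnd) || cnd > 1e8) {
    stop("rank-deficient gradient design (collinear directions); condition number ",
         format(cnd), call. = FALSE)
  }

  S <- matrix(data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE]
  clamp_count <- 0L
  bad <- S <= 0
  if (any(bad)) {
    clamp_count <- sum(bad)
    for (i in which(rowSums(bad) > 0)) {
      pos <- S[i, S[i, ] > 0]
      if (length(pos) == 0L) stop("voxel with no positive signal in mask", call. = FALSE)
      S[i, S[i, ] <= 0] <- min(pos)
    }
  }
  Y <- t(log(S))                       # volumes x voxels
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))  # 7 x voxels
  resid <- Y - X %*% beta
  sse_v <- colSums(resid^2)

  nvox <- ncol(beta)
  evals <- matrix(NA_real_, nvox, 3)
  for (i in seq_len(nvox)) {
    Dm <- matrix(c(beta[2, i], beta[5, i], beta[6, i],
                   beta[5, i], beta[3, i], beta[7, i],
                   beta[6, i], beta[7, i], beta[4, i]), 3, 3)
    evals[i, ] <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
  }
  fa_pre <- fa_from_eigenvalues(evals[, 1], evals[, 2], evals[, 3])
  md_v <- rowMeans(evals)
  ad_v <- evals[, 1]
  rd_v <- (evals[, 2] + evals[, 3]) / 2

  to_map <- function(v) { a <- array(NA_real_, d[1:3]); a[mask] <- v; a }
  b0 <- matrix(data, prod(d[1:3]), d[4])[, !nz, drop = FALSE]
  b0_mean <- array(rowMeans(b0), d[1:3])
  b0_sd <- if (sum(!nz) >= 2L) array(apply(b0, 1, sd), d[1:3]) else NULL

  structure(list(
    fa = to_map(pmin(pmax(fa_pre, 0), 1)), fa_preclip = to_map(fa_pre),
    md = to_map(md_v), ad = to_map(ad_v), rd = to_map(rd_v),
    sse = to_map(sse_v), s0 = to_map(exp(beta[1, ])),
    evals = evals, mask = mask,
    b0_mean = b0_mean, b0_sd = b0_sd, n_b0 = sum(!nz),
    clamp_count = clamp_count, condition_number = cnd
  ), class = "tensor_fit")
}

dwi_domains <- c(
  motion_tx = "motion", motion_ty = "motion", motion_tz = "motion",
  motion_rx = "motion", motion_ry = "motion", motion_rz = "motion",
  fd_mean = "motion", fd_max = "motion", motion_outlier_pct = "motion",
  sse_mean = "noise", sse_p95 = "noise", b0_tsnr = "noise",
  fa_outlier_pct = "noise", neg_eig_pct = "noise",
  fa_mean_wm = "descriptives", fa_sd_wm = "descriptives",
  md_mean_wm = "descriptives", md_sd_wm = "descriptives",
  ad_mean_wm = "descriptives", rd_mean_wm = "descriptives"
)

#' Diffusion QC features from a tensor fit
#'
#' Computes the 20-feature diffusion QC panel: per-axis motion summaries
#' (mean absolute parameter per volume), framewise displacement, the
#' percentage of volumes whose frame-to-frame RMS displacement exceeds
#' `motion_threshold`; fit-quality metrics (mean and 95th-percentile
#' log-signal SSE in white matter, percentage of WM voxels with pre-clip FA
#' outside \[0, 1\], percentage with a negative eigenvalue, b = 0 temporal
#' SNR); and WM tensor-scalar descriptives. With a single b = 0 volume the
#' b = 0 SNR falls back to the spatial mean/SD ratio within WM.
#'
#' @param fit A [fit_tensor()] result.
#' @param wm_mask Logical 3D array; must intersect the fit mask.
#' @param trace Motion-parameter data frame (see
#'   [framewise_displacement()]), one row per volume.
#' @param scan_id Identifier recorded in the output.
#' @param motion_threshold RMS displacement (mm) above which a volume counts
#'   as a motion outlier.
#' @param head_radius Head radius (mm) for rotation terms.
#' @return A tidy QC record tibble (20 rows).
#' @export
dwi_qc_features <- function(fit, wm_mask, trace, scan_id = "scan",
                            motion_threshold = 1, head_radius = 50) {
  stopifnot(inherits(fit, "tensor_fit"))
  wm_mask <- array(as.logical(wm_mask), dim(fit$mask))
  wm <- wm_mask & fit$mask
  if (!any(wm)) stop("white-matter mask does not intersect the fit mask", call. = FALSE)

  p <- as.matrix(tibble::as_tibble(trace)[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  fd <- framewise_displacement(trace, head_radius = head_radius)$fd
  dp <- diff(p)
  rms_disp <- sqrt(rowSums(cbind(dp[, 1:3, drop = FALSE],
                                 head_radius * dp[, 4:6, drop = FALSE])^2))

  fa_pre <- fit$fa_preclip[wm]
  sse <- fit$sse[wm]

  b0_tsnr <- if (!is.null(fit$b0_sd)) {
    v <- fit$b0_mean[wm] / fit$b0_sd[wm]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  } else {
    # single b = 0 volume: spatial SNR within WM
    mean(fit$b0_mean[wm]) / sd(fit$b0_mean[wm])
  }

  feats <- c(
    motion_tx = mean(abs(p[, "tx"])), motion_ty = mean(abs(p[, "ty"])),
    motion_tz = mean(abs(p[, "tz"])),
    motion_rx = mean(abs(p[, "rx"])), motion_ry = mean(abs(p[, "ry"])),
    motion_rz = mean(abs(p[, "rz"])),
    fd_mean = mean(fd), fd_max = max(fd),
    motion_outlier_pct = 100 * mean(rms_disp > motion_threshold),
    sse_mean = mean(sse), sse_p95 = quantile(sse, 0.95, names = FALSE),
    b0_tsnr = b0_tsnr,
    fa_outlier_pct = 100 * mean(fa_pre < 0 | fa_pre > 1),
    neg_eig_pct = 100 * mean(fit$evals[wm_mask[fit$mask], 3] < 0),
    fa_mean_wm = mean(fit$fa[wm]), fa_sd_wm = sd(fit$fa[wm]),
    md_mean_wm = mean(fit$md[wm]), md_sd_wm = sd(fit$md[wm]),
    ad_mean_wm = mean(fit$ad[wm]), rd_mean_wm = mean(fit$rd[wm])
  )
  qc_record(scan_id, "dwi", feats, dwi_domains)
}
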