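#' Specification for a synthetic multi-site phantom cohort
#'
#' Fixes every parameter of the generators: geometry, site-specific intensity
#' and noise multipliers, artifact injection, and the master seed. All
#' downstream randomness is derived from `seed`, so a spec reproduces a
#' cohort bit for bit.
#'
#' @param n_sites Number of scanning sites.
#' @param scans_per_site Scans per site.
#' @param site_intensity_mult,site_noise_mult Per-site multiplicative shifts
#'   of tissue intensity and noise SD; defaults spread evenly around 1.
#' @param tissue_means Named vector of clean tissue intensities (csf, gm, wm),
#'   arbitrary units.
#' @param noise_sigma Base intensity noise SD (units of `tissue_means`).
#' @param bias_amplitude Relative amplitude of the multiplicative low-order
#'   polynomial bias field (0 = none).
#' @param asymmetry Relative left-right intensity asymmetry (0 = none).
#' @param artifact_prevalence Probability that a scan is generated corrupted.
#' @param artifact_noise_mult,artifact_bias,artifact_asymmetry Degradations
#'   applied to corrupted structural scans.
#' @param dim_t1 Edge length of the (cubic) structural phantom grid.
#' @param dim_fmri 4-vector, spatial grid and volume count of the 4D phantom.
#' @param fmri_baseline,fmri_noise_sd,fmri_drift Mean in-mask signal, temporal
#'   noise SD, and total linear drift of the 4D phantom.
#' @param motion_step_sd,motion_step_sd_corrupted Random-walk step SD (mm) of
#'   the translation parameters for clean and corrupted scans.
#' @param rot_step_sd,rot_step_sd_corrupted Step SD (radians) of the rotation
#'   parameters.
#' @param dwi_dim 3-vector, diffusion phantom grid (all voxels fitted).
#' @param dwi_ndirs,dwi_nb0,dwi_bval Gradient scheme: number of
#'   diffusion-weighted directions, b = 0 volumes, and the shell b-value
#'   (s/mm^2).
#' @param dwi_snr b = 0 signal-to-noise ratio of the diffusion phantom
#'   (`Inf` = noiseless).
#' @param dwi_noise `"rician"` (default) or `"gaussian"` noise for the
#'   diffusion signals.
#' @param seed Master integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sites = 4, scans_per_site = 50,
                        site_intensity_mult = NULL, site_noise_mult = NULL,
                        tissue_means = c(csf = 150, gm = 400, wm = 600),
                        noise_sigma = 20,
                        bias_amplitude = 0, asymmetry = 0,
                        artifact_prevalence = 0,
                        artifact_noise_mult = 4, artifact_bias = 0.3,
                        artifact_asymmetry = 0.05,
                        dim_t1 = 64,
                        dim_fmri = c(32, 32, 32, 100),
                        fmri_baseline = 500, fmri_noise_sd = 10, fmri_drift = 2,
                        motion_step_sd = 0.02, motion_step_sd_corrupted = 0.5,
                        rot_step_sd = 2e-4, rot_step_sd_corrupted = 5e-3,
                        dwi_dim = c(10, 10, 10),
                        dwi_ndirs = 54, dwi_nb0 = 1, dwi_bval = 1000,
                        dwi_snr = 30, dwi_noise = c("rician", "gaussian"),
                        seed = 1L) {
  if (is.null(site_intensity_mult)) {
    site_intensity_mult <- seq(0.9, 1.1, length.out = n_sites)
  }
  if (is.null(site_noise_mult)) {
    site_noise_mult <- seq(0.8, 1.25, length.out = n_sites)
  }
  stopifnot(length(site_intensity_mult) == n_sites,
            length(site_noise_mult) == n_sites,
            all(site_intensity_mult > 0), all(site_noise_mult > 0),
            artifact_prevalence >= 0, artifact_prevalence <= 1,
            all(c("csf", "gm", "wm") %in% names(tissue_means)),
            noise_sigma >= 0, dim_t1 >= 8, length(dim_fmri) == 4L,
            dwi_ndirs >= 6, dwi_nb0 >= 1)
  dwi_noise <- match.arg(dwi_noise)
  structure(as.list(environment()), class = "cohort_spec")
}

spec_site <- function(spec, index) ((index - 1L) %/% spec$scans_per_site) + 1L

spec_corrupted <- function(spec, index) {
  with_seed_(sub_seed(spec$seed, index, 1L), runif(1) < spec$artifact_prevalence)
}

scan_label <- function(spec, index) {
  sprintf("sub-%03d", as.integer(index))
}

# normalized coordinate grids in [-1, 1]
norm_grid <- function(d) {
  gx <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
  gy <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  gz <- if (d[3] > 1) seq(-1, 1, length.out = d[3]) else 0
  list(x = array(rep(gx, times = d[2] * d[3]), d),
       y = array(rep(rep(gy, each = d[1]), times = d[3]), d),
       z = array(rep(gz, each = d[1] * d[2]), d))
}

# smooth low-order polynomial field scaled to max |f| = 1
bias_poly <- function(g) {
  f <- 0.4 * g$x + 0.3 * g$y + 0.2 * g$z + 0.6 * g$x * g$y + 0.5 * g$z^2
  f / max(abs(f))
}

#' Generate a structural (T1w-like) phantom with tissue maps
#'
#' Builds a nested-ellipsoid three-compartment phantom (WM core, GM shell,
#' CSF rim) with site-scaled tissue means, additive Gaussian noise, and
#' optional multiplicative polynomial bias field and left-right asymmetry.
#' Scans drawn as corrupted (per `artifact_prevalence`) get their noise SD
#' multiplied by `artifact_noise_mult` and the artifact bias/asymmetry
#' amplitudes. Exact tissue maps and generating parameters are returned as
#' ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param index Scan index (1-based across the cohort); determines the site
#'   and the corruption draw deterministically from the spec seed.
#' @return A list: `image` ([volume_image()]), `tissues` ([tissue_maps()]),
#'   `truth` (one-row tibble with scan id, site, corruption flag and the
#'   generating parameters).
#' @export
make_t1_phantom <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  site <- spec_site(spec, index)
  corrupted <- spec_corrupted(spec, index)
  d <- rep(spec$dim_t1, 3)
  g <- norm_grid(d)
  q <- (g$x / 0.80)^2 + (g$y / 0.85)^2 + (g$z / 0.75)^2
  wm <- q <= 0.35
  gm <- q > 0.35 & q <= 0.80
  csf <- q > 0.80 & q <= 1.00
  if (!any(wm) || !any(gm) || !any(csf)) {
    stop("degenerate phantom geometry: empty tissue compartment", call. = FALSE)
  }
  mult <- spec$site_intensity_mult[site]
  sigma <- spec$noise_sigma * spec$site_noise_mult[site]
  bias_amp <- spec$bias_amplitude
  asym <- spec$asymmetry
  if (corrupted) {
    sigma <- sigma * spec$artifact_noise_mult
    bias_amp <- bias_amp + spec$artifact_bias
    asym <- asym + spec$artifact_asymmetry
  }
  mu <- spec$tissue_means * mult
  bg_mean <- 20

  img <- array(bg_mean, d)
  img[csf] <- mu[["csf"]]
  img[gm] <- mu[["gm"]]
  img[wm] <- mu[["wm"]]
  if (bias_amp > 0) img <- img * (1 + bias_amp * bias_poly(g))
  if (asym != 0) img[g$x > 0] <- img[g$x > 0] * (1 + asym)
  if (sigma > 0) {
    img <- img + with_seed_(sub_seed(spec$seed, index, 2L),
                            array(rnorm(prod(d), 0, sigma), d))
  }

  tis <- tissue_maps(gm = array(as.numeric(gm), d), wm = array(as.numeric(wm), d),
                     csf = array(as.numeric(csf), d))
  truth <- tibble::tibble(
    scan_id = scan_label(spec, index), site = paste0("site", site),
    modality = "T1w", is_corrupted = corrupted,
    artifact = if (corrupted) "noise+bias+asymmetry" else "",
    mu_csf = mu[["csf"]], mu_gm = mu[["gm"]], mu_wm = mu[["wm"]],
    noise_sigma = sigma, bias_amplitude = bias_amp, asymmetry = asym
  )
  list(image = volume_image(img), tissues = tis, truth = truth)
}

# seeded random-walk rigid-body motion trace
make_motion_trace <- function(n, step_sd, rot_step_sd, seed) {
  with_seed_(seed, {
    tr <- sapply(1:3, function(i) cumsum(c(0, rnorm(n - 1, 0, step_sd))))
    ro <- sapply(1:3, function(i) cumsum(c(0, rnorm(n - 1, 0, rot_step_sd))))
    tibble::tibble(tx = tr[, 1], ty = tr[, 2], tz = tr[, 3],
                   rx = ro[, 1], ry = ro[, 2], rz = ro[, 3])
  })
}

#' Generate a 4D (BOLD-like) phantom series with motion trace
#'
#' Static ellipsoid phantom plus temporal Gaussian noise and a linear drift;
#' the motion trace is a random walk whose step SD is inflated for corrupted
#' scans so their mean framewise displacement separates from the clean
#' population.
#'
#' @inheritParams make_t1_phantom
#' @return A list: `series` ([series_image()]), `mask` (logical 3D array),
#'   `trace` (motion tibble), `truth` (one-row tibble).
#' @export
make_fmri_series <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$dim_fmri
  if (d[4] < 2L) stop("series needs at least 2 volumes", call. = FALSE)
  site <- spec_site(spec, index)
  corrupted <- spec_corrupted(spec, index)
  g <- norm_grid(d[1:3])
  mask <- (g$x / 0.8)^2 + (g$y / 0.8)^2 + (g$z / 0.8)^2 <= 1
  base <- array(20, d[1:3])
  base[mask] <- spec$fmri_baseline * spec$site_intensity_mult[site]
  noise_sd <- spec$fmri_noise_sd * spec$site_noise_mult[site]
  drift <- spec$fmri_drift * seq(0, 1, length.out = d[4])
  arr <- with_seed_(sub_seed(spec$seed, index, 3L), {
    a <- array(rnorm(prod(d), 0, noise_sd), d)
    for (t in seq_len(d[4])) a[, , , t] <- a[, , , t] + base + drift[t] * mask
    a
  })
  step_sd <- if (corrupted) spec$motion_step_sd_corrupted else spec$motion_step_sd
  rot_sd <- if (corrupted) spec$rot_step_sd_corrupted else spec$rot_step_sd
  trace <- make_motion_trace(d[4], step_sd, rot_sd, sub_seed(spec$seed, index, 4L))
  truth <- tibble::tibble(
    scan_id = scan_label(spec, index), site = paste0("site", site),
    modality = "bold", is_corrupted = corrupted,
    artifact = if (corrupted) "motion" else "",
    motion_step_sd = step_sd, noise_sd = noise_sd
  )
  list(series = series_image(arr, tr = 2), mask = mask, trace = trace,
       truth = truth)
}

# near-uniform unit directions on the sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a diffusion-weighted phantom from known tensors
#'
#' Signals follow `S = S0 exp(-b g' D g)` voxelwise from a ground-truth
#' tensor field with a high-anisotropy region (eigenvalues 1.7, 0.3, 0.3
#' x 1e-3 mm^2/s, principal axis x) and a low-anisotropy region
#' (1.1, 0.8, 0.8 x 1e-3), with Rician or Gaussian noise at the specified
#' b = 0 SNR. Corrupted scans get doubled noise and an inflated motion trace.
#'
#' @inheritParams make_t1_phantom
#' @return A list: `series` ([series_image()]), `scheme`
#'   ([diffusion_scheme()]), `mask`, `trace`, `truth` (list with per-voxel
#'   true eigenvalue matrix `evals`, `fa_true` map, `region` map, and a
#'   one-row `scan` tibble).
#' @export
make_dwi <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  site <- spec_site(spec, index)
  corrupted <- spec_corrupted(spec, index)
  d <- spec$dwi_dim
  nvox <- prod(d)
  g <- norm_grid(d)
  region <- array(1L, d)
  region[g$x > 0] <- 2L
  ev1 <- c(1.7, 0.3, 0.3) * 1e-3
  ev2 <- c(1.1, 0.8, 0.8) * 1e-3
  evals <- matrix(NA_real_, nvox, 3)
  evals[region == 1L, ] <- matrix(ev1, sum(region == 1L), 3, byrow = TRUE)
  evals[region == 2L, ] <- matrix(ev2, sum(region == 2L), 3, byrow = TRUE)
  # principal axis along x: D is diagonal in the grid frame
  bvecs <- cbind(matrix(0, 3, spec$dwi_nb0), fibonacci_directions(spec$dwi_ndirs))
  bvals <- c(rep(0, spec$dwi_nb0), rep(spec$dwi_bval, spec$dwi_ndirs))
  scheme <- diffusion_scheme(bvals, bvecs)
  s0 <- 1000
  att <- exp(-(outer(evals[, 1], bvals * bvecs[1, ]^2) +
               outer(evals[, 2], bvals * bvecs[2, ]^2) +
               outer(evals[, 3], bvals * bvecs[3, ]^2)))
  S <- s0 * att
  snr <- spec$dwi_snr
  if (corrupted) snr <- snr / 2
  if (is.finite(snr)) {
    sig <- s0 / snr
    S <- with_seed_(sub_seed(spec$seed, index, 5L), {
      if (spec$dwi_noise == "rician") {
        sqrt((S + matrix(rnorm(length(S), 0, sig), nrow(S)))^2 +
             matrix(rnorm(length(S), 0, sig), nrow(S))^2)
      } else {
        S + matrix(rnorm(length(S), 0, sig), nrow(S))
      }
    })
  }
  arr <- array(S, c(d, length(bvals)))
  mask <- array(TRUE, d)
  step_sd <- if (corrupted) spec$motion_step_sd_corrupted else spec$motion_step_sd
  rot_sd <- if (corrupted) spec$rot_step_sd_corrupted else spec$rot_step_sd
  trace <- make_motion_trace(length(bvals), step_sd, rot_sd,
                             sub_seed(spec$seed, index, 6L))
  fa_true <- array(fa_from_eigenvalues(evals[, 1], evals[, 2], evals[, 3]), d)
  truth <- list(
    evals = evals, fa_true = fa_true, region = region,
    scan = tibble::tibble(
      scan_id = scan_label(spec, index), site = paste0("site", site),
      modality = "dwi", is_corrupted = corrupted,
      artifact = if (corrupted) "noise+motion" else "", snr = snr)
  )
  list(series = series_image(arr), scheme = scheme, mask = mask,
       trace = trace, truth = truth)
}

#' Simulate subject covariates for a cohort
#'
#' Age, sex, MMSE, amyloid status and APOE-e4 carriership with plausible
#' elderly-cohort marginals; independent of image quality by construction.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A tibble with columns `age`, `sex`, `mmse`, `amyloid`, `apoe`.
#' @export
simulate_covariates <- function(n, seed) {
  with_seed_(seed, tibble::tibble(
    age = round(rnorm(n, 73, 6), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    mmse = pmin(30L, pmax(18L, round(rnorm(n, 28, 2)))),
    amyloid = sample(c("neg", "pos"), n, replace = TRUE, prob = c(0.7, 0.3)),
    apoe = sample(c("noncarrier", "carrier"), n, replace = TRUE, prob = c(0.65, 0.35))
  ))
}

#' Simulate a feature-level multi-site QC cohort
#'
#' Draws a wide cohort table directly in feature space: per site x feature
#' baseline offsets (site effects), unit within-site SD, and corrupted scans
#' (per `prevalence`) with `n_shifted` randomly chosen features shifted by
#' `shift_sd` within-site SDs. This is the fast generator for flagging and
#' screening studies; the image-level generators exercise the same pipeline
#' end to end.
#'
#' @param n_sites,scans_per_site Cohort dimensions.
#' @param n_features Number of QC features (named `f01`, `f02`, ...).
#' @param prevalence Probability that a scan is corrupted.
#' @param n_shifted Number of features shifted per corrupted scan.
#' @param shift_sd Shift magnitude in within-site SD units.
#' @param site_shift_sd SD of the per-site x feature baseline offsets
#'   (site effect strength); `site_offsets` overrides with an explicit
#'   sites x features matrix.
#' @param site_offsets Optional matrix (`n_sites` x `n_features`) of baseline
#'   offsets.
#' @param seed Integer seed.
#' @return A tibble: `scan_id`, `site`, `is_corrupted`, covariates, and the
#'   feature columns.
#' @export
simulate_qc_features <- function(n_sites = 4, scans_per_site = 50,
                                 n_features = 12, prevalence = 0.05,
                                 n_shifted = 3, shift_sd = 4,
                                 site_shift_sd = 1, site_offsets = NULL,
                                 seed = 1L) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  n_shifted <- min(n_shifted, n_features)
  n <- n_sites * scans_per_site
  with_seed_(seed, {
    if (is.null(site_offsets)) {
      site_offsets <- matrix(rnorm(n_sites * n_features, 0, site_shift_sd),
                             n_sites, n_features)
    }
    stopifnot(all(dim(site_offsets) == c(n_sites, n_features)))
    site_idx <- rep(seq_len(n_sites), each = scans_per_site)
    X <- site_offsets[site_idx, , drop = FALSE] +
      matrix(rnorm(n * n_features), n, n_features)
    corrupted <- runif(n) < prevalence
    for (i in which(corrupted)) {
      j <- sample.int(n_features, n_shifted)
      X[i, j] <- X[i, j] + shift_sd * sample(c(-1, 1), n_shifted, replace = TRUE)
    }
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(scan_id = sprintf("sub-%03d", seq_len(n)),
                     site = paste0("site", site_idx),
                     is_corrupted = corrupted),
      simulate_covariates(n, seed = sub_seed(seed, 0L, 7L)),
      tibble::as_tibble(X)
    )
  })
}

#' Simulate ordinal visual labels from a proportional-odds model
#'
#' Draws labels with `P(Y <= k | x) = logistic(theta_k - x' beta)`; the
#' generative inverse of [fit_ordinal()], used for calibration studies.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param beta Coefficient vector (length p).
#' @param cutpoints Increasing cut-point vector (length K - 1).
#' @param seed Integer seed.
#' @param levels Labels for categories 1..K, worst to best.
#' @return A character vector of labels (or integers when `levels = NULL`).
#' @export
simulate_visual_labels <- function(X, beta, cutpoints, seed,
                                   levels = c("poor", "moderate", "good")) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(beta), !is.unsorted(cutpoints))
  eta <- as.vector(X %*% beta)
  K <- length(cutpoints) + 1L
  y <- with_seed_(seed, {
    u <- runif(nrow(X))
    cum <- vapply(cutpoints, function(t) plogis(t - eta), numeric(nrow(X)))
    1L + rowSums(u > cbind(cum))
  })
  if (is.null(levels)) y else {
    stopifnot(length(levels) == K)
    levels[y]
  }
}

#' Materialize a BIDS-like synthetic cohort on disk
#'
#' Writes phantom images per site and modality under
#' `sub-XXX/ses-1/anat|func|dwi/`, with JSON sidecars, tissue-map and mask
#' NIfTIs, motion-trace and bval/bvec text files, `participants.tsv`
#' (site + covariates) and `ground_truth.tsv` (corruption labels and
#' generating parameters). Nothing is computed from the images here.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @param modalities Subset of `c("T1w", "bold", "dwi")` to generate.
#' @return Invisibly, a list with `participants` and `ground_truth` tibbles
#'   and the output `dir`.
#' @export
make_cohort <- function(spec, dir, modalities = "T1w") {
  stopifnot(inherits(spec, "cohort_spec"),
            all(modalities %in% c("T1w", "bold", "dwi")))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  n <- spec$n_sites * spec$scans_per_site
  truth <- list()
  for (i in seq_len(n)) {
    sub <- scan_label(spec, i)
    if ("T1w" %in% modalities) {
      p <- make_t1_phantom(spec, i)
      adir <- file.path(dir, sub, "ses-1", "anat")
      dir.create(adir, recursive = TRUE, showWarnings = FALSE)
      write_volume(p$image, file.path(adir, paste0(sub, "_ses-1_T1w.nii.gz")))
      for (tt in c("gm", "wm", "csf")) {
        write_volume(volume_image(p$tissues[[tt]]),
                     file.path(adir, sprintf("%s_ses-1_label-%s_probseg.nii.gz",
                                             sub, toupper(tt))))
      }
      jsonlite::write_json(
        list(Modality = "MR", SeriesDescription = "t1_mprage_sag_synthetic",
             ProtocolName = "t1_mprage", RepetitionTime = 2.3, EchoTime = 0.003),
        file.path(adir, paste0(sub, "_ses-1_T1w.json")), auto_unbox = TRUE)
      truth[[length(truth) + 1L]] <- p$truth
    }
    if ("bold" %in% modalities) {
      f <- make_fmri_series(spec, i)
      fdir <- file.path(dir, sub, "ses-1", "func")
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      RNifti::writeNifti(RNifti::asNifti(f$series$data),
                         file.path(fdir, paste0(sub, "_ses-1_task-rest_bold.nii.gz")))
      write_motion_trace(f$trace,
                         file.path(fdir, paste0(sub, "_ses-1_task-rest_motion.txt")))
      jsonlite::write_json(
        list(Modality = "MR", SeriesDescription = "ep2d_bold_rest_synthetic",
             RepetitionTime = f$series$tr),
        file.path(fdir, paste0(sub, "_ses-1_task-rest_bold.json")), auto_unbox = TRUE)
      truth[[length(truth) + 1L]] <- f$truth
    }
    if ("dwi" %in% modalities) {
      w <- make_dwi(spec, i)
      wdir <- file.path(dir, sub, "ses-1", "dwi")
      dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
      RNifti::writeNifti(RNifti::asNifti(w$series$data),
                         file.path(wdir, paste0(sub, "_ses-1_dwi.nii.gz")))
      writeLines(paste(w$scheme$bvals, collapse = " "),
                 file.path(wdir, paste0(sub, "_ses-1_dwi.bval")))
      utils::write.table(w$scheme$bvecs,
                         file.path(wdir, paste0(sub, "_ses-1_dwi.bvec")),
                         row.names = FALSE, col.names = FALSE)
      write_motion_trace(w$trace,
                         file.path(wdir, paste0(sub, "_ses-1_dwi_motion.txt")))
      truth[[length(truth) + 1L]] <- w$truth$scan
    }
  }
  truth <- dplyr::bind_rows(truth)
  participants <- dplyr::bind_cols(
    tibble::tibble(scan_id = scan_label(spec, seq_len(n)),
                   site = paste0("site", spec_site(spec, seq_len(n)))),
    simulate_covariates(n, seed = sub_seed(spec$seed, 0L, 8L))
  )
  readr::write_tsv(participants, file.path(dir, "participants.tsv"))
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"))
  invisible(list(participants = participants, ground_truth = truth, dir = dir))
}
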