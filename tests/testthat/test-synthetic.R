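test_that("the same spec and seed reproduce phantoms bit for bit", {
  sp <- cohort_spec(dim_t1 = 24, artifact_prevalence = 0.3, seed = 7)
  a <- make_t1_phantom(sp, 3)
  b <- make_t1_phantom(sp, 3)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth, b$truth)

  spf <- cohort_spec(dim_fmri = c(8, 8, 8, 12), seed = 7)
  expect_identical(make_fmri_series(spf, 2)$trace, make_fmri_series(spf, 2)$trace)

  spd <- cohort_spec(dwi_dim = c(4, 4, 4), seed = 7)
  expect_identical(make_dwi(spd, 1)$series$data, make_dwi(spd, 1)$series$data)
})

test_that("noiseless phantoms have zero within-tissue spread and exact means", {
  sp <- cohort_spec(noise_sigma = 0, dim_t1 = 32,
                    site_intensity_mult = rep(1, 4), seed = 3)
  p <- make_t1_phantom(sp, 1)
  x <- p$image$data
  expect_equal(sd(x[p$tissues$wm == 1]), 0)
  expect_equal(mean(x[p$tissues$wm == 1]), 600)
  expect_equal(mean(x[p$tissues$gm == 1]), 400)
})

test_that("noisy phantoms hit the requested WM mean within 1%", {
  sp <- cohort_spec(noise_sigma = 20, site_intensity_mult = rep(1, 4), seed = 5)
  p <- make_t1_phantom(sp, 1)
  w <- p$tissues$wm
  m <- sum(w * p$image$data) / sum(w)
  expect_equal(m, 600, tolerance = 0.01)
})

test_that("zero prevalence yields no corrupted scans; counts follow the binomial", {
  sp0 <- cohort_spec(artifact_prevalence = 0, seed = 11)
  expect_false(any(sapply(1:20, function(i) scanqc:::spec_corrupted(sp0, i))))

  counts <- sapply(1:200, function(seed) {
    sum(simulate_qc_features(n_sites = 4, scans_per_site = 50,
                             prevalence = 0.05, seed = seed)$is_corrupted)
  })
  expect_equal(mean(counts), 200 * 0.05, tolerance = 0.1)
})

test_that("a zero-step motion spec gives an identically zero FD series", {
  sp <- cohort_spec(motion_step_sd = 0, rot_step_sd = 0,
                    dim_fmri = c(6, 6, 6, 30), seed = 13)
  f <- make_fmri_series(sp, 1)
  expect_equal(framewise_displacement(f$trace)$fd, rep(0, 30))
})

test_that("corrupted motion walks separate from clean ones under the FD rule", {
  hits <- sapply(1:20, function(seed) {
    sp <- cohort_spec(n_sites = 1, scans_per_site = 20,
                      artifact_prevalence = 0, dim_fmri = c(4, 4, 4, 60),
                      seed = seed)
    mean_fds <- sapply(1:20, function(i) {
      step <- if (i <= 2) sp$motion_step_sd_corrupted else sp$motion_step_sd
      rot <- if (i <= 2) sp$rot_step_sd_corrupted else sp$rot_step_sd
      tr <- scanqc:::make_motion_trace(60, step, rot,
                                       scanqc:::sub_seed(seed, i, 4L))
      attr(framewise_displacement(tr), "mean_fd")
    })
    all(fd_exclusion(mean_fds)$excluded[1:2])
  })
  expect_gte(mean(hits), 0.99)
})

test_that("noiseless DWI output refits to the generating tensors", {
  sp <- cohort_spec(dwi_snr = Inf, dwi_dim = c(5, 5, 5), seed = 17)
  w <- make_dwi(sp, 1)
  fit <- fit_tensor(w$series, w$scheme, w$mask)
  expect_lt(max(abs(fit$evals - w$truth$evals)), 1e-12)
})

test_that("high- and low-anisotropy regions stay well separated at SNR 30", {
  sp <- cohort_spec(dwi_snr = 30, seed = 19)
  w <- make_dwi(sp, 1)
  fit <- fit_tensor(w$series, w$scheme, w$mask)
  gap <- mean(fit$fa[w$truth$region == 1L]) - mean(fit$fa[w$truth$region == 2L])
  expect_gt(gap, 0.5)
})

test_that("simulated covariates and labels have the declared structure", {
  cv <- simulate_covariates(500, seed = 23)
  expect_true(all(cv$mmse <= 30))
  expect_setequal(unique(cv$sex), c("F", "M"))
  expect_identical(cv, simulate_covariates(500, seed = 23))

  X <- matrix(rnorm(3000), 3000, 1)
  y <- simulate_visual_labels(X, 2, c(-1, 1), seed = 24)
  expect_setequal(unique(y), c("poor", "moderate", "good"))
  # strong positive coefficient: high x must skew toward "good"
  expect_gt(mean(y[X > 1] == "good"), mean(y[X < -1] == "good"))
})

test_that("make_cohort writes a BIDS-like tree with ground truth", {
  dir <- withr::local_tempdir()
  sp <- cohort_spec(n_sites = 2, scans_per_site = 2, dim_t1 = 16,
                    dim_fmri = c(8, 8, 8, 6), dwi_dim = c(4, 4, 4),
                    artifact_prevalence = 0.5, seed = 29)
  res <- make_cohort(sp, file.path(dir, "cohort"),
                     modalities = c("T1w", "bold", "dwi"))
  expect_true(file.exists(file.path(dir, "cohort", "sub-001", "ses-1", "anat",
                                    "sub-001_ses-1_T1w.nii.gz")))
  expect_true(file.exists(file.path(dir, "cohort", "sub-003", "ses-1", "func",
                                    "sub-003_ses-1_task-rest_bold.nii.gz")))
  expect_true(file.exists(file.path(dir, "cohort", "sub-002", "ses-1", "dwi",
                                    "sub-002_ses-1_dwi.bval")))
  expect_true(file.exists(file.path(dir, "cohort", "ground_truth.tsv")))
  expect_equal(nrow(res$ground_truth), 4 * 3)
  expect_equal(nrow(res$participants), 4)

  # regeneration reproduces identical voxel data
  res2 <- make_cohort(sp, file.path(dir, "cohort2"), modalities = "T1w")
  v1 <- read_volume(file.path(dir, "cohort", "sub-001", "ses-1", "anat",
                              "sub-001_ses-1_T1w.nii.gz"))
  v2 <- read_volume(file.path(dir, "cohort2", "sub-001", "ses-1", "anat",
                              "sub-001_ses-1_T1w.nii.gz"))
  expect_equal(v1$data, v2$data)
})

test_that("end-to-end: structural artifacts raise flagging scores", {
  # small image-level cohort: every corrupted scan must outscore its site median
  sp <- cohort_spec(n_sites = 2, scans_per_site = 8, dim_t1 = 24,
                    noise_sigma = 10, artifact_prevalence = 0, seed = 31)
  corrupted_idx <- c(2, 11)
  recs <- lapply(1:16, function(i) {
    p <- make_t1_phantom(sp, i)
    img <- p$image
    if (i %in% corrupted_idx) {
      bad <- cohort_spec(n_sites = 2, scans_per_site = 8, dim_t1 = 24,
                         noise_sigma = 40, bias_amplitude = 0.4,
                         asymmetry = 0.08, artifact_prevalence = 0, seed = 31)
      img <- make_t1_phantom(bad, i)$image
    }
    compute_structural_features(img, p$tissues, scan_id = p$truth$scan_id)
  })
  cohort <- qc_records_to_cohort(dplyr::bind_rows(recs)) |>
    dplyr::mutate(site = rep(c("site1", "site2"), each = 8), .after = "scan_id")
  fl <- flag_outliers(site_zscores(cohort), 0.15)
  for (i in corrupted_idx) {
    id <- sprintf("sub-%03d", i)
    site_scores <- fl$score[fl$site == fl$site[fl$scan_id == id]]
    expect_gt(fl$score[fl$scan_id == id], median(site_scores))
  }
  expect_true(all(sprintf("sub-%03d", corrupted_idx) %in%
                    fl$scan_id[fl$status == "flagged"]))
})
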