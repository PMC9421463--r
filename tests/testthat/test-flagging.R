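test_that("site Z-scores match the hand-computed example", {
  co <- tibble::tibble(scan_id = c("a", "b", "c"), site = "s1", f = c(1, 2, 3))
  z <- site_zscores(co)
  expect_equal(z$f, c(-1, 0, 1))
})

test_that("within-site Z has mean 0 and sample SD 1 for every feature", {
  co <- simulate_qc_features(n_sites = 3, scans_per_site = 30, seed = 5)
  z <- site_zscores(co)
  for (f in attr(z, "features")) {
    by_site <- split(z[[f]], z$site)
    expect_true(all(abs(sapply(by_site, mean)) < 1e-10))
    expect_true(all(abs(sapply(by_site, sd) - 1) < 1e-10))
  }
})

test_that("site-wise centering removes pure site offsets", {
  base <- c(5, 7, 9, 11)
  co <- tibble::tibble(
    scan_id = sprintf("s%02d", 1:8),
    site = rep(c("A", "B"), each = 4),
    f = c(base, base + 100))
  z <- site_zscores(co)
  expect_equal(z$f[1:4], z$f[5:8])
})

test_that("constant features and single-scan sites are handled per policy", {
  co <- tibble::tibble(scan_id = c("a", "b", "c"), site = "s1",
                       f = c(1, 2, 3), g = 4)
  expect_message(z <- site_zscores(co), "constant")
  expect_equal(z$g, c(0, 0, 0))

  lone <- tibble::tibble(scan_id = c("a", "b", "c"), site = c("s1", "s1", "s2"),
                         f = 1:3)
  expect_error(site_zscores(lone), "s2")
})

test_that("missing feature values yield missing Z but a rescaled score", {
  co <- tibble::tibble(scan_id = c("a", "b", "c", "d"), site = "s1",
                       f = c(1, 2, 3, 4), g = c(2, NA, 4, 6))
  z <- site_zscores(co)
  expect_true(is.na(z$g[2]))
  fl <- suppressWarnings(flag_outliers(z, fraction = 0.25))
  # scan b's score is its |Z_f| rescaled by 2/1
  expect_equal(fl$score[fl$scan_id == "b"],
               2 * abs(z$f[2]))
})

test_that("per-site flag counts follow ceiling semantics", {
  co <- simulate_qc_features(n_sites = 2, scans_per_site = 20, seed = 7)
  fl <- flag_outliers(site_zscores(co), fraction = 0.15)
  counts <- table(fl$site[fl$status == "flagged"])
  expect_true(all(counts == ceiling(0.15 * 20)))   # exactly 3 per site

  co9 <- simulate_qc_features(n_sites = 1, scans_per_site = 9, seed = 8)
  fl9 <- flag_outliers(site_zscores(co9), fraction = 0.15)
  expect_equal(sum(fl9$status == "flagged"), ceiling(0.15 * 9))  # 2 of 9
})

test_that("uniform scores still flag the required count with a warning", {
  co <- tibble::tibble(scan_id = sprintf("s%02d", 1:10), site = "A",
                       f = rep(c(1, 2), 5), g = rep(c(2, 1), 5))
  z <- site_zscores(co)
  expect_warning(fl <- flag_outliers(z, 0.2), "uniform")
  expect_equal(sum(fl$status == "flagged"), 2L)
  # deterministic tie-break: lexicographically smallest scan ids
  expect_equal(sort(fl$scan_id[fl$status == "flagged"]), c("s01", "s02"))
})

test_that("a scan shifted +10 SD on three features dominates its site", {
  co <- simulate_qc_features(n_sites = 2, scans_per_site = 25,
                             prevalence = 0, seed = 9)
  co[co$scan_id == "sub-007", c("f01", "f02", "f03")] <-
    co[co$scan_id == "sub-007", c("f01", "f02", "f03")] + 10
  z <- site_zscores(co)
  fl <- flag_outliers(z, fraction = 1 / 25)
  feats <- attr(z, "features")
  scores <- sapply(co$scan_id[co$site == "site1"],
                   function(id) oracle_site_score(co, feats, id))
  expect_equal(names(which.max(scores)), "sub-007")
  expect_true("sub-007" %in% fl$scan_id[fl$status == "flagged"])
})

test_that("flagging is equivariant to positive rescaling of any feature", {
  co <- simulate_qc_features(n_sites = 2, scans_per_site = 15, seed = 11)
  z1 <- site_zscores(co)
  co2 <- dplyr::mutate(co, f03 = f03 * 1000, f07 = f07 * 1e-6)
  z2 <- site_zscores(co2)
  expect_equal(as.data.frame(z1), as.data.frame(z2), tolerance = 1e-10)
  f1 <- flag_outliers(z1, 0.15)
  f2 <- flag_outliers(z2, 0.15)
  expect_equal(f1$status, f2$status)
  expect_equal(f1$score, f2$score, tolerance = 1e-10)
})

test_that("matched inliers are site-stratified, disjoint and seed-stable", {
  co <- simulate_qc_features(n_sites = 3, scans_per_site = 20,
                             prevalence = 0.05, seed = 13)
  fl <- flag_outliers(site_zscores(co), 0.15)
  m1 <- sample_matched_inliers(fl, seed = 42)
  m2 <- sample_matched_inliers(fl, seed = 42)
  expect_identical(m1$status, m2$status)
  expect_equal(sum(m1$status == "matched_inlier"), sum(m1$status == "flagged"))
  expect_equal(table(m1$site[m1$status == "matched_inlier"]),
               table(m1$site[m1$status == "flagged"]))
  m3 <- sample_matched_inliers(fl, seed = 43)
  expect_false(identical(m1$status, m3$status))
})

test_that("inlier shortfall in a site is topped up from other sites", {
  co <- tibble::tibble(
    scan_id = sprintf("s%02d", 1:12),
    site = rep(c("A", "B"), c(4, 8)),
    f = c(10, 11, 1, 1.5, rnorm(8)))
  z <- site_zscores(co)
  fl <- flag_outliers(z, fraction = 0.6)   # 3 of 4 flagged in A, 5 of 8 in B
  expect_message(m <- sample_matched_inliers(fl, seed = 3), "only")
  expect_equal(sum(m$status == "matched_inlier"),
               min(sum(fl$status == "flagged"),
                   sum(fl$status == "unreviewed")))
})

test_that("review batches are blinded, seeded and round-trip to statuses", {
  co <- simulate_qc_features(n_sites = 2, scans_per_site = 20,
                             prevalence = 0.1, seed = 17)
  fl <- sample_matched_inliers(flag_outliers(site_zscores(co), 0.15), seed = 1)
  b1 <- build_review_batch(fl, seed = 5)
  b2 <- build_review_batch(fl, seed = 5)
  expect_identical(b1$batch, b2$batch)
  expect_false("status" %in% names(b1$batch))
  expect_setequal(b1$batch$scan_id,
                  fl$scan_id[fl$status %in% c("flagged", "matched_inlier")])
  rejoined <- merge(b1$batch, b1$key, by = c("position", "scan_id"))
  expect_equal(
    rejoined$status[match(fl$scan_id[fl$status != "unreviewed"], rejoined$scan_id)],
    fl$status[fl$status != "unreviewed"])
})

test_that("detection: 4-SD artifact scans are almost always flagged at 15%", {
  # 4 sites x 50 scans, 5% corrupted with 3 features shifted 4 within-site SD
  recalls <- sapply(1:25, function(seed) {
    co <- simulate_qc_features(n_sites = 4, scans_per_site = 50,
                               prevalence = 0.05, n_shifted = 3, shift_sd = 4,
                               seed = seed)
    if (!any(co$is_corrupted)) return(NA_real_)
    fl <- flag_outliers(site_zscores(co), 0.15)
    mean(co$scan_id[co$is_corrupted] %in% fl$scan_id[fl$status == "flagged"])
  })
  expect_gte(mean(recalls, na.rm = TRUE), 0.95)
})
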