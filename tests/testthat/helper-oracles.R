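# Fixtures and independent brute-force oracles used across the suite.
# The oracles recompute each documented feature formula directly on the voxel
# vectors with base R, independent of the package implementation.

# Box phantom whose tissue compartments have EXACT sample moments: each
# region's sampled values are standardized to the target mean/SD, so the
# closed-form feature values (e.g. CJV = (sd_wm + sd_gm)/|mu_wm - mu_gm|)
# hold exactly.
make_contrast_phantom <- function(n = 24, mu_gm = 400, sd_gm = 40,
                                  mu_wm = 600, sd_wm = 30,
                                  mu_csf = 150, sd_csf = 15,
                                  mu_bg = 30, sd_bg = 5, seed = 1) {
  d <- rep(n, 3)
  gm <- wm <- csf <- array(0, d)
  a <- 5:(n %/% 2); b <- (n %/% 2 + 1):(n - 4)
  zlo <- 5:(n - 12); zhi <- (n - 11):(n - 6)
  gm[a, 5:(n - 4), zlo] <- 1
  wm[b, 5:(n - 4), zlo] <- 1
  csf[5:(n - 4), 5:(n - 4), zhi] <- 1
  x <- array(0, d)
  exact <- function(k, mu, s) {
    v <- rnorm(k)
    mu + s * (v - mean(v)) / sd(v)
  }
  set.seed(seed)
  brain <- gm + wm + csf > 0
  inner <- array(FALSE, d)
  inner[3:(n - 2), 3:(n - 2), 3:(n - 2)] <- TRUE
  x[gm == 1] <- exact(sum(gm), mu_gm, sd_gm)
  x[wm == 1] <- exact(sum(wm), mu_wm, sd_wm)
  x[csf == 1] <- exact(sum(csf), mu_csf, sd_csf)
  x[!brain] <- mu_bg
  # exact background moments on the border-eroded mask actually used
  x[!brain & inner] <- exact(sum(!brain & inner), mu_bg, sd_bg)
  list(img = volume_image(x), tissues = tissue_maps(gm, wm, csf),
       gm = gm == 1, wm = wm == 1, csf = csf == 1)
}

# independent 1D-convolution Gaussian smoother (mirror boundary), used only
# to cross-check the IQR bias sub-score
oracle_smooth3d <- function(vol, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    # mirror-pad (reflect about the end points, no edge repeat)
    pad <- c(v[(half + 1):2], v, v[(n - 1):(n - half)])
    vapply(seq_len(n), function(i) sum(pad[i:(i + 2 * half)] * k), numeric(1))
  }
  d <- dim(vol)
  out <- vol
  for (j in seq_len(d[2])) for (l in seq_len(d[3])) out[, j, l] <- conv1(out[, j, l])
  for (i in seq_len(d[1])) for (l in seq_len(d[3])) out[i, , l] <- conv1(out[i, , l])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) out[i, j, ] <- conv1(out[i, j, ])
  out
}

# direct arithmetic evaluation of all 12 structural feature formulas
oracle_structural <- function(x, gm, wm, csf, bias_sigma = 6) {
  brain <- gm | wm | csf
  d <- dim(x)
  inner <- array(FALSE, d)
  inner[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  bg <- !brain & inner
  m_gm <- mean(x[gm]); s_gm <- sd(x[gm])
  m_wm <- mean(x[wm]); s_wm <- sd(x[wm])
  s_bg <- sd(x[bg])
  eps <- 1e-6 * quantile(x[brain], 0.99, names = FALSE)
  xf <- x[dim(x)[1]:1, , ]
  sm <- oracle_smooth3d(x, bias_sigma)
  lg <- function(u) 1 / (1 + exp(-(u - 0.1) / 0.05))
  v <- x[csf]
  n <- length(x); xa <- abs(as.numeric(x)); bmax <- sqrt(sum(xa^2))
  c(
    SNR = m_wm / s_wm,
    CNR = abs(m_gm - m_wm) / sqrt(s_gm^2 + s_wm^2 + s_bg^2),
    CJV = (s_wm + s_gm) / abs(m_wm - m_gm),
    FBER = median(x[brain]^2) / median(x[bg]^2),
    AI_perc = 100 * mean(abs(x[brain] - xf[brain]) / ((x[brain] + xf[brain]) / 2 + eps)),
    IQR = sqrt(0.5 * lg(s_wm / abs(m_wm - m_gm))^2 +
               0.5 * lg(sd(sm[wm]) / mean(sm[wm]))^2),
    CSF_k = mean((v - mean(v))^4) / mean((v - mean(v))^2)^2 - 3,
    WM2MAX = m_wm / quantile(x, 0.9995, names = FALSE),
    GMfrac = sum(gm) / sum(brain),
    WMfrac = sum(wm) / sum(brain),
    CSFfrac = sum(csf) / sum(brain),
    EFC = sum((xa / bmax) * log((xa + 1e-16) / bmax)) / (n / sqrt(n) * log(1 / sqrt(n)))
  )
}

# random (seeded) unit gradient directions, in the 3 x n bvec layout
scanqc_fib_dirs <- function(n, seed = 99) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), 3, n)
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

# seeded random-walk motion trace fixture
make_motion_trace_fixture <- function(n, seed, step_sd = 0.05, rot_step_sd = 5e-4) {
  set.seed(seed)
  walk <- function(s) cumsum(c(0, rnorm(n - 1, 0, s)))
  tibble::tibble(tx = walk(step_sd), ty = walk(step_sd), tz = walk(step_sd),
                 rx = walk(rot_step_sd), ry = walk(rot_step_sd),
                 rz = walk(rot_step_sd))
}

# wide feature value lookup from a tidy QC record
feat <- function(record, name) record$value[record$feature == name]

# brute-force summed-|Z| score for one scan against its site peers
oracle_site_score <- function(cohort, features, id) {
  row <- cohort[cohort$scan_id == id, ]
  peers <- cohort[cohort$site == row$site, ]
  s <- 0
  for (f in features) {
    s <- s + abs((row[[f]] - mean(peers[[f]])) / sd(peers[[f]]))
  }
  s
}
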