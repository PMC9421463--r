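#' @importFrom rlang .data
#' @importFrom stats sd median quantile plogis pnorm pchisq qnorm rnorm runif
#' @importFrom utils head
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-scan sub-seed from a master seed; double arithmetic avoids
# integer overflow, result kept below 2^31.
sub_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
                as.numeric(stream) * 1299709) %% 2147483647)
}

#' Weighted mean and standard deviation of voxel intensities
#'
#' Probability-weighted moments used by the structural features. With binary
#' weights the results equal the ordinary sample mean and sample SD
#' (denominator `sum(w) - 1`).
#'
#' @param x Numeric vector of intensities.
#' @param w Non-negative weights (tissue probabilities), same length as `x`.
#' @return A list with elements `mean`, `sd` and `wsum`.
#' @keywords internal
weighted_moments <- function(x, w) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  sw <- sum(w)
  if (sw <= 0) return(list(mean = NA_real_, sd = NA_real_, wsum = 0))
  m <- sum(w * x) / sw
  v <- if (sw > 1) sum(w * (x - m)^2) / (sw - 1) else NA_real_
  list(mean = m, sd = sqrt(v), wsum = sw)
}

# Excess kurtosis (population moments): m4/m2^2 - 3.
excess_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

# Separable 3D Gaussian smoothing with reflective boundaries.
# sigma is in voxels; kernel truncated at 3 sigma.
gaussian_smooth3d <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L, sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- dp[1]
    idx <- seq_len(n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- idx + off
      # reflect out-of-range indices
      src <- ifelse(src < 1L, 2L - src, src)
      src <- ifelse(src > n, 2L * n - src, src)
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    ap2 <- array(out, dim = dp)
    aperm(ap2, order(perm))
  }
  v <- smooth_axis(vol, 1)
  v <- smooth_axis(v, 2)
  smooth_axis(v, 3)
}

# Locate the left-right axis from an orientation label triple such as "RAS".
lr_axis <- function(orientation) {
  labs <- toupper(strsplit(orientation, "")[[1]])
  ax <- which(labs %in% c("L", "R"))
  if (length(ax) != 1L) {
    stop("orientation '", orientation, "' does not identify a single L/R axis", call. = FALSE)
  }
  ax
}

# Flip a 3D array along one axis.
flip_axis <- function(vol, axis) {
  d <- dim(vol)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
}

# assemble a qc feature record tibble
qc_record <- function(scan_id, modality, features, domains) {
  stopifnot(length(features) == length(domains),
            !anyDuplicated(names(features)))
  tibble::tibble(
    scan_id = scan_id,
    modality = modality,
    feature = names(features),
    value = unname(as.numeric(features)),
    domain = unname(domains[names(features)])
  )
}
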