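# Proportional-odds (cumulative-logit) maximum likelihood.
#
# Model: P(Y <= k | x) = plogis(theta_k - x' beta), common slopes across the
# K - 1 cumulative logits. Fitted by BFGS on the standardized predictors with
# the analytic gradient and a tight relative tolerance; Wald covariance from
# a finite-difference Hessian of that gradient.

po_negloglik <- function(par, Xs, y, K) {
  p <- ncol(Xs)
  theta <- par[seq_len(K - 1)]
  beta <- par[K - 1 + seq_len(p)]
  eta <- as.vector(Xs %*% beta)
  A <- ifelse(y == K, 1, plogis(theta[pmin(y, K - 1)] - eta))
  B <- ifelse(y == 1, 0, plogis(theta[pmax(y - 1, 1)] - eta))
  -sum(log(pmax(A - B, 1e-312)))
}

po_gradient <- function(par, Xs, y, K) {
  p <- ncol(Xs)
  theta <- par[seq_len(K - 1)]
  beta <- par[K - 1 + seq_len(p)]
  eta <- as.vector(Xs %*% beta)
  A <- ifelse(y == K, 1, plogis(theta[pmin(y, K - 1)] - eta))
  B <- ifelse(y == 1, 0, plogis(theta[pmax(y - 1, 1)] - eta))
  P <- pmax(A - B, 1e-312)
  a <- ifelse(y == K, 0, A * (1 - A))
  b <- ifelse(y == 1, 0, B * (1 - B))
  g_theta <- numeric(K - 1)
  for (m in seq_len(K - 1)) {
    g_theta[m] <- sum(a[y == m] / P[y == m]) - sum(b[y == m + 1] / P[y == m + 1])
  }
  g_beta <- -as.vector(crossprod(Xs, (a - b) / P))
  -c(g_theta, g_beta)
}

# analytic Hessian of the negative log-likelihood
po_hessian <- function(par, Xs, y, K) {
  p <- ncol(Xs)
  n <- nrow(Xs)
  theta <- par[seq_len(K - 1)]
  beta <- par[K - 1 + seq_len(p)]
  eta <- as.vector(Xs %*% beta)
  A <- ifelse(y == K, 1, plogis(theta[pmin(y, K - 1)] - eta))
  B <- ifelse(y == 1, 0, plogis(theta[pmax(y - 1, 1)] - eta))
  P <- pmax(A - B, 1e-312)
  a <- ifelse(y == K, 0, A * (1 - A))
  b <- ifelse(y == 1, 0, B * (1 - B))
  ap <- a * (1 - 2 * A)   # d a / d u
  bp <- b * (1 - 2 * B)
  luu <- ap / P - (a / P)^2
  lvv <- -bp / P - (b / P)^2
  luv <- a * b / P^2
  luu[y == K] <- 0; luv[y == K] <- 0
  lvv[y == 1] <- 0; luv[y == 1] <- 0

  npar <- K - 1 + p
  H <- matrix(0, npar, npar)
  # beta-beta block
  wbb <- luu + 2 * luv + lvv
  H[K - 1 + seq_len(p), K - 1 + seq_len(p)] <- crossprod(Xs, Xs * wbb)
  for (m in seq_len(K - 1)) {
    i_m <- y == m
    i_m1 <- y == m + 1
    H[m, m] <- sum(luu[i_m]) + sum(lvv[i_m1])
    if (m < K - 1) {
      off <- sum(luv[y == m + 1])
      H[m, m + 1] <- H[m, m + 1] + off
      H[m + 1, m] <- H[m + 1, m] + off
    }
    w_th <- numeric(n)
    w_th[i_m] <- -(luu[i_m] + luv[i_m])
    w_th[i_m1] <- -(luv[i_m1] + lvv[i_m1])
    hb <- as.vector(crossprod(Xs, w_th))
    H[m, K - 1 + seq_len(p)] <- hb
    H[K - 1 + seq_len(p), m] <- hb
  }
  -H   # Hessian of the NEGATIVE log-likelihood
}

po_fit_core <- function(X, y, K, maxit = 1000L, init = NULL) {
  p <- ncol(X)
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  if (any(s == 0)) {
    stop("constant predictor(s): ", paste(colnames(X)[s == 0], collapse = ", "),
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, m), 2, s, "/")
  if (is.null(init)) {
    cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / length(y)
    init <- c(stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3)), rep(0, p))
  }
  opt <- stats::optim(init, po_negloglik, po_gradient, Xs = Xs, y = y, K = K,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  if (opt$convergence != 0L) {
    stop("proportional-odds fit did not converge after ", maxit,
         " iterations (optim code ", opt$convergence, ")", call. = FALSE)
  }
  # Newton polish to push the score to ~0 (BFGS stops on function decrease)
  par <- opt$par
  val <- opt$value
  for (it in 1:20) {
    gr <- po_gradient(par, Xs, y, K)
    if (max(abs(gr)) < 1e-8) break
    H <- po_hessian(par, Xs, y, K)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    new_par <- par - step
    new_val <- po_negloglik(new_par, Xs, y, K)
    hl <- 0
    while (new_val > val + 1e-10 && hl < 8) {  # halve on overshoot
      step <- step / 2
      new_par <- par - step
      new_val <- po_negloglik(new_par, Xs, y, K)
      hl <- hl + 1
    }
    if (new_val > val + 1e-10) break
    par <- new_par; val <- new_val
  }
  opt$par <- par; opt$value <- val
  beta_std <- opt$par[K - 1 + seq_len(p)]
  if (any(abs(beta_std) > 25)) {
    stop("extreme standardized coefficients: likely complete separation; ",
         "consider a penalized fit or fewer predictors", call. = FALSE)
  }
  H <- po_hessian(opt$par, Xs, y, K)
  V <- tryCatch(solve(H), error = function(e) {
    stop("singular Hessian in the proportional-odds fit", call. = FALSE)
  })
  se_std <- sqrt(pmax(diag(V)[K - 1 + seq_len(p)], 0))
  theta_std <- opt$par[seq_len(K - 1)]
  list(beta_std = beta_std, se_std = se_std, theta_std = theta_std,
       loglik = -opt$value, center = m, scale = s)
}

#' Ordinal (proportional-odds) regression of visual QC labels on features
#'
#' Fits `P(Y <= k | x) = logistic(theta_k - x' beta)` by maximum likelihood,
#' with `Y` the ordinal visual label (default ordering `poor < moderate <
#' good`). Predictors are z-standardized internally for numerical stability;
#' coefficients, odds ratios, Wald 95% confidence intervals and p-values are
#' reported on the raw predictor scale (standardized-scale estimates are kept
#' in the returned object). Rows with missing values in the label or any
#' predictor are dropped (complete-case, count recorded).
#'
#' @param data A data frame with the label column and feature columns.
#' @param label Name of the ordinal label column (character, factor or
#'   ordered factor).
#' @param features Character vector of predictor columns; default: all
#'   numeric non-identifier columns.
#' @param level_order Label levels from worst to best quality.
#' @param .init_std Optional starting values on the standardized scale
#'   (cutpoints then coefficients); used internally for warm-started refits.
#' @return An object of class `ordinal_qc_fit` with elements `coefficients`
#'   (tibble: feature, estimate, se, odds_ratio, ci_low, ci_high, p_value),
#'   `cutpoints`, `loglik`, `aic`, `n`, `n_dropped`, `features`, plus the
#'   complete-case design (`X`, `y`) used for refits.
#' @export
fit_ordinal <- function(data, label = "visual_label", features = NULL,
                        level_order = c("poor", "moderate", "good"),
                        .init_std = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(label %in% names(data))
  features <- feature_columns(data, features)
  features <- setdiff(features, label)
  if (length(features) == 0L) stop("no predictor columns", call. = FALSE)

  lab <- data[[label]]
  if (is.factor(lab)) lab <- as.character(lab)
  if (is.character(lab)) {
    bad <- setdiff(unique(lab[!is.na(lab)]), level_order)
    if (length(bad)) stop("unknown label level(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    y_all <- match(lab, level_order)
  } else {
    y_all <- as.integer(lab)
  }
  X_all <- as.matrix(data[, features, drop = FALSE])
  ok <- !is.na(y_all) & stats::complete.cases(X_all)
  n_dropped <- sum(!ok)
  y <- y_all[ok]
  # drop unobserved levels but keep the ordering
  lev_present <- sort(unique(y))
  if (length(lev_present) < 2L) stop("need at least 2 observed label levels", call. = FALSE)
  y <- match(y, lev_present)
  K <- length(lev_present)
  X <- X_all[ok, , drop = FALSE]

  core <- po_fit_core(X, y, K, init = .init_std)
  beta_raw <- unname(core$beta_std / core$scale)
  se_raw <- unname(core$se_std / core$scale)
  theta_raw <- unname(core$theta_std + sum(core$beta_std * core$center / core$scale))
  zval <- beta_raw / se_raw
  coefs <- tibble::tibble(
    feature = features,
    estimate = beta_raw, se = se_raw,
    odds_ratio = exp(beta_raw),
    ci_low = exp(beta_raw - qnorm(0.975) * se_raw),
    ci_high = exp(beta_raw + qnorm(0.975) * se_raw),
    p_value = 2 * pnorm(-abs(zval))
  )
  n_par <- length(features) + (K - 1)
  structure(list(
    coefficients = coefs, cutpoints = theta_raw,
    loglik = core$loglik, aic = -2 * core$loglik + 2 * n_par,
    n = length(y), n_dropped = n_dropped,
    features = features, level_order = level_order,
    estimate_std = core$beta_std, se_std = core$se_std,
    X = X, y = y, K = K
  ), class = "ordinal_qc_fit")
}

#' @export
print.ordinal_qc_fit <- function(x, ...) {
  cat("Proportional-odds QC model:", length(x$features), "features, n =", x$n,
      "\n  logLik =", format(x$loglik), " AIC =", format(x$aic), "\n")
  print(x$coefficients)
  invisible(x)
}

# refit on a feature subset of an existing fit, warm-started from the parent
# estimates (standardization is per call, so dropping a column keeps the
# remaining standardized coefficients comparable)
refit_subset <- function(fit, features) {
  keep <- match(features, fit$features)
  theta_std <- fit$cutpoints - sum(fit$estimate_std * colMeans(fit$X) / apply(fit$X, 2, sd))
  init <- c(theta_std, fit$estimate_std[keep])
  fit_ordinal(
    data = tibble::as_tibble(cbind(as.data.frame(fit$X),
                                   .qc_label = fit$y)),
    label = ".qc_label", features = features,
    level_order = fit$level_order,
    .init_std = init
  )
}

#' Backward feature elimination by AIC
#'
#' Starting from a full proportional-odds fit, repeatedly removes the single
#' feature whose removal most decreases the AIC; stops when no removal
#' decreases it. The reduced model's AIC is therefore never above the full
#' model's.
#'
#' @param fit An [fit_ordinal()] result with at least one feature.
#' @return A list of class `aic_elimination`: `fit` (the reduced
#'   `ordinal_qc_fit`), `removed` (features in removal order) and `log`
#'   (tibble with `step`, `removed`, `aic`; step 0 is the full model).
#' @export
backward_eliminate_aic <- function(fit) {
  stopifnot(inherits(fit, "ordinal_qc_fit"))
  current <- fit
  log <- tibble::tibble(step = 0L, removed = NA_character_, aic = fit$aic)
  removed <- character()
  repeat {
    feats <- current$features
    if (length(feats) <= 1L) break
    cand <- purrr::map(feats, function(f) refit_subset(fit, setdiff(feats, f)))
    aics <- purrr::map_dbl(cand, "aic")
    best <- which.min(aics)
    if (aics[best] >= current$aic) break
    removed <- c(removed, feats[best])
    current <- cand[[best]]
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = length(removed), removed = feats[best], aic = current$aic))
  }
  structure(list(fit = current, removed = removed, log = log),
            class = "aic_elimination")
}

#' Likelihood-ratio comparison of nested ordinal models
#'
#' `LR = 2 (logLik_full - logLik_reduced)`, degrees of freedom the parameter
#' difference, p-value from the upper chi-square tail. Both fits must use the
#' same observations and the reduced features must nest in the full ones.
#'
#' @param full,reduced `ordinal_qc_fit` objects.
#' @return A one-row tibble: `lr_statistic`, `df`, `p_value`,
#'   `aic_full`, `aic_reduced`.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "ordinal_qc_fit"), inherits(reduced, "ordinal_qc_fit"))
  if (!all(reduced$features %in% full$features)) {
    stop("models are not nested: reduced features are not a subset of full features",
         call. = FALSE)
  }
  if (full$n != reduced$n) {
    stop("models were fitted on different observation sets", call. = FALSE)
  }
  # nesting guarantees loglik_full >= loglik_reduced; clamp optimizer jitter
  lr <- max(2 * (full$loglik - reduced$loglik), 0)
  df <- length(full$features) - length(reduced$features)
  p <- if (df == 0L) 1 else pchisq(lr, df, lower.tail = FALSE)
  tibble::tibble(lr_statistic = lr, df = df, p_value = p,
                 aic_full = full$aic, aic_reduced = reduced$aic)
}
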