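# Frame-marginal temporal clustering: diagonal-covariance Gaussian mixture
# fitted by EM, segmented wherever consecutive frames change component.

.logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# one EM fit with seeded k-means initialization; diagonal covariance with a
# variance floor
.gmmFit <- function(frames, K, seed, var_floor = 1e-6, max_iter = 200L,
                    tol = 1e-8) {
  N <- nrow(frames); d <- ncol(frames)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(frames, centers = K, iter.max = 50L,
                                       nstart = 1L))
  mu <- unname(km$centers)
  w <- pmax(tabulate(km$cluster, K), 1) / N
  va <- t(vapply(seq_len(K), function(k) {
    idx <- km$cluster == k
    if (sum(idx) > 1L)
      pmax(colMeans((frames[idx, , drop = FALSE] -
                     rep(mu[k, ], each = sum(idx)))^2), var_floor)
    else rep(1, d)
  }, numeric(d)))
  va <- matrix(va, K, d)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step: log N(x | mu_k, diag(va_k)) + log w_k
    lp <- vapply(seq_len(K), function(k) {
      z <- (frames - rep(mu[k, ], each = N))^2
      -0.5 * (d * log(2 * pi) + sum(log(va[k, ])) +
              z %*% (1 / va[k, ])) + log(w[k])
    }, numeric(N))
    lp <- matrix(lp, N, K)
    ll <- sum(.logsumexp(lp))
    r <- exp(lp - .logsumexp(lp))
    # M step
    nk <- colSums(r)
    nk <- pmax(nk, 1e-10)
    w <- nk / N
    mu <- t(r) %*% frames / nk
    for (k in seq_len(K)) {
      z <- (frames - rep(mu[k, ], each = N))^2
      va[k, ] <- pmax(colSums(r[, k] * z) / nk[k], var_floor)
    }
    if (ll - ll_prev < tol && iter > 1L) break
    ll_prev <- ll
  }
  lp <- vapply(seq_len(K), function(k) {
    z <- (frames - rep(mu[k, ], each = N))^2
    -0.5 * (d * log(2 * pi) + sum(log(va[k, ])) + z %*% (1 / va[k, ])) + log(w[k])
  }, numeric(N))
  lp <- matrix(lp, N, K)
  list(loglik = sum(.logsumexp(lp)),
       labels = max.col(lp, ties.method = "first") - 1L,
       mu = mu, va = va, w = w)
}

.gmmSingle <- function(frames, K, seed, var_floor = 1e-6) {
  fit <- .gmmFit(frames, K, seed, var_floor = var_floor)
  seg <- segmentationFromFrameLabels(fit$labels, K = K,
    metadata = list(loglik = fit$loglik, seed = seed))
  list(segmentation = seg, energy = -fit$loglik)
}

#' Temporal segmentation by Gaussian mixture model
#'
#' Fits a `K`-component Gaussian mixture (diagonal covariance, variance floor
#' `1e-6`) to the frames by EM with seeded k-means initialization, keeping the
#' highest-likelihood of `n_init` restarts; every frame takes its
#' maximum-posterior component and the series is cut wherever two consecutive
#' frames belong to different components, so the output typically has many
#' more segments than `K`. A purely frame-marginal method: it ignores
#' temporal ordering entirely.
#'
#' @param X a \linkS4class{FeatureFrames} or channels-x-frames matrix.
#' @param K number of mixture components; must satisfy `K < N`.
#' @param seed base seed; restart `i` uses `seed + i - 1`.
#' @param n_init number of restarts (default 5).
#' @return A \linkS4class{Segmentation}; `metadata` records the restart
#'   energies (negative log-likelihoods).
#' @export
gmmSegment <- function(X, K, seed = 1L, n_init = 5L) {
  m <- if (methods::is(X, "FeatureFrames")) X@X else as.matrix(X)
  K <- as.integer(K)
  if (K >= ncol(m)) stop("K must be smaller than the frame count")
  if (K < 1L) stop("K must be at least 1")
  runWithRestarts("gmm", t(m), K = K, n_init = n_init, base_seed = seed)
}
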