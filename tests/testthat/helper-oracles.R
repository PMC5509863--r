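# Independent oracles and fixture builders shared across the suite. Each
# oracle is a deliberately naive computation (enumeration or literal sum)
# kept separate from the package's own code paths.

# all permutations of 1..n as a matrix, one permutation per row
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# brute-force maximum matched trace over all K! permutations
bruteAssignmentMax <- function(C) {
  P <- allPerms(nrow(C))
  max(apply(P, 1L, function(p) sum(C[cbind(seq_len(nrow(C)), p)])))
}

# exhaustive enumeration of monotone alignment paths for the alignment
# kernel: start at (1,1) with weight 2*f(1,1); steps right/down add f, the
# diagonal step adds 2*f; value = best path weight / (na + nb)
bruteDtak <- function(f) {
  na <- nrow(f); nb <- ncol(f)
  best <- -Inf
  walk <- function(p, q, w) {
    if (p == na && q == nb) {
      best <<- max(best, w)
      return(invisible())
    }
    if (p < na) walk(p + 1L, q, w + f[p + 1L, q])
    if (p < na && q < nb) walk(p + 1L, q + 1L, w + 2 * f[p + 1L, q + 1L])
    if (q < nb) walk(p, q + 1L, w + f[p, q + 1L])
  }
  walk(1L, 1L, 2 * f[1L, 1L])
  best / (na + nb)
}

# literal triple-sum evaluation of the segment-to-centroid distance
naiveSegmentDistance <- function(tau, m, labels, k) {
  idx <- which(labels == k)
  Mk <- length(idx)
  s2 <- 0
  for (j in idx) s2 <- s2 + tau[m, j]
  s3 <- 0
  for (j1 in idx) for (j2 in idx) s3 <- s3 + tau[j1, j2]
  tau[m, m] - 2 * s2 / Mk + s3 / Mk^2
}

# trace form of the clustering objective: tr((I - G'(GG')^{-1}G) tau)
traceObjective <- function(tau, labels, K) {
  M <- length(labels)
  G <- matrix(0, K, M)
  G[cbind(labels + 1L, seq_len(M))] <- 1
  keep <- rowSums(G) > 0
  G <- G[keep, , drop = FALSE]
  P <- t(G) %*% solve(G %*% t(G)) %*% G
  sum(diag((diag(M) - P) %*% tau))
}

# per-frame counting confusion matrix
naiveConfusion <- function(pred_frames, truth_frames, K) {
  C <- matrix(0L, K, K)
  for (i in seq_along(pred_frames))
    C[pred_frames[i] + 1L, truth_frames[i] + 1L] <-
      C[pred_frames[i] + 1L, truth_frames[i] + 1L] + 1L
  C
}

# random valid segmentation of N frames into K clusters
randomSegmentationFixture <- function(N, K, min_seg = 1L) {
  M <- sample(seq.int(K, max(K, min(N %/% min_seg, 12L))), 1L)
  cuts <- sort(sample(seq_len(N - 1L), M - 1L))
  labels <- c(sample.int(K) - 1L,
              sample.int(K, max(0L, M - K), replace = TRUE) - 1L)[seq_len(M)]
  Segmentation(c(0L, cuts, N), labels, K = K)
}

# Gaussian kernel of random low-dimensional points: symmetric, PSD,
# unit-diagonal, entries in (0, 1]
randomKernelFixture <- function(N, d = 2L, sigma = 1) {
  pts <- matrix(rnorm(N * d), N, d)
  D2 <- as.matrix(dist(pts))^2
  F <- exp(-D2 / (2 * sigma^2))
  diag(F) <- 1
  (F + t(F)) / 2
}

# block-diagonal kernel with perfect within-block similarity
plantedKernelFixture <- function(n_blocks = 3L, block = 10L, off = exp(-8)) {
  N <- n_blocks * block
  F <- matrix(off, N, N)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block + 1L):(b * block)
    F[idx, idx] <- 1
  }
  F
}

plantedSegmentationFixture <- function(n_blocks = 3L, block = 10L) {
  Segmentation(seq.int(0L, n_blocks * block, by = block),
               seq_len(n_blocks) - 1L, K = n_blocks)
}

# desk-scale trial shared by the end-to-end tests: ~1000 frames at 1 Hz
makeDeskTrial <- function(seed, profiles = NULL, time_scale = 0.13) {
  cfg <- GeneratorConfig(timeScale = time_scale)
  if (is.null(profiles)) profiles <- defaultTaskProfiles(cfg)
  tr <- generateTrial(cfg, profiles, seed = seed)
  truth <- downsampleSegmentation(tr$truth, rateHz(tr$recording), 1)
  rec <- downsampleRecording(tr$recording, 1)
  list(recording = rec, truth = truth, raw = tr)
}
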