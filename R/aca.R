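# Aligned cluster analysis: kernel k-means over temporal segments with a
# dynamic-programming boundary search, and its two-level hierarchical variant.

# per-cluster statistics from a segment kernel matrix and labels (0-based):
# Mk[k] = segment count, ck[k] = (1/Mk^2) sum_{j1,j2 in k} tau_{j1 j2}
.clusterStats <- function(tau, labels, K) {
  Mk <- numeric(K); ck <- numeric(K)
  for (k in seq_len(K) - 1L) {
    idx <- which(labels == k)
    Mk[k + 1L] <- length(idx)
    if (length(idx))
      ck[k + 1L] <- sum(tau[idx, idx]) / length(idx)^2
  }
  list(Mk = Mk, ck = ck)
}

# distance of every segment to every cluster centroid (Eq. 2, matrix form):
# D2[m, k] = tau_mm - (2/Mk) sum_{j in k} tau_mj + ck
.distanceMatrix <- function(tau, labels, K, st = .clusterStats(tau, labels, K)) {
  M <- length(labels)
  G <- matrix(0, M, K)
  G[cbind(seq_len(M), labels + 1L)] <- 1
  A <- tau %*% G                       # A[m, k] = sum_{j in k} tau_mj
  sweep(-2 * sweep(A, 2L, pmax(st$Mk, 1), "/"), 2L, st$ck, "+") + diag(tau)
}

#' Kernel-space distance between a segment and a cluster centroid
#'
#' Squared distance in the implicit feature space between segment `seg` and
#' the geometric centroid of cluster `k` of `segmentation`:
#' `D2 = tau_mm - (2/M_k) sum_j g_kj tau_mj
#'      + (1/M_k^2) sum_{j1 j2} g_kj1 g_kj2 tau_j1j2`,
#' with every `tau` a DTAK value under `F`. A segment against the cluster
#' containing only itself has distance 0.
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param seg integer `(start, end)` pair, 0-based half-open.
#' @param segmentation a \linkS4class{Segmentation} supplying the cluster
#'   membership.
#' @param k cluster index in `[0, K)`.
#' @return nonnegative scalar.
#' @export
segmentClusterDistance <- function(F, seg, segmentation, k) {
  Fm <- .kernelMat(F)
  seg <- .checkRange(seg, nrow(Fm))
  k <- as.integer(k)
  idx <- which(segmentation@labels == k)
  if (length(idx) == 0L)
    stop(structure(class = c("emptyClusterError", "error", "condition"),
                   list(message = sprintf("cluster %d is empty", k),
                        call = sys.call())))
  starts <- head(segmentation@boundaries, -1L)
  lens <- diff(segmentation@boundaries)
  na <- seg[2L] - seg[1L]
  tmm <- .cpp_dtak(Fm, seg[1L], na, seg[1L], na)
  tmj <- vapply(idx, function(j)
    .cpp_dtak(Fm, seg[1L], na, starts[j], lens[j]), numeric(1L))
  tjj <- .cpp_dtak_matrix(Fm, starts[idx], lens[idx])
  tmm - 2 * sum(tmj) / length(idx) + sum(tjj) / length(idx)^2
}

#' ACA objective (within-cluster segment scatter)
#'
#' `J = sum_k sum_m g_km D2(Q_m, z_k)`: the sum over all segments of the
#' kernel-space squared distance to their own cluster centroid
#' (see [segmentClusterDistance()]). Equals the trace form
#' `tr((I - G'(GG')^{-1}G) tau)` on the segment kernel matrix.
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param segmentation a labeled \linkS4class{Segmentation}.
#' @return nonnegative scalar `J`.
#' @export
acaObjective <- function(F, segmentation) {
  tau <- dtakMatrix(F, segmentation)
  .objectiveFromTau(tau, segmentation@labels, segmentation@K)
}

.objectiveFromTau <- function(tau, labels, K) {
  st <- .clusterStats(tau, labels, K)
  D2 <- .distanceMatrix(tau, labels, K, st)
  sum(D2[cbind(seq_along(labels), labels + 1L)])
}

# random initial segmentation: lengths uniform over the feasible subset of
# [l_min, l_max] (feasible = the remainder can still be tiled and the frame
# span stays within span_max), random labels
.randomSegmentation <- function(N, l_min, l_max, K, unit_len = rep(1L, N),
                                span_max = l_max) {
  bounds <- 0L
  rem <- N
  while (rem > 0L) {
    at <- N - rem
    cand <- seq.int(l_min, min(l_max, rem))
    cand <- cand[rem - cand == 0L | rem - cand >= l_min]
    if (length(cand))
      cand <- cand[cumsum(unit_len[(at + 1L):(at + max(cand))])[cand] <= span_max]
    if (length(cand) == 0L)
      stop("no segmentation with lengths in [l_min, l_max] tiles ", N, " frames")
    l <- if (length(cand) == 1L) cand else sample(cand, 1L)
    bounds <- c(bounds, bounds[length(bounds)] + l)
    rem <- rem - l
  }
  M <- length(bounds) - 1L
  Segmentation(bounds, sample.int(K, M, replace = TRUE) - 1L, K = K)
}

# one batch reassignment pass + empty-cluster re-seeding (the farthest
# segment from its own centroid seeds each empty cluster)
.reassign <- function(tau, labels, K) {
  M <- length(labels)
  D2 <- .distanceMatrix(tau, labels, K)
  labels <- max.col(-D2, ties.method = "first") - 1L
  repeat {
    empty <- setdiff(seq_len(K) - 1L, unique(labels))
    if (length(empty) == 0L || M < K) break
    D2 <- .distanceMatrix(tau, labels, K)
    own <- D2[cbind(seq_len(M), labels + 1L)]
    # never empty another cluster while re-seeding
    movable <- which(tabulate(labels + 1L, K)[labels + 1L] > 1L)
    if (length(movable) == 0L) break
    m <- movable[which.max(own[movable])]
    labels[m] <- empty[1L]
  }
  labels
}

.acaSingle <- function(Fm, config, seed, unit_len = NULL, span_max = NULL) {
  N <- nrow(Fm)
  K <- config@K
  if (N < K * config@lMin)
    stop("N (", N, ") must be at least K * lMin (", K * config@lMin, ")")
  if (is.null(unit_len)) unit_len <- rep(1L, N)
  if (is.null(span_max)) span_max <- config@lMax
  set.seed(seed)
  seg <- .randomSegmentation(N, config@lMin, config@lMax, K, unit_len, span_max)
  starts <- head(seg@boundaries, -1L); lens <- diff(seg@boundaries)
  labels <- seg@labels
  trace <- numeric(0L)
  J_prev <- Inf
  for (iter in seq_len(config@maxIter)) {
    tau <- .cpp_dtak_matrix(Fm, starts, lens)
    labels <- .reassign(tau, labels, K)
    J <- .objectiveFromTau(tau, labels, K)
    trace <- c(trace, J)
    if (J_prev - J < config@tol) break
    J_prev <- J
    st <- .clusterStats(tau, labels, K)
    dp <- .cpp_boundary_dp(Fm, starts, lens, labels, K,
                           config@lMin, config@lMax, st$Mk, st$ck,
                           unit_len, span_max)
    starts <- head(dp$boundaries, -1L); lens <- diff(dp$boundaries)
    labels <- dp$labels
  }
  seg <- Segmentation(c(starts, N), labels, K = K,
                      metadata = list(objective = J, trace = trace, seed = seed))
  list(segmentation = seg, energy = J)
}

#' Aligned cluster analysis
#'
#' Temporal clustering by coordinate descent on the ACA objective
#' (see [acaObjective()]): random initial boundaries with lengths uniform in
#' `[lMin, lMax]` and random labels; alternating (a) reassignment of every
#' segment to its nearest cluster centroid in DTAK kernel space, with empty
#' clusters re-seeded by the segment farthest from its own centroid, and (b)
#' a dynamic-programming search over segment boundaries (all lengths kept
#' within `[lMin, lMax]`; ties broken toward the longer segment, then the
#' smaller cluster). The objective is non-increasing across iterations;
#' `config@nInit` seeded restarts are run and the minimum-energy solution
#' returned. The returned segmentation's `metadata` holds the objective, its
#' per-iteration trace, and all restart energies.
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param config an [ACAConfig-class].
#' @param seed base seed; restart `i` uses `seed + i - 1`.
#' @return A \linkS4class{Segmentation}.
#' @export
aca <- function(F, config = ACAConfig(), seed = 1L) {
  runWithRestarts("aca", F, config = config, n_init = config@nInit,
                  base_seed = seed)
}

.hacaSingle <- function(Fm, config, level1_K, l_max_1, l_max_2, seed) {
  cfg1 <- ACAConfig(K = level1_K, lMin = config@lMin, lMax = l_max_1,
                    maxIter = config@maxIter, tol = config@tol, nInit = 1L)
  lvl1 <- .acaSingle(Fm, cfg1, seed)
  seg1 <- lvl1$segmentation
  M1 <- nSegments(seg1)
  if (M1 < config@K)
    stop("level 1 produced ", M1, " segments, fewer than K = ", config@K)
  starts1 <- head(seg1@boundaries, -1L); lens1 <- diff(seg1@boundaries)
  F2 <- .cpp_dtak_matrix(Fm, starts1, lens1)  # reduced kernel, unit diagonal
  # level-2 segments merge level-1 segments but stay within l_max_2 *frames*
  cfg2 <- ACAConfig(K = config@K, lMin = 1L, lMax = min(l_max_2, M1),
                    maxIter = config@maxIter, tol = config@tol, nInit = 1L)
  lvl2 <- .acaSingle(F2, cfg2, seed + 1000L, unit_len = as.integer(lens1),
                     span_max = l_max_2)
  seg2 <- lvl2$segmentation
  # expand level-2 boundaries (in level-1 segment units) back to frames
  bounds <- seg1@boundaries[seg2@boundaries + 1L]
  seg <- Segmentation(bounds, seg2@labels, K = config@K,
                      metadata = list(objective = lvl2$energy,
                                      level1_objective = lvl1$energy,
                                      level1_segments = M1, seed = seed))
  list(segmentation = seg, energy = lvl2$energy)
}

#' Hierarchical aligned cluster analysis
#'
#' Two-level ACA at increasing temporal scales: level 1 runs ACA with a finer
#' motif vocabulary (`level1_K` clusters, maximum segment length `l_max_1`
#' frames); level 2 builds the reduced kernel `F2[a, b] = dtak(F, Q_a, Q_b)`
#' over the level-1 segments and re-runs ACA on it with the target `K`,
#' merging whole level-1 segments while keeping every level-2 segment within
#' `l_max_2` frames of total span, then expands the level-2 labels back to
#' frames. The hierarchy searches small temporal scales first and propagates
#' the result upward, cutting the cost of the boundary search. Both length
#' bounds are in frames, with the study's ordering
#' `l_max_1 = 20 < l_max_2 = 30`. Restart energy is the level-2 objective.
#'
#' @param F a \linkS4class{FrameKernel} or plain kernel matrix.
#' @param config an [ACAConfig-class]; `config@K` is the output cluster count.
#' @param level1_K level-1 cluster count (default `2 * config@K`).
#' @param l_max_1 level-1 maximum segment length in frames (default 20).
#' @param l_max_2 level-2 maximum segment span in frames (default 30).
#' @param seed base seed; restart `i` uses `seed + i - 1`.
#' @return A \linkS4class{Segmentation} on the original frames.
#' @export
haca <- function(F, config = ACAConfig(), level1_K = 2L * config@K,
                 l_max_1 = 20L, l_max_2 = 30L, seed = 1L) {
  if (level1_K < config@K)
    stop("level1_K (", level1_K, ") must be at least the target K (",
         config@K, ")")
  runWithRestarts("haca", F, config = config, n_init = config@nInit,
                  base_seed = seed, level1_K = as.integer(level1_K),
                  l_max_1 = as.integer(l_max_1), l_max_2 = as.integer(l_max_2))
}
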