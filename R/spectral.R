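# Spectral clustering of frames on the Gaussian similarity graph, with the
# normalized symmetric Laplacian embedding.

.spectralEmbedding <- function(Fm, K) {
  deg <- rowSums(Fm)
  if (any(deg <= 0))
    stop("similarity graph has a zero-degree frame; the normalized Laplacian ",
         "is undefined")
  dinv <- 1 / sqrt(deg)
  A <- Fm * (dinv %o% dinv)            # D^{-1/2} F D^{-1/2}
  ev <- eigen(A, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(K), drop = FALSE]  # K smallest-Laplacian modes
  rn <- sqrt(rowSums(emb^2))
  rn[rn == 0] <- 1
  emb / rn
}

.scSingle <- function(emb, K, seed) {
  set.seed(seed)
  best <- NULL
  for (r in 1:10) {
    km <- suppressWarnings(stats::kmeans(emb, centers = K, iter.max = 100L,
                                         nstart = 1L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  seg <- segmentationFromFrameLabels(best$cluster - 1L, K = K,
    metadata = list(inertia = best$tot.withinss, seed = seed))
  list(segmentation = seg, energy = best$tot.withinss)
}

#' Temporal segmentation by spectral clustering
#'
#' Builds the Gaussian similarity graph over frames (see [frameKernel()]),
#' embeds each frame in the `K` leading eigenvectors of the normalized
#' affinity `D^{-1/2} F D^{-1/2}` (equivalently the `K` smallest eigenvalues
#' of the symmetric normalized Laplacian), row-normalizes the embedding, and
#' partitions it with seeded k-means (10 restarts per run). Per-frame labels
#' are then cut into maximal constant runs.
#'
#' @param X a \linkS4class{FeatureFrames} or channels-x-frames matrix.
#' @param K number of clusters; must satisfy `K < N`.
#' @param sigma kernel bandwidth or `"auto"` (median heuristic).
#' @param seed base seed; restart `i` uses `seed + i - 1`.
#' @param n_init number of outer restarts for the minimum-energy protocol
#'   (energy = k-means inertia in the embedded space).
#' @return A \linkS4class{Segmentation}.
#' @export
spectralSegment <- function(X, K, sigma = "auto", seed = 1L, n_init = 1L) {
  m <- if (methods::is(X, "FeatureFrames")) X@X else as.matrix(X)
  K <- as.integer(K)
  if (K >= ncol(m)) stop("K must be smaller than the frame count")
  if (K < 1L) stop("K must be at least 1")
  Fk <- frameKernel(m, sigma = sigma, seed = seed)
  emb <- .spectralEmbedding(Fk@F, K)
  runWithRestarts("sc", emb, K = K, n_init = n_init, base_seed = seed)
}
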