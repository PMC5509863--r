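# Preprocessing: temporal reduction, channel normalization, per-trial k-means
# symbolization, and construction of the Gaussian frame kernel matrix shared
# by spectral clustering and the segment-level alignment kernel.

#' Downsample a recording to a lower frame rate
#'
#' Kinematic channels are averaged over non-overlapping windows of
#' `round(rate_hz / target_hz)` frames; binary event channels take the
#' window-wise maximum (any-on), so a single activation anywhere in a window
#' survives the reduction. The last window may be short. With
#' `target_hz == rate_hz` this is the identity.
#'
#' @param rec a \linkS4class{ProcedureRecording}.
#' @param target_hz target rate in Hz, `0 < target_hz <= rateHz(rec)`.
#' @return A `ProcedureRecording` with `ceil(N / window)` frames.
#' @seealso [downsampleSegmentation()] for reducing labels consistently.
#' @export
downsampleRecording <- function(rec, target_hz) {
  if (target_hz <= 0) stop("target_hz must be positive")
  if (target_hz > rateHz(rec)) stop("target_hz must not exceed the recording rate")
  w <- max(1L, as.integer(round(rateHz(rec) / target_hz)))
  if (w == 1L) return(rec)
  N <- ncol(rec)
  grp <- rep(seq_len(ceiling(N / w)), each = w)[seq_len(N)]
  cnt <- tabulate(grp)
  kin_mean <- function(m) t(rowsum(t(m), grp) / cnt)
  ev <- evtData(rec)
  ev_any <- t(rowsum(t(ev), grp))
  ev_any[ev_any > 0] <- 1
  ProcedureRecording(kin_mean(sscData(rec)), kin_mean(siData(rec)), ev_any,
                     rate_hz = rateHz(rec) / w, trial_id = trialId(rec))
}

#' Downsample a segmentation by per-window majority vote
#'
#' Reduces a frame-level segmentation by the same window used by
#' [downsampleRecording()]: each window takes the label held by the majority
#' of its frames, ties broken toward the label occurring earlier in the
#' window (hence toward the earlier task).
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param rate_hz original rate of the segmentation's frames.
#' @param target_hz target rate.
#' @return A `Segmentation` over the reduced frame count.
#' @export
downsampleSegmentation <- function(seg, rate_hz, target_hz) {
  if (target_hz <= 0) stop("target_hz must be positive")
  w <- max(1L, as.integer(round(rate_hz / target_hz)))
  if (w == 1L) return(seg)
  lab <- frameLabels(seg)
  N <- length(lab)
  grp <- rep(seq_len(ceiling(N / w)), each = w)[seq_len(N)]
  voted <- vapply(split(lab, grp), function(v) {
    tb <- table(factor(v, levels = unique(v)))  # unique() keeps window order
    as.integer(names(tb)[which.max(tb)])
  }, integer(1L))
  segmentationFromFrameLabels(voted, K = seg@K)
}

#' Z-score each channel of a feature matrix
#'
#' Centers every channel to mean 0 and scales it to unit population standard
#' deviation (`sd` computed with denominator `N`). Constant channels map to
#' all-zeros rather than `NaN`. Idempotent.
#'
#' @param X a \linkS4class{FeatureFrames} or a plain channels-x-frames matrix.
#' @return Same type as the input, normalized.
#' @export
zscoreChannels <- function(X) {
  ff <- methods::is(X, "FeatureFrames")
  m <- if (ff) X@X else as.matrix(X)
  mu <- rowMeans(m)
  cen <- m - mu
  s <- sqrt(rowMeans(cen^2))
  s[s == 0] <- Inf  # constant channel -> zeros
  out <- cen / s
  if (ff) methods::new("FeatureFrames", X = out, featureSet = X@featureSet,
                       rateHz = X@rateHz)
  else out
}

#' Symbolize frames by per-trial k-means
#'
#' Quantizes the `d x N` frames into `n_symbols` discrete symbols by k-means
#' with 10 seeded restarts (Lloyd iterations from random distinct-frame
#' starts), keeping the lowest-inertia run. Symbolization is per trial: no
#' codebook is shared across trials.
#'
#' @param X a \linkS4class{FeatureFrames} or channels-x-frames matrix.
#' @param n_symbols number of symbols (the study used 15; its search grid was
#'   10, 15, 20, 50, 100, 150, 200).
#' @param seed integer seed.
#' @return A \linkS4class{SymbolSequence}.
#' @export
symbolize <- function(X, n_symbols, seed = 1L) {
  m <- if (methods::is(X, "FeatureFrames")) X@X else as.matrix(X)
  frames <- t(m)
  N <- nrow(frames)
  n_symbols <- as.integer(n_symbols)
  if (n_symbols < 2L) stop("n_symbols must be at least 2")
  if (n_symbols > N) stop("n_symbols (", n_symbols, ") must not exceed the frame count (", N, ")")
  u <- unique(frames)
  set.seed(seed)
  if (nrow(u) <= n_symbols) {
    # fewer distinct frames than symbols: each distinct frame is its own
    # symbol (codebook padded by repetition), inertia 0
    sym <- match(asplit(frames, 1L), asplit(u, 1L)) - 1L
    cent <- u[c(seq_len(nrow(u)), rep(nrow(u), n_symbols - nrow(u))), , drop = FALSE]
    return(methods::new("SymbolSequence", symbols = as.integer(sym),
                        centroids = cent, nSymbols = n_symbols, inertia = 0))
  }
  best <- NULL
  for (r in 1:10) {
    centers <- u[sample.int(nrow(u), n_symbols), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(frames, centers = centers,
                                         iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  methods::new("SymbolSequence", symbols = as.integer(best$cluster) - 1L,
               centroids = unname(best$centers), nSymbols = n_symbols,
               inertia = best$tot.withinss)
}

#' Build the per-frame feature representation for clustering
#'
#' Kinematic channels of the requested streams are concatenated, z-scored and
#' symbolized; each frame is then replaced by its symbol's centroid vector
#' (not a one-hot code), so the Gaussian kernel retains graded between-symbol
#' similarity. If `EVT` is part of the feature set, the 8 raw binary event
#' channels are appended unmodified. The result is the matrix the kernels,
#' GMM and spectral clustering operate on. `EVT` alone is not a valid feature
#' set.
#'
#' @param rec a \linkS4class{ProcedureRecording} (typically already
#'   downsampled, see [downsampleRecording()]).
#' @param feature_set one of `"SSC"`, `"SI"`, `"SSC+SI"`, `"SSC+EVT"`,
#'   `"SI+EVT"`, `"SSC+SI+EVT"`.
#' @param n_symbols symbol count for [symbolize()] (default 15).
#' @param seed integer seed for the symbolization restarts.
#' @return A \linkS4class{FeatureFrames}.
#' @export
buildFeatures <- function(rec, feature_set, n_symbols = 15L, seed = 1L) {
  if (!feature_set %in% .FEATURE_SETS)
    stop("unknown feature_set '", feature_set, "'; must be one of: ",
         paste(.FEATURE_SETS, collapse = ", "))
  parts <- strsplit(feature_set, "+", fixed = TRUE)[[1L]]
  kin <- NULL
  if ("SSC" %in% parts) kin <- rbind(kin, sscData(rec))
  if ("SI" %in% parts) kin <- rbind(kin, siData(rec))
  kin <- zscoreChannels(kin)
  ss <- symbolize(kin, n_symbols = n_symbols, seed = seed)
  Xq <- t(ss@centroids[ss@symbols + 1L, , drop = FALSE])
  if ("EVT" %in% parts) Xq <- rbind(Xq, evtData(rec))
  rownames(Xq) <- NULL
  methods::new("FeatureFrames", X = Xq, featureSet = feature_set,
               rateHz = rateHz(rec))
}

#' Gaussian frame kernel matrix
#'
#' Computes `F[i, j] = exp(-||t_i - t_j||^2 / (2 sigma^2))` over all frame
#' pairs of `X`. With `sigma = "auto"` the bandwidth is the median pairwise
#' Euclidean distance over a seeded subsample of at most 2000 frames, zero
#' distances excluded. The same matrix is the spectral-clustering similarity
#' graph.
#'
#' @param X a \linkS4class{FeatureFrames} or channels-x-frames matrix.
#' @param sigma bandwidth (> 0), or `"auto"` for the median heuristic.
#' @param seed seed for the auto-bandwidth subsample.
#' @return A \linkS4class{FrameKernel}.
#' @export
frameKernel <- function(X, sigma = "auto", seed = 1L) {
  m <- if (methods::is(X, "FeatureFrames")) X@X else as.matrix(X)
  frames <- t(m)
  N <- nrow(frames)
  if (N < 2L) stop("at least two frames are required")
  if (identical(sigma, "auto") || identical(sigma, "AUTO")) {
    set.seed(seed)
    idx <- if (N > 2000L) sort(sample.int(N, 2000L)) else seq_len(N)
    pd <- as.numeric(stats::dist(frames[idx, , drop = FALSE]))
    pd <- pd[pd > 0]
    if (length(pd) == 0L)
      stop("all frames are identical; the median heuristic is undefined - ",
           "supply an explicit sigma")
    sigma <- stats::median(pd)
  }
  sigma <- as.numeric(sigma)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be a positive scalar")
  D2 <- as.matrix(stats::dist(frames))^2
  F <- exp(-D2 / (2 * sigma^2))
  F <- (F + t(F)) / 2
  diag(F) <- 1
  F[F < 1e-300] <- 1e-300  # keep entries strictly positive under underflow
  methods::new("FrameKernel", F = F, sigma = sigma)
}
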