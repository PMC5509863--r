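#' Construct a ProcedureRecording from the three stream matrices
#'
#' @param ssc numeric matrix, console kinematics, channels x frames.
#' @param si numeric matrix, patient-side kinematics, channels x frames.
#' @param evt binary matrix (0/1), 8 x frames, system events.
#' @param rate_hz sampling rate in Hz.
#' @param trial_id trial identifier string.
#' @return A \linkS4class{ProcedureRecording}.
#' @examples
#' rec <- ProcedureRecording(matrix(rnorm(60), 6), matrix(rnorm(80), 8),
#'                           matrix(rbinom(80, 1, 0.1), 8), rate_hz = 50)
#' rateHz(rec)
#' @export
ProcedureRecording <- function(ssc, si, evt, rate_hz, trial_id = "trial") {
  ssc <- as.matrix(ssc); si <- as.matrix(si); evt <- as.matrix(evt)
  n <- unique(c(ncol(ssc), ncol(si), ncol(evt)))
  if (length(n) != 1L)
    stop("ssc, si and evt must share the same frame count, got: ",
         paste(c(ncol(ssc), ncol(si), ncol(evt)), collapse = "/"))
  storage.mode(ssc) <- "double"; storage.mode(si) <- "double"
  storage.mode(evt) <- "double"
  sig <- rbind(ssc, si, evt)
  rownames(sig) <- c(sprintf("ssc_%02d", seq_len(nrow(ssc))),
                     sprintf("si_%02d", seq_len(nrow(si))),
                     sprintf("evt_%d", seq_len(nrow(evt))))
  colnames(sig) <- NULL
  rd <- S4Vectors::DataFrame(stream = rep(c("SSC", "SI", "EVT"),
                                          c(nrow(ssc), nrow(si), nrow(evt))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig), rowData = rd,
    metadata = list(rate_hz = rate_hz, trial_id = trial_id))
  methods::new("ProcedureRecording", se)
}

.streamData <- function(x, stream) {
  keep <- SummarizedExperiment::rowData(x)$stream == stream
  SummarizedExperiment::assay(x, "signal")[keep, , drop = FALSE]
}

#' @describeIn ProcedureRecording console (surgeon-side) kinematics, d x N
#' @param x a `ProcedureRecording`.
#' @export
sscData <- function(x) .streamData(x, "SSC")

#' @describeIn ProcedureRecording patient-side kinematics, d x N
#' @export
siData <- function(x) .streamData(x, "SI")

#' @describeIn ProcedureRecording binary system events, 8 x N
#' @export
evtData <- function(x) .streamData(x, "EVT")

#' @describeIn ProcedureRecording sampling rate in Hz
#' @export
rateHz <- function(x) S4Vectors::metadata(x)$rate_hz

#' @describeIn ProcedureRecording trial identifier
#' @export
trialId <- function(x) S4Vectors::metadata(x)$trial_id

#' Construct a Segmentation
#'
#' @param boundaries integer vector of length `M + 1`, 0-based half-open
#'   segment boundaries: first element 0, last element `N`.
#' @param labels integer vector of `M` per-segment cluster labels in `[0, K)`.
#' @param K cluster count; defaults to `max(labels) + 1`.
#' @param metadata optional provenance list.
#' @return A \linkS4class{Segmentation}.
#' @examples
#' seg <- Segmentation(c(0, 4, 10), c(0, 1))
#' frameLabels(seg)
#' @export
Segmentation <- function(boundaries, labels, K = max(labels) + 1L,
                         metadata = list()) {
  methods::new("Segmentation",
    boundaries = as.integer(boundaries), labels = as.integer(labels),
    K = as.integer(K), N = as.integer(boundaries[length(boundaries)]),
    metadata = metadata)
}

#' @describeIn Segmentation number of segments `M`
#' @param x a `Segmentation`.
#' @export
nSegments <- function(x) length(x@labels)

#' @describeIn Segmentation frame count `N`
#' @export
nFrames <- function(x) x@N

#' @describeIn Segmentation expand to a length-`N` vector of per-frame labels
#' @export
frameLabels <- function(x) rep(x@labels, diff(x@boundaries))

#' @describeIn Segmentation segments as an [IRanges::IRanges] with a `label`
#'   metadata column (1-based closed ranges)
#' @export
segmentRanges <- function(x) {
  r <- IRanges::IRanges(start = head(x@boundaries, -1L) + 1L,
                        end = tail(x@boundaries, -1L))
  S4Vectors::mcols(r)$label <- x@labels
  r
}

#' @describeIn Segmentation per-segment lengths in frames
#' @export
segmentLengths <- function(x) diff(x@boundaries)

#' Build a Segmentation from a per-frame label vector
#'
#' Maximal runs of a constant label become segments, so the number of
#' segments is the number of label runs (typically more than `K` for
#' frame-wise algorithms such as GMM or spectral clustering).
#'
#' @param labels integer vector of per-frame labels in `[0, K)`.
#' @param K cluster count; defaults to `max(labels) + 1`.
#' @param metadata optional provenance list.
#' @return A \linkS4class{Segmentation}.
#' @examples
#' segmentationFromFrameLabels(c(0, 0, 1, 1, 0))  # s = 0,2,4,5; g = 0,1,0
#' @export
segmentationFromFrameLabels <- function(labels, K = max(labels) + 1L,
                                        metadata = list()) {
  r <- rle(as.integer(labels))
  Segmentation(c(0L, cumsum(r$lengths)), r$values, K = K, metadata = metadata)
}

#' Construct a GeneratorConfig
#'
#' @param sampleRateHz sampling rate in Hz (default 50, the system's rate).
#' @param timeScale duration shrink factor in (0, 1]; 1 reproduces the study's
#'   task-duration statistics, smaller values shrink every task
#'   proportionally for fast desk-scale runs.
#' @param dSsc,dSi synthetic kinematic channel counts (defaults 12 and 24).
#' @param separation emission-mean separation in noise-sd units (default 6).
#' @return A \linkS4class{GeneratorConfig}.
#' @export
GeneratorConfig <- function(sampleRateHz = 50, timeScale = 1,
                            dSsc = 12L, dSi = 24L, separation = 6) {
  methods::new("GeneratorConfig", nTasks = 5L, taskOrder = 0:4,
    sampleRateHz = sampleRateHz, timeScale = timeScale,
    dSsc = as.integer(dSsc), dSi = as.integer(dSi),
    dEvt = .N_EVENT_CHANNELS, separation = separation)
}

#' Construct an ACAConfig
#'
#' Defaults follow the study setup: `lMax = 30` frames for plain ACA,
#' 5 random restarts with the minimum-energy solution kept, and a minimum
#' segment length of 3 frames.
#'
#' @param K number of clusters (default 5, one per surgical task).
#' @param lMin,lMax segment length bounds in frames.
#' @param maxIter iteration cap for the coordinate descent.
#' @param tol convergence tolerance on the objective decrease.
#' @param nInit number of seeded random restarts.
#' @return An \linkS4class{ACAConfig}.
#' @export
ACAConfig <- function(K = 5L, lMin = 3L, lMax = 30L, maxIter = 50L,
                      tol = 1e-7, nInit = 5L) {
  methods::new("ACAConfig", K = as.integer(K), lMin = as.integer(lMin),
    lMax = as.integer(lMax), maxIter = as.integer(maxIter), tol = tol,
    nInit = as.integer(nInit))
}

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d frames, %d segments, K = %d\n",
              object@N, nSegments(object), object@K))
  m <- min(nSegments(object), 8L)
  for (i in seq_len(m))
    cat(sprintf("  [%d, %d) -> %d\n", object@boundaries[i],
                object@boundaries[i + 1L], object@labels[i]))
  if (nSegments(object) > m) cat("  ...\n")
})

setMethod("show", "FrameKernel", function(object) {
  cat(sprintf("FrameKernel: %d x %d, sigma = %.4g\n",
              nrow(object@F), ncol(object@F), object@sigma))
})

setMethod("show", "FeatureFrames", function(object) {
  cat(sprintf("FeatureFrames: %d channels x %d frames, set = %s, %.3g Hz\n",
              nrow(object@X), ncol(object@X),
              if (nzchar(object@featureSet)) object@featureSet else "<raw>",
              object@rateHz))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: K = %d, N = %d\n",
              nrow(object@counts), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "TaskMetrics", function(object) {
  df <- data.frame(task = seq_along(object@precision) - 1L,
                   precision = round(object@precision, 4),
                   recall = round(object@recall, 4),
                   f1 = round(object@f1, 4))
  print(df, row.names = FALSE)
  cat(sprintf("macro-F1: %.4f\n", object@macroF1))
})

#' @describeIn FrameKernel the raw kernel matrix
#' @param x a `FrameKernel`.
#' @export
kernelMatrix <- function(x) x@F

#' @describeIn FrameKernel the kernel bandwidth
#' @export
kernelSigma <- function(x) x@sigma

#' @describeIn FeatureFrames the feature matrix (channels x frames)
#' @param x a `FeatureFrames`.
#' @export
featureMatrix <- function(x) x@X

#' @describeIn ConfusionMatrix the count matrix
#' @param x a `ConfusionMatrix`.
#' @export
confusionCounts <- function(x) x@counts

#' @describeIn Segmentation per-segment cluster labels (0-based)
#' @export
segmentLabels <- function(x) x@labels

#' @describeIn Segmentation the boundary vector `s` (0-based, half-open)
#' @export
segmentBoundaries <- function(x) x@boundaries
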