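#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors metadata DataFrame mcols
#' @importFrom stats kmeans rnorm rbinom runif sd dist filter
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib surgseg, .registration = TRUE
NULL

.FEATURE_SETS <- c("SSC", "SI", "SSC+SI", "SSC+EVT", "SI+EVT", "SSC+SI+EVT")
.N_EVENT_CHANNELS <- 8L

#' ProcedureRecording: synchronized system data streams for one trial
#'
#' A \linkS4class{SummarizedExperiment} holding the three synchronized system
#' data streams of one (pseudo-)procedure as rows of a single `signal` assay:
#' surgeon-side-console kinematics (`SSC`), patient-side kinematics (`SI`) and
#' binary system events (`EVT`). `rowData(x)$stream` records which stream each
#' channel belongs to; columns are frames. The sampling rate (Hz) and a trial
#' identifier live in `metadata()`.
#'
#' Use [ProcedureRecording()] to construct one from the three matrices, and
#' [sscData()], [siData()], [evtData()], [rateHz()], [trialId()] to access the
#' parts.
#'
#' @seealso [generateTrial()], [downsampleRecording()], [buildFeatures()]
#' @export
setClass("ProcedureRecording", contains = "SummarizedExperiment")

setValidity("ProcedureRecording", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"stream" %in% colnames(rd))
    msg <- c(msg, "rowData column 'stream' is required")
  else {
    if (!all(rd$stream %in% c("SSC", "SI", "EVT")))
      msg <- c(msg, "stream must be one of SSC, SI, EVT")
    if (sum(rd$stream == "EVT") != .N_EVENT_CHANNELS)
      msg <- c(msg, sprintf("exactly %d EVT channels are required", .N_EVENT_CHANNELS))
    if (length(msg) == 0L) {
      ev <- SummarizedExperiment::assay(object, "signal")[rd$stream == "EVT", , drop = FALSE]
      if (!all(ev %in% c(0, 1)))
        msg <- c(msg, "EVT entries must be binary (0/1)")
    }
  }
  if (ncol(object) < 1L) msg <- c(msg, "at least one frame is required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$rate_hz) || md$rate_hz <= 0)
    msg <- c(msg, "metadata rate_hz must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Segmentation: segment boundaries and per-segment cluster labels
#'
#' Represents a partition of `N` frames into `M` contiguous segments via a
#' boundary vector `s` of length `M + 1` (0-based, half-open: segment `m`
#' covers frames `[s[m], s[m+1])`) and an integer label in `[0, K)` per
#' segment. This is the common currency of the temporal clustering algorithms
#' and the evaluation metrics: ground truth, ACA/HACA/GMM/SC output and the
#' proportional baseline are all `Segmentation` objects.
#'
#' @slot boundaries integer vector of length `M + 1`; `boundaries[1] == 0`,
#'   `boundaries[M + 1] == N`, strictly increasing.
#' @slot labels integer vector of length `M`, values in `[0, K)`.
#' @slot K integer cluster/task count.
#' @slot N integer frame count.
#' @slot metadata list for algorithm provenance (objective traces, energies).
#'
#' @seealso [Segmentation()], [frameLabels()], [segmentRanges()], [nSegments()]
#' @export
setClass("Segmentation",
  representation(boundaries = "integer", labels = "integer",
                 K = "integer", N = "integer", metadata = "list"),
  prototype(metadata = list()))

setValidity("Segmentation", function(object) {
  s <- object@boundaries; g <- object@labels
  msg <- character()
  if (length(s) < 2L) msg <- c(msg, "boundaries must have length >= 2")
  else {
    if (s[1L] != 0L) msg <- c(msg, "boundaries must start at 0")
    if (s[length(s)] != object@N) msg <- c(msg, "boundaries must end at N")
    if (any(diff(s) <= 0L)) msg <- c(msg, "boundaries must be strictly increasing")
  }
  if (length(g) != length(s) - 1L)
    msg <- c(msg, "labels must have one entry per segment")
  if (length(g) && (any(g < 0L) || any(g >= object@K)))
    msg <- c(msg, "labels must lie in [0, K)")
  if (length(msg)) msg else TRUE
})

#' FeatureFrames: per-frame feature representation of a trial
#'
#' The `d x N` real matrix `X` on which the clustering algorithms operate,
#' with a record of which data streams it was built from and the effective
#' sampling rate after any temporal reduction.
#'
#' @slot X numeric matrix, channels x frames.
#' @slot featureSet one of `"SSC"`, `"SI"`, `"SSC+SI"`, `"SSC+EVT"`,
#'   `"SI+EVT"`, `"SSC+SI+EVT"`, or `""` for raw/unspecified.
#' @slot rateHz effective sampling rate in Hz.
#' @export
setClass("FeatureFrames",
  representation(X = "matrix", featureSet = "character", rateHz = "numeric"))

setValidity("FeatureFrames", function(object) {
  msg <- character()
  if (nrow(object@X) < 1L) msg <- c(msg, "at least one channel is required")
  if (ncol(object@X) < 2L) msg <- c(msg, "at least two frames are required")
  if (!object@featureSet %in% c(.FEATURE_SETS, ""))
    msg <- c(msg, "unknown feature set")
  if (length(msg)) msg else TRUE
})

#' SymbolSequence: per-trial k-means symbolization of frames
#'
#' Per-frame discrete symbols from k-means quantization of the
#' (z-scored) kinematic frames, plus the codebook of centroids. Frames are
#' re-embedded as their centroid vectors before kernel construction so the
#' Gaussian kernel retains graded between-symbol similarity.
#'
#' @slot symbols integer vector length `N`, values in `[0, nSymbols)`.
#' @slot centroids numeric matrix `nSymbols x d`.
#' @slot nSymbols integer symbol count.
#' @slot inertia total within-cluster sum of squares of the kept k-means run.
#' @export
setClass("SymbolSequence",
  representation(symbols = "integer", centroids = "matrix",
                 nSymbols = "integer", inertia = "numeric"))

setValidity("SymbolSequence", function(object) {
  msg <- character()
  if (any(object@symbols < 0L) || any(object@symbols >= object@nSymbols))
    msg <- c(msg, "symbols must lie in [0, nSymbols)")
  if (nrow(object@centroids) != object@nSymbols)
    msg <- c(msg, "centroids must have nSymbols rows")
  if (object@inertia < 0) msg <- c(msg, "inertia must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' FrameKernel: Gaussian frame similarity matrix
#'
#' The `N x N` Gaussian kernel matrix `F` with
#' `f_ij = exp(-||t_i - t_j||^2 / (2 sigma^2))`, the similarity between frames
#' `t_i` and `t_j`. The same matrix serves as the spectral-clustering
#' similarity graph and as the frame kernel driving the dynamic time alignment
#' kernel inside ACA/HACA; a block structure along its diagonal signals task
#' boundaries.
#'
#' @slot F numeric matrix `N x N`, symmetric, unit diagonal, entries in (0, 1].
#' @slot sigma kernel bandwidth (> 0).
#' @export
setClass("FrameKernel", representation(F = "matrix", sigma = "numeric"))

setValidity("FrameKernel", function(object) {
  msg <- character()
  F <- object@F
  if (nrow(F) != ncol(F)) msg <- c(msg, "F must be square")
  else {
    if (max(abs(F - t(F))) > 1e-10) msg <- c(msg, "F must be symmetric")
    if (max(abs(diag(F) - 1)) > 1e-10) msg <- c(msg, "F must have unit diagonal")
    if (any(F <= 0) || any(F > 1 + 1e-12)) msg <- c(msg, "entries must lie in (0, 1]")
  }
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: frame-count cross-tabulation of two segmentations
#'
#' `C[i, j]` counts the frames assigned to cluster `i` by the prediction and
#' to task `j` by the ground truth; entries sum to the frame count `N`.
#' Computed as the indicator-matrix product
#' `C = G_out H_out H_true' G_true'`.
#'
#' @slot C nonnegative integer matrix `K x K`.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  if (nrow(object@counts) != ncol(object@counts)) msg <- c(msg, "C must be square")
  if (any(object@counts < 0)) msg <- c(msg, "entries must be nonnegative")
  if (any(object@counts != round(object@counts))) msg <- c(msg, "entries must be integral")
  if (length(msg)) msg else TRUE
})

#' TaskMetrics: per-task precision/recall/F1 under the optimal matching
#'
#' @slot precision per-task precision (may be `NA` for an absent task).
#' @slot recall per-task recall.
#' @slot f1 per-task F1 (`0` where `P + R = 0`, `NA` where undefined).
#' @slot macroF1 unweighted mean of defined per-task F1 values.
#' @slot matching integer vector: predicted cluster matched to each task
#'   (1-based), from the accuracy-optimal Hungarian assignment.
#' @export
setClass("TaskMetrics",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 macroF1 = "numeric", matching = "integer"))

#' TaskProfile: generative description of one surgical task
#'
#' Parameters of the synthetic generator for a single task of the
#' pseudo-procedure: its duration distribution (seconds), the mean level of
#' each kinematic channel while the task is active, the AR(1) smoothness of
#' the latent kinematic dynamics, the innovation noise level, and the
#' per-second activation probability of each of the 8 binary event channels.
#'
#' @slot taskId integer in `[0, 4]`.
#' @slot name task name.
#' @slot meanDurationS mean task duration in seconds (> 0).
#' @slot stdDurationS duration standard deviation in seconds (>= 0).
#' @slot emissionMean numeric vector, one entry per kinematic channel.
#' @slot smoothness AR(1) coefficient of the latent dynamics, in (0, 1).
#' @slot noiseSd innovation standard deviation (> 0).
#' @slot eventRates 8 per-second activation probabilities in `[0, 1]`.
#' @seealso [defaultTaskProfiles()], [overlapDynamicsProfiles()]
#' @export
setClass("TaskProfile",
  representation(taskId = "integer", name = "character",
                 meanDurationS = "numeric", stdDurationS = "numeric",
                 emissionMean = "numeric", smoothness = "numeric",
                 noiseSd = "numeric", eventRates = "numeric"))

setValidity("TaskProfile", function(object) {
  msg <- character()
  if (object@taskId < 0L || object@taskId > 4L) msg <- c(msg, "taskId must be in [0, 4]")
  if (object@meanDurationS <= 0) msg <- c(msg, "meanDurationS must be positive")
  if (object@stdDurationS < 0) msg <- c(msg, "stdDurationS must be nonnegative")
  if (object@smoothness <= 0 || object@smoothness >= 1)
    msg <- c(msg, "smoothness must lie in (0, 1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(object@eventRates) != .N_EVENT_CHANNELS)
    msg <- c(msg, "eventRates must have 8 entries")
  if (any(object@eventRates < 0) || any(object@eventRates > 1))
    msg <- c(msg, "eventRates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: global settings of the pseudo-procedure generator
#'
#' Five tasks in a fixed order form one pseudo-procedure; streams are sampled
#' at `sampleRateHz`. `timeScale` shrinks all task durations proportionally
#' for desk-scale runs. `separation` sets the Euclidean distance between task
#' emission means in units of the innovation noise; `dSsc`/`dSi` choose the
#' synthetic kinematic dimensionalities (the real system emits 56 and 156
#' channels; the defaults are smaller because algorithm behaviour depends on
#' kernel structure, not raw dimensionality). The event stream is always
#' 8-dimensional.
#'
#' @slot nTasks fixed at 5.
#' @slot taskOrder fixed sequence `0:4`.
#' @slot sampleRateHz sampling rate in Hz (default 50).
#' @slot timeScale duration shrink factor in (0, 1].
#' @slot dSsc console kinematic channels (default 12).
#' @slot dSi patient-side kinematic channels (default 24).
#' @slot dEvt event channels, fixed at 8.
#' @slot separation emission-mean separation in noise-sd units (default 6).
#' @seealso [GeneratorConfig()], [generateTrial()]
#' @export
setClass("GeneratorConfig",
  representation(nTasks = "integer", taskOrder = "integer",
                 sampleRateHz = "numeric", timeScale = "numeric",
                 dSsc = "integer", dSi = "integer", dEvt = "integer",
                 separation = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nTasks != 5L) msg <- c(msg, "nTasks is fixed at 5")
  if (!identical(object@taskOrder, 0:4)) msg <- c(msg, "taskOrder is fixed at 0:4")
  if (object@sampleRateHz <= 0) msg <- c(msg, "sampleRateHz must be positive")
  if (object@timeScale <= 0 || object@timeScale > 1)
    msg <- c(msg, "timeScale must lie in (0, 1]")
  if (object@dSsc < 5L || object@dSi < 5L)
    msg <- c(msg, "kinematic dimensions must be at least 5")
  if (object@dEvt != .N_EVENT_CHANNELS) msg <- c(msg, "dEvt is fixed at 8")
  if (object@separation < 0) msg <- c(msg, "separation must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ACAConfig: parameters of the aligned cluster analysis optimizer
#'
#' @slot K number of clusters.
#' @slot lMin minimum segment length in frames (default 3).
#' @slot lMax maximum segment length in frames (default 30 for plain ACA).
#' @slot maxIter coordinate-descent iteration cap (default 50).
#' @slot tol stop when the objective decreases by less than this (default 1e-7).
#' @slot nInit number of random restarts (default 5).
#' @seealso [ACAConfig()], [aca()], [haca()]
#' @export
setClass("ACAConfig",
  representation(K = "integer", lMin = "integer", lMax = "integer",
                 maxIter = "integer", tol = "numeric", nInit = "integer"))

setValidity("ACAConfig", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be at least 1")
  if (object@lMin < 1L) msg <- c(msg, "lMin must be at least 1")
  if (object@lMax < object@lMin) msg <- c(msg, "lMax must be >= lMin")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be at least 1")
  if (object@tol < 0) msg <- c(msg, "tol must be nonnegative")
  if (object@nInit < 1L) msg <- c(msg, "nInit must be at least 1")
  if (length(msg)) msg else TRUE
})
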