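# Synthetic pseudo-procedure generation and plain-text trial containers.
#
# The generator emulates the statistical structure of the study setting: five
# surgical training tasks in a fixed order form one pseudo-procedure; task
# durations are Normal with the study's per-task means/sds; kinematics follow
# smooth task-specific AR(1) dynamics; binary events fire as task-specific
# Bernoulli processes. It does not emulate joint-space geometry, tool
# identities or camera pose.

.TASK_NAMES <- c("Two-handed robotic suturing",
                 "Uterine horn dissection",
                 "Suspensary ligament dissection",
                 "Running robotic suturing",
                 "Rectal artery skeletonization and clipping")
.TASK_MEAN_S <- c(1329.2, 2159.7, 1999.3, 617.6, 1474.7)
.TASK_SD_S   <- c(733.9, 492.6, 1097.5, 126.7, 276.3)

.defaultEventRates <- function() {
  # per-second activation probabilities, one row per task; each task gets a
  # dominant channel plus a secondary one so EVT alone carries task identity
  r <- matrix(0.05, 5L, .N_EVENT_CHANNELS)
  for (t in 1:5) {
    r[t, t] <- 0.6
    r[t, 6L + ((t - 1L) %% 3L)] <- 0.3
  }
  r
}

.emissionMeans <- function(config, noiseSd = 1) {
  # task means differ in one SSC and one SI coordinate each, so that any pair
  # of tasks is `separation * noiseSd` apart in the full kinematic space
  d <- config@dSsc + config@dSi
  a <- config@separation * noiseSd / 2
  mu <- matrix(0, 5L, d)
  for (t in 1:5) {
    mu[t, t] <- a                    # SSC block
    mu[t, config@dSsc + t] <- a      # SI block
  }
  mu
}

#' Default task profiles matching the study's duration statistics
#'
#' Returns the five [TaskProfile-class] objects of the pseudo-procedure with
#' the study's per-task duration means and standard deviations, emission means
#' separated by `config@separation` noise units, a common AR(1) smoothness of
#' 0.5, unit innovation noise, and distinct per-task event activation rates.
#'
#' @param config a [GeneratorConfig-class].
#' @param smoothness AR(1) coefficient(s), recycled over tasks.
#' @param noiseSd innovation standard deviation(s), recycled over tasks.
#' @return list of five `TaskProfile` objects in task order.
#' @examples
#' profiles <- defaultTaskProfiles(GeneratorConfig())
#' profiles[[1]]@meanDurationS
#' @export
defaultTaskProfiles <- function(config, smoothness = 0.5, noiseSd = 1) {
  smoothness <- rep_len(smoothness, 5L)
  noiseSd <- rep_len(noiseSd, 5L)
  mu <- .emissionMeans(config, noiseSd = noiseSd[1L])
  rates <- .defaultEventRates()
  lapply(1:5, function(t) {
    methods::new("TaskProfile", taskId = t - 1L, name = .TASK_NAMES[t],
      meanDurationS = .TASK_MEAN_S[t], stdDurationS = .TASK_SD_S[t],
      emissionMean = mu[t, ], smoothness = smoothness[t],
      noiseSd = noiseSd[t], eventRates = rates[t, ])
  })
}

#' Task profiles with overlapping marginals but distinct dynamics
#'
#' A harder regime for marginal-density clustering: emission means only 1.5
#' noise units apart (so per-frame marginal distributions overlap heavily at
#' the raw rate) while tasks differ in their AR(1) smoothness — i.e. tasks are
#' distinguished by their temporal dynamics more than by where their frames
#' sit. Event rates stay task-specific. Used to probe the gap between
#' alignment-aware clustering (ACA/HACA) and frame-marginal methods (GMM).
#'
#' @param config a [GeneratorConfig-class]; its `separation` is overridden.
#' @return list of five `TaskProfile` objects in task order.
#' @export
overlapDynamicsProfiles <- function(config) {
  cfg <- config
  cfg@separation <- 1.5
  defaultTaskProfiles(cfg, smoothness = c(0.30, 0.50, 0.70, 0.85, 0.95))
}

.checkProfiles <- function(config, profiles) {
  if (length(profiles) != 5L)
    stop("exactly 5 task profiles are required, got ", length(profiles))
  d <- config@dSsc + config@dSi
  for (p in profiles) {
    methods::validObject(p)
    if (length(p@emissionMean) != d)
      stop("emissionMean length (", length(p@emissionMean),
           ") must equal dSsc + dSi (", d, ")")
  }
  invisible(TRUE)
}

.drawDurationsS <- function(config, profiles) {
  # Normal durations truncated below at max(5 frames / rate, 1 s) * timeScale
  ts <- config@timeScale
  floor_s <- max(5 / config@sampleRateHz, 1) * ts
  vapply(profiles, function(p)
    max(stats::rnorm(1L, p@meanDurationS * ts, p@stdDurationS * ts), floor_s),
    numeric(1L))
}

#' Draw one set of per-task durations (seconds)
#'
#' Samples the five task durations of a single pseudo-procedure exactly as
#' [generateTrial()] does (same RNG stream given the same seed): Normal with
#' each profile's mean/sd scaled by `config@timeScale`, truncated below at
#' `max(5 / rate, 1) * timeScale` seconds.
#'
#' @param config a [GeneratorConfig-class].
#' @param profiles list of five [TaskProfile-class] objects.
#' @param seed integer seed.
#' @return numeric vector of five durations in seconds, task order.
#' @export
sampleTaskDurations <- function(config, profiles, seed) {
  .checkProfiles(config, profiles)
  set.seed(seed)
  .drawDurationsS(config, profiles)
}

#' Generate one synthetic pseudo-procedure trial
#'
#' Produces synchronized SSC/SI/EVT streams for five tasks concatenated in
#' fixed order, plus the exact ground-truth segmentation. Durations are drawn
#' from each task's Normal distribution (scaled by `config@timeScale`);
#' kinematic channels follow an AR(1) process pulled toward the active task's
#' emission mean with Gaussian innovations (the latent state is carried across
#' task boundaries, giving smooth transitions); each event channel fires as an
#' independent per-frame Bernoulli with probability `rate / sampleRateHz`.
#' Identical `(config, profiles, seed)` reproduce bit-identical output.
#'
#' @param config a [GeneratorConfig-class].
#' @param profiles list of five [TaskProfile-class] objects
#'   (see [defaultTaskProfiles()]).
#' @param seed integer seed.
#' @param trial_id identifier stored in the recording.
#' @return list with elements `recording` (a
#'   \linkS4class{ProcedureRecording}) and `truth` (a
#'   \linkS4class{Segmentation} with `K = 5`).
#' @examples
#' cfg <- GeneratorConfig(timeScale = 0.01)
#' tr <- generateTrial(cfg, defaultTaskProfiles(cfg), seed = 1)
#' tr$truth
#' @export
generateTrial <- function(config, profiles, seed, trial_id = paste0("trial", seed)) {
  methods::validObject(config)
  .checkProfiles(config, profiles)
  set.seed(seed)
  rate <- config@sampleRateHz
  dur_s <- .drawDurationsS(config, profiles)
  n_frames <- pmax(1L, as.integer(round(dur_s * rate)))
  d <- config@dSsc + config@dSi
  N <- sum(n_frames)

  X <- matrix(0, d, N)
  p1 <- profiles[[1L]]
  # stationary start around the first task's mean
  dev <- stats::rnorm(d, 0, p1@noiseSd / sqrt(1 - p1@smoothness^2))
  at <- 0L
  for (t in 1:5) {
    p <- profiles[[t]]
    n <- n_frames[t]
    eps <- matrix(stats::rnorm(d * n, 0, p@noiseSd), d, n)
    phi <- p@smoothness
    for (ch in seq_len(d))
      eps[ch, ] <- stats::filter(eps[ch, ], phi, method = "recursive",
                                 init = dev[ch])
    dev <- eps[, n]
    X[, (at + 1L):(at + n)] <- p@emissionMean + eps
    at <- at + n
  }

  E <- matrix(0, .N_EVENT_CHANNELS, N)
  at <- 0L
  for (t in 1:5) {
    p <- profiles[[t]]
    n <- n_frames[t]
    pr <- pmin(p@eventRates / rate, 1)
    E[, (at + 1L):(at + n)] <-
      stats::rbinom(.N_EVENT_CHANNELS * n, 1L, prob = pr)
    at <- at + n
  }

  rec <- ProcedureRecording(X[seq_len(config@dSsc), , drop = FALSE],
                            X[config@dSsc + seq_len(config@dSi), , drop = FALSE],
                            E, rate_hz = rate, trial_id = trial_id)
  truth <- Segmentation(c(0L, cumsum(n_frames)), 0:4, K = 5L)
  list(recording = rec, truth = truth)
}

# ---- plain-text containers ----

.writeNumericCSV <- function(m, path) {
  # frames as rows, header = channel names; %.17g guarantees float64
  # round-trip identity
  df <- as.data.frame(matrix(sprintf("%.17g", t(m)), ncol = nrow(m)))
  names(df) <- rownames(m)
  data.table::fwrite(df, path, quote = FALSE)
}

.readNumericCSV <- function(path, what) {
  if (!file.exists(path))
    stop("malformed trial container: missing '", what, "' table (", path, ")")
  dt <- data.table::fread(path, header = TRUE, colClasses = "numeric")
  if (ncol(dt) < 1L || nrow(dt) < 1L)
    stop("malformed trial container: empty '", what, "' table")
  m <- t(as.matrix(dt))
  rownames(m) <- names(dt)
  m
}

#' Write / read a trial container
#'
#' A trial container is a directory of plain-text files: `ssc.csv`, `si.csv`,
#' `evt.csv` (frames as rows, header = channel names), `meta.json`
#' (`rate_hz`, `trial_id`) and `truth.csv` (`start,end,label`, 0-based
#' half-open frame ranges). Kinematics are written with full float64
#' precision so that `readTrial(writeTrial(x))` is bit-exact.
#'
#' @param rec a \linkS4class{ProcedureRecording}.
#' @param truth the ground-truth \linkS4class{Segmentation}.
#' @param path directory to create/populate.
#' @return `writeTrial` returns `path` invisibly; `readTrial` returns a list
#'   with `recording` and `truth`.
#' @export
writeTrial <- function(rec, truth, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  .writeNumericCSV(sscData(rec), file.path(path, "ssc.csv"))
  .writeNumericCSV(siData(rec), file.path(path, "si.csv"))
  ev <- evtData(rec)
  dfe <- as.data.frame(t(ev))
  names(dfe) <- rownames(ev)
  data.table::fwrite(dfe, file.path(path, "evt.csv"), quote = FALSE)
  jsonlite::write_json(list(rate_hz = rateHz(rec), trial_id = trialId(rec)),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  writeSegmentation(truth, file.path(path, "truth.csv"))
  invisible(path)
}

#' @rdname writeTrial
#' @export
readTrial <- function(path) {
  if (!dir.exists(path)) stop("trial container not found: ", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("malformed trial container: missing 'meta' (", meta_path, ")")
  meta <- jsonlite::read_json(meta_path)
  ssc <- .readNumericCSV(file.path(path, "ssc.csv"), "ssc")
  si <- .readNumericCSV(file.path(path, "si.csv"), "si")
  evt <- .readNumericCSV(file.path(path, "evt.csv"), "evt")
  if (!all(evt %in% c(0, 1)))
    stop("malformed trial container: 'evt' entries must be binary")
  rec <- ProcedureRecording(ssc, si, evt, rate_hz = meta$rate_hz,
                            trial_id = meta$trial_id)
  truth <- readSegmentation(file.path(path, "truth.csv"))
  list(recording = rec, truth = truth)
}

#' Write / read a segmentation CSV
#'
#' Plain CSV with header `start,end,label`: 0-based frame indices, half-open
#' `[start, end)` ranges, one row per segment in temporal order.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param path CSV file path.
#' @param K cluster count for the read segmentation; defaults to
#'   `max(label) + 1`.
#' @return `writeSegmentation` returns `path` invisibly; `readSegmentation`
#'   returns a `Segmentation`.
#' @export
writeSegmentation <- function(seg, path) {
  df <- data.frame(start = head(seg@boundaries, -1L),
                   end = tail(seg@boundaries, -1L),
                   label = seg@labels)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname writeSegmentation
#' @export
readSegmentation <- function(path, K = NULL) {
  if (!file.exists(path)) stop("segmentation file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  need <- c("start", "end", "label")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("malformed segmentation file: missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(dt) < 1L) stop("malformed segmentation file: no segments")
  if (dt$start[1L] != 0L)
    stop("malformed segmentation file: field 'start' must begin at 0")
  if (nrow(dt) > 1L && any(dt$start[-1L] != dt$end[-nrow(dt)]))
    stop("malformed segmentation file: field 'start' must be contiguous with 'end'")
  if (is.null(K)) K <- max(dt$label) + 1L
  Segmentation(c(0L, dt$end), dt$label, K = as.integer(K))
}
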