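# Experiment orchestration: the algorithm x feature-set sweep over trials,
# the restart protocol, and aggregation into report tables.

# stable small integer from a string, for deriving per-run seeds that do not
# shift when algorithms or feature sets are added to the sweep
.hashSeed <- function(...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

#' Preprocess one trial and run one temporal clustering algorithm
#'
#' The full per-trial pipeline: downsample to `target_hz` (kinematics
#' averaged, events any-on), build the requested feature representation
#' (z-scored, symbolized kinematics re-embedded as centroids, raw events
#' appended), construct the Gaussian frame kernel where needed, and run the
#' requested algorithm under the minimum-energy restart protocol.
#'
#' @param rec a \linkS4class{ProcedureRecording}.
#' @param algorithm one of `"sc"`, `"gmm"`, `"aca"`, `"haca"`.
#' @param feature_set one of the six stream combinations (see
#'   [buildFeatures()]).
#' @param K number of clusters (default 5).
#' @param n_init restarts (default 5).
#' @param seed integer seed for the whole pipeline.
#' @param target_hz rate the streams are reduced to before clustering
#'   (default 1 Hz).
#' @param n_symbols symbol count for the k-means symbolization (default 15).
#' @param aca_config optional [ACAConfig-class] overriding the ACA/HACA
#'   defaults (its `K` and `nInit` are taken from `K` and `n_init`).
#' @return A \linkS4class{Segmentation} at the downsampled frame count.
#' @seealso [downsampleSegmentation()] to reduce ground truth to the same
#'   resolution.
#' @export
segmentTrial <- function(rec, algorithm = c("sc", "gmm", "aca", "haca"),
                         feature_set = "SI+EVT", K = 5L, n_init = 5L,
                         seed = 1L, target_hz = 1, n_symbols = 15L,
                         aca_config = NULL) {
  algorithm <- match.arg(algorithm)
  ds <- downsampleRecording(rec, target_hz)
  X <- buildFeatures(ds, feature_set, n_symbols = n_symbols, seed = seed)
  if (algorithm %in% c("aca", "haca")) {
    cfg <- if (is.null(aca_config)) ACAConfig(K = K, nInit = n_init)
           else ACAConfig(K = K, lMin = aca_config@lMin, lMax = aca_config@lMax,
                          maxIter = aca_config@maxIter, tol = aca_config@tol,
                          nInit = n_init)
    Fk <- frameKernel(X, sigma = "auto", seed = seed)
    if (algorithm == "aca") aca(Fk, cfg, seed = seed)
    else haca(Fk, cfg, seed = seed)
  } else if (algorithm == "gmm") {
    gmmSegment(X, K = K, seed = seed, n_init = n_init)
  } else {
    spectralSegment(X, K = K, sigma = "auto", seed = seed, n_init = n_init)
  }
}

#' Run the full algorithm x feature-set sweep
#'
#' For every trial, algorithm and feature set: preprocess, run the algorithm
#' under the minimum-energy restart protocol, and evaluate against the
#' (downsampled) ground truth. Per-run seeds are derived by a stable hash of
#' `(seed, trial, algorithm, feature_set)`, so adding an algorithm or feature
#' set does not shift any other run's randomness and the whole sweep is
#' bit-reproducible given `seed`. Failing runs are logged to stderr and
#' excluded from the results (recorded in `attr(results, "failures")`).
#'
#' @param trials list of trials, each a list with elements `recording` and
#'   `truth` (as returned by [generateTrial()] or [readTrial()]).
#' @param algorithms subset of `c("sc", "gmm", "aca", "haca")`.
#' @param feature_sets subset of the six stream combinations.
#' @param K clusters (default 5).
#' @param n_init restarts per run (default 5).
#' @param seed top-level seed.
#' @param target_hz preprocessing rate (default 1 Hz).
#' @param n_symbols symbolization codebook size (default 15).
#' @return data.frame with one row per completed run: `trial`, `algorithm`,
#'   `feature_set`, `accuracy`, `macro_f1`, per-task precision/recall,
#'   `energy`, `wall_s`.
#' @export
runExperiment <- function(trials, algorithms = c("sc", "gmm", "aca", "haca"),
                          feature_sets = "SI+EVT", K = 5L, n_init = 5L,
                          seed = 1L, target_hz = 1, n_symbols = 15L) {
  if (length(trials) == 0L) stop("at least one trial is required")
  if (length(algorithms) == 0L || length(feature_sets) == 0L)
    stop("algorithm and feature-set lists must be non-empty")
  bad <- setdiff(feature_sets, .FEATURE_SETS)
  if (length(bad)) stop("unknown feature set(s): ", paste(bad, collapse = ", "))
  rows <- list()
  failures <- character(0L)
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    tid <- trialId(tr$recording)
    truth_ds <- downsampleSegmentation(tr$truth, rateHz(tr$recording), target_hz)
    for (algo in algorithms) {
      for (fs in feature_sets) {
        run_seed <- .hashSeed(seed, tid, algo, fs)
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
          pred <- segmentTrial(tr$recording, algorithm = algo,
                               feature_set = fs, K = K, n_init = n_init,
                               seed = run_seed, target_hz = target_hz,
                               n_symbols = n_symbols)
          ev <- evaluateSegmentation(pred, truth_ds)
          wall <- proc.time()[["elapsed"]] - t0
          message(sprintf("[surgseg] %s %s %s: acc=%.3f F1=%.3f (%.1fs)",
                          tid, algo, fs, ev$accuracy, ev$metrics@macroF1, wall))
          data.frame(trial = tid, algorithm = algo, feature_set = fs,
                     accuracy = ev$accuracy, macro_f1 = ev$metrics@macroF1,
                     t(setNames(ev$metrics@precision,
                                paste0("precision_t", seq_len(K)))),
                     t(setNames(ev$metrics@recall,
                                paste0("recall_t", seq_len(K)))),
                     energy = min(pred@metadata$energies), wall_s = wall)
        }, error = function(e) {
          message(sprintf("[surgseg] %s %s %s FAILED: %s", tid, algo, fs,
                          conditionMessage(e)))
          conditionMessage(e)
        })
        if (is.character(res)) {
          failures <- c(failures, sprintf("%s/%s/%s: %s", tid, algo, fs, res))
        } else {
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  if (length(rows) == 0L) stop("no successful runs in the experiment")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Aggregate sweep results into a mean +/- sd grid
#'
#' @param results data.frame from [runExperiment()].
#' @return data.frame with one row per feature set and one `mean +/- sd`
#'   accuracy column per algorithm (accuracies in percent).
#' @export
aggregateResults <- function(results) {
  algos <- unique(results$algorithm)
  fsets <- unique(results$feature_set)
  grid <- data.frame(feature_set = fsets)
  for (a in algos) {
    cell <- vapply(fsets, function(fs) {
      acc <- 100 * results$accuracy[results$algorithm == a &
                                    results$feature_set == fs]
      if (length(acc) == 0L) return(NA_character_)
      sprintf("%.1f ± %.1f", mean(acc),
              if (length(acc) > 1L) stats::sd(acc) else 0)
    }, character(1L))
    grid[[a]] <- cell
  }
  grid
}

#' Write report tables or figures from sweep results
#'
#' Styles: `"table2"` — the algorithm x feature-set grid of mean +/- sd
#' accuracies; `"table3"` — per-task precision and recall for one feature
#' set; `"table4"` — per-task recall (labeled as such) for ACA/HACA;
#' `"fig4"` — per-trial segmentation color bars, ground truth first (requires
#' `segmentations`).
#'
#' @param results data.frame from [runExperiment()].
#' @param style one of `"table2"`, `"table3"`, `"table4"`, `"fig4"`.
#' @param dir output directory.
#' @param feature_set feature set selected for `"table3"`/`"table4"`.
#' @param segmentations for `"fig4"`: named list of
#'   \linkS4class{Segmentation}s, ground truth first.
#' @return paths of the written files, invisibly.
#' @export
reportResults <- function(results, style = c("table2", "table3", "table4", "fig4"),
                          dir = ".", feature_set = "SI+EVT",
                          segmentations = NULL) {
  style <- match.arg(style)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(results) == 0L) stop("results are empty")
  mdTable <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, body)
  }
  writeBoth <- function(df, stem) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    md <- file.path(dir, paste0(stem, ".md"))
    data.table::fwrite(df, csv)
    writeLines(mdTable(df), md)
    c(csv, md)
  }
  paths <- switch(style,
    table2 = writeBoth(aggregateResults(results), "accuracy_grid"),
    table3 = {
      sub <- results[results$feature_set == feature_set, , drop = FALSE]
      if (nrow(sub) == 0L) stop("no results for feature set ", feature_set)
      pcols <- grep("^precision_t", names(sub), value = TRUE)
      rcols <- grep("^recall_t", names(sub), value = TRUE)
      agg <- do.call(rbind, lapply(split(sub, sub$algorithm), function(d)
        data.frame(algorithm = d$algorithm[1L],
                   t(setNames(round(100 * colMeans(d[pcols], na.rm = TRUE), 1), pcols)),
                   t(setNames(round(100 * colMeans(d[rcols], na.rm = TRUE), 1), rcols)))))
      writeBoth(agg, "per_task_precision_recall")
    },
    table4 = {
      sub <- results[results$algorithm %in% c("aca", "haca") &
                     results$feature_set == feature_set, , drop = FALSE]
      if (nrow(sub) == 0L) stop("no ACA/HACA results for feature set ", feature_set)
      rcols <- grep("^recall_t", names(sub), value = TRUE)
      agg <- do.call(rbind, lapply(split(sub, sub$algorithm), function(d) {
        m <- 100 * as.matrix(d[rcols])
        data.frame(algorithm = d$algorithm[1L],
                   t(setNames(sprintf("%.1f ± %.1f", colMeans(m, na.rm = TRUE),
                                      apply(m, 2L, function(x)
                                        if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0)),
                              rcols)))
      }))
      writeBoth(agg, "per_task_recall")
    },
    fig4 = {
      if (is.null(segmentations))
        stop("fig4 style requires a named list of segmentations")
      png_path <- file.path(dir, "segmentation_bars.png")
      grDevices::png(png_path, width = 900, height = 80 * length(segmentations) + 80)
      on.exit(grDevices::dev.off())
      plotSegmentations(segmentations)
      png_path
    })
  invisible(paths)
}

#' Plot segmentations as horizontal color bars
#'
#' One bar per segmentation (ground truth conventionally first), colored by
#' cluster label, drawn on a shared frame axis.
#'
#' @param segmentations named list of \linkS4class{Segmentation}s.
#' @param palette colors, one per cluster label.
#' @return invisibly `NULL`.
#' @export
plotSegmentations <- function(segmentations,
                              palette = grDevices::hcl.colors(
                                max(vapply(segmentations, function(s) s@K,
                                           integer(1L))), "Dark 3")) {
  n <- length(segmentations)
  N <- max(vapply(segmentations, nFrames, integer(1L)))
  graphics::plot(NULL, xlim = c(0, N), ylim = c(0, n), xlab = "frame",
                 ylab = "", yaxt = "n", bty = "n")
  graphics::axis(2, at = seq_len(n) - 0.5,
                 labels = rev(names(segmentations)), las = 1, tick = FALSE)
  for (i in seq_len(n)) {
    s <- segmentations[[i]]
    y0 <- n - i + 0.1; y1 <- n - i + 0.9
    for (m in seq_len(nSegments(s)))
      graphics::rect(s@boundaries[m], y0, s@boundaries[m + 1L], y1,
                     col = palette[s@labels[m] + 1L], border = NA)
  }
  invisible(NULL)
}
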