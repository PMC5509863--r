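# Evaluation: confusion matrix, Hungarian-matched cluster accuracy, per-task
# precision/recall/F1, and the proportional-duration baseline.

# O(n^3) Hungarian algorithm (potential/shortest-augmenting-path form) for the
# minimum-cost square assignment problem; returns match[i] = column assigned
# to row i. No installed package provides weighted bipartite assignment.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1L]] <- j
  match
}

.indicator <- function(labels, K) {
  G <- matrix(0, K, length(labels))
  G[cbind(labels + 1L, seq_along(labels))] <- 1
  G
}

#' Confusion matrix between two segmentations
#'
#' Counts, for every (predicted cluster, true task) pair, the frames shared by
#' the two labelings. Computed as the indicator-matrix product
#' `C = G_out H_out H_true' G_true'` with `G` the cluster-membership and `H`
#' the segment-membership indicators. Both segmentations must cover the same
#' frame count; `K` is the larger of the two cluster counts (the matrix is
#' zero-padded for the smaller side).
#'
#' @param pred predicted \linkS4class{Segmentation}.
#' @param truth ground-truth \linkS4class{Segmentation}.
#' @return A \linkS4class{ConfusionMatrix} with `C[i, j]` = frames predicted
#'   `i` and truly `j`.
#' @export
confusionMatrix <- function(pred, truth) {
  if (pred@N != truth@N)
    stop("frame counts differ: pred has ", pred@N, ", truth has ", truth@N)
  K <- max(pred@K, truth@K)
  segIdx <- function(s) rep(seq_len(nSegments(s)), segmentLengths(s))
  Gp <- .indicator(pred@labels, K)
  Hp <- .indicator(segIdx(pred) - 1L, nSegments(pred))
  Gt <- .indicator(truth@labels, K)
  Ht <- .indicator(segIdx(truth) - 1L, nSegments(truth))
  C <- Gp %*% Hp %*% t(Ht) %*% t(Gt)
  storage.mode(C) <- "double"
  methods::new("ConfusionMatrix", counts = round(C))
}

#' Hungarian-matched clustering accuracy
#'
#' `accuracy = max_P tr(C P) / tr(C 1)`: the fraction of frames on the
#' diagonal after the cluster-to-task permutation `P` that maximizes the
#' matched frame count, found with the Hungarian algorithm. Invariant under
#' any relabeling of predicted clusters or true tasks; equals 1 exactly when
#' the prediction matches the truth up to a label permutation.
#'
#' @param C a \linkS4class{ConfusionMatrix} (or plain count matrix).
#' @return scalar accuracy in `[0, 1]`.
#' @examples
#' clusterAccuracy(matrix(c(6, 4, 4, 6), 2))  # 0.6
#' @export
clusterAccuracy <- function(C) {
  Cm <- if (methods::is(C, "ConfusionMatrix")) C@counts else as.matrix(C)
  tot <- sum(Cm)
  if (tot == 0) stop("confusion matrix is all zeros")
  match <- .hungarian(-Cm)
  sum(Cm[cbind(seq_len(nrow(Cm)), match)]) / tot
}

#' Per-task precision, recall and F1 under the optimal matching
#'
#' Uses the accuracy-optimal Hungarian matching of predicted clusters to true
#' tasks. For task `k` with matched cluster `c`: `TP = C[c, k]`,
#' `precision = TP / (frames predicted c)`, `recall = TP / (true frames of
#' k)`, `F1 = 2PR / (P + R)` (0 where `P + R = 0`). A task with no true
#' frames has undefined recall, reported as `NA` and excluded from the
#' macro-F1 average.
#'
#' @param C a \linkS4class{ConfusionMatrix} (or plain count matrix).
#' @return A \linkS4class{TaskMetrics}.
#' @export
perTaskMetrics <- function(C) {
  Cm <- if (methods::is(C, "ConfusionMatrix")) C@counts else as.matrix(C)
  if (sum(Cm) == 0) stop("confusion matrix is all zeros")
  K <- nrow(Cm)
  match <- .hungarian(-Cm)          # match[c] = task assigned to cluster c
  cluster_of <- integer(K)          # cluster matched to each task
  cluster_of[match] <- seq_len(K)
  precision <- recall <- f1 <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    cc <- cluster_of[k]
    tp <- Cm[cc, k]
    predk <- sum(Cm[cc, ])
    truek <- sum(Cm[, k])
    precision[k] <- if (predk > 0) tp / predk else NA_real_
    recall[k] <- if (truek > 0) tp / truek else NA_real_
    pr <- precision[k] + recall[k]
    f1[k] <- if (is.na(pr)) NA_real_
             else if (pr == 0) 0
             else 2 * precision[k] * recall[k] / pr
  }
  methods::new("TaskMetrics", precision = precision, recall = recall, f1 = f1,
               macroF1 = mean(f1, na.rm = TRUE), matching = cluster_of)
}

#' Proportional-duration baseline segmentation
#'
#' Predicts task boundaries from average task durations alone: the normalized
#' (relative to total trial length) duration of each task is averaged over
#' the training truths, renormalized to sum to one, cumulated, and scaled to
#' `target_N` frames with integer rounding (boundaries kept monotone with at
#' least one frame per task). Labels run `0 .. K-1` in task order. Any
#' algorithm worth running should beat this.
#'
#' @param train_truths list of ground-truth \linkS4class{Segmentation}s, all
#'   with the same tasks in the same order.
#' @param target_N frame count of the trial to segment.
#' @return A \linkS4class{Segmentation}.
#' @export
proportionalBaseline <- function(train_truths, target_N) {
  if (length(train_truths) < 1L) stop("at least one training truth is required")
  lab0 <- train_truths[[1L]]@labels
  props <- vapply(train_truths, function(s) {
    if (!identical(s@labels, lab0))
      stop("training truths must share the same tasks in the same order")
    segmentLengths(s) / s@N
  }, numeric(length(lab0)))
  p <- rowMeans(matrix(props, nrow = length(lab0)))
  p <- p / sum(p)
  K <- length(p)
  b <- round(cumsum(p) * target_N)
  b <- pmax(b, seq_len(K))                      # at least one frame per task
  b <- pmin(b, target_N - (K - seq_len(K)))     # leave room for later tasks
  b <- cummax(b)
  b[K] <- target_N
  Segmentation(c(0L, b), lab0, K = max(lab0) + 1L)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Convenience wrapper returning the Hungarian-matched accuracy, per-task
#' metrics and the confusion matrix in one list.
#'
#' @param pred predicted \linkS4class{Segmentation}.
#' @param truth ground-truth \linkS4class{Segmentation}.
#' @return list with `accuracy`, `metrics` (a \linkS4class{TaskMetrics}),
#'   `confusion` (a \linkS4class{ConfusionMatrix}).
#' @export
evaluateSegmentation <- function(pred, truth) {
  C <- confusionMatrix(pred, truth)
  list(accuracy = clusterAccuracy(C), metrics = perTaskMetrics(C),
       confusion = C)
}
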