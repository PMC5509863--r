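test_that("the confusion matrix matches direct counting", {
  # identical segmentations: a scaled identity
  truth <- Segmentation(seq.int(0L, 500L, by = 100L), 0:4, K = 5L)
  C <- confusionMatrix(truth, truth)
  expect_equal(confusionCounts(C), diag(5) * 100)
  # cyclic label shift: a scaled permutation matrix
  shifted <- Segmentation(truth@boundaries, (truth@labels + 1L) %% 5L, K = 5L)
  Cs <- confusionCounts(confusionMatrix(shifted, truth))
  expect_equal(sum(Cs > 0), 5L)
  expect_true(all(Cs[Cs > 0] == 100))
  # random instances: matrix-product form equals per-frame counting
  for (s in 1:100) {
    set.seed(s)
    K <- sample(2:5, 1L)
    pred <- randomSegmentationFixture(200L, K)
    tru <- randomSegmentationFixture(200L, K)
    expect_equal(confusionCounts(confusionMatrix(pred, tru)),
                 naiveConfusion(frameLabels(pred), frameLabels(tru), K) * 1.0)
  }
})

test_that("frame-count mismatches are rejected", {
  a <- Segmentation(c(0L, 10L), 0L, K = 2L)
  b <- Segmentation(c(0L, 12L), 0L, K = 2L)
  expect_error(confusionMatrix(a, b), "differ")
})

test_that("cluster accuracy matches its closed forms and the permutation oracle", {
  expect_equal(clusterAccuracy(diag(5) * 100), 1)
  anti <- matrix(0, 5, 5)
  anti[cbind(1:5, 5:1)] <- 100
  expect_equal(clusterAccuracy(anti), 1)
  expect_equal(clusterAccuracy(matrix(c(6, 4, 4, 6), 2)), 0.6)
  for (s in 1:100) {
    set.seed(s)
    K <- sample(2:6, 1L)
    C <- matrix(rpois(K * K, 5), K)
    if (sum(C) == 0) C[1L, 1L] <- 1L
    expect_equal(clusterAccuracy(C), bruteAssignmentMax(C) / sum(C))
  }
  expect_error(clusterAccuracy(matrix(0, 3, 3)), "all zeros")
})

test_that("accuracy is invariant to relabeling either side", {
  set.seed(1)
  pred <- randomSegmentationFixture(150L, 4L)
  tru <- randomSegmentationFixture(150L, 4L)
  base <- clusterAccuracy(confusionMatrix(pred, tru))
  for (r in 1:5) {
    pp <- sample.int(4L) - 1L
    tp <- sample.int(4L) - 1L
    pred2 <- Segmentation(pred@boundaries, pp[pred@labels + 1L], K = 4L)
    tru2 <- Segmentation(tru@boundaries, tp[tru@labels + 1L], K = 4L)
    expect_equal(clusterAccuracy(confusionMatrix(pred2, tru2)), base)
  }
})

test_that("accuracy is one exactly for permutation-equivalent labelings", {
  set.seed(2)
  tru <- randomSegmentationFixture(120L, 3L)
  perm <- c(2L, 0L, 1L)
  pred <- Segmentation(tru@boundaries, perm[tru@labels + 1L], K = 3L)
  expect_equal(clusterAccuracy(confusionMatrix(pred, tru)), 1)
  # and strictly below one otherwise
  lab <- frameLabels(tru)
  lab[1:10] <- (lab[1:10] + 1L) %% 3L
  off <- segmentationFromFrameLabels(lab, K = 3L)
  expect_lt(clusterAccuracy(confusionMatrix(off, tru)), 1)
})

test_that("per-task metrics match hand computation", {
  # perfect prediction
  tm <- perTaskMetrics(diag(4) * 25)
  expect_equal(tm@precision, rep(1, 4))
  expect_equal(tm@recall, rep(1, 4))
  expect_equal(tm@macroF1, 1)
  # one predicted cluster covering everything, two equal tasks
  C <- matrix(c(50, 0, 50, 0), 2)
  tm2 <- perTaskMetrics(C)
  expect_equal(tm2@recall[1L], 1)
  expect_equal(tm2@precision[1L], 0.5)
  expect_true(is.na(tm2@precision[2L]))
  expect_equal(tm2@recall[2L], 0)
  # random instance vs counting oracle
  set.seed(3)
  pred <- randomSegmentationFixture(200L, 3L)
  tru <- randomSegmentationFixture(200L, 3L)
  C3 <- confusionMatrix(pred, tru)
  tm3 <- perTaskMetrics(C3)
  Cm <- confusionCounts(C3)
  for (k in 1:3) {
    cc <- tm3@matching[k]
    expect_equal(tm3@precision[k], Cm[cc, k] / sum(Cm[cc, ]))
    expect_equal(tm3@recall[k], Cm[cc, k] / sum(Cm[, k]))
  }
  f1 <- 2 * tm3@precision * tm3@recall / (tm3@precision + tm3@recall)
  f1[tm3@precision + tm3@recall == 0] <- 0
  expect_equal(tm3@macroF1, mean(f1, na.rm = TRUE))
})

test_that("the proportional baseline reproduces its worked examples", {
  # self-consistent proportions give perfect accuracy
  t1 <- Segmentation(c(0L, 30L, 60L, 100L), c(0L, 1L, 2L), K = 3L)
  t2 <- Segmentation(c(0L, 60L, 120L, 200L), c(0L, 1L, 2L), K = 3L)
  base <- proportionalBaseline(list(t1, t2), 100L)
  expect_equal(clusterAccuracy(confusionMatrix(base, t1)), 1)
  # single training trial equal to the target
  solo <- proportionalBaseline(list(t1), 100L)
  expect_identical(solo@boundaries, t1@boundaries)
  # two tasks, train (0.5, 0.5), target truth (0.7, 0.3), N = 100
  train <- Segmentation(c(0L, 50L, 100L), c(0L, 1L), K = 2L)
  target <- Segmentation(c(0L, 70L, 100L), c(0L, 1L), K = 2L)
  pred <- proportionalBaseline(list(train), 100L)
  expect_identical(pred@boundaries, c(0L, 50L, 100L))
  expect_equal(clusterAccuracy(confusionMatrix(pred, target)), 0.8)
})

test_that("the baseline rejects inconsistent task structure", {
  a <- Segmentation(c(0L, 50L, 100L), c(0L, 1L), K = 2L)
  b <- Segmentation(c(0L, 50L, 100L), c(1L, 0L), K = 2L)
  expect_error(proportionalBaseline(list(a, b), 100L), "same tasks")
})

test_that("every task gets at least one frame even when squeezed", {
  tiny <- Segmentation(c(0L, 1L, 2L, 999L), c(0L, 1L, 2L), K = 3L)
  pred <- proportionalBaseline(list(tiny), 10L)
  expect_true(all(segmentLengths(pred) >= 1L))
  expect_equal(nFrames(pred), 10L)
})
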