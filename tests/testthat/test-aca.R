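test_that("segment-to-centroid distances match the literal sum", {
  set.seed(1)
  F <- randomKernelFixture(25)
  seg <- Segmentation(c(0L, 5L, 10L, 15L, 20L, 25L),
                      c(0L, 1L, 0L, 1L, 0L), K = 2L)
  tau <- dtakMatrix(F, seg)
  starts <- head(seg@boundaries, -1L)
  ends <- tail(seg@boundaries, -1L)
  for (m in 1:5) for (k in 0:1) {
    expect_equal(segmentClusterDistance(F, c(starts[m], ends[m]), seg, k),
                 naiveSegmentDistance(tau, m, seg@labels, k),
                 tolerance = 1e-10)
  }
})

test_that("a singleton cluster has zero distance to its only member", {
  set.seed(2)
  F <- randomKernelFixture(12)
  seg <- Segmentation(c(0L, 6L, 12L), c(0L, 1L), K = 2L)
  expect_equal(segmentClusterDistance(F, c(0, 6), seg, 0L), 0,
               tolerance = 1e-12)
  # two-point form: D2 = tau_mm - 2 tau_mj + tau_jj
  tmj <- dtak(F, c(0, 6), c(6, 12))
  expect_equal(segmentClusterDistance(F, c(0, 6), seg, 1L),
               1 - 2 * tmj + 1, tolerance = 1e-12)
})

test_that("an empty cluster is signaled distinctly", {
  F <- randomKernelFixture(10)
  seg <- Segmentation(c(0L, 5L, 10L), c(0L, 0L), K = 2L)
  err <- tryCatch(segmentClusterDistance(F, c(0, 5), seg, 1L),
                  error = function(e) e)
  expect_s3_class(err, "emptyClusterError")
})

test_that("the objective vanishes for singleton clusters and identical segments", {
  set.seed(3)
  F <- randomKernelFixture(20)
  singletons <- Segmentation(c(0L, 5L, 10L, 15L, 20L), 0:3, K = 4L)
  expect_equal(acaObjective(F, singletons), 0, tolerance = 1e-10)
  ones <- matrix(1, 20, 20)
  onecluster <- Segmentation(c(0L, 10L, 20L), c(0L, 0L), K = 1L)
  expect_equal(acaObjective(ones, onecluster), 0, tolerance = 1e-12)
})

test_that("the summed objective agrees with the trace form", {
  for (s in 1:25) {
    set.seed(s)
    N <- sample(20:40, 1L)
    K <- sample(2:4, 1L)
    F <- randomKernelFixture(N)
    seg <- randomSegmentationFixture(N, K)
    tau <- dtakMatrix(F, seg)
    expect_equal(acaObjective(F, seg),
                 traceObjective(tau, seg@labels, seg@K),
                 tolerance = 1e-8)
  }
})

test_that("aca recovers a planted block structure exactly", {
  F <- plantedKernelFixture(3L, 10L)
  planted <- plantedSegmentationFixture(3L, 10L)
  seg <- aca(F, ACAConfig(K = 3, lMin = 2, lMax = 10, nInit = 5), seed = 1)
  acc <- clusterAccuracy(confusionMatrix(seg, planted))
  expect_equal(acc, 1)
  expect_lte(acaObjective(F, seg), acaObjective(F, planted) + 1e-9)
  expect_true(all(segmentLengths(seg) >= 2L & segmentLengths(seg) <= 10L))
})

test_that("the objective trace is non-increasing and lengths stay bounded", {
  for (s in 1:4) {
    trial <- makeDeskTrial(seed = s, time_scale = 0.04)
    X <- buildFeatures(trial$recording, "SI+EVT", seed = s)
    F <- frameKernel(X, seed = s)
    seg <- aca(F, ACAConfig(K = 5, nInit = 1), seed = s)
    tr <- seg@metadata$trace
    expect_true(all(diff(tr) <= 1e-9))
    expect_true(all(segmentLengths(seg) >= 3L & segmentLengths(seg) <= 30L))
  }
})

test_that("a single cluster yields a single-label segmentation", {
  set.seed(4)
  F <- randomKernelFixture(30)
  seg <- aca(F, ACAConfig(K = 1, lMin = 3, lMax = 10, nInit = 1), seed = 1)
  expect_identical(unique(seg@labels), 0L)
  expect_equal(nFrames(seg), 30L)
})

test_that("infeasible problem sizes are rejected", {
  F <- randomKernelFixture(10)
  expect_error(aca(F, ACAConfig(K = 4, lMin = 3, nInit = 1), seed = 1),
               "at least K")
})

test_that("frame-level aca with unit segments is kernel k-means", {
  # with lMin = lMax = 1 every frame is a segment; the boundary step is
  # trivial and the assignment step is exactly kernel k-means
  set.seed(5)
  F <- plantedKernelFixture(2L, 5L, off = 0.1)
  seg <- aca(F, ACAConfig(K = 2, lMin = 1, lMax = 1, nInit = 3), seed = 1)
  truth <- plantedSegmentationFixture(2L, 5L)
  expect_equal(clusterAccuracy(confusionMatrix(seg, truth)), 1)
  expect_true(all(segmentLengths(seg) == 1L))
})
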