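test_that("downsampling averages kinematics and any-ons events", {
  set.seed(1)
  N <- 500L
  ssc <- matrix(rnorm(12 * N), 12)
  si <- matrix(rnorm(24 * N), 24)
  evt <- matrix(0, 8, N)
  evt[3, 17] <- 1  # single activation inside the first window
  rec <- ProcedureRecording(ssc, si, evt, rate_hz = 50)
  ds <- downsampleRecording(rec, 1)
  expect_equal(ncol(ds), 10L)
  expect_equal(unname(sscData(ds)[, 1L]), rowMeans(ssc[, 1:50]))
  expect_equal(unname(sscData(ds)[, 10L]), rowMeans(ssc[, 451:500]))
  expect_equal(unname(evtData(ds)[3L, 1L]), 1)
  expect_equal(sum(evtData(ds)), 1)
  expect_equal(rateHz(ds), 1)
  # identity when target equals the recording rate
  same <- downsampleRecording(rec, 50)
  expect_identical(sscData(same), sscData(rec))
  expect_error(downsampleRecording(rec, 0), "positive")
})

test_that("label downsampling keeps segment order and count", {
  truth <- Segmentation(c(0L, 500L, 1500L, 2000L), c(0L, 1L, 2L), K = 3L)
  ds <- downsampleSegmentation(truth, 50, 1)
  expect_identical(ds@labels, c(0L, 1L, 2L))
  expect_equal(nFrames(ds), 40L)
  expect_identical(ds@boundaries, c(0L, 10L, 30L, 40L))
  # tie in a window goes to the earlier task
  tie <- Segmentation(c(0L, 25L, 50L), c(1L, 0L), K = 2L)
  dtie <- downsampleSegmentation(tie, 50, 1)
  expect_identical(dtie@labels, 1L)
})

test_that("z-scoring normalizes channels and is idempotent", {
  X <- matrix(c(1, 2, 3), 1)
  z <- zscoreChannels(X)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  cst <- zscoreChannels(matrix(7, 2, 5))
  expect_true(all(cst == 0))
  set.seed(2)
  Y <- matrix(rnorm(60), 6)
  expect_equal(zscoreChannels(zscoreChannels(Y)), zscoreChannels(Y),
               tolerance = 1e-12)
})

test_that("symbolization separates well-separated clouds and handles edges", {
  set.seed(3)
  X <- cbind(matrix(rnorm(2 * 30), 2), matrix(rnorm(2 * 30) + 50, 2))
  ss <- symbolize(X, 2, seed = 1)
  sym <- ss@symbols
  expect_true(all(sym[1:30] == sym[1L]))
  expect_true(all(sym[31:60] == sym[31L]))
  expect_false(sym[1L] == sym[31L])
  # one symbol per frame: zero inertia
  set.seed(4)
  Z <- matrix(rnorm(2 * 12), 2)
  full <- symbolize(Z, 12, seed = 1)
  expect_equal(full@inertia, 0)
  expect_equal(sort(unique(full@symbols)), 0:11)
  expect_error(symbolize(Z, 13, seed = 1), "exceed")
  expect_error(symbolize(Z, 1, seed = 1), "at least 2")
})

test_that("the full symbol-count search grid runs", {
  set.seed(5)
  X <- matrix(rnorm(4 * 250), 4)
  for (ns in c(10L, 15L, 20L, 50L, 100L, 150L, 200L)) {
    ss <- symbolize(X, ns, seed = 1)
    expect_equal(ss@nSymbols, ns)
    expect_true(all(ss@symbols >= 0L & ss@symbols < ns))
  }
})

test_that("feature building concatenates, symbolizes and appends raw events", {
  cfg <- GeneratorConfig(timeScale = 0.01)
  tr <- generateTrial(cfg, defaultTaskProfiles(cfg), seed = 6L)
  rec <- downsampleRecording(tr$recording, 1)
  X <- buildFeatures(rec, "SI+EVT", n_symbols = 10, seed = 1)
  expect_equal(nrow(featureMatrix(X)), 24L + 8L)
  expect_equal(ncol(featureMatrix(X)), ncol(rec))
  # events enter unmodified
  expect_identical(unname(featureMatrix(X)[25:32, ]), unname(evtData(rec)))
  # kinematic part takes at most n_symbols distinct frame values
  kin <- featureMatrix(X)[1:24, ]
  expect_lte(nrow(unique(t(kin))), 10L)
  expect_error(buildFeatures(rec, "EVT"), "unknown feature_set")
  expect_error(buildFeatures(rec, "SI+SSC"), "unknown feature_set")
})

test_that("symbolization with one symbol per frame is the identity embedding", {
  set.seed(7)
  rec <- ProcedureRecording(matrix(rnorm(12 * 20), 12),
                            matrix(rnorm(24 * 20), 24),
                            matrix(rbinom(8 * 20, 1, 0.2), 8), rate_hz = 1)
  X <- buildFeatures(rec, "SSC", n_symbols = 20, seed = 1)
  expect_equal(unname(featureMatrix(X)),
               unname(zscoreChannels(sscData(rec))), tolerance = 1e-12)
})

test_that("the frame kernel matches its closed forms", {
  X <- matrix(c(0, 0, 3, 4, 0, 0), 2)  # frames: (0,0), (3,4), (0,0)
  fk <- frameKernel(X, sigma = 5 / sqrt(2))
  F <- kernelMatrix(fk)
  expect_equal(F[1L, 3L], 1)           # identical frames
  expect_equal(F[1L, 2L], exp(-1))     # distance sigma * sqrt(2)
  expect_equal(unname(diag(F)), rep(1, 3))
  expect_error(frameKernel(matrix(1, 2, 5), sigma = "auto"), "identical")
})

test_that("the kernel of symbolized frames has a bounded value set", {
  set.seed(8)
  X <- matrix(rnorm(3 * 120), 3)
  ss <- symbolize(X, 6, seed = 1)
  Xq <- t(ss@centroids[ss@symbols + 1L, ])
  fk <- frameKernel(Xq, sigma = 1)
  F <- kernelMatrix(fk)
  off <- F[upper.tri(F)]
  expect_lte(length(unique(round(off, 12))), 6 * 7 / 2)
})

test_that("frame kernels are positive semidefinite across random inputs", {
  for (s in 1:50) {
    set.seed(s)
    X <- matrix(rnorm(3 * 40), 3)
    F <- kernelMatrix(frameKernel(X, sigma = "auto", seed = s))
    ev <- eigen(F, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
})
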