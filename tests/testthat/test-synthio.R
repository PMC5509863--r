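test_that("task durations match the configured distribution", {
  cfg <- GeneratorConfig()
  prof <- defaultTaskProfiles(cfg)
  durs <- t(vapply(seq_len(200L), function(i)
    sampleTaskDurations(cfg, prof, seed = 7L + i - 1L), numeric(5L)))
  means <- vapply(prof, function(p) p@meanDurationS, numeric(1L))
  sds <- vapply(prof, function(p) p@stdDurationS, numeric(1L))
  se <- sds / sqrt(200L)
  # task 1 within 2 SE of its configured mean, all tasks within 3 SE
  expect_lt(abs(mean(durs[, 1L]) - means[1L]), 2 * se[1L])
  for (t in 1:5)
    expect_lt(abs(mean(durs[, t]) - means[t]), 3 * se[t])
})

test_that("generateTrial is bit-reproducible and yields exact ground truth", {
  cfg <- GeneratorConfig(timeScale = 0.01)
  prof <- defaultTaskProfiles(cfg)
  a <- generateTrial(cfg, prof, seed = 11L)
  b <- generateTrial(cfg, prof, seed = 11L)
  expect_identical(sscData(a$recording), sscData(b$recording))
  expect_identical(evtData(a$recording), evtData(b$recording))
  expect_identical(a$truth@boundaries, b$truth@boundaries)
  c <- generateTrial(cfg, prof, seed = 12L)
  expect_false(identical(sscData(a$recording), sscData(c$recording)))
  # ground truth: contiguous, exhaustive, ordered tasks 0..4
  expect_identical(a$truth@labels, 0:4)
  expect_identical(a$truth@boundaries[1L], 0L)
  expect_identical(a$truth@boundaries[6L], ncol(a$recording))
  expect_true(all(diff(a$truth@boundaries) > 0L))
  expect_true(all(evtData(a$recording) %in% c(0, 1)))
})

test_that("zero-variance durations give deterministic boundaries across seeds", {
  cfg <- GeneratorConfig(timeScale = 0.01)
  prof <- lapply(defaultTaskProfiles(cfg), function(p) {
    p@stdDurationS <- 0
    p
  })
  b <- lapply(c(3L, 33L, 333L), function(s)
    generateTrial(cfg, prof, seed = s)$truth@boundaries)
  expect_identical(b[[1L]], b[[2L]])
  expect_identical(b[[2L]], b[[3L]])
})

test_that("separation zero removes the emission label signal", {
  cfg <- GeneratorConfig(timeScale = 0.005, separation = 0)
  prof <- defaultTaskProfiles(cfg)
  mus <- vapply(prof, function(p) p@emissionMean, numeric(cfg@dSsc + cfg@dSi))
  expect_true(all(apply(mus, 1L, function(r) length(unique(r)) == 1L)))
  tr <- generateTrial(cfg, prof, seed = 5L)
  expect_s4_class(tr$recording, "ProcedureRecording")
})

test_that("well-separated tasks are Bayes-separable at the frame level", {
  cfg <- GeneratorConfig(timeScale = 0.02)  # separation 6 by default
  prof <- defaultTaskProfiles(cfg)
  tr <- generateTrial(cfg, prof, seed = 2L)
  X <- rbind(sscData(tr$recording), siData(tr$recording))
  mus <- vapply(prof, function(p) p@emissionMean, numeric(nrow(X)))
  d2 <- vapply(1:5, function(t) colSums((X - mus[, t])^2), numeric(ncol(X)))
  bayes <- max.col(-d2) - 1L
  acc <- mean(bayes == frameLabels(tr$truth))
  expect_gte(acc, 0.95)
})

test_that("trial containers round-trip bit-exactly", {
  cfg <- GeneratorConfig(timeScale = 0.005)
  tr <- generateTrial(cfg, defaultTaskProfiles(cfg), seed = 4L)
  path <- file.path(tempdir(), "trial_rt")
  writeTrial(tr$recording, tr$truth, path)
  back <- readTrial(path)
  expect_identical(unname(sscData(back$recording)), unname(sscData(tr$recording)))
  expect_identical(unname(siData(back$recording)), unname(siData(tr$recording)))
  expect_identical(unname(evtData(back$recording)), unname(evtData(tr$recording)))
  expect_equal(rateHz(back$recording), rateHz(tr$recording))
  expect_identical(back$truth@boundaries, tr$truth@boundaries)
  expect_identical(back$truth@labels, tr$truth@labels)
  unlink(path, recursive = TRUE)
})

test_that("a single-frame trial is a valid container", {
  rec <- ProcedureRecording(matrix(1.5, 12, 1), matrix(-0.5, 24, 1),
                            matrix(0L, 8, 1), rate_hz = 50)
  truth <- Segmentation(c(0L, 1L), 0L, K = 5L)
  path <- file.path(tempdir(), "trial_one")
  writeTrial(rec, truth, path)
  back <- readTrial(path)
  expect_equal(ncol(back$recording), 1L)
  expect_identical(back$truth@boundaries, c(0L, 1L))
  unlink(path, recursive = TRUE)
})

test_that("a container missing the events table is rejected with its name", {
  cfg <- GeneratorConfig(timeScale = 0.005)
  tr <- generateTrial(cfg, defaultTaskProfiles(cfg), seed = 4L)
  path <- file.path(tempdir(), "trial_noevt")
  writeTrial(tr$recording, tr$truth, path)
  file.remove(file.path(path, "evt.csv"))
  expect_error(readTrial(path), "evt")
  unlink(path, recursive = TRUE)
})

test_that("segmentation files reject malformed contents", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("start,end,label", "0,10,0", "12,20,1"), p)
  expect_error(readSegmentation(p), "contiguous")
  writeLines(c("start,end", "0,10"), p)
  expect_error(readSegmentation(p), "label")
  seg <- Segmentation(c(0L, 4L, 9L), c(1L, 0L), K = 2L)
  writeSegmentation(seg, p)
  back <- readSegmentation(p)
  expect_identical(back@boundaries, seg@boundaries)
  expect_identical(back@labels, seg@labels)
  unlink(p)
})

test_that("invalid generator inputs are rejected", {
  cfg <- GeneratorConfig(timeScale = 0.005)
  prof <- defaultTaskProfiles(cfg)
  expect_error(generateTrial(cfg, prof[1:4], seed = 1L), "5 task profiles")
  bad <- prof
  bad[[2L]]@meanDurationS <- -1
  expect_error(generateTrial(cfg, bad, seed = 1L), "meanDurationS")
  short <- prof
  short[[3L]]@emissionMean <- short[[3L]]@emissionMean[1:5]
  expect_error(generateTrial(cfg, short, seed = 1L), "emissionMean")
})
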