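test_that("synthetic generation is deterministic and shape-correct", {
  spec <- synthSpec(nEpochs = 5L, nChannels = 3L, fs = 100, epochSeconds = 2,
                    seed = 1L)
  a <- generateSynthetic(spec)
  b <- generateSynthetic(spec)
  expect_identical(signals(a), signals(b))
  expect_equal(dim(signals(a)), c(10L, 3L, 200L))
  expect_equal(classLabels(a), rep(c(0L, 1L), each = 5L))
  expect_error(generateSynthetic(synthSpec(nEpochs = 0L)), "positive")
})

test_that("null abnormal effect leaves the classes indistinguishable", {
  spec <- synthSpec(nEpochs = 100L, nChannels = 1L, fs = 125, epochSeconds = 4,
                    burstAmplitude = 1, bandPowerRatio = 1, seed = 3L)
  es <- generateSynthetic(spec)
  bp <- vapply(seq_len(nEpochs(es)), function(e)
    eegensembles:::bandPowerFFT(signals(es)[e, 1, ], 125, 2, 8), numeric(1))
  p <- t.test(bp[classLabels(es) == 1], bp[classLabels(es) == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("abnormal epochs carry the configured low-band power ratio", {
  spec <- synthSpec(nEpochs = 100L, nChannels = 1L, fs = 125, epochSeconds = 4,
                    seed = 7L)
  es <- generateSynthetic(spec)
  bp <- vapply(seq_len(nEpochs(es)), function(e)
    eegensembles:::bandPowerFFT(signals(es)[e, 1, ], 125, 2, 8), numeric(1))
  lab <- classLabels(es)
  ratio <- mean(bp[lab == 1]) / mean(bp[lab == 0])
  expect_lt(abs(ratio - spec$bandPowerRatio) / spec$bandPowerRatio, 0.15)
})

test_that("band-power class separation grows with the configured ratio", {
  cohend <- function(ratio, seed) {
    es <- generateSynthetic(synthSpec(nEpochs = 40L, nChannels = 1L, fs = 125,
                                      epochSeconds = 4, burstAmplitude = 1,
                                      bandPowerRatio = ratio, seed = seed))
    bp <- vapply(seq_len(nEpochs(es)), function(e)
      eegensembles:::bandPowerFFT(signals(es)[e, 1, ], 125, 2, 8), numeric(1))
    lab <- classLabels(es)
    (mean(bp[lab == 1]) - mean(bp[lab == 0])) /
      sqrt((stats::var(bp[lab == 1]) + stats::var(bp[lab == 0])) / 2)
  }
  for (seed in 1:5) {
    d <- vapply(c(1.5, 3, 6), cohend, numeric(1), seed = seed)
    expect_true(all(diff(d) > 0))
  }
})

test_that("stratified train/test split honours fraction, classes and seed", {
  tab <- makeBlobTable(n = 100L)
  plan <- splitTrainTest(tab, 0.9, seed = 4L)
  expect_length(trainIndices(plan), 90L)
  expect_length(testIndices(plan), 10L)
  expect_length(intersect(trainIndices(plan), testIndices(plan)), 0L)
  # class ratio preserved
  expect_equal(sum(classLabels(tab)[trainIndices(plan)] == 1L), 45L)
  plan2 <- splitTrainTest(tab, 0.9, seed = 4L)
  expect_identical(trainIndices(plan), trainIndices(plan2))
  # 50/50 on 10 samples keeps the class ratio
  small <- makeBlobTable(n = 10L)
  p5 <- splitTrainTest(small, 0.5, seed = 1L)
  expect_length(trainIndices(p5), 5L)
  expect_error(splitTrainTest(FeatureTable(
    matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b"))),
    c(0L, 0L, 1L)), 0.5), "2 members")
})

test_that("cross-validation folds partition the training set, stratified", {
  tab <- makeBlobTable(n = 110L)
  plan <- splitTrainTest(tab, 100 / 110, seed = 2L)
  plan <- makeFolds(plan, k = 10L, seed = 2L)
  folds <- cvFolds(plan)
  expect_length(folds, 10L)
  val <- unlist(lapply(folds, `[[`, "validate"))
  expect_length(val, 100L)
  expect_setequal(val, trainIndices(plan))
  expect_false(anyDuplicated(val) > 0)
  y <- classLabels(tab)
  ratio <- mean(y[trainIndices(plan)] == 1L)
  for (f in folds) {
    expect_setequal(c(f$train, f$validate), trainIndices(plan))
    expect_lte(abs(sum(y[f$validate] == 1L) - ratio * length(f$validate)), 1)
    expect_length(intersect(f$train, f$validate), 0L)
  }
  expect_error(makeFolds(plan, k = 1000L), "exceeds")
  # random-case partition property
  for (r in 1:20) {
    n <- sample(20:60, 1L)
    tabr <- makeBlobTable(n = 2L * (n %/% 2L), seed = r)
    pr <- makeFolds(splitTrainTest(tabr, 0.8, seed = r),
                    k = sample(2:5, 1L), seed = r)
    vr <- sort(unlist(lapply(cvFolds(pr), `[[`, "validate")))
    expect_identical(vr, sort(trainIndices(pr)))
  }
})

test_that("EDF files round-trip within 16-bit quantisation", {
  set.seed(10)
  for (r in 1:5) {
    es <- smallEEG(nEpochs = 3L, nChannels = 2L, seed = r)
    path <- tempfile(fileext = ".edf")
    writeEDF(es, path)
    back <- readEDF(path, epochSeconds = 2, label = 0L)
    expect_equal(nEpochs(back), 6L)
    expect_equal(nChannels(back), 2L)
    rng <- apply(signals(es), 2, function(v) diff(range(v)))
    tol <- max(rng) / 65536 * 1.01
    expect_lt(max(abs(signals(back) - signals(es))), tol)
    expect_identical(channelNames(back), channelNames(es))
    unlink(path)
  }
})

test_that("EDF epoching drops the trailing partial epoch", {
  # 6-second single-channel recording read as 2.5 s epochs -> 2 epochs
  es <- smallEEG(nEpochs = 2L, nChannels = 1L, seed = 3L)  # 4 x 2 s epochs
  path <- tempfile(fileext = ".edf")
  writeEDF(es, path)
  back <- readEDF(path, epochSeconds = 3, label = 1L)
  expect_equal(nEpochs(back), 2L)  # 8 s total, 2 s remainder dropped
  expect_equal(nTimepoints(back), 384L)
  expect_true(all(classLabels(back) == 1L))
  unlink(path)
})

test_that("truncated EDF raises a format error naming the byte offset", {
  es <- smallEEG(nEpochs = 2L, nChannels = 1L, seed = 4L)
  path <- tempfile(fileext = ".edf")
  writeEDF(es, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:600], path)
  expect_error(readEDF(path, 2, 0L), "truncated.*byte")
  unlink(path)
})
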