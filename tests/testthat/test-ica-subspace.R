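genIICAData <- function(seed, nSources = 3L, N = 16L, D = 300L, sigma = 0.1) {
  set.seed(seed)
  H <- matrix(rnorm(N * nSources), N, nSources)
  W <- matrix(rnorm(nSources * D), nSources, D)
  H %*% W + matrix(rnorm(N * D, sd = sigma), N, D)
}

test_that("the I-ICA sampler is byte-deterministic under a fixed seed", {
  Z <- genIICAData(31, N = 10L, D = 80L)
  a <- fitIICA(Z, qTrunc = 5L, sweeps = 40L, seed = 9L)
  b <- fitIICA(Z, qTrunc = 5L, sweeps = 40L, seed = 9L)
  expect_identical(a@B, b@B)
  expect_identical(a@W, b@W)
  expect_identical(a@H, b@H)
  expect_identical(a@errorTrace, b@errorTrace)
})

test_that("I-ICA recovers the planted source count on model-class data", {
  counts <- vapply(1:15, function(s) {
    Z <- genIICAData(600 + s)
    activeSourceCount(fitIICA(Z, qTrunc = 8L, sweeps = 200L, seed = s))
  }, numeric(1))
  expect_gte(mean(counts >= 2 & counts <= 4), 14 / 15)
})

test_that("reconstruction error never ends above its starting level", {
  for (s in 1:20) {
    set.seed(s)
    structured <- s %% 2 == 1
    Z <- if (structured) genIICAData(s, N = 10L, D = 60L, sigma = 0.3)
         else matrix(rnorm(10 * 60), 10, 60)
    m <- fitIICA(Z, qTrunc = 4L, sweeps = 40L, seed = s)
    final <- m@errorTrace[length(m@errorTrace)]
    if (structured) expect_lte(final, m@errorTrace[1L])
    else expect_lte(final, m@errorTrace[1L] * 1.01)  # posterior jitter
  }
})

test_that("an all-ones fixed mask at Q=1 gives a rank-1 linear-Gaussian fit", {
  Z <- genIICAData(33, nSources = 1L, N = 8L, D = 60L, sigma = 0.2)
  m <- fitIICA(Z, qTrunc = 1L, sweeps = 60L, seed = 2L,
               fixMask = matrix(1, 1, 60))
  zeroErr <- mean((Z - rowMeans(Z))^2)
  expect_lte(m@errorTrace[length(m@errorTrace)], zeroErr)
  expect_equal(activeSourceCount(m), 1L)
})

test_that("latent features expose active sources, with a guarded fallback", {
  Z <- genIICAData(34)
  m <- fitIICA(Z, qTrunc = 8L, sweeps = 100L, seed = 4L)
  ft <- iicaFeatures(m, Z)
  expect_equal(ncol(featureValues(ft)), activeSourceCount(m))
  expect_equal(nrow(featureValues(ft)), ncol(Z))
  # degenerate all-zero mask triggers the top-variance fallback
  m0 <- m
  m0@B[] <- 0
  expect_warning(f0 <- iicaFeatures(m0, Z), "no active sources")
  expect_gt(ncol(featureValues(f0)), 0L)
})

test_that("latent features linearly separate classes planted in one source", {
  set.seed(35)
  N <- 16L; D <- 300L
  lab <- rep(c(0L, 1L), each = D / 2)
  H <- matrix(rnorm(N * 3L), N, 3L)
  W <- matrix(rnorm(3L * D), 3L, D)
  W[1, ] <- W[1, ] + 4 * lab          # class effect lives in source 1
  Z <- H %*% W + matrix(rnorm(N * D, sd = 0.1), N, D)
  m <- fitIICA(Z, qTrunc = 8L, sweeps = 150L, seed = 6L)
  ft <- iicaFeatures(m, Z, labels = lab)
  df <- data.frame(y = lab, featureValues(ft))
  fit <- suppressWarnings(glm(y ~ ., binomial, df))
  acc <- mean((predict(fit, type = "response") > 0.5) == (lab == 1L))
  expect_gte(acc, 0.9)
})

test_that("subspace plans are uniform near-equal partitions", {
  p <- planSubspaces(10L, 5L, seed = 1L)
  expect_length(p, 5L)
  expect_true(all(lengths(p) == 2L))
  expect_identical(planSubspaces(7L, 1L, seed = 2L)[[1L]], 1:7)
  expect_error(planSubspaces(3L, 4L), "S must")
  set.seed(36)
  for (r in 1:100) {
    Q <- sample(2:40, 1); S <- sample(seq_len(Q), 1)
    pl <- planSubspaces(Q, S, seed = r)
    expect_setequal(unlist(pl), seq_len(Q))
    expect_equal(sum(lengths(pl)), Q)
    expect_lte(diff(range(lengths(pl))), 1L)
  }
})

test_that("extended KNN separates blobs, breaks ties to 0, tracks KNN", {
  tab <- makeBlobTable(n = 40L, q = 3L, sep = 8, seed = 11L)
  qy <- makeBlobTable(n = 20L, q = 3L, sep = 8, seed = 12L)
  for (k in c(1L, 3L, 5L)) {
    pred <- eknnPredict(tab, featureValues(qy), k)
    expect_equal(mean(pred == classLabels(qy)), 1)
  }
  # symmetric configuration at k = n_train resolves to class 0
  sym <- FeatureTable(matrix(c(-2, -1, 1, 2), 4, 1,
                             dimnames = list(NULL, "x")),
                      c(0L, 0L, 1L, 1L))
  expect_equal(eknnPredict(sym, matrix(0, 1, 1), k = 4L), 0L)
  # consistency with plain KNN on well-separated data
  for (s in 1:20) {
    tr <- makeBlobTable(n = 30L, q = 2L, sep = 7, seed = 100 + s)
    te <- makeBlobTable(n = 10L, q = 2L, sep = 7, seed = 200 + s)
    a <- eknnPredict(tr, featureValues(te), 3L)
    b <- eegensembles:::knnVote(featureValues(tr), classLabels(tr),
                                featureValues(te), 3L)
    expect_identical(a, b)
  }
})

test_that("a single-subspace SVM ensemble equals the lone classifier", {
  tab <- makeBlobTable(n = 50L, q = 4L, sep = 5, seed = 13L)
  plan <- planSubspaces(4L, 1L, seed = 1L)
  ens <- fitSubspaceEnsemble(tab, plan, mode = "svm", seed = 2L)
  expect_length(ens@members, 1L)
  hold <- makeBlobTable(n = 30L, q = 4L, sep = 5, seed = 14L)
  expect_identical(predict(ens, hold),
                   as.integer(ens@members[[1L]]$predict(featureValues(hold))))
})

test_that("hybrid subspace ensembles field 3 members per usable subspace", {
  # class signal spread across features, as in the EEG feature bank, so
  # every subspace is informative
  tab <- makeBlobTable(n = 60L, q = 6L, sep = 2, seed = 15L, spread = TRUE)
  plan <- planSubspaces(6L, 2L, seed = 3L)
  ens <- fitSubspaceEnsemble(tab, plan, mode = "hybrid", seed = 4L,
                             config = list(mlpSize = 4L, mlpMaxit = 100L))
  expect_length(ens@members, 6L)
  hold <- makeBlobTable(n = 30L, q = 6L, sep = 2, seed = 16L, spread = TRUE)
  expect_gte(mean(predict(ens, hold) == classLabels(hold)), 0.9)
})

test_that("voting over informative subspaces preserves a strong signal", {
  violations <- 0L
  for (s in 1:10) {
    tr <- makeBlobTable(n = 60L, q = 6L, sep = 3, seed = 300 + s,
                        spread = TRUE)
    te <- makeBlobTable(n = 30L, q = 6L, sep = 3, seed = 400 + s,
                        spread = TRUE)
    ens <- fitSubspaceEnsemble(tr, planSubspaces(6L, 2L, seed = s),
                               mode = "hybrid", seed = s,
                               config = list(mlpSize = 4L, mlpMaxit = 100L))
    votes <- do.call(rbind, lapply(ens@members, function(m)
      m$predict(featureValues(te))))
    single <- max(rowMeans(votes == matrix(classLabels(te), nrow(votes),
                                           ncol(votes), byrow = TRUE)))
    acc <- mean(predict(ens, te) == classLabels(te))
    violations <- violations + (acc < single - 0.05)
  }
  expect_equal(violations, 0L)
})

test_that("a zero-variance subspace is skipped with a warning", {
  m <- cbind(a = rnorm(20), b = rnorm(20), c = 0, d = 0)
  tab <- FeatureTable(m, rep(c(0L, 1L), each = 10L))
  plan <- list(c(1L, 2L), c(3L, 4L))
  expect_warning(ens <- fitSubspaceEnsemble(tab, plan, mode = "svm",
                                            seed = 1L), "zero variance")
  expect_length(ens@members, 1L)
})
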