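genFAData <- function(n, p = 10L, nFactors = 2L, seed = 1L) {
  set.seed(seed)
  W <- matrix(rnorm(p * nFactors), p, nFactors)
  psi <- runif(p, 0.2, 0.5)
  Z <- matrix(rnorm(n * nFactors), n, nFactors)
  X <- Z %*% t(W) + matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi))
  colnames(X) <- sprintf("x%d", seq_len(p))
  list(X = X, W = W, psi = psi, Z = Z)
}

test_that("EM factor analysis recovers a generative covariance", {
  d <- genFAData(3000L, seed = 41L)
  fm <- fitFactorModel(d$X, 2L)
  S <- cov(d$X)
  Chat <- tcrossprod(fm@W) + diag(fm@noise, ncol(d$X))
  expect_lte(norm(S - Chat, "F") / norm(S, "F"), 0.05)
  # reconstruction agrees with exact-ML factanal (rotation-invariant)
  fa <- factanal(d$X, factors = 2L)
  sds <- apply(d$X, 2L, sd)
  Cfa <- (tcrossprod(fa$loadings[]) + diag(fa$uniquenesses)) * outer(sds, sds)
  expect_lte(norm(Chat - Cfa, "F") / norm(S, "F"), 0.02)
})

test_that("on pure noise the factors capture only a small variance share", {
  set.seed(42)
  X <- matrix(rnorm(5000L * 10L), 5000L, 10L)
  fm <- fitFactorModel(X, 2L)
  expect_lte(sum(fm@W^2) / sum(diag(cov(X))), 0.15)
})

test_that("zero-variance columns are dropped with a warning before fitting", {
  d <- genFAData(200L, seed = 43L)
  X <- cbind(d$X, flat = 1)
  expect_warning(fm <- fitFactorModel(X, 2L), "zero-variance")
  expect_length(fm@featureNames, 10L)
})

test_that("factor scores are deterministic, correctly shaped and sufficient", {
  d <- genFAData(1200L, seed = 44L)
  lab <- as.integer(d$Z[, 1L] > 0)
  tab <- FeatureTable(d$X, lab)
  fm <- fitFactorModel(tab, 2L)
  sc <- faTransform(fm, tab)
  expect_equal(ncol(featureValues(sc)), 2L)
  expect_identical(featureValues(faTransform(fm, tab)), featureValues(sc))
  # classifying on scores loses little against the raw features
  accOn <- function(m) {
    df <- data.frame(y = lab, m)
    fit <- suppressWarnings(glm(y ~ ., binomial, df))
    mean((predict(fit, type = "response") > 0.5) == (lab == 1L))
  }
  expect_gte(accOn(featureValues(sc)), accOn(d$X) - 0.03)
  expect_error(faTransform(fm, featureValues(sc)), "missing fitted")
})

test_that("layer construction reproduces the quartile/fence worked case", {
  # one class whose distances to its center are 1..12 plus a far outlier in
  # the other class
  xs <- c(1:12, -(1:12))                 # symmetric so the center stays at 0
  X <- cbind(x = c(xs, 100, 101, -100, -101),
             y = 0)
  yl <- c(rep(0L, 24L), rep(1L, 4L))
  fit <- lknnFit(FeatureTable(X, yl), L = 5L)
  q <- fit@quartiles[[1L]]
  expect_equal(q, c(3.5, 6.5, 9.5))
  expect_equal(fit@fences[[1L]][2L], 9.5 + 1.5 * 6)   # Q3 + 1.5 IQR
  # no class-0 rejections: all 24 distances lie below 18.5
  expect_equal(sum(fit@retainedLabels == 0L), 24L)
})

test_that("Fmax is the largest per-class far distance and sets layer width", {
  set.seed(45)
  a <- matrix(rnorm(20L * 2L, sd = 0.5), 20L, 2L)
  b <- matrix(rnorm(20L * 2L, sd = 0.2), 20L, 2L) + 5
  X <- rbind(a, b); colnames(X) <- c("u", "v")
  fit <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = 20L)), L = 5L)
  expect_equal(fit@fMax, max(fit@fFar))
  expect_true(all(fit@retainedLayer >= 1L & fit@retainedLayer <= 5L))
  expect_equal(fit@layerWeights, c(5, 4, 3, 2, 1))
})

test_that("a planted far outlier is rejected by the upper Tukey fence", {
  rejected <- 0L
  for (s in 1:50) {
    set.seed(s)
    X <- rbind(matrix(rnorm(30L * 2L), 30L, 2L),
               c(30, 30),                       # ~10x the class radius
               matrix(rnorm(10L * 2L), 10L, 2L) + 8)
    colnames(X) <- c("u", "v")
    yl <- c(rep(0L, 31L), rep(1L, 10L))
    fit <- lknnFit(FeatureTable(X, yl), L = 4L)
    # the planted point must be gone (other borderline members may also
    # fall outside their fence)
    rejected <- rejected +
      !any(fit@retained[, 1L] == 30 & fit@retained[, 2L] == 30)
  }
  expect_equal(rejected, 50L)
})

test_that("the strict fence variant rejects at least as much", {
  set.seed(46)
  X <- matrix(rnorm(40L * 2L), 40L, 2L); colnames(X) <- c("u", "v")
  yl <- rep(c(0L, 1L), each = 20L)
  loose <- lknnFit(FeatureTable(X, yl), L = 3L)
  tight <- lknnFit(FeatureTable(X, yl), L = 3L, tightFence = TRUE)
  expect_lte(nrow(tight@retained), nrow(loose@retained))
})

test_that("small classes are refused", {
  X <- matrix(rnorm(10L), 5L, 2L, dimnames = list(NULL, c("u", "v")))
  expect_error(lknnFit(FeatureTable(X, c(0L, 0L, 0L, 0L, 1L)), L = 2L),
               "fewer than 4")
})

test_that("LKNN prediction reproduces the hand-worked affiliation case", {
  # Query at distance 1 from one member of each class; the class-0 member
  # carries layer weight 2 (layer 1 of L=2), the class-1 member weight 1
  # (layer 2): AR = (1, 1), AD = (2, 1), scores (2/3, 1/3), target 0.
  map <- new("LayeredClassMap",
             classes = c(0L, 1L),
             centers = list(c(0, 0), c(2, 0)),
             quartiles = list(c(0, 0, 0), c(0, 0, 0)),
             fences = list(c(0, 0), c(0, 0)),
             retained = matrix(c(0, 0, 2, 0), 2L, 2L, byrow = TRUE,
                               dimnames = list(NULL, c("u", "v"))),
             retainedLabels = c(0L, 1L), retainedLayer = c(1L, 2L),
             layerWeights = c(2, 1), fFar = c(0, 0), fMax = 2, L = 2L)
  res <- lknnPredict(map, matrix(c(1, 0), 1L, 2L), k = 2L)
  expect_equal(unname(res$decisions[[1L]]$scores), c(2 / 3, 1 / 3))
  expect_equal(res$labels[1L], 0L)
  expect_equal(unname(res$decisions[[1L]]$rates), c(1, 1))
})

test_that("a query coincident with a member takes that member's class", {
  set.seed(47)
  X <- rbind(matrix(rnorm(12L * 2L), 12L, 2L),
             matrix(rnorm(12L * 2L), 12L, 2L) + 6)
  colnames(X) <- c("u", "v")
  fit <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = 12L)), L = 3L)
  hit <- fit@retained[15L, , drop = FALSE]
  res <- lknnPredict(fit, hit, k = 5L)
  expect_equal(res$labels, fit@retainedLabels[15L])
})

test_that("classification scores always sum to one", {
  set.seed(48)
  X <- rbind(matrix(rnorm(20L * 3L), 20L, 3L),
             matrix(rnorm(20L * 3L), 20L, 3L) + 2)
  colnames(X) <- c("u", "v", "w")
  fit <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = 20L)), L = 4L)
  qs <- matrix(rnorm(500L * 3L), 500L, 3L)
  res <- lknnPredict(fit, qs, k = 5L)
  sums <- vapply(res$decisions, function(d) sum(d$scores), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("LKNN matches an independent brute-force oracle", {
  set.seed(49)
  for (r in 1:50) {
    n <- sample(12:30, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(2 * n * p), 2 * n, p)
    X[(n + 1):(2 * n), ] <- X[(n + 1):(2 * n), ] + runif(1, 0, 3)
    colnames(X) <- sprintf("c%d", seq_len(p))
    L <- sample(1:4, 1); k <- sample(1:5, 1)
    fit <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = n)), L = L)
    qs <- matrix(rnorm(6 * p), 6, p)
    mine <- lknnPredict(fit, qs, k = k)
    oracle <- bruteLKNN(fit, qs, k)
    expect_identical(mine$labels, oracle$labels)
    for (i in 1:6)
      expect_equal(unname(mine$decisions[[i]]$scores), oracle$scores[[i]],
                   tolerance = 1e-9)
  }
})

test_that("with one layer LKNN is inverse-distance-weighted KNN", {
  set.seed(50)
  X <- rbind(matrix(rnorm(16L * 2L), 16L, 2L),
             matrix(rnorm(16L * 2L), 16L, 2L) + 1.5)
  colnames(X) <- c("u", "v")
  fit <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = 16L)), L = 1L)
  qs <- matrix(rnorm(40L * 2L), 40L, 2L)
  res <- lknnPredict(fit, qs, k = 4L)
  # oracle: plain inverse-distance-weighted vote over the same retained set
  for (i in 1:40) {
    d <- sqrt(colSums((t(fit@retained) - qs[i, ])^2))
    ord <- order(d, seq_along(d))[1:4]
    w <- 1 / d[ord]
    s1 <- sum(w[fit@retainedLabels[ord] == 1L])
    s0 <- sum(w[fit@retainedLabels[ord] == 0L])
    expect_equal(res$labels[i], if (s1 > s0) 1L else 0L)
  }
})

test_that("outlier rejection is near-idempotent on refit", {
  # Tukey fences on Gaussian classes cascade occasionally: removing the
  # farthest member pulls the hinges in, which can expose the next member.
  # The empirical stability rate for Gaussian data sits near 0.9.
  stable <- 0L
  for (s in 1:100) {
    set.seed(s)
    nn <- sample(c(12L, 20L, 25L), 1L)
    X <- rbind(matrix(rnorm(nn * 2L), nn, 2L),
               matrix(rnorm(nn * 2L), nn, 2L) + 3)
    colnames(X) <- c("u", "v")
    f1 <- lknnFit(FeatureTable(X, rep(c(0L, 1L), each = nn)), L = 3L)
    f2 <- lknnFit(FeatureTable(f1@retained, f1@retainedLabels), L = 3L)
    stable <- stable + (nrow(f2@retained) == nrow(f1@retained))
  }
  expect_gte(stable, 85L)
})

test_that("the FA + LKNN pipeline separates easy data deterministically", {
  tab <- makeBlobTable(n = 120L, q = 10L, sep = 4, seed = 51L)
  hold <- makeBlobTable(n = 60L, q = 10L, sep = 4, seed = 52L)
  fit <- fitFaLknn(tab, nFactors = 4L, L = 4L, k = 5L)
  expect_gte(mean(predict(fit, hold) == classLabels(hold)), 0.9)
  fit2 <- fitFaLknn(tab, nFactors = 4L, L = 4L, k = 5L)
  expect_identical(predict(fit, hold), predict(fit2, hold))
})
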