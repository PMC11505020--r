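test_that("equidistant grids honour endpoints, rounding and degeneracy", {
  expect_equal(equidistantGrid(paramSpec("k", 2, 16, 4, integer = TRUE)),
               c(2, 7, 11, 16))
  expect_equal(equidistantGrid(paramSpec("C", 1, 1, 1)), 1)
  expect_equal(equidistantGrid(paramSpec("g", 0, 1, 3)), c(0, 0.5, 1))
  expect_error(paramSpec("x", 0, 1, 0), "steps")
})

test_that("kappa diversity reproduces its worked cases", {
  truth <- rep(c(0L, 1L), each = 5L)
  same <- matrix(rep(truth, 2), nrow = 2, byrow = TRUE)
  expect_equal(kappaDiversity(same, truth), 1)
  # complementary errors at qbar = 0.5
  a <- rep(0L, 10L); b <- rep(1L, 10L)
  expect_equal(kappaDiversity(rbind(a, b), truth), -1)
  # independent fair coins vs random truth: near zero
  set.seed(19)
  v <- matrix(rbinom(2 * 1e4, 1, 0.5), nrow = 2)
  expect_lt(abs(kappaDiversity(v, rbinom(1e4, 1, 0.5))), 0.05)
  expect_error(kappaDiversity(matrix(truth, 1), truth), "at least 2")
})

test_that("kappa matches a brute-force evaluation of the resolved formula", {
  set.seed(20)
  for (r in 1:25) {
    t <- sample(2:6, 1); v <- sample(10:40, 1)
    votes <- matrix(rbinom(t * v, 1, runif(1, 0.2, 0.8)), t, v)
    truth <- rbinom(v, 1, 0.5)
    qbar <- 0; for (i in 1:t) for (j in 1:v)
      qbar <- qbar + (votes[i, j] == truth[j])
    qbar <- qbar / (t * v)
    dis <- 0; np <- 0
    for (i in 1:t) for (k in 1:t) if (i != k) {
      dis <- dis + mean(votes[i, ] != votes[k, ]); np <- np + 1
    }
    dis <- dis / np
    if (dis == 0) expected <- 1
    else if (qbar %in% c(0, 1)) next
    else expected <- 1 - dis / (2 * qbar * (1 - qbar))
    expect_equal(kappaDiversity(votes, truth), expected, tolerance = 1e-12)
  }
})

test_that("majority and weighted votes follow the >= threshold rules", {
  expect_equal(majorityVote(matrix(c(1, 1, 0), 3, 1)), 1L)
  expect_equal(majorityVote(matrix(c(1, 0), 2, 1)), 1L)   # tie -> 1
  expect_equal(majorityVote(matrix(c(1, 0, 0), 3, 1),
                            weights = c(0.6, 0.2, 0.2)), 1L)
  expect_equal(majorityVote(matrix(c(0, 1, 1), 3, 1),
                            weights = c(0.6, 0.2, 0.2)), 0L)
  expect_error(majorityVote(matrix(1, 2, 1), weights = c(0.7, 0.7)),
               "sum to 1")
  expect_error(majorityVote(matrix(1, 2, 1), weights = c(1.2, -0.2)),
               "non-negative")
})

test_that("divide-and-conquer voting equals the plain majority vote", {
  # exhaustive per-column check: all vote patterns for t = 1..5
  for (t in 1:5) {
    pats <- as.matrix(expand.grid(rep(list(0:1), t)))
    votes <- t(pats)
    for (th in c(1L, 2L, 3L, 1000000L))
      expect_identical(divideConquerVote(votes, th), majorityVote(votes))
  }
  # randomized suite incl. weights
  set.seed(21)
  for (r in 1:1000) {
    t <- sample(1:9, 1); v <- sample(1:200, 1)
    votes <- matrix(rbinom(t * v, 1, 0.5), t, v)
    th <- sample(c(1L, 3L, 17L, 10000L), 1)
    expect_identical(divideConquerVote(votes, th), majorityVote(votes))
  }
  w <- c(0.5, 0.3, 0.2)
  votes <- matrix(rbinom(3 * 50, 1, 0.5), 3, 50)
  expect_identical(divideConquerVote(votes, 7L, w), majorityVote(votes, w))
  expect_identical(divideConquerVote(matrix(integer(0), 3, 0), 5L), integer(0))
})

test_that("equidistant assessment picks the best value, order-invariantly", {
  tab <- makeBlobTable(n = 80L, q = 4L, sep = 6)
  plan <- splitTrainTest(tab, 0.75, seed = 2L)
  res <- assessModel("knn", paramSpec("k", 1, 15, 8, integer = TRUE), tab,
                     trainIndices(plan), testIndices(plan), seed = 1L)
  expect_equal(max(res$accuracies), 1)
  # single-value grid returns that value
  res1 <- assessModel("svm", paramSpec("cost", 2, 2, 1), tab,
                      trainIndices(plan), testIndices(plan), seed = 1L)
  expect_equal(res1$param, 2)
  # evaluation order cannot matter: same seed per value, rerun identical
  res2 <- assessModel("knn", paramSpec("k", 1, 15, 8, integer = TRUE), tab,
                      trainIndices(plan), testIndices(plan), seed = 1L)
  expect_identical(res$param, res2$param)
  expect_identical(res$accuracies, res2$accuracies)
  # a single-class training fold is refused
  y <- classLabels(tab)
  expect_error(assessModel("knn", paramSpec("k", 1, 3, 2, TRUE), tab,
                           which(y == 0L)[1:10], which(y == 1L)[1:5],
                           seed = 1L), "single class")
})

test_that("the internal deterministic KNN agrees with class::knn", {
  skip_if_not_installed("class")
  set.seed(30)
  for (r in 1:20) {
    tr <- matrix(rnorm(40 * 3), 40, 3)
    y <- rep(c(0L, 1L), each = 20L)
    te <- matrix(rnorm(15 * 3), 15, 3)
    k <- sample(c(1L, 3L, 5L), 1)       # odd k: no vote ties
    mine <- eegensembles:::knnVote(tr, y, te, k)
    ref <- as.integer(as.character(class::knn(tr, te, factor(y), k = k)))
    expect_identical(mine, ref)
  }
})

makePool <- function(votes, accs) {
  models <- lapply(seq_len(nrow(votes)), function(i)
    list(kind = "stub", param = i, predict = function(X) votes[i, ]))
  new("ModelPool", models = models, votes = votes, accuracies = accs,
      included = rep(TRUE, nrow(votes)), probs = rep(0.4, nrow(votes)))
}

test_that("k-means pruning keeps one best model per prediction cluster", {
  v <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  pool <- makePool(v, c(0.9, 0.7, 0.6, 0.8))
  pruned <- pruneKmeans(pool, k = 2L, seed = 1L)
  expect_equal(which(pruned@included), c(1L, 4L))
  # k >= t leaves the pool unchanged
  expect_identical(pruneKmeans(pool, k = 10L)@included, pool@included)
  # survivors are a subset of size <= k, and the global best survives
  set.seed(22)
  for (r in 1:10) {
    t <- sample(4:12, 1)
    votes <- matrix(rbinom(t * 30, 1, 0.5), t, 30)
    accs <- runif(t)
    p <- pruneKmeans(makePool(votes, accs), k = 3L, seed = r)
    expect_lte(sum(p@included), 3L)
    expect_true(p@included[which.max(accs)])
  }
})

test_that("ranking determination finds dominant members and never regresses", {
  set.seed(23)
  truth <- rbinom(40, 1, 0.5)
  perfect <- truth
  coins <- matrix(rbinom(4 * 40, 1, 0.5), 4, 40)
  votes <- rbind(perfect, coins)
  accs <- c(1, rowMeans(coins == matrix(truth, 4, 40, byrow = TRUE)))
  pool <- makePool(votes, accs)
  inc <- rankingDetermination(pool, truth, iterations = 300L, seed = 5L)
  acc <- mean(majorityVote(votes[inc, , drop = FALSE]) == truth)
  expect_equal(acc, 1)
  # single-model pool: trivially included
  single <- makePool(matrix(truth, 1), 1)
  expect_identical(rankingDetermination(single, truth), TRUE)
  # best-ever objective >= the initial solution's objective for random pools
  for (r in 1:5) {
    votes <- matrix(rbinom(6 * 30, 1, 0.5), 6, 30)
    truth2 <- rbinom(30, 1, 0.5)
    pool2 <- makePool(votes, rowMeans(votes == matrix(truth2, 6, 30,
                                                      byrow = TRUE)))
    inc2 <- rankingDetermination(pool2, truth2, iterations = 100L, seed = r)
    best <- mean(majorityVote(votes[inc2, , drop = FALSE]) == truth2)
    set.seed(r)  # reproduce the annealer's Bernoulli(0.4) start
    cur <- runif(6) < 0.4
    if (!any(cur)) { cur[] <- FALSE; cur[which.max(pool2@accuracies)] <- TRUE }
    init <- mean(majorityVote(votes[cur, , drop = FALSE]) == truth2)
    expect_gte(best, init)
  }
})

test_that("the fitted rank ensemble separates easy data and is reproducible", {
  tab <- makeBlobTable(n = 140L, q = 10L, sep = 4, seed = 9L)
  hold <- makeBlobTable(n = 60L, q = 10L, sep = 4, seed = 10L)
  fit <- fitRankEnsemble(tab, qFeatures = 6L, annealIterations = 150L,
                         seed = 3L)
  acc <- mean(predict(fit, hold) == classLabels(hold))
  expect_gte(acc, 0.9)
  fit2 <- fitRankEnsemble(tab, qFeatures = 6L, annealIterations = 150L,
                          seed = 3L)
  expect_identical(
    as.character(eegensembles:::manifestJSON(fit@manifest)),
    as.character(eegensembles:::manifestJSON(fit2@manifest)))
  expect_identical(which(fit@pool@included), which(fit2@pool@included))
})

test_that("ranked ensemble votes at least as well as the full pruned pool", {
  set.seed(24)
  ok <- 0L
  for (r in 1:10) {
    truth <- rbinom(60, 1, 0.5)
    t <- 8L
    votes <- do.call(rbind, lapply(1:t, function(i) {
      flip <- runif(60) < runif(1, 0.1, 0.5)
      ifelse(flip, 1L - truth, truth)
    }))
    accs <- rowMeans(votes == matrix(truth, t, 60, byrow = TRUE))
    pool <- makePool(votes, accs)
    inc <- rankingDetermination(pool, truth, iterations = 300L, seed = r)
    accSel <- mean(majorityVote(votes[inc, , drop = FALSE]) == truth)
    accAll <- mean(majorityVote(votes) == truth)
    ok <- ok + (accSel >= accAll - 0.02)
  }
  expect_equal(ok, 10L)
})
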