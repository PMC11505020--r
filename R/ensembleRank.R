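# Technique 1: equidistant parameter assessment, kappa diversity, k-means
# pruning in prediction space, annealed ranking determination, and
# majority / weighted / divide-and-conquer voting.

#' Equidistant assessment of one base model
#'
#' Trains the model at every grid value of its parameter on the training
#' indices and scores it on the validation indices; the value with the
#' highest validation accuracy wins (ties break toward the smaller value).
#' The result does not depend on the order the grid is evaluated in.
#'
#' @param kind base-model kind (see [defaultRoster()]).
#' @param spec a [paramSpec()].
#' @param table a [FeatureTable-class].
#' @param trainIdx,valIdx disjoint non-empty row indices.
#' @param seed integer seed (each grid value is fitted under the same seed).
#' @return List with `kind`, `param` (winning value), `accuracies` (named by
#'   grid value), `model` (fitted at the winner) and `votes` (its 0/1
#'   validation predictions).
#' @export
assessModel <- function(kind, spec, table, trainIdx, valIdx, seed = 1L) {
  if (!length(trainIdx) || !length(valIdx)) stopUsage("empty train/validate set")
  if (length(intersect(trainIdx, valIdx)))
    stopUsage("train and validate indices must be disjoint")
  y <- classLabels(table)
  if (length(unique(y[trainIdx])) < 2L)
    stopUsage("training fold holds a single class (indices %d..%d)",
              min(trainIdx), max(trainIdx))
  X <- featureValues(table)
  grid <- equidistantGrid(spec)
  fits <- lapply(grid, function(g)
    trainBaseModel(kind, g, X[trainIdx, , drop = FALSE], y[trainIdx], seed))
  accs <- vapply(fits, function(f)
    mean(f$predict(X[valIdx, , drop = FALSE]) == y[valIdx]), numeric(1))
  best <- which(accs == max(accs))[1L]   # grid is ordered, ties -> smaller
  list(kind = kind, param = grid[best],
       accuracies = stats::setNames(accs, grid), model = fits[[best]],
       votes = as.integer(fits[[best]]$predict(X[valIdx, , drop = FALSE])))
}

#' Kappa diversity of an ensemble's validation predictions
#'
#' Interrater-agreement style statistic
#' `kappa = 1 - Disav / (2 * qbar * (1 - qbar))`, where `qbar` is the mean
#' correctness over models and instances and `Disav` the mean pairwise
#' disagreement fraction over ordered model pairs. Identical members give 1;
#' complementary errors at `qbar = 0.5` give -1.
#'
#' @param votes 0/1 matrix, rows = models (>= 2), columns = instances.
#' @param truth 0/1 vector of true labels.
#' @return The diversity value.
#' @export
kappaDiversity <- function(votes, truth) {
  t <- nrow(votes)
  if (is.null(t) || t < 2L) stopUsage("kappaDiversity needs at least 2 models")
  correct <- votes == matrix(truth, nrow = t, ncol = ncol(votes), byrow = TRUE)
  qbar <- mean(correct)
  pairs <- utils::combn(t, 2L)
  dis <- mean(apply(pairs, 2L, function(p)
    mean(votes[p[1L], ] != votes[p[2L], ])))
  if (dis == 0) return(1)
  if (qbar %in% c(0, 1))
    stopUsage("degenerate pool: qbar = %g with nonzero disagreement", qbar)
  1 - dis / (2 * qbar * (1 - qbar))
}

#' Prune a model pool by k-means in prediction space
#'
#' Clusters the included models on their 0/1 validation prediction vectors
#' (squared Euclidean distance = disagreement count) into at most `k`
#' clusters and keeps only the highest-validation-accuracy model of each
#' cluster (ties break toward the lower model index).
#'
#' @param pool a [ModelPool-class].
#' @param k target cluster count (default 20); `k >= t` leaves the pool
#'   unchanged.
#' @param seed integer seed (k-means uses 10 seeded restarts).
#' @return The pool with losers marked excluded.
#' @export
pruneKmeans <- function(pool, k = 20L, seed = 1L) {
  stopifnot(is(pool, "ModelPool"))
  idx <- which(pool@included)
  t <- length(idx)
  if (t == 0L) stopUsage("empty pool")
  if (k >= t) return(pool)
  v <- pool@votes[idx, , drop = FALSE]
  distinct <- nrow(unique(v))
  kEff <- min(k, distinct)
  cl <- if (kEff == 1L) rep(1L, t) else withSeed(seed,
    stats::kmeans(v, centers = kEff, nstart = 10L)$cluster)
  keep <- logical(t)
  for (g in unique(cl)) {
    members <- which(cl == g)
    keep[members[which.max(pool@accuracies[idx][members])]] <- TRUE
  }
  inc <- logical(length(pool@included))
  inc[idx[keep]] <- TRUE
  methods::initialize(pool, included = inc)
}

#' Ranking determination by simulated annealing
#'
#' Searches 0/1 model-inclusion vectors for the subset whose majority vote
#' maximises validation accuracy (ties prefer fewer members). Start bits are
#' Bernoulli(0.4); the neighbour move flips one model drawn proportionally
#' to its selection probability; worse moves are accepted with probability
#' `exp(-delta/T)` under geometric cooling; models present in accepted
#' improving solutions have their selection probability multiplied by 1.1
#' (clamped at 0.95). An empty selection is repaired to the best single
#' model. The best-ever vector is returned.
#'
#' @param pool a (pruned) [ModelPool-class].
#' @param truth 0/1 validation labels aligned with the pool's predictions.
#' @param iterations annealing iterations (default 500).
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor per iteration.
#' @param seed integer seed.
#' @return Logical inclusion vector over all pool models.
#' @export
rankingDetermination <- function(pool, truth, iterations = 500L, t0 = 1.0,
                                 cooling = 0.95, seed = 1L) {
  stopifnot(is(pool, "ModelPool"))
  idx <- which(pool@included)
  t <- length(idx)
  votes <- pool@votes[idx, , drop = FALSE]
  accs <- pool@accuracies[idx]
  if (t == 1L) return(pool@included)
  obj <- function(z) {
    if (!any(z)) return(-Inf)
    mean(majorityVote(votes[z, , drop = FALSE]) == truth)
  }
  repair <- function(z) { z[] <- FALSE; z[which.max(accs)] <- TRUE; z }
  betterThan <- function(a, na, b, nb) a > b || (a == b && na < nb)
  withSeed(seed, {
    probs <- pool@probs[idx]
    cur <- stats::runif(t) < probs
    if (!any(cur)) cur <- repair(cur)
    curAcc <- obj(cur)
    best <- cur; bestAcc <- curAcc
    temp <- t0
    for (i in seq_len(iterations)) {
      j <- sample.int(t, 1L, prob = probs)
      cand <- cur; cand[j] <- !cand[j]
      if (!any(cand)) cand <- repair(cand)
      candAcc <- obj(cand)
      if (betterThan(candAcc, sum(cand), curAcc, sum(cur))) {
        if (candAcc > curAcc)
          probs[cand] <- pmin(probs[cand] * 1.1, 0.95)
        cur <- cand; curAcc <- candAcc
      } else if (stats::runif(1) < exp(-(curAcc - candAcc) / temp)) {
        cur <- cand; curAcc <- candAcc
      }
      if (betterThan(curAcc, sum(cur), bestAcc, sum(best))) {
        best <- cur; bestAcc <- curAcc
      }
      temp <- temp * cooling
    }
    inc <- logical(length(pool@included))
    inc[idx[best]] <- TRUE
    inc
  })
}

#' Majority and weighted voting
#'
#' Unweighted: an instance is labelled 1 iff at least half of the models
#' vote 1 (ties go to 1). Weighted: labelled 1 iff the weighted vote sum
#' reaches 1/2; weights must be non-negative and sum to one.
#'
#' @param votes 0/1 matrix, rows = models, columns = instances.
#' @param weights optional per-model weights.
#' @return Integer 0/1 vector, one label per instance.
#' @export
majorityVote <- function(votes, weights = NULL) {
  votes <- as.matrix(votes)
  t <- nrow(votes)
  if (t < 1L) stopUsage("no models to vote")
  if (is.null(weights)) return(as.integer(colSums(votes) >= t / 2))
  if (length(weights) != t) stopUsage("one weight per model required")
  if (any(weights < 0)) stopUsage("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stopUsage("weights must sum to 1")
  as.integer(colSums(votes * weights) >= 0.5)
}

#' Divide-and-conquer voting
#'
#' Recursively halves the instance set until blocks are at most `threshold`
#' wide, votes each block, and concatenates — bit-identical to
#' [majorityVote()] for every threshold and block order.
#'
#' @param votes 0/1 matrix, rows = models, columns = instances.
#' @param threshold maximum block width (default 10000).
#' @param weights optional per-model weights (see [majorityVote()]).
#' @return Integer 0/1 vector, one label per instance.
#' @export
divideConquerVote <- function(votes, threshold = 10000L, weights = NULL) {
  votes <- as.matrix(votes)
  if (threshold < 1L) stopUsage("threshold must be >= 1")
  v <- ncol(votes)
  if (v == 0L) return(integer(0))
  if (v <= threshold) return(majorityVote(votes, weights))
  half <- v %/% 2L
  c(divideConquerVote(votes[, seq_len(half), drop = FALSE], threshold, weights),
    divideConquerVote(votes[, (half + 1L):v, drop = FALSE], threshold, weights))
}

#' Fit the ranking-determination ensemble (Technique 1)
#'
#' Pipeline: ESCD feature selection (optional), stratified 90/10 internal
#' validation split, equidistant assessment of every roster model, k-means
#' pruning (default 20 clusters), annealed ranking determination, and a
#' divide-and-conquer majority-vote predictor over the selected members.
#'
#' @param table a [FeatureTable-class].
#' @param roster list of `list(kind, spec)` entries (default
#'   [defaultRoster()]).
#' @param qFeatures number of ESCD-selected features, or NULL for all.
#' @param kClusters k-means pruning cluster count.
#' @param annealIterations ranking-determination iterations.
#' @param voteThreshold divide-and-conquer block threshold.
#' @param seed integer seed recorded in the manifest.
#' @return A [RankEnsemble-class].
#' @export
fitRankEnsemble <- function(table, roster = defaultRoster(), qFeatures = NULL,
                            kClusters = 20L, annealIterations = 500L,
                            voteThreshold = 10000L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (!length(roster)) stopUsage("roster must be non-empty")
  escd <- data.frame()
  if (!is.null(qFeatures)) {
    sel <- escdSelect(table, qFeatures)
    escd <- sel$scores
    table <- selectFeatures(table, sel$selected)
  }
  plan <- splitTrainTest(table, 0.9, seed)
  trainIdx <- trainIndices(plan); valIdx <- testIndices(plan)
  assessed <- lapply(roster, function(r)
    assessModel(r$kind, r$spec, table, trainIdx, valIdx, seed))
  votes <- do.call(rbind, lapply(assessed, `[[`, "votes"))
  accs <- vapply(assessed, function(a) max(a$accuracies), numeric(1))
  pool <- new("ModelPool", models = lapply(assessed, `[[`, "model"),
              votes = votes, accuracies = unname(accs),
              included = rep(TRUE, length(assessed)),
              probs = rep(0.4, length(assessed)))
  pool <- pruneKmeans(pool, kClusters, seed)
  truth <- classLabels(table)[valIdx]
  inc <- rankingDetermination(pool, truth, annealIterations, seed = seed)
  pool <- methods::initialize(pool, included = inc)
  kap <- if (sum(inc) >= 2L)
    kappaDiversity(pool@votes[inc, , drop = FALSE], truth) else NA_real_
  members <- lapply(which(inc), function(i)
    list(kind = pool@models[[i]]$kind, param = pool@models[[i]]$param,
         accuracy = pool@accuracies[i]))
  manifest <- list(method = "rank", seed = seed, qFeatures = qFeatures,
                   kClusters = kClusters, annealIterations = annealIterations,
                   selectedFeatures = featureNames(table), members = members,
                   kappa = kap)
  new("RankEnsemble", pool = pool, selectedFeatures = featureNames(table),
      escd = escd, kappa = kap, voteThreshold = as.integer(voteThreshold),
      manifest = manifest)
}

#' Predict with a fitted RankEnsemble
#'
#' @param object a [RankEnsemble-class].
#' @param newdata a [FeatureTable-class] or feature matrix with named
#'   columns covering the selected features.
#' @param ... unused.
#' @return Integer 0/1 labels.
#' @export
setMethod("predict", "RankEnsemble", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureValues(newdata) else newdata
  X <- X[, object@selectedFeatures, drop = FALSE]
  inc <- which(object@pool@included)
  votes <- do.call(rbind, lapply(object@pool@models[inc], function(m)
    as.integer(m$predict(X))))
  divideConquerVote(votes, object@voteThreshold)
})

setMethod("show", "RankEnsemble", function(object) {
  cat(sprintf("RankEnsemble: %d members over %d features (kappa %.3f)\n",
              sum(object@pool@included), length(object@selectedFeatures),
              object@kappa))
})
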