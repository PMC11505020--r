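# Techniques 3 & 4: GA feature selection + bagged RBF-SVMs, and HHT features
# + GA multiparameter tuning of three tree-ensemble learners with a final
# majority vote.

#' Fit a bagged RBF-SVM ensemble
#'
#' Draws `R` bootstrap resamples (size = training size, with replacement),
#' fits one RBF-kernel SVM per resample, and records each weak classifier's
#' in-bag misclassification fraction. A bootstrap draw containing a single
#' class is redrawn (up to 10 retries). Prediction is by majority vote.
#'
#' @param table a [FeatureTable-class].
#' @param R number of bags (default 25).
#' @param cost SVM cost parameter.
#' @param seed integer seed; bootstrap indices are reproducible.
#' @return A [BaggingPool-class].
#' @export
fitBaggingSVM <- function(table, R = 25L, cost = 1, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  R <- as.integer(R)
  if (R < 1L) stopUsage("R must be >= 1")
  X <- featureValues(table); y <- classLabels(table)
  n <- nrow(X)
  withSeed(seed, {
    models <- vector("list", R)
    eps <- numeric(R)
    boots <- vector("list", R)
    for (r in seq_len(R)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0L
      while (length(unique(y[idx])) < 2L) {
        tries <- tries + 1L
        if (tries > 10L) stopUsage("bootstrap sample kept a single class")
        idx <- sample.int(n, n, replace = TRUE)
      }
      fit <- suppressWarnings(e1071::svm(
        X[idx, , drop = FALSE], factor(y[idx], levels = c(0, 1)),
        kernel = "radial", cost = cost, scale = TRUE))
      inbag <- as.integer(as.character(
        stats::predict(fit, X[idx, , drop = FALSE])))
      eps[r] <- mean(inbag != y[idx])
      models[[r]] <- fit
      boots[[r]] <- idx
    }
    new("BaggingPool", models = models, errorRates = eps,
        bootIndices = boots, featureNames = featureNames(table),
        seed = as.integer(seed))
  })
}

#' Predict with a BaggingPool
#'
#' @param object a [BaggingPool-class].
#' @param newdata a [FeatureTable-class] or feature matrix.
#' @param ... unused.
#' @return Integer 0/1 labels (majority vote over the bags).
#' @export
setMethod("predict", "BaggingPool", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureValues(newdata) else newdata
  X <- X[, object@featureNames, drop = FALSE]
  votes <- do.call(rbind, lapply(object@models, function(m)
    as.integer(as.character(stats::predict(m, X)))))
  majorityVote(votes)
})

setMethod("show", "BaggingPool", function(object) {
  cat(sprintf("BaggingPool: %d bags, mean in-bag error %.3f\n",
              length(object@models), mean(object@errorRates)))
})

# Stratified-CV accuracy of a single RBF-SVM on masked feature columns.
maskedSvmCvAccuracy <- function(X, y, bits, folds = 3L, seed = 1L) {
  cols <- which(bits == 1L)
  if (!length(cols)) return(0)
  withSeed(seed, {
    g <- stratifiedGroups(y, folds)
    mean(unlist(lapply(seq_len(folds), function(j) {
      tr <- g != j
      fit <- suppressWarnings(e1071::svm(
        X[tr, cols, drop = FALSE], factor(y[tr], levels = c(0, 1)),
        kernel = "radial", scale = TRUE))
      as.integer(as.character(stats::predict(
        fit, X[!tr, cols, drop = FALSE]))) == y[!tr]
    })))
  })
}

#' GA feature selection + bagged SVM classification (Technique 3)
#'
#' Runs the binary GA with fitness = internal stratified-CV accuracy of a
#' single RBF-SVM on the masked features (minus the feature-count penalty),
#' then fits the bagged SVM ensemble on the winning mask.
#'
#' @param table a [FeatureTable-class].
#' @param ga a [gaConfig()].
#' @param R number of bags for the final ensemble.
#' @param folds internal CV folds for the evaluator.
#' @param seed integer seed for the bagging stage.
#' @return A [GABaggingModel-class].
#' @export
fitGABagging <- function(table, ga = gaConfig(), R = 25L, folds = 3L,
                         seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  X <- featureValues(table); y <- classLabels(table)
  res <- gaSelect(table, ga, function(bits)
    maskedSvmCvAccuracy(X, y, bits, folds, ga$seed))
  mask <- res$bits == 1L
  pool <- fitBaggingSVM(selectFeatures(table, which(mask)), R = R, seed = seed)
  manifest <- list(method = "gabag", seed = seed, gaSeed = ga$seed, R = R,
                   mask = as.integer(mask),
                   selectedFeatures = featureNames(table)[mask],
                   gaBestFitness = res$fitness)
  new("GABaggingModel", mask = mask, pool = pool, history = res$history,
      featureNames = featureNames(table), manifest = manifest)
}

#' @describeIn fitGABagging predict with the fitted model
#' @param object a `GABaggingModel`
#' @param newdata a [FeatureTable-class] or feature matrix.
#' @param ... unused.
#' @export
setMethod("predict", "GABaggingModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureValues(newdata) else newdata
  predict(object@pool, X[, object@featureNames[object@mask], drop = FALSE])
})

setMethod("show", "GABaggingModel", function(object) {
  cat(sprintf("GABaggingModel: %d/%d features selected, %d bags\n",
              sum(object@mask), length(object@mask),
              length(object@pool@models)))
})

## ---------------------------------------------------------------------------
## Technique 4: GA multiparameter tuning of RF + gradient boosting +
## histogram (leaf-wise) boosting, majority vote of the three.
## ---------------------------------------------------------------------------

#' Hyperparameter search bounds for the tree-ensemble trio
#'
#' Genes are `c(lo, hi, integer?)`; the conventional settings are the
#' defaults and sit at the bounds' midpoints: random forest trees 100,
#' leaf-node cap 10, minimum node size 15; gradient boosting eta 0.4,
#' max depth 4, min child weight 2, gamma 0.2; histogram boosting leaf
#' count 10, learning rate 0.4, max depth 4.
#'
#' @return Named list of gene bounds.
#' @export
hyperBounds <- function() {
  list(rf_ntree = c(50, 150, 1), rf_maxnodes = c(5, 15, 1),
       rf_nodesize = c(10, 20, 1),
       xgb_eta = c(0.1, 0.7, 0), xgb_max_depth = c(2, 6, 1),
       xgb_min_child_weight = c(1, 3, 0), xgb_gamma = c(0, 0.4, 0),
       hist_leaves = c(4, 16, 1), hist_eta = c(0.1, 0.7, 0),
       hist_max_depth = c(2, 6, 1))
}

defaultHyperParams <- function() {
  b <- hyperBounds()
  vals <- vapply(b, function(g) {
    m <- (g[1L] + g[2L]) / 2
    if (g[3L] == 1) roundHalfUp(m) else m
  }, numeric(1))
  as.list(vals)
}

fitTreeTrio <- function(X, y, p, nrounds = 100L, seed = 1L) {
  yf <- factor(y, levels = c(0, 1))
  withSeed(seed, {
    rf <- randomForest::randomForest(
      X, yf, ntree = as.integer(p$rf_ntree),
      maxnodes = as.integer(p$rf_maxnodes),
      nodesize = as.integer(p$rf_nodesize))
    dtr <- xgboost::xgb.DMatrix(X, label = y)
    xgb <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = p$xgb_eta,
                    max_depth = as.integer(p$xgb_max_depth),
                    min_child_weight = p$xgb_min_child_weight,
                    gamma = p$xgb_gamma, max_delta_step = 1.5,
                    lambda = 1, alpha = 1, nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0)
    hist <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    tree_method = "hist", grow_policy = "lossguide",
                    max_leaves = as.integer(p$hist_leaves),
                    eta = p$hist_eta,
                    max_depth = as.integer(p$hist_max_depth),
                    max_delta_step = 1.5, lambda = 1, alpha = 1,
                    nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0)
    list(
      list(kind = "rf", predict = function(newX) as.integer(as.character(
        stats::predict(rf, newX)))),
      list(kind = "xgb", predict = function(newX) as.integer(
        stats::predict(xgb, xgboost::xgb.DMatrix(newX)) > 0.5)),
      list(kind = "hist", predict = function(newX) as.integer(
        stats::predict(hist, xgboost::xgb.DMatrix(newX)) > 0.5)))
  })
}

trioCvAccuracy <- function(X, y, p, folds = 3L, nrounds = 100L, seed = 1L) {
  withSeed(seed, {
    g <- stratifiedGroups(y, folds)
    mean(unlist(lapply(seq_len(folds), function(j) {
      tr <- g != j
      fits <- fitTreeTrio(X[tr, , drop = FALSE], y[tr], p, nrounds, seed + j)
      votes <- do.call(rbind, lapply(fits, function(f)
        f$predict(X[!tr, , drop = FALSE])))
      majorityVote(votes) == y[!tr]
    })))
  })
}

#' GA multiparameter tuning of the tree-ensemble trio (Technique 4)
#'
#' Real-coded GA over the [hyperBounds()] genes with fitness = mean
#' stratified-CV accuracy of the majority vote of the three learners (the
#' classification counterpart of a relative-error fitness for this binary
#' task). The best chromosome is decoded and the trio refitted on the full
#' table; prediction is the (tie-free, three-member) majority vote.
#'
#' @param table a [FeatureTable-class] (typically [hhtFeatures()] output).
#' @param ga a [gaConfig()].
#' @param bounds gene bounds (default [hyperBounds()]).
#' @param folds internal CV folds.
#' @param nrounds boosting rounds (the study's estimator count, 100).
#' @param seed integer seed.
#' @return A [TunedTreeEnsemble-class].
#' @export
gaTuneEnsemble <- function(table, ga = gaConfig(), bounds = hyperBounds(),
                           folds = 3L, nrounds = 100L, seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  X <- featureValues(table); y <- classLabels(table)
  res <- gaOptimizeReal(bounds, ga, function(v) {
    p <- stats::setNames(as.list(v), names(bounds))
    trioCvAccuracy(X, y, p, folds, nrounds, ga$seed)
  })
  params <- stats::setNames(as.list(res$values), names(bounds))
  fits <- fitTreeTrio(X, y, params, nrounds, seed)
  manifest <- list(method = "hht", seed = seed, gaSeed = ga$seed,
                   params = params, nrounds = nrounds,
                   gaBestFitness = res$fitness)
  new("TunedTreeEnsemble", fits = fits, params = params,
      history = res$history, featureNames = featureNames(table),
      manifest = manifest)
}

#' Predict with a TunedTreeEnsemble
#'
#' @param object a [TunedTreeEnsemble-class].
#' @param newdata a [FeatureTable-class] or feature matrix.
#' @param ... unused.
#' @return Integer 0/1 labels (three-member vote; odd count, so tie-free).
#' @export
setMethod("predict", "TunedTreeEnsemble", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureValues(newdata) else newdata
  X <- X[, object@featureNames, drop = FALSE]
  votes <- do.call(rbind, lapply(object@fits, function(f)
    as.integer(f$predict(X))))
  stopifnot(nrow(votes) %% 2L == 1L)
  majorityVote(votes)
})

setMethod("show", "TunedTreeEnsemble", function(object) {
  cat(sprintf("TunedTreeEnsemble: RF + boosting x2, GA best fitness %.3f\n",
              max(object@history)))
})
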