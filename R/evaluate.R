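# Metrics and the cross-validated evaluation harness over the five methods.

#' Confusion counts for binary predictions
#'
#' The positive class is label 1 (abnormal).
#'
#' @param predicted,truth equal-length 0/1 vectors.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopUsage("predicted and truth differ in length")
  c(TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == 0L),
    TN = sum(predicted == 0L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/n`. An empty denominator yields `NA` with a warning.
#'
#' @param counts named vector from [confusionCounts()].
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
classMetrics <- function(counts) {
  n <- sum(counts)
  if (n == 0L) stopUsage("no evaluated instances")
  sens <- if (counts[["TP"]] + counts[["FN"]] > 0)
    counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
  else { warning("sensitivity undefined: no positive instances"); NA_real_ }
  spec <- if (counts[["TN"]] + counts[["FP"]] > 0)
    counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
  else { warning("specificity undefined: no negative instances"); NA_real_ }
  c(sensitivity = sens, specificity = spec,
    accuracy = (counts[["TP"]] + counts[["TN"]]) / n)
}

# Fit one method on the training rows and predict the validation rows.
fitAndPredict <- function(method, table, trainIdx, valIdx, seed, config) {
  sub <- FeatureTable(featureValues(table)[trainIdx, , drop = FALSE],
                      classLabels(table)[trainIdx])
  newX <- featureValues(table)[valIdx, , drop = FALSE]
  cfg <- function(name, default) config[[name]] %||% default
  if (method == "rank") {
    fit <- fitRankEnsemble(
      sub, roster = cfg("roster", defaultRoster()),
      qFeatures = cfg("qFeatures", min(30L, ncol(newX))),
      kClusters = cfg("kClusters", 20L),
      annealIterations = cfg("annealIterations", 500L), seed = seed)
    list(pred = predict(fit, newX), manifest = fit@manifest)
  } else if (method == "ica") {
    Xtr <- zscoreColumns(featureValues(sub))
    mu <- colMeans(featureValues(sub))
    sd <- apply(featureValues(sub), 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- Inf
    model <- fitIICA(t(Xtr), qTrunc = cfg("qTrunc", 16L),
                     sweeps = cfg("sweeps", 200L), seed = seed)
    # project train and validation samples through the same H-basis least
    # squares so both live in one coordinate system
    lat <- FeatureTable(iicaTransform(model, t(Xtr)), classLabels(sub))
    Qa <- ncol(featureValues(lat))
    plan <- planSubspaces(Qa, min(cfg("subspaces", 5L), Qa), seed)
    ens <- fitSubspaceEnsemble(lat, plan, mode = cfg("mode", "hybrid"),
                               config = config, seed = seed)
    Xval <- sweep(sweep(newX, 2L, mu, "-"), 2L, sd, "/")
    latVal <- iicaTransform(model, t(Xval))
    list(pred = predict(ens, latVal),
         manifest = c(ens@manifest, activeSources = activeSourceCount(model)))
  } else if (method == "gabag") {
    fit <- fitGABagging(
      sub, ga = cfg("ga", gaConfig(populationSize = 30L, generations = 20L,
                                   seed = seed)),
      R = cfg("R", 25L), folds = cfg("folds", 3L), seed = seed)
    list(pred = predict(fit, newX), manifest = fit@manifest)
  } else if (method == "hht") {
    fit <- gaTuneEnsemble(
      sub, ga = cfg("ga", gaConfig(populationSize = 20L, generations = 15L,
                                   seed = seed)),
      folds = cfg("folds", 3L), nrounds = cfg("nrounds", 100L), seed = seed)
    list(pred = predict(fit, newX), manifest = fit@manifest)
  } else if (method == "falknn") {
    fit <- fitFaLknn(sub, nFactors = cfg("nFactors", 8L), L = cfg("L", 4L),
                     k = cfg("k", 5L))
    list(pred = predict(fit, newX), manifest = fit@manifest)
  } else stopUsage("unknown method '%s'; valid: rank, ica, gabag, hht, falknn",
                   method)
}

#' Cross-validated evaluation of one pipeline
#'
#' Runs a stratified k-fold loop over the samples; all data-driven fitting
#' (feature selection, GA, annealing, sampling) is re-run inside each
#' training fold only, so no information leaks from the validation folds.
#' Metrics are reported per fold and pooled over the fold confusion counts.
#'
#' @param method one of `"rank"`, `"ica"`, `"gabag"`, `"hht"`, `"falknn"`.
#' @param data a [FeatureTable-class] (for `"hht"` pass a table of
#'   [hhtFeatures()]), or an [EpochSet-class] which is converted via
#'   [extractFeatures()] / [hhtFeatures()] first.
#' @param kFolds number of folds (>= 2, default 10).
#' @param seed integer seed controlling folds and all fitting.
#' @param config named list of method settings (see the method functions).
#' @return An `EvalReport` list: method, per-fold metrics, pooled counts
#'   and metrics, fold-mean metrics, config echo, seed, and a canonical
#'   JSON manifest string (byte-identical across runs with equal inputs).
#' @export
evaluateMethod <- function(method, data, kFolds = 10L, seed = 1L,
                           config = list()) {
  if (is(data, "EpochSet"))
    data <- if (method == "hht") hhtFeatures(data) else extractFeatures(data)
  stopifnot(is(data, "FeatureTable"))
  kFolds <- as.integer(kFolds)
  if (kFolds < 2L) stopUsage("kFolds must be >= 2")
  y <- classLabels(data)
  g <- withSeed(seed, stratifiedGroups(y, kFolds))
  perFold <- vector("list", kFolds)
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  manifests <- vector("list", kFolds)
  for (j in seq_len(kFolds)) {
    trainIdx <- which(g != j); valIdx <- which(g == j)
    res <- fitAndPredict(method, data, trainIdx, valIdx, seed + j, config)
    cc <- confusionCounts(res$pred, y[valIdx])
    counts <- counts + cc
    perFold[[j]] <- c(fold = j, cc, suppressWarnings(classMetrics(cc)))
    manifests[[j]] <- res$manifest
  }
  pooled <- classMetrics(counts)
  foldAcc <- vapply(perFold, function(f) f[["accuracy"]], numeric(1))
  report <- list(method = method, seed = seed, kFolds = kFolds,
                 counts = as.list(counts), pooled = as.list(pooled),
                 foldMeanAccuracy = mean(foldAcc),
                 perFold = perFold, config = config,
                 foldManifests = manifests)
  report$manifestJSON <- as.character(manifestJSON(
    report[c("method", "seed", "kFolds", "counts", "pooled",
             "foldManifests")]))
  class(report) <- "EvalReport"
  report
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport [%s], %d-fold CV (seed %d)\n", x$method, x$kFolds,
              x$seed))
  cat(sprintf("  pooled: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$pooled$sensitivity, x$pooled$specificity, x$pooled$accuracy))
  invisible(x)
}
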