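#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' EpochSet: labelled multichannel EEG epochs
#'
#' Holds a 3-D signal array (epochs x channels x timepoints, microvolts),
#' the sampling rate, one binary label per epoch (0 = normal, 1 = abnormal),
#' channel names and stable epoch identifiers.
#'
#' @slot signals numeric array `[nEpochs x nChannels x nTimepoints]` in uV.
#' @slot fs sampling rate in Hz.
#' @slot labels integer vector in `{0, 1}`, one per epoch.
#' @slot channelNames character vector of channel names.
#' @slot epochIds character vector of stable epoch identifiers.
#'
#' @seealso [generateSynthetic()], [readEDF()], [extractFeatures()]
#' @export
setClass("EpochSet",
  representation(
    signals = "array",
    fs = "numeric",
    labels = "integer",
    channelNames = "character",
    epochIds = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@signals)
  if (length(d) != 3L) return("signals must be a 3-D array (epochs x channels x time)")
  if (d[1L] != length(object@labels)) return("n_epochs must equal length(labels)")
  if (d[1L] != length(object@epochIds)) return("n_epochs must equal length(epochIds)")
  if (d[2L] != length(object@channelNames)) return("n_channels must equal length(channelNames)")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must take values only in {0, 1}")
  TRUE
})

#' Construct an EpochSet
#'
#' @param signals numeric array `[nEpochs x nChannels x nTimepoints]`.
#' @param fs sampling rate (Hz).
#' @param labels binary vector (0/1), one per epoch.
#' @param channelNames optional channel names (default `"ch01"...`).
#' @param epochIds optional epoch identifiers (default `"ep000001"...`).
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(signals, fs, labels,
                     channelNames = NULL, epochIds = NULL) {
  d <- dim(signals)
  if (is.null(channelNames)) channelNames <- sprintf("ch%02d", seq_len(d[2L]))
  if (is.null(epochIds)) epochIds <- sprintf("ep%06d", seq_len(d[1L]))
  new("EpochSet", signals = signals, fs = as.numeric(fs),
      labels = as.integer(labels), channelNames = channelNames,
      epochIds = epochIds)
}

#' @describeIn EpochSet number of epochs
#' @param x,object an `EpochSet`
#' @export
nEpochs <- function(x) dim(x@signals)[1L]

#' @describeIn EpochSet number of channels
#' @export
nChannels <- function(x) dim(x@signals)[2L]

#' @describeIn EpochSet samples per epoch
#' @export
nTimepoints <- function(x) dim(x@signals)[3L]

#' @describeIn EpochSet signal array accessor
#' @export
signals <- function(x) x@signals

#' @describeIn EpochSet sampling rate accessor
#' @export
samplingRate <- function(x) x@fs

#' Labels accessor
#'
#' @param x an [EpochSet-class] or [FeatureTable-class].
#' @return integer 0/1 vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "EpochSet", function(x) x@labels)

#' @describeIn EpochSet channel names accessor
#' @export
channelNames <- function(x) x@channelNames

#' @describeIn EpochSet epoch identifiers accessor
#' @export
epochIds <- function(x) x@epochIds

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@signals)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fs))
  cat(sprintf("  labels: %d normal / %d abnormal\n",
              sum(object@labels == 0L), sum(object@labels == 1L)))
})

## ---------------------------------------------------------------------------

#' SplitPlan: train/test split with optional stratified folds
#'
#' @slot trainIndices,testIndices disjoint 1-based index vectors.
#' @slot folds list of `list(train =, validate =)` pairs partitioning the
#'   training indices (possibly empty).
#' @slot labels 0/1 labels of the full data set the plan indexes (kept so
#'   fold construction can stratify without re-supplying the data).
#' @slot seed integer seed the plan was drawn under.
#' @export
setClass("SplitPlan",
  representation(trainIndices = "integer", testIndices = "integer",
                 folds = "list", labels = "integer", seed = "integer")
)

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainIndices, object@testIndices)))
    return("train and test indices must be disjoint")
  for (f in object@folds) {
    if (!setequal(c(f$train, f$validate), object@trainIndices) ||
        length(intersect(f$train, f$validate)))
      return("each fold must partition the training indices")
  }
  TRUE
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test, %d folds (seed %d)\n",
              length(object@trainIndices), length(object@testIndices),
              length(object@folds), object@seed))
})

#' @describeIn SplitPlan training index accessor
#' @param x a `SplitPlan`
#' @export
trainIndices <- function(x) x@trainIndices

#' @describeIn SplitPlan test index accessor
#' @export
testIndices <- function(x) x@testIndices

#' @describeIn SplitPlan folds accessor
#' @export
cvFolds <- function(x) x@folds

## ---------------------------------------------------------------------------

#' FeatureTable: samples x named features plus binary labels
#'
#' @slot values numeric matrix (samples x features), column names are the
#'   feature names (channel-qualified, e.g. `"ch03.line_length"`).
#' @slot labels integer 0/1 vector aligned with rows.
#' @slot provenance named list mapping feature name to extractor metadata.
#' @export
setClass("FeatureTable",
  representation(values = "matrix", labels = "integer", provenance = "list")
)

setValidity("FeatureTable", function(object) {
  if (nrow(object@values) != length(object@labels))
    return("number of rows must equal length(labels)")
  if (is.null(colnames(object@values)))
    return("feature columns must be named")
  if (anyDuplicated(colnames(object@values)))
    return("feature names must be unique")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must take values only in {0, 1}")
  TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix with named columns.
#' @param labels binary 0/1 vector, one per row.
#' @param provenance optional named list of per-feature extractor metadata.
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(values, labels, provenance = list()) {
  new("FeatureTable", values = values, labels = as.integer(labels),
      provenance = provenance)
}

#' @describeIn FeatureTable feature matrix accessor
#' @param x a `FeatureTable`
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureTable feature names accessor
#' @export
featureNames <- function(x) colnames(x@values)

#' @rdname classLabels
#' @export
setMethod("classLabels", "FeatureTable", function(x) x@labels)

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features\n",
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  labels: %d normal / %d abnormal\n",
              sum(object@labels == 0L), sum(object@labels == 1L)))
})

#' Subset the feature columns of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @param features character vector of feature names (or integer indices).
#' @return A [FeatureTable-class] with the selected columns.
#' @export
selectFeatures <- function(x, features) {
  stopifnot(is(x, "FeatureTable"))
  v <- x@values[, features, drop = FALSE]
  FeatureTable(v, x@labels, x@provenance[colnames(v)])
}

## ---------------------------------------------------------------------------
## Fitted-model containers (one class per pipeline)
## ---------------------------------------------------------------------------

#' ModelPool: trained base models with validation predictions
#'
#' @slot models list of fitted base models (each with `kind`, `param`,
#'   `predict` closure).
#' @slot votes integer 0/1 matrix, rows = models, columns = validation
#'   instances.
#' @slot accuracies numeric validation accuracy per model.
#' @slot included logical inclusion state per model.
#' @slot probs numeric per-model selection probabilities.
#' @export
setClass("ModelPool",
  representation(models = "list", votes = "matrix", accuracies = "numeric",
                 included = "logical", probs = "numeric")
)

setValidity("ModelPool", function(object) {
  t <- length(object@models)
  if (t < 1L) return("pool must hold at least one model")
  if (nrow(object@votes) != t) return("votes must have one row per model")
  if (length(object@votes) && !all(object@votes %in% c(0L, 1L)))
    return("votes must be 0/1")
  if (length(object@accuracies) != t || length(object@included) != t ||
      length(object@probs) != t)
    return("per-model vectors must match the number of models")
  if (any(object@probs <= 0 | object@probs >= 1))
    return("selection probabilities must lie in (0, 1)")
  TRUE
})

setMethod("show", "ModelPool", function(object) {
  cat(sprintf("ModelPool: %d models (%d included), %d validation instances\n",
              length(object@models), sum(object@included), ncol(object@votes)))
})

#' RankEnsemble: fitted equidistant-assessment / ranking-determination model
#'
#' @slot pool the pruned and rank-selected [ModelPool-class].
#' @slot selectedFeatures character feature names used by members.
#' @slot escd data.frame of ESCD scores (or NULL-length when selection off).
#' @slot kappa numeric diversity diagnostic of the final member set.
#' @slot voteThreshold integer divide-and-conquer block threshold.
#' @slot manifest named list (seeds, members, parameters).
#' @export
setClass("RankEnsemble",
  representation(pool = "ModelPool", selectedFeatures = "character",
                 escd = "data.frame", kappa = "numeric",
                 voteThreshold = "integer", manifest = "list")
)

#' IICAModel: finite-truncation infinite-ICA Gibbs posterior state
#'
#' @slot H mixing matrix (observed dim x Q).
#' @slot W source matrix (Q x D).
#' @slot B binary mask (Q x D).
#' @slot piQ per-source activation probabilities.
#' @slot sigmaE2 noise variance.
#' @slot errorTrace per-sweep mean squared reconstruction error.
#' @slot center per-row centering applied to the data before fitting.
#' @slot seed integer seed.
#' @export
setClass("IICAModel",
  representation(H = "matrix", W = "matrix", B = "matrix", piQ = "numeric",
                 sigmaE2 = "numeric", errorTrace = "numeric",
                 center = "numeric", seed = "integer")
)

setValidity("IICAModel", function(object) {
  if (length(object@B) && !all(object@B %in% c(0, 1))) return("B must be binary")
  if (any(object@piQ <= 0 | object@piQ >= 1)) return("pi_q must lie in (0, 1)")
  if (object@sigmaE2 <= 0) return("noise variance must be positive")
  TRUE
})

#' @describeIn IICAModel number of sources with at least one active entry
#' @param x an `IICAModel`
#' @export
activeSourceCount <- function(x) sum(rowSums(x@B) > 0)

setMethod("show", "IICAModel", function(object) {
  cat(sprintf("IICAModel: %d x %d mask, %d active sources, sigma_e^2 = %.4g\n",
              nrow(object@B), ncol(object@B), activeSourceCount(object),
              object@sigmaE2))
})

#' SubspaceEnsemble: random-subspace SVM or hybrid ensemble
#'
#' @slot members list of fitted members (kind, subspace, model, predict).
#' @slot plan list of disjoint feature-index blocks.
#' @slot mode `"svm"` or `"hybrid"`.
#' @slot featureNames training feature names.
#' @slot manifest named list.
#' @export
setClass("SubspaceEnsemble",
  representation(members = "list", plan = "list", mode = "character",
                 featureNames = "character", manifest = "list")
)

#' BaggingPool: bagged RBF-SVM ensemble with in-bag error rates
#'
#' @slot models list of fitted SVMs.
#' @slot errorRates in-bag misclassification fraction per bag.
#' @slot bootIndices list of bootstrap index vectors.
#' @slot featureNames training feature names.
#' @slot seed integer seed.
#' @export
setClass("BaggingPool",
  representation(models = "list", errorRates = "numeric",
                 bootIndices = "list", featureNames = "character",
                 seed = "integer")
)

setValidity("BaggingPool", function(object) {
  if (any(object@errorRates < 0 | object@errorRates > 1))
    return("error rates must lie in [0, 1]")
  TRUE
})

#' @describeIn BaggingPool in-bag error-rate accessor
#' @param x a `BaggingPool`
#' @export
bagErrorRates <- function(x) x@errorRates

#' GABaggingModel: GA-selected features + bagged SVMs
#'
#' @slot mask logical feature-selection mask over the training features.
#' @slot pool the fitted [BaggingPool-class] on the masked features.
#' @slot history per-generation best GA fitness.
#' @slot featureNames all training feature names.
#' @slot manifest named list.
#' @export
setClass("GABaggingModel",
  representation(mask = "logical", pool = "BaggingPool", history = "numeric",
                 featureNames = "character", manifest = "list")
)

#' TunedTreeEnsemble: GA-tuned RF + gradient-boosting + histogram-boosting vote
#'
#' @slot fits list of the three fitted learners (each with predict closure).
#' @slot params named list of tuned hyperparameter values.
#' @slot history per-generation best GA fitness.
#' @slot featureNames training feature names.
#' @slot manifest named list.
#' @export
setClass("TunedTreeEnsemble",
  representation(fits = "list", params = "list", history = "numeric",
                 featureNames = "character", manifest = "list")
)

#' FactorModel: maximum-likelihood factor-analysis fit
#'
#' @slot W loadings matrix (features x factors), covariance scale.
#' @slot noise diagonal noise variances (uniquenesses), covariance scale.
#' @slot center fitted feature means.
#' @slot nFactors number of factors.
#' @slot logLik final log-likelihood.
#' @slot featureNames names of fitted columns (zero-variance columns dropped).
#' @export
setClass("FactorModel",
  representation(W = "matrix", noise = "numeric", center = "numeric",
                 nFactors = "integer", logLik = "numeric",
                 featureNames = "character")
)

setValidity("FactorModel", function(object) {
  if (any(object@noise <= 0)) return("noise variances must be positive")
  TRUE
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf("FactorModel: %d features -> %d factors (logLik %.2f)\n",
              nrow(object@W), object@nFactors, object@logLik))
})

#' LayeredClassMap: per-class centers, fences, layers and weights for LKNN
#'
#' @slot classes the class labels (0, 1).
#' @slot centers list of class center vectors.
#' @slot quartiles list of `c(Q1, Q2, Q3)` of member-to-center distances.
#' @slot fences list of `c(Vlow, Vhigh)` Tukey fences.
#' @slot retained matrix of retained training points (rows).
#' @slot retainedLabels labels of retained points.
#' @slot retainedLayer layer index (1..L) of each retained point.
#' @slot layerWeights weight per layer (length L, non-increasing).
#' @slot fFar farthest retained distance per class.
#' @slot fMax global maximum of `fFar`.
#' @slot L layer count.
#' @export
setClass("LayeredClassMap",
  representation(classes = "integer", centers = "list", quartiles = "list",
                 fences = "list", retained = "matrix",
                 retainedLabels = "integer", retainedLayer = "integer",
                 layerWeights = "numeric", fFar = "numeric", fMax = "numeric",
                 L = "integer")
)

setValidity("LayeredClassMap", function(object) {
  for (f in object@fences) if (f[1L] > f[2L]) return("Vlow must be <= Vhigh")
  if (length(object@retainedLayer) &&
      (min(object@retainedLayer) < 1L || max(object@retainedLayer) > object@L))
    return("layer indices must lie in 1..L")
  if (is.unsorted(rev(object@layerWeights)))
    return("layer weights must be non-increasing in layer index")
  if (any(object@layerWeights <= 0)) return("layer weights must be positive")
  TRUE
})

setMethod("show", "LayeredClassMap", function(object) {
  cat(sprintf("LayeredClassMap: %d retained members, %d layers, Fmax = %.3g\n",
              nrow(object@retained), object@L, object@fMax))
})

#' FaLknnModel: factor analysis + layered KNN pipeline
#'
#' @slot fa the fitted [FactorModel-class].
#' @slot map the fitted [LayeredClassMap-class] on factor scores.
#' @slot k neighbourhood size used at prediction.
#' @slot manifest named list.
#' @export
setClass("FaLknnModel",
  representation(fa = "FactorModel", map = "LayeredClassMap", k = "integer",
                 manifest = "list")
)
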