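# Base-learner wrappers. Each returns a list(kind, param, predict) where
# predict maps a feature matrix to 0/1 integer labels. Standard learners are
# delegated to their established implementations; KNN is resolved internally
# so that distance ties break deterministically.

#' Equidistant parameter specification
#'
#' Describes a parameter swept over `steps` equally spaced values between
#' `start` and `stop` inclusive, e.g. `paramSpec("k", 2, 16, 4, TRUE)`.
#'
#' @param name parameter name.
#' @param start,stop range endpoints, `start <= stop`.
#' @param steps number of equidistant values (>= 1).
#' @param integer round values to integers (ties up) and deduplicate.
#' @return A classed list `ParamSpec`.
#' @export
paramSpec <- function(name, start, stop, steps, integer = FALSE) {
  steps <- as.integer(steps)
  if (steps < 1L) stopUsage("steps must be >= 1")
  if (start > stop) stopUsage("start must not exceed stop")
  structure(list(name = name, start = start, stop = stop, steps = steps,
                 integer = integer), class = "ParamSpec")
}

#' Equidistant parameter grid
#'
#' `steps` equally spaced values including both endpoints; with
#' `integer = TRUE` values are rounded to the nearest integer (ties away
#' from zero) and deduplicated preserving order.
#'
#' @param spec a [paramSpec()].
#' @return Numeric vector of grid values.
#' @export
equidistantGrid <- function(spec) {
  stopifnot(inherits(spec, "ParamSpec"))
  v <- if (spec$steps == 1L) spec$start
       else seq(spec$start, spec$stop, length.out = spec$steps)
  if (spec$integer) v <- unique(roundHalfUp(v))
  v
}

trainBaseModel <- function(kind, param, X, y, seed = 1L) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(0, 1))
  fitted <- withSeed(seed, switch(kind,
    knn = list(X = X, y = as.integer(y), k = as.integer(param)),
    svm = suppressWarnings(
      e1071::svm(X, yf, kernel = "radial", cost = param, scale = TRUE)),
    lr = suppressWarnings(
      stats::glm.fit(cbind(1, X), as.integer(y),
                     family = stats::binomial())),
    rf = randomForest::randomForest(
      X, yf, ntree = 100L, mtry = max(1L, min(ncol(X), as.integer(param)))),
    nb = e1071::naiveBayes(X, yf, laplace = param),
    dt = rpart::rpart(label ~ ., cbind(as.data.frame(X), label = yf),
                      method = "class", cp = param),
    stopUsage("unknown base-model kind '%s'", kind)))
  predictFun <- switch(kind,
    knn = function(newX) knnVote(fitted$X, fitted$y, as.matrix(newX), fitted$k),
    svm = function(newX) as.integer(as.character(
      stats::predict(fitted, as.matrix(newX)))),
    lr = function(newX) {
      eta <- drop(cbind(1, as.matrix(newX)) %*% fitted$coefficients)
      as.integer(eta > 0)
    },
    rf = function(newX) as.integer(as.character(
      stats::predict(fitted, as.matrix(newX)))),
    nb = function(newX) as.integer(as.character(
      stats::predict(fitted, as.matrix(newX)))),
    dt = function(newX) as.integer(as.character(
      stats::predict(fitted, as.data.frame(as.matrix(newX)), type = "class"))))
  list(kind = kind, param = param, predict = predictFun)
}

#' Default base-model roster
#'
#' Six classifier kinds (KNN, RBF SVM, logistic regression, random forest,
#' naive Bayes, decision tree), each with an equidistant parameter grid; the
#' KNN grid is the canonical `"k, 2, 16, 4"` example.
#'
#' @return Named list of `list(kind, spec)` roster entries.
#' @export
defaultRoster <- function() {
  list(
    knn = list(kind = "knn", spec = paramSpec("k", 2, 16, 4, integer = TRUE)),
    svm = list(kind = "svm", spec = paramSpec("cost", 0.5, 8, 4)),
    lr  = list(kind = "lr",  spec = paramSpec("none", 1, 1, 1)),
    rf  = list(kind = "rf",  spec = paramSpec("mtry", 1, 10, 4, integer = TRUE)),
    nb  = list(kind = "nb",  spec = paramSpec("laplace", 0, 3, 4)),
    dt  = list(kind = "dt",  spec = paramSpec("cp", 0.001, 0.05, 4))
  )
}
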