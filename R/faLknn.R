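# Technique 5: maximum-likelihood factor analysis (EM) feeding the layered
# k-nearest-neighbour classifier with IQR outlier rejection.

#' Fit a maximum-likelihood factor model by EM
#'
#' Gaussian factor model `x = W z + n` with isotropic-free diagonal noise:
#' the observed covariance decomposes as `C_x = W W' + C_n`. EM on centered
#' data; converged when the log-likelihood change drops below `tol` or
#' after `maxIter` iterations. Zero-variance columns are dropped with a
#' warning before fitting.
#'
#' @param table a [FeatureTable-class] or numeric matrix (samples x features).
#' @param nFactors number of factors, `1 <= nFactors < Q`.
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param maxIter maximum EM iterations (default 500).
#' @return A [FactorModel-class].
#' @export
fitFactorModel <- function(table, nFactors, tol = 1e-4, maxIter = 500L) {
  X <- if (is(table, "FeatureTable")) featureValues(table) else as.matrix(table)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(X)[v == 0], collapse = ", ")))
    X <- X[, v > 0, drop = FALSE]
  }
  p <- ncol(X); n <- nrow(X)
  nFactors <- as.integer(nFactors)
  if (nFactors < 1L || nFactors >= p)
    stopUsage("nFactors must lie in 1..%d", p - 1L)
  if (n < p) warning("fewer samples than features; the fit may be unstable")
  ctr <- colMeans(X)
  S <- stats::cov(X)
  # spectral initialisation
  eig <- eigen(S, symmetric = TRUE)
  W <- eig$vectors[, seq_len(nFactors), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(nFactors)], 1e-8)), nFactors)
  psiFloor <- 1e-6 * mean(diag(S))   # keeps Sigma positive definite even
  psi <- pmax(diag(S) - rowSums(W^2), psiFloor)  # when S is rank-deficient
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    Sigma <- tcrossprod(W) + diag(psi, p)
    cholS <- chol(Sigma)
    beta <- backsolve(cholS, backsolve(cholS, W, transpose = TRUE))  # Sigma^-1 W
    beta <- t(beta)                                                  # k x p
    Ezz <- diag(nFactors) - beta %*% W + beta %*% S %*% t(beta)
    SWb <- S %*% t(beta)
    W <- SWb %*% solve(Ezz)
    psi <- pmax(diag(S - W %*% beta %*% S), psiFloor)
    SinvS <- backsolve(cholS, backsolve(cholS, S, transpose = TRUE))
    newLL <- -n / 2 * (p * log(2 * pi) +
                       2 * sum(log(diag(cholS))) + sum(diag(SinvS)))
    if (is.finite(ll) && abs(newLL - ll) < tol) { ll <- newLL; break }
    ll <- newLL
  }
  new("FactorModel", W = W, noise = psi, center = ctr,
      nFactors = nFactors, logLik = ll, featureNames = colnames(X))
}

#' Posterior-mean factor scores
#'
#' @param model a [FactorModel-class].
#' @param table a [FeatureTable-class] or matrix with the fitted columns.
#' @return A [FeatureTable-class] of scores named `fa.f<i>` (labels carried
#'   over when the input has them).
#' @export
faTransform <- function(model, table) {
  stopifnot(is(model, "FactorModel"))
  X <- if (is(table, "FeatureTable")) featureValues(table) else as.matrix(table)
  if (!all(model@featureNames %in% colnames(X)))
    stopUsage("input is missing fitted feature columns")
  X <- X[, model@featureNames, drop = FALSE]
  p <- length(model@featureNames)
  Sigma <- tcrossprod(model@W) + diag(model@noise, p)
  cholS <- chol(Sigma)
  beta <- t(backsolve(cholS, backsolve(cholS, model@W, transpose = TRUE)))
  sc <- t(beta %*% t(sweep(X, 2L, model@center, "-")))
  colnames(sc) <- sprintf("fa.f%d", seq_len(ncol(sc)))
  labels <- if (is(table, "FeatureTable")) classLabels(table)
            else integer(nrow(sc))
  FeatureTable(sc, labels)
}

## ---------------------------------------------------------------------------
## Layered KNN
## ---------------------------------------------------------------------------

# Tukey hinges: medians of the lower/upper halves (median included in both
# halves when n is odd).
tukeyHinges <- function(x) {
  x <- sort(x)
  n <- length(x)
  half <- if (n %% 2L == 0L) n / 2 else (n + 1L) / 2
  c(Q1 = stats::median(x[seq_len(half)]),
    Q2 = stats::median(x),
    Q3 = stats::median(x[(n - half + 1L):n]))
}

#' Train the layered KNN class map
#'
#' Per class: the center is the member mean; member-to-center Euclidean
#' distances are summarised by Tukey-hinge quartiles; members beyond the
#' upper fence `Q3 + 1.5 IQR` are rejected as outliers (`tightFence = TRUE`
#' switches to the stricter `Q1 + 1.5 IQR` fence variant).
#' The farthest retained distance per class feeds the global maximum
#' `Fmax`; concentric layers of width `Fmax / L` index each member, and
#' layer `i` carries weight `L - i + 1`, so inner members weigh more.
#'
#' @param table a [FeatureTable-class]; every class needs >= 4 members.
#' @param L number of layers (>= 1, default 4).
#' @param tightFence use `Q1 + 1.5 IQR` as the upper fence instead.
#' @return A [LayeredClassMap-class].
#' @export
lknnFit <- function(table, L = 4L, tightFence = FALSE) {
  stopifnot(is(table, "FeatureTable"))
  L <- as.integer(L)
  if (L < 1L) stopUsage("L must be >= 1")
  X <- featureValues(table); y <- classLabels(table)
  classes <- sort(unique(y))
  centers <- list(); quart <- list(); fences <- list()
  keepIdx <- integer(0); fFar <- numeric(0)
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    if (length(idx) < 4L)
      stopUsage("class %d has fewer than 4 members", classes[ci])
    ctr <- colMeans(X[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2L, ctr, "-")^2))
    qs <- tukeyHinges(d)
    iqr <- qs["Q3"] - qs["Q1"]
    vHigh <- if (tightFence) qs["Q1"] + 1.5 * iqr else qs["Q3"] + 1.5 * iqr
    vLow <- qs["Q1"] - 1.5 * iqr
    keep <- idx[d <= vHigh]   # min(d) <= Q1 <= vHigh, so never empty
    centers[[ci]] <- ctr
    quart[[ci]] <- unname(qs)
    fences[[ci]] <- unname(c(vLow, vHigh))
    keepIdx <- c(keepIdx, keep)
    fFar <- c(fFar, max(d[d <= vHigh]))
  }
  keepIdx <- sort(keepIdx)
  fMax <- max(fFar)
  width <- fMax / L
  layer <- integer(length(keepIdx))
  for (ci in seq_along(classes)) {
    sel <- which(y[keepIdx] == classes[ci])
    d <- sqrt(rowSums(sweep(X[keepIdx[sel], , drop = FALSE], 2L,
                            centers[[ci]], "-")^2))
    li <- as.integer(ceiling(d / width))
    layer[sel] <- pmin(pmax(li, 1L), L)
  }
  new("LayeredClassMap", classes = as.integer(classes), centers = centers,
      quartiles = quart, fences = fences,
      retained = X[keepIdx, , drop = FALSE],
      retainedLabels = y[keepIdx], retainedLayer = layer,
      layerWeights = as.numeric(L - seq_len(L) + 1L), fFar = fFar,
      fMax = fMax, L = L)
}

#' Classify with the layered KNN
#'
#' The k nearest retained members (distance ties at the boundary break
#' toward the lower member index) form the neighbour set; each contributes
#' its inverse distance times its layer weight to its class's affiliation
#' degree. Scores are the normalised affiliation degrees and the label the
#' argmax (ties toward class 0). A query coincident with a member takes
#' that member's class immediately.
#'
#' @param map a [LayeredClassMap-class].
#' @param queries feature matrix (columns as in training).
#' @param k neighbourhood size, `1 <= k <=` retained size.
#' @return List with `labels` (integer 0/1) and `decisions` (list per query:
#'   `scores` summing to 1, `neighbours`, `rates`).
#' @export
lknnPredict <- function(map, queries, k = 5L) {
  stopifnot(is(map, "LayeredClassMap"))
  queries <- as.matrix(queries)
  n <- nrow(map@retained)
  k <- as.integer(k)
  if (k < 1L || k > n) stopUsage("k must lie in 1..%d", n)
  w <- map@layerWeights[map@retainedLayer]
  d2 <- crossDist2(queries, map@retained)
  labels <- integer(nrow(queries))
  decisions <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    d <- sqrt(d2[i, ])
    ord <- order(d, seq_along(d))[seq_len(k)]
    if (d[ord[1L]] == 0) {
      labels[i] <- map@retainedLabels[ord[1L]]
      sc <- as.numeric(map@classes == labels[i])
      decisions[[i]] <- list(scores = stats::setNames(sc, map@classes),
                             neighbours = ord[1L], rates = Inf)
      next
    }
    ar <- 1 / d[ord]
    ad <- vapply(map@classes, function(cl)
      sum(ar[map@retainedLabels[ord] == cl] *
          w[ord][map@retainedLabels[ord] == cl]), numeric(1))
    sc <- ad / sum(ad)
    labels[i] <- map@classes[which.max(sc)]
    decisions[[i]] <- list(scores = stats::setNames(sc, map@classes),
                           neighbours = ord, rates = ar)
  }
  list(labels = labels, decisions = decisions)
}

#' Fit the factor-analysis + layered-KNN pipeline (Technique 5)
#'
#' [fitFactorModel()] then [lknnFit()] on the factor scores; prediction
#' composes [faTransform()] with [lknnPredict()].
#'
#' @param table a [FeatureTable-class].
#' @param nFactors number of factors (default 8, capped at Q - 1).
#' @param L layer count.
#' @param k prediction neighbourhood size.
#' @param tightFence see [lknnFit()].
#' @return A [FaLknnModel-class].
#' @export
fitFaLknn <- function(table, nFactors = 8L, L = 4L, k = 5L,
                      tightFence = FALSE) {
  stopifnot(is(table, "FeatureTable"))
  nFactors <- min(as.integer(nFactors), ncol(featureValues(table)) - 1L)
  fa <- fitFactorModel(table, nFactors)
  scores <- faTransform(fa, table)
  map <- lknnFit(scores, L = L, tightFence = tightFence)
  manifest <- list(method = "falknn", nFactors = nFactors, L = L, k = k,
                   retained = nrow(map@retained), fMax = map@fMax)
  new("FaLknnModel", fa = fa, map = map, k = as.integer(k),
      manifest = manifest)
}

#' Predict with a FaLknnModel
#'
#' @param object a [FaLknnModel-class].
#' @param newdata a [FeatureTable-class] or feature matrix.
#' @param ... unused.
#' @return Integer 0/1 labels.
#' @export
setMethod("predict", "FaLknnModel", function(object, newdata, ...) {
  sc <- faTransform(object@fa, newdata)
  lknnPredict(object@map, featureValues(sc), object@k)$labels
})

setMethod("show", "FaLknnModel", function(object) {
  cat(sprintf("FaLknnModel: %d factors -> LKNN (L = %d, k = %d, %d retained)\n",
              object@fa@nFactors, object@map@L, object@k,
              nrow(object@map@retained)))
})
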