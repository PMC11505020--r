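# Technique 2: finite-truncation infinite-ICA (linear-Gaussian model with a
# Bernoulli source mask under a Beta sparsity prior, Gibbs sampling) and the
# random-subspace ensemble with SVM-only and hybrid (MLP/EKNN/SVM) modes.

#' Fit a finite-truncation infinite-ICA model by Gibbs sampling
#'
#' Model: `Z = H (W * B) + E` with `Z` the (observed dim x samples) data,
#' `H` the mixing matrix, `W` Gaussian source weights, `B` a binary mask
#' with row-wise activation probabilities `pi_q ~ Beta(alpha/Q, 1)` (the
#' standard finite approximation of the unbounded-mask model), and isotropic
#' Gaussian noise `E`. Each sweep samples `B` entry-wise with the sample's
#' source weights integrated out of the likelihood (the column-collapsed
#' update, which lets redundant source entries switch off instead of being
#' entrenched by their conditioned weights), then `W` (conjugate Gaussian),
#' `pi_q` (conjugate Beta), `H` (row-wise conjugate Gaussian) and the noise
#' variance (conjugate inverse-gamma). The chain starts from the truncated
#' SVD of the centered data. The state after the final sweep is returned
#' together with the per-sweep mean squared reconstruction error.
#'
#' @param Z numeric matrix, observed dimensions x data points (finite).
#' @param qTrunc truncation level Q (>= 1; a warning is raised when it
#'   exceeds the observed dimension).
#' @param sweeps Gibbs sweeps (>= 1, default 200).
#' @param alpha sparsity concentration (default 2).
#' @param seed integer seed; fixed seed gives a byte-identical model.
#' @param fixMask optional binary Q x D matrix; when given the mask is held
#'   fixed (e.g. all ones for a plain linear-Gaussian fit).
#' @return An [IICAModel-class].
#' @export
fitIICA <- function(Z, qTrunc = 16L, sweeps = 200L, alpha = 2,
                    seed = 1L, fixMask = NULL) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stopUsage("Z must be finite")
  qTrunc <- as.integer(qTrunc); sweeps <- as.integer(sweeps)
  if (qTrunc < 1L || sweeps < 1L) stopUsage("qTrunc and sweeps must be >= 1")
  N <- nrow(Z); D <- ncol(Z)
  if (qTrunc > N) warning("qTrunc exceeds the observed dimension")
  ctr <- rowMeans(Z)
  Zc <- Z - ctr
  sw2 <- 1  # prior variance of W entries
  sh2 <- 1  # prior variance of H entries
  withSeed(seed, {
    # informed initialisation from the truncated SVD of the centered data:
    # sources start at the principal directions (the standard start for
    # latent linear-Gaussian samplers); rows carried by noise-level singular
    # values lose their mask entries within the first sweeps
    sv <- svd(Zc)
    r <- min(qTrunc, length(sv$d))
    H <- matrix(stats::rnorm(N * qTrunc, sd = 0.1 * sqrt(sh2)), N, qTrunc)
    W <- matrix(stats::rnorm(qTrunc * D, sd = 0.1 * sqrt(sw2)), qTrunc, D)
    H[, seq_len(r)] <- sv$u[, seq_len(r), drop = FALSE] %*%
      diag(sv$d[seq_len(r)] / sqrt(D), r)
    W[seq_len(r), ] <- sqrt(D) * t(sv$v[, seq_len(r), drop = FALSE])
    piQ <- rep(0.5, qTrunc)
    # mask starts empty: entries are born only where the collapsed Bayes
    # factor demands them, so the error trace falls from the zero-model level
    B <- if (is.null(fixMask)) matrix(0, qTrunc, D)
    else {
      if (!all(dim(fixMask) == c(qTrunc, D))) stopUsage("fixMask shape mismatch")
      fixMask
    }
    se2 <- stats::var(as.vector(Zc))
    if (!is.finite(se2) || se2 <= 0) se2 <- 1
    res <- .iicaGibbs(Zc, H, W, B, piQ, se2, sweeps, alpha, sw2, sh2,
                      is.null(fixMask))
    new("IICAModel", H = res$H, W = res$W, B = res$B,
        piQ = as.numeric(res$piQ), sigmaE2 = res$se2,
        errorTrace = as.numeric(res$trace), center = ctr,
        seed = as.integer(seed))
  })
}

#' Latent features from a fitted infinite-ICA model
#'
#' The per-sample features are the active rows of `W * B` (sources with at
#' least one active entry), transposed to samples x active-sources and
#' named `iica.s<q>`. With no active source the top-variance raw features
#' are returned instead, with a warning.
#'
#' @param model an [IICAModel-class].
#' @param Z the data the model was fitted on (observed dim x samples).
#' @param labels optional 0/1 labels for the returned table.
#' @return A [FeatureTable-class].
#' @export
iicaFeatures <- function(model, Z, labels = NULL) {
  stopifnot(is(model, "IICAModel"))
  Z <- as.matrix(Z)
  D <- ncol(Z)
  if (is.null(labels)) labels <- integer(D)
  act <- which(rowSums(model@B) > 0)
  if (!length(act)) {
    warning("no active sources; falling back to top-variance raw features")
    v <- apply(Z, 1L, stats::var)
    keep <- order(-v)[seq_len(min(5L, nrow(Z)))]
    m <- t(Z[keep, , drop = FALSE])
    colnames(m) <- sprintf("raw.v%d", seq_along(keep))
    return(FeatureTable(m, labels))
  }
  m <- t((model@W * model@B)[act, , drop = FALSE])
  colnames(m) <- sprintf("iica.s%d", act)
  FeatureTable(m, labels)
}

# Least-squares source activations for new samples (columns of Znew), using
# the active columns of H.
iicaTransform <- function(model, Znew) {
  Znew <- as.matrix(Znew) - model@center
  act <- which(rowSums(model@B) > 0)
  if (!length(act)) stopUsage("no active sources to project onto")
  Ha <- model@H[, act, drop = FALSE]
  m <- t(qr.solve(Ha, Znew))
  colnames(m) <- sprintf("iica.s%d", act)
  m
}

#' Plan disjoint random feature subspaces
#'
#' Uniformly random partition of `1..Q` into `S` near-equal blocks (sizes
#' differ by at most one).
#'
#' @param Q number of features.
#' @param S number of subspaces, `1 <= S <= Q`.
#' @param seed integer seed.
#' @return List of `S` disjoint, exhaustive index vectors.
#' @export
planSubspaces <- function(Q, S, seed = 1L) {
  if (S < 1L || S > Q) stopUsage("S must lie in 1..Q")
  withSeed(seed, {
    perm <- sample.int(Q)
    g <- rep_len(seq_len(S), Q)
    lapply(seq_len(S), function(j) sort(perm[g == j]))
  })
}

# -- extended nearest neighbour (class-coherence rule) -----------------------

#' Extended-nearest-neighbour prediction
#'
#' For each query the class assignment that maximises the generalised
#' class-wise coherence statistic is chosen: with the query tentatively
#' added to a class, the statistic sums, over classes, the average fraction
#' of that class's members (query included) whose k-neighbourhood stays
#' within their own class. Ties break toward class 0.
#'
#' @param train a [FeatureTable-class] of labelled training samples.
#' @param query feature matrix of query points (same columns).
#' @param k neighbourhood size, `1 <= k <= n_train`.
#' @return Integer 0/1 labels for the queries.
#' @export
eknnPredict <- function(train, query, k = 5L) {
  stopifnot(is(train, "FeatureTable"))
  X <- featureValues(train); y <- classLabels(train)
  query <- as.matrix(query)
  n <- nrow(X); k <- as.integer(k)
  if (k < 1L || k > n) stopUsage("k must lie in 1..n_train")
  if (length(unique(y)) < 2L) stopUsage("training data holds a single class")
  d2tt <- crossDist2(X, X)
  diag(d2tt) <- Inf
  # k nearest train neighbours of each train point, plus the k-th distance
  ord <- apply(d2tt, 1L, function(d) order(d, seq_along(d))[seq_len(k)])
  ord <- matrix(ord, nrow = k)
  kth <- vapply(seq_len(n), function(i) d2tt[i, ord[k, i]], numeric(1))
  ownFrac <- vapply(seq_len(n), function(i)
    sum(y[ord[, i]] == y[i]) / k, numeric(1))
  d2qt <- crossDist2(query, X)
  out <- integer(nrow(query))
  for (qi in seq_len(nrow(query))) {
    dq <- d2qt[qi, ]
    qOrd <- order(dq, seq_along(dq))[seq_len(k)]
    stats <- numeric(2)
    for (cls in c(0L, 1L)) {
      # query joins class cls; train point i gains the query as a neighbour
      # iff dq[i] < its current k-th neighbour distance
      displaced <- dq < kth
      frac <- ownFrac
      gain <- (y == cls) - (y[ord[k, ]] == y)
      frac[displaced] <- frac[displaced] + gain[displaced] / k
      qFrac <- sum(y[qOrd] == cls) / k
      tot <- 0
      for (cc in c(0L, 1L)) {
        members <- frac[y == cc]
        nm <- length(members) + (cc == cls)
        tot <- tot + (sum(members) + if (cc == cls) qFrac else 0) / nm
      }
      stats[cls + 1L] <- tot
    }
    out[qi] <- if (stats[2L] > stats[1L]) 1L else 0L
  }
  out
}

# -- random-subspace ensemble ------------------------------------------------

subspaceMember <- function(kind, X, y, cols, config, seed) {
  Xs <- X[, cols, drop = FALSE]
  yf <- factor(y, levels = c(0, 1))
  if (kind == "svm") {
    grid <- config$svmCost %||% c(0.5, 1, 2, 4)
    accs <- vapply(grid, function(cost) withSeed(seed, {
      g <- stratifiedGroups(y, min(3L, min(table(y))))
      mean(unlist(lapply(unique(g), function(j) {
        fit <- suppressWarnings(e1071::svm(Xs[g != j, , drop = FALSE],
                                           yf[g != j], kernel = "radial",
                                           cost = cost, scale = TRUE))
        as.integer(as.character(stats::predict(
          fit, Xs[g == j, , drop = FALSE]))) == y[g == j]
      })))
    }), numeric(1))
    cost <- grid[which.max(accs)]
    fit <- withSeed(seed, suppressWarnings(
      e1071::svm(Xs, yf, kernel = "radial", cost = cost, scale = TRUE)))
    pred <- function(newX) as.integer(as.character(
      stats::predict(fit, newX[, cols, drop = FALSE])))
  } else if (kind == "mlp") {
    fit <- withSeed(seed, nnet::nnet(
      Xs, as.numeric(y), size = config$mlpSize %||% 32L,
      maxit = config$mlpMaxit %||% 500L, decay = 1e-3, trace = FALSE))
    pred <- function(newX) as.integer(
      drop(stats::predict(fit, newX[, cols, drop = FALSE])) > 0.5)
  } else if (kind == "eknn") {
    tab <- FeatureTable(`colnames<-`(Xs, colnames(X)[cols]), y)
    kk <- min(config$eknnK %||% 5L, nrow(Xs) - 1L)
    pred <- function(newX) eknnPredict(tab, newX[, cols, drop = FALSE], kk)
  } else stopUsage("unknown member kind '%s'", kind)
  list(kind = kind, cols = cols, predict = pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a random-subspace ensemble (Technique 2)
#'
#' Trains one RBF-SVM per subspace (`mode = "svm"`, with the cost chosen by
#' internal cross-validation) or a trio of one-hidden-layer MLP, extended
#' KNN and RBF-SVM per subspace (`mode = "hybrid"`); all members vote by
#' majority. Subspaces whose features are all zero-variance are skipped
#' with a warning.
#'
#' @param table a [FeatureTable-class].
#' @param plan subspace plan from [planSubspaces()] matching the table width.
#' @param mode `"svm"` or `"hybrid"`.
#' @param config optional list: `svmCost` grid, `mlpSize`, `mlpMaxit`,
#'   `eknnK`.
#' @param seed integer seed.
#' @return A [SubspaceEnsemble-class].
#' @export
fitSubspaceEnsemble <- function(table, plan, mode = c("svm", "hybrid"),
                                config = list(), seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  mode <- match.arg(mode)
  X <- featureValues(table); y <- classLabels(table)
  if (!setequal(unlist(plan), seq_len(ncol(X))))
    stopUsage("plan does not partition the table's features")
  kinds <- if (mode == "svm") "svm" else c("mlp", "eknn", "svm")
  members <- list()
  for (si in seq_along(plan)) {
    cols <- plan[[si]]
    if (all(apply(X[, cols, drop = FALSE], 2L, stats::var) == 0)) {
      warning(sprintf("subspace %d has zero variance; members skipped", si))
      next
    }
    for (kind in kinds)
      members[[length(members) + 1L]] <-
        subspaceMember(kind, X, y, cols, config, seed + si)
  }
  if (!length(members)) stopUsage("no usable subspace members")
  manifest <- list(method = "ica-subspace", mode = mode, seed = seed,
                   subspaces = plan,
                   members = lapply(members, function(m)
                     list(kind = m$kind, cols = m$cols)))
  new("SubspaceEnsemble", members = members, plan = plan, mode = mode,
      featureNames = featureNames(table), manifest = manifest)
}

#' Predict with a fitted SubspaceEnsemble
#'
#' @param object a [SubspaceEnsemble-class].
#' @param newdata a [FeatureTable-class] or feature matrix.
#' @param ... unused.
#' @return Integer 0/1 labels (majority vote over all members).
#' @export
setMethod("predict", "SubspaceEnsemble", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureTable")) featureValues(newdata) else newdata
  votes <- do.call(rbind, lapply(object@members, function(m)
    as.integer(m$predict(X))))
  majorityVote(votes)
})

setMethod("show", "SubspaceEnsemble", function(object) {
  cat(sprintf("SubspaceEnsemble (%s): %d members over %d subspaces\n",
              object@mode, length(object@members), length(object@plan)))
})
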