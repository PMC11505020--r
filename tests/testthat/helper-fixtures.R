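# Shared fixtures, generated in code.

# Small separable two-class Gaussian feature table (fast stand-in for EEG
# features in ensemble unit tests).
makeBlobTable <- function(n = 60L, q = 6L, sep = 4, seed = 1L,
                          spread = FALSE) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), each = n / 2)
  m <- matrix(rnorm(n * q), n, q)
  shifted <- if (spread) seq_len(q) else seq_len(min(2L, q))
  m[lab == 1L, shifted] <- m[lab == 1L, shifted] + sep
  colnames(m) <- sprintf("f%02d", seq_len(q))
  FeatureTable(m, lab)
}

# Noise-only table (no class signal) for null checks.
makeNullTable <- function(n = 60L, q = 6L, seed = 2L) {
  set.seed(seed)
  m <- matrix(rnorm(n * q), n, q)
  colnames(m) <- sprintf("f%02d", seq_len(q))
  FeatureTable(m, rep(c(0L, 1L), each = n / 2))
}

# Tiny synthetic EEG set shared across data/feature tests.
smallEEG <- function(nEpochs = 20L, nChannels = 2L, seed = 5L,
                     burstAmplitude = 6, bandPowerRatio = 4) {
  generateSynthetic(synthSpec(
    nEpochs = nEpochs, nChannels = nChannels, fs = 128, epochSeconds = 2,
    burstAmplitude = burstAmplitude, bandPowerRatio = bandPowerRatio,
    seed = seed))
}

# Independent brute-force layered-KNN oracle: direct transliteration of the
# association-rate / affiliation-degree / normalised-score equations,
# written with plain loops so it shares no code with lknnPredict.
bruteLKNN <- function(map, queries, k) {
  X <- map@retained
  y <- map@retainedLabels
  w <- map@layerWeights[map@retainedLayer]
  out <- list(labels = integer(nrow(queries)), scores = list())
  for (i in seq_len(nrow(queries))) {
    d <- numeric(nrow(X))
    for (j in seq_len(nrow(X))) d[j] <- sqrt(sum((queries[i, ] - X[j, ])^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    if (min(d) == 0) {
      out$labels[i] <- y[which(d == 0)[1L]]
      out$scores[[i]] <- as.numeric(map@classes == out$labels[i])
      next
    }
    ad <- numeric(length(map@classes))
    for (ci in seq_along(map@classes)) {
      for (j in ord) {
        if (y[j] == map@classes[ci]) ad[ci] <- ad[ci] + (1 / d[j]) * w[j]
      }
    }
    sc <- ad / sum(ad)
    out$labels[i] <- map@classes[which.max(sc)]
    out$scores[[i]] <- sc
  }
  out
}
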