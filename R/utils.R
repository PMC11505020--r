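# Internal numerical helpers shared across modules.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library randomness never leaks between
# operations. `seed = NULL` runs in the ambient stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Round half away from zero (ties up for positive values).
roundHalfUp <- function(x) floor(x + 0.5)

# Column z-score; zero-variance columns map to 0 rather than NaN.
zscoreColumns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

# Welch power spectral density (Hann window, 50% overlap, one-sided density).
# Integrating the density over (0, fs/2] recovers the signal power.
welchPsd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  acc <- numeric(floor(nperseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything but DC (and Nyquist when nperseg even)
  if (length(psd) > 2L) {
    last <- length(psd)
    dbl <- 2:(if (nperseg %% 2 == 0) last - 1L else last)
    psd[dbl] <- 2 * psd[dbl]
  }
  freq <- (seq_along(psd) - 1L) * fs / nperseg
  list(freq = freq, psd = psd, df = fs / nperseg)
}

# Deterministic k-nearest-neighbour vote: ties at the k-boundary break toward
# the lower training index, vote ties toward class 1 (majority-vote "≥" rule).
knnVote <- function(trainX, trainY, queryX, k) {
  trainX <- as.matrix(trainX); queryX <- as.matrix(queryX)
  k <- min(k, nrow(trainX))
  out <- integer(nrow(queryX))
  tn2 <- rowSums(trainX^2)
  for (i in seq_len(nrow(queryX))) {
    d2 <- tn2 - 2 * drop(trainX %*% queryX[i, ]) + sum(queryX[i, ]^2)
    ord <- order(d2, seq_along(d2))[seq_len(k)]
    out[i] <- as.integer(sum(trainY[ord] == 1L) >= k / 2)
  }
  out
}

# Pairwise squared Euclidean distances between rows of a and b.
crossDist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Stratified assignment of n labelled items into k groups, balanced within
# class; returns an integer group id per item.
stratifiedGroups <- function(labels, k) {
  g <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    g[idx] <- rep_len(seq_len(k), length(idx))
  }
  g
}

# Canonical JSON manifest serialisation used by the determinism contract.
manifestJSON <- function(manifest) {
  jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null")
}

stopUsage <- function(...) stop(sprintf(...), call. = FALSE)
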