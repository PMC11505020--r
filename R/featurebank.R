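#' Frequency-band scheme
#'
#' Named, non-overlapping frequency intervals (Hz) used by band-power and
#' marginal-spectrum features. The defaults are the conventional EEG bands.
#'
#' @param ... named two-element numeric vectors `c(lo, hi)`; omit for the
#'   defaults delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45.
#' @return A named list of intervals, classed `"BandScheme"`.
#' @export
bandScheme <- function(...) {
  bands <- list(...)
  if (!length(bands))
    bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 45))
  if (is.null(names(bands)) || any(names(bands) == ""))
    stopUsage("bands must be named")
  m <- do.call(rbind, bands)
  if (any(m[, 1L] >= m[, 2L]) || any(m[, 1L] < 0))
    stopUsage("each band must satisfy 0 <= lo < hi")
  ord <- order(m[, 1L])
  if (any(m[ord[-1L], 1L] < m[ord[-length(ord)], 2L] - 1e-12))
    stopUsage("bands must not overlap")
  structure(bands, class = "BandScheme")
}

## -- scalar signal features -------------------------------------------------

skewnessV <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

kurtosisV <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

# Zero crossings: strict sign flips between neighbouring samples plus runs of
# exact zeros (each run is one crossing event); an identically zero signal
# has none.
zeroCrossings <- function(x) {
  if (all(x == 0)) return(0L)
  flips <- sum(x[-length(x)] * x[-1L] < 0)
  z <- x == 0
  runs <- sum(z & !c(FALSE, z[-length(z)]))
  as.integer(flips + runs)
}

lineLength <- function(x) sum(abs(diff(x)))

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of
#' the first difference divided by the mobility of the signal. First
#' differences stand in for the derivative. A constant signal returns
#' `c(0, 0)`.
#'
#' @param x numeric vector of length >= 3.
#' @return Named numeric vector `c(mobility =, complexity =)`.
#' @export
hjorthParams <- function(x) {
  if (length(x) < 3L) stopUsage("hjorthParams needs length >= 3")
  v0 <- stats::var(x)
  if (v0 == 0) return(c(mobility = 0, complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) return(c(mobility = mob, complexity = 0))
  c(mobility = mob, complexity = sqrt(stats::var(d2) / v1) / mob)
}

# Shannon entropy of the normalised Welch spectrum, scaled to [0, 1].
spectralEntropy <- function(psd) {
  p <- psd[psd > 0]
  if (length(p) < 2L) return(0)
  p <- p / sum(p)
  -sum(p * log(p)) / log(length(p))
}

# Higuchi fractal dimension, k_max = 10.
higuchiFD <- function(x, kmax = 10L) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  kmax <- min(kmax, floor((n - 1) / 2))
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx) - 1L
      if (nm < 1L) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  ok <- is.finite(log(lk))
  if (sum(ok) < 2L) return(0)
  -stats::coef(stats::lm(log(lk[ok]) ~ log(seq_len(kmax)[ok])))[[2L]]
}

# Rescaled-range Hurst exponent.
hurstRS <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  sizes <- unique(round(exp(seq(log(8), log(n / 2), length.out = 8))))
  sizes <- sizes[sizes >= 8 & sizes <= n / 2]
  if (length(sizes) < 2L) return(0.5)
  rs <- vapply(sizes, function(s) {
    nb <- floor(n / s)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * s + 1L):(b * s)]
      dev <- cumsum(seg - mean(seg))
      sdv <- stats::sd(seg)
      if (sdv == 0) return(NA_real_)
      (max(dev) - min(dev)) / sdv
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(log(rs)) & rs > 0
  if (sum(ok) < 2L) return(0.5)
  stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[[2L]]
}

# Detrended fluctuation analysis scaling exponent (order 1, log-spaced
# windows 4 .. n/4).
dfaExponent <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  prof <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n / 4), length.out = 10))))
  sizes <- sizes[sizes >= 4]
  if (length(sizes) < 2L) return(0.5)
  fl <- vapply(sizes, function(s) {
    nb <- floor(n / s)
    tt <- seq_len(s)
    ms <- vapply(seq_len(nb), function(b) {
      seg <- prof[((b - 1L) * s + 1L):(b * s)]
      res <- stats::lm.fit(cbind(1, tt), seg)$residuals
      mean(res^2)
    }, numeric(1))
    sqrt(mean(ms))
  }, numeric(1))
  ok <- is.finite(log(fl)) & fl > 0
  if (sum(ok) < 2L) return(0.5)
  stats::coef(stats::lm(log(fl[ok]) ~ log(sizes[ok])))[[2L]]
}

# db4 (D8) analysis filter bank with periodic extension; returns detail-band
# energies d1..dL plus the final approximation energy.
db4Lo <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
           -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

dwtEnergies <- function(x, levels = 4L) {
  h <- db4Lo
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  energies <- numeric(levels)
  a <- x
  for (lev in seq_len(levels)) {
    n <- length(a)
    if (n < length(h)) { energies[lev] <- 0; next }
    idx <- outer(seq(2L, n, by = 2L), seq_along(h) - 1L, "-")
    idx <- ((idx - 1L) %% n) + 1L
    av <- matrix(a[idx], nrow = nrow(idx))
    d <- drop(av %*% g)
    a <- drop(av %*% h)
    energies[lev] <- sum(d^2)
  }
  c(energies, sum(a^2))
}

## -- the extraction battery -------------------------------------------------

channelFeatures <- function(x, fs, bands) {
  ps <- welchPsd(x, fs)
  bp <- vapply(bands, function(b)
    sum(ps$psd[ps$freq >= b[1L] & ps$freq <= b[2L]]) * ps$df, numeric(1))
  names(bp) <- paste0("bp_", names(bands))
  hj <- hjorthParams(x)
  dwt <- dwtEnergies(x)
  names(dwt) <- c(paste0("dwt_d", seq_len(length(dwt) - 1L)), "dwt_a")
  amp <- abs(stats::fft(x)) / length(x) * 2
  dom <- which.max(amp[2:(floor(length(x) / 2) + 1L)]) + 1L
  c(mean = mean(x), variance = stats::var(x), skewness = skewnessV(x),
    kurtosis = kurtosisV(x), energy = sum(x^2), peak_amplitude = max(abs(x)),
    abs_sum = sum(abs(x)), zero_cross = zeroCrossings(x),
    line_length = lineLength(x), hj, spectral_entropy = spectralEntropy(ps$psd),
    bp, avg_spectral_power = sum(ps$psd * ps$df) / (fs / 2),
    dwt, fft_dom_mag = amp[dom], higuchi_fd = higuchiFD(x),
    hurst = hurstRS(x), dfa = dfaExponent(x))
}

#' Extract the EEG feature battery from an EpochSet
#'
#' Per channel and epoch: moments (mean, variance, skewness, kurtosis),
#' energy, peak amplitude, absolute sum, zero crossings, line length, Hjorth
#' mobility and complexity, Shannon spectral entropy, Welch band powers and
#' average spectral power, db4 wavelet sub-band energies (4 levels), dominant
#' FFT magnitude, Higuchi fractal dimension, R/S Hurst exponent, DFA scaling
#' exponent, and the mean absolute inter-channel correlation. Non-finite
#' values are imputed via [imputeFailures()].
#'
#' @param data an [EpochSet-class].
#' @param bands a [bandScheme()] (checked against the Nyquist frequency).
#' @param selection `"all"` or a character vector of base feature names
#'   (e.g. `"variance"`, `"bp_alpha"`) to keep.
#' @return A [FeatureTable-class]; rows align with epochs.
#' @export
extractFeatures <- function(data, bands = bandScheme(), selection = "all") {
  stopifnot(is(data, "EpochSet"))
  if (nEpochs(data) < 1L) stopUsage("empty EpochSet")
  fs <- samplingRate(data)
  if (any(vapply(bands, function(b) b[2L], numeric(1)) > fs / 2 + 1e-9))
    stopUsage("band above the Nyquist frequency %g Hz", fs / 2)
  ne <- nEpochs(data); nc <- nChannels(data)
  base <- names(channelFeatures(data@signals[1L, 1L, ], fs, bands))
  base <- c(base, "mean_corr")
  if (!identical(selection, "all")) {
    unknown <- setdiff(selection, base)
    if (length(unknown))
      stopUsage("unknown feature name(s): %s", paste(unknown, collapse = ", "))
    base <- intersect(base, selection)
  }
  cols <- as.vector(t(outer(data@channelNames, base, paste, sep = ".")))
  vals <- matrix(NA_real_, nrow = ne, ncol = length(cols),
                 dimnames = list(epochIds(data), cols))
  for (e in seq_len(ne)) {
    ep <- data@signals[e, , , drop = TRUE]
    if (nc == 1L) ep <- matrix(ep, nrow = 1L)
    if ("mean_corr" %in% base && nc > 1L) {
      cc <- abs(stats::cor(t(ep)))
      cc[!is.finite(cc)] <- 0
      mc <- (rowSums(cc) - 1) / (nc - 1L)
    } else mc <- rep(0, nc)
    for (ch in seq_len(nc)) {
      f <- c(channelFeatures(ep[ch, ], fs, bands), mean_corr = mc[ch])
      vals[e, ] <- `[<-`(vals[e, ], paste0(data@channelNames[ch], ".", base),
                         f[base])
    }
  }
  prov <- stats::setNames(
    rep(list(list(extractor = "featurebank", fs = fs)), length(cols)), cols)
  imputeFailures(FeatureTable(vals, classLabels(data), prov))
}

#' Impute non-finite feature values
#'
#' Replaces NaN/Inf entries by the column median of the finite entries;
#' a column with no finite entry is dropped with a warning.
#'
#' @param table a [FeatureTable-class].
#' @return A [FeatureTable-class] with only finite values.
#' @export
imputeFailures <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  v <- table@values
  bad <- !is.finite(v)
  if (!any(bad)) return(table)
  drop <- logical(ncol(v))
  for (j in which(colSums(bad) > 0)) {
    fin <- v[is.finite(v[, j]), j]
    if (!length(fin)) { drop[j] <- TRUE; next }
    v[!is.finite(v[, j]), j] <- stats::median(fin)
  }
  if (any(drop)) {
    warning(sprintf("dropping all-non-finite feature column(s): %s",
                    paste(colnames(v)[drop], collapse = ", ")))
    v <- v[, !drop, drop = FALSE]
  }
  FeatureTable(v, table@labels, table@provenance[colnames(v)])
}

#' Write a FeatureTable as a delimited text file
#'
#' Header row holds the feature names; the final column is the 0/1 label.
#'
#' @param table a [FeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  df <- as.data.frame(table@values)
  df$label <- table@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureTable written by [writeFeatureTable()]
#'
#' @param path CSV path with a final `label` column.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stopUsage("no label column in %s", path)
  lab <- as.integer(df$label)
  m <- as.matrix(df[setdiff(names(df), "label")])
  FeatureTable(m, lab)
}
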