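#' IMFSet: empirical-mode-decomposition output
#'
#' @slot imfs list of intrinsic mode functions (each the input length).
#' @slot residual the monotone/low-extrema remainder.
#' @slot siftCounts number of sifting iterations per IMF.
#' @export
setClass("IMFSet",
  representation(imfs = "list", residual = "numeric", siftCounts = "integer")
)

setMethod("show", "IMFSet", function(object) {
  cat(sprintf("IMFSet: %d IMFs over %d samples (sift counts: %s)\n",
              length(object@imfs), length(object@residual),
              paste(object@siftCounts, collapse = ", ")))
})

#' @describeIn IMFSet list of IMFs
#' @param x an `IMFSet`
#' @export
imfs <- function(x) x@imfs

#' @describeIn IMFSet residual accessor
#' @export
imfResidual <- function(x) x@residual

#' Analytic signal via the FFT method
#'
#' Returns `x + i * HT(x)`: the FFT coefficients at negative frequencies are
#' zeroed, the positive ones doubled (DC and Nyquist kept), and the inverse
#' FFT taken. The real part equals the input to numerical precision.
#'
#' @param x real vector, length >= 4.
#' @return Complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) stopUsage("empty input")
  if (n < 4L) stopUsage("analyticSignal needs length >= 4")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous frequency of an analytic signal
#'
#' Phase-difference estimate `diff(unwrap(arg z)) * fs / (2 pi)`, padded to
#' the input length by repeating the last value.
#'
#' @param z complex analytic signal.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of instantaneous frequencies (Hz).
#' @export
instantaneousFrequency <- function(z, fs) {
  ph <- Arg(z)
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  f <- d * fs / (2 * pi)
  c(f, f[length(f)])
}

localExtrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # collapse plateaus so flat tops count once
  nz <- which(s != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2L) {
    for (j in seq_len(length(nz) - 1L)) {
      a <- nz[j]; b <- nz[j + 1L]
      if (s[a] > 0 && s[b] < 0) maxima <- c(maxima, b)
      if (s[a] < 0 && s[b] > 0) minima <- c(minima, b)
    }
  }
  list(maxima = maxima, minima = minima)
}

envSpline <- function(idx, x, n) {
  # mirror the outermost extrema across the boundaries so the envelope does
  # not collapse toward the signal endpoints
  xi <- c(2L - idx[1L], idx, 2L * n - idx[length(idx)])
  yi <- x[c(idx[1L], idx, idx[length(idx)])]
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "natural")$y
}

#' Empirical mode decomposition by sifting
#'
#' Standard EMD: cubic-spline envelopes through local maxima and minima,
#' repeated subtraction of the envelope mean. Sifting of a candidate stops
#' when the Cauchy criterion `sum((h_prev - h)^2) / sum(h_prev^2)` falls
#' below `sdTol` and the IMF extrema/zero-crossing counts differ by at most
#' one, or after 50 sifts. Decomposition stops at `maxImfs` or when the
#' residual has fewer than two interior extrema.
#'
#' @param x real vector of length >= 16.
#' @param maxImfs maximum number of IMFs to extract.
#' @param sdTol Cauchy stopping tolerance (default 0.2).
#' @return An [IMFSet-class]; `sum(imfs) + residual` reconstructs `x`.
#' @export
emd <- function(x, maxImfs = 10L, sdTol = 0.2) {
  if (length(x) < 16L) stopUsage("emd needs length >= 16")
  if (sdTol <= 0) stopUsage("sdTol must be positive")
  n <- length(x)
  res <- x
  out <- list(); sifts <- integer(0)
  for (m in seq_len(maxImfs)) {
    ext <- localExtrema(res)
    if (length(ext$maxima) + length(ext$minima) < 2L) break
    h <- res
    count <- 0L
    repeat {
      count <- count + 1L
      e <- localExtrema(h)
      if (length(e$maxima) < 1L || length(e$minima) < 1L) break
      up <- envSpline(e$maxima, h, n)
      lo <- envSpline(e$minima, h, n)
      mean_env <- (up + lo) / 2
      h1 <- h - mean_env
      sd <- sum((h - h1)^2) / max(sum(h^2), .Machine$double.eps)
      e1 <- localExtrema(h1)
      nEx <- length(e1$maxima) + length(e1$minima)
      nZc <- zeroCrossings(h1)
      h <- h1
      if ((sd < sdTol && abs(nEx - nZc) <= 1L) || count >= 50L) break
    }
    out[[m]] <- h
    sifts <- c(sifts, count)
    res <- res - h
  }
  new("IMFSet", imfs = out, residual = res, siftCounts = sifts)
}

#' Hilbert spectrum of an IMF set
#'
#' Squared instantaneous amplitude of each IMF accumulated on a
#' time x frequency grid (64 log-spaced frequency bins from 0.5 Hz to
#' Nyquist, one time bin per sample), plus the marginal spectrum.
#'
#' @param imfset an [IMFSet-class].
#' @param fs sampling rate in Hz.
#' @param nFreq number of log-spaced frequency bins.
#' @return List with `freq` (bin lower edges), `time`, `energy`
#'   (nFreq x nTime, non-negative) and `marginal` (= row sums).
#' @export
hilbertSpectrum <- function(imfset, fs, nFreq = 64L) {
  n <- length(imfset@residual)
  edges <- exp(seq(log(0.5), log(fs / 2), length.out = nFreq + 1L))
  energy <- matrix(0, nrow = nFreq, ncol = n)
  for (im in imfset@imfs) {
    z <- analyticSignal(im)
    a2 <- Mod(z)^2
    f <- instantaneousFrequency(z, fs)
    bin <- findInterval(f, edges, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= nFreq
    if (any(ok))
      energy[cbind(bin[ok], seq_len(n)[ok])] <-
        energy[cbind(bin[ok], seq_len(n)[ok])] + a2[ok]
  }
  list(freq = edges[-length(edges)], time = (seq_len(n) - 1L) / fs,
       energy = energy, marginal = rowSums(energy))
}

# HHT descriptors of one signal: per-IMF energy fraction, mean/SD
# instantaneous frequency, mean instantaneous amplitude; residual energy
# fraction; marginal band energies.
hhtChannelFeatures <- function(x, fs, maxImfs, bands) {
  dec <- emd(x, maxImfs = maxImfs)
  k <- length(dec@imfs)
  eImf <- vapply(dec@imfs, function(v) sum(v^2), numeric(1))
  eTot <- sum(eImf) + sum(dec@residual^2)
  out <- numeric(0)
  for (i in seq_len(maxImfs)) {
    if (i <= k && eTot > 0) {
      z <- analyticSignal(dec@imfs[[i]])
      f <- instantaneousFrequency(z, fs)
      inner <- seq(max(1L, round(0.05 * length(f))),
                   min(length(f), round(0.95 * length(f))))
      v <- c(eImf[i] / eTot, mean(f[inner]), stats::sd(f[inner]),
             mean(Mod(z)))
    } else v <- c(0, 0, 0, 0)
    names(v) <- paste0("imf", i, c("_ef", "_if_mean", "_if_sd", "_ia_mean"))
    out <- c(out, v)
  }
  out <- c(out, resid_ef = if (eTot > 0) sum(dec@residual^2) / eTot else 0)
  hs <- hilbertSpectrum(dec, fs)
  mb <- vapply(bands, function(b)
    sum(hs$marginal[hs$freq >= b[1L] & hs$freq < b[2L]]), numeric(1))
  names(mb) <- paste0("marg_", names(bands))
  c(out, mb)
}

#' Hilbert-Huang feature extraction
#'
#' Per channel and epoch: for each of the first `maxImfs` IMFs the energy
#' fraction, mean and SD of instantaneous frequency and mean instantaneous
#' amplitude (missing IMFs zero-filled so the width is constant), the
#' residual energy fraction, and marginal-spectrum band energies.
#'
#' @param data an [EpochSet-class].
#' @param maxImfs number of IMFs described (default 5).
#' @param bands a [bandScheme()].
#' @return A [FeatureTable-class].
#' @export
hhtFeatures <- function(data, maxImfs = 5L, bands = bandScheme()) {
  stopifnot(is(data, "EpochSet"))
  fs <- samplingRate(data)
  ne <- nEpochs(data); nc <- nChannels(data)
  base <- names(hhtChannelFeatures(data@signals[1L, 1L, ], fs, maxImfs, bands))
  cols <- as.vector(t(outer(data@channelNames, base, paste, sep = ".")))
  vals <- matrix(0, nrow = ne, ncol = length(cols),
                 dimnames = list(epochIds(data), cols))
  for (e in seq_len(ne)) for (ch in seq_len(nc)) {
    f <- hhtChannelFeatures(data@signals[e, ch, ], fs, maxImfs, bands)
    vals[e, paste0(data@channelNames[ch], ".", base)] <- f
  }
  prov <- stats::setNames(
    rep(list(list(extractor = "hht", fs = fs, maxImfs = maxImfs)),
        length(cols)), cols)
  imputeFailures(FeatureTable(vals, classLabels(data), prov))
}
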