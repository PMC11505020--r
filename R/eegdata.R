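#' Specification of the synthetic two-class EEG generator
#'
#' The generator emulates epoched scalp EEG for a binary normal/abnormal
#' contrast. Normal (class 0) epochs are pink (1/f) background activity plus
#' a 10 Hz alpha rhythm and white sensor noise. Abnormal (class 1) epochs
#' additionally carry periodic spike bursts and elevated 2-8 Hz
#' (delta/theta) band power, the two controllable class effects.
#'
#' @param nEpochs epochs per class.
#' @param nChannels channel count (default 24).
#' @param fs sampling rate in Hz (default 250).
#' @param epochSeconds epoch length in seconds (default 10).
#' @param backgroundExponent exponent of the 1/f background spectrum.
#' @param backgroundSd standard deviation of the pink background (uV).
#' @param alphaAmplitude amplitude of the 10 Hz alpha rhythm (uV).
#' @param burstRate abnormal spike rate (events per second).
#' @param burstAmplitude spike amplitude multiplier; spikes have amplitude
#'   `(burstAmplitude - 1)` times the background SD, so 1 means no effect.
#' @param bandPowerRatio target ratio of abnormal to normal 2-8 Hz band
#'   power; 1 means no effect.
#' @param noiseSd white sensor-noise SD (uV).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return A `SynthSpec` (validated named list).
#' @export
synthSpec <- function(nEpochs = 50L, nChannels = 24L, fs = 250, epochSeconds = 10,
                      backgroundExponent = 1, backgroundSd = 10,
                      alphaAmplitude = 5, burstRate = 2, burstAmplitude = 3,
                      bandPowerRatio = 2, noiseSd = 1, seed = 1L) {
  spec <- list(nEpochs = as.integer(nEpochs), nChannels = as.integer(nChannels),
               fs = fs, epochSeconds = epochSeconds,
               backgroundExponent = backgroundExponent,
               backgroundSd = backgroundSd, alphaAmplitude = alphaAmplitude,
               burstRate = burstRate, burstAmplitude = burstAmplitude,
               bandPowerRatio = bandPowerRatio, noiseSd = noiseSd,
               seed = as.integer(seed))
  if (spec$nEpochs < 1L) stopUsage("nEpochs must be positive")
  if (spec$nChannels < 1L) stopUsage("nChannels must be positive")
  if (spec$fs <= 0 || spec$epochSeconds <= 0)
    stopUsage("fs and epochSeconds must be positive")
  rates <- c(spec$backgroundSd, spec$alphaAmplitude, spec$burstRate,
             spec$burstAmplitude, spec$bandPowerRatio, spec$noiseSd)
  if (any(rates < 0)) stopUsage("rates and amplitudes must be non-negative")
  class(spec) <- "SynthSpec"
  spec
}

#' @export
print.SynthSpec <- function(x, ...) {
  cat(sprintf(paste0("SynthSpec: %d epochs/class, %d ch @ %g Hz, %g s epochs; ",
                     "burst x%g @ %g Hz, band ratio %g (seed %d)\n"),
              x$nEpochs, x$nChannels, x$fs, x$epochSeconds, x$burstAmplitude,
              x$burstRate, x$bandPowerRatio, x$seed))
  invisible(x)
}

# 1/f^a noise of length n with standard deviation sd, via spectral shaping.
pinkNoise <- function(n, exponent, sd) {
  f <- c(1, seq_len(n - 1L))                 # avoid DC blow-up
  f <- pmin(f, n - f)                        # symmetric frequency index
  amp <- f^(-exponent / 2)
  amp[1L] <- 0
  ph <- stats::runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::fft(spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Band-limited (lo-hi Hz) unit-power Gaussian noise.
bandNoise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  sp[f < lo | f > hi] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  p <- mean(y^2)
  if (p == 0) return(numeric(n))
  y / sqrt(p)
}

# Power of x within [lo, hi] Hz from the periodogram.
bandPowerFFT <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f >= lo & f <= min(hi, fs / 2)
  2 * sum(sp[keep])
}

# Ricker (Mexican hat) spike shape of the given width (seconds).
spikeShape <- function(fs, width = 0.02) {
  tt <- seq(-3 * width, 3 * width, by = 1 / fs)
  (1 - (tt / width)^2) * exp(-(tt / width)^2 / 2)
}

#' Generate a synthetic two-class EEG EpochSet
#'
#' Produces `2 * nEpochs` balanced epochs; see [synthSpec()] for the signal
#' model. Deterministic under the spec's seed.
#'
#' @param spec a [synthSpec()] object.
#' @return An [EpochSet-class] with class-0 epochs first.
#' @export
generateSynthetic <- function(spec) {
  if (!inherits(spec, "SynthSpec")) stopUsage("spec must be a SynthSpec")
  n <- round(spec$epochSeconds * spec$fs)
  nep <- 2L * spec$nEpochs
  sig <- array(0, dim = c(nep, spec$nChannels, n))
  labels <- rep(c(0L, 1L), each = spec$nEpochs)
  shape <- spikeShape(spec$fs)
  tt <- (seq_len(n) - 1L) / spec$fs
  withSeed(spec$seed, {
    for (e in seq_len(nep)) {
      abnormal <- labels[e] == 1L
      # spike timing is shared across channels within an epoch
      if (abnormal && spec$burstAmplitude > 1 && spec$burstRate > 0) {
        nSpk <- max(1L, round(spec$burstRate * spec$epochSeconds))
        period <- n / nSpk
        phase <- stats::runif(1, 0, period)
        centers <- round(phase + period * (seq_len(nSpk) - 1L)) + 1L
        centers <- centers[centers <= n]
      } else centers <- integer(0)
      for (ch in seq_len(spec$nChannels)) {
        base <- pinkNoise(n, spec$backgroundExponent, spec$backgroundSd) +
          spec$alphaAmplitude * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) +
          stats::rnorm(n, sd = spec$noiseSd)
        x <- base
        if (abnormal && spec$bandPowerRatio != 1) {
          p0 <- bandPowerFFT(base, spec$fs, 2, 8)
          extra <- bandNoise(n, spec$fs, 2, 8) *
            sqrt(max(0, (spec$bandPowerRatio - 1) * p0))
          x <- x + extra
        }
        if (length(centers)) {
          amp <- (spec$burstAmplitude - 1) * spec$backgroundSd
          half <- (length(shape) - 1L) %/% 2L
          for (cidx in centers) {
            lo <- cidx - half; hi <- cidx + half
            sl <- max(1L, lo):min(n, hi)
            x[sl] <- x[sl] + amp * shape[sl - lo + 1L]
          }
        }
        sig[e, ch, ] <- x
      }
    }
  })
  EpochSet(sig, spec$fs, labels,
           channelNames = sprintf("ch%02d", seq_len(spec$nChannels)),
           epochIds = sprintf("%s%06d", ifelse(labels == 0L, "n", "a"),
                              seq_len(nep)))
}

## ---------------------------------------------------------------------------
## Train/test splitting and cross-validation folds
## ---------------------------------------------------------------------------

# Allocate per-class training quotas by largest remainder so the overall
# train size is round(fraction * n) and class ratios stay within one sample.
classQuota <- function(nPerClass, nTrainTotal) {
  quota <- nPerClass * nTrainTotal / sum(nPerClass)
  base <- floor(quota)
  rem <- nTrainTotal - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified random train/test split
#'
#' Randomly sorts the samples and splits them into a training and a test
#' set (default 90/10), stratified by label and reproducible under a seed.
#'
#' @param x an [EpochSet-class] or [FeatureTable-class].
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return A [SplitPlan-class].
#' @export
splitTrainTest <- function(x, trainFraction = 0.9, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stopUsage("trainFraction must lie strictly between 0 and 1")
  labels <- classLabels(x)
  cls <- sort(unique(labels))
  counts <- vapply(cls, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2L))
    stopUsage("stratification requires at least 2 members per class")
  nTrain <- as.integer(roundHalfUp(trainFraction * length(labels)))
  quota <- classQuota(counts, nTrain)
  withSeed(seed, {
    train <- integer(0); test <- integer(0)
    for (i in seq_along(cls)) {
      idx <- which(labels == cls[i])
      idx <- idx[sample.int(length(idx))]
      train <- c(train, idx[seq_len(quota[i])])
      test <- c(test, idx[-seq_len(quota[i])])
    }
    new("SplitPlan", trainIndices = sort(train), testIndices = sort(test),
        folds = list(), labels = as.integer(labels), seed = as.integer(seed))
  })
}

#' Build stratified cross-validation folds over a plan's training set
#'
#' @param plan a [SplitPlan-class] from [splitTrainTest()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return The plan with `k` stratified `(train, validate)` folds; each
#'   training index validates exactly once.
#' @export
makeFolds <- function(plan, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stopUsage("k must be at least 2")
  tr <- plan@trainIndices
  if (k > length(tr)) stopUsage("k exceeds the training-set size")
  withSeed(seed, {
    g <- stratifiedGroups(plan@labels[tr], k)
    folds <- lapply(seq_len(k), function(j)
      list(train = sort(tr[g != j]), validate = sort(tr[g == j])))
    new("SplitPlan", trainIndices = tr, testIndices = plan@testIndices,
        folds = folds, labels = plan@labels, seed = as.integer(seed))
  })
}

#' Serialize a SplitPlan to JSON
#'
#' @param plan a [SplitPlan-class].
#' @return A JSON string.
#' @export
splitPlanJSON <- function(plan) {
  manifestJSON(list(train = plan@trainIndices, test = plan@testIndices,
                    folds = lapply(plan@folds, function(f)
                      list(train = f$train, validate = f$validate)),
                    seed = plan@seed))
}
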