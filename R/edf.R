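# Minimal EDF (European Data Format) reader/writer: standard 256-byte fixed
# header, 256 bytes per signal, 16-bit little-endian data records. Only
# uniformly sampled recordings (same rate on every channel) are supported,
# which covers routine clinical EEG exports.

edfField <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1L, width)
}

#' Write an EpochSet to an EDF file
#'
#' Epochs are written as consecutive data records (one record per epoch),
#' each channel scaled independently to the full 16-bit digital range.
#'
#' @param x an [EpochSet-class].
#' @param path output file path.
#' @param physicalDim physical dimension string (default `"uV"`).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(x, path, physicalDim = "uV") {
  stopifnot(is(x, "EpochSet"))
  ne <- nEpochs(x); nc <- nChannels(x); nt <- nTimepoints(x)
  dur <- nt / samplingRate(x)
  pmin <- apply(x@signals, 2L, min); pmax <- apply(x@signals, 2L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfField("0", 8L), edfField("synthetic", 80L), edfField("eegensembles", 80L),
    edfField("01.01.20", 8L), edfField("00.00.00", 8L),
    edfField(256L * (1L + nc), 8L), edfField("", 44L),
    edfField(ne, 8L), edfField(format(dur, digits = 8), 8L), edfField(nc, 4L))
  writeChar(hdr, con, eos = NULL)
  sigHdr <- paste0(
    paste(edfField(channelNames(x), 16L), collapse = ""),
    paste(rep(edfField("", 80L), nc), collapse = ""),
    paste(rep(edfField(physicalDim, 8L), nc), collapse = ""),
    paste(edfField(formatC(pmin, format = "g", digits = 6), 8L), collapse = ""),
    paste(edfField(formatC(pmax, format = "g", digits = 6), 8L), collapse = ""),
    paste(rep(edfField(dmin, 8L), nc), collapse = ""),
    paste(rep(edfField(dmax, 8L), nc), collapse = ""),
    paste(rep(edfField("", 80L), nc), collapse = ""),
    paste(rep(edfField(nt, 8L), nc), collapse = ""),
    paste(rep(edfField("", 32L), nc), collapse = ""))
  writeChar(sigHdr, con, eos = NULL)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (e in seq_len(ne)) {
    for (ch in seq_len(nc)) {
      dig <- round((x@signals[e, ch, ] - pmin[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmax(dmin, pmin(dmax, dig))), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

readAscii <- function(raw, at, width) {
  trimws(rawToChar(raw[at:(at + width - 1L)]))
}

#' Read an EDF file into an EpochSet
#'
#' Signals are concatenated across data records and cut into contiguous
#' non-overlapping epochs of `epochSeconds`; a trailing partial epoch is
#' dropped. The channel order of the file is preserved.
#'
#' @param path an EDF file.
#' @param epochSeconds epoch length in seconds (> 0).
#' @param label the recording-level 0/1 label inherited by every epoch.
#' @return An [EpochSet-class].
#' @export
readEDF <- function(path, epochSeconds, label) {
  if (epochSeconds <= 0) stopUsage("epochSeconds must be positive")
  if (!file.exists(path)) stopUsage("EDF file not found: %s", path)
  sz <- file.info(path)$size
  if (sz < 256L) stopUsage("EDF format error: truncated header at byte %d", sz)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", 256L)
  nRec <- as.integer(readAscii(raw, 237L, 8L))
  recDur <- as.numeric(readAscii(raw, 245L, 8L))
  nc <- as.integer(readAscii(raw, 253L, 4L))
  if (is.na(nc) || nc < 1L) stopUsage("EDF empty-input error: zero channels")
  sraw <- readBin(con, "raw", 256L * nc)
  if (length(sraw) < 256L * nc)
    stopUsage("EDF format error: truncated signal header at byte %d",
              256L + length(sraw))
  # per-signal header blocks: label 16, transducer 80, physdim 8, physmin 8,
  # physmax 8, digmin 8, digmax 8, prefilter 80, samples/record 8, reserved 32
  fld <- function(blockStart, width)
    vapply(seq_len(nc), function(i)
      readAscii(sraw, blockStart * nc + (i - 1L) * width + 1L, width), "")
  chNames <- fld(0L, 16L)
  pmin <- as.numeric(fld(104L, 8L))
  pmax <- as.numeric(fld(112L, 8L))
  dmin <- as.numeric(fld(120L, 8L))
  dmax <- as.numeric(fld(128L, 8L))
  spr <- as.integer(fld(216L, 8L))
  if (length(unique(spr)) != 1L)
    stopUsage("EDF unsupported: channels differ in samples per record")
  expect <- 256L * (1L + nc) + 2L * nRec * nc * spr[1L]
  if (sz < expect)
    stopUsage("EDF format error: file truncated at byte %.0f (expected %.0f)",
              sz, expect)
  fs <- spr[1L] / recDur
  dat <- readBin(con, "integer", n = nRec * nc * spr[1L], size = 2L,
                 signed = TRUE, endian = "little")
  # records x (channel-major blocks of spr samples)
  dim(dat) <- c(spr[1L], nc, nRec)
  scale <- (pmax - pmin) / (dmax - dmin)
  total <- spr[1L] * nRec
  nt <- round(epochSeconds * fs)
  ne <- floor(total / nt)
  if (ne < 1L) stopUsage("recording shorter than one epoch")
  sig <- array(0, dim = c(ne, nc, nt))
  for (ch in seq_len(nc)) {
    phys <- (as.vector(dat[, ch, ]) - dmin[ch]) * scale[ch] + pmin[ch]
    sig[, ch, ] <- matrix(phys[seq_len(ne * nt)], nrow = ne, byrow = TRUE)
  }
  EpochSet(sig, fs, rep(as.integer(label), ne), channelNames = chNames)
}
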