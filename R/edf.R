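# Minimal European Data Format (EDF) I/O for multichannel LFP.
# Implements the fixed-layout 16-bit EDF container: 256-byte global header,
# 256 bytes per signal, then 1-second data records of little-endian int16.
# Continuous equal-rate signals only; no annotations (EDF, not EDF+).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' Writes a matrix of equal-length signals as a 16-bit EDF file with 1-second
#' data records. Each channel is scaled independently to its physical range,
#' so voltages round-trip within one quantization step
#' `(max - min) / 65535`.
#'
#' @param signals Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz (integer; samples per 1-s record).
#' @param path Output file path.
#' @param labels Channel labels; default column names.
#' @param patient_id,recording_id Free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
edf_write <- function(signals, fs, path, labels = colnames(signals),
                      patient_id = "X", recording_id = "Startdate X") {
  signals <- as.matrix(signals)
  ns <- ncol(signals)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  fs <- as.integer(fs)
  n <- nrow(signals)
  if (n %% fs != 0)
    stop("signal length must be a whole number of seconds for 1-s EDF records")
  nrec <- n %/% fs

  # Physical range: symmetric about zero, rounded up to 2 significant digits
  # so it always fits the 8-character header fields; the value actually
  # written to the header is re-parsed and used for scaling, so file and
  # scaler agree exactly.
  amp <- apply(abs(signals), 2, max)
  amp[amp == 0] <- 1
  amp <- ifelse(signif(amp, 2) >= amp, signif(amp, 2), signif(amp * 1.06, 2))
  pmax <- as.numeric(vapply(amp, edf_num, "", width = 8))
  pmin <- -pmax
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256 * (1 + ns), 8), edf_pad("", 44),
    edf_num(nrec, 8), edf_num(1, 8), edf_num(ns, 4)
  )
  sighdr <- paste0(
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_num(dmin, 8), ns), collapse = ""),
    paste(rep(edf_num(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_num(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeBin(charToRaw(paste0(hdr, sighdr)), con)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- matrix(0L, n, ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(round((signals[, j] - pmin[j]) * scale[j]) + dmin)
  # interleave per 1-s record: record r holds fs samples of each channel in turn
  idx <- matrix(seq_len(n), nrow = fs)        # fs x nrec sample indices
  out <- integer(n * ns)
  pos <- 1L
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      out[pos:(pos + fs - 1L)] <- dig[idx[, r], j]
      pos <- pos + fs
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous 16-bit EDF file written by [edf_write()] (or any EDF
#' whose signals share one sampling rate).
#'
#' @param path EDF file path.
#' @return List with `signals` (samples x channels matrix with channel
#'   labels), `fs` (Hz), `duration_s`, and `phys_range` (per-channel
#'   `pmax - pmin`, from which one quantization step is
#'   `phys_range / 65535`).
#' @export
edf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) rawToChar(readBin(con, "raw", nbytes))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed)
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))               # samples per record, per signal
  fld(32)
  if (length(unique(spr)) != 1)
    stop("EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / recdur
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  signals <- matrix(0, nrec * spr[1], ns, dimnames = list(NULL, labels))
  scale <- (pmax - pmin) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(nrec)) {
    for (j in seq_len(ns)) {
      seg <- raw[(pos + 1L):(pos + spr[j])]
      signals[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        (seg - dmin[j]) * scale[j] + pmin[j]
      pos <- pos + spr[j]
    }
  }
  list(signals = signals, fs = fs, duration_s = nrec * recdur,
       phys_range = stats::setNames(pmax - pmin, labels))
}
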