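#' Construct an EEG recording
#'
#' Container for one multichannel recording: a channels x samples matrix in
#' microvolts, its sampling rate, the ordered channel labels, the half-open
#' sample span of the pre-stimulus baseline and free-form metadata
#' (participant, trial, label reference).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one unique 10-20 label per row.
#' @param baseline_span Integer length-2, half-open `[start, end)` in
#'   0-based samples; `c(0, 0)` means no baseline segment.
#' @param meta Named list of metadata.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names,
                          baseline_span = c(0L, 0L), meta = list()) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (nrow(data) != length(channel_names))
    stop("n_channels (", nrow(data), ") != length(channel_names) (",
         length(channel_names), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  baseline_span <- as.integer(baseline_span)
  if (length(baseline_span) != 2L || baseline_span[1] < 0L ||
      baseline_span[2] < baseline_span[1] || baseline_span[2] > ncol(data))
    stop("baseline_span must be half-open [start, end) within the recording")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 baseline_span = baseline_span, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (x$baseline_span[2] > x$baseline_span[1])
    cat(sprintf("  baseline: samples [%d, %d) = %.1f s\n",
                x$baseline_span[1], x$baseline_span[2],
                diff(x$baseline_span) / x$fs))
  invisible(x)
}

## reorder rows into canonical montage order, case-insensitive label match
.canonicalize <- function(rec) {
  canon <- canonical_channels()
  idx <- match(tolower(canon), tolower(rec$channel_names))
  if (anyNA(idx)) {
    stop("recording is missing canonical channel(s): ",
         paste(canon[is.na(idx)], collapse = ", "))
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, canon,
                rec$baseline_span, rec$meta)
}

#' Read an EEG recording
#'
#' Reads either the delimited matrix+JSON dialect (a tab-separated numeric
#' matrix, rows = channels, plus a `.json` sidecar holding `fs`,
#' `channel_names`, `baseline_span` and `meta`) or a 16-bit EDF file.
#' Channels are returned in canonical montage order regardless of on-disk
#' order; a missing canonical channel is an error naming the absentees.
#'
#' @param path File path (for matrix+json: the matrix file; sidecar is
#'   `<path>.json`).
#' @param format `"matrix+json"` or `"edf"`; default guesses from the
#'   extension.
#' @return [eeg_recording()] in canonical channel order.
#' @export
read_recording <- function(path, format = c("auto", "matrix+json", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix+json"
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- if (format == "edf") .read_edf(path) else .read_matrix_json(path)
  .canonicalize(rec)
}

.read_matrix_json <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  if (!is.numeric(mat)) stop("matrix file is not numeric: ", path)
  eeg_recording(mat, js$fs, js$channel_names,
                baseline_span = if (is.null(js$baseline_span)) c(0L, 0L)
                                else as.integer(js$baseline_span),
                meta = if (is.null(js$meta)) list() else as.list(js$meta))
}

#' Write an EEG recording in the matrix+json dialect
#'
#' @param rec [eeg_recording()].
#' @param path Matrix file path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names,
         baseline_span = rec$baseline_span, meta = rec$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- minimal EDF (16-bit) reader/writer -------------------------------
## Standard 256-byte fixed header + 256 bytes per signal, one data record.
## Physical range is pinned to the digital range (-32768..32767 microvolts)
## so integer-valued data round-trips exactly.  The baseline span is kept
## in the 44-byte reserved header field.

.pad <- function(s, n) {
  s <- substr(s, 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' Write an EEG recording as 16-bit EDF
#'
#' Minimal single-record EDF writer.  Samples are rounded to integer
#' microvolts (the physical range is identified with the 16-bit digital
#' range), so integer-valued data is recovered exactly by [read_recording()].
#'
#' @param rec [eeg_recording()]; all samples must lie in `[-32768, 32767]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (max(abs(rec$data)) > 32767)
    stop("EDF writer supports amplitudes up to 32767 microvolts")
  ns <- nrow(rec$data); nsamp <- ncol(rec$data)
  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  reserved <- sprintf("baseline=%d:%d", rec$baseline_span[1], rec$baseline_span[2])
  writeChar(paste0(
    .pad("0", 8), .pad("X X X X", 80), .pad("Startdate X X X X", 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8), .pad(as.character(hdr_bytes), 8),
    .pad(reserved, 44), .pad("1", 8),
    .pad(format(nsamp / rec$fs, digits = 8), 8), .pad(as.character(ns), 4)),
    con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .pad, "", n = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep("-32768", ns), 8)                  # physical minimum
  field(rep("32767", ns), 8)                   # physical maximum
  field(rep("-32768", ns), 8)                  # digital minimum
  field(rep("32767", ns), 8)                   # digital maximum
  field(rep("", ns), 80)                       # prefiltering
  field(rep(as.character(nsamp), ns), 8)       # samples per record
  field(rep("", ns), 32)                       # reserved
  writeBin(as.integer(round(t(rec$data))), con, size = 2, endian = "little")
  ## write channel-major: EDF stores each signal contiguously within a record
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                # version
  rd(160)                              # patient + recording id
  rd(16)                               # date + time
  rd(8)                                # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rd(8)                                # record duration
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  dat <- matrix(NA_real_, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      dat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin[i] + (raw - dmin[i]) * gain
    }
  }
  ## sampling rate from record duration is unreliable after trimws; recover
  ## it from samples-per-record over record duration stored in the header
  con2 <- file(path, "rb"); on.exit(close(con2), add = TRUE)
  readChar(con2, 244, useBytes = TRUE)
  dur <- as.numeric(readChar(con2, 8, useBytes = TRUE))
  fs <- spr[1] / dur
  bl <- c(0L, 0L)
  m <- regmatches(reserved, regexec("baseline=([0-9]+):([0-9]+)", reserved))[[1]]
  if (length(m) == 3) bl <- as.integer(m[2:3])
  eeg_recording(dat, fs, labels, baseline_span = bl, meta = list())
}

## ---- preprocessing ----------------------------------------------------

#' Band-pass filter and resample a recording
#'
#' Zero-phase 4th-order Butterworth band-pass filtering followed by
#' polyphase rational resampling to `fs_out`.  The forward-backward pass
#' is realized spectrally -- the squared analog Butterworth band-pass
#' magnitude is applied in the frequency domain -- which is numerically
#' exact where a recursive realization with a 0.05 Hz edge is unstable,
#' and introduces no group delay that would shift window boundaries.
#'
#' @param rec [eeg_recording()] with `fs >= 2 * hi`.
#' @param lo,hi Pass-band edges in Hz.
#' @param fs_out Output sampling rate in Hz; must not exceed `rec$fs`.
#' @return Filtered, resampled [eeg_recording()]; the baseline span is
#'   rescaled to the new rate.
#' @export
preprocess <- function(rec, lo = 0.05, hi = 47, fs_out = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < 2 * hi) stop("sampling rate too low for hi = ", hi, " Hz")
  if (fs_out > rec$fs) stop("fs_out exceeds input rate; upsampling unsupported")
  n <- ncol(rec$data)
  f <- (0:(n - 1)) * rec$fs / n
  f <- pmin(f, rec$fs - f)
  ## order-4 Butterworth band-pass magnitude; squared for the zero-phase
  ## forward-backward pass
  Wf <- ifelse(f == 0, Inf, (f^2 - lo * hi) / (pmax(f, 1e-12) * (hi - lo)))
  gain <- ifelse(is.infinite(Wf), 0, (1 / (1 + Wf^8))^2)
  filt1 <- function(x) Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  dat <- t(apply(rec$data, 1, filt1))
  fs <- rec$fs
  if (fs_out != fs) {
    frac <- .as_ratio(fs_out / fs)
    dat <- t(apply(dat, 1, function(x) signal::resample(x, frac[1], frac[2])))
    fs <- fs_out
  }
  scale <- fs / rec$fs
  eeg_recording(dat, fs, rec$channel_names,
                baseline_span = as.integer(round(rec$baseline_span * scale)),
                meta = rec$meta)
}

## smallest integer ratio p/q equal to x (rates are rational in practice)
.as_ratio <- function(x, tol = 1e-9) {
  for (q in 1:10000) {
    p <- x * q
    if (abs(p - round(p)) < tol) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", x, " as a small fraction")
}
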