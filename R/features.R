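#' Canonical feature names
#'
#' The ten per-window, per-channel features in their fixed order: four
#' Welch band powers (theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz),
#' mean, sample standard deviation, zero-crossing rate, Higuchi fractal
#' dimension, approximate entropy and correlation dimension.
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("power_theta", "power_alpha", "power_beta", "power_gamma",
    "mean", "std", "zcr", "fractal_dim", "approx_entropy", "corr_dim")
}

.BANDS <- list(power_theta = c(4, 8), power_alpha = c(8, 12),
               power_beta = c(12, 30), power_gamma = c(30, 45))

#' Slice a recording into analysis windows
#'
#' Returns the sample-index matrix of complete analysis windows over the
#' trial (post-baseline) segment, or over the baseline segment.  Windows
#' start at multiples of `win_seconds * (1 - overlap)` and only full
#' windows are emitted, so a 60-s trial at 128 Hz yields 59 windows of 256
#' samples.
#'
#' @param rec [eeg_recording()].
#' @param win_seconds Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param segment `"trial"` (default; everything after the baseline span)
#'   or `"baseline"`.
#' @return Integer matrix `win_len x n_windows`; entry `[i, w]` is the
#'   column index into `rec$data` of sample `i` of window `w`.
#' @export
window_trial <- function(rec, win_seconds = 2, overlap = 0.5,
                         segment = c("trial", "baseline")) {
  stopifnot(inherits(rec, "eeg_recording"))
  segment <- match.arg(segment)
  n <- ncol(rec$data)
  span <- if (segment == "baseline") {
    if (rec$baseline_span[2] <= rec$baseline_span[1])
      stop("recording has no baseline segment")
    c(rec$baseline_span[1] + 1L, rec$baseline_span[2])
  } else {
    c(rec$baseline_span[2] + 1L, n)
  }
  len <- span[2] - span[1] + 1L
  if (len <= 0L) stop("empty ", segment, " segment")
  win <- as.integer(round(win_seconds * rec$fs))
  step <- as.integer(round(win_seconds * (1 - overlap) * rec$fs))
  if (len < win)
    stop(segment, " segment shorter than one window (",
         len, " < ", win, " samples)")
  n_win <- (len - win) %/% step + 1L
  starts <- span[1] + (seq_len(n_win) - 1L) * step
  idx <- outer(0:(win - 1L), starts, `+`)
  storage.mode(idx) <- "integer"
  idx
}

## one-sided Welch PSD of each column of `wins` (samples x windows):
## Hann-windowed segments of `seg` samples with 50% overlap, periodograms
## averaged per window.  Returns list(freq, psd [n_freq x n_windows]).
.welch_psd <- function(wins, fs, seg = 128L) {
  wins <- as.matrix(wins)
  n <- nrow(wins)
  if (n < seg) stop("window shorter than one Welch segment (", seg, " samples)")
  step <- seg %/% 2L
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nw <- ncol(wins)
  segmat <- matrix(0, seg, length(starts) * nw)
  for (s in seq_along(starts)) {
    segmat[, (s - 1L) * nw + seq_len(nw)] <-
      wins[starts[s]:(starts[s] + seg - 1L), , drop = FALSE]
  }
  ft <- stats::mvfft(segmat * w)
  nf <- seg %/% 2L + 1L
  pxx <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) * scale
  pxx[2:(nf - 1L), ] <- 2 * pxx[2:(nf - 1L), ]  # one-sided
  psd <- matrix(0, nf, nw)
  for (s in seq_along(starts))
    psd <- psd + pxx[, (s - 1L) * nw + seq_len(nw), drop = FALSE]
  list(freq = (0:(nf - 1L)) * fs / seg, psd = psd / length(starts))
}

#' Welch average band power
#'
#' Mean of the one-sided Welch power spectral density (Hann window,
#' 128-sample segments, 50% segment overlap) over the frequency bins with
#' `lo <= f < hi`.
#'
#' @param x Numeric sample vector (at least one Welch segment long).
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric `(lo, hi)` in Hz, inside `[0, fs/2)`.
#' @return Non-negative scalar.
#' @export
band_power <- function(x, fs, band) {
  if (band[1] < 0 || band[2] > fs / 2 || band[2] <= band[1])
    stop("band must satisfy 0 <= lo < hi <= fs/2")
  p <- .welch_psd(matrix(x, ncol = 1), fs)
  sel <- p$freq >= band[1] & p$freq < band[2]
  if (!any(sel)) stop("band (", band[1], ", ", band[2], ") contains no bins")
  mean(p$psd[sel, 1])
}

#' Mean, standard deviation and zero-crossing rate
#'
#' Sample standard deviation uses the N-1 denominator; the zero-crossing
#' rate is `sum(|sgn(x_n) - sgn(x_{n-1})|) / (2N)` with `sgn(0) = 0`.
#'
#' @param x Numeric vector of length >= 2.
#' @return Named list `mean`, `std`, `zcr`.
#' @export
stat_features <- function(x) {
  stopifnot(length(x) >= 2)
  s <- sign(x)
  list(mean = mean(x), std = stats::sd(x),
       zcr = sum(abs(diff(s))) / (2 * length(x)))
}

#' Higuchi fractal dimension
#'
#' Curve-length estimate: slope of `log L(k)` against `log(1/k)` over
#' scales `k = 1..kmax`.  A constant series returns 1.
#'
#' @param x Numeric vector, `length(x) >= 4 * kmax`.
#' @param kmax Largest scale.
#' @return Estimate, approximately in `[1, 2]` for bounded series.
#' @export
fractal_dimension <- function(x, kmax = 10) {
  if (length(x) < 4 * kmax)
    stop("need length(x) >= 4 * kmax = ", 4 * kmax)
  .higuchi_cpp(as.numeric(x), as.integer(kmax))
}

#' Approximate entropy
#'
#' `ApEn = phi^m(r) - phi^(m+1)(r)` from template-match counting with
#' Chebyshev distance and self-matches included.
#'
#' @param x Numeric vector, `length(x) >= m + 2`.
#' @param m Template length.
#' @param r Match tolerance; defaults to `0.2 * sd(x)`.  If `sd(x)` is 0
#'   the series is perfectly regular and 0 is returned.
#' @return Non-negative scalar.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  stopifnot(length(x) >= m + 2)
  if (is.na(r) || r <= 0) return(0)
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Correlation dimension
#'
#' Grassberger-Procaccia estimate: delay-embed the series, compute the
#' correlation sum C(eps) over a log-spaced grid spanning the 5th-50th
#' percentile of pairwise Euclidean distances, and return the
#' least-squares slope of `log C` against `log eps`.
#'
#' @param x Numeric vector, `length(x) >= embed_m * delay + 10`.
#' @param embed_m Embedding dimension.
#' @param delay Embedding delay in samples.
#' @param n_eps Number of grid points.
#' @return Non-negative scalar; identical points give 0.
#' @export
correlation_dimension <- function(x, embed_m = 5, delay = 1, n_eps = 10) {
  stopifnot(length(x) >= embed_m * delay + 10)
  .corrdim_cpp(as.numeric(x), as.integer(embed_m), as.integer(delay),
               as.integer(n_eps))
}

#' Min-max normalize features against the baseline segment
#'
#' Per channel and feature: `v' = clip((v - min_b) / (max_b - min_b + eps),
#' 0, 1)` where `min_b`/`max_b` are the extrema over baseline windows and
#' `eps` guards a zero baseline range.
#'
#' @param raw Numeric array `windows x channels x features`.
#' @param baseline Numeric array `baseline_windows x channels x features`
#'   computed with the same windowing.
#' @param eps Zero-range guard.
#' @return Array like `raw` with all entries in `[0, 1]`.
#' @export
normalize_to_baseline <- function(raw, baseline, eps = 1e-12) {
  stopifnot(length(dim(raw)) == 3, length(dim(baseline)) == 3,
            all(dim(raw)[2:3] == dim(baseline)[2:3]))
  lo <- apply(baseline, c(2, 3), min)
  hi <- apply(baseline, c(2, 3), max)
  out <- raw
  for (w in seq_len(dim(raw)[1]))
    out[w, , ] <- (raw[w, , ] - lo) / (hi - lo + eps)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

## all ten features for a samples x windows matrix of one channel
.channel_window_features <- function(wins, fs) {
  nw <- ncol(wins)
  out <- matrix(NA_real_, nw, 10, dimnames = list(NULL, feature_names()))
  wp <- .welch_psd(wins, fs)
  for (b in names(.BANDS)) {
    sel <- wp$freq >= .BANDS[[b]][1] & wp$freq < .BANDS[[b]][2]
    out[, b] <- colMeans(wp$psd[sel, , drop = FALSE])
  }
  n <- nrow(wins)
  mu <- colMeans(wins)
  out[, "mean"] <- mu
  out[, "std"] <- sqrt(pmax(0, (colSums(wins^2) - n * mu^2) / (n - 1)))
  sg <- sign(wins)
  out[, "zcr"] <- colSums(abs(sg[-1, , drop = FALSE] -
                              sg[-n, , drop = FALSE])) / (2 * n)
  for (w in seq_len(nw)) {
    x <- wins[, w]
    out[w, "fractal_dim"] <- .higuchi_cpp(x, 10L)
    r <- 0.2 * out[w, "std"]
    out[w, "approx_entropy"] <- if (r > 0) .apen_cpp(x, 2L, r) else 0
    out[w, "corr_dim"] <- .corrdim_cpp(x, 5L, 1L, 10L)
  }
  out
}

#' Extract the full windows x channels x features tensor
#'
#' Applies the analysis windowing, computes all ten features per window
#' and channel, and (by default) min-max normalizes each channel/feature
#' against the extrema of the same features over the baseline windows.
#'
#' @param rec Preprocessed [eeg_recording()].
#' @param normalize Normalize to the baseline segment (requires one).
#' @param win_seconds,overlap Windowing parameters.
#' @param label Optional label to attach (see [emotion_label()]).
#' @param window_step Keep every `window_step`-th trial window (baseline
#'   windowing is unaffected).  Overlapping windows are redundant for
#'   *training*, so `window_step = 2` halves extraction cost there; the
#'   result equals [thin_windows()] applied to the full tensor.
#' @return Object of class `feature_tensor`: list with `tensor`
#'   (`windows x 32 x 10` array), `label` and `meta`.
#' @export
extract_feature_tensor <- function(rec, normalize = TRUE, win_seconds = 2,
                                   overlap = 0.5, label = NULL,
                                   window_step = 1) {
  stopifnot(inherits(rec, "eeg_recording"), window_step >= 1)
  idx <- window_trial(rec, win_seconds, overlap, segment = "trial")
  if (window_step > 1)
    idx <- idx[, seq(1, ncol(idx), by = window_step), drop = FALSE]
  nch <- nrow(rec$data)
  raw <- array(NA_real_, c(ncol(idx), nch, 10),
               dimnames = list(NULL, rec$channel_names, feature_names()))
  for (ch in seq_len(nch)) {
    wins <- matrix(rec$data[ch, idx], nrow = nrow(idx))
    raw[, ch, ] <- .channel_window_features(wins, rec$fs)
  }
  tensor <- raw
  baseline <- NULL
  if (normalize) {
    bidx <- window_trial(rec, win_seconds, overlap, segment = "baseline")
    base <- array(NA_real_, c(ncol(bidx), nch, 10))
    for (ch in seq_len(nch)) {
      wins <- matrix(rec$data[ch, bidx], nrow = nrow(bidx))
      base[, ch, ] <- .channel_window_features(wins, rec$fs)
    }
    tensor <- normalize_to_baseline(raw, base)
    ## baseline windows through the same normalization: the reference
    ## state for baseline-relative map values
    baseline <- normalize_to_baseline(base, base)
    dimnames(baseline) <- list(NULL, rec$channel_names, feature_names())
  }
  structure(list(tensor = tensor, baseline = baseline, label = label,
                 meta = rec$meta),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("feature tensor: %d windows x %d channels x %d features\n",
              d[1], d[2], d[3]))
  if (!is.null(x$label))
    cat("  label:", format(x$label), "\n")
  invisible(x)
}

#' Write a feature tensor as a tab-separated table
#'
#' One row per (window, channel); columns `window`, `channel`, then the
#' ten features in canonical order.
#'
#' @param tensor `feature_tensor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tensor, path) {
  stopifnot(inherits(tensor, "feature_tensor"))
  d <- dim(tensor$tensor)
  chans <- dimnames(tensor$tensor)[[2]]
  rows <- expand.grid(channel = seq_len(d[2]), window = seq_len(d[1]))
  vals <- matrix(NA_real_, nrow(rows), d[3])
  for (r in seq_len(nrow(rows)))
    vals[r, ] <- tensor$tensor[rows$window[r], rows$channel[r], ]
  df <- data.frame(window = rows$window, channel = chans[rows$channel], vals)
  names(df) <- c("window", "channel", feature_names())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @param label Optional label to attach.
#' @return `feature_tensor`.
#' @export
read_feature_table <- function(path, label = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  chans <- unique(df$channel)
  nw <- max(df$window)
  arr <- array(NA_real_, c(nw, length(chans), 10),
               dimnames = list(NULL, chans, feature_names()))
  for (r in seq_len(nrow(df))) {
    arr[df$window[r], match(df$channel[r], chans), ] <-
      as.numeric(df[r, feature_names()])
  }
  structure(list(tensor = arr, label = label, meta = list()),
            class = "feature_tensor")
}
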