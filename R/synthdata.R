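#' Emotion label
#'
#' Binary valence/arousal label with its derived quadrant.  When raw 1-9
#' self-assessment scores are supplied, 1-3 maps to low and 7-9 to high;
#' mid-scale scores (4-6) are rejected.
#'
#' @param valence_bin,arousal_bin `"low"` or `"high"`.
#' @param raw_valence,raw_arousal Optional raw 1-9 scores; when given they
#'   override the bins.
#' @return Object of class `emotion_label` with fields `valence_bin`,
#'   `arousal_bin`, `quadrant` (HAHV/LAHV/HALV/LALV) and the raw scores.
#' @export
emotion_label <- function(valence_bin = NULL, arousal_bin = NULL,
                          raw_valence = NULL, raw_arousal = NULL) {
  bin_from_raw <- function(score, what) {
    if (score >= 1 && score <= 3) "low"
    else if (score >= 7 && score <= 9) "high"
    else stop("record rejected: mid-scale ", what, " score ", score)
  }
  if (!is.null(raw_valence)) valence_bin <- bin_from_raw(raw_valence, "valence")
  if (!is.null(raw_arousal)) arousal_bin <- bin_from_raw(raw_arousal, "arousal")
  valence_bin <- match.arg(valence_bin, c("low", "high"))
  arousal_bin <- match.arg(arousal_bin, c("low", "high"))
  quadrant <- paste0(if (arousal_bin == "high") "HA" else "LA",
                     if (valence_bin == "high") "HV" else "LV")
  structure(list(valence_bin = valence_bin, arousal_bin = arousal_bin,
                 quadrant = quadrant, raw_valence = raw_valence,
                 raw_arousal = raw_arousal),
            class = "emotion_label")
}

#' @export
format.emotion_label <- function(x, ...) {
  sprintf("%s (valence %s, arousal %s)", x$quadrant, x$valence_bin, x$arousal_bin)
}

#' @export
print.emotion_label <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Specification of a synthetic emotional EEG dataset
#'
#' Describes a DEAP-structured corpus: 32-channel 60-s trials at 128 Hz
#' preceded by a 5-s baseline, 40 trials per participant split 8/10/10/12
#' over the arousal x valence quadrants.  Class structure is planted as
#' multiplicative amplitude scalings of band-limited oscillations on top
#' of a 1/f^beta background: high valence scales frontal alpha on the left
#' hemisphere (low valence on the right), and high arousal scales
#' posterior beta+gamma.
#'
#' @param n_participants Number of participants.
#' @param trials_per_quadrant Named integer vector with counts for HAHV,
#'   LAHV, HALV and LALV.
#' @param fs Sampling rate, Hz.
#' @param trial_seconds,baseline_seconds Trial and baseline durations.
#' @param valence_effect Amplitude ratio (>= 1) applied to frontal alpha
#'   on the hemisphere favored by the valence class.
#' @param arousal_effect Amplitude ratio (>= 1) applied to posterior
#'   beta and gamma when arousal is high.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param seed Integer seed making the whole corpus deterministic.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_participants = 32,
                       trials_per_quadrant = c(HAHV = 8, LAHV = 10,
                                               HALV = 10, LALV = 12),
                       fs = 128, trial_seconds = 60, baseline_seconds = 5,
                       valence_effect = 1.5, arousal_effect = 1.5,
                       noise_exponent = 1, seed = 1) {
  stopifnot(n_participants >= 1, all(trials_per_quadrant >= 1),
            valence_effect >= 1, arousal_effect >= 1,
            abs(fs * trial_seconds - round(fs * trial_seconds)) < 1e-9)
  tq <- as.integer(trials_per_quadrant)
  names(tq) <- c("HAHV", "LAHV", "HALV", "LALV")
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_quadrant = tq, fs = fs,
                 trial_seconds = trial_seconds,
                 baseline_seconds = baseline_seconds,
                 valence_effect = valence_effect,
                 arousal_effect = arousal_effect,
                 noise_exponent = noise_exponent,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## channel groups carrying the planted effects (hemispheric valence
## hypothesis: high valence -> left frontal alpha)
.LEFT_FRONTAL <- c("Fp1", "AF3", "F3", "F7", "FC5")
.RIGHT_FRONTAL <- c("Fp2", "AF4", "F4", "F8", "FC6")
.POSTERIOR <- c("P3", "P4", "P7", "P8", "PO3", "PO4", "O1", "O2", "Oz")

## 1/f^beta Gaussian background via spectral shaping, unit RMS
.pink_noise <- function(n, beta) {
  half <- n %/% 2
  amp <- numeric(n)
  freqs <- c(0, seq_len(n - 1))
  freqs <- pmin(freqs, n - freqs)          # mirrored bin distance
  amp[freqs > 0] <- freqs[freqs > 0]^(-beta / 2)
  ph <- stats::runif(n, 0, 2 * pi)
  ## enforce Hermitian symmetry so the inverse transform is real
  spec <- amp * exp(1i * ph)
  spec[1] <- 0
  for (k in 2:(half + 1)) spec[n - k + 2] <- Conj(spec[k])
  if (n %% 2 == 0) spec[half + 1] <- Mod(spec[half + 1])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

## band-limited Gaussian oscillation, unit RMS
.band_noise <- function(n, fs, band) {
  freqs <- (0:(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  sel <- freqs >= band[1] & freqs <= band[2]
  amp <- as.numeric(sel)
  ph <- stats::runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  half <- n %/% 2
  for (k in 2:(half + 1)) spec[n - k + 2] <- Conj(spec[k])
  if (n %% 2 == 0) spec[half + 1] <- Mod(spec[half + 1])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic trial
#'
#' One 32-channel recording: 5-s baseline followed by a 60-s trial
#' segment.  Each channel is 1/f^beta background noise (RMS 10 uV) plus
#' band-limited oscillations; frontal channels carry alpha (RMS 4 uV) and
#' posterior channels beta and gamma (RMS 2 uV each).  During the trial
#' segment (not the baseline) the class effects multiply these
#' amplitudes: frontal alpha on the left by `valence_effect` for high
#' valence (on the right for low), posterior beta+gamma by
#' `arousal_effect` for high arousal.
#'
#' @param spec [synth_spec()].
#' @param label [emotion_label()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return [eeg_recording()], bit-identical for identical arguments.
#' @export
generate_trial <- function(spec, label, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"), inherits(label, "emotion_label"))
  .with_seed(seed, {
    fs <- spec$fs
    n_base <- round(spec$baseline_seconds * fs)
    n_trial <- round(spec$trial_seconds * fs)
    n <- n_base + n_trial
    chans <- canonical_channels()
    dat <- matrix(0, 32, n, dimnames = list(chans, NULL))
    trial_idx <- (n_base + 1L):n
    val_side <- if (label$valence_bin == "high") .LEFT_FRONTAL else .RIGHT_FRONTAL
    for (ch in chans) {
      x <- 10 * .pink_noise(n, spec$noise_exponent)
      if (ch %in% c(.LEFT_FRONTAL, .RIGHT_FRONTAL)) {
        osc <- 4 * .band_noise(n, fs, c(8, 12))
        gain <- if (ch %in% val_side) spec$valence_effect else 1
        osc[trial_idx] <- osc[trial_idx] * gain
        x <- x + osc
      }
      if (ch %in% .POSTERIOR) {
        osc <- 2 * .band_noise(n, fs, c(12, 30)) +
               2 * .band_noise(n, fs, c(30, 45))
        if (label$arousal_bin == "high")
          osc[trial_idx] <- osc[trial_idx] * spec$arousal_effect
        x <- x + osc
      }
      dat[ch, ] <- x
    }
    eeg_recording(dat, fs, chans, baseline_span = c(0L, n_base),
                  meta = list(quadrant = label$quadrant))
  })
}

.QUADRANT_LABELS <- list(
  HAHV = c(valence = "high", arousal = "high"),
  LAHV = c(valence = "high", arousal = "low"),
  HALV = c(valence = "low", arousal = "high"),
  LALV = c(valence = "low", arousal = "low"))

#' Generate a full synthetic dataset
#'
#' `n_participants x sum(trials_per_quadrant)` recordings with a random
#' per-participant gain (+/-20%) mimicking inter-subject scale
#' differences.  Deterministic under `spec$seed`: per-trial seeds are
#' derived from (seed, participant, trial), so the corpus does not depend
#' on evaluation order.
#'
#' @param spec [synth_spec()].
#' @return List with one element per trial, each a list with `recording`
#'   ([eeg_recording()]), `label` ([emotion_label()]), `participant` and
#'   `trial`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  out <- list()
  for (p in seq_len(spec$n_participants)) {
    gain <- .with_seed(.derive_seed(spec$seed, 7L, p),
                       stats::runif(1, 0.8, 1.2))
    t_i <- 0L
    for (q in names(spec$trials_per_quadrant)) {
      lab <- emotion_label(valence_bin = .QUADRANT_LABELS[[q]][["valence"]],
                           arousal_bin = .QUADRANT_LABELS[[q]][["arousal"]])
      for (k in seq_len(spec$trials_per_quadrant[[q]])) {
        t_i <- t_i + 1L
        rec <- generate_trial(spec, lab,
                              seed = .derive_seed(spec$seed, p, t_i))
        rec$data <- rec$data * gain
        rec$meta <- list(participant = p, trial = t_i, quadrant = q)
        out[[length(out) + 1L]] <-
          list(recording = rec, label = lab, participant = p, trial = t_i)
      }
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes each recording in the matrix+json dialect plus a JSON-lines
#' manifest (`labels.jsonl`: path, valence_bin, arousal_bin, participant,
#' trial).
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "labels.jsonl")
  con <- file(manifest, "w"); on.exit(close(con))
  for (item in dataset) {
    fn <- sprintf("p%02d_t%02d.tsv", item$participant, item$trial)
    write_recording(item$recording, file.path(dir, fn))
    writeLines(jsonlite::toJSON(
      list(path = fn, valence_bin = item$label$valence_bin,
           arousal_bin = item$label$arousal_bin,
           participant = item$participant, trial = item$trial),
      auto_unbox = TRUE), con)
  }
  invisible(manifest)
}

## evaluate expr under a temporary RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic small-integer seed from a tuple (kept below 2^31)
.derive_seed <- function(...) {
  vals <- as.numeric(c(...))
  Reduce(function(a, b) ((a * 48271 + (b + 1) * 10007 + 13) %% 2147483629),
         vals, accumulate = FALSE, init = 17)
}
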