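test_that("windowing emits only complete windows past the baseline", {
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(32 * fs * 65), 32), fs,
                       canonical_channels(), baseline_span = c(0L, 5L * fs))
  idx <- window_trial(rec)
  expect_identical(ncol(idx), 59L)          # 60-s trial -> 59 windows
  expect_identical(nrow(idx), 256L)
  ## starts at multiples of 1 s after the baseline
  expect_true(all((idx[1, ] - (5L * fs + 1L)) %% fs == 0))
  expect_true(all(idx > 5L * fs))           # baseline excluded

  rec2 <- eeg_recording(matrix(rnorm(32 * 2 * fs), 32), fs,
                        canonical_channels())
  expect_identical(ncol(window_trial(rec2)), 1L)   # exactly one window
  rec3 <- eeg_recording(matrix(rnorm(32 * 192), 32), fs,
                        canonical_channels())
  expect_error(window_trial(rec3), "shorter than one window")
})

test_that("band power concentrates in the right band and vanishes on silence", {
  fs <- 128
  x <- sin(2 * pi * 10 * (0:255) / fs)
  bands <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
                gamma = c(30, 45))
  bp <- vapply(bands, function(b) band_power(x, fs, b), 0)
  ## alpha holds >= 90% of the band mass
  expect_gt(bp["alpha"] / sum(bp), 0.9)
  expect_identical(band_power(numeric(256), fs, c(8, 12)), 0)
  expect_error(band_power(x, fs, c(60, 70)), "fs/2")
})

test_that("band power of white noise matches the flat-density oracle", {
  set.seed(99)
  x <- rnorm(4096)
  v <- var(x)
  ## flat one-sided density: var / (fs/2) per Hz at fs = 128
  for (b in list(c(4, 8), c(8, 12), c(12, 30), c(30, 45))) {
    expect_equal(band_power(x, 128, b), v / 64, tolerance = 0.2)
  }
})

test_that("band power scales quadratically with amplitude", {
  set.seed(3)
  x <- rnorm(512)
  expect_equal(band_power(3 * x, 128, c(8, 12)),
               9 * band_power(x, 128, c(8, 12)), tolerance = 1e-12)
})

test_that("statistical features match closed forms", {
  expect_identical(stat_features(rep(2, 10))$zcr, 0)
  expect_equal(stat_features(c(1, -1, 1, -1))$zcr, 0.75)
  s <- stat_features(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$std, 1)
  ## sgn(0) = 0: 0 contributes |1-0| + |0-(-1)| = half-crossings
  expect_equal(stat_features(c(1, 0, -1))$zcr, zcr_oracle(c(1, 0, -1)))
})

test_that("fractal dimension recovers line and noise benchmarks", {
  expect_equal(fractal_dimension(as.numeric(1:256)), 1, tolerance = 0.05)
  set.seed(11)
  expect_equal(fractal_dimension(rnorm(1024)), 2, tolerance = 0.15)
  expect_identical(fractal_dimension(rep(5, 256)), 1)
  expect_error(fractal_dimension(rnorm(20)), "kmax")
})

test_that("approximate entropy behaves on regular and irregular series", {
  expect_identical(approximate_entropy(rep(1, 64)), 0)
  x <- rep(c(1, 2), 4)
  expect_equal(approximate_entropy(x, m = 2, r = 0.5),
               apen_oracle(x, 2, 0.5), tolerance = 1e-9)
  set.seed(21)
  per <- sin(2 * pi * (0:255) / 16)
  noise <- rnorm(256, sd = stats::sd(per))
  expect_lte(approximate_entropy(per), approximate_entropy(noise))
})

test_that("correlation dimension recovers benchmark geometries", {
  expect_identical(correlation_dimension(rep(1, 64)), 0)
  x <- (1:256) / 256
  expect_equal(correlation_dimension(x, embed_m = 1), 1, tolerance = 0.1)
  set.seed(31)
  u <- runif(512)
  cd2 <- correlation_dimension(u, embed_m = 2)
  expect_gt(cd2, 1.5)
  expect_lte(cd2, 2.1)
})

test_that("nonlinear features are invariant under positive scaling", {
  set.seed(41)
  x <- rnorm(256)
  expect_equal(fractal_dimension(7 * x), fractal_dimension(x),
               tolerance = 1e-9)
  expect_equal(stat_features(7 * x)$zcr, stat_features(x)$zcr)
  ## ApEn with r proportional to sd is scale-free
  expect_equal(approximate_entropy(7 * x), approximate_entropy(x),
               tolerance = 1e-9)
})

test_that("baseline normalization clips to the baseline range", {
  base <- array(runif(4 * 2 * 10), c(4, 2, 10))
  raw <- base
  raw[1, , ] <- apply(base, c(2, 3), min)   # at baseline minimum -> 0
  raw[2, , ] <- apply(base, c(2, 3), max)   # at baseline maximum -> ~1
  raw[3, , ] <- apply(base, c(2, 3), max) + 1  # above -> clipped to 1
  out <- normalize_to_baseline(raw, base)
  expect_true(all(out[1, , ] == 0))
  expect_true(all(abs(out[2, , ] - 1) < 1e-9))
  expect_true(all(out[3, , ] == 1))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("a zero-signal trial yields zero power, std and zcr", {
  fs <- 128
  rec <- eeg_recording(matrix(0, 32, 10 * fs), fs, canonical_channels())
  ft <- extract_feature_tensor(rec, normalize = FALSE)
  for (fn in c("power_theta", "power_alpha", "power_beta", "power_gamma",
               "std", "zcr", "mean"))
    expect_true(all(ft$tensor[, , fn] == 0), info = fn)
  expect_true(all(ft$tensor[, , "fractal_dim"] == 1))   # degenerate branch
  expect_true(all(ft$tensor[, , "approx_entropy"] == 0))
  expect_true(all(ft$tensor[, , "corr_dim"] == 0))
})

test_that("the normalized tensor is finite, bounded and well-shaped", {
  spec <- synth_spec(seed = 7)
  rec <- generate_trial(spec, emotion_label("low", "high"), seed = 5)
  ft <- extract_feature_tensor(rec)
  expect_identical(dim(ft$tensor), c(59L, 32L, 10L))
  expect_true(all(is.finite(ft$tensor)))
  expect_true(all(ft$tensor >= 0 & ft$tensor <= 1))
  expect_identical(dimnames(ft$tensor)[[3]], feature_names())
})

test_that("feature tables round-trip through TSV", {
  spec <- synth_spec(trial_seconds = 6, seed = 7)
  rec <- generate_trial(spec, emotion_label("low", "low"), seed = 9)
  ft <- extract_feature_tensor(rec)
  path <- file.path(tempdir(), "feat.tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$tensor, ft$tensor, tolerance = 1e-12,
               ignore_attr = TRUE)
})
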