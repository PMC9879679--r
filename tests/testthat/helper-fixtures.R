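## Shared fixtures.  The heavy planted-effect pipeline (synthetic corpus,
## feature tensors, trained valence/arousal models) is built lazily once
## per test run and reused by the map and learnability tests.

.fix_env <- new.env(parent = emptyenv())

## small deterministic recording: mixture of sines + noise
make_test_recording <- function(fs = 128, seconds = 10, baseline_seconds = 0,
                                seed = 1) {
  set.seed(seed)
  n <- fs * seconds
  t <- (0:(n - 1)) / fs
  dat <- t(sapply(seq_len(32), function(ch)
    sin(2 * pi * (4 + ch %% 20) * t + ch) + 0.3 * rnorm(n)))
  eeg_recording(dat, fs, canonical_channels(),
                baseline_span = c(0L, as.integer(fs * baseline_seconds)))
}

## tensors for a planted-effect synthetic corpus, cached by key
planted_tensors <- function(key, n_part, tq, seed, effects, window_step = 1) {
  if (!is.null(.fix_env[[key]])) return(.fix_env[[key]])
  spec <- synth_spec(n_participants = n_part, trials_per_quadrant = tq,
                     valence_effect = effects, arousal_effect = effects,
                     seed = seed)
  ds <- generate_dataset(spec)
  tens <- lapply(ds, function(item)
    extract_feature_tensor(preprocess(item$recording), label = item$label,
                           window_step = window_step))
  .fix_env[[key]] <- tens
  tens
}

## fine-tune a model for one dimension on prepared tensors
fit_dimension <- function(tensors, dimension, cfg, pretrained,
                          labels = NULL, epochs = 20) {
  model <- saetm_model(pretrained, dimension, seed = cfg$seed)
  finetune(model, tensors, labels = labels, dimension = dimension,
           epochs = epochs, lr = 0.2, batch = 128, seed = cfg$seed)
}

## the study-scale pipeline: 200 training and 60 held-out trials at
## effect strength 3, with one fine-tuned model per emotion dimension.
## Training tensors use every 2nd (non-overlapping) window; evaluation
## tensors use the full 50%-overlap windowing.
planted_pipeline <- function() {
  if (!is.null(.fix_env$pipeline)) return(.fix_env$pipeline)
  train_t <- planted_tensors("train200", 5,
                             c(HAHV = 8, LAHV = 10, HALV = 10, LALV = 12),
                             seed = 101, effects = 3, window_step = 2)
  test_t <- planted_tensors("test60", 2,
                            c(HAHV = 8, LAHV = 8, HALV = 7, LALV = 7),
                            seed = 202, effects = 3, window_step = 2)
  cfg <- saetm_config(epochs = 40, lr = 0.5, batch = 32, seed = 11,
                      max_rows = 1000)
  pre <- pretrain_saetm(train_t, cfg)
  models <- lapply(c(valence = "valence", arousal = "arousal"), function(dm)
    fit_dimension(train_t, dm, cfg, pre))
  .fix_env$pipeline <- list(train = train_t, test = test_t,
                            pretrained = pre, models = models, config = cfg)
  .fix_env$pipeline
}

## small labelled tensors (short trials) for structural model tests
make_tiny_tensors <- function(n_per_class = 2, seed = 1) {
  key <- sprintf("tiny_%d_%d", n_per_class, seed)
  if (!is.null(.fix_env[[key]])) return(.fix_env[[key]])
  spec <- synth_spec(trial_seconds = 8, baseline_seconds = 4,
                     valence_effect = 2.5, arousal_effect = 2.5, seed = seed)
  labs <- list(emotion_label("low", "low"), emotion_label("low", "high"),
               emotion_label("high", "low"), emotion_label("high", "high"))
  tens <- list()
  for (k in seq_len(n_per_class)) {
    for (lab in labs) {
      rec <- generate_trial(spec, lab,
                            seed = seed + 100 * k + length(tens))
      tens[[length(tens) + 1L]] <-
        extract_feature_tensor(rec, label = lab)
    }
  }
  .fix_env[[key]] <- tens
  tens
}

## null-effect tensors (effects = 1), for contrast and chance controls
null_tensors <- function() {
  planted_tensors("null32", 1, c(HAHV = 8, LAHV = 8, HALV = 8, LALV = 8),
                  seed = 303, effects = 1, window_step = 2)
}

## seeded evaluation without disturbing the session RNG
.with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
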