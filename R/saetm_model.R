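## stack per-channel feature matrices and per-row labels from a list of
## feature tensors; rows are analysis windows
.stack_tensors <- function(tensors, dimension = NULL, labels = NULL) {
  stopifnot(length(tensors) >= 1)
  nch <- dim(tensors[[1]]$tensor)[2]
  if (is.null(labels) && !is.null(dimension)) {
    labels <- vapply(tensors, function(tt) {
      if (is.null(tt$label)) stop("tensor without a label")
      if (dimension == "valence") tt$label$valence_bin else tt$label$arousal_bin
    }, "")
  }
  Xs <- vector("list", nch)
  for (ch in seq_len(nch)) {
    Xs[[ch]] <- do.call(rbind, lapply(tensors, function(tt)
      matrix(tt$tensor[, ch, ], ncol = dim(tt$tensor)[3])))
  }
  nwin <- vapply(tensors, function(tt) dim(tt$tensor)[1], 0L)
  trial <- rep(seq_along(tensors), nwin)
  y <- if (is.null(labels)) NULL else rep(labels, nwin)
  list(X = Xs, y = y, trial = trial, trial_labels = labels)
}

#' Assemble a SAETM model from pretrained channel networks
#'
#' @param channel_saes List of 32 [build_channel_sae()] results in
#'   canonical channel order.
#' @param dimension `"valence"` or `"arousal"` -- the emotion dimension
#'   this binary model classifies.
#' @param seed Seed for the random initialization of the two-neuron
#'   output layer.
#' @return Object of class `saetm_model`: `channel_saes`, `out_beta`
#'   (2 x 32), `out_alpha` (2), `dimension`.
#' @export
saetm_model <- function(channel_saes, dimension = c("valence", "arousal"),
                        seed = 1) {
  dimension <- match.arg(dimension)
  if (length(channel_saes) != 32)
    stop("need exactly 32 channel networks, got ", length(channel_saes))
  out <- .with_seed(.derive_seed(seed, 4242L), {
    lim <- sqrt(6 / (32 + 2))
    list(beta = matrix(stats::runif(64, -lim, lim), 2, 32),
         alpha = numeric(2))
  })
  structure(list(channel_saes = channel_saes, out_beta = out$beta,
                 out_alpha = out$alpha, dimension = dimension,
                 finetuned = FALSE),
            class = "saetm_model")
}

#' @export
print.saetm_model <- function(x, ...) {
  w <- vapply(x$channel_saes, function(cs) paste(cs$widths, collapse = "-"), "")
  cat(sprintf("SAETM model (%s, %sfine-tuned): 32 channel SAEs + 2-neuron output\n",
              x$dimension, if (x$finetuned) "" else "not "))
  cat("  widths:", paste(utils::head(w, 4), collapse = ", "), "...\n")
  invisible(x)
}

## full forward pass: list of 32 batch x 10 matrices -> U (batch x 32),
## Y (batch x 2), plus per-channel hidden activations when keep = TRUE
.model_forward <- function(model, Xs, keep = FALSE) {
  n <- nrow(Xs[[1]])
  U <- matrix(0, n, 32)
  hid <- if (keep) vector("list", 32) else NULL
  for (ch in 1:32) {
    fw <- .channel_forward(model$channel_saes[[ch]], Xs[[ch]])
    U[, ch] <- fw$U
    if (keep) hid[[ch]] <- fw$hidden
  }
  Z <- sweep(U %*% t(model$out_beta), 2, model$out_alpha, `+`)
  list(U = U, Y = .sigmoid(Z), hidden = hid)
}

#' Fine-tune a SAETM model against binary emotion labels
#'
#' Supervised backpropagation through the whole network -- encoder
#' weights, one-neuron heads and the two-neuron output layer -- by
#' mini-batch SGD on the cross-entropy against one-hot targets (low =
#' (1,0), high = (0,1)).  Every analysis window of every trial is one
#' training row carrying its trial's label.
#'
#' @param model [saetm_model()].
#' @param tensors List of labelled `feature_tensor`s.
#' @param labels Optional character vector (`"low"`/`"high"`, one per
#'   tensor) overriding the tensor labels.
#' @param dimension Emotion dimension; defaults to the model's.
#' @param epochs,lr,batch SGD parameters.
#' @param seed Integer seed (shuffling order).
#' @return Fine-tuned model with attribute `loss_curve`.
#' @export
finetune <- function(model, tensors, labels = NULL, dimension = model$dimension,
                     epochs = 200, lr = 0.05, batch = 32, seed = 1) {
  stopifnot(inherits(model, "saetm_model"))
  st <- .stack_tensors(tensors, dimension, labels)
  if (length(unique(st$y)) < 2)
    stop("fine-tuning needs both label classes, got only: ",
         unique(st$y))
  Tmat <- cbind(as.numeric(st$y == "low"), as.numeric(st$y == "high"))
  n <- nrow(Tmat)
  losses <- numeric(epochs)
  .with_seed(.derive_seed(seed, 5L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1, n, by = batch)) {
        rows <- ord[s:min(s + batch - 1, n)]
        Xb <- lapply(st$X, function(x) x[rows, , drop = FALSE])
        fw <- .model_forward(model, Xb, keep = TRUE)
        Yc <- pmin(pmax(fw$Y, 1e-12), 1 - 1e-12)
        Tb <- Tmat[rows, , drop = FALSE]
        tot <- tot + sum(-Tb * log(Yc) - (1 - Tb) * log(1 - Yc))
        scale <- lr / length(rows)
        dZ <- fw$Y - Tb
        dU <- dZ %*% model$out_beta
        model$out_beta <- model$out_beta - scale * (t(dZ) %*% fw$U)
        model$out_alpha <- model$out_alpha - scale * colSums(dZ)
        for (ch in 1:32) {
          cs <- model$channel_saes[[ch]]
          hs <- fw$hidden[[ch]]
          nl <- length(cs$layers)
          u <- fw$U[, ch]
          dpre <- dU[, ch] * u * (1 - u)
          dmu <- drop(t(hs[[nl]]) %*% dpre)
          dh <- outer(dpre, cs$head_mu)
          cs$head_mu <- cs$head_mu - scale * dmu
          cs$head_bias <- cs$head_bias - scale * sum(dpre)
          for (l in nl:1) {
            h <- hs[[l]]
            dz <- dh * h * (1 - h)
            inp <- if (l == 1) Xb[[ch]] else hs[[l - 1]]
            dh <- dz %*% t(cs$layers[[l]]$W)
            cs$layers[[l]]$W <- cs$layers[[l]]$W - scale * (t(inp) %*% dz)
            cs$layers[[l]]$b <- cs$layers[[l]]$b - scale * colSums(dz)
          }
          model$channel_saes[[ch]] <- cs
        }
      }
      losses[ep] <- tot / n
      if (!is.finite(losses[ep]))
        stop("NaN/Inf fine-tuning loss; lower the learning rate")
    }
  })
  model$finetuned <- TRUE
  attr(model, "loss_curve") <- losses
  model
}

#' Predict the emotion bin of one trial
#'
#' Window-level two-neuron outputs are averaged over the trial's windows;
#' the larger mean wins.
#'
#' @param object [saetm_model()].
#' @param tensor `feature_tensor` of one trial.
#' @param ... Unused.
#' @return List: `bin` (`"low"`/`"high"`), `score` (mean two-neuron
#'   output, named).
#' @export
predict.saetm_model <- function(object, tensor, ...) {
  st <- .stack_tensors(list(tensor))
  fw <- .model_forward(object, st$X)
  sc <- colMeans(fw$Y)
  names(sc) <- c("low", "high")
  list(bin = if (sc["high"] > sc["low"]) "high" else "low", score = sc)
}

#' Per-channel abstracted map values for one trial
#'
#' The topographic map scalar of channel i is the mean over the trial's
#' windows of the channel head output `U_i = sigmoid(mu . h + bias)`.
#' When the tensor carries baseline-window features (the default from
#' [extract_feature_tensor()]), the value is referenced to the
#' pre-stimulus baseline: `0.5 + mean(U_trial) - mean(U_baseline)`,
#' clipped to (0, 1).  Referencing removes each head's arbitrary
#' operating point, so 0.5 means "no change from rest" on every channel
#' and left-right contrasts reflect event-related activation rather than
#' initialization offsets.
#'
#' @param model Fine-tuned [saetm_model()].
#' @param tensor `feature_tensor` of one trial.
#' @param reference `"auto"` (baseline-referenced when baseline features
#'   are present), `"baseline"` (require them) or `"none"` (raw head
#'   means).
#' @return Named numeric vector of 32 values in (0, 1), canonical order.
#' @export
channel_map_values <- function(model, tensor,
                               reference = c("auto", "baseline", "none")) {
  stopifnot(inherits(model, "saetm_model"))
  reference <- match.arg(reference)
  st <- .stack_tensors(list(tensor))
  fw <- .model_forward(model, st$X)
  u <- colMeans(fw$U)
  if (reference == "baseline" && is.null(tensor$baseline))
    stop("tensor carries no baseline-window features")
  if (reference != "none" && !is.null(tensor$baseline)) {
    bt <- structure(list(tensor = tensor$baseline, label = NULL,
                         meta = list()), class = "feature_tensor")
    stb <- .stack_tensors(list(bt))
    ub <- colMeans(.model_forward(model, stb$X)$U)
    u <- pmin(pmax(0.5 + u - ub, 0), 1)
  }
  stats::setNames(u, canonical_channels())
}

#' Pretrain all 32 channel stacks
#'
#' Greedy structural-loss pretraining on the pooled windows.  Pretraining
#' is unsupervised, so one set of channel stacks can seed the models of
#' both emotion dimensions.
#'
#' @param tensors List of `feature_tensor`s.
#' @param config [saetm_config()].
#' @return List of 32 [build_channel_sae()] results in canonical order.
#' @export
pretrain_saetm <- function(tensors, config = saetm_config()) {
  st <- .stack_tensors(tensors)
  chans <- canonical_channels()
  lapply(1:32, function(ch)
    build_channel_sae(st$X[[ch]], config, channel = chans[ch]))
}

#' Pretrain and fine-tune a SAETM model in one call
#'
#' Greedy structural-loss pretraining of all 32 channel stacks on the
#' pooled windows, followed by supervised fine-tuning.
#'
#' @param tensors List of labelled `feature_tensor`s.
#' @param dimension `"valence"` or `"arousal"`.
#' @param config [saetm_config()] for pretraining.
#' @param finetune_epochs,finetune_lr,finetune_batch Fine-tuning SGD
#'   parameters.
#' @param pretrained Optional result of [pretrain_saetm()] to reuse
#'   (pretraining is label-free and shared between dimensions).
#' @return Fine-tuned [saetm_model()].
#' @export
train_saetm <- function(tensors, dimension = c("valence", "arousal"),
                        config = saetm_config(), finetune_epochs = 200,
                        finetune_lr = 0.05, finetune_batch = 32,
                        pretrained = NULL) {
  dimension <- match.arg(dimension)
  saes <- if (is.null(pretrained)) pretrain_saetm(tensors, config)
          else pretrained
  model <- saetm_model(saes, dimension, seed = config$seed)
  finetune(model, tensors, dimension = dimension, epochs = finetune_epochs,
           lr = finetune_lr, batch = finetune_batch, seed = config$seed)
}

#' Thin the windows of a feature tensor
#'
#' Keeps every `step`-th analysis window.  Consecutive windows overlap by
#' half, so thinning the training rows trades little information for a
#' proportional cut in supervised training time; evaluation should use
#' the full tensor.
#'
#' @param tensor `feature_tensor`.
#' @param step Keep windows `1, 1+step, 1+2*step, ...`.
#' @return Thinned `feature_tensor`.
#' @export
thin_windows <- function(tensor, step = 2) {
  stopifnot(inherits(tensor, "feature_tensor"), step >= 1)
  keep <- seq(1, dim(tensor$tensor)[1], by = step)
  tensor$tensor <- tensor$tensor[keep, , , drop = FALSE]
  tensor
}

## ---- serialization ----------------------------------------------------

#' Save a SAETM model
#'
#' Writes `model.json` (architecture, dimension, widths) plus
#' `params.bin`, a flat little-endian double array of every parameter
#' tensor in a fixed order; the round trip is bit-exact.
#'
#' @param model [saetm_model()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_saetm <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- numeric(0)
  for (cs in model$channel_saes) {
    for (ly in cs$layers) params <- c(params, as.numeric(ly$W), ly$b, ly$c)
    params <- c(params, cs$head_mu, cs$head_bias)
  }
  params <- c(params, as.numeric(model$out_beta), model$out_alpha)
  manifest <- list(
    dimension = model$dimension, finetuned = model$finetuned,
    channels = vapply(model$channel_saes, function(cs) cs$channel, ""),
    widths = lapply(model$channel_saes, function(cs) cs$widths),
    n_params = length(params))
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "params.bin"), "wb")
  writeBin(params, con, size = 8, endian = "little")
  close(con)
  invisible(dir)
}

#' Load a SAETM model saved by [save_saetm()]
#'
#' @param dir Directory containing `model.json` and `params.bin`.
#' @return [saetm_model()].
#' @export
load_saetm <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "model.json"),
                                  simplifyVector = FALSE)
  manifest$channels <- unlist(manifest$channels)
  manifest$n_params <- as.integer(manifest$n_params)
  con <- file(file.path(dir, "params.bin"), "rb")
  params <- readBin(con, "double", n = manifest$n_params, size = 8,
                    endian = "little")
  close(con)
  pos <- 1L
  take <- function(k) {
    out <- params[pos:(pos + k - 1L)]
    pos <<- pos + as.integer(k)
    out
  }
  saes <- vector("list", length(manifest$channels))
  for (i in seq_along(saes)) {
    widths <- as.integer(unlist(manifest$widths[[i]]))
    n_in <- 10L
    layers <- list()
    for (l in seq_along(widths)) {
      m <- widths[l]
      layers[[l]] <- ae_layer(matrix(take(n_in * m), n_in, m), take(m),
                              take(n_in))
      n_in <- m
    }
    saes[[i]] <- structure(
      list(layers = layers, head_mu = take(n_in), head_bias = take(1),
           widths = widths, slf_curves = NULL,
           channel = manifest$channels[i]),
      class = "channel_sae")
  }
  model <- saetm_model(saes, manifest$dimension)
  model$out_beta <- matrix(take(64), 2, 32)
  model$out_alpha <- take(2)
  model$finetuned <- isTRUE(manifest$finetuned)
  model
}
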