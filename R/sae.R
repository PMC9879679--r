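#' Training configuration for the autoencoder stack
#'
#' @param epochs Pretraining epochs per autoencoder.
#' @param lr Learning rate for plain mini-batch SGD.
#' @param batch Mini-batch size.
#' @param seed Global seed; per-width/per-layer seeds are derived from it.
#' @param max_rows If finite, pretraining subsamples at most this many
#'   feature rows (deterministically) before width search and training --
#'   overlapping analysis windows are highly redundant, so this bounds
#'   runtime without changing what is learned.
#' @return List of class `saetm_config`.
#' @export
saetm_config <- function(epochs = 200, lr = 0.5, batch = 32, seed = 1,
                         max_rows = Inf) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch = as.integer(batch), seed = as.integer(seed),
                 max_rows = max_rows),
            class = "saetm_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Construct an autoencoder layer
#'
#' A tied-weight single-hidden-layer autoencoder: encoder
#' `h = sigmoid(x W + b)`, decoder `x' = sigmoid(h W^T + c)`.
#'
#' @param W Weight matrix `n_in x m_hidden`.
#' @param b Hidden bias, length `m_hidden`.
#' @param c Reconstruction bias, length `n_in`.
#' @return Object of class `ae_layer`.
#' @export
ae_layer <- function(W, b, c) {
  W <- as.matrix(W)
  stopifnot(length(b) == ncol(W), length(c) == nrow(W),
            ncol(W) >= 1, ncol(W) <= nrow(W))
  structure(list(W = W, b = as.numeric(b), c = as.numeric(c)),
            class = "ae_layer")
}

#' Encode through one autoencoder layer
#'
#' @param layer [ae_layer()].
#' @param x Numeric vector of length `n_in`, or a rows x `n_in` matrix.
#' @return Hidden activation(s) in (0, 1): vector of length `m_hidden` or
#'   a rows x `m_hidden` matrix.
#' @export
ae_encode <- function(layer, x) {
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != nrow(layer$W))
    stop("input has ", ncol(x), " features, layer expects ", nrow(layer$W))
  h <- .sigmoid(sweep(x %*% layer$W, 2, layer$b, `+`))
  if (vec) drop(h) else h
}

#' Reconstruct through one autoencoder layer
#'
#' `x' = sigmoid(sigmoid(x W + b) W^T + c)` with the tied transpose
#' decoder.
#'
#' @inheritParams ae_encode
#' @return Reconstruction(s) in (0, 1), same shape as `x`.
#' @export
ae_reconstruct <- function(layer, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  h <- ae_encode(layer, xm)
  xr <- .sigmoid(sweep(h %*% t(layer$W), 2, layer$c, `+`))
  if (vec) drop(xr) else xr
}

## squared-error reconstruction loss and its analytic gradient (tied
## weights: W receives both encoder and decoder contributions)
.ae_loss_grad <- function(layer, X) {
  z1 <- sweep(X %*% layer$W, 2, layer$b, `+`)
  h <- .sigmoid(z1)
  z2 <- sweep(h %*% t(layer$W), 2, layer$c, `+`)
  xr <- .sigmoid(z2)
  err <- xr - X
  loss <- sum(err^2)
  dz2 <- 2 * err * xr * (1 - xr)
  dW_dec <- t(dz2) %*% h
  dh <- dz2 %*% layer$W
  dz1 <- dh * h * (1 - h)
  list(loss = loss,
       dW = t(X) %*% dz1 + dW_dec,
       db = colSums(dz1),
       dc = colSums(dz2))
}

## deterministic Glorot-uniform init
.init_ae <- function(n_in, m_hidden, seed) {
  .with_seed(seed, {
    lim <- sqrt(6 / (n_in + m_hidden))
    ae_layer(matrix(stats::runif(n_in * m_hidden, -lim, lim), n_in, m_hidden),
             numeric(m_hidden), numeric(n_in))
  })
}

#' Train one tied-weight autoencoder
#'
#' Mini-batch stochastic gradient descent on the summed squared
#' reconstruction error.  Deterministic under `seed` (initialization and
#' batch shuffling both derive from it).
#'
#' @param X Rows x `n_in` matrix with entries in `[0, 1]`.
#' @param m_hidden Hidden width, `1 <= m_hidden <= n_in`.
#' @param epochs,lr,batch SGD parameters.
#' @param seed Integer seed.
#' @return [ae_layer()] with attribute `loss_curve` (full-data loss per
#'   epoch, including epoch 0 = after initialization).
#' @export
train_ae <- function(X, m_hidden, epochs = 200, lr = 0.5, batch = 32,
                     seed = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, m_hidden >= 1, m_hidden <= ncol(X))
  layer <- .init_ae(ncol(X), m_hidden, .derive_seed(seed, 1L))
  n <- nrow(X)
  losses <- numeric(epochs)
  .with_seed(.derive_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch)) {
        rows <- ord[s:min(s + batch - 1, n)]
        g <- .ae_loss_grad(layer, X[rows, , drop = FALSE])
        if (!is.finite(g$loss))
          stop("NaN/Inf training loss; lower the learning rate (lr = ",
               lr, ")")
        scale <- lr / length(rows)
        layer$W <- layer$W - scale * g$dW
        layer$b <- layer$b - scale * g$db
        layer$c <- layer$c - scale * g$dc
      }
      losses[ep] <- sum((ae_reconstruct(layer, X) - X)^2)
    }
  })
  attr(layer, "loss_curve") <- losses
  layer
}

#' Structural loss function
#'
#' `SLF = w1 (1 - rho1)^2 + (1 - w1)(1 - rho2)^2` where `rho1` is the
#' Pearson and `rho2` the Spearman rank correlation between the flattened
#' matched entries of the input matrix and its reconstruction.  0 iff both
#' correlations equal 1; at most 4.
#'
#' @param Dx,Dz Equal-shaped numeric matrices with at least 3 entries.
#' @param omega1 Pearson weight in `[0, 1]`.
#' @return Scalar in `[0, 4]`.
#' @export
slf <- function(Dx, Dz, omega1 = 0.5) {
  stopifnot(all(dim(as.matrix(Dx)) == dim(as.matrix(Dz))),
            length(Dx) >= 3, omega1 >= 0, omega1 <= 1)
  x <- as.numeric(Dx); z <- as.numeric(Dz)
  if (stats::sd(x) == 0 || stats::sd(z) == 0)
    stop("correlation undefined: zero variance in input or reconstruction")
  rho1 <- stats::cor(x, z)
  rho2 <- stats::cor(x, z, method = "spearman")
  omega1 * (1 - rho1)^2 + (1 - omega1) * (1 - rho2)^2
}

#' Choose a hidden width by structural loss
#'
#' Trains one autoencoder per candidate width (each with a seed derived
#' from the configuration seed and the width), scores each by
#' `slf(X, reconstruction)` and returns the argmin; ties break toward the
#' smaller width.
#'
#' @param X Rows x `n_in` matrix in `[0, 1]`.
#' @param widths Candidate hidden widths (each `<= ncol(X)`).
#' @param config [saetm_config()].
#' @param slf_tol Numerical tie resolution: all widths whose SLF lies
#'   within `slf_tol` of the minimum are treated as tied and the smallest
#'   wins.  SLF differences below the training noise floor carry no
#'   structure, and the procedure seeks the smallest adequate width.
#' @return List: `best_width`, `slf_curve` (one value per candidate, in
#'   the order of `sort(widths)`), `widths`, and `best_layer` (the trained
#'   [ae_layer()] at the chosen width).
#' @export
select_width <- function(X, widths, config = saetm_config(),
                         slf_tol = 1e-3) {
  stopifnot(length(widths) >= 1, all(widths >= 1), all(widths <= ncol(X)))
  widths <- sort(unique(as.integer(widths)))
  layers <- vector("list", length(widths))
  curve <- numeric(length(widths))
  for (i in seq_along(widths)) {
    layers[[i]] <- train_ae(X, widths[i], epochs = config$epochs,
                            lr = config$lr, batch = config$batch,
                            seed = .derive_seed(config$seed, widths[i]))
    curve[i] <- slf(X, ae_reconstruct(layers[[i]], X))
  }
  best <- which(curve <= min(curve) + slf_tol)[1]  # ties -> smaller width
  list(best_width = widths[best], slf_curve = curve, widths = widths,
       best_layer = layers[[best]])
}

## deterministic row subsample honoring config$max_rows
.subsample_rows <- function(X, config, tag) {
  n <- nrow(X)
  if (!is.finite(config$max_rows) || n <= config$max_rows) return(X)
  keep <- .with_seed(.derive_seed(config$seed, 3L, tag),
                     sort(sample.int(n, config$max_rows)))
  X[keep, , drop = FALSE]
}

#' Build one channel's stacked autoencoder
#'
#' Greedy layerwise pretraining with structural-loss width selection: for
#' each of three hidden layers the candidate widths are `1..w` where `w`
#' is the current input width, the best-SLF autoencoder is kept, and its
#' code becomes the next layer's input.  Widths never increase along the
#' stack.  A randomly initialized one-neuron head (weights over the last
#' code, scalar bias) is attached for later supervised fine-tuning.
#'
#' @param X_channel Windows x 10 matrix of normalized features in
#'   `[0, 1]`.
#' @param config [saetm_config()].
#' @param n_layers Number of hidden layers in the stack.
#' @param channel Channel name stored on the result (also seeds the
#'   layer-specific RNG streams).
#' @return Object of class `channel_sae`: list with `layers` (list of
#'   [ae_layer()]), `head_mu`, `head_bias`, `widths`, `slf_curves`,
#'   `channel`.
#' @export
build_channel_sae <- function(X_channel, config = saetm_config(),
                              n_layers = 3, channel = "") {
  X <- .subsample_rows(as.matrix(X_channel), config,
                       .derive_seed(0L, utf8ToInt(paste0("x", channel))))
  stopifnot(ncol(X) >= 1)
  ch_seed <- .derive_seed(config$seed, utf8ToInt(paste0("c", channel)))
  layers <- list(); widths <- integer(); curves <- list()
  cur <- X
  for (l in seq_len(n_layers)) {
    cfg_l <- config
    cfg_l$seed <- .derive_seed(ch_seed, l)
    sel <- select_width(cur, seq_len(ncol(cur)), cfg_l)
    layers[[l]] <- sel$best_layer
    widths[l] <- sel$best_width
    curves[[l]] <- sel$slf_curve
    cur <- ae_encode(sel$best_layer, cur)
  }
  head <- .with_seed(.derive_seed(ch_seed, 99L), {
    lim <- sqrt(6 / (widths[n_layers] + 1))
    list(mu = stats::runif(widths[n_layers], -lim, lim), bias = 0)
  })
  structure(list(layers = layers, head_mu = head$mu, head_bias = head$bias,
                 widths = widths, slf_curves = curves, channel = channel),
            class = "channel_sae")
}

#' @export
print.channel_sae <- function(x, ...) {
  cat(sprintf("channel SAE [%s]: widths %s -> 1-neuron head\n",
              x$channel, paste(x$widths, collapse = " ")))
  invisible(x)
}

## encoder-only forward pass through a channel SAE; returns list of all
## hidden activations plus the head output U (batch vectors)
.channel_forward <- function(csae, X) {
  hs <- vector("list", length(csae$layers))
  cur <- X
  for (l in seq_along(csae$layers)) {
    cur <- ae_encode(csae$layers[[l]], cur)
    hs[[l]] <- cur
  }
  U <- .sigmoid(drop(cur %*% csae$head_mu) + csae$head_bias)
  list(hidden = hs, U = U)
}
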