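#' Classification metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TN+TP)/total`, F1 `2PR/(P+R)`.  A zero denominator makes the
#' corresponding metric undefined and raises an error naming it.
#'
#' @param counts Named list or vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named list `precision`, `recall`, `accuracy`, `f1`.
#' @export
metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("undefined metrics: empty confusion counts")
  if (tp + fp == 0) stop("undefined precision: TP + FP == 0")
  if (tp + fn == 0) stop("undefined recall: TP + FN == 0")
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0) stop("undefined f1: precision + recall == 0")
  list(precision = p, recall = r, accuracy = (tn + tp) / total,
       f1 = 2 * p * r / (p + r))
}

#' Confusion counts of binary predictions
#'
#' @param truth,pred Vectors of labels; `positive` names the positive
#'   class.
#' @return Named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = "high") {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == positive & pred == positive),
       FP = sum(truth != positive & pred == positive),
       TN = sum(truth != positive & pred != positive),
       FN = sum(truth == positive & pred != positive))
}

#' Balanced k-fold test index sets
#'
#' Shuffles `1..n` deterministically and partitions it into `k` folds
#' whose sizes differ by at most one (the first `n %% k` folds take the
#' extra element).
#'
#' @param n Number of items (`n >= k`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` disjoint integer vectors covering `1..n`.
#' @export
kfold_indices <- function(n, k = 10, seed = 1) {
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  ord <- .with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(i) sort(ord[starts[i]:ends[i]]))
}

#' Output size of a convolution or pooling stage
#'
#' `floor((M + 2P - k) / s) + 1`.
#'
#' @param M Input size.
#' @param k Kernel size.
#' @param P Zero padding.
#' @param s Stride.
#' @return Integer output size (error if below 1).
#' @export
conv_out_size <- function(M, k, P = 0, s = 1) {
  out <- (M + 2 * P - k) %/% s + 1
  if (out < 1) stop("kernel/stride exceed the padded input (output size ",
                    out, ")")
  as.integer(out)
}

#' Map-classifier hyperparameters
#'
#' Two 3x3 convolution blocks (8 then 16 filters, sigmoid), each followed
#' by 2x2 max pooling (stride 2), a dense sigmoid layer of 32 units and a
#' softmax output; trained with RMSprop.
#'
#' @param epochs Training epochs.
#' @param learning_rate RMSprop step size.
#' @param rms_beta RMSprop decay.
#' @param batch Mini-batch size.
#' @param input_res Input grid resolution (square).
#' @param conv_filters Two filter counts.
#' @param dense_units Dense layer width.
#' @return List of class `cnn_spec`.
#' @export
cnn_spec <- function(epochs = 10, learning_rate = 0.001, rms_beta = 0.9,
                     batch = 2, input_res = 64, conv_filters = c(8, 16),
                     dense_units = 32) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 rms_beta = rms_beta, batch = as.integer(batch),
                 input_res = as.integer(input_res),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 conv_stride = 1L, pool_stride = 2L, pool = 2L, kernel = 3L),
            class = "cnn_spec")
}

## ---- small CNN in plain R (im2col convolutions) -----------------------

## precomputed geometry for one conv layer: linear gather indices turning
## an (h x w x cin) input into an (out_h*out_w) x (9*cin) patch matrix
.conv_geom <- function(h, w, cin, k = 3L) {
  oh <- h - k + 1L; ow <- w - k + 1L
  base <- outer(0:(k - 1L), 0:(k - 1L) * h, `+`)          # within-patch
  start <- outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`)  # patch origins
  idx0 <- outer(as.vector(start), as.vector(base), `+`)   # (oh*ow) x 9
  plane <- h * w
  idx <- do.call(cbind, lapply(seq_len(cin) - 1L, function(c) idx0 + c * plane))
  storage.mode(idx) <- "integer"
  list(idx = idx, oh = oh, ow = ow)
}

## max-pool 2x2 stride 2 over (h x w x c) flattened input; returns pooled
## values and argmax linear indices
.pool_geom <- function(h, w, cpl) {
  oh <- h %/% 2L; ow <- w %/% 2L
  or_ <- outer(seq(1L, 2L * oh, by = 2L), (seq(1L, 2L * ow, by = 2L) - 1L) * h,
               `+`)
  offs <- c(0L, 1L, h, h + 1L)
  idx0 <- outer(as.vector(or_), offs, `+`)                # (oh*ow) x 4
  plane <- h * w
  idx <- do.call(rbind, lapply(seq_len(cpl) - 1L,
                               function(c) idx0 + c * plane))
  storage.mode(idx) <- "integer"
  list(idx = idx, oh = oh, ow = ow)
}

.init_cnn <- function(spec, n_class, seed) {
  .with_seed(seed, {
    k2 <- spec$kernel^2
    f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
    r1 <- conv_out_size(spec$input_res, spec$kernel)
    p1 <- r1 %/% 2L
    r2 <- conv_out_size(p1, spec$kernel)
    p2 <- r2 %/% 2L
    nflat <- p2 * p2 * f2
    gl <- function(nin, nout) matrix(stats::runif(nin * nout,
                                                  -sqrt(6 / (nin + nout)),
                                                  sqrt(6 / (nin + nout))),
                                     nin, nout)
    list(W1 = gl(k2, f1), b1 = numeric(f1),
         W2 = gl(k2 * f1, f2), b2 = numeric(f2),
         W3 = gl(nflat, spec$dense_units), b3 = numeric(spec$dense_units),
         W4 = gl(spec$dense_units, n_class), b4 = numeric(n_class),
         geom1 = .conv_geom(spec$input_res, spec$input_res, 1L),
         geomp1 = .pool_geom(r1, r1, f1),
         geom2 = .conv_geom(p1, p1, f1),
         geomp2 = .pool_geom(r2, r2, f2),
         dims = list(r1 = r1, p1 = p1, r2 = r2, p2 = p2, nflat = nflat))
  })
}

## forward one image (flattened input vector); returns activations needed
## for backprop
.cnn_forward <- function(net, x) {
  C1 <- x[net$geom1$idx]
  dim(C1) <- c(nrow(net$geom1$idx), ncol(net$geom1$idx))
  A1 <- .sigmoid(sweep(C1 %*% net$W1, 2, net$b1, `+`))    # (r1*r1) x f1
  v1 <- as.vector(A1)
  pm1 <- v1[net$geomp1$idx]
  dim(pm1) <- dim(net$geomp1$idx)
  am1 <- max.col(pm1, ties.method = "first")
  arg1 <- net$geomp1$idx[cbind(seq_len(nrow(pm1)), am1)]
  P1 <- v1[arg1]                                          # pooled, ch-major
  C2 <- P1[net$geom2$idx]
  dim(C2) <- c(nrow(net$geom2$idx), ncol(net$geom2$idx))
  A2 <- .sigmoid(sweep(C2 %*% net$W2, 2, net$b2, `+`))
  v2 <- as.vector(A2)
  pm2 <- v2[net$geomp2$idx]
  dim(pm2) <- dim(net$geomp2$idx)
  am2 <- max.col(pm2, ties.method = "first")
  arg2 <- net$geomp2$idx[cbind(seq_len(nrow(pm2)), am2)]
  P2 <- v2[arg2]
  H <- .sigmoid(drop(P2 %*% net$W3) + net$b3)
  Z <- drop(H %*% net$W4) + net$b4
  ez <- exp(Z - max(Z))
  Y <- ez / sum(ez)
  list(C1 = C1, A1 = A1, arg1 = arg1, P1 = P1, C2 = C2, A2 = A2,
       arg2 = arg2, P2 = P2, H = H, Y = Y)
}

## backward pass for one image; returns parameter gradients
.cnn_backward <- function(net, x, fw, target) {
  dZ <- fw$Y - target
  dW4 <- outer(fw$H, dZ)
  dH <- drop(net$W4 %*% dZ) * fw$H * (1 - fw$H)
  dW3 <- outer(fw$P2, dH)
  dP2 <- drop(net$W3 %*% dH)
  ## unpool 2: route gradient to argmax positions of the conv-2 volume
  dv2 <- numeric(length(fw$A2))
  dv2[fw$arg2] <- dP2
  dA2 <- matrix(dv2, nrow(fw$A2), ncol(fw$A2))
  dC2pre <- dA2 * fw$A2 * (1 - fw$A2)
  dW2 <- t(fw$C2) %*% dC2pre
  db2 <- colSums(dC2pre)
  dCol2 <- dC2pre %*% t(net$W2)                           # patches x (9*f1)
  dP1 <- numeric(length(fw$P1))
  idx2 <- net$geom2$idx
  for (j in seq_len(ncol(idx2)))
    dP1[idx2[, j]] <- dP1[idx2[, j]] + dCol2[, j]
  dv1 <- numeric(length(fw$A1))
  dv1[fw$arg1] <- dP1
  dA1 <- matrix(dv1, nrow(fw$A1), ncol(fw$A1))
  dC1pre <- dA1 * fw$A1 * (1 - fw$A1)
  list(W1 = t(fw$C1) %*% dC1pre, b1 = colSums(dC1pre),
       W2 = dW2, b2 = db2, W3 = dW3, b3 = dH,
       W4 = dW4, b4 = dZ)
}

## one RMSprop update over accumulated gradients
.rms_update <- function(net, grads, cache, spec, n) {
  for (p in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    g <- grads[[p]] / n
    cache[[p]] <- spec$rms_beta * cache[[p]] + (1 - spec$rms_beta) * g^2
    net[[p]] <- net[[p]] - spec$learning_rate * g / (sqrt(cache[[p]]) + 1e-8)
  }
  list(net = net, cache = cache)
}

.cnn_fit <- function(imgs, y_int, n_class, spec, seed) {
  net <- .init_cnn(spec, n_class, .derive_seed(seed, 11L))
  cache <- lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                  function(p) p * 0)
  n <- length(imgs)
  eye <- diag(n_class)
  losses <- numeric(spec$epochs)
  .with_seed(.derive_seed(seed, 12L), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1, n, by = spec$batch)) {
        rows <- ord[s:min(s + spec$batch - 1, n)]
        grads <- NULL
        for (i in rows) {
          fw <- .cnn_forward(net, imgs[[i]])
          tgt <- eye[y_int[i], ]
          tot <- tot - log(max(fw$Y[y_int[i]], 1e-12))
          g <- .cnn_backward(net, imgs[[i]], fw, tgt)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g)
        }
        upd <- .rms_update(net, grads, cache, spec, length(rows))
        net <- upd$net; cache <- upd$cache
      }
      losses[ep] <- tot / n
    }
  })
  attr(net, "loss_curve") <- losses
  net
}

.cnn_predict <- function(net, imgs) {
  vapply(imgs, function(x) which.max(.cnn_forward(net, x)$Y), 0L)
}

## stratified fold assignment: per class, items are dealt round-robin
## across folds in a seeded shuffled order
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- .with_seed(.derive_seed(seed, 21L, match(cl, unique(y))),
                      sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the map classifier and score class separability
#'
#' Trains the small CNN of [cnn_spec()] on map grids (never on rendered
#' PNG pixels) and returns per-fold held-out accuracy, the paper-style
#' instrument for quantifying how distinguishable two or more groups of
#' topographic maps are.
#'
#' @param maps List of `topo_map` objects or numeric grid matrices.
#' @param labels Class label per map (>= 2 classes, >= 10 maps per
#'   class).
#' @param spec [cnn_spec()].
#' @param split `"holdout"` (single stratified 75/25 split) or `"kfold"`
#'   (stratified k folds).
#' @param k Folds when `split = "kfold"`.
#' @param seed Integer seed.
#' @return List: `fold_accuracy` (numeric vector), `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
train_map_cnn <- function(maps, labels, spec = cnn_spec(),
                          split = c("holdout", "kfold"), k = 10, seed = 1) {
  split <- match.arg(split)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 map classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 maps")
  imgs <- lapply(maps, function(m) {
    g <- if (inherits(m, "topo_map")) map_grid_matrix(m, spec$input_res)
         else as.matrix(m)
    if (!all(dim(g) == spec$input_res))
      stop("map grid is ", paste(dim(g), collapse = "x"),
           ", spec expects ", spec$input_res)
    as.numeric(g)
  })
  y_int <- match(labels, classes)
  nfold <- if (split == "holdout") 4L else as.integer(k)
  fold <- .stratified_folds(labels, nfold, seed)
  test_folds <- if (split == "holdout") 1L else seq_len(nfold)
  acc <- numeric(length(test_folds))
  for (fi in seq_along(test_folds)) {
    te <- fold == test_folds[fi]
    net <- .cnn_fit(imgs[!te], y_int[!te], length(classes), spec,
                    .derive_seed(seed, 31L, fi))
    pred <- .cnn_predict(net, imgs[te])
    acc[fi] <- mean(pred == y_int[te])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc))
}

#' Compare SAETM maps against all ten single-feature maps
#'
#' Runs the map classifier on each of the ten single-feature map sets and
#' on the SAETM map set (same classes, same resolution) and tabulates
#' mean and sd accuracy -- the quantitative map-distinctiveness
#' comparison.
#'
#' @param feature_maps Named list of 10 map sets (each a list of
#'   `topo_map`/grids), one per feature.
#' @param saetm_maps SAETM map set.
#' @param labels Class label per map (shared across sets).
#' @param spec [cnn_spec()].
#' @param split,k,seed Passed to [train_map_cnn()].
#' @param max_maps If finite, use only the first `max_maps` maps of every
#'   set (time-course analyses).
#' @return Data frame with one row per method (10 features + SAETM):
#'   `method`, `mean_acc`, `sd_acc`.
#' @export
compare_map_methods <- function(feature_maps, saetm_maps, labels,
                                spec = cnn_spec(), split = "holdout",
                                k = 10, seed = 1, max_maps = Inf) {
  stopifnot(length(feature_maps) == 10)
  sets <- c(feature_maps, list(SAETM = saetm_maps))
  keep <- seq_len(min(length(labels), max_maps))
  rows <- lapply(names(sets), function(nm) {
    res <- train_map_cnn(sets[[nm]][keep], labels[keep], spec, split, k,
                         seed = .derive_seed(seed, 41L, match(nm, names(sets))))
    data.frame(method = nm, mean_acc = res$mean_accuracy,
               sd_acc = res$sd_accuracy)
  })
  do.call(rbind, rows)
}

#' Write a metrics report as JSON
#'
#' @param table Data frame from [compare_map_methods()] or any metrics
#'   table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(table, path) {
  jsonlite::write_json(table, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
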