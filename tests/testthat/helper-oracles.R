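## Independent literal-formula oracles, written as direct O(N^2) loops so
## they share no code path with the package implementations.

zcr_oracle <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in 2:n) acc <- acc + abs(sign(x[i]) - sign(x[i - 1]))
  acc / (2 * n)
}

apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    logs <- numeric(nv)
    for (i in 1:nv) {
      cnt <- 0
      for (j in 1:nv) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nv)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

higuchi_oracle <- function(x, kmax) {
  n <- length(x)
  logl <- c(); logk <- c()
  for (k in 1:kmax) {
    ls <- c()
    for (m in 1:k) {
      np <- floor((n - m) / k)
      if (np < 1) next
      s <- 0
      for (i in 1:np) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      ls <- c(ls, s * (n - 1) / (np * k) / k)
    }
    if (!length(ls) || sum(ls) <= 0) next
    logl <- c(logl, log(mean(ls)))
    logk <- c(logk, log(1 / k))
  }
  unname(stats::coef(stats::lm(logl ~ logk))[2])
}

corrdim_oracle <- function(x, embed_m, delay, n_eps = 10) {
  n <- length(x)
  nv <- n - (embed_m - 1) * delay
  emb <- sapply(0:(embed_m - 1), function(t) x[(1:nv) + t * delay])
  d <- numeric(nv * (nv - 1) / 2)
  p <- 0L
  for (i in 1:(nv - 1)) {
    for (j in (i + 1):nv) {
      p <- p + 1L
      d[p] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
    }
  }
  np <- length(d)
  ds <- sort(d)
  lo <- ds[floor(0.05 * (np - 1)) + 1]
  hi <- ds[floor(0.50 * (np - 1)) + 1]
  if (!(hi > lo) || lo <= 0) return(0)
  le <- c(); lc <- c()
  for (g in 0:(n_eps - 1)) {
    eps <- exp(log(lo) + (log(hi) - log(lo)) * g / (n_eps - 1))
    cnt <- sum(d < eps)
    if (cnt == 0) next
    le <- c(le, log(eps))
    lc <- c(lc, log(cnt / np))
  }
  sl <- unname(stats::coef(stats::lm(lc ~ le))[2])
  max(sl, 0)
}

## direct (single-periodogram) spectral mass oracle used for filter and
## band-power checks
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  nf <- n %/% 2 + 1
  list(freq = (0:(nf - 1)) * fs / n, power = p[1:nf])
}

## literal confusion counting
confusion_oracle <- function(truth, pred, positive) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1
    if (truth[i] != positive && pred[i] == positive) fp <- fp + 1
    if (truth[i] != positive && pred[i] != positive) tn <- tn + 1
    if (truth[i] == positive && pred[i] != positive) fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

## naive valid convolution, for the conv_out_size shape oracle
conv2d_oracle <- function(img, kern, stride = 1) {
  M <- nrow(img); k <- nrow(kern)
  out_pos <- seq(1, M - k + 1, by = stride)
  out <- matrix(0, length(out_pos), length(out_pos))
  for (a in seq_along(out_pos)) {
    for (b in seq_along(out_pos)) {
      i <- out_pos[a]; j <- out_pos[b]
      out[a, b] <- sum(img[i:(i + k - 1), j:(j + k - 1)] * kern)
    }
  }
  out
}
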