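# Independent brute-force oracles for the entropy estimators. These are
# deliberately written as plain double loops / explicit enumerations, sharing
# no code with the package implementations they check.

oracle_pe <- function(x, m = 3, tau = 1) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- character(n_pat)
  for (i in seq_len(n_pat)) {
    win <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(rank(win, ties.method = "first"), collapse = "-")
  }
  p <- as.numeric(table(pats)) / n_pat
  -sum(p * log(p))
}

oracle_shannon <- function(x, n_bins = 100) {
  if (min(x) == max(x)) return(0)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (v in x) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

oracle_spe <- function(x, rate, n_comp = 100) {
  n <- length(x)
  if (all(x == 0)) return(0)
  pw <- Mod(fft(x))^2 / n
  nf <- floor(n / 2) + 1
  acc <- numeric(n_comp)
  for (i in seq_len(nf)) {
    f_hz <- (i - 1) / n * rate
    b <- if (f_hz == 0) 1 else min(n_comp, max(1, ceiling(f_hz / (rate / 2) * n_comp)))
    acc[b] <- acc[b] + pw[i]
  }
  p <- acc / sum(acc)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_apen <- function(x, m = 2, r, tau = 1) {
  phi <- function(mm) {
    nt <- length(x) - (mm - 1) * tau
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- 0
        for (k in 0:(mm - 1)) {
          d <- max(d, abs(x[i + k * tau] - x[j + k * tau]))
        }
        if (d <= r) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m = 2, r, tau = 1) {
  nt <- length(x) - m * tau
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- 0
      for (k in 0:(m - 1)) d <- max(d, abs(x[i + k * tau] - x[j + k * tau]))
      if (d <= r) {
        B <- B + 1
        if (max(d, abs(x[i + m * tau] - x[j + m * tau])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_svd <- function(x, order = 3, tau = 1) {
  if (all(x == 0)) return(0)
  n_rows <- length(x) - (order - 1) * tau
  Y <- matrix(0, n_rows, order)
  for (i in seq_len(n_rows)) {
    for (j in seq_len(order)) Y[i, j] <- x[i + (j - 1) * tau]
  }
  ev <- eigen(t(Y) %*% Y, symmetric = TRUE, only.values = TRUE)$values
  sv <- sqrt(pmax(ev, 0))
  p <- sv / sum(sv)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# run `code` under a fixed seed (test-local convenience)
withr_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# a tone sampled at `rate` Hz for `n` samples
tone <- function(freq, n, rate, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / rate + phase)
}

# broadband test signal: pink-ish background the decomposition tests share
broadband <- function(n, seed = 1) {
  as.vector(gen_background(
    synth_config(rate = 256, duration_s = n / 256, seed = seed)
  )$samples)
}
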