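#' Entropy estimator configuration
#'
#' Parameters of the six entropy features. Defaults follow common EEG usage:
#' permutation order 3 with delay 1; approximate entropy with embedding 2,
#' similarity radius 0.15 x sd, delay 1; sample entropy with embedding 2,
#' radius 0.2 x sd, delay 1; SVD entropy with embedding order 3, delay 1; and
#' 100 aggregated spectral components for spectral entropy.
#'
#' Logarithm bases differ by definition and are documented per estimator:
#' permutation, spectral, approximate and sample entropy use the natural log
#' (nats); Shannon and SVD entropy use log2 (bits).
#'
#' @param pe_order,pe_delay Permutation-entropy ordinal pattern order (>= 2)
#'   and delay.
#' @param apen_m,apen_r,apen_tau Approximate-entropy embedding dimension,
#'   similarity radius as a fraction of the series' standard deviation, and
#'   delay.
#' @param saen_m,saen_r,saen_tau Sample-entropy embedding dimension, radius
#'   fraction, and delay.
#' @param svd_order,svd_delay SVD-entropy embedding order (>= 2) and delay.
#' @param spe_f Number of equal-width spectral components up to the Nyquist
#'   frequency for spectral entropy.
#' @param she_bins Number of equal-width amplitude histogram bins for Shannon
#'   entropy.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(pe_order = 3L, pe_delay = 1L,
                           apen_m = 2L, apen_r = 0.15, apen_tau = 1L,
                           saen_m = 2L, saen_r = 0.2, saen_tau = 1L,
                           svd_order = 3L, svd_delay = 1L,
                           spe_f = 100L, she_bins = 100L) {
  stopifnot(pe_order >= 2, svd_order >= 2, apen_m >= 1, saen_m >= 1,
            pe_delay >= 1, apen_tau >= 1, saen_tau >= 1, svd_delay >= 1,
            apen_r > 0, saen_r > 0, spe_f >= 1, she_bins >= 1)
  structure(
    list(pe_order = as.integer(pe_order), pe_delay = as.integer(pe_delay),
         apen_m = as.integer(apen_m), apen_r = apen_r,
         apen_tau = as.integer(apen_tau),
         saen_m = as.integer(saen_m), saen_r = saen_r,
         saen_tau = as.integer(saen_tau),
         svd_order = as.integer(svd_order), svd_delay = as.integer(svd_delay),
         spe_f = as.integer(spe_f), she_bins = as.integer(she_bins)),
    class = "entropy_config"
  )
}

#' Permutation entropy
#'
#' Orders each delay vector of `pe_order` consecutive (lagged) values into an
#' ordinal pattern, ties broken by temporal order of occurrence, and returns
#' the Shannon entropy (natural log) of the pattern relative frequencies.
#' Invariant to strictly monotone amplitude transforms.
#'
#' @param x Numeric vector of length > `(pe_order - 1) * pe_delay + 1`.
#' @param cfg An [entropy_config()].
#' @return Permutation entropy in nats (0 for a strictly monotone series).
#' @export
permutation_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$pe_order
  tau <- cfg$pe_delay
  n <- length(x)
  n_pat <- n - (m - 1L) * tau
  if (n_pat < 1) abort("series too short for the requested permutation order/delay.")
  offsets <- seq.int(0L, by = tau, length.out = m)
  emb <- vapply(offsets, function(o) x[seq_len(n_pat) + o], numeric(n_pat))
  emb <- matrix(emb, nrow = n_pat)
  # rank with ties broken by temporal order, vectorized across patterns:
  # rank_j = 1 + #{k: x_k < x_j} + #{k < j: x_k == x_j}
  code <- numeric(n_pat)
  for (j in seq_len(m)) {
    r_j <- 1L
    for (k in seq_len(m)) {
      if (k == j) next
      r_j <- r_j + (emb[, k] < emb[, j]) + (k < j) * (emb[, k] == emb[, j])
    }
    code <- code + r_j * (m + 1)^(j - 1)
  }
  p <- tabulate(factor(code))
  p <- p / n_pat
  -sum(p * log(p))
}

#' Shannon entropy of the amplitude distribution
#'
#' Estimates the value probabilities by an equal-width histogram over
#' `[min(x), max(x)]` with `she_bins` bins (empty bins skipped) and returns
#' the Shannon entropy in bits. A constant series occupies one bin and yields
#' 0 by convention.
#'
#' @inheritParams permutation_entropy
#' @param n_bins Number of histogram bins (overrides `cfg$she_bins`).
#' @return Shannon entropy in bits.
#' @export
shannon_entropy <- function(x, n_bins = NULL, cfg = entropy_config()) {
  if (is.null(n_bins)) n_bins <- cfg$she_bins
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

# One-sided periodogram power at frequencies 0..Nyquist.
periodogram_power <- function(x) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  nf <- floor(n / 2) + 1L
  list(power = p[seq_len(nf)], freq = (seq_len(nf) - 1) / n)
}

#' Spectral entropy
#'
#' Shannon entropy (natural log) of the power spectral density: the
#' periodogram is folded into `spe_f` equal-width frequency components up to
#' the Nyquist frequency and normalized to a probability vector. A single
#' pure tone concentrates all power into one component and yields 0; white
#' noise approaches `log(spe_f)`.
#'
#' @inheritParams permutation_entropy
#' @param rate Sampling rate in Hz (sets the Nyquist frequency).
#' @return Spectral entropy in nats; 0 for an all-zero signal by convention.
#' @export
spectral_entropy <- function(x, rate, cfg = entropy_config()) {
  if (length(x) < 2 * cfg$spe_f) {
    abort("series too short for the requested number of spectral components.")
  }
  if (all(x == 0)) return(0)
  pg <- periodogram_power(x)
  nyquist <- rate / 2
  f_hz <- pg$freq * rate
  bin <- pmin(cfg$spe_f, pmax(1L, ceiling(f_hz / nyquist * cfg$spe_f)))
  bin[f_hz == 0] <- 1L
  p <- vapply(split(pg$power, bin), sum, numeric(1))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Approximate entropy
#'
#' Template-matching regularity statistic `phi^m(r) - phi^(m+1)(r)` with
#' Chebyshev distance and self-matches included, radius
#' `r = apen_r * sd(x)`. Scale-invariant because the radius tracks the
#' standard deviation. Natural log.
#'
#' @inheritParams permutation_entropy
#' @return Approximate entropy in nats; 0 for a constant series (degenerate
#'   radius guard).
#' @export
approximate_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$apen_m
  tau <- cfg$apen_tau
  if (length(x) <= (m + 1) * tau + 1) abort("series too short for approximate entropy.")
  s <- sd(x)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), m, cfg$apen_r * s, tau)
}

#' Sample entropy
#'
#' `-ln(A^m(r) / B^m(r))` where `B` is the probability that two distinct
#' m-point templates match within `r = saen_r * sd(x)` (Chebyshev distance,
#' self-matches excluded) and `A` the same for (m+1)-point templates. Natural
#' log.
#'
#' @inheritParams permutation_entropy
#' @return Sample entropy in nats, or `NA` when undefined (constant series,
#'   or no matching templates at either length).
#' @export
sample_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$saen_m
  tau <- cfg$saen_tau
  if (length(x) <= m * tau + 1) abort("series too short for sample entropy.")
  s <- sd(x)
  if (s == 0) return(NA_real_)
  ab <- sampen_counts_cpp(as.numeric(x), m, cfg$saen_r * s, tau)
  if (ab[["A"]] == 0 || ab[["B"]] == 0) return(NA_real_)
  -log(ab[["A"]] / ab[["B"]])
}

# Delay-embedding matrix: rows y_i = (x_i, x_{i+tau}, ..., x_{i+(r-1)tau}).
delay_embed <- function(x, order, tau) {
  n_rows <- length(x) - (order - 1L) * tau
  if (n_rows < 1) abort("series too short for the requested embedding.")
  idx <- outer(seq_len(n_rows), seq.int(0L, by = tau, length.out = order), "+")
  matrix(x[idx], nrow = n_rows)
}

#' Singular value decomposition entropy
#'
#' Builds the delay-embedding matrix of order `svd_order` at delay
#' `svd_delay`, normalizes its singular values to sum 1, and returns their
#' Shannon entropy in bits. Bounded above by `log2(svd_order)`; a constant
#' (rank-1 embedding) series yields 0.
#'
#' @inheritParams permutation_entropy
#' @return SVD entropy in bits; 0 for an all-zero signal by convention.
#' @export
svd_entropy <- function(x, cfg = entropy_config()) {
  if (all(x == 0)) return(0)
  Y <- delay_embed(as.numeric(x), cfg$svd_order, cfg$svd_delay)
  sv <- svd(Y, nu = 0, nv = 0)$d
  sv <- sv / sum(sv)
  sv <- sv[sv > 0]
  -sum(sv * log2(sv))
}

#' All six entropy features of a series
#'
#' @inheritParams spectral_entropy
#' @return A named numeric vector with elements `permutation_entropy`,
#'   `shannon_entropy`, `spectral_entropy`, `approximate_entropy`,
#'   `sample_entropy`, `svd_entropy`. Estimators whose preconditions fail on
#'   the series are returned as `NA` rather than aborting.
#' @export
entropy_features <- function(x, rate, cfg = entropy_config()) {
  safe <- function(f) tryCatch(f, error = function(e) NA_real_)
  c(
    permutation_entropy = safe(permutation_entropy(x, cfg)),
    shannon_entropy = safe(shannon_entropy(x, cfg = cfg)),
    spectral_entropy = safe(spectral_entropy(x, rate, cfg)),
    approximate_entropy = safe(approximate_entropy(x, cfg)),
    sample_entropy = safe(sample_entropy(x, cfg)),
    svd_entropy = safe(svd_entropy(x, cfg))
  )
}
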