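#' Decomposition configuration
#'
#' Parameters controlling sifting and the noise ensembles. The defaults follow
#' common practice for ensemble empirical mode decomposition: a Cauchy-type
#' normalized squared-difference stopping threshold of 0.2, at most 100 sift
#' iterations, mirror boundary extension, 50 complementary noise pairs (100
#' ensemble members) and white-noise amplitude 0.2 x sd(signal).
#'
#' @param max_imfs Maximum number of IMFs, or `"auto"` for
#'   `floor(log2(n))` (see [max_imf_count()]).
#' @param noise_amplitude White-noise standard deviation as a fraction of the
#'   input signal's standard deviation.
#' @param n_pairs Number of complementary noise pairs (CEEMD) or of
#'   independent noise realizations (EEMD).
#' @param sift_sd_threshold Stop sifting when
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` falls below this value.
#' @param max_sift_iters Hard cap on sift iterations per IMF.
#' @param boundary Envelope boundary rule; only `"mirror"` is implemented.
#' @param seed Integer seed for the ensemble noise (per-pair substreams, so
#'   increasing `n_pairs` does not reshuffle earlier pairs).
#' @return A `decompose_config` list.
#' @export
decompose_config <- function(max_imfs = "auto", noise_amplitude = 0.2,
                             n_pairs = 50L, sift_sd_threshold = 0.2,
                             max_sift_iters = 100L, boundary = "mirror",
                             seed = 1L) {
  if (!identical(max_imfs, "auto")) {
    stopifnot(is.numeric(max_imfs), max_imfs >= 1)
  }
  stopifnot(noise_amplitude >= 0, n_pairs >= 1, sift_sd_threshold > 0,
            max_sift_iters >= 1)
  boundary <- arg_match0(boundary, "mirror")
  structure(
    list(max_imfs = max_imfs, noise_amplitude = noise_amplitude,
         n_pairs = as.integer(n_pairs), sift_sd_threshold = sift_sd_threshold,
         max_sift_iters = as.integer(max_sift_iters), boundary = boundary,
         seed = as.integer(seed)),
    class = "decompose_config"
  )
}

#' Locate strict local extrema
#'
#' Flat plateaus contribute the midpoint index of the tied run. Fewer than two
#' maxima or two minima signals a monotone/trend series, which terminates
#' sifting in the callers.
#'
#' @param x Numeric vector of length >= 3.
#' @return A list with integer vectors `maxima` and `minima` (ascending).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) abort("find_extrema needs at least 3 samples.")
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(maxima = integer(), minima = integer()))
  s_nz <- s[nz]
  k <- length(nz)
  from <- s_nz[-k]
  to <- s_nz[-1]
  i1 <- nz[-k]
  i2 <- nz[-1]
  # plateau spans samples (i1+1)..i2; strict extrema have i1+1 == i2
  mid <- (i1 + 1L + i2) %/% 2L
  list(
    maxima = mid[from > 0 & to < 0],
    minima = mid[from < 0 & to > 0]
  )
}

# Mirror the two extrema nearest each end of the series about the endpoints,
# the standard anti-end-effect extension for spline envelopes.
mirror_knots <- function(idx, vals, n) {
  k <- length(idx)
  kl <- min(2L, k)
  left_pos <- 2L - idx[seq_len(kl)]
  left <- list(pos = rev(left_pos), val = rev(vals[seq_len(kl)]))
  right_sel <- seq.int(k - kl + 1L, k)
  right_pos <- 2L * n - idx[right_sel]
  right <- list(pos = rev(right_pos), val = rev(vals[right_sel]))
  list(pos = c(left$pos, idx, right$pos), val = c(left$val, vals, right$val))
}

#' Mean of the cubic-spline envelopes
#'
#' Interpolates a cubic spline through the local maxima (upper envelope) and
#' the local minima (lower envelope), after mirroring the two extrema nearest
#' each end of the series, and returns the pointwise mean of the two
#' envelopes.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @param extrema Optional precomputed [find_extrema()] result.
#' @return Numeric vector of `length(x)`, or `NULL` if there are not enough
#'   extrema to build both envelopes (sifting termination signal).
#' @export
envelope_mean <- function(x, extrema = NULL) {
  if (is.null(extrema)) extrema <- find_extrema(x)
  mx <- extrema$maxima
  mn <- extrema$minima
  if (length(mx) < 2 || length(mn) < 2) return(NULL)
  n <- length(x)
  up <- mirror_knots(mx, x[mx], n)
  lo <- mirror_knots(mn, x[mn], n)
  upper <- spline(up$pos, up$val, xout = seq_len(n), method = "natural",
                  ties = list("ordered", mean))$y
  lower <- spline(lo$pos, lo$val, xout = seq_len(n), method = "natural",
                  ties = list("ordered", mean))$y
  (upper + lower) / 2
}

#' Sift one candidate intrinsic mode function
#'
#' Repeatedly subtracts the envelope mean (`h <- h - envelope_mean(h)`).
#' Sifting stops once the candidate satisfies the IMF conditions under the
#' Cauchy-type criterion: the normalized squared change a further subtraction
#' would make, `sum(m^2) / sum(h^2)`, is below `config$sift_sd_threshold`,
#' the envelope mean is locally small (max |m| at most 10% of the peak
#' amplitude), and the zero-crossing and extrema counts differ by at most
#' one. The iteration cap guarantees termination; running out of extrema
#' terminates early (trend reached).
#'
#' @param x Numeric vector with enough extrema to build envelopes.
#' @param config A [decompose_config()].
#' @return Numeric vector: the candidate IMF.
#' @export
sift <- function(x, config = decompose_config()) {
  h <- x
  for (iter in seq_len(config$max_sift_iters)) {
    denom <- sum(h^2)
    if (denom == 0) return(h)
    ext <- find_extrema(h)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) return(h)
    m <- envelope_mean(h, ext)
    n_ext <- length(ext$maxima) + length(ext$minima)
    if (sum(m^2) / denom < config$sift_sd_threshold &&
        max(abs(m)) <= 0.1 * max(abs(h)) &&
        abs(count_zero_crossings(h) - n_ext) <= 1L) {
      break
    }
    h <- h - m
  }
  h
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Test the intrinsic-mode-function conditions
#'
#' An IMF must have zero-crossing and extrema counts that differ by at most
#' one, and a near-zero local envelope mean (here: maximum absolute envelope
#' mean at most 10% of the peak amplitude).
#'
#' @param x Numeric vector of length >= 3.
#' @param tolerance Allowed difference between the zero-crossing and extrema
#'   counts (default 1).
#' @return `TRUE` or `FALSE`.
#' @export
is_imf <- function(x, tolerance = 1L) {
  ext <- find_extrema(x)
  n_ext <- length(ext$maxima) + length(ext$minima)
  if (n_ext == 0) return(FALSE)
  zc <- count_zero_crossings(x)
  if (abs(zc - n_ext) > tolerance) return(FALSE)
  m <- envelope_mean(x, ext)
  if (is.null(m)) return(FALSE)
  max(abs(m)) <= 0.1 * max(abs(x))
}

#' Automatic IMF-count cap
#'
#' `floor(log2(n))`: 12 IMFs for the 4097-point single-channel segments and 14
#' for the 17,664-point multi-channel windows.
#'
#' @param n Number of samples (>= 4).
#' @return Integer IMF cap.
#' @export
#' @examples
#' max_imf_count(4097) # 12
#' max_imf_count(17664) # 14
max_imf_count <- function(n) {
  if (n < 4) abort("max_imf_count needs n >= 4.")
  as.integer(floor(log2(n)))
}

new_decomposition <- function(imfs, residue, method, config, degenerate = FALSE) {
  structure(
    list(imfs = imfs, residue = residue, source_n = length(residue),
         method = method, config = config, degenerate = degenerate),
    class = "eeg_decomposition"
  )
}

#' @export
print.eeg_decomposition <- function(x, ...) {
  cat(sprintf("<eeg_decomposition: %s, %d IMFs + residue, n = %d%s>\n",
              x$method, length(x$imfs), x$source_n,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (highest frequency
#' first) plus one residue by repeatedly sifting the running residue until the
#' IMF cap is reached or the residue is monotone (fewer than 2 maxima or 2
#' minima). The IMFs and residue sum back to the input exactly (telescoping
#' construction).
#'
#' @param x Numeric vector (length >= 4) or a single-channel [eeg_signal].
#' @param config A [decompose_config()]; `n_pairs`/`noise_amplitude` are
#'   ignored by plain EMD.
#' @return An `eeg_decomposition`: list with `imfs` (list of numeric vectors),
#'   `residue`, `source_n`, `method`, `config`.
#' @export
emd <- function(x, config = decompose_config()) {
  x <- as_series(x)
  if (length(x) < 4) abort("emd needs at least 4 samples.")
  cap <- if (identical(config$max_imfs, "auto")) max_imf_count(length(x))
         else as.integer(config$max_imfs)
  imfs <- list()
  residue <- x
  while (length(imfs) < cap) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    imf <- sift(residue, config)
    if (all(imf == 0)) break
    imfs <- c(imfs, list(imf))
    residue <- residue - imf
  }
  new_decomposition(imfs, residue, "emd", config,
                    degenerate = length(imfs) == 0)
}

as_series <- function(x) {
  if (inherits(x, "eeg_signal")) {
    if (n_channels(x) > 1) {
      abort("decomposition takes a single series; flatten_multichannel() first.")
    }
    return(as.vector(x$samples))
  }
  as.numeric(x)
}

# Shared machinery for the noise ensembles. `signs` is +1/-1 per member within
# a pair (CEEMD) or just +1 (EEMD). Members that stop early are zero-padded to
# the common IMF count before averaging; the final residue is defined by
# subtraction so reconstruction is exact. The pre-subtraction ensemble
# residue (mean of member residues) is kept for diagnostics.
ensemble_emd <- function(x, config, signs, method) {
  x <- as_series(x)
  if (length(x) < 4) abort(sprintf("%s needs at least 4 samples.", method))
  n <- length(x)
  cap <- if (identical(config$max_imfs, "auto")) max_imf_count(n)
         else as.integer(config$max_imfs)
  sigma <- sd(x) * config$noise_amplitude
  if (sigma == 0) {
    if (config$noise_amplitude == 0) {
      warn(sprintf("noise_amplitude = 0: %s collapses to plain EMD.", method))
    }
    base <- emd(x, config)
    base$method <- method
    return(base)
  }
  member_cfg <- config
  acc <- matrix(0, n, cap)
  res_acc <- numeric(n)
  n_members <- 0L
  for (k in seq_len(config$n_pairs)) {
    noise <- withr_seed(config$seed + k, rnorm(n, sd = sigma))
    for (sgn in signs) {
      dec <- emd(x + sgn * noise, member_cfg)
      m <- length(dec$imfs)
      if (m > 0) {
        take <- min(m, cap)
        for (j in seq_len(take)) acc[, j] <- acc[, j] + dec$imfs[[j]]
      }
      res_acc <- res_acc + dec$residue
      n_members <- n_members + 1L
    }
  }
  acc <- acc / n_members
  imfs <- lapply(seq_len(cap), function(j) acc[, j])
  ens_res <- res_acc / n_members
  raw_err <- mean(abs(rowSums(acc) + ens_res - x))
  residue <- x - rowSums(acc)
  out <- new_decomposition(imfs, residue, method, config)
  out$raw_recon_error <- raw_err
  out
}

#' Complementary ensemble empirical mode decomposition
#'
#' Runs EMD on `n_pairs` complementary pairs `x + w_k` and `x - w_k` of white
#' Gaussian noise realizations (2 x `n_pairs` ensemble members) and averages
#' the j-th IMFs across members; the paired positive/negative noises cancel,
#' suppressing residual noise while still breaking mode mixing. The residue is
#' `x - sum(averaged IMFs)`, so reconstruction is exact by construction.
#'
#' @inheritParams emd
#' @return An `eeg_decomposition` with `method = "ceemd"`. The element
#'   `raw_recon_error` records the mean absolute reconstruction error of the
#'   averaged ensemble before the closing subtraction (a residual-noise
#'   diagnostic).
#' @export
ceemd <- function(x, config = decompose_config()) {
  ensemble_emd(x, config, signs = c(1, -1), method = "ceemd")
}

#' Ensemble empirical mode decomposition
#'
#' As [ceemd()], but with `n_pairs` independent (unpaired) noise realizations:
#' the classic noise-assisted variant, whose averaged modes retain more
#' residual noise than the complementary-pair scheme.
#'
#' @inheritParams emd
#' @return An `eeg_decomposition` with `method = "eemd"`.
#' @export
eemd <- function(x, config = decompose_config()) {
  ensemble_emd(x, config, signs = 1, method = "eemd")
}

#' Reconstruct the input from a decomposition
#'
#' @param decomp An `eeg_decomposition`.
#' @return Numeric vector `sum(IMFs) + residue`.
#' @export
reconstruct <- function(decomp) {
  out <- decomp$residue
  for (imf in decomp$imfs) out <- out + imf
  out
}

#' @rdname emd
#' @param x An `eeg_decomposition`.
#' @param ... Unused.
#' @export
as_tibble.eeg_decomposition <- function(x, ...) {
  cols <- c(
    setNames(x$imfs, paste0("imf_", seq_along(x$imfs))),
    list(residue = x$residue)
  )
  as_tibble(cols)
}

#' @export
tidy.eeg_decomposition <- function(x, ...) {
  tb <- as_tibble(x)
  tb$t <- seq_len(nrow(tb))
  tidyr::pivot_longer(tb, -"t", names_to = "component", values_to = "value")
}

#' Plot a decomposition as stacked component traces
#'
#' @param object An `eeg_decomposition`.
#' @param ... Unused.
#' @return A ggplot object, one facet per IMF/residue.
#' @export
autoplot.eeg_decomposition <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL,
                  title = sprintf("%s decomposition", toupper(object$method))) +
    ggplot2::theme_minimal()
}

#' Write / read a decomposition as CSV
#'
#' Columns `imf_1..imf_M, residue`, one row per sample.
#'
#' @param decomp An `eeg_decomposition`.
#' @param path CSV file path.
#' @export
write_decomposition <- function(decomp, path) {
  readr::write_csv(as_tibble(decomp), path)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  imf_cols <- grep("^imf_", names(tb), value = TRUE)
  new_decomposition(
    imfs = lapply(imf_cols, function(cl) tb[[cl]]),
    residue = tb$residue, method = "unknown", config = NULL
  )
}
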