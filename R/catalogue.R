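# Multi-domain feature catalogue: time, frequency, and time-frequency
# descriptors computed per component. Entropy features live in entropy.R.

lag_names <- function(prefix, lags) sprintf("%s_%02d", prefix, lags)

# corridors for change_quantiles, as (lower, upper) quantile pairs
cq_corridors <- list(
  c(0.0, 0.6), c(0.1, 0.2), c(0.2, 0.4), c(0.2, 1.0), c(0.4, 0.6), c(0.8, 1.0)
)
cq_name <- function(q) sprintf("change_quantiles_%.1f_%.1f", q[1], q[2])

#' Mean absolute change inside a quantile corridor
#'
#' Mean of `|x[i+1] - x[i]|` over consecutive pairs that both lie inside the
#' corridor `[quantile(x, ql), quantile(x, qh)]`. With the full corridor
#' `(0, 1)` this equals the plain mean absolute change.
#'
#' @param x Numeric vector.
#' @param ql,qh Lower and upper corridor quantiles.
#' @return Mean absolute consecutive change within the corridor (0 if no
#'   consecutive pair falls inside).
#' @export
change_quantiles <- function(x, ql, qh) {
  lo <- quantile(x, ql, names = FALSE)
  hi <- quantile(x, qh, names = FALSE)
  inside <- x >= lo & x <= hi
  sel <- inside[-length(x)] & inside[-1]
  if (!any(sel)) return(0)
  mean(abs(diff(x))[sel])
}

# tsfresh-style peak count: x[i] greater than all neighbours within `support`.
number_peaks <- function(x, support) {
  n <- length(x)
  if (n < 2 * support + 1) return(0L)
  core <- seq.int(support + 1L, n - support)
  ok <- rep(TRUE, length(core))
  for (k in seq_len(support)) {
    ok <- ok & x[core] > x[core - k] & x[core] > x[core + k]
  }
  sum(ok)
}

number_crossings <- function(x, level = 1) {
  s <- sign(x - level)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

linear_trend <- function(y, t = seq_along(y)) {
  n <- length(y)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * tm
  res <- y - intercept - slope * t
  stderr <- sqrt(sum(res^2) / (n - 2) / sxx)
  sy <- sd(y)
  rvalue <- if (sy == 0) 0 else slope * sd(t) / sy
  c(slope = slope, intercept = intercept, stderr = stderr, rvalue = rvalue)
}

chunk_stat <- function(x, n_chunks, f) {
  idx <- cut(seq_along(x), n_chunks, labels = FALSE)
  vapply(split(x, idx), f, numeric(1))
}

# Ricker (Mexican-hat) continuous wavelet transform at one width.
cwt_ricker <- function(x, width) {
  half <- min(length(x) - 1L, ceiling(5 * width))
  t <- seq.int(-half, half)
  a <- width
  k <- 2 / (sqrt(3 * a) * pi^0.25) * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  full <- convolve(x, rev(k), type = "open")
  start <- half + 1L
  full[start:(start + length(x) - 1L)]
}

# Peaks of the ricker-smoothed signal that stand out from its own spread:
# a simplified CWT ridge-peak count.
number_cwt_peaks <- function(x, width = 5) {
  sm <- cwt_ricker(x, width)
  thr <- sd(sm)
  n <- length(sm)
  if (n < 3) return(0L)
  core <- 2:(n - 1)
  sum(sm[core] > sm[core - 1] & sm[core] > sm[core + 1] & sm[core] > thr)
}

ar_coefficients <- function(x, order = 10) {
  fit <- tryCatch(
    suppressWarnings(
      stats::ar.ols(x, aic = FALSE, order.max = order, demean = TRUE,
                    intercept = TRUE)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(rep(NA_real_, order))
  co <- as.numeric(fit$ar)
  length(co) <- order
  co
}

#' Multi-domain feature catalogue of one series
#'
#' Computes the fixed catalogue of time-domain (energy, autocorrelation,
#' autoregression, linear trends, change statistics, order statistics, counts),
#' frequency-domain (discrete Fourier coefficients and aggregated spectral
#' moments) and time-frequency (Ricker continuous-wavelet coefficients and
#' peaks) descriptors. Individual features that are undefined on a series are
#' returned as `NA`; they never abort the whole vector.
#'
#' @param x Numeric vector, length >= 16.
#' @param rate Sampling rate in Hz (carried for API symmetry; catalogue
#'   features are sample-indexed).
#' @return A named numeric vector; names and domains are listed by
#'   [feature_registry()].
#' @export
catalogue_features <- function(x, rate = 1) {
  n <- length(x)
  if (n < 16) {
    abort("catalogue_features needs at least 16 samples (autocorrelation/AR/FFT block).")
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out <- c()

  # -- time domain
  out["abs_energy"] <- sum(x^2)
  erc <- chunk_stat(x, 10, function(ch) sum(ch^2))
  total <- sum(erc)
  out[lag_names("energy_ratio_chunk", 1:10)] <-
    if (total == 0) rep(0, 10) else erc / total

  ac <- safe(as.numeric(acf(x, lag.max = 10, plot = FALSE,
                            demean = TRUE)$acf)[2:11])
  if (length(ac) != 10) ac <- rep(NA_real_, 10)
  out[lag_names("autocorr_lag", 1:10)] <- ac
  out["agg_autocorr_mean"] <- mean(ac)
  out["agg_autocorr_var"] <- var(ac)

  pc <- safe(as.numeric(pacf(x, lag.max = 5, plot = FALSE)$acf))
  if (length(pc) != 5) pc <- rep(NA_real_, 5)
  out[lag_names("pacf_lag", 1:5)] <- pc

  out[lag_names("ar_coef", 1:10)] <- ar_coefficients(x, 10)

  lt <- linear_trend(x)
  out[paste0("linear_trend_", names(lt))] <- lt

  dx <- diff(x)
  out["mean_abs_change"] <- mean(abs(dx))
  out["abs_sum_of_changes"] <- sum(abs(dx))
  for (q in cq_corridors) out[cq_name(q)] <- change_quantiles(x, q[1], q[2])

  out["maximum"] <- max(x)
  out["minimum"] <- min(x)
  out["mean"] <- mean(x)
  out["median"] <- median(x)
  out["sum_values"] <- sum(x)
  out["standard_deviation"] <- sd(x)
  out["variance"] <- var(x)
  out["quantile_0.2"] <- quantile(x, 0.2, names = FALSE)
  out["quantile_0.8"] <- quantile(x, 0.8, names = FALSE)
  out["number_peaks_support_1"] <- number_peaks(x, 1)
  out["number_peaks_support_3"] <- number_peaks(x, 3)
  out["number_crossing_1"] <- number_crossings(x, 1)
  out["range_count_m1_1"] <- sum(x >= -1 & x < 1)
  tab <- table(x)
  out["pct_reoccurring_datapoints"] <- sum(tab[tab > 1]) / n
  out["ratio_unique_values"] <- length(tab) / n

  agg <- safe(linear_trend(chunk_stat(x, 10, max)))
  if (length(agg) != 4) agg <- c(slope = NA_real_, intercept = NA_real_,
                                 stderr = NA_real_, rvalue = NA_real_)
  out[paste0("agg_linear_trend_max_", c("slope", "intercept", "rvalue"))] <-
    agg[c("slope", "intercept", "rvalue")]

  # -- frequency domain
  ft <- fft(x)
  k <- 0:19
  out[sprintf("fft_coef_%02d_real", k)] <- Re(ft[k + 1])
  out[sprintf("fft_coef_%02d_imag", k)] <- Im(ft[k + 1])
  out[sprintf("fft_coef_%02d_abs", k)] <- Mod(ft[k + 1])

  spec <- Mod(ft[seq_len(floor(n / 2) + 1)])
  if (sum(spec) == 0) {
    out[c("fft_agg_centroid", "fft_agg_skew", "fft_agg_kurtosis")] <- NA_real_
  } else {
    p <- spec / sum(spec)
    f <- seq_along(spec) - 1
    mu <- sum(f * p)
    m2 <- sum((f - mu)^2 * p)
    out["fft_agg_centroid"] <- mu
    out["fft_agg_skew"] <- if (m2 == 0) NA_real_ else sum((f - mu)^3 * p) / m2^1.5
    out["fft_agg_kurtosis"] <- if (m2 == 0) NA_real_ else sum((f - mu)^4 * p) / m2^2
  }

  # -- time-frequency domain
  for (w in c(2, 5, 10, 20)) {
    cw <- safe(cwt_ricker(x, w))
    out[sprintf("cwt_ricker_w%02d_max_abs", w)] <-
      if (all(is.na(cw))) NA_real_ else max(abs(cw))
    out[sprintf("cwt_ricker_w%02d_mid", w)] <-
      if (all(is.na(cw))) NA_real_ else cw[ceiling(n / 2)]
  }
  out["number_cwt_peaks"] <- safe(number_cwt_peaks(x))

  out
}

entropy_feature_names <- c(
  "permutation_entropy", "shannon_entropy", "spectral_entropy",
  "approximate_entropy", "sample_entropy", "svd_entropy"
)

#' Feature registry
#'
#' Names, domain tags and parameter notes of every per-component feature the
#' package extracts (catalogue plus the six entropies).
#'
#' @return A tibble with columns `feature`, `domain`
#'   (time / frequency / time-frequency / entropy) and `parameters`.
#' @export
feature_registry <- function() {
  template <- catalogue_features(sin(seq_len(64)) + seq_len(64) / 64, rate = 1)
  nm <- names(template)
  domain <- dplyr::case_when(
    grepl("^fft_", nm) ~ "frequency",
    grepl("^cwt_|^number_cwt", nm) ~ "time-frequency",
    TRUE ~ "time"
  )
  params <- dplyr::case_when(
    grepl("^energy_ratio_chunk", nm) ~ "10 chunks",
    grepl("^autocorr_lag|^agg_autocorr", nm) ~ "lags 1-10",
    grepl("^pacf_lag", nm) ~ "lags 1-5",
    grepl("^ar_coef", nm) ~ "OLS, order 10",
    grepl("^agg_linear_trend", nm) ~ "chunk maxima, 10 chunks",
    grepl("^change_quantiles", nm) ~ "quantile corridor",
    grepl("^fft_coef", nm) ~ "DFT coefficients 0-19",
    grepl("^cwt_ricker", nm) ~ "widths 2/5/10/20",
    nm == "number_cwt_peaks" ~ "ricker width 5",
    nm == "range_count_m1_1" ~ "interval [-1, 1)",
    nm == "number_crossing_1" ~ "level 1",
    TRUE ~ ""
  )
  cat_tb <- tibble(feature = nm, domain = domain, parameters = params)
  ent_tb <- tibble(
    feature = entropy_feature_names,
    domain = "entropy",
    parameters = c("order 3, delay 1 (nats)", "100 bins (bits)",
                   "100 components (nats)", "m=2, r=0.15 sd (nats)",
                   "m=2, r=0.2 sd (nats)", "order 3, delay 1 (bits)")
  )
  bind_rows(cat_tb, ent_tb)
}

#' Dump the feature registry as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
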