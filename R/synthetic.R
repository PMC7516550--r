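#' Synthetic EEG generator configuration
#'
#' The generator emulates the two signal states the detector separates:
#' non-seizure background (1/f^beta "pink" noise plus an alpha-band 8-13 Hz
#' oscillation) and seizure activity (the same background plus a
#' high-amplitude rhythmic 3-5 Hz spike-wave train with harmonics). The
#' defaults are the standard synthetic benchmark: 256 Hz, 3-second
#' single-channel segments, 100 segments per class, spike-wave amplitude 4x
#' the background standard deviation, seed 7.
#'
#' @param rate Sampling rate in Hz.
#' @param duration_s Segment duration in seconds.
#' @param n_channels Channels per segment.
#' @param n_per_class Segments per class.
#' @param pink_exponent Spectral exponent beta of the 1/f^beta background.
#' @param alpha_amp Amplitude of the alpha-band oscillation (in background-sd
#'   units).
#' @param alpha_band Alpha oscillation frequency range in Hz.
#' @param noise_sd Standard deviation of the pink-noise background.
#' @param seizure_mult Spike-wave amplitude as a multiple of the background
#'   standard deviation (> 1 for separable benchmarks).
#' @param spike_amp Extra scale on the spike-wave train; 0 disables it, so a
#'   "seizure" segment degenerates to background.
#' @param seizure_band Spike-wave fundamental frequency range in Hz.
#' @param n_harmonics Number of harmonics above the fundamental.
#' @param seed Integer seed; every segment derives its own substream from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(rate = 256, duration_s = 3, n_channels = 1L,
                         n_per_class = 100L, pink_exponent = 1,
                         alpha_amp = 1, alpha_band = c(8, 13),
                         noise_sd = 1, seizure_mult = 4, spike_amp = 1,
                         seizure_band = c(3, 5), n_harmonics = 2L,
                         seed = 7L) {
  alpha_band <- as.numeric(unlist(alpha_band)) # lists arrive from YAML configs
  seizure_band <- as.numeric(unlist(seizure_band))
  stopifnot(rate > 0, duration_s > 0, n_channels >= 1, n_per_class >= 1,
            alpha_amp >= 0, noise_sd >= 0, seizure_mult > 0, spike_amp >= 0,
            length(alpha_band) == 2, length(seizure_band) == 2)
  structure(
    list(rate = rate, duration_s = duration_s,
         n_channels = as.integer(n_channels),
         n_per_class = as.integer(n_per_class),
         pink_exponent = pink_exponent, alpha_amp = alpha_amp,
         alpha_band = alpha_band, noise_sd = noise_sd,
         seizure_mult = seizure_mult, spike_amp = spike_amp,
         seizure_band = seizure_band, n_harmonics = as.integer(n_harmonics),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f^beta noise by spectral shaping of white Gaussian noise; deterministic
# given the RNG state, unit standard deviation.
pink_noise <- function(n, beta) {
  w <- rnorm(n)
  if (beta == 0) return(w)
  f <- fft(w)
  k <- c(1, seq_len(n - 1))
  freq <- pmin(k, n - k + 1) # fold to physical frequency magnitude
  f <- f / freq^(beta / 2)
  f[1] <- 0
  x <- Re(fft(f, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

# One channel of oscillatory background, assuming the RNG is positioned.
background_channel <- function(cfg) {
  n <- round(cfg$rate * cfg$duration_s)
  t <- (seq_len(n) - 1) / cfg$rate
  x <- cfg$noise_sd * pink_noise(n, cfg$pink_exponent)
  if (cfg$alpha_amp > 0) {
    f <- runif(1, cfg$alpha_band[1], cfg$alpha_band[2])
    phi <- runif(1, 0, 2 * pi)
    x <- x + cfg$alpha_amp * sin(2 * pi * f * t + phi)
  }
  x
}

spike_train <- function(cfg, n, base_sd) {
  t <- (seq_len(n) - 1) / cfg$rate
  f0 <- runif(1, cfg$seizure_band[1], cfg$seizure_band[2])
  phi <- runif(1, 0, 2 * pi)
  wave <- numeric(n)
  for (h in 0:cfg$n_harmonics) {
    wave <- wave + sin(2 * pi * (h + 1) * f0 * t + phi) / (h + 1)
  }
  amp <- cfg$seizure_mult * cfg$spike_amp * base_sd
  amp * wave / max(1e-12, sd(wave))
}

#' Generate one synthetic non-seizure (background) segment
#'
#' Independent pink noise plus a randomly phased alpha-band oscillation per
#' channel, drawn from a seeded substream so a fixed seed reproduces the
#' segment exactly.
#'
#' @param cfg A [synth_config()].
#' @param seed Segment seed; defaults to `cfg$seed`.
#' @return An [eeg_signal].
#' @export
gen_background <- function(cfg = synth_config(), seed = cfg$seed) {
  n <- round(cfg$rate * cfg$duration_s)
  samples <- withr_seed(seed, {
    vapply(seq_len(cfg$n_channels), function(ch) background_channel(cfg),
           numeric(n))
  })
  eeg_signal(samples, rate = cfg$rate)
}

#' Generate one synthetic seizure segment
#'
#' The background of [gen_background()] plus a rhythmic 3-5 Hz spike-wave
#' train (fundamental plus `n_harmonics` harmonics, shared across channels up
#' to phase) whose amplitude is `seizure_mult * spike_amp` times the
#' channel's background standard deviation.
#'
#' @inheritParams gen_background
#' @return An [eeg_signal].
#' @export
gen_seizure <- function(cfg = synth_config(), seed = cfg$seed) {
  n <- round(cfg$rate * cfg$duration_s)
  samples <- withr_seed(seed, {
    vapply(seq_len(cfg$n_channels), function(ch) {
      bg <- background_channel(cfg)
      if (cfg$spike_amp > 0) bg + spike_train(cfg, n, sd(bg)) else bg
    }, numeric(n))
  })
  eeg_signal(samples, rate = cfg$rate)
}

#' Generate a balanced labeled synthetic segment set
#'
#' `n_per_class` background and `n_per_class` seizure segments, each from its
#' own seed substream (`cfg$seed + index`), so the set is reproducible and
#' stable under changes of `n_per_class`.
#'
#' @param cfg A [synth_config()].
#' @return A segment-set tibble (`segment_id`, `label`, `signal`), with the
#'   generating config and seed attached as attributes.
#' @export
gen_dataset <- function(cfg = synth_config()) {
  n_each <- cfg$n_per_class
  rows <- vector("list", 2 * n_each)
  for (i in seq_len(n_each)) {
    rows[[i]] <- tibble(
      label = "non-seizure",
      signal = list(gen_background(cfg, seed = cfg$seed + i))
    )
    rows[[n_each + i]] <- tibble(
      label = "seizure",
      signal = list(gen_seizure(cfg, seed = cfg$seed + 500000L + i))
    )
  }
  out <- bind_rows(rows)
  out <- mutate(out, segment_id = sprintf("seg_%04d", dplyr::row_number()),
                .before = 1)
  structure(out, config = cfg, seed = cfg$seed)
}
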