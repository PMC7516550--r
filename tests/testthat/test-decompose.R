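test_that("local extrema are found, plateaus at their midpoint", {
  ext <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(ext$maxima, c(2, 6))
  expect_equal(ext$minima, 4)

  expect_equal(find_extrema(seq_len(10)), list(maxima = integer(), minima = integer()))

  expect_equal(find_extrema(c(0, 1, 1, 0))$maxima, 2)
  expect_equal(find_extrema(c(0, 1, 1, 1, 0))$maxima, 3)
  expect_equal(find_extrema(c(1, 0, 0, 0, 1, 0))$minima, 3)
  expect_error(find_extrema(c(1, 2)), "at least 3")
})

test_that("envelope mean is near zero for a sine and equivariant to shift/scale", {
  n <- 1024
  x <- sin(2 * pi * 16 * (seq_len(n) - 1) / n) # 16 full cycles
  em <- envelope_mean(x)
  interior <- em[floor(n * 0.1):ceiling(n * 0.9)]
  expect_lt(max(abs(interior)), 0.05)

  y <- broadband(512, seed = 2)
  expect_equal(envelope_mean(y + 3.5), envelope_mean(y) + 3.5, tolerance = 1e-9)
  expect_equal(envelope_mean(2.5 * y), 2.5 * envelope_mean(y), tolerance = 1e-9)

  expect_null(envelope_mean(seq_len(10))) # no extrema -> termination signal
})

test_that("sifting preserves a pure tone and yields a valid IMF", {
  n <- 1024
  x <- sin(2 * pi * 16 * (seq_len(n) - 1) / n)
  h <- sift(x)
  expect_gt(cor(h, x), 0.99)
  expect_true(is_imf(h))

  expect_equal(sift(rep(0, 100)), rep(0, 100))

  # sift output of a broadband signal satisfies the IMF conditions
  for (seed in 1:3) {
    h <- sift(broadband(512, seed = seed))
    expect_true(is_imf(h))
  }
})

test_that("the IMF conditions reject trends and offset signals", {
  n <- 512
  x <- sin(2 * pi * 8 * (seq_len(n) - 1) / n)
  expect_true(is_imf(x))
  expect_false(is_imf(seq_len(100) / 10))
  # oscillation riding a large offset ramp: extrema but no zero crossings
  mixed <- x + 10 + 5 * seq_len(n) / n
  expect_false(is_imf(mixed))
})

test_that("the automatic IMF cap is floor(log2(n))", {
  expect_equal(max_imf_count(4097), 12L)
  expect_equal(max_imf_count(17664), 14L)
  expect_equal(max_imf_count(4), 2L)
  expect_error(max_imf_count(3))
})

test_that("EMD separates well-spaced tones and reconstructs exactly", {
  rate <- 512
  n <- 2048
  t <- (seq_len(n) - 1) / rate
  hi <- sin(2 * pi * 30 * t)
  lo <- sin(2 * pi * 3 * t)
  x <- lo + hi
  d <- emd(x)
  expect_gte(length(d$imfs), 2)
  expect_gt(abs(cor(d$imfs[[1]], hi)), 0.95)
  expect_gt(abs(cor(d$imfs[[2]], lo)), 0.95)
  expect_lt(max(abs(reconstruct(d) - x)) / max(abs(x)), 1e-9)

  ramp <- seq_len(256) / 10
  dr <- emd(ramp)
  expect_equal(length(dr$imfs), 0)
  expect_true(dr$degenerate)
  expect_equal(dr$residue, ramp)

  dc <- emd(rep(2, 64))
  expect_true(dc$degenerate)
  expect_equal(dc$residue, rep(2, 64))
})

test_that("ensemble decompositions are deterministic and reconstruct exactly", {
  x <- broadband(512, seed = 9)
  cfg <- decompose_config(n_pairs = 4, seed = 42)
  a <- ceemd(x, cfg)
  b <- ceemd(x, cfg)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residue, b$residue)
  expect_lt(max(abs(reconstruct(a) - x)) / max(abs(x)), 1e-9)

  e <- eemd(x, cfg)
  expect_identical(e$imfs, eemd(x, cfg)$imfs)
  expect_lt(max(abs(reconstruct(e) - x)) / max(abs(x)), 1e-9)
  expect_false(isTRUE(all.equal(e$imfs[[1]], a$imfs[[1]])))
})

test_that("zero noise collapses the ensembles to plain EMD, with a warning", {
  x <- broadband(400, seed = 5)
  cfg0 <- decompose_config(noise_amplitude = 0, n_pairs = 1, seed = 1)
  ref <- emd(x, cfg0)
  expect_warning(c0 <- ceemd(x, cfg0), "collapses")
  expect_equal(c0$imfs, ref$imfs)
  expect_warning(e0 <- eemd(x, cfg0), "collapses")
  expect_equal(e0$imfs, ref$imfs)
})

test_that("complementary noise pairs cancel residual ensemble noise", {
  x <- tone(8, 512, 256)
  cfg <- decompose_config(n_pairs = 50, seed = 7)
  ce <- ceemd(x, cfg)
  ee <- eemd(x, cfg)
  expect_gt(ee$raw_recon_error, ce$raw_recon_error)
  expect_lt(ce$raw_recon_error, 1e-9) # pairs cancel exactly before subtraction
})

test_that("IMF ordering runs high to low frequency and respects the cap", {
  zc <- function(v) {
    s <- sign(v)
    s <- s[s != 0]
    sum(s[-1] != s[-length(s)])
  }
  drops <- 0L
  total <- 0L
  for (seed in 1:5) {
    x <- broadband(1024, seed = seed)
    d <- ceemd(x, decompose_config(n_pairs = 4, seed = seed))
    expect_lte(length(d$imfs), max_imf_count(1024))
    counts <- vapply(d$imfs, zc, numeric(1))
    counts <- counts[counts > 0]
    diffs <- diff(counts)
    drops <- drops + sum(diffs > 0)
    total <- total + length(diffs)
  }
  # statistically non-increasing zero-crossing counts across IMF index
  expect_lt(drops / total, 0.1)
})

test_that("a constant offset moves to the residue, leaving IMFs stable", {
  x <- tone(10, 512, 256)
  cfg <- decompose_config(n_pairs = 4, seed = 3)
  d0 <- ceemd(x, cfg)
  d1 <- ceemd(x + 5, cfg)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(d1$imfs[[1]] - d0$imfs[[1]]), 0.05 * rms(x))
  expect_equal(mean(d1$residue) - mean(d0$residue), 5, tolerance = 0.05)
})

test_that("decompositions round-trip through their CSV layout", {
  x <- broadband(256, seed = 12)
  d <- emd(x)
  path <- tempfile(fileext = ".csv")
  write_decomposition(d, path)
  back <- read_decomposition(path)
  expect_equal(length(back$imfs), length(d$imfs))
  expect_equal(back$residue, d$residue, tolerance = 1e-12)
  expect_equal(reconstruct(back), x, tolerance = 1e-9)
})
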