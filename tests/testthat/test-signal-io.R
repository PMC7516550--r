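write_bonn_fixture <- function(values, path = tempfile(fileext = ".txt")) {
  writeLines(format(values, scientific = FALSE), path)
  path
}

test_that("Bonn-style text segments read with the right shape and errors", {
  p <- write_bonn_fixture(round(sin(seq_len(4097) / 10) * 100))
  s <- read_bonn_segment(p)
  expect_s3_class(s, "eeg_signal")
  expect_equal(n_samples(s), 4097)
  expect_equal(n_channels(s), 1)
  expect_equal(s$rate, 173.61)

  p2 <- write_bonn_fixture(c(0, 1))
  s2 <- read_bonn_segment(p2, rate = 10)
  expect_equal(as.vector(s2$samples), c(0, 1))
  expect_equal(n_samples(s2), 2)

  p3 <- tempfile()
  writeLines(c("1.5", "abc", "2"), p3)
  expect_error(read_bonn_segment(p3), "line 2")

  p4 <- tempfile()
  writeLines(character(), p4)
  expect_error(read_bonn_segment(p4), "empty")
})

test_that("segment-size arithmetic floors fractional counts", {
  expect_equal(expected_segment_points(173.61, 23.6, 1), 4097L)
  expect_equal(expected_segment_points(256, 3, 23), 17664L)
  expect_equal(expected_segment_points(1, 1, 1), 1L)
  expect_error(expected_segment_points(0, 1, 1))
  expect_error(expected_segment_points(256, -1, 1))
})

test_that("EDF round-trip preserves rate and labels exactly, samples to 16-bit", {
  sig <- gen_background(synth_config(rate = 256, duration_s = 2, n_channels = 23,
                                     seed = 11))
  path <- tempfile(fileext = ".edf")
  write_edf(sig, path)
  back <- read_edf(path)
  expect_equal(back$rate, 256)
  expect_equal(n_channels(back), 23)
  expect_equal(back$channels, sig$channels)
  quant <- apply(abs(sig$samples), 2, max) / 32767
  err <- apply(abs(back$samples - sig$samples), 2, max)
  expect_true(all(err <= quant * 1.001))

  one <- eeg_signal(sin(seq_len(1000) / 7), rate = 100)
  p1 <- tempfile(fileext = ".edf")
  write_edf(one, p1)
  expect_equal(n_samples(read_edf(p1)), 1000)
})

test_that("malformed EDF files are rejected", {
  sig <- gen_background(synth_config(rate = 128, duration_s = 1, n_channels = 2,
                                     seed = 3))
  path <- tempfile(fileext = ".edf")
  write_edf(sig, path)

  # truncate the data section
  full <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".edf")
  writeBin(full[seq_len(length(full) - 10)], trunc_path)
  expect_error(read_edf(trunc_path), "malformed|size")

  # patch the second channel's samples-per-record field -> differing rates
  mixed <- full
  offset <- 256 + 2 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 8 # second nsamp field
  mixed[(offset + 1):(offset + 8)] <- charToRaw(formatC("64", width = -8))
  mixed_path <- tempfile(fileext = ".edf")
  writeBin(mixed, mixed_path)
  expect_error(read_edf(mixed_path), "differing sampling rates")

  expect_error(read_edf(tempfile()), "EDF")
})

test_that("flatten_multichannel concatenates channel-major by default", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2)
  s <- eeg_signal(m, rate = 1)
  expect_equal(as.vector(flatten_multichannel(s)$samples), c(1, 2, 3, 10, 20, 30))
  expect_equal(as.vector(flatten_multichannel(s, "time")$samples),
               c(1, 10, 2, 20, 3, 30))

  one <- eeg_signal(c(5, 6, 7), rate = 1)
  expect_identical(flatten_multichannel(one), one)

  wide <- gen_background(synth_config(rate = 256, duration_s = 3, n_channels = 23,
                                      seed = 2))
  expect_equal(n_samples(flatten_multichannel(wide)), 17664)
})

test_that("sliding windows are cut, labeled, and boundary windows dropped", {
  rate <- 100
  sig <- eeg_signal(matrix(sin(seq_len(10 * rate)), ncol = 1), rate = rate)

  plain <- segment_sliding(sig, NULL, window_s = 3, step_s = 3)
  expect_equal(nrow(plain), 3)
  expect_true(all(plain$label == "non-seizure"))

  full <- segment_sliding(sig, seizure_annotations(0, 10), window_s = 3, step_s = 1)
  expect_equal(nrow(full), 8)
  expect_true(all(full$label == "seizure"))
  expect_equal(full$start_s, as.numeric(0:7))

  # a 2-second seizure shorter than the window: every overlapping window dropped
  short <- segment_sliding(sig, seizure_annotations(4, 6), window_s = 3, step_s = 1)
  expect_true(all(short$label == "non-seizure"))
  expect_equal(short$start_s, c(0, 1, 6, 7))

  expect_error(segment_sliding(sig, NULL, window_s = 20), "longer than")
  expect_error(segment_sliding(sig, NULL, window_s = 3, step_s = 0), "positive")
})

test_that("emitted windows never mix annotated and unannotated samples", {
  rate <- 64
  sig <- eeg_signal(matrix(rnorm(30 * rate), ncol = 1), rate = rate)
  ann <- seizure_annotations(c(3, 11.5, 20), c(8, 14, 27))
  segs <- segment_sliding(sig, ann, window_s = 2, step_s = 0.5)
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$start_s[i]
    t1 <- t0 + 2
    inside <- any(ann$start_s <= t0 & t1 <= ann$end_s)
    outside <- all(t1 <= ann$start_s | t0 >= ann$end_s)
    expect_true(xor(inside, outside))
    expect_equal(segs$label[i], if (inside) "seizure" else "non-seizure")
  }
  # step = window tiles the recording exactly
  tiled <- segment_sliding(sig, NULL, window_s = 2, step_s = 2)
  expect_equal(nrow(tiled), floor(30 / 2))
})

test_that("class balancing downsamples the majority class reproducibly", {
  rate <- 50
  sig <- eeg_signal(matrix(rnorm(20 * rate), ncol = 1), rate = rate)
  ann <- seizure_annotations(0, 5)
  raw <- segment_sliding(sig, ann, window_s = 1, step_s = 1)
  bal <- segment_sliding(sig, ann, window_s = 1, step_s = 1,
                         balance = TRUE, seed = 4)
  counts <- table(bal$label)
  expect_equal(unname(counts["seizure"]), unname(counts["non-seizure"]))
  expect_lt(nrow(bal), nrow(raw))
  bal2 <- segment_sliding(sig, ann, window_s = 1, step_s = 1,
                          balance = TRUE, seed = 4)
  expect_equal(bal$start_s, bal2$start_s)
})

test_that("segment sets round-trip through the CSV manifest layout", {
  ds <- gen_dataset(synth_config(n_per_class = 3, duration_s = 1, seed = 5))
  dir <- tempfile()
  write_segments(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_segments(dir)
  expect_equal(back$segment_id, ds$segment_id)
  expect_equal(back$label, ds$label)
  for (i in seq_len(nrow(ds))) {
    expect_equal(back$signal[[i]]$samples, ds$signal[[i]]$samples,
                 tolerance = 1e-12)
    expect_equal(back$signal[[i]]$rate, ds$signal[[i]]$rate)
  }
})
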