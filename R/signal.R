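#' EEG signal objects
#'
#' An `eeg_signal` is the unit every other function in the package consumes:
#' a uniformly sampled real-valued series (one column per channel) together
#' with its sampling rate in Hz and ordered channel labels.
#'
#' @param samples Numeric vector (single channel) or numeric matrix with one
#'   column per channel and one row per time point, in microvolts.
#' @param rate Sampling rate in Hz (samples per second per channel).
#' @param channels Optional character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `eeg_signal`: a list with elements `samples`
#'   (n x C numeric matrix), `rate`, and `channels`.
#' @export
#' @examples
#' s <- eeg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 256)), rate = 256)
#' n_samples(s)
eeg_signal <- function(samples, rate, channels = NULL) {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (nrow(samples) < 2) abort("an eeg_signal needs at least 2 samples per channel.")
  if (!all(is.finite(samples))) abort("all samples must be finite.")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channels) != ncol(samples)) {
    abort("`channels` must have one label per column of `samples`.")
  }
  structure(
    list(samples = samples, rate = as.numeric(rate), channels = as.character(channels)),
    class = "eeg_signal"
  )
}

#' @rdname eeg_signal
#' @param x,object An `eeg_signal`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname eeg_signal
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname eeg_signal
#' @export
duration_s <- function(x) n_samples(x) / x$rate

#' @param ... Unused.
#' @rdname eeg_signal
#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf(
    "<eeg_signal: %d channel(s) x %d samples @ %.6g Hz (%.3g s)>\n",
    n_channels(x), n_samples(x), x$rate, duration_s(x)
  ))
  invisible(x)
}

#' @rdname eeg_signal
#' @export
as_tibble.eeg_signal <- function(x, ...) {
  tb <- as_tibble(as.data.frame(x$samples), .name_repair = "minimal")
  names(tb) <- x$channels
  bind_cols(tibble(time_s = (seq_len(n_samples(x)) - 1) / x$rate), tb)
}

#' Read a Bonn-style plain-text EEG segment
#'
#' Bonn-style segments are single-channel text files with one amplitude value
#' per line (the classic university-hospital segments are 4097 samples at
#' 173.61 Hz, i.e. 23.6 s).
#'
#' @param path Path to a text file with one numeric value per line.
#' @param rate Sampling rate in Hz; defaults to 173.61.
#' @return An [eeg_signal] with a single channel.
#' @export
read_bonn_segment <- function(path, rate = 173.61) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) abort(sprintf("empty Bonn segment file: %s", path))
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals) & trimws(lines) != "NA")
  if (length(bad) > 0) {
    abort(sprintf(
      "non-numeric value %s at line %d of %s",
      encodeString(lines[bad[1]], quote = "'"), bad[1], path
    ))
  }
  eeg_signal(vals, rate = rate)
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(raw, what) {
  s <- trimws(rawToChar(raw))
  v <- suppressWarnings(as.numeric(s))
  if (length(v) != 1 || is.na(v)) {
    abort(sprintf("malformed EDF header: field '%s' is not numeric ('%s')", what, s))
  }
  v
}

#' Write a signal to an EDF file
#'
#' Writes a standard EDF (16-bit) file with one data record holding the whole
#' signal. Each channel is scaled independently to the full digital range, so
#' round-tripping preserves amplitudes within the format's 16-bit
#' quantization.
#'
#' @param signal An [eeg_signal].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path) {
  stopifnot(inherits(signal, "eeg_signal"))
  ns <- n_channels(signal)
  n <- n_samples(signal)
  dur <- n / signal$rate
  pm <- apply(abs(signal$samples), 2, max)
  pm[pm == 0] <- 1
  dig <- round(sweep(signal$samples, 2, pm, "/") * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("synthetic", 80)
  wr("ceemdx export", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(1L, 8)
  wr(format(dur, digits = 7), 8)
  wr(ns, 4)
  for (lab in signal$channels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pm[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pm[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32767L, 8)
  for (i in seq_len(ns)) wr(32767L, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    writeBin(as.integer(dig[, i]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF (European Data Format) recording
#'
#' Parses a standard 16-bit EDF file into an [eeg_signal]. The sampling rate
#' is taken from the header (samples-per-record / record duration) and channel
#' labels are preserved in file order. All channels must share one sampling
#' rate; mixed-rate layouts are rejected.
#'
#' @param path Path to an EDF file.
#' @return A (possibly multi-channel) [eeg_signal].
#' @export
read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) abort(sprintf("malformed EDF file (too short): %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readBin(con, "raw", n = w)
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- edf_num(rd(8), "header bytes")
  rd(44)
  n_rec <- edf_num(rd(8), "number of data records")
  rec_dur <- edf_num(rd(8), "record duration")
  ns <- edf_num(rd(4), "number of signals")
  if (ns < 1 || ns != round(ns)) abort("malformed EDF header: bad signal count")
  if (sz < 256 * (ns + 1)) abort(sprintf("malformed EDF file (truncated header): %s", path))
  rd_field <- function(w, numeric = FALSE, what = "") {
    out <- vector("list", ns)
    for (i in seq_len(ns)) out[[i]] <- rd(w)
    if (numeric) vapply(out, edf_num, numeric(1), what = what)
    else vapply(out, function(r) trimws(rawToChar(r)), character(1))
  }
  labels <- rd_field(16)
  rd_field(80) # transducer
  rd_field(8) # physical dimension
  phys_min <- rd_field(8, TRUE, "physical minimum")
  phys_max <- rd_field(8, TRUE, "physical maximum")
  dig_min <- rd_field(8, TRUE, "digital minimum")
  dig_max <- rd_field(8, TRUE, "digital maximum")
  rd_field(80) # prefiltering
  nsamp <- rd_field(8, TRUE, "samples per record")
  rd_field(32)

  if (rec_dur <= 0) abort("malformed EDF header: non-positive record duration")
  rates <- nsamp / rec_dur
  if (length(unique(rates)) != 1) {
    abort(sprintf(
      "unsupported EDF layout: channels have differing sampling rates (%s)",
      paste(unique(rates), collapse = ", ")
    ))
  }
  expected <- 256 * (ns + 1) + n_rec * 2 * sum(nsamp)
  if (sz != expected) {
    abort(sprintf(
      "malformed EDF file: size %d does not match header (expected %d): %s",
      sz, expected, path
    ))
  }
  if (header_bytes != 256 * (ns + 1)) {
    abort("malformed EDF header: header-bytes field inconsistent with signal count")
  }

  chunks <- matrix(vector("list", n_rec * ns), nrow = ns)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      chunks[[i, r]] <- readBin(con, "integer", n = nsamp[i], size = 2,
                                signed = TRUE, endian = "little")
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - scale * dig_max
  samples <- vapply(
    seq_len(ns),
    function(i) unlist(chunks[i, ]) * scale[i] + offset[i],
    numeric(n_rec * nsamp[1])
  )
  eeg_signal(samples, rate = rates[1], channels = labels)
}

#' Expected sample count of a fixed-duration segment
#'
#' Fractional counts (e.g. 173.61 Hz x 23.6 s = 4097.196) are floored, so the
#' classic single-channel segment holds 4097 points and a 3-second, 23-channel
#' window at 256 Hz holds 17,664.
#'
#' @param rate Sampling rate in Hz.
#' @param duration Segment duration in seconds.
#' @param n_channels Number of channels.
#' @return Integer total number of sampled values in the segment.
#' @export
#' @examples
#' expected_segment_points(173.61, 23.6, 1) # 4097
#' expected_segment_points(256, 3, 23) # 17664
expected_segment_points <- function(rate, duration, n_channels = 1) {
  if (rate <= 0 || duration <= 0 || n_channels < 1) {
    abort("`rate`, `duration` must be positive and `n_channels` >= 1.")
  }
  as.integer(floor(rate * duration) * n_channels)
}

#' Flatten a multi-channel segment into one series
#'
#' Ensemble decomposition operates on a single series; a multi-channel window
#' is treated as one concatenated series. Channel-major order (the default)
#' appends channels end-to-end; time-major interleaves samples across
#' channels.
#'
#' @param segment An [eeg_signal].
#' @param order `"channel"` (channel-major, default) or `"time"` (time-major).
#' @return A single-channel [eeg_signal] of length `n x n_channels`.
#' @export
flatten_multichannel <- function(segment, order = c("channel", "time")) {
  order <- arg_match(order)
  if (n_channels(segment) == 1) return(segment)
  v <- if (order == "channel") as.vector(segment$samples) else as.vector(t(segment$samples))
  eeg_signal(v, rate = segment$rate, channels = "flat")
}

#' Seizure annotation table
#'
#' @param start_s,end_s Numeric vectors of seizure onset/offset times in
#'   seconds from recording start. Intervals are half-open `[start, end)` on a
#'   0-based time axis.
#' @return A tibble with columns `start_s`, `end_s`, `label`.
#' @export
seizure_annotations <- function(start_s = numeric(), end_s = numeric()) {
  if (length(start_s) != length(end_s)) abort("start_s and end_s must have equal length.")
  if (any(start_s < 0) || any(end_s <= start_s)) {
    abort("annotations need 0 <= start_s < end_s.")
  }
  tibble(start_s = as.numeric(start_s), end_s = as.numeric(end_s), label = "seizure")
}

#' Read seizure annotations from a text sidecar
#'
#' One annotation per line, `start_s<TAB>end_s`.
#'
#' @param path Path to the sidecar file.
#' @return An annotation tibble as from [seizure_annotations()].
#' @export
read_annotations <- function(path) {
  tb <- utils::read.table(path, sep = "\t", col.names = c("start_s", "end_s"))
  seizure_annotations(tb$start_s, tb$end_s)
}

#' Cut labeled fixed-length sliding-window segments
#'
#' Slides a `window_s`-second window over a recording in `step_s` steps. A
#' window is labeled `"seizure"` if it lies entirely inside an annotated
#' seizure interval and `"non-seizure"` if it lies entirely outside all
#' intervals; windows straddling a boundary are discarded, so no emitted
#' segment mixes states.
#'
#' @param signal An [eeg_signal] recording.
#' @param annotations Annotation tibble from [seizure_annotations()] /
#'   [read_annotations()], or `NULL` for a seizure-free recording.
#' @param window_s Window length in seconds; `window_s * rate` must be a whole
#'   number of samples. Default 3 s.
#' @param step_s Step between consecutive window starts in seconds (default
#'   1 s, i.e. overlapping windows).
#' @param balance If `TRUE`, downsample the majority class to the minority
#'   class size (seeded).
#' @param seed RNG seed used only when `balance = TRUE`.
#' @return A segment-set tibble with columns `segment_id`, `label`, `start_s`,
#'   and `signal` (list-column of [eeg_signal] windows), carrying `window_s`
#'   and `rate` attributes.
#' @export
segment_sliding <- function(signal, annotations = NULL, window_s = 3, step_s = 1,
                            balance = FALSE, seed = 1L) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (step_s <= 0) abort("`step_s` must be positive.")
  win_n <- window_s * signal$rate
  if (abs(win_n - round(win_n)) > 1e-6 || win_n < 1) {
    abort("`window_s * rate` must be a positive whole number of samples.")
  }
  win_n <- as.integer(round(win_n))
  n <- n_samples(signal)
  if (win_n > n) abort("window longer than recording.")
  step_n <- max(1L, as.integer(round(step_s * signal$rate)))
  starts <- seq.int(1L, n - win_n + 1L, by = step_n)
  eps <- 1e-9

  label_window <- function(t0, t1) {
    if (is.null(annotations) || nrow(annotations) == 0) return("non-seizure")
    inside <- annotations$start_s <= t0 + eps & t1 <= annotations$end_s + eps
    if (any(inside)) return("seizure")
    overlap <- t0 < annotations$end_s - eps & annotations$start_s < t1 - eps
    if (any(overlap)) return(NA_character_)
    "non-seizure"
  }

  rows <- map(starts, function(i) {
    t0 <- (i - 1) / signal$rate
    lab <- label_window(t0, t0 + window_s)
    if (is.na(lab)) return(NULL)
    seg <- eeg_signal(signal$samples[i:(i + win_n - 1L), , drop = FALSE],
                      rate = signal$rate, channels = signal$channels)
    tibble(label = lab, start_s = t0, signal = list(seg))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(label = character(), start_s = numeric(), signal = list())
  }
  if (balance && nrow(out) > 0) {
    counts <- table(out$label)
    if (length(counts) == 2 && min(counts) > 0) {
      k <- min(counts)
      keep <- withr_seed(seed, {
        unlist(lapply(split(seq_len(nrow(out)), out$label),
                      function(ix) if (length(ix) > k) sample(ix, k) else ix))
      })
      out <- out[sort(keep), ]
    }
  }
  out <- mutate(out,
                segment_id = sprintf("seg_%04d", dplyr::row_number()),
                .before = 1)
  structure(out, window_s = window_s, rate = signal$rate)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write / read a segment set as a CSV manifest plus text files
#'
#' The manifest (`manifest.csv`) records segment id, label, file name,
#' sampling rate, channel count and window length; each segment is stored as a
#' plain-text file with one row per time point and one whitespace-separated
#' column per channel.
#'
#' @param segments A segment-set tibble ([segment_sliding()] / [gen_dataset()]).
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or a segment-set tibble (read).
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(segments$segment_id, ".txt")
  for (i in seq_len(nrow(segments))) {
    utils::write.table(segments$signal[[i]]$samples,
                       file.path(dir, files[i]),
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- tibble(
    segment_id = segments$segment_id,
    label = segments$label,
    file = files,
    rate = map_dbl(segments$signal, function(s) s$rate),
    n_channels = map_dbl(segments$signal, n_channels)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  segs <- map(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(file.path(dir, manifest$file[i])))
    dimnames(m) <- NULL
    eeg_signal(m, rate = manifest$rate[i])
  })
  tibble(
    segment_id = manifest$segment_id,
    label = manifest$label,
    signal = segs
  )
}
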