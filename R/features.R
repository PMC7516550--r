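#' Extract the full feature vector of one segment
#'
#' Computes the catalogue plus the six entropy features on the raw series,
#' each IMF, and the residue of its decomposition; names are prefixed with
#' the component (`raw__`, `imf_1__`, ..., `residue__`), so a decomposition
#' into M IMFs yields `M + 2` component blocks. Per-feature failures surface
#' as `NA`, never as an abort.
#'
#' @param decomp An `eeg_decomposition` of the (flattened) raw series, or
#'   `NULL` to extract from the raw series only.
#' @param raw The segment the decomposition was derived from: an
#'   [eeg_signal] (multi-channel segments are flattened channel-major) or a
#'   numeric vector.
#' @param cfg An [entropy_config()].
#' @param rate Sampling rate in Hz when `raw` is a bare vector.
#' @return A one-row tibble of named features.
#' @export
extract_all <- function(decomp, raw, cfg = entropy_config(), rate = NULL) {
  if (inherits(raw, "eeg_signal")) {
    rate <- raw$rate
    raw <- as.vector(flatten_multichannel(raw)$samples)
  }
  if (is.null(rate)) abort("supply `rate` when `raw` is a bare numeric vector.")
  components <- c(
    list(raw = raw),
    if (!is.null(decomp)) {
      if (decomp$source_n != length(raw)) {
        abort("decomposition length does not match the raw series.")
      }
      c(setNames(decomp$imfs, paste0("imf_", seq_along(decomp$imfs))),
        list(residue = decomp$residue))
    }
  )
  blocks <- imap(components, function(series, comp) {
    vals <- c(catalogue_features(series, rate), entropy_features(series, rate, cfg))
    setNames(vals, paste0(comp, "__", names(vals)))
  })
  as_tibble(as.list(unlist(unname(blocks))))
}

#' Split a feature name into component and feature
#'
#' @param names Character vector of `<component>__<feature>` names.
#' @return A tibble with columns `name`, `component`, `feature`, `domain`.
#' @export
parse_feature_names <- function(names) {
  component <- sub("__.*$", "", names)
  feature <- sub("^[^_]+(_[0-9]+)?__", "", names)
  reg <- feature_registry()
  tibble(
    name = names, component = component, feature = feature,
    domain = reg$domain[match(feature, reg$feature)]
  )
}

#' Build a feature table from a segment set
#'
#' Runs the decomposition stage (per segment, after channel-major flattening
#' for multi-channel windows) and [extract_all()] over a segment set,
#' producing the samples-by-features table the classifier consumes.
#'
#' @param segments Segment-set tibble ([segment_sliding()], [gen_dataset()],
#'   [read_segments()]).
#' @param method Decomposition method: `"ceemd"` (default), `"eemd"`,
#'   `"emd"`, or `"none"` for raw-signal features only.
#' @param dconfig A [decompose_config()]. Each segment's ensemble is seeded
#'   from `dconfig$seed` plus the segment index, so extraction is
#'   deterministic and independent of segment order subsets.
#' @param ecfg An [entropy_config()].
#' @return A feature-table tibble: `segment_id`, `label`, then one column per
#'   feature; rectangular with a fixed column order.
#' @export
extract_features <- function(segments, method = c("ceemd", "eemd", "emd", "none"),
                             dconfig = decompose_config(), ecfg = entropy_config()) {
  method <- arg_match(method)
  rows <- map(seq_len(nrow(segments)), function(i) {
    sig <- segments$signal[[i]]
    flat <- flatten_multichannel(sig)
    series <- as.vector(flat$samples)
    dec <- switch(
      method,
      none = NULL,
      emd = emd(series, dconfig),
      eemd = ,
      ceemd = {
        cfg_i <- dconfig
        cfg_i$seed <- dconfig$seed + i * 1000L
        if (method == "ceemd") ceemd(series, cfg_i) else eemd(series, cfg_i)
      }
    )
    extract_all(dec, series, ecfg, rate = sig$rate)
  })
  feat <- bind_rows(rows)
  bind_cols(
    tibble(segment_id = segments$segment_id, label = segments$label),
    feat
  )
}

#' Write / read a feature table as CSV
#'
#' @param table Feature-table tibble.
#' @param path CSV path with a header row.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
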