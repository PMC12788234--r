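# Feature provider: maps window indices to model inputs.
#
# Scalograms are the expensive representation (30 x 1200 x 8 doubles per
# window), so the provider can precompute them once for a designated subset
# (training/validation windows) into a uint16-quantised store backed by a
# raw vector,
# and computes everything else on the fly in batches. Spectra are small and
# always precomputed.

window_key <- function(df) paste(df$trial_idx, df$start_ms, sep = "@")

#' Collect labelled windows from a set of trials
#'
#' Preprocesses each trial (high-pass filter then percentile normalisation)
#' and segments it; returns the preprocessed trials plus one window table.
#'
#' @param trials List of `semg_trial`.
#' @param wcfg A [windowing_config()].
#' @param preprocess Apply [preprocess_trial()] first (default TRUE).
#' @return List with `trials` (preprocessed) and `windows` (data.frame with
#'   `trial_idx`, `start_ms`, `label`, `trial_id`, `subject_id`).
#' @export
collect_windows <- function(trials, wcfg = windowing_config(),
                            preprocess = TRUE) {
  if (preprocess) trials <- lapply(trials, preprocess_trial)
  wins <- lapply(seq_along(trials), function(i) {
    w <- segment_windows(trials[[i]], wcfg)
    if (nrow(w)) w$trial_idx <- i
    w
  })
  windows <- do.call(rbind, wins[vapply(wins, nrow, 1L) > 0])
  rownames(windows) <- NULL
  list(trials = trials, windows = windows)
}

raw_window_batch <- function(trials, windows, rows, ws) {
  B <- length(rows)
  arr <- array(0, c(ws, 8, B))
  for (j in seq_len(B)) {
    w <- rows[j]
    tr <- trials[[windows$trial_idx[w]]]
    i0 <- round(windows$start_ms[w] * tr$fs / 1000)
    arr[, , j] <- tr$samples[i0 + seq_len(ws), ]
  }
  arr
}

#' Build a feature provider over a window table
#'
#' @param trials Preprocessed trials (see [collect_windows()]).
#' @param windows Window table from [collect_windows()].
#' @param wcfg The [windowing_config()] used for segmentation.
#' @param cache_rows Row indices whose scalograms are precomputed into the
#'   quantised store (typically training + validation windows); others are
#'   computed on demand.
#' @param batch Internal batch size for precomputation.
#' @return A `feature_provider` environment.
#' @export
feature_provider <- function(trials, windows, wcfg = windowing_config(),
                             cache_rows = NULL, batch = 64L) {
  pv <- new.env(parent = emptyenv())
  pv$trials <- trials
  pv$windows <- windows
  pv$wcfg <- wcfg
  ws <- wcfg$window_ms * wcfg$fs / 1000
  pv$ws <- ws
  n <- nrow(windows)
  nb <- ws %/% 2 + 1
  pv$spectra <- array(0, c(nb, 8, n))
  for (s in seq(1, n, by = batch)) {
    rows <- s:min(n, s + batch - 1)
    raw <- raw_window_batch(trials, windows, rows, ws)
    pv$spectra[, , rows] <- fft_batch_internal(raw)
  }
  pv$elems <- ws * 30 * 8
  pv$cache_pos <- rep(NA_integer_, n)
  if (!is.null(cache_rows)) {
    # scalograms quantised to uint16 with one scale factor per (band, window);
    # relative error <= 1/65535 of the band maximum, negligible downstream
    cache_rows <- sort(unique(cache_rows))
    pv$cache_pos[cache_rows] <- seq_along(cache_rows) - 1L
    pv$cache <- raw(2 * pv$elems * length(cache_rows))
    pv$qscales <- matrix(1, 30, length(cache_rows))
    for (s in seq(1, length(cache_rows), by = batch)) {
      rows <- cache_rows[s:min(length(cache_rows), s + batch - 1)]
      raw <- raw_window_batch(trials, windows, rows, ws)
      tf <- cwt_batch_internal(raw)
      cpp_qcache_store(pv$cache, tf, pv$qscales, ws, 30L, 8L, length(rows),
                       pv$cache_pos[rows[1]])
      rm(raw, tf)
      if (s %% 1024 == 1) gc(verbose = FALSE)
    }
    gc(verbose = FALSE)
    cpp_release_memory()
  } else {
    pv$cache <- NULL
  }
  class(pv) <- "feature_provider"
  pv
}

#' Fetch model inputs for a set of window rows
#'
#' @param pv A [feature_provider()].
#' @param rows Window row indices.
#' @param dense Return the scalograms as a dense double array even when the
#'   rows are cached (needed by data-level fusion); otherwise cached rows
#'   are returned as a lightweight reference into the quantised store.
#' @return List with `tf` `(ws, 30, 8, B)` scalograms and `spec`
#'   `(bins, 8, B)` spectra.
#' @export
get_features <- function(pv, rows, dense = FALSE) {
  pos <- pv$cache_pos[rows]
  if (!is.null(pv$cache) && !anyNA(pos)) {
    if (!dense) {
      # hand the encoder a reference into the quantised store; stage 1
      # dequantises on the fly without materialising the double array
      tf <- structure(list(cache = pv$cache, scales = pv$qscales,
                           pos = as.numeric(pos),
                           dims = c(pv$ws, 30L, 8L, length(rows))),
                      class = "qbatch")
      return(list(tf = tf, spec = pv$spectra[, , rows, drop = FALSE]))
    }
    tf <- cpp_qcache_fetch(pv$cache, pv$qscales, as.numeric(pos), pv$ws,
                           30L, 8L)
  } else {
    raw <- raw_window_batch(pv$trials, pv$windows, rows, pv$ws)
    tf <- cwt_batch_internal(raw)
  }
  list(tf = tf, spec = pv$spectra[, , rows, drop = FALSE])
}
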