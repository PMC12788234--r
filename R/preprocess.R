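# Trial-level preprocessing and window-level transforms.
#
# Pipeline order is fixed: high-pass filter -> percentile normalisation ->
# sliding-window segmentation -> CWT / FFT transforms. Filtering and
# normalisation are applied to whole trials so window edges are clean and
# amplitudes stay comparable across windows of one trial.

#' Windowing configuration
#'
#' @param window_ms Window length W in ms (default 1200).
#' @param step_ms Sliding step S in ms (default 200).
#' @param plabel_ms Prediction time: the look-ahead between window end and
#'   the time whose motion event labels the window (default 100 ms).
#' @param fs Sampling frequency in Hz (1000).
#' @return A `windowing_config` list.
#' @export
windowing_config <- function(window_ms = 1200, step_ms = 200,
                             plabel_ms = 100, fs = 1000) {
  stopifnot(window_ms > 0, step_ms > 0, plabel_ms >= 0, fs > 0)
  if (window_ms * fs / 1000 != round(window_ms * fs / 1000)) {
    stop("window_ms * fs / 1000 must be integral")
  }
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 plabel_ms = plabel_ms, fs = fs),
            class = "windowing_config")
}

#' Read/write a windowing configuration as YAML
#' @param path YAML file.
#' @return [windowing_config()] for the reader; invisible path for the writer.
#' @export
read_windowing_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("window_ms", "step_ms", "plabel_ms", "fs")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(windowing_config, y)
}

#' @rdname read_windowing_config
#' @param cfg A [windowing_config()].
#' @export
write_windowing_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

as_samples <- function(x) {
  if (inherits(x, "semg_trial")) x$samples else as.matrix(x)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Applied per channel over the whole trial (before segmentation), as a
#' forward-backward pass so the filter has zero phase and labels stay
#' aligned. Removes motion artefact and baseline drift below `cutoff`.
#'
#' @param trial A `semg_trial` or time x channels matrix.
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @param order Filter order (default 4).
#' @return Same type as the input, filtered.
#' @export
highpass_filter <- function(trial, cutoff = 20, order = 4) {
  x <- as_samples(trial)
  fs <- if (inherits(trial, "semg_trial")) trial$fs else 1000
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (nrow(x) < 3 * order) {
    stop("trial too short for filter warm-up (need at least ", 3 * order,
         " samples)")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  y <- apply(x, 2, function(ch) as.numeric(signal::filtfilt(bf, ch)))
  if (inherits(trial, "semg_trial")) {
    trial$samples <- y
    colnames(trial$samples) <- colnames(x)
    trial
  } else {
    y
  }
}

#' 99th-percentile amplitude normalisation
#'
#' Divides each channel by the 99th percentile of its absolute amplitude
#' (linear interpolation between order statistics), so P99(|channel|) = 1
#' afterwards. Robust to outliers compared with max-normalisation.
#'
#' @param trial A `semg_trial` or time x channels matrix.
#' @param p Percentile (default 0.99).
#' @return Same type as the input, normalised.
#' @export
normalize_percentile <- function(trial, p = 0.99) {
  x <- as_samples(trial)
  q <- apply(abs(x), 2, quantile, probs = p, names = FALSE, type = 7)
  bad <- which(q == 0)
  if (length(bad)) {
    stop("channel(s) with zero 99th-percentile amplitude: ",
         paste(bad, collapse = ", "))
  }
  y <- sweep(x, 2, q, "/")
  if (inherits(trial, "semg_trial")) {
    trial$samples <- y
    trial
  } else {
    y
  }
}

#' Standard trial preprocessing (filter then normalise)
#' @inheritParams highpass_filter
#' @return The preprocessed trial.
#' @export
preprocess_trial <- function(trial, cutoff = 20, order = 4) {
  normalize_percentile(highpass_filter(trial, cutoff, order))
}

# label lookup with half-open events [start, end); a label time exactly at an
# event boundary takes the later event; the trial end belongs to the last
# event. Returns NA for times in a gap.
event_label_at <- function(events, t_ms, trial_end_ms) {
  if (t_ms == trial_end_ms) {
    i <- which(events$end_ms == trial_end_ms)
    if (length(i)) return(events$label[tail(i, 1)])
  }
  i <- which(events$start_ms <= t_ms & t_ms < events$end_ms)
  if (length(i)) events$label[i[1]] else NA_integer_
}

#' Segment a trial into overlapping labelled windows
#'
#' Windows start at 0, S, 2S, ...; a window is emitted iff its label time
#' (start + W + Plabel) falls inside the trial and inside a motion event.
#' The label is the class of the event active at the label time, i.e. the
#' movement the subject performs Plabel ms after the window ends.
#'
#' @param trial A `semg_trial`.
#' @param cfg A [windowing_config()].
#' @return data.frame with one row per retained window: `start_ms`,
#'   `label_time_ms`, `label`, `trial_id`, `subject_id`. Attributes:
#'   `n_positions` (sliding positions before label-time pruning) and
#'   `skipped` (windows dropped because the label time hit an event gap).
#' @export
segment_windows <- function(trial, cfg = windowing_config()) {
  L <- nrow(trial$samples) * 1000 / trial$fs
  W <- cfg$window_ms
  S <- cfg$step_ms
  P <- cfg$plabel_ms
  if (L < W) stop("trial duration (", L, " ms) shorter than window (", W,
                  " ms)")
  starts <- seq(0, L - W, by = S)
  label_times <- starts + W + P
  inside <- label_times <= L
  starts <- starts[inside]
  label_times <- label_times[inside]
  labels <- vapply(label_times, function(t)
    event_label_at(trial$events, t, L), integer(1))
  skipped <- sum(is.na(labels))
  keep <- !is.na(labels)
  out <- data.frame(
    start_ms = starts[keep],
    label_time_ms = label_times[keep],
    label = labels[keep],
    trial_id = trial$trial_id,
    subject_id = trial$subject_id,
    stringsAsFactors = FALSE
  )
  attr(out, "n_positions") <- floor((L - W) / S) + 1
  attr(out, "skipped") <- skipped
  attr(out, "config") <- cfg
  out
}

#' Extract the raw samples of one window
#'
#' @param trial A `semg_trial`.
#' @param start_ms Window start in ms.
#' @param cfg A [windowing_config()].
#' @return `window_ms * fs / 1000` x 8 matrix.
#' @export
window_raw <- function(trial, start_ms, cfg = windowing_config()) {
  n <- cfg$window_ms * trial$fs / 1000
  i0 <- round(start_ms * trial$fs / 1000)
  trial$samples[i0 + seq_len(n), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Continuous wavelet transform (complex Morlet)
# ---------------------------------------------------------------------------

#' Scalogram centre frequencies
#'
#' 30 log-spaced centre frequencies spanning `fmax` down to `fmin`
#' (descending, so band 1 is the highest frequency).
#'
#' @param n_scales Number of scales (default 30).
#' @param fmin,fmax Frequency span in Hz (defaults 20 and 450, the sEMG
#'   band).
#' @return Numeric vector of centre frequencies in Hz.
#' @export
cwt_center_freqs <- function(n_scales = 30, fmin = 20, fmax = 450) {
  exp(seq(log(fmax), log(fmin), length.out = n_scales))
}

# Precomputed wavelet filter bank: real spectra of the L2-normalised complex
# Morlet at each scale, on an nfft grid. Cached per (nt, fs, scales) key.
cwt_filterbank_env <- new.env(parent = emptyenv())

cwt_filterbank <- function(nt, fs = 1000, n_scales = 30, fmin = 20,
                           fmax = 450, bandwidth = 1.5, center = 1.0) {
  key <- paste(nt, fs, n_scales, fmin, fmax, bandwidth, center, sep = "_")
  hit <- cwt_filterbank_env[[key]]
  if (!is.null(hit)) return(hit)
  freqs <- cwt_center_freqs(n_scales, fmin, fmax)
  scales <- center * fs / freqs
  # pad so the slowest wavelet's support does not wrap around
  support <- ceiling(max(scales) * sqrt(16 * bandwidth))
  nfft <- 2^ceiling(log2(nt + 2 * support))
  f <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) / nfft # cycles per sample
  wspec <- vapply(scales, function(s)
    sqrt(s) * exp(-pi^2 * bandwidth * (s * f - center)^2), numeric(nfft))
  out <- list(wspec = wspec, center_freqs = freqs, scales = scales,
              nfft = nfft)
  cwt_filterbank_env[[key]] <- out
  out
}

#' Continuous wavelet scalogram of a window
#'
#' Complex Morlet CWT (centre frequency 1.0, bandwidth 1.5) with 30
#' log-spaced scales whose centre frequencies span 20-450 Hz (descending),
#' evaluated by FFT convolution with L2-normalised wavelets; returns
#' coefficient magnitudes.
#'
#' @param x A window: time x channels matrix (or a labelled-window list with
#'   a `raw` element).
#' @param n_scales,fmin,fmax Scale set (see [cwt_center_freqs()]).
#' @param bandwidth,center Morlet shape parameters.
#' @param fs Sampling frequency in Hz.
#' @return Array `(n_scales, time, channels)` of nonnegative magnitudes with
#'   attribute `center_freqs`.
#' @export
cwt_transform <- function(x, n_scales = 30, fmin = 20, fmax = 450,
                          bandwidth = 1.5, center = 1.0, fs = 1000) {
  if (is.list(x) && !is.null(x$raw)) x <- x$raw
  x <- as.matrix(x)
  nt <- nrow(x)
  nc <- ncol(x)
  fb <- cwt_filterbank(nt, fs, n_scales, fmin, fmax, bandwidth, center)
  out <- cpp_cwt_batch(x, fb$wspec) # (nt, n_scales, nc)
  dim(out) <- c(nt, n_scales, nc)
  out <- aperm(out, c(2, 1, 3))
  attr(out, "center_freqs") <- fb$center_freqs
  out
}

# Batched CWT for the model: xarr (nt, channels, B) -> (nt, scales, channels, B)
cwt_batch_internal <- function(xarr, n_scales = 30, fmin = 20, fmax = 450,
                               fs = 1000) {
  d <- dim(xarr)
  fb <- cwt_filterbank(d[1], fs, n_scales, fmin, fmax)
  xm <- xarr
  dim(xm) <- c(d[1], d[2] * d[3])
  out <- cpp_cwt_batch(xm, fb$wspec)
  dim(out) <- c(d[1], n_scales, d[2], d[3])
  out
}

# ---------------------------------------------------------------------------
# FFT spectrum
# ---------------------------------------------------------------------------

#' One-sided FFT magnitude spectrum of a window
#'
#' Real-input transform of the full window, rectangular taper, magnitude
#' (not power). For a 1200-sample window this yields 601 bins at fs/1200 Hz
#' spacing (0 to 500 Hz).
#'
#' @param x A window: time x channels matrix (or labelled-window list).
#' @param fs Sampling frequency in Hz.
#' @return `floor(n/2) + 1` x channels matrix of magnitudes with attribute
#'   `freqs` (Hz).
#' @export
fft_transform <- function(x, fs = 1000) {
  if (is.list(x) && !is.null(x$raw)) x <- x$raw
  x <- as.matrix(x)
  n <- nrow(x)
  nb <- floor(n / 2) + 1
  sp <- abs(mvfft(x))[seq_len(nb), , drop = FALSE]
  attr(sp, "freqs") <- (seq_len(nb) - 1) * fs / n
  sp
}

# Batched spectra: xarr (nt, channels, B) -> (bins, channels, B)
fft_batch_internal <- function(xarr) {
  d <- dim(xarr)
  nb <- floor(d[1] / 2) + 1
  xm <- xarr
  dim(xm) <- c(d[1], d[2] * d[3])
  sp <- abs(mvfft(xm))[seq_len(nb), , drop = FALSE]
  dim(sp) <- c(nb, d[2], d[3])
  sp
}

# ---------------------------------------------------------------------------
# Window container
# ---------------------------------------------------------------------------

#' Save a set of labelled windows to a single container file
#'
#' Stores raw windows `(N, W, 8)`, labels, optional precomputed scalograms
#' and spectra, and the windowing configuration. Round trip is bit exact.
#'
#' @param raw N x W x 8 array of raw windows.
#' @param labels Integer labels, length N.
#' @param cfg The [windowing_config()] used.
#' @param path Output file.
#' @param tfmap,spectrum Optional precomputed `(N, 30, W, 8)` /
#'   `(N, bins, 8)` arrays.
#' @export
write_window_container <- function(raw, labels, cfg, path, tfmap = NULL,
                                   spectrum = NULL) {
  saveRDS(list(format = "ifianet_windows", version = 1L, raw = raw,
               labels = as.integer(labels), config = unclass(cfg),
               tfmap = tfmap, spectrum = spectrum), path)
  invisible(path)
}

#' Read a window container written by [write_window_container()]
#' @param path Container file.
#' @return List with `raw`, `labels`, `config`, `tfmap`, `spectrum`.
#' @export
read_window_container <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "ifianet_windows"))
  obj$config <- do.call(windowing_config, obj$config)
  obj[c("raw", "labels", "config", "tfmap", "spectrum")]
}
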