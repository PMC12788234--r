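# Synthetic multichannel sEMG generator.
#
# Emulates labelled gait-lab recordings: 8 bipolar channels sampled at
# 1000 Hz, organised as trials of ~90 s whose motion-event timeline covers a
# set of locomotion classes. Each class is parameterised by a muscle-synergy
# gain pattern, a spectral support band inside 20-450 Hz and a cadence that
# modulates the amplitude envelope (0 for static postures). Signals are
# band-limited Gaussian noise shaped by that envelope; this reproduces the
# statistical structure the recognition pipeline relies on (per-class band
# power and synergy patterns), not the physiology that created it.

#' The 17-class locomotion label space
#'
#' @return A data.frame with integer `label` (1..17) and a human-readable
#'   `name` for each locomotion mode.
#' @export
motion_class_table <- function() {
  data.frame(
    label = 1:17,
    name = c(
      "Sitting", "Standing", "Walking", "Turn around axes",
      "Ascending stairs", "Descending stairs", "Ascending a ramp",
      "Descending a ramp", "Walking on uneven terrain",
      "Diagonal step in front left", "Diagonal step in front right",
      "Diagonal step backwards right", "Diagonal step backwards left",
      "Small steps in front", "Small steps to the right",
      "Small steps backwards", "Small steps to the left"
    ),
    stringsAsFactors = FALSE
  )
}

#' Muscle channel roster
#'
#' Eight lower-limb muscles in recording order: gluteus maximus (Gmax),
#' rectus femoris (RF), vastus lateralis (VL), biceps femoris (BF),
#' semitendinosus (ST), tibialis anterior (TA), gastrocnemius medialis (GM)
#' and gluteus medius (Gmed).
#'
#' @return Character vector of 8 channel names.
#' @export
muscle_channels <- function() {
  c("Gmax", "RF", "VL", "BF", "ST", "TA", "GM", "Gmed")
}

#' Construct a motion-class specification
#'
#' @param label Integer class id in the 17-label space.
#' @param channel_gains Eight nonnegative amplitude scalars (synergy pattern).
#' @param band_low,band_high Spectral support in Hz, 20 <= low < high <= 450.
#' @param cadence_hz Envelope modulation frequency in Hz; 0 for static
#'   postures.
#' @param noise_floor Nonnegative broadband noise amplitude.
#' @return A `motion_class_spec` list.
#' @export
motion_class_spec <- function(label, channel_gains, band_low, band_high,
                              cadence_hz = 0, noise_floor = 0.03) {
  stopifnot(length(label) == 1L, label %in% 1:17)
  stopifnot(length(channel_gains) == 8L, all(channel_gains >= 0))
  if (!(band_low >= 20 && band_low < band_high && band_high <= 450)) {
    stop("spectral band must satisfy 20 <= band_low < band_high <= 450")
  }
  stopifnot(cadence_hz >= 0, noise_floor >= 0)
  if (cadence_hz > 0 && !any(channel_gains > 0)) {
    stop("dynamic classes need at least one strictly positive channel gain")
  }
  structure(
    list(
      label = as.integer(label),
      channel_gains = as.numeric(channel_gains),
      band_low = band_low, band_high = band_high,
      cadence_hz = cadence_hz, noise_floor = noise_floor
    ),
    class = "motion_class_spec"
  )
}

#' Default motion-class specifications
#'
#' The `"quick"` profile holds five well-separated classes (Sitting,
#' Standing, Walking, Ascending stairs, Small steps in front) sized for CPU
#' experiments; `"full"` covers all 17 classes. Gains rotate the synergy
#' emphasis across the 8 muscles and each class occupies a distinct spectral
#' band, so mean band-power vectors separate clearly between classes. Static
#' postures (cadence 0) use uniformly lower gains than dynamic classes.
#'
#' @param profile `"quick"` or `"full"`.
#' @return Named list of [motion_class_spec()] objects, names = label ids.
#' @export
motion_class_specs <- function(profile = c("quick", "full")) {
  profile <- match.arg(profile)
  gains_for <- function(i) {
    # smooth synergy bump centred on a class-specific muscle, plus baseline
    centre <- ((i * 3) %% 8) + 1
    d <- pmin(abs(seq_len(8) - centre), 8 - abs(seq_len(8) - centre))
    0.35 + 0.95 * exp(-(d / 1.4)^2)
  }
  specs <- vector("list", 17)
  for (i in 1:17) {
    if (i %in% c(1L, 2L)) {
      # static postures: low tonic activation, narrow low bands
      specs[[i]] <- motion_class_spec(
        label = i,
        channel_gains = 0.28 * gains_for(i) / max(gains_for(i)),
        band_low = if (i == 1L) 20 else 45,
        band_high = if (i == 1L) 110 else 170,
        cadence_hz = 0
      )
    } else {
      lo <- 20 + ((i - 3) %% 5) * 28          # 20..132 Hz
      hi <- 210 + ((i * 7) %% 8) * 30         # 210..420 Hz
      specs[[i]] <- motion_class_spec(
        label = i,
        channel_gains = gains_for(i),
        band_low = lo, band_high = hi,
        cadence_hz = 0.8 + 0.18 * ((i * 5) %% 11)
      )
    }
  }
  names(specs) <- as.character(1:17)
  if (profile == "quick") specs[as.character(c(1, 2, 3, 5, 14))] else specs
}

#' Default class subset of the quick profile
#' @return Integer labels of the five quick-profile classes.
#' @export
quick_classes <- function() c(1L, 2L, 3L, 5L, 14L)

# raised-cosine burst envelope, duty cycle 0.5, unit peak
burst_envelope <- function(n, cadence_hz, fs) {
  if (cadence_hz <= 0) return(rep(1, n))
  u <- ((seq_len(n) - 1) / fs * cadence_hz) %% 1
  env <- numeric(n)
  on <- u < 0.5
  env[on] <- 0.5 * (1 - cos(2 * pi * u[on] / 0.5))
  0.15 + env
}

bandlimit_noise <- function(n, band_low, band_high, fs) {
  wn <- rnorm(n)
  bf <- signal::butter(4, c(band_low, band_high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, wn))
}

#' Generate one synthetic sEMG trial
#'
#' Each segment of `segment_plan` is synthesised per channel as
#' `gain * envelope(cadence) * band-limited Gaussian noise + noise_floor *
#' broadband noise`, with a raised-cosine burst envelope (duty cycle 0.5) for
#' dynamic classes and a constant envelope for static postures. Output is
#' deterministic given `seed`.
#'
#' @param specs Named list of [motion_class_spec()] (names = label ids).
#' @param segment_plan data.frame with columns `label`, `duration_ms`, in
#'   trial order.
#' @param seed Integer seed.
#' @param fs Sampling frequency (fixed at 1000 Hz).
#' @param trial_id,subject_id Identifiers stored on the trial.
#' @return A `semg_trial`: list with `samples` (time x 8 matrix), `fs`,
#'   `events` (data.frame start_ms/end_ms/label) and the identifiers.
#' @export
generate_trial <- function(specs, segment_plan, seed, fs = 1000,
                           trial_id = "T01", subject_id = "S01") {
  segment_plan <- as.data.frame(segment_plan)
  stopifnot(all(c("label", "duration_ms") %in% names(segment_plan)))
  if (any(segment_plan$duration_ms <= 0)) stop("segment durations must be > 0")
  missing <- setdiff(as.character(segment_plan$label), names(specs))
  if (length(missing)) {
    stop("no spec for label(s): ", paste(missing, collapse = ", "))
  }
  total_ms <- sum(segment_plan$duration_ms)
  if (total_ms < 1200) {
    stop("trial too short: total duration ", total_ms,
         " ms is below one analysis window (1200 ms)")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_total <- round(total_ms * fs / 1000)
  samples <- matrix(0, n_total, 8)
  events <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                       label = integer(0))
  pos_ms <- 0
  pos <- 0L
  for (i in seq_len(nrow(segment_plan))) {
    lab <- segment_plan$label[i]
    dur <- segment_plan$duration_ms[i]
    sp <- specs[[as.character(lab)]]
    n <- round(dur * fs / 1000)
    env <- burst_envelope(n, sp$cadence_hz, fs)
    for (ch in 1:8) {
      base <- if (sp$channel_gains[ch] > 0) {
        sp$channel_gains[ch] * env * bandlimit_noise(n, sp$band_low,
                                                     sp$band_high, fs)
      } else {
        numeric(n)
      }
      samples[pos + seq_len(n), ch] <- base + sp$noise_floor * rnorm(n)
    }
    events <- rbind(events, data.frame(start_ms = pos_ms,
                                       end_ms = pos_ms + dur,
                                       label = as.integer(lab)))
    pos_ms <- pos_ms + dur
    pos <- pos + n
  }
  colnames(samples) <- muscle_channels()
  structure(
    list(samples = samples, fs = fs, events = events,
         trial_id = trial_id, subject_id = subject_id),
    class = "semg_trial"
  )
}

#' @export
print.semg_trial <- function(x, ...) {
  cat(sprintf("<semg_trial %s/%s: %d samples x %d channels @ %d Hz, %d events>\n",
              x$subject_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$fs, nrow(x$events)))
  invisible(x)
}

perturb_specs <- function(specs, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  lapply(specs, function(sp) {
    sp$channel_gains <- sp$channel_gains * runif(8, 0.8, 1.2)
    lo <- max(20, sp$band_low + runif(1, -10, 10))
    hi <- min(450, sp$band_high + runif(1, -10, 10))
    if (hi - lo < 30) hi <- min(450, lo + 30)
    sp$band_low <- lo
    sp$band_high <- hi
    sp
  })
}

#' Generate a labelled multi-subject, multi-trial dataset
#'
#' Per subject, the base class specifications receive multiplicative gain
#' jitter U(0.8, 1.2) and band-edge jitter of +/- 10 Hz (inter-subject
#' variability). Every trial contains one segment per class in
#' `class_subset`, in a per-trial shuffled order, so each class appears in
#' every trial of every subject.
#'
#' @param n_subjects,trials_per_subject Dataset layout.
#' @param class_subset Nonempty subset of the 17 labels.
#' @param seed Integer seed; output is fully deterministic given it.
#' @param trial_duration_ms Duration of each trial (default 90 s).
#' @param base_specs Optional spec list; defaults to the full profile
#'   restricted to `class_subset`.
#' @return List of `semg_trial` objects.
#' @export
generate_dataset <- function(n_subjects, trials_per_subject, class_subset,
                             seed = 1, trial_duration_ms = 90000,
                             base_specs = NULL) {
  class_subset <- as.integer(class_subset)
  if (length(class_subset) == 0) stop("class_subset must be nonempty")
  if (!all(class_subset %in% 1:17)) {
    stop("class_subset must be a subset of labels 1..17")
  }
  if (is.null(base_specs)) {
    base_specs <- motion_class_specs("full")[as.character(class_subset)]
  }
  nc <- length(class_subset)
  # equal segment durations, remainder distributed to the first segments
  base_dur <- trial_duration_ms %/% nc
  durs <- rep(base_dur, nc)
  rem <- trial_duration_ms - base_dur * nc
  if (rem > 0) durs[seq_len(rem)] <- durs[seq_len(rem)] + 1
  trials <- list()
  for (s in seq_len(n_subjects)) {
    sub_specs <- perturb_specs(base_specs, seed = (seed * 7919 + s * 104729) %%
                                 .Machine$integer.max)
    for (tr in seq_len(trials_per_subject)) {
      tseed <- (seed * 15485863 + s * 32452843 + tr * 49979687) %%
        .Machine$integer.max
      set.seed(as.integer(tseed))
      order_idx <- sample(nc)
      plan <- data.frame(label = class_subset[order_idx], duration_ms = durs)
      trials[[length(trials) + 1L]] <- generate_trial(
        sub_specs, plan, seed = tseed + 1,
        trial_id = sprintf("S%02d_T%02d", s, tr),
        subject_id = sprintf("S%02d", s)
      )
    }
  }
  trials
}

#' Band-power feature vector of a signal segment
#'
#' Mean power per channel in contiguous frequency bands, used to verify class
#' separability of the generator and available as a simple baseline feature.
#'
#' @param x time x channels matrix.
#' @param fs Sampling frequency in Hz.
#' @param edges Band edges in Hz.
#' @return Numeric vector of length `channels * (length(edges) - 1)`.
#' @export
bandpower_features <- function(x, fs = 1000,
                               edges = c(20, 100, 180, 260, 450)) {
  n <- nrow(x)
  sp <- abs(mvfft(as.matrix(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs <= fs / 2
  sp <- sp[keep, , drop = FALSE]
  freqs <- freqs[keep]
  feats <- sapply(seq_len(length(edges) - 1), function(b) {
    idx <- freqs >= edges[b] & freqs < edges[b + 1]
    colMeans(sp[idx, , drop = FALSE])
  })
  as.numeric(feats)
}

# ---------------------------------------------------------------------------
# Trial import/export
# ---------------------------------------------------------------------------

#' Write a trial as a delimited table plus JSON event sidecar
#'
#' @param trial A `semg_trial`.
#' @param path CSV path (columns time_ms, ch1..ch8); the sidecar is written
#'   next to it with extension `.events.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_trial_table <- function(trial, path) {
  df <- data.frame(time_ms = seq_len(nrow(trial$samples)) - 1,
                   trial$samples)
  names(df) <- c("time_ms", paste0("ch", 1:8))
  write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".events.json")
  meta <- list(fs = trial$fs, trial_id = trial$trial_id,
               subject_id = trial$subject_id, events = trial$events)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a trial written by [write_trial_table()]
#' @param path CSV path.
#' @return A `semg_trial`.
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path)
  sidecar <- paste0(sub("\\.csv$", "", path), ".events.json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  samples <- as.matrix(df[, paste0("ch", 1:8)])
  colnames(samples) <- muscle_channels()
  structure(
    list(samples = samples, fs = meta$fs,
         events = as.data.frame(meta$events),
         trial_id = meta$trial_id, subject_id = meta$subject_id),
    class = "semg_trial"
  )
}

#' Write all trials into a single hierarchical container file
#'
#' One group per trial (samples, events, identifiers), serialised as a single
#' file with a bit-exact round trip.
#'
#' @param trials List of `semg_trial`.
#' @param path Output file.
#' @export
write_trial_container <- function(trials, path) {
  groups <- lapply(trials, function(tr) {
    list(samples = tr$samples, fs = tr$fs, events = tr$events,
         trial_id = tr$trial_id, subject_id = tr$subject_id)
  })
  names(groups) <- vapply(trials, function(tr)
    paste(tr$subject_id, tr$trial_id, sep = "/"), character(1))
  saveRDS(list(format = "ifianet_trials", version = 1L, groups = groups),
          path)
  invisible(path)
}

#' Read a container written by [write_trial_container()]
#' @param path Container file.
#' @return List of `semg_trial`.
#' @export
read_trial_container <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "ifianet_trials"))
  lapply(obj$groups, function(g) {
    structure(
      list(samples = g$samples, fs = g$fs, events = g$events,
           trial_id = g$trial_id, subject_id = g$subject_id),
      class = "semg_trial"
    )
  })
}
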