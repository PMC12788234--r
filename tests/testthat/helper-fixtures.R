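# Shared fixtures: hand-built trials, tiny datasets and the lazily built
# quick-profile experiment used by the end-to-end tests.

# a bare trial around a given sample matrix, with one event covering it
make_trial <- function(samples, label = 3L, trial_id = "T01",
                       subject_id = "S01", fs = 1000) {
  structure(
    list(samples = as.matrix(samples), fs = fs,
         events = data.frame(start_ms = 0,
                             end_ms = nrow(samples) * 1000 / fs,
                             label = as.integer(label)),
         trial_id = trial_id, subject_id = subject_id),
    class = "semg_trial"
  )
}

# trial of white noise across 8 channels
noise_trial <- function(n_ms, label = 3L, seed = 1, ...) {
  set.seed(seed)
  make_trial(matrix(rnorm(n_ms * 8), n_ms, 8), label = label, ...)
}

# a small 2-class dataset (10 short trials) for protocol-level tests
tiny_env <- new.env()
tiny_dataset <- function() {
  if (is.null(tiny_env$trials)) {
    tiny_env$trials <- generate_dataset(
      n_subjects = 1, trials_per_subject = 10, class_subset = c(1L, 3L),
      seed = 11, trial_duration_ms = 3000)
  }
  tiny_env$trials
}

# tiny provider over the tiny dataset with everything cached
tiny_experiment <- function() {
  if (is.null(tiny_env$pv)) {
    cw <- collect_windows(tiny_dataset(), windowing_config())
    tiny_env$cw <- cw
    tiny_env$pv <- feature_provider(cw$trials, cw$windows,
                                    cache_rows = seq_len(nrow(cw$windows)))
  }
  tiny_env
}

# The quick-profile study: 1 subject, 10 trials of 90 s over the five quick
# classes (seed 0), fold 1 of the five-fold trial split, scalograms of the
# training and validation windows precomputed once and shared by every
# end-to-end test in the session.
quick_env <- new.env()
quick_experiment <- function() {
  if (!is.null(quick_env$pv)) return(quick_env)
  trials <- generate_dataset(1, 10, quick_classes(), seed = 0)
  cw <- collect_windows(trials, windowing_config())
  split <- kfold_split(cw$trials, seed = 0)
  fold <- split[[1]]
  quick_env$cw <- cw
  quick_env$split <- split
  quick_env$tr <- which(cw$windows$trial_id %in% fold$train)
  quick_env$va <- which(cw$windows$trial_id %in% fold$val)
  quick_env$te <- which(cw$windows$trial_id %in% fold$test)
  quick_env$pv <- feature_provider(cw$trials, cw$windows,
                                   cache_rows = c(quick_env$tr, quick_env$va))
  quick_env
}

# training budget used by the quick-profile runs: the 30-epoch cap with
# early stopping on validation-loss stagnation
quick_tcfg <- function(seed = 0, epochs = 30, batch_size = 128) {
  train_config(epochs = epochs, batch_size = batch_size,
               early_stop_patience = 3, sched_patience = 2,
               min_delta = 1e-3, seed = seed)
}

train_and_eval_quick <- function(variant, seed = 0, epochs = 30,
                                 train_sub = NULL, test_sub = NULL,
                                 batch_size = 128) {
  qe <- quick_experiment()
  w <- qe$cw$windows
  tr <- if (is.null(train_sub)) qe$tr else qe$tr[train_sub]
  te <- if (is.null(test_sub)) qe$te else qe$te[test_sub]
  model <- build_model(variant, seed = seed + 1)
  fit <- train_model(model, qe$pv, tr, w$label[tr], qe$va, w$label[qe$va],
                     quick_tcfg(seed = seed, epochs = epochs,
                                batch_size = batch_size))
  res <- evaluate(fit$model, qe$pv, te, w$label[te])
  rm(model)
  gc(verbose = FALSE)
  ifianet:::cpp_release_memory()
  list(fit = fit, res = res)
}

# free the quick-profile provider once the last end-to-end test is done
quick_experiment_release <- function() {
  rm(list = ls(quick_env), envir = quick_env)
  gc(verbose = FALSE)
  ifianet:::cpp_release_memory()
  invisible(NULL)
}
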