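# Training and evaluation protocol: trial-level five-fold cross-validation,
# cross-entropy loss, AdamW with reduce-on-plateau and early stopping, the
# Table-style classification metrics and the prediction-time (Plabel) sweep.

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 128, up to 100 epochs,
#' initial learning rate 0.003, AdamW with betas (0.9, 0.999) and weight
#' decay 1e-4, reduce-on-plateau (factor 0.5, patience 5 epochs) on the
#' validation loss, early stopping with patience 15.
#'
#' @param batch_size,epochs,lr,beta1,beta2,weight_decay Optimiser settings.
#' @param sched_factor,sched_patience Plateau scheduler settings.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (0 = stop after the first epoch).
#' @param min_delta Minimum validation-loss improvement that counts.
#' @param seed Seed for weight init, batch order and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128, epochs = 100, lr = 0.003,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-4,
                         sched_factor = 0.5, sched_patience = 5,
                         early_stop_patience = 15, min_delta = 1e-4,
                         seed = 1) {
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, weight_decay = weight_decay,
                 sched_factor = sched_factor,
                 sched_patience = sched_patience,
                 early_stop_patience = early_stop_patience,
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Cross-entropy of predicted class probabilities
#'
#' `L = -(1/N) sum_n sum_i y_i^n log(yhat_i^n)` with the logarithm floored
#' at 1e-12.
#'
#' @param y N x C one-hot true labels.
#' @param yhat N x C predicted probabilities (rows sum to 1).
#' @return Mean loss (scalar).
#' @export
cross_entropy <- function(y, yhat) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) {
    stop("y and yhat must have identical dimensions")
  }
  if (any(abs(rowSums(yhat) - 1) > 1e-6)) {
    stop("rows of yhat must sum to 1")
  }
  if (!all(y %in% c(0, 1)) || any(rowSums(y) != 1)) {
    stop("y must be one-hot")
  }
  -mean(rowSums(y * log(pmax(yhat, 1e-12))))
}

#' One-hot encode integer labels
#' @param labels Integer labels in 1..C.
#' @param C Number of classes.
#' @return N x C binary matrix.
#' @export
onehot <- function(labels, C) {
  m <- matrix(0, length(labels), C)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Trial-level five-fold split
#'
#' Trials are shuffled per subject by `seed` and divided into k
#' non-overlapping groups; per fold, group f is the test set and the
#' remaining trials split into training and validation at trial granularity,
#' realising the 7:1:2 ratio for 10 trials (7 train, 1 validation — rotating
#' with the fold — and 2 test). No window of a test trial can ever reach
#' training, because the split is by whole trials.
#'
#' @param trials List of `semg_trial`.
#' @param k Number of folds (5).
#' @param seed Shuffling seed.
#' @return List of k folds, each with character vectors `train`, `val`,
#'   `test` of trial ids.
#' @export
kfold_split <- function(trials, k = 5, seed = 1) {
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  subs <- vapply(trials, function(t) t$subject_id, character(1))
  folds <- replicate(k, list(train = character(0), val = character(0),
                             test = character(0)), simplify = FALSE)
  for (s in unique(subs)) {
    sid <- ids[subs == s]
    n <- length(sid)
    if (n < 10) {
      stop("subject ", s, " has ", n,
           " trials; at least 10 are needed for a 7:1:2 split")
    }
    if (n %% k != 0) stop("trials per subject must be divisible by k")
    set.seed(as.integer((seed * 2654435761 + sum(utf8ToInt(s))) %%
                          .Machine$integer.max))
    sid <- sample(sid)
    gsize <- n %/% k
    nval <- max(1L, round(n / 10))
    for (f in seq_len(k)) {
      test <- sid[((f - 1) * gsize + 1):(f * gsize)]
      rest <- setdiff(sid, test)
      vstart <- ((f - 1) * nval) %% length(rest)
      vidx <- ((vstart + seq_len(nval) - 1) %% length(rest)) + 1
      val <- rest[vidx]
      train <- setdiff(rest, val)
      folds[[f]]$train <- c(folds[[f]]$train, train)
      folds[[f]]$val <- c(folds[[f]]$val, val)
      folds[[f]]$test <- c(folds[[f]]$test, test)
    }
  }
  folds
}

model_needs_spec <- function(model) model$fusion != "baseline"

eval_pass <- function(model, pv, rows, labels, batch_size = 64) {
  n <- length(rows)
  C <- model$mcfg$n_classes
  loss_sum <- 0
  preds <- integer(n)
  probs <- matrix(0, n, C)
  for (s in seq(1, n, by = batch_size)) {
    b <- s:min(n, s + batch_size - 1)
    f <- get_features(pv, rows[b], dense = model$fusion == "data_level")
    scores <- model_forward(model, f$tf,
                            if (model_needs_spec(model)) f$spec else NULL,
                            train = FALSE)
    p <- softmax_cols(scores)
    probs[b, ] <- t(p)
    preds[b] <- apply(p, 2, which.max)
    loss_sum <- loss_sum -
      sum(log(pmax(p[cbind(labels[b], seq_along(b))], 1e-12)))
  }
  model$cache <- list() # drop the last batch's activations
  list(loss = loss_sum / n, preds = preds, probs = probs,
       acc = mean(preds == labels))
}

#' Train a model
#'
#' Mini-batch AdamW with per-epoch validation, reduce-on-plateau learning
#' rate scheduling, early stopping and restoration of the best-validation
#' weights. Fully seeded: batch order, weight initialisation (done in
#' [build_model()]) and dropout derive from `tcfg$seed`.
#'
#' @param model An `ifia_model`.
#' @param pv A [feature_provider()].
#' @param train_rows,val_rows Window row indices in the provider.
#' @param train_labels,val_labels Integer class labels (1..n_classes).
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` (best-validation weights restored)
#'   and a `history` data.frame (epoch, train_loss, val_loss, val_acc, lr).
#' @export
train_model <- function(model, pv, train_rows, train_labels, val_rows,
                        val_labels, tcfg = train_config(), verbose = FALSE) {
  if (length(val_rows) == 0) stop("validation set must be non-empty")
  if (length(train_rows) == 0) stop("training set must be non-empty")
  stopifnot(length(train_rows) == length(train_labels),
            length(val_rows) == length(val_labels))
  opt <- adamw_init(model$params)
  lr <- tcfg$lr
  best_loss <- Inf
  best <- NULL
  since_best <- 0L
  since_sched <- 0L
  hist <- data.frame()
  for (ep in seq_len(tcfg$epochs)) {
    set.seed(as.integer((tcfg$seed * 100003 + ep * 7919) %%
                          .Machine$integer.max))
    ord <- sample(length(train_rows))
    tl_sum <- 0
    nb <- 0
    for (s in seq(1, length(ord), by = tcfg$batch_size)) {
      b <- ord[s:min(length(ord), s + tcfg$batch_size - 1)]
      f <- get_features(pv, train_rows[b],
                        dense = model$fusion == "data_level")
      scores <- model_forward(model, f$tf,
                              if (model_needs_spec(model)) f$spec else NULL,
                              train = TRUE)
      sc <- softmax_ce(scores, train_labels[b])
      model_backward(model, sc$dscores)
      st <- adamw_step(model$params, model$grads, opt, lr, tcfg$beta1,
                       tcfg$beta2, weight_decay = tcfg$weight_decay)
      model$params <- st$params
      opt <- st$state
      tl_sum <- tl_sum + sc$loss
      nb <- nb + 1
    }
    ev <- eval_pass(model, pv, val_rows, val_labels)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl_sum / nb,
                                   val_loss = ev$loss, val_acc = ev$acc,
                                   lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f  lr %.2g",
                      ep, tl_sum / nb, ev$loss, ev$acc, lr))
    }
    if (ev$loss < best_loss - tcfg$min_delta) {
      best_loss <- ev$loss
      best <- list(params = model$params, buffers = model$buffers)
      since_best <- 0L
      since_sched <- 0L
    } else {
      since_best <- since_best + 1L
      since_sched <- since_sched + 1L
    }
    if (since_sched >= tcfg$sched_patience) {
      lr <- lr * tcfg$sched_factor
      since_sched <- 0L
    }
    if (since_best >= tcfg$early_stop_patience) break
  }
  if (!is.null(best)) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  cpp_release_memory()
  list(model = model, history = hist)
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true labels, columns predicted. Precision, recall and F1 are
#' macro-averaged over the classes present in the true labels (row sum > 0
#' by default); undefined per-class ratios (no predictions / no support)
#' count as 0.
#'
#' @param cm Square confusion matrix of counts.
#' @param classes Optional indices over which to macro-average.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (all percent)
#'   and the per-class vectors.
#' @export
metrics_from_confusion <- function(cm, classes = NULL) {
  cm <- as.matrix(cm)
  if (is.null(classes)) classes <- which(rowSums(cm) > 0)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  prec <- diag(cm) / pmax(colSums(cm), 1e-12)
  rec <- diag(cm) / pmax(rowSums(cm), 1e-12)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = 100 * acc,
       precision = 100 * mean(prec[classes]),
       recall = 100 * mean(rec[classes]),
       f1 = 100 * mean(f1[classes]),
       per_class_precision = 100 * prec,
       per_class_recall = 100 * rec)
}

#' Evaluate a model on held-out windows
#'
#' @inheritParams train_model
#' @param test_rows,test_labels Held-out windows and labels.
#' @param keep_predictions Attach the per-window prediction table.
#' @return A `fold_result`: accuracy / macro precision / recall / F1 (in
#'   percent), the n_classes x n_classes confusion matrix (rows = true),
#'   test size, mean test loss and optionally `predictions`.
#' @export
evaluate <- function(model, pv, test_rows, test_labels,
                     keep_predictions = FALSE) {
  if (length(test_rows) == 0) stop("test set must be non-empty")
  C <- model$mcfg$n_classes
  ev <- eval_pass(model, pv, test_rows, test_labels)
  cm <- matrix(0L, C, C)
  for (i in seq_along(test_labels)) {
    cm[test_labels[i], ev$preds[i]] <- cm[test_labels[i], ev$preds[i]] + 1L
  }
  met <- metrics_from_confusion(cm)
  out <- list(accuracy = met$accuracy, precision = met$precision,
              recall = met$recall, f1 = met$f1, confusion = cm,
              n_test = length(test_rows), loss = ev$loss)
  if (keep_predictions) {
    out$predictions <- data.frame(row = test_rows, true = test_labels,
                                  predicted = ev$preds)
    out$probs <- ev$probs
  }
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result n=%d  acc %.2f%%  prec %.2f%%  rec %.2f%%  F1 %.2f%%>\n",
    x$n_test, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

rows_for_trials <- function(windows, trials, trial_ids) {
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  which(windows$trial_idx %in% which(ids %in% trial_ids))
}

#' Run the trial-level cross-validated experiment for one variant
#'
#' Preprocesses the trials, segments windows, builds the five-fold
#' trial-level split and, for each requested fold, trains the variant and
#' evaluates it on the fold's test trials.
#'
#' @param trials List of `semg_trial` (raw; preprocessing is applied here).
#' @param variant Fusion variant name (see [variant_names()]).
#' @param wcfg,tcfg,mcfg,icfg Configurations.
#' @param folds Which folds to run (default 1; use 1:5 for the full
#'   protocol).
#' @param k Number of folds in the split.
#' @param cw Optional precomputed [collect_windows()] result (so several
#'   variants can share it).
#' @param providers Optional per-fold list of prebuilt providers.
#' @param verbose Logical.
#' @return List with per-fold `results` ([evaluate()] output), `histories`,
#'   the `split`, and the window table.
#' @export
run_experiment <- function(trials, variant = "baseline",
                           wcfg = windowing_config(), tcfg = train_config(),
                           mcfg = model_config(), icfg = ifia_config(),
                           folds = 1L, k = 5, cw = NULL, providers = NULL,
                           verbose = FALSE) {
  variant <- normalize_fusion(variant)
  if (is.null(cw)) cw <- collect_windows(trials, wcfg)
  split <- kfold_split(cw$trials, k = k, seed = tcfg$seed)
  results <- list()
  histories <- list()
  for (f in folds) {
    fold <- split[[f]]
    tr_rows <- rows_for_trials(cw$windows, cw$trials, fold$train)
    va_rows <- rows_for_trials(cw$windows, cw$trials, fold$val)
    te_rows <- rows_for_trials(cw$windows, cw$trials, fold$test)
    stopifnot(length(intersect(tr_rows, te_rows)) == 0,
              length(intersect(va_rows, te_rows)) == 0)
    pv <- if (!is.null(providers)) providers[[as.character(f)]] else
      feature_provider(cw$trials, cw$windows, wcfg,
                       cache_rows = c(tr_rows, va_rows))
    model <- build_model(variant, mcfg, icfg, seed = tcfg$seed + f)
    tr <- train_model(model, pv, tr_rows, cw$windows$label[tr_rows],
                      va_rows, cw$windows$label[va_rows], tcfg,
                      verbose = verbose)
    res <- evaluate(tr$model, pv, te_rows, cw$windows$label[te_rows])
    results[[as.character(f)]] <- res
    histories[[as.character(f)]] <- tr$history
    if (verbose) print(res)
  }
  list(variant = variant, results = results, histories = histories,
       split = split, windows = cw$windows)
}

#' Prediction-time (Plabel) sweep
#'
#' Re-segments the trials for each prediction time (window positions are
#' identical; only labels and the retained tail change), retrains the
#' variant per fold and reports per-Plabel summaries.
#'
#' @param trials List of `semg_trial`.
#' @param plabels Prediction times in ms.
#' @param variant Fusion variant.
#' @param wcfg,tcfg,mcfg,icfg Configurations (`wcfg$plabel_ms` is
#'   overridden).
#' @param folds Folds to run per Plabel.
#' @return data.frame with one row per (plabel, fold): accuracy, macro
#'   precision/recall/F1 and window counts.
#' @export
plabel_sweep <- function(trials, plabels = c(100, 200, 300, 400, 500),
                         variant = "ifia_full", wcfg = windowing_config(),
                         tcfg = train_config(), mcfg = model_config(),
                         icfg = ifia_config(), folds = 1L) {
  if (any(plabels < 0)) stop("plabels must be nonnegative")
  # one provider per fold, built at the smallest Plabel (a superset of the
  # window positions of every larger Plabel), shared across the sweep
  wmin <- windowing_config(wcfg$window_ms, wcfg$step_ms, min(plabels),
                           wcfg$fs)
  cw0 <- collect_windows(trials, wmin)
  split <- kfold_split(cw0$trials, seed = tcfg$seed)
  providers <- list()
  for (f in folds) {
    fold <- split[[f]]
    tr_rows <- rows_for_trials(cw0$windows, cw0$trials, fold$train)
    va_rows <- rows_for_trials(cw0$windows, cw0$trials, fold$val)
    providers[[as.character(f)]] <-
      feature_provider(cw0$trials, cw0$windows, wmin,
                       cache_rows = c(tr_rows, va_rows))
  }
  out <- data.frame()
  for (pl in plabels) {
    wc <- windowing_config(wcfg$window_ms, wcfg$step_ms, pl, wcfg$fs)
    cwp <- collect_windows(cw0$trials, wc, preprocess = FALSE)
    ridx <- match(window_key(cwp$windows), window_key(cw0$windows))
    if (anyNA(ridx)) stop("no window survives Plabel = ", pl, " ms")
    for (f in folds) {
      fold <- split[[f]]
      pv <- providers[[as.character(f)]]
      sel <- function(ids) which(cwp$windows$trial_id %in% ids)
      tr <- sel(fold$train); va <- sel(fold$val); te <- sel(fold$test)
      model <- build_model(variant, mcfg, icfg, seed = tcfg$seed + f)
      fit <- train_model(model, pv, ridx[tr], cwp$windows$label[tr],
                         ridx[va], cwp$windows$label[va], tcfg)
      res <- evaluate(fit$model, pv, ridx[te], cwp$windows$label[te])
      out <- rbind(out, data.frame(
        plabel_ms = pl, fold = f, accuracy = res$accuracy,
        precision = res$precision, recall = res$recall, f1 = res$f1,
        n_train = length(tr), n_test = length(te)))
    }
  }
  out
}

#' Write a fold result to disk
#'
#' Metrics and configuration echo as JSON, confusion matrix and optional
#' per-window predictions as CSV next to it.
#'
#' @param res A `fold_result`.
#' @param path JSON output path (confusion CSV uses suffix
#'   `.confusion.csv`).
#' @param meta Optional named list merged into the JSON (configs, seed, ...).
#' @export
write_fold_result <- function(res, path, meta = list()) {
  obj <- c(list(accuracy = res$accuracy, precision = res$precision,
                recall = res$recall, f1 = res$f1, n_test = res$n_test,
                loss = res$loss), meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  cmpath <- paste0(sub("\\.json$", "", path), ".confusion.csv")
  write.csv(res$confusion, cmpath, row.names = FALSE)
  if (!is.null(res$predictions)) {
    pp <- cbind(res$predictions, res$probs)
    names(pp) <- c("row", "true", "predicted",
                   paste0("p", seq_len(ncol(res$probs))))
    write.csv(pp, paste0(sub("\\.json$", "", path), ".predictions.csv"),
              row.names = FALSE)
  }
  invisible(path)
}
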