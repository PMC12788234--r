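# Training/evaluation protocol: loss closed forms, trial-level splitting,
# metric identities, seeding and the prediction-time sweep bookkeeping.

test_that("cross-entropy matches its closed forms", {
  C <- 17
  y <- onehot(sample(C, 10, replace = TRUE), C)
  expect_equal(cross_entropy(y, y), 0)
  unif <- matrix(1 / C, 10, C)
  expect_equal(cross_entropy(y, unif), log(17), tolerance = 1e-6)
  # duplicating every row leaves the mean loss unchanged
  set.seed(1)
  p <- matrix(abs(rnorm(10 * C)), 10, C)
  p <- p / rowSums(p)
  expect_equal(cross_entropy(rbind(y, y), rbind(p, p)), cross_entropy(y, p))
  expect_error(cross_entropy(y, p[1:5, ]), "identical dimensions")
  expect_error(cross_entropy(y, matrix(0.5, 10, C)), "sum to 1")
  expect_error(cross_entropy(p, p), "one-hot")
})

test_that("trial-level five-fold split realises 7:1:2 without leakage", {
  trials <- tiny_dataset()
  folds <- kfold_split(trials, k = 5, seed = 2)
  ids <- vapply(trials, `[[`, "", "trial_id")
  test_union <- character(0)
  test_sets <- list()
  for (f in folds) {
    expect_length(f$train, 7)
    expect_length(f$val, 1)
    expect_length(f$test, 2)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    test_union <- union(test_union, f$test)
    test_sets <- c(test_sets, list(sort(f$test)))
  }
  expect_setequal(test_union, ids)
  expect_gt(length(unique(test_sets)), 1)
  expect_identical(kfold_split(trials, seed = 2), folds)
  expect_false(identical(kfold_split(trials, seed = 3), folds))
  expect_error(kfold_split(trials[1:8]), "at least 10")
})

test_that("no window of a test trial can appear in training", {
  env <- tiny_experiment()
  folds <- kfold_split(env$cw$trials, seed = 4)
  w <- env$cw$windows
  for (f in folds) {
    key <- function(ids) paste(w$trial_id[w$trial_id %in% ids],
                               w$start_ms[w$trial_id %in% ids])
    expect_length(intersect(key(f$train), key(f$test)), 0)
    expect_length(intersect(key(f$val), key(f$test)), 0)
  }
})

test_that("metrics from a confusion matrix match hand computation", {
  cm <- matrix(c(9, 2, 1, 8), 2, 2) # rows true, cols predicted
  met <- metrics_from_confusion(cm)
  expect_equal(met$accuracy, 85)
  expect_equal(met$precision, 100 * (9 / 11 + 8 / 9) / 2, tolerance = 1e-9)
  expect_equal(met$recall, 100 * (0.9 + 0.8) / 2)
  # accuracy identity: trace over total
  expect_equal(met$accuracy, 100 * sum(diag(cm)) / sum(cm))
  # macro F1 is the mean of per-class harmonic means
  f1 <- mean(2 * c(9 / 11, 8 / 9) * c(0.9, 0.8) /
               (c(9 / 11, 8 / 9) + c(0.9, 0.8)))
  expect_equal(met$f1, 100 * f1, tolerance = 1e-9)

  perfect <- diag(c(5, 7, 3))
  mp <- metrics_from_confusion(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$f1, 100)

  # all-one-class predictor on a balanced 2-class set
  lazy <- matrix(c(10, 10, 0, 0), 2, 2)
  ml <- metrics_from_confusion(lazy)
  expect_equal(ml$accuracy, 50)
  expect_equal(ml$recall, 50)
})

test_that("training is seeded, bounded by patience and respects lr = 0", {
  env <- tiny_experiment()
  w <- env$cw$windows
  n <- nrow(w)
  tr <- which(seq_len(n) %% 4 != 0)
  va <- which(seq_len(n) %% 4 == 0)
  mcfg <- model_config(dropout_p = 0)

  # lr = 0: trainable weights unchanged after an epoch
  m <- build_model("baseline", mcfg, seed = 5)
  before <- m$params
  fit <- train_model(m, env$pv, tr, w$label[tr], va, w$label[va],
                     train_config(epochs = 1, lr = 0, batch_size = 64,
                                  early_stop_patience = 5, seed = 1))
  expect_equal(fit$model$params, before, tolerance = 1e-15)

  # early-stop patience 0 runs exactly one epoch
  m0 <- build_model("baseline", mcfg, seed = 5)
  h0 <- train_model(m0, env$pv, tr, w$label[tr], va, w$label[va],
                    train_config(epochs = 10, batch_size = 64,
                                 early_stop_patience = 0, seed = 1))$history
  expect_identical(nrow(h0), 1L)

  # same seed twice gives the identical validation loss trajectory
  run <- function() {
    m <- build_model("baseline", mcfg, seed = 6)
    train_model(m, env$pv, tr, w$label[tr], va, w$label[va],
                train_config(epochs = 2, batch_size = 64,
                             early_stop_patience = 5, seed = 9))$history
  }
  expect_identical(run()$val_loss, run()$val_loss)

  expect_error(train_model(build_model("baseline", mcfg, seed = 5), env$pv,
                           tr, w$label[tr], integer(0), integer(0),
                           train_config()),
               "non-empty")
})

test_that("evaluation exports probabilities that reproduce its loss", {
  env <- tiny_experiment()
  w <- env$cw$windows
  m <- build_model("baseline", seed = 7)
  te <- seq_len(min(40, nrow(w)))
  res <- evaluate(m, env$pv, te, w$label[te], keep_predictions = TRUE)
  expect_equal(dim(res$confusion), c(17, 17))
  expect_equal(sum(res$confusion), length(te))
  expect_equal(rowSums(res$confusion),
               vapply(1:17, function(k) sum(w$label[te] == k), numeric(1)),
               ignore_attr = TRUE)
  # round trip: the exported probabilities evaluate to the reported loss
  expect_equal(cross_entropy(onehot(w$label[te], 17), res$probs), res$loss,
               tolerance = 1e-9)
  expect_error(evaluate(m, env$pv, integer(0), integer(0)), "non-empty")
})

test_that("prediction-time sweep retrains per Plabel with pruned windows", {
  env <- tiny_experiment()
  counts <- vapply(c(100, 500, 900), function(p)
    nrow(segment_windows(env$cw$trials[[1]], windowing_config(1200, 200, p))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  # a single-class trial keeps identical labels for any Plabel
  tr1 <- noise_trial(4000, label = 5L)
  l0 <- segment_windows(tr1, windowing_config(1200, 200, 0))
  l1 <- segment_windows(tr1, windowing_config(1200, 200, 100))
  shared <- seq_len(nrow(l1))
  expect_identical(l0$label[shared], l1$label[shared])

  sw <- plabel_sweep(tiny_dataset(), plabels = c(100, 500),
                     variant = "baseline",
                     tcfg = train_config(epochs = 1, batch_size = 64,
                                         early_stop_patience = 1, seed = 3),
                     folds = 1L)
  expect_identical(sort(unique(sw$plabel_ms)), c(100, 500))
  expect_true(all(is.finite(sw$accuracy)))
  expect_true(all(sw$n_train[sw$plabel_ms == 500] <=
                    sw$n_train[sw$plabel_ms == 100]))
  expect_error(plabel_sweep(tiny_dataset(), plabels = -5), "nonnegative")
})
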