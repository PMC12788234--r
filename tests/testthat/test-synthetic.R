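# Synthetic sEMG generator: determinism, spectral placement, bookkeeping,
# inter-subject jitter and class separability.

test_that("trial generation is deterministic and keeps exact bookkeeping", {
  specs <- motion_class_specs("quick")
  plan <- data.frame(label = c(1, 3), duration_ms = c(1500, 1500))
  t1 <- generate_trial(specs, plan, seed = 42)
  t2 <- generate_trial(specs, plan, seed = 42)
  expect_identical(t1$samples, t2$samples)
  t3 <- generate_trial(specs, plan, seed = 43)
  expect_false(identical(t1$samples, t3$samples))

  big <- generate_trial(specs, data.frame(label = 3, duration_ms = 90000),
                        seed = 1)
  expect_equal(nrow(big$samples), 90000)
  expect_equal(big$events,
               data.frame(start_ms = 0, end_ms = 90000, label = 3L))
})

test_that("generation rejects unknown labels and too-short plans", {
  specs <- motion_class_specs("quick")
  expect_error(generate_trial(specs, data.frame(label = 9,
                                                duration_ms = 2000), 1),
               "no spec")
  expect_error(generate_trial(specs, data.frame(label = 3,
                                                duration_ms = 800), 1),
               "1200 ms")
  expect_error(generate_trial(specs, data.frame(label = 3,
                                                duration_ms = -5), 1),
               "> 0")
})

test_that("band-limited synthesis concentrates spectral energy in band", {
  sp <- list("3" = motion_class_spec(3, rep(1, 8), 60, 120, cadence_hz = 2,
                                     noise_floor = 0))
  tr <- generate_trial(sp, data.frame(label = 3, duration_ms = 10000),
                       seed = 5)
  x <- tr$samples[, 1]
  pw <- abs(fft(x))^2
  freqs <- (seq_along(x) - 1) * 1000 / length(x)
  half <- freqs <= 500
  inband <- sum(pw[half][freqs[half] >= 55 & freqs[half] <= 125])
  expect_gt(inband / sum(pw[half]), 0.90)
})

test_that("dataset generation covers classes with reproducible jitter", {
  trials <- generate_dataset(1, 10, class_subset = c(1, 2, 3, 5, 7),
                             seed = 3, trial_duration_ms = 3000)
  expect_length(trials, 10)
  expect_length(unique(vapply(trials, `[[`, "", "trial_id")), 10)
  labs <- sort(unique(unlist(lapply(trials, function(t) t$events$label))))
  expect_identical(labs, c(1L, 2L, 3L, 5L, 7L))
  expect_error(generate_dataset(1, 2, integer(0), 1), "nonempty")
  expect_error(generate_dataset(1, 2, c(3, 99), 1), "subset")

  two_a <- generate_dataset(2, 1, c(1, 3), seed = 9,
                            trial_duration_ms = 2000)
  two_b <- generate_dataset(2, 1, c(1, 3), seed = 9,
                            trial_duration_ms = 2000)
  expect_identical(two_a[[1]]$samples, two_b[[1]]$samples)
  expect_identical(two_a[[2]]$samples, two_b[[2]]$samples)
  # different subjects receive different spec perturbations
  expect_false(identical(two_a[[1]]$samples, two_a[[2]]$samples))
})

test_that("default quick classes separate by at least 3 within-class sd", {
  specs <- motion_class_specs("quick")
  feats <- lapply(specs, function(sp) {
    t(sapply(1:20, function(i) {
      tr <- generate_trial(setNames(list(sp), as.character(sp$label)),
                           data.frame(label = sp$label, duration_ms = 1200),
                           seed = 1000 * sp$label + i)
      bandpower_features(tr$samples)
    }))
  })
  mus <- lapply(feats, colMeans)
  sds <- vapply(feats, function(f) sqrt(sum(apply(f, 2, var))), numeric(1))
  for (i in seq_along(specs)) {
    for (j in seq_along(specs)) {
      if (i >= j) next
      d <- sqrt(sum((mus[[i]] - mus[[j]])^2))
      expect_gt(d, 3 * max(sds[i], sds[j]))
    }
  }
})

test_that("static postures have lower RMS than dynamic classes", {
  specs <- motion_class_specs("quick")
  rms <- vapply(specs, function(sp) {
    tr <- generate_trial(setNames(list(sp), as.character(sp$label)),
                         data.frame(label = sp$label, duration_ms = 4000),
                         seed = 77)
    sqrt(mean(tr$samples^2))
  }, numeric(1))
  static <- rms[c("1", "2")]
  dynamic <- rms[setdiff(names(rms), c("1", "2"))]
  expect_true(max(static) < min(dynamic))
})

test_that("trial export round-trips through table and container formats", {
  tr <- generate_trial(motion_class_specs("quick"),
                       data.frame(label = c(1, 3),
                                  duration_ms = c(1200, 1200)), seed = 2)
  d <- withr::local_tempdir()
  csv <- file.path(d, "t1.csv")
  write_trial_table(tr, csv)
  back <- read_trial_table(csv)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$events, tr$events)
  expect_identical(back$trial_id, tr$trial_id)

  cont <- file.path(d, "trials.rds")
  write_trial_container(list(tr), cont)
  back2 <- read_trial_container(cont)[[1]]
  expect_identical(back2$samples, tr$samples) # bit-exact
  expect_identical(back2$events, tr$events)
})
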