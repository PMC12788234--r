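# Filtering, normalisation, windowing/labelling, CWT and FFT transforms.

test_that("high-pass filter rejects DC and slow drift, passes the sEMG band", {
  n <- 5000
  dc <- matrix(1, n, 8)
  out <- highpass_filter(dc)
  expect_lt(max(abs(out[1000:4000, ])), 1e-6)

  tt <- (seq_len(n) - 1) / 1000
  mid <- 1001:4000
  s100 <- matrix(sin(2 * pi * 100 * tt), n, 8)
  out100 <- highpass_filter(s100)
  expect_equal(sqrt(mean(out100[mid, 1]^2)), sqrt(mean(s100[mid, 1]^2)),
               tolerance = 0.01)

  s5 <- matrix(sin(2 * pi * 5 * tt), n, 8)
  out5 <- highpass_filter(s5)
  expect_lt(sqrt(mean(out5[mid, 1]^2)), 0.10 * sqrt(mean(s5[mid, 1]^2)))

  expect_error(highpass_filter(matrix(1, 5, 8)), "warm-up")
  expect_error(highpass_filter(matrix(1, 100, 8), cutoff = 600), "Nyquist")
})

test_that("99th-percentile normalisation identities hold", {
  set.seed(4)
  x <- matrix(rnorm(4000 * 8), 4000, 8)
  y <- normalize_percentile(x)
  p99 <- apply(abs(y), 2, quantile, 0.99, names = FALSE)
  expect_equal(p99, rep(1, 8), tolerance = 1e-9)
  # scale invariance
  expect_equal(normalize_percentile(7 * x), y, tolerance = 1e-12)
  # +/-1 square wave is already normalised
  sq <- matrix(rep(c(1, -1), 2000), 4000, 8)
  expect_equal(normalize_percentile(sq), sq)
  # all-zero channel is rejected with its index
  bad <- x; bad[, 3] <- 0
  expect_error(normalize_percentile(bad), "3")
})

test_that("window segmentation follows the look-ahead labelling rule", {
  tr <- noise_trial(90000, label = 3L)
  w <- segment_windows(tr, windowing_config(1200, 200, 100))
  expect_equal(attr(w, "n_positions"), 445)
  expect_equal(nrow(w), 444) # the 445th label time (90,100 ms) is outside
  expect_true(all(w$label == 3L))
  expect_equal(w$label_time_ms, w$start_ms + 1200 + 100)

  # single position, label time exactly at the trial end boundary
  one <- segment_windows(noise_trial(1200, label = 5L),
                         windowing_config(1200, 200, 0))
  expect_equal(nrow(one), 1)
  expect_equal(one$label, 5L)

  # the event active at the label time wins, even across a boundary
  tr2 <- make_trial(matrix(rnorm(90000 * 8), 90000, 8))
  tr2$events <- data.frame(start_ms = c(0, 60000),
                           end_ms = c(60000, 90000), label = c(3L, 5L))
  w2 <- segment_windows(tr2, windowing_config(1200, 200, 500))
  late <- w2$label_time_ms >= 60000
  expect_true(all(w2$label[late] == 5L))
  expect_true(all(w2$label[!late] == 3L))

  expect_error(segment_windows(noise_trial(1000), windowing_config()),
               "shorter")
})

test_that("window count matches brute-force enumeration and Plabel pruning", {
  set.seed(9)
  for (i in 1:200) {
    W <- sample(200:1500, 1)
    S <- sample(50:600, 1)
    L <- W + sample(0:8000, 1)
    starts <- 0
    while (tail(starts, 1) + S + W <= L) starts <- c(starts, tail(starts, 1) + S)
    expect_equal(floor((L - W) / S) + 1, length(starts))
  }
  # segment_windows agrees with enumeration for a concrete sample
  tr <- noise_trial(7400)
  for (S in c(150, 200, 700)) {
    w <- segment_windows(tr, windowing_config(1200, S, 0))
    expect_equal(attr(w, "n_positions"), floor((7400 - 1200) / S) + 1)
    expect_equal(nrow(w), sum(seq(0, 7400 - 1200, by = S) + 1200 <= 7400))
  }
  # retained windows never increase with Plabel
  counts <- vapply(c(0, 100, 300, 500, 1500), function(p)
    nrow(segment_windows(tr, windowing_config(1200, 200, p))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("CWT produces correctly shaped scalograms with ridge localisation", {
  tt <- (0:1199) / 1000
  x <- matrix(0, 1200, 8)
  x[, 2] <- sin(2 * pi * 80 * tt)
  m <- cwt_transform(x)
  expect_equal(dim(m), c(30, 1200, 8))
  expect_true(all(m >= 0) && all(is.finite(m)))
  cf <- attr(m, "center_freqs")
  expect_equal(length(cf), 30)
  expect_true(all(diff(cf) < 0)) # strictly descending
  ridge <- which.max(rowMeans(m[, , 2]))
  step <- cf[1] / cf[2] # log-spacing ratio
  expect_lt(abs(log(cf[ridge] / 80)), log(step) * 1.01)
  # zero window maps to zero
  expect_true(all(cwt_transform(matrix(0, 1200, 8)) == 0))
})

test_that("CWT and FFT are permutation-equivariant across channels", {
  set.seed(12)
  x <- matrix(rnorm(1200 * 8), 1200, 8)
  perm <- sample(8)
  expect_equal(cwt_transform(x[, perm]), cwt_transform(x)[, , perm],
               ignore_attr = TRUE)
  expect_equal(fft_transform(x[, perm]), fft_transform(x)[, perm],
               ignore_attr = TRUE)
})

test_that("FFT spectrum has 601 bins with exact bin arithmetic and Parseval", {
  tt <- (0:1199) / 1000
  x <- matrix(sin(2 * pi * 50 * tt), 1200, 8)
  sp <- fft_transform(x)
  expect_equal(dim(sp), c(601, 8))
  freqs <- attr(sp, "freqs")
  expect_equal(freqs[2] - freqs[1], 1000 / 1200)
  expect_equal(which.max(sp[, 1]) - 1, 60) # 0-based bin 60 = 50 Hz
  expect_equal(freqs[which.max(sp[, 1])], 50)

  set.seed(3)
  z <- matrix(rnorm(1200 * 2), 1200, 2)
  sz <- fft_transform(z)
  one_sided_energy <- (sz[1, ]^2 + 2 * colSums(sz[2:600, ]^2) +
                         sz[601, ]^2) / 1200
  expect_equal(one_sided_energy, colSums(z^2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("window containers and configs round-trip exactly", {
  set.seed(5)
  raw <- array(rnorm(3 * 1200 * 8), c(3, 1200, 8))
  cfg <- windowing_config(1200, 200, 300)
  d <- withr::local_tempdir()
  p <- file.path(d, "wins.rds")
  write_window_container(raw, c(1L, 3L, 5L), cfg, p)
  back <- read_window_container(p)
  expect_identical(back$raw, raw)
  expect_identical(back$labels, c(1L, 3L, 5L))
  expect_equal(back$config, cfg)

  yml <- file.path(d, "w.yaml")
  write_windowing_config(cfg, yml)
  expect_equal(read_windowing_config(yml), cfg)
  writeLines("plable_ms: 100", yml)
  expect_error(read_windowing_config(yml), "unknown")
})

test_that("windowing config enforces its invariants", {
  expect_error(windowing_config(window_ms = 0), ">")
  expect_error(windowing_config(plabel_ms = -1), ">=|positive|invalid",
               class = "simpleError")
  expect_error(windowing_config(window_ms = 1000.5), "integral")
})
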