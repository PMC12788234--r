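# Encoder/decoder architecture: printed-shape conformance, closed-form
# parameter counts, causality, residual identity and permutation symmetry.

rand_tf <- function(B = 1, K = 30, seed = 1) {
  set.seed(seed)
  array(rnorm(1200 * K * 8 * B, sd = 0.5), c(1200, K, 8, B))
}

rand_spec <- function(B = 1, seed = 2) {
  set.seed(seed)
  array(abs(rnorm(601 * 8 * B)), c(601, 8, B))
}

test_that("forward probe reproduces the printed shape ladder", {
  m <- build_model("baseline", seed = 1)
  invisible(model_forward(m, rand_tf()))
  sh <- m$cache$tf$shapes
  expect_equal(sh$input, c(1200, 30, 8))
  expect_equal(sh$s1_conv, c(1198, 30, 8))
  expect_equal(sh$s1_pool, c(299, 30, 8))
  expect_equal(sh$s2_conv, c(297, 30, 8))
  expect_equal(sh$s2_pool, c(74, 30, 8))
  expect_equal(sh$s3_conv, c(72, 30, 8))
  expect_equal(sh$s3_pool, c(18, 30, 8))
  expect_equal(sh$agg_conv, c(16, 16, 8))
  expect_equal(sh$seq, c(16, 128))

  mf <- build_model("feature_level", seed = 1)
  fr <- freq_branch_forward(mf, rand_spec()[, , 1])
  expect_equal(dim(fr$block), c(1, 149, 8))
  expect_length(fr$flat, 1192)
})

test_that("tf branch exposes the stage-2 insertion point and encoded output", {
  m <- build_model("baseline", seed = 2)
  tfmap <- array(abs(rnorm(30 * 1200 * 8)), c(30, 1200, 8))
  out <- tf_branch_forward(m, tfmap)
  expect_equal(dim(out$encoded), c(16, 128))
  expect_equal(dim(out$stage2), c(30, 74, 8))
  expect_error(tf_branch_forward(m, array(0, c(12, 1200, 8))), "bands")
})

test_that("zero input yields identical responses across muscle columns", {
  m <- build_model("baseline", seed = 3)
  z <- tf_branch_forward(m, array(0, c(30, 1200, 8)))$encoded
  for (a in 1:16) {
    block <- z[, (a - 1) * 8 + 1:8]
    expect_equal(block, matrix(block[, 1], 16, 8), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("closed-form parameter counts decompose exactly", {
  m <- build_model("baseline", seed = 1)
  p <- m$params
  count_of <- function(rx) sum(vapply(p[grep(rx, names(p))], length, 1L))
  expect_identical(count_of("^tf\\."), 1848L)
  expect_identical(count_of("^tcn\\.b1\\."), 99072L)
  expect_identical(count_of("^tcn\\.b2\\."), 329472L)
  expect_identical(count_of("^tcn\\.b3\\."), 181120L)
  expect_identical(count_of("^tcn\\."), 609664L)
  expect_identical(count_of("^dec\\."), 70225L)
  expect_identical(count_parameters(m), 681737L)

  mf <- build_model("feature_level", seed = 1)
  fr <- sum(vapply(mf$params[grep("^fr\\.", names(mf$params))], length, 1L))
  expect_identical(fr, 8L)

  # a single affine map 10 -> 5 with bias
  expect_identical(count_parameters(list(W = matrix(0, 5, 10), b = rep(0, 5))),
                   55L)
})

test_that("TCN is causal and its receptive field covers the sequence", {
  m <- build_model("baseline", seed = 4)
  set.seed(8)
  s <- matrix(rnorm(16 * 128), 16, 128)
  y0 <- tcn_forward(m, s)
  expect_equal(dim(y0), c(16, 128))
  s2 <- s
  s2[16, ] <- s2[16, ] + rnorm(128)
  y1 <- tcn_forward(m, s2)
  expect_equal(y0[1:15, ], y1[1:15, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y0[16, ], y1[16, ])))

  expect_identical(receptive_field(model_config()), 29)
  expect_gte(receptive_field(model_config()), 16)
  # perturbing the earliest step reaches the final output step
  s3 <- s
  s3[1, ] <- s3[1, ] + 1
  expect_false(isTRUE(all.equal(tcn_forward(m, s)[16, ],
                                tcn_forward(m, s3)[16, ])))
})

test_that("receptive field closed form behaves under config changes", {
  one <- model_config(tcn_dilations = 1, tcn_channels = 128)
  # one block contributes two convs: 1 + 2*(k-1)*d = 5; a single conv gives 3
  expect_identical(1 + (one$tcn_kernel - 1) * 1, 3)
  expect_identical(receptive_field(one), 5)
  doubled <- model_config(tcn_dilations = c(2, 4, 8))
  expect_gt(receptive_field(doubled), receptive_field(model_config()))
})

test_that("zeroed convolutions reduce TCN blocks to their residual paths", {
  m <- build_model("baseline", seed = 5)
  for (nm in names(m$params)) {
    if (grepl("^tcn\\..*\\.(c1|c2)\\.", nm)) m$params[[nm]][] <- 0
    if (grepl("^tcn\\..*\\.bn.\\.gamma", nm)) m$params[[nm]][] <- 0
    if (grepl("^tcn\\..*\\.bn.\\.beta", nm)) m$params[[nm]][] <- 0
  }
  set.seed(10)
  s <- matrix(rnorm(16 * 128), 16, 128)
  out <- tcn_forward(m, s)
  # block 1 is the identity; blocks 2 and 3 reduce to their 1x1 projections
  z <- s
  z <- t(m$params[["tcn.b2.down.W"]] %*% t(z) + m$params[["tcn.b2.down.b"]])
  z <- t(m$params[["tcn.b3.down.W"]] %*% t(z) + m$params[["tcn.b3.down.b"]])
  expect_equal(out, z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("permuting muscle columns permutes the encoded feature blocks", {
  m <- build_model("baseline", seed = 6)
  tfmap <- array(abs(rnorm(30 * 1200 * 8)), c(30, 1200, 8))
  z <- tf_branch_forward(m, tfmap)$encoded
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  zp <- tf_branch_forward(m, tfmap[, , perm])$encoded
  for (a in 1:16) {
    expect_equal(zp[, (a - 1) * 8 + 1:8], z[, (a - 1) * 8 + perm],
                 tolerance = 1e-12)
  }
})

test_that("decoder is deterministic at evaluation and rejects tiny label sets", {
  m <- build_model("baseline", seed = 7)
  set.seed(3)
  s <- matrix(rnorm(16 * 128), 16, 128)
  expect_length(decode(m, s), 17)
  expect_identical(decode(m, s), decode(m, s))
  expect_error(model_config(n_classes = 1), "at least 2")
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  d <- withr::local_tempdir()
  m <- build_model("ifia_full", seed = 8)
  p <- file.path(d, "ck.rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$fusion, "ifia_full")
  expect_error(load_checkpoint(p, expect_fusion = "baseline"),
               "does not match")
})

test_that("every variant consumes one batch and emits 17 class scores", {
  tf <- rand_tf(B = 2)
  sp <- rand_spec(B = 2)
  for (v in variant_names()) {
    m <- build_model(v, seed = 9)
    sc <- model_forward(m, tf, sp)
    expect_equal(dim(sc), c(17, 2))
    expect_true(all(is.finite(sc)))
  }
  expect_error(build_model("bogus"), "unknown fusion")
})
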