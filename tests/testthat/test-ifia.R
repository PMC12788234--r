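# IFIA fusion module: gating, temporal compression, cross-domain attention,
# ablation variants and the fusion parameter accounting.

stage2_block <- function(seed = 1) {
  set.seed(seed)
  array(abs(rnorm(30 * 74 * 8)), c(30, 74, 8))
}

test_that("channel-enhancement gates are logistic and behave at the limits", {
  m <- build_model("ifia_full", seed = 1)
  X <- stage2_block()
  set.seed(2)
  fv <- abs(rnorm(1192))
  ce <- channel_enhance(X, fv, m)
  expect_length(ce$gates, 30)
  expect_true(all(ce$gates > 0 & ce$gates < 1))
  expect_equal(dim(ce$gated), dim(X))

  # zero frequency features with zero-initialised biases: all gates 0.5
  ce0 <- channel_enhance(X, rep(0, 1192), m)
  expect_equal(ce0$gates, rep(0.5, 30))
  expect_equal(ce0$gated, 0.5 * X)

  # driving one output logit to +/- infinity saturates that band's gate
  m$params[["ifia.mlp.b2"]][7] <- 1000
  expect_equal(channel_enhance(X, fv, m)$gates[7], 1)
  expect_equal(channel_enhance(X, fv, m)$gated[7, , ], X[7, , ])
  m$params[["ifia.mlp.b2"]][7] <- -1000
  expect_equal(channel_enhance(X, fv, m)$gates[7], 0)
  expect_equal(channel_enhance(X, fv, m)$gated[7, , ], 0 * X[7, , ])
})

test_that("gate monotonicity: a larger logit strictly increases its gate", {
  m <- build_model("ifia_full", seed = 3)
  fv <- abs(rnorm(1192))
  g0 <- channel_enhance(stage2_block(), fv, m)$gates
  m$params[["ifia.mlp.b2"]][12] <- m$params[["ifia.mlp.b2"]][12] + 0.5
  g1 <- channel_enhance(stage2_block(), fv, m)$gates
  expect_gt(g1[12], g0[12])
  expect_equal(g1[-12], g0[-12])
})

test_that("temporal compression is the mean over time and is linear", {
  X <- stage2_block(4)
  cm <- temporal_compress(X)
  expect_equal(dim(cm), c(30, 1, 8))
  expect_equal(cm[, 1, ], apply(X, c(1, 3), mean))
  const <- array(rep(as.numeric(X[, 1, ]), each = 1), c(30, 1, 8))
  Xc <- array(0, c(30, 74, 8))
  for (t in 1:74) Xc[, t, ] <- X[, 1, ]
  expect_equal(temporal_compress(Xc)[, 1, ], X[, 1, ])
  Y <- stage2_block(5)
  expect_equal(temporal_compress(X + Y), temporal_compress(X) +
                 temporal_compress(Y))
})

test_that("cross-interaction preserves shape, is residual, and normalises", {
  m <- build_model("ifia_full", seed = 6)
  X <- stage2_block(7)
  cm <- temporal_compress(X)
  fused <- cross_interact(X, cm, m)
  expect_equal(dim(fused), dim(X))
  expect_true(all(is.finite(fused)))

  # zero output projection makes the attention exactly the identity map
  m0 <- build_model("ifia_full", seed = 6)
  m0$params[["ifia.Wo"]][] <- 0
  m0$params[["ifia.bo"]][] <- 0
  expect_equal(cross_interact(X, cm, m0), X)

  A <- attention_weights(X, cm, m, channel = 2)
  expect_equal(dim(A), c(75, 75, 2))
  expect_equal(apply(A, c(1, 3), sum), matrix(1, 75, 2), tolerance = 1e-6)
})

test_that("reduction ratio controls the gating MLP width and validity", {
  for (r in c(1, 2, 4, 8)) {
    m <- build_model("ifia_full", icfg = ifia_config(r = r), seed = 1)
    expect_equal(nrow(m$params[["ifia.mlp.W1"]]), floor(1192 / r))
  }
  expect_error(build_model("ifia_full", icfg = ifia_config(r = 5000)),
               "hidden width")
  expect_error(ifia_config(r = 0), ">= 1")
  expect_error(ifia_config(n_heads = 3, d_model = 64), "divisible")
})

test_that("fusion variants reproduce the printed parameter accounting", {
  counts <- vapply(variant_names(), function(v)
    count_parameters(build_model(v, seed = 1)), integer(1))
  expect_identical(counts[["baseline"]], 681737L)
  expect_identical(counts[["data_level"]], 681797L)
  expect_identical(counts[["data_level"]] - counts[["baseline"]], 60L)
  expect_true(counts[["baseline"]] <= counts[["data_level"]])
  expect_true(counts[["data_level"]] < counts[["feature_level"]])
  expect_true(counts[["feature_level"]] < counts[["ifia_full"]])
  expect_true(counts[["ifia_full"]] < counts[["decision_level"]])
  expect_error(build_variant("nonsense"), "unknown fusion")
})

test_that("ifia insertion preserves the stage-2 shape end to end", {
  set.seed(11)
  tf <- array(abs(rnorm(1200 * 30 * 8 * 2)), c(1200, 30, 8, 2))
  sp <- array(abs(rnorm(601 * 8 * 2)), c(601, 8, 2))
  for (v in c("ifia_full", "no_channel_attention", "no_cross_interaction",
              "no_temporal_compression")) {
    m <- build_model(v, seed = 2)
    invisible(model_forward(m, tf, sp, train = TRUE))
    expect_equal(dim(m$cache$tf$X2), c(74, 30, 8, 2))
    expect_equal(dim(m$cache$tf$X2f), c(74, 30, 8, 2))
  }
})

test_that("gating to one turns no_cross_interaction into the exact baseline", {
  base <- build_model("baseline", seed = 13)
  ncr <- build_model("no_cross_interaction", seed = 13)
  # share the backbone weights, then saturate every gate at exactly 1
  for (nm in names(base$params)) ncr$params[[nm]] <- base$params[[nm]]
  ncr$params[["ifia.mlp.W1"]][] <- 0
  ncr$params[["ifia.mlp.W2"]][] <- 0
  ncr$params[["ifia.mlp.b2"]][] <- 1000 # logistic(1000) == 1 in doubles
  set.seed(14)
  tf <- array(abs(rnorm(1200 * 30 * 8)), c(1200, 30, 8, 1))
  sp <- array(abs(rnorm(601 * 8)), c(601, 8, 1))
  expect_identical(model_forward(ncr, tf, sp), model_forward(base, tf))
})
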