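# The CNN-TCN encoder/decoder and its fusion variants.
#
# Architecture (defaults):
#  * time-frequency branch: 30 frequency bands, each with its OWN three
#    stages of [3x1 temporal conv (1 filter) + 4x1 average pool, stride 4]
#    taking the per-band trajectory 1200 -> 1198 -> 299 -> 297 -> 74 -> 72
#    -> 18; then an aggregation conv across bands (30 -> 16 channels,
#    kernel 3 along time) + BatchNorm + Leaky-ReLU -> (16, 16, 8), finally
#    rearranged to a length-16 sequence of 16*8 = 128 features.
#  * frequency branch: two 3x1 convs (one filter, shared across muscles)
#    and a 4x1 max pool: 601 -> 599 -> 597 -> 149 bins per muscle channel.
#  * TCN: three temporal blocks (two causal dilated convs each, kernel 3,
#    dilations 1/2/4, channels 128/256/128) with BatchNorm + ReLU and
#    residual connections (1x1 conv where widths change).
#  * decoder: BatchNorm over the 2048 flattened features -> dense to a
#    32-dim embedding -> Leaky-ReLU -> dropout -> dense to class scores.
# The IFIA module and the data-/feature-/decision-level fusion baselines
# hook into this skeleton; see R/ifia.R.

#' Model configuration
#'
#' @param n_channels Muscle channels (8).
#' @param n_scales CWT bands feeding the time-frequency branch (30).
#' @param window_samples Samples per window (1200).
#' @param spectrum_bins One-sided FFT bins (601).
#' @param n_classes Locomotion classes (17).
#' @param pool_size,pool_stride Average/max pooling geometry (4, 4).
#' @param agg_out_channels Aggregation conv output channels (16).
#' @param leaky_slope Leaky-ReLU slope (0.01).
#' @param tcn_kernel,tcn_dilations,tcn_channels TCN geometry: kernel 3,
#'   dilations (1, 2, 4) (strictly increasing powers of two), channel plan
#'   (128, 256, 128).
#' @param embed_dim Decoder embedding width (32).
#' @param dropout_p Decoder dropout probability (0.3).
#' @return A `model_config` list.
#' @export
model_config <- function(n_channels = 8, n_scales = 30, window_samples = 1200,
                         spectrum_bins = 601, n_classes = 17, pool_size = 4,
                         pool_stride = 4, agg_out_channels = 16,
                         leaky_slope = 0.01, tcn_kernel = 3,
                         tcn_dilations = c(1, 2, 4),
                         tcn_channels = c(128, 256, 128), embed_dim = 32,
                         dropout_p = 0.3) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (length(tcn_dilations) != length(tcn_channels)) {
    stop("tcn_dilations and tcn_channels must have equal length")
  }
  if (any(diff(tcn_dilations) <= 0) ||
      any(log2(tcn_dilations) != round(log2(tcn_dilations)))) {
    stop("tcn_dilations must be strictly increasing powers of 2")
  }
  if (agg_out_channels * n_channels != tcn_channels[1]) {
    stop("agg_out_channels * n_channels must equal the TCN input width")
  }
  structure(list(
    n_channels = n_channels, n_scales = n_scales,
    window_samples = window_samples, spectrum_bins = spectrum_bins,
    n_classes = as.integer(n_classes), pool_size = pool_size,
    pool_stride = pool_stride, agg_out_channels = agg_out_channels,
    leaky_slope = leaky_slope, tcn_kernel = tcn_kernel,
    tcn_dilations = tcn_dilations, tcn_channels = tcn_channels,
    embed_dim = embed_dim, dropout_p = dropout_p
  ), class = "model_config")
}

#' The closed set of fusion variant names
#' @return Character vector of the eight recognised variants.
#' @export
variant_names <- function() {
  c("baseline", "ifia_full", "no_channel_attention", "no_cross_interaction",
    "no_temporal_compression", "data_level", "feature_level",
    "decision_level")
}

normalize_fusion <- function(fusion) {
  if (fusion == "none") fusion <- "baseline"
  if (fusion == "ifia") fusion <- "ifia_full"
  if (!fusion %in% variant_names()) {
    stop("unknown fusion variant '", fusion, "'; must be one of: ",
         paste(variant_names(), collapse = ", "))
  }
  fusion
}

# time-axis lengths through the band stages for a given window length
band_stage_dims <- function(ws = 1200, pool = 4) {
  t1c <- ws - 2; t1 <- (t1c - pool) %/% pool + 1
  t2c <- t1 - 2; t2 <- (t2c - pool) %/% pool + 1
  t3c <- t2 - 2; t3 <- (t3c - pool) %/% pool + 1
  list(t1c = t1c, t1 = t1, t2c = t2c, t2 = t2, t3c = t3c, t3 = t3,
       t_agg = t3 - 2)
}

rnorm_arr <- function(dims, sd) array(rnorm(prod(dims), 0, sd), dim = dims)

zeros <- function(n) rep(0, n)

#' Assemble a model for a fusion variant
#'
#' Builds the parameter set for the requested variant with a fully seeded
#' initialisation (He-style for convolutions and dense maps, zero biases,
#' unit BatchNorm scale). `"baseline"` carries no frequency information at
#' all; `"data_level"` appends the bilinearly resampled spectrum as a 31st
#' input band; `"feature_level"` concatenates the flattened frequency
#' features into the decoder input; `"decision_level"` runs an independent
#' frequency sub-network and averages class probabilities; the IFIA variants
#' hook in after the second conv+pool stage.
#'
#' @param fusion One of [variant_names()] (aliases: `"none"`, `"ifia"`).
#' @param mcfg A [model_config()].
#' @param icfg An [ifia_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An `ifia_model` environment.
#' @export
build_model <- function(fusion = "baseline", mcfg = model_config(),
                        icfg = ifia_config(), seed = 1) {
  fusion <- normalize_fusion(fusion)
  K <- if (fusion == "data_level") mcfg$n_scales + 1L else mcfg$n_scales
  sd_ <- band_stage_dims(mcfg$window_samples, mcfg$pool_size)
  seq_len_t <- sd_$t_agg
  D <- mcfg$agg_out_channels * mcfg$n_channels
  has_freq <- fusion %in% c("ifia_full", "no_channel_attention",
                            "no_cross_interaction",
                            "no_temporal_compression", "feature_level",
                            "decision_level")
  has_gate <- fusion %in% c("ifia_full", "no_cross_interaction",
                            "no_temporal_compression")
  has_attn <- fusion %in% c("ifia_full", "no_channel_attention",
                            "no_temporal_compression")
  fb <- (mcfg$spectrum_bins - 2 - 2 - mcfg$pool_size) %/% mcfg$pool_stride + 1
  freq_flat <- fb * mcfg$n_channels # 149 * 8 = 1192
  dec_in <- seq_len_t * D
  if (fusion == "feature_level") dec_in <- dec_in + freq_flat

  set.seed(as.integer(seed %% .Machine$integer.max))
  p <- list()
  bu <- list()
  add_bn <- function(prefix, n) {
    p[[paste0(prefix, ".gamma")]] <<- rep(1, n)
    p[[paste0(prefix, ".beta")]] <<- zeros(n)
    bu[[paste0(prefix, ".rmean")]] <<- zeros(n)
    bu[[paste0(prefix, ".rvar")]] <<- rep(1, n)
  }
  # time-frequency branch
  for (s in 1:3) {
    p[[sprintf("tf.s%d.w", s)]] <- rnorm_arr(c(3, K), sqrt(2 / 3))
    p[[sprintf("tf.s%d.b", s)]] <- zeros(K)
  }
  p[["tf.agg.W"]] <- rnorm_arr(c(mcfg$agg_out_channels, 3 * K),
                               sqrt(2 / (3 * K)))
  p[["tf.agg.b"]] <- zeros(mcfg$agg_out_channels)
  add_bn("tf.agg.bn", mcfg$agg_out_channels)
  # frequency branch
  if (has_freq) {
    for (s in 1:2) {
      p[[sprintf("fr.c%d.w", s)]] <- rnorm_arr(c(3, 1), sqrt(2 / 3))
      p[[sprintf("fr.c%d.b", s)]] <- zeros(1)
    }
  }
  # IFIA
  if (has_gate) {
    H <- floor(freq_flat / icfg$r)
    if (H < 1) stop("reduction ratio r too large: MLP hidden width is 0")
    p[["ifia.mlp.W1"]] <- rnorm_arr(c(H, freq_flat), sqrt(2 / freq_flat))
    p[["ifia.mlp.b1"]] <- zeros(H)
    p[["ifia.mlp.W2"]] <- rnorm_arr(c(mcfg$n_scales, H), sqrt(2 / H))
    p[["ifia.mlp.b2"]] <- zeros(mcfg$n_scales)
  }
  if (has_attn) {
    dm <- icfg$d_model
    p[["ifia.Wq"]] <- rnorm_arr(c(mcfg$n_scales, dm), sqrt(1 / mcfg$n_scales))
    p[["ifia.bq"]] <- zeros(dm)
    p[["ifia.Wk"]] <- rnorm_arr(c(mcfg$n_scales, dm), sqrt(1 / mcfg$n_scales))
    p[["ifia.bk"]] <- zeros(dm)
    p[["ifia.Wv"]] <- rnorm_arr(c(mcfg$n_scales, dm), sqrt(1 / mcfg$n_scales))
    p[["ifia.bv"]] <- zeros(dm)
    p[["ifia.Wo"]] <- rnorm_arr(c(dm, mcfg$n_scales), sqrt(1 / dm))
    p[["ifia.bo"]] <- zeros(mcfg$n_scales)
  }
  add_tcn <- function(prefix, width_in) {
    widths <- c(width_in, mcfg$tcn_channels)
    for (i in seq_along(mcfg$tcn_channels)) {
      ci <- widths[i]; co <- widths[i + 1]
      p[[sprintf("%s.b%d.c1.W", prefix, i)]] <<-
        rnorm_arr(c(co, 3 * ci), sqrt(2 / (3 * ci)))
      p[[sprintf("%s.b%d.c1.b", prefix, i)]] <<- zeros(co)
      add_bn(sprintf("%s.b%d.bn1", prefix, i), co)
      p[[sprintf("%s.b%d.c2.W", prefix, i)]] <<-
        rnorm_arr(c(co, 3 * co), sqrt(2 / (3 * co)))
      p[[sprintf("%s.b%d.c2.b", prefix, i)]] <<- zeros(co)
      add_bn(sprintf("%s.b%d.bn2", prefix, i), co)
      if (ci != co) {
        p[[sprintf("%s.b%d.down.W", prefix, i)]] <<-
          rnorm_arr(c(co, ci), sqrt(2 / ci))
        p[[sprintf("%s.b%d.down.b", prefix, i)]] <<- zeros(co)
      }
    }
  }
  add_dec <- function(prefix, n_in) {
    add_bn(paste0(prefix, ".bn"), n_in)
    p[[paste0(prefix, ".fc1.W")]] <<- rnorm_arr(c(mcfg$embed_dim, n_in),
                                                sqrt(2 / n_in))
    p[[paste0(prefix, ".fc1.b")]] <<- zeros(mcfg$embed_dim)
    p[[paste0(prefix, ".fc2.W")]] <<- rnorm_arr(
      c(mcfg$n_classes, mcfg$embed_dim), sqrt(2 / mcfg$embed_dim))
    p[[paste0(prefix, ".fc2.b")]] <<- zeros(mcfg$n_classes)
  }
  add_tcn("tcn", D)
  add_dec("dec", dec_in)
  if (fusion == "decision_level") {
    p[["dl.map.W"]] <- rnorm_arr(c(seq_len_t * D, freq_flat),
                                 sqrt(2 / freq_flat))
    p[["dl.map.b"]] <- zeros(seq_len_t * D)
    add_tcn("tcn2", D)
    add_dec("dec2", seq_len_t * D)
  }
  m <- new.env(parent = emptyenv())
  m$fusion <- fusion
  m$mcfg <- mcfg
  m$icfg <- icfg
  m$n_bands <- K
  m$seq_len <- seq_len_t
  m$seq_width <- D
  m$freq_flat <- freq_flat
  m$dec_in <- dec_in
  m$has_freq <- has_freq
  m$has_gate <- has_gate
  m$has_attn <- has_attn
  m$params <- p
  m$buffers <- bu
  m$grads <- list()
  m$cache <- list()
  class(m) <- "ifia_model"
  m
}

#' @rdname build_model
#' @param name Variant name (see [variant_names()]).
#' @export
build_variant <- function(name, mcfg = model_config(), icfg = ifia_config(),
                          seed = 1) {
  build_model(name, mcfg, icfg, seed)
}

#' @export
print.ifia_model <- function(x, ...) {
  cat(sprintf("<ifia_model fusion=%s, %s trainable parameters>\n",
              x$fusion, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar (convolution and dense weights and biases,
#' BatchNorm scale/shift pairs); BatchNorm running statistics are excluded.
#'
#' @param model An `ifia_model` (or a bare parameter list).
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "ifia_model")) model$params else model
  sum(vapply(p, length, integer(1)))
}

#' Receptive field of the TCN stack
#'
#' Closed form: 1 + sum over all conv layers of (kernel - 1) * dilation;
#' each temporal block contributes two convolutions at its dilation.
#'
#' @param mcfg A [model_config()].
#' @return Receptive field in time steps.
#' @export
receptive_field <- function(mcfg = model_config()) {
  1 + sum(2 * (mcfg$tcn_kernel - 1) * mcfg$tcn_dilations)
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

# linear interpolation of (bins, M) columns onto nt_out points
resample_columns <- function(xm, nt_out) {
  nb <- nrow(xm)
  xi <- seq(1, nb, length.out = nt_out)
  lo <- pmin(floor(xi), nb - 1)
  w <- xi - lo
  xm[lo, , drop = FALSE] * (1 - w) + xm[lo + 1, , drop = FALSE] * w
}

bn_apply <- function(model, prefix, x, fdim, train, cache_key) {
  p <- model$params
  bu <- model$buffers
  fm <- to_feat_mat(x, fdim)
  r <- bn_fwd_mat(fm$xm, p[[paste0(prefix, ".gamma")]],
                  p[[paste0(prefix, ".beta")]],
                  bu[[paste0(prefix, ".rmean")]],
                  bu[[paste0(prefix, ".rvar")]], train)
  if (train) {
    model$buffers[[paste0(prefix, ".rmean")]] <- r$rmean
    model$buffers[[paste0(prefix, ".rvar")]] <- r$rvar
  }
  model$cache[[cache_key]] <- list(bn = r$cache, d = fm$d, perm = fm$perm)
  from_feat_mat(r$y, fm$d, fm$perm)
}

bn_apply_bwd <- function(model, prefix, dy, cache_key) {
  cc <- model$cache[[cache_key]]
  dym <- aperm(dy, cc$perm)
  dim(dym) <- c(cc$d[cc$perm[1]], prod(cc$d[-cc$perm[1]]))
  r <- bn_bwd_mat(dym, cc$bn)
  model$grads[[paste0(prefix, ".gamma")]] <- r$dgamma
  model$grads[[paste0(prefix, ".beta")]] <- r$dbeta
  from_feat_mat(r$dx, cc$d, cc$perm)
}

# frequency branch: spec (601, 8, B) -> list(block (149,1,8,B), flat (1192,B))
freq_fwd <- function(model, spec, train) {
  p <- model$params
  d <- dim(spec)
  B <- d[3]
  x <- spec
  dim(x) <- c(d[1], 1, d[2], B)
  c1 <- cpp_band_conv_fwd(x, p[["fr.c1.w"]], p[["fr.c1.b"]], d[1], 1L,
                          d[2], B)
  c2 <- cpp_band_conv_fwd(c1, p[["fr.c2.w"]], p[["fr.c2.b"]], d[1] - 2, 1L,
                          d[2], B)
  mp <- cpp_pool_max_fwd(c2, d[1] - 4, model$mcfg$pool_size,
                         model$mcfg$pool_stride)
  fb <- (d[1] - 4 - model$mcfg$pool_size) %/% model$mcfg$pool_stride + 1
  block <- mp$y
  dim(block) <- c(fb, 1, d[2], B)
  flat <- mp$y
  dim(flat) <- c(fb * d[2], B)
  model$cache$fr <- list(x = x, c1 = c1, idx = mp$idx, d = d, fb = fb)
  list(block = block, flat = flat)
}

freq_bwd <- function(model, dflat) {
  cc <- model$cache$fr
  d <- cc$d
  B <- d[3]
  dmp <- cpp_pool_max_bwd(dflat, cc$idx, d[1] - 4, cc$fb)
  r2 <- cpp_band_conv_bwd(cc$c1, model$params[["fr.c2.w"]], dmp, d[1] - 2,
                          1L, d[2], B)
  model$grads[["fr.c2.w"]] <- r2$dw
  model$grads[["fr.c2.b"]] <- r2$db
  r1 <- cpp_band_conv_bwd(cc$x, model$params[["fr.c1.w"]], r2$dx, d[1], 1L,
                          d[2], B)
  model$grads[["fr.c1.w"]] <- r1$dw
  model$grads[["fr.c1.b"]] <- r1$db
  invisible(NULL)
}

# TCN over (T, D, B)
tcn_fwd_internal <- function(model, z, prefix, train) {
  mcfg <- model$mcfg
  widths <- c(dim(z)[2], mcfg$tcn_channels)
  cc <- list()
  for (i in seq_along(mcfg$tcn_channels)) {
    dil <- mcfg$tcn_dilations[i]
    inp <- z
    c1 <- tcn_conv_fwd(inp, model$params[[sprintf("%s.b%d.c1.W", prefix, i)]],
                       model$params[[sprintf("%s.b%d.c1.b", prefix, i)]], dil)
    n1 <- bn_apply(model, sprintf("%s.b%d.bn1", prefix, i), c1$y, 2, train,
                   sprintf("%s.b%d.bn1", prefix, i))
    r1 <- relu_fwd(n1)
    c2 <- tcn_conv_fwd(r1$y, model$params[[sprintf("%s.b%d.c2.W", prefix, i)]],
                       model$params[[sprintf("%s.b%d.c2.b", prefix, i)]], dil)
    n2 <- bn_apply(model, sprintf("%s.b%d.bn2", prefix, i), c2$y, 2, train,
                   sprintf("%s.b%d.bn2", prefix, i))
    r2 <- relu_fwd(n2)
    if (widths[i] != widths[i + 1]) {
      dn <- pointwise_fwd(inp, model$params[[sprintf("%s.b%d.down.W", prefix, i)]],
                          model$params[[sprintf("%s.b%d.down.b", prefix, i)]])
      res <- dn$y
      cc[[i]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                      r2 = r2$cache, down = dn$cache)
    } else {
      res <- inp
      cc[[i]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                      r2 = r2$cache, down = NULL)
    }
    z <- r2$y + res
  }
  model$cache[[paste0(prefix, ".blocks")]] <- cc
  z
}

tcn_bwd_internal <- function(model, dz, prefix) {
  mcfg <- model$mcfg
  widths <- c(model$seq_width, mcfg$tcn_channels)
  cc <- model$cache[[paste0(prefix, ".blocks")]]
  for (i in rev(seq_along(mcfg$tcn_channels))) {
    dil <- mcfg$tcn_dilations[i]
    b <- cc[[i]]
    dres <- dz
    dr2 <- relu_bwd(dz, b$r2)
    dn2 <- bn_apply_bwd(model, sprintf("%s.b%d.bn2", prefix, i), dr2,
                        sprintf("%s.b%d.bn2", prefix, i))
    g2 <- tcn_conv_bwd(dn2, b$c2,
                       model$params[[sprintf("%s.b%d.c2.W", prefix, i)]],
                       NULL, dil)
    model$grads[[sprintf("%s.b%d.c2.W", prefix, i)]] <- g2$dW
    model$grads[[sprintf("%s.b%d.c2.b", prefix, i)]] <- g2$db
    dr1 <- relu_bwd(g2$dx, b$r1)
    dn1 <- bn_apply_bwd(model, sprintf("%s.b%d.bn1", prefix, i), dr1,
                        sprintf("%s.b%d.bn1", prefix, i))
    g1 <- tcn_conv_bwd(dn1, b$c1,
                       model$params[[sprintf("%s.b%d.c1.W", prefix, i)]],
                       NULL, dil)
    model$grads[[sprintf("%s.b%d.c1.W", prefix, i)]] <- g1$dW
    model$grads[[sprintf("%s.b%d.c1.b", prefix, i)]] <- g1$db
    dinp <- g1$dx
    if (widths[i] != widths[i + 1]) {
      gd <- pointwise_bwd(dres, b$down,
                          model$params[[sprintf("%s.b%d.down.W", prefix, i)]])
      model$grads[[sprintf("%s.b%d.down.W", prefix, i)]] <- gd$dW
      model$grads[[sprintf("%s.b%d.down.b", prefix, i)]] <- gd$db
      dinp <- dinp + gd$dx
    } else {
      dinp <- dinp + dres
    }
    dz <- dinp
  }
  dz
}

# decoder over flattened features (F, B); extra rows already appended
dec_fwd_internal <- function(model, flat, prefix, train) {
  n <- bn_apply(model, paste0(prefix, ".bn"), flat, 1, train,
                paste0(prefix, ".bn"))
  f1 <- linear_fwd(n, model$params[[paste0(prefix, ".fc1.W")]],
                   model$params[[paste0(prefix, ".fc1.b")]])
  l1 <- leaky_fwd(f1$y, model$mcfg$leaky_slope)
  dp <- dropout_fwd(l1$y, model$mcfg$dropout_p, train)
  f2 <- linear_fwd(dp$y, model$params[[paste0(prefix, ".fc2.W")]],
                   model$params[[paste0(prefix, ".fc2.b")]])
  model$cache[[paste0(prefix, ".dec")]] <-
    list(f1 = f1$cache, l1 = l1$cache, dp = dp$cache, f2 = f2$cache)
  f2$y
}

dec_bwd_internal <- function(model, dscores, prefix) {
  cc <- model$cache[[paste0(prefix, ".dec")]]
  g2 <- linear_bwd(dscores, cc$f2, model$params[[paste0(prefix, ".fc2.W")]])
  model$grads[[paste0(prefix, ".fc2.W")]] <- g2$dW
  model$grads[[paste0(prefix, ".fc2.b")]] <- g2$db
  ddp <- dropout_bwd(g2$dx, cc$dp)
  dl1 <- leaky_bwd(ddp, cc$l1, model$mcfg$leaky_slope)
  g1 <- linear_bwd(dl1, cc$f1, model$params[[paste0(prefix, ".fc1.W")]])
  model$grads[[paste0(prefix, ".fc1.W")]] <- g1$dW
  model$grads[[paste0(prefix, ".fc1.b")]] <- g1$db
  bn_apply_bwd(model, paste0(prefix, ".bn"), g1$dx, paste0(prefix, ".bn"))
}

# time-frequency encoder: tf (ws, K, C, B) -> sequence (T, D, B).
# `fuse` = NULL or a function(X2) -> fused applied at the stage-2 insertion
# point; its backward is handled by the caller via model$cache.
tf_encode_fwd <- function(model, tf, train, fuse = NULL) {
  p <- model$params
  mcfg <- model$mcfg
  d <- if (inherits(tf, "qbatch")) tf$dims else dim(tf)
  K <- d[2]; C <- d[3]; B <- d[4]
  sd_ <- band_stage_dims(d[1], mcfg$pool_size)
  p1 <- if (inherits(tf, "qbatch")) {
    cpp_band_stage_fwd_u16(tf$cache, tf$scales, tf$pos, p[["tf.s1.w"]],
                           p[["tf.s1.b"]], d[1], K, C, mcfg$pool_size)
  } else {
    cpp_band_stage_fwd(tf, p[["tf.s1.w"]], p[["tf.s1.b"]], d[1], K, C, B,
                       mcfg$pool_size)
  }
  p2 <- cpp_band_stage_fwd(p1, p[["tf.s2.w"]], p[["tf.s2.b"]], sd_$t1, K, C,
                           B, mcfg$pool_size)
  X2 <- p2
  X2f <- if (is.null(fuse)) X2 else fuse(X2)
  p3 <- cpp_band_stage_fwd(X2f, p[["tf.s3.w"]], p[["tf.s3.b"]], sd_$t2, K, C,
                           B, mcfg$pool_size)
  ag <- agg_conv_fwd(p3, p[["tf.agg.W"]], p[["tf.agg.b"]])
  nb <- bn_apply(model, "tf.agg.bn", ag$y, 2, train, "tf.agg.bn")
  lk <- leaky_fwd(nb, mcfg$leaky_slope)
  z <- aperm(lk$y, c(1, 3, 2, 4)) # (T, muscle, aggch, B)
  dim(z) <- c(sd_$t_agg, C * mcfg$agg_out_channels, B)
  model$cache$tf <- list(
    x = tf, p1 = p1, X2 = X2, X2f = X2f, p3 = p3, agg = ag$cache,
    lk = lk$cache, sd = sd_, K = K, C = C, B = B,
    shapes = list(
      input = c(d[1], K, C), s1_conv = c(sd_$t1c, K, C),
      s1_pool = c(sd_$t1, K, C), s2_conv = c(sd_$t2c, K, C),
      s2_pool = c(sd_$t2, K, C), s3_conv = c(sd_$t3c, K, C),
      s3_pool = c(sd_$t3, K, C),
      agg_conv = c(sd_$t_agg, mcfg$agg_out_channels, C),
      seq = c(sd_$t_agg, C * mcfg$agg_out_channels)
    )
  )
  z
}

# backward through the encoder; returns gradient wrt the fused stage-2 block
# in dX2f; the caller routes it through the fusion backward.
tf_encode_bwd <- function(model, dz) {
  cc <- model$cache$tf
  p <- model$params
  mcfg <- model$mcfg
  sd_ <- cc$sd
  K <- cc$K; C <- cc$C; B <- cc$B
  dim(dz) <- c(sd_$t_agg, C, mcfg$agg_out_channels, B)
  dlk <- aperm(dz, c(1, 3, 2, 4))
  dnb <- leaky_bwd(dlk, cc$lk, mcfg$leaky_slope)
  dag <- bn_apply_bwd(model, "tf.agg.bn", dnb, "tf.agg.bn")
  g <- agg_conv_bwd(dag, cc$agg, p[["tf.agg.W"]])
  model$grads[["tf.agg.W"]] <- g$dW
  model$grads[["tf.agg.b"]] <- g$db
  r3 <- cpp_band_stage_bwd(cc$X2f, p[["tf.s3.w"]], g$dx, sd_$t2, K, C, B,
                           mcfg$pool_size, TRUE)
  model$grads[["tf.s3.w"]] <- r3$dw
  model$grads[["tf.s3.b"]] <- r3$db
  r3$dx # gradient wrt X2f, dims (t2, K, C, B)
}

# continue backward from the (un-fused) stage-2 gradient down to the input
tf_encode_bwd_tail <- function(model, dX2) {
  cc <- model$cache$tf
  p <- model$params
  mcfg <- model$mcfg
  sd_ <- cc$sd
  K <- cc$K; C <- cc$C; B <- cc$B
  r2 <- cpp_band_stage_bwd(cc$p1, p[["tf.s2.w"]], dX2, sd_$t1, K, C, B,
                           mcfg$pool_size, TRUE)
  model$grads[["tf.s2.w"]] <- r2$dw
  model$grads[["tf.s2.b"]] <- r2$db
  # the input gradient of stage 1 is never consumed (input layer): skip it
  r1 <- if (inherits(cc$x, "qbatch")) {
    cpp_band_stage_bwd_u16(cc$x$cache, cc$x$scales, cc$x$pos, r2$dx,
                           cc$x$dims[1], K, C, mcfg$pool_size)
  } else {
    cpp_band_stage_bwd(cc$x, p[["tf.s1.w"]], r2$dx, dim(cc$x)[1], K, C, B,
                       mcfg$pool_size, FALSE)
  }
  model$grads[["tf.s1.w"]] <- r1$dw
  model$grads[["tf.s1.b"]] <- r1$db
  invisible(NULL)
}

#' Model forward pass
#'
#' @param model An `ifia_model`.
#' @param tf Scalogram batch `(window_samples, 30, 8, B)` (time-major
#'   internal layout).
#' @param spec Spectrum batch `(601, 8, B)`; required for every variant
#'   except `"baseline"`.
#' @param train Logical; training mode enables batch statistics, dropout and
#'   caching for the backward pass.
#' @return Class score matrix `(n_classes, B)`. For `"decision_level"` the
#'   scores are log average probabilities, so a softmax over them recovers
#'   the averaged class probabilities exactly.
#' @export
model_forward <- function(model, tf, spec = NULL, train = FALSE) {
  fusion <- model$fusion
  model$cache <- list()
  model$grads <- list()
  if (fusion != "baseline" && is.null(spec)) {
    stop("variant '", fusion, "' needs the spectrum input")
  }
  B <- if (inherits(tf, "qbatch")) tf$dims[4] else dim(tf)[4]
  if (fusion == "data_level") {
    if (inherits(tf, "qbatch")) {
      stop("data_level fusion needs dense scalogram input")
    }
    sm <- spec
    dim(sm) <- c(dim(spec)[1], dim(spec)[2] * B)
    band31 <- resample_columns(sm, dim(tf)[1])
    dim(band31) <- c(dim(tf)[1], 1, dim(spec)[2], B)
    tf2 <- array(0, dim(tf) + c(0, 1, 0, 0))
    tf2[, seq_len(dim(tf)[2]), , ] <- tf
    tf2[, dim(tf2)[2], , ] <- band31
    z <- tf_encode_fwd(model, tf2, train)
    z <- tcn_fwd_internal(model, z, "tcn", train)
    flat <- z
    dim(flat) <- c(model$seq_len * model$seq_width, B)
    return(dec_fwd_internal(model, flat, "dec", train))
  }
  if (fusion == "baseline") {
    z <- tf_encode_fwd(model, tf, train)
    z <- tcn_fwd_internal(model, z, "tcn", train)
    flat <- z
    dim(flat) <- c(model$seq_len * model$seq_width, B)
    return(dec_fwd_internal(model, flat, "dec", train))
  }
  fr <- freq_fwd(model, spec, train)
  if (fusion %in% c("ifia_full", "no_channel_attention",
                    "no_cross_interaction", "no_temporal_compression")) {
    fuse <- function(X2) ifia_fwd(model, X2, fr$flat)
    z <- tf_encode_fwd(model, tf, train, fuse = fuse)
    z <- tcn_fwd_internal(model, z, "tcn", train)
    flat <- z
    dim(flat) <- c(model$seq_len * model$seq_width, B)
    return(dec_fwd_internal(model, flat, "dec", train))
  }
  if (fusion == "feature_level") {
    z <- tf_encode_fwd(model, tf, train)
    z <- tcn_fwd_internal(model, z, "tcn", train)
    flat <- z
    dim(flat) <- c(model$seq_len * model$seq_width, B)
    flat <- rbind(flat, fr$flat)
    return(dec_fwd_internal(model, flat, "dec", train))
  }
  # decision_level
  z <- tf_encode_fwd(model, tf, train)
  z <- tcn_fwd_internal(model, z, "tcn", train)
  flatA <- z
  dim(flatA) <- c(model$seq_len * model$seq_width, B)
  scoresA <- dec_fwd_internal(model, flatA, "dec", train)
  mp <- linear_fwd(fr$flat, model$params[["dl.map.W"]],
                   model$params[["dl.map.b"]])
  z2 <- mp$y
  dim(z2) <- c(model$seq_len, model$seq_width, B)
  z2 <- tcn_fwd_internal(model, z2, "tcn2", train)
  flatB <- z2
  dim(flatB) <- c(model$seq_len * model$seq_width, B)
  scoresB <- dec_fwd_internal(model, flatB, "dec2", train)
  pA <- softmax_cols(scoresA)
  pB <- softmax_cols(scoresB)
  pavg <- (pA + pB) / 2
  model$cache$dl <- list(pA = pA, pB = pB, pavg = pavg, map = mp$cache)
  log(pavg + 1e-12)
}

#' Model backward pass
#'
#' Accumulates parameter gradients into `model$grads` for the most recent
#' training-mode forward.
#'
#' @param model An `ifia_model` after `model_forward(..., train = TRUE)`.
#' @param dscores Gradient of the loss wrt the returned scores.
#' @export
model_backward <- function(model, dscores) {
  fusion <- model$fusion
  B <- ncol(dscores)
  if (fusion == "decision_level") {
    cc <- model$cache$dl
    dpavg <- dscores / (cc$pavg + 1e-12)
    dsA <- softmax_bwd_cols(dpavg / 2, cc$pA)
    dsB <- softmax_bwd_cols(dpavg / 2, cc$pB)
    dflatB <- dec_bwd_internal(model, dsB, "dec2")
    dim(dflatB) <- c(model$seq_len, model$seq_width, B)
    dz2 <- tcn_bwd_internal(model, dflatB, "tcn2")
    dim(dz2) <- c(model$seq_len * model$seq_width, B)
    gm <- linear_bwd(dz2, model$cache$dl$map, model$params[["dl.map.W"]])
    model$grads[["dl.map.W"]] <- gm$dW
    model$grads[["dl.map.b"]] <- gm$db
    dflatA <- dec_bwd_internal(model, dsA, "dec")
    dim(dflatA) <- c(model$seq_len, model$seq_width, B)
    dz <- tcn_bwd_internal(model, dflatA, "tcn")
    dX2f <- tf_encode_bwd(model, dz)
    tf_encode_bwd_tail(model, dX2f)
    freq_bwd(model, gm$dx)
    model$cache <- list()
    return(invisible(NULL))
  }
  dflat <- dec_bwd_internal(model, dscores, "dec")
  dextra <- NULL
  if (fusion == "feature_level") {
    n_seq <- model$seq_len * model$seq_width
    dextra <- dflat[(n_seq + 1):nrow(dflat), , drop = FALSE]
    dflat <- dflat[seq_len(n_seq), , drop = FALSE]
  }
  dim(dflat) <- c(model$seq_len, model$seq_width, B)
  dz <- tcn_bwd_internal(model, dflat, "tcn")
  dX2f <- tf_encode_bwd(model, dz)
  if (fusion %in% c("ifia_full", "no_channel_attention",
                    "no_cross_interaction", "no_temporal_compression")) {
    r <- ifia_bwd(model, dX2f)
    tf_encode_bwd_tail(model, r$dX2)
    freq_bwd(model, r$dfvec)
  } else {
    tf_encode_bwd_tail(model, dX2f)
    if (fusion == "feature_level") freq_bwd(model, dextra)
  }
  model$cache <- list()
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# spec-level single-input operations
# ---------------------------------------------------------------------------

# accepts (30, T, 8) or (30, T, 8, B); returns internal (T, 30, 8, B)
tfmap_to_internal <- function(tfmap) {
  d <- dim(tfmap)
  if (length(d) == 3) dim(tfmap) <- c(d, 1)
  aperm(tfmap, c(2, 1, 3, 4))
}

#' Time-frequency branch forward
#'
#' Runs one scalogram through the band-wise conv stages, aggregation and
#' rearrangement, exposing the stage-2 intermediate (the IFIA insertion
#' point).
#'
#' @param model An `ifia_model`.
#' @param tfmap Scalogram `(30, time, 8)` as produced by [cwt_transform()].
#' @return List with `encoded` (16 x 128 sequence) and `stage2`
#'   (`(30, 74, 8)` intermediate after the second conv+pool).
#' @export
tf_branch_forward <- function(model, tfmap) {
  x <- tfmap_to_internal(tfmap)
  if (dim(x)[2] != model$n_bands) {
    stop("expected ", model$n_bands, " bands, got ", dim(x)[2])
  }
  z <- tf_encode_fwd(model, x, train = FALSE)
  stage2 <- model$cache$tf$X2[, , , 1]
  list(encoded = z[, , 1], stage2 = aperm(stage2, c(2, 1, 3)))
}

#' Frequency branch forward
#'
#' @param model An `ifia_model` with a frequency branch.
#' @param spectrum `(601, 8)` one-sided magnitude spectrum.
#' @return List with `block` (`(1, 149, 8)`) and `flat` (length 1192).
#' @export
freq_branch_forward <- function(model, spectrum) {
  if (!model$has_freq) stop("variant '", model$fusion,
                            "' has no frequency branch")
  sp <- as.matrix(spectrum)
  dim(sp) <- c(nrow(spectrum), ncol(spectrum), 1)
  fr <- freq_fwd(model, sp, train = FALSE)
  block <- fr$block[, , , 1]
  dim(block) <- c(1, dim(fr$block)[1], dim(fr$block)[3])
  list(block = block, flat = as.numeric(fr$flat))
}

#' TCN forward on one encoded sequence
#'
#' @param model An `ifia_model`.
#' @param seq `(16, 128)` encoded sequence.
#' @return `(16, 128)` output sequence.
#' @export
tcn_forward <- function(model, seq) {
  if (nrow(seq) < 1) stop("sequence must have at least one step")
  z <- array(seq, c(nrow(seq), ncol(seq), 1))
  out <- tcn_fwd_internal(model, z, "tcn", train = FALSE)
  out[, , 1]
}

#' Decode an encoded sequence into class scores
#'
#' @param model An `ifia_model`.
#' @param seq `(16, 128)` sequence (TCN output).
#' @param freq_flat Flattened frequency features, only for the
#'   feature-level fusion decoder.
#' @return Unnormalised class score vector of length `n_classes`.
#' @export
decode <- function(model, seq, freq_flat = NULL) {
  flat <- matrix(as.numeric(seq), ncol = 1)
  if (model$fusion == "feature_level") {
    if (is.null(freq_flat)) stop("feature_level decoder needs freq_flat")
    flat <- rbind(flat, matrix(freq_flat, ncol = 1))
  }
  as.numeric(dec_fwd_internal(model, flat, "dec", train = FALSE))
}

#' Predict class scores for a feature batch
#'
#' @inheritParams model_forward
#' @return `(n_classes, B)` score matrix (inference mode).
#' @export
model_predict <- function(model, tf, spec = NULL) {
  model_forward(model, tf, spec, train = FALSE)
}

# ---------------------------------------------------------------------------
# checkpoints
# ---------------------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A single file holding the weight map keyed by module path plus the model
#' configuration; loading verifies the configuration and fails loudly on a
#' mismatch.
#'
#' @param model An `ifia_model`.
#' @param path Checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "ifianet_checkpoint", version = 1L,
               fusion = model$fusion, mcfg = unclass(model$mcfg),
               icfg = unclass(model$icfg), params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_fusion Optional variant name to enforce.
#' @return The restored `ifia_model`.
#' @export
load_checkpoint <- function(path, expect_fusion = NULL) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "ifianet_checkpoint"))
  if (!is.null(expect_fusion) &&
      normalize_fusion(expect_fusion) != obj$fusion) {
    stop("checkpoint fusion '", obj$fusion, "' does not match expected '",
         expect_fusion, "'")
  }
  mcfg <- do.call(model_config, obj$mcfg)
  icfg <- do.call(ifia_config, obj$icfg)
  m <- build_model(obj$fusion, mcfg, icfg, seed = 0)
  if (!identical(lapply(m$params, dim), lapply(obj$params, dim)) ||
      !identical(names(m$params), names(obj$params))) {
    stop("checkpoint parameter map does not match the declared configuration")
  }
  m$params <- obj$params
  m$buffers <- obj$buffers
  m
}
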