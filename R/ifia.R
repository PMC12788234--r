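# Frequency-Informed Integration Attention (IFIA).
#
# At the stage-2 insertion point of the time-frequency branch (a
# (30 bands, 74 steps, 8 muscles) block), the module
#   1. channel enhancement: a squeeze-style MLP on the flattened frequency
#      features (1192 -> 1192/r -> 30, logistic output) yields one gate per
#      CWT band; the block is multiplied band-wise by the gates;
#   2. temporal compression: the gated block is averaged over time into one
#      global frequency-modulation token per band and muscle;
#   3. cross-domain interaction: per muscle channel, the 74 original
#      time-step band vectors plus the compressed token go through multi-head
#      self-attention (weights shared across muscles); the 74 outputs are
#      added residually to the original block, the compressed token's output
#      is discarded.
# The ablation variants drop one of the three operations each; the module
# always preserves the stage-2 shape so later encoder stages are untouched.

#' IFIA configuration
#'
#' @param r MLP reduction ratio (default 4): the gating MLP hidden width is
#'   `floor(1192 / r)`.
#' @param n_heads Attention heads (default 2).
#' @param d_model Attention width (default 64); must be divisible by
#'   `n_heads`.
#' @return An `ifia_config` list.
#' @export
ifia_config <- function(r = 4, n_heads = 2, d_model = 64) {
  if (r < 1) stop("reduction ratio r must be >= 1")
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  structure(list(r = r, n_heads = n_heads, d_model = d_model),
            class = "ifia_config")
}

# gate broadcast helpers: g (K, B) -> array (t, K, C, B) and its reduction
gate_expand <- function(g, t, C) {
  K <- nrow(g)
  m <- g[rep(seq_len(K), each = t), , drop = FALSE]
  m <- m[rep(seq_len(t * K), times = C), , drop = FALSE]
  array(m, c(t, K, C, dim(g)[2]))
}

gate_reduce <- function(A) {
  s <- colSums(A, dims = 1)  # (K, C, B)
  s <- aperm(s, c(2, 1, 3))
  colSums(s, dims = 1)       # (K, B)
}

gates_fwd <- function(model, fvec) {
  p <- model$params
  hpre <- p[["ifia.mlp.W1"]] %*% fvec + p[["ifia.mlp.b1"]]
  hneg <- hpre < 0
  h <- hpre
  h[hneg] <- 0
  z <- p[["ifia.mlp.W2"]] %*% h + p[["ifia.mlp.b2"]]
  g <- sigmoid(z)
  list(g = g, h = h, hneg = hneg, fvec = fvec)
}

gates_bwd <- function(model, dg, cc) {
  p <- model$params
  dz <- dg * cc$g * (1 - cc$g)
  model$grads[["ifia.mlp.W2"]] <- tcrossprod(dz, cc$h)
  model$grads[["ifia.mlp.b2"]] <- rowSums(dz)
  dh <- crossprod(p[["ifia.mlp.W2"]], dz)
  dh[cc$hneg] <- 0
  model$grads[["ifia.mlp.W1"]] <- tcrossprod(dh, cc$fvec)
  model$grads[["ifia.mlp.b1"]] <- rowSums(dh)
  crossprod(p[["ifia.mlp.W1"]], dh)
}

attn_params <- function(model) {
  p <- model$params
  list(Wq = p[["ifia.Wq"]], bq = p[["ifia.bq"]], Wk = p[["ifia.Wk"]],
       bk = p[["ifia.bk"]], Wv = p[["ifia.Wv"]], bv = p[["ifia.bv"]],
       Wo = p[["ifia.Wo"]], bo = p[["ifia.bo"]])
}

# internal fused forward at the insertion point.
# X2 (t, K, C, B), fvec (1192, B); returns fused block, cache on the model.
ifia_fwd <- function(model, X2, fvec) {
  d <- dim(X2)
  t2 <- d[1]; K <- d[2]; C <- d[3]; B <- d[4]
  S <- C * B
  fusion <- model$fusion
  cc <- list(dims = d)
  gated <- NULL
  if (model$has_gate) {
    gt <- gates_fwd(model, fvec)
    garr <- gate_expand(gt$g, t2, C)
    gated <- X2 * garr
    cc$gate <- gt
    cc$garr <- garr
    cc$X2 <- X2
  }
  if (fusion == "no_cross_interaction") {
    model$cache$ifia <- cc
    return(gated)
  }
  src <- if (fusion == "no_channel_attention") X2 else gated
  if (fusion == "no_temporal_compression") {
    L <- 2 * t2
    tok <- array(0, c(L, K, S))
    Xs <- X2; dim(Xs) <- c(t2, K, S)
    Gs <- gated; dim(Gs) <- c(t2, K, S)
    tok[seq_len(t2), , ] <- Xs
    tok[t2 + seq_len(t2), , ] <- Gs
  } else {
    L <- t2 + 1
    cm <- colMeans(src, dims = 1) # (K, C, B)
    tok <- array(0, c(L, K, S))
    Xs <- X2; dim(Xs) <- c(t2, K, S)
    tok[seq_len(t2), , ] <- Xs
    cms <- cm; dim(cms) <- c(K, S)
    tok[L, , ] <- cms
  }
  ap <- attn_params(model)
  at <- cpp_attn_fwd(tok, L, K, S, ap$Wq, ap$bq, ap$Wk, ap$bk, ap$Wv, ap$bv,
                     ap$Wo, ap$bo, model$icfg$n_heads, t2)
  out <- at$out
  dim(out) <- c(t2, K, C, B)
  cc$tok <- tok
  cc$at <- at
  cc$L <- L
  model$cache$ifia <- cc
  X2 + out
}

# backward: dF is the gradient at the fused block; returns gradients wrt the
# un-fused stage-2 block and the flattened frequency features.
ifia_bwd <- function(model, dF) {
  cc <- model$cache$ifia
  d <- cc$dims
  t2 <- d[1]; K <- d[2]; C <- d[3]; B <- d[4]
  S <- C * B
  fusion <- model$fusion
  zero_fvec <- function() matrix(0, model$freq_flat, B)
  if (fusion == "no_cross_interaction") {
    dXg <- dF
    dX2 <- dXg * cc$garr
    dg <- gate_reduce(dXg * cc$X2)
    dfvec <- gates_bwd(model, dg, cc$gate)
    return(list(dX2 = dX2, dfvec = dfvec))
  }
  dtok_out <- dF
  dim(dtok_out) <- c(t2, K, S)
  ap <- attn_params(model)
  ab <- cpp_attn_bwd(cc$tok, dtok_out, cc$at$Q, cc$at$K, cc$at$V, cc$at$O,
                     cc$at$A, cc$L, K, S, ap$Wq, ap$Wk, ap$Wv, ap$Wo,
                     model$icfg$n_heads, t2)
  model$grads[["ifia.Wq"]] <- ab$dWq
  model$grads[["ifia.bq"]] <- as.numeric(ab$dbq)
  model$grads[["ifia.Wk"]] <- ab$dWk
  model$grads[["ifia.bk"]] <- as.numeric(ab$dbk)
  model$grads[["ifia.Wv"]] <- ab$dWv
  model$grads[["ifia.bv"]] <- as.numeric(ab$dbv)
  model$grads[["ifia.Wo"]] <- ab$dWo
  model$grads[["ifia.bo"]] <- as.numeric(ab$dbo)
  dtok <- ab$dtok
  dX2 <- dF
  dfirst <- dtok[seq_len(t2), , , drop = FALSE]
  dim(dfirst) <- c(t2, K, C, B)
  dX2 <- dX2 + dfirst
  if (fusion == "no_temporal_compression") {
    dXg <- dtok[t2 + seq_len(t2), , , drop = FALSE]
    dim(dXg) <- c(t2, K, C, B)
    dX2 <- dX2 + dXg * cc$garr
    dg <- gate_reduce(dXg * cc$X2)
    dfvec <- gates_bwd(model, dg, cc$gate)
    return(list(dX2 = dX2, dfvec = dfvec))
  }
  dcm <- dtok[cc$L, , ]
  dim(dcm) <- c(K, C, B)
  dsrc <- array(rep(as.numeric(dcm) / t2, each = t2), c(t2, K, C, B))
  if (fusion == "no_channel_attention") {
    dX2 <- dX2 + dsrc
    return(list(dX2 = dX2, dfvec = zero_fvec()))
  }
  # ifia_full: compressed token came from the gated block
  dXg <- dsrc
  dX2 <- dX2 + dXg * cc$garr
  dg <- gate_reduce(dXg * cc$X2)
  dfvec <- gates_bwd(model, dg, cc$gate)
  list(dX2 = dX2, dfvec = dfvec)
}

# ---------------------------------------------------------------------------
# single-input public operations (spec layout: (bands, time, muscles))
# ---------------------------------------------------------------------------

spec_to_internal <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(2, 1, 3))
  dim(y) <- c(d[2], d[1], d[3], 1)
  y
}

internal_to_spec <- function(x) {
  aperm(x[, , , 1, drop = FALSE][, , , 1], c(2, 1, 3))
}

#' Channel enhancement: frequency-guided band gating
#'
#' The flattened frequency features pass through the gating MLP
#' (`1192 -> floor(1192/r) -> 30`, rectifier then logistic); each of the 30
#' scalogram bands of the stage-2 block is scaled by its gate.
#'
#' @param tf_stage2 `(30, 74, 8)` stage-2 block.
#' @param freq_feats Length-1192 flattened frequency features.
#' @param model An `ifia_model` with the gating MLP
#'   (`ifia_full`, `no_cross_interaction` or `no_temporal_compression`).
#' @return List with `gated` (`(30, 74, 8)`) and `gates` (30 values in
#'   (0, 1)).
#' @export
channel_enhance <- function(tf_stage2, freq_feats, model) {
  if (!model$has_gate) stop("variant '", model$fusion,
                            "' has no channel-attention MLP")
  fvec <- matrix(freq_feats, ncol = 1)
  gt <- gates_fwd(model, fvec)
  X <- spec_to_internal(tf_stage2)
  garr <- gate_expand(gt$g, dim(X)[1], dim(X)[3])
  list(gated = internal_to_spec(X * garr), gates = as.numeric(gt$g))
}

#' Temporal compression of a guided block
#'
#' Arithmetic mean over the time axis, yielding one global
#' frequency-modulation vector per band and muscle.
#'
#' @param gated `(30, time, 8)` block.
#' @return `(30, 1, 8)` compressed block.
#' @export
temporal_compress <- function(gated) {
  m <- apply(gated, c(1, 3), mean)
  dim(m) <- c(dim(gated)[1], 1, dim(gated)[3])
  m
}

#' Cross-domain interaction via multi-head self-attention
#'
#' Per muscle channel, the time-step band vectors of `original` plus the
#' compressed token attend to each other; the time-step outputs are projected
#' back and added residually to `original`, the compressed token's output is
#' discarded.
#'
#' @param original `(30, 74, 8)` block.
#' @param compressed `(30, 1, 8)` compressed token.
#' @param model An `ifia_model` with attention weights.
#' @return Fused `(30, 74, 8)` block.
#' @export
cross_interact <- function(original, compressed, model) {
  if (!model$has_attn) stop("variant '", model$fusion,
                            "' has no cross-interaction attention")
  X <- spec_to_internal(original)       # (t, K, C, 1)
  d <- dim(X)
  t2 <- d[1]; K <- d[2]; C <- d[3]
  L <- t2 + 1
  tok <- array(0, c(L, K, C))
  Xs <- X; dim(Xs) <- c(t2, K, C)
  tok[seq_len(t2), , ] <- Xs
  tok[L, , ] <- compressed[, 1, ]
  ap <- attn_params(model)
  at <- cpp_attn_fwd(tok, L, K, C, ap$Wq, ap$bq, ap$Wk, ap$bk, ap$Wv, ap$bv,
                     ap$Wo, ap$bo, model$icfg$n_heads, t2)
  out <- at$out
  dim(out) <- c(t2, K, C, 1)
  internal_to_spec(X + out)
}

#' Attention weights of the cross-interaction for one muscle channel
#'
#' Exposed for inspection/testing: rows are queries, columns keys; each row
#' sums to one per head.
#'
#' @param original,compressed,model As in [cross_interact()].
#' @param channel Muscle channel index (1..8).
#' @return `(L, L, n_heads)` attention array, L = time steps + 1.
#' @export
attention_weights <- function(original, compressed, model, channel = 1) {
  X <- spec_to_internal(original)
  d <- dim(X)
  t2 <- d[1]; K <- d[2]; C <- d[3]
  L <- t2 + 1
  tok <- array(0, c(L, K, C))
  Xs <- X; dim(Xs) <- c(t2, K, C)
  tok[seq_len(t2), , ] <- Xs
  tok[L, , ] <- compressed[, 1, ]
  ap <- attn_params(model)
  at <- cpp_attn_fwd(tok, L, K, C, ap$Wq, ap$bq, ap$Wk, ap$bk, ap$Wv, ap$bv,
                     ap$Wo, ap$bo, model$icfg$n_heads, t2)
  A <- at$A
  dim(A) <- c(L, L, model$icfg$n_heads, C)
  A[, , , channel]
}
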