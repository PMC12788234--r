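# Minimal neural-network primitives with hand-written backpropagation.
#
# Tensors are plain R arrays, column-major with time leading:
#   band stages   (T, K, C, B)   K frequency bands, C muscle channels
#   sequences     (T, D, B)      D features
#   dense blocks  (F, B)
# Each *_fwd returns list(y, cache); each *_bwd consumes the cache and the
# upstream gradient and returns the input gradient plus parameter gradients.
# Heavy inner loops live in src/kernels.cpp; everything else is BLAS.

# ---- activations -----------------------------------------------------------

leaky_fwd <- function(x, slope = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, cache = neg)
}

leaky_bwd <- function(dy, cache, slope = 0.01) {
  dx <- dy
  dx[cache] <- slope * dy[cache]
  dx
}

relu_fwd <- function(x) {
  neg <- x < 0
  y <- x
  y[neg] <- 0
  list(y = y, cache = neg)
}

relu_bwd <- function(dy, cache) {
  dx <- dy
  dx[cache] <- 0
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, cache = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- batch normalisation ---------------------------------------------------
# x arranged (F, M): features along rows. Training uses batch statistics and
# updates running moments (momentum 0.1); evaluation uses the running ones.

bn_fwd_mat <- function(xm, gamma, beta, rmean, rvar, train, momentum = 0.1,
                       eps = 1e-5) {
  if (train) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    new_rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    istd <- 1 / sqrt(rvar + eps)
    xhat <- (xm - rmean) * istd
    new_rmean <- rmean
    new_rvar <- rvar
  }
  y <- gamma * xhat + beta
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma),
       rmean = new_rmean, rvar = new_rvar)
}

bn_bwd_mat <- function(dy, cache) {
  xhat <- cache$xhat
  g <- cache$gamma
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  m <- ncol(xhat)
  dx <- (g * cache$istd) *
    (dy - dbeta / m - xhat * (dgamma / m))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Move feature axis `fdim` of array x to the front and flatten the rest.
to_feat_mat <- function(x, fdim) {
  d <- dim(x)
  perm <- c(fdim, setdiff(seq_along(d), fdim))
  xm <- aperm(x, perm)
  dim(xm) <- c(d[fdim], prod(d[-fdim]))
  list(xm = xm, d = d, perm = perm)
}

from_feat_mat <- function(xm, d, perm) {
  dim(xm) <- d[perm]
  aperm(xm, order(perm))
}

# ---- dense -----------------------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(y = W %*% x + b, cache = x)
}

linear_bwd <- function(dy, cache, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache), db = rowSums(dy))
}

# ---- temporal convolutions (sequence tensors (T, C, B)) --------------------

# Causal dilated conv, kernel 3: output step t sees inputs t, t-d, t-2d.
# Implemented as im2col over a left-padded copy plus one GEMM; the padding
# overhang is never produced, which is the "chomp" in convolution form.
tcn_conv_fwd <- function(x, W, b, dil) {
  d <- dim(x)
  r <- cpp_tcn_conv_fwd(x, W, b, d[1], d[2], d[3], dil)
  list(y = r$y, cache = list(xcol = r$xcol, dims = d))
}

tcn_conv_bwd <- function(dy, cache, W, b, dil) {
  d <- cache$dims
  r <- cpp_tcn_conv_bwd(dy, cache$xcol, W, d[1], d[2], d[3], dil)
  list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

# 1x1 convolution over the feature axis of (T, C, B)
pointwise_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- aperm(x, c(2, 1, 3))
  dim(xm) <- c(d[2], d[1] * d[3])
  y <- W %*% xm + b
  dim(y) <- c(nrow(W), d[1], d[3])
  list(y = aperm(y, c(2, 1, 3)), cache = list(xm = xm, dims = d))
}

pointwise_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dym <- aperm(dy, c(2, 1, 3))
  dim(dym) <- c(nrow(W), d[1] * d[3])
  dW <- tcrossprod(dym, cache$xm)
  db <- rowSums(dym)
  dxm <- crossprod(W, dym)
  dim(dxm) <- c(d[2], d[1], d[3])
  list(dx = aperm(dxm, c(2, 1, 3)), dW = dW, db = db)
}

# ---- band-aggregation convolution ------------------------------------------
# x (Tin, K, C, B) -> y (Tin-2, Cout, C, B); weights (Cout, 3*K) with column
# blocks ordered by kernel position j then band k: col = (j-1)*K + k.

agg_conv_fwd <- function(x, W, b) {
  d <- dim(x)
  Tin <- d[1]; K <- d[2]; C <- d[3]; B <- d[4]
  To <- Tin - 2
  cols <- vector("list", 3)
  for (j in 1:3) {
    sl <- x[j:(j + To - 1), , , , drop = FALSE]
    sl <- aperm(sl, c(2, 1, 3, 4))
    dim(sl) <- c(K, To * C * B)
    cols[[j]] <- sl
  }
  xcol <- do.call(rbind, cols)
  y <- W %*% xcol + b
  dim(y) <- c(nrow(W), To, C, B)
  list(y = aperm(y, c(2, 1, 3, 4)), cache = list(xcol = xcol, dims = d))
}

agg_conv_bwd <- function(dy, cache, W) {
  d <- cache$dims
  Tin <- d[1]; K <- d[2]; C <- d[3]; B <- d[4]
  To <- Tin - 2
  Cout <- nrow(W)
  dym <- aperm(dy, c(2, 1, 3, 4))
  dim(dym) <- c(Cout, To * C * B)
  dW <- tcrossprod(dym, cache$xcol)
  db <- rowSums(dym)
  dxcol <- crossprod(W, dym)
  dx <- array(0, d)
  for (j in 1:3) {
    blk <- dxcol[((j - 1) * K + 1):(j * K), , drop = FALSE]
    dim(blk) <- c(K, To, C, B)
    blk <- aperm(blk, c(2, 1, 3, 4))
    dx[j:(j + To - 1), , , ] <- dx[j:(j + To - 1), , , , drop = FALSE] + blk
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_cols <- function(scores) {
  z <- exp(sweep(scores, 2, apply(scores, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# scores (C, B); labels integer in 1..C. Returns mean loss, probs and the
# gradient wrt scores.
softmax_ce <- function(scores, labels) {
  p <- softmax_cols(scores)
  B <- ncol(scores)
  idx <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  dscores <- dscores / B
  list(loss = loss, probs = p, dscores = dscores)
}

# backward of column-wise softmax given upstream gradient g (C, B)
softmax_bwd_cols <- function(g, p) {
  p * sweep(g, 2, colSums(g * p))
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), # preserves vector/matrix shape
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decoupled weight decay (applied to every parameter, as in standard AdamW).
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
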