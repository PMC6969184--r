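# Neural-network primitives: forward and backward passes built on base R
# matrix operations. Layouts (channel-first, so im2col blocks are
# native-order strided slices and need no transposes):
#   - 2-D feature maps: array (C, H, W, N)  [channels, rows, cols, batch]
#   - vectors:          matrix (D, N)
#   - sequences:        array (D, N, T)     [features, batch, timestep]
# Gradients are verified against finite differences in the test suite.

glorot <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

## ---- 2-D convolution (valid, stride 1) via im2col ----

# X: (C, H, W, N). W_mat: (C*KH*KW, F) with row order channel-fastest,
# then kernel row, then kernel column. Returns list(out = (F,OH,OW,N),
# cols) for backward. Data movement is in C++ (cpp_im2col); the product
# goes through BLAS.
conv2d_forward <- function(X, W_mat, b, KH, KW) {
  d <- dim(X)
  F_ <- ncol(W_mat)
  cols <- cpp_im2col(X, d[1], d[2], d[3], d[4], KH, KW)
  out_mat <- crossprod(W_mat, cols) + b
  dim(out_mat) <- c(F_, d[2] - KH + 1L, d[3] - KW + 1L, d[4])
  list(out = out_mat, cols = cols, X_dim = d)
}

conv2d_backward <- function(dOut, cache, W_mat, KH, KW, need_dX = TRUE) {
  d <- dim(dOut); F_ <- d[1]
  Xd <- cache$X_dim
  dO_mat <- dOut
  dim(dO_mat) <- c(F_, d[2] * d[3] * d[4])
  dW <- tcrossprod(cache$cols, dO_mat)
  db <- rowSums(dO_mat)
  dX <- NULL
  if (need_dX) {
    dcols <- W_mat %*% dO_mat
    dX <- cpp_col2im(dcols, Xd[1], Xd[2], Xd[3], Xd[4], KH, KW)
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- 2x2 non-overlapping max pooling ----

# X: (C, H, W, N); pools non-overlapping 2x2 regions of (H, W); ties go to
# the first element of each block in scan order.
maxpool_forward <- function(X) {
  d <- dim(X)
  r <- cpp_maxpool_fwd(X, d[1], d[2], d[3], d[4])
  list(out = r$out, which = r$which, X_dim = d)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$X_dim
  cpp_maxpool_bwd(dOut, cache$which, d[1], d[2], d[3], d[4])
}

## ---- dropout (inverted scaling; identity when p = 0 or not training) ----

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- array((stats::runif(length(X)) >= p) / (1 - p), dim(X) %||% length(X))
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dOut, cache) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

## ---- activations ----

act_forward <- function(x, kind) {
  switch(kind, tanh = tanh(x), relu = pmax(x, 0),
         stop("unknown activation: ", kind))
}

act_backward <- function(dOut, y, kind) {
  switch(kind, tanh = dOut * (1 - y^2), relu = dOut * (y > 0),
         stop("unknown activation: ", kind))
}

## ---- batch normalization over feature rows of a (D, M) matrix ----

bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5,
                       momentum = 0.9) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - mu
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  list(out = gamma * xhat + beta, xhat = xhat, inv_sd = inv_sd, xc = xc,
       state = state)
}

bn_backward <- function(dOut, cache, gamma) {
  M <- ncol(dOut)
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * gamma
  # standard batch-norm gradient, per feature row
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv_sd
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- gated recurrent unit (full-sequence forward, BPTT backward) ----

sigmoid <- function(x) 1 / (1 + exp(-x))

# X: (D, N, T). Params p: Wz, Wr, Wh (H x D); Uz, Ur, Uh (H x H);
# bz, br, bh (H). Update rule: h_t = (1 - z_t) * h_{t-1} + z_t * hcand_t.
gru_forward <- function(X, p) {
  d <- dim(X); N <- d[2]; T_ <- d[3]
  H <- nrow(p$Wz)
  h <- matrix(0, H, N)
  Hseq <- array(0, c(H, N, T_))
  zs <- rs <- hhs <- hprevs <- array(0, c(H, N, T_))
  for (t in seq_len(T_)) {
    x <- matrix(X[, , t], d[1], N)
    z <- sigmoid(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x + p$Ur %*% h + p$br)
    hh <- tanh(p$Wh %*% x + p$Uh %*% (r * h) + p$bh)
    hprevs[, , t] <- h
    h <- (1 - z) * h + z * hh
    Hseq[, , t] <- h
    zs[, , t] <- z; rs[, , t] <- r; hhs[, , t] <- hh
  }
  list(out = Hseq, X = X, zs = zs, rs = rs, hhs = hhs, hprevs = hprevs)
}

# dH: gradient w.r.t. the full output sequence (H, N, T).
gru_backward <- function(dH, cache, p) {
  d <- dim(cache$X); D <- d[1]; N <- d[2]; T_ <- d[3]
  H <- nrow(p$Wz)
  g <- list(Wz = matrix(0, H, D), Wr = matrix(0, H, D), Wh = matrix(0, H, D),
            Uz = matrix(0, H, H), Ur = matrix(0, H, H), Uh = matrix(0, H, H),
            bz = numeric(H), br = numeric(H), bh = numeric(H))
  dX <- array(0, d)
  dh <- matrix(0, H, N)
  for (t in rev(seq_len(T_))) {
    dh <- dh + matrix(dH[, , t], H, N)
    x <- matrix(cache$X[, , t], D, N)
    z <- matrix(cache$zs[, , t], H, N)
    r <- matrix(cache$rs[, , t], H, N)
    hh <- matrix(cache$hhs[, , t], H, N)
    h_prev <- matrix(cache$hprevs[, , t], H, N)
    dhh <- dh * z
    dz <- dh * (hh - h_prev)
    dh_prev <- dh * (1 - z)
    dah <- dhh * (1 - hh^2)
    g$Wh <- g$Wh + tcrossprod(dah, x)
    g$Uh <- g$Uh + tcrossprod(dah, r * h_prev)
    g$bh <- g$bh + rowSums(dah)
    drh <- crossprod(p$Uh, dah)
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    daz <- dz * z * (1 - z)
    dar <- dr * r * (1 - r)
    g$Wz <- g$Wz + tcrossprod(daz, x)
    g$Uz <- g$Uz + tcrossprod(daz, h_prev)
    g$bz <- g$bz + rowSums(daz)
    g$Wr <- g$Wr + tcrossprod(dar, x)
    g$Ur <- g$Ur + tcrossprod(dar, h_prev)
    g$br <- g$br + rowSums(dar)
    dh_prev <- dh_prev + crossprod(p$Uz, daz) + crossprod(p$Ur, dar)
    dX[, , t] <- crossprod(p$Wz, daz) + crossprod(p$Wr, dar) +
      crossprod(p$Wh, dah)
    dh <- dh_prev
  }
  list(dX = dX, grads = g)
}

## ---- softmax + class-weighted categorical cross-entropy ----

softmax <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# logits: (K, N); y: integer class in 1..K; w: per-example weights.
# Loss is the weighted mean cross-entropy; gradient matches.
softmax_ce <- function(logits, y, w) {
  N <- ncol(logits)
  P <- softmax(logits)
  py <- P[cbind(y, seq_len(N))]
  loss <- -sum(w * log(pmax(py, 1e-12))) / sum(w)
  Y <- matrix(0, nrow(logits), N)
  Y[cbind(y, seq_len(N))] <- 1
  dlogits <- (P - Y) * rep(w, each = nrow(logits)) / sum(w)
  list(loss = loss, dlogits = dlogits, probs = P)
}

## ---- Adam with inverse-time learning-rate decay ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# lr_t = lr0 / (1 + decay * t), t counted per update.
adam_step <- function(params, grads, state, lr0, decay, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr0 / (1 + decay * state$t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
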