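# Architecture registry. Each entry supplies init/forward/backward closures
# over the shared layer primitives in nn-layers.R.
#
# lenet_variant: [input dropout] -> conv 5x5 (32 filters) + tanh ->
#   max-pool 2x2 -> dropout -> conv 5x5 (64 filters) + tanh -> max-pool 2x2
#   -> dropout -> flatten -> FC 500 + tanh -> FC 2 -> softmax.
#   tanh is used in place of ReLU (configurable), max-pooling in place of
#   average pooling, dropout probability 0.2 at every dropout site.
#
# crnn: 1-D convolution along time (the 40 frequency bins are the input
#   channels; 64 filters, kernel length 3 frames) with batch normalization,
#   ReLU and dropout -> two GRU layers of width 64, each batch-normalized
#   -> the final time-step state -> FC 2 -> softmax.

.arch_registry <- new.env(parent = emptyenv())

register_architecture <- function(name, spec) {
  assign(name, spec, envir = .arch_registry)
  invisible(name)
}

#' List registered classifier architectures
#' @return Character vector of architecture names.
#' @export
list_architectures <- function() {
  sort(ls(.arch_registry))
}

#' Build a classifier architecture specification
#'
#' The registry ships two architectures: `"lenet_variant"`, a small
#' convolutional network with 32 and 64 filters in its two convolution
#' stages, max pooling, tanh activations and dropout on the input and
#' after both pooling stages; and `"crnn"`, a 1-D convolution along time
#' feeding two batch-normalized gated recurrent layers. Both take a 40x40
#' spectrogram patch and output a 2-way class distribution (probability
#' that the patch contains an upcall). Third-party architectures can be
#' added with `register_architecture`.
#'
#' @param name Registered architecture name.
#' @return An `architecture_spec` with descriptive fields (`conv_filters`,
#'   `n_recurrent_layers`, `input_shape`, `n_classes`) and the
#'   init/forward/backward closures used by [train_scorer()].
#' @export
build_architecture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !exists(name, envir = .arch_registry)) {
    abort_upcallr(
      sprintf("unknown architecture '%s'; registered: %s",
              as.character(name)[1],
              paste(list_architectures(), collapse = ", ")),
      "upcallr_error_unknown_architecture")
  }
  get(name, envir = .arch_registry)
}

## ---- lenet_variant ----

lenet_init <- function(cfg) {
  f1 <- 32L; f2 <- 64L; k <- 5L
  fc1 <- 500L
  flat <- 7L * 7L * f2
  list(
    W1 = glorot(1L * k * k, f1),
    b1 = numeric(f1),
    W2 = glorot(f1 * k * k, f2),
    b2 = numeric(f2),
    W3 = glorot(fc1, flat, fan_in = flat, fan_out = fc1),
    b3 = numeric(fc1),
    W4 = glorot(2L, fc1, fan_in = fc1, fan_out = 2L),
    b4 = numeric(2L)
  )
}

lenet_forward <- function(params, X, cfg, bn_state, training) {
  act <- cfg$activation
  p <- if (training) cfg$dropout_p else 0
  d0 <- dropout_forward(X, p, training)
  c1 <- conv2d_forward(d0$out, params$W1, params$b1, 5L, 5L)
  a1 <- act_forward(c1$out, act)
  p1 <- maxpool_forward(a1)
  d1 <- dropout_forward(p1$out, p, training)
  c2 <- conv2d_forward(d1$out, params$W2, params$b2, 5L, 5L)
  a2 <- act_forward(c2$out, act)
  p2 <- maxpool_forward(a2)
  d2 <- dropout_forward(p2$out, p, training)
  N <- dim(X)[4]
  flat <- matrix(d2$out, ncol = N)
  h3 <- act_forward(params$W3 %*% flat + params$b3, act)
  logits <- params$W4 %*% h3 + params$b4
  list(logits = logits, bn_state = bn_state,
       cache = list(d0 = d0, c1 = c1, a1 = a1, p1 = p1, d1 = d1, c2 = c2,
                    a2 = a2, p2 = p2, d2 = d2, flat = flat, h3 = h3))
}

lenet_backward <- function(params, cache, dlogits, cfg) {
  act <- cfg$activation
  dW4 <- tcrossprod(dlogits, cache$h3)
  db4 <- rowSums(dlogits)
  dh3 <- crossprod(params$W4, dlogits)
  da3 <- act_backward(dh3, cache$h3, act)
  dW3 <- tcrossprod(da3, cache$flat)
  db3 <- rowSums(da3)
  dflat <- crossprod(params$W3, da3)
  dd2 <- array(dflat, dim(cache$p2$out))
  dp2 <- dropout_backward(dd2, cache$d2)
  da2 <- maxpool_backward(dp2, cache$p2)
  dc2 <- act_backward(da2, cache$a2, act)
  bw2 <- conv2d_backward(dc2, cache$c2, params$W2, 5L, 5L)
  dd1 <- dropout_backward(bw2$dX, cache$d1)
  da1 <- maxpool_backward(dd1, cache$p1)
  dc1 <- act_backward(da1, cache$a1, act)
  # no trainable layers below the first convolution, so skip its dX
  bw1 <- conv2d_backward(dc1, cache$c1, params$W1, 5L, 5L, need_dX = FALSE)
  list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

register_architecture("lenet_variant", structure(list(
  name = "lenet_variant",
  input_shape = c(40L, 40L),
  n_classes = 2L,
  conv_filters = c(32L, 64L),
  n_recurrent_layers = 0L,
  init = lenet_init,
  init_bn = function() list(),
  forward = lenet_forward,
  backward = lenet_backward
), class = "architecture_spec"))

## ---- crnn (Conv1D + GRU) ----

crnn_dims <- list(D = 40L, Tin = 40L, K = 3L, F = 64L, H = 64L)

crnn_init <- function(cfg) {
  d <- crnn_dims
  gru_block <- function(Din) {
    list(Wz = glorot(d$H, Din), Wr = glorot(d$H, Din), Wh = glorot(d$H, Din),
         Uz = glorot(d$H, d$H), Ur = glorot(d$H, d$H), Uh = glorot(d$H, d$H),
         bz = numeric(d$H), br = numeric(d$H), bh = numeric(d$H))
  }
  g1 <- gru_block(d$F)
  g2 <- gru_block(d$H)
  p <- list(
    Wc = glorot(d$F, d$D * d$K), bc = numeric(d$F),
    g0_gamma = rep(1, d$F), g0_beta = numeric(d$F),
    g1_gamma = rep(1, d$H), g1_beta = numeric(d$H),
    g2_gamma = rep(1, d$H), g2_beta = numeric(d$H),
    Wf = glorot(2L, d$H, fan_in = d$H, fan_out = 2L), bf = numeric(2L)
  )
  for (nm in names(g1)) p[[paste0("g1_", nm)]] <- g1[[nm]]
  for (nm in names(g2)) p[[paste0("g2_", nm)]] <- g2[[nm]]
  p
}

crnn_init_bn <- function() {
  d <- crnn_dims
  list(bn0 = list(mean = numeric(d$F), var = rep(1, d$F)),
       bn1 = list(mean = numeric(d$H), var = rep(1, d$H)),
       bn2 = list(mean = numeric(d$H), var = rep(1, d$H)))
}

gru_params <- function(params, prefix) {
  out <- list()
  for (nm in c("Wz", "Wr", "Wh", "Uz", "Ur", "Uh", "bz", "br", "bh")) {
    out[[nm]] <- params[[paste0(prefix, "_", nm)]]
  }
  out
}

crnn_forward <- function(params, X, cfg, bn_state, training) {
  d <- crnn_dims
  N <- dim(X)[4]
  Tout <- d$Tin - d$K + 1L
  # spectrogram as a sequence: timestep t is the t-th frame, the 40
  # frequency bins are the channels
  seqX <- aperm(array(X, c(d$D, d$Tin, N)), c(1L, 3L, 2L))  # (D, N, T)
  conv <- array(0, c(d$F, N, Tout))
  stacks <- vector("list", Tout)
  for (t in seq_len(Tout)) {
    S <- rbind(matrix(seqX[, , t], d$D, N),
               matrix(seqX[, , t + 1L], d$D, N),
               matrix(seqX[, , t + 2L], d$D, N))
    stacks[[t]] <- S
    conv[, , t] <- params$Wc %*% S + params$bc
  }
  bn0 <- bn_forward(matrix(conv, d$F), params$g0_gamma, params$g0_beta,
                    bn_state$bn0, training)
  bn_state$bn0 <- bn0$state
  a0 <- act_forward(bn0$out, "relu")
  p_drop <- if (training) cfg$dropout_p else 0
  dr0 <- dropout_forward(a0, p_drop, training)
  seq0 <- array(dr0$out, c(d$F, N, Tout))

  g1 <- gru_forward(seq0, gru_params(params, "g1"))
  bn1 <- bn_forward(matrix(g1$out, d$H), params$g1_gamma, params$g1_beta,
                    bn_state$bn1, training)
  bn_state$bn1 <- bn1$state
  seq1 <- array(bn1$out, c(d$H, N, Tout))

  g2 <- gru_forward(seq1, gru_params(params, "g2"))
  bn2 <- bn_forward(matrix(g2$out, d$H), params$g2_gamma, params$g2_beta,
                    bn_state$bn2, training)
  bn_state$bn2 <- bn2$state
  seq2 <- array(bn2$out, c(d$H, N, Tout))

  h_last <- matrix(seq2[, , Tout], d$H, N)
  logits <- params$Wf %*% h_last + params$bf
  list(logits = logits, bn_state = bn_state,
       cache = list(stacks = stacks, bn0 = bn0, a0 = a0, dr0 = dr0,
                    g1 = g1, bn1 = bn1, g2 = g2, bn2 = bn2,
                    h_last = h_last, N = N, Tout = Tout))
}

crnn_backward <- function(params, cache, dlogits, cfg) {
  d <- crnn_dims
  N <- cache$N; Tout <- cache$Tout
  g <- list()
  g$Wf <- tcrossprod(dlogits, cache$h_last)
  g$bf <- rowSums(dlogits)
  dseq2 <- array(0, c(d$H, N, Tout))
  dseq2[, , Tout] <- crossprod(params$Wf, dlogits)

  b2 <- bn_backward(matrix(dseq2, d$H), cache$bn2, params$g2_gamma)
  g$g2_gamma <- b2$dgamma; g$g2_beta <- b2$dbeta
  gb2 <- gru_backward(array(b2$dX, c(d$H, N, Tout)), cache$g2,
                      gru_params(params, "g2"))
  for (nm in names(gb2$grads)) g[[paste0("g2_", nm)]] <- gb2$grads[[nm]]

  b1 <- bn_backward(matrix(gb2$dX, d$H), cache$bn1, params$g1_gamma)
  g$g1_gamma <- b1$dgamma; g$g1_beta <- b1$dbeta
  gb1 <- gru_backward(array(b1$dX, c(d$H, N, Tout)), cache$g1,
                      gru_params(params, "g1"))
  for (nm in names(gb1$grads)) g[[paste0("g1_", nm)]] <- gb1$grads[[nm]]

  ddr0 <- matrix(gb1$dX, d$F)
  da0 <- dropout_backward(ddr0, cache$dr0)
  dbn0_out <- act_backward(da0, cache$a0, "relu")
  b0 <- bn_backward(dbn0_out, cache$bn0, params$g0_gamma)
  g$g0_gamma <- b0$dgamma; g$g0_beta <- b0$dbeta
  dconv <- array(b0$dX, c(d$F, N, Tout))
  g$Wc <- matrix(0, d$F, d$D * d$K)
  g$bc <- numeric(d$F)
  for (t in seq_len(Tout)) {
    dc <- matrix(dconv[, , t], d$F, N)
    g$Wc <- g$Wc + tcrossprod(dc, cache$stacks[[t]])
    g$bc <- g$bc + rowSums(dc)
  }
  g
}

register_architecture("crnn", structure(list(
  name = "crnn",
  input_shape = c(40L, 40L),
  n_classes = 2L,
  conv_filters = 64L,
  n_recurrent_layers = 2L,
  init = crnn_init,
  init_bn = crnn_init_bn,
  forward = crnn_forward,
  backward = crnn_backward
), class = "architecture_spec"))

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s: input %dx%d, conv filters (%s), %d recurrent layer(s)\n",
              x$name, x$input_shape[1], x$input_shape[2],
              paste(x$conv_filters, collapse = ", "), x$n_recurrent_layers))
  invisible(x)
}
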