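#' Training configuration
#'
#' Defaults follow the reference protocol for this detector family: batches
#' of 1,000 examples, 100 epochs (one full pass each), the Adam adaptive
#' moment optimizer with an inverse-time learning-rate decay of 0.005
#' applied per update (`lr_t = lr0 / (1 + decay * t)`), and positive
#' (upcall) examples weighted by a factor of three in the categorical
#' cross-entropy loss to counter class imbalance. The base learning rate
#' (1e-3), dropout probability (0.2) and activation are this package's
#' choices. All stochastic choices during training (initialization,
#' shuffling, dropout) are controlled by `rng_seed`.
#'
#' @param batch_size Examples per gradient estimate (default 1000).
#' @param epochs Full passes through the training data (default 100).
#' @param base_learning_rate Adam base learning rate `lr0` (default 1e-3).
#' @param learning_rate_decay Inverse-time decay per update (default 0.005).
#' @param positive_class_weight Loss weight of upcall examples (default 3).
#' @param dropout_p Dropout probability at every dropout site (default 0.2).
#' @param activation `"tanh"` (default) or `"relu"` for the convolutional
#'   network's conv and fully-connected layers.
#' @param rng_seed Integer seed (default 1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 1000L, epochs = 100L,
                         base_learning_rate = 1e-3,
                         learning_rate_decay = 0.005,
                         positive_class_weight = 3,
                         dropout_p = 0.2,
                         activation = c("tanh", "relu"),
                         rng_seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(batch_size >= 1, epochs >= 1, base_learning_rate > 0,
            learning_rate_decay >= 0, positive_class_weight > 0,
            dropout_p >= 0, dropout_p < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 base_learning_rate = base_learning_rate,
                 learning_rate_decay = learning_rate_decay,
                 positive_class_weight = positive_class_weight,
                 dropout_p = dropout_p, activation = activation,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

# Stack example patches into a (1, 40, 40, N) channel-first array; returns
# the array, integer classes (1 = background, 2 = upcall) and the feature
# params / normalization mode shared by the examples.
stack_examples <- function(examples) {
  if (!length(examples)) {
    abort_upcallr("no training examples", "upcallr_error_single_class")
  }
  p0 <- attr(examples[[1]]$patch, "params")
  mode <- attr(examples[[1]]$patch, "normalization_mode") %||% "none"
  d <- dim(examples[[1]]$patch)
  X <- array(0, c(1L, d[1], d[2], length(examples)))
  y <- integer(length(examples))
  for (i in seq_along(examples)) {
    X[1L, , , i] <- examples[[i]]$patch
    y[i] <- if (examples[[i]]$label == "upcall") 2L else 1L
  }
  list(X = X, y = y, params = p0, normalization_mode = mode)
}

#' Train a patch classifier
#'
#' Minimizes class-weighted categorical cross-entropy (two-unit softmax)
#' over labeled spectrogram patches with Adam. Per-epoch training loss and
#' accuracy are recorded in the returned scorer's `history`. Training is
#' bit-reproducible under a fixed `rng_seed`.
#'
#' @param arch An `architecture_spec` from [build_architecture()], or its
#'   name.
#' @param examples List of labeled examples ([extract_positive()],
#'   [sample_negatives()], [augment_examples()], [mine_hard_negatives()]);
#'   both classes must be present.
#' @param config A [train_config()].
#' @return A `trained_scorer`: fitted weights plus the architecture spec,
#'   config, batch-norm state, feature params, normalization mode and
#'   per-epoch history.
#' @export
train_scorer <- function(arch, examples, config = train_config()) {
  if (is.character(arch)) arch <- build_architecture(arch)
  stopifnot(inherits(arch, "architecture_spec"),
            inherits(config, "train_config"))
  data <- stack_examples(examples)
  if (length(unique(data$y)) < 2) {
    abort_upcallr("training data contains a single class; need both upcall and background",
                  "upcallr_error_single_class")
  }
  N <- length(data$y)
  w_all <- ifelse(data$y == 2L, config$positive_class_weight, 1)
  with_seed(config$rng_seed, {
    params <- arch$init(config)
    bn_state <- arch$init_bn()
    opt <- adam_init(params)
    history <- tibble::tibble(epoch = integer(), loss = numeric(),
                              accuracy = numeric())
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(N)
      ep_loss <- 0; ep_w <- 0; ep_correct <- 0
      for (b0 in seq(1L, N, by = config$batch_size)) {
        idx <- perm[b0:min(N, b0 + config$batch_size - 1L)]
        Xb <- data$X[, , , idx, drop = FALSE]
        yb <- data$y[idx]
        wb <- w_all[idx]
        fw <- arch$forward(params, Xb, config, bn_state, training = TRUE)
        bn_state <- fw$bn_state
        ce <- softmax_ce(fw$logits, yb, wb)
        if (!is.finite(ce$loss)) {
          abort_upcallr(sprintf("non-finite loss at epoch %d", epoch),
                        "upcallr_error_nonfinite_loss")
        }
        grads <- arch$backward(params, fw$cache, ce$dlogits, config)
        st <- adam_step(params, grads, opt, config$base_learning_rate,
                        config$learning_rate_decay)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + ce$loss * sum(wb)
        ep_w <- ep_w + sum(wb)
        ep_correct <- ep_correct + sum(apply(ce$probs, 2, which.max) == yb)
      }
      history <- rbind(history,
                       tibble::tibble(epoch = epoch, loss = ep_loss / ep_w,
                                      accuracy = ep_correct / N))
    }
    structure(
      list(arch = arch, params = params, bn_state = bn_state,
           config = config, history = history,
           feature_params = data$params %||% stft_params(),
           normalization_mode = data$normalization_mode,
           trained = TRUE),
      class = "trained_scorer")
  })
}

#' @export
print.trained_scorer <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_scorer> %s: %d epochs, final loss %.4f, accuracy %.3f\n",
              x$arch$name, nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

# Inference on a stacked (1, 40, 40, N) array; returns upcall probabilities.
# The lenet_variant/tanh combination takes the fused C++ forward path;
# everything else runs the modular forward pass in inference mode.
predict_proba_array <- function(scorer, X, batch_size = 256L) {
  N <- dim(X)[4]
  if (scorer$arch$name == "lenet_variant" &&
      identical(scorer$config$activation, "tanh")) {
    p <- scorer$params
    return(cpp_lenet_infer(X, N, p$W1, p$b1, p$W2, p$b2, p$W3, p$b3,
                           p$W4, p$b4))
  }
  out <- numeric(N)
  for (b0 in seq(1L, N, by = batch_size)) {
    idx <- b0:min(N, b0 + batch_size - 1L)
    fw <- scorer$arch$forward(scorer$params, X[, , , idx, drop = FALSE],
                              scorer$config, scorer$bn_state,
                              training = FALSE)
    out[idx] <- softmax(fw$logits)[2L, ]
  }
  out
}

#' Predict upcall probabilities for spectrogram patches
#'
#' The two softmax outputs sum to 1; the upcall-class probability is
#' returned. Inference is deterministic for fixed weights, and batch
#' prediction equals element-wise prediction.
#'
#' @param scorer A `trained_scorer`.
#' @param patches A single `spectrogram_patch`, a list of patches, or a
#'   channel-first `(1, 40, 40, N)` array. Patches must carry the scorer's
#'   training normalization mode.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(scorer, patches) {
  stopifnot(inherits(scorer, "trained_scorer"))
  if (inherits(patches, "spectrogram_patch")) patches <- list(patches)
  if (is.list(patches)) {
    shp <- scorer$arch$input_shape
    X <- array(0, c(1L, shp[1], shp[2], length(patches)))
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      if (!all(dim(p) == shp)) {
        abort_upcallr(
          sprintf("patch %d has shape %dx%d, expected %dx%d", i,
                  nrow(p), ncol(p), shp[1], shp[2]),
          "upcallr_error_shape_mismatch")
      }
      mode <- attr(p, "normalization_mode")
      if (!is.null(mode) && !identical(mode, scorer$normalization_mode)) {
        abort_upcallr(
          sprintf("patch %d normalized with '%s' but scorer trained with '%s'",
                  i, mode, scorer$normalization_mode),
          "upcallr_error_normalization_mismatch")
      }
      X[1L, , , i] <- p
    }
  } else {
    X <- patches
    if (length(dim(X)) != 4) {
      abort_upcallr("patch array must have dimensions (1, freq, time, n)",
                    "upcallr_error_shape_mismatch")
    }
  }
  predict_proba_array(scorer, X)
}

#' Train replicate scorers from consecutive seeds
#'
#' Trains `n` independent instances of the same architecture with seeds
#' `seed, seed + 1, ..., seed + n - 1` to quantify the effect of random
#' initialization; downstream evaluation averages metrics across the
#' replicates (mean results are reported).
#'
#' @param arch Architecture spec or name.
#' @param examples Labeled examples.
#' @param config A [train_config()]; its `rng_seed` is the base seed.
#' @param n Number of replicates (default 10).
#' @return List of `trained_scorer` objects.
#' @export
train_replicates <- function(arch, examples, config = train_config(), n = 10L) {
  if (n < 1) {
    abort_upcallr("n must be >= 1", "upcallr_error_bad_replicates")
  }
  lapply(seq_len(n) - 1L, function(k) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + k
    train_scorer(arch, examples, cfg)
  })
}

#' Save / load a trained scorer checkpoint
#'
#' A checkpoint is self-describing: it carries the weights, architecture
#' name, training config, feature parameters and normalization mode.
#'
#' @param scorer A `trained_scorer`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly for save; the scorer for load.
#' @export
save_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "trained_scorer"))
  obj <- scorer
  obj$arch <- scorer$arch$name  # re-resolved from the registry on load
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  obj <- readRDS(path)
  obj$arch <- build_architecture(obj$arch)
  class(obj) <- "trained_scorer"
  obj
}
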