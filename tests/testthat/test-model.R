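test_that("the architecture registry exposes the two built-in networks", {
  lenet <- build_architecture("lenet_variant")
  expect_equal(lenet$conv_filters, c(32L, 64L))
  expect_equal(lenet$input_shape, c(40L, 40L))

  crnn <- build_architecture("crnn")
  expect_equal(crnn$n_recurrent_layers, 2L)

  err <- tryCatch(build_architecture("vggnet"), error = identity)
  expect_s3_class(err, "upcallr_error_unknown_architecture")
  expect_match(conditionMessage(err), "lenet_variant")
  expect_match(conditionMessage(err), "crnn")
})

test_that("analytic gradients match finite differences for both networks", {
  y <- c(1L, 2L, 2L)
  w <- c(1, 3, 3)
  for (arch_name in c("lenet_variant", "crnn")) {
    arch <- build_architecture(arch_name)
    cfg <- train_config(dropout_p = 0, rng_seed = 1)
    set.seed(2)
    params <- arch$init(cfg)
    bn <- arch$init_bn()
    set.seed(4)
    X <- array(stats::rnorm(40 * 40 * 3), c(1, 40, 40, 3))
    lossfn <- function(p) {
      fw <- arch$forward(p, X, cfg, bn, training = TRUE)
      upcallr:::softmax_ce(fw$logits, y, w)$loss
    }
    fw <- arch$forward(params, X, cfg, bn, training = TRUE)
    ce <- upcallr:::softmax_ce(fw$logits, y, w)
    gr <- arch$backward(params, fw$cache, ce$dlogits, cfg)
    set.seed(3)
    for (nm in names(params)) {
      for (rep in 1:2) {
        i <- sample(length(params[[nm]]), 1)
        eps <- 1e-6
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        # absolute floor: finite differences pick up kinks at max-pool
        # argmax flips, which analytic gradients correctly ignore
        expect_lt(abs(num - gr[[nm]][i]),
                  max(5e-4, 2e-3 * (abs(num) + abs(gr[[nm]][i]))),
                  label = sprintf("%s gradient of %s[%d]", arch_name, nm, i))
      }
    }
  }
})

test_that("training separates a linearly separable toy set", {
  # dropout off: the class signal lives in a single cell, and input
  # dropout would blank it in a fifth of the training-mode forwards
  ex <- separable_examples(40, offset = 1)
  sc <- train_scorer("lenet_variant", ex,
                     train_config(batch_size = 16L, epochs = 20L,
                                  dropout_p = 0, rng_seed = 1L))
  expect_gte(utils::tail(sc$history$accuracy, 1), 0.99)
  # smoothed loss is non-increasing over 10-epoch windows
  sm <- stats::filter(sc$history$loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(utils::tail(sm, 1), sm[1] + 1e-9)

  # trained positives score above 0.5
  pos <- Filter(function(e) e$label == "upcall", ex)
  p <- predict_proba(sc, lapply(pos, function(e) e$patch))
  expect_true(all(p > 0.5))
})

test_that("training is bit-reproducible under a fixed seed", {
  ex <- separable_examples(20)
  a <- train_scorer("lenet_variant", ex, tiny_train_config(epochs = 3, seed = 5))
  b <- train_scorer("lenet_variant", ex, tiny_train_config(epochs = 3, seed = 5))
  expect_identical(a$params, b$params)
  expect_equal(utils::tail(a$history$loss, 1), utils::tail(b$history$loss, 1),
               tolerance = 1e-12)
})

test_that("training rejects single-class data and records history", {
  pos_only <- Filter(function(e) e$label == "upcall", separable_examples(10))
  expect_error(train_scorer("lenet_variant", pos_only, tiny_train_config()),
               class = "upcallr_error_single_class")
  ex <- separable_examples(10)
  sc <- train_scorer("lenet_variant", ex, tiny_train_config(epochs = 4))
  expect_equal(nrow(sc$history), 4)
  expect_true(all(is.finite(sc$history$loss)))
})

test_that("softmax probabilities are valid and batching-invariant", {
  ex <- separable_examples(15)
  sc <- train_scorer("lenet_variant", ex, tiny_train_config(epochs = 2))
  patches <- lapply(ex[1:10], function(e) e$patch)
  batch <- predict_proba(sc, patches)
  expect_true(all(batch >= 0 & batch <= 1))
  single <- vapply(patches, function(p) predict_proba(sc, p), numeric(1))
  expect_equal(batch, single, tolerance = 1e-6)

  # softmax outputs sum to one on the modular forward path
  X <- array(stats::rnorm(40 * 40 * 5), c(1, 40, 40, 5))
  fw <- sc$arch$forward(sc$params, X, sc$config, sc$bn_state,
                        training = FALSE)
  expect_equal(colSums(upcallr:::softmax(fw$logits)), rep(1, 5),
               tolerance = 1e-6)

  expect_error(predict_proba(sc, list(toy_patch(matrix(0, 20, 20)))),
               class = "upcallr_error_shape_mismatch")
  bad <- toy_patch(matrix(1, 40, 40), mode = "unit_frobenius")
  expect_error(predict_proba(sc, bad),
               class = "upcallr_error_normalization_mismatch")
})

test_that("class weighting does not hurt recall on imbalanced data", {
  # imbalanced toy set: few positives, many negatives; majority vote over
  # 5 seeds of weighted-vs-unweighted held-out recall
  set.seed(100)
  mk <- function(n_pos, n_neg, seed) {
    set.seed(seed)
    c(lapply(seq_len(n_pos), function(i) {
        m <- matrix(abs(stats::rnorm(1600, sd = 0.05)), 40, 40)
        m[20, 20] <- m[20, 20] + 0.25
        toy_example(m, "upcall")
      }),
      lapply(seq_len(n_neg), function(i) {
        toy_example(matrix(abs(stats::rnorm(1600, sd = 0.05)), 40, 40),
                    "background")
      }))
  }
  wins <- 0
  for (s in 1:5) {
    train_set <- mk(6, 60, seed = 200 + s)
    test_set <- mk(30, 5, seed = 300 + s)
    test_pos <- Filter(function(e) e$label == "upcall", test_set)
    patches <- lapply(test_pos, function(e) e$patch)
    w3 <- train_scorer("lenet_variant", train_set,
                       train_config(batch_size = 32, epochs = 6,
                                    positive_class_weight = 3, rng_seed = s))
    w1 <- train_scorer("lenet_variant", train_set,
                       train_config(batch_size = 32, epochs = 6,
                                    positive_class_weight = 1,
                                    rng_seed = s))
    rec3 <- mean(predict_proba(w3, patches) > 0.5)
    rec1 <- mean(predict_proba(w1, patches) > 0.5)
    if (rec3 >= rec1) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("replicates reproduce and a single replicate equals plain train", {
  ex <- separable_examples(15)
  cfg <- tiny_train_config(epochs = 2, seed = 11)
  one <- train_replicates("lenet_variant", ex, cfg, n = 1)
  plain <- train_scorer("lenet_variant", ex, cfg)
  expect_identical(one[[1]]$params, plain$params)

  trip_a <- train_replicates("lenet_variant", ex, cfg, n = 3)
  trip_b <- train_replicates("lenet_variant", ex, cfg, n = 3)
  expect_equal(vapply(trip_a, function(s) utils::tail(s$history$loss, 1),
                      numeric(1)),
               vapply(trip_b, function(s) utils::tail(s$history$loss, 1),
                      numeric(1)))
  expect_error(train_replicates("lenet_variant", ex, cfg, n = 0),
               class = "upcallr_error_bad_replicates")
})

test_that("the crnn trains on a small separable set", {
  ex <- separable_examples(15, offset = 1)
  sc <- train_scorer("crnn", ex, tiny_train_config(epochs = 8))
  expect_gte(utils::tail(sc$history$accuracy, 1), 0.9)
  p <- predict_proba(sc, lapply(ex[1:6], function(e) e$patch))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("checkpoints round-trip through save/load", {
  ex <- separable_examples(10)
  sc <- train_scorer("lenet_variant", ex, tiny_train_config(epochs = 2))
  f <- withr::local_tempfile(fileext = ".rds")
  save_scorer(sc, f)
  back <- load_scorer(f)
  X <- array(stats::rnorm(40 * 40 * 4), c(1, 40, 40, 4))
  expect_identical(predict_proba(back, X), predict_proba(sc, X))
  expect_equal(back$arch$name, "lenet_variant")
})
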