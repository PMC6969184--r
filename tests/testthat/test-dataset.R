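test_that("extract_positive centers the clip on the annotation midpoint", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                      snr_db = 12, seed = 3)
  ann <- annotations(10.0, 11.0, 60, 200)
  ex <- extract_positive(scene$stream, ann)
  expect_equal(ex$origin_time_s, 9.5)  # midpoint 10.5 - 1.0
  expect_equal(ex$label, "upcall")
  expect_equal(ex$provenance, "annotated")
  expect_false(ex$edge_padded)

  # annotation near the stream edge is zero-padded and flagged
  edge <- extract_positive(scene$stream, annotations(0.2, 0.6, 60, 200))
  expect_equal(edge$origin_time_s, -0.6)
  expect_true(edge$edge_padded)

  expect_error(
    extract_positive(scene$stream, annotations(500, 501, 60, 200)),
    class = "upcallr_error_annotation_outside_stream")
})

test_that("positive patches carry more in-box energy than background", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                      snr_db = 12, seed = 21)
  ann <- scene$annotations
  expect_gt(nrow(ann), 1)
  pos <- extract_positive(scene$stream, ann[1, ],
                          normalization_mode = "unit_frobenius")
  neg <- sample_negatives(scene$stream, ann, 1, rng_seed = 5,
                          normalization_mode = "unit_frobenius")[[1]]
  rows <- which(39.0625 + (0:39) * 7.8125 >= ann$low_freq_hz[1] &
                  39.0625 + (0:39) * 7.8125 <= ann$high_freq_hz[1])
  expect_gt(sum(pos$patch[rows, ]^2), sum(neg$patch[rows, ]^2))
})

test_that("random negatives avoid annotations and are reproducible", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                      snr_db = 12, seed = 21)
  ann <- scene$annotations

  negs <- sample_negatives(scene$stream, ann, 50, guard_s = 1, rng_seed = 9)
  expect_length(negs, 50)
  for (e in negs) {
    # dilated window overlaps no annotation
    expect_false(any(e$origin_time_s - 1 < ann$end_time_s &
                       e$origin_time_s + 3 > ann$begin_time_s))
    expect_equal(e$provenance, "random_negative")
    expect_equal(e$label, "background")
  }
  negs2 <- sample_negatives(scene$stream, ann, 50, guard_s = 1, rng_seed = 9)
  expect_identical(dataset_manifest(negs), dataset_manifest(negs2))

  # a stream with no call-free time errors
  short <- audio_stream(stats::rnorm(8000), 2000, source_id = "short")
  full <- annotations(0, 4, 50, 200)
  expect_error(sample_negatives(short, full, 3),
               class = "upcallr_error_insufficient_negative_space")
  # no annotations at all: anywhere is fine
  free <- sample_negatives(short, annotations(), 5, rng_seed = 2)
  expect_length(free, 5)
})

test_that("augmentation pools shifted copies with the originals", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                      snr_db = 12, seed = 21)
  ann <- scene$annotations
  pos <- lapply(seq_len(min(5, nrow(ann))), function(i) {
    extract_positive(scene$stream, ann[i, ])
  })

  expect_identical(augment_examples(pos, scene$stream,
                                    copies_per_example = 0), pos)

  aug <- augment_examples(pos, scene$stream, copies_per_example = 1,
                          rng_seed = 3)
  expect_length(aug, 2 * length(pos))
  man <- dataset_manifest(aug)
  expect_equal(sum(man$provenance == "augmented"), length(pos))
  shifts <- man$origin_time_s[man$provenance == "augmented"] -
    man$origin_time_s[man$provenance == "annotated"]
  expect_true(all(abs(shifts) <= 0.2))
  # labels inherited
  expect_true(all(man$label == "upcall"))
})

test_that("a shift of exactly one hop shifts patch columns by one", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                      snr_db = 12, seed = 21)
  ex <- extract_positive(scene$stream, scene$annotations[1, ],
                         normalization_mode = "unit_frobenius")
  cl <- upcallr:::extract_clip(scene$stream, ex$origin_time_s + 0.05)
  shifted <- suppressWarnings(normalize_patch(patch_from_clip(cl$clip),
                                              "unit_frobenius"))
  # interior columns of the shifted patch equal the original moved by one
  a <- unclass(ex$patch); b <- unclass(shifted)
  expect_equal(a[, 2:38] / sqrt(sum(a[, 2:38]^2)),
               b[, 1:37] / sqrt(sum(b[, 1:37]^2)), tolerance = 1e-6)
})

test_that("label/provenance invariants are enforced", {
  p <- toy_patch(matrix(1, 40, 40))
  expect_error(upcallr:::new_labeled_example(p, "background", "annotated", 0, "s"),
               class = "upcallr_error_label_provenance")
  expect_error(upcallr:::new_labeled_example(p, "upcall", "hard_negative", 0, "s"),
               class = "upcallr_error_label_provenance")
})

test_that("hard negatives come only from unannotated detections", {
  scene <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 240,
                      snr_db = 12, seed = 13)
  ann <- scene$annotations
  # a deliberately weak scorer: one epoch on a tiny pool
  pool <- c(
    lapply(seq_len(min(4, nrow(ann))), function(i) {
      extract_positive(scene$stream, ann[i, ],
                       normalization_mode = "unit_frobenius")
    }),
    sample_negatives(scene$stream, ann, 4, rng_seed = 1,
                     normalization_mode = "unit_frobenius"))
  weak <- train_scorer("lenet_variant", pool, tiny_train_config(epochs = 1))
  mined <- mine_hard_negatives(weak, scene$stream, ann,
                               prob_threshold = 0.3)
  for (e in mined) {
    expect_equal(e$provenance, "hard_negative")
    expect_equal(e$label, "background")
    peak <- e$origin_time_s + 1
    # overlap audit: the detection peak hits no annotation (with tolerance)
    expect_false(any(peak >= ann$begin_time_s - 0.5 &
                       peak <= ann$end_time_s + 0.5))
  }
  # pure silence yields nothing
  silent <- audio_stream(numeric(2000 * 30), 2000, source_id = "silence")
  expect_length(mine_hard_negatives(weak, silent, annotations()), 0)

  expect_error(mine_hard_negatives(list(trained = FALSE), scene$stream, ann),
               class = "upcallr_error_untrained_scorer")
})
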