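#' Run configuration for the full detection workflow
#'
#' Bundles the knobs of every stage: featurization, dataset construction,
#' training, hard-negative mining, sliding-window detection and
#' evaluation. All randomness flows from `seed` through named per-stage
#' substreams ([derive_seed()]), so each stage is independently
#' reproducible.
#'
#' @param arch Architecture name (default `"lenet_variant"`).
#' @param train Config from [train_config()].
#' @param normalization_mode Patch normalization (default `"sum_square"`).
#' @param negative_ratio Random negatives drawn per positive (default 0.8,
#'   mirroring the roughly 4:5 negative:positive balance of the reference
#'   training pools).
#' @param guard_s Guard interval for random negatives (default 1 s).
#' @param augment_copies Shifted copies per example (default 1).
#' @param max_shift_s Augmentation shift bound (default 0.2 s).
#' @param prob_threshold Mining probability floor (default 0.5).
#' @param dedup_tol_s Mining de-duplication tolerance (default 0.1 s).
#' @param hop_s Detection window advance (default 0.1 s).
#' @param min_prob Detection NMS floor (default 0.05).
#' @param radius_s NMS suppression radius (default 1 s).
#' @param tolerance_s Evaluation matching tolerance (default 0.5 s).
#' @param review_rate_per_hour Analyst verification rate (default 2000).
#' @param fp_budget_per_hour Operational FP budget (default 20).
#' @param n_replicates Model instances for replicate averaging (default 10).
#' @param seed Global seed (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(arch = "lenet_variant", train = train_config(),
                       normalization_mode = "sum_square",
                       negative_ratio = 0.8, guard_s = 1.0,
                       augment_copies = 1L, max_shift_s = 0.2,
                       prob_threshold = 0.5, dedup_tol_s = 0.1,
                       hop_s = 0.1, min_prob = 0.05, radius_s = 1.0,
                       tolerance_s = 0.5, review_rate_per_hour = 2000,
                       fp_budget_per_hour = 20, n_replicates = 10L,
                       seed = 1L) {
  structure(
    list(arch = arch, train = train,
         normalization_mode = normalization_mode,
         negative_ratio = negative_ratio, guard_s = guard_s,
         augment_copies = as.integer(augment_copies),
         max_shift_s = max_shift_s, prob_threshold = prob_threshold,
         dedup_tol_s = dedup_tol_s, hop_s = hop_s, min_prob = min_prob,
         radius_s = radius_s, tolerance_s = tolerance_s,
         review_rate_per_hour = review_rate_per_hour,
         fp_budget_per_hour = fp_budget_per_hour,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "run_config")
}

# Build the stage-1 training pool (positives + random negatives, both
# augmented) from parallel lists of streams and truth tables.
build_training_pool <- function(streams, truths, config,
                                params = stft_params()) {
  if (inherits(streams, "audio_stream")) streams <- list(streams)
  if (inherits(truths, "annotations") || is.data.frame(truths)) {
    truths <- list(truths)
  }
  stopifnot(length(streams) == length(truths))
  positives <- list()
  negatives <- list()
  for (s in seq_along(streams)) {
    ann <- truths[[s]]
    for (i in seq_len(nrow(ann))) {
      positives[[length(positives) + 1]] <-
        extract_positive(streams[[s]], ann[i, ], params,
                         config$normalization_mode)
    }
    n_neg <- ceiling(config$negative_ratio * max(1L, nrow(ann)))
    negatives <- c(negatives, sample_negatives(
      streams[[s]], ann, n_neg, guard_s = config$guard_s,
      rng_seed = derive_seed(config$seed, paste0("negatives_", s)),
      params = params, normalization_mode = config$normalization_mode))
  }
  augment_examples(
    c(positives, negatives), streams,
    max_shift_s = config$max_shift_s,
    copies_per_example = config$augment_copies,
    rng_seed = derive_seed(config$seed, "augment"),
    params = params, normalization_mode = config$normalization_mode)
}

#' Two-stage training with hard-negative mining
#'
#' Implements the bootstrapped training protocol: (1) extract positives
#' and random negatives; (2) pool shift-augmented copies with the
#' originals; (3) train a preliminary model; (4) run that model as a
#' detector over the training streams and collect false positives at
#' probability `>= prob_threshold` as hard negatives; (5) add them to the
#' pool and train a new model from fresh random initialization.
#'
#' @param streams Training [audio_stream()] or list thereof.
#' @param truths Matching [annotations()] (one per stream).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, dataset manifests, both
#'   checkpoints, the mining log and the resolved config are persisted.
#' @return A list of class `two_stage_result`: `stage1` and `stage2`
#'   scorers, `pool1` and `pool2` example lists, `mined` examples and a
#'   `counts` list (positives, random negatives, augmented, mined).
#' @export
two_stage_train <- function(streams, truths, config = run_config(),
                            out_dir = NULL) {
  if (inherits(streams, "audio_stream")) streams <- list(streams)
  if (inherits(truths, "annotations") || is.data.frame(truths)) {
    truths <- list(truths)
  }
  params <- stft_params()
  pool1 <- build_training_pool(streams, truths, config, params)

  cfg1 <- config$train
  cfg1$rng_seed <- derive_seed(config$seed, "stage1")
  stage1 <- train_scorer(config$arch, pool1, cfg1)

  mined <- list()
  for (s in seq_along(streams)) {
    existing <- vapply(
      Filter(function(e) e$label == "background" &&
               e$origin_stream == streams[[s]]$source_id, pool1),
      function(e) e$origin_time_s, numeric(1))
    mined <- c(mined, mine_hard_negatives(
      stage1, streams[[s]], truths[[s]],
      prob_threshold = config$prob_threshold,
      dedup_tol_s = config$dedup_tol_s,
      tolerance_s = config$tolerance_s,
      existing_negative_times = existing,
      hop_s = config$hop_s, radius_s = config$radius_s))
  }
  pool2 <- c(pool1, mined)

  cfg2 <- config$train
  cfg2$rng_seed <- derive_seed(config$seed, "stage2")
  stage2 <- train_scorer(config$arch, pool2, cfg2)

  counts <- list(
    positives = sum(vapply(pool1, function(e)
      e$provenance == "annotated", logical(1))),
    random_negatives = sum(vapply(pool1, function(e)
      e$provenance == "random_negative", logical(1))),
    augmented = sum(vapply(pool1, function(e)
      e$provenance == "augmented", logical(1))),
    hard_negatives = length(mined))

  res <- structure(
    list(stage1 = stage1, stage2 = stage2, pool1 = pool1, pool2 = pool2,
         mined = mined, counts = counts, config = config),
    class = "two_stage_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(dataset_manifest(pool1),
                       file.path(out_dir, "stage1_manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(dataset_manifest(pool2),
                       file.path(out_dir, "stage2_manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    save_scorer(stage1, file.path(out_dir, "stage1.rds"))
    save_scorer(stage2, file.path(out_dir, "stage2.rds"))
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(unclass(config)[!vapply(config, is.function, logical(1))],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE)
  }
  res
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf(
    "<two_stage_result> %s: %d positives, %d random negatives, %d augmented, %d hard negatives mined\n",
    x$config$arch, x$counts$positives, x$counts$random_negatives,
    x$counts$augmented, x$counts$hard_negatives))
  invisible(x)
}

# Detect on a stream and evaluate against truth.
detect_and_evaluate <- function(scorer, stream, truth, config) {
  track <- score_stream(scorer, stream, hop_s = config$hop_s)
  det <- non_max_suppress(track, min_prob = config$min_prob,
                          radius_s = config$radius_s)
  hours <- duration_s(stream) / 3600
  curve <- pr_curve(det, truth, config$tolerance_s)
  fcurve <- recall_vs_fph(det, truth, hours, config$tolerance_s)
  ok <- fcurve$fp_per_hour <= config$fp_budget_per_hour
  op_recall <- if (any(ok)) max(fcurve$recall[ok]) else 0
  op_row <- if (any(ok)) which(ok)[which.max(fcurve$recall[ok])] else NA_integer_
  list(detections = det, pr = curve, ap = average_precision(curve),
       fph_curve = fcurve,
       operating_point = list(
         fp_budget_per_hour = config$fp_budget_per_hour,
         recall = op_recall,
         threshold = if (!is.na(op_row)) fcurve$threshold[op_row] else NA_real_,
         fp_per_hour = if (!is.na(op_row)) fcurve$fp_per_hour[op_row] else 0),
       workload = workload(
         if (!is.na(op_row)) fcurve$fp_per_hour[op_row] else 0, hours,
         nrow(truth), config$review_rate_per_hour))
}

#' Run a full detection experiment
#'
#' Two-stage training on the training streams, sliding-window detection on
#' held-out streams, and evaluation of both stages (PR curve, average
#' precision, recall-vs-FP/h and analyst workload). A leakage guard
#' refuses stream ids present in both the training and test lists. When
#' `n_replicates > 1`, replicate stage-2 models are trained from
#' consecutive seeds and the reported metrics are means across replicates.
#'
#' @param train_streams,train_truths Training streams and truth tables.
#' @param test_streams,test_truths Held-out streams and truth tables.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for stage artifacts and the
#'   JSON report.
#' @return A list of class `experiment_report` with per-stage evaluation
#'   (`stage1_eval`, `stage2_eval`), replicate summaries and the training
#'   counts.
#' @export
run_experiment <- function(train_streams, train_truths, test_streams,
                           test_truths, config = run_config(),
                           out_dir = NULL) {
  if (inherits(train_streams, "audio_stream")) train_streams <- list(train_streams)
  if (inherits(test_streams, "audio_stream")) test_streams <- list(test_streams)
  if (inherits(test_truths, "annotations") || is.data.frame(test_truths)) {
    test_truths <- list(test_truths)
  }
  tr_ids <- vapply(train_streams, function(s) s$source_id, character(1))
  te_ids <- vapply(test_streams, function(s) s$source_id, character(1))
  common <- intersect(tr_ids, te_ids)
  if (length(common)) {
    abort_upcallr(
      sprintf("stream(s) present in both train and test lists: %s",
              paste(common, collapse = ", ")),
      "upcallr_error_train_test_leakage")
  }
  ts <- two_stage_train(train_streams, train_truths, config, out_dir)

  eval_stage <- function(scorer) {
    evs <- lapply(seq_along(test_streams), function(k) {
      detect_and_evaluate(scorer, test_streams[[k]], test_truths[[k]], config)
    })
    list(per_stream = evs,
         mean_ap = mean(vapply(evs, function(e) e$ap, numeric(1))),
         mean_recall_at_budget = mean(vapply(
           evs, function(e) e$operating_point$recall, numeric(1))))
  }
  stage1_eval <- eval_stage(ts$stage1)
  stage2_eval <- eval_stage(ts$stage2)

  replicate_ap <- NULL
  if (config$n_replicates > 1) {
    cfg2 <- config$train
    cfg2$rng_seed <- derive_seed(config$seed, "stage2")
    reps <- train_replicates(config$arch, ts$pool2, cfg2,
                             n = config$n_replicates)
    replicate_ap <- vapply(reps, function(r) {
      mean(vapply(seq_along(test_streams), function(k) {
        detect_and_evaluate(r, test_streams[[k]], test_truths[[k]], config)$ap
      }, numeric(1)))
    }, numeric(1))
  }

  report <- structure(
    list(counts = ts$counts,
         stage1_eval = stage1_eval, stage2_eval = stage2_eval,
         replicate_ap = replicate_ap,
         replicate_ap_mean = if (!is.null(replicate_ap)) mean(replicate_ap),
         replicate_ap_sd = if (!is.null(replicate_ap)) stats::sd(replicate_ap),
         config = config, two_stage = ts),
    class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_json <- list(
      counts = ts$counts,
      stage1 = list(mean_ap = stage1_eval$mean_ap,
                    mean_recall_at_budget = stage1_eval$mean_recall_at_budget),
      stage2 = list(mean_ap = stage2_eval$mean_ap,
                    mean_recall_at_budget = stage2_eval$mean_recall_at_budget),
      replicate_ap = replicate_ap)
    jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  training pool: %d positives, %d random negatives, %d augmented, %d hard negatives\n",
              x$counts$positives, x$counts$random_negatives,
              x$counts$augmented, x$counts$hard_negatives))
  cat(sprintf("  stage 1: AP %.3f, recall %.3f at <= %g FP/h\n",
              x$stage1_eval$mean_ap, x$stage1_eval$mean_recall_at_budget,
              x$config$fp_budget_per_hour))
  cat(sprintf("  stage 2: AP %.3f, recall %.3f at <= %g FP/h\n",
              x$stage2_eval$mean_ap, x$stage2_eval$mean_recall_at_budget,
              x$config$fp_budget_per_hour))
  if (!is.null(x$replicate_ap)) {
    cat(sprintf("  replicates: mean AP %.3f (sd %.3f, n = %d)\n",
                x$replicate_ap_mean, x$replicate_ap_sd,
                length(x$replicate_ap)))
  }
  invisible(x)
}
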