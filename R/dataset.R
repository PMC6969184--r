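# Labeled training examples: positives cut around annotated calls, random
# negatives from call-free time, waveform-shift augmentation, and hard
# negatives mined from a preliminary detector's false positives.

new_labeled_example <- function(patch, label, provenance, origin_time_s,
                                origin_stream, edge_padded = FALSE) {
  stopifnot(label %in% c("upcall", "background"),
            provenance %in% c("annotated", "random_negative", "augmented",
                              "hard_negative"))
  if (provenance == "annotated" && label != "upcall") {
    abort_upcallr("annotated examples must be labeled upcall",
                  "upcallr_error_label_provenance")
  }
  if (provenance %in% c("random_negative", "hard_negative") &&
      label != "background") {
    abort_upcallr(sprintf("%s examples must be labeled background", provenance),
                  "upcallr_error_label_provenance")
  }
  structure(list(patch = patch, label = label, provenance = provenance,
                 origin_time_s = origin_time_s,
                 origin_stream = origin_stream, edge_padded = edge_padded),
            class = "labeled_example")
}

# Cut a clip of params$clip_s seconds starting at start_s (stream time);
# parts outside the stream are zero-padded and flagged.
extract_clip <- function(stream, start_s, params = stft_params()) {
  sr <- stream$sample_rate_hz
  n <- round(params$clip_s * sr)
  i0 <- round((start_s - stream$start_time_s) * sr)  # 0-based
  idx <- i0 + seq_len(n)
  x <- numeric(n)
  valid <- idx >= 1L & idx <= length(stream$samples)
  x[valid] <- stream$samples[idx[valid]]
  list(clip = audio_stream(x, sr, start_time_s = start_s,
                           source_id = stream$source_id),
       edge_padded = !all(valid))
}

featurize_clip <- function(clip, params, normalization_mode) {
  p <- patch_from_clip(clip, params)
  suppressWarnings(normalize_patch(p, normalization_mode))
}

#' Extract a positive example around an annotated upcall
#'
#' The 2 s clip starts 1 s before the temporal midpoint of the annotation,
#' so the call is centered in the patch. Annotations closer than 1 s to a
#' stream edge are zero-padded and flagged.
#'
#' @param stream The source [audio_stream()] at the analysis rate.
#' @param ann A single-row [annotations()] tibble (or a row index into a
#'   larger one via `ann[i, ]`).
#' @param params [stft_params()].
#' @param normalization_mode Patch normalization (default `"sum_square"`).
#' @return A `labeled_example` with label `"upcall"`, provenance
#'   `"annotated"`.
#' @export
extract_positive <- function(stream, ann, params = stft_params(),
                             normalization_mode = "sum_square") {
  stopifnot(nrow(ann) == 1)
  dur <- duration_s(stream)
  if (ann$end_time_s <= stream$start_time_s ||
      ann$begin_time_s >= stream$start_time_s + dur) {
    abort_upcallr("annotation lies entirely outside the stream",
                  "upcallr_error_annotation_outside_stream")
  }
  mid <- (ann$begin_time_s + ann$end_time_s) / 2
  cl <- extract_clip(stream, mid - params$clip_s / 2, params)
  new_labeled_example(
    patch = featurize_clip(cl$clip, params, normalization_mode),
    label = "upcall", provenance = "annotated",
    origin_time_s = mid - params$clip_s / 2,
    origin_stream = stream$source_id,
    edge_padded = cl$edge_padded)
}

#' Sample random negative examples from call-free time
#'
#' Windows are drawn uniformly from the stream time where the 2 s window,
#' dilated by `guard_s` on both sides, overlaps no annotation. The guard
#' interval prevents near-miss leakage of call energy into the negatives.
#'
#' @param stream Source [audio_stream()].
#' @param ann Ground-truth [annotations()] for the stream.
#' @param n Number of negatives to draw.
#' @param guard_s Guard interval around annotations, seconds (default 1).
#' @param rng_seed Integer seed; sampling is reproducible under it.
#' @param params,normalization_mode As in [extract_positive()].
#' @return List of `labeled_example`s with provenance `"random_negative"`.
#' @export
sample_negatives <- function(stream, ann, n, guard_s = 1.0, rng_seed = 1L,
                             params = stft_params(),
                             normalization_mode = "sum_square") {
  dur <- duration_s(stream)
  t0 <- stream$start_time_s
  win <- params$clip_s
  # a window start t is forbidden iff (t - guard, t + win + guard) hits an
  # annotation; collect the allowed sub-intervals of [t0, t0 + dur - win]
  lo <- t0
  hi <- t0 + dur - win
  if (hi <= lo) {
    abort_upcallr("stream shorter than one window",
                  "upcallr_error_stream_too_short")
  }
  forb <- cbind(ann$begin_time_s - win - guard_s, ann$end_time_s + guard_s)
  pts <- sort(unique(c(lo, hi, pmin(pmax(forb, lo), hi))))
  allowed <- list()
  for (k in seq_len(length(pts) - 1)) {
    a <- pts[k]; b <- pts[k + 1]
    mid <- (a + b) / 2
    if (b > a && !any(mid > forb[, 1] & mid < forb[, 2])) {
      allowed[[length(allowed) + 1]] <- c(a, b)
    }
  }
  total <- sum(vapply(allowed, function(iv) iv[2] - iv[1], numeric(1)))
  if (!length(allowed) || total <= 0) {
    abort_upcallr(
      sprintf("no call-free time to place negatives (achievable n: 0, requested %d)", n),
      "upcallr_error_insufficient_negative_space")
  }
  with_seed(rng_seed, {
    lens <- vapply(allowed, function(iv) iv[2] - iv[1], numeric(1))
    lapply(seq_len(n), function(i) {
      iv <- allowed[[sample.int(length(allowed), 1, prob = lens)]]
      start <- stats::runif(1, iv[1], iv[2])
      cl <- extract_clip(stream, start, params)
      new_labeled_example(
        patch = featurize_clip(cl$clip, params, normalization_mode),
        label = "background", provenance = "random_negative",
        origin_time_s = start, origin_stream = stream$source_id,
        edge_padded = cl$edge_padded)
    })
  })
}

#' Augment examples by random waveform time shifts
#'
#' Each copy re-cuts the source clip with its start shifted by an amount
#' drawn uniformly from `[-max_shift_s, +max_shift_s]` and re-featurizes
#' the shifted waveform, so edge content is real audio (clips shifted past
#' a stream edge are zero-padded and flagged). The shifted copies are
#' pooled with the originals.
#'
#' @param examples List of `labeled_example`s.
#' @param streams A single [audio_stream()] or a list of streams; matched
#'   to examples by `source_id`.
#' @param max_shift_s Maximum absolute shift, seconds (default 0.2).
#' @param copies_per_example Shifted copies per example (default 1).
#' @param rng_seed Integer seed.
#' @param params,normalization_mode As in [extract_positive()].
#' @return `examples` followed by the shifted copies (provenance
#'   `"augmented"`, labels inherited).
#' @export
augment_examples <- function(examples, streams, max_shift_s = 0.2,
                             copies_per_example = 1L, rng_seed = 1L,
                             params = stft_params(),
                             normalization_mode = "sum_square") {
  if (copies_per_example < 1) return(examples)
  if (inherits(streams, "audio_stream")) streams <- list(streams)
  ids <- vapply(streams, function(s) s$source_id, character(1))
  with_seed(rng_seed, {
    shifted <- list()
    for (ex in examples) {
      j <- match(ex$origin_stream, ids)
      if (is.na(j)) {
        abort_upcallr(
          sprintf("no stream with source_id '%s' supplied", ex$origin_stream),
          "upcallr_error_missing_stream")
      }
      for (k in seq_len(copies_per_example)) {
        delta <- stats::runif(1, -max_shift_s, max_shift_s)
        cl <- extract_clip(streams[[j]], ex$origin_time_s + delta, params)
        shifted[[length(shifted) + 1]] <- new_labeled_example(
          patch = featurize_clip(cl$clip, params, normalization_mode),
          label = ex$label, provenance = "augmented",
          origin_time_s = ex$origin_time_s + delta,
          origin_stream = ex$origin_stream,
          edge_padded = cl$edge_padded)
      }
    }
    c(examples, shifted)
  })
}

#' Mine hard negatives from a preliminary detector's false positives
#'
#' Runs the sliding-window detector over training-domain audio, keeps
#' detections with probability at or above `prob_threshold` whose match
#' window (the evaluation module's tolerance) hits no annotation at all —
#' a detection overlapping a true call is never mined as a negative, even
#' when one-to-one matching would count it as a false positive — drops
#' candidates within `dedup_tol_s` of a negative already in the pool, and
#' returns them as background examples with provenance `"hard_negative"`.
#'
#' @param scorer A `trained_scorer`.
#' @param stream Training-domain [audio_stream()].
#' @param ann Ground-truth [annotations()] for the stream.
#' @param prob_threshold Detection probability floor (default 0.5).
#' @param dedup_tol_s Candidates whose clip start falls within this of an
#'   existing negative's origin time are dropped (default 0.1 s, one
#'   detector hop).
#' @param tolerance_s Matching tolerance against annotations (default 0.5).
#' @param existing_negative_times Origin times (s) of negatives already in
#'   the training pool for this stream.
#' @param hop_s,radius_s Detector parameters ([score_stream()],
#'   [non_max_suppress()]).
#' @return List of `labeled_example`s (possibly empty).
#' @export
mine_hard_negatives <- function(scorer, stream, ann, prob_threshold = 0.5,
                                dedup_tol_s = 0.1, tolerance_s = 0.5,
                                existing_negative_times = numeric(),
                                hop_s = 0.1, radius_s = 1.0) {
  if (!inherits(scorer, "trained_scorer") || !isTRUE(scorer$trained)) {
    abort_upcallr("scorer is not a trained_scorer",
                  "upcallr_error_untrained_scorer")
  }
  track <- score_stream(scorer, stream, hop_s = hop_s)
  det <- non_max_suppress(track, min_prob = prob_threshold,
                          radius_s = radius_s)
  if (!nrow(det)) return(list())
  hits_truth <- vapply(det$peak_time_s, function(t) {
    any(t >= ann$begin_time_s - tolerance_s &
          t <= ann$end_time_s + tolerance_s)
  }, logical(1))
  fp <- det[!hits_truth, ]
  params <- scorer$feature_params
  pooled <- existing_negative_times
  out <- list()
  for (i in seq_len(nrow(fp))) {
    start <- fp$peak_time_s[i] - params$clip_s / 2
    if (length(pooled) && any(abs(pooled - start) <= dedup_tol_s)) next
    cl <- extract_clip(stream, start, params)
    if (all(cl$clip$samples == 0)) next  # degenerate window, no content
    out[[length(out) + 1]] <- new_labeled_example(
      patch = featurize_clip(cl$clip, params, scorer$normalization_mode),
      label = "background", provenance = "hard_negative",
      origin_time_s = start, origin_stream = stream$source_id,
      edge_padded = cl$edge_padded)
    pooled <- c(pooled, start)
  }
  out
}

#' Manifest of a labeled example set
#'
#' One row per example: stream id, origin time, label, provenance and
#' edge-padding flag — the bookkeeping needed to reproduce or audit a
#' training pool.
#'
#' @param examples List of `labeled_example`s.
#' @return A tibble.
#' @export
dataset_manifest <- function(examples) {
  tibble::tibble(
    origin_stream = vapply(examples, function(e) e$origin_stream, character(1)),
    origin_time_s = vapply(examples, function(e) e$origin_time_s, numeric(1)),
    label = vapply(examples, function(e) e$label, character(1)),
    provenance = vapply(examples, function(e) e$provenance, character(1)),
    edge_padded = vapply(examples, function(e) e$edge_padded, logical(1))
  )
}
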