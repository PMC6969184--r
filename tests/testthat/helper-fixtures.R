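# Shared fixtures, all generated in code.

# A sine-wave audio stream.
sine_stream <- function(freq_hz, duration_s = 2, sample_rate_hz = 2000,
                        amplitude = 1, source_id = "sine") {
  n <- round(duration_s * sample_rate_hz)
  audio_stream(amplitude * sin(2 * pi * freq_hz * (0:(n - 1)) / sample_rate_hz),
               sample_rate_hz, source_id = source_id)
}

# Synthetic labeled examples with random patches (for model plumbing tests
# that do not need realistic spectra).
toy_patch <- function(values, mode = "sum_square") {
  structure(values,
            time_origin_s = 0, freq_origin_hz = 39.0625,
            params = stft_params(), normalization_mode = mode,
            class = c("spectrogram_patch", "matrix", "array"))
}

toy_example <- function(values, label, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- if (label == "upcall") "annotated" else "random_negative"
  }
  upcallr:::new_labeled_example(toy_patch(values), label, provenance,
                                origin_time_s = 0, origin_stream = "toy")
}

# A linearly separable two-class toy set: classes differ by a constant
# offset in one matrix cell.
separable_examples <- function(n_per_class = 40, seed = 42, offset = 0.5) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_per_class)) {
    m <- matrix(abs(rnorm(1600, sd = 0.05)), 40, 40)
    out[[length(out) + 1]] <- toy_example(m, "background")
    m2 <- matrix(abs(rnorm(1600, sd = 0.05)), 40, 40)
    m2[20, 20] <- m2[20, 20] + offset
    out[[length(out) + 1]] <- toy_example(m2, "upcall")
  }
  out
}

# Small, fast train_config for tests.
tiny_train_config <- function(epochs = 10, seed = 1, ...) {
  train_config(batch_size = 32L, epochs = epochs, rng_seed = seed, ...)
}

# A small rendered scene shared across tests (memoised per options).
test_scene <- local({
  cache <- list()
  function(duration_s = 240, call_rate = 120, conf_rate = 60, snr_db = 12,
           seed = 7) {
    key <- paste(duration_s, call_rate, conf_rate,
                 paste(snr_db, collapse = "_"), seed, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- render_scene(scene_config(
        duration_s = duration_s, call_rate_per_hour = call_rate,
        confounder_rate_per_hour = conf_rate, snr_db = snr_db,
        rng_seed = seed))
    }
    cache[[key]]
  }
})

# Brute-force O(n^2) non-maximum suppression used as an independent oracle.
brute_force_nms <- function(times, scores, window_s, min_prob, radius_s) {
  centers <- times + window_s / 2
  avail <- scores >= min_prob
  keep <- integer()
  while (any(avail)) {
    cand <- which(avail)
    best <- cand[order(-scores[cand], centers[cand])][1]
    keep <- c(keep, best)
    avail[abs(centers - centers[best]) <= radius_s] <- FALSE
  }
  sort(centers[keep])
}

# Independent greedy matcher mirroring the declared matching rule.
reference_match_counts <- function(det_times, det_scores, ann_begin, ann_end,
                                   tolerance_s) {
  used <- rep(FALSE, length(ann_begin))
  tp <- 0
  for (i in order(-det_scores, det_times)) {
    t <- det_times[i]
    elig <- which(!used & t >= ann_begin - tolerance_s &
                    t <= ann_end + tolerance_s)
    if (length(elig)) {
      mid <- (ann_begin[elig] + ann_end[elig]) / 2
      j <- elig[which.min(abs(mid - t))]
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(TP = tp, FP = length(det_times) - tp, FN = sum(!used))
}
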