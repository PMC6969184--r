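#' Score a continuous stream with a sliding 2 s window
#'
#' Advances a 2 s prediction window along the stream at a fixed hop
#' (default 0.1 s), featurizes every window exactly as in training
#' (including the trailing zero-padded frames of each clip), normalizes
#' with the scorer's training normalization mode, and evaluates the
#' classifier in batches. The result equals per-window evaluation to
#' numerical precision.
#'
#' @param scorer A `trained_scorer` from [train_scorer()].
#' @param stream An [audio_stream()] at the scorer's analysis rate, at
#'   least one window long.
#' @param hop_s Window advance, seconds (default 0.1).
#' @param batch_size Windows per forward pass (default 512).
#' @return A `score_track`: list with `times` (window start times, stream
#'   time), `scores` (upcall probabilities), `hop_s` and `window_s`.
#' @export
score_stream <- function(scorer, stream, hop_s = 0.1, batch_size = 512L) {
  stopifnot(inherits(scorer, "trained_scorer"), inherits(stream, "audio_stream"))
  params <- scorer$feature_params
  sr <- params$sample_rate_hz
  if (!isTRUE(all.equal(stream$sample_rate_hz, sr))) {
    abort_upcallr(
      sprintf("stream rate %g Hz != analysis rate %g Hz",
              stream$sample_rate_hz, sr),
      "upcallr_error_bad_clip_rate")
  }
  win_n <- round(params$clip_s * sr)
  if (length(stream$samples) < win_n) {
    abort_upcallr("stream shorter than one prediction window",
                  "upcallr_error_stream_too_short")
  }
  hop_n <- round(hop_s * sr)
  starts <- seq(0L, length(stream$samples) - win_n, by = hop_n)
  n_win <- length(starts)
  scores <- numeric(n_win)
  frame_hop <- round(params$hop_s * sr)
  frame_offsets <- (seq_len(params$n_time_frames) - 1L) * frame_hop
  for (b0 in seq(1L, n_win, by = batch_size)) {
    b <- b0:min(n_win, b0 + batch_size - 1L)
    Xb <- array(0, dim = c(1L, params$n_freq_bins, params$n_time_frames,
                           length(b)))
    for (j in seq_along(b)) {
      s0 <- starts[b[j]]
      # featurize this window in isolation so trailing frames are
      # zero-padded exactly as patch_from_clip does
      seg <- stream$samples[(s0 + 1):(s0 + win_n)]
      vals <- stft_columns(seg, frame_offsets, params)
      ss <- sum(vals^2)
      if (ss > 0) {
        vals <- if (scorer$normalization_mode == "sum_square") vals / ss
                else vals / sqrt(ss)
      }
      Xb[1L, , , j] <- vals
    }
    scores[b] <- predict_proba_array(scorer, Xb)
  }
  structure(
    list(times = stream$start_time_s + starts / sr, scores = scores,
         hop_s = hop_s, window_s = params$clip_s),
    class = "score_track")
}

#' Reduce a score track to isolated detections (non-maximum suppression)
#'
#' Greedy 1-D non-maximum suppression restricted to scores at or above
#' `min_prob`: repeatedly take the highest remaining score (ties broken by
#' earlier time), emit a detection at that window's center, and suppress
#' all windows whose centers lie within `radius_s`. No two detections are
#' closer than `radius_s`; lowering `min_prob` only adds detections.
#'
#' @param track A `score_track` from [score_stream()].
#' @param min_prob Probability floor (default 0.05).
#' @param radius_s Suppression radius in seconds around each kept peak
#'   (default 1.0, half the window length).
#' @return A `detections` tibble sorted by time with columns
#'   `peak_time_s` (window-center time of the kept score maximum),
#'   `score`, `begin_time_s` and `end_time_s` (the 2 s window).
#' @export
non_max_suppress <- function(track, min_prob = 0.05, radius_s = 1.0) {
  centers <- track$times + track$window_s / 2
  alive <- track$scores >= min_prob
  ord <- order(-track$scores, centers)
  ord <- ord[alive[ord]]
  kept <- integer()
  suppressed <- logical(length(centers))
  for (i in ord) {
    if (suppressed[i]) next
    kept <- c(kept, i)
    suppressed[abs(centers - centers[i]) <= radius_s] <- TRUE
  }
  kept <- kept[order(centers[kept])]
  out <- tibble::tibble(
    peak_time_s = centers[kept],
    score = track$scores[kept],
    begin_time_s = track$times[kept],
    end_time_s = track$times[kept] + track$window_s
  )
  class(out) <- c("detections", class(out))
  out
}

#' Convert detections to an annotations table
#'
#' Writes each detection as a 2 s bounding box over the analysis band with
#' a `Score` column, suitable for [write_selection_table()].
#'
#' @param det A `detections` tibble.
#' @param band Frequency bounds in Hz for the boxes (default the analysis
#'   band, `c(39.0625, 343.75)`).
#' @return An [annotations()] tibble with a `Score` column.
#' @export
detections_as_annotations <- function(det, band = c(39.0625, 343.75)) {
  ann <- annotations(
    begin_time_s = det$begin_time_s,
    end_time_s = det$end_time_s,
    low_freq_hz = rep(band[1], nrow(det)),
    high_freq_hz = rep(band[2], nrow(det)),
    label = rep("detection", nrow(det)),
    source = rep("detector", nrow(det)))
  ann$Score <- det$score[order(det$begin_time_s)]
  ann
}
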