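#' Spectrogram parameters for 40x40 patches
#'
#' Defines the short-time Fourier transform used to turn a 2 s clip into the
#' classifier's input patch: a 128 ms Hann window advanced by 50 ms, with
#' frequency rows restricted to 40 FFT bins starting at bin 5. At 2 kHz the
#' transform length is 256 samples, the bin width 7.8125 Hz, and the kept
#' bins span center frequencies 39.0625 to 343.75 Hz — the band where the
#' upcall's fundamental lives.
#'
#' Framing convention: frame `k` starts at `k * hop_s` for `k = 0 ... 39`,
#' so a 2 s clip yields exactly 40 frames; the last frames run past the clip
#' end and are zero-padded. (The usual `(N - W)/hop + 1` convention would
#' give 38 frames and a non-square patch.)
#'
#' @param window_s Analysis window length in seconds (default 0.128).
#' @param hop_s Frame advance in seconds (default 0.050).
#' @param low_bin_index First kept FFT bin (0-based; default 5).
#' @param n_freq_bins Number of kept frequency bins (default 40).
#' @param n_time_frames Number of frames per patch (default 40).
#' @param clip_s Clip length in seconds (default 2).
#' @param sample_rate_hz Analysis sample rate (default 2000).
#' @return A list of class `stft_params` with derived fields
#'   `fft_length_samples`, `bin_width_hz` and `freq_origin_hz`.
#' @export
stft_params <- function(window_s = 0.128, hop_s = 0.050, low_bin_index = 5L,
                        n_freq_bins = 40L, n_time_frames = 40L, clip_s = 2,
                        sample_rate_hz = 2000) {
  stopifnot(window_s > hop_s, hop_s > 0)
  fft_len <- as.integer(round(window_s * sample_rate_hz))
  bin_width <- sample_rate_hz / fft_len
  if ((low_bin_index + n_freq_bins) * bin_width > sample_rate_hz / 2) {
    abort_upcallr("requested frequency bins extend past Nyquist",
                  "upcallr_error_bad_stft_params")
  }
  structure(
    list(window_s = window_s, hop_s = hop_s,
         low_bin_index = as.integer(low_bin_index),
         n_freq_bins = as.integer(n_freq_bins),
         n_time_frames = as.integer(n_time_frames),
         clip_s = clip_s, sample_rate_hz = sample_rate_hz,
         fft_length_samples = fft_len, bin_width_hz = bin_width,
         freq_origin_hz = low_bin_index * bin_width),
    class = "stft_params"
  )
}

# Periodic Hann window of length n.
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

# Magnitude spectrogram columns for frames starting at 0-based sample
# offsets `starts` within `samples`; frames past the end are zero-padded.
# Returns an (n_freq_bins x length(starts)) matrix.
stft_columns <- function(samples, starts, params) {
  w <- params$fft_length_samples
  frames <- matrix(0, nrow = w, ncol = length(starts))
  n <- length(samples)
  idx <- outer(seq_len(w) - 1L, as.integer(starts), `+`) + 1L
  valid <- idx >= 1L & idx <= n
  frames[valid] <- samples[idx[valid]]
  frames <- frames * hann_window(w)
  spec <- stats::mvfft(frames)
  rows <- params$low_bin_index + seq_len(params$n_freq_bins)
  Mod(spec[rows, , drop = FALSE])
}

#' Compute a spectrogram patch from a 2 s clip
#'
#' @param clip An [audio_stream()] of exactly `params$clip_s` seconds
#'   (within one sample) at `params$sample_rate_hz`.
#' @param params An [stft_params()].
#' @return A `spectrogram_patch`: an `n_freq_bins x n_time_frames` matrix of
#'   linear magnitudes (rows = frequency ascending, columns = time
#'   ascending) with attributes `time_origin_s`, `freq_origin_hz`,
#'   `params` and `normalization_mode = "none"`.
#' @export
patch_from_clip <- function(clip, params = stft_params()) {
  stopifnot(inherits(clip, "audio_stream"))
  if (!isTRUE(all.equal(clip$sample_rate_hz, params$sample_rate_hz))) {
    abort_upcallr(
      sprintf("clip sample rate %g Hz != analysis rate %g Hz",
              clip$sample_rate_hz, params$sample_rate_hz),
      "upcallr_error_bad_clip_rate")
  }
  n_expect <- round(params$clip_s * params$sample_rate_hz)
  if (abs(length(clip$samples) - n_expect) > 1) {
    abort_upcallr(
      sprintf("clip length %d samples != expected %d",
              length(clip$samples), n_expect),
      "upcallr_error_bad_clip_length")
  }
  hop <- round(params$hop_s * params$sample_rate_hz)
  starts <- (seq_len(params$n_time_frames) - 1L) * hop
  vals <- stft_columns(clip$samples[seq_len(min(length(clip$samples), n_expect))],
                       starts, params)
  new_patch(vals, time_origin_s = clip$start_time_s,
            params = params, normalization_mode = "none")
}

new_patch <- function(values, time_origin_s, params, normalization_mode) {
  structure(values,
            time_origin_s = time_origin_s,
            freq_origin_hz = params$freq_origin_hz,
            params = params,
            normalization_mode = normalization_mode,
            class = c("spectrogram_patch", "matrix", "array"))
}

#' Normalize a spectrogram patch
#'
#' Two modes are provided. `"sum_square"` (the default) divides each element
#' by the sum of the squared elements of the matrix, the literal
#' normalization used when these patches were introduced; note it is not
#' invariant to input gain (scaling the clip by `c` scales the output by
#' `1/c`). `"unit_frobenius"` divides by the square root of that sum,
#' giving a gain-invariant matrix of Frobenius norm 1 — the likely intent
#' of the formula. A zero-energy patch is returned unchanged with a
#' `zero_energy` attribute set, with a warning.
#'
#' @param patch A `spectrogram_patch` from [patch_from_clip()].
#' @param mode `"sum_square"` or `"unit_frobenius"`.
#' @return The normalized `spectrogram_patch`.
#' @export
normalize_patch <- function(patch, mode = c("sum_square", "unit_frobenius")) {
  mode <- match.arg(mode)
  ss <- sum(patch^2)
  if (ss == 0) {
    warning("zero-energy patch left unnormalized")
    attr(patch, "zero_energy") <- TRUE
    return(patch)
  }
  vals <- if (mode == "sum_square") unclass(patch) / ss
          else unclass(patch) / sqrt(ss)
  p <- new_patch(vals, time_origin_s = attr(patch, "time_origin_s"),
                 params = attr(patch, "params"), normalization_mode = mode)
  p
}

#' @export
print.spectrogram_patch <- function(x, ...) {
  cat(sprintf("<spectrogram_patch> %d x %d, t0 = %.3f s, f0 = %.4f Hz, normalization = %s\n",
              nrow(x), ncol(x), attr(x, "time_origin_s") %||% NA_real_,
              attr(x, "freq_origin_hz") %||% NA_real_,
              attr(x, "normalization_mode") %||% "none"))
  invisible(x)
}
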