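#' Construct an audio stream
#'
#' An `audio_stream` is a mono sequence of pressure amplitudes (dimensionless,
#' nominally in `[-1, 1]`) with a sample rate and a time origin. It is the raw
#' material of every other operation in the package. Recordings from bottom
#' mounted hydrophone units are nominally sampled at 2 kHz; higher-rate
#' streams are brought to the analysis rate with [resample_to()].
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sample_rate_hz Sample rate in Hz, `> 0`.
#' @param start_time_s Stream time of the first sample, seconds (default 0).
#' @param source_id Free-text identifier of the source (file name, sensor id).
#' @return An object of class `audio_stream`.
#' @export
audio_stream <- function(samples, sample_rate_hz, start_time_s = 0,
                         source_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    abort_upcallr("`sample_rate_hz` must be a single positive number",
                  "upcallr_error_bad_sample_rate")
  }
  if (length(samples) && !all(is.finite(samples))) {
    abort_upcallr("audio samples must all be finite",
                  "upcallr_error_nonfinite_samples")
  }
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s, source_id = as.character(source_id)),
    class = "audio_stream"
  )
}

#' @export
print.audio_stream <- function(x, ...) {
  cat(sprintf("<audio_stream> %s: %.3f s @ %g Hz (%d samples)\n",
              if (nzchar(x$source_id)) x$source_id else "<unnamed>",
              duration_s(x), x$sample_rate_hz, length(x$samples)))
  invisible(x)
}

#' Duration of an audio stream in seconds
#' @param stream An [audio_stream()].
#' @return Duration `n_samples / sample_rate_hz` in seconds.
#' @export
duration_s <- function(stream) {
  length(stream$samples) / stream$sample_rate_hz
}

#' Read a PCM WAV file as a mono audio stream
#'
#' Reads 8/16/24/32-bit integer PCM and 32/64-bit IEEE float WAV. Integer
#' PCM is scaled to `[-1, 1]` by the convention `x / 2^(bits-1)`, so a
#' full-scale positive 16-bit sample maps to `32767/32768`.
#'
#' @param path Path to a readable WAV file.
#' @param channel 1-based channel index to extract (no mixdown: each sensor
#'   channel is an independent stream).
#' @return An [audio_stream()] at the file's native rate; `source_id` is the
#'   file's base name.
#' @export
read_audio <- function(path, channel = 1L) {
  if (!file.exists(path)) {
    abort_upcallr(sprintf("audio file not found: %s", path),
                  "upcallr_error_missing_file")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    abort_upcallr(sprintf("not a RIFF/WAV file: %s", path),
                  "upcallr_error_unsupported_encoding")
  }
  readBin(con, "integer", 1, 4, endian = "little")  # riff size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort_upcallr(sprintf("not a WAVE file: %s", path),
                  "upcallr_error_unsupported_encoding")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        channels  = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        rate      = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                            endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort_upcallr(sprintf("WAV file missing fmt/data chunk: %s", path),
                  "upcallr_error_unsupported_encoding")
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) is not parsed; 1 = PCM, 3 = IEEE float
  if (!fmt$format %in% c(1L, 3L)) {
    abort_upcallr(sprintf("unsupported WAV encoding (format tag %d)", fmt$format),
                  "upcallr_error_unsupported_encoding")
  }
  if (channel < 1 || channel > fmt$channels) {
    abort_upcallr(sprintf("channel %d out of range (file has %d)", channel,
                          fmt$channels),
                  "upcallr_error_channel_out_of_range")
  }
  bytes <- fmt$bits / 8
  n_total <- length(data_raw) %/% (bytes * fmt$channels)
  if (fmt$format == 3L) {
    x <- readBin(data_raw, "double", n_total * fmt$channels, size = bytes,
                 endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned with midpoint 128
    x <- (readBin(data_raw, "integer", n_total * fmt$channels, size = 1,
                  signed = FALSE) - 128) / 128
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    x <- readBin(data_raw, "integer", n_total * fmt$channels, size = bytes,
                 signed = TRUE, endian = "little") / (2^(fmt$bits - 1))
  }
  x <- x[seq(channel, by = fmt$channels, length.out = n_total)]
  audio_stream(x, fmt$rate, source_id = basename(path))
}

#' Write an audio stream to a PCM WAV file
#'
#' @param stream An [audio_stream()].
#' @param path Output path.
#' @param bit_depth 16 (integer PCM, samples clipped to `[-1, 1)`) or 32
#'   (IEEE float).
#' @return `path`, invisibly.
#' @export
write_audio <- function(stream, path, bit_depth = 16L) {
  stopifnot(inherits(stream, "audio_stream"))
  if (!bit_depth %in% c(16L, 32L)) {
    abort_upcallr("bit_depth must be 16 or 32",
                  "upcallr_error_unsupported_encoding")
  }
  n <- length(stream$samples)
  bytes <- bit_depth / 8
  fmt_tag <- if (bit_depth == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  sr <- as.integer(round(stream$sample_rate_hz))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, size = 4, endian = "little")
  if (bit_depth == 32L) {
    writeBin(stream$samples, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmin(32767, pmax(-32768, round(stream$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Resample an audio stream to a target rate
#'
#' Resampling is done in the frequency domain (spectrum truncation /
#' zero-padding). When down-sampling, an anti-aliasing low-pass is applied
#' with full gain up to 0.82 of the new Nyquist, a raised-cosine rolloff to
#' 0.9 of the new Nyquist, and zero above — the passband geometry of a
#' practical decimator, so near-Nyquist content is rejected rather than
#' kept by a razor-edge cutoff. Duration is preserved to within one output
#' sample period. A no-op when the rates already match. Upsampling cannot
#' restore content above the original Nyquist; it is permitted but noted
#' with a message.
#'
#' @param stream An [audio_stream()].
#' @param target_hz Target sample rate in Hz, `> 0`.
#' @return An [audio_stream()] at `target_hz`.
#' @export
resample_to <- function(stream, target_hz) {
  stopifnot(inherits(stream, "audio_stream"))
  if (!is.numeric(target_hz) || length(target_hz) != 1 || target_hz <= 0) {
    abort_upcallr("`target_hz` must be a single positive number",
                  "upcallr_error_bad_sample_rate")
  }
  if (isTRUE(all.equal(target_hz, stream$sample_rate_hz))) {
    return(stream)
  }
  if (target_hz > stream$sample_rate_hz) {
    message(sprintf(
      "upsampling %g Hz -> %g Hz: no content exists above the original Nyquist (%g Hz)",
      stream$sample_rate_hz, target_hz, stream$sample_rate_hz / 2))
  }
  n <- length(stream$samples)
  m <- max(1L, as.integer(round(n * target_hz / stream$sample_rate_hz)))
  xf <- stats::fft(stream$samples)
  yf <- complex(m)
  # Copy the low-frequency half-spectra; the shorter of the two limits.
  k <- min(n, m)
  half <- (k + (k %% 2)) / 2          # number of strictly-positive-freq bins kept
  keep_lo <- seq_len(half)            # DC .. positive freqs
  yf[keep_lo] <- xf[keep_lo]
  if (half > 1) {
    neg <- seq_len(half - 1)
    yf[m - neg + 1] <- xf[n - neg + 1]
  }
  # If the shared Nyquist bin exists on both grids, keep it real-safe.
  if (k %% 2 == 0 && m > k) {
    yf[half + 1] <- 0
  }
  if (target_hz < stream$sample_rate_hz) {
    # anti-alias rolloff: unity below 0.82 * Nyquist, raised cosine to
    # 0.9 * Nyquist, zero above
    ny <- target_hz / 2
    f <- (seq_len(m) - 1) * target_hz / m
    f <- pmin(f, target_hz - f)
    gain <- rep(1, m)
    taper <- f > 0.82 * ny & f < 0.9 * ny
    gain[taper] <- cos(pi / 2 * (f[taper] - 0.82 * ny) / (0.08 * ny))^2
    gain[f >= 0.9 * ny] <- 0
    yf <- yf * gain
  }
  y <- Re(stats::fft(yf, inverse = TRUE)) / n
  audio_stream(y, target_hz, start_time_s = stream$start_time_s,
               source_id = stream$source_id)
}
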