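#' Call parameters for a synthetic upcall
#'
#' A synthetic upcall is an upward frequency sweep: instantaneous frequency
#' rises monotonically from `start_hz` to `start_hz + bandwidth_hz`
#' following `f(t) = start + bandwidth * (t/T)^curvature` (curvature 1 is a
#' linear sweep), with a Hann amplitude envelope. Defaults follow the only
#' quantitative envelope available for the call type: duration 0.5–2 s and
#' sweep start 55–157 Hz (the acceptance window of operational upcall
#' detection buoys).
#'
#' @param start_hz Sweep start frequency, Hz.
#' @param bandwidth_hz Upward sweep extent, Hz, `> 0`.
#' @param duration_s Call duration, seconds.
#' @param curvature Shape exponent, `> 0`; 1 = linear sweep.
#' @param amplitude Linear peak amplitude.
#' @param harmonics Number of harmonic components (1 = fundamental only).
#' @return A list of class `call_params`.
#' @export
call_params <- function(start_hz = 100, bandwidth_hz = 100, duration_s = 1,
                        curvature = 1, amplitude = 1, harmonics = 1L) {
  stopifnot(start_hz > 0, bandwidth_hz >= 0, duration_s > 0, curvature > 0,
            amplitude >= 0, harmonics >= 1)
  structure(list(start_hz = start_hz, bandwidth_hz = bandwidth_hz,
                 duration_s = duration_s, curvature = curvature,
                 amplitude = amplitude, harmonics = as.integer(harmonics)),
            class = "call_params")
}

#' Generate an upsweeping call waveform
#'
#' Phase is the exact integral of the instantaneous frequency,
#' `phi(t) = 2*pi*(start*t + bandwidth*T/(curvature+1)*(t/T)^(curvature+1))`.
#'
#' @param params A [call_params()].
#' @param sample_rate_hz Sample rate, Hz.
#' @return Numeric waveform of `round(duration_s * sample_rate_hz)` samples
#'   with peak amplitude `params$amplitude`.
#' @export
gen_upcall <- function(params, sample_rate_hz = 2000) {
  top <- (params$start_hz + params$bandwidth_hz) * params$harmonics
  if (top >= sample_rate_hz / 2) {
    abort_upcallr(
      sprintf("sweep reaches %g Hz, above Nyquist (%g Hz)", top,
              sample_rate_hz / 2),
      "upcallr_error_above_nyquist")
  }
  n <- round(params$duration_s * sample_rate_hz)
  t <- (0:(n - 1)) / sample_rate_hz
  T_ <- params$duration_s
  phase <- 2 * pi * (params$start_hz * t +
    params$bandwidth_hz * T_ / (params$curvature + 1) * (t / T_)^(params$curvature + 1))
  env <- hann_window(n)
  x <- numeric(n)
  for (h in seq_len(params$harmonics)) {
    x <- x + sin(h * phase) / 2^(h - 1)
  }
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- x * params$amplitude / peak
  x
}

#' Generate an upsweep-like confounder waveform
#'
#' Confounders emulate the non-target sounds that make upcall detection
#' hard: `downsweep` (time-reversed chirp), `flat_tonal` (constant
#' frequency tone), `broadband_pulse` (50–200 ms band-limited noise
#' burst), and `near_miss_upsweep` (an upsweep whose start frequency or
#' duration falls outside the upcall envelope, e.g. starting above 200 Hz
#' or shorter than 0.4 s — the kind of sound hard-negative mining exists
#' to suppress).
#'
#' Stochastic choices use the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param type One of `"downsweep"`, `"flat_tonal"`, `"broadband_pulse"`,
#'   `"near_miss_upsweep"`.
#' @param sample_rate_hz Sample rate, Hz.
#' @return Numeric waveform with peak amplitude 1.
#' @export
gen_confounder <- function(type, sample_rate_hz = 2000) {
  types <- c("downsweep", "flat_tonal", "broadband_pulse", "near_miss_upsweep")
  if (!is.character(type) || length(type) != 1 || !type %in% types) {
    abort_upcallr(
      sprintf("unknown confounder type '%s'; available: %s",
              as.character(type)[1], paste(types, collapse = ", ")),
      "upcallr_error_unknown_confounder")
  }
  switch(type,
    downsweep = {
      p <- call_params(start_hz = stats::runif(1, 55, 157),
                       bandwidth_hz = stats::runif(1, 60, 120),
                       duration_s = stats::runif(1, 0.5, 2),
                       curvature = stats::runif(1, 0.8, 1.5))
      rev(gen_upcall(p, sample_rate_hz))
    },
    flat_tonal = {
      f <- stats::runif(1, 60, 300)
      n <- round(stats::runif(1, 0.5, 2) * sample_rate_hz)
      sin(2 * pi * f * (0:(n - 1)) / sample_rate_hz) * hann_window(n)
    },
    broadband_pulse = {
      n <- round(stats::runif(1, 0.05, 0.2) * sample_rate_hz)
      x <- bandpass_fft(stats::rnorm(n), sample_rate_hz, c(40, 400))
      x <- x * hann_window(n)
      x / max(abs(x))
    },
    near_miss_upsweep = {
      if (stats::runif(1) < 0.5) {
        p <- call_params(start_hz = stats::runif(1, 210, 280),
                         bandwidth_hz = stats::runif(1, 40, 60),
                         duration_s = stats::runif(1, 0.5, 1.5))
      } else {
        p <- call_params(start_hz = stats::runif(1, 55, 157),
                         bandwidth_hz = stats::runif(1, 60, 120),
                         duration_s = stats::runif(1, 0.15, 0.35))
      }
      gen_upcall(p, sample_rate_hz)
    })
}

# Zero-phase brick-wall bandpass via the FFT; band = c(low, high) in Hz.
bandpass_fft <- function(x, sample_rate_hz, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f <- pmin(f, sample_rate_hz - f)  # two-sided frequency magnitude
  xf <- stats::fft(x)
  xf[f < band[1] | f > band[2]] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Generate band-limited colored noise
#'
#' Gaussian noise spectrally shaped so that power is proportional to
#' `1/f^slope` inside `band` and zero outside, scaled to unit RMS.
#' `slope = 0` is white (flat in band); `slope = 1` approximates the
#' low-frequency-dominated ocean ambient.
#'
#' @param duration_s Duration in seconds.
#' @param sample_rate_hz Sample rate, Hz.
#' @param slope Spectral exponent of the `1/f^slope` power law.
#' @param band Passband `c(low, high)` in Hz, within Nyquist.
#' @return Numeric waveform of unit RMS; uses the current RNG state.
#' @export
gen_noise <- function(duration_s, sample_rate_hz = 2000, slope = 1,
                      band = c(10, 800)) {
  if (band[2] > sample_rate_hz / 2 || band[1] < 0 || band[1] >= band[2]) {
    abort_upcallr("noise band must lie within (0, Nyquist)",
                  "upcallr_error_bad_band")
  }
  n <- round(duration_s * sample_rate_hz)
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f <- pmin(f, sample_rate_hz - f)
  gain <- numeric(n)
  inb <- f >= band[1] & f <= band[2]
  gain[inb] <- (pmax(f[inb], band[1]))^(-slope / 2)
  xf <- stats::fft(x) * gain
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' Scene configuration for the synthetic soundscape generator
#'
#' Defines the statistical structure of a generated recording: sparse
#' upsweeping calls and upsweep-like confounders arriving as independent
#' Poisson processes, embedded in band-limited (10–800 Hz) colored noise
#' at a controlled per-call SNR. SNR is defined over the call's time
#' support and the 39.06–343.75 Hz analysis band (the band the classifier
#' sees), not broadband.
#'
#' @param duration_s Scene length, seconds.
#' @param sample_rate_hz Sample rate (default 2000 Hz).
#' @param call_rate_per_hour Expected upcalls per hour (default 60).
#' @param confounder_rate_per_hour Expected confounders per hour (default 60).
#' @param snr_db Target in-band SNR per call, dB; a scalar or a
#'   `c(lo, hi)` range to draw from (default 10).
#' @param noise_slope Spectral exponent of the ambient noise (default 1).
#' @param band Noise passband in Hz (default `c(10, 800)`).
#' @param rng_seed Integer seed; the scene is bit-reproducible given it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(duration_s = 600, sample_rate_hz = 2000,
                         call_rate_per_hour = 60,
                         confounder_rate_per_hour = 60,
                         snr_db = 10, noise_slope = 1, band = c(10, 800),
                         rng_seed = 1L) {
  stopifnot(duration_s > 0, call_rate_per_hour >= 0,
            confounder_rate_per_hour >= 0, band[2] <= sample_rate_hz / 2)
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 call_rate_per_hour = call_rate_per_hour,
                 confounder_rate_per_hour = confounder_rate_per_hour,
                 snr_db = snr_db, noise_slope = noise_slope, band = band,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# In-band RMS over the analysis band (39.06-343.75 Hz by default).
inband_rms <- function(x, sample_rate_hz, band = c(39.0625, 343.75)) {
  sqrt(mean(bandpass_fft(x, sample_rate_hz, band)^2))
}

#' Render an annotated synthetic soundscape
#'
#' Call and confounder onsets are drawn from independent Poisson processes.
#' Calls are redrawn if they would overlap another call (upcalls are sparse
#' contact calls); confounders may overlap anything. Each call is scaled so
#' that its in-band SNR over its own time support matches the target, and
#' recorded in the truth table as a time-frequency bounding box.
#'
#' @param config A [scene_config()].
#' @return A list of class `scene_truth` with elements `stream` (an
#'   [audio_stream()]), `annotations` (calls only, an [annotations()]
#'   tibble) and `confounder_log` (an [annotations()] tibble labeled by
#'   confounder type).
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  sr <- config$sample_rate_hz
  with_seed(config$rng_seed, {
    x <- gen_noise(config$duration_s, sr, config$noise_slope, config$band)
    n <- length(x)

    n_calls <- stats::rpois(1, config$call_rate_per_hour * config$duration_s / 3600)
    placed <- list()
    ann_rows <- list()
    for (i in seq_len(n_calls)) {
      ok <- FALSE
      for (attempt in 1:200) {
        p <- call_params(
          start_hz = stats::runif(1, 55, 157),
          bandwidth_hz = stats::runif(1, 60, 120),
          duration_s = stats::runif(1, 0.5, 2),
          curvature = stats::runif(1, 0.8, 1.5))
        onset <- stats::runif(1, 0, config$duration_s - p$duration_s)
        clash <- any(vapply(placed, function(iv) {
          onset < iv[2] + 0.25 && onset + p$duration_s > iv[1] - 0.25
        }, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) {
        abort_upcallr(
          "call rate too high to place non-overlapping calls; lower call_rate_per_hour",
          "upcallr_error_scene_too_dense")
      }
      w <- gen_upcall(p, sr)
      i0 <- round(onset * sr)
      seg <- (i0 + 1):(i0 + length(w))
      snr <- if (length(config$snr_db) == 2) {
        stats::runif(1, config$snr_db[1], config$snr_db[2])
      } else config$snr_db
      rms_noise <- inband_rms(x[seg], sr)
      rms_call <- inband_rms(w, sr)
      scale <- rms_noise * 10^(snr / 20) / rms_call
      x[seg] <- x[seg] + w * scale
      placed[[length(placed) + 1]] <- c(onset, onset + p$duration_s)
      ann_rows[[length(ann_rows) + 1]] <- c(onset, onset + p$duration_s,
                                            p$start_hz,
                                            p$start_hz + p$bandwidth_hz)
    }

    n_conf <- stats::rpois(1,
      config$confounder_rate_per_hour * config$duration_s / 3600)
    conf_types <- c("downsweep", "flat_tonal", "broadband_pulse",
                    "near_miss_upsweep")
    conf_rows <- list()
    conf_labels <- character()
    for (i in seq_len(n_conf)) {
      ty <- sample(conf_types, 1)
      w <- gen_confounder(ty, sr)
      dur <- length(w) / sr
      onset <- stats::runif(1, 0, config$duration_s - dur)
      i0 <- round(onset * sr)
      seg <- (i0 + 1):(i0 + length(w))
      snr <- if (length(config$snr_db) == 2) {
        stats::runif(1, config$snr_db[1], config$snr_db[2])
      } else config$snr_db
      rms_noise <- inband_rms(x[seg], sr)
      rms_conf <- inband_rms(w, sr)
      if (rms_conf > 0) {
        x[seg] <- x[seg] + w * (rms_noise * 10^(snr / 20) / rms_conf)
      }
      conf_rows[[length(conf_rows) + 1]] <- c(onset, onset + dur, 40, 400)
      conf_labels <- c(conf_labels, ty)
    }

    mk_ann <- function(rows, labels) {
      if (!length(rows)) return(annotations())
      m <- do.call(rbind, rows)
      annotations(begin_time_s = m[, 1], end_time_s = m[, 2],
                  low_freq_hz = m[, 3], high_freq_hz = m[, 4],
                  label = labels, source = "synthetic")
    }
    structure(
      list(stream = audio_stream(x, sr, source_id = sprintf("scene_seed%d", config$rng_seed)),
           annotations = mk_ann(ann_rows, rep("upcall", length(ann_rows))),
           confounder_log = mk_ann(conf_rows, conf_labels),
           config = config),
      class = "scene_truth")
  })
}
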