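# Ridge-tracking oracle: dominant STFT bin per frame for a waveform.
ridge_bins <- function(x, sample_rate_hz = 2000) {
  params <- stft_params()
  n_frames <- max(1, floor((length(x) - 256) / 100))
  starts <- (seq_len(n_frames) - 1) * 100
  cols <- upcallr:::stft_columns(x, starts, stft_params(
    low_bin_index = 0L, n_freq_bins = 128L))
  apply(cols, 2, which.max)
}

test_that("gen_upcall sweeps up through the expected mid-call frequency", {
  p <- call_params(start_hz = 100, bandwidth_hz = 100, duration_s = 1,
                   curvature = 1, amplitude = 1)
  x <- gen_upcall(p, 2000)
  expect_equal(length(x), 2000)
  expect_equal(max(abs(x)), 1)
  bins <- ridge_bins(x)
  mid <- bins[round(length(bins) / 2)]
  # mid-call instantaneous frequency = 150 Hz; bin width 7.8125 Hz
  expect_lte(abs((mid - 1) * 7.8125 - 150), 7.8125 * 1.5)
  # monotone rise overall
  expect_gt(bins[length(bins) - 1], bins[2])

  # degenerate: zero bandwidth is a pure tone at start_hz
  tone <- gen_upcall(call_params(start_hz = 78.125, bandwidth_hz = 0,
                                 duration_s = 1), 2000)
  bt <- ridge_bins(tone)
  expect_true(all(abs((bt - 1) * 7.8125 - 78.125) <= 7.8125))

  # linearity in amplitude
  x2 <- gen_upcall(call_params(start_hz = 100, bandwidth_hz = 100,
                               duration_s = 1, amplitude = 2), 2000)
  expect_equal(x2, 2 * x, tolerance = 1e-12)

  expect_error(gen_upcall(call_params(start_hz = 900, bandwidth_hz = 200)),
               class = "upcallr_error_above_nyquist")
})

test_that("confounders have their advertised time-frequency shapes", {
  set.seed(5)
  down <- gen_confounder("downsweep")
  bins <- ridge_bins(down)
  inner <- bins[2:(length(bins) - 1)]
  expect_true(all(diff(inner) <= 0))
  expect_lt(inner[length(inner)], inner[1])

  flat <- gen_confounder("flat_tonal")
  bf <- ridge_bins(flat)
  expect_lt(stats::var(bf[2:(length(bf) - 1)]), 1)

  pulse <- gen_confounder("broadband_pulse")
  expect_lt(length(pulse) / 2000, 0.25)

  expect_error(gen_confounder("humpback_song"),
               class = "upcallr_error_unknown_confounder")
})

test_that("gen_noise is band-limited, unit RMS, flat for slope 0, and seeded", {
  set.seed(8)
  x <- gen_noise(30, 2000, slope = 0, band = c(10, 800))
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-9)

  # averaged periodogram: flat in band within +/- 3 dB
  spec <- Mod(stats::fft(x))^2
  f <- (seq_along(spec) - 1) * 2000 / length(spec)
  inband <- f > 30 & f < 700
  bins <- cut(f[inband], 20)
  band_power <- tapply(spec[inband], bins, mean)
  expect_lt(max(10 * log10(band_power / mean(band_power))), 3)
  expect_gt(min(10 * log10(band_power / mean(band_power))), -3)

  # out-of-band power < 1% of total
  oob <- f > 820 & f < 1000 | f < 9
  expect_lt(sum(spec[oob]), 0.01 * sum(spec))

  set.seed(8)
  x2 <- gen_noise(30, 2000, slope = 0, band = c(10, 800))
  expect_identical(x, x2)

  expect_error(gen_noise(1, 2000, band = c(10, 1500)),
               class = "upcallr_error_bad_band")
})

test_that("render_scene is reproducible and annotates every call", {
  sc1 <- render_scene(scene_config(duration_s = 180, rng_seed = 42))
  sc2 <- render_scene(scene_config(duration_s = 180, rng_seed = 42))
  expect_identical(sc1$stream$samples, sc2$stream$samples)
  expect_identical(sc1$annotations, sc2$annotations)

  empty <- render_scene(scene_config(duration_s = 60,
                                     call_rate_per_hour = 0,
                                     confounder_rate_per_hour = 0,
                                     rng_seed = 1))
  expect_equal(nrow(empty$annotations), 0)
  expect_equal(nrow(empty$confounder_log), 0)

  # call count is Poisson with the configured rate
  counts <- vapply(1:60, function(s) {
    nrow(render_scene(scene_config(duration_s = 120,
                                   call_rate_per_hour = 120,
                                   confounder_rate_per_hour = 0,
                                   rng_seed = s))$annotations)
  }, numeric(1))
  lambda <- 120 * 120 / 3600  # 4 expected calls
  se <- sqrt(lambda / 60)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("rendered calls hit their target in-band SNR within 1 dB", {
  sc <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                   snr_db = 10, seed = 21)
  noise_only <- render_scene(scene_config(
    duration_s = 240, call_rate_per_hour = 0, confounder_rate_per_hour = 0,
    rng_seed = 21))
  ann <- sc$annotations
  expect_gt(nrow(ann), 2)
  for (i in seq_len(nrow(ann))) {
    seg <- (round(ann$begin_time_s[i] * 2000) + 1):(round(ann$end_time_s[i] * 2000))
    call_part <- sc$stream$samples[seg] - noise_only$stream$samples[seg]
    r_call <- upcallr:::inband_rms(call_part, 2000)
    r_noise <- upcallr:::inband_rms(noise_only$stream$samples[seg], 2000)
    snr <- 20 * log10(r_call / r_noise)
    expect_lt(abs(snr - 10), 1)
  }
})

test_that("annotated boxes contain call energy above the noise floor", {
  sc <- test_scene(duration_s = 240, call_rate = 120, conf_rate = 0,
                   snr_db = 10, seed = 21)
  ann <- sc$annotations
  for (i in seq_len(min(nrow(ann), 5))) {
    mid <- (ann$begin_time_s[i] + ann$end_time_s[i]) / 2
    ex <- extract_positive(sc$stream, ann[i, ],
                           normalization_mode = "unit_frobenius")
    p <- ex$patch
    rows <- which(attr(p, "freq_origin_hz") + (0:39) * 7.8125 >=
                    ann$low_freq_hz[i] &
                  attr(p, "freq_origin_hz") + (0:39) * 7.8125 <=
                    ann$high_freq_hz[i])
    # mean energy in the call's frequency rows exceeds the patch average
    expect_gt(mean(p[rows, 10:30]^2), mean(p^2))
  }
})
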