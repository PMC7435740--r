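test_that("constant-rate profiles yield exact interval inverses of the rate", {
  for (case in list(c(120, 500), c(240, 250), c(60, 1000))) {
    beats <- generate_beat_times(fhr_profile(10, case[1]))
    expect_true(all(abs(beats$intervals_ms - case[2]) < 1e-9),
                info = paste("baseline", case[1]))
  }
  # 120 bpm over 10 s: 20 complete 500-ms intervals
  beats <- generate_beat_times(fhr_profile(10, 120))
  expect_equal(length(beats$intervals_ms), 20)
})

test_that("beat-to-beat jitter has the configured magnitude", {
  beats <- generate_beat_times(fhr_profile(60, 120, stv_jitter_sd_ms = 10,
                                           seed = 42))
  sd_diff <- sd(diff(beats$intervals_ms))
  expect_lt(abs(sd_diff - sqrt(2) * 10), 0.2 * sqrt(2) * 10)
})

test_that("profiles are validated and degenerate profiles are rejected", {
  expect_error(fhr_profile(10, 30), "60-240")
  expect_error(fhr_profile(-1, 120))
  # huge deceleration below zero rate must be rejected with a diagnostic
  prof <- fhr_profile(10, 120, episodes = list(c(1, 9, -200)))
  expect_error(generate_beat_times(prof), "non-positive")
})

test_that("LTV sinusoids and episodes modulate the instantaneous rate", {
  prof <- fhr_profile(60, 120, ltv_components = list(c(10, 0.05)))
  beats <- generate_beat_times(prof)
  rate <- 60000 / beats$intervals_ms
  expect_gt(max(rate), 125)
  expect_lt(min(rate), 115)
  prof2 <- fhr_profile(60, 120, episodes = list(c(20, 40, 15)))
  beats2 <- generate_beat_times(prof2)
  mid <- beats2$onsets_ms[-length(beats2$onsets_ms)] / 1000
  expect_gt(mean(60000 / beats2$intervals_ms[mid > 25 & mid < 35]), 130)
  expect_lt(mean(60000 / beats2$intervals_ms[mid < 15]), 125)
})

test_that("waveform synthesis is deterministic for a fixed seed", {
  beats <- generate_beat_times(fhr_profile(5, 120, stv_jitter_sd_ms = 5,
                                           seed = 7))
  r1 <- synthesize_us_signal(beats, us_sim_params(seed = 9))
  r2 <- synthesize_us_signal(beats, us_sim_params(seed = 9))
  expect_identical(r1$samples, r2$samples)
  r3 <- synthesize_us_signal(beats, us_sim_params(seed = 10))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("single-phase synthesis confines spectral power to the phase band", {
  beats <- generate_beat_times(fhr_profile(10, 120))
  vc_only <- default_us_phases()[2, ]  # Vc: wall band, 100-300 Hz
  rec <- synthesize_us_signal(beats, us_sim_params(
    phases = vc_only, noise_sd = 0, drift = NULL))
  spec <- Mod(fft(rec$samples))^2
  freq <- (seq_along(spec) - 1) / length(spec) * rec$fs
  half <- freq <= rec$fs / 2
  in_band <- half & freq >= 100 & freq <= 300
  expect_gt(sum(spec[in_band]) / sum(spec[half]), 0.95)
})

test_that("full six-phase synthesis stays in the 100-600 Hz union band", {
  beats <- generate_beat_times(fhr_profile(10, 120, stv_jitter_sd_ms = 5,
                                           seed = 3))
  rec <- synthesize_us_signal(beats, us_sim_params(noise_sd = 0, drift = NULL))
  spec <- Mod(fft(rec$samples))^2
  freq <- (seq_along(spec) - 1) / length(spec) * rec$fs
  half <- freq <= rec$fs / 2
  in_band <- half & freq >= 100 & freq <= 600
  expect_gt(sum(spec[in_band]) / sum(spec[half]), 0.95)
})

test_that("six-phase synthesis puts one burst cluster per cardiac cycle", {
  beats <- generate_beat_times(fhr_profile(10, 120))
  rec <- synthesize_us_signal(beats, us_sim_params(noise_sd = 0, drift = NULL))
  env <- envelope_rectify_lowpass(bandpass(rec, band_spec(100, 600)),
                                  cutoff = 25)
  # autocorrelation of the envelope must peak at 500 ms
  af <- autocorrelation(env$values[1000:5000], max_lag = 1000)
  peak <- which.max(af$values[251:1001]) + 249
  expect_lt(abs(peak - 500), 2)
})

test_that("phase band constraints are enforced", {
  bad <- default_us_phases()
  bad$center_hz[bad$name == "Ao"] <- 200  # valve phase outside 300-600
  expect_error(us_sim_params(phases = bad), "valve")
  bad2 <- default_us_phases()
  bad2$center_hz[bad2$name == "Vc"] <- 500  # wall phase outside 100-300
  expect_error(us_sim_params(phases = bad2), "wall")
})

test_that("beats_to_reference conserves time and handles edge cases", {
  bt <- structure(list(onsets_ms = c(0, 500, 1000),
                       intervals_ms = c(500, 500)), class = "beat_train")
  ref <- beats_to_reference(bt)
  expect_equal(ref$tau_ms, c(0, 500))
  expect_equal(ref$T_ms, c(500, 500))
  # single onset: no interval definable
  one <- structure(list(onsets_ms = 0, intervals_ms = numeric(0)),
                   class = "beat_train")
  expect_equal(nrow(beats_to_reference(one)), 0)
  # telescoping: sum of intervals equals the span exactly
  beats <- generate_beat_times(fhr_profile(60, 120, stv_jitter_sd_ms = 8,
                                           seed = 11))
  ref2 <- beats_to_reference(beats)
  expect_equal(sum(ref2$T_ms),
               max(beats$onsets_ms) - min(beats$onsets_ms))
})

test_that("movement interference adds energy uncorrelated with beats", {
  beats <- generate_beat_times(fhr_profile(10, 120))
  base <- us_sim_params(noise_sd = 0, drift = NULL, seed = 5)
  with_int <- us_sim_params(noise_sd = 0, drift = NULL, seed = 5,
                            interference = list(c(4, 6)))
  r0 <- synthesize_us_signal(beats, base)
  r1 <- synthesize_us_signal(beats, with_int)
  seg <- function(r, a, b) r$samples[(a * r$fs):(b * r$fs)]
  expect_gt(mean(seg(r1, 4.2, 5.8)^2), 2 * mean(seg(r0, 4.2, 5.8)^2))
  expect_equal(seg(r1, 1, 3), seg(r0, 1, 3))
})
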