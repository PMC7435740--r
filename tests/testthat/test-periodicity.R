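test_that("autocorrelation matches the direct biased estimator", {
  set.seed(4)
  for (n in c(400, 1000, 1500)) {
    x <- rnorm(n) + sin(2 * pi * seq_len(n) / 97)
    af <- autocorrelation(x, max_lag = 300)
    oracle <- stats::acf(x, lag.max = 300, type = "correlation",
                         demean = TRUE, plot = FALSE)$acf[, 1, 1]
    expect_equal(af$values, oracle, tolerance = 1e-9)
  }
})

test_that("autocorrelation is normalized with the biased-estimator decay", {
  n <- 1600  # four full cycles of a 400-ms period
  x <- sin(2 * pi * seq_len(n) / 400)
  af <- autocorrelation(x, max_lag = 1000)
  expect_equal(af$values[1], 1)
  idx <- 251:1001  # lag range 250..1000 ms
  peak_lag <- which.max(af$values[idx]) + 249
  # broad sinusoidal peak: the (n - lag)/n bias tilts it by a few ms
  expect_lte(abs(peak_lag - 400), 5)
  # biased estimator: peak amplitude ~ (n - lag)/n
  expect_equal(max(af$values[idx]), (n - 400) / n, tolerance = 0.05)
})

test_that("burst-train envelopes are located to within one lag quantum", {
  # window chosen so no burst straddles its edges: a clipped burst skews
  # the correlation peak by a few ms (see the free-running test below)
  for (period in c(400, 500, 750)) {
    bpm <- 60000 / period
    beats <- generate_beat_times(fhr_profile(10, bpm))
    env <- make_burst_envelope(beats$onsets_ms)
    w <- env$values[201:(200 + 2 * period + 100)]
    af <- autocorrelation(w, max_lag = min(1000, length(w) - 200))
    idx <- 251:(length(af$values))
    peak_lag <- which.max(af$values[idx]) + 249
    expect_lte(abs(peak_lag - period), 1, label = paste("period", period))
  }
})

test_that("all-constant windows yield an undefined AF (loss)", {
  expect_null(autocorrelation(rep(3.2, 1000), max_lag = 500))
})

test_that("white-noise windows rarely reach the 0.5 quality gate", {
  set.seed(99)
  peaks <- replicate(200, {
    af <- autocorrelation(rnorm(1500), max_lag = 1000)
    max(af$values[251:1001])
  })
  expect_gte(mean(peaks < 0.5), 0.95)
})

test_that("trapezoidal weighting has the 1:4 base geometry", {
  af <- list(lags = 0:1000, values = rep(1, 1001))
  w <- trapezoidal_pf(af, center = 500, S = 400)$values
  expect_equal(w[501], 1)                 # centre of plateau
  expect_equal(w[c(451, 551)], c(1, 1))   # plateau edges at +/- S/8
  expect_equal(w[c(301, 701)], c(0, 0))   # lower base edges at +/- S/2
  expect_equal(w[376], 0.5, tolerance = 1e-9)  # midway down the flank (d = 125)
  expect_true(all(w[0:250] == 0) && all(w[751:1001] == 0))
})

test_that("prediction weighting never raises the AF and rescues true peaks", {
  lags <- 0:1000
  # spurious higher peak at 700 ms, true peak at 490 near the last interval
  vals <- exp(-0.5 * ((lags - 700) / 20)^2) * 0.8 +
    exp(-0.5 * ((lags - 490) / 20)^2) * 0.6
  af <- list(lags = lags, values = vals)
  wtd <- trapezoidal_pf(af, center = 500, S = 500)
  expect_true(all(wtd$values <= af$values + 1e-12))
  idx <- 251:1001
  expect_equal(which.max(af$values[idx]) + 249, 700)   # before weighting
  expect_equal(which.max(wtd$values[idx]) + 249, 490)  # after weighting
})

test_that("clean periodic envelopes are measured to within the lag quantum", {
  beats <- generate_beat_times(fhr_profile(20, 120))
  rec <- synthesize_us_signal(beats, us_sim_params(noise_sd = 0, drift = NULL))
  env <- envelope_hilbert(bandpass(rec, band_spec(300, 600)), 21)
  F <- measure_instantaneous(env, af_config(D_s = 1, K_ms = 25))
  expect_true(all(F$valid))
  expect_equal(sum(!F$valid), 0)
  expect_lte(abs(median(F$F_ms) - 500), 2)
  # noiseless free-running windows: exact to the 1-ms quantum except where
  # a burst straddles the window edge, which can bias the peak by ~2 ms
  expect_true(all(abs(F$F_ms - 500) <= 2))
  expect_gte(mean(abs(F$F_ms - 500) <= 1), 0.8)
  # timestamps strictly increasing by K
  expect_true(all(abs(diff(F$t_ms) - 25) < 1e-9))
})

test_that("degenerate envelopes produce loss markers, short ones a warning", {
  z <- fhr_envelope(numeric(5000))
  F <- measure_instantaneous(z, af_config())
  expect_true(all(!F$valid))
  expect_warning(out <- measure_instantaneous(fhr_envelope(numeric(500)),
                                              af_config()), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("validity is exactly the peak-amplitude threshold rule", {
  set.seed(12)
  beats <- generate_beat_times(fhr_profile(20, 120, stv_jitter_sd_ms = 5,
                                           seed = 2))
  env <- make_burst_envelope(beats$onsets_ms)
  env$values <- env$values + rnorm(length(env$values), 0, 0.3)
  env$values[env$values < 0] <- 0
  F <- measure_instantaneous(env, af_config(pf_enabled = FALSE))
  expect_equal(F$valid, F$af_peak >= 0.1)
})

test_that("without prediction each window is measured independently", {
  beats <- generate_beat_times(fhr_profile(20, 120, stv_jitter_sd_ms = 5,
                                           seed = 6))
  env <- make_burst_envelope(beats$onsets_ms)
  cfg <- af_config(pf_enabled = FALSE)
  full <- measure_instantaneous(env, cfg)
  # measuring from a later start reproduces the same per-window values
  late <- measure_instantaneous(env, cfg, start_ms = 1000)
  common <- intersect(full$t_ms, late$t_ms)
  expect_gt(length(common), 100)
  expect_equal(full$F_ms[match(common, full$t_ms)],
               late$F_ms[match(common, late$t_ms)])
})

test_that("a predicted interval does not move the prediction centre", {
  # strong 500-ms periodicity, then a corrupted stretch, then clean again:
  # during corruption the PF centre must stay at the last reliable period
  beats <- generate_beat_times(fhr_profile(30, 120))
  env <- make_burst_envelope(beats$onsets_ms)
  set.seed(3)
  bad <- env$t0 + seq(12000, 16000)
  env$values[bad] <- 0.3 * env$values[bad] +
    pmax(0, rnorm(length(bad), 0.3, 0.4))
  F <- measure_instantaneous(env, af_config())
  pred <- F$predicted
  if (any(pred)) {
    # predicted measurements stay inside the trapezoid support (+/- S/2)
    expect_true(all(abs(F$F_ms[pred] - 500) <= 250))
  }
  # after the corrupted stretch, measurements return to the true period
  tail_ok <- F$t_ms > 20000
  expect_lt(mean(abs(F$F_ms[tail_ok] - 500)), 3)
})
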