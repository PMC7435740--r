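#' Fetal heart rate profile for the simulator
#'
#' Describes the ground-truth FHR trajectory from which beat times are drawn:
#' a baseline rate, optional long-term-variability sinusoids, optional
#' acceleration/deceleration episodes (trapezoidal ramps), and beat-to-beat
#' Gaussian jitter modelling short-term variability.
#'
#' @param duration_s Signal duration in seconds (> 0).
#' @param baseline_bpm Baseline rate in bpm, within the physiological 60-240
#'   range.
#' @param stv_jitter_sd_ms SD in ms of the iid Gaussian jitter added to each
#'   interval (0 disables).
#' @param ltv_components List of `c(amplitude_bpm, frequency_hz)` sinusoids.
#' @param episodes List of `c(start_s, end_s, delta_bpm)` acceleration
#'   (positive delta) or deceleration (negative) ramps; each ramp rises/falls
#'   linearly over the first and last 20% of the episode.
#' @param seed RNG seed (NULL for the current RNG stream).
#' @return An object of class `fhr_profile`.
#' @export
fhr_profile <- function(duration_s, baseline_bpm = 120,
                        stv_jitter_sd_ms = 0,
                        ltv_components = list(),
                        episodes = list(), seed = NULL) {
  stopifnot(duration_s > 0, stv_jitter_sd_ms >= 0)
  if (baseline_bpm < 60 || baseline_bpm > 240)
    stop("fhr_profile: baseline must lie in the physiological 60-240 bpm range")
  structure(list(duration_s = duration_s, baseline_bpm = baseline_bpm,
                 stv_jitter_sd_ms = stv_jitter_sd_ms,
                 ltv_components = ltv_components,
                 episodes = episodes, seed = seed),
            class = "fhr_profile")
}

# instantaneous target rate in bpm at time t (ms)
profile_rate_bpm <- function(profile, t_ms) {
  t_s <- t_ms / 1000
  r <- rep(profile$baseline_bpm, length(t_s))
  for (cmp in profile$ltv_components)
    r <- r + cmp[1] * sin(2 * pi * cmp[2] * t_s)
  for (ep in profile$episodes) {
    len <- ep[2] - ep[1]
    ramp <- max(0.2 * len, 1e-9)
    w <- pmax(0, pmin(1, (t_s - ep[1]) / ramp)) *
      pmax(0, pmin(1, (ep[2] - t_s) / ramp))
    r <- r + ep[3] * w
  }
  r
}

#' Generate ground-truth beat times from an FHR profile
#'
#' Beats are laid down sequentially: each interval is 60000 / rate(t) ms at
#' the current onset time, plus iid Gaussian jitter. The result is the
#' simulator's ground truth, standing in for the direct-FECG R-wave times
#' against which the Doppler processing channel is scored.
#'
#' @param profile An [fhr_profile()].
#' @return An object of class `beat_train`: list with `onsets_ms` (strictly
#'   increasing beat-onset times covering `[0, duration]`) and `intervals_ms`.
#' @export
generate_beat_times <- function(profile) {
  stopifnot(inherits(profile, "fhr_profile"))
  dur_ms <- profile$duration_s * 1000
  with_local_seed(profile$seed, {
    onsets <- numeric(0)
    t <- 0
    repeat {
      onsets <- c(onsets, t)
      T_i <- 60000 / profile_rate_bpm(profile, t)
      if (profile$stv_jitter_sd_ms > 0)
        T_i <- T_i + stats::rnorm(1, 0, profile$stv_jitter_sd_ms)
      if (T_i <= 0)
        stop("generate_beat_times: profile yields a non-positive interval at t = ",
             round(t), " ms")
      t <- t + T_i
      if (t > dur_ms) break
    }
    intervals <- diff(onsets)
    if (length(intervals) &&
        (any(intervals < 250) || any(intervals > 1000)) &&
        length(profile$episodes) == 0 && length(profile$ltv_components) == 0 &&
        profile$stv_jitter_sd_ms == 0)
      warning("generate_beat_times: intervals outside the physiological 250-1000 ms range")
    structure(list(onsets_ms = onsets, intervals_ms = intervals),
              class = "beat_train")
  })
}

#' @export
print.beat_train <- function(x, ...) {
  cat(sprintf("<beat_train> %d beats over %.1f s, mean interval %.1f ms\n",
              length(x$onsets_ms), max(x$onsets_ms) / 1000,
              mean(x$intervals_ms)))
  invisible(x)
}

#' Default multi-phase cardiac burst configuration
#'
#' One row per cardiac phase observed in the Doppler echo: crescent (aortic)
#' valve opening/closing Ao/Ac and atrioventricular valve Mo/Mc lie in the
#' 300-600 Hz valve band; atrial wall contraction Atc and chamber wall motion
#' Vc lie in the 100-300 Hz wall band. Offsets place each burst as a fraction
#' of the cardiac cycle after the beat onset.
#'
#' @return Data frame with columns `name`, `offset_fraction`, `burst_ms`,
#'   `center_hz`, `amplitude`.
#' @export
default_us_phases <- function() {
  data.frame(
    name            = c("Mc",  "Vc",  "Ao",  "Ac",  "Mo",  "Atc"),
    offset_fraction = c(0.00,  0.05,  0.12,  0.35,  0.45,  0.90),
    burst_ms        = c(30,    60,    30,    30,    30,    60),
    center_hz       = c(400,   200,   480,   450,   420,   150),
    amplitude       = c(1.0,   0.7,   0.9,   0.8,   0.7,   0.5),
    stringsAsFactors = FALSE)
}

#' Simulation parameters for the Doppler waveform synthesizer
#'
#' @param fs Sampling rate in Hz (>= 1500; default 3000, five times the top of
#'   the 600 Hz valve band).
#' @param phases Data frame as returned by [default_us_phases()]. Valve phases
#'   (Ao, Ac, Mo, Mc) must have centre frequencies in 300-600 Hz, wall phases
#'   (Atc, Vc) in 100-300 Hz.
#' @param noise_sd Additive white Gaussian noise SD, relative to the maximum
#'   phase amplitude.
#' @param drift `c(depth, freq_hz)` slow sinusoidal amplitude modulation of
#'   the whole signal (depth in \[0,1)), or NULL.
#' @param interference List of `c(start_s, end_s)` movement-interference
#'   episodes: band-limited (10-80 Hz) noise bursts uncorrelated with beats.
#' @param interference_amp Amplitude of interference episodes relative to the
#'   maximum phase amplitude.
#' @param seed RNG seed for noise and interference.
#' @return An object of class `us_sim_params`.
#' @export
us_sim_params <- function(fs = 3000, phases = default_us_phases(),
                          noise_sd = 0.03, drift = c(0.3, 0.08),
                          interference = list(), interference_amp = 1.5,
                          seed = NULL) {
  stopifnot(fs >= 1500)
  valve <- phases$name %in% c("Ao", "Ac", "Mo", "Mc")
  wall  <- phases$name %in% c("Atc", "Vc")
  if (any(valve & (phases$center_hz < 300 | phases$center_hz > 600)))
    stop("us_sim_params: valve phases must have center_hz in [300, 600]")
  if (any(wall & (phases$center_hz < 100 | phases$center_hz > 300)))
    stop("us_sim_params: wall phases must have center_hz in [100, 300]")
  if (any(phases$offset_fraction < 0 | phases$offset_fraction >= 1))
    stop("us_sim_params: offset_fraction must lie in [0, 1)")
  structure(list(fs = fs, phases = phases, noise_sd = noise_sd,
                 drift = drift, interference = interference,
                 interference_amp = interference_amp, seed = seed),
            class = "us_sim_params")
}

#' Synthesize a raw Doppler ultrasound waveform from a beat train
#'
#' Each beat contributes one Gaussian-windowed sinusoidal burst per configured
#' cardiac phase, centred `offset_fraction * T_i` after the beat onset.
#' Amplitude drift, broadband noise and movement-interference episodes are
#' superimposed. Deterministic for a fixed seed.
#'
#' @param beats A `beat_train`.
#' @param params A [us_sim_params()].
#' @return A [us_record()] covering the span of the beat train.
#' @export
synthesize_us_signal <- function(beats, params = us_sim_params()) {
  stopifnot(inherits(beats, "beat_train"), inherits(params, "us_sim_params"))
  if (length(beats$onsets_ms) < 1L) stop("synthesize_us_signal: empty beat train")
  fs <- params$fs
  dur_ms <- max(beats$onsets_ms)
  n <- ceiling(dur_ms / 1000 * fs) + 1L
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  x <- numeric(n)

  intervals <- beats$intervals_ms
  if (length(intervals) == 0L) intervals <- 500
  if (max(params$phases$burst_ms) > min(intervals))
    warning("synthesize_us_signal: burst duration exceeds the shortest interval; phases overlap")

  n_on <- length(beats$onsets_ms)
  for (i in seq_len(n_on)) {
    T_i <- if (i <= length(beats$intervals_ms)) beats$intervals_ms[i]
           else intervals[length(intervals)]
    for (p in seq_len(nrow(params$phases))) {
      ph <- params$phases[p, ]
      centre <- beats$onsets_ms[i] + ph$offset_fraction * T_i
      sigma <- ph$burst_ms / 6  # +/- 3 sigma spans the nominal burst duration
      i0 <- max(1L, floor((centre - 4 * sigma) / 1000 * fs) + 1L)
      i1 <- min(n, ceiling((centre + 4 * sigma) / 1000 * fs) + 1L)
      if (i0 > i1) next
      tt <- t_ms[i0:i1] - centre
      x[i0:i1] <- x[i0:i1] + ph$amplitude *
        exp(-0.5 * (tt / sigma)^2) * sin(2 * pi * ph$center_hz * tt / 1000)
    }
  }

  if (!is.null(params$drift) && params$drift[1] > 0)
    x <- x * (1 + params$drift[1] * sin(2 * pi * params$drift[2] * t_ms / 1000))

  amax <- max(params$phases$amplitude)
  with_local_seed(params$seed, {
    if (params$noise_sd > 0)
      x <- x + stats::rnorm(n, 0, params$noise_sd * amax)
    for (ep in params$interference) {
      j0 <- max(1L, floor(ep[1] * fs) + 1L)
      j1 <- min(n, ceiling(ep[2] * fs))
      if (j0 >= j1) next
      raw <- stats::rnorm(j1 - j0 + 1L)
      bf <- signal::butter(4, c(10, 80) / (fs / 2), type = "pass")
      burst <- signal::filtfilt(bf, raw)
      burst <- burst / max(abs(burst)) * params$interference_amp * amax
      # taper the episode edges so it switches on and off smoothly
      m <- length(burst)
      ramp <- pmin(1, seq_len(m) / (0.1 * m), rev(seq_len(m)) / (0.1 * m))
      x[j0:j1] <- x[j0:j1] + burst * ramp
    }
    x
  })
  us_record(x, fs)
}

#' Convert a beat train to a reference event series
#'
#' Emits one event per complete interval: `tau_i = onset_i`,
#' `T_i = onset_{i+1} - onset_i`, all marked valid. This plays the role of
#' the FECG-derived reference series in the evaluation methodology.
#'
#' @param beats A `beat_train`.
#' @return A [beat_events()] with source `"reference"`.
#' @export
beats_to_reference <- function(beats) {
  stopifnot(inherits(beats, "beat_train"))
  n <- length(beats$onsets_ms)
  if (n < 2L) return(beat_events(source = "reference"))
  beat_events(tau_ms = beats$onsets_ms[-n], T_ms = diff(beats$onsets_ms),
              source = "reference")
}
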