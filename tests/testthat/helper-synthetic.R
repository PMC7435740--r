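# shared fixture builders (all generated in code; nothing on disk)

# jittered 120 bpm beat train + reference events
make_jittered_reference <- function(duration_s = 60, jitter_sd = 5, seed = 1,
                                    baseline = 120) {
  prof <- fhr_profile(duration_s, baseline, stv_jitter_sd_ms = jitter_sd,
                      seed = seed)
  beats <- generate_beat_times(prof)
  list(beats = beats, ref = beats_to_reference(beats))
}

# synthetic instant_measurements stream: F_j sampled every 25 ms from a
# piecewise-constant truth given by a beat train (plus optional noise)
make_measurement_stream <- function(beats, t_end_ms = NULL, noise_sd = 0,
                                    seed = NULL, K_ms = 25) {
  tau <- beats$onsets_ms
  T_v <- beats$intervals_ms
  if (is.null(t_end_ms)) t_end_ms <- max(tau)
  t <- seq(0, t_end_ms, by = K_ms)
  k <- findInterval(t, tau[-length(tau)])
  k[k < 1] <- 1
  F_vals <- T_v[pmin(k, length(T_v))]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    F_vals <- F_vals + rnorm(length(F_vals), 0, noise_sd)
  }
  out <- data.frame(t_ms = t, F_ms = F_vals, af_peak = 0.9,
                    predicted = FALSE, valid = TRUE)
  class(out) <- c("instant_measurements", "data.frame")
  attr(out, "K_ms") <- K_ms
  out
}

# constant-valued measurement stream
make_constant_stream <- function(F_ms = 500, n = 200, K_ms = 25,
                                 valid = rep(TRUE, n)) {
  out <- data.frame(t_ms = seq(0, by = K_ms, length.out = n),
                    F_ms = rep(F_ms, length.out = n),
                    af_peak = rep(0.9, n),
                    predicted = rep(FALSE, n), valid = valid)
  class(out) <- c("instant_measurements", "data.frame")
  attr(out, "K_ms") <- K_ms
  out
}

# even 250-ms series from raw values (NA = loss)
make_even_series <- function(values, t0 = 0) {
  structure(list(t0_ms = t0, step_ms = 250, values_ms = values),
            class = "even_series")
}

# synthetic 1-kHz envelope: one Gaussian bump per beat
make_burst_envelope <- function(onsets_ms, t_end_ms = max(onsets_ms) + 500,
                                width_ms = 10, rate = 1000) {
  t <- seq(0, t_end_ms, by = 1000 / rate)
  v <- numeric(length(t))
  for (c0 in onsets_ms)
    v <- v + exp(-0.5 * ((t - c0) / width_ms)^2)
  fhr_envelope(v, rate = rate)
}

# events with uniform interval T
make_uniform_events <- function(T_ms = 500, n = 100, t0 = 0, source = "reference") {
  beat_events(tau_ms = t0 + (seq_len(n) - 1) * T_ms,
              T_ms = rep(T_ms, n), source = source)
}

# events from explicit interval values laid end to end
events_from_T <- function(T_ms, t0 = 0, source = "reference") {
  beat_events(tau_ms = t0 + cumsum(c(0, T_ms[-length(T_ms)])),
              T_ms = T_ms, source = source)
}
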