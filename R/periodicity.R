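#' Configuration of the windowed autocorrelation periodicity estimator
#'
#' @param D_s Autocorrelation window width in seconds (0.8, 1, 1.5, 2 or 3).
#' @param K_ms Repetition step in ms between successive windows (25 or 250).
#' @param lag_range_ms Search range for the period in ms; default the
#'   physiological 250-1000 ms (60-240 bpm). The wide legacy range
#'   `c(30, 2000)` is accepted for no-prediction replication runs.
#' @param P_TH Peak-amplitude threshold below which a measurement is marked
#'   as signal loss (default 0.1).
#' @param pf_enabled Use the trapezoidal prediction function when the peak is
#'   weak.
#' @param S_ms Lower-base width of the trapezoidal prediction window in ms
#'   (125, 250 or 500).
#' @param pf_gate AF peak amplitude below which the prediction function is
#'   engaged (default 0.5).
#' @return Object of class `af_config`.
#' @export
af_config <- function(D_s = 1, K_ms = 25, lag_range_ms = c(250, 1000),
                      P_TH = 0.1, pf_enabled = TRUE, S_ms = 500,
                      pf_gate = 0.5) {
  stopifnot(D_s > 0, K_ms > 0, length(lag_range_ms) == 2L,
            lag_range_ms[1] > 0, lag_range_ms[1] < lag_range_ms[2],
            P_TH > 0, P_TH < pf_gate, pf_gate < 1, S_ms > 0)
  structure(list(D_s = D_s, K_ms = K_ms, lag_range_ms = lag_range_ms,
                 P_TH = P_TH, pf_enabled = pf_enabled, S_ms = S_ms,
                 pf_gate = pf_gate),
            class = "af_config")
}

#' Normalized autocorrelation of an envelope window
#'
#' Mean-removed, biased (divide-by-n) autocorrelation normalized by its
#' zero-lag value, so `af(0) = 1` and the 0.1 / 0.5 absolute amplitude
#' thresholds are meaningful. Computed via FFT.
#'
#' @param window Numeric vector (one envelope window at the envelope rate).
#' @param max_lag Largest lag (in samples) to return.
#' @return List with `lags` (0..max_lag, in samples = ms at 1 kHz) and
#'   `values`, or NULL if the window is all-constant (undefined AF, signal
#'   loss).
#' @export
autocorrelation <- function(window, max_lag = length(window) - 1L) {
  n <- length(window)
  stopifnot(n >= 2L, max_lag < n)
  x <- window - mean(window)
  if (all(abs(x) < .Machine$double.eps * max(1, max(abs(window))) * n))
    return(NULL)
  nfft <- 2^ceiling(log2(2L * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1L)] / nfft
  list(lags = 0:max_lag, values = r / r[1])
}

#' Trapezoidal prediction-function weighting
#'
#' Pointwise multiplies an AF curve by a trapezoid centred on the last
#' reliably determined interval: weight 1 on the plateau (upper base = S/4),
#' linear flanks down to 0 at the lower-base edges (lower base = S, base
#' ratio 1:4), and 0 outside. The weighting never increases the AF.
#'
#' @param af List with `lags` and `values` as from [autocorrelation()].
#' @param center_ms Centre of the trapezoid in ms (the last reliable period).
#' @param S_ms Lower-base width in ms.
#' @return The weighted AF curve (same structure).
#' @export
trapezoidal_pf <- function(af, center_ms, S_ms) {
  stopifnot(S_ms > 0)
  w <- trapezoid_weight(af$lags, center_ms, S_ms)
  list(lags = af$lags, values = af$values * w)
}

trapezoid_weight <- function(tau, center, S) {
  d <- abs(tau - center)
  w <- numeric(length(tau))
  w[d <= S / 8] <- 1
  flank <- d > S / 8 & d < S / 2
  w[flank] <- (S / 2 - d[flank]) / (S / 2 - S / 8)
  w
}

#' Instantaneous periodicity measurements from an envelope
#'
#' Slides a window of width `D` over the envelope with hop `K`. Each window
#' yields one measurement `F_j`: the lag of the global AF maximum within the
#' search range. If the peak amplitude is below `P_TH` the measurement is a
#' loss marker. If the prediction function is enabled and the peak amplitude
#' is below `pf_gate`, the AF is re-weighted by the trapezoid centred on the
#' last reliable (non-predicted) period before taking the argmax, and the
#' measurement is flagged `predicted`; a predicted interval does not move the
#' trapezoid centre for later windows. Ties in the argmax break toward the
#' shorter lag, which avoids half-rate doubling errors on smooth wall
#' envelopes. The search lag is additionally capped at `D*1000 - 200` ms so
#' each lag keeps at least 200 ms of overlap support. Measurements are
#' stamped at the window end.
#'
#' @param env A [fhr_envelope()] at 1 kHz.
#' @param cfg An [af_config()].
#' @param start_ms Analysis starting point P in ms (default 0): the first
#'   window is `[start_ms, start_ms + D)`.
#' @return Data frame of class `instant_measurements` with columns `t_ms`,
#'   `F_ms`, `af_peak`, `predicted`, `valid`.
#' @export
measure_instantaneous <- function(env, cfg = af_config(), start_ms = 0) {
  stopifnot(inherits(env, "fhr_envelope"), inherits(cfg, "af_config"))
  rate <- env$rate
  Dn <- round(cfg$D_s * rate)
  Kn <- round(cfg$K_ms * rate / 1000)
  n <- length(env$values)
  i0 <- max(1L, round(start_ms * rate / 1000) + 1L)
  if (n - i0 + 1L < Dn) {
    warning("measure_instantaneous: envelope shorter than the AF window")
    return(empty_measurements())
  }
  lag_lo <- round(cfg$lag_range_ms[1] * rate / 1000)
  lag_hi <- min(round(cfg$lag_range_ms[2] * rate / 1000),
                Dn - round(200 * rate / 1000))
  if (lag_hi <= lag_lo)
    stop("measure_instantaneous: AF window too short for the lag search range")

  starts <- seq.int(i0, n - Dn + 1L, by = Kn)
  m <- length(starts)
  t_ms <- F_ms <- af_peak <- numeric(m)
  predicted <- valid <- logical(m)
  pf_center <- NA_real_  # last valid period that was not itself predicted

  for (j in seq_len(m)) {
    s <- starts[j]
    t_ms[j] <- env$t0 + (s - 1L + Dn) * 1000 / rate
    af <- autocorrelation(env$values[s:(s + Dn - 1L)], max_lag = lag_hi)
    if (is.null(af)) { valid[j] <- FALSE; F_ms[j] <- NA_real_; next }
    idx <- (lag_lo:lag_hi) + 1L
    vals <- af$values[idx]
    k <- which.max(vals)  # first max: tie broken toward the shorter lag
    peak <- vals[k]
    af_peak[j] <- peak
    if (peak < cfg$P_TH) { valid[j] <- FALSE; F_ms[j] <- NA_real_; next }
    lag <- (lag_lo + k - 1L) * 1000 / rate
    if (cfg$pf_enabled && peak < cfg$pf_gate && !is.na(pf_center)) {
      w <- trapezoid_weight((lag_lo:lag_hi) * 1000 / rate, pf_center, cfg$S_ms)
      k2 <- which.max(vals * w)
      lag <- (lag_lo + k2 - 1L) * 1000 / rate
      predicted[j] <- TRUE
    }
    F_ms[j] <- lag
    valid[j] <- TRUE
    if (!predicted[j]) pf_center <- lag
  }
  out <- data.frame(t_ms = t_ms, F_ms = F_ms, af_peak = af_peak,
                    predicted = predicted, valid = valid)
  class(out) <- c("instant_measurements", "data.frame")
  attr(out, "K_ms") <- cfg$K_ms
  out
}

empty_measurements <- function(K_ms = 25) {
  out <- data.frame(t_ms = numeric(0), F_ms = numeric(0),
                    af_peak = numeric(0), predicted = logical(0),
                    valid = logical(0))
  class(out) <- c("instant_measurements", "data.frame")
  attr(out, "K_ms") <- K_ms
  out
}

#' @export
print.instant_measurements <- function(x, ...) {
  cat(sprintf("<instant_measurements> %d windows every %g ms, %d invalid",
              nrow(x), attr(x, "K_ms"), sum(!x$valid)))
  if (any(x$valid))
    cat(sprintf(", median F %.0f ms", stats::median(x$F_ms[x$valid])))
  cat("\n")
  invisible(x)
}
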