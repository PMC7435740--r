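#' Band specification for Doppler component separation
#'
#' The standard bands are (100, 300) Hz for heart-wall movements, (300, 600)
#' Hz for valve movements, and (100, 600) Hz for the full informative band.
#'
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), low > 0, high > low)
  structure(list(low = low, high = high), class = "band_spec")
}

#' Zero-phase band-pass filtering of a Doppler record
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' band separation does not shift beat timing. Output has the same length and
#' sampling rate as the input.
#'
#' @param record A [us_record()].
#' @param band A [band_spec()]; `high` must lie below the Nyquist rate.
#' @return A filtered [us_record()].
#' @export
bandpass <- function(record, band = band_spec(300, 600)) {
  stopifnot(inherits(record, "us_record"), inherits(band, "band_spec"))
  if (band$high >= record$fs / 2)
    stop("bandpass: band edge ", band$high, " Hz infeasible at fs = ",
         record$fs, " Hz")
  bf <- signal::butter(4, c(band$low, band$high) / (record$fs / 2),
                       type = "pass")
  us_record(signal::filtfilt(bf, record$samples), record$fs)
}

# linear resampling onto the fixed 1 kHz envelope grid
resample_to_envelope_rate <- function(values, fs, rate = 1000) {
  n <- length(values)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  grid <- seq(0, t_ms[n], by = 1000 / rate)
  stats::approx(t_ms, values, xout = grid, rule = 2)$y
}

#' Envelope by rectification and low-pass filtering
#'
#' Converts the bipolar Doppler signal into a unipolar one with a module
#' (absolute value) function, smooths with a zero-phase 4th-order Butterworth
#' low-pass at `cutoff` Hz (skipped when `cutoff` is NULL), then resamples to
#' the fixed 1 kHz envelope rate. Undershoot from filtering is clipped to 0.
#'
#' @param record A [us_record()] (typically band-passed first).
#' @param cutoff Low-pass cutoff in Hz, one of 25, 50, 75, 100, 150, or NULL
#'   for no additional filtering.
#' @return A [fhr_envelope()] at 1 kHz.
#' @export
envelope_rectify_lowpass <- function(record, cutoff = 50) {
  stopifnot(inherits(record, "us_record"))
  if (!is.null(cutoff) && !cutoff %in% c(25, 50, 75, 100, 150))
    stop("envelope_rectify_lowpass: cutoff must be NULL or one of 25, 50, 75, 100, 150 Hz")
  x <- abs(record$samples)
  if (!is.null(cutoff)) {
    lf <- signal::butter(4, cutoff / (record$fs / 2), type = "low")
    x <- signal::filtfilt(lf, x)
  }
  fhr_envelope(resample_to_envelope_rate(x, record$fs))
}

# analytic signal via the frequency-domain construction: zero the negative
# frequencies, double the positive ones (no in-package alternative exists)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Envelope by Hilbert transform
#'
#' Magnitude of the analytic signal, optionally smoothed with a centred
#' moving average of `ma_len` raw samples (11 or 21), then resampled to the
#' fixed 1 kHz envelope rate. The moving average tames the high variability
#' of the Hilbert envelope in fragments of high signal dynamics.
#'
#' @param record A [us_record()].
#' @param ma_len NULL (no smoothing), 11 or 21 samples at the raw rate.
#' @return A [fhr_envelope()] at 1 kHz.
#' @export
envelope_hilbert <- function(record, ma_len = 21) {
  stopifnot(inherits(record, "us_record"))
  if (!is.null(ma_len) && !ma_len %in% c(11, 21))
    stop("envelope_hilbert: ma_len must be NULL, 11 or 21 samples")
  x <- Mod(analytic_signal(record$samples))
  if (!is.null(ma_len))
    x <- as.numeric(stats::filter(x, rep(1 / ma_len, ma_len), sides = 2))
  x[is.na(x)] <- 0  # centred MA is undefined at the edges
  fhr_envelope(resample_to_envelope_rate(x, record$fs))
}
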