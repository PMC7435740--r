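#' Sampled Doppler ultrasound record
#'
#' Container for a single-channel demodulated Doppler ultrasound waveform.
#' The audio-band signal carries the velocities of the fetal heart structures:
#' wall movements occupy roughly 100-300 Hz, valve movements 300-600 Hz.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz.
#' @return An object of class `us_record` with elements `samples`, `fs` and
#'   `duration` (seconds).
#' @export
us_record <- function(samples, fs) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!all(is.finite(samples))) stop("us_record: samples must be finite")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 duration = length(samples) / fs),
            class = "us_record")
}

#' @export
print.us_record <- function(x, ...) {
  cat(sprintf("<us_record> %d samples @ %g Hz (%.2f s), range [%.3g, %.3g]\n",
              length(x$samples), x$fs, x$duration,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Unipolar envelope at a fixed envelope rate
#'
#' Non-negative envelope sequence resampled to `rate` Hz (1 kHz by default so
#' that one autocorrelation lag corresponds to 1 ms). `t0` is the time (ms) of
#' the first envelope sample relative to the start of the source record.
#'
#' @param values Non-negative numeric vector.
#' @param rate Envelope rate in Hz (fixed at 1000 in the processing channel).
#' @param t0 Alignment offset in ms.
#' @return An object of class `fhr_envelope`.
#' @export
fhr_envelope <- function(values, rate = 1000, t0 = 0) {
  stopifnot(is.numeric(values), rate > 0)
  values <- as.numeric(values)
  values[values < 0] <- 0  # envelope is a magnitude by definition
  structure(list(values = values, rate = rate, t0 = t0),
            class = "fhr_envelope")
}

#' @export
print.fhr_envelope <- function(x, ...) {
  cat(sprintf("<fhr_envelope> %d samples @ %g Hz, t0 = %g ms, max %.3g\n",
              length(x$values), x$rate, x$t0, max(x$values)))
  invisible(x)
}

#' Beat event series
#'
#' The channel's central output format: one measurement per cardiac interval.
#' Each event is a pair (tau_ms, T_ms): interval start time and interval
#' duration, both in milliseconds, plus a validity flag (FALSE marks signal
#' loss / rejected artifacts).
#'
#' @param tau_ms Strictly increasing event start times in ms.
#' @param T_ms Interval durations in ms (> 0 for valid events).
#' @param valid Logical vector of validity flags (default all TRUE).
#' @param source One of `"reference"`, `"d1"`, `"d2"`, `"monitor"`.
#' @return A data frame of class `beat_events` with columns
#'   `tau_ms`, `T_ms`, `valid` and attribute `source`.
#' @export
beat_events <- function(tau_ms = numeric(0), T_ms = numeric(0),
                        valid = rep(TRUE, length(tau_ms)),
                        source = "reference") {
  stopifnot(length(tau_ms) == length(T_ms), length(valid) == length(tau_ms))
  source <- match.arg(source, c("reference", "d1", "d2", "monitor"))
  if (length(tau_ms) > 1L && any(diff(tau_ms) <= 0))
    stop("beat_events: tau_ms must be strictly increasing")
  if (any(valid & T_ms <= 0))
    stop("beat_events: valid events must have T_ms > 0")
  out <- data.frame(tau_ms = as.numeric(tau_ms), T_ms = as.numeric(T_ms),
                    valid = as.logical(valid))
  class(out) <- c("beat_events", "data.frame")
  attr(out, "source") <- source
  out
}

#' @export
print.beat_events <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<beat_events:%s> %d events", attr(x, "source"), n))
  if (n > 0) {
    v <- x$T_ms[x$valid]
    cat(sprintf(", span %.0f ms, median T %.1f ms, %d invalid",
                x$tau_ms[n] + x$T_ms[n] - x$tau_ms[1],
                stats::median(v), sum(!x$valid)))
  }
  cat("\n")
  invisible(x)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate expr with a temporarily-seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
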