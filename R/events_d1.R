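#' Collapse 25-ms instantaneous measurements to a 250-ms series
#'
#' Method D1 first forms the monitor-standard evenly spaced series: every
#' 250-ms slot takes the median of its 10 constituent 25-ms measurements
#' `F_j` (or passes the measurement through when the stream is already at
#' 250 ms). A slot becomes a loss marker when more than half of its
#' measurements are invalid. Slot values are quantized to the 0.25 bpm
#' monitor resolution so that duplicated measurements repeat exactly.
#'
#' @param F An `instant_measurements` data frame (K = 25 or 250 ms).
#' @param quantize_bpm Output quantization step in bpm (0.25 as in monitor
#'   outputs; NULL disables).
#' @return Object of class `even_series`: list with `t0_ms`, `step_ms` (250)
#'   and `values_ms` (period in ms, NA = loss marker).
#' @export
median_fhr_250 <- function(F, quantize_bpm = 0.25) {
  stopifnot(inherits(F, "instant_measurements"))
  K <- attr(F, "K_ms")
  if (nrow(F) == 0L)
    return(structure(list(t0_ms = 0, step_ms = 250, values_ms = numeric(0)),
                     class = "even_series"))
  if (K == 250) {
    vals <- ifelse(F$valid, F$F_ms, NA_real_)
    t0 <- F$t_ms[1]
  } else if (K == 25) {
    n_slots <- nrow(F) %/% 10L
    vals <- rep(NA_real_, n_slots)
    for (s in seq_len(n_slots)) {
      block <- F[((s - 1L) * 10L + 1L):(s * 10L), ]
      if (sum(!block$valid) > 5L) next  # loss slot
      vals[s] <- stats::median(block$F_ms[block$valid])
    }
    t0 <- F$t_ms[10L] # first slot is represented by its last measurement
  } else stop("median_fhr_250: measurement step must be 25 or 250 ms")
  if (!is.null(quantize_bpm)) {
    ok <- !is.na(vals) & vals > 0
    vals[ok] <- 60000 / (round_half_up(60000 / vals[ok] / quantize_bpm) *
                           quantize_bpm)
  }
  structure(list(t0_ms = t0, step_ms = 250, values_ms = vals),
            class = "even_series")
}

#' @export
print.even_series <- function(x, ...) {
  cat(sprintf("<even_series> %d slots every %g ms from t0 = %g ms, %d loss\n",
              length(x$values_ms), x$step_ms, x$t0_ms, sum(is.na(x$values_ms))))
  invisible(x)
}

# number of events a run of n equal slots of value T represents:
# Min/Max bracket the count; agreement after rounding is the unique answer,
# otherwise the most probable count round(n*step/T) is used (at least 1)
run_event_count <- function(n, T, step = 250) {
  if (T <= 0) return(0L)
  mn <- round_half_up((n - 1) * step / T)
  mx <- round_half_up((n + 1) * step / T)
  k <- if (mn == mx) mn else round_half_up(n * step / T)
  max(1L, as.integer(k))
}

#' Duplicate-measurement correction (method D1)
#'
#' Converts the evenly spaced 250-ms series into a time series of events.
#' The series is partitioned into maximal runs of identical values (loss
#' markers break runs); a run of `n` slots of value `T` is bracketed by
#' `Min = (n-1)*250/T` and `Max = (n+1)*250/T` candidate interval counts.
#' If the rounded `Min` and `Max` agree, that count is the only consistent
#' solution; otherwise the most probable count `round(n*250/T)` is emitted.
#' Events are laid consecutively from the run start.
#'
#' @param series An `even_series` from [median_fhr_250()].
#' @return A [beat_events()] with source `"d1"`.
#' @export
correct_duplicates <- function(series) {
  stopifnot(inherits(series, "even_series"))
  v <- series$values_ms
  if (!any(!is.na(v) & v > 0))
    return(beat_events(source = "d1"))
  v[!is.na(v) & v <= 0] <- NA_real_  # unusable slot treated as loss
  # run-length partition; NA never equals anything, so loss breaks runs
  grp <- cumsum(c(TRUE, is.na(v[-1]) | is.na(v[-length(v)]) |
                    v[-1] != v[-length(v)]))
  tau <- T_out <- numeric(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    T_run <- v[idx[1]]
    if (is.na(T_run)) next
    k <- run_event_count(length(idx), T_run, series$step_ms)
    start <- series$t0_ms + (idx[1] - 1L) * series$step_ms
    tau <- c(tau, start + (seq_len(k) - 1L) * T_run)
    T_out <- c(T_out, rep(T_run, k))
  }
  keep <- c(diff(tau) > 0, TRUE)  # adjacent runs may overlap after layout
  beat_events(tau_ms = tau[keep], T_ms = T_out[keep], source = "d1")
}
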