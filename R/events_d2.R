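#' RMS-based starting point for segmentation
#'
#' Computes the RMS of the envelope in a sliding window (1 ms step) over the
#' first three seconds, locates the RMS maximum, then walks backward from the
#' maximum: the starting point P is the first position at which the RMS drops
#' below 2/3 of the maximum. If it never drops (flat envelope) P = 0.
#' Anchoring the first segment just before a strong cardiac burst makes the
#' segment phase consistent with the underlying cardiac cycles.
#'
#' @param env A [fhr_envelope()] at 1 kHz, at least 3 s long.
#' @param window_ms RMS window width in ms (100, 200, 250, 500 or 1000).
#' @return Starting point P in ms.
#' @export
find_starting_point <- function(env, window_ms = 500) {
  stopifnot(inherits(env, "fhr_envelope"))
  if (!window_ms %in% c(100, 200, 250, 500, 1000))
    stop("find_starting_point: window_ms must be one of 100, 200, 250, 500, 1000")
  rate <- env$rate
  n3 <- min(length(env$values), round(3 * rate))
  if (n3 < round(3 * rate)) {
    warning("find_starting_point: envelope shorter than 3 s; P = 0")
    return(0)
  }
  w <- round(window_ms * rate / 1000)
  x2 <- env$values[1:n3]^2
  cs <- cumsum(c(0, x2))
  m <- n3 - w + 1L
  rms <- sqrt((cs[(w + 1L):(w + m)] - cs[1:m]) / w)  # rms[i] over [i, i+w-1]
  peak <- which.max(rms)
  below <- which(rms[seq_len(peak)] < (2 / 3) * rms[peak])
  if (length(below) == 0L) return(0)
  p_idx <- max(below)  # first drop when walking backward from the maximum
  env$t0 + (p_idx - 1L) * 1000 / rate
}

#' Segmentation of instantaneous measurements (method D2, no matching)
#'
#' Accumulates consecutive valid measurements `F_j` while maintaining their
#' running median `m`; as soon as the accumulated time `n * 25 ms` exceeds
#' `m`, the median is emitted as the interval `T_i` with `tau_i` at the
#' segment start, and accumulation restarts. Invalid measurements close the
#' current segment as a loss gap.
#'
#' @param F An `instant_measurements` data frame at 25 ms steps.
#' @param P Starting point in ms (from [find_starting_point()]); analysis
#'   begins at the first measurement with `t >= P`.
#' @return A [beat_events()] with source `"d2"`.
#' @export
segment_measurements <- function(F, P = 0) {
  stopifnot(inherits(F, "instant_measurements"))
  K <- attr(F, "K_ms")
  F <- F[F$t_ms >= P, , drop = FALSE]
  tau <- T_out <- numeric(0)
  buf <- numeric(0)
  seg_start <- NA_real_
  for (j in seq_len(nrow(F))) {
    if (!F$valid[j]) { buf <- numeric(0); seg_start <- NA_real_; next }
    if (is.na(seg_start)) seg_start <- F$t_ms[j]
    buf <- c(buf, F$F_ms[j])
    med <- stats::median(buf)
    if (length(buf) * K > med) {
      tau <- c(tau, seg_start)
      T_out <- c(T_out, med)
      buf <- numeric(0)
      seg_start <- NA_real_
    }
  }
  if (length(tau) > 1L) {
    keep <- c(TRUE, diff(tau) > 0)
    tau <- tau[keep]; T_out <- T_out[keep]
  }
  beat_events(tau_ms = tau, T_ms = T_out, source = "d2")
}

# mean absolute difference between each valid F_j and the T value of the
# (shifted) interval containing it; NA when no F falls into any interval
maa_shift_score <- function(t_f, F_vals, tau, T_vals, shift) {
  lo <- tau + shift
  hi <- tau + T_vals + shift
  k <- findInterval(t_f, lo)
  ok <- k >= 1L & t_f < hi[pmax(k, 1L)]
  if (!any(ok)) return(NA_real_)
  mean(abs(F_vals[ok] - T_vals[k[ok]]))
}

#' Segmentation with the matching algorithm (method D2 + MAA)
#'
#' On-line variant in which each segment window is bounded by the previously
#' determined interval: segment `i` spans `[tau_i, tau_i + T_{i-1})` and
#' emits `T_i` as the median of the valid measurements inside it. After each
#' emission the matching algorithm scores the agreement between the last (up
#' to) seven intervals and the measurement stream for timestamp shifts of
#' `-gamma, 0, +gamma` (gamma = 25 ms, the measurement repetition step). If
#' the minimum mean absolute difference occurs at a nonzero shift, the next
#' timestamp is nudged by the correction quantum `|epsilon| = gamma/5 = 5 ms`
#' toward the winning shift: `tau_{i+1} = tau_i + T_{i-1} - epsilon`. The
#' `T` values themselves are never altered by the matching.
#'
#' The first interval is bootstrapped with the running-median accumulation
#' rule of [segment_measurements()].
#'
#' @param F An `instant_measurements` data frame at 25 ms steps.
#' @param P Starting point in ms.
#' @param maa_depth Number of recent intervals scored by the matching
#'   algorithm (7).
#' @param audit If TRUE, attach an attribute `audit` with per-event shift
#'   scores and applied corrections.
#' @return A [beat_events()] with source `"d2"`.
#' @export
segment_with_maa <- function(F, P = 0, maa_depth = 7, audit = FALSE) {
  stopifnot(inherits(F, "instant_measurements"))
  K <- attr(F, "K_ms")
  gamma <- K
  eps_q <- gamma / 5
  Fv <- F[F$t_ms >= P & F$valid, , drop = FALSE]
  if (nrow(Fv) == 0L) return(beat_events(source = "d2"))
  t_f <- Fv$t_ms
  F_vals <- Fv$F_ms
  t_end <- max(t_f)

  tau <- T_out <- numeric(0)
  log_eps <- numeric(0)

  # bootstrap: running-median rule for the first interval
  j0 <- 1L
  buf <- numeric(0)
  while (j0 <= length(F_vals)) {
    buf <- c(buf, F_vals[j0])
    if (length(buf) * K > stats::median(buf)) break
    j0 <- j0 + 1L
  }
  if (length(buf) == 0L || length(buf) * K <= stats::median(buf))
    return(beat_events(source = "d2"))
  tau <- t_f[1]
  T_out <- stats::median(buf)
  log_eps <- 0

  cur <- tau + T_out  # next segment start; previous width = T_out
  prev_T <- T_out
  repeat {
    if (cur + prev_T > t_end + K) break
    inseg <- t_f >= cur & t_f < cur + prev_T
    if (!any(inseg)) {
      # loss gap: no usable measurements in this window; skip ahead
      nxt <- t_f[t_f >= cur + prev_T]
      if (length(nxt) == 0L) break
      cur <- nxt[1]
      next
    }
    T_i <- stats::median(F_vals[inseg])
    tau <- c(tau, cur)
    T_out <- c(T_out, T_i)
    n_ev <- length(tau)
    # matching over the last maa_depth intervals
    win <- max(1L, n_ev - maa_depth + 1L):n_ev
    scores <- vapply(c(-gamma, 0, gamma), function(s)
      maa_shift_score(t_f, F_vals, tau[win], T_out[win], s), numeric(1))
    eps <- 0
    if (!anyNA(scores)) {
      best <- which.min(scores)
      if (best != 2L && scores[best] < scores[2L])
        eps <- -sign(c(-gamma, 0, gamma)[best]) * eps_q
    }
    log_eps <- c(log_eps, eps)
    cur <- cur + prev_T - eps
    prev_T <- T_i
  }
  out <- beat_events(tau_ms = tau, T_ms = T_out, source = "d2")
  if (audit) attr(out, "audit") <- data.frame(tau_ms = tau, eps_ms = log_eps)
  out
}

#' Extract a D2 event series from instantaneous measurements
#'
#' Convenience wrapper choosing between plain segmentation and segmentation
#' with the matching algorithm.
#'
#' @param F An `instant_measurements` data frame at 25 ms steps.
#' @param P Starting point in ms.
#' @param maa Apply the matching algorithm (default TRUE).
#' @param ... Passed on to [segment_with_maa()].
#' @return A [beat_events()] with source `"d2"`.
#' @export
extract_events_d2 <- function(F, P = 0, maa = TRUE, ...) {
  if (maa) segment_with_maa(F, P, ...) else segment_measurements(F, P)
}

#' One matching-algorithm scoring step
#'
#' Scores the agreement between a set of recent intervals and the
#' measurement stream for timestamp shifts `-gamma, 0, +gamma` and returns
#' the correction coefficient epsilon that the matching algorithm would
#' apply: 0 when no shift improves the match, otherwise `gamma/5` in
#' magnitude, signed to move the timestamps toward the winning shift.
#'
#' @param F An `instant_measurements` data frame.
#' @param events A [beat_events()] series (the most recent up-to-7 intervals
#'   are scored).
#' @param gamma Measurement repetition step in ms (25).
#' @param maa_depth Number of recent intervals scored (7).
#' @return List with `eps_ms` and the three `scores` (shift -gamma, 0,
#'   +gamma).
#' @export
maa_step <- function(F, events, gamma = 25, maa_depth = 7) {
  stopifnot(inherits(F, "instant_measurements"), inherits(events, "beat_events"))
  Fv <- F[F$valid, , drop = FALSE]
  n <- nrow(events)
  win <- max(1L, n - maa_depth + 1L):n
  shifts <- c(-gamma, 0, gamma)
  scores <- vapply(shifts, function(s)
    maa_shift_score(Fv$t_ms, Fv$F_ms, events$tau_ms[win], events$T_ms[win], s),
    numeric(1))
  eps <- 0
  if (!anyNA(scores)) {
    best <- which.min(scores)
    if (best != 2L && scores[best] < scores[2L])
      eps <- -sign(shifts[best]) * gamma / 5
  }
  list(eps_ms = eps, scores = scores)
}

#' Re-time an event series with the matching algorithm
#'
#' Batch application of the iterative matching rule to an already-extracted
#' event series: the first timestamp is kept; each subsequent timestamp is
#' laid as `tau_{i+1} = tau_i + T_{i-1} - epsilon_i`, with `epsilon_i`
#' determined by [maa_step()] on the series as corrected so far. Interval
#' values `T` are never changed.
#'
#' @param F An `instant_measurements` data frame.
#' @param events A [beat_events()] series.
#' @param gamma Measurement repetition step in ms (25).
#' @param maa_depth Number of recent intervals scored (7).
#' @return The events with corrected timestamps; attribute `eps_ms` records
#'   the per-step corrections.
#' @export
matching_correction <- function(F, events, gamma = 25, maa_depth = 7) {
  stopifnot(inherits(events, "beat_events"))
  n <- nrow(events)
  if (n < 2L) return(events)
  tau <- events$tau_ms
  T_v <- events$T_ms
  eps_log <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    cur <- beat_events(tau_ms = tau[1:i], T_ms = T_v[1:i],
                       valid = events$valid[1:i], source = attr(events, "source"))
    st <- maa_step(F, cur, gamma = gamma, maa_depth = maa_depth)
    eps_log[i] <- st$eps_ms
    prev_T <- if (i >= 2L) T_v[i - 1L] else T_v[i]
    tau[i + 1L] <- tau[i] + prev_T - st$eps_ms
  }
  out <- beat_events(tau_ms = tau, T_ms = T_v, valid = events$valid,
                     source = attr(events, "source"))
  attr(out, "eps_ms") <- eps_log
  out
}
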