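#' Interval-to-rate conversion
#'
#' The instantaneous fetal heart rate in beats per minute corresponding to an
#' inter-beat interval `T` in milliseconds: `FHR = 60000 / T`. The
#' physiological 60-240 bpm range corresponds to intervals of 1000 down to
#' 250 ms.
#'
#' @param T_ms Interval(s) in ms, all > 0.
#' @return Rate(s) in bpm.
#' @export
fhr_from_interval <- function(T_ms) {
  if (any(T_ms <= 0)) stop("fhr_from_interval: intervals must be positive")
  60000 / T_ms
}

# sample a test event series at given times: returns the T of the valid
# interval containing each time, NA where none (loss or no coverage)
sample_events_at <- function(events, t_ms) {
  if (nrow(events) == 0L) return(rep(NA_real_, length(t_ms)))
  k <- findInterval(t_ms, events$tau_ms)
  out <- rep(NA_real_, length(t_ms))
  ok <- k >= 1L
  kk <- k[ok]
  inside <- t_ms[ok] < events$tau_ms[kk] + events$T_ms[kk] & events$valid[kk]
  out[ok][inside] <- events$T_ms[kk][inside]
  out
}

#' Synchronize a test event series against a reference
#'
#' Finds the displacement of the test series relative to the reference
#' (positive shift = test events lag the reference) by scanning
#' `-3000..+3000` ms in 1 ms steps. The objective minimized is the
#' time-integrated `|T_test(t) - T_ref(t)|` over the 5-55 s analysis window:
#' the two interval step functions are overlaid at each candidate shift and
#' the integral of their absolute difference is accumulated where both are
#' valid. This objective is alignment-sensitive at sub-interval scale, so a
#' planted shift on a clean series is recovered exactly; midpoint sampling
#' alone is piecewise constant in the shift and cannot resolve the plateau.
#' Ties break toward the smallest absolute shift. The reported
#' `mean_abs_err_ms` is the midpoint-sampled mean absolute interval
#' difference at the optimum (the same statistic as [interval_errors()]).
#'
#' @param test,ref [beat_events()] series.
#' @param shift_range_ms Search range, default `c(-3000, 3000)`.
#' @param window_s Analysis window on the reference timeline, default
#'   `c(5, 55)`.
#' @return List of class `sync_result`: `shift_ms`, `mean_abs_err_ms`.
#' @export
synchronize <- function(test, ref, shift_range_ms = c(-3000, 3000),
                        window_s = c(5, 55)) {
  stopifnot(inherits(test, "beat_events"), inherits(ref, "beat_events"))
  ref_span <- max(ref$tau_ms + ref$T_ms) / 1000
  if (ref_span < window_s[2])
    warning("synchronize: reference shorter than the analysis window; restricting")
  mids <- ref$tau_ms + ref$T_ms / 2
  in_win <- ref$valid & mids >= window_s[1] * 1000 & mids <= window_s[2] * 1000
  if (!any(in_win))
    stop("synchronize: no reference intervals in the analysis window")
  shifts <- seq(shift_range_ms[1], shift_range_ms[2], by = 1)
  ia <- integrated_err_scan(test, ref, shifts, window_s)
  if (all(!is.finite(ia)))
    stop("synchronize: no overlapping valid pairs at any shift")
  best <- which(ia <= min(ia) + 1e-9)
  best <- best[which.min(abs(shifts[best]))]
  s <- shifts[best]
  Tt <- sample_events_at(test, mids[in_win] + s)
  err <- abs(Tt - ref$T_ms[in_win])
  structure(list(shift_ms = s,
                 mean_abs_err_ms = if (all(is.na(err))) Inf
                                   else mean(err, na.rm = TRUE)),
            class = "sync_result")
}

# mean integrated |T_test(t + s) - T_ref(t)| over the window for each shift
# s (normalized by the jointly-covered time; Inf where nothing overlaps)
integrated_err_scan <- function(test, ref, shifts, window_s) {
  w0 <- window_s[1] * 1000
  w1 <- window_s[2] * 1000
  rb <- sort(unique(c(w0, w1, ref$tau_ms, ref$tau_ms + ref$T_ms)))
  tb <- sort(unique(c(test$tau_ms, test$tau_ms + test$T_ms)))
  vapply(shifts, function(s) {
    brk <- sort(c(rb, tb - s))
    brk <- brk[brk >= w0 & brk <= w1]
    if (length(brk) < 2L) return(Inf)
    mid <- (brk[-1L] + brk[-length(brk)]) / 2
    Tr <- sample_events_at(ref, mid)
    Tt <- sample_events_at(test, mid + s)
    seg <- diff(brk)
    ok <- !is.na(Tr) & !is.na(Tt)
    if (!any(ok)) return(Inf)
    sum(abs(Tt[ok] - Tr[ok]) * seg[ok]) / sum(seg[ok])
  }, numeric(1))
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> shift %+d ms, mean |dT| %.2f ms\n",
              as.integer(x$shift_ms), x$mean_abs_err_ms))
  invisible(x)
}

#' Interval-error statistics and signal loss at a known shift
#'
#' Pairs each reference interval (midpoint inside the analysis window) with
#' the test interval containing the shifted midpoint (`shift_ms` is the
#' test-relative-to-reference displacement from [synchronize()]) and reports
#' the mean, SD and mean absolute value of the differences
#' `dT = T_test - T_ref`, plus the time-weighted signal loss: the percentage
#' of the analysis window not covered by valid test intervals.
#'
#' @param test,ref [beat_events()] series.
#' @param shift_ms Synchronization shift from [synchronize()].
#' @param window_s Analysis window on the reference timeline.
#' @return List of class `comparison_stats`: `mean_dT`, `sd_dT`,
#'   `mean_abs_dT`, `signal_loss_pct`, `n_pairs`.
#' @export
interval_errors <- function(test, ref, shift_ms = 0, window_s = c(5, 55)) {
  stopifnot(inherits(test, "beat_events"), inherits(ref, "beat_events"))
  mids <- ref$tau_ms + ref$T_ms / 2
  in_win <- ref$valid & mids >= window_s[1] * 1000 & mids <= window_s[2] * 1000
  mids <- mids[in_win]
  T_ref <- ref$T_ms[in_win]
  Tt <- sample_events_at(test, mids + shift_ms)
  ok <- !is.na(Tt)
  if (!any(ok)) stop("interval_errors: no valid interval pairs")
  dT <- Tt[ok] - T_ref[ok]

  # loss: reference time in the window not covered by a valid test interval
  w0 <- window_s[1] * 1000 + shift_ms
  w1 <- window_s[2] * 1000 + shift_ms
  cov <- 0
  if (nrow(test) > 0L) {
    lo <- pmax(test$tau_ms[test$valid], w0)
    hi <- pmin((test$tau_ms + test$T_ms)[test$valid], w1)
    seg <- pmax(0, hi - lo)
    if (length(seg)) {
      # valid intervals may overlap after timestamp corrections; merge
      ord <- order(lo)
      lo <- lo[ord]; hi <- hi[ord]
      keep <- seg[ord] > 0
      lo <- lo[keep]; hi <- hi[keep]
      if (length(lo)) {
        end <- w0
        for (i in seq_along(lo)) {
          cov <- cov + max(0, hi[i] - max(lo[i], end))
          end <- max(end, hi[i])
        }
      }
    }
  }
  loss_pct <- 100 * (1 - cov / (w1 - w0))
  structure(list(mean_dT = mean(dT), sd_dT = stats::sd(dT),
                 mean_abs_dT = mean(abs(dT)),
                 signal_loss_pct = max(0, min(100, loss_pct)),
                 n_pairs = sum(ok)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(paste0("<comparison_stats> mean dT %.2f ms, SD %.2f ms, ",
                     "mean |dT| %.2f ms, loss %.2f%% (n = %d)\n"),
              x$mean_dT, x$sd_dT, x$mean_abs_dT, x$signal_loss_pct, x$n_pairs))
  invisible(x)
}

# contiguous runs of valid intervals (difference-based sums never span a gap:
# a gap is any invalid event or a jump in tau)
valid_runs <- function(tau, T_v, valid, tol = 1e-6) {
  n <- length(tau)
  if (n == 0L) return(list())
  brk <- c(TRUE, !valid[-n] | !valid[-1L] |
             abs(tau[-1L] - (tau[-n] + T_v[-n])) > pmax(tol, 0.2 * T_v[-n]))
  grp <- cumsum(brk)
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g & valid)
    if (length(idx)) out[[length(out) + 1L]] <- T_v[idx]
  }
  out
}

#' Variability index registry
#'
#' Operational definitions of the six short-term and six long-term
#' variability indices, named for the authors of the original proposals
#' (Dawes, Yeh, de Haan, Zugaib, Huey, Dalton). Each entry is a function of
#' (`runs`, `epochs`): `runs` is a list of contiguous valid interval vectors
#' (ms) and `epochs` a list of per-3.75-s-epoch interval vectors. The
#' registry is exported so alternative formulations can be substituted.
#'
#' Short-term (beat-to-beat): `S_DAL` mean |successive difference|; `S_DAW`
#' mean absolute difference of successive epoch mean intervals; `S_YEH`
#' 1000 * SD of the differential index (T_i - T_{i+1}) / (T_i + T_{i+1});
#' `S_HAA` interquartile range of arctan(T_{i+1} / T_i); `S_ZUG` SD of
#' successive differences; `S_HUE` mean |successive difference| restricted
#' to sign changes. Long-term: `L_DAL` mean absolute deviation from the
#' mean; `L_DAW` mean per-epoch max-min range; `L_YEH` 1000 * SD / mean;
#' `L_HAA` interquartile range of sqrt(T_i^2 + T_{i+1}^2); `L_ZUG` 1000 *
#' coefficient of variation; `L_HUE` SD of the intervals.
#'
#' @format A named list of 12 functions.
#' @export
variability_index_registry <- local({
  pair_diffs <- function(runs)
    unlist(lapply(runs, function(r) if (length(r) >= 2L) diff(r) else numeric(0)))
  pairs <- function(runs)
    do.call(rbind, lapply(runs, function(r)
      if (length(r) >= 2L) cbind(r[-length(r)], r[-1L]) else NULL))
  all_T <- function(runs) unlist(runs)
  list(
    S_DAL = function(runs, epochs) mean(abs(pair_diffs(runs))),
    S_DAW = function(runs, epochs) {
      em <- vapply(epochs, mean, numeric(1))
      if (length(em) < 2L) return(NA_real_)
      mean(abs(diff(em)))
    },
    S_YEH = function(runs, epochs) {
      p <- pairs(runs)
      if (is.null(p) || nrow(p) < 2L) return(NA_real_)
      1000 * stats::sd((p[, 1] - p[, 2]) / (p[, 1] + p[, 2]))
    },
    S_HAA = function(runs, epochs) {
      p <- pairs(runs)
      if (is.null(p) || nrow(p) < 2L) return(NA_real_)
      stats::IQR(atan(p[, 2] / p[, 1]))
    },
    S_ZUG = function(runs, epochs) {
      d <- pair_diffs(runs)
      if (length(d) < 2L) return(NA_real_)
      stats::sd(d)
    },
    S_HUE = function(runs, epochs) {
      res <- unlist(lapply(runs, function(r) {
        if (length(r) < 3L) return(numeric(0))
        d <- diff(r)
        flip <- which(d[-1L] * d[-length(d)] < 0) + 1L
        abs(d[flip])
      }))
      if (length(res) == 0L) return(0)
      mean(res)
    },
    L_DAL = function(runs, epochs) { x <- all_T(runs); mean(abs(x - mean(x))) },
    L_DAW = function(runs, epochs) {
      rng <- vapply(epochs, function(e) max(e) - min(e), numeric(1))
      mean(rng)
    },
    L_YEH = function(runs, epochs) { x <- all_T(runs); 1000 * stats::sd(x) / mean(x) },
    L_HAA = function(runs, epochs) {
      p <- pairs(runs)
      if (is.null(p) || nrow(p) < 2L) return(NA_real_)
      stats::IQR(sqrt(p[, 1]^2 + p[, 2]^2))
    },
    L_ZUG = function(runs, epochs) { x <- all_T(runs); 1000 * stats::sd(x) / mean(x) },
    L_HUE = function(runs, epochs) stats::sd(all_T(runs))
  )
})

#' Short- and long-term variability indices of an event series
#'
#' Computes the twelve author-named indices over the valid intervals whose
#' midpoints fall in the analysis window. Difference-based sums never span a
#' loss gap; epoch-based indices use 3.75-s epochs of the window.
#'
#' @param events A [beat_events()] series.
#' @param window_s Analysis window in seconds, default `c(5, 55)`.
#' @param epoch_s Epoch length for the Dawes-style indices (3.75 s).
#' @param min_intervals Minimum number of valid intervals required (10);
#'   fewer yields all-NA indices with a warning, never zeros.
#' @param registry Index registry (see [variability_index_registry]).
#' @return Named numeric vector of class `variability_indices`.
#' @export
variability_indices <- function(events, window_s = c(5, 55), epoch_s = 3.75,
                                min_intervals = 10,
                                registry = variability_index_registry) {
  stopifnot(inherits(events, "beat_events"))
  mids <- events$tau_ms + events$T_ms / 2
  sel <- mids >= window_s[1] * 1000 & mids <= window_s[2] * 1000
  ev <- events[sel, , drop = FALSE]
  nv <- sum(ev$valid)
  out <- stats::setNames(rep(NA_real_, length(registry)), names(registry))
  class(out) <- "variability_indices"
  if (nv < min_intervals) {
    warning("variability_indices: only ", nv,
            " valid intervals in the window; indices undefined")
    return(out)
  }
  runs <- valid_runs(ev$tau_ms, ev$T_ms, ev$valid)
  edges <- seq(window_s[1] * 1000, window_s[2] * 1000, by = epoch_s * 1000)
  epoch_id <- findInterval(mids[sel], edges, rightmost.closed = TRUE)
  epochs <- lapply(split(ev$T_ms[ev$valid], epoch_id[ev$valid]), identity)
  epochs <- epochs[vapply(epochs, length, integer(1)) > 0L]
  for (nm in names(registry)) out[nm] <- registry[[nm]](runs, epochs)
  out
}

#' @export
print.variability_indices <- function(x, ...) {
  cat("<variability_indices>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Relative errors of variability indices
#'
#' `delta = (test - ref) / ref * 100` per index, in percent. Undefined
#' (NA) when the reference index is 0 or missing.
#'
#' @param test_idx,ref_idx Named vectors from [variability_indices()].
#' @return Named numeric vector of relative errors in percent.
#' @export
relative_index_error <- function(test_idx, ref_idx) {
  stopifnot(all(names(test_idx) == names(ref_idx)))
  out <- ifelse(is.na(ref_idx) | ref_idx == 0, NA_real_,
                (unclass(test_idx) - unclass(ref_idx)) / unclass(ref_idx) * 100)
  stats::setNames(as.numeric(out), names(test_idx))
}

#' Monitor-style 250-ms rendering of an event series
#'
#' Emulates the evenly spaced output of a classical fetal monitor: every
#' `step_ms` a slot value is produced as the duration-weighted mean interval
#' over the trailing averaging window (the autocorrelation-window averaging
#' responsible for the monitor's underestimated beat-to-beat variability),
#' quantized to the monitor resolution. With `window_ms = NULL` the slot
#' simply duplicates the interval containing the slot time.
#'
#' @param events A [beat_events()] series.
#' @param step_ms Slot step (250 ms).
#' @param window_ms Trailing averaging window (default 1000 ms; NULL =
#'   duplicate-and-hold).
#' @param quantize_bpm Monitor resolution in bpm (0.25; NULL disables).
#' @return An `even_series` (as from [median_fhr_250()]).
#' @export
render_monitor_series <- function(events, step_ms = 250, window_ms = 1000,
                                  quantize_bpm = 0.25) {
  stopifnot(inherits(events, "beat_events"))
  t_end <- max(events$tau_ms + events$T_ms)
  slots <- seq(events$tau_ms[1] + step_ms, t_end, by = step_ms)
  vals <- rep(NA_real_, length(slots))
  for (i in seq_along(slots)) {
    if (is.null(window_ms)) {
      vals[i] <- sample_events_at(events, slots[i])
    } else {
      w0 <- slots[i] - window_ms
      lo <- pmax(events$tau_ms, w0)
      hi <- pmin(events$tau_ms + events$T_ms, slots[i])
      wgt <- pmax(0, hi - lo) * events$valid
      if (sum(wgt) > 0.5 * window_ms)
        vals[i] <- sum(events$T_ms * wgt) / sum(wgt)
    }
  }
  if (!is.null(quantize_bpm)) {
    ok <- !is.na(vals) & vals > 0
    vals[ok] <- 60000 / (round_half_up(60000 / vals[ok] / quantize_bpm) *
                           quantize_bpm)
  }
  structure(list(t0_ms = slots[1], step_ms = step_ms, values_ms = vals),
            class = "even_series")
}
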