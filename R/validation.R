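#' Validation parameters for artifact rejection
#'
#' @param lower_frac Fraction of the tolerance subtracted below the previous
#'   interval in the forward pass (0.1).
#' @param upper_frac Fraction added above it (0.15).
#' @param delta_offset Offset of the tolerance term: `Delta = T_prev - 300`
#'   ms above the breakpoint.
#' @param delta_breakpoint Breakpoint: below 320 ms the tolerance is the
#'   floor value.
#' @param delta_floor Tolerance floor, 20 ms.
#' @param group_min An interval must belong to a group of at least this many
#'   successive corridor-satisfying intervals (3).
#' @param mono_product_max Threshold on the product of differences with both
#'   neighbours in the monotonicity check, 35 ms^2.
#' @param backward_swap Swap the asymmetric corridor fractions on the
#'   backward pass (the "change of thresholds"); set FALSE to keep them
#'   unchanged.
#' @return Object of class `validation_params`.
#' @export
validation_params <- function(lower_frac = 0.1, upper_frac = 0.15,
                              delta_offset = 300, delta_breakpoint = 320,
                              delta_floor = 20, group_min = 3,
                              mono_product_max = 35, backward_swap = TRUE) {
  stopifnot(lower_frac > 0, upper_frac > 0, delta_offset > 0,
            delta_breakpoint > 0, delta_floor > 0, group_min >= 1,
            mono_product_max > 0)
  structure(list(lower_frac = lower_frac, upper_frac = upper_frac,
                 delta_offset = delta_offset,
                 delta_breakpoint = delta_breakpoint,
                 delta_floor = delta_floor, group_min = group_min,
                 mono_product_max = mono_product_max,
                 backward_swap = backward_swap),
            class = "validation_params")
}

#' Acceptance corridor around the previous interval
#'
#' An interval `T_i` is physiologically plausible relative to its predecessor
#' if it lies inside the open corridor
#' `(T_prev - lower_frac * Delta, T_prev + upper_frac * Delta)` with
#' `Delta = T_prev - 300 ms` for `T_prev >= 320 ms` and `Delta = 20 ms`
#' below the breakpoint.
#'
#' @param T_prev Previous interval in ms (> 0).
#' @param params A [validation_params()].
#' @param lower_frac,upper_frac Optional overrides of the corridor fractions
#'   (used by the backward pass).
#' @return Numeric `c(lo, hi)` corridor bounds in ms (open interval).
#' @export
corridor <- function(T_prev, params = validation_params(),
                     lower_frac = params$lower_frac,
                     upper_frac = params$upper_frac) {
  stopifnot(all(T_prev > 0))
  delta <- ifelse(T_prev >= params$delta_breakpoint,
                  T_prev - params$delta_offset, params$delta_floor)
  c(T_prev - lower_frac * delta, T_prev + upper_frac * delta)
}

# one-directional pass: corridor + group rule. The corridor anchor is the
# last interval that itself met the corridor, so one artifact does not
# poison the comparison for its successors, and a stretch of mutually
# consistent artifacts is still judged against the last good value. The
# pass accepts the meeting intervals provided it found at least group_min
# of them (the "group of at least three successive intervals").
directional_pass <- function(T, params, lower_frac, upper_frac) {
  n <- length(T)
  if (n < 2L) return(rep(TRUE, n))
  meets <- logical(n)
  meets[1L] <- TRUE  # no predecessor: provisional anchor
  anchor <- T[1L]
  for (i in 2:n) {
    cr <- corridor(anchor, params, lower_frac, upper_frac)
    if (T[i] > cr[1L] && T[i] < cr[2L]) {
      meets[i] <- TRUE
      anchor <- T[i]
    }
  }
  if (sum(meets) >= params$group_min) meets else rep(FALSE, n)
}

#' Bidirectional corridor validation
#'
#' Forward pass: each interval is checked against the corridor anchored on
#' its predecessor and must belong to a group of at least `group_min`
#' successive corridor-satisfying intervals. Backward pass: the same
#' procedure on the reversed series with the asymmetric fractions swapped.
#' An interval is classed incorrect only when BOTH passes reject it, which
#' protects genuine monotone acceleration/deceleration ramps that one
#' direction alone would reject.
#'
#' @param events A [beat_events()] series.
#' @param params A [validation_params()].
#' @return The events with a logical column `corridor_ok` appended (FALSE =
#'   rejected by both passes). Interval values are never altered.
#' @export
validate_bidirectional <- function(events, params = validation_params()) {
  stopifnot(inherits(events, "beat_events"))
  n <- nrow(events)
  events$corridor_ok <- rep(TRUE, n)
  if (n < params$group_min) {
    warning("validate_bidirectional: fewer than ", params$group_min,
            " events; flags indeterminate (accepted)")
    return(events)
  }
  T_v <- events$T_ms
  fwd <- directional_pass(T_v, params, params$lower_frac, params$upper_frac)
  if (params$backward_swap)
    bwd <- rev(directional_pass(rev(T_v), params,
                                params$upper_frac, params$lower_frac))
  else
    bwd <- rev(directional_pass(rev(T_v), params,
                                params$lower_frac, params$upper_frac))
  events$corridor_ok <- fwd | bwd
  events
}

#' Monotonicity check on rejected intervals
#'
#' Final verification of intervals initially classed incorrect by the
#' bidirectional corridor: an interior interval stays incorrect only if its
#' differences with both neighbours have the same sign and their product
#' exceeds `mono_product_max` (35 ms^2); otherwise it is rehabilitated.
#' Edge intervals (single neighbour) keep their corridor classification.
#'
#' @param events Output of [validate_bidirectional()] (must carry
#'   `corridor_ok`).
#' @param params A [validation_params()].
#' @return The events with the final `valid` flag updated; a
#'   `reject_reason` column records `"corridor"` or `"monotonicity"`.
#' @export
monotonicity_filter <- function(events, params = validation_params()) {
  stopifnot(inherits(events, "beat_events"), "corridor_ok" %in% names(events))
  n <- nrow(events)
  reason <- rep(NA_character_, n)
  final_bad <- rep(FALSE, n)
  for (i in which(!events$corridor_ok)) {
    if (i == 1L || i == n) {
      final_bad[i] <- TRUE
      reason[i] <- "corridor"
      next
    }
    d_prev <- events$T_ms[i] - events$T_ms[i - 1L]
    d_next <- events$T_ms[i] - events$T_ms[i + 1L]
    if (sign(d_prev) == sign(d_next) &&
        d_prev * d_next > params$mono_product_max) {
      final_bad[i] <- TRUE
      reason[i] <- "monotonicity"
    }
  }
  events$valid <- events$valid & !final_bad
  events$reject_reason <- reason
  events
}

#' Full event-series validation
#'
#' Applies the bidirectional corridor pass followed by the monotonicity
#' verification, setting loss markers (`valid = FALSE`) on the rejected
#' intervals. Running the validation twice yields identical flags.
#'
#' @param events A [beat_events()] series.
#' @param params A [validation_params()].
#' @return The validated events (columns `corridor_ok`, `reject_reason`
#'   appended; `valid` updated).
#' @export
validate_events <- function(events, params = validation_params()) {
  monotonicity_filter(validate_bidirectional(events, params), params)
}
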