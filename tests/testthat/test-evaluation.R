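test_that("interval-rate conversion is exact at the physiological bounds", {
  expect_equal(fhr_from_interval(250), 240)
  expect_equal(fhr_from_interval(1000), 60)
  expect_equal(fhr_from_interval(500), 120)
  expect_error(fhr_from_interval(0), "positive")
  for (f in seq(60, 240, by = 15))
    expect_equal(fhr_from_interval(60000 / f), f)
})

test_that("synchronization recovers planted shifts exactly on clean series", {
  fix <- make_jittered_reference(65, jitter_sd = 5, seed = 2)
  ref <- fix$ref
  for (s in c(-3000, -137, 0, 137, 2999)) {
    test <- ref
    test$tau_ms <- test$tau_ms + s
    attr(test, "source") <- "d2"
    sync <- synchronize(test, ref)
    expect_equal(sync$shift_ms, s)
    expect_equal(sync$mean_abs_err_ms, 0)
  }
})

test_that("synchronization tolerates interval noise", {
  fix <- make_jittered_reference(65, jitter_sd = 5, seed = 3)
  ref <- fix$ref
  set.seed(4)
  test <- beat_events(tau_ms = ref$tau_ms + 137,
                      T_ms = ref$T_ms + rnorm(nrow(ref), 0, 5),
                      source = "d2")
  sync <- synchronize(test, ref)
  expect_lte(abs(sync$shift_ms - 137), 3)
})

test_that("interval error statistics match closed forms", {
  fix <- make_jittered_reference(65, jitter_sd = 5, seed = 5)
  ref <- fix$ref
  st <- interval_errors(ref, ref, shift_ms = 0)
  expect_equal(st$mean_dT, 0)
  expect_equal(st$sd_dT, 0)
  expect_equal(st$mean_abs_dT, 0)
  expect_equal(st$signal_loss_pct, 0)

  plus2 <- beat_events(ref$tau_ms, ref$T_ms + 2, source = "d2")
  st2 <- interval_errors(plus2, ref, shift_ms = 0)
  expect_equal(st2$mean_dT, 2)
  expect_equal(st2$sd_dT, 0)
  expect_equal(st2$mean_abs_dT, 2)
})

test_that("a one-second loss gap in the window costs exactly 2% loss", {
  ref <- make_uniform_events(500, n = 130)
  test <- ref
  # invalidate the events covering [20.0, 21.0) s
  kill <- test$tau_ms >= 20000 & test$tau_ms < 21000
  test$valid[kill] <- FALSE
  attr(test, "source") <- "d2"
  st <- interval_errors(test, ref, shift_ms = 0)
  expect_equal(st$signal_loss_pct, 2.0)
})

test_that("all short-term indices vanish on a constant series", {
  idx <- variability_indices(make_uniform_events(500, n = 120))
  for (nm in c("S_DAL", "S_DAW", "S_YEH", "S_HAA", "S_ZUG", "S_HUE"))
    expect_equal(unname(idx[nm]), 0, info = nm)
  expect_equal(unname(idx["L_HUE"]), 0)  # SD of a constant
})

test_that("an alternating series forces the successive-difference indices", {
  T_v <- rep(c(490, 510), 60)
  idx <- variability_indices(events_from_T(T_v))
  expect_equal(unname(idx["S_DAL"]), 20)
  expect_equal(unname(idx["S_HUE"]), 20)  # every difference is a sign change
  d <- diff(T_v[1:100])
  expect_gt(unname(idx["S_ZUG"]), 19)     # sd of +/-20 alternation
})

test_that("relative index errors are simple percentage ratios", {
  ref <- variability_indices(events_from_T(rep(c(490, 510), 60)))
  expect_true(all(abs(relative_index_error(ref, ref)) < 1e-12, na.rm = TRUE))
  half <- ref; half[] <- unclass(ref) * 0.5
  expect_true(all(abs(relative_index_error(half, ref) + 50) < 1e-9,
                  na.rm = TRUE))
  up <- ref; up[] <- unclass(ref) * 1.1
  expect_true(all(abs(relative_index_error(up, ref) - 10) < 1e-9,
                  na.rm = TRUE))
})

test_that("neighbour averaging strictly decreases every STV index", {
  fix <- make_jittered_reference(65, jitter_sd = 6, seed = 6)
  ref <- fix$ref
  T_v <- ref$T_ms
  sm <- (c(T_v[1], T_v[-length(T_v)]) + T_v + c(T_v[-1], T_v[length(T_v)])) / 3
  smoothed <- beat_events(ref$tau_ms, sm, source = "monitor")
  i_ref <- variability_indices(ref)
  i_sm <- variability_indices(smoothed)
  for (nm in c("S_DAL", "S_DAW", "S_YEH", "S_HAA", "S_ZUG", "S_HUE"))
    expect_lt(unname(i_sm[nm]), unname(i_ref[nm]), label = nm)
})

test_that("relative errors are invariant under a common time rescaling", {
  fix <- make_jittered_reference(100, jitter_sd = 5, seed = 7)
  ref <- fix$ref
  mk_scaled <- function(base, c, src) events_from_T(base$T_ms * c, source = src)
  # the analysis window scales with the series so both pairs cover the same
  # beats
  d1 <- relative_index_error(
    variability_indices(mk_scaled(ref, 1.02, "d2")),
    variability_indices(mk_scaled(ref, 1, "reference")))
  d2 <- relative_index_error(
    variability_indices(mk_scaled(ref, 1.5 * 1.02, "d2"), window_s = c(7.5, 82.5)),
    variability_indices(mk_scaled(ref, 1.5, "reference"), window_s = c(7.5, 82.5)))
  # epoch-partition indices (Dawes) depend on fixed 3.75-s epochs and are
  # not exactly scale-invariant; all interval-ratio/difference indices are
  nm <- setdiff(names(d1), c("S_DAW", "L_DAW"))
  expect_equal(d1[nm], d2[nm], tolerance = 1e-6)
})

test_that("too few intervals yield missing indices, never zeros", {
  ev <- make_uniform_events(500, n = 120)
  ev$valid[ev$tau_ms > 6000] <- FALSE
  expect_warning(idx <- variability_indices(ev), "undefined")
  expect_true(all(is.na(unclass(idx))))
})

test_that("difference-based indices never span a loss gap", {
  # two clean halves separated by a huge jump across an invalid stretch;
  # if differences crossed the gap, S_DAL would explode
  T_a <- rep(500, 60)
  T_b <- rep(800, 60)
  ev <- events_from_T(c(T_a, T_b))
  ev$valid[60:62] <- FALSE
  idx <- variability_indices(ev, window_s = c(5, 55))
  expect_equal(unname(idx["S_DAL"]), 0)
})
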