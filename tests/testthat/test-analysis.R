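test_that("edge detection counts pulses and refines with sampling rate", {
  p <- stim_params(1, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6,
                   delay_ms = 10)
  tr <- render_channel(p, 2000, 10.1)
  e <- detect_edges(tr, ttl)
  expect_equal(nrow(e), 400)
  expect_true(all(diff(e$onset_ms) > 0))
  expect_true(all(e$duration_ms > 0))

  # a flat channel is an empty result, not an error
  flat <- tibble::tibble(t_s = (0:99) / 1000, x = 0)
  expect_equal(nrow(detect_edges(flat, x)), 0)

  # onsets at 2 kHz agree with a 20 kHz rendering within one coarse sample
  e_fine <- detect_edges(render_channel(p, 20000, 10.1), ttl)
  expect_equal(nrow(e_fine), 400)
  expect_lt(max(abs(e$onset_ms - e_fine$onset_ms)), 1000 / 2000)
})

test_that("pulse statistics recover frequency and width on a parameter grid", {
  set.seed(3)
  freqs <- c(2, 10, 40, 87, 200)
  for (f in freqs) {
    duty <- runif(1, 0.1, 0.9)
    per <- 1000 / f
    p <- stim_params(1, "square", burst_ms = 20 * per, freq_hz = f,
                     duty = duty, delay_ms = 7)
    rate <- 2000
    tr <- render_channel(p, rate, (20 * per + 20) / 1000)
    ps <- pulse_stats(tr, ttl)
    expect_equal(ps$n_pulses, 20)
    expect_lt(abs(ps$mean_interval_ms - per), 1000 / rate)
    expect_lt(abs(ps$mean_duration_ms - duty * per), 1000 / rate)
    expect_lt(abs(ps$freq_hz_est - f) / f, 1000 / rate / per)
  }
  # fewer than 2 pulses is an error
  one <- render_channel(stim_params(1, "square", burst_ms = 10,
                                    freq_hz = 10, pulse_ms = 5), 2000, 0.2)
  expect_error(pulse_stats(one, ttl), class = "optopulse_analysis_error")
})

test_that("tidy/glance views of pulse stats are consistent", {
  p <- stim_params(1, "square", burst_ms = 500, freq_hz = 20, pulse_ms = 10,
                   delay_ms = 5)
  ps <- pulse_stats(render_channel(p, 2000, 0.6), ttl)
  td <- tidy(ps)
  expect_equal(nrow(td), ps$n_pulses)
  expect_true(is.na(td$interval_ms[1]))
  expect_equal(mean(td$duration_ms), glance(ps)$mean_duration_ms)
  expect_equal(glance(ps)$freq_hz_est, 1000 / mean(ps$onset_intervals_ms))
})

test_that("trigger lag is bounded by one sample period on the ideal device", {
  dev <- virtual_device()
  set_params(dev, stim_params(1, "square", burst_ms = 100, freq_hz = 40,
                              pulse_ms = 6))
  ev <- fixture_trigger_train(10, min_gap_ms = 300, t_max_s = 4, seed = 2)
  run <- run_device(dev, ev, rate_hz = 2000, t_end_s = 4.5)
  lag <- trigger_lag(run$trace, trigger, laser1_ttl)
  expect_equal(nrow(lag), 10)
  expect_true(all(is.finite(lag$lag_ms)))
  expect_true(all(abs(lag$lag_ms) <= 1000 / 2000))

  # a trigger with no following output onset is flagged, not dropped
  t_s <- (0:999) / 1000
  manual <- tibble::tibble(t_s = t_s,
                           trig = t_s >= 0.1 & t_s < 0.105,
                           out = FALSE)
  lag2 <- trigger_lag(manual, trig, out)
  expect_equal(nrow(lag2), 1)
  expect_true(is.na(lag2$lag_ms))
})

test_that("intersignal offsets pair pulses across synchronised channels", {
  dev <- virtual_device()
  set_params(dev, list(
    stim_params(1, "square", burst_ms = 2000, freq_hz = 40, pulse_ms = 6),
    stim_params(2, "square", burst_ms = 2000, freq_hz = 40, pulse_ms = 6)))
  run <- run_device(dev, tibble::tibble(t_ms = 20, kind = "trigger",
                                        line = NA_integer_),
                    rate_hz = 2000, t_end_s = 2.2)
  off <- intersignal_offset(run$trace, laser1_ttl, laser2_ttl)
  expect_equal(mean(abs(off$offset_ms)), 0)

  # deliberate 200 ms delay, paired ordinally via the expected offset
  dev2 <- virtual_device()
  set_params(dev2, list(
    stim_params(1, "square", burst_ms = 2000, freq_hz = 40, pulse_ms = 6),
    stim_params(2, "square", burst_ms = 2000, freq_hz = 40, pulse_ms = 6,
                delay_ms = 200)))
  run2 <- run_device(dev2, tibble::tibble(t_ms = 20, kind = "trigger",
                                          line = NA_integer_),
                     rate_hz = 2000, t_end_s = 2.5)
  off2 <- intersignal_offset(run2$trace, laser1_ttl, laser2_ttl,
                             expected_offset_ms = 200)
  expect_equal(unique(off2$offset_ms), 200)

  # single-pulse channels yield exactly one offset
  t_s <- (0:499) / 1000
  single <- tibble::tibble(t_s = t_s,
                           a = t_s >= 0.1 & t_s < 0.11,
                           b = t_s >= 0.13 & t_s < 0.14)
  off3 <- intersignal_offset(single, a, b)
  expect_equal(nrow(off3), 1)
  expect_equal(off3$offset_ms, 30)
})

test_that("quadrature phase matches the delay convention and a second method", {
  p0 <- stim_params(1, "sine", burst_ms = 4000, freq_hz = 25)
  tr <- render_channel(p0, 2000, 4)
  ph <- instantaneous_phase(tr, analog_V, 25)
  core <- ph$phase_rad[200:7800]
  expect_lt(max(abs(wrap_diff(core - 0))), 0.02)   # undelayed -> phase 0

  # cross-check against the zero-crossing estimator
  zc <- zero_crossing_phase(tr$t_s, tr$analog_V, 25)
  expect_lt(max(abs(wrap_diff(core - zc))), 0.02)

  # a 20 ms delay at 25 Hz is half a cycle: phase difference pi
  pd <- stim_params(2, "sine", burst_ms = 4000, freq_hz = 25, delay_ms = 20)
  trd <- render_channel(pd, 2000, 4)
  tr2 <- tibble::tibble(t_s = tr$t_s, a = tr$analog_V, b = trd$analog_V)
  st <- phase_difference_stats(dplyr::filter(tr2, t_s >= 0.02, t_s < 3.9),
                               a, b, 25, wrap = "positive")
  expect_equal(st$circ_mean_rad, pi, tolerance = 0.01)
  expect_gt(st$resultant_length, 0.99)

  expect_error(instantaneous_phase(tr, analog_V, -1),
               class = "optopulse_param_error")
  short <- dplyr::slice(tr, 1:100)
  expect_error(instantaneous_phase(short, analog_V, 25),
               class = "optopulse_analysis_error")
})

test_that("phase-difference statistics are rotation-equivariant and honest on noise", {
  # shifting both channels by the same delay leaves the statistics alone
  mk <- function(delay) {
    pa <- stim_params(1, "sine", burst_ms = 3000, freq_hz = 25,
                      delay_ms = delay)
    pb <- stim_params(2, "sine", burst_ms = 3000, freq_hz = 25,
                      delay_ms = delay + 8)
    ta <- render_channel(pa, 2000, 3.3)
    tb <- render_channel(pb, 2000, 3.3)
    tib <- tibble::tibble(t_s = ta$t_s, a = ta$analog_V, b = tb$analog_V)
    phase_difference_stats(dplyr::filter(tib, t_s >= (delay + 8) / 1000,
                                         t_s < (delay + 3000) / 1000),
                           a, b, 25)
  }
  s0 <- mk(0)
  s1 <- mk(37)
  expect_lt(abs(wrap_diff(s0$circ_mean_rad - s1$circ_mean_rad)), 0.02)
  expect_lt(abs(s0$resultant_length - s1$resultant_length), 0.02)
  # both should sit at the 8 ms lag: 2 pi * 25 * 0.008
  expect_equal(s0$circ_mean_rad, 2 * pi * 25 * 0.008, tolerance = 0.01)

  # independent white-noise channels carry no phase locking
  set.seed(8)
  t_s <- (0:19999) / 2000
  noise <- tibble::tibble(t_s = t_s, a = runif(20000), b = runif(20000))
  sn <- phase_difference_stats(noise, a, b, 25)
  expect_lt(sn$resultant_length, 0.1)
})

test_that("seeded trigger fixtures are reproducible and respect the gap", {
  e1 <- fixture_trigger_train(30, min_gap_ms = 8000, t_max_s = 300, seed = 4)
  e2 <- fixture_trigger_train(30, min_gap_ms = 8000, t_max_s = 300, seed = 4)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 30)
  expect_true(all(diff(e1$t_ms) >= 8000))
  expect_true(all(e1$t_ms >= 0 & e1$t_ms <= 300000))
  expect_false(identical(
    e1, fixture_trigger_train(30, min_gap_ms = 8000, t_max_s = 300, seed = 5)))
  expect_error(fixture_trigger_train(100, min_gap_ms = 8000, t_max_s = 300),
               class = "optopulse_param_error")
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(fixture_trigger_train(3, 10, 1, seed = 9))
  expect_identical(runif(1), before)
})
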