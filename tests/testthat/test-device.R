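square_p <- function(laser = 1, burst = 100, delay = 0, freq = 40, width = 6,
                     mask = TRUE) {
  stim_params(laser, "square", burst_ms = burst, freq_hz = freq,
              pulse_ms = width, delay_ms = delay, mask_enabled = mask)
}

one_trigger <- function(t_ms = 10) {
  tibble::tibble(t_ms = t_ms, kind = "trigger", line = NA_integer_)
}

test_that("parameters are accepted when idle and rejected mid-episode", {
  dev <- virtual_device()
  expect_silent(set_params(dev, list(square_p(1), square_p(2))))
  expect_s3_class(dev$params[[1]], "stim_params")
  expect_s3_class(dev$params[[2]], "stim_params")

  expect_true(on_trigger_edge(dev, 10))
  expect_equal(device_state(dev, 50), "STIMULATING")
  expect_error(set_params(dev, square_p(1), t_ms = 50),
               class = "optopulse_busy_error")
  expect_error(set_mock(dev, TRUE, t_ms = 50),
               class = "optopulse_busy_error")
  # after the episode the device is idle again and accepts parameters
  expect_equal(device_state(dev, 200), "IDLE")
  expect_silent(set_params(dev, square_p(3), t_ms = 200))

  expect_error(set_params(dev, list(square_p(1), square_p(1)), t_ms = 200),
               class = "optopulse_param_error")
  expect_error(set_params(dev, "not params", t_ms = 200),
               class = "optopulse_param_error")
})

test_that("mock episodes drive the mask only and the flag is per-episode", {
  dev <- virtual_device()
  set_params(dev, list(square_p(1), square_p(2)))
  set_mock(dev, TRUE)
  ev <- rbind(one_trigger(10), one_trigger(300))
  dev2 <- virtual_device()        # same events, mock off
  set_params(dev2, list(square_p(1), square_p(2)))
  run_mock <- run_device(dev, ev[1, ], rate_hz = 2000, t_end_s = 0.25)
  run_live <- run_device(dev2, ev[1, ], rate_hz = 2000, t_end_s = 0.25)

  tr <- run_mock$trace
  expect_true(all(tr$laser1_V == 0) && all(tr$laser2_V == 0))
  expect_false(any(tr$laser1_ttl) || any(tr$laser2_ttl))
  expect_true(any(tr$mask1) && any(tr$mask2))
  # the mask pattern is identical to the non-mock episode's mask
  expect_identical(tr$mask1, run_live$trace$mask1)
  expect_true(any(run_live$trace$laser1_ttl))

  # flag can change between episodes: next episode honours mock off
  set_mock(dev, FALSE, t_ms = 280)
  run3 <- run_device(dev, ev[2, ], rate_hz = 2000, t_end_s = 0.5)
  expect_true(any(run3$trace$laser1_ttl))
})

test_that("priming gates triggers: one prime arms exactly one acceptance", {
  cfg <- device_config(priming_required = TRUE)
  dev <- virtual_device(cfg)
  set_params(dev, square_p(1, burst = 20))

  expect_false(on_trigger_edge(dev, 10))          # no prime -> ignored
  on_prime_edge(dev, 20)
  expect_equal(device_state(dev, 20), "PRIMED")
  expect_true(on_trigger_edge(dev, 30))           # coincidence -> episode
  expect_false(on_trigger_edge(dev, 100))         # prime was consumed
  expect_false(on_trigger_edge(dev, 200))
  on_prime_edge(dev, 250)
  on_prime_edge(dev, 260, "falling")              # disarmed before trigger
  expect_false(on_trigger_edge(dev, 270))
})

test_that("trigger edges are debounced and non-selected lines ignored", {
  dev <- virtual_device()
  set_params(dev, square_p(1, burst = 1))
  expect_true(on_trigger_edge(dev, 0))
  expect_false(on_trigger_edge(dev, 3))           # 3 ms < 5 ms window
  dev2 <- virtual_device()
  set_params(dev2, square_p(1, burst = 1))
  expect_true(on_trigger_edge(dev2, 0))
  expect_true(on_trigger_edge(dev2, 6))           # outside the window
  expect_false(on_trigger_edge(dev2, 100, line = 3))  # wrong input
  log <- episode_log(dev2)
  expect_equal(log$reason, c("accepted", "accepted", "non-selected line"))
})

test_that("software triggers bypass gating but respect busy state", {
  dev <- virtual_device(device_config(priming_required = TRUE))
  set_params(dev, square_p(1, burst = 50))
  expect_true(software_trigger(dev, 10))          # no prime needed
  expect_false(software_trigger(dev, 30))         # mid-episode
  expect_true(software_trigger(dev, 100))

  # mock + software trigger -> mask-only episode
  dev2 <- virtual_device()
  set_params(dev2, square_p(1))
  set_mock(dev2, TRUE)
  software_trigger(dev2, 0)
  snap <- device_step(dev2, 1)
  expect_equal(snap$analog_V[1], 0)
  expect_false(snap$ttl[1])
  expect_true(snap$mask[1])
})

test_that("per-channel delays offset trains and identical params synchronise", {
  dev <- virtual_device()
  set_params(dev, list(square_p(1, burst = 1000, delay = 0),
                       square_p(2, burst = 1000, delay = 200)))
  run <- run_device(dev, one_trigger(50), rate_hz = 2000, t_end_s = 1.5)
  on1 <- detect_edges(run$trace, laser1_ttl)$onset_ms
  on2 <- detect_edges(run$trace, laser2_ttl)$onset_ms
  expect_equal(on2[1] - on1[1], 200)

  dev2 <- virtual_device()
  set_params(dev2, list(square_p(1, burst = 1000), square_p(2, burst = 1000)))
  run2 <- run_device(dev2, one_trigger(50), rate_hz = 2000, t_end_s = 1.5)
  expect_identical(run2$trace$laser1_ttl, run2$trace$laser2_ttl)
  expect_identical(run2$trace$laser1_V, run2$trace$laser2_V)
})

test_that("the device returns to idle with all lines low and time is monotone", {
  dev <- virtual_device()
  set_params(dev, square_p(1, burst = 20))
  software_trigger(dev, 0)
  snap <- device_step(dev, 25)
  expect_equal(snap$state[1], "IDLE")
  expect_true(all(snap$analog_V == 0) && !any(snap$ttl) && !any(snap$mask))
  expect_error(device_step(dev, 10), class = "optopulse_time_error")
})

test_that("event replay is deterministic and counts accepted episodes", {
  ev <- fixture_trigger_train(30, min_gap_ms = 500, t_max_s = 30, seed = 7)
  mk <- function() {
    d <- virtual_device()
    set_params(d, square_p(1, burst = 100))
    d
  }
  run1 <- run_device(mk(), ev, rate_hz = 1000, t_end_s = 31)
  run2 <- run_device(mk(), ev, rate_hz = 1000, t_end_s = 31)
  expect_identical(run1$trace, run2$trace)          # bit-identical replay
  expect_equal(sum(run1$events$accepted), 30)       # every trigger landed

  empty <- run_device(mk(), one_trigger(10)[0, ], rate_hz = 1000, t_end_s = 1)
  expect_true(all(empty$trace$laser1_V == 0) && !any(empty$trace$laser1_ttl))
})

test_that("priming/debounce gate agrees with the reference state machine", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 40
    kinds <- sample(c("trigger", "prime", "prime_off"), n, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
    ev <- tibble::tibble(t_ms = sort(runif(n, 0, 400)), kind = kinds,
                         line = NA_integer_)
    for (priming in c(FALSE, TRUE)) {
      dev <- virtual_device(device_config(priming_required = priming))
      set_params(dev, square_p(1, burst = 15))
      run <- run_device(dev, ev, rate_hz = 500, t_end_s = 0.5)
      got <- run$events$accepted[run$events$kind == "trigger"]
      want <- reference_trigger_fsm(ev, debounce_ms = 5,
                                    priming_required = priming,
                                    episode_dur_ms = 15)
      expect_identical(got, want)
    }
  }
})

test_that("CommEnable reflects busy state and the heartbeat blinks at 6 Hz", {
  dev <- virtual_device()
  set_params(dev, square_p(1, burst = 100))
  expect_false(comm_enable(dev, 0))
  software_trigger(dev, 10)
  expect_true(comm_enable(dev, 50))
  expect_false(comm_enable(dev, 150))
  sa <- virtual_device(device_config(standalone = TRUE))
  set_params(sa, square_p(1, burst = 100))
  software_trigger(sa, 10)
  expect_false(comm_enable(sa, 50))               # disabled in standalone

  idle <- virtual_device()
  per <- 1000 / 6
  expect_true(heartbeat(idle, 0))                 # defined HIGH phase at 0
  expect_false(heartbeat(idle, per / 2))
  expect_true(heartbeat(idle, per))               # 1000/6 ms period
  expect_false(heartbeat(dev, 50))                # suppressed mid-episode
})

test_that("a constant loop latency shifts every episode start", {
  dev <- virtual_device(device_config(loop_latency_ms = 1.68))
  set_params(dev, square_p(1, burst = 100))
  run <- run_device(dev, one_trigger(50), rate_hz = 20000, t_end_s = 0.3)
  lag <- trigger_lag(run$trace, trigger, laser1_ttl)
  expect_equal(lag$lag_ms, 1.68, tolerance = 1000 / 20000 / 1.68)
})
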