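# Independent brute-force oracles used to cross-check the implementation.
# These re-derive the waveform definitions, the trigger gate and the OLS
# fit from scratch (scalar loops, closed forms) and must stay independent
# of the package code paths they check.

# scalar evaluation of one channel at one time point (ms since trigger)
naive_sample <- function(p, t, convention = "raised_cosine") {
  d <- p$delay_ms
  f <- p$freq_hz
  per <- 1000 / f
  if (p$waveform == "square") {
    w <- if (!is.null(p$pulse_ms)) p$pulse_ms else p$duty * per
    in_burst <- (t >= d) && (t < d + p$burst_ms)
    ttl <- in_burst && (((t - d) %% per) < w)
    frac <- if (in_burst) 1 else 0
    mask <- p$mask_enabled && ttl
  } else {
    end <- d + p$burst_ms + p$atten_ms
    active <- (t >= d) && (t < end)
    ttl <- active
    if (!active) {
      frac <- 0
    } else {
      th <- 2 * pi * f * (t - d) / 1000
      base <- if (p$waveform == "sine") {
        if (convention == "raised_cosine") (1 - cos(th)) / 2
        else (1 + sin(th)) / 2
      } else {
        max(0, sin(th))
      }
      gain <- if (t <= d + p$burst_ms) 1
        else 1 - (t - d - p$burst_ms) / p$atten_ms
      frac <- base * gain
    }
    mask <- p$mask_enabled && active && (((t - d) %% per) < per / 2)
  }
  list(frac = frac, ttl = ttl, mask = mask)
}

# full naive render: per-sample loop, round-half-up DAC
naive_render <- function(p, rate_hz, total_s, bits = 12, vref = 5,
                         convention = "raised_cosine") {
  n <- floor(total_s * rate_hz + 1e-9)
  pf <- p$power / 100
  full <- 2^bits - 1
  volts <- numeric(n); ttl <- logical(n); mask <- logical(n)
  for (i in seq_len(n)) {
    t <- (i - 1) / rate_hz * 1000
    s <- naive_sample(p, t, convention)
    code <- floor(s$frac * pf * full + 0.5)
    volts[i] <- code / full * vref
    ttl[i] <- s$ttl
    mask[i] <- s$mask
  }
  list(volts = volts, ttl = ttl, mask = mask)
}

# random but valid parameter set (draws from the current RNG stream)
random_params <- function() {
  wf <- sample(c("square", "sine", "half_sine"), 1)
  f <- runif(1, 1, 200)
  per <- 1000 / f
  burst <- runif(1, 1.5 * per, 5 * per)
  if (wf == "square") {
    stim_params(sample(4, 1), wf, burst_ms = burst, freq_hz = f,
                duty = runif(1, 0.05, 0.95),
                delay_ms = runif(1, 0, 20),
                power = runif(1, 10, 100),
                mask_enabled = sample(c(TRUE, FALSE), 1))
  } else {
    stim_params(sample(4, 1), wf, burst_ms = burst, freq_hz = f,
                atten_ms = runif(1, 0, 2 * per),
                delay_ms = runif(1, 0, 20),
                power = runif(1, 10, 100),
                mask_enabled = sample(c(TRUE, FALSE), 1))
  }
}

# reference trigger gate: replays (t, kind) events through the documented
# accept rule and returns the accept decision for every trigger event
reference_trigger_fsm <- function(events, debounce_ms = 5,
                                  priming_required = FALSE,
                                  episode_dur_ms = 0) {
  primed <- FALSE
  last_edge <- -Inf
  busy_until <- -Inf
  out <- logical(0)
  for (i in seq_len(nrow(events))) {
    t <- events$t_ms[i]
    kind <- events$kind[i]
    if (kind == "prime") {
      primed <- TRUE
    } else if (kind == "prime_off") {
      primed <- FALSE
    } else if (kind == "trigger") {
      debounced_ok <- (t - last_edge) >= debounce_ms
      last_edge <- t
      ok <- debounced_ok && (t >= busy_until) &&
        (primed || !priming_required)
      if (ok) {
        busy_until <- t + episode_dur_ms
        primed <- FALSE
      }
      out <- c(out, ok)
    }
  }
  out
}

# phase estimate from upward mid-level crossings: for a raised cosine
# x = (1 - cos(2 pi f (t - d)))/2, the upward crossing of the mid level
# satisfies 2 pi f t_c + phi = pi/2 (mod 2 pi) with phi = -2 pi f d
zero_crossing_phase <- function(t_s, x, f0_hz) {
  mid <- (max(x) + min(x)) / 2
  above <- x >= mid
  n <- length(x)
  rising <- which(!above[-n] & above[-1])
  tc <- vapply(rising, function(i) {
    t_s[i] + (mid - x[i]) / (x[i + 1] - x[i]) * (t_s[i + 1] - t_s[i])
  }, 1)
  ph <- (pi / 2 - 2 * pi * f0_hz * tc)
  atan2(mean(sin(ph)), mean(cos(ph)))
}

# closed-form OLS for the calibration cross-check
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(sum((y - intercept - slope * x)^2) /
                         (length(x) - 2) / sxx))
}

# wrap an angle difference into (-pi, pi] for comparisons
wrap_diff <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y == -pi] <- pi
  y
}
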