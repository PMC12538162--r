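# optopulse

A pure-software emulation of a microcontroller-based laser stimulation
controller for optogenetic experiments, together with the signal-metrology
toolkit used to characterise such a device.

Optogenetic experiments drive genetically targeted neurons with precisely
timed light. The lasers involved are typically modulated by two lines per
channel: a 3.3 V TTL *enable* line gating emission, and a 0–5 V *analog*
line setting output power through a 12-bit DAC. A behavioural rig needs a
controller that, on a hardware trigger, emits a parameterised pulse train
on up to four such channel pairs — plus masking-LED channels flashing the
same pattern so animals cannot use the laser light itself as a cue.
`optopulse` reproduces that controller entirely in software: the waveform
synthesis, the trigger/priming/debounce state machine, the line-delimited
JSON control protocol, the power calibration, and the timing statistics
one computes from recorded traces to validate such a device. It is useful
for protocol design and visualisation, for regression-testing behavioural
control code against a deterministic device, and as an executable
specification of the controller's semantics.

## The model

Three waveforms are synthesised per channel, each parameterised by a burst
duration `B` (ms), train frequency `f` (Hz), trigger delay `D` (ms) and
power `P`:

- **square** — the TTL line is HIGH for a width `w` at the start of each
  period `T = 1000/f` while `D ≤ t < D + B`; the analog line is held
  constant over the train. `w` is given directly or as a duty cycle
  `w = duty · T`.
- **sine** — raised-cosine amplitude modulation
  `a(t) = (1 − cos 2πf(t−D))/2`, starting at zero (the analog line drives
  non-negative optical power); the TTL is held HIGH throughout.
- **half-sine** — `a(t) = max(0, sin 2πf(t−D))`: the upper half of a
  sinusoid, resting at zero for half of every cycle.

Sinusoidal trains may append an attenuation ramp of length `A`: the
oscillation continues over `(D+B, D+B+A]` while its amplitude descends
linearly to zero. Analog samples are quantised onto a 12-bit DAC spanning
0–5 V (codes `round(a · 4095)`, round-half-up).

The device accepts a trigger edge iff it falls on the selected input
(1–6), at least 5 ms after the previous edge (debounce), while no episode
is running, and — when priming is enabled — while the priming line has
armed the device (each prime buys exactly one acceptance). A *mock*
episode drives only the masking LEDs: lasers stay dark, giving behavioural
control trials.

On the analysis side, pulse onsets/offsets are detected at half-maximum
with sub-sample linear interpolation; the interpulse duration is the
onset-to-onset interval, and the train frequency estimate is
`1000 / mean(interval)`. Phase is estimated by quadrature demodulation at
the known stimulation frequency, and phase offsets between channels are
summarised by the circular mean `atan2(Σ sin, Σ cos)` and resultant
length `R`.

## Worked example

Two synchronised 40 Hz square trains (6 ms pulses, 10 s), the second
offset by 200 ms, triggered at a random time and sampled at 2 kHz:

```r
library(optopulse)
library(dplyr)

dev <- virtual_device()
set_params(dev, list(
  stim_params(1, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6),
  stim_params(2, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6,
              delay_ms = 200)))
events <- fixture_trigger_train(1, min_gap_ms = 100, t_max_s = 0.1, seed = 42)
run <- run_device(dev, events, rate_hz = 2000, t_end_s = 10.5)
run
#> <device_run> 21000 samples at 2000 Hz, 1/1 events accepted

pulse_stats(run$trace, laser1_ttl)
#> <pulse_stats> 400 pulses: duration 6.000 +/- 0.000 ms, interval 25.000 +/- 0.000 ms, freq 40.000 Hz

off <- intersignal_offset(run$trace, laser1_ttl, laser2_ttl,
                          expected_offset_ms = 200)
mean(off$offset_ms)
#> [1] 200

trigger_lag(run$trace, trigger, laser1_ttl)$lag_ms
#> [1] 0
```

The 400 detected pulses are the expected `10 s × 40 Hz`; the 25 ms mean
interpulse interval is the 40 Hz period; durations match the 6 ms setting
exactly because the ideal device has no timing jitter; the per-pulse
offset between the channels is the configured 200 ms delay; and the
trigger-to-output lag is zero (a constant hardware-style lag can be
emulated via `device_config(loop_latency_ms = ...)`).

`autoplot()` methods exist for traces, pulse statistics, phase statistics
and calibration curves; `tidy()`/`glance()` give per-pulse and one-row
summary tables.

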