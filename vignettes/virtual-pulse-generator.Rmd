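---
title: "A virtual pulse-train generator for optogenetic stimulation: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual pulse-train generator for optogenetic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(optopulse)
library(dplyr)
```

`optopulse` emulates, in software, a microcontroller-based stimulation
controller of the kind used to drive lasers in optogenetic behavioural
experiments, and bundles the metrology used to characterise one. This
vignette is the package's account of the underlying models, the
conventions chosen where the hardware semantics left room, and what the
package's own validation does and does not establish.

## The stimulation model

Each of up to four laser channels is described by a `stim_params()`
object. Time is in milliseconds everywhere in parameter structures, and
in seconds on trace time axes; the conversion happens once at the render
boundary. The channel's physical interface is an enable (TTL, 3.3 V
nominal) line and an analog power line driven by a 12-bit DAC spanning
0--5 V.

The three waveforms and their parameters:

| parameter | units | applies to | meaning |
|---|---|---|---|
| `burst_ms` | ms | all | total train duration after the delay |
| `freq_hz` | Hz | all | pulse/oscillation frequency |
| `pulse_ms` / `duty` | ms / – | square | single-pulse width, directly or as a fraction of the period |
| `atten_ms` | ms | sine, half-sine | linear amplitude ramp-down appended after the burst |
| `delay_ms` | ms | all | trigger-to-train-start delay, for offsetting trains |
| `power` | % or mW | all | output amplitude; mW requires a calibration curve |

Conventions that were genuinely open and how they were fixed:

* **Sinusoid baseline.** "Sinusoidal" could mean an oscillation about a
  midpoint or an envelope resting on zero. Because the analog line drives
  non-negative optical power and the output should rise from baseline at
  train onset, the default is the raised cosine
  $a(t) = \tfrac12\,(1 - \cos 2\pi f (t - D))$, which starts at 0 and
  peaks at 1. The midpoint convention
  $\tfrac12 (1 + \sin 2\pi f (t-D))$ remains available via
  `sine_convention = "pure"` for users who want an oscillation about
  half scale.
* **Attenuation extends the train.** The ramp is a continuation: the
  oscillation keeps running over `(D+B, D+B+A]` while the amplitude gain
  falls linearly from 1 to 0, so a channel is active for
  `delay + burst + atten` ms in total. Attenuation is a property of the
  analog envelope and therefore applies to the sinusoidal waveforms only;
  supplying it with a square train drops it with a warning.
* **Both `pulse_ms` and `duty` are accepted** for square trains; if both
  are given they must agree to within $10^{-9}$ (an inconsistent pair is
  a user error worth failing loudly on). Internally the width in ms is
  canonical.
* **Partial final pulse.** If `burst_ms` is not an integer multiple of
  the period, the final pulse is truncated at the burst end rather than
  completed: the burst duration is read as a hard total, and silently
  extending a stimulus aimed at live tissue is the worse failure mode.
* **DAC rounding** is round-half-up to the nearest code, with full scale
  on the top code (4095 at 12 bits), so quantisation error is bounded by
  half an LSB.

## The device state machine

`virtual_device()` holds per-channel parameters and a three-state
machine: `IDLE`, `PRIMED`, `STIMULATING`. A trigger edge is accepted iff
it arrives on the configured input, at least `debounce_ms` (default 5 ms)
after the previous edge on that line, while no episode runs, and — with
priming enabled — while the device is armed. Decisions worth recording:

* **Trigger polarity.** The hardware documentation is contradictory about
  which transition counts; the operating procedure ("drive the pin HIGH
  to start, return it LOW to re-arm") is explicit, so rising-edge is the
  default and the polarity is configurable.
* **Priming consumption.** A prime arms exactly one acceptance and is
  cleared on use or on a falling prime edge. This is what makes priming
  useful against bouncing beam-break triggers: one stimulation per
  trial window, however many crossings occur.
* **Busy semantics.** New parameters and mock toggles are *rejected*
  during an episode, not queued, mirroring the CommEnable line a physical
  board exposes; the protocol layer surfaces this as an `ok = FALSE`
  reply rather than an exception.
* **Mask rule.** The masking LED is a switched digital line. For square
  trains it mirrors the laser TTL exactly. For sinusoids — which a
  digital LED driver cannot reproduce — it toggles at the train frequency
  with 50% duty over the active window, the closest realisable pattern.
* **Mock scope.** The mock flag applies to whole episodes and all
  channels: during a mock episode every laser line is provably silent
  (this is a tested invariant, not a convention) while masks run
  normally.
* **Loop latency.** A physical board has a small trigger-to-output lag
  from its main loop. The emulation is ideal by default
  (`loop_latency_ms = 0`); a constant, configurable latency is provided
  rather than a stochastic model, since a lag *distribution* is a
  property of specific hardware that software should not invent.

`run_device()` replays an event list through the state machine and then
renders each accepted episode vectorised; because episodes cannot
overlap, this is exactly equivalent to stepping sample-by-sample, and the
tests verify bit-identical replays.

## The protocol

Messages are single JSON objects terminated by one line-break, in both
directions; the transport is an abstract byte stream and a `line_buffer()`
reassembles messages under arbitrary fragmentation. The exact key names
of the original firmware are not public, so the package defines a
canonical schema (top-level `kind`, payload keyed by the `stim_params`
field names) explicitly so that a firmware port could adopt it.

## Calibration

Laser output is calibrated by emitting 10 s pulses at stepped control
fractions — ten equal steps, 0.1 to 1.0, by default — measuring each with
a power meter, and fitting measured mW against fraction by ordinary least
squares (`stats::lm()`; the tests cross-check the closed form). Two
safety-minded choices: requests outside the measured power range are an
error, never an extrapolation, and fractions outside $[0,1]$ (possible
with a negative intercept, i.e. a lasing threshold) are clamped with a
warning. `linearity_check()` warns below $r^2 = 0.98$, a deliberately
conservative default for a device pointed at animals.

## Metrology

* **Edge detection** thresholds at 50% of the per-channel maximum and
  refines each crossing by linear interpolation between the bracketing
  samples, so onset error is below one sample period. Pulses truncated at
  the record boundary are kept (dropping them would bias counts); a flat
  channel returns an empty table rather than an error.
* **Interpulse duration is onset-to-onset.** The alternative
  (offset-to-onset gap) would not equal the period; the frequency
  estimate is `1000 / mean(onset interval)`.
* **Phase** is estimated by quadrature demodulation at the *known*
  stimulation frequency (in this tool `f0` is always known): multiply by
  cosine and sine carriers, low-pass with a moving average over exactly
  one period, and take the four-quadrant arctangent. An undelayed raised
  cosine has phase 0; a pure delay $d$ reads as $-2\pi f_0 d$. An
  independent zero-crossing estimator serves as a cross-check in the
  tests, not as the implementation.
* **Circular statistics.** Phase differences are summarised by the
  circular mean and resultant length after trimming one period of
  transient at each end (the moving-average window is incomplete there).
  Angles are reported in $(-\pi, \pi]$ by default; a $[0, 2\pi)$ wrap is
  offered because a delay-induced offset is naturally a lag on that
  scale, and because at an offset of exactly half a cycle the signed
  convention's sign is decided by floating-point noise while the positive
  wrap is stable.

## What the synthetic experiments show — and what they cannot

The package's validation re-creates the characterisation experiments a
physical device would undergo, at the sizes the hardware work used: 10 s
two-train square episodes (40 Hz, 6 ms pulses; also 50 Hz/5 ms and
200 Hz/2.5 ms), a 10 s pair of 25 Hz sinusoids offset by half a cycle
(20 ms), all sampled at 2 kHz, with randomly timed triggers.

```{r validation}
dev <- virtual_device()
set_params(dev, list(
  stim_params(1, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6),
  stim_params(2, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6)))
ev <- fixture_trigger_train(1, min_gap_ms = 100, t_max_s = 0.1, seed = 1)
run <- run_device(dev, ev, rate_hz = 2000, t_end_s = 10.3)
glance(pulse_stats(run$trace, laser1_ttl))
```

On the ideal device these recover the nominal settings essentially
exactly: that validates the *synthesis-plus-metrology pipeline* (the
rendered signal is what the parameters say, and the statistics read it
back correctly through 12-bit quantisation and 2 kHz sampling). It does
**not** validate hardware: real boards add main-loop jitter, DAC settling,
optocoupler rise times and laser response lag, none of which software can
derive. The measured intrinsic trigger lag of a physical board
(of order a couple of ms) is therefore representable only as the
configurable constant `loop_latency_ms`, and the control-to-light delay
of a real laser is out of scope entirely. What the emulation *bounds* is
the measurement floor: with zero latency, every measured trigger lag is
below one sample period of the virtual DAQ — the same resolution limit a
2 kHz recording imposes on hardware measurements.

## Numerical notes and limitations

* Sampling above twice the train frequency is required for meaningful
  timing estimates; `render_channel()` warns otherwise.
* Traces are plain tibbles; the sampling rate rides along as an
  attribute and is re-inferred from `t_s` (constant spacing enforced)
  when the attribute is lost to a dplyr verb.
* The device object has reference semantics (it is an environment):
  mutators update in place, which is the honest model of an instrument
  handle, but means a device should not be shared between independent
  simulations — create one per run.
* Arbitrary user-supplied waveforms and relayed external analog signals
  are out of scope, as is any electrical model of photodiodes or LED
  drive circuits.
* Test and validation problem sizes (10 s episodes at 2 kHz; 100-set
  oracle sweeps; 200-replicate calibration recovery) were chosen as the
  smallest sizes at which the statistics are stable to well inside their
  tolerances.
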