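---
title: "How phstat works: display OCR, dosing models and the simulated plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How phstat works: display OCR, dosing models and the simulated plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phstat)
```

phstat is a software pH-stat. The instrument it models holds a stirred
reaction at a target pH by watching a bench pH meter through a webcam,
decoding the meter's red seven-segment display optically, and dosing titrant
through cheap pump modules whenever the reading falls below the setpoint.
This vignette explains the models and procedures behind each stage, the
parameters that matter, and what the built-in simulation does and does not
tell you about real hardware.

## Seven-segment display decoding

The display decoder works on the red channel only — the target meters use
red LED displays, so the signal-to-background contrast is best there. A
frame is binarized with a strict threshold (`pixel > threshold`; strictness
is a convention, fixed and documented so that thresholds 0 and 255 have
unambiguous meanings). Each digit box, placed by a `segment_geometry`
(anchor of the first digit, box size, pitch between digits), is probed in
seven thin rectangles at the canonical positions of segments a–g: bar
thickness `max(1, floor(h/10))`, horizontal bars inset by one thickness so
the corners are never ambiguous. A segment counts as lit when at least
`on_fraction` (default 0.5, a robust midpoint) of its probe pixels are on.

The lit-segment set is looked up in the canonical digit map. Only 12 of the
128 possible patterns mean anything (0–9, blank, minus); everything else is
*invalid*, which is a value, not an error: frames grabbed while the meter is
mid-transition routinely produce such patterns, and the correct response is
to discard the frame and wait ~0.1 s for the next one, not to guess.
`decode_display` additionally rejects any reading containing a minus sign or
a blank after a non-blank digit, and allows leading blanks (meters suppress
leading zeros). The decimal point is *not* detected optically: the target
meters have a fixed format, so the point position is part of the
calibration (`decimal_index`, the number of digits left of the point; the
default 5-digit layout with `decimal_index = 2` reads values like 10.553).

Threshold calibration is automated: `auto_threshold` renders the decode at
all 256 thresholds against a frame showing a known value and returns the
midpoint of the widest working interval — the choice most tolerant of
lighting drift, which is the main reason thresholds need re-choosing on real
benches.

The synthetic renderer draws segments at exactly the canonical probe
positions (optionally widened), on a red-dominant background, with optional
Gaussian pixel noise. Renderer and prober share one rectangle map, which is
what makes the zero-noise round-trip exact for *every* representable value
and geometry — the test suite verifies all 14 001 values 0.000–14.000.
What this does **not** exercise: perspective distortion, glare, uneven
illumination, camera focus. On real frames those effects move the usable
threshold interval around, which is why `auto_threshold` maximizes interval
width rather than picking any working value.

## Pump models

**Syringe pump.** A stepper (200 steps/revolution by default) on a 0.8 mm
leadscrew gives `lead / steps_per_rev` = 0.004 mm of plunger travel per
step; through the syringe cross-section this is
`pi (d/2)^2 · mm_per_step / 1000` ml/step — 0.0013 ml with a 20 mm bore,
0.0026 ml with 28.8 mm. The bore is a required field, not a default: nominal
"20 ml" syringes vary by brand. Requested volumes are rounded to whole
steps; the sub-step residual is carried forward in an accumulator so a long
sequence of small doses stays within one step of the requested total
(independent rounding would drift without bound).

**Peristaltic pump.** Delivered volume is proportional to run time (1 ms
resolution) through a coefficient in ml/ms, fitted by `fit_calibration` as
the *ratio of sums* `Σ volume / Σ time` over repeated fixed-length doses —
the pooled-total estimator, which is what dosing fifty 500 ms shots into one
beaker physically measures, and which is first-order robust to per-dose
noise (the per-dose coefficient of variation is reported alongside). The
cheap permanent-magnet motors start erratically: this is modelled as a
`dead_time` (0 ms at 12 V, 40 ms at 9 V by default — free parameters, not
measurements) plus a multiplicative delivery error whose standard deviation
is `sigma0 (1 + v_ref / v)`. `v_ref` acts as a start-up-equivalent volume:
doses comparable to it are dominated by spin-up, so small doses are
relatively noisier, and the 9 V profile (`sigma0` 0.03, `v_ref` 1.0) is
noisier than 12 V (0.01, 0.05). Only these *orderings* are meaningful; the
absolute spreads of any particular bench setup are hardware facts the
simulator does not claim to reproduce. Doses below `min_reliable_dose`
(0.5 ml at 12 V, 1.5 ml at 9 V) raise a flag but are never refused.

Modules speak a one-line ASCII protocol (`IDENTIFY`/`IDENTITY`, `DOSE`,
`STOP`, `GET_CAL`/`SET_CAL`, `ACK`, `ERROR`) over a transport contract of
`write_line`/`read_line`; the in-memory loopback and a virtual module
endpoint stand in for the serial port and the microcontroller firmware.
Free-text fields are percent-encoded by hand because the value grammar must
survive *any* text, including `%` and `=`.

## The adaptive controller

The decision rule is deliberately simple: dose `unit_volume` iff the
reading is valid, strictly below the setpoint, and at least `min_interval`
has passed since the last dose. Equality does not dose (one convention had
to be chosen); invalid readings never dose; and a reading drought of
`stale_timeout` (default 10 s) raises an alarm that terminates the loop —
a safety addition, since an unreadable display must not silently stall an
unattended experiment.

Adaptation concretizes "slow down when the process slows down": time is cut
into consecutive windows of the current `min_interval`; after 4 windows in
a row with no dose, the unit volume halves (floor 0.5 ml) and the interval
doubles (cap 60 s). A dose triggered more than 0.05 pH below the setpoint
reverses one step, so the controller re-accelerates if the process does.
All constants are config-exposed; the defaults (2 ml / 5 s initially,
0.5 ml floor, setpoint 10.55) are the regime for an oxidation that consumes
~2 ml of 0.5 M NaOH per 5 s at its start. The decision tick is 1 s,
matching the 1 s logging frame; readings arriving faster are latest-wins.

A PID mode (`pid_step`, positional form with output clamping and frozen
integral while clamped) is included for completeness but off by default:
with a 20 s electrode lag and a fast initial acid burst, negative-feedback
PID cannot stabilize the first phase, while the threshold rule — which never
doses *more* for a larger error, only as often as allowed — degrades
gracefully.

The logged `cumulative_volume_ml` is the pump's own dispensed total (its
accounting), not the noisy physically delivered volume: that is what a real
instrument can know, and it makes log-vs-pump conservation exactly
testable.

## The simulated plant

Ground truth is strong-electrolyte chemistry: the charge balance
`[H]² + (C_b − C_a)[H] − Kw = 0` solved in closed form (rationalized on the
basic side to avoid catastrophic cancellation — the naive quadratic root
loses ~7 digits at pH 13). Acid generation uses the two-regime form
`r(t) = r_fast e^{−t/τ} + r_slow` (truncated at `duration`), integrated
exactly over each step. The reference parameterization, `r_fast` 2e-4
mol/s and `τ` 600 s, is sized so early neutralization demand is ~2 ml of
0.5 M base per 5 s in the 2.5 L vessel, decaying to a slow tail
(`r_slow` 1.5e-6 mol/s, ~0.5 ml every ≈2.5 min); the priority was matching
those two dosing regimes rather than any particular total consumption. Any
buffering of a real reaction mixture is folded into this effective rate —
that keeps the truth closed-form, at the cost that per-dose pH excursions
are sharper than a buffered mixture would show.

The electrode is a first-order lag (default `τ` = 20 s; meters responding
slowly is the main practical obstacle to tight control) plus Gaussian
reading noise (default sd 0.001 pH, one display quantum). Display frames
are emitted from the *measured* pH; with a configurable probability a frame
is corrupted into a half-lit transition pattern that the decoder rejects.
Each simulation draws all randomness (measurement noise, frame corruption,
pump actuation) from R's global RNG, so `set.seed` makes the whole closed
loop — including the zero-noise case — bit-reproducible.

On the reference 3 h run (10 800 one-second ticks, display decoded
optically every tick; well under a minute of compute) the controller holds
the post-transient pH (t > 2700 s) within about [10.545, 10.62]: the lag
means doses fire when the *true* pH is slightly below the displayed one, so
the measured peak after a 0.5 ml dose stays clear of the 10.65 band edge.
Injecting 10 % corrupted frames changes the dosed total by well under 1 % —
a rejected frame merely postpones a dose by a second or two.

## Titration

`titrate` adds increments only after the reading has been *stable*: the
change across a `stability_window` (default 5 s) is at most
`stability_epsilon` (default 0.005 pH — endpoints of the window are
compared, not variance; with a display quantum of 0.001 anything tighter
than ~0.005 flaps on noise). Schedules allow coarse-then-fine increments
mid-run. The recorded x-axis is the pump's dispensed total — for a syringe
pump, step-quantized — which with actuation noise off is exactly what
entered the vessel; near the equivalence point of a strong–strong titration
this distinction is worth several pH units, so recording nominal requested
volumes there would be self-inconsistent.

`equivalence_point` uses the first-derivative method: central finite
differences of pH against the (possibly uneven) volume grid, peak location
refined by a parabola through the peak and its neighbours (vertex accepted
only if the fit is concave and inside the bracket). Parabolic refinement
was chosen over a second-derivative zero crossing because it needs three
points rather than five and behaves on uneven grids; the method is tagged
in the result. A curve whose maximum slope is below 0.5 pH/ml is reported
as having no equivalence point rather than a meaningless argmax. For the
classic 10 ml of 0.1 M HCl vs 0.1 M NaOH the estimate lands within one
increment of the 10 ml stoichiometric point for increments from 0.05 to
0.5 ml.

## Numerical and design choices, in brief

* Pixel coordinates are 0-based, row-major, origin top-left, stated once in
  the geometry documentation to avoid off-by-one drift between renderer and
  prober.
* Binarization is strictly `>`; dosing triggers strictly `<` setpoint;
  both conventions are arbitrary but must be fixed.
* Volume→steps rounds to nearest with a carried residual; volume→runtime is
  exact at 1 ms resolution plus dead time.
* The charge-balance root uses the rationalized form on the basic side;
  residuals stay below 1e-9 relative across the tested range.
* Generation kinetics integrate in closed form, so step size only affects
  controller timing, not chemistry accuracy; the loop runs at the 1 s
  logging period.
* Module persistence (calibration in module memory) is modelled at the
  protocol level (`GET_CAL`/`SET_CAL`), not as byte-level memory emulation.

## Limitations

The simulation validates the *software*: decision logic, decoding, unit
conversions, conservation, protocol. It does not validate hardware physics:
real peristaltic spread magnitudes, syringe drop formation (surface tension
sets the practical resolution, not the 0.0013 ml/step arithmetic), webcam
optics, temperature dependence of Kw, CO₂ absorption, activity
coefficients, or the chemistry of any real oxidation (amounts of functional
groups introduced, true NaOH demand curves). Passing the in-package tests
therefore certifies the toolkit's logic under the stated models, not the
performance of any particular bench build.
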