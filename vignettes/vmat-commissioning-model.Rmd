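---
title: "The delivery model behind vmatqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The delivery model behind vmatqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## What the package models, and for whom

Commissioning volumetric-modulated arc therapy (VMAT) means convincing
yourself that a linac can *simultaneously* modulate dose rate, gantry speed
and MLC leaf positions and still deliver the planned fluence. On
Elekta-style machines the dose rate is not continuous: the controller runs
at discrete bins, each half the previous one, counting down from the
machine maximum (600 MU/min nominally: 600, 300, 150, 75, 38, 19 MU/min).
The classic commissioning suite drives each delivery axis to (and past) its
configured maximum with purpose-built dynamic fields — picket fences,
matched dose-rate/gantry-speed strips, MLC-speed strips, rapid leaf
reversals, dose-rate change junctions — and reads the result off an EPID or
a gantry-mounted diode array.

`vmatqa` implements that whole loop in software: the test-plan generators,
a kinematic model of the delivery (bin selection, axis speed limits,
injectable delivery errors), fluence rendering onto detector models, and
the analyses that turn images and chamber readings into QA reports. It is
aimed at physicists who want to exercise and validate the *analysis* side
of a commissioning programme without a machine, inject known errors and
check they are caught, or reason quantitatively about what a given
controller imperfection does to fluence.

All geometry is in cm at the isocenter plane; cross-plane `x` is the leaf
travel direction (positive toward bank B); dose rates are entered in
MU/min and handled internally in MU/s; MU values are quantized to the
0.1 MU entry resolution of the control software.

## The machine model

`machine_limits()` holds the constraint set: maximum dose rate
$\dot{D}_{max}$ and the number of halving bins, leaf speed $v_{max}$
(2 cm/s), backup-jaw speed (1.5 cm/s), gantry speed $\omega_{max}$
(6°/s), the 0.5 cm minimum leaf-pair gap, and the controller floor
$\Delta MU/\Delta\theta \ge 0.1$ MU/°.

The controller rule (`select_bin()`): a segment of $\Delta MU$ monitor
units delivered at rate $R$ takes $\Delta MU / R$ seconds, so an axis
with travel $d$ must move at $d \, R / \Delta MU$. The selected bin is
the highest rate at which every axis keeps up. Two consequences drive the
speed tests:

* with $MU = \dot{D}_{max}\, d / v_{max}$ the axis runs at *exactly* its
  maximum at the top bin; one 0.1 MU step less forces a drop to half
  maximum — the observable used to verify the configured maxima, inverted
  by `invert_max_speed()` as $v_{max} = \dot{D}_{max}\, d / MU^{*}$;
* custom test files can *prescribe* a lower dose rate per segment (the
  `dr_cap` control-point column). Without this a matched "max/8 : max/8"
  strip would be indistinguishable from "max : max" (same MU per degree)
  and the controller would run everything flat out.

Speed-capped segments (the deliberate 1.2× strips) are not rejected:
`select_bin()` returns the best feasible bin and the simulator extends the
segment time, conserving MU — the "dose is still correctly delivered"
behaviour the tests are designed to confirm.

## Test-plan designs

**Picket fence** (`gen_picket_fence()`). A 5 mm gap sweeps the field at
1 cm/s; at each picket the leading leaf pauses at the strip's far edge and
then the trailing leaf pauses at the near edge for the same time, so only
the 1 mm strip stays open longer (by `width / speed`) and one leaf always
moves. A short proof shows this shape is forced: the extra open time at a
point is the trailing leaf's delay minus the leading leaf's delay there, so
a bright band *narrower than the gap* requires the leading pause to happen
at the strip edge — which transiently narrows the pair gap by the strip
width. A 5 mm fence therefore dips to 4 mm during the pause (visible in
`validate_plan()` output), and the intentional-error fence widens the gap
to 6 mm precisely so adjacent leaves stay near the 5 mm minimum. Error
specs (`widen_to`, `shift`) alter only the named pair.

**Matched DR:GS strips** (`gen_dr_gs_strip_test()`). Eight 3 cm strips at
dose-rate : gantry-speed fractions 1/32 … 1, then (1.2, 1) and (1, 1.2).
A 3 cm slit dwells on each strip while the gantry arcs (the detector is
gantry-mounted, so the image is static in the gantry frame) and translates
between strips at $0.75\,v_{max}$ under a fixed max/8 dose rate, giving
2 s and 2.5 MU per move and a floor margin of
$(\dot{D}_{max}/8)/\omega_{max} = 0.208$ MU/° at full gantry speed. Strip
arc spans follow $\theta_i = MU_{strip}\,\omega_i / \dot{D}_i$: 12° for
every matched pair at the default 20 MU per strip. Each strip centre
receives the dwell MU plus equal contributions from the arriving and
departing moves, so the planned dose is constant across strips.

**MLC-speed strips** (`gen_mlc_speed_strip_test()`). A sweeping 8 mm gap
crosses seven 3 cm strips whose leaf speed and dose rate scale together
(1/32 … 1, then 1.2×): the point dose $g\,\dot{D}/v$ and the strip MU
$w\,\dot{D}_{max}/v_{max} = 15$ MU are then constant. The gantry speed is
constant at $(\dot{D}_{max}/32)/0.1 = 3.125$ °/s — the value that puts the
slowest strip exactly on the MU-per-degree floor. Lateral 1.5 cm strips at
half speed bring the field to the open-field size used for normalization.
A 5 mm gap is refused for this test: sweeping the minimum gap at maximum
leaf speed is known to deliver poorly.

**Leaf reversals** (`gen_reversal_test()`). A constant-speed gap zigzags
across five strips, with junction centres at −5.6, −1.6, 3.6 and 7.6 cm
and a four-cycle oscillation centred at 10.6 cm (these positions make the
middle strip 5.2 cm wide; the others are 4 cm). The zigzag gives
centre-of-strip traversal counts {1, 3, 3, 3, 9}, recorded per strip, so
dose grows with traversal count; every programmed direction change is
recorded in `$meta$turns` together with the aperture edge where
over-travel overdose appears and the local nominal pass count — the
inputs the analyzer needs to invert over-travel. One plan per speed factor
{1.0, 0.95, 0.90, 0.18}; the 0.36 cm/s delivery is the reference with
negligible over-travel, at half-maximum dose rate throughout.

**Dose-rate changes** (`gen_dr_change_test()`). Eight 3 cm strips whose
prescribed rates step max/32 → max by factors of two, the last two strips
forming the extreme max/32 ↔ max jump (the decrease variant mirrors the
steps); leaf speed constant at 1 cm/s, gantry constant at 3.125 °/s, and a
0.25 cm/s reference delivery for normalization. Fluence per strip is
proportional to its dose rate; the junctions probe bin-switching.

**Utility fields** (`gen_utility_fields()`): static open fields per bin
(normalization), 36/1000 MU static and 360° arc monitor-chamber
deliveries, and the gravity sweep — a 1 cm gap crossing 23 cm at
0.74 cm/s while a 180° arc completes in exactly the sweep time
(180/(23/0.74) = 5.79 °/s).

## The simulator

`simulate_delivery()` walks the control-point segments. Axes move at
constant speed per segment; the dose rate is the selected bin; when an
axis would over-speed, it runs at its maximum and the beam idles once the
segment MU completes. Sampling is a fixed `dt` (0.01 s default) with
exact knots at control points, MU-completion instants and over-travel
breakpoints, so closed-form comparisons are clean. Total MU at every
control point is exact by construction.

**Bin switching.** Bin transitions take a finite time (0.25 s default).
Modelling it as "old rate holds, then instant switch" turned out to dump
the accumulated MU debt at the control point while the axes park, creating
junction artefacts an order of magnitude wider than the settle distance
the switching time implies. The model used instead: the delivered rate
ramps linearly from the old to the new bin over the switch window,
*centred* on the control point (the controller knows the plan and
anticipates). The ramp integrates to exactly the step's MU, so
control-point MU stays exact, and the fluence artefact is confined to
`leaf speed × switch time` — 2.5 mm at 1 cm/s, which is what the junction
analysis then measures. With the window set to zero the residual junction
signal is only the 0.1 MU entry quantization of the lowest-dose strips
(≤ 1 mm above 3%).

**Over-travel.** At every leaf direction reversal the leaf proceeds past
the turn point by `reversal_overtravel` at its incoming speed, then
returns to the planned trajectory (a triangular excursion; the return leg
runs at three times the approach speed because the planned position is
already retreating). The excursion redistributes open time: the leading
aperture edge gains $2\delta^2/v$ of open time per turn and the trailing
edge loses the same amount one gap-width away. Against the local nominal
open time $p\,g/v$ ($p$ = nominal pass count, $g$ = gap), the fractional
excess area at an edge with $n$ coincident turns is $2n\delta^2/(p\,g)$,
inverted by `reversal_analysis()` as
$\hat\delta = \sqrt{A\,p\,g/(2n)}$. Where two opposite turns share a
junction, one turn's trailing loss overlaps the other's leading gain and
the net signal largely cancels — such edges are flagged `interference` and
excluded from the plan-level estimate (the median over clean edges).
Noiseless recovery is within about 10% for injected over-travel of
0.1–0.5 mm.

## Detectors and rendering

`render_fluence()` integrates dose rate × open-time per pixel with ideal
binary apertures (leaves plus backup jaws) and fractional pixel coverage
at the aperture edges. Identical leaf-pair trajectories are rendered once
and broadcast to their rows. The EPID model uses a 0.256 mm projected
pitch over 28 cm with a 0.5 mm Gaussian point spread — without some
optical blur a rectangular 1 mm picket would image as a flat-topped
plateau with tied maxima, whereas measured peaks are single pixels; the
diode-array model samples at 1 cm spacing over 32 cm with no blur.
Multiplicative noise and vertical pixilation lines are applied only at
render time under an explicit seed; everything is deterministic when they
are off. No scatter, leaf transmission, tongue-and-groove, energy response
or absolute dose calibration is modelled: all fluence is relative, and
beam energy is configuration only.

## Analysis choices

* **Peak finding** is the pragmatic rule used at the workstation: the
  local maximum pixel per picket window; ties are flagged and broken
  toward smaller `x`, never silently resolved.
* **Sub-pixel picket metrics**: the strip width comes from the excess
  fluence area above the sweeping-gap baseline,
  $w = \sqrt{A\,g/h_0}$ — area is invariant under blur and pixelisation,
  so the 1.5 mm widened strip is recovered to ~1% where a half-maximum
  crossing would be biased by the point spread. The centre is the excess
  centroid; position errors are judged against the per-picket median
  across pairs, which cancels common-mode offsets. Both intentional error
  types (1.5 mm width, 0.5 mm shift) are detected with zero false flags
  at the 0.5 mm tolerance across randomized pair placements.
* **Normalization** is pointwise `100 · test / open` with pixels below 5%
  of the open-field maximum masked rather than divided. Because simulated
  fluence carries no absolute scale, `strip_stats()` (and the junction
  analyses) rescale so the median strip reads 100%: the reported quantity
  is strip-to-strip uniformity, which is exactly what the constant-dose
  constructions guarantee.
* **Smoothing** is the centred moving average with truncated edges: 7
  pixels (1.8 mm) for strip readings, 3 pixels (0.77 mm) for junction
  profiles. **Despiking** removes samples deviating >3% from both
  neighbours 0.5 mm away in their own profile, averaging the surviving
  acquisition; positions spiked in both acquisitions are returned missing.
* **Flatness and symmetry** use the IEC-style definitions —
  $100\,(max-min)/(max+min)$ over the central 80% of the open field and
  the largest point-vs-mirror difference — applied to relative profiles.
* Strip readings exclude the 0.5 cm ramp segments by sampling at strip
  midpoints: 12 diodes across the central 11 cm (diode mode) or the
  7-pixel-smoothed midpoint of a half-leaf-width band 0.5 cm off-axis
  (EPID mode).

## What passing tests do and do not show

The simulator is the package's own physics: a delivery with zero error
model is perfect by construction, so end-to-end checks (strips all 100%,
pickets within half a pixel) validate the *consistency* of generator,
controller model, renderer and analyzer — not the behaviour of any real
linac. Injected errors show that the analyses recover known perturbations
at the stated tolerances (error magnitudes to ~1%, over-travel to ~10%).
Real images add scatter, leaf transmission, detector calibration
structure and beam profile shape that the ideal renderer does not emulate;
analyses that normalize to measured open fields absorb much, but not all,
of that. The bundled example readings under `inst/extdata/` are fixed
commissioning numbers used to exercise the report arithmetic (stability
ratios, linearity, centre-pixel deviations), not simulated quantities.

## Problem sizes and tolerances

The test suite simulates at `dt = 0.01` s and full EPID resolution
(≈1100 px across); the sweep-fluence closed form is matched to better
than 0.5% and the suite completes in a few minutes on one core. The
deliberate tolerance choices: bin feasibility comparisons carry a 1e-9
relative guard; the MU-per-degree floor check allows half an MU-resolution
step (plans are quantized at emission); the total-arc limit (358°) is
enforced at generation with the limiting sum reported.

## Known limitations

* The traversal pattern of the reversal test is a reconstruction: the
  junction positions are fixed by the published layout but the zigzag
  realizing "dose grows with traversal count" is the package's own, with
  counts {1, 3, 3, 3, 9} recorded in metadata rather than assumed.
* Whether a real controller steps through intermediate bins during a
  large dose-rate change is unknown; the centred-ramp model is a stand-in
  with the right settle distance, flagged in the event log (`lag` column).
* Gantry inertia compensation is exposed as a configuration parameter
  only (default 0) and never calculated.
* Collimator rotation is static; interdigitation constraints beyond the
  minimum-gap check are not modelled; the vendor's binary file format is
  out of scope (plans serialize to JSON/CSV).
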