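---
title: "Models and methods behind optomotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optomotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomotor)
```

`optomotor` analyses course-control behaviour of flies walking freely under
closed-loop visual stimulation, and the bilateral lobula-plate circuit
thought to produce it. This vignette explains the models the package
implements, the choices made where the underlying methods left room, and
what the synthetic generators do and do not emulate. Every number quoted
here is computed by the package's tests or scripts; nothing is asserted
from memory.

## Conventions

All arena angles are **CCW-positive** in a y-up coordinate frame. "CW"
rotation means the pattern angle decreases over time. Decomposing a rotating
pinwheel about the body axis then gives: CW rotation presents back-to-front
(BtF) motion to the left eye and front-to-back (FtB) motion to the right
eye; CCW is the mirror image. `local_motion_direction()` encodes this table,
and `condition_drives()` uses the same convention for the network model.
Camera images are y-down with angles measured from +x toward +y;
`pose_to_arena()` performs the flip (12 px/mm).

When both rotation directions are pooled, `align_to_stimulus()` negates the
angular velocity of trials whose stimulus sign is negative under this
convention, so that **positive always means turning with the stimulus**
("syn"); saccades against it are "anti".

## The synthetic walker

`simulate_walker()` generates closed-loop trials with exact ground truth.
Each trial is 5 s static + 5 s motion at 60 Hz in a 55 mm arena. Body angle
integrates a smooth turning process plus saccadic velocity pulses:

* **Smooth channel** - white noise low-pass filtered at 2 Hz (SD 20 deg/s)
  plus a constant, condition-dependent drive during the motion period.
  Trials whose smooth channel would exceed 100 deg/s are rescaled, never
  clipped, so the channel stays band-limited below 5 Hz.
* **Saccadic channel** - raised-cosine (Hann) angular-velocity pulses with
  peaks drawn from U(300, 600) deg/s and supports from U(80, 200) ms,
  injected at Poisson times with a 150 ms refractory between events. The
  refractory keeps successive events separable without saturating the
  motion window at realistic rates; event counts are truncated only when a
  draw cannot be packed, and a rate whose expected occupancy exceeds the
  window is an error.
* **Speed** - a positive low-pass noise process around 10 mm/s.
* **Walls** - travel is specularly reflected 5 mm from the wall; the
  reflection turn is booked on the smooth ground-truth channel (it is a real
  turn), which typically excludes the trial through the jump rule, as such
  events were excluded in the real experiment. Trials start within 8 mm of
  the centre, so fewer than 1% of trials reach the wall.

The ground truth satisfies `smooth + saccadic == total` **exactly**,
framewise - this is the invariant the decomposition analysis is tested
against. The stimulus anchor follows the body angle with the experimental
3-frame closed-loop delay.

Two built-in agents drive the linearity analysis. The **linear** agent's
full-field drive and saccade rates are, by construction, the sums of the two
unilateral ones (drive 30 = 20 + 10 deg/s; syn rates 0.8 = 0.3 + 0.5 /s;
anti rates 0.4 = 0.2 + 0.2 /s). The **antagonistic** agent mirrors the
phenomenology of real flies: full-field rotation drives strong smooth syn
turning (35 deg/s), unilateral FtB drives anti-saccades (1.2 /s) with
slightly negative smooth drive, unilateral BtF a weak syn response. These
magnitudes are declared assumptions - the study this package accompanies
reports no quantitative saccade-amplitude distributions - chosen once to
give realistic event counts (a few saccades per 5 s trial) and turning
speeds (tens of deg/s).

What the walker does **not** emulate: visual-system dynamics (drives are
abstract per-eye FtB/BtF signals), biomechanics, response latencies or
adaptation, head movements, or any dependence of the drive on the closed-loop
stimulus angle. Passing tests on this generator therefore validate the
*analysis chain* - detection, decomposition, exclusion, alignment,
statistics - not any claim about real fly behaviour.

## Preprocessing

Following the standard pipeline: heading is unwrapped, speed and angular
velocity are framewise differences times the frame rate, then denoised by a
centred rolling median followed by a centred rolling mean (both 3 frames,
~50 ms; edges use shrinking windows, so the first/last frame pass through).
Jumps are frames above 100 mm/s or 1000 deg/s, flagged on the smoothed
series (the source method lists smoothing before jump detection but does not
say which series the threshold reads; we apply it to the smoothed one).
Trials are excluded when they contain a jump frame, come within 5 mm of the
wall, or are inactive throughout; "inactive" is implemented as mean speed
below 1 mm/s (configurable - no number is given in the source). A single
exclusion reason is recorded with priority jump > wall > inactive.

## Saccade detection

The detector band-isolates the angular velocity in 10-20 Hz with a
**bior2.6 stationary wavelet transform**: the series is reflect-padded to a
dyadic multiple, decomposed with the periodized à-trous algorithm, every
coefficient outside the detail levels whose nominal dyadic bands intersect
10-20 Hz is zeroed (at 60 Hz that keeps d1 ~ 15-30 Hz and d2 ~ 7.5-15 Hz),
and the series is reconstructed. The transform is implemented in the
package (analysis and synthesis verified to reconstruct exactly, and pinned
against an independent reference implementation by a frozen fixture).

Two properties of band-passed pulses shaped the event logic, and both are
measurable with the package itself:

1. a raised-cosine pulse of 80-200 ms support keeps only 6-43% of its peak
   after band isolation, so a 200 deg/s criterion applied to the
   reconstruction would reject nearly everything it is meant to find;
2. the reconstruction of a pulse is an oscillatory wave packet whose
   individual lobes are about one carrier period wide, so lobe widths say
   little about event duration.

The detector therefore uses the reconstruction for **localization** and the
raw trace for **geometry**: candidates are local maxima of the Hilbert
envelope of the reconstruction above a 10 deg/s floor (an order of
magnitude above the in-band leakage of smooth turning bounded by 100 deg/s
and band-limited below 5 Hz); within a window around each candidate the raw
angular velocity is referenced to a local flanking-median baseline, the
event peak is the largest deviation, onset and offset are the half-peak
crossings (sub-frame interpolated), and the width is reported as twice the
half-peak width - exactly the support of a raised-cosine velocity pulse.
Events are kept when the width lies strictly inside (50, 250) ms and the
raw angular speed inside the event exceeds 200 deg/s. Candidates that
refine onto the same raw event merge. Displacement integrates the raw
signal over the event (trapezoid).

Because geometry is computed on the raw trace, the detector and an
independent **brick-wall FFT oracle** realising the same dyadic band
(7.5-30 Hz at 60 Hz) agree event-for-event on 98-100% of benchmark trials;
on the standard benchmark (50 x 10 s trials, planted peaks >= 300 deg/s,
supports 80-200 ms, >= 300 ms apart, smooth background <= 100 deg/s below
5 Hz) the detector reaches hit rate 1.0 with zero false discoveries and a
mean onset error of ~18 ms, and it detects nothing on 100 smooth-only
trials. These are the quantities `scripts/acceptance.R` recomputes.

Turning decomposes exactly: the saccadic channel equals the input inside
event windows and zero elsewhere; the smooth channel is the remainder.
Cumulative per-class displacements are trapezoids of the zero-padded class
channels, so smooth + syn + anti displacement equals the total cumulative
displacement identically. A known consequence of half-peak event edges is
that pulse tails leak into the smooth channel; the leak is bounded by the
half-peak definition and does not affect the conservation identity.

## Path straightness

Forward-walking bouts are inter-saccade periods longer than 333 ms (20
frames) with mean speed above 5 mm/s. For each interior point a 333 ms
window is centred on it; the chord joins the window endpoints and the
deviation is the perpendicular distance from the chord to the sample at the
window's temporal centre (no interpolation - the source does not specify
any). Bout straightness is the ratio of summed chords to summed deviations
with an `eps = 0.01` mm floor, so an exactly straight bout returns the
finite value `sum(chords) / eps` flagged `straight`. On a circular arc the
chord and deviation have closed forms (`2R sin(L/2R)` and
`R(1 - cos(L/2R))`); with R = 5 mm and window arc L = 2 mm these are
1.98669 mm and 0.09967 mm, which the tests verify to 1e-6. Because the
source does not state the aggregation level, the bout table carries one row
per bout and per-trial or per-fly aggregation is left to the caller.

## The linearity test

If the two eyes contributed independently, the full-field response would be
the sum of the unilateral FtB and BtF responses. `linear_prediction()` sums
the two per-fly unilateral mean time series (per-fly condition means, not
resampled trial pairs - the pairing is not specified in the source);
`prediction_error()` subtracts the prediction from the actual full-field
mean and averages over the 5 s motion period (the averaging window is
ambiguous in the source; the motion period is the default and the full
trial is available from the error series). Group inference is a one-sample
two-sided t-test of per-fly mean errors against zero, with the two-sided
Mann-Whitney U (exact for small untied samples) available for group
comparisons. No multiple-comparison correction is applied, matching
per-panel testing practice.

At the benchmark scale (15 simulated flies x 200 trials x 3 conditions) the
linear agent's group mean error is a few tenths of a deg/s with p well
above 0.05, and the antagonistic agent's is ~ +78 deg/s with p < 1e-20 -
the package's null and positive controls. These runs skip the per-trial
saccade decomposition (the control statistics need only the total channel);
the decomposed errors, which sum exactly to the total error framewise, are
exercised at smaller scale in the unit tests and in
`analysis/03_linearity_test.R`.

## Patch-clamp analyses

* **Rolling baseline**: a centred 60 s rolling mean is subtracted (cumsum
  implementation, shrinking edges); records shorter than the window fall
  back to global-mean subtraction and are flagged.
* **Binning**: responses are averaged in 16.6 ms stimulus-frame bins, with
  half-open sample attribution so a value held constant over a frame is
  recovered exactly.
* **Receptive fields**: a 10 x 2 degree bar visits every node of a 5-degree
  grid (140 x 80 degrees; the screen span) in the four cardinal directions.
  Each grid point's vector is the response-weighted sum of direction units.
  For a noiseless linear cell this vector sum equals exactly twice the
  planted field (`sum over the 4 cardinal units d of (F . d) d = 2F`),
  which the tests verify to machine precision; with per-frame noise at
  one-fifth of the peak response and 3 repetitions, the mean cosine
  similarity to the planted directions on points above 30% of maximum is
  ~0.99. A constant-latency response shift is available and defaults to 0
  (no latency correction is described in the source). Grid binning at
  5 degrees is a default chosen for legibility, not a stated value.
* **Field metrics**: areas above 30%/60% of the maximum vector length are
  solid-angle weighted (cos(elevation) per cell). Because "total
  sensitivity" can be read as the sum of magnitudes or the magnitude of the
  sum, both contralateral shares are computed and labelled
  (`share_sum_abs`, `share_vec_sum`); the grid column on the midline
  belongs to neither hemifield.
* **Power bands**: plain periodogram per repetition, averaged, normalised
  to unit total; band fractions over [0, 10] and (10, 50] Hz (half-open at
  10 Hz, so the ambiguous 10-11 Hz interval is counted once). A 20 Hz tone
  lands >= 99% in the mid band, a 5 Hz tone >= 99% in the low band, and the
  spectrum sums to 1 +/- 1e-9.
* **Flashes and gratings**: flash transients are peak deviations from a
  pre-event baseline within 0.5 s of onset; grating responses subtract the
  preceding static-period mean, and direction tuning is normalised per
  cell.

The scan simulator holds each frame's (noisy) response constant across that
frame's voltage samples; it does not model membrane dynamics, spiking, or
response latency, so reconstruction tests validate attribution and
averaging, not biophysics. The screen's spherical pre-deformation is out of
the numeric core.

## The bilateral HS-H2 network

Eight cells (HS, H2, bIPS, uLPTCrn in both hemispheres) form a linear
steady-state rate network `(I - W + L_g) V = D s`, where `L_g` is the graph
Laplacian of the gap-junction edges (each edge contributes `+g` to both
diagonals, `-g` off-diagonal): ohmic, bidirectional and current-conserving
coupling. An optional half-wave-rectified mode solves the fixed point by
damped iteration (damping is needed because the Laplacian can push the
recurrence spectral radius past 1 even though the steady-state system stays
well conditioned - the direct path checks the condition number instead).

The reference circuit's exact weight table is not republished in the source,
so the default motif is an explicit assumption set satisfying the stated
constraints: HS receives an ipsilateral FtB-minus-BtF opponent drive (weight
0.8), H2 receives ipsilateral BtF (1) plus **0.1 contralateral FtB**, the
**contralateral chemical input to HS is 0** (contralateral BtF reaches HS
only through the HS-contralateral-H2 gap junction), bIPS copies the
contralateral H2, and uLPTCrn receives ipsilateral HS (1) minus ipsilateral
bIPS (0.8). Two defaults were calibrated against the qualitative claim the
model must reproduce - that electrical coupling makes *every* cell more
rotation-selective: the HS drive weight 0.8 places the gap-coupled H2
forward/backward response crossing outside the studied conductance range
(with weight 1 it sits at g = 0.82 and makes H2's DI non-monotone inside
[0, 1]), and the unequal uLPTCrn branch weights prevent the gap effect from
cancelling exactly in the HS-minus-bIPS difference.

The Discrimination Index per cell is
`DI = (OF_trans - OF_rot) / (|OF_trans| + |OF_rot|)` with each OF term the
max-minus-min response over the corresponding condition pair; +1 is purely
translation-selective, -1 purely rotation-selective, and a degenerate
all-zero cell is defined as 0 and flagged. Under the defaults the DI is
strictly below its uncoupled value for every cell at every g in (0, 1] and
monotone non-increasing across the sweep. Setting g = 0 reproduces the
chemical-only model exactly and equals the `shakB` perturbation.

Perturbations: `shakB` zeroes gap conductances; `silence_HS_chem` /
`silence_H2_chem` zero the cell type's chemical output weights;
`kir_HS` removes both chemical and gap outputs of HS. In this motif,
removing the gap junctions or H2's chemical outputs raises the mean DI
(less rotation-selective), while silencing HS's chemical outputs lowers
uLPTCrn's DI - silencing destroys the opponent cancellation that made
uLPTCrn translation-selective. Whether the reference circuit behaves the
same way depends on weights that are not published; the package reports
what this motif does.

## Tracking

`fit_pose()` thresholds the frame (the fast online body threshold is a
required configuration value; it is not published), labels connected
components (`EBImage::bwlabel`, restricted to the foreground bounding box),
and fits the largest component's second-moment ellipse. Components smaller
than 20 px, absent, or touching the border are flagged; a near-circular
component (eigenvalue ratio < 1.1) has no defined major axis and is flagged
degenerate. `resolve_heading()` computes two-threshold Otsu classes on the
expanded bounding box only - on the full frame the bright background would
dominate the histogram - takes the darkest class as body and the
intermediate class as wings, and picks the body-axis direction closer to
the wing-to-body vector (wings trail; a `flip` flag covers rigs with the
opposite contrast ordering). On rendered 1024 x 1024 frames swept through
all 360 headings the recovered orientation is within 0.8 degrees, the
centroid exact, and the 180-degree disambiguation correct for every frame.
The renderer and tracker share one image convention, so these
render-and-recover results validate the geometry; real-video artefacts
(reflections, shadows, motion blur) are out of scope.

## Problem sizes and seeds

The shipped tests and the acceptance script use the benchmark sizes stated
throughout: 50 benchmark trials (plus 100 null trials) for the detector,
15 flies x 200 trials x 3 conditions per agent for the linearity controls,
a 493-node receptive-field grid with 3 repetitions, an 11-point conductance
sweep, and a 360-frame tracking sweep. All generators are pure functions of
their parameters and a seed; the acceptance script derives every stream
from its `--seed` argument.
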