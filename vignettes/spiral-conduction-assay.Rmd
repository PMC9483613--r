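---
title: "Measuring conduction wavelength on a 1D spiral cardiomyocyte assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conduction wavelength on a 1D spiral cardiomyocyte assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralmap)
```

## The scientific problem

Reentrant atrial arrhythmias are sustained when an excitation wave can
return to tissue that has already recovered. Two endpoints govern that
possibility: the conduction velocity (CV, cm/s) of the depolarisation
wavefront, and the duration for which tissue stays refractory — the
effective refractory period (ERP) or, as a surrogate, the action-potential
duration at 80% or 90% repolarisation (APD80/APD90). Their product, the
conduction wavelength

$$\mathrm{WL} = \mathrm{CV} \times \mathrm{ERP}
 \quad (\text{or } \mathrm{CV} \times \mathrm{APD_{80}}),$$

is the spatial extent of tissue depolarised by one wave and is the single
most informative index of reentry risk: a circuit shorter than WL cannot
sustain itself.

On a standard 2D monolayer WL cannot be observed directly — the wave leaves
the field of view long before it repolarises. Winding a single narrow
(200 um) line of cardiomyocytes into an Archimedean spiral packs several
centimetres of 1D conduction path into the ~65 mm^2 field of a low-power
objective, so one camera frame can contain an entire wave: the distance
from the end of depolarisation to the start of repolarisation can be read
off the image as the directly *measured* WL and compared with the
*calculated* CV x APD80.

This package implements the complete computational side of such an assay:

* the spiral micropattern geometry (design, raster mask, arc-position
  bookkeeping);
* a seeded kinematic simulator that renders wave propagation as
  voltage-dye image stacks, line scans, microelectrode-array (MEA)
  recordings, tissue-slice style optical maps, patch-clamp traces, and
  S1–S2 capture series — with closed-form ground truth;
* the analysis chain that recovers CV, APD, ERP, and both wavelengths,
  maps activation and APD90 over 2D fields, and classifies single-cell
  action potentials as nodal, atrial, or ventricular.

## The spiral geometry

The pattern is an Archimedean spiral $r(\theta) = r_0 + p\,\theta/2\pi$
with constant pitch $p = d_l + d_s$ (line width plus gap, centre to
centre). Its arc length is available in closed form, which is how the
default design was calibrated: the two published pattern lengths — 5.5 cm
for the standard design and 7.9 cm with one extra turn — uniquely pin the
two free parameters, giving $n_{\text{turns}} = 3.5763$ and
$r_0 = 1372.7$ um. These are frozen constants; `default_design()` always
returns this geometry.

```{r geometry}
d <- default_design()
d
c(length_cm = total_length(d),
  extended_cm = total_length(add_turn(d)),
  footprint_mm2 = footprint(d))
```

Because "footprint" is ambiguous for a spiral, both an axis-aligned
bounding box (default) and an origin-centred enclosing circle are
provided; both stay under the 65 mm^2 field of a 2x objective.

## The synthetic data model

Propagation is kinematic: the site at arc position $x$ activates at
$|x - x_{\text{stim}}|/\mathrm{CV}$ after each 2 Hz stimulus and plays a
fixed action-potential template. This deliberately simple model has exact
closed-form ground truth for every downstream estimator, which is the
point of the synthetic module: a failure in a recovery test is a failure
of the analysis chain, never an ambiguity of the data generator. A
reaction–diffusion cable model is deliberately out of scope.

The template is a linear upstroke (3 ms for optical signals) followed by a
normalised sigmoid repolarisation with sharpness $k$; every duration level
is analytically invertible, so `ap_template_optical(apd80 = 180)`
reproduces its APD80 to machine precision. Optical templates default to a
squarish shape ($k = 1$ ms) appropriate for processed voltage-dye signals;
patch-clamp templates solve the sigmoid parameters from a target APD90 and
APD90/APD50 ratio, with the upstroke duration following from
APA / dV/dt~max~.

Fluorescence follows
$F = F_0\,(1 + a\,V)\,(1 - \beta t) + \varepsilon$, with dye fraction
$a = 0.02$ (a ~2% peak dF/F over a bright baseline, typical for
voltage-sensitive dyes at low magnification), Gaussian shot noise
$\varepsilon$ with SD 0.5% of baseline per pixel per frame, and a linear
photobleaching drift $\beta = 0.2\%$/s — over a 10 s recording the drift
is therefore the same order as the signal, which is exactly why the
pipeline's scaling and detrending steps exist. Full frames are rendered at
30 fps (300 frames, 10 s) on a 40 um pixel grid; line scans at 150 Hz;
restitution for the S1–S2 protocol is a single-exponential recovery of APD
and CV with an absolute diastolic-interval capture threshold — the
simplest monotone model the protocol needs. One integer seed determines
every simulated byte.

What the generator does *not* emulate: motion artifacts beyond a simple
sub-baseline dip, spatially correlated noise, cell-to-cell APD
heterogeneity, source–sink effects at the stimulus site, and rate
adaptation during the 2 Hz train (the assay paces precisely to suppress
restitution). Passing recovery tests therefore demonstrate the
correctness of the analysis chain under controlled conditions, not its
robustness to every pathology of real recordings.

## The spiral analysis chain

```{r chain, eval = FALSE}
cfg <- spiral_sim_config(cv = 20, apd80 = 180, seed = 11)
stack <- simulate_spiral_recording(d, cfg)
ls <- simulate_linescan(d, cfg, c(0.1, 0.3), c(5.2, 5.4))
analyze_spiral_recording(stack, d, ls, extraction_width = 5)
```

1. **Profile extraction** — mean intensity over a 10-pixel-wide
   cross-section normal to the centerline, for every frame, sampled every
   10 um of arc. The 10 um arc step matters: the spatial filter below has
   a normalised cutoff, so its transition band scales with the step. At
   10 um the band is ~0.4 cm, small against 2–5 cm waves; at coarser
   sampling the filter would smear wave edges in proportion to the
   wavelength itself and bias the measured-vs-calculated WL comparison.
2. **Filtering and normalisation** — per frame, a zero-phase 3rd-order
   Butterworth low-pass along the arc axis at 0.005 of the spatial
   Nyquist (order, axis, and zero-phase application are this package's
   choices; zero phase is what keeps wave edges in place). Each arc
   position is then divided by its own temporal mean over the recording —
   cancelling staining and illumination inhomogeneity — and the residual
   is rescaled to unit maximum. All subsequent measurements are
   threshold-relative, so the amplification factor is provably
   irrelevant (and tested to be).
3. **Wavelength measurement** — per frame, the wave is the maximal
   contiguous arc interval at or above 80% of that frame's wave
   amplitude, with sub-sample interpolated edges. The amplitude is taken
   relative to the frame's 5th-percentile baseline, which makes the
   measurement invariant to residual bleaching; dips that stay above
   `threshold - 0.15 x amplitude` are bridged (noise notches inside a
   plateau), and a wave counts as *complete* only when both edges are
   strictly inside the path **and** both path ends have returned below
   half amplitude — without the latter, a wave still exiting the spiral
   with a noise notch near the end would masquerade as a shorter complete
   wave. At least 10 complete waves are required; otherwise the WL is
   reported as not measurable with the reason recorded, which is the
   expected outcome whenever CV x APD80 exceeds the 5.5 cm path.
4. **Line-scan endpoints** — APD80 as the duration between the sub-sample
   upstroke and repolarisation crossings of 20% of amplitude above the
   preceding diastolic baseline; travel time as the mean difference of
   per-beat peak times between the two scanned regions; CV as arc
   separation over travel time.

Two numerical choices deserve emphasis. First, *peak times* are computed
as the midpoint of the half-amplitude crossings rather than the discrete
argmax: a processed optical action potential is nearly flat-topped, and
because the pacing cycle is an integer number of samples at 150 Hz, the
argmax's quantisation error is phase-locked and does not average out over
the train; the midpoint estimator is shape-consistent, so peak-time
*differences* between identically shaped traces are sub-sample exact.
Second, the trace smoother (standing in for the unreproducible
chain-smoothing of the original acquisition software, and pluggable via
the `smoother` argument) is a diastole-anchored first-order detrend, a
5-sample moving median, and a zero-phase 40 Hz low-pass.

Beat pairing between the two regions allows a +/-2-beat alignment search
and selects the smallest positive mean delay: the proximal/distal role of
the two regions is part of the recording design, and in a periodic train
an aliased alignment one cycle off is otherwise indistinguishable. A
negative delay is only reported (with a warning and `direction_flipped`)
when no forward alignment exists.

## 2D analyses

Slice-style stacks are conditioned the standard way: temporal low-pass at
150 Hz, 7x7 boxcar spatial average, per-pixel min–max normalisation, and
first-order drift removal. The drift fit is anchored to the
lowest-residual quintile (so a long action potential cannot tilt it) and
is applied to all pixels or none, decided by the median fitted drift
(threshold 10% of the normalised range): detrending an essentially
drift-free stack injects small position-dependent tilts — the
repolarisation tail always contaminates the anchor slightly — that bias
downstream gradient fits, and mixing detrended with untouched pixels is
worse than either.

Activation is the first upstroke crossing of 50% of the per-pixel
amplitude, refined with a monotone spline around the crossing (linear
interpolation across a curved upstroke leaves a periodic sub-sample ripple
that propagates into gradient estimates). Local conduction velocity comes
from sliding least-squares *quadratic* surface fits of activation time
(gradient evaluated at the window centre; a plane fit across a curved
elliptical front systematically under-reads the gradient and so over-reads
speed), filtered at R^2 >= 0.95, binned by propagation direction in 10
degree bins; the longitudinal CV is the largest bin median, the transverse
the smallest. This is a generic velocity-field method in the tradition of
polynomial-surface optical-mapping velocimetry, not a reimplementation of
any specific mapping toolbox. The APD90 map applies the same duration
measurement per pixel, flagging traces that dip below baseline by more
than 10% of amplitude as motion artifacts.

For the 8x8 MEA, activation per electrode is the time of maximal negative
slope of the field potential (the standard extracellular convention,
restricted to the first beat so a paced train cannot alias electrode
times), and the monolayer CV is the mean of the three conduction vectors
from the stimulated corner electrode — along its row, its column, and the
main diagonal. Note that this corner-vector average is only meaningful for
a wave radiating from the stimulated corner; for a plane wave the diagonal
vector reads sqrt(2) times the true speed, so the simulator's default
scenario is a corner point source, matching how such devices are paced.

## Classification of single-cell action potentials

Features (MDP, APA, dV/dt~max~, APD50, APD90) are extracted per action
potential with a 5-sample median prefilter; the derivative is a sliding
~1 ms least-squares slope, because the maximum raw first difference over a
shallow nodal upstroke is an extreme-value statistic of the noise and can
triple the apparent dV/dt~max~.

Two rule sets are implemented because the published procedure text and its
figure caption disagree (working-myocyte MDP bound of -55 vs -60 mV;
OR-joined vs jointly listed duration criteria). The `"text"` set is the
default. Under it, a cell satisfying both the ventricular disjunction
(APD90 > 400 ms or ratio < 1.2) and the atrial one (APD90 < 300 ms or
ratio > 1.2) — possible, e.g. APD90 = 450 ms with ratio 1.3 — is returned
as `unclassified` with the conflict recorded in `rule_trace`; likewise
cells in the MDP gap between the nodal (> -50 mV) and working-myocyte
(< -55 or < -60 mV) rules. The gaps are a property of the rules and are
surfaced, never silently patched.

## ERP and cohort endpoints

`erp_from_scan()` reads the ERP off a strictly decreasing S1–S2 capture
scan as the longest non-capturing coupling interval (the interval at loss
of capture); the alternative shortest-captured convention is available,
since the boundary is only defined to within one decrement either way.
Against the restitution simulator the recovered ERP is always within one
10 ms decrement of the continuum refractory boundary. `catheter_cv()`
converts a conduction time over a fixed 20 mm multipolar span, and
`summarize_cohort()` reports mean ± SEM per (group, side, duration-type)
cell with the wavelength computed per record *before* averaging — means of
per-subject products, which differ from products of means whenever records
are heterogeneous (a regression test holds this distinction in place).
Drive-cycle length is carried as metadata only; no restitution correction
is applied, and group inference beyond the summary table is out of scope.

## Problem sizes and verification

The test suite regenerates every dataset it uses. The heavier checks run
at the assay's native scale: full-frame simulations of 300 frames at 30
fps on a ~180x180 px grid (40 um pixels), line scans of 1500 samples at
150 Hz, slice stacks of 100x100 px at 1 kHz, and a 30-preparation
measured-vs-calculated wavelength batch spanning CV 15–25 cm/s and APD80
150–220 ms, which reproduces an ordinary-least-squares slope within a few
percent of unity (the batch is the single most expensive test, a little
over a minute on one core). End-to-end recovery holds CV to within 5% and
APD80 to within 1.5 line-scan frames across CV 15–45 cm/s and APD80
150–300 ms at default noise.

## Known limitations

* The kinematic simulator cannot probe source–sink or curvature effects
  on CV; it validates measurement, not electrophysiology.
* The measured WL carries a small constant negative offset (edge
  shrinkage from the prescribed heavy spatial filter plus the 80%- vs
  20%-level conventions on the two sides of the comparison); it is
  absorbed by the regression intercept and does not bias the slope.
* Longitudinal CV from point-source maps retains a residual upward bias
  of a few percent where wavefront curvature is strong within the
  averaging window; at the default 1 cm / 100x100 px geometry this stays
  within ~4%.
* The corner-vector MEA average assumes corner stimulation, as discussed
  above.
* With travel times beyond half a pacing cycle, beat correspondence
  between line-scan regions relies on the caller's proximal/distal
  labelling; swapped inputs alias by one cycle rather than fail.
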