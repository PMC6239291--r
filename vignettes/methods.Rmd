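---
title: "Methods: non-invasive lung-injury assays and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive lung-injury assays and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `vivorate`, the assumptions
they make, the tunable parameters and why their defaults are what they
are, and the places where the design was genuinely open and a choice
had to be made.

# Video respirometry

## Model

A sleeping mouse's breathing moves its flank fur quasi-periodically.
The pipeline estimates the breathing frequency from grayscale video in
four stages:

1. **Feature detection** (`detect_features`). Up to 10 corners per
   region of interest are selected on the first frame by Shi–Tomasi
   response — the minimum eigenvalue of the locally averaged gradient
   structure tensor — subject to a quality floor (1% of the strongest
   response), a minimum spacing (5 px), and a border margin so the
   tracker always has window support. Corners require high
   spatial-frequency content, which is why the synthetic generator
   textures its scene with speckle.
2. **Tracking** (`track_features`). Each corner is tracked
   frame-to-frame with an iterative pyramidal Lucas–Kanade solver
   (21×21 window, 3 levels, bilinear sub-pixel interpolation). A point
   is invalidated permanently when the solver fails, its window leaves
   the image, or re-tracking it backwards lands more than 1 px from
   where it started (forward–backward check). There is no
   re-acquisition after loss: re-seeding a point mid-clip would splice
   an unrelated phase into the waveform.
3. **Waveform construction** (`build_waveform`). Each track's 2-D
   positions are projected onto that track's principal motion axis,
   detrended by subtracting a 1-second moving average (removing posture
   drift far below the breathing band), and normalized to unit SD so
   that camera distance and viewing angle — which scale amplitude but
   not frequency — drop out. Tracks are sign-aligned to the first
   usable track (a principal axis has no preferred sign) and combined
   by a pointwise median, which tolerates individual tracker failures
   without corrupting the ensemble. The combined waveform's overall
   sign remains arbitrary; only its frequency content is used.
4. **Rate estimation** (`estimate_rate`). The rate is the largest
   periodogram peak (Hann window, 8× zero-padded FFT) inside the
   physiological search band, refined by parabolic interpolation of the
   log-spectrum around the peak. For a noiseless sinusoid this
   estimator is accurate to a small fraction of an FFT bin; a 20-second
   clip has 3 bpm bins, so sub-0.5-bpm accuracy is attainable and is
   asserted in the tests.

## Quality control

Manual practice in respirometry screening is to use only clips with
regular breathing — no gasping, sniffing, or pauses. Two automated
checks stand in for that screening, both computed per clip:

* `peak_prominence` — spectral peak power divided by the median
  in-band power; default threshold ≥ 5. A clip dominated by noise has
  no peak that stands out against the in-band background.
* `ibi_cv` — coefficient of variation of inter-breath intervals,
  measured on the band-passed waveform with peaks at least a quarter
  of its SD high (suppressing ringing ripples during apneic segments);
  default threshold ≤ 0.25. A pause or a sniffing burst makes the
  intervals wildly unequal.

Both thresholds are configurable; there is no published reference
value, so the defaults are deliberately loose screens rather than
tuned discriminators. A single large gasp alters amplitude but not
timing and can pass both checks — a known limitation; the summary over
clips (`summarize_mouse`, median of QC-passing clips, with at least 5
desired per animal) is the robustness backstop.

The physiological search band defaults to 60–400 bpm, bracketing
reported murine rates (roughly 140–190 bpm in irradiation studies)
with a wide margin on both sides.

## What the video generator emulates, and what it does not

`render_breathing_clip` draws a static speckle background and an
elliptical speckle-textured "flank" patch whose texture translates
along a fixed axis by `amplitude_px · s(t)` plus a linear drift. The
unit waveform `s(t)` is a raised cosine per breath with the inhale
occupying 40% of the cycle — breathing is asymmetric, and the asymmetry
exercises the estimator's robustness to non-sinusoidal shape while
keeping the fundamental frequency exact. Inter-breath intervals are
jittered (lognormal-free, truncated Gaussian multiplier) with a
configurable CV, and gasp / pause / sniff events are minimal parametric
stand-ins: one cycle at 3× amplitude, a flat segment, a 3-second burst
at 3× rate.

Defaults are 256×256 8-bit frames at 30 fps — desk-scale stand-ins for
1080p webcam video — and a 2 px motion amplitude. The amplitude of real
fur motion in pixels is unknown (it depends on camera distance); 2 px
is a deliberately conservative choice near the lower end of what makes
corners trackable, and it is exposed for sensitivity testing.

Passing the synthetic validation therefore shows that the measurement
chain (corner selection, sub-pixel flow, robust combination, spectral
estimation with QC) recovers a known quasi-periodic translation under
jitter, drift, quantization and intensity noise. It does not show
robustness to fur deformation (non-rigid motion), lighting changes,
shadows, occlusion by bedding, or multi-animal scenes — none of which
the generator models.

# CT lung densitometry

## Segmentation and volume

Mass-density volumes (g/cm³) are either read directly or converted
from Hounsfield units by the two-point air/water calibration
(−1000 HU → 0 g/cm³, 0 HU → 1 g/cm³), clipped at zero. Healthy lung is
the set of voxels with density in **[0, 0.7) g/cm³** inside the body
mask. The interval is half-open: the upper boundary is a reported
protocol value whose boundary semantics are unstated, and excluding
exactly-0.7 voxels makes the rule deterministic under partial-volume
ties. The body mask is the largest 26-connected component above
0.9 g/cm³ with in-plane holes filled, which separates the animal from
surrounding air without manual input. The thresholded lung mask is
then cleaned by slice-wise hole filling and by keeping at most the two
largest 26-connected components — two lungs, with airway and noise
voxels discarded. Volume is voxel count × voxel volume.

## The seven-ROI protocol

Lung density is summarized by seven square in-plane ROIs: four of
1.5 mm in the apex and three of 2.4 mm in the base, each centred at
fixed fractional coordinates of the lung-mask bounding box and lying
on a single axial slice. Anchoring to the bounding box is what
guarantees the protocol's contract — the same anatomical positions at
every timepoint, without operator bias. The exact fractional
coordinates are a design choice (the original protocol's coordinates
are not published): the defaults place all seven boxes inside lung
parenchyma of a generic two-lobed anatomy (apex boxes at slice
fraction 0.2 over both lungs; base boxes at slice fractions 0.75/0.65,
lateral fractions 0.23/0.77). A midline base ROI was deliberately
avoided: between two lung lobes lies mediastinal soft tissue, and a
midline box would measure it rather than lung. The per-animal summary
is the unweighted mean of the seven ROI means — whether the original
protocol used that summary is unstated; the mean is the simplest
choice consistent with "7 ROIs, one density per animal".

## Phantoms

`make_phantom` builds a body ellipsoid at 1.06 g/cm³ containing two
lung ellipsoids (default semi-axes 8×3×3 mm, i.e. 0.302 cm³ each,
totalling ≈0.60 cm³ — the scale of healthy murine lungs) at
0.474 g/cm³, the control-animal mean density. Injury is a cap of an
exact volume fraction of one lung raised to a consolidated density;
the cut plane solves the ellipsoid-cap volume equation, so the
remaining healthy volume is known in closed form and segmentation can
be checked against it to 1%. Phantoms are voxelized by voxel-centre
membership with no partial-volume blur, so threshold segmentation can
be compared voxel-exactly with the analytic membership. Real CBCT has
partial volume, beam hardening, scatter, breathing motion and texture
that phantoms do not model; phantom tests validate the measurement
geometry and the thresholding logic, not robustness to scanner
physics.

# Cohort statistics

## Dichotomization

A metric is abnormal when it lies strictly beyond the control mean
± 3 SD in the adverse direction (above for respiratory rate and lung
density, below for healthy lung volume). Values exactly at the cutoff
are normal — "no more than 3 SD" is an inclusive bound. Measurements
are taken at 5 months post-irradiation, falling back to 4 months for
animals that die earlier; animals with neither measurement are
excluded with a logged reason. Control statistics pool both field arms
of the unirradiated group (whether the original analysis pooled them
is unstated; pooling doubles the control n and the arms are
biologically identical at 0 Gy).

## Hill dose–response and the ED50 comparison

The fraction of abnormal animals per dose group is fitted with
P(D) = 100 / (1 + (ED50/D)^h), bottom fixed at 0% and top at 100% — the
responses are percentages of animals, so the asymptotes are structural,
and fixing them leaves 2 parameters for 6–7 dose points. Fitting
minimizes unweighted least squares on the group percentages (mirroring
the plotted-curve workflow; a per-animal binomial likelihood would
weight groups by information content but is not what curve-fitting
software does by default). Optimization is multi-start Nelder–Mead on
(log ED50, log h) with a BFGS polish; on noiseless Hill data the
optimum is recovered to ~1e-7 relative error.

Two arms are compared with an extra sum-of-squares F-test. The default
null model shares **both** ED50 and slope across arms (the fully
nested choice); the alternative fits each arm separately. A
`"shared-ed50"` variant (common ED50, per-arm slopes) is selectable.
To guarantee nesting numerically, the alternative fits are also seeded
from the null optimum, so RSS_alt ≤ RSS_null holds by construction.

A calibration caveat, measured by this package's own acceptance test:
at the study design (6 doses, 10 animals per dose and arm, binomial
responses quantized to 10% steps), the F-test's type-I error at
α = 0.05 is slightly above nominal (≈0.075 over 1000 simulations).
The inflation is inherent to applying an unweighted Gaussian F-test to
discrete, heteroscedastic binomial percentages at this sample size —
the fitted optima match an independent `nls` cross-check — and is
reported rather than patched, because reweighting or switching to a
likelihood-ratio test would change the method being implemented.

## Survival and association

Kaplan–Meier curves and the two-group log-rank test delegate to the
`survival` package and are cross-checked in the tests against a
brute-force risk-table computation. Per-dose log-rank comparisons of
the two arms are Bonferroni-adjusted across the dose groups that have
any events (the adjustment behind the original "adjusted p" is
unstated; Bonferroni is the conservative default). Cox models (Efron
ties) are fitted by `survival::coxph`, with hazard ratios reported as
exp(coefficient); survival time is measured in days. Welch's t-test
compares survivors and decedents; Spearman's rank correlation (midrank
ties, asymptotic p) measures association among the three metrics.

## The cohort generator

`simulate_cohort` draws, per animal, a latent responder flag from the
Hill response probability at its dose, with the 1.5 T arm's ED50
multiplied by a configurable factor (default 0.97, i.e. a 3%
sensitization). Responders die of lung injury at a lognormal time
(median 5 months, clamped to 3–7 months) and are events; everyone else
is censored at 8 months. Metric trajectories are control mean + a
responder shift that ramps linearly to its full value by month 4
(pneumonitis develops over months) + Gaussian noise at the control SD.
Control moments (142 ± 16 bpm, 0.474 ± 0.055 g/cm³,
0.580 ± 0.053 cm³) and the design (doses 0–13 Gy, 20 per dose split
between arms, censoring at 8 months) follow the published study; the
responder shifts (+80 bpm, +0.25 g/cm³, −0.22 cm³) are chosen so that
diseased animals sit 1–2 control SDs beyond the 3-SD cutoffs, matching
the reported survived-vs-died group separations in kind. The generator
does not model graded severity within responders, competing causes of
death, or fibrosis after pneumonitis.

# Numerical choices and problem sizes

* FFT rate estimation uses a Hann window and 8× zero padding;
  parabolic interpolation is clamped to ±0.5 bin.
* The LK structure tensor requires a determinant above 1e-9 (on 0–255
  intensities); below that the point is declared untrackable.
* Ellipsoid voxelization is by voxel-centre membership; volume error
  at 0.1 mm spacing is well under the 1% tolerance asserted.
* Degenerate inputs error early with condition classes
  (`vivorate_bad_input`, `vivorate_qc_failure`) that the CLI maps to
  exit codes 2 and 3.
* Test and validation problem sizes: the validation study uses 100
  clips of 20 s at 30 fps and 256×256 px; unit tests use 6–10 s clips
  at 64–128 px; phantom checks run at 0.1–0.3 mm spacing; F-test
  calibration uses 1000 null replicates and ratio recovery 500. These
  sizes were chosen so the complete suite runs on a single CPU in
  minutes while keeping Monte-Carlo error well below the asserted
  margins.

# Known limitations

* The respirometry QC cannot flag a lone gasp (timing-preserving
  amplitude event); multi-clip medians are the mitigation.
* Auto-ROI selection assumes the breathing animal is the single
  highest-temporal-variance region of the frame.
* Segmentation assumes densities are calibrated; no scatter or
  beam-hardening correction is attempted.
* The F-test calibration caveat above applies to small per-dose n with
  steep dose responses.
* Synthetic generators validate the algorithms, not biology: passing
  them does not demonstrate performance on real fur, real CBCT, or
  real cohorts.
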