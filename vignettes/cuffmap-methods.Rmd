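---
title: "Quantifying arterial-wall macromolecule uptake around a tapered perivascular cuff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arterial-wall macromolecule uptake around a tapered perivascular cuff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffmap)
```

## The measurement problem

A rigid tapered cuff placed around the mouse common carotid artery —
its bore narrowing linearly from 500 to 250 µm over 1.5 mm — restricts
flow and, in hypercholesterolaemic mice, provokes plaques of different
phenotype upstream and downstream of it.  A mechanistic question is
whether the *uptake of circulating macromolecules* by the wall is
already non-uniform around the cuff before any lesion exists.  The
measurement chain this package implements has four legs:

1. **En-face confocal uptake quantification.**  Vessels carrying a
   fluorescently labelled albumin tracer are opened, mounted luminal
   side down, and imaged as two-channel 3-D stacks (tracer +
   autofluorescence) at 3 µm pixels over roughly 0.5 × 5 mm.  After
   flat-field and depth-attenuation correction, the luminal surface is
   detected by thresholding the autofluorescence channel, the tracer
   maximum over 0–25 µm into the wall is projected at each (x, y), and
   intensities are averaged circumferentially to give an uptake profile
   along the vessel.
2. **Lumen morphometry.**  From vascular-cast geometry, cross-sections
   at 5 µm intervals along the centerline give area $A$, perimeter $P$,
   Shape Index $SI = 4\pi A/P^2$ (1 for a circle, 0 in the line limit),
   and the maximum inscribed circle; the cuff model is fitted with its
   narrow end at the most restricted station.
3. **Hemodynamic post-processing.**  Wall shear stress (WSS) and
   pressure fields on the lumen surface, mapped to rectangular
   (longitudinal, circumferential) parametric space, are summarized in
   40 µm bands (mean, and the mean of the lower 5th percentile as a
   robust band minimum); pressures are re-referenced to a band 2 mm
   (forward cuff) or 3 mm (reversed cuff) downstream of the throat.
   Flow bookkeeping uses Murray's law, $Re = \rho v D / \mu$ with blood
   treated as Newtonian ($\mu$ = 0.004 kg/(m·s), $\rho$ = 1015 kg/m³),
   the parabolic-profile rule $\bar v = v_\text{centreline}/2$, and
   anaesthesia/activity scalings (×1.05, ×1.72, ×1.88).
4. **Doppler velocimetry.**  Velocity envelopes are segmented into
   beats at end-diastolic minima; systolic peak, end-diastolic velocity
   and cycle-averaged maximum velocity are averaged over 10 contiguous
   beats (about one breathing cycle).

No experimental data ship with the package: a synthetic-data module
generates every input with stored ground truth, so each pipeline stage
is testable end to end.

## Coordinate conventions

* `x` — longitudinal position in µm with `x = 0` at the cuff's *narrow
  end*, increasing in the flow direction.  A forward cuff (wide end
  upstream, the conventional placement) spans `[-1500, 0]`; a reversed
  cuff spans `[0, 1500]`.
* `y` — circumferential position on the opened half-vessel; `z` — depth
  from the mounted luminal face into the wall.
* Voxels are 0-based with centers at `(i + 0.5) × spacing`; a surface
  "at z-index k" has depth `k × z_spacing`.

## The synthetic en-face stack

`gen_enface_stack()` emulates what the microscope sees:

* a **curved luminal surface** whose depth varies quadratically across
  the strip (`surface_sag_um`, default 15 µm) plus an optional
  longitudinal tilt;
* a **tracer channel** equal to the true uptake profile at the surface,
  decaying exponentially with depth into the wall (`decay_length_um`,
  default 40 µm);
* an **autofluorescence channel** at 20 % of the tracer baseline (the
  relative magnitude is not constrained by published data and is
  exposed as `autofluorescence_fraction`), with bright **glare foci**
  at the cuff margins — small Gaussian blobs, 8× the wall
  autofluorescence, at a fixed areal density (so narrower strips carry
  proportionally fewer), extending one plane above the surface to
  emulate the surface-detection hazard they pose in real stacks;
* degradations: a smooth **multiplicative x-y sensitivity bias** (±10 %
  by default, the thing a uniform-slide calibration image corrects), an
  exponential **z attenuation** (length 80 µm, the thing the
  previously-calibrated falloff curve corrects), and **shot-like
  noise** with SD `noise × sqrt(intensity)`.

The true uptake profile is a baseline plus two smoothed top-hats
(Gaussian-convolved rectangles, width = cuff length, edge scale 150
µm): the upstream peak centred on the upstream cuff margin and the
downstream peak centred 0.5 mm beyond the cuff's downstream end, with
the upstream peak higher (default amplitudes 400 vs 250 over a baseline
of 100).  All signal is laid down on the voxel grid *relative to the
surface voxel of each column*.  This is a deliberate modelling choice:
it makes "disable all degradation ⇒ the pipeline recovers the truth
exactly, to machine precision" a meaningful contract rather than an
approximation, which the test suite exploits heavily.

What the generator does **not** emulate: optics (no PSF, refraction or
axial blurring), tissue deformation from mounting, registration error
between segments, or spatially correlated biological texture.  Passing
tests therefore demonstrate correctness of the *computational chain*,
not robustness to every real-world artifact.

## Numerical choices in the uptake pipeline

* **Threshold.**  The surface threshold defaults to Otsu's method
  computed per stack, with a fixed-threshold override.  Otsu is run on
  log-compressed (`log1p`) intensities: between-class variance scales
  with squared class distance, so on a raw histogram a rare but very
  bright glare class can capture the threshold and push it above the
  wall signal; log compression removes that failure mode without
  introducing a tunable parameter.
* **Glare robustness.**  Surface detection optionally (default on)
  median-filters each plane 3 × 3, computed with a 19-exchange
  vectorized sorting network.
* **Window convention.**  The projection window is the *closed*
  interval [0, 25] µm measured from the detected surface voxel.
* **Missing data.**  Columns never reaching the threshold are missing;
  stations with under 25 % of the circumference present are dropped;
  `n_pixels` is carried with every profile.
* **Peak centers.**  The peaks are broad and nearly flat-topped, so the
  raw argmax of a noisy profile wanders over several hundred µm of
  plateau.  `find_uptake_peaks()` uses the argmax (after a 250 µm
  moving-average smooth) only to *locate* the peak and reports as its
  center the intensity-weighted centroid of the contiguous region above
  60 % of the peak height over the local background; exact ties are
  broken toward the cuff and flagged, as are maxima on a search-region
  boundary.  On generated data this recovers the upstream center to a
  few µm and the downstream center to within ~90 µm (the downstream
  search region starts at the throat and clips the peak's left flank,
  a small known bias).

## Group structure and statistics

Each simulated mouse contributes two imaged segments per vessel
(averaged before any group statistic, as the per-vessel unit) and a
small autofluorescence-only group (animals without tracer, emulated by
projecting the autofluorescence channel) whose group-mean profile is
subtracted from every uptake profile.  Between-animal biology is
modelled at the pipeline level: a shared per-mouse uptake scale
(SD 0.15) and independent per-peak amplitude variation (SD 0.10) —
values chosen once as typical of between-animal variability in tracer
studies; without them, paired comparisons across simulated mice would
have essentially zero variance and any systematic 1 % artifact would
reach significance.  The NOS-inhibition scenario equalizes the *group
mean* amplitudes (and halves the baseline); individual mice still vary
around them.

Comparisons use Student's t-tests: paired for within-animal contrasts
(upstream vs downstream 0.7 mm window means at each mouse's own peak
centers by default), pooled-variance unpaired (Welch optional) when
different animals are compared, significance at P < 0.05, no
multiple-testing correction (single planned contrasts).  SEM uses the
sample SD over mice with n = mice.  `simulate_group_comparison()`
checks the paired contrast at the window-mean level: under the null the
paired differences are exactly Gaussian, so the 5 % level is exact by
construction and the Monte-Carlo run (2000 groups) verifies the
implementation rather than an approximation.

## Morphometry details

Contours are resampled at uniform 5 µm arc-length stations by
vertex-wise linear interpolation between stored cross-sections, each in
the plane orthogonal to the local centerline tangent.  Area uses the
shoelace formula (orientation-independent), the Shape Index is clipped
to 1 only within floating-point tolerance (values materially above 1
violate the isoperimetric inequality and raise an error), and the
maximum inscribed circle is found by seeding a Nelder–Mead refinement
of the signed boundary distance from a coarse interior grid — validated
in the tests against a grid distance-transform oracle to within one
grid cell.  Throat finding uses the equivalent diameter
$2\sqrt{A/\pi}$, which is robust to the highly non-circular stenosis
cross-sections.  The maximal lumen inside the cuff follows the
convention that the wall occupies 10 % of the luminal diameter: outer =
1.2 × lumen, so lumen = bore/1.2 (208.3 µm at the throat); cuff fitting
additionally applies the 10 % cast-shrinkage convention when reporting
where the wall contacts the bore.  Oblique sections near the
bifurcation are out of scope; the model is the common carotid segment.

## The quasi-1D viscous surrogate

A full 3-D Navier–Stokes solution is deliberately out of scope.  For
longitudinal *trends* the package provides a locally-Poiseuille
surrogate: with $D(x) = 2\sqrt{A(x)/\pi}$,

$$\tau(x) = \frac{32\,\mu Q}{\pi D^3}, \qquad
p(x) = p_\text{in} - \int_0^x \frac{128\,\mu Q}{\pi D^4}\,dx'$$

(trapezoidal integration).  Pressure is strictly decreasing — a purely
viscous model with no Bernoulli recovery, which is the regime the low
Reynolds numbers (~10) of the mouse carotid put us in.  The surrogate
reproduces the qualitative solver findings (shear maximal at the
throat, no post-stenotic pressure recovery) and the Poiseuille closed
form on uniform tubes to 1 × 10⁻¹⁰ relative; it does not reproduce
recirculation, oscillatory shear, or absolute peak WSS values, which
are genuinely three-dimensional.

Band statistics use half-open 40 µm bands anchored at the upstream end
of the mapped domain (the anchor is a convention; no published
statement fixes it).  The "lower 5th percentile" is nearest-rank: the
set of nodes with value ≤ the ⌈0.05 n⌉-th order statistic, collapsing
to the single minimum for bands with fewer than 20 nodes.  Band means
are node-count weighted by default (area weighting optional in
principle; nodes on the generated parameterization are uniform).

## Doppler conventions

The synthetic envelope is $v = \text{EDV} + (\text{peak} -
\text{EDV})\,h(\phi)$ with $h(\phi) \propto \sin^2(\pi\phi)
e^{-k\phi}$, normalized on the sample grid so the sampled per-beat peak
is exact; $k$ (default 3) sets the diastolic decay, and
`doppler_trace_from_metrics()` solves for $k$ so a generated envelope
matches a published (peak, EDV, cycle-mean) triple — used to
reconstruct the flow-velocity table for the cuffed and contralateral
carotids.  Beats are laid out on the sample grid so stored boundaries
coincide exactly with envelope minima.  Breathing is a multiplicative
sinusoid over 10 beats, which is why 10-beat averages are nearly
modulation-free (the sinusoid averages out over a full cycle).

Segmentation replaces the instrument's manual step: minima of a
low-pass-filtered envelope (moving average over 10 % of a cycle) with
minimum separation 0.6 cycles, snapped to the local raw minimum.  EDV
is read at the boundary sample from a 5-point running-median version of
the envelope (reading a pointwise minimum from a noisy envelope is
biased low; the running median removes the bias and is essentially a
no-op on clean envelopes); peak and cycle mean always come from the raw
envelope.  Insonation-angle correction ($v = v_\text{beam}/\cos\theta$)
is available but off by default, since whether instrument-reported
velocities are already angle-corrected varies by setup.

## Problem sizes

Defaults are the study conditions: stacks of 2066 × 166 × 16 voxels
(3 µm pixels, 5 µm planes, ≈6.2 × 0.5 mm), n = 10 mice with two
segments each plus 3 autofluorescence animals for the forward-cuff
group (n = 6 + 2 for NOS inhibition), geometry at 5 µm stations with
128-vertex contours, 12-beat envelopes at 1 kHz, 2000 Monte-Carlo
groups for calibration.  The test suite exercises the identical code
paths on circumferentially narrower strips (120 µm) and smaller group
sizes so the whole suite completes in a couple of minutes; the
realism-bound check (pipeline CV on uncuffed vessels ≤ 0.19, the
largest single-vessel CV reported for this preparation) runs on
full-size stacks across 10 seeds.

## Known limitations

* The uptake pipeline's absolute units are arbitrary; only contrasts
  and ratios are meaningful, as in the underlying assay.
* The autofluorescence subtraction uses a group-mean profile from
  separate animals, so margin glare leaves a ~1 % systematic dip at the
  upstream peak; it is far below the biological variability the group
  model injects.
* The quasi-1D surrogate shares no machinery with a spectral 3-D
  solver; treat its outputs as trends, not absolute hemodynamic values.
* Beat segmentation assumes reasonably regular rhythm (minimum
  separation 0.6 cycles at the expected rate); arrhythmic traces raise
  errors rather than guessing.
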