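---
title: "Modeling and measuring anaphase II spindle rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring anaphase II spindle rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinsym)
```

## The problem

After fertilization, the metaphase II–arrested mouse oocyte resumes
meiosis: the two sets of sister chromatids separate, and the anaphase
II spindle — initially parallel to the cortex — must rotate
perpendicular to it so that cytokinesis can pinch off a small second
polar body containing one chromatid set. Which of the two DNA clusters
is discarded, and in which direction the spindle turns, is not
predetermined: rotation arises from a spontaneous, stochastic symmetry
break between two antagonistic forces, the outward attraction of each
DNA cluster to the polarized actomyosin cortex above it and the inward
push of the cytokinetic furrow on the central spindle.

`spinsym` implements the computational side of that picture end to
end: a mechanical model of the instability, a closed-form model of the
distribution of symmetry-breaking times, the image-analysis pipeline
used to quantify rotation in 4D recordings (segmentation, tracking,
onset statistics, cortical polarity profiles, particle image
velocimetry), and synthetic-data generators with exact ground truth so
that every stage can be validated without microscopy data.

## The mechanical model

Geometry is two-dimensional, in the equatorial plane of a circular
oocyte of radius $R_{ovo} = 1$ (all lengths are in units of the cell
radius; time is arbitrary because the damping coefficient sets the
scale). Two point-like DNA clusters $x_1, x_2$ sit at the ends of a
spindle of fixed chord length $L_0$. Three ingredients act on them:

* **Cortical attraction.** Each cluster is attracted to its own
  polarized cortical zone through the soft-core potential
  $$V(r) = -A\,(r - r_a + \lambda)\,e^{-r/\lambda},$$
  where $r$ is the distance to the fixed cortical anchor point,
  $\lambda$ the decay length and $r_a$ (about the cluster radius) the
  location of the unique minimum: the well is deepest when the cluster
  is apposed to its attraction zone, short-range repulsive below
  $r_a - \lambda$, and negligible a few $\lambda$ away. The force is
  the gradient, magnitude $(A/\lambda)\,|r - r_a|\,e^{-r/\lambda}$.
* **Cytokinetic ingression.** The central-spindle point $c$ is
  prescribed to move with constant speed $u_{cyto}$ along the inward
  chord normal (orientation kept by continuity). Without it nothing
  happens: the clusters simply stay in their wells.
* **Spindle rigidity.** Bending of the spindle produces an elastic
  restoring force $f_E = k\,w$ on both clusters, where $w$ is the
  component of $c - (x_1+x_2)/2$ perpendicular to the chord. It is
  this coupling that transmits the ingression to the clusters.

Dynamics are overdamped, $v = (f_V + f_E)/\alpha$, integrated with an
explicit Euler step. After each step an independent Gaussian kick of
SD $\sigma$ is added to every cluster coordinate, the pair is
re-projected exactly to the fixed chord length about its midpoint, and
containment inside the cell is enforced by shifting the pair midpoint
toward the origin along the exact root of the containment quadratic
(this preserves the chord exactly, which a per-cluster radial clamp
would not).

Defaults are $A = 150$, $\lambda = 0.1$, $r_a = 4/30$, $k = 200$,
$\alpha = 1$, $u_{cyto} = 1/3$, $L_0 = 0.8$, $t_{max} = 3$
(ingression depth up to one cell radius). The initial configuration is
symmetric: both clusters in their wells on the circle of radius
$R_{ovo} - r_a$, anchors at their radial projections, $c$ at the chord
midpoint.

With $\sigma = 0$ the configuration is an unstable equilibrium that
the symmetric numerics preserve exactly: the spindle stays parallel to
the cortex while being pushed ever deeper, and both clusters
eventually escape together. Any noise breaks the left–right symmetry:
one cluster (the eventually internalized one, "in") escapes its well
while the other ("out") returns to the cortex, and the spindle
rotates. Labels are assigned retrospectively from the final cortex
distances, exactly as one would label an experimental recording after
seeing which cluster was extruded.

### Numerical choices

* **Time step.** The stiffest scale is the well relaxation rate
  $V''(r_a)/\alpha \approx 4\times10^2$; the default $dt = 10^{-3}$
  keeps the explicit Euler step well inside its stability region while
  staying cheap enough for thousand-run ensembles. Note the noise
  model adds a kick of SD $\sigma$ *per step*, not per unit time, so
  the effective diffusion is $\sigma^2/(2\,dt)$ and $dt$ is part of
  the parameter set, reported in all outputs.
* **Termination.** A run stops at $t_{max}$, when the rotation angle
  drops below 5°, or when a cluster exceeds $r_a + 5\lambda$ from its
  anchor (escape essentially complete). Both thresholds are
  configurable plumbing, recorded with the trajectory.
* **Symmetric classification.** A run is "symmetric" when
  $\max_t |r_1 - r_2|$ stayed below $10^{-8}$; with any nonzero noise
  this never happens.
* **Determinism.** The Euler core consumes R's RNG stream, so a seeded
  run is bitwise reproducible; ensembles draw per-run sub-seeds from
  the base seed.

## The symmetry-breaking-time model

Near the unstable equilibrium the dynamics linearize to motion on a
quadratic potential bump: an offset grows as
$r(t) = r_0\,e^{t/\tau}$. The first passage at a breaking distance
$r_c$ happens at $t_c = \tau \log(r_c/|r_0|)$. When the initial offset
is Gaussian with SD $\sigma_0$, the breaking time has the closed-form
density
$$p(t) = \frac{2 r_c}{\sigma_0 \tau \sqrt{2\pi}}\; e^{-t/\tau}\,
  \exp\!\left(-\tfrac{1}{2}\big(r_c e^{-t/\tau}/\sigma_0\big)^2\right),$$
supported on the whole line, unimodal with mode
$\tau\log(r_c/\sigma_0)$, and skewed to the right: the long tail is
the image of small offsets under the logarithm. `breakingTimePdf()`,
`breakingTimeCdf()`, `sampleBreakingTimes()` and `simulateBump()`
implement the density, its CDF, exact Monte-Carlo sampling (folded
normal through the log map) and Euler integration of the escape.
Defaults $\sigma_0 = 1$, $\tau = 1$, $r_c = 10$. The link to the full
mechanical model is qualitative only — the onset-time distribution of
noisy ensembles is right-skewed like $p(t_c)$ — and no quantitative
map between the bump coordinate and the cluster asymmetry is claimed.

## Rotation metrics

All derived quantities are computed identically for simulated
trajectories and for image-derived tracks:

* **Registration**: a line through the early, linearly increasing
  phase of the inter-cluster distance; its intercept with the time
  axis defines $t = 0$. The window is automated as the initial
  strictly increasing run, with a manual override.
* **Rotation angle** $\alpha$: at the spindle midpoint, between the
  internalized cluster and the cell centroid; ~90° parallel to the
  cortex, →0° when fully rotated. **Spin angle** $\beta$: displacement
  of the midpoint around the centroid between two times.
* **Onset** $t_i$: a five-parameter logistic
  $y(t) = D + (A - D)/(1 + (t/C)^B)^E$ is fitted to the rotation curve
  (multi-start in $B \in \{2, 5, 10\}$; asymptotes box-bounded to the
  observed range ± half a span, which keeps truncated rotation curves
  from driving the late asymptote to absurd values while leaving the
  onset exactly invariant under affine rescaling of the angle axis).
  $t_i$ is the unique time at which the fitted curve has completed 5%
  of its span. The model needs positive times, so windows starting at
  or below zero are shifted internally; because the family is not
  closed under translation, time-translation equivariance of $t_i$
  holds to fitting accuracy (about 1%) rather than algebraically.
* **In/out ratio**: mean over an early window of
  $d_{in}(t)/d_{out}(t)$, the cortex distances of the internalized and
  extruded clusters; a ratio above 1 means the extruded cluster sat
  closer to the cortex before rotation. For recordings the window is
  the first 10 minutes. Model time is arbitrary, so the simulation
  analogue is a fraction of the run: the default is $t_{max}/6$,
  chosen by mapping the full simulated ingression ($t_{max} = 3$,
  depth one cell radius) onto the roughly one-hour course of the
  division, which puts 10 minutes at 0.5 time units.
* **Tertiles** of $t_i$ (early/intermediate/late third of the
  population, stable ties) and the **relocation speed** (windowed
  slope of the midpoint-to-centroid distance, 10–50 min, with a 20 µm
  relocated/peripheral cut) follow the corresponding recording
  analyses.

A caveat worth stating plainly: at the default conditions the early
in/out ratio is only a weak predictor of the eventual outcome (the
measured bias over large ensembles is roughly 70% rather than
something stronger). The radial asymmetry relaxes on the well
timescale $\alpha/V''(r_a) \approx 2.5\times10^{-3}$ — some two
orders of magnitude shorter than the early window — so almost no
memory of the window average survives to the moment the instability
picks a side; what bias remains comes from the overlap of the window
with the beginning of asymmetry growth. The statistic is therefore
sensitive to the choice of $dt$ (through the effective diffusion of
the per-step noise), of the window mapping, and of the initial
placement, and should be read qualitatively: the extruded cluster
tends to start closer to the cortex, earlier breaks go with larger
early asymmetry (negative $t_i$-versus-ratio slope), and the onset
distribution is right-skewed.

## Synthetic data and what it does (not) show

`renderStack()` draws the DNA channel as isotropic 3D Gaussian blobs
(in physical µm, sampled on the anisotropic voxel grid — 3.2 µm
z-spacing by default against 1 µm pixels, deliberately exercising the
unit handling) inside a dim cytoplasmic ball, multiplies every slice
by $e^{-\text{decay}\,z}$ to emulate the depth-dependent brightness
loss of confocal stacks of large cells, and adds Gaussian read noise
plus an intensity-proportional variance term. `makeCortexImage()`
builds a circular cell whose cortical band carries a cap (exponential
decay with distance to the nearest cluster, like chromatin-proximal
F-actin) plus a ring (Gaussian bump at a set distance, like the
myosin-II ring around the cap). `makeSpeckleMovie()` advects random
speckles *exactly* with a prescribed flow (uniform, radial, or a
programmed reversal) and re-renders each frame, so the ground-truth
field is analytic and no warping interpolation accumulates.

These generators validate unit handling, adaptive thresholding,
tracking logic, profile extraction and PIV against exact truth. They
do not emulate optics (no PSF, no spectral crosstalk), photobleaching,
cell deformation, or textured chromatin, so passing tests bound
algorithmic error, not performance on real movies.

## Segmentation and tracking

Per time point: Gaussian blur (SD 1 px in xy, scaled by the voxel
ratio in z), then per-slice adaptive thresholds — each z slice gets
its own threshold so attenuated deep slices keep their signal, which a
single global threshold provably loses (there is a test for exactly
that). Robustness required a few choices beyond the obvious sketch,
each with a corresponding test:

* slice intensities are capped at their 90th percentile before the
  *cell* threshold is computed, otherwise the small, very bright DNA
  blobs hijack the background/cytoplasm split;
* per-slice cell thresholds are floored at 0.3× the whole-frame
  threshold, so slices containing only blur leakage (above and below
  the cell in z) stay empty;
* masks get a 3×3 morphological opening — at realistic noise levels a
  naive threshold mask percolates into components that rival the cell;
* the *cluster* threshold on each slice is the maximum of the
  within-cell Otsu, the cell threshold, and a robust floor
  (median + c·MAD of the within-cell values), because Otsu applied to
  a unimodal noise slice happily marks a third of the cytoplasm;
* clusters are searched in the cell mask dilated by 4 px, and
  centroids are intensity-weighted over the above-half-maximum,
  threshold-subtracted core of each component — both counter the
  inward bias a cortex-apposed cluster suffers when its blob is
  clipped at the outline and rides the cytoplasm pedestal.

3D connected components are built from per-slice 8-connected labels
merged across adjacent slices by pixel overlap. Tracking is greedy
mutual-nearest assignment with a 1→2 split at anaphase, gap bridging
(default 2 frames, flagged `recovered`), and ambiguity flagging when
straight and swapped assignments cost the same. The cluster-to-cortex
distance is the mean 3D distance to the 1% closest cell-surface
voxels; cortical polarity levels use the 25% of band pixels closest to
each cluster. The cortical band is the inside ring of the outline at
the selection width (10–20 px in practice, default 15), parameterised
by arclength along the ocontour polygon smoothed with a 5-point
circular average (raw digital contours overestimate perimeters by
about 5%), with the origin at the boundary point equidistant from the
two clusters.

## PIV

Two-pass FFT cross-correlation (80 then 40 px windows at 50% overlap
by default; 160/80 as a coarse preset): pass 1 measures an integer
shift, pass 2 re-correlates offset windows and refines the peak with a
three-point Gaussian fit per axis. Vectors are invalidated outside the
cell mask, in windows with under half mask coverage or zero variance,
and when the first-to-second correlation peak ratio falls below 1.2.
Smoothing is a mask-aware running average (3×3 vectors in space, 9
time points; 5×5/13 as the coarse preset), linear and exact on
constant fields. The 1D axial series projects the field onto the axis
from the polarized cortical domain toward the cell centre inside a
central ROI (default: disc of 0.4 cell radii): positive values mean
inverted, centerward flow; negative values mean metaphase-like flow
toward the polarized domain. The headline scalar is the mean of the
top 10% of velocities inside a 10–50 minute window.

## Problem sizes

The test-suite and acceptance runs use 1,000-run ensembles for
population statistics (binomial SE ≈ 1.5 points on a percentage), 200
runs for the breaking-rate check, 70 for the onset-versus-asymmetry
slope (matching the recording-population size for that analysis),
80×80×20-voxel stacks over 8 time points for the imaging round trip,
200–240 px movies of up to 60 frames for PIV, and $10^5$ Monte-Carlo
draws for the breaking-time distribution (KS distance below 0.01).

## Known limitations

* The mechanical model is 2D, with fixed cortical anchor points and no
  hydrodynamic coupling, actin fields or ring-closure mechanics.
* The early in/out ratio statistic is sensitive to $dt$, the early
  window and the initial placement, as discussed above.
* 3D connectivity is overlap-based (a diagonal-only z contact does not
  join components); irrelevant for blob-like clusters.
* The 5PL onset is only numerically (not algebraically) equivariant
  under time translation.
* PIV has no window deformation or ensemble correlation; strong
  in-window velocity gradients smear the correlation peak, which the
  running-average smoothing mitigates but does not remove.
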