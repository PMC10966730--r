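---
title: "Time-stepped reconstruction of continuous-rotation tomography"
author: "flytomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-stepped reconstruction of continuous-rotation tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytomo)
```

## The model

A continuous-rotation (fly-scan) acquisition records detector frames at a
fixed period while the rotation stage moves at constant angular speed from
0° to an integer multiple of 360°. Indexing frames from 0, the geometry is
fully described by two linear maps,

$$\theta_i = \theta_0 + i\,\Delta\theta, \qquad
  t_i = i\,(t_{\mathrm{exp}} + t_{\mathrm{oh}}),$$

held by `ScanGeometry` and computed multiplicatively from the index (never
by accumulation), so there is no floating-point drift over a 15 001-frame
scan. Angles are kept *unwrapped* — cumulative values up to 1080° — because
unwrapped angles preserve time ordering; wrapping into $[0°, 360°)$ is a
pure helper (`wrapAngle`) applied only where trigonometry needs it.

Counts are fence-post inclusive: a range $R$ commensurate with the step
contains $R/\Delta\theta + 1$ frames, so a 180° window at 0.072° holds 2501
projections, and six such windows tile a 15 001-frame file at stride 2500,
sharing one boundary frame per pair. Any contiguous window spanning at least
180° is a valid parallel-beam tomogram; enumerating windows at stride $s$
gives successive reconstructions whose start times differ by $s$ frame
periods — the time-stepping interpretation. At stride 1 the nominal time
step equals one frame period (0.5 s at the reference settings), the finest
refinement the data supports.

The per-frame timestamp refers to the *start* of the exposure. A window is
labelled with all three of $t_{\mathrm{start}}, t_{\mathrm{mid}},
t_{\mathrm{end}}$; $t_{\mathrm{mid}}$ is the headline label because the
object evolves during the window, while $t_{\mathrm{start}}$ matches the
convention of reporting hh:mm:ss differences between the first projections
of two tomograms (`windowTable` prints both). The per-frame overhead
defaults to 0 but is a free parameter: 15 001 frames at 0.5 s of pure
exposure take 2 h 5 min, so a wall clock of 2 h 8 min implies roughly
12 ms of per-frame readout — the package does not assume a value.

## The synthetic testbed

No reference specimen accompanies the method, so the package generates its
own study conditions. `PhantomState` is a deterministic, time-parameterized
attenuation field emulating a block of enamel in a liquid bath:

* a circular liquid-filled support (95 % of the grid half-width) keeps
  everything inside the reconstruction circle;
* an enamel disc (75 % of the support radius) carries a quasi-periodic
  rod/inter-rod texture: two oblique sinusoids, softly thresholded (gain
  1.5, clipped at ±1) into a near-binary pattern with period 6 µm and ±15 %
  modulation. The pattern is a fixed function of position — there is no
  random field, so every phantom evaluation is bit-identical and all
  phantom tests are seed-free;
* a `DissolutionModel` opens a cavity behind an exposed window on the
  enamel boundary: front depth is $v\,(t - t_{\mathrm{onset}})$ behind a
  sector of given arc width, multiplied by an anisotropy gain along the rod
  axis (the lesion grows faster along rods, as demineralized enamel does).
  Inside the front, attenuation drops to
  $\mu_{\mathrm{liq}} + f\,(\mu_0 - \mu_{\mathrm{liq}})$ with residual
  fraction $f$; dissolved voxels never re-mineralize, making the field
  voxelwise non-increasing in time.

Defaults (96×96 grid at 1 µm, $\mu_{\mathrm{enamel}} = 0.02\,\mu m^{-1}$,
$\mu_{\mathrm{liq}} = 0.004$, $f = 0.25$, front speed 0.01 µm/s, onset
300 s, gain 1.3, window arc 30 µm) were chosen once: they give an optical
depth of order one across the disc — realistic imaging contrast — and a
cavity that grows by a resolvable amount per 180° window. The kinetics are
an order-of-magnitude stand-in, not physiological rates; a constant-speed
front is the simplest model that reproduces progressive grey-value loss and
an anisotropic cavity, and the model is pluggable should √t diffusion-type
kinetics be wanted. 3D grids extrude the slice with a slow axial phase
drift of the texture; analyses are slice-wise throughout.

What the generator deliberately does **not** emulate: polychromatic
(pink-beam) spectra and beam hardening, phase-contrast fringes,
rotation-axis wobble, zingers, flat-field drift, or sample motion other
than the dissolution itself. Passing tests therefore validate the
*bookkeeping, reconstruction and quantification machinery*, not robustness
to those beamline effects; real data additionally need registration and
possibly ring suppression before the analysis module applies.

## Acquisition and preprocessing

`simulateFlyscan` renders frame $i$ as the detector response to
$\exp(-\mathcal{R}[\mu(\cdot, t_i)](\theta_i))$, where $\mathcal{R}$ is the
parallel-beam Radon transform (bilinear sampling along rays, detector
centre $(n+1)/2$, rotation of the field equivalent to shifting the angle).
Each frame uses the single instantaneous angle at its exposure start: at
the reference settings the stage moves 0.072° per frame, well under one
detector pixel at the sample edge, so intra-frame blur is negligible; a
`blur_substeps` flag averages sub-angle renders for stress tests. The
detector model is separable and linear — additive dark offset,
multiplicative smooth flat-field vignette — with Poisson noise on photon
counts (default flux 5000 photons/pixel/frame) and Gaussian read noise on
darks. Twenty darks and twenty flats are simulated once, at the start of
the scan, and stored inline, matching the convention of acquiring
correction fields before the rotation begins. Where the angular step
divides 360° exactly, render angles are reduced in *index* space so frames
at angles equal mod 360° are bit-identical.

Preprocessing is the standard chain: reference fields combined by pixelwise
median (robust to outlier frames; mean available), transmittance
$T = (P - D)/(F - D)$ with dead pixels ($F \le D$) filled from the nearest
valid neighbour and flagged, then $p = -\ln\max(T, \varepsilon)$ with
$\varepsilon = 10^{-6}$; the clamped-pixel count is carried as a QC metric.
No ring suppression is applied by default. The correction is scale-
invariant and, in the noiseless limit, inverts the forward model to machine
precision.

## Reconstruction

`fbpReconstruct` is filtered back-projection with explicit conventions,
since none are universal: pixel-centre coordinates; rotation axis
projecting to detector column $(n+1)/2 + c$ for centre offset $c$; linear
interpolation both in projection and back-projection; output $n \times n$
at the detector pitch, zeroed outside the inscribed circle; grayscale is
unnormalized attenuation. Rows are convolved with the band-limited ramp
kernel ($h_0 = 1/4$, $h_k = -1/(\pi k)^2$ for odd lags) via FFT with
zero-padding to at least twice the row length — exactly linear convolution —
with optional Shepp–Logan or Hann apodization; the default is the plain
ramp. Each filtered row is smeared at its own acquisition angle, so
windows may start anywhere on the (unwrapped) circle: the parallel-beam
identity $p(\theta + 180°, r) = p(\theta, -r)$ is honoured by the geometry
itself rather than by physically flipping rows. Spans covering several
half-turns are averaged by their coverage, so a full 0–1080° reconstruction
is the mean of its six half-turns and has correspondingly lower noise.

Two independent checks pin the implementation down. A brute-force oracle —
direct time-domain convolution plus per-pixel loop back-projection, written
separately from the package code — agrees with the FFT/vectorized path to
better than $10^{-6}$ of dynamic range on small grids. And on a uniform
disc the reconstruction recovers the attenuation value quantitatively
(core mean within a fraction of a percent noiselessly).

The key correctness property of the time-stepping interpretation is
*window invariance*: for a static object without noise, any two valid 180°
windows reconstruct the same image. Windows whose start angles differ by a
multiple of 180° agree to machine precision ($\sim 10^{-15}$ normalized
RMSE); windows at arbitrary offsets sample the half-turn at shifted angle
sets and agree to interpolation tolerance ($\sim 4 \times 10^{-3}$ at 601
angles per 180°, comfortably below the 1 % working tolerance used in the
tests).

## Temporal quantification

`progressionCurve` takes the ordered tomogram sequence, forms difference
maps $\mu_0 - \mu_t$ against the first (reference) tomogram — positive
values mean material loss — and segments the cavity with one threshold
applied to the whole series. Threshold rules:

* `"mad"` (default): $k \times$ the robust noise scale (scaled MAD) of the
  final difference map, $k = 4$. On a signal-free series this segments
  essentially nothing, which keeps the static-phantom null band tight —
  the property the onset estimator relies on.
* `"otsu"`: Otsu's threshold on the final map's in-circle histogram.
  Appropriate for a single map with a clear cavity; on a *noise-only* map
  Otsu has no bimodality to find and splits the noise distribution near
  zero, reporting about half the circle as "cavity", which is why it is
  not the series default.
* a fixed numeric value, for exactly reproducible analyses.

`segmentCavity` optionally keeps only the largest connected component to
suppress speckle. The cavity-area series is reported against
$t_{\mathrm{mid}}$, together with the mean grey value in a fixed ROI and
the fraction of non-decreasing steps. The onset estimator takes the first
$t_{\mathrm{mid}}$ whose volume exceeds a null band (mean + 3 SD of a
static-phantom run under the same noise model); with disjoint windows this
localizes the onset to within one window duration by construction.

Two systematic effects are worth knowing about. Segmentation slightly
over-counts at the blurred cavity rim (the threshold sits below the
half-contrast contour), a few percent of the final area at the default
contrast. And material dissolving *during* a window violates the
static-object assumption of FBP; `motionBlurQC` quantifies this as the
NRMSE between the window's reconstruction and an ideal reconstruction of
the phantom frozen at $t_{\mathrm{mid}}$ — reported, not corrected. At the
default kinetics the front advances ~1.5 µm per window and the metric stays
small. No image registration is performed anywhere: simulated sequences
are co-registered by construction, and registration of real data is a
documented prerequisite, not a feature.

## Numerical and design choices

* **Indices are zero-based** throughout the user API, matching beamline
  frame numbering; R's internal 1-based arrays are an implementation
  detail.
* **Commensurability tolerance**: a range must be a multiple of the step
  within $10^{-9}$ degrees; the error names the two nearest commensurate
  ranges.
* **Ties and degenerate inputs**: an empty segmentation mask is a valid
  result; a zero sinogram reconstructs to zero; `mu_dissolved_frac = 1`
  yields contrast-free dissolution and a zero volume series; all-dead
  detector frames are a hard error, single dead pixels are filled and
  flagged.
* **Containers**: scans and tomograms are written as multi-page 32-bit
  TIFF stacks with a JSON sidecar carrying angles, times, serialized
  geometry, normalization ranges and the configuration hash; the 32-bit
  normalized container round-trips to ~$10^{-9}$ relative. Configurations
  are YAML and round-trip losslessly.
* **Determinism**: one integer seed controls the only stochastic component
  (detector noise); equal seeds give bit-identical stacks, and the demo
  pipeline's outputs are byte-reproducible given config + seed.

## Problem sizes

The test suite and the demo run the full pipeline at a desk scale chosen by
the same fence-post arithmetic as the reference acquisition: a 0–1080° scan
of 3601 frames at 0.3° (six disjoint 601-frame/180° windows at stride 600,
window starts at 0°, 180°, …, 900°), a 96-px detector row and a 96×96
phantom; overlapping enumerations use stride 300. The oracle comparison
uses 48–64 px grids with ~100 angles. A full demo — simulation,
six reconstructions, analysis, consistency checks — completes in well under
a minute on one CPU.

## Known limitations

Parallel-beam only (no cone/fan/helical geometry); scalar centre-of-rotation
offset, no tilt model or automatic centre search; no iterative or
temporally regularized reconstruction; no phase retrieval, ring correction
or zinger removal beyond the dead-pixel mask; monochromatic attenuation
only. Windows never wrap across scan-file boundaries — concatenate
multi-file experiments explicitly first.
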