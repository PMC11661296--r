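---
title: "Quantifying membrane binding and ER morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane binding and ER morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimquant)
```

## The measurement problem

Peripheral membrane proteins such as amphipathic lipid packing sensor (ALPS)
motifs and the C2 domain of cytosolic phospholipase A2 adsorb to lipid
bilayers in proportion to the availability of hydrophobic packing defects,
which grows with membrane tension. Fluorescence imaging therefore gives an
indirect tension readout: the amount of labelled probe on a membrane,
relative to a reference pool, tracks the tension state of that membrane.
rimquant implements three such readouts:

1. **GUV equilibrium binding** — the median probe intensity along the rim of
   a giant unilamellar vesicle, normalized across protein purification
   batches, as the bound signal in an adsorption isotherm.
2. **Nuclear-membrane (NM) binding ratio** — the median probe intensity
   along a contour on the nuclear envelope divided by the median along a
   contour in the nucleoplasm, per nucleus and time point, normalized to
   the first frame.
3. **ER morphology** — per field of view (FOV), the median object area and
   circularity `4 * pi * A / P^2` of segmented endoplasmic-reticulum
   structures, and their fold change over time. Vesiculation of the tubular
   ER network shows up as a simultaneous drop in area and rise in
   circularity.

The binding ratio is a *proxy* for inner-nuclear-membrane tension; the
package never converts it to physical tension units, and none of the
biological claims resting on the readout are computed here.

## Equilibrium model

Bound probe fluorescence versus domain concentration is fitted with the
Langmuir adsorption isotherm with Hill expansion,

$$B_\mathrm{bound} = B_\mathrm{max}\,
  \frac{[D]^H}{[D]^H + K_d'^{\,H}},$$

with saturation amplitude $B_\mathrm{max}$, apparent dissociation constant
$K_d'$ (nM) and apparent Hill coefficient $H$. `fit_hill()` estimates the
three parameters by nonlinear least squares on the log scale (which enforces
positivity), with a multi-start over the concentration quartiles for $K_d'$
and $H \in \{0.5, 1, 2\}$; the lowest-RSS converged fit wins. 95% confidence
intervals come from the asymptotic covariance of the log parameters with a
$t$ quantile on $n - 3$ degrees of freedom; a seeded bootstrap was considered
and rejected as default because the asymptotic intervals already cover the
truth in ≥ 90% of simulations at the noise levels of interest (the suite
checks this). Binding *rates* are ordinary-least-squares slopes on the
linear part of a ratio time course; since "linear part" is not a formal
object, `estimate_rate()` defines it operationally — the sliding window of
`ceiling(0.3 n)` frames with OLS $r^2 \ge 0.9$ that maximizes the slope in
the direction of net change (falling back to the maximum-$r^2$ window) — and
reports the chosen window so every rate is auditable.

Group comparisons use the two-tailed Welch $t$ test with the conventional
star categories (`*` ≤ 0.05 through `****` ≤ 0.0001); no multiple-testing
correction is applied — stars are reported per comparison, as is
conventional in this literature. For correlation plots the per-FOV ER value
is broadcast to every
nucleus in that FOV (`join_fov_correlation()`), because neighbouring cells'
ER cannot be separated reliably.

## Image-analysis pipelines

All pipelines share one container (`image_stack`: a T,C,Z,Y,X array plus a
`pixel_calibration` of dx, dy, dz in µm and dt in minutes) and a common
segmentation core built on EBImage primitives. Pixel coordinates are
1-based in R fashion; physical distances always go through the calibration,
because the method mixes pixel-unit parameters (blur radii, 3-px contour
widths) with micrometre-unit parameters (the 50 µm tracking bound).

**GUV rim quantification.** A user-supplied line from GUV centre to edge
replaces interactive clicking. The crop is a square of half-width
`ceiling(1.5 × line length)`; preprocessing is a 0.1–99.9 percentile rescale
to [0, 1] (robust to hot pixels) and a 3D Gaussian blur of σ = 3 px, the σ
in z scaled by dx/dz. "3-pixel radius" is read as σ = 3 px — the common
convention — and is configurable. Each slice is partitioned by
marker-controlled propagation (`EBImage::propagate`) between a marker at the
line origin and background markers at the crop corners; a basin that floods
the slice or contains no above-Otsu signal is discarded, the rest is
hole-filled. The slice with the largest segmented area is the middle
section (ties to the lowest index, for determinism). The 3-px-wide rim
contour is the band at the segmentation boundary, allowed to shift ±3 px
across it and snapped to the brightest position: after blurring, the
watershed boundary can rest on either flank of the membrane's intensity
crest, and the snap puts the contour on the membrane itself rather than on
a flank. Rim medians are always taken on **raw** intensities — batch
normalization against a 1 µM reference solution is only meaningful on raw
counts — and the normalized rim is `rim_median / reference`.

**Nucleus segmentation, tracking and binding ratio.** Preprocessing is
percentile normalization, σ = 1 px 3D blur, and per-slice rolling-ball
background subtraction (default ball radius 50 px, exposed in the
configuration; the radius must exceed the object radius, a documented
constraint of rolling-ball subtraction). The rolling ball is implemented as
grayscale opening with a disc element; EBImage's grayscale morphology works
on [0, 1], so the wrapper rescales around it. Segmentation is masked-object
thresholding followed by a marker-controlled watershed: global Otsu gives
the foreground; every connected component is re-thresholded by a local Otsu
over its padded bounding box (object *plus local background* — thresholding
the object's own voxels would split uniform objects), and the refinement is
kept only if it retains ≥ 60% of the component, a guard against degenerate
local thresholds on rim-dominant nuclei; markers come from a geometric
per-slice erosion of the mask (radius 7 px, with a per-component fallback),
which separates touching nuclei regardless of their intensity profile;
per-slice intensity propagation, with labels carried into marker-free
adjacent slices, assigns every voxel. EBImage's morphology and `propagate`
are two-dimensional, so 3D connectivity is provided by across-slice
union-find merging — the only hand-written glue in the chain. Objects under
200 voxels are dropped.

Tracking is greedy nearest-neighbour centroid linking in micrometre space
with a hard 50 µm displacement bound — sufficient because nuclei move far
less than that between frames — and no motion model. Tracks shorter than 3
frames are dropped by default.

Per tracked nucleus and frame, the middle section is the slice with the
largest label area (ties to lowest z). The membrane contour is the 3-px
band inside the segmentation boundary; the background ("nucleoplasm")
contour is a 3-px-wide ring at half the equivalent radius, computed inside
the hole-filled mask — the fill matters when a dim nucleoplasm drops out of
the intensity mask — and placed away from both the envelope and the
nuclear-droplet region near the centre. Placement of this ring is a design
choice (the method's description says only "inside the nucleus") and is
configurable. Ratios are medians of raw probe intensities,
membrane / background; `ratio_norm` divides by the first frame (exactly 1
at t0). The ratiometric variant divides the probe membrane median by the
lamin-channel membrane median and controls for the known caveat that a
falling nucleoplasm signal can mimic rising membrane binding; the test
suite constructs exactly that phantom and shows the ratiometric readout
staying flat.

**ER morphometrics.** With a luminal label the same masked-object/watershed
chain runs at ER scale (minimum size 10 px; markers are the refined
components themselves — geometric erosion would shatter 3-px-wide tubules).
With a membrane label a multiscale Hessian ridge (vesselness) filter over
σ ∈ {1, 2} px highlights tubular structure, suppressed on blobs by the
eigenvalue-ratio term; the response is Otsu-thresholded. Because
"perimeter" is a 2D quantity and z-steps (1.4–2 µm) are an order of
magnitude coarser than pixels, morphology is measured on a 2D analysis
plane (a chosen slice or a maximum-intensity projection). Area is pixel
count × dx·dy. The perimeter estimator defaults to a subpixel boundary
polygon — marching squares at the 0.5 level of the lightly smoothed mask —
because the standard 4-direction Crofton count (also provided, as
`method = "crofton"`, and matched against reference values in the tests)
biases disc circularity to ≈ 0.94 at radius 10 px and drifts ≈ 4% between
radii 10 and 30, while the polygon estimator is accurate to 0.2% and scale
stable to ≈ 1%. Circularity is clamped to [0, 1] with the raw value kept in
the per-object table. Medians are per FOV, and fold changes divide by the
t = 0 record (error if it is empty).

## The phantom generator

Synthetic scenes exist to give every pipeline a ground truth: geometry is
rendered analytically on the anisotropic voxel grid (physical-space
ellipsoids sampled at dx, dy, dz), then passed through an acquisition model
— Gaussian PSF blur, optional multiplicative shading, Poisson shot noise
followed by additive Gaussian read noise (the standard EMCCD
approximation), rounding to non-negative integer counts. Integer counts
make TIFF round trips bit-exact. Defaults: σ_PSF = 1 px, read noise SD 2,
background 10, 0.16 µm pixels, 1.5 µm z-steps, 1 min frames; nucleus
phantoms default to 6 × 6 × 3 µm semi-axes (a realistic adherent-cell
nucleus at this pixel size) with a 5-px rim whose amplitude-to-interior
ratio is the ground-truth binding signal; ER scenes place non-overlapping
capsules (tubules, length 8–16 µm, width 0.48 µm) or discs (vesicles,
radius 0.6–1.3 µm) whose analytic area/perimeter/circularity are recorded
exactly. GUV shells default to radius 8–10 µm with a ~2 px shell. All
generators are deterministic given their seed.

What the phantoms do *not* emulate: textured chromatin and cytoplasmic
autofluorescence, nuclear envelope invaginations, true ER network topology
(tubules here are disjoint, so per-object ground truth stays analytic),
depth-dependent aberrations, photobleaching, and drift in z. Passing the
suite therefore demonstrates that the *measurement chain* is faithful on
known geometry at realistic noise, not that segmentation is robust to every
real-microscopy artifact.

Two rendering choices deserve explicit statement. First, the binding-ratio
fidelity checks (and the pipeline's built-in demo scene) are rendered
without PSF blur: with a 1-px PSF the membrane contour's median sits partly
on the rim's blurred flank and the absolute ratio is compressed toward 1
(by roughly 25% at ratio 3) — a systematic optical bias that t0
normalization only partially cancels and that affects the real method
equally. The noise-robustness guarantee (ratio RMS error < 5% at 2% read
noise) is therefore stated at PSF 0, where it isolates the noise response;
the PSF bias itself is a documented limitation of rim-contour readouts.
Second, osmolarity arithmetic treats the water + 1.26 mM CaCl2 diluent as
ideally fully dissociated (3 × 1.26 = 3.78 mOsm), and
`dilution_osmolarity()` returns unrounded values (269.8 / 303.5 mOsm for
the two standard dilution presets).

## Numerical choices and degenerate inputs

- Middle-slice and tie-breaking rules are deterministic (lowest index).
- A constant image degenerates percentile normalization to zeros with a
  warning, not an error; rolling-ball of a constant is exactly zero.
- An erosion that empties a mask falls back to the full mask with a warning
  (objects thinner than twice the contour width).
- An empty background ring flags the frame's ratio as missing (NA) rather
  than fabricating a value; `er_fold_change()` refuses an empty t = 0.
- Zero-variance Welch comparisons return t = 0, p = 1 on equal means.
- A constant series has $r^2$ defined as 1 (perfect fit by a flat line), so
  `estimate_rate()` returns slope 0 rather than NaN.
- Problem sizes in the tests (160–232 px planes, 9 z-planes, ≤ 10 frames,
  200 replicate fits) were chosen so the full suite exercises every chain
  end-to-end in well under a minute per file on one core.

## Known limitations

- Absolute binding ratios carry the PSF flank bias discussed above; only
  ratios of ratios (normalized series, group contrasts) should be compared
  across imaging conditions.
- The GUV pipeline needs a seed line; there is no unseeded GUV detector.
- Tracking is greedy nearest-neighbour: crossing nuclei within one frame
  interval can swap identities; the 50 µm bound makes this unlikely at the
  intended frame rates.
- The ER "tubular vs vesiculated" contrast is validated directionally
  (fold changes), not against absolute circularity values, which depend on
  the perimeter estimator and the analysis plane.
- OME-TIFF support covers reading embedded OME-XML (sizes, physical pixel
  sizes, channel names); writing uses a JSON sidecar because the installed
  TIFF writer cannot embed description tags.
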