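# rimquant

Quantitative image analysis of peripheral-protein binding to membranes, for
cell biologists measuring membrane tension by proxy. Fluorescent tension
probes (ALPS-motif sensors, the cPla2 C2 domain) partition onto membranes in
proportion to tension-induced lipid packing defects; rimquant turns
multi-channel fluorescence z-stack time lapses of such probes into numbers:

- **GUV equilibrium binding** — median probe intensity along the rim of a
  giant unilamellar vesicle (middle optical section, 3-px contour),
  normalized by a 1 µM batch reference, and fitted with the Langmuir
  adsorption isotherm with Hill expansion

  *B*<sub>bound</sub> = *B*<sub>max</sub> · [D]<sup>H</sup> / ([D]<sup>H</sup> + *K*′<sub>d</sub><sup>H</sup>)

  by nonlinear least squares with 95% confidence intervals (`fit_hill()`
  returns a classed model object with `print`/`summary`/`coef`/`predict`/
  `plot`/`residuals`/`simulate` methods).
- **Nuclear-membrane binding ratio** — fully automatic 3D nucleus
  segmentation (masked-object thresholding + marker-controlled watershed),
  nearest-neighbour tracking under a 50 µm displacement bound, and per-
  nucleus time series of the membrane-contour / nucleoplasm-contour median
  intensity ratio, t0-normalized, with an optional lamin-ratiometric
  variant. Binding rates are OLS slopes on the (auditable) linear part of
  the series; groups are compared with Welch *t* tests and star categories.
- **ER morphology** — segmentation of the endoplasmic reticulum from
  luminal (watershed) or membrane (Hessian filament filter) labels, and
  per-field-of-view median object area and circularity 4πA/P² with fold
  changes over time; ER vesiculation appears as fold-area < 1 and
  fold-circularity > 1.
- **Synthetic phantoms** — spherical GUV shells, ellipsoidal nuclei with
  prescribed rim/interior ratio time courses, tubular or vesiculated ER
  scenes, all rendered through a PSF + Poisson–Gaussian acquisition model
  with exact ground truth, so every pipeline is validated end-to-end.

## Worked example

```r
library(rimquant)
out <- run_demo(seed = 0, dir = "demo-out")
```

generates all three synthetic scenes plus a binding curve, runs every
pipeline, and writes `guv.csv`, `nm.csv`, `er.csv`, `hill_fit.json` and a
summary. With seed 0 the summary reads:

```
- GUV rim median: 79 (normalized 0.79)
- nuclear binding ratio_norm at final frame: 2.8199
- ER fold_circularity at final frame: 7.8101
- ER fold_area at final frame: 0.3807
- Hill fit: Bmax 1.0290, Kd' 103.29 nM, H 2.000
```

Reading these: the GUV scene's shell (true amplitude 120) is read back as a
rim median of 79 after PSF blur, i.e. 0.79 of the 1 µM reference — the
batch-normalized bound signal. The nuclear phantom ramps its true
rim/interior ratio from 1 to 3; the measured t0-normalized ratio reaches
2.82 (the residual gap is the camera background offset included in the
scene). The ER pair (tubular network → vesicles) yields the vesiculation
signature: median circularity up 7.8-fold, median area down to 0.38. The
Hill fit recovers the generating parameters (Bmax 1, Kd′ 100 nM, H 2)
within a few percent from an 8-point curve with 2% noise.

Individual steps are plain functions — `crop_guv()` → `preprocess_guv()` →
`segment_guv()` → `measure_rim()` → `normalize_rim()`;
`preprocess_nuclei()` → `segment_nuclei()` → `track_nuclei()` →
`measure_nm_binding()`; `segment_er_luminal()`/`segment_er_membrane()` →
`measure_er_morphology()` → `er_fold_change()` — configured through one
YAML file (`load_config()`), which also carries the osmotic-dilution
presets (`dilution_osmolarity(341, 80, 320)` → Δπ ≈ 270 mOsm).

See `vignettes/methods.Rmd` for the models, parameter defaults, design
decisions and limitations.

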