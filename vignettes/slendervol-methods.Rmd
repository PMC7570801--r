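---
title: "slendervol: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slendervol: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slendervol)
```

## The model

`slendervol` reconstructs the volume of slender, approximately
axi-symmetric produce from one calibrated top-view silhouette. The solid
is treated as a stack of `n` equal axial slices. Each cross-section is an
ellipse whose in-plane diameter is the visible silhouette width `w` and
whose vertical diameter is `w / r`, with `r` the product's width/height
aspect ratio. Interior slices are frustums ("chopped pyramids"),

$$V_k = \frac{h}{3}\left(B_k + B_{k+1} + \sqrt{B_k B_{k+1}}\right),
\qquad B_k = \pi \frac{w_k}{2}\cdot\frac{w_k}{2r},$$

and the two end slices are elliptical caps $V = \pi d_1 d_2 h / 6$.

Assumptions worth stating explicitly:

* **Axi-symmetry up to a fixed squash.** Cross-sections are ellipses of a
  constant aspect ratio along the whole object. Produce with lobed or
  star-shaped sections is out of scope.
* **A straight axis.** Strong bending (a banana) violates the slicing
  geometry; see Limitations.
* **The cap formula is, numerically, a semi-ellipsoid.** The field often
  calls the tip piece an "elliptical cone", but $\pi d_1 d_2 h/6$ is
  exactly the volume of half an ellipsoid with diameters $d_1, d_2$ and
  half-axis $h$ (a true elliptical cone would be $\pi d_1 d_2 h/12$). We
  keep the semi-ellipsoid form: rounded produce tips are much closer to
  ellipsoidal caps than to cones, and the choice is validated against
  analytic fixtures.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `aspect_ratio` (`r`) | – | 0.9531 carrot, 0.9677 cucumber | mean cross-section width/height of each product; visible width maps to depth as `w / r` (width is the top-view-visible dimension, height the unseen vertical one) |
| `density` | g/mL | 1.0987 carrot, 1.019 cucumber | cohort-average density converting volume to mass |
| `n_slices` | – | 8 | the slice-sweep error flattens by ~8 slices for carrot- and cucumber-shaped bodies; more slices only re-measure noise |
| `px_per_cm` | px/cm | user-supplied | measured from a calibration target; never inferred from image metadata |
| `threshold_config()` | – | Otsu on saturation | separates coloured produce from a white/grey background with no manual tuning; explicit HSV boxes available for difficult lighting |

Class tables are half-open `[low, high)` intervals — a boundary mass goes
to the upper class — with one deliberate exception: the cucumber table
closes L at 200 g (`incl_high = TRUE`) so that XL means *strictly more
than* 200 g, matching the published table's "<100 / 100–150 / 150–200 /
\>200" reading. Masses outside every interval report `"out-of-range"`
rather than being force-assigned.

## Measurement conventions

Decisions the sources leave open, frozen here and exercised by the tests:

* **Width = caliper span**, the distance between the two extreme
  foreground pixels on a scan line, not a foreground-pixel count. This
  matches what a physical caliper reads; the two differ only for concave
  or bent objects, which are out of spec.
* **Scan lines at slice borders** (`n + 1` lines for `n` slices): the
  frustum needs both faces of every slice.
* **Caps occupy exactly the first and last slice**, and their base
  diameter is the width at the adjacent interior station — the measured
  width at the very tip is typically a meaningless 0–2 px.
* **Sub-pixel sampling.** Scan lines are sampled every 0.5 px with
  nearest-pixel lookup. The extreme hits undershoot each true edge by up
  to half a step, so spans get a one-step correction; end stations are
  sampled 0.25 px inside the box faces (a station exactly on the face can
  round off the object). The rasteriser uses half-open pixel-centre
  bounds, so a `w`-px bar renders to exactly `w` pixels on any grid
  parity. With these conventions a 200 × 50 px rectangle at 20 px/cm
  measures exactly 10 × 2.5 cm.
* **Morphological cleanup** is a single 3×3 opening then closing, plus
  largest-component retention and hole filling — enough to remove speckle
  without biting visibly into a multi-hundred-pixel silhouette.
* **Ellipse fitting** (for checking cross-section shape) is the direct
  algebraic least-squares fit with the ellipse constraint
  $4ac - b^2 = 1$; the fitted conic must satisfy
  $b^2 - 4ac < -10^{-12}$ after normalisation or the fit errors out.

## The synthetic world

`make_shape()` defines solids by their half-width profile $a(t)$ with
closed-form volumes $V = (\pi/r)\int_0^L a(t)^2\,dt$; `render_top_view()`
rasterises them at arbitrary rotation, resolution and noise;
`make_population()` emulates a grading cohort.

* **Body plans.** Carrot-like: $a(u) \propto u^{s}(1-u)^{p}$ with
  shoulder exponent $s \sim U(0.35, 0.55)$ and tip exponent
  $p \sim U(0.60, 0.90)$ — a rounded (near-ellipsoidal) shoulder and a
  tapering, near-conical tip, the geometry of an actual carrot.
  Cucumber-like: $a(u) \propto \sin(\pi u)^{q}$, $q \sim U(0.40, 0.60)$ —
  a blunt cylinder-ish body with rounded, roughly hemispherical ends. An
  earlier draft used an almost flat-cut shoulder; that produce-that-looks-
  chopped geometry biases the cap model by several per cent and was
  replaced before the defaults were frozen — see Limitations.
* **Cohort sampling** is stratified: each sample draws a size class
  (round-robin), a true mass inside it, then a length in 12–22 cm
  (carrot) / 14–22 cm (cucumber) and the width that yields exactly that
  mass, rejected to 2.5–4.5 / 3–5 cm. This guarantees every class is
  populated at realistic dimensions. One geometric fact falls out: a
  carrot heavier than ~265 g cannot exist inside 22 × 4.5 cm at carrot
  density, so the top of the 2L class (to 320 g) is unreachable in the
  synthetic world; 2L is represented by its attainable lower portion.
* **Noise** is a smooth spline-interpolated boundary jitter (SD in px)
  plus salt-and-pepper pixel flips. The end-to-end grading check uses
  jitter SD 1 px and flip rate $10^{-4}$ as a plausible segmentation-
  noise level. Everything is deterministic from one integer seed.
* **The bent spindle** bends the axis along a circular arc; its ground
  truth uses the centroid (Pappus) rule — cross-sections centred on the
  arc sweep volume $\int A(s)\,ds$ — verified in the tests against an
  independent plane integration.
* **What the generator does *not* emulate:** texture, lighting gradients,
  shadows, specular highlights, colour variation, camera distortion,
  occlusions. A green synthetic test therefore establishes the *geometry*
  of the pipeline (segmentation-to-volume, given a clean two-tone scene),
  not robustness to photographic conditions.

## Numerical behaviour worth knowing

* **Cylinder end bias.** For a perfectly flat-ended cylinder the cap
  model keeps only 2/3 of the end slices' volume, an exact relative error
  of $2/(3n)$ — about 8% at $n = 8$. This is the price of assuming
  rounded tips; for actual rounded produce the residual is a fraction of
  a per cent. Flat-cut produce (e.g. trimmed ends) will read slightly
  low.
* **Slice count.** Error falls steeply from $n = 3$ and flattens by
  $n = 8$; beyond ~13 the changes are within measurement noise, matching
  the behaviour reported for real cohorts.
* **Resolution.** Between roughly 40 and 100 px/cm the volume error is
  dominated by modelling, not rasterisation; dropping from a
  1538×2175-class calibration to 720×960-class costs well under one
  percentage point on clean fixtures.
* **Tie-breaks.** A square bounding box reports `length == width` with an
  arbitrary angle; the box angle is normalised to [0°, 180°).

## Limitations

* **Bent produce.** The straight-axis slicing underestimates strongly
  bent objects (the silhouette width perpendicular to the box axis is not
  the cross-section diameter). The `bent-spindle` fixture exists to
  quantify this degradation; no axis-following correction is attempted.
* **Flat-cut ends** bias volume low by up to $2/(3n)$ (see above).
* **Border-touching objects** yield a warning and a `border_touch` flag;
  their measurements are clipped and should be discarded upstream.
* **Densities are constants.** Real density varies within a cohort; the
  grading error this induces is part of the published confusion matrices
  and is not modelled further here.
* **One object per frame.** Multi-object scenes, shadows and colour
  constancy are out of scope; segmentation assumes a contrasting
  background.
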