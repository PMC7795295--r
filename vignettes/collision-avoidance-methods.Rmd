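---
title: "Methods: stereo-vision bird detection and collision avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo-vision bird detection and collision avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stereobird)
```

This vignette is the package's own account of the measurement model it
implements, the parameters that matter, the design decisions that were
genuinely open, and what the synthetic validation does and does not show.

## 1. The measurement chain and its assumptions

The system observes the air space around a wind turbine with pairs of
identical cameras on a vertical, tilted baseline and derives, per fused
detection: range, position, physical size, a size class, and an action.
Three modelling assumptions run through everything:

* **Ideal pinhole optics.** No lens distortion or intrinsic calibration is
  modelled; fields of view and image sizes follow `FoV = 2 atan(VSS/2f)`
  and `px = S · f · (VSR/VSS)/D`. At the 63° field used here a real lens
  deviates at the image margins; the quantization bound, not distortion,
  is treated as the dominant error.
* **Integer-pixel disparity.** Disparity is a difference of object-centre
  rows with no sub-pixel interpolation. That makes the range resolution
  limit exact and analytic: `ΔDb = Db/(2·ydiff)`, and correspondingly for
  distance and height. These half-widths are symmetric by construction
  (exact-differential propagation); no asymmetric interval arithmetic is
  attempted.
* **Perpendicular gliding posture.** A bird is treated as an isosceles
  triangle seen broadside: base = wingspan, height = body length,
  area = PW·PH/2. This is both the size-estimation model and the shape the
  scene generator renders, which keeps the ground truth analytic.

The rig is parametrized by a single *baseline-aligned axis*: the sensor is
mounted portrait, so its long axis (3280 px, 63.0° for the reference
sensor) runs along the baseline and carries the disparity, while the short
axis (2464 px, 49.4°) is transverse. The tilt α defaults to half the
baseline-axis field of view — the mounting that lays the lower edge of the
field on the horizontal — but is independently configurable because a real
installation may deviate. The printed drone-test numbers are regenerated
exactly by this parametrization (15 px ↔ 178.4 m at B = 1 m); the field
calibration tables imply a slightly different rig constant
(Db·ydiff ≈ 2719 rather than 2676), so it is configuration, never
hard-coded.

Row convention: y is 1-based and continuous with the optical centre at
VSR/2, increasing away from the tilt, so `y_u − y_d ≥ 1` for any physical
object in front of the rig; the disparity floor of 1 px doubles as a
false-pair filter.

## 2. Tunable parameters

All constants live in one YAML file (`inst/extdata/default_config.yaml`);
nothing in the processing logic hard-codes them.

| Parameter | Default | Units | Why |
|---|---|---|---|
| baseline B | 1 | m | mounting practicality; ranging to 300 m stays within ~±17 m at 9 px |
| vsr_axis / fov_axis | 3280 / 63.0 | px / ° | portrait-mounted reference sensor |
| tilt α | fov_axis/2 | ° | lower field edge on the horizon |
| pre-blur | 5 px, σ 1.5 | px | suppress sensor noise before differencing |
| diff_thresh | 25 | intensity | kills illumination drift (a +5 global shift is invisible) |
| merge blur | 21 px, σ 3.5 | px | bridges up to ~10 px between motion ghosts |
| binary_thresh | 10 | intensity | low, so 2 px thin birds survive the wide merge blur |
| min_w × min_h | 12 × 2 | px | detectability rule of thumb |
| refine_thresh | 50 | intensity | object-vs-sky contrast for current-frame re-measurement |
| false-pair offset | 150 | px | rejects near-field insects and mismatches |
| class bounds | 0.68/1.26/1.505 m … | m, m² | published small/medium/large boundaries |
| deterrents / stop | 300 m all; 200 m large | m | illustrative policy, fully user-set |
| CNN recipe | 32/32/128, Adam 1e-5, ε 1e-7, 50 epochs, split 0.1 | — | production recipe |

Class intervals are closed at their stated endpoints; the presentation gaps
between classes (1.25 → 1.26 m) are bridged half-open, `[lo, next_lo)`, so
classification is total and monotone — which in turn makes the safety-first
max rule monotone. Where the published boundary texts disagree (0.65 vs
0.68 m for the small wingspan bound), the tabulated values are the
defaults. The published per-class "detection range" column is treated as
configuration data, not recomputed, because it does not follow from the
stated optical constants.

## 3. Motion detection: the one genuinely open design

The published pipeline names its stages but not its constants, and two of
its stated behaviours conflict under any single Gaussian/threshold
setting: a fast object's difference ghosts (up to ~10 px apart) must merge
into one component, yet a 2 px-tall bird must survive, and measured widths
must reflect the bird, not the bird-plus-motion envelope. A 5×5 merge blur
cannot bridge 10 px; any blur that can, inflates the bounding box by
several pixels at any threshold low enough to keep thin birds.

The package therefore splits the roles: the wide merge blur with a *low*
binary threshold (21 px/σ 3.5/10) does the fusing, and a **refinement
step** re-segments each mask component against the local background in the
*current* frame (|I − background| > 50, background = median of the ROI
border, ROI grown until the object no longer touches its edge). The
refined component provides contour, centroid and sizes. Consequences:

* sizes track the silhouette to ±2 px regardless of frame-to-frame motion;
* a component in whose ROI no current-frame object exists is a ghost of a
  departed object and is dropped;
* two components refining onto the same object (unfused distant ghosts)
  are deduplicated by refined centroid.

Contour area is the shoelace (Green's formula) evaluation over the traced
boundary polygon plus the lattice boundary correction (Pick's theorem), so
a filled w×h rectangle measures exactly w·h px² and the area can never
exceed the bounding box. The published text is ambiguous on whether the
"number of pixels over the contour" means enclosed area or perimeter; the
Green formula yields area, so area is implemented.

## 4. The classifier and its scaled-down training recipe

No deep-learning framework is assumed: the CNN is implemented in the
package (im2col + BLAS GEMM; the memory-layout loops are compiled C++),
with finite-difference gradient checks pinning the backward pass to ~1e-7
relative error. Input crops are 100×100×3 scaled to [0,1] — the crop-mask
size; the published architecture never states its input size. Loss is
two-class cross-entropy behind a softmax; weights are He-normal, seeded.

The production recipe (learning rate 1e-5, 50 epochs, 90k-image corpus)
is the config default but is tied to that corpus, which is not available.
The package's validation instead trains on 2,000 synthetic crops for 10
epochs with Adam's conventional small-data rate of 1e-3 — at 1e-5, ten
epochs of 57 minibatches move the weights by ~10⁻², far too little for
any dataset — and requires ≥ 95 % held-out accuracy. A deliberately crude
baseline (single threshold on dark-pixel area) reaches ~85 % on the same
generator, confirming the classes are separable but not trivially
identical. The published accuracy figures belong to the proprietary corpus
and are not reproduction targets.

## 5. What the scene generator emulates — and what it does not

`render_stereo_frames()` draws filled triangle silhouettes at positions
obtained by inverting the localization equations algebraically, so
projection → localization is an identity to machine precision and every
rendered scene carries exact ground truth. The two validation campaigns
are scripted:

* **Silhouette campaign** — 0.8×0.3, 1.2×0.4, 1.5×0.5 m targets at
  50–300 m in 50 m steps, shifted 4 px between paired frames. The 0.8 m
  target's projected width crosses the 12 px floor just beyond 180 m, so
  the campaign reproduces the published detectability pattern (no returns
  at 200–300 m for small; none at 300 m for medium).
* **Drone campaign** — a circular flight at radius 143.3 m, height
  102.9 m, 15 m/s, with Gaussian jitter of 2.5/1.5 m matching the reported
  GPS scatter; frames are rendered only for samples inside one module's
  field of view.

Synthetic rendering deliberately omits: photometric realism (weather,
glare, motion blur), lens distortion, textured plumage, flocking, and any
GPS error structure beyond the stated jitter. Passing tests therefore
demonstrate the *geometry, propagation and logic* are implemented
correctly and are self-consistent — not that the detector or classifier
would achieve the same rates on field imagery. Field dispersion statistics
are matched only in order of magnitude (quantization-driven σ_D of a few
metres versus reported 7.7–8.4 m, which also contains real-world effects).

Rasterization note: the triangle's base row always carries the full
wingspan (width interpolates apex→base over the drawn rows); naive
ceil/floor spans systematically under-draw sub-pixel-placed small targets
and would push borderline 13 px targets under the 12 px floor.

## 6. Numerical choices and degenerate inputs

* Angles are degrees at every public interface, radians only inside trig.
  Unit conversions (mm ↔ m) are centralized.
* Pixel sizes are returned continuous; rounding is presentation, because
  the published table's rounding is internally inconsistent (its pH cells
  back-solve to a reference height of 0.22–0.25 m, not the stated bird).
* Disparity < 1 px, non-positive distances, even blur kernels, single-class
  training data, and all-zero confusion counts raise descriptive errors;
  empty scenes produce empty candidate lists and empty archives, not
  failures.
* Greedy ascending-distance matching is the tested contract for pairing
  the two views (the published formula's sequential-min structure). For
  well-separated objects it coincides with the optimal assignment — the
  test oracle enumerates all assignments up to 4×4 — and it never reuses
  an object.
* Metric denominators of zero yield `NA`, never silent zeros.
* The quantization-bound round trip holds with the bound evaluated at the
  true range; evaluated at the estimated range instead, a rounding error
  within half a pixel of exactly 0.5 can exceed the bound by O(1/ydiff) —
  a measure-zero edge the tests avoid asserting away.

## 7. Problem sizes used by the validation suite

The acceptance checks run: 1000 random positions for the round-trip bound;
18 scripted silhouette scenes (the six small-target scenes are re-detected
explicitly); 12 drone frame pairs; 2,000 crops / 10 epochs for the
classifier; 25 random matching instances against the exhaustive oracle.
Unit tests use a 10×-downscaled rig (328 px, identical fields of view) so
image-level behaviour is exercised at full fidelity but small cost.

## 8. Known limitations

* Single-module geometry: azimuth only selects which module sees the bird;
  no cross-module fusion or hand-off.
* No temporal tracking (no Kalman/multi-hypothesis state), no flock
  handling — one candidate per connected component per frame pair.
* No sub-pixel disparity, by design; range resolution beyond ~300 m
  degrades as Db²/(B·f_px).
* The refinement step assumes the object contrasts with the local sky by
  more than `refine_thresh`; low-contrast birds fall back to (or are lost
  with) the raw mask measurement.
* The CNN engine is minimal: no augmentation, batch normalization,
  scheduling, or architecture search.
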