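# stereobird

Bird collisions with wind-turbine rotors are a central conflict between
wind-energy expansion and raptor conservation. A practical mitigation is a
camera system on the tower that detects an approaching bird, estimates how
far away and how large it is, and then triggers escalating countermeasures
— strobe and audio deterrents, and for large raptors a turbine stop.
`stereobird` implements the full measurement chain of such a system as a
tested R library, together with a synthetic stereo scene generator that
provides exact ground truth, so every stage can be validated end to end
without field data.

The package is written for researchers and engineers who want to study,
reproduce, or redesign this class of system: wildlife-monitoring method
developers, wind-farm environmental-impact analysts, and anyone needing a
worked, testable example of low-cost stereo ranging with honest uncertainty
bounds.

## The model

**Optics.** A sensor of physical size VSS (mm) and resolution VSR (px)
behind a lens of focal length *f* images a field of view
`FoV = 2 atan(VSS / 2f)`; a bird of wingspan *S* at range *D* spans
`S · f · (VSR/VSS) / D` pixels. A rule-of-thumb detection floor of
12 px × 2 px then fixes which sensor/lens pairs can see which birds at
which ranges (`build_selection_table()`).

**Stereo ranging.** Two identical cameras are mounted one above the other
(baseline *B* = 1 m), both tilted up by α = FoV/2 so the lower edge of the
field grazes the horizon. An object on image rows `y_u` (upper camera) and
`y_d` (lower) has disparity `ydiff = y_u − y_d` and range

    Db = B · VSR / (2 · ydiff · tan(FoV/2)),

with horizontal distance `D = Db (tan φ_u sin α + cos α)` and height
`H = Db (tan φ_d cos α + sin α)`, where `tan φ = (2y/VSR − 1) tan(FoV/2)`.
Because disparity is an integer pixel count, range resolution is bounded by
the closed-form quantization half-widths

    ΔDb = Db / (2 ydiff),   ΔD = (D + B sin α) / (2 ydiff),
    ΔH = (H + B cos α) / (2 ydiff).

**Detection and identification.** Per camera, motion is found by two-frame
differencing (Gaussian pre-blur, absolute difference, threshold, a wider
Gaussian "merge" blur that fuses the two motion ghosts, binary threshold),
contours are measured by image moments and the shoelace (Green's-formula)
polygon area, candidates under 12 × 2 px are discarded, and each survivor
is cropped to a 100 × 100 patch. A compact CNN
(conv 32·3×3 → pool → conv 32·3×3 → pool → dense 128 → softmax 2)
classifies crops bird / non-bird.

**Fusion and decision.** Upper/lower detections are paired greedily by
centre distance (false pairs with offsets > 150 px or disparity < 1 px are
rejected), wingspan and body height follow from the range
(`PW = Db · p_w · VSS/(f · VSR)`), the bird's area is approximated by an
isosceles triangle (`Oapprox = PW · PH / 2`), and the bird is classed
small / medium / large against configurable boundaries using a
safety-first max rule — the largest class indicated by wingspan, height,
or area wins. Class and distance then select the action.

## Worked example

A bird is sighted at rows 2000 (upper) and 1985 (lower) on the reference
rig, spanning 30 × 9 px with a 140 px² contour in both views:

```r
library(stereobird)
rig <- stereo_rig()                      # B = 1 m, 3280 px, FoV 63.0°
loc <- localize(y_u = 2000, y_d = 1985, rig)
loc
#> <localization Db=178.42 m, D=164.66 m, H=112.83 m (ydiff=15.00 px)>
quantization_uncertainty(loc, 15, rig)$delta_db
#> [1] 5.947193
pair <- data.frame(yc_u = 2000, yc_d = 1985,
                   p_w_u = 30, p_w_d = 30, p_h_u = 9, p_h_d = 9,
                   o_s_u = 140, o_s_d = 140)
est <- estimate_size(pair, rig, optical_assembly(sensor_catalog()$C1, 3))
est
#> <size_estimate Db=178.42±5.95 m, PW=2.00 m, PH=0.60 m, Os=0.622 m^2, Oapprox=0.601 m^2>
cls <- classify_size(est)
decide_action(cls, loc$d)
#> [1] "strobe" "audio" "turbine_stop"
```

Read: a 15 px disparity puts the bird 178.4 m from the rig (±5.9 m from
pixel quantization alone), 164.7 m from the tower at 112.8 m height; its
2.0 m wingspan makes it a large bird inside the stop zone, so all three
countermeasures fire.

The synthetic end-to-end path — render a scene, detect, fuse, classify,
archive — is one call:

```r
cfg <- load_config()                              # shipped reference design
campaign <- generate_silhouette_campaign(cfg$rig, cfg$assembly)
events <- run_pipeline(cfg, campaign)             # 18 scripted canvas scenes
```

A thin command-line wrapper over these functions is installed at
`inst/cli/stereobird.R` (subcommands `design`, `simulate`, `train`,
`detect`, `run`, `evaluate`).

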