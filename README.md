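# ncfratio

Ratiometric (e.g. FRET/donor) biosensor imaging divides two noisy
fluorescence channels pixel by pixel. Near the cell edge, where the cell is
thin and the signal small, background subtraction followed by division
produces characteristic artifacts: after subtracting the background the
denominator approaches pure camera noise, and ratios blow up toward large
positive values, creating an apparent activity gradient at the edge that
has nothing to do with biology. Making the background subtraction *more*
accurate makes this worse, because the subtracted values then sit even
closer to the edge signal.

`ncfratio` implements the **noise correction factor (NCF)** approach for
this problem, aimed at anyone quantifying protein activity from
two-channel microscopy near cell edges. Instead of subtracting a
background from both channels,

```
Ratio_MBS(x,y) = (image1(x,y) - B1) / (image2(x,y) - B2),
```

a single constant, the NCF, is subtracted from the numerator only:

```
Ratio_NCF(x,y) = (image1(x,y) - NCF) / image2(x,y),   NCF = B1 - a0 * B2,
```

where `a0` is the proportionality coefficient between the pure channel
signals (`S1 = a0 * S2`) and `B1`, `B2` are the per-channel background
levels. Writing `image1 = a0*S2 + B1 + N1` and `image2 = S2 + B2 + N2`,
an exact rearrangement shows that the NCF ratio equals
`(a0*(S2+B2) + N1) / ((S2+B2) + N2)`: the denominator never drops below
the background level `B2`, so the ratio is defined all the way to the cell
edge — and even outside the cell, where it levels at `a0`. That exterior
level is also how the constant can be *found*: the right NCF is the one
that flattens the background ratio near the edge.

The package provides:

* **Geometry**: global thresholding with hole filling, 8-connected
  component labeling, Moore boundary tracing (inner and outer contours),
  exact Euclidean distance-from-edge maps, eroded interiors and dilated
  near-edge background rings, line scans.
* **Background baselines**: distant-box mean background subtraction (MBS),
  the halfway background, and nonuniform background subtraction (intensity
  sampled just outside the edge, Gaussian-smoothed along the contour, and
  interpolated inward by inverse-distance weighting).
* **NCF estimation**: the theoretical constant `B1 - a0*B2`, the pixelwise
  `image1` vs `image2` regression intercept, and grid minimization of the
  in-cell deviation (`Dev_in`), the background-flattening deviation
  (`Dev_out`), and the distance-profile flatness metric.
* **Diagnostics**: distance profiles, the relative-range flatness metric,
  per-band edge statistics with Welch t-tests, pixel classification,
  display rendering, and a monotone-trend detector for shade artifacts.
* **Synthetic scenes**: a ground-truthed wedge-cell generator (signal
  rising linearly from zero at the edge) with per-cell proportionality,
  activity bands, shade gradients, and unclipped Gaussian noise, so every
  stage can be validated against exact algebra.
* **I/O and pipeline**: TIFF/PNG reading, float32 TIFF export,
  dark-current and flat-field shading correction, and a provenance-logging
  `run_pipeline()`; a thin CLI lives at `inst/cli/ncf-tool.R`.

## Worked example

```r
library(ncfratio)

# a ground-truthed synthetic cell: disc radius 80 px, signal ramp 20 px,
# a0 = 0.7, B1 = 120, B2 = 100  =>  true NCF = 120 - 0.7*100 = 50
scene   <- make_wedge_scene(scene_spec(seed = 42))
regions <- build_region_set(scene$truth$mask_true, depth_in = 10,
                            depth_out = 50, bg_box = bg_box(5, 5, 30, 30))
cal <- calibrate_ncf(scene$img1, scene$img2, regions)
cal
#> ncf_calibration (a0 = 0.6999 )
#>   theoretical fit_intercept        dev_in       dev_out      flatness
#>       50.3378       50.1499       50.3519       50.8315       50.1121
```

All five estimators land within about 1% of the true value 50 and agree
with one another. Comparing edge artifacts:

```r
dmap  <- distance_from_edge(regions$mask)
r_mbs <- mbs_ratio(scene$img1, scene$img2, cal$bg1$mean, cal$bg2$mean)
r_ncf <- ncf_ratio(scene$img1, scene$img2, cal$ncf[["dev_in"]])
relative_range(distance_profile(r_mbs, dmap))   # 0.0060
relative_range(distance_profile(r_ncf, dmap))   # 0.0039
```

The flatness metric `(max_d<I> - min_d<I>) / min_d<I>` of the mean ratio
vs distance-from-edge profile drops when the NCF ratio replaces MBS — the
edge artifact is suppressed. Band statistics work on the NCF ratio even
*outside* the cell (negative offsets), where the MBS ratio is just noise
divided by noise:

```r
edge_band_stats(r_ncf, regions$mask, -2:2)
#>   offset  mean      se   n      t     p p_bonferroni
#> 1     -2 0.695 0.00463 460 -0.425 0.671            1
#> 2     -1 0.698 0.00488 456 -0.317 0.751            1
#> 3      0 0.700 0.00227 452  0.614 0.539            1
#> ...
```

Here (uniform activity) no band differs from its neighbor, as expected;
with a real edge activity band the 0/+1 offsets separate from both flanks
at small p.

## Vignette

`vignettes/ncf-methods.Rmd` describes the model and its assumptions, the
estimators, the synthetic-scene design, parameter defaults, numerical
choices, and known limitations.
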