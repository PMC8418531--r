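---
title: "Noise-correction-factor ratio imaging: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-correction-factor ratio imaging: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncfratio)
```

## The problem

A ratiometric biosensor measurement divides two fluorescence channels per
pixel, typically after subtracting a scalar background from each (mean
background subtraction, MBS):

$$\mathrm{Ratio}_{MBS}(x,y) = \frac{\mathrm{image1}(x,y) - B_1}{\mathrm{image2}(x,y) - B_2}.$$

Model each channel as pure signal plus background plus zero-mean noise,
with the pure signals proportional when activity is uniform:

$$\mathrm{image1} = a_0 S_2 + B_1 + N_1, \qquad \mathrm{image2} = S_2 + B_2 + N_2.$$

Away from the edge ($S_2 \gg B_2 \gg N_2$) MBS is fine. But a cell's
thickness — hence $S_2$ — falls to zero at its edge, so the MBS
denominator approaches pure noise there, and the ratio degenerates to
$N_1/N_2$. Because a noisy denominator near zero produces arbitrarily
large positive ratios but bounded small ones, the *mean* ratio is biased
upward near the edge: an artifactual activity gradient in exactly the
region (the outer 2–3 µm) most interesting for morphodynamics. Improving
the background estimate does not help; subtracting a locally accurate
background brings the denominator even closer to zero.

## The noise correction factor

An exact rearrangement of the raw ratio gives

$$\frac{\mathrm{image1}}{\mathrm{image2}}
 = \frac{a_0 (S_2 + B_2) + (B_1 - a_0 B_2) + N_1}{(S_2 + B_2) + N_2},$$

so subtracting the single constant $\mathrm{NCF} = B_1 - a_0 B_2$ from the
numerator *only* yields

$$\mathrm{Ratio}_{NCF}(x,y) = \frac{\mathrm{image1}(x,y) - \mathrm{NCF}}{\mathrm{image2}(x,y)}
 = \frac{a_0 (S_2 + B_2) + N_1}{(S_2 + B_2) + N_2}.$$

The denominator never drops below $B_2$, so the ratio is well defined at
the edge and outside the cell, where it levels at $a_0 + N_1/B_2$ — flat
on average. With spatially varying activity,
$S_1 = (a_0 + a_1(x,y)) S_2$, the same subtraction gives the closed form

$$\mathrm{Ratio}_{NCF} = a_0 + a_1 \frac{S_2}{S_2 + B_2} + \frac{N_1}{S_2 + B_2},$$

which transitions smoothly between $a_0$ outside and $a_0 + a_1$ in the
bright interior. Activity at the very edge is therefore *attenuated* by
$S_2 / (S_2 + B_2)$, never inflated — the method trades a known,
conservative attenuation for the removal of an unbounded artifact.
`ncf_ratio()` implements the subtraction; both closed forms are verified
to $10^{-12}$ on noise-free synthetic scenes in the test suite.

## Estimating the constant

Five estimators are provided and always reported side by side
(`calibrate_ncf()`); none is declared canonical, since on real data they
differ by a few percent for reasons the data alone cannot attribute.

1. **Theoretical**: $B_1 - a_0 B_2$ with box backgrounds and the fitted
   $a_0$.
2. **Fit intercept**: ordinary least squares of `image1` on `image2` over
   in-cell pixels. Under the generative model the slope is $a_0$ and the
   intercept is itself $B_1 - a_0 B_2$. The fit is unconstrained (no
   forced intercept) and non-robust by design; strong pixelwise
   proportionality is the signature of single-chain sensors.
3. **$Dev_{in}$ minimization**: mean squared difference between the NCF
   and MBS ratios over the interior (mask eroded by `depth_in`, default
   10 px), where both methods must agree.
4. **$Dev_{out}$ minimization**: mean squared deviation of the NCF ratio
   from the zero-activity reference $a_0^{ref}$ over the near-edge
   background ring (mask dilated by `depth_out`, default 50 px, minus all
   cells): the right constant flattens the exterior at $a_0$. We take
   $a_0^{ref}$ as the mean MBS ratio over the *eroded interior*, not the
   full mask, so the reference is not contaminated by the very edge
   artifact being corrected. This estimator needs no channel
   proportionality and is the appropriate route for dual-chain sensors;
   when the proportionality fit is weak, `calibrate_ncf()` says so in an
   advisory message but never switches objectives silently. One subtlety:
   even at the optimal constant, the *mean* ratio over the ring sits
   slightly above $a_0$, by the Jensen term
   $\approx a_0 (\sigma_2 / B_2)^2$ from averaging $1/(B_2 + N_2)$ —
   about 0.5% relative at the default noise level. It is a property of
   averaging reciprocals, not of the calibration.
5. **Flatness minimization**: the candidate minimizing the relative range
   $(\max_d\langle I\rangle - \min_d\langle I\rangle)/\min_d\langle I\rangle$
   of the mean-ratio vs distance-from-edge profile.

All three objective minimizations use exhaustive grid search (default
1001 candidates spanning zero to twice the numerator box background) with
the full objective curve recorded in the result. The objectives are cheap,
one-dimensional, and possibly noisy; an auditable grid beats gradient
descent here. Ties break toward the smallest candidate, and an argmin on
the grid boundary triggers a warning. The $Dev$ objectives are quadratic
in the candidate, so their curves are evaluated from three precomputed
moments; per-bin means of the NCF ratio are linear in the candidate, which
makes the flatness curve similarly cheap. Single-point evaluators
(`dev_in()`, `dev_out()`, `flatness_objective()`) are retained and the
tests confirm the vectorized curves match pointwise evaluation.

When a scene has several cells, `calibrate_ncf_per_cell()` calibrates each
8-connected component with its own interior and ring (ring pixels exclude
every cell in the scene), since different cells generally have different
$a_0$ and hence different NCFs.

## Background baselines

The package implements the methods the NCF approach is measured against.
The *distant* background is the mean of a user-placed rectangle far from
any cell (minimum area 100 px). The *halfway* background is the midpoint
between that value and the mask threshold, representing the common
situation where out-of-focus light makes the true near-cell background
higher than a distant box suggests. *Nonuniform* background subtraction
samples the intensity at background pixels 8-adjacent to the mask
(ordered by projection onto the inner Moore traversal), smooths the
sequence with a Gaussian along the contour, and extends it inward by
inverse-distance-power interpolation

$$BG(x,y) = \frac{\sum_i \bar I(i)\, d_i(x,y)^{-m}}{\sum_i d_i(x,y)^{-m}}.$$

The smoothing kernel is truncated at $\pm 3\sigma$ and renormalized to
unit sum — the infinite-support kernel cannot be evaluated literally, and
truncation *without* renormalization would break the requirement that a
constant background stays exactly constant. Closed contours use circular
indexing; open contours fall back to whole-sample reflection. Defaults
$\sigma = 10$ contour pixels and $m = 2$ are exposed as parameters and
recorded in every result; the interpolated field is meaningful near the
edge, and no claim is made for the cell center, where it tends to the
contour average. Interpolation cost is O(domain × contour); a `domain`
mask and a contour `subsample` stride bound it for large images.

## Synthetic scenes: what they emulate and what they do not

`make_wedge_scene()` builds the idealized cell that motivates the whole
analysis: a disc (or polygon) whose denominator signal rises linearly
with Euclidean distance from the edge, $S_2 = S_2^{max}\min(1, d/w)$,
reaching its plateau at `ramp_width` $w$. Channels are assembled exactly
as the generative model dictates, and the ground truth stores every field
(`S2_field`, `a0_field`, `a1_field`, noise realizations, shade fields) so
that the emitted images reconstruct bit-exactly (`check_scene_identity()`).
Optional modifiers add a narrow edge activity band (activity scales with
$S_2$, the single-chain model) and a linear shade gradient on either
channel (an uncorrected illumination/camera bias).

Defaults, chosen once as a realistic desk-scale condition and used by the
whole validation suite: 256×256 px, disc radius 80 px, ramp 20 px,
$S_2^{max} = 2000$, $B_1 = 120$, $B_2 = 100$, $a_0 = 0.7$ (true NCF
$= 50$), Gaussian noise SD 8 in both channels. The two-cell scene uses
$a_0 = 0.63/0.72$, the canonical pair for neighboring cells with distinct
proportionality. Noise is additive, Gaussian, and *unclipped*: values may
dip below zero, because preserving the algebraic identities exactly is
worth more for validation than emulating a camera's non-negativity.
Consequently the scenes do not model photon shot noise, PSF blur,
out-of-focus light, or spectral bleedthrough; passing tests demonstrate
the correctness of the computations and the behavior of the estimators
under the stated model, not camera calibration. Scene sizes throughout
the tests (96×96 for unit tests, 256×256 for the validation suite, 20
seeds for recovery studies, 10 for the paired nonuniform comparison, 100
for the t-test null) were chosen so the whole suite runs in minutes while
keeping every assertion comfortably powered.

## Geometry conventions and numerical choices

* Coordinates are 1-based `(row, col)`, R's native convention; distances
  are in pixel units. An optional physical pixel size is metadata only.
* Foreground connectivity is 8, background 4 — the standard
  digital-topology pairing that avoids connectivity paradoxes.
* Contours are traced per component by Moore neighbor tracing, clockwise,
  from the topmost-then-leftmost pixel, with out-of-image treated as
  background; traversals are therefore always closed loops, including for
  masks touching the border.
* The distance transform is the exact Euclidean transform (distance to
  the nearest background pixel center); erosion and dilation are defined
  through it, so `depth_in`/`depth_out` are Euclidean depths, not
  structuring-element approximations.
* Distance profiles bin by the *ceiling* of the distance, making bin 1
  exactly the innermost pixel layer; bins below `min_bin_count`
  (default 50) are dropped before the flatness metric to avoid
  tiny-sample spikes.
* Edge band offsets: offset 0 is the innermost in-mask layer, positive
  offsets count inward, negative offsets outward (outside layers use the
  distance transform of the mask complement). Bands are pairwise disjoint
  by construction. Adjacent bands are compared with Welch's two-sided
  t-test — the safer default when variances differ, which they do near
  the edge — and p-values are reported both raw and
  Bonferroni-adjusted.
* Non-positive denominators yield flagged invalid pixels (`NA` in the
  ratio, counted in `params`), never clipped values, so downstream
  statistics exclude them explicitly.
* Pixel classification uses the background box: below
  $\mu_{bg} + 3\sigma_{bg}$ is background, at or above the mask threshold
  is cell, in between is near-edge background; the boundary value belongs
  to the middle class.
* Ratio maps export as true float32 TIFF via a minimal single-strip
  writer (the common R TIFF writer stores only [0,1]-scaled integer
  samples); masks and region sets export as 8-bit TIFF, and every output
  carries a sidecar with the parameters that produced it.

## Known limitations

The NCF is a single scalar per cell: spatially varying background bias
(shade) is *revealed* by the NCF ratio — the exterior stops being flat,
which `ring_gradient_trend()` quantifies — but not corrected; pixels so
affected should be excluded, or the shade corrected upstream. Activity at
the very edge is attenuated by $S_2/(S_2+B_2)$ and is therefore a lower
bound there. Channel registration, bleedthrough estimation, and
photobleaching correction are upstream of this package and assumed done.
Segmentation is global thresholding only; sophisticated segmentation can
be supplied as a precomputed mask.
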