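---
title: "Boundary-aware luminosity and contrast enhancement of fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-aware luminosity and contrast enhancement of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusbf)
```

## The problem

Color fundus photographs — images of the retina taken through the pupil —
routinely suffer from uneven illumination, low contrast and, in a
substantial fraction of acquisitions, a bright *boundary reflection*: a hazy
over-exposure artifact hugging the border of the circular eye region (the
ROI) that occludes vessels and lesions underneath it. Both manual reading
and automated diabetic-retinopathy screening degrade on such images.

`fundusbf` implements an enhancement pipeline built around a simple additive
illumination model. For each color channel \(c \in \{R, G, B\}\), the
observed value decomposes as

\[
c(x, y) = BB_c(x, y) + \mathrm{gap}_c(x, y),
\]

where \(BB_c\) is a smooth *background brightness* surface (the local
illumination, free of foreground objects) and the *gap* is the signal a
pixel carries on top of it — negative on dark vessels, positive on bright
exudates. Because the reflection and the illumination gradient live in
\(BB_c\), estimating \(BB_c\) and levelling it to a fixed baseline removes
both while preserving every pixel's gap.

## The pipeline

1. **ROI detection.** The eye region is a bright disc on a near-black
   surround; it is found by thresholding the channel-mean image (default
   threshold 20 of 255), keeping the largest 4-connected component, filling
   interior holes, and symmetrizing about the vertical center line (union
   with the left–right mirror). The threshold has no published value; 20 was
   fixed a priori because fundus surrounds are essentially black (< 10) and
   the ROI interior is far brighter, so the cut is insensitive over a wide
   range. Union (not intersection) symmetrization was chosen so a
   reflection-clipped ROI is completed, never shrunk.
2. **Ratio storage.** \(R/G\) and \(B/G\) are stored per ROI pixel from the
   *original* channels (green floored at `epsilon = 1` so ratios stay finite
   and bounded by 255). They anchor the color reconstruction at the end.
3. **Pre-filter.** Each channel is smoothed with a ROI-masked 3×3 average:
   off-ROI neighbors are excluded from both sum and count, so border pixels
   are not dragged toward the black surround. The same masked variant is
   used everywhere a 3×3 average appears; an unmasked filter would bleed
   zeros across the ROI border — the exact artifact the pipeline exists to
   remove.
4. **Background estimation.** Each channel is convolved with a large,
   centrally peaked kernel under a boundary-aware rule (below), then
   smoothed again with the masked 3×3 average, giving \(BB_c\).
5. **Luminosity adjustment.** \(A_c = \mathrm{clamp}(128 + c - BB_c,\ 0,
   255)\): every ROI pixel's background is levelled to 128 while its gap is
   preserved exactly wherever no clamping occurs. The clamp to the 8-bit
   range is our choice (the model itself is silent on out-of-range values);
   the equalization stage consumes an 8-bit histogram, and on realistic
   inputs clamping touches almost no pixels. A *full-information* green
   channel adds all three gaps, \(AGF = 128 + \sum_c (c - BB_c)\), because
   the red gap carries most foreground objects and the blue gap tracks the
   background; \(AG\) (green gap only) is retained for inspection but the
   mainline uses \(AGF\).
6. **Constrained equalization.** \(AGF\) is equalized over the whole ROI as
   a single tile (no spatial tiling/interpolation), with a histogram clip
   and a gap constraint (below), yielding \(EG\).
7. **Color recombination.** \(R_{new} = (R/G)\,EG\), \(B_{new} =
   (B/G)\,EG\), \(G_{new} = EG\), rounded half-away-from-zero and clamped.
   Because all three output channels are proportional to the stored ratios,
   the original hue of every pixel is preserved; equalized red/blue channels
   are deliberately *not* recombined directly (doing so distorts the color
   balance).

## The boundary-aware convolution

For a kernel \(b(m, n)\), the background at an ROI pixel is

\[
BB(x,y) \;=\; \frac{\sum_{(m,n)\,:\,(x-m,\,y-n)\,\in\,\mathrm{ROI}}
  b(m,n)\, i(x-m, y-n)}{\sum_{(m,n)\,:\,(x-m,\,y-n)\,\in\,\mathrm{ROI}} b(m,n)},
\]

i.e. neighborhood members outside the ROI (or outside the image — the two
are treated identically) are dropped from both the weighted sum and the
normalizer, so the effective weights always sum to 1. Two consequences are
load-bearing and tested: a constant channel is reproduced exactly on any ROI
shape, and border estimates are unbiased weighted means of in-ROI values
rather than being pulled toward the surround.

The implementation computes this as the exact ratio of two zero-padded
linear convolutions, `conv(channel·mask, b) / conv(mask, b)`, evaluated by
FFT. This is an algebraic identity, not an approximation — per-pixel
renormalization breaks separability, but it does not break linearity — and
the test suite verifies agreement with a literal drop-and-renormalize double
loop to below 1e−9 per pixel.

### Kernels

The production kernel is a **flattened binomial filter**: row \(2w\) of
Pascal's triangle (built by exact integer accumulation, then normalized by
\(4^w\)), outer-multiplied with itself, scaled so the maximum coefficient is
100, multiplied by a flattening factor \(\alpha\), and floored at 1. The
order *scale → α → floor* matters: it is the only order under which
\(\alpha = 0.01\) with the defaults turns every coefficient into 1 (a flat
box). The raw binomial kernel is too peaky — it tracks the data rather than
the illumination trend — and flattening trades peak weight for trend
capture. The production settings are a 41×41 kernel (\(w = 20\)) with
\(\alpha = 0.1\). The stated admissible range \(0.1 < \alpha \le 1\)
excludes the two most useful values actually exercised (0.1 and 0.01), so
the implementation accepts \((0, 1]\) and documents the discrepancy rather
than enforcing the printed open interval.

Two baselines run in the same framework for benchmarking: a **Gaussian**
(\(\sigma = 5\), center scaled to 10, floored at 1) and a **histogram
median** (sliding 256-bin histogram over the ROI members of the window,
lower median on even counts, no kernel weights). All three share the
41×41 footprint and the masked 3×3 post-smoothing, so the only varying
factor is the filter itself.

## The equalization constraints

The ROI histogram of \(AGF\) is concentrated near 128 by construction, so a
classic 256-bin uniform clip would almost never bind. The clip limit is
therefore defined per **occupied** bin: each bin is clipped at
`clip_factor × pixel_count / occupied_bins` (default factor 2, i.e. twice
the uniform occupancy), and the clipped excess is redistributed uniformly
over the occupied bins in a single pass — no iterative re-clipping, a
deliberately conservative scheme. The cumulative distribution of the
clipped histogram is mapped to \([0, 255]\) (floor of \(255 \cdot F\)),
then two constraints are enforced:

* **Level-count preservation** — the mapping is strictly increasing over
  occupied levels, so distinct inputs stay distinct;
* **Gap preservation** — a left-to-right pass sets
  \(out_k = \max(\mathrm{cdf}_k,\ out_{k-1} + (in_k - in_{k-1}))\): a gap
  between consecutive occupied levels may grow, never shrink, so detail is
  not collapsed.

If the gap pass pushes the top level beyond 255, the output gaps are shrunk
by the largest common factor (found by bisection) that keeps every output
gap at least its input gap; if even the input gaps overflow from the
computed anchor, the anchor is lowered instead (the input gaps themselves
always span at most 255). A single-level ROI maps to itself.

## Metrics

* **Mean luminosity** is the mean CIELAB \(L^\*\) (standard sRGB → XYZ →
  Lab, D65 white) over ROI pixels. The conversion is implemented from the
  textbook formulas; `grDevices::convertColor` derives its sRGB matrix
  differently and deviates by ~0.2 L units, so it serves only as a coarse
  cross-check in the tests.
* **Global contrast factor (GCF)**: the image's lightness (Lab \(L\)
  rescaled to \([0,1]\) — an interpretation chosen for internal consistency
  with the luminosity metric, instead of the gamma-based lightness of the
  original GCF formulation) is evaluated at three resolutions; at each, a
  pixel's local contrast is the mean absolute lightness difference against
  its in-ROI 8-neighbors, the level contrast is the mean over ROI pixels,
  and the GCF is the weighted sum with weights 0.12, 0.142, 0.154. Coarser
  levels are 2×2 superpixel averages of the lightness and of the ROI
  fraction (a superpixel is in-ROI when its fraction exceeds 0.5; odd
  trailing rows/columns are dropped). Off-ROI neighbors are excluded, so
  the artificial ROI/surround edge contributes nothing.
* **Gains**: \((\mathrm{after} - \mathrm{before}) / \mathrm{before} \times
  100\%\) for both metrics. Averages over a sample set are reported with
  the gains recomputed from the averaged before/after values; note that
  averaging per-sample gains instead gives slightly different numbers, and
  published summary tables do not always state which path they took.

## The synthetic phantom

`generate_phantom()` builds seeded, bit-reproducible test images: a disc
ROI (radius 0.48 × min dimension) on black; per-channel base levels
(120, 80, 50) — the R ≥ G ≥ B ordering of real fundus backgrounds, dim
enough that the input mean lightness lands near the upper 30s as in
screening-quality photographs; a linear illumination gradient (default
span 40 levels); a Gaussian reflection bump centered **on** the ROI border
(default amplitude 60, scale 80 px) emulating boundary reflection; dark
random-walk vessels (5 walks, width 3 px, 40 levels dark); bright exudate
discs (8 discs, radius 6 px, +70 levels, weaker in blue); and clipped
Gaussian noise (sd 1 — small, so ground-truth comparisons stay tight; no
noise model is prescribed by the method itself). Foreground coverage under
the defaults is about 3–7% of the ROI.

What the phantom does **not** emulate: optic-disc structure, vessel
branching and caliber variation, camera vignetting, JPEG artifacts,
chromatic noise, and reflections with sharp borders (which the method
itself, by design, treats as foreground and preserves). Passing tests on
phantoms therefore validate the *mechanics* of the pipeline — ROI masking,
background recovery, baseline levelling, constraint enforcement, hue
preservation — not clinical image quality.

Worth knowing when testing with phantoms: on a *foreground-free* phantom
the adjusted histogram is unrealistically narrow, and the equalization
stretch then amplifies tiny residual non-uniformities. End-to-end
properties (e.g. how completely the boundary reflection is levelled) are
therefore evaluated on phantoms with the default foreground content, the
condition the generator exists to emulate.

## Numerical choices and degenerate inputs

* Kernel coefficients stay real throughout; no integer quantization.
* The 1-D binomial accumulation is exact integer arithmetic up to
  \(w = 26\); \(w = 20\) (the production size) is well inside that.
* FFT convolution sizes are padded to 2-3-5-smooth lengths; round-off is
  orders of magnitude below the 1e−9 oracle tolerance.
* Background surfaces are clipped to the input's ROI range to keep the
  weighted-mean bound exact under floating-point round-off.
* Off-ROI pixels are zero in every intermediate; degenerate ROIs (empty
  after thresholding) raise an error naming the threshold; a single-level
  equalization histogram maps to itself; an isolated ROI pixel is its own
  3×3 neighborhood.
* Median ties on even member counts take the lower median.
* Adjustment clamps to \([0, 255]\) in signed reals (no wraparound).

## Problem sizes used by the test suite

Unit tests run on small matrices (≤ 64×64) against brute-force oracles; the
end-to-end and recovery tests run the full 500 × 700 phantom with the
production 41×41 kernel, which takes a couple of seconds per pipeline pass.
The full suite completes in under two minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 42))
res <- enhance(ph$image)
res$report
#> <quality_report: L 39.71 -> 55.98 (+41.0%), C 0.003 -> 0.008 (+133.8%)>
```

The luminosity rise (dim input levelled to the 128 baseline, then
recombined through the stored ratios) and the contrast rise (gap-preserving
stretch) are the two directional claims the acceptance suite checks on
eight seeded phantoms for all three filters.

## Known limitations

* Reflections with steep borders are treated as foreground and preserved;
  large smooth-edged exudates at the ROI border can conversely be treated
  as reflection and suppressed. Both behaviors are inherent to the additive
  smooth-background model.
* Absolute GCF values depend strongly on image content; phantom GCFs are an
  order of magnitude below those of clinical images. Comparisons should be
  within-image (before vs after), which is how the gains are defined.
* The ROI detector assumes a single connected, roughly mirror-symmetric eye
  region; montage or stereo images are out of scope.
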