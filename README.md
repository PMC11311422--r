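# fundusbf

Luminosity and contrast enhancement of color retina (fundus) photographs
affected by uneven illumination and **boundary reflection** — the bright,
hazy over-exposure artifact along the border of the eye region that
occludes vessels and lesions. The package is aimed at retinal-imaging
researchers and screening-pipeline builders who need a reproducible,
parameter-transparent enhancement step in R.

## Method

The pipeline models each channel additively, `c(x,y) = BB_c(x,y) + gap`,
where `BB_c` is a smooth background-brightness surface and the gap is the
pixel's foreground signal. Within the eye region (ROI, found by
thresholding, component selection, hole filling and mirror
symmetrization):

1. store the per-pixel ratios `R/G` and `B/G`;
2. smooth each channel with a ROI-masked 3×3 average;
3. estimate `BB_c` by a **boundary-aware convolution** with a flattened
   41×41 binomial kernel (coefficients scaled to max 100, multiplied by
   α = 0.1, floored at 1): neighborhood members outside the ROI are dropped
   from both the weighted sum and the normalizer,

   `BB(x,y) = Σ b(m,n) i(x−m, y−n) / Σ b(m,n)`, sums over in-ROI members;

4. level every pixel's background to 128 while preserving its gap,
   `A_c = 128 + c − BB_c`, and build the full-information green channel
   `AGF = 128 + Σ_c (c − BB_c)`;
5. equalize `AGF` over the whole ROI with a constrained CLAHE (clip at 2×
   the uniform occupancy of occupied bins; distinct levels stay distinct;
   consecutive-level gaps may grow but never shrink), giving `EG`;
6. recombine: `Rnew = (R/G)·EG`, `Bnew = (B/G)·EG`, `Gnew = EG` — the green
   anchor plus stored ratios preserves the original hue.

Evaluation metrics: mean CIELAB `L*` over the ROI and a three-resolution
global contrast factor (mean absolute 8-neighbor lightness differences,
weighted 0.12/0.142/0.154), with relative gains
`(after − before)/before × 100%`. Gaussian (σ = 5, scaled to 10) and
histogram-median 41×41 baselines run in the same framework for
benchmarking. A seeded synthetic fundus phantom generator (disc ROI,
illumination gradient, border reflection bump, vessels, exudates, ground
truth) makes every stage testable without clinical data.

## Worked example

```r
library(fundusbf)

ph  <- generate_phantom(phantom_spec(seed = 42))  # 500 x 700 synthetic fundus
ph
#> <fundus_phantom 500 x 700, ROI 180960 px, foreground 3.0% of ROI, seed 42>

res <- enhance(ph$image)                          # production 41x41 binomial
res$report
#> <quality_report: L 39.71 -> 55.98 (+41.0%), C 0.003 -> 0.008 (+133.8%)>
```

The report reads: the ROI's mean CIELAB lightness rose from 39.7 (a dim,
unevenly lit input) to 56.0 after the background was levelled to the 128
baseline and recombined through the stored color ratios — a +41%
luminosity gain — while the global contrast factor more than doubled
(+134%), because the gap-preserving equalization stretches foreground
detail instead of flattening it. `benchmark()` repeats this per filter
family and appends an average row; `write_benchmark()` emits the table as
CSV or JSON.

A thin command-line front end ships in `inst/cli/fundusbf` with
`enhance`, `benchmark`, `phantom` and `metrics` subcommands:

```sh
Rscript inst/cli/fundusbf enhance -i retina.png -o enhanced.png --filter binomial --size 41 --alpha 0.1
```

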