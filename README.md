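# swaseg

Multilevel weighted-aggregation segmentation for bright-field microscopy
images and space-time image stacks.

Bright-field (and phase-contrast) live-cell imaging avoids the phototoxicity
of fluorescence, but its images are hard to segment: cells show internal
texture, low-contrast boundaries and broken halos, and they touch, divide
and move. swaseg segments such images with a variant of Segmentation by
Weighted Aggregation (SWA): the pixel affinity graph, with edge weights
`exp(-α|Iᵢ - Iⱼ|)` between axis-aligned neighbours, is recursively
coarsened using the first pass of classical algebraic-multigrid
(Ruge–Stüben) C/F splitting; coarse couplings are Galerkin triple products
`PᵀAP` rescaled by block mean intensity (factor `exp(-α̃|ΔI|)`) and by
multilevel intensity-variance texture features (factor `exp(-β‖Δf‖₁)`).
A block is frozen as a final segment when its **scale-invariant saliency**

    Γᵢ = (Lᵢᵢ / Gᵢᵢ) / (Wᵢᵢ / Vᵢᵢ)
       = (average similarity along the boundary) /
         (average similarity in the interior)

falls below a threshold γ — the weighted boundary length `Lᵢᵢ` and weighted
area `Wᵢᵢ` are each normalized by their unweighted counterparts (`Gᵢᵢ`,
`Vᵢᵢ`, Galerkin-coarsened from the Boolean pixel adjacency), which removes
the size and shape dependence of the classical measure
`Γᵢ = Lᵢᵢ/(½Wᵢᵢ)` (also available). A bottom-up pass interpolates the
segments' fractional memberships back to pixels, sharpening them with
threshold `d₁` at each level, and every pixel takes the segment it belongs
to most. Applied to a stack of frames (6-connectivity, time as a third
axis), the segments are space-time "object tunnels" that track moving and
dividing cells.

Intended users: anyone segmenting grayscale microscopy where texture, not
just brightness, distinguishes objects from background — and anyone who
wants a deterministic, near-linear-time, tunable graph-based segmenter with
per-level diagnostics.

## Worked example: texture separates what intensity cannot

The defining experiment: a region that differs from the background only in
*variance*, not in mean intensity (a full-contrast checkerboard on grey).

```r
library(swaseg)
fx <- make_two_texture(60, 20)       # 20x20 textured region, exact equal means
params <- swa_params(alpha = 10, alpha_tilde = 10, beta = 10,
                     theta = 0.1, gamma = 0.1, sigma = 5, rho = 1)
s <- swa_segment(fx$image, params)
print(s)
#> <swa_segmentation> 60x60 image, 2 segment(s), 9 level(s)
#>   id level    saliency mean_intensity n_pixels
#> 1  1     6 0.001420225      0.5122032      322
#> 2  2     9 0.000000000      0.5030067     3278
label_accuracy(s$labels, fx$mask)
#> [1] 0.9783333
```

The textured region is detected as salient on level 6 (saliency 0.0014,
far below γ = 0.1) and the background follows once it has aggregated to a
single decoupled block; 97.8% of pixels match the ground-truth mask. Rerun
with `use_variance = FALSE` and the same image collapses to **one**
segment — mean intensities are equal everywhere, so intensity-based
couplings cannot separate the regions.

Space-time tracking works the same way on a 3D stack:

```r
fx <- make_moving_blob(n = 60, nt = 5)           # blob drifting across 5 frames
s  <- swa_segment(fx$image, swa_params(preset = "space_time"))
tunnel_report(s)                                 # per-frame counts, centroids, boxes
```

## Command line

```sh
exec/swaseg synth two_texture --size 60 --block 20 --out tex.tif --truth gt.tif
exec/swaseg segment tex.tif --alpha 10 --alpha-tilde 10 --beta 10 --sigma 5 \
    --out labels.tif --diagnostics diag.json
exec/swaseg segment3d stack.tif --out tunnels.tif --tracks tracks.csv
```

Labels are written as 16-bit TIFF (8-bit PNG for 2D), diagnostics as JSON,
track tables as CSV; `--config params.yaml` supplies defaults that explicit
flags override.

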