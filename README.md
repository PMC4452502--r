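# spfseg

Region-based active contour segmentation of bright regions of interest with
a masked signed pressure force (SPF), for single-channel medical-style
images — the setting where a radiologist wants the bright, dense structures
(masses, tumors, dense tissue) in a mammogram-like 8-bit image prompted
automatically, together with a topographic summary of how salient each
region is.

## The method

A level-set field φ represents the contour implicitly (zero level = the
contour, φ > 0 = interior). The contour starts near the image border and
evolves strictly inwards through nested subregions M⁰ ⊇ M¹ ⊇ …, driven by a
signed pressure force built from a two-phase global fitted image:

- masked region means (the Chan–Vese minimizers restricted to the current
  subregion M):

      c₁ = ∫ I·H_ε(φ)·M / ∫ H_ε(φ)·M,   c₂ = ∫ I·(1−H_ε(φ))·M / ∫ (1−H_ε(φ))·M

- global fitted image  I_GFI = c₁·H_ε(φ) + c₂·(1−H_ε(φ))

- signed pressure force  spf = (I − I_GFI)·M / max|I − I_GFI|  (0 where
  I = 0), with values in [−1, 1]

- gradient flow  φ ← φ + Δt·[λ·div(spf·∇φ/|∇φ|) + v·spf·δ_ε(φ)], followed
  by Gaussian kernel smoothing φ ← G_σ∗φ in place of any reinitialization.

The run stops when two consecutive subregion masks become similar
(retaining at least a stopping value sv ∈ (98, 100) percent of the area for
a few consecutive iterations), when the subregion empties, or at an
iteration cap. Snapshots of φ recorded along the way give an isocontour
map; an inclusion tree over those contours classifies them as branching /
base / terminal and scores saliency by minimum nesting depth. Defaults
(λ = 1, v = 15, Δt = 1, ε = 1.5, K = 5, σ = 1, ρ = 2) are the operating
point for 8-bit images; see the methods vignette
(`vignettes/spf-active-contours.Rmd`) for the reasoning behind every knob.

## A worked example

```r
library(spfseg)

# synthetic phantom: bright disk (r = 25, intensity 220) on background 30,
# Gaussian noise sigma = 10, fixed seed; ground truth is the exact disk
ph <- make_phantom(shape = c(128, 128), background = 30,
                   blobs = list(list(center = c(64, 64), radius = 25,
                                     intensity = 220)),
                   noise_sigma = 10, seed = 1)
fit <- spf_segment(ph$image)
fit
#> Region-based active contour segmentation (masked SPF)
#>   image: 128 x 128, intensities [0, 250.934]
#>   iterations: 14 (termination: stopping_rule)
#>   stopping value: 98.5610 (mode: converge)
#>   final region: 2018 px (15.00% of initial region)
#>   final region means: c1 = 211.517, c2 = 197.314

dice(fit$final_mask, ph$truth[[1]])
#> [1] 0.9805937
```

The fit prints the iteration count, how the run terminated, and the final
region's size and mean intensities (c1/c2 nearly equal means the final
subregion is homogeneous — the contour has locked onto the disk). The Dice
coefficient scores overlap with the known truth; 0.98 here means the
recovered region and the true disk agree almost pixel for pixel.
`seg_metrics(fit$final_mask, ph$truth[[1]])` gives precision 0.962, recall
1.0, true negative rate 0.995, accuracy 0.995, F1 0.981 for the same run.

`plot(fit, truth = ph$truth[[1]])` overlays initial (green), final (blue)
and truth (red) contours; `contour_map(fit)` and `build_inclusion_tree()`
expose the topography; `run_segmentation()` drives a whole run from an
image file to artifacts on disk (mask, overlay, contour-map JSON, metrics
CSV, reproducible run log). A thin command-line interface with verbs
`segment`, `phantom`, `evaluate` and `contour-tree` lives in
`inst/cli/spfseg.R`.

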