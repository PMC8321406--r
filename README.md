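# pvdmorph

Automated tracing and morphometry of the *C. elegans* PVD neuron's
dendritic arbor from 2-D fluorescence projections.

The PVD is a bilateral nociceptive neuron whose dendrites form repeating
candelabrum ("menorah") units wrapping the worm's body. `pvdmorph` turns a
maximum-intensity-projection image of a PVD into quantitative
morphology:

1. **Pixel classification** — neuron vs. non-neuron probability per pixel,
   either by a deterministic classical chain (background opening,
   hysteresis thresholding, granule-shape filtering) or by a small
   trainable patch segmenter.
2. **Skeletonization** — a one-pixel-wide medial axis with tips (degree-1
   pixels) and vertices (degree ≥ 3), spur pruning, and pixel-chain edges.
3. **Rectangle-element tracing** — a simplified region-based active
   contour: the neuron is fitted with chains of rectangular masks whose
   score is the background-normalized mean intensity
   `clamp((Ī − b)/(I_ref − b), 0, 1)`; orientation is refitted per element
   within ±60° of its predecessor, the apparent width comes from the decay
   onset (second derivative) of the score-vs-width profile, the element
   length is twice its width, and chains grow inward from both segment
   endpoints guided by the skeleton.
4. **Junction geometry** — each branch point is fitted as a circular mask
   on the binary map, with process directions from the orientation peaks
   of a radially aligned rectangle; a three-way junction is summarized by
   its sorted angle triplet {α₁ ≤ α₂ ≤ α₃}, α₁+α₂+α₃ = 360°.
5. **Worm-intrinsic coordinates** — the body midline and radius profile
   r(s) are recovered from the trace by morphological closing and
   transverse recentring; every element gets arclength *s*, signed
   transverse distance *d*, azimuth φ = asin(d/r(s)), and midline
   orientation θ; junction angles are unprojected from the image plane to
   the body surface via (dS, dD) → (dS, dD/cos φ).
6. **Morphological classes** — elements pooled over a cohort are
   clustered in (θ, |φ|) space by thresholding a kernel density until
   exactly four clusters appear; the classes correspond to the
   conventional primary–quaternary branch orders. Per class: total
   length, junction/tip densities per 100 µm, curvature; cohorts are
   compared metric-by-metric with Mann–Whitney U tests.
7. **Junction Monte Carlo** — intrinsic junction configurations
   {α₁, α₂, α₃, σ_α} are fitted to observed angle-triplet distributions by
   simulating ray-direction noise on a grid over (α₁, α₂, σ_α) and
   minimizing a nondimensional binned-density residual.

A synthetic phantom generator (`worm_phantom()`) produces worm images with
exact ground truth — skeleton polylines, class labels, junction angle
triplets, body frame — so every stage is tested without microscopy data.

## Worked example

```r
library(pvdmorph)

## synthetic worm with exact ground truth: 120 um body, menorah spacing
## 30 um, 0.5 um/px, noiseless render
ph <- worm_phantom(length_um = 120, max_radius_um = 12, bend_amplitude = 6,
                   menorah_spacing_um = 30, pixel_size_um = 0.5,
                   psf_sigma_px = 1, noise = "none", n_granules = 0,
                   seed = 5)

cm <- classify_image(ph$image)        # pixel classification (fallback path)
sk <- skeletonize(cm)                 # topological skeleton
tr <- trace_neuron(ph$image, cm, sk, pixel_size_um = 0.5)
tr
#> <pvd_trace> 169 elements in 81 segments; 40 junctions (32 three-way), 42 tips

tr <- element_coords(tr, pixel_size_um = 0.5)   # worm frame from the trace
tr <- junction_coords(tr, pixel_size_um = 0.5)  # projection-corrected angles
round(tr$frame$length_um, 1)
#> [1] 113.3

## junction-configuration Monte Carlo: simulate triplets from the
## symmetric configuration and fit the grid
obs <- simulate_junctions(junction_config(c(120, 120, 120), 19),
                          n = 2620, seed = 1)
round(colMeans(obs), 1)               # sorted-angle means under deformation
#> [1]  92.1 120.0 148.0
fit <- fit_junction_mc(obs, n_sim = 1e4, seed = 2)
fit
#> <junction_mc_fit> best configuration: {114, 114, 132}, sigma = 18 deg (residual 0.00851, n_obs = 2620)
```

The trace object holds per-element tibbles (position, orientation, width,
score), segments, junction angle triplets, and tips; `element_coords()`
adds the (s, d, φ, θ) tibble. The sorted-angle means 92°/120°/148°
illustrate why mean angles overstate junction asymmetry: even a perfectly
symmetric 120°-120°-120° junction, deformed by 19° of angular noise,
yields spread order statistics — which is what the Monte Carlo fit
inverts. The fitted configuration lands in the shallow residual valley
around the symmetric shape; the methods vignette
(`vignettes/pvd-morphometry.Rmd`) discusses the identifiability of this
fit together with every model and default in the package.

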