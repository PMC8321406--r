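---
title: "Tracing and morphometry of PVD dendritic arbors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing and morphometry of PVD dendritic arbors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The PVD neuron of *C. elegans* grows a stereotyped, highly branched
dendritic arbor of repeating candelabrum ("menorah") units that wrap the
worm's body. Quantifying its architecture from fluorescence microscopy
means solving four coupled problems: isolating the neuron signal from a
noisy projection image, converting the signal into a geometric
representation, expressing that representation in coordinates intrinsic to
the worm's body rather than the camera, and reducing the geometry to
comparable morphometric numbers. `pvdmorph` implements this pipeline with
a synthetic phantom generator alongside it, so that every stage can be
validated against exact ground truth.

# Pipeline and models

## Pixel classification

Two interchangeable paths produce a per-pixel neuron probability map. The
default is a deterministic classical chain: grayscale morphological opening
(disc radius 7 px) estimates and removes the smooth background, a mild blur
suppresses single-pixel noise, hysteresis thresholding keeps weak ridge
pixels only when their connected component also contains strong pixels,
and compact bright blobs (area < 150 px with circularity
$4\pi A/P^2 > 0.8$) are removed as autofluorescent gut granules. The
thresholds are relative to the enhanced-image maximum, with an absolute
floor that declares a featureless image empty.

The second path is a compact trainable encoder–decoder that maps a 64×64
grayscale patch to a 64×64 probability map: zero-centred input, a 5×5
convolution bank (8 filters) with ReLU, 2×2 max-pooling, a 3×3
convolution, nearest-neighbour upsampling, and a 1×1 projection to a
per-pixel logit, trained by stochastic gradient descent on pixel
cross-entropy. It is intended for small-scale training on phantom patches
(tens of patches, a few epochs); at that scale it reliably beats the
classical fallback on phantoms (IoU ≈ 0.74 vs ≈ 0.65 in our runs).
Training is deterministic given the seed. Overlapping patch predictions
are averaged when classifying full images.

## Skeletonization

The binary map is thinned to a one-pixel-wide medial axis (Guo–Hall
thinning with a connectivity-preserving clean-up of residual 2×2 blocks).
Tips are skeleton pixels with one neighbour, vertices pixels with three or
more; adjacent vertex pixels are clustered into single nodes, terminal
spurs shorter than 5 px are pruned, and vertex pairs connected by chains
shorter than 4 px are contracted (thinning can split one anatomical
junction into two nearby vertices). Skeleton arclength is measured by
chain code over the pixel set; on noiseless phantoms it is within ~4% of
the generating arbor length.

## Rectangle-element tracing

The neuron is represented as chains of rectangular masks — a simplified
region-based active contour guided by the skeleton. The fit score of a
rectangle is its background-normalized mean intensity,
$\mathrm{clamp}\!\left(\frac{\bar I - b}{I_{\mathrm{ref}} - b}, 0, 1\right)$,
where $b$ is a local background estimate and $I_{\mathrm{ref}}$ a signal
reference. Choices that the problem leaves open, and how we resolved them:

* **Signal reference.** The 90th-percentile intensity along the skeleton
  edge being traced; robust to the ±30% intensity variation along
  processes.
* **Background.** Two flanking rectangles offset laterally by $1.5w$. In
  dense arbor regions one flank frequently overlaps a neighbouring
  process, so normalization and acceptance use the statistics of the
  *dimmer* flank; the pooled statistics are also reported.
* **Orientation.** A fan search of ±60° in 2° steps around the previous
  element's orientation, ties broken towards the smaller deviation (the
  internal-energy smoothness prior). Orientations that leave the skeleton
  guide by more than 50° are snapped back to it.
* **Width.** The score is scanned over widths at fixed length; the
  apparent width is the first width at which the discrete second
  derivative of the profile reaches 60% of its maximum — the earliest
  strong decay onset. (In dense regions the profile kinks a second time
  when the mask reaches a neighbouring process; taking the global argmax
  would chase that.) Widths are floored at 2 px, capped at 16 px, and
  constrained to change at most 25% between neighbouring elements.
* **Stepping and termination.** Elements are centred on the skeleton path
  (so each contains pixels of its own skeleton edge) and advance by half
  an element length (50% overlap). An element is accepted when its score
  is at least 0.15 *and* its mean exceeds the dim-flank mean by two flank
  SDs; on acceptance the local background is subtracted from its
  footprint. Chains grow inward from both endpoints and merge where they
  meet; a chain that cannot proceed flags the segment as partial.
* **Junction margins.** Chains start one fitted junction radius away from
  vertex endpoints. Without this margin the flanking background samples
  of junction-adjacent elements overlap the other arms and the acceptance
  rule misfires.

## Junction geometry

Junction centres and radii are found by fitting a circular mask to the
binary map: the largest disc whose neuron-pixel fraction stays above 0.88,
tie-broken towards the skeleton vertex guess, searched within ±5 px and
radii 2–15 px. (A penalized-area objective degenerates here: any minimal
disc inside a branch attains fraction 1, leaving the centre
underdetermined; the inscribed-disc formulation is well-posed.) Directions
of the emanating processes are the peaks of the mean intensity of a
radially aligned rectangle scanned over orientation in 2° steps, after
5-sample circular smoothing, with a prominence threshold of 15% of the
range and a connectivity filter: the inner and outer halves of a
candidate ray must be neuron in the binary map (a bright neighbouring
process crossing the scan annulus produces a peak but is not an arm). The
junction angles are the circular differences of the sorted directions, so
a triplet sums to 360° *exactly* by construction. Junctions with fewer
than three detected directions are flagged degenerate, those with more
than four as artifacts; both are excluded from angle statistics. On dense
phantoms about three quarters of well-isolated junctions yield exactly
three directions; direction detection is the noisiest stage of the
pipeline, and 95% of fitted centres fall within 3 px of ground truth.

## Worm-intrinsic coordinates

The worm frame is recovered from the trace itself. The element footprint
is closed into a single body blob with a disc whose radius is chosen
automatically from the largest internal gap of the footprint (measured
inside a running column-envelope of the body). The raster is padded before
closing — erosion at image borders otherwise retains the clipped dilation
band — and the closing's overshoot at the tapered ends is clipped with a
tight column envelope. The blob's medial axis, taken between its two most
distant endpoints, seeds the midline; a sliding-window transverse
recentring pass (four iterations with endpoint-pinned smoothing) settles
it onto the mid-crossing line, and the local radius $r(s)$ is half the
transverse crossing distance. The last two closing radii at each end are
replaced by straight extrapolation from the stable interior (the closing
cap biases the medial axis there).

Each element is then assigned the arclength $s$ of its nearest midline
point, its signed transverse distance $d$ (positive dorsal), the azimuth
$\phi = \arcsin(d/r(s))$, and the midline orientation $\theta$ — the
element orientation relative to the local tangent, folded to $[0°, 90°]$
(a signed variant is retained). $|d|$ exceeding $r$ by up to 10% is
clamped to $\phi = \pm 90°$; larger excursions are flagged and excluded.
Junction angles are corrected for the projection of the curved body
surface to the image plane: each incident ray's components along the local
tangent and dorsal normal $(dS, dD)$ map to $(dS, dD/\cos\phi)$ — the
local-cylinder unprojection implied by $d = r\sin\phi$ — and the angles
are recomputed. The correction is the identity at $\phi = 0$ and is
declared unstable (junction excluded) beyond $|\phi| = 80°$. The radial
taper $dr/ds$ is neglected in the unprojection; the body radius varies
slowly away from the tips, which are excluded anyway.

**Accuracy and limits.** On phantoms the recovered midline is within
~1–1.5 px RMS of ground truth and $r(s)$ within ~5% wherever dendrites
cover both body sides. Near the margins of the arbor nothing marks the
body surface, so $r$ degrades there: over the central 80% of arclength the
median error stays below 10% but individual samples near the window edges
can reach ~20%. Azimuths inherit this: with the estimated frame, class-1
elements have median $|\phi| \lesssim 2°$ but a tail out to ~10° near the
arbor ends. These are observability limits of trace-derived outlines, not
free parameters.

## Morphological classes and morphometry

Elements pooled across a cohort are density-estimated over
$(\theta, |\phi|)$ (two-dimensional Gaussian kernel, 12° bandwidth, 91×91
grid; dorsal and ventral are folded together). Scanning the density level
from high to low, the first threshold whose super-level set has exactly
four connected components defines the clusters; they are labeled by
proximity of their modes to the four archetypes — class 1 (longitudinal,
$\phi \approx 0$), class 2 (transverse, low-mid $\phi$), class 3
(longitudinal, $\phi \approx 35°$), class 4 (transverse, high $\phi$) —
and every point of the plane is assigned to the nearest cluster, so
classification is total. Segments take the length-weighted majority class
of their elements (ties to the lower class id); junctions take the
majority class of their incident segments, tips the class of their
segment. If no threshold yields four components the model construction
fails loudly with the achievable component counts.

Per class, the summary reports total length (µm and % of total), junction
and tip counts and densities per 100 µm of class dendrite (the density is
the reciprocal of the mean inter-junction arclength), tips per 100 µm of
midline, the midline length-density profile in 10 µm bins, and mean
unsigned curvature. Curvature is estimated per element as the turn angle
between successive element orientations over the inter-centre arclength
(radians/µm, one-sided at chain ends); on a sampled circle of radius
10 µm it recovers 0.100/µm to within 1%. The count-per-length and
reciprocal-mean-gap readings of junction density coincide only on branches
whose junctions tile most of their span (the primary); on short tertiary
spans the junction-free terminal stubs make count/length systematically
smaller, which is a discreteness property of the branch geometry, not an
implementation artifact. Per-class lengths are exact given labels; with
model classes, residual tertiary/quaternary confusion (mostly hooked
quaternary terminals) can shift up to about a fifth of those two classes'
mass between them while overall segment agreement stays above 90%. Group comparisons use the
two-sided Mann–Whitney U test per metric with star annotations at
p < 0.05, 0.005, and 0.0005; for n ≤ 10 per group the p-values agree with
full enumeration of the rank-sum distribution.

## Junction-configuration Monte Carlo

An intrinsic three-way configuration is a sorted triplet
$\{\alpha_1 \le \alpha_2 \le \alpha_3\}$ summing to 360° plus an angular
noise scale $\sigma_\alpha$. Deformation is modelled by perturbing the
three ray *directions* (at circular positions $0, \alpha_1,
\alpha_1{+}\alpha_2$) with independent zero-mean Gaussian angles of SD
$\sigma_\alpha$; the inter-ray angles then sum to 360° automatically.
This direction-noise model spreads the sorted angles more than naive
per-angle noise; at the symmetric configuration with
$\sigma_\alpha = 19°$ it yields sorted-angle means of about 92°, 120° and
148° — the signature asymmetry of order statistics.

The grid fit simulates every candidate $(\alpha_1, \alpha_2,
\sigma_\alpha)$ (with $\alpha_3$ implied) and scores it by the sum over
the three sorted-angle marginals of the integrated squared difference
between simulated and observed 2°-binned densities, normalized by the
observed densities' total squared mass (nondimensional). One
standard-normal draw is shared across all grid cells and scaled per
$\sigma$; this removes between-cell Monte Carlo jitter from the residual
surface without changing the model.

**Identifiability.** The fit recovers random interior configurations
within one grid step from 10⁴ observed triplets. The symmetric
configuration is different: the sorted-angle marginals change very little
along a valley that trades asymmetry against noise (the expected
normalized residual between $\{120,120,120,\sigma{=}19\}$ and
$\{108,126,126,\sigma{=}18\}$ is ~3×10⁻⁵, far below the sampling noise of
a few thousand observed triplets), and because the ordering constraint
makes the symmetric point a corner of the parameter domain, the noisy
argmin can only move off it towards smaller $\alpha_1$. At realistic
sample sizes the recovered smallest angle therefore scatters roughly
5–15% below 120°. No statistic of the observed triplets can repair this —
the distributions along the valley are nearly identical — so the honest
statement is the paper-level one: the data are consistent with
configurations close to the symmetric one.

# The phantom generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline is validated.

* **Body.** A midline integrated from a sinusoidal heading profile
  (arclength-exact), radius profile
  $r(s) = r_{\max}(4u(1-u))^{0.35}$, $u = s/L$, floored at 2% of
  $r_{\max}$ — smooth, tapering to near zero at both ends. Defaults:
  length 600 µm, maximal radius 25 µm, bend amplitude 8°.
* **Arbor.** A primary process along azimuth 0 spanning 2–98% of the
  body; menorahs alternating dorsal/ventral every half-spacing (default
  spacing 30 µm per side), each with a transverse secondary to azimuth
  35°, a tertiary running as a constant-offset (offset-curve) polyline —
  whose tangents are exactly parallel to the midline, making every
  junction an exact T — spanning ±0.43 spacing, and four transverse
  quaternaries reaching azimuth 80°, the outer two ending in tight
  quarter-arc hooks (radius 0.06 spacing) that give quaternary terminals
  their characteristic high curvature. Same-side tertiary spans leave
  ~4 µm gaps so neighbouring menorahs never fuse under the PSF. Element
  sampling for ground-truth traces keeps 1.5 µm clear of junction centres
  (as traced elements do) and staggers its phase per segment to avoid
  quantized azimuth echoes in the cohort density.
* **Rendering.** Processes are drawn as ridges with per-process apparent
  width drawn from 2–5 px (true diameters are sub-resolution; only the
  apparent width matters), ±30% smooth intensity variation along each
  process, Gaussian PSF blur, exactly `n_granules` bright discs placed
  off the neuron with clearance margins, and Poisson/Gaussian noise.
  Rendering is bit-exact under a fixed seed. The default pixel size
  (0.16 µm/px, a 40× objective scale) is a configurable guess; tests run
  at 0.5 µm/px so a 120–150 µm worm fits in a ~300×90 px raster.

What the phantom does *not* emulate: z-stack projection artifacts of a
truly three-dimensional arbor (all geometry is generated directly in the
2-D projection, matching how the analysis operates), cuticle
autofluorescence textures, multiple worms per image, and coiled or
self-overlapping postures. Passing phantom tests therefore demonstrates
correctness of the geometry, classification and statistics machinery
under realistic density, blur and noise — not robustness to every
real-microscopy artifact.

# Problem sizes used in the tests

The shipped test suite validates on worms of 100–150 µm at 0.5 µm/px
(about 25–50 junctions and 300–800 µm of dendrite per worm), cohorts of
three worms for classification, 10⁴–10⁵ simulated junctions for the Monte
Carlo checks, and a coarsened grid (4° angle and 3° sigma steps) for the
five-configuration recovery property; the full 2°/1° grid is exercised by
the acceptance script. These sizes were chosen so the full suite completes
in a few minutes while every stage still operates in its intended regime.

# Known limitations

* Junction direction detection in dense regions is the noisiest stage;
  non-three-way fits are flagged and excluded from angle statistics
  rather than repaired.
* The body frame is only as good as arbor coverage; radius estimates
  degrade near the arbor margins (see above).
* Isolated skeleton cycles (a ring with no tip or vertex) are not traced.
* The trainable segmenter is a toy: it demonstrates the training loop and
  the patch-assembly contract, not state-of-the-art segmentation.
* SWC export breaks cycles (the format is a tree); the break point is
  where the emitting walk re-encounters a node, with a warning.
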