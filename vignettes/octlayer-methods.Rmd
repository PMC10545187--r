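---
title: "Methods: URCL thickness quantification in OCT volumes and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: URCL thickness quantification in OCT volumes and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Durable layered tissue models — *ex vivo* retina embedded in transparent
gels or resins — are characterized in OCT by the thickness of their upper
retinal cell layers (URCL: nerve fiber + ganglion cell + inner plexiform
layers). The measurement reduces to reconstructing two interfaces on each
B-scan, the embedding medium–retina interface (*i1*) and the IPL–INL
interface (*i2*), and summarizing the distance between them. Two unit
systems interact: OCT samples depth in optical path length (OPL = geometric
distance × refractive index), while the reported thickness is geometric.
`octlayer` keeps volumes on their native OPL axial grid and converts only
inside the thickness computation.

## Pipeline and model

1. **Conditioning.** The volume is filtered with a separable 3D Gaussian
   (`sigma_xz = 1.0` voxel on the depth and fast lateral axes, `sigma_y =
   2.0` across B-scans), contrast is stretched linearly between two
   intensity quantiles, and consecutive B-scans can be averaged. Order is
   fixed: filter → stretch → average.
2. **Interface reconstruction.** Sampling points per interface and B-scan —
   from a CSV (the reproducible stand-in for interactive clicking) or
   auto-seeded from axial gradients — are interpolated by a natural cubic
   spline. The curve passes through every point exactly and is never
   extrapolated beyond its knot span.
3. **Thickness.** *i1* is rasterized at every lateral voxel column of the
   common domain (*m* points), *i2* four times denser. After converting z
   from OPL to geometric µm (division by `n_medium`), the thickness at each
   *i1* point is the minimum Euclidean distance to the *i2* raster;
   per-B-scan mean `t_B` and the per-sample `t_URCL` (mean over the B-scan
   set, ± SD across B-scans) follow.
4. **Quality.** The background-noise metric is the population SD of the
   gray levels in a sample-free ROI above the specimen on the preprocessed
   B-scan; it ranks embedding media by scattering. An optional curvature
   energy score (integrated squared second difference of *i1*, normalized
   by span) flags folded planes; it is reported, never auto-applied,
   because the discard of distorted B-scans is an operator decision.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `sigma_xz`, `sigma_y` | 1.0, 2.0 | voxels | sigma interpreted in image voxels, as the filter is specified against image axes, not physical distances |
| `stretch_low/high` | 0.001 / 0.999 | quantile | robust to hot pixels; exact min/max available via `stretch_mode = "minmax"` |
| `n_average` | 1 | B-scans | averaging is enabled by fine (4 µm) B-scan spacing but its window is a free choice; off by default |
| `dy_um` | 50 | µm | separation of evaluated B-scans; index step is `round(dy / y_spacing)` (round-half-to-even, min 1) |
| `n_medium` | 1.33 | — | gels (agarose, phytagel); 1.49 for epoxy resins |
| `i2` raster density | 4× | — | bounds the polyline discretization error of the minimum-distance search well below the axial voxel size |

## The single most consequential convention

Minimum Euclidean distances are meaningless in anisotropic pixel units, and
the original description leaves the coordinate frame implicit. `octlayer`
computes every distance in **geometric physical micrometres**: z is divided
by `n_medium` *before* the search, x is already metric. Rasters carry a
frame tag and mixing frames is an error. Two invariants pin the convention
down in tests: rigid translations leave t(x) unchanged, and scaling all OPL
z by a constant c while scaling n by c leaves the geometric thickness
unchanged.

Other deliberate choices, made where the procedure was genuinely open:

- **Spline family**: natural cubic *interpolating* spline — the sampling
  points are trusted, not smoothed. Collinear points reproduce a line
  exactly; a sine of 400 µm period sampled every 25 µm is reconstructed to
  better than 1 % of its amplitude.
- **Tie-break**: among exactly equidistant *i2* points the smaller x wins,
  making profiles deterministic and regression-testable. The windowed
  search that exploits the x-sorted raster (pruning on |Δx| > current best)
  is checked against exhaustive pairwise minimization to 10⁻⁹ µm on 100
  random spline pairs.
- **Endpoint minima**: *i1* points whose nearest *i2* point is a raster
  endpoint are kept but flagged — boundary minima may be non-perpendicular
  and users may wish to trim them.
- **SD conventions**: `sd_urcl` is the SD across per-B-scan means (the bar
  plot error-bar convention), not a pooled pixelwise SD; the noise metric
  uses the population (1/N) SD; per-B-scan `sd_b` uses the sample SD. At
  realistic counts the distinction is negligible, but determinism requires
  fixing one.
- **Gradient seeding**: the auto-seeder takes the first strong positive
  axial gradient as *i1* and the next one beyond a 30 OPL µm dead zone as
  *i2*, placing the interface midway between the bracketing voxel centres.
  Thresholds combine an absolute floor (0.05 post-stretch units, so
  featureless planes are reported unseedable) with a fraction (0.25) of the
  plane's strongest gradient.

## What the phantom emulates — and what it does not

`phantom_spec()` describes a layered slab (defaults: NFL 15, GCL 25, IPL
80, INL 30, OPL 20, ONL 60 µm — a murine-like stack whose URCL sums to
120 µm, consistent with the scale of healthy fixed retina) inside a medium
of refractive index 1.33, sampled at 1 OPL µm axially, 5 µm laterally over
~1 mm, and 4 µm across B-scans. Speckle is **multiplicative
gamma-distributed intensity noise** with shape 1/contrast² and unit mean:
homogeneous regions then have mean equal to their reflectivity and SD/mean
equal to the designed contrast, which gives closed-form moment tests (the
suite checks both at 10⁵ voxels under 3σ Monte-Carlo bounds). Layer
boundaries are snapped to the nearest voxel centre so the ground truth
stays exact; zero-reflectivity voxels receive a small positive exponential
noise floor (1 % of the maximum layer reflectivity) so background ROIs are
nondegenerate, and a zero-contrast spec is exactly noise-free. Eyecup-like
curvature is a rigid parabolic bowing (peak sagitta at the lateral edges);
fold distortion is a raised-cosine axial warp applied identically to
intensities (whole-voxel shifts) and truth curves (exact).

Phantom reflectivities are free parameters; they are stylized so that both
target interfaces are dark-to-bright transitions (medium 0.04 → NFL 0.50;
IPL 0.15 → INL 0.45), which is what the gradient seeder is specified to
detect. Real OCT contrast differs (plexiform layers tend to be brighter
than nuclear layers), and the phantom deliberately omits any physical
forward model: no point-spread function, sensitivity roll-off, refraction
at interfaces, shadowing, vasculature or optic-nerve-head geometry.
Passing recovery tests therefore demonstrates the correctness of the
*measurement chain* — geometry, units, statistics — not segmentation
robustness on real tissue.

## Numerical choices

- Gaussian kernels are truncated at 4σ, normalized to unit sum, with
  symmetric-reflection boundary handling (edge sample repeated); a constant
  volume is a fixed point to 10⁻⁹ and the impulse response is verified
  against an independent 1D convolution.
- Quantile stretching uses type-7 sample quantiles; a single-valued volume
  raises a "degenerate histogram" error rather than dividing by zero.
- `round()` in the Δy index step is R's round-half-to-even: at the 4 µm
  B-scan spacing, Δy = 50 µm gives a constant 12-voxel step.
- Thickness values are finite by construction (distances of finite points);
  an assertion guards the invariant anyway.

## Problem sizes

The default phantom is 480 × 200 × 133 voxels (~12.8 M), giving 12
evaluated B-scans at Δy = 50 µm; recovery there is −0.45 µm (flat) and
−0.93 µm (50 µm curvature) against the 120 µm design. The thinning-contrast
study uses 64-plane phantoms (6 evaluated B-scans per sample, ratio
recovered within 0.4 % of the designed 1.8), moment checks use ≥10⁵ voxel
slabs, and oracle sweeps use 100 random spline pairs — sizes chosen so the
whole validation runs comfortably on a laptop while keeping every
Monte-Carlo bound at 3σ.

## Known limitations

- The auto-seeder handles exactly two interfaces and assumes both are
  positive axial gradients; it is a testing surrogate, not a general
  multi-layer segmenter.
- A single medium refractive index converts the whole depth axis; per-layer
  indices inside the tissue are not modelled, so absolute thicknesses
  inherit that approximation exactly as manual analyses do.
- Background-noise values are in post-stretch intensity units and are
  comparable only between runs with an identical preprocessing
  configuration (the report embeds the config hash for this reason).
- On y-invariant phantoms the across-B-scan SD collapses to ~0; it reflects
  the phantom's symmetry, not a claim about real-tissue variability.
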