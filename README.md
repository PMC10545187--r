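# octlayer

Quantification of retinal layer thickness in optical coherence tomography
(OCT) B-scan volumes of embedded *ex vivo* retina, with a synthetic phantom
generator that makes every stage of the pipeline verifiable against exact
ground truth.

The package is aimed at groups that fabricate durable layered tissue models
(retina embedded in gels such as agarose/phytagel, n = 1.33, or in epoxy
resins, n = 1.49) for OCT system performance testing, and need a
reproducible, scriptable measurement of the **upper retinal cell layers
(URCL)** — the composite of the nerve fiber layer (NFL), ganglion cell layer
(GCL) and inner plexiform layer (IPL), bounded by the medium–retina
interface *i1* and the IPL–INL interface *i2*.

## The statistic

OCT delivers depth as optical path length (OPL), so geometric thickness is
obtained by dividing axial distances by the embedding-medium refractive
index *n*. After volume conditioning (3D Gaussian filtering with
σ<sub>x,z</sub> = 1.0, σ<sub>y</sub> = 2.0 voxels; linear histogram
stretching; optional averaging of consecutive B-scans), the two bounding
interfaces are reconstructed per B-scan by interpolating natural cubic
splines through sampling points — placed manually (CSV) or auto-seeded from
axial gradients. The thickness statistic is then computed at three levels,
always in geometric micrometres:

- pointwise, for each rasterized point *P<sub>j</sub>(x, z)* of *i1*:
  *t<sub>j</sub>(x) = min<sub>P ∈ i2</sub> ‖P<sub>j</sub> − P‖*
  (minimum Euclidean distance to the densely rasterized *i2*),
  *j = 1, …, m*, with *m* the length of *i1* in voxel columns;
- per B-scan: *t<sub>B</sub> = mean of t(x)* (with its SD);
- per sample: *t<sub>URCL</sub> = mean of t<sub>B</sub>(y)* over the
  evaluated B-scan set (selected every Δy = 50 µm inside the region of
  interest, distorted planes excluded), reported ± the SD across B-scans.

A closed-form helper, Δt = t·Δn/(n + Δn), quantifies the thickness shift a
refractive-index offset would induce; for the dispersion regime of the
relevant media (|Δn| ≤ 0.02) it stays below 2 % of t.

The phantom generator produces seeded layered-retina volumes (multiplicative
gamma speckle, eyecup-like parabolic curvature, OPL axial sampling, optional
fold distortion) together with the exact interface curves and the designed
URCL thickness, so recovery error is measurable without raw scan data.

## Worked example

```r
library(octlayer)

# healthy-retina phantom at the default study conditions:
# 120 um URCL, n = 1.33, speckle contrast 0.3, ~1 mm B-scans at 4 um spacing
report <- run_pipeline(pipeline_config(sample_id = "healthy",
                                       phantom = phantom_spec(seed = 11)))
report
#> <sample_report> healthy: t_URCL = 119.55 +/- 0.00 um (N_B-scans = 12)

report$t_urcl - 120          # recovery error vs the designed thickness
#> [1] -0.4511278

dispersion_sensitivity(126, 1.33, 0.02)   # um shift if n were off by 0.02
#> [1] 1.866667
```

The recovered 119.55 µm differs from the 120 µm design value by less than
one axial voxel (1 OPL µm ≈ 0.75 geometric µm), the quantization floor of
the boundary-snapped phantom. The per-B-scan SD of 0.00 reflects the
y-invariant phantom geometry, not the real-tissue spread.

The numbered scripts under `analysis/` run the package as a study:
phantom generation (`01`), speckle-reduction accounting (`02`), thickness
recovery on flat and curved phantoms (`03`), the glaucoma-like 1.8-fold
thinning contrast (`04`), and the background-noise ranking of embedding
media (`05`). Each writes its table under `results/`.

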