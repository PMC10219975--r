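# duvtomo

Virtual serial block-face deep-ultraviolet (DUV) microscopy of brain-like
tissue: a forward imaging simulator plus the full analysis chain —
instrument calibration, preprocessing, mosaic stitching and regional cell
quantification — validated end-to-end by parameter recovery on synthetic
data.

## The problem

Deep-UV light (~280 nm) is absorbed within tens of micrometres of
tissue, so wide-field imaging of a cut tissue block excites fluorescence
only in a thin surface layer: an optically sectioned image with no
scanning. Alternating imaging with vibratome sectioning ("serial
block-face" acquisition) yields an aligned 3D data set from which cells
can be counted per anatomical region. The catch is that every number such
an instrument produces — its point-spread function, its effective imaged
depth, a regional density contrast — comes out of an analysis pipeline
whose correctness is hard to establish on real tissue, where ground truth
is unknown.

`duvtomo` makes those analyses testable. It renders block-face images
from ground-truth phantoms under an explicit physical model and then runs
the same estimators a real workflow would, so every claimed measurement
can be checked against the parameter that generated the data. It is aimed
at anyone building or validating block-face / MUSE-style imaging
pipelines.

## The models at the core

**Depth attenuation (Beer–Lambert).** Material at depth *z* below the
block face contributes with weight *w(z) = exp(−z/d)*. The optical
sectioning thickness is defined as the 1/e depth *d*, and is estimated
from data by binning per-cell intensities by depth (2 µm bins), taking
bin medians, and regressing ln(median) on depth:
*d̂ = −1/slope* (`estimate_sectioning_thickness()`).

**PSF profiling.** Bead stacks are reduced to averaged 1D profiles
through each bead centroid along x, y, z and fitted with a Gaussian plus
offset; FWHM = 2√(2 ln 2) σ ≈ 2.35482 σ (`profile_psf()`).

**Acquisition geometry.** Stage resolution = pitch × step/360°
(0.9° on 500 µm/rev → 1.25 µm); tile grids at 20% overlap with
serpentine visit order (`plan_tiles()`); section faces at multiples of
the cutting thickness (`schedule_sections()`).

**Stitching.** Integer-pixel phase correlation on nominal overlap
windows, maximum-confidence spanning-tree placement, feather blending
(`estimate_offset()`, `assemble_mosaic()`).

**Quantification.** Otsu + intensity-watershed nuclei segmentation,
centroid-based atlas assignment, per-section counts and areal densities,
region-hierarchy (sunburst) aggregation, paired *t* (df = n − 1), Welch
ANOVA + Tukey HSD, Shapiro–Wilk (`segment_cells()`,
`count_and_density()`, `aggregate_region_tree()`, `paired_t()`,
`group_stats()`).

## Worked example

A two-region "habenula-like" phantom (2:1 cell-density contrast,
12000 vs 6000 cells/mm³) imaged as 10 serial 50 µm sections, segmented
and quantified:

```r
library(duvtomo)

cfg <- habenula_fixture_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")

dens <- tapply(res$counts$density_per_mm2, res$counts$region_id, mean)
round(dens[c("1", "2")], 1)
#>     1     2
#> 374.2 196.7

res$stats$paired_t_density
#> # A tibble: 1 × 7
#>   statistic    df    p_value mean_diff     n method   flagged
#>       <dbl> <dbl>      <dbl>     <dbl> <int> <chr>    <lgl>
#> 1      9.98     9 0.00000364      178.    10 paired t FALSE
```

The recovered mean areal densities are in ratio ≈ 1.9 (true contrast 2:1;
segmentation merges a few touching cells in the denser region), and the
paired *t* over the 10 sections — df = 9, the per-section pairing
convention — finds the contrast at *p* < 0.001. The run directory
contains the mosaics (TIFF), `cells.csv`, `counts.csv`, `sunburst.csv`,
`stats.yaml` and a log of every parameter and injected default.

Calibration works the same way:

```r
fix <- bead_fixture(seed = 5)
beads <- detect_beads(fix$stack, min_separation_um = 20)
profile_psf(fix$stack, beads)[, c("axis", "fwhm_um")]
#>   axis fwhm_um
#> 1 x       4.18
#> 2 y       4.20
#> 3 z      33.2

fit <- estimate_sectioning_thickness(sectioning_fixture(20, seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>      I0 d_hat_um r_squared n_cells n_bins failed
#>   <dbl>    <dbl>     <dbl>   <int>  <int> <lgl>
#> 1  191.     20.4     0.971     584     20 FALSE
```

Fitted objects have `tidy()` / `glance()` / `autoplot()` methods
(`autoplot(fit)` draws the binned medians with the fitted exponential
and the 1/e depth).

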