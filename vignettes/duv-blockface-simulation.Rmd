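---
title: "Virtual serial block-face DUV microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual serial block-face DUV microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(duvtomo)
```

## The measurement principle

Deep-ultraviolet light around 280 nm is absorbed so strongly by tissue
that fluorescence excitation is confined to a thin layer below an exposed
surface. Imaging the freshly cut face of a tissue block with a wide-field
camera therefore yields an optically sectioned image without any
scanning; shaving a section with a vibratome and re-imaging the new face
produces an intrinsically aligned 3D series. `duvtomo` implements a
forward model of this acquisition on ground-truth phantoms, together with
the analysis chain used to characterise such an instrument and to
quantify cells in the resulting data.

The package exists to make the *procedures* testable by parameter
recovery: every estimator it implements can be run against synthetic data
whose true parameters are known, so a claimed measurement (a PSF width, a
sectioning thickness, a regional density contrast) can be checked against
the value that generated the data.

## The forward model

### Depth attenuation

Material at depth $z$ below the block face contributes with the
Beer–Lambert weight

$$w(z) = e^{-z/d},$$

where $d$ is the 1/e attenuation depth — operationally, the *optical
sectioning thickness*. The default $d = 20\,\mu m$ matches the
characterised instrument. Each cell compartment is a sphere (nucleus,
radius $r_n$) or spherical shell (Nissl-like perikaryal rim, between
$r_n$ and the soma radius $r_s$); for a pixel at lateral offset $\rho$
from a sphere of radius $R$ centred at depth $z_c$, the depth integral of
$w$ along the chord has the closed form

$$d\left(e^{-a/d} - e^{-b/d}\right),\qquad
  a = \max(0,\, z_c - h),\; b = z_c + h,\; h = \sqrt{R^2 - \rho^2},$$

with the $\max(0, \cdot)$ clip expressing that material above the cut
face has been removed. We evaluate this exactly rather than by a
discretised depth sum: the closed form is cheaper and has no truncation
error at all, which matters when tests assert intensity ratios to 1%.

The per-dye emission images are blurred with the lateral Gaussian PSF,
shaded by the illumination field, mixed to RGB, scaled by a gain, and
optionally degraded with shot noise (Poisson, `photons_per_dn`), read
noise (Gaussian sd `read_sd`) and a camera offset, then quantised by
clip-and-round-half-even to the configured bit depth.

### Spectral mixing

Dye emission spectra are idealised as Gaussians (sd 35 nm) around the
emission peaks of the three stains the instrument was characterised with
— a Hoechst-like nuclear dye (496 nm), propidium iodide (659 nm,
nucleus + Nissl rim) and an AF594-like immunolabel (613 nm) — integrated
over idealised R/G/B passbands (580–700, 480–580, 400–480 nm). The true
camera response is unpublished; the matrix is exposed so unmixing can be
tested as an exact inverse.

### Illumination

The oblique (60°) side illumination is modelled as a multiplicative
linear ramp of ±15% across the field plus a 5% radial vignette. This is
deliberately the *same family* that flat-field correction assumes, so the
correction can be validated as an exact inverse; real shading is of
course richer.

### Reference stacks

`render_reference_stack()` emulates a co-registered confocal z-stack:
Gaussian axial sectioning at each requested plane, the same lateral PSF
and pixel grid, and *no* Beer attenuation. The axial sd is a parameter:
the default reuses the instrument's axial PSF (the geometry of a bead
focus scan), while ~2 µm emulates a true confocal's fine sectioning —
that is the appropriate choice when assigning per-cell depths or
computing depth-correlation profiles.

## Instrument parameters and their defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| attenuation depth $d$ | 20 | µm | characterised 1/e depth |
| PSF $\sigma_{x,y,z}$ | 1.5, 1.53, 13.8 | µm | spherical-bead deconvolution of the measured 4 µm-bead FWHMs (4.19, 4.24, 32.5 µm) |
| field of view | 1.3 × 1.0 | mm | 10× objective |
| tile overlap | 20 | % | acquisition convention |
| stage resolution | 1.25 | µm/step | 0.9° steps on a 500 µm/rev micrometer |
| section thickness | 50 or 100 | µm | must exceed the imaged depth so faces never re-image removed material |
| exposure / power | 30 ms / 8.13 mW | | metadata only; no radiometric model |
| camera | 8-bit, gain 25 DN per µm-equivalent emission | | keeps a surface cell near 200 DN, unsaturated |

The PSF defaults deserve a note: the instrument's published axial bead
profile is the *bead-convolved* response, so the package stores the
underlying Gaussian sigmas obtained by deconvolving a 4 µm sphere, and
its own bead simulations then reproduce the published FWHMs.

## The calibration procedures

**Bead profiling.** `detect_beads()` finds strict 3D local maxima above
an adaptive threshold, suppresses maxima within a minimum separation and
refines centroids by background-subtracted intensity weighting.
`profile_psf()` extracts 1D profiles through each centroid along x, y
and z, aligns and averages them across beads, and fits a Gaussian plus
offset; FWHM $= 2\sqrt{2\ln 2}\,\sigma$. The validation oracle is an
independent quadrature of the sphere-times-Gaussian integral.

**Sectioning thickness.** `estimate_sectioning_thickness()` bins per-cell
intensities by depth (default 2 µm, the reference-stack spacing), takes
bin medians — the averaging over many cells that tames the strong
within- and between-cell intensity heterogeneity of Nissl-like staining —
and fits $\ln(\mathrm{median})$ against depth by least squares;
$\hat d = -1/\mathrm{slope}$. The log-linear form has a closed-form
solution and agrees with nonlinear least squares (available via
`nonlinear = TRUE`) to well under 2% on binned medians. A non-negative
slope raises a failure flag rather than returning a meaningless depth.
The median-based estimator is invariant to global intensity scaling.

The recovery fixture (`sectioning_fixture()`) places ~600 cells at
uniform depths over $(r_s, 2d]$: fully submerged cells make the per-cell
intensity exactly proportional to $e^{-z/d}$, whereas cells transected
by the face would flatten the shallow end of the curve through geometric
clipping — a property of the scene, not an estimator defect. Depths are
taken from ground truth (standing in for confocal depth assignment);
intensities are medians over a small disk at the true centroid minus the
frame background, measured on the noisy, quantised render.

**Depth correlation.** `correlation_vs_depth()` computes Pearson r
between the block-face image and each stack slice over the union of the
two images' foreground masks. For a self-consistent render the profile
peaks at the shallowest slices — not exactly at slice 0: the
Beer-weighted image has its effective depth centroid a few micrometres
below the face, so the best-matching symmetric Gaussian window sits at
2–4 µm, with an r margin of only ~0.003 over the surface slice — and
decays monotonically beyond $d$. The tests assert exactly this shape.

## Acquisition geometry

Tile grids use stride $= \mathrm{fov}\times(1-\mathrm{overlap})$ and the
minimal count per axis, with the last tile shifted back to end exactly at
the tissue extent (tiles never leave the block; the trailing overlap
simply grows). Tiles are visited in serpentine order. Section faces sit
at $0, t, 2t, \dots$ with $n = \lfloor z_\mathrm{extent}/t \rfloor$; a
thickness at or below $d$ triggers a warning because consecutive faces
would re-image the same material.

Commanded stage moves quantise to whole motor steps by round-half-even,
leaving a residual of at most half a step (0.625 µm at the default
resolution) — recorded so mosaics can use nominal positions honestly.

## Stitching

Registration is integer-pixel phase correlation computed on the *nominal
overlap windows* of each adjacent pair (cropping first makes the method
immune to FFT aliasing when the true offset exceeds half the tile).
The peak-to-second-peak ratio serves as a confidence score; indecisive
peaks (featureless or pure-noise overlap) fall back to the nominal grid
offset with a warning. Global placement accumulates offsets over a
maximum-confidence spanning tree anchored at the first tile;
loop-closure residuals beyond 3 px trigger one neighbour-averaging
relaxation pass. Fusion is linear feather blending; where one tile
covers a pixel the value passes through bit-exactly, which is what makes
the cut-and-reassemble round-trip test exact off-seam. Subpixel and
affine registration are out of scope.

## Segmentation and quantification

`segment_cells()` is the deterministic surrogate for interactive
counting: Gaussian smooth (1.5 µm), Otsu threshold, hole filling,
watershed on the smoothed *intensity* surface, and an area filter
(15–400 µm²). We use the intensity surface rather than the distance
transform deliberately: touching cells produce a single convex mask
whose distance map has one basin, whereas their nuclei remain separate
intensity peaks — on the two-region fixture this raises recovered
density contrast from ~1.7 to ~1.85 against a ground truth of 2.0, with
no sensitivity to the tolerance parameter. Cells whose somata overlap by
a couple of micrometres are split; nuclei in physical contact (centre
separation below ~1.5 nucleus radii) blur into a unimodal spot that no
peak-based method can divide at this resolution, and remain one
detection — the same limitation a human annotator faces.

Region assignment takes the atlas label at the centroid pixel; counts
and areal densities (cells/mm² per section face) follow per
(section, region), and `aggregate_region_tree()` rolls counts up a
rooted region hierarchy with percentages of the root — the table behind
a sunburst plot. Volumetric density is derivable via the section
thickness but is not the default, since each face samples a fixed imaged
depth rather than the full section.

**Statistics.** `paired_t()` is implemented from the defining formula
(df $= n-1$; ten paired sections give df 9) and is cross-checked against
`stats::t.test` in the tests; `group_stats()` delegates Welch's ANOVA,
Tukey's HSD and Shapiro–Wilk to the standard R implementations, with a
hand-computed Welch oracle in the tests and a type-I-error calibration
(5% ± 2% over 1000 null replicates) in the acceptance suite.

## The synthetic study conditions

The canonical fixtures are package code, not test scaffolding:

- `habenula_fixture_config()`: two abutting 300 × 400 µm regions with a
  2:1 density contrast, 12000 vs 6000 cells/mm³, imaged as 10 serial
  50 µm sections of an 800 × 600 × 520 µm block in one 0.8 × 0.6 mm
  field. Mouse MHb/LHb densities are not established in the literature;
  these values are fixture choices — high enough that cells touch (the
  segmentation must cope), sparse enough that automated counting is a
  faithful surrogate for manual annotation. Amplitude heterogeneity is
  lognormal with sd(log) = 0.3.
- `sectioning_fixture()` / `bead_fixture()` / `correlation_fixture()`:
  described above.

What passing these tests shows — and does not. The phantoms have
spherical cells, axis-aligned regions, exactly exponential attenuation
and shading drawn from the model family the corrections invert. Passing
therefore demonstrates that the estimators are correct and calibrated
*under the stated model*, and says nothing about model mismatch in real
tissue: non-exponential scattering, autofluorescence, vasculature,
irregular morphology and registration error are all outside the
generator.

Problem sizes were chosen to keep a full validation run comfortable on a
laptop: block faces of a few hundred pixels per side, ~600-cell
calibration scenes, 10-bead stacks, 10-section series.

## Numerical choices and degenerate inputs

- Quantisation: clip then round-half-even (`base::round`).
- 8→16-bit conversion multiplies by 257 (0→0, 255→65535), spanning the
  full range, losslessly invertible; downstream quantification is
  scale-invariant, so the choice is inert.
- Flat-field estimation (per-pixel median over ≥ 10 tiles, smoothed by a
  sd of 5% of the field width, normalised to mean 1) requires many
  *distinct stage positions*; the pipeline refuses to median repeated
  views of one position — that would absorb anatomy into the "field" —
  and falls back to the reference-slide field (the virtual acquisition
  of a uniform fluorescent target) instead.
- Colour correction defaults to diagonal white balance; full unmixing is
  applied only when a 3 × 3 matrix (e.g. the inverse mixing matrix) is
  supplied. Whether the original workflow's "colour correction" was one
  or the other is unknowable from the outside, so both are exposed.
- Extended depth of focus selects, per pixel, the slice maximising local
  variance in a 9 px window — a focus measure suited to sparse puncta —
  with plain max-projection as a flag.
- Degenerate inputs fail loudly and specifically: zero-volume or
  overlapping regions, infeasible bead placement, empty stacks, singular
  unmixing matrices, zero-variance statistics (flagged, not silently
  dropped), regions with zero area but nonzero count.

## Reproducibility

Every stochastic step draws from a named substream of a single root
seed (`seed` in the YAML config), so a pipeline run is bit-reproducible:
same config + seed → identical images, CSVs and statistics. Experiment
configurations round-trip through YAML with unknown keys rejected and
injected defaults recorded in the run log.

```{r example}
cfg <- habenula_fixture_config(seed = 1)
res <- run_pipeline(cfg, out_dir = tempfile("duvtomo-run"))
glance(res$stats$intensity_by_section)
autoplot(res$counts)
```

## Known limitations

- No physical optics: diffraction, refraction at the 60° incidence and
  photobleaching are not modelled; the PSF is an ideal Gaussian.
- No autofluorescence or white-matter background model.
- Stitching is translation-only at integer pixels.
- Cell morphology is spherical; dendrites/axons are absent, so
  segmentation difficulty is bounded below its real-tissue level.
- The atlas is a synthetic box-region hierarchy, not a real reference
  atlas registration.
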