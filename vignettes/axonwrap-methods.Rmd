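---
title: "Quantifying 3D myelin wrapping on artificial axon arrays: methods and design"
author: "axonwrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D myelin wrapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonwrap)
```

## The measurement problem

Artificial axons (AAs) are vertical hydrogel micropillars printed on a
square grid — diameters of a few micrometres, spacings of tens of
micrometres, heights of 15–18 µm — around which oligodendrocytes deposit
MBP⁺ myelin membrane. The assay images each field of view as a
three-channel confocal z-stack (pillar dye, MBP immunostain, DAPI) with a
2 µm axial step, so a pillar appears as a stack of 8–10 circular
cross-sections. Myelin ensheathment is inherently three-dimensional: a
cell may touch a pillar in one optical section without wrapping it, so
the readout must combine *angular* coverage of the pillar circumference
within a slice with *axial* persistence of that coverage across adjacent
slices.

`axonwrap` scores each pillar as follows:

1. threshold the three channels to binary volumes;
2. detect pillar cross-sections per slice and link them through z;
3. trace the external 1-pixel outline of each cross-section and measure
   the fraction of outline pixels in contact with the myelin mask
   (the per-slice *coverage*);
4. extract maximal runs of consecutive slices with coverage strictly
   above θ~c~ = 0.8 (*sheath segments*), with segment length
   n~slices~ × Δz;
5. classify the pillar *fully wrapped* when its longest segment strictly
   exceeds L~min~ = 6 µm;
6. report the field's wrapping index WI = fully-wrapped pillars / nuclei,
   and the per-pillar maximal sheath lengths.

Both thresholds are strict inequalities, exactly as the assay defines
them ("> 80%" coverage, "> 6 µm" contiguous length). With Δz = 2 µm and
the slice-owns-one-step length convention, "> 6 µm" requires at least
four qualifying adjacent slices.

## Conventions and parameters

**Axes and indexing.** Voxels are stored as a (channel, z, y, x) array;
all indices are 1-based (R convention), z = 1 is the first acquired
slice, and pixel centres sit at integer coordinates. Wrap-event slice
ranges are 1-based inclusive.

**Calibration defaults.** Pixel size 0.31 µm/px and an 8-slice stack at
2 µm step, a typical 20× air-objective confocal configuration. The
acquisitions behind this assay do not come with a stated in-plane pixel
size, so 0.31 µm/px is a documented assumption; everything downstream is
parameterised by the true calibration, which explicit arguments always
override (file metadata loses, with a warning, because exported TIFFs
routinely carry corrupted physical metadata).

**Key analysis parameters** (all in `fieldParams()`):

| parameter | default | meaning |
|---|---|---|
| `thetaC` | 0.8 | per-slice coverage threshold (strict) |
| `lMinUm` | 6 µm | minimum contiguous sheath length (strict) |
| `contactRadiusPx` | 0 | half-width of the outline–myelin contact window |
| `lengthConvention` | `"slices"` | segment length = n·Δz (alternative `(n−1)·Δz`) |
| `maxLinkDistPx` | 10 px | z-linkage centroid search radius |
| `minAreaPx` | 9 px | minimum cross-section area |
| `borderPolicy` | `"exclude"` | drop pillars touching the image border |

**Why contact radius 0.** The myelin sheath directly abuts the pillar
boundary, so the external 1-pixel outline ring already lies inside a
correctly segmented myelin annulus wherever the pillar is wrapped.
Requiring myelin within a 3×3 neighbourhood (radius 1) instead adds
roughly one extra ring pixel per arc end, inflating measured coverage by
about 2/(π·r~px~) per end; for the smallest pillars of interest (3 µm at
0.31 µm/px, r~px~ ≈ 4.8) this pushes a 70%-covered pillar to a measured
~0.75–0.82 — across the 0.8 decision boundary. Radius 0 is unbiased at
all diameters; tolerance to mask erosion is provided by the robust
threshold (below) rather than by dilating the contact window. The radius
remains a parameter for heavily eroded real-world masks.

**Why a robust floor on the myelin threshold.** Thresholds default to
Otsu computed once on the channel's pooled 3-D histogram (not per slice,
so a slice without signal cannot invent one). Two-class Otsu, however,
degenerates when the foreground occupies a tiny fraction of the voxels —
on a lightly wrapped field the myelin arcs can be < 0.1% of the volume,
and Otsu then splits the *background noise* in half, flooding the mask.
The myelin channel therefore defaults to `"robust-otsu"`: the maximum of
the pooled Otsu threshold and a robust background floor
(median + 6·MAD). The floor only engages when Otsu has failed in this
mode; for well-populated channels the two coincide. The axon and nuclei
channels, whose foreground mass is set by the grid geometry and cell
density, keep plain Otsu. A constant (all-dark) channel is an error for
`thresholdChannel()` but is treated as an empty mask by
`computeFieldMetrics()`, since a field without any myelin or nuclei
signal is a legitimate observation.

**Segmentation details.** Per-slice connected components are linked
greedily across adjacent slices by ascending centroid distance within
`maxLinkDistPx`; unmatched components start new traces. Traces present in
fewer than half the slices are dropped as debris (pillars span the full
imaged height), and border-touching traces are excluded by default.
Pillar ids are assigned deterministically, row-major by first-slice
centroid, so repeated runs and relabeled inputs give identical output.
Nuclei are counted as connected components of the z maximum projection
with area at least that of a 4 µm disk; no declumping is attempted
(the WI normalises by a plain count, and clumped nuclei are an
acknowledged limitation). Pillar diameter is the equivalent-circle
diameter 2·√(A/π)·s from the median cross-section area.

**Degenerate inputs.** A field with no nuclei has an undefined WI: it is
flagged (`wiValid = FALSE`) and excluded from aggregation rather than
imputed as zero, because the definition divides by the nuclei count.
Zero detected pillars give zero counts, not an error. Ties in compound
ranking break alphabetically; the hit threshold is strict, so a compound
exactly on mean + 2·sd is not a hit.

## The Hertz fit

Pillar material stiffness is estimated from AFM force–indentation curves
with the spherical Hertzian contact model
F = (4/3)·(E/(1−ν²))·√R·(δ−δ₀)^{3/2}, fitted over
δ−δ₀ ∈ (0, 200 nm]. The Poisson ratio is not identifiable from a single
indentation curve; ν = 0.5 (incompressible hydrogel) is assumed, exposed
as an argument and reported with every fit — fitted moduli rescale as
(1−ν²) if another value is preferred. Initialisation uses the linearised
form (F^{2/3} is linear in δ), and the final estimate is a
Levenberg–Marquardt fit on the native force scale, so the start is robust
but the estimate carries no linearisation bias. By default the contact
point is taken at δ₀ = 0 (curves are assumed already contact-corrected);
`estimateContact = TRUE` frees δ₀ within the pre-contact region and
refits E in the windowed region. Fits with fewer than 5 points in the
window are refused. Raw deflection-vs-piezo data can be converted with
δ = z − F/k; spring-constant calibration itself is out of scope.

## What the synthetic generator emulates

`generateField()` renders, at the stated calibration: filled pillar
cross-sections at every grid node in every slice; myelin as annular arcs
hugging the pillar boundary (inner radius = pillar radius, radial
thickness 0.6 µm) with controlled angular coverage, angular offset and
contiguous axial extent; nuclei as 8 µm spheres placed by bounded
rejection sampling in the inter-pillar space (so they remain separable
from pillars); then in-plane Gaussian blur (σ = 0.4 µm), optional Poisson
shot noise (150 photons at full scale) and Gaussian read noise
(sd 0.02 of the dynamic range), with intensities clipped to [0, 1] and
quantised to 16-bit levels. Ground truth — per-slice coverage, maximal
contiguous sheath length, the fully-wrapped flag and the expected WI — is
computed analytically from the specification *before* blur and noise, so
it is exact. Identical spec and seed give bit-identical voxels.

The generator deliberately does **not** emulate: axial PSF blur (blur is
in-plane only), MBP⁺ cell somata and processes in the myelin channel,
uneven illumination or autofluorescence gradients, pillar fabrication
defects (tilt, merged or missing pillars), or overlapping nuclei.
Passing the recovery studies therefore shows that the measurement logic
is correct and noise-tolerant under a faithful geometric model of the
assay; it does not show robustness to MBP⁺ soma contamination of the
myelin mask near pillars (no exclusion rule is applied beyond
thresholding) or to clumped nuclei — on real data those remain the main
caveats, as they are for the original assay.

One quantitative consequence of the optics model: after blurring, mask
agreement with the noise-free render is limited by the one-pixel boundary
band where intensity crosses the threshold, so the Jaccard overlap scales
with the object's area-to-perimeter ratio — above 0.95 for 10 µm pillars
but around 0.9 for 3 µm pillars and the 0.6 µm-thin annulus. The
coverage measurement is insensitive to this band by construction (the
outline ring sits well inside the blurred annulus support), which is why
classification accuracy survives noise that the raw masks do not.

## Validation studies and problem sizes

The test-suite and `scripts/acceptance.R` run seeded simulation studies
whose conditions are fixed in the generator defaults above:

* **Decision boundary**: angular coverage {0.5, 0.7, 0.85, 1.0} ×
  contiguous spans {2, 4, 8} µm on 3×3 grids of 3 µm pillars; 20 seeded
  fields per cell in the acceptance script (5 per cell in the unit
  suite), each scored at zero noise (where ground truth is exact by
  construction) and at default noise. Only coverage > 0.8 with span
  > 6 µm may classify as wrapped.
* **WI recovery**: 100 randomized fields (30 in the unit suite) from
  `randomFieldSpec()`, which draws coverage from
  {0.30, 0.50, 0.70, 0.90, 1.00} — both sides of the boundary, but more
  than one outline-pixel-equivalent (~0.065 at 3 µm) away from 0.8, so
  the ground-truth label is well defined on the pixel raster — spans of
  1–6 slices, uniform angular offsets, and 4–8 nuclei, about as many
  non-overlapping 8 µm nuclei as a 60×60 µm field accommodates.
* **Mechanics**: the three pillar materials (13000, 780, 98 Pa),
  noiseless and with force noise at 2% of the peak force, 30 replicate
  curves per material per repetition.
* **Hit calling**: control per-field WI ~ N(1.0, 0.1), 27 fields per
  condition (3 wells × 9 fields), compound shifts of 0 and 0.3 (a
  3σ effect), 200 simulated plates in the acceptance script (100 in the
  unit suite).

These sizes are the package's validation design; the acceptance script
reports every quantity it computes together with the problem size used.

## Known limitations

* Coverage is measured on outline pixels, not angular bins, so pillars
  under ~2 µm diameter would have too few ring pixels for a stable
  fraction at this pixel size.
* The greedy nearest-centroid z-linkage assumes non-overlapping pillars
  (spacing well above diameter, as fabricated); it performs no
  split/merge reasoning.
* The maximal-run semantics require coverage above θ~c~ in *every* slice
  of a segment; no interpolation between slices is attempted.
* Moduli from the Hertz fit are conditional on the assumed ν and on
  curves being expressed as force vs indentation; adhesive (JKR/DMT) and
  viscoelastic behaviour are out of scope.
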