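---
title: "Quantitative 3D reconstruction of serial sections with boxel3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D reconstruction of serial sections with boxel3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxel3d)
```

## The problem

Developing organs grow by locally varying proliferation, and averages over
a whole organ hide exactly the gradients that drive morphogenesis. Serial
physical sectioning lets multiple cell types be stained and identified,
but it also destroys the third dimension: what the microscope delivers is
a stack of 2D images in which every nucleus appears as one or more
*profiles* — cross-sections of a 3D particle. `boxel3d` rebuilds local,
quantitative 3D information from such stacks: per-boxel maps of cell
density, cell size, labeling index, tissue volume and cell number, masked
by the segmented tissue so the numbers sit in their proper morphological
context.

## The measurement model

The tissue's bounding box is divided into a lattice of virtual cubes,
**boxels**, with in-plane edge `boxel_size_um` (default 26 um, on the
order of a cell diameter). Along the cutting axis a boxel spans
`round(boxel_size_um / t)` whole sections, so its z-extent is a multiple
of the section thickness `t`; with the default 26 um boxel and `t = 7` um
the z-extent snaps to 28 um (4 sections). A cubic **sample volume** of
`m x m x m` boxels (default `m = 5`, i.e. 130 um) slides over every boxel
position; within its footprint three raw quantities are accumulated and
projected to the center boxel:

1. the tissue-of-interest area, summed over the included sections,
2. the total number of nuclear profiles (centroid rule, counted only
   inside the tissue mask),
3. the number of profiles positive for the specific marker.

From these, `compute_morpho_fields()` derives the local variables:

* profile areal density `N_A = N / sum(A)`;
* number density by the Abercrombie correction
  `N_V = N_A / (D + t)`, where `D` is the mean nuclear diameter. A
  sphere of diameter `D` intersects on average `(D + t) / t` slabs of
  thickness `t`, so the uncorrected `N_A / t` overestimates density by
  exactly that factor — about 13/7 at the default geometry. The
  correction assumes approximately spherical, convex nuclei of constant
  per-type diameter; this known bias is accepted in exchange for
  simplicity and is why `D` must be measured per cell type when types
  differ in nuclear size;
* cell size `1 / N_V` (mean tissue volume per nucleus);
* labeling index `LI = N_V_pos / (N_V_pos + N_V_neg)`, each type with
  its own `D` in the denominator;
* Cavalieri tissue volume `V = t * sum(A)` and cell number
  `N = N_V * V`, pooled over non-overlapping (`m = 1`) boxels for
  specimen totals.

### Precision and the 171-profile rule

The labeling index is a proportion, so its precision is set by the
number of profiles counted per sample volume. `required_profile_count()`
inverts the normal-approximation half-width `z * sqrt(p(1-p)/n)`: for
`p = 0.5`, a +/- 0.075 half-width and 95% confidence (exact quantile
1.959964, not 1.96) the smallest sufficient count is **171**, the
default reliability threshold. An exact Clopper-Pearson inversion would
give a slightly different count; the normal approximation is used
because it is the standard sample-size calculation for proportions and
reproduces the published requirement. `choose_sample_volume()` runs the
prescribed pilot sweep over increasing `m` and reports, per candidate,
the fraction of tissue-containing boxels measured with fewer than the
required profiles; boxels below the requirement keep their values but
carry `reliability = FALSE` rather than being suppressed, because
peripheral sample volumes systematically contain too few nuclei and a
complete matrix is more useful than a punched-out one.

## Per-section image processing

**Detection.** Staining gradients are removed by subtracting a
`kernel_px` (default 10) box-mean-filtered copy of the pan-nuclear image
("local-maxima image"); the box mean is computed exactly with a
summed-area table and mirror-reflected edges, and negative residuals are
clamped to zero so a single-sided threshold selects profiles. The
detection threshold depends on the kernel size and no closed-form rule
exists for it; it is exposed as a parameter with an automatic mode
(Otsu on the nonzero residuals). Connected components below
`min_area_um2` are discarded as debris.

**Splitting.** Overlapping nuclei merge into one component. A profile
whose area strictly exceeds twice its section's median profile area
(medians over pre-split areas; per section, to be robust against
staining drift across the stack) is divided in two across its minor
principal axis through the centroid. Total area is conserved exactly;
the children's areas are approximately equal. A section's single
profile is never split, and a profile at exactly twice the median is
kept whole.

**Classification.** A profile is positive when its mean intensity in the
specific channel exceeds the local background — the median of the
non-profile pixels in its bounding box expanded by
`background_window_px` — by more than `z_cutoff` (default 3) robust
standard deviations (`1.4826 * MAD`). Median/MAD make the rule invariant
under affine intensity rescaling; a window with no background pixels
yields `excluded`. Chromatic aberration toward image corners can be
side-stepped with the optional `border_um` exclusion margin rather than
an optical correction.

**Quality control.** Every stage emits an inspectable artifact:
complementary-color alignment overlays (red/green, overlap white),
per-section foreground fractions with outliers flagged against the
running median of neighbors (factor 2 by default; more than 20% flagged
sections is advisory for re-staining — a convention, not a derived
value), colored-circle control images for the classification, and the
cumulative count distribution for the sample-volume choice. A lost
section may be substituted by a copy of a neighbor, never twice in a
row; violating that rule is a hard error because the morphometry of
adjacent substitutes is no longer independent.

## What the simulator emulates — and what it does not

`sample_nuclei()` draws a (possibly inhomogeneous) Poisson sphere
population inside an analytic solid; `render_section_stack()` cuts it
into slabs `[(k-1)t, kt)` and renders three channels (all nuclei,
positive nuclei, tissue fill). A nucleus produces a profile in *every*
slab its sphere intersects — precisely the double-counting event the
Abercrombie correction removes — and the disc radius is the maximal
chord of the sphere-slab intersection, matching the projection through
the section that the microscope shows. Overlapping discs are max-blended
so merged profiles genuinely occur. Optional degradations target
specific pipeline stages: Gaussian noise (detection), a linear intensity
gradient (low-pass subtraction), per-section intensity jitter
(segmentation QC), rigid misalignment (alignment). A constant
`background` offset (default 0.1) keeps the background intensity
distribution away from the zero clamp, as in real sections.

The simulator does **not** model point-spread blur, photobleaching,
chromatic aberration, tissue deformation or anisotropic nucleus shapes.
Passing its recovery tests therefore validates the *measurement scheme*
— counting, correction, integration — under controlled geometry, not
the robustness of detection to every real-world artifact.

Defaults mirror the reference use case: `D = 6` um nuclei (a nucleus of
that size comprises roughly 10% of a ~1130 um^3 cell), `t = 7` um
sections, 0.9 um/pixel (a nucleus must span at least 6 pixels for
reliable detection — `validate_resolution()` checks this), 26 um boxels,
`m = 5`.

## Numerical and design choices

* **Coordinates.** Images are `[row = y, col = x]`; pixel centers sit at
  `(i - 0.5) * pixel_size_um`; section `k` occupies `[(k-1)t, kt)`.
  Content exactly on the far bounding-box face joins the last boxel.
* **Sample volumes at the edge** are clipped at the lattice and the
  clipping is recorded per boxel; densities stay ratio-correct because
  the effective `sum(A)` is accumulated over the clipped footprint.
* **Even `m`** (8-boxel, 64-boxel cubes) is rejected: an even cube has
  no center boxel to project into, so only odd `m` is meaningful.
* **12-bit data** are promoted to 16-bit containers without stretching —
  the identity on gray values, so no information is changed.
* **Quantitative TIFF export** stores values through an affine codec
  (`offset`, `scale` in a JSON sidecar) on the TIFF `[0, 1]` sample
  range, with stored value 0 reserved for unmeasured boxels: `float32`
  round-trips to single precision (~1e-7 of the value range), `uint16`
  to at most 1/65535 of the range. The `uint16` mode exists because
  integer gray-value volumes are what legacy 3D viewers ingest.
* **Alignment.** Full iterative rigid registration is delegated to
  dedicated software; the package applies externally estimated
  per-section transforms (and the same transforms to every channel of
  the specimen), offering only FFT cross-correlation translation
  estimation as a convenience, with a normalized-correlation floor below
  which the result is flagged low-confidence.
* **Problem sizes in the test suite.** Recovery tests run on scenes of
  roughly 250-500 um extent with 1e4 nuclei at most (counting-level
  checks) and ~1.2e3 nuclei (full-pipeline checks) — large enough that
  Monte-Carlo error sits well inside the asserted tolerances, small
  enough to run routinely.

## Known limitations

* The Abercrombie estimator is biased for strongly aspherical or
  size-dispersed nuclei; unbiased disector/fractionator counting is out
  of scope by design.
* Detection misses grazing profiles whose discs fall below the debris
  cut, which biases pipeline-level density (not labeling index)
  downward by several percent at the default geometry; counting-level
  validation shows the estimator itself is unbiased.
* The splitting rule always divides a merged profile into exactly two;
  triple mergers remain under-split. Keeping density moderate or `m`
  large enough is the practical mitigation.
* Masks, profiles and fields live in memory; stacks far beyond ~10^3 x
  10^3 x 10^2 voxels need tiling upstream.
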