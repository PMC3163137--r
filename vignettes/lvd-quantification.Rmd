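---
title: "Whole-slide lymphatic vessel density: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide lymphatic vessel density: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvdquant)
```

## The problem

Lymphatic vessel density (LVD) — the number of lymphatic vessel
cross-sections per mm² of stromal tissue — is a candidate predictive marker
for lymph node metastasis in early invasive carcinomas, because lymphatics
are the preferential route of tumor cell dissemination. The conventional
readout counts vessels inside a few manually chosen "hot spot" microscope
fields, a protocol with well-documented inter-observer variability. This
package implements the alternative: quantify *every* vessel section on a
scanned whole slide, so that LVD, its spatial distribution relative to the
tumor invasion front, and its directional heterogeneity around the tumor
are measured objectively.

The expected input is an 8-bit RGB scan (or tile) of a section stained for
podoplanin with the D2-40 antibody revealed in permanent red, counterstained
with hematoxylin, plus a manually delineated tumor mask (binary raster or
GeoJSON polygons). Tumor delineation is deliberately an input, not an
algorithm: on H-DAB/permanent-red sections it is the step pathologists
perform by hand, and automating it (e.g. via cytokeratin staining) is out of
scope.

## The pipeline

Segmentation proceeds in four fixed steps, all deterministic:

1. **Wall detection.** The excess-red transform $ER = 2R - B - G$
   (signed, spanning $[-510, 510]$, never clamped) maximizes the contrast of
   permanent-red endothelium against pink-blue tissue. A global threshold is
   chosen on the occupied-range histogram of $ER$ by Kapur–Sahoo–Wong
   maximum-entropy thresholding: the threshold $t$ maximizes
   $H_b(t) + H_f(t)$, the Shannon entropies of the normalized histogram
   below and above $t$. Candidates leaving a class empty are skipped and
   ties resolve to the lowest $t$. Components smaller than
   `min_wall_area_px` (default 20 px at 0.65 µm/px, ≈ 8.5 µm², far below any
   vessel section) are discarded as staining specks.
2. **Tissue footprint.** The blue channel is decimated by block-mean
   pooling (factor 8 by default, making gigapixel rasters tractable) and
   thresholded with Tsai's moment-preserving method: the two-level image
   preserving the histogram's first three grey moments yields a background
   fraction $p_0$, and the threshold is the smallest level whose cumulative
   fraction reaches $p_0$. The *lower-blue* class is tissue
   (hematoxylin-stained tissue is darker blue than near-white glass); a
   `tissue_polarity` override exists for stains that invert the contrast.
   Interior holes are filled, because lumens and tears look like glass but
   belong to the section footprint.
3. **Lumen rescue.** Collapsed or weakly stained walls ring a bright,
   glass-like lumen. Candidate lumens are pixels inside the tissue footprint
   whose luminance $(R+G+B)/3$ exceeds `lumen_bg_fraction` (default 0.90)
   times the mean luminance of the non-tissue background. A candidate
   component is kept only if its one-pixel 8-connected dilation touches a
   detected wall; this removes blood-vessel lumens and tears, which are
   bright but not wall-adjacent.
4. **Vessel assembly.** The union of walls and kept lumens is hole-filled
   and labeled with 8-connectivity, so one vessel section is one object even
   when the lumen threshold missed interior pixels. Objects intersecting a
   user-supplied exclusion mask (podoplanin-positive tumor cells, epidermis)
   are dropped whole and their labels reported — the programmatic equivalent
   of the manual clean-up step this assay otherwise requires.

The choice of Kapur for "entropy thresholding" and Tsai for
"moment-preserving thresholding" is fixed here, with exact tie-breaking,
so that results are bit-reproducible; both implementations are tested
against independent oracles (an exhaustive criterion scan, and a separately
coded closed form via `polyroot`) on randomized histograms.

## From masks to measurements

Quantification rests on the exact Euclidean distance transform of the
complement of the tumor mask: every pixel holds its centre-to-centre
distance (µm) to the nearest tumor pixel. From it:

* **Stroma** is operationalized as tissue minus tumor. The paper trail
  behind this package measures LVD "per mm² of stromal tissue" while only
  separating tissue from glass; the subtraction is this package's reading
  and is what `run_pipeline()` reports as `whole_tissue`.
* **Peritumoral band**: stromal pixels with $0 < d \le$ `band_mm`
  (default 2 mm), the region where peritumoral LVD is conventionally read.
  The band uses straight-line Euclidean distance; a geodesic
  through-tissue distance would be a defensible alternative reading of
  "within 2 mm of tissue from the tumor edge" and is a known limitation,
  not implemented.
* **Vessel records**: per object, the unweighted pixel centroid, its area,
  the distance-map value at the pixel nearest the centroid, and the angle
  of the centroid seen from the tumor mass centre (unweighted centroid of
  all tumor pixels, even for disconnected bundles). A vessel belongs to a
  region iff its centroid's nearest pixel lies in the region mask, so a
  vessel straddling the band boundary counts exactly once.
* **LVD**: region vessel count divided by region surface
  (true pixels × (pixel size/1000)²).

Angles follow the image convention: 0° points right (+col), angles increase
counter-clockwise *as displayed* (row 0 at top), i.e.
$\theta = \operatorname{atan2}(-(r - r_t),\, c - c_t) \bmod 360°$. The
directional profile assigns vessels with distance in `window_mm`
(default (0, 2] mm) to eight 45°-wide sectors centred at 0°, 45°, …, 315°,
each covering $[c - 22.5°, c + 22.5°)$ with wrap-around; the paper trail
names the eight directions but not the wedge boundaries, so the half-open
centred wedge is fixed here. The reported **linear vessel density** is the
sector count divided by the radial window length (vessels/mm) — the
interpretation of "density by unit of length" with meaningful units; a
normalized-frequency area was the ambiguous alternative. Distance
histograms use half-open bins of `bin_width_mm` (default 0.1 mm); the upper
limit defaults to the smallest bin multiple strictly covering the largest
distance.

## The synthetic slide generator

No public whole-slide dataset with ground-truthed lymphatic vessel
annotations exists for this assay, so validation uses `generate_slide()`:
near-white glass (RGB 245, 245, 248), a wobbled pink-blue tissue blob
(195, 180, 160 — blue channel 160, inside the 150–190 band of hematoxylin
counterstain; excess-red 50), red annular walls (200, 40, 60; excess-red
300), near-white lumens (242, 242, 242), distinctly recolored tumor blobs
(120, 190, 140), optional wall-coloured confounder clumps inside the tumor,
and clipped Gaussian pixel noise (σ = 5 by default). A single RNG stream
seeded by `seed` drives every placement and the noise, so slides are
bit-reproducible.

Default study conditions: 2000 × 2000 px at 0.65 µm/px (the pixel size of a
100× whole-slide scan), 50 vessels of 15–45 µm outer radius with 5 µm
walls, one tumor blob of 150–250 µm radius. The validation experiment runs
the full pipeline on 20 such slides (seeds 0–19) and scores recall against
ground truth with intersection-over-union ≥ 0.3 matching — the synthetic
analog, at tile scale, of checking automated counts against manual counts
on real sections (where ≈ 93% agreement is the reference performance). The
anisotropic scenario (`generate_anisotropic_case()`) confines vessels to
angles (90°, 270°) within 2 mm of the tumor; it is rendered at 2 µm/px on
the same frame so a 2 mm band fits around a centred tumor — at 0.65 µm/px
the frame is only 1.3 mm wide.

What the generator does *not* emulate: real staining texture, DAB edge
pooling, gradual stain fading, overlapping/touching vessel sections,
folded tissue, or out-of-focus regions. Passing the synthetic validation
therefore demonstrates that the implementation is faithful and robust to
pixel noise and geometry, not that the default configuration transfers to
any particular scanner or staining protocol; on real material the staining
quality remains the critical determinant, and thresholds should be
inspected via the run report.

## Numerical and design choices

* **Decimation.** Binary masks decimate by block-OR (an output pixel is
  true iff any source pixel of its block is true): presence-preserving, so
  no vessel is lost at coarse scale, at the cost of slight area inflation
  near boundaries (≤ 10% for regions at least 50·k pixels wide). Grey
  channels decimate by block mean, rounded half-up; edge blocks average
  over available pixels. The exact decimation rule of the original
  gigapixel workflow is not published; block-OR is fixed here as the
  counting-safe choice.
* **Pixel size resolution**: explicit argument > TIFF
  XResolution/ResolutionUnit metadata > default 0.65 µm/px with a warning.
* **Coordinates**: rasters are (row, col), 0-based in all user-facing
  values, row 0 at top; centroid-to-pixel lookup rounds half-up.
* **Ties and degeneracies**: both thresholders break ties toward the lowest
  threshold (the entropy criterion with a 1e-10 slack so mirror-symmetric
  histograms resolve stably); single-level histograms raise degenerate
  errors rather than guessing; an empty tumor mask is an error for every
  distance-dependent operation, while an empty vessel set is a valid result
  (empty records, all-zero profiles).
* **Known limitation — unstained slides.** A global entropy threshold
  always splits the histogram in two. On an image with *no* red-stained
  structures the wall threshold falls between background modes and produces
  spurious foreground; downstream counts from a slide without any positive
  staining are therefore meaningless. This mirrors the assay itself, which
  presumes successful immunostaining; the run report's thresholds (a wall
  threshold at or below typical tissue excess-red is a red flag) are the
  practical guard.
* **Problem sizes.** Unit tests exercise 500–700 px tiles (12–20 vessels);
  the validation experiment uses the full 2000 px default condition. These
  sizes are the package's own test design; the pipeline itself is linear in
  pixel count and runs whole 2000 px tiles in seconds.

## Reading the outputs

`run_pipeline()` writes, per run: all masks (PNG + JSON sidecars), the
label map (16-bit TIFF), `vessels.csv` (one row per vessel record),
`lvd_report.json`, distance and directional profile CSVs, the polar plot,
the distance map (float TIFF + scale sidecar), and `run_report.json`
echoing the tool version, configuration, thresholds, counts and all
warnings. Identical inputs yield byte-identical CSVs; the run report
differs only in its timestamp.
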