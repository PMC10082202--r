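---
title: "Imaging and detecting rare cells on microfilter membranes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging and detecting rare cells on microfilter membranes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filterscan)
```

## The problem

Size-based microfilters capture circulating tumor cells (CTCs) and cancer
associated fibroblasts (CAFs) from blood: cells larger than the pore size are
retained on a thin porous membrane and identified by immunofluorescence
(DAPI nuclear stain, pan-cytokeratin CK for epithelial tumor cells,
fibroblast activation protein FAP for CAFs). The membrane, however, is
flexible and sits slightly wavy on the slide. Under a 20x / NA 0.4 objective
the depth of field is only `wavelength / (2 NA^2)` (about 1.72 µm at 550 nm),
while the membrane height varies by tens of microns — so no single focal
plane shows all cells sharp, even within one camera field of view. The
package implements the computational chain that deals with this: per-field
autofocus, all-in-focus (AIF) synthesis from fine z-stacks, shading
correction, subpixel registration and stitching into a whole-slide image
(WSI), rule-based mCTC/CAF detection, whole-slide detection orchestration,
and statistical evaluation — together with a scene simulator that provides
pixel-exact ground truth for all of it.

## The scene simulator

No public dataset of microfilter z-stacks exists, so every quantitative
claim in this package is made against simulated scenes with known truth.
The simulator emulates the *statistics* of a model-system slide, not its
optics in microphysical detail:

* **Membrane surface.** A band-limited Gaussian random field: white noise
  low-pass filtered at a correlation length (default 500 µm) and rescaled to
  a target height standard deviation. The default amplitude is 15 µm; the
  waviness of real membranes is not published, and this value is inferred
  from the instrument's ±25 µm fine scan half-range, which must bracket the
  cells it is designed for. The filter is periodic in the Fourier domain,
  which is appropriate for a stationary random surface.
* **Objects.** Tumor cells (mCTC, DAPI+/CK+/FAP−, diameter ~N(15, 1.5²) µm
  clipped above 10 µm), fibroblasts (CAF, DAPI+/FAP+/CK−, ~N(20, 3²) µm,
  drawn as ellipses with eccentricity up to 0.8 since CAFs vary more in
  shape), hollow filter pores (8 µm annuli with *no* DAPI anywhere and a
  weak autofluorescent rim in exactly one marker channel), and small bright
  precipitates in one marker channel. No object ever carries both CK and
  FAP. Placement is uniform with a configurable minimum center distance
  (default 20 µm — a cleanly prepared slide; 0 permits clumps). Each
  object's axial position is the membrane height under its center.
* **Image formation.** An object at defocus *d* is drawn as a smooth-edged
  disc whose edge half-width grows as `sqrt(w0^2 + (2 sigma)^2)` with
  `sigma = max(sigma_min, k |d| / pixel_size)` pixels, and whose amplitude
  is attenuated by `R^2 / (R^2 + 2 sigma^2)`. The slope `k` is calibrated so
  `sigma` is about 1.5 px at one depth of field. The kernel width is capped
  at 25 px for tractability while the amplitude attenuation continues
  uncapped, so the Tenengrad focus measure decreases strictly with defocus
  at any distance — the property the autofocus relies on. Per-channel axial
  chromatic offsets shift the best-focus plane per channel. A radial
  vignetting profile multiplies signal plus background; Poisson shot noise
  and Gaussian read noise are optional. This is deliberately not a physical
  point-spread-function model (no Gibson–Lanni, no camera gain): the
  downstream algorithms consume focus *contrast*, not PSF shape.
* **What the simulator does not model** — and hence what green tests do not
  certify on real data: cell texture, staining heterogeneity, debris other
  than round precipitates, filter-pore/cell superposition, optical
  aberrations beyond axial chromatic shift, stage backlash. Results here
  bound algorithmic behavior, not end-to-end hardware performance.

The default pixel size is 0.23 µm/px (a 0.92 mm field imaged on 4000 px).
Simulated tiles in the tests and the acceptance script are 256–640 px
rather than 4000×3700 px: per-field *cell counts* (roughly 10–25, matching
500–1000 spiked cells of each type spread over a ~7×7 mm slide) are
preserved instead of cells-per-area, because per-field content is what
drives focus curves and registration. Tile overlap is scaled to 128 px
rather than a proportional fraction of the paper-scale 310 px, keeping the
overlap strip wider than ~2 cell diameters — the property that makes an
overlap registrable at all; a proportional overlap on a small tile would be
narrower than a single cell.

## Autofocus

Scanning runs coarse-to-fine at every lateral position, in the DAPI channel
only (the nuclear stain is present in every cell class of interest):

1. A coarse z-stack (default 20 µm steps over 200 µm) is acquired.
2. The Tenengrad focus measure — the sum of squared 3×3 Sobel gradient
   magnitude over the image interior — is computed per plane. It is
   offset-invariant, zero on constant images, and strictly decreasing under
   blur.
3. A four-parameter Gaussian `A exp(-(z-mu)^2 / 2 s^2) + B` is fitted to the
   focus curve by Levenberg–Marquardt least squares (initialized at the
   discrete argmax, with `s` at one coarse step, `B` at the curve minimum;
   200 iterations, 1e-8 tolerance). Its peak `mu` is the best focus. The
   true Tenengrad-vs-defocus curve is not Gaussian — it is more sharply
   peaked — but the fitted peak *location* is accurate to a small fraction
   of a coarse step whenever a handful of informative samples straddle the
   peak, which is what the scan plan guarantees.
4. If the fit fails to converge or puts the peak outside the scanned range
   (e.g. an empty field whose curve is flat noise), the estimate falls back
   to the discrete argmax, ties broken toward lower z, and is flagged
   `converged = FALSE`.
5. The fine stack (default 5 µm steps over 50 µm) is centered on the
   estimate and reused for **all** channels; residual axial chromatic
   aberration is absorbed later, because AIF fusion selects z per channel.

## All-in-focus fusion, shading, registration, stitching

**AIF fusion.** Each fine stack is split into patches (600×600 px at full
scale, scaled in tests; adjacent patches overlap 50 px). Per channel and
per patch, the z-slice with the highest Tenengrad is selected; overlapping
patches are blended with linear feathering. Channels select independently —
this is what compensates chromatic focus shifts. With zero patch overlap
the fused patch is *exactly* the best single plane; the default 50 px
overlap trades a bounded blending loss at patch borders for seam-free
output. Whether the original system blended or tiled disjointly is not
stated anywhere; feathering is this package's choice.

**Flat-field.** The per-pixel median across many tiles isolates the smooth
illumination profile (cell signal is sparse), which is Gaussian-smoothed and
normalized to mean 1. Smoothing uses normalized convolution (dividing by
the blurred all-ones image) so image borders are not attenuated. This is a
deliberately simple retrospective estimator standing behind the same
interface a low-rank method would use; it is scale-equivariant and exact on
pure constant-times-vignette stacks.

**Registration.** Adjacent tiles overlap nominally (310 px at full scale).
The overlap strips of the DAPI channel are phase-correlated; the
correlation peak is refined on a locally upsampled Fourier grid
(matrix-multiply DFT, default 1/20 px). Two numerical details matter:
(1) a Hann window is applied before the FFT — without it, the periodic
boundary discontinuity, identical in both strips, locks the correlation
peak at zero shift; (2) the upsampled peak offset enters with a minus sign
(the correlation peak sits at *minus* the shift). If the normalized peak
falls below 0.03, or the usable overlap is under 64 px, the nominal offset
is returned flagged low-confidence — an empty strip cannot be registered
and should not pretend otherwise.

**Stitching.** The upper-left tile anchors the mosaic; every other tile's
global offset is accumulated along the row-major chain (left neighbor, or
top neighbor in the first column). Loop-closure residuals over 2×2 blocks
are reported via the registration table but not globally optimized — chain
accumulation is what the anchor-based scheme specifies, and closure errors
stay below a pixel on clean data. Tiles are placed at the integer part of
their offset, the fractional part applied as a Fourier-domain shift with an
8 px raised-cosine edge taper against wraparound, and overlaps are blended
with weights proportional to each tile's distance to its own border,
normalized to sum to one wherever any tile covers.

## The rule-based detector

The conventional computer-vision detector mirrors a pathologist's screening
protocol; every threshold an observer would tune is explicit configuration:

* per-channel binarization (absolute threshold or Otsu; a near-constant
  channel yields an empty mask rather than an arbitrary Otsu split);
* watershed segmentation of the CK and FAP masks on the Euclidean distance
  transform, with seed separation defaulting to 0.6× the expected cell
  diameter, splitting moderately touching cells;
* inclusive area filtering, defaulting to a ≥8 µm minimum cell diameter at
  0.23 µm/px (≈950 px²) and 40× that as the maximum;
* marker logic: a CK region is an mCTC iff its mean DAPI ≥ 0.15 (nucleated —
  this single rule rejects hollow pores) and its mean FAP ≤ 0.10; the
  symmetric rule yields CAFs. Region bounding boxes become detections.

The method has no native confidence, so the mean positive-marker intensity
(capped at 1 after scaling by `score_norm`) is attached as a heuristic
score — this makes precision–recall curves computable for any detector
through one code path. Known ceiling, by design: heavily clumped cells may
segment as one region; the tests assert `detections <= true count` there,
not equality.

## Whole-slide detection

Detection operates on 1000×1000 px tiles (512 px in scaled tests). Boxes
touching a tile border are discarded — only completely visible cells count —
so cells straddling the base grid's seams would be lost. The mosaic is
therefore re-tiled under three additional grids shifted by half a tile
horizontally, vertically, and diagonally (the diagonal grid covers the
corner case where a cell straddles both seams; it is a toggle). Any object
smaller than half a tile is then fully visible in at least one window, a
fact the tests check exhaustively on a position grid. Detections from an
ensemble of k detectors are fused per tile by greedy same-label IoU
clustering: fused box = score-weighted mean of member boxes, fused score =
(sum of member scores)/k, so missing votes count as zero. Pooled detections
across coverages are deduplicated greedily by *overlap ratio* — intersection
over the smaller box's area, the measure that treats a small box inside a
big one as a duplicate; IoU is available as an option — and finally
thresholded by score.

## Evaluation

Predictions are matched to ground truth greedily by descending score, each
prediction taking the unmatched same-label box of highest IoU ≥ 0.5 (a
center-in-box criterion is available for dot-derived truth). The PR curve
sweeps every distinct score; its AUC is the trapezoid integral of precision
over recall, opened at recall 0 with the top point's precision. Error bars
come from 1000 bootstrap replicates: patch-level testing resamples patches
with replacement and pools confusion counts; WSI-level testing (one slide)
instead draws axis-aligned crops covering 90% of the slide area (side
factor √0.9), assigning boxes to a crop by center inclusion — whether the
original crops were axis-aligned is unstated; this is the simplest faithful
reading. Two detectors are compared with the pooled two-proportion z-test,
two-tailed, with the conventional star thresholds (\*p<0.05 to
\*\*\*\*p<0.0001).

## Numerical choices and degenerate inputs

* Argmax ties (focus curves, AIF slice choice) break toward lower z;
  dedup ties break by score, then lower y, then lower x, then input order —
  everything downstream of a sort is deterministic.
* `amplitude_um = 0` gives an exactly flat membrane; empty scenes render
  pure background; empty masks segment to zero regions; empty prediction
  sets have precision 1 by convention and recall undefined only when ground
  truth is empty too.
* All generators are pure functions of (parameters, seed) and save/restore
  the global RNG state.
* Boxes are half-open `[x_min, x_max) × [y_min, y_max)` in 0-based pixel
  coordinates; row = y. Stage microns run +x right, +y down; z toward the
  objective.

## Worked example

```{r example, eval = FALSE}
optics <- optics_model()                      # NA 0.4, 0.23 um/px
surface <- generate_surface(c(383, 383), amplitude_um = 15, seed = 1)
scene <- populate_scene(surface, n_mctc = 50, n_caf = 20,
                        n_pore = 60, n_precip = 30, seed = 2,
                        min_dist_um = 18, margin_um = 8)
scan <- scan_slide(scene, optics, grid = c(3, 3),
                   tile_shape_px = c(640, 640), tile_overlap_px = 128,
                   seed = 3)
mosaic <- preprocess_scan(scan, patch_size_px = 160, patch_overlap_px = 24)
det <- detect_wsi(mosaic, list(cv_detector_handle()), tiling_scheme(512),
                  score_thresh = 0.2)
gt <- scene_boxes(scene, optics, shape_px = dim(mosaic$data)[1:2])
evaluate_detections(det[det$label == "mCTC", ], gt[gt$label == "mCTC", ],
                    mode = "wsi", slide_shape = dim(mosaic$data)[1:2],
                    n_boot = 1000, seed = 7)
```

The same chain, at these problem sizes, is what `scripts/acceptance.R` and
the acceptance tests execute; the tests assert the properties described
above (autofocus within ±2.5 µm on ≥90% of fields, median registration
error below 0.25 px, stitched mosaic within 0.01 mean absolute intensity of
the directly rendered wide field, perfect precision/recall of the rule
detector on clean well-separated scenes with zero pore false positives, and
≥90% end-to-end mCTC recall).

## Limitations

The simulator's clean-scene conditions are favorable to the rule-based
detector; its known failure modes (clumps, precipitate-adjacent cells) are
represented but not adversarially weighted. The stitcher does not globally
optimize offsets, so very long chains accumulate drift linearly.
The detector interface (`detector_handle`) is where a learned model would
plug in; training one is outside this package's scope.
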