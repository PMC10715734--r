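---
title: "Quantifying B-cell synapse dynamics from TIRF/IRM time-lapse movies"
author: "SynapseQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying B-cell synapse dynamics from TIRF/IRM time-lapse movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseQuant)
```

## The measurement problem

When a B cell meets antigen presented on a planar lipid bilayer (PLB), it
spreads over the bilayer, gathers B-cell receptor (BCR)-antigen complexes
into microclusters, and then — in most wild-type cells — contracts its
contact footprint. Contraction compacts the clusters, raising their
molecular density, and this density increase is associated with the
shedding of both stimulatory kinases (Syk) and inhibitory phosphatases
(SHIP-1) from the clusters, attenuating BCR signaling. The raw data behind
these statements are multi-channel time-lapse movies: an interference
reflection microscopy (IRM) channel in which the membrane-bilayer contact
appears dark, plus total internal reflection fluorescence (TIRF) channels
for an F-actin reporter, a fluorescent Fab' surrogate antigen, and an
immunostained signaling molecule.

SynapseQuant turns such movies into the quantities this assay family
reports:

1. **Contact zone and contraction** — per-frame footprint area from IRM,
   and a contracting/non-contracting call per cell.
2. **Inner F-actin foci** — bright interior actin patches detected by
   three criteria (size, fold intensity, distance from the edge), counted
   per cell and scored for ring-like arrangement.
3. **Kymograph track analytics** — radial space-time maps from which foci
   lifetimes, centripetal speeds and lamellipodial origin are measured.
4. **Antigen clusters** — graded-threshold detection and tracking of
   Fab' microclusters, with per-cluster peak-intensity growth rates.
5. **Density-versus-signaling** — per-cluster ratios of signaling-channel
   to antigen-channel intensity as a function of cluster density.
6. **Statistics** — Mann-Whitney U, paired t, Kolmogorov-Smirnov, and
   Benjamini-Hochberg/Yekutieli false-discovery-rate control.

Because raw microscope data for this assay are rarely shared, the package
also contains a synthetic movie generator (`renderMovie()`) that emulates
the assay's phenomenology with exact ground truth, so every stage can be
validated quantitatively without a microscope.

## Units, conventions and the data model

All physical quantities derive from exactly two calibration constants
(`Calibration`): the pixel size in nanometres and the frame interval in
seconds. Areas are reported in µm², distances in µm, times in s and speeds
in µm/s. Rasters are H×W×T arrays indexed (row, column, frame), 1-based;
centroids are reported in µm with the origin at the centre of the top-left
pixel, x along columns and y down the rows. All connected-component
operations use 8-connectivity, so diagonally touching pixels of a
diffraction-limited spot are never split into two objects.

A `CellMovie` holds the aligned per-channel `ChannelStack`s of one cell
(one cell per movie; multi-cell field segmentation is out of scope).
Movies round-trip through directories of 16-bit multi-page TIFFs with a
YAML sidecar (`writeMovie()` / `readMovie()`).

## Contact-zone segmentation and the contraction call

IRM shows membrane-bilayer proximity as darkness, so the footprint is
segmented per frame by Gaussian smoothing (σ = 1 px), a global Otsu
threshold, hole filling and retention of the largest 8-connected dark
component. Global parameter-free thresholding was chosen over local or
learned alternatives because the IRM footprint is a high-contrast dark
object on a bright field; a frame whose dark class is not genuinely dark
(class-mean ratio above 0.7) is flagged as "cell not landed" and yields an
empty mask. On noise-free two-level disks the segmentation error is
confined to the one-pixel boundary band.

The area trace is smoothed with a 5-frame (10 s at 2 s/frame) centred
moving average before classification; without smoothing, single-frame
noise dips could satisfy the drop rule on noisy data. A cell is classified
as **contracting** when its smoothed area stays at or below 95% of its
maximum for at least 10 s (a run of frames whose length × frame interval
reaches the threshold), after the maximum is reached. The reference
maximum is the *global* maximum of the smoothed trace (first attainment);
a running-maximum variant is available via
`classifyContraction(reference = "running")`, but the global maximum is
the default because these cells show a single spread-then-contract peak.
The contraction *onset* is defined as the time of maximal spreading — the
spreading-to-contraction transition — and the contraction *window* ends at
the first frame where the smoothed area stops declining. Cells whose
post-maximum observation is shorter than the required duration are
classified non-contracting and flagged "insufficient observation".

Recruitment kinetics (e.g. of non-muscle myosin II) are summarized as the
ordinary-least-squares slope of the in-zone mean fluorescence intensity
(MFI) over the first 30 s after landing (`initialRate()`), and antigen
accumulation as separate OLS slopes before and during contraction
(`phaseRates()`).

## Inner F-actin foci

An inner focus must satisfy three criteria: diameter ≥ 250 nm, peak
intensity ≥ 2-fold of a foci-free reference, and location ≥ 1 µm interior
to the contact-zone edge. Diameter is the lesser of the bounding-box
height and width — conservative for elongated regions. Three details are
deliberate design choices, since the criteria alone do not fix an
algorithm:

* **The foci-free reference** is the median of interior pixels (≥ 1 µm
  from the edge, which excludes the bright lamellipodial rim) after
  discarding pixels above 1.5× the interior median. This robust exclusion
  means candidate foci do not inflate their own reference.
* **Edge distance** is the Euclidean distance-transform value of the
  contact mask sampled at the focus centroid pixel.
* **Compactness**: the rounded centroid pixel must belong to the
  component. A compact spot always satisfies this; arcs of the
  lamellipodial rim — whose every pixel hugs the edge but whose centroid
  falls in the actin-poor centre — never do. Without this rule,
  noise-fragmented rim arcs at low SNR pass the centroid-based edge test.

`detectInnerFoci(preSmoothSigmaPx = ...)` optionally smooths the frame
before detection; the default is off so the detector's arithmetic is
exactly the stated criteria.

Ring-like arrangement, judged by eye in the original workflow, is
automated as a declared surrogate: foci angular positions about the mask
centroid are binned into 30° sectors, and `is_ring` requires ≥ 4 foci
covering ≥ 50% of sectors. All three thresholds are parameters and should
be reported with results. Per-image percentages of ring-positive cells are
summarized as mean ± SEM across images (`percentPositivePerImage()`).

## Kymograph analytics

`makeKymographs()` samples `nLines` radial lines (8 by convention for
origin scoring, 3 for lifetime/speed work) from the contact centroid at
maximal spreading, each extending to the movie-wide maximum mask radius
plus 1 µm. Each spatial sample averages bilinear interpolations over a
3-pixel perpendicular stencil.

Track extraction (`extractTracks()`) automates what was manual tracing:
per column (frame), spatial local maxima at ≥ 2-fold of a column-local
reference become detections; detections in consecutive frames are linked
greedily by nearest radial position with jumps ≤ 0.4 µm and no gap
closing; tracks shorter than 4 s are dropped. Numerical details that
matter:

* The column reference is the column median excluding the outermost 1 µm
  of the line, with the same robust bright-pixel exclusion as the foci
  reference — otherwise dense foci plus the rim can cover half the line
  and inflate the median above the background.
* Columns are lightly smoothed (3-bin moving average) and detections
  closer than 0.5 µm are reduced to the brightest (non-maximum
  suppression), so a broad rim plateau yields one detection rather than a
  comb of noise maxima.
* Maxima are refined to sub-bin accuracy by a three-point parabolic fit,
  which removes most of the bin-quantization error in speeds.
* Optionally (and by default in `runPipeline()`), detections within
  1.3 µm of the contemporaneous contact edge are excluded: the rim *is*
  lamellipodial F-actin, not an inner focus, and its plateau otherwise
  spawns spurious tracks. `classifyOrigin(rimOffsetUm = ...)` widens the
  lamellipodial band test by the same amount so that foci first seen just
  inside the excluded zone still count as lamellipodia-born.

**Lifetime convention.** A track detected in frames *f..g* has lifetime
(*g − f + 1*) × frame interval, so a 10-frame track at 2 s/frame lives
20 s and the ≥ 4 s filter means ≥ 2 frames. Speed is net radial
displacement divided by lifetime. Both are *relative* (apparent)
quantities: a focus can leave the sampled line or the TIRF field, so
disappearance does not imply the physical object vanished. One systematic
consequence: displacement accrues over *g − f* intervals while lifetime
counts *g − f + 1*, so measured speed underestimates the true speed by the
factor (n−1)/n for an n-frame track — about 5% at 20 frames. This is
inherent to the distance/lifetime convention, not a bug, and applies
equally to manual tracing.

A track is **lamellipodia-derived** when it is born within 1 µm of the
contemporaneous edge radius, moves inward by more than 0.25 µm, and lasts
longer than 8 s. Per cell, the fraction of kymographs containing at least
one such track is the "lamellipodial fraction"; foci emergence times
relative to contraction onset are histogrammed as percentages of all
events.

## Antigen-cluster detection and tracking

Cluster brightness spans a wide range, so a single threshold either merges
dim clusters into the background or splits bright ones. The graded
strategy uses 16 thresholds, 1.1 to 4.1 fold of background in 0.2 steps.
Background is the median intensity of an outside band grown from the
contact mask ring by ring until it matches the mask's pixel count — the
median, not the mean, so bilayer debris cannot inflate it; it is
re-estimated per frame because bilayer intensity can drift. Folds are
visited from highest to lowest; a component is accepted if its diameter is
≥ 250 nm and it shares no pixel with a previously accepted detection
("same location" is read strictly as pixel overlap, which matches the
nesting of superlevel sets). Each cluster is thus retained at the highest
threshold that still detects it, and accepted pixel sets are disjoint by
construction. The production implementation short-circuits with a claimed-
pixel mask; the test suite proves it equal to the brute-force
materialize-all-16-masks oracle.

Tracking is greedy mutual-nearest-neighbour linking of centroids between
consecutive frames with links ≤ 0.5 µm and no gap closing. When two or
more tracks converge on one detection, the incoming tracks end with
`end_reason = "merged"` and a fresh track starts: the merged object is a
new identity, since nothing ties it to either parent. Tracks shorter than
20 s (boundary inclusive: 10 frames at 2 s) are eliminated — this
trackability filter is also what removes transient noise detections, which
is why `runPipeline()` computes signaling ratios only over detections
belonging to surviving tracks.

Per-cluster density growth is the OLS slope of peak FI versus time
(`peakFiRate()`); peak FI is used as the density proxy precisely because
it does not depend on the area a cluster occupies. The fitting window is
always explicit — there is no silent default — and `perCellRateSummary()`
averages per-track slopes within named phase windows (before/during/after
contraction, from `contractionWindow()`).

## Density-versus-signaling analysis

For every tracked antigen detection, the signaling-channel MFI is measured
over the detection's exact pixel set (not a fixed-size aperture — the
criteria define the cluster, so the cluster defines the aperture) and
divided by the antigen MFI of the same pixels. Signaling puncta
(`detectPuncta()`) are detected independently at channel-specific folds —
1.3 for pSyk-type, 1.5 for pSHIP-1-type stains — and read the antigen
channel at their own pixels. Records are balanced across stimulation-time
groups by drawing the minimum group size from each (`equalRandomSample()`,
seeded and deterministic), binned by antigen peak FI into half-open
20-FI-unit bins (`binCurve()`: per-bin mean ratio, count, fraction of
total), and split into low/medium/high density populations at printed
cutoffs — (190, 280) for pCD79a/Syk/pSyk analyses, (200, 300) for
SHIP-1/pSHIP-1 — with the medium population closed on both ends.
Populations are compared pairwise by two-sided Mann-Whitney tests with
BH (default) or BY correction. The cutoffs are camera-unit-specific and
must be recalibrated for data acquired on other setups; the generator's
cluster intensity parameters are dimensioned so planted peaks straddle
them.

## The synthetic movie generator

`renderMovie()` produces the four channels with exact ground truth
(`GroundTruth`): the area trace, the contraction onset, every focus track
(birth, death, angle, radius, speed, clipping flag) and every cluster's
per-frame position, true peak FI and true signal/antigen ratio.

* **Footprint**: a disk whose area rises logistically, reaching 99.5% of
  π·r_max² at `tMaxSpreadS`, then (for contracting cells) declines
  linearly by `contractionFraction` over `contractionRampS` and stays
  flat. Contraction is isotropic about the centre.
* **Actin**: uniform background, a rim band of `rimAmp`-fold intensity at
  the footprint edge (the lamellipodium), and foci as 2D Gaussians born on
  the rim circle (radius R − rimWidth/2, uniform angle) at a Poisson rate
  after maximal spreading, moving centripetally at constant speed with
  exponential lifetimes. Birth geometry is a simulator choice; the assay
  only constrains foci to originate at lamellipodia. `fociOverride` plants
  foci deterministically for validation.
* **Antigen**: `nClusters` Gaussians at fixed fractions of the current
  radius (so they ride inward with contraction), whose true peak FI ramps
  linearly, `clusterRampBoost`-fold faster inside the contraction window.
* **Signal**: within a 2.5σ disk around each cluster, the noise-free
  antigen channel scaled by `ratioProfile`(true peak FI); elsewhere scaled
  by the profile's base level. This multiplicative construction makes each
  cluster's true signal/antigen MFI ratio equal the profile exactly, so
  ratio recovery has an exact target. The profile itself is biphasic:
  linear rise to a peak at `dRise`, then a linear decline with a floor —
  the shape reported for per-cluster phosphorylation versus density.
* **Noise** is i.i.d. additive Gaussian per pixel (clamped at zero).
  Downstream criteria are folds of background, so the noise family is
  immaterial; Gaussian keeps signal-to-noise bookkeeping simple. We quote
  SNR as (object amplitude above background) / noise σ.
* **Determinism**: all randomness flows through the single `seed`;
  identical `SimParams` give bit-identical movies and ground truth.

Defaults describe a typical contracting splenic B cell at the assay's
acquisition settings: 107.5 nm pixels (60× objective with a 6.45 µm-pixel
CCD), 2 s frames for 7 min, landing radius 1.5 µm spreading to 4 µm by
60 s (≈ 50 µm² contact), 15% area loss over 60 s, a 1 µm rim at 2.5×
background, foci born at 20/min (≈ 7 alive at the 20 s mean lifetime,
matching per-cell counts in contracting cells) at 0.05 µm/s and 3×
background, PSF σ 0.15 µm, 12 clusters starting near 1.3× background and
ramping 0.5 FI/s (3× during contraction), background 100 FI, noise σ 10.

**What the generator does not emulate** — and what passing tests therefore
do not certify on real data: photobleaching, camera gain/offset and
Poisson shot noise, sub-diffraction structure within foci and clusters,
non-circular and re-spreading footprints, cell-to-cell parameter
variability beyond explicit sweeps, and stage drift. The generator
specifies the *study conditions*; conclusions about real microscopes
require real calibration.

## Validation and problem sizes

The test suite validates each stage against an independent oracle or
planted ground truth: the contraction classifier against brute-force run
enumeration on 500 synthetic traces; the graded detector against the
16-mask oracle on 50 random frames; the foci detector against a per-pixel
enumeration oracle, with 100% noise-free separation of criteria-meeting
foci from single-criterion violators and recall/precision ≥ 0.9 over 200
planted foci at SNR 5; kymograph speed recovery within 15% at planted
speeds 0.02/0.05/0.10 µm/s and lifetime recovery within one frame
noise-free; peak-FI slopes exact noise-free, within 3 analytic SE at noise
σ = 2, and the contraction ramp boost recovered within 25% across 20
simulated cells; the binned ratio curve declining with Spearman ρ < −0.8
over the planted decline range, with the proportional-channels identity
exact; the Mann-Whitney exact branch equal to full enumeration (200
cases), BH/BY equal to the direct formulas, and null rejection within
[0.03, 0.07] at α = 0.05 over 1000 replicates; and byte-identical pipeline
reruns with ≥ 18/20 correct contraction calls at SNR 5. Validation movies
use 120×120-pixel grids at 100 nm/px with 40-90 frames — the same
geometry as the defaults at a smaller field and duration, chosen so the
full suite runs in minutes on one CPU; `scripts/acceptance.R` recomputes
the headline numbers from scratch at any seed.

## Known limitations

* Segmentation assumes one high-contrast dark footprint per frame;
  dim or multi-cell fields need upstream cropping.
* Kymograph tracking is an automation surrogate for manual tracing;
  crossing foci can swap identities, and the rim-exclusion zone delays
  track birth by (exclusion − rimWidth/2)/speed seconds, truncating
  apparent lifetimes — consistent with the "relative lifetime" reading,
  but a bias to keep in mind.
* The ring-likeness call is a declared surrogate for visual inspection.
* Merge handling creates a new identity at each merger; lineage through
  merges is not reconstructed.
* Intensity-based cutoffs (190/280, 200/300, FI bins) are camera-specific.
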