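# SynapseQuant

Quantitative image analysis for B cells interacting with antigen-coated
planar lipid bilayers, from multi-channel TIRF + IRM time-lapse movies.

When a B cell engages membrane-presented antigen it spreads, gathers
B-cell receptor (BCR)–antigen microclusters, and then contracts its
contact footprint; contraction compacts the clusters, raising their
molecular density, which is associated with loss of both stimulatory
(Syk) and inhibitory (SHIP-1) signaling molecules from the clusters and
with signal attenuation. SynapseQuant implements the measurements this
assay family reports, for imaging labs analyzing such movies:

* **Contact zone & contraction** — IRM segmentation (smooth → Otsu →
  fill → largest 8-connected component), per-frame area *A(t)* in µm²,
  and a contraction call: contracting ⇔ the smoothed area stays ≤
  (1 − 0.05)·max *A* for ≥ 10 s after the maximum.
* **Inner F-actin foci** — components with diameter ≥ 250 nm, peak FI ≥
  2× a foci-free reference, centroid ≥ 1 µm interior to the edge;
  per-cell counts and a ring-likeness score.
* **Kymograph analytics** — radial space×time maps; track lifetime
  (inclusive span), centripetal speed = displacement/lifetime, and
  lamellipodial-origin classification.
* **Antigen clusters** — 16 graded thresholds (1.1–4.1× background, 0.2
  apart; each cluster retained at its highest passing fold),
  mutual-nearest-neighbour tracking to merge or loss, a ≥ 20 s
  trackability filter, and per-cluster peak-FI growth slopes by
  contraction phase.
* **Density vs signaling** — per-cluster ratio = signal MFI / antigen
  MFI against antigen peak FI: 20-FI-unit binned curves, balanced
  sampling across time points, and low/medium/high population
  comparisons (Mann-Whitney U, BH/BY FDR control).
* **Synthetic movies** — `renderMovie()` generates all four channels
  with exact ground truth (areas, focus tracks, cluster ramps, true
  signal/antigen ratios), so every stage is testable without microscope
  data.

See the methods vignette (`vignettes/synapse-quantification.Rmd`) for the
models, parameter rationale and numerical conventions.

## Worked example

Simulate one contracting cell (2 s frames, 100 nm pixels, 15% area loss
after 60 s of spreading) and run the full pipeline:

```r
library(SynapseQuant)

p   <- simParams(grid = c(120L, 120L, 90L),
                 calibration = Calibration(100, 2),
                 rMaxUm = 3.5, rInitialUm = 1.2, seed = 7L)
sim <- renderMovie(p)
res <- runPipeline(sim$movie)

res$call
#> ContractionCall: contracting, onset 60 s (max 38.4 um^2 at 60 s)

res$summary
#>  cell_id contracting t_max_spread_s onset_s max_area_um2 foci_frame n_foci
#>     sim7        TRUE             60      60       38.392         61      1
#>  is_ring lamellipodial_pct mean_lifetime_s mean_speed_um_s n_cluster_tracks
#>    FALSE                25               7      0.03557502               15
#>  rate_before rate_during rate_after n_ratio_records
#>    0.5593625    1.249482   0.482139             776
```

The cell is called contracting with onset at 60 s — the time of maximal
spreading, where the simulated footprint (peak area 38.4 µm², i.e. a
3.5 µm radius) starts its planted 15% decline. Antigen-cluster peak FI
grows at 0.56 FI/s before contraction and 1.25 FI/s during it — the
planted 3× ramp boost, attenuated by phase-window edges. The binned
density-versus-signaling curve falls once cluster peak FI passes the
planted profile maximum at 150 FI:

```r
head(res$bin_curve[res$bin_curve$n > 0,
                   c("bin_center", "mean_ratio", "n", "fraction")], 8)
#>   bin_center mean_ratio   n   fraction
#> 1        110  0.1877329   1 0.00128866
#> 2        130  0.2489876  10 0.01288660
#> 3        150  0.9348526  85 0.10953608
#> 4        170  0.9095662 128 0.16494845
#> 5        190  0.8278696  72 0.09278351
#> 6        210  0.7486024  76 0.09793814
#> 7        230  0.6580292  87 0.11211340
#> 8        250  0.5676688 142 0.18298969
```

`writeSimulation(p, dir)` / `readMovie(dir)` exchange movies as 16-bit
multi-page TIFFs (one per channel) with a YAML calibration sidecar, and
`runPipeline(..., outDir = ...)` writes every stage table as CSV.

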