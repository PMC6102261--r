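# smlmpipe

An R package for analysing two-colour single-molecule localisation
microscopy (SMLM) of adhesive ligands and adhesion proteins — the kind of
experiment in which RGD peptides on a functionalised surface are imaged
by dSTORM and an adhesion protein such as paxillin by PALM in the same
field of view, and the question is how ligand density and ligand
clustering relate to where cells build adhesive structures.

The package covers the full chain:

* **Localisation** — event detection on camera stacks (Gaussian filter,
  threshold `I − M > kS` with `k = 6`), integrated 2-D Gaussian PSF
  fitting with joint multi-emitter handling, Mortensen localisation
  precision
  `σ_loc² = (σ_a²/N)(16/9 + 8πσ_a²b²/(Na²))`, `σ_a² = σ² + a²/12`,
  blink grouping (100 nm radius, ≤ 5 on-frames, ≤ 50 gap-frames), and
  fiducial-based piecewise-linear drift correction.
* **Spatial statistics** — Ripley `K(r)` / `L(r) − r` with toroidal and
  isotropic edge corrections, densities in windows and polygons, and the
  CSR density-to-spacing conversion `E[d] = 1/(2√λ)`.
* **Clustering** — DBSCAN (`r = 20 nm`, `ε = 3`) with per-cluster
  molecule counts, convex-hull areas and densities.
* **Colocalisation** — per-molecule degree-of-colocalisation (DoC)
  scores: Spearman correlation of the two channels' local density
  gradients over radii 10–500 nm, attenuated by the cross-channel
  nearest-neighbour distance, `DoC = ρ_s·exp(−d/R_max)`; colocalised
  fraction at the DoC ≥ 0.4 threshold.
* **ROI analysis** — densities inside/outside adhesion polygons, surface
  vs under-cell ligand densities, and classification against the
  reported tethering (> 0.8 µm⁻²) and spreading (4–7 µm⁻²) thresholds.
* **Synthetic data** — CSR and Thomas-cluster fields, two-colour scenes
  (colocalised / independent / segregated), cell-with-adhesions scenes,
  and full blinking camera movies (geometric blink/on/off statistics,
  integrated-Gaussian PSF, Poisson noise, fiducials, drift) with ground
  truth, so every stage is testable without experimental data.

File formats: localisation tables as CSV (`frame, x_nm, y_nm, photons,
bkg, sigma_nm, precision_nm, channel, group_id` — a ThunderSTORM-style
dialect, units fixed to nm), ROIs as JSON polygon sets, stacks as
multi-page 16-bit TIFF, configuration as YAML with every published
default preloaded (`smlm_config()`).

## Worked example

```r
library(smlmpipe)

# a 5x5 um field of view with clustered ligands and a colocalised protein
w <- obs_window(0, 0, 5000, 5000)
scene <- simulate_two_color("colocalized", density = 100, jitter_sigma = 20,
                            window = w, seed = 11, base = "clustered")
scene$ch1
#> point pattern: 2444 points, channel 'ch1', 97.8 um^-2
#> window: [0, 5000] x [0, 5000] nm (25 um^2)

# Ripley analysis: the clustering length scale is where L(r) - r peaks
k <- ripley_k(scene$ch1)
k$r_nm[which.max(k$L_minus_r)]
#> [1] 120

# DBSCAN segmentation with r = 20 nm, eps = 3
labels <- dbscan_clusters(scene$ch1, eps = 20, min_neighbors = 3)
stats <- cluster_stats(scene$ch1, labels)
nrow(stats)
#> [1] 119
round(colMeans(stats[, c("n", "area_nm2", "density_per_um2")], na.rm = TRUE))
#>               n        area_nm2 density_per_um2
#>               6             472           24758

# degree of colocalisation between the two channels
res <- doc_scores(scene$ch1, scene$ch2)
doc_summary(res, threshold = 0.4)
#>     channel n_scored mean_rho_s  mean_doc fraction_colocalized
#> ch1     ch1     1799  0.8774629 0.8534895            0.9961089
#> ch2     ch2     1790  0.8737119 0.8480094            0.9977654

# density -> mean CSR spacing
mean_nn_spacing_from_density(0.01, "um")   # 5 (um)
mean_nn_spacing_from_density(600)          # 20.41241 (nm)
```

The simulated ligand field clusters at the ~120 nm scale (`L(r) − r`
peak), its DBSCAN clusters average 6 molecules over ~470 nm², and — as
built into the scene — almost every molecule is colocalised with the
second channel (mean DoC ≈ 0.85 at the 0.4 threshold).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/smlmpipe.R`:

```sh
Rscript inst/scripts/smlmpipe.R spacing --density 0.01     # prints "5 um"
Rscript inst/scripts/smlmpipe.R simulate csr --density 100 --seed 7 --out locs.csv
Rscript inst/scripts/smlmpipe.R cluster --in locs.csv --out clusters.csv
```

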