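# microgliaQuant

Quantification pipelines for ex-vivo microglial fluorescence imaging, plus a
synthetic time-lapse generator with exact ground truth for validating every
stage.

Microglia survey the brain parenchyma with continuously moving processes and
chemotax toward injury cues (ATP, amyloid-beta). Studies of these behaviours
— for example comparisons across *APOE* genotypes in Alzheimer's-relevant
brain regions — quantify them with a small, standard battery of image
measurements that are usually performed by hand in ImageJ. This package
implements that battery as tested, scriptable R code:

| Stage | Measurement |
|---|---|
| surveillance | motility index of a binarized time-lapse: per frame pair, (extending px + retracting px) / stable px, averaged over the lapse |
| chemotaxis | process velocity toward a pipette: total path length / elapsed time (µm/min), truncated at arrival (capture radius, default 2 µm) |
| morphology | cells per calibrated field (and per mm³), skeleton endpoints and total branch length per cell (1 px orthogonal / √2 px diagonal steps) |
| engulfment | percent coverage of an amyloid-beta deposit: 100 · \|microglia ∩ deposit\| / \|deposit\| per time point |
| molecular | soma/process intensity partition (percent in processes); double-delta-Ct qPCR fold change, 2^(−ΔΔCt), reference group ≡ 1 |
| statistics | two-tailed t-test, one-/two-way ANOVA, Sidak/Tukey post-hoc, mean ± SEM |

Supporting machinery: calibrated TIFF stack I/O (JSON sidecar for pixel size
and frame interval), z-max projection, ROI masking, and translation
stabilization by FFT phase correlation with subpixel refinement.

The synthetic generator (`simulate_baseline_timelapse`,
`simulate_chemotaxis`, `simulate_abeta_engulfment`, `simulate_field`,
`simulate_intensity_image`) renders calibrated stacks at the acquisition
geometry of the modelled experiments (e.g. 1024 × 1024 px at 0.277 µm/px
every 20 s) and records exact ground truth — per-pair pixel change counts,
continuous tip tracks, coverage schedules, planted skeletons, programmed
intensity splits — so the analysis side can be validated pixel-for-pixel.

## Worked example

Simulate a 5-min surveillance lapse with 24 % pixel turnover per frame pair,
run the full motility pipeline (register → binarize → classify → average),
and compare with a chemotaxis run:

```r
library(microgliaQuant)

cfg <- sim_config(image_shape = c(256, 256), pixel_size = 284/1024,
                  frame_interval = 20, n_frames = 16, seed = 42)
sim <- simulate_baseline_timelapse(cfg, turnover_rate = 0.24)
timelapse_motility(sim$stack)
#> MotilityResult: mean index 0.2727 over 15 pairs (0 excluded)
```

A mean index of 0.27 means that per 20-s frame pair the cell remodels about
27 % of its stable footprint — the surveillance regime of healthy microglia.

```r
cfg_v <- sim_config(image_shape = c(256, 256), pixel_size = 0.277,
                    frame_interval = 20, n_frames = 25, seed = 42,
                    noise_sigma = 0)
sim_v <- simulate_chemotaxis(cfg_v, tip_velocity = 1.5, n_processes = 3)
tracks <- auto_track_tips(sim_v$stack, sim_v$truth$pipette_xy, n_tips = 3)
v <- sapply(tracks, function(tr)
  track_velocity(tr, cfg_v$pixel_size, cfg_v$frame_interval)$velocity_um_min)
round(v, 3)
#> [1] 1.498 1.511 1.507
aggregate_cell(v)$per_cell_velocity
#> [1] 1.505395
```

The tracker recovers the programmed 1.5 µm/min approach speed to within
1 %. Morphometry on a planted field:

```r
cfg_f <- sim_config(image_shape = c(1024, 1024), pixel_size = 284/1024,
                    n_frames = 1, seed = 42)
sim_f <- simulate_field(cfg_f, n_cells = 12)
count_cells(sim_f$stack)
#> FieldCount: 12 cells in 1613000 um^3 (7439 cells/mm^3)
head(field_morphology(sim_f$stack)$cells[, c("cell_id", "endpoints",
                                             "branch_length_um")], 3)
#>   cell_id endpoints branch_length_um
#> 1       1         5        102.59468
#> 2       2         4         88.62415
#> 3       3         6        121.41463
```

All 12 planted cells are found; the endpoint counts equal the planted branch
tips and the lengths match the planted chains to within a few percent
(rasterization error).

`run_pipeline()` orchestrates multi-condition studies from a YAML config
(datasets × replicates × stages, group comparisons, tidy CSV/JSON output,
provenance log), and `inst/cli/microgliaquant.R` exposes the same functions
as shell subcommands (`simulate`, `motility`, `velocity`, `coverage`,
`intensity`, `qpcr`, `run`).

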