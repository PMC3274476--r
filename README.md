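# spimpipe

Image computation for live light-sheet (SPIM) imaging of multicellular
tumor spheroids with chromatin-labelled nuclei.

Large spheroids are the standard 3D model of avascular tumor
micro-regions: proliferating cells in the outer layers, quiescent cells in
the core. Light-sheet microscopy can follow individual divisions deep
inside a living spheroid at a 3-minute cadence, but the raw stacks carry
artifacts that defeat naive analysis — sample-dependent stripes parallel
to the light sheet, progressive signal loss along the illumination axis,
and slow sample drift between time points. `spimpipe` provides the
computational chain from raw stacks to biology, for microscopists and
image analysts working with such data (or building methods against it):

* **Stripe removal as MAP estimation.** Stripes are modelled as stationary
  noise — white noise `λ` convolved with an elementary stripe-like pattern
  `ψ` — and removed by solving the TV-regularized problem

  ```
  λ̂ = argmin_λ  TV(u0 − λ ⊛ ψ) + α‖λ‖₁ ,   û = u0 − λ̂ ⊛ ψ
  ```

  with a Chambolle–Pock primal–dual solver (C++ core, deterministic,
  exact additive decomposition `û + b̂ = u0`).
* **Opposing-view fusion**: 0°/180° registration (flip + subvoxel phase
  correlation) and attenuation-aware weighted fusion.
* **Drift compensation** for time-lapse stacks by 3D phase correlation.
* **3D nucleus detection** (multiscale Laplacian-of-Gaussian), seeded
  watershed measurement, and mitotic/interphase classification by
  intensity-over-background and condensed-chromosome shape.
* **Spheroid geometry**: sphere fit to the outer detection hull; every
  mitosis is located by its depth from the spheroid surface and z.
* **Division tracking**: mitotic-event delimitation, duration in minutes,
  metaphase-plate alignment, and arrest scoring with the 60-minute horizon
  used to call drug-induced (paclitaxel) mitotic block.
* **A synthetic SPIM-spheroid generator** with exact ground truth (nucleus
  positions and classes, injected stripes, drift, division timings), so
  every stage is testable without any real data.

## Worked example

Simulate a small spheroid with stripes, remove them, detect and classify
nuclei, and locate mitoses relative to the surface:

```r
library(spimpipe)

scene <- scene_preset("tiny", seed = 3)     # 18-um spheroid, 30 nuclei
sim   <- simulate_scene(scene)              # truth + clean + corrupted

res <- destripe_volume(sim$corrupted)
psnr(unclass(res$clean), unclass(sim$clean)) -
  psnr(unclass(sim$corrupted), unclass(sim$clean))
#> [1] 7.870304

det <- detect_nuclei(res$clean)
det <- segment_and_measure(res$clean, det)
det <- classify_mitotic(det)
table(det$klass)
#>
#> interphase    mitotic
#>         27          3

fit <- fit_spheroid(det)
fit
#> <spheroid_fit> center (24.6, 24.5, 25.2) um, radius 18.68 um, RMS residual 0.77 um (21 surface points)

det <- depth_from_surface(det, fit)
round(det$depth_from_surface_um[det$klass == "mitotic"], 1)
#> [1]  2.0 10.8  5.8
```

The destriped volume is 7.9 dB closer to the stripe-free truth than the
corrupted input; all 30 labelled nuclei are found and exactly the three
truly mitotic figures are classified mitotic; their depths fall within
the scene's 10-um proliferative rim (up to the fit tolerance), and the
fitted radius agrees with the generating 18 um.

Time-lapse dynamics run the same way via `render_timelapse()`,
`link_tracks()`, `extract_mitotic_events()` and `compare_conditions()`;
`run_pipeline()` drives everything from one YAML config and writes CSVs,
a JSON report and a run manifest. A thin CLI over these functions lives
in `inst/cli/spimpipe.R` (`simulate`, `destripe`, `fuse`, `driftcorrect`,
`detect`, `track`, `report`, `run`).

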