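# flimAdapt

A desk-scale virtual microscope for **adaptive fluorescence lifetime imaging
microscopy (FLIM)**. In photon-counting FLIM the SNR of a pixel grows as
√N of its detected photons, so a uniform-dwell raster scan of a
heterogeneous specimen — where emission rates span orders of magnitude, and
where the dim species are often the long-lifetime ones that carry the
contrast — overexposes bright regions while starving dim ones. `flimAdapt`
simulates the frame-based adaptive alternative end to end:

1. **Phantom** — seeded synthetic samples with anti-correlated
   intensity/lifetime species (bright/short-τ inside dim/long-τ on empty
   background), or any grayscale TIFF imported as a rate map.
2. **TCSPC simulator** — Poisson photon counts and time-resolved decay
   histograms under an arbitrary per-pixel dwell map (20 MHz excitation,
   100 ps bins over a 50 ns window, Gaussian IRF, incomplete-decay wrap,
   dark counts), with pre-scan photon timing merged into later scans.
3. **Exposure planner** — pixel classification against the dark-count floor
   and adaptive Otsu thresholds, then *intensity inversion*

   E(m,n) = clamp(T_baseline · I_target / P(m,n), t_min, t_max),

   quantized to the dwell step; non-ROI pixels get E = 0 and are skipped.
4. **Waveform synthesizer** — sample-hold X/Y galvo voltages with settling
   insertion ((f + βd)·E samples across gaps of Chebyshev distance d,
   β = 0.02f), 5-point smoothing, embedded dwell/line clocks, predicted
   frame time.
5. **Lifetime estimators** — centre-of-mass (CMM) with truncation
   correction (robust at ~250 photons) and Levenberg–Marquardt
   least-squares decay fitting (the >1000-photon gold standard), plus the
   peak ≥ 5× noise validity rule.
6. **Evaluation harness** — equal-time (signal enhancement) and equal-SNR
   (speedup) comparisons of adaptive vs uniform imaging.

Intended users: microscopy method developers and image-analysis researchers
who want a reproducible, instrument-free testbed for adaptive illumination
planning and low-light lifetime estimation.

## Worked example

```r
library(flimAdapt)

phantom <- twoSpeciesPhantom(c(96, 96), seed = 7)
phantom
#> SampleModel 96 x 96 pixels
#>   emitting pixels: 4144 (45.0%), rate 0.492-9.14 photons/us
#>   tau 0.8-2.5 ns
#>   dcr 100 counts/s, excitation scale 1

params  <- acqParams()                      # 20 MHz, 100 ps x 500 bins
prescan <- simulateAcquisition(phantom, matrix(100, 96, 96), params, seed = 8)
emap    <- planExposure(prescan, dcr = 100, tPrescan = 100, iTarget = 250,
                        tMin = 50, tMax = 600, step = 1)
emap
#> ExposureMap 96 x 96: 4149 ROI pixels (45.0%)
#>   dwell 50-600 us (caps 50/600, step 1), target 250 photons

adaptive <- simulateAcquisition(phantom, emap, params, seed = 9)
mean(photonCounts(adaptive)[uncappedMask(emap)])
#> [1] 252.8
```

The re-acquired mean over ROI pixels whose dwell was not clamped sits at
the 250-photon target (the ~1% overshoot is the expected Jensen effect of
inverting a Poisson count). The planned scan itself:

```r
wf <- smoothWaveform(synthesizeWaveform(emap), 5)
wf
#> ScanWaveform: 8611268 samples at 10 MS/s (0.8611 s), 4149 pixels visited

merged <- mergeAcquisitions(prescan, adaptive)   # pre-scan photons reused
life   <- lifetimeImage(merged, params, estimator = "cmm", noisePerBin = 0.78)
life
#> LifetimeImage 96 x 96: 45.0% valid
#>   tau 0.717-3.06 ns (median 2.46)
```

The dual-mode comparison at matched frame time (uniform raster vs pre-scan
+ adaptive with photon reuse), least-squares fit errors normalized per
photon:

```r
report <- runExperimentSuite(phantom, list(mode = "enhance",
                                           estimator = "ls",
                                           block = 16L, seed = 7))
report
#> ExperimentReport
#>                arm frameTime meanCounts varCounts skewness availability
#> 1          uniform    1.8379      546.9    377075    1.325       0.4308
#> 2 adaptive(merged)    1.8375      569.5    155290    1.301       0.4472
#> 3   adaptive(scan)    0.8978      289.4      7485    0.548       0.4472
#>    dimError brightError
#> 1 0.0009718   5.803e-05
#> 2 0.0005266   7.172e-05
#> 3 0.0005266   7.172e-05
#> deltas (%):
#>      enhancementPct          speedupPct availabilityGainPct
#>                4.13                0.02                3.80
```

Reading it: at equal frame time the intensity-inverted scan's count
histogram collapses from variance 377075 (skewness 1.33) to 7485 (0.55) —
the near-Gaussian distribution around the photon target — the dim-region
fit error roughly halves (0.00097 → 0.00053) while bright regions stay
comparable, and lifetime availability rises. In `mode = "fast"` the same
phantom gives a ~54% shorter scan at unchanged per-pixel SNR by skipping
the empty background.

A file-based pipeline (`cmdPhantom`, `cmdPrescan`, `cmdPlan`, `cmdAcquire`,
`cmdLifetime`, `cmdExperiment`) reads a YAML config and exchanges TIFF maps
with JSON sidecars; `inst/scripts/fli3m.R` is a shell entry point over it:

```sh
Rscript inst/scripts/fli3m.R all --config inst/extdata/demo_config.yaml \
    --outdir demo --seed 7
```

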