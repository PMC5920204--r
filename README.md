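# crDoppler

Complex-regression Doppler optical coherence tomography (OCT) in R.

Doppler OCT estimates velocity from the phase change of the complex OCT
signal between A-lines. The conventional estimator compares two adjacent
A-lines, so its dynamic range is pinched from both sides: the smallest
resolvable phase is the system's phase stability and the largest is π
(phase wrapping). With a 594-ns A-line interval, a 1315-nm center
wavelength, n = 1.38 and 0.096-rad phase stability that is an axial
velocity range of only 12.26–401.05 mm/s — while blood in a developing
embryonic heart spans from ~100 µm/s near the walls to hundreds of mm/s at
systolic peak.

This package implements a multipoint estimator that extends the range
downward without sacrificing the top. Densely sampled scans provide m
(typically 64) A-lines of the same location; the complex-regression
estimator searches for the per-interval phase θ that, after derotating the
k-th A-line by kθ,

```
s_k  ->  s_k · exp(-i k θ),      k = 0 … m-1,
```

minimizes the dispersion (complex standard deviation) of the realigned
points. The total phase shift is Δφ = (m-1)·θ and the axial velocity is

```
v = θ λ0 / (4 π n ΔT).
```

Because the search runs in polar coordinates, Δφ may exceed 2π without
wrapping — wrapping occurs only if the *per-interval* phase exceeds π, so
the upper velocity bound is untouched while the detection floor drops by a
factor (m-1): from 12.26 mm/s to ~195 µm/s for m = 64. Minimizing the
dispersion is exactly equivalent to maximizing the coherent-sum magnitude
|Σ s_k e^(-ikθ)|, which is how the implementation evaluates the 1-mrad
search grid in one matrix product; the estimator is amplitude-weighted, so
strong (reliable) samples dominate.

The package also provides:

- the conventional complex two-point (Kasai autocorrelation) estimator
  with N-average variants (`conventionalDoppler`, `kasaiPhase`);
- analytic dynamic-range and detection-floor calculators
  (`conventionalRange`, `detectionFloor`);
- a capillary-tube flow-phantom simulator with SNR-calibrated phase noise
  (`PhantomSpec`, `calibrateNoise`, `simulateMScan`);
- the evaluation protocol for minimum-detectable-velocity studies
  (`runSweep`, `empiricalMinimum`, `detectionMinimaStudy`, `plotSweep`);
- complex averaging for structural images (`complexAverage`), scan
  container I/O (`readMScan`/`writeMScan`) and a command-line interface
  (`dopplerCLI`, `inst/scripts/crdoppler`).

## Worked example

```r
library(crDoppler)
cfg <- DopplerConfig()
cfg
#> DopplerConfig
#>   wavelength: 1315.0 nm | n: 1.380 | A-line interval: 594.0 ns
#>   Doppler angle: 80.0 deg | phase stability: 0.096 rad
#>   conventional two-point range: 12.26 .. 401.1 mm/s

## analytic detection floors of the three estimators (um/s)
floors <- c(
  cnv5   = detectionFloor(EstimatorSpec("conventional_avg", 5), cfg),
  cnv63  = detectionFloor(EstimatorSpec("conventional_avg", 63), cfg),
  cmpreg = detectionFloor(EstimatorSpec("complex_regression", 64), cfg))
round(floors * 1e6)
#>   cnv5  cnv63 cmpreg
#>   5481   1544    195

## simulate a calibrated flow phantom and estimate the centerline velocity
cal  <- calibrateNoise(0.096, cfg, snr_db = 40)
spec <- applyCalibration(
  PhantomSpec(axial_velocity_mps = 20e-3, n_alines = 2000, n_depth = 64,
              depth_pitch_m = 8e-6, seed = 42), cal)
scan <- simulateMScan(spec, cfg)
z    <- phantomRegions(spec)$centerline

vm <- dopplerImage(scan, EstimatorSpec("complex_regression", 64),
                   config = cfg, depths = z)
sprintf("complex regression: %.2f +/- %.2f mm/s (true 20.00)",
        mean(axialVelocity(vm)) * 1e3,
        sd(axialVelocity(vm)) / sqrt(31) * 1e3)
#> [1] "complex regression: 19.44 +/- 0.33 mm/s (true 20.00)"

detectionReport(EstimatorSpec("complex_regression", 64), "high", cfg)
#> DetectionReport: complex_regression N=64, high SNR
#>   theoretical floor: 0.1945 mm/s | grid minimum: 0.374 mm/s
```

The 2,000-A-line scan splits into 31 non-overlapping 64-point windows; the
report shows the analytic floor of the 64-point regression (~194 µm/s) and
its quantization onto the 18-velocity validation grid (374 µm/s — the
smallest swept velocity at or above the floor).

The same operations are available from the shell:

```sh
Rscript inst/scripts/crdoppler simulate --velocity 0.02 --seed 42 --out phantom.mscan.rds
Rscript inst/scripts/crdoppler doppler --in phantom.mscan.rds --estimator cmpreg --out velocity.csv
Rscript inst/scripts/crdoppler report --estimator cmpreg --snr low --out report.json
```

Every run writes a JSON manifest next to its output; re-running with the
manifest's seed and parameters reproduces the output bit for bit.

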