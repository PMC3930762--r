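# imspeaks

Fully automated peak extraction from MCC/IMS measurements.

An ion mobility spectrometer coupled to a multi-capillary column (MCC/IMS)
measures volatile organic compounds in air or exhaled breath. One measurement
is an *ion mobility spectrum-chromatogram* (IMSC): an m × n matrix of signal
intensities S(r, t) over MCC retention time r (seconds) and reduced inverse
ion mobility t (Vs/cm²). Every analyte appears as a 2D peak; reducing the raw
matrix to a list of peak descriptors (r, t, signal, …) — *peak extraction* —
is the basis for downstream clustering, classification and biomarker
discovery. Experts do this interactively; `imspeaks` does it automatically,
in seconds, for use in high-throughput settings.

## The pipeline

Extraction is a four-stage modular pipeline; each stage has interchangeable
modules and every combination is a valid pipeline, named by concatenating
module shortcuts (e.g. `dn-s-bc-cf-ce-e`):

1. **Preprocessing** (all three, in any order)
   - `bc` baseline correction: per chromatogram t, a Gaussian + uniform
     mixture is fitted by EM to the intensity histogram; everything up to
     B_t = μ(t) + 2σ(t) is baseline (in a RIP chromatogram that level *is*
     the reactant ion peak) and is subtracted with clamping at 0.
   - `dn` de-noising: a Gaussian (noise) + Inverse Gaussian (signal) +
     uniform (background) mixture is fitted to the histogram of the locally
     averaged matrix A; each cell is damped by its posterior noise
     membership, S′ = S · (1 − W).
   - `s` smoothing: isotropic 2D-FFT lowpass (`fftcutoff`) followed by a
     9 × 9 degree-2 Savitzky–Golay filter.
2. **Candidate detection** (one of)
   - `lm` local maxima with an area-size test, or
   - `cf` cross finding: downward zero crossings of the discrete derivatives
     along both axes, chained across neighbouring spectra by order-preserving
     alignment (match score (1+d)⁻¹, gap score 0.1, max distance 9) and
     intersected.
3. **Peak picking** (one of): `ms` greedy merging by signal intensity inside
   tolerance boxes; `ce` weighted cluster editing with
   w = 2ᵇ(1 − d²) − 1 for d² < 1 and 1 − d² otherwise, solved exactly by an
   internal solver; `emc` 2D Gaussian EM clustering with component merging.
   All use the tolerances Δt = 0.003 Vs/cm² and Δr = 0.1·r + 3 s.
4. **Peak modeling** (optional): `pme` describes every picked peak by seven
   parameters — a shifted Inverse Gaussian per axis (μ, λ, offset) plus a
   mixture weight — fitted by intensity-weighted EM inside expanded boxes;
   `e` is the empty module. Modeling may also run before picking.

That yields 108 distinct pipelines (`enumeratePipelines()`). Peak lists are
compared against annotations by tolerance-box matching, giving TP/FP/FN,
sensitivity, positive predictive value, their geometric mean
G = √(SENS · PPV) (Fowlkes–Mallows index), the Jaccard index
J = TP/(TP+FP+FN) and the distance d = 1/J − 1.

## Worked example

```r
library(imspeaks)

## a synthetic 600 x 2500 measurement with 5 planted peaks, a reactant ion
## peak near t = 0.48 Vs/cm2, baseline and noise, quantized to 12 bits
sim <- simulateIMSC(simulationConfig(seed = 1))

pl <- runPipeline("dn-s-bc-cf-ce", sim$measurement,
                  defaultParameters(intensity_threshold = 10))
head(peaks(pl)[, c("retention_time", "inverse_reduced_mobility", "signal")])
#>   retention_time inverse_reduced_mobility   signal
#> 1     150.250417                  0.74994 791.2808
#> 2     349.582638                  0.62002 698.2026
#> 3      60.100167                  0.59972 571.1790
#> 4     250.417362                  0.90016 497.9168
#> 5     479.799666                  1.04980 398.8335
#> 6       3.005008                  0.47096 252.4263

round(evaluatePeakList(pl, sim$truth), 3)
#>   TP   FP   FN SENS  PPV    G    J    d
#>    5    0    0    1    1    1    1    0
```

The sixth entry is the residual reactant ion peak at t = 0.471 Vs/cm² and
r = 3 s; evaluation restricts both lists to the standard region (r > 5 s,
t > 0.48 Vs/cm²), which excludes it by construction.

All five planted peaks are recovered at their planted coordinates (TP = 5)
with no spurious peaks (FP = 0), so sensitivity, PPV, the Fowlkes–Mallows
index G and the Jaccard index are 1 and the peak-list distance d is 0.

Measurements are read and written in a plain-text CSV dialect
(`readIMSC`/`writeIMSC`: `# key=value` header lines, one line with the
mobility grid, then one `r, S_r1, …, S_rn` line per spectrum); peak lists in
the standard 8-column schema (`readPeakList`/`writePeakList`). A thin command
line front end with `run`, `enumerate`, `evaluate` and `simulate` subcommands
is installed under `inst/scripts/imspeaks-cli.R`.

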