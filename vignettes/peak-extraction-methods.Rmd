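---
title: "Methods: automated peak extraction from MCC/IMS measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated peak extraction from MCC/IMS measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imspeaks)
```

## The data model

A coupled multi-capillary column / ion mobility spectrometer produces an ion
mobility spectrum-chromatogram (IMSC): an $m \times n$ matrix $S$ of signal
intensities indexed by retention time $r$ (seconds; one IM spectrum per row,
captured every $\sim$100 ms) and reduced inverse ion mobility $t$ (Vs/cm²,
the drift quantity normalized for instrument geometry and ambient
conditions; one chromatogram per column). Raw intensities are unsigned
12-bit integers (0..4095). Every measurement carries the *reactant ion peak*
(RIP), a high-intensity chromatogram near $t = 0.48$ Vs/cm² produced by the
ionized drift gas; analytes appear as localized 2D peaks, asymmetric with a
heavier right tail in both coordinates, widening with retention time. The
`IMSMeasurement` class stores the two grids, the matrix and opaque metadata;
peak lists (`IMSPeakList`) carry one row per peak with the descriptor
columns (measurement, name, $r$, $t$, signal, volume, grid indices) plus
optional model parameters.

## Mixture machinery

Baseline correction, de-noising and peak modeling all view (parts of) the
data as a heterogeneous finite mixture $f(x) = \sum_c \omega_c f_c(x)$ whose
components can differ in family (Gaussian, Inverse Gaussian, shifted Inverse
Gaussian, uniform), fitted by EM. Fits run on integer-binned histograms
(`weightedSample`): for integer-valued data with bin size 1 this is exactly
equivalent to per-point EM on the expanded sample and much faster; a
property test asserts the equivalence. Numerical guards: variance floor
$10^{-12}$, weight floor $10^{-12}$, convergence when the relative
log-likelihood change falls below $10^{-6}$ (at most 500 iterations) — the
log-likelihood is asserted non-decreasing in the tests. Uniform components
are never re-estimated; their support is the observed data range, except in
de-noising where the background must span *all measured intensities* and the
raw range is passed explicitly (the local averages being fitted occupy a
much narrower range; clamping the uniform to it would make the background an
artificially strong competitor of the noise component). Single-valued data
admit no mixture fit; such fits return with status `"degenerate"` and
callers pass the input through with a warning.

The shifted Inverse Gaussian density used for peak shapes is
$$f(x \mid \mu, \lambda, o) = \sqrt{\frac{\lambda}{2\pi (x-o)^3}}
  \exp\!\Big(\!-\frac{\lambda (x-o-\mu)^2}{2\mu^2 (x-o)}\Big), \quad x > o,$$
with mean $o + \mu$, variance $\mu^3/\lambda$ and mode
$o + \mu(\sqrt{1 + (3\mu/2\lambda)^2} - 3\mu/2\lambda)$. Translating a
(mode, mean, sd) triple back into $(\mu, \lambda, o)$ has two solutions; the
package takes the larger-$\mu$ root, i.e. the mildly skewed, near-Gaussian
shape, which is the relevant branch both for initialization (mean = mode
$+10^{-3}$, sd = 1 index unit) and for the synthetic generator.

## Preprocessing

**Baseline correction (bc).** Per chromatogram, the intensity histogram's
most prominent peak is the "typical" level — plain noise in an ordinary
chromatogram, the RIP level in a RIP chromatogram. A Gaussian (initialized
at the histogram argmax with $\sigma^2 = 1$) plus uniform mixture is fitted
and $B_t = \mu(t) + 2\sigma(t)$ subtracted with clamping at zero. bc is
approximately idempotent, tested as a column-median property.

**De-noising (dn).** The mixture (Gaussian noise + Inverse Gaussian signal +
uniform background) is fitted to the histogram of the locally averaged
matrix $A$ (window half-width `smoothing_radius` = 4, i.e. 9×9; on the
standard 2500-point drift grid the 0.003 Vs/cm² picking tolerance is
$\approx$ 5 index units, so $\rho = 4$ keeps the averaging inside one peak's
tolerance box). Each cell is damped by its posterior noise membership:
$S' = S\,(1 - W)$. Initialization is argmax/$\sigma^2{=}1$ for the noise
component, the 90th intensity percentile with $\lambda = \mu$ for the signal
component, weights (0.8, 0.1, 0.1). Two deliberate numerical choices:

* Inside dn the local average divides by the number of *in-bounds* window
  cells rather than always by $(2\rho+1)^2$. The zero-padded mean biases
  border cells low; the fitted noise component then misses them and a frame
  of raw-valued border cells would survive preprocessing as spurious
  candidates. The exported `localAverage()` offers both boundary modes; the
  zero-padded mean remains the documented default contract.
* The background uniform spans the raw intensity range (see above).

**Smoothing (s).** An isotropic lowpass in the 2D-FFT domain — coefficients
with centered radial frequency index above `fftcutoff` (default 500) are
zeroed — followed by a degree-2 Savitzky–Golay filter on 9×9 windows with a
zero margin at the borders. Degree-2 surfaces are reproduced exactly on
interior cells (tested). Negative values that the filters may produce are
kept; downstream intensity thresholds make them irrelevant. Note that the
zero margin makes the SG filter overshoot by roughly 8% of the local level
in the outermost rows/columns wherever strong signal touches the border
(in practice: the RIP, which spans the full retention range); this is a
known, accepted property of zero-margin boundary handling — border regions
carry no analyte information and the RIP region is excluded from evaluation.

## Candidate detection

Both detectors use the signal threshold `intensity_threshold` ($I$, default
10; 5/10/15 are the conventional settings).

**Local maxima (lm).** A cell is a candidate iff it is $\ge I$, all its
existing 8-neighbours are between $I$ and the cell's value, and the
8-connected component of supra-threshold cells containing it has at least
`area_size` $\ge 9$ cells. Component labeling uses `igraph`. Boundary cells
evaluate only their existing neighbours. Equal-valued plateau maxima are all
reported; picking resolves the duplicates. An exhaustive brute-force scan is
the test oracle.

**Cross finding (cf).** On the zero-padded matrix, discrete derivatives
along each axis are scanned for downward zero crossings ($D_{t-1} \ge 0$,
$D_t < 0$); crossings are chained across consecutive spectra (and, for the
transposed matrix, chromatograms) by a banded global alignment of the sorted
position lists — match score $(1+d)^{-1}$, gap score $\gamma = 0.1$, so
positions more than 9 index units apart never align; ties prefer the
smaller total matched distance, then lexicographic order, making the
pipeline deterministic. Finalized vertical and horizontal bands are
intersected; each band pair sharing cells reports its highest-signal shared
cell, and candidates must exceed $I$. One boundary refinement: a "crossing"
whose negative side is informed only by the far zero pad (a signal still
rising at the matrix edge) is discarded — the apex evidence lies outside the
measured window. Near-border apexes, the reason for padding, are still
found. Alignment optimality is tested against exhaustive enumeration of all
monotone pairings.

## Peak picking

Distinct compounds are separated by at least $\Delta t = 0.003$ Vs/cm² in
mobility and $\Delta r(r) = 0.1\,r + 3$ s in retention time (peak widths grow
with $r$). The normalized squared distance is
$d^2(u,v) = \tfrac12[((t_u{-}t_v)/\Delta t)^2 + ((r_u{-}r_v)/\Delta r)^2]$,
with $\Delta r$ evaluated at the pair's mean retention time (for the greedy
box picker, at the reporting candidate, per its box definition).

* **ms** sorts by descending signal (ties: ascending grid indices, for
  determinism) and greedily reports candidates, merging everything in the
  reporter's $(\pm\Delta r) \times (\pm\Delta t)$ box.
* **ce** builds the complete graph with weights $w = 2^b(1-d^2)-1$ for
  $d^2 < 1$, else $1-d^2$ ($b$ = `ce_weight_exponent` = 26; the two branches
  disagree in the limit $d^2 \to 1^-$, and the printed value $w(1) = 0$ is
  honoured by assigning equality to the second branch) and solves weighted
  cluster editing: minimum-cost edge edits to a disjoint union of cliques.
  The solver decomposes into connected components (optimal clusters never
  span them), solves components of up to 12 vertices exactly by subset
  dynamic programming over the equivalent intra-cluster net-weight
  maximization, and falls back to a greedy pivot heuristic with
  single-vertex local moves above that, flagging the result `"heuristic"`.
  Exactness is tested against full partition enumeration.
* **emc** runs a 2D diagonal-covariance Gaussian mixture EM over the
  candidate coordinates, one component per candidate ($\sigma$ initialized
  to $\Delta r/3$ and $\Delta t/3$; 6$\sigma$ spans the tolerance box).
  Components whose means come closer than $1/3$ in normalized distance
  (consistent with the $\Delta/3$ initialization) merge onto the
  higher-signal anchor. Standard deviations are floored at
  $\tau = 10^{-5}$ Vs/cm² on the mobility axis and $\tau \Delta r/\Delta t$
  on the retention axis; reported peaks keep their anchoring candidate's
  grid position (the output schema stores grid indices).

All pickers return a subset of their input sorted by descending signal and
agree on candidate sets whose pairwise separations exceed the tolerances
(tested).

## Peak modeling

`pme` interprets each box around the picked peaks — expanded per axis until
the signal drops to zero, widened by `expansion_size` = 10 index units, with
intersecting boxes merged into bounding rectangles until a fixpoint — as an
intensity-weighted sample from a mixture of per-peak separable
shifted-Inverse-Gaussian products plus a uniform background (cell
intensities act as fractional observation counts at the cell centers; the
IMSC is a binned sample). Each peak contributes seven parameters. EM
initialization translates (mode = picked index, mean = mode + $10^{-3}$,
sd = 1) into $(\mu, \lambda, o)$; the M-step keeps closed-form weighted
updates for $(\mu, \lambda)$ given the offset and re-estimates the offset by
1D profile-likelihood optimization below the smallest observation. Model
parameters, the derived mode/mean/sd per axis, and the peak volume
$\omega \cdot \sum_{\text{box}} S$ are stored as extra columns; the peak's
reported coordinates move to the modeled (continuous) mode, interpolated on
the grids. The output list always has the input's size; boxes in which EM
fails leave their peaks unmodeled with NA parameters and a warning.
Recovery of planted peaks (mode within 1 index unit, sd within 20%; two
overlapping peaks within 2 index units) is part of the test suite. Modeling
may run before picking, in which case candidates are modeled and picking
operates on the modeled list.

## Pipelines and evaluation

Six preprocessing orders × two detectors × three pickers × three modeling
placements (none, after picking, before picking) give 108 distinct
pipelines; the 144 ordered combinations collapse because the empty module
commutes with picking. Names concatenate shortcuts (`dn-s-bc-cf-ce-e`); the
canonical spelling puts the empty module last.

Peak lists are compared after restricting to the standard evaluation region
($r > 5$ s, $t > 0.48$ Vs/cm², excluding the RIP): a box of half-widths
$(\Delta r, \Delta t)$ around each annotated peak, visited in ascending
$(r, t)$ order, consumes its closest automatic peak (normalized distance,
deterministic tie-breaks); consumed boxes are TP, empty boxes FN, never-
consumed automatic peaks FP — including additional peaks inside an already
consumed box. SENS = TP/(TP+FN), PPV = TP/(TP+FP),
$G = \sqrt{\text{SENS} \cdot \text{PPV}}$ (the Fowlkes–Mallows index; the
product without the radical would not be a geometric mean),
$J = \text{TP}/(\text{TP}+\text{FP}+\text{FN})$, $d = 1/J - 1$ (infinite at
$J = 0$; empty-versus-empty counts as perfect agreement). Pareto fronts over
(SENS, PPV) use strict dominance, keeping duplicates.

## The synthetic test bed

Real annotated clinical measurements cannot be redistributed, so validation
uses a seeded generator (`simulateIMSC`) that emulates the data model:
$\mathrm{clip}_{0..4095}(\mathrm{round}(\text{baseline}(t) + \text{RIP} +
\sum \text{peaks} + \text{noise}))$ on the standard 600 × 2500 grid
($r \le 600$ s, $t \le 1.45$ Vs/cm²). Defaults, chosen once as realistic
operating conditions:

* **Baseline**: a 3-count detector offset (offset-corrected acquisition),
  rising by 40 counts toward the low-mobility edge with exponential decay
  (scale $0.15\,t_{\max}$). The marginal intensity distribution stays
  unimodal; a sinusoidal modulation would produce an arcsine (bimodal)
  marginal that no single-Gaussian noise component can represent — a real
  limitation of the de-noising model worth knowing about.
* **RIP**: Gaussian profile at $t = 0.473$ Vs/cm² (apex grid column below
  the 0.48 evaluation cutoff, which exists precisely to exclude the RIP),
  width sd 0.002 Vs/cm², apex 3000 counts, its position drifting smoothly
  (spline through 11 knots, sd $10^{-4}$ Vs/cm²) over the run — instrument
  drift is slow; it is not independent per 100-ms spectrum.
* **Peaks**: separable products of shifted-IG profiles (the pme model),
  parameterized by apex coordinates, per-axis sd and a skew (mean−mode gap
  of 0.3 sd). The five default peaks have amplitudes 400–800 (two orders
  above the noise), widths growing with retention time, and pairwise
  separations far beyond the picking tolerances.
* **Noise**: additive Gaussian, sd 3 counts, truncated by the 12-bit clip.

What passing the end-to-end test (SENS = PPV = 1 for `dn-s-bc-cf-ce` at
$I = 10$ against the planted truth) does show: the full chain — EM baseline
and noise models, filters, crossing detection, alignment, cluster editing —
localizes well-separated, high-amplitude peaks exactly and produces no
spurious peaks inside the evaluation region under realistic baseline, RIP
and noise. What it does not show: performance on overlapping or
near-threshold peaks, on measurements with large uncorrected offsets (the
multiplicative de-noising update then leaves offset-carrying halos around
real peaks — visible in the generator when the offset is raised), on RIP
tailing/depletion at high analyte load, or against human annotation
variability. The separate pme tests cover shape recovery, not detection.

## Known limitations

* De-noising assumes a quasi-stationary noise level across the matrix; a
  strongly $t$-dependent baseline should be removed first (run `bc` before
  `dn`), and large uniform offsets degrade precision in dn-first orders.
* The zero-margin SG filter distorts the outermost `smoothing_radius`
  rows/columns (up to ~8% overshoot where strong signal meets the border).
* The exact cluster-editing solver is exponential; components above 12
  vertices fall back to a flagged heuristic. With the default tolerances,
  real candidate sets decompose into very small components.
* `emc` merging is greedy in the order merge conditions appear; with many
  equidistant candidates the result can depend on candidate order (made
  deterministic by the fixed candidate sort).
* Problem sizes in the test suite are scaled to keep the default run fast
  (50×50 oracle matrices, $n = 10^4$ recovery samples, 20 cluster-editing
  instances, one full-size end-to-end simulation); all constants above are
  the package defaults, not test-specific values.
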