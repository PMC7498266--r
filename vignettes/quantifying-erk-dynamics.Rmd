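---
title: "Quantifying oncogene-driven ERK dynamics, directed migration and apical extrusion"
author: "mapkdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oncogene-driven ERK dynamics, directed migration and apical extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkdyn)
```

## The measurement problem

When an oncogene such as BRAF^V600E^ is induced in a small fraction of
cells inside an epithelial monolayer, three things happen that can be read
out by live imaging: the inducible cells and their neighbors display
distinct ERK signaling dynamics (discrete activity pulses versus a
sustained plateau), the surrounding wild-type cells migrate directedly
toward the inducible group, and the inducible cells are eventually expelled
apically from the monolayer (apical extrusion, the effector arm of
epithelial defense against cancer).  `mapkdyn` implements the single-cell
quantification chain for all three readouts, plus the population-level
statistics that accompany them (EdU S-phase fold changes and a shed-protein
significance filter for supernatant proteomics), and a seeded synthetic-data
generator that emulates every input modality with known ground truth.

ERK activity is measured with a kinase translocation reporter (KTR): the
reporter exits the nucleus when ERK is active, so the per-cell
cytoplasm/nucleus (C/N) intensity ratio is a monotone proxy of kinase
activity.  The localization of the tagged kinase itself is summarized by
the converse nucleus/cytoplasm (N/C) ratio.  All the pipeline's spatial
units are micrometers, time is in minutes, angles in degrees, and z
increases apically with 0 at the lowest acquired plane.

## Activity traces, cleaning, and the peak caller

`computeActivityTrace()` forms the per-frame C/N ratio and excludes frames
with nonpositive intensities (segmentation failures), flagging the trace.
`cleanTraces()` applies the minimal cleaning rules used for single-cell KTR
data: traces from switched tracks, traces affected by segmentation errors,
and traces covering less than two thirds of the time course are excluded
(the coverage cutoff is a parameter, because fast-moving conditions
systematically shorten tracks and the restraint must then be relaxed).
Cleaning is idempotent and every exclusion is logged with a reason — the
exclusion accounting is part of the method, not bookkeeping.

`countPeaks()` detects activity pulses in four steps:

1. *Smoothing* — a centered moving mean, 3 frames by default.  At 5-min
   sampling this window (15 min) denoises without eroding 20–30 min
   pulses.
2. *Candidate extrema* — local maxima/minima of the smoothed series, ties
   broken toward the earlier frame.  Internal track gaps are linearly
   interpolated **only** for this localization step, never for amplitude
   measurement, so missing frames cannot manufacture extrema.
3. *Gaussian refinement* — each extremum is refined by a least-squares
   Gaussian (inverted for minima) fitted over ±2 frames, yielding
   sub-frame apex times and values.  The fit is evaluated on the smoothed
   series: with only 5 points and 4 parameters, fits to raw frames are
   ill-conditioned and can chase single noisy frames; a fitted apex that
   escapes its window's data range falls back to the raw frame value.
4. *Peak criteria* — a candidate maximum is a peak iff (a) its rise from
   the preceding valley exceeds the amplitude threshold, (b) the rate of
   change of the rising flank exceeds the slope threshold, and (c) a
   fall of at least `fallFraction` of the rise occurs before the trace
   end.  The flank rate is rise / (apex time − onset time), where the
   onset is the last pre-apex time at which the smoothed trace sits
   within 10% of the rise above the valley: this equals the valley time
   whenever the valley is adjacent to the peak, but for an isolated pulse
   following a long flat baseline it prevents the distance to an
   arbitrary baseline minimum from diluting the slope of a genuinely
   fast rise.  Criterion (c) is what distinguishes a pulse from the onset of a
   sustained plateau: a step-and-plateau trace has rises but never falls,
   and is counted as zero peaks.

Two choices in step 4 deserve justification.  First, the *preceding
valley* is the deepest fitted minimum between the previous candidate
maximum and the current one, not merely the immediately preceding local
minimum: a small noise dip on a pulse's rising flank would otherwise
truncate the measured rise and cause misses, while the shallow dip of an
apex split in two by noise yields a small rise for the second fragment and
rejects it automatically.  Second, the amplitude threshold is
`max(minAmplitude, noiseMult × sigma_hat)` where `sigma_hat` is a robust
per-trace noise estimate (the median absolute deviation of the residual
about a 3-frame moving mean, rescaled by `sqrt(2/3)`).  A fixed threshold
alone cannot serve both low-noise and high-noise traces: at a noise sd of
0.1 ratio units, order statistics of ~70 frames of noise routinely produce
apparent rises above 0.15.  The adaptive floor (default 3 noise sd)
suppresses these while leaving noiseless behavior — and therefore
equivalence with a brute-force local-maximum scan — untouched.

Defaults: `minAmplitude` 0.15 ratio units, `minSlope` 0.005 ratio
units/min, `fallFraction` 0.5, `smoothWindow` 3 frames, `fitHalfWidth` 2
frames, `noiseMult` 3.  All are exposed in `peakConfig()`; they were tuned
on the synthetic suite, since no published numeric thresholds exist for
this caller.

`classifyDynamics()` formalizes the pulsatile/sustained dichotomy as a
pure function of features: *sustained* iff the duty cycle (fraction of
frames above `activityThreshold`, default 1.25 — halfway between the
simulated baseline 1.0 and plateau 1.5) is at least 0.8; otherwise
*pulsatile* iff at least 2 peaks were called; else *quiescent*.  The duty
cycle is computed over a caller-supplied post-induction window: response
onset lags induction (the simulated sustained onset is 60 min), and
including pre-onset baseline frames dilutes a genuinely sustained cell's
duty cycle toward the 0.8 boundary.  The validation suite uses t ≥ 120 min
of a 6-h movie.

Per-cell fold-change metrics use two windows of 1 h by default (the window
lengths are parameters): `localizationFoldChange()` is the final-window
over basal-window mean N/C ratio; `migrationFoldChange()` is the
final-window over basal-window path length, undefined (and excluded) when
the basal path length is zero.  `summarizePopulation()` aligns traces on
the union of frame times and reports the per-frame mean and 25th–75th
percentile band, omitting absent cells frame-wise.

## Directed migration statistics

The migration module reproduces the windowed-angle analysis:
`findInducibleCenter()` takes the centroid of inducible-cell positions at
a reference frame (the center is computed once per epoch, not per frame —
inducible groups are near-stationary on the 4–6 h scale, and the choice is
switchable); `selectNeighborsInWindow()` keeps non-inducible cells inside
an axis-aligned 200 × 200 µm square around it (the window half-width is a
parameter; the published value is read as micrometers);
`intervalDisplacements()` takes non-overlapping 20-min displacement
vectors (non-overlapping rather than sliding, to avoid autocorrelated
pseudo-replication); and `migrationAngle()` maps each displacement to the
unsigned angle between it and the direction to the center: 0° is directly
toward, 180° directly away, folded to [0, 180] because the toward/away
statistic is symmetric about the center axis.  Zero displacements have no
angle and are dropped with a log entry.  `radialHistogram()` bins angles
into 12 equal right-open bins over [0, 180].

### The subsampled KS procedure and its calibration

Angle datasets contain 10^4^–10^5^ observations, and a classical two-sample
Kolmogorov–Smirnov test at that n declares microscopic differences
significant.  `subsampledKsTest()` therefore draws, in each of 1000
iterations, 1000 angles *without replacement* independently from each
group (or the whole group when it is smaller), runs the two-sample KS test
(`stats::ks.test`, asymptotic p), and reports the **median** p over
iterations with the usual star coding.  Iteration seeds derive from one
master seed, so the median p is reproducible.  With one iteration and
subsample sizes at least the group sizes, the procedure reduces exactly to
the classical test.

A property worth stating plainly: the median-p decision rule is
*conservative by construction*.  For subsamples of 1000 drawn from groups
of 5000, the subsampling-induced fluctuation of the empirical CDFs
(variance ≈ 0.8·p(1−p)/1000 per group) exceeds the between-group null
discrepancy (variance ≈ p(1−p)/2500) about four-fold, so per-iteration
p-values are nearly uniform conditional on the data and their median
concentrates near 0.5 under the null; `median p < 0.05` then requires a
full-sample discrepancy far out in the null tail.  The procedure's
realized type-I error at α = 0.05 is therefore essentially zero — far
below nominal, never above — which is exactly its purpose: it de-powers
comparisons that huge n would otherwise render trivially significant,
while iteration-level p-values remain marginally calibrated (~5% fall
below 0.05 under the null).  The validation suite demonstrates both facts,
and the power side: a von Mises bias of κ = 1 versus uniform at 1000
angles per group yields median p < 0.001 essentially always.

## Apical extrusion from z-stacks

`zIntensityHistogram()` reduces a two-channel confocal stack (channel 1:
inducible nuclei; channel 2: all nuclei) to per-plane total intensity
after background subtraction; the background is the median of the
lowest-decile pixels of that stack and channel, a deliberately simple
estimator because no published background handling exists for this assay.
Up to normalization this profile is the intensity-weighted nuclear-height
density, which reconciles the two published phrasings (pixel-intensity
histograms vs nuclear-height probability densities) in a single code path.

`fitGaussianProfile()` fits `A·exp(−(z−µ)²/(2σ²)) + c` by Levenberg–
Marquardt least squares (`minpack.lm::nlsLM`), initialized at moment
estimates (intensity-weighted centroid and sd, minimum plane value), with
µ bounded to one z-step beyond the acquired range and σ to [step/4, z
range].  Non-convergence returns the moment estimates flagged
`converged = FALSE`; such fits are excluded from condition statistics.  A
single Gaussian per channel is used deliberately, matching the published
method, even though the inducible channel is transiently bimodal
mid-extrusion; mixture modeling is out of scope.

`deltaZ()` is the difference of fitted means, inducible minus reference,
positive when inducible nuclei sit apically.  The reference is the
all-nuclei channel.  Because that channel contains the displaced inducible
nuclei (at the simulated 10% coculture fraction), one might expect the
recovered ΔZ to under-report the true offset by that fraction; in practice
the single-Gaussian fit is mode-seeking — the displaced minority shifts
the fitted mean far less than the mixture mean — and the recovery slope
across true offsets of 0–8 µm stays within a few percent of unity, as the
validation suite measures.

`normalizeCondition()` subtracts the mean parental ΔZ, making the
parental normalized mean exactly 0.  Subtraction was chosen over division
because parental ΔZ is ≈ 0 by construction and a ratio would be unstable;
the published wording ("normalized to the mean height of parental cells")
does not disambiguate, and this is recorded as the package's choice, not
as authorial intent.  `flagOutliers()` marks observations more than 3
MAD-based robust sd from the median (the published analysis excluded
imaging-artifact outliers without stating a rule; this default is the
field's common robust choice and is idempotent); flagged values are kept
in the output but excluded from means and tests.  `compareConditions()` is
a two-sided Welch t-test with star coding.

## Population statistics

`sphaseFraction()` is the EdU-positive proportion; fold changes over the
no-dox control are ratios (consistent with the "fold-change in S-phase
cell fractions" phrasing), and `eduFoldTable()` normalizes by the mean
parental fold so the parental mean is exactly 1.
`proportionResponseCurve()` emits one row per imaging position with the
percent of inducible nuclei and the neighbor-population fold change.
`filterShedProteins()` retains proteins with raw p < 0.05 in both the
+Dox/−Dox and WT/sheddase-KO comparisons and classifies as "in-box" those
with both fold changes above 1.5 (|ln FC| > ln 1.5 on the enriched side);
no multiplicity correction is applied, mirroring the published raw-p
filter, and the filter is monotone in both thresholds.  For synthetic
tables, per-protein p-values come from unpaired t-tests across triplicates
on the log scale — the upstream test is unpublished, and this is the
simplest defensible stand-in.

## What the synthetic generator emulates — and what it does not

The generator produces every input modality with configurable ground
truth:

* **Pulse traces** — apex times from a homogeneous Poisson process (rate
  in pulses/h) thinned by a refractory period (default 40 min), each pulse
  a symmetric Gaussian bump (FWHM 25 min, amplitude 0.5 ratio units over a
  baseline of 1.0), plus i.i.d. Gaussian noise (sd 0.05).  Pulse centers
  are kept at least one pulse width from the trace ends by default: a
  pulse truncated by the acquisition window has no well-defined in-window
  apex, so count recovery against ground truth is only well-posed for
  fully observed pulses (`edgeMarginMin = 0` disables this).  Published
  amplitude/width statistics for these pulses do not exist; the defaults
  are free parameters of the benchmark, not calibrated claims.
* **Sustained traces** — a logistic step (onset 60 min, 10–90% rise time
  30 min, plateau 1.5).
* **Tracking tables** — neighbor step headings follow a von Mises
  distribution about the direction to the inducible-cell center
  (concentration `biasKappa`, 0 = unbiased, sampled by the Best–Fisher
  algorithm implemented in `rVonMises()`), with constant step length;
  inducible cells form a compact central cluster and move slowly.  The
  reporter mapping conserves nuclear + cytoplasmic intensity per cell so
  the recorded intensities reproduce the programmed ratio exactly.  An
  optional paracrine wave delays each neighbor's activity onset by
  distance/speed — purely kinematic, because no quantitative wave model
  exists to emulate.
* **Z-stacks** — nuclei as isotropic 3-D Gaussian blobs (σ 2.5 µm) on a
  200 × 200 µm field at 1 µm z-steps over 25 µm; inducible z-centers from
  N(8 + ΔZ, 1.5) µm, all others from N(8, 1.5) µm; 16-bit integer
  quantization as a detector would produce.  150 nuclei per field
  approximates a confluent MCF10A monolayer at this field size.
* **EdU and shed-protein tables** — binomial S-phase counts per position
  and population; log-normal triplicate abundances with designated hits
  elevated in the induced wild-type condition only.

Not emulated, deliberately: microscope PSF and shot-noise statistics,
mechanistic ERK pathway dynamics, cell division and lineage, nuclear
shape, segmentation errors (these are injected at the table level via
flags instead).  Passing the synthetic suite therefore demonstrates that
the *quantification chain* recovers known ground truth under realistic
geometry and noise — it does not certify segmentation or tracking, which
sit upstream of this package's inputs.

## Numerical choices and degenerate inputs

* Ties in extremum detection break toward the earlier frame; plateaus
  produce no interior extrema.
* Constant fit windows, too-few-point windows, and fits whose apex leaves
  the window fall back to raw frame values; flat z-profiles fall back to
  moment estimates with `converged = FALSE`; zero-mass profiles are
  errors.
* Two fitted apexes within one frame are merged (larger rise wins).
* `ks.test` is called with `exact = FALSE` throughout: subsample sizes
  are far beyond the exact-p regime, and a fixed method keeps iteration
  p-values exchangeable.
* All generators accept `NULL` seeds (inherit the caller's RNG state) or
  integer seeds (restore the caller's state afterwards); child seeds are
  derived, never reused.

## Validation problem sizes

The validation suite and `scripts/acceptance.R` use: 200 pulsatile traces
(6 h at 5-min frames, rates 1–3/h) for count recovery; 150 traces for
classification at amplitude/noise = 5; 200 replicates of the subsampled KS
procedure at its published scale (1000 iterations × 1000 angles from
groups of 5000) for calibration and 100 replicates for power; 50 simulated
stacks (true offsets 0–8 µm, 10 replicates each) for ΔZ recovery; 50
noiseless profiles against a coarse-to-fine grid-search oracle (0.005 µm
final resolution) for fit agreement; and a 6-stage end-to-end pipeline run
twice for byte-identical determinism.  These sizes give Monte-Carlo
standard errors comfortably below the tolerances being asserted.

## Known limitations

* The peak caller assumes approximately symmetric, isolated pulses; deeply
  overlapping pulse trains (inter-pulse interval below the refractory
  default) merge into single apexes by design.
* The single-Gaussian z-profile model under-reports extrusion while a
  population is split between basal and apical positions.
* The adaptive amplitude floor assumes noise roughly stationary within a
  trace; strongly heteroscedastic traces would need per-window noise
  estimates.
* The subsampled KS procedure should be read as a conservative screen, not
  a calibrated α-level test; see the calibration discussion above.
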