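# mapkdyn

Single-cell quantification of oncogene-driven ERK signaling dynamics,
directed migration, and apical extrusion in epithelial monolayers.

## What this package is for

When an oncogene (e.g. BRAF^V600E^ or MEK2^DD^) is induced in a sparse
subset of cells inside an epithelial monolayer, live imaging reveals three
linked phenomena: distinct single-cell ERK dynamics (discrete activity
pulses vs a sustained plateau, read out with a kinase translocation
reporter), directed migration of wild-type neighbors toward the inducible
group, and apical extrusion of the inducible cells from the monolayer.
`mapkdyn` provides the quantification chain for imaging scientists and
computational biologists analyzing such experiments:

* **Activity traces** — per-cell cytoplasm/nucleus KTR ratios from
  tracking tables, coverage/flag-based cleaning with an exclusion log, and
  a peak caller that refines extrema with local Gaussian fits and applies
  rise / rate-of-change / subsequent-fall criteria (`countPeaks()`); a
  pure-feature classifier labels each cell pulsatile, sustained, or
  quiescent.
* **Directed migration** — windowed 20-min displacement angles of
  neighboring cells relative to the inducible-group center (0° = toward,
  180° = away), radial histograms, and the subsampled two-sample
  Kolmogorov–Smirnov procedure (median p over 1000 iterations × 1000
  subsampled angles) that keeps huge-n comparisons honest.
* **Apical extrusion** — per-channel z-intensity profiles of two-channel
  confocal stacks, least-squares Gaussian fits, the ΔZ statistic
  (inducible minus all-cell fitted mean, in µm), parental-baseline
  normalization, robust outlier flagging, and Welch t-tests.
* **Population statistics** — EdU S-phase fractions and parental-
  normalized fold changes, the coculture proportion–response relation,
  and the shed-protein filter (p < 0.05 in both comparisons, > 1.5-fold
  boxes) for supernatant proteomics.
* **Synthetic data with ground truth** — seeded generators for every
  input modality (pulse/sustained traces, biased migration tracks,
  two-channel z-stacks, EdU and shed-protein tables), used throughout the
  test suite for recovery benchmarks.

The central quantities, in the field's notation: ERK activity is the KTR
ratio C/N per cell per frame; the extrusion statistic is
ΔZ = µ̂(inducible) − µ̂(all) where µ̂ are the means of Gaussians
A·exp(−(z−µ)²/2σ²)+c fitted to background-corrected z-intensity profiles;
migration bias is summarized by the distribution of
θ = arccos(d·û/|d|) ∈ [0°, 180°] for 20-min displacements d relative to
the unit vector û toward the inducible-cell centroid.

## Worked example

Simulate a pulsatile cell at the study conditions (6 h movie, 5-min
frames, baseline ratio 1.0, pulse amplitude 0.5, noise sd 0.05), call its
peaks, and classify its dynamics:

```r
library(mapkdyn)

sim <- simulateTrace(pulseTrainParams(meanRate = 2, seed = 7))
sim$truth$peakTimes
#> [1]  27.69843  76.41520 130.41933 198.80642 264.57170 326.33938

pk <- countPeaks(sim$trace)
pk
#> PeakSet for cell sim_1: 6 peak(s)
#>   times (min): 28.1, 76.2, 130.6, 198.8, 263.7, 325.7

classifyDynamics(pk, sim$trace, windowMin = c(120, 360))
#> DynamicsCall for cell sim_1: pulsatile
#>   peaks 6, duty cycle 0.41, final-window mean 1.240
```

The caller recovers all six programmed pulses with sub-frame apex times
(within ~1 min of truth here).  The duty cycle (fraction of
post-induction frames above the activity threshold of 1.25) stays well
below the sustained cutoff of 0.8, so the cell is labeled pulsatile.

Quantify extrusion from a simulated coculture stack with a programmed
6 µm apical offset:

```r
zsim <- simulateZStack(zStackSimParams(extrusionOffsetUm = 6, seed = 1))
quantifyExtrusion(zsim$stack)
#>   position delta_z_um converged
#> 1    pos_1   5.500519      TRUE
```

The recovered ΔZ is within sampling error of the programmed 6 µm: each
stack holds ~15 inducible nuclei whose true z-centers scatter with sd
1.5 µm, so a single position's ΔZ has a standard error of ~0.4 µm
(averaging replicate positions recovers the offset, as the validation
suite measures).

Compare migration-angle distributions with the subsampled KS procedure:

```r
set.seed(2)
before <- runif(3000, 0, 180)                  # unbiased epoch
after  <- abs(rVonMises(3000, 0, 1)) * 180 / pi  # biased toward 0 deg
subsampledKsTest(after, before, nIter = 1000, nSub = 1000, seed = 3)
#> Subsampled two-sample KS: median p = 0 (***)
#>   1000 iterations, subsample sizes 1000/1000
```

A thin command-line front end is installed with the package
(`system.file("scripts", "mapkdyn.R", package = "mapkdyn")`) with
subcommands `simulate`, `run`, `peaks`, `migrate`, `extrude`, `edu-fold`,
`shed-filter`, and exit codes 0/2/1 for success/validation error/runtime
error.  `runPipeline()` chains simulate → analyze → report from a single
YAML config and writes a manifest with per-file checksums.

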