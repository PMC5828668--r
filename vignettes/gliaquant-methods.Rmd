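---
title: "gliaquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gliaquant quantifies oligodendrocyte-scale biology from two kinds of raw
data: tiled fluorescence images of reporter-labeled somata, and extracellular
recordings from white matter and cortex. This vignette explains the methods
the package implements, the assumptions behind them, the tunable parameters,
and the design decisions taken where more than one reasonable reading
existed. It states no empirical result beyond what the package's own test
suite and acceptance script compute.

## The soma-counting algorithm

Tiled confocal stacks (10 µm thick, 0.8 µm/pixel in the default
calibration) are maximum-projected to 2D and normalized to a 0–1 intensity
scale by dividing by the bit-depth maximum (`normalize_intensity()`); we do
not min–max stretch, so thresholds keep the same meaning across tiles. The
algorithm then proceeds:

1. **Process suppression by grayscale opening** (`open_filter()`). A
   morphological opening (erosion then dilation) with a discrete disk
   removes bright structures narrower than the disk — in reporter-labeled
   tissue, the thin (≈1–2 px) glial processes — while somata wider than the
   disk keep their interior intensity. Opening is anti-extensive, so output
   never exceeds input.
2. **Strict thresholding** (`binarize()`): a pixel is positive iff its
   opened intensity is *strictly greater* than the threshold.
3. **Connected components** (`label_objects()`), 8-connectivity by default,
   with deterministic raster-order IDs.
4. **Small-object removal** (`remove_small()`): components of area
   *strictly below* 5 px are discarded as too small to be a cell.
5. **QC**: the fraction of objects *strictly above* 50 px is reported
   (`qc_large_fraction()`) — an indicator of how much object merging is
   present, not a branch condition.
6. **Erosion splitting** (`split_merged()`): binary erosion of the object
   mask with a 1 px disk separates touching cells at thin waists; the
   resulting components are the final cells. An object that erodes away
   completely is *retained as one cell* at its original centroid — small
   cells must not vanish from the count.
7. **Density** (`count_and_density()`): cells whose centroid falls in the
   ROI, divided by ROI area × depth.

### Design decisions

- **Opened image is thresholded directly, not a difference image.** The
  background-handling step could be read either as top-hat subtraction
  (image − opening) or as thresholding the opened image. Top-hat *keeps*
  thin bright structures and removes wide ones — the opposite of
  suppressing processes to recover cell bodies — so gliaquant thresholds the
  opened image. The alternative reading remains available by composing the
  primitives by hand.
- **Disk rasterization.** The structuring element is
  `{(dr, dc) : dr² + dc² ≤ r²}` (`disk_kernel()`), stated explicitly because
  disk rasterization differs across image-processing ecosystems. Radii may
  be fractional; the shipped presets keep the reported user-mean radii
  (WT 8.72 px, mutant 5.26 px) rather than rounding them.
- **Splitting applies to every surviving object**, not only those above the
  50 px QC cutoff; the cutoff is reported, not acted on. `count_cells(...,
  split_large_only = TRUE)` restricts erosion to large objects for
  comparison.
- **Strict inequalities throughout**: positive ⇔ value > threshold; removal
  ⇔ area < 5 px; QC ⇔ area > 50 px. A pixel exactly at the threshold is
  negative.
- **Volume basis.** Densities use ROI area × the 10 µm projected-stack
  depth by default. Where a physical section thickness (e.g. 30 µm) is the
  appropriate denominator, set `depth_um` accordingly; the package does not
  guess.
- **ROI membership by centroid** (rounded to the nearest pixel) rather than
  any-pixel overlap, so a cell straddling two tiled ROIs is counted once.
- **Presets are presets.** `seg_preset("WT")` (radius 8.72, threshold 0.14)
  and `seg_preset("null")` (5.26, 0.15) package the reported blinded-user
  means; every analysis accepts arbitrary `segmentation_params()`.

### Connectivity

Components use 8-connectivity by default, matching the common default of
connected-component routines in image-analysis toolboxes; 4-connectivity is
available. The labeling itself is a two-pass union-find written for this
package because the installed image stack exposes only 4-connectivity; it is
validated against an independent flood-fill oracle in the tests.

## Colocalization

Double-positive counting is **object-based**: somata are detected per channel
with the counting algorithm and matched by centroid (`match_objects()`),
greedy nearest-first, one-to-one, accepting pairs within a configurable
radius (default 10 px, the largest default soma radius). One-to-one matching
prevents one large object from claiming several partners; ties break
deterministically by (distance, A id, B id). `coloc_metrics()` reports the
double-positive density and both conditional percentages, with 0/0 reported
as missing rather than 0. Pixel-intensity correlation (Pearson/Manders) is
out of scope: the quantity of interest is cells, not overlap area.

## Compound action potentials

`detect_cap_peaks()` finds, within per-component search windows, the most
negative sample (latency) and measures amplitude against the preceding
positive peak within the window. Windows default to
N1 ∈ (blank, blank + d/0.8 m/s] and N2 from the N1 bound to blank +
d/0.1 m/s — generous envelopes around physiological fast/slow callosal
speeds, configurable because published peak definitions are conventionally
inherited by citation rather than stated. Latencies are averaged across the
(by default four) sweeps per distance; misses are counted, never imputed.
`fit_conduction_velocity()` regresses mean latency (ms) on distance (mm);
the inverse slope is the velocity in m/s, with slope SE and r² retained for
the between-genotype ANCOVA (`compare_slopes()`).

**Absence is a first-class outcome.** A deflection is reported only when its
trough lies below the pre-stimulus baseline mean by at least
`prominence_sd` baseline SDs (default 5) *and* by an absolute floor
(default 0.01 voltage units). The extreme value of Gaussian noise over a
several-hundred-sample window routinely exceeds 3 SD, so a 3-SD rule would
fabricate fast peaks in recordings that genuinely lack them; 5 SD keeps the
per-window false-detection probability below about 10⁻⁴ while real
deflections in the simulated regime sit tens of SDs deep. The absolute floor
covers noiseless records, where the SD criterion is vacuous.

## LFP band power

`spectrogram_power()` computes a one-sided short-time power spectral density
with 1 s windows and 90% overlap (1 Hz resolution), Hamming-windowed —
mirroring the defaults of the standard spectrogram routine when only length
and overlap are specified. Scaling follows the Welch convention: summing
power × Δf over frequency recovers the windowed signal variance, which the
tests verify against white noise (Parseval check) and against an
explicit-DFT oracle. Band power uses bins with f_low ≤ f ≤ f_high; a window
belongs to an epoch when its center falls inside it. The baseline epoch is
the 1 s ending at odor onset; the response epoch is 0.5–2.5 s after onset,
aligned with the behavioral scoring window. Group comparisons use the
two-sided Mann–Whitney U test — exact null when both groups have n ≤ 8 and
no ties, normal approximation with tie correction otherwise — with
Benjamini–Hochberg correction across bands. BH is the standard FDR choice
when a methods citation does not pin a specific variant.

## Cohort statistics

- `percent_of_wt()` / `percent_change()` are ratio statistics on group
  means; the SEM of the ratio is propagated by the delta method, the
  conventional choice when a ratio ± SEM is reported without a stated
  propagation rule.
- `blocked_anova()` implements the repeated-measures comparison as a
  two-factor least-squares ANOVA with animal as the blocking error stratum:
  `aov(value ~ genotype * region + Error(animal))`. Genotype is tested
  against between-animal variance; region and the interaction against the
  within-animal residual. No sphericity correction is applied (none was
  specified; with two or three regions the impact is limited, and the
  type-I error of the genotype test is verified empirically at ≈5% in the
  suite). Which factor is "repeated" is an explicit property of the input
  table, not a guess: the blocking factor is always `animal`, and the
  within factor is whatever varies within animals in the table.
- Pairwise per-region genotype contrasts are Welch t tests with Sidak
  adjustment `1 − (1 − p)^m` over the number of regions.
- `compare_slopes()` is the standard equal-slopes ANCOVA: the
  distance × genotype interaction in a pooled OLS.

## The synthetic-data generator

Every analysis is validated end to end on synthetic data whose ground truth
is known exactly. The generator emulates the statistical structure the
analyses assume — not the optics of any instrument.

**Tiles** (`generate_tile()`). Somata are placed by a uniform point process
at the requested density; the realized count is `round(density × volume)`
(the fractional remainder is dropped deterministically, which matters at low
densities: a 1 mm² × 10 µm tile at 558 cells/mm³ realizes 6 cells, i.e. a
true per-tile density of 600). Non-overlap is enforced by rejection sampling
at a minimum centroid separation of twice the maximum soma radius, keeping
ground-truth counts unambiguous; object merging is exercised separately with
dedicated fixtures (bridged discs). Each soma is a uniform-intensity disk
with a Gaussian-blurred edge (default radius 8–10 px — a 13–16 µm cell body
at 0.8 µm/px, the scale of mature oligodendrocyte somata; edge SD 1.5 px
emulating point-spread blur; peak 0.5–0.8). The flat core is what lets a
soma survive opening with the WT-preset 8.72 px disk, and the compact edge
keeps thresholded footprints from merging at the minimum separation.
Processes are 2 px polylines (40 per mm², intensity 0.2–0.4) — suppressed by
any opening radius ≥ 1. Background is a smooth low-frequency field
(amplitude 0.05; the heterogeneity of real backgrounds is not characterized
quantitatively anywhere we could anchor to, so this is a plausible choice,
not a fit), plus i.i.d. Gaussian noise (SD 0.01).

**Cohorts** (`generate_cohort()`). Animal densities are group density ×
a unit-mean lognormal factor (positive by construction) with CV 0.07,
matching the between-animal dispersion implied by published tiled-section
densities (SEM ≈ 3–4% of the mean at n = 4). All per-tile seeds derive
deterministically from the cohort seed.

**CAP sweeps** (`generate_cap_sweeps()`). Baseline Gaussian noise plus two
negative Gaussian deflections centered at `onset + d/v`; the waveform shape
is not parameterized in any published source, so a Gaussian of configurable
width is used. Defaults: v(N1) = 1.5 m/s (the published fast-component
scale), v(N2) = 0.3 m/s (unmyelinated-axon scale, chosen well apart from N1
so the two deflections do not overlap at the shortest electrode separation),
100 kHz sampling, 0.3 ms onset offset, 0.02 ms latency jitter. Amplitude
saturates with stimulus current via a Hill curve (s50 = 1 mA, exponent 3),
emulating axon recruitment. A null-like mode omits N1.

**LFP** (`generate_lfp()`). Per trial, each band is a sum of unit-spaced
sinusoids with random phases whose amplitude steps from baseline to response
at odor onset (defaults: theta 6–14 Hz, 1 → 1.5; beta 15–30 Hz, 0.5 → 0.8;
24 kHz sampling; odor at 1.5 s for 2.5 s), plus white noise.

### What passing on synthetic data does and does not show

The generator gives exact ground truth, so the suite demonstrates that the
*algorithms* are implemented correctly and recover known parameters under
the stated statistical structure: near-exact count recovery, velocity
recovery to sample-grid precision, chance-level colocalization under
independence, nominal type-I error for the blocked ANOVA. It does **not**
demonstrate robustness to what real tissue adds: intensity-correlated
backgrounds, anisotropic somata, densely fasciculated processes, section
artifacts, electrode drift or movement artifacts. Parameters that a blinded
user would tune per image (opening radius, threshold) still need tuning on
real data; the presets only package previously reported user means.

### Numerical conventions

- Images are (row, col), 1-based, origin top-left; ROI membership uses the
  nearest-pixel centroid.
- Morphology at borders uses the in-bounds part of the neighborhood (the
  convention of the underlying image library, matched exactly by the test
  oracles).
- All generator randomness flows from a single integer seed via a splittable
  derivation, and every serialized dataset echoes its seed; identical specs
  are byte-identical.
- Degenerate inputs are conventions, not errors, where a convention is
  defensible: empty object sets give QC 0 and density 0; identical constant
  groups give p = 1; a non-positive latency slope gives an undefined
  velocity with a diagnostic; 0/0 percentages are missing.

### Problem sizes used by the shipped checks

The test suite and acceptance script size their simulations to be
informative yet quick: 20 tiles per density point for recovery checks, 10
tiles for count agreement, 3 animals × 3 tiles per group for cohort
statistics, 300–400 replicates for the type-I-error property, and a few
hundred Monte-Carlo draws for the colocalization chance band. These sizes
give sampling error comfortably below the tolerances being checked.

## Known limitations

- The counting pipeline is 2D after maximum projection; overlapping cells in
  depth merge and are recovered only insofar as erosion splitting separates
  them. No watershed or model-based segmentation is attempted.
- Erosion splitting with a 1 px disk separates thin waists only; heavily
  overlapped footprints count as one cell (the QC fraction flags when this
  is frequent).
- The spectrogram assumes a uniformly sampled, gap-free signal.
- `blocked_anova()` is least-squares with one blocking stratum, not a
  mixed-effects maximum-likelihood fit; unbalanced designs beyond mild
  unbalance deserve `lme4`.
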