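---
title: "Natural-log frequency band decomposition: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural-log frequency band decomposition: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n3lband)
```

## The model

Mammalian brain oscillations organise into bands whose centre frequencies sit
at adjacent integers on a natural-log axis (the natural-log-linear, N3L,
law): the band with centre index $n$ is centred at $e^n$ Hz and spans
$(e^{n-0.5},\, e^{n+0.5})$ Hz, so adjacent bands have the constant edge ratio
$e$. Which of these theoretically fixed bands a given recording can actually
resolve is determined entirely by its sampling parameters. For a recording
with sampling interval $T_R$ (seconds per sample) and $N$ samples, the
Nyquist–Shannon theorem gives

$$f_{max} = \frac{1}{2 T_R}, \qquad f_{min} = \frac{1}{2 N T_R},$$

and the discrete Fourier grid has bin width $\Delta f = 1/(N T_R)$.

`n3lband` turns this into a concrete filter bank in four steps:

1. enumerate the integer centre indices $n$ whose bands intersect the usable
   grid;
2. snap each theoretical upper edge to the nearest DFT bin,
   $K(n) = \mathrm{round}(e^{n+0.5}\, N T_R)$ (halves away from zero);
3. clip band $n$'s bin interval $[K(n-1), K(n)]$ to the usable range
   $[\texttt{minCycles}, \lfloor N/2 \rfloor]$, dropping empty bands and
   flagging clipped ones as truncated;
4. band-pass by DFT bin masking: forward-transform each unit's series, zero
   every bin the band does not own (together with its negative-frequency
   mirror, preserving Hermitian symmetry), inverse-transform and keep the
   real part.

Adjacent bands share an edge bin. Ownership is half-open — each band owns
$[\mathrm{lo}, \mathrm{hi})$ — except that the highest band also owns its
final (Nyquist-side) bin. The owned bins therefore partition the usable
grid, which gives the filter bank its two key exactness properties: the band
components plus the residual (DC and sub-floor bins) reconstruct the input
to floating-point accuracy, and band variances sum to the input variance
(Parseval). Because bin 0 is never owned, every band component has zero mean
per unit by construction; no window, taper or detrending is applied inside
the filter.

## Tunable parameters

* `minCycles` (default 6, dimensionless): the usable floor bin, i.e. the
  minimum number of full cycles an oscillation must complete within the
  record. The theoretical limit $f_{min}$ corresponds to half a cycle; a
  floor of one bin (one full cycle) is still a very unstable estimate. The
  default of 6 is the value uniquely consistent with both reference band
  tables this package reproduces (lowest retained edges at bin 6 on both
  grids: $6\,\Delta f = 0.033$ Hz at 9.285 Hz/1672 samples and $0.007$ Hz at
  $T_R = 0.72$ s/1200 volumes); it is exposed because the right floor for
  other designs is a judgement call.
* `sphereRadiusMm` (default 50 mm): the reference sphere radius that
  converts rotation changes (degrees, converted to radians internally) into
  arc-length displacement in the framewise-displacement (FD) sum — the
  standard Power convention.
* `thresholdMads` (default 5) and `window` (default 11 samples) for the
  despiker, see below.
* `nKeep` (default 1672 samples): the analysis window retained from the
  zeroed time point of a motion log; at 9.285 Hz this is just over three
  minutes.
* `kSd` (default 3): the outlier rule — subjects whose full-band mean FD
  exceeds the group mean by more than `kSd` group SDs are flagged, in one
  pass over all non-short subjects, before any band-wise analysis.
* `minWidthRatio` (default 0.1) in `analysisBands()`: bands whose snapped
  width is below this fraction of their theoretical width (typically the
  Nyquist-truncated top band) are excluded from band-wise statistics. This
  is an analysis choice, not decoder behaviour: the decoder always keeps and
  flags truncated bands.
* ALFF is the mean over the band's owned bins of the single-sided amplitude
  spectrum $(2/N)\,|X_k|$. The mean (not the sum) keeps truncated bands
  comparable with full-width ones; `summary = "sum"` switches conventions.
* ICC: per parcel, a subject-random-intercept model fitted by REML;
  $\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$ with variance
  components non-negative by parameterisation, so ICC $\in [0, 1]$.
  `model = "twoway"` adds a fixed occasion effect (the consistency
  variant); `method = "anova"` gives the classical closed-form estimator
  $(BMS - WMS)/(BMS + (k-1)\,WMS)$, clamped to $[0,1]$, which for balanced
  designs agrees with REML to numerical precision and serves as an
  independent cross-check. Reports annotate ICC $\ge 0.8$ as the
  conventional clinical-reliability threshold.

## Numerical choices

* **Edge snapping** rounds halves away from zero. Display rounding (the CLI
  band table) is 3 decimals, also half-away; all files carry full
  precision.
* **Edge frequencies are bin values.** A reported edge is always
  $\mathrm{bin} \times \Delta f$ on the recording's own grid. Published
  tables for the two worked configurations occasionally print an edge digit
  consistent with a slightly rounded sampling rate instead (e.g. the
  Slow-2/Slow-1 edge at $T_R = 0.72$ s prints as 0.607 in the literature,
  which is bin 524 on a 1.389 Hz grid, while bin 524 on the exact
  $1/0.72$ Hz grid is 0.6065 Hz $\to$ 0.606). This package always uses the
  stated sampling parameters exactly and does not imitate those rounding
  artefacts; the affected digits differ by at most one unit in the third
  decimal.
* **Strategy equivalence.** The three execution strategies (`whole`, ten
  near-equal serial chunks, ten chunks in parallel on up to 10 cores) are
  bit-identical because each unit's transform is independent; `auto`
  chooses `whole` below a ~1 GiB working set, parallel chunking when at
  least 4 physical cores are available, serial chunking otherwise. On
  platforms without fork-based parallelism the parallel strategy falls back
  to serial with a warning.
* **Despiking.** The trend is a running median (default 11 samples); the
  robust scale is `mad(diff(x))/sqrt(2)`, which tracks sample-to-sample
  noise while ignoring both the slow trend and the spikes themselves.
  (The more obvious choice, the MAD of the residuals from the running
  median, is zero-inflated — the median of a mostly monotone window is the
  centre point itself — and over-flags ordinary noise.) Samples deviating
  from the trend by more than `thresholdMads` scale units are replaced by
  the trend value, so the operator is idempotent on spike-free data and a
  repaired spike lands exactly on the local trend. Constant series pass
  through unchanged. This is a self-contained robust operator, not a port
  of any external despiking command.
* **Degenerate inputs.** Recordings whose floor bin reaches the Nyquist bin
  raise a no-decodable-band error; zero-variance parcels yield `NA` ICC;
  zero-SD maps refuse standardisation; non-finite samples are rejected
  naming the offending unit; the first FD sample, having no predecessor, is
  defined as 0.
* **Ranks and ties.** Rank maps assign 1 to the lowest value and break ties
  by lower parcel index, so a rank map is always a permutation of $1..P$.

## What the synthetic generators emulate

`genBandSignal` places one sinusoid per requested band at the bin nearest
the band centre $e^n$ (clamped into the band's owned bins, so edge
ownership never blurs the ground truth) plus white Gaussian noise; a
sinusoid of amplitude $A$ contributes variance $A^2/2$.

`genMotionCohort` emulates a developmental mock-scanner cohort: ages
uniform over 3–16 years, equal sexes, and six-parameter logs whose
parameter increments are white noise scaled per subject by
$e^{a\,\mathrm{age} + b}$ with multiplicative log-normal noise (default
SD 0.05), keeping FD positive for the log transform. Defaults are 42
subjects per sex with $a = -0.1$, $b = 1$. Because increments are white,
every band's mean |FD| is proportional to the subject scale: the log-linear
age fit recovers the slope $a$ in every band, while band intercepts are
offset by a fixed band constant. Logs include a pre-zero segment and end
buffer so the zero-point windowing path is exercised.

`genTestRetest` draws, per parcel, subject effects
$\mathcal N(0, \sigma_b^2)$, visit effects $\mathcal N(0, \sigma_v^2)$ and
scan residuals $\mathcal N(0, \sigma_e^2)$. The short-term table holds two
scans of one visit (shared visit effect), so the true short-term ICC is
$(\sigma_b^2+\sigma_v^2)/(\sigma_b^2+\sigma_v^2+\sigma_e^2)$; the long-term
table holds one draw per visit, giving
$\sigma_b^2/(\sigma_b^2+\sigma_v^2+\sigma_e^2)$. Any visit-level variance
therefore makes long-term reliability lower than short-term, mirroring the
empirical pattern the design emulates.

What the generators deliberately do **not** model: spatial autocorrelation
between voxels or parcels, physiological (cardiac/respiratory) noise,
scanner drift, 1/f spectral shape, or realistic motion spike morphology.
Passing recovery tests on these cohorts therefore demonstrates that the
estimators are correct and calibrated under their stated models — not that
real acquisitions satisfy those models. In particular, the
frequency–reliability gradient is checked on data *constructed* with
band-dependent between-subject variance; it is a data property, not a
property of the estimator.

## Test problem sizes

The packaged tests use problem sizes chosen to make the statistical checks
sharp while keeping the default suite quick to run: full-length recordings
(1672 and 1200 samples) wherever a published band table or closed form is
checked; 84-subject cohorts for slope recovery (slope SE $\approx 0.002$,
comfortably inside the $\pm 0.02$ check); 42 subjects $\times$ 2 occasions
$\times$ 400 parcels for ICC recovery; 500 null replicates for the
repeated-measures interaction calibration (binomial SE $\approx 0.01$ on a
0.05 rate); and 60–200 replicates for the remaining Monte-Carlo
properties.

## Known limitations

* The 6-cycle floor is a reconstruction from the two reference band tables;
  the behaviour of other implementations in untested regimes (very short
  records, exact-half snapping ties) may differ.
* NIfTI support covers 4D volumes; surface containers (CIFTI/GIFTI) and
  DICOM are out of scope, as are GPU execution and O(N·T) time-domain
  bandpass alternatives.
* `parcelIcc` fits one mixed model per parcel; for tens of thousands of
  units the closed-form `method = "anova"` is the practical choice (they
  agree on balanced designs).
* The repeated-measures ANOVA assumes a balanced within-subject band factor
  and reports the unadjusted F tests (no sphericity correction); with the
  small numbers of bands used here that is the conventional choice.
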