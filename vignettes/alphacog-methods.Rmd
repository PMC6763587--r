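---
title: "Estimating fatigue-induced alpha peak shifts from multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fatigue-induced alpha peak shifts from multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Exhaustive physical exercise shifts the dominant frequency of alpha-band
(7.5-13 Hz) EEG activity upward by a few hundredths to tenths of a hertz.
Detecting such a shift reliably - especially with dry-electrode caps, which
trade preparation time for a higher channel-failure rate - requires a
pipeline in which every stage has a known, tested contract: channel quality
control, band limitation, referencing, spatial interpolation, spectral
estimation, a gate against spurious "alpha" in subjects without a clear
peak, and a within-subject analysis of variance. `alphacog` implements that
pipeline and pairs it with a synthetic study generator whose ground truth
is known exactly, so every stage is verifiable end to end without access to
human recordings.

## The estimand: centre-of-gravity iAPF

The individual alpha peak frequency (iAPF) is computed on the *whole-head
mean* power spectral density $\bar P(f)$ (the unweighted average over all
64 channels, interpolated channels included) as the spectral centre of
gravity over the alpha band:

$$\mathrm{iAPF} \;=\; \frac{\sum_{f \in [7.5,\,13]} w_f\, f\, \bar P(f)}
 {\sum_{f \in [7.5,\,13]} w_f\, \bar P(f)},$$

with trapezoid integration weights $w_f$ (band-edge bins count half). The
COG is preferred over the argmax because it is well defined for broad or
split peaks, lies in $[7.5, 13]$ by convexity, and is invariant to positive
rescaling of the spectrum. A whole-head array rather than a posterior
region of interest reduces sensitivity to inter-individual topography and
cap-placement variability.

The iAPF is only computed when *considerable alpha activity* is present:
the maximum of $\bar P$ in the alpha band must be at least 1.3 times the
neighbour power, defined as the mean of the theta-band (4-7.5 Hz) and
beta-band (13-30 Hz) average powers. Two readings of "average power of the
neighbouring bands" are possible; we weight the two bands equally (mean of
the two per-band averages) rather than per hertz, because the 17 Hz-wide
beta band would otherwise dominate the 3.5 Hz-wide theta band. The
threshold is inclusive (a ratio of exactly 1.3 counts as present). Subjects
failing the gate in one or more gated phases are excluded entirely.

Phase-level iAPF is the COG of the interval-averaged mean PSD, not the mean
of per-interval COGs - matching the convention of determining the iAPF "in
the mean PSD". `run_pipeline()` follows this default; a `per_interval`
mode (one COG per 30 s interval, averaged) is available through
`pipeline_config(iapf_mode = "per_interval")`, and the two agree closely
on stationary data because the COG is nearly linear in local spectral
perturbations.

## Processing chain and its parameters

Per phase segment, in order:

1. **Channel QC** (`detect_bad_channels`). A deterministic stand-in for
   expert visual inspection: a channel is bad iff the cumulative duration
   of a failure condition exceeds 30 s. Conditions are evaluated on 1 s
   windows: isoelectric (window SD < 0.1 uV), saturated (>= 50% of samples
   within 1% of the channel's observed rail, applied only when the rail
   exceeds 100 uV - physiological scalp EEG stays far below that, which
   disambiguates "constant at a small value" from "stuck at a rail"), and
   artifactual (window RMS with robust median/MAD z-score > 5). All
   thresholds are configurable; the defaults are fixed for
   reproducibility. QC runs per phase segment, before filtering, on the
   raw data. The artifactual detector's median/MAD baseline assumes the
   contaminated stretch is under half the segment, which holds for
   paradigm-length (>= 120 s) segments.
2. **Bandpass** (`bandpass`): 30th-order Butterworth, 1-40 Hz, realized as
   a cascade of 15 second-order sections designed in zero-pole-gain form
   (an expanded 30-pole transfer function polynomial is numerically
   singular). The cascade is applied forward-backward: phase handling is
   not fixed by convention in spectral work, and zero-phase application
   keeps edge transients symmetric while PSD analysis is insensitive to
   phase. Single-pass -3 dB points sit exactly at 1 and 40 Hz; the
   magnitude response is squared by the two passes. Edge effects are
   handled by odd-reflection padding of 10 s, after which residual DC
   leakage is below 1e-3 of the input offset. Roundoff through the
   30-pole cascade leaves numerical noise around 1e-4 of the signal scale
   (about -80 dB in power), irrelevant for spectral estimates.
3. **Average reference** (`average_reference`): every channel minus the
   mean of the good channels, making results independent of the physical
   reference (mastoid for the dry cap, CPz for the gel cap). The good-
   channel mean is zero to 1e-10 afterwards; the operation is idempotent.
4. **Spherical-spline interpolation** (`interpolate_bad`): bad channels are
   reconstructed from good ones with unit-sphere splines (order m = 4,
   Legendre series truncated at 50 terms, ridge 1e-5 on the spline
   system). Constants are reproduced exactly; leave-one-out error on
   smooth low-order fields is below 5% for interior electrodes. With
   fewer than 10 good channels interpolation is refused and the mean PSD
   falls back to good channels only.
5. **Welch PSD** (`welch_psd`): segments are divided into consecutive
   complete 30 s intervals; within each, periodograms of 4 s Hann windows
   at 50% overlap are averaged, and all windows of all intervals are
   pooled. The 4 s window gives a 0.25 Hz grid - fine enough that COG
   discretization bias is far below the 0.01 Hz reporting precision, with
   14 averages per interval - and places 7.5 and 13 Hz exactly on grid
   points. Normalization is one-sided density: the PSD integrates to the
   signal variance (unit-amplitude sine -> 0.5 within 2%).

The statistics consume phases II (pre-cycling), IV (active recovery) and V
(passive recovery), all eyes closed. Phase I (baseline) and Phase III
(cycling) are processed for QC, reliability and PSD but excluded from iAPF
statistics - Phase III because heavy movement makes it unreliable. The
subject-exclusion gate is evaluated over the analyzed phases plus Phase I
eyes-closed, the minimal defensible reading of "one or more paradigm
phases"; the set is configurable.

## The RM-ANOVA engine

`rm_anova_2x3()` implements the 2 (cap: gel, dry) x 3 (phase: II, IV, V)
fully within-subject decomposition from explicit sums of squares, testing
each effect against its own subject-by-effect stratum. Sphericity is
assessed per effect with Mauchly's W on the covariance of orthonormal
contrast scores; the Greenhouse-Geisser epsilon from the same covariance
(bounded by $1/(k-1)$ and 1) corrects the degrees of freedom, and the
corrected p-value is reported whenever Mauchly's p < 0.05 ("in case of
non-sphericity"). The two-level cap factor is spherical by construction.
Effect size is partial eta squared, $SS_e/(SS_e+SS_{err})$, labelled
small/medium/large at 0.01/0.06/0.14 (inclusive); pairwise effects use
Cohen's d at 0.20/0.50/0.80.

Two conventions are not identifiable from summary reports and are declared
in the output metadata rather than assumed silently: Cohen's d uses the
paired-differences convention $d_z = \bar d / s_d$, and observed power uses
the noncentral F with $\lambda = F \cdot df_{num}$ (the convention of
common commercial statistics packages). Post hoc phase comparisons are
paired t-tests on cap-averaged values with p multiplied by 3 and clipped at
1. Identical phase columns yield d = 0 and p = 1; zero-variance differences
with nonzero mean are refused.

The engine is verified in two independent ways: against `aov()` error
strata for the F decomposition and against `car::Anova()` for Mauchly and
epsilon (agreement to 1e-8), and by simulation - on null tables the phase
effect rejects at the nominal 5% (binomial 99% band over 500 studies),
while tables drawn with the study's phase means and n = 13 are detected in
the vast majority of runs with the cap effect at the null rate.

## The synthetic study generator

The generator emulates the five-phase cycling paradigm: Phase I baseline
(2 min eyes open, 2 min eyes closed), Phase II pre-cycling (120 s), Phase
III cycling (duration free; 180 s by default at desk scale, where the real
task runs to exhaustion over many minutes), Phases IV and V recovery
(120 s each), recorded at 1024 samples/s on 64 channels for both cap
types (idealized equidistant and extended 10-20 spherical montages).

Per channel the signal is

* **alpha**: band-filtered noise with a truncated-Gaussian spectrum,
  symmetric about its centre with support wholly inside (7.5, 13) Hz, so
  the component's band COG equals its centre exactly. A pure sinusoid
  would make the COG trivially the tone frequency and hide discretization
  errors. Default full width at half maximum 2 Hz; eyes-closed whole-head
  band power 17 uV^2, i.e. a whole-head peak density near 8 uV^2/Hz,
  matching the scale of resting eyes-closed grand averages; eyes-open
  alpha power is 1/3.5 of eyes-closed (the 7.8 vs 2.25 uV^2/Hz peak
  contrast). The scalp weighting is dipolar-like - posterior-dominant in
  magnitude with zero spatial mean - because a physical source projects
  both polarities onto the scalp; the zero mean also makes the component
  exactly invariant under average re-referencing (an all-positive
  weighting would be cancelled by it). Half of the alpha power is a
  common source, half per-channel independent with the same spectrum,
  emulating the partial inter-electrode coherence of scalp alpha.
* **background**: independent per-channel 1/f noise (exponent 1, density
  1 uV^2/Hz at 10 Hz).
* **movement-artifact bursts**: Poisson-timed 0.5-3 s windows of
  5x-amplitude broadband noise on a random fifth of the channels; 0.2/min
  in seated phases, 6/min during cycling.
* **injected failures** (per-channel Bernoulli at a per-phase rate):
  isoelectric (constant), saturated (rail-clipped at 500 uV), or
  artifactual (a > 30 s stretch of 12x amplitude), each detectable by the
  QC definitions. Default rates are one minus the reference reliability
  fractions (dry 0.20/0.34/0.09 and gel 0.05/0.15/0.18 for phases
  I/III/V, with interpolated values for II and IV).

**Ground truth.** The `true_iapf` of a phase is the band COG of the *total*
expected spectrum. Because the 1/f background alone has a band COG near
10.0 Hz, the generator solves analytically for the alpha-component centre
that makes the mixture COG hit the configured target; without this the
recovered iAPF would be biased toward 10 Hz by a few hundredths of a hertz.
Default targets for phases II/IV/V are 10.22/10.36/10.41 Hz (dry) and
10.23/10.37/10.43 Hz (gel) - the monotone fatigue shift. The fatigue shift
is encoded purely as per-phase targets with no within-phase drift, since
the analysis operates on phase-level means.

Between-subject variation is an additive offset drawn N(0, 0.26^2) Hz and
then centred to exactly zero mean, so the realized study grand mean equals
the configured per-phase value; without centring, the sampling error of
~17 subject offsets (0.26/sqrt(17) = 0.06 Hz) would dominate the +-0.05 Hz
recovery check and make it a test of the random number generator rather
than of the pipeline. "Alpha-deficient" subjects (4 of 17 by default) have
zero alpha power in one analyzed phase; with a 1/f background the presence
ratio is then about 1.17 analytically (theta mean 1.80, beta mean 0.49,
alpha max 1.33 in background units), safely below the 1.3 gate, whereas a
visible-but-weak bump would sit so close to the boundary that the exclusion
count would become a coin flip.

All randomness flows from one root seed through a documented per-unit
derivation, so identical seeds reproduce the study - and its manifest -
byte for byte, and single units can be regenerated in isolation.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: no biophysical forward model (no dipole
geometry, head conductivity, or realistic inter-channel covariance), no
ocular/cardiac/myogenic artifacts, no sweat-impedance coupling or
electrode drift, no non-stationarity within phases, and no empirical SNR -
the alpha-to-background ratio is a plausible choice, not a fit. The
within-subject residual is only the spectral-estimation noise (~0.015 Hz),
far below the session-to-session physiological variability of real iAPF
measurements, so F statistics and Cohen's d computed on synthetic studies
come out much larger than empirical values; only their direction and
calibration (type-I rate) are meaningful. The pipeline's correctness on
this model is necessary, not sufficient, for correctness on human EEG.

## Numerical choices and degenerate inputs

* EDF I/O quantizes to 16 bits against the physical range actually written
  into the 8-character header fields, so a write-read cycle is exact to
  half a digital step; the sampling rate must be an integer (one data
  record per second). Phase annotations are written both as an EDF+
  annotation signal and as a JSON sidecar; the sidecar wins on read and
  also restores exact sample counts when the last second was zero-padded.
  Signals dimensioned mV or V are converted to uV on read.
* Time is seconds; sample indices are 0-based half-open intervals, so a
  120 s phase at 1024 samples/s is exactly 122880 samples and segmentation
  partitions the recording.
* The filter refuses non-SOS realization, NaN output, and sampling rates
  below twice the upper band edge. Interpolation refuses fewer than 10
  good channels; averaging refuses fewer than 2. A zero neighbour power in
  the presence gate yields an infinite ratio (present) with a warning.
  `compute_iapf` on an all-zero band is an error, as is calling the ANOVA
  with n < 3 or with missing cells.
* Flat spectra give a presence ratio of exactly 1 (absent); the 1.3
  boundary is inclusive.

## Problem sizes used by the tests and scripts

The test suite exercises module contracts at 128-256 samples/s with
reduced studies, and runs the end-to-end recovery check at the full
paradigm scale: 17 dry-cap subjects, failure-free, 1024 samples/s, phases
II/IV/V, asserting each recovered phase grand mean within +-0.05 Hz of its
target and the II < IV < V ordering. `scripts/acceptance.R` runs the
complete default study - 17 subjects, both caps, phase-dependent failure
rates, 4 alpha-deficient subjects - and recomputes every reported quantity
from scratch. The RM-ANOVA calibration uses 500 simulated null iAPF tables
drawn from the additive subject-plus-noise model (the engine's input
contract), not 500 full EEG studies. The `analysis/` drivers run a reduced
4-subject replica at 128 samples/s so the whole workflow can be re-read,
re-run and inspected in minutes.

## Known limitations

* The QC thresholds are proxies for expert judgment, chosen for
  determinism; they are not validated against human raters.
* The spherical montages are idealized geometries, not digitized caps;
  interpolation accuracy on a real head will differ near the cap edge.
* Impedances are aggregated as given numbers (the generator draws them
  lognormal with the reported start/end moments); the package does not
  model impedance physics, and deliberately does not use impedance for
  channel rejection - impedance is a poor predictor of dry-electrode
  channel quality.
* Observed power and Cohen's d follow declared conventions that may differ
  from other software's defaults; compare conventions before comparing
  numbers.
* The 15% agreement bound for disjoint white-noise Welch estimates holds
  at 300 s realizations (the chi-squared sampling error of 4 s Hann
  windows at 50% overlap is ~16% per 120 s estimate, ~22% for a
  difference), so the consistency test uses the longer duration.
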