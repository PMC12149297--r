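---
title: "Complexity and spectral analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and spectral analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegrc)
```

# Scope

`eegrc` implements a complete analysis chain for multichannel resting-state
EEG as used in dementia research: spectral band power, two fractal-dimension
estimators, long-range temporal correlations (LRTCs) of alpha-band amplitude
envelopes, regional summaries over the rostrocaudal axis of the 10-20
montage, and the between-group statistics that compare diagnostic groups
(healthy controls, Alzheimer's-type and frontotemporal-type dementia).
Because clinical recordings cannot ship with a package, a seeded
synthetic-cohort generator reproduces the statistical structure the analysis
assumes, so every stage is testable offline.

# The processing chain

Each recording passes through:

1. **Broadband filtering**, 1-45 Hz, 4th-order Butterworth applied
   forward-backward (zero phase). Zero-phase filtering matters here because
   fractal-dimension estimators operate on waveform shape, which a causal
   filter would distort.
2. **Common average referencing** — each channel minus the instantaneous
   mean of all channels.
3. **Epoch selection** — the earliest contiguous 15 s window in which no
   sample exceeds 100 microvolts on any channel. The 100 uV guard is the
   conventional scalp-EEG rejection threshold; recordings in this setting
   arrive with large artifacts already removed upstream, so the guard is a
   safety net. The position of the epoch within a recording is not uniquely
   determined by convention; earliest-clean-window is ours, and analyses of
   real data that used a different convention will differ slightly.
4. **Band power** — Welch-averaged periodograms (2 s Hamming windows, 50%
   overlap, 0.5 Hz native resolution re-gridded to 1 Hz steps by bin
   summation). The canonical bands tile 1-45 Hz half-open — delta [1,4),
   theta [4,8), alpha [8,13), beta [13,30), gamma [30,45] — so absolute band
   powers sum exactly to the broadband power and relative powers to one.
   Relative power is per channel: band power divided by the 1-45 Hz total
   (the five-band union; we do not normalize by a wider recording band).
5. **Fractal dimension**, two ways (below), on the broadband-filtered epoch.
6. **Alpha LRTCs** — 300 s of the filtered, re-referenced recording is
   narrowband filtered to 8-13 Hz (window-method FIR, 2 Hz transition,
   applied with its group delay compensated), the Hilbert amplitude envelope
   is extracted (1 s trimmed per edge, which exceeds the filter's group
   delay at 500 Hz), and detrended fluctuation analysis (DFA) is run per
   channel.
7. **Regional summaries** — arithmetic means over all 19 channels, the 7
   rostral channels (Fp1, Fp2, F7, F3, Fz, F4, F8) and the 7 caudal channels
   (T5, P3, Pz, P4, T6, O1, O2), plus the rostrocaudal asymmetry index
   (rostral mean minus caudal mean; positive = rostral dominance). The five
   mid-chain channels belong to neither region.
8. **Group statistics** — one-way ANOVA with `r^2` effect size, Tukey HSD
   pairwise comparisons reported alongside per-pair pooled t and Cohen's d
   (the quantities conventionally printed), Pillai's-trace MANOVA over the
   band profile, Mann-Whitney U (min-U convention) for non-normal settings,
   a D'Agostino-Pearson normality screen reported as a diagnostic only, and
   channelwise t maps with Benjamini-Hochberg FDR correction applied within
   each metric-by-comparison family of 19 channels (not pooled across
   metrics).

# Fractal-dimension estimators

**Box counting.** The signal graph is normalized to the unit square (time to
[0,1], amplitude min-max to [0,1]); dyadic grids of box size
`eps = 2^-j`, `j = 1..floor(log2(N)) - 2`, are laid over it; the boxes
crossed by the linearly interpolated curve are counted per grid; the FD is
the least-squares slope of `log N(eps)` against `log(1/eps)`, clamped to
[1, 2]. A constant signal reports FD 1 with a degenerate-input flag. The
dyadic ladder and the unit-square normalization make the estimator
deterministic and amplitude invariant. Box counting is applied to the whole
15 s epoch without sub-windowing.

**Higuchi.** For each step size `k` and offset `m`, the normalized curve
length `L_m(k)` uses the standard `(N-1) / (floor((N-m)/k) k^2)` factor;
`L(k)` is the mean over offsets and the FD is the slope of `log L(k)` vs
`log(1/k)`. The step-size grid is exhaustive (`1..kmax`) up to `kmax = 64`
and `1..16` plus ~25 log-spaced values beyond, bounding the `O(N k)` cost
while preserving the fit. HFD is computed in non-overlapping 1 s windows
whose values are averaged per epoch. The default `kmax` is 126 at 500 Hz
and 32 at 128 Hz. Note that at 500 Hz with 1 s windows, `kmax = 126` leaves
as few as two curve-length segments at the largest step; the implementation
therefore requires only `k <= N/2` rather than a more conservative margin —
the settings in actual use demand it.

**kmax scan.** `kmaxScan()` computes the 19-channel-average HFD of every
subject at every tested `kmax` and selects the value whose across-subject
mean is closest to the median of the mean-HFD-versus-kmax curve. The
selection rule deserves a note: "the kmax corresponding to the median HFD
across subjects" is ambiguous between a median over subjects at fixed kmax
and a median over the kmax curve. We implement the latter
(closest-to-median-of-curve), which reduces to the middle element for any
monotone curve over an odd-length kmax list; the choice is recorded in the
scan object. Curve lengths are computed once per window over the union of
all step grids, so scanning hundreds of kmax values costs little more than
the largest one.

Calibration facts used by the test suite: a straight line has FD 1; Gaussian
white noise approaches 2 (Higuchi reaches 2.00 +/- 0.01 at 15 s, 500 Hz;
box counting saturates slightly lower, around 1.84, because at fine grids
the per-column sample range grows only logarithmically); fractional Brownian
motion with Hurst exponent H has FD `2 - H`, which Higuchi recovers almost
exactly and box counting with a mild compression (regression slope ~0.8
across H in 0.2..0.8, within the 1 +/- 0.2 acceptance band).

# DFA of amplitude envelopes

The envelope is mean-centred and cumulatively summed into a profile; for
each of 10 window sizes log-spaced (base 10) over the 0.8-30 s calculation
interval, the profile is cut into 50%-overlapping windows, each linearly
detrended (order-1 detrending, the common default), the RMS of residuals is
taken per window, and `F(n)` is the mean RMS. The scaling exponent is the
least-squares slope of `log10 F` vs `log10 n` restricted to 2-25 s, with
the RMS log residual reported as a goodness-of-fit diagnostic. "Number of
windows = 10" is interpreted as ten logarithmically spaced window *sizes*
spanning the calculation interval — the toolbox convention this mirrors —
and an explicit size vector can be passed to override the grid. Window
sizes under 4 samples are skipped with a warning.

Calibration facts: uncorrelated noise gives alpha = 0.5, pink (1/f) noise
gives alpha near 1, and for fractional Gaussian noise alpha equals the
Hurst exponent. One subtlety the tests make visible: the Hilbert envelope
of *narrowband-filtered white noise* is not an uncorrelated series — its
low-frequency spectrum declines gently across the fit band (the envelope
spectrum of a B-wide band falls off toward B) — so the measured exponent
sits near 0.54-0.55 rather than exactly 0.5 over a 2-25 s fit at a 5 Hz
bandwidth. This is a property of the benchmark signal, not an estimator
bias: the same value emerges from a naive non-overlapping reference
implementation, and DFA applied to genuinely uncorrelated draws returns
0.49-0.50.

# The synthetic cohort

`genCohort()` builds 19-channel recordings (default: three groups of 20
subjects, 300 s at 500 Hz — long enough for DFA, sized like the study
cohorts this pipeline addresses). Each channel is the sum of:

- **band-limited Gaussian noise** per canonical band, scaled to the group's
  band-amplitude profile. Patient-like profiles raise delta/theta and
  suppress alpha relative to the alpha-dominant control profile;
- the **alpha component amplitude-modulated** by a strictly positive affine
  transform of fractional Gaussian noise whose Hurst exponent sets the
  envelope's LRTC strength (controls ~0.8, patient-like groups ~0.7, with
  the caudal region set slightly apart so caudal effects dominate);
- a **complexity component**: 1-45 Hz band-limited noise with spectral
  density proportional to `1/f^(2H+1)` — the in-band analogue of
  fractional Brownian motion, for which FD = 2 - H holds — whose amplitude
  is larger in patient-like groups (lowering broadband FD) and whose H
  varies linearly along the rostrocaudal axis: the AD-like gradient puts
  the higher FD rostrally, the FTD-like gradient caudally, and the control
  profile is flat.

All unmodulated components are drawn in a single spectral synthesis per
channel (independent Gaussian components combine in quadrature in the
amplitude profile), and the envelope modulator is synthesized at 25 Hz and
upsampled — its scaling at the DFA fit scales (2-25 s) is unaffected, and
cohort generation stays under 2 s per subject. `genSignal()`'s `fgn`/`fbm`
families, used for estimator calibration, keep exact circulant-embedding
(Davies-Harte) synthesis instead, because calibration demands an exact
autocovariance.

Subject-level variability is lognormal jitter on the band and complexity
amplitudes and Gaussian jitter on the Hurst parameters, with per-subject
seeds derived from the master seed — regeneration is bit-identical.
Effect magnitudes were set by pilot calibration so that planted
patient-vs-control contrasts land on the Cohen's d ~ 1-3 scale at n = 20
(the scale the underlying literature reports), with every planted direction
detectable at p < 0.05; between-subject amplitude jitter is the main noise
source for box-counting FD, which is why the box-relevant contrasts are the
largest planted ones.

What the generator does **not** emulate: volume conduction and channel
covariance (channels are independent), non-Gaussian artifacts, eye/muscle
components, non-stationary drowsiness effects, and realistic topographies
beyond the rostrocaudal gradient. Passing tests on synthetic cohorts
therefore validate the estimators and the inference machinery, not the
clinical claims themselves.

# Numerical choices and degenerate inputs

- Filters reject edges at or beyond Nyquist; the narrowband FIR length is
  `ceil(3.3 fs / 2)` (Hamming design, ~53 dB stopband), forced odd so the
  group delay is an integer.
- The Hilbert transformer is the standard frequency-domain one-sided
  weighting; envelopes are edge-trimmed before DFA.
- Welch estimates compensate window power so broadband variance is
  preserved; the tone-concentration and variance checks in the tests bound
  the error at 10%.
- Degenerate inputs: constant signals report FD 1 with a flag; a constant
  fluctuation function yields alpha 0; groups with all-identical values
  return a degenerate ANOVA flag rather than NaNs; zero pooled variance is
  an error for Cohen's d.
- Cohen's d is signed (first group minus second); two-group Tukey reduces
  to the pooled t test; `t = d sqrt(n1 n2 / (n1 + n2))` links the two and
  is property-tested.
- The MANOVA over relative band powers drops the gamma band: the five
  relative powers sum to one, so the full profile is singular by
  construction and four bands carry all the information.
- EDF I/O uses a +/-1000 uV physical range over the 16-bit digital range
  (quantization step ~0.03 uV), one record per second; T5/P7, T6/P8, T3/T7
  and T4/T8 label dialects are unified to the T labels on read, and
  non-montage channels (A1/A2 references, ECG, ...) are dropped with a
  warning. EEGLAB `.set` (a MATLAB container) is not parsed; recordings
  should be exported to EDF or the package's TSV+JSON fixture format.

# Problem sizes in the test suite

The calibration tests run at the study conditions — 300 s at 500 Hz for
everything DFA-related (20+ seeded replicates), 15 s epochs for spectral
and FD calibration — and the end-to-end effect-recovery test runs the full
default cohort (3 x 20 subjects, 19 channels, 300 s at 500 Hz). Unit tests
for the module mechanics use smaller signals chosen to exercise the same
code paths at a fraction of the cost.

# Known limitations

- The box-counting estimator's dyadic ladder includes coarse grids that
  saturate for rough signals and fine grids that under-resolve them; its
  absolute values compress toward the middle of [1, 2] relative to theory,
  which is why group *contrasts*, not absolute FD levels, are the meaningful
  output (the same caveat applies to the published EEG literature on box
  counting).
- DFA fit intervals shorter than a decade (2-25 s) make single-channel
  exponents noisy (sd ~0.04 on 300 s); regional averages over 7+ channels
  are the intended unit of analysis.
- The epoch-selection convention (earliest clean window) is one of several
  defensible choices and shifts per-subject values slightly on real data.
- Statistics assume independent subjects; no covariate adjustment
  (age, severity scores) is implemented.
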