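---
title: "Methods: capacitive ECG/EMG analysis in capsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capacitive ECG/EMG analysis in capsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsig)
```

## The measurement problem

A capacitive biopotential channel couples the body to the front end
through an insulator (e.g. a pillowcase over a cloth electrode), forming
a plate capacitor of some tens of picofarads. The source biopotential —
R-waves and cough EMG with amplitudes around 100 µV — is divided between
the coupling impedance and the front-end input impedance, so the front
end must present an input impedance several orders of magnitude above
the coupling reactance; this is achieved by a bootstrapped varistor in
the voltage follower. The analysis task downstream is fourfold: detect
R-waves on the capacitive channel and quantify the detection against a
contact reference; verify that cough bursts raise the 40–500 Hz spectral
content; compare frequency-domain HRV between the two channels; and
evaluate the front-end circuit analytically. `capsig` implements all
four stages plus a synthetic generator of paired sessions.

## Conventions

All times are seconds from record start; sample `i` (1-based in R) of a
`time_series` occurs at exactly `t0 + (i − 1)/fs`; intervals are
half-open `[start, end)`, and slicing at non-aligned times rounds the
start up and the end down to sample times. These choices remove every
off-by-one ambiguity when segments are cut, concatenated and compared.
Recorded channels are assumed to share one clock. The digitizer model
uses `2^bits` levels spanning `[vmin, vmax]` *inclusive* — both range
bounds are representable, so clipping a +15 V excursion with a ±10 V
range yields exactly +10 V — giving an in-range error bound of half of
one level spacing, `(vmax − vmin)/(2^bits − 1)/2`.

## R-wave detection

The emphasis chain is a centered 20-ms moving average (edges truncated
to the available samples), an IIR band-pass at 10–20 Hz, and the finite
difference `x[n] − x[n − D]` with `D = round(0.010·fs)` (leading `D`
output samples set to zero). The band-pass is a 4th-order Butterworth
applied forward–backward: only "IIR, 10–20 Hz" is inherent to the
method, and the zero-phase realization keeps detected extremum times
alignable with ground truth, which matters when detections are compared
to simulated R apexes. The moving-averaged signal is demeaned before
filtering; DC lies in the stop band, so this is a mathematical no-op for
the ideal filter but suppresses the start-up transient of the zero-phase
pass on records with large offsets.

The threshold is `0.8 ×` the mean amplitude of five assumed R-waves.
Candidates are local extrema of the dominant polarity separated by at
least the refractory period (default 0.25 s, i.e. HR ≤ 240 bpm, enforced
greedily from the largest magnitude down). Polarity is auto-detected as
the sign whose top candidates have the larger mean magnitude —
capacitive channels frequently present R-deflections as troughs — and
can be overridden. Two selection modes exist: `"random"` (seedable
draw without replacement, mirroring a manual "selected in a random
manner" procedure) and the deterministic `"largest"` default. A
magnitude floor (default 40% of the largest candidate) keeps small
ripples from being treated as assumed R-waves; if a single dominant
artifact starves the candidate set below five, the floor is dropped
rather than failing, which reproduces the realistic failure mode of a
threshold estimated from noise.

Detections are emitted at the extremum of each maximal run of samples
beyond the threshold, with refractory suppression keeping the
larger-magnitude detection.

### Beat matching and metrics

The matching rule is RR-interval agreement: a detected beat is correct
when its RR interval lies within ±10 ms of the corresponding reference
RR interval. Whether beats should first be *paired* or RR sequences
compared positionally is genuinely open; `capsig` pairs beats greedily
by nearest time within a 0.15 s window and then applies the ±10 ms rule
to each paired beat whose predecessor is also paired. This construction
makes the counts conserve — every RR-bearing test beat becomes TP or FP,
every RR-bearing reference beat TP or FN — and reduces to the obvious
answer on identical trains (k beats give k−1 TP, since a first beat
carries no RR interval). True negatives are not countable events for a
beat detector, so `n_tn` is fixed at 0, which implies
`P_ACC ≤ min(P_SNS, P_PPV)`. Metrics with zero denominator are reported
as `NA`, never 0. Display rounding is one decimal, half away from zero
(base `round()`'s round-half-even would report 87.45 as 87.4).

## Cough-segment TSA analysis

EMG channels are band-passed at 40–500 Hz (4th-order zero-phase
Butterworth). Segment boundaries were identified manually in the
original workflow; `capsig` automates them with a short-time RMS
envelope (50 ms window): activity is `envelope > μ_rest + 5·σ_rest`
with the rest statistics taken from the designated rest period, the
search is restricted to ±3 s around each recorded stamp, and mask gaps
shorter than 0.5 s are bridged so the two coughs of a cycle form one
segment. All five constants are config-exposed
(`segment_selection_config()`); the defaults were chosen once from the
physiology (a cough burst lasts a few hundred milliseconds; intra-pair
gaps are well under half a second; a 5σ onset criterion is a standard
surface-EMG choice).

The first and last cycles are excluded, the mean duration (MD) of the
interior segments computed, and each interior segment replaced by a
window of `1.2·MD` centred on its midpoint. Five resting windows of the
same duration are tiled over the rest period, skipping any tile whose
envelope maximum crosses the activity threshold — the automated
counterpart of visually excluding swallowing/inhalation firings.

The spectrum is an unwindowed single-sided DFT (`(2/N)|X_k|`, with
`1/N` weighting at DC and Nyquist); a Hann option exists but the
rectangular window is canonical, since the statistic sums amplitudes
rather than estimating a density. The TSA is the sum of amplitude bins
with `40 ≤ f ≤ 500` Hz, inclusive at both edges on the DFT grid —
whether the original statistic summed bins or integrated a density is
not decidable from its description; the bin sum is implemented and
documented, and every conclusion drawn from it here is a comparison
between segments of equal length, for which the two conventions differ
only by a constant factor. Resting vs coughing TSAs are compared
pairwise, gated on Shapiro–Wilk normality of the paired differences at
α = 0.05 (no specific normality test is inherent to the method; the gate
must only decide t vs Wilcoxon), one-sided in the direction coughing >
resting, two-sided available by flag. All-zero differences make the
signed-rank test undefined and are reported as an `NA` sentinel.

## HRV band power

RR intervals are attached to the latter beat, cubic-spline interpolated
onto an 8 Hz grid, and a Welch PSD (Hann window, 256-sample segments,
50% overlap, demeaned) is summarized per band: VLF DC–0.04 Hz (DC bin
excluded), LF 0.04–0.15, HF 0.15–0.40, VHF 0.40–3.00 Hz. The per-band
statistic is the *mean* PSD over in-band bins, switchable to the
integrated power. The commercial HRV analyzer that produced the bundled
validation PSDs uses an unpublished estimator, so absolute PSDs are not
reproduction targets; the estimator here is validated by simulation
properties instead (injected LF/HF RR modulation must peak in its band,
and doubling the modulation depth must quadruple the band power), while
the error-rate arithmetic `100·|ref − test|/ref` is exact on the bundled
PSD pairs. Those pairs are printed rounded, so recomputed error rates
can differ from the reported ones by one unit in the last printed digit;
the headline values (maximum 0.43%, per-band means ≤ 0.2%) reproduce
exactly.

## Front-end circuit model

All impedances are treated as real magnitudes at a stated frequency —
the same approximation the design arithmetic itself uses; a
complex-phasor mode is out of scope. The varistor inequality
`−V_thr < v < +V_thr` is open, so the boundary `|v| = V_thr` needs a
convention and is assigned to the clamped (low-impedance) branch. The
permittivity default `8.85e−12 F/m` is the absolute permittivity: the
plate-capacitor arithmetic `C = εS/d → 57.5 pF` only works with that
reading. The piecewise approximation `Z ≈ R1·Rh/R3` below threshold
agrees with the exact expression within `(R1+Rh)/(R1·Rh/R3)` relative
error, which the test suite asserts numerically.

## The synthetic generator

`synth_cough_session()` emulates the experimental protocol: ≥2 min rest,
seven "cough twice" cycles, rest. Design choices:

* **Gaussian-bump ECG template** (P, Q, R, S, T bumps at fixed offsets)
  rather than a published dynamical model: the pipeline consumes only
  morphology ratios (R vs T amplitude) and timing, and Gaussian bumps
  keep every oracle analytic (the trace extremum *is* the R apex; the
  low-pass response of a bump is closed-form).
* **RR model**: mean RR plus sinusoidal LF/HF modulation plus white
  jitter, redrawing any interval below 0.25 s.
* **Bursts** are white noise band-passed to 40–500 Hz and scaled to a
  target RMS — matching the analysis band by construction. Defaults:
  0.4 s bursts, 0.3 s intra-pair gap, 5 s between cycles, burst RMS
  10× the 20 µV rest floor, capacitive EMG at half the reference burst
  amplitude (the electrode-output EMG amplitude is a free parameter; no
  value is inherent to the method).
* **Annotation stamps** are placed at cycle midpoints — only "a stamp
  was recorded for reference" is inherent; the midpoint makes the
  segment search symmetric.
* **Capacitive distortion** is a causal first-order low-pass (corner
  `hf_attenuation`) plus extra noise/wander; the "degraded-subject"
  profile used in validation is R 30 µV, T 60 µV, corner 15 Hz, 50 µV
  white noise and 50 µV wander — a T-over-R morphology with in-band SNR
  near 2, the regime in which a fixed-threshold detector demonstrably
  breaks down.
* **Determinism**: one seeded generator per session; equal seeds give
  bit-identical sessions, and the RNG state of the caller is restored.

What the generator does **not** emulate: respiration and
ballistocardiographic coupling, electrode motion artifacts, power-line
interference, non-stationary burst spectra, or the physiological
correlation between cough motion and heart rate. Passing tests
therefore demonstrate the correctness of the *pipeline arithmetic* under
controlled conditions, not field performance on real recordings.

## Problem sizes and numerical tolerances

The test suite runs sessions at 2 kHz (the EMG band needs only
fs > 1 kHz) and full 10 kHz for the 2-min detection checks; the
multi-seed TSA property uses 100 sessions. Spectral leakage makes TSA
shift-invariance approximate; the documented tolerance is 15% for a
stationary band-limited signal. Parseval consistency of the amplitude
spectrum is asserted to 1e−9 relative. Filter stability of the
narrow-band 10–20 Hz design at 10 kHz was verified directly (order-4
Butterworth sections remain stable at normalized frequencies of 2–4e−3).

## Known limitations

* The threshold detector is deliberately simple; modern QRS detectors
  (e.g. Pan–Tompkins-family or learned detectors) are out of scope.
* Cough counting and the discrimination of cough vs inhalation vs
  swallowing are not addressed.
* The greedy nearest-time pairing in `match_beats()` is one reasonable
  construction of the matching step; alternative pairings can change
  counts on pathological trains.
* Absolute HRV PSD values depend on the estimator; only relative
  (error-rate) comparisons between channels processed identically are
  meaningful.
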