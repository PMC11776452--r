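---
title: "Measuring audience cardiorespiratory synchrony with cardiosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring audience cardiorespiratory synchrony with cardiosync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiosync)
```

## The problem

When an audience listens to the same music, individual heart and breathing
rhythms can become weakly coupled — to the stimulus and to each other —
through shared attentional and orienting responses. `cardiosync` quantifies
that coupling from continuous ECG and respiration-belt recordings cut per
music piece, and contrasts it between presentation modalities (live,
audio-visual "AV" vs. loudspeaker, audio-only "AO"). Because the effects
are small (sliding-window correlations on the order of 0.02–0.1), every
inferential step — surrogate testing, section averaging, mixed models — is
part of the method, and all of it is implemented and tested here against a
synthetic audience generator with known ground truth.

## Pipeline overview

1. **Preprocessing** (`interpolate_gaps()`, `filter_physio()`,
   `detect_r_peaks()`, `detect_resp_peaks()`, `apply_peak_overrides()`,
   `reject_piece()`): raw 1000 Hz signals → clean, strictly increasing peak
   trains. Respiration is low-passed at 2 Hz, ECG band-passed 0.6–20 Hz
   (Butterworth, 4th order), both demeaned. Filtering is applied
   forward–backward (zero phase) so it cannot bias the phase measures.
2. **Rate and phase** (`peaks_to_rate()`, `fit_cycle_phase()` /
   `cycle_phase_from_peaks()`): peak trains → instantaneous BPM and wrapped
   cycle phase on a common 20 Hz grid.
3. **Stimulus features** (`spectral_flux()`, `audience_band()`,
   `subband_phase()`): audio → spectral flux (25 ms Hann frames, 50%
   overlap, Euclidean distance between consecutive magnitude spectra) and
   its phase inside the audience's heart/respiration frequency bands.
4. **Synchrony** (`src()`, `isc()`, `srpc()`, `ispc()`,
   `estimate_group_lag()`): four families in 10-s windows advanced by 1 s.
5. **Inference** (`circular_null_test()`, `fdr_adjust()`,
   `aggregate_time_averaged()`, `epoch_around_boundaries()`,
   `fit_modality_models()`, `window_contrasts()`, `sanity_paired_test()`,
   `boundary_rate_profile()`).

`run_pipeline()` executes all stages from one seeded configuration and
writes every result table with a config hash.

## The measures

With rate series $x_p(t)$ (BPM, 20 Hz) and stimulus flux $f(t)$:

* **SRC** (stimulus–response correlation): windowed Pearson
  $r\{f(t),\,x_p(t+\ell)\}$ at the constant group lag $\ell$.
* **ISC** (inter-subject correlation): windowed Pearson for every
  participant pair within one concert, combined by Fisher
  $z$-averaging $\tanh\{\mathrm{mean}\,\mathrm{atanh}(r)\}$, with $r$
  clipped at $1-10^{-12}$ so the transform stays finite on degenerate
  windows.
* **SRPC / ISPC** (phase coherence): per time point the phase-clustering
  statistic $\bigl|n^{-1}\sum_r e^{i\theta_r(t)}\bigr|$ over the two (or
  pairwise) phase series, averaged within the window. For two signals this
  equals $|\cos(\Delta\theta/2)|$. Because the time-resolved reading of the
  clustering formula is ambiguous, a phase-locking-value mode
  (`mode = "plv"`, modulus of the window-averaged phasor of the phase
  difference) is also exposed; the per-time-point reading is the default.

**Window convention.** The sliding window is 10 s long. The phrase "1-s
overlap" in the source protocol is read as a 1 s *hop* (9 s overlap): the
boundary-epoch analysis needs per-second synchrony resolution to populate
five 6-s windows, which a 9 s hop could not provide. A 60 s series at 20 Hz
therefore yields 51 windows. The hop is configurable (`hop_s`) and echoed
into run metadata.

**Cycle phase.** Per cycle $k$ one period of
$A\sin(2\pi f_k t + \theta)$, $f_k = 1/\mathrm{IBI}_k$, is synthesised with
its maximum on the detected peak; the concatenated surrogate's
analytic-signal angle gives phase 0 at peaks and $\pm\pi$ mid-cycle. The
surrogate is built over whole cycles only (half-open $[p_1, p_N)$), which
makes a perfectly periodic train an exact DFT grid: the angle at peaks is
then zero to machine precision. At physiological beat-to-beat variability
(±10%) the angle at detected peaks stays within 0.1 rad; at implausible
variability (±30%) the analytic-signal step itself deviates up to ~0.17 rad
near cycle joints — an intrinsic property of the construction, which is why
implausible cycles (outside 0.33–3 s for heart, 1–20 s for respiration) are
masked rather than interpolated.

**Rate interpolation.** Each interval's BPM is anchored at the *interval
midpoint*: an interval measures the average rate over its span, so the
midpoint keeps the series time-unbiased. Anchoring at the second peak
(the moment the interval becomes known) would delay the whole rate series
by half a cycle (~0.5 s at 1 Hz) and push every stimulus–response lag
estimate past the one-cycle search bound, making the lag procedure
unusable; we verified this directly. Anchored rates are linearly
interpolated at `fs_interp` (default 1000 Hz, the raw sampling rate) and
decimated to 20 Hz through a zero-phase anti-alias low-pass. Because the
BPM signal carries almost no energy above a few Hz, `fs_interp` of 100 or
even 20 Hz is numerically indistinguishable (correlation > 0.9999 with the
1000 Hz path) and is used in the package's simulation studies for speed.

**Group lag.** Per participant, lags from 0 to one mean cycle duration are
scanned on the 50 ms grid; the score is the correlation (or coherence)
between stimulus and lag-shifted response over the first 10 s after onset.
For the correlation family the stimulus is first low-passed at 0.5 Hz
(zero phase): heart and respiration rate cannot track faster flux
modulation, and restricting the scan to the response band sharpens the lag
objective without shifting its peak (the smoothing is symmetric).
Participants with no positive score at any lag are excluded and logged.
The group lag — the mean of individual optima — is applied as one constant
for all participants. The constants observed in concert data
(HR 579 ms, RR 1573 ms, heart phase 500 ms, respiration phase 1820 ms) are
shipped as documented, data-dependent defaults for `lag_mode = "fixed"`;
they are properties of those recordings, not universal values.

## Significance testing

Time-locking is tested by circular shifting: each permutation rotates every
participant's raw peak train by an independent uniform offset modulo the
piece length (so the derived rate *and* phase series inherit the shift
coherently, and each signal's autocorrelation is preserved), re-runs the
measure pipeline, and records a one-sample *t* over the time-averaged
observations (participant/pair × section, pooled). With 1000 permutations
(package default; studies here use 200),
$p = (1 + \#\{t_{\mathrm{null}} \ge t_{\mathrm{obs}}\})/(1 + n)$.
Benjamini–Hochberg FDR adjusts across measures. The suite verifies the
test is calibrated: under independent participants the 5%-level rejection
rate over 200 seeded runs falls inside the exact binomial 95% interval.

## Aggregation and epochs

Time-averaged synchrony is the mean of window values whose centers fall in
each annotated musical section — 7/9/9 sections over the three pieces, so
25 observations per participant, condition and measure — with a 30-s-bin
mode as a length-controlled check. Time-resolved analysis cuts ±15 s
epochs around section boundaries into five 6-s windows with edges at
{−15, −9, −3, 3, 9, 15} s. The conventional labels {−10, −5, 0, 5, 10} are
kept even though the partition's geometric centers are {−12, −6, 0, 6, 12};
the geometry is fixed by the partition and the labels are cosmetic.
Boundaries within 15 s of a piece edge are dropped and logged.

## Modality models

`fit_modality_models()` fits the maximal structure the design motivates —
fixed effect(s) of modality (plus time window and their interaction for
epoched tables), random intercepts for concert, piece and participant
(participants globally unique, hence nested in concerts; participant and
piece crossed), and a by-participant modality slope. When a fit does not
converge cleanly or is singular it walks a declared ladder: drop the slope
correlation → drop the slope → drop the smaller-variance of the
concert/piece intercepts → participant-only intercept. The path is stored
in the fit and reported. A final-stage fit that is merely singular (a
boundary estimate, common when true variance components are tiny) is
returned with a note; only a model that cannot be fitted at all errors.
Wald 95% CIs, Satterthwaite p-values and Nakagawa marginal/conditional
R² accompany every fit; `emmeans`-based `window_contrasts()` gives AO−AV
contrasts per window (Bonferroni over the five windows) and
window-vs-boundary contrasts within modality. A paired t/Wilcoxon check
(Shapiro gate at α = 0.05 on the AO−AV differences) runs alongside.

## The synthetic audience

The generator is first-class, tested code: every downstream stage is
validated against it. Each participant's instantaneous heart (and
respiration) rate is

$$\lambda(t) = \mathrm{base} + g \cdot d(t-\ell) + o(t) + \eta(t),$$

where $d$ is the normalised stimulus drive (z-scored spectral flux,
low-passed at 0.5 Hz, zero phase), $\ell$ the participant's lag, $o$ the
orienting waveform, and $\eta$ smooth noise (white noise on a 2 Hz grid,
spline-interpolated, scaled to `noise_sd_bpm`). Peaks are realised by
time-rescaling — a peak is emitted whenever $\int \lambda/60$ advances by
one — so rate modulation maps exactly onto inter-beat intervals and a
constant 60 BPM gives exactly unit intervals.

Defaults are the study conditions: two concerts of 8 participants, three
180-s "pieces" with 7/9/9 sections, AV and AO versions of each; base
heart rate drawn near 1.01 Hz (sd 0.04), respiration near 0.30 Hz
(sd 0.015); lag 600 ms (near the observed HR constant, on the 50 ms
grid); orienting depth 0.5 BPM (matching the observed boundary-window HR
offsets of ~0.46–0.53 BPM); noise 1.5 BPM, a realistic slow HR wander.
Coupling gain defaults to 1 BPM per unit drive, which produces the weak
windowed SRC levels (~0.05) typical of real audiences.

**The orienting waveform** is a raised-cosine dip spanning 20 s with its
minimum (−depth) at the boundary: rate decelerates over the 10 s into the
boundary and accelerates back over the 10 s after it. This sign pattern —
boundary window lowest, windows ±10 highest — is the pattern the epoched
HR models recover. It is applied only when the condition enables it
(AV by default), which is deliberately a free parameter rather than a
mechanistic claim about what visual presence does.

**What the generator does not emulate:** ECG morphology pathology,
heart-rate variability spectra (LF/HF structure), respiratory sinus
arrhythmia, movement artifacts, or inter-participant coupling that is not
stimulus- or boundary-driven. Passing tests therefore demonstrate that the
*pipeline* recovers known structure under realistic noise — not that real
audiences behave like the generator.

**A measurement ceiling worth knowing about.** With zero noise, windowed
SRC is scale-invariant in the coupling gain and plateaus around 0.22–0.28:
a rate series reconstructed from ~1 Hz beat events cannot track flux
content above roughly half the beat rate, which bounds its windowed
correlation with broadband flux regardless of how strong the coupling is.
The package's power study runs at that plateau; real-data SRC values sit
far below it.

## Numerical choices

* **Zero-phase filtering** wraps `signal::filter` with odd-reflection
  padding scaled to the filter's settling time and DC-matched initial
  conditions; plain `filtfilt` (zero initial conditions) leaves large edge
  transients — on a constant series it does not even return a constant.
* **Sub-band flux filtering** happens on the 20 Hz analysis grid: the
  4th-order Butterworth for the respiration band (0.268–0.358 Hz) is
  numerically unstable at the 80 Hz native frame rate (a pole modulus
  exceeds 1) and stable at 20 Hz.
* **Analytic signal** is the standard FFT construction (positive
  frequencies doubled), written in-package.
* **Fisher-z clipping** at $|r| = 1-10^{-12}$; coherence and correlation
  outputs are clipped to their ranges against floating-point overshoot and
  asserted on every run.
* **Degenerate inputs**: zero-variance windows are masked, not zero;
  degenerate audience bands (no spread) are widened by ±0.05 Hz and
  flagged; empty sections yield masked rows; boundaries near piece edges
  are dropped.
* **Determinism**: all randomness is seeded per participant/run through a
  local RNG scope that never disturbs the session RNG; identical config
  and seed reproduce byte-identical pipeline outputs.

## Problem sizes in the test and acceptance studies

Simulation studies use sizes chosen to make their statistical target
well-estimated while keeping the full suite quick to run: the calibration
study uses 200 runs × 200 permutations on 30-s pieces with 4 participants
(the binomial acceptance interval at 200 runs is what constrains the run
count); the power study 50 replicates on 60-s pieces; lag recovery one
60-s piece with 16 participants; CI coverage 100 replicates of the full
25-observation design. Rate interpolation in these studies uses the
coarser grids documented above. The defaults of every function remain the
full-scale settings.

## Known limitations

* The QRS detector is a derivative-energy matched-amplitude detector tuned
  for the rendered synthetic morphology and clean recordings; heavily
  artifacted ECG would need the manual edit-list path.
* Peaks at the very edge of a piece are recovered with reduced timing
  accuracy (filter edge effects); round-trip guarantees hold for interior
  peaks.
* The per-participant ISC used for modelling (Fisher-z mean over the pairs
  a participant belongs to) double-uses each pair; the permutation test,
  which pools observations, is the calibrated inferential route.
* Phase-family permutation statistics cost roughly an order of magnitude
  more than the correlation family and are off by default in
  `run_pipeline()` (available via `statistic_srpc()` / `statistic_ispc()`).
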