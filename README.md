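# cardiosync

Audience cardiorespiratory synchrony analysis: from raw ECG and
respiration-belt signals (or a fully synthetic concert audience) to
stimulus–response and inter-subject synchrony, circular-shift permutation
significance, and audio-visual (AV) vs. audio-only (AO) contrasts.

## The scientific problem

When people listen to the same music, attention-driven responses —
orienting decelerations of heart rate at structural boundaries, slow rate
modulation tracking the sound — can weakly couple their physiology to the
stimulus and to each other. `cardiosync` measures that coupling with four
sliding-window synchrony families on a common 20 Hz grid:

* **SRC** — stimulus–response correlation: windowed Pearson r between
  spectral flux f(t) of the audio and a participant's instantaneous heart
  or respiration rate x(t + ℓ), at a constant group lag ℓ estimated from
  the first 10 s of each piece (`estimate_group_lag()`).
* **ISC** — inter-subject correlation: windowed Pearson r for every
  participant pair within a concert, combined by Fisher z-averaging,
  tanh(mean(atanh r)).
* **SRPC / ISPC** — the phase-coherence counterparts on wrapped cycle
  phase θ(t) (0 at each R-peak / inspiration peak, ±π mid-cycle), using
  the phase-clustering statistic |n⁻¹ Σ e^{iθ}|.

Significance comes from circular-shift surrogates (each participant's peak
train rotated by a uniform random offset modulo the piece length, the full
measure pipeline re-run, a one-sample *t* over time-averaged observations,
1000 shifts by default) with Benjamini–Hochberg FDR across measures.
Synchrony is averaged per annotated musical section (7/9/9 sections over
three pieces → 25 observations per participant, condition and measure) or
epoched ±15 s around section boundaries into five 6-s windows, then
contrasted between AV and AO with linear mixed models (`lme4`, with a
declared simplification ladder) and `emmeans` pairwise window contrasts.

A seedable synthetic audience generator (`simulate_audience_study()`)
provides ground truth for every stage: inhomogeneous point-process heart
and breath trains (time-rescaling, so rate maps exactly onto intervals),
stimulus-coupled rate modulation at a known lag, and deceleration–
acceleration orienting dips at boundaries, applied in AV only.

## Worked example

Simulate a 6-person audience hearing a 60-s piece with one section
boundary, recover the stimulus lag, and test SRC-HR against its
circular-shift null:

```r
library(cardiosync)
set.seed(42)

st    <- generate_stimulus(stimulus_spec(60, 30,
           random_tone_schedule(60, 2, 4), piece_id = "demo"))
parts <- draw_audience(6, seed = 7, coupling_gain = 4, lag_ms = 600)
aud   <- generate_audience(st, parts, condition = "AV")
flux  <- flux_to_grid(spectral_flux(st), duration_s = 60)

pk    <- aud$peaks
heart <- split(pk$peak_time_s[pk$signal == "heart"],
               pk$participant_id[pk$signal == "heart"])
rates <- lapply(heart, peaks_to_rate, duration_s = 60)

estimate_group_lag(lapply(rates, `[[`, "bpm"), flux,
                   max_lag_s = 1 / parts$base_heart_hz)
#> <lag_estimate> group lag 600 ms (correlation, 6 participants, 0 excluded)
```

The true 600 ms lag is recovered exactly (the search grid is 50 ms).
Windowed synchrony and its permutation test:

```r
s <- src(rates[[1]], flux, lag_ms = 600)
mean(s$value, na.rm = TRUE)
#> [1] 0.14

secs <- section_annotation("demo", 60, 30)
stat <- statistic_src(flux, secs, 60, lag_ms = 600, fs_interp = 100)
pt   <- circular_null_test(heart, 60, stat, n_perm = 200, seed = 1,
                           measure = "SRC-HR")
pt
#> <perm_test> SRC-HR: t = 19.081, p = 0.0050 (200 permutations)
tidy(pt)
#> # A tibble: 1 × 6
#>   measure statistic p.value n.perm null.mean null.sd
#>   <chr>       <dbl>   <dbl>  <dbl>     <dbl>   <dbl>
#> 1 SRC-HR       19.1 0.00498    200   -0.0690    1.66
```

The time-averaged SRC-HR of ~0.14 is far outside the null (t = 19.1
against a null centred near 0), so p is at the resolution floor of 200
permutations: the audience is detectably time-locked to the stimulus.
`run_pipeline()` chains all of this — plus ISC/ISPC, section averaging,
boundary epochs, mixed-model AV/AO contrasts, and raw-rate orienting
profiles — from one seeded config and writes every table with a config
hash. `autoplot()` methods and `plot_epochs()` / `plot_rate_profile()`
display sync series, permutation nulls, and boundary profiles.

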