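---
title: "Audifying sleep EEG: method, synthetic data, and scoring statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audifying sleep EEG: method, synthetic data, and scoring statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepsonify)
```

## The method

Sleep staging assigns one of five labels (W, N1, N2, N3, REM) to each
30-second polysomnography epoch by visual inspection of EEG, EOG and chin
EMG. `sleepsonify` renders the same epoch as a short sound: the EEG trace
is played back as audio at a greatly accelerated rate, a transformation
usually called *audification*. Nothing is mapped, filtered into musical
parameters, or pitch-corrected; the sound **is** the signal, sped up.

Concretely, for a channel sampled at the display rate
$f_d$ over an epoch of length $L$ seconds, the $n = L f_d$ samples are
reinterpreted at the effective rate $n / T$, where $T$ is the target clip
duration. With the defaults $L = 30$ s, $f_d = 100$ Hz, $T = 1.36$ s the
effective rate is $3000 / 1.36 \approx 2205.9$ Hz and the playback is a
$(1 - T/L) \cdot 100 \approx 95.5\%$ speed-up. Because consumer playback
chains handle arbitrary sample rates poorly, the clip is band-limit
interpolated onto a standard 44.1 kHz grid; this changes the grid, not the
content.

The compression obeys a strict frequency-mapping law: a spectral component
at $f$ Hz in the EEG appears at $f \cdot L/T$ Hz in the clip. With the
defaults the factor is $30/1.36 \approx 22.06$, so the staged EEG band of
roughly 0.9–45 Hz lands in the low-frequency audio band of roughly
20–993 Hz — audible, and low-pitched. Stage-defining rhythms therefore
become stage-defining timbres: occipital alpha (~10 Hz) renders near
220 Hz, slow-wave delta renders as a low rumble, and spindles as brief
chirps near 290 Hz.

### Conditioning

Raw audified clips click at their boundaries and vary hugely in level, so
`condition_audio()` applies, in order:

1. raised-cosine fades (`fade_ms`, default 10 ms) at both ends;
2. a gain such that the RMS of the clip equals `loudness_dbfs`
   (default −12 dBFS, a typical music-track level), *uniformly reduced*
   whenever that gain would push the waveform peak past `peak_guard_dbfs`
   (default −0.5 dBFS) — the guard prevents digital clipping at the cost
   of a quieter clip;
3. `pad_ms` (default 50 ms) of silence at each end.

The measured RMS over the un-padded region is recorded on the clip and in
the sonification manifest. One subtlety is worth stating: EEG-like
waveforms have crest factors (peak/RMS) of roughly 10.5–12.5 dB, which
straddles the 11.5 dB of headroom between −12 dBFS RMS and the −0.5 dBFS
guard. Whether a given clip sits exactly at −12 dBFS or slightly below
(guard engaged) therefore depends on the realization; both outcomes are
correct behaviour and both are exercised by the test suite. Normalization
is per clip, not per session: each epoch is rendered independently, which
keeps the pipeline stateless and reproducible at the cost of removing
between-epoch amplitude cues (a deliberate trade, recorded in the manifest
by the per-clip RMS).

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `display_fs` | 100 | Hz | display pipeline rate the EEG is reduced to before rendering |
| `target_duration` | 1.36 | s | clip length; sets the 22.06× frequency mapping |
| `out_fs` | 44100 | Hz | standard audio grid for playback |
| `loudness_dbfs` | −12 | dBFS RMS | comfortable, consistent playback level |
| `peak_guard_dbfs` | −0.5 | dBFS | hard anti-clipping ceiling |
| `fade_ms`, `pad_ms` | 10, 50 | ms | suppress onset/offset clicks and pops |
| `display_scale_uv` | 100 | µV | ±100 µV display full scale maps to ±1 |

`loudness_dbfs` is an RMS level relative to digital full scale — not LUFS
and not a peak level — measured over the un-padded region. That is the
simplest reading that is unit-testable to ±0.1 dB.

## Numerical choices

Resampling — both the 200→100 Hz anti-aliased downsampling and the
interpolation onto the audio grid — is done in the Fourier domain: the
spectrum is truncated at the smaller Nyquist frequency (a brick-wall
anti-alias filter when shrinking) and inverted on the new grid. This is
exact for DC and for sinusoids aligned with the 30-s analysis window, and
has no filter warm-up transients at the epoch edges; time-domain FIR/IIR
resamplers were rejected because their edge transients distort short
fixed-length epochs (a constant signal should downsample to a constant).
The method treats the epoch as periodic; the wrap-around discontinuity is
masked by the boundary fades. The Nyquist bin of even-length inputs is
dropped rather than split — at 2 × 10⁻⁵ of the band it is inaudible and
keeps the operation purely real.

Re-referencing subtracts the reference electrode from *all* channels
uniformly (EOG and EMG included) and drops the reference channel; a
referenced recording has no meaningful self-channel. Epochs are 0-based
and half-open, `[30i, 30(i+1))`, with trailing partial windows discarded.

## What the synthetic generator emulates

`synth_epoch()` produces 5-channel (F3, C3, O1, LOC, EMG), 30-s, 200 Hz
epochs: a 1/f (pink) background plus stage-specific narrowband
oscillations, transients and tone:

* **W** — dominant ~10 Hz alpha, occipitally weighted (strongest on O1),
  high chin tone, occasional slow blink deflections;
* **N1** — attenuated alpha, low-amplitude 4–8 Hz theta;
* **N2** — theta background with Gaussian-windowed 12–14 Hz spindle bursts
  of 0.5–1.5 s (central weighting) and biphasic ~1 s K-complexes ≥ 75 µV
  (frontal weighting);
* **N3** — 0.5–2 Hz delta with amplitude exceeding every other stage;
* **REM** — low-voltage mixed-frequency EEG, chin atonia (EMG tone a
  fraction of Wake's), frequent rapid EOG deflections.

Amplitudes and densities are not dictated by any dataset; they were chosen
once, following scoring-manual convention, so that every stage's defining
feature is present, signals render inside the ±100 µV display convention,
and the five stages are separable by a naive band-power classifier (the
test suite checks this). Event counts are Poisson; densities ≥ 1
guarantee at least one event per epoch, so an N2 epoch always contains a
spindle.

All generated channels are band-limited above 0.9 Hz. This emulates the
low-frequency display filter of staging software: the audified material is
the *displayed* signal, and the 22.06× mapping places 0.9 Hz at ~20 Hz
audio, so the rendered clips occupy the low-frequency audio band as the
method intends. Slow-wave delta retains its 0.9–2 Hz body.

What the generator does **not** emulate: volume conduction and realistic
electrode topography, artifacts (movement, sweat, ECG bleed), stage
transitions within an epoch, arousals, and age- or pathology-dependent
morphology. Passing tests on synthetic data show that the pipeline and the
statistics behave correctly on material with the right spectral and
transient structure — they are not evidence about staging performance on
clinical recordings.

Simulated raters are a 5×5 row-stochastic confusion matrix plus a
log-normal reaction-time model (strictly positive and right-skewed, which
is why medians, not means, gate data quality). Under uniform truth and a
symmetric confusion with correct-probability $p$, expected agreement is
$p$ against a chance level of 0.2, so Cohen's kappa recovers
$(p - 0.2)/0.8$ — the calibration the test suite verifies by simulation at
5000 trials.

## Scoring statistics

* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$ corrects agreement
  for the imbalanced stage prevalences that distort raw percent correct.
  It is *undefined* when the true stage is constant across a block (and
  when $p_e = 1$); the package returns a typed `NA` with the reason
  attached, never a silent zero.
* **Per-stage accuracy** is the percent of "true stage X" epochs
  identified as X, omitting absent stages; weighted by prevalence it
  reproduces overall percent correct.
* **RT filtering** drops trials more than `rt_sigma` (default 2) standard
  deviations from the mean RT, computed once on the unfiltered set — not
  iteratively, which would have no fixed stopping rule. RT analyses also
  condition on correct responses. Filtering is per participant-block;
  pooling across blocks would let one slow block shift another's bounds.
* **The practice gate** fails raters whose median practice RT is strictly
  below 2 s (bot-like speed); a median of exactly 2 s passes.
* **Paired comparisons** use the Wilcoxon signed-rank test. Zero
  differences are dropped before ranking (the original signed-rank
  convention). The exact two-sided p-value is computed from the full null
  distribution of $W^+$ by convolution over (possibly tied, mid-)ranks —
  equivalent to enumerating all $2^n$ sign assignments but polynomial in
  cost — with $p = \min(1,\, 2\min(P(W \le w), P(W \ge w)))$; a
  ≥10⁴-draw sign-flip permutation is used above $n = 25$.

## Problem sizes and runtime envelope

The test suite renders single epochs (6000 samples at 200 Hz), scores
blocks of 30 trials (the standard test-block length), uses 5000-trial
simulations for chance-level and calibration checks, 200 random response
sets for the brute-force kappa cross-check, full $2^n$ enumeration up to
$n = 12$ for the signed-rank oracle, and 20 replicate cohorts of 40
simulated participants for the experience-stratification power check.
These sizes give Monte-Carlo error well inside the asserted tolerances
while keeping the whole suite under half a minute.

## Known limitations

* EDF support is the continuous-recording subset (no EDF+ annotations or
  discontinuous files); the columnar text format is the test fixture
  format, EDF the interchange format.
* Audification assumes the epoch is band-limited below the display
  Nyquist; content above `display_fs/2` is removed by design.
* Loudness is RMS dBFS, not a perceptual loudness model (LUFS); for
  1.36-s clips of similar spectra the difference is a near-constant
  offset.
* Whether kappa benefits of sonification exist for human raters is a
  question about humans; this package only provides the stimulus
  generation and the scoring machinery to ask it.
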