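# sleepsonify

Sleep staging is the manual classification of 30-second polysomnography
(PSG) epochs into Wake, N1, N2, N3 and REM from EEG, eye-movement (EOG)
and chin-muscle (EMG) traces. It is labor-intensive, and even trained
scorers agree only imperfectly. One proposed aid is to *listen* to the
EEG as well as look at it: render each epoch as a short sound and let the
auditory system pick up the stage-defining rhythms. `sleepsonify`
implements that rendering — minimal time-compression **audification** —
together with a synthetic PSG generator and the statistics used to
evaluate staging performance. It is aimed at sleep researchers and
auditory-display developers who want to build sonified staging stimuli or
score staging experiments.

## The method

An epoch channel (conventionally occipital O1), displayed at
$f_d = 100$ Hz over $L = 30$ s, is played back so that the whole epoch
lasts $T = 1.36$ s — a $(1 - T/L)\cdot 100 \approx 95.5\%$ speed-up. No
feature mapping, no pitch correction: a component at $f$ Hz in the EEG
appears at

$$f_\text{audio} = f \cdot \frac{L}{T} \approx 22.06\, f$$

so the staged EEG band (~0.9–45 Hz) lands in the ~20–993 Hz audio band:
alpha becomes a ~220 Hz tone, delta a low rumble, spindles brief chirps.
The clip is band-limit interpolated onto a 44.1 kHz grid, faded, padded,
and normalized to −12 dBFS RMS under a −0.5 dBFS anti-clipping peak
guard, then written as 16-bit PCM mono WAV.

Scoring support implements Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ (with a typed undefined marker for
constant-truth blocks), per-stage percent correct, ±2σ reaction-time
outlier exclusion on correct trials, a <2 s median-RT practice gate,
exact Wilcoxon signed-rank paired comparisons, and stratification by
staging experience.

## Worked example

Generate a synthetic 30-epoch test block, sonify its first three epochs,
and score the simulated rater:

```sh
sleepsonify synth  --out-dir fx --seed 5
sleepsonify sonify --in fx/recording.tsv --out-dir clips \
                   --epoch 0,1,2 --hypnogram fx/hypnogram.txt
cat clips/manifest.csv
```

```
"epoch","stage","file","duration_s","rms_dbfs"
0,"W","epoch0000.wav",1.36,-12
1,"N2","epoch0001.wav",1.36,-12
2,"N3","epoch0002.wav",1.36,-12
```

Each 30-s epoch became a 1.36-s clip at −12 dBFS RMS; the Wake clip
carries an audible ~220 Hz alpha tone, the N3 clip a low delta rumble.

```sh
sleepsonify score --responses fx/responses.csv --out report.json
```

```
"kappa": 0.742857142857143,
"per_stage_accuracy": { "W": 40, "N1": 100, "N2": 90,
                        "N3": 83.3333333333333, "REM": 80 }
```

The simulated rater (80% correct per stage by construction) scores
κ ≈ 0.74 — chance-corrected agreement on a block whose stage mix is
imbalanced — and recognized 40% of true-Wake epochs, 90% of true-N2, and
so on. The same operations are available in R (`run_synth()`,
`run_sonify()`, `run_score()`, or the underlying `audify()`,
`condition_audio()`, `cohens_kappa()`, `paired_compare()`, ...).

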