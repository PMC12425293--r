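Package: sleepsonify
Title: Audification of Sleep EEG Epochs and Staging Performance Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders 30-second polysomnography (PSG) epochs into short audio
    clips by minimal time-compression audification: an EEG channel is
    downsampled for display, reinterpreted at an accelerated playback rate so
    that 30 seconds of signal become a 1.36 second clip, band-limit
    interpolated onto a standard audio grid, and conditioned (fades, padding,
    RMS loudness normalization to -12 dBFS with a peak guard) before being
    written as 16-bit PCM WAV. Includes PSG input/output (EDF and a plain
    columnar text format), right-ear re-referencing, 30-second epoch
    extraction, hypnogram handling with a two-scorer consensus filter, a
    synthetic sleep-PSG generator producing stage-characteristic epochs
    (occipital alpha in Wake, sleep spindles and K-complexes in N2,
    high-amplitude delta in N3, REM atonia with rapid eye movements) and
    simulated rater responses, and the statistical machinery used to evaluate
    sleep-staging performance: Cohen's kappa, per-stage percent correct,
    reaction-time outlier filters, a practice-block quality gate, exact
    Wilcoxon signed-rank paired comparisons, and experience stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
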