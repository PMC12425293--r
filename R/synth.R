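# Synthetic polysomnography: stage-characteristic 30-s epochs built from
# pink-noise background plus narrowband oscillations and transient events
# (spindles, K-complexes, eye movements), with an EOG and a chin-EMG channel.
# The point is testability without any recording download: each stage's
# defining phenomenology is present and separable, not a forward model of
# cortical physiology.

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# 1/f ("pink") noise via spectral shaping, scaled to a target RMS (uV).
pink_noise <- function(n, fs, rms_uv, f_floor = 0.5) {
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  w <- 1 / sqrt(pmax(f, f_floor))
  w[1] <- 0  # no DC drift
  z <- stats::fft(stats::rnorm(n)) * w
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / sqrt(mean(x^2)) * rms_uv
}

# Brick-wall high-pass in the frequency domain. The generator emulates the
# band-limited signal the staging display renders (and the audifier hears):
# content below ~0.9 Hz is not part of the stimulus material.
fft_highpass <- function(x, fs, f_cut) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  z <- stats::fft(x)
  z[f < f_cut] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

# Narrowband Gaussian process centred at `center` Hz (Gaussian spectral
# envelope, sd = bw/2), scaled to a target RMS.
narrowband_osc <- function(n, fs, center, bw, rms_uv) {
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  w <- exp(-(f - center)^2 / (2 * (bw / 2)^2))
  z <- stats::fft(stats::rnorm(n)) * w
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / sqrt(mean(x^2)) * rms_uv
}

# Gaussian-windowed sigma burst (sleep spindle), 12-14 Hz, 0.5-1.5 s.
spindle_waveform <- function(fs, freq, dur_s, amp_uv) {
  t <- seq(0, dur_s, by = 1 / fs)
  amp_uv * exp(-((t - dur_s / 2)^2) / (2 * (dur_s / 6)^2)) *
    sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
}

# Biphasic ~1 s high-amplitude transient (K-complex): one windowed sine
# cycle, sharp negative phase first, peak >= 75 uV per AASM convention.
kcomplex_waveform <- function(fs, dur_s = 1.0, amp_uv = 110) {
  t <- seq(0, dur_s, length.out = round(dur_s * fs))
  -amp_uv * sin(2 * pi * t / dur_s) * (0.5 - 0.5 * cos(2 * pi * t / dur_s))
}

add_events <- function(x, fs, count, make_event) {
  n <- length(x)
  for (i in seq_len(count)) {
    ev <- make_event()
    start <- sample.int(max(n - length(ev), 1L), 1L)
    idx <- start:min(start + length(ev) - 1L, n)
    x[idx] <- x[idx] + ev[seq_along(idx)]
  }
  x
}

#' Describe the EEG/EOG/EMG phenotype of one sleep stage
#'
#' @param stage One of [SLEEP_STAGES].
#' @param bands Data frame with columns `center` (Hz), `bw` (Hz bandwidth)
#'   and `amp` (RMS microvolts) describing narrowband oscillations added to
#'   the pink-noise background.
#' @param spindle_density Expected sleep-spindle bursts (12-14 Hz) per
#'   30-s epoch; densities of 1 or more guarantee at least one burst.
#' @param kcomplex_density Expected K-complexes per epoch.
#' @param emg_tone_uv RMS amplitude of chin-EMG tone (low in REM atonia).
#' @param eog_rate Expected rapid eye-movement deflections on the EOG
#'   channel per epoch.
#' @param pink_rms_uv RMS of the 1/f background, microvolts.
#' @return A list of class `stage_model`.
#' @export
stage_model <- function(stage, bands, spindle_density = 0,
                        kcomplex_density = 0, emg_tone_uv = 5,
                        eog_rate = 0, pink_rms_uv = 8) {
  stopifnot(stage %in% SLEEP_STAGES,
            all(c("center", "bw", "amp") %in% names(bands)),
            all(bands$amp >= 0), spindle_density >= 0, kcomplex_density >= 0,
            emg_tone_uv >= 0, eog_rate >= 0)
  structure(list(stage = stage, bands = bands,
                 spindle_density = spindle_density,
                 kcomplex_density = kcomplex_density,
                 emg_tone_uv = emg_tone_uv, eog_rate = eog_rate,
                 pink_rms_uv = pink_rms_uv),
            class = "stage_model")
}

#' Default stage models for the synthetic generator
#'
#' Amplitudes and densities follow scoring-manual convention: Wake carries
#' dominant ~10 Hz occipital alpha with high muscle tone; N1 attenuated
#' alpha and low-amplitude theta; N2 theta background with sleep spindles
#' and K-complexes; N3 high-amplitude (0.5-2 Hz) delta exceeding every
#' other stage; REM low-voltage mixed-frequency EEG with chin atonia and
#' frequent rapid EOG deflections. All signals render comfortably within
#' the +-100 uV display convention.
#'
#' @return Named list of five [stage_model()] objects.
#' @export
default_stage_models <- function() {
  b <- function(...) data.frame(rbind(...))
  mk <- function(...) do.call(stage_model, list(...))
  list(
    W = mk("W", b(c(center = 10, bw = 1.5, amp = 22),
                  c(center = 20, bw = 8, amp = 4),
                  c(center = 1.2, bw = 1.2, amp = 6)),
           emg_tone_uv = 15, eog_rate = 1, pink_rms_uv = 8),
    N1 = mk("N1", b(c(center = 5.5, bw = 2.5, amp = 14),
                    c(center = 10, bw = 1.5, amp = 5),
                    c(center = 1.2, bw = 1.2, amp = 12)),
            emg_tone_uv = 8, eog_rate = 0.3, pink_rms_uv = 9),
    N2 = mk("N2", b(c(center = 5.5, bw = 2.5, amp = 15),
                    c(center = 1.2, bw = 1.2, amp = 22)),
            spindle_density = 3, kcomplex_density = 1.5,
            emg_tone_uv = 6, pink_rms_uv = 9),
    N3 = mk("N3", b(c(center = 1.0, bw = 1.2, amp = 55),
                    c(center = 5.5, bw = 2.5, amp = 10)),
            spindle_density = 0.5, emg_tone_uv = 5, pink_rms_uv = 9),
    REM = mk("REM", b(c(center = 5.5, bw = 3, amp = 10),
                      c(center = 1.2, bw = 1.2, amp = 8)),
             emg_tone_uv = 1.5, eog_rate = 8, pink_rms_uv = 8))
}

# Spatial weighting: alpha is occipital-dominant, slow activity and
# K-complexes frontal-dominant, spindles central-dominant.
eeg_channel_gain <- function(channel, center_hz) {
  if (center_hz >= 8 && center_hz <= 13)
    return(switch(channel, F3 = 0.35, C3 = 0.55, O1 = 1.0))
  if (center_hz < 4)
    return(switch(channel, F3 = 1.0, C3 = 0.85, O1 = 0.6))
  1.0
}

#' Generate one stage-characteristic synthetic PSG epoch
#'
#' Produces a 5-channel (F3, C3, O1, LOC, EMG), 30-second epoch at `fs` Hz
#' whose spectral and transient content follows the stage's model:
#' deterministic for a fixed `(stage, seed)` pair.
#'
#' @param stage One of [SLEEP_STAGES].
#' @param seed Integer seed; same `(stage, seed)` gives identical samples.
#' @param models Named list of [stage_model()]s, one per stage.
#' @param fs Sampling rate, Hz (default 200).
#' @param epoch_len Epoch duration, seconds.
#' @param index 0-based epoch index recorded on the result.
#' @param hp_hz Display high-pass cutoff, Hz: all electrophysiology
#'   channels are band-limited above this frequency, emulating the
#'   low-frequency filter of standard staging displays (default 0.9 Hz, so
#'   the audified material occupies the low-frequency audio band).
#' @return A [psg_epoch()] with `true_stage = stage`.
#' @examples
#' ep <- synth_epoch("N3", seed = 1)
#' range(ep$samples_by_channel$F3)
#' @export
synth_epoch <- function(stage, seed, models = default_stage_models(),
                        fs = 200, epoch_len = 30, index = 0L, hp_hz = 0.9) {
  if (!stage %in% SLEEP_STAGES)
    stop("parameter error: unknown stage '", stage, "'")
  if (!stage %in% names(models))
    stop("parameter error: no model supplied for stage '", stage, "'")
  m <- models[[stage]]
  n <- as.integer(round(epoch_len * fs))
  # offset the seed per stage so equal seeds never alias different stages
  seed_eff <- (as.integer(seed) + 104729L * (match(stage, SLEEP_STAGES) - 1L)) %%
    .Machine$integer.max
  with_seed(seed_eff, {
    eeg <- lapply(c(F3 = "F3", C3 = "C3", O1 = "O1"), function(ch) {
      x <- pink_noise(n, fs, m$pink_rms_uv)
      for (i in seq_len(nrow(m$bands))) {
        bd <- m$bands[i, ]
        x <- x + eeg_channel_gain(ch, bd$center) *
          narrowband_osc(n, fs, bd$center, bd$bw, bd$amp)
      }
      x
    })
    n_spin <- if (m$spindle_density >= 1)
      1L + stats::rpois(1, m$spindle_density - 1) else
      stats::rpois(1, m$spindle_density)
    if (n_spin > 0L) {
      eeg$C3 <- add_events(eeg$C3, fs, n_spin, function()
        spindle_waveform(fs, stats::runif(1, 12, 14),
                         stats::runif(1, 0.5, 1.5), amp_uv = 25))
    }
    n_kc <- if (m$kcomplex_density >= 1)
      1L + stats::rpois(1, m$kcomplex_density - 1) else
      stats::rpois(1, m$kcomplex_density)
    if (n_kc > 0L) {
      kc <- function() kcomplex_waveform(fs)
      eeg$F3 <- add_events(eeg$F3, fs, n_kc, kc)
    }
    loc <- pink_noise(n, fs, 5)
    n_eog <- if (m$eog_rate >= 1) 1L + stats::rpois(1, m$eog_rate - 1) else
      stats::rpois(1, m$eog_rate)
    if (n_eog > 0L) {
      loc <- add_events(loc, fs, n_eog, function() {
        dur <- stats::runif(1, 0.2, 0.45)
        t <- seq(0, dur, by = 1 / fs)
        # sharp rise, slower return: rapid-eye-movement deflection
        sgn <- sample(c(-1, 1), 1)
        sgn * 120 * (t / dur)^0.3 * (1 - t / dur)
      })
    }
    emg <- narrowband_osc(n, fs, 55, 60, m$emg_tone_uv)  # broadband 20-90 Hz
    sig <- c(eeg, list(LOC = loc, EMG = emg))
    if (hp_hz > 0) sig <- lapply(sig, fft_highpass, fs = fs, f_cut = hp_hz)
    psg_epoch(sig, fs = fs, index = index,
              true_stage = stage, epoch_len = epoch_len)
  })
}

#' Render a hypnogram into a continuous synthetic recording
#'
#' Epochs are generated per label (seeded deterministically from `seed` and
#' the epoch index) and concatenated with a short raised-cosine cross-fade
#' confined to each epoch's own boundary region, so epoch boundaries stay
#' exactly at 30-second multiples and [extract_epochs()] round-trips.
#'
#' @param hyp A [hypnogram()] (possibly empty).
#' @param seed Integer master seed.
#' @param models Stage models, as for [synth_epoch()].
#' @param fs Sampling rate, Hz.
#' @param crossfade_ms Boundary fade length, milliseconds.
#' @return List with elements `recording` ([psg_recording]) and
#'   `hypnogram` (the input labels).
#' @export
synth_recording <- function(hyp, seed, models = default_stage_models(),
                            fs = 200, crossfade_ms = 50) {
  labels <- unclass(hypnogram(as.character(hyp)))
  k <- length(labels)
  channels <- c("F3", "C3", "O1", "LOC", "EMG")
  if (k == 0L) {
    rec <- psg_recording(stats::setNames(rep(list(numeric(0)), 5), channels),
                         fs = fs)
    return(list(recording = rec, hypnogram = hypnogram(labels)))
  }
  nf <- as.integer(round(crossfade_ms / 1000 * fs))
  ramp <- if (nf > 0) 0.5 * (1 - cos(pi * (seq_len(nf) - 0.5) / nf)) else numeric(0)
  eps <- lapply(seq_len(k), function(i) {
    e <- synth_epoch(labels[i], seed = (seed + 7919L * (i - 1L)) %%
                       .Machine$integer.max,
                     models = models, fs = fs, index = i - 1L)
    e$samples_by_channel <- lapply(e$samples_by_channel, function(x) {
      n <- length(x)
      if (nf > 0) {
        if (i > 1L) x[seq_len(nf)] <- x[seq_len(nf)] * ramp
        if (i < k) x[n + 1L - seq_len(nf)] <- x[n + 1L - seq_len(nf)] * ramp
      }
      x
    })
    e
  })
  signals <- lapply(stats::setNames(channels, channels), function(ch)
    unlist(lapply(eps, function(e) e$samples_by_channel[[ch]]),
           use.names = FALSE))
  list(recording = psg_recording(signals, fs = fs),
       hypnogram = hypnogram(labels))
}

#' Band-power features of one epoch channel
#'
#' Mean periodogram power in the four scoring-relevant bands: delta
#' (0.5-4 Hz), theta (4-8), alpha (8-13) and sigma (12-14, the spindle
#' band). Used by demos and by the stage-separability checks.
#'
#' @param epoch A [psg_epoch()].
#' @param channel Channel name (default `"O1"`).
#' @return Named numeric vector `c(delta, theta, alpha, sigma)` in uV^2.
#' @export
bandpower_features <- function(epoch, channel = "O1") {
  x <- epoch$samples_by_channel[[channel]]
  if (is.null(x)) stop("no channel '", channel, "' in epoch")
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) / n * epoch$fs
  f <- pmin(f, epoch$fs - f)
  bp <- function(lo, hi) sum(P[f >= lo & f <= hi])
  c(delta = bp(0.5, 4), theta = bp(4, 8), alpha = bp(8, 13),
    sigma = bp(12, 14))
}

#' Describe a simulated sleep-stager
#'
#' The rater issues, for each epoch, a stage drawn from the confusion
#' matrix row of the true stage, and a reaction time drawn from a
#' log-normal distribution with the given natural-scale mean and sd
#' (strictly positive, right-skewed).
#'
#' @param confusion 5x5 row-stochastic matrix, rows = true stage, columns =
#'   issued stage, dimnames in [SLEEP_STAGES] order.
#' @param rt_mean,rt_sd Mean and standard deviation of reaction times,
#'   seconds (natural scale).
#' @param seed Integer seed for the simulated responses.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(confusion, rt_mean = 5, rt_sd = 3, seed = 1L) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(5L, 5L)))
    stop("model error: confusion must be 5x5")
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("model error: confusion rows must be non-negative and sum to 1")
  if (rt_mean <= 0) stop("rt_mean must be positive")
  dimnames(confusion) <- list(SLEEP_STAGES, SLEEP_STAGES)
  structure(list(confusion = confusion, rt_mean = rt_mean, rt_sd = rt_sd,
                 seed = as.integer(seed)),
            class = "rater_model")
}

#' Symmetric stage-confusion matrix
#'
#' Probability `p` on the diagonal, the remainder spread uniformly over the
#' four wrong stages. With uniform truth over five stages this gives
#' expected agreement `p` against chance agreement 0.2, hence expected
#' kappa `(p - 0.2) / 0.8`.
#'
#' @param p Probability of issuing the correct stage.
#' @return 5x5 row-stochastic matrix.
#' @export
symmetric_confusion <- function(p) {
  stopifnot(p >= 0, p <= 1)
  m <- matrix((1 - p) / 4, 5, 5, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  diag(m) <- p
  m
}

#' Simulate one block of rater responses
#'
#' @param truth Character vector of true stages, one per epoch.
#' @param rater A [rater_model()].
#' @param block_id Block label, one of `"sound"`, `"no_sound"`, `"practice"`.
#' @param participant_id Identifier recorded on the result.
#' @return A [response_set()] with one trial per epoch, deterministic for
#'   the rater's seed.
#' @export
synth_responses <- function(truth, rater, block_id = "sound",
                            participant_id = "sim") {
  stopifnot(inherits(rater, "rater_model"))
  truth <- unclass(hypnogram(as.character(truth)))
  if (length(truth) == 0L) stop("truth must be non-empty")
  sdlog <- sqrt(log(1 + (rater$rt_sd / rater$rt_mean)^2))
  meanlog <- log(rater$rt_mean) - sdlog^2 / 2
  with_seed(rater$seed, {
    resp <- vapply(truth, function(s)
      sample(SLEEP_STAGES, 1L, prob = rater$confusion[s, ]), character(1))
    rt <- stats::rlnorm(length(truth), meanlog, sdlog)
    response_set(data.frame(epoch = seq_along(truth) - 1L,
                            true_stage = truth, response = unname(resp),
                            rt = rt, stringsAsFactors = FALSE),
                 block_id = block_id, participant_id = participant_id)
  })
}
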