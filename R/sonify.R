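# Minimal audification: a 30-s EEG trace is reinterpreted at an accelerated
# playback rate so the whole epoch lasts `target_duration` seconds, then
# band-limit interpolated onto a consumer audio grid. No feature mapping, no
# pitch preservation: a spectral component at f Hz in the EEG appears at
# f * (epoch_len / target_duration) Hz in the clip (~22x for 30 s -> 1.36 s).

#' Parameters of the epoch-to-audio rendering
#'
#' @param display_fs Rate (Hz) the EEG is downsampled to before audification;
#'   100 Hz matches the on-screen display pipeline.
#' @param target_duration Length of the rendered clip in seconds before any
#'   padding. The default 1.36 s compresses a 30-s epoch by about 95%.
#' @param out_fs Audio output sample rate in Hz.
#' @param loudness_dbfs Target RMS level of the conditioned clip in dB
#'   relative to digital full scale; -12 dBFS is a typical music-track level.
#' @param fade_ms Raised-cosine fade-in/out length, milliseconds.
#' @param pad_ms Leading and trailing silence, milliseconds; padding and
#'   fades suppress clicks and pops at playback boundaries.
#' @param peak_guard_dbfs Ceiling (dBFS) the waveform peak may not exceed;
#'   when loudness normalization would push the peak past it, gain is
#'   reduced so the peak sits exactly at the ceiling.
#' @param epoch_len Source epoch duration, seconds.
#' @param display_scale_uv Display full-scale in microvolts; the +-100 uV
#'   screen convention maps to +-1 in the raw (unconditioned) waveform.
#' @return A list of class `sonify_params`.
#' @export
sonify_params <- function(display_fs = 100, target_duration = 1.36,
                          out_fs = 44100, loudness_dbfs = -12,
                          fade_ms = 10, pad_ms = 50,
                          peak_guard_dbfs = -0.5, epoch_len = 30,
                          display_scale_uv = 100) {
  stopifnot(display_fs > 0, target_duration > 0, out_fs > 0,
            loudness_dbfs < 0, fade_ms >= 0, pad_ms >= 0,
            peak_guard_dbfs <= 0, epoch_len > 0, display_scale_uv > 0)
  structure(list(display_fs = display_fs, target_duration = target_duration,
                 out_fs = out_fs, loudness_dbfs = loudness_dbfs,
                 fade_ms = fade_ms, pad_ms = pad_ms,
                 peak_guard_dbfs = peak_guard_dbfs, epoch_len = epoch_len,
                 display_scale_uv = display_scale_uv),
            class = "sonify_params")
}

#' Construct an audio clip
#'
#' @param samples Mono waveform (unitless, nominally within \[-1, 1\] after
#'   conditioning).
#' @param fs Sample rate, Hz.
#' @param pad_samples Number of silent samples prepended and appended by
#'   conditioning (0 for raw clips); the un-padded region is
#'   `samples[(pad_samples+1):(length(samples)-pad_samples)]`.
#' @param rms_dbfs Measured RMS level over the un-padded region, dBFS
#'   (`-Inf` for silence, `NA` if not yet measured).
#' @param source_epoch 0-based index of the source epoch, for provenance.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, fs, pad_samples = 0L, rms_dbfs = NA_real_,
                       source_epoch = NA_integer_) {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 pad_samples = as.integer(pad_samples),
                 rms_dbfs = rms_dbfs, source_epoch = source_epoch),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d frames @ %g Hz (%.4f s), pad %d, RMS %s dBFS\n",
              length(x$samples), x$fs, clip_duration(x), x$pad_samples,
              ifelse(is.na(x$rms_dbfs), "?", sprintf("%.2f", x$rms_dbfs))))
  invisible(x)
}

#' Clip duration in seconds
#' @param clip An [audio_clip].
#' @param padded Include the silent padding? Default `FALSE`: the duration
#'   of the rendered content only.
#' @export
clip_duration <- function(clip, padded = FALSE) {
  n <- length(clip$samples)
  if (!padded) n <- n - 2L * clip$pad_samples
  n / clip$fs
}

unpadded <- function(clip) {
  n <- length(clip$samples)
  p <- clip$pad_samples
  if (p == 0L) clip$samples else clip$samples[(p + 1L):(n - p)]
}

# Band-limited resampling in the frequency domain: keep the Fourier bins
# both grids can represent (a brick-wall anti-alias filter when shrinking),
# drop the Nyquist bin, invert on the new grid. Exact for DC and for
# sinusoids aligned to the analysis window; treats the input as periodic.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  K <- (min(n, n_out) - 1L) %/% 2L
  Y <- complex(n_out)
  Y[1L] <- X[1L]
  if (K >= 1L) {
    k <- seq_len(K)
    Y[1L + k] <- X[1L + k]
    Y[n_out + 1L - k] <- X[n + 1L - k]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a signal with anti-aliasing
#'
#' Band-limits the signal below the new Nyquist frequency and resamples it
#' onto the coarser grid; output length is `round(n * fs_out / fs_in)`.
#' Used to bring 200 Hz acquisition data to the 100 Hz display rate before
#' audification.
#'
#' @param x Numeric sample vector at `fs_in`.
#' @param fs_in,fs_out Input and output rates, Hz, with `fs_out <= fs_in`.
#' @return Numeric vector at `fs_out`.
#' @export
downsample_signal <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in)
    stop("parameter error: fs_out (", fs_out, ") exceeds fs_in (", fs_in,
         "); downsampling only")
  n_out <- as.integer(round(length(x) * fs_out / fs_in))
  fft_resample(x, n_out)
}

#' Audify one epoch channel into a raw audio clip
#'
#' The samples are reinterpreted at the accelerated effective rate
#' `n / target_duration` (about 2206 Hz for 3000 samples into 1.36 s) and
#' band-limit interpolated onto the `out_fs` grid, so the clip holds exactly
#' the input waveform played `epoch_len / target_duration` times faster.
#' Amplitude is scaled by the display convention (`display_scale_uv`
#' microvolts to full scale); no loudness normalization or fades are applied
#' here -- see [condition_audio()].
#'
#' @param x Channel samples in microvolts at `params$display_fs`.
#' @param params A [sonify_params()].
#' @param source_epoch Optional 0-based provenance index.
#' @return An unconditioned [audio_clip] of duration `target_duration`
#'   (within one output sample).
#' @export
audify <- function(x, params = sonify_params(), source_epoch = NA_integer_) {
  if (length(x) == 0L) stop("empty input signal")
  n_out <- as.integer(round(params$target_duration * params$out_fs))
  y <- fft_resample(as.numeric(x), n_out) / params$display_scale_uv
  audio_clip(y, fs = params$out_fs, source_epoch = source_epoch)
}

rms <- function(x) sqrt(mean(x^2))
dbfs <- function(a) 20 * log10(a)

#' Condition a raw clip for playback
#'
#' Applies, in order: raised-cosine fades of `fade_ms` at both ends; gain
#' such that the RMS over the (future) un-padded region equals
#' `loudness_dbfs`, uniformly reduced if the peak would exceed
#' `peak_guard_dbfs`; then `pad_ms` of silence at both ends. The measured
#' RMS (dBFS, un-padded region) is recorded on the returned clip. A silent
#' clip is returned unchanged with `rms_dbfs = -Inf` and a warning.
#'
#' @param clip An [audio_clip] from [audify()].
#' @param params A [sonify_params()].
#' @return A conditioned [audio_clip] with samples in \[-1, 1\].
#' @export
condition_audio <- function(clip, params = sonify_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (!all(is.finite(x))) stop("clip contains non-finite samples")
  if (all(x == 0)) {
    warning("silent clip: conditioning skipped, rms_dbfs set to -Inf")
    clip$rms_dbfs <- -Inf
    return(clip)
  }
  nf <- as.integer(round(params$fade_ms / 1000 * clip$fs))
  if (nf > 0L && 2L * nf <= length(x)) {
    w <- 0.5 * (1 - cos(pi * (seq_len(nf) - 0.5) / nf))  # raised cosine 0->1
    x[seq_len(nf)] <- x[seq_len(nf)] * w
    x[length(x) + 1L - seq_len(nf)] <- x[length(x) + 1L - seq_len(nf)] * w
  }
  target <- 10^(params$loudness_dbfs / 20)
  g <- target / rms(x)
  guard <- 10^(params$peak_guard_dbfs / 20)
  pk <- max(abs(x))
  if (g * pk > guard) g <- guard / pk
  x <- g * x
  np <- as.integer(round(params$pad_ms / 1000 * clip$fs))
  audio_clip(c(numeric(np), x, numeric(np)), fs = clip$fs,
             pad_samples = np, rms_dbfs = dbfs(rms(x)),
             source_epoch = clip$source_epoch)
}

#' Fraction of signal power inside a frequency band
#'
#' Parseval-consistent: the periodogram power in `[lo, hi]` Hz divided by
#' the total power of the un-padded waveform. Rendered sleep-EEG clips
#' concentrate nearly all power in the low-frequency 20-1000 Hz audio band.
#'
#' @param clip An [audio_clip].
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return Scalar fraction in \[0, 1\].
#' @export
spectral_summary <- function(clip, band = c(20, 1000)) {
  x <- unpadded(clip)
  if (all(x == 0)) stop("undefined-value error: silent clip has no band power")
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1L) / n * clip$fs
  freqs <- pmin(freqs, clip$fs - freqs)  # fold negative frequencies
  sum(P[freqs >= band[1] & freqs <= band[2]]) / sum(P)
}

#' Write an audio clip as 16-bit PCM mono WAV
#'
#' @param clip An [audio_clip] with samples in \[-1, 1\] (condition first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (length(x) && max(abs(x)) > 1)
    stop("range error: samples exceed [-1, 1]; run condition_audio() first")
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(clip$fs))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(fs * 2L, con, size = 4L, endian = "little")      # byte rate
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  if (length(pcm)) writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Counterpart of [write_wav()]; used for round-trip verification.
#'
#' @param path Path to a WAV file written by this package (PCM16 mono).
#' @return An [audio_clip] with samples in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4L, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("format error: not a WAVE file: ", path)
  fs <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2L, size = 2L, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("unsupported WAV: need PCM mono")
      fs <- readBin(con, "integer", size = 4L, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8L))
    } else if (id == "data") {
      samples <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  if (is.null(fs) || is.null(samples))
    stop("format error: missing fmt/data chunk in ", path)
  audio_clip(samples / 32767, fs = fs)
}
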