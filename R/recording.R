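#' The five AASM sleep-stage labels
#'
#' Scoring of polysomnography assigns each 30-second epoch one of five
#' stages: Wake, the three non-REM depths N1--N3, and REM.
#'
#' @format Character vector of length 5: `c("W", "N1", "N2", "N3", "REM")`.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Construct a multi-channel PSG recording
#'
#' A recording bundles per-channel sample sequences (microvolts), the
#' sampling rate, and the name of the reference electrode (`"none"` for
#' unreferenced data). All channels must have equal length and unique names.
#'
#' @param signals Named list of equal-length numeric vectors, one per
#'   channel, in microvolts. Typical montage: F3, C3, O1, LOC, EMG.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param reference Name of the reference channel already applied, or
#'   `"none"` (default).
#' @return An object of class `psg_recording`.
#' @examples
#' rec <- psg_recording(list(C3 = sin(1:400), O1 = cos(1:400)), fs = 200)
#' rec
#' @export
psg_recording <- function(signals, fs, reference = "none") {
  if (!is.list(signals) || length(signals) == 0L)
    stop("`signals` must be a non-empty named list of numeric vectors")
  nms <- names(signals)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every channel in `signals` must be named")
  if (anyDuplicated(nms))
    stop("channel names must be unique")
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("integrity error: channels have mismatched lengths (",
         paste(nms, lens, sep = "=", collapse = ", "), ")")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  signals <- lapply(signals, as.numeric)
  structure(
    list(signals = signals, channel_names = nms, fs = fs,
         reference = as.character(reference)),
    class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat(sprintf("<psg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), ref: %s\n",
              length(x$signals), n, x$fs, n / x$fs, x$reference))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `psg_recording`.
#' @return Scalar seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "psg_recording"))
  length(rec$signals[[1]]) / rec$fs
}

#' Read a PSG recording from disk
#'
#' Supports European Data Format (EDF) and a plain columnar text format.
#' The columnar format is a first comment line `# fs=<Hz> reference=<name>`
#' followed by a tab-separated header row of channel names and one numeric
#' row per sample (microvolts); it exists so that fixtures and pipelines
#' never require binary files. With `format = "auto"` the `.edf` (or `.rec`)
#' extension selects EDF, anything else the columnar reader.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"edf"`, `"columnar"`.
#' @return A [psg_recording].
#' @seealso [write_recording()], [read_edf()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "columnar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(edf|rec)$", path, ignore.case = TRUE)) "edf"
              else "columnar"
  }
  if (format == "edf") return(read_edf(path))
  read_columnar_recording(path)
}

read_columnar_recording <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("format error: empty file: ", path)
  if (!grepl("^#\\s*fs=", first))
    stop("format error: columnar recording must start with '# fs=<Hz>': ", path)
  fs <- as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", first))
  if (!is.finite(fs) || fs <= 0)
    stop("format error: unparseable sampling rate in header: ", first)
  reference <- if (grepl("reference=", first))
    sub("^.*reference=(\\S+).*$", "\\1", first) else "none"
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, skip = 1L, sep = "\t",
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dat) == 0L || nrow(dat) == 0L)
    stop("format error: no signal data in ", path)
  if (!all(vapply(dat, is.numeric, logical(1))))
    stop("format error: non-numeric sample values in ", path)
  psg_recording(as.list(dat), fs = fs, reference = reference)
}

#' Write a recording in the columnar text format
#'
#' @param rec A [psg_recording].
#' @param path Output path.
#' @param digits Significant digits for samples.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "psg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g reference=%s", rec$fs, rec$reference), con)
  mat <- vapply(rec$signals, function(s) signif(s, digits),
                numeric(length(rec$signals[[1]])))
  utils::write.table(mat, con, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_names, quote = FALSE)
  invisible(path)
}

#' Re-reference all channels to a named electrode
#'
#' Subtracts the reference channel (conventionally the right-ear electrode,
#' A2) from every other channel, drops the reference channel from the
#' output, and records the reference name. Idempotent: a recording already
#' referenced to `ref_channel` is returned unchanged. All channels, EOG and
#' EMG included, are re-referenced uniformly.
#'
#' @param rec A [psg_recording].
#' @param ref_channel Name of the channel to use as reference.
#' @return A re-referenced `psg_recording` without the reference channel.
#' @examples
#' rec <- psg_recording(list(O1 = c(3, 3), A2 = c(1, 2)), fs = 1)
#' rereference(rec, "A2")$signals$O1  # c(2, 1)
#' @export
rereference <- function(rec, ref_channel) {
  stopifnot(inherits(rec, "psg_recording"))
  if (identical(rec$reference, ref_channel)) return(rec)
  if (!ref_channel %in% rec$channel_names)
    stop("lookup error: reference channel '", ref_channel,
         "' not present (have: ", paste(rec$channel_names, collapse = ", "), ")")
  ref <- rec$signals[[ref_channel]]
  keep <- setdiff(rec$channel_names, ref_channel)
  signals <- lapply(rec$signals[keep], function(s) s - ref)
  psg_recording(signals, fs = rec$fs, reference = ref_channel)
}

#' Split a recording into consecutive 30-second epochs
#'
#' Epoch `i` (0-based) covers the half-open interval `[30*i, 30*(i+1))`
#' seconds; a trailing partial window is discarded. If a hypnogram is
#' supplied its labels are attached as the epochs' true stages.
#'
#' @param rec A [psg_recording].
#' @param epoch_len Epoch length in seconds (default 30, the scoring unit).
#' @param hypnogram Optional [hypnogram()] supplying true stages.
#' @return List of `psg_epoch` objects (empty list if the recording is
#'   shorter than one epoch).
#' @export
extract_epochs <- function(rec, epoch_len = 30, hypnogram = NULL) {
  stopifnot(inherits(rec, "psg_recording"))
  spe <- epoch_len * rec$fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch_len * fs must be an integer number of samples")
  spe <- as.integer(round(spe))
  n <- length(rec$signals[[1]])
  k <- n %/% spe
  if (k == 0L) return(list())
  lapply(seq_len(k) - 1L, function(i) {
    idx <- (i * spe + 1L):((i + 1L) * spe)
    stage <- if (!is.null(hypnogram) && length(hypnogram) > i)
      unclass(hypnogram)[i + 1L] else NA_character_
    psg_epoch(lapply(rec$signals, `[`, idx), fs = rec$fs, index = i,
              true_stage = stage)
  })
}

#' Construct a single scoring epoch
#'
#' @param samples_by_channel Named list of equal-length channel vectors, uV.
#' @param fs Sampling rate, Hz.
#' @param index 0-based epoch number within its recording.
#' @param true_stage One of [SLEEP_STAGES], or `NA` when unknown.
#' @param epoch_len Epoch duration in seconds; the sample count must equal
#'   `epoch_len * fs` exactly.
#' @return An object of class `psg_epoch` with `start_time = epoch_len * index`.
#' @export
psg_epoch <- function(samples_by_channel, fs, index = 0L,
                      true_stage = NA_character_, epoch_len = 30) {
  n <- length(samples_by_channel[[1]])
  if (n != epoch_len * fs)
    stop("epoch must hold exactly ", epoch_len * fs, " samples per channel, got ", n)
  if (!is.na(true_stage) && !true_stage %in% SLEEP_STAGES)
    stop("unknown stage label: ", true_stage)
  structure(
    list(samples_by_channel = samples_by_channel, fs = fs,
         index = as.integer(index), start_time = epoch_len * as.integer(index),
         true_stage = true_stage),
    class = "psg_epoch")
}

#' @export
print.psg_epoch <- function(x, ...) {
  cat(sprintf("<psg_epoch> #%d @ %gs, %d ch x %d samples @ %g Hz, stage: %s\n",
              x$index, x$start_time, length(x$samples_by_channel),
              length(x$samples_by_channel[[1]]), x$fs,
              ifelse(is.na(x$true_stage), "?", x$true_stage)))
  invisible(x)
}

#' Construct a hypnogram (per-epoch stage sequence)
#'
#' @param labels Character vector of stage tokens, one per 30-s epoch.
#' @param epoch_len Epoch length in seconds (fixed at 30 for AASM scoring).
#' @return Character vector of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len = 30) {
  labels <- as.character(labels)
  bad <- which(!labels %in% SLEEP_STAGES)
  if (length(bad))
    stop("parse error: unknown stage token '", labels[bad[1]],
         "' at position ", bad[1])
  structure(labels, epoch_len = epoch_len, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs: %s\n", length(x),
              attr(x, "epoch_len"),
              paste(utils::head(unclass(x), 15), collapse = " ")))
  invisible(x)
}

#' Read / write hypnograms as one stage token per line
#'
#' The text format is one of `W`, `N1`, `N2`, `N3`, `REM` per line; a
#' write-then-read round trip reproduces the labels exactly. Unknown tokens
#' raise a parse error naming the offending line.
#'
#' @param path File path.
#' @return `read_hypnogram` returns a [hypnogram()]; `write_hypnogram`
#'   returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- which(!lines %in% SLEEP_STAGES)
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1], ": unknown stage token '",
         lines[bad[1]], "'")
  hypnogram(lines)
}

#' @rdname read_hypnogram
#' @param hyp A [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(unclass(hyp), path)
  invisible(path)
}

#' Keep only epochs on which two scorers agree
#'
#' Epochs of real PSG are often staged independently by two experts;
#' stimulus sets are restricted to epochs where both issued the same stage.
#' Returns the agreeing 0-based epoch indices with the agreed label.
#'
#' @param labels_a,labels_b Two equal-length [hypnogram()]s (or character
#'   vectors of stage tokens).
#' @return A data.frame with columns `index` (0-based) and `stage`;
#'   zero rows when the scorers never agree.
#' @examples
#' consensus_filter(c("W", "N1", "N2"), c("W", "N2", "N2"))
#' @export
consensus_filter <- function(labels_a, labels_b) {
  a <- unclass(hypnogram(as.character(labels_a)))
  b <- unclass(hypnogram(as.character(labels_b)))
  if (length(a) != length(b))
    stop("shape error: hypnograms differ in length (", length(a), " vs ",
         length(b), ")")
  keep <- which(a == b)
  data.frame(index = keep - 1L, stage = a[keep], stringsAsFactors = FALSE)
}
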