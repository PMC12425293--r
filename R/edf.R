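# Minimal European Data Format (EDF) support: fixed 256-byte ASCII header,
# 256 bytes of per-signal header fields, then data records of little-endian
# 16-bit integers scaled between the declared digital and physical ranges.
# Covers continuous equal-rate recordings, which is all PSG export needs here;
# EDF+ annotations and discontinuous files are out of scope.

edf_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read a PSG recording from an EDF file
#'
#' Parses the EDF header, reads every data record, and rescales the 16-bit
#' digital samples to the declared physical range. Samples are returned in
#' microvolts; a warning is issued for channels whose declared physical
#' dimension is not `uV` (the values are still trusted as stored).
#'
#' @param path Path to an EDF file.
#' @return A [psg_recording] with `fs` and channel names as declared in the
#'   file. All signals must share one sampling rate.
#' @export
read_edf <- function(path) {
  hdr <- readBin(path, "raw", n = 256L)
  if (length(hdr) < 256L)
    stop("format error: ", path, " is too short to hold an EDF header")
  header_bytes <- suppressWarnings(as.integer(edf_field(hdr, 184, 8)))
  n_records <- suppressWarnings(as.integer(edf_field(hdr, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(edf_field(hdr, 244, 8)))
  ns <- suppressWarnings(as.integer(edf_field(hdr, 252, 4)))
  if (anyNA(c(header_bytes, n_records, rec_dur, ns)) || ns < 1L)
    stop("format error: unparseable EDF header in ", path)

  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 256L)
  sig_hdr <- readBin(con, "raw", n = ns * 256L)
  if (length(sig_hdr) < ns * 256L)
    stop("format error: truncated EDF signal header in ", path)
  fld <- function(offset, width)
    vapply(seq_len(ns) - 1L,
           function(i) edf_field(sig_hdr, offset * ns + i * width, width),
           character(1))
  labels <- fld(0, 16)
  dims <- fld(96, 8)              # 16+80 bytes precede the dimension block
  phys_min <- as.numeric(fld(104, 8))
  phys_max <- as.numeric(fld(112, 8))
  dig_min <- as.numeric(fld(120, 8))
  dig_max <- as.numeric(fld(128, 8))
  spr <- as.integer(fld(216, 8))  # samples per data record

  if (any(dig_max == dig_min))
    stop("format error: EDF signal with empty digital range in ", path)
  if (length(unique(spr / rec_dur)) != 1L)
    stop("integrity error: EDF channels with mismatched sampling rates")
  off_uv <- which(!(tolower(dims) %in% c("uv", "")))
  if (length(off_uv))
    warning("EDF physical dimension is not uV for channel(s): ",
            paste(labels[off_uv], collapse = ", "),
            " -- values used as stored")

  seek(con, header_bytes)
  total <- n_records * sum(spr)
  raw_samp <- readBin(con, "integer", n = total, size = 2L,
                      signed = TRUE, endian = "little")
  if (length(raw_samp) < total)
    stop("format error: EDF data section shorter than header declares")

  signals <- vector("list", ns)
  names(signals) <- labels
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  pos <- 0L
  chunks <- lapply(seq_len(ns), function(s) vector("list", n_records))
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      chunk <- raw_samp[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      chunks[[s]][[r]] <- phys_min[s] + gain[s] * (chunk - dig_min[s])
    }
  }
  for (s in seq_len(ns)) signals[[s]] <- unlist(chunks[[s]], use.names = FALSE)
  psg_recording(signals, fs = spr[1] / rec_dur, reference = "none")
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a recording to a minimal EDF file
#'
#' Emits one data record per second with the physical range set
#' symmetrically to cover the data and the full 16-bit digital range.
#' Intended for interchange and for building test inputs in code; the
#' recording duration must be a whole number of seconds and `fs` an
#' integer.
#'
#' @param rec A [psg_recording] (samples interpreted as microvolts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- length(rec$signals[[1]])
  if (n %% fs != 0L)
    stop("write_edf requires a whole number of seconds of data")
  n_records <- n %/% fs
  ns <- length(rec$signals)

  pmax_v <- vapply(rec$signals, function(s) max(abs(s), 1), numeric(1))
  # header: 8+80+80+8+8+8+44+8+8+4 = 256 bytes
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_pad(1, 8), edf_pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_names, edf_pad, character(1), width = 16),
          collapse = ""),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad("uV", 8), ns),
    paste(vapply(-pmax_v, function(v) edf_pad(signif(v, 7), 8), character(1)),
          collapse = ""),
    paste(vapply(pmax_v, function(v) edf_pad(signif(v, 7), 8), character(1)),
          collapse = ""),
    strrep(edf_pad(-32768L, 8), ns),
    strrep(edf_pad(32767L, 8), ns),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad(fs, 8), ns),
    strrep(edf_pad("", 32), ns))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)
  dig <- lapply(seq_len(ns), function(s) {
    v <- rec$signals[[s]]
    pm <- pmax_v[s]
    as.integer(round((v + pm) / (2 * pm) * 65535 - 32768))
  })
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns))
      writeBin(dig[[s]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}
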