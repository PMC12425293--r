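# High-level runs behind the command-line interface: each composes the
# module operations, takes an explicit seed where randomness is involved,
# and writes plain-text outputs (WAV, CSV, JSON) plus a manifest.

#' Read / write rater response tables as CSV
#'
#' Columns: `participant_id`, `block`, `epoch`, `true_stage`, `response`,
#' `rt_seconds`, optionally `experience` (one of [EXPERIENCE_BINS]).
#'
#' @param path CSV path.
#' @return `read_responses` returns a named list of [response_set()]s, one
#'   per participant-block, names `"<participant>:<block>"`; an
#'   `experience` attribute maps participants to bins when the column is
#'   present.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "block", "epoch", "true_stage", "response",
            "rt_seconds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: response table lacks column(s): ",
         paste(miss, collapse = ", "))
  keys <- split(df, paste(df$participant_id, df$block, sep = ":"))
  out <- lapply(keys, function(sub)
    response_set(data.frame(epoch = sub$epoch, true_stage = sub$true_stage,
                            response = sub$response, rt = sub$rt_seconds,
                            stringsAsFactors = FALSE),
                 block_id = sub$block[1],
                 participant_id = as.character(sub$participant_id[1])))
  if ("experience" %in% names(df)) {
    exp_map <- tapply(df$experience, as.character(df$participant_id),
                      function(x) x[1])
    attr(out, "experience") <- exp_map
  }
  out
}

#' @rdname read_responses
#' @param sets List of [response_set()]s (or a single one).
#' @param experience Optional named vector mapping participant ids to
#'   [EXPERIENCE_BINS].
#' @export
write_responses <- function(sets, path, experience = NULL) {
  if (inherits(sets, "response_set")) sets <- list(sets)
  rows <- lapply(sets, function(rs) {
    df <- data.frame(participant_id = attr(rs, "participant_id"),
                     block = attr(rs, "block_id"),
                     epoch = rs$epoch, true_stage = rs$true_stage,
                     response = rs$response, rt_seconds = rs$rt,
                     stringsAsFactors = FALSE)
    if (!is.null(experience))
      df$experience <- unname(experience[df$participant_id])
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Sonify epochs of a recording into WAV files
#'
#' Composes the full rendering pipeline: read (or take) a recording,
#' optionally re-reference, split into 30-s epochs, downsample the chosen
#' channel to the display rate, audify, condition, and write one WAV per
#' requested epoch plus a `manifest.csv` (epoch index, stage when a
#' hypnogram is given, file, un-padded duration, measured RMS dBFS). The
#' pipeline is deterministic: rerunning with the same inputs reproduces
#' byte-identical outputs.
#'
#' @param input A [psg_recording] or a path readable by [read_recording()].
#' @param out_dir Output directory (created if needed).
#' @param channel Channel to sonify; the occipital O1 channel by default.
#' @param epochs 0-based epoch indices, or `NULL` for all.
#' @param params A [sonify_params()].
#' @param hyp Optional [hypnogram()] used to label the manifest.
#' @param reference Optional channel name to re-reference to before
#'   epoching (e.g. a right-ear electrode).
#' @return The manifest data frame, invisibly.
#' @export
run_sonify <- function(input, out_dir, channel = "O1", epochs = NULL,
                       params = sonify_params(), hyp = NULL,
                       reference = NULL) {
  rec <- if (inherits(input, "psg_recording")) input else read_recording(input)
  if (!is.null(reference)) rec <- rereference(rec, reference)
  if (!channel %in% rec$channel_names)
    stop("channel '", channel, "' not in recording (have: ",
         paste(rec$channel_names, collapse = ", "), ")")
  eps <- extract_epochs(rec, hypnogram = hyp)
  if (is.null(epochs)) epochs <- vapply(eps, `[[`, integer(1), "index")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(epochs, function(i) {
    if (i < 0 || i >= length(eps))
      stop("epoch ", i, ": index out of range (recording has ",
           length(eps), " complete epochs)")
    ep <- eps[[i + 1L]]
    x <- downsample_signal(ep$samples_by_channel[[channel]], rec$fs,
                           params$display_fs)
    clip <- condition_audio(audify(x, params, source_epoch = i), params)
    file <- file.path(out_dir, sprintf("epoch%04d.wav", i))
    write_wav(clip, file)
    data.frame(epoch = i, stage = ifelse(is.na(ep$true_stage), "",
                                         ep$true_stage),
               file = basename(file),
               duration_s = clip_duration(clip, padded = FALSE),
               rms_dbfs = clip$rms_dbfs, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

default_synth_config <- function() {
  list(n_epochs = 30L,
       stage_counts = c(W = 5L, N1 = 4L, N2 = 10L, N3 = 6L, REM = 5L),
       p_correct = 0.8, rt_mean = 5, rt_sd = 3, fs = 200)
}

load_synth_config <- function(config) {
  base <- default_synth_config()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) {
    tryCatch(yaml::read_yaml(config),
             error = function(e) stop("config error: cannot parse ", config,
                                      ": ", conditionMessage(e)))
  } else config
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  if (!is.null(user$stage_counts))
    base$stage_counts <- unlist(user$stage_counts)
  base
}

#' Generate a synthetic test-block fixture on disk
#'
#' Writes, under `out_dir`: a columnar-text recording and its hypnogram
#' (by default one 30-epoch test block with a realistic stage mix), a
#' simulated rater's response CSV, and a `synth_manifest.json` echoing the
#' seed and configuration. Configuration keys (YAML file or list):
#' `n_epochs`, `stage_counts`, `p_correct`, `rt_mean`, `rt_sd`, `fs`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing all randomness in the run.
#' @param config Optional YAML path or named list overriding defaults.
#' @return Named list of written paths, invisibly.
#' @export
run_synth <- function(out_dir, seed = 1L, config = NULL) {
  cfg <- load_synth_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- cfg$stage_counts
  if (sum(counts) != cfg$n_epochs) {
    # rescale the mix to the requested block length
    counts <- round(counts / sum(counts) * cfg$n_epochs)
    while (sum(counts) > cfg$n_epochs) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
    while (sum(counts) < cfg$n_epochs) counts[which.min(counts)] <-
      counts[which.min(counts)] + 1L
  }
  labels <- with_seed(seed, sample(rep(names(counts), counts)))
  hyp <- hypnogram(labels)
  syn <- synth_recording(hyp, seed = seed, fs = cfg$fs)
  rater <- rater_model(symmetric_confusion(cfg$p_correct),
                       rt_mean = cfg$rt_mean, rt_sd = cfg$rt_sd,
                       seed = (seed + 17L) %% .Machine$integer.max)
  resp <- synth_responses(labels, rater, block_id = "sound",
                          participant_id = "sim1")
  paths <- list(recording = file.path(out_dir, "recording.tsv"),
                hypnogram = file.path(out_dir, "hypnogram.txt"),
                responses = file.path(out_dir, "responses.csv"),
                manifest = file.path(out_dir, "synth_manifest.json"))
  write_recording(syn$recording, paths$recording)
  write_hypnogram(hyp, paths$hypnogram)
  write_responses(resp, paths$responses)
  jsonlite::write_json(list(seed = seed, config = cfg), paths$manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Score a response table and write a JSON report
#'
#' Scores every participant-block with [score_block()]; when participants
#' have both a `sound` and a `no_sound` block, adds the paired signed-rank
#' comparison of kappa across participants, and — when experience bins are
#' available and `by_experience = TRUE` — the per-bin paired comparisons.
#'
#' @param responses Path to a response CSV (see [read_responses()]) or a
#'   list of [response_set()]s.
#' @param out Optional path for the JSON report.
#' @param rt_sigma RT outlier multiplier passed to [score_block()].
#' @param by_experience Stratify the paired comparison by experience bin?
#' @param experience Optional named vector participant id -> bin,
#'   overriding any `experience` column.
#' @return The report as a list, invisibly.
#' @export
run_score <- function(responses, out = NULL, rt_sigma = 2,
                      by_experience = FALSE, experience = NULL) {
  sets <- if (is.character(responses)) read_responses(responses)
          else responses
  if (inherits(sets, "response_set")) sets <- list(sets)
  if (is.null(experience)) experience <- attr(sets, "experience")
  blocks <- lapply(sets, score_block, rt_sigma = rt_sigma)
  names(blocks) <- vapply(sets, function(rs)
    paste(attr(rs, "participant_id"), attr(rs, "block_id"), sep = ":"),
    character(1))
  report <- list(rt_sigma = rt_sigma, blocks = blocks)

  pid <- vapply(sets, function(rs) as.character(attr(rs, "participant_id")),
                character(1))
  bid <- vapply(sets, function(rs) attr(rs, "block_id"), character(1))
  both <- intersect(pid[bid == "sound"], pid[bid == "no_sound"])
  if (length(both) >= 2L) {
    k_of <- function(p, b)
      as.numeric(cohens_kappa(sets[[which(pid == p & bid == b)[1]]]))
    ks <- vapply(both, k_of, numeric(1), b = "sound")
    kn <- vapply(both, k_of, numeric(1), b = "no_sound")
    report$paired_kappa <- c(
      list(n = length(both)),
      paired_compare(ks, kn))
    if (by_experience && !is.null(experience)) {
      recs <- lapply(both, function(p)
        participant_record(p, experience[[p]], list(
          sound = sets[[which(pid == p & bid == "sound")[1]]],
          no_sound = sets[[which(pid == p & bid == "no_sound")[1]]])))
      strat <- stratify_by_experience(recs)
      report$by_experience <- lapply(strat, function(tab) {
        res <- if (nrow(tab) >= 2L)
          paired_compare(tab$kappa_sound, tab$kappa_no_sound)
        else list(p_value = NA, note = "fewer than 2 participants")
        c(list(n = nrow(tab)), res)
      })
    }
  }
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  invisible(report)
}
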