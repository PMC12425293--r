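#' Experience categories: polysomnograms staged in the past year
#' @format Character vector of the five bins.
#' @export
EXPERIENCE_BINS <- c("1-10", "11-20", "21-40", "41-80", ">80")

#' Construct a set of per-trial rater responses
#'
#' One row per staged epoch: the epoch id, the true (consensus) stage, the
#' stage the rater issued, and the reaction time in seconds.
#'
#' @param trials Data frame with columns `epoch`, `true_stage`, `response`,
#'   `rt` (seconds, strictly positive).
#' @param block_id One of `"sound"`, `"no_sound"`, `"practice"`.
#' @param participant_id Identifier of the rater.
#' @return The validated data frame, classed `response_set`, with
#'   `block_id` and `participant_id` attributes.
#' @export
response_set <- function(trials, block_id = "sound", participant_id = "p1") {
  need <- c("epoch", "true_stage", "response", "rt")
  if (!all(need %in% names(trials)))
    stop("schema error: trials must have columns ",
         paste(need, collapse = ", "))
  block_id <- match.arg(block_id, c("sound", "no_sound", "practice"))
  bad <- setdiff(unique(c(trials$true_stage, trials$response)), SLEEP_STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (any(trials$rt <= 0)) stop("reaction times must be positive")
  structure(trials[need], class = c("response_set", "data.frame"),
            block_id = block_id, participant_id = participant_id)
}

reclass_rs <- function(trials, template) {
  structure(trials, class = c("response_set", "data.frame"),
            block_id = attr(template, "block_id"),
            participant_id = attr(template, "participant_id"))
}

#' 5x5 confusion counts of a response set
#'
#' @param responses A [response_set()].
#' @return Integer matrix, rows = true stage, columns = issued stage.
#' @export
confusion_counts <- function(responses) {
  t_f <- factor(responses$true_stage, levels = SLEEP_STAGES)
  r_f <- factor(responses$response, levels = SLEEP_STAGES)
  unclass(table(true = t_f, response = r_f))
}

#' Cohen's kappa between issued and true stages
#'
#' Chance-corrected agreement, `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o` is the observed agreement fraction and `p_e` the agreement
#' expected from the marginal stage frequencies. Kappa corrects the
#' distortion that imbalanced stage prevalences cause in raw percent
#' correct, and is undefined when the true stage is constant across the
#' block (no chance-corrected scale exists); in that case `NA` is returned,
#' never a silent zero, with the reason attached as an attribute.
#'
#' @param responses A [response_set()] with at least one trial.
#' @return Kappa in \[-1, 1\], or `NA_real_` with attribute `reason` when
#'   undefined.
#' @export
cohens_kappa <- function(responses) {
  n <- nrow(responses)
  if (n < 1L) stop("input error: empty response set")
  if (length(unique(responses$true_stage)) < 2L)
    return(structure(NA_real_,
                     reason = "true stage constant across epochs"))
  cm <- confusion_counts(responses)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (1 - p_e < 1e-12)
    return(structure(NA_real_, reason = "expected agreement is 1"))
  unname((p_o - p_e) / (1 - p_e))
}

#' Percent of each true stage identified as that stage
#'
#' For every stage with at least one true instance in the block,
#' `100 * correctly identified / true instances`; e.g. recognizing 5 of 10
#' true Wake epochs gives Wake accuracy 50%. Stages absent from the block
#' are omitted. Unlike kappa, this remains defined for single-stage blocks.
#'
#' @param responses A [response_set()].
#' @return Named numeric vector of percentages, names in [SLEEP_STAGES].
#' @export
per_stage_accuracy <- function(responses) {
  cm <- confusion_counts(responses)
  present <- rowSums(cm) > 0
  100 * diag(cm)[present] / rowSums(cm)[present]
}

#' Drop trials with outlier reaction times
#'
#' Keeps trials whose RT lies within `k` standard deviations of the mean,
#' where mean and sd are computed once on the input set (no iterative
#' re-filtering). With identical RTs nothing is removed (the bound holds at
#' equality); with fewer than two trials the set is returned unchanged with
#' a warning.
#'
#' @param responses A [response_set()].
#' @param k Sigma multiplier (default 2); `Inf` keeps everything.
#' @return The filtered [response_set()], original trial order preserved.
#' @export
filter_rt_outliers <- function(responses, k = 2) {
  n <- nrow(responses)
  if (n < 2L) {
    warning("fewer than 2 trials: RT outlier filter not applied")
    return(responses)
  }
  if (!is.finite(k)) return(responses)
  m <- mean(responses$rt)
  s <- stats::sd(responses$rt)
  keep <- abs(responses$rt - m) <= k * s
  reclass_rs(responses[keep, , drop = FALSE], responses)
}

#' Keep only correctly staged trials
#'
#' Reaction-time analyses condition on correctness: a trial counts only
#' when the issued stage equals the true stage.
#'
#' @param responses A [response_set()].
#' @return Subset [response_set()].
#' @export
correct_only <- function(responses) {
  reclass_rs(responses[responses$response == responses$true_stage, ,
                       drop = FALSE],
             responses)
}

#' Practice-block quality gate against bots and inattentive raters
#'
#' A rater passes only if the median time to stage a practice epoch is at
#' least `threshold` seconds; medians strictly below fail (implausibly fast
#' responding), a median of exactly `threshold` passes.
#'
#' @param practice A non-empty [response_set()] from the practice block.
#' @param threshold Seconds (default 2).
#' @return `TRUE` (pass) or `FALSE` (fail), with the median RT attached as
#'   attribute `median_rt`.
#' @export
practice_gate <- function(practice, threshold = 2) {
  if (nrow(practice) < 1L) stop("input error: empty practice block")
  med <- stats::median(practice$rt)
  structure(!(med < threshold), median_rt = med)
}

# Exact null distribution of the signed-rank statistic W+ under random
# signs, tied (mid-)ranks included: ranks are doubled to integers and the
# distribution built by convolution, so no 2^n enumeration is needed.
signed_rank_null <- function(ranks2) {
  S <- sum(ranks2)
  p <- numeric(S + 1L)
  p[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(S + 1L - r)])
    p <- 0.5 * p + 0.5 * shifted
  }
  p  # p[w + 1] = P(W+ = w) on the doubled-rank scale
}

#' Paired comparison of per-participant metrics
#'
#' Wilcoxon signed-rank test of paired metric values (e.g. kappa in the
#' sound vs the no-sound block). Zero differences are dropped before
#' ranking, per the original signed-rank convention. `"signed_rank_exact"`
#' computes the exact two-sided p-value from the full null distribution of
#' the statistic (ties handled by mid-ranks, distribution built by
#' convolution); `"permutation"` estimates it by random sign flips, for
#' use at larger n.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by
#'   participant.
#' @param method `"signed_rank_exact"` (default for n <= 25) or
#'   `"permutation"`.
#' @param nperm Number of sign-flip draws for the permutation method.
#' @return List with `p_value`, `statistic` (W+, sum of positive-difference
#'   ranks), `direction` (`"a_greater"`, `"b_greater"` or `"none"`),
#'   `n_effective` (pairs after dropping zeros) and `method`.
#' @export
paired_compare <- function(values_a, values_b,
                           method = c("auto", "signed_rank_exact",
                                      "permutation"),
                           nperm = 10000L) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b))
    stop("paired metrics must have equal length")
  if (length(values_a) < 2L) stop("need at least 2 pairs")
  d <- values_a - values_b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(list(p_value = 1, statistic = NA_real_, direction = "none",
                n_effective = 0L, method = method))
  }
  if (method == "auto")
    method <- if (n <= 25L) "signed_rank_exact" else "permutation"
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- sum(r)
  direction <- if (W > S / 2) "a_greater" else if (W < S / 2) "b_greater"
               else "none"
  if (method == "signed_rank_exact") {
    r2 <- as.integer(round(2 * r))  # mid-ranks are multiples of 1/2
    null <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
  } else {
    signs <- matrix(stats::runif(n * nperm) < 0.5, nrow = n)
    W_perm <- as.vector(r %*% signs)
    p_le <- mean(W_perm <= W)
    p_ge <- mean(W_perm >= W)
  }
  list(p_value = min(1, 2 * min(p_le, p_ge)), statistic = W,
       direction = direction, n_effective = n, method = method)
}

#' Bundle one participant's blocks with their staging experience
#'
#' @param participant_id Identifier.
#' @param experience_bin One of [EXPERIENCE_BINS] (polysomnograms staged in
#'   the past year).
#' @param blocks Named list of [response_set()]s, e.g.
#'   `list(sound = ..., no_sound = ...)`.
#' @return A list of class `participant_record`.
#' @export
participant_record <- function(participant_id, experience_bin, blocks) {
  experience_bin <- match.arg(experience_bin, EXPERIENCE_BINS)
  structure(list(participant_id = participant_id,
                 experience_bin = experience_bin, blocks = blocks),
            class = "participant_record")
}

#' Split the cohort by staging experience for paired testing
#'
#' For each experience bin with at least one participant, returns the
#' per-participant (sound, no_sound) kappa pairs ready for
#' [paired_compare()]. Empty bins are omitted with a message.
#'
#' @param records List of [participant_record()]s whose blocks include
#'   `sound` and `no_sound`.
#' @return Named list of data frames (`participant_id`, `kappa_sound`,
#'   `kappa_no_sound`), one per non-empty bin, in [EXPERIENCE_BINS] order.
#' @export
stratify_by_experience <- function(records) {
  rows <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "participant_record"))
    data.frame(participant_id = rec$participant_id,
               experience_bin = rec$experience_bin,
               kappa_sound = as.numeric(cohens_kappa(rec$blocks$sound)),
               kappa_no_sound = as.numeric(cohens_kappa(rec$blocks$no_sound)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- lapply(EXPERIENCE_BINS, function(b) {
    sub <- tab[tab$experience_bin == b,
               c("participant_id", "kappa_sound", "kappa_no_sound")]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- EXPERIENCE_BINS
  empty <- vapply(out, nrow, integer(1)) == 0L
  if (any(empty))
    message("omitting empty experience bin(s): ",
            paste(EXPERIENCE_BINS[empty], collapse = ", "))
  out[!empty]
}

rt_summary_stats <- function(rt) {
  list(n = length(rt),
       mean = if (length(rt)) mean(rt) else NA_real_,
       median = if (length(rt)) stats::median(rt) else NA_real_,
       sd = if (length(rt) > 1) stats::sd(rt) else NA_real_)
}

#' Score one block of responses
#'
#' Computes the block-level performance report: Cohen's kappa, per-stage
#' percent correct, the 5x5 confusion counts, and reaction-time summaries
#' both raw and after the standard RT analysis filter (correct trials only,
#' then RTs within `rt_sigma` standard deviations of the mean).
#'
#' @param responses A [response_set()].
#' @param rt_sigma Sigma multiplier for RT outlier exclusion (default 2).
#' @return A list of class `score_report`.
#' @export
score_block <- function(responses, rt_sigma = 2) {
  cm <- confusion_counts(responses)
  correct <- correct_only(responses)
  filtered <- if (nrow(correct) >= 2L)
    filter_rt_outliers(correct, k = rt_sigma) else correct
  structure(list(
    participant_id = attr(responses, "participant_id"),
    block_id = attr(responses, "block_id"),
    kappa = cohens_kappa(responses),
    per_stage_accuracy = as.list(per_stage_accuracy(responses)),
    confusion = cm,
    n_trials = nrow(responses),
    n_correct = sum(diag(cm)),
    rt_summary = list(raw = rt_summary_stats(responses$rt),
                      correct_filtered = rt_summary_stats(filtered$rt)),
    rt_sigma = rt_sigma),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s / %s: n=%d, correct=%d, kappa=%s\n",
              x$participant_id, x$block_id, x$n_trials, x$n_correct,
              if (is.na(x$kappa)) paste0("undefined (", attr(x$kappa, "reason"), ")")
              else sprintf("%.3f", x$kappa)))
  acc <- unlist(x$per_stage_accuracy)
  if (length(acc))
    cat("  per-stage %:", paste(sprintf("%s=%.0f", names(acc), acc),
                                collapse = " "), "\n")
  cat(sprintf("  RT (correct, %.0f-sigma filtered): median %.2f s over %d trials\n",
              x$rt_sigma, x$rt_summary$correct_filtered$median,
              x$rt_summary$correct_filtered$n))
  invisible(x)
}
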