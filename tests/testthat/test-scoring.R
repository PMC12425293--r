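test_that("kappa is 1 for perfect agreement and undefined for constant truth", {
  truth <- c("W", "N1", "N2", "N3", "REM", "N2")
  expect_equal(cohens_kappa(make_rs(truth, truth)), 1)

  same <- make_rs(rep("N2", 10), sample(SLEEP_STAGES, 10, replace = TRUE))
  k <- cohens_kappa(same)
  expect_true(is.na(k))
  expect_match(attr(k, "reason"), "constant")
  expect_error(cohens_kappa(make_rs(character(0), character(0))),
               "input error")
})

test_that("kappa matches the hand-computed two-label worked case", {
  # confusion [[20,5],[10,15]]: p_o = 35/50 = 0.7, p_e = 0.5, kappa = 0.4
  truth <- c(rep("W", 25), rep("N1", 25))
  resp <- c(rep("W", 20), rep("N1", 5), rep("W", 10), rep("N1", 15))
  expect_equal(cohens_kappa(make_rs(truth, resp)), 0.4)
})

test_that("kappa equals brute-force computation and respects symmetries", {
  for (seed in 1:40) {
    rs <- random_rs(n = 25 + seed %% 20, seed = seed)
    expect_equal(as.numeric(cohens_kappa(rs)),
                 kappa_brute(rs$true_stage, rs$response),
                 tolerance = 1e-12)
    # order invariance
    perm <- sample(nrow(rs))
    shuffled <- make_rs(rs$true_stage[perm], rs$response[perm], rs$rt[perm])
    expect_equal(cohens_kappa(shuffled), cohens_kappa(rs))
    # joint relabeling invariance
    relab <- setNames(sample(SLEEP_STAGES), SLEEP_STAGES)
    relabeled <- make_rs(unname(relab[rs$true_stage]),
                         unname(relab[rs$response]), rs$rt)
    expect_equal(cohens_kappa(relabeled), cohens_kappa(rs))
  }
})

test_that("per-stage accuracy reports percent of each true stage recognized", {
  truth <- c(rep("W", 10), rep("N2", 4))
  resp <- c(rep("W", 5), rep("N1", 5), rep("N2", 4))
  acc <- per_stage_accuracy(make_rs(truth, resp))
  expect_equal(acc[["W"]], 50)
  expect_equal(acc[["N2"]], 100)
  expect_false("N3" %in% names(acc))   # absent stages omitted

  all_right <- make_rs(truth, truth)
  expect_true(all(per_stage_accuracy(all_right) == 100))
})

test_that("prevalence-weighted per-stage accuracy equals overall percent correct", {
  for (seed in 41:60) {
    rs <- random_rs(40, seed)
    acc <- per_stage_accuracy(rs)
    prev <- table(factor(rs$true_stage, SLEEP_STAGES))[names(acc)]
    weighted <- sum(acc * as.numeric(prev)) / nrow(rs)
    expect_equal(weighted, 100 * mean(rs$response == rs$true_stage))
  }
})

test_that("the two-sigma RT filter excludes exactly the outlying trials", {
  rt <- c(rep(2, 9), 50)
  rs <- make_rs(rep(c("W", "N2"), 5), rep(c("W", "N2"), 5), rt)
  kept <- filter_rt_outliers(rs, k = 2)
  # oracle: direct mean/sd computation marks only the 50 s trial
  expect_true(50 > mean(rt) + 2 * sd(rt))
  expect_equal(nrow(kept), 9)
  expect_false(50 %in% kept$rt)

  flat <- make_rs(rep(c("W", "N2"), 3), rep(c("W", "N2"), 3), rep(3, 6))
  expect_equal(nrow(filter_rt_outliers(flat)), 6)     # sigma = 0, all kept
  expect_identical(nrow(filter_rt_outliers(rs, k = Inf)), nrow(rs))
  one <- make_rs("W", "W", 5)
  expect_warning(out <- filter_rt_outliers(one), "fewer than 2")
  expect_equal(nrow(out), 1)
})

test_that("the RT filter keeps the majority of log-normal samples at k = 2", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30 + seed
    rs <- make_rs(rep(c("W", "N2"), length.out = n),
                  rep(c("W", "N2"), length.out = n),
                  rlnorm(n, log(5), 0.6))
    kept <- nrow(filter_rt_outliers(rs, k = 2))
    expect_gt(kept, n - kept)
  }
})

test_that("correct-only keeps trials where the issued stage is true", {
  rs <- make_rs(c("W", "N1", "N2", "N3"), c("W", "N2", "N2", "REM"),
                1:4)
  co <- correct_only(rs)
  expect_equal(nrow(co), 2)
  expect_true(all(co$response == co$true_stage))
  perfect <- make_rs(c("W", "N2"), c("W", "N2"))
  expect_equal(nrow(correct_only(perfect)), 2)
  none <- make_rs(c("W", "N2"), c("N2", "W"))
  expect_equal(nrow(correct_only(none)), 0)
})

test_that("the practice gate fails bot-like medians and passes plausible ones", {
  bot <- make_rs(rep(c("W", "N2"), 5), rep("W", 10),
                 rt = rep(0.59, 10), block = "practice")
  expect_false(practice_gate(bot))
  human <- make_rs(rep(c("W", "N2"), 5), rep("W", 10),
                   rt = rep(5.5, 10), block = "practice")
  expect_true(practice_gate(human))
  boundary <- make_rs(rep(c("W", "N2"), 5), rep("W", 10),
                      rt = rep(2, 10), block = "practice")
  expect_true(practice_gate(boundary))   # strictly-less-than fails
  expect_error(practice_gate(make_rs(character(0), character(0),
                                     numeric(0))), "input error")
})

test_that("exact signed-rank p-values match full 2^n enumeration", {
  # spec'd hand case: n = 5, all differences positive -> 2/32
  res <- paired_compare(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5),
                        method = "signed_rank_exact")
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$direction, "a_greater")

  set.seed(77)
  for (n in c(4, 6, 8, 10, 12)) {
    a <- rnorm(n); b <- rnorm(n)
    got <- paired_compare(a, b, method = "signed_rank_exact")
    expect_equal(got$p_value, signed_rank_enum(a - b), tolerance = 1e-12)
  }
  # tied absolute differences exercise the mid-rank path
  a <- c(3, 1, 4, 4, 2, 6); b <- c(1, 3, 2, 2, 4, 1)
  expect_equal(paired_compare(a, b, method = "signed_rank_exact")$p_value,
               signed_rank_enum(a - b), tolerance = 1e-12)
})

test_that("permutation p-values agree with the exact method", {
  set.seed(99)
  a <- rnorm(10, mean = 0.4); b <- rnorm(10)
  exact <- paired_compare(a, b, method = "signed_rank_exact")$p_value
  perm <- paired_compare(a, b, method = "permutation", nperm = 20000)$p_value
  expect_lt(abs(perm - exact), 0.02)
})

test_that("degenerate paired inputs are handled explicitly", {
  expect_warning(res <- paired_compare(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(res$p_value, 1)
  expect_error(paired_compare(1:3, 1:2), "equal length")
  expect_error(paired_compare(1, 1), "at least 2")
})

test_that("experience stratification returns one kappa table per occupied bin", {
  set.seed(11)
  truth <- rep(SLEEP_STAGES, times = 6)
  mk_rec <- function(id, bin) {
    blocks <- lapply(c(sound = "sound", no_sound = "no_sound"), function(b)
      synth_responses(truth, rater_model(symmetric_confusion(0.8),
                                         seed = abs(utf8ToInt(substr(id, 2, 2))) +
                                           nchar(b)),
                      block_id = b, participant_id = id))
    participant_record(id, bin, blocks)
  }
  counts <- c(14, 8, 10, 5, 3)   # cohort-shaped bin sizes
  ids <- sprintf("p%02d", seq_len(sum(counts)))
  bins <- rep(EXPERIENCE_BINS, counts)
  recs <- Map(mk_rec, ids, bins)
  tabs <- stratify_by_experience(recs)
  expect_named(tabs, EXPERIENCE_BINS)
  expect_equal(unname(vapply(tabs, nrow, integer(1))), counts)
  expect_true(all(c("kappa_sound", "kappa_no_sound") %in% names(tabs[[1]])))

  expect_message(solo <- stratify_by_experience(recs[bins == "11-20"]),
                 "omitting")
  expect_named(solo, "11-20")
})

test_that("a sound benefit confined to novices is detected only in their bin", {
  counts <- c(14, 8, 10, 5, 3)
  n_reps <- 20
  truth <- rep(SLEEP_STAGES, times = 6)
  hits <- logical(n_reps)
  for (rep_i in seq_len(n_reps)) {
    recs <- list(); id <- 0
    for (b in seq_along(EXPERIENCE_BINS)) {
      for (j in seq_len(counts[b])) {
        id <- id + 1
        p_sound <- if (b == 1) 0.95 else 0.75
        p_quiet <- if (b == 1) 0.50 else 0.75
        seed0 <- rep_i * 10000 + id * 10
        blocks <- list(
          sound = synth_responses(truth,
            rater_model(symmetric_confusion(p_sound), seed = seed0),
            block_id = "sound", participant_id = paste0("p", id)),
          no_sound = synth_responses(truth,
            rater_model(symmetric_confusion(p_quiet), seed = seed0 + 1),
            block_id = "no_sound", participant_id = paste0("p", id)))
        recs[[id]] <- participant_record(paste0("p", id),
                                         EXPERIENCE_BINS[b], blocks)
      }
    }
    tabs <- stratify_by_experience(recs)
    ps <- vapply(tabs, function(tb) suppressWarnings(
      paired_compare(tb$kappa_sound, tb$kappa_no_sound)$p_value), numeric(1))
    hits[rep_i] <- ps[["1-10"]] < 0.05 && all(ps[names(ps) != "1-10"] >= 0.05)
  }
  expect_gte(mean(hits), 0.8)
})

test_that("block scoring assembles kappa, accuracies, confusion and RT summaries", {
  set.seed(13)
  truth <- rep(SLEEP_STAGES, times = 6)
  rs <- synth_responses(truth, rater_model(symmetric_confusion(0.8),
                                           rt_mean = 5, rt_sd = 2, seed = 4))
  rep_ <- score_block(rs)
  expect_s3_class(rep_, "score_report")
  expect_equal(sum(rep_$confusion), rep_$n_trials)
  expect_equal(rep_$n_correct, sum(diag(rep_$confusion)))
  expect_equal(rep_$kappa, cohens_kappa(rs))
  expect_lte(rep_$rt_summary$correct_filtered$n, rep_$n_correct)
  expect_output(print(rep_), "score_report")
})
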