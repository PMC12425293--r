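test_that("epoch generation is deterministic per (stage, seed)", {
  a <- synth_epoch("N2", seed = 42)
  b <- synth_epoch("N2", seed = 42)
  expect_identical(a$samples_by_channel, b$samples_by_channel)
  c <- synth_epoch("N2", seed = 43)
  expect_false(identical(a$samples_by_channel$O1, c$samples_by_channel$O1))
  expect_error(synth_epoch("S4", seed = 1), "parameter error")
})

test_that("generated epochs have the right shape and stay displayable", {
  ep <- synth_epoch("W", seed = 1)
  expect_named(ep$samples_by_channel, c("F3", "C3", "O1", "LOC", "EMG"))
  expect_length(ep$samples_by_channel$O1, 6000)   # 30 s at 200 Hz
  expect_equal(ep$fs, 200)
  expect_identical(ep$true_stage, "W")
  # EEG channels sit within ~ the +-100 uV display convention
  for (s in 1:5)
    expect_lt(max(abs(synth_epoch("W", s)$samples_by_channel$O1)), 120)
})

test_that("Wake shows a dominant ~10 Hz occipital rhythm", {
  for (seed in 1:5) {
    ep <- synth_epoch("W", seed = seed)
    # oracle: smoothed periodogram argmax on O1
    sp <- stats::spec.pgram(stats::ts(ep$samples_by_channel$O1,
                                      frequency = 200),
                            spans = 9, taper = 0.1, plot = FALSE)
    peak <- sp$freq[which.max(sp$spec)]
    expect_gte(peak, 9); expect_lte(peak, 11)
  }
})

test_that("N3 carries more delta power than any other stage", {
  for (seed in 1:5) {
    d <- vapply(SLEEP_STAGES, function(st)
      bandpower_features(synth_epoch(st, seed = seed))[["delta"]],
      numeric(1))
    expect_identical(names(which.max(d)), "N3")
  }
})

test_that("N2 spindles raise central sigma power; REM shows atonia and eye movements", {
  for (seed in 1:5) {
    sig_n2 <- bandpower_features(synth_epoch("N2", seed), "C3")[["sigma"]]
    sig_n1 <- bandpower_features(synth_epoch("N1", seed), "C3")[["sigma"]]
    expect_gt(sig_n2, sig_n1)
    emg_rms <- function(st)
      sqrt(mean(synth_epoch(st, seed)$samples_by_channel$EMG^2))
    expect_lt(emg_rms("REM"), emg_rms("W") / 3)
    loc_peak <- function(st)
      max(abs(synth_epoch(st, seed)$samples_by_channel$LOC))
    expect_gt(loc_peak("REM"), loc_peak("N2") * 1.5)
  }
})

test_that("band-power features separate the five stages above chance", {
  feats <- function(st, seeds) t(vapply(seeds, function(s)
    log(bandpower_features(synth_epoch(st, s))), numeric(4)))
  train_seeds <- 1:10; test_seeds <- 11:20
  centroids <- lapply(SLEEP_STAGES, function(st)
    colMeans(feats(st, train_seeds)))
  names(centroids) <- SLEEP_STAGES
  classify <- function(f) {
    d <- vapply(centroids, function(ce) sum((f - ce)^2), numeric(1))
    names(which.min(d))
  }
  truth <- rep(SLEEP_STAGES, each = length(test_seeds))
  pred <- unlist(lapply(SLEEP_STAGES, function(st)
    apply(feats(st, test_seeds), 1, classify)))
  acc <- mean(pred == truth)
  expect_gt(acc, 0.2)   # chance for 5 balanced classes
})

test_that("recordings concatenate epochs with boundaries on 30-s multiples", {
  syn <- synth_recording(hypnogram(c("W", "N2", "N3", "REM")), seed = 9)
  expect_equal(recording_duration(syn$recording), 120)
  expect_length(syn$hypnogram, 4)

  eps <- extract_epochs(syn$recording, hypnogram = syn$hypnogram)
  expect_length(eps, 4)
  expect_identical(vapply(eps, `[[`, character(1), "true_stage"),
                   c("W", "N2", "N3", "REM"))
  # round trip: extracted epochs keep their stage signatures
  d <- vapply(eps, function(e) bandpower_features(e, "F3")[["delta"]],
              numeric(1))
  expect_identical(which.max(d), 3L)   # the N3 epoch
  a <- vapply(eps, function(e) bandpower_features(e, "O1")[["alpha"]],
              numeric(1))
  expect_identical(which.max(a), 1L)   # the Wake epoch

  empty <- synth_recording(hypnogram(character(0)), seed = 1)
  expect_equal(recording_duration(empty$recording), 0)
})

test_that("simulated raters follow their confusion matrix and RT model", {
  truth <- rep(SLEEP_STAGES, times = 6)
  ident <- rater_model(diag(5), rt_mean = 4, rt_sd = 2, seed = 1)
  rs <- synth_responses(truth, ident)
  expect_identical(rs$response, truth)
  expect_true(all(rs$rt > 0))
  expect_identical(synth_responses(truth, ident)$rt, rs$rt)  # seeded

  expect_error(rater_model(matrix(0.3, 5, 5)), "model error")
  expect_error(rater_model(matrix(0.2, 4, 5)), "model error")

  # log-normal RTs approximately match the requested mean and sd
  big <- synth_responses(rep(SLEEP_STAGES, 2000),
                         rater_model(diag(5), rt_mean = 5, rt_sd = 3,
                                     seed = 8))
  expect_equal(mean(big$rt), 5, tolerance = 0.1)
  expect_equal(sd(big$rt), 3, tolerance = 0.15)
})

test_that("a uniform guesser scores chance-level kappa", {
  set.seed(21)
  truth <- sample(SLEEP_STAGES, 5000, replace = TRUE)
  unif <- rater_model(matrix(0.2, 5, 5), seed = 2)
  k <- cohens_kappa(synth_responses(truth, unif))
  expect_lt(abs(k), 0.03)
})

test_that("measured kappa recovers (p - 0.2)/0.8 for symmetric confusions", {
  set.seed(31)
  truth <- sample(SLEEP_STAGES, 5000, replace = TRUE)
  for (p in c(0.3, 0.6, 0.9)) {
    rs <- synth_responses(truth, rater_model(symmetric_confusion(p),
                                             seed = 100 + round(100 * p)))
    k <- cohens_kappa(rs)
    p_o <- mean(rs$response == rs$true_stage)
    se <- sqrt(p_o * (1 - p_o)) / (0.8 * sqrt(nrow(rs)))
    expect_lt(abs(k - (p - 0.2) / 0.8), 3 * se)
  }
})
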