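# Shared builders for small in-code fixtures.

make_rs <- function(truth, response, rt = NULL, block = "sound", pid = "p1") {
  n <- length(truth)
  if (is.null(rt)) rt <- rep(5, n)
  response_set(data.frame(epoch = seq_len(n) - 1L, true_stage = truth,
                          response = response, rt = rt,
                          stringsAsFactors = FALSE),
               block_id = block, participant_id = pid)
}

# Random response set over the 5 stages (truth guaranteed non-constant).
random_rs <- function(n, seed) {
  set.seed(seed)
  truth <- sample(SLEEP_STAGES, n, replace = TRUE)
  truth[1:2] <- c("W", "N2")
  make_rs(truth, sample(SLEEP_STAGES, n, replace = TRUE),
          rt = runif(n, 1, 10))
}

# Brute-force Cohen's kappa: double loop over trials, no contingency table.
kappa_brute <- function(truth, response) {
  n <- length(truth)
  p_o <- sum(truth == response) / n
  agree_chance <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      agree_chance <- agree_chance + (truth[i] == response[j])
  p_e <- agree_chance / n^2
  (p_o - p_e) / (1 - p_e)
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign vectors.
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Downsample + audify + condition one synthetic epoch channel.
render_epoch <- function(stage, seed, channel = "O1",
                         params = sonify_params(), conditioned = TRUE) {
  ep <- synth_epoch(stage, seed)
  x <- downsample_signal(ep$samples_by_channel[[channel]], ep$fs,
                         params$display_fs)
  clip <- audify(x, params)
  if (conditioned) condition_audio(clip, params) else clip
}
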