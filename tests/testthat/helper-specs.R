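# Small cohort specifications reused across tests.  Sizes are reduced
# relative to the default study design so simulation-heavy checks finish
# quickly; statistical properties under test do not depend on them.

tiny_spec <- function(n_subjects = 4, ..., seed = 1) {
  cohort_spec(n_subjects = n_subjects, rest_s = 10, trials_per_block = 3,
              seed = seed, ...)
}

flat_behavior <- function() {
  data.frame(
    phenotype = rep(c("white_benefit", "unaffected", "silence_benefit"), each = 2),
    condition = rep(c("white", "silent"), times = 3),
    score_mean = 80, score_sd = 2, vas_mean = 5, vas_sd = 1,
    stringsAsFactors = FALSE)
}

# cohort with no condition-dependent effect anywhere (null hypothesis
# holds for every channel-wise paired comparison)
null_spec <- function(n_subjects = 10, seed = 1, ...) {
  cohort_spec(
    n_subjects = n_subjects, rest_s = 20, trials_per_block = 3,
    group_fractions = c(white_benefit = 0, unaffected = 1,
                        silence_benefit = 0),
    activation = list(list(phenotype = "all", condition = "both",
                           channels = NULL, amplitude = 0.02)),
    connectivity = list(list(phenotype = "all", condition = "both",
                             channels = NULL, loading = 0.2)),
    behavior = flat_behavior(), seed = seed, ...)
}

# a hand-built design: alternating rest/task blocks of given sample
# lengths, one trivial trial per task block
toy_design <- function(task_lens = c(100, 100), rest_len = 50, fs = 10,
                       trial_period_s = 11) {
  pos <- 0L
  rest <- NULL
  task <- NULL
  trials <- list()
  for (len in task_lens) {
    rest <- rbind(rest, c(pos, pos + rest_len))
    pos <- pos + rest_len
    task <- rbind(task, c(pos, pos + len))
    stopifnot(len > 30)
    trials[[length(trials) + 1L]] <- cbind(
      memorize_start = pos, memorize_end = pos + 10L,
      retain_start = pos + 10L, retain_end = pos + 20L,
      answer_start = pos + 20L, answer_end = pos + len)
    pos <- pos + len
  }
  rest <- rbind(rest, c(pos, pos + rest_len))
  block_design(rest, task, trials, trial_period_s = trial_period_s, fs = fs)
}

# recording with given oxy matrix (deoxy mirrored), optionally marked as
# fully preprocessed so measure-stage functions accept it directly
toy_recording <- function(oxy, fs = 10, preprocessed = FALSE, ...) {
  rec <- fnirs_recording(oxy, -0.4 * oxy, fs = fs, ...)
  if (preprocessed) {
    rec$filtered <- TRUE
    rec$zscored <- TRUE
    rec$baselined <- TRUE
  }
  rec
}

# brute-force node strength: explicit double loop over valid channels
brute_strength <- function(z) {
  n <- nrow(z)
  valid <- sapply(seq_len(n), function(i) any(!is.na(z[i, -i])))
  s <- rep(NA_real_, n)
  for (i in which(valid)) {
    acc <- 0
    for (j in seq_len(n))
      if (j != i && valid[j] && !is.na(z[i, j])) acc <- acc + z[i, j]
    s[i] <- acc
  }
  names(s) <- rownames(z)
  s
}

random_z_matrix <- function(n = 8) {
  z <- matrix(stats::rnorm(n * n, sd = 0.5), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- NA_real_
  dimnames(z) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  z
}
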