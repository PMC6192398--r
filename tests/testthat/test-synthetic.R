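test_that("generated designs have the study's block structure", {
  spec <- cohort_spec(seed = 1)
  set.seed(1)
  design <- generate_design(spec)
  # 3 task blocks, each flanked by 60 s rest, plus a closing rest block
  expect_identical(nrow(design$task_blocks), 3L)
  expect_identical(nrow(design$rest_blocks), 4L)
  expect_true(all(design$rest_blocks[, 2] - design$rest_blocks[, 1] == 600L))
  for (b in 1:3) {
    tr <- design$trials[[b]]
    expect_identical(nrow(tr), 10L)
    # memorize 3 s, retain 1 s, answer in (0, 7] s
    expect_true(all(tr[, "memorize_end"] - tr[, "memorize_start"] == 30L))
    expect_true(all(tr[, "retain_end"] - tr[, "retain_start"] == 10L))
    ans <- tr[, "answer_end"] - tr[, "answer_start"]
    expect_true(all(ans > 0 & ans <= 70L))
    # trials tile the task block
    expect_identical(unname(tr[1, "memorize_start"]),
                     unname(design$task_blocks[b, "start"]))
    expect_identical(unname(tr[10, "answer_end"]),
                     unname(design$task_blocks[b, "end"]))
  }
})

test_that("fixed 7 s answers give T = 11 s and 110 s task blocks", {
  spec <- cohort_spec(answer_range_s = c(7, 7), seed = 1)
  set.seed(1)
  design <- generate_design(spec)
  expect_equal(design$trial_period_s, 11)
  expect_true(all(design$task_blocks[, 2] - design$task_blocks[, 1] == 1100L))
})

test_that("designs vary by seed in answer durations but not in structure", {
  spec <- cohort_spec(seed = 1)
  set.seed(10); d1 <- generate_design(spec)
  set.seed(20); d2 <- generate_design(spec)
  expect_identical(nrow(d1$task_blocks), nrow(d2$task_blocks))
  expect_false(identical(d1$trials, d2$trials))
})

test_that("subject generation is deterministic given (spec, seed)", {
  spec <- tiny_spec()
  s1 <- generate_subject(spec, "white_benefit", seed = 7)
  s2 <- generate_subject(spec, "white_benefit", seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_subject(spec, "white_benefit", seed = 8)
  expect_false(identical(s1$recordings$white$oxy, s3$recordings$white$oxy))
})

test_that("physiological noise peaks at the configured frequencies", {
  spec <- cohort_spec(n_subjects = 2, seed = 1)
  sub <- generate_subject(spec, "unaffected", seed = 3)
  x <- sub$recordings$white$oxy[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = spec$fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  bin <- sp$freq[2] - sp$freq[1]
  for (f0 in c(spec$noise$cardiac_hz, spec$noise$resp_hz)) {
    win <- which(abs(sp$freq - f0) < 0.05)
    peak <- sp$freq[win][which.max(sp$spec[win])]
    expect_lt(abs(peak - f0), 1.5 * bin)
  }
})

test_that("latent-factor channels obey the closed-form correlation", {
  set.seed(123)
  for (lam in c(1, 2)) {
    x <- simulate_factor_channels(c(lam, lam), 1e5)
    expect_lt(abs(stats::cor(x[1, ], x[2, ]) - lam^2 / (lam^2 + 1)), 0.015)
  }
})

test_that("phenotype apportionment uses largest remainders", {
  spec <- cohort_spec(n_subjects = 29, seed = 1)
  cohort <- generate_cohort(spec, include_recordings = FALSE)
  counts <- table(cohort$phenotypes)
  expect_identical(as.integer(counts[c("white_benefit", "unaffected",
                                       "silence_benefit")]),
                   c(8L, 13L, 8L))
  one <- cohort_spec(n_subjects = 4,
                     group_fractions = c(white_benefit = 1, unaffected = 0,
                                         silence_benefit = 0), seed = 1)
  expect_true(all(generate_cohort(one,
                                  include_recordings = FALSE)$phenotypes ==
                    "white_benefit"))
  expect_error(generate_cohort(cohort_spec(n_subjects = 1)), "at least 2")
})

test_that("behavioural draws match between fast and full generation", {
  spec <- tiny_spec(seed = 5)
  fast <- generate_cohort(spec, include_recordings = FALSE)
  full <- generate_cohort(spec)
  expect_identical(fast$behavior, full$behavior)
})

test_that("planted score separation is recovered at cohort level", {
  set.seed(99)
  diffs <- replicate(50, {
    spec <- cohort_spec(seed = sample.int(1e6, 1))
    cohort <- generate_cohort(spec, include_recordings = FALSE)
    beh <- cohort$behavior
    w <- beh[beh$condition == "white", ]
    s <- beh[beh$condition == "silent", ]
    d <- w$score - s$score[match(w$subject, s$subject)]
    mean(d[cohort$phenotypes[w$subject] == "white_benefit"])
  })
  # planted +10% benefit of white noise for the white-benefit phenotype
  expect_lt(abs(mean(diffs) - 10), 2 * stats::sd(diffs) / sqrt(50) + 0.5)
})

test_that("dead channels and motion spikes are planted as specified", {
  spec <- tiny_spec(dead_channel_rate = 0.3, artifact_rate = 5, seed = 2)
  sub <- generate_subject(spec, "unaffected", seed = 9)
  dead <- sub$ground_truth$dead_channels
  expect_gt(length(dead), 0)
  expect_true(all(sub$recordings$white$oxy[dead, ] == 0))
  spikes <- sub$ground_truth$spikes$white
  expect_gt(nrow(spikes), 0)
  live <- spikes[!(spikes$channel %in% dead), ]
  if (nrow(live) > 0) {
    i <- 1L
    expect_gt(abs(sub$recordings$white$oxy[live$channel[i], live$sample[i]]),
              0.2)
  }
})

test_that("artifact-free noise stays below the motion threshold", {
  spec <- tiny_spec(artifact_rate = 0, seed = 4)
  sub <- generate_subject(spec, "unaffected", seed = 13)
  d <- abs(t(diff(t(sub$recordings$white$oxy))))
  expect_lt(max(d), 0.1)
})
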