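test_that("passband is 1/(2T) to 0.33 Hz and rejects empty bands", {
  b <- compute_passband(11)
  expect_equal(b$f_lo, 1 / 22)
  expect_equal(b$f_hi, 0.33)
  expect_equal(compute_passband(50)$f_lo, 0.01)
  expect_error(compute_passband(1), "empty passband")
  expect_error(compute_passband(-2), "positive")
})

interior_amp <- function(x) {
  n <- length(x)
  max(abs(x[seq.int(round(0.3 * n), round(0.7 * n))]))
}

test_that("band-pass keeps mid-band, removes cardiac and DC", {
  band <- compute_passband(11)
  mid <- sqrt(band$f_lo * band$f_hi)
  t <- seq(0, 600, by = 0.1)
  oxy <- rbind(sin(2 * pi * mid * t), sin(2 * pi * 1.0 * t), 1)
  out <- bandpass_filter(toy_recording(oxy), band)
  expect_gt(interior_amp(out$oxy[1, ]), 0.95)
  expect_lt(interior_amp(out$oxy[2, ]), 0.10)
  expect_lt(interior_amp(out$oxy[3, ]), 1e-6)
  expect_true(out$filtered)
})

test_that("filtering is zero-phase and linear", {
  band <- compute_passband(11)
  fs <- 10
  t <- seq(0, 400, by = 1 / fs)
  x <- sin(2 * pi * 0.1 * t)
  y <- sin(2 * pi * 0.08 * t + 1)
  fil <- function(v) {
    r <- toy_recording(matrix(v, 1))
    bandpass_filter(r, band)$oxy[1, ]
  }
  # zero phase: peak of a mid-band sinusoid is not shifted
  fx <- fil(x)
  interior <- seq(1000, 3000)
  expect_lt(max(abs(fx[interior] - x[interior])), 0.05)
  # linearity
  expect_equal(fil(2 * x + 3 * y), 2 * fil(x) + 3 * fil(y), tolerance = 1e-8)
})

test_that("band edges above Nyquist are rejected", {
  rec <- toy_recording(matrix(rnorm(100), 1), fs = 0.6)
  expect_error(bandpass_filter(rec, compute_passband(11)), "Nyquist")
})

test_that("dead-channel detection flags consistently-zero traces", {
  oxy <- matrix(rnorm(300), 3, 100)
  oxy[2, ] <- 0
  rec <- toy_recording(oxy)
  expect_identical(detect_dead_channels(rec), c(FALSE, TRUE, FALSE))
  expect_identical(detect_dead_channels(toy_recording(matrix(1, 2, 10))),
                   c(FALSE, FALSE))
  # tolerance boundary is inclusive
  rec2 <- toy_recording(matrix(1e-12, 1, 10))
  expect_identical(detect_dead_channels(rec2, tol = 1e-12), TRUE)
  expect_error(detect_dead_channels(rec, tol = -1), ">= 0")
})

test_that("a spiked block is excluded and others are retained", {
  set.seed(1)
  design <- toy_design(task_lens = c(100, 100, 100))
  n <- 50 + 3 * 150
  oxy <- matrix(rnorm(4 * n, sd = 0.005), 4, n)
  spike_at <- design$task_blocks[2, 1] + 50L
  oxy[3, spike_at + 1L] <- oxy[3, spike_at + 1L] + 0.5
  res <- reject_motion_blocks(toy_recording(oxy), design)
  expect_identical(res$block_mask, c(TRUE, FALSE, TRUE))
  expect_true(all(res$report$block == 2))
  expect_true(all(res$report$channel == 3))
  expect_true(all(abs(res$report$sample - spike_at) <= 1))
})

test_that("the motion threshold is strict: exactly 0.1 does not reject", {
  design <- toy_design(task_lens = c(100))
  n <- 50 + 100 + 50
  # plateaus alternating between 0 and 0.1 give per-sample changes of
  # exactly the threshold value
  oxy <- matrix(rep(rep(c(0, 0.1), each = 5), length.out = n), 1, n,
                byrow = TRUE)
  res <- reject_motion_blocks(toy_recording(oxy), design)
  expect_identical(res$block_mask, TRUE)
  expect_identical(nrow(res$report), 0L)
  expect_error(reject_motion_blocks(toy_recording(oxy), design, threshold = 0),
               "> 0")
})

test_that("rejection decisions are invariant to channel order", {
  set.seed(2)
  design <- toy_design(task_lens = c(100, 100))
  n <- 50 + 2 * 150
  oxy <- matrix(rnorm(5 * n, sd = 0.005), 5, n)
  oxy[2, design$task_blocks[1, 1] + 10L] <- 1
  m1 <- reject_motion_blocks(toy_recording(oxy), design)$block_mask
  m2 <- reject_motion_blocks(toy_recording(oxy[5:1, ]), design)$block_mask
  expect_identical(m1, m2)
  expect_identical(m1, c(FALSE, TRUE))
})

test_that("Z-scoring standardizes with the population SD convention", {
  set.seed(3)
  oxy <- matrix(rnorm(3 * 200, mean = 5, sd = 3), 3, 200)
  rec <- zscore_channels(toy_recording(oxy))
  for (i in 1:3) {
    x <- rec$oxy[i, ]
    expect_lt(abs(mean(x)), 1e-10)
    expect_equal(sqrt(mean((x - mean(x))^2)), 1, tolerance = 1e-10)
  }
  # affine invariance
  r1 <- zscore_channels(toy_recording(oxy))
  r2 <- zscore_channels(toy_recording(2.5 * oxy + 7))
  expect_equal(r1$oxy, r2$oxy, tolerance = 1e-12)
  # two-sample hand computation under the 1/N convention
  r3 <- zscore_channels(toy_recording(matrix(c(0, 2), 1)))
  expect_equal(r3$oxy[1, ], c(-1, 1))
  expect_error(zscore_channels(toy_recording(matrix(1, 1, 10))),
               "channel 1")
})

test_that("baseline correction zeroes block starts and is idempotent", {
  set.seed(4)
  design <- toy_design(task_lens = c(100, 120))
  n <- 50 + 150 + 170
  oxy <- matrix(rnorm(2 * n), 2, n)
  rec <- toy_recording(oxy)
  rec$zscored <- TRUE
  out <- baseline_correct(rec, design)
  for (b in 1:2) {
    first <- design$task_blocks[b, 1] + 1L
    expect_true(all(out$oxy[, first] == 0))
  }
  # rest samples untouched
  expect_identical(out$oxy[, 1:50], oxy[, 1:50])
  # idempotence
  out2 <- baseline_correct(out, design)
  expect_identical(out2$oxy, out$oxy)
  # constant channel within a block becomes all zeros there
  idx <- (design$task_blocks[1, 1] + 1L):design$task_blocks[1, 2]
  rec$oxy[1, idx] <- 3.14
  expect_true(all(baseline_correct(rec, design)$oxy[1, idx] == 0))
  rec$zscored <- FALSE
  expect_error(baseline_correct(rec, design), "Z-scored")
})

test_that("the preprocessing chain runs in order and reports decisions", {
  spec <- tiny_spec(seed = 6)
  sub <- generate_subject(spec, "unaffected", seed = 21)
  rec <- sub$recordings$white
  design <- sub$designs$white
  # plant a dead channel and a spike
  rec$oxy[5, ] <- 0
  rec$deoxy[5, ] <- 0
  idx <- block_start <- design$task_blocks[2, 1] + 30L
  rec$oxy[9, idx] <- rec$oxy[9, idx] + 0.5
  pp <- preprocess(rec, design)
  expect_s3_class(pp$report, "preprocess_report")
  expect_identical(pp$report$dead_channels, 5L)
  expect_identical(pp$report$block_mask, c(TRUE, FALSE, TRUE))
  expect_gt(nrow(pp$report$artifacts), 0)
  expect_false(pp$recording$valid_channel_mask[5])
  expect_true(all(pp$recording$filtered, pp$recording$zscored,
                  pp$recording$baselined))
  expect_equal(pp$report$passband$f_lo, 1 / (2 * design$trial_period_s))
  # preprocess refuses non-raw input
  expect_error(preprocess(pp$recording, design), "raw")
})
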