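make_behavior <- function(d, vas_w = NULL, vas_s = NULL) {
  n <- length(d)
  ids <- sprintf("s%02d", seq_len(n))
  if (is.null(vas_w)) vas_w <- rep(5, n)
  if (is.null(vas_s)) vas_s <- rep(5, n)
  rbind(data.frame(subject = ids, condition = "white", score = 80 + d,
                   vas = vas_w),
        data.frame(subject = ids, condition = "silent", score = rep(80, n),
                   vas = vas_s))
}

test_that("half-SD split labels follow the sign pattern of differences", {
  d <- c(10, 10, 0, 0, 0, -10, -10)
  ga <- split_groups(make_behavior(d))
  thr <- stats::sd(d) / 2
  expect_equal(attr(ga, "threshold"), thr)
  # brute-force label assignment oracle
  oracle <- ifelse(d > thr, "White", ifelse(d < -thr, "Silence", "Average"))
  expect_identical(ga$label, oracle)
  expect_identical(ga$label[1:2], c("White", "White"))
  expect_identical(ga$label[6:7], c("Silence", "Silence"))
})

test_that("a difference exactly at +threshold is Average", {
  # sum(d) = 0 and sum(d^2) = 16 over 5 subjects: sd = 2 exactly, so the
  # threshold is exactly 1 and subjects with |d| = 1 sit on the boundary
  d <- c(1, 3, -1, -2, -1)
  expect_identical(stats::sd(d), 2)
  ga <- split_groups(make_behavior(d))
  expect_equal(attr(ga, "threshold"), 1)
  expect_identical(ga$label, c("Average", "White", "Average", "Silence",
                               "Average"))
})

test_that("degenerate cohorts are rejected", {
  expect_error(split_groups(make_behavior(rep(5, 4))), "threshold is undefined")
  expect_error(split_groups(make_behavior(3)), "at least 2")
})

test_that("the split is order-invariant and scales with the differences", {
  set.seed(21)
  d <- rnorm(12, sd = 2)
  beh <- make_behavior(d)
  perm <- sample(nrow(beh))
  ga1 <- split_groups(beh)
  ga2 <- split_groups(beh[perm, ])
  expect_identical(ga1$label[match(ga2$subject, ga1$subject)], ga2$label)
  ga3 <- split_groups(make_behavior(3 * d))
  expect_equal(attr(ga3, "threshold"), 3 * attr(ga1, "threshold"))
  expect_identical(ga3$label, ga1$label)
})

test_that("paired tests report df = n - 1 and match the hand formula", {
  set.seed(22)
  w <- rnorm(29); s <- rnorm(29)
  tt <- paired_condition_test(w, s)
  expect_identical(tt$df, 28)
  d <- w - s
  expect_equal(tt$statistic, mean(d) / (stats::sd(d) / sqrt(29)),
               tolerance = 1e-12)
  expect_identical(paired_condition_test(rnorm(8), rnorm(8))$df, 7)
  expect_error(paired_condition_test(w, s[-1]), "matched")
  expect_error(paired_condition_test(1, 2), "at least 2")
  expect_error(paired_condition_test(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_condition_test(c(1, NA), c(1, 2)), "complete pairs")
})

test_that("channel-wise tables flag significance and attach q-values", {
  set.seed(23)
  n <- 12; nch <- 6
  w <- matrix(rnorm(n * nch), n, nch)
  s <- matrix(rnorm(n * nch), n, nch)
  w[, 3] <- w[, 3] + 5  # one strongly affected channel
  s[, 5] <- NA  # masked channel
  res <- channelwise_paired_tests(w, s)
  expect_identical(nrow(res), 6L)
  expect_true(res$significant[3])
  expect_true(is.na(res$p.value[5]))
  ok <- !is.na(res$p.value)
  expect_true(all(res$q.value[ok] >= res$p.value[ok]))
  expect_true(res$significant_fdr[3])
})

test_that("Tukey comparisons detect separated groups and not identical ones", {
  labels <- rep(c("White", "Average", "Silence"), each = 8)
  same <- rep(1, 24)
  res <- between_group_comparison(same, labels)
  expect_identical(nrow(res), 3L)
  expect_false(any(res$significant))

  set.seed(24)
  vals <- rnorm(24, sd = 1)
  vals[labels == "White"] <- vals[labels == "White"] + 10
  res2 <- between_group_comparison(vals, labels)
  sig <- res2$significant[grepl("White", res2$comparison)]
  expect_true(all(sig))
  expect_false(res2$significant[res2$comparison == "Silence-Average"])

  # permutation cross-check of the separated pair
  grp <- vals[labels != "Average"]
  lab <- labels[labels != "Average"]
  obs <- abs(diff(tapply(grp, lab, mean)))
  perm <- replicate(500, {
    sh <- sample(lab)
    abs(diff(tapply(grp, sh, mean)))
  })
  expect_lt(mean(perm >= obs), 0.05)

  expect_error(between_group_comparison(vals, rep("A", 24)), "at least 2 groups")
  expect_error(between_group_comparison(vals[1:9],
                                        c(rep("A", 8), "B")), ">= 2 subjects")
})

test_that("Tukey results are invariant to group ordering", {
  set.seed(25)
  vals <- rnorm(18)
  labels <- rep(c("a", "b", "c"), each = 6)
  r1 <- between_group_comparison(vals, labels)
  perm <- sample(18)
  r2 <- between_group_comparison(vals[perm], labels[perm])
  expect_equal(r1[order(r1$comparison), ], r2[order(r2$comparison), ],
               ignore_attr = TRUE)
})

test_that("BH correction reproduces hand-computed q-values", {
  expect_equal(fdr_correct(rep(0.01, 70)), rep(0.01, 70))
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.2), 0.2)
  p <- c(0.001, 0.01, 0.04, 0.8)
  q <- fdr_correct(p)
  expect_true(all(q >= p) && !is.unsorted(q))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_correct(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("null cohorts yield calibrated channel-wise type-I error", {
  set.seed(26)
  fracs <- replicate(60, {
    n <- 10; nch <- 40
    w <- matrix(rnorm(n * nch), n, nch)
    s <- matrix(rnorm(n * nch), n, nch)
    mean(channelwise_paired_tests(w, s, fdr = FALSE)$significant)
  })
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.05), 3 * se + 0.01)
})
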