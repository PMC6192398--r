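#' Split subjects into White / Average / Silence groups
#'
#' For every subject the task-performance difference
#' `d = score(white) - score(silent)` (percentage points) is computed.
#' The split threshold is half the cohort standard deviation of `d`
#' (sample, n-1 convention).  Subjects with `d` strictly above the
#' threshold form the White group (performance benefits from white
#' noise), those with `|d|` within the threshold (inclusive) the Average
#' group, and those strictly below `-threshold` the Silence group.
#'
#' @param behavior behavioural table (see [write_behavior()]) with both
#'   conditions scored for every subject.
#' @return Object of class `group_assignment`: data frame with columns
#'   `subject`, `d`, `label`, plus attribute `threshold`.
#' @export
split_groups <- function(behavior) {
  validate_behavior(behavior)
  w <- behavior[behavior$condition == "white", ]
  s <- behavior[behavior$condition == "silent", ]
  s <- s[match(w$subject, s$subject), ]
  if (nrow(w) < 2) stop("at least 2 subjects are required")
  d <- w$score - s$score
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("all performance differences are equal: the split threshold is undefined")
  threshold <- sd_d / 2
  label <- ifelse(d > threshold, "White",
                  ifelse(d < -threshold, "Silence", "Average"))
  out <- data.frame(subject = w$subject, d = d, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("White", "Average", "Silence")))
  cat(sprintf("<group_assignment> threshold = %.3f; White %d, Average %d, Silence %d\n",
              attr(x, "threshold"), tab["White"], tab["Average"], tab["Silence"]))
  invisible(x)
}

#' Paired comparison of two conditions
#'
#' Two-sided paired t test (df = n - 1) on matched per-subject
#' measurements; used for VAS ratings, per-channel accumulated CBF
#' change and per-channel connection strength.
#'
#' @param white,silent numeric vectors of per-subject measurements in
#'   matching subject order.
#' @param alpha significance level.
#' @return List with `statistic`, `df`, `p.value`, `significant`,
#'   `mean_diff` (white minus silent) and `n`.
#' @export
paired_condition_test <- function(white, silent, alpha = 0.05) {
  if (length(white) != length(silent))
    stop("'white' and 'silent' must be matched per-subject vectors")
  if (anyNA(white) || anyNA(silent))
    stop("paired test requires complete pairs (no missing values)")
  n <- length(white)
  if (n < 2) stop("at least 2 pairs are required")
  d <- white - silent
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: degenerate test")
  tt <- stats::t.test(white, silent, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, significant = tt$p.value < alpha,
       mean_diff = unname(tt$estimate), n = n)
}

#' Channel-wise paired condition tests
#'
#' Applies [paired_condition_test()] to every channel of a pair of
#' subjects x channels measurement matrices; channels with any missing
#' value (masked channels) yield `NA` rows.
#'
#' @param white,silent numeric matrices, subjects x channels, matching
#'   row (subject) and column (channel) order.
#' @param alpha significance level.
#' @param fdr if `TRUE`, append Benjamini-Hochberg adjusted q-values
#'   (computed over the testable channels).
#' @return Data frame (one row per channel) with `channel`, `statistic`,
#'   `df`, `p.value`, `significant`, and optionally `q.value`,
#'   `significant_fdr`.
#' @export
channelwise_paired_tests <- function(white, silent, alpha = 0.05, fdr = TRUE) {
  if (!identical(dim(white), dim(silent)))
    stop("'white' and 'silent' must have identical dimensions")
  chs <- colnames(white)
  if (is.null(chs)) chs <- as.character(seq_len(ncol(white)))
  res <- lapply(seq_len(ncol(white)), function(j) {
    w <- white[, j]; s <- silent[, j]
    if (anyNA(w) || anyNA(s) || stats::sd(w - s) == 0)
      return(data.frame(channel = chs[j], statistic = NA_real_, df = NA_real_,
                        p.value = NA_real_, significant = NA))
    tt <- paired_condition_test(w, s, alpha = alpha)
    data.frame(channel = chs[j], statistic = tt$statistic, df = tt$df,
               p.value = tt$p.value, significant = tt$significant)
  })
  out <- do.call(rbind, res)
  if (fdr) {
    ok <- !is.na(out$p.value)
    out$q.value <- NA_real_
    out$q.value[ok] <- fdr_correct(out$p.value[ok])
    out$significant_fdr <- out$q.value < alpha
  }
  out
}

#' Between-group multiple comparisons (Tukey HSD)
#'
#' Pairwise comparisons of a per-subject scalar measure across the
#' behavioural groups, using Tukey's honestly-significant-difference
#' test (studentized range) on a one-way ANOVA fit.
#'
#' @param measure numeric per-subject values.
#' @param labels group label per subject (2 or more groups, each with
#'   at least 2 subjects).
#' @param alpha significance level.
#' @return Data frame with one row per group pair: `comparison`, `diff`,
#'   `lwr`, `upr`, `p.adj`, `significant`.
#' @export
between_group_comparison <- function(measure, labels, alpha = 0.05) {
  if (length(measure) != length(labels))
    stop("'measure' and 'labels' must have equal length")
  labels <- factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("at least 2 groups are required")
  if (any(sizes < 2))
    stop(sprintf("every group needs >= 2 subjects (found: %s)",
                 paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  fit <- stats::aov(measure ~ labels, data = data.frame(measure, labels))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$labels
  p <- tk[, "p adj"]
  # zero residual variance (e.g. all values identical) yields NaN
  # p-values; such comparisons are never declared significant
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p.adj = p,
             significant = !is.na(p) & p < alpha, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param pvals numeric p-values in [0, 1].
#' @return Adjusted q-values (monotone, each >= its raw p-value).
#' @export
fdr_correct <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvals, method = "BH")
}
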