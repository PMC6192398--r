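#' Construct a multi-channel fNIRS recording
#'
#' Container for one subject-condition recording of oxy- and
#' deoxy-hemoglobin concentration change.  Concentrations are carried in
#' mM·mm (molar concentration times optical path length), the native unit
#' of continuous-wave fNIRS exports and of the motion-artifact threshold
#' used downstream.
#'
#' @param oxy numeric matrix, channels x samples, oxy-Hb change in mM·mm.
#' @param deoxy numeric matrix, same shape, deoxy-Hb change in mM·mm.
#' @param fs sampling rate in Hz (the reference acquisition uses 10 Hz).
#' @param subject_id character scalar.
#' @param condition `"white"` or `"silent"` auditory environment.
#' @param channels integer channel ids; defaults to `1:nrow(oxy)`.
#' @param valid_channel_mask logical per channel; `FALSE` marks channels
#'   excluded from analysis (e.g. dead optodes).  Defaults to all `TRUE`.
#' @param valid_block_mask logical per task block, or `NULL` when no
#'   design has been applied yet.
#'
#' @return An object of class `fnirs_recording`: a list with the fields
#'   above plus bookkeeping flags (`filtered`, `zscored`, `baselined`)
#'   recording which preprocessing stages have been applied.
#' @export
fnirs_recording <- function(oxy, deoxy, fs, subject_id = "s01",
                            condition = c("white", "silent"),
                            channels = seq_len(nrow(oxy)),
                            valid_channel_mask = NULL,
                            valid_block_mask = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(oxy) || !is.numeric(oxy))
    stop("'oxy' must be a numeric channels x samples matrix")
  if (!is.matrix(deoxy) || !is.numeric(deoxy))
    stop("'deoxy' must be a numeric channels x samples matrix")
  if (!identical(dim(oxy), dim(deoxy)))
    stop("'oxy' and 'deoxy' must have identical dimensions")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive sampling rate in Hz")
  channels <- as.integer(channels)
  if (length(channels) != nrow(oxy))
    stop("length of 'channels' must equal the number of rows of 'oxy'")
  if (anyDuplicated(channels))
    stop("channel ids must be unique")
  if (is.null(valid_channel_mask)) valid_channel_mask <- rep(TRUE, nrow(oxy))
  if (length(valid_channel_mask) != nrow(oxy) || !is.logical(valid_channel_mask))
    stop("'valid_channel_mask' must be logical with one entry per channel")
  rec <- structure(list(
    subject_id = as.character(subject_id),
    condition = condition,
    fs = as.numeric(fs),
    channels = channels,
    oxy = oxy,
    deoxy = deoxy,
    valid_channel_mask = valid_channel_mask,
    valid_block_mask = valid_block_mask,
    filtered = FALSE,
    zscored = FALSE,
    baselined = FALSE
  ), class = "fnirs_recording")
  rec
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("<fnirs_recording> subject %s, %s condition\n",
              x$subject_id, x$condition))
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$oxy), ncol(x$oxy), x$fs, ncol(x$oxy) / x$fs))
  cat(sprintf("  valid channels: %d/%d; stages: filtered=%s zscored=%s baselined=%s\n",
              sum(x$valid_channel_mask), length(x$valid_channel_mask),
              x$filtered, x$zscored, x$baselined))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$oxy)

#' Construct a block design
#'
#' Timing of a block-design session: alternating rest and task blocks,
#' each task block made of memorize / retain / answer trials.  All
#' intervals are 0-based, half-open `[start, end)` in sample coordinates,
#' so `end - start` is the number of samples in the interval.
#'
#' @param rest_blocks integer matrix, n x 2, columns start/end.
#' @param task_blocks integer matrix, n x 2, columns start/end.
#' @param trials list with one element per task block; each element is a
#'   matrix with columns `memorize_start`, `memorize_end`, `retain_start`,
#'   `retain_end`, `answer_start`, `answer_end` and one row per trial.
#' @param trial_period_s nominal trial period T in seconds (used to derive
#'   the subject-specific filter passband).
#' @param fs sampling rate in Hz the sample coordinates refer to.
#'
#' @return Object of class `block_design`.
#' @export
block_design <- function(rest_blocks, task_blocks, trials, trial_period_s, fs) {
  rest_blocks <- matrix(as.integer(rest_blocks), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  task_blocks <- matrix(as.integer(task_blocks), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  all_iv <- rbind(rest_blocks, task_blocks)
  if (any(all_iv[, 2] <= all_iv[, 1]))
    stop("all intervals must satisfy start < end")
  ord <- order(all_iv[, 1])
  s <- all_iv[ord, , drop = FALSE]
  if (nrow(s) > 1 && any(s[-1, 1] < s[-nrow(s), 2]))
    stop("rest and task blocks must be non-overlapping")
  if (length(trials) != nrow(task_blocks))
    stop("'trials' must have one element per task block")
  structure(list(rest_blocks = rest_blocks, task_blocks = task_blocks,
                 trials = trials, trial_period_s = as.numeric(trial_period_s),
                 fs = as.numeric(fs)),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %d rest + %d task blocks at %g Hz, T = %.2f s\n",
              nrow(x$rest_blocks), nrow(x$task_blocks), x$fs, x$trial_period_s))
  invisible(x)
}

n_task_blocks <- function(design) nrow(design$task_blocks)

# indices (1-based, for R matrix columns) of the samples of task block b
block_sample_idx <- function(design, b) {
  iv <- design$task_blocks[b, ]
  seq.int(iv[1] + 1L, iv[2])
}

check_design_fits <- function(rec, design) {
  if (max(design$task_blocks[, 2], design$rest_blocks[, 2]) > n_samples(rec))
    stop("block design extends beyond the end of the recording")
  if (!isTRUE(all.equal(rec$fs, design$fs)))
    stop("recording and design disagree on the sampling rate")
  invisible(TRUE)
}
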