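#' Subject-specific filter passband
#'
#' The band-pass lower edge is the inverse of twice the trial period T,
#' i.e. `f_lo = 1 / (2 T)`; the upper edge is fixed at 0.33 Hz, below
#' respiratory and cardiac frequencies.  Because answer durations vary,
#' T is taken as the subject-condition mean realized trial duration (see
#' [block_design()]).
#'
#' @param trial_period_s trial period T in seconds; must exceed
#'   `1 / (2 * 0.33)` s so the band is non-empty.
#' @param f_hi upper band edge in Hz.
#' @return Object of class `passband` with fields `f_lo`, `f_hi`.
#' @export
compute_passband <- function(trial_period_s, f_hi = 0.33) {
  if (!is.numeric(trial_period_s) || length(trial_period_s) != 1L ||
      trial_period_s <= 0)
    stop("'trial_period_s' must be a positive scalar in seconds")
  f_lo <- 1 / (2 * trial_period_s)
  if (f_lo >= f_hi)
    stop(sprintf(
      "empty passband: f_lo = 1/(2*%g) = %.4g Hz is not below f_hi = %g Hz",
      trial_period_s, f_lo, f_hi))
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "passband")
}

#' Zero-phase band-pass filtering
#'
#' Applies an order-4 Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the output has no phase lag relative to the
#' input.  Both hemoglobin matrices are filtered identically, channel by
#' channel.
#'
#' @param rec an [fnirs_recording].
#' @param band a `passband` from [compute_passband()].
#' @param order overall IIR filter order (must be even; each of the two
#'   passes applies an order-`order` band-pass).
#' @return The filtered recording with `filtered = TRUE` and the band
#'   recorded in `rec$passband`.
#' @export
bandpass_filter <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(band, "passband"))
  nyq <- rec$fs / 2
  if (band$f_hi >= nyq)
    stop(sprintf("upper band edge %g Hz violates the Nyquist limit %g Hz",
                 band$f_hi, nyq))
  if (order < 2 || order %% 2 != 0)
    stop("'order' must be a positive even integer")
  bf <- signal::butter(order / 2, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  filt_rows <- function(m) {
    out <- m
    for (i in seq_len(nrow(m)))
      out[i, ] <- signal::filtfilt(bf, m[i, ])
    out
  }
  rec$oxy <- filt_rows(rec$oxy)
  rec$deoxy <- filt_rows(rec$deoxy)
  rec$filtered <- TRUE
  rec$passband <- band
  rec
}

#' Detect dead (non-detecting) channels
#'
#' A channel is dead when its raw oxy-Hb trace is consistently zero over
#' the whole measurement: `max |oxy| <= tol` (inclusive).  Dead channels
#' are excluded from all downstream statistics but retained in matrices
#' as missing.
#'
#' @param rec a raw (unfiltered) [fnirs_recording].
#' @param tol non-negative tolerance in mM·mm; the default 0 flags exact
#'   zeros, a small tolerance accommodates float-rounded inputs.
#' @return Logical vector, `TRUE` for dead channels.
#' @export
detect_dead_channels <- function(rec, tol = 0) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (tol < 0) stop("'tol' must be >= 0")
  apply(abs(rec$oxy), 1L, max) <= tol
}

#' Motion-artifact rejection of task blocks
#'
#' An oxy-Hb change between consecutive samples whose magnitude strictly
#' exceeds `threshold` (default 0.1 mM·mm per sample) is treated as a
#' motion artifact, and any task block containing one is excluded for
#' this subject-condition across all channels.  Detection should run on
#' the unfiltered concentration trace: the analysis band-pass attenuates
#' a single-sample spike far below the threshold, which would make the
#' rule vacuous.
#'
#' @param rec an [fnirs_recording] (raw trace recommended, see above).
#' @param design the matching [block_design].
#' @param threshold rejection threshold, mM·mm per sample; must be > 0.
#' @param per_second if `TRUE`, interpret `threshold` per second instead
#'   of per sample (it is scaled by `1/fs` before comparison).
#' @return List with `block_mask` (logical, `TRUE` = retained) and
#'   `report`: a data frame of offending `(block, channel, sample)`
#'   triples with the observed per-sample change.
#' @export
reject_motion_blocks <- function(rec, design, threshold = 0.1,
                                 per_second = FALSE) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(design, "block_design"))
  if (threshold <= 0) stop("'threshold' must be > 0")
  check_design_fits(rec, design)
  thr <- if (per_second) threshold / rec$fs else threshold
  nb <- n_task_blocks(design)
  block_mask <- rep(TRUE, nb)
  offenders <- list()
  for (b in seq_len(nb)) {
    idx <- block_sample_idx(design, b)
    d <- abs(rec$oxy[, idx[-1], drop = FALSE] -
               rec$oxy[, idx[-length(idx)], drop = FALSE])
    hit <- which(d > thr, arr.ind = TRUE)
    if (nrow(hit)) {
      block_mask[b] <- FALSE
      offenders[[length(offenders) + 1L]] <- data.frame(
        block = b, channel = rec$channels[hit[, 1]],
        sample = idx[hit[, 2]] - 1L,  # 0-based index of the pair's first sample
        delta = d[hit])
    }
  }
  report <- if (length(offenders)) do.call(rbind, offenders)
  else data.frame(block = integer(0), channel = integer(0),
                  sample = integer(0), delta = numeric(0))
  list(block_mask = block_mask, report = report)
}

#' Per-channel Z-scoring
#'
#' Standardizes every retained channel over the entire recording (rest
#' and task samples) to mean 0 and standard deviation 1, using the
#' population (1/N) SD convention.  fNIRS concentration changes are
#' relative values whose scale varies with optical path length, so
#' between-subject comparison requires this normalization.
#'
#' @param rec an [fnirs_recording].
#' @return The standardized recording (`zscored = TRUE`); masked-out
#'   channels are left untouched.
#' @export
zscore_channels <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  n <- n_samples(rec)
  for (i in seq_len(nrow(rec$oxy))) {
    if (!rec$valid_channel_mask[i]) next
    x <- rec$oxy[i, ]
    s <- sqrt(sum((x - mean(x))^2) / n)
    if (s == 0)
      stop(sprintf("channel %d has zero variance and cannot be Z-scored",
                   rec$channels[i]))
    rec$oxy[i, ] <- (x - mean(x)) / s
    y <- rec$deoxy[i, ]
    sy <- sqrt(sum((y - mean(y))^2) / n)
    if (sy > 0) rec$deoxy[i, ] <- (y - mean(y)) / sy
  }
  rec$zscored <- TRUE
  rec
}

#' Task-block baseline correction
#'
#' Within each task block the value at the first sample of the block is
#' subtracted from every sample of that block, per channel, so each
#' corrected block starts at exactly zero.  Rest samples are untouched.
#' Applying the correction twice is a no-op.
#'
#' @param rec a Z-scored [fnirs_recording].
#' @param design the matching [block_design].
#' @return The corrected recording (`baselined = TRUE`).
#' @export
baseline_correct <- function(rec, design) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(design, "block_design"))
  if (!rec$zscored)
    stop("baseline correction expects a Z-scored recording")
  check_design_fits(rec, design)
  for (b in seq_len(n_task_blocks(design))) {
    idx <- block_sample_idx(design, b)
    if (!length(idx)) stop(sprintf("task block %d is empty", b))
    rec$oxy[, idx] <- rec$oxy[, idx] - rec$oxy[, idx[1]]
    rec$deoxy[, idx] <- rec$deoxy[, idx] - rec$deoxy[, idx[1]]
  }
  rec$baselined <- TRUE
  rec
}

#' Full preprocessing chain for one subject-condition recording
#'
#' Runs the standard chain: dead-channel detection and motion-artifact
#' block rejection on the raw concentration trace, then zero-phase
#' band-pass filtering (passband from the design's trial period),
#' per-channel Z-scoring and task-block baseline correction.  Exclusion
#' masks are computed from the raw trace because both exclusion rules
#' are stated in raw concentration units; they take effect in all
#' downstream statistics.
#'
#' @param rec a raw [fnirs_recording].
#' @param design the matching [block_design].
#' @param motion_threshold rejection threshold in mM·mm per sample.
#' @param dead_tol dead-channel tolerance in mM·mm.
#' @param filter_order overall band-pass order.
#' @param f_hi upper band edge in Hz.
#' @return List with `recording` (preprocessed, masks set) and `report`
#'   (class `preprocess_report`: passband, dead channels, per-block
#'   artifact decisions with offending samples, samples retained).
#' @export
preprocess <- function(rec, design, motion_threshold = 0.1, dead_tol = 0,
                       filter_order = 4, f_hi = 0.33) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (rec$filtered || rec$zscored || rec$baselined)
    stop("'preprocess' expects a raw recording")
  check_design_fits(rec, design)
  dead <- detect_dead_channels(rec, tol = dead_tol)
  rec$valid_channel_mask <- rec$valid_channel_mask & !dead
  motion <- reject_motion_blocks(rec, design, threshold = motion_threshold)
  rec$valid_block_mask <- motion$block_mask
  band <- compute_passband(design$trial_period_s, f_hi = f_hi)
  rec <- bandpass_filter(rec, band, order = filter_order)
  rec <- zscore_channels(rec)
  rec <- baseline_correct(rec, design)
  retained_samples <- sum(vapply(which(motion$block_mask), function(b)
    length(block_sample_idx(design, b)), integer(1)))
  report <- structure(list(
    passband = band, filter_order = filter_order,
    motion_threshold = motion_threshold, dead_tol = dead_tol,
    dead_channels = rec$channels[dead],
    block_mask = motion$block_mask, artifacts = motion$report,
    task_samples_retained = retained_samples), class = "preprocess_report")
  list(recording = rec, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> band (%.4g, %.4g) Hz, order %d\n",
              x$passband$f_lo, x$passband$f_hi, x$filter_order))
  cat(sprintf("  dead channels: %s\n",
              if (length(x$dead_channels)) paste(x$dead_channels, collapse = ", ")
              else "none"))
  cat(sprintf("  task blocks retained: %d/%d (%d artifact samples flagged)\n",
              sum(x$block_mask), length(x$block_mask), nrow(x$artifacts)))
  invisible(x)
}
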