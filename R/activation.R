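#' Accumulated CBF change per channel
#'
#' The activation measure: for each retained task block, the sum of the
#' preprocessed (filtered, Z-scored, baseline-corrected) oxy-Hb samples
#' over the block divided by the number of samples in the block — a
#' duration-normalized accumulated change, so sessions of different
#' length are comparable — then averaged over the retained blocks.
#'
#' @param rec a preprocessed [fnirs_recording].
#' @param design the matching [block_design].
#' @param block_mask logical per task block, `TRUE` = retained; defaults
#'   to the recording's `valid_block_mask` (all blocks if unset).
#' @return Object of class `activation_vector`: `values` (named by
#'   channel id, `NA` for masked channels), `n_blocks_used`, `channels`,
#'   `condition`.
#' @export
accumulated_change <- function(rec, design, block_mask = NULL) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(design, "block_design"))
  if (!(rec$filtered && rec$zscored && rec$baselined))
    stop("activation requires a filtered, Z-scored, baseline-corrected recording")
  check_design_fits(rec, design)
  if (is.null(block_mask)) block_mask <- rec$valid_block_mask
  if (is.null(block_mask)) block_mask <- rep(TRUE, n_task_blocks(design))
  if (length(block_mask) != n_task_blocks(design))
    stop("'block_mask' must have one entry per task block")
  retained <- which(block_mask)
  if (!length(retained))
    stop(sprintf("all task blocks rejected for subject %s (%s): no activation measure",
                 rec$subject_id, rec$condition))
  per_block <- vapply(retained, function(b) {
    idx <- block_sample_idx(design, b)
    rowSums(rec$oxy[, idx, drop = FALSE]) / length(idx)
  }, numeric(nrow(rec$oxy)))
  values <- rowMeans(matrix(per_block, nrow = nrow(rec$oxy)))
  values[!rec$valid_channel_mask] <- NA_real_
  names(values) <- rec$channels
  structure(list(values = values, n_blocks_used = length(retained),
                 channels = rec$channels, condition = rec$condition),
            class = "activation_vector")
}

#' Between-condition activation contrast
#'
#' Channel-wise difference of accumulated CBF change, white noise minus
#' silent; a channel is missing in the contrast if it is missing on
#' either side.
#'
#' @param white,silent `activation_vector`s over the same channel set.
#' @return Named numeric vector of per-channel differences.
#' @export
activation_contrast <- function(white, silent) {
  stopifnot(inherits(white, "activation_vector"),
            inherits(silent, "activation_vector"))
  if (!identical(white$channels, silent$channels))
    stop("activation vectors cover different channel sets")
  white$values - silent$values
}
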