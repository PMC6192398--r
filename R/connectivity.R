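#' Concatenated task time course
#'
#' Extracts the retained task-block segments of the preprocessed oxy-Hb
#' signal and concatenates them in temporal order, per channel.  This is
#' the time course the connectivity analysis correlates.
#'
#' @param rec a preprocessed [fnirs_recording].
#' @param design the matching [block_design].
#' @param block_mask logical per task block; defaults to the recording's
#'   `valid_block_mask` (all blocks if unset).
#' @return Numeric matrix, channels x (retained task samples).
#' @export
task_timecourse <- function(rec, design, block_mask = NULL) {
  stopifnot(inherits(rec, "fnirs_recording"), inherits(design, "block_design"))
  check_design_fits(rec, design)
  if (is.null(block_mask)) block_mask <- rec$valid_block_mask
  if (is.null(block_mask)) block_mask <- rep(TRUE, n_task_blocks(design))
  retained <- which(block_mask)
  if (!length(retained))
    stop(sprintf("no retained task blocks for subject %s (%s)",
                 rec$subject_id, rec$condition))
  idx <- unlist(lapply(retained, function(b) block_sample_idx(design, b)))
  tc <- rec$oxy[, idx, drop = FALSE]
  rownames(tc) <- rec$channels
  tc
}

#' Channel-by-channel Pearson correlation matrix
#'
#' @param tc channels x samples matrix (rows named by channel id).
#' @param valid logical per channel; masked channels yield `NA` rows and
#'   columns.  Defaults to all valid.
#' @return Symmetric correlation matrix with unit diagonal on valid
#'   channels.
#' @export
correlation_matrix <- function(tc, valid = rep(TRUE, nrow(tc))) {
  if (!is.matrix(tc)) stop("'tc' must be a channels x samples matrix")
  if (ncol(tc) < 3) stop("at least 3 samples are needed for a correlation")
  v <- which(valid)
  sds <- apply(tc[v, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance retained channel(s): %s",
                 paste(rownames(tc)[v[sds == 0]], collapse = ", ")))
  n <- nrow(tc)
  r <- matrix(NA_real_, n, n, dimnames = list(rownames(tc), rownames(tc)))
  r[v, v] <- stats::cor(t(tc[v, , drop = FALSE]))
  r[v, v][] <- (r[v, v] + t(r[v, v])) / 2  # enforce exact symmetry
  diag(r)[valid] <- 1
  r
}

#' Fisher z-transformation
#'
#' Elementwise `atanh` of the off-diagonal correlations, mapping them to
#' an approximately normal scale; the diagonal (self-correlation) is
#' masked to `NA` since `atanh(1)` is infinite and carries no
#' information.
#'
#' @param r correlation matrix.
#' @param clip if `TRUE`, off-diagonal values are clipped to
#'   +/-(1 - 1e-12) before transforming, absorbing numerically degenerate
#'   duplicates; with the default `FALSE`, `|r| >= 1` off-diagonal is an
#'   error.
#' @return z matrix, same dimnames, diagonal `NA`.
#' @export
fisher_transform <- function(r, clip = FALSE) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop("'r' must be a square correlation matrix")
  z <- r
  diag(z) <- NA_real_
  off <- z[!is.na(z)]
  if (clip) {
    z[!is.na(z)] <- pmin(pmax(off, -(1 - 1e-12)), 1 - 1e-12)
  } else if (any(abs(off) >= 1)) {
    stop("off-diagonal |r| >= 1: perfectly (anti)correlated channel pair; ",
         "use clip = TRUE only for numerically degenerate duplicates")
  }
  z[!is.na(z)] <- atanh(z[!is.na(z)])
  z
}

#' Node strength of a Fisher-z connectivity graph
#'
#' The z matrix is read as the weighted adjacency matrix of an
#' undirected graph over channels; the strength of a node is the signed
#' sum of the weights of its incident edges (masked channels are
#' excluded from both index sets, the diagonal is never counted).
#'
#' @param z symmetric Fisher-z matrix with `NA` diagonal; rows/columns
#'   that are entirely `NA` are treated as masked channels.
#' @param absolute if `TRUE`, sum `|z|` instead of signed weights
#'   (off by default: negative correlations subtract).
#' @return Named numeric vector of strengths, `NA` for masked channels.
#' @export
node_strength <- function(z, absolute = FALSE) {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop("'z' must be a square matrix")
  n <- nrow(z)
  valid <- vapply(seq_len(n), function(i) any(!is.na(z[i, -i])), logical(1))
  zz <- z
  zz[is.na(zz)] <- 0
  if (max(abs(zz - t(zz))) > 1e-8)
    stop("'z' must be symmetric")
  # accumulate in ascending channel order in double precision, so the
  # result is bit-reproducible against a reference edge-by-edge sum
  s <- rep(NA_real_, n)
  for (i in which(valid)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i || !valid[j]) next
      v <- z[i, j]
      if (!is.na(v)) acc <- acc + (if (absolute) abs(v) else v)
    }
    s[i] <- acc
  }
  names(s) <- rownames(z)
  s
}

#' Build a functional-connectivity graph for one recording
#'
#' Convenience wrapper running [task_timecourse()],
#' [correlation_matrix()], [fisher_transform()] and [node_strength()].
#'
#' @param rec a preprocessed [fnirs_recording].
#' @param design the matching [block_design].
#' @param block_mask optional task-block mask (see [task_timecourse()]).
#' @param clip passed to [fisher_transform()].
#' @return Object of class `connectivity_graph`: `channels`, `r`, `z`,
#'   `strength`, `condition`.
#' @export
connectivity_graph <- function(rec, design, block_mask = NULL, clip = FALSE) {
  tc <- task_timecourse(rec, design, block_mask)
  r <- correlation_matrix(tc, valid = rec$valid_channel_mask)
  z <- fisher_transform(r, clip = clip)
  structure(list(channels = rec$channels, r = r, z = z,
                 strength = node_strength(z), condition = rec$condition),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d channels, %s condition\n",
              length(x$channels), x$condition))
  cat(sprintf("  mean off-diagonal z: %.3f; strength range [%.2f, %.2f]\n",
              mean(x$z, na.rm = TRUE), min(x$strength, na.rm = TRUE),
              max(x$strength, na.rm = TRUE)))
  invisible(x)
}

#' Export a connectivity graph as an edge list
#'
#' @param graph a `connectivity_graph`.
#' @return Data frame with columns `channel_i`, `channel_j`, `r`, `z`
#'   for every unordered pair of valid channels.
#' @export
edge_list <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  n <- length(graph$channels)
  pairs <- which(upper.tri(graph$z) & !is.na(graph$z), arr.ind = TRUE)
  data.frame(channel_i = graph$channels[pairs[, 1]],
             channel_j = graph$channels[pairs[, 2]],
             r = graph$r[pairs], z = graph$z[pairs])
}
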