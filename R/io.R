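#' Read and write fNIRS data in the package's tabular interchange format
#'
#' A recording is stored as a pair of TSV matrices (`<stem>.oxy.tsv`,
#' `<stem>.deoxy.tsv`; samples as rows, one column per channel, header row
#' of channel ids) plus a YAML sidecar (`<stem>.yaml`) carrying the
#' sampling rate, subject/condition metadata and validity masks.  Numbers
#' are written with 17 significant digits so that write/read round trips
#' are lossless at double precision.
#'
#' @param rec an [fnirs_recording].
#' @param stem path stem; the three component files are derived from it.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns an [fnirs_recording].
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "fnirs_recording"))
  write_hb_matrix(rec$oxy, rec$channels, paste0(stem, ".oxy.tsv"))
  write_hb_matrix(rec$deoxy, rec$channels, paste0(stem, ".deoxy.tsv"))
  meta <- list(subject_id = rec$subject_id, condition = rec$condition,
               fs = rec$fs, channels = rec$channels, unit = "mMmm",
               valid_channel_mask = rec$valid_channel_mask,
               valid_block_mask = rec$valid_block_mask,
               filtered = rec$filtered, zscored = rec$zscored,
               baselined = rec$baselined)
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

write_hb_matrix <- function(m, channels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(channels, collapse = "\t"), con)
  # samples as rows: transpose so each line is one time point
  lines <- apply(t(m), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, con)
}

read_hb_matrix <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("recording component '%s' is missing (file %s not found)",
                 what, path))
  lines <- readLines(path)
  channels <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  vals <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nl <- lengths(vals)
  if (any(nl != length(channels)))
    stop(sprintf("inconsistent row lengths in '%s': expected %d values, found %d at data row %d",
                 what, length(channels), nl[which(nl != length(channels))[1L]],
                 which(nl != length(channels))[1L]))
  m <- matrix(as.numeric(unlist(vals, use.names = FALSE)),
              nrow = length(channels), ncol = length(vals))
  list(channels = channels, m = m)
}

#' @rdname write_recording
#' @param format input format; only the documented tabular layout is
#'   supported.
#' @export
read_recording <- function(stem, format = c("tabular")) {
  format <- match.arg(format)
  meta_path <- paste0(stem, ".yaml")
  if (!file.exists(meta_path))
    stop(sprintf("metadata sidecar %s not found", meta_path))
  meta <- yaml::read_yaml(meta_path)
  for (f in c("fs", "subject_id", "condition", "channels"))
    if (is.null(meta[[f]]))
      stop(sprintf("metadata sidecar is missing required field '%s'", f))
  oxy <- read_hb_matrix(paste0(stem, ".oxy.tsv"), "oxy")
  deoxy <- read_hb_matrix(paste0(stem, ".deoxy.tsv"), "deoxy")
  if (!identical(oxy$channels, as.integer(meta$channels)))
    stop("channel ids in oxy matrix do not match the metadata sidecar")
  if (!identical(oxy$channels, deoxy$channels))
    stop("channel ids differ between oxy and deoxy matrices")
  rec <- fnirs_recording(oxy$m, deoxy$m, fs = meta$fs,
                         subject_id = meta$subject_id,
                         condition = meta$condition,
                         channels = oxy$channels,
                         valid_channel_mask = as.logical(meta$valid_channel_mask),
                         valid_block_mask =
                           if (is.null(meta$valid_block_mask)) NULL
                           else as.logical(meta$valid_block_mask))
  rec$filtered <- isTRUE(meta$filtered)
  rec$zscored <- isTRUE(meta$zscored)
  rec$baselined <- isTRUE(meta$baselined)
  rec
}

#' Write or read a block design as TSV
#'
#' One row per interval with columns `kind` (rest/task/trial), `block`,
#' `trial`, `step` (memorize/retain/answer for trial rows), `start`,
#' `end`.  Sampling rate and nominal trial period travel in `#`-prefixed
#' header lines.
#'
#' @param design a [block_design].
#' @param path output path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "block_design"))
  rows <- list()
  for (i in seq_len(nrow(design$rest_blocks)))
    rows[[length(rows) + 1L]] <- data.frame(kind = "rest", block = i,
      trial = NA_integer_, step = NA_character_,
      start = design$rest_blocks[i, 1], end = design$rest_blocks[i, 2])
  for (b in seq_len(nrow(design$task_blocks))) {
    rows[[length(rows) + 1L]] <- data.frame(kind = "task", block = b,
      trial = NA_integer_, step = NA_character_,
      start = design$task_blocks[b, 1], end = design$task_blocks[b, 2])
    tr <- design$trials[[b]]
    for (j in seq_len(nrow(tr)))
      for (step in c("memorize", "retain", "answer"))
        rows[[length(rows) + 1L]] <- data.frame(kind = "trial", block = b,
          trial = j, step = step,
          start = tr[j, paste0(step, "_start")],
          end = tr[j, paste0(step, "_end")])
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.17g", design$fs),
               sprintf("# trial_period_s: %.17g", design$trial_period_s)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("design file is missing '# %s:' header", key))
    as.numeric(sub(sprintf("^# %s:\\s*", key), "", m[1L]))
  }
  fs <- get_num("fs")
  trial_period_s <- get_num("trial_period_s")
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  rest <- df[df$kind == "rest", ]
  task <- df[df$kind == "task", ]
  task <- task[order(task$block), ]
  trials <- lapply(task$block, function(b) {
    tb <- df[df$kind == "trial" & df$block == b, ]
    mk <- function(step, side) tb[tb$step == step, side]
    m <- cbind(memorize_start = mk("memorize", "start"),
               memorize_end = mk("memorize", "end"),
               retain_start = mk("retain", "start"),
               retain_end = mk("retain", "end"),
               answer_start = mk("answer", "start"),
               answer_end = mk("answer", "end"))
    m[order(m[, "memorize_start"]), , drop = FALSE]
  })
  block_design(as.matrix(rest[order(rest$block), c("start", "end")]),
               as.matrix(task[, c("start", "end")]),
               trials, trial_period_s, fs)
}

#' Write or read a behavioural table
#'
#' Long CSV with columns `subject`, `condition` (`white`/`silent`),
#' `score` (percent correct, 0-100) and `vas` (pleasantness, 0-10).
#'
#' @param behavior data frame as described above.
#' @param path file path.
#' @export
write_behavior <- function(behavior, path) {
  validate_behavior(behavior)
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_behavior(df)
  df
}

validate_behavior <- function(df) {
  need <- c("subject", "condition", "score", "vas")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("behavioural table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!all(df$condition %in% c("white", "silent")))
    stop("behavioural 'condition' must be 'white' or 'silent'")
  tab <- table(df$subject, df$condition)
  if (!all(tab == 1L))
    stop("every subject must appear exactly once per condition")
  if (any(df$score < 0 | df$score > 100))
    stop("task scores must lie in [0, 100] percent")
  if (any(df$vas < 0 | df$vas > 10))
    stop("VAS ratings must lie in [0, 10]")
  invisible(df)
}

#' Load a bundled channel-to-region map
#'
#' Probabilistic registrations of the 70 measurement channels (22 frontal,
#' 24 per temporal side) to AAL/Brodmann-style region labels, as produced
#' by virtual registration to MNI space.  Registration was run separately
#' per behavioural group, so three maps are bundled and the caller chooses
#' which to use.
#'
#' @param group `"white"`, `"average"` or `"silence"`.
#' @return Data frame with columns `channel`, `region_id`, `region`,
#'   `probability` (assignment probability in percent), 70 rows.
#' @export
load_channel_map <- function(group = c("white", "average", "silence")) {
  group <- match.arg(group)
  path <- system.file("extdata", sprintf("channel_map_%s.csv", group),
                      package = "fnirsconn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(identical(df$channel, 1:70),
            all(df$probability > 0 & df$probability <= 100))
  df
}

#' Write or read a labeled square channel matrix
#'
#' Plain-text TSV with a header row and leading column of channel ids;
#' values carry 17 significant digits so round trips are lossless at
#' double precision.
#'
#' @param m square numeric matrix; channel ids are taken from
#'   `rownames(m)` (falling back to `1:n`).
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("'m' must be a square matrix")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("channel", ids), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(ids, ids)
  m
}
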