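#' Run the full analysis on a cohort held in memory
#'
#' Applies the preprocessing chain, the activation measure and the
#' connectivity graph to every subject-condition recording, splits the
#' cohort into White / Average / Silence groups from the behavioural
#' table, and runs the group-level statistics: cohort-wide paired
#' condition tests (score, VAS, per-channel activation and strength),
#' per-group channel-wise paired tests with FDR correction, and Tukey
#' between-group comparisons of score and VAS per condition.
#'
#' @param cohort an `fnirs_cohort` from [generate_cohort()], or any list
#'   with the same `subjects` / `behavior` shape.
#' @param alpha significance level for all tests.
#' @param fdr apply Benjamini-Hochberg correction to channel-wise tables.
#' @param motion_threshold,dead_tol,filter_order preprocessing options,
#'   see [preprocess()].
#' @return Object of class `cohort_analysis` with elements `groups`,
#'   `activation` / `strength` (per condition, subjects x channels),
#'   `contrast` (activation, white minus silent), `graphs`, `reports`,
#'   `cohort_tests`, `group_tests`, `tukey`.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, fdr = TRUE,
                           motion_threshold = 0.1, dead_tol = 0,
                           filter_order = 4) {
  subjects <- cohort$subjects
  n <- length(subjects)
  nch <- length(subjects[[1]]$recordings$white$channels)
  ch_names <- as.character(subjects[[1]]$recordings$white$channels)
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  empty <- function() matrix(NA_real_, n, nch, dimnames = list(ids, ch_names))
  activation <- list(white = empty(), silent = empty())
  strength <- list(white = empty(), silent = empty())
  graphs <- list()
  reports <- list()
  for (i in seq_len(n)) {
    sub <- subjects[[i]]
    for (condition in c("white", "silent")) {
      rec <- sub$recordings[[condition]]
      design <- sub$designs[[condition]]
      pp <- tryCatch(
        preprocess(rec, design, motion_threshold = motion_threshold,
                   dead_tol = dead_tol, filter_order = filter_order),
        error = function(e) stop(sprintf("preprocess failed for %s (%s): %s",
                                         sub$subject_id, condition,
                                         conditionMessage(e)), call. = FALSE))
      act <- accumulated_change(pp$recording, design)
      graph <- connectivity_graph(pp$recording, design)
      activation[[condition]][i, ] <- act$values
      strength[[condition]][i, ] <- graph$strength
      graphs[[sub$subject_id]][[condition]] <- graph
      reports[[sub$subject_id]][[condition]] <- pp$report
    }
  }
  behavior <- cohort$behavior
  groups <- split_groups(behavior)
  wb <- behavior[behavior$condition == "white", ]
  sb <- behavior[behavior$condition == "silent", ]
  sb <- sb[match(wb$subject, sb$subject), ]
  cohort_tests <- list(
    score = paired_condition_test(wb$score, sb$score, alpha = alpha),
    vas = paired_condition_test(wb$vas, sb$vas, alpha = alpha),
    activation = channelwise_paired_tests(activation$white, activation$silent,
                                          alpha = alpha, fdr = fdr),
    strength = channelwise_paired_tests(strength$white, strength$silent,
                                        alpha = alpha, fdr = fdr))
  group_tests <- list()
  for (g in c("White", "Average", "Silence")) {
    members <- groups$subject[groups$label == g]
    if (length(members) < 2) next
    sel <- ids %in% members
    group_tests[[g]] <- list(
      n = sum(sel),
      activation = channelwise_paired_tests(activation$white[sel, , drop = FALSE],
                                            activation$silent[sel, , drop = FALSE],
                                            alpha = alpha, fdr = fdr),
      strength = channelwise_paired_tests(strength$white[sel, , drop = FALSE],
                                          strength$silent[sel, , drop = FALSE],
                                          alpha = alpha, fdr = fdr))
  }
  labels <- groups$label[match(wb$subject, groups$subject)]
  tukey <- list()
  if (length(unique(labels)) >= 2 && all(table(labels) >= 2)) {
    tukey <- list(
      score_white = between_group_comparison(wb$score, labels, alpha = alpha),
      score_silent = between_group_comparison(sb$score, labels, alpha = alpha),
      vas_white = between_group_comparison(wb$vas, labels, alpha = alpha),
      vas_silent = between_group_comparison(sb$vas, labels, alpha = alpha))
  }
  contrast <- activation$white - activation$silent
  structure(list(groups = groups, activation = activation,
                 strength = strength, contrast = contrast, graphs = graphs,
                 reports = reports, cohort_tests = cohort_tests,
                 group_tests = group_tests, tukey = tukey,
                 alpha = alpha), class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  print(x$groups)
  cat(sprintf("  cohort VAS paired t(%d) = %.2f, p = %.3g\n",
              x$cohort_tests$vas$df, x$cohort_tests$vas$statistic,
              x$cohort_tests$vas$p.value))
  nsig <- sum(x$cohort_tests$strength$significant, na.rm = TRUE)
  cat(sprintf("  cohort channels with condition-dependent strength at alpha=%.2f: %d\n",
              x$alpha, nsig))
  invisible(x)
}

default_run_config <- function() {
  list(n_subjects = 29, seed = 1L, alpha = 0.05, fdr = TRUE,
       motion_threshold = 0.1, dead_tol = 0, filter_order = 4,
       write_recordings = FALSE, output_dir = "fnirsconn-run")
}

#' Run the simulate -> preprocess -> activation -> connectivity -> stats
#' pipeline and write its outputs to disk
#'
#' @param config a named list or the path of a YAML file.  Recognized
#'   fields (all optional): `n_subjects`, `seed`, `alpha`, `fdr`,
#'   `motion_threshold`, `dead_tol`, `filter_order`, `output_dir`,
#'   `write_recordings`, plus any [cohort_spec()] argument under a
#'   `cohort:` sub-list.  Unknown fields are an error.
#' @return The run manifest (also written to `manifest.json`): package
#'   version, seed, configuration, and an md5 hash per output file.
#'   Re-running with the same configuration reproduces identical
#'   outputs.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file %s does not exist", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- default_run_config()
  spec_args <- config$cohort
  config$cohort <- NULL
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(config)] <- config
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, c(list(n_subjects = cfg$n_subjects,
                                      seed = cfg$seed), spec_args))
  cohort <- generate_cohort(spec)
  res <- analyze_cohort(cohort, alpha = cfg$alpha, fdr = cfg$fdr,
                        motion_threshold = cfg$motion_threshold,
                        dead_tol = cfg$dead_tol,
                        filter_order = cfg$filter_order)
  files <- character(0)
  put <- function(writer, ..., name) {
    path <- file.path(out, name)
    writer(..., path)
    files <<- c(files, path)
    path
  }
  put(write_behavior, cohort$behavior, name = "behavior.csv")
  put(function(df, p) utils::write.csv(df, p, row.names = FALSE),
      data.frame(res$groups, threshold = attr(res$groups, "threshold")),
      name = "group_assignment.csv")
  for (condition in c("white", "silent")) {
    put(function(m, p) utils::write.csv(m, p),
        res$activation[[condition]],
        name = sprintf("activation_%s.csv", condition))
    put(function(m, p) utils::write.csv(m, p),
        res$strength[[condition]],
        name = sprintf("strength_%s.csv", condition))
  }
  put(function(m, p) utils::write.csv(m, p), res$contrast,
      name = "activation_contrast.csv")
  for (nm in names(res$cohort_tests)) {
    obj <- res$cohort_tests[[nm]]
    if (is.data.frame(obj))
      put(function(df, p) utils::write.csv(df, p, row.names = FALSE), obj,
          name = sprintf("cohort_test_%s.csv", nm))
  }
  for (g in names(res$group_tests))
    for (m in c("activation", "strength"))
      put(function(df, p) utils::write.csv(df, p, row.names = FALSE),
          res$group_tests[[g]][[m]],
          name = sprintf("group_%s_%s_tests.csv", tolower(g), m))
  for (nm in names(res$tukey))
    put(function(df, p) utils::write.csv(df, p, row.names = FALSE),
        res$tukey[[nm]], name = sprintf("tukey_%s.csv", nm))
  gdir <- file.path(out, "graphs")
  dir.create(gdir, showWarnings = FALSE)
  for (id in names(res$graphs))
    for (condition in c("white", "silent")) {
      path <- file.path(gdir, sprintf("%s_%s_z.tsv", id, condition))
      write_matrix(res$graphs[[id]][[condition]]$z, path)
      files <- c(files, path)
    }
  if (isTRUE(cfg$write_recordings)) {
    rdir <- file.path(out, "recordings")
    dir.create(rdir, showWarnings = FALSE)
    for (sub in cohort$subjects)
      for (condition in c("white", "silent")) {
        stem <- file.path(rdir, sprintf("%s_%s", sub$subject_id, condition))
        write_recording(sub$recordings[[condition]], stem)
        write_design(sub$designs[[condition]], paste0(stem, ".design.tsv"))
        files <- c(files, paste0(stem, c(".oxy.tsv", ".deoxy.tsv", ".yaml",
                                         ".design.tsv")))
      }
  }
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", out, "/?"), "", names(hashes))
  manifest <- list(package = "fnirsconn",
                   version = as.character(utils::packageVersion("fnirsconn")),
                   seed = cfg$seed, config = cfg, files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
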