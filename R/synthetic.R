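#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak around 5-6 s, late
#' undershoot around 15-16 s, undershoot ratio 1/6), sampled at `fs` and
#' scaled to unit peak.  Convolved with a task boxcar it produces the
#' block-locked oxy-Hb response planted by the synthetic generator.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s kernel support in seconds.
#' @return Numeric vector of kernel samples, `max(h) == 1`.
#' @export
canonical_hrf <- function(fs, duration_s = 32) {
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Channel sets by registered brain region
#'
#' Convenience groupings of the 70-channel montage used by the synthetic
#' generator's default effect maps, derived from a bundled
#' channel-to-region map: channels registered to the middle temporal
#' gyrus, the premotor/supplementary motor cortex, the fusiform gyrus,
#' plus the positional frontal (49-70) and temporal (1-48) blocks.
#'
#' @param group which bundled map to derive region sets from.
#' @return Named list of integer channel-id vectors.
#' @export
channel_sets <- function(group = c("white", "average", "silence")) {
  map <- load_channel_map(match.arg(group))
  list(middle_temporal = map$channel[map$region_id == 21L],
       premotor_sma = map$channel[map$region_id == 6L],
       fusiform = map$channel[map$region_id == 37L],
       superior_temporal = map$channel[map$region_id == 22L],
       # middle temporal gyrus plus the regions it couples with during
       # the task: superior temporal, retrosubicular, subcentral, fusiform
       task_coupled_temporal = sort(map$channel[map$region_id %in%
                                                  c(21L, 22L, 48L, 43L, 37L)]),
       frontal = 49:70,
       temporal = 1:48)
}

default_behavior_model <- function() {
  data.frame(
    phenotype = rep(c("white_benefit", "unaffected", "silence_benefit"), each = 2),
    condition = rep(c("white", "silent"), times = 3),
    score_mean = c(85, 75, 80, 80, 75, 85),
    score_sd = rep(2, 6),
    vas_mean = c(5.5, 5.0, 3.5, 6.0, 2.0, 7.0),
    vas_sd = rep(1, 6),
    stringsAsFactors = FALSE)
}

default_activation_effects <- function() {
  sets <- channel_sets("white")
  list(
    # task engages the montage broadly in both environments
    list(phenotype = "all", condition = "both", channels = NULL,
         amplitude = 0.02),
    # unaffected phenotype: extra frontal / right superior temporal
    # response under white noise (attention-control recruitment)
    list(phenotype = "unaffected", condition = "white",
         channels = sort(unique(c(sets$frontal, sets$superior_temporal))),
         amplitude = 0.025),
    # silence-benefit phenotype: extra fusiform response in silence
    list(phenotype = "silence_benefit", condition = "silent",
         channels = sets$fusiform, amplitude = 0.025))
}

default_connectivity_effects <- function() {
  sets <- channel_sets("white")
  list(
    # weak montage-wide background factor shared by both conditions
    list(phenotype = "all", condition = "both", channels = NULL,
         loading = 0.2),
    # white-benefit phenotype: the middle temporal gyrus couples with its
    # neighbouring temporal regions under white noise
    list(phenotype = "white_benefit", condition = "white",
         channels = sets$task_coupled_temporal, loading = 1.0),
    # the remaining phenotypes couple premotor/SMA channels in silence
    list(phenotype = "unaffected", condition = "silent",
         channels = sets$premotor_sma, loading = 1.0),
    list(phenotype = "silence_benefit", condition = "silent",
         channels = sets$premotor_sma, loading = 1.0))
}

#' Specification of a synthetic cohort
#'
#' Bundles every parameter of the synthetic data model: the block design
#' (60 s rest blocks, three task blocks of ten memorize/retain/answer
#' trials, answer duration varying per trial), the phenotype mix, planted
#' hemodynamic and connectivity effects, structured physiological noise
#' (cardiac ~1 Hz, respiratory ~0.3 Hz, slow drift), optional motion
#' spikes and dead channels, and the behavioural model.
#'
#' Amplitudes are in mM·mm.  The defaults plant a white-benefit
#' phenotype whose middle-temporal channels couple under white noise, an
#' unaffected phenotype with extra frontal activation under white noise,
#' and a silence-benefit phenotype with extra fusiform activation in
#' silence, mirroring the qualitative group-level patterns the analysis
#' is designed to detect, with a 8/13/8 phenotype mix in a 29-subject
#' cohort.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param group_fractions named fractions for the `white_benefit`,
#'   `unaffected` and `silence_benefit` phenotypes; must sum to 1.
#' @param fs sampling rate in Hz.
#' @param rest_s rest-block duration in seconds.
#' @param n_task_blocks,trials_per_block block-design shape.
#' @param memorize_s,retain_s fixed step durations in seconds.
#' @param answer_range_s range the per-trial answer duration is drawn
#'   from (uniform), seconds; upper bound is the 7 s response ceiling.
#' @param n_channels number of measurement channels.
#' @param activation list of activation effects, each
#'   `list(phenotype, condition, channels, amplitude)`; `phenotype =
#'   "all"`, `condition = "both"` and `channels = NULL` act as wildcards.
#' @param connectivity list of latent-factor effects, each
#'   `list(phenotype, condition, channels, loading)`.
#' @param noise list of physiological-noise parameters (see defaults):
#'   sinusoidal cardiac, respiratory and drift components with
#'   per-channel random phase, an independent per-channel Mayer-wave
#'   component (random frequency within `mayer_band`), and white sensor
#'   noise.  `factor_scale` is the standard deviation, in mM·mm, of a
#'   unit-loading connectivity factor (a unit-variance narrowband
#'   oscillation drawn from `factor_band`); see
#'   [simulate_factor_channels()] for the Gaussian-factor closed form
#'   used in calibration checks.
#' @param artifact_rate expected number of motion spikes per recording
#'   (Poisson).
#' @param spike_amp spike amplitude in mM·mm; must exceed the 0.1 mM·mm
#'   per-sample rejection threshold for planted artifacts to be
#'   detectable.
#' @param dead_channel_rate probability that a channel is dead (all-zero
#'   trace).
#' @param behavior data frame phenotype x condition with columns
#'   `score_mean`, `score_sd`, `vas_mean`, `vas_sd`.
#' @param seed RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 29,
                        group_fractions = c(white_benefit = 8 / 29,
                                            unaffected = 13 / 29,
                                            silence_benefit = 8 / 29),
                        fs = 10, rest_s = 60, n_task_blocks = 3,
                        trials_per_block = 10, memorize_s = 3, retain_s = 1,
                        answer_range_s = c(4, 7), n_channels = 70,
                        activation = default_activation_effects(),
                        connectivity = default_connectivity_effects(),
                        noise = list(cardiac_hz = 1.0, cardiac_amp = 0.02,
                                     resp_hz = 0.3, resp_amp = 0.002,
                                     drift_hz = 0.01, drift_amp = 0.02,
                                     mayer_band = c(0.06, 0.15),
                                     mayer_amp = 0.015,
                                     factor_band = c(0.08, 0.12),
                                     white_sd = 0.01, factor_scale = 0.01),
                        artifact_rate = 0, spike_amp = 0.5,
                        dead_channel_rate = 0,
                        behavior = default_behavior_model(),
                        seed = 1L) {
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("'group_fractions' must sum to 1")
  if (any(group_fractions < 0)) stop("'group_fractions' must be non-negative")
  stopifnot(fs > 0, rest_s > 0, n_task_blocks >= 1, trials_per_block >= 1,
            memorize_s > 0, retain_s > 0,
            length(answer_range_s) == 2, all(answer_range_s > 0),
            answer_range_s[1] <= answer_range_s[2])
  if (any(c(behavior$score_sd, behavior$vas_sd) < 0))
    stop("behavioural standard deviations must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_fractions = group_fractions, fs = fs, rest_s = rest_s,
                 n_task_blocks = as.integer(n_task_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 memorize_s = memorize_s, retain_s = retain_s,
                 answer_range_s = answer_range_s,
                 n_channels = as.integer(n_channels),
                 activation = activation, connectivity = connectivity,
                 noise = noise, artifact_rate = artifact_rate,
                 spike_amp = spike_amp,
                 dead_channel_rate = dead_channel_rate,
                 behavior = behavior, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one randomized block design
#'
#' Rest blocks of `rest_s` seconds alternate with task blocks; an extra
#' rest block follows the last task block.  Each task block holds
#' `trials_per_block` memorize/retain/answer trials whose answer duration
#' is drawn uniformly from `answer_range_s`, so total session length
#' differs between draws.  Uses the current RNG stream.
#'
#' @param spec a [cohort_spec].
#' @return A [block_design]; `trial_period_s` is the mean realized trial
#'   duration.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$fs
  rest_n <- as.integer(round(spec$rest_s * fs))
  mem_n <- as.integer(round(spec$memorize_s * fs))
  ret_n <- as.integer(round(spec$retain_s * fs))
  pos <- 0L
  rest_blocks <- matrix(integer(0), ncol = 2)
  task_blocks <- matrix(integer(0), ncol = 2)
  trials <- vector("list", spec$n_task_blocks)
  trial_lens <- numeric(0)
  for (b in seq_len(spec$n_task_blocks)) {
    rest_blocks <- rbind(rest_blocks, c(pos, pos + rest_n))
    pos <- pos + rest_n
    tb_start <- pos
    tr <- matrix(0L, nrow = spec$trials_per_block, ncol = 6,
                 dimnames = list(NULL, c("memorize_start", "memorize_end",
                                         "retain_start", "retain_end",
                                         "answer_start", "answer_end")))
    for (j in seq_len(spec$trials_per_block)) {
      ans_n <- as.integer(round(stats::runif(1, spec$answer_range_s[1],
                                             spec$answer_range_s[2]) * fs))
      tr[j, ] <- c(pos, pos + mem_n,
                   pos + mem_n, pos + mem_n + ret_n,
                   pos + mem_n + ret_n, pos + mem_n + ret_n + ans_n)
      trial_lens <- c(trial_lens, (mem_n + ret_n + ans_n) / fs)
      pos <- pos + mem_n + ret_n + ans_n
    }
    trials[[b]] <- tr
    task_blocks <- rbind(task_blocks, c(tb_start, pos))
  }
  rest_blocks <- rbind(rest_blocks, c(pos, pos + rest_n))  # closing rest block
  block_design(rest_blocks, task_blocks, trials,
               trial_period_s = mean(trial_lens), fs = fs)
}

#' Latent-factor channel model
#'
#' Draws `x[i, t] = loadings[i] * f[t] + noise_sd * e[i, t]` with `f` and
#' `e` independent standard normal.  For two channels with common loading
#' `lambda` and `noise_sd = 1` the population Pearson correlation is
#' `lambda^2 / (lambda^2 + 1)`.  Used internally to plant connectivity
#' structure; exported because the closed form makes it a convenient
#' calibration oracle.
#'
#' @param loadings numeric vector, one loading per channel.
#' @param n_samples number of time points.
#' @param noise_sd standard deviation of the idiosyncratic noise.
#' @return Matrix, `length(loadings)` x `n_samples`.
#' @export
simulate_factor_channels <- function(loadings, n_samples, noise_sd = 1) {
  f <- stats::rnorm(n_samples)
  outer(loadings, f) +
    noise_sd * matrix(stats::rnorm(length(loadings) * n_samples),
                      nrow = length(loadings))
}

effect_applies <- function(effect, phenotype, condition) {
  (effect$phenotype == "all" || effect$phenotype == phenotype) &&
    (effect$condition == "both" || effect$condition == condition)
}

#' Generate one synthetic subject
#'
#' Builds both condition recordings (each with its own randomized block
#' design), the behavioural entries, and a ground-truth record.  The
#' oxy-Hb trace is the sum of the planted hemodynamic response (canonical
#' HRF convolved with the task boxcar, scaled by the phenotype- and
#' condition-specific amplitude map), latent-factor components carrying
#' the planted correlation structure, sinusoidal cardiac/respiratory
#' noise with per-channel random phase, slow drift, white noise, and
#' optional single-sample motion spikes.  Deoxy-Hb is generated as an
#' anticorrelated scaled copy plus independent noise (it is not analysed
#' downstream).  Dead channels are exact-zero traces.
#'
#' @param spec a [cohort_spec].
#' @param phenotype `"white_benefit"`, `"unaffected"` or
#'   `"silence_benefit"`.
#' @param subject_id character id.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so identical (spec, seed) yield bitwise-identical subjects.
#' @param include_recordings if `FALSE`, only behaviour and ground truth
#'   are generated (behavioural draws come first in the RNG stream, so
#'   they are identical to the full-mode draws for the same seed).
#' @return Object of class `fnirs_subject`: recordings and designs per
#'   condition, a behavioural data frame, and `ground_truth` (phenotype,
#'   planted amplitude maps and factor loadings, spike and dead-channel
#'   indices).
#' @export
generate_subject <- function(spec, phenotype = c("white_benefit", "unaffected",
                                                 "silence_benefit"),
                             subject_id = "s01", seed = NULL,
                             include_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  phenotype <- match.arg(phenotype)
  if (!is.null(seed)) set.seed(seed)
  bm <- spec$behavior
  beh <- do.call(rbind, lapply(c("white", "silent"), function(condition) {
    row <- bm[bm$phenotype == phenotype & bm$condition == condition, ]
    if (nrow(row) != 1L)
      stop(sprintf("behaviour model lacks a row for phenotype %s, condition %s",
                   phenotype, condition))
    data.frame(subject = subject_id, condition = condition,
               score = min(100, max(0, stats::rnorm(1, row$score_mean,
                                                    row$score_sd))),
               vas = min(10, max(0, stats::rnorm(1, row$vas_mean, row$vas_sd))),
               stringsAsFactors = FALSE)
  }))
  if (!include_recordings)
    return(structure(list(subject_id = subject_id, phenotype = phenotype,
                          recordings = NULL, designs = NULL, behavior = beh,
                          ground_truth = list(phenotype = phenotype)),
                     class = "fnirs_subject"))
  nch <- spec$n_channels
  hrf <- canonical_hrf(spec$fs)
  hrf_area <- sum(hrf)  # divisor giving unit plateau for long boxcars
  recordings <- list()
  designs <- list()
  gt_amp <- list()
  gt_load <- list()
  gt_spikes <- list()
  dead <- which(stats::runif(nch) < spec$dead_channel_rate)
  for (condition in c("white", "silent")) {
    design <- generate_design(spec)
    n <- max(design$rest_blocks[, 2], design$task_blocks[, 2])
    t <- (seq_len(n) - 1) / spec$fs
    # trial-locked stimulus train: the encoding (memorize + retain) step
    # of every trial; its fundamental (~1/T Hz) lies inside the analysis
    # passband, unlike a whole-block boxcar whose within-block content is
    # near-DC and would not survive the high-pass edge at 1/(2T)
    boxcar <- numeric(n)
    for (b in seq_len(n_task_blocks(design))) {
      tr <- design$trials[[b]]
      for (j in seq_len(nrow(tr)))
        boxcar[seq.int(tr[j, "memorize_start"] + 1L, tr[j, "retain_end"])] <- 1
    }
    regressor <- stats::convolve(boxcar, rev(hrf), type = "open")[seq_len(n)] /
      hrf_area
    amp <- numeric(nch)
    for (eff in spec$activation) {
      if (!effect_applies(eff, phenotype, condition)) next
      chs <- if (is.null(eff$channels)) seq_len(nch) else eff$channels
      amp[chs] <- amp[chs] + eff$amplitude
    }
    oxy <- outer(amp, regressor)
    ns <- spec$noise
    load_map <- matrix(0, nrow = nch, ncol = 0)
    for (eff in spec$connectivity) {
      if (!effect_applies(eff, phenotype, condition)) next
      chs <- if (is.null(eff$channels)) seq_len(nch) else eff$channels
      lam <- numeric(nch)
      lam[chs] <- eff$loading
      # unit-variance narrowband oscillation inside the analysis band:
      # coherent slow vasomotion, smooth enough not to trip the
      # per-sample motion-artifact rule at any reasonable loading
      f0 <- stats::runif(1, ns$factor_band[1], ns$factor_band[2])
      f <- sqrt(2) * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
      oxy <- oxy + spec$noise$factor_scale * outer(lam, f)
      load_map <- cbind(load_map, lam)
    }
    phase_c <- stats::runif(nch, 0, 2 * pi)
    phase_r <- stats::runif(nch, 0, 2 * pi)
    phase_d <- stats::runif(nch, 0, 2 * pi)
    # per-channel Mayer-wave component: independent frequency and phase,
    # so it contributes in-band variance without cross-channel correlation
    mayer_f <- stats::runif(nch, ns$mayer_band[1], ns$mayer_band[2])
    phase_m <- stats::runif(nch, 0, 2 * pi)
    oxy <- oxy +
      ns$cardiac_amp * sin(outer(rep(2 * pi * ns$cardiac_hz, nch), t) + phase_c) +
      ns$resp_amp * sin(outer(rep(2 * pi * ns$resp_hz, nch), t) + phase_r) +
      ns$drift_amp * sin(outer(rep(2 * pi * ns$drift_hz, nch), t) + phase_d) +
      ns$mayer_amp * sin(outer(2 * pi * mayer_f, t) + phase_m) +
      ns$white_sd * matrix(stats::rnorm(nch * n), nrow = nch)
    spikes <- NULL
    k <- stats::rpois(1, spec$artifact_rate)
    if (k > 0) {
      spikes <- data.frame(channel = sample.int(nch, k, replace = TRUE),
                           sample = sample.int(n, k, replace = TRUE),
                           amplitude = spec$spike_amp *
                             sample(c(-1, 1), k, replace = TRUE))
      for (i in seq_len(k))
        oxy[spikes$channel[i], spikes$sample[i]] <-
          oxy[spikes$channel[i], spikes$sample[i]] + spikes$amplitude[i]
    }
    deoxy <- -0.4 * oxy + 0.005 * matrix(stats::rnorm(nch * n), nrow = nch)
    if (length(dead)) {
      oxy[dead, ] <- 0
      deoxy[dead, ] <- 0
    }
    recordings[[condition]] <- fnirs_recording(oxy, deoxy, fs = spec$fs,
                                               subject_id = subject_id,
                                               condition = condition)
    designs[[condition]] <- design
    gt_amp[[condition]] <- amp
    gt_load[[condition]] <- load_map
    gt_spikes[[condition]] <- spikes
  }
  structure(list(subject_id = subject_id, phenotype = phenotype,
                 recordings = recordings, designs = designs, behavior = beh,
                 ground_truth = list(phenotype = phenotype,
                                     activation_map = gt_amp,
                                     factor_loadings = gt_load,
                                     spikes = gt_spikes,
                                     dead_channels = dead)),
            class = "fnirs_subject")
}

# largest-remainder apportionment of n among fractions
apportion <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Generate a synthetic cohort
#'
#' Assigns phenotypes by largest-remainder apportionment of
#' `group_fractions`, draws every subject with a seed derived from
#' `spec$seed`, and assembles the cohort behavioural table.
#'
#' @param spec a [cohort_spec].
#' @param include_recordings if `FALSE`, generate behaviour and ground
#'   truth only (fast mode for behavioural simulation studies); the
#'   behavioural draws match the full mode draw-for-draw.
#' @return Object of class `fnirs_cohort`: `subjects` (list of
#'   [generate_subject()] results), `behavior` (cohort behavioural
#'   table), `phenotypes` (named character vector) and the `spec`.
#' @export
generate_cohort <- function(spec, include_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 2)
    stop("a cohort needs at least 2 subjects (group SD is undefined otherwise)")
  counts <- apportion(spec$group_fractions, spec$n_subjects)
  phenotypes <- rep(names(counts), counts)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max, spec$n_subjects)
  ids <- sprintf("s%02d", seq_len(spec$n_subjects))
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject(spec, phenotypes[i], subject_id = ids[i],
                     seed = seeds[i],
                     include_recordings = include_recordings))
  behavior <- do.call(rbind, lapply(subjects, `[[`, "behavior"))
  rownames(behavior) <- NULL
  structure(list(subjects = subjects, behavior = behavior,
                 phenotypes = stats::setNames(phenotypes, ids), spec = spec),
            class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat(sprintf("<fnirs_cohort> %d subjects (%s)\n", length(x$subjects),
              paste(sprintf("%s: %d", names(table(x$phenotypes)),
                            table(x$phenotypes)), collapse = ", ")))
  invisible(x)
}
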