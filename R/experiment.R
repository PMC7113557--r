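#' Session schedule
#'
#' The fixed within-day protocol: three 5 min closed-loop probes separated by
#' 10 min to assess baseline excitability, a 2 min switch gap, the PAS
#' intervention (300 pairs at 0.5 Hz, ~10 min), another 2 min switch gap, and
#' three post-PAS probes starting 2, 17 and 32 min after the end of PAS
#' (assessing excitability up to ~30 min post intervention).
#'
#' @param n_pre_probes,n_post_probes probes before/after PAS (default 3 each).
#' @param probe_min probe duration (min, default 5).
#' @param inter_probe_gap_min gap between probes (min, default 10).
#' @param switch_gap_min wire-switching gap around PAS (min, default 2).
#' @param post_probe_times_min post-probe start times relative to PAS end
#'   (min); must be consistent with the switch gap and probe/gap pattern.
#' @param pas_pairs number of paired stimulations (default 300).
#' @param pas_rate_hz pairing rate (Hz, default 0.5).
#' @return an object of class `session_schedule`.
#' @export
session_schedule <- function(n_pre_probes = 3, n_post_probes = 3,
                             probe_min = 5, inter_probe_gap_min = 10,
                             switch_gap_min = 2,
                             post_probe_times_min = c(2, 17, 32),
                             pas_pairs = 300, pas_rate_hz = 0.5) {
  stopifnot(n_pre_probes >= 1, n_post_probes >= 1, probe_min > 0,
            inter_probe_gap_min >= 0, switch_gap_min >= 0,
            pas_pairs >= 0, pas_rate_hz > 0,
            length(post_probe_times_min) == n_post_probes)
  expected <- switch_gap_min +
    (seq_len(n_post_probes) - 1L) * (probe_min + inter_probe_gap_min)
  if (any(abs(post_probe_times_min - expected) > 1e-9))
    stop("post_probe_times_min inconsistent with the switch-gap/probe/gap pattern")
  structure(list(n_pre_probes = n_pre_probes, n_post_probes = n_post_probes,
                 probe_min = probe_min,
                 inter_probe_gap_min = inter_probe_gap_min,
                 switch_gap_min = switch_gap_min,
                 post_probe_times_min = post_probe_times_min,
                 pas_pairs = pas_pairs, pas_rate_hz = pas_rate_hz),
            class = "session_schedule")
}

#' Randomized block design
#'
#' Assigns each subject an independent random permutation of the condition
#' labels (repeated-measures randomized block design: the same rat is tested
#' on all ISI conditions in a randomized order). A late-added condition can be
#' appended at the end of selected subjects' orders with [add_condition()].
#'
#' @param n_subjects number of subjects (>= 1).
#' @param conditions condition labels (character) or an
#'   `isi_condition_table`.
#' @param seed integer seed; orders are reproducible under it.
#' @return an object of class `experiment_design` with an
#'   `order_matrix` (subjects x test slots) of condition labels.
#' @export
randomize_design <- function(n_subjects, conditions, seed = 1L) {
  if (inherits(conditions, "isi_condition_table")) conditions <- conditions$label
  stopifnot(n_subjects >= 1, length(conditions) >= 1,
            !anyDuplicated(conditions))
  set.seed(seed)
  om <- t(vapply(seq_len(n_subjects),
                 function(i) sample(conditions, length(conditions)),
                 character(length(conditions))))
  if (length(conditions) == 1L) om <- matrix(conditions, n_subjects, 1L)
  rownames(om) <- sprintf("rat%02d", seq_len(n_subjects))
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 order_matrix = om, seed = seed),
            class = "experiment_design")
}

#' @rdname randomize_design
#' @param design an `experiment_design`.
#' @param label new condition label.
#' @param subjects indices of subjects that receive the new condition appended
#'   at the end of their order (others get `NA` in the new slot).
#' @export
add_condition <- function(design, label, subjects = seq_len(design$n_subjects)) {
  stopifnot(inherits(design, "experiment_design"),
            !label %in% design$conditions)
  newcol <- rep(NA_character_, design$n_subjects)
  newcol[subjects] <- label
  design$order_matrix <- cbind(design$order_matrix, newcol, deparse.level = 0)
  design$conditions <- c(design$conditions, label)
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("experiment_design: %d subjects x %d conditions (seed %d)\n",
              x$n_subjects, length(x$conditions), x$seed))
  invisible(x)
}

#' Estimate a motor threshold by adaptive staircase
#'
#' Operationally, the motor threshold is the minimal stimulation intensity
#' producing a response more than 50% of the time. Responses are Bernoulli
#' with probability given by a logistic recruitment curve around the plant's
#' ground-truth threshold. The estimate is obtained by bisection on the
#' intensity with a fixed number of trials per tested level.
#'
#' @param state a [plant_state()].
#' @param site `"cortex"` (uA) or `"muscle"` (mA).
#' @param n_trials trials per level (default 20).
#' @param n_levels bisection steps (default 8).
#' @param seed seed (default the plant seed).
#' @return estimated threshold, in the site's units.
#' @export
estimate_motor_threshold <- function(state, site = c("cortex", "muscle"),
                                     n_trials = 20, n_levels = 8,
                                     seed = state$rng_seed) {
  site <- match.arg(site)
  stopifnot(inherits(state, "plant_state"))
  if (!is.null(seed)) set.seed(seed)
  thr <- if (site == "cortex") state$cortex_threshold_uA else state$muscle_threshold_mA
  lo <- thr / 4
  hi <- thr * 4
  best <- hi
  for (i in seq_len(n_levels)) {
    mid <- (lo + hi) / 2
    p <- stats::plogis((mid / thr - 1) / state$threshold_slope)
    rate <- mean(stats::rbinom(n_trials, 1, p))
    if (rate > 0.5) {
      best <- mid
      hi <- mid
    } else {
      lo <- mid
    }
  }
  best
}

# one probe -> measure; NULL when no kept trials (flagged upstream)
probe_measure <- function(state, cfg, method, window_ms, rules) {
  p <- run_probe(state, cfg, seed = NULL)
  trials <- screen_trials(p$trials, rules)
  tryCatch(quantify_mep(trials, method, window_ms)$value,
           error = function(e) NA_real_)
}

#' Run one full PAS session on the plant
#'
#' Executes the within-day protocol on an evolving plant: pre-PAS probes, the
#' PAS intervention ([apply_pas()]), then post-PAS probes. Each probe measure
#' is normalized by the mean of the pre-PAS measures. A session in which any
#' probe yields zero kept trials is flagged (and excluded from downstream
#' statistics), mirroring the quality exclusion of sessions with very few
#' MEPs per probe.
#'
#' @param state a [plant_state()]; gains evolve through the session.
#' @param condition an [isi_condition()] or a row of a condition table.
#' @param schedule a [session_schedule()].
#' @param window an [stdp_window()].
#' @param trigger_cfg a [trigger_config()]; calibrated from the plant if
#'   `NULL`.
#' @param method,window_ms MEP quantification method and response window
#'   (see [quantify_mep()]); all measures in a session share them.
#' @param rules [screening_rules()] applied to every probe.
#' @param subject_id,day_index bookkeeping labels.
#' @param probe_duration_s overrides the probe time limit (s); useful for
#'   reduced-scale simulation studies.
#' @param seed session seed (default the plant seed).
#' @return a list with `record` (one-row data frame: measures, normalized
#'   ratios, stimulation bookkeeping, flag) and `state` (the post-intervention
#'   plant, for carryover studies).
#' @export
run_session <- function(state, condition, schedule = session_schedule(),
                        window = stdp_window(), trigger_cfg = NULL,
                        method = "integral_of_average", window_ms = c(8, 30),
                        rules = screening_rules(),
                        subject_id = "rat01", day_index = 1L,
                        probe_duration_s = NULL, seed = state$rng_seed) {
  stopifnot(inherits(state, "plant_state"), inherits(schedule, "session_schedule"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trigger_cfg)) trigger_cfg <- calibrate_trigger_config(state, seed = NULL)
  if (!is.null(probe_duration_s)) trigger_cfg$max_probe_s <- probe_duration_s
  pre <- vapply(seq_len(schedule$n_pre_probes), function(k)
    probe_measure(state, trigger_cfg, method, window_ms, rules), numeric(1))
  state <- apply_pas(state, condition, schedule$pas_pairs,
                     schedule$pas_rate_hz, window)
  post <- vapply(seq_len(schedule$n_post_probes), function(k)
    probe_measure(state, trigger_cfg, method, window_ms, rules), numeric(1))
  flagged <- any(is.na(c(pre, post)))
  ratios <- post / mean(pre)
  label <- if (!is.null(condition$label)) condition$label else condition$kind
  record <- data.frame(
    subject = subject_id, condition = label, kind = condition$kind,
    day = as.integer(day_index),
    pre1 = pre[1], pre2 = pre[2], pre3 = pre[3],
    post1 = post[1], post2 = post[2], post3 = post[3],
    ratio1 = ratios[1], ratio2 = ratios[2], ratio3 = ratios[3],
    cortex_uA = 1.25 * state$cortex_threshold_uA,
    muscle_mA = 1.5 * state$muscle_threshold_mA,
    flagged = flagged, stringsAsFactors = FALSE)
  class(record) <- c("session_records", "data.frame")
  list(record = record, state = state)
}

#' Simulate a full randomized-block experiment
#'
#' Runs every (subject, condition) session of a design and returns the session
#' records. Two fidelities are available. `"measure"` (default) draws probe
#' measures directly from the plant's measurement model - lognormal probe
#' noise around the ground-truth gain product, a lognormal subject baseline
#' scale, and a subject-level post/pre response bias - which is the
#' appropriate scale for Monte-Carlo calibration and power studies.
#' `"waveform"` runs the full signal-level pipeline ([run_session()]) per
#' session; use reduced probe durations to keep it tractable.
#'
#' The plant is re-initialized for every session (each test is separated by
#' ~24 h; the *a posteriori* carryover analysis can then verify the absence of
#' cumulative effects by construction).
#'
#' @param design an [randomize_design()] result.
#' @param conditions an `isi_condition_table` covering every label in the
#'   design.
#' @param window an [stdp_window()]; set both amplitudes to 0 for the null
#'   world.
#' @param schedule a [session_schedule()].
#' @param plant template [plant_state()]; per-session states derive from it.
#' @param fidelity `"measure"` or `"waveform"`.
#' @param probe_cv lognormal CV of a single probe measure around its expected
#'   value (measure fidelity; default 0.2).
#' @param subject_sd SD of the subject-level log post/pre response bias
#'   (measure fidelity; default 0.05).
#' @param baseline_log_sd SD of the subject log baseline scale (default 0.3).
#' @param base_measure_uVs expected probe measure at unit gains (uV s).
#' @param probe_duration_s probe time limit override (waveform fidelity).
#' @param seed experiment seed.
#' @return a `session_records` data frame, one row per session.
#' @export
simulate_experiment <- function(design, conditions = build_condition_table(),
                                window = stdp_window(),
                                schedule = session_schedule(),
                                plant = plant_state(),
                                fidelity = c("measure", "waveform"),
                                probe_cv = 0.2, subject_sd = 0.05,
                                baseline_log_sd = 0.3, base_measure_uVs = 1,
                                probe_duration_s = 30, seed = 1L) {
  fidelity <- match.arg(fidelity)
  stopifnot(inherits(design, "experiment_design"),
            inherits(conditions, "isi_condition_table"))
  om <- design$order_matrix
  if (!all(stats::na.omit(as.vector(om)) %in% conditions$label))
    stop("design contains labels missing from the condition table")
  set.seed(seed)
  n_sub <- design$n_subjects
  recs <- vector("list", n_sub * ncol(om))
  if (fidelity == "measure") {
    u <- stats::rnorm(n_sub, 0, subject_sd)
    B <- base_measure_uVs * exp(stats::rnorm(n_sub, 0, baseline_log_sd))
    s2 <- log(1 + probe_cv^2)
    s <- sqrt(s2)
    k <- 0L
    for (i in seq_len(n_sub)) {
      for (d in seq_len(ncol(om))) {
        lab <- om[i, d]
        if (is.na(lab)) next
        cond <- condition_row(conditions, match(lab, conditions$label))
        st <- plant
        st2 <- apply_pas(st, cond, schedule$pas_pairs, schedule$pas_rate_hz,
                         window)
        net <- (st2$g_spinal * st2$g_cortical) / (st$g_spinal * st$g_cortical)
        pre <- B[i] * exp(stats::rnorm(schedule$n_pre_probes, -s2 / 2, s))
        post <- B[i] * net * exp(u[i]) *
          exp(stats::rnorm(schedule$n_post_probes, -s2 / 2, s))
        ratios <- post / mean(pre)
        k <- k + 1L
        recs[[k]] <- data.frame(
          subject = rownames(om)[i], condition = lab, kind = cond$kind,
          day = d,
          pre1 = pre[1], pre2 = pre[2], pre3 = pre[3],
          post1 = post[1], post2 = post[2], post3 = post[3],
          ratio1 = ratios[1], ratio2 = ratios[2], ratio3 = ratios[3],
          cortex_uA = 1.25 * plant$cortex_threshold_uA,
          muscle_mA = 1.5 * plant$muscle_threshold_mA,
          flagged = FALSE, stringsAsFactors = FALSE)
      }
    }
  } else {
    k <- 0L
    for (i in seq_len(n_sub)) {
      for (d in seq_len(ncol(om))) {
        lab <- om[i, d]
        if (is.na(lab)) next
        cond <- condition_row(conditions, match(lab, conditions$label))
        st <- plant
        st$rng_seed <- (plant$rng_seed + 7919L * i + 104729L * d) %%
          .Machine$integer.max
        out <- run_session(st, cond, schedule, window,
                           subject_id = rownames(om)[i], day_index = d,
                           probe_duration_s = probe_duration_s,
                           seed = st$rng_seed)
        k <- k + 1L
        recs[[k]] <- out$record
      }
    }
  }
  records <- do.call(rbind, recs[seq_len(k)])
  class(records) <- c("session_records", "data.frame")
  records
}

#' Simulate null-world session records with model-matched structure
#'
#' Generates a `session_records` table in which every normalized ratio is
#' 1 plus a subject-level random effect plus i.i.d. probe noise - exactly the
#' generative structure assumed by the mixed model fitted in
#' [fit_mixed_anova()] (random rat intercept, independent residuals). This is
#' the appropriate null world for type-I-error calibration of the test
#' itself: over repeated simulation the three p values are uniform and the
#' rejection rate at alpha = 0.05 is ~0.05.
#'
#' This is deliberately simpler than the end-to-end plant path: normalizing
#' each post measure by the *shared* mean of the three pre measures induces a
#' record-level correlation that the rat-only random effect does not capture
#' (see the methods vignette).
#'
#' @param n_subjects number of subjects.
#' @param conditions condition labels (character) or an
#'   `isi_condition_table`.
#' @param subject_sd SD of the subject-level ratio offset (default 0.05).
#' @param noise_sd SD of the i.i.d. per-session-probe ratio noise
#'   (default 0.15).
#' @param seed integer seed, or `NULL` to continue the current stream.
#' @return a `session_records` data frame, one row per subject x condition.
#' @export
simulate_null_records <- function(n_subjects, conditions,
                                  subject_sd = 0.05, noise_sd = 0.15,
                                  seed = NULL) {
  if (inherits(conditions, "isi_condition_table")) conditions <- conditions$label
  stopifnot(n_subjects >= 1, length(conditions) >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  g <- expand.grid(si = seq_len(n_subjects), condition = conditions,
                   stringsAsFactors = FALSE)
  n <- nrow(g)
  post <- replicate(3, 1 + u[g$si] + stats::rnorm(n, 0, noise_sd))
  rec <- data.frame(
    subject = sprintf("rat%02d", g$si), condition = g$condition,
    kind = "paired",
    day = stats::ave(g$si, g$si, FUN = seq_along),
    pre1 = 1, pre2 = 1, pre3 = 1,
    post1 = post[, 1], post2 = post[, 2], post3 = post[, 3],
    ratio1 = post[, 1], ratio2 = post[, 2], ratio3 = post[, 3],
    cortex_uA = 987.5, muscle_mA = 2.7,
    flagged = FALSE, stringsAsFactors = FALSE)
  class(rec) <- c("session_records", "data.frame")
  rec
}
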