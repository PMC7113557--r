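#' Latent corticospinal plant state
#'
#' Ground-truth state of the simulated freely behaving rat preparation: the
#' spinal and cortical synaptic gains that PAS may modify, the conduction
#' latencies, and the parameters of the synthetic EMG/LFP signal generators.
#'
#' The EMG generator emits, at `rate_hz`, a crest-limited white noise carrier
#' (uniform on +/- sqrt(3), unit variance) scaled by `emg_baseline_sd_uV`
#' times the behavior-state amplitude multiplier. A compact-support carrier
#' guarantees that the peak envelope of the resting signal stays strictly
#' below the closed-loop trigger floor (baseline mean + 2 SD of the rectified
#' signal), as observed in the real preparation, while contraction-state
#' signals land inside the 2-12 SD trigger window.
#'
#' Single-trial MEP amplitudes are lognormal with unit mean and a coefficient
#' of variation that depends on the behavior state at stimulation time;
#' stimulating during low contraction yields less variable MEPs than at rest,
#' which is the rationale for the closed-loop probe.
#'
#' @param g_spinal,g_cortical dimensionless synaptic gains (> 0); the expected
#'   MEP amplitude scales with their product.
#' @param behavior_state default behavior state, one of `"rest"`,
#'   `"low_contraction"`, `"strong_contraction"`.
#' @param latencies a [conduction_latencies()].
#' @param mep_noise_cv named numeric vector of single-trial MEP amplitude CVs
#'   per behavior state; `low_contraction` must not exceed `rest`.
#' @param emg_baseline_sd_uV SD of the resting EMG signal (uV).
#' @param rng_seed integer seed used by generator entry points.
#' @param rate_hz EMG sampling rate (Hz, default 5000).
#' @param lfp_rate_hz LFP channel sampling rate (Hz, default 1000).
#' @param behavior_amp named amplitude multipliers per behavior state,
#'   relative to `emg_baseline_sd_uV`.
#' @param mep_scale_uV MEP template peak amplitude at unit gains (uV).
#' @param mep_duration_ms duration of the biphasic MEP template (ms).
#' @param spinal_ep_uV,spinal_ep_width_ms amplitude and width of the spinal
#'   evoked potential (negative deflection, deepest trough at
#'   `motoneuron_to_muscle_ms`).
#' @param cortical_ep_uV,cortical_ep_width_ms amplitude and width of the
#'   cortical evoked potential from muscle stimulation (negative deflection,
#'   extremum at `muscle_to_cortex_afferent_ms`).
#' @param ep_noise_cv trial-to-trial CV of evoked-potential amplitudes.
#' @param lfp_baseline_sd_uV SD of LFP channel background noise (uV).
#' @param cortex_threshold_uA,muscle_threshold_mA ground-truth motor
#'   thresholds (minimal intensity giving a response more than 50% of the
#'   time); defaults are the mean thresholds across the experiments (790 uA
#'   cortical, 1.8 mA muscle).
#' @param threshold_slope relative width of the stochastic recruitment curve
#'   around threshold (logistic scale as a fraction of threshold).
#' @param plasticity_rule `"additive"` (default) or `"multiplicative"`
#'   per-pair gain update in [apply_pas()].
#' @param cortical_depression_per_pulse optional non-negative gain decrement of
#'   `g_cortical` per cortical stimulation pulse, emulating an LTD-like trend
#'   of slow repetitive cortical stimulation; 0 (off) by default so the null
#'   world is exactly null.
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(g_spinal = 1, g_cortical = 1,
                        behavior_state = c("rest", "low_contraction",
                                           "strong_contraction"),
                        latencies = conduction_latencies(),
                        mep_noise_cv = c(rest = 0.5, low_contraction = 0.25,
                                         strong_contraction = 0.4),
                        emg_baseline_sd_uV = 10,
                        rng_seed = 1L,
                        rate_hz = 5000,
                        lfp_rate_hz = 1000,
                        behavior_amp = c(rest = 1, low_contraction = 2,
                                         strong_contraction = 12),
                        mep_scale_uV = 200,
                        mep_duration_ms = 8,
                        spinal_ep_uV = 80, spinal_ep_width_ms = 4,
                        cortical_ep_uV = 50, cortical_ep_width_ms = 8,
                        ep_noise_cv = 0.3,
                        lfp_baseline_sd_uV = 20,
                        cortex_threshold_uA = 790,
                        muscle_threshold_mA = 1.8,
                        threshold_slope = 0.05,
                        plasticity_rule = c("additive", "multiplicative"),
                        cortical_depression_per_pulse = 0) {
  behavior_state <- match.arg(behavior_state)
  plasticity_rule <- match.arg(plasticity_rule)
  stopifnot(inherits(latencies, "conduction_latencies"),
            g_spinal > 0, g_cortical > 0,
            emg_baseline_sd_uV >= 0, lfp_baseline_sd_uV >= 0,
            rate_hz > 0, lfp_rate_hz > 0,
            mep_scale_uV >= 0, mep_duration_ms > 0,
            ep_noise_cv >= 0, cortical_depression_per_pulse >= 0,
            cortex_threshold_uA > 0, muscle_threshold_mA > 0,
            threshold_slope > 0)
  states <- c("rest", "low_contraction", "strong_contraction")
  if (!all(states %in% names(mep_noise_cv)) || any(mep_noise_cv < 0))
    stop("mep_noise_cv must be a non-negative vector named for all behavior states")
  if (mep_noise_cv[["low_contraction"]] > mep_noise_cv[["rest"]])
    stop("mep_noise_cv under low_contraction must not exceed rest ",
         "(closed-loop probing must reduce MEP variability)")
  if (!all(states %in% names(behavior_amp)) || any(behavior_amp < 0))
    stop("behavior_amp must be a non-negative vector named for all behavior states")
  structure(list(
    g_spinal = g_spinal, g_cortical = g_cortical,
    behavior_state = behavior_state, latencies = latencies,
    mep_noise_cv = mep_noise_cv, emg_baseline_sd_uV = emg_baseline_sd_uV,
    rng_seed = as.integer(rng_seed), rate_hz = rate_hz,
    lfp_rate_hz = lfp_rate_hz, behavior_amp = behavior_amp,
    mep_scale_uV = mep_scale_uV, mep_duration_ms = mep_duration_ms,
    spinal_ep_uV = spinal_ep_uV, spinal_ep_width_ms = spinal_ep_width_ms,
    cortical_ep_uV = cortical_ep_uV, cortical_ep_width_ms = cortical_ep_width_ms,
    ep_noise_cv = ep_noise_cv, lfp_baseline_sd_uV = lfp_baseline_sd_uV,
    cortex_threshold_uA = cortex_threshold_uA,
    muscle_threshold_mA = muscle_threshold_mA,
    threshold_slope = threshold_slope,
    plasticity_rule = plasticity_rule,
    cortical_depression_per_pulse = cortical_depression_per_pulse,
    pas_log = NULL
  ), class = "plant_state")
}

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf("plant_state: g_spinal = %.4f, g_cortical = %.4f (%s)\n",
              x$g_spinal, x$g_cortical, x$behavior_state))
  cat(sprintf("  EMG %g Hz, baseline SD %g uV; LFP %g Hz\n",
              x$rate_hz, x$emg_baseline_sd_uV, x$lfp_rate_hz))
  if (!is.null(x$pas_log))
    cat(sprintf("  last PAS: %d pairs at %g Hz (%g s), condition '%s'\n",
                x$pas_log$n_pairs, x$pas_log$rate_hz, x$pas_log$duration_s,
                x$pas_log$condition_label))
  invisible(x)
}

#' Behavior schedule helpers
#'
#' A behavior schedule is a data frame with columns `time_s` (strictly
#' increasing onset times) and `behavior_state`; each state holds from its
#' onset until the next entry. `behavior_schedule()` validates and normalizes
#' such a table; `random_behavior_schedule()` draws a realistic free-behavior
#' schedule in which rest alternates with contraction bursts
#' (walking/grooming/exploring), most of them low-level.
#'
#' @param time_s onset times (s), strictly increasing, starting within the
#'   trace.
#' @param behavior_state states, one per onset.
#' @return a data frame of class `behavior_schedule`.
#' @export
behavior_schedule <- function(time_s, behavior_state) {
  stopifnot(length(time_s) == length(behavior_state), length(time_s) >= 1L)
  if (any(diff(time_s) <= 0)) stop("schedule times must be strictly increasing")
  ok <- behavior_state %in% c("rest", "low_contraction", "strong_contraction")
  if (!all(ok)) stop("unknown behavior state(s): ",
                     paste(unique(behavior_state[!ok]), collapse = ", "))
  structure(data.frame(time_s = time_s, behavior_state = behavior_state,
                       stringsAsFactors = FALSE),
            class = c("behavior_schedule", "data.frame"))
}

#' @rdname behavior_schedule
#' @param duration_s total duration covered (s).
#' @param gap_range_s range of rest-gap durations between bursts (s).
#' @param burst_range_s range of contraction-burst durations (s).
#' @param p_strong probability that a burst is a strong contraction.
#' @export
random_behavior_schedule <- function(duration_s, gap_range_s = c(1.5, 4),
                                     burst_range_s = c(0.8, 2),
                                     p_strong = 0.15) {
  stopifnot(duration_s > 0)
  times <- 0
  states <- "rest"
  t <- 0
  while (t < duration_s) {
    t <- t + stats::runif(1, gap_range_s[1], gap_range_s[2])
    if (t >= duration_s) break
    st <- if (stats::runif(1) < p_strong) "strong_contraction" else "low_contraction"
    times <- c(times, t); states <- c(states, st)
    t <- t + stats::runif(1, burst_range_s[1], burst_range_s[2])
    if (t >= duration_s) break
    times <- c(times, t); states <- c(states, "rest")
  }
  behavior_schedule(times, states)
}

# behavior state in effect at each query time
behavior_at <- function(schedule, t_s) {
  idx <- findInterval(t_s, schedule$time_s)
  idx[idx < 1L] <- 1L
  schedule$behavior_state[idx]
}

#' Simulate continuous EMG during free behavior
#'
#' Generates a uniformly sampled EMG trace whose instantaneous amplitude is
#' set by the behavior schedule: the resting signal has SD
#' `emg_baseline_sd_uV`, contraction segments are scaled by the state
#' amplitude multipliers. The carrier is crest-limited white noise
#' (see [plant_state()]), so segment-wise rectified means are proportional to
#' the configured state amplitudes.
#'
#' @param state a [plant_state()].
#' @param duration_s trace duration (s), > 0.
#' @param schedule a [behavior_schedule()]; onset times must lie within
#'   `[0, duration_s)`. Defaults to constant `state$behavior_state`.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#'   Defaults to the plant's `rng_seed`, making output reproducible.
#' @return an [emg_trace()] with `t0_s = 0`.
#' @export
simulate_emg <- function(state, duration_s,
                         schedule = behavior_schedule(0, state$behavior_state),
                         seed = state$rng_seed) {
  stopifnot(inherits(state, "plant_state"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (!inherits(schedule, "behavior_schedule"))
    schedule <- behavior_schedule(schedule[[1]], schedule[[2]])
  if (any(schedule$time_s < 0) || any(schedule$time_s >= duration_s))
    stop("schedule times must lie within [0, duration_s)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * state$rate_hz))
  tt <- (seq_len(n) - 1L) / state$rate_hz
  amp <- state$emg_baseline_sd_uV *
    unname(state$behavior_amp[behavior_at(schedule, tt)])
  samples <- amp * stats::runif(n, -sqrt(3), sqrt(3))
  emg_trace(samples, state$rate_hz, t0_s = 0, channel_label = "ECR")
}

# raised-cosine (Hann) bump of given center/width on a relative-time grid
hann_bump <- function(t_rel_ms, center_ms, width_ms) {
  u <- (t_rel_ms - center_ms) / width_ms
  out <- numeric(length(t_rel_ms))
  in_b <- abs(u) <= 0.5
  out[in_b] <- cos(pi * u[in_b])^2
  out
}

# mean-one lognormal multiplier with coefficient of variation cv
lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate a stimulus-evoked response on a background segment
#'
#' Adds the deterministic evoked waveform for a stimulation event to a
#' background trace segment, with lognormal trial-to-trial amplitude
#' variability.
#'
#' For cortical stimulation (`site = "cortex"`) the response is an MEP on the
#' muscle channel: a biphasic (single-period sine) waveform whose onset is at
#' `cortical_stim_to_mep_onset_ms` and whose amplitude scales with
#' `g_spinal * g_cortical`; its single-trial CV is the plant's `mep_noise_cv`
#' for the behavior state in effect.
#'
#' For muscle stimulation (`site = "muscle"`) the response is an evoked
#' potential on the requested recording channel: on the spinal channel a
#' negative deflection with its deepest trough at `motoneuron_to_muscle_ms`
#' (antidromic volley); on the cortical LFP channel a negative deflection with
#' its extremum at `muscle_to_cortex_afferent_ms` (afferent volley).
#'
#' @param state a [plant_state()].
#' @param event a [stimulus_event()].
#' @param background an [emg_trace()] covering at least
#'   `[time_s - pre_ms, time_s + post_ms]` around the event; required.
#' @param channel for `site = "muscle"`, which recording channel to return:
#'   `"spinal"` or `"cortical"`. Ignored for cortical stimulation.
#' @param pre_ms,post_ms peri-stimulus segment extent (ms).
#' @param behavior behavior state at stimulation time (sets the MEP CV);
#'   defaults to the plant's state.
#' @param seed optional seed; `NULL` continues the current stream.
#' @return an [emg_trace()] of the peri-stimulus segment
#'   (`t0_s = time_s - pre_ms/1000`).
#' @export
simulate_evoked_response <- function(state, event, background,
                                     channel = c("spinal", "cortical"),
                                     pre_ms = 50, post_ms = 100,
                                     behavior = state$behavior_state,
                                     seed = NULL) {
  stopifnot(inherits(state, "plant_state"), inherits(event, "stimulus_event"))
  if (missing(background) || is.null(background) ||
      !inherits(background, "emg_trace"))
    stop("a background trace segment covering the peri-stimulus window is required")
  from <- event$time_s - pre_ms / 1000
  to <- event$time_s + post_ms / 1000
  if (background$t0_s > from + 1e-12 ||
      background$t0_s + trace_duration(background) < to - 1e-12)
    stop("background segment does not cover the peri-stimulus window")
  if (!is.null(seed)) set.seed(seed)
  seg <- trace_window(background, from, to)
  t_rel_ms <- (trace_times(seg) - event$time_s) * 1000
  lat <- state$latencies
  if (event$site == "cortex") {
    a <- state$mep_scale_uV * state$g_spinal * state$g_cortical *
      lognorm_mult(1, state$mep_noise_cv[[behavior]])
    onset <- lat$cortical_stim_to_mep_onset_ms
    u <- (t_rel_ms - onset) / state$mep_duration_ms
    w <- numeric(length(u))
    in_b <- u > 0 & u < 1
    w[in_b] <- sin(2 * pi * u[in_b])
    seg$samples <- seg$samples + a * w
  } else {
    channel <- match.arg(channel)
    if (channel == "spinal") {
      a <- state$spinal_ep_uV * lognorm_mult(1, state$ep_noise_cv)
      w <- -hann_bump(t_rel_ms, lat$motoneuron_to_muscle_ms,
                      state$spinal_ep_width_ms)
      seg$channel_label <- "C5_LFP"
    } else {
      a <- state$cortical_ep_uV * lognorm_mult(1, state$ep_noise_cv)
      w <- -hann_bump(t_rel_ms, lat$muscle_to_cortex_afferent_ms,
                      state$cortical_ep_width_ms)
      seg$channel_label <- "M1_LFP"
    }
    seg$samples <- seg$samples + a * w
  }
  seg
}

#' Apply a PAS intervention to the plant
#'
#' Updates the ground-truth spinal and cortical gains by applying the STDP
#' rule once per stimulus pair at the condition's derived spinal and cortical
#' timing offsets. Control conditions (single-site or no stimulation) leave
#' the gains unchanged, except that conditions delivering cortical pulses
#' (paired and cortex-only) are additionally subject to the optional
#' per-pulse cortical depression term (default 0).
#'
#' @param state a [plant_state()].
#' @param condition an [isi_condition()] (or a row of a condition table).
#' @param n_pairs number of paired stimulations (default 300).
#' @param rate_hz pairing rate (Hz, default 0.5); intervention duration is
#'   `n_pairs / rate_hz` seconds (~10 min at the defaults).
#' @param window an [stdp_window()].
#' @return the updated `plant_state`; its `pas_log` records the intervention
#'   bookkeeping (pairs, rate, duration, condition label).
#' @export
apply_pas <- function(state, condition, n_pairs = 300, rate_hz = 0.5,
                      window = stdp_window()) {
  stopifnot(inherits(state, "plant_state"), inherits(window, "stdp_window"),
            n_pairs >= 0, rate_hz > 0)
  kind <- condition$kind
  if (is.null(kind) || !kind %in% c("paired", "cortex_only", "muscle_only", "no_stim"))
    stop("condition must have a valid kind")
  g_s <- state$g_spinal
  g_c <- state$g_cortical
  if (kind == "paired") {
    if (is.null(condition$spinal_offset_ms) || is.null(condition$cortical_offset_ms) ||
        is.na(condition$spinal_offset_ms) || is.na(condition$cortical_offset_ms))
      stop("paired condition lacks derived spinal/cortical offsets")
    d_s <- stdp_delta(condition$spinal_offset_ms, window)
    d_c <- stdp_delta(condition$cortical_offset_ms, window)
    if (state$plasticity_rule == "additive") {
      g_s <- g_s + n_pairs * d_s
      g_c <- g_c + n_pairs * d_c
    } else {
      g_s <- g_s * (1 + d_s)^n_pairs
      g_c <- g_c * (1 + d_c)^n_pairs
    }
  }
  if (kind %in% c("paired", "cortex_only"))
    g_c <- g_c - n_pairs * state$cortical_depression_per_pulse
  state$g_spinal <- max(g_s, 1e-9)
  state$g_cortical <- max(g_c, 1e-9)
  state$pas_log <- list(
    n_pairs = n_pairs, rate_hz = rate_hz, duration_s = n_pairs / rate_hz,
    condition_label = if (!is.null(condition$label)) condition$label else kind)
  state
}
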