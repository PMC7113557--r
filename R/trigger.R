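#' Closed-loop trigger configuration
#'
#' Parameters of the EMG-controlled cortical stimulation probe. A cortical
#' stimulus is delivered when the EMG peak envelope has remained between
#' `baseline_mean + lower_sd_mult * baseline_sd` and
#' `baseline_mean + upper_sd_mult * baseline_sd` continuously for at least
#' `sustain_ms`, entered that window on a rising phase, and at least
#' `refractory_s` has elapsed since the previous stimulus. A probe ends when
#' `max_stims` stimulations have been delivered or `max_probe_s` has elapsed,
#' whichever comes first.
#'
#' @param baseline_mean_uV mean of the rectified EMG over a 2 s fully relaxed
#'   window (uV); see [compute_baseline()].
#' @param baseline_sd_uV SD of the same rectified window (uV).
#' @param lower_sd_mult,upper_sd_mult window bounds in baseline SDs above the
#'   mean (defaults 2 and 12); the window is two-sided, so envelopes above the
#'   upper bound (strong contractions) do not trigger.
#' @param sustain_ms required continuous in-window residence before a trigger
#'   (ms, default 50); brief dropouts reset the clock.
#' @param refractory_s minimum time between stimulations (s, default 1).
#' @param maxima_window_samples trailing window (in samples) used to thin
#'   local maxima in [compute_envelope()] (default 32).
#' @param max_stims stimulation quota per probe (default 30).
#' @param max_probe_s probe time limit (s, default 300, i.e. 5 min).
#' @return an object of class `trigger_config`.
#' @export
trigger_config <- function(baseline_mean_uV, baseline_sd_uV,
                           lower_sd_mult = 2, upper_sd_mult = 12,
                           sustain_ms = 50, refractory_s = 1,
                           maxima_window_samples = 32,
                           max_stims = 30, max_probe_s = 300) {
  stopifnot(baseline_mean_uV >= 0, baseline_sd_uV >= 0,
            lower_sd_mult > 0, upper_sd_mult > lower_sd_mult,
            sustain_ms > 0, refractory_s > 0,
            maxima_window_samples >= 1, max_stims > 0, max_probe_s > 0)
  structure(list(baseline_mean_uV = baseline_mean_uV,
                 baseline_sd_uV = baseline_sd_uV,
                 lower_sd_mult = lower_sd_mult, upper_sd_mult = upper_sd_mult,
                 sustain_ms = sustain_ms, refractory_s = refractory_s,
                 maxima_window_samples = as.integer(maxima_window_samples),
                 max_stims = as.integer(max_stims), max_probe_s = max_probe_s),
            class = "trigger_config")
}

#' @export
print.trigger_config <- function(x, ...) {
  cat(sprintf(
    "trigger_config: window [mean + %g SD, mean + %g SD] = [%.2f, %.2f] uV\n",
    x$lower_sd_mult, x$upper_sd_mult,
    x$baseline_mean_uV + x$lower_sd_mult * x$baseline_sd_uV,
    x$baseline_mean_uV + x$upper_sd_mult * x$baseline_sd_uV))
  cat(sprintf("  sustain %g ms, refractory %g s, quota %d stims or %g s\n",
              x$sustain_ms, x$refractory_s, x$max_stims, x$max_probe_s))
  invisible(x)
}

#' Baseline rectified-EMG statistics
#'
#' Mean and SD of the rectified signal over the first `window_s` seconds of a
#' fully relaxed trace; these define the closed-loop trigger window. In the
#' experiment this calibration is performed per rat prior to data collection
#' (and per session as needed), never within a session.
#'
#' @param trace an [emg_trace()] recorded at rest, covering at least
#'   `window_s`.
#' @param window_s calibration window (s, default 2).
#' @return named numeric vector `c(mean = , sd = )` in uV.
#' @export
compute_baseline <- function(trace, window_s = 2) {
  stopifnot(inherits(trace, "emg_trace"), window_s > 0)
  n <- as.integer(round(window_s * trace$rate_hz))
  if (length(trace$samples) < n)
    stop("trace shorter than the baseline window")
  r <- abs(trace$samples[seq_len(n)])
  c(mean = mean(r), sd = stats::sd(r))
}

# trailing running max over windows of k samples (block prefix/suffix maxima)
runmax_trailing <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  if (n <= k) return(cummax(x))
  nb <- ceiling(n / k)
  xp <- c(x, rep(-Inf, nb * k - n))
  m <- matrix(xp, nrow = k)
  L <- m
  for (r in 2:k) L[r, ] <- pmax(L[r - 1L, ], m[r, ])
  R <- m
  for (r in (k - 1L):1L) R[r, ] <- pmax(R[r + 1L, ], m[r, ])
  Lv <- as.vector(L)
  Rv <- as.vector(R)
  out <- numeric(n)
  head_idx <- seq_len(k - 1L)
  out[head_idx] <- cummax(x[head_idx])
  i <- k:n
  out[i] <- pmax(Rv[i - k + 1L], Lv[i])
  out
}

#' Upper peak envelope of a trace
#'
#' Computes the real-time activity estimate used for closed-loop triggering:
#' the trace is rectified, local maxima are located and thinned so that each
#' retained maximum is the largest rectified value within the trailing window
#' of `maxima_window_samples` samples, and the retained maxima are connected
#' by shape-preserving piecewise-cubic (Hermite) interpolation sampled at the
#' input rate. The interpolant is local (each segment depends only on
#' adjacent maxima), so the envelope well before the end of the trace does not
#' depend on distant future samples; before the first and after the last
#' retained maximum the envelope is held constant.
#'
#' If the trace is shorter than one thinning window, or fewer than two maxima
#' are retained (e.g. a constant signal), the rectified input is returned
#' unchanged.
#'
#' @param trace an [emg_trace()].
#' @param maxima_window_samples trailing thinning window in samples
#'   (default 32).
#' @return an [emg_trace()] of the envelope, same rate and origin.
#' @export
compute_envelope <- function(trace, maxima_window_samples = 32) {
  stopifnot(inherits(trace, "emg_trace"), maxima_window_samples >= 1)
  x <- abs(trace$samples)
  n <- length(x)
  if (n == 0L) stop("empty trace")
  out <- trace
  out$channel_label <- paste0(trace$channel_label, "_env")
  if (n < maxima_window_samples) {
    out$samples <- x
    return(out)
  }
  i <- 2:(n - 1L)
  is_max <- c(FALSE, x[i] > x[i - 1L] & x[i] >= x[i + 1L], FALSE)
  tm <- runmax_trailing(x, as.integer(maxima_window_samples))
  keep <- which(is_max & x >= tm)
  if (length(keep) < 2L) {
    out$samples <- x
    return(out)
  }
  f <- stats::splinefun(keep, x[keep], method = "monoH.FC")
  env <- f(seq_len(n))
  env[seq_len(keep[1L])] <- x[keep[1L]]
  last <- keep[length(keep)]
  if (last < n) env[(last + 1L):n] <- x[last]
  out$samples <- pmax(env, 0)
  out
}

#' Detect closed-loop stimulation triggers on an envelope
#'
#' Scans the envelope and emits a stimulation trigger at the first instant at
#' which (i) the envelope has remained continuously inside the trigger window
#' for at least `sustain_ms`, (ii) the envelope entered the window on a rising
#' phase (non-negative first difference at entry), and (iii) at least
#' `refractory_s` has elapsed since the previous trigger. Detection stops when
#' `max_stims` triggers have been emitted or `max_probe_s` has elapsed since
#' `phase_start_s`, and the termination reason is recorded.
#'
#' @param envelope an [emg_trace()] envelope (see [compute_envelope()]).
#' @param config a [trigger_config()].
#' @param phase_start_s probe start time (s); defaults to the envelope origin.
#' @return an object of class `trigger_log` with elements `trigger_times_s`,
#'   `envelope`, `termination_reason` (`"stim_quota"` or `"time_limit"`) and
#'   the `config` used.
#' @export
detect_triggers <- function(envelope, config,
                            phase_start_s = envelope$t0_s) {
  stopifnot(inherits(envelope, "emg_trace"), inherits(config, "trigger_config"))
  rate <- envelope$rate_hz
  tt <- trace_times(envelope)
  scan <- which(tt >= phase_start_s - 1e-12 &
                tt <= phase_start_s + config$max_probe_s + 1e-12)
  trig_idx <- integer(0)
  reason <- "time_limit"
  if (length(scan)) {
    env <- envelope$samples
    lo <- config$baseline_mean_uV + config$lower_sd_mult * config$baseline_sd_uV
    hi <- config$baseline_mean_uV + config$upper_sd_mult * config$baseline_sd_uV
    sus_n <- as.integer(ceiling(config$sustain_ms / 1000 * rate - 1e-9))
    ref_n <- as.integer(ceiling(config$refractory_s * rate - 1e-9))
    in_win <- env[scan] >= lo & env[scan] <= hi
    r <- rle(in_win)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    last_trig <- -.Machine$integer.max / 2
    for (j in which(r$values)) {
      e <- scan[starts[j]]
      f <- scan[ends[j]]
      # rising-phase test at window entry (first sample has no defined slope)
      if (e <= 1L || env[e] < env[e - 1L]) next
      i0 <- as.integer(max(e + sus_n, last_trig + ref_n))
      while (i0 <= f && length(trig_idx) < config$max_stims) {
        trig_idx <- c(trig_idx, i0)
        last_trig <- i0
        i0 <- i0 + ref_n
      }
      if (length(trig_idx) >= config$max_stims) {
        reason <- "stim_quota"
        break
      }
    }
  }
  structure(list(trigger_times_s = tt[trig_idx],
                 trigger_idx = trig_idx,
                 envelope = envelope,
                 termination_reason = reason,
                 config = config),
            class = "trigger_log")
}

#' @export
print.trigger_log <- function(x, ...) {
  cat(sprintf("trigger_log: %d triggers, terminated by %s\n",
              length(x$trigger_times_s), x$termination_reason))
  if (length(x$trigger_times_s) > 1L)
    cat(sprintf("  min inter-trigger interval: %.3f s\n",
                min(diff(x$trigger_times_s))))
  invisible(x)
}

#' Calibrate a trigger configuration from a resting plant
#'
#' Simulates a relaxed calibration recording from the plant, computes the
#' baseline rectified-EMG statistics and returns a [trigger_config()] built on
#' them (remaining parameters at their defaults unless overridden).
#'
#' @param state a [plant_state()].
#' @param window_s baseline window (s, default 2).
#' @param seed seed for the calibration recording (default derived from the
#'   plant seed).
#' @param ... further arguments passed to [trigger_config()].
#' @return a [trigger_config()].
#' @export
calibrate_trigger_config <- function(state, window_s = 2,
                                     seed = state$rng_seed, ...) {
  rest <- state
  rest$behavior_state <- "rest"
  tr <- simulate_emg(rest, window_s,
                     schedule = behavior_schedule(0, "rest"), seed = seed)
  b <- compute_baseline(tr, window_s)
  trigger_config(baseline_mean_uV = b[["mean"]], baseline_sd_uV = b[["sd"]], ...)
}

#' Run one closed-loop excitability probe
#'
#' Simulates free-behavior EMG from the plant, computes the peak envelope,
#' detects EMG-contingent triggers, and delivers a cortical stimulus at each
#' trigger, collecting one peri-stimulus [mep_trial()] per stimulation. The
#' number of trials equals the number of triggers.
#'
#' @param state a [plant_state()].
#' @param config a [trigger_config()]; calibrated from the plant if `NULL`.
#' @param schedule a [behavior_schedule()]; a random free-behavior schedule is
#'   drawn if `NULL`.
#' @param stim_amplitude_uA cortical stimulation amplitude (bookkeeping;
#'   default 1.25 x the plant's cortical motor threshold).
#' @param seed seed for the probe (default the plant seed).
#' @return a list with elements `trials` (list of [mep_trial()]) and
#'   `log` (a `trigger_log`).
#' @export
run_probe <- function(state, config = NULL, schedule = NULL,
                      stim_amplitude_uA = 1.25 * state$cortex_threshold_uA,
                      seed = state$rng_seed) {
  stopifnot(inherits(state, "plant_state"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config)) config <- calibrate_trigger_config(state, seed = NULL)
  dur <- config$max_probe_s + 0.2
  if (is.null(schedule)) schedule <- random_behavior_schedule(dur)
  trace <- simulate_emg(state, dur, schedule = schedule, seed = NULL)
  env <- compute_envelope(trace, config$maxima_window_samples)
  log <- detect_triggers(env, config, phase_start_s = 0)
  trials <- lapply(seq_along(log$trigger_times_s), function(k) {
    t_k <- log$trigger_times_s[k]
    ev <- stimulus_event(t_k, site = "cortex", amplitude = stim_amplitude_uA,
                         phase = "probe")
    seg <- simulate_evoked_response(state, ev, trace,
                                    behavior = behavior_at(schedule, t_k),
                                    seed = NULL)
    mep_trial(seg, ev,
              background_envelope_uV = env$samples[log$trigger_idx[k]])
  })
  list(trials = trials, log = log)
}
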