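# shared fixtures and independent reference implementations

# deterministic alternating rest / low-contraction schedule
burst_schedule <- function(duration_s, period_s = 2) {
  onsets <- seq(0, duration_s - period_s / 2, by = period_s)
  behavior_schedule(onsets,
                    rep(c("rest", "low_contraction"), length.out = length(onsets)))
}

# brute-force trigger reference: evaluates the three conditions at every sample
brute_force_triggers <- function(env, cfg, phase_start_s = env$t0_s) {
  tt <- trace_times(env)
  x <- env$samples
  rate <- env$rate_hz
  lo <- cfg$baseline_mean_uV + cfg$lower_sd_mult * cfg$baseline_sd_uV
  hi <- cfg$baseline_mean_uV + cfg$upper_sd_mult * cfg$baseline_sd_uV
  sus_n <- ceiling(cfg$sustain_ms / 1000 * rate - 1e-9)
  ref_n <- ceiling(cfg$refractory_s * rate - 1e-9)
  in_win <- x >= lo & x <= hi
  trig <- integer(0)
  last <- -Inf
  for (i in seq_along(x)) {
    if (tt[i] < phase_start_s - 1e-12 ||
        tt[i] > phase_start_s + cfg$max_probe_s + 1e-12) next
    if (length(trig) >= cfg$max_stims) break
    if (!in_win[i]) next
    e <- i
    while (e > 1L && in_win[e - 1L]) e <- e - 1L
    if (e <= 1L || x[e] < x[e - 1L]) next     # rising phase at entry
    if ((i - e) < sus_n) next                 # sustained residence
    if ((i - last) < ref_n) next              # refractory
    trig <- c(trig, i)
    last <- i
  }
  list(idx = trig,
       reason = if (length(trig) >= cfg$max_stims) "stim_quota" else "time_limit")
}

# synthetic peri-stimulus trial from a raw sample vector (stim mid-segment)
make_trial <- function(y, rate = 5000, pre_s = 0.05, status = "kept") {
  seg <- emg_trace(y, rate, t0_s = 0)
  mep_trial(seg, stimulus_event(pre_s, "cortex", amplitude = 988),
            screen_status = status)
}

# records table with directly constructed pre/post probe measures
make_records <- function(subject, day, pre, post,
                         condition = "ISI+6", cortex_uA = 987.5,
                         muscle_mA = 2.7, flagged = FALSE) {
  ratios <- post / mean(pre)
  rec <- data.frame(subject = subject, condition = condition, kind = "paired",
                    day = day,
                    pre1 = pre[1], pre2 = pre[2], pre3 = pre[3],
                    post1 = post[1], post2 = post[2], post3 = post[3],
                    ratio1 = ratios[1], ratio2 = ratios[2], ratio3 = ratios[3],
                    cortex_uA = cortex_uA, muscle_mA = muscle_mA,
                    flagged = flagged, stringsAsFactors = FALSE)
  class(rec) <- c("session_records", "data.frame")
  rec
}
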