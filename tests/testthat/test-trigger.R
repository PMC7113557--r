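test_that("compute_baseline returns rectified mean and SD", {
  const <- emg_trace(rep(-3, 10000), 5000)
  b <- compute_baseline(const)
  expect_equal(unname(b["mean"]), 3)
  expect_equal(unname(b["sd"]), 0)
  zeros <- emg_trace(numeric(10000), 5000)
  expect_equal(unname(compute_baseline(zeros)), c(0, 0))
  set.seed(1)
  g <- emg_trace(rnorm(10000, sd = 4), 5000)
  b <- compute_baseline(g)
  expect_equal(unname(b["mean"]), 4 * sqrt(2 / pi), tolerance = 0.05)
  expect_equal(unname(b["sd"]), 4 * sqrt(1 - 2 / pi), tolerance = 0.05)
  expect_error(compute_baseline(emg_trace(numeric(100), 5000)), "shorter")
})

test_that("compute_envelope tracks flat signals and sinusoid peaks", {
  dc <- emg_trace(rep(2.5, 1000), 5000)
  expect_equal(compute_envelope(dc)$samples, dc$samples)   # fallback: no maxima
  # rectified sinusoid with period much shorter than the window
  t <- seq(0, 0.5, by = 1 / 5000)[-1]
  s <- emg_trace(abs(3 * sin(2 * pi * 250 * t)), 5000)
  env <- compute_envelope(s, 32)
  steady <- env$samples[500:2000]
  expect_true(all(abs(steady - 3) / 3 < 0.05))
  # envelope equals the rectified signal at retained maxima, never below
  x <- abs(s$samples)
  tm <- pasrat:::runmax_trailing(x, 32)
  i <- 2:(length(x) - 1)
  keep <- which(c(FALSE, x[i] > x[i - 1] & x[i] >= x[i + 1], FALSE) & x >= tm)
  expect_true(all(env$samples[keep] >= x[keep] - 1e-9))
  # short input falls back to the rectified trace
  short <- emg_trace(rnorm(10), 5000)
  expect_equal(compute_envelope(short, 32)$samples, abs(short$samples))
})

test_that("trailing running max matches a naive reference", {
  set.seed(2)
  x <- rnorm(500)
  for (k in c(1, 7, 32)) {
    ref <- sapply(seq_along(x), function(i) max(x[max(1, i - k + 1):i]))
    expect_equal(pasrat:::runmax_trailing(x, k), ref)
  }
})

test_that("sub-threshold envelopes yield no triggers and a time-limit exit", {
  cfg <- trigger_config(baseline_mean_uV = 8, baseline_sd_uV = 5,
                        max_probe_s = 10)
  env <- emg_trace(rep(10, 20000), 2000)   # below mean + 2 SD = 18
  log <- detect_triggers(env, cfg)
  expect_length(log$trigger_times_s, 0)
  expect_equal(log$termination_reason, "time_limit")
})

test_that("abundant sustained contractions reach the 30-stimulation quota", {
  st <- plant_state(rng_seed = 13L)
  cfg <- calibrate_trigger_config(st, seed = 130)
  tr <- simulate_emg(st, cfg$max_probe_s + 0.2, burst_schedule(cfg$max_probe_s),
                     seed = 131)
  env <- compute_envelope(tr, cfg$maxima_window_samples)
  log <- detect_triggers(env, cfg)
  expect_length(log$trigger_times_s, 30)
  expect_equal(log$termination_reason, "stim_quota")
  expect_true(min(diff(log$trigger_times_s)) >= cfg$refractory_s)
})

test_that("successive triggers always respect the 1 s refractory period", {
  # permanently in-window envelope after a rising entry
  st <- plant_state(rng_seed = 17L)
  cfg <- calibrate_trigger_config(st, seed = 170)
  sched <- behavior_schedule(c(0, 1), c("rest", "low_contraction"))
  tr <- simulate_emg(st, cfg$max_probe_s + 0.2, sched, seed = 171)
  env <- compute_envelope(tr, cfg$maxima_window_samples)
  log <- detect_triggers(env, cfg)
  expect_gt(length(log$trigger_times_s), 1)
  expect_true(min(diff(log$trigger_times_s)) >= 1)
})

test_that("detect_triggers matches the brute-force per-sample oracle", {
  set.seed(23)
  for (rep in 1:8) {
    rate <- 1000
    n <- 8000
    # random walk envelope wandering in and out of the window
    env <- emg_trace(pmax(abs(cumsum(rnorm(n, 0, 0.6))) + 4, 0), rate)
    cfg <- trigger_config(baseline_mean_uV = 4, baseline_sd_uV = 3,
                          lower_sd_mult = 2, upper_sd_mult = sample(4:12, 1),
                          sustain_ms = sample(c(20, 50), 1),
                          refractory_s = sample(c(0.3, 1), 1),
                          max_stims = sample(c(3, 30), 1), max_probe_s = n / rate)
    got <- detect_triggers(env, cfg)
    ref <- brute_force_triggers(env, cfg)
    expect_equal(got$trigger_idx, ref$idx)
    expect_equal(got$termination_reason, ref$reason)
  }
})

test_that("triggers are causal: truncating after the k-th trigger preserves triggers 1..k", {
  st <- plant_state(rng_seed = 29L)
  cfg <- calibrate_trigger_config(st, seed = 290, max_probe_s = 60)
  tr <- simulate_emg(st, 60.2, burst_schedule(60), seed = 291)
  env <- compute_envelope(tr, cfg$maxima_window_samples)
  log <- detect_triggers(env, cfg)
  expect_gt(length(log$trigger_idx), 3)
  k <- 3L
  # keep a margin of a few maxima windows past trigger k (the local
  # interpolant's lookahead horizon), then recompute the whole pipeline
  cut <- log$trigger_idx[k] + 5L * cfg$maxima_window_samples
  tr2 <- emg_trace(tr$samples[1:cut], tr$rate_hz)
  env2 <- compute_envelope(tr2, cfg$maxima_window_samples)
  log2 <- detect_triggers(env2, cfg)
  expect_equal(log2$trigger_idx[1:k], log$trigger_idx[1:k])
})

test_that("run_probe yields no trials at rest and is seed-deterministic", {
  st <- plant_state(rng_seed = 31L)
  cfg <- calibrate_trigger_config(st, seed = 310, max_probe_s = 30)
  rest_only <- behavior_schedule(0, "rest")
  p <- run_probe(st, cfg, schedule = rest_only, seed = 311)
  expect_length(p$trials, 0)
  expect_equal(p$log$termination_reason, "time_limit")
  p1 <- run_probe(st, cfg, seed = 312)
  p2 <- run_probe(st, cfg, seed = 312)
  expect_identical(length(p1$trials), length(p2$trials))
  expect_identical(p1$log$trigger_times_s, p2$log$trigger_times_s)
  expect_identical(p1$trials[[1]]$segment$samples, p2$trials[[1]]$segment$samples)
})

test_that("probe trials are collected inside the 2-12 SD activity window", {
  st <- plant_state(rng_seed = 37L)
  cfg <- calibrate_trigger_config(st, seed = 370, max_probe_s = 60)
  p <- run_probe(st, cfg, schedule = burst_schedule(60.2), seed = 371)
  expect_gt(length(p$trials), 5)
  expect_equal(length(p$trials), length(p$log$trigger_times_s))
  lo <- cfg$baseline_mean_uV + cfg$lower_sd_mult * cfg$baseline_sd_uV
  hi <- cfg$baseline_mean_uV + cfg$upper_sd_mult * cfg$baseline_sd_uV
  bg <- sapply(p$trials, function(tr) tr$background_envelope_uV)
  expect_true(all(bg >= lo & bg <= hi))
})

test_that("trigger_config validates the window ordering", {
  expect_error(trigger_config(1, 1, lower_sd_mult = 12, upper_sd_mult = 2))
  expect_error(trigger_config(1, 1, refractory_s = 0))
})
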