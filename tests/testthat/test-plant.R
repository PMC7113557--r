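test_that("simulate_emg honors degenerate noise and seed determinism", {
  st0 <- plant_state(emg_baseline_sd_uV = 0)
  tr <- simulate_emg(st0, 1)
  expect_true(all(tr$samples == 0))
  st <- plant_state(rng_seed = 42L)
  a <- simulate_emg(st, 10)
  b <- simulate_emg(st, 10)
  expect_identical(a$samples, b$samples)
  expect_equal(trace_duration(a), 10)
})

test_that("simulate_emg validates schedule and duration", {
  st <- plant_state()
  expect_error(simulate_emg(st, -1), "positive")
  expect_error(behavior_schedule(c(0, 5, 5), rep("rest", 3)), "increasing")
  expect_error(simulate_emg(st, 10, behavior_schedule(c(0, 12), c("rest", "rest"))),
               "within")
})

test_that("contraction segments scale rectified amplitude by the configured state ratio", {
  st <- plant_state(rng_seed = 7L)
  sched <- behavior_schedule(seq(0, 55, by = 5),
                             rep(c("rest", "low_contraction"), 6))
  tr <- simulate_emg(st, 60, sched)
  tt <- trace_times(tr)
  states <- pasrat:::behavior_at(sched, tt)
  m_rest <- mean(abs(tr$samples[states == "rest"]))
  m_low <- mean(abs(tr$samples[states == "low_contraction"]))
  expect_gt(m_low, m_rest)
  ratio_cfg <- st$behavior_amp[["low_contraction"]] / st$behavior_amp[["rest"]]
  expect_equal(m_low / m_rest, ratio_cfg, tolerance = 0.1)
})

test_that("zero gain suppresses the MEP entirely", {
  st <- plant_state(emg_baseline_sd_uV = 5, rng_seed = 3L)
  st$g_spinal <- 1e-12   # effectively zero corticospinal transmission
  bg <- simulate_emg(st, 1)
  ev <- stimulus_event(0.5, "cortex", amplitude = 988)
  seg <- simulate_evoked_response(st, ev, bg, seed = 1)
  base <- pasrat:::trace_window(bg, 0.45, 0.6)
  expect_equal(sum(abs(seg$samples)), sum(abs(base$samples)),
               tolerance = 1e-6)
})

test_that("noise-free MEP onset is at the configured 12 ms latency", {
  st <- plant_state(emg_baseline_sd_uV = 0,
                    mep_noise_cv = c(rest = 0, low_contraction = 0,
                                     strong_contraction = 0))
  bg <- emg_trace(numeric(5000), st$rate_hz)
  ev <- stimulus_event(0.5, "cortex", amplitude = 988)
  trial <- mep_trial(simulate_evoked_response(st, ev, bg), ev)
  expect_equal(detect_mep_onset(list(trial)), 12)
})

test_that("averaged evoked potentials recover the configured latencies", {
  st <- plant_state(rng_seed = 5L)
  set.seed(5)
  n_spinal <- 60
  mk <- function(channel) {
    bg <- emg_trace(st$lfp_baseline_sd_uV * runif(300, -sqrt(3), sqrt(3)),
                    st$lfp_rate_hz)
    ev <- stimulus_event(0.1, "muscle", amplitude = 1.8, phase = "acute")
    simulate_evoked_response(st, ev, bg, channel = channel)
  }
  spinal <- replicate(n_spinal, mk("spinal"), simplify = FALSE)
  expect_equal(evoked_extremum_latency(spinal, rep(0.1, n_spinal), c(0.5, 30)),
               st$latencies$motoneuron_to_muscle_ms)
  cortical <- replicate(n_spinal, mk("cortical"), simplify = FALSE)
  expect_equal(evoked_extremum_latency(cortical, rep(0.1, n_spinal), c(5, 60)),
               st$latencies$muscle_to_cortex_afferent_ms)
  # the spinal and cortical responses are negative-going deflections
  m <- rowMeans(sapply(spinal, function(s) s$samples))
  expect_lt(min(m), -st$spinal_ep_uV / 2)
})

test_that("expected MEP area is monotone in each synaptic gain", {
  st <- plant_state(emg_baseline_sd_uV = 0,
                    mep_noise_cv = c(rest = 0, low_contraction = 0,
                                     strong_contraction = 0))
  bg <- emg_trace(numeric(5000), st$rate_hz)
  ev <- stimulus_event(0.5, "cortex", amplitude = 988)
  area <- function(gs, gc) {
    s <- st; s$g_spinal <- gs; s$g_cortical <- gc
    seg <- simulate_evoked_response(s, ev, bg)
    sum(abs(seg$samples))
  }
  a_ref <- area(1, 1)
  expect_true(all(diff(sapply(c(0.5, 1, 1.5, 2), area, gc = 1)) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 1.5, 2), function(g) area(1, g))) > 0))
  expect_equal(area(2, 1), 2 * a_ref)   # linear in the gain product
})

test_that("MEP variability is lower under low contraction than at rest", {
  st <- plant_state(rng_seed = 9L)
  set.seed(9)
  amp_cv <- function(behavior, n = 400) {
    bg <- emg_trace(numeric(1250), st$rate_hz)
    ev <- stimulus_event(0.08, "cortex", amplitude = 988)
    a <- replicate(n, {
      seg <- simulate_evoked_response(st, ev, bg, behavior = behavior)
      max(seg$samples) - min(seg$samples)
    })
    sd(a) / mean(a)
  }
  expect_lt(amp_cv("low_contraction"), amp_cv("rest"))
})

test_that("plant_state enforces the closed-loop variability rationale", {
  expect_error(plant_state(mep_noise_cv = c(rest = 0.2, low_contraction = 0.5,
                                            strong_contraction = 0.4)),
               "variability")
})

test_that("evoked response requires a covering background segment", {
  st <- plant_state()
  ev <- stimulus_event(0.5, "cortex", amplitude = 988)
  expect_error(simulate_evoked_response(st, ev, NULL), "background")
  short <- emg_trace(numeric(100), st$rate_hz)   # 20 ms, cannot cover
  expect_error(simulate_evoked_response(st, ev, short), "cover")
})

test_that("trace text round-trip preserves samples and metadata", {
  tr <- emg_trace(sin(1:100), 2000, t0_s = 0.5, channel_label = "bicep")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_emg_trace(tr, path)
  tr2 <- read_emg_trace(path)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-12)
  expect_equal(tr2$rate_hz, tr$rate_hz)
  expect_equal(tr2$channel_label, tr$channel_label)
  evs <- list(stimulus_event(1, "cortex", 988, phase = "pas"),
              stimulus_event(3, "muscle", 2.7, phase = "pas"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_events(evs, path2)
  evs2 <- read_stimulus_events(path2)
  expect_equal(evs2[[2]]$site, "muscle")
  expect_equal(evs2[[1]]$time_s, 1)
})
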