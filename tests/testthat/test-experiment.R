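test_that("randomize_design yields per-subject permutations, reproducibly", {
  tab <- build_condition_table()
  des <- randomize_design(9, tab, seed = 3)
  expect_equal(dim(des$order_matrix), c(9L, 15L))
  for (i in 1:9)
    expect_setequal(des$order_matrix[i, ], tab$label)
  des2 <- randomize_design(9, tab, seed = 3)
  expect_identical(des$order_matrix, des2$order_matrix)
  expect_false(identical(des$order_matrix,
                         randomize_design(9, tab, seed = 4)$order_matrix))
  # singleton condition
  one <- randomize_design(4, "only", seed = 1)
  expect_true(all(one$order_matrix == "only"))
})

test_that("a late-added condition is appended for a subset of subjects", {
  des <- randomize_design(6, c("a", "b", "c"), seed = 5)
  des2 <- add_condition(des, "late", subjects = c(1, 3))
  expect_equal(ncol(des2$order_matrix), 4L)
  expect_equal(unname(des2$order_matrix[c(1, 3), 4]), c("late", "late"))
  expect_true(all(is.na(des2$order_matrix[c(2, 4:6), 4])))
  expect_error(add_condition(des, "a"))
})

test_that("session_schedule checks the probe timing pattern", {
  sch <- session_schedule()
  expect_equal(sch$post_probe_times_min, c(2, 17, 32))
  expect_equal(sch$pas_pairs / sch$pas_rate_hz, 600)
  expect_error(session_schedule(post_probe_times_min = c(2, 15, 32)),
               "inconsistent")
})

test_that("the staircase recovers the operational motor threshold", {
  st <- plant_state(rng_seed = 71L)
  thr_c <- estimate_motor_threshold(st, "cortex", seed = 71)
  expect_equal(thr_c, st$cortex_threshold_uA, tolerance = 0.1)
  thr_m <- estimate_motor_threshold(st, "muscle", seed = 72)
  expect_equal(thr_m, st$muscle_threshold_mA, tolerance = 0.1)
})

test_that("a no-stimulation session leaves the plant untouched end to end", {
  st <- plant_state(rng_seed = 73L)
  out <- run_session(st, isi_condition("no_stim"),
                     window = stdp_window(a_plus = 5e-3, a_minus = 5e-3),
                     probe_duration_s = 15, seed = 73)
  expect_equal(out$state$g_spinal, st$g_spinal)
  expect_equal(out$state$g_cortical, st$g_cortical)
  expect_false(out$record$flagged)
  expect_equal(out$record$cortex_uA, 1.25 * st$cortex_threshold_uA)
  expect_equal(out$record$muscle_mA, 1.5 * st$muscle_threshold_mA)
})

test_that("null-world sessions have normalized ratios near 1, LTP sessions above 1", {
  w0 <- stdp_window(0, 0)
  ratios0 <- unlist(lapply(1:6, function(k) {
    st <- plant_state(rng_seed = 200L + k)
    out <- run_session(st, isi_condition("paired", 6, window = w0),
                       window = w0, probe_duration_s = 15, seed = 200 + k)
    unlist(out$record[, c("ratio1", "ratio2", "ratio3")])
  }))
  expect_equal(mean(ratios0), 1, tolerance = 0.08)
  # strong pure-LTP window at spinal offset +5 (ISI +11): net gain ~1.47
  w <- stdp_window(a_plus = 2e-3, a_minus = 0, tau_plus_ms = 20)
  ratios1 <- unlist(lapply(1:3, function(k) {
    st <- plant_state(rng_seed = 300L + k)
    out <- run_session(st, isi_condition("paired", 11, window = w),
                       window = w, probe_duration_s = 15, seed = 300 + k)
    unlist(out$record[, c("ratio1", "ratio2", "ratio3")])
  }))
  expect_gt(mean(ratios1), 1.1)
  expect_gt(mean(ratios1), mean(ratios0))
})

test_that("simulate_experiment (measure fidelity) is centered and tracks ground truth", {
  w0 <- stdp_window(0, 0)
  tab <- build_condition_table(isi_list = c(-15, 6, 9), controls = "no_stim")
  des <- randomize_design(8, tab, seed = 7)
  rec0 <- simulate_experiment(des, tab, w0, seed = 8)
  expect_s3_class(rec0, "session_records")
  expect_equal(nrow(rec0), 32L)
  expect_equal(mean(c(rec0$ratio1, rec0$ratio2, rec0$ratio3)), 1,
               tolerance = 0.05)
  # an LTP world shifts the paired-condition ratios upward
  w <- stdp_window(a_plus = 2e-3, a_minus = 0, tau_plus_ms = 20)
  rec1 <- simulate_experiment(des, tab, w, seed = 8)
  m9 <- with(rec1[rec1$condition == "ISI+9", ],
             mean(c(ratio1, ratio2, ratio3)))
  m_ns <- with(rec1[rec1$condition == "no_stim", ],
               mean(c(ratio1, ratio2, ratio3)))
  expect_gt(m9, 1.2)
  expect_gt(m9, m_ns)
})

test_that("waveform and measure fidelities expose the same record schema", {
  tab <- build_condition_table(isi_list = 6, controls = "no_stim")
  des <- randomize_design(2, tab, seed = 9)
  w0 <- stdp_window(0, 0)
  rec_m <- simulate_experiment(des, tab, w0, seed = 10)
  rec_w <- simulate_experiment(des, tab, w0, fidelity = "waveform",
                               probe_duration_s = 10, seed = 10)
  expect_identical(names(rec_m), names(rec_w))
  expect_equal(nrow(rec_w), 4L)
  expect_true(all(is.finite(rec_w$ratio1)))
})

test_that("normalized ratios are invariant to rescaling a session's measures", {
  rec <- make_records("rat01", 1, pre = c(2, 2.5, 1.8), post = c(2.2, 2.1, 2.6))
  c_scale <- 7.3
  rec2 <- make_records("rat01", 1, pre = c_scale * c(2, 2.5, 1.8),
                       post = c_scale * c(2.2, 2.1, 2.6))
  expect_equal(unlist(rec[, c("ratio1", "ratio2", "ratio3")]),
               unlist(rec2[, c("ratio1", "ratio2", "ratio3")]))
})

test_that("simulate_null_records matches the mixed model's generative structure", {
  rec <- simulate_null_records(6, c("a", "b", "c"), seed = 11)
  expect_equal(nrow(rec), 18L)
  expect_equal(rec$ratio1, rec$post1 / rowMeans(rec[, c("pre1", "pre2", "pre3")]))
  expect_equal(mean(c(rec$ratio1, rec$ratio2, rec$ratio3)), 1, tolerance = 0.1)
})
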