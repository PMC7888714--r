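test_that("breath-train generator honours rate, timing and determinism", {
  sim <- make_train(fr = 120, duration_s = 10)
  expect_equal(nrow(sim$truth), 20L)              # fr x duration
  expect_true(all(abs(sim$truth$ttot_s - 0.5) < 1e-12))
  sim2 <- make_train(fr = 120, duration_s = 10)
  expect_identical(sim$trace$samples, sim2$trace$samples)
  expect_error(make_train(fr = 10, duration_s = 2), "shorter")
})

test_that("generator inverts the tidal-volume equation exactly", {
  sim <- make_train(fr = 150, duration_s = 20, vt_ml = 0.17, amp_cv = 0.08,
                    seed = 5)
  vt_forward <- tidal_volume(sim$truth$p_t, calibration_record(),
                             default_env(), 37)
  expect_equal(vt_forward, sim$truth$v_t_ml, tolerance = 1e-9)
  expect_equal(mean(abs(vt_forward - sim$truth$v_t_ml)), 0, tolerance = 1e-12)
})

test_that("apnea insertion lengthens the local inter-onset gap to (k+1) T", {
  sim <- make_train(fr = 120, duration_s = 60)
  ins <- insert_events(sim$trace, sim$truth,
                       event_plan(apneas = data.frame(time_s = 30,
                                                      missing_cycles = 2)))
  gaps <- diff(ins$truth$onset_s)
  expect_equal(max(gaps), 3 * 0.5, tolerance = 1e-9)   # (k+1) x T_TOT
  expect_equal(sum(gaps > 0.5 + 1e-9), 1L)
  ev <- attr(ins$truth, "events")
  expect_equal(ev$missing_cycles[ev$kind == "SA"], 2)
})

test_that("sigh insertion scales one breath and empty plans are bit-exact", {
  sim <- make_train(fr = 120, duration_s = 60, noise_sd = 0.002, seed = 8)
  ins <- insert_events(sim$trace, sim$truth,
                       event_plan(sighs = data.frame(time_s = 30, fold = 2.5)))
  j <- which(attr(ins$truth, "events")$kind == "sigh")
  sigh_t <- attr(ins$truth, "events")$time_s[j]
  i <- match(sigh_t, ins$truth$onset_s)
  expect_equal(ins$truth$p_t[i] / sim$truth$p_t[i], 2.5, tolerance = 1e-12)

  noop <- insert_events(sim$trace, sim$truth, event_plan())
  expect_identical(noop$trace$samples, sim$trace$samples)
  expect_error(insert_events(sim$trace, sim$truth,
                             event_plan(apneas = data.frame(time_s = 999,
                                                            missing_cycles = 2))),
               "span")
  expect_error(insert_events(sim$trace, sim$truth,
                             event_plan(apneas = data.frame(
                               time_s = c(30, 30.2),
                               missing_cycles = c(2, 2)))),
               "overlap")
})

test_that("gas-trace simulation inverts the calorimetry equation", {
  g0 <- simulate_gas_trace(0, 0.8)
  expect_equal(g0$feo2, g0$fio2)
  expect_equal(g0$feco2, g0$fico2)
  g <- simulate_gas_trace(1.4216, rer = 0.8, fr_e = 300, fio2 = 0.2095,
                          fico2 = 0.0004)
  expect_equal(vo2_lighton(g), 1.4216, tolerance = 1e-9)
  # doubling FR_e halves the O2 depletion at fixed V_O2
  g2 <- simulate_gas_trace(1.4216, rer = 0.8, fr_e = 600, fio2 = 0.2095,
                           fico2 = 0.0004)
  expect_equal(g$fio2 - g$feo2, 2 * (g2$fio2 - g2$feo2), tolerance = 1e-12)
  expect_error(simulate_gas_trace(1e6, 0.8, 300, 0.2095, 0.0004),
               "infeasible")
})

test_that("protocol generator is seed-deterministic with a biphasic response", {
  a <- simulate_protocol_trace("ctrl", seed = 11)
  b <- simulate_protocol_trace("ctrl", seed = 11)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(attr(a$truth, "events"), attr(b$truth, "events"))

  # programmed fR: early hypoxia above baseline, attenuating by late hypoxia
  tr <- a$truth
  ep <- a$epochs
  fr_in <- function(lo, hi) {
    sel <- tr$onset_s >= lo & tr$onset_s < hi
    60 / mean(tr$ttot_s[sel])
  }
  hy <- ep[ep$label == "hypoxia", ]
  base <- fr_in(0, ep$end_s[1])
  early <- fr_in(hy$start_s, hy$start_s + 0.25 * (hy$end_s - hy$start_s))
  late <- fr_in(hy$start_s + 0.5 * (hy$end_s - hy$start_s), hy$end_s)
  expect_gt(early / base, 1.1)
  expect_gt(early, late)
  expect_lt(late / base, 1.15)
})

test_that("noiseless protocol fR trajectory is recovered by detection within 2%", {
  sim <- simulate_protocol_trace(noiseless_preset("ctrl"), seed = 21)
  det <- detect_breaths(sim$trace)
  ep <- sim$epochs
  for (e in seq_len(nrow(ep))) {
    w <- c(ep$start_s[e] + 10, ep$end_s[e] - 10)
    truth_n <- sum(sim$truth$onset_s >= w[1] & sim$truth$onset_s < w[2])
    det_n <- sum(det$onset_s >= w[1] & det$onset_s < w[2])
    expect_equal(det_n, truth_n)
    tm <- timing_metrics(det, w)
    truth_fr <- truth_n * 60 / diff(w)
    expect_equal(tm$fr, truth_fr, tolerance = 0.02)
  }
})

test_that("recovery-minute SA counts follow the preset distributions", {
  set.seed(1)
  x <- draw_recovery_sa_counts(200, 8.2, 5.5)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 8.2), 3 * 5.5 / sqrt(200))
  set.seed(2)
  y <- draw_recovery_sa_counts(2000, 8.2, 5.5)
  expect_lt(abs(stats::sd(y) - 5.5), 0.6)
  # underdispersed preset falls back to Poisson, still truncated at zero
  set.seed(3)
  z <- draw_recovery_sa_counts(500, 0.3, 0.5)
  expect_true(all(z >= 0))
  expect_lt(abs(mean(z) - 0.3), 3 * sqrt(0.3 / 500) + 0.05)
})

test_that("cohort simulation is reproducible and group-structured", {
  a <- simulate_cohort(n_per_group = 2, seed = 5, analyze = FALSE)
  b <- simulate_cohort(n_per_group = 2, seed = 5, analyze = FALSE)
  expect_equal(nrow(a$animals), 6L)
  expect_identical(a$animals, b$animals)
  expect_setequal(unique(a$animals$group), c("ctrl", "ncko_r", "ncko_a"))
  expect_error(simulate_cohort(presets = "mystery", n_per_group = 2),
               "unknown preset")
})

test_that("landmark replicates: identity without jitter, exact affine scaling", {
  tpl <- mouse_skull_template()
  reps <- simulate_landmark_sets(tpl, n_reps = 3, rater_jitter = 0)
  for (r in reps) expect_equal(as.data.frame(r)[, 2:4],
                               as.data.frame(tpl)[, 2:4], tolerance = 0)
  # pure y-scaling shrinks y-extent distances by exactly the factor
  two <- landmark_set(data.frame(name = c("a", "b"), x_mm = c(0, 0),
                                 y_mm = c(0, 10), z_mm = c(0, 0)))
  sc <- simulate_landmark_sets(two, deformation = c(1, 0.9, 1),
                               n_reps = 1, rater_jitter = 0)[[1]]
  expect_equal(interlandmark_distance(sc, "a", "b"), 9, tolerance = 1e-12)
  expect_error(simulate_landmark_sets(tpl, rater_jitter = -1), "non-negative")
})

test_that("rater jitter propagates into the predicted measurement SD", {
  two <- landmark_set(data.frame(name = c("a", "b"), x_mm = c(0, 0),
                                 y_mm = c(0, 10), z_mm = c(0, 0)))
  sigma <- 0.1
  reps <- simulate_landmark_sets(two, rater_jitter = sigma, n_reps = 400,
                                 seed = 9)
  d <- vapply(reps, interlandmark_distance, numeric(1), "a", "b")
  # distance between two isotropically jittered points: SD ~ sigma * sqrt(2)
  expect_equal(stats::sd(d), sigma * sqrt(2), tolerance = 0.12)
})
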