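test_that("apnea scoring applies the pause arithmetic on inter-onset gaps", {
  # fr=120 (T=0.5 s): inter-onset 2.0 s -> pause 1.5 s, 3 missing cycles
  sim <- make_train(fr = 120, duration_s = 60)
  ins <- insert_events(sim$trace, sim$truth,
                       event_plan(apneas = data.frame(time_s = 30,
                                                      pause_s = 1.5)))
  ev <- detect_apneas(detect_breaths(ins$trace))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 1.5, tolerance = 1e-6)
  expect_equal(ev$missing_cycles, 3)

  # inter-onset 1.2 s -> pause 0.7 s: below both gates, no event
  ins2 <- insert_events(sim$trace, sim$truth,
                        event_plan(apneas = data.frame(time_s = 30,
                                                       pause_s = 0.7)))
  expect_equal(nrow(detect_apneas(detect_breaths(ins2$trace))), 0L)

  # perfectly regular train: nothing to score
  expect_equal(nrow(detect_apneas(detect_breaths(sim$trace))), 0L)
})

test_that("tiny tables are flagged as insufficient baseline", {
  sim <- make_train(fr = 60, duration_s = 4)
  tab <- detect_breaths(sim$trace)
  ev <- detect_apneas(tab)
  expect_equal(nrow(ev), 0L)
  expect_true(isTRUE(attr(ev, "insufficient_baseline")))
})

test_that("sigh scoring thresholds at the fold and excludes sighs from the
           baseline median", {
  sim <- make_train(fr = 120, duration_s = 120)
  for (fold in c(1.9, 2.5)) {
    ins <- insert_events(sim$trace, sim$truth,
                         event_plan(sighs = data.frame(time_s = 60,
                                                       fold = fold)))
    n <- nrow(detect_sighs(detect_breaths(ins$trace)))
    expect_equal(n, if (fold >= 2) 1L else 0L)
  }
  # two sighs 5 s apart: the first must not inflate the baseline of the second
  ins2 <- insert_events(sim$trace, sim$truth,
                        event_plan(sighs = data.frame(time_s = c(60, 65),
                                                      fold = c(2.5, 2.1))))
  tab <- detect_breaths(ins2$trace)
  sighs <- detect_sighs(tab)
  expect_equal(nrow(sighs), 2L)
  # oracle: recompute the second sigh's baseline median by hand, excluding
  # the first sigh's breath
  idx <- attr(sighs, "breath_idx")
  vol <- tab$p_t
  j2 <- idx[2]
  prev <- setdiff(which(tab$onset_s < tab$onset_s[j2] &
                          tab$onset_s >= tab$onset_s[j2] - 60), idx[1])
  prev <- utils::tail(prev, 15)
  expect_gte(vol[j2], 2 * stats::median(vol[prev]) - 1e-12)
})

test_that("PSA linkage picks the nearest preceding sigh within 20 s", {
  sim <- make_train(fr = 120, duration_s = 240)
  pl <- event_plan(apneas = data.frame(time_s = 115, missing_cycles = 3),
                   sighs = data.frame(time_s = c(100, 112),
                                      fold = c(2.5, 2.5)))
  ins <- insert_events(sim$trace, sim$truth, pl)
  sc <- score_events(detect_breaths(ins$trace))
  psa <- sc$events[sc$events$kind == "PSA", ]
  expect_equal(nrow(psa), 1L)
  sigh_times <- sc$events$time_s[match(psa$sigh_ref, sc$events$id)]
  expect_equal(sigh_times, 112)

  # outside the window the apnea stays spontaneous
  pl2 <- event_plan(apneas = data.frame(time_s = 121, missing_cycles = 3),
                    sighs = data.frame(time_s = 100, fold = 2.5))
  ins2 <- insert_events(sim$trace, sim$truth, pl2)
  sc2 <- score_events(detect_breaths(ins2$trace))
  expect_equal(sum(sc2$events$kind == "PSA"), 0L)
  expect_equal(sum(sc2$events$kind == "SA"), 1L)
})

test_that("sigh categories count linked apneas and percentages close to 100", {
  sim <- make_train(fr = 120, duration_s = 240)
  pl <- event_plan(apneas = data.frame(time_s = c(105, 110),
                                       missing_cycles = c(2, 2)),
                   sighs = data.frame(time_s = 100, fold = 2.5))
  ins <- insert_events(sim$trace, sim$truth, pl)
  sc <- score_events(detect_breaths(ins$trace))
  expect_equal(sum(sc$events$kind == "PSA"), 2L)
  expect_equal(sc$sigh_categories$n_linked, 2L)
  expect_equal(sc$sigh_categories$category, "ge2")

  ep <- epoch_table("normoxia", 0, 240, 0.21)
  r <- event_rates(sc$events, sc$sigh_categories, ep)
  expect_equal(r$pct_sighs_lt2 + r$pct_sighs_ge2, 100, tolerance = 1e-9)
})

test_that("naive O(n^2) linkage oracle agrees with the implementation", {
  sim <- simulate_protocol_trace(noiseless_preset("ncko_a"), seed = 31)
  sc <- score_events(detect_breaths(sim$trace))
  ap <- sc$events[sc$events$kind %in% c("SA", "PSA"), ]
  sighs <- sc$events[sc$events$kind == "sigh", ]
  link <- naive_psa_link(ap$time_s, sighs$time_s)
  expect_equal(ap$kind == "PSA", !is.na(link))
  expect_equal(ap$sigh_ref[!is.na(link)],
               sighs$id[link[!is.na(link)]])
})

test_that("every apnea is either SA or PSA, and PSA sigh refs precede by <=20 s", {
  for (s in c(2, 17)) {
    sim <- simulate_protocol_trace(noiseless_preset("ncko_a"), seed = s)
    sc <- score_events(detect_breaths(sim$trace))
    ap <- detect_apneas(detect_breaths(sim$trace),
                        sigh_idx = attr(detect_sighs(detect_breaths(sim$trace)),
                                        "breath_idx"))
    expect_equal(sum(sc$events$kind %in% c("SA", "PSA")), nrow(ap))
    psa <- sc$events[sc$events$kind == "PSA", ]
    if (nrow(psa)) {
      st <- sc$events$time_s[match(psa$sigh_ref, sc$events$id)]
      expect_true(all(psa$time_s - st > 0))
      expect_true(all(psa$time_s - st <= 20 + 1e-6))
    }
  }
})

test_that("event rates divide by epoch hours and flag empty sigh sets", {
  ev <- event_table(kind = rep("SA", 3), time_s = c(100, 200, 300),
                    duration_s = rep(1.5, 3), missing_cycles = rep(3, 3))
  cats <- data.frame(sigh_id = integer(), time_s = numeric(),
                     n_linked = integer(), category = character())
  ep <- epoch_table("normoxia", 0, 1800, 0.21)
  r <- event_rates(ev, cats, ep)
  expect_equal(r$sa_per_h, 6)
  expect_true(is.na(r$pct_sighs_ge2))
  expect_equal(r$sighs_per_h, 0)
  expect_error(event_rates(ev, cats,
                           data.frame(label = "normoxia", start_s = 0,
                                      end_s = 0, fio2 = 0.21)),
               "exceed|zero")
})

test_that("first-recovery-minute SA counter uses [start, start + 60)", {
  ep <- protocol_epochs("desk")
  rs <- ep$start_s[ep$label == "recovery"]
  ev <- event_table(kind = c("SA", "SA", "PSA", "SA"),
                    time_s = c(rs + 5, rs + 59.9, rs + 30, rs + 61),
                    duration_s = rep(1.5, 4), missing_cycles = rep(3, 4),
                    sigh_ref = c(NA, NA, 1L, NA))
  expect_equal(first_recovery_minute_sa(ev, ep), 2L)
})
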