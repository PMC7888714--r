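test_that("Student's t matches the textbook example and its symmetries", {
  r <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2879, tolerance = 1e-3)
  expect_equal(r$p, 2 * stats::pt(r$statistic, 4), tolerance = 1e-12)
  swapped <- students_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p, r$p)
  same <- students_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  degen <- students_t(c(1, 1), c(2, 2))
  expect_equal(degen$p, 0)
  expect_true(degen$degenerate)
  expect_error(students_t(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches the sum-of-squares hand oracle and F = t^2", {
  r <- one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(r$statistic, 4)            # SSB/2 / (SSW/3) = 2 / 0.5
  expect_equal(c(r$df1, r$df2), c(2, 3))
  flat <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  set.seed(4)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  expect_equal(one_way_anova(list(a, b))$statistic,
               students_t(a, b)$statistic^2, tolerance = 1e-9)
  expect_equal(one_way_anova(list(a, b))$p, students_t(a, b)$p,
               tolerance = 1e-9)
})

test_that("Holm-Sidak adjustment matches the hand computation and its bounds", {
  expect_equal(holm_sidak(c(0.01, 0.03, 0.04)),
               c(0.029701, 0.059100, 0.059100), tolerance = 1e-6)
  # order-agnostic: same values whatever the input order
  expect_equal(sort(holm_sidak(c(0.04, 0.01, 0.03))),
               sort(holm_sidak(c(0.01, 0.03, 0.04))))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(adj <= pmin(1, p * length(p)) + 1e-12))  # <= Bonferroni
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))                 # rank-monotone
  }
  expect_equal(holm_sidak(numeric()), numeric())
})

test_that("repeated-measures ANOVA detects structure and is location invariant", {
  set.seed(12)
  d <- expand.grid(animal = paste0("a", 1:8),
                   condition = c("normoxia", "hypoxia", "hyperoxia"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$animal %in% paste0("a", 1:4), "ctrl", "ncko_a")
  d$value <- rnorm(nrow(d), sd = 0.3) +
    ifelse(d$group == "ncko_a" & d$condition != "hyperoxia", 3, 0)
  r <- rm_anova_holm_sidak(d)
  expect_setequal(r$anova$effect, c("group", "condition", "group:condition"))
  expect_true(all(r$anova$p >= 0 & r$anova$p <= 1))
  expect_lt(r$anova$p[r$anova$effect == "group:condition"], 0.05)
  expect_true(all(r$posthoc$p_adj >= r$posthoc$p_raw - 1e-12))

  d2 <- d; d2$value <- d2$value + 100
  r2 <- rm_anova_holm_sidak(d2)
  expect_equal(r2$anova$statistic, r$anova$statistic, tolerance = 1e-9)
  expect_equal(r2$anova$p, r$anova$p, tolerance = 1e-9)

  d3 <- d; d3$value <- 7
  r3 <- rm_anova_holm_sidak(d3, posthoc = FALSE)
  expect_true(all(r3$anova$statistic == 0))

  # incomplete animals are dropped with a message, not silently
  d4 <- d[!(d$animal == "a1" & d$condition == "hypoxia"), ]
  expect_message(rm_anova_holm_sidak(d4, posthoc = FALSE), "incomplete")
  expect_error(rm_anova_holm_sidak(d[d$group == "ctrl", ]), "2 groups")
})

test_that("ICC(3,1) matches a variance-component hand computation", {
  # 3 subjects x 2 replicates toy table
  d <- data.frame(animal = rep(c("s1", "s2", "s3"), each = 2),
                  replicate = rep(1:2, 3), name = "m",
                  value = c(10, 11, 20, 19, 30, 32))
  # hand ANOVA: MS_subjects and MS_error after removing the replicate effect
  y <- matrix(d$value, nrow = 3, byrow = TRUE)
  n <- 3; k <- 2
  grand <- mean(y)
  ms_r <- k * sum((rowMeans(y) - grand)^2) / (n - 1)
  ms_c <- n * sum((colMeans(y) - grand)^2) / (k - 1)
  ss_e <- sum((y - outer(rowMeans(y), colMeans(y), "+") + grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc_hand <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  r <- icc_triplicate(d)
  expect_equal(r$icc, icc_hand, tolerance = 1e-9)

  # identical replicates, distinct subjects: perfect reliability
  d2 <- data.frame(animal = rep(c("s1", "s2", "s3"), each = 3),
                   replicate = rep(1:3, 3), name = "m",
                   value = rep(c(1, 2, 3), each = 3))
  expect_equal(icc_triplicate(d2)$icc, 1)

  # replicates that ignore the subject: ICC near zero for many subjects
  set.seed(3)
  d3 <- data.frame(animal = rep(paste0("s", 1:40), each = 3),
                   replicate = rep(1:3, 40), name = "m",
                   value = rnorm(120))
  expect_lt(abs(icc_triplicate(d3)$icc), 0.25)
  expect_error(icc_triplicate(data.frame(animal = "s1", replicate = 1:3,
                                         name = "m", value = 1:3)),
               "2 subjects")
})

test_that("metabolite screen tests every column and finds planted effects", {
  set.seed(7)
  n_met <- 154
  m <- matrix(abs(rnorm(10 * n_met, 50, 5)), nrow = 10,
              dimnames = list(NULL, paste0("met", seq_len(n_met))))
  m[6:10, 17] <- m[6:10, 17] + 50   # ~10 SD shift in one metabolite
  tab <- metabolite_table(m, rep(c("ctrl", "ncko"), each = 5))
  res <- metabolite_screen(tab)
  expect_equal(nrow(res), n_met)
  expect_true("met17" %in% attr(res, "significant"))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  const <- m; const[, 1] <- 42
  resc <- metabolite_screen(metabolite_table(const,
                                             rep(c("a", "b"), each = 5)))
  expect_true(resc$constant[1])
  expect_equal(resc$p[1], 1)
})

test_that("null metabolite tables trigger ~5% of columns across seeds", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    m <- matrix(abs(rnorm(10 * 100, 50, 5)), nrow = 10)
    res <- metabolite_screen(metabolite_table(m, rep(c("a", "b"), each = 5)))
    hits <- hits + sum(res$significant); total <- total + nrow(res)
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("variability metrics recover programmed jitter and scale invariance", {
  reg <- make_train(fr = 150, duration_s = 30)
  v <- variability_metrics(detect_breaths(reg$trace))
  expect_equal(v$cv_ttot, 0, tolerance = 1e-6)

  jit <- make_train(fr = 150, duration_s = 120, amp_cv = 0.10, seed = 6)
  tab <- detect_breaths(jit$trace)
  vj <- variability_metrics(tab)
  expect_equal(vj$cv_vt, 0.10, tolerance = 0.03)
  tab2 <- tab; tab2$p_t <- tab2$p_t * 50
  expect_equal(variability_metrics(tab2)$cv_vt, vj$cv_vt, tolerance = 1e-9)

  few <- breath_table(as.data.frame(tab)[1:5, ])
  expect_true(variability_metrics(few)$insufficient)
})

test_that("epoch summaries average over the declared windows (slice oracle)", {
  sim <- simulate_protocol_trace(noiseless_preset("ctrl"), seed = 14)
  res <- analyze_protocol_trace(sim$trace)
  s <- res$summary
  expect_setequal(s$condition, c("normoxia", "hypoxia_early", "hypoxia_late",
                                 "recovery", "hyperoxia"))
  # hand-sliced oracle for the hypoxia-early window on the detected table
  ep <- sim$epochs; hy <- ep[ep$label == "hypoxia", ]
  w <- c(hy$start_s, hy$start_s + 0.25 * (hy$end_s - hy$start_s))
  sel <- res$breaths$onset_s >= w[1] & res$breaths$onset_s < w[2]
  expect_equal(s$fr[s$condition == "hypoxia_early"],
               sum(sel) * 60 / diff(w), tolerance = 1e-9)
  expect_equal(s$vt_ml[s$condition == "hypoxia_early"],
               mean(res$breaths$v_t_ml[sel]), tolerance = 1e-9)
  # scaled protocols warn that windows were rescaled
  expect_warning(epoch_windows(sim$trace$epochs), "rescaled")
  # event-free summaries report zero rates
  quiet <- make_train(fr = 150, duration_s = 60)
  qres <- score_events(detect_breaths(quiet$trace))
  ep1 <- epoch_table("normoxia", 0, 60, 0.21)
  r <- event_rates(qres$events, qres$sigh_categories, ep1)
  expect_equal(r$sa_per_h + r$psa_per_h + r$sighs_per_h, 0)
})

test_that("synthetic cohorts reproduce the planted group contrasts", {
  res <- simulate_cohort(presets = c("ctrl", "ncko_a"), n_per_group = 4,
                         seed = 3, analyze = TRUE)
  co <- res$cohort
  sa <- co[co$variable == "sa_per_h" & co$condition == "normoxia", ]
  m_ctrl <- mean(sa$value[sa$group == "ctrl"])
  m_a <- mean(sa$value[sa$group == "ncko_a"])
  expect_gt(m_a, m_ctrl)                       # apneic mutants apnea more
  sa_hx <- co[co$variable == "sa_per_h" & co$condition == "hyperoxia", ]
  diff_hx <- mean(sa_hx$value[sa_hx$group == "ncko_a"]) -
    mean(sa_hx$value[sa_hx$group == "ctrl"])
  expect_lt(diff_hx, m_a - m_ctrl)             # contrast shrinks in hyperoxia
  # detected recovery-minute SA equals the inserted ground truth per animal
  expect_equal(res$animals$detected_recovery_sa,
               res$animals$truth_recovery_sa)
})

test_that("Tukey fence flags extreme animals and only extreme animals", {
  x <- c(rnorm(10), 50)
  expect_message(out <- tukey_outliers(x), "outlier")
  expect_true(out[11])
  expect_equal(sum(out), 1L)
  expect_equal(sum(tukey_outliers(rep(1:5, 2))), 0L)
})
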