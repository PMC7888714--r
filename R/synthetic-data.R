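#' @title Seeded synthetic-data generators
#' @name synthetic-data
#' @description
#' Generators for pressure traces, inserted respiratory events, full
#' normoxia/hypoxia/recovery/hyperoxia protocol traces, gas-fraction traces,
#' cohorts and landmark sets, all with known ground truth and full
#' determinism under a seed. The breath waveform is a quarter-period sine
#' rise over T_i (peaking exactly at onset + T_i) followed by an exponential
#' expiratory decay with time constant T_e/3, normalised to return exactly to
#' end-expiratory baseline at the breath end; apnea insertion removes whole
#' cycles and holds the signal at baseline, matching the "missing breath
#' cycles" semantics of the scoring rules.
NULL

#' Eupneic breath profile
#'
#' @param fr respiratory frequency, breaths/min
#' @param vt_ml true tidal volume, ml
#' @param ti_frac T_i / T_TOT, in (0, 1)
#' @param amp_cv coefficient of variation of breath-to-breath amplitude jitter
#' @param noise_sd additive Gaussian sensor-noise SD, pressure units
#' @return an object of class `breath_profile`
#' @export
breath_profile <- function(fr = 150, vt_ml = 0.15, ti_frac = 0.35,
                           amp_cv = 0, noise_sd = 0) {
  if (fr <= 0) stop("fR must be positive")
  if (ti_frac <= 0 || ti_frac >= 1) stop("ti_frac must lie in (0, 1)")
  if (amp_cv < 0 || noise_sd < 0) stop("jitter/noise must be non-negative")
  structure(list(fr = fr, vt_ml = vt_ml, ti_frac = ti_frac,
                 amp_cv = amp_cv, noise_sd = noise_sd),
            class = "breath_profile")
}

# Render a breath schedule (onset/ti/te/p_t per row) into a sampled trace.
render_schedule <- function(sched, sample_rate, duration_s,
                            noise_sd = 0, noise_seed = NULL) {
  n <- round(duration_s * sample_rate)
  p <- numeric(n)
  k <- 1 - exp(-3)
  for (i in seq_len(nrow(sched))) {
    on <- sched$onset_s[i]; ti <- sched$ti_s[i]; te <- sched$te_s[i]
    amp <- sched$p_t[i]
    i0 <- floor(on * sample_rate + 1e-9) + 1L
    i1 <- min(n, ceiling((on + ti + te) * sample_rate - 1e-9))
    if (i1 < i0) next
    u <- (seq(i0, i1) - 1) / sample_rate - on
    val <- ifelse(u < ti,
                  amp * sin(pi / 2 * u / ti),
                  amp * (exp(-3 * (u - ti) / te) - exp(-3)) / k)
    p[i0:i1] <- pmax(val, 0)
  }
  if (noise_sd > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    p <- p + stats::rnorm(n, 0, noise_sd)
  }
  p
}

new_truth <- function(sched, animal, prov, events = NULL) {
  tb <- breath_table(data.frame(
    onset_s = sched$onset_s, insp_end_s = sched$onset_s + sched$ti_s,
    offset_s = sched$onset_s + sched$ti_s + sched$te_s,
    ti_s = sched$ti_s, te_s = sched$te_s, ttot_s = sched$ti_s + sched$te_s,
    p_t = sched$p_t, v_t_ml = sched$v_t_ml), animal = animal,
    provenance = prov)
  attr(tb, "events") <- events %||%
    data.frame(kind = character(), time_s = numeric(), duration_s = numeric(),
               missing_cycles = numeric(), fold = numeric())
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a eupneic breath train
#'
#' Peak deflections are computed by inverting the barometric tidal-volume
#' equation, so that the programmed true V_T maps exactly onto P_T given the
#' calibration and environment; running the detected P_T forward through
#' [tidal_volume()] therefore recovers the programmed V_T.
#'
#' @param profile a [breath_profile()]
#' @param duration_s trace duration, s (must fit at least one breath)
#' @param env an [environment_record()]
#' @param calib a [calibration_record()]
#' @param seed RNG seed for jitter and noise
#' @param sample_rate sampling rate, Hz
#' @param animal an [animal_record()]
#' @param tb_c body temperature used in the inversion, degrees C
#' @return list with `trace` (a [pressure_trace()]) and `truth` (a ground-truth
#'   [breath_table()] carrying an `events` attribute)
#' @export
simulate_breath_train <- function(profile, duration_s,
                                  env = environment_record(),
                                  calib = calibration_record(), seed = 1,
                                  sample_rate = 200,
                                  animal = animal_record("sim"), tb_c = 37) {
  ttot <- 60 / profile$fr
  n <- floor(duration_s / ttot + 1e-9)
  if (n < 1) stop("duration shorter than one breath cycle")
  set.seed(seed)
  cf <- barometric_correction_factor(env, tb_c)
  p0 <- profile$vt_ml * calib$p_k / (calib$v_k_ml * cf)
  jit <- pmax(0.2, 1 + profile$amp_cv * stats::rnorm(n))
  sched <- data.frame(onset_s = (seq_len(n) - 1) * ttot,
                      ti_s = profile$ti_frac * ttot,
                      te_s = (1 - profile$ti_frac) * ttot,
                      p_t = p0 * jit)
  sched$v_t_ml <- calib$v_k_ml * (sched$p_t / calib$p_k) * cf
  prov <- list(sample_rate = sample_rate, duration_s = duration_s,
               noise_sd = profile$noise_sd,
               noise_seed = (seed %% 1000000000L) + 7L,
               env = env, calib = calib, tb_c = tb_c, profile = profile)
  samples <- render_schedule(sched, sample_rate, duration_s,
                             prov$noise_sd, prov$noise_seed)
  epochs <- epoch_table("normoxia", 0, duration_s, 0.21)
  list(trace = pressure_trace(samples, sample_rate, epochs, env, animal),
       truth = new_truth(sched, animal, prov))
}

#' Event insertion plan
#'
#' Apneas are specified either as `missing_cycles` (whole breath cycles are
#' deleted and the signal held at baseline, so the local inter-onset interval
#' becomes (k+1) x T_TOT) or as an explicit `pause_s` (a flat pause of that
#' duration is spliced in, shifting all later breaths). Sighs scale a single
#' breath's amplitude by `fold`.
#'
#' @param apneas data frame with columns `time_s` and one of `missing_cycles`
#'   / `pause_s`
#' @param sighs data frame with columns `time_s`, `fold` (>= 1)
#' @return an object of class `event_plan`
#' @export
event_plan <- function(apneas = NULL, sighs = NULL) {
  empty_ap <- data.frame(time_s = numeric(), missing_cycles = numeric(),
                         pause_s = numeric())
  if (is.null(apneas)) apneas <- empty_ap
  if (!"pause_s" %in% names(apneas)) apneas$pause_s <- NA_real_
  if (!"missing_cycles" %in% names(apneas)) apneas$missing_cycles <- NA_real_
  if (nrow(apneas) &&
      any(is.na(apneas$missing_cycles) == is.na(apneas$pause_s)))
    stop("each apnea needs exactly one of missing_cycles or pause_s")
  if (is.null(sighs)) sighs <- data.frame(time_s = numeric(), fold = numeric())
  if (nrow(sighs) && any(sighs$fold < 1)) stop("sigh folds must be >= 1")
  structure(list(apneas = apneas, sighs = sighs), class = "event_plan")
}

#' Insert planned apneas and sighs into a generated trace
#'
#' @param trace a [pressure_trace()] produced by a generator
#' @param truth its ground-truth [breath_table()]
#' @param plan an [event_plan()]
#' @return list with updated `trace` and `truth` (the `events` attribute of
#'   `truth` gains one row per inserted event)
#' @export
insert_events <- function(trace, truth, plan) {
  stopifnot(inherits(plan, "event_plan"))
  prov <- attr(truth, "provenance")
  if (is.null(prov$sample_rate))
    stop("truth table lacks generator provenance; cannot re-render")
  span <- trace_duration(trace)
  if (nrow(plan$apneas) && any(plan$apneas$time_s < 0 |
                               plan$apneas$time_s >= span))
    stop("apnea insertion time outside the trace span")
  if (nrow(plan$sighs) && any(plan$sighs$time_s < 0 |
                              plan$sighs$time_s >= span))
    stop("sigh insertion time outside the trace span")
  sched <- data.frame(onset_s = truth$onset_s, ti_s = truth$ti_s,
                      te_s = truth$te_s, p_t = truth$p_t,
                      v_t_ml = truth$v_t_ml)
  ev <- attr(truth, "events")
  used <- integer()

  for (i in seq_len(nrow(plan$sighs))) {
    t0 <- plan$sighs$time_s[i]
    j <- findInterval(t0 + 1e-9, sched$onset_s)
    if (j < 1L) stop("sigh time precedes the first breath")
    if (j %in% used) stop("overlapping event insertions")
    used <- c(used, j)
    f <- plan$sighs$fold[i]
    sched$p_t[j] <- sched$p_t[j] * f
    sched$v_t_ml[j] <- sched$v_t_ml[j] * f
    ev <- rbind(ev, data.frame(kind = "sigh", time_s = sched$onset_s[j],
                               duration_s = NA_real_,
                               missing_cycles = NA_real_, fold = f))
  }

  drop <- integer()
  ap <- plan$apneas[order(plan$apneas$time_s), , drop = FALSE]
  for (i in seq_len(nrow(ap))) {
    if (!is.na(ap$missing_cycles[i])) {
      k <- ap$missing_cycles[i]
      j <- which(sched$onset_s >= ap$time_s[i] - 1e-9)[1L]
      if (is.na(j) || j + k - 1L > nrow(sched))
        stop("apnea insertion does not fit inside the trace")
      idx <- seq(j, j + k - 1L)
      if (any(idx %in% c(used, drop))) stop("overlapping event insertions")
      drop <- c(drop, idx)
      gap <- if (j + k <= nrow(sched)) {
        sched$onset_s[j + k] - sched$onset_s[j]
      } else sum(sched$ti_s[idx] + sched$te_s[idx])
      ev <- rbind(ev, data.frame(kind = "SA", time_s = sched$onset_s[j],
                                 duration_s = gap, missing_cycles = k,
                                 fold = NA_real_))
    }
  }
  if (length(drop)) sched <- sched[-drop, , drop = FALSE]

  extra <- 0
  pauses <- ap[!is.na(ap$pause_s), , drop = FALSE]
  for (i in rev(seq_len(nrow(pauses)))) {
    t0 <- pauses$time_s[i]; d <- pauses$pause_s[i]
    sched$onset_s[sched$onset_s >= t0 - 1e-9] <-
      sched$onset_s[sched$onset_s >= t0 - 1e-9] + d
    extra <- extra + d
    ev <- rbind(ev, data.frame(kind = "SA", time_s = t0, duration_s = d,
                               missing_cycles = NA_real_, fold = NA_real_))
  }

  dur <- prov$duration_s + extra
  prov$duration_s <- dur
  samples <- render_schedule(sched, prov$sample_rate, dur,
                             prov$noise_sd, prov$noise_seed)
  epochs <- trace$epochs
  if (extra > 0 && nrow(epochs)) epochs$end_s[nrow(epochs)] <-
      epochs$end_s[nrow(epochs)] + extra
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  truth2 <- new_truth(sched, attr(truth, "animal"), prov, ev)
  list(trace = pressure_trace(samples, prov$sample_rate, epochs,
                              trace$environment, trace$animal),
       truth = truth2)
}

#' Simulate a gas-fraction trace consistent with a known true V_O2
#'
#' Inverts the pull-mode calorimetry equation: FeCO2 is set from the
#' respiratory exchange ratio (`FeCO2 = FiCO2 + RER x V_O2 / FR_e`) and FeO2
#' is solved so that [vo2_lighton()] returns `true_vo2` exactly.
#'
#' @param true_vo2 true oxygen consumption, ml/min
#' @param rer respiratory exchange ratio, in (0, 1.3\]
#' @param fr_e excurrent flow, ml/min
#' @param fio2 inflow O2 fraction
#' @param fico2 inflow CO2 fraction
#' @return a [gas_trace()]
#' @export
simulate_gas_trace <- function(true_vo2, rer = 0.8, fr_e = 300,
                               fio2 = 0.2095, fico2 = 0.0004) {
  if (fio2 <= 0 || fio2 >= 1) stop("FiO2 must lie in (0, 1)")
  if (fr_e <= 0) stop("excurrent flow must be positive")
  if (any(true_vo2 > 0) && (rer <= 0 || rer > 1.3))
    stop("RER must lie in (0, 1.3]")
  feco2 <- fico2 + rer * true_vo2 / fr_e
  feo2 <- fio2 - (true_vo2 * (1 - fio2) + fio2 * rer * true_vo2) / fr_e
  if (any(feo2 < 0 | feo2 > 1 | feco2 < 0 | feco2 > 1))
    stop("requested V_O2 is infeasible for these fractions and flow")
  gas_trace(fr_e, fio2, feo2, fico2, feco2)
}

#' Protocol epoch layout
#'
#' The full protocol records 150 min of normoxia, 20 min of hypoxia (10% O2),
#' 60 min of recovery and 20 min of hyperoxia (40% O2). The desk-scale layout
#' (5/2/3/2 min) preserves the epoch structure at a runtime suitable for
#' automated tests.
#'
#' @param scale `"desk"`, `"full"`, or a numeric vector of four epoch
#'   durations in minutes
#' @return an [epoch_table()]
#' @export
protocol_epochs <- function(scale = "desk") {
  mins <- if (is.numeric(scale)) {
    stopifnot(length(scale) == 4L)
    scale
  } else switch(match.arg(scale, c("desk", "full")),
                desk = c(5, 2, 3, 2), full = c(150, 20, 60, 20))
  ends <- cumsum(mins * 60)
  epoch_table(c("normoxia", "hypoxia", "recovery", "hyperoxia"),
              c(0, ends[-4L]), ends, c(0.21, 0.10, 0.21, 0.40))
}

#' Cohort presets
#'
#' Each preset fixes the eupneic breathing profile, the hypoxic ventilatory
#' response, per-epoch event-rate parameters, and the distribution of
#' spontaneous-apnea counts in the first minute of recovery. The
#' recovery-minute count distributions are the group summaries reported for
#' the study cohorts: ctrl 0.3 +/- 0.5, ncko_r 3.0 +/- 4.7, ncko_a 8.2 +/- 5.5
#' (mean +/- SD). Counts are drawn from a negative binomial matched to the
#' mean/SD when overdispersed, falling back to Poisson otherwise (the ctrl
#' variance 0.25 is below its mean, so no negative binomial exists for it).
#'
#' @param name `"ctrl"`, `"ncko_r"` or `"ncko_a"`
#' @return an object of class `cohort_preset`
#' @export
cohort_preset <- function(name = c("ctrl", "ncko_r", "ncko_a")) {
  name <- match.arg(name)
  base <- list(
    group = name,
    profile = breath_profile(fr = 150, vt_ml = 0.15, ti_frac = 0.35,
                             amp_cv = 0.04),
    noise_frac = 0.03,           # sensor noise as a fraction of eupneic P_T
    hvr_fr = c(early = 1.35, late = 1.05),    # biphasic fR response factors
    hvr_vt = c(early = 1.20, late = 1.05),
    hyperoxia_fr = 0.95, hyperoxia_vt = 1.0,
    sighs_per_h = 25, sigh_fold_range = c(2.3, 3.0),
    psa_prob = 0.10, psa_max_apneas = 2)
  pars <- switch(name,
    ctrl   = list(recovery_sa = c(mean = 0.3, sd = 0.5),
                  sa_per_h = c(normoxia = 2, hypoxia = 6,
                               recovery = 2, hyperoxia = 1)),
    ncko_r = list(recovery_sa = c(mean = 3.0, sd = 4.7),
                  sa_per_h = c(normoxia = 4, hypoxia = 10,
                               recovery = 4, hyperoxia = 2),
                  psa_prob = 0.15),
    ncko_a = list(recovery_sa = c(mean = 8.2, sd = 5.5),
                  sa_per_h = c(normoxia = 25, hypoxia = 45,
                               recovery = 20, hyperoxia = 1),
                  psa_prob = 0.40))
  structure(utils::modifyList(base, pars), class = "cohort_preset")
}

#' Draw recovery-minute spontaneous-apnea counts for a preset
#'
#' @param n number of draws
#' @param mean,sd target mean and SD of the count distribution
#' @return integer counts >= 0
#' @export
draw_recovery_sa_counts <- function(n, mean, sd) {
  if (sd < 0 || mean < 0) stop("mean and sd must be non-negative")
  v <- sd^2
  if (v > mean) {
    stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

# smallest number of missing cycles satisfying both apnea gates with margin
min_detectable_cycles <- function(ttot, min_pause = 1.0) {
  max(2L, as.integer(ceiling((min_pause + 0.1) / ttot)))
}

#' Simulate a full protocol trace for one animal
#'
#' fR and V_T follow the epoch structure: baseline eupnea during normoxia, an
#' early hypoxic rise in both (hyperventilation) that attenuates
#' exponentially toward a late-hypoxia plateau (the biphasic response),
#' return to baseline in recovery and a mild depression under hyperoxia.
#' Sighs, post-sigh apnea clusters and spontaneous apneas are drawn from the
#' preset's rate parameters; the count of spontaneous apneas inserted in the
#' first minute of recovery is drawn from the preset's documented
#' distribution. Sigh insertions are kept out of the 20 s window preceding
#' and overlapping that minute so the inserted apneas score as spontaneous,
#' not post-sigh.
#'
#' @param preset a [cohort_preset()] or preset name
#' @param seed RNG seed
#' @param scale protocol scale passed to [protocol_epochs()]
#' @param env,calib chamber environment and calibration
#' @param animal an [animal_record()]; by default one is built with mild Tb
#'   variation across the protocol timepoints
#' @return list with `trace`, `truth` (events in `attr(truth, "events")`),
#'   `recovery_minute_sa` (ground-truth inserted count) and `epochs`
#' @export
simulate_protocol_trace <- function(preset = "ctrl", seed = 1, scale = "desk",
                                    env = environment_record(),
                                    calib = calibration_record(),
                                    animal = NULL) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  for (key in c("profile", "hvr_fr", "sa_per_h", "recovery_sa", "sighs_per_h"))
    if (is.null(preset[[key]])) stop("preset missing parameter: ", key)
  epochs <- protocol_epochs(scale)
  total <- epochs$end_s[nrow(epochs)]
  hy <- epochs[epochs$label == "hypoxia", ]
  re <- epochs[epochs$label == "recovery", ]
  if (is.null(animal)) {
    animal <- animal_record("sim", if (preset$group %in% GROUP_LABELS)
      preset$group else "custom", mass_g = 25,
      tb = data.frame(time_s = c(0, hy$start_s + 60,
                                 re$start_s + 0.75 * (re$end_s - re$start_s),
                                 total),
                      tb_c = c(37.5, 37.0, 37.3, 37.4)))
  }
  set.seed(seed)
  prof <- preset$profile
  tau <- 0.25 * (hy$end_s - hy$start_s)
  fac <- function(t, early, late) {
    out <- rep(1, length(t))
    inh <- t >= hy$start_s & t < hy$end_s
    out[inh] <- late + (early - late) * exp(-(t[inh] - hy$start_s) / tau)
    out[t >= epochs$start_s[4L]] <- preset$hyperoxia_fr
    out
  }
  fr_t <- function(t) prof$fr * fac(t, preset$hvr_fr["early"],
                                    preset$hvr_fr["late"])
  vfac <- function(t) {
    out <- rep(1, length(t))
    inh <- t >= hy$start_s & t < hy$end_s
    out[inh] <- preset$hvr_vt["late"] +
      (preset$hvr_vt["early"] - preset$hvr_vt["late"]) *
      exp(-(t[inh] - hy$start_s) / tau)
    out[t >= epochs$start_s[4L]] <- preset$hyperoxia_vt
    out
  }

  cap <- ceiling(total * prof$fr * max(preset$hvr_fr) / 60) + 10L
  onset <- ti <- te <- vt <- numeric(cap)
  t0 <- 0; m <- 0L
  while (TRUE) {
    f <- fr_t(t0); ttot <- 60 / f
    if (t0 + ttot > total + 1e-9) break
    m <- m + 1L
    onset[m] <- t0
    ti[m] <- prof$ti_frac * ttot
    te[m] <- ttot - ti[m]
    vt[m] <- prof$vt_ml * vfac(t0)
    t0 <- t0 + ttot
  }
  sched <- data.frame(onset_s = onset[1:m], ti_s = ti[1:m], te_s = te[1:m],
                      v_t_ml = vt[1:m])
  cf <- barometric_correction_factor(env, mean(animal$tb$tb_c))
  jit <- pmax(0.2, 1 + prof$amp_cv * stats::rnorm(m))
  sched$v_t_ml <- sched$v_t_ml * jit
  sched$p_t <- sched$v_t_ml * calib$p_k / (calib$v_k_ml * cf)
  ttot_all <- sched$ti_s + sched$te_s

  # --- event planning on the breath schedule ------------------------------
  used <- rep(FALSE, m)     # breaths consumed by an insertion or its guard
  sigh_idx <- integer(); sigh_fold <- numeric()
  ap_start <- integer(); ap_k <- integer(); ap_kind <- character()
  protected <- sched$onset_s >= re$start_s - 25 &
    sched$onset_s < re$start_s + 65

  reserve <- function(idx, pad) {
    lo <- max(1L, min(idx) - pad); hi <- min(m, max(idx) + pad)
    used[lo:hi] <<- TRUE
  }

  # sighs (with optional post-sigh apnea clusters)
  for (e in seq_len(nrow(epochs))) {
    n_s <- stats::rpois(1L, preset$sighs_per_h *
                          (epochs$end_s[e] - epochs$start_s[e]) / 3600)
    cand <- which(sched$onset_s >= epochs$start_s[e] + 10 &
                    sched$onset_s < epochs$end_s[e] - 30 &
                    !protected & !used)
    n_s <- min(n_s, length(cand) %/% 60L)
    if (n_s < 1L) next
    picks <- sort(sample(cand, n_s))
    for (j in picks) {
      if (used[j]) next
      sigh_idx <- c(sigh_idx, j)
      sigh_fold <- c(sigh_fold, stats::runif(1L, preset$sigh_fold_range[1L],
                                             preset$sigh_fold_range[2L]))
      reserve(j, 8L)
      if (stats::runif(1L) < preset$psa_prob) {
        n_ap <- sample.int(preset$psa_max_apneas, 1L)
        at <- j + 3L
        for (a in seq_len(n_ap)) {
          k <- min_detectable_cycles(ttot_all[j])
          if (at + k + 3L > m) break
          if (sched$onset_s[at] - sched$onset_s[j] > 15) break
          ap_start <- c(ap_start, at); ap_k <- c(ap_k, k)
          ap_kind <- c(ap_kind, "PSA")
          reserve(at:(at + k - 1L), 3L)
          at <- at + k + 3L
        }
      }
    }
  }

  # spontaneous apneas per epoch (recovery: excluding its first minute)
  for (e in seq_len(nrow(epochs))) {
    dur <- epochs$end_s[e] - epochs$start_s[e]
    if (epochs$label[e] == "recovery") dur <- max(0, dur - 60)
    n_a <- stats::rpois(1L, preset$sa_per_h[epochs$label[e]] * dur / 3600)
    if (n_a < 1L) next
    # keep spontaneous apneas out of the 20 s post-sigh window (with margin)
    # so their scored label matches the planned one
    near_sigh <- rep(FALSE, m)
    for (j in sigh_idx)
      near_sigh <- near_sigh | (sched$onset_s >= sched$onset_s[j] - 3 &
                                  sched$onset_s < sched$onset_s[j] + 24)
    cand <- which(sched$onset_s >= max(epochs$start_s[e], 5) &
                    sched$onset_s < epochs$end_s[e] - 5 &
                    !protected & !used & !near_sigh)
    if (!length(cand)) next
    picks <- cand[unique(pmax(1L, round(seq(1L, length(cand),
                                            length.out = min(n_a, length(cand) %/% 12L)))))]
    for (j in picks) {
      k <- min_detectable_cycles(ttot_all[j])
      if (j + k + 1L > m || any(used[j:(j + k - 1L)])) next
      ap_start <- c(ap_start, j); ap_k <- c(ap_k, k)
      ap_kind <- c(ap_kind, "SA")
      reserve(j:(j + k - 1L), 6L)
    }
  }

  # recovery first-minute spontaneous apneas from the preset distribution
  rec_target <- draw_recovery_sa_counts(1L, preset$recovery_sa["mean"],
                                        preset$recovery_sa["sd"])
  rec_cand <- which(sched$onset_s >= re$start_s + 1 &
                      sched$onset_s < re$start_s + 56)
  k_rec <- min_detectable_cycles(stats::median(ttot_all[rec_cand]))
  rec_n <- min(rec_target, length(rec_cand) %/% (k_rec + 3L))
  if (rec_n > 0L) {
    slots <- rec_cand[round(seq(1L, length(rec_cand) - k_rec,
                                length.out = rec_n))]
    for (j in slots) {
      ap_start <- c(ap_start, j); ap_k <- c(ap_k, k_rec)
      ap_kind <- c(ap_kind, "SA")
    }
  }

  # --- realise the plan ----------------------------------------------------
  ev <- data.frame(kind = character(), time_s = numeric(),
                   duration_s = numeric(), missing_cycles = numeric(),
                   fold = numeric())
  for (i in seq_along(sigh_idx)) {
    j <- sigh_idx[i]
    sched$p_t[j] <- sched$p_t[j] * sigh_fold[i]
    sched$v_t_ml[j] <- sched$v_t_ml[j] * sigh_fold[i]
    ev <- rbind(ev, data.frame(kind = "sigh", time_s = sched$onset_s[j],
                               duration_s = NA_real_,
                               missing_cycles = NA_real_,
                               fold = sigh_fold[i]))
  }
  drop <- integer()
  for (i in seq_along(ap_start)) {
    idx <- seq(ap_start[i], ap_start[i] + ap_k[i] - 1L)
    gap <- sched$onset_s[min(m, max(idx) + 1L)] - sched$onset_s[idx[1L]]
    ev <- rbind(ev, data.frame(kind = ap_kind[i],
                               time_s = sched$onset_s[idx[1L]],
                               duration_s = gap, missing_cycles = ap_k[i],
                               fold = NA_real_))
    drop <- c(drop, idx)
  }
  if (length(drop)) sched <- sched[-drop, , drop = FALSE]
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL

  noise_sd <- preset$noise_frac * stats::median(sched$p_t)
  prov <- list(sample_rate = 200, duration_s = total, noise_sd = noise_sd,
               noise_seed = (seed %% 1000000000L) + 13L, env = env,
               calib = calib, tb_c = mean(animal$tb$tb_c), preset = preset)
  samples <- render_schedule(sched, 200, total, noise_sd, prov$noise_seed)
  truth <- new_truth(sched, animal, prov, ev)
  list(trace = pressure_trace(samples, 200, epochs, env, animal),
       truth = truth,
       recovery_minute_sa = as.integer(rec_n),
       epochs = epochs)
}

#' Simulate (and optionally analyze) a multi-group cohort
#'
#' Runs [simulate_protocol_trace()] per animal under per-animal sub-seeds.
#' With `analyze = TRUE` each trace is pushed through the full analysis
#' pipeline (breath segmentation, calibration, event scoring, epoch
#' summaries) and the detected per-animal values are returned as a long
#' [cohort_table()].
#'
#' @param presets character vector of preset names (one group each)
#' @param n_per_group animals per group
#' @param seed master seed; per-animal seeds are derived deterministically
#' @param scale protocol scale (see [protocol_epochs()])
#' @param analyze run the analysis pipeline per animal
#' @param keep_traces keep the raw traces in the result (memory-heavy)
#' @return list with `animals` (metadata + ground-truth recovery-minute SA
#'   counts and, when analyzed, detected counts), `cohort` (long table, when
#'   analyzed) and optionally `traces`
#' @export
simulate_cohort <- function(presets = c("ctrl", "ncko_r", "ncko_a"),
                            n_per_group = 5, seed = 1, scale = "desk",
                            analyze = TRUE, keep_traces = FALSE) {
  if (n_per_group < 1) stop("n_per_group must be at least 1")
  if (!all(presets %in% c("ctrl", "ncko_r", "ncko_a")))
    stop("unknown preset label")
  animals <- list(); rows <- list(); traces <- list()
  idx <- 0L
  for (g in presets) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sub <- as.integer((as.numeric(seed) + 104729 * idx) %% 2147483646) + 1L
      sim <- simulate_protocol_trace(g, seed = sub, scale = scale)
      aid <- paste0(g, "_", i)
      rec <- data.frame(animal = aid, group = g, seed = sub,
                        truth_recovery_sa = sim$recovery_minute_sa,
                        detected_recovery_sa = NA_integer_)
      if (analyze) {
        res <- analyze_protocol_trace(sim$trace)
        rec$detected_recovery_sa <- res$recovery_minute_sa
        s <- res$summary
        rows[[idx]] <- data.frame(animal = aid, group = g,
                                  condition = s$condition,
                                  variable = rep(c("fr", "vt_ml", "ve",
                                                   "sa_per_h", "sighs_per_h"),
                                                 each = nrow(s)),
                                  value = c(s$fr, s$vt_ml, s$ve,
                                            s$sa_per_h, s$sighs_per_h))
      }
      animals[[idx]] <- rec
      if (keep_traces) traces[[aid]] <- sim$trace
    }
  }
  out <- list(animals = do.call(rbind, animals))
  if (analyze) out$cohort <- cohort_table(do.call(rbind, rows))
  if (keep_traces) out$traces <- traces
  out
}

#' Simulate landmark-placement replicates for one specimen
#'
#' Applies an optional deformation to a template (uniform scale, per-axis
#' scale, or an arbitrary 3x3 linear map) and then generates `n_reps`
#' independent rater placements, each perturbed by isotropic Gaussian jitter.
#'
#' @param template a [landmark_set()]
#' @param deformation `NULL` (identity), a scalar scale factor, a length-3
#'   per-axis scale vector, or a 3x3 matrix
#' @param rater_jitter SD of isotropic placement jitter, mm (>= 0)
#' @param n_reps number of replicate placements
#' @param seed RNG seed
#' @param animal animal id attached to the replicates
#' @return list of `n_reps` [landmark_set()]s
#' @export
simulate_landmark_sets <- function(template, deformation = NULL,
                                   rater_jitter = 0, n_reps = 3, seed = 1,
                                   animal = "sim") {
  if (rater_jitter < 0) stop("rater jitter must be non-negative")
  xyz <- as.matrix(template[, c("x_mm", "y_mm", "z_mm")])
  if (!is.null(deformation)) {
    A <- if (is.matrix(deformation)) deformation
    else diag(rep(deformation, length.out = 3L))
    xyz <- xyz %*% t(A)
  }
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    pert <- xyz + matrix(stats::rnorm(length(xyz), 0, rater_jitter),
                         ncol = 3L)
    landmark_set(data.frame(name = template$name, x_mm = pert[, 1L],
                            y_mm = pert[, 2L], z_mm = pert[, 3L]),
                 animal = animal, replicate = r)
  })
}

#' Random between-specimen skull deformation
#'
#' A random linear map `I + E` with i.i.d. Gaussian entries in `E`, giving a
#' generic affine shape change (anisotropic scaling plus shear) of relative
#' magnitude `sd`. Unlike a pure uniform scaling, this perturbs angles as
#' well as distances, which is what between-animal craniofacial variation
#' looks like to a measurement battery.
#'
#' @param sd SD of the strain entries (0.1 = 10% shape spread)
#' @return a 3x3 deformation matrix for [simulate_landmark_sets()]
#' @export
random_skull_deformation <- function(sd = 0.1) {
  if (sd < 0) stop("deformation spread must be non-negative")
  diag(3L) + matrix(stats::rnorm(9L, 0, sd), 3L, 3L)
}

#' Synthetic mouse-skull landmark template
#'
#' A synthetic midline-plus-bilateral landmark configuration with plausible
#' adult-mouse skull proportions (about 22 mm long), providing the named
#' points that the shipped measurement definitions reference. It is a
#' geometric stand-in, not a digitised specimen.
#'
#' @return a [landmark_set()]
#' @export
mouse_skull_template <- function() {
  landmark_set(data.frame(
    name = c("nasale", "nasion", "bregma", "lambda", "opisthion", "basion",
             "sos", "iss", "presphenoid_ant", "ethmoid_post", "ethmoid_ant",
             "nasal_lateral_l", "nasal_lateral_r", "frontal_l", "frontal_r"),
    x_mm = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -1.5, 1.5, -4, 4),
    y_mm = c(11, 4.5, -2, -8, -11, -10.5, -7, -4, -1.5, -1, 2.5,
             9, 9, 1, 1),
    z_mm = c(3, 5.5, 6.5, 5.8, 2.5, 0.5, 0.8, 1.2, 1.6, 1.7, 2.2,
             3.2, 3.2, 5.2, 5.2)))
}
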