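#' Epoch averaging windows
#'
#' The reported variables are averaged over fixed protocol windows: the whole
#' normoxia epoch, minutes 0-5 and 10-15 of hypoxia, the last 10 min of
#' recovery, and minutes 10-15 of hyperoxia. When an epoch is shorter than
#' the full protocol (a scaled desk run) the windows are rescaled
#' proportionally (e.g. hypoxia-early becomes the first quarter of the
#' epoch) and a warning records the rescaling.
#'
#' @param epochs an [epoch_table()]
#' @return data frame with `condition`, `start_s`, `end_s`
#' @export
epoch_windows <- function(epochs) {
  full <- list(hypoxia = 20 * 60, recovery = 60 * 60, hyperoxia = 20 * 60)
  frac <- list(hypoxia_early = c(0, 0.25), hypoxia_late = c(0.5, 0.75),
               recovery = c(5 / 6, 1), hyperoxia = c(0.5, 0.75))
  rows <- list(); scaled <- FALSE
  for (e in seq_len(nrow(epochs))) {
    lab <- epochs$label[e]
    lo <- epochs$start_s[e]; hi <- epochs$end_s[e]; dur <- hi - lo
    if (lab == "normoxia") {
      rows[[length(rows) + 1L]] <- data.frame(condition = "normoxia",
                                              start_s = lo, end_s = hi)
      next
    }
    if (!is.null(full[[lab]]) && dur < full[[lab]] - 1e-9) scaled <- TRUE
    parts <- switch(lab,
                    hypoxia = c("hypoxia_early", "hypoxia_late"),
                    recovery = "recovery", hyperoxia = "hyperoxia")
    for (p in parts) {
      f <- frac[[p]]
      rows[[length(rows) + 1L]] <-
        data.frame(condition = p, start_s = lo + f[1L] * dur,
                   end_s = lo + f[2L] * dur)
    }
  }
  if (scaled)
    warning("epochs shorter than the full protocol: averaging windows ",
            "rescaled proportionally")
  do.call(rbind, rows)
}

#' Per-animal epoch summaries
#'
#' Computes, over each averaging window of [epoch_windows()]: fR, mean V_T,
#' minute ventilation (fR x V_T), event rates, sigh-category percentages and
#' interpolated Tb; optionally V_O2, V_E/V_O2 and RER when per-window gas
#' traces are supplied.
#'
#' @param table a calibrated [breath_table()]
#' @param events combined [event_table()] from [score_events()]
#' @param sigh_categories sigh-category table from [score_events()]
#' @param trace the source [pressure_trace()] (for epochs, animal, env)
#' @param gas optional named list of [gas_trace()]s keyed by condition
#' @param normalize normalize V_E (and V_O2) to body mass per kg
#' @return data frame with one row per condition window
#' @export
summarize_epochs <- function(table, events, sigh_categories, trace,
                             gas = NULL, normalize = TRUE) {
  win <- suppressWarnings(epoch_windows(trace$epochs))
  animal <- trace$animal
  env <- trace$environment
  rows <- lapply(seq_len(nrow(win)), function(i) {
    w <- c(win$start_s[i], win$end_s[i])
    tm <- timing_metrics(table, w)
    h <- (w[2L] - w[1L]) / 3600
    inw <- events$time_s >= w[1L] & events$time_s < w[2L]
    n_sa <- sum(inw & events$kind == "SA")
    n_psa <- sum(inw & events$kind == "PSA")
    n_sigh <- sum(inw & events$kind == "sigh")
    sc <- sigh_categories[sigh_categories$time_s >= w[1L] &
                            sigh_categories$time_s < w[2L], , drop = FALSE]
    ve <- if (is.na(tm$fr) || is.na(tm$vt_ml)) NA_real_ else
      minute_ventilation(tm$fr, tm$vt_ml)
    if (normalize && !is.na(ve))
      ve <- normalize_and_stpd(ve, animal$mass_g, mode = "mass")
    out <- data.frame(
      condition = win$condition[i], start_s = w[1L], end_s = w[2L],
      fr = tm$fr, vt_ml = tm$vt_ml, ve = ve,
      tb_c = tb_at(animal, mean(w)),
      sa_per_h = n_sa / h, psa_per_h = n_psa / h, sighs_per_h = n_sigh / h,
      pct_sighs_ge2 = if (nrow(sc)) 100 * mean(sc$category == "ge2")
      else NA_real_,
      vo2 = NA_real_, ve_vo2 = NA_real_, rer = NA_real_,
      stringsAsFactors = FALSE)
    g <- gas[[win$condition[i]]]
    if (!is.null(g)) {
      vo2 <- vo2_lighton(g)
      vo2 <- normalize_and_stpd(vo2, if (normalize) animal$mass_g else NULL,
                                env, mode = if (normalize) "both" else "stpd")
      out$vo2 <- vo2
      out$ve_vo2 <- air_convection_requirement(ve, vo2)
      out$rer <- clams_metrics(g)$rer
    }
    out
  })
  out <- do.call(rbind, rows)
  out$first_recovery_min_sa <- first_recovery_minute_sa(events, trace$epochs)
  out
}

#' Run the full respiratory pipeline on one trace
#'
#' Breath detection, tidal-volume calibration, event scoring, per-epoch
#' rates and window summaries.
#'
#' @param trace a [pressure_trace()]
#' @param calib a [calibration_record()]
#' @param seg_params a [segmentation_params()]
#' @param event_par an [event_params()]
#' @return list with `breaths`, `events`, `sigh_categories`, `rates`,
#'   `summary`, `recovery_minute_sa`
#' @export
analyze_protocol_trace <- function(trace, calib = calibration_record(),
                                   seg_params = segmentation_params(),
                                   event_par = event_params()) {
  breaths <- detect_breaths(trace, seg_params)
  breaths <- calibrate_breaths(breaths, calib, trace$environment,
                               trace$animal)
  sc <- score_events(breaths, event_par)
  rates <- event_rates(sc$events, sc$sigh_categories, trace$epochs)
  summ <- summarize_epochs(breaths, sc$events, sc$sigh_categories, trace)
  list(breaths = breaths, events = sc$events,
       sigh_categories = sc$sigh_categories, rates = rates, summary = summ,
       recovery_minute_sa = first_recovery_minute_sa(sc$events,
                                                     trace$epochs))
}

# ---- statistical tests ------------------------------------------------------

#' Two-tailed unpaired Student's t-test
#'
#' Classic pooled-variance t. Degenerate zero-variance inputs are handled
#' explicitly: equal means give t = 0, p = 1; unequal means give p = 0
#' flagged `degenerate`.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each)
#' @return data frame of class `stat_result` with statistic, df, p and group
#'   means +/- SD
#' @export
students_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  pooled <- (stats::var(group_a) * (length(group_a) - 1L) +
               stats::var(group_b) * (length(group_b) - 1L))
  degenerate <- FALSE
  if (pooled == 0) {
    degenerate <- mean(group_a) != mean(group_b)
    tstat <- if (degenerate) -sign(mean(group_a) - mean(group_b)) * Inf else 0
    p <- if (degenerate) 0 else 1
    df <- length(group_a) + length(group_b) - 2L
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
    tstat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(data.frame(test = "students_t", statistic = tstat, df = df,
                       p = p, mean_a = mean(group_a),
                       sd_a = stats::sd(group_a), mean_b = mean(group_b),
                       sd_b = stats::sd(group_b), degenerate = degenerate),
            class = c("stat_result", "data.frame"))
}

#' One-way ANOVA
#'
#' @param groups named list of numeric vectors (>= 2 groups, n >= 2 each)
#' @return data frame of class `stat_result` with F, df and p
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    return(structure(data.frame(test = "one_way_anova", statistic = 0,
                                df1 = length(groups) - 1L,
                                df2 = length(y) - length(groups), p = 1),
                     class = c("stat_result", "data.frame")))
  }
  a <- stats::anova(stats::lm(y ~ g))
  structure(data.frame(test = "one_way_anova", statistic = a$`F value`[1L],
                       df1 = a$Df[1L], df2 = a$Df[2L],
                       p = a$`Pr(>F)`[1L]),
            class = c("stat_result", "data.frame"))
}

#' Holm-Sidak step-down adjustment
#'
#' Sort the m raw p-values ascending; the i-th adjusted value is
#' `max over j <= i of 1 - (1 - p_j)^(m - j + 1)`, clipped to 1, reported in
#' the original order. Adjusted values are monotone in rank, at least the
#' raw values, and bounded above by the Bonferroni adjustment.
#'
#' @param p numeric vector of raw p-values
#' @return adjusted p-values in the input order
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-way repeated-measures ANOVA with Holm-Sidak post tests
#'
#' Split-plot decomposition via `aov` with the animal as the whole-plot
#' error stratum: the between factor (group) is tested against
#' animal-within-group, the within factor (gas condition) and the
#' interaction against the within-animal residual. No sphericity correction
#' is applied. Post tests are pairwise between-group Student's t-tests
#' within each condition, Holm-Sidak adjusted over the whole family.
#' Animals with incomplete condition sets are dropped with a message.
#'
#' @param data data frame with columns `animal`, `group`, `condition`,
#'   `value` (e.g. a [cohort_table()] filtered to one variable)
#' @param posthoc run the pairwise post tests
#' @return list with `anova` (data frame of effects) and `posthoc`
#' @export
rm_anova_holm_sidak <- function(data, posthoc = TRUE) {
  d <- data.frame(animal = factor(data$animal), group = factor(data$group),
                  condition = factor(data$condition), value = data$value)
  if (nlevels(d$group) < 2L || nlevels(d$condition) < 2L)
    stop("at least 2 groups and 2 conditions are required")
  counts <- table(d$animal)
  complete <- names(counts)[counts == nlevels(d$condition)]
  if (length(complete) < length(counts)) {
    message("dropping ", length(counts) - length(complete),
            " animal(s) with incomplete condition sets")
    d <- d[d$animal %in% complete, , drop = FALSE]
    d$animal <- droplevels(d$animal)
  }
  if (stats::var(d$value) == 0) {
    eff <- data.frame(effect = c("group", "condition", "group:condition"),
                      statistic = 0, df1 = NA_real_, df2 = NA_real_, p = 1)
  } else {
    fit <- stats::aov(value ~ group * condition + Error(animal),
                      data = d)
    s <- summary(fit)
    btw <- s[["Error: animal"]][[1L]]
    wth <- s[["Error: Within"]][[1L]]
    pick <- function(tab, term) {
      i <- match(term, trimws(rownames(tab)))
      resid <- nrow(tab)
      data.frame(effect = term, statistic = tab$`F value`[i],
                 df1 = tab$Df[i], df2 = tab$Df[resid],
                 p = tab$`Pr(>F)`[i])
    }
    eff <- rbind(pick(btw, "group"), pick(wth, "condition"),
                 pick(wth, "group:condition"))
  }
  out <- list(anova = eff)
  if (posthoc) {
    ph <- list(); r <- 0L
    gl <- levels(d$group)
    for (cond in levels(d$condition)) {
      for (i in seq_len(length(gl) - 1L)) for (j in seq(i + 1L, length(gl))) {
        a <- d$value[d$condition == cond & d$group == gl[i]]
        b <- d$value[d$condition == cond & d$group == gl[j]]
        tt <- students_t(a, b)
        r <- r + 1L
        ph[[r]] <- data.frame(condition = cond, group_a = gl[i],
                              group_b = gl[j], statistic = tt$statistic,
                              df = tt$df, p_raw = tt$p)
      }
    }
    ph <- do.call(rbind, ph)
    ph$p_adj <- holm_sidak(ph$p_raw)
    out$posthoc <- ph
  }
  out
}

#' Intraclass correlation for triplicate measurements, ICC(3,1)
#'
#' Two-way mixed-effects, single-rater, consistency ICC:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` from the
#' two-way (subject + replicate) ANOVA. Values above 0.9 are flagged as
#' excellent reliability. Zero between-subject variance leaves the ICC
#' undefined (NA, flagged).
#'
#' @param results long data frame with columns `animal`, `replicate`,
#'   `name`, `value` (as from [evaluate_measurement_set()])
#' @return data frame with one row per measurement: `icc`, `excellent`,
#'   `undefined`
#' @export
icc_triplicate <- function(results) {
  out <- lapply(split(results, results$name), function(d) {
    sub <- factor(d$animal); rep_f <- factor(d$replicate)
    if (nlevels(sub) < 2L || nlevels(rep_f) < 2L)
      stop("ICC requires >= 2 subjects and >= 2 replicates")
    # only the mean squares are used, so the F-test warning that lm emits on
    # perfect fits (identical replicates) is irrelevant here
    a <- suppressWarnings(stats::anova(stats::lm(value ~ sub + rep_f,
                                                 data = d)))
    ms_r <- a["sub", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
    k <- nlevels(rep_f)
    if (ms_r == 0 && ms_e == 0) {
      icc <- NA_real_
    } else {
      icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    }
    data.frame(name = d$name[1L], icc = icc,
               excellent = !is.na(icc) && icc > 0.9,
               undefined = is.na(icc), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-metabolite two-group screen
#'
#' Column-wise two-tailed unpaired Student's t-tests between the two groups.
#' Significance is declared at raw p < alpha (uncorrected, the convention of
#' the screen this reproduces); a Benjamini-Hochberg FDR column is emitted
#' for reference but not used for the primary call. Constant columns are
#' flagged with p = 1.
#'
#' @param table a [metabolite_table()]
#' @param alpha significance level for the primary call
#' @return data frame with one row per metabolite and an attribute
#'   `significant` naming the hits
#' @export
metabolite_screen <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  gl <- unique(table$groups)
  if (length(gl) != 2L) stop("exactly two groups are required")
  m <- table$concentrations
  ia <- table$groups == gl[1L]; ib <- table$groups == gl[2L]
  if (sum(ia) < 2L || sum(ib) < 2L) stop("each group needs n >= 2")
  res <- lapply(seq_len(ncol(m)), function(j) {
    a <- m[ia, j]; b <- m[ib, j]
    constant <- stats::var(c(a, b)) == 0
    tt <- students_t(a, b)
    data.frame(metabolite = colnames(m)[j] %||% paste0("m", j),
               mean_a = mean(a), mean_b = mean(b), statistic = tt$statistic,
               df = tt$df, p = if (constant) 1 else tt$p,
               constant = constant, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  attr(res, "significant") <- res$metabolite[res$significant]
  res
}

#' Breath-to-breath variability metrics
#'
#' Coefficient of variation and lag-1 consecutive-difference SD of the cycle
#' duration (equivalently fR) and of V_T over a window. These are summary
#' stand-ins for pattern variability; fewer than 10 breaths returns NA,
#' flagged.
#'
#' @param table a [breath_table()]
#' @param window optional `c(start_s, end_s)`; default: the whole table
#' @return data frame with `cv_ttot`, `cv_vt`, `sd1_ttot`, `sd1_vt`, `n`,
#'   `insufficient`
#' @export
variability_metrics <- function(table, window = NULL) {
  sel <- if (is.null(window)) rep(TRUE, nrow(table)) else
    table$onset_s >= window[1L] & table$onset_s < window[2L]
  tt <- table$ttot_s[sel]
  vt <- table$v_t_ml[sel]
  if (all(is.na(vt))) vt <- table$p_t[sel]
  if (length(tt) < 10L) {
    return(data.frame(cv_ttot = NA_real_, cv_vt = NA_real_,
                      sd1_ttot = NA_real_, sd1_vt = NA_real_,
                      n = length(tt), insufficient = TRUE))
  }
  data.frame(cv_ttot = stats::sd(tt) / mean(tt),
             cv_vt = stats::sd(vt) / mean(vt),
             sd1_ttot = stats::sd(diff(tt)), sd1_vt = stats::sd(diff(vt)),
             n = length(tt), insufficient = FALSE)
}

#' Flag outlying animals by a Tukey fence
#'
#' Config-gated, logged outlier exclusion (never silent): values above
#' `Q3 + k IQR` or below `Q1 - k IQR` are flagged.
#'
#' @param x numeric vector
#' @param k fence multiplier (default 3, an extreme-outlier fence)
#' @return logical vector, TRUE for outliers
#' @export
tukey_outliers <- function(x, k = 3) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2L] - q[1L]
  out <- x > q[2L] + k * iqr | x < q[1L] - k * iqr
  if (any(out, na.rm = TRUE))
    message("flagging ", sum(out, na.rm = TRUE), " outlier value(s)")
  out & !is.na(x)
}
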