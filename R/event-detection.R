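#' Event-scoring parameters
#'
#' Defaults implement the published scoring rules: a spontaneous apnea is at
#' least two missing breath cycles AND a pause of at least 1 s (the two gates
#' are applied conjunctively, since the 1 s figure is the fR-dependent
#' correspondence of two missing cycles); a sigh is a breath of at least
#' twice the local normal breath volume; a post-sigh apnea is an apnea within
#' 20 s after a sigh.
#'
#' @param min_missing_cycles minimum missing cycles for an apnea
#' @param min_pause_s minimum pause duration for an apnea, s
#' @param sigh_fold volume multiple defining a sigh
#' @param psa_window_s sigh-to-apnea linkage window, s
#' @param psa_category_boundary linked-apnea count separating the two sigh
#'   categories
#' @param baseline_window_s window for the "normal breath" rolling median, s
#' @param baseline_min_breaths minimum preceding breaths required to score
#' @return an object of class `event_params`
#' @export
event_params <- function(min_missing_cycles = 2, min_pause_s = 1.0,
                         sigh_fold = 2.0, psa_window_s = 20,
                         psa_category_boundary = 2, baseline_window_s = 60,
                         baseline_min_breaths = 5) {
  if (any(c(min_missing_cycles, min_pause_s, psa_window_s,
            psa_category_boundary, baseline_window_s,
            baseline_min_breaths) <= 0))
    stop("all event parameters must be positive")
  if (sigh_fold < 1) stop("sigh fold must be at least 1")
  structure(list(min_missing_cycles = min_missing_cycles,
                 min_pause_s = min_pause_s, sigh_fold = sigh_fold,
                 psa_window_s = psa_window_s,
                 psa_category_boundary = psa_category_boundary,
                 baseline_window_s = baseline_window_s,
                 baseline_min_breaths = baseline_min_breaths),
            class = "event_params")
}

# rolling median of the most recent `n_max` values of v at indices < i,
# restricted to a trailing time window and excluding flagged indices
.trailing_median <- function(i, times, v, exclude, window_s, n_min, n_max = 15L) {
  j <- which(!exclude[seq_len(i - 1L)] &
               times[seq_len(i - 1L)] >= times[i] - window_s)
  if (length(j) < n_min) return(NA_real_)
  if (length(j) > n_max) j <- j[(length(j) - n_max + 1L):length(j)]
  stats::median(v[j])
}

#' Detect spontaneous apneas in a breath table
#'
#' For every consecutive breath pair the pause is the inter-onset interval
#' minus the local expected cycle duration (rolling median of the preceding
#' breaths' T_TOT); the missing-cycle count is the pause divided by that
#' duration, rounded. An apnea is emitted iff the missing-cycle count meets
#' `min_missing_cycles` and the pause meets `min_pause_s`. The apnea time is
#' the expected onset of the first missing breath, its duration the pause.
#'
#' @param table a [breath_table()]
#' @param params an [event_params()]
#' @param sigh_idx optional indices of breaths already flagged as sighs,
#'   excluded from the cycle-duration baseline
#' @return an [event_table()] of `"SA"` events; tables with fewer than
#'   `baseline_min_breaths + 1` breaths return an empty table flagged
#'   `insufficient_baseline`
#' @export
detect_apneas <- function(table, params = event_params(), sigh_idx = integer()) {
  nb <- nrow(table)
  empty <- event_table()
  if (nb < params$baseline_min_breaths + 1L) {
    attr(empty, "insufficient_baseline") <- TRUE
    return(empty)
  }
  excl <- rep(FALSE, nb)
  excl[sigh_idx] <- TRUE
  on <- table$onset_s
  tt <- table$ttot_s
  kind <- character(); time <- dur <- mc <- numeric()
  for (i in seq(2L, nb)) {
    # baseline from breaths strictly before i-1: breath i-1's own T_TOT
    # spans the candidate gap and must not contaminate the estimate
    tbar <- .trailing_median(i - 1L, on, tt, excl,
                             params$baseline_window_s,
                             params$baseline_min_breaths)
    if (is.na(tbar)) next
    gap <- on[i] - on[i - 1L]
    pause <- gap - tbar
    k <- round(pause / tbar)
    if (k >= params$min_missing_cycles &&
        pause >= params$min_pause_s - 1e-9) {
      kind <- c(kind, "SA")
      time <- c(time, on[i - 1L] + tbar)
      dur <- c(dur, pause)
      mc <- c(mc, k)
    }
  }
  event_table(kind = kind, time_s = time, duration_s = dur,
              missing_cycles = mc)
}

#' Detect sighs in a breath table
#'
#' A breath is a sigh iff its volume is at least `sigh_fold` times the
#' rolling median volume of the preceding non-sigh breaths inside the
#' baseline window (sighs are excluded from the baseline as they are found,
#' so a sigh does not inflate the baseline for a nearby later sigh). Breath
#' volume is `v_t_ml` when calibrated, otherwise the peak deflection `p_t`
#' (the two are proportional, so the rule is identical).
#'
#' @param table a [breath_table()]
#' @param params an [event_params()]
#' @return an [event_table()] of `"sigh"` events with an attribute
#'   `breath_idx` giving the flagged breath rows
#' @export
detect_sighs <- function(table, params = event_params()) {
  nb <- nrow(table)
  empty <- event_table()
  if (nb < params$baseline_min_breaths + 1L) {
    attr(empty, "insufficient_baseline") <- TRUE
    return(empty)
  }
  vol <- if (!all(is.na(table$v_t_ml))) table$v_t_ml else table$p_t
  on <- table$onset_s
  is_sigh <- rep(FALSE, nb)
  for (i in seq(2L, nb)) {
    med <- .trailing_median(i, on, vol, is_sigh,
                            params$baseline_window_s,
                            params$baseline_min_breaths)
    if (is.na(med)) next
    if (vol[i] >= params$sigh_fold * med - 1e-12) is_sigh[i] <- TRUE
  }
  idx <- which(is_sigh)
  ev <- event_table(kind = rep("sigh", length(idx)), time_s = on[idx])
  attr(ev, "breath_idx") <- idx
  ev
}

#' Link apneas to preceding sighs (post-sigh apnea scoring)
#'
#' Each apnea whose time lies in `(sigh_time, sigh_time + psa_window_s]` is
#' attached to the nearest preceding sigh and re-labelled `"PSA"`; apneas
#' with no qualifying sigh remain `"SA"`. Each sigh is categorized by its
#' linked-apnea count relative to `psa_category_boundary` (the `">=2 apneas"`
#' category requires distinct apneas, which are separated by at least one
#' breath by construction since every detected apnea is delimited by breaths
#' on both sides).
#'
#' @param apneas an [event_table()] of `"SA"` events
#' @param sighs an [event_table()] of `"sigh"` events
#' @param params an [event_params()]
#' @return list with `events` (combined, time-ordered [event_table()]) and
#'   `sigh_categories` (data frame: sigh id, time, linked-apnea count,
#'   category `"lt2"` / `"ge2"`)
#' @export
link_post_sigh_apneas <- function(apneas, sighs, params = event_params()) {
  n_s <- nrow(sighs); n_a <- nrow(apneas)
  sigh_ids <- seq_len(n_s)
  ap_ids <- n_s + seq_len(n_a)
  link <- rep(NA_integer_, n_a)
  for (i in seq_len(n_a)) {
    ok <- which(sighs$time_s < apneas$time_s[i] &
                  apneas$time_s[i] <= sighs$time_s + params$psa_window_s + 1e-9)
    if (length(ok)) link[i] <- ok[which.max(sighs$time_s[ok])]
  }
  kind <- ifelse(is.na(link), "SA", "PSA")
  ev <- event_table(
    kind = c(rep("sigh", n_s), kind),
    time_s = c(sighs$time_s, apneas$time_s),
    duration_s = c(rep(NA_real_, n_s), apneas$duration_s),
    missing_cycles = c(rep(NA_real_, n_s), apneas$missing_cycles),
    sigh_ref = c(rep(NA_integer_, n_s), sigh_ids[link]),
    id = c(sigh_ids, ap_ids))
  ev <- ev[order(ev$time_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  counts <- tabulate(link, nbins = n_s)
  cats <- data.frame(
    sigh_id = sigh_ids, time_s = sighs$time_s, n_linked = counts,
    category = ifelse(counts >= params$psa_category_boundary, "ge2", "lt2"),
    stringsAsFactors = FALSE)
  list(events = ev, sigh_categories = cats)
}

#' Score all respiratory events in a breath table
#'
#' Convenience wrapper running [detect_sighs()], [detect_apneas()] (with the
#' sigh breaths excluded from the cycle-duration baseline) and
#' [link_post_sigh_apneas()].
#'
#' @param table a [breath_table()]
#' @param params an [event_params()]
#' @return as [link_post_sigh_apneas()]
#' @export
score_events <- function(table, params = event_params()) {
  sighs <- detect_sighs(table, params)
  apneas <- detect_apneas(table, params,
                          sigh_idx = attr(sighs, "breath_idx"))
  link_post_sigh_apneas(apneas, sighs, params)
}

#' Per-epoch event rates and sigh-category percentages
#'
#' Rates are event counts divided by the epoch duration in hours (events are
#' assigned to the epoch containing their onset). Sigh-category percentages
#' are computed over the sighs of the epoch and sum to 100 whenever any sigh
#' exists; with zero sighs they are NA, never silent zeros.
#'
#' @param events a combined [event_table()] (from [score_events()])
#' @param sigh_categories the sigh-category table from [score_events()]
#' @param epochs an [epoch_table()]
#' @return data frame with one row per epoch: counts, `sa_per_h`,
#'   `psa_per_h`, `apneas_per_h`, `sighs_per_h`, `pct_sighs_lt2`,
#'   `pct_sighs_ge2`
#' @export
event_rates <- function(events, sigh_categories, epochs) {
  validate_epochs(epochs)
  if (any(epochs$end_s - epochs$start_s <= 0)) stop("zero-duration epoch")
  out <- lapply(seq_len(nrow(epochs)), function(e) {
    lo <- epochs$start_s[e]; hi <- epochs$end_s[e]
    h <- (hi - lo) / 3600
    inw <- events$time_s >= lo & events$time_s < hi
    n_sa <- sum(inw & events$kind == "SA")
    n_psa <- sum(inw & events$kind == "PSA")
    n_sigh <- sum(inw & events$kind == "sigh")
    sc <- sigh_categories[sigh_categories$time_s >= lo &
                            sigh_categories$time_s < hi, , drop = FALSE]
    pct_ge2 <- if (nrow(sc)) 100 * mean(sc$category == "ge2") else NA_real_
    data.frame(label = epochs$label[e], start_s = lo, end_s = hi,
               n_sa = n_sa, n_psa = n_psa, n_sighs = n_sigh,
               sa_per_h = n_sa / h, psa_per_h = n_psa / h,
               apneas_per_h = (n_sa + n_psa) / h, sighs_per_h = n_sigh / h,
               pct_sighs_lt2 = if (is.na(pct_ge2)) NA_real_ else 100 - pct_ge2,
               pct_sighs_ge2 = pct_ge2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spontaneous-apnea count in the first minute of recovery
#'
#' Counts `"SA"` events with time in `[recovery_start, recovery_start + 60)`.
#'
#' @param events a combined [event_table()]
#' @param epochs an [epoch_table()] containing a `"recovery"` epoch
#' @return integer count
#' @export
first_recovery_minute_sa <- function(events, epochs) {
  re <- epochs[epochs$label == "recovery", , drop = FALSE]
  if (!nrow(re)) stop("no recovery epoch defined")
  lo <- re$start_s[1L]
  sum(events$kind == "SA" & events$time_s >= lo & events$time_s < lo + 60)
}
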