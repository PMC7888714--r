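#' Segmentation parameters
#'
#' Detection is threshold-free in absolute units: all levels are expressed
#' relative to the local signal range estimated in blocks of
#' `baseline_window_s`, so detection is invariant to scaling or offsetting
#' the trace. Hysteresis (default 20% of the local amplitude) prevents noise
#' re-triggering; candidate breaths shorter than `min_breath_s` (default
#' 60 ms, above the physiological maximum mouse fR of ~1000/min) are
#' rejected as noise.
#'
#' @param smoothing_s moving-average smoothing window, s
#' @param hysteresis onset threshold as a fraction of the local amplitude
#' @param min_breath_s minimum breath duration, s
#' @param baseline_window_s window for the local baseline/amplitude blocks, s
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(smoothing_s = 0.015, hysteresis = 0.2,
                                min_breath_s = 0.06, baseline_window_s = 1) {
  vals <- c(smoothing_s, hysteresis, min_breath_s, baseline_window_s)
  if (any(vals <= 0)) stop("all segmentation parameters must be positive")
  if (min_breath_s >= baseline_window_s)
    stop("minimum breath duration must be below the baseline window")
  structure(list(smoothing_s = smoothing_s, hysteresis = hysteresis,
                 min_breath_s = min_breath_s,
                 baseline_window_s = baseline_window_s),
            class = "segmentation_params")
}

#' Detect breaths in a pressure trace
#'
#' Breaths are delimited by upward crossings, with hysteresis, of a threshold
#' set at `hysteresis` x the local amplitude above the local signal floor.
#' For each cycle the onset is refined to the local minimum preceding the
#' crossing (on the raw signal, so noiseless generated traces are recovered
#' to the sample), `insp_end` is the cycle maximum, the offset is the next
#' onset, and `P_T` is the peak height above the onset level. A flat trace
#' yields an empty table (not an error). If the sampling rate resolves fewer
#' than 10 samples per median cycle the table carries a `low_rate_warning`
#' attribute.
#'
#' @param trace a [pressure_trace()]
#' @param params a [segmentation_params()]
#' @return a [breath_table()] (with `v_t_ml` unset; see [calibrate_breaths()])
#' @export
detect_breaths <- function(trace, params = segmentation_params()) {
  x_raw <- trace$samples
  fs <- trace$sample_rate
  n <- length(x_raw)
  empty <- breath_table(data.frame(), animal = trace$animal,
                        provenance = list(params = params))
  if (n < 3L || diff(range(x_raw)) == 0) return(empty)
  if (n / fs < params$baseline_window_s)
    stop("trace shorter than the baseline window")

  k <- max(1L, round(params$smoothing_s * fs))
  x <- if (k > 1L) {
    sm <- as.numeric(stats::filter(x_raw, rep(1 / k, k), sides = 2))
    ifelse(is.na(sm), x_raw, sm)
  } else x_raw

  # local floor / ceiling per block, spread over neighbouring blocks so that
  # thresholds stay meaningful inside apneic gaps
  bs <- max(2L, round(params$baseline_window_s * fs))
  nb <- ceiling(n / bs)
  blk <- rep(seq_len(nb), each = bs)[seq_len(n)]
  lo <- tapply(x, blk, stats::quantile, probs = 0.05, names = FALSE)
  hi <- tapply(x, blk, stats::quantile, probs = 0.98, names = FALSE)
  spread <- function(v, f) vapply(seq_len(nb), function(b)
    f(v[max(1L, b - 3L):min(nb, b + 3L)]), numeric(1L))
  lo_s <- spread(lo, min)
  hi_s <- spread(hi, max)
  amp <- hi_s - lo_s
  thr_hi <- (lo_s + params$hysteresis * amp)[blk]
  thr_lo <- (lo_s + 0.25 * params$hysteresis * amp)[blk]

  above <- x >= thr_hi
  ups <- which(above[-1L] & !above[-n]) + 1L
  if (!length(ups)) return(empty)
  low <- x <= thr_lo
  cum_low <- cumsum(low)

  min_gap <- params$min_breath_s * fs
  kept <- integer(length(ups)); nk <- 0L
  last <- 0L
  for (u in ups) {
    armed <- if (nk == 0L) cum_low[u - 1L] > 0L else
      cum_low[u - 1L] > cum_low[last]
    if (!armed) next
    if (nk > 0L && (u - last) < min_gap) next
    nk <- nk + 1L; kept[nk] <- u; last <- u
  }
  if (nk == 0L) return(empty)
  ups <- kept[seq_len(nk)]

  # refine each crossing back to the preceding raw-signal local minimum
  onsets <- integer(nk)
  for (i in seq_len(nk)) {
    j <- ups[i]
    floor_idx <- if (i == 1L) 1L else onsets[i - 1L] + 1L
    while (j > floor_idx && x_raw[j - 1L] < x_raw[j]) j <- j - 1L
    onsets[i] <- j
  }
  onsets <- unique(onsets)
  nb_breaths <- length(onsets)

  # close the final cycle at the trace end if its expiration has completed
  ends <- c(onsets[-1L], NA_integer_)
  if (nb_breaths >= 1L) {
    tail_min <- min(x[onsets[nb_breaths]:n])
    if (tail_min <= thr_lo[n]) ends[nb_breaths] <- n + 1L
  }
  ok <- !is.na(ends)
  onsets <- onsets[ok]; ends <- ends[ok]
  if (!length(onsets)) return(empty)

  m <- length(onsets)
  peak_idx <- integer(m); p_t <- numeric(m)
  for (i in seq_len(m)) {
    hi_i <- min(n, ends[i] - 1L)
    seg <- onsets[i]:hi_i
    peak_idx[i] <- seg[which.max(x_raw[seg])]
    p_t[i] <- x_raw[peak_idx[i]] - x_raw[onsets[i]]
  }

  onset_s <- (onsets - 1L) / fs
  offset_s <- (ends - 1L) / fs
  insp_end_s <- (peak_idx - 1L) / fs
  tab <- breath_table(data.frame(
    onset_s = onset_s, insp_end_s = insp_end_s, offset_s = offset_s,
    ti_s = insp_end_s - onset_s, te_s = offset_s - insp_end_s,
    ttot_s = offset_s - onset_s, p_t = p_t, v_t_ml = NA_real_),
    animal = trace$animal, provenance = list(params = params))
  if (stats::median(tab$ttot_s) * fs < 10) {
    attr(tab, "low_rate_warning") <- TRUE
    warning("sampling rate resolves fewer than 10 samples per breath cycle")
  }
  tab
}

#' Timing metrics over a window
#'
#' fR is the number of completed breaths whose onset falls in the half-open
#' window, scaled to breaths/min; T_i, T_e and T_TOT are means over those
#' breaths. An empty window returns NA metrics with `empty = TRUE` rather
#' than silent zeros.
#'
#' @param table a [breath_table()]
#' @param window numeric length-2 window `c(start_s, end_s)`
#' @return one-row data frame with `fr`, `ti_s`, `te_s`, `ttot_s`, `vt_ml`,
#'   `n`, `empty`
#' @export
timing_metrics <- function(table, window) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  sel <- table$onset_s >= window[1L] & table$onset_s < window[2L]
  nw <- sum(sel)
  if (nw == 0L) {
    return(data.frame(fr = NA_real_, ti_s = NA_real_, te_s = NA_real_,
                      ttot_s = NA_real_, vt_ml = NA_real_, n = 0L,
                      empty = TRUE))
  }
  data.frame(fr = nw * 60 / (window[2L] - window[1L]),
             ti_s = mean(table$ti_s[sel]), te_s = mean(table$te_s[sel]),
             ttot_s = mean(table$ttot_s[sel]),
             vt_ml = mean(table$v_t_ml[sel]), n = nw, empty = FALSE)
}
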