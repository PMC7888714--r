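# shared fixtures, built in code at test time

default_env <- function() environment_record(ta_c = 25, pb_mmhg = 760,
                                             rh = 0.4, flow_ml_min = 300,
                                             chamber_ml = 200)

make_train <- function(fr = 120, duration_s = 60, vt_ml = 0.2,
                       ti_frac = 0.4, noise_sd = 0, amp_cv = 0, seed = 1) {
  simulate_breath_train(
    breath_profile(fr = fr, vt_ml = vt_ml, ti_frac = ti_frac,
                   amp_cv = amp_cv, noise_sd = noise_sd),
    duration_s, env = default_env(), seed = seed)
}

# a preset with sensor noise switched off, for exact-closure checks
noiseless_preset <- function(name) {
  p <- cohort_preset(name)
  p$noise_frac <- 0
  p
}

# independent naive O(n^2) sigh-apnea linkage used as an oracle
naive_psa_link <- function(apnea_times, sigh_times, window_s = 20) {
  vapply(apnea_times, function(at) {
    best <- NA_integer_
    for (j in seq_along(sigh_times)) {
      if (sigh_times[j] < at && at <= sigh_times[j] + window_s + 1e-9) {
        if (is.na(best) || sigh_times[j] > sigh_times[best]) best <- j
      }
    }
    best
  }, integer(1))
}

# independent brute-force breath counter: upward crossings of the midrange
# level, armed below the 25%-range level
naive_breath_count <- function(x) {
  lo <- min(x); hi <- max(x)
  thr <- lo + 0.5 * (hi - lo)
  arm <- lo + 0.25 * (hi - lo)
  armed <- TRUE; count <- 0L
  for (i in seq_along(x)) {
    if (x[i] <= arm) armed <- TRUE
    if (armed && x[i] >= thr) {
      count <- count + 1L
      armed <- FALSE
    }
  }
  count
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_set <- function(set, R) {
  xyz <- as.matrix(set[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
  landmark_set(data.frame(name = set$name, x_mm = xyz[, 1], y_mm = xyz[, 2],
                          z_mm = xyz[, 3]),
               animal = attr(set, "animal"),
               replicate = attr(set, "replicate"))
}

# six-animal triplicate landmark study: per-landmark anatomical spread
# between animals, rater jitter within animals
make_landmark_study <- function(seed = 1, n_animals = 6, n_reps = 3,
                                between_frac = 0.10, jitter_frac = 0.01) {
  tpl <- mouse_skull_template()
  scale_mm <- mean(dist(as.matrix(tpl[, c("x_mm", "y_mm", "z_mm")])))
  sets <- list()
  for (a in seq_len(n_animals)) {
    anat <- simulate_landmark_sets(tpl, rater_jitter = between_frac * scale_mm,
                                   n_reps = 1, seed = 7777 * seed + a)[[1]]
    sets <- c(sets, simulate_landmark_sets(anat,
                                           rater_jitter = jitter_frac * scale_mm,
                                           n_reps = n_reps,
                                           seed = 1000 * seed + a,
                                           animal = paste0("m", a)))
  }
  sets
}

# one distance and one angle for the reliability study; the angle has long
# rays (>= 10 mm) and sits well away from 0/180, so neither ray collapse nor
# folding at the boundary distorts its error propagation
study_defs <- function() {
  list(measurement_def("facial_length", "distance", c("nasale", "nasion")),
       measurement_def("vault_base_angle", "angle3",
                       c("bregma", "nasale", "basion"), plane = "sagittal"))
}
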