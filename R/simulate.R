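# Synthetic bipedal-stance trials with known per-foot ground truth.
#
# Each trial reproduces the device protocol: >= 3 s recorded without load
# (tare window), the subject steps on, performs a marker squat (start
# trigger), then ~30 s of exercise. Per-foot CoP/Fz truth is constructed
# first; the global state is its exact load-weighted composition; sensor
# signals follow from the bilinear forward model plus Gaussian noise.
#
# The subject-level `strategy` parameter in [0, 1] blends between motion
# that satisfies the analytical split hypothesis exactly (strategy 0) and
# individual-foot motion that violates it (strategy 1): antiphase per-foot
# AP excursions that cancel in the global CoP, and per-foot ML excursions
# smaller than the hypothesis predicts.

#' Subject profile
#'
#' @param weight_kg body mass, kg.
#' @param foot_length foot length, mm.
#' @param foot_width foot (ball) width, mm.
#' @param dy half-separation of the sole midlines, mm.
#' @param sw sole width, mm.
#' @param strategy in `[0, 1]`: 0 = motion conforms exactly to the
#'   analytical hypothesis, 1 = maximal individual-foot strategy.
#' @param seed subject-level RNG seed.
#' @param id subject identifier.
#' @return A list of class `subject_profile` (includes `weight_n`).
#' @export
subject_profile <- function(weight_kg = 76.76, foot_length = 255,
                            foot_width = 100, dy = 100, sw = 100,
                            strategy = 0, seed = 1L, id = 1L) {
  for (nm in c("weight_kg", "foot_length", "foot_width", "dy", "sw")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  if (strategy < 0 || strategy > 1) {
    stop_invalid("`strategy` must lie in [0, 1]", "copsplit_invalid_parameter")
  }
  structure(list(id = id, weight_kg = weight_kg,
                 weight_n = weight_kg * 9.80665,
                 foot_length = foot_length, foot_width = foot_width,
                 dy = dy, sw = sw, strategy = strategy,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' @rdname subject_profile
#' @param subject a [subject_profile()].
#' @return `subject_refs()` returns the [normalization_refs()] of a subject.
#' @export
subject_refs <- function(subject) {
  normalization_refs(subject$foot_length, subject$foot_width, subject$weight_n)
}

exercise_kinds <- c("STC", "AP", "ML", "ROT", "RND")

default_amplitudes <- function(kind) {
  switch(kind,
    STC = list(x = 5, y = 3),
    AP  = list(x = 60, y = 3),
    ML  = list(y = 100, x_strategy = 40, x_jitter = 5),
    ROT = list(x = 60, y = 1.5, x_jitter = 1),
    RND = list(x = 30, y = 40)
  )
}

#' Exercise specification
#'
#' The five stance exercises: `STC` static hold; `AP` slow forward-backward
#' centre-of-mass displacement with equal load; `ML` side-to-side
#' displacement alternating the load between the feet; `ROT` trunk rotation
#' loading one foot's toe and the other's heel (per-foot AP CoPs in
#' antiphase, nearly zero global AP motion); `RND` random movement without
#' lifting the feet.
#'
#' @param kind one of `"STC", "AP", "ML", "ROT", "RND"`.
#' @param duration exercise length in seconds (default 30).
#' @param rate sampling rate in Hz (default 1000, the sensor bandwidth
#'   scale).
#' @param freq main waveform frequency in Hz for the volitional movements
#'   (default 0.25, within the quasi-static regime).
#' @param amplitude named list of amplitude parameters (mm); `NULL` for the
#'   per-kind defaults.
#' @param sway_band frequency band of the involuntary postural sway
#'   component, Hz (default `c(0.5, 1)`).
#' @param sway_amp peak amplitude of the band-limited sway jitter, mm.
#' @return A list of class `exercise_spec`.
#' @export
exercise_spec <- function(kind, duration = 30, rate = 1000, freq = 0.25,
                          amplitude = NULL, sway_band = c(0.5, 1),
                          sway_amp = 2) {
  kind <- match.arg(kind, exercise_kinds)
  check_number(duration, "duration", positive = TRUE)
  check_number(rate, "rate", positive = TRUE)
  amp <- default_amplitudes(kind)
  if (!is.null(amplitude)) amp[names(amplitude)] <- amplitude
  structure(list(kind = kind, duration = duration, rate = rate, freq = freq,
                 amplitude = amp, sway_band = sway_band, sway_amp = sway_amp),
            class = "exercise_spec")
}

# Band-limited unit-peak noise: sum of n_comp sinusoids with frequencies
# drawn in `band`, random phases and amplitudes, rescaled to max |x| = 1.
# Consumes the current RNG stream (deterministic under set.seed).
band_limited_signal <- function(n, rate, band = c(0.5, 1), n_comp = 8L) {
  t <- (seq_len(n) - 1L) / rate
  f <- runif(n_comp, band[1L], band[2L])
  ph <- runif(n_comp, 0, 2 * pi)
  a <- runif(n_comp, 0.5, 1)
  x <- rowSums(vapply(seq_len(n_comp),
                      function(k) a[k] * sin(2 * pi * f[k] * t + ph[k]),
                      numeric(n)))
  x / max(abs(x))
}

# C2-continuous 0 -> 1 ramp (smootherstep); keeps the 10 Hz zero-phase
# filter from leaving measurable residuals at the phase transitions
.smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

# C3-continuous 0 -> 1 -> 0 bump on s in [0, 1]
.smoothbump <- function(s) sin(pi * pmin(pmax(s, 0), 1))^4

# smooth 0 -> 1 envelope over `len` seconds, then 1
.envelope <- function(t_local, len = 2) {
  .smoothstep(t_local / len)
}

# antiphase per-foot pair that cancels exactly in the load-weighted global
# mean: left = 2 a LF, right = -2 a (1 - LF)
.antiphase <- function(a, lf) {
  list(left = 2 * a * lf, right = -2 * a * (1 - lf))
}

#' Generate one synthetic stance trial
#'
#' Builds per-foot ground-truth trajectories for the requested exercise,
#' composes the exact global trajectory, and synthesises sensor-level
#' recordings for the lower plate and both upper plates via the bilinear
#' forward model plus additive Gaussian sensor noise. The timeline prepends
#' 3 s of zero load (tare window), a load ramp, a hold, and a marker squat;
#' the exercise starts at `meta$exercise_start_s` (8 s).
#'
#' Deterministic per `(seed)`: the same seed reproduces the trial
#' bit-identically.
#'
#' @param subject a [subject_profile()].
#' @param spec an [exercise_spec()].
#' @param repetition repetition number (enters the default seed derivation).
#' @param noise_sd additive Gaussian sensor noise per channel, N
#'   (default 0.5).
#' @param geom a [stance_geometry()]; default derives one from the
#'   subject's `dy` and `sw`.
#' @param seed trial seed; default derived from the subject seed, exercise
#'   kind and repetition.
#' @return A list of class `synthetic_trial` with elements `truth_left`,
#'   `truth_right`, `global_cop` (exact composition), `lower_plate`,
#'   `upper_left`, `upper_right` ([plate_recording()]s) and `meta`.
#' @export
generate_trial <- function(subject, spec, repetition = 1L, noise_sd = 0.5,
                           geom = NULL, seed = NULL) {
  if (is.null(geom)) geom <- stance_geometry(dy = subject$dy, sw = subject$sw)
  if (is.null(seed)) {
    kind_idx <- match(spec$kind, exercise_kinds)
    seed <- derive_seed(subject$seed, kind_idx * 100L + repetition)
  }
  set.seed(seed)
  dy <- subject$dy; sw <- subject$sw; s <- subject$strategy
  W <- subject$weight_n
  bos <- dy + sw / 2 # base-of-support half width
  rate <- spec$rate
  # timeline phases (seconds)
  t_zero <- 3; t_ramp <- 0.5; t_hold1 <- 2.5; t_squat <- 1.5; t_hold2 <- 0.5
  t_ex0 <- t_zero + t_ramp + t_hold1 + t_squat + t_hold2 # = 8
  n <- round((t_ex0 + spec$duration) * rate)
  t <- (seq_len(n) - 1L) / rate
  ex <- t >= t_ex0
  n_ex <- sum(ex)
  t_ex <- t[ex] - t_ex0

  # --- total vertical force profile -------------------------------------
  fz_tot <- numeric(n)
  ramp <- t >= t_zero & t < t_zero + t_ramp
  fz_tot[ramp] <- W * .smoothstep((t[ramp] - t_zero) / t_ramp)
  fz_tot[t >= t_zero + t_ramp] <- W
  squat <- t >= t_zero + t_ramp + t_hold1 & t < t_zero + t_ramp + t_hold1 + t_squat
  fz_tot[squat] <- W * (1 - 0.3 *
                          .smoothbump((t[squat] - t_zero - t_ramp - t_hold1) / t_squat))

  # --- exercise-phase global target paths -------------------------------
  env <- .envelope(t_ex)
  amp <- spec$amplitude
  jit <- function(a, band = spec$sway_band) {
    a * band_limited_signal(n_ex, rate, band) * env
  }
  wave <- function(a, phase = 0) a * sin(2 * pi * spec$freq * t_ex + phase) * env
  x_g <- y_g <- numeric(n_ex) # conforming global paths
  anti_x <- NULL # strategy-scaled antiphase AP component (violates hypothesis)
  shrink <- 0 # strategy-scaled reduction of per-foot ML motion
  anti_y_amp <- 0
  switch(spec$kind,
    STC = {
      x_g <- jit(amp$x); y_g <- jit(amp$y)
      anti_y_amp <- 2
    },
    AP = {
      x_g <- wave(amp$x) + jit(spec$sway_amp)
      y_g <- jit(amp$y)
    },
    ML = {
      y_g <- wave(amp$y) + jit(spec$sway_amp)
      x_g <- jit(amp$x_jitter)
      anti_x <- s * amp$x_strategy * sin(2 * pi * spec$freq * t_ex + runif(1, 0, 2 * pi)) * env
      shrink <- s
      anti_y_amp <- 2
    },
    ROT = {
      x_g <- jit(amp$x_jitter)
      y_g <- jit(amp$y)
      anti_x <- s * amp$x * sin(2 * pi * spec$freq * t_ex) * env
    },
    RND = {
      x_g <- jit(amp$x, band = c(0.1, spec$sway_band[2L]))
      y_g <- jit(amp$y, band = c(0.1, spec$sway_band[2L]))
      anti_x <- s * 20 * band_limited_signal(n_ex, rate, c(0.1, 1)) * env
      shrink <- s / 2
      anti_y_amp <- 2
    }
  )
  if (max(abs(y_g)) > bos) {
    stop_invalid("exercise amplitude exceeds the base of support",
                 "copsplit_invalid_spec")
  }

  # --- per-foot truth over the full timeline ----------------------------
  lf <- rep(0.5, n)
  lf[ex] <- 0.5 + y_g / (2 * dy + sw)
  prop <- (1 - shrink) * sw / (2 * dy + sw)
  y_l <- rep(-dy, n); y_r <- rep(dy, n)
  y_l[ex] <- y_g * prop - dy
  y_r[ex] <- y_g * prop + dy
  x_l <- x_r <- numeric(n)
  x_l[ex] <- x_g; x_r[ex] <- x_g
  if (!is.null(anti_x)) {
    ap <- .antiphase(anti_x, lf[ex])
    x_l[ex] <- x_l[ex] + ap$left
    x_r[ex] <- x_r[ex] + ap$right
  }
  if (anti_y_amp > 0 && s > 0) {
    ay <- .antiphase(s * anti_y_amp * band_limited_signal(n_ex, rate, spec$sway_band) * env,
                     lf[ex])
    y_l[ex] <- y_l[ex] + ay$left
    y_r[ex] <- y_r[ex] + ay$right
  }
  fz_r <- fz_tot * lf
  fz_l <- fz_tot - fz_r
  thr <- geom_threshold(geom)
  valid_l <- fz_l >= thr; valid_r <- fz_r >= thr
  truth_left <- grf_trajectory(t, x_l, y_l, fz_l, valid_l)
  truth_right <- grf_trajectory(t, x_r, y_r, fz_r, valid_r)
  # sole containment check (exercise window)
  half_len <- subject$foot_length / 2
  if (any(abs(y_l[ex] + dy) > sw / 2 + 1e-9) ||
      any(abs(y_r[ex] - dy) > sw / 2 + 1e-9) ||
      any(abs(c(x_l[ex], x_r[ex])) > half_len + 1e-9)) {
    stop_invalid("per-foot CoP left its sole rectangle; reduce amplitudes",
                 "copsplit_invalid_spec")
  }
  global_cop <- reconstruct_global(truth_left, truth_right, fz_threshold = thr)

  # --- sensor-level recordings ------------------------------------------
  make_rec <- function(traj, plate) {
    x <- ifelse(traj$fz > 0, traj$x, mean(geom$plates[[plate]]$sensor_xy[, 1L]))
    y <- ifelse(traj$fz > 0, traj$y, mean(geom$plates[[plate]]$sensor_xy[, 2L]))
    f <- .bilinear_forces(x, y, traj$fz, geom$plates[[plate]]$sensor_xy)
    if (noise_sd > 0) f <- f + matrix(rnorm(length(f), sd = noise_sd), nrow(f))
    plate_recording(t, f, rate, plate = plate)
  }
  glob_for_plate <- grf_trajectory(
    t, ifelse(global_cop$fz > 0, global_cop$x, 0),
    ifelse(global_cop$fz > 0, global_cop$y, 0),
    global_cop$fz, global_cop$valid)
  lower <- make_rec(glob_for_plate, "lower")
  up_l <- make_rec(truth_left, "upper_left")
  up_r <- make_rec(truth_right, "upper_right")

  structure(list(
    truth_left = truth_left, truth_right = truth_right,
    global_cop = global_cop,
    lower_plate = lower, upper_left = up_l, upper_right = up_r,
    meta = list(subject = subject, exercise = spec$kind, spec = spec,
                repetition = repetition, seed = seed, noise_sd = noise_sd,
                exercise_start_s = t_ex0, geometry = geom)
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> subject %s, %s rep %d, %d samples at %g Hz, seed %d\n",
              x$meta$subject$id, x$meta$exercise, x$meta$repetition,
              length(x$truth_left$time), x$meta$spec$rate, x$meta$seed))
  invisible(x)
}

#' Truth as a split result over the exercise window
#'
#' @param trial a [synthetic_trial()][generate_trial()].
#' @param from_time keep samples with `time >= from_time`; default the
#'   exercise start.
#' @param to_time keep samples with `time <= to_time` (default: all).
#' @return A [split_result()] holding the per-foot ground truth.
#' @export
trial_truth_split <- function(trial, from_time = trial$meta$exercise_start_s,
                              to_time = Inf) {
  keep <- trial$truth_left$time >= from_time & trial$truth_left$time <= to_time
  l <- trial$truth_left[keep, ]; r <- trial$truth_right[keep, ]
  split_result(l$time,
               grf_trajectory(l$time, l$x, l$y, l$fz, l$valid),
               grf_trajectory(r$time, r$x, r$y, r$fz, r$valid))
}

#' Plan and generate a synthetic cohort
#'
#' `cohort_plan()` draws the subject profiles (weight ~ Normal(76.76,
#' 14.07) kg truncated at +/- 2 SD; strategy ~ Uniform over
#' `strategy_range`) and lays out the full factorial subjects x exercises x
#' repetitions with per-trial seeds derived from `master_seed`.
#' `generate_cohort()` additionally realises all trials (memory scales with
#' `n_subjects * reps * length(exercises)`; for large cohorts keep
#' `realize = FALSE` and call [realize_trial()] per row).
#'
#' @param n_subjects number of subjects (default 10).
#' @param reps repetitions per exercise (default 5).
#' @param exercises character vector of exercise kinds.
#' @param master_seed single integer governing all randomness.
#' @param weight_mean,weight_sd cohort weight distribution, kg.
#' @param strategy_range range of the uniform strategy draw (use
#'   `c(0, 0)` for a fully hypothesis-conforming cohort).
#' @param noise_sd sensor noise per channel, N.
#' @param duration,rate,freq passed to [exercise_spec()].
#' @param foot_length,foot_width,dy,sw cohort anthropometric defaults, mm.
#' @param realize if `TRUE`, generate all trials now.
#' @return A list of class `cohort` with `profiles`, `plan` (tibble with
#'   one row per trial: subject, exercise, repetition, seed) and, if
#'   realised, `trials`.
#' @export
cohort_plan <- function(n_subjects = 10L, reps = 5L,
                        exercises = exercise_kinds, master_seed = 1L,
                        weight_mean = 76.76, weight_sd = 14.07,
                        strategy_range = c(0, 1), noise_sd = 0.5,
                        duration = 30, rate = 1000, freq = 0.25,
                        foot_length = 255, foot_width = 100,
                        dy = 100, sw = 100) {
  if (n_subjects < 1L || reps < 1L) {
    stop_invalid("need at least one subject and one repetition",
                 "copsplit_invalid_parameter")
  }
  set.seed(derive_seed(master_seed, 0L))
  draw_weight <- function() {
    repeat {
      w <- rnorm(1L, weight_mean, weight_sd)
      if (abs(w - weight_mean) <= 2 * weight_sd) return(w)
    }
  }
  profiles <- lapply(seq_len(n_subjects), function(i) {
    subject_profile(weight_kg = draw_weight(),
                    foot_length = foot_length, foot_width = foot_width,
                    dy = dy, sw = sw,
                    strategy = runif(1L, strategy_range[1L], strategy_range[2L]),
                    seed = derive_seed(master_seed, i), id = i)
  })
  plan <- expand.grid(repetition = seq_len(reps), exercise = exercises,
                      subject = seq_len(n_subjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan <- plan[, c("subject", "exercise", "repetition")]
  plan$seed <- vapply(seq_len(nrow(plan)), function(i) {
    derive_seed(master_seed,
                (plan$subject[i] * 10L + match(plan$exercise[i], exercise_kinds)) *
                  100L + plan$repetition[i])
  }, integer(1L))
  structure(list(profiles = profiles, plan = tibble::as_tibble(plan),
                 settings = list(noise_sd = noise_sd, duration = duration,
                                 rate = rate, freq = freq,
                                 master_seed = master_seed)),
            class = "cohort")
}

#' @rdname cohort_plan
#' @param cohort a `cohort` object.
#' @param row row index of `cohort$plan`.
#' @return `realize_trial()` returns the [generate_trial()] result for one
#'   plan row.
#' @export
realize_trial <- function(cohort, row) {
  p <- cohort$plan[row, ]
  st <- cohort$settings
  generate_trial(cohort$profiles[[p$subject]],
                 exercise_spec(p$exercise, duration = st$duration,
                               rate = st$rate, freq = st$freq),
                 repetition = p$repetition, noise_sd = st$noise_sd,
                 seed = p$seed)
}

#' @rdname cohort_plan
#' @param ... passed to `cohort_plan()`.
#' @export
generate_cohort <- function(..., realize = TRUE) {
  cohort <- cohort_plan(...)
  if (realize) {
    cohort$trials <- lapply(seq_len(nrow(cohort$plan)),
                            function(i) realize_trial(cohort, i))
  }
  cohort
}
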