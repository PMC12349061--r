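# Synthetic stance trials: determinism, hypothesis conformance, exercise
# signatures, cohort sampling and the noise-free forward-model consistency.

test_that("trials are bit-identical for the same seed", {
  sub <- subject_profile(strategy = 0.4, seed = 9)
  spec <- exercise_spec("RND", duration = 4)
  a <- generate_trial(sub, spec, repetition = 2)
  b <- generate_trial(sub, spec, repetition = 2)
  expect_identical(a$lower_plate$channels, b$lower_plate$channels)
  expect_identical(a$truth_left, b$truth_left)
  c <- generate_trial(sub, spec, repetition = 3)
  expect_false(identical(a$lower_plate$channels, c$lower_plate$channels))
})

test_that("zero-amplitude static trial is constant and split exactly", {
  sub <- subject_profile(strategy = 0, seed = 1)
  spec <- exercise_spec("STC", duration = 4,
                        amplitude = list(x = 0, y = 0), sway_amp = 0)
  tr <- generate_trial(sub, spec, noise_sd = 0)
  ex <- tr$truth_left$time >= tr$meta$exercise_start_s
  expect_equal(unique(tr$truth_left$x[ex]), 0)
  expect_equal(unique(tr$truth_left$fz[ex]), sub$weight_n / 2)
  # analytical split of the exact global recovers truth exactly
  g <- tr$global_cop[ex, ]
  sp <- split_trajectory(grf_trajectory(g$time, g$x, g$y, g$fz, g$valid),
                         tr$meta$geometry)
  expect_equal(sp$yL, tr$truth_left$y[ex], tolerance = 1e-12)
  expect_equal(sp$FzR, tr$truth_right$fz[ex], tolerance = 1e-12)
})

test_that("strategy-0 trials satisfy the analytical hypothesis exactly", {
  sub <- subject_profile(strategy = 0, seed = 2)
  for (kind in c("AP", "ML", "ROT", "RND")) {
    tr <- generate_trial(sub, exercise_spec(kind, duration = 4), noise_sd = 0)
    ex <- tr$truth_left$time >= tr$meta$exercise_start_s
    g <- tr$global_cop[ex, ]
    sp <- suppressWarnings(
      split_trajectory(grf_trajectory(g$time, g$x, g$y, g$fz, g$valid),
                       tr$meta$geometry))
    truth <- trial_truth_split(tr)
    for (col in c("xL", "yL", "FzL", "xR", "yR", "FzR")) {
      expect_equal(sp[[col]], truth[[col]], tolerance = 1e-9,
                   label = paste(kind, col))
    }
  }
})

test_that("rotation trials cancel the per-foot AP motion globally", {
  sub <- subject_profile(strategy = 1, seed = 5)
  tr <- generate_trial(sub, exercise_spec("ROT", duration = 6), noise_sd = 0)
  ex <- tr$truth_left$time >= tr$meta$exercise_start_s
  foot_amp <- max(abs(tr$truth_left$x[ex]))
  glob_amp <- max(abs(tr$global_cop$x[ex]))
  expect_gt(foot_amp, 30) # the feet really move
  expect_lt(glob_amp, 0.05 * foot_amp)
})

test_that("mediolateral strategy shrinks per-foot ML motion and adds AP motion", {
  conform <- generate_trial(subject_profile(strategy = 0, seed = 6),
                            exercise_spec("ML", duration = 6), noise_sd = 0)
  strat <- generate_trial(subject_profile(strategy = 1, seed = 6),
                          exercise_spec("ML", duration = 6), noise_sd = 0)
  ex <- conform$truth_left$time >= 8
  ml_conform <- sd(conform$truth_right$y[ex])
  ml_strat <- sd(strat$truth_right$y[ex])
  expect_lt(ml_strat, 0.35 * ml_conform)
  expect_gt(sd(strat$truth_right$x[ex]), sd(conform$truth_right$x[ex]))
})

test_that("truth CoP spectra stay inside the sway band", {
  tr <- generate_trial(subject_profile(strategy = 0.5, seed = 8),
                       exercise_spec("ML", duration = 8), noise_sd = 0)
  ex <- tr$truth_left$time >= tr$meta$exercise_start_s
  for (sig in list(tr$truth_right$y[ex], tr$truth_right$x[ex],
                   tr$global_cop$y[ex])) {
    sig <- sig - mean(sig)
    if (sd(sig) < 1e-9) next
    sp <- stats::spec.pgram(stats::ts(sig, frequency = tr$meta$spec$rate),
                            plot = FALSE, taper = 0)
    hi <- sum(sp$spec[sp$freq > 2])
    expect_lt(hi / sum(sp$spec), 0.01)
  }
})

test_that("amplitudes beyond the base of support are rejected", {
  sub <- subject_profile(strategy = 0, seed = 1)
  expect_error(
    generate_trial(sub, exercise_spec("ML", duration = 4,
                                      amplitude = list(y = 200))),
    class = "copsplit_invalid_spec")
})

test_that("noise-free pipeline recovers the truth to instrument precision", {
  sub <- subject_profile(strategy = 0.7, seed = 4)
  tr <- generate_trial(sub, exercise_spec("ML", duration = 6), noise_sd = 0)
  proc <- analyze_trial(tr)
  # the measured per-foot trajectories equal the simulator truth
  ok <- proc$measured$valid & proc$truth$valid
  for (col in c("xL", "yL", "xR", "yR")) {
    expect_lt(max(abs(proc$measured[[col]][ok] - proc$truth[[col]][ok])), 0.01)
  }
  for (col in c("FzL", "FzR")) {
    expect_lt(max(abs(proc$measured[[col]][ok] - proc$truth[[col]][ok])), 0.01)
  }
})

test_that("cohorts are factorial, reproducible and match the stated weights", {
  co <- generate_cohort(n_subjects = 2, reps = 2, exercises = c("STC", "AP"),
                        master_seed = 3, duration = 2, rate = 200)
  expect_identical(nrow(co$plan), 8L) # 2 x 2 x 2 factorial
  expect_identical(length(co$trials), 8L)
  co2 <- generate_cohort(n_subjects = 2, reps = 2, exercises = c("STC", "AP"),
                         master_seed = 3, duration = 2, rate = 200)
  expect_identical(co$plan, co2$plan)
  expect_identical(co$trials[[5]]$lower_plate$channels,
                   co2$trials[[5]]$lower_plate$channels)

  # weight distribution: mean within 3 SE over a large cohort of profiles
  big <- cohort_plan(n_subjects = 1000, reps = 1, exercises = "STC",
                     master_seed = 12)
  w <- vapply(big$profiles, function(p) p$weight_kg, numeric(1))
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 76.76), 3 * se)
  expect_true(all(abs(w - 76.76) <= 2 * 14.07))
  s <- vapply(big$profiles, function(p) p$strategy, numeric(1))
  expect_true(all(s >= 0 & s <= 1))
})
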