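# CoP from corner sensors, the bilinear inverse, and the simulated
# point-load validation.

geom <- stance_geometry()

test_that("compute_cop recovers symmetric and single-sensor loads", {
  # equal forces at the four corners of the lower plate -> CoP at origin
  rec <- const_recording(rep(100, 4))
  traj <- compute_cop(rec, geom, "lower")
  expect_equal(traj$x, rep(0, 10))
  expect_equal(traj$y, rep(0, 10))
  expect_equal(traj$fz, rep(400, 10))

  # all load on the (+x,+y) sensor of the right upper plate at (230, 220)
  rec <- const_recording(c(400, 0, 0, 0), plate = "upper_right")
  traj <- compute_cop(rec, geom, "upper_right")
  expect_equal(traj$x[1], 230)
  expect_equal(traj$y[1], 220)
  expect_equal(traj$fz[1], 400)
})

test_that("compute_cop matches the weighted-moment formula", {
  # corners (+-200, +-150), forces (30, 10, 90, 270) in canonical order
  g <- stance_geometry(lower_extent = c(-220, 220, -170, 170), sensor_inset = 20)
  f <- c(30, 10, 90, 270)
  rec <- const_recording(f)
  traj <- compute_cop(rec, g, "lower")
  expect_equal(traj$fz[1], 400)
  expect_equal(traj$x[1], (30 + 10 - 90 - 270) * 200 / 400) # -160
  expect_equal(traj$y[1], (30 - 10 + 90 - 270) * 150 / 400) # -60
  oracle <- naive_cop(f, g$plates$lower$sensor_xy)
  expect_equal(c(traj$x[1], traj$y[1], traj$fz[1]), unname(oracle))
})

test_that("low load is flagged invalid and channel mismatch errors", {
  rec <- const_recording(rep(2, 4)) # 8 N total, below the 20 N threshold
  traj <- compute_cop(rec, geom)
  expect_false(any(traj$valid))
  expect_true(all(is.na(traj$x)))
  expect_equal(traj$fz, rep(8, 10)) # Fz itself is still the channel sum

  rec3 <- plate_recording((0:9) / 100, matrix(1, 10, 3), 100)
  expect_error(compute_cop(rec3, geom), class = "copsplit_config_error")
})

test_that("negative channels are clipped with a warning", {
  rec <- const_recording(c(100, 100, 100, -5))
  expect_warning(traj <- compute_cop(rec, geom), class = "copsplit_clipped_negative")
  expect_equal(traj$fz[1], 300)
})

test_that("bilinear distribution matches hand-evaluated weights", {
  # CoP at the rectangle centre: four equal forces
  f <- distribute_to_sensors(c(0, 0, 800), geom, "lower")
  expect_equal(as.numeric(f), rep(200, 4))

  # CoP at the (+x,+y) corner: all load on that sensor
  f <- distribute_to_sensors(c(230, 280, 400), geom, "lower")
  expect_equal(as.numeric(f), c(400, 0, 0, 0))

  # (u, v) = (0.25, 0.5), Fz = 400: near corners get 150 each, far 50 each
  sxy <- geom$plates$lower$sensor_xy
  x <- min(sxy[, 1]) + 0.25 * diff(range(sxy[, 1]))
  y <- min(sxy[, 2]) + 0.5 * diff(range(sxy[, 2]))
  f <- distribute_to_sensors(c(x, y, 400), geom, "lower")
  expect_equal(as.numeric(f), c(50, 50, 150, 150))

  expect_error(distribute_to_sensors(c(500, 0, 100), geom, "lower"),
               class = "copsplit_out_of_support")
})

test_that("compute_cop inverts distribute_to_sensors over random states", {
  set.seed(101)
  n <- 500
  sxy <- geom$plates$lower$sensor_xy
  x <- runif(n, min(sxy[, 1]), max(sxy[, 1]))
  y <- runif(n, min(sxy[, 2]), max(sxy[, 2]))
  fz <- runif(n, 50, 1200)
  f <- distribute_to_sensors(grf_trajectory((seq_len(n) - 1) / 100, x, y, fz),
                             geom, "lower")
  rec <- plate_recording((seq_len(n) - 1) / 100, f, 100)
  traj <- compute_cop(rec, geom, "lower")
  expect_equal(traj$x, x, tolerance = 1e-9)
  expect_equal(traj$y, y, tolerance = 1e-9)
  expect_equal(traj$fz, fz, tolerance = 1e-12)
  # CoP stays inside the convex hull (here: the sensor rectangle)
  expect_true(all(traj$x >= min(sxy[, 1]) - 1e-9 & traj$x <= max(sxy[, 1]) + 1e-9))
  expect_true(all(traj$y >= min(sxy[, 2]) - 1e-9 & traj$y <= max(sxy[, 2]) + 1e-9))
})

test_that("point-load fixture is exact without noise and scale-invariant", {
  fx <- point_load_fixture(geom, noise_sd = 0)
  expect_identical(nrow(fx), 12L)
  expect_equal(max(fx$err_mm), 0, tolerance = 1e-9)

  # same point, 200 N vs 1000 N: identical recovered CoP (scale invariance)
  pts <- data.frame(x = c(100, 100), y = c(120, 120), f = c(200, 1000))
  fx <- point_load_fixture(geom, pts, plate = "upper_right", noise_sd = 0)
  expect_equal(fx$x_rec[1], fx$x_rec[2], tolerance = 1e-12)
  expect_equal(fx$y_rec[1], fx$y_rec[2], tolerance = 1e-12)

  # uniform +1 N bias on a centred 400 N load cancels in the moment ratio
  f <- distribute_to_sensors(c(0, 120, 400), geom, "upper_right") + 1
  rec <- plate_recording(0, f, 100, plate = "upper_right")
  traj <- compute_cop(rec, geom, "upper_right")
  expect_equal(c(traj$x, traj$y), c(0, 120), tolerance = 1e-9)
})

test_that("geometry validates its invariants and round-trips via YAML", {
  expect_error(stance_geometry(dy = -5), class = "copsplit_invalid_parameter")
  # left plate is the mirror image of the right one
  expect_equal(geom$plates$upper_left$extent[3:4],
               -rev(geom$plates$upper_right$extent[3:4]))
  path <- tempfile(fileext = ".yaml")
  write_stance_geometry(geom, path)
  back <- read_stance_geometry(path)
  expect_equal(back$plates, geom$plates)
  expect_equal(back$dy, geom$dy)
})
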