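#' GRF trajectory
#'
#' Time series of `(xCoP, yCoP, Fz)` states for a whole plate or a single
#' foot. Stored as a data frame with columns `time` (s), `x`, `y` (mm),
#' `fz` (N) and `valid` (logical; CoP undefined where the load is below the
#' validity threshold).
#'
#' @param time sample times, s.
#' @param x,y CoP coordinates, mm (`NA` where invalid).
#' @param fz vertical force, N (must be `>= 0` where finite).
#' @param valid logical validity flags.
#' @return A data frame of class `grf_trajectory`.
#' @export
grf_trajectory <- function(time, x, y, fz, valid = rep(TRUE, length(time))) {
  n <- length(time)
  if (any(lengths(list(x, y, fz, valid)) != n)) {
    stop_invalid("all trajectory columns must share one length",
                 "copsplit_invalid_input")
  }
  if (any(fz[is.finite(fz)] < -1e-9)) {
    stop_invalid("fz must be non-negative", "copsplit_invalid_input")
  }
  structure(data.frame(time = time, x = x, y = y, fz = fz, valid = valid),
            class = c("grf_trajectory", "data.frame"))
}

#' Centre of pressure from four uniaxial corner sensors
#'
#' Per sample, with sensor forces `Fi` at planar positions `(xi, yi)`:
#' `Fz = sum(Fi)`, `xCoP = sum(Fi * xi) / Fz`, `yCoP = sum(Fi * yi) / Fz`
#' (the resultant moment of the vertical forces). Samples whose total load
#' falls below the geometry's `fz_threshold` are flagged invalid and their
#' CoP set to `NA`. Negative channel values (possible after noise injection;
#' uniaxial sensors cannot pull) are clipped at zero with a warning.
#'
#' @param rec a preprocessed [plate_recording()].
#' @param geom a [stance_geometry()].
#' @param plate which plate's sensor layout to use; defaults to
#'   `rec$plate`.
#' @return A [grf_trajectory()].
#' @export
compute_cop <- function(rec, geom, plate = rec$plate) {
  if (is.null(geom$plates[[plate]])) {
    stop_invalid(sprintf("geometry has no plate '%s'", plate),
                 "copsplit_config_error")
  }
  sxy <- geom$plates[[plate]]$sensor_xy
  ch <- rec$channels
  if (ncol(ch) != nrow(sxy)) {
    stop_invalid(sprintf("recording has %d channels but plate '%s' declares %d sensors",
                         ncol(ch), plate, nrow(sxy)),
                 "copsplit_config_error")
  }
  n_neg <- sum(ch < 0)
  if (n_neg > 0L) {
    warn(sprintf("clipped %d negative sensor samples at 0 N for CoP computation", n_neg),
         class = "copsplit_clipped_negative")
    ch[ch < 0] <- 0
  }
  fz <- rowSums(ch)
  valid <- fz >= geom_threshold(geom)
  x <- as.numeric(ch %*% sxy[, 1L]) / fz
  y <- as.numeric(ch %*% sxy[, 2L]) / fz
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  grf_trajectory(rec$time, x, y, fz, valid)
}

# bilinear weights for states (x, y, fz) on the axis-aligned sensor
# rectangle; exact inverse of compute_cop
.bilinear_forces <- function(x, y, fz, sensor_xy, tol = 1e-9) {
  x_lo <- min(sensor_xy[, 1L]); x_hi <- max(sensor_xy[, 1L])
  y_lo <- min(sensor_xy[, 2L]); y_hi <- max(sensor_xy[, 2L])
  if (!isTRUE(all.equal(sort(unique(sensor_xy[, 1L])), c(x_lo, x_hi))) ||
      !isTRUE(all.equal(sort(unique(sensor_xy[, 2L])), c(y_lo, y_hi)))) {
    stop_invalid("sensors must form an axis-aligned rectangle",
                 "copsplit_config_error")
  }
  loaded <- is.finite(fz) & fz > 0
  u <- (x - x_lo) / (x_hi - x_lo)
  v <- (y - y_lo) / (y_hi - y_lo)
  bad <- loaded & (!is.finite(u) | !is.finite(v) |
                     u < -tol | u > 1 + tol | v < -tol | v > 1 + tol)
  if (any(bad)) {
    stop_invalid(sprintf("CoP outside the sensor rectangle for %d sample(s): a corner force would be negative",
                         sum(bad)),
                 "copsplit_out_of_support")
  }
  u <- pmin(pmax(u, 0), 1)
  v <- pmin(pmax(v, 0), 1)
  # canonical corner order (+x,+y), (+x,-y), (-x,+y), (-x,-y)
  w <- cbind(u * v, u * (1 - v), (1 - u) * v, (1 - u) * (1 - v))
  w[!loaded, ] <- 0
  f <- w * ifelse(loaded, fz, 0)
  colnames(f) <- rownames(sensor_xy)
  f
}

#' Distribute a GRF state onto the four corner sensors
#'
#' Forward model of the plate (exact inverse of [compute_cop()] for
#' rectangular sensor layouts): the vertical load `fz` applied at the CoP is
#' shared between the corner sensors with bilinear weights
#' `fz * {(1-u)(1-v), ...}` where `(u, v)` are the CoP's normalised
#' coordinates inside the sensor rectangle. Used by the trial simulator and
#' the point-load validation fixture.
#'
#' @param state a [grf_trajectory()], or a numeric vector `c(x, y, fz)` for
#'   a single state.
#' @param geom a [stance_geometry()].
#' @param plate plate whose sensors receive the load.
#' @return A numeric matrix of sensor forces (N), one row per sample, in
#'   canonical corner order. Errors with class `copsplit_out_of_support` if
#'   a loaded CoP lies outside the sensor rectangle.
#' @export
distribute_to_sensors <- function(state, geom, plate = "lower") {
  if (is.numeric(state) && length(state) == 3L) {
    state <- grf_trajectory(0, state[1L], state[2L], state[3L])
  }
  sxy <- geom$plates[[plate]]$sensor_xy
  .bilinear_forces(state$x, state$y, state$fz, sxy)
}

#' Simulated point-load validation of a plate
#'
#' Emulates the bench validation of the device: known static loads are
#' applied at known positions (by [distribute_to_sensors()], optionally with
#' additive Gaussian sensor noise), the CoP is recovered with
#' [compute_cop()], and the Euclidean position error is reported per point.
#'
#' The default protocol applies 12 loads spanning 200-1000 N on a 4 x 3
#' grid inside the sensor rectangle.
#'
#' @param geom a [stance_geometry()].
#' @param load_points data frame with columns `x`, `y` (mm) and `f` (N), or
#'   `NULL` for the default 12-point grid.
#' @param plate plate under test.
#' @param noise_sd additive Gaussian sensor noise, N (default 0).
#' @param n_samples static samples recorded per point; the recovered CoP is
#'   their average (default 1).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A [tibble::tibble] with the applied point, load, recovered CoP
#'   and `err_mm`, plus attributes `mean_err` and `max_err`.
#' @export
point_load_fixture <- function(geom, load_points = NULL, plate = "upper_right",
                               noise_sd = 0, n_samples = 1L, seed = 1L) {
  sxy <- geom$plates[[plate]]$sensor_xy
  if (is.null(load_points)) {
    ext <- c(range(sxy[, 1L]), range(sxy[, 2L]))
    g <- expand.grid(u = c(0.2, 0.4, 0.6, 0.8), v = c(0.25, 0.5, 0.75))
    load_points <- data.frame(
      x = ext[1L] + g$u * (ext[2L] - ext[1L]),
      y = ext[3L] + g$v * (ext[4L] - ext[3L]),
      f = seq(200, 1000, length.out = nrow(g))
    )
  }
  if (noise_sd > 0) set.seed(seed)
  rows <- lapply(seq_len(nrow(load_points)), function(i) {
    p <- load_points[i, ]
    f <- .bilinear_forces(rep(p$x, n_samples), rep(p$y, n_samples),
                          rep(p$f, n_samples), sxy)
    if (noise_sd > 0) f <- f + matrix(rnorm(length(f), sd = noise_sd), nrow(f))
    rec <- plate_recording(seq_len(n_samples) - 1, f, rate = 1, plate = plate)
    traj <- suppressWarnings(compute_cop(rec, geom, plate))
    tibble::tibble(point = i, x = p$x, y = p$y, f = p$f,
                   x_rec = mean(traj$x), y_rec = mean(traj$y),
                   err_mm = sqrt((mean(traj$x) - p$x)^2 + (mean(traj$y) - p$y)^2))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_err") <- mean(out$err_mm)
  attr(out, "max_err") <- max(out$err_mm)
  out
}

#' Write a CoP trajectory as CSV
#'
#' Columns `time, xCoP_mm, yCoP_mm, Fz_N, valid`.
#' @param traj a [grf_trajectory()].
#' @param path file path.
#' @export
write_cop_csv <- function(traj, path) {
  df <- data.frame(time = traj$time, xCoP_mm = traj$x, yCoP_mm = traj$y,
                   Fz_N = traj$fz, valid = traj$valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
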