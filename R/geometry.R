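# Plate and stance geometry.
#
# Global frame: x anteroposterior (positive forward), y mediolateral
# (right foot at +y), origin at the centre of the lower plate. Each plate
# carries four uniaxial sensors near its corners; the canonical corner order
# is (+x,+y), (+x,-y), (-x,+y), (-x,-y) relative to the sensor rectangle
# centre, in both geometry objects and channel files.

corner_sensors <- function(extent, inset) {
  x_hi <- extent[2L] - inset; x_lo <- extent[1L] + inset
  y_hi <- extent[4L] - inset; y_lo <- extent[3L] + inset
  m <- cbind(x = c(x_hi, x_hi, x_lo, x_lo), y = c(y_hi, y_lo, y_hi, y_lo))
  rownames(m) <- c("pp", "pm", "mp", "mm")
  m
}

#' Stance and device geometry
#'
#' Describes the double-plate device and the prescribed foot placement: a
#' lower plate measuring the global reaction, and two upper plates (one per
#' foot). Feet are placed symmetrically with the sole midlines at
#' `y = +dy` (right) and `y = -dy` (left); `sw` is the sole width. The base
#' of support spans `|y| <= dy + sw/2`.
#'
#' Default plate sizes mirror the device scale: lower plate 600 x 500 mm
#' (y by x), upper plates 240 x 500 mm, sensors inset 20 mm from the plate
#' corners in the canonical order (+x,+y), (+x,-y), (-x,+y), (-x,-y).
#'
#' @param dy half-separation of the sole midlines, mm (> 0).
#' @param sw sole width, mm (> 0).
#' @param lower_extent,upper_right_extent plate rectangles
#'   `c(x_min, x_max, y_min, y_max)` in mm; the left upper plate is the
#'   mirror image of the right one across the x-axis.
#' @param sensor_inset sensor distance from each plate corner, mm.
#' @param fz_threshold total vertical force (N) below which the CoP is
#'   treated as undefined (the moment ratio is numerically unstable near
#'   zero load). Default 20 N.
#' @return An object of class `stance_geometry`.
#' @export
stance_geometry <- function(dy = 100, sw = 100,
                            lower_extent = c(-250, 250, -300, 300),
                            upper_right_extent = c(-250, 250, 0, 240),
                            sensor_inset = 20, fz_threshold = 20) {
  check_number(dy, "dy", positive = TRUE)
  check_number(sw, "sw", positive = TRUE)
  check_number(sensor_inset, "sensor_inset", positive = TRUE)
  check_number(fz_threshold, "fz_threshold", positive = TRUE)
  upper_left_extent <- c(upper_right_extent[1:2],
                         -upper_right_extent[4L], -upper_right_extent[3L])
  plates <- list(
    lower = list(extent = lower_extent,
                 sensor_xy = corner_sensors(lower_extent, sensor_inset)),
    upper_right = list(extent = upper_right_extent,
                       sensor_xy = corner_sensors(upper_right_extent, sensor_inset)),
    upper_left = list(extent = upper_left_extent,
                      sensor_xy = corner_sensors(upper_left_extent, sensor_inset))
  )
  for (p in names(plates)) {
    s <- plates[[p]]$sensor_xy
    e <- plates[[p]]$extent
    if (anyDuplicated(s) > 0L ||
        any(s[, 1L] < e[1L] | s[, 1L] > e[2L] | s[, 2L] < e[3L] | s[, 2L] > e[4L])) {
      stop_invalid(sprintf("sensors of plate '%s' must be distinct and inside its extent", p),
                   "copsplit_config_error")
    }
  }
  structure(list(dy = dy, sw = sw, plates = plates,
                 sensor_inset = sensor_inset, fz_threshold = fz_threshold),
            class = "stance_geometry")
}

#' @export
print.stance_geometry <- function(x, ...) {
  cat(sprintf("<stance_geometry> dy=%g mm, sw=%g mm, base of support |y| <= %g mm, Fz threshold %g N\n",
              x$dy, x$sw, x$dy + x$sw / 2, x$fz_threshold))
  invisible(x)
}

# Accept a stance_geometry or a bare list(dy=, sw=) (possibly vectorised)
# wherever only the split-model parameters are needed.
geom_dy <- function(geom) {
  if (is.null(geom$dy)) stop_invalid("`geom` lacks dy", "copsplit_config_error")
  geom$dy
}
geom_sw <- function(geom) {
  if (is.null(geom$sw)) stop_invalid("`geom` lacks sw", "copsplit_config_error")
  geom$sw
}
geom_threshold <- function(geom) {
  if (is.null(geom$fz_threshold)) 20 else geom$fz_threshold
}

#' Read / write stance geometry as YAML
#'
#' @param path file path.
#' @param geom a [stance_geometry()].
#' @return `read_stance_geometry()` returns a [stance_geometry()].
#' @export
read_stance_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  stance_geometry(dy = y$dy, sw = y$sw,
                  lower_extent = as.numeric(y$lower_extent),
                  upper_right_extent = as.numeric(y$upper_right_extent),
                  sensor_inset = y$sensor_inset,
                  fz_threshold = y$fz_threshold)
}

#' @rdname read_stance_geometry
#' @export
write_stance_geometry <- function(geom, path) {
  yaml::write_yaml(list(
    dy = geom$dy, sw = geom$sw,
    lower_extent = geom$plates$lower$extent,
    upper_right_extent = geom$plates$upper_right$extent,
    sensor_inset = geom$sensor_inset,
    fz_threshold = geom$fz_threshold
  ), path)
  invisible(path)
}
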