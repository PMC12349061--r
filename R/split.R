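# Analytical split of the global GRF state into per-foot states.
#
# Hypothesis (feet fixed, sole midlines at y = +/- dy, sole width sw,
# quasi-static so horizontal forces are negligible):
#   x_left = x_right = x_global                      (AP identical)
#   y_right = y_global * sw/(2 dy + sw) + dy          (ML proportional)
#   y_left  = y_global * sw/(2 dy + sw) - dy
#   LF      = 0.5 + y_global/(2 dy + sw)              (right-foot load share)
#   Fz_right = Fz * LF ;  Fz_left = Fz - Fz_right
# and the exact inverse (load-weighted mean):
#   x,y_global = x,y_left * Fz_left/Fz + x,y_right * Fz_right/Fz

#' Split the anteroposterior CoP
#'
#' Under the analytical hypothesis the AP displacement of each foot's CoP is
#' identical to the global one, so this is the identity on both outputs.
#'
#' @param x_global global anteroposterior CoP, mm (vectorised).
#' @return A list with numeric elements `left` and `right`.
#' @export
split_xcop <- function(x_global) {
  list(left = x_global, right = x_global)
}

#' Split the mediolateral CoP
#'
#' The ML displacement of each foot's CoP within its sole is proportional to
#' the global ML displacement within the base of support, shifted by `dy` to
#' each sole's midline: `y_right = y * sw/(2*dy+sw) + dy`,
#' `y_left = y * sw/(2*dy+sw) - dy`. A global CoP outside the base of
#' support (`|y| > dy + sw/2`, possible with noise) produces a warning but
#' is computed as-is.
#'
#' @param y_global global mediolateral CoP, mm (vectorised).
#' @param geom a [stance_geometry()] or any list with numeric `dy` and `sw`
#'   (vectors allowed, recycled against `y_global`).
#' @return A list with numeric elements `left` and `right`.
#' @export
split_ycop <- function(y_global, geom) {
  dy <- geom_dy(geom); sw <- geom_sw(geom)
  out <- which(abs(y_global) > dy + sw / 2)
  if (length(out) > 0L) {
    warn(sprintf("%d sample(s) have the global CoP outside the base of support",
                 length(out)),
         class = "copsplit_out_of_support_warning")
  }
  prop <- y_global * sw / (2 * dy + sw)
  list(left = prop - dy, right = prop + dy)
}

#' Mediolateral load factor
#'
#' Fraction of the total vertical force carried by the right foot:
#' `LF = 0.5 + y_global / (2*dy + sw)`, clamped to `[0, 1]` (negative foot
#' loads are unphysical for uniaxial plates). The pre-clamp value is kept in
#' attribute `"raw"`; clamping triggers a warning.
#'
#' @inheritParams split_ycop
#' @return Numeric vector of load factors in `[0, 1]` with attribute
#'   `"raw"` holding the unclamped values.
#' @export
load_factor <- function(y_global, geom) {
  dy <- geom_dy(geom); sw <- geom_sw(geom)
  raw <- 0.5 + y_global / (2 * dy + sw)
  lf <- pmin(pmax(raw, 0), 1)
  n_cl <- sum(lf != raw, na.rm = TRUE)
  if (n_cl > 0L) {
    warn(sprintf("load factor clamped to [0, 1] for %d sample(s)", n_cl),
         class = "copsplit_lf_clamped")
  }
  attr(lf, "raw") <- raw
  lf
}

#' Split the vertical force between the feet
#'
#' `Fz_right = Fz * LF`, `Fz_left = Fz * (1 - LF)`. The larger share is
#' computed by the product and the smaller one by subtraction from `Fz`,
#' which makes the conservation `Fz_left + Fz_right == Fz` exact in
#' floating point (bitwise), not merely to rounding.
#'
#' @param fz_global global vertical force, N (`>= 0`, vectorised).
#' @param lf load factor in `[0, 1]` (clamping happens upstream in
#'   [load_factor()]).
#' @return A list with numeric elements `left` and `right`.
#' @export
split_fz <- function(fz_global, lf) {
  lf <- as.numeric(lf)
  ok <- is.na(lf) | (lf >= 0 & lf <= 1)
  if (!all(ok)) {
    stop_invalid("`lf` must lie in [0, 1]", "copsplit_invalid_parameter")
  }
  # Sterbenz: with the larger share in [Fz/2, Fz] the complementary
  # subtraction is exact, so the pair sums back to Fz bitwise
  hi <- !is.na(lf) & lf >= 0.5
  right <- ifelse(hi, fz_global * lf, NA_real_)
  left <- ifelse(hi, fz_global - right, fz_global * (1 - lf))
  right[!hi] <- (fz_global - left)[!hi]
  list(left = left, right = right)
}

#' Paired per-foot trajectories
#'
#' Result container of the split: a data frame with per-sample columns
#' `time, xL, yL, FzL, xR, yR, FzR, LF, LF_raw, valid`.
#'
#' @param time sample times, s.
#' @param left,right [grf_trajectory()] objects of equal length.
#' @param lf load-factor series (attribute `"raw"` kept if present).
#' @return A data frame of class `split_result`.
#' @export
split_result <- function(time, left, right, lf = NULL) {
  if (is.null(lf)) {
    tot <- left$fz + right$fz
    lf <- ifelse(tot > 0, right$fz / tot, 0.5)
    attr(lf, "raw") <- lf
  }
  raw <- attr(lf, "raw")
  if (is.null(raw)) raw <- as.numeric(lf)
  structure(
    data.frame(time = time, xL = left$x, yL = left$y, FzL = left$fz,
               xR = right$x, yR = right$y, FzR = right$fz,
               LF = as.numeric(lf), LF_raw = raw,
               valid = left$valid & right$valid),
    class = c("split_result", "data.frame")
  )
}

# views of a split_result as per-foot trajectories
split_left <- function(sp) grf_trajectory(sp$time, sp$xL, sp$yL, sp$FzL, sp$valid)
split_right <- function(sp) grf_trajectory(sp$time, sp$xR, sp$yR, sp$FzR, sp$valid)

#' Analytical split of a global GRF trajectory
#'
#' Applies [split_xcop()], [split_ycop()], [load_factor()] and [split_fz()]
#' per sample. Invalid global samples propagate as invalid per-foot samples
#' (`NA` CoP and forces) rather than being interpolated.
#'
#' @param global a [grf_trajectory()] of the global plate.
#' @param geom a [stance_geometry()].
#' @return A [split_result()].
#' @export
split_trajectory <- function(global, geom) {
  ok <- global$valid
  x <- ifelse(ok, global$x, NA_real_)
  y <- ifelse(ok, global$y, NA_real_)
  fz <- ifelse(ok, global$fz, NA_real_)
  xs <- split_xcop(x)
  ys <- split_ycop(y[ok], geom)
  yl <- yr <- rep(NA_real_, length(y))
  yl[ok] <- ys$left; yr[ok] <- ys$right
  lf <- rep(NA_real_, length(y))
  lf_raw <- rep(NA_real_, length(y))
  lf_ok <- load_factor(y[ok], geom)
  lf[ok] <- lf_ok
  lf_raw[ok] <- attr(lf_ok, "raw")
  fzs <- split_fz(fz, lf)
  attr(lf, "raw") <- lf_raw
  left <- grf_trajectory(global$time, xs$left, yl, ifelse(ok, fzs$left, NA_real_), ok)
  right <- grf_trajectory(global$time, xs$right, yr, ifelse(ok, fzs$right, NA_real_), ok)
  split_result(global$time, left, right, lf)
}

#' Reconstruct the global state from per-foot states
#'
#' The exact inverse of the split: `Fz = FzL + FzR` and the global CoP is
#' the load-weighted mean of the per-foot CoPs,
#' `x,y = x,yL * FzL/Fz + x,yR * FzR/Fz`. A foot carrying zero load
#' contributes nothing (its CoP may be undefined).
#'
#' @param left,right [grf_trajectory()] objects with identical time bases,
#'   or a single [split_result()] passed as `left`.
#' @param fz_threshold total force below which the reconstructed CoP is
#'   flagged invalid (default 20 N).
#' @return A [grf_trajectory()] of the global state.
#' @export
reconstruct_global <- function(left, right = NULL, fz_threshold = 20) {
  if (inherits(left, "split_result") && is.null(right)) {
    sp <- left
    left <- split_left(sp); right <- split_right(sp)
  }
  if (nrow(left) != nrow(right) ||
      max(abs(left$time - right$time)) > 1e-9) {
    stop_invalid("left and right trajectories must share one time base",
                 "copsplit_invalid_input")
  }
  fz <- left$fz + right$fz
  wl <- ifelse(fz > 0, left$fz / fz, 0)
  wr <- ifelse(fz > 0, right$fz / fz, 0)
  term <- function(v, w) ifelse(w > 0, v * w, 0)
  x <- term(left$x, wl) + term(right$x, wr)
  y <- term(left$y, wl) + term(right$y, wr)
  valid <- !is.na(fz) & fz >= fz_threshold & left$valid & right$valid
  x[!valid] <- ifelse(fz[!valid] > 0, x[!valid], NA_real_)
  grf_trajectory(left$time, x, y, fz, valid)
}

#' Write a split result as CSV
#'
#' Columns `time, xL, yL, FzL, xR, yR, FzR, LF, LF_raw, valid`.
#' @param sp a [split_result()].
#' @param path file path.
#' @export
write_split_csv <- function(sp, path) {
  write.csv(as.data.frame(sp), path, row.names = FALSE)
  invisible(path)
}
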