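#' Tare a recording against its unloaded baseline
#'
#' The acquisition hardware cannot tare in place, so every trial starts with
#' at least three seconds recorded without load; the per-channel mean over
#' that window is subtracted from the whole recording. Baseline samples are
#' kept (trimming is a separate step, see [trim_trial()]).
#'
#' @param rec a [plate_recording()].
#' @param baseline_seconds length of the initial unloaded window in seconds
#'   (>= 1 s and shorter than the recording). The caller is responsible for
#'   the window actually being unloaded.
#' @return A tared [plate_recording()] of identical shape.
#' @export
tare <- function(rec, baseline_seconds = 3) {
  check_number(baseline_seconds, "baseline_seconds", positive = TRUE)
  if (baseline_seconds < 1) {
    stop_invalid("baseline window must be at least 1 s", "copsplit_invalid_window")
  }
  n_base <- floor(baseline_seconds * rec$rate)
  if (n_base >= n_samples(rec)) {
    stop_invalid("baseline window longer than the recording",
                 "copsplit_invalid_window")
  }
  mu <- colMeans(rec$channels[seq_len(n_base), , drop = FALSE])
  rec_update(rec, sweep(rec$channels, 2L, mu))
}

# butterworth transient settling length used for reflective padding
.pad_length <- function(rate, cutoff_hz, n) {
  min(n - 1L, max(9L, ceiling(3 * rate / cutoff_hz)))
}

# odd (point-reflected) padding, forward-backward filtering of one channel;
# each pass filters deviations from its starting value (steady-state
# initialisation), which removes the zero-state DC startup transient
.filtfilt_odd <- function(b, a, x, pad) {
  n <- length(x)
  dc <- sum(b) / sum(a)
  one_pass <- function(y) {
    z0 <- y[1L]
    as.numeric(signal::filter(b, a, y - z0)) + z0 * dc
  }
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- c(left, x, right)
  y <- one_pass(y)
  y <- rev(one_pass(rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward Butterworth filtering (`filtfilt`), giving exactly zero
#' phase shift and the squared single-pass magnitude response. Cutoff
#' defaults to 10 Hz: CoP dynamics during balance lie in the 0.5-1 Hz band,
#' so 10 Hz suppresses sensor noise without touching the signal. Edge
#' transients are controlled by odd-reflection padding of at least three
#' filter settling lengths.
#'
#' @param rec a [plate_recording()].
#' @param cutoff_hz cutoff frequency in Hz, `0 < cutoff_hz < rate/2`.
#' @param order Butterworth order of each pass (effective order is doubled
#'   by the forward-backward scheme). Default 2.
#' @return A filtered [plate_recording()].
#' @export
lowpass_zero_phase <- function(rec, cutoff_hz = 10, order = 2L) {
  check_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (cutoff_hz >= rec$rate / 2) {
    stop_invalid("cutoff must be below the Nyquist frequency",
                 "copsplit_invalid_parameter")
  }
  bf <- signal::butter(order, cutoff_hz / (rec$rate / 2), type = "low")
  pad <- .pad_length(rec$rate, cutoff_hz, n_samples(rec))
  out <- apply(rec$channels, 2L, function(x) .filtfilt_odd(bf$b, bf$a, x, pad))
  rec_update(rec, out)
}

#' Trim a trial at its start trigger
#'
#' Trials begin with an unloaded tare window and a marker squat before the
#' exercise proper; this drops everything before the trigger. Two modes:
#'
#' * `"index"`: start at the given sample index (manual override).
#' * `"squat"`: detect the marker squat on the total vertical force. The
#'   load plateau level is the median force over loaded samples; the trigger
#'   is the first sample where the force, after having reached the plateau,
#'   drops below `(1 - drop_fraction) * plateau` and then recrosses above it.
#'
#' @param rec a tared [plate_recording()].
#' @param mode `"squat"` or `"index"`.
#' @param index 1-based sample index at which the trimmed recording starts
#'   (mode `"index"`).
#' @param drop_fraction relative force drop identifying the squat
#'   (default 0.15).
#' @return The sub-recording from the trigger onwards, with its original
#'   time stamps. The chosen start index is attached as attribute
#'   `"trigger_index"`.
#' @export
trim_trial <- function(rec, mode = c("squat", "index"), index = NULL,
                       drop_fraction = 0.15) {
  mode <- match.arg(mode)
  n <- n_samples(rec)
  if (mode == "index") {
    check_number(index, "index")
    start <- as.integer(index)
    if (start < 1L || start > n) {
      stop_invalid("trigger index outside the recording",
                   "copsplit_invalid_parameter")
    }
  } else {
    check_number(drop_fraction, "drop_fraction", positive = TRUE)
    total <- rowSums(rec$channels)
    loaded <- total > 0.5 * max(total)
    plateau <- median(total[loaded])
    thr <- (1 - drop_fraction) * plateau
    i1 <- which(total >= thr)[1L] # plateau reached
    below <- which(total < thr)
    i2 <- below[below > i1][1L] # squat dip
    diag <- list(plateau = plateau, threshold = thr,
                 plateau_reached = i1, dip_index = i2)
    if (is.na(i2)) {
      stop_invalid("no squat dip found below the trigger threshold",
                   "copsplit_trigger_not_found", diagnostics = diag)
    }
    above <- which(total >= thr)
    start <- above[above > i2][1L] # recovery
    if (is.na(start)) {
      stop_invalid("force never recovers above the trigger threshold",
                   "copsplit_trigger_not_found", diagnostics = diag)
    }
  }
  keep <- seq(start, n)
  out <- rec_update(rec, rec$channels[keep, , drop = FALSE],
                    time = rec$time[keep])
  attr(out, "trigger_index") <- start
  out
}

#' Full preprocessing chain
#'
#' Convenience wrapper applying [tare()], [lowpass_zero_phase()] and
#' [trim_trial()] in the standard order.
#'
#' @inheritParams tare
#' @inheritParams lowpass_zero_phase
#' @inheritParams trim_trial
#' @param trigger trigger mode passed to [trim_trial()], or `NULL` to skip
#'   trimming.
#' @return A preprocessed [plate_recording()].
#' @export
preprocess <- function(rec, baseline_seconds = 3, cutoff_hz = 10, order = 2L,
                       trigger = "squat", index = NULL, drop_fraction = 0.15) {
  rec <- tare(rec, baseline_seconds)
  rec <- lowpass_zero_phase(rec, cutoff_hz, order)
  if (!is.null(trigger)) {
    rec <- trim_trial(rec, trigger, index = index, drop_fraction = drop_fraction)
  }
  rec
}
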