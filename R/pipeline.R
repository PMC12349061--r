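# End-to-end processing of a single trial: preprocess all three plate
# recordings, compute CoPs, run the analytical split and align everything
# on the common (trimmed) window.

#' Process one trial through the measurement pipeline
#'
#' Tares and filters all three plate recordings, detects the squat trigger
#' on the lower plate, trims the three recordings at the same sample,
#' computes CoP trajectories, applies the analytical split to the lower
#' (global) trajectory and collects the upper-plate measurements and the
#' simulator ground truth over the same window.
#'
#' @param trial a [generate_trial()] trial.
#' @param baseline_seconds,cutoff_hz,order,drop_fraction preprocessing
#'   parameters (see [preprocess()]).
#' @param edge_trim seconds discarded from the end of the recording, where
#'   the zero-phase filter's reflection padding leaves its only measurable
#'   transient (the leading edge falls before the squat trigger and is
#'   dropped anyway). Default 0.2 s.
#' @return A list with elements `global_meas` ([grf_trajectory()] from the
#'   lower plate), `measured` and `analytical` ([split_result()]s from the
#'   upper plates and from the split of the global trajectory), `truth`
#'   (simulator ground truth on the same window), `refs`
#'   ([normalization_refs()] of the subject) and `trigger_index`.
#' @export
analyze_trial <- function(trial, baseline_seconds = 3, cutoff_hz = 10,
                          order = 2L, drop_fraction = 0.15, edge_trim = 0.2) {
  geom <- trial$meta$geometry
  prep <- function(rec) {
    lowpass_zero_phase(tare(rec, baseline_seconds), cutoff_hz, order)
  }
  lower <- prep(trial$lower_plate)
  up_l <- prep(trial$upper_left)
  up_r <- prep(trial$upper_right)
  lower <- trim_trial(lower, "squat", drop_fraction = drop_fraction)
  idx <- attr(lower, "trigger_index")
  up_l <- trim_trial(up_l, "index", index = idx)
  up_r <- trim_trial(up_r, "index", index = idx)
  n_edge <- round(edge_trim * lower$rate)
  if (n_edge > 0L && n_edge < n_samples(lower)) {
    keep <- seq_len(n_samples(lower) - n_edge)
    cut_tail <- function(rec) {
      rec_update(rec, rec$channels[keep, , drop = FALSE], time = rec$time[keep])
    }
    lower <- cut_tail(lower); up_l <- cut_tail(up_l); up_r <- cut_tail(up_r)
  }
  global_meas <- compute_cop(lower, geom, "lower")
  left_meas <- compute_cop(up_l, geom, "upper_left")
  right_meas <- compute_cop(up_r, geom, "upper_right")
  measured <- split_result(global_meas$time, left_meas, right_meas)
  analytical <- split_trajectory(global_meas, geom)
  truth <- trial_truth_split(trial, from_time = global_meas$time[1L],
                             to_time = global_meas$time[length(global_meas$time)])
  list(global_meas = global_meas, measured = measured,
       analytical = analytical, truth = truth,
       refs = subject_refs(trial$meta$subject), trigger_index = idx)
}

#' Device-consistency check for one processed trial
#'
#' Compares the global trajectory measured by the lower plate with the
#' reconstruction composed from the two upper plates — the simulated
#' analogue of validating the double-plate device under real exercise.
#'
#' @param proc output of [analyze_trial()].
#' @return A tibble with RMSE/NRMSE/COR rows for `xCoP`, `yCoP` and `Fz`.
#' @export
consistency_metrics <- function(proc) {
  upper <- reconstruct_global(proc$measured)
  lower <- proc$global_meas
  ok <- upper$valid & lower$valid
  refs <- proc$refs
  rows <- list(
    list(variable = "xCoP", t = lower$x, p = upper$x, ref = refs$foot_length),
    list(variable = "yCoP", t = lower$y, p = upper$y, ref = refs$foot_width),
    list(variable = "Fz", t = lower$fz, p = upper$fz, ref = refs$weight_n)
  )
  dplyr::bind_rows(lapply(rows, function(cc) {
    t <- cc$t[ok]; p <- cc$p[ok]
    r <- rmse(t, p)
    co <- tryCatch(pearson_cor(t, p),
                   copsplit_undefined_correlation = function(e) NA_real_)
    tibble::tibble(variable = cc$variable, metric = c("RMSE", "NRMSE", "COR"),
                   value = c(r, r / cc$ref * 100, co))
  }))
}
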