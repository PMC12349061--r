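# Stabilometry performance indicators and their aggregation.

check_pair <- function(real, pred) {
  if (length(real) != length(pred)) {
    stop_invalid("signal pair must have equal lengths", "copsplit_invalid_input")
  }
  if (length(real) < 2L) {
    stop_invalid("signal pair needs at least 2 samples", "copsplit_invalid_input")
  }
  if (!all(is.finite(real)) || !all(is.finite(pred))) {
    stop_invalid("signal pair must be finite", "copsplit_invalid_input")
  }
  invisible(NULL)
}

#' Root mean square error
#'
#' `sqrt(mean((real - pred)^2))`, the overall error magnitude between a
#' measured and a predicted signal.
#'
#' @param real measured (ground-truth) signal.
#' @param pred predicted signal of the same length.
#' @return A single non-negative number in the units of the signals.
#' @export
rmse <- function(real, pred) {
  check_pair(real, pred)
  sqrt(mean((real - pred)^2))
}

#' Normalised root mean square error
#'
#' `RMSE / ref * 100`, in percent. The normalisation reference is a
#' per-subject constant bounding the variable's range: foot length for the
#' AP CoP, foot (ball) width for the ML CoP, body weight for the vertical
#' force.
#'
#' @inheritParams rmse
#' @param ref normalisation reference, strictly positive (mm or N).
#' @return NRMSE in percent.
#' @export
nrmse <- function(real, pred, ref) {
  check_number(ref, "ref", positive = TRUE)
  rmse(real, pred) / ref * 100
}

#' Pearson correlation coefficient
#'
#' Linear correlation between measured and predicted signals. A
#' zero-variance input has no defined correlation and raises an error of
#' class `copsplit_undefined_correlation`; [evaluate_split()] reports such
#' cells as missing rather than as an arbitrary number.
#'
#' @inheritParams rmse
#' @return A number in `[-1, 1]`.
#' @export
pearson_cor <- function(real, pred) {
  check_pair(real, pred)
  if (sd(real) == 0 || sd(pred) == 0) {
    stop_invalid("correlation undefined for a zero-variance signal",
                 "copsplit_undefined_correlation")
  }
  as.numeric(cor(real, pred))
}

#' Per-subject normalisation references
#'
#' @param foot_length foot length, mm (normalises the AP CoP).
#' @param foot_width foot (ball) width, mm (normalises the ML CoP).
#' @param weight_n body weight, N (normalises the vertical force).
#' @return A named list of class `normalization_refs`.
#' @export
normalization_refs <- function(foot_length, foot_width, weight_n) {
  check_number(foot_length, "foot_length", positive = TRUE)
  check_number(foot_width, "foot_width", positive = TRUE)
  check_number(weight_n, "weight_n", positive = TRUE)
  structure(list(foot_length = foot_length, foot_width = foot_width,
                 weight_n = weight_n),
            class = "normalization_refs")
}

#' Evaluate a predicted split against ground truth
#'
#' Computes RMSE, NRMSE and Pearson correlation for the six per-foot
#' variables (`xCoP`, `yCoP`, `Fz`) x (`left`, `right`), restricted to
#' samples valid in both inputs. NRMSE uses the variable-specific reference
#' from `refs`. Zero-variance correlations are reported as `NA`.
#'
#' @param truth,predicted [split_result()] objects on the same time base.
#' @param refs a [normalization_refs()].
#' @return A tidy [tibble::tibble] with columns `foot`, `variable`,
#'   `metric` (`"RMSE"`, `"NRMSE"`, `"COR"`) and `value`.
#' @export
evaluate_split <- function(truth, predicted, refs) {
  if (nrow(truth) != nrow(predicted)) {
    stop_invalid("truth and prediction must have equal length",
                 "copsplit_invalid_input")
  }
  ok <- truth$valid & predicted$valid
  cols <- list(
    list(foot = "left", variable = "xCoP", t = truth$xL, p = predicted$xL, ref = refs$foot_length),
    list(foot = "left", variable = "yCoP", t = truth$yL, p = predicted$yL, ref = refs$foot_width),
    list(foot = "left", variable = "Fz", t = truth$FzL, p = predicted$FzL, ref = refs$weight_n),
    list(foot = "right", variable = "xCoP", t = truth$xR, p = predicted$xR, ref = refs$foot_length),
    list(foot = "right", variable = "yCoP", t = truth$yR, p = predicted$yR, ref = refs$foot_width),
    list(foot = "right", variable = "Fz", t = truth$FzR, p = predicted$FzR, ref = refs$weight_n)
  )
  rows <- lapply(cols, function(cc) {
    t <- cc$t[ok]; p <- cc$p[ok]
    r <- rmse(t, p)
    co <- tryCatch(pearson_cor(t, p),
                   copsplit_undefined_correlation = function(e) NA_real_)
    tibble::tibble(foot = cc$foot, variable = cc$variable,
                   metric = c("RMSE", "NRMSE", "COR"),
                   value = c(r, r / cc$ref * 100, co))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-trial metrics
#'
#' Mean and standard deviation of metric values across trials, grouped by
#' the identifying columns. The study convention is: metrics per trial,
#' averaged over the repetitions of each subject, then over subjects.
#'
#' @param tbl a tidy metric table (one row per trial x foot x variable x
#'   metric), e.g. row-bound outputs of [evaluate_split()] with added
#'   `exercise`, `subject`, `repetition` columns.
#' @param by grouping columns for the aggregate.
#' @return A tibble with `mean`, `sd` and `n` per group.
#' @export
aggregate_metrics <- function(tbl, by = c("exercise", "foot", "variable", "metric")) {
  by <- intersect(by, names(tbl))
  dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::all_of(by))),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}
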