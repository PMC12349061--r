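# Scaled replication of the network-vs-analytical comparison study:
# mixed-strategy cohort, dataset-3 training, elimination-based selection,
# head-to-head yCoP error on the mediolateral holdout trials.

# lightweight evaluation view of a trial: exact global trajectory + truth
eval_view <- function(trial) {
  keep <- trial$global_cop$time >= trial$meta$exercise_start_s
  g <- trial$global_cop[keep, ]
  list(glob = grf_trajectory(g$time, g$x, g$y, g$fz, g$valid),
       truth = trial_truth_split(trial),
       refs = subject_refs(trial$meta$subject),
       geom = trial$meta$geometry,
       exercise = trial$meta$exercise,
       subject = trial$meta$subject$id)
}

eval_model_on_views <- function(views, predict_fun) {
  dplyr::bind_rows(lapply(views, function(v) {
    pred <- suppressWarnings(predict_fun(v))
    dplyr::bind_cols(tibble::tibble(subject = v$subject, exercise = v$exercise),
                     evaluate_split(v$truth, pred, v$refs))
  }))
}

#' Replicate the network-improvement comparison on a synthetic cohort
#'
#' Generates a mixed-strategy cohort, assembles the three-exercise training
#' dataset (four of five repetitions), trains the ten candidate networks,
#' selects one by the three-round elimination, then retrains the selected
#' configuration under several seeds and compares its mediolateral-exercise
#' yCoP NRMSE on the holdout repetition against the analytical split on the
#' same trials.
#'
#' @param master_seed cohort seed.
#' @param train_seeds seeds for the head-to-head retraining runs.
#' @param n_subjects,reps,duration,rate cohort scale (defaults scaled for
#'   desk runtimes; the cohort covers all five exercises with strategies
#'   drawn uniformly on `[0, 1]`).
#' @param decimate_to,max_rows training-table row controls, see
#'   [assemble_dataset()] and [train_model()].
#' @param configs candidate configuration numbers for the selection grid.
#' @return A list: `selected` config, `grid_reports`, `runs` (one row per
#'   seed with `nn` and `analytical` ML yCoP NRMSE means and `win`),
#'   `wins`, `n_runs`.
#' @export
ml_improvement_study <- function(master_seed = 1L, train_seeds = 1:5,
                                 n_subjects = 6L, reps = 5L, duration = 20,
                                 rate = 1000, decimate_to = 100,
                                 max_rows = 3000L, configs = 1:10) {
  cohort <- cohort_plan(n_subjects = n_subjects, reps = reps,
                        exercises = exercise_kinds, master_seed = master_seed,
                        duration = duration, rate = rate,
                        strategy_range = c(0, 1))
  ds <- assemble_dataset(cohort, dataset_spec(3L), decimate_to = decimate_to)
  hold_idx <- which(cohort$plan$repetition == ds$holdout_rep)
  views <- lapply(hold_idx, function(i) eval_view(realize_trial(cohort, i)))

  # selection grid under the first seed
  grid_reports <- dplyr::bind_rows(lapply(configs, function(k) {
    model <- train_model(ds, nn_config(k), seed = train_seeds[1L],
                         max_rows = max_rows)
    per_trial <- eval_model_on_views(views, function(v) predict_split(model, v$glob))
    agg <- aggregate_metrics(per_trial)
    dplyr::bind_cols(config = k, agg)
  }))
  reports <- grid_reports
  names(reports)[names(reports) == "mean"] <- "value"
  selection <- select_model(reports)

  ml_views <- views[vapply(views, function(v) v$exercise == "ML", logical(1))]
  ycop_nrmse <- function(tbl) {
    mean(tbl$value[tbl$variable == "yCoP" & tbl$metric == "NRMSE"])
  }
  an_tbl <- eval_model_on_views(ml_views, function(v) {
    split_trajectory(v$glob, v$geom)
  })
  an_score <- ycop_nrmse(an_tbl)
  runs <- dplyr::bind_rows(lapply(train_seeds, function(sd) {
    model <- train_model(ds, nn_config(selection$selected), seed = sd,
                         max_rows = max_rows)
    nn_tbl <- eval_model_on_views(ml_views, function(v) predict_split(model, v$glob))
    tibble::tibble(seed = sd, nn = ycop_nrmse(nn_tbl), analytical = an_score,
                   win = ycop_nrmse(nn_tbl) < an_score)
  }))
  list(selected = selection$selected, selection = selection,
       grid_reports = grid_reports, runs = runs,
       wins = sum(runs$win), n_runs = nrow(runs))
}
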