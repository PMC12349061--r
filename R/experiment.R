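# Orchestration of the full synthetic study: simulate a cohort, run the
# measurement pipeline, evaluate the analytical split, train and select the
# network models, and emit the comparison tables.

#' Experiment configuration
#'
#' @param out_dir output directory (created if missing).
#' @param n_subjects,reps,exercises,duration,rate,noise_sd,strategy_range
#'   cohort settings, see [cohort_plan()].
#' @param master_seed seed for the cohort.
#' @param dataset_id training dataset composition, see [dataset_spec()].
#' @param nn_configs configuration numbers to train (default all ten).
#' @param nn_seed seed for network training.
#' @param decimate_to row rate for the training tables, Hz.
#' @param max_rows training-row cap per model, see [train_model()].
#' @param cache reuse cached stage outputs found in `out_dir/cache`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(out_dir, n_subjects = 10L, reps = 5L,
                              exercises = exercise_kinds, duration = 30,
                              rate = 1000, noise_sd = 0.5,
                              strategy_range = c(0, 1), master_seed = 1L,
                              dataset_id = 3L, nn_configs = 1:10,
                              nn_seed = 1L, decimate_to = 100,
                              max_rows = 3000L, cache = TRUE) {
  structure(as.list(environment()), class = "experiment_config")
}

cache_path <- function(cfg, key, obj_desc) {
  dir <- file.path(cfg$out_dir, "cache")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, paste0(key, "-", hash(obj_desc), ".rds"))
}

with_cache <- function(cfg, key, deps, fun) {
  path <- cache_path(cfg, key, deps)
  if (cfg$cache && file.exists(path)) return(readRDS(path))
  val <- fun()
  saveRDS(val, path)
  val
}

# mean metric table of the analytical split and the measured-vs-truth
# channel for every trial of a cohort; streams trials one at a time
cohort_split_metrics <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort$plan)), function(i) {
    tr <- realize_trial(cohort, i)
    proc <- analyze_trial(tr)
    meta <- tibble::tibble(subject = cohort$plan$subject[i],
                           exercise = cohort$plan$exercise[i],
                           repetition = cohort$plan$repetition[i])
    dplyr::bind_rows(
      dplyr::bind_cols(meta, stage = "analytical",
                       evaluate_split(proc$measured, proc$analytical, proc$refs)),
      dplyr::bind_cols(meta, stage = "consistency",
                       consistency_metrics(proc))
    )
  })
  dplyr::bind_rows(rows)
}

# holdout evaluation of one trained model against measured truth, per trial
nn_holdout_metrics <- function(model, cohort, holdout_rep, exercises) {
  sel <- which(cohort$plan$repetition == holdout_rep &
                 cohort$plan$exercise %in% exercises)
  rows <- lapply(sel, function(i) {
    tr <- realize_trial(cohort, i)
    keep <- tr$global_cop$time >= tr$meta$exercise_start_s
    g <- tr$global_cop[keep, ]
    glob <- grf_trajectory(g$time, g$x, g$y, g$fz, g$valid)
    pred <- suppressWarnings(predict_split(model, glob))
    truth <- trial_truth_split(tr)
    dplyr::bind_cols(
      tibble::tibble(subject = cohort$plan$subject[i],
                     exercise = cohort$plan$exercise[i],
                     repetition = cohort$plan$repetition[i]),
      evaluate_split(truth, pred, subject_refs(tr$meta$subject)))
  })
  dplyr::bind_rows(rows)
}

# analytical split of the exact global trajectory vs truth, per trial
analytical_holdout_metrics <- function(cohort, holdout_rep, exercises) {
  sel <- which(cohort$plan$repetition == holdout_rep &
                 cohort$plan$exercise %in% exercises)
  rows <- lapply(sel, function(i) {
    tr <- realize_trial(cohort, i)
    keep <- tr$global_cop$time >= tr$meta$exercise_start_s
    g <- tr$global_cop[keep, ]
    glob <- grf_trajectory(g$time, g$x, g$y, g$fz, g$valid)
    geom <- tr$meta$geometry
    pred <- suppressWarnings(split_trajectory(glob, geom))
    truth <- trial_truth_split(tr)
    dplyr::bind_cols(
      tibble::tibble(subject = cohort$plan$subject[i],
                     exercise = cohort$plan$exercise[i],
                     repetition = cohort$plan$repetition[i]),
      evaluate_split(truth, pred, subject_refs(tr$meta$subject)))
  })
  dplyr::bind_rows(rows)
}

#' Run the full synthetic experiment
#'
#' Stages: (a) device-consistency table (lower plate vs reconstruction from
#' the upper plates); (b) analytical-split metric tables per exercise;
#' (c) per-configuration network tables on the holdout repetition;
#' (d) elimination-based selection and head-to-head comparison of the
#' selected network against the analytical split. All tables are written
#' as CSV under `cfg$out_dir` together with a JSON manifest recording the
#' seeds, settings and package version; every number is reproducible from
#' the manifest alone. Stage outputs are cached by a hash of their inputs.
#'
#' @param cfg an [experiment_config()].
#' @return Invisibly, a list with the four stage tables and the selection.
#' @export
run_experiment <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  cohort_args <- cfg[c("n_subjects", "reps", "exercises", "duration", "rate",
                       "noise_sd", "strategy_range", "master_seed")]
  cohort <- do.call(cohort_plan, cohort_args)

  inform("stage 1/4: pipeline metrics (consistency + analytical split)")
  pipe_tbl <- with_cache(cfg, "pipeline", cohort_args,
                         function() cohort_split_metrics(cohort))
  consistency <- aggregate_metrics(
    pipe_tbl[pipe_tbl$stage == "consistency", ],
    by = c("exercise", "variable", "metric"))
  analytical_tbl <- aggregate_metrics(pipe_tbl[pipe_tbl$stage == "analytical", ])

  inform("stage 2/4: assembling the training dataset")
  ds_deps <- c(cohort_args, list(dataset_id = cfg$dataset_id,
                                 decimate_to = cfg$decimate_to))
  dataset <- with_cache(cfg, "dataset", ds_deps, function() {
    assemble_dataset(cohort, dataset_spec(cfg$dataset_id),
                     decimate_to = cfg$decimate_to)
  })

  inform("stage 3/4: training the network grid")
  nn_deps <- c(ds_deps, list(nn_configs = cfg$nn_configs, nn_seed = cfg$nn_seed,
                             max_rows = cfg$max_rows))
  nn_tbl <- with_cache(cfg, "nn-grid", nn_deps, function() {
    dplyr::bind_rows(lapply(cfg$nn_configs, function(k) {
      model <- train_model(dataset, nn_config(k), seed = cfg$nn_seed,
                           max_rows = cfg$max_rows)
      per_trial <- nn_holdout_metrics(model, cohort, dataset$holdout_rep,
                                      cfg$exercises)
      dplyr::bind_cols(config = k,
                       aggregate_metrics(per_trial))
    }))
  })

  inform("stage 4/4: model selection and comparison")
  reports <- nn_tbl
  names(reports)[names(reports) == "mean"] <- "value"
  selection <- select_model(reports)
  sel_model <- train_model(dataset, nn_config(selection$selected),
                           seed = cfg$nn_seed, max_rows = cfg$max_rows)
  comp_ex <- intersect(c("STC", "AP", "ML"), cfg$exercises)
  nn_cmp <- aggregate_metrics(
    nn_holdout_metrics(sel_model, cohort, dataset$holdout_rep, comp_ex))
  an_cmp <- aggregate_metrics(
    analytical_holdout_metrics(cohort, dataset$holdout_rep, comp_ex))
  comparison <- dplyr::bind_rows(
    dplyr::bind_cols(method = "analytical", an_cmp),
    dplyr::bind_cols(method = sprintf("nn_%d", selection$selected), nn_cmp))

  out <- list(consistency = consistency, analytical = analytical_tbl,
              nn_grid = nn_tbl, selection = selection,
              comparison = comparison)
  write.csv(consistency, file.path(cfg$out_dir, "consistency.csv"), row.names = FALSE)
  write.csv(analytical_tbl, file.path(cfg$out_dir, "analytical.csv"), row.names = FALSE)
  write.csv(nn_tbl, file.path(cfg$out_dir, "nn_grid.csv"), row.names = FALSE)
  write.csv(comparison, file.path(cfg$out_dir, "comparison.csv"), row.names = FALSE)
  manifest <- cfg[setdiff(names(cfg), "cache")]
  manifest$selected_config <- selection$selected
  manifest$package_version <- as.character(utils::packageVersion("copsplit"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    "copsplit experiment summary",
    sprintf("cohort: %d subjects x %d reps x %s", cfg$n_subjects, cfg$reps,
            paste(cfg$exercises, collapse = "/")),
    sprintf("selected network configuration: %d", selection$selected),
    sprintf("tables: consistency.csv analytical.csv nn_grid.csv comparison.csv")
  ), file.path(cfg$out_dir, "summary.txt"))
  invisible(out)
}
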