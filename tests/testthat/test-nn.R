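# Network alternative: dataset assembly, training, prediction and the
# elimination-based selection.

small_cohort <- function(master_seed = 21, strategy_range = c(0, 1)) {
  cohort_plan(n_subjects = 2, reps = 3, exercises = c("STC", "AP", "ML"),
              master_seed = master_seed, duration = 4, rate = 200,
              strategy_range = strategy_range, noise_sd = 0)
}

test_that("dataset assembly partitions holdout rows and checks coverage", {
  co <- small_cohort()
  ds <- assemble_dataset(co, dataset_spec(3), decimate_to = 50)
  # 2 subjects x 3 exercises x 2 training reps x 4 s x 50 Hz
  expect_identical(nrow(ds$train$inputs), 2L * 3L * 2L * 200L)
  expect_identical(nrow(ds$holdout$inputs), 2L * 3L * 1L * 200L)
  expect_true(all(ds$train$meta$repetition != ds$holdout_rep))
  expect_true(all(ds$holdout$meta$repetition == ds$holdout_rep))
  # dataset 3 contains no rotation rows
  expect_false("ROT" %in% ds$train$meta$exercise)
  # dataset 1 asks for AP only; a cohort without AP must fail
  co_noap <- cohort_plan(n_subjects = 1, reps = 2, exercises = "STC",
                         master_seed = 3, duration = 2, rate = 100)
  expect_error(assemble_dataset(co_noap, dataset_spec(1)),
               class = "copsplit_dataset_incomplete")
})

test_that("the configuration table drives nn_config", {
  tb <- nn_config_table()
  expect_identical(nrow(tb), 10L)
  cfg <- nn_config(9)
  expect_identical(cfg$hidden, c(10L, 10L, 25L))
  expect_identical(cfg$epochs, 500L)
  expect_identical(nn_config(10)$epochs, 250L)
  expect_error(nn_config(11), class = "copsplit_invalid_parameter")
})

test_that("analytic MLP gradient matches finite differences", {
  set.seed(2)
  shapes <- copsplit:::mlp_shapes(c(4L, 3L))
  theta <- copsplit:::mlp_init(shapes)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(60), 10, 6)
  g <- copsplit:::mlp_mse_grad(theta, shapes, X, Y)$grad
  eps <- 1e-6
  idx <- sample(length(theta), 12)
  for (j in idx) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    fd <- (copsplit:::mlp_mse_grad(tp, shapes, X, Y, want_grad = FALSE)$mse -
             copsplit:::mlp_mse_grad(tm, shapes, X, Y, want_grad = FALSE)$mse) / (2 * eps)
    expect_equal(g[j], fd, tolerance = 1e-5)
  }
})

test_that("LM normal equations match an explicit numeric Jacobian", {
  set.seed(3)
  shapes <- copsplit:::mlp_shapes(c(3L))
  theta <- copsplit:::mlp_init(shapes)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(30), 5, 6)
  ne <- copsplit:::mlp_normal_eqs(theta, shapes, X, Y, chunk = 2L)
  # numeric Jacobian of the residual vector (column-major output order)
  resid <- function(th) {
    layers <- copsplit:::mlp_unflatten(th, shapes)
    as.numeric(copsplit:::mlp_forward(layers, X)$out - Y)
  }
  eps <- 1e-6
  J <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (resid(tp) - resid(tm)) / (2 * eps)
  }, numeric(30))
  expect_equal(ne$JtJ, crossprod(J), tolerance = 1e-4)
  expect_equal(ne$Jtr, as.numeric(crossprod(J, resid(theta))), tolerance = 1e-4)
})

test_that("training fits hypothesis-conforming data to near-zero holdout error", {
  co <- small_cohort(strategy_range = c(0, 0)) # noiseless, conforming
  ds <- assemble_dataset(co, dataset_spec(3), decimate_to = 50)
  m <- train_model(ds, nn_config(hidden = 10L, epochs = 200L), seed = 4,
                   max_rows = 1200)
  # holdout MSE in scaled units: the map is smooth and noise-free
  Xs <- copsplit:::minmax_apply(ds$holdout$inputs, m$scale_in)
  Ys <- copsplit:::minmax_apply(ds$holdout$targets, m$scale_out)
  layers <- copsplit:::mlp_unflatten(m$theta, m$shapes)
  pred <- copsplit:::mlp_forward(layers, Xs)$out
  expect_lt(mean((pred - Ys)^2), 1e-3)
  expect_identical(m$optimizer, "levenberg-marquardt")
})

test_that("constant targets are learned exactly and training is deterministic", {
  X <- matrix(runif(900, -1, 1), 300, 3)
  Y <- matrix(rep(c(1, -2, 3, 4, -5, 6), each = 300), 300, 6)
  colnames(X) <- c("x", "y", "fz"); colnames(Y) <- paste0("t", 1:6)
  d <- list(inputs = X, targets = Y)
  m1 <- train_model(d, nn_config(hidden = 5L, epochs = 50L), seed = 11)
  m2 <- train_model(d, nn_config(hidden = 5L, epochs = 50L), seed = 11)
  expect_identical(m1$theta, m2$theta) # bit-reproducible
  layers <- copsplit:::mlp_unflatten(m1$theta, m1$shapes)
  pred <- copsplit:::minmax_invert(
    copsplit:::mlp_forward(layers, copsplit:::minmax_apply(X, m1$scale_in))$out,
    m1$scale_out)
  expect_lt(max(abs(sweep(pred, 2, c(1, -2, 3, 4, -5, 6)))), 1e-4)
})

test_that("holdout rows never influence training (no leakage)", {
  co <- small_cohort()
  ds <- assemble_dataset(co, dataset_spec(3), decimate_to = 50)
  m1 <- train_model(ds, nn_config(hidden = 8L, epochs = 60L), seed = 5)
  ds2 <- ds
  ds2$holdout$inputs <- ds2$holdout$inputs * 1.7 + 3
  ds2$holdout$targets <- ds2$holdout$targets - 42
  m2 <- train_model(ds2, nn_config(hidden = 8L, epochs = 60L), seed = 5)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$scale_in, m2$scale_in)
})

test_that("predict_split de-scales, reports the conservation residual, and
           agrees with the analytical split on conforming data", {
  co <- small_cohort(strategy_range = c(0, 0))
  ds <- assemble_dataset(co, dataset_spec(3), decimate_to = 50)
  m <- train_model(ds, nn_config(hidden = 10L, epochs = 200L), seed = 4,
                   max_rows = 1200)
  tr <- realize_trial(co, which(co$plan$exercise == "ML" &
                                  co$plan$repetition == 3)[1])
  keep <- tr$global_cop$time >= tr$meta$exercise_start_s
  g <- tr$global_cop[keep, ]
  glob <- grf_trajectory(g$time, g$x, g$y, g$fz, g$valid)
  pred <- suppressWarnings(predict_split(m, glob))
  expect_true("fz_resid" %in% names(pred))
  an <- split_trajectory(glob, tr$meta$geometry)
  # both approximate the same conforming map
  expect_lt(rmse(an$yR, pred$yR), 2)
  expect_lt(rmse(an$FzR, pred$FzR), 0.03 * tr$meta$subject$weight_n)
  # network conservation is approximate, not exact: the residual is reported
  expect_true(any(pred$fz_resid != 0))
  expect_lt(max(abs(pred$fz_resid)), 0.1 * tr$meta$subject$weight_n)
})

fake_reports <- function(scores) {
  # scores: named list config -> list(nrmse_task, nrmse_rest, cor)
  rows <- lapply(names(scores), function(cfg) {
    s <- scores[[cfg]]
    expand <- function(ex, metric, value) {
      tidyr_grid <- expand.grid(foot = c("left", "right"),
                                variable = c("xCoP", "yCoP", "Fz"),
                                stringsAsFactors = FALSE)
      tibble::tibble(config = as.integer(cfg), exercise = ex,
                     foot = tidyr_grid$foot, variable = tidyr_grid$variable,
                     metric = metric, value = value)
    }
    dplyr::bind_rows(
      expand("AP", "NRMSE", s$task), expand("ML", "NRMSE", s$task),
      expand("STC", "NRMSE", s$rest),
      expand("AP", "COR", s$cor), expand("ML", "COR", s$cor),
      expand("STC", "COR", s$cor))
  })
  dplyr::bind_rows(rows)
}

test_that("select_model eliminates in three rounds and handles ties", {
  # config 1 dominates everywhere -> selected
  rep_dom <- fake_reports(list(`1` = list(task = 1, rest = 1, cor = 0.99),
                               `2` = list(task = 5, rest = 4, cor = 0.5),
                               `3` = list(task = 3, rest = 9, cor = 0.6),
                               `4` = list(task = 2, rest = 2, cor = 0.2)))
  out <- select_model(rep_dom)
  expect_identical(out$selected, 1L)

  # identical reports: trivial selection, lowest index survives
  rep_tie <- fake_reports(list(`1` = list(task = 1, rest = 1, cor = 0.9),
                               `2` = list(task = 1, rest = 1, cor = 0.9),
                               `3` = list(task = 1, rest = 1, cor = 0.9)))
  expect_warning(out <- select_model(rep_tie),
                 class = "copsplit_selection_trivial")
  expect_identical(out$selected, 1L)

  # single config: trivial warning
  rep_one <- fake_reports(list(`1` = list(task = 1, rest = 1, cor = 0.9)))
  expect_warning(out <- select_model(rep_one),
                 class = "copsplit_selection_trivial")
  expect_identical(out$selected, 1L)
})

test_that("select_model reproduces the staged elimination on a 10-config field", {
  # worst task-NRMSE: 9, 10; then worst rest-NRMSE: 6, 7, 8; then worst COR
  # among 1..5: 2, 3, 4, 5 -> survivor 1
  sc <- list()
  for (k in 1:10) {
    sc[[as.character(k)]] <- list(
      task = if (k >= 9) 20 else 5 + k / 10,
      rest = if (k %in% 6:8) 15 else 4 + k / 10,
      cor = if (k == 1) 0.95 else 0.5 - k / 100)
  }
  out <- select_model(fake_reports(sc))
  expect_identical(out$selected, 1L)
  expect_identical(sort(out$rounds$eliminated[out$rounds$round == 1]), c(9L, 10L))
  expect_identical(sort(out$rounds$eliminated[out$rounds$round == 2]), 6:8)
})
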