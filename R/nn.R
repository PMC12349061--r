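# MLP alternative to the analytical split: small feed-forward networks
# mapping the global (xCoP, yCoP, Fz) sample to the six per-foot outputs
# (xL, yL, FzL, xR, yR, FzR). Hidden activation tangent-sigmoid, linear
# output, MSE loss, min-max input/output scaling to [-1, 1] computed on
# training rows only, internal random 70/15/15 train/validation/test split,
# Levenberg-Marquardt optimisation with validation-based early stopping.

#' The ten candidate network configurations
#'
#' Hidden-layer widths and maximum epochs of the ten candidate multilayer
#' perceptrons evaluated by the study design.
#'
#' @return A tibble with columns `network`, `hidden` (list of integer
#'   vectors) and `epochs`.
#' @export
nn_config_table <- function() {
  tibble::tibble(
    network = 1:10,
    hidden = list(10L, 50L, 100L, c(10L, 10L), c(10L, 25L), c(10L, 50L),
                  c(25L, 50L), c(10L, 10L, 10L), c(10L, 10L, 25L),
                  c(10L, 25L, 50L)),
    epochs = c(750L, 750L, 500L, 750L, 750L, 750L, 500L, 750L, 500L, 250L)
  )
}

#' Network configuration
#'
#' @param network configuration number 1-10 (row of [nn_config_table()]),
#'   or `NULL` to supply `hidden`/`epochs` directly.
#' @param hidden integer vector of hidden-layer widths.
#' @param epochs maximum optimiser iterations.
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(network = NULL, hidden = NULL, epochs = NULL) {
  if (!is.null(network)) {
    tb <- nn_config_table()
    if (!network %in% tb$network) {
      stop_invalid("`network` must be in 1..10", "copsplit_invalid_parameter")
    }
    hidden <- tb$hidden[[network]]
    if (is.null(epochs)) epochs <- tb$epochs[[network]]
  }
  structure(list(network = network, hidden = as.integer(hidden),
                 epochs = as.integer(epochs)),
            class = "nn_config")
}

#' Training-dataset definitions
#'
#' The four dataset compositions: 1 = AP only; 2 = ML only; 3 = STC, AP and
#' ML; 4 = all five exercises. Four of the five repetitions train the
#' models; the remaining repetition is the holdout used for evaluation.
#'
#' @param id dataset id 1-4.
#' @return A list of class `dataset_spec` with `id` and `exercises`.
#' @export
dataset_spec <- function(id) {
  ex <- switch(as.character(id),
               "1" = "AP", "2" = "ML",
               "3" = c("STC", "AP", "ML"),
               "4" = exercise_kinds,
               stop_invalid("dataset id must be 1-4", "copsplit_invalid_parameter"))
  structure(list(id = id, exercises = ex), class = "dataset_spec")
}

# decimated (inputs, targets) rows of one trial over its exercise window
trial_rows <- function(trial, decimate_to = 100) {
  keep <- which(trial$truth_left$time >= trial$meta$exercise_start_s)
  stride <- max(1L, round(trial$meta$spec$rate / decimate_to))
  keep <- keep[seq(1L, length(keep), by = stride)]
  g <- trial$global_cop[keep, ]
  l <- trial$truth_left[keep, ]
  r <- trial$truth_right[keep, ]
  list(inputs = cbind(x = g$x, y = g$y, fz = g$fz),
       targets = cbind(xL = l$x, yL = l$y, FzL = l$fz,
                       xR = r$x, yR = r$y, FzR = r$fz))
}

#' Assemble training and holdout row tables
#'
#' One row per (decimated) time sample: inputs are the global
#' `(xCoP, yCoP, Fz)`, targets the six per-foot values. Rows from the
#' holdout repetition are kept in a separate table and never touch the
#' training pipeline (scaling included).
#'
#' @param trials list of trials ([generate_trial()]) or a `cohort` from
#'   [cohort_plan()] (trials are then realised one at a time and
#'   discarded, keeping memory flat).
#' @param spec a [dataset_spec()] (or id 1-4).
#' @param holdout_rep repetition reserved for evaluation; default the
#'   highest repetition present.
#' @param decimate_to target row rate in Hz (default 100; CoP content is
#'   below ~1 Hz so this loses nothing material).
#' @return A list with elements `train` and `holdout`, each containing
#'   `inputs`, `targets` and a `meta` tibble (subject, exercise,
#'   repetition per row), plus `spec`.
#' @export
assemble_dataset <- function(trials, spec, holdout_rep = NULL,
                             decimate_to = 100) {
  if (!inherits(spec, "dataset_spec")) spec <- dataset_spec(spec)
  is_cohort <- inherits(trials, "cohort")
  plan <- if (is_cohort) {
    trials$plan
  } else {
    tibble::tibble(
      subject = vapply(trials, function(tr) tr$meta$subject$id, numeric(1)),
      exercise = vapply(trials, function(tr) tr$meta$exercise, character(1)),
      repetition = vapply(trials, function(tr) tr$meta$repetition, numeric(1))
    )
  }
  if (is.null(holdout_rep)) holdout_rep <- max(plan$repetition)
  sel <- plan$exercise %in% spec$exercises
  have <- unique(plan$exercise[sel])
  if (!setequal(have, spec$exercises) ||
      !holdout_rep %in% plan$repetition ||
      length(unique(plan$repetition[sel])) < 2L) {
    stop_invalid("trials do not cover the dataset's exercises and repetitions",
                 "copsplit_dataset_incomplete")
  }
  grab <- function(rows) {
    parts <- lapply(rows, function(i) {
      tr <- if (is_cohort) realize_trial(trials, i) else trials[[i]]
      rw <- trial_rows(tr, decimate_to)
      k <- nrow(rw$inputs)
      list(inputs = rw$inputs, targets = rw$targets,
           meta = tibble::tibble(subject = rep(plan$subject[i], k),
                                 exercise = rep(plan$exercise[i], k),
                                 repetition = rep(plan$repetition[i], k)))
    })
    list(inputs = do.call(rbind, lapply(parts, `[[`, "inputs")),
         targets = do.call(rbind, lapply(parts, `[[`, "targets")),
         meta = dplyr::bind_rows(lapply(parts, `[[`, "meta")))
  }
  train_rows <- which(sel & plan$repetition != holdout_rep)
  hold_rows <- which(sel & plan$repetition == holdout_rep)
  out <- list(train = grab(train_rows), holdout = grab(hold_rows),
              spec = spec, holdout_rep = holdout_rep,
              decimate_to = decimate_to)
  class(out) <- "nn_dataset"
  out
}

# ---------------------------------------------------------------------------
# weight flattening and forward/backward passes

mlp_shapes <- function(hidden, n_in = 3L, n_out = 6L) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L),
         function(l) c(out = sizes[l + 1L], inp = sizes[l]))
}

mlp_n_par <- function(shapes) {
  sum(vapply(shapes, function(s) s["out"] * (s["inp"] + 1L), numeric(1)))
}

mlp_unflatten <- function(theta, shapes) {
  off <- 0L
  lapply(shapes, function(s) {
    nw <- s[["out"]] * s[["inp"]]
    W <- matrix(theta[off + seq_len(nw)], s[["out"]], s[["inp"]])
    b <- theta[off + nw + seq_len(s[["out"]])]
    off <<- off + nw + s[["out"]]
    list(W = W, b = b)
  })
}

mlp_init <- function(shapes) {
  unlist(lapply(shapes, function(s) {
    fan <- s[["inp"]]
    c(runif(s[["out"]] * fan, -1, 1) / sqrt(fan), runif(s[["out"]], -0.1, 0.1))
  }))
}

# forward pass; returns list(out, acts) with acts[[l]] the activations
# feeding layer l (acts[[1]] = X)
mlp_forward <- function(layers, X, keep_acts = FALSE) {
  L <- length(layers)
  acts <- if (keep_acts) vector("list", L) else NULL
  A <- X
  for (l in seq_len(L)) {
    if (keep_acts) acts[[l]] <- A
    Z <- tcrossprod(A, layers[[l]]$W)
    Z <- sweep(Z, 2L, layers[[l]]$b, `+`)
    A <- if (l < L) tanh(Z) else Z
  }
  list(out = A, acts = acts)
}

# mean-squared-error and its gradient over all weights
mlp_mse_grad <- function(theta, shapes, X, Y, want_grad = TRUE) {
  layers <- mlp_unflatten(theta, shapes)
  fw <- mlp_forward(layers, X, keep_acts = want_grad)
  E <- fw$out - Y
  mse <- mean(E^2)
  if (!want_grad) return(list(mse = mse))
  n <- nrow(X)
  L <- length(layers)
  D <- 2 * E / (n * ncol(Y))
  grads <- vector("list", L)
  for (l in seq(L, 1L)) {
    A_prev <- fw$acts[[l]]
    grads[[l]] <- c(crossprod(D, A_prev), colSums(D))
    if (l > 1L) {
      D <- (D %*% layers[[l]]$W) * (1 - fw$acts[[l]]^2)
    }
  }
  list(mse = mse, grad = unlist(grads))
}

# Accumulate J'J and J'r over chunks for the Levenberg-Marquardt step;
# residuals r = yhat - y (scaled units). Analytic Jacobian via per-output
# backpropagation.
mlp_normal_eqs <- function(theta, shapes, X, Y, chunk = 2048L) {
  layers <- mlp_unflatten(theta, shapes)
  p <- length(theta)
  JtJ <- matrix(0, p, p)
  Jtr <- numeric(p)
  sse <- 0
  n <- nrow(X)
  n_out <- ncol(Y)
  L <- length(layers)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    Xc <- X[idx, , drop = FALSE]
    fw <- mlp_forward(layers, Xc, keep_acts = TRUE)
    r <- fw$out - Y[idx, , drop = FALSE]
    sse <- sse + sum(r^2)
    nc <- length(idx)
    J <- matrix(0, nc * n_out, p)
    for (k in seq_len(n_out)) {
      D <- matrix(0, nc, n_out)
      D[, k] <- 1
      off <- p
      rows <- (k - 1L) * nc + seq_len(nc)
      for (l in seq(L, 1L)) {
        A_prev <- fw$acts[[l]]
        u <- ncol(D)
        ni <- ncol(A_prev)
        # columns for W_l (column-major: W[i,j] at (j-1)*u + i), then b_l
        blk <- A_prev[, rep(seq_len(ni), each = u), drop = FALSE] *
          D[, rep(seq_len(u), times = ni), drop = FALSE]
        off <- off - u * (ni + 1L)
        J[rows, off + seq_len(u * ni)] <- blk
        J[rows, off + u * ni + seq_len(u)] <- D
        if (l > 1L) D <- (D %*% layers[[l]]$W) * (1 - fw$acts[[l]]^2)
      }
    }
    JtJ <- JtJ + crossprod(J)
    # residual vector in column-major order matches J's output-major blocks
    Jtr <- Jtr + as.numeric(crossprod(J, as.numeric(r)))
  }
  list(JtJ = JtJ, Jtr = Jtr, sse = sse)
}

minmax_fit <- function(M) {
  lo <- apply(M, 2L, min)
  hi <- apply(M, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}
minmax_apply <- function(M, sc) {
  sweep(sweep(M, 2L, sc$lo), 2L, sc$span, `/`) * 2 - 1
}
minmax_invert <- function(M, sc) {
  sweep(sweep((M + 1) / 2, 2L, sc$span, `*`), 2L, sc$lo, `+`)
}

#' Train an MLP on an assembled dataset
#'
#' Scales inputs and targets to `[-1, 1]` (min-max fitted on the training
#' table only), draws the internal random 70/15/15
#' train/validation/test split, and optimises the mean squared error by
#' Levenberg-Marquardt with analytic Jacobian. Training stops at
#' `config$epochs` iterations or after `patience` consecutive validation
#' failures, returning the weights with the best validation loss.
#' Networks with more than `lm_max_par` weights use full-batch L-BFGS
#' instead (the quasi-Newton fallback; recorded in the model metadata).
#' Deterministic given `seed`.
#'
#' @param data an `nn_dataset` from [assemble_dataset()], or a list with
#'   `inputs` and `targets` matrices.
#' @param config an [nn_config()].
#' @param seed RNG seed governing the split and the weight initialisation.
#' @param max_rows cap on training rows (uniform stride subsample before
#'   the internal split); the band-limited CoP signals are heavily
#'   oversampled even at 100 Hz, so a few thousand rows carry the full
#'   input-output relation. Default 3000.
#' @param patience consecutive validation failures tolerated (default 6).
#' @param lm_max_par largest weight count optimised by
#'   Levenberg-Marquardt (default 600).
#' @param optimizer `"auto"`, `"lm"` or `"lbfgs"`.
#' @return A list of class `copsplit_nn`: weights, scaling parameters,
#'   config, seed, optimiser name and training history.
#' @export
train_model <- function(data, config, seed = 1L, max_rows = 3000L,
                        patience = 6L, lm_max_par = 600L,
                        optimizer = c("auto", "lm", "lbfgs")) {
  optimizer <- match.arg(optimizer)
  tr <- if (inherits(data, "nn_dataset")) data$train else data
  X <- tr$inputs
  Y <- tr$targets
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop_invalid("training rows must be finite", "copsplit_invalid_input")
  }
  if (nrow(X) > max_rows) {
    keep <- round(seq(1L, nrow(X), length.out = max_rows))
    X <- X[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  set.seed(seed)
  sc_in <- minmax_fit(X)
  sc_out <- minmax_fit(Y)
  Xs <- minmax_apply(X, sc_in)
  Ys <- minmax_apply(Y, sc_out)
  n <- nrow(Xs)
  shuffled <- sample.int(n)
  n_tr <- floor(0.70 * n)
  n_va <- floor(0.15 * n)
  i_tr <- shuffled[seq_len(n_tr)]
  i_va <- shuffled[n_tr + seq_len(n_va)]
  i_te <- shuffled[(n_tr + n_va + 1L):n]
  shapes <- mlp_shapes(config$hidden)
  p <- mlp_n_par(shapes)
  theta <- mlp_init(shapes)
  use_lm <- switch(optimizer, lm = TRUE, lbfgs = FALSE, auto = p <= lm_max_par)
  val_mse <- function(th) {
    mlp_mse_grad(th, shapes, Xs[i_va, , drop = FALSE],
                 Ys[i_va, , drop = FALSE], want_grad = FALSE)$mse
  }
  history <- list(train = numeric(0), val = numeric(0))
  best <- list(theta = theta, val = val_mse(theta), iter = 0L)
  fails <- 0L

  if (use_lm) {
    lambda <- 1e-2
    Xt <- Xs[i_tr, , drop = FALSE]
    Yt <- Ys[i_tr, , drop = FALSE]
    m6 <- length(i_tr) * ncol(Yt)
    for (iter in seq_len(config$epochs)) {
      ne <- mlp_normal_eqs(theta, shapes, Xt, Yt)
      if (!is.finite(ne$sse)) {
        stop_invalid("training diverged: non-finite loss",
                     "copsplit_training_diverged",
                     iteration = iter)
      }
      improved <- FALSE
      for (try in 1:10) {
        step <- tryCatch(
          solve(ne$JtJ + lambda * diag(p), ne$Jtr),
          error = function(e) NULL)
        if (!is.null(step)) {
          cand <- theta - step
          sse_new <- mlp_mse_grad(cand, shapes, Xt, Yt, want_grad = FALSE)$mse * m6
          if (is.finite(sse_new) && sse_new < ne$sse) {
            theta <- cand
            lambda <- max(lambda * 0.1, 1e-12)
            improved <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
      tr_mse <- mlp_mse_grad(theta, shapes, Xt, Yt, want_grad = FALSE)$mse
      v <- val_mse(theta)
      history$train <- c(history$train, tr_mse)
      history$val <- c(history$val, v)
      # a validation "pass" needs a meaningful (0.1% relative) improvement;
      # the best weights are still tracked at full precision
      meaningful <- v < best$val * (1 - 1e-3)
      if (v < best$val) best <- list(theta = theta, val = v, iter = iter)
      fails <- if (meaningful) 0L else fails + 1L
      if (fails >= patience || !improved) break
    }
    opt_name <- "levenberg-marquardt"
  } else {
    Xt <- Xs[i_tr, , drop = FALSE]
    Yt <- Ys[i_tr, , drop = FALSE]
    seg <- 25L
    iters_done <- 0L
    while (iters_done < config$epochs) {
      res <- optim(theta,
                   fn = function(th) mlp_mse_grad(th, shapes, Xt, Yt, want_grad = FALSE)$mse,
                   gr = function(th) mlp_mse_grad(th, shapes, Xt, Yt)$grad,
                   method = "L-BFGS-B",
                   control = list(maxit = min(seg, config$epochs - iters_done)))
      theta <- res$par
      if (!is.finite(res$value)) {
        stop_invalid("training diverged: non-finite loss",
                     "copsplit_training_diverged")
      }
      iters_done <- iters_done + seg
      v <- val_mse(theta)
      history$train <- c(history$train, res$value)
      history$val <- c(history$val, v)
      meaningful <- v < best$val * (1 - 1e-3)
      if (v < best$val) best <- list(theta = theta, val = v, iter = iters_done)
      fails <- if (meaningful) 0L else fails + 1L
      if (fails >= patience || res$convergence == 0) break
    }
    opt_name <- "l-bfgs"
  }

  test_mse <- mlp_mse_grad(best$theta, shapes, Xs[i_te, , drop = FALSE],
                           Ys[i_te, , drop = FALSE], want_grad = FALSE)$mse
  structure(list(
    config = config, shapes = shapes, theta = best$theta,
    scale_in = sc_in, scale_out = sc_out,
    seed = seed, optimizer = opt_name,
    history = history,
    final = list(train = tail(history$train, 1L), val = best$val,
                 test = test_mse, best_iter = best$iter),
    split_sizes = c(train = length(i_tr), val = length(i_va), test = length(i_te)),
    n_rows = n
  ), class = "copsplit_nn")
}

#' @export
print.copsplit_nn <- function(x, ...) {
  cat(sprintf("<copsplit_nn> hidden (%s), %d weights, %s, %d rows; val MSE %.3g (iter %d)\n",
              paste(x$config$hidden, collapse = ","),
              length(x$theta), x$optimizer, x$n_rows,
              x$final$val, x$final$best_iter))
  invisible(x)
}

#' Predict a per-foot split with a trained network
#'
#' Maps each global sample through the network and de-scales to physical
#' units. Unlike the analytical split, the network does not guarantee
#' `FzL + FzR = Fz`; the conservation residual is returned in column
#' `fz_resid`. Inputs outside the training range produce a single
#' extrapolation warning.
#'
#' @param model a trained [train_model()] network.
#' @param global a [grf_trajectory()].
#' @return A [split_result()] with extra column `fz_resid`.
#' @export
predict_split <- function(model, global) {
  ok <- global$valid
  X <- cbind(global$x, global$y, global$fz)
  Xok <- X[ok, , drop = FALSE]
  margin <- 0.05 * model$scale_in$span
  out_rng <- sweep(Xok, 2L, model$scale_in$lo - margin) < 0 |
    sweep(Xok, 2L, model$scale_in$lo + model$scale_in$span + margin) > 0
  if (any(out_rng)) {
    warn(sprintf("%d sample(s) outside the training input range; extrapolating",
                 sum(rowSums(out_rng) > 0)),
         class = "copsplit_extrapolation")
  }
  layers <- mlp_unflatten(model$theta, model$shapes)
  Yh <- minmax_invert(mlp_forward(layers, minmax_apply(Xok, model$scale_in))$out,
                      model$scale_out)
  full <- matrix(NA_real_, nrow(X), 6L)
  full[ok, ] <- Yh
  fzL <- pmax(full[, 3L], 0)
  fzR <- pmax(full[, 6L], 0)
  left <- grf_trajectory(global$time, full[, 1L], full[, 2L], fzL, ok)
  right <- grf_trajectory(global$time, full[, 4L], full[, 5L], fzR, ok)
  sp <- split_result(global$time, left, right)
  sp$fz_resid <- global$fz - (fzL + fzR)
  sp
}

#' Elimination-based model selection
#'
#' Given per-configuration metric reports, performs three elimination
#' rounds: (1) drop the configurations with the highest NRMSE on the AP and
#' ML exercises (the machine's task exercises); (2) drop those with the
#' highest NRMSE on the remaining exercises; (3) drop those with the worst
#' correlation index. The per-round score is the maximum over the round's
#' exercise set of the mean NRMSE across the six per-foot variables (mean
#' correlation for round 3). Ties drop all tied configurations; with fewer
#' than 10 configurations the drop counts (2, 3, 4) are scaled down
#' proportionally.
#'
#' @param reports tidy tibble with columns `config`, `exercise`, `foot`,
#'   `variable`, `metric`, `value` (means over holdout trials).
#' @param task_exercises exercises driving round 1 (default AP and ML).
#' @param drop_counts configurations eliminated per round for a 10-config
#'   field.
#' @return A list with `selected` (config number), `rounds` (tibble of
#'   eliminations) and `trivial` (logical; all reports identical).
#' @export
select_model <- function(reports, task_exercises = c("AP", "ML"),
                         drop_counts = c(2L, 3L, 4L)) {
  configs <- sort(unique(reports$config))
  n0 <- length(configs)
  if (n0 < 2L) {
    warn("fewer than 2 configurations: selection is trivial",
         class = "copsplit_selection_trivial")
    return(list(selected = configs[1L], rounds = tibble::tibble(), trivial = TRUE))
  }
  if (n0 < 10L) {
    drop_counts <- pmax(0L, round(drop_counts * n0 / 10))
    while (sum(drop_counts) >= n0) {
      i <- which.max(drop_counts)
      drop_counts[i] <- drop_counts[i] - 1L
    }
  }
  score_nrmse <- function(cfgs, exs) {
    d <- reports[reports$config %in% cfgs & reports$exercise %in% exs &
                   reports$metric == "NRMSE", ]
    agg <- dplyr::summarise(
      dplyr::group_by(d, .data$config, .data$exercise),
      m = mean(.data$value, na.rm = TRUE), .groups = "drop")
    out <- dplyr::summarise(dplyr::group_by(agg, .data$config),
                            score = max(.data$m), .groups = "drop")
    setNames(out$score, out$config)
  }
  score_cor <- function(cfgs) {
    d <- reports[reports$config %in% cfgs & reports$metric == "COR", ]
    out <- dplyr::summarise(dplyr::group_by(d, .data$config),
                            score = mean(.data$value, na.rm = TRUE),
                            .groups = "drop")
    setNames(out$score, out$config)
  }
  drop_worst <- function(scores, k, higher_is_worse = TRUE) {
    if (k <= 0L) return(character(0))
    ord <- sort(scores, decreasing = higher_is_worse)
    if (length(unique(scores)) == 1L) return(names(scores)) # all tied
    cut <- ord[k]
    worst <- if (higher_is_worse) names(scores)[scores >= cut] else
      names(scores)[scores <= cut]
    worst
  }
  remaining <- as.character(configs)
  all_ex <- unique(reports$exercise)
  rest_ex <- setdiff(all_ex, task_exercises)
  if (length(rest_ex) == 0L) rest_ex <- all_ex
  rounds <- list()
  plan <- list(
    list(score = function(c) score_nrmse(c, intersect(task_exercises, all_ex)),
         k = drop_counts[1L], worse_high = TRUE, label = "NRMSE task exercises"),
    list(score = function(c) score_nrmse(c, rest_ex),
         k = drop_counts[2L], worse_high = TRUE, label = "NRMSE remaining exercises"),
    list(score = function(c) score_cor(c),
         k = drop_counts[3L], worse_high = FALSE, label = "correlation index")
  )
  trivial <- FALSE
  for (rd in seq_along(plan)) {
    if (length(remaining) <= 1L) break
    sc <- plan[[rd]]$score(remaining)
    sc <- sc[remaining]
    if (length(unique(round(sc, 12))) == 1L) {
      trivial <- TRUE
      next
    }
    worst <- drop_worst(sc, min(plan[[rd]]$k, length(remaining) - 1L),
                        plan[[rd]]$worse_high)
    worst <- head(worst, length(remaining) - 1L)
    rounds[[rd]] <- tibble::tibble(round = rd, criterion = plan[[rd]]$label,
                                   eliminated = as.integer(worst),
                                   score = as.numeric(sc[worst]))
    remaining <- setdiff(remaining, worst)
  }
  if (trivial && length(remaining) == n0) {
    warn("all configurations score identically: selection is trivial",
         class = "copsplit_selection_trivial")
  }
  list(selected = as.integer(min(as.integer(remaining))),
       rounds = dplyr::bind_rows(rounds), trivial = trivial)
}
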