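# Independent naive oracles used to cross-check the vectorised
# implementations. Deliberately written as explicit double loops.

naive_rmse <- function(real, pred) {
  acc <- 0
  for (i in seq_along(real)) acc <- acc + (real[i] - pred[i])^2
  sqrt(acc / length(real))
}

naive_nrmse <- function(real, pred, ref) naive_rmse(real, pred) / ref * 100

naive_cor <- function(real, pred) {
  n <- length(real)
  mr <- 0; mp <- 0
  for (i in seq_len(n)) { mr <- mr + real[i]; mp <- mp + pred[i] }
  mr <- mr / n; mp <- mp / n
  num <- 0; dr <- 0; dp <- 0
  for (i in seq_len(n)) {
    num <- num + (real[i] - mr) * (pred[i] - mp)
    dr <- dr + (real[i] - mr)^2
    dp <- dp + (pred[i] - mp)^2
  }
  num / sqrt(dr * dp)
}

# CoP by explicit per-sensor accumulation
naive_cop <- function(forces, sensor_xy) {
  fz <- 0; mx <- 0; my <- 0
  for (j in seq_along(forces)) {
    fz <- fz + forces[j]
    mx <- mx + forces[j] * sensor_xy[j, 1]
    my <- my + forces[j] * sensor_xy[j, 2]
  }
  c(x = mx / fz, y = my / fz, fz = fz)
}

# constant-state recording helper: n samples of the given channel forces
const_recording <- function(forces, n = 10, rate = 100, plate = "lower") {
  plate_recording((seq_len(n) - 1) / rate,
                  matrix(rep(forces, each = n), n), rate, plate = plate)
}

# single-sample global trajectory
state_traj <- function(x, y, fz) grf_trajectory(0, x, y, fz)
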