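# Independent oracles for the turnover model, deliberately sharing no code
# with R/: eigendecomposition instead of Matrix::expm / RK45, and direct
# formula evaluation.

# generator of the five-pool linear system, rebuilt from scratch
oracle_matrix <- function(k_tilde, gamma, k_DT, psi, sigma = 0) {
  A <- matrix(0, 5, 5)
  A[1, 1] <- -(gamma + psi); A[1, 4] <- k_tilde
  A[2, 2] <- -psi;           A[2, 4] <- sigma * k_tilde
  A[3, 1] <- gamma;          A[3, 3] <- -(k_DT + psi)
  A[4, 3] <- k_DT;           A[4, 4] <- -((1 + sigma) * k_tilde + psi)
  A[5, 1:4] <- psi
  A
}

# x(t) = E exp(D t) E^-1 x0 via eigendecomposition (generic parameter draws
# give distinct eigenvalues)
oracle_solve <- function(k_tilde, gamma, k_DT, psi, sigma, x0, times) {
  A <- oracle_matrix(k_tilde, gamma, k_DT, psi, sigma)
  eg <- eigen(A)
  c0 <- solve(eg$vectors, x0)
  t(vapply(times, function(t)
    Re(eg$vectors %*% (exp(eg$values * t) * c0))[, 1], numeric(5)))
}

# assembly-mode tail length, evaluated straight from the printed formula
oracle_assembly_l <- function(t, V0, l_max, sigma)
  l_max / (1 + sigma) * (1 - exp(-(1 + sigma) * V0 * t / l_max))

# velocity series of a noiseless track as data.frame for fitting tests
make_model_track <- function(params, duration_min, dt_min,
                             id = "oracle_track") {
  tg <- seq(0, duration_min, by = dt_min)
  traj <- simulate_turnover(params, t_grid = tg)
  comet_track(time_min = tg, comet_length_um = traj$states[, "l"],
              track_id = id,
              bead_velocity_um_per_min = traj$velocities)
}

expect_rel_equal <- function(actual, expected, rtol, info = NULL) {
  expect_true(all(abs(actual - expected) <= rtol * abs(expected)),
              info = info)
}
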