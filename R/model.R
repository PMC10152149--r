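#' Tail assembly rate from the ATP-G-actin pool
#'
#' The growth speed law in length units: `V = k_tilde * G_T`. With the whole
#' pool as ATP-G-actin (`G_T = l_max`) this gives the maximal velocity
#' `V0 = k_tilde * l_max` (about 1 um/min at the canonical constants).
#'
#' @param G_T ATP-G-actin, um length-equivalent (scalar or vector).
#' @param params a [turnover_params()].
#' @return assembly velocity, um/min.
#' @export
assembly_rate <- function(G_T, params) {
  stopifnot(inherits(params, "turnover_params"))
  if (any(G_T < 0)) stop("G_T must be nonnegative")
  params$k_tilde * G_T
}

#' Closed-form solution of the assembly-only model
#'
#' Without disassembly machinery the tail and the non-tail F-actin grow at
#' rates `V0 * (1 - (l + l_tilde)/l_max)` and `sigma` times that, giving
#' `l(t) = l_max/(1+sigma) * (1 - exp(-(1+sigma) V0 t / l_max))` and
#' `l_tilde = sigma * l`. With `sigma = 1` the tail saturates at half the
#' pool, matching the observed ~50% of subunits in the tail.
#'
#' @param t time, minutes (scalar or vector, >= 0).
#' @param V0 initial (maximal) velocity, um/min.
#' @param l_max pool length, um.
#' @param sigma non-tail assembly factor, >= 0.
#' @return data.frame with columns `time_min`, `l_um`, `l_tilde_um`.
#' @export
assembly_closed_form <- function(t, V0, l_max, sigma = 0) {
  if (any(t < 0)) stop("t must be nonnegative")
  stopifnot(V0 > 0, l_max > 0, sigma >= 0)
  l <- l_max / (1 + sigma) * (1 - exp(-(1 + sigma) * V0 * t / l_max))
  data.frame(time_min = t, l_um = l, l_tilde_um = sigma * l)
}

#' Saturation timescale of assembly-only growth
#'
#' The exponential time constant of the closed-form solution,
#' `l_max / ((1 + sigma) V0)`: with l_max ~ 100 um, V0 ~ 1 um/min and
#' sigma = 1 the tail saturates on the hour scale.
#'
#' @inheritParams assembly_closed_form
#' @return time constant, minutes.
#' @export
saturation_timescale <- function(l_max, V0, sigma = 0) {
  if (V0 <= 0) stop("V0 must be positive")
  stopifnot(l_max > 0, sigma >= 0)
  l_max / ((1 + sigma) * V0)
}

#' Simulate the turnover model
#'
#' Integrates the pool dynamics
#' \deqn{dl/dt = V - (\gamma + \psi) l}
#' \deqn{dG_D/dt = \gamma l - (k_{DT} + \psi) G_D}
#' \deqn{dG_T/dt = k_{DT} G_D - V - \psi G_T}
#' with `V = k_tilde * G_T`, plus (assembly mode only) the non-tail pool
#' `dl_tilde/dt = sigma V - psi l_tilde` and the aged bookkeeping pool
#' `d(aged)/dt = psi * (l + l_tilde + G_D + G_T)`, so the five pools sum to
#' `l_max` exactly at all times. With `psi = 0` this is the pure turnover
#' system; with `gamma = k_DT = psi = 0` and `sigma > 0` it reduces to the
#' assembly-only model with the closed-form solution.
#'
#' The system is linear, so the default method propagates the exact matrix
#' exponential (stiff-proof, conservation to machine precision). The
#' `"rk45"` method runs the adaptive Dormand-Prince integrator instead and
#' exists as an independent numerical route.
#'
#' @param params a [turnover_params()]. `sigma > 0` requires
#'   `gamma = k_DT = 0` (non-tail filaments are disassembled rapidly once
#'   ADF/cofilin is present and are dropped from the turnover analysis).
#' @param initial a [pool_state()] satisfying conservation against
#'   `params$l_max`; default all-monomer.
#' @param t_grid output times in minutes, strictly increasing, starting at 0.
#' @param method `"analytic"` (default) or `"rk45"`.
#' @param rtol,atol tolerances for the RK45 route.
#' @return a `comet_trajectory`: list with `times`, `states` (matrix with
#'   columns l, l_tilde, G_D, G_T, aged), `velocities` (`V = k_tilde G_T`),
#'   and `params`.
#' @export
simulate_turnover <- function(params, initial = initial_pool(params$l_max),
                              t_grid, method = c("analytic", "rk45"),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "turnover_params"))
  method <- match.arg(method)
  if (params$sigma > 0 && (params$gamma > 0 || params$k_DT > 0))
    stop("sigma > 0 is only supported in assembly mode (gamma = k_DT = 0)")
  if (!inherits(initial, "pool_state"))
    initial <- do.call(pool_state, as.list(initial))
  if (abs(sum(initial) - params$l_max) > 1e-6 * params$l_max)
    stop(sprintf("initial state sums to %.6g but l_max = %.6g",
                 sum(initial), params$l_max))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")
  A <- .turnover_matrix(params)
  x0 <- unclass(initial)
  states <- switch(method,
    analytic = .propagate_expm(A, x0, t_grid),
    rk45 = ode_rk45(function(t, y) drop(A %*% y), x0, t_grid,
                    rtol = rtol, atol = atol))
  states <- pmax(states, 0) # clip solver-level negative round-off
  structure(list(times = t_grid, states = states,
                 velocities = params$k_tilde * states[, "G_T"],
                 params = params),
            class = "comet_trajectory")
}

#' @export
print.comet_trajectory <- function(x, ...) {
  cat(sprintf("comet trajectory: %d time points over %.6g min\n",
              length(x$times), max(x$times)))
  cat(sprintf("  final pools (um): l = %.4g, l_tilde = %.4g, G_D = %.4g, G_T = %.4g, aged = %.4g\n",
              x$states[nrow(x$states), 1], x$states[nrow(x$states), 2],
              x$states[nrow(x$states), 3], x$states[nrow(x$states), 4],
              x$states[nrow(x$states), 5]))
  invisible(x)
}

#' @export
as.data.frame.comet_trajectory <- function(x, ...) {
  data.frame(time_min = x$times,
             l_um = x$states[, "l"],
             l_tilde_um = x$states[, "l_tilde"],
             GD_um = x$states[, "G_D"],
             GT_um = x$states[, "G_T"],
             aged_um = x$states[, "aged"],
             V_um_per_min = x$velocities)
}

#' Conservation residual of a trajectory
#'
#' Max over output times of `|l + l_tilde + G_D + G_T + aged - l_max|`.
#' @param traj a `comet_trajectory`.
#' @return residual, um.
#' @export
conservation_residual <- function(traj) {
  max(abs(rowSums(traj$states) - traj$params$l_max))
}

#' Analytic dynamic steady state of the turnover model
#'
#' Without aging (`psi = 0`) the turnover system relaxes to a unique steady
#' state where the assembly, disassembly and recycling fluxes balance:
#' `gamma l* = k_tilde G_T* = k_DT G_D*`. With `alpha = k_tilde / k_DT` and
#' `beta = k_tilde / gamma`,
#' `G_T* = l_max / S`, `G_D* = alpha l_max / S`, `l* = beta l_max / S`,
#' `V* = k_tilde l_max / S`, where `S = 1 + alpha + beta`.
#'
#' @param params a [turnover_params()] with `psi = 0`, `gamma > 0`,
#'   `k_DT > 0`.
#' @return object of class `steady_state_solution`: list with `alpha`,
#'   `beta`, `S`, `G_T_star`, `G_D_star`, `l_star` (um) and `V_star`
#'   (um/min).
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "turnover_params"))
  if (params$psi != 0)
    stop("no nontrivial steady state with aging (psi != 0)")
  if (params$gamma <= 0 || params$k_DT <= 0)
    stop("steady state requires gamma > 0 and k_DT > 0")
  if (params$sigma > 0)
    stop("sigma > 0 is only supported in assembly mode")
  alpha <- params$k_tilde / params$k_DT
  beta <- params$k_tilde / params$gamma
  S <- 1 + alpha + beta
  structure(list(alpha = alpha, beta = beta, S = S,
                 G_T_star = params$l_max / S,
                 G_D_star = alpha * params$l_max / S,
                 l_star = beta * params$l_max / S,
                 V_star = params$k_tilde * params$l_max / S,
                 params = params),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("steady state: alpha = %.4g, beta = %.4g, 1+alpha+beta = %.4g\n",
              x$alpha, x$beta, x$S))
  cat(sprintf("  l* = %.4g um, G_T* = %.4g um, G_D* = %.4g um, V* = %.4g um/min\n",
              x$l_star, x$G_T_star, x$G_D_star, x$V_star))
  invisible(x)
}

#' Assembly, disassembly and recycling fluxes of a pool state
#'
#' Returns `(k_tilde G_T, gamma l, k_DT G_D)` in um/min. At steady state the
#' three are equal.
#'
#' @param state a [pool_state()] (or coercible named vector).
#' @param params a [turnover_params()].
#' @return named numeric vector `c(assembly, disassembly, recycling)`.
#' @export
flux_triplet <- function(state, params) {
  stopifnot(inherits(params, "turnover_params"))
  if (!inherits(state, "pool_state"))
    state <- do.call(pool_state, as.list(state))
  c(assembly = params$k_tilde * state[["G_T"]],
    disassembly = params$gamma * state[["l"]],
    recycling = params$k_DT * state[["G_D"]])
}
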