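#' Measurement and between-track noise model for synthetic experiments
#'
#' The source experiments report mean +/- SD curves but no error
#' magnitudes, so every default here is an explicit generator choice, not a
#' measured value. Multiplicative lognormal noise is used because lengths,
#' areas and intensities are positive.
#'
#' @param cv_obs multiplicative CV on observed lengths/velocities/areas
#'   (lognormal, mean 1). Default 0.10.
#' @param additive_floor additive noise floor, a.u. Default 0.
#' @param cv_params between-track lognormal CV on `gamma`, `k_DT`, `psi`.
#'   Default 0.15.
#' @param frame_interval_min frame interval, minutes. Default 2.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(cv_obs = 0.10, additive_floor = 0, cv_params = 0.15,
                        frame_interval_min = 2, seed = 1) {
  stopifnot(cv_obs >= 0, cv_params >= 0, additive_floor >= 0,
            frame_interval_min > 0)
  structure(list(cv_obs = cv_obs, additive_floor = additive_floor,
                 cv_params = cv_params,
                 frame_interval_min = frame_interval_min,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Specification of a synthetic microwell cohort
#'
#' @param preset condition preset name (see [comet_preset()]).
#' @param n_tracks number of tracks. Default 16.
#' @param duration_h experiment duration, hours. Default 20.
#' @param l_max pool length-equivalent, um. Default 110 (experimental pool
#'   estimate; overrides the preset's own l_max).
#' @param G_bar total actin, uM. Default 3.
#' @param tail_width_um tail width used to synthesize areas, um. Default 2
#'   (bead-radius scale; the source never prints a width).
#' @param noise a [noise_model()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(preset = "recycling", n_tracks = 16, duration_h = 20,
                        l_max = 110, G_bar = 3, tail_width_um = 2,
                        noise = noise_model()) {
  stopifnot(n_tracks >= 1, duration_h > 0, l_max > 0, tail_width_um > 0)
  preset <- match.arg(preset, comet_preset())
  structure(list(preset = preset, n_tracks = as.integer(n_tracks),
                 duration_h = duration_h, l_max = l_max, G_bar = G_bar,
                 tail_width_um = tail_width_um, noise = noise),
            class = "cohort_spec")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.lognorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic comet track
#'
#' Draws per-track rates from the between-track distribution, forward-
#' simulates the turnover model from the all-monomer state, then observes
#' the trajectory: lengths/velocities/areas with multiplicative lognormal
#' noise, and bead positions by integrating the true velocity along a
#' slowly wandering direction. Fully deterministic given
#' `spec$noise$seed` and `track_index`.
#'
#' @param spec a [cohort_spec()].
#' @param track_index 1-based track index (also seeds the per-track draws).
#' @return a [comet_track()] with attribute `true_params` (the per-track
#'   [turnover_params()]).
#' @export
generate_track <- function(spec, track_index = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- spec$noise
  base <- comet_preset(spec$preset, l_max = spec$l_max)
  withr::with_seed(nm$seed + 7919L * as.integer(track_index), {
    mult <- .lognorm_mult(3, nm$cv_params)
    p <- turnover_params(l_max = spec$l_max, k_tilde = base$k_tilde,
                         gamma = base$gamma * mult[1],
                         k_DT = base$k_DT * mult[2],
                         psi = base$psi * mult[3],
                         sigma = base$sigma)
    t_grid <- seq(0, spec$duration_h * 60, by = nm$frame_interval_min)
    traj <- simulate_turnover(p, t_grid = t_grid)
    n <- length(t_grid)
    l_true <- traj$states[, "l"]
    v_true <- traj$velocities
    l_obs <- l_true * .lognorm_mult(n, nm$cv_obs) + nm$additive_floor
    v_obs <- v_true * .lognorm_mult(n, nm$cv_obs)
    area_obs <- l_obs * spec$tail_width_um * .lognorm_mult(n, nm$cv_obs)
    # persistent-direction random walk of the bead heading
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n - 1, 0, 0.05)))
    dt <- diff(t_grid)
    step <- v_true[-1] * dt
    x <- cumsum(c(0, step * cos(theta[-1])))
    y <- cumsum(c(0, step * sin(theta[-1])))
    track <- comet_track(time_min = t_grid, comet_length_um = l_obs,
                         track_id = sprintf("%s_%02d", spec$preset,
                                            track_index),
                         x_um = x, y_um = y, comet_area_um2 = area_obs,
                         bead_velocity_um_per_min = v_obs)
    attr(track, "true_params") <- p
    track
  })
}

#' Generate a synthetic defect-intensity decay trace
#'
#' `I(t_i) = I0 exp(-t_i / tau) * lognormal(cv)`, emulating the photometry
#' of a tracked comet defect during network disassembly.
#'
#' @param tau_min decay time constant, minutes.
#' @param I0 initial intensity, a.u. Default 100.
#' @param cv multiplicative noise CV. Default 0.
#' @param n_points number of samples. Default 60.
#' @param dt_min sampling interval, minutes. Default 2.
#' @param seed integer seed.
#' @return data.frame with `time_min`, `intensity_au`.
#' @export
generate_defect_trace <- function(tau_min, I0 = 100, cv = 0, n_points = 60,
                                  dt_min = 2, seed = 1) {
  stopifnot(tau_min > 0, I0 > 0, dt_min > 0, n_points >= 2)
  t <- seq(0, by = dt_min, length.out = n_points)
  withr::with_seed(seed, {
    data.frame(time_min = t,
               intensity_au = I0 * exp(-t / tau_min) *
                 .lognorm_mult(n_points, cv))
  })
}

#' Generate a cohort of synthetic tracks with a ground-truth manifest
#'
#' @param spec a [cohort_spec()].
#' @return list with `tracks` (single data.frame, stacked) and `manifest`
#'   (list: spec echo plus per-track true parameters — the ground truth for
#'   parameter-recovery tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tracks <- lapply(seq_len(spec$n_tracks), function(i)
    generate_track(spec, i))
  truth <- lapply(tracks, function(tr) {
    p <- attr(tr, "true_params")
    list(track_id = tr$track_id[1], gamma = p$gamma, k_DT = p$k_DT,
         psi = p$psi, k_tilde = p$k_tilde, sigma = p$sigma,
         l_max = p$l_max)
  })
  list(tracks = do.call(rbind, lapply(tracks, as.data.frame)),
       manifest = list(preset = spec$preset, n_tracks = spec$n_tracks,
                       duration_h = spec$duration_h, l_max = spec$l_max,
                       G_bar = spec$G_bar,
                       tail_width_um = spec$tail_width_um,
                       noise = unclass(spec$noise), truth = truth))
}
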