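#' Build and validate a comet track table
#'
#' Per-frame observables for one comet: time, optional bead position,
#' comet length/area, optional measured velocity and actin intensity.
#' This is the table an upstream image pipeline (threshold / skeletonize /
#' particle analysis / spot tracking) would export; no image processing
#' happens here.
#'
#' @param time_min frame times, minutes, strictly increasing.
#' @param comet_length_um comet (skeleton) length, um, >= 0.
#' @param track_id identifier. Default `"track1"`.
#' @param x_um,y_um optional bead coordinates, um.
#' @param comet_area_um2 optional comet area, um^2, >= 0.
#' @param bead_velocity_um_per_min optional measured velocity series.
#' @param actin_intensity_au optional comet fluorescence.
#' @return data.frame of class `comet_track`.
#' @export
comet_track <- function(time_min, comet_length_um = NULL, track_id = "track1",
                        x_um = NULL, y_um = NULL, comet_area_um2 = NULL,
                        bead_velocity_um_per_min = NULL,
                        actin_intensity_au = NULL) {
  if (length(time_min) < 1 || any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing")
  cols <- list(track_id = track_id, frame = seq_along(time_min),
               time_min = time_min, x_um = x_um, y_um = y_um,
               comet_length_um = comet_length_um,
               comet_area_um2 = comet_area_um2,
               bead_velocity_um_per_min = bead_velocity_um_per_min,
               actin_intensity_au = actin_intensity_au)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  for (nm in c("comet_length_um", "comet_area_um2"))
    if (!is.null(cols[[nm]]) && any(cols[[nm]] < 0))
      stop(nm, " must be nonnegative")
  lens <- vapply(cols[-(1:2)], length, integer(1))
  if (any(lens != length(time_min)))
    stop("all columns must match the length of time_min")
  structure(as.data.frame(cols), class = c("comet_track", "data.frame"))
}

#' Instantaneous comet velocity from a track
#'
#' Central differences of the bead displacement (if `x_um`/`y_um` are
#' present) or of the comet length, with one-sided differences at the
#' endpoints, followed by a centered moving average of odd width
#' (shrinking symmetrically at the ends). Differencing at typical 2-5 min
#' frame intervals amplifies tracking jitter, hence the default 5-frame
#' smoothing window.
#'
#' @param track a [comet_track()].
#' @param window odd moving-average width in frames; 1 disables smoothing.
#' @param source `"auto"` (positions if present, else length),
#'   `"position"`, or `"length"`.
#' @return velocity series, um/min, same length as the track.
#' @export
instantaneous_velocity <- function(track, window = 5,
                                   source = c("auto", "position", "length")) {
  source <- match.arg(source)
  t <- track$time_min
  if (length(t) < 2) stop("need at least 2 frames")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  has_pos <- all(c("x_um", "y_um") %in% names(track))
  use_pos <- switch(source, auto = has_pos, position = TRUE, length = FALSE)
  n <- length(t)
  if (use_pos) {
    if (!has_pos) stop("track has no x_um/y_um columns")
    x <- track$x_um; y <- track$y_um
    # speed over the centered interval; endpoints one-sided
    v <- numeric(n)
    for (i in seq_len(n)) {
      j0 <- max(1L, i - 1L); j1 <- min(n, i + 1L)
      v[i] <- sqrt((x[j1] - x[j0])^2 + (y[j1] - y[j0])^2) / (t[j1] - t[j0])
    }
  } else {
    s <- track$comet_length_um
    if (is.null(s)) stop("track has no comet_length_um column")
    v <- numeric(n)
    for (i in seq_len(n)) {
      j0 <- max(1L, i - 1L); j1 <- min(n, i + 1L)
      v[i] <- (s[j1] - s[j0]) / (t[j1] - t[j0])
    }
  }
  .moving_average(v, window)
}

# centered moving average, window shrinking symmetrically near the ends
.moving_average <- function(v, window) {
  if (window == 1) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(v[(i - h):(i + h)])
  }, numeric(1))
}

#' Exponential decay fit of a velocity or intensity series
#'
#' Fits `y(t) = A exp(-lambda t)` by nonlinear least squares with
#' log-linear initialization (no additive offset). Returns a `decay_fit`
#' carrying the amplitude, rate, time constant `tau = 1/lambda`, half-life
#' `ln(2)/lambda` and R^2. A non-decaying or degenerate series yields a
#' no-fit result (`ok = FALSE`) with a diagnostic rather than an error.
#'
#' @param y series values (positive where used for initialization).
#' @param time time points (same unit as the reported rate's inverse).
#' @param time_unit label stored on the fit (e.g. `"min"`, `"h"`).
#' @param min_points minimum usable points. Default 5.
#' @return object of class `decay_fit`: list with `ok`, `amplitude`,
#'   `rate`, `tau`, `half_life`, `r_squared`, `time_unit`, `note`.
#' @export
fit_exponential_decay <- function(y, time, time_unit = "min",
                                  min_points = 5) {
  keep <- is.finite(y) & is.finite(time) & y > 0
  no_fit <- function(note)
    structure(list(ok = FALSE, amplitude = NA_real_, rate = NA_real_,
                   tau = NA_real_, half_life = NA_real_,
                   r_squared = NA_real_, time_unit = time_unit, note = note),
              class = "decay_fit")
  if (sum(keep) < min_points)
    return(no_fit(sprintf("only %d positive points (need %d)",
                          sum(keep), min_points)))
  tt <- time[keep]; yy <- y[keep]
  ll <- stats::lm(log(yy) ~ tt)
  lam0 <- -unname(stats::coef(ll)[2])
  A0 <- exp(unname(stats::coef(ll)[1]))
  if (!is.finite(lam0) || lam0 <= 0)
    return(no_fit(sprintf("series not decaying (log-linear rate %.3g)",
                          lam0)))
  # noise-free series make the log-linear start exact and nls then stalls on
  # a zero-residual surface; its warnings are not informative here
  fit <- try(suppressWarnings(
    stats::nls(yy ~ A * exp(-lambda * tt),
               start = list(A = A0, lambda = lam0),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    A <- A0; lam <- lam0 # fall back to the log-linear estimate
  } else {
    cf <- stats::coef(fit)
    A <- unname(cf["A"]); lam <- unname(cf["lambda"])
  }
  if (!is.finite(lam) || lam <= 0)
    return(no_fit("nonlinear fit collapsed to a non-decaying rate"))
  resid <- yy - A * exp(-lam * tt)
  r2 <- 1 - sum(resid^2) / sum((yy - mean(yy))^2)
  structure(list(ok = TRUE, amplitude = A, rate = lam, tau = 1 / lam,
                 half_life = log(2) / lam, r_squared = r2,
                 time_unit = time_unit, note = ""),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$ok) {
    cat("exponential decay: no fit (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf(
      "exponential decay: A = %.4g, rate = %.4g /%s, tau = %.4g %s, half-life = %.4g %s (R2 = %.3f)\n",
      x$amplitude, x$rate, x$time_unit, x$tau, x$time_unit,
      x$half_life, x$time_unit, x$r_squared))
  }
  invisible(x)
}

#' Bead-motility half-life from a velocity curve
#'
#' Exponential fit `v(t) = v0 exp(-lambda t)` to the bead velocity series;
#' half-life is `ln(2)/lambda`. Motility decays on the ~0.6 h scale without
#' disassembly machinery, ~2 h with ADF/cofilin and ~8 h with CAP added.
#'
#' @param velocity velocity series, um/min.
#' @param time time points, minutes.
#' @param min_points minimum positive points. Default 5.
#' @return a `decay_fit` with rate per minute.
#' @export
motility_half_life <- function(velocity, time, min_points = 5)
  fit_exponential_decay(velocity, time, time_unit = "min",
                        min_points = min_points)

#' Cumulative polymerized length from a velocity curve
#'
#' Trapezoidal integral of the velocity series: the cumulative length of
#' actin polymerized, the quantity that — divided by the pool length
#' `l_max` — counts monomer-pool cycles.
#'
#' @param velocity velocity series, um/min, >= 0.
#' @param time time points, minutes, strictly increasing.
#' @param clip_negative clip small negative velocities (tracking jitter) to
#'   zero instead of erroring. Default FALSE: silent clipping biases the
#'   integral, so it must be requested explicitly.
#' @return data.frame of class `cycle_series` with `time_min`,
#'   `cumulative_length_um` (non-decreasing).
#' @export
cumulative_polymerized <- function(velocity, time, clip_negative = FALSE) {
  if (length(velocity) != length(time)) stop("length mismatch")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(velocity < 0)) {
    if (!clip_negative)
      stop("negative velocities present; pass clip_negative = TRUE to clip them to 0")
    velocity <- pmax(velocity, 0)
  }
  dt <- diff(time)
  increments <- dt * (utils::head(velocity, -1) + utils::tail(velocity, -1)) / 2
  structure(data.frame(time_min = time,
                       cumulative_length_um = c(0, cumsum(increments))),
            class = c("cycle_series", "data.frame"))
}

#' Monomer-pool cycles from cumulative polymerized length
#'
#' `cycles(t) = cumulative_length(t) / l_max`: how many times the initial
#' monomer pool has been assembled. One cycle corresponds to the full
#' initial pool (3 uM at the canonical composition).
#'
#' @param cycle_series output of [cumulative_polymerized()].
#' @param l_max pool length-equivalent, um (canonically 110).
#' @return the input with a `cycles` column added; attribute `max_cycles`.
#' @export
cycle_count <- function(cycle_series, l_max) {
  if (l_max <= 0) stop("l_max must be positive")
  cycle_series$cycles <- cycle_series$cumulative_length_um / l_max
  attr(cycle_series, "max_cycles") <- max(cycle_series$cycles)
  cycle_series
}

#' Monomer consumption rate from cumulative polymerized length
#'
#' Windowed slope of the cumulative length, converted to concentration per
#' hour: `slope_um_per_min * 60 * G_bar / l_max`. At the reference constant
#' velocity 1.1 um/min with G_bar = 3 uM and l_max = 110 um this is
#' 1.8 uM/h ("about 2").
#'
#' @param cycle_series output of [cumulative_polymerized()].
#' @param G_bar total actin, uM.
#' @param l_max pool length-equivalent, um.
#' @param window slope window, minutes (>= 2 sampling intervals).
#' @return the input with a `consumption_rate_uM_per_h` column added.
#' @export
consumption_rate <- function(cycle_series, G_bar, l_max, window = 60) {
  t <- cycle_series$time_min
  cum <- cycle_series$cumulative_length_um
  if (length(t) >= 2 && window < 2 * stats::median(diff(t)))
    stop("window must span at least 2 sampling intervals")
  n <- length(t)
  rate <- vapply(seq_len(n), function(i) {
    sel <- which(t >= t[i] - window / 2 & t <= t[i] + window / 2)
    if (length(sel) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(cum[sel] ~ t[sel]))[2])
  }, numeric(1))
  cycle_series$consumption_rate_uM_per_h <- rate * 60 * G_bar / l_max
  cycle_series
}

#' Fraction of the actin pool in the comet tail
#'
#' Ratio of background-corrected comet fluorescence to background-corrected
#' total microwell fluorescence. The measured value in assembly conditions
#' is 0.57.
#'
#' @param comet_intensity comet fluorescence, a.u.
#' @param total_intensity total microwell fluorescence, a.u.
#' @param background background level subtracted from both (scalar, or
#'   length-2 `c(comet, total)`).
#' @return list with `fraction` and logical `in_range`.
#' @export
tail_fraction <- function(comet_intensity, total_intensity, background = 0) {
  bg <- if (length(background) == 1) rep(background, 2) else background[1:2]
  denom <- total_intensity - bg[2]
  if (denom <= 0) stop("corrected total intensity must be positive")
  f <- (comet_intensity - bg[1]) / denom
  if (f < 0 || f > 1)
    warning(sprintf("tail fraction %.4g outside [0, 1]", f))
  list(fraction = f, in_range = f >= 0 && f <= 1)
}

#' Network disassembly time constant from a defect-intensity trace
#'
#' Single-exponential fit `I(t) = I0 exp(-t/tau)` to the fluorescence of a
#' tracked comet defect; `tau` is the comet disassembly time (55 min in
#' disassembly conditions, 22 min in recycling conditions on average).
#'
#' @param intensity defect fluorescence trace, a.u.
#' @param time time points, minutes.
#' @param min_points minimum positive points. Default 5.
#' @return a `decay_fit` with `tau` in minutes.
#' @export
decay_time_constant <- function(intensity, time, min_points = 5)
  fit_exponential_decay(intensity, time, time_unit = "min",
                        min_points = min_points)

#' Network disassembly speed
#'
#' Comet length over disassembly time constant; in both disassembly and
#' recycling conditions this is ~1.2 um/min, matching the assembly speed.
#'
#' @param comet_length_um comet length, um.
#' @param tau_min disassembly time constant, minutes.
#' @return disassembly speed, um/min.
#' @export
disassembly_speed <- function(comet_length_um, tau_min) {
  if (tau_min <= 0) stop("tau must be positive")
  if (comet_length_um < 0) stop("comet length must be nonnegative")
  comet_length_um / tau_min
}

#' Barbed-end association rate constant from filament growth
#'
#' Least-squares slope of filament length vs time, divided by
#' `subunit_rise * G`: the per-monomer elongation converted into an
#' association rate constant in subunits/(uM s). At 0.8 uM actin a slope of
#' 0.0216 um/s gives 10 /(uM s).
#'
#' @param filament_length_um filament lengths, um (>= 3 points).
#' @param time_s times, seconds.
#' @param G actin monomer concentration, uM.
#' @param subunit_rise length per subunit, um. Default 0.0027.
#' @return list with `k_plus` (per uM s), `slope_um_per_s` and logical
#'   `depolymerizing` (negative slope flag).
#' @export
estimate_kplus <- function(filament_length_um, time_s, G,
                           subunit_rise = 0.0027) {
  if (length(filament_length_um) < 3) stop("need at least 3 points")
  if (G <= 0) stop("G must be positive")
  slope <- unname(stats::coef(stats::lm(filament_length_um ~ time_s))[2])
  if (slope < 0)
    warning("negative elongation slope: filament is depolymerizing")
  list(k_plus = slope / (subunit_rise * G), slope_um_per_s = slope,
       depolymerizing = slope < 0)
}
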