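# ODE machinery for the turnover model.
#
# The model is linear and time-invariant, x' = A x, so the default propagator
# is exact: x(t + dt) = expm(A dt) x(t), evaluated with Matrix::expm and
# cached per unique step size. This is unconditionally stable (hence
# stiff-proof) and costs one 5x5 matrix exponential per distinct dt.
# An adaptive Dormand-Prince RK45 integrator is kept as the independent
# numerical route; equivalence of the two is a standing test.

# Generator matrix of the turnover system in state order
# (l, l_tilde, G_D, G_T, aged). Columns sum to zero: exact conservation.
.turnover_matrix <- function(params) {
  kt <- params$k_tilde; g <- params$gamma; kdt <- params$k_DT
  psi <- params$psi; s <- params$sigma
  A <- matrix(0, 5, 5,
              dimnames = list(c("l", "l_tilde", "G_D", "G_T", "aged"),
                              c("l", "l_tilde", "G_D", "G_T", "aged")))
  A["l", "l"] <- -(g + psi);        A["l", "G_T"] <- kt
  A["l_tilde", "l_tilde"] <- -psi;  A["l_tilde", "G_T"] <- s * kt
  A["G_D", "l"] <- g;               A["G_D", "G_D"] <- -(kdt + psi)
  A["G_T", "G_D"] <- kdt;           A["G_T", "G_T"] <- -((1 + s) * kt + psi)
  A["aged", c("l", "l_tilde", "G_D", "G_T")] <- psi
  A
}

# Exact propagation of x' = A x over the (possibly non-uniform) grid `times`.
.propagate_expm <- function(A, x0, times) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(x0))
  out[1, ] <- x0
  dts <- diff(times)
  cache <- new.env(parent = emptyenv())
  x <- x0
  for (i in seq_along(dts)) {
    key <- sprintf("%.15g", dts[i])
    P <- cache[[key]]
    if (is.null(P)) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(A * dts[i])))
      cache[[key]] <- P
    }
    x <- drop(P %*% x)
    out[i + 1L, ] <- x
  }
  colnames(out) <- names(x0)
  out
}

#' Adaptive Dormand-Prince RK45 integrator
#'
#' General-purpose embedded Runge-Kutta 5(4) solver with PI step-size
#' control, used as the numerical cross-check route for the exact
#' matrix-exponential propagator of the (linear) turnover model.
#'
#' @param f right-hand side, `function(t, y)` returning `dy/dt`.
#' @param y0 initial state (numeric vector).
#' @param times output time points, strictly increasing.
#' @param rtol,atol relative and absolute local-error tolerances.
#' @param max_steps safety cap on accepted + rejected steps.
#' @return matrix of states, one row per output time.
#' @keywords internal
ode_rk45 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                     max_steps = 1e6) {
  # Dormand-Prince coefficients
  c_ <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  stopifnot(all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  t <- times[1]; y <- y0
  k1 <- f(t, y)
  h <- min(diff(times)[1], 1)
  err_prev <- 1
  nsteps <- 0L
  for (iout in 2:length(times)) {
    t_target <- times[iout]
    while (t < t_target) {
      if ((nsteps <- nsteps + 1L) > max_steps)
        stop("ode_rk45: step budget exhausted (system too stiff for the explicit route; use method = \"analytic\")")
      h <- min(h, t_target - t)
      ks <- matrix(NA_real_, 7, n)
      ks[1, ] <- k1
      for (s in 2:7) {
        ys <- y + h * drop(a[[s - 1]] %*% ks[seq_len(s - 1), , drop = FALSE])
        ks[s, ] <- f(t + c_[s] * h, ys)
      }
      y5 <- y + h * drop(b5 %*% ks)
      y4 <- y + h * drop(b4 %*% ks)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1 || h <= 1e-12 * max(1, abs(t))) {
        t <- t + h
        y <- y5
        k1 <- ks[7, ] # FSAL
        fac <- 0.9 * err^(-0.7 / 5) * err_prev^(0.4 / 5)
        err_prev <- max(err, 1e-10)
        h <- h * min(5, max(0.2, fac))
      } else {
        h <- h * max(0.2, 0.9 * err^-0.2)
      }
    }
    out[iout, ] <- y
  }
  colnames(out) <- names(y0)
  out
}
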