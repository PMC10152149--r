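#' Actin pool state in length-equivalent units
#'
#' The five bookkeeping pools of the turnover model, all in um of
#' tail-equivalent length: tail F-actin `l`, non-tail F-actin `l_tilde`
#' (assembly mode only), ADP-G-actin `G_D`, ATP-G-actin `G_T`, and the
#' cumulative aged (polymerization-incompetent) pool. Their sum is the
#' conserved total `l_max`.
#'
#' @param l tail F-actin, um.
#' @param l_tilde non-tail F-actin, um.
#' @param G_D ADP-G-actin, um length-equivalent.
#' @param G_T ATP-G-actin, um length-equivalent.
#' @param aged cumulative aged actin, um length-equivalent.
#' @param l_max if given, conservation `l + l_tilde + G_D + G_T + aged ==
#'   l_max` is enforced within `tol * l_max`.
#' @param tol relative conservation tolerance. Default 1e-9.
#' @return an object of class `pool_state` (named numeric vector).
#' @export
pool_state <- function(l = 0, l_tilde = 0, G_D = 0, G_T = 0, aged = 0,
                       l_max = NULL, tol = 1e-9) {
  s <- c(l = unname(l), l_tilde = unname(l_tilde), G_D = unname(G_D),
         G_T = unname(G_T), aged = unname(aged))
  if (any(!is.finite(s))) stop("pool state must be finite")
  if (any(s < 0)) stop("all pools must be nonnegative")
  if (!is.null(l_max) && abs(sum(s) - l_max) > tol * l_max)
    stop(sprintf("conservation violated: pools sum to %.9g, l_max = %.9g",
                 sum(s), l_max))
  structure(s, class = "pool_state")
}

#' All-monomer initial state
#'
#' The canonical initial condition: the entire pool as ATP-G-actin.
#' @param l_max pool size, um.
#' @return a [pool_state()].
#' @export
initial_pool <- function(l_max) pool_state(G_T = l_max, l_max = l_max)

#' Length-equivalent <-> concentration conversion
#'
#' `l = l_max * G / G_bar` maps a molar concentration onto the length of
#' tail it could build, and back.
#'
#' @param G concentration, uM.
#' @param l length-equivalent, um.
#' @param params a [turnover_params()] (supplies `l_max` and `G_bar`).
#' @return converted value.
#' @export
conc_to_length <- function(G, params) params$l_max * G / params$G_bar

#' @rdname conc_to_length
#' @export
length_to_conc <- function(l, params) params$G_bar * l / params$l_max
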