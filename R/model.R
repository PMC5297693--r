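# Right-hand side and Jacobian of the four-variable decision network.
#
# Sensors (PERK, IRE-1) follow saturating mass action: the inactive pool
# (total - active) is activated by stress plus the partner sensor, and
# inactivated at a constant rate.  Inducers (autophagy, apoptosis) follow
# Goldbeter-Koshland activation/inactivation fluxes in which the opposing
# inducer raises the inactivation rate; with Michaelis constants well below
# the totals this is the zero-order ultrasensitive regime that lets the
# double-negative loop act as a toggle switch.

.as_state <- function(state) {
  if (is.null(names(state))) {
    if (length(state) != 4L) stop("state must have four components", call. = FALSE)
    names(state) <- .upr_state_names
  }
  state[.upr_state_names]
}

#' Instantaneous rates of change of the four network variables
#'
#' @param state numeric vector `(perk, ire1, auto, apop)`; named or in that
#'   order.
#' @param params a [upr_params] object (or full named numeric vector).
#' @return named numeric vector of derivatives, in a.u. per time unit.
#' @export
#' @examples
#' upr_rhs(c(perk = 0, ire1 = 0, auto = 0, apop = 0), default_params())
upr_rhs <- function(state, params) {
  s <- .as_state(state)
  p <- unclass(params)
  if (!all(is.finite(s))) stop("non-finite state", call. = FALSE)
  if (anyNA(p)) stop("non-finite parameters", call. = FALSE)
  d <- .rhs_fast(as.numeric(s), as.numeric(p[.upr_param_names]))
  names(d) <- .upr_state_names
  d
}

#' Analytic Jacobian of the right-hand side
#'
#' Used for Newton root finding and for linear stability (eigenvalue)
#' analysis of steady states.
#'
#' @inheritParams upr_rhs
#' @return 4 x 4 numeric matrix, rows/columns ordered
#'   `(perk, ire1, auto, apop)`.
#' @export
upr_jacobian <- function(state, params) {
  s <- .as_state(state)
  p <- unclass(params)
  J <- .jac_fast(as.numeric(s), as.numeric(p[.upr_param_names]))
  dimnames(J) <- list(.upr_state_names, .upr_state_names)
  J
}

# ---- fast positional internals -------------------------------------------
#
# The named-access versions above are the documented surface; the hot loops
# (Newton iteration, lsoda callbacks) use these positional equivalents on the
# raw parameter vector, in .upr_param_names order:
#  1 stress  2 PERKT  3 IRE1T  4 AT_auto  5 AT_apop
#  6 k_sp  7 k_si  8 k_ip  9 k_pi 10 k_dp 11 k_di
# 12 k_pa 13 k_ia 14 k_pap 15 k_iap 16 k_da 17 k_dap 18 k_x_aa 19 k_x_apa
# 20 J_a_on 21 J_a_off 22 J_ap_on 23 J_ap_off

.rhs_fast <- function(x, p) {
  P <- x[1L]; I <- x[2L]; A <- x[3L]; D <- x[4L]
  freeA <- p[4L] - A; freeD <- p[5L] - D
  uA <- if (is.finite(p[20L])) freeA / (p[20L] + freeA) else freeA
  vA <- if (is.finite(p[21L])) A / (p[21L] + A) else A
  uD <- if (is.finite(p[22L])) freeD / (p[22L] + freeD) else freeD
  vD <- if (is.finite(p[23L])) D / (p[23L] + D) else D
  c((p[6L] * p[1L] + p[8L] * I) * (p[2L] - P) - p[10L] * P,
    (p[7L] * p[1L] + p[9L] * P) * (p[3L] - I) - p[11L] * I,
    (p[12L] * P + p[13L] * I) * uA - (p[16L] + p[18L] * D) * vA,
    (p[14L] * P + p[15L] * I) * uD - (p[17L] + p[19L] * A) * vD)
}

.jac_fast <- function(x, p) {
  P <- x[1L]; I <- x[2L]; A <- x[3L]; D <- x[4L]
  freeA <- p[4L] - A; freeD <- p[5L] - D
  if (is.finite(p[20L])) { uA <- freeA / (p[20L] + freeA); duA <- -p[20L] / (p[20L] + freeA)^2 }
  else { uA <- freeA; duA <- -1 }
  if (is.finite(p[21L])) { vA <- A / (p[21L] + A); dvA <- p[21L] / (p[21L] + A)^2 }
  else { vA <- A; dvA <- 1 }
  if (is.finite(p[22L])) { uD <- freeD / (p[22L] + freeD); duD <- -p[22L] / (p[22L] + freeD)^2 }
  else { uD <- freeD; duD <- -1 }
  if (is.finite(p[23L])) { vD <- D / (p[23L] + D); dvD <- p[23L] / (p[23L] + D)^2 }
  else { vD <- D; dvD <- 1 }
  aA <- p[12L] * P + p[13L] * I
  aD <- p[14L] * P + p[15L] * I
  matrix(c(
    -(p[6L] * p[1L] + p[8L] * I) - p[10L], p[9L] * (p[3L] - I), p[12L] * uA, p[14L] * uD,
    p[8L] * (p[2L] - P), -(p[7L] * p[1L] + p[9L] * P) - p[11L], p[13L] * uA, p[15L] * uD,
    0, 0, aA * duA - (p[16L] + p[18L] * D) * dvA, -p[19L] * vD,
    0, 0, -p[18L] * vA, aD * duD - (p[17L] + p[19L] * A) * dvD
  ), nrow = 4L, ncol = 4L)
}

# deSolve-style callbacks (time-autonomous; stress enters via parms)
.upr_deriv <- function(t, state, parms) {
  list(.rhs_fast(state, parms))
}

.upr_jac <- function(t, state, parms) {
  .jac_fast(state, parms)
}

#' Totals box of a parameter set
#'
#' Upper bounds of the forward-invariant box `[0, total]` for each variable.
#' @param params a [upr_params] object.
#' @return named numeric vector of totals in state order.
#' @export
state_totals <- function(params) {
  p <- unclass(params)
  c(perk = p[["PERKT"]], ire1 = p[["IRE1T"]],
    auto = p[["AT_auto"]], apop = p[["AT_apop"]])
}
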