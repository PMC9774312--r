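#' Sternal spring-damper parameters
#'
#' The thorax is reduced to a linear elastic-damping system
#' \eqn{F(t) = k_1 X + m \dot X}: `k1` is the sternal spring elasticity
#' coefficient and `m` the damping factor (damper constant, N s/m, despite
#' the mass-like symbol). Defaults are the measured adult-thorax constants
#' k1 = 7028.9 N/m and m = 438.1 N s/m.
#'
#' @param k1 spring elasticity coefficient, N/m (> 0).
#' @param m damping factor, N s/m (>= 0).
#' @return An object of class `chest_params`.
#' @export
chest_params <- function(k1 = 7028.9, m = 438.1) {
  stopifnot(k1 > 0, m >= 0)
  structure(list(k1 = k1, m = m), class = "chest_params")
}

#' Sternal reaction force
#'
#' Chest reaction to a compression displacement `X` and velocity `Xdot`:
#' `k1 * X + m * Xdot`. This is the effective resistance F2 fed back to the
#' piston force balance; during decompression the same expression (with
#' its natural sign) returns the stored elastic energy to the piston.
#' A negative displacement (over-extension above the resting chest) gives
#' no spring contribution.
#'
#' @param X chest compression displacement, m (resting chest at 0).
#' @param Xdot compression velocity, m/s.
#' @param p a [chest_params()] object.
#' @return Reaction force, N.
#' @examples
#' reaction_force(0.05, 0)     # static stiffness: 351.445 N
#' reaction_force(0.05, 0.5)   # with damping: 570.495 N
#' @export
reaction_force <- function(X, Xdot, p = chest_params()) {
  p$k1 * pmax(X, 0) + p$m * Xdot
}
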