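#' Pneumatic cylinder and supply parameters
#'
#' Geometry, load and supply conditions of the double-acting cylinder that
#' drives the compression piston. The rodless (working) chamber has action
#' area `A1`, the rod-side (exhaust) chamber `A2`; `X10` and `X20` are the
#' equivalent lengths of the chambers' dead volumes, so the chamber volumes
#' at piston extension `X` are `V1 = A1 (X10 + X)` and
#' `V2 = A2 (L + X20 - X)`.
#'
#' `A_exh1` and `A_exh2` are the effective open areas of the two 5-port
#' valve exhaust paths (rodless-chamber and rod-chamber side respectively)
#' through which the deflating chamber blows down; the inflating chamber
#' is always fed from the supply through the regulator throttle.
#'
#' Defaults describe a 50 mm stroke, 40 mm bore cylinder fed at
#' 0.45 MPa absolute; together with the shipped PID gains they reproduce
#' the reference trapezoid-like compression trajectory of the prototype.
#'
#' @param A1,A2 piston action areas on the rodless / rod side, m^2
#'   (`A1 > A2 > 0`).
#' @param L piston stroke, m.
#' @param X10,X20 equivalent initial-volume lengths, m.
#' @param M_W moving mass (piston + driving parts), kg.
#' @param F1 Coulomb friction force magnitude, N.
#' @param F3 gravity component of the moving parts along the motion, N
#'   (assists extension).
#' @param Ps,Ts supply absolute pressure (Pa) and temperature (K).
#' @param Pa,Ta ambient absolute pressure (Pa) and temperature (K).
#' @param A_exh1,A_exh2 effective exhaust-path areas of the directional
#'   valve on the rodless / rod chamber side, m^2.
#' @return An object of class `cylinder_params`.
#' @export
cylinder_params <- function(A1 = 1.2566e-3, A2 = 7.0e-4, L = 0.05,
                            X10 = 0.005, X20 = 0.005, M_W = 1.5,
                            F1 = 40, F3 = 14.7,
                            Ps = 4.5e5, Ts = 293.15,
                            Pa = 1.01325e5, Ta = 293.15,
                            A_exh1 = 3.0e-6, A_exh2 = 4.0e-6) {
  stopifnot(A1 > A2, A2 > 0, L > 0, X10 > 0, X20 > 0, M_W > 0,
            F1 >= 0, Ps >= Pa, Pa > 0, Ts > 0, Ta > 0,
            A_exh1 > 0, A_exh2 > 0)
  structure(list(A1 = A1, A2 = A2, L = L, X10 = X10, X20 = X20,
                 M_W = M_W, F1 = F1, F3 = F3, Ps = Ps, Ts = Ts,
                 Pa = Pa, Ta = Ta, A_exh1 = A_exh1, A_exh2 = A_exh2),
            class = "cylinder_params")
}

#' Chamber pressure rates under adiabatic charge/discharge
#'
#' Rates of change of the two chamber pressures for a piston state and a
#' pair of net charging mass flows. Chamber 1 (rodless) charging from the
#' supply obeys
#' \eqn{\dot P_1 = k R T_s Q_1 / V_1 - k P_1 A_1 \dot X / V_1} with
#' \eqn{V_1 = A_1 (X_{10} + X)}; chamber 2 (rod side) discharging obeys
#' \eqn{\dot P_2 = k P_2 A_2 \dot X / V_2 - k R T_2 Q_2 / V_2} with
#' \eqn{V_2 = A_2(L + X_{20} - X)} and the isentropic chamber temperature
#' \eqn{T_2 = T_s (P_2/P_s)^{(k-1)/k}}.
#'
#' @param state list with piston displacement `X` (m), velocity `Xdot`
#'   (m/s) and chamber pressures `P1`, `P2` (Pa).
#' @param Q1 net mass flow into chamber 1 (charging positive), kg/s.
#' @param Q2 net mass flow out of chamber 2 (discharging positive), kg/s.
#' @param p a [cylinder_params()] object.
#' @param gas a [gas_constants()] object.
#' @return Numeric vector `c(dP1, dP2)`, Pa/s.
#' @export
chamber_pressure_rates <- function(state, Q1, Q2, p = cylinder_params(),
                                   gas = gas_constants()) {
  if (state$X < 0 || state$X > p$L)
    stop("piston displacement outside the stroke", call. = FALSE)
  k <- gas$k
  V1 <- p$A1 * (p$X10 + state$X)
  V2 <- p$A2 * (p$L + p$X20 - state$X)
  T2 <- p$Ts * (state$P2 / p$Ps)^((k - 1) / k)
  dP1 <- k * gas$R * p$Ts * Q1 / V1 - k * state$P1 * p$A1 * state$Xdot / V1
  dP2 <- k * state$P2 * p$A2 * state$Xdot / V2 - k * gas$R * T2 * Q2 / V2
  c(dP1 = unname(dP1), dP2 = unname(dP2))
}

#' Net force on the piston
#'
#' Force balance \eqn{M_W \ddot X = a_0 P_1 A_1 - P_2 A_2 - F}, where the
#' load term is \eqn{F = \pm F_1 + F_2 - F_3 + P_a (A_1 - A_2)}: Coulomb
#' friction `F1` opposes the motion (sign follows `direction`), the
#' external (sternal) reaction enters as `F_ext` = F2, gravity `F3` assists
#' extension, and the last term is the ambient-pressure imbalance across
#' the rod. The working-area coefficient is a0 = 0.8 at X = 0 (breakaway)
#' and 1 once the piston has left the retracted stop.
#'
#' @param state list with `X`, `P1`, `P2` (see [chamber_pressure_rates()]).
#' @param F_ext external reaction force on the piston (the chest), N.
#' @param p a [cylinder_params()] object.
#' @param direction sign of the piston velocity (+1 extending, -1
#'   retracting, 0 at rest: static friction is then capped at `F1`).
#' @return Net force, N (positive accelerates extension).
#' @export
piston_net_force <- function(state, F_ext, p = cylinder_params(),
                             direction = 0) {
  a0 <- if (state$X <= 0) 0.8 else 1
  thrust <- a0 * state$P1 * p$A1 - state$P2 * p$A2 -
    (F_ext - p$F3 + p$Pa * (p$A1 - p$A2))
  if (direction > 0) thrust - p$F1
  else if (direction < 0) thrust + p$F1
  else sign(thrust) * max(abs(thrust) - p$F1, 0)
}
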