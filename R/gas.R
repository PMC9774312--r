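#' Gas constants for compressible orifice flow
#'
#' Bundles the specific gas constant, adiabatic index and throttle flow
#' coefficient used by the pneumatic model, together with the two derived
#' orifice constants of the ISO-style compressible flow law,
#' \eqn{\eta_1 = \sqrt{2k/(k-1)}} and
#' \eqn{\eta_2 = \sqrt{k}\,(2/(k+1))^{(k+1)/(2(k-1))}}.
#'
#' The critical (choking) pressure ratio is derived from the adiabatic
#' index as \eqn{r_c = (2/(k+1))^{k/(k-1)}}, which is 0.528 for air
#' (k = 1.4); the flow function is exactly continuous (= 1) there.
#'
#' @param R specific gas constant, J/(kg K). Default 287.05 (dry air).
#' @param k adiabatic index (ratio of specific heats), dimensionless,
#'   must exceed 1. Default 1.4.
#' @param c0 throttle flow (discharge) coefficient in (0, 1]. Default 0.9.
#' @return An object of class `gas_constants`: a list with fields `R`,
#'   `k`, `c0`, the derived `eta1`, `eta2` and the critical pressure
#'   ratio `r_crit`.
#' @examples
#' g <- gas_constants()
#' g$r_crit    # 0.528 for air
#' @export
gas_constants <- function(R = 287.05, k = 1.4, c0 = 0.9) {
  stopifnot(R > 0, k > 1, c0 > 0, c0 <= 1)
  structure(list(
    R = R, k = k, c0 = c0,
    eta1 = sqrt(2 * k / (k - 1)),
    eta2 = sqrt(k) * (2 / (k + 1))^((k + 1) / (2 * (k - 1))),
    r_crit = (2 / (k + 1))^(k / (k - 1))
  ), class = "gas_constants")
}

#' Dimensionless orifice flow function
#'
#' The flow function \eqn{f_1(p_d/p_u)} of the compressible orifice law.
#' Below the critical pressure ratio the flow is sonic (choked) and
#' \eqn{f_1 = 1}, independent of downstream pressure; above it the flow is
#' subsonic, \eqn{f_1 = (\eta_1/\eta_2)\sqrt{r^{2/k} - r^{(k+1)/k}}},
#' decreasing to 0 as the pressures equalise. Continuous at the critical
#' ratio.
#'
#' @param ratio downstream-to-upstream pressure ratio(s) in \[0, 1\].
#' @param gas a [gas_constants()] object.
#' @return Dimensionless flow function value(s) in \[0, 1\].
#' @examples
#' g <- gas_constants()
#' flow_function_f1(0.3, g)   # choked: 1
#' flow_function_f1(1.0, g)   # equal pressures: 0
#' @export
flow_function_f1 <- function(ratio, gas = gas_constants()) {
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 1))
    stop("pressure ratio must lie in [0, 1]", call. = FALSE)
  sub <- ratio > gas$r_crit
  out <- rep(1, length(ratio))
  r <- ratio[sub]
  out[sub] <- gas$eta1 / gas$eta2 *
    sqrt(pmax(r^(2 / gas$k) - r^((gas$k + 1) / gas$k), 0))
  out
}

#' Mass flow through the regulator throttle
#'
#' Compressible mass flow through the electro-pneumatic regulator orifice,
#' \eqn{Q_m = c_0 \eta_2 x_v w \, p_u/\sqrt{RT} \; f_1(p_d/p_u)},
#' where the effective open area is the spool displacement times the area
#' gain, \eqn{A_0 = x_v w}.
#'
#' @param x_v spool displacement, m (>= 0).
#' @param p_u,p_d upstream and downstream absolute pressures, Pa (> 0).
#' @param T_up upstream gas temperature, K.
#' @param gas a [gas_constants()] object.
#' @param reg a [regulator_params()] object (supplies the area gain `w`).
#' @return Mass flow, kg/s (>= 0; downstream pressure above upstream gives 0).
#' @export
orifice_mass_flow <- function(x_v, p_u, p_d, T_up, gas = gas_constants(),
                              reg = regulator_params()) {
  if (p_u <= 0 || p_d < 0) stop("pressures must be positive", call. = FALSE)
  if (x_v < 0) stop("spool displacement must be non-negative", call. = FALSE)
  if (p_d >= p_u) return(0)
  ratio <- p_d / p_u
  gas$c0 * gas$eta2 * (x_v * reg$w) * p_u / sqrt(gas$R * T_up) *
    flow_function_f1(ratio, gas)
}
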