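#' Electro-pneumatic regulator parameters
#'
#' First-order spool model: \eqn{\dot x_v = -x_v/\tau_v + (k_v/\tau_v) u},
#' so a constant command voltage `u` drives the spool to the steady state
#' \eqn{x_v = k_v u} with time constant `tau_v`. The effective throttle
#' area is `x_v * w`.
#'
#' @param tau_v spool response time, s.
#' @param k_v spool displacement gain, m/V.
#' @param w area gain (open area per spool travel), m^2/m.
#' @return An object of class `regulator_params`.
#' @export
regulator_params <- function(tau_v = 0.005, k_v = 1e-3, w = 6e-4) {
  stopifnot(tau_v > 0, k_v > 0, w > 0)
  structure(list(tau_v = tau_v, k_v = k_v, w = w),
            class = "regulator_params")
}

#' Advance the spool first-order lag one step
#'
#' Exact discrete update of the linear spool ODE over `dt` (matrix
#' exponential of a scalar system): used both on its own and as the
#' reference for the compiled integrator.
#'
#' @param x_v current spool displacement, m.
#' @param u command voltage, V.
#' @param dt time step, s (> 0).
#' @param reg a [regulator_params()] object.
#' @return Spool displacement after `dt`, m.
#' @export
spool_step <- function(x_v, u, dt, reg = regulator_params()) {
  stopifnot(dt > 0)
  xs <- reg$k_v * u
  xs + (x_v - xs) * exp(-dt / reg$tau_v)
}

#' PID controller gains
#'
#' @param kp proportional gain, V/m.
#' @param ki integral gain, V/(m s).
#' @param kd derivative gain, V s/m.
#' @param u_max saturation voltage, V (output clamped to \[0, u_max\]).
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 1000, ki = 100, kd = 18, u_max = 5) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, u_max > 0)
  structure(list(kp = kp, ki = ki, kd = kd, u_max = u_max),
            class = "pid_gains")
}

#' One PID update with output saturation and anti-windup
#'
#' Positional PID on the depth error with the output clamped to
#' \[0, `u_max`\]; the integral state is frozen while the output is
#' saturated in the direction of the error (conditional integration).
#'
#' @param setpoint commanded displacement, m.
#' @param measured measured displacement, m.
#' @param state controller state: list with `integral` (m s) and
#'   `prev_error` (m); pass `pid_state()` at start-up.
#' @param gains a [pid_gains()] object.
#' @param dt control interval, s (> 0).
#' @return List with the saturated voltage `u` (V) and the updated `state`.
#' @export
pid_voltage <- function(setpoint, measured, state = pid_state(),
                        gains = pid_gains(), dt) {
  stopifnot(dt > 0)
  e <- setpoint - measured
  deriv <- (e - state$prev_error) / dt
  int_trial <- state$integral + e * dt
  u_raw <- gains$kp * e + gains$ki * int_trial + gains$kd * deriv
  u <- min(max(u_raw, 0), gains$u_max)
  # anti-windup: keep the integral only if it does not push further into
  # saturation
  if ((u_raw > gains$u_max && e > 0) || (u_raw < 0 && e < 0))
    int_trial <- state$integral
  list(u = u, state = list(integral = int_trial, prev_error = e))
}

#' Fresh PID controller state
#' @return List with zero integral and previous error.
#' @export
pid_state <- function() list(integral = 0, prev_error = 0)
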