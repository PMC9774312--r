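#' Thoracic and pulmonary pressure-source parameters
#'
#' The two power sources that couple chest motion into the circulation.
#' The mediastinal source obeys \eqn{\dot P_M = E(\dot X + \dot x_2)/d_0},
#' where `E` is the effective Young's modulus of the chest, `d0` the
#' anterior-posterior cardiac tissue thickness and \eqn{\dot x_2} the
#' vessel-expansion speed; the alveolar source obeys
#' \eqn{\dot P_{lung} = (\dot X A_L - (P_{lung}-P_{mouth})/R_{airway})/C_{lung}}.
#'
#' With `x2_mode = "volume"` the vessel-expansion speed is the rate of
#' intrathoracic vascular volume change divided by the effective area
#' `A_eff`; `x2_mode = "zero"` switches the coupling off.
#'
#' @param E effective chest Young's modulus, mmHg.
#' @param d0 anterior-posterior cardiac tissue thickness, m.
#' @param A_L cross-sectional area of the compressed lung, m^2.
#' @param R_airway airway gas-flow impedance, mmHg s/L.
#' @param C_lung lung compliance, L/mmHg.
#' @param P_mouth mouth pressure, mmHg.
#' @param x2_mode `"volume"` (default) or `"zero"`.
#' @param A_eff effective area converting intrathoracic volume rate to
#'   vessel-expansion speed, m^2.
#' @return An object of class `pump_source_params`.
#' @export
pump_source_params <- function(E = 78, d0 = 0.125, A_L = 0.008,
                               R_airway = 20, C_lung = 0.01, P_mouth = 0,
                               x2_mode = c("volume", "zero"),
                               A_eff = 0.01) {
  x2_mode <- match.arg(x2_mode)
  stopifnot(E > 0, d0 > 0, A_L > 0, R_airway > 0, C_lung > 0, A_eff > 0)
  structure(list(E = E, d0 = d0, A_L = A_L, R_airway = R_airway,
                 C_lung = C_lung, P_mouth = P_mouth, x2_mode = x2_mode,
                 A_eff = A_eff),
            class = "pump_source_params")
}

#' Ohmic flow along a vascular edge
#'
#' Flow positive from the upstream to the downstream compartment,
#' `(P_from - P_to)/R`; an edge flagged as a valve is an ideal diode and
#' carries no reverse flow.
#'
#' @param P_from,P_to compartment pressures, mmHg.
#' @param R edge resistance, mmHg min/L.
#' @param valve logical; ideal diode (forward = from -> to).
#' @return Flow, L/min.
#' @examples
#' edge_flow(40, 10, 15)          # 2 L/min
#' edge_flow(10, 40, 15, TRUE)    # diode blocks: 0
#' @export
edge_flow <- function(P_from, P_to, R, valve = FALSE) {
  q <- (P_from - P_to) / R
  if (valve) q <- pmax(q, 0)
  q
}

#' Compartment pressure rate from net inflow
#'
#' `dP/dt = (Q_in - Q_out)/C` with flows in L/min and compliance in
#' mL/mmHg; the 1000/60 factor converts L/min to mL/s so the result is in
#' mmHg/s.
#'
#' @param Q_in,Q_out total in/outflow, L/min.
#' @param C compliance, mL/mmHg (> 0).
#' @return Pressure rate, mmHg/s.
#' @export
pressure_rate <- function(Q_in, Q_out, C) {
  stopifnot(C > 0)
  (Q_in - Q_out) * 1000 / 60 / C
}

#' Mediastinal pressure-source rate
#'
#' @param Xdot chest compression velocity, m/s.
#' @param x2dot vessel-expansion speed, m/s.
#' @param p a [pump_source_params()] object.
#' @return dP_M/dt, mmHg/s.
#' @export
thoracic_pump_rate <- function(Xdot, x2dot = 0, p = pump_source_params()) {
  p$E * (Xdot + x2dot) / p$d0
}

#' Alveolar pressure-source rate
#'
#' @param Xdot chest compression velocity, m/s.
#' @param P_lung current lung pressure, mmHg.
#' @param p a [pump_source_params()] object.
#' @return dP_lung/dt, mmHg/s.
#' @export
lung_pressure_rate <- function(Xdot, P_lung, p = pump_source_params()) {
  (Xdot * p$A_L * 1000 - (P_lung - p$P_mouth) / p$R_airway) / p$C_lung
}

#' Declare a lumped-parameter circulation network
#'
#' @param compartments data.frame with columns `name`, `C` (compliance,
#'   mL/mmHg), `P0` (initial pressure, mmHg), `intrathoracic` (logical:
#'   receives the mediastinal source P_M), `pulmonary` (logical: receives
#'   the alveolar source P_lung).
#' @param edges data.frame with columns `from`, `to` (compartment names),
#'   `R` (resistance, mmHg min/L) and `valve` (logical).
#' @param sources a [pump_source_params()] object.
#' @param roles named list designating the metric extraction points:
#'   `cardiac_output_edge` and `cerebral_edge` (each `c(from, to)`),
#'   `aorta` and `right_atrium` (compartment names).
#' @return An object of class `circulation_network`.
#' @export
circulation_network <- function(compartments, edges,
                                sources = pump_source_params(),
                                roles = list()) {
  stopifnot(all(c("name", "C", "P0", "intrathoracic", "pulmonary") %in%
                  names(compartments)),
            all(c("from", "to", "R", "valve") %in% names(edges)),
            all(compartments$C > 0), all(edges$R > 0))
  if (anyDuplicated(compartments$name))
    stop("duplicate compartment names", call. = FALSE)
  unknown <- setdiff(c(edges$from, edges$to), compartments$name)
  if (length(unknown))
    stop("edges reference unknown compartments: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # closed loop: every compartment must both receive and shed flow
  no_in <- setdiff(compartments$name, edges$to)
  no_out <- setdiff(compartments$name, edges$from)
  if (length(no_in) || length(no_out))
    stop("network is not a closed loop (dead-end compartments: ",
         paste(unique(c(no_in, no_out)), collapse = ", "), ")",
         call. = FALSE)
  structure(list(compartments = compartments, edges = edges,
                 sources = sources, roles = roles),
            class = "circulation_network")
}

#' @export
print.circulation_network <- function(x, ...) {
  cat(sprintf("<circulation_network> %d compartments, %d edges (%d valves)\n",
              nrow(x$compartments), nrow(x$edges), sum(x$edges$valve)))
  invisible(x)
}

#' Shipped 14-compartment human circulation
#'
#' Reads the default topology file (`circulation_default.yaml` under the
#' package's `extdata`): a closed 14-compartment loop with left and right
#' heart, pulmonary artery / lung / pulmonary-vein chain, thoracic and
#' abdominal aorta, carotid-cerebral-jugular branch, splanchnic and leg
#' circuits and both venae cavae, with ideal-diode valves at the four
#' cardiac stations and in the jugular vein. Resistances, compliances,
#' arrest baselines and source constants are data, not code; pass a
#' different `path` to load a custom topology.
#'
#' @param path topology YAML file; default the shipped one.
#' @return A `circulation_network`.
#' @export
default_circulation <- function(path = system.file("extdata",
                                                   "circulation_default.yaml",
                                                   package = "cprsim")) {
  read_circulation(path)
}

#' Integrate the circulation driven by a chest-velocity waveform
#'
#' Fixed-step RK4 integration of all compartment pressures and the two
#' source states over `n_cycles` compression periods, discarding
#' `warmup_cycles` before recording. Flows are Ohmic with ideal-diode
#' valves; intrathoracic compartments see the mediastinal pressure P_M
#' and the lung compartment the alveolar pressure P_lung as additive
#' external offsets (pressures are states of the vessel compliances, so
#' total blood volume is conserved exactly by construction).
#'
#' @param network a [circulation_network()].
#' @param drive a `cpr_waveform` (one or more cycles; the last full period
#'   is tiled periodically as the chest drive), or `NULL` for a
#'   zero-velocity drive of `period` seconds.
#' @param n_cycles total cycles to integrate (default 25).
#' @param warmup_cycles cycles discarded before recording (default 10).
#' @param dt integration step, s (default 2e-4).
#' @param sample_every record every n-th step (default 5).
#' @param period drive period, s; only used when `drive` is NULL.
#' @return An object of class `hemodynamic_trace`: `time` (s, from the
#'   start of the recorded span), `pressures` and `stored` (matrices,
#'   mmHg; effective and transmural), `flows` (matrix, L/min), `PM`,
#'   `Plung` (mmHg), the drive `period` (s) and the `decomp_window`
#'   (fractions of the period bounding the decompression phase).
#' @export
run_circulation <- function(network, drive, n_cycles = 25,
                            warmup_cycles = 10, dt = 2e-4,
                            sample_every = 5L, period = NULL) {
  stopifnot(inherits(network, "circulation_network"),
            n_cycles > warmup_cycles, dt > 0)
  comp <- network$compartments
  edges <- network$edges
  src <- network$sources

  if (is.null(drive)) {
    if (is.null(period)) period <- 0.6
    dt_w <- 1e-3
    vel <- rep(0, round(period / dt_w) + 1)
    decomp <- c(0.5, 1)
  } else {
    stopifnot(inherits(drive, "cpr_waveform"))
    period <- waveform_period(drive)
    # take the last full period of the drive and resample uniformly
    tmax <- max(drive$samples$t_s)
    ncyc_avail <- max(1L, floor(tmax / period + 1e-9))
    t0 <- (ncyc_avail - 1) * period
    dt_w <- 2e-4
    tg <- seq(0, period, by = dt_w)
    xg <- stats::approx(drive$samples$t_s, drive$samples$X_mm,
                        xout = pmin(t0 + tg, tmax), rule = 2)$y / 1000
    n <- length(xg)
    vel <- numeric(n)
    vel[1] <- (xg[2] - xg[1]) / dt_w
    vel[n] <- (xg[n] - xg[n - 1]) / dt_w
    vel[2:(n - 1)] <- (xg[3:n] - xg[1:(n - 2)]) / (2 * dt_w)
    decomp <- if (!is.na(drive$duty_cycle)) c(drive$duty_cycle, 1)
              else c(0.5, 1)
  }

  idx <- function(nm) match(nm, comp$name) - 1L
  raw <- sim_circulation_cpp(
    comp$C, as.integer(comp$intrathoracic), as.integer(comp$pulmonary),
    comp$P0, idx(edges$from), idx(edges$to),
    edges$R * 60 / 1000,  # mmHg min/L -> mmHg s/mL
    as.integer(edges$valve), vel, dt_w, period,
    list(E_over_d0 = src$E / src$d0, A_L = src$A_L,
         R_airway = src$R_airway, C_lung = src$C_lung,
         P_mouth = src$P_mouth,
         x2_volume = identical(src$x2_mode, "volume"),
         A_eff = src$A_eff),
    as.integer(n_cycles), as.integer(warmup_cycles), dt,
    as.integer(sample_every))

  P <- raw$P; X <- raw$x; Q <- raw$Q
  colnames(P) <- colnames(X) <- comp$name
  colnames(Q) <- paste0(edges$from, "->", edges$to)
  structure(list(time = raw$t - raw$t[1],
                 pressures = P, stored = X,
                 flows = Q * 0.06,  # mL/s -> L/min
                 PM = raw$PM, Plung = raw$Plung,
                 period = period, decomp_window = decomp,
                 network = network),
            class = "hemodynamic_trace")
}

#' @export
print.hemodynamic_trace <- function(x, ...) {
  cat(sprintf(
    "<hemodynamic_trace> %d samples over %.2f s (%d compartments)\n",
    length(x$time), max(x$time), ncol(x$pressures)))
  invisible(x)
}

#' @export
plot.hemodynamic_trace <- function(x, compartments = NULL, ...) {
  if (is.null(compartments))
    compartments <- intersect(c("aorta", "right_heart"),
                              colnames(x$pressures))
  graphics::matplot(x$time, x$pressures[, compartments, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "pressure (mmHg)", ...)
  graphics::legend("topright", legend = compartments, lty = 1,
                   col = seq_along(compartments), bty = "n")
  invisible(x)
}

#' Total stored blood volume of a trace
#'
#' Volume audit of the closed loop: `sum(C_i * stored_i)` per sample
#' (transmural pressures times compliances), mL.
#'
#' @param trace a `hemodynamic_trace`.
#' @return Numeric vector, one value per recorded sample.
#' @export
blood_volume <- function(trace) {
  as.numeric(trace$stored %*% trace$network$compartments$C)
}
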