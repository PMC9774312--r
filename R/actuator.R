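#' Simulate the pneumatic compression actuator
#'
#' Event-handled fixed-step (classical RK4) integration of the coupled
#' spool, chamber-pressure and piston ODEs under a square-wave depth
#' instruction. During the compression phase of each cycle the PID
#' controller drives the regulator to track the commanded depth and the
#' rod chamber exhausts; at the instruction edge the 5-port valve commutes
#' instantaneously (the chambers swap supply/exhaust roles) and the piston
#' retracts at full throttle against the recoiling chest. Stroke limits
#' are inelastic stops (velocity zeroed on contact) and the sternal
#' reaction force `k1 X + m Xdot` is fed back into the piston force
#' balance at every stage.
#'
#' @param depth_mm commanded compression depth, mm (must not exceed the
#'   stroke).
#' @param frequency compressions per minute.
#' @param duty_cycle active fraction of the period, in (0, 1).
#' @param n_cycles number of compression cycles to simulate.
#' @param dt integration step, s (default 5e-5; <= 1e-4 recommended).
#' @param gas,reg,cyl,chest,gains component parameter objects; defaults
#'   are the shipped 50 mm-stroke prototype configuration.
#' @param sample_every record every n-th integration step (default 4).
#' @param event_threshold_mm displacement threshold defining the per-cycle
#'   event times, mm (default 0.5): "start to compress" is the first
#'   crossing above it after the instruction rise, "fully compressed" the
#'   first arrival within it of the commanded depth, and analogously on
#'   release.
#' @return An object of class `piston_trajectory`: list with `samples`
#'   (data.frame `t_s`, `X_mm`, `Xdot_mm_s`, `P1_kPa`, `P2_kPa`, `xv_mm`,
#'   `u_V`),
#'   `events` (per-cycle event times, s, relative to each cycle start),
#'   and the instruction parameters.
#' @examples
#' \donttest{
#' traj <- simulate_compression(50, 100, 0.5, n_cycles = 2)
#' traj$events
#' }
#' @export
simulate_compression <- function(depth_mm, frequency, duty_cycle,
                                 n_cycles = 3, dt = 5e-5,
                                 gas = gas_constants(),
                                 reg = regulator_params(),
                                 cyl = cylinder_params(),
                                 chest = chest_params(),
                                 gains = pid_gains(),
                                 sample_every = 4L,
                                 event_threshold_mm = 0.5) {
  depth_m <- depth_mm / 1000
  if (depth_m > cyl$L)
    stop("commanded depth exceeds the piston stroke", call. = FALSE)
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("duty cycle must lie in (0, 1)", call. = FALSE)
  stopifnot(dt > 0, n_cycles >= 1)
  period <- 60 / frequency

  raw <- sim_actuator_cpp(unclass(gas), unclass(reg), unclass(cyl),
                          unclass(chest), unclass(gains),
                          depth_m, period, duty_cycle,
                          as.integer(n_cycles), dt,
                          as.integer(sample_every))
  samples <- data.frame(t_s = raw$t,
                        X_mm = raw$X * 1000,
                        Xdot_mm_s = raw$Xdot * 1000,
                        P1_kPa = raw$P1 / 1000,
                        P2_kPa = raw$P2 / 1000,
                        xv_mm = raw$xv * 1000,
                        u_V = raw$u)
  events <- trajectory_events(samples, depth_mm, period, duty_cycle,
                              n_cycles, event_threshold_mm)
  structure(list(samples = samples, events = events,
                 depth = depth_mm, frequency = frequency,
                 duty_cycle = duty_cycle, dt = dt),
            class = "piston_trajectory")
}

# first time the linear interpolant of (t, x) crosses `level` in the
# stated direction, searching t >= t0; NA if never
first_crossing <- function(t, x, level, t0, rising = TRUE) {
  sel <- t >= t0
  t <- t[sel]; x <- x[sel]
  hit <- if (rising) x >= level else x <= level
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  frac <- (level - x[i - 1]) / (x[i] - x[i - 1])
  t[i - 1] + frac * (t[i] - t[i - 1])
}

trajectory_events <- function(samples, depth_mm, period, duty_cycle,
                              n_cycles, eps) {
  t <- samples$t_s; x <- samples$X_mm
  ev <- lapply(seq_len(n_cycles) - 1L, function(cyc) {
    t_rise <- cyc * period
    t_fall <- t_rise + duty_cycle * period
    in_cyc <- t >= t_rise & t < t_rise + period
    stc <- first_crossing(t, x, eps, t_rise, rising = TRUE)
    fc  <- first_crossing(t, x, depth_mm - eps, t_rise, rising = TRUE)
    x_edge <- stats::approx(t, x, xout = t_fall, rule = 2)$y
    std <- first_crossing(t, x, x_edge - eps, t_fall, rising = FALSE)
    fd  <- first_crossing(t, x, eps, t_fall, rising = FALSE)
    clip <- function(v) if (!is.na(v) && v < t_rise + period) v - t_rise
                        else NA_real_
    data.frame(cycle = cyc + 1L,
               start_compress = clip(stc),
               fully_compressed = clip(fc),
               start_decompress = clip(std),
               fully_decompressed = clip(fd),
               peak_mm = max(x[in_cyc]))
  })
  do.call(rbind, ev)
}

#' @export
print.piston_trajectory <- function(x, ...) {
  cat(sprintf(
    "<piston_trajectory> %.0f mm @ %g/min duty %.2f, %d cycle(s)\n",
    x$depth, x$frequency, x$duty_cycle, nrow(x$events)))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' @export
plot.piston_trajectory <- function(x, ...) {
  graphics::plot(x$samples$t_s, x$samples$X_mm, type = "l",
                 xlab = "time (s)", ylab = "piston displacement (mm)",
                 ...)
  invisible(x)
}

#' Convert a piston trajectory to a compression waveform
#'
#' Extracts the displacement record of one steady cycle (by default the
#' last simulated cycle, when start-up transients have died out) as a
#' `cpr_waveform` with provenance `"simulated"`.
#'
#' @param traj a [simulate_compression()] result.
#' @param cycle which cycle to extract (default the last).
#' @return A `cpr_waveform`.
#' @export
trajectory_waveform <- function(traj, cycle = NULL) {
  period <- 60 / traj$frequency
  if (is.null(cycle)) cycle <- nrow(traj$events)
  t0 <- (cycle - 1) * period
  sel <- traj$samples$t_s >= t0 & traj$samples$t_s <= t0 + period
  df <- data.frame(t_s = traj$samples$t_s[sel] - t0,
                   X_mm = traj$samples$X_mm[sel])
  new_waveform(df, traj$depth, traj$frequency, traj$duty_cycle,
               "simulated")
}

#' Write a piston trajectory to CSV
#'
#' Columns `t_s,X_mm,Xdot_mm_s,P1_kPa,P2_kPa`.
#'
#' @param traj a `piston_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(
    traj$samples[c("t_s", "X_mm", "Xdot_mm_s", "P1_kPa", "P2_kPa")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
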