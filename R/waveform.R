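#' Compression waveform container
#'
#' @param samples data.frame with columns `t_s` (time, s) and `X_mm`
#'   (compression displacement, mm), sorted by time.
#' @param depth commanded depth, mm.
#' @param frequency compression rate, press/min.
#' @param duty_cycle active fraction of the period (instruction waveforms),
#'   or NA.
#' @param provenance one of `"instruction"`, `"manual_synthetic"`,
#'   `"simulated"`, `"recorded"`.
#' @param seed RNG seed used to generate the waveform, or NA.
#' @return An object of class `cpr_waveform`.
#' @keywords internal
new_waveform <- function(samples, depth, frequency, duty_cycle = NA,
                         provenance, seed = NA) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "X_mm") %in% names(samples)),
            !is.unsorted(samples$t_s))
  structure(list(samples = samples, depth = depth, frequency = frequency,
                 duty_cycle = duty_cycle, provenance = provenance,
                 seed = seed),
            class = "cpr_waveform")
}

#' @export
print.cpr_waveform <- function(x, ...) {
  cat(sprintf(
    "<cpr_waveform: %s>  depth %.1f mm, %g press/min%s, %d samples over %.3f s\n",
    x$provenance, x$depth, x$frequency,
    if (!is.na(x$duty_cycle)) sprintf(", duty %.2f", x$duty_cycle) else "",
    nrow(x$samples), max(x$samples$t_s)))
  invisible(x)
}

#' @export
plot.cpr_waveform <- function(x, ...) {
  graphics::plot(x$samples$t_s, x$samples$X_mm, type = "l",
                 xlab = "time (s)", ylab = "compression (mm)",
                 main = sprintf("%s waveform", x$provenance), ...)
  invisible(x)
}

#' Period of a waveform in seconds
#' @param wf a `cpr_waveform`.
#' @return Period 60/frequency, s.
#' @export
waveform_period <- function(wf) 60 / wf$frequency

#' Square-wave compression instruction
#'
#' The controller's commanded depth schedule: the full depth for
#' `duty_cycle` of each period, zero for the remainder, tiled over
#' `n_cycles` periods. The standard instruction is 50 mm at 100 press/min
#' with duty cycle 0.5 (period 0.6 s, 0.3 s commanded high).
#'
#' @param depth commanded depth, mm.
#' @param frequency compressions per minute (> 0).
#' @param duty_cycle active fraction of the period, in \[0.05, 0.95\].
#' @param n_cycles number of periods to generate.
#' @param dt sample spacing, s.
#' @return A `cpr_waveform` with provenance `"instruction"`.
#' @export
instruction_signal <- function(depth, frequency, duty_cycle, n_cycles = 1,
                               dt = 1e-3) {
  if (duty_cycle < 0.05 || duty_cycle > 0.95)
    stop("duty cycle must lie in [0.05, 0.95]", call. = FALSE)
  stopifnot(frequency > 0, depth > 0, n_cycles >= 1)
  period <- 60 / frequency
  t <- seq(0, n_cycles * period, by = dt)
  phase <- t %% period
  x <- ifelse(phase < duty_cycle * period & t < n_cycles * period, depth, 0)
  new_waveform(data.frame(t_s = t, X_mm = x), depth, frequency, duty_cycle,
               "instruction")
}

#' Synthetic manual (half-sine) compression waveform
#'
#' Surrogate for a human rescuer's compressions: each cycle is a half-sine
#' displacement hump sampled at 50 points, with an independent uniform
#' perturbation on \[-noise, +noise\] mm added to each of the first 25
#' points (the downstroke half of the cycle); the release half is the
#' noiseless mirrored half-sine. Reproducible from `seed`.
#'
#' @param depth peak compression depth, mm (> 2).
#' @param frequency compressions per minute.
#' @param n_cycles number of cycles.
#' @param seed integer RNG seed, or NA for no reseeding.
#' @param noise_mm half-width of the uniform perturbation, mm; 0 disables
#'   noise. Default 1.
#' @param points_per_cycle samples per cycle. Default 50.
#' @return A `cpr_waveform` with provenance `"manual_synthetic"`.
#' @export
manual_waveform <- function(depth, frequency, n_cycles = 1, seed = NA,
                            noise_mm = 1, points_per_cycle = 50L) {
  stopifnot(depth > 2, frequency > 0, n_cycles >= 1, noise_mm >= 0)
  if (!is.na(seed)) set.seed(as.integer(seed))
  period <- 60 / frequency
  npc <- as.integer(points_per_cycle)
  half <- npc %/% 2L
  tt <- xx <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    t_loc <- (seq_len(npc) - 1) / npc * period
    x <- depth * sin(pi * t_loc / period)
    if (noise_mm > 0)
      x[seq_len(half)] <- x[seq_len(half)] +
        stats::runif(half, -noise_mm, noise_mm)
    tt[[cyc]] <- t_loc + (cyc - 1) * period
    xx[[cyc]] <- x
  }
  samples <- data.frame(t_s = c(unlist(tt), n_cycles * period),
                        X_mm = c(unlist(xx), 0))
  new_waveform(samples, depth, frequency, NA, "manual_synthetic",
               seed = seed)
}

#' Batch of seeded manual waveforms
#'
#' Generates `n_sets` manual waveforms whose per-set seeds are derived
#' deterministically from one master seed, mirroring a study arm of
#' repeated manual-compression recordings.
#'
#' @inheritParams manual_waveform
#' @param n_sets number of waveforms (default 10).
#' @param master_seed integer master seed.
#' @return List of `cpr_waveform` objects.
#' @export
manual_waveform_batch <- function(depth, frequency, n_cycles = 1,
                                  n_sets = 10, master_seed = 1,
                                  noise_mm = 1) {
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_sets)
  lapply(seeds, function(s)
    manual_waveform(depth, frequency, n_cycles, seed = s,
                    noise_mm = noise_mm))
}

#' Read / write a compression waveform CSV
#'
#' The on-disk dialect is a two-column CSV with header `t_s,X_mm`,
#' decimal point and comma separator, UTF-8.
#'
#' @param path file path.
#' @param frequency,depth,provenance metadata for the loaded waveform;
#'   depth defaults to the sample maximum and frequency to one cycle over
#'   the record length.
#' @return `load_waveform` returns a `cpr_waveform`;
#'   `write_waveform` returns `path` invisibly.
#' @export
load_waveform <- function(path, frequency = NULL, depth = NULL,
                          provenance = "recorded") {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "X_mm") %in% names(df)))
    stop("waveform file must have columns t_s,X_mm: ", path, call. = FALSE)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone time in %s at line %d", path, bad[1] + 2),
         call. = FALSE)
  if (is.null(frequency)) frequency <- 60 / max(df$t_s)
  if (is.null(depth)) depth <- max(df$X_mm)
  new_waveform(df, depth, frequency, NA, provenance)
}

#' @rdname load_waveform
#' @param wf a `cpr_waveform` to write.
#' @export
write_waveform <- function(wf, path) {
  utils::write.csv(wf$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a waveform on a uniform grid
#'
#' Linear interpolation onto a uniform grid of spacing `dt` covering the
#' original time span.
#'
#' @param wf a `cpr_waveform`.
#' @param dt target sample spacing, s (> 0).
#' @return A `cpr_waveform` on the uniform grid.
#' @export
resample_waveform <- function(wf, dt) {
  stopifnot(dt > 0)
  tmax <- max(wf$samples$t_s)
  t <- seq(0, tmax, by = dt)
  x <- stats::approx(wf$samples$t_s, wf$samples$X_mm, xout = t,
                     rule = 2)$y
  out <- wf
  out$samples <- data.frame(t_s = t, X_mm = x)
  out
}

#' Compression velocity of a waveform
#'
#' Central-difference velocity (one-sided at the endpoints) of the
#' displacement record, in SI units for use as the circulation drive.
#'
#' @param wf a `cpr_waveform`.
#' @return data.frame with `t_s` (s), `Xdot_m_s` (m/s) and `X_m` (m).
#' @export
waveform_velocity <- function(wf) {
  t <- wf$samples$t_s
  x <- wf$samples$X_mm / 1000
  n <- length(t)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  data.frame(t_s = t, Xdot_m_s = v, X_m = x)
}
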