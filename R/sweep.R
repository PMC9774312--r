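#' One-at-a-time sweep of a compression parameter
#'
#' Sweeps compression depth, duty cycle or frequency over a grid while
#' holding the other two parameters at the standard instruction (50 mm,
#' 100 press/min, duty 0.5), simulating the full actuator-chest pipeline
#' for each grid point and scoring the resulting waveform on the
#' circulation model. Validated grid ranges follow the study protocol:
#' depth 20-50 mm, duty cycle 0.2-0.8, frequency 90-150 press/min.
#'
#' @param kind `"depth"`, `"duty"` or `"frequency"`.
#' @param grid strictly increasing grid of parameter values; defaults to
#'   the protocol resolution (1 mm / 0.01 / 1 press/min).
#' @param base named list of the standard parameters (`depth`,
#'   `frequency`, `duty`).
#' @param engine `"simulated"` (pneumatic-model waveform, default) or
#'   `"manual"` (noiseless half-sine surrogate).
#' @param actuator actuator configuration as returned by
#'   [default_actuator()].
#' @param network circulation topology.
#' @param n_cycles,warmup_cycles,dt_circ circulation run controls, passed
#'   to [run_circulation()].
#' @param act_cycles,dt_act actuator run controls (cycles simulated and
#'   integration step) for the `"simulated"` engine.
#' @return An object of class `sweep_result`: `table` (data.frame with
#'   `param`, `CO`, `CPP`, `CF`), `argmax` (named list of the grid value
#'   maximising each metric) and the sweep `kind`.
#' @export
parameter_sweep <- function(kind = c("depth", "duty", "frequency"),
                            grid = NULL,
                            base = list(depth = 50, frequency = 100,
                                        duty = 0.5),
                            engine = c("simulated", "manual"),
                            actuator = default_actuator(),
                            network = default_circulation(),
                            n_cycles = 25, warmup_cycles = 10,
                            dt_circ = 2e-4,
                            act_cycles = 3, dt_act = 5e-5) {
  kind <- match.arg(kind)
  engine <- match.arg(engine)
  lim <- switch(kind, depth = c(20, 50), duty = c(0.2, 0.8),
                frequency = c(90, 150))
  if (is.null(grid))
    grid <- switch(kind,
                   depth = seq(20, 50, by = 1),
                   duty = seq(0.2, 0.8, by = 0.01),
                   frequency = seq(90, 150, by = 1))
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (min(grid) < lim[1] || max(grid) > lim[2])
    stop(sprintf("%s grid outside the validated range [%g, %g]",
                 kind, lim[1], lim[2]), call. = FALSE)

  eval_point <- function(v) {
    depth <- if (kind == "depth") v else base$depth
    freq <- if (kind == "frequency") v else base$frequency
    duty <- if (kind == "duty") v else base$duty
    wf <- if (engine == "simulated") {
      traj <- simulate_compression(depth, freq, duty,
                                   n_cycles = act_cycles, dt = dt_act,
                                   gas = actuator$gas, reg = actuator$reg,
                                   cyl = actuator$cyl,
                                   chest = actuator$chest,
                                   gains = actuator$gains)
      trajectory_waveform(traj)
    } else {
      manual_waveform(depth, freq, noise_mm = 0)
    }
    m <- evaluate_waveform(wf, network, n_cycles = n_cycles,
                           warmup_cycles = warmup_cycles, dt = dt_circ)
    c(CO = m$CO, CPP = m$CPP, CF = m$CF)
  }

  res <- t(vapply(grid, eval_point, numeric(3)))
  tab <- data.frame(param = grid, res)
  argmax <- lapply(c(CO = "CO", CPP = "CPP", CF = "CF"),
                   function(m) grid[which.max(tab[[m]])])
  structure(list(kind = kind, table = tab, argmax = argmax,
                 engine = engine),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s, %s engine> %d grid points\n",
              x$kind, x$engine, nrow(x$table)))
  for (m in c("CO", "CPP", "CF"))
    cat(sprintf("  max %s = %.4f at %s = %g\n", m,
                max(x$table[[m]]), x$kind, x$argmax[[m]]))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, metric = "CO", ...) {
  graphics::plot(x$table$param, x$table[[metric]], type = "l",
                 xlab = x$kind, ylab = metric, ...)
  invisible(x)
}

#' Write a sweep table to CSV
#'
#' Columns `param,CO,CPP,CF`.
#'
#' @param sweep a `sweep_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(sweep$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
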