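trace_edge_col <- function(trace, role) {
  e <- trace$network$roles[[role]]
  if (is.null(e))
    stop("topology does not designate the '", role, "' role",
         call. = FALSE)
  col <- paste0(e[1], "->", e[2])
  if (!col %in% colnames(trace$flows))
    stop("designated edge ", col, " not present in the network",
         call. = FALSE)
  col
}

trace_comp <- function(trace, role) {
  nm <- trace$network$roles[[role]]
  if (is.null(nm) || !nm %in% colnames(trace$pressures))
    stop("topology does not designate a valid '", role, "' compartment",
         call. = FALSE)
  nm
}

#' Cardiac output of a hemodynamic trace
#'
#' Mean flow through the designated cardiac-output valve edge (the left
#' heart outflow in the shipped topology) over the recorded steady-state
#' span, in L/min.
#'
#' @param trace a `hemodynamic_trace` at periodic steady state.
#' @param n_cycles average over this many final whole cycles (default all
#'   recorded samples).
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(trace, n_cycles = NULL) {
  q <- trace$flows[, trace_edge_col(trace, "cardiac_output_edge")]
  mean(cycle_subset(trace, q, n_cycles))
}

#' Cerebral flow of a hemodynamic trace
#'
#' Mean flow through the designated cerebral branch edge, L/min.
#'
#' @inheritParams cardiac_output
#' @return Cerebral flow, L/min.
#' @export
cerebral_flow <- function(trace, n_cycles = NULL) {
  q <- trace$flows[, trace_edge_col(trace, "cerebral_edge")]
  mean(cycle_subset(trace, q, n_cycles))
}

cycle_subset <- function(trace, v, n_cycles) {
  if (is.null(n_cycles)) return(v)
  t_end <- max(trace$time)
  v[trace$time > t_end - n_cycles * trace$period + 1e-12]
}

#' Coronary perfusion pressure of a hemodynamic trace
#'
#' Time-average of the aorta-to-right-atrium pressure gradient over the
#' diastolic (decompression) windows of the driving waveform, mmHg. With
#' no intrinsic heartbeat during CPR, "diastole" is the phase in which
#' the compression command is released.
#'
#' @inheritParams cardiac_output
#' @param window decompression window as fractions of the period
#'   `c(start, end)`; defaults to the window recorded in the trace.
#' @return Coronary perfusion pressure, mmHg.
#' @export
coronary_perfusion_pressure <- function(trace, window = NULL,
                                        n_cycles = NULL) {
  if (is.null(window)) window <- trace$decomp_window
  if (window[2] <= window[1])
    stop("empty decompression window", call. = FALSE)
  phase <- (trace$time %% trace$period) / trace$period
  sel <- phase >= window[1] & phase < window[2]
  if (!any(sel)) stop("empty decompression window", call. = FALSE)
  grad <- trace$pressures[, trace_comp(trace, "aorta")] -
    trace$pressures[, trace_comp(trace, "right_atrium")]
  grad[!sel] <- NA
  mean(cycle_subset(trace, grad, n_cycles), na.rm = TRUE)
}

#' Perfusion metric summary of a trace
#'
#' CO, CPP and CF together with the peak aortic and right-atrial
#' pressures and the times (within the compression cycle) at which they
#' are reached.
#'
#' @inheritParams cardiac_output
#' @return An object of class `perfusion_metrics`: list with `CO` (L/min),
#'   `CPP` (mmHg), `CF` (L/min), `peak_Pao`, `t_peak_Pao`, `peak_Pra`,
#'   `t_peak_Pra`.
#' @export
perfusion_metrics <- function(trace) {
  last_cycle <- trace$time > max(trace$time) - trace$period + 1e-12
  tt <- trace$time[last_cycle] %% trace$period
  pao <- trace$pressures[last_cycle, trace_comp(trace, "aorta")]
  pra <- trace$pressures[last_cycle, trace_comp(trace, "right_atrium")]
  structure(list(CO = cardiac_output(trace),
                 CPP = coronary_perfusion_pressure(trace),
                 CF = cerebral_flow(trace),
                 peak_Pao = max(pao), t_peak_Pao = tt[which.max(pao)],
                 peak_Pra = max(pra), t_peak_Pra = tt[which.max(pra)]),
            class = "perfusion_metrics")
}

#' @export
print.perfusion_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("CO  %.4f L/min\nCPP %.3f mmHg\nCF  %.4f L/min\n",
           "peak Pao %.2f mmHg @ %.3f s, peak Pra %.2f mmHg @ %.3f s\n"),
    x$CO, x$CPP, x$CF, x$peak_Pao, x$t_peak_Pao, x$peak_Pra,
    x$t_peak_Pra))
  invisible(x)
}

#' Compression-to-perfusion pipeline for one waveform
#'
#' Runs the circulation model under a given compression waveform and
#' summarises the perfusion metrics.
#'
#' @param wf a `cpr_waveform` (any provenance).
#' @param network a [circulation_network()]; default the shipped topology.
#' @param ... passed to [run_circulation()].
#' @return A `perfusion_metrics` object.
#' @export
evaluate_waveform <- function(wf, network = default_circulation(), ...) {
  perfusion_metrics(run_circulation(network, wf, ...))
}
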