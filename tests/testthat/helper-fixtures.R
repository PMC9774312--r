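# shared fixtures: the standard instruction pipeline is used by many tests;
# simulate once per test run
std_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_compression(50, 100, 0.5, n_cycles = 3)
    cache
  }
})

std_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_circulation(default_circulation(),
                                trajectory_waveform(std_trajectory()))
    cache
  }
})

# hand-built constant trace for metric unit tests (no simulation)
constant_trace <- function(Pao = 40, Pra = 10, n = 601, period = 0.6) {
  comp <- data.frame(name = c("aorta", "right_heart"), C = c(1, 1),
                     P0 = c(Pao, Pra), intrathoracic = FALSE,
                     pulmonary = FALSE)
  P <- cbind(aorta = rep(Pao, n), right_heart = rep(Pra, n))
  structure(list(time = seq(0, period * 2, length.out = n),
                 pressures = P, stored = P,
                 flows = matrix(0.5, n, 1,
                                dimnames = list(NULL, "aorta->right_heart")),
                 PM = numeric(n), Plung = numeric(n),
                 period = period, decomp_window = c(0.5, 1),
                 network = list(compartments = comp,
                                roles = list(aorta = "aorta",
                                             right_atrium = "right_heart",
                                             cardiac_output_edge =
                                               c("aorta", "right_heart"),
                                             cerebral_edge =
                                               c("aorta", "right_heart")))),
            class = "hemodynamic_trace")
}

# minimal closed two-compartment loop for analytic RC checks
two_node_network <- function(CA = 2, CB = 5, R1 = 10, R2 = 25,
                             PA0 = 30, PB0 = 5) {
  comp <- data.frame(name = c("A", "B"), C = c(CA, CB), P0 = c(PA0, PB0),
                     intrathoracic = FALSE, pulmonary = FALSE)
  edges <- data.frame(from = c("A", "B"), to = c("B", "A"),
                      R = c(R1, R2), valve = FALSE)
  circulation_network(comp, edges,
                      roles = list(aorta = "A", right_atrium = "B",
                                   cardiac_output_edge = c("A", "B"),
                                   cerebral_edge = c("B", "A")))
}
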