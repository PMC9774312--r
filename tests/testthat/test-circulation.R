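test_that("edge flow is Ohmic with an ideal-diode valve option", {
  expect_equal(edge_flow(40, 10, 15), 2)
  expect_equal(edge_flow(10, 10, 15), 0)
  expect_equal(edge_flow(10, 40, 15), -2)
  expect_equal(edge_flow(10, 40, 15, valve = TRUE), 0)
})

test_that("pressure rate is net inflow over compliance, unit-consistent", {
  expect_equal(pressure_rate(2, 2, 10), 0)
  # 2 L/min net = 33.33 mL/s into 10 mL/mmHg
  expect_equal(pressure_rate(3, 1, 10), 2 * 1000 / 60 / 10)
  expect_equal(pressure_rate(3, 1, 20), pressure_rate(3, 1, 10) / 2)
  expect_error(pressure_rate(1, 0, -1))
})

test_that("pump source rates obey their defining relations", {
  p <- pump_source_params()
  expect_equal(thoracic_pump_rate(0, 0, p), 0)
  expect_gt(thoracic_pump_rate(0.3, 0, p), 0)
  expect_equal(thoracic_pump_rate(0.3, 0.01, p), p$E * 0.31 / p$d0)
  # mediastinal pressure closes over a closed displacement cycle
  t <- seq(0, 0.6, by = 1e-4)
  v <- 0.05 * pi / 0.6 * cos(pi * t / 0.6) *
    sign(sin(pi * t / 0.6 + 1e-12))  # d/dt of a half-sine hump
  v <- c(diff(0.05 * sin(pi * t / 0.6)) / 1e-4, 0)
  integral <- sum(thoracic_pump_rate(v, 0, p)) * 1e-4
  expect_equal(integral, 0, tolerance = 1e-6)

  # alveolar source: equilibrium, decay sign and steady state
  expect_equal(lung_pressure_rate(0, p$P_mouth, p), 0)
  expect_lt(lung_pressure_rate(0, p$P_mouth + 5, p), 0)
  P_ss <- 0.2 * p$A_L * 1000 * p$R_airway + p$P_mouth
  expect_equal(lung_pressure_rate(0.2, P_ss, p), 0, tolerance = 1e-12)
})

test_that("two-compartment reduction matches the closed-form exponential", {
  net <- two_node_network(CA = 2, CB = 5, R1 = 10, R2 = 25,
                          PA0 = 30, PB0 = 5)
  tr <- run_circulation(net, NULL, n_cycles = 2, warmup_cycles = 0,
                        period = 0.6, dt = 2e-4, sample_every = 1L)
  g <- (1 / 10 + 1 / 25) / 0.06          # conductance, mL/s per mmHg
  lambda <- g * (1 / 2 + 1 / 5)
  D <- tr$pressures[, "A"] - tr$pressures[, "B"]
  expect_equal(D, 25 * exp(-lambda * tr$time), tolerance = 1e-6)
})

test_that("stiff ODE solver agrees with the fixed-step integrator on the RC loop", {
  net <- two_node_network()
  tr <- run_circulation(net, NULL, n_cycles = 2, warmup_cycles = 0,
                        period = 0.6, dt = 2e-4, sample_every = 25L)
  g <- (1 / 10 + 1 / 25) / 0.06
  rhs <- function(t, y, parms)
    list(c((y[2] - y[1]) * g / 2, (y[1] - y[2]) * g / 5))
  sol <- deSolve::lsoda(c(30, 5), tr$time, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(tr$pressures[, "A"], unname(sol[, 2]), tolerance = 1e-6)
})

test_that("zero drive relaxes to a static equilibrium with closed valves", {
  # slowest venous RC constants are minutes long: relax for 3 min
  net <- default_circulation()
  tr <- run_circulation(net, NULL, n_cycles = 300, warmup_cycles = 298,
                        period = 0.6, sample_every = 20L)
  n <- length(tr$time)
  valve_cols <- which(net$edges$valve)
  expect_lt(max(abs(tr$flows[n, valve_cols])), 2e-3)
  # pressures essentially constant at the end of the relaxation
  expect_lt(max(apply(tr$pressures, 2, function(x) diff(range(x)))), 0.01)
})

test_that("total blood volume is conserved through compression cycles", {
  vol <- blood_volume(std_trace())
  expect_lt(diff(range(vol)) / mean(vol), 1e-6)
})

test_that("valve-edge flows are never negative", {
  tr <- std_trace()
  valve_cols <- which(tr$network$edges$valve)
  expect_gte(min(tr$flows[, valve_cols]), 0)
})

test_that("the trace reaches periodic steady state after warm-up", {
  tr <- std_trace()
  per_samples <- sum(tr$time < tr$period - 1e-12)
  n <- length(tr$time)
  last <- (n - per_samples + 1):n
  prev <- last - per_samples
  for (cmp in c("aorta", "right_heart", "lungs", "abdominal_aorta")) {
    a <- tr$pressures[last, cmp]; b <- tr$pressures[prev, cmp]
    expect_lt(sqrt(mean((a - b)^2)), 0.005 * sqrt(mean(a^2)))
  }
})

test_that("vessel-expansion coupling modes both integrate and differ", {
  net <- default_circulation()
  wf <- trajectory_waveform(std_trajectory())
  net0 <- net
  net0$sources$x2_mode <- "zero"
  m1 <- perfusion_metrics(run_circulation(net, wf, n_cycles = 14,
                                          warmup_cycles = 8))
  m0 <- perfusion_metrics(run_circulation(net0, wf, n_cycles = 14,
                                          warmup_cycles = 8))
  expect_true(is.finite(m1$CO) && is.finite(m0$CO))
  expect_false(isTRUE(all.equal(m1$CO, m0$CO)))
})

test_that("malformed topologies are rejected", {
  comp <- data.frame(name = c("A", "B"), C = 1, P0 = 0,
                     intrathoracic = FALSE, pulmonary = FALSE)
  edges <- data.frame(from = "A", to = "B", R = 1, valve = FALSE)
  expect_error(circulation_network(comp, edges), "closed loop")
  edges2 <- data.frame(from = c("A", "B"), to = c("B", "Z"), R = 1,
                       valve = FALSE)
  expect_error(circulation_network(comp, edges2), "unknown")
})
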