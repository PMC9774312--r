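test_that("constant-gradient trace gives CPP equal to the gradient", {
  tr <- constant_trace(Pao = 40, Pra = 10)
  expect_equal(coronary_perfusion_pressure(tr), 30)
  expect_equal(coronary_perfusion_pressure(tr, window = c(0.6, 0.9)), 30)
  tr0 <- constant_trace(Pao = 25, Pra = 25)
  expect_equal(coronary_perfusion_pressure(tr0), 0)
  expect_error(coronary_perfusion_pressure(tr, window = c(0.5, 0.5)),
               "window")
})

test_that("zero drive produces no cardiac output or cerebral flow", {
  # the deepest venous RC time constants are on the order of minutes, so
  # the arrest baseline needs a long passive relaxation
  net <- default_circulation()
  tr <- run_circulation(net, NULL, n_cycles = 300, warmup_cycles = 298,
                        period = 0.6, sample_every = 20L)
  expect_lt(cardiac_output(tr), 2e-3)
  expect_lt(cerebral_flow(tr), 2e-3)
})

test_that("metric extraction requires the designated roles", {
  tr <- std_trace()
  tr$network$roles$cardiac_output_edge <- NULL
  expect_error(cardiac_output(tr), "role")
  tr2 <- std_trace()
  tr2$network$roles$cerebral_edge <- c("aorta", "legs")
  expect_error(cerebral_flow(tr2), "not present")
})

test_that("cerebral flow never exceeds cardiac output at steady state", {
  tr <- std_trace()
  expect_lte(cerebral_flow(tr), cardiac_output(tr))
})

test_that("averaging over one or five steady cycles agrees within 0.5%", {
  tr <- std_trace()
  co1 <- cardiac_output(tr, n_cycles = 1)
  co5 <- cardiac_output(tr, n_cycles = 5)
  expect_equal(co1, co5, tolerance = 5e-3)
})

test_that("perfusion summary reports distinct peak pressures and times", {
  m <- perfusion_metrics(std_trace())
  expect_gt(m$peak_Pao, m$peak_Pra)
  expect_true(m$t_peak_Pao >= 0 && m$t_peak_Pao <= 0.6)
  expect_true(m$t_peak_Pra >= 0 && m$t_peak_Pra <= 0.6)
  expect_output(print(m), "CPP")
})

test_that("standard simulated waveform reproduces the shipped operating point", {
  # regression guard on the calibrated defaults (deterministic pipeline)
  m <- perfusion_metrics(std_trace())
  expect_equal(m$CO, 1.221542, tolerance = 1e-3)
  expect_equal(m$CPP, 31.08751, tolerance = 1e-3)
  expect_equal(m$CF, 0.315386, tolerance = 1e-3)
})
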