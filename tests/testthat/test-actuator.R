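test_that("standard instruction reproduces the reference event times", {
  traj <- std_trajectory()
  ev <- traj$events[3, ]   # steady cycle
  # shipped-configuration reference timings (s within the cycle)
  expect_equal(ev$start_compress, 0.0087, tolerance = 0.02 / 0.0087)
  expect_equal(ev$fully_compressed, 0.2171, tolerance = 0.02 / 0.2171)
  expect_equal(ev$start_decompress, 0.3088, tolerance = 0.02 / 0.3088)
  expect_equal(ev$fully_decompressed, 0.4721, tolerance = 0.02 / 0.4721)
  expect_equal(ev$peak_mm, 50, tolerance = 2 / 50)
})

test_that("event times are strictly ordered within every cycle", {
  ev <- std_trajectory()$events
  for (i in seq_len(nrow(ev))) {
    times <- unlist(ev[i, c("start_compress", "fully_compressed",
                            "start_decompress", "fully_decompressed")])
    expect_false(anyNA(times))
    expect_true(all(diff(times) > 0))
  }
})

test_that("the thorax delays compression more than decompression", {
  ev <- std_trajectory()$events[3, ]
  comp_delay <- ev$fully_compressed               # from instruction rise
  decomp_delay <- ev$fully_decompressed - 0.3     # from instruction fall
  expect_gt(comp_delay, decomp_delay)
})

test_that("displacement stays clamped to the stroke", {
  s <- std_trajectory()$samples
  expect_gte(min(s$X_mm), 0)
  expect_lte(max(s$X_mm), 50 + 1e-9)
})

test_that("no supply pressure margin means no motion", {
  cyl <- cylinder_params(Ps = 1.01325e5)   # Ps = Pa
  traj <- simulate_compression(50, 100, 0.5, n_cycles = 1, cyl = cyl)
  expect_equal(max(abs(traj$samples$X_mm)), 0)
})

test_that("trajectories converge under step halving", {
  t1 <- simulate_compression(50, 100, 0.5, n_cycles = 1, dt = 5e-5,
                             sample_every = 8L)
  t2 <- simulate_compression(50, 100, 0.5, n_cycles = 1, dt = 2.5e-5,
                             sample_every = 16L)
  expect_equal(t1$samples$t_s, t2$samples$t_s)
  expect_lt(max(abs(t1$samples$X_mm - t2$samples$X_mm)), 0.1)
})

test_that("compiled trajectory is consistent with the R rate operations", {
  traj <- std_trajectory()
  s <- traj$samples
  gas <- gas_constants(); cyl <- cylinder_params()
  chest <- chest_params(); reg <- regulator_params()
  # mid-compression sample: piston rising, chamber 1 charging choked
  i <- which(s$t_s > 0.05 & s$t_s < 0.15 & s$Xdot_mm_s > 50)[1]
  st <- list(X = s$X_mm[i] / 1000, Xdot = s$Xdot_mm_s[i] / 1000,
             P1 = s$P1_kPa[i] * 1000, P2 = s$P2_kPa[i] * 1000)
  # acceleration implied by neighbouring velocity samples
  dts <- diff(s$t_s[c(i - 1, i + 1)])
  acc_num <- (s$Xdot_mm_s[i + 1] - s$Xdot_mm_s[i - 1]) / 1000 / dts
  F_ext <- reaction_force(st$X, st$Xdot, chest)
  acc_R <- piston_net_force(st, F_ext, cyl, direction = 1) / cyl$M_W
  expect_equal(acc_num, acc_R, tolerance = 0.05)
})

test_that("commanded depth beyond the stroke is rejected", {
  expect_error(simulate_compression(60, 100, 0.5), "stroke")
  expect_error(simulate_compression(50, 100, 0), "duty")
})

test_that("trajectory round-trips through the CSV writer", {
  traj <- simulate_compression(50, 100, 0.5, n_cycles = 1,
                               sample_every = 100L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  df <- read.csv(f)
  expect_named(df, c("t_s", "X_mm", "Xdot_mm_s", "P1_kPa", "P2_kPa"))
  expect_equal(df$X_mm, traj$samples$X_mm, tolerance = 1e-12)
})
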