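test_that("instruction signal has the commanded period, duty and tiling", {
  wf <- instruction_signal(50, 100, 0.5, n_cycles = 3)
  expect_equal(waveform_period(wf), 0.6)
  s <- wf$samples
  one <- s[s$t_s < 0.6, ]
  expect_equal(max(one$t_s[one$X_mm == 50]), 0.3 - 1e-3, tolerance = 1e-9)
  # 3 identical periods
  for (k in 1:2) {
    shifted <- s$X_mm[s$t_s >= k * 0.6 - 1e-12 & s$t_s < (k + 1) * 0.6 - 1e-12]
    expect_equal(shifted, one$X_mm)
  }
  expect_error(instruction_signal(50, 100, 0.01), "duty")
})

test_that("manual waveform is reproducible from its seed", {
  a <- manual_waveform(50, 100, seed = 11)
  b <- manual_waveform(50, 100, seed = 11)
  c <- manual_waveform(50, 100, seed = 12)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("noiseless manual waveform is an exact half-sine peaking at depth", {
  wf <- manual_waveform(40, 100, noise_mm = 0)
  s <- wf$samples[-nrow(wf$samples), ]
  expect_equal(s$X_mm, 40 * sin(pi * s$t_s / 0.6), tolerance = 1e-12)
  expect_equal(max(s$X_mm), 40, tolerance = 0.02)
  i_max <- which.max(s$X_mm)
  expect_true(i_max %in% 25:26)   # peak in the 25th-point region
})

test_that("noise perturbations are uniform on [-1, 1] mm", {
  wf <- manual_waveform(50, 100, n_cycles = 400, seed = 99)
  s <- wf$samples[-nrow(wf$samples), ]
  pure <- 50 * sin(pi * (s$t_s %% 0.6) / 0.6)
  dev <- (s$X_mm - pure)
  noisy <- abs(dev) > 1e-9
  expect_equal(sum(noisy), 400 * 25)      # first half-cycle points only
  expect_gt(stats::ks.test(dev[noisy], "punif", -1, 1)$p.value, 0.01)
  # mean absolute deviation from the half-sine bounded by the noise width
  expect_lte(max(abs(dev)), 1 + 1e-9)
})

test_that("waveform batch derives distinct reproducible per-set seeds", {
  b1 <- manual_waveform_batch(50, 100, n_sets = 10, master_seed = 5)
  b2 <- manual_waveform_batch(50, 100, n_sets = 10, master_seed = 5)
  expect_length(b1, 10)
  expect_identical(lapply(b1, `[[`, "samples"), lapply(b2, `[[`, "samples"))
  expect_equal(length(unique(vapply(b1, `[[`, 0, "seed"))), 10)
})

test_that("waveform CSV round-trips and validates its input", {
  wf <- manual_waveform(50, 100, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, f)
  back <- load_waveform(f, frequency = 100)
  expect_equal(back$samples$X_mm, wf$samples$X_mm, tolerance = 1e-12)
  writeLines(c("t_s,X_mm", "0,0", "0.2,10", "0.1,20"), f)
  expect_error(load_waveform(f), "non-monotone")
  writeLines(c("a,b", "0,0"), f)
  expect_error(load_waveform(f), "t_s")
})

test_that("resampling a uniform series at its own spacing is the identity", {
  wf <- instruction_signal(50, 100, 0.5, n_cycles = 1, dt = 1e-3)
  rs <- resample_waveform(wf, 1e-3)
  expect_equal(rs$samples$X_mm, wf$samples$X_mm)
})

test_that("velocity of a half-sine matches the analytic derivative", {
  # 1 kHz sampling: 600 points per 0.6 s cycle
  wf <- manual_waveform(50, 100, noise_mm = 0, points_per_cycle = 600L)
  v <- waveform_velocity(wf)
  keep <- seq(3, nrow(v) - 2)
  analytic <- (0.05 * pi / 0.6) * cos(pi * v$t_s[keep] / 0.6)
  rms_err <- sqrt(mean((v$Xdot_m_s[keep] - analytic)^2))
  expect_lt(rms_err, 0.01 * sqrt(mean(analytic^2)))
})

test_that("velocity re-integrates to the displacement within 0.1 mm", {
  traj <- std_trajectory()
  wf <- trajectory_waveform(traj)
  v <- waveform_velocity(wf)
  dt <- diff(v$t_s)
  drift <- sum((v$Xdot_m_s[-1] + v$Xdot_m_s[-length(dt) - 1]) / 2 * dt)
  expect_lt(abs(drift * 1000 -
                  (wf$samples$X_mm[nrow(wf$samples)] - wf$samples$X_mm[1])),
            0.1)
})
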