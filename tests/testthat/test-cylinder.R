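test_that("chamber pressure rates match an independent re-derivation", {
  p <- cylinder_params()
  g <- gas_constants()
  st <- list(X = 0.02, Xdot = 0.3, P1 = 3e5, P2 = 1.5e5)
  Q1 <- 2e-3; Q2 <- 1e-3
  got <- chamber_pressure_rates(st, Q1, Q2, p, g)
  # energy balance written out from scratch: V dP = k R T dM - k P dV
  V1 <- p$A1 * (p$X10 + st$X)
  V2 <- p$A2 * (p$L + p$X20 - st$X)
  T2 <- p$Ts * (st$P2 / p$Ps)^((g$k - 1) / g$k)
  exp1 <- (g$k * g$R * p$Ts * Q1 - g$k * st$P1 * p$A1 * st$Xdot) / V1
  exp2 <- (g$k * st$P2 * p$A2 * st$Xdot - g$k * g$R * T2 * Q2) / V2
  expect_equal(unname(got), c(exp1, exp2), tolerance = 1e-12)
})

test_that("static closed chambers hold pressure; expansion depressurises", {
  p <- cylinder_params()
  st0 <- list(X = 0.02, Xdot = 0, P1 = 3e5, P2 = 1.5e5)
  expect_equal(unname(chamber_pressure_rates(st0, 0, 0, p)), c(0, 0))
  st1 <- list(X = 0.02, Xdot = 0.2, P1 = 3e5, P2 = 1.5e5)
  r <- chamber_pressure_rates(st1, 0, 0, p)
  expect_lt(r[["dP1"]], 0)   # rodless chamber expands
  expect_gt(r[["dP2"]], 0)   # rod chamber is squeezed
  expect_error(
    chamber_pressure_rates(list(X = 0.06, Xdot = 0, P1 = 1e5, P2 = 1e5),
                           0, 0, p),
    "stroke")
})

test_that("piston force balance honours breakaway derating and friction sign", {
  p <- cylinder_params()
  # balanced configuration: thrust exactly cancels the load
  F_ext <- 100
  P2 <- 2e5
  P1 <- (P2 * p$A2 + F_ext - p$F3 + p$Pa * (p$A1 - p$A2)) / p$A1
  st <- list(X = 0.01, P1 = P1, P2 = P2)
  expect_equal(piston_net_force(st, F_ext, p, direction = 0), 0,
               tolerance = 1e-9)
  # at the retracted stop only 0.8 of the working area acts
  st0 <- list(X = 0, P1 = 3e5, P2 = 1.01325e5)
  stx <- list(X = 1e-4, P1 = 3e5, P2 = 1.01325e5)
  d <- piston_net_force(stx, 0, p, 1) - piston_net_force(st0, 0, p, 1)
  expect_equal(d, 0.2 * 3e5 * p$A1, tolerance = 1e-9)
  # kinetic friction flips with the motion direction
  up <- piston_net_force(stx, 0, p, direction = 1)
  dn <- piston_net_force(stx, 0, p, direction = -1)
  expect_equal(dn - up, 2 * p$F1)
  # at rest, static friction absorbs sub-threshold thrust
  expect_equal(piston_net_force(st, F_ext + p$F1 / 2, p, direction = 0), 0)
})
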