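p_ctrl <- da_params("control")
p_imb <- da_params("imbalance")

test_that("tonic release rate follows the release equation and its scalings", {
  # direct arithmetic: rho*Pr*n0/(alpha*NA)*nu, in uM/L/s
  expect_equal(tonic_release_rate(p_ctrl), 0.1423319, tolerance = 1e-6)
  expect_equal(tonic_release_rate(da_params(nu_tonic = 0)), 0)
  p2 <- da_params(rho = 2 * p_ctrl$rho)
  expect_equal(tonic_release_rate(p2), 2 * tonic_release_rate(p_ctrl))
})

test_that("phasic release carries the inverse-square autoreceptor scaling", {
  # at AR = AR_norm the scale factors cancel: nu_phasic/nu_tonic x tonic
  expect_equal(phasic_release_rate(p_ctrl, AR = 0.334, rpe = 1),
               10 * tonic_release_rate(p_ctrl), tolerance = 1e-12)
  expect_equal(phasic_release_rate(p_ctrl, AR = 0.5, rpe = 0), 0)
  r1 <- phasic_release_rate(p_ctrl, AR = 0.6, rpe = 1)
  r2 <- phasic_release_rate(p_ctrl, AR = 0.3, rpe = 1)
  expect_equal(r2, 4 * r1, tolerance = 1e-12)
  expect_error(phasic_release_rate(p_ctrl, AR = 0, rpe = 1), "AR")
})

test_that("tonic steady state matches the calibration targets and closed form", {
  ss <- da_steady_state(p_ctrl)
  expect_equal(ss$C_tonic, 0.02, tolerance = 0.02)
  expect_equal(ss$AR, 0.334, tolerance = 0.01)
  expect_equal(ss$AR, p_ctrl$kon * ss$C_tonic /
                 (p_ctrl$kon * ss$C_tonic + p_ctrl$koff), tolerance = 1e-12)
  # independent bisection oracle for the imbalance equilibrium
  f <- function(C) tonic_release_rate(p_imb) -
    p_imb$Vmax * C / (p_imb$km + C) - p_imb$krem * C
  C_oracle <- uniroot(f, c(1e-8, 1), tol = 1e-12)$root
  expect_equal(da_steady_state(p_imb)$C_tonic, C_oracle, tolerance = 1e-8)
  expect_equal(C_oracle, 0.0128, tolerance = 0.01)
})

test_that("steady state agrees with long-time integration of the step map", {
  for (p in list(p_ctrl, p_imb)) {
    ss <- da_steady_state(p)
    st <- list(C_DA = 0.001, AR = 0.9, t = 0)
    for (i in 1:20000) st <- da_step(st, p, list(), dt = 1e-3)
    expect_equal(st$C_DA, ss$C_tonic, tolerance = 1e-4)
    expect_equal(st$AR, ss$AR, tolerance = 1e-4)
  }
})

test_that("the step map honours fixed points, clamps and closed forms", {
  ss <- da_steady_state(p_ctrl)
  st <- list(C_DA = ss$C_tonic, AR = ss$AR, t = 0)
  st2 <- da_step(st, p_ctrl, list(), dt = 1e-3)
  expect_equal(st2$C_DA, st$C_DA, tolerance = 1e-8)
  # punishment window clamps the concentration to zero outright
  ev <- rpe_event("punishment", onset = 0)
  st3 <- da_step(list(C_DA = 0.05, AR = 0.4, t = 0.12), p_ctrl, ev, dt = 1e-3)
  expect_identical(st3$C_DA, 0)
  expect_lt(st3$AR, 0.4)  # pure unbinding
  # with no reuptake the closed-form equilibrium release/krem is a fixed
  # point of the step map
  p3 <- da_params(Vmax = 0)
  C_star <- tonic_release_rate(p3) / p3$krem
  expect_equal(da_steady_state(p3)$C_tonic, C_star, tolerance = 1e-10)
  st4 <- list(C_DA = C_star, AR = p3$kon * C_star /
                (p3$kon * C_star + p3$koff), t = 0)
  st5 <- da_step(st4, p3, list(), dt = 1e-3)
  expect_equal(st5$C_DA, C_star, tolerance = 1e-10)
  expect_error(da_step(st, p_ctrl, list(), dt = -1e-3), "dt")
  expect_error(da_step(st, p_ctrl, list(), dt = 0.01), "1 ms")
})

test_that("single-burst transients reproduce the phasic/tonic ratios", {
  tr0 <- phasic_transient(p_ctrl, rpe = 0)
  expect_equal(tr0$C_peak, tr0$C_tonic, tolerance = 1e-6)
  expect_equal(da_ratio(p_ctrl), 3, tolerance = 0.15)
  expect_equal(da_ratio(p_imb), 8.3, tolerance = 0.15)
  tr <- phasic_transient(p_ctrl, rpe = 1)
  expect_gt(tr$C_peak, tr$C_tonic)
  expect_true(all(tr$trace$C_DA >= 0))
  expect_true(all(tr$trace$AR >= 0 & tr$trace$AR <= 1))
})

test_that("receptor occupancy is saturating Michaelis-Menten binding", {
  occ0 <- receptor_occupancy(0, p_ctrl)
  expect_equal(occ0$D1, 0)
  expect_equal(occ0$D2, 0)
  half <- receptor_occupancy(p_ctrl$kD_D1, p_ctrl)
  expect_equal(half$D1, p_ctrl$Bmax_D1 / 2)
  occ <- receptor_occupancy(0.02, p_ctrl)
  expect_equal(occ$D1, 0.03137255, tolerance = 1e-6)
  expect_equal(occ$D2, 0.05333333, tolerance = 1e-6)
  # monotone and bounded by Bmax
  Cs <- seq(0, 5, length.out = 50)
  o <- receptor_occupancy(Cs, p_ctrl)
  expect_true(all(diff(o$D1) > 0) && all(diff(o$D2) > 0))
  expect_true(all(o$D1 <= p_ctrl$Bmax_D1) && all(o$D2 <= p_ctrl$Bmax_D2))
})

test_that("pause decay takes ~500 ms and matches the linearised rate", {
  t_decay <- punishment_decay_time(p_ctrl, threshold_frac = 0.01)
  expect_equal(t_decay, 0.5, tolerance = 0.3)
  # small-C limit: exponential with rate Vmax/km + krem
  p_small <- da_params(rho = p_ctrl$rho / 100)  # tiny steady state
  rate <- p_small$Vmax / p_small$km + p_small$krem
  expect_equal(punishment_decay_time(p_small, 0.01, dt = 1e-4),
               log(100) / rate, tolerance = 0.02)
  # threshold close to 1 gives a vanishing time
  expect_lt(punishment_decay_time(p_ctrl, threshold_frac = 0.99), 0.01)
  expect_error(punishment_decay_time(p_ctrl, threshold_frac = 1.5))
})

test_that("raising reuptake lowers tonic dopamine and raises the burst ratio", {
  vmax <- c(1.0, 1.2, 1.5, 1.8, 2.2)
  C <- vapply(vmax, function(v) da_steady_state(da_params(Vmax = v))$C_tonic,
              numeric(1))
  AR <- vapply(vmax, function(v) da_steady_state(da_params(Vmax = v))$AR,
               numeric(1))
  ratio <- vapply(vmax, function(v) da_ratio(da_params(Vmax = v)), numeric(1))
  expect_true(all(diff(C) < 0))       # C_tonic strictly decreasing in Vmax
  expect_true(all(diff(AR) < 0))      # AR* follows C_tonic
  expect_true(all(diff(ratio) > 0))   # burst amplification grows
})

test_that("parameter validation rejects degenerate values", {
  expect_error(da_params(Vmax = -1), ">= 0")
  expect_error(da_params(alpha_vf = 1.5), "alpha_vf")
  expect_error(da_params(AR_norm = 0), "AR_norm")
  expect_error(da_params(bogus = 1), "unknown")
})

test_that("trajectory export has the expected tidy shape", {
  ev <- list(rpe_event("reward", 1, onset = 0.1),
             rpe_event("punishment", onset = 0.6))
  tr <- da_simulate(p_ctrl, ev, t_end = 1)
  expect_named(tr, c("t", "C_DA", "AR", "D1", "D2"))
  expect_true(all(tr$C_DA >= 0))
  # the punishment window [0.7, 0.75] is clamped to zero
  expect_true(all(tr$C_DA[tr$t > 0.701 & tr$t < 0.749] == 0))
})
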