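test_that("velocity profile obeys volume continuity", {
  p <- velocity_profile(0.25, Q = 0.25)
  expect_equal(p$v, 4 * 0.25 / (pi * 0.0625), tolerance = 1e-12)
  d <- seq(0.3, 0.8, by = 0.05)
  pr <- velocity_profile(d, Q = 0.25)
  expect_equal(pr$v * pr$A, rep(0.25, length(d)), tolerance = 1e-9)
  # halving the diameter quadruples the velocity
  expect_equal(velocity_profile(0.2, 1)$v / velocity_profile(0.4, 1)$v, 4)
  expect_error(velocity_profile(0, 0.25), "d")
})

test_that("strain rate: numeric and closed forms agree", {
  s <- seq(0, 8, length.out = 2000)
  d0 <- 0.8; d_inf <- 0.3; s_c <- 3; Q <- 0.25
  d <- d_inf + (d0 - d_inf) * exp(-s / s_c)
  prof <- velocity_profile(d, Q)
  num <- strain_rate(prof, s)
  cf <- strain_rate_closed_form(s, d0, d_inf, s_c, Q)
  inner <- 2:(length(s) - 1)
  expect_equal(num[inner], cf[inner], tolerance = 1e-6)
  expect_true(all(cf > 0))                      # thinning profile stretches
  expect_equal(strain_rate(velocity_profile(rep(0.5, 10), 1), 1:10),
               rep(0, 10), tolerance = 1e-12)
})

test_that("diameter-profile fit recovers the exponential decay", {
  cond <- default_conditions()
  g0 <- gen_trajectory(cond, d0 = 0.8, d_inf = 0.3, s_c = 3, noise_px = 0)
  f0 <- fit_diameter_profile(g0$traj)
  expect_equal(f0$d0, 0.8, tolerance = 1e-6)
  expect_equal(f0$d_inf, 0.3, tolerance = 1e-6)
  expect_equal(f0$s_c, 3, tolerance = 1e-6)
  # 1-px noise (0.025 mm): parameters within 5%
  g1 <- gen_trajectory(cond, noise_px = 1, seed = 8)
  f1 <- fit_diameter_profile(g1$traj)
  expect_lt(abs(f1$d0 / 0.8 - 1), 0.05)
  expect_lt(abs(f1$s_c / 3 - 1), 0.05)
  # increasing profile flagged as non-decaying
  tr <- strut_trajectory(s = 0:9, x = 0:9, alpha = rep(0.2, 10),
                         d = seq(0.3, 0.8, length.out = 10))
  expect_warning(fit_diameter_profile(tr), "non-decaying")
})

test_that("pitch-angle fit returns the exact slope on linear data", {
  x <- seq(0, 5, length.out = 30)
  tr <- strut_trajectory(s = x * 1.02, x = x, alpha = 0.1 + 0.08 * x,
                         d = seq(0.8, 0.4, length.out = 30))
  pf <- suppressWarnings(fit_pitch_angle(tr))
  expect_equal(pf$m, 0.08, tolerance = 1e-10)
  # noisy pitch angle, sigma = 0.5 deg over >= 20 points: slope within 5%
  set.seed(12)
  tr2 <- strut_trajectory(s = x * 1.02, x = x,
                          alpha = 0.1 + 0.08 * x + rnorm(30, 0, 0.5 * pi / 180),
                          d = seq(0.8, 0.4, length.out = 30))
  expect_lt(abs(fit_pitch_angle(tr2)$m / 0.08 - 1), 0.05)
})

test_that("viscous regime selection finds the diameter minimum", {
  s <- seq(0, 8, length.out = 81)
  d <- 0.4 + 0.05 * (s - 4)^2 / 16            # parabola, minimum at s = 4
  tr <- strut_trajectory(s, s, rep(0.3, 81), d)
  reg <- select_viscous_regime(tr)
  expect_lt(abs(reg[2] - 4), 0.2)              # within a grid step
  expect_equal(reg[1], tr$s[3])                # after the 2-point exclusion
  # monotone decreasing: regime extends to the last point
  trd <- strut_trajectory(s, s, rep(0.3, 81), 0.3 + 0.5 * exp(-s / 3))
  expect_equal(select_viscous_regime(trd)[2], max(s))
  # monotone increasing: no stretching regime
  tri <- strut_trajectory(s, s, rep(0.3, 81), 0.3 + 0.05 * s)
  expect_error(select_viscous_regime(tri), "regime")
})

test_that("noiseless pipeline reproduces the analytic viscosity curve", {
  cond <- default_conditions(gamma = 0.01)
  g <- gen_trajectory(cond, d0 = 0.8, d_inf = 0.4, s_c = 3, alpha0 = 0.1,
                      m = 0.02, s_max = 8, noise_px = 0)
  reg <- select_viscous_regime(g$traj)
  dfit <- fit_diameter_profile(g$traj, reg)
  pfit <- suppressWarnings(fit_pitch_angle(g$traj, reg))
  cv <- elongational_viscosity(g$traj, dfit, pfit, cond, regime = reg)
  truth <- approx(g$truth$eta_true$s, g$truth$eta_true$eta_E, cv$s)$y
  expect_equal(cv$eta_E, truth, tolerance = 1e-6)
  expect_true(all(cv$eta_E > 0))
})

test_that("surface-tension term reduces to the gamma = 0 force balance", {
  cond0 <- default_conditions(gamma = 0)
  g <- gen_trajectory(cond0, noise_px = 0)
  reg <- select_viscous_regime(g$traj)
  dfit <- fit_diameter_profile(g$traj, reg)
  pfit <- suppressWarnings(fit_pitch_angle(g$traj, reg))
  with_g <- elongational_viscosity(g$traj, dfit, pfit, cond0,
                                   include_gamma = TRUE, regime = reg)
  without <- elongational_viscosity(g$traj, dfit, pfit, cond0,
                                    include_gamma = FALSE, regime = reg)
  expect_identical(with_g$eta_E, without$eta_E)
})

test_that("axis = s and axis = x formulations agree for a linear pitch angle", {
  cond <- default_conditions()
  g <- gen_trajectory(cond, noise_px = 0)
  reg <- select_viscous_regime(g$traj)
  dfit <- fit_diameter_profile(g$traj, reg)
  pfit <- suppressWarnings(fit_pitch_angle(g$traj, reg))
  cx <- elongational_viscosity(g$traj, dfit, pfit, cond, axis = "x", regime = reg)
  cs <- elongational_viscosity(g$traj, dfit, pfit, cond, axis = "s", regime = reg)
  expect_equal(cs$eta_E, cx$eta_E, tolerance = 1e-6)
})

test_that("viscosity is linear in the gravity loading (gamma = 0)", {
  cond1 <- default_conditions()
  cond2 <- print_conditions(v_p = 5, Q = 0.25, density = 2000, gamma = 0)
  g <- gen_trajectory(cond1, noise_px = 0)
  reg <- select_viscous_regime(g$traj)
  dfit <- fit_diameter_profile(g$traj, reg)
  pfit <- suppressWarnings(fit_pitch_angle(g$traj, reg))
  c1 <- elongational_viscosity(g$traj, dfit, pfit, cond1, regime = reg)
  c2 <- elongational_viscosity(g$traj, dfit, pfit, cond2, regime = reg)
  expect_equal(c2$eta_E / c1$eta_E, rep(2, nrow(c1)), tolerance = 1e-12)
})

test_that("a flat pitch angle surfaces a physical-validity error", {
  cond <- default_conditions()
  g <- gen_trajectory(cond, noise_px = 0)
  reg <- select_viscous_regime(g$traj)
  dfit <- fit_diameter_profile(g$traj, reg)
  expect_error(elongational_viscosity(g$traj, dfit, list(m = 0), cond,
                                      regime = reg), "m <= 0")
})

test_that("trajectory CSV round-trips with degree conversion", {
  g <- gen_trajectory(default_conditions(), noise_px = 0)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(g$traj, f)
  tr <- read_trajectory_csv(f)
  expect_equal(tr$alpha, g$traj$alpha, tolerance = 1e-9)
  expect_equal(tr$d, g$traj$d, tolerance = 1e-9)
})
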