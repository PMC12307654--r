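test_that("compute_msd equals the brute-force all-pairs average exactly", {
  cfg <- simulation_config(seed = 31, n_particles = 6, n_frames = 50,
                           dt = 0.02)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 0.7))
  m <- compute_msd(traj, max_lag_fraction = 0.25)
  expect_equal(m$msd, brute_force_msd(traj, nrow(m)), tolerance = 1e-12)
})

test_that("closed-form trajectories give their exact MSDs", {
  dt <- 0.1
  # stationary particle
  still <- trajectory_ensemble(
    data.frame(particle = 1L, frame = 0:19, t_s = (0:19) * dt,
               x_um = 1, y_um = 2), dt = dt)
  expect_equal(compute_msd(still)$msd, rep(0, 4))
  # ballistic drift x = v t with v = 1 um/s: msd(tau) = tau^2 exactly
  drift <- trajectory_ensemble(
    data.frame(particle = 1L, frame = 0:40, t_s = (0:40) * dt,
               x_um = (0:40) * dt, y_um = 0), dt = dt)
  m <- compute_msd(drift)
  expect_equal(m$msd, m$lag^2, tolerance = 1e-12)
})

test_that("non-uniform sampling is rejected", {
  df <- data.frame(particle = 1L, frame = c(0L, 1L, 5L), t_s = c(0, 1, 5),
                   x_um = 0, y_um = 0)
  expect_error(compute_msd(trajectory_ensemble(df, dt = 1)), "non-uniform")
})

test_that("fit_powerlaw is exact on a pure power law", {
  tau <- exp(seq(log(0.02), log(1), length.out = 20))
  fit <- fit_powerlaw(msd_curve(tau, 4 * 0.5 * tau^0.8),
                      window = c(0.02, 1))
  expect_equal(fit$alpha, 0.8, tolerance = 1e-10)
  expect_equal(fit$D_app, 0.5, tolerance = 1e-10)
  expect_equal(fit$alpha_local, rep(0.8, 20), tolerance = 1e-8)
  expect_error(fit_powerlaw(msd_curve(tau[1:4], c(0, 1, 2, 3))), "zero")
})

test_that("the diffusive exponent of Brownian motion is Fickian (alpha = 1)", {
  cfg <- simulation_config(seed = 32, n_particles = 1000, n_frames = 200,
                           dt = 0.02)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 1))
  m <- compute_msd(traj)
  fit <- fit_powerlaw(m)
  expect_equal(fit$alpha, 1, tolerance = 0.05)
  expect_equal(m$msd[1:10] / m$lag[1:10], rep(4, 10), tolerance = 0.02)
})

test_that("fBm ensembles recover their exponents within 0.05 at 500 tracks", {
  for (a in c(0.3, 0.8054)) {
    cfg <- simulation_config(seed = 33, n_particles = 500, n_frames = 200,
                             dt = 0.02)
    traj <- simulate_trajectories(
      cfg, motion_model("subdiffusive", alpha_true = a, K = 0.5))
    fit <- fit_powerlaw(compute_msd(traj), window = c(0.1, 1))
    expect_equal(fit$alpha, a, tolerance = 0.05)
  }
})

test_that("GSER recovers the Stokes-Einstein viscosity on a Newtonian oracle", {
  a <- 0.1; Tk <- 298.15
  tau <- exp(seq(log(0.02), log(1), length.out = 30))
  D <- stokes_einstein_D(eta = 1, a_um = a, T = Tk)
  m <- msd_curve(tau, 4 * D * tau)
  fit <- fit_powerlaw(m, window = range(tau))
  g <- gser_moduli(m, fit, gser_params(a, Tk))
  expect_equal(g$G_loss / g$omega, rep(1, 30), tolerance = 0.01)
  expect_lt(max(abs(g$G_storage)), 1e-10)
  # frequency grid is exactly the reciprocal lag grid
  expect_equal(sort(g$omega), sort(1 / tau), tolerance = 1e-12)
})

test_that("GSER elastic and viscous limits are exact", {
  a <- 0.1; Tk <- 298.15; kB <- 1.380649e-23
  tau <- exp(seq(log(0.02), log(1), length.out = 10))
  # plateaued MSD (alpha = 0): pure storage, G' = 2kBT/(3 pi a msd0)
  msd0 <- 0.01
  m <- msd_curve(tau, rep(msd0, 10))
  fit <- fit_powerlaw(m, window = range(tau))
  # local alpha hovers at 0 up to rounding; the clamp announces itself
  expect_warning(g <- gser_moduli(m, fit, gser_params(a, Tk)), "clamped")
  expect_equal(g$G_loss, rep(0, 10), tolerance = 1e-12)
  expect_equal(g$G_storage,
               rep(2 * kB * Tk / (3 * pi * a * 1e-6 * msd0 * 1e-12), 10),
               tolerance = 1e-9)
  # alpha = 1 exactly: phase pi/2, no storage
  m1 <- msd_curve(tau, 4 * tau)
  g1 <- gser_moduli(m1, fit_powerlaw(m1, window = range(tau)),
                    gser_params(a, Tk))
  expect_lt(max(abs(g1$G_storage / g1$G_loss)), 1e-8)
})

test_that("literal GSER mode differs from the default by exactly 3*pi", {
  tau <- exp(seq(log(0.02), log(1), length.out = 10))
  m <- msd_curve(tau, 4 * 0.3 * tau^0.7)
  fit <- fit_powerlaw(m, window = range(tau))
  g_def <- gser_moduli(m, fit, gser_params(prefactor_mode = "stokes_einstein_consistent"))
  g_lit <- gser_moduli(m, fit, gser_params(prefactor_mode = "literal"))
  expect_equal(g_lit$G_loss, 3 * pi * g_def$G_loss, tolerance = 1e-12)
  expect_equal(g_lit$G_storage, 3 * pi * g_def$G_storage, tolerance = 1e-12)
})

test_that("find_crossover locates the Maxwell relaxation time within 2%", {
  for (tau_c in c(0.1, 1, 10)) {
    st <- find_crossover(maxwell_moduli(G = 1, tau = tau_c))
    expect_equal(st$state, "maxwell")
    expect_equal(st$tau_c, tau_c, tolerance = 0.02)
    expect_equal(st$omega_c * st$tau_c, 1, tolerance = 1e-9)
  }
})

test_that("pure viscous and pure elastic moduli are classified as such", {
  omega <- exp(seq(log(0.1), log(100), length.out = 20))
  visc <- find_crossover(moduli_curve(omega, rep(1e-12, 20), 1 * omega))
  expect_equal(visc$state, "viscous")
  expect_true(is.na(visc$omega_c))
  elas <- find_crossover(moduli_curve(omega, rep(1, 20), rep(0.1, 20)))
  expect_equal(elas$state, "elastic")
})

test_that("time-course classification flags non-monotone aging paths", {
  expect_true(classify_timecourse(list("viscous", "maxwell", "elastic"))$consistent)
  expect_true(classify_timecourse(list("viscous"))$consistent)
  expect_false(classify_timecourse(list("elastic", "viscous"))$consistent)
  expect_true(classify_timecourse(list("viscous", "viscous", "elastic"))$consistent)
})
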