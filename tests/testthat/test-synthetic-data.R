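test_that("Brownian generator matches the analytic 4*D*tau MSD at large n", {
  cfg <- simulation_config(seed = 11, n_particles = 10000, n_frames = 200,
                           dt = 0.02)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 1))
  m <- compute_msd(traj)
  expect_equal(m$msd[1], 4 * 1 * 0.02, tolerance = 0.02)
  # per-axis increments are i.i.d. Gaussian with variance 2*D*dt: check the
  # empirical variance within 3 standard errors
  x <- matrix(traj$x_um, nrow = cfg$n_frames)
  incr <- diff(x)
  v <- 2 * 1 * 0.02
  se <- v * sqrt(2 / (length(incr) - 1))
  expect_lt(abs(var(as.vector(incr)) - v), 3 * se)
})

test_that("motionless particles give identically zero MSD", {
  cfg <- simulation_config(seed = 1, n_particles = 5, n_frames = 50,
                           dt = 0.02)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 0))
  expect_equal(compute_msd(traj)$msd, rep(0, 12))
})

test_that("subdiffusive generator reproduces the target log-log slope", {
  cfg <- simulation_config(seed = 12, n_particles = 10000, n_frames = 200,
                           dt = 0.02)
  traj <- simulate_trajectories(
    cfg, motion_model("subdiffusive", alpha_true = 0.5, K = 0.5))
  fit <- fit_powerlaw(compute_msd(traj), window = c(0.1, 1))
  expect_equal(fit$alpha, 0.5, tolerance = 0.05)
})

test_that("Jeffreys generator matches its analytic MSD pointwise within 5%", {
  model <- motion_model("jeffreys", D_free = 0.005, plateau = 0.01,
                        tau_relax = 0.005)
  cfg <- simulation_config(seed = 13, n_particles = 10000, n_frames = 200,
                           dt = 0.02)
  m <- compute_msd(simulate_trajectories(cfg, model))
  expect_lt(max(abs(m$msd - msd_theoretical(model, m$lag)) /
                  msd_theoretical(model, m$lag)), 0.05)
})

test_that("localization noise inflates the MSD by the constant 4*sd^2", {
  model <- motion_model("newtonian", D = 0.5)
  cfg0 <- simulation_config(seed = 14, n_particles = 3000, n_frames = 100,
                            dt = 0.02, localization_noise_sd = 0)
  cfg1 <- simulation_config(seed = 14, n_particles = 3000, n_frames = 100,
                            dt = 0.02, localization_noise_sd = 0.05)
  m0 <- compute_msd(simulate_trajectories(cfg0, model))
  m1 <- compute_msd(simulate_trajectories(cfg1, model))
  offset <- mean(m1$msd - m0$msd)
  expect_equal(offset, 4 * 0.05^2, tolerance = 0.05)
  expect_equal(msd_theoretical(model, 1, localization_noise_sd = 0.05) -
                 msd_theoretical(model, 1), 4 * 0.05^2)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 99, n_particles = 10, n_frames = 30,
                           dt = 0.02)
  model <- motion_model("subdiffusive", alpha_true = 0.7, K = 0.2)
  expect_identical(simulate_trajectories(cfg, model),
                   simulate_trajectories(cfg, model))
  tr <- simulate_tht(0, 1, 1, 10, seq(0, 24, 1), noise_sd = 0.05, seed = 3)
  expect_identical(tr, simulate_tht(0, 1, 1, 10, seq(0, 24, 1),
                                    noise_sd = 0.05, seed = 3))
})

test_that("invalid generator parameters are rejected naming the field", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(bead_radius = -1), "bead_radius")
  expect_error(motion_model("subdiffusive", alpha_true = 1.2, K = 1),
               "superdiffusion")
  expect_error(motion_model("subdiffusive", alpha_true = 0, K = 1),
               "alpha_true")
  expect_error(simulate_tht(1, 0.5, 1, 10, 0:10), "Imax")
  expect_error(simulate_tht(0, 1, 1, 10, c(0, 0, 1)), "increasing")
  expect_error(simulate_kinetics(20, 40, 1, numeric(0), 0:10), "S_grid")
  expect_error(frap_ground_truth(1.5, 1), "F_m_true")
})

test_that("FRAP generator limits behave as designed", {
  # full recovery, no drift: trace reaches pre-bleach level
  rec <- simulate_frap(frap_ground_truth(1, 0.5), n_pre = 3, n_post = 60,
                       dt = 0.1, seed = 1)
  t_post <- rec$t[rec$bleach_frame:length(rec$t)] -
    rec$t[rec$bleach_frame]
  expect_gte(rec$roi[rec$bleach_frame:length(rec$t)][t_post >= 5][1], 0.99)
  # fully immobile: post-bleach trace constant at I_min
  rec0 <- simulate_frap(frap_ground_truth(0, 3, bleach_depth = 0.8),
                        n_pre = 3, n_post = 20, dt = 0.5, seed = 1)
  post <- rec0$roi[rec0$bleach_frame:length(rec0$roi)]
  expect_equal(post, rep(post[1], length(post)))
})

test_that("ThT generator hits the sigmoid midpoint and lower asymptote", {
  s <- simulate_tht(I0 = 2, Imax = 8, k = 1.5, t_half = 10,
                    t_grid = c(10 - 20 / 1.5, 10, 30), noise_sd = 0, seed = 1)
  expect_equal(s$intensity[2], (2 + 8) / 2)
  expect_lt(abs(s$intensity[1] - 2), 1e-4)
})

test_that("kinetics generator obeys half-saturation and saturation limits", {
  kd <- simulate_kinetics(20, 40, 1, S_grid = c(40, 40000),
                          t_grid = seq(0, 1, 0.1), noise_sd = 0, seed = 1)
  v_half <- initial_rate(kd$t_min, kd$conc[, 1], window = 1)
  v_sat <- initial_rate(kd$t_min, kd$conc[, 2], window = 1)
  expect_equal(v_half, 20 * 1 / 2, tolerance = 1e-9)
  expect_lt(abs(v_sat - 20 * 1) / (20 * 1), 0.001)
})

test_that("trajectory CSV round trip preserves the ensemble", {
  cfg <- simulation_config(seed = 21, n_particles = 4, n_frames = 20,
                           dt = 0.02)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_equal(back$x_um, traj$x_um, tolerance = 1e-12)
  expect_equal(attr(back, "dt"), attr(traj, "dt"), tolerance = 1e-9)
})

test_that("FRAP record CSV + sidecar round trip is faithful", {
  rec <- simulate_frap(frap_ground_truth(0.6, 1.5, 0.02, noise_sd = 0.01),
                       n_pre = 4, n_post = 30, dt = 0.5, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_record(rec, path)
  back <- read_frap_record(path)
  expect_equal(back$roi, rec$roi, tolerance = 1e-12)
  expect_identical(back$bleach_frame, rec$bleach_frame)
  expect_equal(back$bleach_radius, rec$bleach_radius)
})
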