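make_static_stack <- function(positions_um, cfg, snr = Inf,
                              dim_px = c(64L, 64L), n_frames = 1L) {
  df <- do.call(rbind, lapply(seq_len(nrow(positions_um)), function(i) {
    data.frame(particle = i, frame = 0:(n_frames - 1L),
               t_s = (0:(n_frames - 1L)) * cfg$dt,
               x_um = positions_um[i, 1], y_um = positions_um[i, 2])
  }))
  traj <- trajectory_ensemble(df, dt = cfg$dt, pixel_size = cfg$pixel_size)
  render_frames(traj, psf_sigma = 0.15, snr = snr, cfg, dim_px = dim_px)
}

test_that("a noiseless Gaussian spot is localized to sub-pixel accuracy", {
  cfg <- simulation_config(seed = 1, n_particles = 1, n_frames = 2,
                           dt = 0.02, pixel_size = 0.1)
  st <- make_static_stack(cbind(1.03, 2.07), cfg)
  locs <- detect_spots(st, spot_sigma = 1.5, threshold_sd = 5)
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$x - 10.3), 0.05)
  expect_lt(abs(locs$y - 20.7), 0.05)
  # the raw frame's intensity-weighted centroid agrees (noiseless)
  cen <- frame_intensity_centroid(st$frames[[1]])
  expect_lt(abs(cen["x"] - 10.3), 0.01)
  expect_lt(abs(cen["y"] - 20.7), 0.01)
})

test_that("pure background yields zero localizations", {
  cfg <- simulation_config(seed = 2, n_particles = 1, n_frames = 3,
                           dt = 0.02, pixel_size = 0.1)
  empty <- trajectory_ensemble(
    data.frame(particle = integer(), frame = integer(), t_s = numeric(),
               x_um = numeric(), y_um = numeric()),
    dt = cfg$dt, pixel_size = cfg$pixel_size)
  st <- render_frames(empty, psf_sigma = 0.15, snr = 10, cfg,
                      dim_px = c(64L, 64L))
  expect_equal(length(st$frames), 3L)
  expect_equal(nrow(detect_spots(st, 1.5)), 0L)
  # background mean close to the configured level
  expect_equal(mean(st$frames[[1]]), 100, tolerance = 0.02)
})

test_that("two well-separated spots give exactly two localizations", {
  cfg <- simulation_config(seed = 3, n_particles = 2, n_frames = 2,
                           dt = 0.02, pixel_size = 0.1)
  st <- make_static_stack(rbind(c(2, 2), c(4.5, 4.5)), cfg)  # 35 px > 10 sigma
  locs <- detect_spots(st, spot_sigma = 1.5, threshold_sd = 5)
  expect_equal(nrow(locs[locs$frame == 0, ]), 2L)
})

test_that("particles leaving the field of view are rejected by name", {
  cfg <- simulation_config(seed = 4, n_particles = 1, n_frames = 2,
                           dt = 0.02, pixel_size = 0.1)
  df <- data.frame(particle = 1L, frame = 0:1, t_s = c(0, 0.02),
                   x_um = c(1, 12), y_um = c(1, 1))
  traj <- trajectory_ensemble(df, dt = 0.02, pixel_size = 0.1)
  expect_error(render_frames(traj, 0.15, 10, cfg, dim_px = c(64L, 64L)),
               "particle 1")
})

test_that("well-separated particles link into full tracks with no swap", {
  # two particles far apart, small motion: identity must be preserved
  locs <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, x = c(10 + 0.3 * f, 40 - 0.3 * f),
               y = c(10, 40), intensity = 1)
  }))
  tr <- link_trajectories(locs, linking_params(2, 0, 5), 0.1, 0.02)
  expect_equal(length(unique(tr$particle)), 2L)
  expect_true(all(table(tr$particle) == 10L))
  p1 <- tr[tr$particle == 1L, ]
  expect_equal(diff(range(p1$y_um)), 0)  # no identity swap across tracks
})

test_that("memory = 1 bridges a single missing detection", {
  locs <- do.call(rbind, lapply(0:9, function(f) {
    if (f == 5) return(NULL)
    data.frame(frame = f, x = 10 + 0.2 * f, y = 20, intensity = 1)
  }))
  tr <- link_trajectories(locs, linking_params(2, 1, 5), 0.1, 0.02)
  expect_equal(length(unique(tr$particle)), 1L)
  expect_equal(sort(tr$frame), 0:9)  # gap frame interpolated
  expect_equal(tr$x_um[tr$frame == 5], 0.1 * (10 + 0.2 * 5), tolerance = 1e-9)
})

test_that("conflicting assignments equal the brute-force minimum-cost matching", {
  # two particles approach within max_displacement: greedy nearest-neighbor
  # would swap; the global matching must not
  prev <- rbind(c(10, 10), c(13, 10))
  cur <- rbind(c(11.4, 10), c(13.5, 10))
  cost <- outer(prev[, 1], cur[, 1], "-")^2 + outer(prev[, 2], cur[, 2], "-")^2
  cost[cost > 2.5^2] <- Inf
  oracle <- brute_force_matching(cost)
  locs <- data.frame(frame = rep(0:1, each = 2),
                     x = c(prev[, 1], cur[, 1]),
                     y = c(prev[, 2], cur[, 2]), intensity = 1)
  tr <- link_trajectories(locs, linking_params(2.5, 0, 2), 1, 1)
  # reconstruct the implied assignment from the linked tracks
  got <- vapply(1:2, function(j) {
    hit <- tr[tr$frame == 1 & abs(tr$x_um - cur[j, 1]) < 1e-9, "particle"]
    p0 <- tr[tr$particle == hit & tr$frame == 0, ]
    which(abs(prev[, 1] - p0$x_um) < 1e-9)
  }, 0L)
  expect_equal(got, oracle)
  # per-frame uniqueness invariant
  expect_false(any(duplicated(tr[c("particle", "frame")])))
})

test_that("random conflict instances match the exhaustive matching oracle", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    prev <- cbind(runif(m, 0, 10), runif(m, 0, 10))
    cur <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    cost <- outer(prev[, 1], cur[, 1], "-")^2 +
      outer(prev[, 2], cur[, 2], "-")^2
    cost[cost > 16] <- Inf
    oracle <- brute_force_matching(cost)
    got <- condensage:::.best_matching(cost)
    # same cardinality and same total cost (assignments may tie)
    expect_equal(sum(!is.na(got)), sum(!is.na(oracle)))
    tc <- function(a) sum(cost[cbind(a[!is.na(a)], which(!is.na(a)))])
    expect_equal(tc(got), tc(oracle), tolerance = 1e-12)
  }
})

test_that("the full tracking front-end reproduces the true MSD", {
  cfg <- simulation_config(seed = 7, n_particles = 9, n_frames = 150,
                           dt = 0.02, pixel_size = 0.1)
  traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 0.02))
  grid <- expand.grid(x = c(3.2, 6.4, 9.6), y = c(3.2, 6.4, 9.6))
  traj$x_um <- traj$x_um + grid$x[traj$particle]
  traj$y_um <- traj$y_um + grid$y[traj$particle]
  st <- render_frames(traj, psf_sigma = 0.15, snr = 10, cfg,
                      dim_px = c(128L, 128L))
  locs <- detect_spots(st, spot_sigma = 1.5, threshold_sd = 5)
  # detection: 9 +/- 0 spots per frame, localization RMSE < 0.2 px
  expect_true(all(table(locs$frame) == 9L))
  d0 <- locs[locs$frame == 0, ]; t0 <- traj[traj$frame == 0, ]
  err2 <- vapply(seq_len(nrow(t0)), function(k) {
    min((d0$x * 0.1 - t0$x_um[k])^2 + (d0$y * 0.1 - t0$y_um[k])^2)
  }, 0)
  expect_lt(sqrt(mean(err2)) / 0.1, 0.2)
  tl <- link_trajectories(locs, linking_params(5, 1, 50), 0.1, 0.02)
  # track count never exceeds the per-frame localization maximum
  expect_lte(length(unique(tl$particle)), max(table(locs$frame)))
  m_true <- compute_msd(traj)
  m_det <- compute_msd(tl)
  i <- 1:12
  offset <- mean(m_det$msd[i] - m_true$msd[i])  # localization-noise floor
  expect_gt(offset, 0)
  expect_lt(max(abs(m_det$msd[i] - offset - m_true$msd[i]) / m_true$msd[i]),
            0.05)
})

test_that("frame stack TIFF + sidecar round trip preserves metadata", {
  cfg <- simulation_config(seed = 9, n_particles = 1, n_frames = 3,
                           dt = 0.02, pixel_size = 0.1)
  st <- make_static_stack(cbind(3, 3), cfg, snr = 10, n_frames = 3L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, path)
  back <- read_frame_stack(path)
  expect_equal(back$pixel_size, 0.1)
  expect_equal(back$dt, 0.02)
  expect_equal(length(back$frames), 3L)
  # 16-bit quantization: relative error bounded
  expect_lt(max(abs(back$frames[[1]] - st$frames[[1]])) /
              max(st$frames[[1]]), 1 / 65000)
})
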