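#' Simulation configuration for probe-particle trajectories
#'
#' Bundles the acquisition parameters of a particle-tracking microrheology
#' experiment. Defaults mirror a typical spinning-disk acquisition: 50 frames
#' per second for 200 frames with 100 nm-radius beads at room temperature.
#'
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_particles number of probe particles.
#' @param n_frames frames per trajectory (>= 2).
#' @param dt frame interval, seconds.
#' @param pixel_size microns per pixel.
#' @param bead_radius probe bead radius, microns.
#' @param temperature absolute temperature, kelvin.
#' @param localization_noise_sd standard deviation of additive Gaussian
#'   localization noise per frame and axis, microns. Inflates the measured
#'   MSD by a constant `4 * sd^2` offset.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_particles = 100L, n_frames = 200L,
                              dt = 0.02, pixel_size = 0.1, bead_radius = 0.1,
                              temperature = 298.15,
                              localization_noise_sd = 0) {
  .assert_scalar(dt, "dt", positive = TRUE)
  .assert_scalar(bead_radius, "bead_radius", positive = TRUE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  .assert_scalar(pixel_size, "pixel_size", positive = TRUE)
  .assert_scalar(localization_noise_sd, "localization_noise_sd", min = 0)
  if (n_frames < 2) stop("'n_frames' must be >= 2", call. = FALSE)
  if (n_particles < 1) stop("'n_particles' must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames), dt = dt,
                 pixel_size = pixel_size, bead_radius = bead_radius,
                 temperature = temperature,
                 localization_noise_sd = localization_noise_sd),
            class = "simulation_config")
}

#' Probe-particle motion model
#'
#' Three generative models covering the material states a condensate traverses
#' as it ages:
#'
#' * `newtonian` — Brownian motion with diffusivity `D`; 2D MSD `4 D tau`.
#' * `subdiffusive` — fractional Brownian motion with Hurst index
#'   `alpha_true / 2` per axis; 2D MSD `4 K tau^alpha_true`
#'   (`0 < alpha_true <= 1`).
#' * `jeffreys` — free diffusion plus a saturating confinement term;
#'   2D MSD `4 D_free tau + plateau (1 - exp(-tau/tau_relax))`. Yields a
#'   single storage/loss crossover, i.e. Maxwell-fluid phenomenology.
#'
#' @param kind one of `"newtonian"`, `"subdiffusive"`, `"jeffreys"`.
#' @param D diffusivity, um^2/s (newtonian).
#' @param alpha_true anomalous exponent in (0, 1] (subdiffusive).
#' @param K generalized diffusivity, um^2/s^alpha (subdiffusive).
#' @param D_free long-time diffusivity, um^2/s (jeffreys).
#' @param plateau confinement plateau, um^2 (jeffreys).
#' @param tau_relax confinement relaxation time, s (jeffreys).
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(kind = c("newtonian", "subdiffusive", "jeffreys"),
                         D = NULL, alpha_true = NULL, K = NULL,
                         D_free = NULL, plateau = NULL, tau_relax = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    newtonian = {
      .assert_scalar(D, "D", min = 0)
      list(kind = kind, D = D)
    },
    subdiffusive = {
      .assert_scalar(K, "K", positive = TRUE)
      if (!is.numeric(alpha_true) || alpha_true <= 0)
        stop("'alpha_true' must be > 0", call. = FALSE)
      if (alpha_true > 1)
        stop("'alpha_true' must be <= 1 (superdiffusion unsupported)",
             call. = FALSE)
      list(kind = kind, alpha_true = alpha_true, K = K)
    },
    jeffreys = {
      .assert_scalar(D_free, "D_free", positive = TRUE)
      .assert_scalar(plateau, "plateau", positive = TRUE)
      .assert_scalar(tau_relax, "tau_relax", positive = TRUE)
      list(kind = kind, D_free = D_free, plateau = plateau,
           tau_relax = tau_relax)
    })
  structure(m, class = "motion_model")
}

#' Analytic ensemble MSD of a motion model
#'
#' @param model a [motion_model()].
#' @param tau lag times, seconds.
#' @param localization_noise_sd optional localization noise sd (um), adding
#'   the constant `4 sd^2` offset seen by a tracker.
#' @return 2D MSD in um^2 at each lag.
#' @export
msd_theoretical <- function(model, tau, localization_noise_sd = 0) {
  base <- switch(model$kind,
    newtonian = 4 * model$D * tau,
    subdiffusive = 4 * model$K * tau^model$alpha_true,
    jeffreys = 4 * model$D_free * tau +
      model$plateau * (1 - exp(-tau / model$tau_relax)))
  base + 4 * localization_noise_sd^2
}

# Cholesky factor of the fractional-Gaussian-noise covariance for n increments
# at spacing dt, position variance C t^{2H}. Exact but O(n^3); n ~ 200 here.
.fgn_chol <- function(n, H, C, dt) {
  k <- 0:(n - 1)
  gamma_k <- (C / 2) * dt^(2 * H) *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  Sigma <- stats::toeplitz(gamma_k)
  chol(Sigma)
}

#' Simulate probe-particle trajectories
#'
#' Draws `n_particles` 2D trajectories from the given motion model, adds
#' Gaussian localization noise, and returns them as a tidy trajectory
#' ensemble. Subdiffusive motion is sampled exactly from the fractional
#' Gaussian noise covariance (Cholesky factorization); the Jeffreys model is
#' an exactly discretized Brownian + stationary Ornstein-Uhlenbeck sum, so in
#' all three cases the ensemble MSD converges to [msd_theoretical()] as
#' `n_particles` grows.
#'
#' @param config a [simulation_config()].
#' @param model a [motion_model()].
#' @return a `trajectory_ensemble`: data frame with columns `particle`,
#'   `frame` (0-based), `t_s`, `x_um`, `y_um`; attributes `dt`, `pixel_size`
#'   and a `ground_truth` sidecar holding the generating model.
#' @examples
#' cfg <- simulation_config(seed = 7, n_particles = 20)
#' traj <- simulate_trajectories(cfg, motion_model("newtonian", D = 1))
#' head(traj)
#' @export
simulate_trajectories <- function(config, model) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(model, "motion_model"))
  set.seed(config$seed)
  n <- config$n_frames
  np <- config$n_particles
  dt <- config$dt
  inc <- n - 1L

  steps <- switch(model$kind,
    newtonian = {
      sd_step <- sqrt(2 * model$D * dt)
      list(x = matrix(rnorm(inc * np, sd = sd_step), inc, np),
           y = matrix(rnorm(inc * np, sd = sd_step), inc, np))
    },
    subdiffusive = {
      # per-axis fBm with Var B(t) = 2 K t^alpha  =>  2D MSD = 4 K tau^alpha
      L <- .fgn_chol(inc, H = model$alpha_true / 2, C = 2 * model$K, dt = dt)
      list(x = crossprod(L, matrix(rnorm(inc * np), inc, np)),
           y = crossprod(L, matrix(rnorm(inc * np), inc, np)))
    },
    jeffreys = {
      # Brownian + stationary OU per axis; OU variance plateau/4 per axis
      # gives the 2D confinement term plateau * (1 - exp(-tau/tau_relax)).
      s0 <- sqrt(model$plateau / 4)
      rho <- exp(-dt / model$tau_relax)
      sd_ou <- s0 * sqrt(1 - rho^2)
      sd_bm <- sqrt(2 * model$D_free * dt)
      ou_path <- function() {
        z <- matrix(rnorm(n * np), n, np)
        out <- matrix(0, n, np)
        out[1, ] <- s0 * z[1, ]
        for (i in 2:n) out[i, ] <- rho * out[i - 1, ] + sd_ou * z[i, ]
        out
      }
      ou_x <- ou_path(); ou_y <- ou_path()
      list(x = diff(ou_x) + matrix(rnorm(inc * np, sd = sd_bm), inc, np),
           y = diff(ou_y) + matrix(rnorm(inc * np, sd = sd_bm), inc, np))
    })

  X <- rbind(0, apply(steps$x, 2, cumsum))
  Y <- rbind(0, apply(steps$y, 2, cumsum))
  if (config$localization_noise_sd > 0) {
    X <- X + matrix(rnorm(n * np, sd = config$localization_noise_sd), n, np)
    Y <- Y + matrix(rnorm(n * np, sd = config$localization_noise_sd), n, np)
  }

  df <- data.frame(particle = rep(seq_len(np), each = n),
                   frame = rep(0:(n - 1L), times = np),
                   t_s = rep((0:(n - 1L)) * dt, times = np),
                   x_um = as.vector(X), y_um = as.vector(Y))
  trajectory_ensemble(df, dt = dt, pixel_size = config$pixel_size,
                      ground_truth = list(model = model, config = config))
}

#' Construct a trajectory ensemble from a tidy table
#'
#' @param df data frame with columns `particle`, `frame`, `t_s`, `x_um`,
#'   `y_um`.
#' @param dt frame interval, seconds.
#' @param pixel_size microns per pixel (metadata only).
#' @param ground_truth optional sidecar consumed by tests.
#' @return a `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(df, dt, pixel_size = NA_real_,
                                ground_truth = NULL) {
  need <- c("particle", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(as.data.frame(df)[need], dt = dt, pixel_size = pixel_size,
            ground_truth = ground_truth,
            class = c("trajectory_ensemble", "data.frame"))
}

#' Write / read a trajectory ensemble as CSV
#'
#' Columns `particle, frame, t_s, x_um, y_um`, UTF-8, `.` decimal separator.
#'
#' @param traj a `trajectory_ensemble`.
#' @param path output CSV path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a `trajectory_ensemble`.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  ts <- sort(unique(df$t_s))
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else NA_real_
  trajectory_ensemble(df, dt = dt)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d particles, %d rows, dt = %g s\n",
              length(unique(x$particle)), nrow(x), attr(x, "dt")))
  invisible(x)
}
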