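#' Ensemble mean-squared displacement
#'
#' Computes the time-averaged MSD of each trajectory over all overlapping
#' frame pairs at each lag, then ensemble-averages across trajectories
#' weighted by pair counts. This equals the brute-force all-pairs average
#' \eqn{\langle (r(t+\tau) - r(t))^2 \rangle} exactly.
#'
#' @param traj a `trajectory_ensemble` with uniform frame spacing.
#' @param max_lag_fraction lags are retained up to this fraction of the
#'   longest track (default 0.25; time-averaged MSDs at longer lags are
#'   statistically unreliable).
#' @return an `msd_curve`: data frame with columns `lag` (s), `msd` (um^2),
#'   `n_pairs`; attribute `dt`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  .assert_scalar(max_lag_fraction, "max_lag_fraction", positive = TRUE,
                 max = 1)
  dt <- attr(traj, "dt")
  parts <- split(traj[c("frame", "t_s", "x_um", "y_um")], traj$particle)
  len <- vapply(parts, nrow, 0L)
  if (max(len) < 2L) stop("need at least one trajectory of >= 2 frames",
                          call. = FALSE)
  for (p in parts) {
    fr <- p$frame
    if (length(fr) > 1L && any(diff(fr) != diff(fr)[1L]))
      stop("non-uniform frame sampling within a trajectory", call. = FALSE)
  }
  max_lag <- max(1L, floor(max_lag_fraction * (max(len) - 1L)))
  ssum <- numeric(max_lag)
  npair <- numeric(max_lag)
  for (p in parts) {
    n <- nrow(p)
    if (n < 2L) next
    x <- p$x_um; y <- p$y_um
    for (k in seq_len(min(max_lag, n - 1L))) {
      dx <- x[(1L + k):n] - x[1L:(n - k)]
      dy <- y[(1L + k):n] - y[1L:(n - k)]
      ssum[k] <- ssum[k] + sum(dx * dx + dy * dy)
      npair[k] <- npair[k] + (n - k)
    }
  }
  keep <- npair > 0
  structure(data.frame(lag = seq_len(max_lag)[keep] * dt,
                       msd = ssum[keep] / npair[keep],
                       n_pairs = npair[keep]),
            dt = dt, max_lag_fraction = max_lag_fraction,
            class = c("msd_curve", "data.frame"))
}

#' Construct an MSD curve from lag/MSD vectors
#'
#' Used to wrap analytic or externally computed MSDs for downstream fitting.
#'
#' @param lag lag times, seconds (strictly increasing).
#' @param msd MSD values, um^2 (non-negative).
#' @param n_pairs optional pair counts per lag.
#' @return an `msd_curve`.
#' @export
msd_curve <- function(lag, msd, n_pairs = rep(1L, length(lag))) {
  if (any(diff(lag) <= 0)) stop("'lag' must be strictly increasing",
                                call. = FALSE)
  if (any(msd < 0)) stop("'msd' must be >= 0", call. = FALSE)
  structure(data.frame(lag = lag, msd = msd, n_pairs = n_pairs),
            dt = lag[1], class = c("msd_curve", "data.frame"))
}

#' Power-law fit of an MSD curve
#'
#' Estimates the diffusive exponent \eqn{\alpha(\tau) = d\ln\langle\Delta
#' r^2\rangle / d\ln\tau} two ways: a local exponent per lag from a sliding
#' quadratic fit in log-log coordinates (Mason-style smoothing, used by the
#' GSER stage), and a single long-time exponent from a global linear log-log
#' fit over `window`, whose intercept gives the apparent diffusivity through
#' \eqn{\langle\Delta r^2\rangle = 4 D_{app} \tau^\alpha}.
#'
#' @param msd an `msd_curve`.
#' @param window numeric length-2 lag range (s) for the global fit; default
#'   the first decade of available lags.
#' @param local_window odd number of points for the sliding quadratic fit
#'   (default 7).
#' @return a `powerlaw_fit`: list with `alpha`, `D_app`, `alpha_local`
#'   (one per retained lag), `fit_window`.
#' @export
fit_powerlaw <- function(msd, window = NULL, local_window = 7L) {
  stopifnot(inherits(msd, "msd_curve"))
  if (is.null(window)) window <- c(msd$lag[1], 10 * msd$lag[1])
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 4L) stop("fit window must contain >= 4 lags", call. = FALSE)
  if (any(msd$msd[sel] <= 0))
    stop("msd contains zeros inside the fit window; log fit undefined",
         call. = FALSE)
  lt <- log(msd$lag); lm_all <- log(pmax(msd$msd, .Machine$double.xmin))
  gfit <- lm(lm_all[sel] ~ lt[sel])
  alpha <- unname(coef(gfit)[2])
  D_app <- exp(unname(coef(gfit)[1])) / 4

  # local alpha(tau): derivative of a quadratic in log-log over a sliding
  # window, evaluated at the centre point; windows are clipped at the edges
  n <- nrow(msd)
  h <- (local_window - 1L) %/% 2L
  alpha_local <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (hi - lo + 1L < 3L) { lo <- max(1L, hi - 2L); hi <- min(n, lo + 2L) }
    xi <- lt[lo:hi]; yi <- lm_all[lo:hi]
    cf <- coef(lm(yi ~ xi + I(xi^2)))
    unname(cf[2] + 2 * cf[3] * lt[i])
  }, 0)

  structure(list(alpha = alpha, D_app = D_app, alpha_local = alpha_local,
                 fit_window = window, lag = msd$lag),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law MSD fit: alpha = %.4f, D_app = %.4g um^2/s^alpha (window %g-%g s)\n",
              x$alpha, x$D_app, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' GSER parameters
#'
#' @param bead_radius probe radius, microns.
#' @param temperature kelvin.
#' @param prefactor_mode `"stokes_einstein_consistent"` (default) uses
#'   \eqn{|G^*| = 2 k_B T / (3\pi a \langle\Delta r^2\rangle \Gamma[1+\alpha])},
#'   which recovers Stokes-Einstein exactly for a Newtonian fluid with a 2D
#'   MSD; `"literal"` drops the \eqn{3\pi}, i.e.
#'   \eqn{|G^*| = 2 k_B T / (a \langle\Delta r^2\rangle \Gamma[1+\alpha])}.
#' @return a `gser_params` object.
#' @export
gser_params <- function(bead_radius = 0.1, temperature = 298.15,
                        prefactor_mode = c("stokes_einstein_consistent",
                                           "literal")) {
  .assert_scalar(bead_radius, "bead_radius", positive = TRUE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  structure(list(bead_radius = bead_radius, temperature = temperature,
                 kB = .kB, prefactor_mode = match.arg(prefactor_mode)),
            class = "gser_params")
}

#' Viscoelastic moduli from an MSD curve (generalized Stokes-Einstein)
#'
#' Evaluates the complex shear modulus at \eqn{\omega = 1/\tau}:
#' \deqn{G^*(\omega) = \frac{2 k_B T \, e^{i\pi\alpha(\omega)/2}}
#'   {C \, a \, \langle\Delta r^2(1/\omega)\rangle \, \Gamma[1+\alpha(\omega)]}}
#' so that \eqn{G' = |G^*|\cos(\pi\alpha/2)} and
#' \eqn{G'' = |G^*|\sin(\pi\alpha/2)}, with `C = 3*pi` in the default
#' Stokes-Einstein-consistent mode and `C = 1` in literal mode. The local
#' exponent is clamped to `[0, 1]` before use (subdiffusive regime); MSD and
#' radius are converted to metres so moduli come out in pascals.
#'
#' @param msd an `msd_curve`.
#' @param fit a `powerlaw_fit` on the same curve (supplies `alpha_local`).
#' @param params a [gser_params()].
#' @return a `moduli_curve`: data frame with `omega` (rad/s, increasing),
#'   `G_storage`, `G_loss` (Pa), `alpha_at_omega`.
#' @export
gser_moduli <- function(msd, fit, params = gser_params()) {
  stopifnot(inherits(msd, "msd_curve"), inherits(fit, "powerlaw_fit"),
            inherits(params, "gser_params"))
  if (length(fit$alpha_local) != nrow(msd))
    stop("'fit' does not match 'msd': alpha_local length differs",
         call. = FALSE)
  keep <- msd$msd > 0
  if (any(!keep))
    warning(sum(!keep), " lag(s) with zero MSD dropped from moduli")
  alpha <- fit$alpha_local[keep]
  if (any(alpha < 0))
    warning("negative local alpha clamped to 0 at ",
            sum(alpha < 0), " lag(s)")
  alpha <- pmin(pmax(alpha, 0), 1)
  tau <- msd$lag[keep]
  msd_m2 <- msd$msd[keep] * 1e-12          # um^2 -> m^2
  a_m <- params$bead_radius * 1e-6          # um -> m
  C <- if (params$prefactor_mode == "stokes_einstein_consistent") 3 * pi else 1
  Gmag <- 2 * params$kB * params$temperature /
    (C * a_m * msd_m2 * gamma(1 + alpha))
  phase <- pi * alpha / 2
  ord <- order(1 / tau)
  structure(data.frame(omega = (1 / tau)[ord],
                       G_storage = (Gmag * cos(phase))[ord],
                       G_loss = (Gmag * sin(phase))[ord],
                       alpha_at_omega = alpha[ord]),
            params = params, class = c("moduli_curve", "data.frame"))
}

#' Construct a moduli curve from raw vectors
#'
#' @param omega angular frequencies, rad/s (strictly increasing).
#' @param G_storage,G_loss storage and loss moduli, Pa.
#' @return a `moduli_curve`.
#' @export
moduli_curve <- function(omega, G_storage, G_loss) {
  if (any(diff(omega) <= 0)) stop("'omega' must be strictly increasing",
                                  call. = FALSE)
  structure(data.frame(omega = omega, G_storage = G_storage,
                       G_loss = G_loss,
                       alpha_at_omega = NA_real_),
            class = c("moduli_curve", "data.frame"))
}

# 3-point running median (endpoints kept)
.med3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  for (i in 2:(n - 1L)) out[i] <- median(x[(i - 1L):(i + 1L)])
  out
}

#' Locate the storage/loss crossover and classify the material state
#'
#' Examines the sign of `log G' - log G''` (after 3-point median smoothing)
#' across frequency. All negative: the medium is viscous (loss-dominated at
#' every probed frequency). All positive: elastic. A single sign change with
#' loss dominating at low frequency: a Maxwell fluid, whose critical
#' frequency \eqn{\omega_c} (where G' = G'') is located by linear
#' interpolation of `log G' - log G''` against `log omega`, and whose
#' relaxation time is \eqn{\tau_c = 1/\omega_c}.
#'
#' @param moduli a `moduli_curve` with at least 4 frequencies.
#' @return a `material_state`: list with `state` (one of `"viscous"`,
#'   `"maxwell"`, `"elastic"`), `omega_c` and `tau_c` (`NA` unless Maxwell).
#' @export
find_crossover <- function(moduli) {
  stopifnot(inherits(moduli, "moduli_curve"))
  if (nrow(moduli) < 4L) stop("need >= 4 frequencies", call. = FALSE)
  eps <- .Machine$double.xmin
  d <- .med3(log(pmax(moduli$G_storage, eps)) -
             log(pmax(moduli$G_loss, eps)))
  lw <- log(moduli$omega)
  s <- sign(d)
  if (all(s <= 0)) return(.material_state("viscous"))
  if (all(s >= 0)) return(.material_state("elastic"))
  flips <- which(s[-1] * s[-length(s)] < 0)
  if (length(flips) > 1L)
    warning("multiple storage/loss crossings after smoothing; ",
            "using the lowest-frequency crossing")
  if (d[1] > 0) {
    # storage-dominated at low frequency: not the Maxwell pattern, but a
    # crossing exists; report it with the elastic-at-low-omega caveat
    warning("G' > G'' at the lowest frequency; crossover reported anyway")
  }
  i <- flips[1]
  w <- d[i] / (d[i] - d[i + 1])
  log_wc <- lw[i] + w * (lw[i + 1] - lw[i])
  omega_c <- exp(log_wc)
  .material_state("maxwell", omega_c = omega_c, tau_c = 1 / omega_c)
}

.material_state <- function(state, omega_c = NA_real_, tau_c = NA_real_) {
  structure(list(state = state, omega_c = omega_c, tau_c = tau_c),
            class = "material_state")
}

#' @export
print.material_state <- function(x, ...) {
  if (x$state == "maxwell")
    cat(sprintf("Material state: maxwell (omega_c = %.4g rad/s, tau_c = %.4g s)\n",
                x$omega_c, x$tau_c))
  else cat("Material state:", x$state, "\n")
  invisible(x)
}

#' Summarize a material-state time course
#'
#' Checks whether an age-ordered sequence of material states is consistent
#' with the monotone viscous -> maxwell -> elastic aging path (each state may
#' repeat or be skipped, but the order may not reverse).
#'
#' @param states list of `material_state` objects (or character states),
#'   ordered by condensate age.
#' @return list with `sequence` (character) and `consistent` (logical).
#' @export
classify_timecourse <- function(states) {
  if (length(states) < 1L) stop("need >= 1 state", call. = FALSE)
  seqs <- vapply(states, function(s) {
    if (inherits(s, "material_state")) s$state else as.character(s)
  }, "")
  rank <- c(viscous = 1L, maxwell = 2L, elastic = 3L)
  if (any(!seqs %in% names(rank)))
    stop("unknown state in sequence", call. = FALSE)
  list(sequence = seqs, consistent = !is.unsorted(rank[seqs]))
}

#' Write MSD and moduli curves as CSV
#'
#' @param msd an `msd_curve`; `moduli` a `moduli_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msd <- function(msd, path) {
  df <- data.frame(tau_s = msd$lag, msd_um2 = msd$msd, n_pairs = msd$n_pairs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @param moduli a `moduli_curve`.
#' @export
write_moduli <- function(moduli, path) {
  df <- data.frame(omega_rad_s = moduli$omega,
                   G_storage_Pa = moduli$G_storage,
                   G_loss_Pa = moduli$G_loss,
                   alpha = moduli$alpha_at_omega)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
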