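#' Simulate a thioflavin T aggregation time series
#'
#' Draws values from the sigmoid
#' \eqn{I(t) = I_0 + (I_{max} - I_0)/(1 + e^{-k (t - t_{1/2})})} plus
#' Gaussian noise. ThT fluorescence reports beta-sheet content, so this
#' emulates the aggregation kinetics of an aging condensate.
#'
#' @param I0 lower asymptote, a.u.
#' @param Imax upper asymptote, a.u. (must exceed `I0`).
#' @param k growth rate of beta-sheet content, 1/h.
#' @param t_half half-time of the fluorescence rise, h.
#' @param t_grid strictly increasing time grid, h.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed integer seed.
#' @return a `tht_series`: data frame with `t_h`, `intensity`; attribute
#'   `ground_truth`.
#' @export
simulate_tht <- function(I0, Imax, k, t_half, t_grid, noise_sd = 0,
                         seed = 1L) {
  if (Imax <= I0) stop("'Imax' must exceed 'I0'", call. = FALSE)
  .assert_scalar(k, "k", positive = TRUE)
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be non-empty and strictly increasing", call. = FALSE)
  set.seed(seed)
  mu <- I0 + (Imax - I0) / (1 + exp(-k * (t_grid - t_half)))
  structure(data.frame(t_h = t_grid,
                       intensity = mu + rnorm(length(t_grid), sd = noise_sd)),
            ground_truth = list(I0 = I0, Imax = Imax, k = k, t_half = t_half,
                                noise_sd = noise_sd),
            class = c("tht_series", "data.frame"))
}

#' Simulate Michaelis-Menten progress curves
#'
#' For each substrate concentration, produces an early-time (linear) product
#' trace with slope \eqn{v = k_{cat} E_0 S / (K_M + S)} plus noise, and the
#' matching absorbance trace through a linear standard curve
#' (`A = blank + slope * conc`).
#'
#' @param kcat turnover number, 1/min.
#' @param K_M Michaelis constant, uM.
#' @param E0 enzyme concentration, uM.
#' @param S_grid substrate concentrations, uM (non-empty).
#' @param t_grid time grid, min (non-empty).
#' @param noise_sd Gaussian noise sd on concentrations, uM.
#' @param seed integer seed.
#' @param standard_curve_slope absorbance per uM.
#' @param blank blank absorbance.
#' @return a `kinetics_dataset`: list with `t_min`, `S_grid`, `E0`, `conc`
#'   (time x substrate matrix, uM), `absorbance`, `standard_curve_slope`,
#'   `blank`; attribute `ground_truth`.
#' @export
simulate_kinetics <- function(kcat, K_M, E0, S_grid, t_grid, noise_sd = 0,
                              seed = 1L, standard_curve_slope = 0.01,
                              blank = 0.05) {
  .assert_scalar(kcat, "kcat", positive = TRUE)
  .assert_scalar(K_M, "K_M", positive = TRUE)
  .assert_scalar(E0, "E0", positive = TRUE)
  .assert_scalar(standard_curve_slope, "standard_curve_slope",
                 positive = TRUE)
  if (length(S_grid) < 1L) stop("'S_grid' must be non-empty", call. = FALSE)
  if (length(t_grid) < 1L) stop("'t_grid' must be non-empty", call. = FALSE)
  set.seed(seed)
  v <- kcat * E0 * S_grid / (K_M + S_grid)
  conc <- outer(t_grid, v) +
    matrix(rnorm(length(t_grid) * length(S_grid), sd = noise_sd),
           length(t_grid), length(S_grid))
  structure(list(t_min = t_grid, S_grid = S_grid, E0 = E0, conc = conc,
                 absorbance = blank + standard_curve_slope * conc,
                 standard_curve_slope = standard_curve_slope, blank = blank),
            ground_truth = list(kcat = kcat, K_M = K_M, E0 = E0, v = v,
                                noise_sd = noise_sd),
            class = "kinetics_dataset")
}

#' Convert absorbance to concentration via a linear standard curve
#'
#' `conc = (A - blank) / slope`; negative results are floored at zero with a
#' warning reporting how many were clipped.
#'
#' @param trace absorbance values, a.u.
#' @param slope standard-curve slope, a.u. per uM.
#' @param blank blank absorbance subtracted before conversion.
#' @return concentrations, uM.
#' @export
absorbance_to_conc <- function(trace, slope, blank = 0) {
  if (!is.numeric(slope) || slope <= 0)
    stop("'slope' must be > 0", call. = FALSE)
  conc <- (trace - blank) / slope
  n_neg <- sum(conc < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative concentration(s) floored at 0")
    conc[conc < 0] <- 0
  }
  conc
}

#' Initial reaction rate from a progress curve
#'
#' Ordinary least-squares slope of concentration against time over the early
#' window of the trace (default: the first 20\% of points, at least 3).
#'
#' @param t time, min.
#' @param conc product concentration, uM.
#' @param window either a fraction in (0, 1\] of points to use, or an
#'   integer number of points (>= 3).
#' @return initial rate, uM/min.
#' @export
initial_rate <- function(t, conc, window = 0.2) {
  stopifnot(length(t) == length(conc))
  n_use <- if (window <= 1) max(3L, ceiling(window * length(t)))
           else as.integer(window)
  if (n_use < 3L || n_use > length(t))
    stop("initial-rate window must contain >= 3 points within the trace",
         call. = FALSE)
  idx <- seq_len(n_use)
  unname(coef(lm(conc[idx] ~ t[idx]))[2])
}

#' Fit the Michaelis-Menten equation to initial rates
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)} with analytic
#' initial guesses (\eqn{V_{max}} = max observed rate, \eqn{K_M} = substrate
#' concentration at half-maximal rate); \eqn{k_{cat} = V_{max}/E_0} and
#' catalytic efficiency \eqn{k_{cat}/K_M} are derived.
#'
#' @param S substrate concentrations, uM (>= 4 points).
#' @param v initial rates, uM/min.
#' @param E0 enzyme concentration, uM.
#' @return a `menten_fit`: list with `kcat` (1/min), `K_M` (uM), `Vmax`
#'   (uM/min), `efficiency` (1/(uM min)), `rss`, `identifiable`.
#' @export
fit_menten <- function(S, v, E0) {
  stopifnot(length(S) == length(v))
  if (length(S) < 4L) stop("need >= 4 substrate points", call. = FALSE)
  .assert_scalar(E0, "E0", positive = TRUE)
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                           start = list(Vmax = vmax0, Km = max(km0, 1e-6)),
                           lower = c(.Machine$double.eps,
                                     .Machine$double.eps),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  Km <- unname(cf["Km"]); Vmax <- unname(cf["Vmax"])
  identifiable <- Km <= 100 * max(S) && Km >= min(S) / 100
  if (!identifiable)
    warning("fitted K_M lies far outside the substrate range; ",
            "parameters flagged unidentifiable")
  structure(list(kcat = Vmax / E0, K_M = Km, Vmax = Vmax,
                 efficiency = (Vmax / E0) / Km,
                 rss = sum(residuals(fit)^2), identifiable = identifiable),
            class = "menten_fit")
}

#' @export
print.menten_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit: kcat = %.4g /min, K_M = %.4g uM, kcat/K_M = %.4g /(uM min)\n",
    x$kcat, x$K_M, x$efficiency))
  invisible(x)
}

#' Relative reaction rate
#'
#' Ratio of a condensate-phase rate to its matched free-enzyme control.
#' Values above 1 mean the condensate enhances the reaction, 1 is parity,
#' below 1 impairment.
#'
#' @param rate_condensate rate measured in the condensate system.
#' @param rate_control rate of the control system (same units, > 0).
#' @return dimensionless ratio.
#' @export
relative_rate <- function(rate_condensate, rate_control) {
  if (!is.numeric(rate_control) || rate_control <= 0)
    stop("'rate_control' must be > 0", call. = FALSE)
  rate_condensate / rate_control
}

#' Fit a sigmoid to a ThT aggregation series
#'
#' Nonlinear least squares of
#' \eqn{I(t) = I_0 + (I_{max} - I_0)/(1 + e^{-k(t - t_{1/2})})}, with
#' analytic initial guesses (asymptotes from the data extremes, half-time at
#' the mid-crossing, rate from the central slope). The coefficient of
#' determination is reported as \eqn{R^2 = 1 - RSS/TSS}.
#'
#' @param series a `tht_series`, or a data frame with time in the first
#'   column and intensity in the second (>= 8 points).
#' @return a `sigmoid_fit`: list with `I0`, `Imax`, `k` (1/h), `t_half` (h),
#'   `r_squared`, `rss`.
#' @export
fit_sigmoid <- function(series) {
  t <- series[[1]]; y <- series[[2]]
  if (length(t) < 8L) stop("need >= 8 points", call. = FALSE)
  if (unname(coef(lm(y ~ t))[2]) < 0)
    stop("series is decreasing overall; sigmoid growth model not applicable",
         call. = FALSE)
  i0 <- min(y); imax <- max(y)
  mid <- (i0 + imax) / 2
  t0 <- t[which.min(abs(y - mid))]
  # central slope dI/dt ~ k (Imax - I0) / 4 at the midpoint
  span <- max(t) - min(t)
  near <- abs(t - t0) <= span / 8
  slope0 <- if (sum(near) >= 2) unname(coef(lm(y[near] ~ t[near]))[2]) else NA
  k0 <- if (is.finite(slope0) && slope0 > 0 && imax > i0)
    4 * slope0 / (imax - i0) else 1 / max(span / 10, 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ I0 + (Imax - I0) / (1 + exp(-k * (t - th))),
    start = list(I0 = i0, Imax = imax, k = k0, th = t0),
    lower = c(-Inf, -Inf, .Machine$double.eps, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(I0 = unname(cf["I0"]), Imax = unname(cf["Imax"]),
                 k = unname(cf["k"]), t_half = unname(cf["th"]),
                 r_squared = 1 - rss / tss, rss = rss),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit: I0 = %.4g, Imax = %.4g, k = %.4g /h, t_half = %.4g h, R^2 = %.4f\n",
    x$I0, x$Imax, x$k, x$t_half, x$r_squared))
  invisible(x)
}
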