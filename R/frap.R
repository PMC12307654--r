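#' Ground-truth parameters for a synthetic FRAP experiment
#'
#' @param F_m_true true mobile fraction in \[0, 1\].
#' @param tau_half_true true recovery half-time, seconds.
#' @param acquisition_bleach_rate single-exponential photobleaching rate of
#'   the imaging laser, 1/s; applied to both ROI and reference, so the
#'   reference-based correction is exact for this model.
#' @param bleach_depth fraction of ROI intensity removed by the bleach pulse,
#'   in (0, 1\].
#' @param bleach_radius bleach spot radius, microns.
#' @param noise_sd additive Gaussian noise sd, intensity units (on a
#'   pre-bleach intensity of 1).
#' @return a `frap_ground_truth` object.
#' @export
frap_ground_truth <- function(F_m_true, tau_half_true,
                              acquisition_bleach_rate = 0,
                              bleach_depth = 1, bleach_radius = 1,
                              noise_sd = 0) {
  .assert_scalar(F_m_true, "F_m_true", min = 0, max = 1)
  .assert_scalar(tau_half_true, "tau_half_true", positive = TRUE)
  .assert_scalar(acquisition_bleach_rate, "acquisition_bleach_rate", min = 0)
  .assert_scalar(bleach_depth, "bleach_depth", positive = TRUE, max = 1)
  .assert_scalar(bleach_radius, "bleach_radius", positive = TRUE)
  .assert_scalar(noise_sd, "noise_sd", min = 0)
  structure(list(F_m_true = F_m_true, tau_half_true = tau_half_true,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 bleach_depth = bleach_depth, bleach_radius = bleach_radius,
                 noise_sd = noise_sd),
            class = "frap_ground_truth")
}

#' Simulate a FRAP record
#'
#' The underlying (bleach-corrected) ROI intensity recovers as
#' \eqn{I_i [(1 - d) + d F_m (1 - e^{-\ln 2\, t'/\tau_{1/2}})]} from the
#' bleach pulse of depth `d`; both ROI and reference are then multiplied by
#' `exp(-acquisition_bleach_rate * t)` and Gaussian noise is added.
#'
#' @param truth a [frap_ground_truth()].
#' @param n_pre pre-bleach frames (>= 1).
#' @param n_post post-bleach frames (>= 2).
#' @param dt frame interval, seconds.
#' @param seed integer seed.
#' @param I_i,R_i pre-bleach ROI and reference intensities (arbitrary units).
#' @return a `frap_record`: list with `t`, `roi`, `reference`,
#'   `bleach_frame` (index of the first post-bleach sample), `bleach_radius`;
#'   attribute `ground_truth`.
#' @export
simulate_frap <- function(truth, n_pre = 5L, n_post = 120L, dt = 0.5,
                          seed = 1L, I_i = 1, R_i = 1) {
  stopifnot(inherits(truth, "frap_ground_truth"))
  if (n_pre < 1L) stop("'n_pre' must be >= 1", call. = FALSE)
  if (n_post < 2L) stop("'n_post' must be >= 2", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_pre) + as.integer(n_post)
  t <- (seq_len(n) - 1L) * dt
  bleach_frame <- as.integer(n_pre) + 1L
  t_post <- t[bleach_frame:n] - t[bleach_frame]
  d <- truth$bleach_depth
  rec <- I_i * ((1 - d) + d * truth$F_m_true *
                  (1 - exp(-log(2) * t_post / truth$tau_half_true)))
  roi_clean <- c(rep(I_i, n_pre), rec)
  fade <- exp(-truth$acquisition_bleach_rate * t)
  roi <- roi_clean * fade + rnorm(n, sd = truth$noise_sd)
  reference <- R_i * fade + rnorm(n, sd = truth$noise_sd)
  structure(list(t = t, roi = roi, reference = reference,
                 bleach_frame = bleach_frame,
                 bleach_radius = truth$bleach_radius),
            ground_truth = truth, class = "frap_record")
}

#' Construct a FRAP record from raw traces
#'
#' @param t time points, seconds (strictly increasing).
#' @param roi ROI intensity trace.
#' @param reference unbleached-reference intensity trace.
#' @param bleach_frame 1-based index of the first post-bleach sample
#'   (must be >= 2 so at least one pre-bleach point exists).
#' @param bleach_radius bleach spot radius, microns.
#' @return a `frap_record`.
#' @export
frap_record <- function(t, roi, reference, bleach_frame, bleach_radius) {
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing",
                              call. = FALSE)
  if (bleach_frame < 2L) stop("'bleach_frame' must leave >= 1 pre-bleach point",
                              call. = FALSE)
  .assert_scalar(bleach_radius, "bleach_radius", positive = TRUE)
  stopifnot(length(roi) == length(t), length(reference) == length(t))
  structure(list(t = t, roi = roi, reference = reference,
                 bleach_frame = as.integer(bleach_frame),
                 bleach_radius = bleach_radius),
            class = "frap_record")
}

#' Correct a FRAP trace for acquisition bleaching and normalize it
#'
#' Applies the reference-based correction
#' \eqn{C_f(t) = R_i / R(t)}, \eqn{I_{cor}(t) = C_f(t) I(t)}, then scales to
#' \eqn{I_n(t) = (I_{cor}(t) - I_{min}) / (I_i - I_{min})} where \eqn{I_i}
#' is the mean pre-bleach corrected intensity and \eqn{I_{min}} the corrected
#' intensity at the first post-bleach frame. \eqn{R_i} is the mean pre-bleach
#' reference. Noise can push \eqn{I_n} slightly outside \[0, 1\]; no clipping
#' is applied.
#'
#' @param rec a `frap_record` with strictly positive reference trace.
#' @return list with `C_f`, `I_cor`, `I_n`, `I_i`, `I_min`, `t_post`
#'   (post-bleach time re-zeroed at the bleach frame) and `I_n_post`.
#' @export
correct_and_normalize <- function(rec) {
  stopifnot(inherits(rec, "frap_record"))
  if (any(rec$reference <= 0))
    stop("reference trace must be strictly positive", call. = FALSE)
  pre <- seq_len(rec$bleach_frame - 1L)
  R_i <- mean(rec$reference[pre])
  C_f <- R_i / rec$reference
  I_cor <- C_f * rec$roi
  I_i <- mean(I_cor[pre])
  I_min <- I_cor[rec$bleach_frame]
  if (isTRUE(all.equal(I_i, I_min)))
    stop("degenerate record: no bleach detected (I_i == I_min)",
         call. = FALSE)
  I_n <- (I_cor - I_min) / (I_i - I_min)
  post <- rec$bleach_frame:length(rec$t)
  list(C_f = C_f, I_cor = I_cor, I_n = I_n, I_i = I_i, I_min = I_min,
       t_post = rec$t[post] - rec$t[rec$bleach_frame],
       I_n_post = I_n[post])
}

#' Immobile and mobile fractions from FRAP intensities
#'
#' \eqn{F_{im} = (I_i - I_\infty) / (I_i - I_{min})}, \eqn{F_m = 1 - F_{im}}.
#'
#' @param I_i pre-bleach intensity.
#' @param I_min first post-bleach intensity (must be < `I_i`).
#' @param I_inf plateau intensity after recovery.
#' @param tolerance relative headroom allowed for `I_inf` above `I_i`
#'   before clipping (default 2\%, noise headroom).
#' @return list with `F_im` and `F_m` (summing to 1 exactly).
#' @export
immobile_fraction <- function(I_i, I_min, I_inf, tolerance = 0.02) {
  if (I_i <= I_min) stop("'I_i' must exceed 'I_min'", call. = FALSE)
  if (I_inf < I_min) stop("'I_inf' below 'I_min'", call. = FALSE)
  if (I_inf > I_i * (1 + tolerance))
    stop("'I_inf' exceeds 'I_i' beyond tolerance", call. = FALSE)
  if (I_inf > I_i) {
    warning("I_inf > I_i within tolerance; clipped to I_i (F_im = 0)")
    I_inf <- I_i
  }
  F_im <- (I_i - I_inf) / (I_i - I_min)
  list(F_im = F_im, F_m = 1 - F_im)
}

#' Fit the exponential recovery model to a normalized FRAP trace
#'
#' Nonlinear least squares of
#' \eqn{I_n(t) = F_m (1 - e^{-\ln 2 \, t / \tau_{1/2}})} on the post-bleach
#' trace, with initial guesses \eqn{F_m =} last observed value and
#' \eqn{\tau_{1/2}} the time at which the trace first reaches half of it;
#' bounds \eqn{F_m \in [0, 1.2]}, \eqn{\tau_{1/2} > 0}.
#'
#' @param I_n normalized post-bleach trace (0 at the bleach frame).
#' @param t_post post-bleach times, seconds, starting at 0.
#' @return list with `F_m`, `tau_half`, `rss` and `identifiable` (FALSE when
#'   the trace is flat and the half-time is meaningless).
#' @export
fit_recovery <- function(I_n, t_post) {
  stopifnot(length(I_n) == length(t_post))
  if (length(I_n) < 5L) stop("need >= 5 post-bleach points", call. = FALSE)
  last <- mean(tail(I_n, max(3L, length(I_n) %/% 10L)))
  if (last < 0.02) {
    # essentially no recovery: F_m ~ 0, tau_half unidentifiable
    return(list(F_m = max(0, last), tau_half = NA_real_,
                rss = sum((I_n - max(0, last))^2), identifiable = FALSE))
  }
  i_half <- which(I_n >= last / 2)[1]
  t0 <- max(t_post[2], t_post[i_half], na.rm = TRUE)
  fit <- minpack.lm::nlsLM(
    I_n ~ Fm * (1 - exp(-log(2) * t_post / tau)),
    start = list(Fm = min(max(last, 0.01), 1.2), tau = t0),
    lower = c(0, .Machine$double.eps), upper = c(1.2, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(F_m = unname(cf["Fm"]), tau_half = unname(cf["tau"]),
       rss = sum(residuals(fit)^2), identifiable = TRUE)
}

#' Apparent diffusion coefficient from a FRAP half-time
#'
#' \eqn{D_{app} = 0.22\, r^2 / \tau_{1/2}} for a circular bleach spot of
#' radius `r`.
#'
#' @param r bleach radius, microns.
#' @param tau_half recovery half-time, seconds.
#' @return apparent diffusivity, um^2/s.
#' @export
apparent_diffusion <- function(r, tau_half) {
  .assert_scalar(r, "r", positive = TRUE)
  .assert_scalar(tau_half, "tau_half", positive = TRUE)
  0.22 * r^2 / tau_half
}

#' Ratio of two immobile fractions
#'
#' Both values must be on the same scale (both fractions or both percent);
#' the ratio is reported rounded to one decimal, matching how fold-changes
#' in immobile fraction are usually quoted.
#'
#' @param f_a,f_b immobile fractions (or percentages).
#' @return `round(f_a / f_b, 1)`.
#' @export
immobile_ratio <- function(f_a, f_b) {
  if (f_b <= 0) stop("'f_b' must be > 0", call. = FALSE)
  on_frac <- c(f_a <= 1, f_b <= 1)
  if (xor(on_frac[1], on_frac[2]))
    stop("mixed scales: one value looks like a fraction, the other percent",
         call. = FALSE)
  round(f_a / f_b, 1)
}

#' Immobile fraction normalized to a reference construct
#'
#' @param f_sample immobile fraction of the sample.
#' @param f_control immobile fraction of the fully immobile control
#'   (e.g. a solid aggregate).
#' @return `f_sample / f_control`; a warning is issued above 1.05 (sample
#'   apparently less mobile than the solid control).
#' @export
relative_immobile <- function(f_sample, f_control) {
  if (f_control <= 0) stop("'f_control' must be > 0", call. = FALSE)
  r <- f_sample / f_control
  if (r > 1.05)
    warning("relative immobile fraction > 1.05; check the control")
  r
}

#' Full FRAP analysis of a record
#'
#' Runs [correct_and_normalize()], fits the recovery with [fit_recovery()],
#' derives the immobile fraction from the fitted asymptote (default) or the
#' literal last corrected frame, and computes the apparent diffusivity from
#' the bleach radius.
#'
#' @param rec a `frap_record`.
#' @param i_inf `"fitted"` (default) takes \eqn{I_\infty} from the fitted
#'   recovery asymptote; `"last"` uses the final corrected sample.
#' @return a `frap_fit`: list with `I_i`, `I_min`, `I_inf`, `C_f`, `I_n`,
#'   `F_im`, `F_m`, `tau_half`, `D_app`, `rss`, `identifiable`.
#' @examples
#' rec <- simulate_frap(frap_ground_truth(0.7, 2, 0.01, noise_sd = 0.01),
#'                      seed = 42)
#' frap_analyze(rec)
#' @export
frap_analyze <- function(rec, i_inf = c("fitted", "last")) {
  i_inf <- match.arg(i_inf)
  cn <- correct_and_normalize(rec)
  fit <- fit_recovery(cn$I_n_post, cn$t_post)
  I_inf <- if (i_inf == "fitted" && fit$identifiable) {
    cn$I_min + fit$F_m * (cn$I_i - cn$I_min)
  } else if (i_inf == "fitted") {
    cn$I_min + fit$F_m * (cn$I_i - cn$I_min)
  } else tail(cn$I_cor, 1L)
  fr <- immobile_fraction(cn$I_i, cn$I_min, min(I_inf, cn$I_i))
  D_app <- if (fit$identifiable)
    apparent_diffusion(rec$bleach_radius, fit$tau_half) else NA_real_
  structure(list(I_i = cn$I_i, I_min = cn$I_min, I_inf = I_inf,
                 C_f = cn$C_f, I_n = cn$I_n, F_im = fr$F_im, F_m = fr$F_m,
                 tau_half = fit$tau_half, D_app = D_app, rss = fit$rss,
                 identifiable = fit$identifiable),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: F_im = %.3f, F_m = %.3f, tau_half = %s s, D_app = %s um^2/s\n",
    x$F_im, x$F_m,
    if (is.na(x$tau_half)) "NA" else sprintf("%.3g", x$tau_half),
    if (is.na(x$D_app)) "NA" else sprintf("%.3g", x$D_app)))
  invisible(x)
}

#' Write / read a FRAP record as CSV plus JSON sidecar
#'
#' CSV columns `t_s, roi, reference`; the sidecar stores `bleach_frame` and
#' `bleach_radius_um`.
#'
#' @param rec a `frap_record`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_frap_record()` returns `path` invisibly;
#'   `read_frap_record()` returns a `frap_record`.
#' @export
write_frap_record <- function(rec, path) {
  utils::write.csv(data.frame(t_s = rec$t, roi = rec$roi,
                              reference = rec$reference),
                   path, row.names = FALSE)
  jsonlite::write_json(list(bleach_frame = rec$bleach_frame,
                            bleach_radius_um = rec$bleach_radius),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frap_record
#' @export
read_frap_record <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  frap_record(df$t_s, df$roi, df$reference,
              bleach_frame = side$bleach_frame,
              bleach_radius = side$bleach_radius_um)
}
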