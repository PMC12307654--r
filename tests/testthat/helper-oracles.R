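# Independent oracles used across test files.

# O(N^2) brute-force time-averaged MSD over all overlapping pairs,
# ensemble-averaged with pair-count weights. Deliberately naive.
brute_force_msd <- function(traj, max_lag) {
  parts <- split(traj[c("x_um", "y_um")], traj$particle)
  dt <- attr(traj, "dt")
  vapply(seq_len(max_lag), function(k) {
    num <- 0; den <- 0
    for (p in parts) {
      n <- nrow(p)
      if (n <= k) next
      for (i in 1:(n - k)) {
        num <- num + (p$x_um[i + k] - p$x_um[i])^2 +
          (p$y_um[i + k] - p$y_um[i])^2
        den <- den + 1
      }
    }
    num / den
  }, 0)
}

# Analytic single-mode Maxwell moduli on a log-spaced frequency grid.
maxwell_moduli <- function(G = 1, tau = 1, omega = NULL) {
  if (is.null(omega))
    omega <- exp(seq(log(0.01 / tau), log(100 / tau), length.out = 30))
  wt <- omega * tau
  moduli_curve(omega, G_storage = G * wt^2 / (1 + wt^2),
               G_loss = G * wt / (1 + wt^2))
}

# Exhaustive minimum-cost bipartite matching oracle: enumerate every
# assignment of detections to tracks (or none), maximize matches then
# minimize total cost. cost has Inf for disallowed pairs.
brute_force_matching <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  options <- lapply(seq_len(n), function(j) c(NA_integer_, which(is.finite(cost[, j]))))
  grid <- expand.grid(options, stringsAsFactors = FALSE)
  best <- NULL; best_key <- c(-Inf, Inf)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[!is.na(a)]
    if (anyDuplicated(used)) next
    total <- sum(cost[cbind(used, which(!is.na(a)))])
    key <- c(length(used), total)
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- a; best_key <- key
    }
  }
  best
}

# Stokes-Einstein diffusivity (um^2/s) of a bead of radius a_um (um) in a
# fluid of viscosity eta (Pa s) at temperature T (K).
stokes_einstein_D <- function(eta, a_um, T = 298.15) {
  1.380649e-23 * T / (6 * pi * eta * a_um * 1e-6) * 1e12
}

frame_intensity_centroid <- function(img) {
  tot <- sum(img - min(img))
  w <- img - min(img)
  c(x = sum(t(w) * (seq_len(ncol(img)) - 0.5)) / tot,
    y = sum(w * (seq_len(nrow(img)) - 0.5)) / tot)
}
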