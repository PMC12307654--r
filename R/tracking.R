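#' Render trajectory frames as a synthetic fluorescence video
#'
#' Each particle is drawn as a pixel-integrated 2D Gaussian of width
#' `psf_sigma`; the background is Poisson-distributed with mean `background`
#' and the spot amplitude is scaled so that peak / background-sd equals
#' `snr` (`snr = Inf` gives a noiseless stack with flat background).
#'
#' Continuous pixel coordinates place the centre of pixel `(row r, col c)`
#' at `(x = c - 0.5, y = r - 0.5)`; micron positions are converted with
#' `config$pixel_size`.
#'
#' @param traj a `trajectory_ensemble` (positions in microns).
#' @param psf_sigma point-spread-function width, microns.
#' @param snr peak-signal to background-noise ratio.
#' @param config the [simulation_config()] used to generate `traj`
#'   (supplies `pixel_size`, `dt`, `seed`).
#' @param dim_px frame height and width, pixels.
#' @param background mean background level, counts.
#' @param offset_um optional `c(x, y)` shift applied to all positions before
#'   rendering, microns (to centre trajectories in the field).
#' @return a `frame_stack`: list with `frames` (list of matrices),
#'   `pixel_size`, `dt`.
#' @export
render_frames <- function(traj, psf_sigma, snr, config,
                          dim_px = c(128L, 128L), background = 100,
                          offset_um = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  .assert_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  px <- config$pixel_size
  sig_px <- psf_sigma / px
  h <- dim_px[1]; w <- dim_px[2]
  if (is.null(offset_um)) offset_um <- c(0, 0)
  xs <- (traj$x_um + offset_um[1]) / px
  ys <- (traj$y_um + offset_um[2]) / px
  pad <- 3 * sig_px
  bad <- xs < pad | xs > w - pad | ys < pad | ys > h - pad
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "particle %d leaves the field of view at frame %d (x = %.1f, y = %.1f px)",
      traj$particle[i], traj$frame[i], xs[i], ys[i]), call. = FALSE)
  }
  amp <- if (is.finite(snr)) snr * sqrt(background) else 1000
  # peak pixel weight of a perfectly centred integrated Gaussian
  wmax <- (2 * pnorm(0.5 / sig_px) - 1)^2
  set.seed(config$seed + 1L)
  frame_ids <- if (nrow(traj)) sort(unique(traj$frame))
               else 0:(config$n_frames - 1L)  # pure-background stack
  frames <- lapply(frame_ids, function(f) {
    img <- if (is.finite(snr))
      matrix(rpois(h * w, background), h, w)
    else matrix(background, h, w)
    sel <- which(traj$frame == f)
    for (i in sel) {
      x0 <- xs[i]; y0 <- ys[i]
      c_lo <- max(1L, floor(x0 - 4 * sig_px)); c_hi <- min(w, ceiling(x0 + 4 * sig_px))
      r_lo <- max(1L, floor(y0 - 4 * sig_px)); r_hi <- min(h, ceiling(y0 + 4 * sig_px))
      cc <- c_lo:c_hi; rr <- r_lo:r_hi
      wx <- pnorm((cc - x0) / sig_px) - pnorm((cc - 1 - x0) / sig_px)
      wy <- pnorm((rr - y0) / sig_px) - pnorm((rr - 1 - y0) / sig_px)
      img[rr, cc] <- img[rr, cc] + (amp / wmax) * outer(wy, wx)
    }
    img
  })
  structure(list(frames = frames, pixel_size = px, dt = config$dt),
            class = "frame_stack")
}

#' Write / read a frame stack as multi-page 16-bit TIFF with JSON sidecar
#'
#' Pixel values are scaled by the stack maximum (recorded in the sidecar,
#' along with `pixel_size_um` and `dt_s`) to use the 16-bit range.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  mx <- max(vapply(stack$frames, max, 0))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size,
                            dt_s = stack$dt, intensity_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  structure(list(frames = lapply(pages, function(p) p * side$intensity_scale),
                 pixel_size = side$pixel_size_um, dt = side$dt_s),
            class = "frame_stack")
}

#' Detect fluorescent spots with sub-pixel localization
#'
#' Per frame: difference-of-Gaussians band-pass filter (sigmas `spot_sigma`
#' and `3 * spot_sigma`), local maxima above
#' `mean + threshold_sd * sd` of the filtered image, then intensity-weighted
#' centroid refinement in a `(2 ceil(3 sigma) + 1)^2` window on the
#' background-free filtered image (two re-centering iterations). Spots whose
#' refinement window exits the frame are discarded.
#'
#' @param stack a `frame_stack`.
#' @param spot_sigma expected spot width, pixels.
#' @param threshold_sd detection threshold in background-sd units.
#' @return a data frame of localizations: `frame` (0-based), `x`, `y`
#'   (sub-pixel, continuous pixel coordinates), `intensity`.
#' @export
detect_spots <- function(stack, spot_sigma, threshold_sd = 5) {
  stopifnot(inherits(stack, "frame_stack"))
  .assert_scalar(spot_sigma, "spot_sigma", positive = TRUE)
  if (length(stack$frames) == 0) stop("empty stack", call. = FALSE)
  wh <- ceiling(3 * spot_sigma)
  out <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    img <- stack$frames[[f]]
    h <- nrow(img); w <- ncol(img)
    fil <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = spot_sigma)) -
      as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 3 * spot_sigma))
    thr <- mean(fil) + threshold_sd * sd(fil)
    # local maxima: strictly greater than all 8 neighbours, above threshold
    core <- fil[2:(h - 1), 2:(w - 1)]
    is_max <- core > thr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & core >= fil[2:(h - 1) + dr, 2:(w - 1) + dc]
    }
    peaks <- which(is_max, arr.ind = TRUE)
    if (nrow(peaks) == 0) { out[[f]] <- NULL; next }
    peaks <- peaks + 1L  # back to full-image indices
    pos <- fil - min(0, min(fil))
    locs <- lapply(seq_len(nrow(peaks)), function(k) {
      r <- peaks[k, 1]; c <- peaks[k, 2]
      xc <- c - 0.5; yc <- r - 0.5
      for (it in 1:2) {
        r0 <- round(yc + 0.5); c0 <- round(xc + 0.5)
        if (r0 - wh < 1 || r0 + wh > h || c0 - wh < 1 || c0 + wh > w)
          return(NULL)  # window exits the frame: discard (edge bias)
        rr <- (r0 - wh):(r0 + wh); cc <- (c0 - wh):(c0 + wh)
        win <- pmax(fil[rr, cc], 0)
        tot <- sum(win)
        if (tot == 0) return(NULL)
        yc <- sum((rr - 0.5) * rowSums(win)) / tot
        xc <- sum((cc - 0.5) * colSums(win)) / tot
      }
      c(x = xc, y = yc, intensity = fil[r, c])
    })
    locs <- do.call(rbind, locs[!vapply(locs, is.null, TRUE)])
    if (is.null(locs) || nrow(locs) == 0) { out[[f]] <- NULL; next }
    # collapse duplicate refinements converging to the same spot
    locs <- as.data.frame(locs)
    keep <- rep(TRUE, nrow(locs))
    if (nrow(locs) > 1) {
      for (i in seq_len(nrow(locs) - 1)) {
        if (!keep[i]) next
        d <- sqrt((locs$x[-(1:i)] - locs$x[i])^2 +
                  (locs$y[-(1:i)] - locs$y[i])^2)
        dup <- which(d < spot_sigma) + i
        keep[dup[locs$intensity[dup] <= locs$intensity[i]]] <- FALSE
      }
    }
    locs <- locs[keep, ]
    out[[f]] <- data.frame(frame = f - 1L, locs)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(frame = integer(), x = numeric(),
                                      y = numeric(), intensity = numeric())
  rownames(res) <- NULL
  res
}

#' Linking parameters for trajectory assembly
#'
#' @param max_displacement maximum frame-to-frame displacement, pixels.
#' @param memory frames a particle may go undetected and still be re-linked.
#' @param min_track_length minimum retained track length, frames (>= 2).
#' @return a `linking_params` object.
#' @export
linking_params <- function(max_displacement, memory = 0L,
                           min_track_length = 2L) {
  .assert_scalar(max_displacement, "max_displacement", positive = TRUE)
  if (memory < 0) stop("'memory' must be >= 0", call. = FALSE)
  if (min_track_length < 2) stop("'min_track_length' must be >= 2",
                                 call. = FALSE)
  structure(list(max_displacement = max_displacement,
                 memory = as.integer(memory),
                 min_track_length = as.integer(min_track_length)),
            class = "linking_params")
}

# Minimum-total-cost bipartite matching on a small component, maximizing the
# number of matches first. cost: m x n matrix with Inf for disallowed pairs.
# Returns integer vector of length n (column -> row index or NA). Ties are
# broken toward the lowest row (track) index by the enumeration order.
.best_matching <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  best <- list(nmatch = -1L, total = Inf, assign = rep(NA_integer_, n))
  assign <- rep(NA_integer_, n)
  used <- rep(FALSE, m)
  recurse <- function(j, nmatch, total) {
    if (total > best$total && nmatch + (n - j + 1L) <= best$nmatch) return()
    if (j > n) {
      if (nmatch > best$nmatch ||
          (nmatch == best$nmatch && total < best$total)) {
        best <<- list(nmatch = nmatch, total = total, assign = assign)
      }
      return()
    }
    for (i in seq_len(m)) {
      if (!used[i] && is.finite(cost[i, j])) {
        used[i] <<- TRUE; assign[j] <<- i
        recurse(j + 1L, nmatch + 1L, total + cost[i, j])
        used[i] <<- FALSE; assign[j] <<- NA_integer_
      }
    }
    recurse(j + 1L, nmatch, total)
  }
  recurse(1L, 0L, 0)
  best$assign
}

#' Link localizations into trajectories
#'
#' Frame-to-frame assignment minimizes total squared displacement among
#' candidate pairs within `max_displacement` (conflicts are resolved by
#' exhaustive minimum-cost matching inside each connected conflict
#' component, maximizing the number of links first). Particles undetected
#' for at most `memory` frames are re-linked, with the gap filled by linear
#' interpolation; tracks shorter than `min_track_length` are dropped.
#' Output positions are converted to microns and seconds.
#'
#' @param locs localization data frame from [detect_spots()] (sorted by
#'   frame).
#' @param params a [linking_params()].
#' @param pixel_size microns per pixel.
#' @param dt frame interval, seconds.
#' @return a `trajectory_ensemble`.
#' @export
link_trajectories <- function(locs, params, pixel_size, dt) {
  stopifnot(inherits(params, "linking_params"))
  .assert_scalar(pixel_size, "pixel_size", positive = TRUE)
  .assert_scalar(dt, "dt", positive = TRUE)
  if (nrow(locs) == 0)
    return(trajectory_ensemble(
      data.frame(particle = integer(), frame = integer(), t_s = numeric(),
                 x_um = numeric(), y_um = numeric()),
      dt = dt, pixel_size = pixel_size))
  if (is.unsorted(locs$frame)) locs <- locs[order(locs$frame), ]
  frames <- sort(unique(locs$frame))
  maxd2 <- params$max_displacement^2

  tracks <- list()   # each: list(frames =, x =, y =, last_frame =)
  last_frames <- integer(0)
  for (f in frames) {
    det <- locs[locs$frame == f, ]
    nd <- nrow(det)
    # linkable tracks: last seen at most memory+1 frames ago
    active <- which(f - last_frames <= params$memory + 1L)
    na <- length(active)
    assign <- rep(NA_integer_, nd)
    if (na > 0 && nd > 0) {
      ax <- vapply(tracks[active], function(tr) tail(tr$x, 1L), 0)
      ay <- vapply(tracks[active], function(tr) tail(tr$y, 1L), 0)
      cost <- outer(ax, det$x, "-")^2 + outer(ay, det$y, "-")^2
      cost[cost > maxd2] <- Inf
      # decompose into connected components over finite-cost edges
      comp_t <- rep(0L, na); comp_d <- rep(0L, nd); nc <- 0L
      for (j in seq_len(nd)) {
        if (comp_d[j] > 0L) next
        nc <- nc + 1L
        dq <- j
        while (length(dq)) {
          jj <- dq[1]; dq <- dq[-1]
          if (comp_d[jj] > 0L) next
          comp_d[jj] <- nc
          ti <- which(is.finite(cost[, jj]) & comp_t == 0L)
          comp_t[ti] <- nc
          for (i in ti) dq <- c(dq, which(is.finite(cost[i, ]) & comp_d == 0L))
        }
      }
      for (k in seq_len(nc)) {
        rows <- which(comp_t == k); cols <- which(comp_d == k)
        if (!length(rows) || !length(cols)) next
        sub <- cost[rows, cols, drop = FALSE]
        a <- if (length(rows) * length(cols) <= 64)
          .best_matching(sub)
        else {  # large ambiguous component: greedy by ascending cost
          aa <- rep(NA_integer_, length(cols)); usedr <- rep(FALSE, length(rows))
          ord <- order(sub)
          for (e in ord) {
            if (!is.finite(sub[e])) break
            i <- (e - 1) %% length(rows) + 1; j <- (e - 1) %/% length(rows) + 1
            if (!usedr[i] && is.na(aa[j])) { aa[j] <- i; usedr[i] <- TRUE }
          }
          aa
        }
        assign[cols] <- ifelse(is.na(a), NA_integer_, rows[a])
      }
    }
    for (j in seq_len(nd)) {
      if (!is.na(assign[j])) {
        ti <- active[assign[j]]
        tr <- tracks[[ti]]
        gap <- f - tr$last_frame
        if (gap > 1L) {  # fill memory gap by linear interpolation
          gf <- (tr$last_frame + 1L):(f - 1L)
          wgt <- (gf - tr$last_frame) / gap
          tr$frames <- c(tr$frames, gf)
          tr$x <- c(tr$x, tail(tr$x, 1) + wgt * (det$x[j] - tail(tr$x, 1)))
          tr$y <- c(tr$y, tail(tr$y, 1) + wgt * (det$y[j] - tail(tr$y, 1)))
        }
        tr$frames <- c(tr$frames, f)
        tr$x <- c(tr$x, det$x[j]); tr$y <- c(tr$y, det$y[j])
        tr$last_frame <- f
        tracks[[ti]] <- tr
        last_frames[ti] <- f
      } else {
        tracks[[length(tracks) + 1L]] <-
          list(frames = f, x = det$x[j], y = det$y[j], last_frame = f)
        last_frames[length(tracks)] <- f
      }
    }
  }
  keep <- which(vapply(tracks, function(tr) length(tr$frames), 0L) >=
                  params$min_track_length)
  if (!length(keep))
    return(trajectory_ensemble(
      data.frame(particle = integer(), frame = integer(), t_s = numeric(),
                 x_um = numeric(), y_um = numeric()),
      dt = dt, pixel_size = pixel_size))
  df <- do.call(rbind, lapply(seq_along(keep), function(i) {
    tr <- tracks[[keep[i]]]
    data.frame(particle = i, frame = tr$frames, t_s = tr$frames * dt,
               x_um = tr$x * pixel_size, y_um = tr$y * pixel_size)
  }))
  trajectory_ensemble(df, dt = dt, pixel_size = pixel_size)
}
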