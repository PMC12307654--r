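#' Render a synthetic two-channel condensate image
#'
#' Places non-overlapping disk-shaped condensates in a field with exterior
#' intensity 1 per channel and interior intensity equal to the requested
#' in/out ratio, then adds Gaussian noise. The true label map is attached as
#' a sidecar for validation.
#'
#' @param n_condensates number of disks.
#' @param radius_px disk radius, pixels.
#' @param scaffold_in_out interior/exterior intensity ratio of the scaffold
#'   channel (>= 0).
#' @param cargo_in_out interior/exterior ratio of the cargo channel (>= 0);
#'   1 means no enrichment.
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed integer seed.
#' @param dim image height and width, pixels.
#' @param pixel_size microns per pixel (metadata only).
#' @return a `condensate_image`: list with matrices `scaffold` and `cargo`
#'   plus `pixel_size`; attribute `ground_truth` holding the label map and
#'   the generating ratios.
#' @export
render_condensate_image <- function(n_condensates, radius_px = 12,
                                    scaffold_in_out = 5,
                                    cargo_in_out = 1, noise_sd = 0,
                                    seed = 1L, dim = c(192L, 192L),
                                    pixel_size = 0.1) {
  if (n_condensates < 0) stop("'n_condensates' must be >= 0", call. = FALSE)
  if (scaffold_in_out < 0 || cargo_in_out < 0)
    stop("in/out ratios must be >= 0", call. = FALSE)
  set.seed(seed)
  h <- dim[1]; w <- dim[2]
  centers <- matrix(numeric(0), 0, 2)
  margin <- radius_px + 2
  tries <- 0L
  while (nrow(centers) < n_condensates) {
    if ((tries <- tries + 1L) > 5000L)
      stop("could not place ", n_condensates,
           " non-overlapping disks of radius ", radius_px,
           " in a ", h, "x", w, " field", call. = FALSE)
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * radius_px + 3))
      centers <- rbind(centers, cand)
  }
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  labels <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    inside <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
      radius_px^2
    labels[inside] <- i
  }
  make_channel <- function(ratio) {
    ch <- matrix(1, h, w)
    ch[labels > 0] <- ratio
    if (noise_sd > 0) ch <- ch + matrix(rnorm(h * w, sd = noise_sd), h, w)
    pmax(ch, 0)
  }
  structure(list(scaffold = make_channel(scaffold_in_out),
                 cargo = make_channel(cargo_in_out),
                 pixel_size = pixel_size),
            ground_truth = list(labels = labels, centers = centers,
                                scaffold_in_out = scaffold_in_out,
                                cargo_in_out = cargo_in_out),
            class = "condensate_image")
}

#' Construct a condensate image from channel matrices
#'
#' @param scaffold,cargo intensity matrices of identical dimensions.
#' @param pixel_size microns per pixel.
#' @return a `condensate_image`.
#' @export
condensate_image <- function(scaffold, cargo, pixel_size = NA_real_) {
  if (!identical(base::dim(scaffold), base::dim(cargo)))
    stop("channels must share dimensions", call. = FALSE)
  if (any(scaffold < 0) || any(cargo < 0))
    stop("intensities must be >= 0", call. = FALSE)
  structure(list(scaffold = scaffold, cargo = cargo,
                 pixel_size = pixel_size),
            class = "condensate_image")
}

# merge 4-connectivity labels that touch diagonally (=> 8-connectivity)
.merge_diagonal <- function(lab) {
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (dd[2] == 1) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (dd[2] == 1) 2:w else seq_len(w - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment condensates in the scaffold channel
#'
#' Thresholds the scaffold channel (Otsu by default), labels connected
#' components with 8-connectivity, and removes components smaller than
#' `min_area_px`.
#'
#' @param img a `condensate_image`.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param min_area_px minimum component area, pixels (default 9, suppressing
#'   shot-noise specks).
#' @param fixed_threshold threshold value when `threshold_mode = "fixed"`.
#' @return a `segmentation_result`: list with `label_map` (0 = background,
#'   labels contiguous 1..n), `n_condensates`, and a per-label `table`
#'   (area, centroid, mean intensity per channel).
#' @export
segment_condensates <- function(img, threshold_mode = c("otsu", "fixed"),
                                min_area_px = 9L, fixed_threshold = NULL) {
  stopifnot(inherits(img, "condensate_image"))
  threshold_mode <- match.arg(threshold_mode)
  sc <- img$scaffold
  if (length(sc) == 0) stop("empty image", call. = FALSE)
  thr <- if (threshold_mode == "otsu") {
    rng <- range(sc)
    if (diff(rng) == 0) Inf  # flat image: nothing to segment
    else {
      norm <- (sc - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng) +
        rng[1]
    }
  } else {
    if (is.null(fixed_threshold))
      stop("'fixed_threshold' required in fixed mode", call. = FALSE)
    fixed_threshold
  }
  mask <- sc > thr
  lab <- .merge_diagonal(matrix(as.integer(
    EBImage::bwlabel(EBImage::Image(mask * 1))), nrow(sc), ncol(sc)))
  if (max(lab) > 0 && min_area_px > 1) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab[lab > 0] <- match(lab[lab > 0], sort(unique(lab[lab > 0])))
  }
  n <- max(lab)
  tab <- if (n > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rr <- ((idx - 1) %% nrow(lab)) + 1
    cc <- ((idx - 1) %/% nrow(lab)) + 1
    data.frame(label = seq_len(n),
               area_px = as.vector(tabulate(l, n)),
               centroid_row = as.vector(tapply(rr, l, mean)),
               centroid_col = as.vector(tapply(cc, l, mean)),
               mean_scaffold = as.vector(tapply(img$scaffold[idx], l, mean)),
               mean_cargo = as.vector(tapply(img$cargo[idx], l, mean)))
  } else {
    data.frame(label = integer(), area_px = integer(),
               centroid_row = numeric(), centroid_col = numeric(),
               mean_scaffold = numeric(), mean_cargo = numeric())
  }
  structure(list(label_map = lab, n_condensates = n, table = tab,
                 threshold = thr),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation: %d condensate(s), threshold = %.4g\n",
              x$n_condensates, x$threshold))
  invisible(x)
}

#' Cargo enrichment index
#'
#' Mean cargo-channel intensity over condensate pixels divided by the mean
#' over background pixels, where the background excludes a 2-pixel dilated
#' halo around each condensate (edge-blur bias avoidance). By default all
#' condensate pixels are pooled across the field; `per_condensate = TRUE`
#' instead computes one index per condensate and averages them.
#'
#' @param img a `condensate_image`.
#' @param seg a `segmentation_result` for `img`.
#' @param per_condensate average of per-condensate indices instead of the
#'   pooled-pixel index.
#' @param halo_px background exclusion margin around condensates, pixels.
#' @return enrichment index (dimensionless ratio).
#' @export
enrichment_index <- function(img, seg, per_condensate = FALSE,
                             halo_px = 2L) {
  stopifnot(inherits(img, "condensate_image"),
            inherits(seg, "segmentation_result"))
  if (seg$n_condensates < 1L) stop("no condensates segmented", call. = FALSE)
  fg <- seg$label_map > 0
  brush <- EBImage::makeBrush(2L * halo_px + 1L, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(fg * 1), brush) > 0
  bg <- !matrix(as.logical(dil), nrow(fg), ncol(fg))
  if (!any(bg)) stop("background region is empty", call. = FALSE)
  bg_mean <- mean(img$cargo[bg])
  if (bg_mean == 0) stop("zero background mean", call. = FALSE)
  if (per_condensate) {
    mean(vapply(seq_len(seg$n_condensates), function(i) {
      mean(img$cargo[seg$label_map == i]) / bg_mean
    }, 0))
  } else {
    mean(img$cargo[fg]) / bg_mean
  }
}

#' Relative condensate count after treatment
#'
#' Condensate survival expressed as a percentage of the pre-treatment count,
#' e.g. before/after 1,6-hexanediol challenge or dilution.
#'
#' @param before,after `segmentation_result`s (or plain counts).
#' @return percentage `100 * after / before`.
#' @export
relative_count <- function(before, after) {
  n_of <- function(x) if (inherits(x, "segmentation_result"))
    x$n_condensates else as.numeric(x)
  nb <- n_of(before); na <- n_of(after)
  if (nb <= 0) stop("'before' count must be > 0", call. = FALSE)
  100 * na / nb
}

#' Two-channel intensity profile along a line
#'
#' Samples both channels by bilinear interpolation along the segment from
#' `p0` to `p1`, averaging over `width_px` parallel lines perpendicular to
#' the segment, then min-max normalizes each channel to \[0, 1\]. The
#' Pearson correlation between the two normalized profiles quantifies
#' colocalization along the line.
#'
#' @param img a `condensate_image`.
#' @param p0,p1 segment endpoints, `c(row, col)` in pixels (inside the
#'   image).
#' @param width_px number of parallel sampling lines (odd; default 1).
#' @param n_samples samples along the segment (default: ceiling of segment
#'   length + 1).
#' @return a `line_profile`: data frame with `distance_px`, `scaffold`,
#'   `cargo` (normalized); attributes `pearson_r` and `degenerate`
#'   (per-channel flag set when a channel was constant and its profile
#'   returned as all zero).
#' @export
line_profile <- function(img, p0, p1, width_px = 1L, n_samples = NULL) {
  stopifnot(inherits(img, "condensate_image"))
  h <- nrow(img$scaffold); w <- ncol(img$scaffold)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w)
      stop("endpoint outside image", call. = FALSE)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length segment", call. = FALSE)
  if (is.null(n_samples)) n_samples <- ceiling(len) + 1L
  u <- (p1 - p0) / len                   # along-line unit vector
  v <- c(-u[2], u[1])                    # perpendicular
  offs <- seq_len(width_px) - (width_px + 1) / 2
  tgrid <- seq(0, len, length.out = n_samples)

  bilinear <- function(ch, r, c) {
    r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
    r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
    fr <- r - r0; fc <- c - c0
    ch[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      ch[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      ch[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      ch[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  sample_channel <- function(ch) {
    prof <- rowMeans(vapply(offs, function(o) {
      r <- p0[1] + tgrid * u[1] + o * v[1]
      c <- p0[2] + tgrid * u[2] + o * v[2]
      bilinear(ch, r, c)
    }, numeric(n_samples)))
    prof
  }
  s <- sample_channel(img$scaffold)
  g <- sample_channel(img$cargo)
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 1e-12 * max(abs(rng), 1))  # constant up to rounding
      list(x = rep(0, length(x)), degenerate = TRUE)
    else list(x = (x - rng[1]) / diff(rng), degenerate = FALSE)
  }
  ns <- norm01(s); ng <- norm01(g)
  r <- if (ns$degenerate || ng$degenerate) NA_real_ else cor(ns$x, ng$x)
  structure(data.frame(distance_px = tgrid, scaffold = ns$x, cargo = ng$x),
            pearson_r = r,
            degenerate = c(scaffold = ns$degenerate, cargo = ng$degenerate),
            class = c("line_profile", "data.frame"))
}

#' Write a two-channel condensate image as TIFF
#'
#' Channels are stored as two pages of a 32-bit float TIFF.
#'
#' @param img a `condensate_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_condensate_image <- function(img, path) {
  tiff::writeTIFF(list(img$scaffold / max(img$scaffold, 1),
                       img$cargo / max(img$cargo, 1)),
                  path, bits.per.sample = 32L)
  invisible(path)
}
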