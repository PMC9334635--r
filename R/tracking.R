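#' Background subtraction by border-ring median
#'
#' Subtracts, per frame, the median intensity of a border ring of the
#' image (a simple, documented stand-in for dedicated fluorescence
#' background-estimation algorithms), clamping at zero. Appropriate when
#' the signal is confined to the image interior.
#'
#' @param image Numeric intensity matrix.
#' @param border_width Width (pixels) of the border ring; default 3.
#' @return Background-subtracted intensity matrix.
#' @export
subtract_background <- function(image, border_width = 3) {
  nx <- nrow(image)
  ny <- ncol(image)
  if (2 * border_width >= min(nx, ny)) {
    stop("border ring covers the whole image; reduce border_width")
  }
  ring <- matrix(TRUE, nx, ny)
  ring[(border_width + 1):(nx - border_width),
       (border_width + 1):(ny - border_width)] <- FALSE
  pmax(image - stats::median(image[ring]), 0)
}

#' Fluorescence center of mass of an image
#'
#' `r_CM = sum(r * I(r)) / sum(I(r))` over pixel centers, in cavity
#' coordinates.
#'
#' @param image Numeric intensity matrix; `image[i, j]` at
#'   `x = origin[1] + (i-1)*pixel_size`, `y = origin[2] + (j-1)*pixel_size`.
#' @param pixel_size Pixel pitch (um).
#' @param origin Coordinates (um) of pixel `[1, 1]`'s center.
#' @return Numeric `c(x, y)` (um), or an error if the total intensity is
#'   not positive.
#' @export
fluorescence_cm <- function(image, pixel_size, origin = c(0, 0)) {
  tot <- sum(image)
  if (!is.finite(tot) || tot <= 0) {
    stop("fluorescence_cm: zero total intensity")
  }
  xs <- origin[1] + (seq_len(nrow(image)) - 1) * pixel_size
  ys <- origin[2] + (seq_len(ncol(image)) - 1) * pixel_size
  c(sum(rowSums(image) * xs) / tot, sum(colSums(image) * ys) / tot)
}

#' Track fluorescence centroids through a movie
#'
#' Applies background subtraction and centroid extraction frame by frame
#' to each channel of a movie. Frames in which any channel has zero total
#' intensity after background subtraction are flagged and dropped
#' consistently across channels (with a warning, since dropping breaks
#' the uniform time base).
#'
#' After subtraction, pixels below `noise_sigmas` robust standard
#' deviations of the border ring are zeroed, so residual shot noise
#' (clipped at zero by the subtraction) does not bias the centroid toward
#' the frame center.
#'
#' @param movie List of per-channel image stacks, each a 3D array
#'   `[x, y, frame]`.
#' @param pixel_size Pixel pitch (um).
#' @param frame_interval Time between frames (s).
#' @param origin Coordinates (um) of pixel `[1, 1, ]`'s center.
#' @param border_width Border-ring width for background subtraction.
#' @param noise_sigmas Noise-floor threshold in units of the border-ring
#'   robust SD (default 4).
#' @return List of `trajectory` objects, one per channel.
#' @export
track_movie <- function(movie, pixel_size, frame_interval,
                        origin = c(0, 0), border_width = 3,
                        noise_sigmas = 4) {
  n_frames <- dim(movie[[1]])[3]
  if (n_frames < 2) stop("track_movie: need at least 2 frames")
  n_chan <- length(movie)
  pos <- lapply(seq_len(n_chan), function(c) matrix(NA_real_, n_frames, 2))
  flagged <- rep(FALSE, n_frames)
  for (f in seq_len(n_frames)) {
    for (c in seq_len(n_chan)) {
      raw <- movie[[c]][, , f]
      img <- subtract_background(raw, border_width)
      ring <- matrix(TRUE, nrow(raw), ncol(raw))
      ring[(border_width + 1):(nrow(raw) - border_width),
           (border_width + 1):(ncol(raw) - border_width)] <- FALSE
      floor_level <- noise_sigmas * stats::mad(raw[ring])
      img[img < floor_level] <- 0
      if (sum(img) <= 0) {
        flagged[f] <- TRUE
      } else {
        pos[[c]][f, ] <- fluorescence_cm(img, pixel_size, origin)
      }
    }
  }
  if (all(flagged)) stop("track_movie: every frame flagged (no signal)")
  if (any(flagged)) {
    warning(sprintf("track_movie: dropped %d flagged frame(s)", sum(flagged)))
  }
  keep <- !flagged
  lapply(seq_len(n_chan), function(c) {
    trajectory(pos[[c]][keep, 1], pos[[c]][keep, 2], frame_interval,
               label = sprintf("channel%d", c))
  })
}

#' Position histogram of trajectories over the cavity
#'
#' Normalized 2D histogram of all positions (pooled over the supplied
#' trajectories) on the canonical cavity grid; the estimator of the
#' position probability density `P_CM` / `P_plasmid`. Positions outside
#' the cavity are clipped into the nearest grid cell and their count
#' reported via the `n_outside` attribute.
#'
#' @param trajs List of `trajectory` objects (or a single one), or a
#'   two-column matrix of positions.
#' @param cavity A `cavity_geometry`.
#' @param bin_size Histogram bin (um), default 0.05.
#' @return A probability `scalar_field` with attribute `n_outside`.
#' @export
position_histogram <- function(trajs, cavity, bin_size = 0.05) {
  if (is.matrix(trajs)) {
    x <- trajs[, 1]; y <- trajs[, 2]
  } else {
    if (inherits(trajs, "trajectory")) trajs <- list(trajs)
    x <- unlist(lapply(trajs, `[[`, "x"))
    y <- unlist(lapply(trajs, `[[`, "y"))
  }
  grid <- cavity_grid(cavity, bin_size, cover = "intersect")
  n_outside <- sum(!cavity_contains(cavity, x, y))
  h <- bin_size
  i <- floor((x - (grid$origin[1] - h / 2)) / h) + 1
  j <- floor((y - (grid$origin[2] - h / 2)) / h) + 1
  i <- pmin(pmax(as.integer(i), 1L), nrow(grid$values))
  j <- pmin(pmax(as.integer(j), 1L), ncol(grid$values))
  counts <- matrix(0, nrow(grid$values), ncol(grid$values))
  tab <- table(factor(i, seq_len(nrow(counts))),
               factor(j, seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  vals <- counts / (sum(counts) * h^2)
  out <- scalar_field(vals, h, grid$origin, grid$mask, cavity = cavity,
                      role = "probability")
  attr(out, "n_outside") <- n_outside
  out
}

#' Free-energy map from a position histogram
#'
#' `F = -kBT log P`, minimum shifted to zero; delegates to
#' [landscape_from_probability()] (single implementation for both the
#' descriptive map and the dynamics landscape).
#'
#' @inheritParams landscape_from_probability
#' @return An energy `scalar_field` (kBT).
#' @export
free_energy_map <- function(prob, floor_fraction = 0.5) {
  landscape_from_probability(prob, floor_fraction)
}
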