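#' Configuration for the two-blob chain surrogate
#'
#' The two confined chains are represented as point "blobs" carrying a
#' soft Gaussian-core mutual repulsion
#' `U_pair = pair_strength * exp(-|r1 - r2|^2 / (2 pair_range^2))`
#' plus the boundary-integrated wall repulsion acting on each; the pair
#' analyzes exactly like the two-chain experiment (position histograms,
#' separation vector, order parameter, pole swaps). Defaults emulate two
#' cavity-confined lambda-DNA coils: `pair_range` 0.7 um (the coil
#' gyration radius), `pair_strength` 10 kBT (the order-10-kBT overlap
#' penalty of two cavity-confined self-avoiding coils), a wall kernel reaching ~2 kBT about 0.2 um from
#' the wall, and `diffusivity` 0.3 um^2 s^-1 for the confined coil.
#'
#' @param cavity A `cavity_geometry`.
#' @param pair_strength Gaussian-core amplitude (kBT).
#' @param pair_range Gaussian-core width (um).
#' @param wall_kernel A `kernel_params` for the wall repulsion.
#' @param diffusivity Blob diffusivity (um^2 s^-1).
#' @param time_step Integration step (s).
#' @param n_frames Recorded frames.
#' @param frame_interval Time between recorded frames (s); must be an
#'   integer multiple of `time_step`.
#' @param burn_in_frames Frames integrated and discarded before recording.
#' @param seed Integer RNG seed.
#' @param grid_spacing Spacing of the precomputed wall-potential grid.
#' @return An object of class `two_blob_config`.
#' @export
two_blob_config <- function(cavity, pair_strength = 10, pair_range = 0.7,
                            wall_kernel = kernel_params("exponential",
                                                        wall_strength = 20,
                                                        decay_range = 0.15),
                            diffusivity = 0.3, time_step = 0.002,
                            n_frames = 30000, frame_interval = 0.05,
                            burn_in_frames = 200, seed = 1,
                            grid_spacing = 0.025) {
  stopifnot(pair_range > 0, pair_strength >= 0, diffusivity > 0,
            time_step > 0, n_frames >= 2)
  n_sub <- frame_interval / time_step
  if (abs(n_sub - round(n_sub)) > 1e-9) {
    stop("frame_interval must be an integer multiple of time_step")
  }
  structure(
    list(cavity = cavity, pair_strength = pair_strength,
         pair_range = pair_range, wall_kernel = wall_kernel,
         diffusivity = diffusivity, time_step = time_step,
         n_frames = n_frames, frame_interval = frame_interval,
         burn_in_frames = burn_in_frames, seed = as.integer(seed),
         grid_spacing = grid_spacing),
    class = "two_blob_config"
  )
}

#' Simulate two mutually repelling blobs in a cavity
#'
#' Coupled overdamped Langevin dynamics of two blobs under the Gaussian
#' pair repulsion and the gridded wall potential, Euler-Maruyama at
#' `time_step`, recorded every `frame_interval`, with rejection-resampling
#' reflection at the cavity wall. Deterministic under the configured seed.
#'
#' @param config A `two_blob_config`.
#' @return List of two `trajectory` objects.
#' @export
simulate_two_blobs <- function(config) {
  cav <- config$cavity
  step <- sqrt(2 * config$diffusivity * config$time_step)
  if (step >= config$grid_spacing * 2) {
    stop("time_step too large for the wall-potential grid")
  }
  wall <- wall_potential(cav, config$wall_kernel,
                         grid_spacing = config$grid_spacing)
  vals <- wall$values
  vmax <- max(vals[wall$mask])
  vals[!is.finite(vals)] <- vmax
  n_sub <- as.integer(round(config$frame_interval / config$time_step))
  set.seed(config$seed)
  total <- config$n_frames + config$burn_in_frames
  pos <- cpp_two_blob_sim(vals, wall$origin[1], wall$origin[2],
                          wall$spacing, cav$semi_major, cav$semi_minor,
                          -cav$semi_major / 2, 0, cav$semi_major / 2, 0,
                          config$pair_strength, config$pair_range,
                          config$diffusivity, config$time_step,
                          total, n_sub)
  keep <- (config$burn_in_frames + 1):(total + 1)
  list(
    trajectory(pos[keep, 1], pos[keep, 2], config$frame_interval, "blob1"),
    trajectory(pos[keep, 3], pos[keep, 4], config$frame_interval, "blob2")
  )
}

#' Sample positions from a Boltzmann distribution
#'
#' Draws `n` i.i.d. positions with density proportional to
#' `exp(-U(r)/kBT)` over the cavity interior by rejection sampling: the
#' proposal is uniform over the grid bounding box and the acceptance
#' probability is the bilinear interpolant of `exp(-(U - Umin))` (zero
#' outside the cavity). Deterministic under the seed.
#'
#' @param potential A potential or energy `scalar_field` (kBT) carrying
#'   its cavity; exterior values may be NA (treated as impenetrable).
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @return An `n x 2` matrix of positions (um).
#' @export
sample_boltzmann_positions <- function(potential, n, seed = 1) {
  cav <- potential$cavity
  if (is.null(cav)) stop("potential field must carry its cavity")
  u <- potential$values
  u_min <- min(u[potential$mask], na.rm = TRUE)
  w <- exp(-(u - u_min))
  w[!is.finite(w)] <- 0
  wf <- scalar_field(w, potential$spacing, potential$origin,
                     potential$mask, cavity = cav, role = "generic")
  co <- field_coords(potential)
  xr <- range(co$x)
  yr <- range(co$y)
  set.seed(seed)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tried <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 1000L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    acc_p <- field_interp(wf, px, py)
    acc_p[!cavity_contains(cav, px, py)] <- 0
    keep <- stats::runif(m) < acc_p
    tried <- tried + m
    k <- which(keep)
    if (length(k) > 0) {
      k <- k[seq_len(min(length(k), n - got))]
      out[(got + 1):(got + length(k)), ] <- cbind(px[k], py[k])
      got <- got + length(k)
    }
    if (tried > 1e4 && got / tried < 1e-4) {
      stop("rejection acceptance rate < 1e-4; supply a tighter envelope (e.g. shift the potential minimum)")
    }
  }
  out
}

#' Crowding-modified model parameters
#'
#' Emulates the effect of a neutral-crowder volume fraction `v_phi` at the
#' parameter level: crowders accumulating at the cavity perimeter extend
#' the effective wall repulsion (decay range scaled by `1 + c1 * v_phi`)
#' and compact the large chain, strengthening exclusion (`a` scaled by
#' `1 + c2 * v_phi`). The scalings encode observed phenomenology
#' (inward displacement of the plasmid density edge, enhanced
#' segregation), not a microscopic crowder model.
#'
#' @param exclusion An `exclusion_params`.
#' @param kernel A `kernel_params` (exponential family).
#' @param v_phi Crowder volume fraction in `[0, 0.5)`.
#' @param c1,c2 Phenomenological coefficients (defaults 5 and 5).
#' @return List with modified `exclusion` and `kernel`.
#' @export
make_crowded_variant <- function(exclusion, kernel, v_phi, c1 = 5, c2 = 5) {
  stopifnot(v_phi >= 0, v_phi < 0.5)
  list(
    exclusion = exclusion_params(exclusion$a_coefficient * (1 + c2 * v_phi)),
    kernel = kernel_params(kernel$family,
                           wall_strength = kernel$wall_strength,
                           decay_range = kernel$decay_range * (1 + c1 * v_phi),
                           epsilon = kernel$epsilon, sigma = kernel$sigma)
  )
}

#' Rendering configuration for synthetic fluorescence movies
#'
#' @param pixel_size Pixel pitch (um).
#' @param image_shape Two-vector of image dimensions (pixels).
#' @param psf_sigma Gaussian point-spread width (um); must be at least
#'   half a pixel.
#' @param photons_per_frame Integrated blob intensity per frame (counts).
#' @param background_level Constant background (counts / pixel).
#' @param noise_model "poisson", "gaussian" (sd = sqrt(background + 1)),
#'   or "none".
#' @param seed Integer RNG seed.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size = 0.05, image_shape = c(64, 64),
                          psf_sigma = 0.1, photons_per_frame = 5000,
                          background_level = 10,
                          noise_model = c("poisson", "gaussian", "none"),
                          seed = 1) {
  stopifnot(psf_sigma >= pixel_size / 2, photons_per_frame > 0)
  structure(
    list(pixel_size = pixel_size, image_shape = as.integer(image_shape),
         psf_sigma = psf_sigma, photons_per_frame = photons_per_frame,
         background_level = background_level,
         noise_model = match.arg(noise_model), seed = as.integer(seed)),
    class = "render_config"
  )
}

#' Render trajectories into synthetic fluorescence movies
#'
#' Each trajectory becomes one channel: per frame, a Gaussian blob of
#' integrated intensity `photons_per_frame` centered at the particle
#' position, plus the constant background, with the configured shot
#' noise. The image is centered on the cavity frame (pixel grid centered
#' at the origin). Deterministic under the seed.
#'
#' @param trajs List of `trajectory` objects (one per channel).
#' @param config A `render_config`.
#' @return List of per-channel 3D arrays `[x, y, frame]`, with attributes
#'   `pixel_size` and `origin`.
#' @export
render_movie <- function(trajs, config) {
  nx <- config$image_shape[1]
  ny <- config$image_shape[2]
  ps <- config$pixel_size
  origin <- c(-(nx - 1) / 2 * ps, -(ny - 1) / 2 * ps)
  xs <- origin[1] + (seq_len(nx) - 1) * ps
  ys <- origin[2] + (seq_len(ny) - 1) * ps
  n_frames <- length(trajs[[1]]$x)
  set.seed(config$seed)
  s2 <- config$psf_sigma^2
  amp <- config$photons_per_frame * ps^2 / (2 * pi * s2)
  lapply(trajs, function(tr) {
    stack <- array(0, dim = c(nx, ny, n_frames))
    clipped <- logical(n_frames)
    for (f in seq_len(n_frames)) {
      gx <- exp(-(xs - tr$x[f])^2 / (2 * s2))
      gy <- exp(-(ys - tr$y[f])^2 / (2 * s2))
      img <- amp * outer(gx, gy) + config$background_level
      # blob mass lost off the frame edge
      clipped[f] <- abs(tr$x[f]) > max(xs) - 3 * config$psf_sigma ||
        abs(tr$y[f]) > max(ys) - 3 * config$psf_sigma
      img <- switch(config$noise_model,
        poisson = matrix(stats::rpois(length(img), img), nx, ny),
        gaussian = img + stats::rnorm(length(img),
                                      sd = sqrt(config$background_level + 1)),
        none = img
      )
      stack[, , f] <- img
    }
    if (any(clipped)) {
      warning(sprintf("render_movie: blob near frame edge in %d frame(s)",
                      sum(clipped)))
    }
    attr(stack, "pixel_size") <- ps
    attr(stack, "origin") <- origin
    attr(stack, "clipped") <- clipped
    stack
  })
}

#' Gyration radius of dextran from molecular weight
#'
#' Empirical relation `R_g = 0.066 * Mw^0.43` (nm, Mw in g/mol) for
#' dextran crowders.
#'
#' @param molecular_weight Molecular weight (g/mol), > 0.
#' @return Gyration radius (nm).
#' @export
dextran_radius <- function(molecular_weight) {
  stopifnot(all(molecular_weight > 0))
  0.066 * molecular_weight^0.43
}

#' Ionic-strength correction of a coil gyration radius
#'
#' For a self-avoiding coil, `R_g` scales with the effective chain width
#' as `w^(1/5)`; this rescales a gyration radius measured at one
#' effective width to another (e.g. a light-scattering value at high salt
#' rescaled to a low-salt buffer where the DNA effective width is
#' larger).
#'
#' @param rg_reference Measured gyration radius (any length unit).
#' @param width_reference Effective chain width in the measurement buffer.
#' @param width_target Effective chain width in the target buffer.
#' @return Rescaled gyration radius (same unit as `rg_reference`).
#' @export
coil_radius_width_corrected <- function(rg_reference, width_reference,
                                        width_target) {
  stopifnot(width_reference > 0, width_target > 0)
  rg_reference * (width_target / width_reference)^(1 / 5)
}
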