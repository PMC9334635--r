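#' Free-energy landscape from a position distribution
#'
#' `F(r) = -kBT log P(r)`, with the probability floored at
#' `floor_fraction` times the smallest positive interior value so that
#' never-visited (and exterior) cells are strongly repulsive but finite,
#' and the minimum shifted to zero. The inverse of
#' [boltzmann_distribution()] on cells above the floor.
#'
#' @param prob A probability `scalar_field`.
#' @param floor_fraction Fraction of the smallest positive interior
#'   probability used as the floor, in `(0, 1]`; default 0.5.
#' @return An energy `scalar_field` (kBT). Exterior cells carry the
#'   (finite) floored maximum so gradients remain defined for dynamics up
#'   to the boundary.
#' @export
landscape_from_probability <- function(prob, floor_fraction = 0.5) {
  stopifnot(floor_fraction > 0, floor_fraction <= 1)
  p_in <- prob$values[prob$mask]
  pos <- p_in[p_in > 0]
  if (length(pos) == 0) stop("landscape_from_probability: all-zero field")
  floor_p <- floor_fraction * min(pos)
  vals <- -log(pmax(prob$values, floor_p))
  vals <- vals - min(vals[prob$mask])
  scalar_field(vals, prob$spacing, prob$origin, prob$mask,
               cavity = prob$cavity, role = "energy")
}

#' Brownian-dynamics configuration
#'
#' Settings for the overdamped Langevin (Euler-Maruyama) simulation of a
#' point particle on a free-energy landscape. The diffusivity and time
#' step defaults follow the package's stated conventions: `D = 0.5`
#' um^2 s^-1 (typical for a ~100 nm particle in aqueous buffer) and, when
#' `time_step` is NULL, `dt` such that the thermal step length
#' `sqrt(2 D dt)` is 0.4 grid spacings — small enough to resolve the
#' landscape, and enforced to stay below one spacing.
#'
#' @param diffusivity Diffusion coefficient (um^2 s^-1).
#' @param time_step Time step (s), or NULL to derive from the landscape
#'   spacing at simulation time.
#' @param n_steps Steps per clip (default 3000).
#' @param n_clips Number of independent clips (default 250).
#' @param seed Integer RNG seed.
#' @param start_rule "stationary_sample" (draw the start from the
#'   Boltzmann distribution of the landscape) or "center".
#' @return An object of class `bd_config`.
#' @export
bd_config <- function(diffusivity = 0.5, time_step = NULL, n_steps = 3000,
                      n_clips = 250, seed = 1,
                      start_rule = c("stationary_sample", "center")) {
  stopifnot(diffusivity > 0, n_steps >= 2, n_clips >= 1)
  structure(
    list(diffusivity = diffusivity, time_step = time_step,
         n_steps = n_steps, n_clips = n_clips, seed = as.integer(seed),
         start_rule = match.arg(start_rule)),
    class = "bd_config"
  )
}

#' Position trajectory
#'
#' Time series of 2D positions at a uniform frame interval.
#'
#' @param x,y Position coordinates (um).
#' @param frame_interval Time between frames (s).
#' @param label Molecule / channel identifier.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(x, y, frame_interval, label = "") {
  stopifnot(length(x) == length(y), length(x) >= 2, frame_interval > 0)
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         frame_interval = frame_interval, label = label),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d frames at %.4g s\n",
              x$label, length(x$x), x$frame_interval))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = (seq_along(x$x) - 1) * x$frame_interval,
             x_um = x$x, y_um = x$y, label = x$label)
}

#' Brownian dynamics on a free-energy landscape
#'
#' Simulates `n_clips` independent overdamped trajectories
#' `dr = -D grad(F) dt + sqrt(2 D dt) eta` on the landscape `F` (kBT),
#' with the gradient taken as central differences of the bilinear
#' interpolant and a rejection-resampling reflecting boundary at the
#' cavity wall (a step that would leave the cavity is rediscarded and its
#' noise redrawn). Each clip is seeded deterministically from
#' `config$seed`, so identical inputs give bitwise-identical output.
#'
#' @param landscape An energy `scalar_field` (kBT) carrying its cavity.
#' @param cavity A `cavity_geometry` (defaults to the landscape's).
#' @param config A `bd_config`.
#' @return List of `trajectory` objects (frame interval = time step).
#' @export
simulate_bd <- function(landscape, cavity = landscape$cavity,
                        config = bd_config()) {
  if (is.null(cavity)) stop("simulate_bd: no cavity available")
  h <- landscape$spacing
  dt <- config$time_step %||% (0.4 * h)^2 / (2 * config$diffusivity)
  if (sqrt(2 * config$diffusivity * dt) >= h) {
    stop("time_step too large: thermal step exceeds the grid spacing")
  }
  # exterior cells must be finite for interpolation; fill NA with the max
  vals <- landscape$values
  vmax <- max(vals[landscape$mask])
  vals[!is.finite(vals)] <- vmax
  starts <- matrix(0, config$n_clips, 2)
  if (config$start_rule == "stationary_sample") {
    boltz <- boltzmann_distribution(
      scalar_field(vals, h, landscape$origin, landscape$mask,
                   cavity = cavity, role = "potential")
    )
    starts <- sample_boltzmann_positions(boltz_to_potential(boltz),
                                         config$n_clips,
                                         seed = config$seed + 10007L)
  }
  out <- vector("list", config$n_clips)
  for (k in seq_len(config$n_clips)) {
    set.seed(config$seed + k)
    pos <- cpp_bd_sim(vals, landscape$origin[1], landscape$origin[2], h,
                      cavity$semi_major, cavity$semi_minor,
                      starts[k, 1], starts[k, 2],
                      config$diffusivity, dt, config$n_steps)
    out[[k]] <- trajectory(pos[, 1], pos[, 2], dt,
                           label = sprintf("clip%03d", k))
  }
  out
}

# re-express a probability field as the potential whose Boltzmann
# distribution it is (for stationary-start sampling)
boltz_to_potential <- function(prob) {
  landscape_from_probability(prob, floor_fraction = 1)
}

#' Pooled occupancy histogram of simulated trajectories
#'
#' Bins all positions of a set of trajectories onto the grid of a
#' reference field; used to compare BD occupancy with the Boltzmann
#' distribution of the landscape (ergodicity check).
#'
#' @param trajs List of `trajectory` objects.
#' @param template A `scalar_field` providing the grid.
#' @return A probability `scalar_field`.
#' @export
occupancy_histogram <- function(trajs, template) {
  x <- unlist(lapply(trajs, `[[`, "x"))
  y <- unlist(lapply(trajs, `[[`, "y"))
  h <- template$spacing
  i <- floor((x - (template$origin[1] - h / 2)) / h) + 1
  j <- floor((y - (template$origin[2] - h / 2)) / h) + 1
  i <- pmin(pmax(as.integer(i), 1L), nrow(template$values))
  j <- pmin(pmax(as.integer(j), 1L), ncol(template$values))
  counts <- matrix(0, nrow(template$values), ncol(template$values))
  tab <- table(factor(i, seq_len(nrow(counts))),
               factor(j, seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  vals <- counts / (sum(counts) * h^2)
  scalar_field(vals, h, template$origin, template$mask,
               cavity = template$cavity, role = "probability")
}

#' Total-variation distance between two probability fields
#'
#' `0.5 * sum |p_i - q_i| * spacing^2` over the union of cells.
#'
#' @param p,q Probability `scalar_field`s on the same grid.
#' @return Total-variation distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (!identical(dim(p$values), dim(q$values))) {
    stop("total_variation: grid mismatch")
  }
  0.5 * sum(abs(p$values - q$values)) * p$spacing^2
}
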