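#' Wall-kernel parameters
#'
#' The plasmid interacts with each arc-length patch of the cavity boundary
#' through a short-ranged repulsive kernel `u(d)` (units kBT per um of
#' boundary). Two families are supported:
#' \describe{
#'   \item{exponential}{`u(d) = wall_strength * exp(-d / decay_range)`;
#'     `wall_strength` (kBT um^-1) sets the depletion strength, and
#'     `decay_range` (um, the standoff scale `r_b`) sets how far the
#'     repulsion reaches.}
#'   \item{wca}{truncated-shifted Lennard-Jones (Weeks-Chandler-Andersen):
#'     `u(d) = 4 eps ((sigma/d)^12 - (sigma/d)^6) + eps` for
#'     `d < 2^(1/6) sigma`, 0 beyond the cutoff; values are capped at
#'     1e3 kBT um^-1 so `d -> 0` stays finite (the cap only affects
#'     positions the particle never occupies).}
#' }
#'
#' @param family "exponential" or "wca".
#' @param wall_strength Exponential amplitude (kBT um^-1).
#' @param decay_range Exponential decay length (um).
#' @param epsilon WCA energy scale (kBT um^-1).
#' @param sigma WCA length scale (um).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(family = c("exponential", "wca"),
                          wall_strength = NULL, decay_range = NULL,
                          epsilon = NULL, sigma = NULL) {
  family <- match.arg(family)
  if (family == "exponential") {
    stopifnot(!is.null(wall_strength), !is.null(decay_range),
              wall_strength > 0, decay_range > 0)
  } else {
    stopifnot(!is.null(epsilon), !is.null(sigma), epsilon > 0, sigma > 0)
  }
  structure(
    list(family = family, wall_strength = wall_strength,
         decay_range = decay_range, epsilon = epsilon, sigma = sigma),
    class = "kernel_params"
  )
}

#' Chain-exclusion parameters
#'
#' The plasmid is excluded from the chain-occupied region through the
#' linear coupling `U_chain(r) = a * rho(r)`, with `a` (kBT um^3 bp^-1) the
#' proportionality constant measuring the strength of exclusion.
#'
#' @param a_coefficient Exclusion coefficient (kBT um^3 bp^-1), >= 0.
#' @return An object of class `exclusion_params`.
#' @export
exclusion_params <- function(a_coefficient) {
  stopifnot(is.finite(a_coefficient), a_coefficient >= 0)
  structure(list(a_coefficient = a_coefficient), class = "exclusion_params")
}

.wca_cap <- 1e3

#' Evaluate the wall kernel at a distance
#'
#' @param params A `kernel_params`.
#' @param distance Distance(s) from a boundary patch (um), >= 0.
#' @return Kernel value(s), kBT um^-1.
#' @export
kernel_value <- function(params, distance) {
  stopifnot(all(distance >= 0))
  if (params$family == "exponential") {
    params$wall_strength * exp(-distance / params$decay_range)
  } else {
    cutoff <- 2^(1 / 6) * params$sigma
    out <- distance
    out[] <- 0
    inside <- distance < cutoff
    d <- pmax(distance[inside], 1e-12)
    sr6 <- (params$sigma / d)^6
    out[inside] <- pmin(4 * params$epsilon * (sr6^2 - sr6) + params$epsilon,
                        .wca_cap)
    out
  }
}

# distances from points (x, y) to every boundary-segment midpoint;
# returns a length(x) x n_segments matrix
.segment_distances <- function(segs, x, y) {
  sqrt(outer(x, segs$x, "-")^2 + outer(y, segs$y, "-")^2)
}

# wall potential at arbitrary points by direct summation over patches
.wall_at_points <- function(segs, params, x, y) {
  D <- .segment_distances(segs, x, y)
  as.numeric(kernel_value(params, D) %*% segs$arc_length)
}

#' Boundary-integrated wall potential on the cavity grid
#'
#' `U_wall(r) = sum over boundary patches of u(|r_s - r|) * ds`: the line
#' integral of the kernel along the cavity boundary, discretized with
#' `n_segments` patches. The potential rises toward the boundary; exterior
#' cells are NA.
#'
#' @param cavity A `cavity_geometry`.
#' @param params A `kernel_params`.
#' @param grid_spacing Grid spacing (um), default 0.025.
#' @param n_segments Number of boundary patches (>= 180; default 720).
#' @return A potential `scalar_field` (kBT).
#' @export
wall_potential <- function(cavity, params, grid_spacing = 0.025,
                           n_segments = 720) {
  if (n_segments < 180) stop("n_segments must be >= 180")
  grid <- cavity_grid(cavity, grid_spacing, cover = "center")
  segs <- boundary_segments(cavity, n_segments)
  co <- field_coords(grid)
  ij <- which(grid$mask, arr.ind = TRUE)
  u <- .wall_at_points(segs, params, co$x[ij[, 1]], co$y[ij[, 2]])
  vals <- matrix(NA_real_, nrow(grid$mask), ncol(grid$mask))
  vals[grid$mask] <- u
  scalar_field(vals, grid_spacing, grid$origin, grid$mask, cavity = cavity,
               role = "potential")
}

#' Wall potential at arbitrary points
#'
#' Evaluates the boundary line integral `U_wall(r)` directly at the given
#' points (no grid): the same discretized integral as [wall_potential()],
#' summed over `n_segments` patches.
#'
#' @inheritParams wall_potential
#' @param x,y Evaluation points (um).
#' @return Numeric vector of potentials (kBT).
#' @export
wall_potential_at <- function(cavity, params, x, y, n_segments = 720) {
  segs <- boundary_segments(cavity, n_segments)
  .wall_at_points(segs, params, x, y)
}

#' Reference plasmid-model parameters
#'
#' A parameter set at the scale of the fitted plasmid-exclusion model:
#' exclusion coefficient `a = 1.1e-6` kBT um^3 bp^-1 and an exponential
#' wall kernel with `decay_range` 0.1 um whose strength is calibrated so
#' the boundary potential reaches 2 kBT at 0.19 um from the wall along
#' the minor axis — the interaction range scale of a ~100-nm plasmid.
#' Useful as a realistic operating point for simulations and examples.
#'
#' @param cavity A `cavity_geometry` (the calibration is done on this
#'   cavity).
#' @param decay_range Wall decay range (um), default 0.1.
#' @param range_2kBT Distance from the wall (um) at which the calibrated
#'   wall potential equals 2 kBT; default 0.19.
#' @return List with `exclusion` (`exclusion_params`) and `kernel`
#'   (`kernel_params`).
#' @export
reference_model_params <- function(cavity, decay_range = 0.1,
                                   range_2kBT = 0.19) {
  unit <- kernel_params("exponential", wall_strength = 1,
                        decay_range = decay_range)
  p <- c(0, cavity$semi_minor - range_2kBT)
  u1 <- wall_potential_at(cavity, unit, p[1], p[2])
  list(
    exclusion = exclusion_params(1.1e-6),
    kernel = kernel_params("exponential", wall_strength = 2 / u1,
                           decay_range = decay_range)
  )
}

#' Chain-exclusion potential from a concentration field
#'
#' Pointwise `U = a * rho`; zero wherever the concentration vanishes.
#'
#' @param density A concentration `scalar_field` (bp um^-3).
#' @param params An `exclusion_params`.
#' @return A potential `scalar_field` (kBT) on the same grid.
#' @export
exclusion_potential <- function(density, params) {
  if (density$role != "concentration") {
    stop("exclusion_potential expects a concentration field")
  }
  if (any(density$values[density$mask] < 0)) {
    stop("negative concentration values")
  }
  vals <- matrix(NA_real_, nrow(density$values), ncol(density$values))
  vals[density$mask] <- params$a_coefficient * density$values[density$mask]
  scalar_field(vals, density$spacing, density$origin, density$mask,
               cavity = density$cavity, role = "potential")
}

#' Total plasmid potential
#'
#' `U_p = U_chain + U_wall`, the superposition of chain exclusion and wall
#' repulsion whose competition carves the off-center segregation zone.
#'
#' @param exclusion,wall Potential `scalar_field`s on the same grid.
#' @return A potential `scalar_field` (kBT).
#' @export
total_potential <- function(exclusion, wall) {
  if (!identical(dim(exclusion$values), dim(wall$values)) ||
      abs(exclusion$spacing - wall$spacing) > 1e-12 ||
      !identical(exclusion$mask, wall$mask)) {
    stop("total_potential: grid mismatch")
  }
  vals <- exclusion$values + wall$values
  scalar_field(vals, wall$spacing, wall$origin, wall$mask,
               cavity = wall$cavity, role = "potential")
}

#' Boltzmann position distribution from a potential
#'
#' `P(r) proportional to exp(-U(r)/kBT)`, normalized so the interior
#' probability mass is 1. Invariant under adding a constant to `U`.
#'
#' @param potential A potential `scalar_field` (kBT).
#' @return A probability `scalar_field` (um^-2).
#' @export
boltzmann_distribution <- function(potential) {
  u <- potential$values[potential$mask]
  if (!any(is.finite(u))) stop("boltzmann_distribution: no finite potential")
  p <- exp(-(u - min(u)))
  z <- sum(p) * potential$spacing^2
  vals <- matrix(0, nrow(potential$values), ncol(potential$values))
  vals[potential$mask] <- p / z
  scalar_field(vals, potential$spacing, potential$origin, potential$mask,
               cavity = potential$cavity, role = "probability")
}

#' Distance from the wall at which the wall potential hits a threshold
#'
#' Measures, along a ray from the center (by default the minor axis, where
#' the boundary is nearest), the distance inward from the boundary at which
#' the boundary-integrated wall potential equals `threshold` (default
#' 2 kBT, corresponding to ~90% suppression of occupancy). Uses bisection
#' on the continuous line-integral evaluation, not the gridded field.
#'
#' @param cavity A `cavity_geometry`.
#' @param params A `kernel_params`.
#' @param threshold Potential threshold (kBT), > 0.
#' @param direction Unit-vector direction of the ray; default the minor
#'   axis `c(0, 1)`.
#' @param n_segments Boundary patches for the line integral.
#' @return Distance (um) inward from the boundary.
#' @export
range_at_threshold <- function(cavity, params, threshold = 2,
                               direction = c(0, 1), n_segments = 720) {
  stopifnot(threshold > 0)
  direction <- direction / sqrt(sum(direction^2))
  segs <- boundary_segments(cavity, n_segments)
  # boundary point along the ray: scale so the point is on the ellipse
  s_max <- 1 / sqrt((direction[1] / cavity$semi_major)^2 +
                    (direction[2] / cavity$semi_minor)^2)
  u_of <- function(d) {
    p <- direction * (s_max - d)
    .wall_at_points(segs, params, p[1], p[2]) - threshold
  }
  d_lo <- 1e-4 * s_max
  if (u_of(d_lo) < 0) {
    stop("threshold exceeds the wall potential near the boundary")
  }
  if (u_of(s_max) > 0) {
    stop("threshold never reached: wall potential exceeds it everywhere along the ray")
  }
  stats::uniroot(u_of, c(d_lo, s_max), tol = 1e-6)$root
}

#' Effective plasmid radius from the fitted exclusion coefficient
#'
#' Converts the exclusion coefficient `a` (kBT um^3 bp^-1) to an effective
#' hard-sphere radius under the Flory repulsion picture: the excluded
#' volume per Kuhn segment is `v = a * basepairs_per_kuhn`, and the
#' plasmid is approximated as a sphere, `v = (4/3) pi r_p^3`. Note that
#' under this literal sphere approximation the fitted magnitude
#' `a ~ 1.1e-6 kBT um^3 bp^-1` yields `r_p ~ 43 nm`, smaller than
#' light-scattering estimates of the plasmid size; the conversion is
#' provided for order-of-magnitude use only.
#'
#' @param params An `exclusion_params`.
#' @param basepairs_per_kuhn Base pairs per Kuhn segment (default 300).
#' @return Effective radius (nm).
#' @export
effective_plasmid_radius <- function(params, basepairs_per_kuhn = 300) {
  v <- params$a_coefficient * basepairs_per_kuhn # um^3
  1e3 * (3 * v / (4 * pi))^(1 / 3)
}
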