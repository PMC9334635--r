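#' Scalar fields on a cavity-masked grid
#'
#' A `scalar_field` holds values on a regular Cartesian grid whose cell
#' edges lie at integer multiples of the spacing (edge-aligned), masked to
#' the cavity interior. Edge alignment guarantees that a fine model grid
#' (e.g. 25 nm) bins exactly onto the canonical coarse comparison grid
#' (e.g. 50 nm) for the same cavity. Exterior cells are flagged by the mask
#' and are never silently folded into integrals; their stored value depends
#' on the field's role (0 for concentration/probability by the boundary
#' condition, NA for potentials, a finite ceiling for free energies used in
#' dynamics).
#'
#' @param values Numeric matrix, `values[i, j]` at `x_i = origin[1] +
#'   (i-1)*spacing`, `y_j = origin[2] + (j-1)*spacing`.
#' @param spacing Grid spacing (um).
#' @param origin Coordinates (um) of the cell center `values[1, 1]`.
#' @param mask Logical matrix, TRUE for cavity-interior cells.
#' @param cavity The `cavity_geometry` the grid was built for (may be NULL
#'   for free-standing fields, e.g. toy fixtures).
#' @param role One of "concentration", "potential", "energy", "probability",
#'   "generic".
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, spacing, origin, mask, cavity = NULL,
                         role = "generic") {
  stopifnot(is.matrix(values), is.matrix(mask),
            all(dim(values) == dim(mask)))
  if (any(!is.finite(values[mask]))) {
    stop("scalar_field: non-finite values on interior (masked-in) cells")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, mask = mask,
         cavity = cavity, role = role),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf(
    "scalar_field [%s]: %d x %d cells, spacing %.4g um, %d interior\n",
    x$role, nrow(x$values), ncol(x$values), x$spacing, sum(x$mask)
  ))
  invisible(x)
}

#' Build the canonical edge-aligned grid for a cavity
#'
#' Cell edges sit at integer multiples of `spacing`; cell centers at
#' half-integer multiples. The grid just covers the ellipse bounding box.
#' With `cover = "center"` the mask selects cells whose center lies strictly
#' inside the ellipse (the Dirichlet interior used by the field solvers);
#' with `cover = "intersect"` it selects every cell that intersects the
#' ellipse interior, so that any point inside the cavity falls in a masked
#' cell (the convention for histogram and comparison grids).
#'
#' @param cavity A `cavity_geometry`.
#' @param spacing Grid spacing (um).
#' @param cover Mask convention, `"center"` (default) or `"intersect"`.
#' @return A `scalar_field` of zeros (role "generic") carrying the mask and
#'   coordinates; use as a template.
#' @export
cavity_grid <- function(cavity, spacing, cover = c("center", "intersect")) {
  cover <- match.arg(cover)
  if (spacing <= 0) stop("spacing must be > 0")
  mx <- ceiling(cavity$semi_major / spacing - 1e-9)
  my <- ceiling(cavity$semi_minor / spacing - 1e-9)
  nx <- 2L * mx
  ny <- 2L * my
  xs <- (seq_len(nx) - mx - 0.5) * spacing
  ys <- (seq_len(ny) - my - 0.5) * spacing
  if (cover == "center") {
    r2 <- outer((xs / cavity$semi_major)^2, (ys / cavity$semi_minor)^2, "+")
    mask <- r2 < 1 - 1e-12
  } else {
    # nearest point of each cell rectangle to the center, in ellipse metric
    half <- spacing / 2
    cx <- pmax(abs(xs) - half, 0) / cavity$semi_major
    cy <- pmax(abs(ys) - half, 0) / cavity$semi_minor
    mask <- outer(cx^2, cy^2, "+") < 1 - 1e-12
  }
  scalar_field(matrix(0, nx, ny), spacing, c(xs[1], ys[1]), mask,
               cavity = cavity)
}

#' Grid cell-center coordinates
#' @param field A `scalar_field`.
#' @return List with vectors `x` and `y` of cell-center coordinates (um).
#' @export
field_coords <- function(field) {
  list(
    x = field$origin[1] + (seq_len(nrow(field$values)) - 1) * field$spacing,
    y = field$origin[2] + (seq_len(ncol(field$values)) - 1) * field$spacing
  )
}

#' Bilinear interpolation of a scalar field
#'
#' Interpolates `field$values` at arbitrary points. Queries outside the grid
#' bounding box raise an error; queries on exterior cells see the stored
#' exterior values (role-dependent), so concentration and probability fields
#' interpolate smoothly to 0 across the boundary.
#'
#' @param field A `scalar_field`.
#' @param x,y Query coordinates (um).
#' @return Numeric vector of interpolated values.
#' @export
field_interp <- function(field, x, y) {
  h <- field$spacing
  nx <- nrow(field$values)
  ny <- ncol(field$values)
  u <- (x - field$origin[1]) / h
  v <- (y - field$origin[2]) / h
  if (any(u < -0.5 - 1e-9 | u > nx - 0.5 + 1e-9 |
          v < -0.5 - 1e-9 | v > ny - 0.5 + 1e-9)) {
    stop("field_interp: point outside grid bounding box")
  }
  i0 <- pmin(pmax(floor(u), 0), nx - 2)
  j0 <- pmin(pmax(floor(v), 0), ny - 2)
  fu <- pmin(pmax(u - i0, 0), 1)
  fv <- pmin(pmax(v - j0, 0), 1)
  i0 <- as.integer(i0) + 1L
  j0 <- as.integer(j0) + 1L
  V <- field$values
  idx <- cbind(i0, j0)
  v00 <- V[idx]
  v10 <- V[cbind(i0 + 1L, j0)]
  v01 <- V[cbind(i0, j0 + 1L)]
  v11 <- V[cbind(i0 + 1L, j0 + 1L)]
  (1 - fu) * (1 - fv) * v00 + fu * (1 - fv) * v10 +
    (1 - fu) * fv * v01 + fu * fv * v11
}

#' Total probability mass of a probability field
#' @param field A `scalar_field` with role "probability".
#' @return `sum(values) * spacing^2` over interior cells.
#' @export
field_mass <- function(field) {
  sum(field$values[field$mask]) * field$spacing^2
}

#' Bin a probability field down to a coarser resolution
#'
#' Block-sums probability mass onto the canonical cavity grid at
#' `target_spacing` (which must be an integer multiple of the field
#' spacing), then renormalizes. This is how model distributions computed on
#' a fine grid are compared with histograms binned at the measurement
#' resolution (~50 nm). A binning factor of 1 leaves the values unchanged
#' and only re-projects onto the comparison (intersect-mask) grid.
#'
#' @param field A probability `scalar_field` carrying its cavity.
#' @param target_spacing Target spacing (um), integer multiple of
#'   `field$spacing`; default 0.05.
#' @return A probability `scalar_field` on the coarse grid.
#' @export
bin_to_resolution <- function(field, target_spacing = 0.05) {
  f <- target_spacing / field$spacing
  if (abs(f - round(f)) > 1e-9) {
    stop("target_spacing must be an integer multiple of the field spacing")
  }
  f <- as.integer(round(f))
  if (is.null(field$cavity)) {
    stop("bin_to_resolution requires a field carrying its cavity")
  }
  coarse <- cavity_grid(field$cavity, target_spacing, cover = "intersect")
  co <- field_coords(field)
  # fine cell centers never coincide with coarse edges (edge-aligned grids)
  ci <- floor((co$x - (coarse$origin[1] - target_spacing / 2)) / target_spacing) + 1
  cj <- floor((co$y - (coarse$origin[2] - target_spacing / 2)) / target_spacing) + 1
  ci <- pmin(pmax(as.integer(ci), 1L), nrow(coarse$values))
  cj <- pmin(pmax(as.integer(cj), 1L), ncol(coarse$values))
  mass <- field$values * field$spacing^2
  vals <- matrix(0, nrow(coarse$values), ncol(coarse$values))
  ii <- ci[row(mass)]
  jj <- cj[col(mass)]
  sums <- tapply(as.vector(mass), list(factor(ii, seq_len(nrow(vals))),
                                       factor(jj, seq_len(ncol(vals)))), sum)
  sums[is.na(sums)] <- 0
  vals[] <- sums
  total <- sum(vals)
  if (total <= 0) stop("bin_to_resolution: field has no mass")
  vals <- vals / total / target_spacing^2
  scalar_field(vals, target_spacing, coarse$origin, coarse$mask,
               cavity = field$cavity, role = "probability")
}
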