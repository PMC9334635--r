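#' Confined-chain specification
#'
#' Coarse-grained description of a long dsDNA chain treated as a
#' semi-dilute solution inside the cavity. Defaults describe T4 DNA:
#' contour length ~60 um, Kuhn length 0.1 um (twice the 50 nm persistence
#' length), 166,000 bp at ~300 bp per Kuhn segment, i.e. ~600 Kuhn
#' segments.
#'
#' @param contour_length Chain contour length (um).
#' @param kuhn_length Kuhn segment length (um).
#' @param basepairs Number of base pairs.
#' @param basepairs_per_kuhn Base pairs per Kuhn segment.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(contour_length = 60, kuhn_length = 0.1,
                       basepairs = 166000, basepairs_per_kuhn = 300) {
  stopifnot(contour_length > 0, kuhn_length > 0, basepairs > 0,
            basepairs_per_kuhn > 0)
  n_kuhn <- contour_length / kuhn_length
  n_kuhn_bp <- basepairs / basepairs_per_kuhn
  if (abs(n_kuhn_bp - n_kuhn) / n_kuhn > 0.2) {
    warning(sprintf(
      "chain_spec: Kuhn counts from contour (%.0f) and basepairs (%.0f) differ by > 20%%",
      n_kuhn, n_kuhn_bp
    ))
  }
  structure(
    list(contour_length = contour_length, kuhn_length = kuhn_length,
         basepairs = basepairs, basepairs_per_kuhn = basepairs_per_kuhn),
    class = "chain_spec"
  )
}

#' Number of Kuhn segments of a chain
#' @param chain A `chain_spec`.
#' @return `contour_length / kuhn_length`.
#' @export
kuhn_segments <- function(chain) chain$contour_length / chain$kuhn_length

# Shortley-Weller 5-point Laplacian on the ellipse interior, Dirichlet 0 on
# the true elliptical boundary. For an interior cell whose neighbor in a
# given direction falls outside the ellipse, the grid leg is shortened to
# the actual boundary crossing (fraction theta of the spacing), restoring
# O(h^2) accuracy lost to the staircase mask. Returns -laplacian as a
# sparse (generally nonsymmetric) matrix over interior cells.
sw_neg_laplacian <- function(grid) {
  cav <- grid$cavity
  A <- cav$semi_major
  B <- cav$semi_minor
  h <- grid$spacing
  mask <- grid$mask
  nx <- nrow(mask)
  ny <- ncol(mask)
  idx <- matrix(0L, nx, ny)
  idx[mask] <- seq_len(sum(mask))
  co <- field_coords(grid)
  ij <- which(mask, arr.ind = TRUE)
  xs <- co$x[ij[, 1]]
  ys <- co$y[ij[, 2]]
  n <- nrow(ij)

  neigh <- function(di, dj) {
    i2 <- ij[, 1] + di
    j2 <- ij[, 2] + dj
    ok <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    out <- rep(0L, n)
    out[ok] <- idx[cbind(i2[ok], j2[ok])]
    out
  }
  nE <- neigh(1L, 0L); nW <- neigh(-1L, 0L)
  nN <- neigh(0L, 1L); nS <- neigh(0L, -1L)

  # boundary-leg fractions; 1 for interior neighbors
  xb <- A * sqrt(pmax(1 - (ys / B)^2, 0))
  yb <- B * sqrt(pmax(1 - (xs / A)^2, 0))
  thE <- ifelse(nE > 0, 1, pmax((xb - xs) / h, 1e-6))
  thW <- ifelse(nW > 0, 1, pmax((xs + xb) / h, 1e-6))
  thN <- ifelse(nN > 0, 1, pmax((yb - ys) / h, 1e-6))
  thS <- ifelse(nS > 0, 1, pmax((ys + yb) / h, 1e-6))

  diag_val <- (2 / h^2) * (1 / (thE * thW) + 1 / (thN * thS))
  ii <- seq_len(n)
  tr_i <- ii; tr_j <- ii; tr_x <- diag_val
  add <- function(nb, th_a, th_b) {
    sel <- nb > 0
    tr_i <<- c(tr_i, ii[sel])
    tr_j <<- c(tr_j, nb[sel])
    tr_x <<- c(tr_x, -(2 / h^2) / (th_a[sel] * (th_a[sel] + th_b[sel])))
  }
  add(nE, thE, thW)
  add(nW, thW, thE)
  add(nN, thN, thS)
  add(nS, thS, thN)
  Matrix::sparseMatrix(i = tr_i, j = tr_j, x = tr_x, dims = c(n, n))
}

#' Ground-state-dominance concentration profile of a confined chain
#'
#' Solves for the equilibrium monomer concentration `rho(r)` of a long
#' chain confined in the cavity, in the ground-state-dominance mean-field
#' approximation. The order parameter `psi` minimizes
#' `E[psi] = integral( (a_k^2/6) |grad psi|^2 + (g/2) psi^4 ) dA`
#' subject to `integral(psi^2) dA = 1` and `psi = 0` on the cavity
#' boundary; equivalently it is the nodeless ground state of the nonlinear
#' Schroedinger (Gross-Pitaevskii-type) eigenproblem
#' `-(a_k^2/6) lap psi + g psi^3 = lambda psi`.
#' The 200 nm slit dimension is integrated out (quasi-2D reduction), so the
#' returned concentration is `rho = (basepairs / depth) * psi^2` in
#' bp um^-3, normalized so that `integral(rho) dA * depth = basepairs`.
#'
#' Numerics: Shortley-Weller 5-point Laplacian on an edge-aligned Cartesian
#' grid (boundary legs shortened to the true ellipse), semi-implicit
#' normalized gradient flow (backward Euler in the Laplacian, explicit in
#' the cubic term) with a single sparse LU factorization; the flow step is
#' halved and refactored whenever the eigenvalue estimate fails to
#' decrease, preserving the energy-descent property.
#'
#' @param cavity A `cavity_geometry`.
#' @param chain A `chain_spec`.
#' @param g Self-interaction strength (um^2, multiplying `psi^3`); >= 0.
#'   `g = 0` gives the linear (ideal-chain) ground state; the default NULL
#'   picks `g` so the peak self-interaction energy density equals half the
#'   linear confinement eigenvalue — a mildly semi-dilute regime in which
#'   the profile remains dome-shaped. Large `g` drives the flat-center
#'   Thomas-Fermi limit.
#' @param grid_spacing Grid spacing (um); must be <= semi_minor / 10.
#'   Default 0.025 um.
#' @param tolerance Relative change of the eigenvalue between iterations at
#'   which the flow is declared converged.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   eigenvalue trace.
#' @return A concentration `scalar_field` (bp um^-3) with attributes
#'   `lambda`, `lambda_trace`, `iterations`, `g`, `psi` (the normalized
#'   order parameter values).
#' @export
solve_gsd <- function(cavity, chain = chain_spec(), g = NULL,
                      grid_spacing = 0.025, tolerance = 1e-8,
                      max_iter = 5000) {
  if (grid_spacing > cavity$semi_minor / 10 + 1e-12) {
    stop("grid too coarse: grid_spacing must be <= semi_minor / 10")
  }
  if (tolerance <= 0) stop("tolerance must be > 0")
  grid <- cavity_grid(cavity, grid_spacing, cover = "center")
  h <- grid_spacing
  mask <- grid$mask
  co <- field_coords(grid)
  ij <- which(mask, arr.ind = TRUE)
  xs <- co$x[ij[, 1]]
  ys <- co$y[ij[, 2]]

  # symmetric, nodeless initialization
  psi <- pmax(1 - (xs / cavity$semi_major)^2 - (ys / cavity$semi_minor)^2, 0)
  psi <- psi / sqrt(sum(psi^2) * h^2)

  if (is.null(g)) {
    # mildly semi-dilute default: peak self-interaction energy density
    # g * psi_c^2 set to half the linear confinement eigenvalue, so the
    # profile stays dome-shaped (the exclusion zone spans the cavity
    # interior) rather than collapsing to the flat Thomas-Fermi limit
    lin <- solve_gsd(cavity, chain, g = 0, grid_spacing = grid_spacing,
                     tolerance = tolerance, max_iter = max_iter)
    g <- 0.5 * attr(lin, "lambda") / max(attr(lin, "psi")^2)
  }
  if (g < 0) stop("g must be >= 0")
  cc <- chain$kuhn_length^2 / 6
  L <- sw_neg_laplacian(grid) * cc
  n <- length(psi)

  lam_of <- function(p) h^2 * (sum(p * as.numeric(L %*% p)) + g * sum(p^4))
  lam <- lam_of(psi)
  # flow step: fast (inverse-iteration-like) for the linear part, bounded
  # by the explicit cubic term's scale
  dt <- min(2 / max(lam, 1e-12), 0.5 / (g * max(psi^2) + 1e-12))
  make_M <- function(dt) {
    Matrix::lu(Matrix::Diagonal(n, 1 / dt) + L)
  }
  M <- make_M(dt)
  trace <- lam
  it <- 0L
  repeat {
    it <- it + 1L
    rhs <- psi / dt - g * psi^3
    p_new <- as.numeric(Matrix::solve(M, rhs))
    p_new <- p_new / sqrt(sum(p_new^2) * h^2)
    lam_new <- lam_of(p_new)
    if (lam_new > lam + max(tolerance, 1e-12) * abs(lam)) {
      dt <- dt / 2
      if (dt < 1e-12) {
        stop(sprintf("solve_gsd: step collapsed at iteration %d (lambda %.6g)",
                     it, lam))
      }
      M <- make_M(dt)
      next
    }
    conv <- abs(lam_new - lam) <= tolerance * abs(lam)
    psi <- p_new
    lam <- lam_new
    trace <- c(trace, lam)
    if (conv) break
    if (it >= max_iter) {
      stop(sprintf(
        "solve_gsd: no convergence in %d iterations (last rel. change %.3g)",
        max_iter, abs(diff(utils::tail(trace, 2))) / abs(lam)
      ))
    }
  }

  vals <- matrix(0, nrow(mask), ncol(mask))
  vals[mask] <- (chain$basepairs / cavity$depth) * psi^2
  out <- scalar_field(vals, h, grid$origin, mask, cavity = cavity,
                      role = "concentration")
  attr(out, "lambda") <- lam
  attr(out, "lambda_trace") <- trace
  attr(out, "iterations") <- it
  attr(out, "g") <- g
  attr(out, "psi") <- psi
  out
}

#' Concentration at a point
#'
#' Bilinear interpolation of a concentration field; the Dirichlet boundary
#' condition makes the field interpolate to 0 at the cavity wall, and
#' points outside the cavity return 0.
#'
#' @param field A concentration `scalar_field`.
#' @param x,y Query point (um); must lie within the grid bounding box.
#' @return Concentration (bp um^-3).
#' @export
concentration_at <- function(field, x, y) {
  out <- field_interp(field, x, y)
  if (!is.null(field$cavity)) {
    out[!cavity_contains(field$cavity, x, y)] <- 0
  }
  out
}
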