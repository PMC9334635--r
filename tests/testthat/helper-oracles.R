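# Independent oracles used across test files.

# ellipse perimeter by adaptive quadrature of the arc-length integrand
perimeter_oracle <- function(cavity) {
  A <- cavity$semi_major
  B <- cavity$semi_minor
  stats::integrate(function(t) sqrt(A^2 * sin(t)^2 + B^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# boundary line integral of a wall kernel by adaptive quadrature
wall_integral_oracle <- function(cavity, params, x, y) {
  A <- cavity$semi_major
  B <- cavity$semi_minor
  stats::integrate(function(t) {
    d <- sqrt((A * cos(t) - x)^2 + (B * sin(t) - y)^2)
    kernel_value(params, d) * sqrt(A^2 * sin(t)^2 + B^2 * cos(t)^2)
  }, 0, 2 * pi, rel.tol = 1e-10)$value
}

# first zero of the Bessel function J0 (standard special-function value,
# reproducible via uniroot on besselJ)
bessel_j0_zero <- function() {
  stats::uniroot(function(x) besselJ(x, 0), c(2, 3), tol = 1e-12)$root
}

# a free-standing two-cell probability field (toy fixture)
two_cell_field <- function(p, spacing = 1) {
  scalar_field(matrix(p / spacing^2, 2, 1), spacing, c(0, 0),
               matrix(TRUE, 2, 1), cavity = NULL, role = "probability")
}
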