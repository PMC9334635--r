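kp <- kernel_params("exponential", wall_strength = 20, decay_range = 0.15)

test_that("wall kernels evaluate to their closed forms", {
  expect_equal(kernel_value(kp, 0), 20)
  expect_equal(kernel_value(kp, 0.15), 20 / exp(1))
  wca <- kernel_params("wca", epsilon = 3, sigma = 0.1)
  expect_equal(kernel_value(wca, 2^(1 / 6) * 0.1), 0)
  expect_equal(kernel_value(wca, 0.5), 0)
  expect_equal(kernel_value(wca, 0), 1e3)     # capped at contact
  expect_gt(kernel_value(wca, 0.09), kernel_value(wca, 0.1))
  expect_error(kernel_value(kp, -1))
})

test_that("wall potential at the circle center equals perimeter times kernel", {
  circ <- make_cavity(0, 1.0)
  segs <- boundary_segments(circ, 720)
  expect_equal(wall_potential_at(circ, kp, 0, 0),
               sum(segs$arc_length) * kernel_value(kp, 1), tolerance = 1e-9)
  # radial symmetry: value on a ring is independent of angle
  phi <- seq(0, 2 * pi, length.out = 13)
  u <- wall_potential_at(circ, kp, 0.5 * cos(phi), 0.5 * sin(phi))
  expect_lt(max(abs(u - u[1])), 1e-6 * u[1])
})

test_that("segment sum matches the adaptive-quadrature line integral", {
  for (e in c(0.6, 0.9)) {
    cav <- make_cavity(e, 1.0)
    for (pt in list(c(0.3, -0.2), c(-0.8, 0.1) * cav$semi_minor)) {
      expect_equal(wall_potential_at(cav, kp, pt[1], pt[2]),
                   wall_integral_oracle(cav, kp, pt[1], pt[2]),
                   tolerance = 1e-3)
    }
  }
})

test_that("gridded wall potential has the ellipse mirror symmetries", {
  cav <- make_cavity(0.9, 1.0)
  U <- wall_potential(cav, kp, 0.05, 360)
  v <- U$values
  v[!U$mask] <- 0
  expect_lt(max(abs(v - v[nrow(v):1, ])), 1e-6 * max(v))
  expect_lt(max(abs(v - v[, ncol(v):1])), 1e-6 * max(v))
  # increases toward the boundary along the minor axis
  ys <- seq(0, cav$semi_minor - 0.06, by = 0.05)
  expect_true(all(diff(field_interp(U, rep(0, length(ys)), ys)) > 0))
})

test_that("exclusion potential is the linear coupling a * rho", {
  cav <- make_cavity(0.6, 1.0)
  rho <- solve_gsd(cav, grid_spacing = 0.05)
  expect_true(all(exclusion_potential(rho, exclusion_params(0))$values[rho$mask] == 0))
  u1 <- exclusion_potential(rho, exclusion_params(1.1e-6))
  u2 <- exclusion_potential(rho, exclusion_params(2.2e-6))
  expect_equal(u2$values[rho$mask], 2 * u1$values[rho$mask])
  # fitted-scale coefficient on a uniform 1e6 bp/um^3 solution: 1.1 kBT
  expect_equal(1.1e-6 * 1e6, 1.1)
  # a typical mid-cavity chain concentration produces kBT-scale exclusion
  expect_gt(field_interp(u1, 0, 0), 0.3)
})

test_that("total potential develops an off-center well on the e=0.9 major axis", {
  cav <- make_cavity(0.9, 1.0)
  rho <- solve_gsd(cav, grid_spacing = 0.025)
  rp <- reference_model_params(cav)
  Up <- total_potential(exclusion_potential(rho, rp$exclusion),
                        wall_potential(cav, rp$kernel, 0.025))
  xs <- seq(0, cav$semi_major - 0.05, by = 0.01)
  u <- field_interp(Up, xs, rep(0, length(xs)))
  k <- which.min(u)
  expect_gt(xs[k], 0.3 * cav$semi_major)       # well lies off-center
  expect_lt(xs[k], 0.98 * cav$semi_major)      # ... but inside the wall zone
  expect_lt(u[k], u[1] - 0.1)                  # clearly below the center
  expect_error(total_potential(Up, wall_potential(cav, rp$kernel, 0.05)),
               "mismatch")
})

test_that("Boltzmann distribution normalizes, shifts and orders correctly", {
  cav <- make_cavity(0.6, 1.0)
  U0 <- wall_potential(cav, kp, 0.05)
  P <- boltzmann_distribution(U0)
  expect_equal(field_mass(P), 1, tolerance = 1e-9)
  # adding a constant changes nothing
  Uc <- scalar_field(U0$values + 3.7, U0$spacing, U0$origin, U0$mask,
                     cavity = cav, role = "potential")
  expect_equal(boltzmann_distribution(Uc)$values, P$values,
               tolerance = 1e-12)
  # uniform potential -> uniform density 1/area over interior cells
  Uu <- scalar_field(ifelse(U0$mask, 0, NA_real_), U0$spacing, U0$origin,
                     U0$mask, cavity = cav, role = "potential")
  Pu <- boltzmann_distribution(Uu)
  expect_equal(max(Pu$values), min(Pu$values[Pu$mask]))
  # raising U on a subset lowers that subset's probability
  Um <- U0$values
  sel <- which(U0$mask)[1:200]
  Um[sel] <- Um[sel] + 1
  P2 <- boltzmann_distribution(
    scalar_field(Um, U0$spacing, U0$origin, U0$mask, cavity = cav,
                 role = "potential"))
  expect_lt(sum(P2$values[sel]), sum(P$values[sel]))
})

test_that("two-level system has Boltzmann occupancies 2/3 and 1/3", {
  U <- scalar_field(matrix(c(0, log(2)), 2, 1), 1, c(0, 0),
                    matrix(TRUE, 2, 1), role = "potential")
  P <- boltzmann_distribution(U)
  expect_equal(as.numeric(P$values), c(2 / 3, 1 / 3))
})

test_that("binning to coarser resolution conserves probability mass", {
  cav <- make_cavity(0.6, 1.0)
  P <- boltzmann_distribution(wall_potential(cav, kp, 0.025))
  Pc <- bin_to_resolution(P, 0.05)
  expect_equal(field_mass(Pc), 1, tolerance = 1e-12)
  expect_equal(Pc$spacing, 0.05)
  # factor 1 leaves the values unchanged (canonical-grid re-projection)
  P1 <- bin_to_resolution(P, 0.025)
  expect_equal(P1$values[P$mask], P$values[P$mask], tolerance = 1e-12)
  expect_error(bin_to_resolution(P, 0.06), "integer multiple")
  # a uniform distribution stays uniform away from the boundary
  Uu <- scalar_field(ifelse(P$mask, 0, NA_real_), P$spacing, P$origin,
                     P$mask, cavity = cav, role = "potential")
  Pc2 <- bin_to_resolution(boltzmann_distribution(Uu), 0.05)
  interior <- effective_radius(cav, field_coords(Pc2)$x[row(Pc2$values)],
                               field_coords(Pc2)$y[col(Pc2$values)]) < 0.7
  vals <- Pc2$values[interior]
  expect_lt(diff(range(vals)) / mean(vals), 1e-9)
})

test_that("threshold range of the wall potential behaves physically", {
  cav <- make_cavity(0.9, 1.0)
  rp <- reference_model_params(cav)
  d <- range_at_threshold(cav, rp$kernel, threshold = 2)
  expect_equal(d, 0.19, tolerance = 1e-3)   # calibrated operating point
  # monotone in the decay range at fixed strength
  k2 <- kernel_params("exponential",
                      wall_strength = rp$kernel$wall_strength,
                      decay_range = rp$kernel$decay_range * 1.5)
  expect_gt(range_at_threshold(cav, k2, threshold = 2), d)
  # on a circle the distance is direction-independent
  circ <- make_cavity(0, 1.0)
  d1 <- range_at_threshold(circ, kp, 2, direction = c(0, 1))
  d2 <- range_at_threshold(circ, kp, 2, direction = c(1, 0))
  d3 <- range_at_threshold(circ, kp, 2, direction = c(1, 1))
  expect_lt(max(abs(c(d1 - d2, d1 - d3))), 1e-3)
  expect_error(range_at_threshold(circ, kp, 1e6), "exceeds")
})

test_that("effective plasmid radius conversion follows the sphere picture", {
  # v = a * 300 bp; r = (3v/4pi)^(1/3); at the fitted-scale a this is ~43 nm
  expect_equal(effective_plasmid_radius(exclusion_params(1.1e-6)),
               1e3 * (3 * 1.1e-6 * 300 / (4 * pi))^(1 / 3))
  expect_equal(round(effective_plasmid_radius(exclusion_params(1.1e-6))), 43)
})
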