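test_that("generators are bitwise deterministic under their seeds", {
  cav <- make_cavity(0.6, 1.0)
  cfg <- two_blob_config(cav, n_frames = 200, seed = 4)
  expect_identical(simulate_two_blobs(cfg), simulate_two_blobs(cfg))

  kp <- kernel_params("exponential", wall_strength = 10, decay_range = 0.1)
  U <- wall_potential(cav, kp, 0.05)
  expect_identical(sample_boltzmann_positions(U, 500, seed = 2),
                   sample_boltzmann_positions(U, 500, seed = 2))
  expect_false(identical(sample_boltzmann_positions(U, 500, seed = 2),
                         sample_boltzmann_positions(U, 500, seed = 3)))

  tr <- trajectory(rep(0, 20), rep(0, 20), 0.1)
  rc <- render_config(seed = 6)
  expect_identical(render_movie(list(tr), rc), render_movie(list(tr), rc))
})

test_that("decoupled blobs are statistically independent", {
  cav <- make_cavity(0.6, 1.0)
  cfg <- two_blob_config(cav, pair_strength = 0, n_frames = 8000, seed = 14)
  tb <- simulate_two_blobs(cfg)
  expect_lt(abs(stats::cor(tb[[1]]$x, tb[[2]]$x)), 0.1)
  expect_lt(abs(stats::cor(tb[[1]]$y, tb[[2]]$y)), 0.1)
  # every position inside the cavity
  for (tr in tb) expect_true(all(cavity_contains(cav, tr$x, tr$y)))
})

test_that("single-blob occupancy follows the wall-potential Boltzmann law", {
  cav <- make_cavity(0.6, 1.0)
  cfg <- two_blob_config(cav, pair_strength = 0, n_frames = 50000,
                         seed = 15, frame_interval = 0.01)
  tb <- simulate_two_blobs(cfg)
  occ <- position_histogram(tb, cav, 0.1)
  wall <- wall_potential(cav, cfg$wall_kernel, 0.025)
  model <- bin_to_resolution(boltzmann_distribution(wall), 0.1)
  expect_lt(total_variation(occ, model), 0.05)
})

test_that("Boltzmann sampler reproduces known occupancy ratios", {
  cav <- make_cavity(0.6, 1.0)
  g <- cavity_grid(cav, 0.05)
  # uniform potential: chi-square-consistent uniform occupancy
  Uu <- scalar_field(ifelse(g$mask, 0, NA_real_), 0.05, g$origin, g$mask,
                     cavity = cav, role = "potential")
  pos <- sample_boltzmann_positions(Uu, 1e5, seed = 8)
  expect_true(all(cavity_contains(cav, pos[, 1], pos[, 2])))
  P <- position_histogram(pos, cav, 0.1)
  counts <- P$values * 1e5 * 0.01
  inner <- effective_radius(cav, field_coords(P)$x[row(counts)],
                            field_coords(P)$y[col(counts)]) < 0.8
  expected <- 1e5 * 0.01 / (pi * cav$semi_major * cav$semi_minor)
  expect_lt(max(abs(counts[inner] - expected) / sqrt(expected)), 5)

  # double-well potential: occupancy ratio exp(-dU)
  co <- field_coords(g)
  vals <- 3 * (1 - exp(-((outer(co$x, co$y * 0, "+") - 0.6)^2) / 0.05)) *
    (1 - exp(-((outer(co$x, co$y * 0, "+") + 0.6)^2) / 0.05))
  vals <- vals + 1.0 * (outer(co$x, co$y * 0, "+") > 0) # bias one well
  Ud <- scalar_field(vals, 0.05, g$origin, g$mask, cavity = cav,
                     role = "potential")
  posd <- sample_boltzmann_positions(Ud, 4e4, seed = 9)
  n_right <- sum(posd[, 1] > 0)
  ratio <- n_right / (nrow(posd) - n_right)
  # ratio of well populations approximates the Boltzmann factor
  expect_equal(ratio, exp(-1), tolerance = 0.1)
})

test_that("crowding emulation shifts the distribution edge inward", {
  v_phi <- 0.063
  base_k <- kernel_params("exponential", wall_strength = 30,
                          decay_range = 0.1)
  base_a <- exclusion_params(1.1e-6)
  expect_identical(make_crowded_variant(base_a, base_k, 0)$kernel$decay_range,
                   base_k$decay_range)
  shifts <- sapply(c(0, 0.9), function(e) {
    cav <- make_cavity(e, 1.0)
    rho <- solve_gsd(cav, grid_spacing = 0.025)
    crowd <- make_crowded_variant(base_a, base_k, v_phi)
    mode <- if (e == 0) "radial" else "elliptical"
    prof <- function(p) {
      U <- total_potential(exclusion_potential(rho, p$exclusion),
                           wall_potential(cav, p$kernel, 0.025))
      contour_profile(boltzmann_distribution(U), cav, mode)
    }
    edge_shift(prof(list(exclusion = base_a, kernel = base_k)),
               prof(crowd), cav, mode)$shift_um
  })
  expect_gt(shifts[1], 0)           # inward displacement, circular cavity
  expect_gt(shifts[2], shifts[1])   # anisotropy amplifies the shift
})

test_that("rendered movies localize to the configured precision", {
  tr <- trajectory(c(0.2, -0.1, 0, 0.15), c(0, 0.1, -0.2, 0.05), 0.1)
  clean <- render_movie(list(tr), render_config(noise_model = "none",
                                                background_level = 0))
  ps <- attr(clean[[1]], "pixel_size")
  for (f in 1:4) {
    cm <- fluorescence_cm(clean[[1]][, , f], ps, attr(clean[[1]], "origin"))
    expect_lt(max(abs(cm - c(tr$x[f], tr$y[f]))), 0.05 * ps)
  }
  # centroid error shrinks roughly as 1/sqrt(photons)
  errs <- sapply(c(500, 5000, 50000), function(ph) {
    mv <- render_movie(list(tr), render_config(photons_per_frame = ph,
                                               background_level = 0,
                                               noise_model = "poisson",
                                               seed = 20))
    trk <- track_movie(mv, ps, 0.1, origin = attr(mv[[1]], "origin"))
    sqrt(mean((trk[[1]]$x - tr$x)^2 + (trk[[1]]$y - tr$y)^2))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 3)
  # two channels with disjoint trajectories have no cross-talk
  tr2 <- trajectory(rep(-0.8, 4), rep(-0.8, 4), 0.1)
  mv2 <- render_movie(list(tr, tr2), render_config(noise_model = "none",
                                                   background_level = 0))
  far <- mv2[[2]][, , 1]
  xs <- attr(mv2[[2]], "origin")[1] + (seq_len(64) - 1) * ps
  expect_equal(sum(far[xs > 0, ]), 0, tolerance = 1e-10)
})

test_that("dextran gyration radius follows the empirical power law", {
  expect_equal(round(dextran_radius(5000), 1), 2.6)
  expect_equal(dextran_radius(1), 0.066)
  mw <- c(1e3, 5e3, 2e4, 5e5)
  expect_true(all(diff(dextran_radius(mw)) > 0))
})

test_that("width-corrected coil radius applies the 1/5-power rescaling", {
  # a 102 nm high-salt radius maps to ~140 nm at 10 nm effective width
  expect_equal(coil_radius_width_corrected(102, 2, 10), 102 * 5^(1 / 5))
  expect_equal(round(coil_radius_width_corrected(102, 2, 10), -1), 140)
})
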