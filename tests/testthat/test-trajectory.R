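test_that("background subtraction removes a constant offset", {
  img <- matrix(7, 21, 21)
  expect_true(all(subtract_background(img) == 0))
  expect_true(all(subtract_background(matrix(0, 21, 21)) == 0))
  # blob mass preserved after offset removal
  xs <- seq_len(21)
  blob <- 100 * outer(exp(-(xs - 11)^2 / 8), exp(-(xs - 11)^2 / 8))
  out <- subtract_background(blob + 5)
  expect_equal(sum(out), sum(blob), tolerance = 0.01)
  expect_error(subtract_background(matrix(1, 4, 4), border_width = 3),
               "border")
})

test_that("fluorescence center of mass is the intensity-weighted mean", {
  img <- matrix(0, 9, 9)
  img[3, 7] <- 5
  expect_equal(fluorescence_cm(img, 1, c(0, 0)), c(2, 6))
  # intensities 1 at x=0 and 3 at x=4 in the same row -> x_cm = 3
  img2 <- matrix(0, 9, 9)
  img2[1, 1] <- 1
  img2[5, 1] <- 3
  expect_equal(fluorescence_cm(img2, 1, c(0, 0))[1], 3)
  expect_error(fluorescence_cm(matrix(0, 5, 5), 1), "zero total")
  # render-and-recover: symmetric Gaussian blob centered off-grid
  ps <- 0.05
  xs <- (seq_len(33) - 17) * ps
  ctr <- c(0.013, -0.021)
  img3 <- outer(exp(-(xs - ctr[1])^2 / (2 * 0.01)),
                exp(-(xs - ctr[2])^2 / (2 * 0.01)))
  cm <- fluorescence_cm(img3, ps, c(xs[1], xs[1]))
  expect_lt(max(abs(cm - ctr)), 0.05 * ps)
})

test_that("movie tracking recovers a rendered trajectory", {
  set.seed(3)
  n <- 40
  tr1 <- trajectory(0.3 * cos(seq(0, 4, length.out = n)),
                    0.3 * sin(seq(0, 4, length.out = n)), 0.1, "a")
  tr2 <- trajectory(rep(-0.4, n), rep(0.2, n), 0.1, "b")
  movie <- render_movie(list(tr1, tr2),
                        render_config(noise_model = "poisson", seed = 8))
  trk <- track_movie(movie, attr(movie[[1]], "pixel_size"), 0.1,
                     origin = attr(movie[[1]], "origin"))
  rms1 <- sqrt(mean((trk[[1]]$x - tr1$x)^2 + (trk[[1]]$y - tr1$y)^2))
  expect_lt(rms1, 0.5 * 0.05)   # < 0.5 pixel
  # static blob: constant trajectory within the noise floor
  expect_lt(stats::sd(trk[[2]]$x), 0.01)
  # channels are independent: static channel unaffected by moving one
  expect_lt(max(abs(trk[[2]]$x + 0.4)), 0.02)
})

test_that("position histogram is a normalized estimator of the density", {
  cav <- make_cavity(0.6, 1.0)
  # single repeated position: all mass in one bin
  tr <- trajectory(rep(0.21, 10), rep(-0.11, 10), 1)
  P <- position_histogram(tr, cav, 0.05)
  expect_equal(field_mass(P), 1, tolerance = 1e-12)
  expect_equal(sum(P$values > 0), 1)
  # uniform samples: per-bin counts consistent with Poisson fluctuations
  set.seed(12)
  n <- 1e5
  pos <- matrix(nrow = 0, ncol = 2)
  while (nrow(pos) < n) {
    cand <- cbind(runif(n, -cav$semi_major, cav$semi_major),
                  runif(n, -cav$semi_minor, cav$semi_minor))
    pos <- rbind(pos, cand[cavity_contains(cav, cand[, 1], cand[, 2]), ])
  }
  pos <- pos[1:n, ]
  Pu <- position_histogram(pos, cav, 0.1)
  counts <- Pu$values * n * 0.1^2
  inner <- effective_radius(cav, field_coords(Pu)$x[row(counts)],
                            field_coords(Pu)$y[col(counts)]) < 0.8
  expected <- n * 0.1^2 / (pi * cav$semi_major * cav$semi_minor)
  dev <- abs(counts[inner] - expected) / sqrt(expected)
  expect_lt(max(dev), 5)
  expect_equal(attr(Pu, "n_outside"), 0)
})

test_that("separation series folds the angle and signs the projection", {
  cav <- make_cavity(0.6, 1.0)
  t1 <- trajectory(c(0.5, 0, 0.3), c(0, 0.2, 0.3), 1)
  t2 <- trajectory(c(-0.5, 0, 0), c(0, -0.2, 0), 1)
  ss <- separation_series(t1, t2, cav)
  expect_equal(ss$theta[1], pi / 2)   # r along major axis
  expect_equal(ss$theta[2], 0)        # r along minor axis
  ss_swapped <- separation_series(t2, t1, cav)
  expect_equal(ss$theta, ss_swapped$theta)
  expect_equal(ss$normalized_projection, -ss_swapped$normalized_projection)
  expect_error(separation_series(t1, trajectory(1:5, 1:5, 1), cav),
               "time bases")
})

test_that("order parameter distinguishes isotropic from polar alignment", {
  set.seed(99)
  expect_equal(order_parameter(runif(1e5, 0, pi)), 0, tolerance = 0.01)
  expect_equal(order_parameter(rep(pi / 2, 10)), 1)
  expect_equal(order_parameter(c(0, pi / 2)), 0)
  # literal minor-axis convention is the negative counterpart
  expect_equal(order_parameter(rep(pi / 2, 10), convention = "minor"), -1)
  expect_error(order_parameter(numeric(0)), "empty")
})

test_that("swap detection with hysteresis ignores failed attempts", {
  # clean square wave, period 20 s
  proj <- rep(rep(c(1, -1), 10), each = 10)
  mk <- function(p) {
    structure(list(times = seq_along(p) - 1, normalized_projection = p,
                   frame_interval = 1), class = "separation_series")
  }
  sw <- detect_swaps(mk(proj))
  expect_equal(sw$n_swaps, 19)
  expect_true(all(sw$stats$samples == 10))
  # a one-frame excursion to 0 must not add a swap
  proj2 <- proj
  proj2[5] <- 0
  expect_equal(detect_swaps(mk(proj2))$n_swaps, 19)
  # an excursion beyond the opposite threshold does count (out and back)
  proj3 <- proj
  proj3[5] <- -1
  expect_equal(detect_swaps(mk(proj3))$n_swaps, 21)
  # constant series: no swaps, warning-free single state
  expect_equal(detect_swaps(mk(rep(1, 50)))$n_swaps, 0)
  expect_warning(detect_swaps(mk(rep(0, 50))), "never enters")
})

test_that("single-exponential dwell fit recovers the timescale", {
  set.seed(77)
  d <- rexp(500, rate = 1 / 10)
  fit <- fit_exponential_dwell(dwell_time_stats(d))
  expect_gt(fit$tau, 9)
  expect_lt(fit$tau, 11)
  expect_equal(fit$tau_mean, mean(d))
  expect_gt(fit$r_squared, 0.95)
  # time-unit invariance
  fit_ms <- fit_exponential_dwell(dwell_time_stats(d * 1000))
  expect_equal(fit_ms$tau / 1000, fit$tau, tolerance = 1e-9)
  expect_error(fit_exponential_dwell(dwell_time_stats(c(1, 2))), "at least 5")
})

test_that("pole dwell times follow the |x| > l/3 rule", {
  # deterministic oscillation: 5 frames at +l, 5 at -l, repeated
  x <- rep(rep(c(1, -1), 10), each = 5)
  tr <- trajectory(x, x * 0, frame_interval = 0.2)
  st <- pole_dwell_times(tr, l = 1)
  expect_true(all(st$samples == 5 * 0.2))
  expect_equal(attr(st, "n_censored"), 2)
  # confined to |x| < l/3: no events
  tr2 <- trajectory(runif(50, -0.3, 0.3), rep(0, 50), 0.2)
  expect_warning(st2 <- pole_dwell_times(tr2, l = 1), "never enters")
  expect_equal(st2$n_events, 0)
})

test_that("double-exponential mixture fit recovers both timescales", {
  set.seed(31)
  d <- c(rexp(1000, 1 / 10), rexp(1000, 1))
  fit <- fit_double_exponential(d)
  expect_equal(fit$tau_long, 10, tolerance = 0.15)
  expect_equal(fit$tau_short, 1, tolerance = 0.15)
  expect_equal(fit$weight_short, 0.5, tolerance = 0.15)
  expect_gt(fit$log_lik, fit$log_lik_single)
  # scale invariance under time-unit change
  fit_ms <- fit_double_exponential(d * 1000)
  expect_equal(fit_ms$tau_long / 1000, fit$tau_long, tolerance = 1e-6)
  # pure exponential input: long component matches the single fit
  set.seed(32)
  d1 <- rexp(2000, 1 / 5)
  nested <- fit_double_exponential(d1)
  expect_equal(nested$tau_long, mean(d1), tolerance = 0.1)
  expect_error(fit_double_exponential(d1[1:10]), "at least 20")
})

test_that("per-axis MSD matches closed forms", {
  # ballistic motion: MSD = (v tau)^2 exactly
  v <- 0.3
  tr <- trajectory(v * (0:199) * 0.1, rep(0, 200), 0.1)
  msd <- msd_per_axis(tr, max_lag = 2)
  expect_equal(msd$msd_parallel, (v * msd$lags)^2, tolerance = 1e-12)
  expect_true(all(msd$msd_perpendicular == 0))
  # static trajectory: identically zero
  tr0 <- trajectory(rep(1, 50), rep(2, 50), 0.1)
  msd0 <- msd_per_axis(tr0, max_lag = 1)
  expect_true(all(msd0$msd_parallel == 0))
  expect_warning(msd_per_axis(tr0, max_lag = 100), "truncated")
})

test_that("MSD exponent fit is exact on a pure power law", {
  lags <- seq(0.05, 1, by = 0.05)
  msd <- structure(list(lags = lags, msd_parallel = 0.2 * lags^0.8,
                        msd_perpendicular = 0.1 * lags^1.0),
                   class = "msd_result")
  a <- fit_msd_exponent(msd, window = c(0, 1))
  expect_equal(a$alpha_parallel, 0.8, tolerance = 1e-9)
  expect_equal(a$alpha_perpendicular, 1.0, tolerance = 1e-9)
  expect_error(fit_msd_exponent(msd, window = c(0, 0.1)), "4 usable")
})

test_that("contour profiles localize rings and report edges", {
  cav <- make_cavity(0, 1.0)
  grid <- cavity_grid(cav, 0.05)
  co <- field_coords(grid)
  r <- sqrt(outer(co$x^2, co$y^2, "+"))
  # radially symmetric annulus at r = 0.6, Gaussian width 0.1
  vals <- exp(-(r - 0.6)^2 / (2 * 0.1^2))
  vals[!grid$mask] <- 0
  vals <- vals / (sum(vals[grid$mask]) * 0.05^2)
  P <- scalar_field(vals, 0.05, grid$origin, grid$mask, cavity = cav,
                    role = "probability")
  prof <- contour_profile(P, cav, "radial", n_bins = 40)
  expect_equal(prof$mid[which.max(prof$density)], 0.6, tolerance = 0.03)
  # 1/e edge of a Gaussian ring sits one width outside the ring
  edge <- distribution_edge(prof)
  expect_false(edge$flagged)
  expect_equal(edge$edge, 0.6 + sqrt(2) * 0.1, tolerance = 0.03)
  # radial and elliptical modes coincide on a circle
  prof_e <- contour_profile(P, cav, "elliptical", n_bins = 40)
  expect_equal(prof$density, prof_e$density, tolerance = 1e-12)
  # flat profile: flagged edge at 1
  flat <- data.frame(mid = prof$mid, density = 1)
  expect_true(distribution_edge(flat)$flagged)
})

test_that("edge shift converts normalized displacement to micrometres", {
  mids <- (1:40 - 0.5) / 40
  prof_a <- data.frame(mid = mids, density = exp(-(mids - 0.6)^2 / 0.02))
  prof_b <- data.frame(mid = mids - 0.05,
                       density = exp(-(mids - 0.6)^2 / 0.02))
  cav <- make_cavity(0, 1.0)
  expect_equal(edge_shift(prof_a, prof_a, cav, "radial")$shift_um, 0)
  sh <- edge_shift(prof_a, prof_b, cav, "radial")
  expect_equal(sh$shift_um, 0.05, tolerance = 1e-9)
})
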