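#' Separation-vector series of two trajectories
#'
#' For two simultaneously tracked molecules, computes the separation
#' vector `r = r1 - r2`, the angle `theta` between `r` and the cavity
#' semi-minor axis folded into `[0, pi)` (so swapping the two molecules
#' leaves `theta` unchanged), and the major-axis projection of `r`
#' normalized to the semi-major axis (the two-state pole-swap observable).
#'
#' @param traj1,traj2 `trajectory` objects on the same time base.
#' @param cavity A `cavity_geometry`.
#' @return An object of class `separation_series` with fields `times`,
#'   `dx`, `dy`, `theta`, `normalized_projection`, `frame_interval`.
#' @export
separation_series <- function(traj1, traj2, cavity) {
  if (length(traj1$x) != length(traj2$x) ||
      abs(traj1$frame_interval - traj2$frame_interval) > 1e-12) {
    stop("separation_series: trajectories on different time bases")
  }
  dx <- traj1$x - traj2$x
  dy <- traj1$y - traj2$y
  theta <- atan2(dx, dy) %% pi
  structure(
    list(
      times = (seq_along(dx) - 1) * traj1$frame_interval,
      dx = dx, dy = dy, theta = theta,
      normalized_projection = dx / cavity$semi_major,
      frame_interval = traj1$frame_interval
    ),
    class = "separation_series"
  )
}

#' Alignment order parameter
#'
#' Nematic-style scalar measuring alignment of the separation vector with
#' the cavity major axis. With `phi = pi/2 - theta` the angle to the major
#' axis, `S_align = 2 <cos^2(phi) - 1/2>`: 1 for perfect polar alignment,
#' 0 for an isotropic angle distribution. The `convention = "minor"`
#' option returns the literal minor-axis form `2 <cos^2(theta) - 1/2>`
#' (which decreases to -1 under polar alignment).
#'
#' @param thetas Angles to the minor axis (radians, `[0, pi)`); or a
#'   `separation_series`.
#' @param convention "major" (default) or "minor".
#' @return Order parameter in `[-1, 1]`.
#' @export
order_parameter <- function(thetas, convention = c("major", "minor")) {
  convention <- match.arg(convention)
  if (inherits(thetas, "separation_series")) thetas <- thetas$theta
  if (length(thetas) == 0) stop("order_parameter: empty input")
  if (convention == "major") {
    2 * mean(cos(pi / 2 - thetas)^2 - 0.5)
  } else {
    2 * mean(cos(thetas)^2 - 0.5)
  }
}

#' Dwell-time sample container
#'
#' @param samples Dwell durations (s), all > 0.
#' @param censored_first,censored_last Whether the first/last interval of
#'   the source series was censored (excluded from `samples`).
#' @return An object of class `dwell_time_stats`.
#' @export
dwell_time_stats <- function(samples, censored_first = TRUE,
                             censored_last = TRUE) {
  samples <- as.numeric(samples)
  stopifnot(all(samples > 0))
  structure(
    list(samples = samples, n_events = length(samples),
         censored_first = censored_first, censored_last = censored_last),
    class = "dwell_time_stats"
  )
}

#' Detect pole swaps in a separation series
#'
#' Two-state assignment with hysteresis on the normalized major-axis
#' projection: the system enters state +1 when the projection exceeds
#' `+enter_threshold` and state -1 when it drops below
#' `-enter_threshold`; the state is retained until the *opposite* enter
#' threshold is crossed, so brief failed swap attempts (spikes that
#' revert) do not count. Dwell times are the intervals between successive
#' state changes; the intervals before the first and after the last
#' change are censored.
#'
#' @param series A `separation_series`.
#' @param enter_threshold Hysteresis threshold in `(0, 1)`; default 0.5.
#' @return List with `stats` (a `dwell_time_stats` of uncensored dwells),
#'   `n_swaps` (number of state changes) and `switch_times` (s).
#' @export
detect_swaps <- function(series, enter_threshold = 0.5) {
  stopifnot(enter_threshold > 0, enter_threshold < 1)
  p <- series$normalized_projection
  state <- 0L
  switches <- numeric(0)
  for (k in seq_along(p)) {
    new_state <- state
    if (p[k] >= enter_threshold) new_state <- 1L
    if (p[k] <= -enter_threshold) new_state <- -1L
    if (new_state != state) {
      if (state != 0L) switches <- c(switches, series$times[k])
      state <- new_state
    }
  }
  if (state == 0L) {
    warning("detect_swaps: series never enters either polar state")
    return(list(stats = dwell_time_stats(numeric(0)), n_swaps = 0L,
                switch_times = numeric(0)))
  }
  dwells <- diff(switches)
  list(stats = dwell_time_stats(dwells), n_swaps = length(switches),
       switch_times = switches)
}

#' Single-exponential dwell-time fit
#'
#' Fits `P(dwell > t) = exp(-t / tau)` by weighted least squares on the
#' log empirical complementary CDF (the survival curve), the standard
#' cumulative-histogram route for exponentially distributed escape times;
#' points are weighted by the inverse sampling variance of the log
#' survival estimate, which tames the noisy tail.
#' Also reports the sample mean (the maximum-likelihood estimate) and the
#' goodness of the log-linear fit.
#'
#' @param stats A `dwell_time_stats` (>= 5 events) or numeric vector of
#'   dwells.
#' @return List with `tau` (s), `tau_mean` (sample mean), `r_squared`.
#' @export
fit_exponential_dwell <- function(stats) {
  samples <- if (inherits(stats, "dwell_time_stats")) stats$samples else stats
  n <- length(samples)
  if (n < 5) stop("fit_exponential_dwell: need at least 5 dwell events")
  t_sorted <- sort(samples)
  surv <- 1 - seq_len(n) / n
  keep <- surv > 0
  # inverse-variance weights: var(log S_hat) ~ (1 - S) / (n S)
  w <- surv[keep] / (1 - surv[keep])
  fit <- stats::lm(log(surv[keep]) ~ t_sorted[keep], weights = w)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("fit_exponential_dwell: non-decaying survival curve")
  list(tau = -1 / slope, tau_mean = mean(samples),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Pole dwell times of a single trajectory
#'
#' A particle is in a pole region while its major-axis position satisfies
#' `|x| > l/3` with a consistent sign; `l` is the maximum extension
#' (default: the observed `max |x|` of the trajectory). Contiguous
#' in-pole runs are dwell events; a run that crosses from one pole to the
#' other is split at the sign change. Runs touching the start or end of
#' the series are censored.
#'
#' @param traj A `trajectory`.
#' @param l Maximum extension (um); default `max(abs(x))`.
#' @return A `dwell_time_stats` (attribute `n_censored` counts censored
#'   runs).
#' @export
pole_dwell_times <- function(traj, l = NULL) {
  x <- traj$x
  l <- l %||% max(abs(x))
  stopifnot(l > 0)
  state <- ifelse(abs(x) > l / 3, sign(x), 0)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  pole <- r$values != 0
  censored <- pole & (starts == 1 | ends == length(x))
  dwells <- r$lengths[pole & !censored] * traj$frame_interval
  if (length(dwells) == 0 && !any(pole)) {
    warning("pole_dwell_times: trajectory never enters the pole region")
  }
  out <- dwell_time_stats(dwells)
  attr(out, "n_censored") <- sum(censored)
  out
}

#' Double-exponential (mixture) dwell-time fit
#'
#' Maximum-likelihood fit of a two-component exponential mixture
#' `w/tau_s exp(-t/tau_s) + (1-w)/tau_l exp(-t/tau_l)` to dwell samples by
#' expectation-maximization, with `tau_long >= tau_short` enforced by
#' ordering. Degenerate fits (component weight collapsing) fall back to
#' the single-exponential description with a flag.
#'
#' @param stats A `dwell_time_stats` (>= 20 events) or numeric vector.
#' @param max_iter,tol EM iteration cap and relative parameter-change
#'   tolerance (invariant under time-unit rescaling).
#' @return List with `tau_long`, `tau_short`, `weight_short`,
#'   `log_lik`, `log_lik_single`, `fallback_single`.
#' @export
fit_double_exponential <- function(stats, max_iter = 500, tol = 1e-8) {
  samples <- if (inherits(stats, "dwell_time_stats")) stats$samples else stats
  n <- length(samples)
  if (n < 20) stop("fit_double_exponential: need at least 20 events")
  t <- samples
  med <- stats::median(t)
  tau1 <- mean(t[t <= med])
  tau2 <- mean(t[t > med])
  if (tau1 <= 0) tau1 <- min(t)
  w <- 0.5
  fallback <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dexp(t, 1 / tau1)
    d2 <- (1 - w) * stats::dexp(t, 1 / tau2)
    tot <- d1 + d2
    g <- d1 / tot
    w_new <- mean(g)
    if (w_new < 1e-8 || w_new > 1 - 1e-8) { fallback <- TRUE; break }
    tau1_new <- sum(g * t) / sum(g)
    tau2_new <- sum((1 - g) * t) / sum(1 - g)
    # parameter-relative stopping rule (invariant under time-unit change)
    delta <- max(abs(tau1_new - tau1) / tau1, abs(tau2_new - tau2) / tau2,
                 abs(w_new - w))
    w <- w_new; tau1 <- tau1_new; tau2 <- tau2_new
    if (delta < tol) break
  }
  ll_single <- sum(stats::dexp(t, 1 / mean(t), log = TRUE))
  taus <- sort(c(tau1, tau2))
  w_short <- if (tau1 <= tau2) w else 1 - w
  if (fallback) {
    taus <- c(mean(t), mean(t))
    w_short <- 0
  }
  list(tau_long = taus[2], tau_short = taus[1], weight_short = w_short,
       log_lik = sum(log(w_short * stats::dexp(t, 1 / taus[1]) +
                           (1 - w_short) * stats::dexp(t, 1 / taus[2]))),
       log_lik_single = ll_single, fallback_single = fallback)
}

#' Per-axis mean-squared displacement of a trajectory
#'
#' Time-averaged MSD at each lag, projected on the cavity major (x,
#' "parallel") and minor (y, "perpendicular") axes:
#' `MSD_par(k dt) = mean_t (x(t + k dt) - x(t))^2`.
#'
#' @param traj A `trajectory`.
#' @param max_lag Largest lag (s); truncated with a warning if it exceeds
#'   the trajectory duration.
#' @return An object of class `msd_result`: data.frame-like list with
#'   `lags` (s), `msd_parallel`, `msd_perpendicular` (um^2).
#' @export
msd_per_axis <- function(traj, max_lag) {
  dt <- traj$frame_interval
  n <- length(traj$x)
  k_max <- floor(max_lag / dt + 1e-9)
  if (k_max > n - 1) {
    warning("msd_per_axis: max_lag exceeds trajectory duration; truncated")
    k_max <- n - 1
  }
  if (k_max < 1) stop("msd_per_axis: max_lag below one frame interval")
  lags <- seq_len(k_max) * dt
  mx <- vapply(seq_len(k_max), function(k) {
    mean((traj$x[(k + 1):n] - traj$x[1:(n - k)])^2)
  }, numeric(1))
  my <- vapply(seq_len(k_max), function(k) {
    mean((traj$y[(k + 1):n] - traj$y[1:(n - k)])^2)
  }, numeric(1))
  structure(list(lags = lags, msd_parallel = mx, msd_perpendicular = my),
            class = "msd_result")
}

#' Ensemble-averaged per-axis MSD
#'
#' Averages the time-averaged per-axis MSDs of a set of clips (equal
#' length and frame interval).
#'
#' @param trajs List of `trajectory` objects.
#' @param max_lag Largest lag (s).
#' @return An `msd_result`.
#' @export
msd_ensemble <- function(trajs, max_lag) {
  parts <- lapply(trajs, msd_per_axis, max_lag = max_lag)
  structure(
    list(
      lags = parts[[1]]$lags,
      msd_parallel = rowMeans(vapply(parts, `[[`, numeric(length(parts[[1]]$lags)),
                                     "msd_parallel")),
      msd_perpendicular = rowMeans(vapply(parts, `[[`,
                                          numeric(length(parts[[1]]$lags)),
                                          "msd_perpendicular"))
    ),
    class = "msd_result"
  )
}

#' Short-time anomalous-diffusion exponents from an MSD
#'
#' Power-law fit `MSD ~ lag^alpha` per axis by linear regression of
#' `log(MSD)` on `log(lag)` over a lag window (default up to 1 s, the
#' short-time regime). `alpha = 1` is Brownian; `alpha < 1` sub-diffusive.
#'
#' @param msd An `msd_result`.
#' @param window Two-vector `(lo, hi]` of lags (s); default `c(0, 1)`.
#' @return List with `alpha_parallel`, `alpha_perpendicular`, standard
#'   errors `se_parallel`, `se_perpendicular`, and `n_lags`.
#' @export
fit_msd_exponent <- function(msd, window = c(0, 1)) {
  sel <- msd$lags > window[1] & msd$lags <= window[2]
  fit_one <- function(y) {
    ok <- sel & y > 0
    if (sum(ok) < 4) stop("fit_msd_exponent: fewer than 4 usable lags in window")
    f <- stats::lm(log(y[ok]) ~ log(msd$lags[ok]))
    s <- suppressWarnings(summary(f)$coefficients[2, 2])
    c(unname(stats::coef(f)[2]), s)
  }
  par <- fit_one(msd$msd_parallel)
  per <- fit_one(msd$msd_perpendicular)
  list(alpha_parallel = par[1], se_parallel = par[2],
       alpha_perpendicular = per[1], se_perpendicular = per[2],
       n_lags = sum(sel))
}

#' Contour-averaged density profile
#'
#' Mean probability density in bins of a normalized radial coordinate:
#' the plain radius `r / semi_major` ("radial" mode, intended for
#' circular cavities) or the effective elliptical coordinate `r_eff`
#' ("elliptical" mode). Bins are uniform on `[0, 1]`; empty bins are NA.
#'
#' @param prob A probability `scalar_field`.
#' @param cavity A `cavity_geometry`.
#' @param mode "radial" or "elliptical".
#' @param n_bins Number of bins (default 40).
#' @return Data.frame with `mid` (bin midpoint, normalized), `density`
#'   (um^-2), `n_cells`.
#' @export
contour_profile <- function(prob, cavity, mode = c("radial", "elliptical"),
                            n_bins = 40) {
  mode <- match.arg(mode)
  co <- field_coords(prob)
  ij <- which(prob$mask, arr.ind = TRUE)
  x <- co$x[ij[, 1]]
  y <- co$y[ij[, 2]]
  rho <- if (mode == "radial") {
    sqrt(x^2 + y^2) / cavity$semi_major
  } else {
    effective_radius(cavity, x, y)
  }
  bin <- pmin(pmax(ceiling(rho * n_bins), 1L), n_bins)
  dens <- prob$values[prob$mask]
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  out <- data.frame(
    mid = mids,
    density = as.numeric(tapply(dens, factor(bin, seq_len(n_bins)), mean)),
    n_cells = as.numeric(table(factor(bin, seq_len(n_bins))))
  )
  out
}

#' Distribution edge of a density profile
#'
#' The outermost point, scanning outward from the profile maximum, at
#' which the density falls to `1/e` of its maximum (linear interpolation
#' between bins). If the profile never falls below `max/e`, the edge is
#' reported as 1.0 with `flagged = TRUE`.
#'
#' @param profile Data.frame from [contour_profile()].
#' @return List with `edge` (normalized coordinate) and `flagged`.
#' @export
distribution_edge <- function(profile) {
  ok <- !is.na(profile$density)
  mid <- profile$mid[ok]
  dens <- profile$density[ok]
  if (length(dens) == 0 || max(dens) <= 0) {
    stop("distribution_edge: profile has no positive maximum")
  }
  m <- which.max(dens)
  target <- dens[m] / exp(1)
  cross <- NULL
  if (m < length(dens)) {
    for (i in m:(length(dens) - 1)) {
      if (dens[i] >= target && dens[i + 1] < target) cross <- i
    }
  }
  if (is.null(cross)) {
    return(list(edge = 1.0, flagged = TRUE))
  }
  frac <- (dens[cross] - target) / (dens[cross] - dens[cross + 1])
  list(edge = mid[cross] + frac * (mid[cross + 1] - mid[cross]),
       flagged = FALSE)
}

#' Edge displacement between two profiles
#'
#' Physical (um) displacement of the distribution edge between two
#' profiles on the same normalized coordinate, e.g. uncrowded vs crowded;
#' positive when profile `b`'s edge lies inward of profile `a`'s. The
#' normalized shift is scaled by the cavity radius (radial mode) or the
#' contour mean radius `(A + B)/2` (elliptical mode).
#'
#' @param profile_a,profile_b Profiles from [contour_profile()].
#' @param cavity A `cavity_geometry`.
#' @param mode "radial" or "elliptical" (must match the profiles).
#' @return List with `shift_um` and `flagged` (TRUE if either edge was
#'   flagged).
#' @export
edge_shift <- function(profile_a, profile_b, cavity,
                       mode = c("radial", "elliptical")) {
  mode <- match.arg(mode)
  ea <- distribution_edge(profile_a)
  eb <- distribution_edge(profile_b)
  scale <- if (mode == "radial") {
    cavity$semi_major
  } else {
    (cavity$semi_major + cavity$semi_minor) / 2
  }
  list(shift_um = (ea$edge - eb$edge) * scale,
       flagged = ea$flagged || eb$flagged)
}
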