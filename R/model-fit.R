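#' Cosine similarity of two distributions
#'
#' `sum(p_i q_i) / (||p||_2 ||q||_2)` over interior cells; 1 for identical
#' shapes, 0 for disjoint supports, invariant to overall positive
#' rescaling of either field. The two fields must live on identical grids.
#'
#' @param p,q Probability `scalar_field`s on the same grid.
#' @return Cosine similarity in `[0, 1]` for non-negative fields.
#' @export
cosine_similarity <- function(p, q) {
  if (!identical(dim(p$values), dim(q$values)) ||
      abs(p$spacing - q$spacing) > 1e-12 || !identical(p$mask, q$mask)) {
    stop("cosine_similarity: grids/masks differ")
  }
  a <- p$values[p$mask]
  b <- q$values[q$mask]
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero-norm field")
  sum(a * b) / (na * nb)
}

# model distribution for given parameters, on the fine grid, binned down
# to the observed resolution. rho_vec, wall kernel distances D and patch
# lengths ds are precomputed once per fit.
.model_distribution <- function(a, wall_strength, decay_range, rho_vals,
                                D, ds, template, target_spacing) {
  u <- a * rho_vals + wall_strength * as.numeric(exp(-D / decay_range) %*% ds)
  p <- exp(-(u - min(u)))
  vals <- matrix(0, nrow(template$mask), ncol(template$mask))
  vals[template$mask] <- p / (sum(p) * template$spacing^2)
  f <- scalar_field(vals, template$spacing, template$origin, template$mask,
                    cavity = template$cavity, role = "probability")
  bin_to_resolution(f, target_spacing)
}

#' Fit the plasmid-potential model to an observed position distribution
#'
#' Finds the exclusion coefficient `a`, wall strength and wall decay range
#' that maximize the cosine similarity between the observed binned plasmid
#' position distribution and the modeled Boltzmann distribution
#' `P ~ exp(-(a*rho + U_wall))`, binned to the observation resolution.
#'
#' The objective surface is plateaued, so a derivative-free strategy is
#' used: a log-spaced seed grid over the parameter box (default 5x5x5),
#' then Nelder-Mead restarts in log-parameter space from the best seeds.
#' The search is deterministic for a fixed configuration; the full
#' evaluation trace is returned.
#'
#' @param observed Observed probability `scalar_field` (e.g. from
#'   [position_histogram()] at 50 nm bins).
#' @param cavity A `cavity_geometry`.
#' @param density The chain concentration `scalar_field` (from
#'   [solve_gsd()]), on a grid at least as fine as the observation.
#' @param family Kernel family; only "exponential" is fit (the WCA family
#'   can be evaluated through [wall_potential()] but its two parameters
#'   are strongly degenerate with `a` under the cosine objective).
#' @param bounds Named list with two-vectors `a`, `wall_strength`,
#'   `decay_range`; defaults `a` in \[1e-8, 1e-4\] kBT um^3 bp^-1,
#'   `wall_strength` in \[1e-2, 1e3\] kBT um^-1, `decay_range` in
#'   \[0.02, 1\] um.
#' @param init Optional named vector of starting values; if supplied it is
#'   added to the seed set.
#' @param n_seed Seed-grid points per axis (default 5).
#' @param n_restarts Nelder-Mead restarts from the best seeds (default 3).
#' @param n_segments Boundary patches for the wall integral.
#' @param maxit Nelder-Mead iteration cap per restart.
#' @return An object of class `fit_result`: `params` (list with
#'   `exclusion` and `kernel`), `objective`, `trace` (data.frame of all
#'   evaluations), `config`.
#' @export
fit_plasmid_model <- function(observed, cavity, density,
                              family = "exponential", bounds = NULL,
                              init = NULL, n_seed = 5, n_restarts = 3,
                              n_segments = 720, maxit = 200) {
  if (family != "exponential") {
    stop("only the exponential kernel family is supported by the fit")
  }
  default_bounds <- list(a = c(1e-8, 1e-4), wall_strength = c(1e-2, 1e3),
                         decay_range = c(0.02, 1.0))
  bounds <- utils::modifyList(default_bounds, bounds %||% list())

  template <- cavity_grid(cavity, density$spacing, cover = "center")
  if (!identical(dim(template$values), dim(density$values))) {
    stop("density grid is not the canonical cavity grid at its spacing")
  }
  rho_vals <- density$values[density$mask]
  segs <- boundary_segments(cavity, n_segments)
  co <- field_coords(template)
  ij <- which(template$mask, arr.ind = TRUE)
  D <- .segment_distances(segs, co$x[ij[, 1]], co$y[ij[, 2]])
  ds <- segs$arc_length
  target_spacing <- observed$spacing

  check <- bin_to_resolution(
    scalar_field(ifelse(density$mask, 1, 0) /
                   (sum(density$mask) * density$spacing^2),
                 density$spacing, density$origin, density$mask,
                 cavity = cavity, role = "probability"),
    target_spacing
  )
  if (!identical(dim(check$values), dim(observed$values))) {
    stop("observed grid does not match the binned model grid; build it with position_histogram() on the same cavity")
  }

  trace <- list()
  objective <- function(theta, stage) {
    a <- exp(theta[1]); w <- exp(theta[2]); rb <- exp(theta[3])
    if (a < bounds$a[1] || a > bounds$a[2] ||
        w < bounds$wall_strength[1] || w > bounds$wall_strength[2] ||
        rb < bounds$decay_range[1] || rb > bounds$decay_range[2]) {
      return(-1)
    }
    model <- .model_distribution(a, w, rb, rho_vals, D, ds, template,
                                 target_spacing)
    obj <- cosine_similarity(observed, model)
    trace[[length(trace) + 1L]] <<- c(a = a, wall_strength = w,
                                      decay_range = rb, objective = obj,
                                      stage = stage)
    obj
  }

  lseq <- function(b, n) exp(seq(log(b[1]), log(b[2]), length.out = n))
  seeds <- as.matrix(expand.grid(
    a = lseq(bounds$a, n_seed),
    wall_strength = lseq(bounds$wall_strength, n_seed),
    decay_range = lseq(bounds$decay_range, n_seed)
  ))
  if (!is.null(init)) {
    seeds <- rbind(seeds, c(init[["a"]], init[["wall_strength"]],
                            init[["decay_range"]]))
  }
  seed_obj <- apply(seeds, 1, function(s) objective(log(s), stage = 1))
  best_idx <- order(seed_obj, decreasing = TRUE)[seq_len(min(n_restarts, nrow(seeds)))]

  best_seed_val <- max(seed_obj)
  polish_vals <- vapply(best_idx, function(k) {
    opt <- stats::optim(log(seeds[k, ]), function(th) -objective(th, stage = 2),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    -opt$value
  }, numeric(1))
  grid_only <- max(polish_vals) < best_seed_val - 1e-12
  if (grid_only) {
    warning("fit_plasmid_model: Nelder-Mead fell below the seed grid; returning best-of-grid")
  }

  trace_df <- as.data.frame(do.call(rbind, trace))
  # return the best parameters actually evaluated (guards against the
  # simplex terminating off its best-ever point)
  best_row <- trace_df[which.max(trace_df$objective), ]
  pars <- c(best_row$a, best_row$wall_strength, best_row$decay_range)
  best_val <- best_row$objective
  structure(
    list(
      params = list(
        exclusion = exclusion_params(pars[[1]]),
        kernel = kernel_params("exponential", wall_strength = pars[[2]],
                               decay_range = pars[[3]])
      ),
      objective = best_val,
      grid_only = grid_only,
      trace = trace_df,
      config = list(bounds = bounds, n_seed = n_seed,
                    n_restarts = n_restarts, n_segments = n_segments,
                    maxit = maxit, grid_spacing = density$spacing,
                    target_spacing = target_spacing)
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Plasmid-model fit: a = %.3g kBT um^3/bp, wall_strength = %.3g kBT/um, r_b = %.3g um\n  cosine objective = %.5f (%d evaluations)\n",
    x$params$exclusion$a_coefficient, x$params$kernel$wall_strength,
    x$params$kernel$decay_range, x$objective, nrow(x$trace)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
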