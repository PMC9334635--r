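#!/usr/bin/env Rscript
# Stage 3: polar organization and pole swapping of two confined chains.
#
# Simulates the two-blob chain surrogate across cavity eccentricities,
# then runs the full descriptive pipeline: center-of-mass position
# histograms and free-energy maps, separation-vector angle distribution,
# alignment order parameter, and pole-swap dwell statistics.

suppressPackageStartupMessages(library(cavitydemix))
dir.create("results", showWarnings = FALSE)

eccs <- c(0, 0.3, 0.6, 0.9)
rows <- list()
dwell_rows <- list()
for (e in eccs) {
  cav <- make_cavity(e, 1.0, 0.2)
  tb <- simulate_two_blobs(two_blob_config(cav, seed = 11))
  ss <- separation_series(tb[[1]], tb[[2]], cav)
  P <- position_histogram(tb, cav, 0.1)
  F <- free_energy_map(P)
  sw <- detect_swaps(ss)
  tau_fit <- if (sw$stats$n_events >= 5) {
    fit_exponential_dwell(sw$stats)$tau
  } else NA_real_
  rows[[length(rows) + 1]] <- data.frame(
    eccentricity = e,
    S_align = order_parameter(ss),
    S_literal_minor = order_parameter(ss, convention = "minor"),
    n_swaps = sw$n_swaps,
    mean_dwell_s = mean(sw$stats$samples),
    tau_ccdf_fit_s = tau_fit,
    p_center_over_max = field_interp(P, 0, 0) / max(P$values),
    f_barrier_kBT = field_interp(F, 0, 0) - min(F$values[F$mask])
  )
  if (sw$stats$n_events > 0) {
    dwell_rows[[length(dwell_rows) + 1]] <- data.frame(
      eccentricity = e, dwell_s = sw$stats$samples)
  }
  message(sprintf(
    "e = %.1f: S = %.2f, %d swaps, mean dwell %.1f s, center/max = %.2f",
    e, order_parameter(ss), sw$n_swaps, mean(sw$stats$samples),
    field_interp(P, 0, 0) / max(P$values)))
}
write.csv(do.call(rbind, rows), "results/two_chain_summary.csv",
          row.names = FALSE)
write.csv(do.call(rbind, dwell_rows), "results/two_chain_dwells.csv",
          row.names = FALSE)
message("Wrote results/two_chain_summary.csv, two_chain_dwells.csv")
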