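# cavitydemix

Entropy-driven demixing of DNA molecules in shallow elliptical
nanocavities: equilibrium models, Boltzmann fits, Brownian dynamics, and
trajectory statistics, with synthetic-data generators in place of the
microscope.

Two self-avoiding DNA coils confined together in a slit-like cavity demix
rather than mix: overlap costs conformational entropy. In a circular
cavity the pair forms an opposed, freely rotating dimer; making the
cavity elliptical at constant area breaks the rotational symmetry and
locks the pair onto the poles, with thermally activated pole swaps whose
rate falls as eccentricity grows. A small plasmid confined with one large
chain is likewise squeezed between the chain-occupied interior and the
repulsive wall into a peripheral ring that becomes pole-peaked at high
eccentricity — a minimal physical picture for nucleoid occlusion and the
polar clustering of high-copy-number plasmids in bacteria. This package
is for single-molecule biophysicists and polymer physicists who want that
entire analysis chain as tested, scriptable R.

## The model

- **Geometry.** Constant-area ellipse family at fixed depth
  h = 0.2 µm: semi-axes `A = r0 (1-e²)^(-1/4)`, `B = r0 (1-e²)^(1/4)`,
  so `AB = r0²` (2 µm circle → 3 µm long axis at e = 0.9).
- **Chain concentration.** Ground-state dominance:
  `ρ ∝ ψ²` with `-(a_k²/6)∇²ψ + gψ³ = λψ`, `ψ = 0` on the boundary —
  solved by a Shortley–Weller (boundary-fitted) finite-difference
  normalized gradient flow.
- **Plasmid potential.** `U_p(r) = a ρ(r) + ∮ u(|r_s − r|) ds` with an
  exponential (or WCA) wall kernel integrated along the boundary;
  equilibrium positions follow `P(r) ∝ exp(−U_p/k_BT)`.
- **Fit.** `(a, b, r_b)` maximize the cosine similarity between modeled
  and observed 50 nm-binned position distributions (seed grid +
  log-space Nelder–Mead).
- **Dynamics.** Overdamped Euler–Maruyama on `F = −k_BT log P` with
  reflecting walls; per-axis MSD exponents, pole-swap and pole-dwell
  statistics with exponential and mixture fits, order parameter
  `S_align = 2⟨cos²(π/2 − θ) − ½⟩`, crowding density profiles and 1/e
  distribution edges.

## Worked example

```r
library(cavitydemix)

cav <- make_cavity(eccentricity = 0.9, reference_radius = 1.0)
cav
#> Elliptical cavity: e = 0.900, A = 1.5146 um, B = 0.6602 um, depth = 0.200 um

rho  <- solve_gsd(cav)                 # mean-field chain concentration
pars <- reference_model_params(cav)    # fitted-scale a, wall kernel
U <- total_potential(exclusion_potential(rho, pars$exclusion),
                     wall_potential(cav, pars$kernel))
P <- bin_to_resolution(boltzmann_distribution(U), 0.05)

range_at_threshold(cav, pars$kernel)   # 2 kBT standoff from the wall
#> [1] 0.19

# where does the plasmid sit? (major-axis pole preference)
field_coords(P)$x[which(P$values == max(P$values), arr.ind = TRUE)[1, 1]]
#> [1] -0.825

# two-chain surrogate: polar order and pole swapping
tb <- simulate_two_blobs(two_blob_config(cav, n_frames = 10000, seed = 11))
ss <- separation_series(tb[[1]], tb[[2]], cav)
order_parameter(ss)                    # 1 = polar alignment, 0 = isotropic
#> [1] 0.9248068
detect_swaps(ss)$n_swaps               # pole swaps in 500 s of video
#> [1] 2
```

Read: at e = 0.9 the wall repulsion reaches 2 k_BT about 190 nm from the
boundary, the modeled plasmid distribution peaks near the poles
(|x| ≈ 0.8 µm of a 1.51 µm semi-major axis), and the two-chain system is
strongly polar (S ≈ 0.92) with rare pole swaps.

## The analysis pipeline

Numbered scripts under `analysis/` run the full study on synthetic data
and write tables under `results/`:

1. `01_cavity_model.R` — cavity family, chain profiles, potentials,
   Boltzmann maps, 2 k_BT wall range.
2. `02_fit_recovery.R` — 50,000 sampled positions at e = 0.6; fit
   recovers the wall decay range to a few percent at cosine
   objective > 0.99.
3. `03_two_chain_demixing.R` — two-blob simulations across
   e ∈ {0, 0.3, 0.6, 0.9}: donut → bipolar distributions, rising order
   parameter, swap dwell times growing from ~3 s to ~150 s.
4. `04_plasmid_dynamics.R` — Brownian dynamics on fitted landscapes
   (250 clips × 3000 steps): sub-diffusive major-axis MSD exponents,
   two-timescale pole dwells.
5. `05_crowding.R` — crowding emulation at volume fraction 0.063:
   inward shift of the 1/e distribution edge, amplified by anisotropy.

Run them in order from the repository root:
`Rscript analysis/01_cavity_model.R` etc.

## Layout

```
R/                 geometry, fields, mean-field solver, potentials, fit,
                   landscape dynamics, trajectory statistics, generators
src/               compiled Brownian-dynamics cores (Rcpp)
analysis/          numbered pipeline scripts (write to results/)
scripts/           acceptance.R
tests/testthat/    unit, property and end-to-end tests
vignettes/         methods vignette (model, numerics, design choices)
```
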