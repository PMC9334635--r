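---
title: "Methods: modeling DNA demixing in elliptical nanocavities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling DNA demixing in elliptical nanocavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitydemix)
```

## The physical problem

Two long, self-avoiding DNA molecules confined together in a shallow
(slit-like) cavity pay an entropic price for overlapping. When the cavity
is circular the two coils displace each other into an opposed pair that
rotates freely; when the cavity is made elliptical at constant area, the
rotational symmetry is broken and the pair locks onto the poles of the
long axis, swapping ends only by thermally activated barrier crossing. A
small plasmid confined with one large chain feels the same physics as a
tracer: it is excluded from the chain-occupied interior and repelled from
the cavity wall, and the competition carves a ring-shaped — and, at high
eccentricity, pole-peaked — equilibrium distribution.

`cavitydemix` implements this entire analysis chain: the equilibrium
model, the fit of its parameters to position histograms, stochastic
dynamics on empirical free-energy landscapes, and the descriptive
statistics of trajectories, together with synthetic-data generators that
replace the microscope. The numbered scripts under `analysis/` run the
stages in order; every computation they perform lives in the package and
is exercised by the test suite. The package is driven from R; the
analysis scripts are the pipeline interface.

## Geometry

Cavities form a constant-volume family at fixed etch depth
$h = 0.2\,\mu\mathrm{m}$, so constant volume means constant footprint
area. With $r_0$ the radius of the circular member, the ellipse at
eccentricity $e$ has semi-axes

$$A = r_0 (1-e^2)^{-1/4}, \qquad B = r_0 (1-e^2)^{+1/4},$$

so $AB = r_0^2$ exactly; at $r_0 = 1\,\mu\mathrm{m}$ the maximum diameter
grows from $2\,\mu\mathrm{m}$ ($e=0$) to $\approx 3\,\mu\mathrm{m}$
($e=0.9$). All modules share a cavity-centered Cartesian frame with $x$
along the major axis, lengths in micrometres, energies in units of
$k_BT$. The boundary is parameterized by the standard angle (closed form,
no root finding); arc-length weights
$\sqrt{A^2\sin^2 t + B^2\cos^2 t}\,\Delta t$ carry the metric, and the
midpoint rule on this smooth periodic integrand converges spectrally.

## Mean-field chain concentration

The large chain is treated as a semi-dilute solution whose monomer
concentration follows ground-state dominance: $\rho \propto \psi^2$ where
$\psi$ is the nodeless minimizer of

$$E[\psi] = \int \left[ \tfrac{a_k^2}{6} |\nabla\psi|^2 +
\tfrac{g}{2}\,\psi^4 \right] dA, \qquad \int \psi^2\,dA = 1, \qquad
\psi|_{\partial\Omega} = 0,$$

the Euler–Lagrange equation being the nonlinear Schrödinger
(Gross–Pitaevskii-type) eigenproblem
$-\tfrac{a_k^2}{6}\nabla^2\psi + g\psi^3 = \lambda\psi$. The Kuhn length
is $a_k = 0.1\,\mu\mathrm{m}$ (twice the 50 nm persistence length); T4
DNA defaults are 60 µm of contour, 166,000 bp, about 600 Kuhn segments.
The 200 nm slit dimension is integrated out, so
$\rho = (\mathrm{bp}/h)\,\psi^2$ in $\mathrm{bp}\,\mu\mathrm{m}^{-3}$.

**Numerics.** The Laplacian is a Shortley–Weller 5-point stencil on an
edge-aligned Cartesian grid: for cells adjacent to the boundary the
stencil legs are shortened to the true ellipse crossing, which restores
the $O(h^2)$ accuracy a plain staircase mask destroys (a masked Laplacian
at spacing $R/100$ leaves $\sim 1\%$ eigenfunction error; the
boundary-fitted stencil reaches the $10^{-4}$ scale and passes a
$10^{-3}$ $L_2$ comparison against the circular-cavity Bessel mode
$J_0(j_{0,1} r/R)$). The ground state is found by a semi-implicit
normalized gradient flow — backward Euler in the Laplacian (one sparse LU
factorization, reused), explicit in the cubic term, renormalization and
eigenvalue evaluation each step. The step is halved and the operator
refactored whenever $\lambda$ fails to decrease, so the flow is
energy-descending by construction; convergence is declared on the
relative change of $\lambda$ (default $10^{-8}$). Initialization is the
symmetric paraboloid $(1 - (x/A)^2 - (y/B)^2)_+$, which guarantees a
nodeless, symmetry-respecting start. Default grid spacing is 25 nm, half
the 50 nm comparison bin.

**Choice of the self-interaction `g`.** Position data do not determine
the chain self-interaction magnitude, and only the profile *shape*
matters downstream (the amplitude is absorbed into the fitted exclusion
coefficient). The flat-center (Thomas–Fermi) regime is ruled out by the
observed phenomenology: if $\rho$ is flat except for a thin healing zone
at the wall, the total plasmid potential is minimized at the cavity
center for *any* exclusion strength and no ring can form. The default
therefore sets the peak self-interaction energy density to half the
linear confinement eigenvalue ($g\,\psi_c^2 = \lambda_{\rm lin}/2$, found
from a preliminary linear solve): mildly semi-dilute, dome-preserving,
and producing the ring ($e=0$) and off-center major-axis wells
($e=0.9$, depth $\approx 0.2\,k_BT$) at the fitted parameter scale. `g`
remains exposed, and solver metadata records the value used.

## Plasmid potential and Boltzmann fit

The plasmid potential is
$U_p(\mathbf r) = a\,\rho(\mathbf r) + U_{\rm wall}(\mathbf r)$, with

$$U_{\rm wall}(\mathbf r) = \oint u(|\mathbf r_s - \mathbf r|)\, ds,$$

the boundary line integral of a short-ranged kernel: exponential
$u(d) = b\,e^{-d/r_b}$ by default, or a truncated-shifted
Lennard-Jones (WCA) alternative cut at $2^{1/6}\sigma$ and capped at
$10^3\,k_BT\,\mu\mathrm{m}^{-1}$ so contact stays finite (the cap only
affects positions the plasmid never occupies; there is no single
canonical per-arc-length WCA normalization, so the standard
truncated-shifted form is adopted and stated). Wall distances use exact point-to-patch-midpoint
distances; at 720 patches the discretization error is below grid
resolution (verified against adaptive quadrature to $10^{-3}$ relative,
typically $10^{-15}$). The equilibrium position distribution is
$P \propto e^{-U_p/k_BT}$, normalized on the cavity interior and block-
summed to the 50 nm measurement resolution for comparison — no kernel
smoothing, matching direct-histogram comparisons.

`reference_model_params()` provides the fitted-scale operating point used
across the analyses: $a = 1.1\times10^{-6}\,k_BT\,\mu\mathrm{m}^3\,
\mathrm{bp}^{-1}$, $r_b = 0.1\,\mu\mathrm{m}$, and wall strength
calibrated so the boundary potential reaches $2\,k_BT$ at 190 nm from the
wall — the interaction-range scale of a ~100 nm plasmid (whose
light-scattering radius of 102 nm rescales to ~140 nm at the ~10 nm
effective DNA width of a low-salt buffer, via the self-avoiding-coil
$R_g \sim w^{1/5}$ law). The sphere-approximation conversion from $a$ to
an effective plasmid radius ($v = a \times 300\,\mathrm{bp}$,
$v = \tfrac43\pi r_p^3$) gives $\approx 43$ nm and is provided for
order-of-magnitude use only; it sits below light-scattering size
estimates and is documented as such.

**Fitting.** Parameters $(a, b, r_b)$ maximize the cosine similarity
$\sum p_i q_i / (\|p\|\,\|q\|)$ between the observed and modeled binned
distributions. The objective is plateaued and scale-degenerate in places,
so the search is derivative-free: a $5^3$ log-spaced seed grid over the
bounds ($a \in [10^{-8}, 10^{-4}]$, $b \in [10^{-2}, 10^{3}]$,
$r_b \in [0.02, 1]$ in the units above), then Nelder–Mead in log space
from the best three seeds. The returned parameters are the best point
actually evaluated (guarding against the simplex terminating off its
best vertex); the full evaluation trace is kept, and restart spread — not
a covariance — is the uncertainty report. Wall-kernel distances and the
chain profile are precomputed once per fit, so one objective evaluation
is a single matrix-vector pass. Self-consistency: 50,000 positions
sampled from a known model on the $e=0.6$ cavity return the decay range
within a few percent at cosine objective > 0.99.

## Brownian dynamics on empirical landscapes

A position distribution is converted to a free energy by
$F = -k_BT \log P$ with $P$ floored at half its smallest positive value
(never-visited and exterior cells stay strongly repulsive but finite;
floor fraction 0.5 by default) and the minimum shifted to zero. The
overdamped Euler–Maruyama update
$\Delta\mathbf r = -D\,\nabla F\,\Delta t + \sqrt{2D\,\Delta t}\,
\boldsymbol\eta$ uses central differences of the bilinear interpolant for
$\nabla F$ and a rejection-resampling reflecting boundary: a step that
would leave the ellipse is discarded and its noise redrawn (up to 50
tries, then the particle stays). Neither $D$ nor $\Delta t$ is
constrained by equilibrium position data; defaults are $D = 0.5\,\mu\mathrm{m}^2\mathrm{s}^{-1}$
(a ~100 nm particle in aqueous buffer) and $\Delta t$ such that the
thermal step is 0.4 grid spacings — the MSD exponents that are compared
downstream are insensitive to $D$ at matched lag ranges. Each clip is
seeded deterministically, so identical configurations are bitwise
reproducible. Ergodicity is verified directly: pooled occupancy from
stationary-start clips matches $e^{-F}$ with total-variation distance
below 0.05 at $10^6$ total steps.

## Trajectory statistics

*Tracking.* Synthetic movies are Gaussian point-spread renders (default
5000 photons/frame, Poisson noise) of trajectories; centroids are
intensity-weighted means after border-ring median background subtraction
— a simple, documented substitute for dedicated denoising algorithms —
plus a 4-robust-SD noise floor that prevents clipped shot noise from
biasing centroids toward the frame center.

*Separation vector and order parameter.* For two molecules,
$\mathbf r = \mathbf r_1 - \mathbf r_2$; $\theta$ is the angle to the
minor axis folded into $[0,\pi)$ so molecule relabeling is immaterial.
The literal order parameter $2\langle\cos^2\theta - \tfrac12\rangle$ with
$\theta$ from the *minor* axis decreases to $-1$ under polar alignment,
contradicting the increase it is meant to describe; the package therefore
reports $S_{\rm align} = 2\langle\cos^2(\pi/2-\theta) - \tfrac12\rangle$
(angle to the *major* axis: 1 = polar, 0 = isotropic) by default and
exposes the literal convention as an option.

*Pole swaps.* The normalized major-axis projection of $\mathbf r$ is a
two-state signal. State assignment uses hysteresis: a state is entered
when the projection crosses $\pm 0.5$ and retained until the *opposite*
threshold is crossed, so failed swap attempts — spikes that revert —
never count. The first and last intervals are censored. No debouncing
rule is published; hysteresis is this package's explicit, testable
choice. Dwell times are fit on the log survival curve by weighted least
squares (weights = inverse sampling variance of $\log\hat S$, taming the
noisy tail); the sample mean is reported alongside.

*Pole dwells and mixtures.* A single molecule is "at a pole" while
$|x| > l/3$ with consistent sign, $l$ being the maximum extension
(default: observed $\max|x|$, recomputed per dataset); runs crossing
poles split at the sign change. Two-timescale dwell histograms are fit by
maximum-likelihood EM on the two-component exponential mixture (ordering
enforced, parameter-relative stopping so the fit is invariant under time
units, collapse to one component flagged and reported against the
single-exponential likelihood).

*MSD.* Time-averaged per-axis MSDs, ensemble-averaged over clips;
short-time exponents from log-log regression over lags up to 1 s.
Free diffusion recovers $\alpha = 1.00 \pm 0.05$ and $D$ within 5%;
on the fitted $e=0.9$ landscape at 250 clips × 3000 steps the major-axis
exponent is sub-diffusive, as expected for motion on a structured
landscape. Measured minor-axis exponents of tracers in polymer
solutions fall harder than any landscape-only simulation because the
solution modifies the local microrheology; that physics is deliberately out of scope here, so
agreement is expected for the major axis only.

*Crowding.* Density profiles are averaged over radii (circular cavities)
or confocal elliptical contours labeled by
$r_{\rm eff} = \sqrt{x^2/A^2 + y^2/B^2}$; the distribution edge is the
outermost $1/e$-of-maximum crossing (linear interpolation; a profile that
never falls below the threshold is flagged at 1.0). Edge shifts convert
to micrometres via the cavity radius (radial) or the contour mean radius
$(A+B)/2$ (elliptical). Crowders are emulated at the parameter level —
wall range scaled by $(1 + 5 v_\phi)$ and exclusion by $(1 + 5 v_\phi)$ —
encoding the observed phenomenology (inward edge displacement, enhanced
segregation, amplified by anisotropy) rather than simulating explicit
crowder particles; the coefficients are declared phenomenological and are
not fitted to the experimental shift magnitudes.

## The two-chain surrogate

The synthetic stand-in for two confined chains is a pair of point blobs
with a Gaussian-core mutual repulsion
$U_{\rm pair} = \varepsilon_p \exp(-|\mathbf r_1-\mathbf r_2|^2 /
2\sigma_p^2)$ plus the wall potential, integrated by Euler–Maruyama with
the same reflecting boundary. Defaults are chosen once, on physical
grounds, to represent two lambda-DNA coils: $\sigma_p = 0.7\,\mu\mathrm{m}$
(the coil gyration radius), $\varepsilon_p = 10\,k_BT$ (the order-10
$k_BT$ overlap penalty of two cavity-confined self-avoiding coils — the
strongly demixed regime the experiments operate in), wall kernel
$b = 20\,k_BT/\mu\mathrm{m}$, $r_b = 0.15\,\mu\mathrm{m}$ (about
$2\,k_BT$ at a 0.2 µm standoff), $D = 0.3\,\mu\mathrm{m}^2\mathrm{s}^{-1}$,
2 ms integration steps recorded every 50 ms, 30,000 frames (1500 s of
surrogate video). With matched parameters across $e \in \{0, 0.3, 0.6,
0.9\}$ the pipeline reproduces the demixing phenomenology end to end:
an annular center-of-mass distribution at $e=0$, pole-peaked maxima
within 15° of the major axis and $S_{\rm align} > 0.9$ at $e=0.9$,
monotone growth of $S_{\rm align}$, and mean swap dwell times rising from
seconds to minutes as the waist tightens (the Kramers trend
$\tau \sim e^{\Delta F / k_B T}$).

What the surrogate does *not* model: chain deformability (blobs cannot
squeeze past each other the way real coils do, so high-eccentricity
swaps are rarer than in experiment), internal conformational dynamics,
hydrodynamics, photophysics beyond Gaussian PSF + shot noise, and
explicit crowders. Passing tests therefore certify the *analysis
pipeline* — estimators, fits, and their invariances — on data whose
ground truth is known, not the microscopic faithfulness of the surrogate
to real DNA.

## Problem sizes and determinism

The test suite and scripts use the analyses' standard operating points: 50 nm histogram bins, 50,000 fitted positions,
250 clips × 3000 steps for MSD ensembles, $10^6$ steps for ergodicity
checks, dwell-fit calibrations at $n = 500$ (single) and $n = 2000$
(mixture). Solver grids default to 25 nm spacing; the Bessel-mode
comparison runs at $R/100$. Every stochastic component takes an explicit
integer seed and is bitwise reproducible under it; optimizer traces and
solver metadata (g, $\lambda$, iterations) are recorded with results.

## Known limitations

- The mean-field model loses validity for $e > 0.9$, where the cavity
  becomes tube-like and chain semiflexibility matters; fits there are
  expected to disagree and are not attempted.
- The WCA kernel is provided for robustness checks but is not fit (its
  two parameters are strongly degenerate with $a$ under the cosine
  objective).
- Minor-axis MSD exponents are expected to disagree with experiment by
  construction (no microrheology).
- Crowding coefficients $c_1 = c_2 = 5$ set the direction and ordering of
  edge shifts, not their absolute magnitudes.
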