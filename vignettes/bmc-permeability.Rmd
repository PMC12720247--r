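---
title: "Shell permeability, diffusion and crowding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell permeability, diffusion and crowding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bmcperm)
```

Bacterial microcompartments (BMCs) are closed polyhedral protein shells
whose hexamer and trimer tiles carry central pores a few Angstrom wide.
Whether encapsulated enzymes are starved of substrate depends on the shell's
permeability to small metabolites such as the triose phosphates G3P and
DHAP. This vignette documents the models implemented in **bmcperm**, the
parameters that matter, the design of the synthetic data generators used to
validate every estimator, and the numerical and statistical choices behind
them.

Canonical internal units are Angstrom, nanosecond and kcal/mol throughout;
permeability is reported in cm/s via 1 Å/ns = 10 cm/s, and concentration as
molecules/Å³ with 1 M = 6.022140857e-4 molecules/Å³. All conversions pass
through `bmc_constants`, so there is a single point where units can go
wrong.

## Permeability by transition counting

The permeability coefficient relates molecular flux to area and
concentration difference, $J = P A \Delta C$. At equilibrium the same $P$
can be read off from the rate of spontaneous crossings:
$$P = \frac{x}{2\,c\,A\,t},$$
with $x$ the number of committed crossings in both directions, $c$ the
solute concentration in water, $A$ the shell surface area, and $t$ the
aggregate simulation time. The factor of two credits the bidirectionality
of equilibrium flux.

**Crossing detection.** A crossing is scored by a two-state hysteresis
automaton on each solute's radius relative to the per-frame shell centroid:
the state becomes *inside* only below $R_{in} = R_{mid} - \delta$ and
*outside* only above $R_{out} = R_{mid} + \delta$; each flip emits one
event at the first frame past the threshold (no sub-frame interpolation).
The default half-width $\delta = 10$ Å suppresses single-frame recrossing
noise at the ~5 Å pore scale while keeping the detection band thin relative
to the shell radius. Events for one particle alternate in direction by
construction, which is also a tested invariant.

**Concentration convention.** $c$ is the species count divided by the
aqueous volume, with the aqueous volume inferred from the water count at
55.345 M pure-water molarity (`concentration_estimate`), taken at initial
loading — the only unambiguous reference. For synthetic shell-BD data the
equivalent quantity is the Boltzmann-accessible volume
$\int e^{-\beta G}\,dV$ (`accessible_volume`), since the barrier band
excludes solutes the way shell protein excludes water.

**Shell geometry.** How a shell radius and area are derived from particle
data is not standardized anywhere we know of; `fit_shell_geometry` defines
the center as the shell-particle centroid, $R_{mid}$ as their mean radial
distance, and $A = 4\pi R_{mid}^2$. This is a documented package choice and
users with asymmetric shells should supply their own geometry.

**Errors.** $x$ is treated as Poisson, so the standard error is
$\sqrt{x}/(2cAt)$; at $x = 0$ a one-sided 95% upper bound
($-\ln 0.05$ expected events) is reported instead of a spurious zero
uncertainty.

## Permeability from biased sampling (ISDM)

The inhomogeneous solubility-diffusion model integrates a free-energy
profile $G(\xi)$ and diffusivity profile $D(\xi)$ along the permeation
coordinate:
$$P = \left[\int_{\xi_l}^{\xi_u}
  \frac{\exp(\beta G(\xi))}{D(\xi)}\,d\xi\right]^{-1}.$$

**WHAM.** `wham` implements standard binned iterative WHAM on the window
histograms, converged to 1e-7 relative tolerance on the window free
energies. The default bin width of 0.5 Å matches the conventional window
spacing for pore-axis sampling with a 5 kcal/mol/Å² restraint. A Bayesian
WHAM variant exists in the literature, but its priors are not published in
a reproducible form; standard WHAM plus a Bayesian bootstrap (Dirichlet
weights over each window's samples, 200 seeded resamples, per-bin standard
deviation) is deterministic, testable, and yields the same quantity with an
honest error bar. Adjacent windows must share occupied bins; a sampling gap
is an error naming the interval rather than a silently disconnected
profile. A single unbiased window degenerates to direct Boltzmann
inversion, which is the tested bridge between the two free-energy routes.

**Window diffusivity.** For a harmonically restrained coordinate,
$D = \mathrm{var}(\xi)/\tau_\xi$, with $\tau_\xi$ from an exponential fit
to the normalized autocorrelation function restricted to lags below 2 ps —
the effective exchange interval in replica-exchange umbrella sampling,
beyond which swaps decorrelate the series non-diffusively. Windows with
fewer than 1000 production samples, zero variance, or a non-decaying ACF
are rejected with advice rather than silently fit. Whether synthetic
windows should also emulate swap-induced decorrelation is left
configurable: the generator produces independent windows, and the ACF lag
cap makes the estimator insensitive to that choice.

**Splines and quadrature.** Profiles are smoothed with
generalized-cross-validation cubic smoothing splines
(`stats::smooth.spline`), inverse-variance weighted where errors exist, and
clamped (not extrapolated) outside the data range. The ISDM integral runs
through adaptive quadrature at 1e-8 relative tolerance. Uncertainty is
propagated by resampling $G$ within its standard errors (200 seeded draws).
Conventional integration bounds are ±30 Å for hexamer pores and ±60 Å for
trimer pores, integrated exactly over the stated bounds; a trimer sampled
in two half-ranges should be concatenated on the shared grid before
integration.

**Cylinder correction.** Per-pore REUS estimates are biased upward by the
cylindrical restraint that keeps the molecule over the pore. Treating the
tile as impermeable outside the pore cylinders gives
$$P_{eff} = (n_H P_H + P_T)\,\frac{\pi r^2}{A},$$
with $r = 15$ Å and tile area $A = 16166$ Å² as defaults (area fraction
0.0437). This is exact arithmetic and is tested at printed precision.

## Diffusion and crowding

`msd_lag` computes $D(\Delta t) = \mathrm{MSD}(\Delta t)/(6\Delta t)$ over
all particles and overlapping time origins with stride = lag/2 — a variance
reduction compromise that avoids full autocorrelation bookkeeping. Wrapped
trajectories are refused outright: unwrapping heuristics corrupt diffusion
estimates, and the columnar trajectory format carries an explicit
`unwrapped` header for that reason. The headline lag default is 2 ns, a
scale long enough to average ballistic noise yet short enough to see
confinement. Region-resolved estimates assign particles inside/outside by
radius at the window start and discard windows that straddle a crossing, so
neither subset is contaminated by transiting molecules.

`radial_diffusion_profile` bins particles by radius at the window start and
uses 1 ns displacement intervals; errors come from the spread across
replica trajectories when available, otherwise from a block bootstrap over
time origins — an approximation that understates long-range temporal
correlation and is flagged as such. `radial_density` normalizes counts by
the spherical bin area $4\pi r^2 \Delta r$ and can reduce interior bins'
free area by a protein-occupied fraction (default 0.20).

The Stokes–Einstein–Sutherland fit treats a complex of molecular weight
$MW$ as a sphere of density $\rho$ (default 1.35 g/cm³):
$$D = \frac{k_B T}{6\pi\eta}\left(\frac{4\pi\rho}{3\,MW}\right)^{1/3} + b.$$
The slope of $D$ vs $MW^{-1/3}$ recovers the viscosity $\eta$; the constant
offset $b$ absorbs the constant-density idealization (lighter complexes are
denser, so negative offsets are expected on real cargo). `predict_diffusion`
and `stokes_einstein_fit` are exact mutual inverses on noiseless data — a
tested invariant. No TIP3P-style viscosity rescaling is applied to reported
diffusivities; users who want the ×2.4 correction can apply it to the
output column.

## Contact networks and nearest neighbors

Contacts use a differentiable coordination number,
$C = \sum_{ij} 1/(1 + e^{5(d_{ij} - 4\text{ Å})})$, over heavy-atom cross
pairs; pairs beyond 12 Å contribute < 4e-18 and are skipped via a cell-list
grid whose equivalence to brute force is property-tested. Complex-level
graphs connect two complexes when any alpha-carbon pair is within 10 Å;
edges carry both the contact-frame fraction and the mean minimum distance,
because "weighted by closeness" is consumer-dependent. Nearest-neighbor
distances are minima over any atom pair between distinct complexes; since
"the average of the first 10 neighbors" is ambiguous, both per-rank means
and the grand mean are reported. Graphs export to GEXF 1.2 and GraphML
(layout is a visualization concern and out of scope).

## Shell stability diagnostics

`interior_volume` reimplements interior-volume measurement as a voxel flood
fill: voxels within 2.4 Å of a shell atom are occupied, a 6-connected fill
from all eight box corners marks the exterior (eight corners so a shell
touching one face cannot confuse the seed), and the remaining voxels are
interior. A fill that reaches the geometric center means a leaky shell and
warns rather than errors, since partially open shells are a real
intermediate state. Water counting offers both the spherical criterion
(radius below $R_{mid}$) and the grid criterion, judged on the oxygen site;
the two agree within 1% on an ideal closed shell at 1 Å spacing, which is a
tested invariant. `replicate_interior_waters` duplicates a sampled fraction
of interior waters at 0.5 Å random displacement with a 0.8 Å clash guard
(10 re-draws then error), preserving all original particles verbatim. The
osmotic "guess and check" loop itself deliberately stays human-in-the-loop:
the package provides the diagnostics, not an auto-balancer, because
structural deformation judgments on large shells still need eyes.

## The synthetic data generators

The generators are first-class, tested code, and their defaults are the
package's study conditions — they are not tuning knobs.

**Shell permeation** (`gen_shell_bd`): non-interacting point solutes under
Euler–Maruyama overdamped Langevin dynamics,
$$dx = \left[-\beta D(x)\nabla G(x) + \nabla D(x)\right]dt +
  \sqrt{2D(x)\,dt}\;\eta,$$
where the $\nabla D$ term is the Ito correction that keeps the stationary
density $\propto e^{-\beta G}$ under position-dependent diffusivity. The
potential is a radial Gaussian barrier centered on the shell mid-surface,
gated smoothly to zero inside the pore cones by a cosine switch over a 2 Å
arc (differentiable forces, including the tangential gate gradient); the
diffusivity dips from `D_free` to `D_shell` across the same radial band.
Boundaries reflect at the box edge rather than wrapping, so inside/outside
bookkeeping is unambiguous and coordinates are intrinsically unwrapped.
Initial positions are rejection-sampled from the stationary density; a
uniform draw would overfill the small interior reservoir from the barrier
band and only relax on the slow leakage timescale, biasing early crossing
statistics. The stability guard rejects time steps whose rms displacement
exceeds half the pore radius (skipped for pore-free walls, where there is
nothing to resolve).

Defaults, chosen once as a desk-scale analogue of a packed-shell system:
shell radius 40 Å, four tetrahedral pores of radius 12 Å, barrier
3 kcal/mol × width 5 Å, D_free 100 Å²/ns, D_shell 10 Å²/ns, 500 solutes in
a 120 Å box, 1e5 steps of 5 ps, seed 7, 298 K. The pore size and barrier
suppress off-pore leakage to a small fraction of the pore flux while
accumulating several hundred crossings in 500 ns, enough for the counting
estimator's Poisson error to sit well under the 25% cross-validation band
against `analytic_pore_permeability` — the independent oracle that applies
the ISDM integral to the generating profile along a pore axis and scales by
the pore-area fraction. On the pore axis the gated barrier is exactly zero,
so the oracle's default mode depends only on the diffusivity dip; the
ungated mode (`gate_axis = FALSE`) integrates the full radial barrier and
decreases monotonically with barrier height, bounded below by
$e^{-\beta\Delta G}$ per added height.

What this generator deliberately does not emulate: explicit solvent,
electrostatics, protein flexibility, solute-solute interactions (hence no
pore queuing or saturation at high concentration), and anything about
specific pore chemistry. Passing tests therefore demonstrate correctness of
the estimators on diffusive barrier-crossing data, not fidelity of any
particular molecular system.

**Umbrella windows** (`gen_umbrella_windows`): 1D overdamped Langevin on
$U(\xi) = G(\xi) + \tfrac{k}{2}(\xi-\xi_0)^2$ with the same drift
correction, all windows advanced in lockstep from one seeded stream,
sampled every 0.2 ps after discarding the stated equilibration (0.05 ns for
synthetic windows, which equilibrate in picoseconds; the 20 ns discard
convention belongs to raw replica-exchange data). The flat-landscape window
is an exact Ornstein–Uhlenbeck process, giving closed-form targets:
variance $k_BT/k$ (0.1185 Å² at k = 5, 298 K) and relaxation time
$\tau = \mathrm{var}/D$. The double-well reconstruction target is
$G(\xi) = 2(1-(\xi/3)^2)^2$ kcal/mol over 24 windows spanning ±5 Å with
8000 samples each, sized so WHAM's statistical error sits comfortably under
the 0.2 kcal/mol RMS acceptance band.

**Clustering cargo** (`gen_cargo_frames`): rigid clusters of pseudo-Cα
sites whose centers experience a soft repulsive core at contact, a
constant-magnitude attraction out to six complex radii, harmonic
confinement, and thermal noise; initial centers are drawn uniform in the
confinement sphere, which is the stationary distribution of the no-drive
system (so zero attraction is statistically flat, a tested null). Defaults:
25 complexes of radius 5 Å, five sites each, attraction 3 kcal/mol in a
60 Å sphere, 150 frames × 0.1 ns.

## Numerical choices and degenerate inputs

* WHAM convergence 1e-7 on window free energies; bootstrap solves at 1e-6.
* Quadrature at 1e-8 relative tolerance; diffusivity splines floored at
  1e-9 Å²/ns inside the integrand to keep the integral finite if a spline
  undershoots between points.
* Profile splines fall back to natural-spline interpolation if the GCV
  smoother rejects the data (e.g. near-constant input); evaluations are
  clamped to the fitted range.
* Readers reject NaN coordinates, non-increasing frame times, and
  frame/particle count mismatches with messages naming the expected and
  actual values; the PDB pre-scan reports the offending line number.
* Empty histogram bins become `NA` ("unreachable"), never zero free energy;
  empty radial-diffusion bins are `NA`, never zero diffusivity.
* Seeded generators snapshot and restore the caller's RNG state, so
  `gen_*` calls are bit-reproducible without clobbering the session stream.

## Problem sizes

The test suite and analysis drivers run at deliberately desk-scale sizes:
500 solutes × 1e5 steps for the counting cross-check (~800 crossing
events), 24 × 8000-sample windows for WHAM, 5e4-sample OU windows for the
diffusivity estimator, 1000 particles × 1e4 steps for MSD recovery, and a
10000-atom closed shell on a ~110³ voxel grid for the flood fill. These
sizes keep the full suite under a couple of minutes while leaving each
acceptance band limited by the estimator, not the sample count.

## Known limitations

* The counting and ISDM routes are only directly comparable when crossings
  are pore-dominated; the synthetic conditions are designed so off-pore
  leakage is a small correction, but real shells with leaky seams violate
  this.
* Event times are frame-resolution; if the frame interval approaches the
  diffusion time across the hysteresis band, excursions between frames are
  missed and counts bias low. The defaults keep the band crossing time two
  orders of magnitude above the frame interval.
* The block bootstrap for single-trajectory radial-diffusion errors
  understates long-range temporal correlation; replica trajectories are
  preferred when available.
* `fit_shell_geometry` assumes an approximately spherical shell.
* DCD input relies on the caller's `unwrapped` declaration; the format
  itself records nothing about imaging.
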