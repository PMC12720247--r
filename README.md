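# bmcperm

Analysis toolkit for quantifying small-molecule permeability, diffusion,
crowding, and shell stability in particle simulations of bacterial
microcompartments (BMCs) — polyhedral protein shells built from hexamer,
trimer and pentamer tiles, each pierced by a central pore, that encapsulate
enzymes together with their metabolites. The package is aimed at
simulators who have trajectories (or umbrella-sampling window series) of
shell systems and want permeability coefficients, diffusion profiles,
contact networks and osmotic-balance diagnostics out of them, with every
estimator testable against synthetic data of known ground truth.

## What it computes

Two independent routes to the permeability coefficient *P* (cm/s), defined
by the flux relation *J = P·A·ΔC*:

1. **Transition counting.** Committed shell crossings are detected on each
   solute's radial trace with a two-threshold hysteresis automaton
   (R_in = R_mid − δ, R_out = R_mid + δ), and

   *P = x / (2·c·A·t)*,

   with *x* crossings in both directions, *c* the solute concentration in
   water (molecules/Å³), *A* the shell surface area (Å²) and *t* the
   aggregate time (ns); the factor 2 credits equilibrium bidirectionality
   and the Poisson error √x is propagated.

2. **Inhomogeneous solubility-diffusion model (ISDM).** From umbrella
   windows, WHAM reconstructs the free-energy profile G(ξ) and
   variance/autocorrelation analysis gives the local diffusivity D(ξ); then

   *P = [ ∫ exp(β·G(ξ)) / D(ξ) dξ ]⁻¹*

   by adaptive quadrature on spline fits. Cylinder-confined per-pore
   estimates are converted to an effective tile permeability
   *P_eff = (n_H·P_H + P_T)·π·r²/A*.

Around these sit lag-time MSD diffusion (*D(Δt) = MSD(Δt)/6Δt*) with
inside/outside partitioning and radial profiles, the
Stokes–Einstein–Sutherland viscosity fit *D = a·MW^(−1/3) + b*,
differentiable coordination-number contact scores
(Σ 1/(1+exp(5(d_ij − 4 Å)))), complex-level contact graphs with GEXF/GraphML
export, nearest-neighbor clustering statistics, voxel flood-fill interior
volumes, interior-water counting/ingress rates, and the interior-water
replication utility used to balance osmotic pressure before production runs.

A first-class synthetic-data module (`gen_shell_bd`, `gen_umbrella_windows`,
`gen_cargo_frames`) generates overdamped-Langevin data on stated profiles so
each pipeline can be scored against analytic ground truth.

## Worked example

Simulate solutes crossing a porous shell and recover the permeability both
by counting and from the generating profile:

```r
library(bmcperm)

p   <- shell_bd_params()          # 40 A shell, four 12 A pores, seed 7
run <- gen_shell_bd(p)            # 500 solutes, 500 ns Brownian dynamics
sh  <- run$shell

rs  <- radial_series(run$traj, sh)
ev  <- detect_transitions(rs, sh$R_in, sh$R_out, species = "G3P")
directional_tally(ev)
#>  n_inbound n_outbound
#>        420        412

c_aq <- p$n_solutes / accessible_volume(p)   # molecules per aqueous A^3
permeability_from_counts(ev, c = c_aq, A = sh$A, t = max(run$traj$times))
#> PermeabilityEstimate (counting): P = 1.113 +/- 0.039 cm/s [832 transitions]

analytic_pore_permeability(p)     # ISDM integral on the generating profile
#> [1] 1.119722
```

The balanced in/out tallies are the detailed-balance check, and the
counting estimate lands within a few percent of the ISDM value for the same
profile. The per-tile arithmetic for published per-pore estimates:

```r
effective_permeability(pore_set(P_H = 23.9, P_T = 13.5))
#> PermeabilityEstimate (isdm_effective): P = 3.725 +/- 0 cm/s
```

The numbered drivers under `analysis/` run the full workflow: `01_simulate`
(generate all synthetic datasets), `02_count_permeability`, `03_reus_isdm`
(WHAM → diffusivity → ISDM → tile correction), `04_diffusion`,
`05_network`, `06_stability`. Each writes its tables under `results/`.

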