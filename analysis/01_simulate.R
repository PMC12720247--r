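#!/usr/bin/env Rscript
# Generate the three synthetic datasets the downstream analyses run on:
#   - shell permeation: 500 solutes crossing a 40 A shell with four 12 A
#     pores through a 3 kcal/mol barrier (500 ns of Brownian dynamics),
#   - 24 umbrella windows biased onto a double-well free-energy profile,
#   - 25 pseudo-protein cargo complexes clustering inside a confining sphere.
# Every dataset has analytically known ground truth, so each later script can
# score its estimator against the generating profile. Trajectories are
# regenerated from seeds by the scripts that need them; this driver writes
# the portable text forms (umbrella windows, cargo trajectory) plus a summary.

library(bmcperm)

dir.create("results/windows", recursive = TRUE, showWarnings = FALSE)

## 1. shell-permeation Brownian dynamics ------------------------------------
p <- shell_bd_params()   # canonical study conditions, seed 7
cat(sprintf("shell BD: %d solutes, %g ns, shell R=%g A, %d pores of %g A\n",
            p$n_solutes, p$n_steps * p$dt, p$shell_radius,
            nrow(p$pore_axes), p$pore_radius))
run <- gen_shell_bd(p)
cat(sprintf("  -> %d frames saved; analytic pore permeability %.3f cm/s\n",
            length(run$traj$times), analytic_pore_permeability(p)))

## 2. umbrella windows on a double-well landscape ---------------------------
dw <- function(x) 2 * (1 - (x / 3)^2)^2       # 2 kcal/mol central barrier
sp <- umbrella_spec(dw, function(x) rep(70, length(x)),
                    window_centers = seq(-5, 5, length.out = 24),
                    k_bias = 5, n_samples = 8000, seed = 9)
ws <- gen_umbrella_windows(sp)
for (i in seq_along(ws)) {
  w <- ws[[i]]
  f <- sprintf("results/windows/window_%02d.csv", i)
  con <- file(f, "wt")
  writeLines(sprintf("# center %.6f k %.3f interval_ps %.3f",
                     w$center, w$k, w$interval), con)
  writeLines("time_ps,xi_A", con)
  writeLines(sprintf("%.3f,%.8f", seq_along(w$samples) * w$interval,
                     w$samples), con)
  close(con)
}
cat(sprintf("umbrella: %d windows x %d samples written to results/windows/\n",
            length(ws), sp$n_samples))

## 3. clustering cargo -------------------------------------------------------
spc <- cargo_spec(n_complexes = 25, attraction_strength = 3,
                  n_frames = 150, seed = 22)
cargo <- gen_cargo_frames(spc)
write_trajectory(cargo, "results/cargo_trajectory.csv")
cat(sprintf("cargo: %d complexes x %d sites over %d frames -> results/cargo_trajectory.csv\n",
            spc$n_complexes, spc$sites_per_complex, spc$n_frames))
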