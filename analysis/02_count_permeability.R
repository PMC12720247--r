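#!/usr/bin/env Rscript
# Transition-counting permeability. Track every solute's radius relative to
# the shell, detect committed crossings with the +/-10 A hysteresis band, and
# convert counts to a permeability via P = x/(2 c A t). The counting estimate
# is scored against the analytic pore-path permeability of the generating
# profile, and the printed-input worked example is re-derived for reference.

library(bmcperm)
dir.create("results", showWarnings = FALSE)

p <- shell_bd_params()
run <- gen_shell_bd(p)
sh <- run$shell
rs <- radial_series(run$traj, sh)
ev <- detect_transitions(rs, sh$R_in, sh$R_out, species = "G3P")
tal <- directional_tally(ev)
cat(sprintf("%d crossing events over %g ns (%d inbound / %d outbound)\n",
            nrow(ev), max(run$traj$times), tal[1], tal[2]))

# concentration: solutes per Boltzmann-accessible (aqueous-equivalent) volume
c_aq <- p$n_solutes / accessible_volume(p)
est <- permeability_from_counts(ev, c = c_aq, A = sh$A,
                                t = max(run$traj$times))
P_ref <- analytic_pore_permeability(p)
cat(sprintf("counting: P = %.3f +/- %.3f cm/s; ISDM oracle %.3f cm/s (ratio %.2f)\n",
            est$P, est$stderr, P_ref, est$P / P_ref))

utils::write.csv(ev, "results/crossing_events.csv", row.names = FALSE)
utils::write.csv(data.frame(
  method = c("counting", "analytic_oracle"),
  P_cm_s = c(est$P, P_ref),
  stderr = c(est$stderr, 0),
  n_transitions = c(est$n_transitions, NA)
), "results/permeability_counting.csv", row.names = FALSE)

# worked example with published-scale inputs: 15 events at 250 mM across a
# 180 A shell over 750 ns
ex <- permeability_from_counts(15, c = 0.250, A = 4 * pi * 180^2, t = 750,
                               c_molar = TRUE)
cat(sprintf("printed-input example: 15 events, 250 mM, 4*pi*180^2 A^2, 750 ns -> %.2e cm/s\n",
            ex$P))

# steady-state gradient a 19 nm shell would sustain at 1 molecule/s
fb <- steady_state_gradient(P = 0.0055, A = 4 * pi * 190^2, J = 1)
cat(sprintf("flux balance: 1 molecule/s at P=0.0055 cm/s -> dC = %.2g nM\n",
            fb$dC_molar * 1e9))
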