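# Shared fixtures, built in code and memoised so heavy Brownian-dynamics
# runs are generated once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# evenly spaced points on a sphere (Fibonacci lattice): a closed shell for
# voxel flood-fill tests
fib_sphere <- function(n, R) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(R * sin(phi) * cos(theta), R * sin(phi) * sin(theta), R * cos(phi))
}

closed_shell_particles <- function(n = 10000, cavity_radius = 50,
                                   atom_radius = 2.4) {
  u <- fib_sphere(n, cavity_radius + atom_radius)
  particle_set(seq_len(n), "pseudo", "shell", u[, 1], u[, 2], u[, 3])
}

# canonical shell-permeation study conditions (the generator defaults)
canonical_shell_run <- function() {
  fixture("canonical_shell_run", function() {
    p <- shell_bd_params()
    run <- gen_shell_bd(p)
    sh <- run$shell
    rs <- radial_series(run$traj, sh)
    ev <- detect_transitions(rs, sh$R_in, sh$R_out, species = "G3P")
    list(params = p, run = run, shell = sh, series = rs, events = ev)
  })
}

# free-diffusion run: 1000 particles, 1e4 steps, large box so reflections
# are negligible at the lags tested
free_diffusion_run <- function() {
  fixture("free_diffusion_run", function() {
    p <- shell_bd_params(barrier_height = 0, D_shell = 100, n_solutes = 1000,
                         n_steps = 1e4, box_edge = 400, seed = 17)
    gen_shell_bd(p, save_every = 4)
  })
}

# double-well umbrella windows: 2 kcal/mol barrier, 24 windows
double_well_G <- function(x) 2 * (1 - (x / 3)^2)^2

double_well_windows <- function() {
  fixture("double_well_windows", function() {
    sp <- umbrella_spec(double_well_G, function(x) rep(70, length(x)),
                        window_centers = seq(-5, 5, length.out = 24),
                        k_bias = 5, n_samples = 8000, seed = 9)
    gen_umbrella_windows(sp)
  })
}

# single harmonic window on a flat landscape: an Ornstein-Uhlenbeck process
# with known variance kBT/k and relaxation time var/D
ou_window <- function() {
  fixture("ou_window", function() {
    sp <- umbrella_spec(function(x) 0 * x, function(x) rep(70, length(x)),
                        window_centers = 0, k_bias = 5, n_samples = 5e4,
                        seed = 4)
    gen_umbrella_windows(sp)[[1]]
  })
}

# minimal CHARMM-format DCD writer (enough for bio3d::read.dcd)
write_minimal_dcd <- function(path, coords) {
  nf <- dim(coords)[1]; nat <- dim(coords)[2]
  con <- file(path, open = "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf
    icntrl[2] <- 1L
    icntrl[3] <- 1L
    icntrl[4] <- nf
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- formatC("generated fixture", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nat), con, size = 4), 4)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(coords[f, , d]), con, size = 4),
          4 * nat)
    }
  }
  invisible(path)
}
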