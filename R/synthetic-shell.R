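# Synthetic shell-permeation generator: overdamped Langevin (Euler-Maruyama)
# point solutes diffusing across a spherical shell pierced by circular pores.
# The radial potential is a Gaussian barrier centered on the shell mid-surface,
# smoothly gated to zero inside the pore cones by a cosine switch, and the
# diffusivity dips from D_free to D_shell across the same radial band. Because
# the generating G(xi) and D(xi) are known analytically, every downstream
# estimator can be checked against closed-form or quadrature ground truth.

#' Parameters for the shell-permeation Brownian-dynamics generator
#'
#' Defaults are the package's canonical desk-scale study conditions: a 40 A
#' shell pierced by four tetrahedral pores of radius 12 A, a 3 kcal/mol
#' radial Gaussian barrier of width 5 A outside the pore cones, free
#' diffusivity 100 A^2/ns dipping to 10 A^2/ns across the shell band,
#' 500 solutes in a 120 A box, 1e5 steps of 0.005 ns.
#'
#' @param shell_radius Shell mid-surface radius (A).
#' @param pore_axes Matrix (k x 3) of pore axis unit vectors; default the four
#'   tetrahedral directions.
#' @param pore_radius Pore radius (A); must be < `shell_radius`. 0 disables
#'   pores (impermeable wall when the barrier is high).
#' @param barrier_height Barrier height (kcal/mol), >= 0.
#' @param barrier_width Gaussian sigma of the radial barrier and of the
#'   diffusivity dip (A).
#' @param D_free,D_shell Diffusivity outside/inside the barrier band (A^2/ns).
#' @param n_solutes Number of point solutes.
#' @param box_edge Cubic box edge (A); solutes reflect at the box boundary.
#' @param dt Time step (ns).
#' @param n_steps Number of integration steps.
#' @param seed Integer RNG seed (bit-reproducible runs).
#' @param T_K Temperature (K) used for beta in the drift term.
#' @param switch_width Arc length (A) of the cosine switch gating the barrier
#'   to zero inside pore cones (default 2 A).
#' @return A validated list of class `ShellBDParams`.
#' @export
shell_bd_params <- function(shell_radius = 40, pore_axes = tetrahedral_axes(),
                            pore_radius = 12, barrier_height = 3,
                            barrier_width = 5, D_free = 100, D_shell = 10,
                            n_solutes = 500, box_edge = 120, dt = 0.005,
                            n_steps = 1e5, seed = 7, T_K = 298,
                            switch_width = 2) {
  if (is.null(pore_axes) || length(pore_axes) == 0) {
    pore_axes <- matrix(numeric(0), 0, 3)
  }
  pore_axes <- as.matrix(pore_axes)
  if (nrow(pore_axes) > 0) {
    pore_axes <- pore_axes / sqrt(rowSums(pore_axes^2))
  }
  p <- list(shell_radius = shell_radius, pore_axes = pore_axes,
            pore_radius = pore_radius, barrier_height = barrier_height,
            barrier_width = barrier_width, D_free = D_free, D_shell = D_shell,
            n_solutes = as.integer(n_solutes), box_edge = box_edge,
            dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed),
            T_K = T_K, switch_width = switch_width)
  class(p) <- "ShellBDParams"
  validate_shell_bd_params(p)
  p
}

validate_shell_bd_params <- function(p) {
  stopifnot(p$shell_radius > 0, p$D_free > 0, p$D_shell > 0, p$dt > 0,
            p$barrier_height >= 0, p$barrier_width > 0, p$n_solutes >= 1,
            p$n_steps >= 1, p$box_edge > 2 * p$shell_radius)
  if (p$pore_radius >= p$shell_radius) stop("pore_radius must be < shell_radius")
  if (p$pore_radius < 0) stop("pore_radius must be >= 0")
  # dt stability: the rms step must resolve the pore (only meaningful if
  # there is a pore to resolve)
  if (p$pore_radius > 0) {
    step <- sqrt(6 * max(p$D_free, p$D_shell) * p$dt)
    if (step > p$pore_radius / 2) {
      stop(sprintf(paste0("dt too large: rms displacement per step (%.2f A) ",
                          "exceeds pore_radius/2 (%.2f A); integration would be unstable"),
                   step, p$pore_radius / 2))
    }
  }
  invisible(p)
}

#' Four tetrahedral unit vectors
#' @return A 4 x 3 matrix of unit vectors.
#' @export
tetrahedral_axes <- function() {
  m <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m / sqrt(3)
}

# radial Gaussian profile and its derivative
shell_gaussian <- function(r, R, sigma) exp(-(r - R)^2 / (2 * sigma^2))

# generating diffusivity profile D(r) along the radial coordinate
shell_D_profile <- function(r, p) {
  p$D_free + (p$D_shell - p$D_free) * shell_gaussian(r, p$shell_radius, p$barrier_width)
}

# full generating potential G(x) = h * g(r) * s(theta_min) at arbitrary points
potential_at <- function(X, p) {
  if (p$barrier_height == 0) return(numeric(nrow(X)))
  r <- pmax(sqrt(rowSums(X^2)), 1e-8)
  g <- shell_gaussian(r, p$shell_radius, p$barrier_width)
  s <- rep(1, nrow(X))
  if (nrow(p$pore_axes) > 0 && p$pore_radius > 0) {
    cosang <- (X / r) %*% t(p$pore_axes)
    cmax <- do.call(pmax, lapply(seq_len(ncol(cosang)), function(j) cosang[, j]))
    s <- pore_gate(acos(pmin(1, pmax(-1, cmax))), p)$s
  }
  p$barrier_height * g * s
}

# pore-cone cosine gate: 0 deep inside a pore cone, 1 outside, smooth ramp
# over an arc length `switch_width` at the cone edge. Returns s and ds/dtheta.
pore_gate <- function(theta, p) {
  theta_p <- asin(min(1, p$pore_radius / p$shell_radius))
  theta_sw <- min(p$switch_width / p$shell_radius, theta_p)
  theta0 <- theta_p - theta_sw
  s <- ifelse(theta >= theta_p, 1,
              ifelse(theta <= theta0, 0,
                     0.5 * (1 - cos(pi * (theta - theta0) / theta_sw))))
  dsdtheta <- ifelse(theta > theta0 & theta < theta_p,
                     0.5 * pi / theta_sw * sin(pi * (theta - theta0) / theta_sw),
                     0)
  list(s = s, dsdtheta = dsdtheta)
}

#' Simulate solutes permeating a porous spherical shell
#'
#' Evolves `n_solutes` non-interacting point particles by Euler-Maruyama
#' overdamped Langevin dynamics on the radial Gaussian barrier (gated open
#' inside the pore cones) with position-dependent diffusivity. The drift is
#' `-beta*D(x)*grad G(x) + grad D(x)`; the gradient-of-D term is the Ito
#' correction that keeps the stationary density proportional to
#' `exp(-beta*G)`. Particles reflect at the box boundary (reflecting, not
#' periodic, so inside/outside bookkeeping stays unambiguous) and coordinates
#' are therefore intrinsically unwrapped.
#'
#' @param params A `ShellBDParams` object.
#' @param save_every Store every `save_every`-th step (default sized so about
#'   2500 frames are kept). Frame 0 is always stored.
#' @return A list with elements `traj` (a `Trajectory`; solutes carry an
#'   `init_inside` flag column) and `shell` (the `ShellGeometry`, surface area
#'   `4*pi*shell_radius^2`).
#' @examples
#' p <- shell_bd_params(n_solutes = 50, n_steps = 2000, seed = 1)
#' run <- gen_shell_bd(p)
#' run$traj
#' @export
gen_shell_bd <- function(params, save_every = NULL) {
  validate_shell_bd_params(params)
  p <- params
  if (is.null(save_every)) save_every <- max(1L, floor(p$n_steps / 2500))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(p$seed)

  N <- p$n_solutes
  L2 <- p$box_edge / 2
  # equilibrium initial condition: rejection-sample against exp(-beta*G) so
  # the run starts in the stationary state (a uniform draw would overfill the
  # small interior reservoir from the barrier band and relax only on the slow
  # leakage timescale)
  beta0 <- 1 / (bmc_constants$kB * p$T_K)
  X <- matrix(NA_real_, N, 3)
  filled <- 0L
  while (filled < N) {
    prop <- matrix(stats::runif(3 * (N - filled), -L2, L2), ncol = 3)
    w <- exp(-beta0 * potential_at(prop, p))
    keep <- stats::runif(nrow(prop)) < w
    nk <- sum(keep)
    if (nk) {
      X[(filled + 1):(filled + nk), ] <- prop[keep, , drop = FALSE]
      filled <- filled + nk
    }
  }
  r0 <- sqrt(rowSums(X^2))
  init_inside <- r0 < p$shell_radius

  beta <- 1 / (bmc_constants$kB * p$T_K)
  h <- p$barrier_height
  R <- p$shell_radius
  sig <- p$barrier_width
  dD <- p$D_shell - p$D_free
  have_pores <- nrow(p$pore_axes) > 0 && p$pore_radius > 0
  axes_t <- if (have_pores) t(p$pore_axes) else NULL  # 3 x k

  nsave <- floor(p$n_steps / save_every) + 1L
  coords <- array(NA_real_, c(nsave, N, 3))
  times <- numeric(nsave)
  coords[1, , ] <- X
  isave <- 1L
  sqrt2dt <- sqrt(2 * p$dt)

  for (step in seq_len(p$n_steps)) {
    r <- sqrt(rowSums(X^2))
    r <- pmax(r, 1e-8)
    g <- exp(-(r - R)^2 / (2 * sig^2))
    dgdr <- -(r - R) / sig^2 * g
    D <- p$D_free + dD * g
    dDdr <- dD * dgdr
    U <- X / r

    if (h > 0 || dD != 0) {
      if (have_pores && h > 0) {
        cosang <- U %*% axes_t                      # N x k
        k <- ncol(cosang)
        cmax <- do.call(pmax, lapply(seq_len(k), function(j) cosang[, j]))
        theta <- acos(pmin(1, pmax(-1, cmax)))
        gt <- pore_gate(theta, p)
        # radial force component
        Fr <- -h * dgdr * gt$s
        # tangential component where the cosine ramp is active
        act <- which(gt$dsdtheta != 0 & g > 1e-12)
        drift <- (beta * D * Fr + dDdr) * U
        if (length(act)) {
          idx <- max.col(cosang[act, , drop = FALSE], ties.method = "first")
          pn <- p$pore_axes[idx, , drop = FALSE]   # nearest axis per particle
          sinth <- sqrt(pmax(1 - cmax[act]^2, 1e-12))
          # grad theta = -(axis - cos*u) / (r*sin(theta))
          gradth <- -(pn - cmax[act] * U[act, , drop = FALSE]) /
            (r[act] * sinth)
          Ft <- -h * g[act] * gt$dsdtheta[act]
          drift[act, ] <- drift[act, ] + (beta * D[act] * Ft) * gradth
        }
      } else if (h > 0) {
        drift <- (-beta * D * h * dgdr + dDdr) * U
      } else {
        drift <- dDdr * U
      }
      X <- X + drift * p$dt
    }
    X <- X + (sqrt(D) * sqrt2dt) * matrix(stats::rnorm(3 * N), N, 3)
    # reflecting walls
    over <- X > L2
    X[over] <- 2 * L2 - X[over]
    under <- X < -L2
    X[under] <- -2 * L2 - X[under]

    if (step %% save_every == 0L) {
      isave <- isave + 1L
      coords[isave, , ] <- X
      times[isave] <- step * p$dt
    }
  }

  ps <- particle_set(seq_len(N), species = "G3P", role = "metabolite",
                     x = coords[1, , 1], y = coords[1, , 2], z = coords[1, , 3])
  ps$init_inside <- init_inside
  # trajectory() requires strictly increasing times; frame 0 is at t=0
  traj <- trajectory(times, coords, ps,
                     box = rep(p$box_edge, 3), unwrapped = TRUE)
  pores <- if (have_pores) {
    lapply(seq_len(nrow(p$pore_axes)),
           function(i) list(axis = p$pore_axes[i, ], radius = p$pore_radius))
  } else list()
  shell <- shell_geometry(c(0, 0, 0), R, delta = min(10, R / 2), pores = pores)
  list(traj = traj, shell = shell, params = p)
}

#' Analytic permeability of the generating pore profile
#'
#' Independent oracle for the counting estimator: applies the inhomogeneous
#' solubility-diffusion integral to the generating profile along a pore axis
#' (where the barrier is gated to exactly zero), then scales by the fraction
#' of the shell surface occupied by pores,
#' `n_pores * pi * pore_radius^2 / (4*pi*shell_radius^2)`.
#'
#' With `gate_axis = FALSE` the ungated radial profile (barrier included) is
#' integrated instead, which makes the result decrease monotonically with
#' barrier height; this mode quantifies the leakage path over the barrier.
#'
#' @param params A `ShellBDParams`.
#' @param bounds Integration bounds along the axis (A); default
#'   `shell_radius + c(-3, 3) * barrier_width`.
#' @param pore_fraction Override for the pore-area fraction (e.g. 1 for a
#'   fully open surface); default computed from the params.
#' @param gate_axis Logical; `TRUE` (default) evaluates the gated on-axis
#'   potential (identically zero), `FALSE` the ungated radial barrier.
#' @param rel_tol Quadrature relative tolerance (default 1e-8).
#' @return Permeability in cm/s.
#' @export
analytic_pore_permeability <- function(params, bounds = NULL,
                                       pore_fraction = NULL, gate_axis = TRUE,
                                       rel_tol = 1e-8) {
  validate_shell_bd_params(params)
  p <- params
  if (is.null(bounds)) {
    bounds <- p$shell_radius + c(-3, 3) * p$barrier_width
  }
  if (is.null(pore_fraction)) {
    n_pores <- nrow(p$pore_axes)
    pore_fraction <- n_pores * pi * p$pore_radius^2 / (4 * pi * p$shell_radius^2)
  }
  if (pore_fraction <= 0) return(0)
  beta <- 1 / (bmc_constants$kB * p$T_K)
  integrand <- function(xi) {
    G <- if (gate_axis) 0 else p$barrier_height * shell_gaussian(xi, p$shell_radius, p$barrier_width)
    exp(beta * G) / shell_D_profile(xi, p)
  }
  I <- stats::integrate(integrand, bounds[1], bounds[2],
                        rel.tol = rel_tol, abs.tol = 0)$value
  (1 / I) * pore_fraction * bmc_constants$A_per_ns_to_cm_s
}

#' Boltzmann-accessible (aqueous-equivalent) volume of the shell BD box
#'
#' `V_eff = integral of exp(-beta*G(x)) over the box`: the volume the solutes
#' actually occupy at equilibrium. The barrier band excludes solutes the way
#' shell protein excludes water in the emulated system, so this is the
#' correct denominator for the "concentration in water" entering the counting
#' estimator. Evaluated by radialxangular quadrature of the generating
#' potential (deterministic; no sampling).
#'
#' @param params A `ShellBDParams`.
#' @param n_r,n_theta Quadrature points in radius and polar angle.
#' @return Volume in A^3.
#' @export
accessible_volume <- function(params, n_r = 2000, n_theta = 400) {
  p <- params
  V_box <- p$box_edge^3
  if (p$barrier_height == 0) return(V_box)
  beta <- 1 / (bmc_constants$kB * p$T_K)
  r_lo <- max(0, p$shell_radius - 6 * p$barrier_width)
  r_hi <- min(p$box_edge / 2, p$shell_radius + 6 * p$barrier_width)
  r <- seq(r_lo, r_hi, length.out = n_r)
  Gr <- p$barrier_height * shell_gaussian(r, p$shell_radius, p$barrier_width)
  Ebg <- exp(-beta * Gr)
  n_pores <- nrow(p$pore_axes)
  if (n_pores > 0 && p$pore_radius > 0) {
    theta_p <- asin(min(1, p$pore_radius / p$shell_radius))
    th <- seq(0, theta_p, length.out = n_theta)
    s <- pore_gate(th, p)$s
    # angular mean of exp(-beta*G*s) over the full sphere, pores non-overlapping
    cap <- vapply(seq_along(r), function(i) {
      integ <- (exp(-beta * Gr[i] * s) - Ebg[i]) * sin(th)
      sum((integ[-1] + integ[-n_theta]) / 2 * diff(th)) / 2
    }, numeric(1))
    avg <- Ebg + n_pores * cap
  } else {
    avg <- Ebg
  }
  deficit_int <- 4 * pi * r^2 * (1 - avg)
  deficit <- sum((deficit_int[-1] + deficit_int[-n_r]) / 2 * diff(r))
  V_box - deficit
}

# RNG bookkeeping: generators seed the RNG for bit-reproducibility but must
# not clobber the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
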