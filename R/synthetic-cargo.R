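# Clustering-cargo generator: rigid pseudo-protein complexes (small clusters
# of labeled pseudo-C-alpha sites) drifting under pairwise attraction inside a
# confining sphere. Emulates the liquid-liquid-phase-separation-like
# clustering of encapsulated cargo used to exercise the contact-network and
# nearest-neighbor analyses.

#' Specification for the clustering-cargo generator
#'
#' @param n_complexes Number of pseudo-protein complexes (>= 2).
#' @param complex_radii Effective complex radius (A); sets the contact
#'   distance and the site cluster size.
#' @param attraction_strength Pairwise attraction (kcal/mol); 0 disables the
#'   clustering drive.
#' @param confinement_radius Radius of the confining sphere (A).
#' @param dt Frame spacing (ns).
#' @param n_frames Number of frames generated.
#' @param seed Integer RNG seed.
#' @param sites_per_complex Pseudo-C-alpha sites per complex (default 5).
#' @param T_K Temperature (K).
#' @return A validated list of class `CargoSpec`.
#' @export
cargo_spec <- function(n_complexes = 30, complex_radii = 5,
                       attraction_strength = 1, confinement_radius = 60,
                       dt = 0.1, n_frames = 200, seed = 1,
                       sites_per_complex = 5, T_K = 298) {
  if (n_complexes < 2) stop("need at least 2 complexes")
  stopifnot(complex_radii > 0, confinement_radius > 0, dt > 0, n_frames >= 2,
            sites_per_complex >= 1)
  structure(
    list(n_complexes = as.integer(n_complexes), complex_radii = complex_radii,
         attraction_strength = attraction_strength,
         confinement_radius = confinement_radius, dt = dt,
         n_frames = as.integer(n_frames), seed = as.integer(seed),
         sites_per_complex = as.integer(sites_per_complex), T_K = T_K),
    class = "CargoSpec"
  )
}

#' Generate drifting, clustering pseudo-protein cargo frames
#'
#' Complex centers follow overdamped Langevin dynamics with a soft repulsive
#' core at contact, a constant-magnitude pairwise attraction of range
#' 6 x complex radius (zero when `attraction_strength = 0`), and harmonic
#' confinement at the sphere boundary. Each complex carries a rigid cluster
#' of pseudo-C-alpha sites sharing one `complex_id`; when
#' `attraction_strength > 0` later frames are more clustered than earlier
#' frames.
#'
#' @param spec A `CargoSpec`.
#' @return A `Trajectory` whose particles have `role = "cargo"`,
#'   `species = "pseudo"`, `is_calpha = TRUE`.
#' @export
gen_cargo_frames <- function(spec) {
  stopifnot(inherits(spec, "CargoSpec"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(spec$seed)

  n <- spec$n_complexes
  m <- spec$sites_per_complex
  a <- spec$complex_radii
  Rc <- spec$confinement_radius
  beta <- 1 / (bmc_constants$kB * spec$T_K)
  D <- 50 / a                       # Stokes-like mobility, A^2/ns
  d_contact <- 2 * a
  d_range <- 6 * a
  k_rep <- 2                        # kcal/mol/A^2 soft core
  k_conf <- 1                       # kcal/mol/A^2 at the wall
  f_att <- spec$attraction_strength / 10  # kcal/mol/A constant pull

  # initial centers: uniform in the confinement sphere (the stationary
  # distribution when attraction_strength = 0, up to the soft wall tail)
  C <- matrix(stats::rnorm(3 * n), n, 3)
  C <- C / sqrt(rowSums(C^2)) * (Rc * stats::runif(n)^(1 / 3))
  # rigid site offsets, fixed for the whole run
  offs <- lapply(seq_len(n), function(i) {
    o <- matrix(stats::rnorm(3 * m), m, 3)
    o / sqrt(rowSums(o^2)) * a * stats::runif(m)^(1 / 3)
  })

  coords <- array(NA_real_, c(spec$n_frames, n * m, 3))
  dt <- spec$dt
  for (f in seq_len(spec$n_frames)) {
    if (f > 1) {
      Fc <- matrix(0, n, 3)
      for (i in seq_len(n - 1)) {
        dv <- C[(i + 1):n, , drop = FALSE] -
          matrix(C[i, ], n - i, 3, byrow = TRUE)
        d <- sqrt(rowSums(dv^2))
        d <- pmax(d, 1e-6)
        u <- dv / d
        fmag <- numeric(length(d))
        fmag[d < d_contact] <- -k_rep * (d_contact - d[d < d_contact]) # push apart
        att <- d >= d_contact & d < d_range
        fmag[att] <- f_att                                            # pull together
        Fi <- u * fmag          # force on i toward j when fmag > 0
        Fc[i, ] <- Fc[i, ] + colSums(Fi)
        Fc[(i + 1):n, ] <- Fc[(i + 1):n, ] - Fi
      }
      rC <- sqrt(rowSums(C^2))
      outw <- rC > Rc
      if (any(outw)) {
        Fc[outw, ] <- Fc[outw, ] - k_conf * (rC[outw] - Rc) * C[outw, , drop = FALSE] / rC[outw]
      }
      C <- C + beta * D * Fc * dt + sqrt(2 * D * dt) * matrix(stats::rnorm(3 * n), n, 3)
    }
    for (i in seq_len(n)) {
      rows <- ((i - 1) * m + 1):(i * m)
      coords[f, rows, ] <- sweep(offs[[i]], 2, C[i, ], `+`)
    }
  }

  ps <- particle_set(
    particle_id = seq_len(n * m), species = "pseudo", role = "cargo",
    x = coords[1, , 1], y = coords[1, , 2], z = coords[1, , 3],
    complex_id = rep(seq_len(n), each = m), is_calpha = TRUE
  )
  trajectory(seq_len(spec$n_frames) * dt, coords, ps, unwrapped = TRUE)
}
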