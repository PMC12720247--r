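# Inhomogeneous solubility-diffusion model: P = [ integral over the
# permeation coordinate of exp(beta*G(xi)) / D(xi) ]^-1, with G from WHAM,
# D from per-window variance/autocorrelation estimates, both spline-smoothed
# before adaptive quadrature; plus the cylinder-confinement correction that
# converts per-pore permeabilities into an effective shell permeability.

#' Diffusivity of a biased window from variance and autocorrelation
#'
#' For a harmonically restrained coordinate, `D = var(xi) / tau`, where
#' `tau` is the time constant of an exponential fit to the normalized
#' autocorrelation function restricted to lags shorter than `acf_max_lag`
#' (default 2 ps, the effective replica-exchange interval, beyond which
#' swaps decorrelate the series non-diffusively).
#'
#' @param window An `UmbrellaWindow` (>= 1000 production samples).
#' @param thermo A `ThermoConstants` or temperature in K (unused by the
#'   estimator itself; accepted for interface symmetry).
#' @param acf_max_lag Maximum lag (ps) entering the exponential fit.
#' @param equil_discard Override for the window's equilibration discard (ns).
#' @return Diffusivity in A^2/ns.
#' @export
window_diffusivity <- function(window, thermo = 298, acf_max_lag = 2,
                               equil_discard = NULL) {
  s <- window_production(window, equil_discard = equil_discard)
  if (length(s) < 1000) {
    stop(sprintf("window at %.2f A has %d production samples; need >= 1000",
                 window$center, length(s)))
  }
  v <- stats::var(s)
  if (v < 1e-12) stop("window variance is zero (constant series)")
  max_lag <- max(2L, floor(acf_max_lag / window$interval))
  ac <- as.numeric(stats::acf(s, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  lags_ps <- (seq_along(ac) - 1) * window$interval
  pos <- ac > 0.01
  if (sum(pos) < 3 || ac[2] >= 1) {
    stop("autocorrelation does not decay within the fit range; sample longer")
  }
  fit <- stats::lm(log(ac[pos]) ~ lags_ps[pos])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("autocorrelation does not decay within the fit range; sample longer")
  }
  tau_ns <- (-1 / slope) / 1000
  v / tau_ns
}

#' Cubic smoothing spline through profile points
#'
#' Generalized-cross-validation smoothing spline ([stats::smooth.spline()]),
#' inverse-variance weighted when standard errors are supplied; evaluations
#' outside the data range are clamped to the range endpoints rather than
#' extrapolated.
#'
#' @param x Reaction-coordinate points (>= 4 distinct values).
#' @param y Profile values.
#' @param stderr Optional standard errors used as inverse-variance weights
#'   (zeros are treated as the smallest positive error).
#' @return A function of xi; attributes `range` (data range) and `fit`.
#' @export
fit_profile_spline <- function(x, y, stderr = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4) stop("need at least 4 distinct points for a spline fit")
  w <- NULL
  if (!is.null(stderr)) {
    stderr <- stderr[ok]
    if (any(stderr > 0)) {
      s <- pmax(stderr, min(stderr[stderr > 0]))
      w <- 1 / s^2
    }
  }
  fit <- tryCatch(
    stats::smooth.spline(x, y, w = w, cv = FALSE, keep.data = FALSE),
    error = function(e) NULL
  )
  rng <- range(x)
  if (is.null(fit) || stats::sd(stats::predict(fit, x)$y - y) > 10 * max(stats::sd(y), 1e-12)) {
    sf <- stats::splinefun(x, y, method = "natural")
    f <- function(xi) sf(pmin(pmax(xi, rng[1]), rng[2]))
  } else {
    f <- function(xi) stats::predict(fit, pmin(pmax(xi, rng[1]), rng[2]))$y
  }
  attr(f, "range") <- rng
  attr(f, "fit") <- fit
  f
}

#' ISDM permeability from free-energy and diffusivity profiles
#'
#' `P = [ integral from xi_l to xi_u of exp(beta*G(xi)) / D(xi) dxi ]^-1`,
#' evaluated by adaptive quadrature on smoothing-spline fits of the two
#' profiles and converted to cm/s. The conventional integration bounds are
#' +/-30 A for hexamer pores and +/-60 A for trimer pores. Uncertainty is
#' propagated by resampling G within its standard errors (`n_draws`
#' independent normal draws, seeded) and integrating each draw.
#'
#' @param G A `FreeEnergyProfile` covering `[xi_l, xi_u]`.
#' @param D A `DiffusivityProfile` (positive) covering the same range.
#' @param xi_l,xi_u Integration bounds (A).
#' @param thermo A `ThermoConstants` or temperature in K (default 298).
#' @param n_draws Resampling draws for the error estimate (default 200).
#' @param seed Seed for the resampling (default 1).
#' @param rel_tol Quadrature relative tolerance (default 1e-8).
#' @return A `PermeabilityEstimate` with `method = "isdm"`.
#' @export
isdm_permeability <- function(G, D, xi_l, xi_u, thermo = 298, n_draws = 200,
                              seed = 1, rel_tol = 1e-8) {
  stopifnot(inherits(G, "FreeEnergyProfile"), inherits(D, "DiffusivityProfile"))
  th <- as_thermo(thermo)
  if (xi_l >= xi_u) stop("xi_l must be < xi_u")
  for (pr in list(G, D)) {
    if (min(pr$grid) > xi_l + 1e-9 || max(pr$grid) < xi_u - 1e-9) {
      stop(sprintf("profile covers [%.2f, %.2f] but integration needs [%.2f, %.2f]",
                   min(pr$grid), max(pr$grid), xi_l, xi_u))
    }
  }
  if (length(G$grid) >= 4) {
    gfun <- fit_profile_spline(G$grid, G$G, G$stderr)
  } else {
    af <- stats::approxfun(G$grid, G$G, rule = 2)
    gfun <- af
  }
  dfun <- if (length(D$grid) >= 4) fit_profile_spline(D$grid, D$D)
          else stats::approxfun(D$grid, D$D, rule = 2)

  integral <- function(gf) {
    stats::integrate(function(xi) exp(th$beta * gf(xi)) / pmax(dfun(xi), 1e-9),
                     xi_l, xi_u, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L)$value
  }
  P_A_ns <- 1 / integral(gfun)
  err <- 0
  if (n_draws > 0 && any(G$stderr > 0)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed))
    set.seed(seed)
    draws <- vapply(seq_len(n_draws), function(i) {
      Gi <- G$G + stats::rnorm(length(G$G), 0, G$stderr)
      Gi <- Gi - min(Gi)
      gfi <- if (length(G$grid) >= 4) fit_profile_spline(G$grid, Gi, G$stderr)
             else stats::approxfun(G$grid, Gi, rule = 2)
      1 / integral(gfi)
    }, numeric(1))
    err <- stats::sd(draws)
  }
  conv <- bmc_constants$A_per_ns_to_cm_s
  structure(
    list(P = P_A_ns * conv, stderr = err * conv, method = "isdm",
         xi_l = xi_l, xi_u = xi_u),
    class = "PermeabilityEstimate"
  )
}

#' Pore set for the cylinder-confinement correction
#'
#' @param P_H Per-pore hexamer permeability (cm/s).
#' @param P_T Per-pore trimer permeability (cm/s).
#' @param n_H Number of hexamer pores in the tile (default 3).
#' @param r_cyl Confining-cylinder radius (A), default 15.
#' @param A_tile Tile surface area (A^2), default 16166.
#' @return An object of class `PoreSet`.
#' @export
pore_set <- function(P_H, P_T, n_H = 3, r_cyl = 15, A_tile = 16166) {
  stopifnot(P_H >= 0, P_T >= 0, n_H >= 1, r_cyl > 0, A_tile > 0)
  structure(list(P_H = P_H, P_T = P_T, n_H = as.integer(n_H),
                 r_cyl = r_cyl, A_tile = A_tile),
            class = "PoreSet")
}

#' Cylinder-area fraction of a shell tile
#'
#' `pi * r^2 / A`: the fraction of the tile surface one confining cylinder
#' occupies (0.0437 for r = 15 A on a 16166 A^2 tile).
#'
#' @param r_cyl Cylinder radius (A).
#' @param A_tile Tile area (A^2).
#' @return Dimensionless fraction.
#' @export
cylinder_area_fraction <- function(r_cyl = 15, A_tile = 16166) {
  pi * r_cyl^2 / A_tile
}

#' Effective shell permeability from per-pore ISDM estimates
#'
#' The cylinder-confined per-pore permeabilities overestimate transport
#' through the full surface, since molecules outside the pore cylinders are
#' taken as fully blocked; the effective permeability scales the pore sum by
#' the cylinder-area fraction:
#' `P_eff = (n_H * P_H + P_T) * pi * r_cyl^2 / A_tile`.
#'
#' @param pores A `PoreSet`.
#' @return A `PermeabilityEstimate` with `method = "isdm_effective"`.
#' @examples
#' effective_permeability(pore_set(P_H = 23.9, P_T = 13.5))$P  # ~3.7 cm/s
#' @export
effective_permeability <- function(pores) {
  stopifnot(inherits(pores, "PoreSet"))
  frac <- cylinder_area_fraction(pores$r_cyl, pores$A_tile)
  structure(
    list(P = (pores$n_H * pores$P_H + pores$P_T) * frac, stderr = 0,
         method = "isdm_effective", pores = pores, area_fraction = frac),
    class = "PermeabilityEstimate"
  )
}

#' Free energy by Boltzmann inversion of a pore-axis density
#'
#' `G(z) = -kB*T*log(p(z))` from per-atom z histograms of the selected
#' species inside a cylinder aligned with a pore axis (the equilibrium
#' counterpart of the biased-window profile). Anchored to `min(G) = 0`;
#' per-bin standard errors are `kB*T / sqrt(count)`.
#'
#' @param traj A `Trajectory`.
#' @param shell A `ShellGeometry`; its first pore's axis is the default
#'   cylinder axis.
#' @param cylinder_radius Cylinder radius (A), default 15.
#' @param species Species included (default `c("G3P", "DHAP")`).
#' @param bin_width Histogram bin width along z (A), default 0.5.
#' @param thermo A `ThermoConstants` or temperature in K.
#' @param axis Optional axis unit vector overriding the shell's first pore.
#' @return A `FreeEnergyProfile` over z (A; negative = shell interior).
#' @export
boltzmann_inversion <- function(traj, shell, cylinder_radius = 15,
                                species = c("G3P", "DHAP"), bin_width = 0.5,
                                thermo = 298, axis = NULL) {
  th <- as_thermo(thermo)
  if (is.null(axis)) {
    if (!length(shell$pores)) stop("no pore axis available; supply `axis`")
    axis <- shell$pores[[1]]$axis
  }
  axis <- axis / sqrt(sum(axis^2))
  sel <- traj$particles$species %in% species
  if (!any(sel)) stop("empty selection: no particles of species ",
                      paste(species, collapse = "/"))
  zs <- numeric(0)
  for (i in seq_len(n_frames(traj))) {
    m <- sweep(frame_coords(traj, i)[sel, , drop = FALSE], 2, shell$center)
    z <- as.numeric(m %*% axis)
    rho2 <- rowSums(m^2) - z^2
    # z measured from the shell mid-surface: negative inside
    zs <- c(zs, z[rho2 < cylinder_radius^2] - shell$R_mid)
  }
  if (!length(zs)) stop("no selected atoms found inside the cylinder")
  edges <- seq(floor(min(zs) / bin_width) * bin_width,
               ceiling(max(zs) / bin_width) * bin_width + bin_width / 2,
               by = bin_width)
  h <- graphics::hist(zs, breaks = edges, plot = FALSE)
  keep <- h$counts > 0
  G <- -th$kBT * log(h$counts[keep] / sum(h$counts))
  free_energy_profile(h$mids[keep], G, th$kBT / sqrt(h$counts[keep]))
}

#' Radially reweighted 2D free-energy surface around a pore axis
#'
#' Bins species atoms by axial position z and cylindrical radius r around a
#' pore axis, divides counts by the cylindrical bin volume `2*pi*r*dr*dz`
#' before inversion `G = -kB*T*log(p)` (so a uniform 3D density gives a flat
#' surface), anchors the occupied minimum to 0, and flags empty bins as
#' unreachable (`NA`) rather than zero.
#'
#' @param traj A `Trajectory`.
#' @param shell A `ShellGeometry`.
#' @param species Species included.
#' @param z_bins,r_bins Bin edges (A) for z (relative to the shell
#'   mid-surface along the axis) and cylindrical radius.
#' @param thermo A `ThermoConstants` or temperature in K.
#' @param axis Optional axis unit vector (default: first pore axis).
#' @return A list of class `Pmf2D`: `z_mids`, `r_mids`, `G` (matrix z x r,
#'   `NA` where unreachable), `stderr`, `counts`.
#' @export
pmf_2d <- function(traj, shell, species = c("G3P", "DHAP"), z_bins, r_bins,
                   thermo = 298, axis = NULL) {
  th <- as_thermo(thermo)
  if (any(diff(z_bins) <= 0) || any(diff(r_bins) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  if (is.null(axis)) {
    if (!length(shell$pores)) stop("no pore axis available; supply `axis`")
    axis <- shell$pores[[1]]$axis
  }
  axis <- axis / sqrt(sum(axis^2))
  sel <- traj$particles$species %in% species
  if (!any(sel)) stop("empty selection: no particles of species ",
                      paste(species, collapse = "/"))
  nz <- length(z_bins) - 1; nr <- length(r_bins) - 1
  counts <- matrix(0, nz, nr)
  for (i in seq_len(n_frames(traj))) {
    m <- sweep(frame_coords(traj, i)[sel, , drop = FALSE], 2, shell$center)
    z <- as.numeric(m %*% axis) - shell$R_mid
    r <- sqrt(pmax(rowSums(m^2) - (z + shell$R_mid)^2, 0))
    iz <- findInterval(z, z_bins, rightmost.closed = TRUE)
    ir <- findInterval(r, r_bins, rightmost.closed = TRUE)
    ok <- iz >= 1 & iz <= nz & ir >= 1 & ir <= nr
    if (any(ok)) {
      tab <- table(factor(iz[ok], levels = seq_len(nz)),
                   factor(ir[ok], levels = seq_len(nr)))
      counts <- counts + unclass(tab)
    }
  }
  z_mids <- z_bins[-1] - diff(z_bins) / 2
  r_mids <- r_bins[-1] - diff(r_bins) / 2
  vol <- outer(diff(z_bins), 2 * pi * r_mids * diff(r_bins))
  dens <- counts / vol
  G <- matrix(NA_real_, nz, nr)
  occ <- counts > 0
  G[occ] <- -th$kBT * log(dens[occ] / sum(dens[occ]))
  G <- G - min(G, na.rm = TRUE)
  err <- matrix(NA_real_, nz, nr)
  err[occ] <- th$kBT / sqrt(counts[occ])
  structure(list(z_mids = z_mids, r_mids = r_mids, G = G, stderr = err,
                 counts = counts, unreachable = !occ),
            class = "Pmf2D")
}
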