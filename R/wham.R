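# Weighted histogram analysis method: self-consistent unbiasing of
# overlapping harmonically biased window histograms into one free-energy
# profile, with a Bayesian-bootstrap standard error (Dirichlet weights over
# each window's samples, the WHAM solve repeated per resample).

#' Construct a gridded free-energy profile
#'
#' @param grid Strictly increasing reaction-coordinate grid (A).
#' @param G Free energy (kcal/mol); re-anchored so `min(G) = 0`.
#' @param stderr Standard errors (kcal/mol), same length as `grid` (0 if
#'   unknown).
#' @return An object of class `FreeEnergyProfile`.
#' @export
free_energy_profile <- function(grid, G, stderr = rep(0, length(grid))) {
  if (any(diff(grid) <= 0)) stop("profile grid must be strictly increasing")
  if (length(G) != length(grid) || length(stderr) != length(grid)) {
    stop("grid, G and stderr must have equal length")
  }
  structure(list(grid = as.numeric(grid), G = G - min(G),
                 stderr = as.numeric(stderr)),
            class = "FreeEnergyProfile")
}

#' Construct a gridded diffusivity profile
#'
#' @param grid Strictly increasing reaction-coordinate grid (A).
#' @param D Diffusivity (A^2/ns), strictly positive everywhere.
#' @return An object of class `DiffusivityProfile`.
#' @export
diffusivity_profile <- function(grid, D) {
  if (any(diff(grid) <= 0)) stop("profile grid must be strictly increasing")
  if (any(D <= 0)) stop("diffusivity must be positive everywhere")
  structure(list(grid = as.numeric(grid), D = as.numeric(D)),
            class = "DiffusivityProfile")
}

# core self-consistent solve on (possibly weighted) histogram counts
# counts: bins x windows, Ni: samples per window, cib: bias factors bins x windows
wham_core <- function(counts, Ni, cib, tol = 1e-7, max_iter = 20000) {
  Mb <- rowSums(counts)
  f <- rep(1, length(Ni))
  g_old <- rep(0, length(Ni))
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(cib %*% (Ni * f))
    p <- ifelse(denom > 0, Mb / denom, 0)
    p <- p / sum(p)
    f <- 1 / as.numeric(crossprod(cib, p))
    g <- log(f)
    g <- g - g[1]
    if (max(abs(g - g_old)) < tol) return(list(p = p, g = g, iter = it))
    g_old <- g
  }
  warning("WHAM did not converge to tolerance ", tol, " in ", max_iter,
          " iterations")
  list(p = p, g = g, iter = max_iter)
}

#' WHAM free-energy profile from umbrella windows
#'
#' Standard binned iterative WHAM: window histograms on a common grid are
#' unbiased self-consistently to relative tolerance `tol` on the window free
#' energies, the probability is inverted to `G = -kB*T*log(p)` and anchored
#' to `min(G) = 0`. Standard errors come from a Bayesian bootstrap: per
#' resample, each window's samples get Dirichlet(1) weights, the weighted
#' histograms are re-solved, and the per-bin standard deviation over
#' `n_boot` resamples (each re-anchored) is reported.
#'
#' Adjacent windows must overlap (share at least one occupied bin); a gap is
#' an error naming the offending interval. A single unbiased window
#' degenerates to direct Boltzmann inversion of its histogram.
#'
#' @param windows List of `UmbrellaWindow` objects.
#' @param bin_width Histogram bin width (A), default 0.5 (matching the
#'   window spacing the profiles were sampled with).
#' @param thermo A `ThermoConstants` or temperature in K (default 298).
#' @param equil_discard Override for the per-window equilibration discard
#'   (ns); `NULL` uses each window's own `equil_discard` field. The
#'   conventional discard for raw replica-exchange windows is 20 ns.
#' @param tol Relative tolerance on window free energies (default 1e-7).
#' @param n_boot Bootstrap resamples for the standard error (default 200; 0
#'   disables).
#' @param boot_seed Seed for the bootstrap (default 1).
#' @return A `FreeEnergyProfile` on the occupied bin centers.
#' @export
wham <- function(windows, bin_width = 0.5, thermo = 298, equil_discard = NULL,
                 tol = 1e-7, n_boot = 200, boot_seed = 1) {
  th <- as_thermo(thermo)
  if (inherits(windows, "UmbrellaWindow")) windows <- list(windows)
  if (!length(windows)) stop("no windows supplied")
  samples <- lapply(windows, window_production, equil_discard = equil_discard)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  W <- length(windows)

  rng <- range(unlist(samples))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width + bin_width / 2,
               by = bin_width)
  mids <- edges[-1] - bin_width / 2
  B <- length(mids)
  bin_of <- lapply(samples, function(s) {
    pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), B)
  })
  counts <- vapply(bin_of, function(b) tabulate(b, nbins = B), numeric(B))
  Ni <- vapply(samples, length, numeric(1))

  # overlap check on occupied bins, in center order
  ord <- order(centers)
  occ <- counts > 0
  for (i in seq_len(W - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    if (!any(occ[, a] & occ[, b])) {
      stop(sprintf(paste0("windows at %.3f and %.3f A share no occupied bins; ",
                          "sampling gap in (%.3f, %.3f)"),
                   centers[a], centers[b],
                   max(mids[occ[, a]]), min(mids[occ[, b]])))
    }
  }

  cib <- exp(-th$beta *
               outer(mids, seq_len(W),
                     function(x, w) 0.5 * ks[w] * (x - centers[w])^2))
  sol <- wham_core(counts, Ni, cib, tol = tol)
  keep <- rowSums(counts) > 0
  Gk <- -th$kBT * log(sol$p[keep])

  err <- rep(0, sum(keep))
  if (n_boot > 0) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed))
    set.seed(boot_seed)
    Gb <- matrix(NA_real_, n_boot, sum(keep))
    for (r in seq_len(n_boot)) {
      wcounts <- vapply(seq_len(W), function(w) {
        wts <- stats::rgamma(Ni[w], 1)
        wts <- wts / sum(wts) * Ni[w]
        as.numeric(rowsum(wts, bin_of[[w]],
                          reorder = FALSE)[match(seq_len(B),
                                                 sort(unique(bin_of[[w]])))])
      }, numeric(B))
      wcounts[is.na(wcounts)] <- 0
      solb <- wham_core(wcounts, Ni, cib, tol = tol * 10)
      gb <- -th$kBT * log(pmax(solb$p[keep], 1e-300))
      Gb[r, ] <- gb - min(gb)
    }
    err <- apply(Gb, 2, stats::sd)
  }
  free_energy_profile(mids[keep], Gk, err)
}
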