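# Lag-time MSD diffusion: D(dt) = MSD(dt) / (6 dt), averaged over particles
# and overlapping time origins. Region-resolved variants discard displacement
# windows that straddle a shell crossing, so "inside" and "outside" estimates
# are not contaminated by transiting molecules.

msd_lag_frames <- function(times, lag) {
  dtf <- stats::median(diff(times))
  lf <- round(lag / dtf)
  if (lf < 1) stop(sprintf("lag %.3g ns is below the frame spacing %.3g ns", lag, dtf))
  lf
}

#' Mean-squared displacement and diffusion coefficient by lag time
#'
#' For each requested lag, displacements are collected over all particles in
#' `subset` and all valid overlapping time origins (origin stride = half the
#' lag, a variance-reduction compromise short of full autocorrelation
#' bookkeeping), and `D = MSD / (6 * lag)`. Refuses wrapped trajectories:
#' unwrapping heuristics corrupt diffusion estimates.
#'
#' When `shell` and `region` are given, particles are assigned to the region
#' by their radius at the window start, and windows during which the particle
#' crosses `R_mid` are discarded.
#'
#' @param traj An unwrapped `Trajectory`.
#' @param lags Lag times (ns) within the trajectory span. The conventional
#'   headline lag is 2 ns.
#' @param subset Logical/integer particle selector (default: all particles).
#' @param shell Optional `ShellGeometry` for region-resolved estimates.
#' @param region `"inside"` or `"outside"` (requires `shell`).
#' @return A data.frame of class `MSDResult`: `lag` (ns), `MSD` (A^2),
#'   `D` (A^2/ns), `subset` label, `n_pairs`.
#' @export
msd_lag <- function(traj, lags, subset = NULL, shell = NULL, region = NULL) {
  if (!traj$unwrapped) {
    stop("trajectory is wrapped; MSD requires unwrapped coordinates")
  }
  nf <- n_frames(traj)
  np <- dim(traj$coords)[2]
  if (is.null(subset)) subset <- seq_len(np)
  if (is.logical(subset)) subset <- which(subset)
  lab <- if (is.null(region)) "all" else region
  side <- NULL
  if (!is.null(region)) {
    if (is.null(shell)) stop("region-resolved MSD requires a ShellGeometry")
    rad <- radii_matrix(traj, shell, subset)
    side <- rad < shell$R_mid           # frames x subset
    want_inside <- match.arg(region, c("inside", "outside")) == "inside"
    cs <- apply(side, 2, cumsum)        # for fast window-constancy checks
  }
  res <- lapply(lags, function(lag) {
    lf <- msd_lag_frames(traj$times, lag)
    if (lf >= nf) stop(sprintf("lag %.3g ns exceeds the trajectory span", lag))
    stride <- max(1L, floor(lf / 2))
    origins <- seq(1L, nf - lf, by = stride)
    d2 <- (traj$coords[origins + lf, subset, , drop = FALSE] -
             traj$coords[origins, subset, , drop = FALSE])^2
    sq <- d2[, , 1] + d2[, , 2] + d2[, , 3]
    sq <- matrix(sq, length(origins), length(subset))
    if (!is.null(side)) {
      # windows must stay on one side of R_mid for all lf+1 frames
      n_in <- cs[origins + lf, , drop = FALSE] - cs[origins, , drop = FALSE] +
        side[origins, , drop = FALSE]
      keep <- if (want_inside) n_in == (lf + 1L) else n_in == 0L
      sq[!keep] <- NA
    }
    real_lag <- traj$times[1 + lf] - traj$times[1]
    msd <- mean(sq, na.rm = TRUE)
    data.frame(lag = real_lag, MSD = msd, D = msd / (6 * real_lag),
               subset = lab, n_pairs = sum(!is.na(sq)))
  })
  out <- do.call(rbind, res)
  class(out) <- c("MSDResult", "data.frame")
  out
}

radii_matrix <- function(traj, shell, subset = NULL) {
  np <- dim(traj$coords)[2]
  if (is.null(subset)) subset <- seq_len(np)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(subset))
  for (i in seq_len(nf)) {
    d <- sweep(frame_coords(traj, i)[subset, , drop = FALSE], 2, shell$center)
    out[i, ] <- sqrt(rowSums(d^2))
  }
  out
}

#' Inside/outside region labels per particle per time origin
#'
#' Assigns each particle inside or outside at each frame by its radius versus
#' `R_mid`. Consumers that measure displacements over a window `[o, o + lag]`
#' should discard windows whose labels are not constant (the particle crossed
#' mid-window); [msd_lag()] applies that rule internally.
#'
#' @param traj A `Trajectory`.
#' @param shell A `ShellGeometry`.
#' @param subset Optional particle selector.
#' @return Character matrix frames x particles of `"inside"`/`"outside"`,
#'   with the radii as `attr(, "radii")`.
#' @export
partition_by_region <- function(traj, shell, subset = NULL) {
  rad <- radii_matrix(traj, shell, subset)
  lab <- ifelse(rad < shell$R_mid, "inside", "outside")
  attr(lab, "radii") <- rad
  lab
}

#' Radial diffusion profile
#'
#' Particles are binned by their radius at the window start; the diffusion
#' coefficient per bin is the mean squared displacement over a fixed interval
#' divided by `6 * interval`. With a list of replica trajectories the per-bin
#' error is the standard deviation across replicas; with a single trajectory
#' a block bootstrap over time origins (blocks of consecutive origins) is
#' substituted.
#'
#' @param traj A `Trajectory` or list of replica `Trajectory` objects.
#' @param shell A `ShellGeometry`.
#' @param r_bins Radial bin edges (A).
#' @param interval Displacement interval (ns), default 1; must be at least
#'   the frame spacing.
#' @param subset Optional particle selector.
#' @param n_boot Bootstrap resamples for the single-trajectory error
#'   (default 100).
#' @param seed Bootstrap seed.
#' @return Data.frame: `r_lo`, `r_hi`, `r_mid`, `D`, `stderr`, `n` (window
#'   count); empty bins carry `NA` (flagged missing, not zero).
#' @export
radial_diffusion_profile <- function(traj, shell, r_bins, interval = 1,
                                     subset = NULL, n_boot = 100, seed = 1) {
  trajs <- if (inherits(traj, "Trajectory")) list(traj) else traj
  nb <- length(r_bins) - 1
  collect <- function(tr) {
    if (!tr$unwrapped) stop("radial diffusion requires unwrapped coordinates")
    lf <- msd_lag_frames(tr$times, interval)
    nf <- n_frames(tr)
    if (lf >= nf) stop("interval exceeds the trajectory span")
    np <- dim(tr$coords)[2]
    if (is.null(subset)) subset <- seq_len(np)
    if (is.logical(subset)) subset <- which(subset)
    rad <- radii_matrix(tr, shell, subset)
    origins <- seq(1L, nf - lf, by = max(1L, lf))
    d2 <- (tr$coords[origins + lf, subset, , drop = FALSE] -
             tr$coords[origins, subset, , drop = FALSE])^2
    sq <- matrix(d2[, , 1] + d2[, , 2] + d2[, , 3], length(origins), length(subset))
    bin <- findInterval(rad[origins, , drop = FALSE], r_bins,
                        rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    real <- tr$times[1 + lf] - tr$times[1]
    data.frame(bin = as.integer(bin[ok]), sq = as.numeric(sq[ok]),
               origin = as.integer(row(sq)[ok]), interval = real)
  }
  per_traj <- lapply(trajs, collect)
  interval_real <- per_traj[[1]]$interval[1]
  all <- do.call(rbind, per_traj)
  Dmean <- tapply(all$sq, factor(all$bin, levels = seq_len(nb)), mean) /
    (6 * interval_real)
  n <- tapply(all$sq, factor(all$bin, levels = seq_len(nb)), length)
  n[is.na(n)] <- 0

  err <- rep(NA_real_, nb)
  if (length(per_traj) > 1) {
    Ds <- vapply(per_traj, function(d) {
      as.numeric(tapply(d$sq, factor(d$bin, levels = seq_len(nb)), mean)) /
        (6 * interval_real)
    }, numeric(nb))
    err <- apply(Ds, 1, stats::sd, na.rm = TRUE)
  } else if (n_boot > 0) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed))
    set.seed(seed)
    d <- per_traj[[1]]
    no <- max(d$origin)
    blocks <- split(seq_len(no), ceiling(seq_len(no) / max(1L, floor(no / 10))))
    boot <- matrix(NA_real_, n_boot, nb)
    for (b in seq_len(n_boot)) {
      pick <- unlist(blocks[sample(length(blocks), length(blocks), replace = TRUE)])
      dd <- d[d$origin %in% pick, ]
      boot[b, ] <- as.numeric(tapply(dd$sq, factor(dd$bin, levels = seq_len(nb)),
                                     mean)) / (6 * interval_real)
    }
    err <- apply(boot, 2, stats::sd, na.rm = TRUE)
  }
  data.frame(r_lo = r_bins[-length(r_bins)], r_hi = r_bins[-1],
             r_mid = r_bins[-length(r_bins)] + diff(r_bins) / 2,
             D = as.numeric(Dmean), stderr = err, n = as.integer(n))
}

#' Radial probability-per-area density profile
#'
#' Counts of the selected particles per radial bin, normalized to a
#' probability and divided by the spherical-bin area `4*pi*r^2*dr`.
#' Optionally, interior bins (entirely below `R_mid`) have their effective
#' free area reduced by the protein-occupied volume fraction, scaling the
#' interior density by `1 / (1 - free_volume_fraction)`; the conventional
#' interior occupancy is 0.20.
#'
#' @param traj A `Trajectory`.
#' @param shell A `ShellGeometry`.
#' @param r_bins Radial bin edges (A).
#' @param free_volume_fraction Interior protein-occupied fraction in
#'   `[0, 1)`; 0 disables the correction (default 0.20).
#' @param subset Optional particle selector.
#' @return Data.frame: `r_mid`, `count`, `density` (probability per A^2 of
#'   shell area per A of radius), `corrected` flag.
#' @export
radial_density <- function(traj, shell, r_bins, free_volume_fraction = 0.20,
                           subset = NULL) {
  stopifnot(free_volume_fraction >= 0, free_volume_fraction < 1)
  nb <- length(r_bins) - 1
  rad <- radii_matrix(traj, shell, subset)
  bin <- findInterval(rad, r_bins, rightmost.closed = TRUE)
  counts <- tabulate(bin[bin >= 1 & bin <= nb], nbins = nb)
  r_mid <- r_bins[-length(r_bins)] + diff(r_bins) / 2
  area <- 4 * pi * r_mid^2 * diff(r_bins)
  interior <- r_bins[-1] <= shell$R_mid
  if (free_volume_fraction > 0) {
    area[interior] <- area[interior] * (1 - free_volume_fraction)
  }
  p <- counts / sum(counts)
  data.frame(r_mid = r_mid, count = counts, density = p / area,
             corrected = interior & free_volume_fraction > 0)
}

#' Stokes-Einstein-Sutherland diffusion prediction
#'
#' Treats a complex of molecular weight MW as a sphere of density rho:
#' `D = kB*T / (6*pi*eta) * (4*pi*rho / (3*MW))^(1/3)`, reported in units of
#' 1e-8 cm^2/s. With the defaults (rho = 1.35 g/cm^3, eta = 1 cP, T = 298 K)
#' a 50 kDa complex predicts approximately 90 (x 1e-8 cm^2/s).
#'
#' @param MW Molecular weight (kDa).
#' @param rho Protein density (g/cm^3), default 1.35.
#' @param eta Viscosity (cP), default 1.
#' @param T_K Temperature (K), default 298.
#' @return Diffusion coefficient in 1e-8 cm^2/s.
#' @export
predict_diffusion <- function(MW, rho = 1.35, eta = 1, T_K = 298) {
  stopifnot(all(MW > 0), rho > 0, eta > 0, T_K > 0)
  kB_erg <- 1.380649e-16
  r_cm <- (3 * (MW * 1000) / (4 * pi * rho * bmc_constants$avogadro))^(1 / 3)
  D <- kB_erg * T_K / (6 * pi * (eta * 0.01) * r_cm)   # cm^2/s
  D / 1e-8
}

#' Fit observed complex diffusion to the Stokes-Einstein-Sutherland form
#'
#' Least squares of `D = a * MW^(-1/3) + b`. The slope recovers the
#' viscosity through the Stokes-Einstein-Sutherland prefactor; the constant
#' offset `b` absorbs the constant-density assumption (lighter complexes are
#' denser than the fixed rho, so a negative offset is expected on real
#' cargo).
#'
#' @param points Data.frame with columns `MW` (kDa) and `D` (1e-8 cm^2/s);
#'   at least 3 distinct MW values.
#' @param rho Assumed protein density (g/cm^3).
#' @param T_K Temperature (K).
#' @return An object of class `SEFit`: `eta` (cP), `offset` (1e-8 cm^2/s),
#'   `slope`, `rho`, `T`, `residuals`, and the underlying `lm` fit.
#' @export
stokes_einstein_fit <- function(points, rho = 1.35, T_K = 298) {
  stopifnot(all(c("MW", "D") %in% names(points)))
  if (length(unique(points$MW)) < 3) {
    stop("need at least 3 distinct MW values to fit slope and offset")
  }
  x <- points$MW^(-1 / 3)
  fit <- stats::lm(points$D ~ x)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (a <= 0) stop("fitted slope is non-positive; data do not follow D ~ MW^(-1/3)")
  # prefactor at unit viscosity: predict_diffusion(MW) = C/eta * MW^(-1/3)
  C1 <- predict_diffusion(1, rho = rho, eta = 1, T_K = T_K)
  structure(
    list(eta = C1 / a, offset = b, slope = a, rho = rho, T = T_K,
         residuals = stats::residuals(fit), fit = fit),
    class = "SEFit"
  )
}

#' @export
print.SEFit <- function(x, ...) {
  cat(sprintf("SEFit: eta = %.3g cP, offset = %.3g x1e-8 cm^2/s (rho = %.2f g/cm^3, T = %g K)\n",
              x$eta, x$offset, x$rho, x$T))
  invisible(x)
}
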