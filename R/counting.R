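# Transition-event counting: track per-solute radial position relative to the
# shell centroid, detect crossings with a two-threshold hysteresis automaton,
# and convert counts + concentration + area + time into a permeability
# coefficient P = x / (2 c A t). The factor 2 credits equilibrium
# bidirectionality; the Poisson standard error sqrt(x) is propagated.

#' Per-particle radial position time series
#'
#' Radii (A) relative to the per-frame shell centroid. When the trajectory
#' contains shell particles the centroid is refit each frame from
#' `shell_selection`; otherwise the fixed shell center is used.
#'
#' @param traj A `Trajectory`.
#' @param shell A `ShellGeometry` (fixed-center fallback).
#' @param species Character vector of species to include (default: all
#'   non-shell, non-solvent particles).
#' @param shell_selection Logical index of shell particles used to refit the
#'   centroid per frame; `NULL` uses `role == "shell"`, and if that selects
#'   nothing the fixed `shell$center` is used.
#' @return A matrix frames x particles of radii, with frame times as
#'   `attr(, "times")` and particle ids as column names.
#' @export
radial_series <- function(traj, shell, species = NULL, shell_selection = NULL) {
  ps <- traj$particles
  if (is.null(shell_selection)) shell_selection <- ps$role == "shell"
  sel <- if (is.null(species)) {
    !(ps$role %in% c("shell", "solvent"))
  } else ps$species %in% species
  if (!any(sel)) stop("no particles selected for radial series")
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, sum(sel))
  colnames(out) <- as.character(ps$particle_id[sel])
  refit <- any(shell_selection)
  for (i in seq_len(nf)) {
    m <- frame_coords(traj, i)
    ctr <- if (refit) colMeans(m[shell_selection, , drop = FALSE]) else shell$center
    d <- sweep(m[sel, , drop = FALSE], 2, ctr)
    out[i, ] <- sqrt(rowSums(d^2))
  }
  attr(out, "times") <- traj$times
  out
}

#' Detect shell-crossing events with a hysteresis automaton
#'
#' Two-state automaton per particle: the state becomes "inside" only when the
#' radius drops below `R_in` and "outside" only when it exceeds `R_out`;
#' every state flip emits one event timestamped at the first frame past the
#' threshold. Excursions confined to the hysteresis band `(R_in, R_out)`
#' produce no events, which suppresses single-frame recrossing noise. The
#' initial state is the first frame's side of the band midpoint. Events for
#' any one particle therefore alternate in direction by construction.
#'
#' @param series Radius matrix from [radial_series()] (frames x particles),
#'   or a numeric vector for a single particle.
#' @param R_in,R_out Hysteresis thresholds (A), `R_in < R_out`.
#' @param times Frame times (ns); defaults to `attr(series, "times")` or the
#'   frame index.
#' @param species Species label stored on the events (default `NA`).
#' @return A data.frame of class `TransitionEvents` with columns
#'   `particle_id`, `crossing_time`, `direction` ("inbound"/"outbound"),
#'   `species`.
#' @export
detect_transitions <- function(series, R_in, R_out, times = NULL, species = NA) {
  if (R_in >= R_out) stop("R_in must be < R_out")
  if (is.null(dim(series))) series <- matrix(series, ncol = 1,
                                             dimnames = list(NULL, "1"))
  if (is.null(times)) times <- attr(series, "times")
  if (is.null(times)) times <- seq_len(nrow(series))
  R_mid <- (R_in + R_out) / 2
  empty <- data.frame(particle_id = integer(), crossing_time = numeric(),
                      direction = character(), species = character(),
                      stringsAsFactors = FALSE)
  if (nrow(series) < 2) {
    class(empty) <- c("TransitionEvents", "data.frame")
    return(empty)
  }
  ev <- vector("list", ncol(series))
  for (j in seq_len(ncol(series))) {
    r <- series[, j]
    # definite states: 1 = inside (< R_in), 2 = outside (> R_out), NA in band
    s <- ifelse(r < R_in, 1L, ifelse(r > R_out, 2L, NA_integer_))
    s[1] <- if (is.na(s[1])) (if (r[1] < R_mid) 1L else 2L) else s[1]
    filled <- zoo::na.locf(s)
    flips <- which(diff(filled) != 0) + 1L
    if (length(flips)) {
      ev[[j]] <- data.frame(
        particle_id = as.integer(colnames(series)[j]),
        crossing_time = times[flips],
        direction = ifelse(filled[flips] == 1L, "inbound", "outbound"),
        species = as.character(species),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(list(empty), ev))
  rownames(out) <- NULL
  class(out) <- c("TransitionEvents", "data.frame")
  out
}

#' Partition transition events by direction
#'
#' @param events A `TransitionEvents` data.frame.
#' @return Named integer vector `c(n_inbound, n_outbound)`.
#' @export
directional_tally <- function(events) {
  c(n_inbound = sum(events$direction == "inbound"),
    n_outbound = sum(events$direction == "outbound"))
}

#' Permeability from crossing counts
#'
#' `P = x / (2 c A t)`, with `x` the number of crossing events in both
#' directions, `c` the solute concentration in water (molecules/A^3), `A` the
#' shell surface area (A^2) and `t` the aggregate simulation time (ns); the
#' result is converted to cm/s. The standard error propagates the Poisson
#' uncertainty `sqrt(x)`. When `x = 0` the point estimate is 0 and a
#' one-sided 95% Poisson upper bound (2.996 expected events) is reported.
#'
#' @param events A `TransitionEvents` data.frame, or an event count.
#' @param c Solute concentration; molecules/A^3 by default, or molar if
#'   `c_molar = TRUE`.
#' @param A Shell surface area (A^2).
#' @param t Aggregate trajectory time (ns).
#' @param c_molar Interpret `c` as mol/L instead of molecules/A^3.
#' @return An object of class `PermeabilityEstimate`: list with `P` (cm/s),
#'   `stderr`, `method = "counting"`, `upper95` (only when `x = 0`), and the
#'   inputs `c`, `A`, `t`, `n_transitions`, plus the area-normalized rate `r`.
#' @examples
#' permeability_from_counts(15, c = 250e-3 * bmc_constants$molar_to_per_A3,
#'                          A = 4 * pi * 180^2, t = 750)
#' @export
permeability_from_counts <- function(events, c, A, t, c_molar = FALSE) {
  x <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (c_molar) c <- c * bmc_constants$molar_to_per_A3
  if (c <= 0) stop("concentration must be positive")
  if (A <= 0) stop("surface area must be positive")
  if (t <= 0) stop("time must be positive")
  denom <- 2 * c * A * t                      # A^3 per A/ns
  P_A_ns <- x / denom
  conv <- bmc_constants$A_per_ns_to_cm_s
  est <- list(
    P = P_A_ns * conv,
    stderr = sqrt(x) / denom * conv,
    method = "counting",
    c = c, A = A, t = t, n_transitions = x,
    r = x / (A * t)                           # transitions per A^2 per ns
  )
  if (x == 0) est$upper95 <- -log(0.05) / denom * conv
  class(est) <- "PermeabilityEstimate"
  est
}

#' @export
print.PermeabilityEstimate <- function(x, ...) {
  cat(sprintf("PermeabilityEstimate (%s): P = %.4g +/- %.2g cm/s", x$method,
              x$P, x$stderr))
  if (!is.null(x$n_transitions)) cat(sprintf(" [%d transitions]", x$n_transitions))
  cat("\n")
  invisible(x)
}

#' Solute concentration from water counts
#'
#' Molarity of a species in a region, with the aqueous volume inferred from
#' the water count: one water accounts for 1/55.345 L/mol of aqueous volume,
#' so `molarity = n_species / n_waters * 55.345 M`.
#'
#' @param traj A `Trajectory` (region assignment by radius vs `shell$R_mid`),
#'   or `NULL` if `n_species`/`n_waters` are given directly.
#' @param shell A `ShellGeometry` (required for region selection on a
#'   trajectory).
#' @param species Species label(s) counted.
#' @param region `"inside"`, `"outside"` or `"all-aqueous"`.
#' @param frame Frame used for the counts (default 1: initial loading is the
#'   unambiguous reference for the counting estimator's `c`).
#' @param n_species,n_waters Direct counts, bypassing the trajectory.
#' @return Concentration in mol/L.
#' @examples
#' concentration_estimate(n_species = 5, n_waters = 60000)  # ~0.0046 M ~ 5 mM
#' @export
concentration_estimate <- function(traj = NULL, shell = NULL, species = NULL,
                                   region = c("all-aqueous", "inside", "outside"),
                                   frame = 1, n_species = NULL, n_waters = NULL) {
  region <- match.arg(region)
  if (is.null(n_species) || is.null(n_waters)) {
    stopifnot(inherits(traj, "Trajectory"))
    ps <- traj$particles
    m <- frame_coords(traj, frame)
    keep <- rep(TRUE, nrow(ps))
    if (region != "all-aqueous") {
      if (is.null(shell)) stop("region selection requires a ShellGeometry")
      r <- sqrt(rowSums(sweep(m, 2, shell$center)^2))
      keep <- if (region == "inside") r < shell$R_mid else r >= shell$R_mid
    }
    n_waters <- sum(keep & ps$species == "water")
    n_species <- sum(keep & ps$species %in% species)
  }
  if (n_waters <= 0) {
    if (n_species == 0) return(0)
    stop("no water molecules in region; cannot form an aqueous volume")
  }
  n_species / n_waters * bmc_constants$water_molarity
}

#' Steady-state concentration gradient from flux balance
#'
#' Inverts the flux relation `J = P * A * dC` for the standing concentration
#' difference a constant consumption flux would maintain.
#'
#' @param P Permeability (cm/s).
#' @param A Surface area (A^2).
#' @param J Flux in molecules/s.
#' @return An object of class `FluxBalance`: list with `J` (molecules/s),
#'   `dC_molar` (mol/L), `dC_per_A3` (molecules/A^3), `A` (A^2), `P` (cm/s).
#'   The invariant `J = P * A * dC` holds by construction after unit
#'   conversion.
#' @examples
#' # ~19 nm shell consuming 1 molecule/s at P = 0.0055 cm/s -> ~6.7 nM
#' steady_state_gradient(P = 0.0055, A = 4 * pi * 190^2, J = 1)
#' @export
steady_state_gradient <- function(P, A, J) {
  if (P <= 0) stop("P must be positive")
  if (A <= 0) stop("A must be positive")
  A_cm2 <- A * 1e-16
  dC_cm3 <- J / (P * A_cm2)                      # molecules / cm^3
  dC_molar <- dC_cm3 / bmc_constants$avogadro * 1000
  structure(
    list(J = J, dC_molar = dC_molar,
         dC_per_A3 = dC_cm3 * 1e-24, A = A, P = P),
    class = "FluxBalance"
  )
}

#' @export
print.FluxBalance <- function(x, ...) {
  cat(sprintf("FluxBalance: J = %.3g molecules/s, P = %.3g cm/s, dC = %.3g M\n",
              x$J, x$P, x$dC_molar))
  invisible(x)
}
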