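# Harmonically biased window generator: 1D overdamped Langevin on
# U(xi) = G(xi) + k/2 (xi - xi0)^2 with a position-dependent diffusivity
# profile, emulating umbrella-sampling windows along a pore axis. All windows
# are generated independently (no replica-exchange swap logic).

#' Specification for synthetic umbrella-sampling windows
#'
#' @param profile_G Function of xi (A) returning the free energy (kcal/mol).
#' @param profile_D Function of xi (A) returning the diffusivity (A^2/ns).
#' @param window_centers Strictly increasing bias centers (A).
#' @param k_bias Harmonic force constant (kcal/mol/A^2), default 5 as used
#'   for pore-axis restraints.
#' @param n_samples Samples recorded per window after equilibration.
#' @param sample_interval Recording interval (ps), default 0.2.
#' @param equil_discard Equilibration discarded before recording (ns).
#' @param seed Integer RNG seed.
#' @param T_K Temperature (K).
#' @param dt_ps Integration step (ps); default `sample_interval/10`.
#' @return A validated list of class `UmbrellaSpec`.
#' @export
umbrella_spec <- function(profile_G, profile_D, window_centers, k_bias = 5,
                          n_samples = 4000, sample_interval = 0.2,
                          equil_discard = 0.05, seed = 1, T_K = 298,
                          dt_ps = NULL) {
  stopifnot(is.function(profile_G), is.function(profile_D))
  if (any(diff(window_centers) <= 0)) {
    stop("window_centers must be strictly increasing")
  }
  if (k_bias <= 0) stop("k_bias must be positive")
  if (n_samples <= 0) stop("n_samples must be positive (window would be empty)")
  if (is.null(dt_ps)) dt_ps <- sample_interval / 10
  structure(
    list(profile_G = profile_G, profile_D = profile_D,
         window_centers = as.numeric(window_centers), k_bias = k_bias,
         n_samples = as.integer(n_samples), sample_interval = sample_interval,
         equil_discard = equil_discard, seed = as.integer(seed), T_K = T_K,
         dt_ps = dt_ps),
    class = "UmbrellaSpec"
  )
}

#' Construct an umbrella-sampling window
#'
#' @param center Bias center xi0 (A).
#' @param k Force constant (kcal/mol/A^2); 0 denotes an unbiased window
#'   (used for direct Boltzmann inversion through the WHAM degenerate case).
#' @param samples Reaction-coordinate samples (A) at fixed interval.
#' @param interval Sampling interval (ps).
#' @param equil_discard Initial span (ns) that consumers such as [wham()]
#'   should discard; 0 for synthetic windows that are pre-equilibrated.
#' @return An object of class `UmbrellaWindow`.
#' @export
umbrella_window <- function(center, k, samples, interval, equil_discard = 0) {
  if (k < 0) stop("force constant k must be non-negative")
  if (length(samples) == 0) stop("window has no samples")
  structure(
    list(center = center, k = k, samples = as.numeric(samples),
         interval = interval, equil_discard = equil_discard),
    class = "UmbrellaWindow"
  )
}

# samples remaining after discarding the window's declared equilibration
window_production <- function(w, equil_discard = NULL) {
  disc <- if (is.null(equil_discard)) w$equil_discard else equil_discard
  ndrop <- floor(disc * 1000 / w$interval)  # ns -> ps
  if (ndrop >= length(w$samples)) {
    stop(sprintf("window at %.2f A has no samples after discarding %.3f ns",
                 w$center, disc))
  }
  w$samples[(ndrop + 1):length(w$samples)]
}

#' Generate biased window time series on a stated profile
#'
#' Each window's reaction coordinate evolves by Euler-Maruyama overdamped
#' Langevin dynamics on `U(xi) = G(xi) + k/2 (xi - xi0)^2` with diffusivity
#' `D(xi)` and the gradient-of-D drift correction; samples are recorded every
#' `sample_interval` ps after discarding `equil_discard` ns. Windows are
#' independent (all advanced in lockstep from one seeded stream).
#'
#' @param spec An `UmbrellaSpec`.
#' @return A list of `UmbrellaWindow` objects (with `equil_discard = 0`:
#'   equilibration has already been removed).
#' @examples
#' sp <- umbrella_spec(function(x) 0 * x, function(x) rep(70, length(x)),
#'                     window_centers = c(-1, 0, 1), n_samples = 500, seed = 2)
#' ws <- gen_umbrella_windows(sp)
#' length(ws[[2]]$samples)
#' @export
gen_umbrella_windows <- function(spec) {
  stopifnot(inherits(spec, "UmbrellaSpec"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(spec$seed)

  beta <- 1 / (bmc_constants$kB * spec$T_K)
  centers <- spec$window_centers
  W <- length(centers)
  k <- spec$k_bias
  dt_ns <- spec$dt_ps / 1000
  substeps <- max(1L, round(spec$sample_interval / spec$dt_ps))
  n_equil <- ceiling(spec$equil_discard * 1000 / spec$dt_ps)

  eps <- 1e-5
  Gfun <- spec$profile_G
  Dfun <- spec$profile_D
  dG <- function(x) (Gfun(x + eps) - Gfun(x - eps)) / (2 * eps)
  dD <- function(x) (Dfun(x + eps) - Dfun(x - eps)) / (2 * eps)

  xi <- centers  # start at the bias centers
  step_once <- function(xi) {
    D <- Dfun(xi)
    drift <- -beta * D * (dG(xi) + k * (xi - centers)) + dD(xi)
    xi + drift * dt_ns + sqrt(2 * D * dt_ns) * stats::rnorm(W)
  }
  for (i in seq_len(n_equil)) xi <- step_once(xi)
  out <- matrix(NA_real_, spec$n_samples, W)
  for (s in seq_len(spec$n_samples)) {
    for (j in seq_len(substeps)) xi <- step_once(xi)
    out[s, ] <- xi
  }
  lapply(seq_len(W), function(w) {
    umbrella_window(centers[w], k, out[, w], spec$sample_interval,
                    equil_discard = 0)
  })
}
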