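# Osmotic-balance diagnostics: interior water counting (spherical or
# voxel-grid criterion), flood-fill interior volume, water ingress rate, and
# the interior-water replication utility used to rebalance osmotic pressure
# before production runs (the rebalancing loop itself stays human-in-the-loop;
# these are the diagnostics, not an auto-balancer).

#' Voxel occupancy grid and flood-fill interior volume
#'
#' Voxels within `atom_radius` of any shell atom are marked occupied; a
#' 6-connected flood fill seeded at all eight box corners marks the exterior;
#' remaining unoccupied voxels are the interior and their count times
#' `spacing^3` is the interior volume. If the fill reaches the geometric
#' center the shell is leaky: a warning is raised and the volume is still
#' reported.
#'
#' @param frame A `ParticleSet` (or `Trajectory` + `frame_index`).
#' @param shell_selection Logical/integer selector of shell atoms (default
#'   `role == "shell"`).
#' @param spacing Voxel edge (A), default 1.
#' @param atom_radius Occupancy radius around each shell atom (A),
#'   default 2.4.
#' @param frame_index Frame used for a `Trajectory` input.
#' @param return_grid Also return the `VoxelGrid` (origin, spacing,
#'   occupancy and interior masks).
#' @return The interior volume (A^3); with `return_grid = TRUE`, a list
#'   `(volume, grid)` where `grid` has class `VoxelGrid`.
#' @export
interior_volume <- function(frame, shell_selection = NULL, spacing = 1,
                            atom_radius = 2.4, frame_index = 1,
                            return_grid = FALSE) {
  if (inherits(frame, "Trajectory")) {
    ps <- frame$particles
    m <- frame_coords(frame, frame_index)
  } else {
    ps <- frame
    m <- coords_matrix(ps)
  }
  stopifnot(spacing > 0, atom_radius > 0)
  if (is.null(shell_selection)) shell_selection <- ps$role == "shell"
  m <- m[shell_selection, , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no shell atoms: entire box is exterior, interior volume 0")
    vol <- 0
    if (!return_grid) return(vol)
    return(list(volume = vol, grid = NULL))
  }
  pad <- atom_radius + 2 * spacing
  origin <- apply(m, 2, min) - pad
  upper <- apply(m, 2, max) + pad
  dims <- pmax(ceiling((upper - origin) / spacing), 3)

  # occupancy via a precomputed sphere stencil of voxel offsets
  reach <- ceiling(atom_radius / spacing) + 1L
  off <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  off <- off[rowSums(off^2) * spacing^2 <=
               (atom_radius + spacing * sqrt(3) / 2)^2, , drop = FALSE]
  n_at <- nrow(m)
  n_off <- nrow(off)
  base_ix <- floor(sweep(m, 2, origin) / spacing) + 1L
  cand <- base_ix[rep(seq_len(n_at), each = n_off), ] +
    off[rep(seq_len(n_off), times = n_at), ]
  ctr <- sweep((cand - 0.5) * spacing, 2, origin, `+`)
  am <- m[rep(seq_len(n_at), each = n_off), , drop = FALSE]
  d2 <- (ctr[, 1] - am[, 1])^2 + (ctr[, 2] - am[, 2])^2 + (ctr[, 3] - am[, 3])^2
  hit <- d2 <= atom_radius^2 &
    cand[, 1] >= 1 & cand[, 1] <= dims[1] &
    cand[, 2] >= 1 & cand[, 2] <= dims[2] &
    cand[, 3] >= 1 & cand[, 3] <= dims[3]
  occ <- array(FALSE, dims)
  occ[cand[hit, , drop = FALSE]] <- TRUE

  # flood fill exterior from all eight corners: 6-connected, implemented as
  # directional slab sweeps iterated to a fixed point
  ext <- array(FALSE, dims)
  corners <- as.matrix(expand.grid(c(1, dims[1]), c(1, dims[2]), c(1, dims[3])))
  seed_ok <- !occ[corners]
  ext[corners[seed_ok, , drop = FALSE]] <- TRUE
  free <- !occ
  repeat {
    n_before <- sum(ext)
    for (i in 2:dims[1])  ext[i, , ] <- (ext[i, , ] | ext[i - 1, , ]) & free[i, , ]
    for (i in (dims[1] - 1):1) ext[i, , ] <- (ext[i, , ] | ext[i + 1, , ]) & free[i, , ]
    for (j in 2:dims[2])  ext[, j, ] <- (ext[, j, ] | ext[, j - 1, ]) & free[, j, ]
    for (j in (dims[2] - 1):1) ext[, j, ] <- (ext[, j, ] | ext[, j + 1, ]) & free[, j, ]
    for (k in 2:dims[3])  ext[, , k] <- (ext[, , k] | ext[, , k - 1]) & free[, , k]
    for (k in (dims[3] - 1):1) ext[, , k] <- (ext[, , k] | ext[, , k + 1]) & free[, , k]
    if (sum(ext) == n_before) break
  }
  interior <- !occ & !ext
  ctr_ix <- matrix(pmax(1, round(dims / 2)), 1)
  if (ext[ctr_ix]) {
    warning("flood fill reached the geometric center: shell is leaky; ",
            "volume reported anyway")
  }
  vol <- sum(interior) * spacing^3
  if (!return_grid) return(vol)
  grid <- structure(list(origin = origin, spacing = spacing, dims = dims,
                         occupancy = occ, interior = interior),
                    class = "VoxelGrid")
  list(volume = vol, grid = grid)
}

#' Count water molecules enclosed by the shell
#'
#' Spherical mode counts water sites with radius below `R_mid`; grid mode
#' counts water sites falling in the interior mask of a [interior_volume()]
#' voxel grid. Waters are judged by their oxygen site (each water particle
#' row in the package's data model is the oxygen).
#'
#' @param frame A `ParticleSet` (or `Trajectory` + `frame_index`).
#' @param shell A `ShellGeometry` (spherical mode) or `VoxelGrid` (grid
#'   mode).
#' @param frame_index Frame used for a `Trajectory` input.
#' @return Integer count.
#' @export
count_interior_waters <- function(frame, shell, frame_index = 1) {
  if (inherits(frame, "Trajectory")) {
    ps <- frame$particles
    m <- frame_coords(frame, frame_index)
  } else {
    ps <- frame
    m <- coords_matrix(ps)
  }
  w <- ps$species == "water"
  if (!any(w)) return(0L)
  m <- m[w, , drop = FALSE]
  if (inherits(shell, "ShellGeometry")) {
    r <- sqrt(rowSums(sweep(m, 2, shell$center)^2))
    return(sum(r < shell$R_mid))
  }
  if (inherits(shell, "VoxelGrid")) {
    ix <- floor(sweep(m, 2, shell$origin) / shell$spacing) + 1L
    inside <- ix[, 1] >= 1 & ix[, 1] <= shell$dims[1] &
      ix[, 2] >= 1 & ix[, 2] <= shell$dims[2] &
      ix[, 3] >= 1 & ix[, 3] <= shell$dims[3]
    ix <- ix[inside, , drop = FALSE]
    if (!nrow(ix)) return(0L)
    return(sum(shell$interior[ix]))
  }
  stop("`shell` must be a ShellGeometry or VoxelGrid")
}

#' Water ingress rate and interior percentage over time
#'
#' Finite-difference rate of the interior water count over a sliding window,
#' and the count as a percentage of the initial interior count.
#'
#' @param times Time points (ns), at least 2.
#' @param counts Interior water counts at `times`.
#' @param window Window length in time points (default 1: adjacent-point
#'   differences).
#' @return A list of class `WaterBalanceReport`: `times`, `counts`,
#'   `percentage` (relative to the initial count), `rate_times` (window
#'   midpoints) and `rate` (waters/ns).
#' @export
ingress_rate <- function(times, counts, window = 1) {
  if (length(times) < 2 || length(counts) != length(times)) {
    stop("need >= 2 (time, count) points of equal length")
  }
  window <- as.integer(window)
  stopifnot(window >= 1, window < length(times))
  i <- seq_len(length(times) - window)
  rate <- (counts[i + window] - counts[i]) / (times[i + window] - times[i])
  structure(
    list(times = times, counts = counts,
         percentage = counts / counts[1] * 100,
         rate_times = (times[i + window] + times[i]) / 2, rate = rate),
    class = "WaterBalanceReport"
  )
}

#' Replicate interior waters to rebalance osmotic pressure
#'
#' Duplicates a uniformly sampled fraction of the interior water molecules
#' at their original position plus a small random-direction displacement,
#' assigning fresh particle ids. A duplicate landing within `min_dist` of
#' any non-parent atom gets its direction resampled up to 10 times before
#' the call errors. All original particles are preserved verbatim. The
#' stable condition for cargo-loaded shells is typically a 20% replication
#' fraction.
#'
#' @param particles A `ParticleSet`.
#' @param shell A `ShellGeometry`; interior = radius below `R_mid`.
#' @param fraction Fraction of interior waters to replicate, in (0, 1].
#' @param displacement Displacement magnitude (A), default 0.5.
#' @param seed Integer RNG seed (identical output across invocations).
#' @param min_dist Clash distance (A), default 0.8.
#' @return A new `ParticleSet` with `attr(, "n_added")` duplicates appended.
#' @export
replicate_interior_waters <- function(particles, shell, fraction,
                                      displacement = 0.5, seed = 1,
                                      min_dist = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  validate_particle_set(particles)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  m <- coords_matrix(particles)
  r <- sqrt(rowSums(sweep(m, 2, shell$center)^2))
  interior_w <- which(particles$species == "water" & r < shell$R_mid)
  if (!length(interior_w)) stop("no interior waters to replicate")
  n_add <- floor(fraction * length(interior_w))
  if (n_add < 1) stop("fraction too small: zero waters would be added")
  chosen <- sample(interior_w, n_add)
  newpos <- matrix(NA_real_, n_add, 3)
  for (i in seq_len(n_add)) {
    parent <- chosen[i]
    placed <- FALSE
    for (attempt in 1:10) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- m[parent, ] + displacement * u
      d2 <- (m[, 1] - cand[1])^2 + (m[, 2] - cand[2])^2 + (m[, 3] - cand[3])^2
      d2[parent] <- Inf
      if (all(d2 >= min_dist^2)) {
        newpos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place duplicate of particle %d without a clash after 10 attempts",
                   particles$particle_id[parent]))
    }
  }
  dup <- particles[chosen, , drop = FALSE]
  dup$particle_id <- max(particles$particle_id) + seq_len(n_add)
  dup$x <- newpos[, 1]; dup$y <- newpos[, 2]; dup$z <- newpos[, 3]
  out <- rbind(particles, dup)
  class(out) <- c("ParticleSet", "data.frame")
  rownames(out) <- NULL
  attr(out, "n_added") <- as.integer(n_add)
  validate_particle_set(out)
  out
}
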