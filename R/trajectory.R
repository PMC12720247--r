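#' Construct a labeled trajectory
#'
#' A `Trajectory` holds time-ordered positions for a fixed `ParticleSet`:
#' a frames x particles x 3 coordinate array (Angstrom), strictly increasing
#' frame times (ns), per-trajectory box edge lengths (Angstrom), and an
#' `unwrapped` flag. Operations that consume displacements (MSD, diffusion)
#' refuse wrapped input rather than attempting to unwrap it.
#'
#' @param times Numeric vector of frame times in ns, strictly increasing.
#' @param coords Numeric array `[frame, particle, xyz]` in Angstrom.
#' @param particles The `ParticleSet` the coordinates refer to.
#' @param box Numeric length-3 box edge lengths in Angstrom (or `NA` for a
#'   non-periodic system).
#' @param unwrapped Logical: are coordinates continuous (not wrapped into the
#'   primary box)?
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(times, coords, particles, box = c(NA_real_, NA_real_, NA_real_),
                       unwrapped = TRUE) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (length(times) != dim(coords)[1]) {
    stop("length(times) must equal the number of frames")
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (dim(coords)[2] != nrow(particles)) {
    stop(sprintf("per-frame position count (%d) must equal particle count (%d)",
                 dim(coords)[2], nrow(particles)))
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("trajectory coordinates must be finite (no NaN/Inf)")
  }
  structure(
    list(times = as.numeric(times), coords = coords,
         particles = particles, box = rep_len(as.numeric(box), 3),
         unwrapped = isTRUE(unwrapped)),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d particles, %.4g-%.4g ns, %s\n",
              length(x$times), dim(x$coords)[2], min(x$times), max(x$times),
              if (x$unwrapped) "unwrapped" else "wrapped"))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a trajectory in the columnar text dialect
#'
#' The dialect is deliberately language-agnostic: header lines
#' `# unwrapped true|false` and `# box X Y Z`, then comma-separated rows
#' `frame,time_ns,particle_id,x,y,z` with decimal points and no locale
#' dependence.
#'
#' @param traj A `Trajectory`.
#' @param path Output path.
#' @param digits Significant digits written (default 10; round-trips to
#'   better than 1e-4 Angstrom).
#' @export
write_trajectory <- function(traj, path, digits = 10) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# unwrapped %s", if (traj$unwrapped) "true" else "false"), con)
  writeLines(sprintf("# box %s", paste(format(traj$box, digits = digits), collapse = " ")), con)
  writeLines("frame,time_ns,particle_id,x,y,z", con)
  np <- dim(traj$coords)[2]
  ids <- traj$particles$particle_id
  for (i in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, i)
    rows <- sprintf("%d,%s,%d,%s,%s,%s", i,
                    format(traj$times[i], digits = digits), ids,
                    format(m[, 1], digits = digits),
                    format(m[, 2], digits = digits),
                    format(m[, 3], digits = digits))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory from columnar text or DCD
#'
#' For the columnar text dialect (see [write_trajectory()]) the `unwrapped`
#' flag and box are taken from the header. For DCD files (read via
#' [bio3d::read.dcd()]) the caller must state `unwrapped` explicitly, since
#' the format does not record it.
#'
#' @param path Path to a `.csv`/`.txt` columnar trajectory or a `.dcd` file.
#' @param particles The `ParticleSet` the frames refer to; the per-frame atom
#'   count must match.
#' @param unwrapped Required for DCD input; ignored (header wins) for text.
#' @param times For DCD input, optional frame times in ns (default 1..n ns).
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(path, particles, unwrapped = NULL, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(unwrapped)) {
      stop("DCD input requires an explicit `unwrapped` flag")
    }
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nat <- ncol(xyz) / 3
    if (nat != nrow(particles)) {
      stop(sprintf("atom-count mismatch: expected %d particles, DCD has %d",
                   nrow(particles), nat))
    }
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nf, nat, 3))
    coords[, , 1] <- xyz[, seq(1, 3 * nat, 3)]
    coords[, , 2] <- xyz[, seq(2, 3 * nat, 3)]
    coords[, , 3] <- xyz[, seq(3, 3 * nat, 3)]
    if (is.null(times)) times <- seq_len(nf)
    return(trajectory(times, coords, particles, unwrapped = unwrapped))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  unw <- grepl("true", grep("unwrapped", hdr, value = TRUE)[1], fixed = TRUE)
  box <- c(NA_real_, NA_real_, NA_real_)
  bh <- grep("# box", hdr, value = TRUE)
  if (length(bh)) {
    box <- suppressWarnings(as.numeric(strsplit(trimws(sub("# box", "", bh[1])), "\\s+")[[1]]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- utils::read.csv(textConnection(paste(body, collapse = "\n")))
  need <- c("frame", "time_ns", "particle_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("columnar trajectory must have columns: ", paste(need, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  np <- nrow(particles)
  counts <- table(df$frame)
  if (any(counts != np)) {
    bad <- names(counts)[counts != np][1]
    stop(sprintf("atom-count mismatch in frame %s: expected %d, found %d",
                 bad, np, counts[[bad]]))
  }
  nf <- length(frames)
  coords <- array(NA_real_, c(nf, np, 3))
  times <- numeric(nf)
  ord_id <- match(df$particle_id, particles$particle_id)
  if (anyNA(ord_id)) stop("trajectory refers to particle_ids not in the ParticleSet")
  for (i in seq_len(nf)) {
    sel <- df$frame == frames[i]
    rows <- which(sel)
    times[i] <- df$time_ns[rows[1]]
    coords[i, ord_id[rows], 1] <- df$x[rows]
    coords[i, ord_id[rows], 2] <- df$y[rows]
    coords[i, ord_id[rows], 3] <- df$z[rows]
  }
  trajectory(times, coords, particles, box = box, unwrapped = unw)
}

#' Shell geometry: center, radii, pores, surface area
#'
#' @param center Length-3 center (Angstrom).
#' @param R_mid Mid-surface radius (Angstrom).
#' @param delta Hysteresis half-width: `R_in = R_mid - delta`,
#'   `R_out = R_mid + delta` (default 10 Angstrom; must be positive).
#' @param pores Optional list of pores, each `list(axis = unit vector,
#'   radius = Angstrom)`.
#' @return An object of class `ShellGeometry` with fields `center`, `R_mid`,
#'   `R_in`, `R_out`, `pores` and surface area `A = 4*pi*R_mid^2` (Angstrom^2).
#' @export
shell_geometry <- function(center, R_mid, delta = 10, pores = list()) {
  stopifnot(length(center) == 3, R_mid > 0)
  if (delta <= 0) stop("hysteresis half-width `delta` must be positive")
  if (delta >= R_mid) stop("`delta` must be smaller than R_mid")
  structure(
    list(center = as.numeric(center), R_mid = R_mid,
         R_in = R_mid - delta, R_out = R_mid + delta,
         pores = pores, A = 4 * pi * R_mid^2),
    class = "ShellGeometry"
  )
}

#' @export
print.ShellGeometry <- function(x, ...) {
  cat(sprintf("ShellGeometry: R_mid=%.2f A (R_in=%.2f, R_out=%.2f), A=%.4g A^2, %d pores\n",
              x$R_mid, x$R_in, x$R_out, x$A, length(x$pores)))
  invisible(x)
}

#' Fit a spherical shell geometry to shell particles
#'
#' The center is the centroid of the selected shell particles and `R_mid`
#' their mean radial distance; the hysteresis radii are `R_mid` minus/plus
#' `delta` and the surface area is that of the mid-surface sphere. The
#' underlying simulations never state how shell radius or area were obtained,
#' so this estimator is the package's documented choice; see the methods
#' vignette.
#'
#' @param traj A `Trajectory` or `ParticleSet`.
#' @param shell_selection Logical or integer index into the particles
#'   selecting shell particles; default `role == "shell"`.
#' @param delta Hysteresis half-width in Angstrom (default 10, must be > 0).
#' @param frame Frame index used when `traj` is a `Trajectory` (default 1).
#' @return A `ShellGeometry`.
#' @export
fit_shell_geometry <- function(traj, shell_selection = NULL, delta = 10, frame = 1) {
  if (inherits(traj, "Trajectory")) {
    ps <- traj$particles
    m <- frame_coords(traj, frame)
  } else {
    ps <- traj
    m <- coords_matrix(ps)
  }
  if (is.null(shell_selection)) shell_selection <- ps$role == "shell"
  m <- m[shell_selection, , drop = FALSE]
  if (nrow(m) < 10) stop("need at least 10 shell particles to fit a shell geometry")
  ctr <- colMeans(m)
  r <- sqrt(rowSums(sweep(m, 2, ctr)^2))
  shell_geometry(ctr, mean(r), delta = delta)
}
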