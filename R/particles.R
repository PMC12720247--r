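#' Construct a labeled particle set
#'
#' A `ParticleSet` is the package's structural data model: one row per
#' particle, carrying a unique integer id, a chemical species label, a
#' functional role, an optional multimer grouping (`complex_id`), an
#' alpha-carbon flag, and Cartesian coordinates in Angstrom.
#'
#' @param particle_id Integer vector of unique ids.
#' @param species Character vector: one of `"water"`, `"G3P"`, `"DHAP"`,
#'   `"ion"`, `"pseudo"` (free-form labels are allowed but these are the
#'   conventional ones).
#' @param role Character vector: `"shell"`, `"cargo"`, `"solvent"` or
#'   `"metabolite"`.
#' @param x,y,z Numeric coordinate vectors (Angstrom), all finite.
#' @param complex_id Integer vector grouping multimer members; `NA` for
#'   particles that belong to no complex. Every `role == "cargo"` particle
#'   must carry one.
#' @param is_calpha Logical vector flagging alpha-carbon sites.
#' @return A `data.frame` of class `ParticleSet`.
#' @export
particle_set <- function(particle_id, species, role, x, y, z,
                         complex_id = NA_integer_, is_calpha = FALSE) {
  n <- length(particle_id)
  ps <- data.frame(
    particle_id = as.integer(particle_id),
    species     = as.character(species),
    role        = as.character(role),
    complex_id  = rep_len(as.integer(complex_id), n),
    is_calpha   = rep_len(as.logical(is_calpha), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  class(ps) <- c("ParticleSet", "data.frame")
  validate_particle_set(ps)
  ps
}

validate_particle_set <- function(ps) {
  if (anyDuplicated(ps$particle_id)) stop("particle_id values must be unique")
  if (!all(is.finite(ps$x) & is.finite(ps$y) & is.finite(ps$z))) {
    stop("particle coordinates must be finite (no NaN/Inf)")
  }
  cargo <- ps$role == "cargo"
  if (any(cargo & is.na(ps$complex_id))) {
    stop("every cargo particle must carry a complex_id")
  }
  invisible(ps)
}

#' @export
print.ParticleSet <- function(x, ...) {
  cat(sprintf("ParticleSet: %d particles (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  invisible(x)
}

#' Coordinates of a ParticleSet as an n x 3 matrix
#' @param ps A `ParticleSet`.
#' @return Numeric matrix with columns `x`, `y`, `z` (Angstrom).
#' @export
coords_matrix <- function(ps) {
  m <- cbind(ps$x, ps$y, ps$z)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Read a PDB structure into a ParticleSet
#'
#' Parses a PDB v3.3 file with [bio3d::read.pdb()] and assigns roles from a
#' user-supplied selection map keyed by chain (or segment) identifier.
#' Chains absent from the map default to `role = "shell"` with a warning.
#' Water residues (HOH/TIP3/WAT/SOL) become `species = "water"`,
#' `role = "solvent"`; common ions become `species = "ion"`; G3P/DHAP residue
#' names map to metabolites; everything else is `species = "pseudo"`.
#'
#' @param path Path to a PDB file.
#' @param role_map Named character vector mapping chain id to role, e.g.
#'   `c(A = "shell", B = "cargo")`. May be `NULL` (everything defaults to
#'   shell, with a warning if there are non-water chains).
#' @param complex_by Grouping used to assign `complex_id` to cargo particles:
#'   `"chain"` (default) makes each cargo chain one complex.
#' @return A `ParticleSet`.
#' @export
read_structure <- function(path, role_map = NULL, complex_by = "chain") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_idx) == 0) stop("no ATOM/HETATM records in ", path)
  # pre-validate coordinate columns so we can report the offending line number
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM record at line %d: record too short", i))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      stop(sprintf("malformed ATOM record at line %d: non-numeric coordinates", i))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | at$chain == "", "_", at$chain)

  water_res <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC")
  ion_res   <- c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "CA2", "CAL")
  species <- rep("pseudo", nrow(at))
  species[at$resid %in% water_res] <- "water"
  species[at$resid %in% ion_res]   <- "ion"
  species[at$resid == "G3P"]  <- "G3P"
  species[at$resid == "DHA" | at$resid == "DHAP"] <- "DHAP"

  role <- rep(NA_character_, nrow(at))
  if (!is.null(role_map)) {
    mapped <- chain %in% names(role_map)
    role[mapped] <- unname(role_map[chain[mapped]])
  }
  role[is.na(role) & species == "water"] <- "solvent"
  role[is.na(role) & species %in% c("G3P", "DHAP")] <- "metabolite"
  if (any(is.na(role))) {
    unmapped <- unique(chain[is.na(role)])
    warning("chains not in role_map default to role 'shell': ",
            paste(unmapped, collapse = ", "))
    role[is.na(role)] <- "shell"
  }

  complex_id <- rep(NA_integer_, nrow(at))
  cargo <- role == "cargo"
  if (any(cargo) && identical(complex_by, "chain")) {
    complex_id[cargo] <- as.integer(factor(chain[cargo]))
  }

  particle_set(
    particle_id = seq_len(nrow(at)),
    species = species, role = role,
    x = at$x, y = at$y, z = at$z,
    complex_id = complex_id,
    is_calpha = at$elety == "CA" & !(at$resid %in% c(water_res, ion_res))
  )
}

#' Write a ParticleSet as a PDB file
#'
#' Round-trips through [bio3d::write.pdb()]; coordinates are preserved to the
#' PDB fixed-format precision (0.001 Angstrom). Roles are encoded in the chain
#' column (shell = A, cargo = B, solvent = W, metabolite = M) so that
#' [read_structure()] with the matching `role_map` recovers them.
#'
#' @param ps A `ParticleSet`.
#' @param path Output path.
#' @return Invisibly, the role-to-chain map used.
#' @export
write_structure <- function(ps, path) {
  validate_particle_set(ps)
  chain_of <- c(shell = "A", cargo = "B", solvent = "W", metabolite = "M")
  chain <- unname(chain_of[ps$role])
  chain[is.na(chain)] <- "X"
  resid <- ifelse(ps$species == "water", "HOH",
           ifelse(ps$species == "ion", "NA",
           ifelse(ps$species %in% c("G3P", "DHAP"), substr(ps$species, 1, 3), "GLY")))
  elety <- ifelse(ps$is_calpha, "CA", ifelse(ps$species == "water", "OH2", "C"))
  xyz <- as.numeric(t(coords_matrix(ps)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(ps)),
    resno = seq_len(nrow(ps)) %% 9999 + 1,
    resid = resid, elety = elety, chain = chain
  )
  invisible(chain_of)
}
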