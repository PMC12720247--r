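# Contact scoring and protein interaction networks. The contact score is a
# differentiable coordination number: each heavy-atom cross pair contributes
# 1 / (1 + exp(5*(d_ij - 4 A))). Pairs beyond 12 A are skipped via a spatial
# cell grid; their contribution (< 4e-18) is below any tolerance used here.

# cell-list search: all cross pairs (a in A, b in B) with d <= cutoff.
# B = NULL searches within A (unordered pairs, i < j).
pairs_within <- function(A, B = NULL, cutoff) {
  self <- is.null(B)
  if (self) B <- A
  na <- nrow(A); nb <- nrow(B)
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (na == 0 || nb == 0) return(empty)
  cs <- cutoff
  keyb <- floor(B / cs)
  bkey <- paste(keyb[, 1], keyb[, 2], keyb[, 3])
  bmap <- split(seq_len(nb), bkey)
  keya <- floor(A / cs)
  out_i <- vector("list", na)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  akey <- paste(keya[, 1], keya[, 2], keya[, 3])
  acells <- split(seq_len(na), akey)
  res <- vector("list", length(acells))
  ci <- 0L
  for (key in names(acells)) {
    ia <- acells[[key]]
    base <- keya[ia[1], ]
    cand <- unlist(bmap[paste(base[1] + shifts[, 1], base[2] + shifts[, 2],
                              base[3] + shifts[, 3])], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    # distances |A[ia,] - B[cand,]| pairwise
    d2 <- outer(rowSums(A[ia, , drop = FALSE]^2),
                rowSums(B[cand, , drop = FALSE]^2), `+`) -
      2 * A[ia, , drop = FALSE] %*% t(B[cand, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    ci <- ci + 1L
    res[[ci]] <- data.frame(i = ia[hit[, 1]], j = cand[hit[, 2]],
                            d = sqrt(pmax(d2[hit], 0)))
  }
  if (ci == 0L) return(empty)
  out <- do.call(rbind, res[seq_len(ci)])
  if (self) out <- out[out$i < out$j, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# logistic contact kernel
contact_kernel <- function(d, d0 = 4, steep = 5) 1 / (1 + exp(steep * (d - d0)))

#' Differentiable coordination-number contact score
#'
#' Sums `1 / (1 + exp(5*(d_ij - 4)))` over all cross pairs between two
#' disjoint heavy-atom selections. Pairs beyond `cutoff` (default 12 A,
#' where the kernel is below 4e-18) are skipped via a spatial grid; a
#' brute-force mode is provided for verification.
#'
#' @param coords_a,coords_b Coordinate matrices (n x 3, A) of the two groups.
#' @param cutoff Skip distance (A), default 12.
#' @param method `"grid"` (cell list, default) or `"brute"` (all pairs).
#' @return An object of class `ContactScore`: `value`, `n_pairs` (pairs
#'   within cutoff), `n_a`, `n_b`.
#' @examples
#' coordination_contacts(matrix(0, 1, 3), matrix(c(4, 0, 0), 1, 3))$value # 0.5
#' @export
coordination_contacts <- function(coords_a, coords_b, cutoff = 12,
                                  method = c("grid", "brute")) {
  method <- match.arg(method)
  coords_a <- as_coord_matrix(coords_a)
  coords_b <- as_coord_matrix(coords_b)
  if (method == "grid") {
    pr <- pairs_within(coords_a, coords_b, cutoff)
    val <- sum(contact_kernel(pr$d))
    npair <- nrow(pr)
  } else {
    d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), `+`) -
      2 * coords_a %*% t(coords_b)
    d <- sqrt(pmax(d2, 0))
    val <- sum(contact_kernel(d[d <= cutoff]))
    npair <- sum(d <= cutoff)
  }
  structure(list(value = val, n_pairs = npair,
                 n_a = nrow(coords_a), n_b = nrow(coords_b)),
            class = "ContactScore")
}

as_coord_matrix <- function(x) {
  if (inherits(x, "ParticleSet")) return(coords_matrix(x))
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3)
  m
}

#' Complex-level contact graph over a trajectory
#'
#' Two complexes are in contact in a frame when any alpha-carbon cross pair
#' is closer than `cutoff` (default 10 A). Edges carry two weights:
#' `weight`, the fraction of frames in contact, and `mean_min_dist`, the
#' mean over contact frames of the minimum cross distance; consumers choose
#' which to use. Intra-complex pairs are excluded.
#'
#' @param traj A `Trajectory` whose cargo particles carry `complex_id`.
#' @param calpha_only Restrict to `is_calpha` sites (default `TRUE`).
#' @param cutoff Contact distance (A), default 10.
#' @return An object of class `ContactGraph`: `nodes` (complex_id, species),
#'   `edges` (a, b, weight, mean_min_dist, n_frames_contact), `frame_count`,
#'   and `graph` (an igraph object).
#' @export
contact_graph <- function(traj, calpha_only = TRUE, cutoff = 10) {
  ps <- traj$particles
  sel <- !is.na(ps$complex_id)
  if (calpha_only) sel <- sel & ps$is_calpha
  if (!any(sel)) stop("no complex-labeled (C-alpha) particles in trajectory")
  idx <- which(sel)
  cid <- ps$complex_id[idx]
  complexes <- sort(unique(cid))
  nf <- n_frames(traj)
  acc <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)[idx, , drop = FALSE]
    pr <- pairs_within(m, NULL, cutoff)
    if (!nrow(pr)) next
    ca <- cid[pr$i]; cb <- cid[pr$j]
    cross <- ca != cb
    if (!any(cross)) next
    a <- pmin(ca[cross], cb[cross]); b <- pmax(ca[cross], cb[cross])
    dmin <- tapply(pr$d[cross], paste(a, b), min)
    for (key in names(dmin)) {
      cur <- get0(key, envir = acc, ifnotfound = c(0, 0))
      assign(key, c(cur[1] + 1, cur[2] + dmin[[key]]), envir = acc)
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    ab <- do.call(rbind, strsplit(keys, " "))
    vals <- t(vapply(keys, get, numeric(2), envir = acc))
    edges <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                        weight = vals[, 1] / nf,
                        mean_min_dist = vals[, 2] / vals[, 1],
                        n_frames_contact = as.integer(vals[, 1]))
    edges <- edges[order(edges$a, edges$b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = integer(), b = integer(), weight = numeric(),
                        mean_min_dist = numeric(), n_frames_contact = integer())
  }
  species <- vapply(complexes, function(ci) {
    as.character(ps$species[sel & ps$complex_id == ci][1])
  }, character(1))
  nodes <- data.frame(complex_id = complexes, species = species)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = as.character(edges$a),
                                to = as.character(edges$b),
                                weight = edges$weight,
                                mean_min_dist = edges$mean_min_dist)
    else data.frame(from = character(), to = character(),
                    weight = numeric(), mean_min_dist = numeric()),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$complex_id),
                          species = nodes$species)
  )
  structure(list(nodes = nodes, edges = edges, frame_count = nf, graph = g),
            class = "ContactGraph")
}

#' @export
print.ContactGraph <- function(x, ...) {
  cat(sprintf("ContactGraph: %d complexes, %d edges over %d frames\n",
              nrow(x$nodes), nrow(x$edges), x$frame_count))
  invisible(x)
}

#' Nearest-neighbor distances between complexes
#'
#' The distance between two complexes is the minimum Euclidean distance over
#' any atom pair between them. For each complex the `k` smallest distances
#' are reported in ascending order, together with the per-rank mean across
#' complexes and (because "the average of the first k neighbors" is
#' ambiguous) the grand mean over all k ranks.
#'
#' @param frame A `ParticleSet`, or a `Trajectory` plus `frame` index.
#' @param k Number of neighbors (must be < number of complexes).
#' @param frame_index Frame used when `frame` is a `Trajectory`.
#' @return A list of class `NearestNeighbors`: `distances` (n_complexes x k,
#'   ascending per row), `rank_means` (length k), `grand_mean`,
#'   `complex_ids`.
#' @export
nearest_neighbors <- function(frame, k, frame_index = 1) {
  if (inherits(frame, "Trajectory")) {
    ps <- frame$particles
    m <- frame_coords(frame, frame_index)
  } else {
    ps <- frame
    m <- coords_matrix(ps)
  }
  sel <- !is.na(ps$complex_id)
  if (!any(sel)) stop("no complex-labeled particles")
  cid <- ps$complex_id[sel]
  m <- m[sel, , drop = FALSE]
  complexes <- sort(unique(cid))
  n <- length(complexes)
  if (k >= n) stop(sprintf("k = %d but only %d complexes (need k < n)", k, n))
  # complex-pair minimum distances from the full atom distance matrix
  d2 <- outer(rowSums(m^2), rowSums(m^2), `+`) - 2 * m %*% t(m)
  d <- sqrt(pmax(d2, 0))
  dmin <- matrix(Inf, n, n)
  ci <- match(cid, complexes)
  for (a in seq_len(n - 1)) {
    ra <- ci == a
    for (b in (a + 1):n) {
      rb <- ci == b
      dmin[a, b] <- dmin[b, a] <- min(d[ra, rb])
    }
  }
  nn <- vapply(seq_len(n), function(a) {
    sort(dmin[a, ][is.finite(dmin[a, ])])[seq_len(k)]
  }, numeric(k))
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  structure(
    list(distances = nn, rank_means = colMeans(nn), grand_mean = mean(nn),
         complex_ids = complexes),
    class = "NearestNeighbors"
  )
}

#' Shell/cargo and cargo/cargo contact time series
#'
#' Per frame, the coordination-number score between shell and cargo heavy
#' atoms, and among cargo heavy atoms with intra-complex pairs excluded.
#'
#' @param traj A `Trajectory` with `role` labels assigned.
#' @param cutoff Grid skip distance (A), default 12.
#' @return Data.frame: `time_ns`, `shell_cargo`, `cargo_cargo`.
#' @export
shell_cargo_contact_series <- function(traj, cutoff = 12) {
  ps <- traj$particles
  heavy <- if ("is_hydrogen" %in% names(ps)) !ps$is_hydrogen else rep(TRUE, nrow(ps))
  ish <- which(ps$role == "shell" & heavy)
  isc <- which(ps$role == "cargo" & heavy)
  cid <- ps$complex_id[isc]
  nf <- n_frames(traj)
  sc <- cc <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    sc[f] <- if (length(ish) && length(isc)) {
      coordination_contacts(m[ish, , drop = FALSE], m[isc, , drop = FALSE],
                            cutoff = cutoff)$value
    } else 0
    if (length(isc) > 1) {
      pr <- pairs_within(m[isc, , drop = FALSE], NULL, cutoff)
      if (nrow(pr)) {
        cross <- cid[pr$i] != cid[pr$j]
        cc[f] <- sum(contact_kernel(pr$d[cross]))
      }
    }
  }
  data.frame(time_ns = traj$times, shell_cargo = sc, cargo_cargo = cc)
}

#' Export a contact graph as GEXF and GraphML
#'
#' Writes `<path>.graphml` (via igraph) and `<path>.gexf` (GEXF 1.2 with
#' node `species` and edge `weight`/`mean_min_dist` attributes). Both
#' round-trip losslessly through [read_contact_graph()].
#'
#' @param graph A `ContactGraph`.
#' @param path Output path; any `.gexf`/`.graphml` extension is stripped and
#'   both files are written.
#' @return Invisibly, the two file paths.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "ContactGraph"))
  base <- sub("\\.(gexf|graphml)$", "", path)
  gml <- paste0(base, ".graphml")
  gexf <- paste0(base, ".gexf")
  igraph::write_graph(graph$graph, gml, format = "graphml")

  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natt <- xml2::xml_add_child(gr, "attributes", class = "node")
  xml2::xml_add_child(natt, "attribute", id = "0", title = "species",
                      type = "string")
  eatt <- xml2::xml_add_child(gr, "attributes", class = "edge")
  xml2::xml_add_child(eatt, "attribute", id = "0", title = "mean_min_dist",
                      type = "double")
  nodes <- xml2::xml_add_child(gr, "nodes")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = as.character(graph$nodes$complex_id[i]),
                              label = as.character(graph$nodes$complex_id[i]))
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = graph$nodes$species[i])
  }
  edges <- xml2::xml_add_child(gr, "edges")
  for (i in seq_len(nrow(graph$edges))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                              source = as.character(graph$edges$a[i]),
                              target = as.character(graph$edges$b[i]),
                              weight = format(graph$edges$weight[i], digits = 12))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = format(graph$edges$mean_min_dist[i], digits = 12))
  }
  xml2::write_xml(doc, gexf)
  invisible(c(graphml = gml, gexf = gexf))
}

#' Read a contact graph written by [export_graph()]
#'
#' @param path A `.graphml` or `.gexf` file.
#' @return A list with `nodes` (complex_id, species) and `edges`
#'   (a, b, weight, mean_min_dist).
#' @export
read_contact_graph <- function(path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vs <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(complex_id = as.integer(vs$name), species = vs$species)
    edges <- if (nrow(el)) {
      data.frame(a = pmin(as.integer(el$from), as.integer(el$to)),
                 b = pmax(as.integer(el$from), as.integer(el$to)),
                 weight = el$weight, mean_min_dist = el$mean_min_dist)
    } else {
      data.frame(a = integer(), b = integer(), weight = numeric(),
                 mean_min_dist = numeric())
    }
    return(list(nodes = nodes[order(nodes$complex_id), ],
                edges = edges[order(edges$a, edges$b), ]))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nd <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- data.frame(
    complex_id = as.integer(xml2::xml_attr(nd, "id")),
    species = xml2::xml_attr(xml2::xml_find_first(nd, ".//attvalue"), "value")
  )
  ed <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- data.frame(
    a = as.integer(xml2::xml_attr(ed, "source")),
    b = as.integer(xml2::xml_attr(ed, "target")),
    weight = as.numeric(xml2::xml_attr(ed, "weight")),
    mean_min_dist = as.numeric(
      xml2::xml_attr(xml2::xml_find_first(ed, ".//attvalue"), "value"))
  )
  if (!nrow(edges)) {
    edges <- data.frame(a = integer(), b = integer(), weight = numeric(),
                        mean_min_dist = numeric())
  }
  list(nodes = nodes[order(nodes$complex_id), , drop = FALSE],
       edges = edges[order(edges$a, edges$b), , drop = FALSE])
}
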