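# Weighted residue neighbourhoods under four environment definitions:
# Voronoi tessellation, Euclidean sphere, sequence sliding window, none.

#' Environment configuration
#'
#' @param mode `"voronoi"` (facet contacts from the heavy-atom Voronoi
#'   diagram, the default), `"sphere"` (Euclidean distance cutoff),
#'   `"window"` (sequence sliding window) or `"none"`.
#' @param sphere_radius Sphere cutoff in Angstrom (default 15).
#' @param window_length Odd window length (default 9).
#' @param facet_distance_filter Optional distance (Angstrom); Voronoi
#'   atom-pair facets further apart than this are discarded, guarding
#'   against contacts across surface clefts.  Default `NULL` (off).
#' @param exposed_only Restrict nodes/edges to exposed residues; applies to
#'   the Voronoi and sphere modes only (the window mode deliberately keeps
#'   buried residues).  Default `TRUE`.
#' @param representative Sphere-mode residue representative point:
#'   `"centroid"` of heavy atoms (default) or `"ca"`.
#' @return An `env_config` list.
#' @export
env_config <- function(mode = c("voronoi", "sphere", "window", "none"),
                       sphere_radius = 15, window_length = 9,
                       facet_distance_filter = NULL, exposed_only = TRUE,
                       representative = c("centroid", "ca")) {
  mode <- match.arg(mode)
  representative <- match.arg(representative)
  if (sphere_radius <= 0) stop("sphere_radius must be positive")
  if (window_length < 1 || window_length %% 2 == 0) {
    stop("window_length must be a positive odd integer")
  }
  structure(list(mode = mode, sphere_radius = sphere_radius,
                 window_length = window_length,
                 facet_distance_filter = facet_distance_filter,
                 exposed_only = exposed_only,
                 representative = representative),
            class = "env_config")
}

#' Delaunay adjacency of a 3-D point set
#'
#' Edge list of the Delaunay triangulation (equivalently: pairs of sites
#' whose Voronoi cells share a facet).  An optional deterministic joggle
#' (a fixed quasi-random perturbation of magnitude `joggle`) makes
#' degenerate inputs such as lattices tractable, in the spirit of Qhull's
#' joggle option.
#'
#' @param coords Numeric matrix, one row per point (x, y, z).
#' @param joggle Perturbation magnitude in input units; 0 disables.
#' @return Two-column integer matrix of 1-based point index pairs (i < j).
#' @export
delaunay_edges <- function(coords, joggle = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have three columns")
  if (nrow(coords) < 5) stop("need at least 5 points for a 3-D tessellation")
  if (anyDuplicated(round(coords, 9))) stop("duplicate points in input")
  if (joggle > 0) coords <- joggle_points(coords, joggle)
  tryCatch(.delaunay_edges_cpp(coords),
           error = function(e) stop("tessellation failed (",
                                    conditionMessage(e),
                                    "); consider joggle > 0"))
}

# deterministic quasi-random (Weyl sequence) perturbation
joggle_points <- function(coords, eps) {
  n <- nrow(coords)
  k <- seq_len(n)
  coords + eps * (cbind((k * sqrt(2)) %% 1, (k * sqrt(3)) %% 1,
                        (k * sqrt(5)) %% 1) - 0.5)
}

# evenly distributed points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(center[1] + radius * r * cos(phi),
        center[2] + radius * r * sin(phi),
        center[3] + radius * z)
}

new_contact_graph <- function(pairs, nodes, mode, params) {
  # pairs: data.frame(i, j, n) undirected with i != j
  if (nrow(pairs) > 0) {
    dir <- data.frame(i = c(pairs$i, pairs$j), j = c(pairs$j, pairs$i),
                      n_ij = c(pairs$n, pairs$n))
    dir <- dir[dir$i %in% nodes & dir$j %in% nodes, , drop = FALSE]
  } else {
    dir <- data.frame(i = integer(0), j = integer(0), n_ij = numeric(0))
  }
  totals <- numeric(0)
  if (nrow(dir) > 0) {
    tot <- rowsum(dir$n_ij, dir$i)
    totals <- structure(tot[, 1], names = rownames(tot))
    dir$c_ij <- dir$n_ij / totals[as.character(dir$i)]
    dir <- dir[order(dir$i, dir$j), , drop = FALSE]
    rownames(dir) <- NULL
  } else {
    dir$c_ij <- numeric(0)
  }
  structure(list(nodes = sort(nodes), edges = dir, totals = totals,
                 mode = mode, params = params),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> mode=", x$mode, ", ", length(x$nodes), " nodes, ",
      nrow(x$edges) / 2, " contacts\n", sep = "")
  invisible(x)
}

#' Neighbours of a residue in a contact graph
#' @param graph A `contact_graph`.
#' @param residue Residue index (`res_index`).
#' @return Data frame with columns `j`, `n_ij`, `c_ij`.
#' @export
graph_neighbours <- function(graph, residue) {
  e <- graph$edges[graph$edges$i == residue, c("j", "n_ij", "c_ij"),
                   drop = FALSE]
  rownames(e) <- NULL
  e
}

exposed_nodes <- function(structure) {
  if (all(is.na(structure$residues$exposed))) {
    stop("exposure not computed; run compute_rsasa() first")
  }
  structure$residues$res_index[structure$residues$exposed %in% TRUE]
}

#' Voronoi-diagram residue contact graph
#'
#' Tessellates all heavy-atom centres (surrounded by a pseudo-solvent shell
#' that bounds surface cells; shell facets are discarded).  Residues i and j
#' are in contact when at least one pair of heavy atoms, one from each,
#' share a Voronoi facet; `N_ij` counts such atom pairs, `N_i = sum_j N_ij`,
#' and the contact strength is `c_ij = N_ij / N_i` (an asymmetric
#' normalisation of a symmetric count).
#'
#' @param structure A `vs_structure` (with accessibility computed when
#'   `exposed_only`).
#' @param config An [env_config()]; `facet_distance_filter` and
#'   `exposed_only` are honoured, distance/window parameters are ignored.
#' @return A `contact_graph`.
#' @export
voronoi_neighbours <- function(structure, config = env_config("voronoi")) {
  a <- structure$atoms[structure$atoms$heavy, , drop = FALSE]
  if (nrow(a) < 2) stop("need at least 2 heavy atoms for a contact graph in ",
                        structure$structure_id)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  rmax <- sqrt(max(rowSums((xyz - rep(ctr, each = nrow(xyz)))^2)))
  shell <- fibonacci_sphere(256, radius = rmax + 10, center = ctr)
  ed <- tryCatch(
    delaunay_edges(rbind(xyz, shell), joggle = 1e-4),
    error = function(e) stop("Voronoi tessellation failed for structure ",
                             structure$structure_id, ": ",
                             conditionMessage(e))
  )
  ed <- ed[ed[, 1] <= nrow(a) & ed[, 2] <= nrow(a), , drop = FALSE]
  if (!is.null(config$facet_distance_filter)) {
    d <- sqrt(rowSums((xyz[ed[, 1], , drop = FALSE] -
                       xyz[ed[, 2], , drop = FALSE])^2))
    ed <- ed[d <= config$facet_distance_filter, , drop = FALSE]
  }
  ri <- a$res_index[ed[, 1]]
  rj <- a$res_index[ed[, 2]]
  keep <- ri != rj
  ri <- ri[keep]; rj <- rj[keep]
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  cnt <- table(paste(lo, hi))
  if (length(cnt) > 0) {
    ij <- do.call(rbind, strsplit(names(cnt), " "))
    pairs <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                        n = as.numeric(cnt))
  } else {
    pairs <- data.frame(i = integer(0), j = integer(0), n = numeric(0))
  }
  nodes <- if (isTRUE(config$exposed_only)) exposed_nodes(structure)
           else structure$residues$res_index
  new_contact_graph(pairs, nodes, "voronoi",
                    list(facet_distance_filter = config$facet_distance_filter,
                         exposed_only = isTRUE(config$exposed_only)))
}

#' Euclidean-sphere residue neighbourhood
#'
#' Residue j neighbours i when their representative points lie within
#' `radius`.  Contacts are unweighted (`N_ij = 1`), so strengths are uniform
#' over the realised neighbour set.
#'
#' @inheritParams voronoi_neighbours
#' @param radius Cutoff in Angstrom.
#' @param exposed_only Restrict to exposed residues (default `TRUE`).
#' @param representative `"centroid"` of heavy atoms or `"ca"`.
#' @return A `contact_graph`.
#' @export
sphere_neighbours <- function(structure, radius = 15, exposed_only = TRUE,
                              representative = c("centroid", "ca")) {
  representative <- match.arg(representative)
  if (radius <= 0) stop("radius must be positive")
  rp <- residue_points(structure, representative)
  nodes <- if (exposed_only) exposed_nodes(structure)
           else structure$residues$res_index
  rp <- rp[rp$res_index %in% nodes, , drop = FALSE]
  xyz <- as.matrix(rp[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  w <- which(d2 <= radius^2 & upper.tri(d2), arr.ind = TRUE)
  pairs <- data.frame(i = rp$res_index[w[, 1]], j = rp$res_index[w[, 2]],
                      n = rep(1, nrow(w)))
  new_contact_graph(pairs, nodes, "sphere",
                    list(radius = radius, representative = representative,
                         exposed_only = exposed_only))
}

residue_points <- function(structure, representative) {
  a <- structure$atoms[structure$atoms$heavy, , drop = FALSE]
  if (representative == "ca") {
    ca <- a[a$name == "CA", , drop = FALSE]
    miss <- setdiff(unique(a$res_index), ca$res_index)
    a <- rbind(ca, a[a$res_index %in% miss, , drop = FALSE])
  }
  x <- rowsum(as.matrix(a[, c("x", "y", "z")]), a$res_index)
  n <- as.vector(table(a$res_index)[rownames(x)])
  data.frame(res_index = as.integer(rownames(x)), x = x[, 1] / n,
             y = x[, 2] / n, z = x[, 3] / n)
}

#' Sequence sliding-window neighbourhood
#'
#' Neighbours of a residue are the `window_length - 1` sequence-adjacent
#' residues of the same chain (truncated at termini), regardless of burial;
#' strengths are uniform over the realised window.
#'
#' @inheritParams voronoi_neighbours
#' @param window_length Odd window length (9 gives 4 residues either side).
#' @return A `contact_graph` over all residues.
#' @export
window_neighbours <- function(structure, window_length = 9) {
  if (window_length < 1 || window_length %% 2 == 0) {
    stop("window_length must be a positive odd integer")
  }
  h <- (window_length - 1) / 2
  res <- structure$residues
  pairs <- NULL
  if (h > 0) {
    by_chain <- split(res$res_index, res$chain)
    pl <- lapply(by_chain, function(idx) {
      n <- length(idx)
      if (n < 2) return(NULL)
      do.call(rbind, lapply(seq_len(min(h, n - 1)), function(d) {
        cbind(idx[seq_len(n - d)], idx[seq_len(n - d) + d])
      }))
    })
    pm <- do.call(rbind, pl)
    if (!is.null(pm) && nrow(pm) > 0) {
      pairs <- data.frame(i = pm[, 1], j = pm[, 2], n = 1)
    }
  }
  if (is.null(pairs)) pairs <- data.frame(i = integer(0), j = integer(0),
                                          n = numeric(0))
  new_contact_graph(pairs, res$res_index, "window",
                    list(window_length = window_length))
}

#' Build the residue environment graph for a configuration
#'
#' Dispatches to [voronoi_neighbours()], [sphere_neighbours()],
#' [window_neighbours()] or an edgeless graph for mode `"none"`.
#'
#' @param structure A `vs_structure`.
#' @param config An [env_config()].
#' @return A `contact_graph`.
#' @export
env_graph <- function(structure, config = env_config()) {
  stopifnot(inherits(config, "env_config"))
  switch(config$mode,
    voronoi = voronoi_neighbours(structure, config),
    sphere = sphere_neighbours(structure, config$sphere_radius,
                               isTRUE(config$exposed_only),
                               config$representative),
    window = window_neighbours(structure, config$window_length),
    none = {
      nodes <- if (isTRUE(config$exposed_only)) exposed_nodes(structure)
               else structure$residues$res_index
      new_contact_graph(data.frame(i = integer(0), j = integer(0),
                                   n = numeric(0)),
                        nodes, "none", list())
    }
  )
}

#' Write a contact graph as a three-column edge list
#'
#' Tab-separated `res_i`, `res_j`, `c_ij` using `chain:resno:icode` keys.
#' @param graph A `contact_graph`.
#' @param structure The `vs_structure` it was built from.
#' @param file Output path.
#' @export
write_edge_list <- function(graph, structure, file) {
  e <- graph$edges
  out <- data.frame(res_i = residue_keys(structure, e$i),
                    res_j = residue_keys(structure, e$j),
                    c_ij = e$c_ij)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
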