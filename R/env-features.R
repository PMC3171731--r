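# Environment descriptors built on a contact graph: the contact-strength
# weighted neighbour feature average (EF), the contact description vector
# (CDV, contact strength summed by neighbour residue type) and the
# environment description matrix (EDM, normalised contacts among the
# neighbours themselves, excluding the central residue).

#' Environment feature vectors (EF)
#'
#' For every graph node i with neighbours j, `ef_ik = sum_j c_ij * f_jk`
#' for each feature k: the contact-strength weighted (convex) combination of
#' the neighbours' features.
#'
#' @param fv Feature matrix from [residue_features()] (rows named by
#'   `res_index`; must cover every neighbour in the graph).
#' @param graph A `contact_graph`.
#' @return Numeric matrix with one row per graph node (rows named by
#'   `res_index`), columns `ef_<feature>`, and attribute `isolated`: logical
#'   flag per node marking empty neighbourhoods (their EF rows are `NA`).
#' @export
environment_features <- function(fv, graph) {
  nodes <- graph$nodes
  e <- graph$edges
  out <- matrix(NA_real_, length(nodes), ncol(fv),
                dimnames = list(nodes, paste0("ef_", colnames(fv))))
  isolated <- !(nodes %in% e$i)
  if (nrow(e) > 0) {
    jr <- match(as.character(e$j), rownames(fv))
    if (anyNA(jr)) {
      stop("neighbour residue(s) lack feature vectors: ",
           paste(utils::head(unique(e$j[is.na(jr)]), 5), collapse = ", "))
    }
    if (anyNA(fv[unique(jr), , drop = FALSE])) {
      stop("neighbour feature vectors contain missing values")
    }
    wf <- fv[jr, , drop = FALSE] * e$c_ij
    agg <- rowsum(wf, e$i)
    out[match(rownames(agg), rownames(out)), ] <- agg
  }
  attr(out, "isolated") <- structure(isolated, names = nodes)
  out
}

#' Contact description vectors (CDV)
#'
#' 20-vector per node: component l sums the contact strengths `c_ij` of
#' neighbours of residue type l, so components add to 1 for any node with
#' neighbours.  Neighbour-less nodes get a zero vector (flagged).
#'
#' @param graph A `contact_graph`.
#' @param structure The `vs_structure` providing residue types.
#' @return Numeric matrix (nodes x 20), columns `cdv_<AA>`, with an
#'   `isolated` attribute as in [environment_features()].
#' @export
contact_description_vector <- function(graph, structure) {
  nodes <- graph$nodes
  e <- graph$edges
  out <- matrix(0, length(nodes), 20,
                dimnames = list(nodes, paste0("cdv_", AA3)))
  if (nrow(e) > 0) {
    ty <- structure$residues$restype[
      match(e$j, structure$residues$res_index)]
    agg <- rowsum(e$c_ij * stats::model.matrix(~ 0 + factor(ty, levels = AA3)),
                  e$i)
    out[match(rownames(agg), rownames(out)), ] <- agg
  }
  attr(out, "isolated") <- stats::setNames(!(nodes %in% e$i), nodes)
  out
}

# index pairs of the 20x20 upper triangle (including diagonal) used to
# flatten symmetric EDMs into 210 columns
edm_flat_index <- function() {
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(idx = idx,
       names = paste0("edm_", AA3[idx[, 1]], "_", AA3[idx[, 2]]))
}

#' Environment description matrix (EDM) for one residue
#'
#' The 20 x 20 symmetric matrix whose (l, k) entry is the number of contacts
#' between environment residues of types l and k, normalised by the total
#' number of contacts within the environment (central residue excluded).
#' Contact counts `N_rs` come from the same graph that defined the
#' environment.  An environment with no internal contacts yields the zero
#' matrix, flagged via the `degenerate` attribute.
#'
#' @param graph A `contact_graph`.
#' @param structure The `vs_structure` providing residue types.
#' @param residue Central residue (`res_index`).
#' @return 20 x 20 numeric matrix with AA dimnames.
#' @export
environment_description_matrix <- function(graph, structure, residue) {
  nb <- graph_neighbours(graph, residue)$j
  m <- matrix(0, 20, 20, dimnames = list(AA3, AA3))
  e <- graph$edges
  ee <- e[e$i %in% nb & e$j %in% nb & e$i < e$j, , drop = FALSE]
  if (nrow(ee) == 0) {
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  ty_i <- structure$residues$restype[match(ee$i, structure$residues$res_index)]
  ty_j <- structure$residues$restype[match(ee$j, structure$residues$res_index)]
  for (r in seq_len(nrow(ee))) {
    m[ty_i[r], ty_j[r]] <- m[ty_i[r], ty_j[r]] + ee$n_ij[r]
    if (ty_i[r] != ty_j[r]) {
      m[ty_j[r], ty_i[r]] <- m[ty_j[r], ty_i[r]] + ee$n_ij[r]
    }
  }
  tot <- sum(ee$n_ij)
  m <- m / tot
  attr(m, "degenerate") <- FALSE
  m
}

# batch EDM: one flattened upper-triangle (210 columns) row per graph node
edm_features <- function(graph, structure) {
  nodes <- graph$nodes
  fl <- edm_flat_index()
  out <- matrix(0, length(nodes), length(fl$names),
                dimnames = list(nodes, fl$names))
  for (r in seq_along(nodes)) {
    m <- environment_description_matrix(graph, structure, nodes[r])
    out[r, ] <- m[fl$idx]
  }
  out
}
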