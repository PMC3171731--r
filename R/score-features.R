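# Score-feedback features for the second classification step: the
# environmental score (contact-strength weighted mean of neighbour scores),
# its decomposition by neighbour residue type (CSV), and max/min neighbour
# score summaries (Mms).

score_of <- function(scores, idx) {
  s <- scores[as.character(idx)]
  if (anyNA(s)) {
    stop("unscored neighbour residue(s): ",
         paste(utils::head(idx[is.na(s)], 5), collapse = ", "))
  }
  unname(s)
}

#' Environmental score of a residue
#'
#' `es_i = sum_j c_ij * s_j` over the neighbours of i: a convex combination
#' of the neighbours' first-step scores, so always within their envelope.
#' A neighbour-less residue falls back to its own score (flagged via the
#' `isolated` attribute).
#'
#' @param scores Named numeric vector of first-step scores, names =
#'   `res_index`.
#' @param graph A `contact_graph`.
#' @param residue Central residue (`res_index`).
#' @return The environmental score (scalar).
#' @export
environmental_score <- function(scores, graph, residue) {
  nb <- graph_neighbours(graph, residue)
  if (nrow(nb) == 0) {
    out <- score_of(scores, residue)
    attr(out, "isolated") <- TRUE
    return(out)
  }
  out <- sum(nb$c_ij * score_of(scores, nb$j))
  attr(out, "isolated") <- FALSE
  out
}

#' Contact score vector of a residue
#'
#' 20-vector whose component l is `sum c_ij * s_j` over neighbours of
#' residue type l; components add up exactly to the environmental score.
#'
#' @inheritParams environmental_score
#' @param structure The `vs_structure` providing residue types.
#' @return Named numeric 20-vector (`csv_<AA>`).
#' @export
contact_score_vector <- function(scores, graph, structure, residue) {
  nb <- graph_neighbours(graph, residue)
  out <- stats::setNames(numeric(20), paste0("csv_", AA3))
  if (nrow(nb) == 0) return(out)
  ty <- structure$residues$restype[match(nb$j, structure$residues$res_index)]
  v <- nb$c_ij * score_of(scores, nb$j)
  agg <- tapply(v, factor(ty, levels = AA3), sum, default = 0)
  out[] <- as.numeric(agg)
  out
}

#' Maximum-minimum neighbour score summaries
#'
#' The 4-tuple (max_j `c_ij * s_j`, min_j `c_ij * s_j`, max_j `s_j`,
#' min_j `s_j`) over the neighbours of a residue; since `c_ij <= 1`, the
#' weighted components never exceed the raw ones.  A neighbour-less residue
#' yields its own score in all four slots (flagged).
#'
#' @inheritParams environmental_score
#' @return Named numeric 4-vector (`mms_wmax`, `mms_wmin`, `mms_max`,
#'   `mms_min`) with an `isolated` attribute.
#' @export
max_min_scores <- function(scores, graph, residue) {
  nb <- graph_neighbours(graph, residue)
  if (nrow(nb) == 0) {
    s <- score_of(scores, residue)
    out <- structure(rep(s, 4),
                     names = c("mms_wmax", "mms_wmin", "mms_max", "mms_min"))
    attr(out, "isolated") <- TRUE
    return(out)
  }
  s <- score_of(scores, nb$j)
  w <- nb$c_ij * s
  out <- structure(c(max(w), min(w), max(s), min(s)),
                   names = c("mms_wmax", "mms_wmin", "mms_max", "mms_min"))
  attr(out, "isolated") <- FALSE
  out
}

# batch feedback feature block for the second-step design matrix:
# [score_first | es | csv (20) | mms (4)] per graph node, with the
# neighbour-less fallback (own score, zero csv) applied
score_feedback_features <- function(scores, graph, structure) {
  nodes <- graph$nodes
  out <- matrix(0, length(nodes), 26,
                dimnames = list(nodes,
                                c("score_first", "es", paste0("csv_", AA3),
                                  "mms_wmax", "mms_wmin", "mms_max",
                                  "mms_min")))
  for (r in seq_along(nodes)) {
    i <- nodes[r]
    es <- environmental_score(scores, graph, i)
    csv <- contact_score_vector(scores, graph, structure, i)
    mms <- max_min_scores(scores, graph, i)
    out[r, ] <- c(score_of(scores, i), as.numeric(es), csv, mms)
  }
  out
}
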