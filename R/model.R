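# Two-step random-forest binding-site model.
#
# Step 1 scores every exposed residue from its own features plus the
# environment descriptors (EF, CDV, flattened EDM).  Step 2 refits with the
# step-1 scores fed back through the same contact graph (es, CSV, Mms),
# smoothing predictions over contiguous surface patches.

#' Bundle a structure with its training labels
#'
#' @param structure A `vs_structure` (a single protomer; accessibility is
#'   computed on it if missing).
#' @param labels Logical interface labels, either one per residue in
#'   `res_index` order or a named vector keyed by `res_index`.  Typically
#'   produced by [label_interface()] on the bound complex.
#' @param msa Optional conservation input (see [residue_features()]).
#' @param id Unit identifier (defaults to the structure id).
#' @return A `training_unit` list.
#' @export
training_unit <- function(structure, labels, msa = NULL,
                          id = structure$structure_id) {
  stopifnot(inherits(structure, "vs_structure"))
  res <- structure$residues
  if (!is.null(names(labels))) {
    lab <- labels[as.character(res$res_index)]
  } else {
    if (length(labels) != nrow(res)) {
      stop("labels length (", length(labels), ") != residue count (",
           nrow(res), ")")
    }
    lab <- labels
  }
  structure(list(structure = structure, labels = as.logical(lab),
                 msa = msa, id = id),
            class = "training_unit")
}

ensure_rsasa <- function(structure, sasa_params) {
  if (all(is.na(structure$residues$rsasa))) {
    structure <- compute_rsasa(
      structure,
      probe_radius = sasa_params$probe_radius,
      n_points = sasa_params$n_points,
      exposure_threshold = sasa_params$exposure_threshold
    )
  }
  structure
}

# restrict a contact graph to a node subset, renormalising strengths
restrict_graph <- function(graph, keep) {
  e <- graph$edges
  e <- e[e$i %in% keep & e$j %in% keep & e$i < e$j, , drop = FALSE]
  new_contact_graph(data.frame(i = e$i, j = e$j, n = e$n_ij),
                    intersect(graph$nodes, keep), graph$mode, graph$params)
}

# assemble the first-step design matrix for one structure
build_design <- function(structure, msa, groups, env) {
  graph <- env_graph(structure, env)
  fv <- residue_features(structure, msa, groups)
  rows <- exposed_nodes(structure)
  rkey <- as.character(rows)
  if (env$mode == "none") {
    X <- fv[rkey, , drop = FALSE]
  } else {
    ef <- environment_features(fv, graph)
    iso <- attr(ef, "isolated")
    # neighbour-less residues: EF falls back to the residue's own features
    # (the convex-combination limit); the isolated flag records it
    if (any(iso)) {
      ef[iso, ] <- fv[rownames(ef)[iso], , drop = FALSE]
    }
    cdv <- contact_description_vector(graph, structure)
    edm <- edm_features(graph, structure)
    X <- cbind(fv[rkey, , drop = FALSE],
               ef[rkey, , drop = FALSE],
               cdv[rkey, , drop = FALSE],
               edm[rkey, , drop = FALSE],
               isolated = as.numeric(iso[rkey]))
  }
  rownames(X) <- rkey
  if (any(!is.finite(X))) stop("non-finite values in design matrix")
  # feedback graph: environments restricted to scored (exposed) residues
  fb_graph <- if (identical(sort(graph$nodes), sort(rows))) graph
              else restrict_graph(graph, rows)
  list(X = X, graph = graph, fb_graph = fb_graph, rows = rows)
}

fit_rf <- function(X, y, ntree, mtry, balance, seed) {
  yfac <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  if (nlevels(droplevels(yfac)) < 2) {
    stop("training labels contain a single class")
  }
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(X))))
  set.seed(seed)
  if (balance) {
    m <- min(table(yfac))
    randomForest::randomForest(x = X, y = yfac, ntree = ntree, mtry = mtry,
                               strata = yfac, sampsize = c(m, m))
  } else {
    randomForest::randomForest(x = X, y = yfac, ntree = ntree, mtry = mtry)
  }
}

rf_score <- function(rf, X) {
  unname(stats::predict(rf, X, type = "prob")[, "pos"])
}

#' Fit the two-step binding-site random forest
#'
#' Trains the first-step random forest on per-residue features plus
#' environment descriptors, generates unbiased first-step scores for the
#' training data by structure-wise out-of-fold prediction, derives the
#' score-feedback features (first-step score, environmental score, contact
#' score vector, max/min scores) and trains the second-step forest on the
#' first-step design extended by those features.
#'
#' @param units List of [training_unit()]s (at least two; folds are split by
#'   structure, never by residue).
#' @param env Environment definition, an [env_config()].
#' @param groups Feature groups to use, subset of `c("s","e","c","b")`.
#' @param ntree Trees per forest (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Random seed (mandatory for reproducible forests).
#' @param inner_folds Structure-wise folds used to produce out-of-fold
#'   first-step scores for second-step training (default 5).
#' @param balance Downsample the majority class per tree (default `TRUE`;
#'   exposed non-interface residues far outnumber interface ones).
#' @param threshold Score threshold used by downstream confusion-matrix
#'   reporting (default 0.5).
#' @param sasa_params Accessibility parameters applied to structures that
#'   arrive without rsasa.
#' @return An object of class `vorsite` with `predict`, `print`, `summary`
#'   and `plot` methods.
#' @export
vorsite <- function(units, env = env_config(), groups = c("s", "e", "c", "b"),
                    ntree = 500, mtry = NULL, seed = 1, inner_folds = 5,
                    balance = TRUE, threshold = 0.5,
                    sasa_params = list(probe_radius = 1.4, n_points = 960,
                                       exposure_threshold = 0.05)) {
  if (!is.list(units) || length(units) < 2) {
    stop("need at least two training structures")
  }
  groups <- match.arg(groups, FEATURE_GROUPS, several.ok = TRUE)
  units <- lapply(units, function(u) {
    stopifnot(inherits(u, "training_unit"))
    u$structure <- ensure_rsasa(u$structure, sasa_params)
    u
  })
  designs <- lapply(units, function(u) {
    d <- build_design(u$structure, u$msa, groups, env)
    d$y <- u$labels[d$rows]
    if (anyNA(d$y)) {
      stop("unlabeled exposed residue(s) in unit ", u$id)
    }
    d
  })
  reg1 <- colnames(designs[[1]]$X)
  for (d in designs) {
    if (!identical(colnames(d$X), reg1)) {
      stop("feature registry mismatch between training structures")
    }
  }
  X1 <- do.call(rbind, lapply(designs, `[[`, "X"))
  y <- unlist(lapply(designs, `[[`, "y"))
  first_rf <- fit_rf(X1, y, ntree, mtry, balance, seed)

  # out-of-fold first-step scores, folds split by structure
  k <- min(inner_folds, length(units))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(units)))
  s1_oof <- vector("list", length(units))
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    rf_f <- fit_rf(do.call(rbind, lapply(designs[tr], `[[`, "X")),
                   unlist(lapply(designs[tr], `[[`, "y")),
                   ntree, mtry, balance, seed + f)
    for (u in te) s1_oof[[u]] <- rf_score(rf_f, designs[[u]]$X)
  }

  X2 <- do.call(rbind, lapply(seq_along(units), function(u) {
    d <- designs[[u]]
    sc <- stats::setNames(s1_oof[[u]], rownames(d$X))
    fb <- score_feedback_features(sc, d$fb_graph, units[[u]]$structure)
    cbind(d$X, fb[rownames(d$X), , drop = FALSE])
  }))
  second_rf <- fit_rf(X2, y, ntree, mtry, balance, seed + 1000L)

  oof <- data.frame(
    unit = rep(vapply(units, `[[`, "", "id"),
               vapply(designs, function(d) length(d$rows), 0L)),
    res_index = unlist(lapply(designs, `[[`, "rows")),
    label = y,
    first_step_score = unlist(s1_oof)
  )
  obj <- list(first_rf = first_rf, second_rf = second_rf,
              registry = list(x1 = reg1, x2 = colnames(X2)),
              env = env, groups = groups, seed = seed, ntree = ntree,
              mtry = mtry, balance = balance, inner_folds = k,
              threshold = threshold, sasa_params = sasa_params,
              oof = oof,
              n_units = length(units),
              call = match.call())
  class(obj) <- "vorsite"
  obj
}

#' Score the exposed residues of a structure
#'
#' Every exposed residue receives a first-step and a final score in
#' `[0, 1]`; buried residues are not scored (their count is reported in the
#' `n_buried` attribute).
#'
#' @param object A fitted [vorsite()] model.
#' @param structure A `vs_structure` to score.
#' @param msa Optional conservation input; required when the model was
#'   trained with the conservation group.
#' @param ... Unused.
#' @return A `score_set` data frame: `chain`, `resno`, `icode`, `restype`,
#'   `res_index`, `first_step_score`, `final_score`.
#' @export
predict.vorsite <- function(object, structure, msa = NULL, ...) {
  stopifnot(inherits(structure, "vs_structure"))
  if ("c" %in% object$groups && is.null(msa)) {
    stop("model was trained with the conservation group; an MSA is required")
  }
  structure <- ensure_rsasa(structure, object$sasa_params)
  if (length(exposed_nodes(structure)) == 0) {
    warning("structure has no exposed residues; empty score set")
    out <- data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), restype = character(0),
                      res_index = integer(0), first_step_score = numeric(0),
                      final_score = numeric(0))
    class(out) <- c("score_set", "data.frame")
    return(out)
  }
  d <- build_design(structure, msa, object$groups, object$env)
  if (!identical(colnames(d$X), object$registry$x1)) {
    stop("feature registry mismatch: model expects ",
         length(object$registry$x1), " first-step features; structure ",
         "yields ", ncol(d$X))
  }
  s1 <- rf_score(object$first_rf, d$X)
  sc <- stats::setNames(s1, rownames(d$X))
  fb <- score_feedback_features(sc, d$fb_graph, structure)
  X2 <- cbind(d$X, fb[rownames(d$X), , drop = FALSE])
  stopifnot(identical(colnames(X2), object$registry$x2))
  s2 <- rf_score(object$second_rf, X2)

  r <- structure$residues[match(d$rows, structure$residues$res_index), ]
  out <- data.frame(chain = r$chain, resno = r$resno, icode = r$icode,
                    restype = r$restype, res_index = r$res_index,
                    first_step_score = s1, final_score = s2)
  class(out) <- c("score_set", "data.frame")
  attr(out, "n_buried") <- nrow(structure$residues) - nrow(out)
  attr(out, "structure_id") <- structure$structure_id
  attr(out, "threshold") <- object$threshold
  out
}

#' @export
print.vorsite <- function(x, ...) {
  cat("Two-step random-forest binding-site model\n")
  cat("  environment: ", x$env$mode, "\n", sep = "")
  cat("  feature groups: ", paste(x$groups, collapse = "+"), "\n", sep = "")
  cat("  trees: ", x$ntree, "  structures: ", x$n_units,
      "  residues: ", nrow(x$oof), " (", sum(x$oof$label),
      " interface)\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @method summary vorsite
#' @export
summary.vorsite <- function(object, ...) {
  oof <- object$oof
  auc1 <- roc_auc(oof$first_step_score, oof$label)$auc
  cat("Two-step random-forest binding-site model\n\n")
  cat("Training: ", object$n_units, " structures, ", nrow(oof),
      " exposed residues (", sum(oof$label), " interface, ",
      sprintf("%.1f%%", 100 * mean(oof$label)), ")\n", sep = "")
  cat("Environment: ", object$env$mode,
      "; feature groups: ", paste(object$groups, collapse = "+"),
      "; ", length(object$registry$x1), " first-step / ",
      length(object$registry$x2), " second-step features\n", sep = "")
  cat(sprintf("Out-of-fold first-step AUC: %.3f (%d-fold, by structure)\n",
              auc1, object$inner_folds))
  invisible(list(oof_auc_first = auc1, n_residues = nrow(oof)))
}

#' @method plot vorsite
#' @export
plot.vorsite <- function(x, ...) {
  oof <- x$oof
  r <- roc_auc(oof$first_step_score, oof$label)
  plot(r$roc$fpr, r$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Out-of-fold first-step ROC (AUC = %.3f)", r$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Thin RDS wrappers that preserve the full bundle (both forests, feature
#' registry, environment configuration, seed); predictions after a
#' round-trip are bit-identical.
#'
#' @param object A `vorsite` model.
#' @param path File path.
#' @return `read_vorsite` returns the model.
#' @export
save_vorsite <- function(object, path) {
  stopifnot(inherits(object, "vorsite"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_vorsite
#' @export
read_vorsite <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "vorsite")) stop("not a vorsite model bundle: ", path)
  obj
}

#' Write a score table as tab-separated text
#' @param scores A `score_set` from [predict.vorsite()].
#' @param file Output path.
#' @export
write_scores <- function(scores, file) {
  utils::write.table(as.data.frame(scores), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a PDB with final scores in the B-factor column
#'
#' Convenient for colouring predictions in molecular viewers; unscored
#' (buried) residues get B = 0.
#'
#' @param structure The scored `vs_structure`.
#' @param scores Matching `score_set`.
#' @param file Output path.
#' @export
write_scored_pdb <- function(structure, scores, file) {
  a <- structure$atoms
  res <- structure$residues
  b <- scores$final_score[match(a$res_index, scores$res_index)]
  b[is.na(b)] <- 0
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = res$resno[match(a$res_index, res$res_index)],
                   resid = res$restype[match(a$res_index, res$res_index)],
                   eleno = a$serial, elety = a$name,
                   chain = res$chain[match(a$res_index, res$res_index)],
                   insert = res$icode[match(a$res_index, res$res_index)],
                   o = a$occ, b = round(b, 2), elesy = a$element)
  invisible(file)
}
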