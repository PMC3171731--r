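#' Parse a PDB file into a structure object
#'
#' Reads ATOM/HETATM records (via [bio3d::read.pdb()]) into a light-weight
#' structure representation: a flat atom table plus a residue table keyed by
#' `(chain, resno, icode)`.  Alternate locations are resolved to the highest
#' occupancy (ties broken by altloc identifier), hydrogens are retained but
#' flagged as non-heavy, and non-standard residues are either mapped to a
#' standard parent type (e.g. MSE to MET) or skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"first"` (default) uses the first model of
#'   multi-model files; `"error"` refuses multi-model input.
#' @return An object of class `vs_structure`: a list with elements
#'   `structure_id`, `chains`, `atoms` (data frame with one row per atom),
#'   `residues` (one row per residue: `res_index`, `chain`, `resno`,
#'   `icode`, `restype`, `rsasa`, `exposed`, `interface`) and `source_path`.
#' @seealso [compute_rsasa()], [label_interface()], [residue_table()]
#' @export
parse_pdb <- function(path, model_policy = c("first", "error")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (n_models > 1L && model_policy == "error") {
    stop("multi-model PDB file refused under model_policy = 'error': ", path)
  }

  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # resolve alternate locations: highest occupancy, ties by altloc order
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  # map residue types; drop unmappable residues with a warning
  restype <- toupper(at$resid)
  mapped <- !is.na(NONSTANDARD_MAP[restype])
  restype[mapped] <- NONSTANDARD_MAP[restype[mapped]]
  keep <- restype %in% AA3
  if (!all(keep)) {
    skipped <- sort(unique(toupper(at$resid)[!keep]))
    warning("skipping non-standard residue types: ",
            paste(skipped, collapse = ", "))
    at <- at[keep, , drop = FALSE]
    restype <- restype[keep]
  }
  if (nrow(at) == 0L) stop("no standard amino-acid residues in ", path)

  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back to the first alphabetic character of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", at$elety[missing_el]))
    element[missing_el] <- toupper(substr(nm, 1, 1))
  }
  heavy <- !(element %in% c("H", "D"))

  # residue ordering: chain, then sequence number, then insertion code
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ord <- order(at$chain, at$resno, at$insert,
               method = "radix")
  at <- at[ord, , drop = FALSE]
  restype <- restype[ord]; element <- element[ord]; heavy <- heavy[ord]
  rkey <- rkey[ord]
  res_index <- cumsum(!duplicated(rkey))

  first <- !duplicated(rkey)
  residues <- data.frame(
    res_index = res_index[first],
    chain = at$chain[first],
    resno = at$resno[first],
    icode = at$insert[first],
    restype = restype[first],
    rsasa = NA_real_,
    exposed = NA,
    interface = NA,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = at$o,
    heavy = heavy,
    res_index = res_index,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in ", path)
  }

  new_structure(
    structure_id = sub("\\.[^.]*$", "", basename(path)),
    atoms = atoms, residues = residues, source_path = path
  )
}

new_structure <- function(structure_id, atoms, residues, source_path = "") {
  structure(
    list(structure_id = structure_id,
         chains = unique(residues$chain),
         atoms = atoms,
         residues = residues,
         source_path = source_path),
    class = "vs_structure"
  )
}

#' @export
print.vs_structure <- function(x, ...) {
  cat("<vs_structure> ", x$structure_id, "\n", sep = "")
  cat("  chains:   ", paste(x$chains, collapse = ", "), "\n", sep = "")
  cat("  residues: ", nrow(x$residues), "  atoms: ", nrow(x$atoms),
      " (", sum(x$atoms$heavy), " heavy)\n", sep = "")
  if (!all(is.na(x$residues$rsasa))) {
    cat("  exposed:  ", sum(x$residues$exposed, na.rm = TRUE), "\n", sep = "")
  }
  if (!all(is.na(x$residues$interface))) {
    cat("  interface:", sum(x$residues$interface, na.rm = TRUE), "\n")
  }
  invisible(x)
}

#' Residue identifier strings
#'
#' `chain:resno:icode` keys used in score tables and edge lists.
#' @param structure A `vs_structure`.
#' @param idx Residue indices (default all).
#' @return Character vector of keys.
#' @export
residue_keys <- function(structure, idx = structure$residues$res_index) {
  r <- structure$residues[match(idx, structure$residues$res_index), ]
  paste(r$chain, r$resno, r$icode, sep = ":")
}

#' Extract one or more chains as a stand-alone structure
#'
#' Used to mimic the unbound form of a complex: labels are derived from the
#' bound complex while features are computed on the isolated chain.
#'
#' @param structure A `vs_structure`.
#' @param chains Chain identifiers to keep.
#' @return A `vs_structure` with residues renumbered by `res_index`.
#' @export
subset_chains <- function(structure, chains) {
  missing <- setdiff(chains, structure$chains)
  if (length(missing) > 0) {
    stop("chain(s) not in structure: ", paste(missing, collapse = ", "))
  }
  res <- structure$residues[structure$residues$chain %in% chains, , drop = FALSE]
  atoms <- structure$atoms[structure$atoms$res_index %in% res$res_index, ,
                           drop = FALSE]
  old <- res$res_index
  res$res_index <- seq_len(nrow(res))
  atoms$res_index <- match(atoms$res_index, old)
  # rsasa refers to the full input structure; recompute on the subset
  res$rsasa <- NA_real_
  res$exposed <- NA
  new_structure(paste0(structure$structure_id, "_",
                       paste(chains, collapse = "")),
                atoms, res, structure$source_path)
}

#' Per-residue accessibility and exposure (Shrake-Rupley)
#'
#' Computes solvent-accessible surface area over heavy atoms by sphere
#' sampling, converts it to relative accessibility using maximal Gly-X-Gly
#' reference areas, and flags residues as exposed when
#' `rsasa >= exposure_threshold`.
#'
#' @param structure A `vs_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960, at which
#'   per-residue areas are stable to about 1% under doubling).
#' @param exposure_threshold Relative accessibility defining "exposed"
#'   (default 0.05).
#' @return The structure with `rsasa` and `exposed` filled in.  Residues
#'   without heavy atoms get `rsasa = NA` and are marked buried (with a
#'   warning).
#' @export
compute_rsasa <- function(structure, probe_radius = 1.4, n_points = 960,
                          exposure_threshold = 0.05) {
  stopifnot(inherits(structure, "vs_structure"))
  a <- structure$atoms
  hv <- a[a$heavy, , drop = FALSE]
  if (nrow(hv) == 0L) stop("no heavy atoms in structure ",
                           structure$structure_id)
  radii <- VDW_RADII[hv$element]
  radii[is.na(radii)] <- VDW_DEFAULT
  area <- .shrake_rupley_cpp(as.matrix(hv[, c("x", "y", "z")]),
                             as.numeric(radii), probe_radius,
                             as.integer(n_points))
  per_res <- rowsum(area, hv$res_index)
  res <- structure$residues
  res$rsasa <- NA_real_
  ridx <- as.integer(rownames(per_res))
  ref <- MAX_SASA[res$restype[match(ridx, res$res_index)]]
  res$rsasa[match(ridx, res$res_index)] <- pmin(1, per_res[, 1] / ref)
  no_heavy <- !(res$res_index %in% hv$res_index)
  if (any(no_heavy)) {
    warning(sum(no_heavy), " residue(s) without heavy atoms: ",
            "rsasa undefined, marked buried")
  }
  res$exposed <- !is.na(res$rsasa) & res$rsasa >= exposure_threshold
  structure$residues <- res
  structure$sasa_params <- list(probe_radius = probe_radius,
                                n_points = n_points,
                                exposure_threshold = exposure_threshold)
  structure
}

#' Label interface residues of a bound complex
#'
#' A residue of the receptor chain set is an interface residue when any of
#' its heavy atoms lies within `cutoff` of any heavy atom of the ligand
#' chain set, and symmetrically for the ligand side.
#'
#' @param structure A `vs_structure` holding the complex.
#' @param receptor_chains,ligand_chains Disjoint, non-empty chain sets.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5).
#' @return The structure with `residues$interface` set (`TRUE`/`FALSE`) for
#'   residues of either chain set; other residues keep `NA`.
#' @export
label_interface <- function(structure, receptor_chains, ligand_chains,
                            cutoff = 5) {
  stopifnot(inherits(structure, "vs_structure"))
  if (length(receptor_chains) == 0 || length(ligand_chains) == 0) {
    stop("both chain sets must be non-empty")
  }
  if (length(intersect(receptor_chains, ligand_chains)) > 0) {
    stop("receptor and ligand chain sets must be disjoint")
  }
  missing <- setdiff(c(receptor_chains, ligand_chains), structure$chains)
  if (length(missing) > 0) {
    stop("chain(s) not in structure: ", paste(missing, collapse = ", "))
  }
  res <- structure$residues
  a <- structure$atoms[structure$atoms$heavy, , drop = FALSE]
  a$chain <- res$chain[match(a$res_index, res$res_index)]
  ra <- a[a$chain %in% receptor_chains, , drop = FALSE]
  la <- a[a$chain %in% ligand_chains, , drop = FALSE]
  hit <- cross_within(as.matrix(ra[, c("x", "y", "z")]),
                      as.matrix(la[, c("x", "y", "z")]), cutoff)
  rec_if <- unique(ra$res_index[hit$i])
  lig_if <- unique(la$res_index[hit$j])
  in_sets <- res$chain %in% c(receptor_chains, ligand_chains)
  res$interface[in_sets] <- res$res_index[in_sets] %in% c(rec_if, lig_if)
  structure$residues <- res
  structure
}

# indices (i, j) of cross pairs within `cutoff`; blocked to bound memory
cross_within <- function(A, B, cutoff) {
  out_i <- integer(0); out_j <- integer(0)
  step <- max(1L, floor(4e6 / max(1L, nrow(B))))
  c2 <- cutoff^2
  bb <- rowSums(B^2)
  for (s in seq(1L, nrow(A), by = step)) {
    e <- min(nrow(A), s + step - 1L)
    blk <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), bb, "+") - 2 * blk %*% t(B)
    w <- which(d2 <= c2, arr.ind = TRUE)
    out_i <- c(out_i, w[, 1] + s - 1L)
    out_j <- c(out_j, w[, 2])
  }
  list(i = out_i, j = out_j)
}

#' Export the residue table
#'
#' @param structure A `vs_structure`.
#' @return Data frame with chain, resno, icode, restype, rsasa, exposed and
#'   interface columns.
#' @export
residue_table <- function(structure) {
  structure$residues[, c("chain", "resno", "icode", "restype", "rsasa",
                         "exposed", "interface")]
}

#' Write the residue table as tab-separated text
#' @param structure A `vs_structure`.
#' @param file Output path.
#' @export
write_residue_table <- function(structure, file) {
  utils::write.table(residue_table(structure), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
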