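# Per-residue feature providers.  Features come in four groups, selected by
# the letters used throughout the package:
#   s (structure):     rsasa, 3-state secondary structure, residue type
#   e (energy):        hydrophobicity desolvation proxy, contact pseudo-energy
#   c (conservation):  MSA column Shannon entropy and relative entropy
#   b (B-factor):      chain-normalised mean heavy-atom B-factor
# A missing group's columns are absent from the feature matrix, never
# zero-filled; the registry (column names) records what was computed.

FEATURE_GROUPS <- c("s", "e", "c", "b")

feature_names_for <- function(groups) {
  nm <- character(0); gr <- character(0)
  if ("s" %in% groups) {
    s_nm <- c("rsasa", "ss_H", "ss_E", "ss_C", paste0("aa_", AA3))
    nm <- c(nm, s_nm); gr <- c(gr, rep("s", length(s_nm)))
  }
  if ("e" %in% groups) {
    nm <- c(nm, "hphob_desolv", "contact_energy"); gr <- c(gr, "e", "e")
  }
  if ("c" %in% groups) {
    nm <- c(nm, "cons_entropy", "cons_relent"); gr <- c(gr, "c", "c")
  }
  if ("b" %in% groups) {
    nm <- c(nm, "bfactor_z"); gr <- c(gr, "b")
  }
  structure(gr, names = nm)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Aligned FASTA file; all sequences must share one length.
#' @return Character matrix, one row per sequence, one column per alignment
#'   column (upper-case, `-` for gaps).
#' @export
read_msa <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty alignment: ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1) {
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Three-state secondary structure from backbone hydrogen-bond patterns
#'
#' A self-contained simplified assignment in the Kabsch-Sander spirit:
#' amide hydrogens are reconstructed from the preceding peptide unit, the
#' electrostatic hydrogen-bond energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` identifies bonds
#' (`E < -0.5` kcal/mol), `i+4 -> i` bonds mark helix (H), mutual long-range
#' bonds mark strand bridges (E), everything else is coil (C).  Residues
#' lacking backbone atoms are coil.
#'
#' @param structure A `vs_structure`.
#' @return Character vector (`"H"`, `"E"`, `"C"`) aligned with
#'   `structure$residues`.
#' @export
ss3_assign <- function(structure) {
  res <- structure$residues
  a <- structure$atoms
  ss <- rep("C", nrow(res))
  get_atom <- function(name) {
    sel <- a[a$name == name, , drop = FALSE]
    m <- matrix(NA_real_, nrow(res), 3)
    idx <- match(res$res_index, sel$res_index)
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(sel[idx[ok], c("x", "y", "z")])
    m
  }
  N <- get_atom("N"); CA <- get_atom("CA"); C <- get_atom("C")
  O <- get_atom("O")
  for (ch in unique(res$chain)) {
    ri <- which(res$chain == ch)
    n <- length(ri)
    if (n < 5) next
    # reconstructed amide H for residues 2..n
    H <- matrix(NA_real_, n, 3)
    for (k in 2:n) {
      co <- C[ri[k - 1], ] - O[ri[k - 1], ]
      if (all(is.finite(co)) && all(is.finite(N[ri[k], ]))) {
        H[k, ] <- N[ri[k], ] + co / sqrt(sum(co^2))
      }
    }
    hb <- matrix(FALSE, n, n)  # hb[d, a]: N-H of d bonds C=O of a
    for (d in 2:n) {
      if (!all(is.finite(H[d, ]))) next
      for (acc in seq_len(n)) {
        if (abs(d - acc) < 2) next
        if (!all(is.finite(O[ri[acc], ])) || !all(is.finite(C[ri[acc], ])))
          next
        r_on <- sqrt(sum((O[ri[acc], ] - N[ri[d], ])^2))
        r_ch <- sqrt(sum((C[ri[acc], ] - H[d, ])^2))
        r_oh <- sqrt(sum((O[ri[acc], ] - H[d, ])^2))
        r_cn <- sqrt(sum((C[ri[acc], ] - N[ri[d], ])^2))
        if (r_on > 5.5) next
        e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
        if (e < -0.5) hb[d, acc] <- TRUE
      }
    }
    lab <- rep("C", n)
    for (i in seq_len(n - 4)) {
      if (hb[i + 4, i]) lab[(i + 1):(i + 4)] <- "H"
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) > 2 && hb[i, j] && hb[j, i]) {
          if (lab[i] == "C") lab[i] <- "E"
          if (lab[j] == "C") lab[j] <- "E"
        }
      }
    }
    ss[ri] <- lab
  }
  ss
}

#' Per-residue feature matrix
#'
#' Computes the selected feature groups for every residue of the structure
#' (all residues, not only exposed ones, so that window-mode environments
#' can draw on buried neighbours).
#'
#' @param structure A `vs_structure` with accessibility computed (needed by
#'   the s and e groups).
#' @param msa Optional conservation input: a character matrix from
#'   [read_msa()] (single-chain structures) or a named list of such
#'   matrices / file paths keyed by chain id.  The first alignment row,
#'   ungapped, must match the chain sequence.
#' @param groups Subset of `c("s","e","c","b")`.
#' @return Numeric matrix, rows named by `res_index`, with a `groups`
#'   attribute mapping each column to its group letter.
#' @export
residue_features <- function(structure, msa = NULL,
                             groups = c("s", "e", "c", "b")) {
  groups <- match.arg(groups, FEATURE_GROUPS, several.ok = TRUE)
  res <- structure$residues
  reg <- feature_names_for(groups)
  X <- matrix(NA_real_, nrow(res), length(reg),
              dimnames = list(res$res_index, names(reg)))

  needs_rsasa <- any(c("s", "e") %in% groups)
  if (needs_rsasa && all(is.na(res$rsasa))) {
    stop("rsasa not computed; run compute_rsasa() first")
  }
  rs <- res$rsasa
  rs[is.na(rs)] <- 0

  if ("s" %in% groups) {
    X[, "rsasa"] <- rs
    ss <- ss3_assign(structure)
    X[, "ss_H"] <- as.numeric(ss == "H")
    X[, "ss_E"] <- as.numeric(ss == "E")
    X[, "ss_C"] <- as.numeric(ss == "C")
    for (t in AA3) X[, paste0("aa_", t)] <- as.numeric(res$restype == t)
  }
  if ("e" %in% groups) {
    X[, "hphob_desolv"] <- KD_HYDROPATHY[res$restype] * rs
    X[, "contact_energy"] <- contact_energy(structure)
  }
  if ("c" %in% groups) {
    cons <- conservation_features(structure, msa)
    X[, "cons_entropy"] <- cons$entropy
    X[, "cons_relent"] <- cons$relent
  }
  if ("b" %in% groups) {
    X[, "bfactor_z"] <- bfactor_z(structure)
  }
  if (any(!is.finite(X))) stop("non-finite feature values computed")
  attr(X, "groups") <- reg
  X
}

# statistical contact pseudo-energy: sum of pair potentials over residues
# whose heavy-atom centroids lie within 8 Angstrom
contact_energy <- function(structure, cutoff = 8) {
  rp <- residue_points(structure, "centroid")
  res <- structure$residues
  pot <- contact_potential()
  d2 <- as.matrix(stats::dist(as.matrix(rp[, c("x", "y", "z")])))^2
  adj <- d2 <= cutoff^2
  diag(adj) <- FALSE
  ty <- res$restype[match(rp$res_index, res$res_index)]
  e <- vapply(seq_len(nrow(rp)), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) == 0) return(0)
    sum(pot[ty[i], ty[nb]])
  }, numeric(1))
  out <- rep(0, nrow(res))
  out[match(rp$res_index, res$res_index)] <- e
  out
}

bfactor_z <- function(structure) {
  res <- structure$residues
  a <- structure$atoms[structure$atoms$heavy, , drop = FALSE]
  mb <- rowsum(a$b, a$res_index) / as.vector(table(a$res_index))
  bz <- rep(0, nrow(res))
  bmean <- rep(NA_real_, nrow(res))
  bmean[match(as.integer(rownames(mb)), res$res_index)] <- mb[, 1]
  for (ch in unique(res$chain)) {
    ri <- which(res$chain == ch & !is.na(bmean))
    if (length(ri) < 2) next
    s <- stats::sd(bmean[ri])
    if (s > 0) bz[ri] <- (bmean[ri] - mean(bmean[ri])) / s
  }
  bz
}

conservation_features <- function(structure, msa) {
  res <- structure$residues
  entropy <- rep(NA_real_, nrow(res))
  relent <- rep(NA_real_, nrow(res))
  if (is.null(msa)) {
    stop("conservation features requested but no MSA provided")
  }
  msa_for <- function(ch) {
    m <- if (is.list(msa)) msa[[ch]] else msa
    if (is.null(m)) stop("no MSA provided for chain ", ch)
    if (is.character(m) && length(m) == 1) m <- read_msa(m)
    m
  }
  bg <- AA_BACKGROUND
  names(bg) <- AA1[names(bg)]
  for (ch in unique(res$chain)) {
    ri <- which(res$chain == ch)
    m <- msa_for(ch)
    ref <- m[1, ]
    map <- which(ref != "-")  # alignment column of each ungapped position
    chain_seq <- AA1[res$restype[ri]]
    if (length(map) != length(ri) ||
        !all(ref[map] == unname(chain_seq))) {
      bad <- if (length(map) == length(ri)) {
        which(ref[map] != unname(chain_seq))
      } else seq_along(ri)
      stop("MSA column mapping failure for chain ", ch,
           ": residue position(s) ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    }
    for (k in seq_along(ri)) {
      col <- m[, map[k]]
      col <- col[col %in% names(bg)]
      p <- table(factor(col, levels = names(bg)))
      p <- p / sum(p)
      nz <- p > 0
      entropy[ri[k]] <- -sum(p[nz] * log2(p[nz]))
      relent[ri[k]] <- sum(p[nz] * log2(p[nz] / bg[names(p)[nz]]))
    }
  }
  list(entropy = entropy, relent = relent)
}
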