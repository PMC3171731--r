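# Synthetic two-chain complexes with planted interface signal, plus matching
# synthetic MSAs, so the whole pipeline is testable without external data.
#
# Helical geometry: chains are ideal alpha-helices (phi = -57, psi = -47,
# omega = 180, standard backbone bond lengths/angles) with one C-beta-like
# pseudo-atom per residue standing in for the side chain; two copies are
# docked side by side at a separation chosen so that the requested fraction
# of residues lies within the labelling cutoff of the partner.  Signal is
# planted per feature group: interface residues get hydrophobic-biased
# residue types (structure/energy groups), lowered B-factors, and more
# conserved MSA columns.

#' Specification of a synthetic two-chain complex
#'
#' @param n_residues Residues per chain (default 50).
#' @param geometry `"helix"` (ideal alpha-helices, default) or `"lattice"`
#'   (cubic blocks of single-atom pseudo-residues).
#' @param interface_fraction Target fraction of each chain's residues in
#'   contact with the partner (default 0.2).
#' @param signal Named effect sizes for the planted per-group signal,
#'   `c(s=, e=, c=, b=)`; 0 disables a group's signal, 1 is the default
#'   "clearly detectable" strength.  `s`/`e` tilt interface residue types
#'   towards hydrophobics, `b` scales the B-factor decrease, `c` scales the
#'   conservation increase.
#' @param bfactor_shift B-factor decrease (A^2) for interface residues;
#'   default `5 * signal["b"]` (one population SD per unit effect).
#' @param conservation_shift Multiplier exponent controlling how much less
#'   often interface MSA columns mutate; default `signal["c"]`.
#' @param cutoff Labelling distance cutoff in Angstrom (default 5).
#' @param seed Mandatory random seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 50, geometry = c("helix", "lattice"),
                         interface_fraction = 0.2,
                         signal = c(s = 1, e = 1, c = 1, b = 1),
                         bfactor_shift = NULL, conservation_shift = NULL,
                         cutoff = 5, seed) {
  geometry <- match.arg(geometry)
  if (missing(seed)) stop("fixture seed is mandatory")
  if (interface_fraction <= 0 || interface_fraction >= 1) {
    stop("interface_fraction must be in (0, 1)")
  }
  sg <- c(s = 0, e = 0, c = 0, b = 0)
  sg[names(signal)] <- signal
  if (any(!is.finite(sg))) stop("signal effect sizes must be finite")
  if (is.null(bfactor_shift)) bfactor_shift <- 5 * sg[["b"]]
  if (is.null(conservation_shift)) conservation_shift <- sg[["c"]]
  structure(list(n_residues = n_residues, geometry = geometry,
                 interface_fraction = interface_fraction, signal = sg,
                 bfactor_shift = bfactor_shift,
                 conservation_shift = conservation_shift,
                 cutoff = cutoff, seed = seed),
            class = "fixture_spec")
}

# --- ideal-geometry chain building (NeRF internal-coordinate placement) ---

place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone + pseudo-CB coordinates of an ideal alpha-helix, one row per atom
build_helix <- function(n, phi = -57, psi = -47, omega = 180) {
  atoms <- c("N", "CA", "C", "O", "CB")
  xyz <- matrix(NA_real_, n * length(atoms), 3)
  an <- rep(atoms, n)
  ri <- rep(seq_len(n), each = length(atoms))
  idx <- function(i, name) which(ri == i & an == name)
  set_at <- function(i, name, v) xyz[idx(i, name), ] <<- v

  set_at(1, "N", c(0, 0, 0))
  set_at(1, "CA", c(1.458, 0, 0))
  th <- 111.2 * pi / 180
  set_at(1, "C", c(1.458 - 1.525 * cos(th), 1.525 * sin(th), 0))
  get_at <- function(i, name) xyz[idx(i, name), ]
  for (i in seq_len(n)) {
    if (i > 1) {
      set_at(i, "N", place_atom(get_at(i - 1, "N"), get_at(i - 1, "CA"),
                                get_at(i - 1, "C"), 1.329, 116.2, psi))
      set_at(i, "CA", place_atom(get_at(i - 1, "CA"), get_at(i - 1, "C"),
                                 get_at(i, "N"), 1.458, 121.7, omega))
      set_at(i, "C", place_atom(get_at(i - 1, "C"), get_at(i, "N"),
                                get_at(i, "CA"), 1.525, 111.2, phi))
    }
    set_at(i, "O", place_atom(get_at(i, "N"), get_at(i, "CA"),
                              get_at(i, "C"), 1.231, 120.8, psi + 180))
    set_at(i, "CB", place_atom(get_at(i, "C"), get_at(i, "N"),
                               get_at(i, "CA"), 1.530, 110.5, 122.6))
  }
  list(xyz = xyz, atom = an, res = ri)
}

# rotate so the principal axis of the CA trace is z, centred at the origin
align_to_z <- function(ch) {
  ca <- ch$xyz[ch$atom == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  x <- sweep(ch$xyz, 2, ctr)
  v <- svd(sweep(ca, 2, ctr))$v
  if (det(v) < 0) v[, 3] <- -v[, 3]
  # principal axis (first right singular vector) becomes z
  rot <- v[, c(2, 3, 1)]
  ch$xyz <- x %*% rot
  ch
}

rot_x_180 <- function(xyz) {
  xyz[, 2] <- -xyz[, 2]
  xyz[, 3] <- -xyz[, 3]
  xyz
}

lattice_block <- function(n, frac) {
  side <- max(2L, round(sqrt(n * frac)))
  depth <- ceiling(n / side^2)
  g <- expand.grid(y = seq_len(side), z = seq_len(side), x = seq_len(depth))
  g <- g[order(-g$x, g$y, g$z), , drop = FALSE][seq_len(n), ]
  list(xyz = 3.8 * cbind(g$x, g$y, g$z), atom = rep("CA", n),
       res = seq_len(n))
}

# chains as atom tables; separation along +x tuned to the target fraction
dock_chains <- function(spec) {
  if (spec$geometry == "helix") {
    chA <- align_to_z(build_helix(spec$n_residues))
    chB <- chA
    chB$xyz <- rot_x_180(chB$xyz)
  } else {
    chA <- lattice_block(spec$n_residues, spec$interface_fraction)
    chB <- chA
    chB$xyz[, 1] <- -chB$xyz[, 1]
  }
  heavyA <- chA$xyz; heavyB0 <- chB$xyz
  target <- spec$interface_fraction * spec$n_residues
  best <- NULL
  for (d in seq(2, 40, by = 0.25)) {
    off <- max(heavyA[, 1]) - min(heavyB0[, 1]) + d
    hit <- cross_within(heavyA, cbind(heavyB0[, 1] + off,
                                      heavyB0[, 2], heavyB0[, 3]),
                        spec$cutoff)
    nif <- length(unique(chA$res[hit$i]))
    if (is.null(best) || abs(nif - target) < best$err) {
      best <- list(d = d, off = off, err = abs(nif - target), nif = nif)
    }
  }
  if (best$err > max(2, 0.25 * target)) {
    stop("interface_fraction ", spec$interface_fraction,
         " unreachable for this geometry (closest: ",
         best$nif / spec$n_residues, ")")
  }
  chB$xyz[, 1] <- chB$xyz[, 1] + best$off
  list(A = chA, B = chB, separation = best$d)
}

sample_types <- function(n, interface, tilt) {
  w_bg <- AA_BACKGROUND
  w_if <- AA_BACKGROUND * exp(tilt * KD_HYDROPATHY / max(abs(KD_HYDROPATHY)))
  w_if <- w_if / sum(w_if)
  ty <- character(n)
  ty[!interface] <- sample(AA3, sum(!interface), replace = TRUE, prob = w_bg)
  if (any(interface)) {
    ty[interface] <- sample(AA3, sum(interface), replace = TRUE, prob = w_if)
  }
  ty
}

make_msa <- function(seq1, interface, n_rows, cons_shift) {
  p_base <- 0.45
  p_col <- ifelse(interface, p_base * exp(-1.2 * cons_shift), p_base)
  bg1 <- AA_BACKGROUND
  names(bg1) <- AA1[names(bg1)]
  rows <- matrix(rep(seq1, n_rows), n_rows, length(seq1), byrow = TRUE)
  for (j in seq_along(seq1)) {
    mut <- stats::runif(n_rows - 1) < p_col[j]
    if (any(mut)) {
      rows[1 + which(mut), j] <- sample(names(bg1), sum(mut),
                                        replace = TRUE, prob = bg1)
    }
  }
  rows
}

#' Generate a synthetic two-chain complex with planted interface signal
#'
#' Emits a PDB file of the docked complex, a tab-separated label file and
#' one synthetic aligned-FASTA MSA per chain, all deterministic given the
#' spec's seed.  The planted labels agree with [label_interface()] applied
#' to the emitted complex at the generation cutoff.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the in-memory
#'   `structure` (labelled complex) and the labels data frame.
#' @export
generate_complex <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  dk <- dock_chains(spec)
  n <- spec$n_residues

  atoms <- rbind(
    data.frame(chain = "A", res = dk$A$res, name = dk$A$atom,
               x = dk$A$xyz[, 1], y = dk$A$xyz[, 2], z = dk$A$xyz[, 3]),
    data.frame(chain = "B", res = dk$B$res, name = dk$B$atom,
               x = dk$B$xyz[, 1], y = dk$B$xyz[, 2], z = dk$B$xyz[, 3])
  )

  # geometric labels first; types/B-factors/MSA are planted on top
  labA <- interface_of(atoms, "A", "B", spec$cutoff)
  labB <- interface_of(atoms, "B", "A", spec$cutoff)

  tilt <- 1.2 * mean(spec$signal[c("s", "e")])
  tyA <- sample_types(n, labA, tilt)
  tyB <- sample_types(n, labB, tilt)

  bA <- stats::rnorm(n, 30, 5) - spec$bfactor_shift * labA
  bB <- stats::rnorm(n, 30, 5) - spec$bfactor_shift * labB
  bA <- pmax(bA, 1); bB <- pmax(bB, 1)

  msaA <- make_msa(unname(AA1[tyA]), labA, 50, spec$conservation_shift)
  msaB <- make_msa(unname(AA1[tyB]), labB, 50, spec$conservation_shift)

  restype <- ifelse(atoms$chain == "A", tyA[atoms$res], tyB[atoms$res])
  bfac <- ifelse(atoms$chain == "A", bA[atoms$res], bB[atoms$res]) +
    stats::rnorm(nrow(atoms), 0, 0.5)
  bfac <- pmax(bfac, 1)

  pdb_path <- file.path(dir, "complex.pdb")
  bio3d::write.pdb(pdb = NULL, file = pdb_path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$res, resid = restype,
                   eleno = seq_len(nrow(atoms)), elety = atoms$name,
                   chain = atoms$chain, o = rep(1, nrow(atoms)),
                   b = round(bfac, 2),
                   elesy = substr(atoms$name, 1, 1))

  labels <- data.frame(chain = rep(c("A", "B"), each = n),
                       resno = rep(seq_len(n), 2),
                       icode = "",
                       restype = c(tyA, tyB),
                       interface = c(labA, labB))
  labels_path <- file.path(dir, "labels.tsv")
  utils::write.table(labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  msa_paths <- c(A = file.path(dir, "msa_A.fasta"),
                 B = file.path(dir, "msa_B.fasta"))
  write_msa(msaA, msa_paths["A"], "A")
  write_msa(msaB, msa_paths["B"], "B")

  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       digits = NA)

  cx <- parse_pdb(pdb_path)
  cx <- label_interface(cx, "A", "B", spec$cutoff)
  invisible(list(paths = list(pdb = pdb_path, labels = labels_path,
                              msa = as.list(msa_paths), spec = spec_path),
                 structure = cx, labels = labels, separation = dk$separation))
}

interface_of <- function(atoms, ch, partner, cutoff) {
  A <- as.matrix(atoms[atoms$chain == ch, c("x", "y", "z")])
  B <- as.matrix(atoms[atoms$chain == partner, c("x", "y", "z")])
  hit <- cross_within(A, B, cutoff)
  seq_len(max(atoms$res)) %in% unique(atoms$res[atoms$chain == ch][hit$i])
}

write_msa <- function(m, path, chain) {
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- c(paste0("chain_", chain),
                   sprintf("synthetic_homolog_%02d", seq_len(nrow(m) - 1)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Random point-cloud pseudo-structure
#'
#' `n` single-atom pseudo-residues uniform in a cube (or the regular
#' tetrahedron preset), used to exercise the tessellation machinery against
#' brute-force oracles.
#'
#' @param n Number of points (at least 4).
#' @param seed Random seed.
#' @param preset `"tetrahedron"` overrides `n` with the 4-vertex regular
#'   tetrahedron of edge 5 Angstrom.
#' @return A `vs_structure` whose residues each hold one C-alpha pseudo-atom.
#' @export
generate_point_cloud <- function(n, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "tetrahedron")
    xyz <- 5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                     c(0.5, sqrt(3) / 6, sqrt(6) / 3))
    n <- 4L
    set.seed(seed)
  } else {
    if (n < 4) stop("need at least 4 points")
    set.seed(seed)
    side <- max(10, 3 * n^(1 / 3))
    repeat {
      xyz <- matrix(stats::runif(3 * n, 0, side), n, 3)
      if (min(stats::dist(xyz)) > 1e-6) break
    }
  }
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      b = 30, occ = 1, heavy = TRUE, res_index = seq_len(n))
  residues <- data.frame(res_index = seq_len(n), chain = "A",
                         resno = seq_len(n), icode = "",
                         restype = sample(AA3, n, replace = TRUE),
                         rsasa = NA_real_, exposed = NA, interface = NA)
  new_structure(sprintf("cloud_n%d_seed%d", n, seed), atoms, residues)
}

#' Load a generated fixture as training units
#'
#' Re-parses the emitted complex, labels interfaces from the bound form,
#' and extracts each chain as an unbound-like structure with its labels and
#' MSA — the shape expected by [vorsite()] and [vorsite_cv()].
#'
#' @param dir Directory written by [generate_complex()].
#' @param groups Feature groups the units will be used with (the MSA is
#'   attached only if conservation is among them).
#' @return List of two [training_unit()]s (chains A and B).
#' @export
fixture_units <- function(dir, groups = c("s", "e", "c", "b")) {
  sp <- jsonlite::read_json(file.path(dir, "spec.json"))
  cx <- parse_pdb(file.path(dir, "complex.pdb"))
  cx <- label_interface(cx, "A", "B", sp$cutoff)
  lapply(c("A", "B"), function(ch) {
    sub <- subset_chains(cx, ch)
    full <- cx$residues[cx$residues$chain == ch, ]
    lab <- stats::setNames(full$interface, seq_len(nrow(full)))
    msa <- NULL
    if ("c" %in% groups) {
      msa <- read_msa(file.path(dir, paste0("msa_", ch, ".fasta")))
    }
    training_unit(sub, lab, msa = msa, id = paste0(cx$structure_id, "_", ch))
  })
}

#' Generate a set of independent fixture complexes
#'
#' Convenience wrapper producing `n_complexes` fixtures (seeds
#' `seed, seed+1, ...`) under one directory and returning the pooled
#' training units.
#'
#' @param n_complexes Number of complexes.
#' @param dir Output directory.
#' @param seed Base seed.
#' @param ... Passed to [fixture_spec()].
#' @param groups See [fixture_units()].
#' @return List of training units (two per complex).
#' @export
generate_fixture_set <- function(n_complexes, dir, seed,
                                 groups = c("s", "e", "c", "b"), ...) {
  units <- list()
  for (i in seq_len(n_complexes)) {
    sub <- file.path(dir, sprintf("complex_%02d", i))
    generate_complex(fixture_spec(seed = seed + i - 1, ...), sub)
    units <- c(units, fixture_units(sub, groups))
  }
  units
}
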