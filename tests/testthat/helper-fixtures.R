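# Shared test helpers: brute-force geometric oracles and cached fixtures
# (expensive objects are built once per test run).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# Brute-force Delaunay adjacency by the empty-circumsphere test: a 4-subset
# is a Delaunay tetrahedron iff its circumsphere contains no other point;
# edges of such tetrahedra are the Delaunay edges.  Independent of the
# incremental implementation under test.
brute_delaunay_edges <- function(x) {
  n <- nrow(x)
  nrm <- rowSums(x^2)
  cmb <- utils::combn(n, 4)
  edges <- matrix(0L, 0, 2)
  for (q in seq_len(ncol(cmb))) {
    s <- cmb[, q]
    A <- 2 * (x[s[2:4], , drop = FALSE] -
                matrix(x[s[1], ], 3, 3, byrow = TRUE))
    rhs <- nrm[s[2:4]] - nrm[s[1]]
    ctr <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(ctr)) next
    r2 <- sum((x[s[1], ] - ctr)^2)
    d2 <- colSums((t(x) - ctr)^2)
    if (all(d2[-s] > r2 * (1 + 1e-9))) {
      edges <- rbind(edges, t(utils::combn(s, 2)))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

sort_edges <- function(e) {
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# brute-force cross-chain interface labels at a distance cutoff
brute_interface <- function(structure, chain_a, chain_b, cutoff) {
  res <- structure$residues
  a <- structure$atoms[structure$atoms$heavy, ]
  ch <- res$chain[match(a$res_index, res$res_index)]
  A <- a[ch == chain_a, ]; B <- a[ch == chain_b, ]
  lab <- logical(nrow(res))
  for (i in unique(A$res_index)) {
    ai <- as.matrix(A[A$res_index == i, c("x", "y", "z")])
    for (j in unique(B$res_index)) {
      bj <- as.matrix(B[B$res_index == j, c("x", "y", "z")])
      d <- sqrt(outer(rowSums(ai^2), rowSums(bj^2), "+") - 2 * ai %*% t(bj))
      if (min(d) <= cutoff) {
        lab[res$res_index == i] <- TRUE
        lab[res$res_index == j] <- TRUE
      }
    }
  }
  lab
}

# minimal fixed-width PDB ATOM record for hand-built parser inputs
pdb_line <- function(serial, name, alt, resid, chain, resno, x, y, z,
                     occ = 1, b = 30, element = substr(name, 1, 1),
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, x, y, z, occ, b,
          element)
}

# a small labelled fixture set for classifier tests (built once)
small_units <- function() {
  cached("small_units", {
    generate_fixture_set(3, file.path(tempdir(), "vs_small"), seed = 501,
                         n_residues = 36)
  })
}

# one parsed, accessibility-annotated single chain
small_chain <- function() {
  cached("small_chain", {
    d <- file.path(tempdir(), "vs_chain")
    fx <- generate_complex(fixture_spec(n_residues = 40, seed = 77), d)
    compute_rsasa(subset_chains(fx$structure, "A"))
  })
}
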