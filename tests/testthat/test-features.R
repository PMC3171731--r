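test_that("feature groups produce the registered columns and nothing else", {
  st <- small_chain()
  units <- small_units()
  fv <- residue_features(st, msa = NULL, groups = c("s", "e", "b"))
  gr <- attr(fv, "groups")
  expect_equal(unname(gr[c("rsasa", "hphob_desolv", "bfactor_z")]),
               c("s", "e", "b"))
  expect_false(any(c("cons_entropy", "cons_relent") %in% colnames(fv)))
  expect_true(all(is.finite(fv)))
  # conservation without an MSA is an error, never imputed
  expect_error(residue_features(st, msa = NULL, groups = "c"), "no MSA")
})

test_that("uniform B-factors give all-zero z-scores", {
  st <- small_chain()
  st$atoms$b <- 25
  fv <- residue_features(st, groups = "b")
  expect_equal(unname(fv[, "bfactor_z"]), rep(0, nrow(st$residues)))
})

test_that("column entropy hits both conservation limits", {
  # 20 single-atom residues, one of each type, in generic positions
  st <- generate_point_cloud(20, seed = 5)
  st$residues$restype <- AA <- vorsite:::AA3
  seq1 <- unname(vorsite:::AA1[AA])

  # fully conserved columns: zero entropy
  msa_const <- matrix(rep(seq1, 30), 30, 20, byrow = TRUE)
  fv <- residue_features(st, msa = msa_const, groups = "c")
  expect_equal(unname(fv[, "cons_entropy"]), rep(0, 20))

  # columns uniform over all 20 types: maximal entropy log2(20)
  msa_unif <- t(vapply(0:19, function(r) {
    unname(vorsite:::AA1[AA[(seq(0, 19) + r) %% 20 + 1]])
  }, character(20)))
  expect_equal(msa_unif[1, ], seq1)
  fv <- residue_features(st, msa = msa_unif, groups = "c")
  expect_equal(unname(fv[, "cons_entropy"]), rep(log2(20), 20),
               tolerance = 1e-12)
  # and relative entropy vs the background is constant across columns
  expect_lt(diff(range(fv[, "cons_relent"])), 1e-12)
})

test_that("MSA mapping failures name the offending residues", {
  st <- generate_point_cloud(5, seed = 6)
  st$residues$restype <- c("ALA", "GLY", "ALA", "GLY", "ALA")
  bad <- matrix(c("A", "G", "W", "G", "A"), 1)  # mismatch at position 3
  expect_error(residue_features(st, msa = bad, groups = "c"),
               "MSA column mapping failure.*3")
})

test_that("helical fixtures are assigned mostly helix", {
  st <- small_chain()
  ss <- ss3_assign(st)
  expect_gt(mean(ss == "H"), 0.8)
})

test_that("environment features are the strength-weighted neighbour averages", {
  # hand-built two-neighbour case: f = 2 and 4 with c = 0.75 / 0.25
  g <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L), j = c(2L, 3L), n = c(3, 1)),
    nodes = 1:3, mode = "voronoi", params = list())
  fv <- matrix(c(0, 2, 4), 3, 1, dimnames = list(1:3, "f"))
  ef <- environment_features(fv, g)
  expect_equal(ef["1", "ef_f"], 0.75 * 2 + 0.25 * 4)

  # convex-combination identity: constant field passes through
  fv[] <- 7
  ef <- environment_features(fv, g)
  expect_equal(unname(ef[, "ef_f"]), rep(7, 3))
})

test_that("environment features match a naive double-loop oracle", {
  cloud <- generate_point_cloud(30, seed = 10)
  g <- voronoi_neighbours(cloud, env_config(exposed_only = FALSE))
  set.seed(1)
  fv <- matrix(rnorm(30 * 4), 30, 4,
               dimnames = list(1:30, paste0("f", 1:4)))
  ef <- environment_features(fv, g)
  for (i in g$nodes) {
    nb <- graph_neighbours(g, i)
    want <- colSums(nb$c_ij * fv[as.character(nb$j), , drop = FALSE])
    expect_equal(unname(ef[as.character(i), ]), unname(want),
                 tolerance = 1e-12)
  }
})

test_that("missing neighbour features raise a consistency error", {
  g <- vorsite:::new_contact_graph(
    data.frame(i = 1L, j = 2L, n = 1), nodes = 1:2, mode = "voronoi",
    params = list())
  fv <- matrix(c(1, NA), 2, 1, dimnames = list(1:2, "f"))
  expect_error(environment_features(fv, g), "missing values")
  fv_short <- matrix(1, 1, 1, dimnames = list(1, "f"))
  expect_error(environment_features(fv_short, g), "lack feature vectors")
})

test_that("contact description vectors aggregate strengths by residue type", {
  cloud <- generate_point_cloud(5, seed = 3)
  cloud$residues$restype <- c("SER", "ALA", "GLY", "ALA", "TRP")
  g <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L), n = c(3, 5, 2)),
    nodes = 1:5, mode = "voronoi", params = list())
  cdv <- contact_description_vector(g, cloud)
  expect_equal(cdv["1", "cdv_ALA"], 0.5)   # 0.3 + 0.2
  expect_equal(cdv["1", "cdv_GLY"], 0.5)
  expect_equal(sum(cdv["1", ]), 1)
  expect_equal(sum(cdv["1", ] != 0), 2)
  expect_true(attr(cdv, "isolated")[["5"]])
  expect_equal(sum(cdv["5", ]), 0)  # zero vector for neighbour-less nodes
})

test_that("CDV sums to one on real tessellations", {
  st <- small_chain()
  g <- voronoi_neighbours(st)
  cdv <- contact_description_vector(g, st)
  with_nb <- !attr(cdv, "isolated")
  expect_lt(max(abs(rowSums(cdv[with_nb, , drop = FALSE]) - 1)), 1e-12)
  expect_true(all(cdv >= 0))
})

test_that("the environment description matrix follows the worked example", {
  # environment of node 1 = {2 (ALA), 3 (ALA), 4 (GLY)};
  # internal contacts: N(2,4) = 2 ALA-GLY, N(2,3) = 2 ALA-ALA
  cloud <- generate_point_cloud(4, seed = 4)
  cloud$residues$restype <- c("SER", "ALA", "ALA", "GLY")
  g <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L, 1L, 2L, 2L), j = c(2L, 3L, 4L, 4L, 3L),
               n = c(1, 1, 1, 2, 2)),
    nodes = 1:4, mode = "voronoi", params = list())
  m <- environment_description_matrix(g, cloud, 1)
  expect_equal(m["ALA", "GLY"], 0.5)
  expect_equal(m["ALA", "ALA"], 0.5)
  expect_equal(m, t(m))
  expect_false(attr(m, "degenerate"))

  # single internal contact pair: that entry is 1
  g2 <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L), n = c(1, 1, 4)),
    nodes = 1:3, mode = "voronoi", params = list())
  m2 <- environment_description_matrix(g2, cloud, 1)
  expect_equal(m2["ALA", "ALA"], 1)
  expect_equal(sum(m2), 1)

  # no internal contacts: zero matrix, flagged
  g3 <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L), j = c(2L, 3L), n = c(1, 1)),
    nodes = 1:3, mode = "voronoi", params = list())
  m3 <- environment_description_matrix(g3, cloud, 1)
  expect_equal(sum(m3), 0)
  expect_true(attr(m3, "degenerate"))
})

test_that("EDM entries sum to one over unordered type pairs on random fixtures", {
  st <- small_chain()
  g <- voronoi_neighbours(st)
  fl <- vorsite:::edm_flat_index()
  for (i in sample(g$nodes, 10)) {
    m <- environment_description_matrix(g, st, i)
    if (attr(m, "degenerate")) next
    # sum over unordered pairs = upper triangle including diagonal
    expect_equal(sum(m[upper.tri(m, diag = TRUE)]), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  # flattened block used by the classifier matches the per-residue matrices
  edm <- vorsite:::edm_features(g, st)
  i <- g$nodes[5]
  m <- environment_description_matrix(g, st, i)
  expect_equal(unname(edm[as.character(i), ]), unname(m[fl$idx]))
})
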