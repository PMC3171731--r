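test_that("Delaunay adjacency equals the brute-force empty-circumsphere oracle", {
  for (s in c(2, 3)) {
    for (n in c(20, 40)) {
      cloud <- generate_point_cloud(n, seed = s)
      x <- as.matrix(cloud$atoms[, c("x", "y", "z")])
      got <- sort_edges(delaunay_edges(x))
      want <- sort_edges(brute_delaunay_edges(x))
      expect_equal(got, want, info = sprintf("n=%d seed=%d", n, s))
    }
  }
})

test_that("the Voronoi residue graph is sandwiched by the circumsphere oracles", {
  # The pseudo-solvent shell bounds surface cells, so the residue graph sits
  # between two brute-force references: it can only lose edges relative to
  # the bare-cloud Delaunay (adding sites never creates adjacency), and it
  # must keep every edge of a real-point tetrahedron whose circumsphere is
  # empty of shell points too.
  cloud <- generate_point_cloud(30, seed = 8)
  g <- voronoi_neighbours(cloud, env_config(exposed_only = FALSE))
  got <- sort_edges(as.matrix(g$edges[g$edges$i < g$edges$j, c("i", "j")]))
  gkey <- paste(got[, 1], got[, 2])

  x <- as.matrix(cloud$atoms[, c("x", "y", "z")])
  bare <- sort_edges(brute_delaunay_edges(x))
  expect_true(all(gkey %in% paste(bare[, 1], bare[, 2])))

  ctr <- colMeans(x)
  rmax <- sqrt(max(rowSums(sweep(x, 2, ctr)^2)))
  shell <- vorsite:::fibonacci_sphere(256, radius = rmax + 10, center = ctr)
  nrm <- rowSums(x^2)
  must_keep <- character(0)
  for (q in utils::combn(30, 4, simplify = FALSE)) {
    A <- 2 * (x[q[2:4], , drop = FALSE] - matrix(x[q[1], ], 3, 3,
                                                 byrow = TRUE))
    ctr4 <- tryCatch(solve(A, nrm[q[2:4]] - nrm[q[1]]),
                     error = function(e) NULL)
    if (is.null(ctr4)) next
    r2 <- sum((x[q[1], ] - ctr4)^2)
    if (any(colSums((t(x) - ctr4)^2)[-q] <= r2 * (1 + 1e-9))) next
    if (any(colSums((t(shell) - ctr4)^2) <= r2 * (1 + 1e-9))) next
    e <- t(utils::combn(q, 2))
    must_keep <- c(must_keep, paste(e[, 1], e[, 2]))
  }
  expect_true(all(unique(must_keep) %in% gkey))
})

test_that("four single-atom residues at tetrahedron vertices are all mutual neighbours", {
  tet <- generate_point_cloud(4, preset = "tetrahedron")
  g <- voronoi_neighbours(tet, env_config(exposed_only = FALSE))
  expect_equal(nrow(g$edges), 12)  # 6 undirected pairs
  expect_equal(unname(g$totals[as.character(1:4)]), rep(3, 4))
  expect_equal(g$edges$n_ij, rep(1, 12))
  expect_equal(g$edges$c_ij, rep(1 / 3, 12))
})

test_that("contact strengths are the facet-count fractions", {
  # direct check of the normalisation on a constructed count table
  g <- vorsite:::new_contact_graph(
    data.frame(i = c(1L, 1L), j = c(2L, 3L), n = c(3, 1)),
    nodes = 1:3, mode = "voronoi", params = list())
  e <- g$edges
  expect_equal(e$c_ij[e$i == 1 & e$j == 2], 0.75)
  expect_equal(e$c_ij[e$i == 1 & e$j == 3], 0.25)
  expect_equal(e$c_ij[e$i == 2], 1)  # single neighbour
  # symmetric counts, asymmetric strengths
  expect_equal(e$n_ij[e$i == 1 & e$j == 2], e$n_ij[e$i == 2 & e$j == 1])

  # and on a real tessellation: c_ij == n_ij / N_i everywhere
  st <- small_chain()
  gv <- voronoi_neighbours(st)
  expect_equal(gv$edges$c_ij,
               gv$edges$n_ij / gv$totals[as.character(gv$edges$i)],
               ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("strengths sum to one for every node with neighbours, in every mode", {
  st <- small_chain()
  for (mode in c("voronoi", "sphere", "window")) {
    g <- env_graph(st, env_config(mode))
    sums <- tapply(g$edges$c_ij, g$edges$i, sum)
    expect_lt(max(abs(sums - 1)), 1e-12)
    expect_true(all(g$edges$c_ij > 0 & g$edges$c_ij <= 1))
  }
})

test_that("the Voronoi graph ignores sphere/window parameters", {
  st <- small_chain()
  g1 <- env_graph(st, env_config("voronoi", sphere_radius = 5,
                                 window_length = 3))
  g2 <- env_graph(st, env_config("voronoi", sphere_radius = 20,
                                 window_length = 15))
  expect_equal(g1$edges, g2$edges)
})

test_that("sphere neighbourhoods respect the radius and use uniform weights", {
  # two residues 14 A apart
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      x = c(0, 14), y = 0, z = 0, b = 30, occ = 1,
                      heavy = TRUE, res_index = 1:2)
  residues <- data.frame(res_index = 1:2, chain = "A", resno = 1:2,
                         icode = "", restype = "ALA", rsasa = 1,
                         exposed = TRUE, interface = NA)
  st <- vorsite:::new_structure("two", atoms, residues)
  g15 <- sphere_neighbours(st, radius = 15)
  expect_equal(nrow(g15$edges), 2)
  g10 <- sphere_neighbours(st, radius = 10)
  expect_equal(nrow(g10$edges), 0)

  st40 <- small_chain()
  g <- sphere_neighbours(st40, radius = 12)
  deg <- table(g$edges$i)
  expect_equal(as.vector(tapply(g$edges$c_ij, g$edges$i, unique)),
               unname(1 / as.numeric(deg)), tolerance = 1e-15)
  # monotone in the radius
  g_small <- sphere_neighbours(st40, radius = 8)
  key <- function(gr) paste(gr$edges$i, gr$edges$j)
  expect_true(all(key(g_small) %in% key(g)))
})

test_that("window neighbourhoods truncate at termini and window 1 is empty", {
  st <- small_chain()  # one chain of 40 residues
  g9 <- window_neighbours(st, 9)
  nb_mid <- graph_neighbours(g9, 20)
  expect_equal(nrow(nb_mid), 8)
  expect_equal(nb_mid$c_ij, rep(1 / 8, 8))
  expect_equal(sort(nb_mid$j), c(16:19, 21:24))
  nb_nterm <- graph_neighbours(g9, 1)
  expect_equal(nrow(nb_nterm), 4)
  expect_equal(nb_nterm$c_ij, rep(1 / 4, 4))

  g1 <- window_neighbours(st, 1)
  expect_equal(nrow(g1$edges), 0)
  g_none <- env_graph(st, env_config("none", exposed_only = FALSE))
  expect_equal(nrow(g_none$edges), nrow(g1$edges))
  expect_error(window_neighbours(st, 4), "odd")
})

test_that("exposed-only restriction drops buried nodes and renormalises", {
  st <- small_chain()
  # force some residues buried to exercise the restriction
  st$residues$exposed[c(5, 6, 7, 20, 21)] <- FALSE
  g <- voronoi_neighbours(st, env_config("voronoi", exposed_only = TRUE))
  expect_false(any(c(5, 6, 7, 20, 21) %in% g$edges$i))
  expect_false(any(c(5, 6, 7, 20, 21) %in% g$edges$j))
  sums <- tapply(g$edges$c_ij, g$edges$i, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("degenerate lattice inputs tessellate via the deterministic joggle", {
  g <- expand.grid(x = 0:3, y = 0:3, z = 0:3)
  x <- 3.8 * as.matrix(g)
  expect_silent(e <- delaunay_edges(x, joggle = 1e-4))
  expect_gt(nrow(e), 100)
  expect_error(delaunay_edges(x[c(1, 1, 2, 3, 4), ]), "duplicate")
})

test_that("edge lists export with residue keys and strengths", {
  st <- small_chain()
  g <- voronoi_neighbours(st)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, st, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("res_i", "res_j", "c_ij"))
  expect_equal(nrow(tab), nrow(g$edges))
  expect_match(tab$res_i[1], "^A:\\d+:$")
})
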