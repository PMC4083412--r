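test_that("generic contact edges follow the 5 A closest-atom rule", {
  g <- build_rin(two_residue_structure(4.9))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$etype, "IAC")
  expect_equal(g$edges$distance, 4.9, tolerance = 1e-9)
  g2 <- build_rin(two_residue_structure(5.1))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("raising the contact cutoff never removes an edge", {
  s <- make_fixture_structure("hairpin", 16, sequence = "random", seed = 8)
  pair_set <- function(cutoff) {
    e <- build_rin(s, contact_cutoff = cutoff)$edges
    e <- e[e$etype == "IAC", ]
    paste(e$u, e$v)
  }
  p5 <- pair_set(5); p6 <- pair_set(6); p8 <- pair_set(8)
  expect_true(all(p5 %in% p6))
  expect_true(all(p6 %in% p8))
})

test_that("IAC distance equals the brute-force closest heavy-atom distance", {
  s <- make_fixture_structure("helix", 12, sequence = "random", seed = 2)
  g <- build_rin(s)
  e <- g$edges[g$edges$etype == "IAC", ]
  heavy <- s$atoms[s$atoms$element != "H", ]
  for (k in seq_len(nrow(e))) {
    i <- match(e$u[k], s$residues$key); j <- match(e$v[k], s$residues$key)
    ai <- heavy[heavy$res_idx == i, ]; aj <- heavy[heavy$res_idx == j, ]
    dmin <- min(sqrt(outer(seq_len(nrow(ai)), seq_len(nrow(aj)),
      function(p, q) (ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                     (ai$z[p] - aj$z[q])^2)))
    expect_equal(e$distance[k], dmin, tolerance = 1e-9)
  }
})

test_that("covalently adjacent residues are never connected", {
  s <- make_fixture_structure("helix", 6)
  g <- build_rin(s)
  idx_u <- match(g$edges$u, s$residues$key)
  idx_v <- match(g$edges$v, s$residues$key)
  expect_true(all(abs(idx_u - idx_v) >= 2))
})

test_that("a salt bridge fires at 3.8 A between Lys NZ and Asp OD1", {
  s <- two_residue_structure(3.8, aa = c("LYS", "ASP"),
    atoms1 = atom_df("NZ", "N", 0, 0, 0),
    atoms2 = atom_df("OD1", "O", 3.8, 0, 0))
  g <- build_rin(s)
  expect_setequal(g$edges$etype, c("IAC", "IONIC"))
  ion <- g$edges[g$edges$etype == "IONIC", ]
  expect_equal(ion$distance, 3.8, tolerance = 1e-9)
  # beyond the ionic threshold the salt bridge disappears
  s2 <- two_residue_structure(4.2, aa = c("LYS", "ASP"),
    atoms1 = atom_df("NZ", "N", 0, 0, 0),
    atoms2 = atom_df("OD1", "O", 4.2, 0, 0))
  expect_false("IONIC" %in% build_rin(s2)$edges$etype)
})

test_that("aromatic ring centroids at 6.0 A stack, at 7.0 A do not", {
  ring <- function(cx) {
    # flat hexagonal ring of radius 1.39 A centred at (cx, 0, 0)
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    data.frame(name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               element = "C", x = cx + 1.39 * cos(th), y = 1.39 * sin(th),
               z = 0, stringsAsFactors = FALSE)
  }
  mk <- function(d) toy_structure(list(list(aa = "PHE", atoms = ring(0)),
                                       list(aa = "PHE", atoms = ring(d))),
                                  resno = c(1L, 4L))
  expect_true("PIPISTACK" %in% build_rin(mk(6.0))$edges$etype)
  expect_false("PIPISTACK" %in% build_rin(mk(7.0))$edges$etype)
})

test_that("edges are invariant under residue-order reversal", {
  s <- make_fixture_structure("hairpin", 14, sequence = "random", seed = 6)
  g <- build_rin(s)
  rev_res <- s$residues[rev(seq_len(nrow(s$residues))),
                        c("chain", "resno", "ins", "aa")]
  rownames(rev_res) <- NULL
  rev_atoms <- s$atoms
  rev_atoms$res_idx <- nrow(s$residues) + 1L - rev_atoms$res_idx
  s_rev <- new_structure(rev_res, rev_atoms, s$pdb_id, s$chain)
  g_rev <- build_rin(s_rev)
  canon <- function(g) {
    e <- g$edges
    key <- paste(pmin(e$u, e$v), pmax(e$u, e$v), e$etype)
    sort(key)
  }
  expect_equal(canon(g_rev), canon(g))
})

test_that("subnetworks share the node set and split edges by type", {
  s <- two_residue_structure(3.8, aa = c("LYS", "ASP"),
    atoms1 = atom_df("NZ", "N", 0, 0, 0),
    atoms2 = atom_df("OD1", "O", 3.8, 0, 0))
  g <- build_rin(s)
  subs <- subnetworks(g)
  expect_named(subs, c("HBOND", "IAC", "PIPISTACK", "PICATION", "IONIC",
                       "ALL"))
  for (nm in names(subs))
    expect_equal(nrow(subs[[nm]]$nodes), nrow(g$nodes))
  expect_equal(nrow(subs$PIPISTACK$edges), 0L)
  expect_equal(nrow(subs$IONIC$edges), 1L)
  # typed subnetwork edge counts sum to at least the distinct pairs in ALL
  typed <- sum(vapply(subs[1:5], function(x) nrow(x$edges), numeric(1)))
  pairs_all <- nrow(unique(g$edges[, c("u", "v")]))
  expect_gte(typed, pairs_all)
})

test_that("centralities follow the stated conventions on simple graphs", {
  tri <- rin_from_adj(matrix(c(0,1,1, 1,0,1, 1,1,0), 3, 3))
  ct <- node_centralities(tri)
  expect_equal(ct$degree, rep(2L, 3))
  expect_equal(ct$clustering, rep(1, 3))
  expect_equal(ct$betweenness, rep(0, 3))
  path <- rin_from_adj(matrix(c(0,1,0, 1,0,1, 0,1,0), 3, 3))
  cp <- node_centralities(path, "A/2")
  expect_equal(cp$betweenness, 1)
  expect_equal(cp$closeness, 1)
  iso <- rin_from_adj(matrix(0, 2, 2))
  ci <- node_centralities(iso, "A/1")
  expect_equal(unlist(ci[, c("degree", "clustering", "closeness",
                             "betweenness")]),
               c(degree = 0, clustering = 0, closeness = 0, betweenness = 0))
  expect_error(node_centralities(tri, "A/99"), "unknown node")
})

test_that("neighbour composition counts each neighbour once", {
  # node 1 contacts ALA(2x) and GLY via multiple edge types
  s <- toy_structure(list(
    list(aa = "SER", atoms = atom_df("OG", "O", 0, 0, 0)),
    list(aa = "ALA", atoms = atom_df("CB", "C", 3, 0, 0)),
    list(aa = "ALA", atoms = atom_df("CB", "C", 0, 3, 0)),
    list(aa = "GLY", atoms = atom_df("N", "N", 0, 0, 3))
  ), resno = c(1L, 3L, 5L, 7L))
  g <- build_rin(s)
  nc <- neighbor_composition(g, s$residues$key[1])
  expect_equal(unname(nc$composition["ALA"]), 2L)
  expect_equal(unname(nc$composition["GLY"]), 1L)
  expect_equal(sum(nc$composition), 3L)
  expect_equal(nc$network_size, 4L)
  # the SER-GLY pair carries both HBOND and IAC, still one neighbour
  expect_gte(sum(g$edges$etype[g$edges$u == s$residues$key[1] |
                               g$edges$v == s$residues$key[1]] == "HBOND"), 1)
  expect_error(neighbor_composition(g, "A/99"), "unknown node")
})

test_that("centralities match the brute-force oracle on random graphs", {
  for (seed in 1:20) {
    n <- sample(4:25, 1)
    adj <- random_graph_adj(n, runif(1, 0.1, 0.5), seed = seed * 7)
    got <- node_centralities(rin_from_adj(adj))
    want <- oracle_centralities(adj)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
  }
})

test_that("node and edge tables are written for viewers", {
  s <- annotate_structure(make_fixture_structure("helix", 8))
  g <- build_rin(s)
  nf <- withr::local_tempfile(fileext = ".tsv")
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_rin_tables(g, s, nf, ef)
  nodes <- read.delim(nf); edges <- read.delim(ef)
  expect_equal(nrow(nodes), 8L)
  expect_true(all(c("degree", "clustering", "closeness", "betweenness")
                  %in% names(nodes)))
  expect_true(all(edges$etype %in% c("HBOND", "IAC", "PIPISTACK",
                                     "PICATION", "IONIC")))
})
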