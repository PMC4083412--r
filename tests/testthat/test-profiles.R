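test_that("FASTA alignments read with query mapping and format checks", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACD", ">a", "ACD", ">b", "ACD"), tf)
  msa <- read_msa(tf, "q")
  expect_equal(msa$n_rows, 3L)
  expect_equal(msa$n_cols, 3L)
  expect_equal(msa$query_row, 1L)

  writeLines(c(">q", "ACDE", ">a", "ACD"), tf)
  expect_error(read_msa(tf), "ragged")
  writeLines(c(">a", "ACD"), tf)
  expect_error(read_msa(tf, "zz"), "not found")
})

test_that("query gaps are skipped when mapping structure positions", {
  msa <- msa_from_rows(c("A-CD", "AACD"))
  s <- toy_structure(list(
    list(aa = "ALA", atoms = atom_df("CA", "C", 0, 0, 0)),
    list(aa = "CYS", atoms = atom_df("CA", "C", 4, 0, 0)),
    list(aa = "ASP", atoms = atom_df("CA", "C", 8, 0, 0))))
  expect_equal(msa_column_map(msa, s), c(1L, 3L, 4L))
  # mismatch names the first bad structure position
  s$residues$aa[2] <- "GLY"
  s2 <- new_structure(s$residues[, c("chain", "resno", "ins", "aa")],
                      s$atoms)
  expect_error(msa_column_map(msa, s2), "position 2")
})

test_that("conservation spans its range and matches hand computation", {
  one_type <- msa_from_rows(rep("A", 6))
  expect_equal(conservation(one_type, 1), 1.0)
  all20 <- msa_from_rows(c("A","R","N","D","C","Q","E","G","H","I",
                           "L","K","M","F","P","S","T","W","Y","V"))
  expect_equal(conservation(all20, 1), 0.0)
  half <- msa_from_rows(c("A", "A", "C", "C"))
  expect_equal(conservation(half, 1), 1 - 1 / log2(20), tolerance = 1e-12)
  gaps <- msa_from_rows(c("-", "-"))
  expect_equal(conservation(gaps, 1), 0)
})

test_that("mutual information behaves as an information measure", {
  # identical columns: MI = H = 1 bit
  msa <- msa_from_rows(c("AA", "AA", "CC", "CC"))
  expect_equal(mutual_information(msa, 1, 2), 1.0, tolerance = 1e-12)
  # independent columns with identical marginals at large n
  set.seed(31)
  rows <- paste0(sample(c("A", "C"), 10000, TRUE),
                 sample(c("A", "C"), 10000, TRUE))
  big <- msa_from_rows(rows)
  expect_lt(mutual_information(big, 1, 2), 0.01)
  # fewer than two co-ungapped rows
  tiny <- msa_from_rows(c("A-", "-C"))
  expect_equal(mutual_information(tiny, 1, 2), 0)
})

test_that("MI is symmetric, non-negative and bounded by column entropies", {
  set.seed(77)
  ab <- c("A","R","N","D","C","Q","E","G","-")
  for (rep_ in 1:25) {
    m <- matrix(sample(ab, 30 * 4, TRUE), 30, 4)
    msa <- rinstab:::msa_from_matrix(m)
    i <- sample(4, 1); j <- sample(4, 1)
    mij <- mutual_information(msa, i, j)
    expect_gte(mij, -1e-12)
    expect_equal(mij, mutual_information(msa, j, i), tolerance = 1e-12)
    if (i != j) {
      ent <- function(col) {
        p <- table(m[, col][m[, col] != "-"]) / sum(m[, col] != "-")
        -sum(p * log2(p))
      }
      expect_lte(mij, min(ent(i), ent(j)) + 1e-9)
    }
  }
})

test_that("conservation is invariant under row permutation", {
  set.seed(5)
  m <- matrix(sample(c("A", "C", "G", "-"), 40, TRUE), 10, 4)
  msa <- rinstab:::msa_from_matrix(m)
  perm <- rinstab:::msa_from_matrix(m[sample(10), , drop = FALSE])
  for (cc in 1:4)
    expect_equal(conservation(msa, cc), conservation(perm, cc))
})

test_that("a partner column constant given the query residue has purity 1", {
  msa <- msa_from_rows(c("AC", "AC", "GT", "GT"))
  expect_equal(acp(msa, 1, contacts = 2L), 1.0)
  # an even split has purity 0.5
  msa2 <- msa_from_rows(c("AC", "AT", "AC", "AT"))
  expect_equal(acp(msa2, 1, contacts = 2L), 0.5)
})

test_that("potential scores reduce to zero in the uniform/no-contact limits", {
  s <- compute_rsa(make_fixture_structure("helix", 10,
                                          sequence = "random", seed = 9))
  uniform <- list(contact = matrix(1, 20, 20, dimnames = list(
                    rinstab:::AA3, rinstab:::AA3)),
                  p_buried_given_aa = setNames(rep(0.5, 20), rinstab:::AA3),
                  p_buried = 0.5)
  ps <- potential_scores(s, ref = uniform)
  expect_equal(ps$pairwise, rep(0, 10))
  expect_equal(ps$solvation, rep(0, 10))
  # a residue with no contacts has pairwise 0
  iso <- compute_rsa(two_residue_structure(30))
  ps2 <- potential_scores(iso, ref = uniform)
  expect_equal(ps2$pairwise, c(0, 0))
})

test_that("solvation follows the burial log-odds", {
  # single fully exposed residue; reference with
  # P(buried|ALA)=0.2, P(buried)=0.6 -> exposed ratio (0.8/0.4)=2
  s <- compute_rsa(toy_structure(list(
    list(aa = "ALA", atoms = atom_df("CA", "C", 0, 0, 0)))))
  ref <- list(contact = matrix(1, 20, 20, dimnames = list(
                rinstab:::AA3, rinstab:::AA3)),
              p_buried_given_aa = setNames(rep(0.2, 20), rinstab:::AA3),
              p_buried = 0.6)
  ps <- potential_scores(s, rin = rin_from_single(s), ref = ref)
  expect_equal(ps$solvation, -log(2), tolerance = 1e-12)
})

test_that("potential scores are rigid-motion invariant", {
  s <- compute_rsa(make_fixture_structure("hairpin", 12,
                                          sequence = "random", seed = 3))
  base <- potential_scores(s)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11; s2$atoms$y <- xyz[, 2] - 4
  s2$atoms$z <- xyz[, 3] + 2
  s2 <- compute_rsa(s2)
  moved <- potential_scores(s2)
  expect_equal(moved$pairwise, base$pairwise, tolerance = 1e-9)
  expect_equal(moved$solvation, base$solvation, tolerance = 1e-9)
})

test_that("external score files override the built-in provider", {
  s <- make_fixture_structure("helix", 5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tname\tvalue", "2\tpairwise\t1.5",
               "2\tsolvation\t-0.25"), tf)
  sc <- load_external_scores(tf, s)
  expect_equal(sc$pairwise[2], 1.5)
  expect_equal(sc$solvation[2], -0.25)
  expect_equal(sc$pairwise[1], 0)
  writeLines(c("position\tname\tvalue", "2\tbogus\t1"), tf)
  expect_error(load_external_scores(tf, s), "unknown score name")
})

test_that("missing MSA falls back to neutral features with a warning", {
  s <- make_fixture_structure("helix", 6)
  expect_warning(ev <- evo_profile(s, NULL), "no MSA")
  expect_equal(ev$conservation, rep(1, 6))
  expect_equal(ev$mi, rep(0, 6))
  expect_equal(ev$acp, rep(1, 6))
})
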