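# Shared fixtures built in code at test time.

# Minimal hand-placed structure: residues given as list(aa, atoms) where
# atoms is a data.frame(name, element, x, y, z).
toy_structure <- function(residues, chain = "A", resno = NULL) {
  if (is.null(resno)) resno <- seq_along(residues)
  res <- data.frame(chain = chain, resno = resno, ins = "",
                    aa = vapply(residues, function(r) r$aa, ""),
                    stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    a <- residues[[i]]$atoms
    data.frame(res_idx = i, name = a$name, element = a$element,
               x = a$x, y = a$y, z = a$z, occupancy = 1,
               stringsAsFactors = FALSE)
  }))
  new_structure(res, atoms, pdb_id = "TOY", chain = chain)
}

atom_df <- function(name, element, x, y, z) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# two single-atom GLY residues separated by `d` along x, numbered 1 and 3
# so the sequence-separation rule does not interfere
two_residue_structure <- function(d, aa = c("GLY", "GLY"),
                                  atoms1 = NULL, atoms2 = NULL) {
  a1 <- if (is.null(atoms1)) atom_df("CA", "C", 0, 0, 0) else atoms1
  a2 <- if (is.null(atoms2)) atom_df("CA", "C", d, 0, 0) else atoms2
  toy_structure(list(list(aa = aa[1], atoms = a1),
                     list(aa = aa[2], atoms = a2)),
                resno = c(1L, 3L))
}

toy_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.423   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.963   2.849   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.480   2.706   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.030   1.604   0.000  1.00  0.00           O",
    "ATOM     10  N   ALA A   3       6.179   3.836   0.000  1.00  0.00           N",
    "ATOM     11  CA  ALA A   3       7.637   3.829   0.000  1.00  0.00           C",
    "ATOM     12  C   ALA A   3       8.190   5.250   0.000  1.00  0.00           C",
    "ATOM     13  O   ALA A   3       7.438   6.223   0.000  1.00  0.00           O",
    "ATOM     14  CB  ALA A   3       8.166   3.051   1.199  1.00  0.00           C",
    "TER", "END", sep = "\n")
}

# annotated fixture structures shared by encoding/model/acceptance tests
fixture_pair <- function() {
  hlx <- annotate_structure(make_fixture_structure("helix", 30,
                                                   sequence = "random",
                                                   seed = 3))
  hpn <- annotate_structure(make_fixture_structure("hairpin", 20,
                                                   sequence = "random",
                                                   seed = 4))
  hlx$pdb_id <- "HLX"; hpn$pdb_id <- "HPN"
  list(HLX = hlx, HPN = hpn)
}

# synthetic-target coefficients, scaled once so sd(X %*% coef) = 1.5
# kcal/mol (a realistic spread for single-mutation stability data)
recovery_coefficients <- function(X, seed = 42) {
  set.seed(seed)
  coef <- rnorm(ncol(X), 0, 0.1) * (runif(ncol(X)) < 0.3)
  sig <- drop(X %*% coef)
  coef * 1.5 / sd(sig)
}

# edgeless network over a structure's residues (for single-residue cases
# where build_rin refuses to run)
rin_from_single <- function(s) {
  out <- list(nodes = data.frame(key = s$residues$key, aa = s$residues$aa,
                                 stringsAsFactors = FALSE),
              edges = data.frame(u = character(), v = character(),
                                 etype = character(), distance = numeric(),
                                 atom_u = character(), atom_v = character(),
                                 stringsAsFactors = FALSE),
              pdb_id = s$pdb_id, chain = s$chain)
  class(out) <- "rin"
  out
}

msa_from_rows <- function(rows, ids = NULL) {
  m <- do.call(rbind, strsplit(rows, ""))
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  rownames(m) <- ids
  rinstab:::msa_from_matrix(m)
}
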