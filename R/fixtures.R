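## Deterministic synthetic structures built from ideal internal
## coordinates. These provide desk-scale inputs for the whole pipeline:
## an alpha-helix, a two-stranded antiparallel beta-hairpin, and a
## "cage" (one residue enclosed by an occluding shell) for accessibility
## checks. Backbones carry N, CA, C, O plus an ideal CB for non-glycine
## residues; side chains beyond CB are not modelled.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension reference frame: place atom d bonded to c, with bond
# angle b-c-d and torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal backbone from phi/psi/omega torsions. Returns N/CA/C/O/CB matrices.
build_backbone_from_torsions <- function(phi, psi, omega = NULL,
                                         glycine = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(glycine)) glycine <- rep(FALSE, n)
  b <- list(NCA = 1.458, CAC = 1.525, CN = 1.329, CO = 1.231, CACB = 1.521)
  a <- list(NCAC = 111.2, CACN = 116.2, CNCA = 121.7, CACO = 120.8,
            NCACB = 110.5)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b$NCA, 0, 0)
  ang <- a$NCAC * pi / 180
  C[1, ] <- CA[1, ] + b$CAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            b$CN, a$CACN, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            b$NCA, a$CNCA, omega[i - 1])
      C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            b$CAC, a$NCAC, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b$CO, a$CACO,
                         psi[i] + 180)
    if (!glycine[i]) {
      # ideal tetrahedral CB, L-configuration
      u <- N[i, ] - CA[i, ]; u <- u / sqrt(sum(u^2))
      v <- C[i, ] - CA[i, ]; v <- v / sqrt(sum(v^2))
      bis <- (u + v); bis <- bis / sqrt(sum(bis^2))
      nrm <- cross3(u, v); nrm <- nrm / sqrt(sum(nrm^2))
      CB[i, ] <- CA[i, ] + b$CACB * (-sqrt(1 / 3) * bis + sqrt(2 / 3) * nrm)
    }
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

backbone_to_structure <- function(bb, sequence, pdb_id, chain = "A",
                                  resno_start = 1L) {
  n <- nrow(bb$N)
  aa3 <- aa_one_to_three(strsplit(sequence, "")[[1]])
  stopifnot(length(aa3) == n)
  res <- data.frame(chain = chain, resno = seq.int(resno_start,
                                                   length.out = n),
                    ins = "", aa = aa3, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (aa3[i] != "GLY" && all(is.finite(bb$CB[i, ]))) {
      nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, bb$CB[i, ])
    }
    rows[[i]] <- data.frame(res_idx = i, name = nm, element = el,
                            x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                            z = round(xyz[, 3], 3), occupancy = 1,
                            stringsAsFactors = FALSE)
  }
  new_structure(res, do.call(rbind, rows), pdb_id = pdb_id, chain = chain)
}

#' Generate a synthetic test structure
#'
#' Builds small, fully deterministic structures from ideal geometry:
#' `"helix"` (phi = -57, psi = -47), `"hairpin"` (two antiparallel
#' strands, phi = -139 / psi = 135, joined by a two-residue turn), and
#' `"cage"` (a central residue surrounded by an occluding glycine shell
#' at the given radius, for burial tests). Coordinates are rounded to
#' PDB precision (3 decimals) so the objects round-trip exactly through
#' [write_pdb()] and [parse_pdb()]. The `seed` perturbs nothing
#' geometric; it only selects the sequence when `sequence = "random"`.
#'
#' @param kind one of `"helix"`, `"hairpin"`, `"cage"`.
#' @param n_residues chain length (>= 4); for hairpins an even strand
#'   split is used with a two-residue turn.
#' @param sequence one-letter sequence of length `n_residues`, `"polyA"`
#'   (default) or `"random"` (seeded draw over the 20 standard types,
#'   proline excluded so backbone torsions stay ideal).
#' @param seed integer seed used only for `sequence = "random"`.
#' @param cage_radius shell radius in Angstrom for `kind = "cage"`.
#' @param cage_points number of shell atoms for `kind = "cage"`.
#' @return an `rin_structure`.
#' @export
make_fixture_structure <- function(kind = c("helix", "hairpin", "cage"),
                                   n_residues = 15, sequence = "polyA",
                                   seed = 1L, cage_radius = 6,
                                   cage_points = 250) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 4)
  seq1 <- fixture_sequence(sequence, n_residues, seed)
  if (kind == "helix") {
    bb <- build_backbone_from_torsions(rep(-57, n_residues),
                                       rep(-47, n_residues),
                                       glycine = strsplit(seq1, "")[[1]] == "G")
    return(backbone_to_structure(bb, seq1, pdb_id = "HLX1"))
  }
  if (kind == "hairpin") {
    ns <- (n_residues - 2L) %/% 2L
    n2 <- n_residues - 2L - ns
    phi <- c(rep(-139, ns), 60, -80, rep(-139, n2))
    psi <- c(rep(135, ns), -120, 0, rep(135, n2))
    bb <- build_backbone_from_torsions(phi, psi,
                                       glycine = strsplit(seq1, "")[[1]] == "G")
    return(backbone_to_structure(bb, seq1, pdb_id = "HPN1"))
  }
  # cage: one central residue (helix geometry for the backbone) plus a
  # shell of single-atom glycine residues on a sphere around its centroid
  core <- make_fixture_structure("helix", 5, sequence = "polyA")
  mid <- which(core$residues$resno == 3)
  sel <- core$atoms$res_idx == mid
  atoms <- core$atoms[sel, , drop = FALSE]
  atoms$res_idx <- 1L
  centroid <- colMeans(cbind(atoms$x, atoms$y, atoms$z))
  shell <- sphere_points(cage_points) * cage_radius
  shell <- sweep(shell, 2, centroid, "+")
  res <- data.frame(chain = "A",
                    resno = seq_len(1 + cage_points),
                    ins = "",
                    aa = c(substr(sequence_or_ala(seq1), 1, 3),
                           rep("GLY", cage_points)),
                    stringsAsFactors = FALSE)
  shell_atoms <- data.frame(res_idx = 1L + seq_len(cage_points),
                            name = "CA", element = "C",
                            x = round(shell[, 1], 3),
                            y = round(shell[, 2], 3),
                            z = round(shell[, 3], 3),
                            occupancy = 1, stringsAsFactors = FALSE)
  new_structure(res, rbind(atoms, shell_atoms), pdb_id = "CAGE")
}

sequence_or_ala <- function(seq1) {
  aa_one_to_three(substr(seq1, 1, 1))
}

fixture_sequence <- function(sequence, n, seed) {
  if (identical(sequence, "polyA")) return(strrep("A", n))
  if (identical(sequence, "random")) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    return(paste(sample(setdiff(AA1, "P"), n, replace = TRUE), collapse = ""))
  }
  stopifnot(nchar(sequence) == n)
  toupper(sequence)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
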