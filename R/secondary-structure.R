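## Three-state secondary-structure assignment in the Kabsch-Sander style.
##
## A backbone hydrogen bond between the CO group of residue i and the NH
## group of residue j is scored with the electrostatic energy
##   E = 0.084 * (1/d(ON) + 1/d(CH) - 1/d(OH) - 1/d(CN)) * 332 kcal/mol
## and accepted when E < -0.5 kcal/mol. The amide hydrogen is taken from
## the file when present, otherwise placed 1 A from N along the previous
## residue's O->C direction (the classic DSSP construction).

backbone_coords <- function(s) {
  n <- nrow(s$residues)
  get <- function(name) {
    m <- matrix(NA_real_, n, 3)
    sel <- s$atoms$name == name
    m[s$atoms$res_idx[sel], ] <- cbind(s$atoms$x[sel], s$atoms$y[sel],
                                       s$atoms$z[sel])
    m
  }
  list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"),
       H = get("H"))
}

amide_hydrogens <- function(bb) {
  n <- nrow(bb$N)
  H <- bb$H
  for (i in seq_len(n)[-1]) {
    if (all(is.finite(H[i, ]))) next
    v <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (!all(is.finite(v)) || !all(is.finite(bb$N[i, ]))) next
    H[i, ] <- bb$N[i, ] + v / sqrt(sum(v^2))
  }
  H[1, ] <- NA_real_  # N-terminal amide has no carbonyl to define it
  H
}

# logical n x n matrix: TRUE when CO(i) donates to NH(j)
ks_hbond_matrix <- function(bb, cutoff = -0.5) {
  n <- nrow(bb$N)
  H <- amide_hydrogens(bb)
  hb <- matrix(FALSE, n, n)
  ok_co <- is.finite(bb$C[, 1]) & is.finite(bb$O[, 1])
  ok_nh <- is.finite(bb$N[, 1]) & is.finite(H[, 1])
  d <- function(a, b) sqrt(sum((a - b)^2))
  for (i in which(ok_co)) {
    for (j in which(ok_nh)) {
      if (abs(i - j) < 2) next
      dON <- d(bb$O[i, ], bb$N[j, ])
      if (dON > 5.2) next  # beyond any plausible H-bond; skip the rest
      E <- 27.888 * (1 / dON +
                     1 / d(bb$C[i, ], H[j, ]) -
                     1 / d(bb$O[i, ], H[j, ]) -
                     1 / d(bb$C[i, ], bb$N[j, ]))
      if (E < cutoff) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign three-state secondary structure
#'
#' Labels each residue H (helix), E (strand) or C (coil) from backbone
#' hydrogen-bond patterns. A four-turn at i is a CO(i) to NH(i+4) bond;
#' residues covered by two consecutive four-turns are helical. Strand
#' residues are members of a parallel or antiparallel bridge formed by the
#' usual paired bond patterns. Helix takes precedence over strand;
#' residues with incomplete backbones, and all residues of chains shorter
#' than five residues, are coil.
#'
#' @param s an `rin_structure` with backbone atoms N, CA, C, O.
#' @param energy_cutoff hydrogen-bond acceptance threshold, kcal/mol.
#' @return the structure with `residues$ss` filled.
#' @export
assign_secondary_structure <- function(s, energy_cutoff = -0.5) {
  n <- nrow(s$residues)
  ss <- rep("C", n)
  if (n >= 5) {
    bb <- backbone_coords(s)
    hb <- ks_hbond_matrix(bb, energy_cutoff)
    # helices: four-turn at i when CO(i)->NH(i+4)
    turn <- rep(FALSE, n)
    for (i in seq_len(max(0, n - 4))) turn[i] <- hb[i, i + 4]
    helix <- rep(FALSE, n)
    for (i in 2:max(2, n - 4)) {
      if (turn[i - 1] && turn[i]) helix[i:(i + 3)] <- TRUE
    }
    # bridges: parallel / antiparallel bond patterns, |i-j| >= 3
    bridge <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3) next
        anti <- (hb[i, j] && hb[j, i]) ||
                (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        para <- (hb[i - 1, j] && hb[j, i + 1]) ||
                (hb[j - 1, i] && hb[i, j + 1])
        if (anti || para) bridge[c(i, j)] <- TRUE
      }
    }
    ss[bridge] <- "E"
    ss[helix] <- "H"
  }
  s$residues$ss <- ss
  s
}
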