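#' @keywords internal
"_PACKAGE"

## Amino-acid lookup tables used across the package.

# Fixed alphabetical ordering of the 20 standard three-letter codes.
# This ordering defines the index layout of every one-hot block and of
# the neighbour-composition vector.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
         "M", "F", "P", "S", "T", "W", "Y", "V")

names(AA1) <- AA3

#' Convert between one- and three-letter amino-acid codes
#'
#' @param aa character vector of residue codes.
#' @return character vector of the converted codes.
#' @examples
#' aa_three_to_one("ALA")
#' aa_one_to_three("W")
#' @export
aa_three_to_one <- function(aa) {
  out <- AA1[toupper(aa)]
  if (anyNA(out)) stop("non-standard residue code: ",
                       paste(aa[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(aa) {
  idx <- match(toupper(aa), AA1)
  if (anyNA(idx)) stop("non-standard residue code: ",
                       paste(aa[is.na(idx)], collapse = ", "))
  AA3[idx]
}

is_standard_aa <- function(aa3) toupper(aa3) %in% AA3

# Maximum accessible surface areas (A^2) per residue type, used to
# normalise absolute ASA into relative solvent accessibility.
# Values follow the Rost & Sander (1994) reference table.
MAX_ASA <- c(
  ALA = 106, ARG = 248, ASN = 157, ASP = 163, CYS = 135,
  GLN = 198, GLU = 194, GLY =  84, HIS = 184, ILE = 169,
  LEU = 164, LYS = 205, MET = 188, PHE = 197, PRO = 136,
  SER = 130, THR = 142, TRP = 227, TYR = 222, VAL = 142
)

# Van der Waals radii (A) by element for surface-area computation.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70  # unknown elements treated as carbon-like
  unname(r)
}

# Atom names forming charged groups and aromatic rings, used for typed
# residue-interaction-network edges.
CHARGED_POS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
CHARGED_NEG <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
CATION_ATOM <- list(LYS = "NZ", ARG = "CZ")
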