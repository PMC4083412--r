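## Accessible surface area by the Shrake-Rupley point-sampling method.

# Near-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Accessible surface area and relative solvent accessibility
#'
#' Computes per-atom accessible surface area by rolling a probe sphere
#' over van der Waals surfaces sampled with a fixed set of sphere points,
#' sums it per residue, and normalises by the residue type's maximum
#' accessible area (Rost & Sander reference values) to give RSA in
#' `[0,1]`. Hydrogens are excluded from both the surface and the
#' occluding set.
#'
#' @param s an `rin_structure`.
#' @param probe_radius solvent probe radius in Angstrom, default 1.4.
#' @param sphere_points number of sample points per atom, default 92.
#' @return the structure with `residues$asa` (A^2) and `residues$rsa` filled.
#' @export
compute_rsa <- function(s, probe_radius = 1.4, sphere_points = 92) {
  stopifnot(probe_radius >= 0, sphere_points >= 12)
  heavy <- s$atoms[toupper(s$atoms$element) != "H", , drop = FALSE]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  radii <- vdw_radius(heavy$element) + probe_radius
  pts <- sphere_points(sphere_points)
  n_at <- nrow(heavy)
  asa_atom <- numeric(n_at)
  # neighbour lists via squared-distance screening
  max_r <- max(radii)
  for (i in seq_len(n_at)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (radii[i] + max_r)^2 & d2 > 0)
    nb <- nb[d2[nb] < (radii[i] + radii[nb])^2]
    surf <- pts * radii[i]
    surf <- sweep(surf, 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, nrow(surf))
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
               (surf[, 3] - xyz[j, 3])^2
        acc <- acc & (dj2 >= radii[j]^2)
      }
      frac <- sum(acc) / nrow(surf)
    } else {
      frac <- 1
    }
    asa_atom[i] <- frac * 4 * pi * radii[i]^2
  }
  asa <- vapply(seq_len(nrow(s$residues)), function(r)
    sum(asa_atom[heavy$res_idx == r]), numeric(1))
  s$residues$asa <- asa
  s$residues$rsa <- pmin(1, pmax(0, asa / MAX_ASA[s$residues$aa]))
  s
}

#' Annotate a structure with secondary structure and accessibility
#'
#' Convenience wrapper running [assign_secondary_structure()] followed by
#' [compute_rsa()].
#'
#' @inheritParams compute_rsa
#' @return annotated `rin_structure`.
#' @export
annotate_structure <- function(s, probe_radius = 1.4, sphere_points = 92) {
  compute_rsa(assign_secondary_structure(s),
              probe_radius = probe_radius, sphere_points = sphere_points)
}
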