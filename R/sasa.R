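# van der Waals radii (Angstrom) for SASA
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# near-uniform points on the unit sphere (golden-spiral construction)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a 92-point test sphere per atom and a 1.4 Angstrom
#' probe, summed per residue. Used to decorate RIN nodes when no external
#' DSSP program is available.
#'
#' @param system A \code{molecular_system}.
#' @param frame Frame index.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom sphere (default 92).
#' @return Numeric vector of per-residue SASA (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(system, frame = 1, probe = 1.4,
                               n_points = 92) {
  at <- system$atoms
  xyz <- system$frames[[frame]]
  radii <- .vdw_radii[at$element]
  radii[is.na(radii)] <- 1.7
  radii <- radii + probe
  pts <- sphere_points(n_points)
  n <- nrow(at)
  area <- numeric(n)
  # neighbour search radius: two largest inflated radii
  rmax <- max(radii)
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (radii[i] + rmax)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < radii[i] + radii[nb]]
    test <- pts * radii[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- rowSums((test - matrix(xyz[j, ], n_points, 3, byrow = TRUE))^2)
      accessible <- accessible & dd >= radii[j]^2
      if (!any(accessible)) break
    }
    area[i] <- 4 * pi * radii[i]^2 * sum(accessible) / n_points
  }
  rid <- atom_residue_index(system)
  as.numeric(tapply(area, factor(rid, levels = seq_len(nrow(system$residues))),
                    sum, default = 0))
}
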