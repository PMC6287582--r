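#' Interaction detection criteria
#'
#' All tunable thresholds for the nine interaction detectors, with the
#' published defaults. Distances in Angstrom, angles in degrees, energies in
#' kcal/mol. Every "<= d" distance criterion is inclusive.
#'
#' @param calpha_d C-alpha contact distance cutoff (default 8).
#' @param hb_d Hydrogen-bond donor--acceptor distance cutoff (default 3).
#' @param hb_angle_min Minimum D-H...A angle at the hydrogen (default 120).
#' @param sb_d Salt-bridge N--O distance cutoff (default 6).
#' @param ss_d Disulfide S--S distance cutoff (default 3).
#' @param ss_dihedral_lo,ss_dihedral_hi Allowed band for |chi_SS| =
#'   |dihedral(CB-SG-SG-CB)| in degrees (defaults 60 and 90).
#' @param pipi_d Aromatic ring centroid--centroid cutoff (default 6).
#' @param catpi_d Ring-centroid--cation cutoff (default 7).
#' @param catpi_angle_bands Allowed bands for the angle between the ring
#'   normal and the centroid-to-cation vector; a 2-column matrix of
#'   \code{[lo, hi]} rows (default \code{[0,60]} and \code{[120,180]}, i.e.
#'   the cation sits over a ring face, symmetric in the normal sign).
#' @param argarg_d Arg--Arg guanidinium centroid cutoff (default 5).
#' @param coulomb_cutoff Atom-pair cutoff for Coulomb and Lennard-Jones
#'   summation (default 12).
#' @param coulomb_energy_thr Minimum |E| (kcal/mol) for a Coulomb edge
#'   (default 1.0).
#' @param vdw_energy_thr Maximum energy for a van der Waals edge; an edge is
#'   an attractive contact with E at or below this value (default -0.1).
#' @param seq_exclusion_calpha C-alpha contacts exclude residue pairs within
#'   this many sequence positions on the same chain (default 2).
#' @param dielectric Relative dielectric constant (default 1).
#' @return An object of class \code{interaction_criteria}.
#' @export
interaction_criteria <- function(calpha_d = 8,
                                 hb_d = 3,
                                 hb_angle_min = 120,
                                 sb_d = 6,
                                 ss_d = 3,
                                 ss_dihedral_lo = 60,
                                 ss_dihedral_hi = 90,
                                 pipi_d = 6,
                                 catpi_d = 7,
                                 catpi_angle_bands = rbind(c(0, 60),
                                                           c(120, 180)),
                                 argarg_d = 5,
                                 coulomb_cutoff = 12,
                                 coulomb_energy_thr = 1.0,
                                 vdw_energy_thr = -0.1,
                                 seq_exclusion_calpha = 2L,
                                 dielectric = 1) {
  dists <- c(calpha_d, hb_d, sb_d, ss_d, pipi_d, catpi_d, argarg_d,
             coulomb_cutoff)
  if (any(dists <= 0)) stop("interaction_criteria(): distances must be > 0")
  if (ss_dihedral_lo > ss_dihedral_hi) {
    stop("interaction_criteria(): dihedral band requires lo <= hi")
  }
  bands <- as.matrix(catpi_angle_bands)
  if (ncol(bands) != 2 || any(bands < 0) || any(bands > 180)) {
    stop("interaction_criteria(): angle bands must lie in [0, 180]")
  }
  structure(
    list(
      calpha_d = calpha_d, hb_d = hb_d, hb_angle_min = hb_angle_min,
      sb_d = sb_d, ss_d = ss_d,
      ss_dihedral_lo = ss_dihedral_lo, ss_dihedral_hi = ss_dihedral_hi,
      pipi_d = pipi_d, catpi_d = catpi_d, catpi_angle_bands = bands,
      argarg_d = argarg_d,
      coulomb_cutoff = coulomb_cutoff,
      coulomb_energy_thr = coulomb_energy_thr,
      vdw_energy_thr = vdw_energy_thr,
      seq_exclusion_calpha = as.integer(seq_exclusion_calpha),
      dielectric = dielectric
    ),
    class = "interaction_criteria"
  )
}

#' Interaction type names
#'
#' The nine interaction classes, in the canonical order used for sorting
#' detection records and naming output files.
#' @return Character vector of type names.
#' @export
interaction_types <- function() {
  c("CALPHA", "HBOND", "SALT_BRIDGE", "DISULFIDE", "CATION_PI", "PI_PI",
    "ARG_ARG", "COULOMB", "VDW")
}
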