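#' Construct a MolecularSystem
#'
#' The single source of structural truth: an atom table, a residue table
#' derived from it, and one or more coordinate frames. Charges and
#' Lennard-Jones parameters are zero until assigned (from a PSF or from the
#' bundled residue templates plus a CHARMM-format parameter file).
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resno}, \code{chain},
#'   \code{insert}, and optionally \code{type} (force-field atom type),
#'   \code{charge}, \code{lj_epsilon}, \code{lj_rmin_half}.
#' @param frames list of numeric n_atoms x 3 matrices (Angstrom).
#' @param bonds optional 2-column integer matrix of atom-index bonds.
#' @param frame_times optional numeric vector of frame times (ps).
#' @return An object of class \code{molecular_system}.
#' @export
molecular_system <- function(atoms, frames, bonds = NULL, frame_times = NULL) {
  stopifnot(is.data.frame(atoms), length(frames) >= 1)
  atoms$serial <- as.integer(atoms$serial)
  atoms$insert <- as.character(if (is.null(atoms$insert)) "" else atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms$element[is.na(atoms$element) | atoms$element == ""] <-
    guess_element(atoms$name[is.na(atoms$element) | atoms$element == ""])
  if (is.null(atoms$type)) atoms$type <- NA_character_
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$lj_epsilon)) atoms$lj_epsilon <- 0
  if (is.null(atoms$lj_rmin_half)) atoms$lj_rmin_half <- 0
  atoms$is_hydrogen <- atoms$element == "H"
  for (fr in frames) {
    if (!is.matrix(fr) || nrow(fr) != nrow(atoms) || ncol(fr) != 3) {
      stop("molecular_system(): every frame needs one (x,y,z) row per atom")
    }
    if (!all(is.finite(fr))) stop("molecular_system(): non-finite coordinates")
  }
  sys <- structure(
    list(
      atoms = atoms,
      residues = derive_residues(atoms),
      frames = frames,
      frame_times = frame_times,
      bonds = bonds
    ),
    class = "molecular_system"
  )
  sys
}

# Residue table: residues partition the atom list in file order.
# Identity is (chain, resno, insert); ordering is first-appearance order,
# which for well-formed files equals (chain, resno, insert) order.
derive_residues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  change <- c(TRUE, key[-1] != key[-length(key)])
  first <- which(change)
  last <- c(first[-1] - 1L, nrow(atoms))
  res <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    resname = atoms$resname[first],
    first = first,
    last = last,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(res$chain, res$resno, res$insert, sep = "\r"))) {
    stop("derive_residues(): residues do not partition the atom list ",
         "(same (chain, resno, insert) appears in disjoint atom spans)")
  }
  res
}

#' Residue node labels
#'
#' Stable Cytoscape-friendly identifiers of the form
#' \code{chain:resname:resno} (plus \code{:icode} when an insertion code is
#' present).
#'
#' @param system A \code{molecular_system}.
#' @return Character vector, one label per residue.
#' @export
residue_labels <- function(system) {
  r <- system$residues
  lab <- paste(r$chain, r$resname, r$resno, sep = ":")
  has_ic <- !is.na(r$insert) & r$insert != ""
  lab[has_ic] <- paste(lab[has_ic], r$insert[has_ic], sep = ":")
  lab
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf(
    "molecular_system: %d atoms, %d residues, %d chain(s), %d frame(s)\n",
    nrow(x$atoms), nrow(x$residues), length(unique(x$atoms$chain)),
    length(x$frames)
  ))
  invisible(x)
}

#' Number of frames in a system
#' @param system A \code{molecular_system}.
#' @return Integer frame count.
#' @export
n_frames <- function(system) length(system$frames)

# Element from atom name under PDB conventions. Digits and primes are
# stripped; a leading H after that always means hydrogen for protein atoms
# (metals never survive strip_non_protein).
guess_element <- function(name) {
  nm <- gsub("[0-9'\"]", "", trimws(name))
  el <- toupper(substr(nm, 1, 1))
  el[el == ""] <- "X"
  el
}

# standard atomic masses (u) for center-of-mass work
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

atom_masses <- function(system) {
  m <- .atomic_masses[system$atoms$element]
  m[is.na(m)] <- 12.011
  unname(m)
}

# amino-acid residue names retained by strip_non_protein
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
.his_variants <- c("HSD", "HSE", "HSP", "HID", "HIE", "HIP")

#' Remove everything but protein residues
#'
#' Keeps atoms belonging to the 20 standard amino acids plus histidine
#' protonation variants (HSD/HSE/HSP and the AMBER-style HID/HIE/HIP), which
#' must survive filtering because protonated histidine acts as a cation.
#' Waters, ions, ligands and other heteroatoms are dropped; atom order is
#' preserved and residue spans re-derived.
#'
#' @param system A \code{molecular_system}.
#' @param extra_residues Additional residue names to retain.
#' @return Filtered \code{molecular_system}.
#' @export
strip_non_protein <- function(system, extra_residues = character(0)) {
  keep_names <- c(.standard_aa, .his_variants, extra_residues)
  keep <- system$atoms$resname %in% keep_names
  if (!any(keep)) {
    stop("strip_non_protein(): no protein residues remain (empty system)")
  }
  subset_atoms(system, which(keep))
}

# Subset a system to the given atom indices (ordered), remapping bonds.
subset_atoms <- function(system, idx) {
  idx <- as.integer(idx)
  atoms <- system$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  frames <- lapply(system$frames, function(fr) fr[idx, , drop = FALSE])
  bonds <- NULL
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    map <- rep(NA_integer_, nrow(system$atoms))
    map[idx] <- seq_along(idx)
    b <- cbind(map[system$bonds[, 1]], map[system$bonds[, 2]])
    bonds <- b[stats::complete.cases(b), , drop = FALSE]
  }
  molecular_system(atoms, frames, bonds = bonds,
                   frame_times = system$frame_times)
}

# residue index (row of system$residues) for each atom
atom_residue_index <- function(system) {
  r <- system$residues
  rep(seq_len(nrow(r)), times = r$last - r$first + 1L)
}

# Map H atoms to their bonded heavy atom. Uses PSF bonds when present,
# otherwise pairs each H with the nearest heavy atom within `dmax` Angstrom
# in the given frame.
hydrogen_partners <- function(system, frame = 1, dmax = 1.25) {
  at <- system$atoms
  hidx <- which(at$is_hydrogen)
  out <- rep(NA_integer_, nrow(at))
  if (length(hidx) == 0) return(out)
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    b <- system$bonds
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]
      if (at$is_hydrogen[i] && !at$is_hydrogen[j]) out[i] <- j
      if (at$is_hydrogen[j] && !at$is_hydrogen[i]) out[j] <- i
    }
    return(out)
  }
  xyz <- system$frames[[frame]]
  rid <- atom_residue_index(system)
  heavy <- which(!at$is_hydrogen)
  for (h in hidx) {
    cand <- heavy[rid[heavy] == rid[h]]
    if (length(cand) == 0) next
    d2 <- rowSums((xyz[cand, , drop = FALSE] -
                     matrix(xyz[h, ], length(cand), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    if (d2[j] <= dmax^2) out[h] <- cand[j]
  }
  out
}
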