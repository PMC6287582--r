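#' @name detectors
#' @title Residue-residue interaction detectors
#'
#' @description Each detector scans one coordinate frame of a
#' \code{molecular_system} and returns a data.frame of interaction records
#' with columns \code{type}, \code{res_i}, \code{res_j} (residue row
#' indices, \code{res_i < res_j} except for hydrogen bonds where
#' \code{res_i} is the donor residue), \code{label_i}, \code{label_j},
#' \code{atoms} (participating atom names), the geometric/energetic
#' descriptors (\code{distance} in Angstrom, \code{angle}/\code{dihedral} in
#' degrees, \code{energy} in kcal/mol; NA where not applicable) and
#' \code{frame}. Every "<= d" distance criterion is inclusive.
#'
#' @param system A \code{molecular_system}.
#' @param frame Frame index (1-based).
#' @param criteria An \code{\link{interaction_criteria}} object.
NULL

COULOMB_K <- 332.0636 # kcal/mol * Angstrom / e^2

interaction_record <- function(type, res_i, res_j, labels, atoms,
                               distance = NA_real_, angle = NA_real_,
                               dihedral = NA_real_, energy = NA_real_,
                               frame = 1L) {
  data.frame(
    type = type, res_i = as.integer(res_i), res_j = as.integer(res_j),
    label_i = labels[res_i], label_j = labels[res_j],
    atoms = atoms, distance = distance, angle = angle,
    dihedral = dihedral, energy = energy, frame = as.integer(frame),
    stringsAsFactors = FALSE
  )
}

empty_records <- function() {
  data.frame(
    type = character(0), res_i = integer(0), res_j = integer(0),
    label_i = character(0), label_j = character(0), atoms = character(0),
    distance = numeric(0), angle = numeric(0), dihedral = numeric(0),
    energy = numeric(0), frame = integer(0), stringsAsFactors = FALSE
  )
}

bind_records <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(empty_records())
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# canonical deterministic ordering of a record set
sort_records <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  ord <- order(match(rec$type, interaction_types()), rec$res_i, rec$res_j,
               rec$atoms)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# index of a named atom within each residue (NA when absent)
residue_atom_index <- function(system, atom_name) {
  at <- system$atoms
  res <- system$residues
  out <- rep(NA_integer_, nrow(res))
  hits <- which(at$name == atom_name)
  rid <- atom_residue_index(system)[hits]
  out[rid] <- hits
  out
}

# sequence position used for the C-alpha neighbour exclusion: author
# residue numbering, so |i - j| matches the printed sequence separation
chain_position <- function(system) {
  system$residues$resno
}

# residue pairs directly bonded to each other (adjacent along the backbone);
# from explicit bonds when available, else same-chain consecutive numbering
adjacent_residue_pairs <- function(system) {
  res <- system$residues
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    rid <- atom_residue_index(system)
    a <- rid[system$bonds[, 1]]
    b <- rid[system$bonds[, 2]]
    keep <- a != b
    p <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    return(unique(p))
  }
  n <- nrow(res)
  if (n < 2) return(matrix(integer(0), 0, 2))
  i <- seq_len(n - 1)
  same <- res$chain[i] == res$chain[i + 1] &
    abs(res$resno[i + 1] - res$resno[i]) <= 1
  cbind(i[same], i[same] + 1L)
}

pair_key <- function(i, j, n) (pmin(i, j) - 1) * n + pmax(i, j)

#' @rdname detectors
#' @details \code{detect_calpha}: classic contact map; an edge for every
#' residue pair whose C-alpha atoms lie within \code{calpha_d} (default 8
#' Angstrom), excluding pairs separated by at most
#' \code{seq_exclusion_calpha} positions on the same chain. Inter-chain
#' pairs are never excluded.
#' @export
detect_calpha <- function(system, frame = 1, criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  ca <- residue_atom_index(system, "CA")
  have <- which(!is.na(ca))
  if (length(have) < nrow(system$residues)) {
    warning("detect_calpha(): ", nrow(system$residues) - length(have),
            " residue(s) lack a CA atom and were skipped")
  }
  if (length(have) < 2) return(empty_records())
  xyz <- system$frames[[frame]][ca[have], , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  pos <- chain_position(system)
  chain <- system$residues$chain
  recs <- list()
  for (a in seq_along(have)) {
    for (b in seq_along(have)) {
      if (b <= a) next
      i <- have[a]; j <- have[b]
      if (chain[i] == chain[j] &&
          abs(pos[i] - pos[j]) <= criteria$seq_exclusion_calpha) next
      if (d[a, b] <= criteria$calpha_d) {
        recs[[length(recs) + 1]] <- interaction_record(
          "CALPHA", i, j, labels, "CA|CA", distance = d[a, b], frame = frame
        )
      }
    }
  }
  sort_records(bind_records(recs))
}

# donor/acceptor chemistry: donors are N/O/S heavy atoms carrying >= 1
# hydrogen; acceptors are all O, N with no bonded H, and S of MET/CYS
hbond_roles <- function(system, hpart) {
  at <- system$atoms
  heavy_has_h <- tabulate(hpart[!is.na(hpart)], nbins = nrow(at)) > 0
  donors <- which(at$element %in% c("N", "O", "S") & heavy_has_h)
  acceptors <- which(
    at$element == "O" |
      (at$element == "N" & !heavy_has_h) |
      (at$element == "S" & at$resname %in% c("MET", "CYS"))
  )
  list(donors = donors, acceptors = acceptors, heavy_has_h = heavy_has_h)
}

#' @rdname detectors
#' @details \code{detect_hbonds}: donor--acceptor distance at most
#' \code{hb_d} (default 3 Angstrom) and D-H...A angle at the hydrogen of at
#' least \code{hb_angle_min} (default 120 degrees). The donor residue is
#' stored as \code{res_i} (direction attribute). One record per satisfying
#' (donor, H, acceptor) triple.
#' @export
detect_hbonds <- function(system, frame = 1, criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  at <- system$atoms
  if (!any(at$is_hydrogen)) {
    warning("detect_hbonds(): no hydrogens in system; H-bond detection ",
            "needs explicit hydrogens (none built)")
    return(empty_records())
  }
  hpart <- hydrogen_partners(system, frame)
  roles <- hbond_roles(system, hpart)
  rid <- atom_residue_index(system)
  xyz <- system$frames[[frame]]
  recs <- list()
  hs <- which(at$is_hydrogen & !is.na(hpart))
  for (h in hs) {
    d_at <- hpart[h]
    if (!(d_at %in% roles$donors)) next
    for (a_at in roles$acceptors) {
      if (rid[a_at] == rid[d_at]) next
      dda <- vec_distance(xyz[d_at, ], xyz[a_at, ])
      if (dda > criteria$hb_d) next
      ang <- vec_angle(xyz[d_at, ] - xyz[h, ], xyz[a_at, ] - xyz[h, ])
      if (ang >= criteria$hb_angle_min) {
        recs[[length(recs) + 1]] <- interaction_record(
          "HBOND", rid[d_at], rid[a_at], labels,
          paste(at$name[d_at], at$name[h], at$name[a_at], sep = "|"),
          distance = dda, angle = ang, frame = frame
        )
      }
    }
  }
  sort_records(bind_records(recs))
}

.basic_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
  HSP = c("ND1", "NE2"), HIP = c("ND1", "NE2")
)
.acidic_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# rows of system$residues that are cationic histidines
is_protonated_his <- function(system) {
  res <- system$residues
  at <- system$atoms
  vapply(seq_len(nrow(res)), function(r) {
    if (!(res$resname[r] %in% c("HIS", "HSD", "HSE", "HSP", "HID", "HIE",
                                "HIP"))) {
      return(FALSE)
    }
    if (res$resname[r] %in% c("HSP", "HIP")) return(TRUE)
    if (res$resname[r] %in% c("HSD", "HSE", "HID", "HIE")) return(FALSE)
    nm <- at$name[res$first[r]:res$last[r]]
    ("HD1" %in% nm) && ("HE2" %in% nm)
  }, logical(1))
}

#' @rdname detectors
#' @details \code{detect_salt_bridges}: a basic side-chain nitrogen (Arg
#' NE/NH1/NH2, Lys NZ, protonated His ND1/NE2) within \code{sb_d} (default 6
#' Angstrom) of an acidic carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2); one
#' record per residue pair carrying the minimum N--O distance and the atom
#' pair achieving it.
#' @export
detect_salt_bridges <- function(system, frame = 1,
                                criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  at <- system$atoms
  res <- system$residues
  rid <- atom_residue_index(system)
  xyz <- system$frames[[frame]]
  prot_his <- is_protonated_his(system)
  n_atoms_of <- function(r) {
    rn <- res$resname[r]
    span <- res$first[r]:res$last[r]
    names_want <- if (prot_his[r]) c("ND1", "NE2") else .basic_atoms[[rn]]
    span[at$name[span] %in% names_want]
  }
  basic_res <- which(res$resname %in% c("ARG", "LYS") | prot_his)
  acidic_res <- which(res$resname %in% names(.acidic_atoms))
  recs <- list()
  for (b in basic_res) {
    nb <- n_atoms_of(b)
    if (length(nb) == 0) next
    for (a in acidic_res) {
      oa <- res$first[a]:res$last[a]
      oa <- oa[at$name[oa] %in% .acidic_atoms[[res$resname[a]]]]
      if (length(oa) == 0) next
      dmin <- Inf; best <- NULL
      for (ni in nb) {
        for (oi in oa) {
          dd <- vec_distance(xyz[ni, ], xyz[oi, ])
          if (dd < dmin) { dmin <- dd; best <- c(ni, oi) }
        }
      }
      if (dmin <= criteria$sb_d) {
        i <- min(b, a); j <- max(b, a)
        recs[[length(recs) + 1]] <- interaction_record(
          "SALT_BRIDGE", i, j, labels,
          paste(at$name[best[1]], at$name[best[2]], sep = "|"),
          distance = dmin, frame = frame
        )
      }
    }
  }
  sort_records(bind_records(recs))
}

#' @rdname detectors
#' @details \code{detect_disulfides}: cysteine SG atoms within \code{ss_d}
#' (default 3 Angstrom) with |chi_SS| = |dihedral(CB-SG-SG-CB)| inside
#' \code{[ss_dihedral_lo, ss_dihedral_hi]} (default [60, 90] degrees; the
#' band is unsigned).
#' @export
detect_disulfides <- function(system, frame = 1,
                              criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  at <- system$atoms
  res <- system$residues
  xyz <- system$frames[[frame]]
  cys <- which(res$resname == "CYS")
  if (length(cys) < 2) return(empty_records())
  find_atom <- function(r, nm) {
    span <- res$first[r]:res$last[r]
    span[at$name[span] == nm][1]
  }
  recs <- list()
  for (a in seq_along(cys)) {
    for (b in seq_along(cys)) {
      if (b <= a) next
      i <- cys[a]; j <- cys[b]
      sg_i <- find_atom(i, "SG"); sg_j <- find_atom(j, "SG")
      if (is.na(sg_i) || is.na(sg_j)) next
      d <- vec_distance(xyz[sg_i, ], xyz[sg_j, ])
      if (d > criteria$ss_d) next
      cb_i <- find_atom(i, "CB"); cb_j <- find_atom(j, "CB")
      if (is.na(cb_i) || is.na(cb_j)) {
        warning("detect_disulfides(): CYS pair ", labels[i], "--", labels[j],
                " skipped (missing CB for the dihedral)")
        next
      }
      chi <- vec_dihedral(xyz[cb_i, ], xyz[sg_i, ], xyz[sg_j, ], xyz[cb_j, ])
      if (abs(chi) >= criteria$ss_dihedral_lo &&
          abs(chi) <= criteria$ss_dihedral_hi) {
        recs[[length(recs) + 1]] <- interaction_record(
          "DISULFIDE", i, j, labels, "SG|SG",
          distance = d, dihedral = chi, frame = frame
        )
      }
    }
  }
  sort_records(bind_records(recs))
}

# aromatic pi-system ring atoms per residue class; Trp's fused indole is one
# 9-atom ring (single centroid/normal)
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# ring descriptors for all aromatic residues in a frame; His only when not
# protonated (a protonated His is a cation, not a pi-system)
system_rings <- function(system, frame) {
  at <- system$atoms
  res <- system$residues
  xyz <- system$frames[[frame]]
  prot_his <- is_protonated_his(system)
  out <- list()
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    cls <- if (rn %in% c("PHE", "TYR", "TRP")) rn
      else if (rn %in% c("HIS", "HSD", "HSE", "HID", "HIE") && !prot_his[r]) "HIS"
      else next
    span <- res$first[r]:res$last[r]
    idx <- span[match(.ring_atoms[[cls]], at$name[span])]
    if (anyNA(idx)) next
    out[[length(out) + 1]] <- list(
      residue = r,
      ring = ring_descriptor(xyz[idx, , drop = FALSE], idx)
    )
  }
  out
}

#' @rdname detectors
#' @details \code{detect_pi_pi}: aromatic ring systems (Phe, Tyr, Trp as one
#' fused ring, non-protonated His) with centroid--centroid distance at most
#' \code{pipi_d} (default 6 Angstrom). The inter-normal angle (folded to
#' [0, 90] degrees) is reported as a descriptor but not filtered on.
#' @export
detect_pi_pi <- function(system, frame = 1, criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  rings <- system_rings(system, frame)
  if (length(rings) < 2) return(empty_records())
  recs <- list()
  for (a in seq_along(rings)) {
    for (b in seq_along(rings)) {
      if (b <= a) next
      d <- vec_distance(rings[[a]]$ring$centroid, rings[[b]]$ring$centroid)
      if (d > criteria$pipi_d) next
      ang <- vec_angle(rings[[a]]$ring$normal, rings[[b]]$ring$normal)
      if (ang > 90) ang <- 180 - ang
      i <- min(rings[[a]]$residue, rings[[b]]$residue)
      j <- max(rings[[a]]$residue, rings[[b]]$residue)
      recs[[length(recs) + 1]] <- interaction_record(
        "PI_PI", i, j, labels, "ring|ring",
        distance = d, angle = ang, frame = frame
      )
    }
  }
  sort_records(bind_records(recs))
}

# cation sites: ARG CZ (guanidinium proxy), LYS NZ, protonated-His ring-N
# midpoint; returns list of (residue, point, atoms)
cation_sites <- function(system, frame) {
  at <- system$atoms
  res <- system$residues
  xyz <- system$frames[[frame]]
  prot_his <- is_protonated_his(system)
  out <- list()
  for (r in seq_len(nrow(res))) {
    span <- res$first[r]:res$last[r]
    rn <- res$resname[r]
    if (rn == "ARG") {
      i <- span[at$name[span] == "CZ"][1]
      if (!is.na(i)) out[[length(out) + 1]] <-
          list(residue = r, point = xyz[i, ], atoms = "CZ")
    } else if (rn == "LYS") {
      i <- span[at$name[span] == "NZ"][1]
      if (!is.na(i)) out[[length(out) + 1]] <-
          list(residue = r, point = xyz[i, ], atoms = "NZ")
    } else if (prot_his[r]) {
      i1 <- span[at$name[span] == "ND1"][1]
      i2 <- span[at$name[span] == "NE2"][1]
      if (!is.na(i1) && !is.na(i2)) out[[length(out) + 1]] <-
          list(residue = r, point = (xyz[i1, ] + xyz[i2, ]) / 2,
               atoms = "ND1+NE2")
    }
  }
  out
}

in_angle_bands <- function(ang, bands) {
  any(ang >= bands[, 1] & ang <= bands[, 2])
}

#' @rdname detectors
#' @details \code{detect_cation_pi}: a cationic group (Arg CZ, Lys NZ,
#' protonated-His ring-N midpoint) within \code{catpi_d} (default 7
#' Angstrom) of an aromatic ring centroid, with the angle between the ring
#' normal and the centroid-to-cation vector inside the allowed bands
#' (default [0, 60] or [120, 180] degrees, i.e. over a ring face; the bands
#' are symmetric so the arbitrary normal sign cannot matter).
#' @export
detect_cation_pi <- function(system, frame = 1,
                             criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  rings <- system_rings(system, frame)
  cats <- cation_sites(system, frame)
  if (length(rings) == 0 || length(cats) == 0) return(empty_records())
  recs <- list()
  for (rg in rings) {
    for (ct in cats) {
      if (rg$residue == ct$residue) next
      d <- vec_distance(rg$ring$centroid, ct$point)
      if (d > criteria$catpi_d) next
      ang <- vec_angle(rg$ring$normal, ct$point - rg$ring$centroid)
      if (!in_angle_bands(ang, criteria$catpi_angle_bands)) next
      i <- min(rg$residue, ct$residue); j <- max(rg$residue, ct$residue)
      recs[[length(recs) + 1]] <- interaction_record(
        "CATION_PI", i, j, labels, paste0("ring|", ct$atoms),
        distance = d, angle = ang, frame = frame
      )
    }
  }
  sort_records(bind_records(recs))
}

#' @rdname detectors
#' @details \code{detect_arg_arg}: arginine pairs whose guanidinium
#' centroids (mean of CZ, NH1, NH2, NE) lie within \code{argarg_d} (default
#' 5 Angstrom).
#' @export
detect_arg_arg <- function(system, frame = 1,
                           criteria = interaction_criteria()) {
  labels <- residue_labels(system)
  at <- system$atoms
  res <- system$residues
  xyz <- system$frames[[frame]]
  args <- which(res$resname == "ARG")
  if (length(args) < 2) return(empty_records())
  cent <- lapply(args, function(r) {
    span <- res$first[r]:res$last[r]
    idx <- span[at$name[span] %in% c("CZ", "NH1", "NH2", "NE")]
    if (length(idx) < 4) return(NULL)
    colMeans(xyz[idx, , drop = FALSE])
  })
  recs <- list()
  for (a in seq_along(args)) {
    for (b in seq_along(args)) {
      if (b <= a) next
      if (is.null(cent[[a]]) || is.null(cent[[b]])) next
      d <- vec_distance(cent[[a]], cent[[b]])
      if (d <= criteria$argarg_d) {
        recs[[length(recs) + 1]] <- interaction_record(
          "ARG_ARG", args[a], args[b], labels, "guanidinium|guanidinium",
          distance = d, frame = frame
        )
      }
    }
  }
  sort_records(bind_records(recs))
}

# vectorized inter-residue pairwise energies (Coulomb and Lennard-Jones in
# one pass); returns per-residue-pair sums for atom pairs within the cutoff,
# excluding intra-residue and backbone-adjacent residue pairs
residue_pair_energies <- function(system, frame, criteria) {
  at <- system$atoms
  n_res <- nrow(system$residues)
  rid <- atom_residue_index(system)
  xyz <- system$frames[[frame]]
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(at)
  ii <- matrix(rid, n, n)
  jj <- t(ii)
  mask <- upper.tri(d) & ii != jj & d <= criteria$coulomb_cutoff
  adj <- adjacent_residue_pairs(system)
  if (nrow(adj) > 0) {
    adj_keys <- pair_key(adj[, 1], adj[, 2], n_res)
    keys_all <- pair_key(ii, jj, n_res)
    mask <- mask & !(keys_all %in% adj_keys)
  }
  sel <- which(mask)
  if (length(sel) == 0) {
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      coulomb = numeric(0), vdw = numeric(0)))
  }
  ai <- ((sel - 1) %% n) + 1
  aj <- ((sel - 1) %/% n) + 1
  r <- d[sel]
  e_coul <- COULOMB_K * at$charge[ai] * at$charge[aj] /
    (criteria$dielectric * r)
  eps <- sqrt(at$lj_epsilon[ai] * at$lj_epsilon[aj])
  rmin <- at$lj_rmin_half[ai] + at$lj_rmin_half[aj]
  sr6 <- (rmin / r)^6
  e_lj <- eps * (sr6^2 - 2 * sr6)
  key <- pair_key(rid[ai], rid[aj], n_res)
  coul <- tapply(e_coul, key, sum)
  lj <- tapply(e_lj, key, sum)
  k <- as.numeric(names(coul))
  data.frame(
    res_i = as.integer((k - 1) %/% n_res + 1),
    res_j = as.integer((k - 1) %% n_res + 1),
    coulomb = as.numeric(coul),
    vdw = as.numeric(lj)
  )
}

#' Coulomb interaction energy between two residues
#'
#' Screened point-charge sum E = k * sum(q_a q_b / (eps_r * r_ab)) with
#' k = 332.0636 kcal mol^-1 A e^-2, over inter-residue atom pairs within
#' \code{coulomb_cutoff}.
#'
#' @inheritParams detectors
#' @param residue_i,residue_j Residue row indices.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(system, frame, residue_i, residue_j,
                           criteria = interaction_criteria()) {
  if (all(system$atoms$charge == 0)) {
    stop("coulomb_energy(): charges are not assigned ",
         "(read a PSF or run assign_nonbonded_params())")
  }
  res <- system$residues
  xyz <- system$frames[[frame]]
  ai <- res$first[residue_i]:res$last[residue_i]
  aj <- res$first[residue_j]:res$last[residue_j]
  e <- 0
  for (a in ai) {
    for (b in aj) {
      r <- vec_distance(xyz[a, ], xyz[b, ])
      if (r <= criteria$coulomb_cutoff) {
        e <- e + COULOMB_K * system$atoms$charge[a] *
          system$atoms$charge[b] / (criteria$dielectric * r)
      }
    }
  }
  e
}

#' @rdname detectors
#' @details \code{detect_coulomb}: residue pairs whose summed screened
#' point-charge energy has magnitude at least \code{coulomb_energy_thr}
#' (default 1 kcal/mol). Backbone-adjacent residue pairs are excluded.
#' @export
detect_coulomb <- function(system, frame = 1,
                           criteria = interaction_criteria()) {
  if (all(system$atoms$charge == 0)) {
    stop("detect_coulomb(): charges are not assigned ",
         "(read a PSF or run assign_nonbonded_params())")
  }
  labels <- residue_labels(system)
  pe <- residue_pair_energies(system, frame, criteria)
  keep <- abs(pe$coulomb) >= criteria$coulomb_energy_thr
  recs <- lapply(which(keep), function(k) {
    interaction_record("COULOMB", pe$res_i[k], pe$res_j[k], labels,
                       "group|group", energy = pe$coulomb[k], frame = frame)
  })
  sort_records(bind_records(recs))
}

#' @rdname detectors
#' @details \code{detect_vdw}: residue pairs whose 12-6 Lennard-Jones energy
#' E = sum eps_ab[(Rmin_ab/r)^12 - 2 (Rmin_ab/r)^6], with combination rules
#' eps_ab = sqrt(eps_a eps_b) and Rmin_ab = Rmin/2_a + Rmin/2_b, is at or
#' below \code{vdw_energy_thr} (default -0.1 kcal/mol, an attractive
#' contact). Backbone-adjacent residue pairs are excluded.
#' @export
detect_vdw <- function(system, frame = 1, criteria = interaction_criteria()) {
  if (all(system$atoms$lj_epsilon == 0)) {
    stop("detect_vdw(): Lennard-Jones parameters are not assigned ",
         "(run assign_nonbonded_params())")
  }
  labels <- residue_labels(system)
  pe <- residue_pair_energies(system, frame, criteria)
  keep <- pe$vdw <= criteria$vdw_energy_thr
  recs <- lapply(which(keep), function(k) {
    interaction_record("VDW", pe$res_i[k], pe$res_j[k], labels,
                       "group|group", energy = pe$vdw[k], frame = frame)
  })
  sort_records(bind_records(recs))
}

#' Run all enabled detectors on one frame
#'
#' @inheritParams detectors
#' @param enabled_types Character vector of interaction type names (see
#'   \code{\link{interaction_types}}).
#' @return Concatenated records in deterministic order (type, residue pair).
#' @export
detect_all <- function(system, frame = 1, criteria = interaction_criteria(),
                       enabled_types = interaction_types()) {
  bad <- setdiff(enabled_types, interaction_types())
  if (length(bad) > 0) {
    stop("detect_all(): unknown interaction type(s): ",
         paste(bad, collapse = ", "))
  }
  fns <- list(
    CALPHA = detect_calpha, HBOND = detect_hbonds,
    SALT_BRIDGE = detect_salt_bridges, DISULFIDE = detect_disulfides,
    CATION_PI = detect_cation_pi, PI_PI = detect_pi_pi,
    ARG_ARG = detect_arg_arg, COULOMB = detect_coulomb, VDW = detect_vdw
  )
  recs <- lapply(interaction_types()[interaction_types() %in% enabled_types],
                 function(ty) fns[[ty]](system, frame, criteria))
  sort_records(bind_records(recs))
}
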