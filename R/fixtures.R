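#' @name fixtures
#' @title Synthetic fixture generators
#'
#' @description Builders for small systems with planted, exactly-known
#' interactions: idealized pairwise geometries at controlled
#' distances/angles, multi-chain assemblies, and short trajectories in
#' which interactions form and break on a schedule with known pairwise
#' correlation structure. No external structure data is needed; geometry
#' uses standard bond lengths assembled by explicit construction.
NULL

frag <- function(name, element, x, y, z) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

shift_frag <- function(f, offset) {
  f$x <- f$x + offset[1]; f$y <- f$y + offset[2]; f$z <- f$z + offset[3]
  f
}

# hexagonal aromatic ring (PHE naming), radius 1.39, in the z = 0 plane
ring_frag <- function() {
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  th <- seq(0, by = pi / 3, length.out = 6)
  frag(nm, "C", 1.39 * cos(th), 1.39 * sin(th), 0)
}

# guanidinium group (ARG naming); centroid of (CZ, NE, NH1, NH2) at origin
guanidinium_frag <- function() {
  f <- frag(
    c("CZ", "NE", "NH1", "NH2"), c("C", "N", "N", "N"),
    c(0, 1.33, -0.665, -0.665),
    c(0, 0, 1.152, -1.152),
    c(0, 0, 0, 0)
  )
  ctr <- c(mean(f$x), mean(f$y), mean(f$z))
  shift_frag(f, -ctr)
}

# Geometry builders: each returns list(res1, res2) of atom fragments posed
# so that exactly the requested interaction descriptor holds. `params` is a
# list whose names depend on the type (all distances Angstrom, angles deg).
pair_geometry <- function(type, params) {
  p <- params
  switch(
    type,
    CALPHA = {
      list(
        res1 = list(resname = "ALA", atoms = frag("CA", "C", 0, 0, 0)),
        res2 = list(resname = "ALA", atoms = frag("CA", "C", p$distance, 0, 0))
      )
    },
    HBOND = {
      # donor N at origin, H along +x (1.0 A); acceptor at distance
      # p$distance from N with D-H...A angle p$angle at the hydrogen
      th <- p$angle * pi / 180
      ct <- cos(th)
      # acceptor direction from H makes angle th with the H->N vector (-x)
      t_ <- ct + sqrt(ct^2 - 1 + p$distance^2)
      a_pos <- c(1 - t_ * ct, t_ * sin(th), 0)
      list(
        res1 = list(resname = "ALA", atoms = rbind(
          frag("N", "N", 0, 0, 0),
          frag("HN", "H", 1, 0, 0),
          frag("CA", "C", -0.9, -1.2, 0)
        )),
        res2 = list(resname = "ALA", atoms = rbind(
          frag("O", "O", a_pos[1], a_pos[2], a_pos[3]),
          frag("C", "C", a_pos[1] + 1.23, a_pos[2] + 0.4, 0),
          frag("CA", "C", a_pos[1] + 2.2, a_pos[2] + 1.4, 0)
        ))
      )
    },
    SALT_BRIDGE = {
      # LYS NZ at origin; GLU OE1 at exactly p$distance, OE2 farther
      list(
        res1 = list(resname = "LYS", atoms = rbind(
          frag("NZ", "N", 0, 0, 0),
          frag("CE", "C", -1.5, 0, 0),
          frag("CA", "C", -4.0, 0, 0)
        )),
        res2 = list(resname = "GLU", atoms = rbind(
          frag("OE1", "O", p$distance, 0, 0),
          frag("OE2", "O", p$distance + 1.6, 1.6, 0),
          frag("CD", "C", p$distance + 1.1, 0.7, 0),
          frag("CA", "C", p$distance + 4.0, 0.7, 0)
        ))
      )
    },
    DISULFIDE = {
      # SG-SG along x at p$distance; CB positions set the C-S-S-C torsion
      # to p$dihedral with a 104-degree C-S-S angle
      ang <- 104 * pi / 180
      chi <- p$dihedral * pi / 180
      d <- p$distance
      cb1 <- 1.81 * c(cos(pi - ang), sin(pi - ang), 0)
      # direction from SG2, measured from the SG2->SG1 (-x) axis, rotated
      # about x by chi (right-hand rule gives the requested signed torsion)
      cb2 <- c(d, 0, 0) + 1.81 * c(-cos(pi - ang),
                                   sin(pi - ang) * cos(chi),
                                   sin(pi - ang) * sin(chi))
      list(
        res1 = list(resname = "CYS", atoms = rbind(
          frag("SG", "S", 0, 0, 0),
          frag("CB", "C", cb1[1], cb1[2], cb1[3]),
          frag("CA", "C", cb1[1] - 1.0, cb1[2] + 1.0, 0)
        )),
        res2 = list(resname = "CYS", atoms = rbind(
          frag("SG", "S", d, 0, 0),
          frag("CB", "C", cb2[1], cb2[2], cb2[3]),
          frag("CA", "C", cb2[1] + 1.0, cb2[2] + 1.0, cb2[3])
        ))
      )
    },
    PI_PI = {
      r1 <- ring_frag()
      r2 <- shift_frag(ring_frag(), c(0, 0, p$distance))
      list(
        res1 = list(resname = "PHE", atoms = rbind(
          r1, frag("CA", "C", 0, 0, -3)
        )),
        res2 = list(resname = "PHE", atoms = rbind(
          r2, frag("CA", "C", 0, 0, p$distance + 3)
        ))
      )
    },
    CATION_PI = {
      # ring centered at origin, normal +z; cation at p$distance along a
      # direction making p$angle with the normal
      th <- p$angle * pi / 180
      pos <- p$distance * c(sin(th), 0, cos(th))
      list(
        res1 = list(resname = "PHE", atoms = rbind(
          ring_frag(), frag("CA", "C", 0, -3, 0)
        )),
        res2 = list(resname = "LYS", atoms = rbind(
          frag("NZ", "N", pos[1], pos[2], pos[3]),
          frag("CE", "C", pos[1] + 1.5, pos[2], pos[3]),
          frag("CA", "C", pos[1] + 4, pos[2], pos[3])
        ))
      )
    },
    ARG_ARG = {
      g1 <- guanidinium_frag()
      g2 <- shift_frag(guanidinium_frag(), c(0, 0, p$distance))
      list(
        res1 = list(resname = "ARG", atoms = rbind(
          g1, frag("CA", "C", -4, 0, 0)
        )),
        res2 = list(resname = "ARG", atoms = rbind(
          g2, frag("CA", "C", -4, 0, p$distance)
        ))
      )
    },
    COULOMB = {
      # opposite unit charges at exactly p$distance
      list(
        res1 = list(resname = "LYS", atoms = rbind(
          frag("NZ", "N", 0, 0, 0),
          frag("CA", "C", -4, 0, 0)
        ), charge = c(NZ = 1, CA = 0)),
        res2 = list(resname = "GLU", atoms = rbind(
          frag("OE1", "O", p$distance, 0, 0),
          frag("CA", "C", p$distance + 4, 0, 0)
        ), charge = c(OE1 = -1, CA = 0))
      )
    },
    VDW = {
      # one Lennard-Jones site per residue at exactly p$distance
      eps <- p$epsilon %||num% 0.2
      rmh <- p$rmin_half %||num% 2.0
      list(
        res1 = list(resname = "ALA", atoms = rbind(
          frag("CB", "C", 0, 0, 0),
          frag("CA", "C", -4, 0, 0)
        ), lj = list(CB = c(eps, rmh), CA = c(0, 0))),
        res2 = list(resname = "ALA", atoms = rbind(
          frag("CB", "C", p$distance, 0, 0),
          frag("CA", "C", p$distance + 4, 0, 0)
        ), lj = list(CB = c(eps, rmh), CA = c(0, 0)))
      )
    },
    stop("pair_geometry(): unknown interaction type ", type)
  )
}

assemble_pair_atoms <- function(geom, chain = c("A", "A"),
                                resno = c(1L, 10L), serial_start = 1L,
                                offset = c(0, 0, 0)) {
  rows <- list()
  serial <- serial_start
  for (k in 1:2) {
    part <- geom[[k]]
    f <- shift_frag(part$atoms, offset)
    charge <- rep(0, nrow(f))
    eps <- rep(0, nrow(f)); rmh <- rep(0, nrow(f))
    if (!is.null(part$charge)) charge <- unname(part$charge[f$name])
    if (!is.null(part$lj)) {
      eps <- vapply(f$name, function(nm) part$lj[[nm]][1], numeric(1))
      rmh <- vapply(f$name, function(nm) part$lj[[nm]][2], numeric(1))
    }
    rows[[k]] <- data.frame(
      serial = seq(serial, length.out = nrow(f)),
      name = f$name, element = f$element,
      resname = part$resname, resno = resno[k], chain = chain[k],
      insert = "", charge = charge, lj_epsilon = eps, lj_rmin_half = rmh,
      x = f$x, y = f$y, z = f$z, stringsAsFactors = FALSE
    )
    serial <- serial + nrow(f)
  }
  do.call(rbind, rows)
}

`%||num%` <- function(a, b) if (is.null(a)) b else a

#' Build a two-residue system with one planted interaction
#'
#' Poses two minimal residues so that exactly the requested interaction
#' holds at the requested descriptor values (or is absent, for
#' planted-negative geometries beyond the threshold). The residues sit on
#' one chain at sequence positions 1 and 10, clear of every
#' sequence-neighbour exclusion.
#'
#' @param type Interaction type name (see \code{\link{interaction_types}}).
#' @param ... Geometry parameters: \code{distance} (all types),
#'   \code{angle} (HBOND: D-H...A angle; CATION_PI: angle from the ring
#'   normal), \code{dihedral} (DISULFIDE chi_SS), \code{epsilon} and
#'   \code{rmin_half} (VDW site parameters).
#' @param dir Optional directory: when given, PDB, PSF and CHARMM parameter
#'   files are written there and their paths attached as the
#'   \code{files} attribute.
#' @return A \code{molecular_system} with one frame.
#' @export
make_dipeptide_pair <- function(type, ..., dir = NULL) {
  params <- list(...)
  if (is.null(params$distance)) {
    stop("make_dipeptide_pair(): a target distance is required")
  }
  geom <- pair_geometry(type, params)
  atoms <- assemble_pair_atoms(geom)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  sys <- molecular_system(atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                          list(xyz))
  if (!is.null(dir)) {
    attr(sys, "files") <- write_fixture_files(sys, dir, "pair")
  }
  sys
}

#' Write PDB + PSF + CHARMM parameter files for a fixture system
#'
#' @param system A \code{molecular_system}.
#' @param dir Output directory.
#' @param name File-name stem.
#' @return Named character vector of paths (pdb, psf, prm).
#' @export
write_fixture_files <- function(system, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  psf <- file.path(dir, paste0(name, ".psf"))
  prm <- file.path(dir, paste0(name, ".prm"))
  write_pdb(system, pdb)
  write_psf(system, psf)
  write_fixture_prm(system, prm)
  c(pdb = pdb, psf = psf, prm = prm)
}

#' Write a CHARMM/X-PLOR PSF for a system
#'
#' Atom types default to atom names when no force-field type is set, and a
#' matching synthetic parameter file can be produced with
#' \code{\link{write_fixture_prm}}.
#'
#' @param system A \code{molecular_system}.
#' @param path Output path.
#' @param ext Use the wide EXT column layout (default FALSE).
#' @return Invisibly, \code{path}.
#' @export
write_psf <- function(system, path, ext = FALSE) {
  at <- system$atoms
  type <- ifelse(is.na(at$type), at$name, at$type)
  mass <- atom_masses(system)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(if (ext) "PSF EXT" else "PSF", con)
  writeLines("", con)
  writeLines(sprintf("%8d !NTITLE", 1L), con)
  writeLines(" REMARKS synthetic fixture topology", con)
  writeLines("", con)
  writeLines(sprintf("%8d !NATOM", nrow(at)), con)
  fmt <- if (ext) {
    "%10d %-8s %-8d %-8s %-8s %-8s %14.6f %14.4f %11d"
  } else {
    "%8d %-4s %-4d %-4s %-4s %-4s %10.6f %13.4f %11d"
  }
  writeLines(sprintf(fmt, at$serial, substr(at$chain, 1, 4), at$resno,
                     at$resname, at$name, type, at$charge, mass, 0L), con)
  writeLines("", con)
  b <- system$bonds
  nb <- if (is.null(b)) 0L else nrow(b)
  writeLines(sprintf("%8d !NBOND: bonds", nb), con)
  if (nb > 0) {
    flat <- as.integer(t(b))
    per_line <- 8L
    for (i in seq(1, length(flat), by = per_line)) {
      chunk <- flat[i:min(i + per_line - 1, length(flat))]
      writeLines(paste(sprintf("%8d", chunk), collapse = ""), con)
    }
  }
  writeLines("", con)
  invisible(path)
}

#' Write a NONBONDED parameter file matching a fixture system
#'
#' One line per distinct atom type carrying that atom's planted epsilon and
#' Rmin/2 (epsilon printed negative, CHARMM convention).
#'
#' @param system A \code{molecular_system}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fixture_prm <- function(system, path) {
  at <- system$atoms
  type <- ifelse(is.na(at$type), at$name, at$type)
  first <- !duplicated(type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("* synthetic parameter file for generated fixtures", con)
  writeLines("*", con)
  writeLines("", con)
  writeLines("NONBONDED nbxmod 5 atom cdiel shift -", con)
  writeLines("cutnb 14.0 ctofnb 12.0 eps 1.0", con)
  writeLines(sprintf("%-6s 0.000000 %11.6f %11.6f",
                     type[first], -abs(at$lj_epsilon[first]),
                     at$lj_rmin_half[first]), con)
  writeLines("", con)
  writeLines("END", con)
  invisible(path)
}

#' Write frames to a CHARMM/NAMD DCD file
#'
#' @param frames List of n_atoms x 3 coordinate matrices.
#' @param path Output path.
#' @param endian "little" or "big".
#' @return Invisibly, \code{path}.
#' @export
write_dcd <- function(frames, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  natom <- nrow(frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = endian)
  # header record: CORD + 20 control ints
  wint(84)
  writeBin(charToRaw("CORD"), con)
  icntrl <- integer(20)
  icntrl[1] <- length(frames)   # frames in file
  icntrl[2] <- 1L               # first step
  icntrl[3] <- 1L               # save frequency
  icntrl[4] <- length(frames)   # total steps
  icntrl[20] <- 24L             # CHARMM version stamp
  wint(icntrl)
  wint(84)
  # title record
  title <- sprintf("%-80s", "synthetic trajectory")
  wint(4 + 80)
  wint(1)
  writeBin(charToRaw(title), con)
  wint(4 + 80)
  # natom record
  wint(4)
  wint(natom)
  wint(4)
  for (fr in frames) {
    for (dim_ in 1:3) {
      wint(4 * natom)
      writeBin(as.numeric(fr[, dim_]), con, size = 4, endian = endian)
      wint(4 * natom)
    }
  }
  invisible(path)
}

#' Bernoulli presence schedules with planted pairwise correlation
#'
#' Draws a Bernoulli(0.5) driver series; the first schedule is the driver
#' itself and every further schedule is a copy whose elements are flipped
#' independently with probability (1 - rho)/2. The expected Pearson
#' correlation between schedule 1 and any other schedule is then exactly
#' rho (and rho^2 between two flipped copies).
#'
#' @param n_schedules Number of schedules.
#' @param n_frames Frames per schedule.
#' @param rho Target correlation between the driver schedule and each copy,
#'   in [-1, 1].
#' @param seed RNG seed (same seed, same schedules).
#' @return List with \code{driver} (logical) and \code{schedules} (list of
#'   logicals; \code{schedules[[1]]} is the driver).
#' @export
bernoulli_schedules <- function(n_schedules, n_frames, rho, seed = 1) {
  set.seed(seed)
  driver <- stats::runif(n_frames) < 0.5
  schedules <- c(list(driver), lapply(seq_len(n_schedules - 1), function(i) {
    flip <- stats::runif(n_frames) < (1 - rho) / 2
    xor(driver, flip)
  }))
  list(driver = driver, schedules = schedules[seq_len(n_schedules)])
}

# margin (in the controlling unit) between a planted geometry and its
# detection threshold; used to validate the noise level
planted_margin <- function(type, formed, broken, criteria) {
  thr <- switch(type,
    CALPHA = criteria$calpha_d, HBOND = criteria$hb_d,
    SALT_BRIDGE = criteria$sb_d, DISULFIDE = criteria$ss_d,
    PI_PI = criteria$pipi_d, CATION_PI = criteria$catpi_d,
    ARG_ARG = criteria$argarg_d, COULOMB = NA, VDW = NA
  )
  if (is.na(thr)) return(Inf)
  min(abs(thr - formed$distance), abs(thr - broken$distance))
}

#' Generate a trajectory with scheduled interactions
#'
#' Each planted interaction pair occupies its own spatial region (regions
#' 60 Angstrom apart, beyond every cutoff) and switches between a "formed"
#' and a "broken" geometry according to its presence schedule, with
#' optional Gaussian coordinate noise. Noise must stay below a quarter of
#' the smallest planted threshold margin, keeping detection exact.
#'
#' @param planted List of plants; each a list with \code{type},
#'   \code{formed} and \code{broken} geometry parameter lists (see
#'   \code{\link{make_dipeptide_pair}}), and a logical \code{schedule} of
#'   length \code{n_frames}.
#' @param n_frames Number of frames.
#' @param noise Gaussian coordinate noise s.d. in Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @param dir Optional output directory for PDB + PSF + DCD + parameter
#'   files (paths attached as the \code{files} attribute).
#' @param criteria Criteria used to validate noise margins.
#' @return A \code{molecular_system} with \code{n_frames} frames; residues
#'   of plant k sit at chain "A" sequence positions 20k+1 and 20k+10.
#' @export
make_trajectory <- function(planted, n_frames, noise = 0, seed = 1,
                            dir = NULL, criteria = interaction_criteria()) {
  stopifnot(length(planted) >= 1)
  for (p in planted) {
    if (length(p$schedule) != n_frames) {
      stop("make_trajectory(): schedule length must equal n_frames")
    }
    m <- planted_margin(p$type, p$formed, p$broken, criteria)
    if (noise > m / 4) {
      stop("make_trajectory(): noise ", noise,
           " exceeds a planted margin (", signif(m, 3), ") for ", p$type)
    }
  }
  set.seed(seed)
  atoms <- NULL
  coords_formed <- list()
  coords_broken <- list()
  serial <- 1L
  for (k in seq_along(planted)) {
    p <- planted[[k]]
    offset <- c(60 * (k - 1), 0, 0)
    resno <- c(20L * k + 1L, 20L * k + 10L)
    gf <- assemble_pair_atoms(pair_geometry(p$type, p$formed),
                              resno = resno, serial_start = serial,
                              offset = offset)
    gb <- assemble_pair_atoms(pair_geometry(p$type, p$broken),
                              resno = resno, serial_start = serial,
                              offset = offset)
    if (!identical(gf$name, gb$name)) {
      stop("make_trajectory(): formed/broken geometries differ in atoms")
    }
    serial <- serial + nrow(gf)
    atoms <- rbind(atoms, gf[, setdiff(names(gf), c("x", "y", "z"))])
    coords_formed[[k]] <- as.matrix(gf[, c("x", "y", "z")])
    coords_broken[[k]] <- as.matrix(gb[, c("x", "y", "z")])
  }
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- do.call(rbind, lapply(seq_along(planted), function(k) {
      if (planted[[k]]$schedule[f]) coords_formed[[k]] else coords_broken[[k]]
    }))
    if (noise > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise),
                          nrow(xyz), 3)
    }
    dimnames(xyz) <- NULL
    xyz
  })
  sys <- molecular_system(atoms, frames)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(dir, "traj.pdb")
    psf <- file.path(dir, "traj.psf")
    dcd <- file.path(dir, "traj.dcd")
    prm <- file.path(dir, "traj.prm")
    write_pdb(sys, pdb)
    write_psf(sys, psf)
    write_dcd(sys$frames, dcd)
    write_fixture_prm(sys, prm)
    attr(sys, "files") <- c(pdb = pdb, psf = psf, dcd = dcd, prm = prm)
  }
  sys
}

#' Generate a multi-chain assembly with planted cross-chain interactions
#'
#' Chains are labelled A, B, C, ... and split into contiguous blocks over
#' assemblies 1..n_assemblies (as the monomers of two docked half-channels
#' would be); each chain carries a backbone of isolated alanine
#' residues on a coarse grid. Planted interactions place a posed residue
#' pair across the named chains (or within one chain).
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_assemblies Number of assembly labels.
#' @param planted List of plants: each a list with \code{type},
#'   \code{chain_i}, \code{chain_j} and geometry \code{params}.
#' @param residues_per_chain Baseline alanines per chain (default 3).
#' @return List with \code{system} (a \code{molecular_system}) and
#'   \code{assembly_map} (named chain -> assembly label vector).
#' @export
make_assembly <- function(n_chains = 4, n_assemblies = 2, planted = list(),
                          residues_per_chain = 3) {
  stopifnot(n_chains >= 2)
  chains <- LETTERS[seq_len(n_chains)]
  assembly_map <- stats::setNames(
    as.character(rep(seq_len(n_assemblies),
                     each = ceiling(n_chains / n_assemblies))[seq_len(n_chains)]),
    chains
  )
  rows <- list()
  serial <- 1L
  next_resno <- stats::setNames(rep(1L, n_chains), chains)
  for (ci in seq_along(chains)) {
    for (r in seq_len(residues_per_chain)) {
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = "CA", element = "C", resname = "ALA",
        resno = next_resno[[chains[ci]]], chain = chains[ci], insert = "",
        charge = 0, lj_epsilon = 0, lj_rmin_half = 0,
        x = 200 + 20 * ci, y = 20 * r, z = 0, stringsAsFactors = FALSE
      )
      serial <- serial + 1L
      next_resno[[chains[ci]]] <- next_resno[[chains[ci]]] + 10L
    }
  }
  for (k in seq_along(planted)) {
    p <- planted[[k]]
    geom <- pair_geometry(p$type, p$params)
    resno <- c(next_resno[[p$chain_i]], next_resno[[p$chain_j]])
    if (p$chain_i == p$chain_j) resno[2] <- resno[1] + 10L
    part <- assemble_pair_atoms(
      geom, chain = c(p$chain_i, p$chain_j), resno = resno,
      serial_start = serial, offset = c(-60 * k, 0, 0)
    )
    next_resno[[p$chain_i]] <- max(resno) + 10L
    next_resno[[p$chain_j]] <- max(resno) + 10L
    serial <- serial + nrow(part)
    rows[[length(rows) + 1]] <- part
  }
  atoms <- do.call(rbind, rows)
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  sys <- molecular_system(atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                          list(xyz))
  list(system = sys, assembly_map = assembly_map)
}
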