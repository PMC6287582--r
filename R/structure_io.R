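#' Read a PDB file into a MolecularSystem
#'
#' Both ATOM and HETATM records are kept (heteroatom removal is a separate,
#' explicit step via \code{\link{strip_non_protein}}). Alternate locations
#' are resolved to a single conformer: for each (residue, atom name) the
#' highest-occupancy altloc is kept, ties broken in favour of altloc "A" /
#' first encountered. Charges and Lennard-Jones parameters are left unset
#' (zero) until \code{\link{assign_nonbonded_params}}.
#'
#' @param path Path to a PDB file.
#' @return A \code{molecular_system} with one frame.
#' @seealso \code{\link{read_psf}}, \code{\link{read_dcd}}
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("read_pdb(): file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("read_pdb(): PDB format error in ", path,
                             ": ", conditionMessage(e))
  )
  a <- pdb$atom
  if (nrow(a) == 0) stop("read_pdb(): no ATOM/HETATM records in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  keep <- resolve_altloc(a)
  a <- a[keep, , drop = FALSE]
  atoms <- data.frame(
    serial = a$eleno,
    name = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     guess_element(a$elety), a$elesy),
    resname = a$resid,
    resno = a$resno,
    chain = a$chain,
    insert = a$insert,
    record = a$type,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(a$x, a$y, a$z)
  if (!all(is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))[1]
    stop("read_pdb(): unparseable coordinates at atom record ", bad,
         " of ", path)
  }
  molecular_system(atoms, list(xyz))
}

# one conformer per (residue, atom name): highest occupancy, ties -> 'A'/first
resolve_altloc <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  occ <- a$o
  occ[is.na(occ)] <- 1
  # prefer high occupancy, then altloc "" < "A" < "B"..., then file order
  ord <- order(key, -occ, a$alt, seq_len(nrow(a)))
  first_of_key <- !duplicated(key[ord])
  sort(ord[first_of_key])
}

#' Write a MolecularSystem frame to a PDB file
#'
#' @param system A \code{molecular_system}.
#' @param path Output path.
#' @param frame Frame index to write (default 1).
#' @export
write_pdb <- function(system, path, frame = 1) {
  at <- system$atoms
  rec <- if (!is.null(at$record)) at$record else rep("ATOM", nrow(at))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(system$frames[[frame]])),
    type = rec,
    resno = at$resno,
    resid = at$resname,
    eleno = at$serial,
    elety = at$name,
    chain = ifelse(at$chain == "", " ", substr(at$chain, 1, 1)),
    insert = ifelse(at$insert == "", "", at$insert),
    elesy = at$element,
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Read a CHARMM/X-PLOR PSF topology file
#'
#' Parses the atom section (segment, residue id, residue name, atom name,
#' atom type, partial charge, mass) and the bond section (needed for
#' donor-hydrogen pairing and the disulfide C-S-S-C dihedral). Standard and
#' EXT(ended) column layouts are both accepted; the atom-type field may be
#' alphanumeric (CHARMM dialect) or an integer index (X-PLOR dialect).
#'
#' @param path Path to a PSF file.
#' @return A \code{molecular_system} with the topology populated and zero
#'   frames recorded as an empty placeholder frame list; combine with
#'   \code{\link{read_dcd}} to add coordinates. The returned object has a
#'   \code{frames} list containing one all-zero frame so that structural
#'   invariants hold; \code{read_dcd} replaces it.
#' @export
read_psf <- function(path) {
  if (!file.exists(path)) stop("read_psf(): file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^PSF", lines[1])) {
    stop("read_psf(): not a PSF file (missing PSF header): ", path)
  }
  flags <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]][-1]
  known <- c("EXT", "CMAP", "CHEQ", "XPLOR", "DRUDE", "NAMD")
  unknown <- setdiff(flags, known)
  if (length(unknown) > 0) {
    stop("read_psf(): unsupported PSF dialect flag(s): ",
         paste(unknown, collapse = ", "))
  }
  natom_line <- grep("!NATOM", lines, fixed = TRUE)[1]
  if (is.na(natom_line)) stop("read_psf(): no !NATOM section in ", path)
  natom <- as.integer(strsplit(trimws(lines[natom_line]), "[[:space:]]+")[[1]][1])
  atom_lines <- lines[(natom_line + 1):(natom_line + natom)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) != natom) {
    stop("read_psf(): NATOM header says ", natom, " atoms but ",
         length(atom_lines), " atom lines found")
  }
  # whitespace-split covers both standard and EXT widths
  fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop("read_psf(): malformed atom line: ",
         atom_lines[which(nf < 8)[1]])
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  atoms <- data.frame(
    serial = as.integer(get(1)),
    chain = get(2),                      # segment id acts as the chain
    resno = as.integer(get(3)),
    insert = "",
    resname = get(4),
    name = get(5),
    type = get(6),
    charge = as.numeric(get(7)),
    mass = as.numeric(get(8)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$charge)) {
    stop("read_psf(): non-numeric charge column in atom section")
  }
  atoms$element <- ifelse(atoms$mass < 3.5, "H", guess_element(atoms$name))
  bonds <- parse_psf_bonds(lines, natom)
  placeholder <- matrix(0, natom, 3)
  molecular_system(atoms, list(placeholder), bonds = bonds)
}

parse_psf_bonds <- function(lines, natom) {
  bond_line <- grep("!NBOND", lines, fixed = TRUE)[1]
  if (is.na(bond_line)) return(NULL)
  nbond <- as.integer(strsplit(trimws(lines[bond_line]), "[[:space:]]+")[[1]][1])
  if (is.na(nbond) || nbond == 0) return(NULL)
  ints <- integer(0)
  i <- bond_line + 1
  while (length(ints) < 2 * nbond && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    ints <- c(ints, as.integer(strsplit(ln, "[[:space:]]+")[[1]]))
    i <- i + 1
  }
  if (length(ints) < 2 * nbond) {
    stop("read_psf(): bond section truncated (expected ", nbond, " bonds)")
  }
  b <- matrix(ints[seq_len(2 * nbond)], ncol = 2, byrow = TRUE)
  if (any(b < 1) || any(b > natom)) {
    stop("read_psf(): bond indices out of range")
  }
  b
}

#' Total charge of a system
#' @param system A \code{molecular_system}.
#' @return Sum of partial charges (elementary charge units).
#' @export
total_charge <- function(system) sum(system$atoms$charge)

#' Read frames from a CHARMM/NAMD DCD trajectory
#'
#' Endianness is auto-detected from the leading Fortran record marker; both
#' little- and big-endian files are accepted. Unit-cell records are skipped.
#' Files with a fixed-atom block (NFIXED > 0) are rejected. Frames
#' \code{first..last} (0-based, inclusive) sampled every \code{stride} are
#' appended to \code{system}, replacing any placeholder frame from
#' \code{\link{read_psf}}.
#'
#' @param path Path to a DCD file.
#' @param system The \code{molecular_system} providing the topology.
#' @param stride Keep every \code{stride}-th frame (default 1).
#' @param first,last 0-based first/last frame indices (defaults: whole file).
#' @return \code{system} with frames loaded.
#' @export
read_dcd <- function(path, system, stride = 1, first = 0, last = NULL) {
  if (!file.exists(path)) stop("read_dcd(): file not found: ", path)
  stopifnot(stride >= 1)
  hdr <- dcd_header(path)
  if (hdr$nfixed > 0) {
    stop("read_dcd(): DCD files with fixed-atom blocks are not supported")
  }
  if (hdr$natom != nrow(system$atoms)) {
    stop("read_dcd(): topology/trajectory inconsistency: DCD has ",
         hdr$natom, " atoms, system has ", nrow(system$atoms))
  }
  trj <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
  nf <- nrow(trj)
  if (nf < hdr$nframes) {
    stop("read_dcd(): truncated trajectory: header promises ", hdr$nframes,
         " frames, last complete frame is ", nf)
  }
  if (is.null(last)) last <- nf - 1
  if (first < 0 || last >= nf || first > last) {
    stop("read_dcd(): frame range [", first, ", ", last,
         "] invalid for ", nf, "-frame file")
  }
  sel <- seq(first + 1, last + 1, by = stride)
  frames <- lapply(sel, function(i) {
    matrix(trj[i, ], ncol = 3, byrow = TRUE)
  })
  system$frames <- frames
  if (hdr$delta > 0) {
    system$frame_times <- (sel - 1) * hdr$delta * hdr$nsavc * 0.0488882 # AKMA->ps
  }
  system
}

# Parse the DCD header with explicit endianness detection.
dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw4 <- readBin(con, "raw", n = 4)
  le <- readBin(raw4, "integer", size = 4, endian = "little")
  be <- readBin(raw4, "integer", size = 4, endian = "big")
  endian <- if (le == 84) "little" else if (be == 84) "big" else
    stop("dcd_header(): not a DCD file (bad leading record marker)")
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (magic != "CORD") stop("dcd_header(): missing CORD magic")
  icntrl <- readBin(con, "integer", n = 20, size = 4, endian = endian)
  readBin(con, "integer", n = 1, size = 4, endian = endian) # close marker
  # title block
  tlen <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  readBin(con, "raw", n = tlen)
  readBin(con, "integer", n = 1, size = 4, endian = endian)
  # natom block
  readBin(con, "integer", n = 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  list(
    big_endian = endian == "big",
    nframes = icntrl[1],
    nsavc = max(icntrl[3], 1),
    delta = readBin(writeBin(icntrl[10], raw(), size = 4, endian = endian),
                    "numeric", size = 4, endian = endian),
    nfixed = icntrl[9],
    has_cell = icntrl[11] == 1,
    natom = natom
  )
}

#' Assign partial charges and Lennard-Jones parameters
#'
#' For trajectory input the atom types come from the PSF; for static PDB
#' input, types and charges are first filled from the bundled residue
#' template table (CHARMM-style names). Epsilon/Rmin/2 are then looked up in
#' the NONBONDED section of a CHARMM-format parameter file. CHARMM prints
#' epsilon as a negative number; it is stored here as its magnitude
#' (kcal/mol).
#'
#' @param system A \code{molecular_system}.
#' @param param_path Path to a CHARMM-format parameter file; default is the
#'   bundled synthetic parameter set.
#' @return \code{system} with \code{charge}, \code{lj_epsilon} and
#'   \code{lj_rmin_half} populated.
#' @export
assign_nonbonded_params <- function(system,
                                    param_path = default_param_file()) {
  at <- system$atoms
  if (all(is.na(at$type))) {
    system <- assign_template_types(system)
    at <- system$atoms
  }
  tab <- read_charmm_nonbonded(param_path)
  known <- !is.na(at$type)
  idx <- match(at$type[known], tab$type)
  if (anyNA(idx)) {
    missing <- sort(unique(at$type[known][is.na(idx)]))
    stop("assign_nonbonded_params(): atom type(s) absent from ", param_path,
         ": ", paste(missing, collapse = ", "))
  }
  at$lj_epsilon[known] <- tab$epsilon[idx]
  at$lj_rmin_half[known] <- tab$rmin_half[idx]
  system$atoms <- at
  system
}

#' @rdname assign_nonbonded_params
#' @export
default_param_file <- function() {
  system.file("extdata", "params_synthetic.prm", package = "rinmd",
              mustWork = TRUE)
}

#' Parse the NONBONDED section of a CHARMM parameter file
#'
#' @param path Parameter file path.
#' @return data.frame with columns \code{type}, \code{epsilon} (kcal/mol,
#'   positive magnitude) and \code{rmin_half} (Angstrom).
#' @export
read_charmm_nonbonded <- function(path) {
  if (!file.exists(path)) {
    stop("read_charmm_nonbonded(): file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  start <- grep("^[[:space:]]*NONBONDED", lines)[1]
  if (is.na(start)) {
    stop("read_charmm_nonbonded(): no NONBONDED section in ", path)
  }
  # skip the option line(s): continuation is marked by a trailing '-'
  i <- start
  while (i <= length(lines) && grepl("-[[:space:]]*$", trimws(lines[i]))) {
    i <- i + 1
  }
  i <- i + 1
  section_end <- c("HBOND", "NBFIX", "CMAP", "END", "BONDS", "ANGLES",
                   "DIHEDRALS", "IMPROPER")
  out <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    i <- i + 1
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (toupper(tok[1]) %in% section_end) break
    if (length(tok) < 4 || is.na(suppressWarnings(as.numeric(tok[3])))) {
      stop("read_charmm_nonbonded(): malformed NONBONDED line: ", ln)
    }
    out[[length(out) + 1]] <- data.frame(
      type = tok[1],
      epsilon = abs(as.numeric(tok[3])),
      rmin_half = as.numeric(tok[4]),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    stop("read_charmm_nonbonded(): empty NONBONDED section in ", path)
  }
  do.call(rbind, out)
}

# --- residue-template assignment (static-PDB path) -------------------------

residue_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "residue_templates_synthetic.tsv",
                       package = "rinmd", mustWork = TRUE)
      cache <<- utils::read.table(f, header = TRUE, sep = "\t",
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
    }
    cache
  }
})

# PDB-v3 / CHARMM atom-name aliases tried when a direct lookup fails
.name_aliases <- c(
  "H" = "HN", "HT1" = "HN", "H1" = "HN",
  "HB3" = "HB1", "HG3" = "HG1", "HD3" = "HD1", "HE3" = "HE1",
  "HA3" = "HA1", "HG13" = "HG11", "HZ3" = "HZ1",
  "CD1" = "CD", "HD11" = "HD1", "HD12" = "HD2", "HD13" = "HD3",
  "OXT" = "OC", "OT1" = "O", "OT2" = "OC"
)

#' Assign force-field atom types and charges from the bundled templates
#'
#' Used on the static-PDB path, where no PSF topology supplies types and
#' charges. Histidine (HIS) is resolved to HSD/HSE/HSP from its hydrogen
#' inventory. Atoms that cannot be matched keep zero charge and NA type; a
#' single warning lists them.
#'
#' @param system A \code{molecular_system}.
#' @return \code{system} with \code{type} and \code{charge} filled in where
#'   a template matches.
#' @export
assign_template_types <- function(system) {
  tpl <- residue_templates()
  at <- system$atoms
  res <- system$residues
  resnames <- at$resname
  # resolve HIS variants residue-by-residue from the atom inventory
  for (r in which(res$resname %in% c("HIS", .his_variants))) {
    span <- res$first[r]:res$last[r]
    resnames[span] <- his_variant(at$name[span], res$resname[r])
  }
  unmatched <- character(0)
  for (i in seq_len(nrow(at))) {
    rn <- resnames[i]
    nm <- at$name[i]
    hit <- tpl[tpl$resname == rn & tpl$atom == nm, ]
    if (nrow(hit) == 0 && !(rn %in% c("GLY", "PRO"))) {
      hit <- tpl[tpl$resname == "BB" & tpl$atom == nm, ]
    }
    if (nrow(hit) == 0 && nm %in% names(.name_aliases)) {
      alias <- .name_aliases[[nm]]
      hit <- tpl[tpl$resname %in% c(rn, "BB") & tpl$atom == alias, ]
    }
    if (nrow(hit) == 0) {
      unmatched <- c(unmatched, paste0(rn, ":", nm))
      next
    }
    at$type[i] <- hit$type[1]
    at$charge[i] <- hit$charge[1]
  }
  if (length(unmatched) > 0) {
    warning("assign_template_types(): no template for ",
            paste(unique(unmatched), collapse = ", "),
            " (charge left at 0)")
  }
  system$atoms <- at
  system
}

# histidine protonation variant from hydrogen inventory:
# HD1 and HE2 both present -> HSP (cationic); HE2 only -> HSE; else HSD
his_variant <- function(atom_names, resname) {
  if (resname %in% .his_variants) {
    return(c(HID = "HSD", HIE = "HSE", HIP = "HSP")[resname] %||% resname)
  }
  has_hd1 <- "HD1" %in% atom_names
  has_he2 <- "HE2" %in% atom_names
  if (has_hd1 && has_he2) "HSP" else if (has_he2) "HSE" else "HSD"
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
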