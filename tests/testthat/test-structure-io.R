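test_that("hand-written PDB text parses into residues and one frame", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.674   6.661  -4.120  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       9.902   5.778  -3.459  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       8.930   6.174  -2.452  1.00  0.00           C",
    "ATOM      6  N   SER A   3       8.201   5.098  -1.851  1.00  0.00           N",
    "ATOM      7  CA  SER A   3       7.252   5.339  -0.778  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  sys <- read_pdb(f)
  expect_equal(nrow(sys$residues), 3)
  expect_equal(length(sys$frames), 1)
  expect_equal(sys$atoms$name[2], "CA")
  expect_equal(sys$frames[[1]][1, ], c(11.104, 6.134, -6.504))
})

test_that("waters survive read but not strip_non_protein", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  sys <- read_pdb(f)
  expect_equal(nrow(sys$atoms), 2)
  stripped <- strip_non_protein(sys)
  expect_equal(nrow(stripped$atoms), 1)
  expect_equal(stripped$atoms$resname, "ALA")
  # idempotent
  expect_identical(strip_non_protein(stripped)$atoms, stripped$atoms)
})

test_that("ligand-only input raises an empty-system error; His variants survive", {
  pdb <- c(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_error(strip_non_protein(read_pdb(f)), "empty")

  sys <- random_system(6, seed = 2)
  sys$atoms$resname[sys$atoms$resname == "ALA"] <- "HSD"
  sys <- molecular_system(sys$atoms, sys$frames)
  kept <- strip_non_protein(sys)
  expect_equal(nrow(kept$atoms), nrow(sys$atoms))
})

test_that("PDB write -> read round-trips coordinates at format precision", {
  sys <- random_system(50, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(sys$atoms))
  expect_identical(back$atoms$name, sys$atoms$name)
  expect_identical(back$atoms$resname, sys$atoms$resname)
  expect_lt(max(abs(back$frames[[1]] - sys$frames[[1]])), 5e-4)
  # second round trip is exact (idempotence at PDB precision)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  expect_identical(read_pdb(f2)$frames[[1]], back$frames[[1]])
})

test_that("altloc resolution keeps the highest-occupancy single conformer", {
  pdb <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  sys <- read_pdb(f)
  expect_equal(nrow(sys$atoms), 2)
  expect_equal(sys$frames[[1]][1, 1], 9.0)
})

test_that("PSF parse recovers atoms, charges, segments and bonds", {
  sys <- make_dipeptide_pair("COULOMB", distance = 4)
  sys$bonds <- cbind(1L, 2L)
  f <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys, f)
  top <- read_psf(f)
  expect_equal(nrow(top$atoms), nrow(sys$atoms))
  expect_equal(top$atoms$charge, sys$atoms$charge, tolerance = 1e-9)
  expect_equal(total_charge(top), 0)
  expect_equal(top$bonds, cbind(1L, 2L))
  # charge conservation is exact summation of the file column
  sys2 <- random_system(10, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys2, f2)
  expect_equal(total_charge(read_psf(f2)), sum(sys2$atoms$charge),
               tolerance = 1e-9)
})

test_that("EXT and standard PSF layouts parse identically", {
  sys <- random_system(8, seed = 4)
  f1 <- withr::local_tempfile(fileext = ".psf")
  f2 <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys, f1, ext = FALSE)
  write_psf(sys, f2, ext = TRUE)
  a <- read_psf(f1); b <- read_psf(f2)
  expect_identical(a$atoms$name, b$atoms$name)
  expect_equal(a$atoms$charge, b$atoms$charge, tolerance = 1e-9)
  expect_identical(a$atoms$resno, b$atoms$resno)
})

test_that("PSF atom-count mismatch and unknown dialect are format errors", {
  sys <- random_system(4, seed = 6)
  f <- withr::local_tempfile(fileext = ".psf")
  write_psf(sys, f)
  lines <- readLines(f)
  lines[grep("!NATOM", lines)] <- sprintf("%8d !NATOM", nrow(sys$atoms) + 3)
  writeLines(lines, f)
  expect_error(read_psf(f), "NATOM")
  lines[1] <- "PSF WEIRD"
  writeLines(lines, f)
  expect_error(read_psf(f), "dialect")
})

test_that("DCD frame selection follows floor((last-first)/stride)+1", {
  sys <- random_system(6, seed = 7)
  frames <- lapply(1:10, function(f) sys$frames[[1]] + f * 0.1)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(frames, f)
  top <- sys
  expect_equal(n_frames(read_dcd(f, top, stride = 2)), 5)
  expect_equal(n_frames(read_dcd(f, top, stride = 3)), 4)
  one <- read_dcd(f, top, first = 0, last = 0)
  expect_equal(n_frames(one), 1)
  expect_lt(max(abs(one$frames[[1]] - frames[[1]])), 1e-5)
  for (st in 1:4) {
    for (first in 0:2) {
      got <- n_frames(read_dcd(f, top, stride = st, first = first))
      expect_equal(got, floor((9 - first) / st) + 1)
    }
  }
})

test_that("byte-swapped DCD parses to identical coordinates", {
  sys <- random_system(6, seed = 8)
  frames <- lapply(1:4, function(f) sys$frames[[1]] + f)
  fl <- withr::local_tempfile(fileext = ".dcd")
  fb <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(frames, fl, endian = "little")
  write_dcd(frames, fb, endian = "big")
  a <- read_dcd(fl, sys); b <- read_dcd(fb, sys)
  expect_identical(a$frames, b$frames)
})

test_that("DCD atom-count mismatch is a topology/trajectory error", {
  sys <- random_system(6, seed = 9)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(list(sys$frames[[1]]), f)
  small <- subset_residues_for_test(sys, 1:3)
  expect_error(read_dcd(f, small), "inconsisten")
})

test_that("CHARMM NONBONDED parsing reads epsilon magnitude and Rmin/2", {
  prm <- c(
    "* test", "*", "",
    "NONBONDED nbxmod 5 atom cdiel shift -",
    "cutnb 14.0 eps 1.0",
    "CT3    0.000000  -0.078000     2.040000",
    "OX     0.000000  -0.120000     1.700000 ! comment",
    "",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".prm")
  writeLines(prm, f)
  tab <- read_charmm_nonbonded(f)
  expect_equal(tab$epsilon[tab$type == "CT3"], 0.078)
  expect_equal(tab$rmin_half[tab$type == "CT3"], 2.040)
  expect_equal(nrow(tab), 2)
})

test_that("parameter assignment fills every typed atom or names the gap", {
  sys <- random_system(5, seed = 10)
  sys$atoms$type <- "CT3"
  prm <- withr::local_tempfile(fileext = ".prm")
  writeLines(c("NONBONDED nbxmod 5", "CT3 0.0 -0.078 2.040", "END"), prm)
  got <- assign_nonbonded_params(sys, prm)
  expect_true(all(got$atoms$lj_epsilon == 0.078))
  expect_true(all(got$atoms$lj_rmin_half == 2.040))
  sys$atoms$type[3] <- "ZZ9"
  expect_error(assign_nonbonded_params(sys, prm), "ZZ9")
})

test_that("template assignment gives integer formal charges per residue", {
  # full-atom residues are not generated here; instead check the bundled
  # template table directly: each residue template sums to its formal charge
  tf <- system.file("extdata", "residue_templates_synthetic.tsv",
                    package = "rinmd")
  tpl <- read.table(tf, header = TRUE, sep = "\t", comment.char = "#")
  bb <- sum(tpl$charge[tpl$resname == "BB"])
  expect_equal(bb, 0, tolerance = 1e-9)
  formal <- c(ALA = 0, VAL = 0, LEU = 0, ILE = 0, SER = 0, THR = 0, CYS = 0,
              MET = 0, PHE = 0, TYR = 0, TRP = 0, ASN = 0, GLN = 0,
              ASP = -1, GLU = -1, LYS = 1, ARG = 1,
              GLY = 0, PRO = 0, HSD = 0, HSE = 0, HSP = 1)
  for (rn in names(formal)) {
    side <- sum(tpl$charge[tpl$resname == rn])
    total <- if (rn %in% c("GLY", "PRO")) side else side + bb
    expect_equal(total, unname(formal[rn]), tolerance = 1e-9,
                 label = paste("formal charge of", rn))
  }
  # and the bundled parameter file covers every template type
  tab <- read_charmm_nonbonded(default_param_file())
  expect_true(all(unique(tpl$type) %in% tab$type))
})
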