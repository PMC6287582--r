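crit <- interaction_criteria()

rec_keys <- function(rec) {
  if (nrow(rec) == 0) return(character(0))
  sort(paste(rec$res_i, rec$res_j))
}

test_that("every detector matches its exhaustive brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    for (n in c(20, 40)) {
      sys <- random_system(n, seed = seed)
      expect_identical(rec_keys(detect_calpha(sys, 1, crit)),
                       oracle_calpha(sys, crit),
                       label = sprintf("calpha n=%d seed=%d", n, seed))
      got_hb <- detect_hbonds(sys, 1, crit)
      hb_keys <- sort(paste(got_hb$res_i, got_hb$res_j,
                            gsub("\\|", " ", got_hb$atoms)))
      expect_identical(hb_keys, oracle_hbonds(sys, crit),
                       label = sprintf("hbond n=%d seed=%d", n, seed))
      expect_identical(rec_keys(detect_salt_bridges(sys, 1, crit)),
                       oracle_salt_bridges(sys, crit))
      expect_identical(rec_keys(suppressWarnings(
        detect_disulfides(sys, 1, crit))),
        oracle_disulfides(sys, crit))
      expect_identical(rec_keys(detect_pi_pi(sys, 1, crit)),
                       oracle_pi_pi(sys, crit))
      expect_identical(rec_keys(detect_cation_pi(sys, 1, crit)),
                       oracle_cation_pi(sys, crit))
      expect_identical(rec_keys(detect_arg_arg(sys, 1, crit)),
                       oracle_arg_arg(sys, crit))
      en <- oracle_energy_edges(sys, crit)
      expect_identical(rec_keys(detect_coulomb(sys, 1, crit)), en$coulomb)
      expect_identical(rec_keys(detect_vdw(sys, 1, crit)), en$vdw)
    }
  }
})

test_that("detection is invariant under global rigid transforms", {
  set.seed(21)
  sys <- random_system(25, seed = 21)
  moved <- transform_system(sys, random_rotation(), rnorm(3, sd = 25))
  for (fn in list(detect_calpha, detect_hbonds, detect_salt_bridges,
                  detect_pi_pi, detect_cation_pi, detect_arg_arg,
                  detect_coulomb, detect_vdw)) {
    a <- fn(sys, 1, crit)
    b <- fn(moved, 1, crit)
    expect_identical(a[, c("res_i", "res_j", "atoms")],
                     b[, c("res_i", "res_j", "atoms")])
    expect_equal(a$distance, b$distance, tolerance = 1e-8)
    expect_equal(a$energy, b$energy, tolerance = 1e-7)
  }
})

test_that("distance thresholds include exact equality", {
  expect_equal(nrow(detect_calpha(
    make_dipeptide_pair("CALPHA", distance = 8))), 1)
  expect_equal(nrow(detect_salt_bridges(
    make_dipeptide_pair("SALT_BRIDGE", distance = 6))), 1)
  expect_equal(nrow(detect_pi_pi(
    make_dipeptide_pair("PI_PI", distance = 6))), 1)
  expect_equal(nrow(detect_cation_pi(
    make_dipeptide_pair("CATION_PI", distance = 7, angle = 0))), 1)
  expect_equal(nrow(detect_arg_arg(
    make_dipeptide_pair("ARG_ARG", distance = 5))), 1)
  expect_equal(nrow(detect_hbonds(
    make_dipeptide_pair("HBOND", distance = 3, angle = 180))), 1)
  expect_equal(nrow(detect_disulfides(
    make_dipeptide_pair("DISULFIDE", distance = 3, dihedral = 75))), 1)
})

test_that("C-alpha contacts: default cutoff and sequence-neighbour exclusion", {
  sys <- make_dipeptide_pair("CALPHA", distance = 7.5)
  rec <- detect_calpha(sys)
  expect_equal(rec$distance, 7.5)
  expect_equal(nrow(detect_calpha(
    make_dipeptide_pair("CALPHA", distance = 8.3))), 0)
  # |i-j| <= 2 on the same chain is excluded
  near <- sys
  near$atoms$resno <- c(1L, 3L)
  near <- molecular_system(near$atoms, near$frames)
  expect_equal(nrow(detect_calpha(near)), 0)
  # but inter-chain pairs never are
  cross <- sys
  cross$atoms$chain <- c("A", "B")
  cross$atoms$resno <- c(1L, 1L)
  cross <- molecular_system(cross$atoms, cross$frames)
  expect_equal(nrow(detect_calpha(cross)), 1)
})

test_that("hydrogen bonds respect both the distance and the angle criterion", {
  ok <- detect_hbonds(make_dipeptide_pair("HBOND", distance = 2.9,
                                          angle = 180))
  expect_equal(nrow(ok), 1)
  expect_equal(ok$distance, 2.9, tolerance = 1e-9)
  expect_equal(ok$angle, 180, tolerance = 1e-6)
  # donor is stored as residue i
  expect_match(ok$atoms, "^N\\|HN\\|O$")
  expect_equal(nrow(detect_hbonds(
    make_dipeptide_pair("HBOND", distance = 2.9, angle = 90))), 0)
  expect_equal(nrow(detect_hbonds(
    make_dipeptide_pair("HBOND", distance = 2.9, angle = 119))), 0)
  expect_equal(nrow(detect_hbonds(
    make_dipeptide_pair("HBOND", distance = 3.4, angle = 180))), 0)
  # no hydrogens at all -> warning and empty result
  sys <- make_dipeptide_pair("CALPHA", distance = 5)
  expect_warning(out <- detect_hbonds(sys), "hydrogen")
  expect_equal(nrow(out), 0)
})

test_that("disulfide dihedral band is inclusive at both edges", {
  # the 85-degree construction reproduces its torsion to the last bit, so
  # shrinking the band to [85, 85] probes exact-boundary inclusivity
  tight <- interaction_criteria(ss_dihedral_lo = 85, ss_dihedral_hi = 85)
  at_edge <- detect_disulfides(
    make_dipeptide_pair("DISULFIDE", distance = 2.05, dihedral = 85),
    criteria = tight
  )
  expect_equal(nrow(at_edge), 1)
})

test_that("disulfides use an unsigned dihedral band", {
  for (chi in c(85, -85, 61, 90)) {
    got <- detect_disulfides(make_dipeptide_pair("DISULFIDE",
                                                 distance = 2.05,
                                                 dihedral = chi))
    expect_equal(nrow(got), 1, label = paste("chi", chi))
    expect_equal(got$dihedral, chi, tolerance = 1e-6)
  }
  expect_equal(nrow(detect_disulfides(
    make_dipeptide_pair("DISULFIDE", distance = 2.05, dihedral = 30))), 0)
  expect_equal(nrow(detect_disulfides(
    make_dipeptide_pair("DISULFIDE", distance = 2.05, dihedral = 110))), 0)
  expect_equal(nrow(detect_disulfides(
    make_dipeptide_pair("DISULFIDE", distance = 3.4, dihedral = 85))), 0)
})

test_that("cation-pi uses ring-face angle bands symmetric in the normal sign", {
  on_axis <- detect_cation_pi(make_dipeptide_pair("CATION_PI", distance = 4,
                                                  angle = 0))
  expect_equal(nrow(on_axis), 1)
  expect_equal(on_axis$angle, 0, tolerance = 1e-6)
  expect_equal(nrow(detect_cation_pi(
    make_dipeptide_pair("CATION_PI", distance = 5, angle = 90))), 0)
  flip <- detect_cation_pi(make_dipeptide_pair("CATION_PI", distance = 4,
                                               angle = 175))
  expect_equal(nrow(flip), 1)
  expect_equal(flip$angle, 175, tolerance = 1e-6)
})

test_that("Coulomb energy matches the closed form and the 1/r law", {
  co <- make_dipeptide_pair("COULOMB", distance = 3.32)
  e <- coulomb_energy(co, 1, 1, 2)
  expect_equal(e, -332.0636 / 3.32, tolerance = 1e-10)
  co2 <- make_dipeptide_pair("COULOMB", distance = 6.64)
  expect_equal(coulomb_energy(co2, 1, 1, 2), e / 2, tolerance = 1e-10)
  # random-charge residues against the naive double loop
  sys <- random_system(8, seed = 31)
  for (i in 1:4) {
    for (j in 5:8) {
      expect_equal(coulomb_energy(sys, 1, i, j, crit),
                   unname(oracle_pair_energy(sys, i, j, crit)["coulomb"]),
                   tolerance = 1e-10)
    }
  }
  bare <- sys
  bare$atoms$charge <- 0
  expect_error(detect_coulomb(bare, 1, crit), "not assigned")
})

test_that("Lennard-Jones pair energy hits -epsilon at Rmin", {
  v <- make_dipeptide_pair("VDW", distance = 4, epsilon = 0.2, rmin_half = 2)
  got <- detect_vdw(v)
  expect_equal(got$energy, -0.2, tolerance = 1e-12)
  # r = 2 Rmin: epsilon (2^-12 - 2 * 2^-6)
  v2 <- make_dipeptide_pair("VDW", distance = 8, epsilon = 0.2, rmin_half = 2)
  pe <- residue_pair_energies_for_test(v2, crit)
  expect_equal(pe$vdw, 0.2 * (2^-12 - 2 * 2^-6), tolerance = 1e-12)
  bare <- v
  bare$atoms$lj_epsilon <- 0
  expect_error(detect_vdw(bare, 1, crit), "not assigned")
})

test_that("detect_all composes detectors deterministically", {
  sys <- random_system(25, seed = 41)
  expect_identical(detect_all(sys, 1, crit, "CALPHA"),
                   detect_calpha(sys, 1, crit))
  expect_equal(nrow(detect_all(sys, 1, crit, character(0))), 0)
  all_got <- suppressWarnings(detect_all(sys, 1, crit))
  per_type <- suppressWarnings(lapply(
    list(detect_calpha, detect_hbonds, detect_salt_bridges,
         detect_disulfides, detect_cation_pi, detect_pi_pi, detect_arg_arg,
         detect_coulomb, detect_vdw),
    function(f) f(sys, 1, crit)
  ))
  expect_equal(nrow(all_got), sum(vapply(per_type, nrow, numeric(1))))
  expect_error(detect_all(sys, 1, crit, "NOPE"), "unknown")
})

test_that("atom-order permutation does not change the detected set", {
  sys <- random_system(20, seed = 51)
  # permute atoms within each residue (residue spans must stay contiguous)
  set.seed(52)
  idx <- unlist(lapply(seq_len(nrow(sys$residues)), function(r) {
    span <- sys$residues$first[r]:sys$residues$last[r]
    span[sample(length(span))]
  }))
  atoms2 <- sys$atoms[idx, , drop = FALSE]
  perm <- molecular_system(atoms2, list(sys$frames[[1]][idx, , drop = FALSE]))
  for (fn in list(detect_calpha, detect_salt_bridges, detect_pi_pi,
                  detect_cation_pi, detect_arg_arg, detect_coulomb,
                  detect_vdw)) {
    expect_identical(rec_keys(fn(sys, 1, crit)), rec_keys(fn(perm, 1, crit)))
  }
})
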