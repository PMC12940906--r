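# Torsion measurement, planes, axial repeat and group distances.

test_that("dihedral_angle reproduces reference configurations", {
  # eclipsed and anti arrangements in a plane
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  # right-angle case, checked against the atan2 torsion formula by hand
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
})

test_that("dihedral_angle is invariant under rigid motion and order reversal", {
  set.seed(101)
  for (k in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 2))
    ref <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    m <- random_rigid_motion()
    q <- lapply(p, function(v) as.numeric(m$R %*% v + m$t))
    expect_equal(dihedral_angle(q[[1]], q[[2]], q[[3]], q[[4]]), ref,
                 tolerance = 1e-9)
    expect_equal(dihedral_angle(p[[4]], p[[3]], p[[2]], p[[1]]), ref,
                 tolerance = 1e-9)
  }
})

test_that("reflection negates every dihedral and signed twist", {
  s <- build_peptide("AAAA", phi = -100, psi = 125)
  m <- mirror_structure(s)
  dh <- backbone_dihedrals(s)
  dm <- backbone_dihedrals(m)
  for (col in c("phi", "psi", "omega")) {
    ok <- !is.na(dh[[col]]) & abs(abs(dh[[col]]) - 180) > 1e-9
    expect_equal(dm[[col]][ok], -dh[[col]][ok], tolerance = 1e-9)
  }
  expect_equal(peptide_plane_twist(m, 1)$twist,
               -peptide_plane_twist(s, 1)$twist, tolerance = 1e-9)
})

test_that("degenerate (collinear) points are refused", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("backbone_dihedrals recovers build angles and flags chain ends", {
  s <- build_peptide("AAA", phi = c(180, -120, -80), psi = c(135, 135, 170))
  dh <- backbone_dihedrals(s)
  expect_true(is.na(dh$phi[1]))
  expect_true(is.na(dh$psi[3]))
  expect_true(is.na(dh$omega[3]))
  expect_equal(dh$phi[2], -120, tolerance = 1e-6)
  expect_equal(dh$phi[3], -80, tolerance = 1e-6)
  expect_equal(dh$psi[1], 135, tolerance = 1e-6)
  expect_equal(dh$psi[2], 135, tolerance = 1e-6)
  expect_equal(dh$omega[1], 180, tolerance = 1e-6)
})

test_that("backbone_dihedrals errors on missing backbone atoms", {
  s <- build_peptide("AAA")
  s$atoms <- s$atoms[!(s$atoms$resid == 2 & s$atoms$name == "CA"), ]
  expect_error(backbone_dihedrals(s), "residue 2.*CA")
})

test_that("dihedrals agree with an independent torsion implementation", {
  s <- build_peptide("AAAA", phi = -139, psi = 135)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  dh <- backbone_dihedrals(s)
  # PDB coordinates are rounded to 1e-3 A, so allow a few hundredths of a degree
  expect_equal(unname(tor$phi[2:4]), dh$phi[2:4], tolerance = 1e-3)
  expect_equal(unname(tor$psi[1:3]), dh$psi[1:3], tolerance = 1e-3)
})

test_that("axial repeat distinguishes extended from beta conformations", {
  ext <- build_peptide("AAAAA")
  beta <- build_peptide("AAAAA", phi = -139, psi = 135)
  expect_gt(axial_repeat(ext, 2), 7.0)
  expect_gt(axial_repeat(beta, 2), 6.5)
  expect_lt(axial_repeat(beta, 2), 7.0)
  expect_error(axial_repeat(ext, 4), "out of range")
})

test_that("peptide planes: coplanar all-trans, uniform conformations uniform", {
  ext <- build_peptide("AAAAA")
  expect_equal(peptide_plane_twist(ext, 2)$twist, 0, tolerance = 1e-3)
  beta <- build_peptide("AAAAAA", phi = -120, psi = 135)
  tw <- vapply(1:4, function(i) peptide_plane_twist(beta, i)$twist, 0)
  expect_gt(min(tw), 0)                         # right-handed throughout
  expect_lt(max(tw) - min(tw), 1e-6)            # helical symmetry
})

test_that("bend angle is bounded, uniform for uniform dihedrals, rigid-invariant", {
  beta <- build_peptide("AAAAAAA", phi = -139, psi = 135)
  b <- vapply(1:4, function(i) bend_angle(beta, i), 0)
  expect_true(all(b >= 0 & b < 180))
  expect_lt(max(b) - min(b), 1e-6)
  m <- random_rigid_motion()
  expect_equal(bend_angle(transform_structure(beta, m$R, m$t), 2), b[2],
               tolerance = 1e-9)
  expect_error(bend_angle(beta, 5), "out of range")
})

test_that("min_group_distance finds the closest pair and validates selections", {
  s <- build_peptide("AAA")
  hit <- min_group_distance(s, list(resid = 1, name = "O"),
                            list(resid = 2, name = "HB*"))
  expect_equal(hit$distance, 2.20408, tolerance = 1e-4)
  expect_identical(hit$atomA, "O@1")
  expect_match(hit$atomB, "^HB[0-9]@2$")
  expect_error(min_group_distance(s, list(name = "ZZ"), list(name = "CA")),
               "empty")
  expect_error(min_group_distance(s, list(name = "CA"), list(name = "CA")),
               "overlap")
})
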