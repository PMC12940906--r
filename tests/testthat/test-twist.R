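# Handedness classification from the wrapped sum phi + psi.

test_that("wrap_sum reduces into (-180, 180] with 180 canonical", {
  expect_equal(wrap_sum(180, 180), 0)
  expect_equal(wrap_sum(-120, 135), 15)
  expect_equal(wrap_sum(-90, -170), 100)
  expect_equal(wrap_sum(90, 90), 180)
  expect_equal(wrap_sum(-90, -90), 180)   # -180 is identified with 180
  expect_true(is.na(wrap_sum(NA, 20)))
})

test_that("classify_twist labels the reference conformations", {
  expect_identical(classify_twist(-120, 135)$handedness, "right")
  expect_identical(classify_twist(-60, -45)$handedness, "left")
  expect_identical(classify_twist(180, 180)$handedness, "none")
  expect_identical(classify_twist(10, 0)$handedness, "right")
  expect_identical(classify_twist(-350, 0)$handedness, "right") # periodic input
  nb <- classify_twist(90, 90)
  expect_identical(nb$handedness, "none")
  expect_true(nb$non_beta)
  ends <- classify_twist(NA, 135)
  expect_identical(ends$handedness, "none")
  expect_true(ends$end_of_chain)
})

test_that("wrapped-sign rule matches the literal interval rule on a 1-deg grid", {
  literal <- function(t) {
    if ((t > -180 && t < 0) || (t > 180 && t < 360)) return("left")
    if ((t > -360 && t < -180) || (t > 0 && t < 180)) return("right")
    "none"
  }
  for (split in c(0, -90, 137)) {   # decompositions t = phi + psi
    t <- seq(-359, 359, by = 1)
    got <- classify_twist(t - split, rep(split, length(t)))$handedness
    expect_identical(got, vapply(t, literal, ""))
  }
})

test_that("classification is periodic and antisymmetric", {
  phi <- seq(-170, 170, by = 20)
  psi <- seq(-150, 150, by = 17)[seq_along(phi)]
  base <- classify_twist(phi, psi)$handedness
  expect_identical(classify_twist(phi + 360, psi)$handedness, base)
  expect_identical(classify_twist(phi, psi - 360)$handedness, base)
  flipped <- classify_twist(-phi, -psi)$handedness
  swap <- c(right = "left", left = "right", none = "none")
  expect_identical(flipped, unname(swap[base]))
})

test_that("classify_residues labels built strands consistently", {
  ext <- classify_residues(backbone_dihedrals(build_peptide("AAAA")))
  mid <- !ext$end_of_chain
  expect_true(all(ext$handedness[mid] == "none"))
  beta <- classify_residues(backbone_dihedrals(
    build_peptide("AAAAA", phi = -120, psi = 135)))
  expect_true(all(beta$handedness[!beta$end_of_chain] == "right"))
  # (-139, +135) sums to -4: locally left by the diagonal rule
  pl <- classify_residues(backbone_dihedrals(
    build_peptide("AAAAA", phi = -139, psi = 135)))
  expect_true(all(pl$handedness[!pl$end_of_chain] == "left"))
})

test_that("strand aggregation nets the sign of the mean wrapped sum", {
  lab <- classify_twist(c(15, 20, -5), c(0, 0, 0))
  rep1 <- strand_net_twist(lab)
  expect_identical(rep1$net_handedness, "right")
  expect_equal(rep1$mean_wrapped_sum, 10)
  expect_identical(rep1$counts[["left"]], 1L)
  expect_identical(strand_net_twist(classify_twist(c(10, -10), 0))$net_handedness,
                   "none")
  expect_identical(strand_net_twist(classify_twist(-40, 0))$net_handedness,
                   "left")
  expect_error(strand_net_twist(classify_twist(NA, NA)), "no residue")
})

test_that("plane-twist sign agrees with the diagonal rule across the beta box", {
  d <- sample_beta_dihedrals(100, seed = 42)
  s <- wrap_sum(d$phi, d$psi)
  ok <- abs(s) > 10 & abs(abs(s) - 180) > 10
  tw <- mapply(function(p, q) {
    peptide_plane_twist(build_peptide("AAAAA", phi = p, psi = q), 2)$twist
  }, d$phi[ok], d$psi[ok])
  expect_gte(mean(sign(tw) == sign(s[ok])), 0.95)
})

test_that("ramachandran_plot writes an image and a faithful TSV twin", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rama.pdf")
  d <- sample_beta_dihedrals(2000, seed = 3)
  out <- ramachandran_plot(d, path, track = 1:10)
  expect_true(file.exists(out$image))
  tsv <- read.delim(out$tsv)
  expect_identical(nrow(tsv), 2000L)
  # the TSV twin reports exactly what the classifier computes
  expect_identical(tsv$handedness, classify_twist(d$phi, d$psi)$handedness)
  expect_gt(sum(tsv$handedness == "right"), sum(tsv$handedness == "left"))
  # all-trans input is a single point on the wrapped diagonal corner
  one <- ramachandran_plot(data.frame(phi = 180, psi = 180),
                           file.path(dir, "one.pdf"))
  t1 <- read.delim(one$tsv)
  expect_identical(t1$handedness, "none")
  expect_error(ramachandran_plot(d, file.path(dir, "rama.svg")),
               "unsupported image format")
})

test_that("propeller increment divides the end-to-end angle evenly", {
  expect_identical(propeller_increment(4, 90), 30)
  expect_identical(propeller_increment(2, 90), 90)
  expect_identical(propeller_increment(10, 90), 10)
  expect_error(propeller_increment(1), "at least 2")
})
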