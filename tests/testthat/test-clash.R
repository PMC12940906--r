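# Van der Waals overlap detection and the four-category clash scheme.

test_that("the extended tri-alanine shows the two initiating clashes", {
  s <- build_peptide("AAA")
  cl <- detect_clashes(s)
  # carbonyl O against the next residue's beta hydrogens (radii 1.5 + 1.2)
  o_hb <- cl[cl$category == "CB_O_prev" & grepl("^O@", cl$atomA), ]
  expect_gt(nrow(o_hb), 0)
  expect_equal(o_hb$radii_sum[1], 2.7)
  expect_equal(min(o_hb$distance), 2.20408, tolerance = 1e-4)
  # amide H against the previous residue's side chain: H-H pairs at
  # radii 1.2 + 1.2, the CB-H pair at 1.7 + 1.2
  h_hb <- cl[cl$category == "CB_HN_next", ]
  expect_gt(nrow(h_hb), 0)
  expect_setequal(unique(h_hb$radii_sum), c(2.4, 2.9))
  expect_true(all(h_hb$overlap > 0))
  expect_equal(min(h_hb$distance), 2.08099, tolerance = 1e-4)
  # sorted by descending overlap
  expect_true(all(diff(cl$overlap) <= 0))
})

test_that("distance exactly equal to the radii sum is not a clash", {
  s <- list(sequence = "XX",
            atoms = data.frame(name = c("O", "O"), element = c("O", "O"),
                               resid = c(1L, 2L), resno = c(1L, 2L),
                               resname = "UNK", x = c(0, 3), y = 0, z = 0),
            bonds = data.frame(i = integer(), j = integer(),
                               key = character()),
            provenance = "built")
  class(s) <- "peptide"
  expect_identical(nrow(detect_clashes(s)), 0L)
  s$atoms$x[2] <- 2.9
  expect_identical(nrow(detect_clashes(s)), 1L)
})

test_that("unknown elements are reported by atom", {
  s <- build_peptide("AA")
  s$atoms$element[1] <- "Zz"
  expect_error(detect_clashes(s), "Zz.*missing from the radius table")
})

test_that("overlap is invariant under rigid motion", {
  s <- build_peptide("AAA")
  m <- random_rigid_motion()
  canon <- function(cl) cl[order(cl$atomA, cl$atomB), ]
  ref <- canon(detect_clashes(s))
  moved <- canon(detect_clashes(transform_structure(s, m$R, m$t)))
  expect_equal(moved$overlap, ref$overlap, tolerance = 1e-9)
  expect_identical(moved$category, ref$category)
  expect_identical(moved$atomA, ref$atomA)
})

test_that("clash profile covers the four categories with correct neighbours", {
  s <- build_peptide("AAA")
  p2 <- paper_clash_profile(s, 2)
  expect_setequal(p2$category,
                  c("CB_O_prev", "CB_HN_same", "CB_HN_next", "CB_O_same"))
  expect_gt(p2$overlap[p2$category == "CB_O_prev"], 0)   # initiates phi
  expect_gt(p2$overlap[p2$category == "CB_HN_next"], 0)  # initiates psi
  # residue 1 has no previous residue: category dropped with a message
  expect_message(p1 <- paper_clash_profile(s, 1), "omitted")
  expect_false("CB_O_prev" %in% p1$category)
  expect_error(paper_clash_profile(build_peptide("GGG"), 2), "no side chain")
})

test_that("all-trans polyglycine is free of side-chain clash categories", {
  g <- build_peptide("GGGG")
  cl <- detect_clashes(g)
  expect_identical(sum(cl$category != "other"), 0L)
})

test_that("phi scan opens CB_O_prev and closes CB_HN_same monotonically", {
  sc <- clash_scan("AAA", 2, "phi", dihedral_path(180, -90, "cw", 5))
  expect_identical(sc$angle[1], 180)
  expect_identical(sc$angle[nrow(sc)], -90)
  expect_true(all(diff(sc$CB_O_prev_dist) > 0))
  expect_true(all(diff(sc$CB_HN_same_dist) < 0))
  # opposite rank movement at every step
  expect_true(all(diff(sc$CB_O_prev_dist) * diff(sc$CB_HN_same_dist) < 0))
})

test_that("psi scan opens CB_HN_next and closes CB_O_same monotonically", {
  sc <- clash_scan("AAA", 2, "psi", dihedral_path(180, 120, "ccw", 5))
  expect_true(all(diff(sc$CB_HN_next_dist) > 0))
  expect_true(all(diff(sc$CB_O_same_dist) < 0))
  expect_true(all(diff(sc$CB_HN_next_dist) * diff(sc$CB_O_same_dist) < 0))
})

test_that("profile and pairwise detection agree on per-category minima", {
  for (ang in c(180, -150, -110, -90)) {
    s <- build_peptide("AAA", phi = c(180, ang, 180))
    cl <- detect_clashes(s)
    prof <- suppressMessages(paper_clash_profile(s, 2))
    sc_res <- ifelse(grepl("^(CB|HB)", cl$atomA), cl$residA, cl$residB)
    for (cat in prof$category) {
      hits <- cl[cl$category == cat & sc_res == 2, ]
      if (prof$overlap[prof$category == cat] > 0) {
        # a clashing minimum must be found identically by both routes
        expect_equal(min(hits$distance),
                     prof$distance[prof$category == cat],
                     tolerance = 1e-9)
      } else if (nrow(hits) > 0) {
        # clash records can never undercut the unconstrained minimum
        expect_gte(min(hits$distance),
                   prof$distance[prof$category == cat] - 1e-9)
      }
    }
  }
})

test_that("scan grids outside (-180, 180] are rejected", {
  expect_error(clash_scan("AAA", 2, "phi", c(0, 181)), "grid")
  expect_error(clash_scan("AAA", 2, "phi", c(-180)), "grid")
})

test_that("dihedral paths wrap through +-180 in the stated sense", {
  cw <- dihedral_path(180, -90, "cw", 30)
  expect_equal(cw, c(180, -150, -120, -90))
  ccw <- dihedral_path(180, 120, "ccw", 20)
  expect_equal(ccw, c(180, 160, 140, 120))
})
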