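# Coordinate-level measurements: torsions, distances, peptide planes,
# twist/bend metrics and the axial repeat.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# collinearity threshold on the cross-product norm (A^2)
.collinear_tol <- 1e-9

#' Wrap angles into (-180, 180]
#'
#' Reduces any angle in degrees modulo 360 into the canonical interval
#' `(-180, 180]`. The Ramachandran torus identifies 180 with -180; the
#' positive representative is kept.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `(-180, 180]`.
#' @examples
#' wrap_angle(c(360, -180, 190))
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w <= -180] <- 180
  w
}

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion about the p2-p3 axis with the IUPAC convention: the angle
#' is positive when, looking from p2 toward p3, the far bond rotates
#' clockwise relative to the near bond. Cis (eclipsed) is 0 degrees, trans
#' (anti) is 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, coordinates in Angstrom.
#' @return angle in degrees, in `(-180, 180]`.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)) # -90
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < .collinear_tol || vnorm(n2) < .collinear_tol)
    stop("degenerate geometry: collinear atom triple in dihedral",
         call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit3(b2))
  wrap_angle(rad2deg(atan2(y, x)))
}

# Place atom D bonded to c with |cD| = bond, angle(b, c, D) = angle and
# torsion(a, b, c, D) = torsion (degrees). Standard internal-coordinate
# (NeRF-style) chain extension.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  ub <- unit3(c - b)
  n <- unit3(cross3(b - a, ub))
  m <- cross3(n, ub)
  c + bond * (-cos(th) * ub + sin(th) * (cos(ph) * m + sin(ph) * n))
}

# ---- structure accessors ------------------------------------------------

# row index of atom `name` in residue ordinal `resid`; 0 if absent
.atom_row <- function(s, resid, name) {
  i <- which(s$atoms$resid == resid & s$atoms$name == name)
  if (length(i) == 0L) 0L else i[1L]
}

.atom_xyz <- function(s, row) as.numeric(s$atoms[row, c("x", "y", "z")])

# xyz of one named atom, or NULL if absent
atom_coord <- function(s, resid, name) {
  i <- .atom_row(s, resid, name)
  if (i == 0L) NULL else .atom_xyz(s, i)
}

.n_residues <- function(s) max(s$atoms$resid)

# residues i and i+1 form a peptide bond only when their author-assigned
# numbers are consecutive (gaps in PDB numbering break phi/psi)
.chain_linked <- function(s, i) {
  a <- s$atoms$resno[match(i, s$atoms$resid)]
  b <- s$atoms$resno[match(i + 1L, s$atoms$resid)]
  !is.na(a) && !is.na(b) && (b - a == 1L)
}

.require_backbone <- function(s) {
  for (i in seq_len(.n_residues(s))) {
    for (nm in c("N", "CA", "C")) {
      if (.atom_row(s, i, nm) == 0L)
        stop(sprintf("structure incomplete: residue %d is missing backbone atom %s",
                     i, nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Backbone dihedral angles of a peptide structure
#'
#' Computes phi, psi and omega for every residue: phi(i) is the torsion
#' C(i-1)-N(i)-CA(i)-C(i), psi(i) is N(i)-CA(i)-C(i)-N(i+1) and omega(i) is
#' CA(i)-C(i)-N(i+1)-CA(i+1). Angles that need a neighbour beyond a chain
#' end, or across a gap in residue numbering, are `NA`.
#'
#' @param s a `peptide` structure (see [build_peptide()] or [read_pdb()]).
#' @return data frame with columns `resid`, `resno`, `resname`, `phi`,
#'   `psi`, `omega` (degrees in `(-180, 180]` or `NA`).
#' @export
backbone_dihedrals <- function(s) {
  .require_backbone(s)
  n <- .n_residues(s)
  out <- data.frame(
    resid = seq_len(n),
    resno = s$atoms$resno[match(seq_len(n), s$atoms$resid)],
    resname = s$atoms$resname[match(seq_len(n), s$atoms$resid)],
    phi = NA_real_, psi = NA_real_, omega = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    N <- atom_coord(s, i, "N")
    CA <- atom_coord(s, i, "CA")
    C <- atom_coord(s, i, "C")
    if (i > 1L && .chain_linked(s, i - 1L)) {
      Cprev <- atom_coord(s, i - 1L, "C")
      out$phi[i] <- dihedral_angle(Cprev, N, CA, C)
    }
    if (i < n && .chain_linked(s, i)) {
      Nnext <- atom_coord(s, i + 1L, "N")
      out$psi[i] <- dihedral_angle(N, CA, C, Nnext)
      out$omega[i] <- dihedral_angle(CA, C, Nnext, atom_coord(s, i + 1L, "CA"))
    }
  }
  out
}

#' Axial repeat of a strand
#'
#' Euclidean distance from CA(i) to CA(i+2), the repeat length along a
#' strand. Typical beta-strands fall between 6.5 and 7.0 Angstrom; the fully
#' extended all-trans chain exceeds 7.0 Angstrom.
#'
#' @param s a `peptide` structure.
#' @param i residue ordinal; residues `i` and `i + 2` must exist.
#' @return distance in Angstrom.
#' @export
axial_repeat <- function(s, i) {
  n <- .n_residues(s)
  if (i < 1L || i + 2L > n)
    stop(sprintf("residue index %d out of range: need residues %d and %d in a chain of %d",
                 i, i, i + 2L, n), call. = FALSE)
  a <- atom_coord(s, i, "CA")
  b <- atom_coord(s, i + 2L, "CA")
  if (is.null(a) || is.null(b))
    stop("structure incomplete: CA atom missing", call. = FALSE)
  vnorm(b - a)
}

# least-squares plane through a set of points: list(centroid, normal)
.ls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3L])
}

# peptide-plane atoms of plane i: the unit between residues i and i+1
.plane_atoms <- function(s, i) {
  need <- list(c(i, "CA"), c(i, "C"), c(i, "O"), c(i + 1L, "N"), c(i + 1L, "CA"))
  opt <- list(c(i + 1L, "H"))
  rows <- list()
  for (a in need) {
    r <- .atom_row(s, as.integer(a[1L]), a[2L])
    if (r == 0L)
      stop(sprintf("structure incomplete: peptide plane %d needs atom %s of residue %s",
                   i, a[2L], a[1L]), call. = FALSE)
    rows[[length(rows) + 1L]] <- r
  }
  for (a in opt) {
    r <- .atom_row(s, as.integer(a[1L]), a[2L])
    if (r > 0L) rows[[length(rows) + 1L]] <- r
  }
  as.matrix(s$atoms[unlist(rows), c("x", "y", "z")])
}

# normal of peptide plane i, oriented by the local atom order so that
# reflection flips it
.plane_normal <- function(s, i) {
  pl <- .ls_plane(.plane_atoms(s, i))
  ca <- atom_coord(s, i, "CA")
  ref <- cross3(atom_coord(s, i, "C") - ca, atom_coord(s, i + 1L, "N") - ca)
  n <- pl$normal
  if (sum(n * ref) < 0) n <- -n
  list(centroid = pl$centroid, normal = n)
}

#' Twist and bend between successive peptide planes
#'
#' Fits a least-squares plane through each of two successive peptide units
#' (CA(i), C(i), O(i), N(i+1), CA(i+1) and the amide H when present) and
#' decomposes their relative rotation about the local chain direction into a
#' signed twist and an unsigned bend. The twist is positive when the second
#' plane is rotated clockwise relative to the first, viewed from the N-
#' toward the C-terminus, which matches a right-handed strand twist.
#'
#' @param s a `peptide` structure.
#' @param i plane index; peptide units `i` and `i + 1` must exist.
#' @return list with `plane_index`, the two unit `normal`s, `twist`
#'   (degrees, signed, in `(-180, 180]`) and `bend` (degrees, `[0, 180)`).
#' @export
peptide_plane_twist <- function(s, i) {
  n <- .n_residues(s)
  if (i < 1L || i + 2L > n)
    stop(sprintf("plane index %d out of range", i), call. = FALSE)
  p1 <- .plane_normal(s, i)
  p2 <- .plane_normal(s, i + 1L)
  u <- unit3(p2$centroid - p1$centroid)
  # components of the normals perpendicular to the chain direction
  q1 <- p1$normal - sum(p1$normal * u) * u
  q2 <- p2$normal - sum(p2$normal * u) * u
  if (vnorm(q1) < .collinear_tol || vnorm(q2) < .collinear_tol)
    stop("degenerate geometry: peptide-plane normal parallel to the chain axis",
         call. = FALSE)
  # successive peptide units flip their local orientation along the chain
  # (the extended chain is a two-fold screw), so the twist proper is the
  # inter-normal rotation less that structural half-turn
  m <- rad2deg(atan2(sum(cross3(q1, q2) * u), sum(q1 * q2)))
  tilt1 <- rad2deg(acos(max(-1, min(1, sum(p1$normal * u)))))
  tilt2 <- 180 - rad2deg(acos(max(-1, min(1, sum(p2$normal * u)))))
  list(plane_index = i,
       normal1 = p1$normal, normal2 = p2$normal,
       twist = wrap_angle(m + 180),
       bend = abs(tilt2 - tilt1))
}

#' Bend at a peptide-bond midpoint
#'
#' A strand is bent where the midpoints of three consecutive peptide (C-N)
#' bonds are not collinear. Returns 180 degrees minus the angle at the
#' middle midpoint, so a perfectly straight chain gives 0.
#'
#' @param s a `peptide` structure.
#' @param i peptide-bond index (bond `i` joins residues `i` and `i + 1`);
#'   bonds `i`, `i + 1` and `i + 2` must exist.
#' @return bend in degrees, in `[0, 180)`.
#' @export
bend_angle <- function(s, i) {
  n <- .n_residues(s)
  if (i < 1L || i + 3L > n)
    stop(sprintf("peptide-bond index %d out of range", i), call. = FALSE)
  mid <- function(j) {
    (atom_coord(s, j, "C") + atom_coord(s, j + 1L, "N")) / 2
  }
  m1 <- mid(i)
  m2 <- mid(i + 1L)
  m3 <- mid(i + 2L)
  v1 <- unit3(m1 - m2)
  v2 <- unit3(m3 - m2)
  180 - rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# ---- atom selection and group distances --------------------------------

#' Select atom rows of a structure
#'
#' @param s a `peptide` structure.
#' @param resid optional residue ordinals to keep.
#' @param name optional atom names; entries ending in `*` are prefix
#'   patterns (`"HB*"` matches HB1, HB2, HB3).
#' @return integer row indices into `s$atoms`.
#' @export
select_atoms <- function(s, resid = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(resid)) keep <- keep & s$atoms$resid %in% resid
  if (!is.null(name)) {
    hit <- rep(FALSE, nrow(s$atoms))
    for (nm in name) {
      if (grepl("\\*$", nm)) {
        hit <- hit | startsWith(s$atoms$name, sub("\\*$", "", nm))
      } else {
        hit <- hit | s$atoms$name == nm
      }
    }
    keep <- keep & hit
  }
  which(keep)
}

#' Minimum distance between two atom selections
#'
#' @param s a `peptide` structure.
#' @param selA,selB selections: integer row indices, or lists with elements
#'   `resid` and/or `name` passed to [select_atoms()].
#' @return list with `distance` (Angstrom), and `atomA`, `atomB`, the
#'   realizing pair as `"NAME@resid"` labels.
#' @export
min_group_distance <- function(s, selA, selB) {
  rows <- function(sel) {
    if (is.list(sel)) do.call(select_atoms, c(list(s), sel)) else as.integer(sel)
  }
  ia <- rows(selA)
  ib <- rows(selB)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty atom selection", call. = FALSE)
  if (length(intersect(ia, ib)) > 0L)
    stop("atom selections overlap", call. = FALSE)
  xa <- as.matrix(s$atoms[ia, c("x", "y", "z")])
  xb <- as.matrix(s$atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  k <- arrayInd(which.min(d2), dim(d2))
  lab <- function(r) sprintf("%s@%d", s$atoms$name[r], s$atoms$resid[r])
  list(distance = sqrt(max(0, d2[k])),
       atomA = lab(ia[k[1L]]), atomB = lab(ib[k[2L]]))
}

#' Write per-residue dihedrals as TSV
#'
#' @param dihedrals data frame from [backbone_dihedrals()].
#' @param path output file.
#' @param chain chain identifier recorded in the first column.
#' @return the path, invisibly.
#' @export
write_dihedrals_tsv <- function(dihedrals, path, chain = "A") {
  out <- data.frame(chain = chain,
                    residue_index = dihedrals$resno,
                    residue_name = dihedrals$resname,
                    phi = round(dihedrals$phi, 4),
                    psi = round(dihedrals$psi, 4),
                    omega = round(dihedrals$omega, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
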