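# Deterministic construction of idealized peptides from internal
# coordinates, and sampling of the beta-region of the Ramachandran plot.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
.aa1 <- stats::setNames(names(.aa3), .aa3)

#' Ideal covalent geometry table
#'
#' Bond lengths and bond angles used by [build_peptide()]. Backbone values
#' are standard protein single-conformer values; the amide nitrogen is
#' treated as sp2 (C-N-H 119.2 degrees, amide H in the peptide plane);
#' every angle not listed is tetrahedral (109.5 degrees).
#'
#' @param bonds,angles named numeric vectors overriding individual entries
#'   (names as in the defaults, e.g. `"CA-C"`, `"N-CA-C"`).
#' @return object of class `geometry_table` with elements `bonds` (Angstrom),
#'   `angles` (degrees) and `tetrahedral`.
#' @export
default_geometry <- function(bonds = NULL, angles = NULL) {
  g <- list(
    bonds = c("N-CA" = 1.458, "CA-C" = 1.525, "C-N" = 1.329,
              "C-O" = 1.231, "CA-CB" = 1.530, "N-H" = 1.010,
              "CA-HA" = 1.090, "CB-HB" = 1.090,
              "C-OXT" = 1.340, "OXT-HXT" = 0.960),
    angles = c("N-CA-C" = 111.2, "CA-C-N" = 116.2, "C-N-CA" = 121.7,
               "CA-C-O" = 120.8, "C-N-H" = 119.2,
               "CA-C-OXT" = 116.2, "C-OXT-HXT" = 109.5),
    tetrahedral = 109.5
  )
  if (!is.null(bonds)) g$bonds[names(bonds)] <- bonds
  if (!is.null(angles)) g$angles[names(angles)] <- angles
  if (any(g$bonds <= 0.8 | g$bonds >= 2.0))
    stop("geometry table: bond lengths must lie in (0.8, 2.0) Angstrom",
         call. = FALSE)
  if (any(c(g$angles, g$tetrahedral) <= 90 | c(g$angles, g$tetrahedral) >= 135))
    stop("geometry table: bond angles must lie in (90, 135) degrees",
         call. = FALSE)
  class(g) <- "geometry_table"
  g
}

# chirality sign of the Calpha centre: +1 places CB on the L side  (fixed below)
# (improper torsion C-N-CA-CB comes out near -122 degrees, as in
# L-amino acids); the D mirror is only reachable by reflecting coordinates
.L_CHIRALITY <- 1

#' Build an idealized peptide at chosen backbone dihedrals
#'
#' Constructs Cartesian coordinates for a peptide by internal-coordinate
#' chain extension: each atom is placed from three predecessors by a bond
#' length, a bond angle and a torsion from the [default_geometry()] table.
#' Residues are L-amino acids; the amide hydrogen sits in the peptide plane
#' trans to the carbonyl oxygen; beta hydrogens are staggered. The termini
#' are completed as NH2 and C(=O)OH. Alanine and glycine are modelled
#' exactly; any other residue letter gets an alanine-like CB stub
#' (side-chain atoms beyond CB are not built).
#'
#' @param sequence one-letter amino-acid string, length >= 2.
#' @param phi,psi,omega backbone dihedrals in degrees, each a scalar or a
#'   vector recycled to one value per residue. `phi[1]` and `psi[n]` do not
#'   correspond to measurable torsions; `psi[n]` still orients the terminal
#'   carboxyl group. `omega[i]` is the peptide bond between residues `i`
#'   and `i + 1` and should be 180 (trans) or 0 (cis).
#' @param chi1 torsion N-CA-CB-HB1 in degrees (the other two beta hydrogens
#'   follow at +120 and +240); default 60 gives the staggered methyl.
#' @param geometry a `geometry_table`.
#' @return object of class `peptide`: list with `sequence`, `atoms` (data
#'   frame: `name`, `element`, `resid`, `resno`, `resname`, `x`, `y`, `z`),
#'   `bonds` (data frame of bonded atom-row pairs and their geometry-table
#'   key) and `provenance = "built"`.
#' @examples
#' s <- build_peptide("AAA")                      # all-trans tri-alanine
#' backbone_dihedrals(s)
#' @export
build_peptide <- function(sequence, phi = 180, psi = 180, omega = 180,
                          chi1 = 60, geometry = default_geometry()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (n < 2L)
    stop("sequence must contain at least 2 residues", call. = FALSE)
  bad <- setdiff(letters1, names(.aa3))
  if (length(bad) > 0L)
    stop(sprintf("unsupported residue letter(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  stub <- setdiff(letters1, c("A", "G"))
  if (length(stub) > 0L)
    message("side chains beyond CB are approximated by an alanine-like stub for: ",
            paste(unique(stub), collapse = ", "))

  phi <- wrap_angle(rep_len(as.numeric(phi), n))
  psi <- wrap_angle(rep_len(as.numeric(psi), n))
  omega <- wrap_angle(rep_len(as.numeric(omega), n))
  if (any(!is.finite(c(phi, psi, omega))))
    stop("dihedral angles must be finite", call. = FALSE)
  odd <- abs(omega) > 1e-6 & abs(abs(omega) - 180) > 1e-6
  if (any(odd[-n]))
    warning("omega outside {180, 0} at residue(s) ",
            paste(which(odd[-n]), collapse = ", "),
            ": peptide bonds are planar in real chains")
  if (any(abs(omega[-n]) <= 1e-6))
    message("cis peptide bond (omega = 0) at residue(s) ",
            paste(which(abs(omega[-n]) <= 1e-6), collapse = ", "))

  gb <- geometry$bonds
  ga <- geometry$angles
  tet <- geometry$tetrahedral

  a_name <- character(0); a_resid <- integer(0)
  a_xyz <- vector("list", 0)
  b_i <- integer(0); b_j <- integer(0); b_key <- character(0)
  add_atom <- function(name, resid, xyz) {
    a_name[[length(a_name) + 1L]] <<- name
    a_resid[[length(a_resid) + 1L]] <<- resid
    a_xyz[[length(a_xyz) + 1L]] <<- xyz
    length(a_name)
  }
  add_bond <- function(i, j, key) {
    b_i[[length(b_i) + 1L]] <<- i
    b_j[[length(b_j) + 1L]] <<- j
    b_key[[length(b_key) + 1L]] <<- key
  }

  # backbone trace
  N <- CA <- C <- vector("list", n)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(gb[["N-CA"]], 0, 0)
  th <- deg2rad(ga[["N-CA-C"]])
  C[[1L]] <- CA[[1L]] + gb[["CA-C"]] * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1L)) {
    N[[i + 1L]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                              gb[["C-N"]], ga[["CA-C-N"]], psi[i])
    CA[[i + 1L]] <- place_atom(CA[[i]], C[[i]], N[[i + 1L]],
                               gb[["N-CA"]], ga[["C-N-CA"]], omega[i])
    C[[i + 1L]] <- place_atom(C[[i]], N[[i + 1L]], CA[[i + 1L]],
                              gb[["CA-C"]], ga[["N-CA-C"]], phi[i + 1L])
  }

  for (i in seq_len(n)) {
    iN <- add_atom("N", i, N[[i]])
    if (i == 1L) {
      # NH2 terminus
      for (k in c(1L, 2L)) {
        h <- place_atom(C[[1L]], CA[[1L]], N[[1L]],
                        gb[["N-H"]], tet, c(60, -60)[k])
        add_bond(iN, add_atom(paste0("H", k), i, h), "N-H")
      }
    } else {
      O_prev <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                           gb[["C-O"]], ga[["CA-C-O"]],
                           wrap_angle(psi[i - 1L] + 180))
      h <- place_atom(O_prev, C[[i - 1L]], N[[i]],
                      gb[["N-H"]], ga[["C-N-H"]], 180)
      add_bond(iN, add_atom("H", i, h), "N-H")
    }
    iCA <- add_atom("CA", i, CA[[i]])
    add_bond(iN, iCA, "N-CA")

    # tetrahedral substituents on CA via the N/C bisector frame
    u1 <- unit3(N[[i]] - CA[[i]])
    u2 <- unit3(C[[i]] - CA[[i]])
    bis <- -unit3(u1 + u2)
    perp <- unit3(cross3(u1, u2))
    gam <- acos(max(-1, min(1, sum(u1 * u2))))
    lam <- acos(-cos(deg2rad(tet)) / cos(gam / 2))
    up <- cos(lam) * bis + sin(lam) * perp * .L_CHIRALITY
    dn <- cos(lam) * bis - sin(lam) * perp * .L_CHIRALITY

    if (letters1[i] == "G") {
      add_bond(iCA, add_atom("HA1", i, CA[[i]] + gb[["CA-HA"]] * dn), "CA-HA")
      add_bond(iCA, add_atom("HA2", i, CA[[i]] + gb[["CA-HA"]] * up), "CA-HA")
    } else {
      add_bond(iCA, add_atom("HA", i, CA[[i]] + gb[["CA-HA"]] * dn), "CA-HA")
      CB <- CA[[i]] + gb[["CA-CB"]] * up
      iCB <- add_atom("CB", i, CB)
      add_bond(iCA, iCB, "CA-CB")
      for (k in 0:2) {
        hb <- place_atom(N[[i]], CA[[i]], CB, gb[["CB-HB"]], tet,
                         wrap_angle(chi1 + 120 * k))
        add_bond(iCB, add_atom(paste0("HB", k + 1L), i, hb), "CB-HB")
      }
    }

    iC <- add_atom("C", i, C[[i]])
    add_bond(iCA, iC, "CA-C")
    O <- place_atom(N[[i]], CA[[i]], C[[i]],
                    gb[["C-O"]], ga[["CA-C-O"]], wrap_angle(psi[i] + 180))
    add_bond(iC, add_atom("O", i, O), "C-O")
    if (i == n) {
      # COOH terminus: OXT where the next amide nitrogen would sit
      OXT <- place_atom(N[[n]], CA[[n]], C[[n]],
                        gb[["C-OXT"]], ga[["CA-C-OXT"]], psi[n])
      iOXT <- add_atom("OXT", i, OXT)
      add_bond(iC, iOXT, "C-OXT")
      hxt <- place_atom(CA[[n]], C[[n]], OXT,
                        gb[["OXT-HXT"]], ga[["C-OXT-HXT"]], 180)
      add_bond(iOXT, add_atom("HXT", i, hxt), "OXT-HXT")
    }
  }
  # inter-residue peptide bonds
  for (i in seq_len(n - 1L)) {
    add_bond(which(a_resid == i & a_name == "C"),
             which(a_resid == i + 1L & a_name == "N"), "C-N")
  }
  xyz <- do.call(rbind, a_xyz)
  structure(list(
    sequence = paste(letters1, collapse = ""),
    atoms = data.frame(name = a_name, element = substr(a_name, 1L, 1L),
                       resid = a_resid, resno = a_resid,
                       resname = unname(.aa3[letters1[a_resid]]),
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       stringsAsFactors = FALSE),
    bonds = data.frame(i = b_i, j = b_j, key = b_key,
                       stringsAsFactors = FALSE),
    provenance = "built"
  ), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d residues, %d atoms, %s)\n",
              x$sequence, max(x$atoms$resid), nrow(x$atoms), x$provenance))
  invisible(x)
}

#' Mirror image of a structure
#'
#' Reflects all coordinates through the yz-plane, turning every L-centre
#' into its D-enantiomer and negating every dihedral and twist angle.
#'
#' @param s a `peptide` structure.
#' @return the reflected structure.
#' @export
mirror_structure <- function(s) {
  s$atoms$x <- -s$atoms$x
  s
}

#' Sample backbone dihedrals from the beta region
#'
#' Draws (phi, psi) pairs uniformly from the beta-sheet region of the
#' Ramachandran plot, taken as the wrapped rectangle phi in \[160, -70\]
#' crossing +-180 and psi in \[80, -160\] crossing +-180.
#'
#' @param n number of pairs, >= 1.
#' @param seed integer seed; the same seed reproduces the same draw.
#' @return data frame with columns `phi` and `psi`, degrees in
#'   `(-180, 180]`.
#' @export
sample_beta_dihedrals <- function(n, seed) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  data.frame(
    phi = wrap_angle(160 + stats::runif(n) * 130),   # 160 -> 180/-180 -> -70
    psi = wrap_angle(80 + stats::runif(n) * 120)     # 80 -> 180/-180 -> -160
  )
}
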