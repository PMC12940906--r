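# Van der Waals overlap detection and the four-category intrastrand clash
# scheme (side chain vs carbonyl/amide groups of the same and adjacent
# residues), with dihedral scans following how those clashes trade off.

#' Bondi van der Waals radii
#'
#' Hard-sphere radii per element, Angstrom. Hydrogen and oxygen are the
#' values the twist argument rests on (1.2 and 1.5); carbon, nitrogen and
#' sulfur complete the same radius system for heavy-atom work.
#'
#' @param ... named overrides or additions, e.g. `P = 1.8`.
#' @return named numeric vector, element -> radius in Angstrom.
#' @export
bondi_radii <- function(...) {
  r <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8)
  over <- c(...)
  if (length(over) > 0) r[names(over)] <- over
  if (any(r <= 0)) stop("van der Waals radii must be positive", call. = FALSE)
  r
}

# names that belong to the chain termini, never to a clash category
.terminal_names <- c("H1", "H2", "H3", "OXT", "HXT")

# single-bond covalent radii for bond inference on read structures
.cov_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

# bonded atom-row pairs; built structures carry them, read structures get
# them from a distance criterion
.bond_pairs <- function(s) {
  if (!is.null(s$bonds) && nrow(s$bonds) > 0)
    return(as.matrix(s$bonds[, c("i", "j")]))
  at <- s$atoms
  rc <- .cov_radii[at$element]
  rc[is.na(rc)] <- 0.77
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rc, rc, "+") * 1.25
  idx <- which(d > 0 & d < lim, arr.ind = TRUE)
  idx[idx[, 1] < idx[, 2], , drop = FALSE]
}

# logical matrix: TRUE for pairs fewer than 3 covalent bonds apart
# (1-2 and 1-3; those distances are fixed by the geometry table)
.excluded_pairs <- function(s) {
  n <- nrow(s$atoms)
  A <- matrix(FALSE, n, n)
  bp <- .bond_pairs(s)
  A[bp] <- TRUE
  A <- A | t(A)
  near <- A | ((A %*% A) > 0)
  diag(near) <- TRUE
  near
}

.is_sidechain <- function(name) name == "CB" | startsWith(name, "HB")

# The amide group is represented by its hydrogen; the bare nitrogen stands
# in only when no hydrogens were placed (heavy-atom fallback for crystal
# structures). Pinning the category to the H keeps the scan distances
# strictly monotone, as the clash argument requires.
.nh_names <- function(s, resid) {
  if (any(s$atoms$resid == resid & s$atoms$name == "H")) "H" else "N"
}

# category of a nonbonded pair from residue offset and atom names;
# "other" for anything outside the four-clash scheme. `nh` gives, per
# residue ordinal, the atom name representing the amide group there.
.clash_category <- function(nameA, residA, nameB, residB, nh) {
  sc_a <- .is_sidechain(nameA)
  sc_b <- .is_sidechain(nameB)
  if (sc_a == sc_b) return("other")
  if (sc_b) {  # make A the side-chain atom
    tmp <- nameA; nameA <- nameB; nameB <- tmp
    tmp <- residA; residA <- residB; residB <- tmp
  }
  if (nameB %in% .terminal_names) return("other")
  off <- residB - residA
  if (off == -1 && nameB %in% c("C", "O")) return("CB_O_prev")
  if (off == 0 && nameB == nh[residB]) return("CB_HN_same")
  if (off == 1 && nameB == nh[residB]) return("CB_HN_next")
  if (off == 0 && nameB == "O") return("CB_O_same")
  "other"
}

#' Detect van der Waals clashes
#'
#' Finds every nonbonded atom pair (three or more covalent bonds apart)
#' whose distance falls short of the sum of the two van der Waals radii by
#' more than `min_overlap`. The boundary case distance == radii sum is not
#' a clash.
#'
#' @param s a `peptide` structure.
#' @param radii named element -> radius table, see [bondi_radii()].
#' @param min_overlap minimum overlap in Angstrom to report, >= 0.
#' @return data frame sorted by descending overlap with columns `atomA`,
#'   `atomB` (as `"NAME@resid"`), `residA`, `residB`, `distance`,
#'   `radii_sum`, `overlap` and `category` (one of `CB_O_prev`,
#'   `CB_HN_same`, `CB_HN_next`, `CB_O_same`, `other`).
#' @export
detect_clashes <- function(s, radii = bondi_radii(), min_overlap = 0) {
  stopifnot(min_overlap >= 0)
  at <- s$atoms
  r <- radii[at$element]
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1L]
    stop(sprintf("element %s of atom %s@%d missing from the radius table",
                 at$element[bad], at$name[bad], at$resid[bad]), call. = FALSE)
  }
  d <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
  rs <- outer(r, r, "+")
  hit <- (rs - d > min_overlap) & !.excluded_pairs(s)
  idx <- which(hit & upper.tri(hit), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(atomA = character(), atomB = character(),
                      residA = integer(), residB = integer(),
                      distance = numeric(), radii_sum = numeric(),
                      overlap = numeric(), category = character(),
                      stringsAsFactors = FALSE))
  }
  i <- idx[, 1L]; j <- idx[, 2L]
  nh <- vapply(seq_len(.n_residues(s)), function(r) .nh_names(s, r), "")
  out <- data.frame(
    atomA = sprintf("%s@%d", at$name[i], at$resid[i]),
    atomB = sprintf("%s@%d", at$name[j], at$resid[j]),
    residA = at$resid[i], residB = at$resid[j],
    distance = d[idx], radii_sum = rs[idx],
    overlap = rs[idx] - d[idx],
    category = mapply(.clash_category, at$name[i], at$resid[i],
                      at$name[j], at$resid[j],
                      MoreArgs = list(nh = nh), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  out[order(-out$overlap), , drop = FALSE]
}

#' Per-residue clash profile of the four twist-driving contacts
#'
#' For residue `i`, measures the minimum distance from its side chain (CB
#' and attached hydrogens) to each of the four groups that initiate and
#' limit the phi and psi rotations: the carbonyl group of the previous
#' residue (`CB_O_prev`, initiates the clockwise phi rotation), the amide
#' NH of the same residue (`CB_HN_same`, limits phi), the amide NH of the
#' next residue (`CB_HN_next`, initiates the counter-clockwise psi
#' rotation) and the carbonyl oxygen of the same residue (`CB_O_same`,
#' limits psi). Pairs fewer than three covalent bonds apart are skipped, as
#' in [detect_clashes()]. Amide groups are represented by their hydrogen;
#' the bare nitrogen stands in only on structures without hydrogens.
#'
#' @param s a `peptide` structure.
#' @param i residue ordinal; must have a side chain (not glycine).
#' @param radii element -> radius table.
#' @return data frame with one row per available category: `category`,
#'   `distance`, `radii_sum` (of the closest pair), `overlap`.
#' @export
paper_clash_profile <- function(s, i, radii = bondi_radii()) {
  at <- s$atoms
  n <- .n_residues(s)
  if (i < 1L || i > n) stop("residue index out of range", call. = FALSE)
  sc <- which(at$resid == i & .is_sidechain(at$name))
  if (length(sc) == 0L)
    stop(sprintf("residue %d (%s) has no side chain",
                 i, at$resname[match(i, at$resid)]), call. = FALSE)
  groups <- list(
    CB_O_prev = list(resid = i - 1L, names = c("C", "O")),
    CB_HN_same = list(resid = i, names = .nh_names(s, i)),
    CB_HN_next = list(resid = i + 1L,
                      names = if (i + 1L <= n) .nh_names(s, i + 1L) else "H"),
    CB_O_same = list(resid = i, names = "O")
  )
  excl <- .excluded_pairs(s)
  rows <- list()
  for (cat in names(groups)) {
    g <- groups[[cat]]
    if (g$resid < 1L || g$resid > n) {
      message(sprintf("residue %d: category %s omitted (no residue %d)",
                      i, cat, g$resid))
      next
    }
    tgt <- which(at$resid == g$resid & at$name %in% g$names &
                   !(at$name %in% .terminal_names))
    best <- NULL
    for (a in sc) for (b in tgt) {
      if (excl[a, b]) next
      dd <- sqrt(sum((as.numeric(at[a, c("x", "y", "z")]) -
                        as.numeric(at[b, c("x", "y", "z")]))^2))
      if (is.null(best) || dd < best$d) {
        best <- list(d = dd, rs = radii[[at$element[a]]] + radii[[at$element[b]]])
      }
    }
    if (!is.null(best)) {
      rows[[cat]] <- data.frame(category = cat, distance = best$d,
                                radii_sum = best$rs,
                                overlap = best$rs - best$d,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan one backbone dihedral and follow the clash categories
#'
#' Rebuilds an idealized peptide at each grid angle, varying only `phi` or
#' `psi` of residue `i`, and records the per-category minimum distances and
#' overlaps of [paper_clash_profile()]. Following the clockwise phi path
#' from 180 toward -90 the initiating `CB_O_prev` contact opens while
#' `CB_HN_same` closes; along the counter-clockwise psi path from 180
#' toward 120 the initiating `CB_HN_next` opens while `CB_O_same` closes.
#'
#' @param sequence one-letter sequence for [build_peptide()].
#' @param i residue whose dihedral is scanned.
#' @param which `"phi"` or `"psi"`.
#' @param angles grid of dihedral values, degrees in `(-180, 180]`; see
#'   [dihedral_path()] for the wrapped rotation paths.
#' @param phi,psi,omega,chi1,geometry fixed conformation for everything
#'   else, as in [build_peptide()].
#' @param radii element -> radius table.
#' @return data frame with one row per grid angle: `angle` plus
#'   `<category>_dist` and `<category>_overlap` columns.
#' @export
clash_scan <- function(sequence, i, which = c("phi", "psi"), angles,
                       phi = 180, psi = 180, omega = 180, chi1 = 60,
                       geometry = default_geometry(),
                       radii = bondi_radii()) {
  which <- match.arg(which)
  if (any(!is.finite(angles)) || any(angles <= -180 | angles > 180))
    stop("scan grid must lie in (-180, 180]", call. = FALSE)
  n <- nchar(sequence)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  cats <- c("CB_O_prev", "CB_HN_same", "CB_HN_next", "CB_O_same")
  rows <- lapply(angles, function(a) {
    if (which == "phi") phi[i] <- a else psi[i] <- a
    s <- suppressMessages(build_peptide(sequence, phi = phi, psi = psi,
                                        omega = omega, chi1 = chi1,
                                        geometry = geometry))
    prof <- suppressMessages(paper_clash_profile(s, i, radii))
    row <- data.frame(angle = a)
    for (cat in cats) {
      k <- match(cat, prof$category)
      row[[paste0(cat, "_dist")]] <- if (is.na(k)) NA_real_ else prof$distance[k]
      row[[paste0(cat, "_overlap")]] <- if (is.na(k)) NA_real_ else prof$overlap[k]
    }
    row
  })
  do.call(rbind, rows)
}

#' Wrapped rotation path between two dihedral values
#'
#' Angles visited when rotating a dihedral from `from` to `to` in a fixed
#' sense, crossing +-180 when needed. Dihedrals increase under clockwise
#' rotation (viewed from the N- toward the C-terminus), so `"cw"` steps
#' upward and `"ccw"` downward.
#'
#' @param from,to endpoint angles in degrees.
#' @param direction `"cw"` or `"ccw"`.
#' @param step grid spacing in degrees, > 0.
#' @return numeric vector of angles in `(-180, 180]`, starting at `from`
#'   and ending at `to`.
#' @export
dihedral_path <- function(from, to, direction = c("cw", "ccw"), step = 5) {
  direction <- match.arg(direction)
  stopifnot(step > 0)
  span <- (if (direction == "cw") (to - from) else (from - to)) %% 360
  offs <- unique(c(seq(0, span, by = step), span))
  sgn <- if (direction == "cw") 1 else -1
  wrap_angle(from + sgn * offs)
}
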