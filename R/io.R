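# PDB input/output so the same analysis runs on real beta-sheets as on
# built peptides. Reading goes through bio3d (fixed-column ATOM and SHEET
# records); writing is a minimal deterministic ATOM formatter so that
# write -> read -> write is byte-identical.

.pdb_to_peptide <- function(atom, chain) {
  a <- atom[atom$chain == chain, , drop = FALSE]
  resid <- as.integer(factor(a$resno, levels = unique(a$resno)))
  elem <- a$elesy  # bio3d: element symbol column; resid column = 3-letter name
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1L, 1L)
  }
  seq1 <- .aa1[a$resid[match(seq_len(max(resid)), resid)]]
  seq1[is.na(seq1)] <- "X"
  structure(list(
    sequence = paste(seq1, collapse = ""),
    atoms = data.frame(name = a$elety, element = toupper(trimws(elem)),
                       resid = resid, resno = a$resno,
                       resname = a$resid,
                       x = a$x, y = a$y, z = a$z,
                       stringsAsFactors = FALSE),
    bonds = NULL,
    provenance = "read"
  ), class = "peptide")
}

#' Read a PDB file
#'
#' Parses ATOM records into one `peptide` structure per chain and SHEET
#' records into strand ranges. Only the first model is used; HETATM
#' records are skipped with a message; for alternate locations the highest
#' occupancy wins; missing hydrogens are permitted (clash analysis then
#' falls back to heavy atoms). Files with insertion codes are refused.
#'
#' @param path PDB file.
#' @return list with `structures` (named list of `peptide`, one per chain)
#'   and `strands` (data frame `chain`, `first`, `last`, `source`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read %s", path), call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("empty structure: no ATOM records in %s", path),
                         call. = FALSE))
  atom <- pdb$atom
  if (any(atom$type == "HETATM")) {
    message(sum(atom$type == "HETATM"), " HETATM records skipped")
    atom <- atom[atom$type == "ATOM", , drop = FALSE]
  }
  if (nrow(atom) == 0L)
    stop(sprintf("empty structure: no ATOM records in %s", path), call. = FALSE)
  ins <- !is.na(atom$insert) & atom$insert != ""
  if (any(ins))
    stop(sprintf("insertion codes are not supported (residue %s%d)",
                 atom$chain[ins][1L], atom$resno[ins][1L]), call. = FALSE)
  # altloc: keep the highest occupancy per (chain, residue, atom name)
  alt <- !is.na(atom$alt) & atom$alt != ""
  if (any(alt)) {
    key <- paste(atom$chain, atom$resno, atom$elety)
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    keep <- !duplicated(key[order(-occ)])[order(order(-occ))]
    atom <- atom[keep, , drop = FALSE]
  }
  chains <- unique(atom$chain)
  structures <- stats::setNames(
    lapply(chains, function(ch) .pdb_to_peptide(atom, ch)), chains)
  strands <- data.frame(chain = character(), first = integer(),
                        last = integer(), source = character(),
                        stringsAsFactors = FALSE)
  sh <- pdb$sheet
  if (!is.null(sh) && length(sh$start) > 0) {
    strands <- data.frame(chain = sh$chain,
                          first = as.integer(sh$start),
                          last = as.integer(sh$end),
                          source = "sheet_record",
                          stringsAsFactors = FALSE)
  }
  list(structures = structures, strands = strands)
}

.format_atom_name <- function(name) {
  if (nchar(name) >= 4L) substr(name, 1L, 4L)
  else sprintf(" %-3s", name)
}

#' Write a peptide structure as a PDB file
#'
#' Standard fixed-column ATOM records (serial, name, residue, chain,
#' residue number, coordinates at 8.3 width, element symbol), a TER and an
#' END record. Serialization is deterministic: writing, reading the file
#' back and writing again reproduces it byte for byte.
#'
#' @param s a `peptide` structure.
#' @param path output file.
#' @param chain one-character chain identifier.
#' @return the path, invisibly.
#' @export
write_pdb <- function(s, path, chain = "A") {
  at <- s$atoms
  if (is.null(at) || nrow(at) == 0L)
    stop("cannot write an empty structure", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(xyz >= 1e4 | xyz <= -1e3))
    stop("formatting overflow: coordinates do not fit the 8.3 PDB field",
         call. = FALSE)
  lines <- character(nrow(at) + 2L)
  for (k in seq_len(nrow(at))) {
    lines[k] <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, .format_atom_name(at$name[k]), at$resname[k], chain, at$resno[k],
      at$x[k], at$y[k], at$z[k], 1, 0, at$element[k])
  }
  n <- nrow(at)
  lines[n + 1L] <- sprintf("TER   %5d      %3s %1s%4d",
                           n + 1L, at$resname[n], chain, at$resno[n])
  lines[n + 2L] <- "END"
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Extract a strand (residue range) from a structure
#'
#' @param s a `peptide` structure.
#' @param first,last residue numbers (`resno`, inclusive); alternatively
#'   `first` may be a one-row strand data frame from [read_pdb()].
#' @return the contiguous substructure with original numbering preserved.
#' @export
select_strand <- function(s, first, last = NULL) {
  if (is.data.frame(first)) {
    last <- first$last[1L]
    first <- first$first[1L]
  }
  if (first > last)
    stop(sprintf("reversed range: first (%d) > last (%d)", first, last),
         call. = FALSE)
  have <- unique(s$atoms$resno)
  if (!(first %in% have) || !(last %in% have))
    stop(sprintf("range %d-%d outside the chain (residues %d-%d)",
                 first, last, min(have), max(have)), call. = FALSE)
  keep <- which(s$atoms$resno >= first & s$atoms$resno <= last)
  at <- s$atoms[keep, , drop = FALSE]
  old_resid <- at$resid
  at$resid <- as.integer(factor(old_resid, levels = unique(old_resid)))
  bonds <- NULL
  if (!is.null(s$bonds)) {
    ok <- s$bonds$i %in% keep & s$bonds$j %in% keep
    bonds <- s$bonds[ok, , drop = FALSE]
    bonds$i <- match(bonds$i, keep)
    bonds$j <- match(bonds$j, keep)
  }
  res_keep <- sort(unique(old_resid))
  seq1 <- strsplit(s$sequence, "")[[1L]][res_keep]
  structure(list(sequence = paste(seq1, collapse = ""),
                 atoms = at, bonds = bonds, provenance = s$provenance),
            class = "peptide")
}

#' Rebuild missing amide and beta hydrogens with ideal geometry
#'
#' Crystal structures usually lack hydrogens; this adds the amide H (in
#' the peptide plane, trans to the carbonyl oxygen) and staggered beta
#' hydrogens on existing CB atoms, so that hydrogen-level clash analysis
#' can run on read structures.
#'
#' @param s a `peptide` structure.
#' @param geometry a `geometry_table`.
#' @return the structure with hydrogens added (bond list dropped; bonds
#'   are re-inferred from distances when needed).
#' @export
add_ideal_hydrogens <- function(s, geometry = default_geometry()) {
  at <- s$atoms
  gb <- geometry$bonds
  ga <- geometry$angles
  new <- list()
  n <- .n_residues(s)
  for (i in seq_len(n)) {
    if (i > 1L && .atom_row(s, i, "H") == 0L && .chain_linked(s, i - 1L)) {
      O <- atom_coord(s, i - 1L, "O")
      C <- atom_coord(s, i - 1L, "C")
      N <- atom_coord(s, i, "N")
      if (!is.null(O) && !is.null(C) && !is.null(N)) {
        new[[length(new) + 1L]] <- data.frame(
          name = "H", element = "H", resid = i,
          resno = at$resno[match(i, at$resid)],
          resname = at$resname[match(i, at$resid)],
          x = NA, y = NA, z = NA)
        p <- place_atom(O, C, N, gb[["N-H"]], ga[["C-N-H"]], 180)
        new[[length(new)]][, c("x", "y", "z")] <- as.list(p)
      }
    }
    cb <- atom_coord(s, i, "CB")
    if (!is.null(cb) && !any(at$resid == i & startsWith(at$name, "HB"))) {
      N <- atom_coord(s, i, "N")
      CA <- atom_coord(s, i, "CA")
      for (k in 0:2) {
        p <- place_atom(N, CA, cb, gb[["CB-HB"]], geometry$tetrahedral,
                        wrap_angle(60 + 120 * k))
        new[[length(new) + 1L]] <- data.frame(
          name = paste0("HB", k + 1L), element = "H", resid = i,
          resno = at$resno[match(i, at$resid)],
          resname = at$resname[match(i, at$resid)],
          x = p[1L], y = p[2L], z = p[3L])
      }
    }
  }
  if (length(new) > 0) {
    at <- rbind(at, do.call(rbind, new))
    at <- at[order(at$resid), , drop = FALSE]
    rownames(at) <- NULL
    s$atoms <- at
    s$bonds <- NULL
  }
  s
}
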