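# Orchestration: build -> measure -> classify -> report, with deterministic
# TSV/JSON outputs. Each writer stamps a header with the package version,
# a hash of the configuration and the seed, so identical configurations
# give byte-identical tables.

.pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("betatwist")),
           error = function(e) "0.0.0")
}

.header_lines <- function(config) {
  config <- config[setdiff(names(config), "out")]
  c(sprintf("# betatwist %s", .pkg_version()),
    sprintf("# config: %s", rlang::hash(config)),
    sprintf("# seed: %s", if (is.null(config$seed)) "none" else config$seed))
}

.write_tsv_with_header <- function(df, path, config) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(.header_lines(config), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

.resolve_radii <- function(config) {
  if (is.null(config$radii)) return(bondi_radii())
  if (is.character(config$radii)) {
    over <- unlist(jsonlite::read_json(config$radii))
    return(bondi_radii(stats::setNames(as.numeric(over), names(over))))
  }
  bondi_radii(config$radii)
}

#' Build an idealized peptide and report its twist-driving contacts
#'
#' Builds the configured peptide, writes it as PDB and tabulates the
#' per-residue clash profile (the extended-chain contacts between each
#' side chain and the neighbouring carbonyl/amide groups, with Bondi radii
#' sums and overlaps).
#'
#' @param config list with `sequence` (required), optional `phi`, `psi`,
#'   `omega`, `chi1`, `radii` (named vector or path to a JSON element ->
#'   Angstrom table), `seed`, and `out` (output directory, default
#'   `"betatwist_out"`).
#' @return invisible list with the output `pdb` and `distances` paths and
#'   the profile data frame.
#' @export
run_build <- function(config) {
  out <- config$out %||% "betatwist_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  radii <- .resolve_radii(config)
  s <- build_peptide(config$sequence,
                     phi = config$phi %||% 180,
                     psi = config$psi %||% 180,
                     omega = config$omega %||% 180,
                     chi1 = config$chi1 %||% 60)
  pdb_path <- file.path(out, "structure.pdb")
  write_pdb(s, pdb_path)
  rows <- list()
  for (i in seq_len(.n_residues(s))) {
    prof <- tryCatch(
      suppressMessages(paper_clash_profile(s, i, radii)),
      error = function(e) NULL)
    if (!is.null(prof)) rows[[length(rows) + 1L]] <- cbind(residue = i, prof)
  }
  prof_all <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(residue = integer(), category = character(),
               distance = numeric(), radii_sum = numeric(),
               overlap = numeric())
  tsv_path <- file.path(out, "distances.tsv")
  .write_tsv_with_header(prof_all, tsv_path, config)
  invisible(list(pdb = pdb_path, distances = tsv_path, profile = prof_all))
}

#' Analyze a PDB file: dihedrals, handedness labels, Ramachandran plot
#'
#' Reads a structure, and for each chain (restricted to strand ranges when
#' given or found in SHEET records, otherwise whole chains) writes the
#' per-residue dihedral/label table, a strand twist report as JSON and a
#' Ramachandran plot with its TSV twin.
#'
#' @param config list with `input` (PDB path), optional `ranges` (data
#'   frame `chain`, `first`, `last` overriding SHEET records), `use_sheets`
#'   (default TRUE), `tolerance`, `seed`, `out`.
#' @return invisible list of per-unit results (`labels`, `report`, paths).
#' @export
run_analyze <- function(config) {
  out <- config$out %||% "betatwist_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  contents <- read_pdb(config$input)
  ranges <- config$ranges
  if (is.null(ranges) && isTRUE(config$use_sheets %||% TRUE) &&
      nrow(contents$strands) > 0) {
    ranges <- contents$strands
  }
  units <- list()
  if (is.null(ranges)) {
    message("no strand ranges given or found; analyzing whole chain(s)")
    for (ch in names(contents$structures)) {
      units[[sprintf("chain_%s", ch)]] <- contents$structures[[ch]]
    }
  } else {
    for (k in seq_len(nrow(ranges))) {
      ch <- as.character(ranges$chain[k] %||% names(contents$structures)[1L])
      units[[sprintf("chain_%s_%d_%d", ch, ranges$first[k], ranges$last[k])]] <-
        select_strand(contents$structures[[ch]], ranges$first[k],
                      ranges$last[k])
    }
  }
  tol <- config$tolerance %||% 1e-6
  res <- list()
  for (nm in names(units)) {
    dh <- backbone_dihedrals(units[[nm]])
    labels <- classify_residues(dh, tolerance = tol)
    report <- strand_net_twist(labels, tolerance = tol)
    lab_path <- file.path(out, sprintf("%s_residues.tsv", nm))
    .write_tsv_with_header(labels, lab_path, config)
    json_path <- file.path(out, sprintf("%s_twist.json", nm))
    jsonlite::write_json(
      list(version = .pkg_version(),
           config = rlang::hash(config[setdiff(names(config), "out")]),
           seed = config$seed %||% "none",
           unit = nm,
           counts = as.list(report$counts),
           n_classified = report$n_classified,
           mean_wrapped_sum = report$mean_wrapped_sum,
           net_handedness = report$net_handedness),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    plot_path <- file.path(out, sprintf("%s_ramachandran.png", nm))
    ok <- which(!is.na(dh$phi) & !is.na(dh$psi))
    ramachandran_plot(dh, plot_path, track = ok,
                      main = sprintf("Ramachandran: %s", nm))
    res[[nm]] <- list(labels = labels, report = report,
                      tsv = lab_path, json = json_path, plot = plot_path)
  }
  invisible(res)
}

#' Scan phi or psi and tabulate the clash-category distances
#'
#' @param config list with `sequence`, `residue`, `which` ("phi"/"psi"),
#'   and either `angles` or `from`/`to`/`direction`/`step` for
#'   [dihedral_path()]; optional `radii`, `seed`, `out`.
#' @return invisible list with the scan data frame and the TSV path.
#' @export
run_scan <- function(config) {
  out <- config$out %||% "betatwist_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  angles <- config$angles %||%
    dihedral_path(config$from %||% 180, config$to,
                  direction = config$direction %||%
                    if ((config$which %||% "phi") == "phi") "cw" else "ccw",
                  step = config$step %||% 5)
  tab <- clash_scan(config$sequence, config$residue %||% 2L,
                    which = config$which %||% "phi", angles = angles,
                    radii = .resolve_radii(config))
  path <- file.path(out, sprintf("scan_%s.tsv", config$which %||% "phi"))
  .write_tsv_with_header(tab, path, config)
  invisible(list(scan = tab, tsv = path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
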