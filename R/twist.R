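# Per-residue twist handedness from the wrapped sum phi + psi, strand-level
# aggregation, Ramachandran visualization and the propeller-increment rule.
#
# On the Ramachandran torus the diagonal phi + psi = 0 (mod 180) carries no
# local twist; the sum wrapped into (-180, 180] is positive for a locally
# right-handed (clockwise, viewed N- to C-terminus) twist and negative for
# a left-handed one.

#' Wrapped sum of phi and psi
#'
#' phi + psi reduced modulo 360 into `(-180, 180]`. `NA` inputs (undefined
#' chain-end angles) give `NA`, not an error.
#'
#' @param phi,psi angles in degrees, vectorized.
#' @return numeric vector in `(-180, 180]`, `NA` where either input is.
#' @export
wrap_sum <- function(phi, psi) wrap_angle(phi + psi)

#' Classify local twist handedness from phi and psi
#'
#' A residue twists its strand right-handedly when the wrapped sum
#' phi + psi lies in (0, 180) and left-handedly when it lies in (-180, 0).
#' Sums within `tolerance` of 0 carry no twist; sums within `tolerance` of
#' 180 (= -180) also get `"none"` and are flagged `non_beta`, since such
#' conformations are no longer beta-strands. Undefined inputs (chain ends)
#' give `"none"` with `end_of_chain` set.
#'
#' @param phi,psi angles in degrees, vectorized (recycled).
#' @param tolerance half-width in degrees of the no-twist bands around 0
#'   and 180; default 1e-6.
#' @return data frame with columns `phi`, `psi`, `wrapped_sum`,
#'   `handedness` (`"right"`, `"left"` or `"none"`), `non_beta`,
#'   `end_of_chain`.
#' @export
classify_twist <- function(phi, psi, tolerance = 1e-6) {
  stopifnot(tolerance >= 0)
  k <- max(length(phi), length(psi))
  phi <- rep_len(phi, k)
  psi <- rep_len(psi, k)
  s <- wrap_sum(phi, psi)
  end <- is.na(s)
  non_beta <- !end & (abs(abs(s) - 180) <= tolerance)
  none <- end | non_beta | (!end & abs(s) <= tolerance)
  hand <- ifelse(none, "none", ifelse(s > 0, "right", "left"))
  data.frame(phi = phi, psi = psi, wrapped_sum = s,
             handedness = hand, non_beta = non_beta, end_of_chain = end,
             stringsAsFactors = FALSE)
}

#' Classify every residue of a dihedral table
#'
#' @param dihedrals data frame with `phi` and `psi` columns, e.g. from
#'   [backbone_dihedrals()]; extra columns (`resid`, `resno`, `resname`)
#'   are carried through.
#' @param tolerance passed to [classify_twist()].
#' @return data frame of per-residue labels.
#' @export
classify_residues <- function(dihedrals, tolerance = 1e-6) {
  stopifnot(nrow(dihedrals) > 0)
  lab <- classify_twist(dihedrals$phi, dihedrals$psi, tolerance)
  keep <- intersect(c("resid", "resno", "resname"), names(dihedrals))
  cbind(dihedrals[, keep, drop = FALSE], lab[, -(1:2)])
}

#' Aggregate residue labels into a strand-level twist report
#'
#' Counts the per-residue labels and takes the mean wrapped sum over
#' residues with defined angles; the net handedness is the sign of that
#' mean. A strand with a few left-handed residues still nets right when
#' their sums are over-compensated by the right-handed majority.
#'
#' @param labels data frame from [classify_residues()] (or
#'   [classify_twist()]).
#' @param tolerance mean magnitudes at or below this count as no net
#'   twist.
#' @return object of class `strand_twist_report`: list with `counts`,
#'   `n_classified`, `mean_wrapped_sum`, `net_handedness`.
#' @export
strand_net_twist <- function(labels, tolerance = 1e-6) {
  ok <- !is.na(labels$wrapped_sum)
  if (!any(ok)) stop("no residue with defined phi and psi", call. = FALSE)
  counts <- c(right = sum(labels$handedness[ok] == "right"),
              left = sum(labels$handedness[ok] == "left"),
              none = sum(labels$handedness[ok] == "none"))
  m <- mean(labels$wrapped_sum[ok])
  net <- if (abs(m) <= tolerance) "none" else if (m > 0) "right" else "left"
  structure(list(counts = counts, n_classified = sum(ok),
                 mean_wrapped_sum = m, net_handedness = net),
            class = "strand_twist_report")
}

#' @export
print.strand_twist_report <- function(x, ...) {
  cat(sprintf(
    "<strand twist> %d residues classified: %d right / %d left / %d none\n",
    x$n_classified, x$counts[["right"]], x$counts[["left"]],
    x$counts[["none"]]))
  cat(sprintf("  mean wrapped phi+psi: %+.2f deg  ->  net %s-handed twist\n",
              x$mean_wrapped_sum, x$net_handedness))
  invisible(x)
}

#' Ramachandran plot with handedness shading
#'
#' Scatter of (phi, psi) on the [-180, 180] torus. The diagonal from
#' (-180, 180) to (180, -180) separates the locally right-handed region
#' (wrapped phi + psi in (0, 180), shaded blue, continuing past the wrap
#' into the lower-left corner) from the left-handed region (shaded purple).
#' An optional track connects a residue subset in order. A TSV twin of the
#' plotted points is written next to the image.
#'
#' @param dihedrals data frame with `phi`, `psi` (and optionally `resid`).
#' @param path output image file; `.pdf` and `.png` are supported.
#' @param track optional integer vector of row indices drawn as a
#'   connected track.
#' @param main plot title.
#' @return invisible list with `image` and `tsv` paths.
#' @export
ramachandran_plot <- function(dihedrals, path, track = NULL,
                              main = "Ramachandran plot") {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                pdf = function(p) grDevices::pdf(p, width = 6, height = 6),
                png = function(p) grDevices::png(p, width = 900, height = 900,
                                                 res = 150),
                stop(sprintf("unsupported image format '%s' for %s", ext, path),
                     call. = FALSE))
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  pts <- dihedrals[ok, , drop = FALSE]
  dev(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(pty = "s", mar = c(4.5, 4.5, 3, 1))
  graphics::plot(NULL, xlim = c(-180, 180), ylim = c(-180, 180),
                 xlab = expression(phi ~ "(deg)"),
                 ylab = expression(psi ~ "(deg)"),
                 main = main, xaxs = "i", yaxs = "i", axes = FALSE)
  graphics::axis(1, at = seq(-180, 180, 90))
  graphics::axis(2, at = seq(-180, 180, 90))
  graphics::box()
  blue <- grDevices::adjustcolor("lightskyblue", 0.45)
  purple <- grDevices::adjustcolor("plum", 0.45)
  # right-handed: 0 < phi+psi < 180, re-entering below phi+psi = -180
  graphics::polygon(c(-180, 0, 180, 180), c(180, 180, 0, -180),
                    col = blue, border = NA)
  graphics::polygon(c(-180, -180, 0), c(0, -180, -180),
                    col = blue, border = NA)
  # left-handed: -180 < phi+psi < 0, re-entering above phi+psi = 180
  graphics::polygon(c(-180, -180, 180, 0), c(180, 0, -180, -180),
                    col = purple, border = NA)
  graphics::polygon(c(0, 180, 180), c(180, 180, 0),
                    col = purple, border = NA)
  graphics::segments(-180, 180, 180, -180, lty = 2)
  graphics::segments(-180, 0, 180, 0, col = "grey60")
  graphics::segments(0, -180, 0, 180, col = "grey60")
  if (!is.null(track) && length(track) > 1) {
    tr <- dihedrals[track, , drop = FALSE]
    graphics::lines(tr$phi, tr$psi, col = "darkgreen", lwd = 1.5)
  }
  graphics::points(pts$phi, pts$psi, pch = 16, cex = 0.6)
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  lab <- classify_twist(pts$phi, pts$psi)
  out <- data.frame(residue = if ("resid" %in% names(pts)) pts$resid
                    else seq_len(nrow(pts)),
                    phi = round(pts$phi, 4), psi = round(pts$psi, 4),
                    wrapped_sum = round(lab$wrapped_sum, 4),
                    handedness = lab$handedness)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(image = path, tsv = tsv))
}

#' Twist increment between neighbouring strands of a propeller blade
#'
#' A propeller blade packs `n_strands` strands with the innermost nearly
#' perpendicular to the outermost; spreading that end-to-end rotation
#' evenly gives the twist between neighbours: 90 / (4 - 1) = 30 degrees
#' for the usual four-stranded blade.
#'
#' @param n_strands number of strands in the blade, >= 2.
#' @param end_to_end_angle rotation from innermost to outermost strand,
#'   degrees; default 90.
#' @return per-neighbour twist angle in degrees.
#' @export
propeller_increment <- function(n_strands, end_to_end_angle = 90) {
  if (n_strands < 2) stop("a blade needs at least 2 strands", call. = FALSE)
  end_to_end_angle / (n_strands - 1)
}
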