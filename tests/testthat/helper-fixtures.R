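# shared helpers: rigid motions, backbone extraction, tiny PDB fixtures

random_rigid_motion <- function() {
  M <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}

transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

backbone_xyz <- function(s) {
  at <- s$atoms[s$atoms$name %in% c("N", "CA", "C", "O"), ]
  as.matrix(at[order(at$resid, match(at$name, c("N", "CA", "C", "O"))),
               c("x", "y", "z")])
}

end_to_end <- function(s) {
  n <- max(s$atoms$resid)
  a <- s$atoms[s$atoms$resid == 1 & s$atoms$name == "N", c("x", "y", "z")]
  b <- s$atoms[s$atoms$resid == n & s$atoms$name == "C", c("x", "y", "z")]
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

# a minimal hand-written PDB with a SHEET record (glycine stubs)
write_sheet_fixture <- function(path) {
  res <- 10:14
  lines <- c(
    "HEADER    TEST STRUCTURE",
    "SHEET    1   A 2 GLY A  10  GLY A  14  0")
  serial <- 0
  for (k in seq_along(res)) {
    base <- (k - 1) * 3.2
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      off <- switch(nm, N = 0, CA = 1.2, C = 2.4, O = 2.4)
      z <- if (nm == "O") 1.23 else 0
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, nm, res[k], base + off, (k %% 2) * 0.5, z,
        substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}
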