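Package: betatwist
Title: Steric Origin and Handedness of the Beta-Sheet Twist
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study why beta-strands twist, and why almost always to
    the right. Builds idealized peptides from internal coordinates (bond
    lengths, bond angles, backbone dihedrals), measures the intrastrand van
    der Waals clashes between a residue's side chain and the carbonyl and
    amide groups of the same and adjacent residues, scans phi and psi to
    follow how those clashes trade off, and classifies per-residue twist
    handedness from the wrapped sum phi + psi with Ramachandran
    visualization. Reads and writes PDB files so the same analysis runs on
    real beta-sheets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    grDevices,
    graphics,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
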