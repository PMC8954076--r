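# Shared fixtures, built in code at test time.

# A chiral 5-atom configuration (no symmetry plane) and its mirror image.
chiral_fixture <- function() {
  molecule(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1.3, 0.7, 0.2)),
           rep("C", 5), name = "chiral")
}

mirror_of <- function(mol) {
  out <- mol
  out$coords[, 3] <- -out$coords[, 3]
  out$name <- paste0(mol$name, "_mirror")
  out
}

# Random proper rotation (via quaternion), deterministic under seed.
random_rotation <- function(seed) {
  q <- betashape:::with_seed(seed, stats::rnorm(4))
  betashape:::.quat_to_rot(q)
}

# Text of a minimal 3-atom water XYZ file.
water_xyz_lines <- function() {
  c("3", "water",
    "O   0.00000000   0.00000000   0.00000000",
    "H   0.95720000   0.00000000   0.00000000",
    "H  -0.23990000   0.92660000   0.00000000")
}

write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small ligand-like PDBQT file (Vina output dialect), written in code.
pdbqt_fixture_lines <- function() {
  coords <- rbind(c(1.000, 2.000, 3.000), c(2.500, 2.000, 3.000),
                  c(1.000, 3.500, 3.000), c(1.000, 2.000, 4.750),
                  c(3.100, 2.900, 3.300))
  types <- c("C", "OA", "N", "HD", "A")
  names <- c("C1", "O1", "N1", "H1", "C2")
  atoms <- sprintf(
    "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    %6.3f %-2s",
    1:5, names, coords[, 1], coords[, 2], coords[, 3],
    c(0.1, -0.3, -0.2, 0.15, 0.05), types)
  c("ROOT", atoms[1:3], "ENDROOT", "BRANCH   1   4", atoms[4:5],
    "ENDBRANCH   1   4", "TORSDOF 1")
}

# Build a parent molecule with an obvious deprotonation geometry: heavy
# atoms plus hydrogens, one of which sits on a labelled carboxyl carbon.
parent_with_sites <- function(seed = 11L) {
  mol <- random_molecule(12, elements = c("C", "C", "O", "O", "C", "N",
                                          "H", "H", "H", "O", "H", "C"),
                         seed = seed, name = "parent")
  mol$labels[5] <- "C17"
  mol$labels[7] <- "H17"
  # put H7 right next to the C17 carbon so the nearest-H rule is clear-cut
  mol$coords[7, ] <- mol$coords[5, ] + c(0.95, 0, 0)
  mol
}
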