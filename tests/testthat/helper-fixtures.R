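# Shared helpers for the test suite.

# Minimal ProteinStructure from a coordinate matrix.
structureFromCoords <- function(xyz, id = "test", element = "C",
                                residueName = "ALA") {
  n <- nrow(xyz)
  new("ProteinStructure",
      atoms = data.frame(
        serial = seq_len(n), atom_name = "CA",
        residue_name = rep_len(residueName, n), chain_id = "A",
        residue_seq = seq_len(n),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        element = rep_len(element, n), occupancy = 1, b_factor = 0,
        stringsAsFactors = FALSE),
      id = id)
}

# Roughly uniform atom ball: lattice fill of a sphere (convex, no pockets).
convexBallStructure <- function(radius = 6, pitch = 1.5) {
  g <- seq(-radius, radius, by = pitch)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  structureFromCoords(pts, id = "ball")
}

randomRotationMatrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# point directly from their definitions.
bruteForceKS <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

extdataPath <- function(f) system.file("extdata", f, package = "PocketScreen")

# Compounds tested at 40 uM but absent from the printed efficacy table
# (never active): everything in the bone-marrow table minus the table 2 set.
table2ExtraCompounds <- function() {
  t1 <- utils::read.delim(extdataPath("table1_bone_marrow.tsv"))
  setdiff(t1$compound,
          c("Dxr2-017", "Dxr2-055", "Dxr2-069", "FolC2-001", "FolC2-005",
            "FolC2-044", "FolC1-042", "FolC1-020", "Dxr1-021", "TYLT-072"))
}
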