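test_that("PDB write/read round trip preserves atoms and coordinates", {
  set.seed(11)
  xyz <- matrix(rnorm(45, sd = 8), ncol = 3)
  s <- structureFromCoords(xyz, id = "roundtrip")
  path <- tempfile(fileext = ".pdb")
  writeStructure(s, path)
  back <- readStructure(path)
  a <- atoms(back)
  expect_equal(nrow(a), nrow(xyz))
  expect_equal(as.matrix(a[, c("x", "y", "z")]), xyz,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(a$element, rep("C", nrow(xyz)))
  expect_equal(a$residue_seq, seq_len(nrow(xyz)))
})

test_that("missing and empty files are errors", {
  expect_error(readStructure(tempfile()), "not found")
  hetOnly <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), hetOnly)
  expect_error(readStructure(hetOnly), "empty structure")
})

test_that("HETATM and waters are excluded by default, kept on request", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 MG    MG A   3       9.000   0.000   0.000  1.00  0.00          MG",
    "END"), path)
  expect_equal(nrow(atoms(readStructure(path))), 1L)
  all3 <- readStructure(path, includeHetatm = TRUE)
  expect_equal(nrow(atoms(all3)), 3L)
  expect_true("MG" %in% atoms(all3)$element)
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  a <- atoms(readStructure(path))
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$atom_name == "CA"], 2.0)
})

test_that("residue polarity follows the documented 12-residue set", {
  expect_true(residueIsPolar("SER"))
  expect_true(residueIsPolar("ARG"))
  expect_true(residueIsPolar("TRP"))
  expect_false(residueIsPolar("LEU"))
  expect_false(residueIsPolar("GLY"))
  expect_equal(sum(residueIsPolar(c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN",
                                    "GLU", "GLY", "HIS", "ILE", "LEU", "LYS",
                                    "MET", "PHE", "PRO", "SER", "THR", "TRP",
                                    "TYR", "VAL"))), 12L)
})

test_that("non-standard residues warn when lenient and error when strict", {
  expect_warning(res <- residueIsPolar("XYZ"), "non-standard")
  expect_false(res)
  expect_error(residueIsPolar("XYZ", strict = TRUE), "non-standard")
  # the polar set itself is overridable
  expect_false(residueIsPolar("SER", polarSet = c("THR")))
})

test_that("van der Waals radii: known values, unknown default with warning", {
  expect_equal(vdwRadius("C"), 1.70)
  expect_equal(vdwRadius("N"), 1.55)
  expect_equal(vdwRadius(c("O", "S")), c(1.52, 1.80))
  expect_warning(r <- vdwRadius("XX"), "unknown element")
  expect_equal(r, 1.7)
  expect_warning(r2 <- vdwRadius("XX", default = 2.2), "unknown element")
  expect_equal(r2, 2.2)
})

test_that("structure validity rejects non-finite coordinates and duplicates", {
  xyz <- matrix(0, nrow = 2, ncol = 3)
  expect_error({
    df <- structureFromCoords(xyz)@atoms
    df$x[1] <- NaN
    new("ProteinStructure", atoms = df, id = "bad")
  })
  expect_error({
    df <- structureFromCoords(matrix(rnorm(6), 2))@atoms
    df$residue_seq <- c(1L, 1L)  # same chain, seq, atom name
    new("ProteinStructure", atoms = df, id = "dup")
  })
})
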