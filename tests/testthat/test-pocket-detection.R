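test_that("buildGrid occupancy matches a brute-force sphere rasterization", {
  s <- structureFromCoords(matrix(c(0, 0, 0), 1), id = "one")
  g <- buildGrid(s, spacing = 0.5, margin = 3)
  # independent oracle: enumerate all voxel centres, test distance directly
  dims <- g@dim
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  ctr <- sweep((idx - 1) * g@spacing, 2, g@origin, `+`)
  inside <- rowSums(ctr^2) <= 1.70^2
  lin <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  expect_equal(sum(g@protein), sum(inside))
  expect_equal(which(g@protein), sort(lin[inside] + 1))
})

test_that("grid box spans the atoms plus margin", {
  s <- structureFromCoords(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 5, 5)),
                           id = "span")
  g <- buildGrid(s, spacing = 1, margin = 5)
  expect_equal(g@origin[1], -5)
  expect_gte((g@dim[1] - 1) * g@spacing + g@origin[1], 105)
})

test_that("buildGrid validates spacing and the voxel budget", {
  s <- structureFromCoords(matrix(rnorm(9), 3), id = "v")
  expect_error(buildGrid(s, spacing = 0.1), "spacing")
  expect_error(buildGrid(s, spacing = 2), "spacing")
  expect_error(buildGrid(s, spacing = 0.25, maxVoxels = 10), "larger spacing")
})

test_that("a convex atom ball has no pockets", {
  g <- buildGrid(convexBallStructure(), spacing = 0.5)
  expect_length(detectPockets(g), 0)
})

test_that("hemisphere fixture: one single-mouth pocket, volume near analytic", {
  fx <- makePocketStructure(5, seed = 1)
  p <- detectPockets(buildGrid(fx$structure, spacing = 0.5))
  expect_length(p, 1)
  expect_equal(mouthCount(p[[1]]), fx$manifest$ground_truth$mouth_count)
  expect_lt(abs(pocketVolume(p[[1]]) / fx$manifest$ground_truth$analytic_volume - 1),
            0.15)
  expect_gt(pocketArea(p[[1]]), 0)
  expect_gt(nrow(liningResidues(p[[1]])), 0)
})

test_that("sealed cavity fixture: one cavity with zero mouths", {
  fx <- makePocketStructure(5, sealed = TRUE, seed = 1)
  p <- detectPockets(buildGrid(fx$structure, spacing = 0.5))
  expect_length(p, 1)
  expect_equal(mouthCount(p[[1]]), 0L)
})

test_that("pocket components are disjoint and fit in free space", {
  fx <- makePocketStructure(4, seed = 2)
  g <- buildGrid(fx$structure, spacing = 0.5)
  p <- detectPockets(g)
  keys <- unlist(lapply(p, function(pk)
    paste(pk@voxels[, 1], pk@voxels[, 2], pk@voxels[, 3])))
  expect_equal(anyDuplicated(keys), 0L)
  expect_lte(length(keys), sum(!g@protein))
})

test_that("rigid rotation preserves pocket count, mouths, and volume within 10%", {
  fx <- makePocketStructure(5, seed = 1)
  a <- atoms(fx$structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  set.seed(99)
  R <- randomRotationMatrix()
  a[, c("x", "y", "z")] <- xyz %*% t(R)
  rot <- new("ProteinStructure", atoms = a, id = "rot")
  p0 <- detectPockets(buildGrid(fx$structure, spacing = 0.5))
  p1 <- detectPockets(buildGrid(rot, spacing = 0.5))
  expect_length(p1, length(p0))
  expect_equal(mouthCount(p1[[1]]), mouthCount(p0[[1]]))
  expect_lt(abs(pocketVolume(p1[[1]]) / pocketVolume(p0[[1]]) - 1), 0.10)
  expect_lt(abs(pocketArea(p1[[1]]) / pocketArea(p0[[1]]) - 1), 0.15)
})

test_that("detection is deterministic", {
  fx <- makePocketStructure(4, seed = 3)
  r1 <- pocketReport(detectPockets(buildGrid(fx$structure, spacing = 0.5)))
  r2 <- pocketReport(detectPockets(buildGrid(fx$structure, spacing = 0.5)))
  expect_identical(r1, r2)
})

test_that("filterPockets hard-excludes and deprioritizes as documented", {
  mk <- function(id, area, polar, mouths) {
    new("Pocket", id = id, voxels = matrix(1L, 1, 3,
                                           dimnames = list(NULL, c("i", "j", "k"))),
        gridOrigin = c(0, 0, 0), gridSpacing = 0.5,
        liningAtoms = data.frame(), area = area, volume = 1,
        mouthCount = as.integer(mouths),
        residues = data.frame(chain = "A", seq = 1:3,
                              name = c("SER", "THR", "LEU")),
        polarResidueCount = as.integer(polar), priorityFlags = character(0))
  }
  pk <- list(mk(1L, 400, 3, 1),   # too small -> excluded
             mk(2L, 600, 1, 1),   # too few polar -> excluded
             mk(3L, 700, 3, 2),   # multi-mouth -> kept, deprioritized
             mk(4L, 600, 3, 1))   # kept first
  out <- filterPockets(pk)
  expect_equal(vapply(out, function(p) p@id, integer(1)), c(4L, 3L))
  expect_equal(out[[2]]@priorityFlags, "multi_mouth_deprioritized")
  expect_equal(out[[1]]@priorityFlags, character(0))
  # idempotence
  out2 <- filterPockets(out)
  expect_equal(pocketReport(out2), pocketReport(out))
})

test_that("pocket report and lining-residue table have the documented shape", {
  expect_equal(nrow(pocketReport(list())), 0)
  expect_named(pocketReport(list()),
               c("id", "volume", "area", "mouths", "residues",
                 "polar_residues", "flags"))
  fx <- makePocketStructure(5, seed = 4)
  p <- detectPockets(buildGrid(fx$structure, spacing = 0.5))
  tab <- liningResidueTable(p)
  expect_named(tab, c("chain", "seq", "name", "pocket"))
  expect_true(all(tab$pocket == 1L))
  # polar count consistent with the manifest's residue-name assignment
  names <- fx$manifest$ground_truth$residue_names
  expect_equal(p[[1]]@polarResidueCount,
               sum(suppressWarnings(residueIsPolar(
                 names[match(tab$seq, seq_along(names))]))))
})
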