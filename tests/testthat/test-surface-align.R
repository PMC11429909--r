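test_that("superpose recovers a known rigid motion exactly", {
  set.seed(61)
  A <- matrix(rnorm(36, sd = 5), ncol = 3)
  R <- randomRotationMatrix()
  t <- c(3, -2, 8)
  B <- sweep((A - 0) %*% t(R), 2, t, `+`)  # B = R A + t, so A = R' (B - t)
  al <- superpose(A, B)
  expect_lt(crmsd(al), 1e-9)
  expect_equal(rotation(al) %*% R, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  mapped <- sweep(B %*% t(rotation(al)), 2, translation(al), `+`)
  expect_equal(mapped, A, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(rotation(al)), 1, tolerance = 1e-9)
})

test_that("superpose validates correspondences", {
  A <- matrix(rnorm(9), 3)
  expect_error(superpose(A, matrix(rnorm(12), 4)), "pairs")
  expect_error(superpose(A[1:2, ], A[1:2, ], pairs = cbind(1:2, 1:2)),
               "at least 3")
  expect_error(superpose(A, A, pairs = cbind(c(1, 1, 2), 1:3)), "unique")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("greedy correspondence respects chemical classes and is deterministic", {
  set.seed(71)
  A <- matrix(rnorm(30), ncol = 3)
  B <- A + matrix(rnorm(30, sd = 0.01), ncol = 3)
  eA <- c("C", "C", "N", "O", "S", "C", "N", "O", "C", "C")
  pr <- greedyCorrespondence(A, B, eA, eA)
  expect_equal(nrow(pr), 10)
  expect_equal(eA[pr[, 1]], eA[pr[, 2]])
  expect_identical(pr, greedyCorrespondence(A, B, eA, eA))
  # near-identical sets pair index to itself
  expect_equal(pr[, 1], pr[, 2], ignore_attr = TRUE)
})

test_that("orientation vectors are unit length; glycine is skipped", {
  atoms <- data.frame(
    serial = 1:7,
    atom_name = c("N", "CA", "C", "CB", "OG", "CA", "CA"),
    residue_name = c(rep("SER", 5), "GLY", "ALA"),
    chain_id = "A",
    residue_seq = c(1, 1, 1, 1, 1, 2, 3),
    x = c(0, 1, 2, 1.5, 2.0, 5, 8), y = c(0, 0, 0, 1, 2, 5, 8),
    z = c(0, 0, 0, 0, 0.5, 5, 8),
    element = c("N", "C", "C", "C", "O", "C", "C"),
    occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  s <- new("ProteinStructure", atoms = atoms, id = "ov")
  res <- data.frame(chain = "A", seq = c(1, 2, 3))
  expect_warning(v <- orientationVectors(s, res), "side-chain")
  expect_equal(nrow(v), 1)          # SER only: GLY skipped, ALA has no CB here
  expect_equal(attr(v, "skipped_gly"), 1L)
  expect_equal(sqrt(sum(v[1, ]^2)), 1, tolerance = 1e-12)
  # independent arithmetic for the SER vector
  expect_equal(v[1, ], local({
    d <- c(mean(c(1.5, 2.0)), mean(c(1, 2)), mean(c(0, 0.5))) - c(1, 0, 0)
    d / sqrt(sum(d^2))
  }), ignore_attr = TRUE)
})

test_that("ormsd matches independent arithmetic and detects mismatch", {
  u <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(ormsd(diag(3), u, u), 0)
  flip <- rbind(c(-1, 0, 0), c(0, -1, 0))
  expect_equal(ormsd(diag(3), u, flip), 2)
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  # Rz maps (1,0,0) to (0,1,0): perfect match against itself rotated
  expect_equal(ormsd(Rz, u, u %*% t(Rz)), 0, tolerance = 1e-12)
  expect_error(ormsd(diag(3), u, u[1, , drop = FALSE]), "differ")
})

test_that("Monte-Carlo significance follows the add-one formula and is seeded", {
  set.seed(81)
  A <- matrix(rnorm(24, sd = 3), ncol = 3)
  B <- A %*% t(randomRotationMatrix())
  m1 <- mcSignificance(A, B, nNull = 39, seed = 5)
  m2 <- mcSignificance(A, B, nNull = 39, seed = 5)
  expect_identical(m1, m2)
  expect_equal(m1$p, (1 + sum(m1$null <= m1$observed)) / 40)
  expect_gte(m1$p, 1 / 40)
  expect_lte(m1$p, 1)
  expect_length(m1$null, 39)
  expect_error(mcSignificance(A, B, nNull = 5), ">= 19")
  # caller's RNG stream is untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(mcSignificance(A, B, nNull = 19, seed = 9))
  expect_identical(rnorm(3), before)
})

test_that("gsvot reproduces the analytic Tanimoto cases", {
  idAl <- new("AlignmentResult", rotation = diag(3), translation = c(0, 0, 0),
              crmsd = 0, ormsd = NA_real_, pEmpirical = NA_real_,
              gsvot = NA_real_, composite = NA_real_)
  A <- cbind(i = 1:2, j = c(1L, 1L), k = c(1L, 1L))
  expect_equal(gsvot(A, A, idAl, spacing = 1), 1)
  Bdisjoint <- cbind(i = 8:9, j = c(1L, 1L), k = c(1L, 1L))
  expect_equal(gsvot(A, Bdisjoint, idAl, spacing = 1), 0)
  Bshift <- cbind(i = 2:3, j = c(1L, 1L), k = c(1L, 1L))
  expect_equal(gsvot(A, Bshift, idAl, spacing = 1), 1 / 3)
})

test_that("composite score is a clamped geometric mean, monotone in inputs", {
  expect_equal(surfaceScreenScore(0.2, 0.3, 0.5),
               exp(mean(log(c(0.8, 0.7, 0.5)))))
  expect_gt(surfaceScreenScore(0.1, 0.3, 0.5),
            surfaceScreenScore(0.2, 0.3, 0.5))
  expect_gt(surfaceScreenScore(0.2, 0.3, 0.6),
            surfaceScreenScore(0.2, 0.3, 0.5))
  # p = 1 clamps instead of zeroing the product
  expect_gt(surfaceScreenScore(0.2, 1, 0.5), 0)
  expect_error(surfaceScreenScore(NA, 0.5, 0.5), "populated")
})

test_that("alignPockets populates every score on fixture pockets", {
  fx1 <- makePocketStructure(4, seed = 1)
  fx2 <- makePocketStructure(4, seed = 2)
  p1 <- detectPockets(buildGrid(fx1$structure, spacing = 0.5))[[1]]
  p2 <- detectPockets(buildGrid(fx2$structure, spacing = 0.5))[[1]]
  al <- alignPockets(p1, p2, nNull = 19, seed = 3)
  expect_true(is.finite(crmsd(al)))
  expect_true(al@pEmpirical >= 1 / 20 && al@pEmpirical <= 1)
  expect_true(al@gsvot >= 0 && al@gsvot <= 1)
  expect_true(al@composite >= 0 && al@composite <= 1)
})
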