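#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the root-mean-square
#' distance between paired points, mapping set B onto set A
#' (\code{x_A ~ R x_B + t}). The solution is the classical singular-value
#' decomposition of the cross-covariance with reflection correction (the
#' determinant is forced to +1), so the returned cRMSD is the minimum over
#' rigid motions for the given correspondence.
#'
#' @param coordsA,coordsB numeric matrices (n x 3), Angstrom.
#' @param pairs integer matrix (m x 2) of paired row indices (A, B); defaults
#'   to the identity correspondence when both sets have equal size. At least
#'   3 pairs are required and the paired points must not be collinear.
#' @return an \linkS4class{AlignmentResult} with rotation, translation and
#'   cRMSD populated.
#' @examples
#' A <- matrix(rnorm(18), ncol = 3)
#' superpose(A, A)  # cRMSD 0, identity rotation
#' @export
superpose <- function(coordsA, coordsB, pairs = NULL) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (is.null(pairs)) {
    if (nrow(coordsA) != nrow(coordsB))
      stop("pairs must be supplied when the point sets differ in size")
    pairs <- cbind(seq_len(nrow(coordsA)), seq_len(nrow(coordsA)))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("at least 3 correspondence pairs are required")
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("correspondence indices must be unique within each side")
  A <- coordsA[pairs[, 1], , drop = FALSE]
  B <- coordsB[pairs[, 2], , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (svd(Ac)$d[2] < 1e-8 || svd(Bc)$d[2] < 1e-8)
    stop("degenerate correspondence: paired points are collinear")
  H <- crossprod(Bc, Ac)          # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- ca - as.vector(R %*% cb)
  resid <- Bc %*% t(R) - Ac
  new("AlignmentResult", rotation = R, translation = tvec,
      crmsd = sqrt(mean(rowSums(resid^2))),
      ormsd = NA_real_, pEmpirical = NA_real_, gsvot = NA_real_,
      composite = NA_real_)
}

# chemical classes used for correspondence generation: N, O and S atoms keep
# their identity, everything else is lumped with carbon
.chemClass <- function(element) {
  e <- toupper(element)
  ifelse(e %in% c("N", "O", "S"), e, "C")
}

#' Greedy chemical-class correspondence between two atom sets
#'
#' Default correspondence generator for pocket superposition: both sets are
#' centred on their centroids, then within each chemical class (N, O, S,
#' other) pairs are formed greedily by smallest centred distance until one
#' side of the class is exhausted. Ties resolve to the lowest atom index, so
#' the result is deterministic.
#'
#' @param coordsA,coordsB numeric matrices (n x 3).
#' @param elementsA,elementsB element symbols per atom; when NULL all atoms
#'   fall into one class.
#' @return integer matrix (m x 2) of paired row indices.
#' @export
greedyCorrespondence <- function(coordsA, coordsB,
                                 elementsA = NULL, elementsB = NULL) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  clA <- if (is.null(elementsA)) rep("C", nrow(coordsA)) else .chemClass(elementsA)
  clB <- if (is.null(elementsB)) rep("C", nrow(coordsB)) else .chemClass(elementsB)
  Ac <- sweep(coordsA, 2, colMeans(coordsA))
  Bc <- sweep(coordsB, 2, colMeans(coordsB))
  pairs <- NULL
  for (cl in sort(intersect(unique(clA), unique(clB)))) {
    ia <- which(clA == cl); ib <- which(clB == cl)
    D <- as.matrix(stats::dist(rbind(Ac[ia, , drop = FALSE],
                                     Bc[ib, , drop = FALSE])))
    D <- D[seq_along(ia), length(ia) + seq_along(ib), drop = FALSE]
    while (length(ia) > 0 && length(ib) > 0) {
      k <- which.min(D)  # lowest linear index on ties -> deterministic
      ri <- ((k - 1) %% nrow(D)) + 1
      ci <- ((k - 1) %/% nrow(D)) + 1
      pairs <- rbind(pairs, c(ia[ri], ib[ci]))
      ia <- ia[-ri]; ib <- ib[-ci]
      D <- D[-ri, -ci, drop = FALSE]
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Residue orientation vectors
#'
#' For each requested residue, the unit vector from the backbone CA to the
#' centroid of the side-chain heavy atoms. These vectors summarize side-chain
#' orientation and tolerate pocket flexibility better than raw coordinates.
#' Glycine has no side chain and is skipped (the count is recorded in the
#' \code{"skipped_gly"} attribute); non-glycine residues lacking side-chain
#' atoms are skipped with a warning (\code{"skipped_missing"} attribute).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param residues data.frame with columns \code{chain} and \code{seq} (as
#'   returned by \code{liningResidues}).
#' @return numeric matrix (m x 3) of unit vectors with rownames
#'   \code{"chain:seq"}; attributes \code{skipped_gly}, \code{skipped_missing}.
#' @export
orientationVectors <- function(structure, residues) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- structure@atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  out <- NULL; ids <- character(0)
  skippedGly <- 0L; skippedMissing <- character(0)
  for (r in seq_len(nrow(residues))) {
    sel <- a$chain_id == residues$chain[r] &
      a$residue_seq == residues$seq[r]
    ra <- a[sel, , drop = FALSE]
    if (nrow(ra) == 0) {
      warning("residue ", residues$chain[r], ":", residues$seq[r],
              " not found; skipped")
      next
    }
    if (ra$residue_name[1] == "GLY") { skippedGly <- skippedGly + 1L; next }
    caRow <- ra[ra$atom_name == "CA", , drop = FALSE]
    if (nrow(caRow) == 0) {
      warning("residue ", residues$chain[r], ":", residues$seq[r],
              " lacks a CA atom; skipped")
      next
    }
    side <- ra[!(ra$atom_name %in% backbone) & ra$element != "H", ,
               drop = FALSE]
    if (nrow(side) == 0) {
      skippedMissing <- c(skippedMissing,
                          paste0(residues$chain[r], ":", residues$seq[r]))
      warning("residue ", residues$chain[r], ":", residues$seq[r],
              " has no side-chain heavy atoms; skipped")
      next
    }
    v <- colMeans(as.matrix(side[, c("x", "y", "z")])) -
      as.numeric(caRow[1, c("x", "y", "z")])
    out <- rbind(out, v / sqrt(sum(v^2)))
    ids <- c(ids, paste0(residues$chain[r], ":", residues$seq[r]))
  }
  if (!is.null(out)) rownames(out) <- ids
  attr(out, "skipped_gly") <- skippedGly
  attr(out, "skipped_missing") <- skippedMissing
  out
}

#' Orientation RMSD between matched unit-vector sets
#'
#' \code{sqrt(mean_i |R u_i - v_i|^2)} for unit vectors, which lies in
#' [0, 2]: 0 for perfectly matched orientations under the rotation, 2 for
#' antiparallel ones.
#'
#' @param rotation 3x3 rotation matrix (as from \code{superpose}).
#' @param vecsA,vecsB numeric matrices (m x 3) of unit vectors, equal m >= 1.
#' @return numeric(1).
#' @export
ormsd <- function(rotation, vecsA, vecsB) {
  vecsA <- as.matrix(vecsA); vecsB <- as.matrix(vecsB)
  if (nrow(vecsA) != nrow(vecsB))
    stop("orientation vector counts differ: ", nrow(vecsA), " vs ",
         nrow(vecsB))
  if (nrow(vecsA) < 1) stop("at least one vector pair is required")
  sqrt(mean(rowSums((vecsA %*% t(rotation) - vecsB)^2)))
}

# n uniformly distributed rotation matrices via normalized quaternions
.randomRotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  })
}

.pocketCoords <- function(x) {
  if (is(x, "Pocket"))
    list(xyz = as.matrix(x@liningAtoms[, c("x", "y", "z")]),
         elem = x@liningAtoms$element)
  else if (is.list(x) && !is.null(x$xyz))
    list(xyz = as.matrix(x$xyz), elem = x$elem)
  else
    list(xyz = as.matrix(x), elem = NULL)
}

#' Monte-Carlo significance of a surface alignment
#'
#' Null model: the second surface is rotated uniformly at random about its
#' centroid (quaternion sampling), the greedy chemical-class correspondence is
#' re-derived, and the alignment is scored exactly like the observed one
#' (cRMSD by default; lower = better). The empirical p-value uses the add-one
#' estimator \code{p = (1 + #\{null <= observed\}) / (1 + nNull)}, so it is
#' never zero. Deterministic for a fixed seed.
#'
#' @param pocketA,pocketB \linkS4class{Pocket} objects, coordinate matrices,
#'   or lists with elements \code{xyz} and \code{elem}.
#' @param nNull number of random alignments (>= 19).
#' @param seed integer seed for the quaternion draws.
#' @param statistic alignment score used for the comparison; only
#'   \code{"crmsd"} is currently provided (the switch exists so other scores
#'   can be slotted in).
#' @return list with \code{p}, \code{observed}, \code{null} scores.
#' @export
mcSignificance <- function(pocketA, pocketB, nNull = 99L, seed = 1L,
                           statistic = c("crmsd")) {
  statistic <- match.arg(statistic)
  if (nNull < 19) stop("nNull must be >= 19")
  A <- .pocketCoords(pocketA); B <- .pocketCoords(pocketB)
  score <- function(bxyz) {
    pr <- greedyCorrespondence(A$xyz, bxyz, A$elem, B$elem)
    superpose(A$xyz, bxyz, pr)@crmsd
  }
  observed <- score(B$xyz)
  cb <- colMeans(B$xyz)
  Bc <- sweep(B$xyz, 2, cb)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  rots <- .randomRotations(nNull)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  nullScores <- vapply(rots, function(R)
    score(sweep(Bc %*% t(R), 2, cb, `+`)), numeric(1))
  list(p = (1 + sum(nullScores <= observed)) / (1 + nNull),
       observed = observed, null = nullScores)
}

#' Global surface volume overlap Tanimoto (gSVOT)
#'
#' Maps the voxel centres of pocket B through the alignment
#' (\code{x' = R x + t}), re-rasterizes them onto A's grid by nearest-voxel
#' rounding, and returns the Tanimoto coefficient
#' \code{|A intersect B'| / |A union B'|} of the two voxel sets. Surfaces of
#' similar shape that also occupy similar volumes score near 1.
#'
#' @param voxelsA,voxelsB \linkS4class{Pocket} objects or integer matrices
#'   (n x 3) of voxel indices.
#' @param alignment an \linkS4class{AlignmentResult} mapping B onto A.
#' @param spacing voxel edge length of A's grid (taken from the Pocket when
#'   one is supplied).
#' @param originA,originB grid origins (taken from Pockets when supplied).
#' @return numeric(1) in [0, 1].
#' @export
gsvot <- function(voxelsA, voxelsB, alignment, spacing = NULL,
                  originA = c(0, 0, 0), originB = c(0, 0, 0)) {
  if (is(voxelsA, "Pocket")) {
    originA <- voxelsA@gridOrigin
    if (is.null(spacing)) spacing <- voxelsA@gridSpacing
    voxelsA <- voxelsA@voxels
  }
  if (is(voxelsB, "Pocket")) {
    originB <- voxelsB@gridOrigin
    voxelsB <- voxelsB@voxels
  }
  if (is.null(spacing)) stop("spacing must be given for raw voxel matrices")
  voxelsA <- as.matrix(voxelsA); voxelsB <- as.matrix(voxelsB)
  if (nrow(voxelsA) == 0 || nrow(voxelsB) == 0)
    stop("empty voxel set")
  centersB <- sweep((voxelsB - 1) * spacing, 2, originB, `+`)
  mapped <- sweep(centersB %*% t(alignment@rotation), 2,
                  alignment@translation, `+`)
  idxB <- round(sweep(mapped, 2, originA, `-`) / spacing) + 1
  keyA <- unique(paste(voxelsA[, 1], voxelsA[, 2], voxelsA[, 3]))
  keyB <- unique(paste(idxB[, 1], idxB[, 2], idxB[, 3]))
  inter <- length(intersect(keyA, keyB))
  inter / (length(keyA) + length(keyB) - inter)
}

#' Composite surface-similarity score
#'
#' Combines shape (the Kolmogorov-Smirnov D between shape signatures),
#' alignment significance (the Monte-Carlo empirical p) and volume overlap
#' (gSVOT) into one similarity in [0, 1] via the geometric mean of
#' \code{1 - D}, \code{1 - p} and \code{gsvot}, each clamped to
#' \code{[1e-6, 1]}. Monotone non-decreasing in every similarity component;
#' the combination rule is isolated here and swappable.
#'
#' @param ks a \linkS4class{KSResult} or the D statistic directly.
#' @param pAlign Monte-Carlo alignment p-value in (0, 1].
#' @param gsvot volume-overlap Tanimoto in [0, 1].
#' @return numeric(1) in [0, 1].
#' @export
surfaceScreenScore <- function(ks, pAlign, gsvot) {
  d <- if (is(ks, "KSResult")) ks@d else as.numeric(ks)
  if (is.na(d) || is.na(pAlign) || is.na(gsvot))
    stop("all composite components must be populated")
  eps <- 1e-6
  comp <- pmin(pmax(c(1 - d, 1 - pAlign, gsvot), eps), 1)
  exp(mean(log(comp)))
}

#' End-to-end comparison of two pockets
#'
#' Convenience wrapper running the full surface-comparison stack: greedy
#' correspondence and least-squares superposition, Monte-Carlo alignment
#' significance, volume-overlap Tanimoto, shape-signature KS comparison and
#' the composite score.
#'
#' @param pocketA,pocketB \linkS4class{Pocket} objects.
#' @param nNull,seed passed to \code{\link{mcSignificance}}.
#' @return an \linkS4class{AlignmentResult} with all slots populated.
#' @export
alignPockets <- function(pocketA, pocketB, nNull = 99L, seed = 1L) {
  stopifnot(is(pocketA, "Pocket"), is(pocketB, "Pocket"))
  A <- .pocketCoords(pocketA); B <- .pocketCoords(pocketB)
  pr <- greedyCorrespondence(A$xyz, B$xyz, A$elem, B$elem)
  al <- superpose(A$xyz, B$xyz, pr)
  mc <- mcSignificance(pocketA, pocketB, nNull = nNull, seed = seed)
  g <- gsvot(pocketA, pocketB, al)
  ks <- ksCompare(computeSignature(pocketA), computeSignature(pocketB))
  al@pEmpirical <- mc$p
  al@gsvot <- g
  al@composite <- surfaceScreenScore(ks, mc$p, g)
  al
}
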