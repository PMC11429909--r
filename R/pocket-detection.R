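#' Build a voxel occupancy grid around a protein
#'
#' Lays a regular cubic grid over the structure's bounding box plus a margin,
#' and labels a voxel protein iff its centre lies within the van der Waals
#' radius of some atom. The grid keeps the atom coordinates and radii so that
#' probe-inflated occupancies can be derived later without re-reading the
#' structure.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param spacing voxel edge length in Angstrom; must lie in [0.25, 1.5].
#' @param margin padding beyond the atom bounding box, Angstrom.
#' @param maxVoxels voxel budget; exceeding it is an error advising a larger
#'   spacing.
#' @return an \linkS4class{OccupancyGrid}.
#' @export
buildGrid <- function(structure, spacing = 0.5, margin = 5,
                      maxVoxels = 6.4e7) {
  stopifnot(is(structure, "ProteinStructure"))
  if (spacing < 0.25 || spacing > 1.5)
    stop("spacing must lie in [0.25, 1.5] Angstrom")
  if (margin < 0) stop("margin must be >= 0")
  a <- structure@atoms
  if (nrow(a) == 0) stop("empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radius <- vdwRadius(a$element)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > maxVoxels)
    stop("grid of ", paste(dims, collapse = " x "),
         " voxels exceeds the budget of ", format(maxVoxels, scientific = FALSE),
         "; use a larger spacing or a smaller margin")
  occ <- .cppOccupancy(xyz, radius, lo, spacing, dims)
  new("OccupancyGrid", origin = unname(lo), spacing = spacing, dim = dims,
      protein = occ$mask, voxelAtom = occ$atom, atomXYZ = xyz,
      atomRadius = radius, atomTable = a, structureId = structure@id)
}

# Correction applied to voxel boundary-face counts when estimating curved
# surface areas; raw axis-aligned face counts systematically overestimate.
.AREA_CORRECTION <- 0.894

#' Detect solvent-accessible pockets and interior cavities
#'
#' Purely geometric detection on the occupancy grid. Free space that a water
#' probe (radius \code{smallProbe}) can occupy is computed by morphological
#' opening (probe-centre erosion against probe-inflated atom spheres, then
#' dilation back). Within that space, pocket voxels are those whose sampled
#' sky is mostly occluded: rays are cast along the 26 grid directions (6
#' axial, 12 face-diagonal, 8 body-diagonal) and the voxel counts as enclosed
#' when at least \code{minEnclosed} rays hit protein before leaving the grid.
#' The default, 14, is a strict majority of the sampled sky; it admits bowls
#' and clefts while rejecting flat surfaces (half the sky occluded) and is
#' insensitive to the orientation of the structure relative to the grid
#' axes. Pockets are 26-connected components with at least
#' \code{minVoxels} voxels; sealed interior cavities are detected the same way
#' and are reported with \code{mouthCount == 0}.
#'
#' Measurements per pocket: volume = voxel count x spacing^3; area = exposed
#' boundary-face count x spacing^2 x 0.894 (documented correction for the
#' staircase overestimate of curved surfaces); mouths = 26-connected clusters
#' of pocket voxels face-adjacent (6-adjacency) to bulk solvent, i.e. to
#' probe-accessible space connected to the box boundary; lining atoms = atoms
#' owning a protein voxel face-adjacent to the pocket. Pockets are returned
#' sorted by volume (descending), ties broken by lowest voxel index, so output
#' order is reproducible bit-for-bit at a fixed spacing.
#'
#' @param grid an \linkS4class{OccupancyGrid}.
#' @param smallProbe water-probe radius, Angstrom (default 1.4).
#' @param minEnclosed minimum number of protein-hitting rays, of 26
#'   (default 14, a strict majority).
#' @param minVoxels minimum component size in voxels.
#' @return list of \linkS4class{Pocket} objects (possibly empty).
#' @export
detectPockets <- function(grid, smallProbe = 1.4, minEnclosed = 14L,
                          minVoxels = 30L) {
  stopifnot(is(grid, "OccupancyGrid"))
  if (smallProbe <= 0) stop("smallProbe must be positive")
  if (minEnclosed < 1 || minEnclosed > 26)
    stop("minEnclosed must lie in 1..26")
  dims <- grid@dim
  s <- grid@spacing
  protein <- grid@protein
  free <- !protein

  # probe-centre space: not within (vdw + probe) of any atom
  inflated <- .cppOccupancy(grid@atomXYZ, grid@atomRadius + smallProbe,
                            grid@origin, s, dims)$mask
  allowed <- !inflated
  opened <- .cppDilate(allowed, dims, s, smallProbe) & free
  reach <- .cppFloodBoundary(allowed, dims)
  bulkAll <- .cppDilate(reach, dims, s, smallProbe) & free

  counts <- .cppEnclosure(protein, opened, dims)
  pocketMask <- opened & (counts >= minEnclosed)
  lab <- .cppLabel(pocketMask, dims, 26L)
  if (max(lab) == 0L) return(list())

  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= minVoxels)
  if (length(keep) == 0) return(list())

  bulk <- bulkAll & !pocketMask
  nxy <- dims[1] * dims[2]
  # deterministic ordering: volume (size) desc, then lowest linear voxel index
  firstIdx <- vapply(keep, function(id) match(id, lab), integer(1))
  ord <- keep[order(-sizes[keep], firstIdx)]

  pockets <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    id <- ord[r]
    surf <- .cppComponentSurface(lab, id, protein, bulk, dims)
    vox <- which(lab == id)
    vi <- ((vox - 1L) %% dims[1]) + 1L
    vj <- (((vox - 1L) %/% dims[1]) %% dims[2]) + 1L
    vk <- ((vox - 1L) %/% nxy) + 1L

    nmouth <- 0L
    if (length(surf$mouth) > 0) {
      mm <- logical(length(lab))
      mm[surf$mouth] <- TRUE
      nmouth <- max(.cppLabel(mm, dims, 26L))
    }

    atomIdx <- sort(unique(grid@voxelAtom[surf$lining]))
    atomIdx <- atomIdx[atomIdx > 0]
    lining <- grid@atomTable[atomIdx, , drop = FALSE]
    res <- .residueTable(lining)
    npolar <- if (nrow(res) > 0)
      sum(suppressWarnings(residueIsPolar(res$name))) else 0L

    pockets[[r]] <- new("Pocket",
      id = r,
      voxels = cbind(i = vi, j = vj, k = vk),
      gridOrigin = grid@origin, gridSpacing = s,
      liningAtoms = lining,
      area = surf$faces * s^2 * .AREA_CORRECTION,
      volume = length(vox) * s^3,
      mouthCount = nmouth,
      residues = res,
      polarResidueCount = as.integer(npolar),
      priorityFlags = character(0))
  }
  pockets
}

#' Apply druggability filters to detected pockets
#'
#' Hard-excludes pockets with boundary area below \code{minArea} (default
#' 500 Angstrom^2, the lower-limit pocket size commonly assumed by docking
#' programs) or with fewer than \code{minPolar} polar lining residues (default
#' 2, the modal polar-contact count of marketed oral drugs). Pockets whose
#' mouth count differs from one are retained but tagged
#' \code{"multi_mouth_deprioritized"} and sorted after single-mouth pockets:
#' drug-binding pockets are almost always single-mouthed, so they lose
#' priority rather than being excluded.
#'
#' @param pockets list of \linkS4class{Pocket}.
#' @param minArea minimum boundary area, Angstrom^2.
#' @param minPolar minimum number of polar lining residues.
#' @return filtered, re-prioritized list of \linkS4class{Pocket}.
#' @export
filterPockets <- function(pockets, minArea = 500, minPolar = 2L) {
  if (minArea < 0 || minPolar < 0) stop("thresholds must be >= 0")
  keep <- vapply(pockets, function(p)
    p@area >= minArea && p@polarResidueCount >= minPolar, logical(1))
  pockets <- pockets[keep]
  if (length(pockets) == 0) return(pockets)
  multi <- vapply(pockets, function(p) p@mouthCount != 1L, logical(1))
  pockets <- lapply(pockets, function(p) {
    if (p@mouthCount != 1L &&
        !("multi_mouth_deprioritized" %in% p@priorityFlags))
      p@priorityFlags <- c(p@priorityFlags, "multi_mouth_deprioritized")
    p
  })
  c(pockets[!multi], pockets[multi])
}

#' Tabular report of detected pockets
#'
#' One row per pocket: id, volume, area, mouth count, residue counts and
#' flags. Serializable to JSON for the command-line interface.
#'
#' @param pockets list of \linkS4class{Pocket}.
#' @return data.frame.
#' @export
pocketReport <- function(pockets) {
  if (length(pockets) == 0)
    return(data.frame(id = integer(), volume = numeric(), area = numeric(),
                      mouths = integer(), residues = integer(),
                      polar_residues = integer(), flags = character()))
  data.frame(
    id = vapply(pockets, function(p) p@id, integer(1)),
    volume = vapply(pockets, function(p) p@volume, numeric(1)),
    area = vapply(pockets, function(p) p@area, numeric(1)),
    mouths = vapply(pockets, function(p) p@mouthCount, integer(1)),
    residues = vapply(pockets, function(p) nrow(p@residues), integer(1)),
    polar_residues = vapply(pockets, function(p) p@polarResidueCount,
                            integer(1)),
    flags = vapply(pockets, function(p)
      paste(p@priorityFlags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Lining residues in BED-like tab-delimited form
#'
#' @param pockets list of \linkS4class{Pocket}.
#' @return data.frame with columns chain, seq, name, pocket.
#' @export
liningResidueTable <- function(pockets) {
  if (length(pockets) == 0)
    return(data.frame(chain = character(), seq = integer(),
                      name = character(), pocket = integer()))
  do.call(rbind, lapply(pockets, function(p) {
    if (nrow(p@residues) == 0) return(NULL)
    cbind(p@residues, pocket = p@id)
  }))
}
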