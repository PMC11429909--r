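#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ProteinStructure: atom records of a protein model
#'
#' Container for the atoms of a single protein model. Atoms are stored as a
#' data.frame with one row per atom and the fixed columns \code{serial},
#' \code{atom_name}, \code{residue_name}, \code{chain_id}, \code{residue_seq},
#' \code{x}, \code{y}, \code{z}, \code{element}, \code{occupancy},
#' \code{b_factor}. Residues are recovered by grouping on
#' \code{(chain_id, residue_seq)}.
#'
#' @slot atoms data.frame of atom records (see above).
#' @slot id character(1) identifier for the structure.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", id = "character"),
  validity = function(object) {
    req <- c("serial", "atom_name", "residue_name", "chain_id", "residue_seq",
             "x", "y", "z", "element", "occupancy", "b_factor")
    miss <- setdiff(req, names(object@atoms))
    if (length(miss) > 0)
      return(paste("missing atom columns:", paste(miss, collapse = ", ")))
    if (nrow(object@atoms) == 0)
      return("structure has no atoms")
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      return("non-finite atom coordinates")
    if (any(!nzchar(object@atoms$element)))
      return("empty element symbols after inference")
    key <- paste(object@atoms$chain_id, object@atoms$residue_seq,
                 object@atoms$atom_name)
    if (anyDuplicated(key))
      return("duplicated (chain_id, residue_seq, atom_name) within model")
    TRUE
  })

#' OccupancyGrid: voxelized protein occupancy
#'
#' Regular cubic grid over a protein. Voxel \code{(i, j, k)} (1-based) has its
#' centre at \code{origin + (i-1, j-1, k-1) * spacing}. A voxel is labelled
#' protein iff its centre lies within the van der Waals radius of some atom.
#' The grid retains the atom coordinates and radii so that downstream probe
#' occupancies can be derived at any probe radius, plus a per-voxel map to the
#' nearest covering atom (0 for non-protein voxels).
#'
#' @slot origin numeric(3), Angstrom.
#' @slot spacing numeric(1), Angstrom, > 0.
#' @slot dim integer(3) voxel counts per axis.
#' @slot protein logical array mask (length prod(dim)).
#' @slot voxelAtom integer vector, nearest covering atom per voxel (row index
#'   into the source structure's atoms; 0 outside the protein).
#' @slot atomXYZ numeric matrix n x 3 of atom coordinates.
#' @slot atomRadius numeric vdW radius per atom.
#' @slot atomTable data.frame of the source structure's atom records.
#' @slot structureId character(1) id of the source structure.
#' @export
setClass("OccupancyGrid",
  representation(origin = "numeric", spacing = "numeric", dim = "integer",
                 protein = "logical", voxelAtom = "integer",
                 atomXYZ = "matrix", atomRadius = "numeric",
                 atomTable = "data.frame", structureId = "character"),
  validity = function(object) {
    if (length(object@spacing) != 1 || object@spacing <= 0)
      return("spacing must be a single positive value")
    if (length(object@dim) != 3 || any(object@dim < 1))
      return("dim must be three positive integers")
    if (length(object@protein) != prod(object@dim))
      return("protein mask length does not match grid dimensions")
    if (length(object@voxelAtom) != prod(object@dim))
      return("voxelAtom length does not match grid dimensions")
    TRUE
  })

#' Pocket: a detected surface pocket or interior cavity
#'
#' @slot id integer(1) rank of the pocket (1 = largest by volume).
#' @slot voxels integer matrix n x 3 of 1-based voxel indices in the source grid.
#' @slot gridOrigin numeric(3), Angstrom.
#' @slot gridSpacing numeric(1), Angstrom.
#' @slot liningAtoms data.frame of atom records lining the pocket.
#' @slot area numeric(1), boundary area estimate, Angstrom^2.
#' @slot volume numeric(1), voxel count x spacing^3, Angstrom^3.
#' @slot mouthCount integer(1); 0 denotes a fully enclosed cavity.
#' @slot residues data.frame with columns chain, seq, name.
#' @slot polarResidueCount integer(1).
#' @slot priorityFlags character vector of triage flags.
#' @export
setClass("Pocket",
  representation(id = "integer", voxels = "matrix", gridOrigin = "numeric",
                 gridSpacing = "numeric", liningAtoms = "data.frame",
                 area = "numeric", volume = "numeric", mouthCount = "integer",
                 residues = "data.frame", polarResidueCount = "integer",
                 priorityFlags = "character"),
  validity = function(object) {
    if (object@volume <= 0) return("volume must be positive")
    if (object@area <= 0) return("area must be positive")
    if (object@mouthCount < 0) return("mouthCount must be >= 0")
    if (object@polarResidueCount > nrow(object@residues))
      return("polarResidueCount exceeds number of lining residues")
    TRUE
  })

#' ShapeSignature: pairwise-distance shape descriptor of a pocket
#'
#' The full multiset of pairwise Euclidean distances between a pocket's lining
#' atoms, stored sorted. Rotation- and translation-invariant but size-aware
#' (scaling the pocket changes the signature). A fixed-width histogram is kept
#' for presentation; all comparisons operate on the raw multiset.
#'
#' @slot sourceId character(1).
#' @slot distances sorted numeric vector, length n(n-1)/2.
#' @slot histBreaks numeric bin edges (0.5 Angstrom bins by default).
#' @slot histDensity numeric normalized masses (sums to 1).
#' @export
setClass("ShapeSignature",
  representation(sourceId = "character", distances = "numeric",
                 histBreaks = "numeric", histDensity = "numeric"),
  validity = function(object) {
    if (length(object@distances) < 1) return("empty distance multiset")
    if (any(object@distances < 0)) return("negative distances")
    if (is.unsorted(object@distances)) return("distances must be sorted")
    if (length(object@histDensity) > 0 &&
        abs(sum(object@histDensity) - 1) > 1e-9)
      return("histogram masses must sum to 1")
    TRUE
  })

#' KSResult: two-sample Kolmogorov-Smirnov comparison
#'
#' @slot d numeric(1) supremum ECDF difference in [0, 1].
#' @slot p numeric(1) asymptotic p-value in (0, 1].
#' @slot n1,n2 integer sample sizes.
#' @export
setClass("KSResult",
  representation(d = "numeric", p = "numeric", n1 = "integer", n2 = "integer"),
  validity = function(object) {
    if (object@d < 0 || object@d > 1) return("d must lie in [0, 1]")
    if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
    TRUE
  })

#' AlignmentResult: rigid superposition of two pocket surfaces
#'
#' The rotation/translation map B onto A: \code{x_A ~ R x_B + t}. Optional
#' slots (filled by downstream scoring steps) are NA until populated.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation numeric(3), Angstrom.
#' @slot crmsd numeric(1) >= 0, coordinate RMSD after superposition.
#' @slot ormsd numeric(1) in [0, 2] or NA, orientation-vector RMSD.
#' @slot pEmpirical numeric(1) in (0, 1] or NA, Monte-Carlo significance.
#' @slot gsvot numeric(1) in [0, 1] or NA, volume-overlap Tanimoto.
#' @slot composite numeric(1) in [0, 1] or NA, composite similarity.
#' @export
setClass("AlignmentResult",
  representation(rotation = "matrix", translation = "numeric",
                 crmsd = "numeric", ormsd = "numeric",
                 pEmpirical = "numeric", gsvot = "numeric",
                 composite = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthonormal to 1e-9")
    if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
    if (object@crmsd < 0) return("crmsd must be >= 0")
    TRUE
  })

#' EfficacyTable: compound x cell-line efficacy ratios at one concentration
#'
#' Efficacy ratio = (percent of remaining cancer-cell colonies) /
#' (percent of remaining bone-marrow colonies) at a fixed concentration.
#' Missing entries (cell lines not examined for a compound) are NA and are
#' first-class: they are excluded from activity denominators.
#'
#' @slot concentration numeric(1), micromolar.
#' @slot ratios numeric matrix, rows = cell lines, cols = compounds, NA allowed.
#' @slot siteOf named character, protein site per compound; may cover
#'   compounds absent from \code{ratios} (tested but never active).
#' @export
setClass("EfficacyTable",
  representation(concentration = "numeric", ratios = "matrix",
                 siteOf = "character"),
  validity = function(object) {
    if (!is.numeric(object@ratios)) return("ratios must be numeric")
    if (is.null(rownames(object@ratios)) || is.null(colnames(object@ratios)))
      return("ratios must have cell-line rownames and compound colnames")
    vals <- object@ratios[!is.na(object@ratios)]
    if (any(!is.finite(vals)) || any(vals < 0))
      return("ratios must be finite and >= 0 (or NA)")
    if (!all(colnames(object@ratios) %in% names(object@siteOf)))
      return("siteOf must cover every compound in ratios")
    TRUE
  })

#' DoseResponseFit: four-parameter logistic dose-response fit
#'
#' Model: response = bottom + (top - bottom) /
#'   (1 + 10^((logIC50 - log10(dose)) * hill)).
#' With responses in percent of control, inhibition corresponds to a negative
#' Hill slope.
#'
#' @slot bottom,top numeric(1), percent of control.
#' @slot logIC50 numeric(1), log10 micromolar.
#' @slot hill numeric(1) slope.
#' @slot ic50 numeric(1), micromolar, 10^logIC50.
#' @slot convergence list of solver diagnostics.
#' @export
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", logIC50 = "numeric",
                 hill = "numeric", ic50 = "numeric", convergence = "list"),
  validity = function(object) {
    if (object@bottom > object@top) return("bottom must be <= top")
    if (object@ic50 <= 0) return("ic50 must be positive")
    if (abs(object@ic50 - 10^object@logIC50) > 1e-8 * object@ic50)
      return("ic50 must equal 10^logIC50")
    TRUE
  })
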