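#' Accessor generics
#'
#' Small accessor layer so downstream code never reaches into slots.
#'
#' @param x an object of one of the PocketScreen S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("pocketArea", function(x) standardGeneric("pocketArea"))
#' @rdname accessors
#' @export
setGeneric("pocketVolume", function(x) standardGeneric("pocketVolume"))
#' @rdname accessors
#' @export
setGeneric("mouthCount", function(x) standardGeneric("mouthCount"))
#' @rdname accessors
#' @export
setGeneric("liningAtoms", function(x) standardGeneric("liningAtoms"))
#' @rdname accessors
#' @export
setGeneric("liningResidues", function(x) standardGeneric("liningResidues"))
#' @rdname accessors
#' @export
setGeneric("polarResidueCount", function(x) standardGeneric("polarResidueCount"))
#' @rdname accessors
#' @export
setGeneric("priorityFlags", function(x) standardGeneric("priorityFlags"))
#' @rdname accessors
#' @export
setGeneric("signatureDistances", function(x) standardGeneric("signatureDistances"))
#' @rdname accessors
#' @export
setGeneric("ksD", function(x) standardGeneric("ksD"))
#' @rdname accessors
#' @export
setGeneric("ksP", function(x) standardGeneric("ksP"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("crmsd", function(x) standardGeneric("crmsd"))
#' @rdname accessors
#' @export
setGeneric("efficacyRatios", function(x) standardGeneric("efficacyRatios"))
#' @rdname accessors
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))
#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setGeneric("hillSlope", function(x) standardGeneric("hillSlope"))

setMethod("atoms", "ProteinStructure", function(x) x@atoms)
setMethod("structureId", "ProteinStructure", function(x) x@id)
setMethod("pocketArea", "Pocket", function(x) x@area)
setMethod("pocketVolume", "Pocket", function(x) x@volume)
setMethod("mouthCount", "Pocket", function(x) x@mouthCount)
setMethod("liningAtoms", "Pocket", function(x) x@liningAtoms)
setMethod("liningResidues", "Pocket", function(x) x@residues)
setMethod("polarResidueCount", "Pocket", function(x) x@polarResidueCount)
setMethod("priorityFlags", "Pocket", function(x) x@priorityFlags)
setMethod("signatureDistances", "ShapeSignature", function(x) x@distances)
setMethod("structureId", "ShapeSignature", function(x) x@sourceId)
setMethod("ksD", "KSResult", function(x) x@d)
setMethod("ksP", "KSResult", function(x) x@p)
setMethod("rotation", "AlignmentResult", function(x) x@rotation)
setMethod("translation", "AlignmentResult", function(x) x@translation)
setMethod("crmsd", "AlignmentResult", function(x) x@crmsd)
setMethod("efficacyRatios", "EfficacyTable", function(x) x@ratios)
setMethod("siteOf", "EfficacyTable", function(x) x@siteOf)
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)
setMethod("hillSlope", "DoseResponseFit", function(x) x@hill)

setMethod("show", "ProteinStructure", function(object) {
  res <- unique(paste(object@atoms$chain_id, object@atoms$residue_seq))
  cat("ProteinStructure '", object@id, "': ", nrow(object@atoms),
      " atoms, ", length(res), " residues, ",
      length(unique(object@atoms$chain_id)), " chain(s)\n", sep = "")
})

setMethod("show", "OccupancyGrid", function(object) {
  cat("OccupancyGrid ", paste(object@dim, collapse = " x "),
      " voxels @ ", object@spacing, " A (",
      sum(object@protein), " protein voxels)\n", sep = "")
})

setMethod("show", "Pocket", function(object) {
  cat(sprintf(
    "Pocket %d: volume %.1f A^3, area %.1f A^2, %d mouth(s), %d residues (%d polar)%s\n",
    object@id, object@volume, object@area, object@mouthCount,
    nrow(object@residues), object@polarResidueCount,
    if (length(object@priorityFlags))
      paste0(" [", paste(object@priorityFlags, collapse = ","), "]") else ""))
})

setMethod("show", "ShapeSignature", function(object) {
  cat("ShapeSignature '", object@sourceId, "': ",
      length(object@distances), " pairwise distances, range [",
      sprintf("%.2f", min(object@distances)), ", ",
      sprintf("%.2f", max(object@distances)), "] A\n", sep = "")
})

setMethod("show", "KSResult", function(object) {
  cat(sprintf("KS comparison: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              object@d, object@p, object@n1, object@n2))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: cRMSD %.4f A", object@crmsd))
  if (!is.na(object@ormsd)) cat(sprintf(", oRMSD %.4f", object@ormsd))
  if (!is.na(object@pEmpirical)) cat(sprintf(", p %.4g", object@pEmpirical))
  if (!is.na(object@gsvot)) cat(sprintf(", gSVOT %.4f", object@gsvot))
  if (!is.na(object@composite)) cat(sprintf(", composite %.4f", object@composite))
  cat("\n")
})

setMethod("show", "EfficacyTable", function(object) {
  cat(sprintf("EfficacyTable at %g uM: %d cell lines x %d compounds (%d missing entries)\n",
              object@concentration, nrow(object@ratios), ncol(object@ratios),
              sum(is.na(object@ratios))))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "4PL fit: IC50 %.4g uM, hill %.3f, bottom %.1f%%, top %.1f%% (%s)\n",
    object@ic50, object@hill, object@bottom, object@top,
    if (isTRUE(object@convergence$converged)) "converged" else "NOT converged"))
})
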