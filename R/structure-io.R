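#' Read a protein structure from a PDB file
#'
#' Parses fixed-width ATOM/HETATM records (wwPDB v3.3 layout) into a
#' \linkS4class{ProteinStructure}. Only the first model of multi-model files
#' is read. HETATM records and waters are excluded unless
#' \code{includeHetatm = TRUE}. Alternate locations are resolved per
#' (chain, residue, atom name) by keeping the highest-occupancy record, first
#' encountered on ties. Elements are taken from columns 77-78 when present,
#' otherwise inferred from the atom name. Coordinates are kept in the file's
#' frame; no re-centering occurs at parse time.
#'
#' @param path path to a PDB file.
#' @param includeHetatm logical; also keep non-water HETATM records and waters.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(paste0(
#'   "ATOM      1  CA  SER A   1       1.000   2.000   3.000",
#'   "  1.00  0.00           C"), pdb)
#' readStructure(pdb)
#' @export
readStructure <- function(path, includeHetatm = FALSE) {
  if (!file.exists(path))
    stop("cannot read structure: file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  water <- c("HOH", "WAT", "DOD")
  keep <- if (includeHetatm) rep(TRUE, nrow(at))
          else at$type == "ATOM" & !(at$resid %in% water)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop("empty structure: no ATOM records after filtering in '", path, "'")

  elem <- at$elesy
  elem[is.na(elem)] <- ""
  elem <- toupper(trimws(elem))
  need <- !nzchar(elem)
  if (any(need))
    elem[need] <- toupper(suppressWarnings(
      bio3d::atom2ele(at$elety[need], rescue = TRUE)))

  occ <- at$o
  occ[is.na(occ)] <- 1
  # altloc: keep the highest-occupancy record per (chain, resno, atom name);
  # ties resolved by file order
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(at)))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]
  occ <- occ[sel]

  bfac <- at$b
  bfac[is.na(bfac)] <- 0
  chain <- at$chain
  chain[is.na(chain)] <- " "
  df <- data.frame(
    serial = at$eleno,
    atom_name = at$elety,
    residue_name = at$resid,
    chain_id = chain,
    residue_seq = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = elem,
    occupancy = occ,
    b_factor = bfac,
    stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = df,
      id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
}

#' Write a protein structure to a PDB file
#'
#' Emits fixed-width ATOM records (three-decimal coordinates); round-tripping
#' through \code{writeStructure}/\code{readStructure} preserves coordinates to
#' three decimals.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   eleno = a$serial, elety = a$atom_name,
                   resid = a$residue_name, chain = a$chain_id,
                   resno = a$residue_seq, o = a$occupancy, b = a$b_factor,
                   elesy = a$element)
  invisible(path)
}

# The 12 residues treated as polar: charged (ARG LYS HIS ASP GLU), polar
# uncharged (SER THR ASN GLN), plus TYR, CYS and TRP, whose side chains carry
# hydrogen-bonding heteroatoms. Fixed and documented; override via `polarSet`.
.POLAR_RESIDUES <- c("ARG", "LYS", "HIS", "ASP", "GLU", "SER", "THR",
                     "ASN", "GLN", "TYR", "CYS", "TRP")

.STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Is a residue polar?
#'
#' Membership of the three-letter residue name in the documented polar set
#' (charged + polar-uncharged + TYR/CYS/TRP; 12 of the 20 standard residues).
#'
#' @param residueName character vector of 3-letter residue names.
#' @param strict logical; if TRUE, a non-standard name is an error. If FALSE
#'   (lenient, the default), it yields FALSE with a warning.
#' @param polarSet character vector overriding the default polar set.
#' @return logical vector.
#' @examples
#' residueIsPolar("SER")  # TRUE
#' residueIsPolar("LEU")  # FALSE
#' @export
residueIsPolar <- function(residueName, strict = FALSE,
                           polarSet = .POLAR_RESIDUES) {
  residueName <- toupper(residueName)
  bad <- !(residueName %in% .STANDARD_RESIDUES)
  if (any(bad)) {
    if (strict)
      stop("non-standard residue name(s): ",
           paste(unique(residueName[bad]), collapse = ", "))
    warning("non-standard residue name(s) treated as non-polar: ",
            paste(unique(residueName[bad]), collapse = ", "))
  }
  residueName %in% polarSet
}

# Bondi van der Waals radii (Angstrom) for the elements commonly present in
# protein structures and ligands.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27,
                K = 2.75, MN = 2.00)

#' Van der Waals radius of an element
#'
#' Bondi-table lookup. Unknown elements fall back to a configurable default
#' (1.7 Angstrom, the carbon radius) with a warning.
#'
#' @param element character vector of element symbols.
#' @param default numeric(1) radius for unknown elements.
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdwRadius(c("C", "N", "O"))
#' @export
vdwRadius <- function(element, default = 1.7) {
  element <- toupper(trimws(element))
  r <- unname(.VDW_RADII[element])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) assigned default radius ", default, " A: ",
            paste(unique(element[unknown]), collapse = ", "))
    r[unknown] <- default
  }
  r
}

# internal: split atoms into residues, preserving first-seen order
.residueTable <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_seq, sep = "|")
  idx <- !duplicated(key)
  data.frame(chain = atoms$chain_id[idx], seq = atoms$residue_seq[idx],
             name = atoms$residue_name[idx], stringsAsFactors = FALSE)
}
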