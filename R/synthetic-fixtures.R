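# Seeded fixture generators. Every generator derives a child seed from the
# single global seed so fixture families are reproducible as a set, runs its
# draws under that seed, and restores the caller's RNG state afterwards. All
# ground-truth quantities in the manifests are computed by generator-side
# code paths (analytic formulas, inline predicates, exhaustive cuts), never
# by calling the module they are meant to test.

.childSeed <- function(seed, generator) {
  offsets <- c(pocket_structure = 101L, compound_table = 211L,
               colony_data = 307L, score_tables = 401L)
  off <- offsets[[generator]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rad <- sqrt(pmax(0, 1 - z^2))
  cbind(rad * cos(phi), rad * sin(phi), z)
}

#' Synthetic pocket-bearing structure
#'
#' Builds a slab of pseudo-atoms (carbon, 1.7 Angstrom radius, cubic lattice)
#' with a hemispherical cavity of the requested radius opening upward. The
#' cavity wall is lined with a dense quasi-uniform shell of atoms whose
#' centres sit exactly \code{cavityRadius + 1.7} Angstrom from the cavity
#' centre, so the free cavity matches the analytic hemisphere closely (a
#' carved cubic lattice alone leaves wall bumps worth roughly 10 percent
#' extra volume). With \code{sealed = TRUE} the lattice continues above the
#' cavity and the shell is a full sphere, burying the cavity completely: same
#' centre and radius, no mouth. Each atom is its own single-atom residue;
#' residue names are drawn from the 20 standard residues under the derived
#' seed and recorded in the manifest, so polar-residue counts are well
#' defined.
#'
#' @param cavityRadius cavity radius, Angstrom, in [3, 10].
#' @param sealed logical; bury the cavity instead of opening it upward.
#' @param seed global fixture seed.
#' @param dir output directory (created if needed).
#' @return list with \code{pdb} (file path), \code{structure}
#'   (\linkS4class{ProteinStructure}) and \code{manifest}; the manifest's
#'   ground truth holds the analytic volume (\code{(2/3) pi r^3} open,
#'   \code{(4/3) pi r^3} sealed), the mouth count (1, or 0 if sealed) and the
#'   per-atom residue names.
#' @export
makePocketStructure <- function(cavityRadius, sealed = FALSE, seed = 1L,
                                dir = tempdir()) {
  if (cavityRadius < 3 || cavityRadius > 10)
    stop("cavityRadius must lie in [3, 10] Angstrom")
  pitch <- 1.5; rAtom <- 1.7
  rShell <- cavityRadius + rAtom
  halfW <- cavityRadius + 7
  depth <- cavityRadius + 4.5
  g <- seq(-halfW, halfW, by = pitch)
  gz <- if (sealed) seq(-depth, depth + 2 * rAtom, by = pitch)
        else seq(-depth, -pitch, by = pitch)
  slab <- as.matrix(expand.grid(x = g, y = g, z = gz))
  if (!sealed) {
    # dense surface layer so the wall band just under the mouth plane has no
    # gaps a grid scan line can slip through
    gf <- seq(-halfW, halfW, by = pitch / 2)
    slab <- rbind(slab, as.matrix(expand.grid(x = gf, y = gf, z = 0)))
  }
  surfaceZ <- rAtom             # protein surface plane (top layer at z = 0)
  centre <- c(0, 0, surfaceZ)   # cavity centre sits on the surface plane
  d2 <- (slab[, 1] - centre[1])^2 + (slab[, 2] - centre[2])^2 +
    (slab[, 3] - centre[3])^2
  slab <- slab[d2 >= rShell^2, , drop = FALSE]
  # smooth shell lining the cavity wall (about one atom per 0.7 A^2)
  shell <- .fibonacciSphere(ceiling(4 * pi * rShell^2 / 0.7)) * rShell
  shell <- sweep(shell, 2, centre, `+`)
  # open bowl: no shell atom may rise above the surface plane, or the ring
  # would form a crater above the mouth that reads as extra pocket volume
  if (!sealed) shell <- shell[shell[, 3] <= surfaceZ - rAtom, , drop = FALSE]
  slab <- rbind(slab, shell)
  n <- nrow(slab)
  resNames <- .withSeed(.childSeed(seed, "pocket_structure"),
                        sample(.STANDARD_RESIDUES, n, replace = TRUE))
  atomsDf <- data.frame(
    serial = seq_len(n), atom_name = "CA", residue_name = resNames,
    chain_id = "A", residue_seq = seq_len(n),
    x = slab[, 1], y = slab[, 2], z = slab[, 3],
    element = "C", occupancy = 1, b_factor = 0,
    stringsAsFactors = FALSE)
  id <- sprintf("slab_r%.1f_%s_seed%d", cavityRadius,
                if (sealed) "sealed" else "open", seed)
  structure <- new("ProteinStructure", atoms = atomsDf, id = id)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdbPath <- file.path(dir, paste0(id, ".pdb"))
  writeStructure(structure, pdbPath)
  manifest <- list(
    generator = "pocket_structure", seed = seed,
    parameters = list(cavity_radius = cavityRadius, sealed = sealed,
                      lattice_pitch = pitch, atom_radius = rAtom,
                      cavity_centre = centre),
    ground_truth = list(
      analytic_volume = (if (sealed) 4 else 2) / 3 * pi * cavityRadius^3,
      mouth_count = if (sealed) 0L else 1L,
      n_atoms = n,
      residue_names = resNames))
  manifestPath <- file.path(dir, paste0(id, ".manifest.json"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  list(pdb = pdbPath, structure = structure, manifest = manifest,
       manifestPath = manifestPath)
}

#' Synthetic compound property table
#'
#' Properties are drawn from documented uniform/discrete distributions chosen
#' to straddle all four drug-likeness thresholds: MW ~ U(100, 550) g/mol,
#' TPSA ~ U(50, 180) Angstrom^2, HBD ~ uniform on 0..7, HBA ~ uniform on
#' 0..13. The manifest records the exact survivor set of the default
#' drug-likeness window, computed by an inline predicate at generation time.
#'
#' @param n number of compounds.
#' @param seed global fixture seed.
#' @param dir output directory, or NULL to skip writing.
#' @return list with \code{records} (data.frame), optional \code{csv} path,
#'   and \code{manifest}.
#' @export
makeCompoundTable <- function(n, seed = 1L, dir = NULL) {
  if (n < 1) stop("n must be >= 1")
  records <- .withSeed(.childSeed(seed, "compound_table"), {
    data.frame(
      compound_id = sprintf("CMP-%05d", seq_len(n)),
      smiles = "C",
      mw = stats::runif(n, 100, 550),
      tpsa = stats::runif(n, 50, 180),
      hbd = sample(0:7, n, replace = TRUE),
      hba = sample(0:13, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  # independent predicate (not the filter module)
  surv <- records$mw >= 160 & records$mw <= 480 & records$tpsa < 140 &
    records$hbd < 5 & records$hba < 10
  manifest <- list(
    generator = "compound_table", seed = seed,
    parameters = list(n = n),
    ground_truth = list(n_survivors = sum(surv),
                        survivor_ids = records$compound_id[surv]))
  csv <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- file.path(dir, sprintf("compounds_n%d_seed%d.csv", n, seed))
    utils::write.csv(records, csv, row.names = FALSE)
    jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", csv),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = records, csv = csv, manifest = manifest)
}

#' Synthetic colony-formation assay data with known dose-response truth
#'
#' Expected colony counts follow a four-parameter logistic curve (evaluated
#' by an inline copy of the formula) scaled by a control mean; multiplicative
#' lognormal noise with unit mean and the requested coefficient of variation
#' is applied before rounding to integer counts. The default dose grid is the
#' nine-point screening series 0.0061 to 40 micromolar plus the vehicle
#' control; zero-dose rows are present for every cell line.
#'
#' @param params list with \code{bottom}, \code{top} (percent), \code{ic50}
#'   (micromolar), \code{hill}.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates replicate wells per dose.
#' @param seed global fixture seed.
#' @param doses dose grid, micromolar (0 = vehicle control).
#' @param controlMean expected control colony count.
#' @param cellLine,compound,day labels for the generated records.
#' @param dir output directory, or NULL to skip writing.
#' @return list with \code{assays} (data.frame in assay CSV layout), optional
#'   \code{csv} path, and \code{manifest} recording the generating truth.
#' @export
makeColonyData <- function(params = list(bottom = 0, top = 100,
                                         ic50 = 0.012, hill = -1),
                           cv = 0.1, replicates = 2L, seed = 1L,
                           doses = c(0, 0.0061, 0.018, 0.05, 0.16, 0.49,
                                     1.48, 4.44, 13.33, 40),
                           controlMean = 250, cellLine = "CELL-1",
                           compound = "CMP-001", day = 8L, dir = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  resp <- vapply(doses, function(d) {
    if (d == 0) return(100)
    # inline 4PL (independent of the fitting module)
    params$bottom + (params$top - params$bottom) /
      (1 + 10^((log10(params$ic50) - log10(d)) * params$hill))
  }, numeric(1))
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_uM = doses)
  mu <- controlMean * resp[match(grid$concentration_uM, doses)] / 100
  counts <- .withSeed(.childSeed(seed, "colony_data"), {
    if (cv == 0) mu else {
      sdlog <- sqrt(log(1 + cv^2))
      mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  })
  assays <- data.frame(
    cell_line = cellLine, compound = compound,
    concentration_uM = grid$concentration_uM, day = day,
    replicate = grid$replicate, colonies = as.integer(round(counts)),
    stringsAsFactors = FALSE)
  manifest <- list(
    generator = "colony_data", seed = seed,
    parameters = list(cv = cv, replicates = replicates,
                      control_mean = controlMean, doses = doses),
    ground_truth = params)
  csv <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- file.path(dir, sprintf("colonies_seed%d.csv", seed))
    utils::write.csv(assays, csv, row.names = FALSE)
    jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", csv),
                         auto_unbox = TRUE, digits = NA)
  }
  list(assays = assays, csv = csv, manifest = manifest)
}

#' Synthetic multi-stage docking score tables
#'
#' Scores share a planted latent affinity (so stages are correlated, as real
#' rescoring stages are) plus independent noise; lower is better. The first
#' stage has two method tables (two docking programs run in tandem); later
#' stages have one each. The manifest records the survivors of every stage of
#' the accompanying funnel specification, computed by an exhaustive
#' generator-side composition of cuts.
#'
#' @param nCompounds number of compounds.
#' @param stages total number of stages (>= 1).
#' @param seed global fixture seed.
#' @param keepCounts integer vector of per-stage keep counts (recycled);
#'   default keeps a quarter, an eighth, ... of the library.
#' @param finalK final list length.
#' @param dir output directory, or NULL to skip writing.
#' @return list with \code{stageTables} (ready for \code{\link{runFunnel}}),
#'   \code{spec} (a \code{\link{funnelSpec}}), optional \code{csv} paths and
#'   \code{manifest}.
#' @export
makeScoreTables <- function(nCompounds, stages = 3L, seed = 1L,
                            keepCounts = NULL, finalK = 100L, dir = NULL) {
  if (stages < 1) stop("stages must be >= 1")
  if (is.null(keepCounts))
    keepCounts <- pmax(1L, ceiling(nCompounds / 2^(1 + seq_len(stages))))
  keepCounts <- rep_len(as.integer(keepCounts), stages)
  ids <- sprintf("CMP-%05d", seq_len(nCompounds))
  tabs <- .withSeed(.childSeed(seed, "score_tables"), {
    latent <- stats::rnorm(nCompounds)
    mk <- function() {
      v <- latent + stats::rnorm(nCompounds, sd = 0.5)
      names(v) <- ids
      v
    }
    c(list(list(mk(), mk())), lapply(seq_len(stages - 1), function(i) mk()))
  })
  stageDefs <- lapply(seq_len(stages), function(i)
    list(name = paste0("stage", i), keepCount = keepCounts[i]))
  spec <- funnelSpec(stageDefs, finalK = finalK)
  # exhaustive generator-side composition of cuts (independent of runFunnel)
  topN <- function(v, n) {
    ord <- names(v)[order(v, names(v))]
    ord[seq_len(min(n, length(ord)))]
  }
  survivors <- list()
  cur <- NULL
  for (i in seq_len(stages)) {
    tt <- if (i == 1) tabs[[1]] else list(tabs[[i]])
    sv <- character(0)
    for (v in tt) {
      if (!is.null(cur)) v <- v[names(v) %in% cur]
      sv <- union(sv, topN(v, keepCounts[i]))
    }
    survivors[[i]] <- sort(sv)
    cur <- sv
  }
  manifest <- list(
    generator = "score_tables", seed = seed,
    parameters = list(n_compounds = nCompounds, stages = stages,
                      keep_counts = keepCounts, final_k = finalK),
    ground_truth = list(survivors = survivors))
  csv <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- character(0)
    flat <- c(list(tabs[[1]][[1]], tabs[[1]][[2]]),
              if (stages > 1) tabs[2:stages] else list())
    nm <- c("stage1a", "stage1b",
            if (stages > 1) paste0("stage", 2:stages) else character(0))
    for (i in seq_along(flat)) {
      p <- file.path(dir, sprintf("scores_%s_seed%d.csv", nm[i], seed))
      utils::write.csv(data.frame(compound_id = names(flat[[i]]),
                                  score = unname(flat[[i]])),
                       p, row.names = FALSE)
      csv <- c(csv, p)
    }
    jsonlite::write_json(manifest,
                         file.path(dir, sprintf("scores_seed%d.manifest.json",
                                                seed)),
                         auto_unbox = TRUE, digits = NA)
  }
  list(stageTables = tabs, spec = spec, csv = csv, manifest = manifest)
}
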