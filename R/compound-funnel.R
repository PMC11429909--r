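#' Drug-likeness pre-filter for compound libraries
#'
#' Keeps compounds inside the oral drug-likeness window used before virtual
#' screening: molecular weight between 160 and 480 g/mol (bounds inclusive),
#' topological polar surface area strictly below 140 Angstrom^2, and strictly
#' fewer than 5 hydrogen-bond donors and 10 acceptors. Every rejected record
#' carries the full list of reasons; records with missing properties are
#' rejected with reason \code{"missing_property"}. All four thresholds are
#' overridable.
#'
#' @param records data.frame with columns \code{compound_id}, \code{mw},
#'   \code{tpsa}, \code{hbd}, \code{hba} (an optional \code{smiles} column is
#'   passed through untouched).
#' @param mwRange numeric(2) inclusive molecular-weight window, g/mol.
#' @param tpsaMax exclusive TPSA upper bound, Angstrom^2.
#' @param hbdMax,hbaMax exclusive donor/acceptor upper bounds.
#' @return list with \code{kept} (data.frame) and \code{rejected} (data.frame
#'   with a \code{reasons} column, ";"-separated).
#' @examples
#' recs <- data.frame(compound_id = c("a", "b"),
#'                    mw = c(100, 300), tpsa = c(50, 80),
#'                    hbd = c(1, 2), hba = c(2, 4))
#' druglikeFilter(recs)$rejected$reasons  # "mw_out_of_range"
#' @export
druglikeFilter <- function(records, mwRange = c(160, 480), tpsaMax = 140,
                           hbdMax = 5L, hbaMax = 10L) {
  req <- c("compound_id", "mw", "tpsa", "hbd", "hba")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("records must be non-empty")
  reasons <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    why <- character(0)
    vals <- c(r$mw, r$tpsa, r$hbd, r$hba)
    if (any(is.na(vals))) {
      why <- "missing_property"
    } else {
      if (r$mw < mwRange[1] || r$mw > mwRange[2]) why <- c(why, "mw_out_of_range")
      if (r$tpsa >= tpsaMax) why <- c(why, "tpsa_too_high")
      if (r$hbd >= hbdMax) why <- c(why, "too_many_hbd")
      if (r$hba >= hbaMax) why <- c(why, "too_many_hba")
    }
    reasons[[i]] <- why
  }
  ok <- lengths(reasons) == 0
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0)
    rejected$reasons <- vapply(reasons[!ok], paste, character(1),
                               collapse = ";")
  else rejected$reasons <- character(0)
  rownames(rejected) <- NULL
  kept <- records[ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Dense ranks of compounds within one scoring stage
#'
#' Raw docking and rescoring values are treated as relative to the dataset for
#' a target: only rank positions propagate between stages. Ranks are dense
#' (best score = rank 1, ties share a rank); the cut order within a tied rank
#' is lexicographic by compound id, so propagation cuts are deterministic.
#'
#' @param scores named numeric vector (names = compound ids) or data.frame
#'   with columns \code{compound_id}, \code{score}. Lower scores are better;
#'   set \code{lowerIsBetter = FALSE} otherwise.
#' @param lowerIsBetter logical.
#' @return named integer vector of dense ranks.
#' @examples
#' rankWithinStage(c(a = -9.1, b = -7.0, c = -9.1))  # a=1, c=1, b=2
#' @export
rankWithinStage <- function(scores, lowerIsBetter = TRUE) {
  if (is.data.frame(scores)) {
    s <- scores$score
    names(s) <- scores$compound_id
    scores <- s
  }
  if (length(scores) == 0) stop("empty score table")
  if (anyDuplicated(names(scores)))
    stop("duplicate compound ids within a stage")
  v <- if (lowerIsBetter) scores else -scores
  ranks <- match(v, sort(unique(v)))
  names(ranks) <- names(scores)
  ranks
}

# order compounds for a propagation cut: by rank, ties lexicographic by id
.cutOrder <- function(ranks) {
  names(ranks)[order(ranks, names(ranks))]
}

#' Build a funnel specification
#'
#' @param stages list of stage descriptors, each a list with \code{name} and
#'   either \code{keepCount} or \code{keepFraction} (fraction of the
#'   candidates entering the stage, cut by \code{ceiling}).
#' @param finalK length of the final ranked list (default 100).
#' @return object of class \code{FunnelSpec}.
#' @export
funnelSpec <- function(stages, finalK = 100L) {
  for (st in stages) {
    if (is.null(st$name)) stop("every stage needs a name")
    kc <- st$keepCount; kf <- st$keepFraction
    if (is.null(kc) && is.null(kf))
      stop("stage '", st$name, "' needs keepCount or keepFraction")
    if (!is.null(kc) && kc < 1) stop("keepCount must be positive")
    if (!is.null(kf) && (kf <= 0 || kf > 1))
      stop("keepFraction must lie in (0, 1]")
  }
  if (finalK < 1) stop("finalK must be >= 1")
  structure(list(stages = stages, finalK = as.integer(finalK)),
            class = "FunnelSpec")
}

#' Run the staged virtual-screening rank funnel
#'
#' Stage 1 may consist of several score tables (one per docking method run in
#' tandem); its survivors are the union of the per-method top cuts. Each later
#' stage re-ranks the compounds surviving the previous stage by its own scores
#' and keeps its top \code{keepCount} (or \code{ceiling(keepFraction x
#' candidates)}). Compounds missing a score in a later stage are dropped with
#' a logged reason (rescoring operates on the top poses, which implies
#' presence). The final ranking is the last stage's rank order, truncated to
#' \code{finalK}.
#'
#' @param stageTables list; element i corresponds to spec stage i and is
#'   either one score table (named numeric vector or data.frame with
#'   \code{compound_id}, \code{score}) or, for the first stage, a list of
#'   such tables.
#' @param spec a \code{\link{funnelSpec}}.
#' @return character vector of compound ids in final rank order (length <=
#'   \code{finalK}), with attribute \code{"dropped"} naming compounds lost to
#'   missing later-stage scores.
#' @export
runFunnel <- function(stageTables, spec) {
  stopifnot(inherits(spec, "FunnelSpec"))
  if (length(stageTables) != length(spec$stages))
    stop("stageTables must match the spec: expected ",
         length(spec$stages), " stages, got ", length(stageTables))
  asVec <- function(tab) {
    if (is.data.frame(tab)) {
      v <- tab$score; names(v) <- tab$compound_id; v
    } else tab
  }
  dropped <- character(0)
  survivors <- NULL
  lastOrder <- NULL
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    tabs <- stageTables[[i]]
    if (!is.list(tabs) || is.data.frame(tabs)) tabs <- list(tabs)
    if (i > 1 && length(tabs) > 1)
      stop("only the first stage may have multiple method tables")
    stageSurv <- character(0)
    for (tab in tabs) {
      v <- asVec(tab)
      if (!is.null(survivors)) {
        lost <- setdiff(survivors, names(v))
        if (length(lost) > 0) {
          message("stage '", st$name, "': dropped ", length(lost),
                  " compound(s) with no score: ",
                  paste(sort(lost), collapse = ", "))
          dropped <- union(dropped, lost)
        }
        v <- v[names(v) %in% survivors]
      }
      if (length(v) == 0) stop("stage '", st$name, "' has no candidates")
      ranks <- rankWithinStage(v)
      n <- if (!is.null(st$keepCount)) st$keepCount
           else ceiling(st$keepFraction * length(v))
      ord <- .cutOrder(ranks)
      cut <- ord[seq_len(min(n, length(ord)))]
      stageSurv <- union(stageSurv, cut)
      lastOrder <- ord
    }
    survivors <- stageSurv
  }
  final <- lastOrder[lastOrder %in% survivors]
  final <- final[seq_len(min(spec$finalK, length(final)))]
  attr(final, "dropped") <- dropped
  final
}

#' Read a compound property or score table from delimited text
#'
#' Comma- or tab-delimited with a header row; the delimiter is sniffed from
#' the header line. SMILES strings, when present, are carried through as
#' opaque identifiers.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCompoundTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}
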