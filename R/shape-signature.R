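#' Compute the shape signature of a pocket
#'
#' The signature is the full multiset of pairwise Euclidean distances between
#' the pocket's lining atoms, modelling the pocket's global shape as a
#' distance distribution. It is invariant under rigid motions but sensitive to
#' size, so pockets of similar shape and different volume are distinguished.
#' A histogram with fixed-width bins (0.5 Angstrom by default) over
#' [0, max + bin] is attached for presentation; comparisons always use the raw
#' multiset.
#'
#' @param x a \linkS4class{Pocket}, or a numeric matrix (n x 3) of
#'   coordinates.
#' @param sourceId identifier recorded in the signature (defaults to the
#'   pocket id).
#' @param binWidth histogram bin width in Angstrom.
#' @return a \linkS4class{ShapeSignature}.
#' @examples
#' computeSignature(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
#' @export
computeSignature <- function(x, sourceId = NULL, binWidth = 0.5) {
  if (is(x, "Pocket")) {
    coords <- as.matrix(x@liningAtoms[, c("x", "y", "z")])
    if (is.null(sourceId)) sourceId <- paste0("pocket_", x@id)
  } else {
    coords <- as.matrix(x)
    if (is.null(sourceId)) sourceId <- "coords"
  }
  if (nrow(coords) < 3)
    stop("a shape signature needs at least 3 lining atoms, got ",
         nrow(coords))
  d <- sort(as.vector(stats::dist(coords)))
  breaks <- seq(0, (floor(max(d) / binWidth) + 1) * binWidth, by = binWidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  new("ShapeSignature", sourceId = as.character(sourceId), distances = d,
      histBreaks = breaks, histDensity = h$counts / length(d))
}

# Asymptotic two-sided Kolmogorov distribution tail:
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
.kolmogorovQ <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(100)
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, .Machine$double.xmin), 1)
}

#' Compare two shape signatures with the two-sample Kolmogorov-Smirnov test
#'
#' The statistic D is the exact supremum of |ECDF_a - ECDF_b| over the pooled
#' sample points of the raw distance multisets (histograms are never used).
#' The p-value is asymptotic, from the Kolmogorov distribution evaluated at
#' sqrt(n_eff) * D with n_eff = n1 n2 / (n1 + n2); it is approximate for
#' n_eff < 35.
#'
#' @param a,b \linkS4class{ShapeSignature} objects (or raw numeric multisets).
#' @return a \linkS4class{KSResult}.
#' @examples
#' s1 <- computeSignature(matrix(rnorm(30), ncol = 3), "a")
#' ksCompare(s1, s1)  # D = 0, p = 1
#' @export
ksCompare <- function(a, b) {
  da <- if (is(a, "ShapeSignature")) a@distances else sort(as.numeric(a))
  db <- if (is(b, "ShapeSignature")) b@distances else sort(as.numeric(b))
  n1 <- length(da); n2 <- length(db)
  if (n1 == 0 || n2 == 0) stop("empty distance multiset")
  # exact sup |ECDF_a - ECDF_b| evaluated at every pooled sample point
  pooled <- sort(unique(c(da, db)))
  Fa <- findInterval(pooled, da) / n1
  Fb <- findInterval(pooled, db) / n2
  d <- max(abs(Fa - Fb))
  neff <- n1 * n2 / (n1 + n2)
  p <- if (d == 0) 1 else .kolmogorovQ(sqrt(neff) * d)
  new("KSResult", d = d, p = p, n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Rank a signature library against a query
#'
#' Compares the query against every library member, GPSS-style, and returns
#' the top \code{k} ordered by ascending D, ties broken by descending p and
#' then lexicographic source id. Members with D below
#' \code{similarityThreshold} (default 0.25, a documented toolkit decision:
#' the threshold at which two pockets are flagged as candidate binders of
#' similar ligands) are marked \code{candidate}.
#'
#' @param query a \linkS4class{ShapeSignature}.
#' @param library non-empty list of \linkS4class{ShapeSignature}.
#' @param k number of hits to return; clamped to the library size with a
#'   warning when larger.
#' @param similarityThreshold D value below which a hit is flagged candidate.
#' @return data.frame with columns source_id, d, p, n1, n2, candidate, in
#'   rank order.
#' @export
librarySearch <- function(query, library, k = 10L,
                          similarityThreshold = 0.25) {
  if (length(library) == 0) stop("empty signature library")
  if (k < 1) stop("k must be >= 1")
  if (k > length(library)) {
    warning("k = ", k, " exceeds library size ", length(library),
            "; returning the full ranking")
    k <- length(library)
  }
  res <- lapply(library, function(sig) {
    ks <- ksCompare(query, sig)
    data.frame(source_id = sig@sourceId, d = ks@d, p = ks@p,
               n1 = ks@n1, n2 = ks@n2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$d, -res$p, res$source_id), , drop = FALSE]
  res <- res[seq_len(k), , drop = FALSE]
  res$candidate <- res$d < similarityThreshold
  rownames(res) <- NULL
  res
}

#' Serialize / deserialize signatures as JSON
#'
#' The on-disk form is a JSON object with the source id and the sorted
#' distance multiset; a directory of such files constitutes a signature
#' library.
#'
#' @param signature a \linkS4class{ShapeSignature}.
#' @param path file path.
#' @return \code{writeSignature}: \code{path}, invisibly.
#' @export
writeSignature <- function(signature, path) {
  jsonlite::write_json(
    list(source_id = signature@sourceId,
         distances = signature@distances),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeSignature
#' @return \code{readSignature}: a \linkS4class{ShapeSignature}.
#' @export
readSignature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- sort(as.numeric(x$distances))
  binWidth <- 0.5
  breaks <- seq(0, (floor(max(d) / binWidth) + 1) * binWidth, by = binWidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  new("ShapeSignature", sourceId = as.character(x$source_id), distances = d,
      histBreaks = breaks, histDensity = h$counts / length(d))
}
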