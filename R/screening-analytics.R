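# rounding convention used for printed tables: half-up, not banker's
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percent of control colony formation
#'
#' Mean treated colony count expressed as a percentage of the mean control
#' (vehicle-only) count. When full assay records are supplied, the cell line
#' and assay day must match between treated and control.
#'
#' @param treated,control numeric replicate colony counts, or lists with
#'   elements \code{counts} and optionally \code{cell_line} and \code{day}.
#' @return numeric(1) percentage.
#' @examples
#' percentOfControl(c(35, 35), c(50, 50))  # 70
#' @export
percentOfControl <- function(treated, control) {
  getCounts <- function(x) if (is.list(x)) x$counts else x
  for (fld in c("cell_line", "day")) {
    if (is.list(treated) && is.list(control) &&
        !is.null(treated[[fld]]) && !is.null(control[[fld]]) &&
        !identical(treated[[fld]], control[[fld]]))
      stop("treated and control records disagree on ", fld)
  }
  tc <- getCounts(treated); cc <- getCounts(control)
  if (length(tc) < 1 || length(cc) < 1)
    stop("at least one replicate count is required")
  if (mean(cc) <= 0) stop("control mean must be positive")
  100 * mean(tc) / mean(cc)
}

#' Compute percent-of-control for a whole assay table
#'
#' For every (cell line, compound, concentration, day) group the mean colony
#' count is divided by the mean of the matching zero-concentration (vehicle)
#' control for that cell line and day.
#'
#' @param assays data.frame with columns \code{cell_line}, \code{compound},
#'   \code{concentration_uM}, \code{day}, \code{replicate}, \code{colonies}.
#' @return data.frame with one row per treated group and a \code{pct} column.
#' @export
assayPercentOfControl <- function(assays) {
  req <- c("cell_line", "compound", "concentration_uM", "day", "colonies")
  miss <- setdiff(req, names(assays))
  if (length(miss) > 0)
    stop("assay table lacks column(s): ", paste(miss, collapse = ", "))
  ctrl <- assays[assays$concentration_uM == 0, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no zero-concentration control records")
  ctrlMean <- stats::aggregate(colonies ~ cell_line + day, ctrl, mean)
  trt <- assays[assays$concentration_uM > 0, , drop = FALSE]
  grp <- stats::aggregate(colonies ~ cell_line + compound +
                            concentration_uM + day, trt, mean)
  m <- merge(grp, ctrlMean, by = c("cell_line", "day"),
             suffixes = c("", ".ctrl"))
  if (any(m$colonies.ctrl <= 0)) stop("control mean must be positive")
  m$pct <- 100 * m$colonies / m$colonies.ctrl
  m[order(m$compound, m$cell_line, m$concentration_uM),
    c("cell_line", "compound", "concentration_uM", "day", "pct")]
}

#' Efficacy ratio
#'
#' Ratio of remaining cancer-cell colonies to remaining bone-marrow colonies,
#' both as percent of their respective controls at the same concentration.
#' Values below 0.5 denote activity with at least partial selectivity.
#'
#' @param cancerPct,marrowPct percent-of-control values; \code{marrowPct}
#'   must be positive.
#' @return numeric, unrounded (tables print 2 decimals).
#' @examples
#' efficacyRatio(70, 70)   # 1
#' efficacyRatio(2.1, 70)  # 0.03
#' @export
efficacyRatio <- function(cancerPct, marrowPct) {
  if (any(marrowPct <= 0))
    stop("efficacy ratio undefined: bone-marrow percent of control must be positive")
  cancerPct / marrowPct
}

#' Construct an efficacy table
#'
#' @param ratios numeric matrix, rows = cell lines, cols = compounds; NA marks
#'   untested combinations.
#' @param concentration concentration in micromolar.
#' @param siteOf named character mapping compound to protein site; defaults to
#'   the prefix of the compound name before the first "-". May include
#'   compounds absent from \code{ratios} (tested at the site but never
#'   active); they enter site-level denominators.
#' @return an \linkS4class{EfficacyTable}.
#' @export
efficacyTable <- function(ratios, concentration, siteOf = NULL) {
  if (is.null(siteOf)) {
    siteOf <- sub("-.*$", "", colnames(ratios))
    names(siteOf) <- colnames(ratios)
  }
  new("EfficacyTable", concentration = concentration,
      ratios = as.matrix(ratios), siteOf = siteOf)
}

#' Read a packaged efficacy-ratio table
#'
#' Reads the tab-delimited layout used for the packaged transcriptions of the
#' printed efficacy tables: first column = cell line, remaining columns =
#' compounds, "-" = not examined.
#'
#' @param path TSV file path.
#' @param concentration concentration of the table, micromolar.
#' @param extraCompounds character vector of additional tested compounds (not
#'   listed because never active) to include in site denominators.
#' @return an \linkS4class{EfficacyTable}.
#' @export
readEfficacyTable <- function(path, concentration,
                              extraCompounds = character(0)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "-")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  compounds <- c(colnames(m), extraCompounds)
  siteOf <- sub("-.*$", "", compounds)
  names(siteOf) <- compounds
  efficacyTable(m, concentration, siteOf)
}

#' Classify compound/cell-line pairs as active
#'
#' Strict inequality: a pair is active iff its efficacy ratio is below the
#' cutoff. Missing entries remain NA and are excluded from all denominators.
#'
#' @param table an \linkS4class{EfficacyTable}.
#' @param cutoff activity cutoff (default 0.5).
#' @return logical matrix with the table's dimensions (NA preserved).
#' @export
classifyActive <- function(table, cutoff = 0.5) {
  stopifnot(is(table, "EfficacyTable"))
  table@ratios < cutoff
}

#' Relative activity of one compound
#'
#' Percentage of tested cell lines in which the compound's efficacy ratio is
#' below the cutoff; missing entries are excluded from the denominator.
#' Rounded half-up to an integer, matching printed table precision.
#'
#' @param table an \linkS4class{EfficacyTable}.
#' @param compound compound id present in the table.
#' @param cutoff activity cutoff.
#' @return integer percentage.
#' @export
relativeActivity <- function(table, compound, cutoff = 0.5) {
  stopifnot(is(table, "EfficacyTable"))
  if (!compound %in% colnames(table@ratios))
    stop("compound not in table: ", compound)
  col <- table@ratios[, compound]
  tested <- sum(!is.na(col))
  if (tested == 0) stop("compound has no tested cell lines: ", compound)
  as.integer(.roundHalfUp(100 * sum(col < cutoff, na.rm = TRUE) / tested))
}

#' Per-site activity summary
#'
#' Segregates compounds by protein site and summarizes activity: the
#' percentage of tested compounds with at least one active cell line, the
#' pooled mean and SEM over all sub-cutoff ratios of those active compounds
#' (sample SEM, n - 1 denominator; 0 when only one ratio contributes), and
#' the min-max range of per-compound relative activity. Compounds present in
#' \code{siteOf} but absent from the ratio matrix count as tested and
#' inactive. Sites whose active compounds contribute no ratios report NA
#' summary fields.
#'
#' @param table an \linkS4class{EfficacyTable}.
#' @param cutoff activity cutoff.
#' @return data.frame with one row per site: \code{site}, \code{tested},
#'   \code{pct_active_compounds}, \code{pooled_mean}, \code{pooled_sem},
#'   \code{pooled_n}, \code{activity_min}, \code{activity_max}.
#' @export
siteSummary <- function(table, cutoff = 0.5) {
  stopifnot(is(table, "EfficacyTable"))
  sites <- unique(unname(table@siteOf))
  out <- lapply(sites, function(site) {
    comps <- names(table@siteOf)[table@siteOf == site]
    inTable <- comps[comps %in% colnames(table@ratios)]
    activeComp <- inTable[vapply(inTable, function(cp)
      sum(table@ratios[, cp] < cutoff, na.rm = TRUE) > 0, logical(1))]
    pooled <- unlist(lapply(activeComp, function(cp) {
      col <- table@ratios[, cp]
      col[!is.na(col) & col < cutoff]
    }))
    n <- length(pooled)
    relAct <- vapply(activeComp, function(cp)
      relativeActivity(table, cp, cutoff), integer(1))
    data.frame(
      site = site,
      tested = length(comps),
      pct_active_compounds =
        .roundHalfUp(100 * length(activeComp) / length(comps)),
      pooled_mean = if (n > 0) mean(pooled) else NA_real_,
      pooled_sem = if (n > 1) stats::sd(pooled) / sqrt(n)
                   else if (n == 1) 0 else NA_real_,
      pooled_n = n,
      activity_min = if (length(relAct) > 0) min(relAct) else NA_integer_,
      activity_max = if (length(relAct) > 0) max(relAct) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bone-marrow toxicity flags
#'
#' Inhibition is 100 minus the eight-day percent of control; a compound is
#' flagged at a threshold when its inhibition strictly exceeds it.
#'
#' @param day8 named numeric vector of eight-day bone-marrow percent of
#'   control per compound.
#' @param thresholds numeric vector of inhibition thresholds (percent).
#' @return list with \code{counts} (named by threshold) and \code{flagged}
#'   (list of sorted compound ids per threshold).
#' @export
marrowToxicityFlags <- function(day8, thresholds = c(10, 30)) {
  if (length(day8) == 0) stop("day8 must be non-empty")
  if (is.null(names(day8))) stop("day8 must be named by compound")
  inhibition <- 100 - day8
  counts <- vapply(thresholds, function(th) sum(inhibition > th), integer(1))
  names(counts) <- paste0("over_", thresholds)
  flagged <- lapply(thresholds, function(th)
    sort(names(day8)[inhibition > th]))
  names(flagged) <- names(counts)
  list(counts = counts, flagged = flagged)
}

#' Four-parameter logistic dose-response curve
#'
#' \code{bottom + (top - bottom) / (1 + 10^((logIC50 - log10(dose)) * hill))}.
#' With responses in percent of control, inhibition curves have a negative
#' Hill slope (response falls from \code{top} toward \code{bottom} as dose
#' rises).
#'
#' @param dose dose(s), micromolar, > 0.
#' @param bottom,top asymptotes, percent of control.
#' @param logIC50 log10 of the IC50 in micromolar.
#' @param hill Hill slope.
#' @return numeric responses.
#' @export
fourPL <- function(dose, bottom, top, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - log10(dose)) * hill))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of log-transformed doses
#' against responses in percent of control. Zero-dose controls are the
#' normalization denominator, not fitted points (log 0 is undefined), and are
#' silently excluded. Starting values come from the data: asymptotes from the
#' response extremes, logIC50 from the dose whose response is nearest the
#' half-way point, Hill slope sign from the dose-response trend. Flat
#' response profiles and solver failures raise errors, never silent
#' misconvergence; diagnostics (iterations, residual sum of squares,
#' convergence message) are kept in the fit object.
#'
#' @param doses numeric doses, micromolar; at least 4 distinct positive dose
#'   levels after removing zero-dose entries (5 including the control).
#' @param responses percent-of-control responses, same length.
#' @return a \linkS4class{DoseResponseFit}.
#' @examples
#' d <- c(0.0061, 0.018, 0.05, 0.16, 0.49, 1.48, 4.44, 13.33, 40)
#' y <- fourPL(d, 0, 100, log10(0.012), -1)
#' ic50(fit4PL(d, y))  # ~0.012
#' @export
fit4PL <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  ok <- doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (!all(is.finite(responses))) stop("responses must be finite")
  if (length(unique(doses)) < 4)
    stop("at least 4 distinct positive dose levels are required ",
         "(5 including the zero-dose control)")
  if (diff(range(responses)) < 1e-6)
    stop("no dose-response signal: responses are flat; cannot fit a 4PL model")
  lx <- log10(doses)
  topStart <- max(responses); botStart <- min(responses)
  half <- (topStart + botStart) / 2
  licStart <- lx[which.min(abs(responses - half))]
  hillStart <- if (stats::cor(lx, responses) < 0) -1 else 1
  dat <- data.frame(lx = lx, y = responses)
  # box constraints keep the Levenberg-Marquardt search out of the
  # degenerate region (asymptotes far outside the response range, inflexion
  # far outside the tested doses) where flat plateaus stall convergence
  rng <- diff(range(responses))
  lower <- c(bottom = botStart - rng, top = botStart,
             logIC50 = min(lx) - 2, hill = -10)
  upper <- c(bottom = topStart, top = topStart + rng,
             logIC50 = max(lx) + 2, hill = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((logIC50 - lx) * hill)),
      data = dat,
      start = list(bottom = botStart, top = topStart,
                   logIC50 = licStart, hill = hillStart),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000)),
    error = function(e)
      stop("4PL fit failed to converge: ", conditionMessage(e),
           "; response range [", min(responses), ", ", max(responses), "]"))
  cf <- stats::coef(fit)
  info <- fit$convInfo
  if (!isTRUE(info$isConv))
    stop("4PL fit did not converge: ", info$stopMessage)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"]); lic <- unname(cf["logIC50"])
  # the 4PL is symmetric under (bottom, top, hill) -> (top, bottom, -hill);
  # canonicalize to bottom <= top
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  new("DoseResponseFit", bottom = bottom, top = top, logIC50 = lic,
      hill = hill, ic50 = 10^lic,
      convergence = list(converged = TRUE,
                         iterations = info$finIter,
                         rss = sum(stats::resid(fit)^2),
                         message = info$stopMessage))
}
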