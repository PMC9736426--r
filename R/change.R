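#' @include ensemble.R
NULL

#' Standard scores of a suitability map
#'
#' Converts raw suitability (0-1 scale) into standard scores using the
#' mean and sample standard deviation (n - 1) of a reference map over the
#' reference cells. Future maps are standardized with the statistics of
#' the corresponding current map, so a cell's change in standard score
#' measures how many current-scale standard deviations its suitability
#' moves — comparable across species whose raw scales differ.
#'
#' @param map a \code{SuitabilityMap} to standardize.
#' @param ref the reference \code{SuitabilityMap} supplying mean and sd
#'   (the current prediction); defaults to \code{map} itself.
#' @param refCells linear indices of the reference population; default all
#'   cells.
#' @return numeric matrix of z-scores aligned to the grid.
#' @export
standardizeScores <- function(map, ref = map, refCells = NULL) {
  stopifnot(is(map, "SuitabilityMap"), is(ref, "SuitabilityMap"))
  if (!identical(dim(map@scores), dim(ref@scores)))
    stop("maps are not aligned", call. = FALSE)
  refVals <- if (is.null(refCells)) as.vector(ref@scores)
             else as.vector(ref@scores)[refCells]
  s <- stats::sd(refVals)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate reference: suitability has no spread", call. = FALSE)
  (map@scores - mean(refVals)) / s
}

#' Standardized suitability change on a cell mask
#'
#' Per-cell difference of standard scores (future minus current) restricted
#' to a mask: positive where future suitability exceeds current suitability
#' and negative in the opposite case. For sensitive native species the mask
#' is their occupied cells; for an invader it can also be a conjectural
#' long-distance-dispersal potential range.
#'
#' @param zFuture,zCurrent z-score matrices from
#'   \code{\link{standardizeScores}}.
#' @param maskCells linear indices of the cells the change is evaluated on.
#' @param species,scenario,range labels recorded on the result.
#' @return a \code{ChangeMap}.
#' @export
changeMap <- function(zFuture, zCurrent, maskCells, species = "unnamed",
                      scenario = "rcp26", range = "invaded") {
  if (!identical(dim(zFuture), dim(zCurrent)))
    stop("z maps are not aligned", call. = FALSE)
  maskCells <- as.integer(maskCells)
  if (!length(maskCells)) stop("mask is empty", call. = FALSE)
  delta <- as.vector(zFuture)[maskCells] - as.vector(zCurrent)[maskCells]
  new("ChangeMap", cells = maskCells, delta = delta, species = species,
      scenario = scenario, range = range)
}

#' Potential dispersal range from native occurrences
#'
#' The union of presence cells across the listed native species: under a
#' successful long-distance-dispersal scenario the invader is assumed able
#' to reach every locality where any of the sensitive native species is
#' recorded.
#'
#' @param occList list of \code{OccurrenceSet}s.
#' @param shape grid shape (rows, cols).
#' @return sorted integer vector of linear cell indices.
#' @export
potentialRange <- function(occList, shape) {
  if (!length(occList)) stop("need at least one occurrence set", call. = FALSE)
  sort(unique(unlist(lapply(occList, presenceCells, shape = shape))))
}

#' Summarize change by protection regime
#'
#' Partitions the cells of a change map into three groups — outside the
#' protected network, generic protection, and sites explicitly targeted at
#' the focal species (targeted sites of other species count as generic
#' protection here) — and reports the 5, 25, 50, 75 and 95 percent
#' quantiles of standardized change per group, computed by linear
#' interpolation between order statistics. Empty groups are omitted with a
#' notice.
#'
#' @param cm a \code{ChangeMap}.
#' @param pm a \code{ProtectionMask} on the same grid.
#' @param targetSpecies species whose targeted sites define the targeted
#'   group; defaults to the change map's species.
#' @return data.frame with species, scenario, range, regime, n_cells, p5,
#'   q25, median, q75, p95.
#' @export
regimeSummary <- function(cm, pm, targetSpecies = NULL) {
  stopifnot(is(cm, "ChangeMap"), is(pm, "ProtectionMask"))
  if (is.null(targetSpecies)) targetSpecies <- cm@species
  regime <- as.vector(pm@regime)[cm@cells]
  tgt <- cm@cells %in% targetedCells(pm, targetSpecies)
  group <- ifelse(tgt, "targeted_n2000",
                  ifelse(regime == "outside", "outside", "n2000"))
  rows <- lapply(REGIME_LABELS, function(g) {
    d <- cm@delta[group == g]
    if (!length(d)) {
      message("regime '", g, "' holds no cells for ", cm@species,
              " (", cm@scenario, ", ", cm@range, "); row omitted")
      return(NULL)
    }
    q <- stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                         names = FALSE)
    data.frame(species = cm@species, scenario = cm@scenario,
               range = cm@range, regime = g, n_cells = length(d),
               p5 = q[1], q25 = q[2], median = q[3], q75 = q[4], p95 = q[5])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare change distributions between two groups
#'
#' Paired t-test on cellwise differences when the two vectors share a
#' cell-to-cell pairing (e.g. the same cells under two scenarios); Welch
#' two-sample t-test otherwise (e.g. inside vs. outside protection, which
#' are different cell sets). Two-sided throughout. Zero-variance paired
#' differences leave the statistic undefined and raise a degenerate-test
#' error.
#'
#' @param a,b numeric vectors of standardized change.
#' @param paired logical; requires equal length.
#' @param label description of the comparison carried into the result.
#' @return data.frame with comparison, test, statistic, df, p_value,
#'   mean_difference.
#' @export
compareGroups <- function(a, b, paired = FALSE, label = "") {
  if (paired) {
    if (length(a) != length(b))
      stop("paired comparison needs equal lengths", call. = FALSE)
    d <- a - b
    if (stats::sd(d) < 1e-14)
      stop("degenerate test: paired differences have zero variance",
           call. = FALSE)
    tt <- stats::t.test(a, b, paired = TRUE)
    test <- "paired t"
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop("unpaired comparison needs n >= 2 per group", call. = FALSE)
    tt <- stats::t.test(a, b, paired = FALSE, var.equal = FALSE)
    test <- "Welch t"
  }
  data.frame(comparison = label, test = test,
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             mean_difference = if (paired) mean(a - b) else mean(a) - mean(b))
}
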