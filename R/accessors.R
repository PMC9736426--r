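#' @include AllGenerics.R
NULL

#' @describeIn gridShape rows and columns of the layer grid
#' @export
setMethod("gridShape", "EnvStack", function(x) dim(x@layers[[1]]))

#' @describeIn gridShape grid of the stratum map
#' @export
setMethod("gridShape", "StrataMap", function(x) dim(x@strata))

#' @describeIn gridShape grid of the protection mask
#' @export
setMethod("gridShape", "ProtectionMask", function(x) dim(x@regime))

#' @describeIn gridShape grid of the suitability scores
#' @export
setMethod("gridShape", "SuitabilityMap", function(x) dim(x@scores))

#' @describeIn envLayer layer matrix by name
#' @export
setMethod("envLayer", "EnvStack", function(x, variable) {
  if (!variable %in% names(x@layers))
    stop("unknown variable: ", variable, call. = FALSE)
  x@layers[[variable]]
})

#' @describeIn scenarioLabel scenario of an environmental stack
#' @export
setMethod("scenarioLabel", "EnvStack", function(x) x@scenario)

#' @describeIn scenarioLabel scenario of a suitability map
#' @export
setMethod("scenarioLabel", "SuitabilityMap", function(x) x@scenario)

#' @describeIn speciesLabel species of an occurrence set
#' @export
setMethod("speciesLabel", "OccurrenceSet", function(x) x@species)

#' @describeIn speciesLabel species of a hull polygon
#' @export
setMethod("speciesLabel", "HullPolygon", function(x) x@species)

#' @describeIn speciesLabel species of an ensemble
#' @export
setMethod("speciesLabel", "SDMEnsemble", function(x) x@species)

#' @describeIn occRecords records data.frame
#' @export
setMethod("occRecords", "OccurrenceSet", function(x) x@records)

#' @describeIn presenceCells linear indices of presence records
#' @export
setMethod("presenceCells", "OccurrenceSet", function(x, shape) {
  r <- x@records[x@records$presence == 1L, , drop = FALSE]
  sort(unique(as.integer((r$col - 1L) * shape[1] + r$row)))
})

#' @describeIn evalTable full member evaluation table
#' @export
setMethod("evalTable", "SDMEnsemble", function(x) x@evalTable)

#' @describeIn memberWeights normalized AUC weights of retained members
#' @export
setMethod("memberWeights", "SDMEnsemble", function(x) x@weights)

#' Region mask accessor
#' @param x an \code{EnvStack}.
#' @return character matrix of region labels.
#' @export
regionMask <- function(x) {
  stopifnot(is(x, "EnvStack"))
  x@regionMask
}

#' Hull vertices accessor
#' @param x a \code{HullPolygon}.
#' @return n x 2 matrix of CCW vertices.
#' @export
hullVertices <- function(x) {
  stopifnot(is(x, "HullPolygon"))
  x@vertices
}

#' Protection regime matrix accessor
#' @param x a \code{ProtectionMask}.
#' @export
protectionRegime <- function(x) {
  stopifnot(is(x, "ProtectionMask"))
  x@regime
}

#' Targeted cells for one species
#' @param x a \code{ProtectionMask}.
#' @param species species label.
#' @return integer vector of linear cell indices (empty if untargeted).
#' @export
targetedCells <- function(x, species) {
  stopifnot(is(x, "ProtectionMask"))
  idx <- x@targets[[species]]
  if (is.null(idx)) integer() else idx
}

#' Suitability scores accessor
#' @param x a \code{SuitabilityMap}.
#' @export
suitabilityScores <- function(x) {
  stopifnot(is(x, "SuitabilityMap"))
  x@scores
}

#' Change values accessor
#' @param x a \code{ChangeMap}.
#' @return named list with cells and delta.
#' @export
changeValues <- function(x) {
  stopifnot(is(x, "ChangeMap"))
  list(cells = x@cells, delta = x@delta)
}

setMethod("show", "EnvStack", function(object) {
  d <- gridShape(object)
  cat("EnvStack:", d[1], "x", d[2], "cells of", object@cellSize, "km,",
      "scenario", object@scenario, "\n")
  for (v in names(object@layers)) {
    r <- range(object@layers[[v]])
    cat(sprintf("  %-6s [%.2f, %.2f]\n", v, r[1], r[2]))
  }
})

setMethod("show", "OccurrenceSet", function(object) {
  cat("OccurrenceSet:", object@species, "-", nrow(object@records), "records (",
      sum(object@records$presence), "presences ),", object@design,
      "design, region", object@region, "\n")
})

setMethod("show", "VirtualSpecies", function(object) {
  cat("VirtualSpecies:", object@name, "- prevalence", object@prevalence, "\n")
  for (v in names(object@optima))
    cat(sprintf("  %-6s optimum %.2f breadth %.2f\n", v,
                object@optima[[v]], object@breadths[[v]]))
})

setMethod("show", "NicheSpace", function(object) {
  cat("NicheSpace:", length(object@center), "variables,",
      object@retainedK, "retained components\n")
  ef <- round(100 * object@explainedFraction, 1)
  cat("  explained variance (%):", paste(ef, collapse = ", "), "\n")
})

setMethod("show", "HullPolygon", function(object) {
  cat("HullPolygon:", object@species, "-", nrow(object@vertices),
      "vertices, area", signif(.polygonArea(object@vertices), 4), "\n")
})

setMethod("show", "SDMEnsemble", function(object) {
  cat("SDMEnsemble:", object@species, "-", length(object@members),
      "retained members (AUC >", object@aucThreshold, ")\n")
  if (nrow(object@evalTable)) {
    agg <- stats::aggregate(test_auc ~ family, object@evalTable, mean)
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-4s mean test AUC %.3f\n", agg$family[i], agg$test_auc[i]))
  }
})

setMethod("show", "SuitabilityMap", function(object) {
  d <- dim(object@scores)
  cat("SuitabilityMap:", object@species, "under", object@scenario, "-",
      d[1], "x", d[2], "grid, mean score", signif(mean(object@scores), 3), "\n")
})

setMethod("show", "ChangeMap", function(object) {
  cat("ChangeMap:", object@species, object@scenario, object@range, "-",
      length(object@cells), "cells, median dz",
      signif(stats::median(object@delta), 3), "\n")
})
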