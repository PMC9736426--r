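#' @include AllClasses.R
NULL

#' Grid shape of a gridded object
#' @param x an object with a grid.
#' @return integer vector (rows, cols).
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' Environmental layer accessor
#' @param x an \code{EnvStack}.
#' @param variable layer name, e.g. \code{"BIO12"}.
#' @return numeric matrix.
#' @export
setGeneric("envLayer", function(x, variable) standardGeneric("envLayer"))

#' Scenario label accessor
#' @param x an object carrying a scenario label.
#' @export
setGeneric("scenarioLabel", function(x) standardGeneric("scenarioLabel"))

#' Species label accessor
#' @param x an object tied to one species.
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' Occurrence records accessor
#' @param x an \code{OccurrenceSet}.
#' @return data.frame with row, col, presence.
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))

#' Presence cells as linear indices
#' @param x an \code{OccurrenceSet}.
#' @param shape grid shape (rows, cols).
#' @export
setGeneric("presenceCells", function(x, shape) standardGeneric("presenceCells"))

#' Suitability of a virtual species under given conditions
#'
#' Evaluates the product-Gaussian niche response, either over every cell of
#' an environmental stack (returning a matrix) or on a data.frame/matrix of
#' environmental vectors (returning a vector).
#'
#' @param species a \code{VirtualSpecies}.
#' @param env an \code{EnvStack}, data.frame or matrix of environments.
#' @return suitability values in [0, 1].
#' @export
setGeneric("suitability", function(species, env) standardGeneric("suitability"))

#' Project environmental vectors into the principal-component space
#'
#' Standardizes each point with the calibration means and standard
#' deviations stored in the niche space (never the points' own statistics)
#' and applies the retained loadings.
#'
#' @param ns a \code{NicheSpace}.
#' @param points matrix or data.frame carrying all calibrated variables.
#' @return matrix of scores, one column per retained component.
#' @export
setGeneric("projectScores", function(ns, points) standardGeneric("projectScores"))

#' Ensemble suitability projection
#'
#' Cellwise AUC-weighted average of member predictions over an
#' environmental stack; identical machinery for current and future stacks.
#'
#' @param ens an \code{SDMEnsemble}.
#' @param env an \code{EnvStack} carrying all model predictors.
#' @return a \code{SuitabilityMap}.
#' @export
setGeneric("predictSuitability", function(ens, env) standardGeneric("predictSuitability"))

#' Per-family evaluation table of an ensemble
#' @param x an \code{SDMEnsemble}.
#' @return data.frame with one row per fitted member.
#' @export
setGeneric("evalTable", function(x) standardGeneric("evalTable"))

#' Ensemble member weights
#' @param x an \code{SDMEnsemble}.
#' @export
setGeneric("memberWeights", function(x) standardGeneric("memberWeights"))
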