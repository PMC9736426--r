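#' @import methods
NULL

ENV_VARIABLES <- c("BIO5", "BIO6", "BIO12", "ALT", "SLOPE")
CLIMATE_VARIABLES <- c("BIO5", "BIO6", "BIO12")
SCENARIO_LABELS <- c("current", "rcp26", "rcp85")
REGIME_LABELS <- c("outside", "n2000", "targeted_n2000")
MODEL_FAMILIES <- c("GLM", "GAM", "MARS", "GBM", "FDA")

#' Gridded environmental stack for one climate scenario
#'
#' An \code{EnvStack} holds the five aligned environmental layers used
#' throughout the analysis: maximum temperature of the warmest month
#' (\code{BIO5}, deg C), minimum temperature of the coldest month
#' (\code{BIO6}, deg C), annual precipitation (\code{BIO12}, mm), altitude
#' (\code{ALT}, m) and slope (\code{SLOPE}, degrees), together with a
#' scenario label and a per-cell region mask separating the native range,
#' the invaded range and everything else.
#'
#' Validity enforces the physical invariants: all layers share one grid
#' shape, all values are finite, precipitation and slope are non-negative,
#' and \code{BIO5 > BIO6} in every cell.
#'
#' @slot layers named list of numeric matrices, one per variable.
#' @slot cellSize cell edge length in abstract km.
#' @slot scenario one of \code{"current"}, \code{"rcp26"}, \code{"rcp85"}.
#' @slot regionMask character matrix with entries \code{"native"},
#'   \code{"invaded"} or \code{"other"}.
#' @exportClass EnvStack
setClass("EnvStack", representation(
  layers = "list",
  cellSize = "numeric",
  scenario = "character",
  regionMask = "matrix"
))

setValidity("EnvStack", function(object) {
  msgs <- character()
  if (!all(ENV_VARIABLES %in% names(object@layers)))
    msgs <- c(msgs, paste("layers must include", paste(ENV_VARIABLES, collapse = ", ")))
  dims <- lapply(object@layers, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) > 1L)
    msgs <- c(msgs, "all layers must share one grid shape")
  if (!all(vapply(object@layers, function(m) all(is.finite(m)), logical(1))))
    msgs <- c(msgs, "all layer values must be finite")
  if (length(msgs) == 0L) {
    if (any(object@layers$BIO12 < 0)) msgs <- c(msgs, "BIO12 must be >= 0")
    if (any(object@layers$SLOPE < 0)) msgs <- c(msgs, "SLOPE must be >= 0")
    if (any(object@layers$BIO5 <= object@layers$BIO6))
      msgs <- c(msgs, "BIO5 must exceed BIO6 cellwise")
    if (!identical(dim(object@regionMask), dim(object@layers[[1]])))
      msgs <- c(msgs, "regionMask must match the layer grid shape")
  }
  if (!object@scenario %in% SCENARIO_LABELS)
    msgs <- c(msgs, "scenario must be one of current/rcp26/rcp85")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' Virtual species with a known niche response
#'
#' A virtual species is defined by a product-Gaussian suitability function:
#' for an environmental vector x,
#' suitability(x) = prevalence * prod_v exp(-(x_v - mu_v)^2 / (2 sigma_v^2)),
#' which lies in [0, 1] and equals \code{prevalence} exactly at the optimum.
#' Because the true suitability surface is known, downstream niche and
#' distribution-model estimates can be validated by parameter recovery.
#'
#' @slot name species label.
#' @slot optima named numeric vector of per-variable optima (variable units).
#' @slot breadths named numeric vector of per-variable niche breadths (> 0).
#' @slot prevalence maximum suitability, in (0, 1].
#' @exportClass VirtualSpecies
setClass("VirtualSpecies", representation(
  name = "character",
  optima = "numeric",
  breadths = "numeric",
  prevalence = "numeric"
))

setValidity("VirtualSpecies", function(object) {
  msgs <- character()
  if (length(object@optima) == 0L || is.null(names(object@optima)) ||
      any(!nzchar(names(object@optima))))
    msgs <- c(msgs, "optima must be a named vector of niche variables")
  if (!identical(sort(names(object@optima)), sort(names(object@breadths))))
    msgs <- c(msgs, "optima and breadths must cover the same variables")
  if (any(object@breadths <= 0)) msgs <- c(msgs, "breadths must be positive")
  if (object@prevalence <= 0 || object@prevalence > 1)
    msgs <- c(msgs, "prevalence must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Species occurrence records on the analysis grid
#'
#' Records are grid cells with a presence flag. Presence-only sets (field
#' surveys) contain only presences; atlas sets record explicit absences as
#' well, one record per atlas cell.
#'
#' @slot species species label.
#' @slot records data.frame with columns \code{row}, \code{col},
#'   \code{presence} (0/1).
#' @slot region label of the region the records were drawn from.
#' @slot design \code{"presence_only"} or \code{"atlas"}.
#' @exportClass OccurrenceSet
setClass("OccurrenceSet", representation(
  species = "character",
  records = "data.frame",
  region = "character",
  design = "character"
))

setValidity("OccurrenceSet", function(object) {
  msgs <- character()
  req <- c("row", "col", "presence")
  if (!all(req %in% names(object@records)))
    msgs <- c(msgs, "records needs columns row, col, presence")
  else {
    if (!all(object@records$presence %in% c(0L, 1L)))
      msgs <- c(msgs, "presence must be 0 or 1")
    if (object@design == "presence_only" && any(object@records$presence == 0L))
      msgs <- c(msgs, "presence-only sets cannot contain absences")
  }
  if (!object@design %in% c("presence_only", "atlas"))
    msgs <- c(msgs, "design must be presence_only or atlas")
  if (length(msgs)) msgs else TRUE
})

#' Ecoregion-like environmental strata
#'
#' Integer stratum ids on the grid; every cell belongs to exactly one
#' stratum. Used to spread pseudo-absence samples across environmental
#' regions rather than clumping them.
#'
#' @slot strata integer matrix of stratum ids in 1..K.
#' @exportClass StrataMap
setClass("StrataMap", representation(strata = "matrix"))

setValidity("StrataMap", function(object) {
  s <- object@strata
  if (any(is.na(s)) || any(s < 1L)) return("every cell needs a stratum id >= 1")
  TRUE
})

#' Protected-area mask with species-level targets
#'
#' Cells carry one of three regimes: \code{outside} the protected network,
#' generic \code{n2000} protection, or \code{targeted_n2000} sites that
#' explicitly list one or more species as conservation objects. Targeted
#' cells are always a subset of the protected network.
#'
#' @slot regime character matrix over the grid.
#' @slot targets named list: species label -> integer vector of linear cell
#'   indices of targeted sites for that species.
#' @exportClass ProtectionMask
setClass("ProtectionMask", representation(
  regime = "matrix",
  targets = "list"
))

setValidity("ProtectionMask", function(object) {
  msgs <- character()
  if (!all(object@regime %in% REGIME_LABELS))
    msgs <- c(msgs, "regimes must be outside/n2000/targeted_n2000")
  tgt <- which(object@regime == "targeted_n2000")
  covered <- sort(unique(unlist(object@targets)))
  if (length(covered) && !all(covered %in% tgt))
    msgs <- c(msgs, "species targets must lie on targeted_n2000 cells")
  if (length(msgs)) msgs else TRUE
})

#' Principal-component environmental space
#'
#' The shared environmental space in which species niches are compared.
#' Variables are centred and scaled by the calibration sample (correlation
#' PCA, sample sd with n - 1); loadings are the orthonormal eigenvectors of
#' the correlation matrix, ordered by explained variance.
#'
#' @slot center,scale named numeric vectors used for standardization.
#' @slot loadings variables x components orthonormal matrix.
#' @slot eigenvalues all eigenvalues, non-increasing.
#' @slot explainedFraction per-component fraction of total variance.
#' @slot retainedK number of components used for niche delimitation.
#' @exportClass NicheSpace
setClass("NicheSpace", representation(
  center = "numeric",
  scale = "numeric",
  loadings = "matrix",
  eigenvalues = "numeric",
  explainedFraction = "numeric",
  retainedK = "integer"
))

setValidity("NicheSpace", function(object) {
  msgs <- character()
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(object@loadings)))) > 1e-8)
    msgs <- c(msgs, "loading columns must be orthonormal")
  ef <- object@explainedFraction
  if (any(ef < -1e-12 | ef > 1 + 1e-12) || any(diff(ef) > 1e-12))
    msgs <- c(msgs, "explained fractions must be in [0,1] and non-increasing")
  if (abs(sum(ef) - 1) > 1e-8)
    msgs <- c(msgs, "explained fractions must sum to 1")
  if (object@retainedK < 1L || object@retainedK > ncol(object@loadings))
    msgs <- c(msgs, "retainedK out of range")
  if (length(msgs)) msgs else TRUE
})

#' Maximum convex polygon delimiting a species environmental space
#'
#' Vertices are ordered counter-clockwise in the plane of the first two
#' principal components. A hull with positive area requires at least three
#' non-collinear projected occurrences.
#'
#' @slot species species label.
#' @slot vertices n x 2 matrix of (PC1, PC2) vertices, convex, CCW.
#' @exportClass HullPolygon
setClass("HullPolygon", representation(
  species = "character",
  vertices = "matrix"
))

setValidity("HullPolygon", function(object) {
  v <- object@vertices
  if (ncol(v) != 2L || nrow(v) < 3L) return("vertices must be an n x 2 matrix, n >= 3")
  if (.polygonArea(v) <= 0) return("vertices must be counter-clockwise with positive area")
  TRUE
})

#' One fitted ensemble member
#'
#' A presence-absence classifier of one of the five model families, with
#' the replicate id it belongs to and its test AUC from the 70/30 split.
#'
#' @slot family one of GLM, GAM, MARS, GBM, FDA.
#' @slot replicate replicate id in 1..R.
#' @slot model opaque fitted object.
#' @slot testAuc test AUC in [0, 1].
#' @exportClass FittedMember
setClass("FittedMember", representation(
  family = "character",
  replicate = "integer",
  model = "ANY",
  testAuc = "numeric"
))

#' AUC-weighted ensemble of distribution models
#'
#' Retains only members whose test AUC exceeds the skill threshold and
#' weights their predictions by raw test AUC, normalized to sum to one.
#'
#' @slot species species label.
#' @slot members list of retained \code{FittedMember}s.
#' @slot weights per-member positive weights summing to 1.
#' @slot aucThreshold retention threshold (default 0.7, strict).
#' @slot evalTable data.frame of every fitted member: family, replicate,
#'   test_auc, retained, weight.
#' @slot predictors predictor variable names used by the members.
#' @exportClass SDMEnsemble
setClass("SDMEnsemble", representation(
  species = "character",
  members = "list",
  weights = "numeric",
  aucThreshold = "numeric",
  evalTable = "data.frame",
  predictors = "character"
))

setValidity("SDMEnsemble", function(object) {
  msgs <- character()
  if (length(object@members) != length(object@weights))
    msgs <- c(msgs, "one weight per member")
  if (length(object@weights)) {
    if (any(object@weights <= 0)) msgs <- c(msgs, "weights must be positive")
    if (abs(sum(object@weights) - 1) > 1e-8) msgs <- c(msgs, "weights must sum to 1")
    aucs <- vapply(object@members, function(m) m@testAuc, numeric(1))
    if (any(aucs <= object@aucThreshold))
      msgs <- c(msgs, "retained members must exceed the AUC threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' Gridded ensemble suitability scores
#'
#' @slot scores numeric matrix of ensemble suitability in [0, 1], aligned
#'   to the EnvStack grid.
#' @slot scenario scenario label of the projected climate.
#' @slot species species label.
#' @exportClass SuitabilityMap
setClass("SuitabilityMap", representation(
  scores = "matrix",
  scenario = "character",
  species = "character"
))

#' Standardized suitability change on a cell mask
#'
#' Per-cell difference of standard scores, future minus current, defined
#' only on the masked cells (occupied range or potential dispersal range).
#'
#' @slot cells integer vector of linear cell indices.
#' @slot delta numeric vector of z-score changes, parallel to \code{cells}.
#' @slot species,scenario,range labels identifying the comparison.
#' @exportClass ChangeMap
setClass("ChangeMap", representation(
  cells = "integer",
  delta = "numeric",
  species = "character",
  scenario = "character",
  range = "character"
))

setValidity("ChangeMap", function(object) {
  if (length(object@cells) != length(object@delta))
    return("cells and delta must be parallel")
  if (length(object@cells) == 0L) return("change map must cover at least one cell")
  if (!all(is.finite(object@delta))) return("delta must be finite")
  TRUE
})
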