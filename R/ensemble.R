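#' @include members.R pseudoabsence.R
NULL

#' Build an AUC-weighted ensemble of distribution models
#'
#' The full ensemble protocol: for each of R replicates a fresh
#' environmentally stratified presence-absence subsample is assembled
#' (pseudo-absences are re-drawn every replicate, of equal size to the
#' presences), split 70/30 stratified by class, and every model family is
#' fitted on the training part and scored by AUC on the held-out part.
#' Members whose test AUC does not exceed the skill threshold (strictly
#' greater than 0.7 by default) are dropped; the survivors form the
#' consensus with weights proportional to their raw test AUC, normalized
#' to sum to one. The evaluation table keeps every fitted member so the
#' filter is auditable.
#'
#' @param occ an \code{OccurrenceSet}.
#' @param env an \code{EnvStack} (current conditions).
#' @param strata a \code{StrataMap} for pseudo-absence stratification.
#' @param R number of replicates, default 10.
#' @param families model families to fit, default all five.
#' @param aucThreshold retention threshold, default 0.7 (strict).
#' @param trainFraction training share of each split, default 0.7.
#' @param predictors predictor variables, default the three climate
#'   variables BIO5, BIO6, BIO12 (relief belongs to the niche-space
#'   analysis, not to climate projections).
#' @param backgroundCells optional background restriction for
#'   pseudo-absences.
#' @param hyperparams passed to \code{\link{fitMember}}.
#' @param seed integer seed governing every replicate's draw and split.
#' @return an \code{SDMEnsemble}.
#' @export
buildEnsemble <- function(occ, env, strata, R = 10L,
                          families = MODEL_FAMILIES, aucThreshold = 0.7,
                          trainFraction = 0.7,
                          predictors = CLIMATE_VARIABLES,
                          backgroundCells = NULL, hyperparams = list(),
                          seed = 1) {
  stopifnot(is(occ, "OccurrenceSet"), is(env, "EnvStack"),
            is(strata, "StrataMap"))
  members <- list()
  rows <- list()
  for (r in seq_len(R)) {
    repSeed <- (as.integer(seed) * 131L + r) %% .Machine$integer.max
    samp <- buildTrainingSample(occ, env, strata,
                                backgroundCells = backgroundCells,
                                predictors = predictors, seed = repSeed)
    sp <- splitSample(samp, trainFraction, seed = repSeed + 1L)
    for (fam in families) {
      m <- fitMember(fam, sp$train, predictors, replicate = r,
                     hyperparams = hyperparams)
      m@testAuc <- aucScore(sp$test$presence,
                            predictMember(m, sp$test, predictors))
      members[[length(members) + 1L]] <- m
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, replicate = r, test_auc = m@testAuc)
    }
  }
  eval <- do.call(rbind, rows)
  keep <- eval$test_auc > aucThreshold
  eval$retained <- keep
  if (!any(keep))
    stop("empty ensemble: no member exceeded AUC threshold ", aucThreshold,
         call. = FALSE)
  w <- eval$test_auc[keep] / sum(eval$test_auc[keep])
  eval$weight <- 0
  eval$weight[keep] <- w
  new("SDMEnsemble", species = occ@species, members = members[keep],
      weights = w, aucThreshold = aucThreshold, evalTable = eval,
      predictors = predictors)
}

#' Mean and standard deviation of test AUC per family
#'
#' Aggregates the replicated cross-validations of an ensemble into the
#' per-family mean and standard deviation of test AUC.
#'
#' @param ens an \code{SDMEnsemble}.
#' @return data.frame with family, mean_auc, sd_auc, n_retained.
#' @export
aucSummary <- function(ens) {
  stopifnot(is(ens, "SDMEnsemble"))
  tab <- ens@evalTable
  out <- do.call(rbind, lapply(split(tab, tab$family), function(d)
    data.frame(family = d$family[1], mean_auc = mean(d$test_auc),
               sd_auc = stats::sd(d$test_auc), n_retained = sum(d$retained))))
  rownames(out) <- NULL
  out
}

#' @describeIn predictSuitability cellwise weighted mean of member
#'   predictions over the stack
#' @export
setMethod("predictSuitability", signature("SDMEnsemble", "EnvStack"),
  function(ens, env) {
    missing <- setdiff(ens@predictors, names(env@layers))
    if (length(missing))
      stop("stack lacks predictor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    newdata <- as.data.frame(envAsMatrix(env, ens@predictors))
    acc <- numeric(nrow(newdata))
    for (i in seq_along(ens@members))
      acc <- acc + ens@weights[i] *
        predictMember(ens@members[[i]], newdata, ens@predictors)
    shape <- gridShape(env)
    new("SuitabilityMap", scores = matrix(acc, shape[1], shape[2]),
        scenario = env@scenario, species = ens@species)
  })

#' Transferability of an ensemble to a disjoint region
#'
#' Assesses how well an ensemble trained in one region (typically the
#' native range) predicts occurrences in another (the invaded range):
#' presences of the target occurrence set are scored against an equal-size
#' stratified pseudo-absence sample drawn from the target region's
#' background, and the agreement is summarized as an AUC.
#'
#' @param ens an \code{SDMEnsemble} trained elsewhere.
#' @param occB an \code{OccurrenceSet} from the evaluation region.
#' @param env an \code{EnvStack}.
#' @param strata a \code{StrataMap}.
#' @param backgroundCells background for the evaluation region; default
#'   the cells of \code{occB}'s region.
#' @param seed integer seed for the pseudo-absence draw.
#' @return transfer AUC in [0, 1].
#' @export
evaluateTransfer <- function(ens, occB, env, strata, backgroundCells = NULL,
                             seed = 1) {
  stopifnot(is(ens, "SDMEnsemble"), is(occB, "OccurrenceSet"))
  shape <- gridShape(env)
  if (is.null(backgroundCells)) {
    rg <- strsplit(occB@region, "+", fixed = TRUE)[[1]]
    backgroundCells <- if (identical(occB@region, "all")) seq_len(prod(shape))
      else which(as.vector(env@regionMask) %in% rg)
  }
  pres <- presenceCells(occB, shape)
  absRec <- stratifiedPseudoabsences(occB, strata, backgroundCells,
                                     seed = seed)
  absCells <- .cellIndex(absRec$row, absRec$col, shape)
  map <- predictSuitability(ens, env)
  cells <- c(pres, absCells)
  labels <- c(rep(1L, length(pres)), rep(0L, length(absCells)))
  aucScore(labels, as.vector(map@scores)[cells])
}
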