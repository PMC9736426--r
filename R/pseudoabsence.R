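#' @include accessors.R
NULL

#' Largest-remainder apportionment
#'
#' Allocates n items across groups proportionally to group sizes: each
#' group first receives the floor of its exact quota, then the remaining
#' items go to the groups with the largest fractional remainders (ties
#' broken by group order).
#'
#' @param sizes positive group sizes.
#' @param n total items to allocate.
#' @return integer allocation summing to n, no entry exceeding its size.
#' @export
largestRemainder <- function(sizes, n) {
  quota <- n * sizes / sum(sizes)
  alloc <- floor(quota)
  left <- n - sum(alloc)
  if (left > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
  }
  # cap at group size, redistributing any spillover to groups with room
  over <- alloc > sizes
  while (any(over)) {
    spill <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    room <- which(alloc < sizes)
    if (!length(room) || spill == 0) break
    ord <- room[order(sizes[room] - alloc[room], decreasing = TRUE)]
    for (i in ord) {
      if (spill == 0) break
      add <- min(spill, sizes[i] - alloc[i])
      alloc[i] <- alloc[i] + add
      spill <- spill - add
    }
    over <- alloc > sizes
  }
  as.integer(alloc)
}

#' Environmentally stratified pseudo-absence sample
#'
#' Draws background cells to stand in for absences when only presences are
#' known. Absences are spread across environmental strata proportionally to
#' each stratum's background size (largest-remainder rounding) and sampled
#' uniformly without replacement within a stratum, so the sample tracks the
#' available environmental gradient instead of clumping. Presence cells are
#' always excluded from the background.
#'
#' @param presences an \code{OccurrenceSet} (its presence cells are
#'   excluded from the background).
#' @param strata a \code{StrataMap}.
#' @param backgroundCells linear indices of candidate background cells.
#' @param n number of pseudo-absences; defaults to the presence count,
#'   matching samples of equal size to the presences.
#' @param seed integer seed.
#' @return data.frame with columns row, col, presence (all 0).
#' @export
stratifiedPseudoabsences <- function(presences, strata, backgroundCells,
                                     n = NULL, seed = 1) {
  stopifnot(is(presences, "OccurrenceSet"), is(strata, "StrataMap"))
  shape <- gridShape(strata)
  pres <- presenceCells(presences, shape)
  if (is.null(n)) n <- length(pres)
  bg <- setdiff(backgroundCells, pres)
  if (n > length(bg))
    stop("background (", length(bg), " cells) smaller than n = ", n,
         call. = FALSE)
  set.seed(as.integer(seed))
  sid <- as.vector(strata@strata)[bg]
  groups <- split(bg, sid)
  alloc <- largestRemainder(lengths(groups), n)
  cells <- unlist(lapply(seq_along(groups), function(k) {
    if (alloc[k] == 0L) return(integer())
    g <- groups[[k]]
    if (length(g) == 1L) g else sample(g, alloc[k])
  }), use.names = FALSE)
  rc <- .cellRowCol(cells, shape)
  data.frame(row = rc[, "row"], col = rc[, "col"], presence = 0L)
}

#' Assemble a presence-absence training sample with climate predictors
#'
#' Combines presence records with absences (explicit atlas absences when
#' the occurrence design provides them, otherwise stratified
#' pseudo-absences) and attaches the climate predictor values of each cell.
#'
#' @param occ an \code{OccurrenceSet}.
#' @param env an \code{EnvStack}.
#' @param strata a \code{StrataMap} (used only when pseudo-absences are
#'   needed).
#' @param backgroundCells candidate background cells for pseudo-absences;
#'   default all cells of the occurrence region.
#' @param predictors predictor variables, default BIO5, BIO6, BIO12.
#' @param seed integer seed for the pseudo-absence draw.
#' @return data.frame with presence, provenance and predictor columns.
#' @export
buildTrainingSample <- function(occ, env, strata, backgroundCells = NULL,
                                predictors = CLIMATE_VARIABLES, seed = 1) {
  stopifnot(is(occ, "OccurrenceSet"), is(env, "EnvStack"))
  shape <- gridShape(env)
  rec <- occRecords(occ)
  rec$cell <- .cellIndex(rec$row, rec$col, shape)
  if (any(rec$presence == 0L)) {
    rec$provenance <- ifelse(rec$presence == 1L, "presence", "true_absence")
    out <- rec
  } else {
    if (is.null(backgroundCells)) {
      rg <- strsplit(occ@region, "+", fixed = TRUE)[[1]]
      backgroundCells <- if (identical(occ@region, "all")) seq_len(prod(shape))
        else which(as.vector(env@regionMask) %in% rg)
    }
    abs <- stratifiedPseudoabsences(occ, strata, backgroundCells, seed = seed)
    abs$cell <- .cellIndex(abs$row, abs$col, shape)
    abs$provenance <- "pseudo_absence"
    rec$provenance <- "presence"
    out <- rbind(rec, abs)
  }
  X <- envAsMatrix(env, predictors)
  cbind(out, as.data.frame(X[out$cell, , drop = FALSE]))
}

#' Stratified 70/30 train/test split
#'
#' Randomly splits a presence-absence sample into a training subset (70%
#' by default) and a testing subset, stratified by the presence label so
#' both classes appear on both sides. The split is disjoint and exhaustive.
#'
#' @param sample data.frame with a \code{presence} column.
#' @param trainFraction fraction for training, default 0.7.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} data.frames.
#' @export
splitSample <- function(sample, trainFraction = 0.7, seed = 1) {
  counts <- table(factor(sample$presence, levels = c(0L, 1L)))
  if (any(counts < 2L))
    stop("each class needs at least 2 records to split", call. = FALSE)
  set.seed(as.integer(seed))
  trainIdx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(sample$presence == cl)
    k <- min(max(1L, round(trainFraction * length(idx))), length(idx) - 1L)
    sample(idx, k)
  }), use.names = FALSE)
  list(train = sample[sort(trainIdx), , drop = FALSE],
       test = sample[setdiff(seq_len(nrow(sample)), trainIdx), , drop = FALSE])
}
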