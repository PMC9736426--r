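#' @include auc.R
NULL

# --- hinge-basis machinery shared by MARS and FDA -------------------------

# knot grid per variable: interior quantiles of the training data
.hingeKnots <- function(X, probs = c(0.25, 0.5, 0.75)) {
  lapply(as.data.frame(X), function(x) unique(stats::quantile(x, probs)))
}

# expand data into paired hinge columns max(x-k,0) / max(k-x,0)
.hingeBasis <- function(X, knots) {
  cols <- list()
  for (v in names(knots)) {
    for (k in knots[[v]]) {
      cols[[paste0("h(", v, "-", signif(k, 6), ")")]] <- pmax(X[, v] - k, 0)
      cols[[paste0("h(", signif(k, 6), "-", v, ")")]] <- pmax(k - X[, v], 0)
    }
  }
  do.call(cbind, cols)
}

.deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Forward/backward selection of hinge pairs on a logistic link: hinge pairs
# enter greedily by deviance reduction, then a backward pass prunes pairs
# whose removal lowers AIC. Small and deterministic.
.fitMars <- function(y, X, maxPairs = NULL) {
  knots <- .hingeKnots(X)
  B <- .hingeBasis(X, knots)
  npairs <- ncol(B) / 2L
  if (is.null(maxPairs)) maxPairs <- min(npairs, max(2L, ncol(X) * 2L))
  selected <- integer()
  refit <- function(sel) {
    d <- data.frame(y = y)
    if (length(sel)) {
      Bi <- B[, .pairCols(sel), drop = FALSE]
      colnames(Bi) <- paste0("b", seq_len(ncol(Bi)))
      d <- cbind(d, as.data.frame(Bi))
    }
    suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  }
  fit <- refit(selected)
  dev <- fit$deviance
  while (length(selected) < maxPairs) {
    cand <- setdiff(seq_len(npairs), selected)
    devs <- vapply(cand, function(p) refit(c(selected, p))$deviance, numeric(1))
    best <- which.min(devs)
    if (dev - devs[best] < 4) break  # ~ chi^2 cost of 2 extra df
    selected <- c(selected, cand[best])
    dev <- devs[best]
  }
  # backward prune by AIC
  repeat {
    if (length(selected) < 2L) break
    aic0 <- refit(selected)$aic
    aics <- vapply(seq_along(selected),
                   function(i) refit(selected[-i])$aic, numeric(1))
    if (min(aics) >= aic0) break
    selected <- selected[-which.min(aics)]
  }
  fit <- refit(selected)
  list(glm = fit, knots = knots, selected = selected)
}

.pairCols <- function(pairs) as.vector(rbind(2L * pairs - 1L, 2L * pairs))

.predictMars <- function(m, X) {
  B <- .hingeBasis(X, m$knots)
  d <- if (length(m$selected)) {
    Bi <- B[, .pairCols(m$selected), drop = FALSE]
    colnames(Bi) <- paste0("b", seq_len(ncol(Bi)))
    as.data.frame(Bi)
  } else data.frame(row.names = seq_len(nrow(X)))
  as.vector(stats::predict(m$glm, newdata = d, type = "response"))
}

# drop columns that are (near-)constant or linearly dependent
.independentCols <- function(B) {
  keep <- which(apply(B, 2, stats::sd) > 1e-10)
  B2 <- B[, keep, drop = FALSE]
  q <- qr(scale(B2))
  keep[q$pivot[seq_len(q$rank)]]
}

# Flexible discriminant analysis: LDA on the full hinge-basis expansion,
# scored by the posterior probability of the presence class.
.fitFda <- function(y, X) {
  knots <- .hingeKnots(X)
  B <- cbind(as.matrix(X), .hingeBasis(X, knots))
  cols <- .independentCols(B)
  fit <- MASS::lda(B[, cols, drop = FALSE], grouping = factor(y))
  list(lda = fit, knots = knots, cols = cols)
}

.predictFda <- function(m, X) {
  B <- cbind(as.matrix(X), .hingeBasis(X, m$knots))
  p <- stats::predict(m$lda, B[, m$cols, drop = FALSE])$posterior
  as.vector(p[, "1"])
}

# --- the five families ----------------------------------------------------

.glmFormula <- function(predictors) {
  terms <- paste(vapply(predictors, function(v)
    sprintf("%s + I(%s^2)", v, v), ""), collapse = " + ")
  stats::as.formula(paste("presence ~", terms))
}

.gamFormula <- function(predictors, k) {
  terms <- paste(sprintf("s(%s, k = %d)", predictors, k), collapse = " + ")
  stats::as.formula(paste("presence ~", terms))
}

#' Fit one ensemble member
#'
#' Trains a presence-absence classifier of one of the five model families
#' on a training sample, returning predictions on the probability scale.
#' Families: \code{GLM} — logistic regression with linear and quadratic
#' terms; \code{GAM} — logistic additive model with thin-plate smooths
#' (mgcv, REML); \code{MARS} — forward/backward hinge-basis selection on a
#' logistic link; \code{GBM} — gradient-boosted shallow trees (xgboost);
#' \code{FDA} — linear discriminant analysis on the hinge-basis expansion.
#' All fits are deterministic given the data and hyperparameters.
#'
#' @param family one of \code{"GLM"}, \code{"GAM"}, \code{"MARS"},
#'   \code{"GBM"}, \code{"FDA"}.
#' @param train data.frame with \code{presence} and predictor columns.
#' @param predictors predictor variable names, default BIO5, BIO6, BIO12.
#' @param replicate replicate id recorded on the member.
#' @param hyperparams optional list: \code{gam_k} (basis size, default 5),
#'   \code{gbm_depth} (default 3), \code{gbm_eta} (default 0.1),
#'   \code{gbm_rounds} (default 80).
#' @return a \code{FittedMember} (test AUC unset until evaluation).
#' @export
fitMember <- function(family, train, predictors = CLIMATE_VARIABLES,
                      replicate = 1L, hyperparams = list()) {
  if (!family %in% MODEL_FAMILIES)
    stop("unknown model family: ", family, call. = FALSE)
  hp <- utils::modifyList(
    list(gam_k = 5L, gbm_depth = 3L, gbm_eta = 0.1, gbm_rounds = 80L),
    hyperparams)
  y <- train$presence
  X <- train[, predictors, drop = FALSE]
  model <- tryCatch(switch(family,
    GLM = suppressWarnings(
      stats::glm(.glmFormula(predictors), data = train,
                 family = stats::binomial())),
    GAM = mgcv::gam(.gamFormula(predictors, hp$gam_k), data = train,
                    family = stats::binomial(), method = "REML"),
    MARS = .fitMars(y, X),
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$gbm_depth,
                    eta = hp$gbm_eta, nthread = 1L, seed = 1L),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1L),
      nrounds = hp$gbm_rounds, verbose = 0),
    FDA = .fitFda(y, X)
  ), error = function(e)
    stop(sprintf("%s fit failed (replicate %d): %s", family, replicate,
                 conditionMessage(e)), call. = FALSE))
  new("FittedMember", family = family, replicate = as.integer(replicate),
      model = model, testAuc = NA_real_)
}

#' Predict from one fitted member
#'
#' @param member a \code{FittedMember}.
#' @param newdata data.frame or matrix carrying the predictor columns.
#' @param predictors predictor names, default BIO5, BIO6, BIO12.
#' @return probabilities in [0, 1].
#' @export
predictMember <- function(member, newdata, predictors = CLIMATE_VARIABLES) {
  stopifnot(is(member, "FittedMember"))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(predictors, names(newdata))
  if (length(missing))
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- newdata[, predictors, drop = FALSE]
  p <- switch(member@family,
    GLM = stats::predict(member@model, newdata = newdata, type = "response"),
    GAM = as.vector(stats::predict(member@model, newdata = newdata,
                                   type = "response")),
    MARS = .predictMars(member@model, X),
    GBM = stats::predict(member@model,
                         xgboost::xgb.DMatrix(as.matrix(X), nthread = 1L)),
    FDA = .predictFda(member@model, X))
  pmin(pmax(as.vector(p), 0), 1)
}
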