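# toy training frame with a clean BIO5 separation between classes
separableSample <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    presence = rep(c(1L, 0L), each = n),
    BIO5 = c(runif(n, 30, 40), runif(n, 15, 25)),
    BIO6 = runif(2 * n, -5, 10),
    BIO12 = runif(2 * n, 200, 1500))
}

test_that("largest-remainder apportionment matches hand computations", {
  expect_identical(largestRemainder(c(30, 10), 8), c(6L, 2L))
  expect_identical(largestRemainder(c(7, 5, 3), 7), c(3L, 2L, 2L))
  expect_identical(sum(largestRemainder(c(13, 7, 11, 3), 20)), 20L)
  # allocation never exceeds a group's size
  expect_identical(largestRemainder(c(2, 100), 50), c(1L, 49L))
})

test_that("stratified pseudo-absences follow background strata proportions", {
  env <- tinyEnv(seed = 1)
  sp <- midSpecies()
  occ <- sampleOccurrences(sp, env, 50, "presence_only", seed = 2)
  strata <- generateStrata(c(30, 30), 3, seed = 3)
  bg <- seq_len(900)
  abs <- stratifiedPseudoabsences(occ, strata, bg, seed = 4)
  expect_identical(nrow(abs), 50L)   # equal size to the presences
  expect_true(all(abs$presence == 0L))
  cells <- (abs$col - 1L) * 30L + abs$row
  pres <- presenceCells(occ, c(30, 30))
  expect_length(intersect(cells, pres), 0)
  expect_false(anyDuplicated(cells) > 0)
  # allocation across strata equals largest-remainder apportionment
  sid <- as.vector(strata@strata)
  sizes <- table(sid[setdiff(bg, pres)])
  expected <- largestRemainder(as.vector(sizes), 50)
  got <- table(factor(sid[cells], levels = names(sizes)))
  expect_identical(as.vector(got), expected)
  expect_error(stratifiedPseudoabsences(occ, strata, bg[1:10], n = 50),
               "smaller")
})

test_that("70/30 splits are stratified, disjoint and exhaustive", {
  samp <- data.frame(presence = rep(c(1L, 0L), each = 50),
                     BIO5 = rnorm(100))
  sp <- splitSample(samp, seed = 1)
  expect_identical(nrow(sp$train), 70L)
  expect_identical(nrow(sp$test), 30L)
  expect_identical(sum(sp$train$presence), 35L)
  expect_identical(sum(sp$test$presence), 15L)
  recombined <- rbind(sp$train, sp$test)
  expect_identical(sort(as.integer(rownames(recombined))), 1:100)
  for (seed in 1:10) {
    s2 <- splitSample(samp, seed = seed)
    expect_lte(abs(sum(s2$train$presence) - 35), 1)
  }
  expect_error(splitSample(data.frame(presence = c(1L, 0L, 0L))), "at least 2")
})

test_that("every family separates a separable toy problem", {
  train <- separableSample()
  for (fam in c("GLM", "GAM", "MARS", "GBM", "FDA")) {
    # perfect separation legitimately makes likelihood-based fits complain
    m <- suppressWarnings(fitMember(fam, train))
    p <- predictMember(m, train)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(aucScore(train$presence, p), 1,
                 tolerance = 1e-12, label = fam)
  }
  expect_error(fitMember("MAXENT", train), "unknown")
})

test_that("families hover near AUC 0.5 when labels carry no signal", {
  for (fam in c("GLM", "GAM", "MARS", "GBM", "FDA")) {
    aucs <- vapply(1:3, function(seed) {
      set.seed(seed)
      d <- data.frame(presence = rbinom(500, 1, 0.5),
                      BIO5 = runif(500, 15, 45),
                      BIO6 = runif(500, -15, 15),
                      BIO12 = runif(500, 100, 2000))
      sp <- splitSample(d, seed = seed)
      m <- fitMember(fam, sp$train)
      aucScore(sp$test$presence, predictMember(m, sp$test))
    }, numeric(1))
    expect_gt(mean(aucs), 0.4, label = fam)
    expect_lt(mean(aucs), 0.6, label = fam)
  }
})

test_that("GLM recovers known logistic coefficients within 3 SE", {
  set.seed(21)
  n <- 2000
  X <- data.frame(BIO5 = rnorm(n), BIO6 = rnorm(n), BIO12 = rnorm(n))
  eta <- 1 * X$BIO5 - 1 * X$BIO6 + 0 * X$BIO12
  d <- cbind(presence = rbinom(n, 1, plogis(eta)), X)
  m <- fitMember("GLM", d)
  est <- coef(m@model)
  se <- sqrt(diag(vcov(m@model)))
  truth <- c(BIO5 = 1, BIO6 = -1, BIO12 = 0)
  for (v in names(truth))
    expect_lt(abs(est[[v]] - truth[[v]]), 3 * se[[v]])
  # oracle: an independent maximum-likelihood fit on the same draw
  oracle <- glm(presence ~ BIO5 + BIO6 + BIO12, data = d, family = binomial())
  for (v in names(truth))
    expect_lt(abs(est[[v]] - coef(oracle)[[v]]), 0.15)
})

test_that("ensembles retain by strict AUC threshold and weight by AUC", {
  env <- tinyEnv(seed = 5)
  sp <- midSpecies()
  occ <- sampleOccurrences(sp, env, 60, "presence_only", seed = 6)
  strata <- generateStrata(c(30, 30), 3, seed = 7)
  ens <- buildEnsemble(occ, env, strata, R = 2, seed = 8)
  tab <- evalTable(ens)
  expect_identical(nrow(tab), 10L)  # 2 replicates x 5 families
  expect_true(all(tab$retained == (tab$test_auc > 0.7)))
  expect_true(all(tab$weight[!tab$retained] == 0))
  w <- memberWeights(ens)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-10)
  expect_equal(w, tab$test_auc[tab$retained] / sum(tab$test_auc[tab$retained]))
  agg <- aucSummary(ens)
  expect_identical(nrow(agg), 5L)
  expect_true(all(agg$mean_auc >= 0 & agg$mean_auc <= 1))
  # an impossible threshold empties the ensemble
  expect_error(buildEnsemble(occ, env, strata, R = 1, families = "GLM",
                             aucThreshold = 1, seed = 8), "empty ensemble")
})

# members whose intercept-only fits emit constant probabilities let the
# weighted-consensus arithmetic be checked by hand
constantMember <- function(p, auc, replicate = 1L) {
  y <- c(rep(1, round(p * 10)), rep(0, 10 - round(p * 10)))
  new("FittedMember", family = "GLM", replicate = replicate,
      model = suppressWarnings(glm(y ~ 1, family = binomial())),
      testAuc = auc)
}

test_that("consensus is the AUC-weighted mean of member predictions", {
  m1 <- constantMember(0.2, 0.8)
  m2 <- constantMember(0.4, 0.9, 2L)
  ens <- new("SDMEnsemble", species = "toy", members = list(m1, m2),
             weights = c(0.8, 0.9) / 1.7, aucThreshold = 0.7,
             evalTable = data.frame(), predictors = c("BIO5", "BIO6", "BIO12"))
  map <- predictSuitability(ens, constEnv())
  expect_equal(unique(as.vector(suitabilityScores(map))),
               (0.8 * 0.2 + 0.9 * 0.4) / 1.7, tolerance = 1e-9)
  # single retained member carries weight one
  solo <- new("SDMEnsemble", species = "toy", members = list(m1),
              weights = 1, aucThreshold = 0.7, evalTable = data.frame(),
              predictors = c("BIO5", "BIO6", "BIO12"))
  expect_equal(unique(as.vector(suitabilityScores(
    predictSuitability(solo, constEnv())))), 0.2, tolerance = 1e-9)
  # invalid weights are rejected by the class
  expect_error(new("SDMEnsemble", species = "x", members = list(m1, m2),
                   weights = c(0.5, 0.2), aucThreshold = 0.7,
                   evalTable = data.frame(), predictors = "BIO5"),
               "sum to 1")
})

test_that("ensemble predictions stay within member bounds and match a loop", {
  env <- tinyEnv(c(10, 10), seed = 9, len = 20)
  sp <- midSpecies()
  occ <- sampleOccurrences(sp, env, 30, "presence_only", seed = 10)
  strata <- generateStrata(c(10, 10), 2, seed = 11)
  ens <- buildEnsemble(occ, env, strata, R = 1,
                       families = c("GLM", "GBM", "FDA"), aucThreshold = 0,
                       seed = 12)
  map <- suitabilityScores(predictSuitability(ens, env))
  newdata <- as.data.frame(envAsMatrix(env, c("BIO5", "BIO6", "BIO12")))
  preds <- sapply(ens@members, predictMember, newdata = newdata)
  w <- memberWeights(ens)
  oracle <- matrix(0, 10, 10)
  for (cell in 1:100) {
    acc <- 0
    for (k in seq_along(w)) acc <- acc + w[k] * preds[cell, k]
    oracle[cell] <- acc
  }
  expect_equal(map, oracle, tolerance = 1e-12)
  expect_true(all(map >= apply(preds, 1, min) - 1e-12))
  expect_true(all(map <= apply(preds, 1, max) + 1e-12))
})

test_that("transfer evaluation reproduces a manual AUC computation", {
  env <- tinyEnv(seed = 13)
  sp <- midSpecies()
  occ <- sampleOccurrences(sp, env, 50, "presence_only", "native", seed = 14)
  occB <- sampleOccurrences(sp, env, 40, "presence_only", "invaded", seed = 15)
  strata <- generateStrata(c(30, 30), 3, seed = 16)
  ens <- buildEnsemble(occ, env, strata, R = 2,
                       families = c("GLM", "GAM"), seed = 17)
  got <- evaluateTransfer(ens, occB, env, strata, seed = 18)
  bg <- which(as.vector(regionMask(env)) == "invaded")
  absRec <- stratifiedPseudoabsences(occB, strata, bg, seed = 18)
  absCells <- (absRec$col - 1L) * 30L + absRec$row
  pres <- presenceCells(occB, c(30, 30))
  scores <- as.vector(suitabilityScores(predictSuitability(ens, env)))
  oracle <- aucScore(c(rep(1, length(pres)), rep(0, length(absCells))),
                     scores[c(pres, absCells)])
  expect_identical(got, oracle)
  expect_gt(got, 0.5)  # a conserved niche transfers better than chance
})

test_that("a signal-free species transfers at chance level", {
  env <- tinyEnv(seed = 19)
  flat <- virtualSpecies("flat", c(BIO5 = 30), c(BIO5 = 1e6),
                         prevalence = 0.5)
  occ <- sampleOccurrences(flat, env, 60, "presence_only", "native",
                           seed = 20)
  occB <- sampleOccurrences(flat, env, 60, "presence_only", "invaded",
                            seed = 21)
  strata <- generateStrata(c(30, 30), 3, seed = 22)
  aucs <- vapply(1:5, function(seed)
    evaluateTransfer(
      buildEnsemble(occ, env, strata, R = 1, families = "GLM",
                    aucThreshold = 0, seed = seed),
      occB, env, strata, seed = seed + 50), numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("ensembles recover a known suitability surface", {
  env <- generateEnvStack(c(40, 40), autocorrelationLength = 40, seed = 23)
  sp <- midSpecies()
  occ <- sampleOccurrences(sp, env, 150, "presence_only", seed = 24)
  strata <- generateStrata(c(40, 40), 4, seed = 25)
  ens <- buildEnsemble(occ, env, strata, R = 3, seed = 26)
  map <- suitabilityScores(predictSuitability(ens, env))
  rho <- cor(as.vector(suitability(sp, env)), as.vector(map),
             method = "spearman")
  expect_gt(rho, 0.7)
})
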