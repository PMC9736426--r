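# shared fixtures: a small synthetic world and species used across tests

tinyEnv <- function(shape = c(30, 30), seed = 1, len = 40) {
  generateEnvStack(shape, cellSize = 10, autocorrelationLength = len,
                   seed = seed)
}

# a species with a broad niche centred inside the realized climate
midSpecies <- function(name = "mid") {
  virtualSpecies(name,
                 optima = c(BIO5 = 30, BIO6 = 2, BIO12 = 800),
                 breadths = c(BIO5 = 6, BIO6 = 6, BIO12 = 400))
}

# the focal study species: the same niche response the default pipeline
# configuration assigns to the invader
focalSpecies <- function(name = "focal") {
  virtualSpecies(name,
                 optima = c(BIO5 = 33, BIO6 = 5, BIO12 = 600),
                 breadths = c(BIO5 = 4, BIO6 = 4, BIO12 = 250))
}

# a warm-edge species: both temperature optima lie beyond the warmest
# available cell, so suitability rises monotonically with warming everywhere
warmEdgeSpecies <- function(name = "warmedge") {
  virtualSpecies(name,
                 optima = c(BIO5 = 48, BIO6 = 18, BIO12 = 800),
                 breadths = c(BIO5 = 6, BIO6 = 8, BIO12 = 500))
}

# hand-built EnvStack with constant layers (BIO5 > BIO6 kept valid)
constEnv <- function(shape = c(12, 12), BIO5 = 30, BIO6 = 5, BIO12 = 800,
                     ALT = 500, SLOPE = 5) {
  mk <- function(v) matrix(v, shape[1], shape[2])
  new("EnvStack",
      layers = list(BIO5 = mk(BIO5), BIO6 = mk(BIO6), BIO12 = mk(BIO12),
                    ALT = mk(ALT), SLOPE = mk(SLOPE)),
      cellSize = 10, scenario = "current",
      regionMask = mk("other"))
}

# brute-force convex hull area: an edge (i, j) is on the hull iff every
# other point lies on its left (or on the segment); vertices are then
# ordered by angle around their centroid and the shoelace formula applied
bruteHullArea <- function(pts) {
  n <- nrow(pts)
  onHull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cross <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
             (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    if (all(cross[-c(i, j)] >= -1e-12)) onHull[c(i, j)] <- TRUE
  }
  v <- pts[onHull, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  k <- nrow(v)
  idx <- seq_len(k); nxt <- c(idx[-1], 1L)
  abs(sum(v[idx, 1] * v[nxt, 2] - v[nxt, 1] * v[idx, 2]) / 2)
}

# exhaustive concordant-pair AUC (ties count one half)
pairCountAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# a scaled-down pipeline configuration exercising every stage quickly
smallConfig <- function(baseSeed = 1) {
  cfg <- defaultConfig(baseSeed)
  cfg$grid <- list(nrow = 30L, ncol = 30L, cell_size = 10,
                   autocorrelation_length = 30)
  cfg$gcm_count <- 2L
  cfg$strata_k <- 4L
  cfg$sdm$replicates <- 2L
  cfg$sdm$families <- c("GLM", "GBM")
  cfg$species$invader$native$n <- 50L
  cfg$species$invader$invaded$n <- 30L
  cfg$species$native_lowland$invaded$n <- 250L
  cfg$species$native_upland <- NULL
  cfg
}

# Moran's I over rook neighbours on a grid
moranI <- function(m) {
  z <- m - mean(m)
  num <- sum(z[-nrow(m), ] * z[-1, ]) + sum(z[, -ncol(m)] * z[, -1])
  W <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  (length(m) / W) * (num / sum(z^2))
}
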