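test_that("PCA of collinear data loads everything on one component", {
  set.seed(1)
  x <- rnorm(50)
  X <- cbind(a = x, b = 2 * x + 1)
  ns <- fitNicheSpace(X, variables = c("a", "b"), retainedK = 1L)
  expect_equal(ns@explainedFraction[1], 1, tolerance = 1e-10)
})

test_that("independent standardized variables share variance evenly", {
  set.seed(2)
  X <- matrix(rnorm(5000 * 5), 5000, 5,
              dimnames = list(NULL, c("v1", "v2", "v3", "v4", "v5")))
  ns <- fitNicheSpace(X, variables = colnames(X))
  expect_true(all(abs(ns@explainedFraction - 0.2) < 0.05))
})

test_that("eigenstructure matches an independent decomposition", {
  set.seed(3)
  X <- matrix(rnorm(50 * 5), 50, 5,
              dimnames = list(NULL, c("v1", "v2", "v3", "v4", "v5")))
  ns <- fitNicheSpace(X, variables = colnames(X))
  oracle <- eigen(cor(X), symmetric = TRUE)
  expect_equal(ns@eigenvalues, oracle$values, tolerance = 1e-8)
  for (k in 1:5)  # loadings agree up to sign
    expect_lt(min(max(abs(ns@loadings[, k] - oracle$vectors[, k])),
                  max(abs(ns@loadings[, k] + oracle$vectors[, k]))), 1e-8)
  # trace conservation: eigenvalues sum to the number of variables
  expect_equal(sum(ns@eigenvalues), 5, tolerance = 1e-8)
  expect_equal(sum(ns@explainedFraction), 1, tolerance = 1e-10)
  # cross-check against the reference PCA implementations
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(ns@eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)
  if (requireNamespace("ade4", quietly = TRUE)) {
    # correlation is scale-invariant, so the reference PCA agrees exactly
    du <- ade4::dudi.pca(as.data.frame(X), scannf = FALSE, nf = 2)
    expect_equal(ns@eigenvalues, du$eig, tolerance = 1e-8)
  }
  expect_error(fitNicheSpace(cbind(v1 = rep(1, 10), v2 = rnorm(10)),
                             variables = c("v1", "v2")), "v1")
})

test_that("projection uses calibration statistics and conserves variance", {
  env <- tinyEnv(seed = 4)
  ns <- fitNicheSpace(env)
  ctr <- matrix(ns@center, 1, dimnames = list(NULL, names(ns@center)))
  expect_equal(as.vector(projectScores(ns, ctr)), c(0, 0), tolerance = 1e-10)
  S <- projectScores(ns, env)
  expect_equal(unname(apply(S, 2, var)), ns@eigenvalues[1:2],
               tolerance = 1e-8)
  p <- envAsMatrix(env)[c(5, 5), ]
  sc <- projectScores(ns, p)
  expect_identical(sc[1, ], sc[2, ])
  expect_error(projectScores(ns, matrix(1, 1, 1, dimnames = list(NULL, "x"))),
               "lack")
})

test_that("convex hull contains its points and is idempotent", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
              c(0.5, 0.5), c(0.2, 0.8))
  h <- convexHull(sq, "sq")
  expect_equal(hullArea(h), 1)
  expect_identical(nrow(hullVertices(h)), 4L)
  h2 <- convexHull(hullVertices(h), "sq")
  expect_equal(hullArea(h2), hullArea(h))
  expect_equal(pointsOutside(sq, h)$count, 0)
  expect_error(convexHull(cbind(1:5, 2 * (1:5))), "collinear")
  expect_error(convexHull(sq[1:2, ]), "3 points")
})

test_that("hull area matches the brute-force triple-enumeration oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    pts <- cbind(rnorm(30), rnorm(30))
    h <- convexHull(pts)
    expect_equal(hullArea(h), bruteHullArea(pts), tolerance = 1e-9)
  }
})

test_that("hull overlap behaves as a convex intersection measure", {
  sq <- convexHull(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)), "A")
  self <- hullOverlap(sq, sq)
  expect_equal(self$fraction_of_a, 1)
  expect_equal(self$fraction_of_b, 1)
  far <- convexHull(rbind(c(10, 10), c(11, 10), c(10.5, 11)), "B")
  expect_equal(hullOverlap(sq, far)$area_intersection, 0)
  # partial: unit square shifted by 0.5 in x overlaps in a 1.5 x 2 strip
  sh <- convexHull(rbind(c(0.5, 0), c(2.5, 0), c(2.5, 2), c(0.5, 2)), "C")
  ov <- hullOverlap(sq, sh)
  expect_equal(ov$area_intersection, 3)
  expect_equal(ov$fraction_of_a, 0.75)
  # symmetry of the intersection area
  ba <- hullOverlap(sh, sq)
  expect_equal(ov$area_intersection, ba$area_intersection, tolerance = 1e-10)
})

test_that("intersection area agrees with Monte-Carlo integration", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- convexHull(cbind(rnorm(25), rnorm(25)), "a")
    b <- convexHull(cbind(rnorm(25, 0.8), rnorm(25, 0.5)), "b")
    ov <- hullOverlap(a, b)
    va <- hullVertices(a); vb <- hullVertices(b)
    lo <- pmin(apply(va, 2, min), apply(vb, 2, min))
    hi <- pmax(apply(va, 2, max), apply(vb, 2, max))
    set.seed(seed + 100)
    px <- runif(1e6, lo[1], hi[1]); py <- runif(1e6, lo[2], hi[2])
    inA <- {
      out <- logical(1e6)
      v <- va; n <- nrow(v)
      for (i in seq_len(n)) {
        p1 <- v[i, ]; p2 <- v[if (i == n) 1L else i + 1L, ]
        out <- out | ((p2[1] - p1[1]) * (py - p1[2]) -
                        (p2[2] - p1[2]) * (px - p1[1]) < 0)
      }
      !out
    }
    inB <- {
      out <- logical(1e6)
      v <- vb; n <- nrow(v)
      for (i in seq_len(n)) {
        p1 <- v[i, ]; p2 <- v[if (i == n) 1L else i + 1L, ]
        out <- out | ((p2[1] - p1[1]) * (py - p1[2]) -
                        (p2[2] - p1[2]) * (px - p1[1]) < 0)
      }
      !out
    }
    mc <- mean(inA & inB) * prod(hi - lo)
    expect_equal(ov$area_intersection, mc, tolerance = 0.005)
  }
})

test_that("overlap never increases when one hull shrinks", {
  set.seed(8)
  a <- convexHull(cbind(rnorm(40), rnorm(40)), "a")
  b <- convexHull(cbind(rnorm(40, 0.5), rnorm(40)), "b")
  full <- hullOverlap(a, b)$area_intersection
  vb <- hullVertices(b)
  for (drop in seq_len(nrow(vb))) {
    if (nrow(vb) <= 3) break
    smaller <- convexHull(vb[-drop, , drop = FALSE], "b2")
    expect_lte(hullOverlap(a, smaller)$area_intersection, full + 1e-10)
  }
})

test_that("points outside the hull are counted by strict exteriority", {
  h <- convexHull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "sq")
  ctr <- matrix(rep(0.5, 20), ncol = 2)
  expect_equal(pointsOutside(ctr, h), list(count = 0L, fraction = 0))
  pts <- rbind(matrix(rep(0.5, 18), ncol = 2), c(5, 5))
  expect_equal(pointsOutside(pts, h)$count, 1)
  expect_equal(pointsOutside(pts, h)$fraction, 0.1)
  # boundary points are inside
  expect_equal(pointsOutside(rbind(c(0, 0), c(1, 0.5), c(0.5, 1)), h)$count, 0)
  # seeded points against the per-edge sign-test oracle
  set.seed(5)
  cloud <- cbind(rnorm(200, 0.5, 0.6), rnorm(200, 0.5, 0.6))
  got <- pointsOutside(cloud, h)$count
  oracle <- sum(cloud[, 1] < 0 | cloud[, 1] > 1 | cloud[, 2] < 0 | cloud[, 2] > 1)
  expect_identical(as.integer(got), as.integer(oracle))
})

test_that("two samples of one niche in disjoint regions conserve the niche", {
  # a 20 km correlation length keeps the two disjoint regions climatically
  # exchangeable, which is what makes a twin-population comparison valid
  fracOut <- numeric(10); ovAB <- numeric(10); ovBA <- numeric(10)
  for (seed in 1:10) {
    env <- generateEnvStack(c(80, 80), autocorrelationLength = 20,
                            seed = seed)
    sp <- midSpecies()
    a <- sampleOccurrences(sp, env, 400, "presence_only", "native",
                           seed = seed * 2)
    b <- sampleOccurrences(sp, env, 400, "presence_only", "invaded",
                           seed = seed * 2 + 1)
    ns <- fitNicheSpace(env)
    S <- projectScores(ns, env)
    sa <- S[presenceCells(a, c(80, 80)), ]
    sb <- S[presenceCells(b, c(80, 80)), ]
    ha <- convexHull(sa, "a"); hb <- convexHull(sb, "b")
    fracOut[seed] <- pointsOutside(sb, ha)$fraction
    ov <- hullOverlap(ha, hb)
    ovAB[seed] <- ov$fraction_of_a; ovBA[seed] <- ov$fraction_of_b
  }
  expect_lt(mean(fracOut), 0.10)
  expect_gt(mean(ovAB), 0.8)
  expect_gt(mean(ovBA), 0.8)
})
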