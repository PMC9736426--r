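#' @include accessors.R
NULL

# signed (shoelace) area; positive for counter-clockwise vertex order
.polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i <- seq_len(nrow(v)); j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x[i] * y[j] - x[j] * y[i]) / 2
}

#' Fit the shared principal-component environmental space
#'
#' Correlation PCA of the calibration cells: each variable is centred and
#' scaled by its calibration mean and sample standard deviation (n - 1),
#' and the correlation matrix is eigen-decomposed. Components are ordered
#' by explained variance; the first two (default) span the plane in which
#' species environmental spaces are delimited and compared. Calibrating on
#' the full study area (every cell, both ranges pooled) puts all species in
#' one common environmental space.
#'
#' @param env an \code{EnvStack}, or a numeric matrix of calibration
#'   observations with variables in columns.
#' @param calibrationCells linear cell indices to calibrate on; default all
#'   cells (ignored when \code{env} is already a matrix).
#' @param variables variables to include, default all five.
#' @param retainedK number of components used for niche delimitation,
#'   default 2.
#' @return a \code{NicheSpace}.
#' @export
fitNicheSpace <- function(env, calibrationCells = NULL,
                          variables = ENV_VARIABLES, retainedK = 2L) {
  X <- if (is(env, "EnvStack")) envAsMatrix(env, variables) else as.matrix(env)
  if (!is.null(calibrationCells) && is(env, "EnvStack"))
    X <- X[calibrationCells, , drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- variables[seq_len(ncol(X))]
  if (nrow(X) < retainedK + 1L)
    stop("need at least retainedK + 1 calibration cells", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- names(scl)[scl < 1e-12]
  if (length(zero))
    stop("zero-variance variable(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  C <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  # fix the sign convention: largest-magnitude loading of each component
  # is positive, so results are reproducible across eigen-solvers
  for (k in seq_len(ncol(load))) {
    m <- which.max(abs(load[, k]))
    if (load[m, k] < 0) load[, k] <- -load[, k]
  }
  new("NicheSpace", center = ctr, scale = scl, loadings = load,
      eigenvalues = ev, explainedFraction = ev / sum(ev),
      retainedK = as.integer(retainedK))
}

#' @describeIn projectScores scores for rows of an environment matrix
#' @export
setMethod("projectScores", signature("NicheSpace", "matrix"),
  function(ns, points) {
    vars <- names(ns@center)
    missing <- setdiff(vars, colnames(points))
    if (length(missing))
      stop("points lack variable(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    Z <- sweep(sweep(points[, vars, drop = FALSE], 2, ns@center),
               2, ns@scale, `/`)
    S <- Z %*% ns@loadings[, seq_len(ns@retainedK), drop = FALSE]
    colnames(S) <- paste0("PC", seq_len(ns@retainedK))
    S
  })

#' @describeIn projectScores scores for rows of a data.frame
#' @export
setMethod("projectScores", signature("NicheSpace", "data.frame"),
  function(ns, points) projectScores(ns, as.matrix(points)))

#' @describeIn projectScores scores for every cell of an EnvStack
#' @export
setMethod("projectScores", signature("NicheSpace", "EnvStack"),
  function(ns, points) projectScores(ns, envAsMatrix(points)))

#' Maximum convex polygon of a set of PC scores
#'
#' The minimal convex polygon containing every projected occurrence — the
#' species' delimited environmental space. Vertices are returned in
#' counter-clockwise order.
#'
#' @param scores n x 2 matrix of (PC1, PC2) scores, n >= 3.
#' @param species species label attached to the hull.
#' @return a \code{HullPolygon}.
#' @export
convexHull <- function(scores, species = "unnamed") {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("need at least 3 points", call. = FALSE)
  idx <- grDevices::chull(scores[, 1], scores[, 2])
  v <- scores[idx, , drop = FALSE]
  if (nrow(v) < 3L || abs(.polygonArea(v)) < 1e-12)
    stop("points are collinear; hull is degenerate", call. = FALSE)
  if (.polygonArea(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  colnames(v) <- c("PC1", "PC2")
  rownames(v) <- NULL
  new("HullPolygon", species = species, vertices = v)
}

#' Area of a hull polygon
#' @param hull a \code{HullPolygon}.
#' @return area in squared PC units.
#' @export
hullArea <- function(hull) {
  stopifnot(is(hull, "HullPolygon"))
  .polygonArea(hull@vertices)
}

# Sutherland-Hodgman clipping of convex polygon subj by convex CCW clip;
# returns a vertex matrix (possibly with < 3 rows when the intersection
# is empty or degenerate)
.clipConvex <- function(subj, clip) {
  out <- subj
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    # inside = left of directed edge a->b for a CCW clip polygon
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    sv <- apply(inp, 1, side)
    for (j in seq_len(m)) {
      k <- if (j == m) 1L else j + 1L
      cur <- inp[j, ]; nxt <- inp[k, ]
      if (sv[j] >= 0) out <- rbind(out, cur)
      if ((sv[j] >= 0) != (sv[k] >= 0)) {
        t <- sv[j] / (sv[j] - sv[k])
        out <- rbind(out, cur + t * (nxt - cur))
      }
    }
  }
  out
}

#' Niche overlap between two hull polygons
#'
#' Intersects the two convex environmental spaces by half-plane clipping
#' and reports the intersection area both in absolute PC units and as a
#' fraction of each species' own hull area. The intersection of spaces is
#' the niche-overlap measure; reporting both fractions keeps the measure
#' interpretable whichever species is the denominator.
#'
#' @param a,b \code{HullPolygon}s.
#' @return data.frame with species_a, species_b, area_a, area_b,
#'   area_intersection, fraction_of_a, fraction_of_b.
#' @export
hullOverlap <- function(a, b) {
  stopifnot(is(a, "HullPolygon"), is(b, "HullPolygon"))
  inter <- .clipConvex(a@vertices, b@vertices)
  areaI <- if (nrow(inter) >= 3L) abs(.polygonArea(inter)) else 0
  areaA <- hullArea(a); areaB <- hullArea(b)
  areaI <- min(areaI, areaA, areaB)  # guard float overshoot
  data.frame(species_a = a@species, species_b = b@species,
             area_a = areaA, area_b = areaB, area_intersection = areaI,
             fraction_of_a = areaI / areaA, fraction_of_b = areaI / areaB)
}

#' Count scores falling strictly outside a hull
#'
#' Boundary points count as inside: a score is outside only if it lies
#' strictly beyond some hull edge (beyond a small numerical tolerance
#' scaled to the hull size). Used to diagnose niche shift — occurrences of
#' an invading population outside the native environmental space.
#'
#' @param scores n x 2 matrix of PC scores.
#' @param hull a \code{HullPolygon}.
#' @return list with \code{count} and \code{fraction}.
#' @export
pointsOutside <- function(scores, hull) {
  stopifnot(is(hull, "HullPolygon"))
  scores <- as.matrix(scores)
  v <- hull@vertices
  n <- nrow(v)
  tol <- 1e-9 * max(1, max(abs(v)))
  outside <- rep(FALSE, nrow(scores))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (scores[, 2] - a[2]) -
             (b[2] - a[2]) * (scores[, 1] - a[1])
    outside <- outside | (cross < -tol)
  }
  list(count = sum(outside), fraction = mean(outside))
}
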