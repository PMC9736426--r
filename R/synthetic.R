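#' @include accessors.R
NULL

# linear index helpers (column-major, R convention)
.cellIndex <- function(row, col, shape) (col - 1L) * shape[1] + row
.cellRowCol <- function(idx, shape) {
  cbind(row = ((idx - 1L) %% shape[1]) + 1L,
        col = ((idx - 1L) %/% shape[1]) + 1L)
}

# Gaussian-smoothed white noise via circular FFT convolution. The kernel sd
# is expressed in cells; the periodic wrap is harmless for a synthetic world.
.smoothField <- function(nrow, ncol, lengthCells) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (lengthCells < 1e-8) return(z)
  kr <- stats::dnorm(.circDist(nrow), sd = lengthCells)
  kc <- stats::dnorm(.circDist(ncol), sd = lengthCells)
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nrow * ncol)
}

.circDist <- function(n) {
  d <- seq_len(n) - 1L
  pmin(d, n - d)
}

.rescaleRange <- function(m, lo, hi) {
  r <- range(m)
  if (r[2] - r[1] < 1e-12) return(m * 0 + (lo + hi) / 2)
  lo + (m - r[1]) / (r[2] - r[1]) * (hi - lo)
}

# Default region layout: westernmost 40% of columns are the native range,
# easternmost 40% the invaded range, the strip between is "other".
.defaultRegionMask <- function(shape) {
  cols <- seq_len(shape[2])
  lab <- ifelse(cols <= floor(0.4 * shape[2]), "native",
                ifelse(cols > ceiling(0.6 * shape[2]), "invaded", "other"))
  matrix(rep(lab, each = shape[1]), shape[1], shape[2])
}

#' Generate a spatially autocorrelated environmental stack
#'
#' Builds the five-layer synthetic world: each layer is Gaussian-kernel
#' smoothed white noise rescaled to a realistic range (BIO5 in [15, 45] deg C,
#' BIO6 in [-15, 15] deg C, BIO12 in [100, 2000] mm, ALT in [0, 3000] m,
#' SLOPE in [0, 30] deg), with \code{BIO5 > BIO6} enforced cellwise. The
#' smoothing length controls spatial autocorrelation, standing in for the
#' smooth structure of interpolated climate surfaces. Layers are loosely
#' coupled (BIO6 and BIO12 share part of their field with ALT) so the world
#' has the temperature-altitude-precipitation structure real landscapes do.
#'
#' @param gridShape integer (rows, cols), at least 10 x 10.
#' @param cellSize cell edge length (abstract km), default 10.
#' @param autocorrelationLength correlation length in km (> 0).
#' @param seed integer seed; identical seeds give identical stacks.
#' @param regionMask optional character matrix of region labels; defaults
#'   to a native / other / invaded west-to-east split.
#' @return an \code{EnvStack} with scenario \code{"current"}.
#' @examples
#' env <- generateEnvStack(c(30, 30), autocorrelationLength = 50, seed = 1)
#' range(envLayer(env, "BIO12"))
#' @export
generateEnvStack <- function(gridShape, cellSize = 10,
                             autocorrelationLength = 50, seed = 1,
                             regionMask = NULL) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 2L || any(gridShape < 10L))
    stop("gridShape must be (rows, cols) with both >= 10", call. = FALSE)
  if (autocorrelationLength <= 0)
    stop("autocorrelationLength must be positive", call. = FALSE)
  if (cellSize <= 0) stop("cellSize must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  len <- autocorrelationLength / cellSize
  nr <- gridShape[1]; nc <- gridShape[2]
  f <- replicate(6, .smoothField(nr, nc, len), simplify = FALSE)
  alt <- .rescaleRange(f[[4]], 0, 3000)
  layers <- list(
    BIO5 = .rescaleRange(f[[1]], 15, 45),
    # colder and wetter at altitude: blend independent fields with relief
    BIO6 = .rescaleRange(0.7 * scale(as.vector(f[[2]])) -
                           0.3 * scale(as.vector(alt)), -15, 15) |>
      matrix(nr, nc),
    BIO12 = .rescaleRange(0.8 * scale(as.vector(f[[3]])) +
                            0.2 * scale(as.vector(alt)), 100, 2000) |>
      matrix(nr, nc),
    ALT = alt,
    SLOPE = .rescaleRange(abs(f[[5]]) + 0.5 * abs(f[[6]]), 0, 30)
  )
  layers$BIO6 <- pmin(layers$BIO6, layers$BIO5 - 0.1)
  if (is.null(regionMask)) regionMask <- .defaultRegionMask(gridShape)
  new("EnvStack", layers = layers, cellSize = cellSize,
      scenario = "current", regionMask = regionMask)
}

#' Apply additive climate deltas to build a future stack
#'
#' Adds per-variable shifts (scalars or full fields) to the climate layers;
#' relief (ALT, SLOPE) never changes. Precipitation driven below zero is
#' clamped at zero with a warning.
#'
#' @param current an \code{EnvStack}.
#' @param deltas named list of shifts for climate variables (subset of
#'   BIO5, BIO6, BIO12); each a scalar or a matrix matching the grid.
#' @param scenarioLabel \code{"rcp26"} or \code{"rcp85"}.
#' @return a shifted \code{EnvStack}.
#' @export
makeFutureStack <- function(current, deltas, scenarioLabel) {
  stopifnot(is(current, "EnvStack"))
  if (!scenarioLabel %in% c("rcp26", "rcp85"))
    stop("scenarioLabel must be rcp26 or rcp85", call. = FALSE)
  bad <- setdiff(names(deltas), CLIMATE_VARIABLES)
  if (length(bad))
    stop("deltas only apply to climate variables, not: ",
         paste(bad, collapse = ", "), call. = FALSE)
  layers <- current@layers
  for (v in names(deltas)) layers[[v]] <- layers[[v]] + deltas[[v]]
  if (any(layers$BIO12 < 0)) {
    warning("BIO12 driven below zero by delta; clamped at 0", call. = FALSE)
    layers$BIO12 <- pmax(layers$BIO12, 0)
  }
  # keep the physical ordering of the temperature extremes under any delta
  layers$BIO6 <- pmin(layers$BIO6, layers$BIO5 - 0.1)
  new("EnvStack", layers = layers, cellSize = current@cellSize,
      scenario = scenarioLabel, regionMask = current@regionMask)
}

#' Average climate-model stacks into a single consensus stack
#'
#' Cellwise arithmetic mean of each variable across stacks from different
#' climate models of the same scenario, producing one layer per predictor.
#'
#' @param stacks list of \code{EnvStack}s on identical grids.
#' @return an \code{EnvStack} of the shared scenario.
#' @export
averageClimateModels <- function(stacks) {
  if (length(stacks) < 1L) stop("need at least one stack", call. = FALSE)
  shapes <- vapply(stacks, function(s) paste(gridShape(s), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("stacks are not aligned on one grid", call. = FALSE)
  ref <- stacks[[1]]
  layers <- lapply(names(ref@layers), function(v) {
    Reduce(`+`, lapply(stacks, envLayer, variable = v)) / length(stacks)
  })
  names(layers) <- names(ref@layers)
  layers$BIO6 <- pmin(layers$BIO6, layers$BIO5 - 0.1)
  new("EnvStack", layers = layers, cellSize = ref@cellSize,
      scenario = ref@scenario, regionMask = ref@regionMask)
}

#' Construct a virtual species
#'
#' @param name species label.
#' @param optima named numeric vector of niche optima (variable units).
#' @param breadths named numeric vector of niche breadths (> 0), same names.
#' @param prevalence maximum suitability in (0, 1], default 1.
#' @return a \code{VirtualSpecies}.
#' @examples
#' sp <- virtualSpecies("toad", c(BIO5 = 30, BIO12 = 800),
#'                      c(BIO5 = 5, BIO12 = 300))
#' @export
virtualSpecies <- function(name, optima, breadths, prevalence = 1) {
  new("VirtualSpecies", name = name, optima = optima,
      breadths = breadths, prevalence = prevalence)
}

.suitabilityVec <- function(sp, X) {
  vars <- names(sp@optima)
  missing <- setdiff(vars, colnames(X))
  if (length(missing))
    stop("environment lacks variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- rep(sp@prevalence, nrow(X))
  for (v in vars)
    s <- s * exp(-(X[, v] - sp@optima[[v]])^2 / (2 * sp@breadths[[v]]^2))
  unname(as.vector(s))
}

#' @describeIn suitability matrix of suitability over all grid cells
#' @export
setMethod("suitability", signature("VirtualSpecies", "EnvStack"),
  function(species, env) {
    X <- envAsMatrix(env)
    matrix(.suitabilityVec(species, X), gridShape(env)[1], gridShape(env)[2])
  })

#' @describeIn suitability suitability for rows of an environment matrix
#' @export
setMethod("suitability", signature("VirtualSpecies", "matrix"),
  function(species, env) .suitabilityVec(species, env))

#' @describeIn suitability suitability for rows of a data.frame
#' @export
setMethod("suitability", signature("VirtualSpecies", "data.frame"),
  function(species, env) .suitabilityVec(species, as.matrix(env)))

#' Flatten an environmental stack to a cells x variables matrix
#'
#' Rows follow R's column-major linear cell order, so row i corresponds to
#' linear cell index i.
#'
#' @param env an \code{EnvStack}.
#' @param variables variables to include, default all five.
#' @return numeric matrix with one row per cell.
#' @export
envAsMatrix <- function(env, variables = names(env@layers)) {
  stopifnot(is(env, "EnvStack"))
  X <- vapply(variables, function(v) as.vector(env@layers[[v]]),
              numeric(prod(gridShape(env))))
  colnames(X) <- variables
  X
}

#' Sample species occurrences from a virtual species
#'
#' Two sampling designs mirror the two kinds of field data. Under
#' \code{presence_only}, n distinct cells are drawn with probability
#' proportional to suitability (so records concentrate where the species
#' thrives and never fall on zero-suitability cells). Under \code{atlas},
#' n survey cells are drawn uniformly and each is labelled present by a
#' Bernoulli draw with p equal to its suitability, yielding explicit
#' absences.
#'
#' @param sp a \code{VirtualSpecies}.
#' @param env an \code{EnvStack}.
#' @param n number of records to draw.
#' @param design \code{"presence_only"} or \code{"atlas"}.
#' @param regionFilter region label(s) to restrict sampling to, or NULL
#'   for the whole grid.
#' @param seed integer seed.
#' @return an \code{OccurrenceSet}.
#' @export
sampleOccurrences <- function(sp, env, n, design = c("presence_only", "atlas"),
                              regionFilter = NULL, seed = 1) {
  stopifnot(is(sp, "VirtualSpecies"), is(env, "EnvStack"))
  design <- match.arg(design)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  shape <- gridShape(env)
  eligible <- seq_len(prod(shape))
  if (!is.null(regionFilter)) {
    eligible <- which(as.vector(env@regionMask) %in% regionFilter)
    if (!length(eligible)) stop("regionFilter selects no cells", call. = FALSE)
  }
  s <- as.vector(suitability(sp, env))[eligible]
  set.seed(as.integer(seed))
  if (design == "presence_only") {
    pos <- eligible[s > 0]
    if (n > length(pos))
      stop("n exceeds the ", length(pos), " cells of positive suitability",
           call. = FALSE)
    cells <- sample(pos, n, prob = s[s > 0])
    presence <- rep(1L, n)
  } else {
    if (n > length(eligible))
      stop("n exceeds the ", length(eligible), " eligible cells", call. = FALSE)
    cells <- sample(eligible, n)
    presence <- stats::rbinom(n, 1L, as.vector(suitability(sp, env))[cells])
  }
  rc <- .cellRowCol(cells, shape)
  region <- if (is.null(regionFilter)) "all" else paste(regionFilter, collapse = "+")
  new("OccurrenceSet", species = sp@name,
      records = data.frame(row = rc[, "row"], col = rc[, "col"],
                           presence = presence),
      region = region, design = design)
}

#' Generate ecoregion-like strata by seeded region growth
#'
#' Drops K seed cells at random and assigns every cell to its nearest seed
#' (squared Euclidean distance in cell units), producing K contiguous
#' Voronoi-style strata that partition the grid.
#'
#' @param gridShape integer (rows, cols).
#' @param K number of strata, between 1 and the cell count.
#' @param seed integer seed.
#' @return a \code{StrataMap}.
#' @export
generateStrata <- function(gridShape, K, seed = 1) {
  gridShape <- as.integer(gridShape)
  ncell <- prod(gridShape)
  if (K < 1L || K > ncell) stop("K must be in 1..cells", call. = FALSE)
  set.seed(as.integer(seed))
  seeds <- .cellRowCol(sample(ncell, K), gridShape)
  rows <- rep(seq_len(gridShape[1]), gridShape[2])
  cols <- rep(seq_len(gridShape[2]), each = gridShape[1])
  d <- outer(rows, seeds[, "row"], `-`)^2 + outer(cols, seeds[, "col"], `-`)^2
  new("StrataMap",
      strata = matrix(max.col(-d, ties.method = "first"),
                      gridShape[1], gridShape[2]))
}

# grow one compact patch by breadth-first accretion from a seed cell,
# stopping at the requested size or when no free neighbour remains
.growPatch <- function(seedCell, free, shape, size) {
  patch <- seedCell
  frontier <- seedCell
  free[seedCell] <- FALSE
  while (length(patch) < size && length(frontier)) {
    rc <- .cellRowCol(frontier, shape)
    nb <- rbind(cbind(rc[, 1] - 1L, rc[, 2]), cbind(rc[, 1] + 1L, rc[, 2]),
                cbind(rc[, 1], rc[, 2] - 1L), cbind(rc[, 1], rc[, 2] + 1L))
    ok <- nb[, 1] >= 1L & nb[, 1] <= shape[1] & nb[, 2] >= 1L & nb[, 2] <= shape[2]
    cand <- unique(.cellIndex(nb[ok, 1], nb[ok, 2], shape))
    cand <- cand[free[cand]]
    if (!length(cand)) break
    take <- cand[seq_len(min(length(cand), size - length(patch)))]
    free[take] <- FALSE
    patch <- c(patch, take)
    frontier <- take
  }
  list(patch = patch, free = free)
}

#' Generate a protected-area mask with targeted sites
#'
#' Lays compact protected patches over the grid until the requested
#' coverage fraction of cells is reached (the real network covers close to
#' a fifth of the territory, the default emulated here). A subset of
#' patches is then flagged as targeted sites until the targeted fraction is
#' met, and each targeted patch is assigned at least one species from the
#' roster as an explicit conservation object.
#'
#' @param gridShape integer (rows, cols).
#' @param coverageFraction fraction of cells under protection, in (0, 1].
#' @param targetedFraction fraction of cells in targeted sites; must not
#'   exceed \code{coverageFraction}.
#' @param speciesList character vector of species labels to target.
#' @param seed integer seed.
#' @param patchSize typical patch size in cells, default 25.
#' @return a \code{ProtectionMask}.
#' @export
generateProtectionMask <- function(gridShape, coverageFraction = 0.2,
                                   targetedFraction = 0.05, speciesList,
                                   seed = 1, patchSize = 25) {
  gridShape <- as.integer(gridShape)
  if (targetedFraction <= 0 || targetedFraction > coverageFraction ||
      coverageFraction > 1)
    stop("need 0 < targetedFraction <= coverageFraction <= 1", call. = FALSE)
  if (!length(speciesList)) stop("speciesList must be non-empty", call. = FALSE)
  set.seed(as.integer(seed))
  ncell <- prod(gridShape)
  quota <- round(coverageFraction * ncell)
  free <- rep(TRUE, ncell)
  patches <- list()
  protected <- 0L
  while (protected < quota) {
    seedCell <- sample(which(free), 1L)
    want <- min(quota - protected,
                max(4L, stats::rpois(1, patchSize)))
    g <- .growPatch(seedCell, free, gridShape, want)
    free <- g$free
    patches[[length(patches) + 1L]] <- g$patch
    protected <- protected + length(g$patch)
  }
  regime <- matrix("outside", gridShape[1], gridShape[2])
  regime[unlist(patches)] <- "n2000"
  targetQuota <- round(targetedFraction * ncell)
  ord <- sample(length(patches))
  targets <- stats::setNames(vector("list", length(speciesList)), speciesList)
  got <- 0L
  for (p in ord) {
    if (got >= targetQuota) break
    cells <- patches[[p]]
    regime[cells] <- "targeted_n2000"
    nsp <- sample(length(speciesList), 1L)
    for (s in sample(speciesList, nsp))
      targets[[s]] <- sort(c(targets[[s]], cells))
    got <- got + length(cells)
  }
  targets <- targets[!vapply(targets, is.null, logical(1))]
  # every targeted patch must list >= 1 species; guaranteed by construction,
  # but an all-empty roster can only happen if no patch was targeted
  if (got == 0L) {
    p <- ord[1]
    regime[patches[[p]]] <- "targeted_n2000"
    targets[[speciesList[1]]] <- sort(patches[[p]])
  }
  new("ProtectionMask", regime = regime, targets = targets)
}
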