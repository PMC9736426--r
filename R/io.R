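#' @include change.R
NULL

#' Write a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster with the standard 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from the
#' top of the grid down.
#'
#' @param m numeric matrix (row 1 = northern edge).
#' @param path output file.
#' @param cellSize cell size written to the header.
#' @param nodata NODATA sentinel, default -9999.
#' @export
writeAsciiGrid <- function(m, path, cellSize = 10, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", cellSize), paste("NODATA_value", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII grid
#'
#' @param path file with a 6-line header and one line per grid row.
#' @return list with \code{values} (matrix), \code{cellSize}, \code{nodata}
#'   (NODATA cells are NA in the matrix).
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  list(values = m, cellSize = h[["cellsize"]], nodata = h[["nodata_value"]])
}

#' Write occurrence sets to CSV
#'
#' One row per record, columns species, row, col, presence, region, design.
#'
#' @param occList list of \code{OccurrenceSet}s.
#' @param path output CSV file.
#' @export
writeOccurrenceCSV <- function(occList, path) {
  rows <- lapply(occList, function(o) {
    r <- occRecords(o)
    data.frame(species = o@species, row = r$row, col = r$col,
               presence = r$presence, region = o@region, design = o@design)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read occurrence sets from CSV
#'
#' Rebuilds one \code{OccurrenceSet} per (species, region, design)
#' combination, validating that every record lies on the grid and
#' optionally applying a species-merge map — e.g. pooling atlas records of
#' taxa that cannot be split objectively into the most widespread species.
#'
#' @param path CSV with columns species, row, col, presence, region, design.
#' @param shape grid shape (rows, cols) used for bounds validation.
#' @param mergeMap optional named character vector old label -> new label.
#' @return list of \code{OccurrenceSet}s.
#' @export
readOccurrenceCSV <- function(path, shape, mergeMap = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "row", "col", "presence", "region", "design")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop(path, " lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(d$row < 1 | d$row > shape[1] | d$col < 1 | d$col > shape[2])
  if (length(bad))
    stop(path, ": record at data row ", bad[1], " lies outside the ",
         shape[1], "x", shape[2], " grid", call. = FALSE)
  if (!is.null(mergeMap)) {
    hit <- d$species %in% names(mergeMap)
    d$species[hit] <- unname(mergeMap[d$species[hit]])
  }
  keys <- unique(d[, c("species", "region", "design")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- d[d$species == k$species & d$region == k$region &
               d$design == k$design, ]
    new("OccurrenceSet", species = k$species,
        records = data.frame(row = sub$row, col = sub$col,
                             presence = as.integer(sub$presence)),
        region = k$region, design = k$design)
  })
}

#' Export hull polygons as GeoJSON
#'
#' A FeatureCollection of one Polygon per hull, in PC coordinates.
#'
#' @param hulls list of \code{HullPolygon}s.
#' @param path output file.
#' @export
writeHullGeoJSON <- function(hulls, path) {
  features <- lapply(hulls, function(h) {
    v <- rbind(h@vertices, h@vertices[1, , drop = FALSE])
    ring <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
    list(type = "Feature",
         properties = list(species = h@species,
                           area = .polygonArea(h@vertices)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write an environmental stack as per-variable ASCII grids
#'
#' @param env an \code{EnvStack}.
#' @param dir output directory; files are named
#'   \code{<scenario>_<variable>.asc}.
#' @return invisibly, the written paths.
#' @export
writeEnvStack <- function(env, dir) {
  stopifnot(is(env, "EnvStack"))
  paths <- vapply(names(env@layers), function(v) {
    p <- file.path(dir, paste0(env@scenario, "_", v, ".asc"))
    writeAsciiGrid(env@layers[[v]], p, cellSize = env@cellSize)
    p
  }, "")
  invisible(paths)
}

#' Load a real-data study from files on disk
#'
#' Real-data mode: per-variable ASCII grids for each scenario, an
#' occurrence CSV, an integer strata grid, an integer protection-regime
#' grid (0 = outside, 1 = protected, 2 = targeted) with a CSV of targeted
#' cells per species, and an optional integer region grid (1 = native,
#' 2 = invaded, 0 = other). All grids must align; misalignment, unknown
#' labels or out-of-grid records raise load errors naming the file.
#'
#' @param paths list with components \code{env} (named list scenario ->
#'   named list variable -> grid file), \code{occurrences} (CSV),
#'   \code{strata} (grid), \code{regime} (grid), \code{targets} (CSV with
#'   species, row, col), and optionally \code{region} (grid).
#' @param mergeMap optional species-merge map passed to
#'   \code{\link{readOccurrenceCSV}}.
#' @return list with \code{env} (named list of \code{EnvStack}s),
#'   \code{occurrences} (list of \code{OccurrenceSet}s), \code{strata},
#'   \code{protection}.
#' @export
loadRealData <- function(paths, mergeMap = NULL) {
  stacks <- list()
  shape <- NULL
  cellSize <- NULL
  regionM <- NULL
  if (!is.null(paths$region)) {
    g <- readAsciiGrid(paths$region)
    regionM <- matrix(c("other", "native", "invaded")[g$values + 1],
                      nrow(g$values), ncol(g$values))
  }
  for (scen in names(paths$env)) {
    layers <- lapply(paths$env[[scen]], function(f) {
      g <- readAsciiGrid(f)
      if (is.null(shape)) {
        shape <<- dim(g$values); cellSize <<- g$cellSize
      } else if (!identical(dim(g$values), shape))
        stop("grid misalignment in ", f, ": expected ",
             paste(shape, collapse = "x"), call. = FALSE)
      g$values
    })
    if (is.null(regionM)) regionM <- .defaultRegionMask(shape)
    stacks[[scen]] <- new("EnvStack", layers = layers, cellSize = cellSize,
                          scenario = scen, regionMask = regionM)
  }
  occ <- readOccurrenceCSV(paths$occurrences, shape, mergeMap)
  sg <- readAsciiGrid(paths$strata)
  strata <- new("StrataMap", strata = matrix(as.integer(sg$values),
                                             shape[1], shape[2]))
  rg <- readAsciiGrid(paths$regime)
  if (!identical(dim(rg$values), shape))
    stop("grid misalignment in ", paths$regime, call. = FALSE)
  regime <- matrix(REGIME_LABELS[rg$values + 1], shape[1], shape[2])
  tgt <- utils::read.csv(paths$targets, stringsAsFactors = FALSE)
  targets <- lapply(split(tgt, tgt$species), function(d)
    sort(unique(.cellIndex(d$row, d$col, shape))))
  protection <- new("ProtectionMask", regime = regime, targets = targets)
  list(env = stacks, occurrences = occ, strata = strata,
       protection = protection)
}
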