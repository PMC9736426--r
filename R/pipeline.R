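#' @include io.R
NULL

#' Default run configuration for the synthetic study
#'
#' The study conditions of the synthetic world: a 100 x 100 grid of
#' 10 x 10 km cells with a 50 km climate correlation length; an invading
#' species sampled presence-only in its native range (150 records) and
#' its invaded range (80 records); two sensitive native species recorded
#' in atlas design within the invaded region (800 survey cells each);
#' ten ecoregion-like strata; a protected network covering 20% of cells
#' with 5% in species-targeted sites; six climate-model variants averaged
#' per scenario; additive warming deltas of +1.5 deg C / -50 mm under the
#' optimistic scenario and +4.5 deg C / -150 mm under the pessimistic one;
#' and ensembles of all five families, ten replicates, AUC threshold 0.7.
#' Every stochastic stage carries an explicit seed derived from
#' \code{baseSeed}.
#'
#' @param baseSeed integer master seed from which stage seeds derive.
#' @return a nested configuration list.
#' @export
defaultConfig <- function(baseSeed = 1) {
  baseSeed <- as.integer(baseSeed)
  s <- function(k) (baseSeed * 1009L + k) %% 2147483647L
  list(
    grid = list(nrow = 100L, ncol = 100L, cell_size = 10,
                autocorrelation_length = 50),
    seeds = list(env = s(1L), gcm = s(2L), strata = s(3L),
                 protection = s(4L), occurrences = s(5L), sdm = s(6L)),
    scenarios = list(
      rcp26 = list(BIO5 = 1.5, BIO6 = 1.5, BIO12 = -50),
      rcp85 = list(BIO5 = 4.5, BIO6 = 4.5, BIO12 = -150)),
    gcm_count = 6L,
    gcm_spread = list(BIO5 = 0.5, BIO6 = 0.5, BIO12 = 30),
    strata_k = 10L,
    protection = list(coverage = 0.2, targeted = 0.05),
    species = list(
      invader = list(
        optima = list(BIO5 = 33, BIO6 = 5, BIO12 = 600),
        breadths = list(BIO5 = 4, BIO6 = 4, BIO12 = 250),
        prevalence = 1,
        native = list(design = "presence_only", n = 150L, region = "native"),
        invaded = list(design = "presence_only", n = 80L, region = "invaded")),
      native_lowland = list(
        optima = list(BIO5 = 31, BIO6 = 4, BIO12 = 650),
        breadths = list(BIO5 = 4, BIO6 = 4, BIO12 = 250),
        prevalence = 1,
        invaded = list(design = "atlas", n = 800L, region = "invaded")),
      native_upland = list(
        optima = list(BIO5 = 26, BIO6 = 0, BIO12 = 950),
        breadths = list(BIO5 = 4, BIO6 = 4, BIO12 = 300),
        prevalence = 1,
        invaded = list(design = "atlas", n = 800L, region = "invaded"))),
    invader = "invader",
    sdm = list(replicates = 10L, families = MODEL_FAMILIES,
               auc_threshold = 0.7, train_fraction = 0.7)
  )
}

.validateConfig <- function(cfg) {
  need <- c("grid", "seeds", "scenarios", "gcm_count", "strata_k",
            "protection", "species", "invader", "sdm")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(cfg$species)))
    stop("species labels must be unique", call. = FALSE)
  if (!cfg$invader %in% names(cfg$species))
    stop("invader label not in species roster", call. = FALSE)
  invisible(TRUE)
}

.stage <- function(name, expr) {
  message("[stage] ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.speciesFromConfig <- function(cfg) {
  lapply(names(cfg$species), function(nm) {
    sp <- cfg$species[[nm]]
    virtualSpecies(nm, unlist(sp$optima), unlist(sp$breadths),
                   sp$prevalence)  # unlist: YAML maps load as lists
  }) |> stats::setNames(names(cfg$species))
}

# one future stack per scenario: average of gcm_count variants whose deltas
# are the scenario deltas plus a smooth seeded perturbation field
.futureStacks <- function(current, cfg) {
  shape <- gridShape(current)
  out <- list()
  for (scen in names(cfg$scenarios)) {
    base <- cfg$scenarios[[scen]]
    gcms <- lapply(seq_len(cfg$gcm_count), function(g) {
      set.seed((cfg$seeds$gcm + 37L * g +
                  971L * match(scen, names(cfg$scenarios))) %% 2147483647L)
      deltas <- lapply(stats::setNames(nm = names(base)), function(v) {
        spread <- cfg$gcm_spread[[v]]
        if (is.null(spread)) spread <- 0
        base[[v]] + spread * .smoothField(shape[1], shape[2], 5)
      })
      suppressWarnings(makeFutureStack(current, deltas, scen))
    })
    out[[scen]] <- averageClimateModels(gcms)
  }
  out
}

#' Run the full invasion-risk analysis end-to-end
#'
#' Executes every stage in order from one declarative configuration:
#' simulate the environmental world, average climate-model variants into
#' one future stack per scenario, sample all species occurrences, fit the
#' shared PCA space and measure hull overlaps and niche shift, build an
#' AUC-weighted ensemble per species, project current and future
#' suitability, standardize with current-prediction statistics, compute
#' change maps over occupied and potential dispersal ranges, summarize by
#' protection regime, and run the group comparisons. All tables are
#' written as CSV, grids as ASCII grids, hulls as GeoJSON, plus a
#' reproducibility manifest with file digests. Stage failures abort with
#' the failing stage named.
#'
#' @param cfg configuration list, see \code{\link{defaultConfig}}; or a
#'   path to a YAML file with the same structure.
#' @param outDir output directory, created if needed.
#' @param writeGrids write the (large) suitability and environment grids,
#'   default TRUE.
#' @return invisibly, a list with every in-memory result plus the manifest.
#' @export
runPipeline <- function(cfg = defaultConfig(), outDir = tempfile("climrun"),
                        writeGrids = TRUE) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  .validateConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  shape <- c(cfg$grid$nrow, cfg$grid$ncol)

  env <- .stage("simulate environment", generateEnvStack(
    shape, cfg$grid$cell_size, cfg$grid$autocorrelation_length,
    seed = cfg$seeds$env))
  futures <- .stage("average climate models", .futureStacks(env, cfg))
  strata <- .stage("strata", generateStrata(shape, cfg$strata_k,
                                            seed = cfg$seeds$strata))
  natives <- setdiff(names(cfg$species), cfg$invader)
  protection <- .stage("protection mask", generateProtectionMask(
    shape, cfg$protection$coverage, cfg$protection$targeted,
    speciesList = natives, seed = cfg$seeds$protection))

  species <- .speciesFromConfig(cfg)
  occ <- .stage("sample occurrences", {
    out <- list()
    i <- 0L
    for (nm in names(cfg$species)) {
      blocks <- cfg$species[[nm]]
      for (b in setdiff(names(blocks), c("optima", "breadths", "prevalence"))) {
        i <- i + 1L
        blk <- blocks[[b]]
        out[[paste(nm, b, sep = ".")]] <- sampleOccurrences(
          species[[nm]], env, blk$n, blk$design, blk$region,
          seed = (cfg$seeds$occurrences + i) %% 2147483647L)
      }
    }
    out
  })

  niche <- .stage("niche space and overlap", {
    ns <- fitNicheSpace(env)
    allScores <- projectScores(ns, env)
    scoreOf <- function(o) {
      cells <- presenceCells(o, shape)
      allScores[cells, , drop = FALSE]
    }
    hulls <- list()
    for (nm in names(occ)) {
      sc <- scoreOf(occ[[nm]])
      if (nrow(sc) < 3L) {
        message("  ", nm, ": fewer than 3 presence cells, no hull")
        next
      }
      hulls[[nm]] <- convexHull(sc, species = nm)
    }
    invNat <- paste0(cfg$invader, ".native")
    invInv <- paste0(cfg$invader, ".invaded")
    overlaps <- list()
    if (invNat %in% names(hulls) && invInv %in% names(hulls))
      overlaps[["native_vs_invaded"]] <- hullOverlap(hulls[[invNat]],
                                                     hulls[[invInv]])
    for (nm in natives) {
      key <- names(hulls)[startsWith(names(hulls), paste0(nm, "."))][1]
      if (!is.na(key) && invInv %in% names(hulls))
        overlaps[[paste0(nm, "_vs_invader")]] <-
          hullOverlap(hulls[[key]], hulls[[invInv]])
    }
    shift <- if (invNat %in% names(hulls) && invInv %in% names(occ)) {
      po <- pointsOutside(scoreOf(occ[[invInv]]), hulls[[invNat]])
      data.frame(species = cfg$invader, n_outside = po$count,
                 fraction_outside = po$fraction)
    } else NULL
    list(space = ns, hulls = hulls,
         overlaps = do.call(rbind, overlaps), shift = shift)
  })

  ensembles <- .stage("ensembles", {
    out <- list()
    for (nm in names(cfg$species)) {
      # the invader is trained on its native range only; natives on their data
      key <- if (nm == cfg$invader) paste0(nm, ".native")
             else names(occ)[startsWith(names(occ), paste0(nm, "."))][1]
      out[[nm]] <- buildEnsemble(
        occ[[key]], env, strata, R = cfg$sdm$replicates,
        families = cfg$sdm$families, aucThreshold = cfg$sdm$auc_threshold,
        trainFraction = cfg$sdm$train_fraction,
        seed = (cfg$seeds$sdm + match(nm, names(cfg$species))) %% 2147483647L)
    }
    out
  })

  transfer <- .stage("transferability", {
    invInv <- paste0(cfg$invader, ".invaded")
    if (!invInv %in% names(occ)) NULL else {
      data.frame(species = cfg$invader,
                 internal_mean_auc = mean(evalTable(
                   ensembles[[cfg$invader]])$test_auc),
                 transfer_auc = evaluateTransfer(
                   ensembles[[cfg$invader]], occ[[invInv]], env, strata,
                   seed = (cfg$seeds$sdm + 97L) %% 2147483647L))
    }
  })

  projections <- .stage("projections", {
    out <- list()
    for (nm in names(ensembles)) {
      out[[nm]] <- list(current = predictSuitability(ensembles[[nm]], env))
      for (scen in names(futures))
        out[[nm]][[scen]] <- predictSuitability(ensembles[[nm]],
                                                futures[[scen]])
    }
    out
  })

  changes <- .stage("change maps and regime summaries", {
    refCells <- which(as.vector(regionMask(env)) == "invaded")
    if (!length(refCells)) refCells <- seq_len(prod(shape))
    potRange <- potentialRange(
      occ[vapply(natives, function(nm)
        names(occ)[startsWith(names(occ), paste0(nm, "."))][1], "")],
      shape)
    summaries <- list(); comparisons <- list(); deltas <- list()
    for (nm in names(ensembles)) {
      zc <- standardizeScores(projections[[nm]]$current,
                              refCells = refCells)
      masks <- if (nm == cfg$invader) {
        invInv <- paste0(nm, ".invaded")
        m <- list()
        if (invInv %in% names(occ))
          m$invaded <- presenceCells(occ[[invInv]], shape)
        m$potential <- potRange
        m
      } else {
        key <- names(occ)[startsWith(names(occ), paste0(nm, "."))][1]
        list(invaded = presenceCells(occ[[key]], shape))
      }
      for (scen in names(futures)) {
        zf <- standardizeScores(projections[[nm]][[scen]],
                                ref = projections[[nm]]$current,
                                refCells = refCells)
        for (rg in names(masks)) {
          cm <- changeMap(zf, zc, masks[[rg]], species = nm,
                          scenario = scen, range = rg)
          deltas[[paste(nm, scen, rg, sep = ".")]] <- cm
          summaries[[paste(nm, scen, rg, sep = ".")]] <-
            suppressMessages(regimeSummary(cm, protection))
          inside <- as.vector(protection@regime)[cm@cells] != "outside"
          if (sum(inside) >= 2L && sum(!inside) >= 2L)
            comparisons[[paste(nm, scen, rg, "inVsOut", sep = ".")]] <-
              compareGroups(cm@delta[inside], cm@delta[!inside],
                            paired = FALSE,
                            label = paste(nm, scen, rg,
                                          "inside vs outside N2000"))
        }
      }
      # same cells under the two scenarios: a paired comparison
      for (rg in names(masks)) {
        a <- deltas[[paste(nm, "rcp26", rg, sep = ".")]]
        b <- deltas[[paste(nm, "rcp85", rg, sep = ".")]]
        if (!is.null(a) && !is.null(b) && stats::sd(a@delta - b@delta) > 1e-14)
          comparisons[[paste(nm, rg, "scenarios", sep = ".")]] <-
            compareGroups(a@delta, b@delta, paired = TRUE,
                          label = paste(nm, rg, "rcp26 vs rcp85"))
      }
    }
    message("  ", length(comparisons), " uncorrected group comparisons")
    list(summary = do.call(rbind, unname(summaries)),
         comparisons = do.call(rbind, unname(comparisons)),
         maps = deltas, potential_range = potRange)
  })

  manifest <- .stage("write outputs", {
    paths <- character()
    wr <- function(obj, f, writer) {
      p <- file.path(outDir, f)
      writer(obj, p)
      paths[length(paths) + 1L] <<- p
      p
    }
    wr(niche$overlaps, "overlap.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (!is.null(niche$shift))
      wr(niche$shift, "niche_shift.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    loadings <- data.frame(variable = rownames(niche$space@loadings),
                           niche$space@loadings[, 1:niche$space@retainedK])
    wr(loadings, "pca_loadings.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(niche$hulls, "hulls.geojson", writeHullGeoJSON)
    evals <- do.call(rbind, lapply(names(ensembles), function(nm)
      cbind(species = nm, evalTable(ensembles[[nm]]))))
    wr(evals, "eval_table.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (!is.null(transfer))
      wr(transfer, "transfer.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(changes$summary, "change_summary.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (!is.null(changes$comparisons))
      wr(changes$comparisons, "comparisons.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(occ, "occurrences.csv", writeOccurrenceCSV)
    if (writeGrids) {
      for (st in c(list(env), futures)) {
        ps <- writeEnvStack(st, outDir)
        paths <- c(paths, ps)
      }
      for (nm in names(projections))
        for (scen in names(projections[[nm]])) {
          p <- file.path(outDir, paste0("suitability_", nm, "_", scen, ".asc"))
          writeAsciiGrid(projections[[nm]][[scen]]@scores, p,
                         cellSize = cfg$grid$cell_size)
          paths <- c(paths, p)
        }
    }
    cfgFile <- file.path(outDir, "config.yaml")
    yaml::write_yaml(cfg, cfgFile)
    digests <- tools::md5sum(c(cfgFile, paths))
    man <- list(config_digest = unname(digests[1]),
                files = as.list(stats::setNames(unname(digests[-1]),
                                                basename(paths))),
                r_version = as.character(getRversion()))
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(config = cfg, env = env, futures = futures,
                 strata = strata, protection = protection,
                 occurrences = occ, niche = niche, ensembles = ensembles,
                 transfer = transfer, projections = projections,
                 changes = changes, manifest = manifest, outDir = outDir))
}
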