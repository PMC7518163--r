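# End-to-end orchestration: one call runs species x season from
# configuration to maps, tables and a machine-readable manifest.

.CONFIG_KEYS <- c("species", "seasons", "synthetic", "envConfig", "virtual",
                  "predictorDir", "occurrenceFile", "extent", "vifThreshold",
                  "holdoutFraction", "holdoutRepeats", "paReplicates",
                  "paCount", "aucThreshold", "families", "hyper",
                  "nPermutations", "partialGrid", "importanceRows",
                  "excludePresenceCells", "seed")

#' Pipeline configuration
#'
#' Assembles and validates the flat key set driving [runPipeline()].
#' Unknown keys are errors (typo protection); every default is overridable.
#'
#' @param ... configuration keys. The main ones: `species` (labels),
#'   `seasons` (`"summer"`/`"winter"`), `synthetic` (use the virtual-species
#'   generator), `envConfig` ([synthEnvConfig()]), `virtual`
#'   ([virtualSpecies()]), `predictorDir`/`occurrenceFile` (real-data
#'   inputs), `extent` (`c(lonMin, lonMax, latMin, latMax)` clip box),
#'   `vifThreshold` (3), `holdoutFraction` (0.7), `holdoutRepeats` (10),
#'   `paReplicates` (10), `paCount` (1000, regression designs),
#'   `aucThreshold` (0.7), `families` (all seven), `hyper` (per-family
#'   overrides), `nPermutations` (10), `partialGrid` (50),
#'   `importanceRows` (500, cap on the diagnostics evaluation table),
#'   `excludePresenceCells` (TRUE), `seed` (1).
#' @return list of class `PipelineConfig`.
#' @export
sdmConfig <- function(...) {
  user <- list(...)
  bad <- setdiff(names(user), .CONFIG_KEYS)
  if (length(bad))
    sdmStop("sdmConfigError", "unknown config key(s): %s",
            paste(bad, collapse = ", "))
  cfg <- list(
    species = "virtual species", seasons = "summer", synthetic = TRUE,
    envConfig = NULL, virtual = NULL, predictorDir = NULL,
    occurrenceFile = NULL, extent = NULL, vifThreshold = 3,
    holdoutFraction = 0.7, holdoutRepeats = 10L, paReplicates = 10L,
    paCount = 1000L, aucThreshold = 0.7, families = .FAMILIES,
    hyper = list(), nPermutations = 10L, partialGrid = 50L,
    importanceRows = 500L, excludePresenceCells = TRUE, seed = 1L)
  cfg[names(user)] <- user
  if (cfg$aucThreshold < 0 || cfg$aucThreshold > 1)
    sdmStop("sdmConfigError", "aucThreshold must lie in [0, 1]")
  if (cfg$holdoutFraction <= 0 || cfg$holdoutFraction >= 1)
    sdmStop("sdmConfigError", "holdoutFraction must lie in (0, 1)")
  if (cfg$vifThreshold <= 1)
    sdmStop("sdmConfigError", "vifThreshold must exceed 1")
  if (!all(cfg$seasons %in% c("summer", "winter")))
    sdmStop("sdmConfigError", "seasons must be 'summer' and/or 'winter'")
  if (!all(cfg$families %in% .FAMILIES))
    sdmStop("sdmConfigError", "unknown families: %s",
            paste(setdiff(cfg$families, .FAMILIES), collapse = ", "))
  if (cfg$paReplicates < 1 || cfg$paCount < 1 || cfg$holdoutRepeats < 1)
    sdmStop("sdmConfigError", "counts must be >= 1")
  if (cfg$synthetic) {
    if (is.null(cfg$envConfig)) cfg$envConfig <- synthEnvConfig(seed = cfg$seed)
    if (is.null(cfg$virtual)) cfg$virtual <- virtualSpecies(seed = cfg$seed + 17L)
  } else if (is.null(cfg$predictorDir) || is.null(cfg$occurrenceFile)) {
    sdmStop("sdmConfigError",
            "non-synthetic runs need predictorDir and occurrenceFile")
  }
  structure(cfg, class = "PipelineConfig")
}

# deterministic per-stage seed fan-out from the global seed
stageSeed <- function(seed, stage, k = 0L) {
  off <- c(vif = 101L, occ = 211L, pa = 1000L, evalr = 2000L, fit = 3000L,
           imp = 4000L)[[stage]]
  as.integer(seed + off + k)
}

#' Run the full modelling pipeline
#'
#' For every species x season: build or load the predictor stack, screen
#' collinearity (VIF), ingest and thin occurrences, draw family-specific
#' pseudo-absences, fit and evaluate every learner family by repeated
#' holdout, assemble the AUC-gated ensemble with its uncertainty map, and
#' compute permutation importance and partial-effect curves. A stage error
#' aborts that species x season (recorded in the manifest) and the run
#' continues with the others.
#'
#' @param config a [sdmConfig()].
#' @param outdir output directory for maps/tables/manifest, or `NULL` to
#'   skip writing.
#' @return list with `manifest` (nested list; written as JSON when `outdir`
#'   is set) and `results` (per species x season: the fitted objects).
#' @export
runPipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- list(version = as.character(utils::packageVersion("EnsembleSDM")),
                   config = configSnapshot(config), runs = list())
  results <- list()
  for (sp in config$species) for (season in config$seasons) {
    tag <- paste(gsub("\\s+", "_", sp), season, sep = "_")
    run <- tryCatch(
      runOne(config, sp, season,
             if (is.null(outdir)) NULL else file.path(outdir, tag)),
      error = function(e) list(manifest = list(
        species = sp, season = season, status = "error",
        error = conditionMessage(e))))
    manifest$runs[[tag]] <- run$manifest
    if (!is.null(run$result)) results[[tag]] <- run$result
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(manifest = manifest, results = results)
}

configSnapshot <- function(config) {
  snap <- unclass(config)
  snap$envConfig <- if (!is.null(snap$envConfig)) {
    ec <- snap$envConfig
    list(grid = as.list(gridKey(ec$grid)), recipes = ec$recipes,
         landMask = ec$landMask, seed = ec$seed)
  }
  snap$virtual <- if (!is.null(snap$virtual)) unclass(snap$virtual)
  snap
}

runOne <- function(config, sp, season, rundir) {
  warningsSeen <- character()
  withCallingHandlers({
    ## 1. predictors
    stack <- if (config$synthetic) synthEnvStack(config$envConfig)
             else readEnvStack(config$predictorDir)
    if (!is.null(config$extent))
      stack <- clipToExtent(stack, config$extent[1], config$extent[2],
                            config$extent[3], config$extent[4])
    g <- gridOf(stack)

    ## 2. collinearity screen on a deterministic sample of valid cells
    msk <- envMask(stack)
    validCells <- which(t(msk))
    set.seed(stageSeed(config$seed, "vif"))
    cs <- sort(sample(validCells, min(2000L, length(validCells))))
    row <- (cs - 1L) %/% g@nCols + 1L; col <- (cs - 1L) %% g@nCols + 1L
    ctr <- cellCenter(g, row, col)
    vifTab <- extractAtPoints(stack, ctr$lon, ctr$lat)
    vif <- vifScreen(vifTab, config$vifThreshold)
    stackR <- subsetStack(stack, vif$retained)

    ## 3. occurrences
    truth <- NULL
    if (config$synthetic) {
      truth <- virtualSpeciesSuitability(stack, config$virtual)
      distLayer <- if ("dist_shore" %in% layerNames(stack))
        stack@layers[["dist_shore"]] else NULL
      occ <- samplePresences(truth, config$virtual$nPresences,
                             bias = config$virtual$bias,
                             distLayer = distLayer,
                             seed = stageSeed(config$seed, "occ"),
                             species = sp, season = season)
    } else {
      recs <- readOccurrences(config$occurrenceFile)
      occ <- assignSeason(recs, species = sp)[[season]]
    }
    originalN <- nRecords(occ)
    thin <- thinToGrid(occ, g)
    pres <- occRecords(thin)
    presTab <- extractAtPoints(stackR, pres$lon, pres$lat)
    presTab <- presTab[presTab$valid, , drop = FALSE]

    ## 4-6. per family: pseudo-absences, evaluation, replicate fits, map
    famInfo <- list()
    famModels <- list()
    paDraws <- list()
    for (fi in seq_along(config$families)) {
      fam <- config$families[[fi]]
      design <- designForFamily(fam, nReplicates = config$paReplicates,
                                fixedCount = config$paCount,
                                excludePresenceCells =
                                  config$excludePresenceCells,
                                seed = stageSeed(config$seed, "pa", fi * 100L))
      draws <- drawReplicates(design, stackR, thin)
      paTabs <- lapply(draws, function(d) {
        t <- extractAtPoints(stackR, d$lon, d$lat)
        t[t$valid, , drop = FALSE]
      })
      spec <- learnerSpec(fam, config$hyper[[fam]] %||% list(),
                          seed = stageSeed(config$seed, "fit", fi * 100L))
      evalr <- repeatedHoldout(spec, presTab, paTabs,
                               fraction = config$holdoutFraction,
                               nRepeats = config$holdoutRepeats,
                               seed = stageSeed(config$seed, "evalr",
                                                fi * 100L))
      models <- lapply(seq_along(paTabs), function(r) {
        sp_r <- learnerSpec(fam, spec$hyper,
                            seed = stageSeed(config$seed, "fit",
                                             fi * 100L + r))
        fitLearner(sp_r, presTab, paTabs[[r]])
      })
      maps <- lapply(models, predictRaster, stack = stackR)
      famModels[[fam]] <- aggregateFamily(fam, maps,
                                          replicateAucs = evalr@meanAuc,
                                          models = models)
      paDraws[[fam]] <- cbind(do.call(rbind, draws),
                              family_class = design@familyClass)
      famInfo[[fam]] <- list(
        family = fam, familyClass = design@familyClass,
        nPresence = nrow(presTab),
        paPerReplicate = vapply(paTabs, nrow, integer(1)),
        nReplicates = design@nReplicates,
        paSeed = design@seed,
        hyper = spec$hyper,
        variables = models[[1]]@variables,
        fitSeeds = vapply(models, function(m) m@seed, integer(1)),
        holdoutFraction = config$holdoutFraction,
        holdoutRepeats = evalr@nRepeats,
        aucs = evalr@aucs, meanAuc = evalr@meanAuc)
    }

    ## 7. ensemble
    ens <- buildEnsemble(famModels, aucThreshold = config$aucThreshold)

    ## 8. diagnostics: importance on presences + one replicate per design
    impTab <- importanceTable(config, stackR, thin, presTab)
    imp <- importanceAll(famModels, ens, impTab,
                         nPermutations = config$nPermutations,
                         seed = stageSeed(config$seed, "imp"))
    curves <- list()
    for (obj in c(list(ensemble = ens), famModels)) {
      nm <- if (is(obj, "EnsembleResult")) "ensemble" else obj@family
      curves[[nm]] <- do.call(rbind, lapply(vif$retained, function(v)
        partialEffect(obj, impTab, v, nGrid = config$partialGrid)))
    }

    result <- list(stack = stackR, truth = truth, occurrences = thin,
                   familyModels = famModels, ensemble = ens,
                   importance = imp, curves = curves, vif = vif,
                   paDraws = paDraws)
    runManifest <- list(
      species = sp, season = season, status = "ok",
      seed = config$seed,
      grid = list(nRows = g@nRows, nCols = g@nCols, res = g@res),
      nValidCells = sum(msk),
      vif = list(values = as.list(vif$vif), retained = vif$retained,
                 dropped = vif$dropped, threshold = vif$threshold),
      occurrences = list(originalN = originalN,
                         thinnedN = attr(thin, "thinnedN"),
                         removedN = attr(thin, "removedN"),
                         outOfExtentN = attr(thin, "outOfExtentN")),
      families = famInfo,
      ensemble = list(aucThreshold = config$aucThreshold,
                      included = ens@included,
                      excluded = ens@excluded$family,
                      maxUncertainty = if (!is.null(ens@uncertaintyMap))
                        max(ens@uncertaintyMap@values, na.rm = TRUE)),
      importance = list(ensemble = as.list(stats::setNames(
        imp$ensemble$share, imp$ensemble$variable))),
      warnings = warningsSeen)
    if (!is.null(rundir)) writeRunArtifacts(rundir, result, runManifest)
    list(result = result, manifest = runManifest)
  }, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluation table for diagnostics: presences plus the first replicate of
# each distinct pseudo-absence design (equal-count and fixed-count),
# deduplicated by cell -- the full calibration support at a tractable size
importanceTable <- function(config, stackR, thin, presTab) {
  fams <- config$families
  pick <- c(fams[match(TRUE, fams %in% c("ANN", "CTA", "GBM", "RF", "SVM"))],
            fams[match(TRUE, fams %in% c("GLM", "MARS"))])
  pick <- pick[!is.na(pick)]
  paRows <- list()
  for (fam in pick) {
    fi <- match(fam, config$families)
    design <- designForFamily(fam, nReplicates = 1L,
                              fixedCount = config$paCount,
                              excludePresenceCells =
                                config$excludePresenceCells,
                              seed = stageSeed(config$seed, "pa", fi * 100L))
    d <- drawReplicates(design, stackR, thin)[[1]]
    t <- extractAtPoints(stackR, d$lon, d$lat)
    paRows[[fam]] <- t[t$valid, , drop = FALSE]
  }
  tab <- rbind(presTab, do.call(rbind, paRows))
  tab <- tab[!duplicated(round(tab[c("lon", "lat")], 10)), , drop = FALSE]
  # cap the evaluation table: correlations over ~500 points are stable
  # (SE ~ 0.045) and diagnostics cost scales linearly in rows
  if (nrow(tab) > config$importanceRows) {
    set.seed(stageSeed(config$seed, "imp", 1L))
    tab <- tab[sort(sample(nrow(tab), config$importanceRows)), , drop = FALSE]
  }
  tab
}

# per-family and ensemble permutation importance sharing one set of
# permutations and one batched prediction pass per replicate model
importanceAll <- function(famModels, ens, table, nPermutations, seed) {
  vars <- importanceVars(ens)
  x <- table[stats::complete.cases(table[vars]), , drop = FALSE]
  set.seed(seed)
  perms <- replicate(nPermutations, sample.int(nrow(x)), simplify = FALSE)
  blocks <- list(x)
  key <- list()
  for (v in vars) for (k in seq_len(nPermutations)) {
    xb <- x
    xb[[v]] <- xb[[v]][perms[[k]]]
    blocks[[length(blocks) + 1]] <- xb
    key[[length(key) + 1]] <- c(v, k)
  }
  big <- do.call(rbind, blocks)
  n <- nrow(x)
  famPred <- lapply(famModels, predictProbability, table = big)
  ensPred <- Reduce(`+`, famPred[ens@included]) / length(ens@included)
  mkTable <- function(p) {
    pf <- p[seq_len(n)]
    raw <- stats::setNames(numeric(length(vars)), vars)
    for (j in seq_along(key)) {
      v <- key[[j]][1]
      pv <- p[(j * n + 1):((j + 1) * n)]
      cc <- if (stats::sd(pf) == 0 || stats::sd(pv) == 0) 1
            else stats::cor(pf, pv)
      raw[v] <- raw[v] + (1 - cc) / nPermutations
    }
    imp <- pmin(pmax(raw, 0), 1)
    share <- if (sum(imp) > 0) 100 * imp / sum(imp) else imp
    data.frame(variable = vars, importance = unname(imp),
               share = unname(share), stringsAsFactors = FALSE)
  }
  perFamily <- lapply(famPred, mkTable)
  ensemble <- mkTable(ensPred)
  memberAvg <- ensemble
  inc <- perFamily[ens@included]
  memberAvg$importance <- rowMeans(sapply(inc, `[[`, "importance"))
  memberAvg$share <- if (sum(memberAvg$importance) > 0)
    100 * memberAvg$importance / sum(memberAvg$importance)
    else memberAvg$importance
  list(ensemble = ensemble, perFamily = perFamily, memberAverage = memberAvg,
       nPermutations = nPermutations, seed = seed)
}

writeRunArtifacts <- function(rundir, result, runManifest) {
  dir.create(rundir, recursive = TRUE, showWarnings = FALSE)
  ens <- result$ensemble
  writeRasterLayer(ens@meanMap, file.path(rundir, "ensemble_mean.tif"))
  if (!is.null(ens@uncertaintyMap))
    writeRasterLayer(ens@uncertaintyMap,
                     file.path(rundir, "ensemble_uncertainty.tif"))
  for (fm in result$familyModels)
    writeRasterLayer(fm@map, file.path(rundir,
                                       sprintf("family_%s.tif", fm@family)))
  writeOccurrences(result$occurrences,
                   file.path(rundir, "occurrences_thinned.csv"))
  for (nm in names(result$paDraws))
    utils::write.csv(result$paDraws[[nm]],
                     file.path(rundir, sprintf("pseudo_absences_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(runManifest$families))
    jsonlite::write_json(runManifest$families[[nm]],
                         file.path(rundir, sprintf("model_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  aucTab <- do.call(rbind, lapply(runManifest$families, function(f)
    data.frame(family = f$family, meanAuc = f$meanAuc,
               included = f$family %in% runManifest$ensemble$included)))
  utils::write.csv(aucTab, file.path(rundir, "auc.csv"), row.names = FALSE)
  utils::write.csv(result$importance$ensemble,
                   file.path(rundir, "importance_ensemble.csv"),
                   row.names = FALSE)
  for (nm in names(result$importance$perFamily))
    utils::write.csv(result$importance$perFamily[[nm]],
                     file.path(rundir, sprintf("importance_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(result$curves))
    utils::write.csv(result$curves[[nm]],
                     file.path(rundir, sprintf("curves_%s.csv", nm)),
                     row.names = FALSE)
  jsonlite::write_json(runManifest, file.path(rundir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rundir)
}

#' Human-readable summary tables from a manifest
#'
#' Mirrors the study's reporting shapes: a per-family counts table
#' (presences and pseudo-absences per replicate), an AUC/inclusion table,
#' and an importance-share table. Regeneration from the same manifest is
#' deterministic.
#'
#' @param manifest the manifest list from [runPipeline()], or a path to a
#'   written `manifest.json`.
#' @return list of data.frames: `counts`, `auc`, `importance`; failed runs
#'   are summarised in `errors`.
#' @export
exportReport <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  counts <- list(); aucs <- list(); imps <- list(); errs <- list()
  for (tag in names(manifest$runs)) {
    run <- manifest$runs[[tag]]
    if (!identical(run$status, "ok")) {
      errs[[tag]] <- data.frame(run = tag, species = run$species,
                                season = run$season, error = run$error)
      next
    }
    for (f in run$families) {
      counts[[paste(tag, f$family)]] <- data.frame(
        run = tag, family = f$family, familyClass = f$familyClass,
        originalN = run$occurrences$originalN,
        thinnedN = run$occurrences$thinnedN,
        nPresence = f$nPresence,
        paPerReplicate = paste(unique(unlist(f$paPerReplicate)),
                               collapse = "/"),
        nReplicates = f$nReplicates)
      aucs[[paste(tag, f$family)]] <- data.frame(
        run = tag, family = f$family, meanAuc = f$meanAuc,
        included = f$family %in% unlist(run$ensemble$included))
    }
    imp <- unlist(run$importance$ensemble)
    imps[[tag]] <- data.frame(run = tag, variable = names(imp),
                              share = unname(imp))
  }
  bindOrEmpty <- function(l) if (length(l)) do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL
  list(counts = bindOrEmpty(counts), auc = bindOrEmpty(aucs),
       importance = bindOrEmpty(imps), errors = bindOrEmpty(errs))
}
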