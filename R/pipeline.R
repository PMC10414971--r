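## End-to-end orchestration over synthetic data: simulate -> gradients ->
## microstructure profiles -> change maps -> contrasts -> spin tests ->
## behavioral prediction, with a provenance manifest. Stages communicate
## only through files in the run directory, so any stage's outputs can be
## inspected or re-derived in isolation.

stageTagged <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = c("PipelineError", "gpError", "error", "condition"),
      list(message = sprintf("stage '%s': %s", stage, conditionMessage(e)),
           call = NULL, stage = stage)
    ))
  })
}

#' Run the full synthetic-study pipeline
#'
#' Generates a latent-manifold connectome and a crossover training cohort
#' with planted module-specific effects, derives gradients and eccentricity,
#' builds equivolumetric qT1 profiles on an analytic cortex, fits the
#' Presence-vs-Perspective mixed-model contrast for function and
#' microstructure, runs a spin test between the two change maps, and
#' predicts planted behavior from the 35 network features. Every numeric
#' table is written losslessly, so a re-run with the same configuration and
#' seed is byte-identical.
#'
#' @param config configuration list from [loadRunConfig()].
#' @param outDir output directory (created if absent).
#' @param seed master seed; defaults to the configured seed.
#' @return the run manifest (invisibly), also written as
#'   `run_manifest.json`.
#' @export
runPipeline <- function(config = loadRunConfig(), outDir, seed = config$seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "gradplast",
    version = as.character(utils::packageVersion("gradplast")),
    seed = as.integer(seed),
    config = config,
    stages = list()
  )
  out <- function(...) file.path(outDir, ...)
  addStage <- function(name, t0, files) {
    manifest$stages[[name]] <<- list(
      elapsed = round(as.numeric(Sys.time()) - t0, 3),
      outputs = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      })
    )
  }
  nP <- config$nParcels

  ## --- stage 1: synthetic connectome + reference embedding ----------------
  t0 <- as.numeric(Sys.time())
  stageData <- stageTagged("connectome", {
    manifold <- makeLatentManifold(nP, noiseSd = 0.01,
                                   seed = deriveSeed(seed, 10L))
    conn <- makeConnectome(manifold, seed = deriveSeed(seed, 11L))
    refManifold <- new("LatentManifold", coords = manifold@coords,
                       kernelScale = manifold@kernelScale, noiseSd = 0)
    refConn <- makeConnectome(refManifold, seed = 0L)
    pre <- function(cm) {
      m <- if (config$fisherZ) fisherZ(cm) else cm
      normalizedAngle(thresholdRows(m, config$density))
    }
    refEmb <- diffusionEmbedding(pre(refConn$connectome),
      alpha = config$embeddingAlpha, t = config$diffusionTime,
      k = config$kComputed)
    writeConnectivityMatrix(conn$connectome, out("fc.tsv"))
    writeNumericTable(manifold@coords, out("latent_coords.tsv"))
    writeNumericTable(scores(refEmb), out("reference_scores.tsv"))
    list(conn = conn, manifold = manifold, refEmb = refEmb, pre = pre)
  })
  addStage("connectome", t0,
           out(c("fc.tsv", "latent_coords.tsv", "reference_scores.tsv")))

  ## --- stage 2: gradients + eccentricity ----------------------------------
  t0 <- as.numeric(Sys.time())
  grad <- stageTagged("gradients", {
    emb <- diffusionEmbedding(stageData$pre(stageData$conn$connectome),
      alpha = config$embeddingAlpha, t = config$diffusionTime,
      k = config$kComputed)
    aligned <- procrustesAlign(emb, stageData$refEmb, refId = "synthetic-group")
    ecc <- eccentricity(aligned)
    writeNumericTable(scores(aligned), out("gradient_scores.tsv"))
    writeNumericTable(cbind(eigenvalue = eigenvalues(aligned),
                            varianceExplained = varianceExplained(aligned)),
                      out("gradient_eigenvalues.tsv"))
    writeNumericTable(cbind(eccentricity = eccValues(ecc)),
                      out("eccentricity.tsv"))
    list(embedding = aligned, ecc = ecc)
  })
  addStage("gradients", t0, out(c("gradient_scores.tsv",
                                  "gradient_eigenvalues.tsv",
                                  "eccentricity.tsv")))

  ## --- stage 3: crossover cohort with planted effects ---------------------
  t0 <- as.numeric(Sys.time())
  netW <- makeNetworkWeights(stageData$manifold@coords,
                             seed = deriveSeed(seed, 20L))
  cohort <- stageTagged("cohort", {
    ## planted study-like effects: Presence segregates (ecc up) where the
    ## attention network loads, Perspective integrates (ecc down) where
    ## theory-of-mind loads; microstructure gains myelin (qT1 down) after
    ## Perspective in superficial depths.
    attn <- netW[, "attention"] / max(netW[, "attention"])
    tom <- netW[, "theory_of_mind"] / max(netW[, "theory_of_mind"])
    eff <- list(
      ecc = makeEffectSpec(list(Presence = 0.05 * attn,
                                Perspective = -0.05 * tom),
                           config$subjectSd, config$residualSd),
      G1 = makeEffectSpec(list(), config$subjectSd, config$residualSd),
      G2 = makeEffectSpec(list(Presence = 0.03 * attn),
                          config$subjectSd, config$residualSd),
      G3 = makeEffectSpec(list(), config$subjectSd, config$residualSd),
      qt1_superficial = makeEffectSpec(list(Perspective = -8 * tom),
                                       15 * config$subjectSd,
                                       15 * config$residualSd),
      qt1_middle = makeEffectSpec(list(), 15 * config$subjectSd,
                                  15 * config$residualSd),
      qt1_deep = makeEffectSpec(list(Affect = -6 * tom),
                                15 * config$subjectSd, 15 * config$residualSd)
    )
    design <- makeCohortDesign(config$nTC1, config$nTC2, config$nRCC,
                               config$ageRange, config$pFemale,
                               seed = deriveSeed(seed, 21L))
    maps <- lapply(seq_along(eff), function(i) {
      makeCohortMaps(design, eff[[i]], nP, seed = deriveSeed(seed, 21L + i))
    })
    names(maps) <- names(eff)
    writeDesignTable(design, out("design.tsv"))
    writeNumericTable(maps$ecc, out("maps_ecc.tsv"))
    writeNumericTable(maps$qt1_superficial, out("maps_qt1_superficial.tsv"))
    list(design = design, maps = maps)
  })
  addStage("cohort", t0, out(c("design.tsv", "maps_ecc.tsv",
                               "maps_qt1_superficial.tsv")))

  ## --- stage 4: analytic cortex + depth profiles --------------------------
  t0 <- as.numeric(Sys.time())
  stageTagged("microstructure", {
    grid <- max(10L, min(40L, as.integer(round(sqrt(nP) * 3))))
    cortex <- makeCortex("wedge", nx = grid, ny = grid, thickness = 3,
                         areaRatio = 2, extent = 20)
    stack <- buildLaminarStack(cortex, config$nSurfaces)
    field <- makeQt1Field(function(x, y, z) 1200 + 200 * (1 - z / 3) + 5 * x)
    samples <- sampleField(stack, field)
    labels <- parcelLabelsForGrid(grid, grid, nP)
    profiles <- parcelProfiles(samples, labels, nParcels = nP)
    writeNumericTable(as.matrix(profiles), out("qt1_profiles.tsv"))
    writeNumericTable(compartmentMeans(profiles), out("qt1_compartments.tsv"))
    writeNumericTable(as.matrix(depthZscore(profiles)),
                      out("qt1_profiles_z.tsv"))
    NULL
  })
  addStage("microstructure", t0, out(c("qt1_profiles.tsv",
                                       "qt1_compartments.tsv",
                                       "qt1_profiles_z.tsv")))

  ## --- stage 5: change maps + mixed-model contrasts -----------------------
  t0 <- as.numeric(Sys.time())
  contrasts <- stageTagged("contrasts", {
    chEcc <- changeMaps(cohort$maps$ecc, cohort$design)
    chQt1 <- changeMaps(cohort$maps$qt1_superficial, cohort$design)
    crEcc <- fitContrast(chEcc, c("Presence", "Perspective"),
                         useIntervalIndex = config$useIntervalIndex)
    crQt1 <- fitContrast(chQt1, c("Presence", "Perspective"),
                         useIntervalIndex = config$useIntervalIndex)
    writeNumericTable(as.matrix(contrastStats(crEcc)[, -1L]),
                      out("contrast_ecc.tsv"))
    writeNumericTable(as.matrix(contrastStats(crQt1)[, -1L]),
                      out("contrast_qt1_superficial.tsv"))
    list(ecc = crEcc, qt1 = crQt1, changes = list(ecc = chEcc, qt1 = chQt1))
  })
  addStage("contrasts", t0, out(c("contrast_ecc.tsv",
                                  "contrast_qt1_superficial.tsv")))

  ## --- stage 6: spin test function vs microstructure ----------------------
  t0 <- as.numeric(Sys.time())
  spin <- stageTagged("spin", {
    centroids <- fibonacciSphere(nP)
    sp <- spinTest(contrasts$ecc@t, contrasts$qt1@t, coords = centroids,
                   nPerm = config$nPerm, seed = deriveSeed(seed, 40L))
    writeNumericTable(cbind(observedR = observedR(sp), pSpin = pSpin(sp),
                            nPerm = sp@nPerm),
                      out("spin_test.tsv"))
    sp
  })
  addStage("spin", t0, out("spin_test.tsv"))

  ## --- stage 7: behavioral prediction -------------------------------------
  t0 <- as.numeric(Sys.time())
  stageTagged("prediction", {
    design <- cohort$design
    trained <- design$cohort %in% c("TC1", "TC2")
    subjects <- unique(design$subjectId[trained])
    ## per-subject Presence-interval (T0 -> T1) change per metric
    deltaFor <- function(maps) {
      ch <- changeMaps(maps, design)
      ix <- ch@info$interval == "T0_T1" & ch@info$subjectId %in% subjects
      m <- ch@delta[ix, , drop = FALSE]
      rownames(m) <- ch@info$subjectId[ix]
      m[subjects, , drop = FALSE]
    }
    deltas <- lapply(cohort$maps, deltaFor)
    names(deltas) <- c("ecc", "G1", "G2", "G3", "qt1_superficial",
                       "qt1_middle", "qt1_deep")
    features <- assembleFeatureTable(deltas, netW)
    w <- numeric(ncol(features))
    names(w) <- colnames(features)
    w[c("attention.ecc", "attention.qt1_superficial", "attention.G2",
        "interoception.ecc", "theory_of_mind.G3", "empathy.qt1_middle",
        "emotion.qt1_deep")] <- 0.25
    sdF <- apply(features, 2L, stats::sd)
    wScaled <- ifelse(sdF > 0, w / pmax(sdF, 1e-12), 0)
    y <- makeBehavior(features, wScaled,
                      noiseSd = stats::sd(features %*% wScaled) * 1.5,
                      seed = deriveSeed(seed, 50L))
    firstRow <- match(subjects, design$subjectId)
    pr <- crossValidate(features, y, age = design$age[firstRow],
                        sex = design$sex[firstRow], folds = config$folds,
                        reps = config$reps, nSelect = config$nSelect,
                        lambdaRange = config$lambdaRange,
                        nLambda = config$nLambda,
                        seed = deriveSeed(seed, 51L))
    writeNumericTable(as.matrix(repeatMetrics(pr)[, -1L]),
                      out("prediction_metrics.tsv"))
    writeNumericTable(cbind(selectionFrequency = selectionFrequency(pr),
                            meanCoefficient = meanCoefficients(pr),
                            trueWeight = w),
                      out("prediction_features.tsv"))
    NULL
  })
  addStage("prediction", t0, out(c("prediction_metrics.tsv",
                                   "prediction_features.tsv")))

  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

## block-structured vertex parcellation of an nx x ny grid into nParcels
## contiguous patches (row-major tiles); used for the synthetic cortex.
parcelLabelsForGrid <- function(nx, ny, nParcels) {
  side <- ceiling(sqrt(nParcels))
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  tx <- pmin(side, 1L + ((ix - 1L) * side) %/% nx)
  ty <- pmin(side, 1L + ((iy - 1L) * side) %/% ny)
  lab <- (ty - 1L) * side + tx
  lab[lab > nParcels] <- nParcels
  as.integer(lab)
}
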