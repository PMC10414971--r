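## Readers, writers and run configuration.

#' Read a connectivity matrix
#'
#' Delimited text carries parcel ids in the header and first column; `rds`
#' is accepted as a single-file binary container for large matrices. Nearly
#' symmetric input (asymmetry at most 1e-8, e.g. from truncated decimal
#' output) is symmetrized by averaging with the transpose; anything worse is
#' an error.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"rds"`; default guessed from extension.
#' @return a [ConnectivityMatrix-class].
#' @export
readConnectivityMatrix <- function(path, format = c("auto", "tsv", "csv", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) inputValueError(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", rds = "rds",
                     "tsv")
  }
  m <- switch(format,
    rds = readRDS(path),
    tsv = as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                      row.names = 1L, check.names = FALSE)),
    csv = as.matrix(utils::read.table(path, header = TRUE, sep = ",",
                                      row.names = 1L, check.names = FALSE))
  )
  if (!is.numeric(m)) inputValueError("connectivity matrix must be numeric")
  if (anyNA(m) || any(!is.finite(m))) {
    inputValueError("connectivity matrix contains NA/NaN/Inf entries")
  }
  if (nrow(m) != ncol(m)) {
    inputShapeError(sprintf("connectivity matrix must be square, got %d x %d",
                            nrow(m), ncol(m)))
  }
  ConnectivityMatrix(m, parcelIds = rownames(m))
}

#' Write a connectivity matrix
#'
#' @param x a [ConnectivityMatrix-class].
#' @param path output path; `.rds` writes the binary container, anything else
#'   lossless tab-separated text (17 significant digits).
#' @export
writeConnectivityMatrix <- function(x, path) {
  stopifnot(is(x, "ConnectivityMatrix"))
  if (tolower(tools::file_ext(path)) == "rds") {
    saveRDS(x@values, path)
  } else {
    writeNumericTable(x@values, path)
  }
  invisible(path)
}

## crossover orderings of the training modules per cohort; the tm recorded at
## timepoint Tk is the module trained in the interval T(k-1) -> Tk, and T0 is
## always the untrained baseline.
cohortSchedules <- function() {
  list(
    TC1 = c(T0 = "None", T1 = "Presence", T2 = "Affect", T3 = "Perspective"),
    TC2 = c(T0 = "None", T1 = "Presence", T2 = "Perspective", T3 = "Affect"),
    TC3 = c(T0 = "None", T1 = "Affect"),
    RCC = c(T0 = "None", T1 = "None", T2 = "None", T3 = "None")
  )
}

designColumns <- c("subjectId", "cohort", "timepoint", "tm", "age", "sex",
                   "intervalIndex")

#' Validate a longitudinal design table
#'
#' Checks the structural invariants of the design: required columns, unique
#' (subject, timepoint) pairs, positive ages, 0/1 sex codes, and consistency
#' of the recorded training module with the cohort crossover schedule (TC1
#' trains Presence-Affect-Perspective, TC2 Presence-Perspective-Affect, TC3
#' a single Affect module, RCC nothing).
#'
#' @param design a data.frame.
#' @return the design, invisibly, with factor-ish columns as character.
#' @export
validateDesignTable <- function(design) {
  missing <- setdiff(designColumns, names(design))
  if (length(missing)) {
    designError(paste("design table lacks columns:", paste(missing, collapse = ", ")))
  }
  design <- as.data.frame(design)
  for (col in c("subjectId", "cohort", "timepoint", "tm")) {
    design[[col]] <- as.character(design[[col]])
  }
  key <- paste(design$subjectId, design$timepoint)
  if (anyDuplicated(key)) {
    designError(sprintf("duplicate (subject, timepoint) rows: %s",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (any(design$age <= 0)) designError("ages must be positive")
  if (!all(design$sex %in% c(0, 1))) designError("sex must be coded 0/1")
  if (!all(design$cohort %in% names(cohortSchedules()))) {
    designError("cohort must be one of TC1, TC2, TC3, RCC")
  }
  sched <- cohortSchedules()
  for (i in seq_len(nrow(design))) {
    expect <- sched[[design$cohort[i]]][design$timepoint[i]]
    if (is.na(expect)) {
      designError(sprintf("timepoint %s not defined for cohort %s",
                          design$timepoint[i], design$cohort[i]))
    }
    if (design$tm[i] != expect) {
      designError(sprintf(
        "subject %s (%s, %s): tm '%s' inconsistent with crossover order (expected '%s')",
        design$subjectId[i], design$cohort[i], design$timepoint[i],
        design$tm[i], expect))
    }
  }
  invisible(design)
}

#' Read / write a longitudinal design table
#'
#' Tab-separated text with columns subjectId, cohort, timepoint, tm, age,
#' sex, intervalIndex. The table is validated on read.
#'
#' @param path file path.
#' @return the validated design data.frame.
#' @export
readDesignTable <- function(path) {
  if (!file.exists(path)) inputValueError(sprintf("no such file: %s", path))
  design <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  validateDesignTable(design)
  design
}

#' @rdname readDesignTable
#' @param design a validated design data.frame.
#' @export
writeDesignTable <- function(design, path) {
  validateDesignTable(design)
  out <- design
  out$age <- sprintf("%.17g", design$age) # lossless double round trip
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## configuration ------------------------------------------------------------

defaultConfigList <- function() {
  list(
    nParcels = 400L,          # parcellation size
    density = 0.10,           # row density retained by proportional threshold
    embeddingAlpha = 0.5,     # diffusion-map density normalisation
    diffusionTime = 0,        # t = 0 selects the multiscale scaling
    kComputed = 10L,          # components computed
    kReport = 3L,             # gradients reported (G1-G3)
    nSurfaces = 12L,          # intracortical surfaces
    compartments = list(superficial = 1:4, middle = 5:8, deep = 9:12),
    folds = 5L,               # outer CV folds for prediction
    reps = 100L,              # outer CV repeats
    nSelect = 7L,             # ceil(0.2 * 35) features kept by greedy selection
    lambdaRange = c(1e-4, 1), # lasso penalty grid limits
    nLambda = 100L,
    nPerm = 1000L,            # spin rotations
    nTC1 = 100L, nTC2 = 100L, nRCC = 100L,  # synthetic cohort sizes
    subjectSd = 0.1, residualSd = 0.1,      # synthetic change-score noise
    ageRange = c(20, 55), pFemale = 0.59,   # demographics of the cohorts
    useIntervalIndex = TRUE,  # include scans-since-baseline covariate
    fisherZ = FALSE,          # optional Fisher z transform before threshold
    seed = 42L
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) file and fills unset keys with package defaults.
#' Unknown keys and out-of-range values are errors; an empty or absent file
#' yields the full default configuration, including a documented default
#' seed, so every run is reproducible by construction.
#'
#' @param path optional YAML/JSON file.
#' @param overrides optional named list applied after the file.
#' @return a named list of validated settings.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfigList()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) inputValueError(sprintf("no such file: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    configError(paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, user)
  if (cfg$density <= 0 || cfg$density > 1) {
    configError("density must lie in (0, 1]")
  }
  if (cfg$embeddingAlpha < 0 || cfg$embeddingAlpha > 1) {
    configError("embeddingAlpha must lie in [0, 1]")
  }
  if (cfg$nSurfaces < 1L) configError("nSurfaces must be at least 1")
  if (cfg$folds < 2L) configError("folds must be at least 2")
  if (any(cfg$lambdaRange <= 0) || diff(cfg$lambdaRange) <= 0) {
    configError("lambdaRange must be an increasing positive pair")
  }
  if (cfg$nPerm < 1L) configError("nPerm must be at least 1")
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("nParcels", "kComputed", "kReport", "nSurfaces", "folds",
              "reps", "nSelect", "nLambda", "nPerm", "nTC1", "nTC2", "nRCC")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  cfg
}
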