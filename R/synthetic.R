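## Synthetic-data generators. Everything the pipeline consumes can be built
## here with planted ground truth: latent-manifold connectomes, crossover
## cohorts with module-specific effects, analytic cortical meshes, qT1 fields
## and behavior tied to a sparse set of brain features.

#' Latent manifold for synthetic connectomes
#'
#' Parcels are placed uniformly on the unit sphere with a small radial
#' jitter, and connectivity decays as a Gaussian kernel of squared latent
#' distance. The sphere mirrors the geometry of the cortex (a closed 2D
#' sheet); its leading diffusion eigenfunctions are essentially linear in the
#' coordinates, so the gradient pipeline should recover the planted positions
#' up to an orthogonal transform.
#'
#' @param nParcels number of parcels (at least 10).
#' @param kernelScale Gaussian kernel bandwidth on squared distance; the
#'   default, 2, is the mean squared pairwise distance on the unit sphere.
#' @param noiseSd SD of symmetric additive edge noise.
#' @param radialJitter SD of the multiplicative radial jitter.
#' @param seed integer seed.
#' @return a [LatentManifold-class].
#' @export
makeLatentManifold <- function(nParcels = 400L, kernelScale = 2, noiseSd = 0.01,
                               radialJitter = 0.05, seed = 1L) {
  if (nParcels < 10L) inputValueError("need at least 10 parcels")
  if (noiseSd < 0) configError("noiseSd must be nonnegative")
  coords <- withSeed(seed, {
    z <- matrix(stats::rnorm(nParcels * 3L), nParcels, 3L)
    z <- z / sqrt(rowSums(z^2))
    z * (1 + stats::rnorm(nParcels, 0, radialJitter))
  })
  rownames(coords) <- sprintf("p%03d", seq_len(nParcels))
  new("LatentManifold", coords = coords, kernelScale = kernelScale,
      noiseSd = noiseSd)
}

#' Generate a connectome from a latent manifold
#'
#' Edge weights are `exp(-d_ij^2 / kernelScale)` plus symmetric Gaussian
#' noise, clipped to `[-1, 1]`, with unit diagonal. The generating
#' coordinates are returned alongside the matrix so recovery can be scored.
#'
#' @param manifold a [LatentManifold-class].
#' @param seed integer seed for the edge noise.
#' @return list with `connectome` ([ConnectivityMatrix-class]) and `coords`.
#' @export
makeConnectome <- function(manifold, seed = 1L) {
  stopifnot(is(manifold, "LatentManifold"))
  coords <- manifold@coords
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  vals <- exp(-d2 / manifold@kernelScale)
  if (manifold@noiseSd > 0) {
    noise <- withSeed(seed, matrix(stats::rnorm(n * n, 0, manifold@noiseSd), n, n))
    noise <- (noise + t(noise)) / 2
    vals <- vals + noise
  }
  vals <- clamp(vals, -1, 1)
  diag(vals) <- 1
  list(connectome = ConnectivityMatrix(vals, parcelIds = rownames(coords)),
       coords = coords)
}

#' Planted effect specification for the cohort generator
#'
#' @param maps named list of per-parcel mean change maps keyed by training
#'   module (`Presence`, `Affect`, `Perspective`); missing modules plant no
#'   effect, and untrained (RCC) intervals always receive a zero map.
#' @param subjectSd random-intercept SD of interval change per subject.
#' @param residualSd residual SD of interval change.
#' @return an [EffectSpec-class].
#' @export
makeEffectSpec <- function(maps = list(), subjectSd = 0.1, residualSd = 0.1) {
  new("EffectSpec", maps = maps, subjectSd = subjectSd, residualSd = residualSd)
}

#' Generate the design table of a crossover training cohort
#'
#' TC1 trains Presence-Affect-Perspective, TC2 Presence-Perspective-Affect
#' and RCC is an untrained retest cohort; all are measured at T0-T3. Ages are
#' uniform on `ageRange` and sex is Bernoulli(`pFemale`), used only as
#' nuisance structure.
#'
#' @param nTC1,nTC2,nRCC subjects per cohort (may be 0).
#' @param ageRange,pFemale demographic sampling parameters.
#' @param seed integer seed.
#' @return a validated design data.frame.
#' @export
makeCohortDesign <- function(nTC1 = 100L, nTC2 = 100L, nRCC = 100L,
                             ageRange = c(20, 55), pFemale = 0.59, seed = 1L) {
  if (min(nTC1, nTC2, nRCC) < 0L) inputValueError("cohort sizes must be >= 0")
  sched <- cohortSchedules()
  cohorts <- rep(c("TC1", "TC2", "RCC"), times = c(nTC1, nTC2, nRCC))
  nSub <- length(cohorts)
  withSeed(seed, {
    age <- stats::runif(nSub, ageRange[1L], ageRange[2L])
    sex <- stats::rbinom(nSub, 1L, pFemale)
    rows <- lapply(seq_len(nSub), function(s) {
      tps <- names(sched[[cohorts[s]]])
      data.frame(
        subjectId = sprintf("s%04d", s),
        cohort = cohorts[s],
        timepoint = tps,
        tm = unname(sched[[cohorts[s]]][tps]),
        age = age[s],
        sex = sex[s],
        intervalIndex = seq_along(tps) - 1L,
        stringsAsFactors = FALSE
      )
    })
    design <- do.call(rbind, rows)
    validateDesignTable(design)
    design
  })
}

#' Generate per-(subject, timepoint) metric maps for a cohort
#'
#' Maps accumulate over intervals: the map at T(k+1) equals the map at Tk
#' plus the planted mean change of the module trained in that interval, plus
#' a per-subject (per-parcel) random intercept and residual noise. Untrained
#' intervals receive only intercept and noise.
#'
#' @param design a validated design table.
#' @param effects an [EffectSpec-class].
#' @param nParcels number of parcels.
#' @param baseline per-parcel baseline map (default zero).
#' @param seed integer seed.
#' @return matrix of maps, rows named `subjectId.timepoint`, aligned with
#'   `design` rows.
#' @export
makeCohortMaps <- function(design, effects = makeEffectSpec(), nParcels = 400L,
                           baseline = NULL, seed = 1L) {
  validateDesignTable(design)
  if (is.null(baseline)) baseline <- numeric(nParcels)
  if (length(baseline) != nParcels) {
    inputShapeError("baseline map length must equal nParcels")
  }
  effectMap <- function(tm) {
    m <- effects@maps[[tm]]
    if (is.null(m)) numeric(nParcels) else {
      if (length(m) != nParcels) inputShapeError("effect map length mismatch")
      m
    }
  }
  subjects <- unique(design$subjectId)
  maps <- matrix(NA_real_, nrow(design), nParcels,
                 dimnames = list(paste(design$subjectId, design$timepoint,
                                       sep = "."),
                                 sprintf("p%03d", seq_len(nParcels))))
  withSeed(seed, {
    for (s in subjects) {
      rows <- which(design$subjectId == s)
      rows <- rows[order(design$timepoint[rows])]
      b <- stats::rnorm(nParcels, 0, effects@subjectSd)
      current <- baseline
      maps[rows[1L], ] <- current
      for (k in seq_along(rows)[-1L]) {
        tm <- design$tm[rows[k]]
        eff <- if (tm == "None") numeric(nParcels) else effectMap(tm)
        current <- current + eff + b +
          stats::rnorm(nParcels, 0, effects@residualSd)
        maps[rows[k], ] <- current
      }
    }
  })
  maps
}

#' One-call cohort generator
#'
#' Convenience wrapper producing the design and the metric maps together.
#'
#' @inheritParams makeCohortDesign
#' @inheritParams makeCohortMaps
#' @return list with `design` and `maps`.
#' @export
makeCohort <- function(nTC1 = 100L, nTC2 = 100L, nRCC = 100L,
                       effects = makeEffectSpec(), nParcels = 400L,
                       ageRange = c(20, 55), pFemale = 0.59, baseline = NULL,
                       seed = 1L) {
  design <- makeCohortDesign(nTC1, nTC2, nRCC, ageRange, pFemale,
                             seed = deriveSeed(seed, 1L))
  maps <- makeCohortMaps(design, effects, nParcels, baseline,
                         seed = deriveSeed(seed, 2L))
  list(design = design, maps = maps)
}

## mesh helpers --------------------------------------------------------------

gridFaces <- function(nx, ny) {
  ## consistent CCW triangulation of an nx x ny vertex grid
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- vector("list", (nx - 1L) * (ny - 1L) * 2L)
  k <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      faces[[k]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)); k <- k + 1L
      faces[[k]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)); k <- k + 1L
    }
  }
  do.call(rbind, faces)
}

vertexNormals <- function(vertices, faces) {
  fn <- faceCross(vertices, faces) # face normal * 2*area
  vn <- matrix(0, nrow(vertices), 3L)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- tapply(fn[, ax], faces[, c], sum)
      vn[as.integer(names(acc)), ax] <- vn[as.integer(names(acc)), ax] + acc
    }
  }
  vn / sqrt(rowSums(vn^2))
}

faceCross <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a; v <- c - a
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Generate an analytic cortical surface pair
#'
#' Builds paired white/pial triangle meshes with 1-1 vertex correspondence:
#' * `sheet`: flat square sheet; pial offset by `thickness` along the normal.
#' * `wedge`: flat white sheet; the pial sheet is stretched along x about its
#'   center so that every column has outer/inner area ratio `areaRatio`.
#'   Cross-sectional area then varies linearly with depth, the regime in
#'   which the equivolumetric placement preserves volume exactly.
#' * `sphere_patch`: polar cap of a sphere; white at radius `radii[1]`, pial
#'   at `radii[2]`.
#' * `sinusoidal_sheet`: sinusoidally folded sheet; pial offset along the
#'   local vertex normal.
#'
#' @param shape mesh family, see above.
#' @param nx,ny grid resolution (vertices per side).
#' @param thickness cortical thickness in mm (scalar or per-vertex).
#' @param areaRatio outer/inner area ratio for the wedge.
#' @param radii white/pial radii (mm) for the sphere patch.
#' @param extent sheet edge length in mm.
#' @param amplitude fold amplitude (mm) for the sinusoidal sheet.
#' @param maxPolar angular radius (radians) of the spherical cap.
#' @return a [SurfacePair-class].
#' @export
makeCortex <- function(shape = c("sheet", "wedge", "sphere_patch",
                                 "sinusoidal_sheet"),
                       nx = 30L, ny = 30L, thickness = 3, areaRatio = 2,
                       radii = c(30, 33), extent = 20, amplitude = 2,
                       maxPolar = pi / 3) {
  shape <- match.arg(shape)
  if (any(thickness <= 0)) inputValueError("thickness must be positive")
  xs <- seq(0, extent, length.out = nx)
  ys <- seq(0, extent, length.out = ny)
  grid <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  faces <- gridFaces(nx, ny)
  if (shape == "sheet") {
    white <- cbind(grid, 0)
    pial <- cbind(grid, thickness)
  } else if (shape == "wedge") {
    white <- cbind(grid, 0)
    cx <- mean(range(xs))
    pial <- cbind(cx + (grid[, 1L] - cx) * areaRatio, grid[, 2L], thickness)
  } else if (shape == "sphere_patch") {
    if (length(radii) != 2L || radii[2L] <= radii[1L]) {
      inputValueError("radii must be an increasing (white, pial) pair")
    }
    polar <- seq(1e-3, maxPolar, length.out = nx)
    azim <- seq(0, 2 * pi, length.out = ny) # seam duplicated, ring closed
    ang <- cbind(rep(polar, times = ny), rep(azim, each = nx))
    unit <- cbind(sin(ang[, 1L]) * cos(ang[, 2L]),
                  sin(ang[, 1L]) * sin(ang[, 2L]),
                  cos(ang[, 1L]))
    white <- unit * radii[1L]
    pial <- unit * radii[2L]
  } else { # sinusoidal_sheet
    z <- amplitude * sin(2 * pi * grid[, 1L] / extent) *
      cos(2 * pi * grid[, 2L] / extent)
    white <- cbind(grid, z)
    nrm <- vertexNormals(white, faces)
    pial <- white + nrm * thickness
  }
  areas2 <- sqrt(rowSums(faceCross(white, faces)^2))
  if (any(areas2 <= 1e-12)) meshError("degenerate (zero-area) triangle in mesh")
  new("SurfacePair", white = white, pial = pial, faces = faces)
}

#' Analytic qT1 field and its rasterization
#'
#' `makeQt1Field` wraps a vectorized function of world coordinates
#' `f(x, y, z) -> qT1 (ms)` as a field object that [sampleField()] can
#' evaluate exactly. `rasterizeField` grids it onto voxels; the two agree at
#' voxel centers by construction.
#'
#' @param fun vectorized function of three coordinate vectors returning qT1.
#' @return an object of class `qt1Field` (analytic) or `qt1Volume` (raster).
#' @export
makeQt1Field <- function(fun) {
  if (!is.function(fun)) inputValueError("fun must be a function(x, y, z)")
  structure(list(fun = fun), class = "qt1Field")
}

#' @rdname makeQt1Field
#' @param field a `qt1Field`.
#' @param origin world coordinate of the first voxel center.
#' @param spacing voxel edge length(s) in mm.
#' @param dims integer triple of voxel counts.
#' @export
rasterizeField <- function(field, origin, spacing, dims) {
  stopifnot(inherits(field, "qt1Field"))
  spacing <- rep(spacing, length.out = 3L)
  gx <- origin[1L] + (seq_len(dims[1L]) - 1L) * spacing[1L]
  gy <- origin[2L] + (seq_len(dims[2L]) - 1L) * spacing[2L]
  gz <- origin[3L] + (seq_len(dims[3L]) - 1L) * spacing[3L]
  pts <- expand.grid(x = gx, y = gy, z = gz)
  vol <- array(field$fun(pts$x, pts$y, pts$z), dim = dims)
  structure(list(volume = vol, origin = origin, spacing = spacing),
            class = "qt1Volume")
}

#' Behavior linearly linked to sparse brain features
#'
#' `y = X w + e` with Gaussian noise: the planted generative model for the
#' behavioral prediction stage.
#'
#' @param features n x 35 feature matrix.
#' @param weights length-35 weight vector (sparse; typically 7 nonzero).
#' @param noiseSd residual SD.
#' @param seed integer seed.
#' @return numeric behavior-change vector.
#' @export
makeBehavior <- function(features, weights, noiseSd = 1, seed = 1L) {
  features <- as.matrix(features)
  if (length(weights) != ncol(features)) {
    inputShapeError(sprintf("weights length %d != %d features",
                            length(weights), ncol(features)))
  }
  drop(features %*% weights) +
    withSeed(seed, stats::rnorm(nrow(features), 0, noiseSd))
}

#' Synthetic a-priori network weight vectors
#'
#' Five smooth nonnegative per-parcel weight vectors standing in for the
#' meta-analytic networks targeted by the training modules (attention,
#' interoception, emotion, empathy, theory of mind). Each network is a
#' Gaussian bump around a random seed parcel in latent space, so networks are
#' spatially coherent and partially overlapping.
#'
#' @param coords n x 3 parcel coordinates (e.g. manifold latents).
#' @param ell bump width relative to coordinate scale.
#' @param seed integer seed.
#' @return n x 5 weight matrix with network column names.
#' @export
makeNetworkWeights <- function(coords, ell = 0.6, seed = 1L) {
  networks <- c("attention", "interoception", "emotion", "empathy",
                "theory_of_mind")
  n <- nrow(coords)
  withSeed(seed, {
    centers <- coords[sample.int(n, length(networks)), , drop = FALSE]
    w <- sapply(seq_along(networks), function(k) {
      d2 <- rowSums(sweep(coords, 2L, centers[k, ], "-")^2)
      exp(-d2 / (2 * ell^2))
    })
    colnames(w) <- networks
    rownames(w) <- rownames(coords)
    w
  })
}

#' Smooth Gaussian random maps on the sphere
#'
#' Draws maps with a squared-exponential covariance in chordal distance,
#' giving spatially autocorrelated fields like real cortical maps; used to
#' calibrate the spin test.
#'
#' @param coords n x 3 unit-sphere centroids.
#' @param ell correlation length (chordal).
#' @param nMaps number of maps.
#' @param seed integer seed.
#' @return n x nMaps matrix.
#' @export
makeSmoothSphereMaps <- function(coords, ell = 0.6, nMaps = 1L, seed = 1L) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  K <- exp(-d^2 / (2 * ell^2)) + diag(1e-8, n)
  L <- chol(K)
  withSeed(seed, crossprod(L, matrix(stats::rnorm(n * nMaps), n, nMaps)))
}
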