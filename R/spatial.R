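## Spatial correspondence between parcel maps, with spin-permutation nulls
## that preserve spatial autocorrelation.

#' Pearson spatial correlation of two parcel maps
#'
#' @param mapA,mapB per-parcel numeric vectors of equal length (>= 3);
#'   missing parcels are excluded pairwise.
#' @return Pearson correlation.
#' @export
spatialCorr <- function(mapA, mapB) {
  if (length(mapA) != length(mapB) || length(mapA) < 3L) {
    inputShapeError("maps must have equal length of at least 3")
  }
  ok <- stats::complete.cases(mapA, mapB)
  if (stats::var(mapA[ok]) == 0 || stats::var(mapB[ok]) == 0) {
    numericalError("zero-variance map: correlation undefined")
  }
  stats::cor(mapA[ok], mapB[ok])
}

#' Precompute spin permutations for a parcellation
#'
#' Draws Haar-uniform 3D rotations and maps every parcel to the nearest
#' rotated centroid, yielding reusable permutation index vectors. With a
#' hemisphere factor the same rotation is applied to the left hemisphere and
#' its x-mirrored version to the right (the standard spin-test convention),
#' with nearest-neighbour reassignment within hemisphere.
#'
#' @param coords parcel centroids; projected onto the unit sphere.
#' @param nPerm number of rotations.
#' @param seed integer seed.
#' @param hemisphere optional factor (`"L"`/`"R"`) per parcel; `NULL` treats
#'   all parcels as one sphere.
#' @return nPerm x nParcels integer matrix of permutation indices.
#' @export
spinPermutations <- function(coords, nPerm = 1000L, seed = 1L,
                             hemisphere = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) inputShapeError("centroids must be n x 3")
  if (anyNA(coords)) inputShapeError("missing centroids")
  if (nPerm < 1L) inputValueError("nPerm must be at least 1")
  unit <- coords / sqrt(rowSums(coords^2))
  n <- nrow(unit)
  mirror <- diag(c(-1, 1, 1))
  groups <- if (is.null(hemisphere)) {
    list(seq_len(n))
  } else {
    if (length(hemisphere) != n) inputShapeError("one hemisphere label per parcel")
    split(seq_len(n), hemisphere)
  }
  withSeed(seed, {
    rots <- randomRotations(nPerm)
    perms <- matrix(0L, nPerm, n)
    for (k in seq_len(nPerm)) {
      Q <- rots[[k]]
      for (gi in seq_along(groups)) {
        ix <- groups[[gi]]
        Qg <- if (gi == 2L) mirror %*% Q %*% mirror else Q
        rotated <- unit[ix, , drop = FALSE] %*% t(Qg)
        ## parcel p takes the value of the nearest rotated centroid
        near <- max.col(tcrossprod(unit[ix, , drop = FALSE], rotated),
                        ties.method = "first")
        perms[k, ix] <- ix[near]
      }
    }
    perms
  })
}

#' Spin permutation test for spatial correspondence
#'
#' Correlates `mapA` with `mapB`, then builds a null by randomly rotating
#' the parcel centroids on the sphere and re-assigning `mapA` by nearest
#' rotated centroid, which preserves its spatial autocorrelation. The
#' two-sided p value follows the permutation counting rule
#' `p = (1 + #{|null| >= |observed|}) / (nPerm + 1)`.
#'
#' @param mapA,mapB per-parcel maps; `mapA` is the rotated one.
#' @param coords parcel centroids on (or near) the unit sphere; required
#'   unless `perms` is given.
#' @param nPerm rotations, default 1000.
#' @param seed rotation seed.
#' @param hemisphere optional hemisphere factor, see [spinPermutations()].
#' @param perms optional precomputed permutation matrix (from
#'   [spinPermutations()]), reusable across map pairs of one parcellation.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a [SpinNull-class].
#' @export
spinTest <- function(mapA, mapB, coords = NULL, nPerm = 1000L, seed = 1L,
                     hemisphere = NULL, perms = NULL,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(mapA) != length(mapB)) {
    inputShapeError("maps must have equal length")
  }
  if (is.null(perms)) {
    if (is.null(coords)) inputShapeError("either coords or perms is required")
    if (nrow(as.matrix(coords)) != length(mapA)) {
      inputShapeError("one centroid per parcel required")
    }
    perms <- spinPermutations(coords, nPerm = nPerm, seed = seed,
                              hemisphere = hemisphere)
  } else {
    seed <- NA_integer_
    if (ncol(perms) != length(mapA)) {
      inputShapeError("permutation matrix does not match map length")
    }
    nPerm <- nrow(perms)
  }
  obs <- spatialCorr(mapA, mapB)
  nulls <- apply(perms, 1L, function(ix) {
    suppressWarnings(stats::cor(mapA[ix], mapB, use = "pairwise.complete.obs"))
  })
  exceed <- switch(alternative,
    two.sided = sum(abs(nulls) >= abs(obs), na.rm = TRUE),
    greater = sum(nulls >= obs, na.rm = TRUE),
    less = sum(nulls <= obs, na.rm = TRUE)
  )
  p <- (1 + exceed) / (nPerm + 1)
  new("SpinNull", observedR = obs, nullRs = as.numeric(nulls), pSpin = p,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      alternative = alternative)
}
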