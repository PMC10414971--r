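## Microstructure stage: vertex areas, equivolumetric depth fractions,
## intracortical surface stacks, field sampling, parcel profiles and
## compartment summaries.

triangleAreas <- function(vertices, faces) {
  sqrt(rowSums(faceCross(vertices, faces)^2)) / 2
}

#' Per-vertex surface area
#'
#' Each vertex receives one third of the summed area of its incident
#' triangles, so vertex areas sum exactly to the total mesh area.
#'
#' @param vertices n x 3 coordinate matrix (mm).
#' @param faces m x 3 triangulation.
#' @return per-vertex areas in mm^2.
#' @export
vertexAreas <- function(vertices, faces) {
  fa <- triangleAreas(vertices, faces)
  if (any(fa <= 1e-12)) meshError("degenerate (zero-area) triangle")
  va <- numeric(nrow(vertices))
  for (c in 1:3) {
    acc <- tapply(fa / 3, faces[, c], sum)
    ix <- as.integer(names(acc))
    va[ix] <- va[ix] + acc
  }
  va
}

#' Equivolumetric depth fraction
#'
#' Distance fraction `rho` (measured from the inner surface) at which a
#' surface must be placed so that a fraction `alpha` of the local cortical
#' volume lies beneath it, when the cross-sectional area varies linearly
#' from `aIn` to `aOut` across the cortical ribbon:
#' `rho = (-A_in + sqrt(alpha * A_out^2 + (1 - alpha) * A_in^2)) /
#' (A_out - A_in)`, i.e. the root of the cumulative-volume quadratic
#' `V(rho) = A_in * rho + rho^2 (A_out - A_in) / 2 = alpha * V(1)`. In the
#' flat limit `A_out = A_in` the analytic limit `rho = alpha` is returned.
#'
#' @param aIn,aOut inner/outer areas (positive; vectorized).
#' @param alpha volume fraction(s) in [0, 1].
#' @return depth fraction(s) in [0, 1], monotone increasing in `alpha`.
#' @export
equivolumeFraction <- function(aIn, aOut, alpha) {
  if (any(aIn <= 0) || any(aOut <= 0)) {
    inputValueError("areas must be positive")
  }
  if (any(alpha < 0 | alpha > 1)) {
    inputValueError("alpha must lie in [0, 1]")
  }
  n <- max(length(aIn), length(aOut), length(alpha))
  aIn <- rep_len(aIn, n); aOut <- rep_len(aOut, n); alpha <- rep_len(alpha, n)
  rho <- numeric(n)
  flat <- abs(aOut - aIn) < 1e-9 * pmax(aOut, aIn)
  rho[flat] <- alpha[flat]
  if (any(!flat)) {
    i <- !flat
    rho[i] <- (-aIn[i] + sqrt(alpha[i] * aOut[i]^2 + (1 - alpha[i]) * aIn[i]^2)) /
      (aOut[i] - aIn[i])
  }
  clamp(rho, 0, 1)
}

#' Build the equivolumetric laminar stack
#'
#' Places `nSurfaces` intracortical surfaces strictly between the white and
#' pial surfaces at volume fractions `alpha_i = i / (nSurfaces + 1)`
#' (measured from the white surface; the alternative midpoint rule
#' `(i - 0.5) / nSurfaces` is selectable). Every vertex is positioned on the
#' straight segment joining its linked white/pial vertices at the per-vertex
#' equivolumetric fraction computed from the white and pial vertex areas.
#' Surfaces are returned superficial-first, so depth index 1 is
#' pial-adjacent.
#'
#' @param sp a [SurfacePair-class].
#' @param nSurfaces number of intracortical surfaces, default 12.
#' @param placement `"interior"` (default, fractions i/(n+1)) or
#'   `"midpoint"` (fractions (i - 0.5)/n).
#' @return a [LaminarStack-class].
#' @export
buildLaminarStack <- function(sp, nSurfaces = 12L,
                              placement = c("interior", "midpoint")) {
  stopifnot(is(sp, "SurfacePair"))
  placement <- match.arg(placement)
  aIn <- vertexAreas(sp@white, sp@faces)
  aOut <- vertexAreas(sp@pial, sp@faces)
  fr <- seq_len(nSurfaces)
  alphaWhite <- switch(placement,
    interior = fr / (nSurfaces + 1),
    midpoint = (fr - 0.5) / nSurfaces
  )
  ## depth order: index 1 superficial (largest volume fraction from white)
  alphaDepth <- rev(alphaWhite)
  nV <- nrow(sp@white)
  rho <- matrix(NA_real_, nV, nSurfaces)
  surfaces <- vector("list", nSurfaces)
  for (d in seq_len(nSurfaces)) {
    rho[, d] <- equivolumeFraction(aIn, aOut, alphaDepth[d])
    surfaces[[d]] <- sp@white + rho[, d] * (sp@pial - sp@white)
  }
  new("LaminarStack", surfaces = surfaces, depthFractions = rho,
      volumeFractions = alphaDepth, faces = sp@faces,
      orientation = list(
        depthIndex = "1 = superficial (pial-adjacent)",
        volumeFraction = "measured from the white surface (0 = white, 1 = pial)",
        placement = placement))
}

#' Sample a qT1 field on a laminar stack
#'
#' Evaluates the field at every surface vertex: analytic fields
#' ([makeQt1Field()]) exactly, voxel volumes (`qt1Volume` or an RNifti
#' image) by trilinear interpolation. Out-of-bounds vertices are marked
#' missing; more than 5% missing aborts.
#'
#' @param stack a [LaminarStack-class].
#' @param field a `qt1Field`, a `qt1Volume`, or an `RNifti` image.
#' @param method interpolation kernel for voxel fields: `"trilinear"`
#'   (default) or `"nearest"`; analytic fields are always evaluated exactly.
#' @return vertex x depth matrix of qT1 samples (ms), NA where missing.
#' @export
sampleField <- function(stack, field, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is(stack, "LaminarStack"))
  ns <- length(stack@surfaces)
  nV <- nrow(stack@surfaces[[1L]])
  out <- matrix(NA_real_, nV, ns,
                dimnames = list(NULL, paste0("depth", seq_len(ns))))
  interp <- if (method == "trilinear") trilinearInterp else nearestInterp
  evalAt <- function(pts) {
    if (inherits(field, "qt1Field")) {
      field$fun(pts[, 1L], pts[, 2L], pts[, 3L])
    } else if (inherits(field, "qt1Volume")) {
      interp(field$volume, pts, field$origin, field$spacing)
    } else if (inherits(field, "niftiImage") &&
               requireNamespace("RNifti", quietly = TRUE)) {
      ## voxel grid of an RNifti image: use its world transform
      xf <- RNifti::xform(field)
      vol <- as.array(field)
      ijk <- cbind(pts, 1) %*% t(solve(xf))
      interp(vol, ijk[, 1:3, drop = FALSE], c(0, 0, 0), c(1, 1, 1))
    } else {
      inputValueError("unsupported field type")
    }
  }
  for (d in seq_len(ns)) out[, d] <- evalAt(stack@surfaces[[d]])
  nMiss <- sum(is.na(out))
  if (nMiss > 0) {
    message(sprintf("sampleField: %d of %d samples out of bounds",
                    nMiss, length(out)))
    if (nMiss / length(out) > 0.05) {
      samplingError("more than 5% of samples out of field bounds")
    }
  }
  out
}

#' Parcel-wise depth profiles
#'
#' Averages vertex samples within each parcel at every depth, skipping
#' missing samples pairwise. Parcels with fewer than 10 valid vertices are
#' flagged low-confidence; parcels with no vertices yield NA rows.
#'
#' @param samples vertex x depth matrix from [sampleField()].
#' @param labels integer parcel label per vertex; 0 = unassigned.
#' @param nParcels number of parcels (default: max label).
#' @return a [DepthProfileTable-class].
#' @export
parcelProfiles <- function(samples, labels, nParcels = NULL) {
  samples <- as.matrix(samples)
  if (length(labels) != nrow(samples)) {
    inputShapeError("one label per vertex required")
  }
  if (all(labels == 0L)) parcellationError("all vertices unassigned")
  if (is.null(nParcels)) nParcels <- max(labels)
  prof <- matrix(NA_real_, nParcels, ncol(samples),
                 dimnames = list(sprintf("p%03d", seq_len(nParcels)),
                                 colnames(samples)))
  nValid <- integer(nParcels)
  for (p in seq_len(nParcels)) {
    ix <- labels == p
    if (!any(ix)) next
    sub <- samples[ix, , drop = FALSE]
    prof[p, ] <- colMeans(sub, na.rm = TRUE)
    nValid[p] <- min(colSums(!is.na(sub)))
  }
  low <- rownames(prof)[nValid < 10L]
  new("DepthProfileTable", values = prof, standardized = FALSE,
      lowConfidence = low)
}

#' Depth-wise z-scoring of parcel profiles
#'
#' Standardizes each depth column across parcels using the population
#' (n-denominator) standard deviation, so column means are exactly 0 and
#' population SDs exactly 1.
#'
#' @param x a [DepthProfileTable-class] with at least 2 parcels.
#' @return the z-scored [DepthProfileTable-class].
#' @export
depthZscore <- function(x) {
  stopifnot(is(x, "DepthProfileTable"))
  v <- x@values
  if (nrow(v) < 2L) inputShapeError("z-scoring needs at least 2 parcels")
  mu <- colMeans(v, na.rm = TRUE)
  sdp <- sqrt(colMeans(sweep(v, 2L, mu, "-")^2, na.rm = TRUE))
  if (any(sdp == 0)) numericalError("zero-variance depth column")
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sdp, "/")
  new("DepthProfileTable", values = z, standardized = TRUE,
      lowConfidence = x@lowConfidence)
}

#' Depth-compartment means
#'
#' Means over the superficial (depths 1-4), middle (5-8) and deep (9-12)
#' compartments, with depth 1 the most superficial surface.
#'
#' @param x a [DepthProfileTable-class] with exactly 12 depths.
#' @return parcel x 3 matrix with columns superficial, middle, deep.
#' @export
compartmentMeans <- function(x) {
  stopifnot(is(x, "DepthProfileTable"))
  v <- x@values
  if (ncol(v) != 12L) {
    inputShapeError(sprintf("compartments are defined for 12 depths, got %d",
                            ncol(v)))
  }
  out <- cbind(
    superficial = rowMeans(v[, 1:4, drop = FALSE]),
    middle = rowMeans(v[, 5:8, drop = FALSE]),
    deep = rowMeans(v[, 9:12, drop = FALSE])
  )
  rownames(out) <- rownames(v)
  out
}
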