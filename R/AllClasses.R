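#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers. Validity methods enforce the structural invariants that
## downstream stages rely on; constructors do coercion and friendlier checks.
## ---------------------------------------------------------------------------

#' ConnectivityMatrix: symmetric parcel x parcel association matrix
#'
#' The input of the gradient pipeline. Values are unitless association
#' strengths (e.g. correlations); the diagonal is ignored by every downstream
#' operation.
#'
#' @slot values square numeric matrix.
#' @slot parcelIds character vector of parcel labels, one per row.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", parcelIds = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (!all(is.finite(v))) return("entries must be finite")
    if (length(object@parcelIds) != nrow(v)) {
      return("parcelIds length must equal matrix dimension")
    }
    asym <- max(abs(v - t(v)))
    if (asym > 1e-8) return(sprintf("matrix asymmetry %.3g exceeds 1e-8", asym))
    TRUE
  }
)

#' Construct a ConnectivityMatrix
#'
#' Symmetrizes by averaging with the transpose when the asymmetry is within
#' numerical tolerance (1e-8) and errors otherwise.
#'
#' @param values square numeric matrix.
#' @param parcelIds optional parcel labels; defaults to existing rownames or
#'   `p001`-style labels.
#' @return a [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(values, parcelIds = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    inputShapeError(sprintf("connectivity matrix must be square, got %d x %d",
                            nrow(values), ncol(values)))
  }
  if (any(!is.finite(values))) {
    inputValueError("connectivity matrix contains non-finite entries")
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) {
    inputValueError(sprintf("asymmetry %.3g exceeds tolerance 1e-8", asym))
  }
  values <- (values + t(values)) / 2
  if (is.null(parcelIds)) {
    parcelIds <- rownames(values)
    if (is.null(parcelIds)) {
      parcelIds <- sprintf("p%03d", seq_len(nrow(values)))
    }
  }
  dimnames(values) <- list(parcelIds, parcelIds)
  new("ConnectivityMatrix", values = values, parcelIds = as.character(parcelIds))
}

#' LatentManifold: generative description of a synthetic connectome
#'
#' Parcels live at 3D latent positions; connectivity decays with squared
#' latent distance under a Gaussian kernel. The default generator places
#' parcels on a radially jittered unit sphere, mirroring the fact that the
#' cortex is a two-dimensional sheet whose leading diffusion eigenfunctions
#' are close to linear in position.
#'
#' @slot coords n x 3 latent positions (unitless).
#' @slot kernelScale positive kernel bandwidth applied to squared distance.
#' @slot noiseSd standard deviation of symmetric additive edge noise.
#' @export
setClass("LatentManifold",
  representation(coords = "matrix", kernelScale = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (!all(is.finite(object@coords))) return("coords must be finite")
    if (length(object@kernelScale) != 1L || object@kernelScale <= 0) {
      return("kernelScale must be a positive scalar")
    }
    if (length(object@noiseSd) != 1L || object@noiseSd < 0) {
      return("noiseSd must be a nonnegative scalar")
    }
    TRUE
  }
)

#' EffectSpec: planted longitudinal effects for the cohort generator
#'
#' @slot maps named list of per-parcel mean change maps, one per training
#'   module; modules without an entry get a zero map.
#' @slot subjectSd random-intercept standard deviation (per subject, per
#'   parcel) of interval-to-interval change.
#' @slot residualSd residual standard deviation of interval change.
#' @export
setClass("EffectSpec",
  representation(maps = "list", subjectSd = "numeric", residualSd = "numeric"),
  validity = function(object) {
    if (length(object@maps) &&
        !all(vapply(object@maps, function(m) all(is.finite(m)), TRUE))) {
      return("effect maps must be finite")
    }
    if (object@subjectSd < 0 || object@residualSd < 0) {
      return("standard deviations must be nonnegative")
    }
    TRUE
  }
)

#' GradientEmbedding: diffusion-map scores of a connectome
#'
#' Columns are gradients ordered by eigenvalue (G1, G2, G3, ...). Under the
#' multiscale convention used at diffusion time t = 0 the i-th component is
#' scaled by lambda_i / (1 - lambda_i).
#'
#' @slot scores n_parcels x k score matrix.
#' @slot eigenvalues k nonincreasing eigenvalues of the diffusion operator
#'   (trivial unit eigenvalue removed).
#' @slot varianceExplained share lambda_i^2 / sum(lambda^2) over all
#'   nontrivial eigenvalues; sums to at most 1.
#' @slot alignmentRef identifier of the alignment reference, or `NA` when the
#'   embedding is unaligned.
#' @slot params list with `alpha` (density normalisation), `t` (diffusion
#'   time), `k`, and `mode` (`"multiscale"` or `"eigenvector"`).
#' @export
setClass("GradientEmbedding",
  representation(scores = "matrix", eigenvalues = "numeric",
                 varianceExplained = "numeric", alignmentRef = "character",
                 params = "list"),
  validity = function(object) {
    k <- ncol(object@scores)
    if (length(object@eigenvalues) != k) return("one eigenvalue per component")
    if (length(object@varianceExplained) != k) {
      return("one variance share per component")
    }
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE)) {
      return("eigenvalues must be nonincreasing")
    }
    if (sum(object@varianceExplained) > 1 + 1e-8) {
      return("variance explained must sum to at most 1")
    }
    TRUE
  }
)

#' EccentricityMap: per-parcel distance to the center of gradient space
#'
#' Euclidean distance of each parcel from the center of the space spanned by
#' the first three gradients. Low values mean functional integration, high
#' values segregation.
#'
#' @slot values named nonnegative numeric vector, one entry per parcel.
#' @slot center the 3-vector used as center.
#' @slot centerType `"centroid"` or `"origin"`.
#' @export
setClass("EccentricityMap",
  representation(values = "numeric", center = "numeric", centerType = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("eccentricity is nonnegative")
    if (length(object@center) != 3L) return("center must be a 3-vector")
    TRUE
  }
)

#' SurfacePair: corresponding pial and white cortical surfaces
#'
#' Both meshes share one triangulation and have 1-1 vertex correspondence,
#' i.e. vertex v of the white surface is linked to vertex v of the pial
#' surface. Coordinates are in millimetres.
#'
#' @slot white n x 3 vertex coordinates of the inner (white) surface.
#' @slot pial n x 3 vertex coordinates of the outer (pial) surface.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("SurfacePair",
  representation(white = "matrix", pial = "matrix", faces = "matrix"),
  validity = function(object) {
    if (!all(dim(object@white) == dim(object@pial))) {
      return("white and pial must have matching vertices")
    }
    if (ncol(object@white) != 3L) return("vertices must be n x 3")
    if (ncol(object@faces) != 3L) return("faces must be m x 3")
    if (!all(is.finite(object@white)) || !all(is.finite(object@pial))) {
      return("coordinates must be finite")
    }
    if (max(object@faces) > nrow(object@white) || min(object@faces) < 1L) {
      return("face indices out of range")
    }
    TRUE
  }
)

#' LaminarStack: equivolumetric intracortical surfaces
#'
#' Surfaces are stored in depth order: index 1 is the most superficial
#' (pial-adjacent) surface and index `nSurfaces` the deepest. Each vertex of
#' surface d sits on the straight segment joining its white and pial
#' positions at the per-vertex equivolumetric fraction `rho` (measured from
#' the white surface).
#'
#' @slot surfaces list of n x 3 vertex matrices, superficial to deep.
#' @slot depthFractions n x nSurfaces matrix of per-vertex fractions rho.
#' @slot volumeFractions the volume fractions alpha (measured from the white
#'   surface) that define each surface.
#' @slot faces shared triangulation.
#' @slot orientation metadata list recording both conventions.
#' @export
setClass("LaminarStack",
  representation(surfaces = "list", depthFractions = "matrix",
                 volumeFractions = "numeric", faces = "matrix",
                 orientation = "list"),
  validity = function(object) {
    ns <- length(object@surfaces)
    if (ncol(object@depthFractions) != ns) {
      return("one depth-fraction column per surface")
    }
    rho <- object@depthFractions
    if (any(rho <= 0) || any(rho >= 1)) {
      return("depth fractions must lie strictly inside (0, 1)")
    }
    ## depth order: superficial first, so rho decreases with depth index
    if (ns > 1L && any(rho[, -1L, drop = FALSE] >= rho[, -ns, drop = FALSE])) {
      return("depth fractions must decrease from superficial to deep")
    }
    TRUE
  }
)

#' DepthProfileTable: parcel x depth microstructure profiles
#'
#' Mean qT1 (ms) per parcel at each of the sampled intracortical depths,
#' depth 1 most superficial. `standardized` records whether columns have been
#' z-scored across parcels.
#'
#' @slot values parcel x depth numeric matrix.
#' @slot standardized logical flag.
#' @slot lowConfidence parcels averaged over fewer than 10 valid vertices.
#' @export
setClass("DepthProfileTable",
  representation(values = "matrix", standardized = "logical",
                 lowConfidence = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values) & !is.na(object@values))) {
      return("profiles must be finite or NA")
    }
    TRUE
  }
)

#' ContrastResult: per-parcel mixed-model contrast statistics
#'
#' @slot estimate contrast estimate per parcel (metric units).
#' @slot t Wald t statistic per parcel.
#' @slot p two-sided p value.
#' @slot q Benjamini-Hochberg adjusted p value.
#' @slot d effect size, d = t / sqrt(df).
#' @slot df residual degrees of freedom of the fixed-effects design.
#' @slot contrast human-readable contrast description.
#' @export
setClass("ContrastResult",
  representation(estimate = "numeric", t = "numeric", p = "numeric",
                 q = "numeric", d = "numeric", df = "numeric",
                 contrast = "character"),
  validity = function(object) {
    if (any(object@p < 0 | object@p > 1, na.rm = TRUE)) {
      return("p values must lie in [0, 1]")
    }
    if (any(object@q + 1e-12 < object@p, na.rm = TRUE)) {
      return("BH-adjusted values cannot be smaller than raw p values")
    }
    TRUE
  }
)

#' SpinNull: spin permutation test result
#'
#' @slot observedR observed Pearson correlation of the two maps.
#' @slot nullRs correlations under random spherical rotations.
#' @slot pSpin permutation p value, (1 + #{|null| >= |obs|}) / (nPerm + 1)
#'   for the two-sided default.
#' @slot nPerm number of rotations.
#' @slot seed rotation seed (NA when precomputed permutations were supplied).
#' @slot alternative `"two.sided"`, `"greater"` or `"less"`.
#' @export
setClass("SpinNull",
  representation(observedR = "numeric", nullRs = "numeric", pSpin = "numeric",
                 nPerm = "integer", seed = "integer", alternative = "character"),
  validity = function(object) {
    if (object@pSpin <= 0 || object@pSpin > 1) return("pSpin must lie in (0, 1]")
    if (length(object@nullRs) != object@nPerm) {
      return("one null correlation per permutation")
    }
    TRUE
  }
)

#' PredictionResult: repeated cross-validated behavioral prediction
#'
#' @slot repeatR out-of-sample Pearson r per repeat (pooled test
#'   predictions). Pooled r carries a small negative bias under the null
#'   because each fold's intercept is anti-correlated with its held-out
#'   mean; see the methods vignette.
#' @slot repeatRFoldMean per-repeat mean of fold-wise correlations; folds
#'   with constant predictions score 0 (no predictive signal). Preferred for
#'   null calibration checks.
#' @slot repeatNMAE negative mean absolute error per repeat (always <= 0).
#' @slot selectionFreq fraction of folds in which each feature was selected.
#' @slot meanCoef mean lasso coefficient per feature across folds.
#' @slot settings list (folds, reps, nSelect, lambda grid, seed).
#' @export
setClass("PredictionResult",
  representation(repeatR = "numeric", repeatRFoldMean = "numeric",
                 repeatNMAE = "numeric", selectionFreq = "numeric",
                 meanCoef = "numeric", settings = "list"),
  validity = function(object) {
    if (any(object@repeatNMAE > 1e-12)) return("nMAE must be nonpositive")
    if (any(object@selectionFreq < 0 | object@selectionFreq > 1)) {
      return("selection frequencies must lie in [0, 1]")
    }
    TRUE
  }
)
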