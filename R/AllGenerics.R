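## Accessor generics. Slots are never reached into from user code.

#' @rdname accessors
#' @param x a gradplast object.
#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))

#' Accessors for gradplast containers
#'
#' Small accessor family: `parcelIds` returns parcel labels,
#' `scores`/`eigenvalues`/`varianceExplained`/`alignmentRef`/`embeddingParams`
#' unpack a [GradientEmbedding-class], `eccValues` the per-parcel values of an
#' [EccentricityMap-class], `whiteSurface`/`pialSurface`/`meshFaces` the parts
#' of a [SurfacePair-class], `stackSurfaces`/`depthFractions`/`volumeFractions`
#' the parts of a [LaminarStack-class], `contrastStats` the per-parcel table
#' of a [ContrastResult-class], and `pSpin`/`observedR`/`nullDistribution`
#' the parts of a [SpinNull-class]. `repeatMetrics`, `selectionFrequency` and
#' `meanCoefficients` unpack a [PredictionResult-class].
#'
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("alignmentRef", function(x) standardGeneric("alignmentRef"))

#' @rdname accessors
#' @export
setGeneric("embeddingParams", function(x) standardGeneric("embeddingParams"))

#' @rdname accessors
#' @export
setGeneric("eccValues", function(x) standardGeneric("eccValues"))

#' @rdname accessors
#' @export
setGeneric("whiteSurface", function(x) standardGeneric("whiteSurface"))

#' @rdname accessors
#' @export
setGeneric("pialSurface", function(x) standardGeneric("pialSurface"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("stackSurfaces", function(x) standardGeneric("stackSurfaces"))

#' @rdname accessors
#' @export
setGeneric("depthFractions", function(x) standardGeneric("depthFractions"))

#' @rdname accessors
#' @export
setGeneric("volumeFractions", function(x) standardGeneric("volumeFractions"))

#' @rdname accessors
#' @export
setGeneric("contrastStats", function(x) standardGeneric("contrastStats"))

#' @rdname accessors
#' @export
setGeneric("pSpin", function(x) standardGeneric("pSpin"))

#' @rdname accessors
#' @export
setGeneric("observedR", function(x) standardGeneric("observedR"))

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @rdname accessors
#' @export
setGeneric("repeatMetrics", function(x) standardGeneric("repeatMetrics"))

#' @rdname accessors
#' @export
setGeneric("selectionFrequency", function(x) standardGeneric("selectionFrequency"))

#' @rdname accessors
#' @export
setGeneric("meanCoefficients", function(x) standardGeneric("meanCoefficients"))

## ---------------------------------------------------------------------------
## Methods
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @aliases parcelIds,ConnectivityMatrix-method
setMethod("parcelIds", "ConnectivityMatrix", function(x) x@parcelIds)

#' @rdname accessors
setMethod("parcelIds", "GradientEmbedding", function(x) rownames(x@scores))

#' @rdname accessors
setMethod("parcelIds", "EccentricityMap", function(x) names(x@values))

#' @rdname accessors
setMethod("parcelIds", "DepthProfileTable", function(x) rownames(x@values))

#' Matrix view of a ConnectivityMatrix
#' @param x the object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "ConnectivityMatrix", function(x, ...) x@values)

#' Matrix view of a DepthProfileTable
#' @param x the object.
#' @param ... unused.
#' @export
setMethod("as.matrix", "DepthProfileTable", function(x, ...) x@values)

#' @rdname accessors
setMethod("scores", "GradientEmbedding", function(x) x@scores)

#' @rdname accessors
setMethod("eigenvalues", "GradientEmbedding", function(x) x@eigenvalues)

#' @rdname accessors
setMethod("varianceExplained", "GradientEmbedding", function(x) x@varianceExplained)

#' @rdname accessors
setMethod("alignmentRef", "GradientEmbedding", function(x) x@alignmentRef)

#' @rdname accessors
setMethod("embeddingParams", "GradientEmbedding", function(x) x@params)

#' @rdname accessors
setMethod("eccValues", "EccentricityMap", function(x) x@values)

#' @rdname accessors
setMethod("whiteSurface", "SurfacePair", function(x) x@white)

#' @rdname accessors
setMethod("pialSurface", "SurfacePair", function(x) x@pial)

#' @rdname accessors
setMethod("meshFaces", "SurfacePair", function(x) x@faces)

#' @rdname accessors
setMethod("meshFaces", "LaminarStack", function(x) x@faces)

#' @rdname accessors
setMethod("stackSurfaces", "LaminarStack", function(x) x@surfaces)

#' @rdname accessors
setMethod("depthFractions", "LaminarStack", function(x) x@depthFractions)

#' @rdname accessors
setMethod("volumeFractions", "LaminarStack", function(x) x@volumeFractions)

#' @rdname accessors
setMethod("contrastStats", "ContrastResult", function(x) {
  data.frame(parcel = names(x@t), estimate = x@estimate, t = x@t, p = x@p,
             q = x@q, d = x@d, row.names = NULL)
})

#' @rdname accessors
setMethod("pSpin", "SpinNull", function(x) x@pSpin)

#' @rdname accessors
setMethod("observedR", "SpinNull", function(x) x@observedR)

#' @rdname accessors
setMethod("nullDistribution", "SpinNull", function(x) x@nullRs)

#' @rdname accessors
setMethod("repeatMetrics", "PredictionResult", function(x) {
  data.frame(repeatIndex = seq_along(x@repeatR), r = x@repeatR,
             rFoldMean = x@repeatRFoldMean, nMAE = x@repeatNMAE)
})

#' @rdname accessors
setMethod("selectionFrequency", "PredictionResult", function(x) x@selectionFreq)

#' @rdname accessors
setMethod("meanCoefficients", "PredictionResult", function(x) x@meanCoef)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ConnectivityMatrix", function(object) {
  v <- object@values
  cat(sprintf("ConnectivityMatrix: %d parcels\n", nrow(v)))
  off <- v[upper.tri(v)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f\n",
              min(off), max(off), mean(off)))
})

setMethod("show", "GradientEmbedding", function(object) {
  cat(sprintf("GradientEmbedding: %d parcels x %d components\n",
              nrow(object@scores), ncol(object@scores)))
  cat(sprintf("  alpha=%.2g t=%g mode=%s aligned=%s\n",
              object@params$alpha, object@params$t, object@params$mode,
              ifelse(is.na(object@alignmentRef), "no", object@alignmentRef)))
  ve <- object@varianceExplained
  cat(sprintf("  variance explained (top 3): %s\n",
              paste(sprintf("%.1f%%", 100 * ve[seq_len(min(3L, length(ve)))]),
                    collapse = ", ")))
})

setMethod("show", "EccentricityMap", function(object) {
  cat(sprintf("EccentricityMap: %d parcels, center=%s\n",
              length(object@values), object@centerType))
  cat(sprintf("  range [%.4f, %.4f]\n", min(object@values), max(object@values)))
})

setMethod("show", "SurfacePair", function(object) {
  cat(sprintf("SurfacePair: %d linked vertices, %d triangles\n",
              nrow(object@white), nrow(object@faces)))
})

setMethod("show", "LaminarStack", function(object) {
  cat(sprintf("LaminarStack: %d intracortical surfaces, %d vertices\n",
              length(object@surfaces), nrow(object@depthFractions)))
  cat("  depth 1 = superficial (pial-adjacent); fractions measured from white\n")
})

setMethod("show", "DepthProfileTable", function(object) {
  cat(sprintf("DepthProfileTable: %d parcels x %d depths%s\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) " (z-scored per depth)" else ""))
  if (length(object@lowConfidence)) {
    cat(sprintf("  %d low-confidence parcels (<10 valid vertices)\n",
                length(object@lowConfidence)))
  }
})

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("ContrastResult: %s (%d parcels, df=%.0f)\n",
              object@contrast, length(object@t), object@df))
  cat(sprintf("  FDR q<0.05 parcels: %d\n", sum(object@q < 0.05, na.rm = TRUE)))
})

setMethod("show", "SpinNull", function(object) {
  cat(sprintf("SpinNull: observed r=%.3f, p_spin=%.4g (%d rotations, %s)\n",
              object@observedR, object@pSpin, object@nPerm, object@alternative))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d repeats x %d folds\n",
              length(object@repeatR), object@settings$folds))
  cat(sprintf("  out-of-sample r (mean +/- SD): %.3f +/- %.3f\n",
              mean(object@repeatR), stats::sd(object@repeatR)))
  cat(sprintf("  nMAE (mean +/- SD): %.3f +/- %.3f\n",
              mean(object@repeatNMAE), stats::sd(object@repeatNMAE)))
})
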