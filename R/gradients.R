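## Functional-gradient stage: row thresholding, normalized-angle affinity,
## diffusion map embedding, Procrustes alignment, eccentricity and network
## summaries.

#' Fisher z transform of a connectivity matrix
#'
#' Applies `atanh` to the off-diagonal entries (clipped just inside (-1, 1)),
#' an optional preprocessing step before thresholding when the association
#' values are correlations. The diagonal is left untouched (it is ignored
#' downstream). Whether the transform was applied is recorded by the run
#' configuration, not inferred from the data.
#'
#' @param x a [ConnectivityMatrix-class] or square numeric matrix.
#' @return a numeric matrix.
#' @export
fisherZ <- function(x) {
  m <- if (is(x, "ConnectivityMatrix")) as.matrix(x) else as.matrix(x)
  d <- diag(m)
  m <- atanh(clamp(m, -1 + 1e-7, 1 - 1e-7))
  diag(m) <- d
  m
}

#' Row-wise proportional thresholding
#'
#' Keeps, in every row, the `ceil(density * (n - 1))` largest off-diagonal
#' entries and zeroes the rest (the diagonal is always zeroed). The default
#' density of 0.10 corresponds to thresholding at 90% per row. Boundary ties
#' are broken deterministically by (value descending, column index
#' ascending). The output is generally asymmetric.
#'
#' @param x a [ConnectivityMatrix-class] or square numeric matrix.
#' @param density fraction of off-diagonal entries retained per row, in (0, 1].
#' @return a numeric matrix of the same size.
#' @export
thresholdRows <- function(x, density = 0.10) {
  m <- if (is(x, "ConnectivityMatrix")) x@values else as.matrix(x)
  if (nrow(m) != ncol(m)) inputShapeError("matrix must be square")
  if (density <= 0 || density > 1) {
    inputValueError("density must lie in (0, 1]")
  }
  n <- nrow(m)
  keep <- ceiling(density * (n - 1L))
  out <- matrix(0, n, n, dimnames = dimnames(m))
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    v <- m[i, ]
    v[i] <- -Inf
    ord <- order(-v, cols) # ties: larger value first, then lower index
    sel <- ord[seq_len(keep)]
    out[i, sel] <- m[i, sel]
  }
  out
}

#' Normalized-angle affinity
#'
#' Converts a (thresholded) connectivity matrix into the affinity
#' `a_ij = 1 - arccos(cosine(row_i, row_j)) / pi`, bounded in [0, 1]:
#' identical rows map to 1, orthogonal rows to 0.5, anti-parallel rows to 0.
#' The result is symmetric with unit diagonal.
#'
#' @param x numeric matrix whose rows are connectivity profiles.
#' @return symmetric affinity matrix in [0, 1].
#' @export
normalizedAngle <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    inputValueError("zero-norm row: cosine similarity undefined")
  }
  cs <- tcrossprod(x / norms)
  cs <- clamp((cs + t(cs)) / 2, -1, 1)
  a <- 1 - acos(cs) / pi
  diag(a) <- 1
  a
}

## single connected component of the positive-affinity graph?
isConnectedAffinity <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(a[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Diffusion map embedding
#'
#' Embeds an affinity matrix by the diffusion-map spectral decomposition:
#' the kernel `W = D^-alpha A D^-alpha` (with `D` the degree of `A`)
#' controls how strongly the sampling density influences the manifold
#' (alpha = 0 maximal, alpha = 1 none); the transition operator `P`
#' row-normalizes `W`. Eigenvectors of `P` are computed through the
#' symmetric conjugate of `P` for numerical stability and normalized so the
#' trivial constant eigenvector is exactly 1, then dropped. At diffusion
#' time t = 0 the multiscale convention scales component i by
#' `lambda_i / (1 - lambda_i)`; `t > 0` uses `lambda_i^t`, and
#' `mode = "eigenvector"` applies no scaling. The variance explained by
#' component i is `lambda_i^2 / sum(lambda^2)` over all nontrivial
#' eigenvalues.
#'
#' @param a symmetric affinity matrix in [0, 1] with unit diagonal (e.g.
#'   from [normalizedAngle()]).
#' @param alpha density-normalisation exponent, default 0.5.
#' @param t diffusion time; 0 (default) selects the multiscale scaling.
#' @param k number of components returned, default 10.
#' @param mode `"multiscale"` (default, matches t = 0) or `"eigenvector"`
#'   (unscaled eigenvectors, flagged in the embedding provenance).
#' @return a [GradientEmbedding-class].
#' @export
diffusionEmbedding <- function(a, alpha = 0.5, t = 0, k = 10L,
                               mode = c("multiscale", "eigenvector")) {
  mode <- match.arg(mode)
  a <- as.matrix(a)
  n <- nrow(a)
  if (n != ncol(a)) inputShapeError("affinity must be square")
  if (max(abs(a - t(a))) > 1e-8) inputValueError("affinity must be symmetric")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12) {
    inputValueError("affinity entries must lie in [0, 1]")
  }
  if (!isConnectedAffinity(a)) {
    graphError("affinity graph is disconnected; embedding undefined")
  }
  if (k > n - 1L) inputShapeError("k must be at most n - 1")
  deg <- rowSums(a)
  W <- a / outer(deg^alpha, deg^alpha)
  dw <- rowSums(W)
  S <- W / outer(sqrt(dw), sqrt(dw))
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  if (lam[2L] >= 1 - 1e-10) {
    numericalError("nontrivial eigenvalue at 1: operator numerically singular")
  }
  if (lam[1L] > 1 + 1e-8) {
    numericalError("leading eigenvalue exceeds 1 beyond tolerance")
  }
  phi <- es$vectors / sqrt(dw)         # eigenvectors of P
  psi <- phi / phi[, 1L]               # trivial eigenvector == 1
  lamK <- lam[2:(k + 1L)]
  scal <- switch(mode,
    multiscale = if (t == 0) lamK / (1 - lamK) else lamK^t,
    eigenvector = rep(1, k)
  )
  sc <- psi[, 2:(k + 1L), drop = FALSE] * rep(scal, each = n)
  dimnames(sc) <- list(rownames(a), paste0("G", seq_len(k)))
  ve <- lamK^2 / sum(lam[-1L]^2)
  new("GradientEmbedding", scores = sc, eigenvalues = lamK,
      varianceExplained = ve, alignmentRef = NA_character_,
      params = list(alpha = alpha, t = t, k = as.integer(k), mode = mode))
}

#' Procrustes alignment of a gradient embedding to a reference
#'
#' Applies the orthogonal (rotation/reflection, no scaling or translation)
#' transform minimizing the Frobenius distance between the source and
#' reference score matrices over the first `nComponents` components.
#' Eigenvalues are unchanged; pairwise distances between parcels within the
#' embedding are preserved exactly.
#'
#' @param source,reference [GradientEmbedding-class] objects over the same
#'   parcels in the same order.
#' @param nComponents number of components aligned and returned (default:
#'   all shared components).
#' @param refId identifier stored in the alignment provenance.
#' @return the aligned [GradientEmbedding-class].
#' @export
procrustesAlign <- function(source, reference, nComponents = NULL,
                            refId = "reference") {
  stopifnot(is(source, "GradientEmbedding"), is(reference, "GradientEmbedding"))
  if (nrow(source@scores) != nrow(reference@scores) ||
      !identical(rownames(source@scores), rownames(reference@scores))) {
    inputShapeError("source and reference must share the parcel set and order")
  }
  kS <- ncol(source@scores); kR <- ncol(reference@scores)
  if (is.null(nComponents)) nComponents <- min(kS, kR)
  if (nComponents > min(kS, kR)) {
    inputShapeError("nComponents exceeds available components")
  }
  S <- source@scores[, seq_len(nComponents), drop = FALSE]
  R <- reference@scores[, seq_len(nComponents), drop = FALSE]
  sv <- svd(crossprod(S, R))
  Q <- sv$u %*% t(sv$v)
  aligned <- S %*% Q
  dimnames(aligned) <- dimnames(R)
  new("GradientEmbedding", scores = aligned,
      eigenvalues = source@eigenvalues[seq_len(nComponents)],
      varianceExplained = source@varianceExplained[seq_len(nComponents)],
      alignmentRef = refId, params = source@params)
}

#' Gradient eccentricity
#'
#' Per-parcel Euclidean distance of (G1, G2, G3) from the center of the
#' 3D gradient space -- the across-parcel centroid by default, or the origin
#' of the (aligned) space. Low eccentricity reads as functional integration,
#' high as segregation.
#'
#' @param embedding a [GradientEmbedding-class] with at least 3 components.
#' @param center `"centroid"` (default) or `"origin"`.
#' @return an [EccentricityMap-class].
#' @export
eccentricity <- function(embedding, center = c("centroid", "origin")) {
  center <- match.arg(center)
  stopifnot(is(embedding, "GradientEmbedding"))
  sc <- embedding@scores
  if (ncol(sc) < 3L) {
    inputShapeError("eccentricity needs at least 3 gradient components")
  }
  g <- sc[, 1:3, drop = FALSE]
  ctr <- if (center == "centroid") colMeans(g) else c(0, 0, 0)
  vals <- sqrt(rowSums(sweep(g, 2L, ctr, "-")^2))
  names(vals) <- rownames(sc)
  new("EccentricityMap", values = vals, center = unname(ctr),
      centerType = center)
}

#' Weighted network summary of a parcel map
#'
#' Weighted mean `sum(w * x) / sum(w)` of a per-parcel map within each
#' a-priori network.
#'
#' @param values per-parcel numeric vector.
#' @param weights per-parcel weight vector, or parcel x network matrix.
#' @return named numeric vector, one mean per network.
#' @export
networkSummary <- function(values, weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(values)) {
    inputShapeError("weight length must equal the number of parcels")
  }
  totals <- colSums(weights)
  if (any(totals == 0)) inputValueError("all-zero network weight vector")
  out <- drop(crossprod(weights, values)) / totals
  stats::setNames(out, colnames(weights))
}
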