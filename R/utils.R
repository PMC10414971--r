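#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Stages that need several independent streams derive child seeds from the
#' master seed with this helper, keeping every stream below 2^31 and fully
#' determined by `(seed, label)`.
#'
#' @param seed master integer seed.
#' @param label integer offset distinguishing the stream.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, label = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(label) * 16807) %% 2147483647
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Write / read a numeric table losslessly
#'
#' Text tables are written with 17 significant digits so that a write/read
#' round trip reproduces every double bit-identically, which is what makes
#' pipeline re-runs byte-comparable.
#'
#' @param x numeric matrix (row and column names are preserved).
#' @param path file path; tab-separated with a header line.
#' @return `readNumericTable` returns the matrix.
#' @export
writeNumericTable <- function(x, path) {
  x <- as.matrix(x)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(x)))
  rn <- rownames(x)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(x)))
  body <- apply(x, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
  lines <- c(
    paste(c("id", cn), collapse = "\t"),
    paste(rn, body, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNumericTable
#' @export
readNumericTable <- function(path) {
  if (!file.exists(path)) inputValueError(sprintf("no such file: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L)
  as.matrix(tab)
}

## clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a Haar-uniform 3D rotation
#'
#' Rotations are drawn by QR decomposition of a Gaussian matrix with the sign
#' convention of Mezzadri (2007), then reflected onto SO(3) if needed.
#'
#' @param n number of rotations.
#' @return a list of 3x3 rotation matrices (determinant +1).
#' @export
randomRotations <- function(n = 1L) {
  lapply(seq_len(n), function(i) {
    M <- matrix(stats::rnorm(9L), 3L, 3L)
    qrM <- qr(M)
    Q <- qr.Q(qrM)
    Q <- Q %*% diag(sign(diag(qr.R(qrM))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  })
}

#' Evenly distributed points on the unit sphere
#'
#' Fibonacci lattice, used as synthetic parcel centroids for spin tests.
#'
#' @param n number of points.
#' @return an n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azim <- pi * (1 + sqrt(5)) * i
  cbind(
    x = sin(polar) * cos(azim),
    y = sin(polar) * sin(azim),
    z = cos(polar)
  )
}

#' Procrustes congruence between two score matrices
#'
#' Columns of both matrices are centered, `a` is rotated onto `b` by the
#' orthogonal Procrustes solution with a single global scale, and Tucker's
#' congruence coefficient between the aligned matrices is returned. Equals 1
#' when `a` and `b` agree up to translation, rotation/reflection and scale.
#'
#' @param a,b numeric matrices with matching dimensions.
#' @return congruence coefficient in [-1, 1].
#' @export
procrustesCongruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) inputShapeError("matrices must share dimensions")
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  sv <- svd(crossprod(a, b))
  aq <- a %*% (sv$u %*% t(sv$v))
  sum(aq * b) / sqrt(sum(aq^2) * sum(b^2))
}

## nearest-voxel lookup of a 3D array at world coordinates
nearestInterp <- function(vol, pts, origin, spacing) {
  dims <- dim(vol)
  g <- round(sweep(sweep(pts, 2L, origin, "-"), 2L, spacing, "/")) + 1L
  ok <- g[, 1L] >= 1L & g[, 2L] >= 1L & g[, 3L] >= 1L &
    g[, 1L] <= dims[1L] & g[, 2L] <= dims[2L] & g[, 3L] <= dims[3L]
  out <- rep(NA_real_, nrow(pts))
  out[ok] <- vol[g[ok, , drop = FALSE]]
  out
}

## trilinear interpolation of a 3D array at world coordinates.
## origin: world position of voxel [1,1,1] center; spacing: voxel edge (mm).
## Points outside the grid return NA.
trilinearInterp <- function(vol, pts, origin, spacing) {
  dims <- dim(vol)
  g <- sweep(sweep(pts, 2L, origin, "-"), 2L, spacing, "/") # 0-based voxel coords
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1L] >= 0 & i0[, 2L] >= 0 & i0[, 3L] >= 0 &
    i0[, 1L] <= dims[1L] - 2L & i0[, 2L] <= dims[2L] - 2L & i0[, 3L] <= dims[3L] - 2L
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1L # 1-based lower corner
  f <- f[ok, , drop = FALSE]
  idx <- function(dx, dy, dz) {
    vol[cbind(i0[, 1L] + dx, i0[, 2L] + dy, i0[, 3L] + dz)]
  }
  out[ok] <-
    idx(0L, 0L, 0L) * (1 - f[, 1L]) * (1 - f[, 2L]) * (1 - f[, 3L]) +
    idx(1L, 0L, 0L) * f[, 1L]       * (1 - f[, 2L]) * (1 - f[, 3L]) +
    idx(0L, 1L, 0L) * (1 - f[, 1L]) * f[, 2L]       * (1 - f[, 3L]) +
    idx(0L, 0L, 1L) * (1 - f[, 1L]) * (1 - f[, 2L]) * f[, 3L] +
    idx(1L, 1L, 0L) * f[, 1L]       * f[, 2L]       * (1 - f[, 3L]) +
    idx(1L, 0L, 1L) * f[, 1L]       * (1 - f[, 2L]) * f[, 3L] +
    idx(0L, 1L, 1L) * (1 - f[, 1L]) * f[, 2L]       * f[, 3L] +
    idx(1L, 1L, 1L) * f[, 1L]       * f[, 2L]       * f[, 3L]
  out
}
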