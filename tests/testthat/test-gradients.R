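test_that("row thresholding keeps the right entries with deterministic ties", {
  m <- withr::with_seed(1, matrix(runif(16), 4, 4))
  m <- (m + t(m)) / 2; diag(m) <- 1

  # density 1: off-diagonal entries unchanged, diagonal zeroed
  t1 <- thresholdRows(m, 1)
  expect_equal(t1[upper.tri(t1) | lower.tri(t1)],
               m[upper.tri(m) | lower.tri(m)])
  expect_true(all(diag(t1) == 0))

  # density 1/3 on 4 parcels: exactly one survivor per row, the row max
  t2 <- thresholdRows(m, 1 / 3)
  for (i in 1:4) {
    surv <- which(t2[i, ] != 0)
    expect_length(surv, 1L)
    off <- m[i, -i]
    expect_equal(t2[i, surv], max(off))
  }

  # boundary ties resolve by (value desc, index asc): brute-force oracle
  tied <- rbind(c(0, 5, 5, 5, 1), c(5, 0, 1, 5, 5),
                c(5, 1, 0, 5, 5), c(5, 5, 5, 0, 1), c(1, 5, 5, 1, 0))
  tied <- (tied + t(tied)) / 2
  keep <- ceiling(0.5 * 4) # 2 survivors of 4 off-diagonal entries
  tt <- thresholdRows(tied, 0.5)
  for (i in 1:5) {
    v <- tied[i, ]; v[i] <- -Inf
    oracle <- order(-v, seq_along(v))[seq_len(keep)]
    expect_setequal(which(tt[i, ] != 0), oracle)
  }
})

test_that("normalized angle maps known row geometries to 1, 0.5, 0", {
  x <- rbind(c(1, 0, 1, 0), c(2, 0, 2, 0),   # parallel
             c(0, 1, 0, 1),                  # orthogonal to rows 1-2
             c(-1, 0, -1, 0))                # anti-parallel to rows 1-2
  a <- normalizedAngle(x)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0.5)
  expect_equal(a[1, 4], 0)
  expect_true(isSymmetric(a))
  expect_true(all(diag(a) == 1))
  expect_error(normalizedAngle(rbind(c(1, 1), c(0, 0))),
               class = "InputValueError")
})

test_that("embedding separates a two-block affinity on the first gradient", {
  n <- 20L
  blocks <- rep(c(1, 2), each = n / 2)
  a <- outer(blocks, blocks, function(i, j) ifelse(i == j, 0.9, 0.1))
  diag(a) <- 1
  emb <- diffusionEmbedding(a, k = 3)
  g1 <- scores(emb)[, 1]
  expect_true(all(sign(g1[blocks == 1]) == sign(g1[1])))
  expect_true(all(sign(g1[blocks == 2]) == -sign(g1[1])))
})

test_that("ring-graph affinity yields paired sine/cosine eigenvectors", {
  n <- 24L
  idx <- seq_len(n)
  circ <- pmin(abs(outer(idx, idx, "-")), n - abs(outer(idx, idx, "-")))
  a <- exp(-(circ / 3)^2)
  diag(a) <- 1
  emb <- diffusionEmbedding(a, k = 4)
  lam <- eigenvalues(emb)
  expect_equal(lam[1], lam[2], tolerance = 1e-10)
  expect_equal(lam[3], lam[4], tolerance = 1e-10)
  # leading pair spans the fundamental Fourier mode of the ring
  theta <- 2 * pi * (idx - 1) / n
  base <- cbind(sin(theta), cos(theta))
  sc <- scores(emb)[, 1:2]
  proj <- base %*% solve(crossprod(base), crossprod(base, sc))
  expect_lt(max(abs(sc - proj)), 1e-8)
})

test_that("constant affinity embeds to identically zero scores", {
  a <- matrix(1, 15, 15)
  emb <- diffusionEmbedding(a, k = 3)
  expect_true(all(abs(eigenvalues(emb)) < 1e-10))
  expect_true(all(abs(scores(emb)) < 1e-8))
})

test_that("embedding matches the brute-force dense operator", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    a <- randomAffinity(n, seed + 100)
    emb <- diffusionEmbedding(a, k = 3)
    oracle <- bruteEmbedding(a, k = 3)
    expect_lt(max(abs(alignSigns(scores(emb), oracle) - oracle)), 1e-8)
  }
})

test_that("disconnected affinity graphs are refused", {
  a <- as.matrix(Matrix::bdiag(matrix(1, 5, 5), matrix(1, 5, 5)))
  expect_error(diffusionEmbedding(a, k = 2), class = "GraphError")
})

test_that("the eigenvector mode skips the multiscale scaling", {
  a <- randomAffinity(20, 42)
  ms <- diffusionEmbedding(a, k = 3)
  ev <- diffusionEmbedding(a, k = 3, mode = "eigenvector")
  lam <- eigenvalues(ms)
  expect_equal(scores(ms),
               scores(ev) * rep(lam / (1 - lam), each = 20),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(embeddingParams(ev)$mode, "eigenvector")
})

test_that("Procrustes alignment inverts a known rotation exactly", {
  emb <- diffusionEmbedding(randomAffinity(25, 7), k = 3)
  # identity: source == reference
  self <- procrustesAlign(emb, emb)
  expect_equal(scores(self), scores(emb), tolerance = 1e-12)

  th <- 0.7
  R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- new("GradientEmbedding", scores = scores(emb) %*% R3,
             eigenvalues = eigenvalues(emb),
             varianceExplained = varianceExplained(emb),
             alignmentRef = NA_character_, params = embeddingParams(emb))
  back <- procrustesAlign(rot, emb)
  expect_lt(max(abs(scores(back) - scores(emb))), 1e-8)
  expect_equal(alignmentRef(back), "reference")

  # reflections are allowed: a sign-flipped component is corrected
  refl <- rot
  refl@scores <- scores(emb) %*% diag(c(-1, 1, 1))
  fixed <- procrustesAlign(refl, emb)
  expect_lt(max(abs(scores(fixed) - scores(emb))), 1e-10)

  # pairwise distances within the embedding are preserved
  d0 <- dist(scores(rot))
  d1 <- dist(scores(procrustesAlign(rot, emb)))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-10)
})

test_that("eccentricity matches direct arithmetic and is rotation invariant", {
  sc <- diag(3)
  emb <- new("GradientEmbedding", scores = sc, eigenvalues = c(3, 2, 1) / 10,
             varianceExplained = rep(0.1, 3), alignmentRef = NA_character_,
             params = list(alpha = 0.5, t = 0, k = 3L, mode = "multiscale"))
  ecc <- eccentricity(emb)
  expect_equal(unname(eccValues(ecc)), rep(sqrt(6) / 3, 3))
  expect_equal(ecc@center, rep(1 / 3, 3))

  # all parcels identical: zero eccentricity in centroid mode
  same <- emb; same@scores <- matrix(2, 5, 3)
  expect_true(all(eccValues(eccentricity(same)) == 0))

  # origin mode uses the origin
  expect_equal(unname(eccValues(eccentricity(emb, "origin"))), rep(1, 3))

  # global rotation leaves centroid eccentricity unchanged
  th <- 1.1
  R3 <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- emb; rot@scores <- sc %*% R3
  expect_equal(eccValues(eccentricity(rot)), eccValues(ecc),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("network summaries are weighted means", {
  expect_equal(unname(networkSummary(c(0, 4), matrix(c(1, 3), 2, 1))), 3)
  vals <- rep(2, 10)
  expect_equal(unname(networkSummary(vals, matrix(1, 10, 1))), 2)
  w <- withr::with_seed(3, matrix(runif(20), 10, 2))
  x <- withr::with_seed(4, rnorm(10))
  expect_equal(unname(networkSummary(x, w)),
               c(sum(w[, 1] * x) / sum(w[, 1]), sum(w[, 2] * x) / sum(w[, 2])))
  expect_error(networkSummary(x, matrix(0, 10, 1)), class = "InputValueError")
})

test_that("the Fisher z transform acts on off-diagonal entries only", {
  m <- withr::with_seed(8, { v <- matrix(runif(25, -0.8, 0.8), 5, 5); (v + t(v)) / 2 })
  diag(m) <- 1
  z <- fisherZ(ConnectivityMatrix(m))
  expect_equal(unname(diag(z)), rep(1, 5))
  off <- row(m) != col(m)
  expect_equal(z[off], atanh(m[off]))
  # monotone, so thresholding selects the same entries
  expect_equal(unname(thresholdRows(z, 0.5) != 0), unname(thresholdRows(m, 0.5) != 0))
})
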