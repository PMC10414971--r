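# Fixtures and independent oracles shared across the test files. Oracles are
# deliberately naive (loops, brute-force sorting, direct formulas) so they
# stay independent of the implementation paths they check.

# tiny valid design: 2 subjects TC1, 2 TC2, 1 RCC, all four timepoints
tinyDesign <- function() {
  makeCohortDesign(nTC1 = 2L, nTC2 = 2L, nRCC = 1L, seed = 99L)
}

# random symmetric affinity with unit diagonal, entries in [0, 1]
randomAffinity <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(n * n, 0.05, 1), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
}

# brute-force diffusion embedding through the non-symmetric operator P,
# mirroring the definition rather than the stabilized implementation. Each
# eigenvector of P is rescaled to unit norm under the degree inner product
# (the scale convention of the symmetric-normalized decomposition) before
# the trivial-eigenvector normalization.
bruteEmbedding <- function(a, alpha = 0.5, k = 3L) {
  deg <- rowSums(a)
  W <- a / outer(deg^alpha, deg^alpha)
  dw <- rowSums(W)
  P <- W / dw
  es <- eigen(P)
  ord <- order(-Re(es$values))
  lam <- Re(es$values[ord])
  vec <- Re(es$vectors[, ord, drop = FALSE])
  for (j in seq_len(ncol(vec))) {
    vec[, j] <- vec[, j] / sqrt(sum((vec[, j] * sqrt(dw))^2))
  }
  psi <- vec / vec[, 1L]           # constant trivial eigenvector -> 1
  lamK <- lam[2:(k + 1L)]
  psi[, 2:(k + 1L), drop = FALSE] * rep(lamK / (1 - lamK), each = nrow(a))
}

# align signs of columns of a to b (no rotation), for comparing eigenvectors
alignSigns <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  }
  a
}

# exact volume between two corresponding triangulated surfaces, by
# decomposing each triangular prism into three tetrahedra
prismStackVolume <- function(bottom, top, faces) {
  tet <- function(a, b, c, d) abs(det(rbind(b - a, c - a, d - a))) / 6
  total <- 0
  for (f in seq_len(nrow(faces))) {
    A <- bottom[faces[f, ], , drop = FALSE]
    B <- top[faces[f, ], , drop = FALSE]
    total <- total +
      tet(A[1, ], A[2, ], A[3, ], B[1, ]) +
      tet(A[2, ], A[3, ], B[1, ], B[2, ]) +
      tet(A[3, ], B[1, ], B[2, ], B[3, ])
  }
  total
}

# total triangle area of a mesh
meshArea <- function(vertices, faces) {
  area <- 0
  for (f in seq_len(nrow(faces))) {
    u <- vertices[faces[f, 2L], ] - vertices[faces[f, 1L], ]
    v <- vertices[faces[f, 3L], ] - vertices[faces[f, 1L], ]
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    area <- area + sqrt(sum(cr^2)) / 2
  }
  area
}

# brute-force Benjamini-Hochberg step-up rejections at level q
bruteBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  reject <- logical(m)
  if (kmax > 0L) reject[ord[seq_len(kmax)]] <- TRUE
  reject
}
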