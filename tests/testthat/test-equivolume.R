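test_that("vertex areas follow the thirds rule and sum to the mesh area", {
  # single triangle of area 3: each vertex receives 1
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0))
  f <- matrix(c(1L, 2L, 3L), 1)
  expect_equal(vertexAreas(v, f), rep(1, 3))

  # unit square as two triangles: areas sum to 1, split by incidence
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  fs <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  va <- vertexAreas(sq, fs)
  expect_equal(sum(va), 1)
  expect_equal(va, c(1 / 3, 1 / 6, 1 / 3, 1 / 6))

  # similarity: scaling the mesh by s scales areas by s^2
  expect_equal(vertexAreas(2.5 * sq, fs), 2.5^2 * va)

  degen <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(vertexAreas(degen, f), class = "MeshError")
})

test_that("equivolume fraction solves the cumulative-volume quadratic", {
  # boundaries and flat limit
  expect_equal(equivolumeFraction(1, 2, 0), 0)
  expect_equal(equivolumeFraction(1, 2, 1), 1)
  expect_equal(equivolumeFraction(1.7, 1.7, 0.35), 0.35)

  # A_in=1, A_out=2, alpha=0.5: root of V(rho) = rho + rho^2/2 = 0.5 * 1.5
  expect_equal(equivolumeFraction(1, 2, 0.5), sqrt(2.5) - 1, tolerance = 1e-12)

  # oracle: numeric root of the cumulative-volume quadratic for random areas
  withr::with_seed(9, {
    for (i in 1:20) {
      aIn <- runif(1, 0.2, 3); aOut <- runif(1, 0.2, 3); al <- runif(1)
      vol <- function(r) aIn * r + r^2 * (aOut - aIn) / 2
      root <- uniroot(function(r) vol(r) - al * vol(1), c(0, 1),
                      tol = 1e-14)$root
      expect_equal(equivolumeFraction(aIn, aOut, al), root, tolerance = 1e-9)
    }
  })

  # monotone in alpha, bounded in [0, 1]
  rho <- equivolumeFraction(0.5, 3, seq(0, 1, 0.01))
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0 & rho <= 1))

  expect_error(equivolumeFraction(-1, 2, 0.5), class = "InputValueError")
  expect_error(equivolumeFraction(1, 2, 1.2), class = "InputValueError")
})

test_that("flat cortex collapses the equivolumetric stack to equidistance", {
  sp <- makeCortex("sheet", nx = 10, ny = 10, thickness = 3)
  st <- buildLaminarStack(sp, 12L)
  alphaDepth <- volumeFractions(st)
  expect_equal(alphaDepth, rev(1:12) / 13)
  for (d in 1:12) {
    expected <- whiteSurface(sp) + alphaDepth[d] *
      (pialSurface(sp) - whiteSurface(sp))
    expect_lt(max(abs(stackSurfaces(st)[[d]] - expected)), 1e-9 * 3)
  }
  # single mid surface on a flat sheet: the midthickness surface
  mid <- buildLaminarStack(sp, 1L)
  expect_equal(volumeFractions(mid), 0.5)
  expect_lt(max(abs(stackSurfaces(mid)[[1]] -
                      (whiteSurface(sp) + pialSurface(sp)) / 2)), 1e-12)
})

test_that("wedge stack preserves fractional volume between surfaces", {
  sp <- makeCortex("wedge", nx = 25, ny = 25, thickness = 3, areaRatio = 2)
  st <- buildLaminarStack(sp, 12L)
  surfaces <- c(list(pialSurface(sp)), stackSurfaces(st),
                list(whiteSurface(sp)))
  vols <- vapply(seq_len(12), function(i) {
    prismStackVolume(surfaces[[i + 1]], surfaces[[i]], meshFaces(sp))
  }, numeric(1))
  gaps <- vols[2:12] # the 11 gaps between the 12 intracortical surfaces
  expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 1e-3)
  # and all 13 compartments (including the boundary ones) tile the ribbon
  total <- prismStackVolume(whiteSurface(sp), pialSurface(sp), meshFaces(sp))
  expect_equal(sum(vols) + prismStackVolume(surfaces[[13]], surfaces[[14]],
                                            meshFaces(sp)),
               total, tolerance = 1e-10)
})

test_that("field sampling is exact for analytic and linear voxel fields", {
  sp <- makeCortex("sheet", nx = 6, ny = 6, thickness = 3, extent = 5)
  st <- buildLaminarStack(sp, 12L)

  cst <- makeQt1Field(function(x, y, z) rep(1500, length(x)))
  expect_true(all(sampleField(st, cst) == 1500))

  # analytic depth profile q = 1200 + 600 * rho(depth): exact recovery
  prof <- makeQt1Field(function(x, y, z) 1200 + 600 * (z / 3))
  s <- sampleField(st, prof)
  rho <- depthFractions(st)
  expect_lt(max(abs(s - (1200 + 600 * rho))), 1e-6)

  # trilinear interpolation reproduces a linear field exactly off-grid
  lin <- makeQt1Field(function(x, y, z) 2 * x - 3 * y + 4 * z + 100)
  vol <- rasterizeField(lin, origin = c(-1, -1, -1), spacing = 0.5,
                        dims = c(16L, 16L, 12L))
  sVol <- sampleField(st, vol)
  sAna <- sampleField(st, lin)
  expect_lt(max(abs(sVol - sAna)), 1e-9)

  # surfaces far outside the volume: sampling error
  tiny <- rasterizeField(lin, origin = c(0, 0, 0), spacing = 0.1,
                         dims = c(4L, 4L, 4L))
  expect_error(suppressMessages(sampleField(st, tiny)),
               class = "SamplingError")
})

test_that("parcel profiles equal brute-force group means", {
  withr::with_seed(12, {
    samples <- matrix(rnorm(60 * 12, 1400, 50), 60, 12)
    labels <- sample(0:4, 60, replace = TRUE)
  })
  pt <- parcelProfiles(samples, labels, nParcels = 4L)
  vals <- as.matrix(pt)
  for (p in 1:4) {
    for (d in 1:12) {
      expect_equal(unname(vals[p, d]), mean(samples[labels == p, d]))
    }
  }
  # two parcels with distinct constants are recovered exactly
  cs <- matrix(rep(c(1300, 1600), times = c(5, 5)), 10, 12)
  expect_equal(unname(as.matrix(parcelProfiles(cs, rep(1:2, each = 5))))[, 1],
               c(1300, 1600))
  expect_error(parcelProfiles(samples, rep(0L, 60)),
               class = "ParcellationError")
})

test_that("depth z-scoring uses the population convention", {
  two <- new("DepthProfileTable",
             values = matrix(c(1, 3), 2, 12), standardized = FALSE,
             lowConfidence = character(0))
  z <- depthZscore(two)
  expect_equal(unname(as.matrix(z)), matrix(c(-1, 1), 2, 12))

  withr::with_seed(5, {
    v <- matrix(rnorm(60), 5, 12)
  })
  tab <- new("DepthProfileTable", values = v, standardized = FALSE,
             lowConfidence = character(0))
  z2 <- as.matrix(depthZscore(tab))
  oracle <- apply(v, 2, function(col) (col - mean(col)) /
                    sqrt(mean((col - mean(col))^2)))
  expect_equal(unname(z2), oracle)
  expect_equal(unname(colMeans(z2)), rep(0, 12))
  # an already-standardized table is unchanged
  expect_equal(as.matrix(depthZscore(depthZscore(tab))), z2)

  flat <- new("DepthProfileTable", values = matrix(1, 3, 12),
              standardized = FALSE, lowConfidence = character(0))
  expect_error(depthZscore(flat), class = "NumericalError")
})

test_that("compartment means group depths 1-4, 5-8, 9-12", {
  prof <- new("DepthProfileTable",
              values = matrix(1:12, 1, 12, byrow = TRUE),
              standardized = FALSE, lowConfidence = character(0))
  cm <- compartmentMeans(prof)
  expect_equal(unname(cm[1, ]), c(2.5, 6.5, 10.5))

  cst <- new("DepthProfileTable", values = matrix(7, 3, 12),
             standardized = FALSE, lowConfidence = character(0))
  expect_true(all(compartmentMeans(cst) == 7))

  short <- new("DepthProfileTable", values = matrix(1, 2, 11),
               standardized = FALSE, lowConfidence = character(0))
  expect_error(compartmentMeans(short), class = "InputShapeError")
})

test_that("nearest-neighbour sampling snaps to voxel centers", {
  sp <- makeCortex("sheet", nx = 5, ny = 5, thickness = 3, extent = 4)
  st <- buildLaminarStack(sp, 3L)
  f <- makeQt1Field(function(x, y, z) 100 * round(x) + round(y))
  vol <- rasterizeField(f, origin = c(-1, -1, -1), spacing = 1,
                        dims = c(8L, 8L, 7L))
  sNear <- sampleField(st, vol, method = "nearest")
  # the nearest voxel center carries the field value at rounded coordinates
  expect_equal(sNear[, 1],
               100 * round(stackSurfaces(st)[[1]][, 1]) +
                 round(stackSurfaces(st)[[1]][, 2]))
})
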