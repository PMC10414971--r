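test_that("in-fold residualization uses training betas only", {
  # feature exactly linear in age: training residuals are exactly zero
  age <- c(20, 30, 40, 50); sex <- c(0, 1, 0, 1)
  x <- matrix(2 * age - 7, 4, 1)
  rz <- residualizeInFold(x, x, cbind(age, sex), cbind(age, sex))
  expect_lt(max(abs(rz$train)), 1e-10)

  # hand-built case where train and test betas differ: the test rows must
  # be residualized with the training fit, not their own
  covTr <- cbind(age = c(20, 30, 40, 50), sex = c(0, 0, 1, 1))
  xTr <- matrix(c(1, 2, 3, 4), 4, 1)
  covTe <- cbind(age = c(25, 45, 35, 28), sex = c(1, 0, 0, 1))
  xTe <- matrix(c(10, 20, 15, 12), 4, 1)
  B <- solve(crossprod(cbind(1, covTr)),
             crossprod(cbind(1, covTr), xTr)) # closed-form OLS
  rz2 <- residualizeInFold(xTr, xTe, covTr, covTe)
  expect_equal(rz2$test, xTe - cbind(1, covTe) %*% B)
  # residualizing the test rows with their own betas would differ
  Bte <- solve(crossprod(cbind(1, covTe)), crossprod(cbind(1, covTe), xTe))
  expect_false(isTRUE(all.equal(rz2$test, xTe - cbind(1, covTe) %*% Bte)))

  # covariates uncorrelated with the feature, large n: residual ~ centered
  withr::with_seed(31, {
    n <- 4000
    cv <- cbind(age = runif(n, 20, 55), sex = rbinom(n, 1, 0.5))
    x3 <- matrix(rnorm(n), n, 1)
    rz3 <- residualizeInFold(x3, x3, cv, cv)
    expect_lt(max(abs(rz3$train - (x3 - mean(x3)))), 0.25)
    expect_lt(mean(abs(rz3$train - (x3 - mean(x3)))), 0.05)
  })

  expect_error(residualizeInFold(xTr, xTe, cbind(1:4, 2 * (1:4)),
                                 covTe[, 1:2]),
               class = "NumericalError")
})

test_that("the single-penalty lasso matches glmnet", {
  withr::with_seed(41, {
    n <- 80; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1] * 1.5 - X[, 3] + rnorm(n, 0, 0.5)
  })
  for (lam in c(0.005, 0.05, 0.3)) {
    fit <- gradplast:::lassoCD(X, y, lam)
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam,
                        thresh = 1e-12)
    expect_equal(fit$beta, as.numeric(g$beta), tolerance = 1e-5)
    expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-5)
  }
})

test_that("greedy selection finds an exact feature first and is exhaustive", {
  withr::with_seed(42, {
    X <- matrix(rnorm(50 * 10), 50, 10)
  })
  y <- 2 * X[, 7]   # zero-error feature
  sel <- sequentialSelect(X, y, nSelect = 3)
  expect_equal(sel[1], 7L)
  # n_select = n_features returns all features
  expect_setequal(sequentialSelect(X, y, nSelect = 10), 1:10)
  expect_error(sequentialSelect(X, rep(1, 50), nSelect = 2),
               class = "InputValueError")
  expect_error(sequentialSelect(X, y, nSelect = 11),
               class = "InputShapeError")
})

test_that("greedy selection recovers a planted support at high SNR", {
  recalls <- withr::with_seed(43, {
    vapply(1:25, function(i) {
      n <- 100; p <- 35
      true <- sample(p, 7)
      X <- matrix(rnorm(n * p), n, p)
      w <- numeric(p); w[true] <- sqrt((0.7 / 0.3) / 7) # population R^2 = 0.7
      y <- drop(X %*% w) + rnorm(n)
      length(intersect(sequentialSelect(X, y, 7), true))
    }, numeric(1))
  })
  expect_gte(median(recalls), 5)
})

test_that("cross-validated lasso recovers a clean signal and handles edge cases", {
  withr::with_seed(44, {
    n <- 60
    X <- matrix(rnorm(n * 4), n, 4)
    y <- 3 * X[, 1]
  })
  fit <- fitPredictLasso(X, y, X, seed = 1)
  expect_gt(fit$coef[1], 2.7)
  expect_lt(max(abs(fit$coef[-1])), 0.15)
  expect_lt(mean(abs(fit$pred - y)), 0.2)

  # all-zero target: predictions are all zero
  z <- fitPredictLasso(X, rep(0, n), X, seed = 1)
  expect_true(all(z$pred == 0))

  # predictions are invariant to feature ordering
  perm <- c(3, 1, 4, 2)
  fit2 <- fitPredictLasso(X[, perm], y, X[, perm], seed = 1)
  expect_equal(fit2$pred, fit$pred, tolerance = 1e-8)
  expect_equal(fit2$coef, fit$coef[perm], tolerance = 1e-6)

  # single-feature path (closed-form univariate lasso)
  f1 <- fitPredictLasso(X[, 1, drop = FALSE], y, X[, 1, drop = FALSE],
                        seed = 1)
  expect_lt(mean(abs(f1$pred - y)), 0.1)

  expect_error(fitPredictLasso(X[1, , drop = FALSE], y[1], X),
               class = "InputShapeError")
})

test_that("repeated cross-validation detects a planted sparse signal", {
  withr::with_seed(45, {
    n <- 100; p <- 35
    true <- sample(p, 7)
    X <- matrix(rnorm(n * p), n, p)
    w <- numeric(p); w[true] <- sqrt((0.6 / 0.4) / 7) # R^2 = 0.6
    y <- drop(X %*% w) + rnorm(n)
    age <- runif(n, 20, 55); sex <- rbinom(n, 1, 0.5)
  })
  pr <- crossValidate(X, y, age, sex, folds = 5, reps = 5, seed = 9)
  expect_gt(mean(repeatMetrics(pr)$r), 0.4)
  expect_true(all(repeatMetrics(pr)$nMAE <= 0))
  # informative features are selected more often than noise features
  expect_gt(mean(selectionFrequency(pr)[true]),
            2 * mean(selectionFrequency(pr)[-true]))
  # bit-reproducible given (seed, data)
  pr2 <- crossValidate(X, y, age, sex, folds = 5, reps = 5, seed = 9)
  expect_identical(repeatMetrics(pr), repeatMetrics(pr2))
  expect_error(crossValidate(X[1:8, ], y[1:8], age[1:8], sex[1:8],
                             folds = 5),
               class = "InputShapeError")
})

test_that("specificity controls separate in-domain from off-domain targets", {
  withr::with_seed(46, {
    n <- 90; p <- 35
    X <- matrix(rnorm(n * p), n, p)
    w <- numeric(p); w[1:7] <- sqrt((0.6 / 0.4) / 7)
    y <- drop(X %*% w) + rnorm(n)
    yShuffled <- sample(y)
    age <- runif(n, 20, 55); sex <- rbinom(n, 1, 0.5)
  })
  res <- specificityTests(X, y, list(shuffled = yShuffled), age, sex,
                          folds = 5, reps = 6, seed = 12)
  expect_gt(res$comparison$meanDiff, 0)
  expect_lt(res$comparison$p, 0.05)
  # identical targets in both slots: no dominance
  same <- specificityTests(X, y, list(same = y), age, sex,
                           folds = 5, reps = 4, seed = 12)
  expect_equal(same$comparison$meanDiff, 0, tolerance = 1e-12)
})

test_that("feature tables assemble 5 networks x 7 metrics", {
  nSub <- 6L; nP <- 30L
  coords <- fibonacciSphere(nP)
  w <- makeNetworkWeights(coords, seed = 3)
  deltas <- withr::with_seed(47, {
    ms <- lapply(1:7, function(i) matrix(rnorm(nSub * nP), nSub, nP))
    names(ms) <- c("ecc", "G1", "G2", "G3", "qt1_superficial",
                   "qt1_middle", "qt1_deep")
    ms
  })
  ft <- assembleFeatureTable(deltas, w)
  expect_equal(dim(ft), c(nSub, 35L))
  expect_true("attention.ecc" %in% colnames(ft))
  # spot-check one cell against the weighted-mean definition
  expect_equal(ft[2, "empathy.G2"],
               sum(w[, "empathy"] * deltas$G2[2, ]) / sum(w[, "empathy"]),
               ignore_attr = TRUE)
  expect_error(assembleFeatureTable(deltas[1:3], w),
               class = "InputShapeError")
})
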