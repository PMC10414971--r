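## Behavioral prediction stage: leakage-controlled nuisance removal,
## sequential feature selection, lasso fitting and repeated cross-validation.

#' In-fold nuisance residualization
#'
#' Regresses every feature on (1, age, sex) using the training rows only and
#' applies the training coefficients to the test rows, so no test
#' information leaks into the nuisance model.
#'
#' @param xTrain,xTest feature matrices.
#' @param covTrain,covTest covariate matrices (columns age, sex) for the
#'   corresponding rows.
#' @return list with residualized `train` and `test` matrices.
#' @export
residualizeInFold <- function(xTrain, xTest, covTrain, covTest) {
  xTrain <- as.matrix(xTrain); xTest <- as.matrix(xTest)
  C <- cbind(1, as.matrix(covTrain))
  if (qr(C)$rank < ncol(C)) {
    numericalError("collinear nuisance covariates")
  }
  B <- solve(crossprod(C), crossprod(C, xTrain))
  list(train = xTrain - C %*% B,
       test = xTest - cbind(1, as.matrix(covTest)) %*% B)
}

## Coordinate-descent lasso at a single penalty, glmnet parameterisation:
## minimize (1/2n)||y - b0 - X b||^2 + lambda * sum_j |b_j| with the penalty
## applied to coefficients of columns standardized by the population SD.
## Used for the greedy selection pass, where the candidate sets are tiny
## (<= nSelect columns) and a full glmnet call per candidate would dominate
## the runtime. Validated against glmnet in the test suite.
lassoCD <- function(x, y, lambda, tol = 1e-10, maxIter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  mx <- colMeans(x)
  sx <- sqrt(colMeans(x^2) - mx^2)
  active <- sx > 0
  xs <- sweep(sweep(x[, active, drop = FALSE], 2L, mx[active], "-"),
              2L, sx[active], "/")
  my <- mean(y); yc <- y - my
  pa <- ncol(xs)
  b <- numeric(pa)
  r <- yc
  for (iter in seq_len(maxIter)) {
    maxDelta <- 0
    for (j in seq_len(pa)) {
      bOld <- b[j]
      z <- mean(xs[, j] * r) + bOld
      bNew <- sign(z) * max(abs(z) - lambda, 0)
      if (bNew != bOld) {
        r <- r - xs[, j] * (bNew - bOld)
        b[j] <- bNew
        maxDelta <- max(maxDelta, abs(bNew - bOld))
      }
    }
    if (maxDelta < tol) break
  }
  beta <- numeric(p)
  beta[active] <- b / sx[active]
  intercept <- my - sum(beta * mx)
  list(intercept = intercept, beta = beta)
}

lassoPredict <- function(fit, x) {
  drop(as.matrix(x) %*% fit$beta) + fit$intercept
}

## Gram-matrix coordinate descent for the same objective as lassoCD, on
## standardized columns: b_j <- S(c_j - sum_{k != j} G_jk b_k, lambda) with
## G = Xs'Xs/n and c = Xs'y/n. All n-dependent work happens once per fold,
## which is what makes the greedy pass cheap.
lassoGramCD <- function(G, cvec, lambda, tol = 1e-9, maxIter = 500L) {
  p <- length(cvec)
  b <- numeric(p)
  for (iter in seq_len(maxIter)) {
    maxDelta <- 0
    for (j in seq_len(p)) {
      z <- cvec[j] - sum(G[j, ] * b) + b[j]
      bNew <- sign(z) * max(abs(z) - lambda, 0)
      if (bNew != b[j]) {
        maxDelta <- max(maxDelta, abs(bNew - b[j]))
        b[j] <- bNew
      }
    }
    if (maxDelta < tol) break
  }
  b
}

#' Greedy sequential feature selection
#'
#' Forward selection: at each step the feature whose addition minimizes the
#' training-set mean absolute error of the lasso estimator (at a fixed
#' mid-grid penalty, no cross-validation during the greedy pass) joins the
#' set, until `nSelect` features are chosen. Deterministic given the input;
#' ties resolve to the lowest feature index.
#'
#' @param x training feature matrix.
#' @param y training target; must not be constant.
#' @param nSelect number of features to select (default 7 = 20% of 35).
#' @param lambda penalty used during the greedy pass; the default 0.01 is
#'   the geometric midpoint of the [1e-4, 1] grid.
#' @return integer vector of selected feature indices, in selection order.
#' @export
sequentialSelect <- function(x, y, nSelect = 7L, lambda = 0.01) {
  x <- as.matrix(x)
  if (nSelect > ncol(x)) inputShapeError("nSelect exceeds feature count")
  if (stats::var(y) == 0) inputValueError("constant target: selection undefined")
  n <- nrow(x)
  mx <- colMeans(x)
  sx <- sqrt(colMeans(x^2) - mx^2)
  usable <- which(sx > 0)
  if (nSelect > length(usable)) {
    inputShapeError("nSelect exceeds the number of non-constant features")
  }
  xs <- sweep(sweep(x[, usable, drop = FALSE], 2L, mx[usable], "-"),
              2L, sx[usable], "/")
  yc <- y - mean(y)
  G <- crossprod(xs) / n
  cvec <- drop(crossprod(xs, yc)) / n
  selected <- integer(0)   # indices into `usable`
  candidates <- seq_along(usable)
  while (length(selected) < nSelect) {
    errs <- vapply(candidates, function(j) {
      idx <- c(selected, j)
      b <- lassoGramCD(G[idx, idx, drop = FALSE], cvec[idx], lambda)
      mean(abs(yc - xs[, idx, drop = FALSE] %*% b))
    }, numeric(1L))
    best <- candidates[which.min(errs)]
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  usable[selected]
}

#' Lasso fit with inner cross-validated penalty
#'
#' Chooses the penalty by inner 5-fold cross-validation over a 100-point
#' log-spaced grid on [1e-4, 1] with L1 ratio 1 (a lasso), refits on the
#' full training rows at the selected penalty, and predicts the test rows.
#' A degenerate inner fold (constant response) triggers one refold with a
#' derived seed.
#'
#' @param xTrain,yTrain training data (at least 2 rows).
#' @param xTest test feature matrix.
#' @param lambdaRange penalty grid limits.
#' @param nLambda grid size.
#' @param innerFolds inner folds for penalty selection.
#' @param seed seed for the inner fold assignment.
#' @return list with `pred` (test predictions), `coef` (coefficients on the
#'   training feature scale) and `lambda` (selected penalty).
#' @export
fitPredictLasso <- function(xTrain, yTrain, xTest, lambdaRange = c(1e-4, 1),
                            nLambda = 100L, innerFolds = 5L, seed = 1L) {
  xTrain <- as.matrix(xTrain); xTest <- as.matrix(xTest)
  if (nrow(xTrain) < 2L) inputShapeError("need at least 2 training rows")
  if (stats::var(yTrain) == 0) {
    ## constant target: lasso shrinks everything, predict the constant
    return(list(pred = rep(mean(yTrain), nrow(xTest)),
                coef = numeric(ncol(xTrain)), lambda = NA_real_))
  }
  grid <- sort(10^seq(log10(lambdaRange[1L]), log10(lambdaRange[2L]),
                      length.out = nLambda), decreasing = TRUE)
  n <- nrow(xTrain)
  ## keep at least 3 observations per inner fold on small training sets
  innerFolds <- max(2L, min(as.integer(innerFolds), n %/% 3L))
  innerCV <- function(s) {
    foldid <- withSeed(s, sample(rep(seq_len(innerFolds), length.out = n)))
    if (ncol(xTrain) >= 2L) {
      cv <- glmnet::cv.glmnet(xTrain, yTrain, alpha = 1, lambda = grid,
                              foldid = foldid, standardize = TRUE)
      lam <- cv$lambda.min
      co <- stats::coef(cv$glmnet.fit, s = lam)
      list(pred = drop(stats::predict(cv$glmnet.fit, xTest, s = lam)),
           coef = as.numeric(co)[-1L], lambda = lam)
    } else {
      ## single-feature path: closed-form univariate lasso, same objective
      mse <- sapply(grid, function(l) {
        errs <- vapply(seq_len(innerFolds), function(f) {
          tr <- foldid != f
          fit <- lassoCD(xTrain[tr, , drop = FALSE], yTrain[tr], l)
          mean((yTrain[!tr] - lassoPredict(fit, xTrain[!tr, , drop = FALSE]))^2)
        }, numeric(1L))
        mean(errs)
      })
      lam <- grid[which.min(mse)]
      fit <- lassoCD(xTrain, yTrain, lam)
      list(pred = lassoPredict(fit, xTest), coef = fit$beta, lambda = lam)
    }
  }
  tryCatch(innerCV(seed), error = function(e) {
    message("fitPredictLasso: degenerate inner fold, refolding")
    innerCV(deriveSeed(seed, 9901L))
  })
}

#' Repeated cross-validated behavioral prediction
#'
#' Per repeat: subjects are shuffled into `folds` folds; per fold, features
#' are residualized for age and sex inside the fold, the greedy pass selects
#' `nSelect` features, and a lasso with inner cross-validated penalty
#' predicts the held-out subjects. Test predictions are pooled per repeat
#' into an out-of-sample Pearson r and negative mean absolute error (nMAE,
#' on the behavior's native scale); fold-wise mean r is also recorded.
#'
#' @param features subject x feature matrix (the 35 network features).
#' @param y behavioral change vector.
#' @param age,sex nuisance covariates, never candidate predictors.
#' @param folds,reps cross-validation geometry (defaults 5 x 100).
#' @param nSelect features kept by the greedy pass.
#' @param lambdaRange,nLambda penalty grid.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @return a [PredictionResult-class].
#' @export
crossValidate <- function(features, y, age, sex, folds = 5L, reps = 100L,
                          nSelect = 7L, lambdaRange = c(1e-4, 1),
                          nLambda = 100L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L * folds) inputShapeError("need at least 2 * folds subjects")
  if (length(y) != n) inputShapeError("one target per subject required")
  cov <- cbind(age = age, sex = sex)
  nF <- ncol(features)
  repR <- repRFold <- repNMAE <- numeric(reps)
  selCount <- numeric(nF)
  coefSum <- numeric(nF)
  nFits <- 0L
  for (r in seq_len(reps)) {
    repSeed <- deriveSeed(seed, r)
    foldid <- withSeed(repSeed, sample(rep(seq_len(folds), length.out = n)))
    pred <- numeric(n)
    foldR <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- foldid == f; tr <- !te
      rz <- residualizeInFold(features[tr, , drop = FALSE],
                              features[te, , drop = FALSE],
                              cov[tr, , drop = FALSE], cov[te, , drop = FALSE])
      sel <- sequentialSelect(rz$train, y[tr], nSelect = nSelect,
                              lambda = sqrt(prod(lambdaRange)))
      fit <- fitPredictLasso(rz$train[, sel, drop = FALSE], y[tr],
                             rz$test[, sel, drop = FALSE],
                             lambdaRange = lambdaRange, nLambda = nLambda,
                             seed = deriveSeed(repSeed, f))
      pred[te] <- fit$pred
      selCount[sel] <- selCount[sel] + 1
      coefSum[sel] <- coefSum[sel] + fit$coef
      nFits <- nFits + 1L
      ## constant predictions carry no signal: score the fold as r = 0
      foldR[f] <- if (stats::sd(pred[te]) > 0 && sum(te) > 2L) {
        stats::cor(y[te], pred[te])
      } else 0
    }
    repR[r] <- if (stats::sd(pred) > 0) stats::cor(y, pred) else 0
    repRFold[r] <- mean(foldR)
    repNMAE[r] <- -mean(abs(y - pred))
  }
  fnames <- colnames(features)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(nF))
  new("PredictionResult", repeatR = repR, repeatRFoldMean = repRFold,
      repeatNMAE = repNMAE,
      selectionFreq = stats::setNames(selCount / nFits, fnames),
      meanCoef = stats::setNames(coefSum / nFits, fnames),
      settings = list(folds = as.integer(folds), reps = as.integer(reps),
                      nSelect = as.integer(nSelect),
                      lambdaRange = lambdaRange, nLambda = as.integer(nLambda),
                      seed = as.integer(seed)))
}

#' Specificity controls for a prediction model
#'
#' Re-runs the full pipeline on alternative targets (shuffled scores,
#' off-domain behavioral scores, other cohorts' targets) with the same
#' repeat seeds, and compares the per-repeat r distributions of the primary
#' target against each alternative with a paired sign-flip permutation test
#' on the repeat-wise differences.
#'
#' @param features subject x feature matrix.
#' @param y primary behavioral target.
#' @param alternatives named list of alternative target vectors.
#' @param age,sex nuisance covariates.
#' @param folds,reps,seed cross-validation settings shared by all targets.
#' @param nFlip sign-flip draws for the permutation p value.
#' @return list with `primary` ([PredictionResult-class]), `alternatives`
#'   (list of results) and `comparison` (data.frame with mean r difference
#'   and permutation p per alternative).
#' @export
specificityTests <- function(features, y, alternatives, age, sex,
                             folds = 5L, reps = 20L, seed = 1L,
                             nFlip = 2000L) {
  if (length(alternatives) < 1L) {
    inputShapeError("at least one alternative target required")
  }
  primary <- crossValidate(features, y, age, sex, folds = folds, reps = reps,
                           seed = seed)
  alts <- lapply(alternatives, function(ya) {
    crossValidate(features, ya, age, sex, folds = folds, reps = reps,
                  seed = seed)
  })
  cmp <- do.call(rbind, lapply(names(alts), function(nm) {
    d <- primary@repeatR - alts[[nm]]@repeatR
    obs <- mean(d)
    flips <- withSeed(deriveSeed(seed, 777L), {
      vapply(seq_len(nFlip), function(i) {
        mean(d * sample(c(-1, 1), length(d), replace = TRUE))
      }, numeric(1L))
    })
    data.frame(alternative = nm, meanRPrimary = mean(primary@repeatR),
               meanRAlternative = mean(alts[[nm]]@repeatR),
               meanDiff = obs,
               p = (1 + sum(abs(flips) >= abs(obs))) / (nFlip + 1))
  }))
  list(primary = primary, alternatives = alts, comparison = cmp)
}

#' Assemble the 35-feature network table
#'
#' Summarizes per-subject change maps of the seven brain metrics
#' (eccentricity, G1-G3, and superficial/middle/deep qT1 compartments)
#' within the five a-priori networks, producing the subject x 35 feature
#' matrix used for behavioral prediction.
#'
#' @param deltaMaps named list of 7 subject x parcel change-map matrices.
#' @param weights parcel x 5 network weight matrix.
#' @return subject x 35 matrix with `network.metric` column names.
#' @export
assembleFeatureTable <- function(deltaMaps, weights) {
  if (length(deltaMaps) != 7L) {
    inputShapeError("expected 7 metric change maps (ecc, G1-G3, 3 qT1 compartments)")
  }
  weights <- as.matrix(weights)
  blocks <- lapply(names(deltaMaps), function(metric) {
    m <- as.matrix(deltaMaps[[metric]])
    if (ncol(m) != nrow(weights)) {
      inputShapeError("change maps and weights disagree on parcel count")
    }
    block <- t(apply(m, 1L, networkSummary, weights = weights))
    colnames(block) <- paste(colnames(weights), metric, sep = ".")
    block
  })
  do.call(cbind, blocks)
}
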