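## Longitudinal stage: change-score construction and massively univariate
## linear mixed-effects contrasts between training modules, with FDR control.

#' ChangeTable: subject-wise longitudinal change maps
#'
#' One row per subject and consecutive-timepoint interval; `delta` holds the
#' per-parcel difference map(T_{k+1}) - map(T_k) and `info` the interval
#' covariates (training module, age, sex, interval index).
#'
#' @slot delta interval x parcel matrix of change scores.
#' @slot info data.frame with subjectId, interval, tm, age, sex,
#'   intervalIndex per row of `delta`.
#' @export
setClass("ChangeTable",
  representation(delta = "matrix", info = "data.frame"),
  validity = function(object) {
    if (nrow(object@delta) != nrow(object@info)) {
      return("delta and info must have matching rows")
    }
    need <- c("subjectId", "interval", "tm", "age", "sex", "intervalIndex")
    if (!all(need %in% names(object@info))) {
      return(paste("info lacks columns:",
                   paste(setdiff(need, names(object@info)), collapse = ", ")))
    }
    TRUE
  }
)

#' Build change maps from per-timepoint metric maps
#'
#' Subtracts parcel-wise maps of subsequent timepoints within each subject.
#' An interval is produced only when both endpoints are present; dropped
#' intervals are counted in a message. The training module attached to an
#' interval is the module trained during it (the `tm` recorded at the later
#' timepoint); retest-control intervals carry `tm = "None"`.
#'
#' @param maps observation x parcel matrix, rows aligned with `design` rows.
#' @param design a validated design table (see [validateDesignTable()]).
#' @return a [ChangeTable-class].
#' @export
changeMaps <- function(maps, design) {
  design <- validateDesignTable(design)
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(design)) {
    inputShapeError("one map row per design row required")
  }
  tpOrder <- sort(unique(design$timepoint))
  rows <- list(); info <- list()
  dropped <- 0L
  for (s in unique(design$subjectId)) {
    ix <- which(design$subjectId == s)
    have <- design$timepoint[ix]
    for (k in seq_len(length(tpOrder) - 1L)) {
      t0 <- tpOrder[k]; t1 <- tpOrder[k + 1L]
      i0 <- ix[match(t0, have)]; i1 <- ix[match(t1, have)]
      if (is.na(i0) || is.na(i1)) {
        if (xor(is.na(i0), is.na(i1))) dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- maps[i1, ] - maps[i0, ]
      info[[length(info) + 1L]] <- data.frame(
        subjectId = s,
        interval = paste(t0, t1, sep = "_"),
        tm = design$tm[i1],
        age = design$age[i1],
        sex = design$sex[i1],
        intervalIndex = design$intervalIndex[i1],
        stringsAsFactors = FALSE
      )
    }
  }
  if (dropped > 0L) {
    message(sprintf("changeMaps: %d intervals dropped (missing endpoint)", dropped))
  }
  delta <- do.call(rbind, rows)
  colnames(delta) <- colnames(maps)
  new("ChangeTable", delta = delta, info = do.call(rbind, info))
}

## ---------------------------------------------------------------------------
## Massively univariate random-intercept ReML.
##
## The model per parcel is
##   delta ~ 1 + age_c + sex + intervalIndex + tm + (1 | subject)
## with a single variance ratio gamma = tau^2 / sigma^2. Because the design
## (X, Z) is shared by all parcels, the data are rotated once by a per-subject
## orthonormal basis whose first vector is constant: in the rotated frame the
## covariance is diagonal, 1 + gamma * m_s for the subject-mean component
## (m_s = observations of subject s) and 1 elsewhere, so each parcel needs
## only a one-dimensional REML optimisation over gamma with weighted least
## squares. Estimates agree with a general mixed-model fit (validated against
## lme4 in the test suite); inference uses the residual degrees of freedom of
## the fixed-effects design, n - p, and the effect size d = t / sqrt(df).
## ---------------------------------------------------------------------------

subjectRotation <- function(subjectIds) {
  n <- length(subjectIds)
  U <- matrix(0, n, n)
  lamv <- numeric(n)
  col <- 1L
  for (s in unique(subjectIds)) {
    ix <- which(subjectIds == s)
    m <- length(ix)
    if (m == 1L) {
      U[ix, col] <- 1
      lamv[col] <- 1
      col <- col + 1L
      next
    }
    B <- cbind(rep(1 / sqrt(m), m), diag(m)[, -1L, drop = FALSE])
    H <- qr.Q(qr(B))
    H[, 1L] <- rep(1 / sqrt(m), m)
    U[ix, col:(col + m - 1L)] <- H
    lamv[col] <- m
    col <- col + m
  }
  list(U = U, lambda = lamv)
}

remlProfile <- function(Xt, yt, lamv, n, p, logGamma) {
  g <- exp(logGamma)
  sw <- 1 / sqrt(1 + g * lamv)
  fit <- .lm.fit(Xt * sw, yt * sw)
  rss <- sum(fit$residuals^2)
  if (rss <= 0) return(Inf)
  sum(log1p(g * lamv)) + (n - p) * log(rss) +
    as.numeric(determinant(crossprod(Xt * sw), logarithm = TRUE)$modulus)
}

fitRandomInterceptReml <- function(Xt, yt, lamv, cvec) {
  n <- length(yt); p <- ncol(Xt)
  ## degenerate response: OLS already interpolates, no variance to model
  if (sum(.lm.fit(Xt, yt)$residuals^2) <= 1e-300) {
    numericalError("zero residual variance")
  }
  opt <- stats::optimize(function(lg) remlProfile(Xt, yt, lamv, n, p, lg),
                         interval = c(log(1e-10), log(1e6)))
  ## boundary handling: a profile minimum at the lower end is a singular fit
  ## (zero between-subject variance); gamma floors at ~0 and the model
  ## reduces to OLS, which is the documented fallback.
  g <- exp(opt$minimum)
  sw <- 1 / sqrt(1 + g * lamv)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  if (sigma2 <= 1e-300) numericalError("zero residual variance")
  XtWXi <- chol2inv(chol(crossprod(Xt * sw)))
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(sigma2 * drop(t(cvec) %*% XtWXi %*% cvec))
  tval <- est / se
  list(estimate = est, t = tval, df = df, gamma = g, sigma2 = sigma2)
}

#' Mixed-effects contrast between training modules
#'
#' Fits, per parcel, the linear mixed model
#' `delta ~ 1 + age + sex + intervalIndex + tm + (1 | subject)` by
#' restricted maximum likelihood and tests the requested module contrast
#' with a Wald t statistic. Age is centered before fitting (affects the
#' intercept only); the interval-index covariate (scans since baseline) can
#' be toggled off. Degrees of freedom are the residual degrees of freedom of
#' the fixed-effects design (`n - p`); the effect size is `d = t / sqrt(df)`
#' and p values are corrected across parcels by Benjamini-Hochberg.
#'
#' A zero between-subject variance estimate is a boundary (singular) fit and
#' falls back to the variance floor 0; a parcel with zero residual variance
#' is a `NumericalError`.
#'
#' @param changes a [ChangeTable-class].
#' @param contrast length-2 character: modules to compare, e.g.
#'   `c("Presence", "Perspective")`; use `"RCC"` (or `"None"`) for the
#'   untrained retest intervals.
#' @param useIntervalIndex include the scans-since-baseline covariate.
#' @param extraCovariate optional interval x parcel matrix of per-parcel
#'   covariates (e.g. cortical thickness change), entered per parcel.
#' @return a [ContrastResult-class].
#' @export
fitContrast <- function(changes, contrast = c("Presence", "Perspective"),
                        useIntervalIndex = TRUE, extraCovariate = NULL) {
  stopifnot(is(changes, "ChangeTable"))
  info <- changes@info
  delta <- changes@delta
  contrast <- ifelse(contrast == "RCC", "None", contrast)
  if (length(contrast) != 2L) {
    inputValueError("contrast must name exactly two groups")
  }
  tms <- unique(info$tm)
  if (!all(contrast %in% tms)) {
    inputValueError(sprintf("contrast groups absent from data: %s",
                            paste(setdiff(contrast, tms), collapse = ", ")))
  }
  counts <- table(info$tm)
  if (length(counts) < 2L || any(counts[contrast] < 3L)) {
    inputValueError("each contrasted group needs at least 3 observations")
  }
  tmLevels <- c(setdiff(sort(tms), c("None")), if ("None" %in% tms) "None")
  tmLevels <- c(tmLevels[length(tmLevels)], tmLevels[-length(tmLevels)])
  tmFac <- factor(info$tm, levels = tmLevels) # reference = None if present
  Xparts <- list(`(Intercept)` = rep(1, nrow(info)),
                 age = info$age - mean(info$age),
                 sex = info$sex)
  if (useIntervalIndex) Xparts$intervalIndex <- info$intervalIndex
  X <- do.call(cbind, Xparts)
  tmMat <- stats::model.matrix(~ tmFac)[, -1L, drop = FALSE]
  colnames(tmMat) <- sub("tmFac", "tm", colnames(tmMat))
  X <- cbind(X, tmMat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    numericalError("fixed-effects design is rank deficient")
  }
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  for (sgn in c(1, -1)) {
    grp <- contrast[if (sgn > 0) 1L else 2L]
    col <- paste0("tm", grp)
    if (col %in% colnames(X)) cvec[col] <- sgn  # reference level contributes 0
  }
  rot <- subjectRotation(info$subjectId)
  Xt <- crossprod(rot$U, X)
  deltat <- crossprod(rot$U, delta)
  nP <- ncol(delta)
  est <- tval <- numeric(nP)
  df <- NA_real_
  ## per-parcel covariate columns change X, so rotate per parcel when given
  for (p in seq_len(nP)) {
    if (is.null(extraCovariate)) {
      f <- fitRandomInterceptReml(Xt, deltat[, p], rot$lambda, cvec)
    } else {
      Xp <- cbind(X, covar = extraCovariate[, p])
      f <- fitRandomInterceptReml(crossprod(rot$U, Xp), deltat[, p],
                                  rot$lambda, c(cvec, 0))
    }
    est[p] <- f$estimate; tval[p] <- f$t; df <- f$df
  }
  pval <- 2 * stats::pt(-abs(tval), df)
  q <- stats::p.adjust(pval, method = "BH")
  names(est) <- names(tval) <- names(pval) <- names(q) <- colnames(delta)
  new("ContrastResult", estimate = est, t = tval, p = pval, q = q,
      d = tval / sqrt(df), df = df,
      contrast = paste(contrast, collapse = " - "))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control across a family of p values (one contrast, all
#' parcels). Thin wrapper over [stats::p.adjust()] returning both the
#' monotone adjusted values and the rejection mask at `qLevel`.
#'
#' @param p vector of p values in [0, 1].
#' @param qLevel target FDR, default 0.05.
#' @return list with `q` (adjusted values) and `reject` (logical mask).
#' @export
fdrBH <- function(p, qLevel = 0.05) {
  if (length(p) == 0L) inputShapeError("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    inputValueError("p values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= qLevel)
}

#' One-way ANOVA across parcel groups
#'
#' Tests whether parcel groups (e.g. the five a-priori networks) differ in a
#' per-parcel map, as in the baseline characterization of network embedding
#' in 3D gradient space.
#'
#' @param values per-parcel numeric vector.
#' @param groups group label per parcel.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
groupAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) inputValueError("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    inputValueError("every group needs at least 2 members")
  }
  a <- stats::anova(stats::lm(values ~ groups))
  list(F = a$`F value`[1L], df1 = a$Df[1L], df2 = a$Df[2L],
       p = a$`Pr(>F)`[1L])
}
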