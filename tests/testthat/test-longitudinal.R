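test_that("change maps subtract subsequent timepoints and log dropouts", {
  d <- tinyDesign()
  maps <- matrix(0, nrow(d), 3)
  s1 <- d$subjectId[1]
  maps[d$subjectId == s1 & d$timepoint == "T0", ] <- 1.0
  maps[d$subjectId == s1 & d$timepoint == "T1", ] <- 1.5
  ch <- changeMaps(maps, d)
  row <- ch@info$subjectId == s1 & ch@info$interval == "T0_T1"
  expect_equal(unname(ch@delta[row, ]), rep(0.5, 3))

  # RCC rows carry tm = "None"
  rccSub <- unique(d$subjectId[d$cohort == "RCC"])
  expect_true(all(ch@info$tm[ch@info$subjectId %in% rccSub] == "None"))

  # a missing middle timepoint drops both adjacent intervals
  dMiss <- d[!(d$subjectId == s1 & d$timepoint == "T2"), ]
  mMiss <- maps[!(d$subjectId == s1 & d$timepoint == "T2"), ]
  expect_message(chM <- changeMaps(mMiss, dMiss), "2 intervals dropped")
  expect_equal(sum(chM@info$subjectId == s1), 1L) # only T0 -> T1 left
})

test_that("the mixed-model contrast agrees with lme4 on single parcels", {
  library(lme4)
  eff <- c(rep(0.15, 3), rep(0, 3))
  co <- makeCohort(20, 20, 10, makeEffectSpec(list(Presence = eff),
                                              subjectSd = 0.1,
                                              residualSd = 0.15),
                   nParcels = 6L, seed = 31)
  ch <- changeMaps(co$maps, co$design)
  res <- fitContrast(ch, c("Presence", "Perspective"))
  info <- ch@info
  tmFac <- factor(info$tm, levels = c("None", "Affect", "Perspective",
                                      "Presence"))
  for (p in c(1L, 4L)) {
    y <- ch@delta[, p]
    m <- lmer(y ~ I(age - mean(age)) + sex + intervalIndex + tmFac +
                (1 | subjectId), data = cbind(info, y = y), REML = TRUE)
    cf <- summary(m)$coefficients
    tOracle <- (cf["tmFacPresence", "Estimate"] -
                  cf["tmFacPerspective", "Estimate"]) /
      sqrt(vcov(m)["tmFacPresence", "tmFacPresence"] +
             vcov(m)["tmFacPerspective", "tmFacPerspective"] -
             2 * vcov(m)["tmFacPresence", "tmFacPerspective"])
    expect_equal(res@t[p], unname(tOracle), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  # effect-size convention ties d to t through the residual df
  expect_equal(res@d, res@t / sqrt(res@df), ignore_attr = TRUE)
  expect_equal(res@df, nrow(ch@delta) - 7) # 1 + age + sex + interval + 3 tm
})

test_that("planted contrasts are detected and null parcels are not", {
  eff <- c(rep(0.2, 2), rep(0, 2))
  co <- makeCohort(40, 40, 20, makeEffectSpec(list(Presence = eff),
                                              0.1, 0.1),
                   nParcels = 4L, seed = 8)
  ch <- changeMaps(co$maps, co$design)
  res <- fitContrast(ch, c("Presence", "RCC"))
  expect_true(all(res@q[1:2] < 0.05))
  expect_true(all(abs(res@estimate[1:2] - 0.2) < 0.05))
  expect_true(all(res@p >= 0 & res@p <= 1))
  expect_match(res@contrast, "Presence - None")
})

test_that("contrast preconditions and degenerate inputs are rejected", {
  co <- makeCohort(5, 5, 3, makeEffectSpec(subjectSd = 0.1, residualSd = 0.1),
                   nParcels = 3L, seed = 2)
  ch <- changeMaps(co$maps, co$design)
  expect_error(fitContrast(ch, c("Presence", "Swimming")),
               class = "InputValueError")
  expect_error(fitContrast(ch, "Presence"), class = "InputValueError")

  zero <- makeCohort(5, 5, 3, makeEffectSpec(subjectSd = 0, residualSd = 0),
                     nParcels = 3L, seed = 2)
  chz <- changeMaps(zero$maps, zero$design)
  expect_error(fitContrast(chz, c("Presence", "Perspective")),
               class = "NumericalError")
})

test_that("BH correction matches the brute-force step-up", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  res <- fdrBH(p, 0.05)
  expect_equal(sum(res$reject), 3L)
  expect_equal(res$reject, bruteBH(p, 0.05))

  expect_false(any(fdrBH(rep(1, 10))$reject))
  expect_true(all(fdrBH(rep(0, 10))$reject))
  expect_error(fdrBH(numeric(0)), class = "InputShapeError")
  expect_error(fdrBH(c(0.5, 1.2)), class = "InputValueError")

  withr::with_seed(77, {
    for (i in 1:10) {
      pr <- runif(50)^2
      expect_equal(fdrBH(pr, 0.1)$reject, bruteBH(pr, 0.1))
    }
  })
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  withr::with_seed(14, {
    g <- rep(1:3, times = c(10, 12, 8))
    y <- rnorm(30) + 0.5 * (g == 2)
  })
  res <- groupAnova(y, g)
  # brute force
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 27)
  expect_equal(res$F, Fo)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 27L)
  expect_equal(res$p, pf(Fo, 2, 27, lower.tail = FALSE))

  expect_error(groupAnova(y, rep(1, 30)), class = "InputValueError")
  expect_error(groupAnova(c(1, 2, 3), c(1, 1, 2)), class = "InputValueError")

  # degenerate separation: p collapses toward 0
  expect_lt(groupAnova(c(0, 0, 0.0001, 1, 1, 1.0001),
                       rep(1:2, each = 3))$p, 1e-6)
})

test_that("rejection rate grows with the planted effect size", {
  rates <- vapply(c(0, 0.1, 0.25, 0.5), function(es) {
    nP <- 60L
    eff <- rep(es * 0.28, nP) # scaled to metric units via the change SD
    co <- makeCohort(30, 30, 0, makeEffectSpec(list(Presence = eff),
                                               0.1, 0.1),
                     nParcels = nP, seed = 61)
    ch <- changeMaps(co$maps, co$design)
    res <- fitContrast(ch, c("Presence", "Perspective"))
    mean(res@p < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[4], 0.9)
})
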