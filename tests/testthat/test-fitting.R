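test_that("initial guesses land near the truth and reject degenerate series", {
  p <- FourPLParams(sFloor = 0, sSpan = 1, rate = 1, logInfl = log(1e-8))
  ser <- make4PLSeries(p)
  g <- initGuess(ser, "GL")
  expect_lt(abs(g@logInfl - log(1e-8)), 0.5)
  expect_equal(g@nu, 1)
  expect_gt(g@rate, 0)
  # flat series
  flat <- TitrationSeries(10^seq(-10, -6, length.out = 8), rep(5, 8))
  expect_error(initGuess(flat, "GL"), "no dynamic range")
  # descending series
  desc <- TitrationSeries(10^seq(-10, -6, length.out = 8),
                          seq(10, 3, length.out = 8))
  expect_error(initGuess(desc, "GL"), "non-increasing trend")
})

test_that("noiseless GL data are recovered to high relative accuracy", {
  p <- GLParams(sFloor = 0, sSpan = 1000, rate = 1.2, logInfl = log(5e-9),
                nu = 0.5)
  fit <- fitModel(makeGLSeries(p), "GL")
  expect_true(converged(fit))
  est <- coef(fit)
  expect_lt(abs(est[["sFloor"]]) / 1000, 1e-4)        # true floor is 0
  expect_lt(relErr(est[["sSpan"]], 1000), 1e-4)
  expect_lt(relErr(est[["rate"]], 1.2), 1e-4)
  expect_lt(relErr(est[["logInfl"]], log(5e-9)), 1e-4)
  expect_lt(relErr(est[["nu"]], 0.5), 1e-4)
  # rss is consistent with the returned fitted values, and refitting the
  # same data reproduces the optimum exactly (deterministic pipeline)
  obsY <- as.vector(signals(fit@series))
  expect_equal(fitStats(fit)$rss, sum((obsY - fitted(fit))^2),
               tolerance = 1e-12)
  expect_identical(coef(fitModel(makeGLSeries(p), "GL")), est)
})

test_that("symmetric data fitted with GL give nu close to one", {
  p <- FourPLParams(sFloor = 50, sSpan = 900, rate = 0.8,
                    logInfl = log(2e-8))
  fit <- fitModel(make4PLSeries(p), "GL")
  expect_true(coef(fit)[["nu"]] > 0.95 && coef(fit)[["nu"]] < 1.05)
})

test_that("parameters are recovered across a rate-by-asymmetry grid", {
  for (rate in c(0.5, 1, 2)) {
    for (nu in c(0.2, 0.5, 1, 2, 5)) {
      p <- GLParams(sFloor = 10, sSpan = 500, rate = rate,
                    logInfl = log(1e-8), nu = nu)
      fit <- fitModel(makeGLSeries(p, nPoints = 15, decades = 3.5), "GL")
      est <- coef(fit)
      lbl <- sprintf("rate=%g nu=%g", rate, nu)
      expect_lt(relErr(est[["sFloor"]], 10), 1e-3, label = lbl)
      expect_lt(relErr(est[["sSpan"]], 500), 1e-3, label = lbl)
      expect_lt(relErr(est[["rate"]], rate), 1e-3, label = lbl)
      expect_lt(relErr(est[["logInfl"]], log(1e-8)), 1e-3, label = lbl)
      expect_lt(relErr(est[["nu"]], nu), 1e-3, label = lbl)
    }
  }
})

test_that("under-determined fits error while richer models still fit", {
  cg <- 10^seq(-10, -6, length.out = 5)
  p <- FourPLParams(0, 100, 1, log(1e-8))
  ser <- TitrationSeries(cg, fourPLValue(log(cg), p))
  expect_error(fitModel(ser, "5PL"), "under-determined")
  expect_error(fitModel(ser, "GL"), "under-determined")
  cmp <- compareModels(ser)
  expect_s4_class(cmp[["4PL"]], "FitResult")
  expect_type(cmp[["5PL"]], "character")
  expect_match(cmp[["5PL"]], "under-determined")
})

test_that("AIC ranks a symmetric curve to the leaner model, an asymmetric one to GL", {
  p4 <- FourPLParams(0, 1, 1, log(5e-9))
  cmp <- compareModels(make4PLSeries(p4, nPoints = 12))
  tab <- comparisonTable(cmp)
  expect_lte(tab$aic[tab$model == "4PL"], tab$aic[tab$model == "GL"])
  # strongly asymmetric GL data: GL must beat 4PL on rss
  pG <- GLParams(0, 1, 1, log(5e-9), nu = 0.1)
  cmpG <- compareModels(makeGLSeries(pG, nPoints = 14, decades = 4))
  expect_lt(fitStats(cmpG[["GL"]])$rss, fitStats(cmpG[["4PL"]])$rss)
})

test_that("AIC ordering is invariant to affine rescaling of the signal axis", {
  p <- GLParams(0, 1, 1, log(1e-8), nu = 0.4)
  mix <- ClonalMixture(kd = 1e-8, concTotal = 1e-9)
  ser <- simulateTitration(mix, AssayConfig(noiseCV = 0.02, replicates = 2L,
                                            seed = 5))
  order1 <- comparisonTable(compareModels(ser))$model
  ser2 <- TitrationSeries(conc(ser), 7 + 3.5 * signals(ser),
                          seriesMeta(ser))
  order2 <- comparisonTable(compareModels(ser2))$model
  expect_identical(order1, order2)
})

test_that("rescaling signals scales the asymptote parameters only", {
  p <- GLParams(5, 800, 1.1, log(4e-9), nu = 2)
  ser <- makeGLSeries(p)
  fit1 <- fitModel(ser, "GL")
  k <- 37
  ser2 <- TitrationSeries(conc(ser), k * signals(ser))
  fit2 <- fitModel(ser2, "GL")
  e1 <- coef(fit1); e2 <- coef(fit2)
  expect_lt(relErr(e2[["sFloor"]], k * e1[["sFloor"]]), 1e-6)
  expect_lt(relErr(e2[["sSpan"]], k * e1[["sSpan"]]), 1e-6)
  expect_lt(relErr(e2[["rate"]], e1[["rate"]]), 1e-6)
  expect_lt(relErr(e2[["logInfl"]], e1[["logInfl"]]), 1e-8)
  expect_lt(relErr(e2[["nu"]], e1[["nu"]]), 1e-6)
})

test_that("4PL and 5PL parameterizations describe the same symmetric curve", {
  p4 <- FourPLParams(2, 120, 1.3, log(8e-9))
  ser <- make4PLSeries(p4, nPoints = 15)
  fit4 <- fitModel(ser, "4PL")
  fit5 <- fitModel(ser, "5PL")
  grid <- 10^seq(-11, -6, length.out = 40)
  expect_lt(max(abs(predict(fit4, grid) - predict(fit5, grid))) / 120, 1e-8)
})

test_that("bootstrap intervals are reproducible, contain the estimate, and collapse without noise", {
  p <- GLParams(0, 1000, 1.2, log(5e-9), nu = 1)
  ser <- makeGLSeries(p)
  fit <- fitModel(ser, "GL")
  cfg <- FitConfig(bootstrapN = 100L, seed = 99)
  ci <- bootstrapCI(ser, fit, cfg)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # zero residuals: interval width vanishes on the parameter scale
  # (asymptote parameters are scaled by the signal span, the truth for
  # sFloor being 0)
  scale <- pmax(abs(ci$estimate), 1e-3 * coef(fit)[["sSpan"]])
  width <- (ci$upper - ci$lower) / scale
  expect_true(all(width < 1e-6))
  ci2 <- bootstrapCI(ser, fit, cfg)
  expect_identical(ci, ci2)
  # guard rails
  bad <- fit; bad@converged <- FALSE
  expect_error(bootstrapCI(ser, bad, cfg), "non-converged")
  expect_error(bootstrapCI(ser, fit, FitConfig(bootstrapN = 10L)), ">= 100")
})

test_that("pinning the floor to the blank mean fixes sFloor", {
  p <- GLParams(50, 1000, 1.2, log(5e-9), nu = 1)
  ser <- makeGLSeries(p, meta = list(blankMean = 50))
  fit <- fitModel(ser, "GL", pinFloorToBlank = TRUE)
  expect_identical(coef(fit)[["sFloor"]], 50)
  expect_identical(paramSE(fit)[["sFloor"]], 0)
  expect_lt(relErr(coef(fit)[["logInfl"]], log(5e-9)), 1e-4)
})
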