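test_that("independent-sites Langmuir fractions follow the closed form", {
  one <- ClonalMixture(kd = 1e-8, concTotal = 1e-9)
  expect_equal(boundFractionIndependent(one, 1e-8)$aggregate, 0.5)
  expect_equal(boundFractionIndependent(one, 0)$aggregate, 0)
  # two equal clones, kd 1e-9 and 1e-7, probed at 1e-8
  two <- ClonalMixture(kd = c(1e-9, 1e-7), concTotal = c(1e-9, 1e-9))
  expect_equal(boundFractionIndependent(two, 1e-8)$aggregate,
               (10 / 11 + 1 / 11) / 2, tolerance = 1e-12)
  expect_error(boundFractionIndependent(one, -1e-9), ">= 0")
})

test_that("the competitive solver matches the quadratic oracle and conserves mass", {
  mixQ <- ClonalMixture(kd = 1e-9, concTotal = 1e-9, regime = "competitive")
  sol <- solveCompetitive(mixQ, 2e-9)
  # independent quadratic-formula solution of
  # af^2 + af (kd + ct - At) - kd At = 0
  kd <- 1e-9; ct <- 1e-9; At <- 2e-9
  afQuad <- (-(kd + ct - At) + sqrt((kd + ct - At)^2 + 4 * kd * At)) / 2
  expect_equal(sol$agFree, afQuad, tolerance = 1e-9)
  expect_lt(abs(sol$agFree + sol$boundTotal - At) / At, 1e-9)
  # trivial limits
  expect_equal(solveCompetitive(mixQ, 0)$agFree, 0)
  expect_equal(solveCompetitive(mixQ, 0)$boundTotal, 0)
  noAb <- ClonalMixture(kd = 1e-9, concTotal = 0, regime = "competitive")
  expect_equal(solveCompetitive(noAb, 3e-9)$agFree, 3e-9)
  # random mixtures: relative mass conservation
  set.seed(123)
  for (i in 1:50) {
    m <- generateMixture(sample(1:30, 1), stats::runif(1, -10, -6),
                         stats::runif(1, 0, 1.5),
                         10^stats::runif(1, -10, -7),
                         regime = "competitive", seed = i)
    At <- 10^stats::runif(1, -11, -5)
    s <- solveCompetitive(m, At)
    expect_lt(abs(s$agFree + s$boundTotal - At) / At, 1e-9)
  }
})

test_that("aggregate binding is non-decreasing in total antigen in both regimes", {
  ags <- 10^seq(-12, -5, length.out = 40)
  for (regime in c("independent_sites", "competitive")) {
    m <- generateMixture(8L, -8, 1, 2e-9, regime = regime, seed = 4)
    bound <- if (regime == "competitive") solveCompetitive(m, ags)$boundTotal
             else boundFractionIndependent(m, ags)$boundTotal
    expect_true(all(diff(bound) >= 0), label = regime)
  }
})

test_that("simulated titrations are deterministic and noiseless when asked", {
  mix <- ClonalMixture(kd = 1e-8, concTotal = 1e-9)
  clean <- simulateTitration(mix, AssayConfig(noiseCV = 0))
  expected <- 100 + 1e12 *
    boundFractionIndependent(mix, conc(clean))$boundTotal
  expect_equal(as.vector(signals(clean)), expected, tolerance = 1e-12)
  a <- AssayConfig(noiseCV = 0.1, replicates = 3L, seed = 42)
  s1 <- simulateTitration(mix, a)
  s2 <- simulateTitration(mix, a)
  expect_identical(signals(s1), signals(s2))
  expect_false(identical(signals(s1),
                         signals(simulateTitration(mix, AssayConfig(
                           noiseCV = 0.1, replicates = 3L, seed = 43)))))
  expect_identical(seriesMeta(s1)$seed, 42)
})

test_that("a monoclonal Langmuir titration is exactly the nu = 1 logistic", {
  mix <- ClonalMixture(kd = 1e-8, concTotal = 1e-9)
  ser <- simulateTitration(mix, AssayConfig())
  fit <- fitModel(ser, "GL")
  est <- coef(fit)
  expect_lt(abs(exp(est[["logInfl"]]) - 1e-8) / 1e-8, 0.02)
  expect_true(est[["nu"]] > 0.97 && est[["nu"]] < 1.03)
  expect_lt(abs(log(est[["nu"]])), 0.05)
})

test_that("mixture generation honours its distributional parameters and seed", {
  m1 <- generateMixture(1L, -8, 0, 1e-9, seed = 3)
  expect_equal(cloneTable(m1)$kd, 1e-8, tolerance = 1e-15)
  expect_identical(sum(cloneTable(m1)$concTotal), 1e-9)
  mEq <- generateMixture(7L, -8.5, 0, 1e-9, seed = 3)
  expect_true(all(abs(cloneTable(mEq)$kd - 10^-8.5) < 1e-22))
  mA <- generateMixture(12L, -8, 1, 1e-9, seed = 5)
  mB <- generateMixture(12L, -8, 1, 1e-9, seed = 5)
  expect_identical(cloneTable(mA), cloneTable(mB))
  expect_equal(sum(cloneTable(mA)$concTotal), 1e-9)
  expect_error(generateMixture(0L), ">= 1")
  expect_error(generateMixture(3L, log10_kd_sd = -1), ">= 0")
})

test_that("scenario presets encode the active vs memory contrast", {
  act <- scenarioPreset("active_response", seed = 1)
  mem <- scenarioPreset("memory_response", seed = 1)
  expect_identical(nClones(act$mixture), 20L)
  expect_identical(nClones(mem$mixture), 3L)
  expect_lt(mean(log10(cloneTable(mem$mixture)$kd)),
            mean(log10(cloneTable(act$mixture)$kd)))
  expect_error(scenarioPreset("chronic_response"), "arg")
  # overrides reach both the mixture and the assay
  sc <- scenarioPreset("memory_response", seed = 2, n_clones = 5L,
                       noiseCV = 0.1, replicates = 2L)
  expect_identical(nClones(sc$mixture), 5L)
  expect_identical(sc$assay@replicates, 2L)
  expect_error(scenarioPreset("memory_response", bogus = 1), "unknown")
})
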