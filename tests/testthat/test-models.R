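test_that("the Richards curve passes through its inflection value (1+nu)^(-1/nu)", {
  # nu = 1: the classical logistic half-maximum
  p1 <- GLParams(rate = 1.3, logInfl = log(1e-8), nu = 1)
  expect_equal(glValue(log(1e-8), p1), 0.5, tolerance = 1e-12)
  # general nu: value at logInfl is (1+nu)^(-1/nu)
  for (nu in c(0.1, 0.5, 1, 2, 5, 20)) {
    p <- GLParams(rate = 0.8, logInfl = log(3e-9), nu = nu)
    expect_equal(glValue(p@logInfl, p), (1 + nu)^(-1 / nu),
                 tolerance = 1e-12, label = paste("nu =", nu))
  }
  expect_equal(glValue(log(1e-8), GLParams(logInfl = log(1e-8), nu = 2)),
               3^(-1 / 2), tolerance = 1e-12)
})

test_that("GL with nu = 1 collapses onto the 4PL, and limits are respected", {
  grid <- seq(-25, -10, length.out = 25)
  g <- GLParams(sFloor = 3, sSpan = 40, rate = 1.7, logInfl = -17, nu = 1)
  f <- FourPLParams(sFloor = 3, sSpan = 40, rate = 1.7, logInfl = -17)
  expect_equal(max(abs(glValue(grid, g) - fourPLValue(grid, f))), 0,
               tolerance = 1e-13)
  # asymptotes
  p <- GLParams(rate = 2, logInfl = -18, nu = 0.7)
  expect_equal(glValue(-18 - 50 / 2, p), 0, tolerance = 1e-12)
  expect_equal(glValue(-18 + 50 / 2, p), 1, tolerance = 1e-12)
  expect_equal(fourPLValue(f@logInfl - 50 / f@rate, f), f@sFloor,
               tolerance = 1e-12 * f@sSpan)
})

test_that("model evaluation rejects invalid inputs and parameters", {
  p <- GLParams(rate = 1, logInfl = -18, nu = 1)
  expect_error(glValue(NA_real_, p), "finite")
  expect_error(glValue(Inf, p), "finite")
  expect_error(GLParams(nu = -1), "nu")
  expect_error(GLParams(sSpan = -1), "sSpan")
  expect_error(fivePLValue(0, FivePLParams()), "> 0")
  expect_error(fivePLValue(-1e-9, FivePLParams()), "> 0")
  expect_error(glOdeRhs(1.2, p), "\\[0, 1\\]")
  expect_error(glOdeRhs(-0.1, p), "\\[0, 1\\]")
})

test_that("growth-law right-hand sides vanish at fixed points and match each other", {
  p <- GLParams(rate = 1, logInfl = 0, nu = 1)
  expect_identical(glOdeRhs(0, p), 0)
  expect_identical(glOdeRhs(1, p), 0)
  expect_equal(glOdeRhs(0.5, p), 0.25)
  expect_equal(logisticOdeRhs(0.5, 2), 0.5)
  expect_identical(logisticOdeRhs(0, 3), 0)
  a <- seq(0, 1, by = 0.1)
  expect_equal(logisticOdeRhs(a, 1.4), glOdeRhs(a, GLParams(rate = 1.4, nu = 1)))
  # general RHS formula
  p2 <- GLParams(rate = 2, nu = 3)
  expect_equal(glOdeRhs(0.6, p2), (2 / 3) * 0.6 * (1 - 0.6^3))
})

test_that("4PL is symmetric about its inflection and hits known values", {
  p <- FourPLParams(sFloor = 10, sSpan = 200, rate = 0.9, logInfl = -16)
  expect_equal(fourPLValue(-16, p), 10 + 100)
  # normalized, rate 1: value at logInfl + ln 3 is exactly 3/4
  pn <- FourPLParams(0, 1, 1, 0)
  expect_equal(fourPLValue(log(3), pn), 0.75, tolerance = 1e-12)
  # symmetry: f(xi + d) - floor == floor + span - f(xi - d)
  d <- seq(0.1, 5, by = 0.3)
  expect_equal(fourPLValue(-16 + d, p) - 10, 210 - fourPLValue(-16 - d, p),
               tolerance = 1e-10)
})

test_that("5PL reduces to 4PL at g = 1 and scales as 2^-g at cMid", {
  cg <- 10^seq(-11, -5, length.out = 25)
  p5 <- FivePLParams(sFloor = 2, sSpan = 80, slopeB = 1.4, cMid = 1e-8,
                     asymG = 1)
  p4 <- FourPLParams(sFloor = 2, sSpan = 80, rate = 1.4, logInfl = log(1e-8))
  expect_lt(max(abs(fivePLValue(cg, p5) - fourPLValue(log(cg), p4))), 1e-12)
  expect_equal(fivePLValue(1e-8, FivePLParams(0, 1, 1, 1e-8, 1)), 0.5)
  expect_equal(fivePLValue(1e-8, FivePLParams(0, 1, 1, 1e-8, 2)), 0.25)
})

test_that("glInflection returns the argmax of the numerical slope", {
  for (nu in c(0.3, 1, 4)) {
    p <- GLParams(sFloor = 5, sSpan = 100, rate = 1.2, logInfl = -17,
                  nu = nu)
    infl <- glInflection(p)
    expect_equal(infl$logAg, -17)
    expect_equal(infl$value, 5 + 100 * (1 + nu)^(-1 / nu), tolerance = 1e-12)
    # brute-force oracle: finite-difference slope on a fine grid
    h <- 0.005
    grid <- seq(-22, -12, by = h)
    slope <- diff(glValue(grid, p)) / h
    xmax <- grid[which.max(slope)] + h / 2
    expect_lt(abs(xmax - infl$logAg), h)
  }
})

test_that("numerically integrating the growth law reproduces the closed form", {
  p <- GLParams(rate = 1.1, logInfl = -18, nu = 0.6)
  grid <- seq(-24, -12, length.out = 50)
  a0 <- glValue(grid[1], p)
  traj <- glSolveODE(p, grid, a0)
  expect_lt(max(abs(traj - glValue(grid, p))), 1e-8)
  # nu = 1 trajectory matches the 4PL closed form
  p1 <- GLParams(rate = 2, logInfl = -18, nu = 1)
  f1 <- FourPLParams(0, 1, 2, -18)
  traj1 <- glSolveODE(p1, grid, fourPLValue(grid[1], f1))
  expect_lt(max(abs(traj1 - fourPLValue(grid, f1))), 1e-8)
  # rate = 0: stuck at the initial condition
  p0 <- new("GLParams", sFloor = 0, sSpan = 1, rate = 0, logInfl = -18,
            nu = 1)
  expect_equal(glSolveODE(p0, grid, 0.3), rep(0.3, length(grid)),
               tolerance = 1e-10)
  # degenerate initial conditions are rejected
  expect_error(glSolveODE(p, grid, 0), "strictly inside")
  expect_error(glSolveODE(p, grid, 1), "strictly inside")
  expect_error(glSolveODE(p, rev(grid), 0.5), "increasing")
})

test_that("the Gompertz curve emerges as the small-nu limit", {
  grid <- seq(-24, -12, length.out = 60)
  p <- GLParams(sFloor = 2, sSpan = 30, rate = 1.4, logInfl = -18,
                nu = 1e-4)
  gomp <- 2 + 30 * exp(-exp(-1.4 * (grid + 18)))
  expect_lt(max(abs(glValue(grid, p) - gomp)) / 30, 1e-3)
})

test_that("the Richards curve is strictly increasing for all valid parameters", {
  set.seed(7)
  for (p in randomGLParams(20, seed = 11)) {
    grid <- sort(stats::runif(40, p@logInfl - 8, p@logInfl + 8))
    expect_true(all(diff(glValue(grid, p)) > 0),
                label = sprintf("rate=%g nu=%g", p@rate, p@nu))
  }
})

test_that("the bound fraction at the inflection grows from 1/e toward 1 with nu", {
  # (1+nu)^(-1/nu) is monotone increasing in nu: it approaches the
  # Gompertz value 1/e as nu -> 0+, passes exactly 1/2 at nu = 1, and
  # tends to 1 as nu -> infinity
  nus <- c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  vals <- vapply(nus, function(nu)
    glInflection(GLParams(nu = nu))$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals[nus <= 1] > exp(-1) & vals[nus <= 1] <= 0.5))
  expect_equal(vals[nus == 1], 0.5)
})
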