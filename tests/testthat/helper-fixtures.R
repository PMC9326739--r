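# Programmatic fixtures shared across test files.

# Noiseless series sampled from a known curve on a log-spaced grid.
makeGLSeries <- function(p, nPoints = 12, decades = 3, meta = list()) {
  centre <- p@logInfl / log(10)
  cg <- 10^seq(centre - decades, centre + decades, length.out = nPoints)
  TitrationSeries(cg, glValue(log(cg), p), meta)
}

make4PLSeries <- function(p, nPoints = 12, decades = 3) {
  centre <- p@logInfl / log(10)
  cg <- 10^seq(centre - decades, centre + decades, length.out = nPoints)
  TitrationSeries(cg, fourPLValue(log(cg), p))
}

# Random valid normalized GL parameters, log-uniform in rate and nu.
randomGLParams <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    GLParams(sFloor = 0, sSpan = 1,
             rate = exp(stats::runif(1, log(0.3), log(3))),
             logInfl = stats::runif(1, -25, -10),
             nu = exp(stats::runif(1, log(0.1), log(10)))))
}

# Relative error with a floor for near-zero truths.
relErr <- function(est, tru, floor = 1e-9) abs(est - tru) / pmax(abs(tru), floor)
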