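#' @describeIn GLParams-class Constructor. `nu` outside \[1e-4, 1e3\] is
#'   clamped to that range (the closed form is numerically meaningless
#'   beyond it).
#' @param sFloor,sSpan,rate,logInfl,nu see slots.
#' @export
GLParams <- function(sFloor = 0, sSpan = 1, rate = 1, logInfl = 0, nu = 1) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0", call. = FALSE)
  nu <- min(max(nu, .NU_MIN), .NU_MAX)
  new("GLParams", sFloor = as.numeric(sFloor), sSpan = as.numeric(sSpan),
      rate = as.numeric(rate), logInfl = as.numeric(logInfl),
      nu = as.numeric(nu))
}

#' @describeIn FourPLParams-class Constructor.
#' @param sFloor,sSpan,rate,logInfl see slots.
#' @export
FourPLParams <- function(sFloor = 0, sSpan = 1, rate = 1, logInfl = 0) {
  new("FourPLParams", sFloor = as.numeric(sFloor), sSpan = as.numeric(sSpan),
      rate = as.numeric(rate), logInfl = as.numeric(logInfl))
}

#' @describeIn FivePLParams-class Constructor.
#' @param sFloor,sSpan,slopeB,cMid,asymG see slots.
#' @export
FivePLParams <- function(sFloor = 0, sSpan = 1, slopeB = 1, cMid = 1,
                         asymG = 1) {
  new("FivePLParams", sFloor = as.numeric(sFloor), sSpan = as.numeric(sSpan),
      slopeB = as.numeric(slopeB), cMid = as.numeric(cMid),
      asymG = as.numeric(asymG))
}

#' @describeIn TitrationSeries-class Constructor. `signal` may be a
#'   vector (one replicate) or a matrix with one column per replicate.
#' @param conc,signal,meta see slots.
#' @export
TitrationSeries <- function(conc, signal, meta = list()) {
  if (is.null(dim(signal))) signal <- matrix(as.numeric(signal), ncol = 1L)
  storage.mode(signal) <- "double"
  defaults <- list(antigen = "antigen1", isotype = "IgG", dilution = 1,
                   assay = "assay1")
  meta <- utils::modifyList(defaults, meta)
  new("TitrationSeries", conc = as.numeric(conc), signal = signal,
      meta = meta)
}

#' @describeIn ClonalMixture-class Constructor.
#' @param kd,concTotal,regime,seed see slots.
#' @export
ClonalMixture <- function(kd, concTotal,
                          regime = c("independent_sites", "competitive"),
                          seed = NA_real_) {
  regime <- match.arg(regime)
  new("ClonalMixture", kd = as.numeric(kd), concTotal = as.numeric(concTotal),
      regime = regime, seed = as.numeric(seed))
}

#' @describeIn AssayConfig-class Constructor. The default grid is 12
#'   concentrations log-spaced over three decades either side of 10 nM,
#'   the span a microspot titration typically covers.
#' @param concGrid,noiseCV,replicates,signalPerBound,background,noiseType,seed
#'   see slots.
#' @export
AssayConfig <- function(concGrid = 10^seq(-11, -5, length.out = 12),
                        noiseCV = 0, replicates = 1L,
                        signalPerBound = 1e12, background = 100,
                        noiseType = c("lognormal", "gaussian"),
                        seed = 1L) {
  noiseType <- match.arg(noiseType)
  new("AssayConfig", concGrid = as.numeric(concGrid),
      noiseCV = as.numeric(noiseCV), replicates = as.integer(replicates),
      signalPerBound = as.numeric(signalPerBound),
      background = as.numeric(background), noiseType = noiseType,
      seed = as.numeric(seed))
}

#' @describeIn FitConfig-class Constructor.
#' @param loss,weighting,maxIter,tolerance,bounds,bootstrapN,seed see slots.
#' @export
FitConfig <- function(loss = c("ols", "soft_l1"),
                      weighting = c("none", "relative"),
                      maxIter = 200L, tolerance = 1e-10, bounds = list(),
                      bootstrapN = 0L, seed = 1L) {
  new("FitConfig", loss = match.arg(loss), weighting = match.arg(weighting),
      maxIter = as.integer(maxIter), tolerance = as.numeric(tolerance),
      bounds = bounds, bootstrapN = as.integer(bootstrapN),
      seed = as.numeric(seed))
}
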