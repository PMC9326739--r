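#' @import methods
NULL

## Asymmetry exponent is kept inside a range where (1 + nu*exp(E))^(-1/nu)
## is computable in double precision.
.NU_MIN <- 1e-4
.NU_MAX <- 1e3

#' Generalized logistic (Richards) curve parameters
#'
#' Parameters of the Richards sigmoid in measurement space,
#' \deqn{s(x) = s_{floor} + s_{span} (1 + \nu e^{-r(x - x_i)})^{-1/\nu},}
#' where \eqn{x = \ln [Ag]} is the natural log of antigen concentration
#' (mol/L). The parameterization makes the log inflection point
#' \eqn{x_i = \ln [Ag]_i} an explicit parameter, so the antigen
#' concentration at the inflection (the apparent dissociation constant of
#' the bound antibody pool) is read off directly, and the asymmetry
#' exponent \eqn{\nu} carries the limiting activity coefficient
#' \eqn{\gamma^\infty = 1/\nu}. The normalized (fraction-bound) form is
#' obtained with `sFloor = 0`, `sSpan = 1`.
#'
#' @slot sFloor lower asymptote, signal units.
#' @slot sSpan distance between asymptotes, signal units; must be > 0.
#' @slot rate dimensionless growth rate per natural-log unit of
#'   concentration; must be >= 0 (0 only as a degenerate limit; fitted
#'   values are bounded away from 0).
#' @slot logInfl natural log of the inflection-point antigen concentration
#'   \eqn{[Ag]_i} (mol/L).
#' @slot nu dimensionless asymmetry exponent, constrained to
#'   \[1e-4, 1e3\] so the closed form stays finite in double precision.
#' @export
setClass("GLParams",
  representation(sFloor = "numeric", sSpan = "numeric", rate = "numeric",
                 logInfl = "numeric", nu = "numeric"),
  validity = function(object) {
    v <- c(object@sFloor, object@sSpan, object@rate, object@logInfl, object@nu)
    if (length(v) != 5L || any(!is.finite(v)))
      return("all five parameters must be finite scalars")
    if (object@sSpan <= 0) return("sSpan must be > 0")
    if (object@rate < 0) return("rate must be >= 0")
    if (object@nu < .NU_MIN || object@nu > .NU_MAX)
      return(sprintf("nu must lie in [%g, %g]", .NU_MIN, .NU_MAX))
    TRUE
  })

#' Four-parameter logistic (4PL) parameters
#'
#' The symmetric logistic sigmoid in natural-log concentration; identical
#' to [GLParams] with the asymmetry exponent fixed at \eqn{\nu = 1}.
#'
#' @slot sFloor,sSpan,rate,logInfl as in [GLParams].
#' @export
setClass("FourPLParams",
  representation(sFloor = "numeric", sSpan = "numeric", rate = "numeric",
                 logInfl = "numeric"),
  validity = function(object) {
    v <- c(object@sFloor, object@sSpan, object@rate, object@logInfl)
    if (length(v) != 4L || any(!is.finite(v)))
      return("all four parameters must be finite scalars")
    if (object@sSpan <= 0) return("sSpan must be > 0")
    if (object@rate < 0) return("rate must be >= 0")
    TRUE
  })

#' Five-parameter logistic (5PL) parameters
#'
#' Conventional asymmetric immunoassay calibration curve
#' \deqn{s(c) = s_{floor} + s_{span} (1 + (c_{mid}/c)^{b})^{-g}.}
#' Provided as a comparison model. Note that `cMid` is *not* the
#' inflection point of the curve unless \eqn{g = 1}: the inflection
#' concentration must be computed from all of \eqn{(b, c_{mid}, g)},
#' which is the practical drawback of this parameterization relative to
#' the Richards form.
#'
#' @slot sFloor,sSpan asymptote parameters, signal units.
#' @slot slopeB dimensionless Hill-type slope, > 0 for increasing curves.
#' @slot cMid mol/L scale parameter, > 0.
#' @slot asymG dimensionless asymmetry exponent, > 0.
#' @export
setClass("FivePLParams",
  representation(sFloor = "numeric", sSpan = "numeric", slopeB = "numeric",
                 cMid = "numeric", asymG = "numeric"),
  validity = function(object) {
    v <- c(object@sFloor, object@sSpan, object@slopeB, object@cMid,
           object@asymG)
    if (length(v) != 5L || any(!is.finite(v)))
      return("all five parameters must be finite scalars")
    if (object@sSpan <= 0) return("sSpan must be > 0")
    if (object@slopeB <= 0) return("slopeB must be > 0")
    if (object@cMid <= 0) return("cMid must be > 0")
    if (object@asymG <= 0) return("asymG must be > 0")
    TRUE
  })

#' A single antigen (or serum) titration series
#'
#' One dilution series: strictly increasing positive antigen
#' concentrations, a matrix of signal readings (one column per
#' replicate), and assay metadata. Zero-concentration blank readings do
#' not belong in the series (their log is undefined); [readTitration()]
#' splits them out and records their mean under `meta$blankMean`.
#'
#' @slot conc numeric, mol/L, strictly increasing, > 0.
#' @slot signal numeric matrix, `length(conc)` rows, >= 1 replicate
#'   columns, arbitrary assay units.
#' @slot meta named list: `antigen`, `isotype`, `dilution`, `assay`,
#'   optionally `seed`, `blankMean`, `blankCount`.
#' @export
setClass("TitrationSeries",
  representation(conc = "numeric", signal = "matrix", meta = "list"),
  validity = function(object) {
    if (length(object@conc) == 0L) return("empty concentration vector")
    if (any(!is.finite(object@conc)) || any(object@conc <= 0))
      return("concentrations must be finite and > 0")
    if (is.unsorted(object@conc, strictly = TRUE))
      return("concentrations must be strictly increasing")
    if (!is.numeric(object@signal))
      return("signal must be numeric")
    if (nrow(object@signal) != length(object@conc))
      return("signal must have one row per concentration")
    if (ncol(object@signal) < 1L) return("need at least one signal column")
    TRUE
  })

#' Least-squares fit of a binding model to a titration series
#'
#' Returned by [fitModel()]. Access the estimates with [coef()],
#' [fitParams()] (the typed parameter object), [vcov()], [paramSE()] and
#' [fitStats()]; `converged(fit)` reports optimizer convergence honestly
#' (a non-converged fit is returned, flagged, never masked).
#'
#' @slot model one of `"4PL"`, `"5PL"`, `"GL"`.
#' @slot params the fitted [GLParams], [FourPLParams] or [FivePLParams].
#' @slot paramSE named numeric, asymptotic standard errors.
#' @slot cov parameter covariance matrix (fitting scale).
#' @slot rss residual sum of squares.
#' @slot aic,bic Gaussian-likelihood information criteria,
#'   \eqn{n \ln(rss/n) + 2k} with \eqn{k} = number of curve parameters
#'   + 1 for the noise variance.
#' @slot rSquared 1 - rss / total sum of squares.
#' @slot converged logical convergence flag.
#' @slot nObs number of observations fitted (replicates counted
#'   individually).
#' @slot residuals numeric residuals (observed - fitted), fitting order.
#' @slot fitted numeric fitted values, fitting order.
#' @slot series the [TitrationSeries] that was fitted.
#' @export
setClass("FitResult",
  representation(model = "character", params = "ANY", paramSE = "numeric",
                 cov = "matrix", rss = "numeric", aic = "numeric",
                 bic = "numeric", rSquared = "numeric",
                 converged = "logical", nObs = "integer",
                 residuals = "numeric", fitted = "numeric",
                 series = "ANY"),
  validity = function(object) {
    if (!object@model %in% c("4PL", "5PL", "GL"))
      return("model must be one of '4PL', '5PL', 'GL'")
    if (is.finite(object@rss) && object@rss < 0) return("rss must be >= 0")
    TRUE
  })

#' Ranked comparison of the 4PL, 5PL and GL fits of one series
#'
#' Returned by [compareModels()]. `fits` holds the per-model
#' [FitResult]s (or the error message for a model that failed), `table`
#' ranks the successful fits by AIC with \eqn{\Delta}AIC; fits within
#' \eqn{\Delta AIC < 2} of the best are flagged indistinguishable.
#'
#' @slot fits named list of [FitResult] or character error message.
#' @slot table data.frame: model, k, rss, aic, deltaAIC, indistinguishable.
#' @export
setClass("ModelComparison",
  representation(fits = "list", table = "data.frame"))

#' Thermodynamic descriptors derived from a GL fit
#'
#' @slot agInfl mol/L, antigen concentration at the inflection point,
#'   \eqn{[Ag]_i = e^{x_i}}.
#' @slot kdApparent mol/L, apparent equilibrium dissociation constant of
#'   the bound antibody pool; equals `agInfl`.
#' @slot deltaMuStandard J/mol, standard chemical potential of
#'   dissociation, \eqn{RT \ln(K_d / c^\circ)} with
#'   \eqn{c^\circ = 1} mol/L.
#' @slot gammaInf dimensionless limiting activity coefficient of the
#'   antigen at infinite antibody dilution, \eqn{1/\nu}.
#' @slot temperature K.
#' @export
setClass("DerivedQuantities",
  representation(agInfl = "numeric", kdApparent = "numeric",
                 deltaMuStandard = "numeric", gammaInf = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    if (object@agInfl <= 0) return("agInfl must be > 0")
    if (object@gammaInf <= 0) return("gammaInf must be > 0")
    if (object@temperature <= 0) return("temperature must be > 0 K")
    TRUE
  })

#' Relative thermodynamic activity of the antigen
#'
#' \eqn{a = \gamma c / c^\circ} with standard state
#' \eqn{c^\circ = 1} mol/L, so `value` is dimensionless.
#'
#' @slot value dimensionless relative activity.
#' @slot gamma dimensionless activity coefficient.
#' @slot conc mol/L.
#' @export
setClass("Activity",
  representation(value = "numeric", gamma = "numeric", conc = "numeric"))

#' A polyclonal antibody pool as a finite clonal mixture
#'
#' Each clone `j` is a (Kd, total binding-site concentration) pair; the
#' mixture stands in for a polyclonal serum. In the `"competitive"`
#' regime all clones target one shared epitope and compete through the
#' free-antigen mass balance; in the `"independent_sites"` regime each
#' clone equilibrates against the free antigen concentration
#' independently (the antibody-dilute limit).
#'
#' @slot kd numeric, mol/L, per-clone dissociation constants, > 0.
#' @slot concTotal numeric, mol/L, per-clone total binding-site
#'   concentrations, >= 0.
#' @slot regime `"independent_sites"` or `"competitive"`.
#' @slot seed integer or NA; the seed that generated the mixture, if any.
#' @export
setClass("ClonalMixture",
  representation(kd = "numeric", concTotal = "numeric", regime = "character",
                 seed = "numeric"),
  validity = function(object) {
    if (length(object@kd) < 1L) return("need at least one clone")
    if (length(object@kd) != length(object@concTotal))
      return("kd and concTotal must have equal length")
    if (any(!is.finite(object@kd)) || any(object@kd <= 0))
      return("all kd must be finite and > 0")
    if (any(!is.finite(object@concTotal)) || any(object@concTotal < 0))
      return("all concTotal must be finite and >= 0")
    if (!object@regime %in% c("independent_sites", "competitive"))
      return("regime must be 'independent_sites' or 'competitive'")
    TRUE
  })

#' Fitting configuration
#'
#' @slot loss `"ols"` (squared residuals) or `"soft_l1"` (Huber-like
#'   robust loss, implemented by iteratively reweighted least squares).
#' @slot weighting `"none"` (homoscedastic) or `"relative"` (residuals
#'   divided by the floor-protected model value; appropriate for
#'   fluorescence-like multiplicative noise).
#' @slot maxIter maximum optimizer iterations per start.
#' @slot tolerance relative convergence tolerance, > 0.
#' @slot bounds named list overriding default parameter bounds; entries
#'   are `c(lower, upper)` named by parameter.
#' @slot bootstrapN number of residual-bootstrap resamples for
#'   [bootstrapCI()], >= 0.
#' @slot seed integer seed for the bootstrap resampling.
#' @export
setClass("FitConfig",
  representation(loss = "character", weighting = "character",
                 maxIter = "integer", tolerance = "numeric",
                 bounds = "list", bootstrapN = "integer", seed = "numeric"),
  validity = function(object) {
    if (!object@loss %in% c("ols", "soft_l1"))
      return("loss must be 'ols' or 'soft_l1'")
    if (!object@weighting %in% c("none", "relative"))
      return("weighting must be 'none' or 'relative'")
    if (object@tolerance <= 0) return("tolerance must be > 0")
    if (object@bootstrapN < 0L) return("bootstrapN must be >= 0")
    TRUE
  })

#' Assay layout and noise model for simulated titrations
#'
#' @slot concGrid mol/L antigen concentrations, positive ascending.
#' @slot noiseCV dimensionless coefficient of variation of the
#'   multiplicative log-normal measurement noise (median 1); 0 for
#'   noiseless curves.
#' @slot replicates number of replicate signal columns, >= 1.
#' @slot signalPerBound assay units produced per mol/L of bound antibody.
#' @slot background assay units added to every reading.
#' @slot noiseType `"lognormal"` (multiplicative, fluorescence-like) or
#'   `"gaussian"` (additive, sd = noiseCV * span of the noiseless curve).
#' @slot seed integer seed for the noise draws.
#' @export
setClass("AssayConfig",
  representation(concGrid = "numeric", noiseCV = "numeric",
                 replicates = "integer", signalPerBound = "numeric",
                 background = "numeric", noiseType = "character",
                 seed = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@concGrid)) || any(object@concGrid <= 0))
      return("concGrid must be finite and > 0")
    if (is.unsorted(object@concGrid, strictly = TRUE))
      return("concGrid must be strictly increasing")
    if (object@noiseCV < 0) return("noiseCV must be >= 0")
    if (object@replicates < 1L) return("replicates must be >= 1")
    if (!object@noiseType %in% c("lognormal", "gaussian"))
      return("noiseType must be 'lognormal' or 'gaussian'")
    TRUE
  })
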