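#' @describeIn GLParams-class compact display
#' @param object object to display.
#' @export
setMethod("show", "GLParams", function(object) {
  cat(sprintf(
    "GLParams: floor=%.4g span=%.4g rate=%.4g logInfl=%.4g ([Ag]_i=%.3g M) nu=%.4g\n",
    object@sFloor, object@sSpan, object@rate, object@logInfl,
    exp(object@logInfl), object@nu))
})

#' @describeIn FourPLParams-class compact display
#' @param object object to display.
#' @export
setMethod("show", "FourPLParams", function(object) {
  cat(sprintf(
    "FourPLParams: floor=%.4g span=%.4g rate=%.4g logInfl=%.4g ([Ag]_i=%.3g M)\n",
    object@sFloor, object@sSpan, object@rate, object@logInfl,
    exp(object@logInfl)))
})

#' @describeIn FivePLParams-class compact display
#' @param object object to display.
#' @export
setMethod("show", "FivePLParams", function(object) {
  cat(sprintf(
    "FivePLParams: floor=%.4g span=%.4g b=%.4g cMid=%.3g M g=%.4g\n",
    object@sFloor, object@sSpan, object@slopeB, object@cMid, object@asymG))
})

#' @describeIn TitrationSeries-class compact display
#' @param object object to display.
#' @export
setMethod("show", "TitrationSeries", function(object) {
  m <- object@meta
  cat(sprintf(
    "TitrationSeries '%s' (%s, dilution %s): %d concentrations x %d replicate(s)\n",
    m$antigen, m$isotype, format(m$dilution), length(object@conc),
    ncol(object@signal)))
  cat(sprintf("  conc range: %.3g .. %.3g mol/L; signal range: %.4g .. %.4g\n",
              min(object@conc), max(object@conc),
              min(object@signal), max(object@signal)))
})

#' @describeIn FitResult-class compact display
#' @param object object to display.
#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s] %s (n=%d, rss=%.4g, AIC=%.2f, R2=%.5f)\n",
              object@model,
              if (object@converged) "converged" else "NOT CONVERGED",
              object@nObs, object@rss, object@aic, object@rSquared))
  est <- coef(object); se <- paramSE(object)
  for (p in names(est))
    cat(sprintf("  %-8s %12.6g  (se %.3g)\n", p, est[[p]], se[[p]]))
})

#' @describeIn ModelComparison-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison (ranked by AIC):\n")
  print(object@table, row.names = FALSE)
  failed <- names(object@fits)[!vapply(object@fits, is, logical(1),
                                       "FitResult")]
  if (length(failed))
    cat("  failed:", paste(failed, collapse = ", "), "\n")
})

#' @describeIn DerivedQuantities-class compact display
#' @param object object to display.
#' @export
setMethod("show", "DerivedQuantities", function(object) {
  cat(sprintf(
    paste0("DerivedQuantities @ %.2f K:\n",
           "  [Ag]_i = Kd(app) = %.4g mol/L\n",
           "  delta mu standard = %.4g kJ/mol\n",
           "  gamma_inf = %.4g\n"),
    object@temperature, object@kdApparent,
    object@deltaMuStandard / 1000, object@gammaInf))
})

#' @describeIn Activity-class compact display
#' @param object object to display.
#' @export
setMethod("show", "Activity", function(object) {
  cat(sprintf("Activity: a = %.4g (gamma=%.4g, conc=%.4g mol/L)\n",
              object@value, object@gamma, object@conc))
})

#' @describeIn ClonalMixture-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ClonalMixture", function(object) {
  cat(sprintf(
    "ClonalMixture: %d clone(s), regime=%s, total sites=%.3g mol/L\n",
    length(object@kd), object@regime, sum(object@concTotal)))
  cat(sprintf("  Kd range: %.3g .. %.3g mol/L\n",
              min(object@kd), max(object@kd)))
})

#' @describeIn AssayConfig-class compact display
#' @param object object to display.
#' @export
setMethod("show", "AssayConfig", function(object) {
  cat(sprintf(
    "AssayConfig: %d-point grid %.3g..%.3g mol/L, %d replicate(s), CV=%.3g (%s), seed=%g\n",
    length(object@concGrid), min(object@concGrid), max(object@concGrid),
    object@replicates, object@noiseCV, object@noiseType, object@seed))
})
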