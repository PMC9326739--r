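#' @importFrom stats coef vcov residuals fitted predict
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers; slot access
#' from user code is never needed.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("conc", function(object) standardGeneric("conc"))
#' @rdname accessors
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
#' @rdname accessors
#' @export
setGeneric("seriesMeta", function(object) standardGeneric("seriesMeta"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("paramSE", function(object) standardGeneric("paramSE"))
#' @rdname accessors
#' @export
setGeneric("fitStats", function(object) standardGeneric("fitStats"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("agInfl", function(object) standardGeneric("agInfl"))
#' @rdname accessors
#' @export
setGeneric("kdApparent", function(object) standardGeneric("kdApparent"))
#' @rdname accessors
#' @export
setGeneric("deltaMu", function(object) standardGeneric("deltaMu"))
#' @rdname accessors
#' @export
setGeneric("gammaInf", function(object) standardGeneric("gammaInf"))
#' @rdname accessors
#' @export
setGeneric("activityValue", function(object) standardGeneric("activityValue"))
#' @rdname accessors
#' @export
setGeneric("comparisonTable",
           function(object) standardGeneric("comparisonTable"))
#' @rdname accessors
#' @export
setGeneric("cloneTable", function(object) standardGeneric("cloneTable"))

#' @rdname accessors
#' @export
setMethod("conc", "TitrationSeries", function(object) object@conc)
#' @rdname accessors
#' @export
setMethod("signals", "TitrationSeries", function(object) object@signal)
#' @rdname accessors
#' @export
setMethod("seriesMeta", "TitrationSeries", function(object) object@meta)
#' @rdname accessors
#' @export
setMethod("nObs", "TitrationSeries",
          function(object) length(object@conc) * ncol(object@signal))

#' @rdname accessors
#' @export
setMethod("modelName", "FitResult", function(object) object@model)
#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("paramSE", "FitResult", function(object) object@paramSE)
#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("nObs", "FitResult", function(object) object@nObs)
#' @rdname accessors
#' @export
setMethod("fitStats", "FitResult", function(object)
  list(rss = object@rss, aic = object@aic, bic = object@bic,
       rSquared = object@rSquared, nObs = object@nObs,
       converged = object@converged))

#' Named parameter vector of a fitted model
#'
#' @param object a [FitResult].
#' @param ... ignored.
#' @return named numeric vector of the fitted curve parameters.
#' @export
setMethod("coef", "FitResult", function(object, ...)
  paramsToVector(object@params))

#' @describeIn coef-FitResult-method parameter covariance matrix
#'   (natural parameter scale).
#' @export
setMethod("vcov", "FitResult", function(object, ...) object@cov)

#' @describeIn coef-FitResult-method residuals in fitting order.
#' @export
setMethod("residuals", "FitResult", function(object, ...) object@residuals)

#' @describeIn coef-FitResult-method fitted values in fitting order.
#' @export
setMethod("fitted", "FitResult", function(object, ...) object@fitted)

#' Predict signal from a fitted binding model
#'
#' @param object a [FitResult].
#' @param conc antigen concentrations (mol/L) at which to evaluate; the
#'   fitted series' concentrations by default.
#' @param ... ignored.
#' @export
setMethod("predict", "FitResult", function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object@series@conc
  predictParams(object@params, conc)
})

#' @rdname accessors
#' @export
setMethod("agInfl", "DerivedQuantities", function(object) object@agInfl)
#' @rdname accessors
#' @export
setMethod("kdApparent", "DerivedQuantities",
          function(object) object@kdApparent)
#' @rdname accessors
#' @export
setMethod("deltaMu", "DerivedQuantities",
          function(object) object@deltaMuStandard)
#' @rdname accessors
#' @export
setMethod("gammaInf", "DerivedQuantities", function(object) object@gammaInf)

#' @rdname accessors
#' @export
setMethod("activityValue", "Activity", function(object) object@value)

#' @rdname accessors
#' @export
setMethod("comparisonTable", "ModelComparison",
          function(object) object@table)

#' @describeIn accessors the per-model fits of a [ModelComparison]
#'   (a [FitResult], or the error message for a model that failed).
#' @param name model name: `"4PL"`, `"5PL"` or `"GL"`.
#' @export
setMethod("[[", "ModelComparison",
          function(x, i, ...) x@fits[[i]])

#' @rdname accessors
#' @export
setMethod("cloneTable", "ClonalMixture", function(object)
  data.frame(clone = seq_along(object@kd), kd = object@kd,
             concTotal = object@concTotal))

#' @rdname accessors
#' @export
setGeneric("nClones", function(object) standardGeneric("nClones"))
#' @rdname accessors
#' @export
setMethod("nClones", "ClonalMixture", function(object) length(object@kd))
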