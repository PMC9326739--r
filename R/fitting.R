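## Nonlinear least-squares fitting of 4PL / 5PL / GL curves.
##
## Internally each model is fitted on a transformed parameter scale
## (positive shape parameters on the log scale) with box bounds, via
## Levenberg-Marquardt (minpack.lm::nls.lm). The GL likelihood surface
## has a known valley correlating nu and rate, so fits are multi-start:
## three starts jittering logInfl by +/-1 ln-unit and nu over
## {0.3, 1, 3}; lowest rss wins, ties broken by the smaller |ln nu|.

.clipE <- function(E) pmin(pmax(E, -.EXP_CLIP), .EXP_CLIP)

## Raw predictors on the fitting scale; x = ln(conc).
.pred4PL <- function(th, x)
  th[1] + th[2] / (1 + exp(.clipE(-th[3] * (x - th[4]))))
.predGL <- function(th, x)
  th[1] + th[2] * .glCore(x, th[3], th[4], exp(th[5]))
.pred5PL <- function(th, x)
  th[1] + th[2] * (1 + exp(.clipE(th[3] * (th[4] - x))))^(-exp(th[5]))

## Model descriptor on the fitting scale.
.modelSpec <- function(model, xs, ys) {
  span0 <- max(ys) - min(ys)
  xlo <- min(xs) - 3
  xhi <- max(xs) + 3
  common <- list(
    sFloor = c(min(ys) - span0, min(ys) + span0),
    sSpan = c(span0 * 1e-6, span0 * 10))
  switch(model,
    "4PL" = list(
      predict = .pred4PL, k = 4L,
      names = c("sFloor", "sSpan", "rate", "logInfl"),
      lower = c(common$sFloor[1], common$sSpan[1], 1e-3, xlo),
      upper = c(common$sFloor[2], common$sSpan[2], 1e3, xhi),
      toNatural = identity, jacNatural = function(th) rep(1, 4L)),
    "GL" = list(
      predict = .predGL, k = 5L,
      names = c("sFloor", "sSpan", "rate", "logInfl", "nu"),
      lower = c(common$sFloor[1], common$sSpan[1], 1e-3, xlo, log(1e-2)),
      upper = c(common$sFloor[2], common$sSpan[2], 1e3, xhi, log(1e2)),
      toNatural = function(th) c(th[1:4], exp(th[5])),
      jacNatural = function(th) c(1, 1, 1, 1, exp(th[5]))),
    "5PL" = list(
      predict = .pred5PL, k = 5L,
      names = c("sFloor", "sSpan", "slopeB", "cMid", "asymG"),
      lower = c(common$sFloor[1], common$sSpan[1], 1e-3, xlo, log(1e-2)),
      upper = c(common$sFloor[2], common$sSpan[2], 1e3, xhi, log(1e2)),
      toNatural = function(th) c(th[1:3], exp(th[4]), exp(th[5])),
      jacNatural = function(th) c(1, 1, 1, exp(th[4]), exp(th[5]))),
    stop("unknown model '", model, "'; use '4PL', '5PL' or 'GL'",
         call. = FALSE))
}

.flattenSeries <- function(series) {
  nr <- ncol(series@signal)
  list(xs = rep(log(series@conc), times = nr),
       ys = as.vector(series@signal))
}

#' Data-driven starting values for a curve fit
#'
#' Floor and span from the signal range; the log inflection from the
#' first half-range crossing of the replicate-mean signal (linearly
#' interpolated in log concentration); the rate from the steepest local
#' slope, scaled by `4/span` so that a symmetric logistic with that
#' maximal slope has the right rate; asymmetry starts at 1 (symmetric).
#'
#' @param series a [TitrationSeries].
#' @param model `"4PL"`, `"5PL"` or `"GL"`.
#' @return the corresponding parameter object.
#' @export
initGuess <- function(series, model = c("GL", "4PL", "5PL")) {
  stopifnot(is(series, "TitrationSeries"))
  validObject(series)
  model <- match.arg(model)
  x <- log(series@conc)
  m <- rowMeans(series@signal)
  lo <- min(m); hi <- max(m); span <- hi - lo
  if (span <= 1e-10 * max(abs(m), 1))
    stop("no dynamic range: signal is flat across the titration",
         call. = FALSE)
  trend <- stats::coef(stats::lm(m ~ x))[2]
  if (!is.finite(trend) || trend <= 0)
    stop("non-increasing trend: signal does not grow with concentration",
         call. = FALSE)
  half <- lo + span / 2
  i <- which(m >= half)[1]
  logInfl <- if (i == 1L) x[1] else {
    f <- (half - m[i - 1]) / (m[i] - m[i - 1])
    x[i - 1] + f * (x[i] - x[i - 1])
  }
  slopes <- diff(m) / diff(x)
  rate <- 4 * max(slopes) / span
  rate <- min(max(rate, 1e-3), 1e3)
  switch(model,
    "GL" = GLParams(lo, span, rate, logInfl, 1),
    "4PL" = FourPLParams(lo, span, rate, logInfl),
    "5PL" = FivePLParams(lo, span, rate, exp(logInfl), 1))
}

.startTheta <- function(model, guess) {
  g <- paramsToVector(guess)
  switch(model,
    "4PL" = unname(g),
    "GL" = c(unname(g[1:4]), log(g[["nu"]])),
    "5PL" = c(unname(g[1:3]), log(g[["cMid"]]), log(g[["asymG"]])))
}

## The three starts: base, and logInfl +/- 1 with asymmetry 3 / 0.3.
.multiStarts <- function(model, theta0, lower, upper) {
  jitter <- function(dx, lnNu) {
    th <- theta0
    th[4] <- th[4] + dx
    if (model %in% c("GL", "5PL")) th[5] <- lnNu
    pmin(pmax(th, lower), upper)
  }
  list(jitter(0, 0), jitter(1, log(3)), jitter(-1, log(0.3)))
}

.residFun <- function(spec, xs, ys, wFloor, weighting, robustW = NULL) {
  function(th) {
    f <- spec$predict(th, xs)
    r <- ys - f
    if (weighting == "relative") r <- r / pmax(abs(f), wFloor)
    if (!is.null(robustW)) r <- r * robustW
    r
  }
}

.runLM <- function(resFn, theta0, lower, upper, config) {
  minpack.lm::nls.lm(
    par = theta0, lower = lower, upper = upper, fn = resFn,
    control = minpack.lm::nls.lm.control(
      maxiter = config@maxIter, ftol = config@tolerance,
      ptol = config@tolerance))
}

## Measurement-resolution floor on the residual variance entering the
## information criteria: below (1e-8 * span)^2 per point, rss differences
## are floating-point debris, not evidence.
.sigma2Floor <- function(span0) (1e-8 * max(span0, .Machine$double.xmin))^2

#' Fit a binding model to a titration series
#'
#' Bounded Levenberg-Marquardt least squares with multi-start
#' initialization (see [initGuess()]). Replicate columns are fitted as
#' independent observations. Convergence is reported honestly in
#' `converged(fit)`; a non-converged fit is returned, not masked.
#'
#' @param series a [TitrationSeries].
#' @param model `"GL"` (default), `"4PL"` or `"5PL"`.
#' @param config a [FitConfig].
#' @param pinFloorToBlank if `TRUE` and the series carries a
#'   `blankMean` in its metadata (zero-concentration wells split out by
#'   [readTitration()]), `sFloor` is fixed at that mean instead of being
#'   estimated.
#' @return a [FitResult-class].
#' @examples
#' mix <- ClonalMixture(kd = 1e-8, concTotal = 1e-9)
#' ser <- simulateTitration(mix, AssayConfig())
#' fit <- fitModel(ser, "GL")
#' coef(fit)
#' @export
fitModel <- function(series, model = c("GL", "4PL", "5PL"),
                     config = FitConfig(), pinFloorToBlank = FALSE) {
  stopifnot(is(series, "TitrationSeries"), is(config, "FitConfig"))
  validObject(series); validObject(config)
  model <- match.arg(model)
  obs <- .flattenSeries(series)
  xs <- obs$xs; ys <- obs$ys
  spec <- .modelSpec(model, xs, ys)
  nDistinct <- length(unique(series@conc))
  n <- length(ys)
  if (n <= spec$k || nDistinct < spec$k)
    stop("under-determined: ", n, " observations at ", nDistinct,
         " distinct concentrations cannot identify ", spec$k,
         " parameters (", model, ")", call. = FALSE)
  guess <- initGuess(series, model)
  theta0 <- .startTheta(model, guess)
  lower <- spec$lower; upper <- spec$upper
  fixFloor <- isTRUE(pinFloorToBlank) &&
    is.numeric(series@meta$blankMean) && is.finite(series@meta$blankMean)
  if (fixFloor) {
    theta0[1] <- series@meta$blankMean
    lower[1] <- upper[1] <- series@meta$blankMean
  }
  theta0 <- pmin(pmax(theta0, lower), upper)
  span0 <- max(ys) - min(ys)
  wFloor <- 0.05 * span0
  resFn <- .residFun(spec, xs, ys, wFloor, config@weighting)
  starts <- .multiStarts(model, theta0, lower, upper)
  best <- NULL
  for (st in starts) {
    lm <- tryCatch(.runLM(resFn, st, lower, upper, config),
                   error = function(e) NULL)
    if (is.null(lm)) next
    cand <- list(lm = lm, rss = lm$deviance)
    if (is.null(best)) { best <- cand; next }
    rel <- abs(cand$rss - best$rss) / max(best$rss, 1e-300)
    if (cand$rss < best$rss && rel > 1e-8) best <- cand
    else if (rel <= 1e-8 && length(st) >= 5L &&
             abs(lm$par[5]) < abs(best$lm$par[5])) best <- cand
  }
  if (is.null(best))
    stop("optimizer failed for model ", model, call. = FALSE)
  lm <- best$lm
  if (config@loss == "soft_l1") {
    ## iteratively reweighted soft-L1: down-weights outlying readings
    for (it in 1:3) {
      r <- ys - spec$predict(lm$par, xs)
      s <- stats::mad(r)
      if (!is.finite(s) || s <= 0) break
      delta <- 1.345 * s
      w <- (1 + (r / delta)^2)^(-0.25)
      lm2 <- tryCatch(
        .runLM(.residFun(spec, xs, ys, wFloor, config@weighting, w),
               lm$par, lower, upper, config),
        error = function(e) NULL)
      if (is.null(lm2)) break
      lm <- lm2
    }
  }
  .finishFit(series, model, spec, lm, xs, ys, fixFloor)
}

.finishFit <- function(series, model, spec, lm, xs, ys, fixFloor) {
  th <- lm$par
  fittedVals <- spec$predict(th, xs)
  res <- ys - fittedVals
  rss <- sum(res^2)
  n <- length(ys)
  k <- spec$k + 1L  # + noise variance
  sigma2 <- max(rss / n, .sigma2Floor(max(ys) - min(ys)))
  aic <- n * log(sigma2) + 2 * k
  bic <- n * log(sigma2) + log(n) * k
  tss <- sum((ys - mean(ys))^2)
  rsq <- if (tss > 0) 1 - rss / tss else NA_real_
  dof <- n - spec$k + if (fixFloor) 1L else 0L
  s2hat <- rss / max(dof, 1L)
  covTheta <- matrix(NA_real_, spec$k, spec$k)
  free <- if (fixFloor) 2:spec$k else seq_len(spec$k)
  h <- tryCatch(solve(lm$hessian[free, free, drop = FALSE] / 2),
                error = function(e) NULL)
  if (!is.null(h)) covTheta[free, free] <- s2hat * h
  if (fixFloor) covTheta[1, ] <- covTheta[, 1] <- 0
  D <- spec$jacNatural(th)
  covNat <- covTheta * tcrossprod(D)
  dimnames(covNat) <- list(spec$names, spec$names)
  se <- sqrt(pmax(diag(covNat), 0))
  names(se) <- spec$names
  natural <- spec$toNatural(th)
  names(natural) <- spec$names
  params <- vectorToParams(model, natural)
  new("FitResult", model = model, params = params, paramSE = se,
      cov = covNat, rss = rss, aic = aic, bic = bic, rSquared = rsq,
      converged = lm$info %in% 1:3, nObs = as.integer(n),
      residuals = res, fitted = fittedVals, series = series)
}

#' Fit and rank the 4PL, 5PL and GL models on one series
#'
#' Fits all three models and ranks the successful fits by AIC
#' (Gaussian-likelihood form, \eqn{n\ln(rss/n) + 2k}, with the noise
#' variance counted in \eqn{k}). Fits within \eqn{\Delta AIC < 2} of
#' the best are flagged indistinguishable. A model that errors (e.g. an
#' under-determined 5PL) is reported by its message; the other models
#' are still fitted.
#'
#' @inheritParams fitModel
#' @return a [ModelComparison-class].
#' @export
compareModels <- function(series, config = FitConfig()) {
  stopifnot(is(series, "TitrationSeries"))
  models <- c("4PL", "5PL", "GL")
  fits <- lapply(models, function(m)
    tryCatch(fitModel(series, m, config), error = function(e)
      conditionMessage(e)))
  names(fits) <- models
  ok <- vapply(fits, function(f) is(f, "FitResult"), logical(1))
  if (!any(ok))
    stop("all models failed: ",
         paste(unlist(fits[!ok]), collapse = " | "), call. = FALSE)
  tab <- do.call(rbind, lapply(models[ok], function(m) {
    f <- fits[[m]]
    data.frame(model = m, k = length(coef(f)), rss = f@rss, aic = f@aic,
               converged = f@converged)
  }))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$deltaAIC <- tab$aic - tab$aic[1]
  tab$indistinguishable <- tab$deltaAIC < 2
  rownames(tab) <- NULL
  new("ModelComparison", fits = fits, table = tab)
}

#' Residual-bootstrap percentile confidence intervals
#'
#' Resamples residuals with replacement, adds them back to the fitted
#' curve, and refits from the point estimate; per-parameter percentile
#' intervals at the requested level. Bit-exact reproducible for a given
#' `config@seed`.
#'
#' @param series the fitted [TitrationSeries].
#' @param fit a converged [FitResult] for that series.
#' @param config a [FitConfig]; `bootstrapN` must be >= 100.
#' @param level coverage level, default 0.95.
#' @return data.frame: parameter, estimate, lower, upper, nBoot.
#' @export
bootstrapCI <- function(series, fit, config = FitConfig(bootstrapN = 200L),
                        level = 0.95) {
  stopifnot(is(series, "TitrationSeries"), is(fit, "FitResult"))
  if (!converged(fit))
    stop("cannot bootstrap a non-converged fit", call. = FALSE)
  if (config@bootstrapN < 100L)
    stop("bootstrapN must be >= 100", call. = FALSE)
  obs <- .flattenSeries(series)
  xs <- obs$xs
  spec <- .modelSpec(fit@model, xs, obs$ys)
  theta <- .startTheta(fit@model, fitParams(fit))
  lower <- spec$lower; upper <- spec$upper
  theta <- pmin(pmax(theta, lower), upper)
  fittedVals <- spec$predict(theta, xs)
  res <- obs$ys - fittedVals
  n <- length(res)
  wFloor <- 0.05 * (max(obs$ys) - min(obs$ys))
  draws <- matrix(NA_real_, config@bootstrapN, spec$k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config@seed %% .Machine$integer.max)
  for (b in seq_len(config@bootstrapN)) {
    ysB <- fittedVals + res[sample.int(n, n, replace = TRUE)]
    resFn <- .residFun(spec, xs, ysB, wFloor, config@weighting)
    lmB <- tryCatch(.runLM(resFn, theta, lower, upper, config),
                    error = function(e) NULL)
    if (!is.null(lmB)) draws[b, ] <- spec$toNatural(lmB$par)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  if (nrow(draws) < config@bootstrapN * 0.5)
    stop("bootstrap refits failed too often", call. = FALSE)
  alpha <- (1 - level) / 2
  est <- coef(fit)
  data.frame(
    parameter = spec$names,
    estimate = unname(est[spec$names]),
    lower = pmin(apply(draws, 2, stats::quantile, alpha),
                 unname(est[spec$names])),
    upper = pmax(apply(draws, 2, stats::quantile, 1 - alpha),
                 unname(est[spec$names])),
    nBoot = nrow(draws))
}

## Save/restore the global RNG state so seeded helpers do not disturb
## the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
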