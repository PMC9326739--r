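## Closed-form binding models and the ODEs they solve.
##
## All sigmoids are functions of x = ln([Ag]/1 mol/L). The Richards
## (generalized logistic, GL) curve is the solution of
##   da/dx = (r/nu) * a * (1 - a^nu),  a in (0,1),
## written so that the log inflection point x_i is itself a parameter:
##   a(x) = (1 + nu * exp(-r (x - x_i)))^(-1/nu).
## nu = 1 gives the 4PL (symmetric logistic); nu -> 0 gives the Gompertz
## curve. In measurement space the curve is sFloor + sSpan * a(x).

## exp() argument clip: beyond +/-700 a double overflows/underflows anyway.
.EXP_CLIP <- 700

.checkLogAg <- function(log_ag) {
  if (length(log_ag) == 0L || any(!is.finite(log_ag)))
    stop("log_ag must be finite", call. = FALSE)
  invisible(log_ag)
}

## Normalized Richards curve, numerically stable for nu in [1e-4, 1e3]:
## computed through log1p so tiny nu never underflows the power.
.glCore <- function(log_ag, rate, logInfl, nu) {
  E <- -rate * (log_ag - logInfl)
  E <- pmin(pmax(E, -.EXP_CLIP), .EXP_CLIP)
  z <- nu * exp(E)
  t <- ifelse(z < 1e300, log1p(z), log(nu) + E)
  exp(-t / nu)
}

#' Evaluate the generalized logistic (Richards) binding curve
#'
#' Signal at natural-log antigen concentration `log_ag` under the
#' Richards model
#' \deqn{s(x) = s_{floor} + s_{span}(1 + \nu e^{-r(x - x_i)})^{-1/\nu},}
#' the closed-form solution of the growth law
#' \eqn{da/dx = (r/\nu)\,a\,(1 - a^\nu)}. Strictly increasing in
#' `log_ag` (for `rate > 0`), tending to `sFloor` as
#' \eqn{x \to -\infty} and to `sFloor + sSpan` as \eqn{x \to +\infty}.
#'
#' @param log_ag natural log of antigen concentration (mol/L); finite.
#' @param p a [GLParams].
#' @return numeric signal, same length as `log_ag`.
#' @seealso [fourPLValue()], [fivePLValue()], [glInflection()],
#'   [glSolveODE()]
#' @examples
#' p <- GLParams(rate = 1, logInfl = log(1e-8), nu = 2)
#' glValue(log(1e-8), p)   # (1 + 2)^(-1/2) = 0.577
#' @export
glValue <- function(log_ag, p) {
  stopifnot(is(p, "GLParams"))
  validObject(p)
  .checkLogAg(log_ag)
  p@sFloor + p@sSpan * .glCore(log_ag, p@rate, p@logInfl, p@nu)
}

#' Richards growth law: rate of bound-antibody generation
#'
#' The right-hand side \eqn{(r/\nu)\,a\,(1 - a^\nu)} of the generalized
#' logistic ODE in \eqn{x = \ln[Ag]}: the rate at which the bound
#' fraction `a` grows per natural-log unit of antigen concentration.
#' Zero exactly at the fixed points `a = 0` and `a = 1`.
#'
#' @param a bound fraction(s) in \[0, 1\].
#' @param p a [GLParams] (only `rate` and `nu` enter).
#' @export
glOdeRhs <- function(a, p) {
  stopifnot(is(p, "GLParams"))
  validObject(p)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("bound fraction a must lie in [0, 1]", call. = FALSE)
  (p@rate / p@nu) * a * (1 - a^p@nu)
}

#' Logistic growth law (symmetric special case)
#'
#' \eqn{r\,a\,(1 - a)}: the [glOdeRhs()] with \eqn{\nu = 1}, i.e. the
#' classical logistic ODE whose solution is the 4PL.
#'
#' @param a bound fraction(s) in \[0, 1\].
#' @param rate dimensionless growth rate.
#' @export
logisticOdeRhs <- function(a, rate) {
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("bound fraction a must lie in [0, 1]", call. = FALSE)
  if (!is.finite(rate)) stop("rate must be finite", call. = FALSE)
  rate * a * (1 - a)
}

#' Evaluate the four-parameter logistic curve
#'
#' The symmetric sigmoid
#' \eqn{s(x) = s_{floor} + s_{span}/(1 + e^{-r(x - x_i)})}; its value at
#' the inflection `logInfl` is exactly `sFloor + sSpan/2`.
#'
#' @param log_ag natural log of antigen concentration (mol/L); finite.
#' @param p a [FourPLParams].
#' @export
fourPLValue <- function(log_ag, p) {
  stopifnot(is(p, "FourPLParams"))
  validObject(p)
  .checkLogAg(log_ag)
  E <- pmin(pmax(-p@rate * (log_ag - p@logInfl), -.EXP_CLIP), .EXP_CLIP)
  p@sFloor + p@sSpan / (1 + exp(E))
}

#' Evaluate the five-parameter logistic curve
#'
#' The conventional asymmetric immunoassay calibration model
#' \deqn{s(c) = s_{floor} + s_{span}\,(1 + (c_{mid}/c)^{b})^{-g},}
#' increasing in `c` for `slopeB > 0`. At `asymG = 1` it coincides with
#' the 4PL with `rate = slopeB`, `logInfl = log(cMid)`. For
#' `asymG != 1`, `cMid` is *not* the inflection concentration, which is
#' why the Richards parameterization is preferred for affinity readout.
#'
#' @param ag antigen concentration, mol/L, > 0.
#' @param p a [FivePLParams].
#' @export
fivePLValue <- function(ag, p) {
  stopifnot(is(p, "FivePLParams"))
  validObject(p)
  if (length(ag) == 0L || any(!is.finite(ag)) || any(ag <= 0))
    stop("ag must be finite and > 0", call. = FALSE)
  E <- pmin(pmax(p@slopeB * (log(p@cMid) - log(ag)), -.EXP_CLIP), .EXP_CLIP)
  p@sFloor + p@sSpan * (1 + exp(E))^(-p@asymG)
}

#' Inflection point of the Richards curve
#'
#' The log-concentration of maximal slope is the parameter `logInfl`
#' itself; the curve value there is
#' \eqn{s_{floor} + s_{span}(1 + \nu)^{-1/\nu}}, which equals the
#' half-maximum only at \eqn{\nu = 1} and decreases toward the Gompertz
#' value \eqn{1/e} as \eqn{\nu \to 0^+} (and toward 0 as
#' \eqn{\nu \to \infty}).
#'
#' @param p a [GLParams].
#' @return list with `logAg` (natural-log mol/L) and `value` (signal).
#' @export
glInflection <- function(p) {
  stopifnot(is(p, "GLParams"))
  validObject(p)
  list(logAg = p@logInfl,
       value = p@sFloor + p@sSpan * (1 + p@nu)^(-1 / p@nu))
}

#' Integrate the Richards ODE along a log-concentration grid
#'
#' Numerically integrates \eqn{da/dx = (r/\nu)a(1 - a^\nu)} from the
#' grid start with initial bound fraction `a0`, via `deSolve::ode`
#' (lsoda). This is a verification oracle for [glValue()]: starting from
#' the closed-form value at the grid start, the trajectory must
#' reproduce the closed form everywhere.
#'
#' @param p a [GLParams] (normalized scale; `sFloor`/`sSpan` ignored).
#' @param log_ag_grid strictly increasing natural-log concentrations.
#' @param a0 initial bound fraction, strictly inside (0, 1): the ODE's
#'   fixed points 0 and 1 give degenerate constant trajectories.
#' @return numeric bound fraction at each grid point.
#' @export
glSolveODE <- function(p, log_ag_grid, a0) {
  stopifnot(is(p, "GLParams"))
  validObject(p)
  if (is.unsorted(log_ag_grid, strictly = TRUE))
    stop("log_ag_grid must be strictly increasing", call. = FALSE)
  if (!is.finite(a0) || a0 <= 0 || a0 >= 1)
    stop("a0 must lie strictly inside (0, 1)", call. = FALSE)
  rhs <- function(x, state, parms)
    list((parms$rate / parms$nu) * state * (1 - state^parms$nu))
  ## atol must stay below the trajectory scale: an absolute error at a
  ## tiny a0 is amplified exponentially through the growth phase, so the
  ## error control has to be relative even near zero
  atol <- max(min(1e-14, a0 * 1e-10), 1e-280)
  out <- deSolve::ode(y = c(a = a0), times = log_ag_grid, func = rhs,
                      parms = list(rate = p@rate, nu = p@nu),
                      method = "lsoda", rtol = 1e-12, atol = atol)
  unname(out[, "a"])
}
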