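#' Gas constant, J/(mol K)
#' @keywords internal
.R_GAS <- 8.314462618

#' Relative thermodynamic activity of the antigen
#'
#' \eqn{a_{Ag} = \gamma_{Ag} \cdot [Ag] / c^\circ}: the activity
#' coefficient adjusts concentration to the effective,
#' interaction-corrected concentration, made dimensionless by the
#' standard state \eqn{c^\circ = 1} mol/L.
#'
#' @param conc antigen concentration, mol/L, >= 0.
#' @param gamma dimensionless activity coefficient, > 0.
#' @return an [Activity-class] object.
#' @export
antigenActivity <- function(conc, gamma = 1) {
  if (!is.finite(conc) || conc < 0)
    stop("conc must be finite and >= 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be finite and > 0", call. = FALSE)
  new("Activity", value = gamma * conc / 1, gamma = gamma, conc = conc)
}

#' Limiting activity coefficient from the Richards exponent
#'
#' The antigen's thermodynamic activity coefficient at infinite antibody
#' dilution is the reciprocal of the fitted asymmetry exponent:
#' \eqn{\gamma_{Ag}^\infty = 1/\nu}. A homogeneous (monoclonal-like)
#' bound pool gives \eqn{\nu \approx 1} and hence
#' \eqn{\gamma^\infty \approx 1}; departures in either direction track
#' the clonal composition of the binding antibody pool.
#'
#' @param nu dimensionless asymmetry exponent, > 0.
#' @return dimensionless \eqn{1/\nu}.
#' @export
limitingActivityCoefficient <- function(nu) {
  if (any(!is.finite(nu)) || any(nu <= 0))
    stop("nu must be finite and > 0", call. = FALSE)
  1 / nu
}

#' Thermodynamic descriptors of a fitted binding curve
#'
#' Converts a converged generalized-logistic fit into the quantities
#' that characterize the bound antibody pool:
#' \itemize{
#'   \item \eqn{[Ag]_i = e^{x_i}} — the antigen concentration at the
#'     inflection point, an estimate of the apparent equilibrium
#'     dissociation constant of the bound pool;
#'   \item \eqn{\Delta\mu^\circ = RT\ln(K_d/c^\circ)} — the standard
#'     chemical potential of dissociation (dissociation convention:
#'     sub-molar \eqn{K_d}, i.e. higher affinity, gives a more negative
#'     \eqn{\Delta\mu^\circ});
#'   \item \eqn{\gamma^\infty = 1/\nu} — the limiting activity
#'     coefficient, a clonal-heterogeneity readout.
#' }
#'
#' @param fit a converged [FitResult] from a `"GL"` model fit.
#' @param temperature K; default 298.15.
#' @return a [DerivedQuantities-class] object.
#' @export
deriveQuantities <- function(fit, temperature = 298.15) {
  stopifnot(is(fit, "FitResult"))
  if (!converged(fit))
    stop("fit did not converge; derived quantities undefined",
         call. = FALSE)
  if (modelName(fit) != "GL")
    stop("derived quantities are defined for the GL model only",
         call. = FALSE)
  p <- fitParams(fit)
  kd <- exp(p@logInfl)
  new("DerivedQuantities",
      agInfl = kd, kdApparent = kd,
      deltaMuStandard = .R_GAS * temperature * log(kd / 1),
      gammaInf = limitingActivityCoefficient(p@nu),
      temperature = temperature)
}
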