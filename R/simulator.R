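## Ground-truth simulator of mono- and polyclonal binding equilibria.
##
## Each clone is a single-site Langmuir binder. Two regimes:
##   independent_sites — every clone sees the nominal antigen
##     concentration as free antigen (antibody-dilute limit);
##   competitive — all clones share one epitope and deplete a common
##     free-antigen pool, found by solving the mass balance
##       Ag_total = Ag_free * (1 + sum_j c_j / (Kd_j + Ag_free)).
## A single Langmuir clone plotted against ln(Ag) is exactly the nu = 1
## logistic with logInfl = ln(Kd), which is what makes the simulator a
## ground-truth check on the fitted Richards parameters.

#' Per-clone and aggregate bound fractions at a free antigen concentration
#'
#' Independent-sites equilibrium: clone `j` is bound with probability
#' \eqn{Ag_{free} / (Kd_j + Ag_{free})}; the aggregate bound fraction is
#' the concentration-weighted mean over clones, always in \[0, 1\].
#'
#' @param mix a [ClonalMixture].
#' @param ag_free free antigen concentration, mol/L, >= 0 (scalar or
#'   vector).
#' @return list with `perClone` (matrix, one row per `ag_free`, one
#'   column per clone), `boundTotal` (mol/L bound antibody) and
#'   `aggregate` (bound fraction of the whole pool).
#' @export
boundFractionIndependent <- function(mix, ag_free) {
  stopifnot(is(mix, "ClonalMixture"))
  validObject(mix)
  if (any(!is.finite(ag_free)) || any(ag_free < 0))
    stop("ag_free must be finite and >= 0", call. = FALSE)
  frac <- outer(ag_free, mix@kd, function(a, k) a / (k + a))
  boundTotal <- as.vector(frac %*% mix@concTotal)
  total <- sum(mix@concTotal)
  aggregate <- if (total > 0) boundTotal / total else rep(0, length(ag_free))
  list(perClone = frac, boundTotal = boundTotal, aggregate = aggregate)
}

#' Free antigen under shared-epitope competition
#'
#' Solves the antigen mass balance
#' \eqn{Ag_t = Ag_f (1 + \sum_j c_j/(Kd_j + Ag_f))}
#' for the free concentration by bracketed root finding on
#' \eqn{[0, Ag_t]} (the balance is strictly monotone in \eqn{Ag_f}, so
#' the root is unique), then distributes the bound antigen over clones.
#' Mass is conserved to 1e-9 relative.
#'
#' @param mix a [ClonalMixture] in the `"competitive"` regime.
#' @param ag_total total antigen concentration, mol/L, >= 0 (scalar or
#'   vector).
#' @return list with `agFree` (mol/L), `boundPerClone` (matrix, mol/L)
#'   and `boundTotal` (mol/L).
#' @export
solveCompetitive <- function(mix, ag_total) {
  stopifnot(is(mix, "ClonalMixture"))
  validObject(mix)
  if (mix@regime != "competitive")
    stop("solveCompetitive requires the competitive regime", call. = FALSE)
  if (any(!is.finite(ag_total)) || any(ag_total < 0))
    stop("ag_total must be finite and >= 0", call. = FALSE)
  kd <- mix@kd; ct <- mix@concTotal
  agFree <- vapply(ag_total, function(At) {
    if (At == 0 || sum(ct) == 0) return(At)
    g <- function(af) af * (1 + sum(ct / (kd + af))) - At
    ## g(0) = -At < 0, g(At) >= 0: root bracketed in [0, At]
    af <- stats::uniroot(g, lower = 0, upper = At, tol = 1e-12 * At,
                         maxiter = 200L)$root
    ## Newton polish: the bracketed root alone can leave a residual of
    ## order g'(af) * tol when the pool is strongly depleting
    for (it in 1:3) {
      gp <- 1 + sum(ct * kd / (kd + af)^2)
      afNew <- af - g(af) / gp
      if (!is.finite(afNew) || afNew < 0 || afNew > At) break
      af <- afNew
    }
    af
  }, numeric(1))
  boundPerClone <- outer(agFree, seq_along(kd), function(af, j)
    ct[j] * af / (kd[j] + af))
  list(agFree = agFree,
       boundPerClone = boundPerClone,
       boundTotal = rowSums(boundPerClone))
}

## Bound antibody (mol/L) at nominal antigen concentrations, per regime.
.boundAtConc <- function(mix, ag) {
  if (mix@regime == "competitive") solveCompetitive(mix, ag)$boundTotal
  else boundFractionIndependent(mix, ag)$boundTotal
}

#' Simulate a titration series from a clonal mixture
#'
#' Noiseless signal is `background + signalPerBound * bound(Ag)`; the
#' measurement noise is multiplicative log-normal with median 1 and
#' coefficient of variation `noiseCV` (fluorescence-like), or additive
#' Gaussian if `noiseType = "gaussian"`. Fully deterministic given
#' `assay@seed`; the seed is recorded in the series metadata.
#'
#' @param mix a [ClonalMixture].
#' @param assay an [AssayConfig].
#' @param meta extra metadata merged into the series.
#' @return a [TitrationSeries-class].
#' @export
simulateTitration <- function(mix, assay = AssayConfig(), meta = list()) {
  stopifnot(is(mix, "ClonalMixture"), is(assay, "AssayConfig"))
  validObject(mix); validObject(assay)
  bound <- .boundAtConc(mix, assay@concGrid)
  clean <- assay@background + assay@signalPerBound * bound
  nr <- assay@replicates
  sig <- matrix(rep(clean, nr), ncol = nr)
  if (assay@noiseCV > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(assay@seed %% .Machine$integer.max)
    if (assay@noiseType == "lognormal") {
      sdlog <- sqrt(log(1 + assay@noiseCV^2))
      noise <- matrix(stats::rlnorm(length(sig), 0, sdlog), ncol = nr)
      sig <- sig * noise
    } else {
      sdAbs <- assay@noiseCV * (max(clean) - min(clean))
      sig <- sig + matrix(stats::rnorm(length(sig), 0, sdAbs), ncol = nr)
    }
  }
  TitrationSeries(assay@concGrid, sig,
                  utils::modifyList(list(seed = assay@seed,
                                         regime = mix@regime), meta))
}

#' Draw a random polyclonal mixture
#'
#' Per-clone dissociation constants are log-normal over Kd
#' (\eqn{\log_{10} Kd \sim N(\mu, \sigma)}), the standard model for
#' polyclonal affinity spectra; clone abundances split a fixed total
#' binding-site concentration by symmetric Dirichlet weights (drawn as
#' normalized Gamma variates). Reproducible by `seed`.
#'
#' @param n_clones number of clones, >= 1.
#' @param log10_kd_mean mean of log10(Kd / (mol/L)).
#' @param log10_kd_sd standard deviation of log10 Kd, >= 0.
#' @param conc_total total binding-site concentration, mol/L.
#' @param conc_dirichlet_alpha symmetric Dirichlet concentration for the
#'   clone abundances; large values give near-equal clones.
#' @param regime `"independent_sites"` or `"competitive"`.
#' @param seed integer seed.
#' @return a [ClonalMixture-class] with the seed recorded.
#' @export
generateMixture <- function(n_clones, log10_kd_mean = -8, log10_kd_sd = 1,
                            conc_total = 1e-9, conc_dirichlet_alpha = 1,
                            regime = c("independent_sites", "competitive"),
                            seed = 1L) {
  regime <- match.arg(regime)
  if (n_clones < 1L) stop("n_clones must be >= 1", call. = FALSE)
  if (!is.finite(log10_kd_sd) || log10_kd_sd < 0)
    stop("log10_kd_sd must be finite and >= 0", call. = FALSE)
  if (!is.finite(conc_total) || conc_total < 0)
    stop("conc_total must be finite and >= 0", call. = FALSE)
  if (!is.finite(conc_dirichlet_alpha) || conc_dirichlet_alpha <= 0)
    stop("conc_dirichlet_alpha must be > 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  kd <- 10^stats::rnorm(n_clones, log10_kd_mean, log10_kd_sd)
  w <- if (n_clones == 1L) 1 else {
    g <- stats::rgamma(n_clones, shape = conc_dirichlet_alpha, rate = 1)
    g / sum(g)
  }
  ClonalMixture(kd = kd, concTotal = conc_total * w, regime = regime,
                seed = seed)
}

#' Immune-response scenario presets
#'
#' Two stylized serum states. An *active response* is a clonally
#' heterogeneous pool: many clones (20) with a broad affinity spread
#' (sd of log10 Kd = 1.0) around a moderate mean affinity
#' (Kd ~ 10 nM). A *memory response* is an optimized pool: few clones
#' (3), narrow spread (sd 0.2), mean affinity 10-fold higher
#' (Kd ~ 1 nM). Both compete for a shared epitope at a fixed total
#' paratope concentration, and are assayed noiselessly over a wide
#' antigen grid by default; every setting can be overridden.
#'
#' @param name `"active_response"` or `"memory_response"`.
#' @param seed integer seed for the mixture draw.
#' @param ... overrides passed to [generateMixture()] (e.g. `n_clones`,
#'   `log10_kd_sd`) and/or [AssayConfig()] (e.g. `noiseCV`,
#'   `replicates`), matched by argument name.
#' @return list with `mixture` (a [ClonalMixture]) and `assay`
#'   (an [AssayConfig]).
#' @export
scenarioPreset <- function(name = c("active_response", "memory_response"),
                           seed = 1L, ...) {
  name <- match.arg(name)
  over <- list(...)
  mixDefaults <- switch(name,
    active_response = list(n_clones = 20L, log10_kd_mean = -8,
                           log10_kd_sd = 1.0),
    memory_response = list(n_clones = 3L, log10_kd_mean = -9,
                           log10_kd_sd = 0.2))
  mixDefaults <- c(mixDefaults,
                   list(conc_total = 2e-9, conc_dirichlet_alpha = 1,
                        regime = "competitive", seed = seed))
  assayDefaults <- list(concGrid = 10^seq(-12, -4, length.out = 17),
                        noiseCV = 0, replicates = 1L,
                        signalPerBound = 1e12, background = 100,
                        noiseType = "lognormal", seed = seed)
  mixArgs <- utils::modifyList(mixDefaults,
                               over[names(over) %in% names(mixDefaults)])
  assayArgs <- utils::modifyList(assayDefaults,
                                 over[names(over) %in% names(assayDefaults)])
  unknown <- setdiff(names(over),
                     c(names(mixDefaults), names(assayDefaults)))
  if (length(unknown))
    stop("unknown scenario override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  list(mixture = do.call(generateMixture, mixArgs),
       assay = do.call(AssayConfig, assayArgs),
       name = name)
}
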