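---
title: "Richards-curve serology: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Richards-curve serology: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serocurve)
```

## The measurement problem

A serum sample contains a polyclonal pool of antibodies against any
given antigen: many structurally distinct clones, each with its own
equilibrium dissociation constant and concentration. Conventional
serology reduces an antigen-titration curve to an arbitrary titer, which
is not comparable across platforms, isotypes or antigens. `serocurve`
instead fits the titration curve with a model whose parameters are
physical quantities of the bound antibody pool, so that different assays
can be reported in common biochemical units.

## The model family

All models describe the equilibrium signal as a sigmoid in
$x = \ln([Ag]/\mathrm{mol\,L^{-1}})$. The bound fraction
$a = Ab_{bound}/Ab_{total}$ of a well-behaved titration obeys a growth
law along the concentration axis:

$$\frac{da}{dx} = \frac{r}{\nu}\, a \left(1 - a^{\nu}\right).$$

Its solution is the generalized logistic (Richards) curve, written here
so that the log inflection point is itself a parameter:

$$a(x) = \left(1 + \nu e^{-r (x - x_i)}\right)^{-1/\nu},
\qquad s(x) = s_{floor} + s_{span}\, a(x).$$

* $\nu = 1$ gives the classical logistic — the four-parameter logistic
  (4PL) of immunoassay practice. A single-clone (Langmuir) titration is
  *exactly* this curve with $x_i = \ln K_d$, which anchors the
  interpretation of the parameters.
* $\nu \to 0^+$ gives the Gompertz curve.
* The inflection sits at $x = x_i$ with bound fraction
  $(1+\nu)^{-1/\nu}$. This is an increasing function of $\nu$: it rises
  from $1/e$ in the Gompertz limit through $1/2$ at $\nu = 1$ toward 1
  as $\nu \to \infty$. (A curve's inflection is at its half-maximum
  only in the symmetric case.)

Two quantities are derived from a converged GL fit
(`deriveQuantities()`):

* $[Ag]_i = e^{x_i}$, the antigen concentration at the inflection — an
  estimate of the apparent equilibrium dissociation constant of the
  bound pool, with standard chemical potential
  $\Delta\mu^\circ = RT \ln(K_d/c^\circ)$, $c^\circ = 1$ mol/L
  (dissociation convention: higher affinity, more negative
  $\Delta\mu^\circ$);
* $\gamma^\infty_{Ag} = 1/\nu$, the limiting thermodynamic activity
  coefficient of the antigen at infinite antibody dilution — a readout
  of the clonal composition of the binders: a homogeneous pool gives
  $\gamma^\infty \approx 1$, heterogeneous pools push it away from 1.

The five-parameter logistic (5PL),
$s(c) = s_{floor} + s_{span}(1+(c_{mid}/c)^b)^{-g}$, is included purely
as a comparison model. Note its scale parameter $c_{mid}$ is *not* the
inflection concentration unless $g = 1$, which is exactly the practical
objection to using it for affinity readout. Published descriptions of
the 5PL differ in the sign convention of the slope; `serocurve` uses
the orientation that is increasing in concentration for $b > 0$ and
reduces to the 4PL at $g = 1$.

## Fitting

`fitModel()` minimizes squared residuals with bounded
Levenberg–Marquardt (via `minpack.lm`), with the positive shape
parameters ($\nu$, $g$, $c_{mid}$) optimized on the log scale.
Decisions that matter:

* **Logarithm base.** All internal logs are natural; the rate
  parameter absorbs base changes ($r_{10} = r_{\ln}\,\ln 10$).
  Concentration grids in examples are specified in decades for
  readability.
* **Initialization.** Floor/span from the signal range; $x_i$ from the
  first half-range crossing of the replicate-mean signal (linear
  interpolation); rate from the steepest local slope scaled by
  $4/s_{span}$; $\nu = 1$. A flat series errors with "no dynamic
  range"; a descending series errors with "non-increasing trend"
  (descending axes, e.g. competition formats, are out of scope).
* **Multi-start.** The GL surface has a correlated $\nu$–$r$ valley, so
  three starts are run — the base start, and $x_i \pm 1$ ln-unit with
  $\nu \in \{3, 0.3\}$ — keeping the lowest residual sum of squares;
  near-ties go to the smaller $|\ln\nu|$ (the less asymmetric
  explanation).
* **Bounds.** $r \in [10^{-3}, 10^{3}]$, $\nu \in [10^{-2}, 10^{2}]$,
  $x_i$ within the data range $\pm 3$ ln-units, $s_{floor}$ within one
  observed span of the signal minimum. At the type level $\nu$ is kept
  in $[10^{-4}, 10^{3}]$, where $(\cdot)^{-1/\nu}$ is representable;
  exponent arguments are clipped at $\pm 700$ before `exp()`.
* **Replicates** enter as independent observations rather than being
  averaged, preserving degrees of freedom for the residual variance.
* **Blank wells** ($[Ag] \le 0$) cannot enter a log-concentration fit;
  `readTitration()` splits them out and records their mean, and
  `fitModel(pinFloorToBlank = TRUE)` can fix $s_{floor}$ at that mean.
* **Weighting and loss.** Default is unweighted least squares;
  `weighting = "relative"` divides residuals by the model value
  (floor-protected at 5% of the span) for strongly multiplicative
  noise, and `loss = "soft_l1"` applies an iteratively reweighted
  robust loss for outlying readings.
* **Model comparison.** AIC in the Gaussian-likelihood form
  $n\ln(rss/n) + 2k$, $k$ counting curve parameters plus one for the
  noise variance; $\Delta AIC < 2$ is reported as indistinguishable.
  On effectively noiseless data the rss is floating-point debris, so
  the variance entering the criterion is floored at
  $(10^{-8}\,s_{span})^2$ — below that, differences between models are
  numerically meaningless and the parameter penalty should decide.
* **Uncertainty.** Asymptotic standard errors from the Gauss–Newton
  covariance (delta method back to the natural scale), and a
  residual-resampling percentile bootstrap (`bootstrapCI()`), refit
  from the point estimate, bit-reproducible by seed.

## The simulator and what it does (not) show

`generateMixture()`/`simulateTitration()` provide ground truth for
validating the fit and the interpretation of $\nu$. Clones are
single-site Langmuir binders; affinities are log-normal over $K_d$
(the standard model for polyclonal affinity spectra) and abundances
split a fixed total by a symmetric Dirichlet. Two regimes are
available, because antibody clones recognizing one epitope compete:

* *independent sites* — each clone equilibrates against the nominal
  antigen concentration (the antibody-dilute limit);
* *competitive* — all clones share one epitope and deplete a common
  free-antigen pool, solved from the monotone mass balance
  $Ag_t = Ag_f(1 + \sum_j c_j/(K_{d,j} + Ag_f))$ by bracketed root
  finding (relative tolerance $10^{-12}$, Newton-polished so antigen is
  conserved to better than $10^{-9}$ relative).

Noise is multiplicative log-normal with median 1, parameterized by its
coefficient of variation (fluorescence-like; additive Gaussian is
available). All randomness flows from one integer seed, which is
recorded in the simulated series' metadata.

Scenario presets encode two stylized serum states at defaults chosen
once, from typical serum IgG affinities and microspot dynamic ranges,
and verified by simulation before being frozen: an **active response**
(20 clones, $\log_{10} K_d \sim N(-8, 1)$ — heterogeneous, moderate
affinity) and a **memory response** (3 clones,
$\log_{10} K_d \sim N(-9, 0.2)$ — optimized, 10-fold higher affinity,
narrow spread), both at $2\times 10^{-9}$ mol/L total paratope over a
17-point grid spanning $10^{-12}$–$10^{-4}$ mol/L, noiseless by
default. Under these defaults the memory scenario yields a smaller
fitted $[Ag]_i$ and a $\gamma^\infty$ closer to 1 than the active
scenario, and the median $|\ln\hat\nu|$ over seeded mixtures grows
monotonically with the affinity spread — the direction-of-effect
claims the test suite and acceptance script verify. Because single
mixture draws are random, scenario-level comparisons are made on
medians over seeds, not on a single draw.

What the simulator deliberately is **not**: a physical model of surface
microspots. Varying immobilized antigen density is emulated by varying
total antigen in a solution-phase mass balance; surface transport and
depletion, bivalent IgG avidity, Fc-receptor-bound antibody and
B-cell population dynamics are all outside its scope. Passing tests
therefore demonstrate that the fitting machinery recovers known
equilibrium ground truth and that $\nu$ responds to clonal
heterogeneity in the stated direction — not that any particular real
assay satisfies the model's assumptions.

## Problem sizes

The shipped checks use the sizes the package's claims are stated at:
50 random parameter sets for the ODE/closed-form equivalence; a
15-parameter-combination recovery grid; 100 seeded simulations at 5%
CV with 3 replicates (bootstrap n = 200) for the noisy-recovery and
coverage study; 50 mixtures per affinity-spread level for the
heterogeneity trend; 1000 random mixtures for mass conservation.

## Known limitations

* Antigen- and antibody-titration curves are both fit, but the derived
  thermodynamic quantities are computed for antigen titration only;
  their meaning under serum dilution is left open.
* $[Ag]_i$ is reported as the *apparent* dissociation constant of the
  pool; no mixture-averaging law over clones is asserted, and the
  relation between $\nu$ and clonal structure is validated as a
  direction/monotonicity statement, not a functional form.
* Concentrations are accepted in mol/L only; mass-unit conversion is
  intentionally out of scope (molecular-weight ambiguity).
* Fits assume a monotone increasing sigmoid; hook effects, descending
  (competition) formats and kinetic (time-resolved) data are not
  modelled.
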