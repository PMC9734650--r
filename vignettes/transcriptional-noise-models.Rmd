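---
title: "SDE-driven models of transcriptional noise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SDE-driven models of transcriptional noise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdecme)
```

## The model class

`sdecme` implements stationary joint distributions of nascent (unspliced)
and mature (spliced) RNA counts in single cells when the transcription rate
is itself a continuous stochastic process.  The reaction network is the
standard two-stage one:

* transcription: nothing &rarr; nascent, at rate $K(t)$;
* splicing: nascent &rarr; mature, at per-molecule rate $\beta$;
* degradation: mature &rarr; nothing, at per-molecule rate $\gamma$.

$K(t)$ follows a mean-reverting SDE whose stationary law is
$\Gamma(a/\kappa, \theta)$ in both of the model's two variants:

* the **jump driver** (gamma Ornstein--Uhlenbeck): exponential decay at rate
  $\kappa$ punctuated by compound-Poisson jumps with frequency $a$ and
  exponential sizes of mean $\theta$.  Biophysically this captures DNA
  mechanics: transcription progressively frustrates the template while
  topoisomerase arrivals relax it in jumps.
* the **diffusion driver** (Cox--Ingersoll--Ross): the square-root diffusion
  $\dot K = a\theta - \kappa K + \sqrt{2\kappa\theta K}\,\xi(t)$, the
  large-copy-number limit of birth--death fluctuations of an abundant
  regulator.

The two drivers share every first- and second-order stationary summary
(means, variances, covariances, autocorrelation functions) yet differ in
their full count distributions, most strongly where the gain $\theta$
dominates the arrival frequency $a$.  That asymmetry is the package's
central scientific object: summary statistics cannot discriminate the two
mechanisms, whole joint distributions can.

### Parameters and regimes

All functions use the five kinetic parameters $(\kappa, \theta, a, \beta,
\gamma)$, bundled by `sde_params()`, all strictly positive (the limiting
models are represented by their own model tags, never by boundary parameter
values, which keeps every closed form free of division by zero).  Qualitative
behaviour is summarized by two dimensionless coordinates,
$\kappa/(\kappa+\beta+\gamma)$ (reversion) and $\theta/(\theta+a)$ (gain);
`params_from_regime()` inverts the map given the mean rate
$\langle K\rangle = a\theta/\kappa$, $\beta$ and $\gamma$.  Corners of the
unit square recover the constitutive (fast reversion or low gain), mixture
(slow reversion) and geometric-burst (fast reversion and high gain, jump
driver only) models; the diffusion driver produces a heavier-tailed family
in the burst corner, which is precisely what makes the drivers
distinguishable there.

## Exact distributions

The solver works through the log probability-generating function
$\phi(u_N, u_M)$ with shifted arguments $u = g - 1$:

* jump driver: $\phi = \langle K\rangle \int_0^\infty
  U_0(s)/(1 - (\theta/\kappa)U_0(s))\,ds$ where $U_0$ solves a linear
  characteristic cascade and is available in closed three-exponential form
  (`gou_u0_coeffs()`), validated in the tests against direct numerical
  integration of the cascade to $10^{-8}$;
* diffusion driver: $\phi = \langle K\rangle \int_0^\infty U_0(s)\,ds$ with
  $U_0$ the solution of the Riccati equation
  $dU_0/ds = \kappa(U_1 - U_0) + \theta U_0^2$, integrated numerically.

PMFs are recovered by evaluating $\exp \phi$ on a product grid of complex
unit roots and taking a two-dimensional inverse FFT (`joint_pmf()`).

### Numerical choices

* **Grid extents.** Closed-form moments are free, so state-space extents
  default to $\lceil \mu + 10\sigma \rceil$ per species; the boundary mass of
  the recovered PMF is checked and a too-small grid is refused with a
  suggested size.  In likelihood evaluations the extent is additionally
  capped relative to the observed counts (about $1.3\,x_{\max} + 20$), since
  parameter sets whose bulk lies far beyond the data have negligible
  likelihood and must not force enormous transforms; the boundary check is
  disabled there deliberately.
* **Quadrature.** The semi-infinite $s$ integral is truncated at
  $\max(30/\min(\kappa,\beta,\gamma), 50)$, where the integrand (which decays
  like $e^{-\min(\kappa,\beta,\gamma) s}$) is below $10^{-13}$, and computed
  by composite Gauss--Legendre quadrature on geometrically graded panels
  (order 8, at least 10 panels, more when the horizon is long so that the
  innermost panel always resolves the fast transient).  Halving the rule
  changes $\phi$ by less than $10^{-8}$ at moderate parameters.
* **Riccati integration.** The characteristic system is diagonal across grid
  nodes and parameter sets, so whole likelihood surfaces are integrated in
  one batched call.  The default integrator is the complex-valued BDF code
  (`zvode`, diagonal Jacobian, rtol $10^{-10}$): in the high-gain corner the
  quadratic term makes the equation *nonlinearly* stiff (effective rate
  $\approx 2\theta|U_0| \gg \kappa$) and a stiff integrator is dramatically
  faster there.  A compiled adaptive Dormand--Prince integrator is kept as an
  independent cross-validation route (`grid_spec(ode_solver = "dp45")`); the
  two agree to $10^{-11}$ on PMFs in the tests.  Batches mixing very
  different $\kappa$ are grouped by decade so that slow members do not force
  long horizons onto stiff members.
* **Degenerate rates.** The closed forms have removable singularities when
  any two of $(\kappa, \beta, \gamma)$ coincide.  Below a relative gap of
  $10^{-5}$ the smaller rate is deterministically shrunk by that amount.
  The value balances the $O(\delta)$ perturbation bias against floating-point
  cancellation in the near-singular partial fractions, which grows like
  $\varepsilon/\delta^2$; at $10^{-5}$ both are near $10^{-5}$, and the
  mature autocorrelation at lag zero is exact to about $10^{-4}$ in the fully
  degenerate case.
* **Tiny negatives.** FFT round-off produces entries at the $-10^{-16}$
  level; they are clipped to zero and counted (`n_clipped`), with the
  largest imaginary residual reported (`im_max`, $<10^{-10}$ in all tests).

## Moments and noise decomposition

`steady_state_moments()` and `autocorrelation()` implement the shared
closed forms; `noise_decomposition()` splits each squared coefficient of
variation into an intrinsic reaction-timing part ($1/\mu$) and an extrinsic
transcription-rate-variation part, with the compact nascent extrinsic
fraction $\theta/(\theta+\kappa+\beta)$.  A property test verifies the
algebraic identity between the two routes at $10^{-12}$ over random
parameter sets.  The three-exponential bracket in the mature
autocorrelation vanishes identically at lag zero (a partial-fraction
identity), so $R_M(0)=1$ exactly and no additive constant is required.

## Stochastic simulation

`simulate_cells()` is a hybrid scheme that is exact up to one explicitly
controlled approximation:

* the rate path is generated first (no feedback exists): jump-driver paths
  exactly from their construction; diffusion paths on a uniform grid by the
  exact noncentral-chi-squared transition law, so path marginals carry no
  discretization error at any step size;
* discrete reactions are generated by inverting the integrated total
  propensity.  On each decay segment of the jump driver the transcription
  flux is $K_0(1-e^{-\kappa\tau})/\kappa$ and the inversion is solved
  exactly with the Lambert W function (evaluated in log space by a globally
  convergent Newton iteration, robust for extreme arguments); unconsumed
  exponential targets roll over across jumps.  For the diffusion driver the
  flux between grid points is accumulated by the trapezoidal rule on the
  linearly interpolated path, the one controlled approximation; the default
  step is $0.01/\max(\kappa, \langle K\rangle)$ and a halving test confirms
  count moments are insensitive at the three-standard-error level.
* reaction types are chosen with probabilities proportional to the channel
  propensities at the firing time; splicing and degradation are
  constant-rate channels and need no special treatment.

Equilibration defaults to $15/\min(\kappa,\beta,\gamma)$ with a warning
below $10/\min(\kappa,\beta,\gamma)$.  Because the rate process is started
from its exact stationary law, only the count transient (time scale
$1/\min(\beta,\gamma)$) actually needs burning in; the validation suites use
that shorter, equivalent protocol to keep run times reasonable.

An independent exact sampler built on the Poisson representation
(conditional on the path, both species are independent Poissons with
exponentially weighted path integrals as means) lives in the test helpers
and cross-checks the event-driven simulator without sharing any code with
it.

## Inference and model selection

`sde_fit()` maximizes the likelihood over free parameters in log10 space
(L-BFGS-B, moment-matched start plus Latin-hypercube restarts).  The
stationary distribution is invariant under joint time rescaling, so one rate
(conventionally $\beta = 1$) is fixed, leaving four identifiable parameters
for the full models; supplying a known mean rate pins
$a = \langle K\rangle\kappa/\theta$.

Bayesian machinery is deliberately deterministic by default:
`posterior_grid()` evaluates the likelihood on a tensor grid over a uniform
log10-box prior (defaults $10^{-2}$ to $10^{2}$ per parameter), yielding the
normalized posterior, marginal intervals (rounded outward by one node so
discretization cannot shrink them), and the log10 model evidence by
trapezoid quadrature with a half-resolution error estimate.  Credible-region
membership is available in two forms: a node-based HPD test with multilinear
interpolation (`in_credible_region()`), and a likelihood-ratio construction
(`lr_region_contains()`) that compares the exact log-likelihood at the
queried point against a parabolic-refined maximum -- the latter is free of
grid-discretization bias and is what the calibration experiments use,
together with a zoomed refinement pass around the coarse mode; its coverage
was validated against a brute-force fine-grid HPD computation.  For the full models a `"regime"` parameterization places the
uniform prior on the qualitative-regime square instead: the $(\kappa,
\theta)$ posterior is a long diagonal ridge (the two trade off), while in
regime coordinates it is compact, which is the right space both for
credible-region calibration and for reading off mechanism.  A
differential-evolution Metropolis sampler (`posterior_sample()`, z-history
proposals, no gradients) is provided for workflows that want draws; a test
checks its agreement with the grid posterior.

`log10_bayes_factor()` compares marginal likelihoods; magnitude 2 is
treated as decisive.  `distinguishability_experiment()` reproduces the
regime-lattice experiment: data are sampled from the diffusion-driver's
exact PMF, both models' evidences are computed under each observation
channel (joint, nascent-only, mature-only) from one shared set of PMF
solves, and Bayes factors are averaged over replicate datasets.  For that
experiment the prior box on $(\kappa, \theta)$ spans 0.03 to 30: stationary
PMFs are insensitive to $\kappa$ beyond the fast-reversion plateau, so a
wider box only adds likelihood plateau (and integration cost), not
information.

## The screening pipeline

The pipeline mirrors a transcriptome-wide screen on spliced/unspliced count
matrices (Matrix Market + TSV sidecars): strict depth filtering of cells
(total below $10^4$ by default), expression filtering of genes (mean at or
below 0.01, maximum at or below 3, or maximum at or above 400, all
inclusive, each recorded per gene in a reconciling report), coarse regime
assignment, chi-squared ranking, and full-model likelihood-ratio selection
with the customary exclusion of $|\log_{10} \mathrm{LR}| > 150$ as
non-converged.

Design choices where the workflow was genuinely open:

* **Reduced models.** The three overdispersed limiting models are the
  geometric-burst model, the gamma mixture, and a fast-reversion
  heavy-tailed diffusion stand-in (the diffusion driver with $\kappa$ pinned
  at 20 splicing rates, deep in the fast-reversion regime).  Each is fit with
  the time scale pinned ($\beta = 1$), the mean rate and degradation rate
  pinned by their model-agnostic moment estimators ($K = \mu_N$,
  $\gamma = \mu_N/\mu_M$), and the remaining shape parameter profiled on a
  log grid with parabolic refinement.  All three therefore carry three
  estimated quantities, so Akaike weights compare them on an equal footing
  (and reduce to likelihood comparison).
* **"Consistently assigned"** means: the same model attains the top Akaike
  weight in every subtype dataset *and* that weight is at least 0.5
  everywhere; otherwise the gene is `unassigned`.  Both pieces are
  configurable.
* **Chi-squared ranking** uses the Pearson statistic of the best reduced
  model against the observed joint histogram, pooling cells with expected
  count below 5, ranked within category and summarized by the worst rank
  across subtypes.
* **Full-model selection** shares one $(\kappa, \theta)$ log-grid likelihood
  surface per gene across all replicate datasets (one batched Riccati solve
  per gene), with $K$ and $\gamma$ pinned from the pooled moments, so both
  full models carry four estimated quantities and the likelihood-ratio sign
  is computed identically in every replicate.
* Cell-type labels are taken from the input annotation; no reclustering.

## The synthetic-data generator

`generate_fixture()` emulates the statistical structure the pipeline
assumes: genes drawn from the three regime corners (regime boxes of
half-width 0.05 around reversion/gain 0.9/0.9 for both drivers and 0.08/0.9
for the mixture corner), per-gene mean rates of order 10, $\beta = 1.2$,
$\gamma = 0.7$, around five thousand cells per replicate "animal"
(defaults 5343, 6604, 5892, 4497), genes planted to violate each expression
filter rule (sampled from their exact constitutive laws and labelled
`planted_filter`), and a fraction of binomially thinned low-depth cells.
Replicates share gene-level ground truth and differ only by RNG stream --
the strictest version of biological replication, which makes the
cross-replicate consistency check well-posed.  What the generator does *not*
emulate: technical noise (dropout, ambient RNA), cell-cycle or growth
effects, batch structure, or gene-gene dependence.  Passing tests therefore
validate the machinery under the model's own assumptions, not robustness to
those artefacts.

## Problem sizes used in the validation suites

The package's own validation experiments run at deliberately chosen scales:
six validation parameter sets (four near regime-space corners, two
intermediate, $\beta = 1.2$, $\gamma = 0.7$, $\langle K\rangle = 10$) with
$10^4$ simulated cells for the jump driver and $3\times10^3$ for the
diffusion driver; parameter-recovery calibration over 20 seeded repetitions
of 1000-cell datasets (11-node coarse regime grid plus a 7-node zoom around
the mode); the distinguishability lattice at $3\times3$ points, 1000 cells
and 3 datasets per point with 7-node-per-axis evidence quadrature; and a
screening fixture of six regime genes plus three planted violations across
four 1000-cell replicates.  These sizes give the moment checks three-standard-error
resolution of a few percent and keep each experiment's conclusions stable
under seed changes.

## Known limitations

* Time-dependent (non-stationary) distributions are out of scope; only the
  stationary solution is computed.
* The transcription-rate marginal is not exposed; the generating-function
  slot that carries it is fixed at its stationary value.
* Splicing graphs with more than one intermediate species are not
  implemented.
* The heavy-tailed fast-reversion limit of the diffusion driver is verified
  numerically (total-variation separation from the burst model), not against
  its closed form.
* Evidence quadrature is designed for at most three free dimensions; for
  larger parameter spaces use the Metropolis sampler and an external
  evidence estimator.
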