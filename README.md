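# sdecme

Stochastic-transcription-rate models of single-cell RNA counts: exact joint
distributions, moments, simulation, inference and model selection.

## The problem

Single-cell RNA counts are overdispersed, and the standard fix — fitting
negative-binomial-like distributions — says nothing about *why*. This
package implements a class of models that is both mechanistic and exactly
solvable: a continuous stochastic transcription rate K(t) drives the
two-stage reaction network

```
∅ --K(t)--> nascent --β--> mature --γ--> ∅
```

with two biophysically motivated choices of rate dynamics that share the
stationary rate law Γ(a/κ, θ):

* **jump driver** (gamma Ornstein–Uhlenbeck): dK = −κK dt + jumps at
  frequency a with exponential sizes of mean θ — DNA
  mechanics/topoisomerase relaxation;
* **diffusion driver** (Cox–Ingersoll–Ross): dK = (aθ − κK) dt +
  √(2κθK) dW — copy-number fluctuations of an abundant regulator.

Both drivers produce *identical* means, variances, covariances and
autocorrelation functions (so no summary statistic can tell them apart),
but different joint nascent/mature count distributions. The package
computes those distributions exactly (generating-function characteristics
plus inverse FFT), simulates them exactly (hybrid event-driven simulation
with Lambert-W waiting times), and quantifies when data can discriminate
the mechanisms (likelihoods, posteriors, log₁₀ Bayes factors with the
conventional decisiveness threshold of 2). A screening pipeline applies the
machinery gene-by-gene to spliced/unspliced count matrices, and a seeded
synthetic-data generator makes every stage testable offline.

Audience: quantitative biologists modelling transcriptional noise in
single-cell data, and anyone needing exact distributions for SDE-driven
birth–death cascades.

## Worked example

```r
library(sdecme)

# a moderately overdispersed parameter set, specified by its regime
# coordinates (reversion 0.5, gain 0.5), mean rate 10, beta 1.2, gamma 0.7
p <- params_from_regime(0.5, 0.5, mean_rate = 10, beta = 1.2, gamma = 0.7)
p
#> SDE-CME kinetic parameters
#>   kappa (mean reversion): 1.9
#>   theta (gain):           4.3589
#>   a     (arrival freq.):  4.3589
#>   beta  (splicing):       1.2
#>   gamma (degradation):    0.7
#>   <K> = a*theta/kappa:    10
#>   regime: reversion 0.500, gain 0.500

steady_state_moments(p)
#> Stationary moments (identical for both SDE drivers)
#>   <K>   = 10
#>   mu_N  = 8.33333   var_N = 20.0508
#>   mu_M  = 14.2857   var_M = 32.8276
#>   Cov(N,K) = 14.061   Cov(M,K) = 6.48968   Cov(N,M) = 10.8161

# exact joint PMFs for the two drivers, and how far apart they are
jg <- joint_pmf("gou", p)
jc <- joint_pmf("cir", p)
tv_distance(jg, jc)
#> [1] 0.03640968

# simulate cells with the hybrid stochastic simulator and fit the jump model
cells <- simulate_cells("gou", p, 2000, seed = 1)
cells
#> count_data: 2000 cells; mean nascent 8.348, mean mature 14.178

fit <- sde_fit(cells, "gou", fixed = list(beta = 1.2, gamma = 0.7,
                                          mean_rate = 10),
               n_restarts = 3, seed = 2)
coef(fit)[c("kappa", "theta")]
#>    kappa    theta
#> 1.849376 4.439096

# can 1000-cell data from the diffusion driver reject the jump driver at
# this regime point?  (Bayes factors averaged over 3 synthetic datasets)
lat <- data.frame(reversion = 0.5, gain = 0.5)
lat$params <- list(p)
distinguishability_experiment(lat, "cir", cells_per_set = 1000,
                              n_datasets = 3, seed = 42)
#>   reversion gain    mode mean_log10_bf sd_log10_bf
#> 1       0.5  0.5   joint      2.935716    2.407195
#> 2       0.5  0.5 nascent      1.448418    1.067290
#> 3       0.5  0.5  mature      1.059339    1.290462
```

The fitted (kappa, theta) land close to the truth (1.9, 4.36) even though the
two drivers' joint distributions differ by only 3.6% in total variation.  The
mean log10 Bayes factor of 2.9 for the joint data crosses the conventional
decisiveness threshold of 2 (the diffusion driver is favoured by a factor
of about 900), while either marginal alone stays below it.  The package's
lattice experiment (`distinguishability_experiment()` over a regime-square
lattice) maps this out: decisive evidence wherever the data are strongly
overdispersed, none in the Poisson-like corner where the drivers coincide.

A thin command-line wrapper for the main operations (solve / moments /
simulate / fit) ships in `inst/cli/sdecme.R`.

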