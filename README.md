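# semimech

Semi-mechanistic inference of regulatory networks from concentration time
series, by Bayesian gradient matching.

## The problem

Given time courses of species concentrations (say, mRNA abundances of
circadian-clock genes measured every 2 h), which species regulate which?
Fully mechanistic inference — fitting a system of kinetic ODEs — is accurate
but requires a numerical ODE solve inside every likelihood evaluation.
Generic machine-learning regressors are fast but ignore the chemistry.
Gradient matching sits in between: estimate the temporal derivative
\(y_i(t) = dx_i/dt\) *from the data*, then treat network inference as a
regression of those derivatives on mechanistically motivated kinetic terms.
No ODE is ever integrated during inference.

## The model

For a target species \(i\) with candidate regulator set \(\pi_i\),

$$
y_i(t) \;=\; -v_{0,i}\,x_i(t) \;+\; \sum_{u \in \pi_i} v_{u,i}\,
\frac{I_{u,i}\,x_u(t) + (1-I_{u,i})\,k_{u,i}}{x_u(t) + k_{u,i}}
\;+\; \varepsilon_t ,
\qquad \varepsilon_t \sim N(0, \sigma_i^2),
$$

where \(v\) are maximum reaction rates, \(k\) Michaelis–Menten
half-saturation constants, and \(I_{u,i}\) flags activation (1) or
inhibition (0). Complex formation (two transcription factors acting
jointly) enters as a product of two Michaelis–Menten fractions with one
effective rate. Rates carry a truncated ridge prior
\(V \sim N_{\{V\ge 0\}}(\mathbf 1, \delta^2\sigma^2 I)\) (a truncated
g-prior variant is provided for comparison), the constants a truncated
normal \(K \sim N_{\{K\ge 0\}}(\mathbf 1, \nu I)\), and the variances
inverse-gamma priors. A Metropolis-within-Gibbs sampler draws
\((V, K, \sigma^2, \delta^2)\); parent sets are compared by marginal
likelihood (Chib's method with a stabilized pivot, or thermodynamic
integration) or by information criteria (DIC, WAIC, CVIC, WBIC); edge
probabilities come from Bayesian model averaging over all parent sets up to
cardinality 3.

Derivatives are estimated either by finite differences or — usually much
better on noisy data — as the posterior mean of the derivative of a fitted
Gaussian process (RBF, periodic, or Matérn kernels), which is available in
closed form because GPs are closed under differentiation.

## Worked example

```r
library(semimech)

# synthetic benchmark: x1 drives degradation, x2 is the true activator,
# x3/x4 are decoys; T = 240 points, noise variance 0.05
dat <- generate_gradient_data(setting = 1, sigma2 = 0.05, seed = 1)

cfg <- run_config(iterations = 2000, burnin = 500, thin = 2,
                  chains = 1, criterion = "chib")
scores <- score_parent_sets(dat$ts, dat$grads, target = "x1",
                            candidates = c("x2", "x3", "x4"),
                            cfg = cfg, seed = 2)
scores[order(-scores$score), ]
#>      parents      score criterion
#> 2       {x2}   1.408303      chib
#> 5    {x2,x3}  -5.926149      chib
#> 6    {x2,x4}  -6.535079      chib
#> 8 {x2,x3,x4} -11.233795      chib
#> 3       {x3} -30.332985      chib
#> 4       {x4} -33.234450      chib
#> 7    {x3,x4} -35.166227      chib
#> 1         {} -52.346112      chib

round(edge_posterior(scores), 4)
#>    x2    x3    x4
#> 1e+00 7e-04 4e-04
```

The true regulator set `{x2}` wins by about 7 log-evidence units over the
best over-complex alternative — decisive on the Bayes-factor scale — and
model averaging puts essentially all posterior edge mass on `x2 -> x1`.
Parent sets missing the true regulator lose by 30+ units; the
degradation-only model by 50+.

Estimating gradients from data rather than taking them as given:

```r
g_fd <- finite_difference_gradient(ts, dt = 2)       # central quotients
g_gp <- gp_gradient(ts, family = "rbf", seed = 1)    # derivative-GP mean
```

A thin command-line interface over the same functions lives at
`inst/cli/semimech.R` (subcommands `simulate`, `gradients`, `infer`,
`select`, `evaluate`).

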