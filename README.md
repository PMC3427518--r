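# spectrabc

Likelihood-free Bayesian inference for models of protein interaction
network (PIN) evolution.

## The problem

Interactome datasets are single, incomplete snapshots of a network shaped
by gene duplication, divergence of interactions and de-novo edge
formation.  Fitting stochastic growth models to such a snapshot runs into
three walls at once: the likelihood of a network under a growth model is
intractable; networks can only be compared up to an unknown node
correspondence; and the data cover just a fraction of the proteome.
spectrabc addresses all three for anyone who wants to ask *which growth
mechanism explains an observed network, with what parameters, and what
does the unobserved full network look like*.

## The method

**Approximate Bayesian computation with sequential Monte Carlo.**  A
population of N weighted particles θ is evolved through a decreasing
tolerance schedule ε₁ > ε₂ > … > ε_T.  A proposal is kept when simulations
from it land within ε of the data; with R repeated simulations the count

    s(θ) = #{ r : d(D_r', D) ≤ ε_t },  r = 1…R

approximates the likelihood, and accepted particles are weighted by the
sequential importance formula P(θ)·s(θ) over the Gaussian-kernel mixture
of the previous population.  Model selection treats the model label m as a
discrete particle coordinate with its own switch kernel; the marginal
posterior P(m | D) is the summed weight of m's particles, and statistics
are pooled across models as E[t] = Σ_m P(m | D)·t_m (Bayesian model
averaging).

**A spectral data distance.**  Graphs are compared through the ordered
eigenvalues of their adjacency matrices,

    d(A, B) = sqrt( Σ_i (α_i − β_i)² ),

a lower bound (Umeyama) on the permutation-minimised edit distance between
the unlabelled graphs — a function of the complete adjacency structure
rather than a summary statistic, at the cost of one symmetric
eigendecomposition.

**A sampling model for incompleteness.**  Simulations grow to the
organism's protein count N_T and are reduced to the data's size N_S by a
uniform induced node subsample before comparison, so parameters refer to
the full network.  (5035 of S. cerevisiae's 6532 genes gives sampling
fraction 0.77; 1888 of E. coli's 5416 gives 0.35.)

Six growth models ship with the package: duplication–divergence with
heterodimerisation (DA), its complementarity-preserving variant (DAC),
linear preferential attachment (LPA, degree exponent 3), generalized
scale-free growth (GSF, exponent 2 + 1/(1+2ω)), and the DAC mixtures with
uniform (DACR) or preferential (DACL) edge addition.

## Worked example

Simulate an "observed" duplication–divergence network, pretend we do not
know its parameters, and fit:

```r
library(spectrabc)

set.seed(1001)
obs <- grow_da(200, delta = 0.3, alpha = 0.2)
obs
#> <pin_graph> 200 nodes, 836 edges

fit <- run_abc_smc(obs, "DA",
                   config = abc_config(n_particles = 100, n_populations = 5),
                   seed = 2001)
glance(fit)
#> # A tibble: 1 × 6
#>   n_particles n_populations n_models final_epsilon acceptance_rate   ess
#>         <int>         <int>    <int>         <dbl>           <dbl> <dbl>
#> 1         100             5        1          10.1           0.178  95.7

final <- tidy(fit)
sum(final$weight * final$delta)          # posterior mean of delta
#> [1] 0.3498453
autoplot(fit)                            # posterior marginals
```

The tolerance fell from ∞ to 10.1 over five populations and the weighted
posterior mean of the divergence probability δ lands near the generating
value 0.3, from a single observed network.  Model selection and posterior
prediction work the same way:

```r
post <- run_abc_smc_model_selection(obs, c("DA", "LPA"),
          config = abc_config(n_particles = 100, n_populations = 4),
          seed = 3001)$model_posterior
round(post, 2)
#>   DA  LPA
#> 0.61 0.39

dd <- posterior_predictive_degree_distribution(fit, n_draws = 100)
head(dd, 3)
#> # A tibble: 3 × 2
#>   degree probability
#>    <int>       <dbl>
#> 1      1      0.104
#> 2      2      0.0956
#> 3      3      0.0820
```

Four populations of 100 particles already favour the generating model
(0.61 vs 0.39); longer runs sharpen the verdict.
`posterior_predictive_degree_distribution()` renormalises over degrees
k ≥ 1 because real interactome data contain no degree-zero proteins.

A command-line surface wraps the same functions
(`inst/cli/spectrabc simulate|distance|infer|select|average|make-fixture`);
all runs are byte-reproducible under a fixed `--seed`.

## Documentation

The methods vignette
(`vignettes/network-evolution-inference.Rmd`) describes the models, the
sampler's numerical choices, the sampling model's assumptions and the
package's known limitations.
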