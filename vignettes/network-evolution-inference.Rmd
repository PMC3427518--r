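---
title: "Likelihood-free inference for models of protein interaction network evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-free inference for models of protein interaction network evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(spectrabc)
```

## The problem

Protein interaction networks (PINs) are snapshots of an evolutionary
process — gene duplication, divergence of interactions, de-novo edge
formation — observed through incomplete experimental screens.  Given an
observed undirected network, we would like to ask: which growth mechanism
best explains it, with what parameters, and what does the *full* (not yet
observed) network probably look like?

Likelihoods of network-growth models are intractable for all but toy cases,
so spectrabc performs approximate Bayesian computation (ABC): simulate a
candidate model at proposed parameters, compare the simulation to the data
with a distance, and accept proposals whose simulations come within a
tolerance $\varepsilon$.  A sequential Monte Carlo (SMC) scheme sharpens the
tolerance over a series of particle populations, so the weighted particles
converge from the prior towards the ABC posterior.

Three design choices define the method:

1. **The data distance is spectral.**  Two graphs are compared through the
   descending-ordered eigenvalues of their adjacency matrices:
   $d(A, B) = \sqrt{\sum_i (\alpha_i - \beta_i)^2}$.  This is a lower bound
   on the permutation-minimised edit distance between the unlabelled graphs
   (Umeyama's theorem), computable in one symmetric eigendecomposition
   instead of a hopeless search over $n!$ node correspondences.  Unlike a
   degree distribution or clustering coefficient it is a function of the
   complete adjacency structure, not a summary statistic.
2. **Incompleteness is modelled, not ignored.**  Interactome screens cover a
   fraction of the proteome.  Simulations are grown to the organism's full
   protein count $N_T$ and reduced to the data's size $N_S$ by uniform node
   sampling (the induced subgraph on a uniform node subset), so parameters
   are inferred for the full network while comparison happens at the
   observed size.
3. **Model identity is a particle coordinate.**  Model selection runs the
   same SMC sampler over joint (model, parameter) particles with a discrete
   model-perturbation kernel; the marginal posterior probability of a model
   is the summed weight of its particles, and statistics can be averaged
   across models in proportion to those probabilities.

## The growth models

Six models, all growing node by node from a small seed (two nodes and one
edge by default; the results at the scales used here are insensitive to the
seed choice):

| model | moves | active parameters |
|-------|-------|-------------------|
| DA    | duplicate a uniform node; inherited edges survive divergence with prob. $1-\delta$; original–copy edge with prob. $\alpha$ | $\delta, \alpha$ |
| DAC   | as DA, but one of each original/copy edge pair always survives | $\delta, \alpha$ |
| LPA   | new node attaches $\mathrm{Pois}(m)$ edges preferentially by degree ($k/2M$) | $m$ |
| GSF   | edge-weighted attachment; selected edge's weight grows by $\omega$ | $m, \omega$ |
| DACR  | DAC duplication with prob. $p$, else new node + $\mathrm{Pois}(m)$ uniformly random edges | $\delta, \alpha, p, m$ |
| DACL  | as DACR with preferential edge addition | $\delta, \alpha, p, m$ |

LPA's limiting degree exponent is 3; GSF's is $2 + 1/(1 + 2\omega)$, which
is what makes $\omega$ identifiable.

```{r growth}
g <- grow_dacr(300, delta = 0.4, alpha = 0.25, p = 0.7, m = 3)
g
degree_tail_exponent(grow_lpa(5000, m = 2))
```

Conventions that the models' probabilistic statements leave open are fixed
as follows and never varied: proposed edges that already exist, self-pairs,
and duplicate targets within a step are discarded without retry (simple
graphs, minimal distortion of the stated attachment probabilities); Poisson
draws are capped at the number of eligible targets; nodes that lose every
edge stay in the graph as degree-zero nodes; a preferential step on an
edgeless graph falls back to a uniform choice.  In the GSF model a
discarded duplicate proposal does not increment any edge weight, so the
total edge weight always equals the edge count plus $\omega$ times the
number of successful attachments.  The mixed models skip their move-choice
draw when $p$ is exactly 0 or 1, so the degenerate mixtures replay the pure
models' random stream exactly.

## Spectral distance and its oracle

```{r distance}
k3 <- pin_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
p3 <- pin_graph(3, rbind(c(1, 2), c(2, 3)))
spectral_distance(k3, p3)
labelled_edit_distance(k3, p3)   # ordered-pair count: one edge differs, twice
min_edit_distance(k3, p3)        # exhaustive over all 6 permutations
```

`min_edit_distance()` enumerates all $n!$ node correspondences and exists
only to validate the bound on small graphs; the test suite checks
`spectral_distance() <= min_edit_distance()` on hundreds of random pairs and
exact zeros on isomorphic pairs.  The distance is used raw (not normalised
by graph size): the adaptive tolerance schedule absorbs the scale of the
data, so normalisation would only relabel $\varepsilon$.  Graphs of unequal
size are rejected by default — simulations are always grown or sampled to
the data's size — with an opt-in zero-padding comparison for exploratory
use.

## The sampler

`run_abc_smc()` fits one model; `run_abc_smc_model_selection()` fits a
candidate set jointly.  The numerical choices that matter:

* **Tolerance schedule** — adaptive by default: population 1 accepts
  everything ($\varepsilon_1 = \infty$, an importance-weighted prior
  sample), and each later $\varepsilon_t$ is the median of the previous
  population's realized distances.  An explicit strictly decreasing
  schedule can be supplied instead.
* **Kernel** — diagonal Gaussian; each parameter's bandwidth is
  $\sqrt{2 \times \text{weighted variance}}$ of the previous population,
  recomputed every generation (the standard adaptive choice for Gaussian
  ABC-SMC kernels).  Out-of-prior proposals are redrawn up to a retry cap,
  then a new source particle is resampled, keeping the effective kernel a
  truncated Gaussian without zero-prior weights.
* **Weights** — first population: the acceptance count $s$ (out of $R$
  repeated simulations).  Later populations: uniform prior density
  $\times\, s$, divided by the kernel mixture density over the previous
  population.  In the joint sampler the denominator multiplies the model
  kernel mass ($\sum_{m'} P_{t-1}(m')K_M(m''\,|\,m')$) by the within-model
  parameter mixture; on a model switch the parameter particle is resampled
  from the *proposed* model's previous particles (parameters of different
  models are not commensurable), or from its prior if that model currently
  has none.
* **Model kernel** — stay with probability $1 - p_{\mathrm{switch}}$, else
  move to a uniformly chosen other model; $p_{\mathrm{switch}} = 0.2$ by
  default.
* **Defaults** — $N = 1000$ particles, $T = 8$ populations, $R = 1$
  repeats, all overridable; a generation whose acceptance rate falls below
  a configurable floor aborts with a diagnostic naming the tolerance.
* **Degenerate safeguards** — a model whose previous population variance is
  zero (or that holds fewer than two particles) gets a prior-scale fallback
  bandwidth, floored away from zero.

Priors are independent uniforms; the defaults span the full legal range for
the probabilities ($[0,1]$ for $\delta, \alpha, p$) and pragmatic ranges
$[0.1, 8]$ for the Poisson mean $m$ (strictly positive, generously above
the edge densities seen in interactome data) and $[0, 5]$ for $\omega$
(covering degree exponents from 3 down to barely above 2).

```{r abc, eval = FALSE}
obs <- grow_da(200, delta = 0.3, alpha = 0.2)
fit <- run_abc_smc(obs, "DA",
                   config = abc_config(n_particles = 100, n_populations = 5),
                   seed = 1)
glance(fit)
autoplot(fit)
```

Everything downstream — `tidy()`, `glance()`, `autoplot()`,
`marginal_model_posterior()` — works off the flat particle trace (one row
per particle: generation, model, parameters, weight, acceptance count,
realized distance), which the command-line interface writes as a TSV.

## Sampling model and posterior prediction

```{r sampling}
cfg <- sampling_config(n_total = 600, n_sampled = 300)
truth <- grow_dacr(600, delta = 0.4, alpha = 0.25, p = 0.7, m = 3)
obs <- induced_subsample(truth, 300)
obs
```

`posterior_predictive_degree_distribution()` resamples particles from the
final population by weight (which automatically averages over models in
proportion to their marginal posterior), simulates each through the
sampling scheme, pools the degree distributions, and then truncates to
degrees $k \ge 1$ and renormalises.  The truncation is the degree-zero
correction: real interactome data never contain proteins with no observed
interactions, whereas induced subsamples of simulations do; truncation plus
renormalisation is the minimal correction consistent with that fact.  The
number of predictive draws defaults to the particle count, trading variance
for cost one simulation per particle.

Two caveats the uniform-sampling model deliberately accepts: simulated
subsamples retain degree-zero nodes during *distance* computation (only the
inferred degree distributions are corrected), and experimental ascertainment
is certainly not uniform (bait–prey designs, study bias).  Both are
documented trade-offs of a parsimonious model, not claims about the data.

## What the synthetic benchmarks do and do not show

The package's self-tests are built entirely on its own simulators: recovery
runs fit data *generated by a known model*, so they demonstrate internal
consistency of the sampler, distance and sampling scheme — not that any
model is true of a real interactome.  The reference test case is a DACR
network ($\delta = 0.4$, $\alpha = 0.25$, $p = 0.7$, $m = 3$;
`make_test_network()`), whose realized edge count is a single stochastic
draw and is treated as such.  Real data differ in ways the generator does
not emulate: false-positive and false-negative interactions, non-uniform
ascertainment, whole-genome duplications, and functional constraints on
which interactions can be lost.

Problem sizes used in the shipped experiments were chosen to make the
suite a routine desk-scale run: recovery on 200-node duplication networks
with 100 particles over 5 populations; model discrimination (LPA vs DA) on
150-node data with 100 particles over 4 populations; the
sampling-degradation comparison on a 600-node truth with 50%/25% induced
subsamples, 100 particles over 6 populations, and 200 predictive draws
(the pooled predictive must be estimated tightly enough that its
Monte-Carlo noise does not mask the ordering between conditions); the
attachment-exponent check on twenty 20,000-node LPA replicates (discrete
maximum likelihood on the degree tail $k \ge 10$).  At these scales the
expected qualitative results hold comfortably: credible intervals cover
generating parameters, the generating model wins discrimination, and the
50% subsample reconstructs the full network's degree distribution better
than the 25% one.  The two four-parameter duplication mixtures (DACR and
DACL) are *expected* to be hard to tell apart from a single network
realization — their posteriors overlapping is correct behaviour of the
method, not a failure.

## Known limitations

* Dense eigendecomposition makes the distance $O(n^3)$: fine to a few
  thousand nodes, expensive beyond (the original application of this method
  class used GPU linear algebra for 5000-node networks; this package stays
  on the CPU).
* The spectral distance is a lower bound, not the edit distance itself;
  graphs with equal spectra (cospectral mates) are indistinguishable to it.
* Uniform priors and uniform node sampling are modelling choices, exposed
  but not validated against any specific experimental design.
* ABC posteriors are conditional on the tolerance reached; with few
  populations or particles they remain prior-dominated, which the particle
  trace makes visible (`glance()` reports the final tolerance and effective
  sample size).
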