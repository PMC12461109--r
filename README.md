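# phylopom

Bayesian **ph**ylogenetic multi-species **o**ccupancy **m**odels in R.

## The problem

Community surveys along environmental gradients (the motivating case: bats
along a subtropical elevational gradient, sampled with mist nets and
autonomous acoustic recorders) observe each species imperfectly: a species
can occupy a site and go undetected in any given season. Multi-species
occupancy models separate the ecological signal — where species truly occur
and how occupancy responds to temperature, precipitation and forest cover —
from the observation process. When the species pool spans several clades,
responses to the environment are often *phylogenetically conserved*:
related species respond alike. `phylopom` is for ecologists who want to
estimate that conservatism, test it with honest Bayes factors, and carry
phylogenetic and detection uncertainty through to species-richness
estimates.

## The model

For species *k* at site *i*, with latent occupancy *Z* and up to two
detection methods *m*:

    Z[i,k]      ~ Bernoulli(psi[i,k])
    logit(psi)  = alpha_k + beta[1,k]*Temp_i + beta[2,k]*Prec_i + beta[3,k]*Forest_i
    Y[m][i,k]   ~ Binomial(N[m][i], p[m][k] * Z[i,k])

    beta[j, ]   ~ MVN( m_j , sigma_j^2 * ( lambda_j * C + (1 - lambda_j) * I ) )
    lambda_j    ~ 0.5 * delta_0 + 0.5 * Uniform(0, 1)      (spike and slab)

`C` is the species correlation matrix implied by a phylogeny (shared
root-to-divergence path / total depth), and Pagel's `lambda_j` measures how
phylogenetically conserved the responses to covariate `j` are. The mean
`m_j` is a common community mean (model 1) or a linear function of species
traits (model 2, trait-environment interactions). The Bayes factor for
phylogenetic signal is the posterior ratio of `lambda > 0` draws to
`lambda = 0` draws; BF > 3 reads as well-supported signal. Phylogenetic
uncertainty is handled by resampling a tree from a candidate set inside the
MCMC. The sampler is Metropolis-within-Gibbs with a compiled core (see
`vignettes/phylopom-methods.Rmd` for priors, moves, and design decisions).

The package also provides maximum-likelihood Pagel's lambda for single
traits, phylogenetic imputation of missing trait values (multivariate
Brownian conditional means), survey-effort arithmetic and collinearity
screening, detectability-corrected richness, Poisson richness regressions,
and a synthetic-community generator (`study_mimic()`) that reproduces the
statistical shape of a 27-species / 14-site / 2-method survey so the whole
pipeline is testable offline.

## Worked example

```r
library(phylopom)
world <- study_mimic(seed = 1)                     # synthetic 27 sp x 14 sites
spec  <- pom_spec(chains = 3, iterations = 20000,
                  burnin = 10000, thinning = 10, seed = 2)
fit   <- fit_pom(world$data, world$covariates, world$trees, spec = spec)
print(fit)
```

```
Phylogenetic occupancy model fit: 27 species, 14 sites, 3 chains x 1000 draws
  model 1; 100 candidate tree(s); converged: TRUE (max R-hat 1.088)
  lambda[temperature]: mean 0.354, BF 2.63
  lambda[precipitation]: mean 0.221, BF 0.89
  lambda[forest_cover]: mean 0.185, BF 0.78
```

The temperature response shows the strongest (here, at 14 sites, still
inconclusive) phylogenetic signal; precipitation and forest cover show
none — their Bayes factors sit at the prior odds. Richness, corrected for
detection:

```r
rich <- richness_table(world$data, fit)
head(rich, 4)
#     site observed estimated q2.5 q97.5
#   site01       16      22.0   19    25
#   site02       20      23.9   22    26
#   site03       14      22.2   18    25
#   site04       18      23.3   20    26

richness_regressions(rich, world$covariates_raw)$estimated_environment
#               Estimate Z value      p
# Intercept       2.6571 36.0082 0.0000
# temperature     0.3584  3.4655 0.0005
# precipitation  -0.0116 -0.1515 0.8796
# forest_cover    0.0946  1.0830 0.2788
```

Estimated richness exceeds observed richness (imperfect detection) and
increases with site temperature — the warm, low-elevation end of the
gradient holds more species. Per-trait phylogenetic signal:

```r
fit_pagel_lambda_trees(world$traits$values[, "body_mass"],
                       world$trees[1:10])$lambda_mean
# [1] 0.97
```

The end-to-end pipeline (simulate, validate, impute, fit both models,
Bayes factors, richness, four GLMs, JSON/CSV report):

```r
run_full(pipeline_config(mode = "full", outdir = "out", seed = 1))
# or from a shell:
#   Rscript -e 'phylopom::pom_cli()' full --outdir out --seed 1
```

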