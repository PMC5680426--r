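# phylotox

Two-scale evolutionary ecotoxicology of chloride (road salt) in fresh
waters, as an R package.

Road de-icing salt has pushed chloride concentrations in many temperate
ponds and streams to levels that kill aquatic animals outright. Toxicologists
summarize acute sensitivity as the LC50 — the concentration lethal to half
of the exposed organisms in a short standardized test — and decades of such
tests now cover dozens of species. phylotox is for researchers who want to
ask two evolutionary questions of those data:

1. **Across species:** is chloride sensitivity phylogenetically structured —
   do closely related species have similar LC50s? Answered with Pagel's λ
   (maximum likelihood, likelihood-ratio test), Blomberg's K (permutation
   test) and a Mantel test of patristic versus trait distances, on a tree
   with Grafen branch lengths, repeated over taxonomic subsets
   (macroinvertebrates, phyla, fish, amphibians).
2. **Within species:** have populations with a history of roadside chloride
   exposure evolved different sensitivities from nearby woodland
   populations? Answered with a logit-binomial mixed model (pond and
   container random intercepts, Laplace-approximate ML) for the
   concentration × population-type interaction, and per-type LC50s from
   binomial GLMs with delta-method 95% confidence intervals,
   LC50 = −β̂₀/β̂₁.

The statistics at the core — the λ profile likelihood over
C(λ) = λC + (1−λ)diag(C), K = (MSE₀/MSE)/E[MSE₀/MSE | BM], the permutation
and Mantel tests, the IRLS logit fit and the Laplace-approximated marginal
likelihood — are implemented in the package and verified in the test suite
against independent routes (exhaustive enumeration, direct numerical
maximization, Gauss–Hermite quadrature, and the standard comparative-methods
packages). Seeded generators simulate Brownian traits on Yule trees and
binomial mortality under the ten-pond acute-exposure design, so the whole
pipeline is testable without any external data. See
`vignettes/chloride-toxicity-methods.Rmd` for the models, defaults, and
limitations.

## Worked example

Simulate a 55-species dataset under pure Brownian motion (λ = 1), then run
both analysis arms:

```r
library(phylotox)

tree    <- simulate_yule_tree(55, seed = 1)
traits  <- simulate_trait_dataset(tree, lambda_true = 1, seed = 1)
species <- aggregate_species(traits)
run_signal_suite(species, grafen_branch_lengths(tree),
  groups = list(all = species$species),
  n_perm = 999, seed = 1, trait_scale = "log10"
)
#>   group n_species lambda p_lambda     K   p_K mantel_r p_mantel
#> 1   all        55  0.946 1.41e-20 0.575 0.001    0.411    0.001

mort <- simulate_mortality(seed = 1)   # 200 units, true LC50s 3412 / 4395 mg/L
tox  <- run_toxicity_pipeline(mort)
tox$lc50
#>   population   lc50     se ci_low ci_high     slope n_obs
#> 1   roadside 3499.1 98.747 3305.5  3692.6 0.0015765   100
#> 2   woodland 4376.8 82.834 4214.4  4539.1 0.0012640   100
```

Reading the output: the simulated λ = 1 trait is recovered as λ̂ = 0.95 with
an overwhelming likelihood-ratio test; K = 0.58 with permutation p = 0.001
and Mantel p = 0.001 agree that relatives resemble each other. In the
toxicity arm, each population type's delta-method interval covers its
simulation truth (roadside 3,412; woodland 4,395 mg/L Cl), and the roadside
estimate sits well below the woodland one. `tox$interaction` holds the
mixed-model Wald test of whether the two dose-response slopes differ.

Fitted objects follow broom conventions (`tidy()`, `glance()`), results are
tibbles, and `autoplot()` / `plot_signal_results()` give ggplot2 graphics.
A thin command-line wrapper is included
(`inst/scripts/phylotox-cli.R`; subcommands `signal`, `lc50`, `glmm`,
`pipeline`, `simulate-*`), and `run_pipeline()` writes
`signal_results.csv`, `lc50_results.csv`, `glmm_summary.json`,
`report.json` and `run.log` for any configured input files.

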