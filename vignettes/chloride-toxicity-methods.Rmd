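---
title: "Methods: phylogenetic signal and dose-response analysis of chloride toxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic signal and dose-response analysis of chloride toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylotox implements a two-scale evolutionary view of acute chloride (road
salt) toxicity in freshwater animals. At the macroevolutionary scale it asks
whether species-level chloride LC50 values carry phylogenetic signal — do
close relatives tolerate similar chloride levels? At the population scale it
asks whether populations of one species, differing in their history of
chloride exposure (roadside versus woodland breeding ponds), differ in their
acute sensitivity. This vignette explains the models, the tunable parameters
and their defaults, the numerical choices, what the synthetic-data
generators do and do not emulate, and the package's known limitations.

```{r setup}
library(phylotox)
```

## The comparative model

### Tree preparation

Species trees for toxicity compilations typically arrive as topology-only
Newick subtrees of a synthesis tree. `grafen_branch_lengths()` turns
topology into an ultrametric tree by assigning each node the height

$$h(v) = \left(\frac{t_v - 1}{n - 1}\right)^{\rho},$$

where $t_v$ is the number of tips descending from $v$ and $n$ the total tip
count; tips sit at height 0, the root at height 1, and each branch is the
height difference between its endpoints. The default $\rho = 1$ is the
standard choice; $\rho$ is exposed because it controls how quickly heights
shrink toward the tips. Polytomies are accepted everywhere. A tree whose
outermost grouping is a polytomy is read as rooted at that node — Newick
cannot distinguish this from an unrooted tree, and comparative synthesis
subtrees are conventionally rooted.

When a pruned subanalysis is run, `prune_to_taxa()` keeps the merged
branch lengths of the full-tree assignment (the standard drop-tip
behaviour), so patristic distances among retained species are unchanged.
Because one could equally re-normalize heights on each subtree, the
`regrafen_after_prune` option recomputes Grafen lengths after pruning; the
default is off, and the choice is recorded in the provenance block of every
report.

### Trait aggregation and the duration check

Literature compilations often report several LC50 estimates per species.
`aggregate_species()` applies a two-stage rule: estimates within a study are
averaged first, then study-level means are averaged, so no single prolific
study dominates a species value. Before pooling exposure durations,
`duration_effect_test()` runs a one-way OLS F test of LC50 on duration
category; a non-significant result supports treating 48-, 72- and 96-h
estimates as exchangeable. The reported degrees of freedom are whatever the
supplied records imply.

### Phylogenetic signal

Both signal statistics take Brownian motion (BM) as the null model of trait
evolution: under BM with rate $\sigma^2$, tip traits are multivariate normal
with covariance $\sigma^2 C$, where $C_{ij}$ is the shared root-to-MRCA path
length (`phylo_vcv()`).

**Pagel's λ** rescales the off-diagonal of $C$: $C_\lambda = \lambda C +
(1-\lambda)\,\mathrm{diag}(C)$. `estimate_lambda()` profiles out the GLS
root state and rate analytically,

$$\hat\mu = \frac{1'C_\lambda^{-1}x}{1'C_\lambda^{-1}1}, \qquad
\hat\sigma^2 = \frac{(x-\hat\mu 1)'C_\lambda^{-1}(x-\hat\mu 1)}{n},$$

and maximizes the resulting one-dimensional profile likelihood. The search
interval is $[0, \lambda_{\max}]$ with $\lambda_{\max} =
\max_i C_{ii} / \max_{i \ne j} C_{ij}$, the largest value keeping
$C_\lambda$ positive semidefinite; at exactly $\lambda_{\max}$ one tip pair
becomes perfectly correlated and the likelihood is evaluated up to
$\lambda_{\max}(1 - 10^{-6})$. A 21-point grid scan followed by bounded
golden-section refinement from several spread brackets (tolerance $10^{-8}$)
guards against local ripples; the best candidate across all brackets and
grid points is kept, with ties at the bound reported as the bound.
Significance is a likelihood-ratio test against $\lambda = 0$ on the upper
tail of $\chi^2_1$. Because the null sits on the parameter boundary this
test is conservative — calibration simulations in the test suite show
rejection rates well below the nominal 5%, and users should read borderline
p-values accordingly.

**Blomberg's K** compares observed to BM-expected phylogenetic dependence:

$$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
        {\left[\mathrm{tr}(C) - n/(1'C^{-1}1)\right]/(n-1)},$$

with $\mathrm{MSE}_0$ the ordinary and $\mathrm{MSE}$ the
$C^{-1}$-weighted mean squared error about the GLS mean. $K = 1$ matches BM;
$K < 1$ means relatives resemble each other less than BM predicts. On a star
phylogeny $K$ is identically 1, which the tests assert to $10^{-10}$.
Significance comes from `permutation_test_K()`: trait values are shuffled
across tips and signal summarized by MSE (smaller = stronger signal), with
the add-one estimate $p = (1 + \#\{\mathrm{MSE}^* \le
\mathrm{MSE}_{obs}\})/(1 + n_{perm})$.

**Mantel test.** `mantel_test()` correlates the upper triangles of the
patristic and absolute-trait-difference matrices and permutes rows and
columns of the second matrix jointly. The test is one-tailed for positive
association, matching the working hypothesis that close relatives are
similar; `n_perm` defaults to 999. For $n \le 5$ the sampler is checked
against exhaustive enumeration of all label permutations.

### Trait scale

Nothing in the LC50 compilation fixes whether signal should be assessed on
raw mg/L or log10 values. The package default is raw mg/L; every suite
result records its `trait_scale`, and `trait_scale = "log10"` is a
first-class option. The two scales can genuinely disagree — LC50s span
orders of magnitude, and on the raw scale the few very tolerant species
dominate the trait variance — so reports always state which scale was used,
and analysts comparing against published values should try both.

### Group structure

`run_signal_suite()` repeats the three statistics over taxonomic subsets
(default: all species, macroinvertebrates, each phylum among Chordata /
Arthropoda / Mollusca, and the chordate classes fish and amphibians, built
from the trait table's taxonomy columns). Groups with fewer than four
species in the tree are skipped with a warning and listed in the report;
species in the trait table but absent from the tree are dropped and listed.
Nothing is discarded silently.

## The population-level model

### Design

The acute-exposure design crossed 10 ponds (5 per population type) with 5
chloride concentrations — 0, 3,800, 5,100, 6,500 and 7,300 mg/L Cl,
obtained from road-salt doses of 0, 6.3, 8.4, 10.7 and 12 g/L NaCl via
`nacl_to_chloride()` (mass fraction 35.453/58.443, rounded to the nearest
100 mg/L) — with 4 replicate containers of 10 larvae each: 200 experimental
units.

### Interaction test: binomial mixed model

`fit_glmm_laplace()` models per-container deaths as binomial with

$$\mathrm{logit}\, p_{ij} = \beta_0 + \beta_1\,\mathrm{conc}_{ij}
  + \beta_2\,\mathrm{type}_i + \beta_3\,\mathrm{conc}_{ij}\times\mathrm{type}_i
  + b_{\mathrm{pond}(i)} + b_{ij},$$

with independent normal random intercepts for pond of origin and for each
container (an observation-level term absorbing the overdispersion typical
of binomial mortality counts). The marginal likelihood is approximated by
the Laplace method: a damped Newton loop finds the joint mode of the random
effects, and the curvature there supplies the correction term. The outer
optimization over fixed effects and the two SDs uses L-BFGS-B with the SDs
bounded below by zero; an SD estimated below $10^{-4}$ is flagged as a
boundary fit, and with both SDs at zero the model collapses exactly onto the
plain GLM, which the tests assert. Concentration is standardized internally
for optimizer conditioning and every reported effect is back-transformed to
the raw mg/L scale. Wald z tests condition on the estimated variance
components, the usual GLMM convention. The test suite checks the Laplace
log-likelihood against 50-point adaptive Gauss-Hermite quadrature
(agreement to $10^{-3}$) and the full fit against an independent mixed-model
implementation. `compare_aic()` supports the conventional comparison of
random-effect structures on identical data, guarded by a data fingerprint.

Inference here is Laplace-approximate maximum likelihood with Wald tests.
This is a deliberate design choice: it is deterministic, fast, and
sufficient for the scientific questions (direction and strength of the
interaction); posterior summaries from MCMC fits of the same model are not
expected to match Wald summaries numerically.

### LC50 estimation

Following the conventional two-step analysis, LC50s are estimated per
population type by pooling that type's ponds into a plain binomial logit GLM
of mortality on concentration (`fit_binomial_glm()`, IRLS, convergence at
relative deviance change $< 10^{-10}$, separation raised as an error rather
than silently returned). Then

$$\widehat{\mathrm{LC50}} = -\hat\beta_0/\hat\beta_1,$$

with the delta-method variance
$(v_{00} + 2L v_{01} + L^2 v_{11})/\hat\beta_1^2$ evaluated at
$L = \widehat{\mathrm{LC50}}$ and the 95% interval using $z = 1.959964$. The
dose axis is raw mg/L Cl by default — the design includes a true zero dose,
which a log-dose model cannot represent — with `lc50_dose_scale =
"salt_g_l"` available for refitting data recorded in salt units (results
are converted back to mg/L Cl). Zero-dose control rows stay in the fit;
they inform the intercept. Coverage of the delta-method interval under the
full study design is checked by simulation (92–98% across 1,000 runs), and
its endpoints against a parametric bootstrap.

## What the generators emulate — and what they do not

`simulate_yule_tree()` grows a pure-birth tree (exponential waiting times,
uniform lineage choice, a final extension so all pendant branches are
positive): the simplest ultrametric substrate matching the Grafen-tree
regime the analyses run on. `simulate_bm_traits()` draws tip traits from
the exact multivariate normal implied by $\sigma^2 C_\lambda$ via a
symmetric eigen factorization. `simulate_mortality()` reproduces the
acute-exposure design literally — same concentrations, replication and
stocking — with logit-linear dose response and the two random-intercept
levels. Defaults are fixed once to read like the study: per-type true LC50s
of 3,412 (roadside) and 4,395 (woodland) mg/L — the published wood-frog
point estimates, reused as convenient simulation truths — a logit slope of
$1.5 \times 10^{-3}$ per mg/L (a dose-response steep enough that the design
spans ~2% to ~99% mortality, as in the experiment), and logit-scale SDs of
0.3 at both levels, a moderate overdispersion consistent with the need for
an observation-level term but not overwhelming the dose signal.

All generators draw from per-generator streams derived from the single user
seed by a fixed splitting rule (a multiplicative hash folded into the
31-bit seed range), so adding one generator call never shifts another
generator's stream and every result is reproducible from `(seed, n_perm)`.

What passing tests on these generators show is that the estimators recover
the parameters of their own assumed models at the study's sample sizes.
What they cannot show: real LC50 compilations mix laboratories, protocols
and water chemistries (the generators have no between-study variance
component); real trait evolution is not Brownian; real mortality curves
need not be logit-linear in concentration; and real phylogenies are neither
pure-birth nor free of topology error. Conclusions about real data rest on
the model assumptions, not on these calibrations.

## Numerical choices and degenerate inputs

* Branch lengths serialize to 10 significant digits; round trips are exact
  for topology and labels.
* `is_ultrametric()` uses an absolute tolerance on the root-to-tip depth
  spread (default $10^{-8}$), appropriate for Grafen trees of height 1.
* Likelihood evaluations use Cholesky factorizations; a factorization
  failure is reported as a singular covariance, and in the λ search scores
  $-\infty$ rather than aborting the optimization.
* Constant traits, flat dose responses (slope z below $10^{-6}$), complete
  separation, rank-deficient designs, single-type mortality tables, and
  label mismatches between distance matrices all raise immediate,
  named errors.
* Mantel with $n = 3$ is allowed but flagged: only 6 permutations exist.
* Permutation p-values use add-one smoothing in numerator and denominator,
  so 0 is never reported.

## Problem sizes used in the checks

The shipped verification suite calibrates Blomberg's K on 500 simulated
50-tip datasets, λ on 200 simulated 100-tip datasets, the λ = 0
likelihood-ratio test on 500 datasets, and delta-method CI coverage on
1,000 simulated experiments, with the Mantel sampler checked against all
120 permutations at $n = 5$. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the whole suite quick
to run on a laptop.

## Known limitations

* λ and K are point summaries; the package deliberately offers no other
  signal statistics (no Moran's I, no Abouheif's $C_{mean}$) and no
  ancestral-state reconstruction or phylogenetic regression beyond the
  internal GLS mean.
* The LR test for λ and the Wald test for the GLMM interaction are
  asymptotic; at the study's sizes (55 species, 10 ponds) they are serviceable
  but approximate, and the λ test is boundary-conservative.
* The mixed model supports exactly the two random-intercept levels of the
  design (pond, container); crossed or nested extensions are out of scope.
* Only the logit link is provided for dose-response fits, matching the
  analysis the package reproduces; probit users must look elsewhere.
* The pipeline assumes the tree and trait table agree on species names
  exactly (no fuzzy name resolution); mismatches are reported, not repaired.
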