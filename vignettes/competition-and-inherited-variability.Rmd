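---
title: "Competition, indirect genetic effects, and inherited variability: the IGEvar model"
author: "IGEvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition, indirect genetic effects, and inherited variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IGEvar)
```

## The question

Genotypes differ not only in the mean of the traits they express but also in
how variable those traits are — "inherited variability", or genetic
variation in environmental variance. The usual quantitative-genetic models
for inherited variability treat variability as a property of the focal
individual alone. Social interactions break that assumption: when growth is
suppressed by a larger partner (competition) or boosted by a cooperative
one, part of the variability among individuals is caused by the *genes of
their social partners* — an indirect genetic effect (IGE) on variability.

IGEvar simulates a population in which exactly this happens, and asks how
much of the direct and indirect genetic structure four standard mixed models
can recover from a single final phenotype per individual.

## The growth model

Individuals grow in pairs over `nSteps` discrete time increments. The
weight gain of focal individual $i$ with partner $j$ between $t-1$ and $t$
is

$$P_{t,i} - P_{t-1,i} = \mu_{GR} + A_{GR,i} + E_{p,i} + E_{t,i}
  + b_{ij}\,(P_{t-1,j} - P_{t-1,i}),$$

so growth responds to the body-weight difference with the partner through
an interaction coefficient

$$b_{ij} = \bar b + A_{D,i} + E_{D,i} + A_{I,j} + E_{I,j}.$$

A negative $\bar b$ is competition (a heavier partner suppresses growth), a
positive $\bar b$ cooperation. $A_{D}$ is the focal individual's genetic
*resistance to competition* (direct effect on its own $b$), $A_{I}$ its
genetic *cooperativeness* (indirect effect on the partner's $b$). All four
$b$-components are fixed for life, so $b_{ij}$ is constant over time and in
general $b_{ij} \neq b_{ji}$. Under competition, small initial differences
within a pair are amplified multiplicatively — the channel through which
IGEs create variability.

## Parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `muGR` | 10 g | mean growth per step |
| `startWeight` | 10 g | weight at $t=0$ |
| `nSteps` | 10 | growth increments; the final weight is the analysis trait |
| `sigmaAGR` | 1 g | genetic SD of growth rate (alternates 3, 0.3) |
| `h2` | 0.5 | heritability of growth rate at $b=0$ |
| `repeatability` | 0.7 | of growth rate; splits the environmental variance |
| `bBar` | −0.05 / 0 / +0.05 | competition / neutral / cooperation |
| `sigmaAD`, `sigmaAI` | 0.015 | genetic SDs of the $b$ components (alternates 0.045, 0.005) |
| `sigmaED`, `sigmaEI` | 0.015 | environmental SDs of the $b$ components |

The variance budget of growth rate is derived, not set: the phenotypic
variance at $b=0$ is $\sigma^2_P = \sigma^2_{A_{GR}}/h^2$ (2 g² at
defaults), the permanent environmental variance is
$(\text{repeatability}-h^2)\sigma^2_P$ (0.4 g²) and the temporary,
per-time-step variance $(1-\text{repeatability})\sigma^2_P$ (0.6 g²). The
four $b$-component SDs of 0.015 make the total SD of $b$ equal to 0.03 —
60% of $|\bar b|$ — split equally over the genetic and environmental,
direct and indirect channels. `canonicalScenarios()` enumerates the 21
combinations of $\bar b$ with default, tripled and one-third values of
$\sigma_{AD}$, $\sigma_{AI}$ and $\sigma_{A_{GR}}$, one at a time.

## What the generator emulates — and what it does not

`simulateCohort()` produces one generation: 100 unrelated sires each mated
to 100 unrelated dams, every dam mated once, offspring receiving midparent
breeding values plus a Mendelian deviate, and a uniform random pairing of
the whole cohort into groups of two. Cohorts of $10^6$ offspring (100 per
dam) feed the variability analyses; $10^5$ (10 per dam) feed the trait
analyses. This is a deliberately idealized design — large, balanced,
pedigree-perfect and one generation deep — built to measure what the
estimation models *can* capture, not their power under realistic data. Real
populations add unbalancedness, deeper pedigrees with inbreeding, selection,
common-environment effects, group sizes above two, and measurement error;
none of these are emulated, so a model that works here need not work on
field data.

## Estimation models

All four models are intercept-only mixed models with one variance
component, fitted by REML.

* **Direct variability model** (`fitSireModel(..., "direct")`): the
  response for each of the 10,000 sire–dam families is the natural log of
  the unbiased sample variance of the family's final weights, treated as a
  trait of the sire. Predicted sire effects estimate the sire's
  contribution to the variability of its own offspring.
* **Indirect variability model** (`"indirect"`): the response is the log
  variance of the final weights of the family's *social partners* —
  the variability a family induces in its group mates.
* **Direct / indirect sire–dam trait models** (`fitParentModel()`):
  individual final weight linked via a sparse incidence matrix to its own
  parents (direct) or its partner's parents (indirect), with sires and dams
  pooled into one effect vector sharing a single variance.

Predicted effects are correlated (Pearson) with the simulated breeding
values: sire models against the sires' $(A_{GR}, A_D, A_I)$, sire–dam
models against the pooled sire-and-dam values. Because predictions
estimate *half* breeding values and Pearson correlations are
scale-invariant, the halving is immaterial to every reported number.

## Numerical choices

* **REML as a 1-D profile likelihood.** With a single variance ratio
  $\gamma = \sigma^2_u/\sigma^2_e$, the restricted likelihood is profiled
  in $\gamma$ (and analytically in $\mu$ and $\sigma^2_e$) and maximized by
  a bounded search over $\log\gamma \in [\log 10^{-10}, \log 10^{6}]$. All
  linear algebra runs on the $q \times q$ sparse system
  $Z'Z + I/\gamma$ with a cached symbolic Cholesky factorization, so the
  $10^5$-record sire–dam designs fit in seconds. On balanced one-way data
  the interior solution coincides with the ANOVA closed form
  $\hat\sigma^2_s = (MSB - MSW)/n$, which the tests assert, alongside a
  dense-matrix evaluation of the same criterion on small crossed designs.
* **Boundary estimates.** A maximizer at the lower end of the
  $\log\gamma$ interval is reported as $\hat\sigma^2_u = 0$ with all
  predictions zero, flagged as converged (it is the boundary REML
  solution, not a failure).
* **Logs and variances.** Natural log; unbiased ($n-1$) sample variance. A
  family with fewer than two offspring, or zero within-family variance, is
  an error rather than a silent drop. Correlations of a constant prediction
  vector are reported as missing.
* **Degenerate inputs.** Negative weights are possible in principle for
  extreme parameters; they are never clamped, only counted in
  `metadata(cohort)$nNegativeWeights` (zero throughout the canonical
  grid). Covariance matrices are factored by symmetric eigendecomposition
  with clipping of numerically negative eigenvalues, so positive
  *semi*-definite genetic correlation structures (e.g. all pairwise
  correlations −0.5) are valid inputs.
* **Seeding.** Each replicate uses one master seed; stage seeds (base
  population, offspring, pairing, growth noise) are derived from it by
  `deriveSeed()`, an integer mixing function, so every stage is
  independently reproducible and identical seeds give bit-identical
  cohorts.

## Design choices where the design was open

* **Mendelian sampling variance** is half the additive variance for all
  three traits, with off-diagonal covariances scaled by the same genetic
  correlation matrix — the standard infinitesimal-model result, applied
  uniformly.
* **The temporary environmental effect is redrawn at every time step.** A
  single lifetime draw would be statistically indistinguishable from the
  permanent effect and would contradict a repeatability of 0.7 being
  distinct from $h^2 = 0.5$. `Ep`, `E_D` and `E_I` are drawn once per
  individual.
* **Pairing is uniform over the whole cohort**; full sibs may meet. Both
  pair members are updated synchronously from the weights at $t-1$.
* **Environmental covariances** among `Ep`, `Et`, `E_D`, `E_I` are zero;
  genetic correlations among the three breeding values default to zero but
  are a free 3×3 input for correlated-breeding-value scenarios.
* **Aggregation over replicates** is the arithmetic mean of per-replicate
  correlations, with a standard error and (for transparency) the pooled
  correlation reported alongside. `runScenario()` defaults to 100
  replicates for variability purposes and 10 for trait purposes; the
  acceptance script uses 5 full-scale replicates per scenario, enough for a
  standard error of the mean around 0.005 on the strong correlations.
* **Problem sizes.** Tests exercise the full 100 × 100 × 100 design where
  the claim depends on it (the acceptance checks) and a labelled
  `"reduced"` preset (100 sires × 20 dams × 50 offspring) elsewhere; the
  reduced preset attenuates family-variance precision, so its correlations
  are expected to be somewhat weaker than full-scale ones.

## Known limitations

* Groups of two only; the record construction and the incidence matrices
  assume a single partner per individual.
* One generation; no selection, no evolution of $b$, no random-regression
  estimation of $b$ from time series.
* The two variability analyses use the data twice (each individual is
  focal in one family's direct record and partner in another's indirect
  record); the models are therefore fitted separately, as a two-step
  analysis, and a joint direct+indirect variability model is out of scope.
* Under the symmetric data-generating process, the direct and indirect
  variability records are mirror images of each other (exchange the roles
  of $A_D$ and $A_I$), so the two sire models are expected to perform
  near-symmetrically at matched signal sizes; the indirect record carries
  the larger baseline variance (partners span families), which slightly
  reduces its log-scale response to the same absolute signal.

## A minimal session

```{r example, eval = FALSE}
sc <- applyScale(canonicalScenarios("variability", ids = 1)[[1]], "reduced")
rpt <- runScenario(sc, nReplicates = 1, seed = 1)
reportSummary(rpt)
```

The full study — all 21 scenarios, both purposes, with artifacts and a
manifest on disk — is one call to `runStudy()` or one invocation of
`scripts/run_study.R`.
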