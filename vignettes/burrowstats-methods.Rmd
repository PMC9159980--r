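---
title: "Models and methods behind burrowstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind burrowstats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burrowstats)
```

## The scientific problem

African mole-rats (Bathyergidae) dig with their incisors (chisel-tooth
digging) or fore-claws (scratch-digging), and their limb bones carry discrete
superstructures tied to that lifestyle: a distally projected deltoid
tuberosity (DT) on the humerus, an enlarged olecranon process (OP) on the
ulna, a third trochanter (TT) on the femur, and a distal fusion of tibia and
fibula (DFTFi). The naked mole-rat (*Heterocephalus glaber*) is the outlier:
it lacks a projected DT and the tibio-fibular fusion.

`burrowstats` implements the two quantitative analyses such data call for:

1. **Allometric scaling.** Do continuous morpho-functional indices of these
   structures scale with body mass once species identity and phylogeny are
   accounted for? This is a Bayesian multilevel regression fitted at the
   individual level, compared by WAIC against a body-mass-free null.
2. **Ancestral states.** Were the discrete superstructures present in the
   ancestors of the group? This is stochastic character mapping under the Mk
   model, pooled over a posterior sample of phylogenies.

## Morpho-functional indices

All three indices are percent ratios of linear measurements (mm), so they are
dimensionless and scale-invariant:

* `RDT = (proximal end -> DT distance) / humerus length x 100`
* `IFA = olecranon length / (ulna length - olecranon length) x 100`
* `TJI = (proximal end -> tibio-fibular junction) / tibia length x 100`

IFA uses the *functional* ulna length (total minus olecranon) in the
denominator — the standard fossorial-ability construction. An absent
superstructure yields a missing value, never zero: zero is a meaningful
position on these scales, absence is not. That is why species lacking a
structure drop out of the corresponding regression (the naked mole-rat for
RDT and TJI) instead of distorting it.

`build_dataset()` takes natural logarithms of both index and body mass
(grams) and centers log body mass at the retained-rows mean. The log base is
a convention (it rescales coefficients, not model comparison); centering
decorrelates intercepts from slopes and gives the grand intercept a concrete
meaning — the expected log index at the study's average body mass.

## The varying-effects regression

For individual $i$ of species $s(i)$, with $y_i$ the log index and $x_i$
centered log body mass:

$$y_i \sim \mathrm{N}(\mu_i, \sigma), \qquad
\mu_i = (\bar\alpha + a^{phy}_{s(i)} + a^{sp}_{s(i)})
      + (\bar\beta + b^{phy}_{s(i)} + b^{sp}_{s(i)})\, x_i$$

Each species deviation splits into a **phylogenetic** part, multivariate
normal with correlation $R$ from the tree ($a^{phy} \sim
\mathrm{MVN}(0, \sigma^2_{a,phy} R)$, likewise for slopes), and an
**independent species** part ($a^{sp}_s \sim \mathrm{N}(0, \sigma_{a,sp})$).
$R_{ij}$ is the shared root-to-MRCA path length of species $i$ and $j$
divided by tree height — the trait correlation Brownian motion induces on an
ultrametric tree. Splitting the deviations this way is what lets the model
attribute between-species variance to phylogeny versus species-specific
ecology: `variance_shares()` reports
$\sigma^2_{a,phy}/(\sigma^2_{a,phy}+\sigma^2_{a,sp})$ per draw.

Trees are rescaled to unit height before computing $R$ (`to_unit_height()`),
so the variance parameters are in trait units rather than per-Ma and priors
are portable across trees dated in different units. Trees failing the
ultrametricity tolerance (1e-6 relative) are rejected, not silently
normalized, because the correlation derivation assumes ultrametry.

**Priors.** Weakly informative and centered on the standardized data: grand
intercept $\mathrm{N}(\bar y, 1)$; grand slope $\mathrm{N}(0, 1)$; residual
sd and all four component sds $\mathrm{Exponential}(1)$. On log-percent and
log-gram scales these are broad; they regularize the weakly identified
variance split without forcing it.

**Sampler.** Posterior draws come from a blocked Gibbs sampler (compiled
core) on the non-centered parameterization, effects = sd x Cholesky($R$) x
standard normals:

* all location parameters (grand terms plus every standard-normal latent)
  are jointly Gaussian given the scales and are drawn exactly from that
  conditional;
* each component sd enters the mean linearly under non-centering, so its
  conditional is a zero-truncated normal — drawn exactly;
* the residual sd is updated by slice sampling on the log scale;
* an interweaving step then re-draws each component sd conditional on the
  *centered* effects (rescaling the latents to keep the effects fixed).
  Without it, scales and latents are each tight given the other and the
  chain creeps along that ridge; the interweaved chain mixes with split
  R-hat $\approx$ 1.00 on all parameters.

No gradient-based sampler is involved: every conditional here is either
exact or a one-dimensional slice update, which is both correct and fast for
this conditionally conjugate structure. Defaults mirror standard practice
for this model class: 4 chains, 5000 iterations, 50% warm-up, a fixed seed
recorded in the output. Convergence is assessed by split-chain R-hat
(flagged above 1.05) and effective sample size, computed for every
parameter.

**Model comparison.** `compute_waic()` uses the pointwise log-likelihood
matrix: $\mathrm{lppd} = \sum_i \log \mathrm{mean}_d\, p(y_i\mid d)$,
$p_{\mathrm{WAIC}} = \sum_i \mathrm{var}_d \log p(y_i \mid d)$, WAIC
$= -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$. `compare_models()` reports
$\Delta$WAIC together with its pointwise standard error
$\sqrt{n\,\mathrm{var}(\Delta_i)}$; a $\Delta$WAIC comparable to its SE is
weak evidence, whatever its sign.

## Mk model and stochastic character mapping

Binary superstructure states evolve as a continuous-time Markov chain with
generator $Q$. The likelihood of tip states is computed by Felsenstein's
postorder pruning with per-branch transition matrices $e^{Qt}$ (closed form
for two states; eigendecomposition otherwise). `fit_mk()` maximizes it —
a bounded 1-D search on the log rate for the equal-rates (ER) model
(bracket $[10^{-8}, 100]$ per unit height, tolerance 1e-8), 2-D for binary
all-rates-different. A constant character has its optimum at the rate
boundary; it is flagged and, in the pipeline, skipped — with every taxon
sharing one state there is nothing to reconstruct (the OP character is the
bundled example).

`marginal_node_posteriors()` computes the *exact* marginal posterior of
every internal node state by combined postorder/preorder message passing.
It exists both as a user-facing result and as the analytic oracle against
which the stochastic mapping sampler is validated.

`sample_character_histories()` draws full histories: root state from its
marginal posterior, node states preorder proportional to transition
probability times the child's partial likelihood, and each branch filled
with a CTMC path conditioned on its endpoints. Paths use rejection sampling
(with the first jump forced when the endpoints differ), capped at 10,000
attempts per branch, after which an exact uniformization sampler takes over;
endpoint consistency is guaranteed by construction.

`summarize_node_pp()` pools maps over a tree sample: per tree, $Q$ is
re-estimated by maximum likelihood (the empirical variant of the method) and
a fixed number of maps drawn; node states are pooled **by clade key** — the
sorted tip set a node subtends — because topologies differ across a
posterior sample and node indices do not travel between trees. Posterior
probability is pooled frequency; the fraction of trees containing each clade
is reported alongside, and probabilities for a clade average only over the
trees that contain it. The default number of maps per tree makes the total
1000 (one per tree for a 1000-tree sample).

Choices the method leaves open, and our defaults: ER rather than ARD (the
standard default for binary presence/absence; ARD is available), a uniform
root prior (stationary available), and per-tree ML estimation of $Q$ rather
than integrating over rate uncertainty — posterior sampling of $Q$ is out of
scope. Deep-node probabilities can shift by several points under these
choices; with very few observed transitions the ML rate is small and deep
nodes are pulled toward the majority tip state, while methods that average
over substantial rate uncertainty report more equivocal deep nodes.

## What the synthetic generators emulate

Every testable claim in the package is validated against data whose truth is
known, produced by seeded generators that mirror the two models exactly:

* `simulate_yule_tree()`: pure-birth ultrametric trees rescaled to unit
  height. Only the Brownian correlation structure matters downstream, so no
  attempt is made to mimic empirical node ages.
* `simulate_varying_effects()` / `simulate_measurements()`: species
  intercepts and slopes with exactly the phylogenetic-plus-independent
  covariance of the regression, then individuals normal around their species
  line in log-log space.
* `simulate_mk_character()`: forward CTMC simulation with the full event
  history retained as ground truth.
* `simulate_molerat_study()`: the study-shaped configuration — eight species
  with the published mean body masses, per-species counts chosen so the
  ulna dataset has 247 individuals and the humerus/tibia datasets 151 after
  the naked-mole-rat exclusion, weak scaling
  ($\bar\beta = 0.1$), between-species variability dominated by the
  species-specific component ($\sigma_{a,sp} = 0.2$ vs $\sigma_{a,phy} =
  0.05$), residual sd 0.1, and within-species log-body-mass sd 0.2 (a
  sample spanning ontogenetic stages varies more than an adults-only one).

`molerat_reference_tree()` and `molerat_reference_tree_sample()` are
**synthetic stand-ins** for a published time-calibrated phylogeny and its
posterior sample: accepted topology, the two published divergence dates
(29.02 Ma for *Heterocephalus*, 13.37 Ma for *Heliophobius*), plausible
round ages elsewhere, and lognormal node-age jitter (cv 0.1) for the sample.
They reproduce the *kind* of input the analysis consumes — they are not a
substitute for real posterior trees, whose topological variation and
branch-length spread they understate. Consequently, passing tests show the
machinery is correct and the qualitative findings are reproducible; node
probabilities at deep nodes remain input-dependent.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance 1e-6 relative; correlation matrices are
  symmetrized and checked PSD (eigenvalues >= -1e-8 tolerated, Cholesky with
  eigendecomposition fallback).
* Partial likelihoods are renormalized per edge with the log scale
  accumulated, so long ladders cannot underflow.
* Impossible data under a zero-rate generator return `-Inf` with an
  `impossible` flag rather than an error from `log(0)`.
* Ties in state sampling are resolved by inverse-CDF on the fixed state
  order; all randomness flows from user-supplied seeds through deterministic
  per-stage subseeds (`spawn_seed()`), so whole pipelines are bit-for-bit
  reproducible from one integer.
* Draws where both variance components are exactly zero are skipped (and
  counted) in `variance_shares()` — the share is undefined there.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to make Monte-Carlo
tolerances meaningful while keeping a full run fast on one CPU: 200 random
small-tree instances against the exhaustive-enumeration likelihood oracle;
10,000 stochastic maps against the exact marginals on a 5-taxon tree; 100
replicate regressions (8 species x 30 individuals, 4 chains x 1000
iterations) for interval coverage and WAIC detection of a true slope of 0.3;
100 replicates of 32 species x 10 individuals for variance attribution under
zero generating phylogenetic variance — attribution needs many species
because separating the tree correlation from independent species effects is
exactly the contrast that eight species barely inform, whereas interval
coverage does not (the sampler's posterior was additionally cross-checked
against an independent MCMC engine on a reference dataset); and
1000 pooled maps over a 200-tree sample for the ancestral reconstructions.
`scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* The regression assumes a strictly ultrametric, time-calibrated tree; no
  within-species phylogenetic structure, no measurement-error model on
  species means (deliberately: the model works at the individual level).
* ARD fitting is implemented for binary characters only; multistate
  characters are fitted under ER.
* Rate uncertainty in the character mapping is not propagated (per-tree ML
  $Q$); deep-node posterior probabilities are accordingly sharper than a
  fully Bayesian treatment would give.
* With eight species, the split of between-species variance into
  phylogenetic and independent parts is weakly identified; the priors keep
  it proper, and conclusions should rest on the reported intervals, not
  point estimates.
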