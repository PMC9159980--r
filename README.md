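# burrowstats

Phylogenetic comparative analysis of limb-bone morphometrics in fossorial
rodents, built around the African mole-rats (Bathyergidae) and their closest
relatives.

Subterranean rodents dig either with their fore-claws (scratch-digging) or
their incisors (chisel-tooth digging), and their limb bones carry discrete
superstructures tied to that lifestyle: a distally projected deltoid
tuberosity (DT) on the humerus, an enlarged olecranon process (OP) on the
ulna, a third trochanter (TT) on the femur, and a distal tibio-fibular fusion
(DFTFi). `burrowstats` answers two questions about such data:

1. **Do the continuous indices of these structures scale with body mass?**
   Via a Bayesian multilevel regression fitted at the individual level, with
   species-varying intercepts and slopes split into a phylogenetic and an
   independent species component, compared by WAIC against a body-mass-free
   null:

   $$y_i \sim \mathrm{N}(\mu_i,\ \sigma), \qquad
     \mu_i = (\bar\alpha + a^{phy}_{s(i)} + a^{sp}_{s(i)}) +
             (\bar\beta + b^{phy}_{s(i)} + b^{sp}_{s(i)})\,x_i,$$

   where $y$ is a log morpho-functional index (RDT, IFA or TJI), $x$ centered
   log body mass, $a^{phy} \sim \mathrm{MVN}(0, \sigma^2_{a,phy}R)$ with $R$
   the Brownian-motion correlation of the tree, and $a^{sp}_s \sim
   \mathrm{N}(0, \sigma_{a,sp})$ (slopes analogous).

2. **Were the discrete structures present in the group's ancestors?** Via
   stochastic character mapping under the Mk model: Felsenstein-pruning
   likelihood, per-tree maximum-likelihood rates, exact marginal node
   posteriors, endpoint-conditioned character histories, and node posterior
   probabilities pooled by clade over a posterior sample of trees.

Both stages are backed by seeded synthetic-data generators with exactly the
statistical structure the models assume, so every claim is testable against
known truth. Tabular results come back as tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`; trees are `ape::phylo` objects.

## Worked example

```r
library(burrowstats)

# a study-calibrated synthetic dataset: 8 mole-rat species, 247 ulnae
rec <- simulate_molerat_study("IFA", seed = 42)
ds  <- build_dataset(rec, "IFA", molerat_reference_tree())
ds
#> <regression_dataset> index IFA: 247 individuals, 8 species
#>   centering constant (mean log body mass, g): 4.69445

fit_bm <- fit_varying_effects(ds, include_bm = TRUE,  iter = 2000, seed = 1)
fit_0  <- fit_varying_effects(ds, include_bm = FALSE, iter = 2000, seed = 2)
posterior_summary(fit_bm, pars = c("alpha_bar", "beta_bar", "sigma"))
#>   term      estimate std.error conf.low conf.high  rhat   ess converged
#> 1 alpha_bar   3.08     0.128    2.91        3.28   1.00 2761. TRUE
#> 2 beta_bar    0.126    0.0842   0.00552     0.249  1.00 3845. TRUE
#> 3 sigma       0.0976   0.00438  0.0909      0.105  1.00 3166. TRUE

compare_models(fit_bm, fit_0, labels = c("with_bm", "without_bm"))
#>   preferred delta_waic delta_se waic_full waic_reduced     n
#> 1 with_bm         2.69     7.53     -436.        -433.   247

variance_shares(fit_bm)
#>   component phylo_share conf.low conf.high n_skipped
#> 1 intercept       0.490  0.00693     0.989         0
#> 2 slope           0.566  0.0121      0.994         0
```

Read: the grand intercept 3.08 is the expected log IFA (so `exp(3.08)` ≈ 22%
relative olecranon length) at the study's mean body mass; the slope of log
IFA on log body mass is weakly positive (0.126, 89% interval barely above
zero); the body-mass model is preferred by WAIC, but the difference (2.7) is
smaller than its pointwise standard error (7.5) — weak evidence, and the
between-species variance splits roughly evenly (and very uncertainly)
between phylogeny and species-specific effects. `autoplot(fit_bm)` draws the
log-log scatter with the population line and its 89% compatibility band.

Ancestral states of the tibio-fibular fusion, pooled over a posterior-like
sample of 200 trees with 5 maps each (1000 maps total):

```r
pp <- summarize_node_pp(molerat_reference_tree_sample(200, seed = 3),
                        tip_state_vector(molerat_tip_states(), "DFTFi"),
                        n_maps_per_tree = 5, seed = 4)
clade_pp(pp, c("Ha", "Bs", "Bj", "Gc", "Ch", "Fd", "Fm"), "present")
#> [1] 0.984
```

The fusion is reconstructed as present (PP 0.98) in the common ancestor of
*Heliophobius* and the derived bathyergids, with only the naked mole-rat
lacking it inside the family. `molerat_tip_states()` carries the observed
codings of all four superstructures across the 11 study taxa;
`molerat_reference_tree()` is a synthetic, code-built stand-in for a
time-calibrated consensus tree (see its help page).

End-to-end, config-driven runs (YAML in, CSVs out) are available through
`simulate_study()`, `run_regression_pipeline()` and `run_asr_pipeline()`.

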