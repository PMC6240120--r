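# frugicue

Do fruit colours tell frugivorous birds anything about what is inside the
fruit — and do birds use that information to regulate their nutrient intake?
`frugicue` is an R package for answering this question at the scale of whole
plant–frugivore networks. It is aimed at community ecologists working with
seasonal interaction data (visitation rates of birds on fleshy-fruited
plants), fruit reflectance spectra, fruit trait tables and dated phylogenies.

The package covers the full analysis chain:

1. **Avian colour space** (`make_receptors`, `quantum_catches`, `to_tetra`,
   `brightness`, `spectra_to_colours`). Reflectance spectra (300–700 nm,
   5-nm grid) are converted to quantum catches of the four avian single
   cones, mapped into the tetrahedral colour space (chromatic coordinates
   *x*, *y*, *z*; equal stimulation at the origin; chromaticity bounded by
   the 0.75 circumradius), and to double-cone brightness *a* normalized by a
   perfect reflector.
2. **Seasonal networks and diet profiles** (`build_networks`,
   `partner_diversity`, `interaction_strength`, `diet_colour_profile`,
   `diet_nutrient_intake`, `frugivore_roles`). Consumption rates
   f<sub>ij</sub> (fruits/h) are built from visitation × per-visit
   consumption with a three-step imputation ladder for missing per-visit
   rates. Diet profiles are interaction-weighted means,
   c̄<sub>j</sub> = Σ c<sub>i</sub> f<sub>ij</sub> / Σ f<sub>ij</sub> and
   n̄<sub>j</sub> = Σ n<sub>i</sub> m<sub>i</sub> f<sub>ij</sub> /
   Σ m<sub>i</sub> f<sub>ij</sub> (per gram dry pulp).
3. **Bayesian hierarchical engine** (`fit_bhm`, `shrinkage_summary`,
   `bayes_factor`, `r_squared`, `bhm_diagnostics`). A purpose-built Gibbs
   sampler for y = α + Xθ + ζ + ε with θ<sub>j</sub> = I<sub>j</sub>β<sub>j</sub>
   (Kuo–Mallick indicator selection, prior inclusion 0.5, shared slope
   variance σ²<sub>β</sub> ~ U(0, 100) — "global adaptation"), phylogenetic
   (cov σ²<sub>a</sub>C from `correlation_from_tree`), species, site and
   season random effects, data augmentation for missing responses, 2·ln
   Bayes factors with finite-draw bounds (the "> 15" convention), shrinkage
   estimates, marginal/conditional r², split-R̂ and effective sample size.
4. **The three-sub-model pipeline** (`run_submodel1`, `run_submodel2`,
   `run_submodel3`, `marginal_selection`, `concordance`, `run_pipeline`):
   pulp-mass imputation from fruit diameter; colour–reward regressions of
   log nutrient contents on (x, y, z, a); an eight-equation structural
   equation model of fruit choice (colour profiles and nutrient intakes on
   partner diversity, interaction strength and seasonally coded migratory
   distance); and the concordance analysis relating which colour components
   indicate rewards to which mediate fruit choice.
5. **Synthetic data with known truth** (`sim_tree`, `sim_plant_traits`,
   `sim_frugivores`, `sim_networks`, `sim_sem_data`, `sim_spectra`,
   `sim_study`), emulating the study conditions (44 plants, 43 birds, 3
   sites, 4 seasons; brightness–nutrient couplings at r² ≈ 0.11–0.35;
   planted fruit-choice preferences) so every stage can be validated.

## Worked example

```r
library(frugicue)

sim <- sim_sem_data(seed = 1)            # 160 obs, planted paths at known truth
sem <- run_submodel3(sim$roles, sim$tree, mode = "main",
                     config = mcmc_config(chains = 4, iterations = 4000,
                                          burnin = 500, thin = 20, seed = 8))
subset(sem$paths, response == "a" & term == "partner_diversity")
#>     response              term estimate ci_lower ci_upper P     bf     bf_flag supported
#> a.1        a partner_diversity 0.463679 0.338702 0.583421 1 14.487 lower_bound      TRUE
```

The planted partner-diversity → diet-brightness path (+0.4 before response
standardization, ≈ +0.46 on the standardized scale of this replicate) is
recovered with inclusion probability 1 and a Bayes factor reported as the
finite-draw bound (700 retained draws → 2·ln((700−0.5)/0.5) ≈ 14.5),
i.e. decisive support. `marginal_selection(sem)` then gives the mean
inclusion probability of each colour component, and
`concordance(marginal_selection(colour_reward_fit), sem)` the logistic fit
linking cue reliability to cue use.

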