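# lidarflora

Bayesian models linking airborne-lidar forest structure to understory
plant abundance and richness.

Understory vegetation responds to canopy structure — height, layering,
gaps, cover — because structure controls the light and microclimate at
the forest floor. Airborne laser scanning (ALS) measures that structure in
three dimensions over whole landscapes, including quantities that are
impractical to record in the field. `lidarflora` is for ecologists and
biostatisticians who want to test, plot network by plot network, whether
ALS structure variables improve plot-level biodiversity models, when lidar
covers only part of the network.

The package implements the full chain:

- **Structure metrics.** Ten plot-level variables from normalized point
  clouds and 1 m canopy height models at any extraction radius:
  H_max, H_median, H_mean, σ²_H (population variance above 2 m), the Gini
  coefficient of canopy heights G = Σ(2i−n−1)z₍ᵢ₎ / (Σz·(n−1)), the
  coefficient of variation of the leaf area density profile (MacArthur–Horn
  transmittance inverted by Beer–Lambert, LAD = −ln(P_enr)/(k·dz), k = 0.5),
  maximum gap area (8-connected CHM cells ≤ 2 m), cover fraction C_f,
  attenuation rate C_r = n(z>2)/n, and canopy volume.
- **Models.** A shared linear predictor η over seven abiotic covariates
  (restricted cubic splines on standardized soil, climate and topography
  terms, a capped slope–aspect interaction sin(min(Slope, π/4))·cos(Aspect))
  plus one standardized structure indicator with coefficient ξ₁₈. Richness
  counts follow a family indexed by mean e^η and index of dispersion ω
  (Poisson / negative binomial / an exact-moment underdispersed binomial
  mixture); Braun-Blanquet cover classes 0–5 follow a zero-inflated
  cumulative beta model whose *global* latent mean is logit⁻¹(η).
- **Two-step fitting.** Step 1 estimates all parameters on the full plot
  network with field-measured crown cover as the indicator; step 2 refits
  on the lidar-covered subset with each ALS variable in turn, sampling only
  the intercept, ξ₁₈ and the nuisance parameters over a fixed abiotic
  offset at the step-1 posterior means.
- **Sampling.** An adaptive MCMC combining component-wise
  Metropolis-within-Gibbs (acceptance target 0.44, diminishing
  adaptation), differential-evolution proposals with variable crossover,
  and equi-energy exchanges between heated trajectories; convergence at
  split Rhat ≤ 1.007; draws thinned to a 0.01 successive-state
  correlation.
- **Assessment.** Mode-based DIC differences (ΔDIC, lower = better),
  empirical two-tailed significance (** / * / ns), and equivalence
  classification of the per-sd effect β·sd against negligibility bounds
  (0.1/0.2 richness, 0.25/0.5 abundance), combined into six effect
  classes with per-site, per-variable and per-radius count tables.
- **Synthetic data.** Two-site plot networks (789 plots / 48 lidar-covered
  at 9 m; 1155 / 171 at 15 m) with realistic covariate distributions,
  simulated forest point clouds (half-ellipsoid crowns, Poisson stems and
  pulses, forced gaps) and responses drawn from the model's own
  likelihoods with recorded ground truth.

## Worked example

Simulate a reduced study (300 plots, 60 lidar-covered), compute ALS
metrics, fit both steps, and test the ALS cover fraction against
heliophilous species richness:

```r
library(lidarflora)

ds  <- make_dataset("reduced", seed = 42, n_plots = 300, n_covered = 60,
                    responses = "richness")
met <- extract_dataset_metrics(ds)

resp <- response_spec("richness", "richness_helio")
cfg  <- sampler_config(n_trajectories = 3, n_tempered = 0,
                       max_iterations = 5000, n_posterior_draws = 400,
                       max_thin = 8, max_collect = 1600, min_adapt = 800,
                       check_every = 400, archive_every = 5, seed = 7)

s1  <- fit_step1(ds, resp, cfg)
sub <- dplyr::left_join(dplyr::filter(ds$plots, als_covered), met,
                        by = "plot_id")
run <- fit_step2(sub, resp, "c_f", s1, cfg)
run
```

```
<lf_run> richness_helio ~ c_f (radius NA): DIC 385.48 (ref 410.74, delta -25.26)
  effect 0.641 +/- 0.121, p = 0.000 -> Significant: Positive non-negligible
```

Reading this: adding the ALS cover fraction lowers the mode-based DIC by
25.3 relative to the same model without it, so it clearly improves the
richness model; the posterior of the per-sd effect is 0.64 ± 0.12 on the
log-richness scale, every draw is positive (empirical p = 0, `**`), and
more than 95 % of the effect mass lies above the wide negligibility bound
0.2, so the run classifies as `Significant: Positive non-negligible`. The
estimate sits below the generative per-sd effect (1.0 on the true
structure variable `c_tot`) because `c_f` is a correlated but noisy proxy
of it — exactly the attenuation a field study would see. `tidy(run)`,
`glance(run)` and `tidy(s1)` return the same information as tibbles, and
`run_all()` iterates the full response × variable × radius grid, feeding
`count_tables()` and the plotting helpers (`plot_delta_dic()`,
`plot_effect_counts()`, `autoplot()` on draws and canopy grids).

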