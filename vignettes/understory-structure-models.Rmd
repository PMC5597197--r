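---
title: "Linking airborne-lidar forest structure to understory plant abundance and richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking airborne-lidar forest structure to understory plant abundance and richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidarflora)
```

## The modelling problem

Understory plant communities respond to the structure of the canopy above
them — its height, vertical layering, gaps and cover — because structure
controls light, microclimate and litter input. Airborne laser scanning
(ALS) measures that structure directly in three dimensions, including
quantities that are impractical to record in the field (maximum gap size,
attenuation of returns through the canopy, canopy volume). `lidarflora`
implements a complete chain for asking whether ALS-derived structure
variables improve plot-level Bayesian models of floristic biodiversity:

1. compute ten forest-structure variables from normalized point clouds at
   one or more extraction radii around each field plot;
2. fit Bayesian models of species abundance (ordinal Braun-Blanquet cover
   classes) and ecological-group species richness (counts) on abiotic
   covariates plus one structure indicator, with a two-step scheme that
   copes with lidar covering only a fraction of the plot network;
3. assess each candidate structure variable by the change in a mode-based
   deviance information criterion, an empirical two-tailed significance
   test and a Bayesian equivalence (negligibility) classification.

A synthetic-data module generates two-site plot networks and forest point
clouds with known ground truth, so the whole chain is testable without any
proprietary survey data.

## Forest-structure variables

For a disc around a plot centre the package computes, from all normalized
returns: the maximum height `h_max`; the median height `h_median` over
*all* points including ground returns; and, over canopy points only
(strictly above the 2 m understory threshold): the mean height `h_mean`,
the *population* variance `var_h` (the divisor is `n`, matching the
variable's printed definition), and the Gini coefficient of heights

$$G = \frac{\sum_i (2i - n - 1)\, z_{(i)}}{\sum_i z_i \,(n-1)},$$

with the `(n - 1)` denominator (a single canopy point therefore returns
`NA` rather than a spurious value). `G` is exactly 0 for equal heights and
exactly 1 when all height mass sits on one point.

Vertical structure is further summarized by the coefficient of variation of
the leaf area density profile. Transmittance per 1 m layer is estimated
MacArthur–Horn style from cumulative return counts — the fraction of pulses
reaching below a layer's bottom among those reaching below its top — and
inverted with the Beer–Lambert law, $LAD = -\ln(P_{enr})/(k\,dz)$ with
extinction coefficient $k = 0.5$. Layers that intercept every pulse have
zero transmittance; their LAD is capped (default 10 m²/m³) rather than
infinite.

Horizontal structure comes from a 1 m canopy height model (per-cell
maximum height, empty cells 0, negative values clamped): `gap_max` is the
area of the largest 8-connected component of cells at or below 2 m among
cells whose *centre* falls inside the query disc; `c_f` is the fraction of
those cells above 2 m; `vol_can` is the sum of cell heights. The
point-based attenuation rate `c_r` (share of returns above 2 m) captures
sub-metre openings that the 1 m raster cannot.

Conventions worth knowing: a point at exactly 2 m counts as understory
(the canopy threshold is strict); discs use centre-in-cell inclusion for
raster cells and squared-distance inclusion for points; discs with fewer
than 10 returns produce a flagged all-`NA` row.

## The linear predictor

Every model shares one linear predictor over seven abiotic covariates plus
one structure indicator:

$$\eta_i = \xi_0 + \sum_{v} \sum_{c=1}^{3} \xi_{v,c}\, v_{c,i}
 + \xi_{16}\,TTS0_i + \xi_{17}\sin(\min(Slope_i, \pi/4))\cos(Aspect_i)
 + \xi_{18}\, I_i,$$

where each of soil reaction, soil water capacity, mean temperature and
solar radiation enters through the three components of a restricted cubic
spline with four knots, applied to the standardized covariate (knots at
the 0.05/0.35/0.65/0.95 quantiles of the training data — the conventional
default for four-knot restricted splines). The topographic situation code
TTS (0–9, with the flat codes 0/6/8 merged into 0) enters numerically
through a spline with fixed knots 2.5/4.5/5.5/7, masked by `(1 - TTS0)`,
plus the flat-terrain indicator `TTS0`. Slope arrives in percent and is
converted to an angle via `atan(slope/100)` and capped at π/4; aspect
arrives in grades (400 per circle) and is converted to radians — both
conversions are needed because the slope–aspect term takes a sine and a
cosine. The indicator $I$ (total crown cover `c_tot`, or an ALS variable)
is standardized, so $\xi_{18}$ is directly the effect of a one-standard-
deviation increase in structure.

## Response families

**Richness** counts use a family indexed by its mean $\mu = e^\eta$ and its
index of dispersion $\omega$ (variance/mean): Poisson at $\omega = 1$,
negative binomial with variance $\omega\mu$ for $\omega > 1$, and, for
under-dispersion ($\omega < 1$), an equal-mean mixture of two adjacent
binomials, $w\,\mathrm{Bin}(n_0, \mu/n_0) + (1-w)\,\mathrm{Bin}(n_0+1,
\mu/(n_0+1))$ with $n_0 = \lfloor \mu/(1-\omega)\rfloor$ and $w$ solving
the dispersion constraint. Both the mean and the index of dispersion are
then matched *exactly* wherever the pair $(\mu, \omega)$ is attainable by
an integer-valued variable ($n_0 \ge \max(\mu, 1)$); outside that region
the likelihood is $-\infty$ and simulation refuses. Among the several
mixture families in the ecology literature that bridge under- and
over-dispersed counts, this construction was chosen because it is in
closed form and moment-exact, which is what the validation suite
measures.

**Abundance** is observed as Braun-Blanquet classes 0–5 with cut points at
5/25/50/75 % cover. The latent plot cover $C$ is zero with probability
$\pi_0$ and otherwise beta-distributed with precision $\phi$; the *global*
mean $(1-\pi_0)\mu_\beta$ equals $\mathrm{logit}^{-1}(\eta)$, honouring
the statement that $\eta$ models the logit of the global latent mean.
$\mu_\beta$ is clamped to $[10^{-6}, 1-10^{-6}]$; a global mean at or
above $1-\pi_0$ is infeasible and yields $-\infty$ (the sampler simply
rejects such proposals). $\pi_0$ is a free intercept-only parameter.

Priors are weakly informative Normal(0, sd 2) on every coefficient and on
the nuisance transforms $\log\omega$, $\log\phi$, $\mathrm{logit}\,\pi_0$.

## Two-step fitting

Lidar covers only part of each plot network, so abiotic effects are
estimated where the data are: step 1 fits the full model (all 19
coefficients plus nuisance) on *every* plot of a site with field-measured
total crown cover as the indicator. Step 2 refits on the lidar-covered
subset with the indicator replaced, in turn, by each ALS variable at each
extraction radius; only the intercept, the indicator coefficient and the
nuisance parameters are sampled, while the abiotic contribution enters as
a fixed per-plot offset evaluated at the step-1 posterior *means* (a
deliberate simplification — propagating the full step-1 posterior would
mean integrating it inside every step-2 likelihood call). By default all
17 abiotic terms are held in the offset; `offset_terms = "reaction_swc"`
restricts it to the soil terms for users who prefer a sparser second
step. The reference model for the DIC difference
is the same step-2 model without the indicator, refit on the *same*
subset, so the two DICs are comparable.

Per-run sampler seeds are derived by hashing the run labels with the
master seed, so a grid of hundreds of runs is reproducible and each run
has an independent stream.

## The sampler

The posterior is explored by a population of trajectories (default 17,
read as 13 at temperature 1 plus 4 heated at 2/4/8/16). Each iteration
every trajectory receives:

- a component-wise Metropolis-within-Gibbs sweep (Gaussian random walk per
  coordinate, tempered acceptance), with per-coordinate proposal scales
  adapted towards the scalar-update optimum 0.44 by multiplicative steps
  that decay as `iteration^-0.66` — the diminishing-adaptation condition;
- a differential-evolution proposal: `gamma * (a - b)` on a
  crossover-selected coordinate subset (crossover drawn from 1/3, 2/3, 1),
  with `gamma = 2.38/sqrt(2d)` most of the time and the mode-jumping
  `gamma = 1` with probability 0.1. Difference pairs are drawn from a
  thinned archive of past states once available, so even a 3-trajectory
  configuration can move along correlated posterior directions;
- periodically, equi-energy exchanges: states of trajectories at different
  temperatures may swap only if their log-posteriors fall in the same
  energy ring (five quantile bands of recent cold-chain log-posteriors,
  refreshed every 1000 iterations), accepted with the tempering exchange
  ratio.

Convergence is declared when the split Gelman-Rubin Rhat of every
parameter across the cold trajectories is at or below 1.007 — deliberately
far stricter than the textbook 1.1–1.2. Adaptation then stops, draws are
collected from the cold trajectories, and a thinning lag is chosen so the
mean absolute successive-state correlation of the retained draws is at or
below 0.01 (floored by the autocorrelation estimator's own noise level on
the pilot window, about `1/sqrt(window)`), until the configured number of
posterior draws (default 2000) is retained. If the iteration budget runs
out first, the second half of the history is used and the result is
flagged unconverged.

One implementation choice deserves emphasis: restricted-spline design
columns are strongly collinear, and a component-wise kernel mixes poorly
along the resulting posterior ridges. The model-fitting wrappers therefore
sample on a QR-orthogonalized coefficient basis — the likelihood sees the
orthogonal columns, the Normal priors are applied to the original
coefficients through the back-transform, and draws are returned on the
original scale. The posterior is unchanged; only the chain's geometry
improves. The likelihood kernels and the Gibbs sweep run in compiled code
(the proposals use R's RNG, so runs remain bit-reproducible given a seed).

## Model assessment

Each run is scored three ways.

- **Mode-based DIC**: $DIC = 2\overline{D(\theta)} - D(\hat\theta)$ with
  deviance $D = -2\log L$ and the plug-in $\hat\theta$ the sampled draw
  with highest posterior density. `delta_dic` is the difference between
  the models with and without the ALS variable; lower is better.
- **Empirical significance**: $p = 2\min(\#\{\beta>0\},
  \#\{\beta<0\})/n$ over the posterior draws (exact zeros split evenly);
  `**` for $p \le 0.01$, `*` for $p \le 0.05$, `ns` otherwise.
- **Negligibility**: the per-sd effect $e = \beta \cdot sd$ is classified
  against equivalence bounds $b_1/b_2$ (0.1/0.2 for richness on the log
  scale, 0.25/0.5 for abundance on the logit scale): `00`/`0` when $e$
  lies within the narrow/wide interval with posterior probability above
  0.95 (strict), `--`/`-`/`+`/`++` for directional effects beyond the
  bounds with probability at least 0.95 (inclusive), `no-info` otherwise,
  with the stronger claims tested first. Significance and symbol combine
  into six summary classes; non-significant runs only distinguish
  Negligible from No info. No multiple-comparison correction is applied:
  the assessment screens many individually interpreted runs for overall
  trends rather than testing one family-wise hypothesis.
  `count_tables()` emits
  the per-site, per-variable and per-radius tallies (and DIC-difference
  summaries) from which any downstream comparison — e.g. a binomial GLM of
  counts on radius — can be run with standard tools.

## The synthetic-data generator

The generator defines the study conditions and is deliberately fixed:

- **Plot networks.** The lowland profile has 789 plots with 48
  lidar-covered at 9 m radius (the remainder at 15 m); the mountain
  profile 1155 plots with 171 covered at 15 m; a reduced profile (200/50)
  serves simulation studies.
- **Abiotic covariates** are drawn independently per plot from truncated
  normal distributions matching each site profile's nominal mean, spread
  and range. The underlying location is calibrated by root-finding so the
  *truncated* mean equals the target mean (a plain truncated normal at the
  printed location can miss the printed mean by more than its Monte-Carlo
  error when the range is asymmetric); the printed spread is used as the
  underlying scale, so the realized spread is slightly smaller. TTS is
  uniform over its categories with the three flat codes merged, giving
  code 0 probability 3/10.
- **Point clouds.** Trees at Poisson locations with half-ellipsoid crowns
  (flat base at half tree height, gamma-distributed crown radii); pulses
  at Poisson intensity matching the survey's pulse density; under a crown,
  30 % of pulses reach the ground (so the attenuation rate is
  non-trivial), the rest return uniformly between crown base and crown
  surface of the tallest intercepting crown. Forced gap discs suppress
  canopy returns. Stem density scales with the plot's field cover `c_tot`,
  so ALS cover metrics correlate with the generative structure variable.
- **Responses** are drawn from the package's own likelihoods with fixed
  true coefficients: richness intercepts matched to the reported group
  means (about 0.5 shade-tolerant, 2.5 intermediate and 5.3 heliophilous
  species per plot) with mild overdispersion (1.2/1.5/2.0), abundance
  intercepts graded over the eight species on the logit-cover scale with
  `phi = 4`, `pi0 = 0.15`, and moderate abiotic effects (0.05–0.3 per
  spline component). The per-sd indicator effect is the single free knob
  (`default_true_models(effect = )`), because effect recovery is what the
  validation studies measure.

What the generator does *not* emulate: spatial autocorrelation between
plots (the fitted model treats plots as independent), terrain (the
synthetic ground is flat, so height normalization is exercised by separate
analytic fixtures), species co-occurrence, waveform or intensity
information, and any real survey's noise structure. Passing recovery tests
therefore show that the chain estimates what it claims to estimate under
the model's own assumptions — not that those assumptions hold in any
particular forest.

## Validation studies and problem sizes

The test suite runs, among others: exact analytic limits of the Gini
coefficient; equality of all ten structure metrics with brute-force
recomputation on 1000 random mini-clouds (tolerance 1e-9); exact
normalization and moment recovery of both likelihoods over a 100-point
parameter grid (tolerance 1e-6); sampler correctness on a correlated
Gaussian (moments), a 5-state discrete target (total variation at or below
0.01 over 10^6 steps) and the 2000-draw/Rhat-1.007 output contract; and
two-step recovery studies at 800 plots with 200 lidar-covered, 20
replicates per arm, using reduced sampler settings (3 cold trajectories, a
5000-iteration budget, 400 retained draws) — recovering a true per-sd
effect of 1.0 within ±0.3 with 95 % interval coverage, centring on 0 under
a null effect, and producing negative DIC differences under the strong
effect. `scripts/acceptance.R` recomputes the same quantities from scratch
at 6 replicates per arm and 200 oracle clouds; sizes are the package's
choice of a desk-scale validation.

## Known limitations

- The under-dispersed count construction has a feasibility boundary
  (`floor(mu/(1-omega)) >= max(mu, 1)`); fits whose chains wander towards
  strong under-dispersion at small means reject those proposals, which is
  correct but can slow mixing there.
- Step 2 conditions on step-1 posterior means, not the full posterior;
  uncertainty in the abiotic effects is deliberately not propagated
  (doing so would require integrating the step-1 posterior inside every
  step-2 likelihood evaluation).
- The per-plot synthetic clouds extend only a couple of metres beyond the
  field-plot radius; the 50/100/200 m extraction radii are supported by
  `extract_plot_metrics()` on any sufficiently large cloud, but the
  bundled generator does not produce full-scene clouds.
- LAS/LAZ binary formats are not read; point clouds are tabular
  (`x, y, z, classification`, class 2 = ground).
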