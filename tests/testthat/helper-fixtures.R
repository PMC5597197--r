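# Shared fixtures and reduced sampler settings for the test suite.

random_cloud <- function(n, seed, extent = 20) {
  set.seed(seed)
  tibble::tibble(
    x = runif(n, -extent / 2, extent / 2),
    y = runif(n, -extent / 2, extent / 2),
    z = pmax(0, runif(n, -1, 30)),
    classification = sample(c(1L, 2L), n, replace = TRUE)
  )
}

# reduced sampler settings for simulation studies: 3 cold trajectories,
# 5,000-iteration budget, 400 retained draws
reduced_config <- function(seed, ...) {
  sampler_config(n_trajectories = 3, n_tempered = 0, max_iterations = 5000,
                 n_posterior_draws = 400, max_thin = 8, max_collect = 1600,
                 min_adapt = 800, check_every = 400, archive_every = 5,
                 seed = seed, ...)
}

# tiny settings for smoke tests only
tiny_config <- function(seed, ...) {
  sampler_config(n_trajectories = 3, n_tempered = 1, max_iterations = 600,
                 n_posterior_draws = 100, max_thin = 5, max_collect = 600,
                 min_adapt = 200, check_every = 200, swap_every = 5,
                 seed = seed, ...)
}

# One two-step replicate at the study's reduced simulation conditions:
# 800 plots, 200 lidar-covered, richness response, per-sd indicator effect
# as given. Returns the step-2 summary used by the recovery checks.
two_step_replicate <- function(effect, seed) {
  ds <- make_dataset("lowland", true_models = default_true_models(effect),
                     seed = seed, n_plots = 800, n_covered = 200,
                     clouds = FALSE, responses = "richness")
  resp <- response_spec("richness", "richness_helio")
  suppressWarnings({
    s1 <- fit_step1(ds, resp, reduced_config(seed))
    sub <- dplyr::filter(ds$plots, als_covered)
    r <- fit_step2(sub, resp, "c_tot", s1, reduced_config(seed + 1))
  })
  beta <- r$draws$draws[, "b_indicator"]
  ci <- unname(quantile(beta, c(0.025, 0.975)))
  # the generator standardizes the indicator over all plots while step 2
  # standardizes over the fitted subset, so the exact estimand on the
  # step-2 scale is effect * sd(subset)/sd(all plots)
  truth <- effect * sd(sub$c_tot) / sd(ds$plots$c_tot)
  tibble::tibble(seed = seed, effect = effect, truth = truth, est = mean(beta),
                 ci_lo = ci[1], ci_hi = ci[2], delta_dic = r$delta_dic)
}

# replicate cache shared between acceptance checks (recovery and DIC
# directionality reuse the same fits)
.replicate_cache <- new.env(parent = emptyenv())

recovery_replicates <- function(effect, n_rep = 20, base_seed = 2600) {
  key <- sprintf("eff%s_n%d_s%d", effect, n_rep, base_seed)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  out <- purrr::map_dfr(seq_len(n_rep), function(r)
    two_step_replicate(effect, base_seed + 7 * r))
  .replicate_cache[[key]] <- out
  out
}
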