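test_that("Metropolis-within-Gibbs accepts on flat targets and rejects barriers", {
  set.seed(1)
  flat <- function(th) 0
  st <- mwg_step(c(0, 0), scales = 1, log_post = flat)
  expect_true(all(st$accepted))

  wall <- function(th) if (any(th > 0.5)) -Inf else 0
  cur <- c(0.4999, 0.4999)
  rejected_all <- TRUE
  for (i in 1:50) {
    st <- mwg_step(cur, scales = 10, log_post = wall)
    if (any(st$theta > 0.5)) rejected_all <- FALSE
  }
  expect_true(rejected_all)
  expect_error(mwg_step(c(0, 0), scales = c(1, -1), log_post = flat))

  # standard normal target: long-run mean within 3 batch-means SEs
  ch <- mwg_chain(function(th) -0.5 * th^2, init = 2, n_steps = 20000,
                  scales = 2.4, seed = 42)
  x <- drop(ch$draws)
  bm <- vapply(split(x, rep(1:40, each = 500)), mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(x)), 3 * se)
})

test_that("differential-evolution proposals respect crossover and degenerate populations", {
  set.seed(2)
  pop <- matrix(rnorm(15), 5, 3)
  cur <- rnorm(3)
  pr <- de_proposal(cur, pop, crossover = 1)
  expect_true(all(attr(pr, "mask")))
  same <- matrix(1, 4, 3)
  pr2 <- de_proposal(c(1, 1, 1), same, crossover = 1, jitter_sd = 1e-6)
  expect_lt(max(abs(pr2 - 1)), 1e-4)       # jitter only
  pr3 <- de_proposal(cur, pop, crossover = 0.5)
  expect_true(all(pr3[!attr(pr3, "mask")] == cur[!attr(pr3, "mask")]))
  expect_error(de_proposal(cur, pop[1:2, ]))
})

test_that("equi-energy swaps exchange within rings only", {
  th <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  # equal log-posteriors, adjacent temperatures, same ring: accepted surely
  set.seed(3)
  out <- equi_energy_swap(th, lp = c(-3, -3), temperatures = c(1, 2),
                          ring_breaks = c(-10, 10))
  expect_equal(out$swaps, 1L)
  expect_equal(out$theta[1, ], c(5, 5))
  # different rings: no swap proposed
  out2 <- equi_energy_swap(th, lp = c(-3, -30), temperatures = c(1, 2),
                           ring_breaks = c(-20))
  expect_equal(out2$swaps, 0L)
  # single temperature: no-op
  out3 <- equi_energy_swap(th, lp = c(-3, -3), temperatures = c(1, 1))
  expect_equal(out3$swaps, 0L)
})

test_that("adaptation moves scales towards the target and diminishes", {
  s1 <- adapt_scales(1, accept = 1, iteration = 100)
  expect_gt(s1, 1)
  s2 <- adapt_scales(1, accept = 0, iteration = 100)
  expect_lt(s2, 1)
  expect_lt(attr(adapt_scales(1, 1, 10000), "step"),
            attr(adapt_scales(1, 1, 100), "step"))
})

test_that("split Gelman-Rubin matches the textbook formula and flags degeneracy", {
  set.seed(4)
  x <- rnorm(400)
  same <- list(cbind(x), cbind(x))
  expect_lte(gelman_rubin(same)[1], 1.007)
  apart <- list(cbind(rnorm(200)), cbind(rnorm(200) + 100))
  expect_gt(gelman_rubin(apart)[1], 10)
  chains <- lapply(1:3, function(i) cbind(rnorm(300, 0.1 * i)))
  expect_equal(unname(gelman_rubin(chains)[1]),
               oracle_rhat(lapply(chains, drop)), tolerance = 1e-10)
  flatc <- list(cbind(rep(1, 100)), cbind(rep(1, 100)))
  expect_true(is.na(gelman_rubin(flatc)[1]))
})

test_that("thinning reaches the target correlation", {
  set.seed(5)
  wn <- matrix(rnorm(100000), ncol = 1)
  th <- thin_to_correlation(wn, target = 0.01)
  expect_equal(attr(th, "lag"), 1L)

  # AR(1, rho = 0.9): the 0.01 crossing sits at k = log(0.01)/log(0.9) ~ 44.
  # The sample ACF at that depth carries Bartlett noise of about
  # sqrt((1 + 2 rho^2/(1-rho^2))/n) ~ 0.01 on 100,000 draws, so the selected
  # lag scatters around the analytic value; the thinned stream must in any
  # case come out close to uncorrelated.
  ar <- matrix(as.numeric(stats::filter(rnorm(100000), 0.9, "recursive")), ncol = 1)
  th2 <- thin_to_correlation(ar, target = 0.01)
  k <- attr(th2, "lag")
  expect_gt(k, 25)
  expect_lt(k, 70)
  ac1 <- acf(th2[, 1], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac1), 0.05)

  const <- matrix(1, 1000, 1)
  thc <- thin_to_correlation(const)
  expect_true(is.na(attr(thc, "lag")))
  expect_false(attr(thc, "reached"))
})

test_that("the full sampler recovers an analytic Gaussian and is reproducible", {
  S <- matrix(c(1, 0.6, 0.6, 1.5), 2)
  P <- solve(S)
  lp <- function(th) -0.5 * drop(t(th) %*% P %*% th)
  cfg <- sampler_config(n_trajectories = 4, n_tempered = 1,
                        max_iterations = 8000, n_posterior_draws = 800,
                        min_adapt = 500, seed = 11)
  fit <- run_sampler(lp, c(a = 2, b = -2), cfg)
  expect_s3_class(fit, "lf_draws")
  expect_equal(nrow(fit$draws), 800)
  expect_lt(max(abs(colMeans(fit$draws))), 3 * sqrt(max(diag(S)) / 800) * 1.5)
  expect_lt(max(abs(cov(fit$draws) - S)), 0.25)
  # bit-identical rerun under the same seed
  fit2 <- run_sampler(lp, c(a = 2, b = -2), cfg)
  expect_identical(fit$draws, fit2$draws)
  # tidy/glance surface
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_true(all(c("estimate", "conf.low", "rhat") %in% names(td)))
  expect_equal(glance(fit)$n_draws, 800)
})

test_that("heated trajectories let the sampler cross deep valleys", {
  # two widely separated modes: a cold-only walker with small steps sticks
  lp <- function(th) log(0.5 * dnorm(th, -8, 0.6) + 0.5 * dnorm(th, 8, 0.6))
  cfg <- sampler_config(n_trajectories = 6, n_tempered = 3,
                        temperatures = c(1, 1, 1, 4, 16, 64),
                        max_iterations = 15000, n_posterior_draws = 1500,
                        min_adapt = 1000, swap_every = 5, seed = 21)
  fit <- run_sampler(lp, c(x = -8), cfg)
  mass_right <- mean(fit$draws > 0)
  expect_gt(mass_right, 0.2)
  expect_gt(1 - mass_right, 0.2)
})

test_that("adaptation records are non-increasing after burn-in", {
  lp <- function(th) -0.5 * sum(th^2)
  cfg <- sampler_config(n_trajectories = 3, n_tempered = 0,
                        max_iterations = 2000, n_posterior_draws = 200,
                        max_collect = 800, seed = 31)
  fit <- run_sampler(lp, c(0, 0), cfg)
  steps <- fit$adapt_steps
  expect_true(all(diff(steps) <= 1e-12))
})
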