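test_that("restricted cubic spline basis is restricted and matches the direct formula", {
  kn <- c(-1.2, -0.3, 0.4, 1.5)
  x <- seq(-3, 4, by = 0.01)
  b <- rcs_basis(x, kn)
  # zero nonlinear components below the first knot
  expect_true(all(b[x < kn[1], 2:3] == 0))
  # linear beyond the last knot: vanishing second differences
  xr <- x[x > kn[4]]
  br <- rcs_basis(xr, kn)
  for (j in 1:3) expect_lt(max(abs(diff(diff(br[, j])))), 1e-8)
  set.seed(3)
  xs <- rnorm(100, 0, 2)
  expect_lt(max(abs(rcs_basis(xs, kn) - oracle_rcs(xs, kn))), 1e-10)
})

test_that("design rows implement the TTS and slope-aspect conventions", {
  base <- tibble::tibble(reaction = c(5, 5.5, 4.8, 5.2), swc = c(5, 5.1, 5.3, 4.9),
                         tmean = c(9, 9.5, 9.2, 9.1), solrad = c(640, 620, 650, 630),
                         tts = c(0L, 1L, 6L, 9L), slope = c(0, 10, 200, 30),
                         aspect = c(0, 100, 0, 200), c_tot = c(50, 80, 60, 70))
  spec <- abiotic_spec(base)
  X <- design_matrix(base, spec, indicator = "c_tot")
  expect_equal(ncol(X), 18)
  # flat codes: tts 0 and 6 both give tts0 = 1 and masked spline columns
  expect_equal(unname(X[c(1, 3), "tts0"]), c(1, 1))
  expect_equal(unname(X[1, paste0("tts", 1:3)]), c(0, 0, 0))
  # slope 0 kills the slope-aspect term
  expect_equal(unname(X[1, "slope_aspect"]), 0)
  # slope 200 % caps at pi/4; aspect 0 grades has cos = 1
  expect_equal(unname(X[3, "slope_aspect"]), sin(pi / 4))
  # aspect 100 grades = pi/2 rad kills the term for any slope
  expect_equal(unname(X[2, "slope_aspect"]), 0, tolerance = 1e-12)
  expect_error(design_matrix(dplyr::mutate(base, tts = c(0L, 12L, 1L, 2L)), spec))

  # linear predictor is the plain dot product with intercept first
  xi <- c(2, rep(0, 18))
  expect_equal(linear_predictor(X, xi), rep(2, 4))
  set.seed(5)
  xi2 <- rnorm(19)
  expect_equal(linear_predictor(X, xi2),
               drop(xi2[1] + X %*% xi2[-1]), tolerance = 1e-12)
  expect_error(linear_predictor(X, xi2[-1]))
})

test_that("richness family reduces to Poisson and matches its stated moments", {
  expect_equal(richness_logpmf(0, 0, 1), -1)   # Poisson(1) at zero
  # normalization for over- and under-dispersion
  expect_equal(sum(exp(richness_logpmf(0:10000, log(5), 2))), 1, tolerance = 1e-8)
  expect_equal(sum(exp(richness_logpmf(0:100, log(4), 0.5))), 1, tolerance = 1e-10)
  m <- oracle_count_moments(log(4), 0.5, y_max = 100)
  expect_equal(unname(m["mean"]), 4, tolerance = 1e-6)
  expect_equal(unname(m["id"]), 0.5, tolerance = 1e-6)
  expect_error(richness_logpmf(-1, 0, 1))
  expect_error(richness_logpmf(1.5, 0, 1))
  expect_error(richness_logpmf(1, 0, -2))
  # unattainable underdispersion at tiny means is refused
  expect_error(richness_logpmf(0, log(0.05), 0.2), "not attainable")
})

test_that("abundance class probabilities are a zero-inflated beta partition", {
  expect_equal(drop(abundance_class_probs(0.3, 4, 1)),
               setNames(c(1, 0, 0, 0, 0, 0), paste0("class", 0:5)))
  # uniform latent cover: cut-point differences
  expect_equal(unname(drop(abundance_class_probs(0, 2, 0))),
               c(0, 0.05, 0.20, 0.25, 0.25, 0.25), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    eta <- rnorm(1); phi <- rexp(1) + 0.2; pi0 <- runif(1, 0, 0.6)
    if (plogis(eta) >= 1 - pi0) next
    p <- drop(abundance_class_probs(eta, phi, pi0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    mu_b <- min(max(plogis(eta) / (1 - pi0), 1e-6), 1 - 1e-6)
    a <- mu_b * phi; b <- (1 - mu_b) * phi
    cuts <- c(0, 0.05, 0.25, 0.5, 0.75, 1)
    ref <- (1 - pi0) * diff(pbeta(cuts, a, b))
    expect_equal(unname(p[-1]), ref, tolerance = 1e-10)
  }
  expect_error(abundance_class_probs(5, 2, 0.5), "infeasible")
  expect_error(abundance_class_probs(0, -1, 0))
  expect_error(abundance_class_probs(0, 1, 2))
})

test_that("log prior is independent normal on the sampling scale", {
  expect_equal(log_prior(rep(0, 19)), 19 * log(1 / (2 * sqrt(2 * pi))))
  th <- rnorm(21)
  expect_equal(log_prior(th), log_prior(-th))
  expect_equal(log_prior(c(rep(0, 18), 2)) - log_prior(rep(0, 19)), -0.5)
})

test_that("log posterior equals per-plot summation plus prior", {
  set.seed(21)
  n <- 50
  plots <- simulate_covariates(n, "lowland", seed = 3)
  spec <- abiotic_spec(plots)
  X <- design_matrix(plots, spec, indicator = "c_tot")
  eta <- linear_predictor(X, c(1, rnorm(18, 0, 0.1)))
  plots$rich <- simulate_richness(eta, 1.5, seed = 4)
  theta <- c(rnorm(19, 0, 0.3), log(1.5))
  lp <- make_log_posterior(X, plots$rich, "richness")
  manual <- sum(vapply(seq_len(n), function(i)
    richness_logpmf(plots$rich[i],
                    theta[1] + sum(X[i, ] * theta[2:19]),
                    exp(theta[20])), numeric(1))) + log_prior(theta)
  expect_equal(lp(theta), manual, tolerance = 1e-9)

  # empty data: prior only
  lp0 <- make_log_posterior(X[0, , drop = FALSE], integer(0), "richness")
  expect_equal(lp0(theta), log_prior(theta))

  # abundance path agrees between the R probabilities and the compiled kernel
  plots$ab <- simulate_abundance(eta - 2, 4, 0.2, seed = 5)
  thb <- c(-1, rnorm(18, 0, 0.1), log(4), qlogis(0.2))
  lpb <- make_log_posterior(X, plots$ab, "abundance")
  pr <- abundance_class_probs(drop(thb[1] + X %*% thb[2:19]), 4, 0.2)
  manual_b <- sum(log(pr[cbind(seq_len(n), plots$ab + 1)])) + log_prior(thb)
  expect_equal(lpb(thb), manual_b, tolerance = 1e-9)

  # infeasible abundance mean yields -Inf, not an error
  expect_identical(lpb(c(5, rep(0, 18), log(4), qlogis(0.5))), -Inf)

  # user-facing wrapper ties the pieces together
  expect_equal(log_posterior(theta, plots, response_spec("richness", "rich"),
                             spec = spec),
               lp(theta), tolerance = 1e-12)
})

test_that("pmfs normalize across random parameter draws", {
  set.seed(31)
  for (i in 1:100) {
    om <- exp(runif(1, log(0.4), log(4)))
    eta <- runif(1, -1, 3)
    if (om < 1 && floor(exp(eta) / (1 - om)) < max(1, exp(eta))) next
    expect_equal(sum(exp(richness_logpmf(0:3000, eta, om))), 1, tolerance = 1e-6)
  }
})
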