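test_that("point-cloud simulation honours its configuration", {
  # no trees: ground only
  bare <- simulate_point_cloud(stand_config(extent_m = 30, stem_density = 0,
                                            pulse_density = 2, seed = 1))
  expect_true(all(bare$z == 0))
  expect_true(all(bare$classification == 2L))

  # expected point count = pulse density x area (Poisson)
  cl <- simulate_point_cloud(stand_config(extent_m = 100, stem_density = 200,
                                          pulse_density = 4, seed = 2))
  expect_lt(abs(nrow(cl) - 40000), 3 * sqrt(40000))

  # forced gap disc: CHM cells inside stay at understory level
  gap <- simulate_point_cloud(stand_config(
    extent_m = 40, stem_density = 2000, pulse_density = 10,
    gap_discs = list(c(0, 0, 5)), seed = 3))
  # roughly the disc area (78.5 m^2) less boundary cells whose centre lies
  # inside the disc but which catch crown points from just outside it
  m <- extract_plot_metrics(gap, c(0, 0), radius = 15)
  expect_gte(m$gap_max, 65)

  # determinism
  cfg <- stand_config(extent_m = 25, stem_density = 300, pulse_density = 5, seed = 9)
  expect_identical(simulate_point_cloud(cfg), simulate_point_cloud(cfg))

  expect_error(stand_config(extent_m = -1))
  expect_error(stand_config(pulse_density = 0))
  expect_error(stand_config(height_mean = 1))
})

test_that("covariate simulation matches the site profiles", {
  expect_error(simulate_covariates(10, "desert"))
  one <- simulate_covariates(1, "mountain", seed = 5)
  expect_identical(one, simulate_covariates(1, "mountain", seed = 5))

  mt <- simulate_covariates(10000, "mountain", seed = 6)
  expect_true(all(mt$slope >= 0 & mt$slope <= 85))
  expect_true(all(mt$reaction >= 2.9 & mt$reaction <= 6.3))
  expect_true(all(mt$tts %in% c(0L, 1L, 2L, 3L, 4L, 5L, 7L, 9L)))
  # flat codes merged: code 0 carries the mass of 0, 6 and 8
  expect_gt(mean(mt$tts == 0), 0.25)

  lw <- simulate_covariates(10000, "lowland", seed = 7)
  expect_lt(abs(mean(lw$tmean) - 9.3), 0.05)
  expect_lt(abs(mean(lw$reaction) - 5.2), 0.05)
  expect_lt(abs(mean(lw$c_tot) - 76.7), 1.5)
  expect_true(all(lw$c_tot >= 0 & lw$c_tot <= 150))
})

test_that("richness draws follow the count family", {
  # Poisson reduction
  r1 <- simulate_richness(rep(0, 10000), 1, seed = 1)
  expect_lt(abs(mean(r1) - 1), 0.03)

  # vanishing mean
  expect_true(all(simulate_richness(rep(-20, 5000), 1.5, seed = 2) == 0))

  # index of dispersion for over- and under-dispersion
  r2 <- simulate_richness(rep(log(4), 100000), 2, seed = 3)
  expect_lt(abs(var(r2) / mean(r2) - 2), 0.1)
  r3 <- simulate_richness(rep(log(4), 100000), 0.5, seed = 4)
  expect_lt(abs(var(r3) / mean(r3) - 0.5), 0.1)

  expect_error(simulate_richness(0, -1))

  # goodness of fit against the family pmf
  y <- simulate_richness(rep(log(3), 100000), 1.6, seed = 5)
  ymax <- max(y)
  p <- exp(richness_logpmf(0:ymax, log(3), 1.6))
  obs <- tabulate(y + 1, nbins = ymax + 1)
  keep <- p * length(y) >= 5
  chi <- sum((obs[keep] - length(y) * p[keep])^2 / (length(y) * p[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("abundance draws follow the class probabilities", {
  expect_true(all(simulate_abundance(rnorm(200), 3, 1, seed = 1) == 0L))

  cls <- simulate_abundance(rep(0, 100000), 2, 0, seed = 2)
  freq <- tabulate(cls + 1, nbins = 6) / length(cls)
  expect_lt(max(abs(freq - c(0, 0.05, 0.2, 0.25, 0.25, 0.25))), 0.01)

  expect_identical(simulate_abundance(rep(0.2, 50), 3, 0.2, seed = 9),
                   simulate_abundance(rep(0.2, 50), 3, 0.2, seed = 9))

  # chi-square goodness of fit at arbitrary parameters
  eta <- -0.8; phi <- 5; pi0 <- 0.25
  cls2 <- simulate_abundance(rep(eta, 100000), phi, pi0, seed = 3)
  p <- drop(abundance_class_probs(eta, phi, pi0))
  obs <- tabulate(cls2 + 1, nbins = 6)
  chi <- sum((obs - 1e5 * p)^2 / (1e5 * p))
  expect_gt(stats::pchisq(chi, df = 5, lower.tail = FALSE), 0.01)
})

test_that("datasets reproduce the two site layouts and record their truth", {
  ds <- make_dataset("lowland", seed = 1, clouds = FALSE)
  expect_equal(nrow(ds$plots), 789)
  expect_equal(sum(ds$plots$als_covered), 48)
  expect_equal(unique(ds$plots$plot_radius[ds$plots$als_covered]), 9)
  expect_equal(unique(ds$plots$plot_radius[!ds$plots$als_covered]), 15)
  expect_true(all(c("richness_shade", "richness_mid", "richness_helio",
                    "abund_sp1", "abund_sp8") %in% names(ds$plots)))

  mt <- make_dataset("mountain", seed = 2, clouds = FALSE, responses = "richness")
  expect_equal(nrow(mt$plots), 1155)
  expect_equal(sum(mt$plots$als_covered), 171)
  expect_equal(unique(mt$plots$plot_radius[mt$plots$als_covered]), 15)
  expect_false(any(c("abund_sp1") %in% names(mt$plots)))

  red <- make_dataset("reduced", seed = 3, n_plots = 200, n_covered = 50,
                      clouds = FALSE, responses = "richness")
  expect_equal(nrow(red$plots), 200)
  expect_equal(sum(red$plots$als_covered), 50)

  # responses are reproducible functions of the seed
  ds2 <- make_dataset("lowland", seed = 1, clouds = FALSE)
  expect_identical(dplyr::select(ds$plots, -cloud), dplyr::select(ds2$plots, -cloud))

  # recorded truth generates the observed response distribution scale
  tm <- ds$true_models$richness_helio
  X <- design_matrix(ds$plots, ds$spec, indicator = "c_tot")
  eta <- linear_predictor(X, tm$xi)
  expect_lt(abs(mean(ds$plots$richness_helio) - mean(exp(eta))) /
              mean(exp(eta)), 0.25)
})

test_that("covered plots carry local clouds that yield valid metrics", {
  ds <- make_dataset("reduced", seed = 4, n_plots = 40, n_covered = 6,
                     responses = "richness")
  idx <- which(ds$plots$als_covered)
  expect_true(all(!vapply(ds$plots$cloud[idx], is.null, logical(1))))
  expect_true(all(vapply(ds$plots$cloud[-idx], is.null, logical(1))))
  met <- extract_dataset_metrics(ds)
  expect_equal(nrow(met), 6)
  expect_true(all(met$ok))
  expect_true(all(met$c_f >= 0 & met$c_f <= 1))
  # denser cover in the field implies denser simulated canopy
  expect_gt(cor(ds$plots$c_tot[idx], met$c_f), 0)
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- make_dataset("reduced", seed = 5, n_plots = 25, n_covered = 4,
                     responses = "richness")
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  plots <- utils::read.csv(file.path(dir, "plots.csv"))
  expect_equal(nrow(plots), 25)
  clouds <- utils::read.csv(file.path(dir, "clouds.csv"))
  expect_setequal(unique(clouds$plot_id), ds$plots$plot_id[ds$plots$als_covered])
  truth <- jsonlite::read_json(file.path(dir, "true_models.json"))
  expect_equal(length(truth$richness_helio$xi), 19)
})
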