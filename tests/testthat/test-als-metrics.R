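test_that("height metrics follow the printed definitions", {
  cl <- tibble::tibble(x = 1:4 / 10, y = 1:4 / 10, z = c(0, 0, 3, 5))
  hm <- height_metrics(cl)
  expect_equal(hm$h_max, 5)
  expect_equal(hm$h_median, 1.5)   # median over ALL points incl. ground
  expect_equal(hm$h_mean, 4)       # mean over points above 2 m
  expect_equal(hm$var_h, 1)        # population variance (1/n)
  expect_equal(attenuation_rate(cl), 0.5)

  same <- tibble::tibble(x = 1:5, y = 1:5, z = rep(10, 5))
  expect_equal(height_metrics(same)$var_h, 0)

  set.seed(42)
  z <- runif(1000, 0, 35)
  cl2 <- tibble::tibble(x = runif(1000), y = runif(1000), z = z)
  hm2 <- height_metrics(cl2)
  z2 <- z[z > 2]
  expect_equal(hm2$h_mean, sum(z2) / length(z2), tolerance = 1e-9)
  expect_equal(hm2$var_h, sum((z2 - mean(z2))^2) / length(z2), tolerance = 1e-9)
})

test_that("gini has the documented limits and matches the pairwise-difference identity", {
  expect_equal(gini(rep(17.3, 100)), 0)
  expect_equal(gini(c(30, rep(0, 99))), 1)
  expect_equal(gini(c(1, 2, 3, 4)), 1 / 3)
  expect_true(is.na(gini(5)))       # single point: no inequality information
  expect_error(gini(numeric(0)))
  expect_error(gini(c(1, -2)))
  for (s in 1:20) {
    set.seed(s)
    z <- rexp(sample(2:40, 1), 1 / 10)
    expect_equal(gini(z), oracle_gini_mad(z), tolerance = 1e-12)
    expect_equal(gini(3.7 * z), gini(z), tolerance = 1e-12)  # scale invariance
  }
})

test_that("LAD profile inverts transmittance with Beer-Lambert and cv_lad behaves", {
  # one layer fully transparent, one with known interception
  cl <- tibble::tibble(x = runif(40), y = runif(40),
                       z = c(rep(1, 10), rep(2.5, 10), rep(3.5, 20)))
  prof <- lad_profile(cl)
  # layer [2,3): below bottom 10, below top 20 -> penr 0.5
  expect_equal(prof$penr[1], 0.5)
  expect_equal(prof$lad[1], -log(0.5) / 0.5, tolerance = 1e-12)
  # layer [3,4): 20/40 -> 0.5 again
  expect_equal(prof$penr[2], 0.5)

  flat <- tibble::tibble(x = 1:5, y = 1:5, z = rep(1, 5))
  expect_equal(nrow(lad_profile(flat)), 0)

  two <- tibble::tibble(z_bottom = 2:3, z_top = 3:4, penr = c(0.5, 0.5),
                        lad = c(1, 3))
  expect_equal(cv_lad(two), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(cv_lad(dplyr::mutate(two, lad = lad * 5)), cv_lad(two))
  expect_equal(cv_lad(dplyr::mutate(two, lad = c(2, 2))), 0)

  # total interception is capped and flagged through the cap value
  blocked <- tibble::tibble(x = 1:20, y = 1:20, z = c(rep(0, 10), rep(5, 10)))
  pb <- lad_profile(blocked)
  expect_equal(pb$lad[pb$penr == 0], rep(10, sum(pb$penr == 0)))
})

test_that("CHM construction and metrics follow the per-cell max / clump rules", {
  one <- tibble::tibble(x = 3.4, y = 2.6, z = 7)
  g <- build_chm(one, bbox = c(0, 6, 0, 6))
  expect_equal(g$values[4, 3], 7)
  expect_equal(sum(g$values), 7)

  neg <- tibble::tibble(x = c(1, 2), y = c(1, 2), z = c(-0.4, -0.1))
  expect_true(all(build_chm(neg)$values == 0))
  expect_error(build_chm(one[0, ]))

  # two gap patches of 3 and 5 cells
  m <- matrix(10, 6, 6)
  m[1, 1:3] <- 0            # 3-cell gap
  m[4:5, 5] <- 0; m[4:5, 6] <- 0; m[6, 6] <- 0  # 5-cell 8-connected gap
  cm <- chm_metrics(make_grid(c(0, 0), m))
  expect_equal(cm$gap_max, 5)
  expect_equal(cm$c_f, 28 / 36)

  cells <- matrix(c(0, 2, 10), 1, 3)
  cm2 <- chm_metrics(make_grid(c(0, 0), cells))
  expect_equal(cm2$vol_can, 12)
  expect_equal(cm2$c_f, 1 / 3)   # a 2 m cell is understory, not cover

  all_high <- chm_metrics(make_grid(c(0, 0), matrix(5, 4, 4)))
  expect_equal(all_high$gap_max, 0)
  expect_equal(all_high$c_f, 1)
})

test_that("height normalization subtracts the ground model", {
  pts <- tibble::tibble(x = runif(50, 0, 10), y = runif(50, 0, 10),
                        z = 120)
  ground <- tibble::tibble(x = rep(seq(0.5, 9.5, 1), 10),
                           y = rep(seq(0.5, 9.5, 1), each = 10), z = 100)
  out <- normalize_heights(pts, ground)
  expect_equal(out$z, rep(20, 50))

  # tilted analytic plane supplied as a DTM grid: bilinear interpolation is
  # exact for a plane
  xs <- seq(0.5, 19.5, 1)
  dtm <- make_grid(c(0, 0), outer(xs, xs, function(a, b) 50 + 0.3 * a - 0.1 * b))
  set.seed(7)
  px <- runif(1000, 1, 19); py <- runif(1000, 1, 19)
  raw <- tibble::tibble(x = px, y = py, z = 50 + 0.3 * px - 0.1 * py + 5)
  nz <- normalize_heights(raw, dtm)
  expect_lt(max(abs(nz$z - 5)), 0.01)

  # points outside the footprint are dropped with a message
  far <- dplyr::bind_rows(raw, tibble::tibble(x = 100, y = 100, z = 60))
  expect_message(out2 <- normalize_heights(far, dtm), "dropped")
  expect_equal(nrow(out2), 1000)
})

test_that("plot extraction clips correctly and is translation invariant", {
  cl <- random_cloud(400, seed = 9, extent = 40)
  m1 <- extract_plot_metrics(cl, c(0, 0), radius = 9)
  shifted <- dplyr::mutate(cl, x = x + 123, y = y - 57)
  m2 <- extract_plot_metrics(shifted, c(123, -57), radius = 9)
  expect_equal(m1, m2)

  # nested radii differ only through the clip
  m15 <- extract_plot_metrics(cl, c(0, 0), radius = 15)
  expect_true(m15$n_points >= m1$n_points)

  sparse <- extract_plot_metrics(cl[1:5, ], c(0, 0), radius = 9)
  expect_false(sparse$ok)
  expect_true(is.na(sparse$h_max))
})

test_that("metric invariants hold on random clouds", {
  for (s in 1:200) {
    cl <- random_cloud(sample(10:60, 1), seed = 1000 + s)
    m <- extract_plot_metrics(cl, c(0, 0), radius = 10, min_points = 5)
    if (!m$ok) next
    expect_true(m$c_f >= 0 && m$c_f <= 1)
    expect_true(m$c_r >= 0 && m$c_r <= 1)
    expect_true(is.na(m$gini) || (m$gini >= 0 && m$gini <= 1))
    expect_true(is.na(m$var_h) || m$var_h >= 0)
    expect_true(m$gap_max >= 0 && m$vol_can >= 0)
  }
})
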