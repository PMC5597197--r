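# Survey and covariate profiles for the two study sites. Covariate
# moments/ranges follow the published site summaries; plot counts and radii
# follow the two field networks (789 plots / 48 lidar-covered at 9 m for the
# lowland site; 1,155 / 171 at 15 m for the mountain site). The "reduced"
# profile is a small mountain-like configuration for simulation studies.
site_profiles <- list(
  lowland = list(
    n_plots = 789L, n_covered = 48L, covered_radius = 9, other_radius = 15,
    pulse_density = 20.7, height_mean = 22, height_sd = 6,
    covariates = list(
      reaction = c(mean = 5.2, sd = 0.6, min = 3.5, max = 6.7),
      swc      = c(mean = 5.1, sd = 0.3, min = 4.5, max = 6.9),
      tmean    = c(mean = 9.3, sd = 0.4, min = 8.7, max = 10.5),
      solrad   = c(mean = 639.3, sd = 22.5, min = 563.1, max = 682.5),
      slope    = c(mean = 9.6, sd = 7.4, min = 0, max = 29.4),
      aspect   = c(mean = 208.3, sd = 123.2, min = 0, max = 400),
      c_tot    = c(mean = 76.7, sd = 29.7, min = 0, max = 150)
    )
  ),
  mountain = list(
    n_plots = 1155L, n_covered = 171L, covered_radius = 15, other_radius = 15,
    pulse_density = 3.4, height_mean = 25, height_sd = 7,
    covariates = list(
      reaction = c(mean = 4.1, sd = 0.5, min = 2.9, max = 6.3),
      swc      = c(mean = 5.2, sd = 0.3, min = 4.4, max = 7.7),
      tmean    = c(mean = 8.6, sd = 0.7, min = 6.2, max = 10.2),
      solrad   = c(mean = 614.9, sd = 39.8, min = 479.3, max = 710.1),
      slope    = c(mean = 27.1, sd = 18.8, min = 0, max = 85),
      aspect   = c(mean = 210.6, sd = 114.0, min = 0, max = 400),
      c_tot    = c(mean = 83.5, sd = 24.1, min = 2.5, max = 170)
    )
  )
)
site_profiles$reduced <- utils::modifyList(
  site_profiles$mountain, list(n_plots = 200L, n_covered = 50L)
)

# Location-calibrated truncated normal: the underlying mean is adjusted by
# root-finding so that the *truncated* mean equals the published mean (the
# published sd is used as the underlying sd, so the realized sd is slightly
# smaller than printed).
truncnorm_mean <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  z <- pnorm(be) - pnorm(al)
  if (z < 1e-12) return(if (mu < (a + b) / 2) a else b)
  mu + s * (dnorm(al) - dnorm(be)) / z
}

rtruncnorm_calibrated <- function(n, target_mean, s, a, b) {
  mu <- uniroot(function(m) truncnorm_mean(m, s, a, b) - target_mean,
                lower = a - 2 * s, upper = b + 2 * s, extendInt = "upX",
                tol = 1e-10)$root
  lo <- pnorm((a - mu) / s); hi <- pnorm((b - mu) / s)
  pmin(pmax(mu + s * qnorm(runif(n, lo, hi)), a), b)
}

#' Simulate abiotic plot covariates for a site profile
#'
#' Draws the soil, climate and topography covariates of one site from
#' truncated normal distributions whose truncated means match the published
#' site means and whose support matches the published ranges. The
#' topographic-situation code `tts` is uniform over its categories with the
#' flat codes (0, 6, 8) merged into 0, i.e. code 0 has probability 3/10.
#'
#' @param n_plots Number of plots (>= 1).
#' @param site_profile `"lowland"`, `"mountain"` or `"reduced"`.
#' @param seed Integer seed; the draw is a pure function of it.
#' @return A tibble with columns `reaction`, `swc`, `tmean`, `solrad`,
#'   `tts`, `slope`, `aspect`, `c_tot`.
#' @export
simulate_covariates <- function(n_plots, site_profile = "lowland", seed = 1L) {
  stopifnot(n_plots >= 1)
  if (!site_profile %in% names(site_profiles))
    stop("unknown site_profile: ", site_profile)
  prof <- site_profiles[[site_profile]]$covariates
  set.seed(seed)
  draws <- lapply(prof, function(p)
    rtruncnorm_calibrated(n_plots, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]]))
  tts <- sample(c(0L, 1L, 2L, 3L, 4L, 5L, 7L, 9L), n_plots, replace = TRUE,
                prob = c(3, 1, 1, 1, 1, 1, 1, 1) / 10)
  tibble::tibble(
    reaction = draws$reaction, swc = draws$swc, tmean = draws$tmean,
    solrad = draws$solrad, tts = tts, slope = draws$slope,
    aspect = draws$aspect, c_tot = draws$c_tot
  )
}

#' Stand configuration for the point-cloud simulator
#'
#' @param extent_m Side of the square simulated stand (m).
#' @param stem_density Stems per hectare (>= 0).
#' @param height_mean,height_sd Tree top height distribution (m);
#'   `height_mean` must exceed 2 m.
#' @param crown_radius_mean Mean crown radius (m).
#' @param pulse_density Lidar pulses per m^2 (> 0).
#' @param gap_discs Optional list of `c(x, y, r)` discs inside which no
#'   canopy return is produced (forced gaps).
#' @param ground_fraction Fraction of pulses under canopy that still reach
#'   the ground (controls the attenuation rate).
#' @param seed Integer seed.
#' @return A list of class `lf_stand_config`.
#' @export
stand_config <- function(extent_m = 100, stem_density = 300, height_mean = 22,
                         height_sd = 6, crown_radius_mean = 2.5,
                         pulse_density = 3.4, gap_discs = NULL,
                         ground_fraction = 0.3, seed = 1L) {
  if (extent_m <= 0) stop("extent_m must be > 0")
  if (pulse_density <= 0) stop("pulse_density must be > 0")
  if (stem_density < 0) stop("stem_density must be >= 0")
  if (crown_radius_mean <= 0) stop("crown_radius_mean must be > 0")
  if (height_mean <= 2) stop("height_mean must be > 2")
  structure(list(extent_m = extent_m, stem_density = stem_density,
                 height_mean = height_mean, height_sd = height_sd,
                 crown_radius_mean = crown_radius_mean,
                 pulse_density = pulse_density, gap_discs = gap_discs,
                 ground_fraction = ground_fraction, seed = seed),
            class = "lf_stand_config")
}

#' Simulate a normalized lidar point cloud over a synthetic stand
#'
#' Trees are placed at Poisson locations; each crown is a vertical
#' half-ellipsoid (flat base at 50 % of tree height). Pulses fall uniformly
#' at Poisson intensity `pulse_density`; a pulse under one or more crowns
#' returns a canopy point uniformly between the crown base and the crown
#' surface of the tallest intercepting crown, except that a configurable
#' fraction of pulses penetrates to the ground. Pulses outside any crown —
#' or inside a forced gap disc — return ground points at z = 0. Coordinates
#' are centred on the stand centre.
#'
#' @param config A [stand_config()].
#' @return A tibble `x, y, z, classification` (2 = ground, 1 = canopy).
#' @export
simulate_point_cloud <- function(config) {
  stopifnot(inherits(config, "lf_stand_config"))
  set.seed(config$seed)
  e <- config$extent_m
  area <- e^2
  n_pulse <- rpois(1, config$pulse_density * area)
  px <- runif(n_pulse, -e / 2, e / 2)
  py <- runif(n_pulse, -e / 2, e / 2)
  top <- rep(0, n_pulse)    # crown surface height at the pulse, 0 = open
  base <- rep(0, n_pulse)   # crown base height of the intercepting tree
  n_tree <- if (config$stem_density > 0)
    rpois(1, config$stem_density / 1e4 * area) else 0L
  if (n_tree > 0 && n_pulse > 0) {
    tx <- runif(n_tree, -e / 2, e / 2)
    ty <- runif(n_tree, -e / 2, e / 2)
    th <- pmax(3, rnorm(n_tree, config$height_mean, config$height_sd))
    tdepth <- 0.5 * th
    trad <- stats::rgamma(n_tree, shape = 4, scale = config$crown_radius_mean / 4)
    for (t in seq_len(n_tree)) {
      d2 <- (px - tx[t])^2 + (py - ty[t])^2
      inside <- d2 < trad[t]^2
      if (!any(inside)) next
      surf <- (th[t] - tdepth[t]) +
        tdepth[t] * sqrt(1 - d2[inside] / trad[t]^2)
      better <- surf > top[inside]
      idx <- which(inside)[better]
      top[idx] <- surf[better]
      base[idx] <- th[t] - tdepth[t]
    }
  }
  if (!is.null(config$gap_discs)) {
    for (g in config$gap_discs) {
      top[(px - g[1])^2 + (py - g[2])^2 < g[3]^2] <- 0
    }
  }
  covered <- top > 0
  canopy <- covered & runif(n_pulse) >= config$ground_fraction
  z <- numeric(n_pulse)
  z[canopy] <- runif(sum(canopy), base[canopy], top[canopy])
  tibble::tibble(
    x = px, y = py, z = pmax(z, 0),
    classification = ifelse(canopy, 1L, 2L)
  )
}

#' Simulate richness counts from the count family
#'
#' Draws counts with mean `exp(eta)` and index of dispersion `omega` from
#' the same family used by [richness_logpmf()].
#'
#' @param eta Linear predictor vector.
#' @param omega Index of dispersion (> 0).
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return Integer vector of counts.
#' @export
simulate_richness <- function(eta, omega, seed = NULL) {
  if (length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("omega must be a single positive number")
  if (!is.null(seed)) set.seed(seed)
  mu <- exp(eta)
  n <- length(mu)
  if (abs(omega - 1) < 1e-12) return(rpois(n, mu))
  if (omega > 1) return(rnbinom(n, size = mu / (omega - 1), mu = mu))
  pp <- underdispersed_pars(mu, omega)
  if (any(!pp$feasible))
    stop("index of dispersion ", omega, " is not attainable at mean ",
         format(mu[!pp$feasible][1]))
  pick <- runif(n) < pp$w
  as.integer(ifelse(pick, rbinom(n, pp$n0, pp$p0),
                    rbinom(n, pp$n0 + 1, pp$p1)))
}

#' Simulate Braun-Blanquet cover classes
#'
#' Draws ordinal classes 0-5 from the zero-inflated cumulative beta model
#' of [abundance_class_probs()].
#'
#' @inheritParams abundance_class_probs
#' @param seed Optional integer seed.
#' @return Integer vector of classes 0-5.
#' @export
simulate_abundance <- function(eta, phi, pi0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- abundance_class_probs(eta, phi, pi0)
  n <- nrow(probs)
  cum <- probs %*% upper.tri(matrix(0, 6, 6), diag = TRUE)
  as.integer(rowSums(runif(n) > cum))
}

#' True generating model
#'
#' Bundles the 19 linear-predictor coefficients and the nuisance parameters
#' of one response so that synthetic datasets can record their ground truth.
#'
#' @param kind `"richness"` or `"abundance"`.
#' @param xi Numeric vector of 19 coefficients (`xi0` intercept, 16 abiotic
#'   spline/topography coefficients, `xi17` slope-aspect, `xi18` indicator).
#' @param omega Index of dispersion (richness).
#' @param phi,pi0 Beta precision and zero-inflation probability (abundance).
#' @return A list of class `lf_true_model`.
#' @export
true_model <- function(kind = c("richness", "abundance"), xi,
                       omega = NULL, phi = NULL, pi0 = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(xi) == 19L)
  if (kind == "richness") {
    if (is.null(omega) || omega <= 0) stop("richness truth needs omega > 0")
  } else {
    if (is.null(phi) || phi <= 0) stop("abundance truth needs phi > 0")
    if (is.null(pi0) || pi0 < 0 || pi0 > 1) stop("abundance truth needs pi0 in [0, 1]")
  }
  structure(list(kind = kind, xi = xi, omega = omega, phi = phi, pi0 = pi0),
            class = "lf_true_model")
}

# Fixed default abiotic coefficients: moderate effects (0.05-0.3 on the
# eta scale per unit of spline component) so the abiotic signal is present
# but does not dominate the structure indicator.
default_abiotic_xi <- c(
  0.30, 0.15, -0.20,   # reaction
  -0.25, 0.10, 0.05,   # swc
  0.20, -0.10, 0.10,   # tmean
  0.15, 0.05, -0.05,   # solrad
  0.05, -0.02, 0.01,   # tts spline
  0.10,                # tts0
  0.20                 # slope-aspect
)

#' Default true models for a synthetic site
#'
#' Three richness groups with intercepts matching the reported group means
#' (shade ~0.5, intermediate ~2.5, heliophilous ~5.3 species per plot) and
#' mild overdispersion, plus eight species abundance models with graded
#' intercepts on the logit-cover scale. `effect` is the per-standard-
#' deviation coefficient of the structure indicator, shared by all
#' responses.
#'
#' @param effect Indicator coefficient (per sd of the indicator).
#' @return Named list of [true_model()] objects.
#' @export
default_true_models <- function(effect = 1) {
  rich_int <- c(richness_shade = log(0.5), richness_mid = log(2.5),
                richness_helio = log(5.3))
  rich_omega <- c(1.2, 1.5, 2.0)
  out <- purrr::imap(rich_int, function(int, nm) {
    true_model("richness", xi = c(int, default_abiotic_xi, effect),
               omega = rich_omega[[match(nm, names(rich_int))]])
  })
  ab_int <- seq(-1.2, -2.6, length.out = 8)
  ab <- lapply(seq_len(8), function(s) {
    true_model("abundance",
               xi = c(ab_int[s], 0.5 * default_abiotic_xi, 0.5 * effect),
               phi = 4, pi0 = 0.15)
  })
  names(ab) <- sprintf("abund_sp%d", seq_len(8))
  c(out, ab)
}

#' Generate a synthetic two-step study dataset
#'
#' Assembles a full site plot network: abiotic covariates drawn from the
#' site profile, responses drawn from the recorded true models (linear
#' predictor built on this dataset's own covariate standardization, with
#' standardized total crown cover `c_tot` as the structure indicator), and —
#' for the lidar-covered subset — per-plot point clouds whose stem density
#' increases with the plot's `c_tot`, so ALS canopy metrics correlate with
#' the generative structure variable.
#'
#' @param site `"lowland"`, `"mountain"` or `"reduced"`.
#' @param true_models Named list of [true_model()] objects keyed by response
#'   column name; defaults to [default_true_models()].
#' @param seed Integer seed; the dataset is a pure function of it.
#' @param n_plots,n_covered Optional overrides of the profile plot counts.
#' @param clouds Generate point clouds for covered plots (set `FALSE` for
#'   covariate/response-only simulation studies).
#' @param responses Which response families to simulate.
#' @return An object of class `lf_dataset`: a list with elements `plots`
#'   (tibble; `cloud` is a list-column, `NULL` where not covered), `spec`
#'   (the [abiotic_spec()] defining the truth), `true_models`, `site`.
#' @export
make_dataset <- function(site = "lowland", true_models = NULL, seed = 1L,
                         n_plots = NULL, n_covered = NULL, clouds = TRUE,
                         responses = c("richness", "abundance")) {
  if (!site %in% names(site_profiles)) stop("unknown site profile: ", site)
  responses <- match.arg(responses, several.ok = TRUE)
  prof <- site_profiles[[site]]
  if (is.null(n_plots)) n_plots <- prof$n_plots
  if (is.null(n_covered)) n_covered <- prof$n_covered
  stopifnot(n_covered <= n_plots)
  if (is.null(true_models)) true_models <- default_true_models()
  set.seed(seed)
  plots <- simulate_covariates(n_plots, site, seed = sample.int(2^31 - 1, 1))
  covered <- sort(sample.int(n_plots, n_covered))
  plots <- dplyr::mutate(
    plots,
    plot_id = sprintf("%s_%04d", site, dplyr::row_number()),
    site = site,
    als_covered = dplyr::row_number() %in% covered,
    plot_radius = ifelse(dplyr::row_number() %in% covered,
                         prof$covered_radius, prof$other_radius),
    .before = 1
  )
  spec <- abiotic_spec(plots)
  X <- design_matrix(plots, spec, indicator = "c_tot")
  keep <- purrr::keep(true_models, function(tm)
    tm$kind %in% responses)
  for (nm in names(keep)) {
    tm <- keep[[nm]]
    eta <- linear_predictor(X, tm$xi)
    plots[[nm]] <- if (tm$kind == "richness") {
      simulate_richness(eta, tm$omega)
    } else {
      simulate_abundance(eta, tm$phi, tm$pi0)
    }
  }
  plots$cloud <- vector("list", n_plots)
  if (clouds && n_covered > 0) {
    cseeds <- sample.int(2^31 - 1, n_covered)
    for (k in seq_along(covered)) {
      i <- covered[k]
      dens <- max(20, 900 * plots$c_tot[i] / max(prof$covariates$c_tot[["max"]], 1))
      cfg <- stand_config(
        extent_m = 2 * (plots$plot_radius[i] + 2),
        stem_density = dens,
        height_mean = prof$height_mean, height_sd = prof$height_sd,
        pulse_density = prof$pulse_density, seed = cseeds[k]
      )
      plots$cloud[[i]] <- simulate_point_cloud(cfg)
    }
  }
  structure(list(plots = plots, spec = spec, true_models = keep, site = site),
            class = "lf_dataset")
}

#' @export
print.lf_dataset <- function(x, ...) {
  cat(sprintf("<lf_dataset> %s site: %d plots, %d lidar-covered (radius %g m)\n",
              x$site, nrow(x$plots), sum(x$plots$als_covered),
              unique(x$plots$plot_radius[x$plots$als_covered])[1]))
  cat("  responses:", paste(names(x$true_models), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `plots.csv` (one row per plot, without the cloud column),
#' `clouds.csv` (long table `plot_id, x, y, z, classification`; class 2 =
#' ground) and `true_models.json` (the generating parameters) to a
#' directory.
#'
#' @param dataset An `lf_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lf_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plots <- dplyr::select(dataset$plots, -"cloud")
  utils::write.csv(plots, file.path(dir, "plots.csv"), row.names = FALSE)
  covered <- which(dataset$plots$als_covered &
                     !vapply(dataset$plots$cloud, is.null, logical(1)))
  clouds <- purrr::map_dfr(covered, function(i)
    dplyr::mutate(dataset$plots$cloud[[i]],
                  plot_id = dataset$plots$plot_id[i], .before = 1))
  utils::write.csv(clouds, file.path(dir, "clouds.csv"), row.names = FALSE)
  truth <- lapply(dataset$true_models, unclass)
  jsonlite::write_json(truth, file.path(dir, "true_models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
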