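#' Restricted cubic spline basis
#'
#' Expands a numeric vector into the three components of a restricted
#' (natural) cubic spline with four knots: the variable itself plus two
#' truncated-power terms that are linear beyond the boundary knots.
#' The truncated-power terms use the conventional \eqn{(t_4 - t_1)^2}
#' normalization so all components live on the scale of `x`.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of 4 strictly increasing knot locations.
#' @return A numeric matrix with `length(x)` rows and 3 columns.
#' @examples
#' rcs_basis(seq(-2, 2, by = 0.5), knots = c(-1.5, -0.5, 0.5, 1.5))
#' @export
rcs_basis <- function(x, knots) {
  stopifnot(is.numeric(x), length(knots) == 4L, !is.unsorted(knots, strictly = TRUE))
  t1 <- knots[1]; t3 <- knots[3]; t4 <- knots[4]
  norm <- (t4 - t1)^2
  pp3 <- function(u) pmax(u, 0)^3
  comp <- function(tj) {
    (pp3(x - tj) -
       pp3(x - t3) * (t4 - tj) / (t4 - t3) +
       pp3(x - t4) * (t3 - tj) / (t4 - t3)) / norm
  }
  out <- cbind(x, comp(knots[1]), comp(knots[2]))
  dimnames(out) <- NULL
  out
}

#' Preprocessing specification for the abiotic covariates
#'
#' Records, from a training plot table, the centring/scaling constants and
#' spline knots used to build the model design matrix: `reaction`, `swc`,
#' `tmean` and `solrad` are standardized and expanded with 4-knot restricted
#' cubic splines (knots at the 0.05/0.35/0.65/0.95 quantiles of the scaled
#' training values); the topographic-situation code `tts` keeps fixed knots
#' at 2.5, 4.5, 5.5 and 7 on its raw numeric value. Reusing the returned
#' specification guarantees that new data (e.g. the lidar-covered subset in
#' a second fitting step) is transformed exactly as the training set was.
#'
#' @param data A plot table containing at least the columns `reaction`,
#'   `swc`, `tmean`, `solrad`.
#' @param knot_probs Quantile levels for the 4 spline knots.
#' @return An object of class `lf_spec`.
#' @export
abiotic_spec <- function(data, knot_probs = c(0.05, 0.35, 0.65, 0.95)) {
  covs <- c("reaction", "swc", "tmean", "solrad")
  stopifnot(all(covs %in% names(data)), length(knot_probs) == 4L)
  center <- vapply(covs, function(v) mean(data[[v]]), numeric(1))
  scale <- vapply(covs, function(v) stats::sd(data[[v]]), numeric(1))
  if (any(scale == 0)) stop("constant abiotic covariate: cannot standardize")
  knots <- lapply(covs, function(v) {
    z <- (data[[v]] - center[[v]]) / scale[[v]]
    kn <- unname(quantile(z, probs = knot_probs, type = 7))
    if (is.unsorted(kn, strictly = TRUE)) kn else sort(unique(kn)) # degenerate guard
  })
  names(knots) <- covs
  structure(
    list(center = center, scale = scale, knots = knots,
         tts_knots = c(2.5, 4.5, 5.5, 7)),
    class = "lf_spec"
  )
}

#' @export
print.lf_spec <- function(x, ...) {
  cat("<lf_spec> abiotic preprocessing\n")
  for (v in names(x$knots)) {
    cat(sprintf("  %-8s center %8.3f  scale %7.3f  knots %s\n", v,
                x$center[[v]], x$scale[[v]],
                paste(sprintf("%.2f", x$knots[[v]]), collapse = ", ")))
  }
  cat("  tts      knots", paste(x$tts_knots, collapse = ", "), "\n")
  invisible(x)
}

# slope given in %, aspect in grades (400/circle); the slope-aspect term
# needs both as angles.
slope_to_rad <- function(slope_pct) atan(slope_pct / 100)
aspect_to_rad <- function(aspect_grades) aspect_grades * (2 * pi / 400)

merge_flat_tts <- function(tts) {
  stopifnot(all(tts %in% 0:9))
  tts[tts %in% c(6L, 8L)] <- 0L
  as.integer(tts)
}

#' Model design matrix for the abiotic linear predictor
#'
#' Builds the 17 abiotic columns of the linear predictor — three restricted
#' cubic spline components for each of `reaction`, `swc`, `tmean` and
#' `solrad`, three spline components of the numeric `tts` code masked by
#' `(1 - tts0)`, the flat-terrain indicator `tts0`, and the slope-aspect
#' term `sin(min(slope, pi/4)) * cos(aspect)` — plus, optionally, an 18th
#' column holding the standardized structure indicator (total crown cover
#' `c_tot` or an ALS variable).
#'
#' @param data Plot table with columns `reaction`, `swc`, `tmean`, `solrad`,
#'   `tts` (integer codes 0-9; flat codes 6 and 8 are merged to 0), `slope`
#'   (percent) and `aspect` (grades), plus the indicator column when
#'   requested.
#' @param spec An [abiotic_spec()] object (defaults to one fitted on `data`).
#' @param indicator Name of the indicator column, or `NULL` for the 17
#'   abiotic columns only.
#' @param indicator_stats Optional `c(center, scale)` used to standardize
#'   the indicator; defaults to its mean/sd in `data`.
#' @return A numeric matrix (17 or 18 columns) with attributes
#'   `indicator_center` and `indicator_scale` when an indicator is present.
#' @export
design_matrix <- function(data, spec = abiotic_spec(data), indicator = NULL,
                          indicator_stats = NULL) {
  stopifnot(inherits(spec, "lf_spec"))
  covs <- c("reaction", "swc", "tmean", "solrad")
  blocks <- lapply(covs, function(v) {
    z <- (data[[v]] - spec$center[[v]]) / spec$scale[[v]]
    rcs_basis(z, spec$knots[[v]])
  })
  tts <- merge_flat_tts(data$tts)
  tts0 <- as.numeric(tts == 0L)
  tts_sp <- rcs_basis(as.numeric(tts), spec$tts_knots) * (1 - tts0)
  sa <- sin(pmin(slope_to_rad(data$slope), pi / 4)) * cos(aspect_to_rad(data$aspect))
  X <- cbind(do.call(cbind, blocks), tts_sp, tts0, sa)
  cn <- c(paste0(rep(covs, each = 3), 1:3), paste0("tts", 1:3), "tts0", "slope_aspect")
  if (!is.null(indicator)) {
    stopifnot(indicator %in% names(data))
    v <- data[[indicator]]
    if (is.null(indicator_stats)) indicator_stats <- c(mean(v), stats::sd(v))
    if (indicator_stats[2] == 0) stop("constant indicator: cannot standardize")
    X <- cbind(X, (v - indicator_stats[1]) / indicator_stats[2])
    cn <- c(cn, "indicator")
  }
  colnames(X) <- cn
  if (!is.null(indicator)) {
    attr(X, "indicator_center") <- indicator_stats[1]
    attr(X, "indicator_scale") <- indicator_stats[2]
  }
  X
}

#' Linear predictor
#'
#' Evaluates \eqn{\eta = \xi_0 + \sum_j \xi_j x_j} for each design row.
#'
#' @param design Design matrix from [design_matrix()] (or any numeric
#'   matrix).
#' @param xi Coefficient vector of length `ncol(design) + 1`; the first
#'   element is the intercept \eqn{\xi_0}.
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(design, xi) {
  design <- as.matrix(design)
  if (length(xi) != ncol(design) + 1L)
    stop("xi must have length ncol(design) + 1 (intercept first)")
  drop(xi[1] + design %*% xi[-1])
}

# ---- richness count family ---------------------------------------------

# Equal-mean two-point binomial mixture for the under-dispersed regime
# (index of dispersion omega < 1): components Binomial(n0, mu/n0) and
# Binomial(n0 + 1, mu/(n0 + 1)) both have mean mu; the weight solves
# w*p0 + (1-w)*p1 = 1 - omega so that Var = mu*omega exactly.
underdispersed_pars <- function(mu, omega) {
  n0 <- floor(mu / (1 - omega))
  feasible <- n0 >= 1 & n0 >= mu
  p0 <- mu / n0
  p1 <- mu / (n0 + 1)
  w <- ((1 - omega) - p1) / (p0 - p1)
  list(n0 = n0, p0 = p0, p1 = p1, w = pmin(pmax(w, 0), 1), feasible = feasible)
}

#' Log-probability mass of the richness count family
#'
#' A count family indexed by its mean \eqn{\mu = e^\eta} and its index of
#' dispersion \eqn{\omega} (variance/mean). For \eqn{\omega = 1} it is
#' exactly Poisson; for \eqn{\omega > 1} the negative binomial with
#' variance \eqn{\omega\mu}; for \eqn{\omega < 1} an equal-mean mixture of
#' two adjacent binomials whose weight is chosen so the mean and index of
#' dispersion are matched exactly (feasible whenever
#' \eqn{\lfloor\mu/(1-\omega)\rfloor \ge \max(\mu, 1)}).
#'
#' @param y Non-negative integer counts.
#' @param eta Linear predictor; the distribution mean is `exp(eta)`.
#' @param omega Index of dispersion (> 0).
#' @return Vector of log-probabilities (recycled over `y`/`eta`).
#' @export
richness_logpmf <- function(y, eta, omega) {
  if (length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("omega must be a single positive number")
  if (any(y < 0) || any(y != floor(y)))
    stop("y must contain non-negative integers")
  n <- max(length(y), length(eta))
  y <- rep_len(y, n); eta <- rep_len(eta, n)
  mu <- exp(eta)
  if (abs(omega - 1) < 1e-12) return(dpois(y, mu, log = TRUE))
  if (omega > 1) return(dnbinom(y, size = mu / (omega - 1), mu = mu, log = TRUE))
  pp <- underdispersed_pars(mu, omega)
  if (any(!pp$feasible))
    stop("index of dispersion ", omega,
         " is not attainable at mean ", format(mu[!pp$feasible][1]),
         " (requires floor(mu/(1-omega)) >= max(mu, 1))")
  log(pp$w * dbinom(y, pp$n0, pp$p0) + (1 - pp$w) * dbinom(y, pp$n0 + 1, pp$p1))
}

# ---- abundance cover-class model ---------------------------------------

# Braun-Blanquet class boundaries on the latent cover scale.
bb_cuts <- c(0, 0.05, 0.25, 0.50, 0.75, 1)

#' Braun-Blanquet class probabilities under the zero-inflated beta model
#'
#' Latent plot cover \eqn{C} is zero with probability `pi0` and otherwise
#' beta-distributed with precision `phi`; the *global* mean
#' \eqn{E[C] = (1-\pi_0)\mu_\beta} equals `plogis(eta)`. Cover is observed
#' as the ordinal class 0-5 with boundaries at 5, 25, 50 and 75 % cover
#' (class 0 is exact absence).
#'
#' @param eta Linear predictor (logit of the global mean cover).
#' @param phi Beta precision (> 0); shapes are \eqn{\mu_\beta\phi} and
#'   \eqn{(1-\mu_\beta)\phi}.
#' @param pi0 Zero-inflation probability in \[0, 1\].
#' @return A matrix with `length(eta)` rows and 6 columns (classes 0-5),
#'   each row summing to 1.
#' @export
abundance_class_probs <- function(eta, phi, pi0) {
  if (length(phi) != 1L || !is.finite(phi) || phi <= 0) stop("phi must be > 0")
  if (length(pi0) != 1L || !is.finite(pi0) || pi0 < 0 || pi0 > 1)
    stop("pi0 must be in [0, 1]")
  n <- length(eta)
  if (pi0 >= 1) {
    out <- matrix(0, n, 6, dimnames = list(NULL, paste0("class", 0:5)))
    out[, 1] <- 1
    return(out)
  }
  m <- plogis(eta)
  ratio <- m / (1 - pi0)
  if (any(ratio >= 1))
    stop("infeasible global mean: plogis(eta) must be < 1 - pi0")
  mu_b <- pmin(pmax(ratio, 1e-6), 1 - 1e-6)
  a <- mu_b * phi
  b <- (1 - mu_b) * phi
  cdf <- vapply(bb_cuts[2:5], function(cc) pbeta(cc, a, b), numeric(n))
  cdf <- cbind(matrix(0, n, 1), matrix(cdf, n, 4), rep(1, n))
  probs <- (1 - pi0) * (cdf[, -1, drop = FALSE] - cdf[, -6, drop = FALSE])
  out <- cbind(pi0, probs)
  colnames(out) <- paste0("class", 0:5)
  out
}

# ---- priors and log-posterior ------------------------------------------

#' Log prior density
#'
#' Independent weakly informative Normal(0, sd 2) priors on every free
#' parameter on the sampling scale: the coefficients \eqn{\xi_j} directly,
#' and the nuisance parameters through their transforms `log(omega)`,
#' `log(phi)` and `qlogis(pi0)`.
#'
#' @param theta Parameter vector on the sampling scale.
#' @param sd Prior standard deviation (default 2).
#' @return Scalar log prior density.
#' @export
log_prior <- function(theta, sd = 2) sum(dnorm(theta, 0, sd, log = TRUE))

#' Response specification
#'
#' @param kind `"richness"` or `"abundance"`.
#' @param column Name of the response column in the plot table.
#' @return A list of class `lf_response`.
#' @export
response_spec <- function(kind = c("richness", "abundance"), column) {
  kind <- match.arg(kind)
  structure(list(kind = kind, column = column), class = "lf_response")
}

n_nuisance <- function(kind) if (kind == "richness") 1L else 2L

param_names <- function(kind, design_cols) {
  nuis <- if (kind == "richness") "log_omega" else c("log_phi", "logit_pi0")
  mid <- if (length(design_cols)) paste0("b_", design_cols) else character(0)
  c("xi0", mid, nuis)
}

# Total data log-likelihood closure over a fixed design/response; the
# compiled kernels carry the per-plot loop.
make_loglik <- function(design, y, kind = c("richness", "abundance"),
                        offset = 0) {
  kind <- match.arg(kind)
  design <- as.matrix(design)
  offset <- rep_len(offset, nrow(design))
  y <- as.integer(y)
  if (kind == "richness") {
    if (any(y < 0)) stop("richness counts must be non-negative")
    function(theta) ll_richness_cpp(theta, design, y, offset)
  } else {
    if (any(y < 0 | y > 5)) stop("abundance classes must be in 0..5")
    function(theta) ll_abundance_cpp(theta, design, y, offset)
  }
}

#' Log-posterior factory
#'
#' Returns a function of the full sampling-scale parameter vector
#' `c(xi0, coefficients for each design column, nuisance transforms)` that
#' evaluates log-likelihood + log-prior. Used directly by the sampler; the
#' heavy likelihood loop runs in compiled code. Rows whose likelihood is
#' infeasible (e.g. an abundance global mean exceeding `1 - pi0`) yield
#' `-Inf`, so such proposals are rejected.
#'
#' @param design Design matrix (its columns receive one coefficient each).
#' @param y Response vector (counts or classes 0-5).
#' @param kind `"richness"` or `"abundance"`.
#' @param offset Optional per-plot fixed contribution added to the linear
#'   predictor (used in step 2 to hold abiotic effects fixed).
#' @param prior_sd Prior standard deviation; `prior_mask` can switch the
#'   prior off for individual parameters (1 = has prior, 0 = none).
#' @param prior_mask Optional 0/1 vector over parameters.
#' @param coef_transform Optional linear map `A` from the sampled
#'   coefficient block to the model coefficients `xi = A gamma` on which
#'   the independent normal priors apply — used when the design has been
#'   orthogonalized for sampling (the likelihood then runs on the
#'   orthogonal columns while the prior stays on the original scale).
#' @return A function `theta -> scalar`.
#' @export
make_log_posterior <- function(design, y, kind = c("richness", "abundance"),
                               offset = 0, prior_sd = 2, prior_mask = NULL,
                               coef_transform = NULL) {
  kind <- match.arg(kind)
  design <- as.matrix(design)
  n <- nrow(design)
  offset <- rep_len(offset, n)
  n_coef <- 1L + ncol(design)
  d <- n_coef + n_nuisance(kind)
  fn_ll <- make_loglik(design, y, kind, offset)
  if (is.null(prior_mask)) prior_mask <- rep(1, d)
  stopifnot(length(prior_mask) == d)
  if (!is.null(coef_transform))
    stopifnot(is.matrix(coef_transform),
              all(dim(coef_transform) == n_coef))
  fn <- function(theta) {
    if (length(theta) != d) stop("theta must have length ", d)
    ll <- fn_ll(theta)
    if (!is.finite(ll)) return(-Inf)
    coefs <- theta[seq_len(n_coef)]
    if (!is.null(coef_transform)) coefs <- drop(coef_transform %*% coefs)
    pri <- c(coefs, theta[-seq_len(n_coef)])
    ll + sum(dnorm(pri[prior_mask > 0], 0, prior_sd, log = TRUE))
  }
  # model description consumed by the sampler's compiled sweep kernel
  attr(fn, "model") <- list(
    kind = if (kind == "richness") 0L else 1L,
    X = as.matrix(design), y = as.integer(y),
    offset = rep_len(as.numeric(offset), nrow(design)),
    prior_sd = prior_sd, has_prior = prior_mask > 0,
    coef_transform = if (is.null(coef_transform))
      matrix(numeric(0), 0, 0) else coef_transform
  )
  fn
}

#' Log-posterior of a plot table
#'
#' Convenience wrapper around [make_log_posterior()] that builds the design
#' matrix from a plot table with [design_matrix()].
#'
#' @param theta Sampling-scale parameter vector: `xi0`, the 17 abiotic
#'   coefficients, the indicator coefficient `xi18`, then the nuisance
#'   transforms (`log_omega` for richness; `log_phi`, `logit_pi0` for
#'   abundance).
#' @param data Plot table.
#' @param response An [response_spec()] object.
#' @param spec An [abiotic_spec()]; defaults to one fitted on `data`.
#' @param indicator Indicator column name (default `"c_tot"`).
#' @return Scalar log-posterior (`-Inf` when the likelihood is infeasible).
#' @export
log_posterior <- function(theta, data, response, spec = abiotic_spec(data),
                          indicator = "c_tot") {
  stopifnot(inherits(response, "lf_response"))
  X <- design_matrix(data, spec, indicator = indicator)
  lp <- make_log_posterior(X, data[[response$column]], response$kind)
  lp(theta)
}
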