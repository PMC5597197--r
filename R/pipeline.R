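# Deterministic per-run seed: a small polynomial string hash of the run
# labels folded with the master seed, kept below 2^31.
run_seed <- function(master, ...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master)) %% 2147483647 + 1)
}

plots_of <- function(data) {
  if (inherits(data, "lf_dataset")) data$plots else data
}

init_theta <- function(y, kind, n_design_cols) {
  if (kind == "richness") {
    c(log(mean(y) + 0.1), rep(0, n_design_cols), 0)
  } else {
    pi0 <- min(0.9, max(0.02, mean(y == 0) - 0.05))
    mid <- c(0, 0.025, 0.15, 0.375, 0.625, 0.875)[y + 1]
    m <- min(max(mean(mid), 0.01), (1 - pi0) * 0.8)
    c(qlogis(m), rep(0, n_design_cols), log(4), qlogis(pi0))
  }
}

# Fit one model by MCMC. The coefficient block is sampled on a
# QR-orthogonalized basis (the posterior is invariant; priors are applied
# on the original coefficient scale through the back-transform, and draws
# are returned on the original scale). Orthogonalization decorrelates the
# spline design columns, which the component-wise kernel mixes over far
# faster than on the raw, heavily collinear basis.
fit_model_mcmc <- function(X, y, kind, offset = 0, config,
                           col_names = colnames(X), orthogonalize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_coef <- 1L + ncol(X)
  A <- NULL
  Xs <- X
  if (orthogonalize && ncol(X) > 0 && n > n_coef) {
    qrd <- qr(cbind(1, X))
    Q <- qr.Q(qrd)
    R <- qr.R(qrd)
    sgn <- sign(diag(R)); sgn[sgn == 0] <- 1
    Q <- sweep(Q, 2, sgn, `*`)
    R <- sweep(R, 1, sgn, `*`)
    Rs <- R / sqrt(n)
    A <- solve(Rs)            # xi = A %*% gamma
    Xs <- (Q * sqrt(n))[, -1, drop = FALSE]
  }
  lp <- make_log_posterior(Xs, y, kind, offset = offset, coef_transform = A)
  init <- init_theta(y, kind, ncol(X))
  if (!is.null(A))
    init[seq_len(n_coef)] <- solve(A, init[seq_len(n_coef)])
  fit <- run_sampler(lp, init, config)
  if (!is.null(A)) {
    fit$draws[, seq_len(n_coef)] <-
      fit$draws[, seq_len(n_coef), drop = FALSE] %*% t(A)
  }
  nms <- param_names(kind, if (is.null(col_names)) seq_len(ncol(X)) else col_names)
  colnames(fit$draws) <- nms
  names(fit$rhat) <- nms
  names(fit$acceptance$mwg) <- nms
  fit
}

#' Step 1: fit the full model on the whole plot network
#'
#' Fits the complete model — intercept, all 17 abiotic terms, the
#' structure-indicator coefficient and the nuisance parameters — on every
#' plot of a site, with total crown cover `c_tot` (the only structure
#' variable available everywhere) as the indicator. The posterior means of
#' the abiotic coefficients are stored for reuse as fixed values in step 2.
#'
#' @param data An `lf_dataset` or a plot tibble.
#' @param response An [response_spec()].
#' @param config A [sampler_config()].
#' @param indicator Indicator column (default `"c_tot"`).
#' @param spec Optional [abiotic_spec()]; fitted on `data` when `NULL`.
#' @return An object of class `lf_step1`: `draws` (`lf_draws`), `xi_mean`
#'   (posterior means: intercept, abiotic terms, indicator), `spec`,
#'   `response`, `converged`.
#' @export
fit_step1 <- function(data, response, config = sampler_config(),
                      indicator = "c_tot", spec = NULL) {
  plots <- plots_of(data)
  stopifnot(inherits(response, "lf_response"))
  if (is.null(spec)) spec <- abiotic_spec(plots)
  X <- design_matrix(plots, spec, indicator = indicator)
  y <- plots[[response$column]]
  fit <- fit_model_mcmc(X, y, response$kind, config = config)
  n_xi <- 1L + ncol(X)
  xi_mean <- colMeans(fit$draws)[seq_len(n_xi)]
  if (!fit$converged)
    warning("step-1 sampler did not reach the Rhat threshold; ",
            "treat downstream runs with caution")
  structure(list(draws = fit, xi_mean = xi_mean, spec = spec,
                 response = response, indicator = indicator,
                 converged = fit$converged),
            class = "lf_step1")
}

#' @export
print.lf_step1 <- function(x, ...) {
  cat(sprintf("<lf_step1> %s (%s), %s\n", x$response$column, x$response$kind,
              if (x$converged) "converged" else "NOT converged"))
  print(x$draws)
  invisible(x)
}

#' Step 2: test one ALS variable on the lidar-covered subset
#'
#' Refits the model on the subset of plots with ALS coverage, replacing the
#' step-1 structure indicator by one ALS variable. Only the intercept, the
#' indicator coefficient and the nuisance parameters are sampled; the
#' abiotic contribution enters as a fixed per-plot offset evaluated at the
#' step-1 posterior means (using the step-1 covariate scaling and knots).
#' A reference model without the indicator is fitted on the same subset,
#' giving the DIC difference, and the indicator effect is classified by
#' empirical significance and negligibility.
#'
#' @param data Plot tibble of the ALS-covered subset, containing the
#'   indicator column (rows with missing indicator values are dropped with
#'   a message).
#' @param response An [response_spec()].
#' @param indicator Name of the ALS variable column (or `"c_tot"`).
#' @param step1 The [fit_step1()] result for this response.
#' @param config A [sampler_config()].
#' @param radius Optional extraction radius label carried into the result.
#' @param offset_terms `"all"` holds every abiotic term fixed;
#'   `"reaction_swc"` retains only the soil terms in the offset.
#' @return An object of class `lf_run`.
#' @export
fit_step2 <- function(data, response, indicator, step1,
                      config = sampler_config(), radius = NA,
                      offset_terms = c("all", "reaction_swc")) {
  plots <- plots_of(data)
  offset_terms <- match.arg(offset_terms)
  stopifnot(inherits(step1, "lf_step1"), indicator %in% names(plots))
  miss <- !is.finite(plots[[indicator]])
  if (any(miss)) {
    message(sum(miss), " plot(s) with missing indicator values dropped")
    plots <- plots[!miss, , drop = FALSE]
  }
  X_ab <- design_matrix(plots, step1$spec)
  keep_cols <- if (offset_terms == "all") colnames(X_ab)
               else grep("^(reaction|swc)", colnames(X_ab), value = TRUE)
  ab_coef <- step1$xi_mean[paste0("b_", keep_cols)]
  offset <- drop(X_ab[, keep_cols, drop = FALSE] %*% ab_coef)
  sd_ind <- sd(plots[[indicator]])
  if (!is.finite(sd_ind) || sd_ind == 0) stop("indicator is constant on the subset")
  Xi <- matrix((plots[[indicator]] - mean(plots[[indicator]])) / sd_ind, ncol = 1,
               dimnames = list(NULL, "indicator"))
  y <- plots[[response$column]]
  kind <- response$kind

  fit <- fit_model_mcmc(Xi, y, kind, offset = offset, config = config)

  X0 <- matrix(numeric(0), nrow = nrow(plots), ncol = 0)
  cfg_ref <- config
  cfg_ref$seed <- run_seed(config$seed, "reference", indicator)
  fit_ref <- fit_model_mcmc(X0, y, kind, offset = offset, config = cfg_ref,
                            col_names = character(0))

  ll_with <- make_loglik(Xi, y, kind, offset = offset)
  ll_ref <- make_loglik(X0, y, kind, offset = offset)
  dic <- mode_dic(fit, ll_with)
  dic_ref <- mode_dic(fit_ref, ll_ref)
  ddic <- delta_dic(dic, dic_ref)

  beta <- fit$draws[, "b_indicator"]
  assessment <- assess_run(beta, kind, sd_als = 1, delta_dic = ddic)
  structure(list(
    response = response, indicator = indicator, radius = radius,
    draws = fit, draws_reference = fit_ref,
    dic = dic, dic_reference = dic_ref, delta_dic = ddic,
    assessment = assessment, sd_indicator = sd_ind, offset = offset,
    n_plots = nrow(plots), converged = fit$converged && fit_ref$converged
  ), class = "lf_run")
}

#' @export
print.lf_run <- function(x, ...) {
  cat(sprintf("<lf_run> %s ~ %s (radius %s): DIC %.2f (ref %.2f, delta %.2f)\n",
              x$response$column, x$indicator, format(x$radius),
              x$dic, x$dic_reference, x$delta_dic))
  cat(sprintf("  effect %.3f +/- %.3f, p = %.3f -> %s\n",
              x$assessment$effect_mean, x$assessment$effect_sd,
              x$assessment$p_value, x$assessment$effect_class))
  invisible(x)
}

#' Plan the model-run grid
#'
#' Enumerates one run per response x ALS variable x extraction radius —
#' the bookkeeping grid over which [run_all()] iterates (e.g. 8 abundance
#' responses and 3 richness groups x 10 variables x 4 radii = 440 runs per
#' site).
#'
#' @param responses Named character vector mapping response column names to
#'   kinds (`"richness"`/`"abundance"`), or a list of [response_spec()]s.
#' @param indicators Character vector of ALS variable names.
#' @param radii Vector of radius labels.
#' @return Tibble with columns `response`, `kind`, `indicator`, `radius`.
#' @export
plan_runs <- function(responses, indicators, radii) {
  if (is.list(responses) && all(vapply(responses, inherits, logical(1), "lf_response")))
    responses <- setNames(vapply(responses, `[[`, character(1), "kind"),
                          vapply(responses, `[[`, character(1), "column"))
  stopifnot(!is.null(names(responses)), all(responses %in% c("richness", "abundance")))
  tidyr::expand_grid(
    response = names(responses), indicator = indicators, radius = radii
  ) |>
    dplyr::mutate(kind = unname(responses[.data$response]), .after = "response")
}

#' Run the full two-step analysis grid
#'
#' Fits step 1 once per response on the full plot network, then one step-2
#' model per row of the run plan on the lidar-covered subset. Per-run
#' sampler seeds are derived from the master seed and the run labels, so
#' the grid is reproducible and each run has an independent stream.
#'
#' @param dataset An `lf_dataset` (or a plot tibble with an `als_covered`
#'   column).
#' @param responses As in [plan_runs()].
#' @param indicators ALS variable columns; these must be present on the
#'   covered subset, either already in the plot table or supplied via
#'   `metrics`.
#' @param radii Radius labels (the synthetic per-plot clouds support the
#'   field-plot radius).
#' @param config Sampler configuration; its `seed` acts as the master seed.
#' @param metrics Optional tibble from [extract_dataset_metrics()] joined
#'   onto the covered subset by `plot_id`.
#' @param site Site label recorded in the summary.
#' @return A list with `runs` (list of `lf_run`), `step1` (per response),
#'   and `summary` (one row per run, ready for [count_tables()]).
#' @export
run_all <- function(dataset, responses, indicators, radii = "plot",
                    config = sampler_config(), metrics = NULL, site = NULL) {
  plots <- plots_of(dataset)
  if (is.null(site))
    site <- if (inherits(dataset, "lf_dataset")) dataset$site else "site"
  plan <- plan_runs(responses, indicators, radii)
  spec <- abiotic_spec(plots)
  sub <- dplyr::filter(plots, .data$als_covered)
  if (!is.null(metrics)) sub <- dplyr::left_join(sub, metrics, by = "plot_id")

  step1 <- list()
  for (resp in unique(plan$response)) {
    kind <- plan$kind[match(resp, plan$response)]
    cfg <- config
    cfg$seed <- run_seed(config$seed, site, resp, "step1")
    step1[[resp]] <- fit_step1(plots, response_spec(kind, resp), cfg,
                               spec = spec)
  }

  runs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cfg <- config
    cfg$seed <- run_seed(config$seed, site, row$response, row$indicator,
                         row$radius)
    runs[[i]] <- tryCatch(
      fit_step2(sub, response_spec(row$kind, row$response), row$indicator,
                step1[[row$response]], cfg, radius = row$radius),
      error = function(e) {
        message("run ", i, " (", row$response, " ~ ", row$indicator,
                ") failed: ", conditionMessage(e))
        NULL
      })
  }
  summary <- purrr::imap_dfr(runs, function(r, i) {
    row <- plan[i, ]
    base <- tibble::tibble(site = site, response = row$response,
                           kind = row$kind, indicator = row$indicator,
                           radius = row$radius)
    if (is.null(r)) return(dplyr::mutate(base, failed = TRUE))
    dplyr::bind_cols(
      base,
      tibble::tibble(dic = r$dic, dic_reference = r$dic_reference,
                     converged = r$converged, failed = FALSE),
      r$assessment
    )
  })
  list(runs = runs, step1 = step1, summary = summary)
}
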