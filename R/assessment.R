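# The six combined effect classes used in the count summaries.
effect_class_levels <- c(
  "Significant: Negligible",
  "Significant: Negative non-negligible",
  "Significant: Positive non-negligible",
  "Significant: No info",
  "Non-significant: Negligible",
  "Non-significant: No info"
)

#' Negligibility bounds for a response kind
#'
#' Half-widths of the narrow (`b1`) and wide (`b2`) equivalence intervals
#' for the per-standard-deviation effect: 0.25/0.5 on the logit scale for
#' abundance, 0.1/0.2 on the log scale for richness.
#'
#' @param kind `"richness"` or `"abundance"`.
#' @return Named vector `c(b1, b2)`.
#' @export
negligibility_bounds <- function(kind = c("richness", "abundance")) {
  kind <- match.arg(kind)
  if (kind == "abundance") c(b1 = 0.25, b2 = 0.5) else c(b1 = 0.1, b2 = 0.2)
}

#' Mode-based deviance information criterion
#'
#' \eqn{DIC = 2\,\overline{D(\theta)} - D(\hat\theta)} with deviance
#' \eqn{D = -2\,\log L} and the plug-in \eqn{\hat\theta} taken as the
#' sampled draw with the highest posterior density (a mode estimate, more
#' stable than the posterior mean for skewed posteriors).
#'
#' @param draws An `lf_draws` object, or a draw matrix.
#' @param loglik_fn Function returning the total data log-likelihood at one
#'   parameter vector.
#' @param log_post Per-draw log-posterior values (taken from `draws` when it
#'   is an `lf_draws`); used only to locate the plug-in draw.
#' @return Scalar DIC.
#' @export
mode_dic <- function(draws, loglik_fn, log_post = NULL) {
  if (inherits(draws, "lf_draws")) {
    if (is.null(log_post)) log_post <- draws$log_post
    draws <- draws$draws
  }
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) > 0)
  if (is.null(log_post)) stop("log_post values are needed to locate the plug-in draw")
  D <- -2 * apply(draws, 1, loglik_fn)
  theta_hat <- draws[which.max(log_post), ]
  2 * mean(D) - (-2 * loglik_fn(theta_hat))
}

#' DIC difference between models with and without the ALS predictor
#'
#' Negative values favour the model that includes the structure variable.
#'
#' @param with_als,without_als DIC values computed on the same data subset.
#' @return `with_als - without_als`.
#' @export
delta_dic <- function(with_als, without_als) with_als - without_als

#' Empirical two-tailed significance of an effect
#'
#' \eqn{p = 2 \min(\#\{\beta > 0\}, \#\{\beta < 0\}) / n}; draws exactly
#' zero are split evenly between the two tails.
#'
#' @param beta_draws Posterior draws of the effect parameter.
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(beta_draws) {
  n <- length(beta_draws)
  if (n < 100) stop("at least 100 draws are needed for the empirical test")
  n_pos <- sum(beta_draws > 0) + 0.5 * sum(beta_draws == 0)
  n_neg <- sum(beta_draws < 0) + 0.5 * sum(beta_draws == 0)
  min(1, 2 * min(n_pos, n_neg) / n)
}

#' Significance class of an empirical p-value
#'
#' `"**"` (highly significant) for p <= 0.01, `"*"` for 0.01 < p <= 0.05,
#' `"ns"` otherwise.
#'
#' @param p Empirical p-value.
#' @return Character class.
#' @export
significance_class <- function(p) {
  dplyr::case_when(p <= 0.01 ~ "**", p <= 0.05 ~ "*", .default = "ns")
}

#' Equivalence (negligibility) classification of an effect
#'
#' Classifies the per-standard-deviation effect \eqn{e = \beta\,sd} by
#' posterior interval probabilities: `"00"` (strongly negligible) when
#' \eqn{P(|e| < b_1) > 0.95}; `"0"` when \eqn{P(|e| < b_2) > 0.95}; `"--"`
#' / `"-"` when \eqn{P(e < -b_2)} / \eqn{P(e < -b_1) \ge 0.95}; `"++"` /
#' `"+"` when \eqn{P(e > b_2)} / \eqn{P(e > b_1) \ge 0.95}; otherwise
#' `"no-info"`. Two-sided checks are strict (> 0.95) and one-sided checks
#' inclusive (>= 0.95), with the stronger claim tested first.
#'
#' @param beta_draws Posterior draws of the effect parameter.
#' @param sd_als Standard deviation of the ALS variable over the fitted
#'   subset (1 when the variable was standardized before fitting).
#' @param bounds `c(b1, b2)` from [negligibility_bounds()].
#' @return One of `"00"`, `"0"`, `"-"`, `"--"`, `"+"`, `"++"`, `"no-info"`.
#' @export
classify_negligibility <- function(beta_draws, sd_als = 1,
                                   bounds = negligibility_bounds("richness")) {
  stopifnot(sd_als > 0, length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  e <- beta_draws * sd_als
  b1 <- bounds[[1]]; b2 <- bounds[[2]]
  if (mean(abs(e) < b1) > 0.95) return("00")
  if (mean(abs(e) < b2) > 0.95) return("0")
  if (mean(e < -b2) >= 0.95) return("--")
  if (mean(e < -b1) >= 0.95) return("-")
  if (mean(e > b2) >= 0.95) return("++")
  if (mean(e > b1) >= 0.95) return("+")
  "no-info"
}

#' Combined significance x negligibility class
#'
#' Maps a significance class and negligibility symbol to one of the six
#' summary classes: significant effects split into Negligible, Negative
#' non-negligible, Positive non-negligible and No info; non-significant
#' effects only into Negligible and No info.
#'
#' @param significance `"**"`, `"*"` or `"ns"`.
#' @param symbol Output of [classify_negligibility()].
#' @return One of the six class labels.
#' @export
combined_class <- function(significance, symbol) {
  stopifnot(significance %in% c("**", "*", "ns"),
            symbol %in% c("00", "0", "-", "--", "+", "++", "no-info"))
  if (significance == "ns") {
    if (symbol %in% c("00", "0")) return("Non-significant: Negligible")
    return("Non-significant: No info")
  }
  direction <- switch(symbol,
    "00" = , "0" = "Negligible",
    "-" = , "--" = "Negative non-negligible",
    "+" = , "++" = "Positive non-negligible",
    "no-info" = "No info")
  paste0("Significant: ", direction)
}

#' Assess one model run
#'
#' Computes the empirical p-value, significance class, negligibility symbol
#' and combined effect class of an indicator-effect posterior.
#'
#' @param beta_draws Posterior draws of the indicator coefficient.
#' @param kind Response kind (selects the negligibility bounds).
#' @param sd_als Indicator standard deviation over the fitted subset.
#' @param delta_dic Optional DIC difference carried into the result.
#' @return One-row tibble with `p_value`, `significance`, `symbol`,
#'   `effect_class`, `effect_mean`, `effect_sd`, `delta_dic`.
#' @export
assess_run <- function(beta_draws, kind = c("richness", "abundance"),
                       sd_als = 1, delta_dic = NA_real_) {
  kind <- match.arg(kind)
  p <- empirical_pvalue(beta_draws)
  sig <- significance_class(p)
  sym <- classify_negligibility(beta_draws, sd_als, negligibility_bounds(kind))
  e <- beta_draws * sd_als
  tibble::tibble(
    p_value = p, significance = sig, symbol = sym,
    effect_class = combined_class(sig, sym),
    effect_mean = mean(e), effect_sd = sd(e), delta_dic = delta_dic
  )
}

complete_counts <- function(df, ..., classes = effect_class_levels) {
  df |>
    dplyr::mutate(effect_class = factor(.data$effect_class, levels = classes)) |>
    dplyr::count(..., .data$effect_class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "effect_class", values_from = "n",
                       values_fill = 0L)
}

#' Count and DIC summaries over a set of classified runs
#'
#' Cross-tabulates the combined effect classes by site x response kind, by
#' ALS variable and by extraction radius, and summarizes the DIC-difference
#' distributions per response and per ALS variable (median, quartiles,
#' minimum). The per-radius table counts runs whose effect was negative or
#' positive non-negligible.
#'
#' @param runs Tibble with one row per classified run; columns `site`,
#'   `kind`, `response`, `indicator`, `radius`, `effect_class` and
#'   `delta_dic`.
#' @return A list of tibbles: `by_site_kind`, `by_variable`, `by_radius`,
#'   `delta_dic_by_response`, `delta_dic_by_variable`.
#' @export
count_tables <- function(runs) {
  needed <- c("site", "kind", "response", "indicator", "radius",
              "effect_class", "delta_dic")
  stopifnot(all(needed %in% names(runs)))
  if (nrow(runs) == 0) {
    zero <- tibble::as_tibble(setNames(
      rep(list(integer(0)), length(effect_class_levels)), effect_class_levels))
    empty_dic <- tibble::tibble(site = character(0), n = integer(0),
                                median = numeric(0), q25 = numeric(0),
                                q75 = numeric(0), min = numeric(0))
    return(list(
      by_site_kind = dplyr::bind_cols(
        tibble::tibble(site = character(0), kind = character(0)), zero),
      by_variable = dplyr::bind_cols(
        tibble::tibble(site = character(0), indicator = character(0)), zero),
      by_radius = tibble::tibble(site = character(0), radius = character(0),
                                 n_models = integer(0),
                                 n_non_negligible = integer(0),
                                 n_significant = integer(0)),
      delta_dic_by_response = dplyr::mutate(empty_dic, response = character(0)),
      delta_dic_by_variable = dplyr::mutate(empty_dic, indicator = character(0))
    ))
  }
  dic_summary <- function(df, ...) {
    df |>
      dplyr::filter(is.finite(.data$delta_dic)) |>
      dplyr::group_by(...) |>
      dplyr::summarise(
        n = dplyr::n(),
        median = median(.data$delta_dic),
        q25 = quantile(.data$delta_dic, 0.25),
        q75 = quantile(.data$delta_dic, 0.75),
        min = min(.data$delta_dic),
        .groups = "drop")
  }
  non_negl <- c("Significant: Negative non-negligible",
                "Significant: Positive non-negligible")
  list(
    by_site_kind = complete_counts(runs, .data$site, .data$kind),
    by_variable = complete_counts(runs, .data$site, .data$indicator),
    by_radius = runs |>
      dplyr::group_by(.data$site, .data$radius) |>
      dplyr::summarise(
        n_models = dplyr::n(),
        n_non_negligible = sum(.data$effect_class %in% non_negl),
        n_significant = sum(.data$effect_class != "Non-significant: Negligible" &
                              .data$effect_class != "Non-significant: No info"),
        .groups = "drop"),
    delta_dic_by_response = dic_summary(runs, .data$site, .data$response),
    delta_dic_by_variable = dic_summary(runs, .data$site, .data$indicator)
  )
}
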