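#' Tidy posterior draws
#'
#' One row per parameter with posterior mean, sd, central 95% interval and
#' the split Rhat.
#'
#' @param x An `lf_draws` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lf_draws <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, probs = c(0.025, 0.5, 0.975))
  nms <- colnames(x$draws)
  if (is.null(nms)) nms <- paste0("theta", seq_len(ncol(x$draws)))
  tibble::tibble(
    term = nms,
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, sd),
    conf.low = qs[1, ], median = qs[2, ], conf.high = qs[3, ],
    rhat = unname(x$rhat)
  )
}

#' Glance at a sampler run
#'
#' @param x An `lf_draws` object.
#' @param ... Unused.
#' @return One-row tibble of run-level diagnostics.
#' @export
glance.lf_draws <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws), n_parameters = ncol(x$draws),
    thin_by = x$thin_by, converged = x$converged,
    n_iterations = x$n_iterations,
    max_rhat = if (any(is.finite(x$rhat))) max(x$rhat, na.rm = TRUE) else NA_real_,
    de_acceptance = x$acceptance$de
  )
}

#' @export
tidy.lf_step1 <- function(x, ...) tidy(x$draws, ...)

#' @export
glance.lf_step1 <- function(x, ...) {
  dplyr::mutate(glance(x$draws), response = x$response$column,
                kind = x$response$kind, .before = 1)
}

#' Tidy a step-2 model run
#'
#' Returns the classified indicator effect: posterior summary, empirical
#' p-value, negligibility symbol, combined class and DIC difference.
#'
#' @param x An `lf_run` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.lf_run <- function(x, ...) {
  dplyr::mutate(x$assessment,
                response = x$response$column, kind = x$response$kind,
                indicator = x$indicator, radius = x$radius, .before = 1)
}

#' @export
glance.lf_run <- function(x, ...) {
  tibble::tibble(
    response = x$response$column, indicator = x$indicator,
    radius = x$radius, n_plots = x$n_plots,
    dic = x$dic, dic_reference = x$dic_reference, delta_dic = x$delta_dic,
    converged = x$converged
  )
}
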