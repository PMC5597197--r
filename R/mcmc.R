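#' Sampler configuration
#'
#' Settings for the adaptive MCMC: a population of trajectories, most at
#' temperature 1 and a few heated on a geometric ladder, advanced by
#' component-wise Metropolis-within-Gibbs sweeps plus differential-
#' evolution proposals, with equi-energy state exchanges between
#' temperatures. Proposal scales adapt towards a target acceptance rate on
#' a diminishing schedule; convergence is declared when every parameter's
#' split Gelman-Rubin Rhat over the cold trajectories falls below
#' `rhat_threshold`, after which draws are collected and thinned until the
#' mean absolute lag-1 autocorrelation of the retained draws is at or below
#' `thin_target`.
#'
#' @param n_trajectories Number of trajectories (default 17).
#' @param n_tempered Number of heated trajectories (default 4; temperatures
#'   2, 4, 8, 16 unless `temperatures` is supplied).
#' @param temperatures Optional explicit temperature per trajectory.
#' @param crossover Crossover probabilities the differential-evolution
#'   kernel draws from.
#' @param rhat_threshold Convergence bound on Rhat (default 1.007).
#' @param n_posterior_draws Number of post-convergence draws to return
#'   (default 2000).
#' @param thin_target Average absolute successive-state correlation the
#'   thinned draws must reach (default 0.01).
#' @param adapt_target Metropolis-within-Gibbs acceptance target (0.44, the
#'   scalar-update optimum).
#' @param adapt_decay Diminishing-adaptation decay exponent in (0.5, 1].
#' @param max_iterations Adaptation/burn-in budget before collection starts
#'   regardless of convergence.
#' @param min_adapt,check_every First iteration and cadence of convergence
#'   checks.
#' @param swap_every Iterations between equi-energy exchange attempts.
#' @param n_rings,ring_refresh Number of energy rings and refresh cadence.
#' @param de_gamma_mode_prob Probability of the mode-jumping step size
#'   (gamma = 1) instead of 2.38/sqrt(2 d).
#' @param de_jitter_sd Standard deviation of the differential-evolution
#'   jitter.
#' @param init_scale Initial Metropolis-within-Gibbs proposal sd.
#' @param init_jitter Sd of the overdispersion applied to trajectory
#'   starting points.
#' @param max_thin Cap on the thinning lag.
#' @param max_collect Cap on post-convergence collection iterations.
#' @param archive_every,archive_max Cadence and capacity of the past-state
#'   archive from which differential-evolution difference pairs may be
#'   drawn (helps small populations follow correlated directions).
#' @param seed Integer seed; the whole run is a pure function of it.
#' @return A list of class `lf_sampler_config`.
#' @export
sampler_config <- function(n_trajectories = 17, n_tempered = 4,
                           temperatures = NULL, crossover = c(1/3, 2/3, 1),
                           rhat_threshold = 1.007, n_posterior_draws = 2000,
                           thin_target = 0.01, adapt_target = 0.44,
                           adapt_decay = 0.66, max_iterations = 20000,
                           min_adapt = 500, check_every = 250,
                           swap_every = 10, n_rings = 5, ring_refresh = 1000,
                           de_gamma_mode_prob = 0.1, de_jitter_sd = 1e-6,
                           init_scale = 0.5, init_jitter = 0.5,
                           max_thin = 50, max_collect = 20000,
                           archive_every = 10, archive_max = 1000,
                           seed = 1L) {
  if (n_tempered >= n_trajectories)
    stop("n_tempered must be smaller than n_trajectories")
  if (rhat_threshold <= 1) stop("rhat_threshold must exceed 1")
  if (any(crossover <= 0 | crossover > 1)) stop("crossover probabilities must be in (0, 1]")
  if (adapt_decay <= 0.5 || adapt_decay > 1) stop("adapt_decay must be in (0.5, 1]")
  if (is.null(temperatures))
    temperatures <- c(rep(1, n_trajectories - n_tempered), 2^seq_len(n_tempered))
  stopifnot(length(temperatures) == n_trajectories, all(temperatures >= 1))
  structure(as.list(environment()), class = "lf_sampler_config")
}

#' Differential-evolution proposal
#'
#' Proposes `current + gamma * (a - b) + jitter` on a crossover-selected
#' coordinate subset, where `a` and `b` are two distinct members of the
#' population other than the current state. The difference vector is
#' symmetric in distribution, so the move is a valid Metropolis proposal.
#'
#' @param current Numeric parameter vector.
#' @param population Matrix of population states (one row per member;
#'   at least 3 rows).
#' @param crossover Probability that each coordinate is updated (at least
#'   one always is).
#' @param gamma Step length; default 2.38/sqrt(2 d_updated) with
#'   probability `1 - gamma_mode_prob`, else 1.
#' @param gamma_mode_prob Probability of the mode-jumping gamma = 1.
#' @param jitter_sd Sd of the additive jitter.
#' @return Proposed parameter vector (attribute `"mask"` marks updated
#'   coordinates).
#' @export
de_proposal <- function(current, population, crossover = 1, gamma = NULL,
                        gamma_mode_prob = 0.1, jitter_sd = 1e-6) {
  population <- as.matrix(population)
  if (nrow(population) < 3) stop("population must have at least 3 members")
  d <- length(current)
  mask <- runif(d) < crossover
  if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
  pair <- sample.int(nrow(population), 2)
  ab <- population[pair[1], ] - population[pair[2], ]
  if (is.null(gamma))
    gamma <- if (runif(1) < gamma_mode_prob) 1 else 2.38 / sqrt(2 * sum(mask))
  prop <- current
  prop[mask] <- current[mask] + gamma * ab[mask] +
    rnorm(sum(mask), 0, jitter_sd)
  attr(prop, "mask") <- mask
  prop
}

#' One Metropolis-within-Gibbs sweep
#'
#' Cycles through the coordinates of the current state, proposing each from
#' a Gaussian random walk and accepting with the (optionally tempered)
#' Metropolis ratio. Proposals whose log-posterior evaluates to `NaN` are
#' treated as `-Inf` and rejected.
#'
#' @param current Numeric parameter vector.
#' @param scales Positive proposal sd per coordinate.
#' @param log_post Function mapping a parameter vector to a scalar
#'   log-posterior.
#' @param temperature Tempering temperature (>= 1).
#' @param lp Current log-posterior (recomputed when `NULL`).
#' @return List with `theta`, `lp` and logical `accepted` per coordinate.
#' @export
mwg_step <- function(current, scales, log_post, temperature = 1, lp = NULL) {
  d <- length(current)
  scales <- rep_len(scales, d)
  if (any(scales <= 0)) stop("scales must be positive")
  if (is.null(lp)) lp <- log_post(current)
  accepted <- logical(d)
  for (j in seq_len(d)) {
    prop <- current
    prop[j] <- current[j] + rnorm(1) * scales[j]
    lpn <- log_post(prop)
    if (is.nan(lpn)) lpn <- -Inf
    if (log(runif(1)) < (lpn - lp) / temperature) {
      current <- prop; lp <- lpn; accepted[j] <- TRUE
    }
  }
  list(theta = current, lp = lp, accepted = accepted)
}

#' Run a plain Metropolis-within-Gibbs chain
#'
#' Repeated [mwg_step()] sweeps without adaptation; useful as a bare
#' sampling kernel on cheap targets.
#'
#' @inheritParams mwg_step
#' @param init Starting parameter vector.
#' @param n_steps Number of sweeps.
#' @param seed Optional seed.
#' @return List with `draws` (n_steps x d matrix), `lp` and the overall
#'   acceptance rate per coordinate.
#' @export
mwg_chain <- function(log_post, init, n_steps, scales, temperature = 1,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  scales <- rep_len(scales, d)
  draws <- matrix(NA_real_, n_steps, d)
  lps <- numeric(n_steps)
  acc <- numeric(d)
  th <- init
  lp <- log_post(th)
  for (t in seq_len(n_steps)) {
    st <- mwg_step(th, scales, log_post, temperature, lp)
    th <- st$theta; lp <- st$lp
    acc <- acc + st$accepted
    draws[t, ] <- th
    lps[t] <- lp
  }
  list(draws = draws, lp = lps, acceptance = acc / n_steps)
}

#' Equi-energy state exchange between temperatures
#'
#' Attempts one state swap between two trajectories at different
#' temperatures whose current log-posteriors fall in the same energy ring,
#' accepted with the tempering exchange ratio
#' \eqn{\min(1, \exp((1/T_i - 1/T_j)(\ell_j - \ell_i)))}. No eligible pair
#' is a no-op.
#'
#' @param theta Matrix of trajectory states (rows).
#' @param lp Log-posterior per trajectory.
#' @param temperatures Temperature per trajectory.
#' @param ring_breaks Interior break points of the energy rings; computed
#'   from `lp` quantiles when `NULL`.
#' @param n_rings Number of rings used when computing breaks.
#' @return List with updated `theta`, `lp` and the number of accepted
#'   swaps.
#' @export
equi_energy_swap <- function(theta, lp, temperatures, ring_breaks = NULL,
                             n_rings = 5) {
  if (length(unique(temperatures)) < 2) return(list(theta = theta, lp = lp, swaps = 0L))
  if (is.null(ring_breaks)) {
    fin <- lp[is.finite(lp)]
    if (length(fin) < 2) return(list(theta = theta, lp = lp, swaps = 0L))
    ring_breaks <- unique(quantile(fin, probs = seq_len(n_rings - 1) / n_rings))
  }
  ring <- findInterval(lp, ring_breaks)
  idx <- which(is.finite(lp))
  pairs <- which(outer(temperatures[idx], temperatures[idx], "!=") &
                   outer(ring[idx], ring[idx], "==") &
                   upper.tri(matrix(TRUE, length(idx), length(idx))),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) return(list(theta = theta, lp = lp, swaps = 0L))
  pick <- pairs[sample.int(nrow(pairs), 1), ]
  i <- idx[pick[1]]; j <- idx[pick[2]]
  log_ratio <- (1 / temperatures[i] - 1 / temperatures[j]) * (lp[j] - lp[i])
  swaps <- 0L
  if (log(runif(1)) < log_ratio) {
    tmp <- theta[i, ]; theta[i, ] <- theta[j, ]; theta[j, ] <- tmp
    tmp <- lp[i]; lp[i] <- lp[j]; lp[j] <- tmp
    swaps <- 1L
  }
  list(theta = theta, lp = lp, swaps = swaps)
}

#' Diminishing-adaptation scale update
#'
#' Moves each proposal scale towards the target acceptance rate by a
#' multiplicative step whose size decays as `iteration^(-decay)`, so total
#' adaptation vanishes as the chain runs (diminishing adaptation).
#'
#' @param scales Current proposal sds.
#' @param accept Realized acceptance rate(s) over the last batch.
#' @param iteration Current iteration number (>= 1).
#' @param target Target acceptance rate (default 0.44).
#' @param decay Decay exponent in (0.5, 1].
#' @param c0 Step-size constant.
#' @return Updated scales, with the step size as attribute `"step"`.
#' @export
adapt_scales <- function(scales, accept, iteration, target = 0.44,
                         decay = 0.66, c0 = 10) {
  stopifnot(iteration >= 1)
  step <- min(0.5, c0 * iteration^(-decay))
  out <- scales * exp(ifelse(accept > target, step, -step))
  attr(out, "step") <- step
  out
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor per parameter, computed after splitting
#' every chain in half (so within-chain trends register as between-chain
#' variance).
#'
#' @param chains A list of draw matrices (iterations x parameters), a
#'   single matrix, or a 3-d array (iterations x chains x parameters).
#' @return Named numeric vector of Rhat values (`NA` where the within-chain
#'   variance is zero in all segments).
#' @export
gelman_rubin <- function(chains) {
  if (is.array(chains) && length(dim(chains)) == 3) {
    d3 <- dim(chains)[3]
    chains <- lapply(seq_len(dim(chains)[2]), function(c2)
      matrix(chains[, c2, ], ncol = d3))
  }
  if (is.matrix(chains) || is.numeric(chains)) chains <- list(chains)
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    if (nrow(ch) < 10) stop("each chain needs at least 10 draws")
    ch
  })
  n2 <- floor(min(vapply(chains, nrow, numeric(1))) / 2)
  segs <- unlist(lapply(chains, function(ch) {
    n <- nrow(ch)
    list(ch[(n - 2 * n2 + 1):(n - n2), , drop = FALSE],
         ch[(n - n2 + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  d <- ncol(segs[[1]])
  rhat <- vapply(seq_len(d), function(p) {
    x <- vapply(segs, function(s) c(mean(s[, p]), var(s[, p])), numeric(2))
    W <- mean(x[2, ])
    if (W == 0) return(NA_real_)
    B_over_n <- var(x[1, ])
    sqrt(((n2 - 1) / n2 * W + B_over_n) / W)
  }, numeric(1))
  names(rhat) <- colnames(chains[[1]])
  rhat
}

# Smallest lag k at which the mean absolute lag-k autocorrelation across
# parameters (and chains) is at or below `target`.
thin_lag <- function(chains, target = 0.01, max_lag = 100) {
  if (is.matrix(chains) || is.numeric(chains)) chains <- list(as.matrix(chains))
  chains <- lapply(chains, as.matrix)
  max_lag <- min(max_lag, min(vapply(chains, nrow, numeric(1))) - 1)
  acmat <- lapply(chains, function(ch) {
    apply(ch, 2, function(x) {
      if (var(x) == 0) return(rep(NA_real_, max_lag))
      drop(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)[-1]
    })
  })
  ac <- do.call(cbind, acmat)
  if (all(is.na(ac))) return(structure(NA_integer_, reached = FALSE))
  mean_abs <- rowMeans(abs(ac), na.rm = TRUE)
  k <- which(mean_abs <= target)
  if (length(k) == 0) structure(as.integer(max_lag), reached = FALSE)
  else structure(as.integer(min(k)), reached = TRUE)
}

#' Thin draws to a target successive-state correlation
#'
#' Finds the smallest lag at which the mean absolute autocorrelation across
#' parameters is at or below `target` and keeps every lag-th draw. When the
#' target is unreachable within `max_lag` the maximum lag is used and the
#' result flagged; constant (zero-variance) streams are flagged undefined
#' and returned unthinned.
#'
#' @param draws Draw matrix (iterations x parameters).
#' @param target Mean absolute autocorrelation target (default 0.01).
#' @param max_lag Largest lag considered.
#' @return The thinned matrix with attributes `"lag"` and `"reached"`.
#' @export
thin_to_correlation <- function(draws, target = 0.01, max_lag = 100) {
  draws <- as.matrix(draws)
  k <- thin_lag(draws, target, max_lag)
  if (is.na(k)) {
    attr(draws, "lag") <- NA_integer_
    attr(draws, "reached") <- FALSE
    return(draws)
  }
  out <- draws[seq(k, nrow(draws), by = k), , drop = FALSE]
  attr(out, "lag") <- as.integer(k)
  attr(out, "reached") <- attr(k, "reached")
  out
}

#' Run the adaptive sampler
#'
#' Orchestrates the trajectory population: every iteration each trajectory
#' receives a Metropolis-within-Gibbs sweep and a differential-evolution
#' proposal (difference pairs drawn from a thinned archive of past states
#' once available, otherwise from the other trajectories); equi-energy
#' exchanges between temperatures are attempted periodically; proposal
#' scales adapt on the diminishing schedule. Convergence is monitored by
#' split Rhat over the temperature-1 trajectories; once reached (or the
#' iteration budget is exhausted), adaptation stops and draws are collected
#' from the cold trajectories, thinned to the configured successive-state
#' correlation, and returned.
#'
#' @param log_post Log-posterior function of the parameter vector.
#' @param init Starting parameter vector (optionally named), or a matrix
#'   with one row per trajectory.
#' @param config A [sampler_config()].
#' @return An object of class `lf_draws`: `draws` (matrix
#'   `n_posterior_draws` x d), `log_post` per draw, `rhat`, `acceptance`,
#'   `thin_by`, `converged`, `n_iterations`, `adapt_steps`, `config`.
#' @export
run_sampler <- function(log_post, init, config = sampler_config()) {
  set.seed(config$seed)
  n_traj <- config$n_trajectories
  temps <- config$temperatures
  if (is.matrix(init)) {
    stopifnot(nrow(init) == n_traj)
    theta <- init
    d <- ncol(init)
    par_names <- colnames(init)
  } else {
    d <- length(init)
    par_names <- names(init)
    theta <- matrix(rep(as.numeric(init), each = n_traj), n_traj, d)
    theta <- theta + rnorm(n_traj * d, 0, config$init_jitter)
    theta[1, ] <- as.numeric(init)
  }
  lp <- apply(theta, 1, function(th) {
    v <- log_post(th); if (is.nan(v)) -Inf else v
  })
  for (k in which(!is.finite(lp))) {
    for (try in 1:200) {
      cand <- theta[1, ] + rnorm(d, 0, config$init_jitter / try)
      v <- log_post(cand)
      if (is.finite(v)) { theta[k, ] <- cand; lp[k] <- v; break }
    }
  }
  if (any(!is.finite(lp)))
    stop("could not find finite-posterior starting points for all trajectories")

  cold <- which(temps == 1)
  n_cold <- length(cold)
  scales <- matrix(config$init_scale, n_traj, d)
  acc_cnt <- matrix(0, n_traj, d); prop_cnt <- matrix(0, n_traj, d)
  acc_tot <- matrix(0, n_traj, d); prop_tot <- matrix(0, n_traj, d)
  de_acc <- 0; de_prop <- 0
  adapt_steps <- numeric(0)

  cap <- 4096L
  H <- array(NA_real_, c(cap, n_cold, d))
  Hlp <- matrix(NA_real_, cap, n_cold)
  hn <- 0L
  grow <- function() {
    cap2 <- cap * 2L
    H2 <- array(NA_real_, c(cap2, n_cold, d)); H2[1:hn, , ] <- H[1:hn, , ]
    Hlp2 <- matrix(NA_real_, cap2, n_cold); Hlp2[1:hn, ] <- Hlp[1:hn, ]
    H <<- H2; Hlp <<- Hlp2; cap <<- cap2
  }

  archive <- matrix(NA_real_, config$archive_max, d)
  arch_n <- 0L; arch_pos <- 0L
  ring_breaks <- NULL
  lp_buf <- rep(NA_real_, 1000); lpb_pos <- 0L

  phase <- "adapt"
  converged <- FALSE
  t_iter <- 0L
  collect_start <- NA_integer_
  k_thin <- NA_integer_
  need <- NA_integer_
  pilot_n <- 1000L
  n_draws <- config$n_posterior_draws

  model <- attr(log_post, "model")
  repeat {
    t_iter <- t_iter + 1L
    for (k in seq_len(n_traj)) {
      Tk <- temps[k]
      th <- theta[k, ]; lpk <- lp[k]
      if (!is.null(model)) {
        sw <- mwg_sweep_cpp(th, scales[k, ], Tk, model$kind, model$X,
                            model$y, model$offset, model$prior_sd,
                            model$has_prior, model$coef_transform)
        th <- sw$theta; lpk <- sw$lp
        acc_cnt[k, ] <- acc_cnt[k, ] + sw$accepted
        prop_cnt[k, ] <- prop_cnt[k, ] + 1
      } else {
        for (j in seq_len(d)) {
          zj <- th[j]
          th[j] <- zj + rnorm(1) * scales[k, j]
          lpn <- log_post(th)
          if (is.nan(lpn)) lpn <- -Inf
          if (log(runif(1)) < (lpn - lpk) / Tk) {
            lpk <- lpn
            acc_cnt[k, j] <- acc_cnt[k, j] + 1
          } else {
            th[j] <- zj
          }
          prop_cnt[k, j] <- prop_cnt[k, j] + 1
        }
      }
      # differential-evolution move
      pop <- if (arch_n >= 3) archive[seq_len(arch_n), , drop = FALSE]
             else theta[-k, , drop = FALSE]
      if (nrow(pop) >= 2) {
        cr <- config$crossover[sample.int(length(config$crossover), 1)]
        mask <- runif(d) < cr
        if (!any(mask)) mask[sample.int(d, 1)] <- TRUE
        pair <- sample.int(nrow(pop), 2)
        diffv <- pop[pair[1], ] - pop[pair[2], ]
        gam <- if (runif(1) < config$de_gamma_mode_prob) 1
               else 2.38 / sqrt(2 * sum(mask))
        prop <- th
        prop[mask] <- th[mask] + gam * diffv[mask] +
          rnorm(sum(mask), 0, config$de_jitter_sd)
        lpn <- log_post(prop)
        if (is.nan(lpn)) lpn <- -Inf
        de_prop <- de_prop + 1
        if (log(runif(1)) < (lpn - lpk) / Tk) {
          th <- prop; lpk <- lpn; de_acc <- de_acc + 1
        }
      }
      theta[k, ] <- th; lp[k] <- lpk
    }

    if (config$n_tempered > 0 && t_iter %% config$swap_every == 0) {
      fin <- lp_buf[!is.na(lp_buf) & is.finite(lp_buf)]
      if (is.null(ring_breaks) || t_iter %% config$ring_refresh == 0) {
        if (length(fin) >= config$n_rings)
          ring_breaks <- unique(quantile(
            fin, probs = seq_len(config$n_rings - 1) / config$n_rings))
      }
      sw <- equi_energy_swap(theta, lp, temps, ring_breaks, config$n_rings)
      theta <- sw$theta; lp <- sw$lp
    }

    if (t_iter %% config$archive_every == 0) {
      for (k in cold) {
        arch_pos <- (arch_pos %% config$archive_max) + 1L
        archive[arch_pos, ] <- theta[k, ]
        arch_n <- min(arch_n + 1L, config$archive_max)
      }
    }
    lpb_pos <- (lpb_pos %% length(lp_buf)) + 1L
    lp_buf[lpb_pos] <- max(lp[cold])

    if (hn + 1L > cap) grow()
    hn <- hn + 1L
    H[hn, , ] <- theta[cold, ]
    Hlp[hn, ] <- lp[cold]

    if (phase == "adapt" && t_iter %% 50 == 0) {
      rate <- acc_cnt / pmax(prop_cnt, 1)
      step <- min(0.5, 10 * t_iter^(-config$adapt_decay))
      scales <- scales * exp(ifelse(rate > config$adapt_target, step, -step))
      adapt_steps <- c(adapt_steps, step)
      acc_tot <- acc_tot + acc_cnt; prop_tot <- prop_tot + prop_cnt
      acc_cnt[] <- 0; prop_cnt[] <- 0
    }

    if (phase == "adapt" && n_cold >= 2 && t_iter >= config$min_adapt &&
        t_iter %% config$check_every == 0) {
      w <- floor(hn / 2)
      if (w >= 20) {
        rh <- gelman_rubin(H[(hn - w + 1):hn, , , drop = FALSE])
        if (all(is.finite(rh)) && all(rh <= config$rhat_threshold)) {
          phase <- "collect"; converged <- TRUE
          collect_start <- hn + 1L
        }
      }
    }
    if (phase == "adapt" && t_iter >= config$max_iterations) {
      phase <- "collect"
      collect_start <- floor(hn / 2) + 1L
    }

    if (phase == "collect" && hn >= collect_start) {
      avail <- hn - collect_start + 1L
      if (is.na(k_thin) && avail >= min(pilot_n, config$max_collect)) {
        pil <- lapply(seq_len(n_cold), function(c2)
          matrix(H[collect_start:hn, c2, ], ncol = d))
        # the pilot's autocorrelation estimates have a noise floor of about
        # 0.8/sqrt(pilot length); thinning beyond it is indistinguishable
        # from independence
        eff_target <- max(config$thin_target, 1 / sqrt(avail))
        k_thin <- thin_lag(pil, eff_target, config$max_thin)
        if (is.na(k_thin)) k_thin <- 1L
        need <- as.integer(k_thin * ceiling(n_draws / n_cold))
      }
      if (!is.na(k_thin) && (avail >= need ||
                             avail >= config$max_collect)) break
    }
    if (t_iter >= config$max_iterations + config$max_collect) {
      if (is.na(collect_start)) collect_start <- floor(hn / 2) + 1L
      if (is.na(k_thin)) k_thin <- 1L
      break
    }
  }

  avail <- hn - collect_start + 1L
  draw_list <- lapply(seq_len(n_cold), function(c2) {
    idx <- collect_start - 1L + seq(k_thin, avail, by = k_thin)
    list(draws = matrix(H[idx, c2, ], ncol = d), lp = Hlp[idx, c2])
  })
  draws <- do.call(rbind, lapply(draw_list, `[[`, "draws"))
  dlp <- unlist(lapply(draw_list, `[[`, "lp"))
  if (nrow(draws) > n_draws) {
    keep <- seq_len(n_draws)
    draws <- draws[keep, , drop = FALSE]
    dlp <- dlp[keep]
  }
  if (!is.null(par_names)) colnames(draws) <- par_names
  rh_final <- if (n_cold >= 2 && avail >= 20)
    gelman_rubin(H[collect_start:hn, , , drop = FALSE]) else rep(NA_real_, d)
  names(rh_final) <- par_names
  mwg_rate <- colSums(acc_tot + acc_cnt)[seq_len(d)] /
    pmax(colSums(prop_tot + prop_cnt), 1)
  names(mwg_rate) <- par_names
  structure(list(
    draws = draws, log_post = dlp, rhat = rh_final,
    acceptance = list(mwg = mwg_rate,
                      de = if (de_prop > 0) de_acc / de_prop else NA_real_),
    thin_by = as.integer(k_thin), converged = converged,
    n_iterations = t_iter, adapt_steps = adapt_steps, config = config
  ), class = "lf_draws")
}

#' @export
print.lf_draws <- function(x, ...) {
  cat(sprintf("<lf_draws> %d draws x %d parameters (thin %d, %s after %d iterations)\n",
              nrow(x$draws), ncol(x$draws), x$thin_by,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if (any(is.finite(x$rhat)))
    cat(sprintf("  max Rhat %.4f; MwG acceptance %.2f-%.2f; DE acceptance %.2f\n",
                max(x$rhat, na.rm = TRUE), min(x$acceptance$mwg),
                max(x$acceptance$mwg), x$acceptance$de))
  invisible(x)
}
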