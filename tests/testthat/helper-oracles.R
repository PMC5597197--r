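# Independent brute-force recomputations used as oracles. These
# deliberately use naive loops and alternative formulas rather than the
# package's code paths.

oracle_gini_mad <- function(z) {
  n <- length(z)
  if (n < 2 || sum(z) == 0) return(NA_real_)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + abs(z[i] - z[j])
  acc / (2 * n * (n - 1) * mean(z))
}

# label-propagation connected components (8-neighbour) on a logical matrix;
# returns the largest component size
oracle_gap_max <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nxt <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (mask[i, j]) { nxt <- nxt + 1L; lab[i, j] <- nxt }
  }
  if (nxt == 0L) return(0)
  repeat {
    changed <- FALSE
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  max(table(lab[mask]))
}

# full metric set recomputed from scratch for a disc query
oracle_plot_metrics <- function(cloud, centre, radius) {
  keep <- logical(nrow(cloud))
  for (i in seq_len(nrow(cloud)))
    keep[i] <- (cloud$x[i] - centre[1])^2 + (cloud$y[i] - centre[2])^2 <= radius^2
  cl <- cloud[keep, , drop = FALSE]
  z <- cl$z
  z2 <- z[z > 2]
  # CHM over the disc bounding box, per-cell max by scanning
  x0 <- floor(centre[1] - radius); y0 <- floor(centre[2] - radius)
  nx <- ceiling(centre[1] + radius) - x0; ny <- ceiling(centre[2] + radius) - y0
  chm <- matrix(0, nx, ny)
  for (i in seq_len(nrow(cl))) {
    ix <- floor(cl$x[i] - x0) + 1L; iy <- floor(cl$y[i] - y0) + 1L
    if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny)
      chm[ix, iy] <- max(chm[ix, iy], cl$z[i], 0)
  }
  in_disc <- matrix(FALSE, nx, ny)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    cx <- x0 + ix - 0.5; cy <- y0 + iy - 0.5
    in_disc[ix, iy] <- (cx - centre[1])^2 + (cy - centre[2])^2 <= radius^2
  }
  # LAD profile from cumulative counts
  cv <- NA_real_
  if (length(z) && max(z) > 2) {
    nl <- floor(max(z) - 2) + 1L
    lads <- rep(NA_real_, nl)
    for (l in seq_len(nl)) {
      lo <- sum(z < 2 + l - 1); hi <- sum(z < 2 + l)
      if (hi > 0) {
        penr <- lo / hi
        lads[l] <- if (penr == 0) 10 else -log(penr) / 0.5
      }
    }
    lads <- lads[is.finite(lads)]
    if (length(lads) >= 2 && mean(lads) > 0) cv <- sd(lads) / mean(lads)
  }
  gap_mask <- (chm <= 2) & in_disc
  tibble::tibble(
    h_max = if (length(z)) max(z) else NA_real_,
    h_median = if (length(z)) median(z) else NA_real_,
    h_mean = if (length(z2)) sum(z2) / length(z2) else NA_real_,
    var_h = if (length(z2)) sum((z2 - mean(z2))^2) / length(z2) else NA_real_,
    gini = if (length(z2)) oracle_gini_mad(z2) else NA_real_,
    cv_lad = cv,
    gap_max = oracle_gap_max(gap_mask),
    c_f = sum(chm > 2 & in_disc) / sum(in_disc),
    c_r = mean(z > 2),
    vol_can = sum(chm[in_disc])
  )
}

# direct truncated-power restricted cubic spline (textbook form)
oracle_rcs <- function(x, k) {
  pp <- function(u) pmax(u, 0)^3
  f <- function(tj)
    (pp(x - tj) - pp(x - k[3]) * (k[4] - tj) / (k[4] - k[3]) +
       pp(x - k[4]) * (k[3] - tj) / (k[4] - k[3])) / (k[4] - k[1])^2
  cbind(x, f(k[1]), f(k[2]))
}

# textbook split-chain Rhat for a list of equal-length chains (one parameter)
oracle_rhat <- function(xs) {
  segs <- list()
  for (x in xs) {
    n2 <- floor(length(x) / 2)
    segs <- c(segs, list(x[seq_len(n2)]), list(x[n2 + seq_len(n2)]))
  }
  n <- length(segs[[1]])
  mns <- vapply(segs, mean, numeric(1))
  vrs <- vapply(segs, var, numeric(1))
  W <- mean(vrs)
  sqrt(((n - 1) / n * W + var(mns)) / W)
}

# moments of the richness family by explicit pmf summation
oracle_count_moments <- function(eta, omega, y_max = 4000) {
  y <- 0:y_max
  p <- exp(richness_logpmf(y, eta, omega))
  m <- sum(y * p)
  v <- sum(y^2 * p) - m^2
  c(total = sum(p), mean = m, id = v / m)
}
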