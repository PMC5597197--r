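# Regular 1 m grid used for DTMs and canopy height models.
make_grid <- function(origin, values, res = 1) {
  structure(list(origin = origin, res = res, values = values),
            class = "lf_grid")
}

#' @export
print.lf_grid <- function(x, ...) {
  cat(sprintf("<lf_grid> %d x %d cells at %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin[1]) / grid$res) + 1L
  iy <- floor((y - grid$origin[2]) / grid$res) + 1L
  list(ix = ix, iy = iy,
       inside = ix >= 1L & ix <= nrow(grid$values) &
         iy >= 1L & iy <= ncol(grid$values))
}

# Fill NA cells from their nearest filled neighbours by iterative dilation
# (mean of available 8-neighbours), so the DTM is defined over its whole
# bounding box.
fill_na_nearest <- function(m) {
  while (anyNA(m)) {
    nx <- nrow(m); ny <- ncol(m)
    padded <- matrix(NA_real_, nx + 2, ny + 2)
    padded[2:(nx + 1), 2:(ny + 1)] <- m
    acc <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- padded[2:(nx + 1) + dx, 2:(ny + 1) + dy, drop = FALSE]
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    fill <- is.na(m) & cnt > 0
    if (!any(fill)) break
    m[fill] <- acc[fill] / cnt[fill]
  }
  m
}

# 1 m DTM from classified ground points: per-cell mean elevation, gaps
# filled from neighbours.
dtm_from_points <- function(ground) {
  stopifnot(nrow(ground) > 0)
  origin <- c(floor(min(ground$x)), floor(min(ground$y)))
  nx <- max(1L, ceiling(max(ground$x)) - origin[1])
  ny <- max(1L, ceiling(max(ground$y)) - origin[2])
  g <- make_grid(origin, matrix(NA_real_, nx, ny))
  ci <- grid_cell_index(g, ground$x, ground$y)
  ix <- pmin(pmax(ci$ix, 1L), nx); iy <- pmin(pmax(ci$iy, 1L), ny)
  idx <- (iy - 1L) * nx + ix
  means <- tapply(ground$z, idx, mean)
  g$values[as.integer(names(means))] <- as.numeric(means)
  g$values <- fill_na_nearest(g$values)
  g
}

# Bilinear interpolation on cell centres; positions outside the grid are
# clamped to the border cell centres (constant extrapolation).
grid_interp_bilinear <- function(grid, x, y) {
  nx <- nrow(grid$values); ny <- ncol(grid$values)
  u <- (x - grid$origin[1]) / grid$res - 0.5
  v <- (y - grid$origin[2]) / grid$res - 0.5
  u <- pmin(pmax(u, 0), nx - 1); v <- pmin(pmax(v, 0), ny - 1)
  i0 <- pmin(floor(u) + 1L, nx - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(v) + 1L, ny - 1L); j0 <- pmax(j0, 1L)
  fu <- u - (i0 - 1L); fv <- v - (j0 - 1L)
  if (nx == 1L) { i0 <- rep(1L, length(u)); fu <- rep(0, length(u)) }
  if (ny == 1L) { j0 <- rep(1L, length(v)); fv <- rep(0, length(v)) }
  i1 <- pmin(i0 + 1L, nx); j1 <- pmin(j0 + 1L, ny)
  vals <- grid$values
  vals[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    vals[cbind(i1, j0)] * fu * (1 - fv) +
    vals[cbind(i0, j1)] * (1 - fu) * fv +
    vals[cbind(i1, j1)] * fu * fv
}

#' Normalize point heights against a ground model
#'
#' Converts raw elevations to heights above ground by subtracting the
#' ground elevation at each point. The ground model is either a table of
#' classified ground points — rasterized to a 1 m DTM by per-cell means,
#' with empty cells filled from their neighbours — or a DTM grid built
#' elsewhere. Points falling outside the ground model's footprint are
#' dropped with a message.
#'
#' @param points Tibble with `x`, `y`, `z` (raw elevation).
#' @param ground Tibble of ground points (`x`, `y`, `z`) or an internal
#'   `lf_grid` DTM.
#' @return `points` with `z` replaced by height above ground.
#' @export
normalize_heights <- function(points, ground) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  dtm <- if (inherits(ground, "lf_grid")) ground else dtm_from_points(ground)
  nx <- nrow(dtm$values); ny <- ncol(dtm$values)
  xmax <- dtm$origin[1] + nx * dtm$res
  ymax <- dtm$origin[2] + ny * dtm$res
  inside <- points$x >= dtm$origin[1] & points$x <= xmax &
    points$y >= dtm$origin[2] & points$y <= ymax
  if (any(!inside)) {
    message(sum(!inside), " point(s) outside the ground model footprint dropped")
    points <- points[inside, , drop = FALSE]
  }
  points$z <- points$z - grid_interp_bilinear(dtm, points$x, points$y)
  points
}

#' Canopy height model from a normalized point cloud
#'
#' Builds a 1 m canopy height model: each cell takes the maximum height of
#' its points (first returns where a `return_number` column exists, all
#' points otherwise), empty cells are 0, and negative heights are clamped
#' to 0.
#'
#' @param cloud Normalized point cloud (`x`, `y`, `z`).
#' @param bbox Optional `c(xmin, xmax, ymin, ymax)`; defaults to the cloud
#'   bounding box rounded outward to whole metres.
#' @return An `lf_grid` canopy height model.
#' @export
build_chm <- function(cloud, bbox = NULL) {
  if (nrow(cloud) == 0) stop("cannot build a CHM from an empty cloud")
  pts <- cloud
  if ("return_number" %in% names(pts) && any(pts$return_number == 1L))
    pts <- pts[pts$return_number == 1L, , drop = FALSE]
  if (is.null(bbox))
    bbox <- c(floor(min(pts$x)), ceiling(max(pts$x)),
              floor(min(pts$y)), ceiling(max(pts$y)))
  origin <- c(floor(bbox[1]), floor(bbox[3]))
  nx <- max(1L, as.integer(ceiling(bbox[2]) - origin[1]))
  ny <- max(1L, as.integer(ceiling(bbox[4]) - origin[2]))
  g <- make_grid(origin, matrix(0, nx, ny))
  ci <- grid_cell_index(g, pts$x, pts$y)
  keep <- ci$inside
  if (any(keep)) {
    idx <- (ci$iy[keep] - 1L) * nx + ci$ix[keep]
    mx <- tapply(pts$z[keep], idx, max)
    g$values[as.integer(names(mx))] <- pmax(as.numeric(mx), 0)
  }
  g
}

#' Point-height summary metrics
#'
#' Height metrics of a normalized cloud: maximum height over all points,
#' median height over all points including ground returns, and — over
#' canopy points only (strictly above the 2 m understory threshold) — the
#' mean height and the population variance \eqn{\frac1n\sum(z_i - \bar z)^2}.
#'
#' @param cloud Normalized point cloud.
#' @return One-row tibble `h_max`, `h_median`, `h_mean`, `var_h`
#'   (`h_mean`/`var_h` are `NA` when no point exceeds 2 m).
#' @export
height_metrics <- function(cloud) {
  if (nrow(cloud) == 0) stop("empty cloud")
  z <- cloud$z
  z2 <- z[z > 2]
  tibble::tibble(
    h_max = max(z),
    h_median = median(z),
    h_mean = if (length(z2)) mean(z2) else NA_real_,
    var_h = if (length(z2)) mean((z2 - mean(z2))^2) else NA_real_
  )
}

#' Gini coefficient of point heights
#'
#' \eqn{G = \sum_i (2i - n - 1) z_{(i)} / (\sum_i z_i \, (n - 1))} with the
#' heights sorted ascending — 0 when all heights are equal, 1 when all mass
#' sits on a single point. Callers pass the canopy subset (heights above
#' 2 m). A single height has no inequality information and returns `NA`.
#'
#' @param heights Non-negative heights (canopy points).
#' @return Scalar in \[0, 1\], or `NA`.
#' @export
gini <- function(heights) {
  if (length(heights) == 0) stop("empty height vector")
  if (any(heights < 0)) stop("heights must be non-negative")
  n <- length(heights)
  if (n == 1L) return(NA_real_)
  s <- sum(heights)
  if (s == 0) return(NA_real_)
  if (all(heights == heights[1])) return(0)  # perfect equality, exactly
  zs <- sort(heights)
  sum((2 * seq_len(n) - n - 1) * zs) / (s * (n - 1))
}

#' Leaf area density profile via Beer-Lambert inversion
#'
#' Computes a MacArthur-Horn style transmittance profile from cumulative
#' point counts and inverts it with the Beer-Lambert law: for each layer,
#' the entry proportion is the number of pulses reaching below the layer
#' bottom over the number reaching below its top (a return below a height
#' stands in for a pulse having penetrated to it), and
#' \eqn{LAD = -\ln(P_{enr}) / (k\,dz)} with extinction coefficient `k`.
#' Layers in which every pulse is intercepted (zero transmittance) are
#' capped at `max_lad`.
#'
#' @param cloud Normalized point cloud (all returns, ground included).
#' @param dz Layer thickness in m (default 1).
#' @param k Extinction coefficient (default 0.5).
#' @param z_floor Bottom of the profile; layers start above the 2 m
#'   understory threshold.
#' @param max_lad Cap applied when transmittance is 0.
#' @return Tibble `z_bottom`, `z_top`, `penr`, `lad` (0 rows when no point
#'   lies above `z_floor`).
#' @export
lad_profile <- function(cloud, dz = 1, k = 0.5, z_floor = 2, max_lad = 10) {
  if (nrow(cloud) == 0) stop("empty cloud")
  z <- cloud$z
  if (max(z) <= z_floor)
    return(tibble::tibble(z_bottom = numeric(), z_top = numeric(),
                          penr = numeric(), lad = numeric()))
  n_layer <- floor((max(z) - z_floor) / dz) + 1L
  bounds <- z_floor + dz * (0:n_layer)
  below <- vapply(bounds, function(b) sum(z < b), numeric(1))
  penr <- below[seq_len(n_layer)] / below[seq_len(n_layer) + 1L]
  penr[below[seq_len(n_layer) + 1L] == 0] <- NA_real_
  lad <- -log(penr) / (k * dz)
  capped <- is.finite(penr) & penr == 0
  lad[capped] <- max_lad
  tibble::tibble(
    z_bottom = bounds[seq_len(n_layer)],
    z_top = bounds[seq_len(n_layer) + 1L],
    penr = penr, lad = lad
  )
}

#' Coefficient of variation of a leaf area density profile
#'
#' Sample standard deviation over mean of the layer LAD values.
#'
#' @param profile Output of [lad_profile()].
#' @return Scalar CV, or `NA` when fewer than two defined layers or a zero
#'   mean.
#' @export
cv_lad <- function(profile) {
  lad <- profile$lad[is.finite(profile$lad)]
  if (length(lad) < 2 || mean(lad) == 0) return(NA_real_)
  stats::sd(lad) / mean(lad)
}

# Sizes of 8-connected components of TRUE cells (NA treated as outside).
clump_sizes <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  labels <- matrix(0L, nx, ny)
  sizes <- integer(0)
  lab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    labels[start] <- lab
    size <- 0L
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      cx <- ((cell - 1L) %% nx) + 1L
      cy <- ((cell - 1L) %/% nx) + 1L
      for (dx in -1:1) for (dy in -1:1) {
        nxx <- cx + dx; nyy <- cy + dy
        if (nxx < 1L || nxx > nx || nyy < 1L || nyy > ny) next
        ncell <- (nyy - 1L) * nx + nxx
        if (mask[ncell] && labels[ncell] == 0L) {
          labels[ncell] <- lab
          stack <- c(stack, ncell)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Canopy-height-model metrics
#'
#' From a 1 m CHM: `gap_max`, the area (m^2; cell count) of the largest
#' 8-connected component of cells at or below 2 m; `c_f`, the cover
#' fraction (proportion of cells above 2 m); and `vol_can`, the canopy
#' volume (sum of cell heights). When a disc is given, only cells whose
#' centre lies inside it are counted.
#'
#' @param grid An `lf_grid` CHM from [build_chm()].
#' @param centre,radius Optional query disc.
#' @return One-row tibble `gap_max`, `c_f`, `vol_can`.
#' @export
chm_metrics <- function(grid, centre = NULL, radius = NULL) {
  stopifnot(inherits(grid, "lf_grid"))
  vals <- grid$values
  nx <- nrow(vals); ny <- ncol(vals)
  in_disc <- matrix(TRUE, nx, ny)
  if (!is.null(centre) && !is.null(radius)) {
    cx <- grid$origin[1] + (seq_len(nx) - 0.5) * grid$res
    cy <- grid$origin[2] + (seq_len(ny) - 0.5) * grid$res
    in_disc <- outer(cx, cy, function(a, b)
      (a - centre[1])^2 + (b - centre[2])^2 <= radius^2)
  }
  if (!any(in_disc)) stop("query disc contains no grid cell centre")
  gap_mask <- (vals <= 2) & in_disc
  sizes <- clump_sizes(gap_mask)
  tibble::tibble(
    gap_max = if (length(sizes)) max(sizes) * grid$res^2 else 0,
    c_f = sum(vals > 2 & in_disc) / sum(in_disc),
    vol_can = sum(vals[in_disc])
  )
}

#' Canopy attenuation rate
#'
#' Proportion of returns above the 2 m understory threshold; a proxy for
#' light interception that, unlike the CHM cover fraction, is sensitive to
#' sub-metre openings.
#'
#' @param cloud Normalized point cloud.
#' @return Scalar in \[0, 1\].
#' @export
attenuation_rate <- function(cloud) {
  if (nrow(cloud) == 0) stop("empty cloud")
  mean(cloud$z > 2)
}

#' All ten forest-structure variables for one plot disc
#'
#' Clips a point cloud to a disc, builds the 1 m CHM over the disc's
#' bounding box and returns the full structure-variable set: `h_max`,
#' `h_median`, `h_mean`, `var_h`, `gini`, `cv_lad`, `gap_max`, `c_f`,
#' `c_r`, `vol_can`. Discs with fewer than `min_points` returns yield a
#' flagged all-`NA` row.
#'
#' @param cloud Normalized point cloud covering the disc.
#' @param centre `c(x, y)` of the disc centre.
#' @param radius Disc radius (m).
#' @param plot_id Optional identifier carried through to the result.
#' @param min_points Minimum number of clipped points for a valid run.
#' @return One-row tibble of the ten metrics plus `radius`, `n_points`,
#'   `ok`, and `plot_id` when given.
#' @export
extract_plot_metrics <- function(cloud, centre = c(0, 0), radius,
                                 plot_id = NULL, min_points = 10) {
  stopifnot(is.numeric(radius), radius > 0)
  keep <- (cloud$x - centre[1])^2 + (cloud$y - centre[2])^2 <= radius^2
  clip <- cloud[keep, , drop = FALSE]
  na_row <- tibble::tibble(
    h_max = NA_real_, h_median = NA_real_, h_mean = NA_real_,
    var_h = NA_real_, gini = NA_real_, cv_lad = NA_real_,
    gap_max = NA_real_, c_f = NA_real_, c_r = NA_real_, vol_can = NA_real_
  )
  if (nrow(clip) < min_points) {
    out <- dplyr::mutate(na_row, radius = radius, n_points = nrow(clip), ok = FALSE)
  } else {
    hm <- height_metrics(clip)
    z2 <- clip$z[clip$z > 2]
    chm <- build_chm(clip, bbox = c(centre[1] - radius, centre[1] + radius,
                                    centre[2] - radius, centre[2] + radius))
    cm <- chm_metrics(chm, centre = centre, radius = radius)
    out <- tibble::tibble(
      h_max = hm$h_max, h_median = hm$h_median, h_mean = hm$h_mean,
      var_h = hm$var_h,
      gini = if (length(z2)) gini(z2) else NA_real_,
      cv_lad = cv_lad(lad_profile(clip)),
      gap_max = cm$gap_max, c_f = cm$c_f,
      c_r = attenuation_rate(clip), vol_can = cm$vol_can,
      radius = radius, n_points = nrow(clip), ok = TRUE
    )
  }
  if (!is.null(plot_id)) out <- dplyr::mutate(out, plot_id = plot_id, .before = 1)
  out
}

#' Structure metrics for every lidar-covered plot of a dataset
#'
#' Runs [extract_plot_metrics()] on each covered plot's point cloud at its
#' field-plot radius (clouds generated by [make_dataset()] are local to the
#' plot, centred on its centre).
#'
#' @param dataset An `lf_dataset`.
#' @return Tibble keyed by `plot_id` with the ten metrics.
#' @export
extract_dataset_metrics <- function(dataset) {
  stopifnot(inherits(dataset, "lf_dataset"))
  idx <- which(dataset$plots$als_covered &
                 !vapply(dataset$plots$cloud, is.null, logical(1)))
  purrr::map_dfr(idx, function(i)
    extract_plot_metrics(dataset$plots$cloud[[i]], centre = c(0, 0),
                         radius = dataset$plots$plot_radius[i],
                         plot_id = dataset$plots$plot_id[i]))
}
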