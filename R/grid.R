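# Discretized lon/lat domain and the mass-conserving advection-diffusion
# prediction step with zero-flux boundaries at coastlines and domain edges.
#
# Conventions: fields are ny x nx matrices, row r = latitude index (ascending
# south->north), column c = longitude index (ascending west->east). Fields
# hold probability MASS per cell (summing to 1), not density. Local metric:
# one degree of latitude = 111.32 km; longitude scaled by cos(lat) per row.

KM_PER_DEG <- 111.32

#' Build a model grid
#'
#' Discretizes a lon/lat bounding box at a nominal resolution in km and
#' attaches a land mask and bathymetry. Mask and bathymetry may be supplied
#' as functions of (lon, lat) (vectorized), as matrices already at grid
#' dimension, or as "raster-lite" lists `list(lon=, lat=, z=)` which are
#' resampled (nearest neighbour for the mask, bilinear for bathymetry).
#'
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param resolution_km nominal cell size (default 9 km); latitude spacing is
#'   exact, longitude spacing matches it in km at the central latitude.
#' @param land land mask input; TRUE/1 = land, FALSE/0 = water. Default: all
#'   water.
#' @param bathymetry water depth in metres (positive down). Default 5000 m
#'   everywhere.
#' @return object of class `tag_grid`: lon/lat cell centres, `water` logical
#'   matrix, `bathy` matrix, per-row cell widths `dx_km`, height `dy_km`,
#'   cell areas `area_km2`.
#' @export
build_grid <- function(bbox, resolution_km = 9, land = NULL, bathymetry = NULL) {
  stopifnot(length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3],
            resolution_km > 0)
  if (bbox[1] < -180 || bbox[2] > 180) stop("lon must lie within [-180, 180]")
  dlat <- resolution_km / KM_PER_DEG
  midlat <- (bbox[3] + bbox[4]) / 2
  dlon <- resolution_km / (KM_PER_DEG * cos(deg2rad(midlat)))
  ny <- max(1L, round((bbox[4] - bbox[3]) / dlat))
  nx <- max(1L, round((bbox[2] - bbox[1]) / dlon))
  lat <- bbox[3] + (seq_len(ny) - 0.5) * (bbox[4] - bbox[3]) / ny
  lon <- bbox[1] + (seq_len(nx) - 0.5) * (bbox[2] - bbox[1]) / nx
  dy_km <- (bbox[4] - bbox[3]) / ny * KM_PER_DEG
  dx_km <- (bbox[2] - bbox[1]) / nx * KM_PER_DEG * cos(deg2rad(lat))

  eval_layer <- function(input, default, nearest) {
    if (is.null(input)) return(matrix(default, ny, nx))
    if (is.function(input)) {
      ll <- expand.grid(lon = lon, lat = lat) # varies lon fastest
      return(matrix(input(ll$lon, ll$lat), ny, nx, byrow = TRUE))
    }
    if (is.matrix(input)) {
      if (!all(dim(input) == c(ny, nx)))
        stop("matrix layer must be ny x nx (", ny, " x ", nx, ")")
      return(input)
    }
    if (is.list(input) && all(c("lon", "lat", "z") %in% names(input)))
      return(resample_raster(input, lon, lat, nearest = nearest))
    stop("layer must be NULL, a function(lon,lat), a matrix, or list(lon,lat,z)")
  }

  land_m <- eval_layer(land, FALSE, nearest = TRUE)
  water <- !(matrix(as.logical(land_m), ny, nx))
  bathy <- eval_layer(bathymetry, 5000, nearest = FALSE)
  bathy[!water] <- 0
  bathy[water & (bathy < 0)] <- 0
  if (!any(water)) stop("domain contains no water cells")

  g <- list(
    lon = lon, lat = lat, nx = nx, ny = ny,
    resolution_km = resolution_km,
    dlon = (bbox[2] - bbox[1]) / nx, dlat = (bbox[4] - bbox[3]) / ny,
    bbox = bbox,
    water = water, bathy = bathy,
    dx_km = dx_km, dy_km = dy_km,
    area_km2 = outer(dx_km, rep(dy_km, nx))
  )
  class(g) <- "tag_grid"
  g
}

# Nearest / bilinear resampling of list(lon, lat, z) onto target centres.
resample_raster <- function(r, lon, lat, nearest) {
  stopifnot(is.matrix(r$z), length(r$lat) == nrow(r$z), length(r$lon) == ncol(r$z))
  if (nearest) {
    ri <- vapply(lat, function(y) which.min(abs(r$lat - y)), integer(1))
    ci <- vapply(lon, function(x) which.min(abs(r$lon - x)), integer(1))
    return(r$z[ri, ci, drop = FALSE])
  }
  # bilinear: interpolate rows then columns
  z1 <- apply(r$z, 2, function(col) stats::approx(r$lat, col, lat, rule = 2)$y)
  z1 <- matrix(z1, length(lat), ncol(r$z))
  t(apply(z1, 1, function(row) stats::approx(r$lon, row, lon, rule = 2)$y))
}

#' @export
print.tag_grid <- function(x, ...) {
  cat(sprintf("tag_grid: %d x %d cells (~%g km), lon [%g, %g], lat [%g, %g]\n",
              x$ny, x$nx, x$resolution_km, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  cat(sprintf("  water fraction %.2f\n", mean(x$water)))
  invisible(x)
}

#' Locate the cell containing a point
#'
#' @param grid a `tag_grid`.
#' @param lon,lat point coordinates (vectors of equal length).
#' @return data.frame with `row`, `col` (NA when off-grid).
#' @export
cell_at <- function(grid, lon, lat) {
  col <- floor((lon - grid$bbox[1]) / grid$dlon) + 1
  row <- floor((lat - grid$bbox[3]) / grid$dlat) + 1
  off <- col < 1 | col > grid$nx | row < 1 | row > grid$ny
  data.frame(row = ifelse(off, NA_integer_, row),
             col = ifelse(off, NA_integer_, col))
}

#' Probability field on a grid
#'
#' Light container pairing a mass matrix with its grid. Mass is nonnegative,
#' zero on land, and sums to 1.
#'
#' @param grid a `tag_grid`.
#' @param m ny x nx matrix of nonnegative cell masses (normalized on entry).
#' @param date optional date label.
#' @export
prob_field <- function(grid, m, date = NULL) {
  stopifnot(all(dim(m) == c(grid$ny, grid$nx)))
  if (any(m < 0)) stop("negative mass in probability field")
  if (any(m[!grid$water] != 0)) stop("mass on land cells")
  s <- sum(m)
  if (s <= 0) stop("probability field has zero total mass")
  structure(list(grid = grid, m = m / s, date = date), class = "prob_field")
}

#' @export
print.prob_field <- function(x, ...) {
  idx <- which(x$m == max(x$m), arr.ind = TRUE)[1, ]
  cat(sprintf("prob_field%s: mode at (%.2f, %.2f), max mass %.3g\n",
              if (is.null(x$date)) "" else paste0(" [", x$date, "]"),
              x$grid$lon[idx[2]], x$grid$lat[idx[1]], max(x$m)))
  invisible(x)
}

#' Point-mass initial field
#'
#' All probability mass in the cell containing (lon, lat). On-land points are
#' snapped to the nearest water cell within a 2-cell radius (flagged via
#' attribute `snapped`), otherwise an error.
#'
#' @inheritParams cell_at
#' @param date optional date label.
#' @return a [prob_field()].
#' @export
delta_field <- function(grid, lon, lat, date = NULL) {
  rc <- cell_at(grid, lon, lat)
  if (is.na(rc$row[1])) stop("point (", lon, ", ", lat, ") is off the grid")
  r <- rc$row[1]; c <- rc$col[1]
  snapped <- FALSE
  if (!grid$water[r, c]) {
    win_r <- max(1, r - 2):min(grid$ny, r + 2)
    win_c <- max(1, c - 2):min(grid$nx, c + 2)
    w <- which(grid$water[win_r, win_c, drop = FALSE], arr.ind = TRUE)
    if (nrow(w) == 0)
      stop("point (", lon, ", ", lat, ") is on land with no water cell within 2 cells")
    d2 <- (win_r[w[, 1]] - r)^2 + (win_c[w[, 2]] - c)^2
    k <- which.min(d2)
    r <- win_r[w[k, 1]]; c <- win_c[w[k, 2]]
    snapped <- TRUE
  }
  m <- matrix(0, grid$ny, grid$nx)
  m[r, c] <- 1
  f <- prob_field(grid, m, date)
  attr(f, "snapped") <- snapped
  f
}

#' Movement model parameters
#'
#' @param D isotropic diffusivity, km^2/day (>= 0).
#' @param u,v optional advection fields, km/day eastward/northward: scalars
#'   or ny x nx matrices. Default 0 (pure diffusion).
#' @param dt time step in days (default 1, one tag-day).
#' @return object of class `movement_params`.
#' @export
movement_params <- function(D, u = NULL, v = NULL, dt = 1) {
  stopifnot(D >= 0, dt > 0)
  structure(list(D = D, u = u, v = v, dt = dt), class = "movement_params")
}

# Stable sub-step count for the explicit scheme: the drained fraction of a
# cell per substep, dt*(2D/dx^2 + 2D/dy^2 + |u|/dx + |v|/dy), must stay
# below 1 (0.9 safety) so nonnegativity is preserved.
stable_substeps <- function(grid, mp) {
  dxmin <- min(grid$dx_km); dy <- grid$dy_km
  umax <- if (is.null(mp$u)) 0 else max(abs(mp$u))
  vmax <- if (is.null(mp$v)) 0 else max(abs(mp$v))
  rate <- 2 * mp$D / dxmin^2 + 2 * mp$D / dy^2 + umax / dxmin + vmax / dy
  if (rate <= 0) return(1L)
  max(1L, as.integer(ceiling(mp$dt * rate / 0.9)))
}

# Bare-matrix prediction over mp$dt days. adjoint = TRUE applies the exact
# transpose of the mass-propagation operator (used by the backward filter):
# for the self-adjoint-in-area diffusion operator this is
# P^T x = P(A * x) / A; advection velocities are negated.
propagate_mass <- function(m, grid, mp, adjoint = FALSE) {
  nsub <- stable_substeps(grid, mp)
  as_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x else matrix(x, grid$ny, grid$nx)
  }
  u <- as_mat(mp$u); v <- as_mat(mp$v)
  if (adjoint) {
    m <- m * grid$area_km2
    if (!is.null(u)) u <- -u
    if (!is.null(v)) v <- -v
  }
  m <- cpp_propagate(m, grid$water, grid$dx_km, grid$dy_km, grid$area_km2,
                     mp$D, mp$dt, nsub, u, v)
  if (adjoint) m <- m / grid$area_km2
  m
}

#' Advection-diffusion prediction step
#'
#' Advances a probability field by `mp$dt` days under the movement model,
#' solving the advection-diffusion equation in explicit flux form with
#' zero-flux boundaries along coastlines and domain edges. Mass is conserved
#' to machine precision and never leaks onto land; the step auto-substeps to
#' satisfy the explicit stability bound.
#'
#' @param field a [prob_field()].
#' @param mp a [movement_params()].
#' @return the predicted [prob_field()].
#' @export
predict_step <- function(field, mp) {
  m <- propagate_mass(field$m, field$grid, mp)
  out <- field
  out$m <- m
  out
}

# Per-axis variance (km^2) of a mass field about its mean, in the local
# metric. Used by tests and diagnostics.
field_variance_km2 <- function(field) {
  g <- field$grid; m <- field$m
  x <- outer(rep(1, g$ny), g$lon)
  y <- outer(g$lat, rep(1, g$nx))
  # local km coordinates about the mean position
  mx <- sum(m * x); my <- sum(m * y)
  kx <- (x - mx) * KM_PER_DEG * cos(deg2rad(my))
  ky <- (y - my) * KM_PER_DEG
  c(var_x = sum(m * kx^2), var_y = sum(m * ky^2))
}

# Chamfer (8-neighbour, metric-weighted) distance transform from a seed mask,
# with land impassable. Returns km distances; Inf where unreachable.
grid_distance_km <- function(grid, seed_mask, max_km = Inf) {
  cpp_chamfer(seed_mask, grid$water, grid$dx_km, grid$dy_km)
}

#' Dilate a cell mask by a travel distance
#'
#' Cells reachable from the mask within `dist_km` along 8-neighbour paths
#' through water (land is impassable), using local great-circle step lengths.
#'
#' @param grid a `tag_grid`.
#' @param mask logical ny x nx seed mask.
#' @param dist_km maximum travel distance, km.
#' @return logical ny x nx mask (subset of water cells).
#' @export
dilate_mask <- function(grid, mask, dist_km) {
  d <- grid_distance_km(grid, mask, max_km = dist_km)
  d <= dist_km
}
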