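# Synthetic ocean environment, track simulation under the filter's own
# movement kernel, and tag-record emission with realistic sparsity/noise.

#' Simulation configuration
#'
#' Defaults encode the observation process the filter assumes: about 7% of
#' tag-days carry sunrise/sunset times, about 41% carry an SST estimate,
#' with Gaussian noise of 20 min and 1 deg C respectively.
#'
#' @param D diffusivity of the simulated movement, km^2/day (default 300).
#' @param n_days deployment length in days (default 120).
#' @param start optional `c(lon, lat)` start; random water cell if NULL.
#' @param end optional `c(lon, lat)` target; when given, a constant drift
#'   (advection) moving the expected position from start to end over the
#'   deployment is added to the movement kernel.
#' @param p_event_day probability a day carries sunrise+sunset times (0.07).
#' @param p_sst_day probability a day carries an SST estimate (0.41).
#' @param sigma_sst SST observation noise, deg C (1.0).
#' @param sigma_event event-time observation noise, minutes (20).
#' @param p_corrupt fraction of event times replaced by uniform garbage
#'   times (default 0; used for screening experiments).
#' @param max_depth_cap_m deepest daily dive drawn (default 900 m).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(D = 300, n_days = 120, start = NULL, end = NULL,
                       p_event_day = 0.07, p_sst_day = 0.41,
                       sigma_sst = 1.0, sigma_event = 20,
                       p_corrupt = 0, max_depth_cap_m = 900, seed = 1) {
  stopifnot(D >= 0, n_days >= 1,
            p_event_day >= 0, p_event_day <= 1,
            p_sst_day >= 0, p_sst_day <= 1,
            p_corrupt >= 0, p_corrupt <= 1,
            sigma_sst > 0, sigma_event > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Smooth pseudo-random surface: white noise on a coarse lattice, bilinearly
# interpolated onto the grid, unit variance-ish.
smooth_noise <- function(grid, coarse_cells = 8, sd = 1) {
  ny_c <- max(2, ceiling(grid$ny / coarse_cells))
  nx_c <- max(2, ceiling(grid$nx / coarse_cells))
  z <- matrix(stats::rnorm(ny_c * nx_c), ny_c, nx_c)
  r <- list(lon = seq(grid$bbox[1], grid$bbox[2], length.out = nx_c),
            lat = seq(grid$bbox[3], grid$bbox[4], length.out = ny_c),
            z = z)
  out <- resample_raster(r, grid$lon, grid$lat, nearest = FALSE)
  out * sd / max(stats::sd(out), 1e-9)
}

#' Generate a synthetic ocean environment
#'
#' A western-boundary landmass with a wiggly coastline, shelf-to-deep
#' bathymetry increasing away from the coast, and a daily reference SST field
#' built from a latitudinal gradient, a seasonal cycle (amplitude growing
#' poleward, peak in late August) and a static smooth spatial anomaly. The
#' SST range mirrors the 5-30 deg C span typical of the northwest Atlantic.
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`; default a 20 x 25
#'   degree northwest-Atlantic-like box.
#' @param resolution_km grid cell size (default 30 km, the testing scale;
#'   use 9 km for production-like runs).
#' @param dates Date vector the SST field covers (default calendar 2008).
#' @param seed integer seed.
#' @return list of class `tag_env`: `grid`, `dates`, `sst` (ny x nx x n_dates
#'   array), `seed`.
#' @export
make_environment <- function(bbox = c(-75, -55, 20, 45), resolution_km = 30,
                             dates = seq(as.Date("2008-01-01"),
                                         as.Date("2008-12-31"), by = "day"),
                             seed = 1) {
  set.seed(seed)
  coast_amp <- 1.2
  coast <- function(lat) bbox[1] + 0.15 * (bbox[2] - bbox[1]) +
    coast_amp * sin(lat / 2.3) + 0.6 * sin(lat / 0.9)
  land_fun <- function(lon, lat) lon < coast(lat)
  grid0 <- build_grid(bbox, resolution_km, land = land_fun)
  # bathymetry from (approximate) distance east of the coastline
  lonm <- outer(rep(1, grid0$ny), grid0$lon)
  latm <- outer(grid0$lat, rep(1, grid0$nx))
  ddeg <- lonm - coast(latm)
  bathy <- matrix(pmin(5200, pmax(0, 40 + 900 * pmax(0, ddeg)^1.3)),
                  grid0$ny, grid0$nx)
  grid <- build_grid(bbox, resolution_km, land = land_fun, bathymetry = bathy)

  anomaly <- smooth_noise(grid, coarse_cells = 7, sd = 0.8)
  doy <- as.POSIXlt(dates)$yday + 1
  base <- 29.5 - 0.82 * (latm - bbox[3])
  amp <- 1 + 2.5 * (latm - bbox[3]) / (bbox[4] - bbox[3])
  sst <- array(NA_real_, c(grid$ny, grid$nx, length(dates)))
  for (i in seq_along(dates)) {
    f <- base + amp * cos(2 * pi * (doy[i] - 236) / 365.25) + anomaly
    sst[, , i] <- pmin(31, pmax(4, f))
  }
  structure(list(grid = grid, dates = dates, sst = sst, seed = seed),
            class = "tag_env")
}

#' @export
print.tag_env <- function(x, ...) {
  cat(sprintf("tag_env: %s to %s, SST %.1f-%.1f degC\n",
              min(x$dates), max(x$dates),
              min(x$sst[x$grid$water]), max(x$sst)))
  print(x$grid)
  invisible(x)
}

#' Reference SST field for a date
#'
#' @param env a `tag_env`.
#' @param date Date; the nearest covered day is used.
#' @return ny x nx matrix, deg C.
#' @export
env_sst <- function(env, date) {
  i <- which.min(abs(as.numeric(env$dates - as.Date(date))))
  env$sst[, , i]
}

random_water_cell <- function(grid, margin_km = 150) {
  # keep starts away from the domain edge so tracks rarely pile on it
  cand <- grid$water
  mr <- ceiling(margin_km / grid$dy_km)
  if (grid$ny > 2 * mr) cand[c(seq_len(mr), grid$ny - seq_len(mr) + 1), ] <- FALSE
  mc <- ceiling(margin_km / min(grid$dx_km))
  if (grid$nx > 2 * mc) cand[, c(seq_len(mc), grid$nx - seq_len(mc) + 1)] <- FALSE
  if (!any(cand)) cand <- grid$water
  idx <- which(cand)
  k <- sample(idx, 1)
  r <- (k - 1) %% grid$ny + 1
  c <- (k - 1) %/% grid$ny + 1
  c(lon = grid$lon[c], lat = grid$lat[r])
}

track_movement_params <- function(cfg, start, n_days) {
  u <- v <- NULL
  if (!is.null(cfg$end)) {
    u <- (cfg$end[1] - start[1]) * KM_PER_DEG *
      cos(deg2rad((cfg$end[2] + start[2]) / 2)) / n_days
    v <- (cfg$end[2] - start[2]) * KM_PER_DEG / n_days
  }
  movement_params(D = cfg$D, u = u, v = v, dt = 1)
}

#' Simulate a daily track under the filter's movement kernel
#'
#' Positions are grid cells; each day the next cell is drawn from the
#' distribution obtained by applying the advection-diffusion prediction step
#' to a point mass at the current cell. Simulation and inference therefore
#' share a single transition-kernel implementation, and tracks can never
#' step onto land.
#'
#' @param env a `tag_env`.
#' @param cfg a [sim_config()].
#' @param start_date first day (default first environment date).
#' @return data.frame `date`, `lon`, `lat`, `row`, `col`.
#' @export
simulate_track <- function(env, cfg, start_date = NULL) {
  grid <- env$grid
  set.seed(cfg$seed)
  if (is.null(start_date)) start_date <- env$dates[1]
  start <- cfg$start
  if (is.null(start)) start <- random_water_cell(grid)
  rc <- cell_at(grid, start[1], start[2])
  if (is.na(rc$row[1]) || !grid$water[rc$row[1], rc$col[1]])
    stop("track start is on land or off the grid")
  mp <- track_movement_params(cfg, start, cfg$n_days)
  rows <- cols <- integer(cfg$n_days)
  rows[1] <- rc$row[1]; cols[1] <- rc$col[1]
  for (t in 2:max(2, cfg$n_days)) {
    if (t > cfg$n_days) break
    m <- matrix(0, grid$ny, grid$nx)
    m[rows[t - 1], cols[t - 1]] <- 1
    m <- propagate_mass(m, grid, mp)
    k <- sample.int(length(m), 1, prob = pmax(m, 0))
    rows[t] <- (k - 1) %% grid$ny + 1
    cols[t] <- (k - 1) %/% grid$ny + 1
  }
  data.frame(date = seq(as.Date(start_date), by = "day", length.out = cfg$n_days),
             lon = grid$lon[cols], lat = grid$lat[rows],
             row = rows, col = cols)
}

#' Emit tag records from a simulated track
#'
#' Each day independently carries an SST estimate with probability
#' `p_sst_day` (reference SST at the true cell plus Gaussian noise) and a
#' sunrise+sunset pair with probability `p_event_day` (solar predictions at
#' the true position plus circular Gaussian noise; skipped under polar
#' day/night). Daily maximum depth is drawn below the local bathymetry.
#' Optionally a fraction `p_corrupt` of event times is replaced by uniform
#' garbage (returned labelled, for screening experiments).
#'
#' @param track output of [simulate_track()].
#' @param env the `tag_env` the track was simulated in.
#' @param cfg the same [sim_config()].
#' @param tag_id identifier for the deployment.
#' @param ljfl_cm fish length for the deployment record (default drawn
#'   uniformly in 100-260 cm).
#' @return list: `dep` ([deployment()]), `records` (daily records
#'   data.frame), `corrupted` data.frame (`date`, `event`) of injected bad
#'   event times.
#' @export
simulate_tag_records <- function(track, env, cfg, tag_id = "sim-1",
                                 ljfl_cm = NULL) {
  grid <- env$grid
  set.seed(cfg$seed + 1013L)
  nd <- nrow(track)
  if (is.null(ljfl_cm)) ljfl_cm <- round(stats::runif(1, 100, 260))
  dep <- deployment(tag_id,
                    track$date[1], track$lon[1], track$lat[1],
                    track$date[nd], track$lon[nd], track$lat[nd],
                    ljfl_cm = ljfl_cm, agency = "synthetic")
  rec <- data.frame(date = track$date, sst = NA_real_, sunrise_ut = NA_real_,
                    sunset_ut = NA_real_, max_depth = 0, n_samples = 0L)
  corrupted <- list()
  for (i in seq_len(nd)) {
    bathy_i <- grid$bathy[track$row[i], track$col[i]]
    rec$max_depth[i] <- stats::runif(1, 30, max(31, min(0.9 * bathy_i, cfg$max_depth_cap_m)))
    if (stats::runif(1) < cfg$p_sst_day) {
      ref <- env_sst(env, track$date[i])[track$row[i], track$col[i]]
      rec$sst[i] <- ref + stats::rnorm(1, 0, cfg$sigma_sst)
      rec$n_samples[i] <- rec$n_samples[i] + 3L
    }
    if (stats::runif(1) < cfg$p_event_day) {
      pr <- predict_event_times(track$lon[i], track$lat[i], track$date[i])
      if (pr$status[1] == "normal") {
        rec$sunrise_ut[i] <- (pr$sunrise_ut[1] + stats::rnorm(1, 0, cfg$sigma_event)) %% 1440
        rec$sunset_ut[i] <- (pr$sunset_ut[1] + stats::rnorm(1, 0, cfg$sigma_event)) %% 1440
        for (ev in c("sunrise", "sunset")) {
          if (stats::runif(1) < cfg$p_corrupt) {
            rec[[paste0(ev, "_ut")]][i] <- stats::runif(1, 0, 1440)
            corrupted[[length(corrupted) + 1]] <-
              data.frame(date = track$date[i], event = ev)
          }
        }
      }
    }
  }
  corrupted <- if (length(corrupted)) do.call(rbind, corrupted) else
    data.frame(date = as.Date(character()), event = character())
  list(dep = dep, records = rec, corrupted = corrupted)
}

#' Expand daily records into a synthetic sensor time series
#'
#' Inverse-direction helper for round-trip tests of the preprocessing stage:
#' emits, per day, three shallow samples at the recorded SST (so the 0-15 m
#' median reproduces it) and one deep sample at the recorded maximum depth.
#'
#' @param records daily records.
#' @param tag_id tag identifier column value.
#' @return sensor series data.frame `tag_id`, `timestamp`, `depth_m`, `temp_c`.
#' @export
records_to_series <- function(records, tag_id = "sim-1") {
  out <- list()
  for (i in seq_len(nrow(records))) {
    day <- as.POSIXct(paste(records$date[i], "00:00:00"), tz = "UTC")
    if (!is.na(records$sst[i])) {
      out[[length(out) + 1]] <- data.frame(
        tag_id = tag_id,
        timestamp = day + c(3600, 3720, 3840),
        depth_m = c(3, 8, 12),
        temp_c = records$sst[i] + c(-0.05, 0, 0.05))
    }
    if (records$max_depth[i] > 0) {
      out[[length(out) + 1]] <- data.frame(
        tag_id = tag_id, timestamp = day + 43200,
        depth_m = records$max_depth[i],
        temp_c = 6)
    }
  }
  if (!length(out)) return(data.frame(tag_id = character(), timestamp = as.POSIXct(character()),
                                      depth_m = numeric(), temp_c = numeric()))
  do.call(rbind, out)
}

#' End-to-end calibration experiment on simulated tags
#'
#' Simulates `n_tags` deployments, runs the full pipeline (records, forward
#' and backward filters, two-filter smoother) on each, and reports whether
#' the daily smoothed 95% HPD region covers the true position, the mean HPD
#' area, endpoint mode errors, and the realized observation sparsity.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds tag i with `seed + i`.
#' @param n_tags number of simulated deployments (>= 1).
#' @param env optional prebuilt `tag_env` (one is made from `cfg$seed` if
#'   NULL).
#' @param mp_fit movement parameters used by the filter (defaults to the
#'   true simulated diffusivity - the well-specified regime).
#' @param op observation parameters for the filter (defaults match the
#'   simulated noise).
#' @param hpd_level daily HPD level scored (default 0.95).
#' @return list: `coverage` (fraction of fish-days with the true cell inside
#'   the daily HPD region), `mean_hpd_area_km2`, `frac_event_days`,
#'   `frac_sst_days`, `n_fish_days`, `per_tag` data.frame, and `results`
#'   (per-tag list of `dep`, `track`, `smoothed`).
#' @export
calibration_experiment <- function(cfg, n_tags = 20, env = NULL,
                                   mp_fit = NULL, op = NULL,
                                   hpd_level = 0.95) {
  stopifnot(n_tags >= 1)
  if (is.null(env)) env <- make_environment(seed = cfg$seed)
  if (is.null(mp_fit)) mp_fit <- movement_params(D = cfg$D)
  if (is.null(op)) op <- observation_params(sigma_sst = cfg$sigma_sst,
                                            sigma_event = cfg$sigma_event)
  per_tag <- list()
  results <- list()
  for (i in seq_len(n_tags)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    start_date <- env$dates[1] + (cfg$seed + 7 * i) %%
      max(1, length(env$dates) - cfg$n_days)
    track <- simulate_track(env, cfg_i, start_date = start_date)
    sim <- simulate_tag_records(track, env, cfg_i, tag_id = sprintf("sim-%03d", i))
    fwd <- forward_filter(sim$dep, sim$records, env, mp_fit, op)
    bwd <- backward_filter(sim$dep, sim$records, env, mp_fit, op)
    st <- two_filter_smooth(fwd, bwd)
    nd <- nrow(track)
    cov <- area <- numeric(nd)
    for (t in seq_len(nd)) {
      mask <- hpd_mask(st$fields[[t]], hpd_level)
      cov[t] <- mask[track$row[t], track$col[t]]
      area[t] <- sum(env$grid$area_km2[mask])
    }
    mode_err_end <- {
      mlast <- st$fields[[nd]]
      idx <- which(mlast == max(mlast), arr.ind = TRUE)[1, ]
      sqrt((env$grid$lat[idx[1]] - track$lat[nd])^2 +
             (env$grid$lon[idx[2]] - track$lon[nd])^2) * KM_PER_DEG
    }
    per_tag[[i]] <- data.frame(
      tag = sim$dep$tag_id, n_days = nd,
      coverage = mean(cov), mean_area_km2 = mean(area),
      endpoint_err_km = mode_err_end,
      frac_event = mean(!is.na(sim$records$sunrise_ut) | !is.na(sim$records$sunset_ut)),
      frac_sst = mean(!is.na(sim$records$sst)),
      log_lik = fwd$log_lik)
    results[[i]] <- list(dep = sim$dep, track = track, smoothed = st,
                         records = sim$records)
  }
  per_tag <- do.call(rbind, per_tag)
  n_days_tot <- sum(per_tag$n_days)
  list(
    coverage = sum(per_tag$coverage * per_tag$n_days) / n_days_tot,
    mean_hpd_area_km2 = mean(per_tag$mean_area_km2),
    frac_event_days = sum(per_tag$frac_event * per_tag$n_days) / n_days_tot,
    frac_sst_days = sum(per_tag$frac_sst * per_tag$n_days) / n_days_tot,
    n_fish_days = n_days_tot,
    per_tag = per_tag,
    results = results
  )
}
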