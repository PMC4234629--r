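# Conversion of sensor time series into daily records and set-membership
# cleaning of solar event times.

#' Deployment metadata
#'
#' @param tag_id identifier.
#' @param release_date,release_lon,release_lat deployment date and position.
#' @param popup_date,popup_lon,popup_lat pop-up date and position.
#' @param ljfl_cm lower-jaw fork length, cm (> 0).
#' @param agency free-text agency label.
#' @return object of class `deployment`.
#' @export
deployment <- function(tag_id, release_date, release_lon, release_lat,
                       popup_date, popup_lon, popup_lat,
                       ljfl_cm = NA_real_, agency = NA_character_) {
  release_date <- as.Date(release_date); popup_date <- as.Date(popup_date)
  if (!(popup_date > release_date)) stop("popup date must follow release date")
  if (!is.na(ljfl_cm) && ljfl_cm <= 0) stop("ljfl_cm must be positive")
  structure(list(
    tag_id = as.character(tag_id),
    release_date = release_date, release_lon = release_lon, release_lat = release_lat,
    popup_date = popup_date, popup_lon = popup_lon, popup_lat = popup_lat,
    ljfl_cm = ljfl_cm, agency = agency
  ), class = "deployment")
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("deployment %s: %s (%.2f, %.2f) -> %s (%.2f, %.2f), %d d, LJFL %s cm\n",
              x$tag_id, x$release_date, x$release_lon, x$release_lat,
              x$popup_date, x$popup_lon, x$popup_lat,
              as.integer(x$popup_date - x$release_date),
              format(x$ljfl_cm)))
  invisible(x)
}

n_deployment_days <- function(dep) as.integer(dep$popup_date - dep$release_date) + 1L

deployment_dates <- function(dep) seq(dep$release_date, dep$popup_date, by = "day")

# ---- daily summaries --------------------------------------------------------

validate_series <- function(series) {
  need <- c("timestamp", "depth_m", "temp_c")
  if (!all(need %in% names(series)))
    stop("sensor series needs columns: ", paste(need, collapse = ", "))
  bad <- !is.na(series$depth_m) & series$depth_m < 0
  if (any(bad)) {
    warning(sum(bad), " samples with negative depth rejected")
    series <- series[!bad, , drop = FALSE]
  }
  series
}

#' Daily SST estimate from a sensor series
#'
#' Median of the temperatures measured between the surface and 15 m depth on
#' the given day; absent (NA) when the animal never visited that layer.
#'
#' @param series data.frame with `timestamp` (POSIXct UT), `depth_m`, `temp_c`.
#' @param date the day (Date).
#' @param max_sst_depth_m surface layer depth (default 15).
#' @return SST in deg C, or NA.
#' @export
daily_sst_estimate <- function(series, date, max_sst_depth_m = 15) {
  series <- validate_series(series)
  sel <- as.Date(series$timestamp, tz = "UTC") == as.Date(date) &
    series$depth_m <= max_sst_depth_m & !is.na(series$temp_c)
  if (!any(sel)) return(NA_real_)
  stats::median(series$temp_c[sel])
}

#' Daily maximum depth from a sensor series
#'
#' @inheritParams daily_sst_estimate
#' @return maximum depth in metres that day; 0 when the day has no samples.
#' @export
daily_max_depth <- function(series, date) {
  series <- validate_series(series)
  sel <- as.Date(series$timestamp, tz = "UTC") == as.Date(date) & !is.na(series$depth_m)
  if (!any(sel)) return(0)
  max(series$depth_m[sel])
}

#' Build daily records for a deployment
#'
#' One row per day between release and pop-up: daily SST estimate, maximum
#' depth, and (optionally merged) sunrise/sunset observation times. Days with
#' no samples yield all-absent fields and are treated by the filter as pure
#' prediction days.
#'
#' @param dep a [deployment()].
#' @param series sensor series data.frame (may be empty).
#' @param events optional data.frame `date`, `sunrise_ut`, `sunset_ut`
#'   (minutes UT; NA where unobserved).
#' @return data.frame of daily records: `date`, `sst`, `sunrise_ut`,
#'   `sunset_ut`, `max_depth`, `n_samples`.
#' @export
build_daily_records <- function(dep, series = NULL, events = NULL) {
  dates <- deployment_dates(dep)
  rec <- data.frame(date = dates, sst = NA_real_, sunrise_ut = NA_real_,
                    sunset_ut = NA_real_, max_depth = 0, n_samples = 0L)
  if (!is.null(series) && nrow(series)) {
    series <- validate_series(series)
    sday <- as.Date(series$timestamp, tz = "UTC")
    for (i in seq_along(dates)) {
      sel <- sday == dates[i]
      rec$n_samples[i] <- sum(sel)
      if (any(sel)) {
        sub <- series[sel, , drop = FALSE]
        rec$sst[i] <- daily_sst_estimate(sub, dates[i])
        rec$max_depth[i] <- daily_max_depth(sub, dates[i])
      }
    }
  }
  if (!is.null(events) && nrow(events)) {
    ev <- events
    ev$date <- as.Date(ev$date)
    idx <- match(ev$date, rec$date)
    ok <- !is.na(idx)
    if ("sunrise_ut" %in% names(ev)) rec$sunrise_ut[idx[ok]] <- ev$sunrise_ut[ok]
    if ("sunset_ut" %in% names(ev)) rec$sunset_ut[idx[ok]] <- ev$sunset_ut[ok]
  }
  rec
}

# ---- set-membership feasibility --------------------------------------------

# Observation gate for one day: water & bathymetry & SST band.
day_constraint_mask <- function(grid, env, date, sst_obs, max_depth,
                                k_sst, sigma_sst) {
  m <- grid$water
  if (!is.na(max_depth) && max_depth > 0)
    m <- m & (grid$bathy >= max_depth)
  if (!is.na(sst_obs)) {
    ref <- env_sst(env, date)
    m <- m & (abs(ref - sst_obs) <= k_sst * sigma_sst)
  }
  m
}

#' Propagate daily feasible position sets
#'
#' Set-membership cleaning support: starting from the deployment cell, each
#' day's feasible set is the previous day's set dilated by the maximum
#' sustainable speed (through water only), intersected with the land mask,
#' the bathymetry-vs-max-depth constraint and the SST band. An analogous
#' backward pass starts from the pop-up cell; the returned per-day set is the
#' intersection of the two passes. A day whose observation constraints empty
#' the set keeps only speed+land for that day and is flagged (sensor error is
#' more plausible than teleportation).
#'
#' @param dep a [deployment()].
#' @param records daily records from [build_daily_records()].
#' @param env an environment object (see [make_environment()]); supplies the
#'   grid, reference SST, land mask, bathymetry.
#' @param vmax maximum sustained speed, km/day (default 150).
#' @param k_sst SST gate width in units of `sigma_sst` (default 3).
#' @param sigma_sst SST observation standard deviation, deg C (default 1).
#' @return list with `masks` (list of logical ny x nx, one per day),
#'   `relaxed` (logical per day: observation constraints dropped), and
#'   `dates`.
#' @export
propagate_feasible_sets <- function(dep, records, env, vmax = 150,
                                    k_sst = 3, sigma_sst = 1) {
  grid <- env$grid
  dates <- deployment_dates(dep)
  nd <- length(dates)
  stopifnot(nrow(records) == nd, vmax > 0)

  endpoint_mask <- function(lon, lat, what) {
    f <- delta_field(grid, lon, lat)
    if (isTRUE(attr(f, "snapped")))
      message(what, " position snapped to nearest water cell")
    f$m > 0
  }
  rel <- endpoint_mask(dep$release_lon, dep$release_lat, "release")
  pop <- endpoint_mask(dep$popup_lon, dep$popup_lat, "popup")

  one_pass <- function(init, forward) {
    idx <- if (forward) seq_len(nd) else rev(seq_len(nd))
    masks <- vector("list", nd)
    relaxed <- logical(nd)
    cur <- init
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (k > 1) cur <- dilate_mask(grid, cur, vmax)
      gate <- day_constraint_mask(grid, env, dates[i], records$sst[i],
                                  records$max_depth[i], k_sst, sigma_sst)
      nxt <- cur & gate
      if (k == 1) nxt <- cur  # endpoint day: trust the known position
      if (!any(nxt)) {
        nxt <- cur
        relaxed[i] <- TRUE
      }
      masks[[i]] <- nxt
      cur <- nxt
    }
    list(masks = masks, relaxed = relaxed)
  }

  fwd <- one_pass(rel, forward = TRUE)
  bwd <- one_pass(pop, forward = FALSE)

  masks <- vector("list", nd)
  relaxed <- fwd$relaxed | bwd$relaxed
  for (i in seq_len(nd)) {
    m <- fwd$masks[[i]] & bwd$masks[[i]]
    if (!any(m)) {
      # fall back to speed+land reachability from both endpoints
      df <- grid_distance_km(grid, rel, max_km = vmax * (i - 1))
      db <- grid_distance_km(grid, pop, max_km = vmax * (nd - i))
      m <- (df <= vmax * (i - 1)) & (db <= vmax * (nd - i))
      relaxed[i] <- TRUE
      if (!any(m)) {
        m <- grid$water
      }
    }
    masks[[i]] <- m
  }
  list(masks = masks, relaxed = relaxed, dates = dates)
}

#' Screen solar event times against feasible sets
#'
#' For each observed sunrise/sunset time, the predicted event time is
#' computed over every cell of that day's feasible set; the observation is
#' discarded (set to NA) when its minimal circular distance to the set of
#' predictions exceeds `k_reject * sigma_min`.
#'
#' @param records daily records.
#' @param fsets output of [propagate_feasible_sets()].
#' @param grid the model grid.
#' @param h0 twilight sun altitude, degrees.
#' @param sigma_min event-time observation standard deviation, minutes.
#' @param k_reject gate width in sigmas (default 3).
#' @return list with `records` (edited) and `report` data.frame
#'   (`date`, `event`, `obs_min`, `dist_min`, `kept`, `reason`).
#' @export
screen_event_times <- function(records, fsets, grid, h0 = -0.833,
                               sigma_min = 20, k_reject = 3) {
  report <- list()
  out <- records
  for (i in seq_len(nrow(records))) {
    for (ev in c("sunrise", "sunset")) {
      colname <- paste0(ev, "_ut")
      obs <- records[[colname]][i]
      if (is.na(obs)) next
      mask <- fsets$masks[[i]]
      idx <- which(mask, arr.ind = TRUE)
      lons <- grid$lon[idx[, 2]]
      lats <- grid$lat[idx[, 1]]
      pr <- predict_event_times(lons, lats, records$date[i], h0 = h0)
      pred <- if (ev == "sunrise") pr$sunrise_ut else pr$sunset_ut
      ok <- pr$status == "normal"
      if (!any(ok)) {
        report[[length(report) + 1]] <- data.frame(
          date = records$date[i], event = ev, obs_min = obs,
          dist_min = NA_real_, kept = TRUE, reason = "all_polar")
        next
      }
      dmin <- min(abs(circular_minutes(obs, pred[ok])))
      keep <- dmin <= k_reject * sigma_min
      if (!keep) out[[colname]][i] <- NA_real_
      report[[length(report) + 1]] <- data.frame(
        date = records$date[i], event = ev, obs_min = obs,
        dist_min = dmin, kept = keep,
        reason = if (keep) "within_gate" else "outside_gate")
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(date = as.Date(character()), event = character(),
               obs_min = numeric(), dist_min = numeric(),
               kept = logical(), reason = character())
  list(records = out, report = report)
}
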