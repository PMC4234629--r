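# File formats, configuration and the pipeline tying the stages together.

# ---- CSV formats ------------------------------------------------------------

#' Read a tag sensor series CSV
#'
#' Columns: `tag_id`, `timestamp` (ISO-8601 UT), `depth_m`, `temp_c`.
#'
#' @param path file path.
#' @return data.frame with POSIXct timestamps, negative-depth samples
#'   dropped with a warning.
#' @export
read_tag_series <- function(path) {
  if (!file.exists(path)) stop("tag series file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "timestamp", "depth_m", "temp_c")
  if (!all(need %in% names(df)))
    stop("tag series CSV must have columns: ", paste(need, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  for (id in unique(df$tag_id)) {
    ts <- df$timestamp[df$tag_id == id]
    if (is.unsorted(ts, strictly = FALSE))
      stop("timestamps not increasing for tag ", id)
  }
  validate_series(df)
}

#' Read deployment metadata CSV
#'
#' Columns: `tag_id`, `release_date`, `release_lon`, `release_lat`,
#' `popup_date`, `popup_lon`, `popup_lat`, `ljfl_cm`, `agency`.
#'
#' @param path file path.
#' @return list of [deployment()] objects, named by tag_id.
#' @export
read_deployments <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "release_date", "release_lon", "release_lat",
            "popup_date", "popup_lon", "popup_lat")
  if (!all(need %in% names(df)))
    stop("metadata CSV must have columns: ", paste(need, collapse = ", "))
  deps <- lapply(seq_len(nrow(df)), function(i)
    deployment(df$tag_id[i], df$release_date[i], df$release_lon[i],
               df$release_lat[i], df$popup_date[i], df$popup_lon[i],
               df$popup_lat[i],
               ljfl_cm = if ("ljfl_cm" %in% names(df)) df$ljfl_cm[i] else NA_real_,
               agency = if ("agency" %in% names(df)) df$agency[i] else NA_character_))
  names(deps) <- df$tag_id
  deps
}

#' Write deployment metadata CSV
#'
#' @param deps list of [deployment()] objects.
#' @param path output path.
#' @export
write_deployments <- function(deps, path) {
  df <- do.call(rbind, lapply(deps, function(d)
    data.frame(tag_id = d$tag_id,
               release_date = as.character(d$release_date),
               release_lon = d$release_lon, release_lat = d$release_lat,
               popup_date = as.character(d$popup_date),
               popup_lon = d$popup_lon, popup_lat = d$popup_lat,
               ljfl_cm = d$ljfl_cm, agency = d$agency)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write daily records CSV
#'
#' Columns: `date`, `sst`, `sunrise_ut`, `sunset_ut`, `max_depth` (and
#' optionally `n_samples`).
#'
#' @param path file path.
#' @return data.frame of daily records.
#' @export
read_daily_records <- function(path) {
  if (!file.exists(path)) stop("daily records file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "sst", "sunrise_ut", "sunset_ut", "max_depth")
  if (!all(need %in% names(df)))
    stop("daily records CSV must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  if (!"n_samples" %in% names(df)) df$n_samples <- NA_integer_
  df
}

#' @rdname read_daily_records
#' @param records daily records data.frame.
#' @export
write_daily_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a stack of probability fields to long-format CSV
#'
#' Plain-text stand-in for a (time, lat, lon) gridded export: one row per
#' water cell and day with nonzero mass.
#'
#' @param fields list of ny x nx mass matrices.
#' @param dates Date vector parallel to `fields`.
#' @param grid the `tag_grid`.
#' @param path output path.
#' @export
write_field_stack <- function(fields, dates, grid, path) {
  rows <- lapply(seq_along(fields), function(t) {
    idx <- which(fields[[t]] > 0, arr.ind = TRUE)
    data.frame(date = as.character(dates[t]),
               lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
               p = fields[[t]][idx])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export HPD regions to GeoJSON
#'
#' Each level becomes a MultiPolygon feature of the member cells' bounding
#' boxes (no dissolving of shared edges - consumers see the exact cell set).
#'
#' @param regions an `hpd_regions` object.
#' @param path output path.
#' @export
write_hpd_geojson <- function(regions, path) {
  g <- regions$grid
  hx <- g$dlon / 2; hy <- g$dlat / 2
  features <- lapply(seq_along(regions$levels), function(i) {
    mask <- regions$masks[[i]]
    idx <- which(mask, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(idx)), function(k) {
      x <- g$lon[idx[k, 2]]; y <- g$lat[idx[k, 1]]
      list(list(
        c(x - hx, y - hy), c(x + hx, y - hy), c(x + hx, y + hy),
        c(x - hx, y + hy), c(x - hx, y - hy)))
    })
    list(type = "Feature",
         properties = list(level = regions$levels[i]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' All tunable parameters of the stages with their defaults. Unknown
#' arguments are rejected.
#'
#' @param resolution_km grid resolution (9).
#' @param sigma_sst,sigma_event observation noise (1 deg C, 20 min).
#' @param h0 twilight altitude (-0.833 deg).
#' @param vmax maximum sustained speed for feasibility (150 km/day).
#' @param k_sst,k_reject feasibility / screening gate widths in sigmas (3).
#' @param D movement diffusivity km^2/day (300), or a vector of candidates
#'   to select by likelihood per tag.
#' @param levels HPD mass levels (0.5, 0.75, 0.95).
#' @param min_days minimum deployment length retained (30).
#' @param seed integer seed (1).
#' @return list of class `run_config`.
#' @export
run_config <- function(resolution_km = 9, sigma_sst = 1.0, sigma_event = 20,
                       h0 = -0.833, vmax = 150, k_sst = 3, k_reject = 3,
                       D = 300, levels = c(0.5, 0.75, 0.95),
                       min_days = 30, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small stable fingerprint without extra deps
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Select tags by minimum deployment length
#'
#' @param deps list of [deployment()] objects.
#' @param min_days minimum (popup - release) in days retained (default 30).
#' @return list: `selected` (list of deployments), `report` data.frame
#'   (`tag_id`, `days`, `retained`).
#' @export
select_tags <- function(deps, min_days = 30) {
  if (!length(deps)) {
    warning("empty deployment metadata")
    return(list(selected = list(),
                report = data.frame(tag_id = character(), days = integer(),
                                    retained = logical())))
  }
  days <- vapply(deps, function(d) as.integer(d$popup_date - d$release_date),
                 integer(1))
  keep <- days >= min_days
  list(selected = deps[keep],
       report = data.frame(tag_id = vapply(deps, `[[`, "", "tag_id"),
                           days = days, retained = keep))
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full geolocation pipeline
#'
#' For each selected tag: feasible-set propagation, event-time screening,
#' forward and backward filters, two-filter smoothing; then pooled UDs by
#' quarter/maturity with HPD regions, and point coverage when point data are
#' given. Writes per-tag rejection reports, smoothed field stacks, pooled UD
#' surfaces, GeoJSON contours and a provenance header; deterministic given
#' (inputs, cfg, seed). Per-tag failures are caught, logged and skipped; the
#' run errors only if every tag fails.
#'
#' @param deps list of [deployment()] objects.
#' @param records_by_tag named list of daily-record data.frames.
#' @param env a `tag_env` (grid + reference SST).
#' @param cfg a [run_config()].
#' @param points optional data.frame `lon`, `lat`, `date` for coverage.
#' @param out_dir output directory (created if missing); NULL disables file
#'   output.
#' @return list: `tracks` (per tag: dep, smoothed, screening report),
#'   `uds` (by quarter x maturity where nonempty), `regions`, `coverage`
#'   (or NULL), `failures`.
#' @export
run_pipeline <- function(deps, records_by_tag, env, cfg = run_config(),
                         points = NULL, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  op <- observation_params(sigma_sst = cfg$sigma_sst,
                           sigma_event = cfg$sigma_event, h0 = cfg$h0)
  tracks <- list()
  failures <- character()
  for (dep in deps) {
    id <- dep$tag_id
    res <- tryCatch({
      records <- records_by_tag[[id]]
      if (is.null(records)) stop("no records for tag ", id)
      fs <- propagate_feasible_sets(dep, records, env, vmax = cfg$vmax,
                                    k_sst = cfg$k_sst, sigma_sst = cfg$sigma_sst)
      sc <- screen_event_times(records, fs, env$grid, h0 = cfg$h0,
                               sigma_min = cfg$sigma_event,
                               k_reject = cfg$k_reject)
      D <- cfg$D
      if (length(D) > 1)
        D <- fit_diffusion(dep, sc$records, env, op, D_candidates = D)$D_hat
      mp <- movement_params(D = D)
      fwd <- forward_filter(dep, sc$records, env, mp, op)
      bwd <- backward_filter(dep, sc$records, env, mp, op)
      st <- two_filter_smooth(fwd, bwd)
      list(dep = dep, track = st, screening = sc$report, D = D,
           log_lik = fwd$log_lik)
    }, error = function(e) {
      message("tag ", id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, id) else tracks[[id]] <- res
  }
  if (!length(tracks)) stop("all tags failed: ", paste(failures, collapse = ", "))

  pool_in <- lapply(tracks, function(x) list(track = x$track, dep = x$dep))
  uds <- list()
  regions <- list()
  for (q in c(1:4, "all")) {
    ud <- tryCatch(pool_ud(pool_in, quarter = if (q == "all") "all" else as.integer(q)),
                   error = function(e) NULL)
    if (!is.null(ud)) {
      key <- paste0("Q", q)
      uds[[key]] <- ud
      regions[[key]] <- hpd_regions(ud, levels = cfg$levels)
    }
  }
  coverage <- NULL
  if (!is.null(points) && nrow(points)) {
    regs_q <- lapply(1:4, function(q) regions[[paste0("Q", q)]])
    coverage <- point_coverage(points, regs_q, level = max(cfg$levels),
                               grid = env$grid)
  }

  if (!is.null(out_dir)) {
    prov <- list(package = "gridtag",
                 version = as.character(utils::packageVersion("gridtag")),
                 config = unclass(cfg), config_hash = config_hash(cfg))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    for (id in names(tracks)) {
      x <- tracks[[id]]
      utils::write.csv(x$screening,
                       file.path(out_dir, paste0(id, "_screening.csv")),
                       row.names = FALSE)
      write_field_stack(x$track$fields, deployment_dates(x$dep), env$grid,
                        file.path(out_dir, paste0(id, "_smoothed.csv")))
      utils::write.csv(track_summary(x$track),
                       file.path(out_dir, paste0(id, "_track_summary.csv")),
                       row.names = FALSE)
    }
    for (key in names(uds)) {
      ud <- uds[[key]]
      idx <- which(ud$m > 0, arr.ind = TRUE)
      utils::write.csv(data.frame(lon = env$grid$lon[idx[, 2]],
                                  lat = env$grid$lat[idx[, 1]],
                                  p = ud$m[idx]),
                       file.path(out_dir, paste0("ud_", key, ".csv")),
                       row.names = FALSE)
      write_hpd_geojson(regions[[key]],
                        file.path(out_dir, paste0("ud_", key, ".geojson")))
    }
    if (!is.null(coverage))
      utils::write.csv(coverage$table, file.path(out_dir, "coverage.csv"),
                       row.names = FALSE)
  }
  list(tracks = tracks, uds = uds, regions = regions, coverage = coverage,
       failures = failures)
}
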