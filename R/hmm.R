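# The grid-filter HMM: per-day observation likelihood fields, forward and
# backward filters, two-filter smoothing, and diffusivity estimation.

#' Observation model parameters
#'
#' @param sigma_sst SST standard deviation, deg C (default 1.0).
#' @param sigma_event sunrise/sunset standard deviation, minutes (default 20).
#' @param h0 twilight sun altitude, degrees (default -0.833).
#' @param use_depth_gate apply the bathymetry-vs-max-depth constraint in the
#'   likelihood (default TRUE).
#' @return object of class `observation_params`.
#' @export
observation_params <- function(sigma_sst = 1.0, sigma_event = 20,
                               h0 = -0.833, use_depth_gate = TRUE) {
  stopifnot(sigma_sst > 0, sigma_event > 0)
  structure(list(sigma_sst = sigma_sst, sigma_event = sigma_event,
                 h0 = h0, use_depth_gate = use_depth_gate),
            class = "observation_params")
}

#' Per-day observation likelihood field
#'
#' Cellwise product of: a Gaussian SST match against the day's reference SST
#' field (when the record carries SST); Gaussian sunrise / sunset time
#' matches against the solar prediction at each cell (when present), with a
#' finite floor on polar-status cells; and a hard bathymetry gate (zero where
#' the water is shallower than the day's maximum measured depth). A record
#' with no observations yields a uniform likelihood over water.
#'
#' @param rec one daily record (single row of [build_daily_records()] output,
#'   or a list with the same fields).
#' @param env environment object (grid + reference SST).
#' @param op [observation_params()].
#' @return ny x nx likelihood matrix (not normalized; zero on land).
#' @export
observation_likelihood_field <- function(rec, env, op = observation_params()) {
  grid <- env$grid
  ll <- matrix(0, grid$ny, grid$nx)  # log-likelihood accumulator over water
  any_obs <- FALSE
  if (!is.null(rec$sst) && !is.na(rec$sst)) {
    ref <- env_sst(env, rec$date)
    ll <- ll + stats::dnorm(rec$sst, mean = ref, sd = op$sigma_sst, log = TRUE)
    any_obs <- TRUE
  }
  ev_obs <- c(sunrise = rec$sunrise_ut, sunset = rec$sunset_ut)
  if (any(!is.na(ev_obs))) {
    lonm <- outer(rep(1, grid$ny), grid$lon)
    latm <- outer(grid$lat, rep(1, grid$nx))
    pr <- predict_event_times(as.vector(lonm), as.vector(latm), rec$date, h0 = op$h0)
    if (!is.na(ev_obs["sunrise"]))
      ll <- ll + matrix(event_log_likelihood(ev_obs[["sunrise"]], pr$sunrise_ut,
                                             op$sigma_event, pr$status),
                        grid$ny, grid$nx)
    if (!is.na(ev_obs["sunset"]))
      ll <- ll + matrix(event_log_likelihood(ev_obs[["sunset"]], pr$sunset_ut,
                                             op$sigma_event, pr$status),
                        grid$ny, grid$nx)
    any_obs <- TRUE
  }
  lik <- exp(ll - max(ll[grid$water]))
  if (!any_obs) lik[] <- 1
  if (op$use_depth_gate && !is.null(rec$max_depth) &&
      !is.na(rec$max_depth) && rec$max_depth > 0)
    lik[grid$bathy < rec$max_depth] <- 0
  lik[!grid$water] <- 0
  lik
}

# ---- core filter ------------------------------------------------------------

#' Run the grid filter over a sequence of likelihood fields
#'
#' Low-level HMM recursion: alternate the advection-diffusion prediction step
#' with Bayes observation updates. Day 1 is the initial field updated by the
#' first likelihood; each later day is predicted from the previous posterior
#' then updated. Fields are renormalized every day; the log normalizing
#' constants accumulate to the data log-likelihood.
#'
#' @param init initial [prob_field()].
#' @param liks list of ny x nx likelihood matrices, one per day (the first
#'   applies to the initial day).
#' @param mp [movement_params()].
#' @param adjoint propagate with the transpose kernel (backward information
#'   filter); advection, if any, is negated.
#' @return list of class `filter_result`: `pred`, `post` (lists of mass
#'   matrices), `log_norm` (per-day), `log_lik`, `grid`.
#' @export
grid_filter <- function(init, liks, mp, adjoint = FALSE) {
  grid <- init$grid
  nd <- length(liks)
  stopifnot(nd >= 1)
  pred <- vector("list", nd)
  post <- vector("list", nd)
  log_norm <- numeric(nd)
  m <- init$m
  relaxed <- logical(nd)
  for (t in seq_len(nd)) {
    if (t > 1) m <- propagate_mass(m, grid, mp, adjoint = adjoint)
    pred[[t]] <- m
    up <- m * liks[[t]]
    s <- sum(up)
    if (s <= 0) {
      # all cells gated out: drop the hard gate by using ranks of the
      # likelihood support only where prediction lives
      up <- m
      s <- sum(up)
      relaxed[t] <- TRUE
    }
    log_norm[t] <- log(s)
    m <- up / s
    post[[t]] <- m
  }
  structure(list(pred = pred, post = post, log_norm = log_norm,
                 log_lik = sum(log_norm), grid = grid, relaxed = relaxed,
                 adjoint = adjoint),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d days, log-likelihood %.3f%s\n",
              length(x$post), x$log_lik,
              if (x$adjoint) " (backward)" else ""))
  invisible(x)
}

build_likelihoods <- function(dep, records, env, op) {
  dates <- deployment_dates(dep)
  stopifnot(nrow(records) == length(dates))
  lapply(seq_along(dates), function(i)
    observation_likelihood_field(records[i, ], env, op))
}

#' Forward filter for a deployment
#'
#' Initializes at the deployment position, runs the predict/update recursion
#' over all days, and applies the pop-up position as a final (exact) update.
#'
#' @param dep a [deployment()].
#' @param records daily records spanning release to pop-up.
#' @param env environment object.
#' @param mp [movement_params()].
#' @param op [observation_params()].
#' @return a `filter_result` (see [grid_filter()]).
#' @export
forward_filter <- function(dep, records, env, mp, op = observation_params()) {
  grid <- env$grid
  liks <- build_likelihoods(dep, records, env, op)
  nd <- length(liks)
  liks[[nd]] <- liks[[nd]] * delta_field(grid, dep$popup_lon, dep$popup_lat)$m
  init <- delta_field(grid, dep$release_lon, dep$release_lat, dep$release_date)
  grid_filter(init, liks, mp, adjoint = FALSE)
}

#' Backward filter for a deployment
#'
#' Mirror of [forward_filter()]: initialized at the pop-up position, runs on
#' time-reversed records propagating with the transpose (adjoint) kernel, and
#' applies the release position as its final update. With pure-diffusion
#' dynamics the adjoint kernel equals the forward kernel up to cell-area
#' weighting; advection velocities are negated.
#'
#' @inheritParams forward_filter
#' @return a `filter_result` in backward time (element 1 = last day).
#' @export
backward_filter <- function(dep, records, env, mp, op = observation_params()) {
  grid <- env$grid
  liks <- build_likelihoods(dep, records, env, op)
  nd <- length(liks)
  liks[[1]] <- liks[[1]] * delta_field(grid, dep$release_lon, dep$release_lat)$m
  liks <- rev(liks)
  init <- delta_field(grid, dep$popup_lon, dep$popup_lat, dep$popup_date)
  grid_filter(init, liks, mp, adjoint = TRUE)
}

#' Two-filter smoother
#'
#' Combines forward-filtered posteriors with backward-filter predicted
#' densities: `smoothed(t)` is proportional to the cellwise product of the
#' forward updated field at day t with the backward predicted field at day t
#' (which excludes day-t observations, so nothing is double counted). The
#' result is the exact HMM smoothing marginal on the grid, anchored at the
#' deployment and pop-up positions.
#'
#' @param fwd forward `filter_result`.
#' @param bwd backward `filter_result` from [backward_filter()].
#' @return list of class `smoothed_track`: `fields` (per-day mass matrices),
#'   `dates` optional, `fallback` (days where the product vanished and the
#'   forward posterior was used), `grid`.
#' @export
two_filter_smooth <- function(fwd, bwd) {
  nd <- length(fwd$post)
  stopifnot(length(bwd$post) == nd)
  fields <- vector("list", nd)
  fallback <- logical(nd)
  for (t in seq_len(nd)) {
    # backward element for day t sits at reversed index nd - t + 1; its
    # predicted (pre-update) field excludes day-t observations. At t = nd
    # this is the backward init itself (pred[[1]] = init).
    bidx <- nd - t + 1
    binfo <- bwd$pred[[bidx]]
    m <- fwd$post[[t]] * binfo
    s <- sum(m)
    if (s <= 0) {
      m <- fwd$post[[t]]
      s <- sum(m)
      fallback[t] <- TRUE
    }
    fields[[t]] <- m / s
  }
  structure(list(fields = fields, fallback = fallback, grid = fwd$grid),
            class = "smoothed_track")
}

#' @export
print.smoothed_track <- function(x, ...) {
  cat(sprintf("smoothed_track: %d days on %d x %d grid\n",
              length(x$fields), x$grid$ny, x$grid$nx))
  invisible(x)
}

#' Daily mode and HPD area summary of a smoothed track
#'
#' @param st a `smoothed_track`.
#' @param level HPD mass level (default 0.95).
#' @return data.frame `day`, `mode_lon`, `mode_lat`, `hpd_area_km2`.
#' @export
track_summary <- function(st, level = 0.95) {
  g <- st$grid
  do.call(rbind, lapply(seq_along(st$fields), function(t) {
    m <- st$fields[[t]]
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    reg <- hpd_mask(m, level)
    data.frame(day = t - 1, mode_lon = g$lon[idx[2]], mode_lat = g$lat[idx[1]],
               hpd_area_km2 = sum(g$area_km2[reg]))
  }))
}

#' Estimate diffusivity by likelihood grid search
#'
#' Runs the forward filter at each candidate diffusivity and returns the
#' maximizer of the data log-likelihood together with the profile.
#'
#' @inheritParams forward_filter
#' @param D_candidates numeric vector of diffusivities, km^2/day.
#' @return list: `D_hat`, `profile` data.frame (`D`, `log_lik`).
#' @export
fit_diffusion <- function(dep, records, env, op = observation_params(),
                          D_candidates) {
  stopifnot(length(D_candidates) >= 1)
  grid <- env$grid
  # likelihood fields are independent of D: build once, filter per candidate
  liks <- build_likelihoods(dep, records, env, op)
  nd <- length(liks)
  liks[[nd]] <- liks[[nd]] * delta_field(grid, dep$popup_lon, dep$popup_lat)$m
  init <- delta_field(grid, dep$release_lon, dep$release_lat, dep$release_date)
  ll <- vapply(D_candidates, function(D) {
    grid_filter(init, liks, movement_params(D = D))$log_lik
  }, numeric(1))
  if (all(!is.finite(ll))) stop("non-finite likelihood for every candidate D")
  list(D_hat = D_candidates[which.max(ll)],
       profile = data.frame(D = D_candidates, log_lik = ll))
}
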