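# Independent oracles and small fixture builders, used by unit and
# acceptance tests. These deliberately re-derive results by different
# algorithms than the package's own code paths.

# ---- solar oracle: Spencer (1971) Fourier-series sunrise solver ------------
# Declination and equation of time from the fractional-year Fourier series;
# event time from solar noon +/- hour angle. Algorithmically independent of
# the package's mean-elements ephemeris + GMST/right-ascension iteration.

oracle_sun <- function(doy, hour_ut) {
  g <- 2 * pi / 365 * (doy - 1 + (hour_ut - 12) / 24)
  oracle_sun_gamma(g)
}

oracle_sun_gamma <- function(g) {
  dec <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  list(dec_rad = dec, eot_min = eot)
}

oracle_event_times <- function(lon, lat, date, h0 = -0.833) {
  # seasonal phase referenced to J2000 Jan 1 with the mean tropical-ish year,
  # so the 365-day day-of-year convention does not drift across leap years
  n0 <- as.numeric(as.Date(date) - as.Date("2000-01-01"))
  phi <- lat * pi / 180
  res <- list(sunrise = NA_real_, sunset = NA_real_, status = "normal")
  for (ev in c("sunrise", "sunset")) {
    t <- 720 - 4 * lon  # provisional: solar noon
    for (k in 1:3) {
      s <- oracle_sun_gamma(2 * pi * (((n0 + t / 1440) %% 365.2425) / 365.2425))
      cosw <- (sin(h0 * pi / 180) - sin(phi) * sin(s$dec_rad)) /
        (cos(phi) * cos(s$dec_rad))
      if (cosw > 1) { res$status <- "polar_night"; break }
      if (cosw < -1) { res$status <- "polar_day"; break }
      w <- acos(cosw) * 180 / pi
      noon <- 720 - 4 * lon - s$eot_min
      t <- noon + if (ev == "sunrise") -4 * w else 4 * w
    }
    if (res$status != "normal") break
    res[[ev]] <- t %% 1440
  }
  res
}

# ---- dense-matrix HMM oracle ------------------------------------------------
# Transition matrix columns are the prediction step applied to basis vectors;
# forward/backward/smoothing marginals computed by explicit matrix algebra.

dense_kernel <- function(grid, mp) {
  N <- grid$ny * grid$nx
  K <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- matrix(0, grid$ny, grid$nx)
    e[j] <- 1
    K[, j] <- as.vector(gridtag:::propagate_mass(e, grid, mp))
  }
  K
}

# alphas: filtered masses (normalized); betas: standard backward variables;
# gamma: smoothing marginals. liks: list of matrices; init: matrix.
dense_forward_backward <- function(K, init, liks) {
  N <- length(init)
  nd <- length(liks)
  a <- vector("list", nd)
  pred <- vector("list", nd)
  logZ <- numeric(nd)
  v <- as.vector(init)
  for (t in seq_len(nd)) {
    if (t > 1) v <- K %*% v
    pred[[t]] <- as.vector(v)
    v <- as.vector(v) * as.vector(liks[[t]])
    logZ[t] <- log(sum(v))
    v <- v / sum(v)
    a[[t]] <- v
  }
  b <- vector("list", nd)
  b[[nd]] <- rep(1, N)
  for (t in rev(seq_len(nd - 1))) {
    b[[t]] <- as.vector(t(K) %*% (as.vector(liks[[t + 1]]) * b[[t + 1]]))
    b[[t]] <- b[[t]] / sum(b[[t]])
  }
  g <- lapply(seq_len(nd), function(t) {
    x <- a[[t]] * b[[t]]
    x / sum(x)
  })
  list(filtered = a, predicted = pred, smoothed = g, log_lik = sum(logZ))
}

# ---- brute-force reachability (independent of the chamfer transform) -------
# Plain BFS ring expansion: cells reachable in <= n_steps 8-neighbour moves
# through water. Used against speed/land-only feasibility on small grids.

bfs_reachable <- function(water, seed, n_steps) {
  cur <- seed & water
  for (s in seq_len(n_steps)) {
    ny <- nrow(cur); nx <- ncol(cur)
    nxt <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(FALSE, ny, nx)
      rs <- max(1, 1 + dr):min(ny, ny + dr)
      cs <- max(1, 1 + dc):min(nx, nx + dc)
      sh[rs, cs] <- cur[rs - dr, cs - dc]
      nxt <- nxt | sh
    }
    cur <- nxt & water
  }
  cur
}

# ---- small fixture worlds ---------------------------------------------------

# Fast small environment for unit tests (33 x 30 cells, one year of SST).
test_env <- function(seed = 7, resolution_km = 40) {
  make_environment(bbox = c(-70, -58, 26, 38), resolution_km = resolution_km,
                   seed = seed)
}

# A closed rectangular basin with a land frame is overkill; domain edges are
# already zero-flux. Simple open-water grid helper:
open_grid <- function(nx = 30, ny = 30, res = 30, lat0 = -4) {
  dlat <- res / 111.32 * ny
  dlon <- res / (111.32 * cos((lat0 + dlat / 2) * pi / 180)) * nx
  build_grid(c(0, dlon, lat0, lat0 + dlat), resolution_km = res)
}

random_lik <- function(grid, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(grid$ny * grid$nx, 0.05, 1), grid$ny, grid$nx)
  m[!grid$water] <- 0
  m
}
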