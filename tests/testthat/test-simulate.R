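test_that("environment is reproducible, bounded, and has coast + shelf", {
  e1 <- make_environment(seed = 3, resolution_km = 50)
  e2 <- make_environment(seed = 3, resolution_km = 50)
  expect_identical(e1$sst, e2$sst)
  expect_identical(e1$grid$water, e2$grid$water)
  w <- e1$grid$water
  expect_gt(mean(w), 0); expect_lt(mean(w), 1)
  expect_gte(min(e1$sst[rep(w, dim(e1$sst)[3])]), 3)
  expect_lte(max(e1$sst), 32)
  # bathymetry deepens away from the western coast
  row <- which(rowSums(!w) > 0)[5]
  wet <- which(w[row, ])
  expect_gt(e1$grid$bathy[row, max(wet)], e1$grid$bathy[row, min(wet)])
})

test_that("track: stationary at D=0, stays in water, reproducible", {
  env <- test_env()
  cfg0 <- sim_config(D = 0, n_days = 10, seed = 2, start = c(-64, 30))
  tr <- simulate_track(env, cfg0)
  expect_equal(length(unique(tr$lon)), 1L)
  expect_equal(length(unique(tr$lat)), 1L)

  cfg <- sim_config(D = 400, n_days = 60, seed = 2)
  t1 <- simulate_track(env, cfg)
  t2 <- simulate_track(env, cfg)
  expect_identical(t1, t2)
  expect_true(all(env$grid$water[cbind(t1$row, t1$col)]))
  expect_error(simulate_track(env, sim_config(start = c(-69.9, 38), seed = 1)),
               "land")
})

test_that("mean squared displacement follows the diffusion law", {
  # large open-water world so reflections don't bias the MSD
  env <- list(grid = open_grid(60, 60, res = 50),
              dates = seq(as.Date("2008-01-01"), by = "day", length.out = 30),
              sst = array(20, c(60, 60, 30)))
  class(env) <- "tag_env"
  D <- 300; t_days <- 9
  n <- 350
  msd <- numeric(n)
  mid <- c(mean(env$grid$lon), mean(env$grid$lat))
  for (i in seq_len(n)) {
    cfg <- sim_config(D = D, n_days = t_days + 1, seed = 5000 + i, start = mid)
    tr <- simulate_track(env, cfg)
    dx <- (tr$lon[t_days + 1] - tr$lon[1]) * 111.32 * cos(mid[2] * pi / 180)
    dy <- (tr$lat[t_days + 1] - tr$lat[1]) * 111.32
    msd[i] <- dx^2 + dy^2
  }
  expect_lt(abs(mean(msd) / (4 * D * t_days) - 1), 0.10)
})

test_that("simulated and filtered dynamics share one kernel (step distribution)", {
  g <- open_grid(41, 15, res = 100, lat0 = -7)
  env <- list(grid = g,
              dates = seq(as.Date("2008-01-01"), by = "day", length.out = 10),
              sst = array(20, c(15, 41, 10)))
  class(env) <- "tag_env"
  mp <- movement_params(D = 300)
  # exact one-day kernel column marginal at the domain centre
  e <- matrix(0, g$ny, g$nx); e[8, 21] <- 1
  kern <- gridtag:::propagate_mass(e, g, mp)
  px <- colSums(kern)      # x-displacement marginal
  # empirical steps from a long simulated track, restricted to the interior
  cfg <- sim_config(D = 300, n_days = 1500, seed = 77,
                    start = c(mean(g$lon), mean(g$lat)))
  tr <- simulate_track(env, cfg)
  interior <- tr$row > 3 & tr$row < 13 & tr$col > 4 & tr$col < 38
  ok <- which(interior[-nrow(tr)] & interior[-1])
  steps <- tr$col[ok + 1] - tr$col[ok]
  # kernel column c corresponds to displacement c - 21; pad to 43 bins
  emp_cdf <- cumsum(tabulate(steps + 22, nbins = 43)) / length(steps)
  th_cdf <- cumsum(c(0, px, 0))
  ks <- max(abs(emp_cdf - th_cdf))
  expect_lt(ks, 0.05)
})

test_that("tag records: sparsity, noiseless limit, depth below bathymetry", {
  env <- test_env()
  cfg <- sim_config(n_days = 400, seed = 21)
  # sparsity over many days (pooled over 5 tags)
  n_ev <- n_sst <- n_tot <- 0
  for (i in 1:5) {
    cfg_i <- sim_config(n_days = 300, seed = 21 + i)
    tr <- simulate_track(env, cfg_i, start_date = as.Date("2008-02-01"))
    sim <- simulate_tag_records(tr, env, cfg_i)
    n_ev <- n_ev + sum(!is.na(sim$records$sunrise_ut) | !is.na(sim$records$sunset_ut))
    n_sst <- n_sst + sum(!is.na(sim$records$sst))
    n_tot <- n_tot + nrow(sim$records)
    expect_true(all(sim$records$max_depth <=
                      env$grid$bathy[cbind(tr$row, tr$col)]))
  }
  expect_lt(abs(n_ev / n_tot - 0.07), 0.02)
  expect_lt(abs(n_sst / n_tot - 0.41), 0.04)

  # noiseless, dense limit reproduces the solar predictions exactly
  cfg2 <- sim_config(n_days = 15, seed = 8, p_event_day = 1,
                     sigma_event = 1e-9, start = c(-64, 30))
  tr2 <- simulate_track(env, cfg2)
  sim2 <- simulate_tag_records(tr2, env, cfg2)
  for (t in which(!is.na(sim2$records$sunrise_ut))) {
    p <- predict_event_times(tr2$lon[t], tr2$lat[t], tr2$date[t])
    expect_equal(sim2$records$sunrise_ut[t], p$sunrise_ut, tolerance = 1e-5)
    expect_equal(sim2$records$sunset_ut[t], p$sunset_ut, tolerance = 1e-5)
  }

  # deployment endpoints come from the track
  expect_equal(sim2$dep$release_lon, tr2$lon[1])
  expect_equal(sim2$dep$popup_lat, tr2$lat[15])
})

test_that("drifted track reaches the target region", {
  env <- test_env()
  cfg <- sim_config(D = 150, n_days = 60, seed = 13,
                    start = c(-65, 28), end = c(-61, 35))
  tr <- simulate_track(env, cfg)
  d_km <- sqrt((((tr$lon[60] - -61) * 111.32 * cos(35 * pi / 180))^2 +
                  ((tr$lat[60] - 35) * 111.32)^2))
  expect_lt(d_km, 500)  # within diffusive scatter of the target
})

test_that("records round-trip through the sensor-series preprocessing", {
  env <- test_env()
  cfg <- sim_config(n_days = 30, seed = 17)
  tr <- simulate_track(env, cfg)
  sim <- simulate_tag_records(tr, env, cfg)
  series <- records_to_series(sim$records, tag_id = sim$dep$tag_id)
  rec2 <- build_daily_records(sim$dep, series)
  has_sst <- !is.na(sim$records$sst)
  expect_equal(rec2$sst[has_sst], sim$records$sst[has_sst])
  expect_equal(rec2$max_depth[sim$records$max_depth > 15],
               sim$records$max_depth[sim$records$max_depth > 15])
})
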