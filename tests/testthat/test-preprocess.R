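mk_series <- function(date, depths, temps) {
  data.frame(tag_id = "t1",
             timestamp = as.POSIXct(paste(date, "06:00"), tz = "UTC") +
               seq_along(depths) * 600,
             depth_m = depths, temp_c = temps)
}

test_that("daily SST estimate is the 0-15 m median, absent otherwise", {
  s <- mk_series("2008-05-01", c(5, 10, 120), c(20, 22, 8))
  expect_equal(daily_sst_estimate(s, "2008-05-01"), 21)
  deep <- mk_series("2008-05-01", c(40, 120), c(15, 8))
  expect_true(is.na(daily_sst_estimate(deep, "2008-05-01")))
  one <- mk_series("2008-05-01", 2, 18.3)
  expect_equal(daily_sst_estimate(one, "2008-05-01"), 18.3)
  # other days' samples don't leak in
  expect_true(is.na(daily_sst_estimate(s, "2008-05-02")))
})

test_that("daily max depth: max, empty day, negative samples rejected", {
  s <- mk_series("2008-05-01", c(5, 120, 300), c(20, 10, 6))
  expect_equal(daily_max_depth(s, "2008-05-01"), 300)
  expect_equal(daily_max_depth(s, "2008-05-02"), 0)
  bad <- mk_series("2008-05-01", c(-3, 50), c(20, 12))
  expect_warning(d <- daily_max_depth(bad, "2008-05-01"), "negative")
  expect_equal(d, 50)
})

test_that("daily records assemble per-day summaries and merge event times", {
  dep <- deployment("t1", "2008-05-01", -65, 30, "2008-05-04", -64, 31)
  s <- rbind(mk_series("2008-05-01", c(4, 9, 200), c(21, 21.4, 9)),
             mk_series("2008-05-03", c(500), c(5)))
  ev <- data.frame(date = as.Date("2008-05-02"), sunrise_ut = 610,
                   sunset_ut = 1390)
  rec <- build_daily_records(dep, s, ev)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$sst[1], 21.2)
  expect_equal(rec$max_depth, c(200, 0, 500, 0))
  expect_equal(rec$sunrise_ut, c(NA, 610, NA, NA))
  expect_equal(rec$n_samples, c(3L, 0L, 1L, 0L))
})

test_that("feasible sets start at the release cell and grow within the speed bound", {
  env <- test_env()
  grid <- env$grid
  dep <- deployment("t1", "2008-06-01", -64, 30, "2008-06-10", -63, 31)
  rec <- build_daily_records(dep)
  fs <- propagate_feasible_sets(dep, rec, env, vmax = 120)
  rc <- cell_at(grid, -64, 30)
  expect_equal(which(fs$masks[[1]]),
               (rc$col - 1) * grid$ny + rc$row)
  # dilation bound: day t+1 never farther than vmax from release
  for (t in c(3, 6)) {
    idx <- which(fs$masks[[t]], arr.ind = TRUE)
    dx <- (grid$lon[idx[, 2]] - (-64)) * 111.32 * cos(30 * pi / 180)
    dy <- (grid$lat[idx[, 1]] - 30) * 111.32
    expect_true(all(sqrt(dx^2 + dy^2) <= 120 * (t - 1) + 2 * grid$resolution_km))
  }
  expect_true(all(!fs$masks[[5]][!grid$water]))
})

test_that("feasible sets are monotone in vmax and match brute-force reachability", {
  env <- test_env()
  dep <- deployment("t1", "2008-06-01", -64, 30, "2008-06-08", -62, 32)
  rec <- build_daily_records(dep)
  f_slow <- propagate_feasible_sets(dep, rec, env, vmax = 80)
  f_fast <- propagate_feasible_sets(dep, rec, env, vmax = 160)
  for (t in seq_along(f_slow$masks))
    expect_true(all(which(f_slow$masks[[t]]) %in% which(f_fast$masks[[t]])))

  # speed+land only: final set subset of BFS reach from both endpoints
  grid <- env$grid
  rel <- delta_field(grid, -64, 30)$m > 0
  pop <- delta_field(grid, -62, 32)$m > 0
  vmax <- 160
  min_step <- min(grid$dx_km, grid$dy_km)
  for (t in c(2, 5, 8)) {
    reach <- bfs_reachable(grid$water, rel, floor(vmax * (t - 1) / min_step)) &
      bfs_reachable(grid$water, pop, floor(vmax * (8 - t) / min_step))
    expect_true(all(which(f_fast$masks[[t]]) %in% which(reach)))
  }
})

test_that("SST gradient confines the feasible set to the matching band", {
  env <- test_env()
  grid <- env$grid
  dep <- deployment("t1", "2008-06-01", -64, 30, "2008-06-07", -64, 30)
  rec <- build_daily_records(dep)
  day <- 4
  obs_sst <- env_sst(env, rec$date[day])[cell_at(grid, -64, 33)$row,
                                         cell_at(grid, -64, 33)$col]
  rec$sst[day] <- obs_sst
  fs <- propagate_feasible_sets(dep, rec, env, vmax = 200, k_sst = 3, sigma_sst = 1)
  # brute-force: every cell of the day's set satisfies the SST gate
  ref <- env_sst(env, rec$date[day])
  expect_true(all(abs(ref[fs$masks[[day]]] - obs_sst) <= 3))
  expect_false(fs$relaxed[day])
})

test_that("screening keeps consistent events, rejects gross outliers", {
  env <- test_env()
  grid <- env$grid
  dep <- deployment("t1", "2008-06-01", -64, 30, "2008-06-06", -64, 30)
  rec <- build_daily_records(dep)
  fs <- propagate_feasible_sets(dep, rec, env)
  truth <- predict_event_times(-64, 30.4, "2008-06-03")
  rec$sunrise_ut[3] <- truth$sunrise_ut       # noiseless, inside the set
  rec$sunset_ut[3] <- (truth$sunset_ut + 300) %% 1440  # 5 h off
  sc <- screen_event_times(rec, fs, grid)
  expect_equal(sc$records$sunrise_ut[3], truth$sunrise_ut)
  expect_true(is.na(sc$records$sunset_ut[3]))
  rep3 <- sc$report[sc$report$event == "sunset", ]
  expect_false(rep3$kept)
  expect_gt(rep3$dist_min, 60)
})

test_that("screening never discards a noiseless event from inside the feasible set", {
  env <- test_env()
  grid <- env$grid
  dep <- deployment("t1", "2008-04-10", -64, 30, "2008-04-20", -62, 33)
  rec <- build_daily_records(dep)
  fs <- propagate_feasible_sets(dep, rec, env)
  set.seed(11)
  for (t in 2:10) {
    idx <- which(fs$masks[[t]], arr.ind = TRUE)
    k <- idx[sample(nrow(idx), 1), ]
    p <- predict_event_times(grid$lon[k[2]], grid$lat[k[1]], rec$date[t])
    rec$sunrise_ut[t] <- p$sunrise_ut
    rec$sunset_ut[t] <- p$sunset_ut
  }
  sc <- screen_event_times(rec, fs, grid)
  expect_true(all(sc$report$kept))
})
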