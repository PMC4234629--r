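test_that("observation likelihood: uniform when empty, Gaussian SST ridge, depth gate", {
  env <- test_env()
  grid <- env$grid
  op <- observation_params()
  empty <- list(date = as.Date("2008-06-01"), sst = NA, sunrise_ut = NA,
                sunset_ut = NA, max_depth = NA)
  L <- observation_likelihood_field(empty, env, op)
  expect_true(all(L[grid$water] == 1))
  expect_true(all(L[!grid$water] == 0))

  sst_rec <- list(date = as.Date("2008-06-01"), sst = 24, sunrise_ut = NA,
                  sunset_ut = NA, max_depth = NA)
  L2 <- observation_likelihood_field(sst_rec, env, op)
  ref <- env_sst(env, "2008-06-01")
  expected <- exp(dnorm(24, ref, 1, log = TRUE) - max(dnorm(24, ref, 1, log = TRUE)[grid$water]))
  expect_equal(L2[grid$water], expected[grid$water], tolerance = 1e-12)

  deep <- list(date = as.Date("2008-06-01"), sst = NA, sunrise_ut = NA,
               sunset_ut = NA, max_depth = 500)
  L3 <- observation_likelihood_field(deep, env, op)
  expect_true(all(L3[grid$bathy < 500] == 0))
  expect_true(all(L3[grid$water & grid$bathy >= 500] == 1))
})

test_that("filter with no observations is pure prediction from the release delta", {
  env <- test_env()
  grid <- env$grid
  mp <- movement_params(D = 300)
  init <- delta_field(grid, -64, 30)
  ones <- matrix(1, grid$ny, grid$nx); ones[!grid$water] <- 0
  liks <- rep(list(ones), 6)
  fr <- grid_filter(init, liks, mp)
  m <- init$m
  for (t in 2:6) {
    m <- gridtag:::propagate_mass(m, grid, mp)
    expect_lt(max(abs(fr$post[[t]] - m / sum(m))), 1e-12)
  }
})

test_that("filters and smoother match the dense-matrix HMM oracle", {
  # small irregular world with a land blob; endpoints within the discrete
  # kernel's reach (one cell per substep)
  land <- function(lon, lat) lon > 1.2 & lon < 2 & lat > 1 & lat < 2.4
  g <- build_grid(c(0, 4, 0, 3), resolution_km = 40, land = land)
  expect_lte(g$ny * g$nx, 144)
  mp <- movement_params(D = 600)
  K <- dense_kernel(g, mp)
  nd <- 8
  liks <- lapply(1:nd, function(t) random_lik(g, seed = 100 + t))
  init <- delta_field(g, 0.3, 0.4)
  # scripted endpoint: delta folded into last likelihood, as the wrappers do
  popup <- delta_field(g, 2.8, 1.6)
  liks[[nd]] <- liks[[nd]] * popup$m

  fwd <- grid_filter(init, liks, mp)
  oracle <- dense_forward_backward(K, init$m, liks)
  for (t in 1:nd)
    expect_lt(max(abs(as.vector(fwd$post[[t]]) - oracle$filtered[[t]])), 1e-10)
  expect_equal(fwd$log_lik, oracle$log_lik, tolerance = 1e-10)

  # backward filter matches the dense adjoint recursion
  liks_b <- rev(liks)
  bwd <- grid_filter(popup, liks_b, mp, adjoint = TRUE)
  vb <- as.vector(popup$m)
  for (s in 1:nd) {
    if (s > 1) vb <- as.vector(t(K) %*% vb)
    got <- as.vector(bwd$pred[[s]])
    expect_lt(max(abs(got / sum(got) - vb / sum(vb))), 1e-10)
    vb <- vb * as.vector(liks_b[[s]])
    vb <- vb / sum(vb)
  }

  sm <- two_filter_smooth(fwd, bwd)
  for (t in 1:nd)
    expect_lt(max(abs(as.vector(sm$fields[[t]]) - oracle$smoothed[[t]])), 1e-8)
})

test_that("total forward and backward log-likelihood agree", {
  env <- test_env()
  cfg <- sim_config(n_days = 25, seed = 3)
  track <- simulate_track(env, cfg)
  sim <- simulate_tag_records(track, env, cfg)
  mp <- movement_params(D = 300)
  fwd <- forward_filter(sim$dep, sim$records, env, mp)
  bwd <- backward_filter(sim$dep, sim$records, env, mp)
  expect_lt(abs(fwd$log_lik - bwd$log_lik), 1e-6)
})

test_that("a near-exact observation concentrates the posterior", {
  env <- test_env()
  grid <- env$grid
  # likelihood strongly peaked at the true cell
  true_rc <- c(15, 12)
  lik <- matrix(1e-12, grid$ny, grid$nx)
  lik[true_rc[1], true_rc[2]] <- 1
  lik[!grid$water] <- 0
  init <- delta_field(grid, grid$lon[12], grid$lat[15])
  ones <- matrix(1, grid$ny, grid$nx) * grid$water
  fr <- grid_filter(init, list(ones, ones, lik), movement_params(D = 300))
  expect_gt(fr$post[[3]][true_rc[1], true_rc[2]], 0.99)
})

test_that("smoothed endpoints anchor at release and pop-up; bridge is symmetric", {
  env <- test_env()
  cfg <- sim_config(n_days = 20, seed = 5)
  track <- simulate_track(env, cfg)
  sim <- simulate_tag_records(track, env, cfg)
  mp <- movement_params(D = 300)
  fwd <- forward_filter(sim$dep, sim$records, env, mp)
  bwd <- backward_filter(sim$dep, sim$records, env, mp)
  sm <- two_filter_smooth(fwd, bwd)
  grid <- env$grid
  rc0 <- cell_at(grid, sim$dep$release_lon, sim$dep$release_lat)
  rcT <- cell_at(grid, sim$dep$popup_lon, sim$dep$popup_lat)
  expect_gt(sm$fields[[1]][rc0$row, rc0$col], 0.999)
  expect_gt(sm$fields[[20]][rcT$row, rcT$col], 0.999)

  # no observations, coincident endpoints: time symmetry of the bridge
  dep <- deployment("b1", "2008-06-01", -64, 30, "2008-06-11", -64, 30)
  rec <- build_daily_records(dep)
  f2 <- forward_filter(dep, rec, env, mp)
  b2 <- backward_filter(dep, rec, env, mp)
  s2 <- two_filter_smooth(f2, b2)
  nd <- 11
  for (t in 1:nd)
    expect_lt(max(abs(s2$fields[[t]] - s2$fields[[nd - t + 1]])), 1e-9)
})

test_that("fit_diffusion returns the single candidate and a finite profile", {
  env <- test_env()
  cfg <- sim_config(n_days = 20, seed = 9)
  track <- simulate_track(env, cfg)
  sim <- simulate_tag_records(track, env, cfg)
  one <- fit_diffusion(sim$dep, sim$records, env, D_candidates = 300)
  expect_equal(one$D_hat, 300)
  prof <- fit_diffusion(sim$dep, sim$records, env,
                        D_candidates = c(100, 300, 900))
  expect_true(all(is.finite(prof$profile$log_lik)))
  expect_true(prof$D_hat %in% c(100, 300, 900))
})

test_that("zero-likelihood days relax the gate instead of failing", {
  env <- test_env()
  grid <- env$grid
  dep <- deployment("t1", "2008-06-01", -64, 30, "2008-06-05", -64, 30)
  rec <- build_daily_records(dep)
  rec$max_depth[3] <- 10000  # deeper than any bathymetry: gates out every cell
  fwd <- forward_filter(dep, rec, env, movement_params(D = 300))
  expect_true(fwd$relaxed[3])
  expect_true(is.finite(fwd$log_lik))
})
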