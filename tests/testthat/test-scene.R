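test_that("scene configuration rejects degenerate settings", {
  expect_error(scene_config(n_rows = 4, n_cols = 4), "degenerate")
  expect_error(scene_config(gap_fraction = 1), "gap_fraction")
  expect_error(scene_config(gap_fraction = -0.1), "gap_fraction")
  expect_error(scene_config(noise_sd = -1), "noise_sd")
  expect_error(scene_config(target_r2 = 1.2), "target_r2")
})

test_that("identical config and seed give bit-identical scenes", {
  cf <- scene_config(n_rows = 16, n_cols = 16, n_hours = 2,
                     n_reference_sites = 3, n_lowcost_sites = 8, seed = 42)
  a <- simulate_scene(cf)
  b <- simulate_scene(cf)
  expect_identical(a$truth$true_pm25, b$truth$true_pm25)
  expect_identical(a$truth$met, b$truth$met)
  expect_identical(a$satellite_aod, b$satellite_aod)
  expect_identical(a$observations, b$observations)
})

test_that("theoretical R2 follows the variance-ratio identity", {
  cf0 <- scene_config(n_rows = 16, n_cols = 16, n_hours = 2,
                      n_reference_sites = 3, n_lowcost_sites = 8,
                      noise_sd = 0, seed = 5)
  t0 <- simulate_fields(cf0)
  expect_equal(t0$theoretical_r2, 1) # zero-noise limit
  # choose noise so Var(signal) = 4 * noise_sd^2 -> R2 = 0.8 exactly
  nsd <- sqrt(t0$signal_var / 4)
  t1 <- simulate_fields(scene_config(n_rows = 16, n_cols = 16, n_hours = 2,
                                     n_reference_sites = 3,
                                     n_lowcost_sites = 8,
                                     noise_sd = nsd, seed = 5))
  expect_equal(t1$theoretical_r2, 0.8, tolerance = 1e-12)
  # target_r2 calibration realizes the requested ratio
  t2 <- simulate_fields(scene_config(n_rows = 16, n_cols = 16, n_hours = 2,
                                     n_reference_sites = 3,
                                     n_lowcost_sites = 8,
                                     target_r2 = 0.85, seed = 5))
  expect_equal(t2$theoretical_r2, 0.85, tolerance = 1e-12)
  # the noise-free signal is identical across noise settings (same seed)
  expect_identical(t0$signal, t1$signal)
})

test_that("scene truth carries the ten meteorological fields on one grid", {
  tr <- simulate_fields(scene_config(n_rows = 12, n_cols = 12, n_hours = 1,
                                     n_reference_sites = 2,
                                     n_lowcost_sites = 4, seed = 1))
  expect_setequal(names(tr$met),
                  c("temp_2m", "u_wind", "v_wind", "pblh", "sw_down", "sw_up",
                    "lw_flux", "sp_hum", "sfc_pres", "rel_hum"))
  for (v in names(tr$met))
    expect_true(identical(unclass(tr$met[[v]][[1]]$grid), unclass(tr$grid)))
  expect_false(anyNA(tr$true_aod[[1]]$values))
})

test_that("cloud masking hits the requested fraction and keeps values bitwise", {
  g <- grid_spec(0, 0, 1, 100, 100)
  set.seed(6)
  f <- field(g, rnorm(1e4, 0.5, 0.1))
  expect_identical(apply_cloud_mask(f, 0, seed = 1), f)
  m <- apply_cloud_mask(f, 0.3, blob_scale = 8, seed = 9)
  frac <- mean(is.na(m$values))
  expect_gte(frac, 0.25); expect_lte(frac, 0.35)
  keep <- !is.na(m$values)
  expect_identical(m$values[keep], f$values[keep])
  expect_error(apply_cloud_mask(f, 1.0, seed = 1), "gap_fraction")
})

test_that("background AOD correlates with the truth but differs cellwise", {
  tr <- simulate_fields(scene_config(n_rows = 48, n_cols = 48, n_hours = 2,
                                     n_reference_sites = 4,
                                     n_lowcost_sites = 12, seed = 3))
  for (t in 1:2) {
    a <- as.vector(tr$true_aod[[t]]$values)
    b <- as.vector(tr$background_aod[[t]]$values)
    expect_gt(cor(a, b), 0.5)
    expect_gt(mean(a != b), 0.99) # not a copy
  }
})

test_that("observations report the truth at their cells with tagged sources", {
  cf <- scene_config(n_rows = 20, n_cols = 20, n_hours = 3,
                     n_reference_sites = 5, n_lowcost_sites = 15,
                     sensor_bias_sd = 0, obs_noise_sd = 0, seed = 11)
  tr <- simulate_fields(cf)
  sites <- sample_sites(tr$grid, 5, 15, seed = 2)
  obs <- sample_observations(tr, sites, 0, 0, seed = 3)
  expect_equal(nrow(obs), 20 * 3) # site x hour bookkeeping
  expect_setequal(unique(obs$source), c("REF", "LC"))
  # with zero bias and noise every record equals true pm25 at its cell
  for (i in seq_len(nrow(obs))) {
    rc <- nearest_cell(tr$grid, c(obs$x[i], obs$y[i]))
    expect_equal(obs$pm25[i],
                 tr$true_pm25[[obs$hour[i] + 1]]$values[rc[1] + 1, rc[2] + 1])
  }
  # sites outside the grid are rejected by id
  bad <- sites; bad$x[2] <- 1e4; bad$site_id[2] <- "WAYOUT"
  expect_error(sample_observations(tr, bad, 0, 0, 1), "WAYOUT")
})

test_that("low-cost site biases realize the configured spread", {
  cf <- scene_config(n_rows = 16, n_cols = 16, n_hours = 1,
                     n_reference_sites = 2, n_lowcost_sites = 150,
                     noise_sd = 0, seed = 8)
  tr <- simulate_fields(cf)
  sites <- sample_sites(tr$grid, 2, 150, seed = 4)
  obs <- sample_observations(tr, sites, sensor_bias_sd = 3, obs_noise_sd = 0,
                             seed = 5)
  lc <- obs[obs$source == "LC", ]
  truth <- vapply(seq_len(nrow(lc)), function(i) {
    rc <- nearest_cell(tr$grid, c(lc$x[i], lc$y[i]))
    tr$true_pm25[[1]]$values[rc[1] + 1, rc[2] + 1]
  }, 1)
  bias <- lc$pm25 - truth
  expect_equal(sd(bias), 3, tolerance = 0.5) # Monte-Carlo at n = 150
})
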