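test_that("stand generation is seeded, Poisson-sized and slope-aware", {
  cfg <- scene_config(seed = 5L)
  s1 <- generate_stand(cfg)
  s2 <- generate_stand(cfg)
  expect_identical(s1$trees, s2$trees)
  expect_identical(s1$shrubs, s2$shrubs)

  # expected count = density x area; average over seeds within Poisson noise
  area_ha <- 150 * 70 / 1e4
  counts <- vapply(1:10, function(s) {
    nrow(generate_stand(scene_config(seed = s))$trees)
  }, numeric(1))
  expected <- 730 * area_ha
  se <- sqrt(expected / 10)
  expect_lt(abs(mean(counts) - expected), 4 * se)

  flat <- generate_stand(scene_config(terrain_slope = 0, seed = 2L))
  expect_true(all(flat$trees$z_ground == 0))
  sloped <- generate_stand(scene_config(terrain_slope = 3, seed = 2L))
  expect_equal(sloped$ground_z(100, 0), 100 * tan(3 * pi / 180))

  expect_error(scene_config(extent = c(0, 70), seed = 1L))
  expect_error(scene_config(extent = c(50, 50)), "seed")
})

test_that("surface sampling scales with density and stays inside the plot", {
  cfg <- scene_config(extent = c(30, 30), seed = 31L)
  stand <- generate_stand(cfg)
  # single crown, no other elements: isolate by zeroing class densities
  one_tree <- stand
  one_tree$trees <- stand$trees[1L, , drop = FALSE]
  one_tree$shrubs <- stand$shrubs[0L, , drop = FALSE]
  n1 <- vapply(1:8, function(s) {
    npoints(sample_surface_points(one_tree,
                                  c(terrain = 0, stem = 0, crown = 1, shrub = 0),
                                  seed = s))
  }, numeric(1))
  n2 <- vapply(1:8, function(s) {
    npoints(sample_surface_points(one_tree,
                                  c(terrain = 0, stem = 0, crown = 2, shrub = 0),
                                  seed = 100 + s))
  }, numeric(1))
  ratio <- mean(n2) / mean(n1)
  expect_lt(abs(ratio - 2), 0.25)

  expect_equal(npoints(sample_surface_points(stand, 0, seed = 1)), 0L)

  cloud <- sample_surface_points(stand, seed = 2L)
  expect_true(all(cloud$xyz[, 1] >= 0 & cloud$xyz[, 1] < 30))
  expect_true(all(cloud$xyz[, 2] >= 0 & cloud$xyz[, 2] < 30))
  zmax <- max(stand$trees$height) + max(stand$trees$z_ground) + 1
  expect_true(all(cloud$xyz[, 3] <= zmax))
  expect_setequal(unique(cloud$source_id),
                  c("terrain", "stem", "crown", "shrub"))

  c1 <- sample_surface_points(stand, seed = 7L)
  c2 <- sample_surface_points(stand, seed = 7L)
  expect_identical(c1$xyz, c2$xyz)
})

test_that("aerial scans keep the highest returns per pulse and occlude deeper ones", {
  # 8 points stacked in one pulse footprint
  stack <- point_cloud(cbind(rep(0.2, 8), rep(0.2, 8), 8:1))
  cfg <- scan_config("aerial", max_returns = 5L, noise_sd = 0, seed = 1L)
  got <- simulate_aerial_scan(stack, cfg)
  expect_equal(npoints(got), 5L)
  expect_setequal(got$xyz[, 3], 8:4)  # the 5 highest

  all_kept <- simulate_aerial_scan(stack,
                                   scan_config("aerial", max_returns = 32L,
                                               noise_sd = 0, seed = 1L))
  expect_equal(npoints(all_kept), 8L)
})

test_that("raising the return limit never loses returns anywhere", {
  sc <- get_small_scene()
  k5 <- simulate_aerial_scan(sc$truth, scan_config("aerial", max_returns = 5L,
                                                   noise_sd = 0, seed = 3L))
  k32 <- simulate_aerial_scan(sc$truth, scan_config("aerial", max_returns = 32L,
                                                    noise_sd = 0, seed = 3L))
  d5 <- planar_density_map(k5, 0.5, origin = c(0, 0), dims = c(120L, 80L))
  d32 <- planar_density_map(k32, 0.5, origin = c(0, 0), dims = c(120L, 80L))
  expect_true(all(d32$counts >= d5$counts))
  expect_gt(npoints(k32), npoints(k5))
})

test_that("ground scans retain near-trajectory clear points and occlude the canopy", {
  # a clear point sitting on the trajectory with nothing below is always kept
  lone <- point_cloud(cbind(c(5, 5), c(5, 5), c(0.5, 30)))
  traj <- rbind(c(0, 5), c(10, 5))
  cfg <- scan_config("ground", trajectory = traj, occlusion_coef = 0,
                     noise_sd = 0, seed = 1L)
  kept <- vapply(1:20, function(s) {
    cfg$seed <- s
    npoints(simulate_ground_scan(point_cloud(cbind(5, 5, 0.5)), cfg))
  }, numeric(1))
  expect_true(all(kept == 1L))

  # halving the range-decay scale loses points on a fixed scene
  sc <- get_small_scene()
  n_long <- npoints(simulate_ground_scan(sc$truth,
                                         scan_config("ground", range_decay = 15,
                                                     seed = 4L)))
  n_short <- npoints(simulate_ground_scan(sc$truth,
                                          scan_config("ground", range_decay = 7.5,
                                                      seed = 4L)))
  expect_lt(n_short, n_long)

  expect_error(simulate_ground_scan(sc$truth,
                                    scan_config("ground",
                                                trajectory = matrix(numeric(0), ncol = 2),
                                                seed = 1L)),
               "trajectory")
})

test_that("ground scans under-sample the upper canopy relative to the lower", {
  sc <- get_small_scene()
  truth <- sc$truth
  ground <- simulate_ground_scan(truth, scan_config("ground", seed = 9L))
  # retention by height stratum over the whole scene
  lower <- truth$xyz[, 3] < 10
  upper <- truth$xyz[, 3] >= 25
  ret_low <- sum(ground$xyz[, 3] < 10) / sum(lower)
  ret_up <- sum(ground$xyz[, 3] >= 25) / sum(upper)
  expect_lt(ret_up, ret_low)
})

test_that("synthetic satellites close the loop exactly at zero noise", {
  sc <- get_small_scene()
  clean <- synthesize_satellite(sc$truth, 0.5, 0.02, 0.01, 10, noise_sd = 0,
                                seed = 3, origin = sc$lattice$origin,
                                dims = sc$lattice$dims)
  sim <- resample_average(column_radiance(clean$grid, rt_params(0.02, 0.01)),
                          10)$values
  expect_equal(pearson_r(sim, clean$observed$values), 1, tolerance = 1e-12)
  expect_equal(clean$observed$values, clean$signal)

  b1 <- synthesize_satellite(sc$truth, 0.5, 0.02, 0.01, 10, noise_sd = 0.02,
                             seed = 3, origin = sc$lattice$origin,
                             dims = sc$lattice$dims)
  b2 <- synthesize_satellite(sc$truth, 0.5, 0.02, 0.01, 10, noise_sd = 0.02,
                             seed = 3, origin = sc$lattice$origin,
                             dims = sc$lattice$dims)
  expect_identical(b1$observed$values, b2$observed$values)
  expect_named(b1$provenance,
               c("voxel_size", "pixel_size", "I", "R", "origin", "dims",
                 "reflect_range"))
})

test_that("platform asymmetry and fusion completeness hold on the standard scene", {
  sc <- get_small_scene()
  g <- scene_grids(sc)
  truth_ref <- occupancy_set(g$truth)
  cgr_aer <- coverage_gap_ratio(truth_ref, occupancy_set(g$aerial))
  cgr_grd <- coverage_gap_ratio(truth_ref, occupancy_set(g$ground))
  cgr_mrg <- coverage_gap_ratio(truth_ref, occupancy_set(g$merged))

  zmax <- max(cgr_aer$bin_hi[!is.na(cgr_aer$cgr)])
  # aerial covers the upper canopy better; ground covers the bottom better
  expect_lt(cgr_band_mean(cgr_aer, zmax - 15, zmax),
            cgr_band_mean(cgr_grd, zmax - 15, zmax))
  expect_lt(cgr_band_mean(cgr_grd, 0, 5), cgr_band_mean(cgr_aer, 0, 5))

  # fusing both platforms approaches the truth occupancy everywhere
  ok <- !is.na(cgr_mrg$cgr)
  expect_true(all(cgr_mrg$cgr[ok] <=
                    pmin(cgr_aer$cgr[ok], cgr_grd$cgr[ok]) + 1e-12))
})
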