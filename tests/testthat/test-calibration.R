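test_that("pearson_r matches the textbook formula and rejects degenerate input", {
  s <- c(1, 2, 3, 4, 5)
  o <- c(2.0, 1.5, 3.5, 3.0, 5.5)
  # hand oracle: direct product-moment formula
  r_hand <- sum((s - mean(s)) * (o - mean(o))) /
    sqrt(sum((s - mean(s))^2) * sum((o - mean(o))^2))
  expect_equal(pearson_r(s, o), r_hand, tolerance = 1e-14)

  expect_equal(pearson_r(s, s), 1)
  expect_equal(pearson_r(s, 3.2 * s + 7), 1)           # affine invariance
  expect_equal(pearson_r(s, -2 * s + 1), -1)

  expect_error(pearson_r(1:2, 2:3), "fewer than 3")
  expect_error(pearson_r(rep(1, 5), o), "zero variance")
  expect_error(pearson_r(s, o, mask = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               "fewer than 3")
  expect_error(pearson_r(s, o[1:4]), "length")
})

test_that("shift_search agrees with an independently coded exhaustive loop", {
  set.seed(91)
  vals <- matrix(runif(40 * 30), 40, 30)
  fine <- radiance_map_for_test(vals, 1)
  obs_vals <- matrix(runif(8 * 6), 8, 6)
  obs <- observed_raster(obs_vals, cell_size = 5)

  got <- shift_search(fine, obs, max_shift = 2, step = 1)

  # independent enumeration: manual index shifting + block means + cor
  best <- list(r = -Inf)
  for (dx in -2:2) for (dy in -2:2) {
    sh <- matrix(NA_real_, 40, 30)
    si <- seq_len(40) - dx; sj <- seq_len(30) - dy
    oki <- si >= 1 & si <= 40; okj <- sj >= 1 & sj <= 30
    sh[oki, okj] <- vals[si[oki], sj[okj]]
    cm <- matrix(NA_real_, 8, 6)
    for (ci in 1:8) for (cj in 1:6) {
      blk <- sh[(5 * ci - 4):(5 * ci), (5 * cj - 4):(5 * cj)]
      if (any(!is.na(blk))) cm[ci, cj] <- mean(blk, na.rm = TRUE)
    }
    ok <- !is.na(cm)
    r <- cor(cm[ok], obs_vals[ok])
    better <- r > best$r + 1e-15 ||
      (abs(r - best$r) <= 1e-15 &&
         (dx^2 + dy^2 < best$dx^2 + best$dy^2 ||
            (dx^2 + dy^2 == best$dx^2 + best$dy^2 &&
               (dx < best$dx || (dx == best$dx && dy < best$dy)))))
    if (better) best <- list(r = r, dx = dx, dy = dy)
  }
  expect_equal(got$r, best$r, tolerance = 1e-12)
  expect_equal(unname(c(got$dx, got$dy)), c(best$dx, best$dy))
})

test_that("a planted shift is recovered exactly and max_shift 0 is a no-op", {
  sc <- get_small_scene()
  fine <- column_radiance(sc$bundle$grid, rt_params(0.02, 0.01))
  planted <- shift_map(fine, 1, -2)
  obs <- observed_raster(resample_average(planted, 10)$values, cell_size = 10)
  got <- shift_search(fine, obs, max_shift = 3, step = 0.5)
  expect_equal(unname(c(got$dx, got$dy)), c(1, -2))
  expect_gt(got$r, 0.9999)

  null_search <- shift_search(fine, obs, max_shift = 0)
  expect_equal(unname(c(null_search$dx, null_search$dy)), c(0, 0))
  expect_equal(nrow(null_search$all), 1L)
})

test_that("the engine's shifted coarse maps equal the reference pipeline", {
  sc <- get_small_scene()
  grid <- sc$bundle$grid
  obs <- sc$bundle$observed
  engine <- vpdp:::rt_corr_engine(grid, obs, max_shift = 1, step = 0.5)
  for (gamma in c(0.005, 0.03, 0.2)) {
    p <- rt_params(gamma / 2, gamma / 2)
    fine <- column_radiance(grid, p)
    for (q in c(1L, 4L, nrow(engine$offsets))) {
      dx <- engine$offsets$dx[q]; dy <- engine$offsets$dy[q]
      ref <- resample_average(shift_map(fine, dx, dy), obs$cell_size)$values
      got <- engine$coarse_at(p$alpha, p$beta, q)
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("calibration recovers a noise-free synthetic observation", {
  sc <- get_small_scene()
  clean <- synthesize_satellite(sc$truth, 0.5, 0.02, 0.01, 10, noise_sd = 0,
                                seed = 5, origin = sc$lattice$origin,
                                dims = sc$lattice$dims)
  fit <- vpdp(sc$bundle$grid, clean$observed)
  expect_gt(fit$r, 0.999)
  expect_equal(unname(fit$shift), c(0, 0))
  # the identified quantity is the coefficient sum
  expect_lt(abs(log(fit$gamma / 0.03)), log(1.5))
})

test_that("structure-free noise yields only small correlations", {
  sc <- get_small_scene()
  set.seed(77)
  noise_vals <- matrix(rnorm(prod(dim(sc$bundle$observed$values))),
                       nrow(sc$bundle$observed$values))
  noise_obs <- observed_raster(noise_vals, cell_size = 10)
  fit <- vpdp(sc$bundle$grid, noise_obs, coarse_n = 9, refine_n = 5)
  # shift search maximizes over 169 offsets, so some optimism is expected,
  # but nothing near a structural correlation
  expect_lt(fit$r, 0.6)
})

test_that("a single-layer grid makes the objective independent of the coefficients", {
  counts <- array(0L, c(40, 40, 1))
  set.seed(8)
  counts[cbind(sample(40, 300, TRUE), sample(40, 300, TRUE), 1L)] <- 1L
  g <- voxel_grid(counts, voxel_size = 0.5)
  obs_vals <- resample_average(column_radiance(g, rt_params(0.1, 0.1)), 10)$values
  set.seed(9)
  obs <- observed_raster(obs_vals + rnorm(length(obs_vals), 0, 1e-4),
                         cell_size = 10)
  fit <- vpdp(g, obs, coarse_n = 5, refine_n = 3, max_shift = 0)
  # nothing lies above an occupied voxel, so attenuation never acts and all
  # candidates tie; the tie-break picks the smallest coefficients
  expect_equal(unname(coef(fit)), c(1e-4, 1e-4))
})

test_that("calibrated r is invariant to radiometric rescaling", {
  sc <- get_small_scene()
  grid <- sc$bundle$grid
  obs <- sc$bundle$observed
  args <- list(coarse_n = 7, refine_n = 5, max_shift = 1)
  f0 <- do.call(vpdp, c(list(grid, obs), args))
  f_ir <- do.call(vpdp, c(list(grid, obs, I = 40, R = 0.8), args))
  expect_equal(f_ir$r, f0$r, tolerance = 1e-12)
  obs2 <- observed_raster(2.7 * obs$values + 0.3, cell_size = 10,
                          mask = obs$mask)
  f_aff <- do.call(vpdp, c(list(grid, obs2), args))
  expect_equal(f_aff$r, f0$r, tolerance = 1e-12)
  expect_equal(unname(f_aff$shift), unname(f0$shift))
})

test_that("vpdp objects expose the standard modelling methods", {
  sc <- get_small_scene()
  fit <- vpdp(sc$bundle$grid, sc$bundle$observed,
              coarse_n = 7, refine_n = 5, max_shift = 1)
  expect_s3_class(fit, "vpdp")
  expect_named(coef(fit), c("alpha", "beta"))
  expect_equal(fit$gamma, sum(coef(fit)))
  expect_output(print(fit), "Pearson r")
  expect_output(print(summary(fit)), "r\\^2")
  expect_equal(dim(predict(fit)), dim(sc$bundle$observed$values))
  pred2 <- predict(fit, newgrid = sc$bundle$grid)
  expect_equal(dim(pred2), dim(sc$bundle$observed$values))
  expect_length(residuals(fit), sum(fit$mask))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # refinement never worsens the objective
  expect_gte(fit$r, fit$trace$coarse$r)
})

test_that("subsampling validation is reproducible and guards its preconditions", {
  sc <- get_small_scene()
  grid <- sc$bundle$grid
  obs <- sc$bundle$observed
  args <- list(coarse_n = 7, refine_n = 5, max_shift = 1)
  v1 <- do.call(subsample_validate,
                c(list(grid, obs, n_iter = 3, base_seed = 17), args))
  v2 <- do.call(subsample_validate,
                c(list(grid, obs, n_iter = 3, base_seed = 17), args))
  expect_identical(v1$iterations, v2$iterations)
  expect_equal(v1$n_iter, 3L)
  expect_equal(nrow(v1$iterations), 3L)
  expect_true(all(v1$iterations$n_calib >= 3))
  expect_true(all(v1$iterations$n_holdout >= 3))

  v_one <- do.call(subsample_validate,
                   c(list(grid, obs, n_iter = 1, base_seed = 17), args))
  expect_true(is.na(v_one$sd_r))

  tiny_mask <- matrix(FALSE, nrow(obs$values), ncol(obs$values))
  tiny_mask[1:5] <- TRUE
  tiny_obs <- observed_raster(obs$values, cell_size = 10, mask = tiny_mask)
  expect_error(do.call(subsample_validate,
                       c(list(grid, tiny_obs, n_iter = 2, base_seed = 1),
                         args)),
               ">= 3 per side")
})

test_that("calibration and validation results export to JSON and CSV", {
  sc <- get_small_scene()
  fit <- vpdp(sc$bundle$grid, sc$bundle$observed,
              coarse_n = 5, refine_n = 3, max_shift = 0.5)
  f_json <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(fit, f_json)
  back <- jsonlite::fromJSON(f_json)
  expect_equal(back$pearson_r, fit$r)
  expect_equal(back$alpha + back$beta, fit$gamma)

  v <- subsample_validate(sc$bundle$grid, sc$bundle$observed, n_iter = 2,
                          base_seed = 3, coarse_n = 5, refine_n = 3,
                          max_shift = 0.5)
  f_csv <- withr::local_tempfile(fileext = ".csv")
  write_validation_csv(v, f_csv)
  df <- read.csv(f_csv)
  expect_equal(df$r_holdout, v$iterations$r_holdout)
})

test_that("held-out correlations track the full-data fit on synthetic scenes", {
  sc <- get_small_scene()
  grid <- sc$bundle$grid
  obs <- sc$bundle$observed
  args <- list(coarse_n = 9, refine_n = 5)
  full <- do.call(vpdp, c(list(grid, obs), args))
  v <- do.call(subsample_validate,
               c(list(grid, obs, n_iter = 5, base_seed = 23), args))
  # overfitting monitor: full-data r within sampling noise of held-out mean
  expect_gte(full$r, v$mean_r - 3 * max(v$sd_r, 0.02))
  # near-noise-free calibration subset fits stay strong on holdout
  expect_gt(v$mean_r, 0.7)
})
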