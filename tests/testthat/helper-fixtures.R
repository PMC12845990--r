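# Shared fixtures and independent oracles. Expensive scenes are built once
# per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# The canonical end-to-end scene (full plot, default generator settings).
get_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- standard_scene(seed = 101)
  }
  .fixture_cache$scene
}

# A reduced-extent scene for tests that need a full pipeline but not the
# full plot.
get_small_scene <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- standard_scene(seed = 11, extent = c(60, 40))
  }
  .fixture_cache$small
}

# Voxel grids for the scene's scan clouds on the shared lattice.
scene_grids <- function(sc) {
  key <- paste0("grids_", sc$seed)
  if (is.null(.fixture_cache[[key]])) {
    lat <- sc$lattice
    .fixture_cache[[key]] <- list(
      truth = sc$bundle$grid,
      aerial = voxelize(sc$aerial, sc$voxel_size, lat$origin, lat$dims),
      ground = voxelize(sc$ground, sc$voxel_size, lat$origin, lat$dims),
      merged = voxelize(concat_clouds(sc$aerial, sc$ground), sc$voxel_size,
                        lat$origin, lat$dims))
  }
  .fixture_cache[[key]]
}

# Radiance map built directly from a value matrix (internal constructor).
radiance_map_for_test <- function(values, cell_size, origin = c(0, 0)) {
  vpdp:::radiance_map(values, origin = origin, cell_size = cell_size)
}

# Random sparse count grid.
random_grid <- function(dims = c(10, 10, 10), p_occupied = 0.3,
                        max_count = 9L, voxel_size = 1, seed = 1L) {
  set.seed(seed)
  counts <- array(0L, dims)
  occ <- stats::runif(prod(dims)) < p_occupied
  counts[occ] <- sample.int(max_count, sum(occ), replace = TRUE)
  voxel_grid(counts, voxel_size = voxel_size)
}

random_cloud <- function(n = 500L, lo = c(0, 0, 0), hi = c(10, 10, 10),
                         seed = 1L) {
  set.seed(seed)
  point_cloud(cbind(stats::runif(n, lo[1L], hi[1L]),
                    stats::runif(n, lo[2L], hi[2L]),
                    stats::runif(n, lo[3L], hi[3L])))
}

# Independent oracle for the radiative transfer core: explicit per-voxel
# loops evaluating the attenuation, reflection and column-sum equations
# directly, with no shared code with the implementation.
naive_column_radiance <- function(grid, alpha, beta, I = 1, R = 0.05,
                                  reflect_empty = FALSE) {
  d <- grid$dims
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    isum <- 0
    for (k in seq_len(d[3L])) {
      p_above <- 0
      if (k < d[3L]) {
        for (kk in (k + 1L):d[3L]) p_above <- p_above + grid$counts[i, j, kk]
      }
      i_prime <- I * exp(-alpha * p_above)
      if (reflect_empty || grid$counts[i, j, k] >= 1L) {
        isum <- isum + R * i_prime * exp(-beta * p_above) / pi
      }
    }
    out[i, j] <- isum
  }
  out
}

# Independent occupancy scan: full lattice sweep.
naive_occupancy <- function(grid) {
  out <- NULL
  d <- grid$dims
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    if (grid$counts[i, j, k] >= 1L) out <- rbind(out, c(i, j, k))
  }
  out
}

# Random occupancy set on a given lattice (built through the public API).
random_occupancy <- function(dims = c(6, 6, 8), p = 0.4, seed = 1L) {
  occupancy_set(random_grid(dims, p_occupied = p, seed = seed))
}
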