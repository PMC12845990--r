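#' Synthetic forest scene configuration
#'
#' Parameters of the virtual stand generator. The defaults emulate the kind
#' of temperate larch plantation the model is aimed at: a 150 m x 70 m plot
#' on a gentle (3 degree) slope carrying about 730 stems per hectare of
#' tall, crowned trees over a sparse broadleaf understory.
#'
#' @param extent plot extent \code{c(x, y)} in meters (default
#'   \code{c(150, 70)}).
#' @param stem_density overstory stems per hectare (default 730).
#' @param tree_height height range of overstory trees in meters (default
#'   \code{c(25, 38)}).
#' @param crown_radius crown horizontal semi-axis range in meters (default
#'   \code{c(1.5, 3)}).
#' @param crown_depth crown vertical extent range in meters (default
#'   \code{c(8, 14)}).
#' @param stem_radius stem cylinder radius in meters (default 0.1).
#' @param understory_density shrubs per hectare (default 1000).
#' @param shrub_height shrub height range in meters (default
#'   \code{c(0.5, 3)}).
#' @param terrain_slope terrain slope in degrees, dipping along +x (default
#'   3.0).
#' @param seed mandatory integer random seed.
#' @return An object of class \code{scene_config}.
#' @export
scene_config <- function(extent = c(150, 70), stem_density = 730,
                         tree_height = c(25, 38), crown_radius = c(1.5, 3),
                         crown_depth = c(8, 14), stem_radius = 0.1,
                         understory_density = 1000,
                         shrub_height = c(0.5, 3), terrain_slope = 3.0,
                         seed) {
  if (missing(seed)) stop("'seed' is mandatory for a scene_config")
  stopifnot(all(extent > 0), stem_density > 0, understory_density >= 0,
            terrain_slope >= 0)
  structure(list(extent = extent, stem_density = stem_density,
                 tree_height = tree_height, crown_radius = crown_radius,
                 crown_depth = crown_depth, stem_radius = stem_radius,
                 understory_density = understory_density,
                 shrub_height = shrub_height, terrain_slope = terrain_slope,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Virtual scan configuration
#'
#' Acquisition parameters for the two platform archetypes. The aerial scan
#' abstracts a nadir UAV acquisition: pulses on a horizontal grid, a limited
#' number of returns per pulse (common sensor limits are 5 and 32), deeper
#' hits occluded. The ground scan abstracts a handheld/mobile acquisition
#' along a walking trajectory: retention decays exponentially with
#' horizontal distance from the trajectory and with the amount of material
#' below the target point (canopy blocking seen from below); sensor return
#' limits are typically 1-3 but the ground model is probabilistic and does
#' not enumerate pulses.
#'
#' @param platform \code{"aerial"} or \code{"ground"}.
#' @param max_returns maximum returns per pulse (aerial; default 5).
#' @param pulse_spacing aerial pulse grid spacing in meters (default 0.5).
#' @param trajectory ground walking path as a 2-column matrix of (x, y)
#'   vertices; default NULL (a path is derived from the scene extent by
#'   \code{\link{simulate_ground_scan}}).
#' @param range_decay ground range-decay scale lambda in meters (default 15):
#'   retention drops by 1/e every lambda meters from the trajectory.
#' @param occlusion_coef ground upward-occlusion coefficient per blocking
#'   point (default 0.08).
#' @param max_range ground maximum range in meters (default 100).
#' @param noise_sd per-coordinate Gaussian noise sd in meters (default 0.02
#'   aerial, 0.03 ground).
#' @param seed mandatory integer random seed.
#' @return An object of class \code{scan_config}.
#' @export
scan_config <- function(platform = c("aerial", "ground"), max_returns = NULL,
                        pulse_spacing = 0.5, trajectory = NULL,
                        range_decay = 15, occlusion_coef = 0.08,
                        max_range = 100, noise_sd = NULL, seed) {
  platform <- match.arg(platform)
  if (missing(seed)) stop("'seed' is mandatory for a scan_config")
  if (is.null(max_returns)) max_returns <- if (platform == "aerial") 5L else 3L
  if (is.null(noise_sd)) noise_sd <- if (platform == "aerial") 0.02 else 0.03
  stopifnot(max_returns >= 1L, pulse_spacing > 0, range_decay > 0,
            occlusion_coef >= 0, max_range > 0, noise_sd >= 0)
  structure(list(platform = platform, max_returns = as.integer(max_returns),
                 pulse_spacing = pulse_spacing, trajectory = trajectory,
                 range_decay = range_decay, occlusion_coef = occlusion_coef,
                 max_range = max_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Read a scene or scan configuration from YAML
#' @param path YAML file whose top-level keys are constructor arguments.
#' @param type \code{"scene"} or \code{"scan"}.
#' @return A \code{scene_config} or \code{scan_config}.
#' @export
read_config_yaml <- function(path, type = c("scene", "scan")) {
  type <- match.arg(type)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  args <- yaml::read_yaml(path)
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(if (type == "scene") scene_config else scan_config, args)
}

#' Generate a virtual forest stand
#'
#' Draws tree and shrub positions from a seeded Poisson point process over
#' the plot, assigns each tree a height, crown radius, crown vertical
#' extent and crown base, and lays a planar sloped terrain under them. The
#' two-layer structure (tall crowned overstory above bare stems, plus low
#' shrubs) reproduces the characteristic mid-canopy density minimum of
#' mature plantations.
#'
#' @param config a \code{scene_config}.
#' @return An object of class \code{forest_stand}: list with data.frames
#'   \code{trees} (x, y, z_ground, height, crown_radius, crown_depth,
#'   crown_base) and \code{shrubs}, the terrain function parameters, and the
#'   config.
#' @export
generate_stand <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (prod(config$extent) <= 0) stop("zero-area plot")
  set.seed(config$seed)
  area_ha <- prod(config$extent) / 1e4
  slope_tan <- tan(config$terrain_slope * pi / 180)
  ground_z <- function(x, y) slope_tan * x

  n_tree <- stats::rpois(1L, config$stem_density * area_ha)
  trees <- data.frame(
    x = stats::runif(n_tree, 0, config$extent[1L]),
    y = stats::runif(n_tree, 0, config$extent[2L]),
    height = stats::runif(n_tree, config$tree_height[1L],
                          config$tree_height[2L]),
    crown_radius = stats::runif(n_tree, config$crown_radius[1L],
                                config$crown_radius[2L]),
    crown_depth = stats::runif(n_tree, config$crown_depth[1L],
                               config$crown_depth[2L]))
  trees$z_ground <- ground_z(trees$x, trees$y)
  trees$crown_base <- trees$height - trees$crown_depth

  n_shrub <- stats::rpois(1L, config$understory_density * area_ha)
  shrubs <- data.frame(
    x = stats::runif(n_shrub, 0, config$extent[1L]),
    y = stats::runif(n_shrub, 0, config$extent[2L]),
    height = stats::runif(n_shrub, config$shrub_height[1L],
                          config$shrub_height[2L]))
  shrubs$radius <- 0.3 + 0.4 * shrubs$height
  shrubs$z_ground <- ground_z(shrubs$x, shrubs$y)

  structure(list(trees = trees, shrubs = shrubs, slope_tan = slope_tan,
                 ground_z = ground_z, config = config),
            class = "forest_stand")
}

#' @export
print.forest_stand <- function(x, ...) {
  cat(sprintf("Forest stand: %d trees, %d shrubs on %.0f x %.0f m (slope %.1f deg)\n",
              nrow(x$trees), nrow(x$shrubs), x$config$extent[1L],
              x$config$extent[2L], x$config$terrain_slope))
  invisible(x)
}

# Approximate spheroid surface area (semi-axes a = b, c), Thomsen's formula.
spheroid_area <- function(a, c) {
  p <- 1.6075
  4 * pi * (((a^p) * (a^p) + 2 * (a^p) * (c^p)) / 3)^(1 / p)
}

#' Sample a ground-truth point cloud from a stand
#'
#' Turns the geometric stand into a dense reference point cloud: crowns as
#' spheroids (a denser shell plus uniform interior points), stems as
#' vertical cylinders, shrubs as small spheroids, terrain as a surface.
#' Expected point counts per element are surface area times the class
#' density (Poisson-distributed), so doubling a density doubles expected
#' counts.
#'
#' @param stand a \code{forest_stand}.
#' @param surface_density points per square meter: either a single number
#'   applied to every element class or a named vector with entries
#'   \code{terrain}, \code{stem}, \code{crown}, \code{shrub} (defaults
#'   8, 12, 1.5, 1.5).
#' @param shell_fraction fraction of crown points on the spheroid shell,
#'   the rest uniform in its volume (default 0.6).
#' @param seed random seed; default: the stand's scene seed + 1.
#' @return A \code{point_cloud} with \code{source_id} labelling the element
#'   type of every point.
#' @export
sample_surface_points <- function(stand, surface_density = NULL,
                                  shell_fraction = 0.6, seed = NULL) {
  stopifnot(inherits(stand, "forest_stand"))
  dens <- c(terrain = 8, stem = 12, crown = 1.5, shrub = 1.5)
  if (!is.null(surface_density)) {
    if (is.null(names(surface_density))) {
      dens[] <- surface_density
    } else {
      dens[names(surface_density)] <- surface_density
    }
  }
  stopifnot(all(dens >= 0))
  if (is.null(seed)) seed <- stand$config$seed + 1L
  set.seed(seed)
  ext <- stand$config$extent
  parts <- list()

  # terrain
  n_t <- stats::rpois(1L, prod(ext) * dens[["terrain"]])
  if (n_t > 0L) {
    x <- stats::runif(n_t, 0, ext[1L]); y <- stats::runif(n_t, 0, ext[2L])
    parts$terrain <- cbind(x, y, stand$ground_z(x, y))
  }

  tr <- stand$trees
  if (nrow(tr) > 0L) {
    # stems: cylinder lateral surfaces from ground to crown base
    h <- pmax(tr$crown_base, 0.1)
    n_s <- stats::rpois(nrow(tr), 2 * pi * stand$config$stem_radius * h *
                          dens[["stem"]])
    if (sum(n_s) > 0L) {
      id <- rep(seq_len(nrow(tr)), n_s)
      theta <- stats::runif(sum(n_s), 0, 2 * pi)
      parts$stem <- cbind(
        tr$x[id] + stand$config$stem_radius * cos(theta),
        tr$y[id] + stand$config$stem_radius * sin(theta),
        tr$z_ground[id] + stats::runif(sum(n_s)) * h[id])
    }
    # crowns: spheroid shell + interior
    n_c <- stats::rpois(nrow(tr),
                        spheroid_area(tr$crown_radius, tr$crown_depth / 2) *
                          dens[["crown"]])
    if (sum(n_c) > 0L) {
      id <- rep(seq_len(nrow(tr)), n_c)
      cz <- tr$z_ground[id] + tr$crown_base[id] + tr$crown_depth[id] / 2
      parts$crown <- spheroid_points(length(id), tr$x[id], tr$y[id], cz,
                                     tr$crown_radius[id],
                                     tr$crown_depth[id] / 2, shell_fraction)
    }
  }

  sh <- stand$shrubs
  if (nrow(sh) > 0L && dens[["shrub"]] > 0) {
    n_u <- stats::rpois(nrow(sh),
                        spheroid_area(sh$radius, sh$height / 2) *
                          dens[["shrub"]])
    if (sum(n_u) > 0L) {
      id <- rep(seq_len(nrow(sh)), n_u)
      cz <- sh$z_ground[id] + sh$height[id] / 2
      parts$shrub <- spheroid_points(length(id), sh$x[id], sh$y[id], cz,
                                     sh$radius[id], sh$height[id] / 2,
                                     shell_fraction)
    }
  }

  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (length(parts) == 0L) return(point_cloud(NULL))
  xyz <- do.call(rbind, parts)
  # clip to the plot footprint (crowns may overhang the boundary)
  keep <- xyz[, 1L] >= 0 & xyz[, 1L] < ext[1L] &
          xyz[, 2L] >= 0 & xyz[, 2L] < ext[2L]
  src <- rep(names(parts), vapply(parts, nrow, integer(1L)))[keep]
  point_cloud(xyz[keep, , drop = FALSE], source_id = src,
              crs_note = "synthetic local meters")
}

# n points on/in spheroids centered at (cx, cy, cz) with semi-axes (a, a, c);
# a fraction on the shell (directions uniform on the sphere, then scaled),
# the rest uniform-in-ball scaled. Shell sampling is direction-uniform, an
# adequate approximation for emulation purposes.
spheroid_points <- function(n, cx, cy, cz, a, c, shell_fraction) {
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  r <- ifelse(stats::runif(n) < shell_fraction, 1, stats::runif(n)^(1 / 3))
  cbind(cx + a * r * u[, 1L], cy + a * r * u[, 2L], cz + c * r * u[, 3L])
}

#' Simulate a nadir aerial LiDAR scan
#'
#' Emulates a UAV acquisition over the truth cloud: vertical pulses on a
#' horizontal grid; within each pulse footprint the truth points are ordered
#' top-down and only the first \code{max_returns} are kept (deeper points
#' are occluded), then Gaussian coordinate noise is added.
#'
#' @param truth_cloud the ground-truth \code{point_cloud}.
#' @param scan_config a \code{scan_config} with \code{platform = "aerial"}.
#' @return The scanned \code{point_cloud} (source_id = "aerial").
#' @export
simulate_aerial_scan <- function(truth_cloud, scan_config) {
  stopifnot(inherits(truth_cloud, "point_cloud"),
            inherits(scan_config, "scan_config"),
            scan_config$platform == "aerial")
  set.seed(scan_config$seed)
  xyz <- truth_cloud$xyz
  if (nrow(xyz) == 0L) return(point_cloud(NULL))
  sp <- scan_config$pulse_spacing
  ci <- floor(xyz[, 1L] / sp)
  cj <- floor(xyz[, 2L] / sp)
  cell <- ci + (max(ci) - min(ci) + 1L) * cj
  ord <- order(cell, -xyz[, 3L])
  rank_in_cell <- stats::ave(seq_along(ord), cell[ord],
                             FUN = seq_along)
  keep <- logical(nrow(xyz))
  keep[ord] <- rank_in_cell <= scan_config$max_returns
  out <- xyz[keep, , drop = FALSE]
  out <- out + matrix(stats::rnorm(length(out), 0, scan_config$noise_sd),
                      ncol = 3L)
  point_cloud(out, source_id = rep("aerial", nrow(out)),
              crs_note = truth_cloud$crs_note)
}

#' Simulate a ground (handheld/mobile) LiDAR scan
#'
#' Emulates a walking acquisition: every truth point is retained with
#' probability \code{exp(-d / lambda) * exp(-mu * n_below)}, where \code{d}
#' is the horizontal distance to the trajectory, \code{lambda} the
#' range-decay scale, \code{n_below} the number of truth points below the
#' target in its 0.5 m vertical column (material blocking the upward view),
#' and \code{mu} the occlusion coefficient. Points beyond \code{max_range}
#' are never returned. Gaussian coordinate noise is added to retained
#' points. The model reproduces the signature ground-scan pattern: dense
#' near-trajectory understory coverage and strongly occluded upper canopy.
#'
#' @param truth_cloud the ground-truth \code{point_cloud}.
#' @param scan_config a \code{scan_config} with \code{platform = "ground"};
#'   if its \code{trajectory} is NULL, a two-line walking path spanning the
#'   cloud's x extent at 30\% and 70\% of its y extent is used.
#' @return The scanned \code{point_cloud} (source_id = "ground").
#' @export
simulate_ground_scan <- function(truth_cloud, scan_config) {
  stopifnot(inherits(truth_cloud, "point_cloud"),
            inherits(scan_config, "scan_config"),
            scan_config$platform == "ground")
  xyz <- truth_cloud$xyz
  if (nrow(xyz) == 0L) return(point_cloud(NULL))
  traj <- scan_config$trajectory
  if (is.null(traj)) {
    rx <- range(xyz[, 1L]); ry <- range(xyz[, 2L])
    y1 <- ry[1L] + 0.3 * diff(ry); y2 <- ry[1L] + 0.7 * diff(ry)
    traj <- rbind(c(rx[1L], y1), c(rx[2L], y1),
                  c(rx[2L], y2), c(rx[1L], y2))
  }
  if (!is.matrix(traj) || nrow(traj) < 1L) stop("empty trajectory")
  set.seed(scan_config$seed)
  d <- dist_to_polyline(xyz[, 1L], xyz[, 2L], traj)
  n_below <- count_below(xyz, cell = 0.5)
  p <- exp(-d / scan_config$range_decay) *
    exp(-scan_config$occlusion_coef * n_below)
  p[d > scan_config$max_range] <- 0
  keep <- stats::runif(nrow(xyz)) < p
  out <- xyz[keep, , drop = FALSE]
  out <- out + matrix(stats::rnorm(length(out), 0, scan_config$noise_sd),
                      ncol = 3L)
  point_cloud(out, source_id = rep("ground", nrow(out)),
              crs_note = truth_cloud$crs_note)
}

# Horizontal distance from points to a polyline (minimum over segments;
# a single vertex degenerates to point distance).
dist_to_polyline <- function(x, y, traj) {
  d <- rep(Inf, length(x))
  if (nrow(traj) == 1L) {
    return(sqrt((x - traj[1L, 1L])^2 + (y - traj[1L, 2L])^2))
  }
  for (s in seq_len(nrow(traj) - 1L)) {
    a <- traj[s, ]; b <- traj[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - a[1L]) * ab[1L] + (y - a[2L]) * ab[2L]) / len2))
    d <- pmin(d, sqrt((x - (a[1L] + t * ab[1L]))^2 +
                        (y - (a[2L] + t * ab[2L]))^2))
  }
  d
}

# Number of cloud points strictly below each point within its own
# cell x cell vertical column.
count_below <- function(xyz, cell = 0.5) {
  ci <- floor(xyz[, 1L] / cell)
  cj <- floor(xyz[, 2L] / cell)
  col_id <- ci + (max(ci) - min(ci) + 1L) * cj
  ord <- order(col_id, xyz[, 3L])
  r <- stats::ave(seq_along(ord), col_id[ord], FUN = seq_along)
  out <- integer(nrow(xyz))
  out[ord] <- r - 1L
  out
}

#' Synthesize a coarse satellite reflectance raster from a truth cloud
#'
#' Closes the simulation loop: voxelizes the ground-truth cloud, runs the
#' forward radiance model at known coefficients (alpha*, beta*), aggregates
#' to the satellite pixel size, rescales affinely into a plausible NIR
#' top-of-atmosphere reflectance range, and adds i.i.d. Gaussian noise.
#' Because the stand-in observation is produced by the package's own forward
#' model, parameter and correlation recovery against it are
#' internal-consistency checks, not validation against independent physics.
#'
#' @param truth_cloud the ground-truth \code{point_cloud}.
#' @param voxel_size fine voxel size in meters (default 0.5).
#' @param alpha_star,beta_star true attenuation coefficients per point.
#' @param pixel_size satellite pixel size in meters (default 10).
#' @param noise_sd Gaussian noise sd in reflectance units (default 0).
#' @param seed integer seed for the noise draw.
#' @param I,R forward-model irradiance and leaf reflectance (defaults 1,
#'   0.05).
#' @param origin,dims optional lattice override (see \code{\link{voxelize}});
#'   by default the lattice covers the cloud and is padded so the plot is an
#'   exact number of satellite pixels.
#' @param reflect_range target reflectance range for the affine rescale
#'   (default \code{c(0.15, 0.45)}).
#' @return An object of class \code{truth_bundle}: list with \code{observed}
#'   (an \code{\link{observed_raster}}), \code{signal} (the noise-free
#'   scaled raster matrix), \code{grid} (the truth \code{voxel_grid}),
#'   \code{alpha_star}, \code{beta_star}, \code{noise_sd}, \code{gain},
#'   \code{offset}, \code{seed}, and a \code{provenance} record of every
#'   generation parameter.
#' @export
synthesize_satellite <- function(truth_cloud, voxel_size = 0.5, alpha_star,
                                 beta_star, pixel_size = 10, noise_sd = 0,
                                 seed = 1L, I = 1, R = 0.05, origin = NULL,
                                 dims = NULL,
                                 reflect_range = c(0.15, 0.45)) {
  stopifnot(inherits(truth_cloud, "point_cloud"), voxel_size > 0,
            alpha_star >= 0, beta_star >= 0, pixel_size > 0, noise_sd >= 0)
  ratio <- pixel_size / voxel_size
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("'pixel_size' must be an integer multiple of 'voxel_size'")
  }
  ratio <- as.integer(round(ratio))
  if (is.null(origin) || is.null(dims)) {
    lat <- shared_lattice(list(truth_cloud), voxel_size)
    if (is.null(origin)) origin <- lat$origin
    if (is.null(dims)) {
      dims <- lat$dims
      dims[1:2] <- as.integer(ceiling(dims[1:2] / ratio) * ratio)
    }
  }
  grid <- voxelize(truth_cloud, voxel_size, origin = origin, dims = dims)
  fine <- column_radiance(grid, rt_params(alpha_star, beta_star, I = I, R = R))
  coarse <- resample_average(fine, pixel_size)
  signal <- coarse$values
  rng <- range(signal, na.rm = TRUE)
  gain <- if (diff(rng) > 0) diff(reflect_range) / diff(rng) else 1
  offset <- reflect_range[1L] - gain * rng[1L]
  signal <- gain * signal + offset
  set.seed(seed)
  noisy <- signal + stats::rnorm(length(signal), 0, noise_sd)
  obs <- observed_raster(matrix(noisy, nrow(signal), ncol(signal)),
                         origin = origin[1:2], cell_size = pixel_size)
  structure(list(observed = obs, signal = signal, grid = grid,
                 alpha_star = alpha_star, beta_star = beta_star,
                 noise_sd = noise_sd, gain = gain, offset = offset,
                 seed = as.integer(seed),
                 provenance = list(voxel_size = voxel_size,
                                   pixel_size = pixel_size, I = I, R = R,
                                   origin = origin, dims = dims,
                                   reflect_range = reflect_range)),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("Synthetic satellite bundle: %d x %d pixels of %g m; alpha* = %g, beta* = %g, noise sd = %g\n",
              nrow(x$observed$values), ncol(x$observed$values),
              x$observed$cell_size, x$alpha_star, x$beta_star, x$noise_sd))
  invisible(x)
}

#' The standard synthetic scene
#'
#' One canonical end-to-end scene used throughout the package's examples and
#' tests: the default virtual stand, its ground-truth cloud, one aerial and
#' one ground scan, a shared voxel lattice covering all clouds (padded to
#' whole satellite pixels), and a synthetic 10 m satellite raster generated
#' from the truth cloud at known coefficients (alpha* = 0.02, beta* = 0.01
#' per point) with noise at \code{noise_rel} times the spatial standard
#' deviation of the noise-free signal.
#'
#' @param seed integer seed controlling every random draw (default 101).
#' @param noise_rel satellite noise, relative to the signal sd (default 0.5).
#' @param extent plot extent passed to \code{\link{scene_config}}.
#' @param voxel_size fine voxel size (default 0.5 m).
#' @param pixel_size satellite pixel size (default 10 m).
#' @param alpha_star,beta_star true coefficients (defaults 0.02, 0.01).
#' @return list with \code{stand}, \code{truth}, \code{aerial},
#'   \code{ground}, \code{lattice} (origin + dims), \code{voxel_size},
#'   \code{bundle} (a \code{truth_bundle}), and \code{seed}.
#' @export
standard_scene <- function(seed = 101L, noise_rel = 0.5, extent = c(150, 70),
                           voxel_size = 0.5, pixel_size = 10,
                           alpha_star = 0.02, beta_star = 0.01) {
  cfg <- scene_config(extent = extent, seed = seed)
  stand <- generate_stand(cfg)
  truth <- sample_surface_points(stand, seed = seed + 1L)
  aerial <- simulate_aerial_scan(truth, scan_config("aerial", seed = seed + 2L))
  ground <- simulate_ground_scan(truth, scan_config("ground", seed = seed + 3L))
  lat <- shared_lattice(list(truth, aerial, ground), voxel_size)
  ratio <- as.integer(round(pixel_size / voxel_size))
  lat$dims[1:2] <- as.integer(ceiling(lat$dims[1:2] / ratio) * ratio)
  # noise level: scale to the noise-free signal's sd
  clean <- synthesize_satellite(truth, voxel_size, alpha_star, beta_star,
                                pixel_size, noise_sd = 0, seed = seed + 4L,
                                origin = lat$origin, dims = lat$dims)
  nsd <- noise_rel * stats::sd(clean$signal)
  bundle <- synthesize_satellite(truth, voxel_size, alpha_star, beta_star,
                                 pixel_size, noise_sd = nsd, seed = seed + 4L,
                                 origin = lat$origin, dims = lat$dims)
  list(stand = stand, truth = truth, aerial = aerial, ground = ground,
       lattice = lat, voxel_size = voxel_size, bundle = bundle,
       seed = as.integer(seed))
}
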