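#' Radiative transfer parameters
#'
#' Parameters of the Beer-Lambert point-density-proxy model. Light enters
#' each column vertically from above with incident irradiance \code{I}; the
#' cumulative point count along the path attenuates it with coefficient
#' \code{alpha} (per point), each occupied voxel reflects a fraction
#' \code{R} of the transmitted irradiance as Lambertian upward radiance, and
#' the return path is attenuated with coefficient \code{beta} (per point).
#'
#' Because the analysis is correlation-based, \code{I} conventionally stays
#' at 1 and \code{R} at the mean NIR leaf reflectance of the target species
#' (0.05 for larch); both only rescale the simulated radiance linearly.
#'
#' @param alpha attenuation coefficient per point (>= 0).
#' @param beta return-path attenuation coefficient per point (>= 0).
#' @param I incident irradiance (> 0, default 1).
#' @param R leaf spectral reflectance in (0, 1] (default 0.05).
#' @return An object of class \code{rt_params}.
#' @export
rt_params <- function(alpha, beta, I = 1, R = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            I > 0, R > 0, R <= 1)
  structure(list(alpha = alpha, beta = beta, I = I, R = R),
            class = "rt_params")
}

#' @export
print.rt_params <- function(x, ...) {
  cat(sprintf("RT parameters: alpha = %g, beta = %g per point; I = %g, R = %g\n",
              x$alpha, x$beta, x$I, x$R))
  invisible(x)
}

# Cumulative point count strictly above each voxel in its own column
# (the attenuating mass between the overhead light source and the voxel,
# excluding the voxel itself). Returned as a double array of dim(grid).
cumulative_above <- function(grid) {
  d <- grid$dims
  S <- array(0, d)
  if (d[3L] > 1L) {
    for (k in (d[3L] - 1L):1L) {
      S[, , k] <- S[, , k + 1L] + grid$counts[, , k + 1L]
    }
  }
  S
}

#' Transmitted irradiance field
#'
#' Downward Beer-Lambert attenuation: the irradiance reaching voxel
#' \code{[i, j, k]} is \code{I * exp(-alpha * P_sum)}, where \code{P_sum} is
#' the total point count stored in voxels of the same column strictly above
#' \code{k}. The topmost voxel of every column receives the full incident
#' irradiance.
#'
#' @param grid a \code{voxel_grid}.
#' @param params an \code{rt_params}.
#' @return Numeric 3-D array of transmitted irradiance, same dimension as
#'   \code{grid$counts}.
#' @export
transmitted_irradiance <- function(grid, params) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "rt_params"))
  params$I * exp(-params$alpha * cumulative_above(grid))
}

#' Upward radiance field
#'
#' Lambertian reflection of the transmitted irradiance back toward a nadir
#' sensor: an occupied voxel contributes
#' \code{R * I' * exp(-beta * P_above) / pi}, where \code{P_above} is the
#' point count in the same column strictly above it (the return path crosses
#' the same material as the incident path under vertical geometry). Empty
#' voxels have no scattering surface and contribute 0 by default;
#' \code{reflect_empty = TRUE} evaluates the literal all-voxel sum instead,
#' which makes column radiance depend on the empty lattice depth and is
#' provided for comparison only.
#'
#' @param grid a \code{voxel_grid}.
#' @param i_prime transmitted irradiance array from
#'   \code{\link{transmitted_irradiance}} on the same grid.
#' @param params an \code{rt_params}.
#' @param reflect_empty logical; include empty voxels in the sum.
#' @return Numeric 3-D array of per-voxel upward radiance.
#' @export
upward_radiance <- function(grid, i_prime, params, reflect_empty = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "rt_params"),
            identical(dim(i_prime), dim(grid$counts)))
  out <- params$R * i_prime * exp(-params$beta * cumulative_above(grid)) / pi
  if (!reflect_empty) out[grid$counts < 1L] <- 0
  out
}

#' Column radiance map
#'
#' Total upward radiance per (i, j) column: the sum of per-voxel upward
#' radiance over the column, simulated at the voxel grid's horizontal
#' resolution. Empty columns yield 0.
#'
#' @param grid a \code{voxel_grid}.
#' @param params an \code{rt_params}.
#' @param reflect_empty see \code{\link{upward_radiance}}.
#' @return An object of class \code{radiance_map}: list with \code{origin}
#'   (x0, y0), \code{cell_size} (= voxel size), and numeric matrix
#'   \code{values} (nx rows by ny columns) of column radiance.
#' @export
column_radiance <- function(grid, params, reflect_empty = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "rt_params"))
  S <- cumulative_above(grid)
  contrib <- params$R * params$I *
    exp(-(params$alpha + params$beta) * S) / pi
  if (!reflect_empty) contrib[grid$counts < 1L] <- 0
  vals <- rowSums(contrib, dims = 2L)
  radiance_map(vals, origin = grid$origin[1:2], cell_size = grid$voxel_size)
}

radiance_map <- function(values, origin, cell_size) {
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = cell_size),
            class = "radiance_map")
}

#' @export
print.radiance_map <- function(x, ...) {
  cat(sprintf("Radiance map: %d x %d cells of %.2g m; range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Average-aggregation resampling of a radiance map
#'
#' Resamples a fine radiance map to a coarser pixel size (typically the 10 m
#' satellite grid) by taking the arithmetic mean of the fine cells each
#' coarse pixel covers. When the target size is an exact integer multiple of
#' the fine cell size each coarse pixel is the plain mean of a full block;
#' otherwise the mean is area-weighted. NA fine cells (e.g. introduced by
#' shifting) are excluded from the mean; a coarse pixel covered only by NA
#' cells is NA.
#'
#' @param fine_map a \code{radiance_map}.
#' @param target_cell coarse pixel size in meters (>= fine cell size).
#' @return A \code{radiance_map} at the coarse resolution.
#' @export
resample_average <- function(fine_map, target_cell) {
  stopifnot(inherits(fine_map, "radiance_map"))
  t_fine <- fine_map$cell_size
  if (target_cell < t_fine) {
    stop("'target_cell' must be at least the fine cell size")
  }
  M <- fine_map$values
  Wx <- overlap_weights(nrow(M), t_fine, target_cell)
  Wy <- overlap_weights(ncol(M), t_fine, target_cell)
  V <- !is.na(M)
  M0 <- ifelse(V, M, 0)
  num <- Wx %*% M0 %*% t(Wy)
  den <- Wx %*% (V + 0) %*% t(Wy)
  vals <- ifelse(den > 0, num / den, NA_real_)
  radiance_map(vals, origin = fine_map$origin, cell_size = target_cell)
}

# Overlap length of each coarse interval [c*T, (c+1)*T) with each fine
# interval [f*t, (f+1)*t), as an (ncoarse x nfine) matrix.
overlap_weights <- function(nfine, t, T) {
  ncoarse <- ceiling(nfine * t / T)
  W <- matrix(0, ncoarse, nfine)
  f_lo <- (seq_len(nfine) - 1L) * t
  f_hi <- f_lo + t
  for (c in seq_len(ncoarse)) {
    lo <- (c - 1L) * T
    hi <- c * T
    ov <- pmin(f_hi, hi) - pmax(f_lo, lo)
    W[c, ] <- pmax(ov, 0)
  }
  W
}
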