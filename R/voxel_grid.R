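#' Construct a voxel grid from a count array
#'
#' Low-level constructor for programmatically built grids (the usual route
#' is \code{\link{voxelize}}). Counts must be non-negative integers; the z
#' index (third array dimension) increases upward from \code{origin[3]}.
#'
#' @param counts non-negative integer 3-D array of per-voxel point counts.
#' @param voxel_size voxel edge length in meters (> 0).
#' @param origin lattice origin \code{c(x0, y0, z0)} (default \code{c(0,0,0)}).
#' @return A \code{voxel_grid}.
#' @export
voxel_grid <- function(counts, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L, voxel_size > 0,
            length(origin) == 3L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 dims = dim(counts), counts = counts, n_outside = 0L),
            class = "voxel_grid")
}

#' Voxelize a point cloud
#'
#' Converts a point cloud into a regular 3-D lattice of per-voxel point
#' counts, the state on which both the structural metrics and the radiative
#' transfer simulation operate. Binning is half-open with floor indexing:
#' voxel \code{[i, j, k]} covers
#' \code{[x0 + (i-1) s, x0 + i s) x ... x [z0 + (k-1) s, z0 + k s)} and a
#' point exactly on a boundary goes to the higher-index voxel. The z index
#' increases upward from \code{z0}.
#'
#' Typical voxel edge lengths for forest canopies are 0.2, 0.5, 1.0 and
#' 2.0 m; 0.5 m is a common working resolution that balances structural
#' detail against per-voxel count stability.
#'
#' @param cloud a \code{point_cloud}.
#' @param voxel_size voxel edge length s in meters (isotropic, > 0).
#' @param origin optional \code{c(x0, y0, z0)}; default: floor of the cloud's
#'   minimum coordinates.
#' @param dims optional \code{c(nx, ny, nz)}; default: cover the cloud from
#'   \code{origin}.
#' @return An object of class \code{voxel_grid}: list with \code{origin},
#'   \code{voxel_size}, \code{dims}, an integer count array \code{counts}
#'   of dimension \code{dims}, and \code{n_outside}, the number of points
#'   falling outside the lattice (counted and reported, never stored).
#' @examples
#' pc <- point_cloud(cbind(runif(50, 0, 2), runif(50, 0, 2), runif(50, 0, 2)))
#' g <- voxelize(pc, 0.5)
#' sum(g$counts) + g$n_outside == npoints(pc)
#' @export
voxelize <- function(cloud, voxel_size, origin = NULL, dims = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("'voxel_size' must be a single positive number")
  }
  xyz <- cloud$xyz
  if (is.null(origin)) {
    origin <- if (nrow(xyz) > 0L) floor(apply(xyz, 2L, min)) else c(0, 0, 0)
  }
  origin <- as.numeric(origin)
  ijk <- floor(sweep(xyz, 2L, origin) / voxel_size)  # 0-based
  if (is.null(dims)) {
    dims <- if (nrow(ijk) > 0L) apply(ijk, 2L, max) + 1L else c(1L, 1L, 1L)
  }
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1L))
  inside <- if (nrow(ijk) > 0L) {
    ijk[, 1L] >= 0L & ijk[, 1L] < dims[1L] &
    ijk[, 2L] >= 0L & ijk[, 2L] < dims[2L] &
    ijk[, 3L] >= 0L & ijk[, 3L] < dims[3L]
  } else logical(0L)
  if (nrow(xyz) > 0L && !any(inside)) {
    warning("supplied lattice excludes every point")
  }
  counts <- array(0L, dims)
  if (any(inside)) {
    lin <- 1L + ijk[inside, 1L] +
      dims[1L] * (ijk[inside, 2L] + dims[2L] * ijk[inside, 3L])
    counts <- array(as.integer(tabulate(lin, nbins = prod(dims))), dims)
  }
  structure(list(origin = origin, voxel_size = voxel_size, dims = dims,
                 counts = counts, n_outside = sum(!inside)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d voxels of %.2g m at origin (%.1f, %.1f, %.1f)\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size,
              x$origin[1L], x$origin[2L], x$origin[3L]))
  cat(sprintf("  %d points stored, %d occupied voxels, %d points outside lattice\n",
              sum(x$counts), sum(x$counts > 0L), x$n_outside))
  invisible(x)
}

#' Shared lattice covering several point clouds
#'
#' Computes a single origin and dimension triple from the union bounding box
#' of the supplied clouds so that every cloud (and any merge) is voxelized on
#' one common lattice. Comparing occupancy index sets is only meaningful on a
#' shared lattice.
#'
#' @param clouds list of \code{point_cloud} objects.
#' @param voxel_size voxel edge length (m).
#' @return list with \code{origin} and \code{dims} suitable for
#'   \code{\link{voxelize}}.
#' @export
shared_lattice <- function(clouds, voxel_size) {
  stopifnot(length(clouds) >= 1L, voxel_size > 0)
  xyz <- do.call(rbind, lapply(clouds, `[[`, "xyz"))
  if (is.null(xyz) || nrow(xyz) == 0L) {
    return(list(origin = c(0, 0, 0), dims = c(1L, 1L, 1L)))
  }
  origin <- floor(apply(xyz, 2L, min))
  dims <- as.integer(floor(sweep(xyz, 2L, origin) / voxel_size) |>
                       apply(2L, max)) + 1L
  list(origin = as.numeric(origin), dims = dims)
}

#' Merge voxel grids on a shared lattice
#'
#' Element-wise sum of counts; the merge of per-sensor grids equals the
#' voxelization of the concatenated clouds on the same lattice.
#'
#' @param grids list of \code{voxel_grid} objects sharing origin, voxel size
#'   and dimensions.
#' @return The merged \code{voxel_grid}.
#' @export
merge_grids <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1L,
            all(vapply(grids, inherits, logical(1L), "voxel_grid")))
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!isTRUE(all.equal(g$origin, ref$origin))) {
      stop("lattice mismatch: origin differs between grids")
    }
    if (!isTRUE(all.equal(g$voxel_size, ref$voxel_size))) {
      stop("lattice mismatch: voxel_size differs between grids")
    }
    if (!identical(g$dims, ref$dims)) {
      stop("lattice mismatch: dims differ between grids")
    }
  }
  counts <- Reduce(`+`, lapply(grids, `[[`, "counts"))
  storage.mode(counts) <- "integer"
  structure(list(origin = ref$origin, voxel_size = ref$voxel_size,
                 dims = ref$dims, counts = counts,
                 n_outside = sum(vapply(grids, `[[`, numeric(1L), "n_outside"))),
            class = "voxel_grid")
}

#' Re-aggregate a fine voxel grid to a coarser nested resolution
#'
#' Sums counts of \code{factor^3} fine voxels into each coarse voxel. Only
#' meaningful when the coarse size is an integer multiple of the fine size
#' and the origins coincide; then the result equals direct voxelization at
#' the coarse size.
#'
#' @param grid a \code{voxel_grid}.
#' @param factor integer aggregation factor per axis (>= 1).
#' @return The coarser \code{voxel_grid}.
#' @export
rebin_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "voxel_grid"), factor >= 1L,
            factor == as.integer(factor))
  factor <- as.integer(factor)
  newdims <- as.integer(ceiling(grid$dims / factor))
  idx <- lapply(grid$dims, function(n) (seq_len(n) - 1L) %/% factor + 1L)
  counts <- array(0L, newdims)
  # accumulate by coarse linear index
  lin <- as.vector(
    outer(outer(idx[[1L]], (idx[[2L]] - 1L) * newdims[1L], "+"),
          (idx[[3L]] - 1L) * newdims[1L] * newdims[2L], "+"))
  agg <- tabulate_weighted(lin, as.vector(grid$counts), prod(newdims))
  counts <- array(as.integer(agg), newdims)
  structure(list(origin = grid$origin, voxel_size = grid$voxel_size * factor,
                 dims = newdims, counts = counts, n_outside = grid$n_outside),
            class = "voxel_grid")
}

# sum of weights per integer bin (base tabulate only counts)
tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Write a voxel grid as a sparse CSV table with a JSON header
#'
#' Occupied voxels are written as rows \code{i, j, k, count} (1-based
#' indices) to \code{path}; the lattice descriptors (origin, voxel size,
#' dims, points outside) go to \code{paste0(path, ".json")}.
#'
#' @param grid a \code{voxel_grid}.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- which(grid$counts >= 1L, arr.ind = TRUE)
  df <- data.frame(i = occ[, 1L], j = occ[, 2L], k = occ[, 3L],
                   count = grid$counts[occ])
  utils::write.csv(df, path, row.names = FALSE)
  hdr <- sprintf(
    '{"origin": [%.10g, %.10g, %.10g], "voxel_size": %.10g, "dims": [%d, %d, %d], "n_outside": %d}',
    grid$origin[1L], grid$origin[2L], grid$origin[3L], grid$voxel_size,
    grid$dims[1L], grid$dims[2L], grid$dims[3L], grid$n_outside)
  writeLines(hdr, paste0(path, ".json"))
  invisible(path)
}

#' Read a voxel grid written by \code{\link{write_voxel_grid}}
#' @param path the CSV path (its \code{.json} header must sit beside it).
#' @return A \code{voxel_grid}.
#' @export
read_voxel_grid <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to read voxel grid headers")
  }
  hdr <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- utils::read.csv(path)
  counts <- array(0L, hdr$dims)
  counts[cbind(df$i, df$j, df$k)] <- as.integer(df$count)
  g <- voxel_grid(counts, voxel_size = hdr$voxel_size, origin = hdr$origin)
  g$n_outside <- as.integer(hdr$n_outside)
  g
}

#' Vertical layer profile of voxel point counts
#'
#' Stratifies a voxel grid into horizontal layers of fixed height above the
#' grid's minimum z and reports, per layer, the median point count over
#' occupied voxels (count >= 1) together with occupied and total voxel
#' tallies. Medians over occupied voxels characterize the vertical density
#' distribution; layers with no occupied voxel get an NA median.
#'
#' @param grid a \code{voxel_grid}.
#' @param layer_height layer thickness in meters (default 10).
#' @return A data.frame of class \code{layer_profile} with columns
#'   \code{layer_lo}, \code{layer_hi} (m above the grid origin z),
#'   \code{median_count}, \code{n_occupied}, \code{n_voxels}, ordered
#'   bottom-up.
#' @export
vertical_profile <- function(grid, layer_height = 10) {
  stopifnot(inherits(grid, "voxel_grid"), layer_height > 0)
  s <- grid$voxel_size
  nz <- grid$dims[3L]
  z_center <- (seq_len(nz) - 0.5) * s       # height above z0
  layer <- floor(z_center / layer_height)   # 0-based layer index
  nlay <- max(layer) + 1L
  out <- data.frame(layer_lo = (0:(nlay - 1L)) * layer_height,
                    layer_hi = (1:nlay) * layer_height,
                    median_count = NA_real_,
                    n_occupied = 0L, n_voxels = 0L)
  per_slab <- prod(grid$dims[1:2])
  for (l in 0:(nlay - 1L)) {
    ks <- which(layer == l)
    v <- as.vector(grid$counts[, , ks, drop = FALSE])
    occ <- v[v >= 1L]
    out$n_voxels[l + 1L] <- per_slab * length(ks)
    out$n_occupied[l + 1L] <- length(occ)
    if (length(occ) > 0L) out$median_count[l + 1L] <- stats::median(occ)
  }
  class(out) <- c("layer_profile", "data.frame")
  out
}
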