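#' Construct a point cloud
#'
#' A point cloud is the raw structural observation: a set of 3-D coordinates
#' in meters in a common projected coordinate system, optionally labelled by
#' the sensor or platform each point came from.
#'
#' @param xyz numeric matrix (or data.frame) with three columns x, y, z in
#'   meters. A zero-row matrix gives a legal empty cloud.
#' @param source_id optional vector with one label per point (sensor/platform
#'   of origin).
#' @param crs_note free-text coordinate-system tag carried along unmodified.
#' @return An object of class \code{point_cloud}: a list with a numeric
#'   \code{n x 3} matrix \code{xyz}, optional \code{source_id}, and
#'   \code{crs_note}.
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), runif(10)))
#' npoints(pc)
#' @export
point_cloud <- function(xyz, source_id = NULL, crs_note = "") {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz)
  if (is.null(xyz) || length(xyz) == 0L) {
    xyz <- matrix(numeric(0), ncol = 3L)
  }
  if (!is.matrix(xyz) || ncol(xyz) != 3L) {
    stop("'xyz' must be a matrix with 3 columns (x, y, z)")
  }
  storage.mode(xyz) <- "double"
  if (nrow(xyz) > 0L && !all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1L, all))
    stop("non-finite coordinates at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  if (!is.null(source_id) && length(source_id) != nrow(xyz)) {
    stop("'source_id' must have one value per point")
  }
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, source_id = source_id, crs_note = crs_note),
            class = "point_cloud")
}

#' Number of points in a point cloud
#' @param cloud a \code{point_cloud}.
#' @return Integer point count.
#' @export
npoints <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points", npoints(x)))
  if (!is.null(x$source_id)) {
    cat(sprintf(" (%d source labels)", length(unique(x$source_id))))
  }
  cat("\n")
  if (npoints(x) > 0L) {
    r <- apply(x$xyz, 2L, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
                r[1L, 1L], r[2L, 1L], r[1L, 2L], r[2L, 2L], r[1L, 3L], r[2L, 3L]))
  }
  if (nzchar(x$crs_note)) cat("  crs: ", x$crs_note, "\n", sep = "")
  invisible(x)
}

#' Concatenate point clouds
#' @param ... \code{point_cloud} objects.
#' @return A single \code{point_cloud} with points stacked in argument order;
#'   source labels are kept when every input has them.
#' @export
concat_clouds <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1L && is.list(clouds[[1L]]) &&
      !inherits(clouds[[1L]], "point_cloud")) {
    clouds <- clouds[[1L]]
  }
  stopifnot(all(vapply(clouds, inherits, logical(1L), "point_cloud")))
  xyz <- do.call(rbind, lapply(clouds, `[[`, "xyz"))
  ids <- lapply(clouds, `[[`, "source_id")
  src <- if (all(!vapply(ids, is.null, logical(1L)))) unlist(ids) else NULL
  point_cloud(xyz, source_id = src,
              crs_note = clouds[[1L]]$crs_note)
}

# ---- file formats -----------------------------------------------------------

#' Read a point cloud from file
#'
#' Supports whitespace-separated ASCII XYZ (one \code{x y z} triple per line,
#' \code{#} comments allowed) and uncompressed LAS (point formats 0-3; only
#' x, y, z are consumed). LAZ is recognized but rejected: decoding the
#' compressed payload is not supported.
#'
#' @param path file path.
#' @param format one of \code{"xyz"}, \code{"las"}, \code{"laz"}, or
#'   \code{"auto"} (default; decided from the file extension).
#' @return A \code{point_cloud}; input point order is preserved.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las", "laz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, las = "las", laz = "laz", "xyz")
  }
  switch(format,
         xyz = read_xyz(path),
         las = read_las(path),
         laz = stop("LAZ (compressed LAS) is not supported; ",
                    "decompress to LAS or export ASCII XYZ"))
}

#' Write a point cloud to file
#' @param cloud a \code{point_cloud}.
#' @param path destination path.
#' @param format \code{"xyz"} or \code{"las"} (\code{"auto"}: from extension).
#' @param digits significant digits for ASCII output.
#' @return \code{path}, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "las"),
                              digits = 6L) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "las") "las" else "xyz"
  }
  if (format == "xyz") {
    utils::write.table(format(cloud$xyz, digits = digits, trim = TRUE,
                              scientific = FALSE),
                       path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    write_las(cloud, path)
  }
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(point_cloud(NULL))
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed XYZ record at line(s): ",
         paste(utils::head(which(nf < 3L), 5L), collapse = ", "))
  }
  xyz <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(fields, `[`, 1:3)))), ncol = 3L, byrow = TRUE)
  if (anyNA(xyz)) {
    bad <- which(apply(is.na(xyz), 1L, any))
    stop("non-numeric coordinates at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  point_cloud(xyz)
}

# Minimal LAS 1.2 support, point data record format 0, x/y/z only.
# Header layout follows the ASPRS LAS 1.2 specification; all multi-byte
# fields are little-endian.
read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file (bad signature): ", path)
  seek(con, 24L)
  ver <- readBin(con, "integer", n = 2L, size = 1L, signed = FALSE)
  seek(con, 96L)
  offset_to_points <- readBin(con, "integer", size = 4L, endian = "little")
  readBin(con, "integer", size = 4L, endian = "little")   # n VLRs
  pdrf <- readBin(con, "integer", size = 1L, signed = FALSE)
  if (pdrf > 127L) {
    stop("LAZ-compressed point records are not supported")
  }
  if (!pdrf %in% 0:3) stop("unsupported LAS point data record format: ", pdrf)
  reclen <- readBin(con, "integer", size = 2L, signed = FALSE,
                    endian = "little")
  npts <- readBin(con, "integer", size = 4L, endian = "little")
  seek(con, 131L)  # skip returns-by-count
  scale <- readBin(con, "double", n = 3L, size = 8L, endian = "little")
  off <- readBin(con, "double", n = 3L, size = 8L, endian = "little")
  if (npts == 0L) return(point_cloud(NULL))
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = npts * reclen)
  if (length(raw) < npts * reclen) stop("truncated LAS point data: ", path)
  rec <- matrix(raw, nrow = reclen)
  ints <- function(rows) {
    readBin(as.vector(rec[rows, , drop = FALSE]), "integer", n = npts,
            size = 4L, endian = "little")
  }
  xyz <- cbind(ints(1:4) * scale[1L] + off[1L],
               ints(5:8) * scale[2L] + off[2L],
               ints(9:12) * scale[3L] + off[3L])
  point_cloud(xyz, crs_note = sprintf("LAS %d.%d", ver[1L], ver[2L]))
}

write_las <- function(cloud, path) {
  xyz <- cloud$xyz
  n <- nrow(xyz)
  scale <- rep(0.001, 3L)  # millimeter quantization
  off <- if (n > 0L) floor(apply(xyz, 2L, min)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  header_size <- 227L
  writeChar("LASF", con, 4L, eos = NULL)
  writeBin(rep(0L, 2L), con, size = 2L, endian = "little")   # source id, encoding
  writeBin(raw(16L), con)                                    # project GUID
  writeBin(c(1L, 2L), con, size = 1L)                        # version 1.2
  writeChar(formatC("vpdp", width = 32L, flag = "-"), con, 32L, eos = NULL)
  writeChar(formatC("vpdp", width = 32L, flag = "-"), con, 32L, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2L, endian = "little")  # day, year
  writeBin(header_size, con, size = 2L, endian = "little")
  writeBin(header_size, con, size = 4L, endian = "little")   # offset to points
  writeBin(0L, con, size = 4L, endian = "little")            # n VLRs
  writeBin(0L, con, size = 1L)                               # PDRF 0
  writeBin(20L, con, size = 2L, endian = "little")           # record length
  writeBin(n, con, size = 4L, endian = "little")
  writeBin(rep(0L, 5L), con, size = 4L, endian = "little")   # returns by count
  writeBin(scale, con, size = 8L, endian = "little")
  writeBin(as.double(off), con, size = 8L, endian = "little")
  mins <- if (n > 0L) apply(xyz, 2L, min) else c(0, 0, 0)
  maxs <- if (n > 0L) apply(xyz, 2L, max) else c(0, 0, 0)
  writeBin(as.double(c(maxs[1L], mins[1L], maxs[2L], mins[2L],
                       maxs[3L], mins[3L])), con, size = 8L, endian = "little")
  stopifnot(seek(con) == header_size)
  if (n > 0L) {
    q <- round(sweep(xyz, 2L, off) / rep(scale, each = n))
    storage.mode(q) <- "integer"
    rec <- matrix(raw(0L), nrow = 20L, ncol = n)
    for (d in 1:3) {
      b <- writeBin(as.vector(q[, d]), raw(), size = 4L, endian = "little")
      rec[(4L * d - 3L):(4L * d), ] <- matrix(b, nrow = 4L)
    }
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

# ---- cleaning & diagnostics -------------------------------------------------

#' Remove isolated outlier points
#'
#' Statistical k-nearest-neighbour isolation filter: a point is removed when
#' its mean distance to its \code{k_neighbors} nearest neighbours exceeds the
#' global mean of that statistic by more than \code{distance_factor} standard
#' deviations. This is a deterministic, reproducible stand-in for manual
#' removal of isolated returns; results on real data depend on the two
#' parameters.
#'
#' @param cloud a \code{point_cloud} (non-empty).
#' @param k_neighbors number of nearest neighbours (default 5).
#' @param distance_factor threshold in standard deviations (default 3).
#' @return The filtered \code{point_cloud} (a subset of the input, original
#'   order preserved). Clouds with \code{<= k_neighbors} points are returned
#'   unchanged with a warning.
#' @export
remove_isolated_outliers <- function(cloud, k_neighbors = 5L,
                                     distance_factor = 3) {
  stopifnot(inherits(cloud, "point_cloud"),
            k_neighbors >= 1L, distance_factor > 0)
  n <- npoints(cloud)
  if (n == 0L) stop("cloud is empty")
  if (n <= k_neighbors) {
    warning("cloud has <= k_neighbors points; returned unchanged")
    return(cloud)
  }
  d <- knn_mean_distance(cloud$xyz, k_neighbors)
  keep <- d <= mean(d) + distance_factor * stats::sd(d)
  subset_cloud(cloud, keep)
}

# Mean distance to the k nearest neighbours of every point. Blocked full
# distance computation: exact, O(n^2) in time but bounded memory.
knn_mean_distance <- function(xyz, k) {
  n <- nrow(xyz)
  sq <- rowSums(xyz^2)
  block <- max(1L, floor(4e6 / n))
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xyz[idx, , drop = FALSE], xyz)
    d2[cbind(seq_along(idx), idx)] <- Inf  # self
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1L, function(v) mean(sqrt(sort(v, partial = k)[1:k])))
  }
  out
}

subset_cloud <- function(cloud, keep) {
  point_cloud(cloud$xyz[keep, , drop = FALSE],
              source_id = if (!is.null(cloud$source_id)) cloud$source_id[keep],
              crs_note = cloud$crs_note)
}

#' Extract a cross-section slab from a point cloud
#'
#' Returns the points lying in a thin vertical slab, the standard visual
#' diagnostic for comparing canopy and ground returns between sensors
#' (typically on the order of 100 m long and 1 m deep).
#'
#' @param cloud a \code{point_cloud}.
#' @param axis slab-normal axis, \code{"x"} or \code{"y"}.
#' @param center slab center coordinate along \code{axis} (m).
#' @param width slab depth along \code{axis} (m); membership is half-open,
#'   \code{[center - width/2, center + width/2)}.
#' @param length optional 2-vector of bounds along the other horizontal axis
#'   (half-open); default keeps the full extent.
#' @return The slab as a \code{point_cloud} (possibly empty).
#' @export
extract_cross_section <- function(cloud, axis = c("y", "x"), center, width,
                                  length = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), width > 0)
  axis <- match.arg(axis)
  norm_col <- if (axis == "x") 1L else 2L
  along_col <- if (axis == "x") 2L else 1L
  v <- cloud$xyz[, norm_col]
  keep <- v >= center - width / 2 & v < center + width / 2
  if (!is.null(length)) {
    u <- cloud$xyz[, along_col]
    keep <- keep & u >= length[1L] & u < length[2L]
  }
  subset_cloud(cloud, keep)
}

#' Planar point-density map
#'
#' Bins points into a horizontal grid and counts points per cell (the 0.5 m
#' planar density map used to visualize acquisition coverage). Binning is
#' half-open with floor indexing: a point exactly on a cell boundary goes to
#' the higher-index cell.
#'
#' @param cloud a \code{point_cloud}.
#' @param cell_size cell edge length in meters (default 0.5).
#' @param origin optional \code{c(x0, y0)}; default: floor of the cloud's
#'   minimum x/y (0 for an empty cloud).
#' @param dims optional \code{c(nx, ny)} cell counts; default: cover the cloud.
#' @return An object of class \code{density_raster}: list with \code{origin},
#'   \code{cell_size}, integer count matrix \code{counts} (nx rows = x index),
#'   and \code{n_outside}, the number of points falling outside the grid.
#' @export
planar_density_map <- function(cloud, cell_size = 0.5, origin = NULL,
                               dims = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), cell_size > 0)
  xy <- cloud$xyz[, 1:2, drop = FALSE]
  if (is.null(origin)) {
    origin <- if (nrow(xy) > 0L) floor(apply(xy, 2L, min)) else c(0, 0)
  }
  ij <- floor(sweep(xy, 2L, origin) / cell_size)  # 0-based cell indices
  if (is.null(dims)) {
    dims <- if (nrow(ij) > 0L) apply(ij, 2L, max) + 1L else c(1L, 1L)
  }
  dims <- as.integer(dims)
  inside <- if (nrow(ij) > 0L) {
    ij[, 1L] >= 0L & ij[, 1L] < dims[1L] & ij[, 2L] >= 0L & ij[, 2L] < dims[2L]
  } else logical(0L)
  counts <- matrix(0L, dims[1L], dims[2L])
  if (any(inside)) {
    lin <- ij[inside, 1L] + dims[1L] * ij[inside, 2L] + 1L
    tab <- tabulate(lin, nbins = dims[1L] * dims[2L])
    counts <- matrix(as.integer(tab), dims[1L], dims[2L])
  }
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 counts = counts, n_outside = sum(!inside)),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("Planar density raster: %d x %d cells of %.2g m, %d points (%d outside grid)\n",
              nrow(x$counts), ncol(x$counts), x$cell_size,
              sum(x$counts), x$n_outside))
  invisible(x)
}

#' Export a density raster or coarse radiance/reflectance grid as CSV
#' @param raster a \code{density_raster} or any list with \code{origin},
#'   \code{cell_size} and a matrix field named \code{counts} or \code{values}.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  m <- if (!is.null(raster$counts)) raster$counts else raster$values
  df <- data.frame(
    i = as.vector(row(m)) - 1L,
    j = as.vector(col(m)) - 1L,
    x = raster$origin[1L] + (as.vector(row(m)) - 0.5) * raster$cell_size,
    y = raster$origin[2L] + (as.vector(col(m)) - 0.5) * raster$cell_size,
    value = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a single-band grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text raster interchange readable by GIS software. Rows are written
#' north-to-south as the format requires.
#'
#' @inheritParams write_raster_csv
#' @param na_value value written for missing cells.
#' @return \code{path}, invisibly.
#' @export
write_raster_asc <- function(raster, path, na_value = -9999) {
  m <- if (!is.null(raster$counts)) raster$counts else raster$values
  m[is.na(m)] <- na_value
  hdr <- c(sprintf("ncols %d", nrow(m)),
           sprintf("nrows %d", ncol(m)),
           sprintf("xllcorner %.6f", raster$origin[1L]),
           sprintf("yllcorner %.6f", raster$origin[2L]),
           sprintf("cellsize %.6f", raster$cell_size),
           sprintf("NODATA_value %s", format(na_value)))
  rows <- apply(m[, rev(seq_len(ncol(m))), drop = FALSE], 2L,
                function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
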