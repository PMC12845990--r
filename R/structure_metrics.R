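#' Occupancy set of a voxel grid
#'
#' The set of voxel index triplets with at least one point, the basic object
#' of the coverage-gap analysis. Indices are 1-based on the grid's lattice.
#'
#' @param grid a \code{voxel_grid}.
#' @return An object of class \code{occupancy_set}: list with an integer
#'   matrix \code{ijk} (one row per occupied voxel, columns i, j, k) and the
#'   lattice descriptors \code{origin}, \code{voxel_size}, \code{dims}.
#' @export
occupancy_set <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- which(grid$counts >= 1L, arr.ind = TRUE)
  colnames(occ) <- c("i", "j", "k")
  structure(list(ijk = occ, origin = grid$origin,
                 voxel_size = grid$voxel_size, dims = grid$dims),
            class = "occupancy_set")
}

#' @export
print.occupancy_set <- function(x, ...) {
  cat(sprintf("Occupancy set: %d voxels on a %d x %d x %d lattice (%.2g m)\n",
              nrow(x$ijk), x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_size))
  invisible(x)
}

#' Union of occupancy sets on a shared lattice
#' @param sets list of \code{occupancy_set} objects on the same lattice.
#' @return The union as an \code{occupancy_set}.
#' @export
union_occupancy <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "occupancy_set")))
  ref <- sets[[1L]]
  for (s in sets[-1L]) check_same_lattice(ref, s)
  keys <- unique(unlist(lapply(sets, function(s) occ_keys(s))))
  structure(list(ijk = keys_to_ijk(keys, ref$dims), origin = ref$origin,
                 voxel_size = ref$voxel_size, dims = ref$dims),
            class = "occupancy_set")
}

occ_keys <- function(set) {
  ijk <- set$ijk
  (ijk[, 1L] - 1L) + set$dims[1L] *
    ((ijk[, 2L] - 1L) + set$dims[2L] * (ijk[, 3L] - 1L))
}

keys_to_ijk <- function(keys, dims) {
  keys <- sort(keys)
  i <- keys %% dims[1L]
  rest <- keys %/% dims[1L]
  out <- cbind(i = i + 1L, j = rest %% dims[2L] + 1L,
               k = rest %/% dims[2L] + 1L)
  storage.mode(out) <- "integer"
  out
}

check_same_lattice <- function(a, b) {
  if (!identical(a$dims, b$dims) ||
      !isTRUE(all.equal(a$origin, b$origin)) ||
      !isTRUE(all.equal(a$voxel_size, b$voxel_size))) {
    stop("occupancy sets are not on the same lattice")
  }
  invisible(TRUE)
}

#' Coverage gap ratio profile
#'
#' For each vertical bin z, the coverage gap ratio is the fraction of
#' reference-occupied voxels at that height that are absent from the
#' evaluated dataset:
#' \deqn{CGR_z = |\{v \in V_{All,z} : v \notin V_c\}| / |V_{All,z}|}
#' where \eqn{V_{All}} is the reference occupancy set (typically the merge of
#' all datasets) and \eqn{V_c} the evaluated one. CGR is a relative occlusion
#' measure: 0 means the dataset covers every reference voxel in the bin, 1
#' that it covers none. Bins with an empty reference are reported as NA,
#' never as 0.
#'
#' A voxel's bin is determined by its center height above the lattice origin
#' z0; with 0.5 m bins and 0.5 m voxels each bin is exactly one voxel layer.
#'
#' @param v_all reference \code{occupancy_set} (the all-merged model, or an
#'   external ground-truth set).
#' @param v_c evaluated \code{occupancy_set}; must be on the same lattice.
#' @param bin_height vertical bin height in meters (default 0.5).
#' @return A data.frame of class \code{cgr_profile} with columns
#'   \code{bin_lo}, \code{bin_hi} (m above z0), \code{cgr},
#'   \code{n_reference_voxels}, \code{n_missing}, ordered bottom-up.
#' @export
coverage_gap_ratio <- function(v_all, v_c, bin_height = 0.5) {
  stopifnot(inherits(v_all, "occupancy_set"), bin_height > 0)
  if (!inherits(v_c, "occupancy_set")) {
    stop("'v_c' must be an occupancy_set on the same lattice")
  }
  check_same_lattice(v_all, v_c)
  s <- v_all$voxel_size
  nz <- v_all$dims[3L]
  bin_of_k <- floor(((seq_len(nz) - 0.5) * s) / bin_height)  # 0-based
  nbin <- max(bin_of_k) + 1L
  ref_keys <- occ_keys(v_all)
  missing <- !(ref_keys %in% occ_keys(v_c))
  ref_bin <- bin_of_k[v_all$ijk[, 3L]]
  n_ref <- tabulate(ref_bin + 1L, nbins = nbin)
  n_miss <- tabulate(ref_bin[missing] + 1L, nbins = nbin)
  cgr <- ifelse(n_ref > 0L, n_miss / n_ref, NA_real_)
  out <- data.frame(bin_lo = (0:(nbin - 1L)) * bin_height,
                    bin_hi = (1:nbin) * bin_height,
                    cgr = cgr,
                    n_reference_voxels = n_ref,
                    n_missing = n_miss)
  class(out) <- c("cgr_profile", "data.frame")
  out
}

#' Mean CGR over a height interval
#'
#' Convenience summary of a CGR profile: the mean of defined per-bin ratios
#' whose bin midpoint falls in \code{[lo, hi)}.
#'
#' @param profile a \code{cgr_profile}.
#' @param lo,hi height bounds in meters above the lattice origin z.
#' @return Mean CGR (NA when no defined bin falls in the interval).
#' @export
cgr_band_mean <- function(profile, lo, hi) {
  mid <- (profile$bin_lo + profile$bin_hi) / 2
  sel <- mid >= lo & mid < hi & !is.na(profile$cgr)
  if (!any(sel)) return(NA_real_)
  mean(profile$cgr[sel])
}

#' Export a CGR profile as CSV
#' @param profile a \code{cgr_profile}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_cgr_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
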