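#' Observed coarse reflectance raster
#'
#' Container for the satellite observation the simulation is calibrated
#' against: a single-band coarse reflectance grid (e.g. 10 m NIR
#' top-of-atmosphere reflectance) plus a logical validity mask used for
#' pixel screening (e.g. exclusion of non-target species). The raster is
#' assumed co-registered with the fine simulation grid: its origin is the
#' lower-left corner of the fine map.
#'
#' @param values numeric matrix of reflectance (nx by ny, x index in rows).
#' @param origin \code{c(x0, y0)} of the lower-left corner (m).
#' @param cell_size pixel size in meters (default 10).
#' @param mask optional logical matrix congruent with \code{values};
#'   default: all finite pixels are valid.
#' @return An object of class \code{observed_raster}.
#' @export
observed_raster <- function(values, origin = c(0, 0), cell_size = 10,
                            mask = NULL) {
  stopifnot(is.matrix(values), cell_size > 0)
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  mask <- mask & is.finite(values)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = cell_size, mask = mask),
            class = "observed_raster")
}

#' @export
print.observed_raster <- function(x, ...) {
  cat(sprintf("Observed raster: %d x %d pixels of %g m, %d masked-in\n",
              nrow(x$values), ncol(x$values), x$cell_size, sum(x$mask)))
  invisible(x)
}

#' Read an observed raster from an ESRI ASCII grid (.asc)
#' @param path path to the .asc file.
#' @param mask optional logical matrix, or path to a CSV of 0-based masked-in
#'   pixel indices with columns \code{i, j}.
#' @return An \code{observed_raster}.
#' @export
read_observed_asc <- function(path, mask = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  nh <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1L])))) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      nh <- nh + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[-(1:nh)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(vals) == ncols * nrows)
  # .asc rows run north to south; matrix columns run south to north
  m <- matrix(NA_real_, ncols, nrows)
  for (r in seq_len(nrows)) {
    m[, nrows - r + 1L] <- vals[((r - 1L) * ncols + 1L):(r * ncols)]
  }
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  mk <- NULL
  if (is.character(mask)) {
    idx <- utils::read.csv(mask)
    mk <- matrix(FALSE, ncols, nrows)
    mk[cbind(idx$i + 1L, idx$j + 1L)] <- TRUE
  } else if (!is.null(mask)) mk <- mask
  observed_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner),
                  cell_size = hdr$cellsize, mask = mk)
}

#' Pearson correlation between simulated and observed grids
#'
#' Standard product-moment correlation over masked-in pixel pairs, the
#' radiometric agreement metric of the whole framework. Degenerate inputs
#' (fewer than 3 pairs, or zero variance on either side) raise an error
#' rather than returning NaN.
#'
#' @param simulated numeric vector or matrix of simulated radiance.
#' @param observed numeric vector or matrix of observed reflectance,
#'   congruent with \code{simulated}.
#' @param mask optional logical vector/matrix selecting the pairs to use;
#'   default: pairs where both sides are finite.
#' @return The correlation coefficient (single number in [-1, 1]).
#' @export
pearson_r <- function(simulated, observed, mask = NULL) {
  s <- as.vector(simulated)
  o <- as.vector(observed)
  if (length(s) != length(o)) stop("'simulated' and 'observed' differ in length")
  keep <- is.finite(s) & is.finite(o)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  s <- s[keep]; o <- o[keep]
  if (length(s) < 3L) stop("fewer than 3 masked-in pixel pairs")
  if (stats::sd(s) == 0 || stats::sd(o) == 0) {
    stop("degenerate input: zero variance on one side of the correlation")
  }
  stats::cor(s, o)
}

# NA-returning variant used inside searches (a single degenerate candidate
# must not abort the whole search).
pearson_r_or_na <- function(s, o, mask) {
  keep <- is.finite(s) & is.finite(o) & mask
  s <- s[keep]; o <- o[keep]
  if (length(s) < 3L || stats::sd(s) == 0 || stats::sd(o) == 0) {
    return(list(r = NA_real_, n = length(s)))
  }
  list(r = stats::cor(s, o), n = length(s))
}

#' Shift a radiance map by whole cells
#'
#' Moves the map content by (+dx, +dy) meters (integer multiples of the cell
#' size); cells shifted in from outside the original extent are NA.
#'
#' @param map a \code{radiance_map}.
#' @param dx,dy shift in meters.
#' @return The shifted \code{radiance_map}.
#' @export
shift_map <- function(map, dx, dy) {
  stopifnot(inherits(map, "radiance_map"))
  cs <- map$cell_size
  dxc <- dx / cs
  dyc <- dy / cs
  if (abs(dxc - round(dxc)) > 1e-9 || abs(dyc - round(dyc)) > 1e-9) {
    stop("shift must be an integer multiple of the cell size")
  }
  dxc <- as.integer(round(dxc)); dyc <- as.integer(round(dyc))
  M <- map$values
  out <- matrix(NA_real_, nrow(M), ncol(M))
  src_i <- seq_len(nrow(M)) - dxc
  src_j <- seq_len(ncol(M)) - dyc
  ok_i <- src_i >= 1L & src_i <= nrow(M)
  ok_j <- src_j >= 1L & src_j <= ncol(M)
  out[ok_i, ok_j] <- M[src_i[ok_i], src_j[ok_j]]
  radiance_map(out, map$origin, cs)
}

#' Exhaustive horizontal shift search
#'
#' Shifts the fine radiance map on a square grid of offsets (accounting for
#' satellite geolocation error, typically up to +/- 3 m), aggregates each
#' shifted map to the observed pixel size, and returns the shift maximizing
#' the Pearson correlation with the observed raster. Ties are broken
#' deterministically: smallest shift magnitude first, then lexicographic
#' (dx, dy).
#'
#' @param fine_map a \code{radiance_map} at the fine (voxel) resolution.
#' @param observed an \code{observed_raster}.
#' @param max_shift maximum absolute shift in meters (default 3).
#' @param step shift step in meters; default: the fine cell size. Must be an
#'   integer multiple of the fine cell size.
#' @param mask optional logical matrix overriding \code{observed$mask}.
#' @return list with \code{dx}, \code{dy} (m), \code{r}, \code{n} (pixels
#'   used), \code{coarse} (the winning aggregated \code{radiance_map}), and
#'   \code{all} (data.frame of every evaluated shift and its r).
#' @export
shift_search <- function(fine_map, observed, max_shift = 3, step = NULL,
                         mask = NULL) {
  stopifnot(inherits(fine_map, "radiance_map"),
            inherits(observed, "observed_raster"), max_shift >= 0)
  if (is.null(step)) step <- fine_map$cell_size
  stopifnot(step > 0)
  if (is.null(mask)) mask <- observed$mask
  offsets <- shift_offsets(max_shift, step)
  res <- vector("list", nrow(offsets))
  for (q in seq_len(nrow(offsets))) {
    shifted <- shift_map(fine_map, offsets$dx[q], offsets$dy[q])
    coarse <- resample_average(shifted, observed$cell_size)
    if (!identical(dim(coarse$values), dim(observed$values))) {
      stop("aggregated map and observed raster dimensions disagree")
    }
    pr <- pearson_r_or_na(as.vector(coarse$values),
                          as.vector(observed$values), as.vector(mask))
    res[[q]] <- c(r = pr$r, n = pr$n)
  }
  tab <- cbind(offsets, do.call(rbind, res))
  if (all(is.na(tab$r))) {
    stop("degenerate correlation at every shift")
  }
  best <- which.max(tab$r)  # offsets pre-ordered by the tie-break priority
  win <- shift_map(fine_map, tab$dx[best], tab$dy[best])
  list(dx = tab$dx[best], dy = tab$dy[best], r = tab$r[best],
       n = tab$n[best],
       coarse = resample_average(win, observed$cell_size),
       all = tab)
}

# Shift grid ordered by the deterministic tie-break priority:
# smallest magnitude first, then lexicographic (dx, dy).
shift_offsets <- function(max_shift, step) {
  v <- if (max_shift == 0) 0 else seq(-max_shift, max_shift, by = step)
  g <- expand.grid(dx = v, dy = v)
  g[order(g$dx^2 + g$dy^2, g$dx, g$dy), , drop = FALSE]
}

# ---- fast correlation engine ------------------------------------------------

# Shared machinery behind vpdp() and subsample_validate(). Under strictly
# vertical light geometry every voxel's contribution to column radiance is
# (R*I/pi) * exp(-(alpha+beta) * S) with S the column count strictly above
# it, so the aggregated coarse map depends on (alpha, beta) only through
# gamma = alpha + beta. Shifted block aggregation is separable in x and y,
# so each shifted coarse map is a product of two small 0/1 aggregation
# matrices with the fine map; per-shift coarse maps are cached keyed by
# gamma so that repeated fits (e.g. the subsampling validation) do not
# recompute them.
rt_corr_engine <- function(grid, observed, max_shift = 3, step = NULL,
                           I = 1, R = 0.05, reflect_empty = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(observed, "observed_raster"))
  cs <- grid$voxel_size
  if (is.null(step)) step <- cs
  ratio <- observed$cell_size / cs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("observed pixel size must be an integer multiple of the voxel size")
  }
  ratio <- as.integer(round(ratio))
  nx <- grid$dims[1L]; ny <- grid$dims[2L]
  nxc <- as.integer(ceiling(nx / ratio)); nyc <- as.integer(ceiling(ny / ratio))
  if (!identical(c(nxc, nyc), dim(observed$values))) {
    stop("aggregated map and observed raster dimensions disagree")
  }
  idx <- if (reflect_empty) seq_along(grid$counts) else which(grid$counts >= 1L)
  S <- cumulative_above(grid)
  lin0 <- idx - 1L
  cellid <- 1L + lin0 %% nx + nx * ((lin0 %/% nx) %% ny)  # fine column id
  # sort contributing voxels by column once; per-gamma column totals then
  # come from one cumsum + diff pass instead of a grouped sum
  ord <- order(cellid)
  s_con <- S[idx][ord]
  cellid <- cellid[ord]
  bounds <- c(0L, cumsum(tabulate(cellid, nbins = nx * ny)))
  nonempty <- which(diff(bounds) > 0L)
  c0 <- R * I / pi

  offsets <- shift_offsets(max_shift, step)
  # 0/1 aggregation matrix for one axis at one shift (in cells): row c picks
  # the in-bounds fine indices whose shifted position falls in coarse cell c
  axis_agg <- function(nf, nc, sc) {
    pos <- (seq_len(nf) - 1L) + sc
    ok <- pos >= 0L & pos < nf
    W <- matrix(0, nc, nf)
    W[cbind(pos[ok] %/% ratio + 1L, which(ok))] <- 1
    W
  }
  shift_cells <- function(d) {
    scd <- d / cs
    if (abs(scd - round(scd)) > 1e-9) {
      stop("shift step must be an integer multiple of the voxel size")
    }
    as.integer(round(scd))
  }
  sxs <- sort(unique(offsets$dx)); sys <- sort(unique(offsets$dy))
  Wx <- lapply(sxs, function(d) axis_agg(nx, nxc, shift_cells(d)))
  Wy <- lapply(sys, function(d) axis_agg(ny, nyc, shift_cells(d)))
  den <- vector("list", nrow(offsets))
  qx <- match(offsets$dx, sxs); qy <- match(offsets$dy, sys)
  for (q in seq_len(nrow(offsets))) {
    den[[q]] <- outer(rowSums(Wx[[qx[q]]]), rowSums(Wy[[qy[q]]]))
  }

  cache <- new.env(parent = emptyenv())
  coarse_maps <- function(gamma) {
    key <- sprintf("%.15g", gamma)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fine <- numeric(nx * ny)
    cs_e <- cumsum(c0 * exp(-gamma * s_con))
    fine[nonempty] <- cs_e[bounds[nonempty + 1L]] -
      c(0, cs_e)[bounds[nonempty] + 1L]
    M <- matrix(fine, nx, ny)
    left <- lapply(Wx, function(W) W %*% M)   # one per distinct x shift
    maps <- vector("list", nrow(offsets))
    for (q in seq_len(nrow(offsets))) {
      num <- left[[qx[q]]] %*% t(Wy[[qy[q]]])
      d <- den[[q]]
      m <- num / d
      m[d == 0] <- NA_real_
      maps[[q]] <- as.vector(m)
    }
    cache[[key]] <- maps
    maps
  }

  obs_vec <- as.vector(observed$values)
  score <- function(alpha, beta, mask = observed$mask) {
    maps <- coarse_maps(alpha + beta)
    mk <- as.vector(mask)
    best <- NULL
    for (q in seq_along(maps)) {
      pr <- pearson_r_or_na(maps[[q]], obs_vec, mk)
      if (!is.na(pr$r) && (is.null(best) || pr$r > best$r)) {
        best <- list(r = pr$r, n = pr$n, dx = offsets$dx[q],
                     dy = offsets$dy[q], q = q)
      }
    }
    if (is.null(best)) return(NULL)  # degenerate everywhere for this gamma
    best
  }

  coarse_at <- function(alpha, beta, q) {
    matrix(coarse_maps(alpha + beta)[[q]], nxc, nyc)
  }

  list(score = score, coarse_at = coarse_at, offsets = offsets,
       dims_coarse = c(nxc, nyc))
}

# ---- the model fit ----------------------------------------------------------

#' Calibrate the point-density-proxy radiative transfer model
#'
#' Fits the two empirical attenuation coefficients (alpha for the incident
#' path, beta for the reflected path, both per point) of the Beer-Lambert
#' point-density-proxy model by maximizing the Pearson correlation between
#' the simulated column radiance — aggregated to the observed pixel size —
#' and an observed reflectance raster. Each candidate parameter pair is
#' scored at its best horizontal shift (see \code{\link{shift_search}});
#' the optimizer is a deterministic two-stage log-spaced grid search whose
#' objective never worsens between refinement passes.
#'
#' Under the model's strictly vertical (nadir) light geometry the simulated
#' map depends on alpha and beta only through their sum, so the objective
#' has a flat ridge along constant alpha + beta; ties are resolved
#' deterministically toward the smallest alpha + beta, then the smallest
#' alpha. The fitted sum is the physically identified quantity.
#'
#' @param grid a \code{voxel_grid} of the point cloud under evaluation.
#' @param observed an \code{observed_raster} (coarse reflectance + mask).
#' @param range search range for both coefficients, per point (default
#'   \code{c(1e-4, 1)}).
#' @param coarse_n points per axis of the first log-spaced grid (default 17).
#' @param refine_n points per axis of each refinement grid (default 9).
#' @param refine_passes number of refinement passes (default 1).
#' @param max_shift maximum horizontal shift in meters (default 3).
#' @param shift_step shift step in meters (default: the voxel size).
#' @param I incident irradiance (default 1).
#' @param R leaf reflectance (default 0.05).
#' @param reflect_empty include empty voxels as reflectors (default FALSE).
#' @param mask optional logical matrix overriding \code{observed$mask}.
#' @param engine internal: a prebuilt correlation engine (reused by
#'   \code{\link{subsample_validate}}).
#' @return An object of class \code{vpdp}: list with fitted \code{alpha},
#'   \code{beta}, \code{gamma} (their sum), \code{shift} (c(dx, dy), m),
#'   \code{r}, \code{n} (pixels used), \code{params} (\code{rt_params}),
#'   \code{coarse} (fitted aggregated map, matrix), \code{observed},
#'   \code{trace} (per-stage incumbents), and the \code{call}.
#' @seealso \code{\link{subsample_validate}}, \code{\link{column_radiance}}
#' @export
vpdp <- function(grid, observed, range = c(1e-4, 1), coarse_n = 17L,
                 refine_n = 9L, refine_passes = 1L, max_shift = 3,
                 shift_step = NULL, I = 1, R = 0.05, reflect_empty = FALSE,
                 mask = NULL, engine = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(observed, "observed_raster"),
            range[1L] > 0, range[2L] > range[1L], coarse_n >= 2L)
  if (sum(grid$counts) == 0L) stop("voxel grid is empty: nothing to calibrate")
  if (is.null(mask)) mask <- observed$mask
  if (is.null(engine)) {
    engine <- rt_corr_engine(grid, observed, max_shift = max_shift,
                             step = shift_step, I = I, R = R,
                             reflect_empty = reflect_empty)
  }
  axis <- exp(seq(log(range[1L]), log(range[2L]), length.out = coarse_n))
  best <- NULL
  trace <- list()
  evaluate_grid <- function(ax_a, ax_b, incumbent) {
    for (a in ax_a) for (b in ax_b) {
      sc <- engine$score(a, b, mask)
      if (is.null(sc)) next
      better <- is.null(incumbent) ||
        sc$r > incumbent$r + 1e-15 ||
        (abs(sc$r - incumbent$r) <= 1e-15 &&
           (a + b < incumbent$alpha + incumbent$beta - 1e-15 ||
              (abs(a + b - (incumbent$alpha + incumbent$beta)) <= 1e-15 &&
                 a < incumbent$alpha)))
      if (better) {
        incumbent <- c(sc, list(alpha = a, beta = b))
      }
    }
    incumbent
  }
  best <- evaluate_grid(axis, axis, NULL)
  if (is.null(best)) stop("correlation objective undefined everywhere")
  trace$coarse <- best
  span <- axis[2L] / axis[1L]  # multiplicative spacing of the coarse grid
  for (p in seq_len(refine_passes)) {
    ref_axis <- function(center) {
      lo <- max(range[1L], center / span)
      hi <- min(range[2L], center * span)
      exp(seq(log(lo), log(hi), length.out = refine_n))
    }
    best <- evaluate_grid(ref_axis(best$alpha), ref_axis(best$beta), best)
    trace[[paste0("refine", p)]] <- best
    span <- span^(2 / (refine_n - 1))  # shrink for a further pass
  }
  structure(list(alpha = best$alpha, beta = best$beta,
                 gamma = best$alpha + best$beta,
                 shift = c(dx = best$dx, dy = best$dy),
                 r = best$r, n = best$n,
                 params = rt_params(best$alpha, best$beta, I = I, R = R),
                 coarse = engine$coarse_at(best$alpha, best$beta, best$q),
                 observed = observed, mask = mask,
                 reflect_empty = reflect_empty,
                 grid = grid, trace = trace, call = match.call()),
            class = "vpdp")
}

#' @export
print.vpdp <- function(x, ...) {
  cat("Point-density-proxy RT calibration\n")
  cat(sprintf("  alpha = %.5g, beta = %.5g per point (alpha + beta = %.5g)\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  shift = (%+.1f, %+.1f) m;  Pearson r = %.4f  (n = %d pixels)\n",
              x$shift[1L], x$shift[2L], x$r, x$n))
  invisible(x)
}

#' @export
summary.vpdp <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(fit = object,
                 resid_summary = summary(res),
                 r_squared = object$r^2),
            class = "summary.vpdp")
}

#' @export
print.summary.vpdp <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  r^2 = %.4f\n", x$r_squared))
  cat("  residuals of observed ~ simulated (masked-in pixels):\n")
  print(x$resid_summary)
  invisible(x)
}

#' @export
coef.vpdp <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Simulated coarse radiance from a fitted calibration
#'
#' Returns the fitted aggregated radiance map, or re-runs the forward model
#' with the fitted coefficients on a new voxel grid.
#'
#' @param object a \code{vpdp} fit.
#' @param newgrid optional \code{voxel_grid}; default: the training grid's
#'   fitted coarse map (at the fitted shift).
#' @param ... unused.
#' @return A numeric matrix of coarse simulated radiance.
#' @export
predict.vpdp <- function(object, newgrid = NULL, ...) {
  if (is.null(newgrid)) return(object$coarse)
  fine <- column_radiance(newgrid, object$params,
                          reflect_empty = object$reflect_empty)
  shifted <- shift_map(fine, object$shift[1L], object$shift[2L])
  resample_average(shifted, object$observed$cell_size)$values
}

#' @export
fitted.vpdp <- function(object, ...) {
  object$coarse[object$mask]
}

#' Residuals of the calibrated radiance-reflectance relation
#'
#' The model is calibrated through correlation, so its radiometric scale is
#' arbitrary; residuals are therefore taken from the least-squares affine
#' map of simulated radiance onto observed reflectance over the masked-in
#' pixels.
#'
#' @param object a \code{vpdp} fit.
#' @param ... unused.
#' @return Numeric vector of residuals (observed units), one per masked-in
#'   pixel.
#' @export
residuals.vpdp <- function(object, ...) {
  s <- object$coarse[object$mask]
  o <- object$observed$values[object$mask]
  ok <- is.finite(s) & is.finite(o)
  stats::residuals(stats::lm(o[ok] ~ s[ok]))
}

#' Scatter diagnostic of a calibration
#'
#' Simulated coarse radiance against observed reflectance over masked-in
#' pixels, with the least-squares line.
#'
#' @param x a \code{vpdp} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.vpdp <- function(x, ...) {
  s <- x$coarse[x$mask]
  o <- x$observed$values[x$mask]
  graphics::plot(s, o, xlab = "simulated radiance",
                 ylab = "observed reflectance",
                 main = sprintf("r = %.3f (n = %d)", x$r, x$n), ...)
  ok <- is.finite(s) & is.finite(o)
  graphics::abline(stats::lm(o[ok] ~ s[ok]), col = "red3")
  invisible(x)
}

# ---- subsampling validation -------------------------------------------------

#' Repeated calibration/validation split of the pixel set
#'
#' Guards against overfitting of the two calibrated coefficients: the
#' masked-in pixels are repeatedly split into a calibration subset (default
#' 70\%) and a held-out validation subset (30\%); the coefficients and the
#' shift are fitted on the calibration subset only and the Pearson
#' correlation is then evaluated on the held-out pixels. The split is
#' stratified by observed-reflectance quartiles by default so both subsets
#' span the radiometric range; plain random splitting is available.
#'
#' @param grid a \code{voxel_grid}.
#' @param observed an \code{observed_raster}.
#' @param calib_fraction fraction of pixels used for calibration, in (0, 1)
#'   (default 0.7).
#' @param n_iter number of random splits (default 20).
#' @param base_seed integer seed; iteration i uses seed \code{base_seed + i},
#'   making the whole summary reproducible.
#' @param strata \code{"quartile"} (default) or \code{"none"}.
#' @param ... further arguments passed to \code{\link{vpdp}} (search ranges,
#'   shift limits, I, R, ...).
#' @return An object of class \code{validation_summary}: list with
#'   \code{iterations} (data.frame: iteration, seed, r_calib, r_holdout,
#'   n_calib, n_holdout, alpha, beta, dx, dy), \code{mean_r}, \code{sd_r}
#'   (NA when \code{n_iter} = 1), \code{n_iter}, \code{calib_fraction}.
#' @export
subsample_validate <- function(grid, observed, calib_fraction = 0.7,
                               n_iter = 20L, base_seed = 1L,
                               strata = c("quartile", "none"), ...) {
  stopifnot(calib_fraction > 0, calib_fraction < 1, n_iter >= 1L)
  strata <- match.arg(strata)
  pix <- which(observed$mask)
  n_calib <- round(length(pix) * calib_fraction)
  if (n_calib < 3L || length(pix) - n_calib < 3L) {
    stop("too few masked-in pixels to split with >= 3 per side")
  }
  dots <- list(...)
  engine <- rt_corr_engine(grid, observed,
                           max_shift = dots$max_shift %||% 3,
                           step = dots$shift_step,
                           I = dots$I %||% 1, R = dots$R %||% 0.05,
                           reflect_empty = isTRUE(dots$reflect_empty))
  strat_id <- if (strata == "quartile") {
    cut(rank(observed$values[pix], ties.method = "first"),
        breaks = 4L, labels = FALSE)
  } else rep(1L, length(pix))
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    seed <- base_seed + it
    calib_idx <- local({
      set.seed(seed)
      unlist(lapply(split(seq_along(pix), strat_id), function(g) {
        take <- round(length(g) * calib_fraction)
        if (take == 0L && length(g) > 0L) take <- 1L
        sample(g, take)
      }), use.names = FALSE)
    })
    calib_mask <- matrix(FALSE, nrow(observed$values), ncol(observed$values))
    calib_mask[pix[calib_idx]] <- TRUE
    holdout_mask <- observed$mask & !calib_mask
    fit <- vpdp(grid, observed, mask = calib_mask, engine = engine, ...)
    coarse <- engine$coarse_at(fit$alpha, fit$beta,
                               which(engine$offsets$dx == fit$shift[1L] &
                                       engine$offsets$dy == fit$shift[2L]))
    pr <- pearson_r_or_na(as.vector(coarse), as.vector(observed$values),
                          as.vector(holdout_mask))
    rows[[it]] <- data.frame(iteration = it, seed = seed,
                             r_calib = fit$r, r_holdout = pr$r,
                             n_calib = fit$n, n_holdout = pr$n,
                             alpha = fit$alpha, beta = fit$beta,
                             dx = fit$shift[1L], dy = fit$shift[2L])
  }
  iters <- do.call(rbind, rows)
  structure(list(iterations = iters,
                 mean_r = mean(iters$r_holdout, na.rm = TRUE),
                 sd_r = if (n_iter > 1L) stats::sd(iters$r_holdout) else NA_real_,
                 n_iter = n_iter, calib_fraction = calib_fraction,
                 base_seed = base_seed, strata = strata),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Subsampling validation: %d iterations, %.0f%%/%.0f%% split (%s strata)\n",
              x$n_iter, 100 * x$calib_fraction, 100 * (1 - x$calib_fraction),
              x$strata))
  cat(sprintf("  held-out Pearson r: mean = %.4f, sd = %s\n",
              x$mean_r,
              if (is.na(x$sd_r)) "NA" else sprintf("%.4f", x$sd_r)))
  invisible(x)
}

#' Export a calibration result as JSON
#' @param fit a \code{vpdp} fit.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_calibration_json <- function(fit, path) {
  stopifnot(inherits(fit, "vpdp"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON export")
  }
  jsonlite::write_json(
    list(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
         shift_dx = unname(fit$shift[1L]), shift_dy = unname(fit$shift[2L]),
         pearson_r = fit$r, n_pixels = fit$n,
         I = fit$params$I, R = fit$params$R),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export per-iteration validation correlations as CSV
#' @param summary a \code{validation_summary}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_validation_csv <- function(summary, path) {
  stopifnot(inherits(summary, "validation_summary"))
  utils::write.csv(summary$iterations, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
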