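# Per-scale predictor stacks: circular focal means of the morphometrics plus
# Euclidean distance-to-shoreline / distance-to-shelf-edge surfaces.

#' Scale configuration for multi-scale focal statistics
#'
#' @param radii_m ordered vector of focal radii in meters (default the five
#'   scales 5, 25, 50, 100, 300).
#' @param min_valid_fraction minimum fraction of kernel cells that must hold
#'   valid data for a focal mean to be reported (default 0.5); guards against
#'   means dominated by a handful of edge cells at large radii.
#' @return A list of class `scale_config`.
#' @export
scale_config <- function(radii_m = c(5, 25, 50, 100, 300),
                         min_valid_fraction = 0.5) {
  if (any(radii_m <= 0) || is.unsorted(radii_m, strictly = TRUE))
    stop("radii must be positive and strictly increasing")
  if (min_valid_fraction <= 0 || min_valid_fraction > 1)
    stop("min_valid_fraction must be in (0, 1]")
  structure(list(radii_m = radii_m, min_valid_fraction = min_valid_fraction),
            class = "scale_config")
}

#' Circular focal-window footprint
#'
#' Binary kernel matrix whose TRUE cells are those whose center lies within
#' `radius_m` of the focal cell center. Symmetric under quarter-turn rotation
#' and reflection; a radius below the cell spacing degenerates to the single
#' focal cell.
#'
#' @param radius_m window radius in meters.
#' @param cell_size_m cell edge length in meters.
#' @return A logical matrix of odd dimensions with the focal cell at the
#'   center.
#' @examples
#' circular_kernel(5, 4)   # the 5-cell plus shape
#' @export
circular_kernel <- function(radius_m, cell_size_m) {
  if (radius_m <= 0 || cell_size_m <= 0)
    stop("radius and cell size must be positive")
  r <- floor(radius_m / cell_size_m)
  off <- (-r):r
  d2 <- outer(off, off, function(i, j) (i * cell_size_m)^2 + (j * cell_size_m)^2)
  d2 <= radius_m^2
}

# centered FFT convolution of `mat` with kernel `k` (both numeric); returns a
# matrix of the same size as `mat`. Kernel dims must be odd.
fft_convolve_num <- function(mat, k) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- nrow(k); kc <- ncol(k)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  A <- matrix(0, pr, pc); A[1:nr, 1:nc] <- mat
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- k
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  conv[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

#' Nodata-aware circular focal mean
#'
#' Mean of the kernel neighbourhood around every cell, ignoring nodata.
#' The output is nodata where the focal cell itself is nodata or where fewer
#' than `min_valid_fraction` of the kernel cells hold valid data (kernel
#' cells beyond the grid edge count as invalid).
#'
#' @param raster a [raster_grid].
#' @param kernel logical footprint matrix from [circular_kernel()].
#' @param min_valid_fraction minimum valid fraction of the kernel (default
#'   0.5).
#' @return A [raster_grid] of focal means.
#' @export
focal_mean <- function(raster, kernel, min_valid_fraction = 0.5) {
  stopifnot(inherits(raster, "raster_grid"))
  if (!is.matrix(kernel) || !any(kernel)) stop("kernel is empty")
  v <- raster$values
  valid <- !is.na(v)
  v0 <- v; v0[!valid] <- 0
  k <- kernel * 1
  sums <- fft_convolve_num(v0, k)
  cnts <- round(fft_convolve_num(valid * 1, k))
  out <- sums / cnts
  frac <- cnts / sum(kernel)
  out[frac < min_valid_fraction | cnts == 0] <- NA_real_
  out[!valid] <- NA_real_
  grid_like(raster, out)
}

#' Circular (vector) focal mean for aspect
#'
#' Aspect is a directional quantity; its focal mean is taken by averaging
#' unit vectors and converting the resultant back to a bearing, so that e.g.
#' 350 and 10 degrees average to 0, not 180. Cells whose neighbourhood has no
#' preferred direction (resultant length below 1e-6) are nodata.
#'
#' @param aspect a [raster_grid] of bearings in degrees `[0, 360)`.
#' @inheritParams focal_mean
#' @return A [raster_grid] of mean bearings in degrees `[0, 360)`.
#' @export
focal_mean_aspect <- function(aspect, kernel, min_valid_fraction = 0.5) {
  stopifnot(inherits(aspect, "raster_grid"))
  if (!is.matrix(kernel) || !any(kernel)) stop("kernel is empty")
  a <- aspect$values * pi / 180
  valid <- !is.na(a)
  s <- sin(a); s[!valid] <- 0
  co <- cos(a); co[!valid] <- 0
  k <- kernel * 1
  ms <- fft_convolve_num(s, k)
  mc <- fft_convolve_num(co, k)
  cnts <- round(fft_convolve_num(valid * 1, k))
  resultant <- sqrt(ms^2 + mc^2) / pmax(cnts, 1)
  out <- (atan2(ms, mc) * 180 / pi) %% 360
  frac <- cnts / sum(kernel)
  out[frac < min_valid_fraction | cnts == 0] <- NA_real_
  out[resultant < 1e-6] <- NA_real_
  out[!valid] <- NA_real_
  grid_like(aspect, out)
}

#' Euclidean distance surface from a binary mask
#'
#' Per-cell straight-line distance (meters, center to center) to the nearest
#' mask cell, computed with an exact two-pass distance transform; 0 inside
#' the mask.
#'
#' @param mask a [raster_grid] whose nonzero, non-nodata cells form the mask.
#' @return A [raster_grid] of distances in meters.
#' @export
distance_surface <- function(mask) {
  stopifnot(inherits(mask, "raster_grid"))
  m <- !is.na(mask$values) & mask$values != 0
  if (!any(m)) stop("mask is empty")
  d2 <- cpp_edt_sq(m)
  grid_like(mask, sqrt(d2) * mask$cell_size_m)
}

#' Per-scale predictor stack
#'
#' Focal means of the six morphometrics at one radius plus the two
#' scale-independent distance surfaces, all aligned. Layer names are fixed:
#' `depth`, `slope`, `aspect`, `slope_of_slope`, `plan_curvature`,
#' `rugosity`, `dist_to_shore`, `dist_to_shelf`.
#'
#' @param morph a `morphometric_set` from [compute_morphometrics()].
#' @param masks list with elements `shoreline` and `shelf` (binary
#'   [raster_grid]s), as returned by [make_masks()]. Ignored when `distances`
#'   is supplied.
#' @param radius_m focal radius in meters for this stack.
#' @param config a [scale_config()] (supplies `min_valid_fraction`).
#' @param distances optional precomputed list with `dist_to_shore` and
#'   `dist_to_shelf` [raster_grid]s, to avoid recomputing distance
#'   transforms for every radius.
#' @return An object of class `predictor_stack`: `scale_m` plus a named list
#'   `layers` of eight aligned [raster_grid]s.
#' @export
build_stack <- function(morph, masks = NULL, radius_m, config = scale_config(),
                        distances = NULL) {
  stopifnot(inherits(morph, "morphometric_set"))
  if (is.null(distances)) {
    if (is.null(masks)) stop("either `masks` or `distances` must be supplied")
    distances <- list(dist_to_shore = distance_surface(masks$shoreline),
                      dist_to_shelf = distance_surface(masks$shelf))
  }
  check_aligned(c(unclass(morph), distances))
  k <- circular_kernel(radius_m, morph$depth$cell_size_m)
  mvf <- config$min_valid_fraction
  layers <- list(
    depth = focal_mean(morph$depth, k, mvf),
    slope = focal_mean(morph$slope, k, mvf),
    aspect = focal_mean_aspect(morph$aspect, k, mvf),
    slope_of_slope = focal_mean(morph$slope_of_slope, k, mvf),
    plan_curvature = focal_mean(morph$plan_curvature, k, mvf),
    rugosity = focal_mean(morph$rugosity, k, mvf),
    dist_to_shore = distances$dist_to_shore,
    dist_to_shelf = distances$dist_to_shelf
  )
  structure(list(scale_m = radius_m, layers = layers),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> radius %g m, %d layers: %s\n", x$scale_m,
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Predictor stacks for several radii
#'
#' Convenience wrapper around [build_stack()] computing the distance
#' transforms once and the focal means per radius.
#'
#' @inheritParams build_stack
#' @param config a [scale_config()]; its `radii_m` are the stack radii.
#' @return A named list of `predictor_stack`s (names `"r<radius>"`).
#' @export
build_stacks <- function(morph, masks, config = scale_config()) {
  distances <- list(dist_to_shore = distance_surface(masks$shoreline),
                    dist_to_shelf = distance_surface(masks$shelf))
  out <- lapply(config$radii_m, function(r)
    build_stack(morph, radius_m = r, config = config, distances = distances))
  names(out) <- paste0("r", config$radii_m)
  out
}

#' Extract predictor values at survey points
#'
#' Nearest-cell (not interpolated) lookup of every stack layer at each site;
#' survey transects exceed the cell size, so sub-cell interpolation would add
#' false precision. Sites whose cell is nodata in any layer are dropped, with
#' the count recorded in the `n_excluded` attribute.
#'
#' @param stack a `predictor_stack`.
#' @param sites data frame with at least `x` and `y` columns (map meters).
#' @return Numeric matrix, one row per retained site and one column per
#'   layer; attributes `n_excluded` (dropped sites) and `kept` (logical
#'   vector over input rows).
#' @export
extract_features <- function(stack, sites) {
  stopifnot(inherits(stack, "predictor_stack"))
  ref <- stack$layers[[1]]
  rc <- xy_to_rowcol(ref, sites$x, sites$y)
  if (anyNA(rc)) {
    bad <- which(is.na(rc[, 1]) | is.na(rc[, 2]))
    stop("site(s) outside raster extent: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  idx <- cbind(rc[, "row"], rc[, "col"])
  X <- vapply(stack$layers, function(g) g$values[idx], numeric(nrow(sites)))
  if (nrow(sites) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  kept <- stats::complete.cases(X)
  out <- X[kept, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!kept)
  attr(out, "kept") <- kept
  out
}
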