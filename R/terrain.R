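# 3x3 neighbourhood operators for benthic terrain analysis.
#
# All operators share the border/nodata policy: a cell whose full 3x3 support
# contains any nodata (or lies on the grid border) yields nodata. Slope and
# aspect use Horn's weighted finite differences, the de facto GIS standard;
# rugosity uses the triangulated surface-area method (Jenness); planar
# curvature comes from a quadratic surface fit.

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# the 8 compass neighbours of every cell (N = row above = larger y)
neigh3 <- function(m) {
  list(
    N  = shift_mat(m, -1,  0), S  = shift_mat(m,  1,  0),
    E  = shift_mat(m,  0,  1), W  = shift_mat(m,  0, -1),
    NE = shift_mat(m, -1,  1), NW = shift_mat(m, -1, -1),
    SE = shift_mat(m,  1,  1), SW = shift_mat(m,  1, -1)
  )
}

check_terrain_input <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  if (nrow(grid$values) < 3 || ncol(grid$values) < 3)
    stop("grid must be at least 3x3 cells")
  if (all(is.na(grid$values)))
    stop("grid contains no valid cells")
  invisible(TRUE)
}

# Horn gradient: list(gx = eastward, gn = northward slope components)
horn_gradient <- function(grid) {
  z <- neigh3(grid$values)
  c8 <- 8 * grid$cell_size_m
  gx <- ((z$NE + 2 * z$E + z$SE) - (z$NW + 2 * z$W + z$SW)) / c8
  gn <- ((z$NW + 2 * z$N + z$NE) - (z$SW + 2 * z$S + z$SE)) / c8
  # Horn weights omit the center, but the nodata policy covers the full 3x3
  gx[is.na(grid$values)] <- NA_real_
  gn[is.na(grid$values)] <- NA_real_
  list(gx = gx, gn = gn)
}

#' Terrain slope from a raster surface
#'
#' Per-cell slope in degrees via Horn's 3x3 weighted finite differences:
#' the arctangent of the gradient magnitude of the cell's value field.
#'
#' @param grid a [raster_grid] (values treated as a height field).
#' @return A [raster_grid] of slope in degrees (0--90); border and
#'   nodata-adjacent cells are nodata.
#' @export
compute_slope <- function(grid) {
  check_terrain_input(grid)
  g <- horn_gradient(grid)
  grid_like(grid, atan(sqrt(g$gx^2 + g$gn^2)) * 180 / pi)
}

#' Terrain aspect from a raster surface
#'
#' Downslope direction in degrees clockwise from grid north. Cells with zero
#' gradient (flat) have no defined aspect and are nodata.
#'
#' @inheritParams compute_slope
#' @return A [raster_grid] of aspect in degrees `[0, 360)`.
#' @export
compute_aspect <- function(grid) {
  check_terrain_input(grid)
  g <- horn_gradient(grid)
  east <- -g$gx; north <- -g$gn
  asp <- (atan2(east, north) * 180 / pi) %% 360
  asp[!is.na(g$gx) & g$gx == 0 & g$gn == 0] <- NA_real_
  grid_like(grid, asp)
}

#' Surface rugosity (surface-area to planar-area ratio)
#'
#' Triangulated-facet rugosity over the 3x3 neighbourhood: the center and the
#' eight half-way edge points to its neighbours define eight 3-D triangles
#' whose total area is divided by the planar cell area. Flat terrain gives
#' exactly 1; an inclined plane of slope theta gives exactly `1/cos(theta)`.
#'
#' @inheritParams compute_slope
#' @return A [raster_grid] of rugosity (>= 1 where defined).
#' @export
compute_rugosity <- function(grid) {
  check_terrain_input(grid)
  z0 <- grid$values
  cs <- grid$cell_size_m
  z <- neigh3(z0)
  # cyclic neighbour order with (dx east, dy north) offsets in cell units
  ord <- list(
    N = c(0, 1), NE = c(1, 1), E = c(1, 0), SE = c(1, -1),
    S = c(0, -1), SW = c(-1, -1), W = c(-1, 0), NW = c(-1, 1)
  )
  total <- 0
  for (k in seq_along(ord)) {
    a <- ord[[k]]; b <- ord[[(k %% 8) + 1]]
    za <- z[[names(ord)[k]]]; zb <- z[[names(ord)[(k %% 8) + 1]]]
    # edge points relative to the center: u, v
    ux <- a[1] * cs / 2; uy <- a[2] * cs / 2; uz <- (za - z0) / 2
    vx <- b[1] * cs / 2; vy <- b[2] * cs / 2; vz <- (zb - z0) / 2
    cx <- uy * vz - uz * vy
    cy <- uz * vx - ux * vz
    cz <- ux * vy - uy * vx
    total <- total + 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  grid_like(grid, total / cs^2)
}

#' Slope of the slope (topographic complexity)
#'
#' The slope operator applied to the slope raster, with slope-in-degrees
#' treated as the height field: a second-derivative measure of terrain
#' complexity. Carries a two-cell nodata border.
#'
#' @inheritParams compute_slope
#' @return A [raster_grid] of slope-of-slope in degrees.
#' @export
compute_slope_of_slope <- function(grid) {
  compute_slope(compute_slope(grid))
}

#' Planar (plan) curvature
#'
#' Curvature of the surface in the direction tangential to the contour lines,
#' from a 3x3 quadratic surface fit. Sign convention: negative values are
#' convex forms (ridges, bumps), positive values are concave forms (channels,
#' bowls). Cells with zero gradient have no contour direction and are
#' assigned 0.
#'
#' @inheritParams compute_slope
#' @return A [raster_grid] of signed plan curvature (1/m).
#' @export
compute_plan_curvature <- function(grid) {
  check_terrain_input(grid)
  z0 <- grid$values
  cs <- grid$cell_size_m
  z <- neigh3(z0)
  gx <- (z$E - z$W) / (2 * cs)
  gn <- (z$N - z$S) / (2 * cs)
  fxx <- (z$E - 2 * z0 + z$W) / cs^2
  fnn <- (z$N - 2 * z0 + z$S) / cs^2
  fxn <- (z$NE - z$NW - z$SE + z$SW) / (4 * cs^2)
  g2 <- gx^2 + gn^2
  plan <- (fxx * gn^2 - 2 * fxn * gx * gn + fnn * gx^2) / g2
  plan[!is.na(g2) & g2 < 1e-12] <- 0
  grid_like(grid, plan)
}

#' All six terrain morphometrics of a bathymetric surface
#'
#' Computes depth (the input values passed through), slope, aspect, slope of
#' slope, plan curvature and rugosity, each as a [raster_grid] aligned to the
#' input.
#'
#' @inheritParams compute_slope
#' @return An object of class `morphometric_set`: a named list of six
#'   aligned [raster_grid]s.
#' @examples
#' b <- raster_grid(outer(1:9, 1:9, function(i, j) j * 0.5), cell_size_m = 4)
#' m <- compute_morphometrics(b)
#' names(m)
#' @export
compute_morphometrics <- function(grid) {
  check_terrain_input(grid)
  out <- list(
    depth = grid,
    slope = compute_slope(grid),
    aspect = compute_aspect(grid),
    slope_of_slope = compute_slope_of_slope(grid),
    plan_curvature = compute_plan_curvature(grid),
    rugosity = compute_rugosity(grid)
  )
  structure(out, class = "morphometric_set")
}

#' @export
print.morphometric_set <- function(x, ...) {
  cat("<morphometric_set> layers:", paste(names(x), collapse = ", "), "\n")
  d <- dim(x$depth$values)
  cat(sprintf("  %d x %d cells @ %g m\n", d[1], d[2], x$depth$cell_size_m))
  invisible(x)
}
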