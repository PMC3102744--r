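#' Georeferenced single-band raster grid
#'
#' A minimal planar raster container: a numeric matrix of cell values plus a
#' square cell size in meters and the map coordinates of the upper-left
#' corner. Rows run north to south (row 1 is the top of the map), columns run
#' west to east. Missing data are `NA`. This is the carrier for bathymetry,
#' terrain morphometrics, distance surfaces and habitat-suitability maps.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_size_m positive cell edge length in meters.
#' @param origin numeric length-2 vector `c(x0, y0)`: map coordinates of the
#'   upper-left corner of the upper-left cell.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), cell_size_m = 4)
#' dim(g)
#' @export
raster_grid <- function(values, cell_size_m, origin = c(0, nrow(values) * cell_size_m)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L || cell_size_m <= 0)
    stop("`cell_size_m` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be c(x0, y0)")
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         origin = as.numeric(origin)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells @ %g m (%g x %g m)\n",
              d[1], d[2], x$cell_size_m,
              d[2] * x$cell_size_m, d[1] * x$cell_size_m))
  cat(sprintf("  origin (UL): %g, %g   nodata: %d cells\n",
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  values: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

# x/y coordinates of cell centers, as vectors along columns / rows
grid_x <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size_m
grid_y <- function(g) g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * g$cell_size_m

# a grid with the same geometry but new values
grid_like <- function(g, values) raster_grid(values, g$cell_size_m, g$origin)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

# error unless all grids share geometry; names used in the message
check_aligned <- function(grids) {
  ref <- grids[[1]]
  nm <- names(grids)
  for (i in seq_along(grids)) {
    if (!same_geometry(ref, grids[[i]]))
      stop(sprintf("raster '%s' is not aligned with '%s'",
                   if (is.null(nm)) as.character(i) else nm[i],
                   if (is.null(nm)) "1" else nm[1]))
  }
  invisible(TRUE)
}

# map coordinates -> (row, col); NA outside the extent
xy_to_rowcol <- function(g, x, y) {
  col <- floor((x - g$origin[1]) / g$cell_size_m) + 1L
  row <- floor((g$origin[2] - y) / g$cell_size_m) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text GIS raster interchange (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values, north row first. Every desktop GIS reads
#' this format.
#'
#' @param grid a [raster_grid].
#' @param path file path to write to / read from.
#' @param digits significant digits written (default 10).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid].
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid$origin[2] - nr * grid$cell_size_m
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size_m),
    "NODATA_value -9999"
  )
  vv <- v
  vv[is.na(vv)] <- -9999
  rows <- apply(vv, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (!length(ln)) stop("missing header field: ", key)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) stop("grid body does not match header dimensions")
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, cs, origin = c(xll, yll + nr * cs))
}
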