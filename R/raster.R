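#' elkscape: dispersal-informed landscape connectivity
#'
#' @useDynLib elkscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom graphics hist
#' @importFrom stats aggregate anova as.formula binomial coef complete.cases
#'   cor dist glm lm.fit median na.omit pnorm predict pt qnorm quantile rexp
#'   rnorm runif sd setNames t.test vcov var
#' @importFrom utils head read.csv tail write.csv
"_PACKAGE"

#' Gridded raster in projected metre coordinates
#'
#' A minimal single-band raster: a numeric matrix anchored at an upper-left
#' origin, square cells, row-major with row 1 at the top. Cell centres sit at
#' `origin + (index - 0.5) * cell_size` (x increasing with column, y
#' decreasing with row). Nodata is held as `NA` internally; the `nodata`
#' sentinel is only used on disk.
#'
#' @param values numeric matrix (row 1 = northern edge).
#' @param origin length-2 numeric, (x, y) of the upper-left *corner* in
#'   projected metres.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata sentinel written to / read from disk; matching values are
#'   converted to `NA` on construction.
#' @param crs_tag opaque string describing the projection; never interpreted.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 250,
                        nodata = -9999, crs_tag = "local-metres") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(origin) != 2 || !is.numeric(origin))
    stop("`origin` must be numeric length 2")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), nodata = nodata,
                 crs_tag = crs_tag),
            class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d nodata cells, crs '%s'\n",
              rng[1], rng[2], sum(is.na(x$values)), x$crs_tag))
  invisible(x)
}

#' Replace the values of a raster, keeping its grid
#' @param grid a `raster_grid` supplying the geometry.
#' @param values matrix (same dimensions) or vector recycled column-major.
#' @return a `raster_grid`.
#' @export
raster_like <- function(grid, values) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!is.matrix(values))
    values <- matrix(values, nrow = nrow(grid$values), ncol = ncol(grid$values))
  if (!all(dim(values) == dim(grid$values)))
    stop("replacement values have wrong dimensions")
  out <- grid
  out$values <- values
  out
}

#' Cell-centre coordinates
#'
#' `raster_x`/`raster_y` return the centre coordinate of each column/row;
#' `cell_centers` returns the full grid as vectors ordered column-major
#' (matching `as.vector(values)`).
#' @param grid a `raster_grid`.
#' @return numeric vector(s); `cell_centers` returns a list with `x` and `y`.
#' @export
raster_x <- function(grid) {
  grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname raster_x
#' @export
raster_y <- function(grid) {
  grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname raster_x
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values)
  list(x = rep(raster_x(grid), each = nr),
       y = rep(raster_y(grid), times = ncol(grid$values)))
}

#' Spatial extent of a raster
#' @param grid a `raster_grid`.
#' @return named numeric `c(xmin, xmax, ymin, ymax)` of the outer edges.
#' @export
raster_extent <- function(grid) {
  d <- dim(grid$values)
  c(xmin = grid$origin[1], xmax = grid$origin[1] + d[2] * grid$cell_size,
    ymin = grid$origin[2] - d[1] * grid$cell_size, ymax = grid$origin[2])
}

#' Map point coordinates to (row, col) indices
#'
#' Points on the outer boundary are assigned to the adjacent boundary cell
#' (inclusive extent); points outside return `NA` rows.
#' @param grid a `raster_grid`.
#' @param x,y point coordinates in metres.
#' @return integer matrix with columns `row`, `col`.
#' @export
xy_to_rowcol <- function(grid, x, y) {
  cs <- grid$cell_size
  ext <- raster_extent(grid)
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- floor((grid$origin[2] - y) / cs) + 1L
  # inclusive right/bottom boundary
  col[x == ext["xmax"]] <- ncol(grid$values)
  row[y == ext["ymin"]] <- nrow(grid$values)
  bad <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#' @param grid a `raster_grid`.
#' @param x,y point coordinates in metres.
#' @return numeric vector (`NA` for out-of-extent or nodata cells).
#' @export
raster_extract <- function(grid, x, y) {
  rc <- xy_to_rowcol(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange (`.asc`). Values are written
#' row by row from the northern edge; `NA` becomes the `nodata` sentinel.
#' @param grid a `raster_grid`.
#' @param path file path.
#' @return `read_asc` returns a `raster_grid`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  d <- dim(grid$values)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - d[1] * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  for (i in seq_len(d[1]))
    writeLines(paste(format(v[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @param crs_tag projection tag attached on read (not stored in `.asc`).
#' @export
read_asc <- function(path, crs_tag = "local-metres") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  raster_grid(m,
              origin = c(h[["xllcorner"]],
                         h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]]),
              cell_size = h[["cellsize"]],
              nodata = h[["nodata_value"]], crs_tag = crs_tag)
}

#' Resample a raster onto another grid
#'
#' Nearest-neighbour for categorical layers, bilinear for continuous ones.
#' Used to bring mixed-resolution sources onto one master grid before
#' analysis.
#' @param r the source `raster_grid`.
#' @param grid the target `raster_grid` (geometry only is used).
#' @param method `"bilinear"` or `"nearest"`.
#' @return a `raster_grid` on the target grid.
#' @export
resample_to <- function(r, grid, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  cc <- cell_centers(grid)
  if (method == "nearest") {
    v <- raster_extract(r, cc$x, cc$y)
  } else {
    v <- .bilinear(r, cc$x, cc$y)
  }
  raster_like(grid, matrix(v, nrow = nrow(grid$values)))
}

.bilinear <- function(r, x, y) {
  cs <- r$cell_size
  xs <- raster_x(r); ys <- raster_y(r)
  nr <- nrow(r$values); nc <- ncol(r$values)
  # fractional column/row position in centre coordinates, clamped to the
  # centre lattice so edge cells extrapolate flat
  fx <- pmin(pmax((x - xs[1]) / cs, 0), nc - 1)
  fy <- pmin(pmax((ys[1] - y) / cs, 0), nr - 1)
  j0 <- pmin(floor(fx) + 1L, nc - 1L); i0 <- pmin(floor(fy) + 1L, nr - 1L)
  tx <- fx - (j0 - 1L); ty <- fy - (i0 - 1L)
  v00 <- r$values[cbind(i0, j0)];     v01 <- r$values[cbind(i0, j0 + 1L)]
  v10 <- r$values[cbind(i0 + 1L, j0)]; v11 <- r$values[cbind(i0 + 1L, j0 + 1L)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

# shift a matrix by (dr, dc), padding with NA; used by terrain derivatives
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
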