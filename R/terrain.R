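#' Terrain ruggedness index (TRI)
#'
#' Riley's TRI: for each cell, the square root of the summed squared
#' elevation differences between the cell and its eight neighbours. Edge and
#' nodata-adjacent cells use only the neighbours that exist.
#'
#' @param dem a `raster_grid` of elevations in metres.
#' @return a `raster_grid` of TRI values (>= 0; `NA` where the DEM is nodata).
#' @export
terrain_ruggedness <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  m <- dem$values
  if (all(is.na(m))) stop("DEM is entirely nodata; TRI undefined")
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(raster_like(dem, ifelse(is.na(m), NA_real_, 0)))
  }
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- .shift_mat(m, dr, dc)
    d2 <- (m - nb)^2
    d2[is.na(d2)] <- 0
    acc <- acc + d2
  }
  out <- sqrt(acc)
  out[is.na(m)] <- NA_real_
  raster_like(dem, out)
}

#' Slope and aspect from a DEM
#'
#' Central-difference gradients (one-sided at edges). Slope in degrees;
#' aspect in compass degrees clockwise from north, `NA` on flat cells.
#'
#' @param dem a `raster_grid` of elevations in metres.
#' @return a `raster_grid`.
#' @export
terrain_slope <- function(dem) {
  g <- .dem_gradients(dem)
  raster_like(dem, atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi)
}

#' @rdname terrain_slope
#' @export
terrain_aspect <- function(dem) {
  g <- .dem_gradients(dem)
  asp <- (atan2(g$dzdx, g$dzdy) * 180 / pi + 180) %% 360
  asp[g$dzdx == 0 & g$dzdy == 0] <- NA_real_
  raster_like(dem, asp)
}

.dem_gradients <- function(dem) {
  m <- dem$values
  cs <- dem$cell_size
  e <- .shift_mat(m, 0, -1); w <- .shift_mat(m, 0, 1)
  n <- .shift_mat(m, 1, 0);  s <- .shift_mat(m, -1, 0)
  # fall back to the centre cell where a neighbour is missing (one-sided)
  e[is.na(e)] <- m[is.na(e)]; w[is.na(w)] <- m[is.na(w)]
  n[is.na(n)] <- m[is.na(n)]; s[is.na(s)] <- m[is.na(s)]
  list(dzdx = (e - w) / (2 * cs), dzdy = (n - s) / (2 * cs))
}
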