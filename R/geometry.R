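#' Minimum convex polygon (100% MCP)
#'
#' Convex hull of a point set, used to delimit the availability domain for
#' the used-available resource selection design.
#'
#' @param points two-column matrix or data.frame of (x, y).
#' @return closed ring: numeric matrix, first vertex repeated last.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points for a convex polygon")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) stop("points are collinear; hull is degenerate")
  ring <- pts[h, , drop = FALSE]
  unname(rbind(ring, ring[1, ]))
}

#' Signed and absolute polygon area (shoelace)
#' @param ring closed-ring matrix of (x, y).
#' @return area in square metres (absolute value).
#' @export
polygon_area <- function(ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  abs(sum(ring[-n, 1] * ring[-1, 2] - ring[-1, 1] * ring[-n, 2]) / 2)
}

.signed_area <- function(ring) {
  n <- nrow(ring)
  sum(ring[-n, 1] * ring[-1, 2] - ring[-1, 1] * ring[-n, 2]) / 2
}

#' Point-in-polygon test (ray casting)
#' @param x,y point coordinates (vectorised).
#' @param ring closed-ring matrix.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(x, y, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    on_edge <- on_edge | (.point_seg_dist2(x, y, x1, y1, x2, y2) < 1e-18)
  }
  inside | on_edge
}

#' Uniform random points inside a polygon
#' @param ring closed-ring matrix.
#' @param n number of points.
#' @param seed integer RNG seed.
#' @return data.frame with columns x, y.
#' @export
sample_points_in_polygon <- function(ring, n, seed = 1) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  if (polygon_area(ring) <= 0) stop("degenerate polygon")
  set.seed(seed)
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    px <- runif(m, xr[1], xr[2]); py <- runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, ring)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# label 8-connected components of a logical matrix; returns integer matrix
# (0 = background)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cell - 1L) %% nr) + 1L
      j <- ((cell - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          nb <- (jj - 1L) * nr + ii
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# trace boundary rings of a cell set (rows of `cells` are (row, col)); the
# outer ring (largest |area|) is returned in xy coordinates
.trace_outer_ring <- function(cells, grid) {
  cs <- grid$cell_size
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  key <- function(i, j) i * 1e6 + j          # corner key, corner grid indices
  member <- new.env(hash = TRUE)
  for (k in seq_len(nrow(cells)))
    assign(sprintf("%d_%d", cells[k, 1], cells[k, 2]), TRUE, envir = member)
  has <- function(i, j) !is.null(member[[sprintf("%d_%d", i, j)]])
  # directed boundary edges, interior on the left (counter-clockwise in xy)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    tl <- key(i - 1, j - 1); tr <- key(i - 1, j)
    bl <- key(i, j - 1);     br <- key(i, j)
    if (!has(i + 1, j)) { from <- c(from, bl); to <- c(to, br) }  # bottom ->x
    if (!has(i, j + 1)) { from <- c(from, br); to <- c(to, tr) }  # right  ->y
    if (!has(i - 1, j)) { from <- c(from, tr); to <- c(to, tl) }  # top    <-x
    if (!has(i, j - 1)) { from <- c(from, tl); to <- c(to, bl) }  # left   <-y
  }
  used <- rep(FALSE, length(from))
  nxt <- split(seq_along(from), from)
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring_keys <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      v <- to[e]
      ring_keys <- c(ring_keys, v)
      cand <- nxt[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      e <- cand[1]
    }
    ki <- ring_keys %/% 1e6; kj <- ring_keys %% 1e6
    rings[[length(rings) + 1L]] <-
      cbind(x = x0 + kj * cs, y = y0 - ki * cs)
  }
  areas <- vapply(rings, function(r) abs(.signed_area(r)), 0)
  rings[[which.max(areas)]]
}

# build a "core set" (polygons with ids) from a logical mask on a grid
.cells_to_polygons <- function(mask, grid, min_cells = 1L, season = NA_character_) {
  lab <- .label_components(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  polys <- list()
  for (id in ids) {
    cells <- which(lab == id, arr.ind = TRUE)
    if (nrow(cells) < min_cells) next
    ring <- .trace_outer_ring(cells, grid)
    cc <- list(x = grid$origin[1] + (cells[, 2] - 0.5) * grid$cell_size,
               y = grid$origin[2] - (cells[, 1] - 0.5) * grid$cell_size)
    polys[[length(polys) + 1L]] <- list(
      id = length(polys) + 1L,
      cells = unname(cells),
      n_cells = nrow(cells),
      area = nrow(cells) * grid$cell_size^2,
      ring = ring,
      centroid = c(mean(cc$x), mean(cc$y)),
      season = season)
  }
  structure(list(polygons = polys, grid = grid), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d polygon(s); areas (km2): %s\n",
              length(x$polygons),
              paste(sprintf("%.1f", vapply(x$polygons, `[[`, 0, "area") / 1e6),
                    collapse = ", ")))
  invisible(x)
}

#' Kernel-density isopleth polygons
#'
#' Estimates a Gaussian kernel density of a point set on the cells of `grid`
#' (normal-reference bandwidth) and returns the smallest set of cells whose
#' density mass reaches `level`, grouped into 8-connected polygons. Used for
#' the 50% winter source-area contours.
#'
#' @param points two-column matrix or data.frame of (x, y).
#' @param level isopleth level, fraction of density mass in (0, 1).
#' @param grid a `raster_grid` defining the evaluation cells.
#' @return a `core_set`; attribute `mass` carries the attained density mass.
#' @export
density_isopleth <- function(points, level, grid) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 10) stop("need at least 10 points for a density isopleth")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  ext <- raster_extent(grid)
  h <- c(MASS::bandwidth.nrd(pts[, 1]), MASS::bandwidth.nrd(pts[, 2]))
  h[h <= 0] <- grid$cell_size  # guard against zero-variance clusters
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = h,
                    n = c(ncol(grid$values), nrow(grid$values)),
                    lims = c(ext[["xmin"]], ext[["xmax"]],
                             ext[["ymin"]], ext[["ymax"]]))
  # kde2d: z[xi, yj] with ascending x and y; our matrix is row 1 = top
  dens <- t(kd$z)[rev(seq_len(nrow(grid$values))), , drop = FALSE]
  p <- dens / sum(dens)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  n_in <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  mask[ord[seq_len(n_in)]] <- TRUE
  out <- .cells_to_polygons(mask, grid)
  attr(out, "mass") <- cum[n_in]
  attr(out, "level") <- level
  out
}

#' Extract per-point covariates from a landscape stack
#'
#' One row per point, one column per layer. Points falling in a nodata cell
#' are flagged in the `.missing` column; points outside the stack extent are
#' an error (the offending point is named).
#'
#' @param points two-column matrix or data.frame of (x, y).
#' @param stack a `landscape_stack`.
#' @return data.frame of layer values plus logical `.missing`.
#' @export
extract_covariates <- function(points, stack) {
  stopifnot(inherits(stack, "landscape_stack"))
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  grid <- stack$layers[[1]]
  rc <- xy_to_rowcol(grid, pts[, 1], pts[, 2])
  bad <- which(is.na(rc[, 1]))
  if (length(bad))
    stop(sprintf("point %d (%.1f, %.1f) lies outside the stack extent",
                 bad[1], pts[bad[1], 1], pts[bad[1], 2]))
  out <- as.data.frame(lapply(stack$layers, function(l)
    l$values[cbind(rc[, 1], rc[, 2])]))
  names(out) <- names(stack$layers)
  out$.missing <- !complete.cases(out)
  out
}
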