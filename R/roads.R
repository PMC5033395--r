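#' Split a highway network into near-equal-length segments
#'
#' Segments are contiguous along each polyline: the `n_segments` are first
#' allocated to polylines proportionally to their length (largest
#' remainder), then each polyline is divided into that many equal arcs.
#' Segment ids are assigned deterministically in network order.
#'
#' @param highways a `vector_layer` of polylines.
#' @param n_segments number of segments (default 20).
#' @return a `vector_layer` of polyline segments with `segment_id` and
#'   `length_km` attributes.
#' @export
split_highways <- function(highways, n_segments = 20) {
  lens <- vapply(highways$geometries, .polyline_length, 0)
  total <- sum(lens)
  if (total <= 0) stop("highway network has zero length")
  n_segments <- max(1L, as.integer(n_segments))
  # largest-remainder allocation, at least 1 segment per polyline
  raw <- lens / total * n_segments
  alloc <- pmax(floor(raw), 1L)
  while (sum(alloc) < n_segments) {
    i <- which.max(raw - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_segments) {
    cand <- which(alloc > 1L)
    i <- cand[which.min((raw - alloc)[cand])]
    alloc[i] <- alloc[i] - 1L
  }
  geoms <- list(); ids <- integer(0)
  for (gi in seq_along(highways$geometries)) {
    g <- highways$geometries[[gi]]
    cuts <- seq(0, lens[gi], length.out = alloc[gi] + 1)
    for (k in seq_len(alloc[gi])) {
      geoms[[length(geoms) + 1L]] <- .polyline_substring(g, cuts[k],
                                                         cuts[k + 1])
      ids <- c(ids, length(geoms))
    }
  }
  vector_layer(geoms,
               attributes = data.frame(
                 segment_id = ids,
                 length_km = vapply(geoms, .polyline_length, 0) / 1000))
}

# extract the sub-polyline between arc lengths s0 and s1
.polyline_substring <- function(coords, s0, s1) {
  seg <- diff(coords)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  point_at <- function(s) {
    s <- min(max(s, 0), cum[length(cum)])
    k <- findInterval(s, cum, rightmost.closed = TRUE)
    k <- min(k, length(seglen))
    t <- if (seglen[k] > 0) (s - cum[k]) / seglen[k] else 0
    coords[k, ] + t * seg[k, ]
  }
  inner <- which(cum > s0 & cum < s1)
  rbind(point_at(s0), coords[inner, , drop = FALSE], point_at(s1))
}

#' Highway length lying inside corridor cells
#'
#' For each segment, the length (km) of the polyline falling within valid
#' (non-nodata) cells of a cropped corridor raster. Each segment edge is
#' clipped exactly at grid-line crossings, so pieces are attributed to
#' single cells.
#'
#' @param segments a `vector_layer` from [split_highways()].
#' @param corridor a `raster_grid` (cropped corridor mosaic; NA = outside).
#' @return data.frame with `segment_id`, `length_total_km`,
#'   `length_in_corridor_km`.
#' @export
corridor_overlap_length <- function(segments, corridor) {
  v <- corridor$values
  out <- lapply(seq_along(segments$geometries), function(i) {
    g <- segments$geometries[[i]]
    inside <- 0
    for (k in seq_len(nrow(g) - 1))
      inside <- inside + .edge_length_in_valid(g[k, ], g[k + 1, ], corridor, v)
    data.frame(segment_id = segments$attributes$segment_id[i],
               length_total_km = .polyline_length(g) / 1000,
               length_in_corridor_km = inside / 1000)
  })
  do.call(rbind, out)
}

# length of one edge lying in valid cells: split at all grid-line crossings,
# classify each piece by its midpoint cell
.edge_length_in_valid <- function(a, b, grid, v) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(0)
  cs <- grid$cell_size
  ts <- c(0, 1)
  for (dimn in 1:2) {
    lo <- min(a[dimn], b[dimn]); hi <- max(a[dimn], b[dimn])
    orig <- if (dimn == 1) grid$origin[1] else
      grid$origin[2] - nrow(v) * cs  # y measured from bottom edge
    kk <- seq(ceiling((lo - orig) / cs), floor((hi - orig) / cs))
    lines_at <- orig + kk * cs
    lines_at <- lines_at[lines_at > lo & lines_at < hi]
    if (length(lines_at) && b[dimn] != a[dimn])
      ts <- c(ts, (lines_at - a[dimn]) / (b[dimn] - a[dimn]))
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  inside <- 0
  for (k in seq_len(length(ts) - 1)) {
    tm <- (ts[k] + ts[k + 1]) / 2
    p <- a + tm * (b - a)
    val <- raster_extract(grid, p[1], p[2])
    if (!is.na(val)) inside <- inside + (ts[k + 1] - ts[k]) * len
  }
  inside
}

#' Paired t-test of per-segment corridor permeability
#'
#' Classical paired t statistic on `d = x - y` with `df = n - 1` and a
#' two-sided p-value; the test used to compare corridor-highway overlap
#' between the actual and no-roads scenarios. Zero variance with a nonzero
#' mean difference reports `t = +-Inf`, `p = 0` with a warning; identical
#' vectors report `t = 0`, `p = 1`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    warning("zero variance of differences; t is infinite")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}
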