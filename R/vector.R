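#' Vector layer of polylines or polygons
#'
#' Geometries are two-column coordinate matrices in projected metres;
#' polygons must be closed rings (first vertex repeated last; closed on
#' construction if not).
#'
#' @param geometries list of numeric matrices with columns x, y.
#' @param attributes optional data.frame, one row per geometry.
#' @param type `"polyline"` or `"polygon"`.
#' @return an object of class `vector_layer`.
#' @export
vector_layer <- function(geometries, attributes = NULL,
                         type = c("polyline", "polygon")) {
  type <- match.arg(type)
  if (!is.list(geometries) || length(geometries) == 0)
    stop("`geometries` must be a non-empty list")
  geometries <- lapply(geometries, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 2) stop("each geometry needs >= 2 xy rows")
    if (type == "polygon" && !all(g[1, ] == g[nrow(g), ]))
      g <- rbind(g, g[1, ])
    unname(g)
  })
  if (is.null(attributes))
    attributes <- data.frame(id = seq_along(geometries))
  if (nrow(attributes) != length(geometries))
    stop("`attributes` must have one row per geometry")
  structure(list(geometries = geometries, attributes = attributes,
                 type = type), class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  cat(sprintf("<vector_layer> %d %s feature(s), total length %.1f km\n",
              length(x$geometries), x$type,
              sum(vapply(x$geometries, .polyline_length, 0)) / 1000))
  invisible(x)
}

.polyline_length <- function(coords) {
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

#' Total length of a polyline layer in metres
#' @param layer a `vector_layer`.
#' @return numeric scalar (metres).
#' @export
layer_length <- function(layer) {
  sum(vapply(layer$geometries, .polyline_length, 0))
}

#' Write / read a vector layer as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection interchange (LineString / Polygon),
#' coordinates in the projected metre system of the analysis.
#' @param layer a `vector_layer`.
#' @param path file path.
#' @return `read_geojson` returns a `vector_layer`; `write_geojson` the path,
#'   invisibly.
#' @export
write_geojson <- function(layer, path) {
  gtype <- if (layer$type == "polyline") "LineString" else "Polygon"
  feats <- lapply(seq_along(layer$geometries), function(i) {
    coords <- lapply(seq_len(nrow(layer$geometries[[i]])),
                     function(k) layer$geometries[[i]][k, ])
    if (gtype == "Polygon") coords <- list(coords)
    list(type = "Feature",
         properties = as.list(layer$attributes[i, , drop = FALSE]),
         geometry = list(type = gtype, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(fc$features) == 0) stop("empty FeatureCollection")
  gtype <- fc$features[[1]]$geometry$type
  type <- if (gtype == "Polygon") "polygon" else "polyline"
  geoms <- lapply(fc$features, function(f) {
    cc <- f$geometry$coordinates
    if (gtype == "Polygon") cc <- cc[[1]]
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  })
  attrs <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  vector_layer(geoms, attrs, type = type)
}

# squared distance from points (px, py) to segment (ax, ay)-(bx, by),
# vectorised over points
.point_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / l2, 0), 1)
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Euclidean distance from each cell centre to the nearest feature
#'
#' The workhorse behind the distance-to-highway and distance-to-gravel-road
#' layers: exact point-to-segment distances, minimised over every segment of
#' every feature.
#' @param features a `vector_layer` (polylines or polygon boundaries).
#' @param grid a `raster_grid` defining the cells to evaluate.
#' @return a `raster_grid` of distances in metres.
#' @export
distance_to_features <- function(features, grid) {
  if (!inherits(features, "vector_layer") || length(features$geometries) == 0)
    stop("`features` must be a non-empty vector_layer")
  stopifnot(inherits(grid, "raster_grid"))
  cc <- cell_centers(grid)
  best <- rep(Inf, length(cc$x))
  for (g in features$geometries) {
    for (k in seq_len(nrow(g) - 1)) {
      d2 <- .point_seg_dist2(cc$x, cc$y, g[k, 1], g[k, 2],
                             g[k + 1, 1], g[k + 1, 2])
      best <- pmin(best, d2)
    }
  }
  raster_like(grid, matrix(sqrt(best), nrow = nrow(grid$values)))
}

# minimum distance between two segments; for non-crossing segments the
# minimum is attained at an endpoint of one of them
.seg_seg_dist <- function(a1, a2, b1, b2) {
  if (.segments_cross(a1, a2, b1, b2)) return(0)
  sqrt(min(
    .point_seg_dist2(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
    .point_seg_dist2(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
    .point_seg_dist2(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
    .point_seg_dist2(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2])))
}

.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) ||
    (d1 == 0 && .on_seg(p3, p4, p1)) || (d2 == 0 && .on_seg(p3, p4, p2)) ||
    (d3 == 0 && .on_seg(p1, p2, p3)) || (d4 == 0 && .on_seg(p1, p2, p4))
}

.on_seg <- function(a, b, p) {
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}
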