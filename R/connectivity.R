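#' Relative-probability prediction surface from a fitted model
#'
#' Evaluates `exp(beta . x)` on every valid cell of the stack and rescales
#' by the maximum, giving a relative selection surface in (0, 1]. Every
#' model term must correspond to a landscape layer (step-geometry terms such
#' as length or turn angle cannot be mapped and are an error).
#'
#' @param model a `fitted_model`.
#' @param stack a `landscape_stack`.
#' @return a `raster_grid` with values in (0, 1].
#' @export
prediction_surface <- function(model, stack) {
  need <- unique(model$terms$base)
  have <- names(stack$layers)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("model term(s) with no landscape layer: ",
         paste(miss, collapse = ", "))
  grid <- stack$layers[[1]]
  if (length(need) == 0) {  # intercept-only model: flat surface
    vals <- ifelse(is.na(grid$values), NA_real_, 1)
    return(raster_like(grid, vals))
  }
  valid <- !Reduce(`|`, lapply(stack$layers[need], function(l) is.na(l$values)))
  idx <- which(valid)
  rows <- as.data.frame(lapply(stack$layers[need], function(l) l$values[idx]))
  names(rows) <- need
  for (nm in need) {
    if (stack$layer_type[[nm]] == "categorical") {
      levs <- attr(stack$layers[[nm]], "levels")
      rows[[nm]] <- levs[rows[[nm]]]
    }
  }
  eta <- .model_eta(model, rows)
  vals <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  vals[idx] <- exp(eta - max(eta, na.rm = TRUE))
  raster_like(grid, vals)
}

#' Invert a selection surface into a friction surface
#'
#' `friction = max(1 - surface, epsilon)`: the better a cell is for
#' movement, the cheaper it is to cross; the floor keeps cost-weighted
#' distances well defined where predicted selection is exactly 1.
#'
#' @param surface a `raster_grid` with values in `[0, 1]`.
#' @param epsilon resistance floor (default 1e-6).
#' @param scenario `"actual"` or `"no_roads"` (metadata).
#' @param season `"spring"` or `"autumn"` (metadata).
#' @return a `raster_grid` with attributes `scenario` and `season`.
#' @export
friction_from_surface <- function(surface, epsilon = 1e-6,
                                  scenario = "actual", season = NA_character_) {
  v <- surface$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("surface values must lie in [0, 1]")
  out <- raster_like(surface, pmax(1 - v, epsilon))
  attr(out, "scenario") <- scenario
  attr(out, "season") <- season
  attr(out, "epsilon") <- epsilon
  out
}

#' Prediction surface under the no-roads counterfactual
#'
#' Re-evaluates the fitted model with both road-distance layers replaced
#' everywhere by their cap values (the distance beyond which roads no longer
#' influence selection), then renormalises by its own maximum. Cells already
#' beyond both caps keep their raw score; near-road cells can only improve.
#'
#' @param model a `fitted_model`.
#' @param stack a `landscape_stack`.
#' @param road_layers names of the road-distance layers.
#' @return a `raster_grid` in (0, 1].
#' @export
no_roads_surface <- function(model, stack,
                             road_layers = c("dist_highway", "dist_gravel")) {
  stack2 <- stack
  for (nm in intersect(road_layers, names(stack$layers))) {
    cap <- unname(model$spec$caps[nm])
    # without a declared cap, "no roads" means the layer's own maximum
    if (length(cap) != 1 || is.na(cap))
      cap <- max(stack$layers[[nm]]$values, na.rm = TRUE)
    v <- stack$layers[[nm]]$values
    v[!is.na(v)] <- cap
    stack2$layers[[nm]] <- raster_like(stack$layers[[nm]], v)
  }
  prediction_surface(model, stack2)
}

#' Extract core areas from a selection-score raster
#'
#' Cells scoring at or above the stated quantile of valid-cell scores are
#' grouped into 8-connected components; components smaller than `min_cells`
#' are discarded. Used to delimit residency core areas from RSF surfaces
#' (upper quartile by default).
#'
#' @param score_raster a `raster_grid` of selection scores.
#' @param quantile score quantile defining "high" (default 0.75).
#' @param min_cells minimum component size in cells (default 4).
#' @param season optional season tag carried on the polygons.
#' @param max_cores keep at most this many components (largest first);
#'   bounds the downstream cost-distance workload.
#' @return a `core_set`.
#' @export
extract_cores <- function(score_raster, quantile = 0.75, min_cells = 4,
                          season = NA_character_, max_cores = Inf) {
  v <- score_raster$values
  if (sum(!is.na(v)) < 4) stop("raster has fewer than 4 valid cells")
  vals <- v[!is.na(v)]
  if (max(vals) == min(vals)) {
    warning("degenerate score raster (all values equal); all cells qualify")
    thr <- vals[1]
  } else {
    thr <- stats::quantile(vals, quantile, names = FALSE)
  }
  mask <- !is.na(v) & v >= thr
  out <- .cells_to_polygons(mask, score_raster, min_cells = min_cells,
                            season = season)
  if (is.finite(max_cores) && length(out$polygons) > max_cores) {
    ord <- order(vapply(out$polygons, `[[`, 0, "area"), decreasing = TRUE)
    out$polygons <- out$polygons[sort(ord[seq_len(max_cores)])]
    for (i in seq_along(out$polygons)) out$polygons[[i]]$id <- i
  }
  out
}

#' Pair core areas within a maximum dispersal distance
#'
#' All (A, B) pairs whose minimum edge-to-edge Euclidean distance is at most
#' `max_km` (inclusive; the longest recorded dispersal bounds the search).
#' Overlapping cores have distance 0.
#'
#' @param cores_from,cores_to `core_set` objects (may be the same object).
#' @param max_km maximum pairing distance in kilometres (default 80).
#' @return data.frame with `from`, `to`, `distance_km`.
#' @export
pair_cores <- function(cores_from, cores_to, max_km = 80) {
  pf <- cores_from$polygons; pt <- cores_to$polygons
  if (length(pf) == 0 || length(pt) == 0) stop("empty core set")
  same <- identical(cores_from, cores_to)
  out <- list()
  for (i in seq_along(pf)) {
    jj <- if (same) seq_along(pt)[-seq_len(i)] else seq_along(pt)
    for (j in jj) {
      d <- .core_distance(pf[[i]], pt[[j]], cores_from$grid, cores_to$grid)
      if (d / 1000 <= max_km)
        out[[length(out) + 1L]] <- data.frame(from = i, to = j,
                                              distance_km = d / 1000)
    }
  }
  if (length(out) == 0)
    return(data.frame(from = integer(0), to = integer(0),
                      distance_km = numeric(0)))
  do.call(rbind, out)
}

# minimum distance between two cores: 0 when they share a cell (same grid)
# or one contains a vertex of the other; otherwise the minimum distance
# between boundary vertex sets. Ring vertices lie at every cell corner
# along the boundary, so the vertex-set minimum equals the true
# edge-to-edge minimum up to grid resolution (exactly, for axis-aligned
# closest approaches).
.core_distance <- function(a, b, grid_a, grid_b) {
  if (identical(grid_a[c("origin", "cell_size")],
                grid_b[c("origin", "cell_size")])) {
    ka <- a$cells[, 1] * 1e6 + a$cells[, 2]
    kb <- b$cells[, 1] * 1e6 + b$cells[, 2]
    if (length(intersect(ka, kb))) return(0)
  } else {
    if (point_in_polygon(a$ring[1, 1], a$ring[1, 2], b$ring) ||
        point_in_polygon(b$ring[1, 1], b$ring[1, 2], a$ring)) return(0)
  }
  va <- a$ring[-nrow(a$ring), , drop = FALSE]
  vb <- b$ring[-nrow(b$ring), , drop = FALSE]
  d2 <- outer(va[, 1], vb[, 1], "-")^2 + outer(va[, 2], vb[, 2], "-")^2
  sqrt(min(d2))
}

#' Cost-weighted distance from a source area
#'
#' Minimal accumulated cost from any source cell to every cell, over
#' 8-connected moves; the cost of a move is the mean of the two cell
#' frictions times the centre-to-centre distance (`cell_size`, times sqrt(2)
#' for diagonal moves) - the Linkage Mapper / ArcGIS convention. Computed by
#' Dijkstra's algorithm (igraph) from a zero-cost virtual node attached to
#' all source cells.
#'
#' @param friction a `raster_grid` of per-cell resistance (NA = barrier).
#' @param source a core (list with a `cells` matrix), a two-column
#'   (row, col) matrix, or a logical mask matrix.
#' @param graph optional prebuilt move graph from [friction_graph()]
#'   (reused across sources on the same friction surface).
#' @return a `raster_grid` of accumulated costs (0 on the source, NA where
#'   unreachable or nodata).
#' @export
cost_weighted_distance <- function(friction, source, graph = NULL) {
  if (is.null(graph)) graph <- friction_graph(friction)
  f <- friction$values
  nr <- nrow(f); nc <- ncol(f)
  if (is.list(source) && !is.null(source$cells)) source <- source$cells
  if (is.matrix(source) && is.logical(source))
    source <- which(source, arr.ind = TRUE)
  source <- matrix(as.integer(source), ncol = 2)
  src_idx <- (source[, 2] - 1L) * nr + source[, 1]
  src_idx <- src_idx[!is.na(f[src_idx])]
  if (length(src_idx) == 0) stop("source lies entirely on nodata cells")
  # one Dijkstra from a zero-cost virtual vertex attached to all source cells
  virt <- length(graph$valid) + 1L
  g2 <- igraph::add_vertices(graph$g, 1)
  g2 <- igraph::add_edges(g2, rbind(virt, graph$vid[src_idx]))
  w2 <- c(graph$weights, rep(0, length(src_idx)))
  d <- igraph::distances(g2, v = virt, weights = w2,
                         algorithm = "dijkstra")[1, ]
  out <- rep(NA_real_, nr * nc)
  out[graph$valid] <- d[seq_along(graph$valid)]
  out[is.infinite(out)] <- NA_real_
  raster_like(friction, matrix(out, nr, nc))
}

#' Build the 8-connected move graph of a friction surface
#'
#' Constructing the weighted move graph dominates the cost of a single
#' cost-weighted-distance call; build it once and pass it to
#' [cost_weighted_distance()] when computing distances from many cores on
#' the same surface.
#'
#' @param friction a `raster_grid` of per-cell resistance.
#' @return a list with the igraph object, edge weights, valid-cell indices
#'   and the cell-to-vertex map.
#' @export
friction_graph <- function(friction) {
  f <- friction$values
  nr <- nrow(f); nc <- ncol(f)
  valid <- which(!is.na(f))
  vid <- rep(NA_integer_, nr * nc)
  vid[valid] <- seq_along(valid)
  cs <- friction$cell_size
  edge_set <- function(di, dj, w_mult) {
    i <- ((valid - 1L) %% nr) + 1L
    j <- ((valid - 1L) %/% nr) + 1L
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    nb <- (jj[ok] - 1L) * nr + ii[ok]
    ok2 <- !is.na(f[nb])
    a <- valid[ok][ok2]; b <- nb[ok2]
    cbind(vid[a], vid[b], (f[a] + f[b]) / 2 * cs * w_mult)
  }
  e <- rbind(edge_set(0L, 1L, 1), edge_set(1L, 0L, 1),
             edge_set(1L, 1L, sqrt(2)), edge_set(-1L, 1L, sqrt(2)))
  g <- igraph::make_empty_graph(n = length(valid), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e[, 1:2])))
  list(g = g, weights = e[, 3], valid = valid, vid = vid)
}

#' Normalised least-cost corridor between two sources
#'
#' The least-cost path distance is `LCD = min(CWD_A + CWD_B)` over cells;
#' the normalised corridor value is `CWD_A + CWD_B - LCD`, which is 0 along
#' every least-cost path and grows with detour cost.
#'
#' @param cwd_a,cwd_b cost-weighted-distance rasters on one grid.
#' @return list with `lcd` (scalar) and `nlcc` (a `raster_grid`).
#' @export
normalized_corridor <- function(cwd_a, cwd_b) {
  if (!all(dim(cwd_a$values) == dim(cwd_b$values)))
    stop("CWD rasters are not on one grid")
  s <- cwd_a$values + cwd_b$values
  if (all(is.na(s)))
    stop("no cell is reachable from both sources (disjoint valid regions)")
  lcd <- min(s, na.rm = TRUE)
  list(lcd = lcd, nlcc = raster_like(cwd_a, s - lcd))
}

#' Cellwise-minimum mosaic of corridor rasters
#'
#' Each cell of the mosaic takes the minimum value over all input corridors,
#' ignoring nodata unless every input is nodata there.
#'
#' @param rasters list of `raster_grid` objects on one grid.
#' @return a `raster_grid`.
#' @export
mosaic_minimum <- function(rasters) {
  if (length(rasters) < 1) stop("need at least one raster")
  ref <- rasters[[1]]
  for (r in rasters)
    if (!all(dim(r$values) == dim(ref$values)) ||
        !all(r$origin == ref$origin) || r$cell_size != ref$cell_size)
      stop("mosaic inputs are not on one grid")
  acc <- ref$values
  for (r in rasters[-1]) {
    v <- r$values
    take <- !is.na(v) & (is.na(acc) | v < acc)
    acc[take] <- v[take]
  }
  raster_like(ref, acc)
}

#' Crop a corridor mosaic at a maximum cost-weighted distance
#'
#' Cells above the cutoff become nodata; the cutoff itself is retained
#' (inclusive). The conventional display cutoff of 200,000 cost units is a
#' configuration value, not a privileged constant.
#'
#' @param mosaic a `raster_grid` corridor mosaic.
#' @param cwd_cutoff maximum retained value (> 0).
#' @return a `raster_grid`.
#' @export
crop_corridors <- function(mosaic, cwd_cutoff) {
  stopifnot(cwd_cutoff > 0)
  v <- mosaic$values
  v[!is.na(v) & v > cwd_cutoff] <- NA_real_
  if (all(is.na(v)))
    warning("all corridor cells exceed the cutoff; result is empty")
  raster_like(mosaic, v)
}
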