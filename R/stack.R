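#' Co-registered stack of landscape layers
#'
#' A named list of `raster_grid` layers sharing one grid, with a
#' continuous/categorical tag per layer. Categorical layers store their class
#' labels in a `levels` attribute on the raster (integer codes in the
#' matrix). Road polylines may ride along in `vectors`.
#'
#' @param layers named list of `raster_grid` objects on one grid.
#' @param layer_type named character, `"continuous"` or `"categorical"` per
#'   layer; defaults to continuous.
#' @param vectors optional named list of `vector_layer` objects (e.g.
#'   `highway`, `gravel`).
#' @return an object of class `landscape_stack`.
#' @export
landscape_stack <- function(layers, layer_type = NULL, vectors = list()) {
  if (length(layers) == 0 || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a non-empty named list")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "raster_grid")) stop("layer '", nm, "' is not a raster_grid")
    if (!all(dim(l$values) == dim(ref$values)) ||
        !all(l$origin == ref$origin) || l$cell_size != ref$cell_size)
      stop("layer '", nm, "' is not on the shared grid")
  }
  if (is.null(layer_type))
    layer_type <- setNames(rep("continuous", length(layers)), names(layers))
  lt <- setNames(rep("continuous", length(layers)), names(layers))
  lt[names(layer_type)] <- layer_type
  structure(list(layers = layers, layer_type = lt, vectors = vectors),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("<landscape_stack> %d layer(s) on %d x %d @ %g m\n",
              length(x$layers), d[1], d[2], x$layers[[1]]$cell_size))
  cat("  ", paste(sprintf("%s(%s)", names(x$layers),
                          substr(x$layer_type, 1, 3)), collapse = " "), "\n")
  if (length(x$vectors))
    cat("  vectors:", paste(names(x$vectors), collapse = ", "), "\n")
  invisible(x)
}

#' Class labels of a categorical layer
#' @param stack a `landscape_stack`.
#' @param layer layer name.
#' @return character vector of labels, index = integer code.
#' @export
layer_levels <- function(stack, layer) {
  attr(stack$layers[[layer]], "levels")
}

# continuous layers capped (road distances) and z-scored over valid cells;
# categorical layers expanded to one 0/1 matrix per non-reference class.
# Returns a named list of plain matrices plus the scaling used.
.prepare_model_layers <- function(stack, caps = numeric(0),
                                  reference = c(landcover = "conifer")) {
  out <- list()
  scale_info <- list()
  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]]$values
    if (stack$layer_type[[nm]] == "continuous") {
      if (nm %in% names(caps)) v <- pmin(v, caps[[nm]])
      mu <- mean(v, na.rm = TRUE); sdv <- sd(as.vector(v), na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      out[[nm]] <- (v - mu) / sdv
      scale_info[[nm]] <- c(center = mu, scale = sdv)
    } else {
      levs <- attr(stack$layers[[nm]], "levels")
      ref <- if (nm %in% names(reference)) reference[[nm]] else levs[1]
      for (cl in setdiff(levs, ref)) {
        code <- match(cl, levs)
        out[[cl]] <- (v == code) * 1.0
      }
    }
  }
  list(layers = out, scale = scale_info)
}

# per-cell linear predictor sum(beta_j * prepared_layer_j); beta names must
# match prepared layer names (continuous layer names or categorical class
# labels); a "<layer>_sq" name is the squared standardized layer, so peaked
# (quadratic) selection can be stated as truth
.truth_score_matrix <- function(stack, beta, caps = numeric(0)) {
  prep <- .prepare_model_layers(stack, caps = caps)
  base <- sub("_sq$", "", names(beta))
  miss <- setdiff(base, names(prep$layers))
  if (length(miss))
    stop("beta names not found among prepared layers: ",
         paste(miss, collapse = ", "))
  s <- matrix(0, nrow(stack$layers[[1]]$values), ncol(stack$layers[[1]]$values))
  for (k in seq_along(beta)) {
    l <- prep$layers[[base[k]]]
    if (grepl("_sq$", names(beta)[k])) l <- l^2
    s <- s + beta[[k]] * l
  }
  # propagate nodata from any layer
  for (l in prep$layers) s[is.na(l)] <- NA_real_
  s
}

#' Selection surface from known (ground-truth) coefficients
#'
#' Evaluates `exp(beta . x)` per cell on the capped/standardized layer scale
#' and rescales by the maximum; with `scenario = "no_roads"` the road
#' distance layers are first set everywhere to their cap value (the
#' distance beyond which roads no longer matter). This is the generator's
#' own selection surface, used to verify the model-based
#' [prediction_surface()] / [no_roads_surface()] pair against known truth.
#'
#' @param stack a `landscape_stack`.
#' @param beta named coefficients (layer names / land-cover class names).
#' @param caps road-distance caps in metres.
#' @param scenario `"actual"` or `"no_roads"`.
#' @return a `raster_grid` with values in (0, 1].
#' @export
truth_surface <- function(stack, beta,
                          caps = c(dist_highway = 2000, dist_gravel = 1000),
                          scenario = c("actual", "no_roads")) {
  scenario <- match.arg(scenario)
  stack2 <- stack
  if (scenario == "no_roads") {
    for (nm in intersect(names(caps), names(stack$layers))) {
      v <- stack$layers[[nm]]$values
      v[!is.na(v)] <- caps[[nm]]
      stack2$layers[[nm]] <- raster_like(stack$layers[[nm]], v)
    }
    # keep the actual-scenario standardization so both surfaces share scale
    prep_ref <- .prepare_model_layers(stack, caps = caps)
    s <- matrix(0, nrow(stack$layers[[1]]$values),
                ncol(stack$layers[[1]]$values))
    for (k in seq_along(beta)) {
      nm <- names(beta)[k]
      base <- sub("_sq$", "", nm)
      if (base %in% names(caps)) {
        sc <- prep_ref$scale[[base]]
        v <- pmin(stack2$layers[[base]]$values, caps[[base]])
        v <- (v - sc[["center"]]) / sc[["scale"]]
      } else {
        v <- prep_ref$layers[[base]]
      }
      if (grepl("_sq$", nm)) v <- v^2
      s <- s + beta[[k]] * v
    }
    for (l in prep_ref$layers) s[is.na(l)] <- NA_real_
  } else {
    s <- .truth_score_matrix(stack, beta, caps = caps)
  }
  raster_like(stack$layers[[1]], exp(s - max(s, na.rm = TRUE)))
}

#' Landscape stack with model-scale layers
#'
#' Returns a stack whose continuous layers are capped (road distances) and
#' z-scored over valid cells, and whose categorical layers are expanded into
#' one 0/1 indicator layer per non-reference class. This is the scale on
#' which the synthetic generator's ground-truth coefficients are defined, so
#' parameter-recovery experiments extract covariates from it directly.
#'
#' @param stack a `landscape_stack`.
#' @param caps named numeric of per-layer caps in metres (e.g.
#'   `c(dist_highway = 2000, dist_gravel = 1000)`).
#' @param reference named character giving the reference class of each
#'   categorical layer.
#' @return a `landscape_stack` of continuous layers.
#' @export
standardize_stack <- function(stack,
                              caps = c(dist_highway = 2000, dist_gravel = 1000),
                              reference = c(landcover = "conifer")) {
  prep <- .prepare_model_layers(stack, caps = caps, reference = reference)
  grid <- stack$layers[[1]]
  layers <- lapply(prep$layers, function(m) raster_like(grid, m))
  landscape_stack(layers, vectors = stack$vectors)
}
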