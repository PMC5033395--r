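test_that("prediction surfaces follow the exponential form", {
  vals <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  g <- raster_grid(vals, origin = c(0, 500), cell_size = 250)
  stack <- landscape_stack(list(z = g))
  spec <- design_spec(continuous = "z", quadratic = FALSE, caps = numeric(0),
                      standardize = FALSE)
  model <- structure(list(
    beta = c(`(Intercept)` = 0, z = 1), se = c(1, 1), vcov = diag(2),
    loglik = 0, model_kind = "ssf_clogit", spec = spec, learned = NULL,
    terms = data.frame(column = "z", base = "z", kind = "linear")),
    class = "fitted_model")
  s <- prediction_surface(model, stack)
  expect_equal(s$values, exp(vals - 1))
  expect_equal(max(s$values), 1)

  model0 <- model; model0$beta["z"] <- 0
  expect_true(all(prediction_surface(model0, stack)$values == 1))

  # strictly better covariates -> strictly larger score
  expect_true(s$values[2, 1] > s$values[1, 1])

  model_bad <- model
  model_bad$terms <- rbind(model_bad$terms,
                           data.frame(column = "length", base = "length",
                                      kind = "linear"))
  expect_error(prediction_surface(model_bad, stack), "length")
})

test_that("friction inverts the surface with an epsilon floor", {
  g <- raster_grid(matrix(c(0, 0.3, 1, NA), 2, 2), cell_size = 100)
  fr <- friction_from_surface(g, epsilon = 1e-6)
  expect_equal(fr$values[1, 1], 1)
  expect_equal(fr$values[2, 1], 0.7)
  expect_equal(fr$values[1, 2], 1e-6)
  expect_true(is.na(fr$values[2, 2]))
  # friction + surface = 1 wherever surface <= 1 - eps
  expect_equal(fr$values[2, 1] + g$values[2, 1], 1)
  expect_error(friction_from_surface(raster_like(g, matrix(2, 2, 2))))
})

test_that("the no-roads counterfactual saturates road distances at the caps", {
  fx <- shared_landscape()
  spec <- design_spec(continuous = c("canopy", "dist_highway", "dist_gravel"),
                      quadratic = FALSE)
  set.seed(41)
  # a fitted model object built around known negative road-proximity effects
  d <- extract_covariates(
    simulate_residency_fixes(fx$stack, NULL, 300, seed = 42), fx$stack)
  des <- build_design(d, spec)
  model <- structure(list(
    beta = c(`(Intercept)` = 0,
             setNames(c(-0.3, 0.9, 0.4), colnames(des$X))),
    se = rep(0.1, 4), vcov = diag(4), loglik = 0,
    model_kind = "ssf_clogit", spec = spec, learned = des$learned,
    terms = des$terms), class = "fitted_model")
  act <- prediction_surface(model, fx$stack)
  cf <- no_roads_surface(model, fx$stack)
  dh <- fx$stack$layers$dist_highway$values
  dg <- fx$stack$layers$dist_gravel$values
  # cells already beyond both caps: identical raw scores, so the ratio
  # act/cf is constant there (both are max-rescaled)
  far <- dh >= 2000 & dg >= 1000
  ratio <- act$values[far] / cf$values[far]
  expect_lt(diff(range(ratio)), 1e-10)
  # near-highway cells improve at least as much as far cells under no-roads
  near <- dh < 500
  expect_gt(min(cf$values[near] / act$values[near]),
            max(ratio) - 1e-10)

  # a model without road terms gives identical surfaces
  spec2 <- design_spec(continuous = "canopy", quadratic = FALSE)
  des2 <- build_design(d, spec2)
  model2 <- structure(list(
    beta = c(`(Intercept)` = 0, canopy = -0.3), se = c(0.1, 0.1),
    vcov = diag(2), loglik = 0, model_kind = "ssf_clogit", spec = spec2,
    learned = des2$learned, terms = des2$terms), class = "fitted_model")
  expect_identical(prediction_surface(model2, fx$stack)$values,
                   no_roads_surface(model2, fx$stack)$values)
})

test_that("core extraction thresholds at the quantile and groups components", {
  m <- matrix(0.1, 20, 20)
  m[3:12, 3:12] <- 0.9        # one 10x10 block = top quartile of cells
  g <- raster_grid(m, origin = c(0, 5000), cell_size = 250)
  cores <- extract_cores(g, quantile = 0.75, min_cells = 4)
  expect_length(cores$polygons, 1)
  expect_equal(cores$polygons[[1]]$n_cells, 100)

  m2 <- matrix(0.1, 20, 20)
  m2[2:9, 2:9] <- 0.9; m2[12:19, 12:19] <- 0.9  # two separated blocks
  cores2 <- extract_cores(raster_like(g, m2), quantile = 0.75, min_cells = 4)
  expect_length(cores2$polygons, 2)

  expect_warning(extract_cores(raster_like(g, matrix(1, 20, 20))),
                 "degenerate")
  expect_length(
    suppressWarnings(extract_cores(raster_like(g, matrix(1, 20, 20))))$polygons,
    1)
})

test_that("core pairing respects the inclusive maximum distance", {
  mk_core <- function(rows, cols, g) {
    mask <- matrix(FALSE, nrow(g$values), ncol(g$values))
    mask[rows, cols] <- TRUE
    elkscape:::.cells_to_polygons(mask, g)
  }
  g <- raster_grid(matrix(0, 100, 500), origin = c(0, 100 * 1000),
                   cell_size = 1000)  # 500 km wide grid, 1 km cells
  a <- mk_core(40:45, 10:15, g)
  b_far <- mk_core(40:45, 120:125, g)    # ~104 km edge-to-edge
  b_near <- mk_core(40:45, 50:55, g)     # ~34 km
  expect_equal(nrow(pair_cores(a, b_far, max_km = 80)), 0)
  expect_equal(nrow(pair_cores(a, b_near, max_km = 80)), 1)
  # overlapping cores pair at distance zero
  b_same <- mk_core(42:47, 12:17, g)
  p0 <- pair_cores(a, b_same, max_km = 80)
  expect_equal(p0$distance_km, 0)
  # exactly at the maximum: edge-to-edge 80 km is inclusive
  b_edge <- mk_core(40:45, 96:101, g)    # gap of 80 cells = 80 km
  p80 <- pair_cores(a, b_edge, max_km = 80)
  expect_equal(nrow(p80), 1)
  expect_equal(p80$distance_km, 80)
})

test_that("cost-weighted distance matches the brute-force move graph", {
  # orthogonal and diagonal single moves at uniform friction 1
  f <- raster_grid(matrix(1, 3, 3), cell_size = 100)
  d <- cost_weighted_distance(f, cbind(1, 1))
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[1, 2], 100)
  expect_equal(d$values[2, 2], 100 * sqrt(2))

  set.seed(42)
  for (k in 1:50) {
    m <- matrix(runif(64, 0.05, 1), 8, 8)
    if (k %% 4 == 0) m[sample(64, 5)] <- NA
    g <- raster_grid(m, cell_size = 250)
    src <- matrix(FALSE, 8, 8)
    src[sample(which(!is.na(m)), 2)] <- TRUE
    got <- cost_weighted_distance(g, src)$values
    want <- brute_cwd(m, 250, src)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(cost_weighted_distance(
    raster_grid(matrix(c(NA, 1, 1, 1), 2, 2), cell_size = 100),
    cbind(1, 1)), "nodata")
})

test_that("CWD is linear in friction and respects the triangle property", {
  set.seed(43)
  m <- matrix(runif(100, 0.1, 1), 10, 10)
  g <- raster_grid(m, cell_size = 250)
  d1 <- cost_weighted_distance(g, cbind(1, 1))$values
  d2 <- cost_weighted_distance(raster_like(g, 2 * m), cbind(1, 1))$values
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  # triangle property through an intermediate cell
  db <- cost_weighted_distance(g, cbind(5, 5))$values
  expect_true(all(d1 <= d1[5, 5] + db + 1e-9))
})

test_that("normalized corridors satisfy the defining identities", {
  set.seed(44)
  m <- matrix(runif(81, 0.1, 1), 9, 9)
  g <- raster_grid(m, cell_size = 250)
  ca <- cost_weighted_distance(g, cbind(1, 1))
  cb <- cost_weighted_distance(g, cbind(9, 9))
  nc_ <- normalized_corridor(ca, cb)
  s <- ca$values + cb$values
  expect_equal(nc_$lcd, min(s))
  expect_true(all(nc_$nlcc$values >= 0))
  expect_equal(min(nc_$nlcc$values), 0)  # attained on the least-cost path

  # uniform friction 3x3, opposite corners: hand-composable from the oracle
  u <- raster_grid(matrix(1, 3, 3), cell_size = 100)
  ua <- cost_weighted_distance(u, cbind(1, 1))
  ub <- cost_weighted_distance(u, cbind(3, 3))
  un <- normalized_corridor(ua, ub)
  expect_equal(un$lcd, 2 * 100 * sqrt(2))
  expect_equal(un$nlcc$values[1, 3],
               ua$values[1, 3] + ub$values[1, 3] - un$lcd)

  # doubling friction doubles LCD and NLCC exactly
  ca2 <- cost_weighted_distance(raster_like(g, 2 * m), cbind(1, 1))
  cb2 <- cost_weighted_distance(raster_like(g, 2 * m), cbind(9, 9))
  nc2 <- normalized_corridor(ca2, cb2)
  expect_equal(nc2$lcd, 2 * nc_$lcd, tolerance = 1e-12)
  expect_equal(nc2$nlcc$values, 2 * nc_$nlcc$values, tolerance = 1e-12)

  # disjoint valid regions cannot be joined
  left <- matrix(1, 5, 5); left[, 3] <- NA
  gl <- raster_grid(left, cell_size = 100)
  da <- cost_weighted_distance(gl, cbind(1, 1))
  db <- cost_weighted_distance(gl, cbind(1, 5))
  expect_error(normalized_corridor(da, db), "disjoint|reachable")
})

test_that("corridor mosaics take cellwise minima with nodata pass-through", {
  g <- raster_grid(matrix(1, 2, 2), cell_size = 100)
  a <- raster_like(g, matrix(c(1, 5, NA, 2), 2, 2))
  b <- raster_like(g, matrix(c(3, 2, 4, NA), 2, 2))
  m <- mosaic_minimum(list(a, b))
  expect_equal(m$values, matrix(c(1, 2, 4, 2), 2, 2))
  expect_equal(mosaic_minimum(list(a))$values, a$values)
  # permutation invariance
  expect_equal(mosaic_minimum(list(b, a))$values, m$values)
  g2 <- raster_grid(matrix(1, 3, 3), cell_size = 100)
  expect_error(mosaic_minimum(list(a, raster_like(g2, matrix(1, 3, 3)))),
               "one grid")
})

test_that("corridor cropping is inclusive at the cutoff", {
  g <- raster_grid(matrix(c(100, 200, 300, NA), 2, 2), cell_size = 100)
  cr <- crop_corridors(g, 200)
  expect_equal(cr$values[1, 1], 100)
  expect_equal(cr$values[2, 1], 200)   # exactly at the cutoff: retained
  expect_true(is.na(cr$values[1, 2]))
  expect_equal(crop_corridors(g, Inf)$values, g$values)
  expect_warning(crop_corridors(g, 1), "empty")
})
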