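test_that("terrain ruggedness follows the eight-neighbour formula", {
  flat <- raster_grid(matrix(1000, 5, 5), cell_size = 100)
  expect_true(all(terrain_ruggedness(flat)$values == 0))

  m <- matrix(0, 3, 3); m[2, 2] <- 10
  tri <- terrain_ruggedness(raster_grid(m, cell_size = 100))
  expect_equal(tri$values[2, 2], sqrt(8 * 100))

  # random DEMs against the brute-force loop, including nodata holes
  set.seed(1)
  for (k in 1:50) {
    mm <- matrix(runif(36, 900, 3400), 6, 6)
    if (k %% 3 == 0) mm[sample(36, 3)] <- NA
    if (all(is.na(mm))) next
    expect_equal(terrain_ruggedness(raster_grid(mm))$values, brute_tri(mm))
  }
  expect_error(terrain_ruggedness(raster_grid(matrix(NA_real_, 3, 3))),
               "nodata")
})

test_that("distance transform is exact point-to-segment geometry", {
  g <- raster_grid(matrix(0, 10, 10), origin = c(0, 2500), cell_size = 250)
  # vertical line through the first column of cell centres -> 0 there
  line <- vector_layer(list(cbind(c(125, 125), c(0, 2500))))
  d <- distance_to_features(line, g)
  expect_equal(d$values[, 1], rep(0, 10))
  expect_equal(d$values[1, 2], 250)
  # cell centre at x = 375 vs line at x = 0
  line0 <- vector_layer(list(cbind(c(0, 0), c(0, 2500))))
  d0 <- distance_to_features(line0, g)
  expect_equal(d0$values[1, 2], 375)
  expect_true(all(d0$values >= 0))

  # random line sets against a densely resampled vertex oracle
  set.seed(2)
  for (k in 1:5) {
    coords <- cbind(runif(4, 0, 2500), runif(4, 0, 2500))
    lay <- vector_layer(list(coords))
    d <- distance_to_features(lay, g)
    dense <- do.call(rbind, lapply(1:3, function(i) {
      t <- seq(0, 1, length.out = 2000)
      cbind(coords[i, 1] + t * (coords[i + 1, 1] - coords[i, 1]),
            coords[i, 2] + t * (coords[i + 1, 2] - coords[i, 2]))
    }))
    cc <- cell_centers(g)
    for (ix in sample(100, 10)) {
      od <- min(sqrt((dense[, 1] - cc$x[ix])^2 + (dense[, 2] - cc$y[ix])^2))
      expect_lt(abs(as.vector(d$values)[ix] - od), 2.5)  # 0.5 * resample step
    }
  }
  expect_error(distance_to_features(vector_layer(list()), g))
})

test_that("minimum convex polygon equals the brute-force hull", {
  tri <- minimum_convex_polygon(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(tri), 4)  # closed triangle
  sq <- minimum_convex_polygon(cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)))
  expect_equal(nrow(sq), 5)
  expect_false(any(sq[, 1] == 0.5 & sq[, 2] == 0.5))

  set.seed(3)
  for (k in 1:50) {
    pts <- cbind(runif(50), runif(50))
    ring <- minimum_convex_polygon(pts)
    verts <- unique(ring[-nrow(ring), , drop = FALSE])
    oracle <- pts[brute_hull_vertices(pts), , drop = FALSE]
    expect_equal(nrow(verts), nrow(oracle))
    expect_true(all(apply(verts, 1, function(v)
      any(abs(oracle[, 1] - v[1]) < 1e-12 & abs(oracle[, 2] - v[2]) < 1e-12))))
  }
  expect_error(minimum_convex_polygon(cbind(0:1, 0:1)), "3 points")
  expect_error(minimum_convex_polygon(cbind(0:4, 0:4)), "collinear")
})

test_that("density isopleths contain the stated mass and nest", {
  g <- raster_grid(matrix(0, 40, 40), origin = c(0, 4000), cell_size = 100)
  set.seed(4)
  cl <- cbind(rnorm(200, 2000, 150), rnorm(200, 2000, 150))
  iso <- density_isopleth(cl, 0.5, g)
  expect_s3_class(iso, "core_set")
  cent <- colMeans(cl)
  hit <- any(vapply(iso$polygons, function(p)
    point_in_polygon(cent[1], cent[2], p$ring), TRUE))
  expect_true(hit)

  # two separated equal clusters: attained mass in [level, level + 1 cell]
  two <- rbind(cbind(rnorm(300, 1000, 120), rnorm(300, 1000, 120)),
               cbind(rnorm(300, 3000, 120), rnorm(300, 3000, 120)))
  iso2 <- density_isopleth(two, 0.5, g)
  expect_gte(attr(iso2, "mass"), 0.5)
  # one-cell granularity: overshoot bounded by the largest single-cell mass
  iso_small <- density_isopleth(two, 0.01, g)
  max_cell_mass <- attr(iso_small, "mass")  # >= densest single cell's mass
  expect_lte(attr(iso2, "mass"), 0.5 + max_cell_mass)

  a50 <- sum(vapply(density_isopleth(cl, 0.5, g)$polygons, `[[`, 0, "area"))
  a99 <- sum(vapply(density_isopleth(cl, 0.99, g)$polygons, `[[`, 0, "area"))
  expect_gte(a99, a50)
  expect_error(density_isopleth(cl[1:5, ], 0.5, g), "10 points")
})

test_that("isopleth cells are the smallest qualifying set across levels", {
  g <- raster_grid(matrix(0, 30, 30), origin = c(0, 3000), cell_size = 100)
  set.seed(5)
  pts <- cbind(rnorm(400, 1500, 400), rnorm(400, 1500, 400))
  areas <- vapply(c(0.25, 0.5, 0.75, 0.95), function(lv)
    sum(vapply(density_isopleth(pts, lv, g)$polygons, `[[`, 0, "area")), 0)
  expect_true(all(diff(areas) >= 0))  # nested by construction
})

test_that("covariate extraction maps points to cells and flags nodata", {
  fx <- shared_landscape()
  g <- fx$stack$layers$elevation
  cs <- g$cell_size
  # a point at an exact cell centre returns that cell's value on every layer
  x <- g$origin[1] + 10.5 * cs; y <- g$origin[2] - 7.5 * cs
  row <- extract_covariates(cbind(x, y), fx$stack)
  for (nm in names(fx$stack$layers))
    expect_equal(row[[nm]], fx$stack$layers[[nm]]$values[8, 11])
  expect_false(row$.missing)

  # 1 cm inside the boundary -> the boundary cell
  ext <- raster_extent(g)
  row2 <- extract_covariates(cbind(ext[["xmax"]] - 0.01, ext[["ymin"]] + 0.01),
                             fx$stack)
  expect_equal(row2$elevation,
               g$values[nrow(g$values), ncol(g$values)])

  # nodata cell -> flagged missing
  st2 <- fx$stack
  v <- st2$layers$elevation$values; v[8, 11] <- NA
  st2$layers$elevation <- raster_like(st2$layers$elevation, v)
  expect_true(extract_covariates(cbind(x, y), st2)$.missing)

  expect_error(extract_covariates(cbind(ext[["xmax"]] + 10, y), fx$stack),
               "outside")
})

test_that("rasters round-trip through ESRI ASCII grids", {
  set.seed(6)
  m <- matrix(runif(30), 5, 6); m[2, 3] <- NA
  g <- raster_grid(m, origin = c(1000, 5000), cell_size = 250)
  p <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, p)
  g2 <- read_asc(p)
  expect_equal(g2$values, g$values)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$cell_size, g$cell_size)
})

test_that("vector layers round-trip through GeoJSON", {
  lay <- vector_layer(list(cbind(c(0, 100, 200), c(0, 50, 0)),
                           cbind(c(10, 20), c(30, 40))),
                      attributes = data.frame(id = 1:2,
                                              class = c("highway", "gravel")))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(lay, p)
  lay2 <- read_geojson(p)
  expect_equal(lay2$geometries, lay$geometries)
  expect_equal(lay2$attributes$class, lay$attributes$class)
})

test_that("bilinear and nearest resampling land on a common grid", {
  src <- raster_grid(matrix(as.numeric(1:16), 4, 4), origin = c(0, 400),
                     cell_size = 100)
  dst <- raster_grid(matrix(0, 8, 8), origin = c(0, 400), cell_size = 50)
  rn <- resample_to(src, dst, "nearest")
  rb <- resample_to(src, dst, "bilinear")
  expect_equal(dim(rn$values), c(8L, 8L))
  # nearest preserves the value set; bilinear stays within the range
  expect_true(all(rn$values %in% src$values))
  expect_true(all(rb$values >= min(src$values) &
                    rb$values <= max(src$values)))
})
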