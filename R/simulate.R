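#' Default biological-season calendar
#'
#' Month-day windows for the four phases of the dispersal year: winter
#' residency Jan 1-Mar 31, spring movements Apr 1-Aug 31, summer residency
#' Jul 1-Aug 31 (deliberately overlapping spring, as the residency and
#' movement definitions do), autumn movements Sep 1-Nov 30. Windows are
#' month-day strings so they apply to any year.
#'
#' @return data.frame with columns `name`, `start`, `end`, `kind`.
#' @export
default_phase_calendar <- function() {
  data.frame(
    name  = c("winter_residency", "spring_movement",
              "summer_residency", "autumn_movement"),
    start = c("01-01", "04-01", "07-01", "09-01"),
    end   = c("03-31", "08-31", "08-31", "11-30"),
    kind  = c("residency", "movement", "residency", "movement"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The stated world of the synthetic study system: 54 young male elk on a
#' 2-hour fix schedule for one calendar year, on a 120 x 120 cell landscape
#' at 250 m resolution (30 x 30 km; a desk-scale stand-in for the 46,000 km2
#' study region). Movement is a two-regime mixture: short undirected
#' foraging/resting moves (exponential speeds, mean 3 m/min) and long
#' forward-persistent travel steps (mean 40 m/min) whose endpoints are
#' selected among candidates with probability proportional to
#' exp(beta_ssf . x). Ground-truth selection coefficients are on the
#' capped-and-standardized layer scale (see [standardize_stack()]).
#'
#' @param seed master integer seed.
#' @param n_animals number of simulated animals.
#' @param fix_interval fix interval in minutes.
#' @param n_rows,n_cols,cell_size landscape grid (cells and metres).
#' @param year calendar year simulated.
#' @param beta_rsf_winter,beta_rsf_summer named residency selection
#'   coefficients (layer names / land-cover class names).
#' @param beta_ssf_spring,beta_ssf_autumn named movement selection
#'   coefficients.
#' @param behaviour list with `p_travel` (probability a movement-window fix
#'   is a travel step), `encamped_mean_speed` and `travel_mean_speed`
#'   (m/min), `travel_persistence` (von Mises-like turn concentration; turn
#'   sd = 1/sqrt(persistence) radians) and `K_candidates` (candidate
#'   endpoints per travel step). `K_candidates` must be large for the
#'   simulator to honour its contract that endpoint choice follows the
#'   exponential selection form: choosing the best of a *small* candidate
#'   set saturates (the winner's advantage is capped at probability one),
#'   which attenuates fitted coefficients by 10-20% at K = 30; K = 300
#'   keeps the distortion inside estimation noise.
#' @param autumn_dropout probability an animal is lost (hunting mortality)
#'   at a uniform date between Sep 15 and Nov 30.
#' @param caps road-distance caps in metres (selection is flat beyond them).
#' @param field_sigma spatial correlation range of the landscape fields, in
#'   cells.
#' @param calendar phase calendar, see [default_phase_calendar()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_animals = 54L,
    fix_interval = 120,
    n_rows = 120L, n_cols = 120L, cell_size = 250,
    year = 2009L,
    beta_rsf_winter = c(elevation = -1.0, elevation_sq = -0.5,
                        ruggedness = 0.4, ndvi_winter = 0.9, canopy = -0.4,
                        grassland = 0.5, deciduous = 0.4,
                        shrub = 0.4, cropland = 0.4),
    beta_rsf_summer = c(elevation = 0.5, elevation_sq = -0.5,
                        ruggedness = -0.3, ndvi_summer = 0.9, canopy = -0.3,
                        deciduous = 0.4, mixed = 0.4,
                        shrub = 0.4, grassland = 0.4, cropland = -0.4),
    beta_ssf_spring = c(ruggedness = -0.4, canopy = -0.5,
                        dist_highway = 0.8, dist_gravel = 0.4,
                        deciduous = 0.4, grassland = 0.4),
    beta_ssf_autumn = c(ruggedness = 0.3, canopy = 0.4,
                        dist_highway = 0.8, dist_gravel = 0.4,
                        other = -0.5),
    behaviour = list(p_travel = 0.3, encamped_mean_speed = 3,
                     travel_mean_speed = 40, travel_persistence = 4,
                     K_candidates = 300L),
    autumn_dropout = 0.25,
    caps = c(dist_highway = 2000, dist_gravel = 1000),
    field_sigma = 10,
    calendar = default_phase_calendar()) {
  b <- behaviour
  stopifnot(b$p_travel >= 0, b$p_travel <= 1,
            b$encamped_mean_speed > 0, b$travel_mean_speed > 0,
            b$encamped_mean_speed < b$travel_mean_speed,
            b$travel_persistence > 0,
            autumn_dropout >= 0, autumn_dropout <= 1,
            n_rows >= 50, n_cols >= 50, cell_size > 0, fix_interval > 0)
  structure(list(seed = as.integer(seed), n_animals = as.integer(n_animals),
                 fix_interval = fix_interval, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), cell_size = cell_size,
                 year = as.integer(year),
                 beta_rsf_winter = beta_rsf_winter,
                 beta_rsf_summer = beta_rsf_summer,
                 beta_ssf_spring = beta_ssf_spring,
                 beta_ssf_autumn = beta_ssf_autumn,
                 behaviour = b, autumn_dropout = autumn_dropout,
                 caps = caps, field_sigma = field_sigma,
                 calendar = calendar),
            class = "sim_config")
}

# row-stochastic Gaussian smoothing matrix for a lattice of size n
.smoother <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

# smoothed standard-normal random field (zero mean, unit sd over cells)
.smooth_field <- function(nr, nc, sigma) {
  f <- .smoother(nr, sigma) %*% matrix(rnorm(nr * nc), nr, nc) %*%
    t(.smoother(nc, sigma))
  (f - mean(f)) / sd(as.vector(f))
}

# smoothed 1-d standard-normal series
.smooth_series <- function(n, sigma) {
  s <- .smoother(n, sigma) %*% rnorm(n)
  as.vector((s - mean(s)) / sd(s))
}

#' Generate a synthetic mountain landscape
#'
#' Builds a seeded, fully deterministic landscape emulating the structure of
#' a Rocky Mountain foothills study region: a DEM rising westward within
#' 900-3400 m, canopy cover, winter and summer NDVI (summer greener on
#' average), a 7-class land-cover map (conifer reference class), one
#' east-west highway and two gravel roads, plus derived ruggedness, slope,
#' aspect and road-distance layers.
#'
#' @param config a [sim_config()].
#' @return a `landscape_stack` with layers `elevation`, `ruggedness`,
#'   `slope`, `aspect`, `canopy`, `ndvi_winter`, `ndvi_summer`, `landcover`
#'   (categorical), `dist_highway`, `dist_gravel`, and road polylines in
#'   `$vectors`.
#' @export
generate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  sg <- config$field_sigma
  origin <- c(0, nr * cs)
  W <- nc * cs; H <- nr * cs

  f1 <- .smooth_field(nr, nc, sg); f2 <- .smooth_field(nr, nc, sg)
  f3 <- .smooth_field(nr, nc, sg); f4 <- .smooth_field(nr, nc, sg)
  f5 <- .smooth_field(nr, nc, sg)

  ramp <- matrix(rep((nc - seq_len(nc) + 0.5) / nc, each = nr), nr, nc)
  rampz <- (ramp - mean(ramp)) / sd(as.vector(ramp))
  demz <- rampz * 1.1 + f1
  dem <- 900 + (demz - min(demz)) / (max(demz) - min(demz)) * 2500
  zdem <- (dem - mean(dem)) / sd(as.vector(dem))

  canopy <- 100 * stats::plogis(0.9 * f2 + 0.5 * zdem)
  ndvi_w <- 0.5 * tanh(0.3 + 0.35 * f3 - 0.45 * zdem)
  ndvi_s <- pmax(pmin(ndvi_w + 0.25 + 0.08 * f4, 0.95), -1)

  # land cover: quantile slices of a smooth latent field guarantee all seven
  # classes are present with fixed shares (urban/'other' and cropland low,
  # conifer towards the high, western end)
  latent <- 0.65 * f5 + 0.35 * zdem
  shares <- c(other = 0.05, cropland = 0.10, grassland = 0.17,
              deciduous = 0.13, shrub = 0.12, mixed = 0.15, conifer = 0.28)
  cuts <- quantile(latent, probs = cumsum(shares)[-length(shares)])
  slice <- findInterval(latent, cuts) + 1L  # 1..7 in `shares` order
  levels <- c("conifer", "deciduous", "mixed", "shrub", "grassland",
              "cropland", "other")
  code_of <- match(names(shares), levels)
  lc <- matrix(code_of[slice], nr, nc)

  grid <- raster_grid(dem, origin = origin, cell_size = cs)

  # roads follow terrain the way real ones do: the highway tracks the
  # lowest band of each column (the valley bottom), so near-road cells are
  # otherwise attractive habitat - the geometry that makes the road-barrier
  # counterfactual meaningful
  Sm <- .smoother(nc, sg)
  valley_row <- as.vector(Sm %*% apply(dem, 2, which.min))
  highway <- vector_layer(list(cbind(
    x = raster_x(grid),
    y = pmin(pmax(grid$origin[2] - (valley_row - 0.5) * cs, 0.02 * H),
             0.98 * H))),
    attributes = data.frame(id = 1, class = "highway"))
  # N-S gravel road: valley of the detrended DEM (east-west ramp removed)
  det <- dem - matrix(rep(colMeans(dem), each = nr), nr, nc)
  band <- seq.int(max(1L, floor(0.15 * nc)), ceiling(0.85 * nc))
  g1_col <- band[apply(det[, band, drop = FALSE], 1, which.min)]
  g1_col <- as.vector(.smoother(nr, sg) %*% g1_col)
  g1 <- cbind(x = pmin(pmax((g1_col - 0.5) * cs, 0.02 * W), 0.98 * W),
              y = raster_y(grid))
  tt <- seq(0, 1, length.out = nc)
  g2 <- cbind(x = tt * (W - 2 * cs) + cs,
              y = pmin(pmax(H * (0.85 - 0.65 * tt) +
                              0.05 * H * .smooth_series(nc, sg), 0.02 * H),
                       0.98 * H))
  gravel <- vector_layer(list(g1, g2),
                         attributes = data.frame(id = 1:2, class = "gravel"))

  lay <- function(v) raster_like(grid, v)
  lc_r <- lay(lc)
  attr(lc_r, "levels") <- levels
  stack <- landscape_stack(
    layers = list(
      elevation = lay(dem),
      canopy = lay(canopy),
      ndvi_winter = lay(ndvi_w),
      ndvi_summer = lay(ndvi_s),
      landcover = lc_r),
    layer_type = c(landcover = "categorical"),
    vectors = list(highway = highway, gravel = gravel))
  stack$layers$ruggedness <- terrain_ruggedness(stack$layers$elevation)
  stack$layers$slope <- terrain_slope(stack$layers$elevation)
  stack$layers$aspect <- terrain_aspect(stack$layers$elevation)
  stack$layers$dist_highway <- distance_to_features(highway, grid)
  stack$layers$dist_gravel <- distance_to_features(gravel, grid)
  stack$layer_type[c("ruggedness", "slope", "aspect",
                     "dist_highway", "dist_gravel")] <- "continuous"
  stack
}

#' Draw residency fixes from an exponential selection surface
#'
#' Samples point locations with density proportional to
#' `w(x) = exp(beta . x)` over the valid cells of the stack (the generative
#' inverse of the resource selection function), uniform within a cell.
#'
#' @param stack a `landscape_stack`.
#' @param beta named coefficients on the capped/standardized layer scale
#'   (see [standardize_stack()]); `beta = NULL` or all zero gives uniform
#'   points.
#' @param n number of points (`0` returns an empty set).
#' @param seed integer seed.
#' @param caps road-distance caps passed to the layer preparation.
#' @return data.frame with columns `x`, `y`.
#' @export
simulate_residency_fixes <- function(stack, beta, n, seed = 1,
                                     caps = c(dist_highway = 2000,
                                              dist_gravel = 1000)) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  if (is.null(beta) || length(beta) == 0)
    beta <- c(elevation = 0)
  s <- .truth_score_matrix(stack, beta, caps = caps)
  valid <- which(!is.na(s))
  if (length(valid) == 0) stop("stack has no valid cells")
  set.seed(seed)
  w <- exp(s[valid] - max(s[valid], na.rm = TRUE))
  pick <- valid[sample.int(length(valid), n, replace = TRUE, prob = w)]
  grid <- stack$layers[[1]]
  nrg <- nrow(grid$values)
  row <- ((pick - 1L) %% nrg) + 1L
  col <- ((pick - 1L) %/% nrg) + 1L
  cs <- grid$cell_size
  data.frame(
    x = grid$origin[1] + (col - 1) * cs + runif(n) * cs,
    y = grid$origin[2] - (row - 1) * cs - runif(n) * cs)
}

# generator regime code per step: residency windows take precedence over the
# overlapping spring window (travel is only proposed outside residency)
.phase_codes <- function(md, calendar) {
  inw <- function(name) {
    w <- calendar[calendar$name == name, ]
    md >= w$start & md <= w$end
  }
  code <- integer(length(md))
  code[inw("spring_movement")] <- 1L
  code[inw("autumn_movement")] <- 2L
  code[inw("winter_residency") | inw("summer_residency")] <- 0L
  code
}

#' Simulate one animal's telemetry track
#'
#' One calendar year of fixes at the configured interval. Within residency
#' windows every step is an encamped move; within movement windows each fix
#' is encamped with probability `1 - p_travel`, otherwise a travel step
#' whose endpoint is selected among `K_candidates` proposals with
#' probability proportional to `exp(beta_ssf . x)`. Animals may be lost in
#' autumn with probability `autumn_dropout` (truncated track).
#'
#' @param stack a `landscape_stack` (the one the config's betas refer to).
#' @param config a [sim_config()].
#' @param animal_id identifier recorded on every fix.
#' @param start optional (x, y) start location; default: drawn from the
#'   winter residency selection surface.
#' @param seed integer seed (default derived from the config seed and
#'   animal id).
#' @return data.frame: `animal_id`, `timestamp` (POSIXct UTC), `x`, `y`,
#'   `regime` (`"encamped"`/`"travel"`, `NA` for the first fix).
#' @export
simulate_track <- function(stack, config, animal_id = "elk01", start = NULL,
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed))
    seed <- (config$seed * 1009L + sum(utf8ToInt(as.character(animal_id)))) %%
      2147483647L
  s_spring <- .truth_score_matrix(stack, config$beta_ssf_spring, config$caps)
  s_autumn <- .truth_score_matrix(stack, config$beta_ssf_autumn, config$caps)

  n_fix <- as.integer(365 * 24 * 60 / config$fix_interval)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$year), tz = "UTC")
  ts <- t0 + (seq_len(n_fix) - 1) * config$fix_interval * 60
  md <- format(ts, "%m-%d")
  phase <- .phase_codes(md[-n_fix], config$calendar)

  ext <- raster_extent(stack$layers[[1]])
  set.seed(seed)
  if (is.null(start)) {
    sp <- simulate_residency_fixes(stack, config$beta_rsf_winter, 1,
                                   seed = seed, caps = config$caps)
    start <- c(sp$x, sp$y)
  }
  if (start[1] < ext["xmin"] || start[1] > ext["xmax"] ||
      start[2] < ext["ymin"] || start[2] > ext["ymax"])
    stop("start location lies outside the landscape extent")

  b <- config$behaviour
  dt <- config$fix_interval
  set.seed(seed + 1L)
  m <- sim_track_cpp(s_spring, s_autumn, phase,
                     start[1], start[2],
                     stack$layers[[1]]$origin[1], stack$layers[[1]]$origin[2],
                     stack$layers[[1]]$cell_size,
                     as.integer(b$K_candidates), b$p_travel,
                     b$encamped_mean_speed * dt, b$travel_mean_speed * dt,
                     1 / sqrt(b$travel_persistence), 20L)
  keep <- seq_len(n_fix)
  if (runif(1) < config$autumn_dropout) {
    lo <- as.POSIXct(sprintf("%d-09-15", config$year), tz = "UTC")
    hi <- as.POSIXct(sprintf("%d-11-30", config$year), tz = "UTC")
    cut <- lo + runif(1) * as.numeric(difftime(hi, lo, units = "secs"))
    keep <- which(ts <= cut)
  }
  data.frame(animal_id = animal_id, timestamp = ts[keep],
             x = m[keep, 1], y = m[keep, 2],
             regime = c("encamped", "travel")[m[keep, 3] + 1],
             stringsAsFactors = FALSE)
}

#' Simulate the full telemetry data set
#'
#' One track per configured animal, with per-animal seeds derived from the
#' master seed.
#'
#' @param stack a `landscape_stack`.
#' @param config a [sim_config()].
#' @return data.frame of stacked tracks (see [simulate_track()]).
#' @export
simulate_telemetry <- function(stack, config = sim_config()) {
  out <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    id <- sprintf("elk%02d", a)
    out[[a]] <- simulate_track(stack, config, animal_id = id,
                               seed = (config$seed * 7919L + a * 104729L) %%
                                 2147483647L)
  }
  do.call(rbind, out)
}

#' Write telemetry to CSV (ISO-8601 timestamps)
#' @param track telemetry data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_telemetry <- function(track, path) {
  out <- track
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d
}
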