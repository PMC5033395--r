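#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end connectivity analysis: the
#' synthetic-world configuration, the four model design specifications
#' (winter/summer RSF, spring/autumn SSF), sampling and validation
#' settings, and the corridor thresholds. Defaults follow the study design
#' they emulate: availability ratio 10, ten random steps per stratum,
#' 50 m / 10 degree step bins, 800 (spring) and 600 (autumn) subsampled
#' steps per animal, upper-quartile cores, 80 km maximum pairing distance,
#' and a cost-weighted-distance display cutoff of 200,000.
#'
#' @param seed master seed; all per-stage seeds derive from it.
#' @param out_dir artifact directory.
#' @param sim a [sim_config()] describing the synthetic world.
#' @param availability_ratio available points per used point.
#' @param rsf_max_used cap on used fixes per residency season (desk-scale
#'   runtime control; the fit subsamples deterministically beyond it).
#' @param n_subsample_spring,n_subsample_autumn steps per animal entering
#'   the broken-stick fit.
#' @param n_bins_broken_stick histogram bins for the broken stick.
#' @param R_random random steps per stratum.
#' @param bin_len,bin_turn step-length (m) and turn-angle (deg) bin widths.
#' @param boyce_k,boyce_bins RSF cross-validation folds and score bins.
#' @param fortin_reps,fortin_train_frac SSF cross-validation settings.
#' @param rsf_random_intercept fit the RSF GLMM (TRUE) or the fixed-effects
#'   fallback; cross-validation always uses the fast fixed-effects path.
#' @param core_quantile,min_core_cells core-area extraction settings.
#' @param max_cores_per_season cap on cores kept per season (largest first).
#' @param isopleth_level winter source isopleth level.
#' @param max_pair_km core pairing limit (km).
#' @param cwd_cutoff corridor crop value (cost units).
#' @param epsilon friction floor.
#' @param scenarios scenarios to run.
#' @param n_road_segments highway segments for the permeability test.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "elkscape_run",
                            sim = sim_config(seed = seed),
                            availability_ratio = 10,
                            rsf_max_used = 2000,
                            n_subsample_spring = 800,
                            n_subsample_autumn = 600,
                            n_bins_broken_stick = 50,
                            R_random = 10, bin_len = 50, bin_turn = 10,
                            boyce_k = 5, boyce_bins = 10,
                            fortin_reps = 100, fortin_train_frac = 0.8,
                            rsf_random_intercept = TRUE,
                            core_quantile = 0.75, min_core_cells = 40,
                            max_cores_per_season = 8,
                            isopleth_level = 0.5,
                            max_pair_km = 80, cwd_cutoff = 200000,
                            epsilon = 1e-6,
                            scenarios = c("actual", "no_roads"),
                            n_road_segments = 20) {
  stopifnot(availability_ratio > 0, R_random > 0, core_quantile > 0,
            core_quantile < 1, max_pair_km > 0, cwd_cutoff > 0, epsilon > 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 availability_ratio = availability_ratio,
                 rsf_max_used = rsf_max_used,
                 n_subsample_spring = n_subsample_spring,
                 n_subsample_autumn = n_subsample_autumn,
                 n_bins_broken_stick = n_bins_broken_stick,
                 R_random = R_random, bin_len = bin_len, bin_turn = bin_turn,
                 boyce_k = boyce_k, boyce_bins = boyce_bins,
                 fortin_reps = fortin_reps,
                 fortin_train_frac = fortin_train_frac,
                 rsf_random_intercept = rsf_random_intercept,
                 core_quantile = core_quantile,
                 min_core_cells = min_core_cells,
                 max_cores_per_season = max_cores_per_season,
                 isopleth_level = isopleth_level,
                 max_pair_km = max_pair_km, cwd_cutoff = cwd_cutoff,
                 epsilon = epsilon, scenarios = scenarios,
                 n_road_segments = n_road_segments),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `pipeline_config_load` returns a `pipeline_config`;
#'   `pipeline_config_save` the path, invisibly.
#' @export
pipeline_config_save <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  for (nm in c("beta_rsf_winter", "beta_rsf_summer",
               "beta_ssf_spring", "beta_ssf_autumn", "caps"))
    x$sim[[nm]] <- as.list(x$sim[[nm]])  # keep names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname pipeline_config_save
#' @export
pipeline_config_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- x$sim
  sim <- sim_config(
    seed = s$seed, n_animals = s$n_animals, fix_interval = s$fix_interval,
    n_rows = s$n_rows, n_cols = s$n_cols, cell_size = s$cell_size,
    year = s$year,
    beta_rsf_winter = unlist(s$beta_rsf_winter),
    beta_rsf_summer = unlist(s$beta_rsf_summer),
    beta_ssf_spring = unlist(s$beta_ssf_spring),
    beta_ssf_autumn = unlist(s$beta_ssf_autumn),
    behaviour = as.list(unlist(s$behaviour)),
    autumn_dropout = s$autumn_dropout, caps = unlist(s$caps),
    field_sigma = s$field_sigma,
    calendar = as.data.frame(s$calendar, stringsAsFactors = FALSE))
  pipeline_config(
    seed = x$seed, out_dir = x$out_dir, sim = sim,
    availability_ratio = x$availability_ratio,
    rsf_max_used = x$rsf_max_used,
    n_subsample_spring = x$n_subsample_spring,
    n_subsample_autumn = x$n_subsample_autumn,
    n_bins_broken_stick = x$n_bins_broken_stick,
    R_random = x$R_random, bin_len = x$bin_len, bin_turn = x$bin_turn,
    boyce_k = x$boyce_k, boyce_bins = x$boyce_bins,
    fortin_reps = x$fortin_reps, fortin_train_frac = x$fortin_train_frac,
    rsf_random_intercept = x$rsf_random_intercept,
    core_quantile = x$core_quantile, min_core_cells = x$min_core_cells,
    max_cores_per_season = x$max_cores_per_season,
    isopleth_level = x$isopleth_level,
    max_pair_km = x$max_pair_km, cwd_cutoff = x$cwd_cutoff,
    epsilon = x$epsilon, scenarios = x$scenarios,
    n_road_segments = x$n_road_segments)
}

# deterministic per-stage seeds derived from the master seed
.stage_seed <- function(config, stage) {
  idx <- match(stage, .pipeline_stages)
  (config$seed * 2654435L + idx * 97L) %% 2147483647L
}

.pipeline_stages <- c("simulate", "phases", "rsf", "ssf", "friction",
                      "corridors", "roads")

#' Default model design specifications
#'
#' Residency models use elevation, ruggedness, seasonal NDVI and canopy
#' (with quadratics) plus land cover against the conifer reference;
#' movement models use ruggedness, canopy and the two capped road
#' distances plus land cover.
#'
#' @param season one of `"winter"`, `"summer"`, `"spring"`, `"autumn"`.
#' @param quadratic include quadratic terms (default TRUE).
#' @return a [design_spec()].
#' @export
default_design <- function(season, quadratic = TRUE) {
  switch(season,
    winter = design_spec(
      continuous = c("elevation", "ruggedness", "ndvi_winter", "canopy"),
      quadratic = quadratic, categorical = "landcover"),
    summer = design_spec(
      continuous = c("elevation", "ruggedness", "ndvi_summer", "canopy"),
      quadratic = quadratic, categorical = "landcover"),
    spring = ,
    autumn = design_spec(
      continuous = c("ruggedness", "canopy", "dist_highway", "dist_gravel"),
      quadratic = quadratic, categorical = "landcover"),
    stop("unknown season '", season, "'"))
}

# ---- artifact I/O helpers ----

.write_landscape <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(layers = names(stack$layers),
               layer_type = as.list(stack$layer_type),
               levels = list())
  for (nm in names(stack$layers)) {
    write_asc(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
    if (stack$layer_type[[nm]] == "categorical")
      meta$levels[[nm]] <- attr(stack$layers[[nm]], "levels")
  }
  for (nm in names(stack$vectors))
    write_geojson(stack$vectors[[nm]], file.path(dir, paste0(nm, ".geojson")))
  meta$vectors <- names(stack$vectors)
  jsonlite::write_json(meta, file.path(dir, "landscape_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a landscape stack written by the pipeline
#' @param dir directory holding `landscape_meta.json`, `.asc` layers and
#'   `.geojson` vectors.
#' @return a `landscape_stack`.
#' @export
load_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape_meta.json"),
                              simplifyVector = TRUE)
  layers <- list()
  for (nm in meta$layers) {
    l <- read_asc(file.path(dir, paste0(nm, ".asc")))
    if (!is.null(meta$levels[[nm]])) attr(l, "levels") <- meta$levels[[nm]]
    layers[[nm]] <- l
  }
  vectors <- list()
  for (nm in meta$vectors)
    vectors[[nm]] <- read_geojson(file.path(dir, paste0(nm, ".geojson")))
  landscape_stack(layers, layer_type = unlist(meta$layer_type),
                  vectors = vectors)
}

.manifest <- function(config, stage, inputs, outputs, extra = list()) {
  man <- c(list(stage = stage, seed = .stage_seed(config, stage),
                master_seed = config$seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                outputs = outputs),
           extra)
  jsonlite::write_json(man,
                       file.path(config$out_dir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

.need <- function(config, paths, stage_hint) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing upstream artifact(s): ",
         paste(basename(missing), collapse = ", "),
         "; run stage '", stage_hint, "' first")
  invisible(TRUE)
}

.write_model <- function(model, path_prefix) {
  write.csv(coef_table(model), paste0(path_prefix, "_coefs.csv"),
            row.names = FALSE)
  meta <- list(model_kind = model$model_kind, loglik = model$loglik,
               random_intercept_variance = model$random_intercept_variance,
               fallback_glm = isTRUE(model$fallback_glm),
               center = as.list(model$learned$center),
               scale = as.list(model$learned$scale),
               levels = model$learned$levels)
  elim <- attr(model, "elimination")
  if (!is.null(elim) && nrow(elim)) meta$eliminated <- elim$dropped
  jsonlite::write_json(meta, paste0(path_prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

# ---- stages ----

.stage_simulate <- function(config) {
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  stack <- generate_landscape(config$sim)
  .write_landscape(stack, file.path(od, "landscape"))
  trk <- simulate_telemetry(stack, config$sim)
  write_telemetry(trk, file.path(od, "telemetry.csv"))
  truth <- do.call(rbind, lapply(
    c("beta_rsf_winter", "beta_rsf_summer",
      "beta_ssf_spring", "beta_ssf_autumn"),
    function(nm) data.frame(model = nm, term = names(config$sim[[nm]]),
                            beta = unname(config$sim[[nm]]))))
  write.csv(truth, file.path(od, "truth_betas.csv"), row.names = FALSE)
  .manifest(config, "simulate", character(0),
            c("landscape/", "telemetry.csv", "truth_betas.csv"),
            list(n_animals = config$sim$n_animals, n_fixes = nrow(trk)))
  invisible(od)
}

.stage_phases <- function(config) {
  od <- config$out_dir
  .need(config, file.path(od, "telemetry.csv"), "simulate")
  trk <- read_telemetry(file.path(od, "telemetry.csv"))
  steps <- compute_steps(trk, calendar = config$sim$calendar)
  write.csv(steps, file.path(od, "steps.csv"), row.names = FALSE)
  nd <- do.call(rbind, lapply(split(trk, trk$animal_id), function(tr) {
    cbind(animal_id = tr$animal_id[1], net_displacement(tr))
  }))
  write.csv(nd, file.path(od, "net_displacement.csv"), row.names = FALSE)
  .manifest(config, "phases", file.path(od, "telemetry.csv"),
            c("steps.csv", "net_displacement.csv"),
            list(n_steps = nrow(steps)))
  invisible(od)
}

.rsf_season_data <- function(config, season) {
  od <- config$out_dir
  trk <- read_telemetry(file.path(od, "telemetry.csv"))
  trk <- assign_phase(trk, config$sim$calendar)
  win <- paste0(season, "_residency")
  used <- trk[trk[[win]], , drop = FALSE]
  seed <- .stage_seed(config, "rsf") + match(season, c("winter", "summer"))
  if (nrow(used) > config$rsf_max_used) {
    set.seed(seed)
    used <- used[sample(nrow(used), config$rsf_max_used), , drop = FALSE]
  }
  mcp <- minimum_convex_polygon(trk[, c("x", "y")])
  avail <- sample_availability(used[, c("x", "y")], mcp,
                               ratio = config$availability_ratio,
                               seed = seed + 10L)
  list(used = used, avail = avail, mcp = mcp, seed = seed)
}

.stage_rsf <- function(config) {
  od <- config$out_dir
  .need(config, c(file.path(od, "telemetry.csv"),
                  file.path(od, "landscape", "landscape_meta.json")),
        "simulate")
  stack <- load_landscape(file.path(od, "landscape"))
  for (season in c("winter", "summer")) {
    d <- .rsf_season_data(config, season)
    spec <- default_design(season)
    cov_u <- extract_covariates(d$used[, c("x", "y")], stack)
    cov_a <- extract_covariates(d$avail, stack)
    lc_levels <- layer_levels(stack, "landcover")
    prep <- function(cov, ids, used) {
      cov$landcover <- lc_levels[cov$landcover]
      cov$animal_id <- ids
      cov$used <- used
      cov[!cov$.missing, setdiff(names(cov), ".missing"), drop = FALSE]
    }
    tab_u <- prep(cov_u, d$used$animal_id, 1)
    tab_a <- prep(cov_a, "available", 0)
    scr <- screen_collinearity(tab_u[, spec$continuous, drop = FALSE])
    spec$continuous <- scr$retained
    spec$quadratic <- spec$quadratic[scr$retained]
    dat <- rbind(tab_u, tab_a)
    fit <- fit_rsf(dat, spec,
                   random_intercept = config$rsf_random_intercept)
    fit <- eliminate_by_wald(fit, dat,
                             random_intercept = config$rsf_random_intercept)
    .write_model(fit, file.path(od, paste0("rsf_", season)))
    surf <- prediction_surface(fit, stack)
    write_asc(surf, file.path(od, paste0("rsf_", season, "_surface.asc")))
    cv <- boyce_cv(tab_u, tab_a, fit$spec, k = config$boyce_k,
                   n_bins = config$boyce_bins, seed = d$seed + 20L,
                   random_intercept = FALSE)
    write.csv(data.frame(fold = seq_along(cv$rho), rho = cv$rho),
              file.path(od, paste0("rsf_", season, "_boyce.csv")),
              row.names = FALSE)
  }
  .manifest(config, "rsf", file.path(od, "telemetry.csv"),
            c("rsf_winter_coefs.csv", "rsf_summer_coefs.csv",
              "rsf_winter_surface.asc", "rsf_summer_surface.asc"))
  invisible(od)
}

.stage_ssf <- function(config) {
  od <- config$out_dir
  .need(config, file.path(od, "steps.csv"), "phases")
  stack <- load_landscape(file.path(od, "landscape"))
  steps <- read.csv(file.path(od, "steps.csv"), stringsAsFactors = FALSE)
  lc_levels <- layer_levels(stack, "landcover")
  thresholds <- list()
  for (season in c("spring", "autumn")) {
    win <- paste0(season, "_movement")
    ss <- steps[steps[[win]] == TRUE | steps[[win]] == "TRUE", , drop = FALSE]
    n_sub <- if (season == "spring") config$n_subsample_spring else
      config$n_subsample_autumn
    seed <- .stage_seed(config, "ssf") + match(season, c("spring", "autumn"))
    sub <- suppressWarnings(subsample_steps(ss, n_sub, seed = seed))
    bs <- broken_stick_threshold(sub$speed,
                                 n_bins = config$n_bins_broken_stick)
    thresholds[[season]] <- bs$threshold
    long <- filter_long_steps(sub, bs)
    strata <- sample_random_steps(long, stack, R = config$R_random,
                                  bin_len = config$bin_len,
                                  bin_turn = config$bin_turn,
                                  seed = seed + 10L)
    strata$landcover <- lc_levels[strata$landcover]
    spec <- default_design(season)
    scr <- screen_collinearity(
      strata[strata$used == 1, spec$continuous, drop = FALSE])
    spec$continuous <- scr$retained
    spec$quadratic <- spec$quadratic[scr$retained]
    fit <- fit_ssf(strata, spec)
    fit <- eliminate_by_wald(fit, strata)
    .write_model(fit, file.path(od, paste0("ssf_", season)))
    cv <- fortin_cv(strata, fit$spec, train_frac = config$fortin_train_frac,
                    reps = config$fortin_reps, seed = seed + 20L)
    write.csv(data.frame(mean_rho = cv$mean_rho, lo = cv$ci[1],
                         hi = cv$ci[2], null_mean_rho = cv$null_mean_rho,
                         null_lo = cv$null_ci[1], null_hi = cv$null_ci[2]),
              file.path(od, paste0("ssf_", season, "_fortin.csv")),
              row.names = FALSE)
  }
  write.csv(data.frame(season = names(thresholds),
                       threshold_m_per_min = unlist(thresholds)),
            file.path(od, "broken_stick_thresholds.csv"), row.names = FALSE)
  .manifest(config, "ssf", file.path(od, "steps.csv"),
            c("ssf_spring_coefs.csv", "ssf_autumn_coefs.csv",
              "broken_stick_thresholds.csv"),
            list(thresholds = thresholds))
  invisible(od)
}

.load_model <- function(od, prefix, season) {
  co <- read.csv(file.path(od, sprintf("%s_%s_coefs.csv", prefix, season)),
                 stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(
    file.path(od, sprintf("%s_%s_meta.json", prefix, season)),
    simplifyVector = TRUE)
  terms <- co$term[co$term != "(Intercept)"]
  base <- sub("_sq$", "", terms)
  kind <- ifelse(grepl("_sq$", terms), "quadratic", "linear")
  lc <- names(meta$levels)
  for (v in lc) {
    hit <- grepl(paste0("^", v, "_"), terms)
    base[hit] <- v
    kind[hit] <- "dummy"
  }
  cont <- unique(base[kind != "dummy"])
  spec <- design_spec(
    continuous = cont,
    quadratic = setNames(cont %in% base[kind == "quadratic"], cont),
    categorical = lc,
    levels = meta$levels)
  beta <- setNames(co$beta, co$term)
  structure(list(beta = beta, se = setNames(co$se, co$term),
                 vcov = diag(co$se^2, length(co$se)),
                 loglik = meta$loglik, model_kind = meta$model_kind,
                 random_intercept_variance = meta$random_intercept_variance,
                 spec = spec,
                 learned = list(center = unlist(meta$center),
                                scale = unlist(meta$scale),
                                levels = meta$levels),
                 terms = data.frame(column = terms, base = base,
                                    kind = kind)),
            class = "fitted_model")
}

.stage_friction <- function(config) {
  od <- config$out_dir
  .need(config, file.path(od, "ssf_spring_coefs.csv"), "ssf")
  stack <- load_landscape(file.path(od, "landscape"))
  for (season in c("spring", "autumn")) {
    fit <- .load_model(od, "ssf", season)
    for (scen in config$scenarios) {
      surf <- if (scen == "actual") prediction_surface(fit, stack) else
        no_roads_surface(fit, stack)
      fr <- friction_from_surface(surf, epsilon = config$epsilon,
                                  scenario = scen, season = season)
      write_asc(fr, file.path(od, sprintf("friction_%s_%s.asc",
                                          season, scen)))
    }
  }
  .manifest(config, "friction",
            file.path(od, c("ssf_spring_coefs.csv", "ssf_autumn_coefs.csv")),
            as.vector(outer(c("spring", "autumn"), config$scenarios,
                            function(s, c) sprintf("friction_%s_%s.asc", s, c))))
  invisible(od)
}

.stage_corridors <- function(config) {
  od <- config$out_dir
  .need(config, c(file.path(od, "rsf_winter_surface.asc"),
                  file.path(od, "friction_spring_actual.asc")),
        "friction")
  stack <- load_landscape(file.path(od, "landscape"))
  trk <- read_telemetry(file.path(od, "telemetry.csv"))
  trk <- assign_phase(trk, config$sim$calendar)

  cores <- list()
  for (season in c("winter", "summer")) {
    surf <- read_asc(file.path(od, sprintf("rsf_%s_surface.asc", season)))
    cores[[season]] <- extract_cores(surf, quantile = config$core_quantile,
                                     min_cells = config$min_core_cells,
                                     season = season,
                                     max_cores = config$max_cores_per_season)
  }
  # winter telemetry source polygons (isopleths) join the winter core set
  wfix <- trk[trk$winter_residency, c("x", "y")]
  iso <- density_isopleth(wfix, config$isopleth_level, stack$layers[[1]])
  cores$winter <- merge_core_sets(cores$winter, iso)

  pair_tab <- pair_cores(cores$winter, cores$summer,
                         max_km = config$max_pair_km)
  write.csv(pair_tab, file.path(od, "core_pairs.csv"), row.names = FALSE)
  for (season in c("winter", "summer"))
    .write_cores(cores[[season]], file.path(od, paste0("cores_", season)))

  for (season in c("spring", "autumn")) {
    from <- if (season == "spring") cores$winter else cores$summer
    to <- if (season == "spring") cores$summer else cores$winter
    for (scen in config$scenarios) {
      fr <- read_asc(file.path(od, sprintf("friction_%s_%s.asc",
                                           season, scen)))
      gr <- friction_graph(fr)
      cwd_from <- lapply(from$polygons, function(p)
        cost_weighted_distance(fr, p, graph = gr))
      cwd_to <- lapply(to$polygons, function(p)
        cost_weighted_distance(fr, p, graph = gr))
      nlccs <- list()
      for (k in seq_len(nrow(pair_tab))) {
        i <- if (season == "spring") pair_tab$from[k] else pair_tab$to[k]
        j <- if (season == "spring") pair_tab$to[k] else pair_tab$from[k]
        nc_ <- normalized_corridor(cwd_from[[i]], cwd_to[[j]])
        nlccs[[length(nlccs) + 1L]] <- nc_$nlcc
      }
      if (length(nlccs) == 0) {
        warning("no core pairs within ", config$max_pair_km, " km")
        next
      }
      mosaic <- mosaic_minimum(nlccs)
      cropped <- crop_corridors(mosaic, config$cwd_cutoff)
      write_asc(mosaic, file.path(od, sprintf("corridor_%s_%s.asc",
                                              season, scen)))
      write_asc(cropped, file.path(od, sprintf("corridor_%s_%s_cropped.asc",
                                               season, scen)))
    }
  }
  .manifest(config, "corridors", file.path(od, "core_pairs.csv"),
            "corridor_<season>_<scenario>[_cropped].asc",
            list(n_pairs = nrow(pair_tab),
                 n_winter_cores = length(cores$winter$polygons),
                 n_summer_cores = length(cores$summer$polygons)))
  invisible(od)
}

.write_cores <- function(core_set, prefix) {
  polys <- core_set$polygons
  layer <- vector_layer(lapply(polys, `[[`, "ring"),
                        attributes = data.frame(
                          id = vapply(polys, `[[`, 0L, "id"),
                          n_cells = vapply(polys, `[[`, 0L, "n_cells"),
                          area_km2 = vapply(polys, `[[`, 0, "area") / 1e6),
                        type = "polygon")
  write_geojson(layer, paste0(prefix, ".geojson"))
}

#' Merge two core sets on one grid
#' @param a,b `core_set` objects sharing a grid.
#' @return a `core_set` with ids reassigned.
#' @export
merge_core_sets <- function(a, b) {
  polys <- c(a$polygons, b$polygons)
  for (i in seq_along(polys)) polys[[i]]$id <- i
  structure(list(polygons = polys, grid = a$grid), class = "core_set")
}

.stage_roads <- function(config) {
  od <- config$out_dir
  .need(config, file.path(od, "corridor_spring_actual_cropped.asc"),
        "corridors")
  stack <- load_landscape(file.path(od, "landscape"))
  segs <- split_highways(stack$vectors$highway,
                         n_segments = config$n_road_segments)
  report <- list()
  tests <- list()
  for (season in c("spring", "autumn")) {
    ov <- list()
    for (scen in config$scenarios) {
      corr <- read_asc(file.path(od, sprintf("corridor_%s_%s_cropped.asc",
                                             season, scen)))
      o <- corridor_overlap_length(segs, corr)
      o$season <- season; o$scenario <- scen
      ov[[scen]] <- o
      report[[length(report) + 1L]] <- o
    }
    if (all(c("actual", "no_roads") %in% names(ov))) {
      tt <- paired_t_test(ov$actual$length_in_corridor_km,
                          ov$no_roads$length_in_corridor_km)
      tests[[season]] <- data.frame(
        season = season, t = tt$t, df = tt$df, p = tt$p,
        total_actual_km = sum(ov$actual$length_in_corridor_km),
        total_no_roads_km = sum(ov$no_roads$length_in_corridor_km))
    }
  }
  overlaps <- do.call(rbind, report)
  write.csv(overlaps, file.path(od, "road_overlaps.csv"), row.names = FALSE)
  test_tab <- do.call(rbind, tests)
  write.csv(test_tab, file.path(od, "road_tests.csv"), row.names = FALSE)
  lines <- c("Corridor-highway permeability report", "")
  for (k in seq_len(nrow(test_tab)))
    lines <- c(lines, sprintf(
      "%s: overlap %.1f km (actual) vs %.1f km (no roads); paired t = %.3f, df = %d, p = %.4g",
      test_tab$season[k], test_tab$total_actual_km[k],
      test_tab$total_no_roads_km[k], test_tab$t[k], test_tab$df[k],
      test_tab$p[k]))
  writeLines(lines, file.path(od, "report.txt"))
  .manifest(config, "roads", file.path(od, "road_overlaps.csv"),
            c("road_overlaps.csv", "road_tests.csv", "report.txt"))
  invisible(od)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (landscape + telemetry), `phases` (steps and net
#' displacement), `rsf` (residency models + validation + surfaces), `ssf`
#' (broken stick, strata, movement models + validation), `friction`
#' (4 surfaces: 2 seasons x 2 scenarios), `corridors` (cores, pairs,
#' normalised corridors, mosaics), `roads` (segment overlaps and paired
#' t-tests). Each stage writes its artifacts plus a JSON manifest into
#' `config$out_dir` and is deterministic given config and seed.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly.
#' @export
run_stage <- function(name, config) {
  if (!name %in% .pipeline_stages)
    stop("unknown stage '", name, "'; valid stages: ",
         paste(.pipeline_stages, collapse = ", "))
  fn <- switch(name, simulate = .stage_simulate, phases = .stage_phases,
               rsf = .stage_rsf, ssf = .stage_ssf,
               friction = .stage_friction, corridors = .stage_corridors,
               roads = .stage_roads)
  message("[elkscape] stage ", name, " ...")
  t0 <- Sys.time()
  out <- fn(config)
  message(sprintf("[elkscape] stage %s done (%.1f s)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns the path of the summary
#' report.
#'
#' @param config a [pipeline_config()].
#' @return list with `out_dir`, `report` (text lines), and `road_tests`
#'   (data.frame), invisibly.
#' @export
run_all <- function(config) {
  for (s in .pipeline_stages) run_stage(s, config)
  report <- readLines(file.path(config$out_dir, "report.txt"))
  invisible(list(out_dir = config$out_dir, report = report,
                 road_tests = read.csv(file.path(config$out_dir,
                                                 "road_tests.csv"))))
}
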