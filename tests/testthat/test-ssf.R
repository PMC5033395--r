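# build a small set of long steps on the shared landscape for stratum tests
shared_long_steps <- function() {
  if (is.null(.fixture_env$long_steps)) {
    fx <- shared_landscape()
    steps <- compute_steps(shared_telemetry(), fx$config$calendar)
    sp <- steps[steps$spring_movement, ]
    bs <- broken_stick_threshold(sp$speed)
    .fixture_env$long_steps <- filter_long_steps(sp, bs)
  }
  .fixture_env$long_steps
}

shared_strata <- function() {
  if (is.null(.fixture_env$strata)) {
    fx <- shared_landscape()
    .fixture_env$strata <- sample_random_steps(shared_long_steps(),
                                               fx$std_stack, seed = 55)
  }
  .fixture_env$strata
}

test_that("strata pair each observed step with matched random steps", {
  strata <- shared_strata()
  per <- table(strata$stratum_id, strata$used)
  expect_true(all(per[, "1"] == 1))      # exactly one used step per stratum
  expect_true(all(per[, "0"] <= 10))     # up to R randoms (edge redraws drop)
  expect_gte(mean(per[, "0"] == 10), 0.85)

  # identical seed reproduces the strata exactly
  fx <- shared_landscape()
  s2 <- sample_random_steps(shared_long_steps(), fx$std_stack, seed = 55)
  expect_identical(strata$x, s2$x)
})

test_that("random-step lengths are drawn from the observed binned distribution", {
  # interior geometry (no boundary redraws): steps start at the centre of a
  # large empty landscape, so drawn lengths mirror the source bins exactly
  big <- landscape_stack(list(
    flat = raster_grid(matrix(0, 200, 200), origin = c(0, 200 * 250),
                       cell_size = 250)))
  set.seed(90)
  n <- 1000
  ctr <- 200 * 250 / 2
  lens <- sample(c(900, 1700, 2600, 4100), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)) + runif(n, 0, 50)
  ang <- runif(n, 0, 2 * pi)
  long <- data.frame(
    animal_id = "a",
    x1 = ctr, y1 = ctr,
    x2 = ctr + lens * cos(ang), y2 = ctr + lens * sin(ang),
    length = lens, speed = lens / 120,
    bearing = ang * 180 / pi,
    prev_bearing = runif(n, -180, 180),
    turn_angle = runif(n, -90, 90))
  strata <- sample_random_steps(long, big, seed = 91)
  breaks <- seq(0, 4500, by = 500)
  obs <- hist(long$length, breaks = breaks, plot = FALSE)$counts
  rnd <- hist(strata$length[strata$used == 0], breaks = breaks,
              plot = FALSE)$counts
  keep <- obs > 0
  p <- stats::chisq.test(rnd[keep], p = obs[keep] / sum(obs[keep]))$p.value
  expect_gt(p, 0.01)
  # turn angles likewise come from the source bins (forward-concentrated)
  expect_true(all(abs(strata$turn_angle[strata$used == 0]) <= 100))

  # forward concentration carries over on the real simulated strata too
  real <- shared_strata()
  expect_lt(mean(abs(real$turn_angle[real$used == 0])),
            mean(abs(runif(10000, -180, 180))))
})

test_that("conditional-logit likelihood is correct at beta = 0 and matches a scan", {
  strata <- shared_strata()
  spec <- design_spec(continuous = "canopy", quadratic = FALSE,
                      caps = numeric(0), standardize = FALSE)
  fit <- fit_ssf(strata, spec)
  # at beta = 0 every stratum is a uniform choice among its candidates
  full <- names(which(table(strata$stratum_id) == 11))
  sub <- strata[strata$stratum_id %in% full, ]
  fit_full <- fit_ssf(sub, spec)
  expect_equal(fit_full$null_loglik, length(full) * log(1 / 11))

  # 1-D likelihood: package fit equals an independent brute-force scan
  X <- matrix(sub$canopy, ncol = 1)
  bb <- seq(fit_full$beta - 0.5, fit_full$beta + 0.5, length.out = 2001)
  ll <- vapply(bb, function(b)
    brute_ssf_loglik(b, X, sub$used, sub$stratum_id), 0)
  expect_lt(abs(bb[which.max(ll)] - fit_full$beta), 1e-3)
  expect_equal(brute_ssf_loglik(fit_full$beta, X, sub$used, sub$stratum_id),
               fit_full$loglik, tolerance = 1e-8)
})

test_that("tiny strata match the brute-force likelihood oracle closely", {
  # 3 strata x (1 used + 1 random), one covariate: 1-D problem (the used
  # step does not always score higher, so the MLE is finite)
  dat <- data.frame(
    stratum_id = rep(1:3, each = 2),
    used = rep(c(1, 0), 3),
    z = c(0.6, -0.2, 0.3, 1.1, -0.4, -1.0))
  spec <- design_spec(continuous = "z", quadratic = FALSE, caps = numeric(0),
                      standardize = FALSE)
  fit <- fit_ssf(dat, spec)
  bb <- seq(-5, 5, by = 1e-4)
  ll <- vapply(bb, function(b)
    brute_ssf_loglik(b, matrix(dat$z), dat$used, dat$stratum_id), 0)
  expect_lt(abs(fit$beta - bb[which.max(ll)]), 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
})

test_that("the conditional likelihood ignores stratum-constant covariates", {
  strata <- shared_strata()
  spec <- design_spec(continuous = "canopy", quadratic = FALSE,
                      caps = numeric(0), standardize = FALSE)
  fit1 <- fit_ssf(strata, spec)
  # add a stratum-constant covariate to canopy: likelihood unchanged
  strata2 <- strata
  shift <- setNames(rnorm(length(unique(strata$stratum_id))),
                    unique(strata$stratum_id))
  strata2$canopy <- strata2$canopy + shift[as.character(strata2$stratum_id)]
  fit2 <- fit_ssf(strata2, spec)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-5)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-5)

  # a purely stratum-constant covariate is inestimable
  strata3 <- strata
  strata3$flat <- shift[as.character(strata3$stratum_id)]
  spec3 <- design_spec(continuous = "flat", quadratic = FALSE,
                       caps = numeric(0), standardize = FALSE)
  expect_error(fit_ssf(strata3, spec3), "inestimable")
})

test_that("SSF recovery from simulated tracks finds the stated selection", {
  fx <- shared_landscape()
  truth <- fx$config$beta_ssf_spring
  strata <- shared_strata()
  strata$landcover <- NULL
  spec <- design_spec(
    continuous = c("ruggedness", "canopy", "dist_highway", "dist_gravel",
                   "deciduous", "grassland"),
    quadratic = FALSE, caps = numeric(0), standardize = FALSE)
  fit <- fit_ssf(strata, spec)
  for (nm in names(truth))
    expect_equal(sign(fit$beta[[nm]]), sign(truth[[nm]]))
})

test_that("case-control cross-validation separates signal from null", {
  strata <- shared_strata()
  spec <- design_spec(
    continuous = c("ruggedness", "canopy", "dist_highway", "dist_gravel"),
    quadratic = FALSE, caps = numeric(0), standardize = FALSE)
  cv <- fortin_cv(strata, spec, reps = 20, seed = 77)
  # rank 1 = highest score: good models pile used steps at rank 1, so the
  # rank-frequency correlation is strongly negative
  expect_lt(cv$mean_rho, -0.5)
  expect_equal(cv$rank_convention, "rank 1 = highest SSF score")
  # exchangeable random steps: the null interval straddles zero
  expect_lt(cv$null_ci[1], 0.25)
  expect_gt(cv$null_ci[2], -0.25)

  cv2 <- fortin_cv(strata, spec, reps = 20, seed = 77)
  expect_identical(cv$rho, cv2$rho)
})
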