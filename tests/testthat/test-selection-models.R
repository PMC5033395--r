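test_that("collinearity screen drops duplicates and near-duplicates", {
  set.seed(10)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  tab <- data.frame(x1 = x1, dup = x1, x2 = x2, x3 = x3)
  scr <- screen_collinearity(tab)
  expect_true(sum(c("x1", "dup") %in% scr$retained) == 1)

  # independent columns all survive
  scr2 <- screen_collinearity(data.frame(x1, x2, x3))
  expect_setequal(scr2$retained, c("x1", "x2", "x3"))

  # near-collinear pair: the later (lower-priority) member is dropped and
  # the recomputed correlation matches a direct computation
  x2b <- x1 + rnorm(n, sd = 0.3)
  expect_gt(abs(cor(x1, x2b)), 0.7)
  scr3 <- screen_collinearity(data.frame(x1 = x1, x2b = x2b, x3 = x3))
  expect_true("x1" %in% scr3$retained)
  expect_false("x2b" %in% scr3$retained)
  expect_equal(as.numeric(sub(".*r=([0-9.]+) .*", "\\1",
                              scr3$dropped$detail[1])),
               round(abs(cor(x1, x2b)), 3), tolerance = 1e-3)

  expect_warning(screen_collinearity(data.frame(x1, const = 1, x2)),
                 "constant")
})

test_that("VIF stage removes linear combinations that pass the pairwise screen", {
  set.seed(11)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  csum <- a + b + rnorm(n, sd = 0.5)  # high VIF, moderate pairwise r
  expect_true(all(abs(cor(cbind(a, b, csum))[upper.tri(diag(3))]) < 0.7))
  scr <- screen_collinearity(data.frame(a, b, csum))
  expect_lt(length(scr$retained), 3)
  expect_true(any(scr$dropped$reason == "vif"))
})

test_that("design construction caps roads, standardizes and dummy-codes", {
  rows <- data.frame(
    dist_highway = c(5000, 1000, 2000), dist_gravel = c(1500, 200, 999),
    ruggedness = c(1, 2, 3),
    landcover = c("conifer", "grassland", "deciduous"))
  spec <- design_spec(continuous = c("dist_highway", "dist_gravel",
                                     "ruggedness"),
                      quadratic = FALSE, categorical = "landcover",
                      standardize = FALSE)
  d <- build_design(rows, spec)
  expect_equal(d$X[, "dist_highway"], c(2000, 1000, 2000))  # capped at 2 km
  expect_equal(d$X[, "dist_gravel"], c(1000, 200, 999))     # capped at 1 km
  # conifer is the reference: all dummies zero in its row
  dummies <- grep("^landcover_", colnames(d$X))
  expect_true(all(d$X[1, dummies] == 0))
  expect_equal(sum(d$X[2, dummies]), 1)

  # standardization constants learned once and reused
  spec2 <- design_spec(continuous = "ruggedness", quadratic = TRUE,
                       caps = numeric(0))
  d2 <- build_design(rows, spec2)
  expect_equal(mean(d2$X[, "ruggedness"]), 0)
  expect_equal(d2$X[, "ruggedness_sq"], d2$X[, "ruggedness"]^2)
  d3 <- build_design(rows[2, , drop = FALSE], spec2, learned = d2$learned)
  expect_equal(d3$X[, "ruggedness"], d2$X[2, "ruggedness"])

  # unseen categorical level at prediction time is an error
  spec3 <- design_spec(categorical = "landcover")
  d4 <- build_design(rows, spec3)
  bad <- rows[1, , drop = FALSE]; bad$landcover <- "lava"
  expect_error(build_design(bad, spec3, learned = d4$learned), "unseen")
})

test_that("availability sampling is uniform within the MCP at 10:1", {
  mcp <- rbind(c(0, 0), c(4000, 0), c(4000, 4000), c(0, 4000), c(0, 0))
  used <- data.frame(x = runif(100, 0, 4000), y = runif(100, 0, 4000))
  av <- sample_availability(used, mcp, ratio = 10, seed = 3)
  expect_equal(nrow(av), 1000)
  expect_true(all(point_in_polygon(av$x, av$y, mcp)))

  # chi-square uniformity over a 4 x 4 partition of the square
  av2 <- sample_availability(data.frame(x = 1:4000, y = 1:4000), mcp,
                             ratio = 10, seed = 4)
  cnt <- table(cut(av2$x, seq(0, 4000, 1000)), cut(av2$y, seq(0, 4000, 1000)))
  p <- stats::chisq.test(as.vector(cnt))$p.value
  expect_gt(p, 0.01)
})

test_that("single-animal RSF collapses to plain logistic regression", {
  set.seed(12)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-1 + 0.8 * x))
  dat <- data.frame(used = y, x = x, animal_id = "one")
  spec <- design_spec(continuous = "x", quadratic = FALSE, caps = numeric(0),
                      standardize = FALSE)
  fit <- fit_rsf(dat, spec)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("RSF recovers known coefficients and nulls give null answers", {
  fx <- shared_landscape()
  truth <- c(elevation = 0.8, canopy = -0.5)
  used <- simulate_residency_fixes(fx$stack, truth, 1500, seed = 21)
  avail <- simulate_residency_fixes(fx$stack, NULL, 15000, seed = 22)
  cu <- extract_covariates(used, fx$std_stack)
  ca <- extract_covariates(avail, fx$std_stack)
  cu$used <- 1; ca$used <- 0
  cu$animal_id <- rep(sprintf("e%02d", 1:10), length.out = nrow(cu))
  ca$animal_id <- "avail"
  dat <- rbind(cu[!cu$.missing, ], ca[!ca$.missing, ])
  spec <- design_spec(continuous = names(truth), quadratic = FALSE,
                      caps = numeric(0), standardize = FALSE)
  fit <- fit_rsf(dat, spec, random_intercept = FALSE)
  expect_lt(abs(fit$beta[["elevation"]] - 0.8) / fit$se[["elevation"]], 2.5)
  expect_lt(abs(fit$beta[["canopy"]] + 0.5) / fit$se[["canopy"]], 2.5)

  # used drawn identically to available: slopes indistinguishable from 0
  used0 <- simulate_residency_fixes(fx$stack, NULL, 1500, seed = 23)
  cu0 <- extract_covariates(used0, fx$std_stack)
  cu0$used <- 1; cu0$animal_id <- "e01"
  dat0 <- rbind(cu0[!cu0$.missing, ], ca[!ca$.missing, ])
  fit0 <- fit_rsf(dat0, spec, random_intercept = FALSE)
  expect_lt(abs(fit0$beta[["elevation"]] / fit0$se[["elevation"]]), 3)
  expect_lt(abs(fit0$beta[["canopy"]] / fit0$se[["canopy"]]), 3)
})

test_that("the GLMM path estimates a real random-intercept variance", {
  set.seed(13)
  n_per <- 120; n_animal <- 15
  b <- c(-1, 0.7)
  u <- rnorm(n_animal, sd = 1)
  dat <- do.call(rbind, lapply(seq_len(n_animal), function(a) {
    x <- rnorm(n_per)
    data.frame(used = rbinom(n_per, 1, stats::plogis(b[1] + u[a] + b[2] * x)),
               x = x, animal_id = sprintf("a%02d", a))
  }))
  spec <- design_spec(continuous = "x", quadratic = FALSE, caps = numeric(0),
                      standardize = FALSE)
  fit <- fit_rsf(dat, spec)
  expect_false(fit$fallback_glm)
  expect_gt(fit$random_intercept_variance, 0.2)
  expect_lt(abs(fit$beta[["x"]] - 0.7) / fit$se[["x"]], 3)
})

test_that("Wald backward elimination drops noise and respects hierarchy", {
  fx <- shared_landscape()
  set.seed(14)
  dropped_noise <- vapply(1:20, function(k) {
    n <- 600
    x <- rnorm(n); z <- rnorm(n)  # z is pure noise
    y <- rbinom(n, 1, stats::plogis(-0.5 + 1.2 * x))
    dat <- data.frame(used = y, x = x, z = z, animal_id = "a")
    spec <- design_spec(continuous = c("x", "z"), quadratic = FALSE,
                        caps = numeric(0), standardize = FALSE)
    fit <- eliminate_by_wald(fit_rsf(dat, spec), dat)
    !"z" %in% names(fit$beta)
  }, TRUE)
  expect_gte(mean(dropped_noise), 0.9)

  # strong quadratic signal: nothing is dropped
  set.seed(15)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-0.5 + x - 0.8 * x^2))
  dat <- data.frame(used = y, x = x, animal_id = "a")
  spec <- design_spec(continuous = "x", quadratic = TRUE, caps = numeric(0),
                      standardize = FALSE)
  fit <- eliminate_by_wald(fit_rsf(dat, spec), dat)
  expect_setequal(setdiff(names(fit$beta), "(Intercept)"), c("x", "x_sq"))

  # intercept-only model comes back unchanged
  dat2 <- data.frame(used = rbinom(200, 1, 0.3), z = rnorm(200),
                     animal_id = "a")
  spec2 <- design_spec(continuous = "z", quadratic = FALSE,
                       caps = numeric(0), standardize = FALSE)
  f0 <- eliminate_by_wald(fit_rsf(dat2, spec2), dat2)
  f1 <- eliminate_by_wald(f0, dat2)
  expect_equal(names(f1$beta), names(f0$beta))
})

test_that("RSF scores follow the exponential form and rescale to max 1", {
  rows <- data.frame(b = c(0, 1, 0, 1))
  spec <- design_spec(continuous = "b", quadratic = FALSE, caps = numeric(0),
                      standardize = FALSE)
  model <- structure(list(
    beta = c(`(Intercept)` = -2, b = log(2)), se = c(1, 1),
    vcov = diag(2), loglik = 0, model_kind = "rsf_glmm",
    spec = spec, learned = NULL,
    terms = data.frame(column = "b", base = "b", kind = "linear")),
    class = "fitted_model")
  s <- rsf_score(model, rows)
  expect_equal(s, c(0.5, 1, 0.5, 1))  # raw {1, 2} rescaled by the max
  expect_equal(max(s), 1)

  model0 <- model; model0$beta["b"] <- 0
  expect_equal(rsf_score(model0, rows), rep(1, 4))

  # invariant to adding a constant to the linear predictor (intercept shift)
  model2 <- model; model2$beta["(Intercept)"] <- 5
  expect_equal(rsf_score(model2, rows), s)
})

test_that("Boyce cross-validation calibrates as expected", {
  fx <- shared_landscape()
  truth <- c(ndvi_winter = 1.5)
  used <- simulate_residency_fixes(fx$stack, truth, 1200, seed = 31)
  avail <- simulate_residency_fixes(fx$stack, NULL, 6000, seed = 32)
  cu <- extract_covariates(used, fx$std_stack)
  ca <- extract_covariates(avail, fx$std_stack)
  cu <- cu[!cu$.missing, ]; ca <- ca[!ca$.missing, ]
  spec <- design_spec(continuous = "ndvi_winter", quadratic = FALSE,
                      caps = numeric(0), standardize = FALSE)
  cv <- boyce_cv(cu, ca, spec, seed = 33, random_intercept = FALSE)
  expect_length(cv$rho, 5)
  expect_gt(cv$mean_rho, 0.8)

  # same seed, same folds, same answer
  cv2 <- boyce_cv(cu, ca, spec, seed = 33, random_intercept = FALSE)
  expect_identical(cv$rho, cv2$rho)

  # used points drawn like availability: no calibration signal
  used0 <- simulate_residency_fixes(fx$stack, NULL, 1200, seed = 35)
  cu0 <- extract_covariates(used0, fx$std_stack)
  cu0 <- cu0[!cu0$.missing, ]
  cv0 <- boyce_cv(cu0, ca, spec, seed = 36, random_intercept = FALSE)
  expect_lt(abs(cv0$mean_rho), 0.75)
})
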